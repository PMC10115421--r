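#' @keywords internal
"_PACKAGE"

# Condition cells of the 2x2 design, in canonical order.
# li/hi = low/high stimulus intensity; LE/HE = low/high expectation cue.
CELLS <- c("liLE", "liHE", "hiLE", "hiHE")

#' Condition cells of the 2x2 design
#'
#' Returns the four condition labels in canonical order: low intensity /
#' low expectation, low intensity / high expectation, high intensity /
#' low expectation, high intensity / high expectation.
#'
#' @return Character vector of length 4.
#' @export
condition_cells <- function() CELLS

# Indicator helpers for the three experimental factors. "interaction"
# indexes the prediction-error (cue/stimulus mismatch) cells.
cell_is_hi <- function(cells) cells %in% c("hiLE", "hiHE")
cell_is_he <- function(cells) cells %in% c("liHE", "hiHE")
cell_is_mismatch <- function(cells) cells %in% c("hiLE", "liHE")

factor_indicator <- function(factor, cells) {
  switch(factor,
    intensity = cell_is_hi(cells),
    expectation = cell_is_he(cells),
    interaction = cell_is_mismatch(cells),
    all = rep(TRUE, length(cells)),
    stop("unknown factor: ", factor)
  )
}

#' Derive a stage-specific random seed from a master seed
#'
#' All stochastic stages of the pipeline draw their seed from a single
#' master seed so that runs are reproducible while stages stay isolated.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return An integer seed in [0, 2^31).
#' @export
derive_seed <- function(master, stage) {
  h <- 104729
  for (b in utf8ToInt(stage)) h <- (h * 69069 + b) %% 2^31
  as.integer((master + h) %% .Machine$integer.max)
}

# Evaluate expr with a local RNG state seeded by `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

logmeanexp <- function(x) logsumexp(x) - log(length(x))

# Stable FNV-style hash of an R object, for provenance stamping.
config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 104729
  for (b in as.integer(raw)) h <- (h * 69069 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}
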