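#' Build a subjects-by-cells matrix from a long table
#'
#' @param tab long data frame with columns subject, condition (or cell) and
#'   a value column; one row per subject and cell (rows are averaged if
#'   duplicated).
#' @param value name of the value column.
#' @return n_subjects x 4 matrix with columns in canonical cell order.
#' @export
cell_matrix <- function(tab, value) {
  cellcol <- if ("condition" %in% names(tab)) "condition" else "cell"
  ag <- stats::aggregate(tab[[value]],
                         list(subject = tab$subject, cell = tab[[cellcol]]),
                         FUN = mean)
  subj <- sort(unique(ag$subject))
  M <- matrix(NA_real_, length(subj), 4,
              dimnames = list(subj, condition_cells()))
  for (i in seq_len(nrow(ag)))
    M[as.character(ag$subject[i]), ag$cell[i]] <- ag$x[i]
  if (anyNA(M)) stop("missing subject x cell combinations")
  M
}

# Orthonormal within-design contrasts over the canonical cell order
# (liLE, liHE, hiLE, hiHE).
design_contrasts <- function() {
  list(intensity   = c(-1, -1,  1, 1) / 2,
       expectation = c(-1,  1, -1, 1) / 2,
       interaction = c( 1, -1, -1, 1) / 2)
}

# Orthonormal subject contrasts (helmert, normalized); n x (n-1).
subject_contrasts <- function(n) {
  cs <- stats::contr.helmert(n)
  sweep(cs, 2, sqrt(colSums(cs^2)), "/")
}

# Log marginal likelihood of y = mu*1 + sum_b X_b beta_b + eps under
# Jeffreys priors on (mu, sigma^2) and block g-priors
# beta_b | g_b ~ N(0, sigma^2 g_b I), g_b ~ InvGamma(1/2, r_b^2/2).
# Requires all design columns mutually orthogonal and orthogonal to the
# intercept (asserted), which holds for the balanced cell-matrix designs
# used here; the g integrals are done by tensor-product Gauss-Legendre
# quadrature on t = g/(g + r^2) in (0,1), where the integrand is smooth.
gprior_logml <- function(y, blocks, rscales, nodes = NULL) {
  N <- length(y)
  yt <- y - mean(y)
  yty <- sum(yt^2)
  nb <- length(blocks)
  if (nb == 0)
    return(lgamma((N - 1) / 2) - ((N - 1) / 2) * log(pi) - 0.5 * log(N) -
             ((N - 1) / 2) * log(yty))
  X <- do.call(cbind, blocks)
  blk <- rep(seq_len(nb), vapply(blocks, ncol, 1L))
  XtX <- crossprod(X)
  if (max(abs(XtX - diag(diag(XtX)))) > 1e-8 * max(diag(XtX)) ||
      max(abs(colSums(X))) > 1e-8)
    stop("design columns must be orthogonal (balanced design required)")
  d <- diag(XtX)
  tj <- as.numeric(crossprod(X, yt))
  if (is.null(nodes)) nodes <- c(48, 32, 24, 16)[min(nb, 4)]
  gl <- pracma::gaussLegendre(nodes, 0, 1)
  # per-block node values of g and log prior mass: with g = r^2 t/(1-t),
  # prior density (r^2/2)^(1/2)/gamma(1/2) g^(-3/2) exp(-r^2/(2g)) and
  # jacobian dg/dt = r^2/(1-t)^2
  gvals <- vector("list", nb)
  lwb <- vector("list", nb)
  for (b in seq_len(nb)) {
    r <- rscales[b]
    t <- gl$x
    g <- r^2 * t / (1 - t)
    lp <- 0.5 * log(r^2 / 2) - lgamma(0.5) - 1.5 * log(g) - r^2 / (2 * g)
    lj <- 2 * log(r) - 2 * log(1 - t)
    gvals[[b]] <- g
    lwb[[b]] <- log(gl$w) + lp + lj
  }
  idx <- as.matrix(do.call(expand.grid, rep(list(seq_len(nodes)), nb)))
  ng <- nrow(idx)
  logw <- 0
  for (b in seq_len(nb)) logw <- logw + lwb[[b]][idx[, b]]
  # collapse columns sharing a block and diagonal value d into sufficient
  # statistics (count, sum of t^2): the integrand only depends on those
  logdet <- 0
  Rg <- yty
  for (b in seq_len(nb)) {
    gb <- gvals[[b]][idx[, b]]
    db <- d[blk == b]
    tb <- tj[blk == b]
    for (dv in unique(signif(db, 12))) {
      sel <- signif(db, 12) == dv
      gd <- gb * dv
      logdet <- logdet + sum(sel) * log1p(gd)
      Rg <- Rg - (gd / (1 + gd)) * (sum(tb[sel]^2) / dv)
    }
  }
  logf <- -0.5 * logdet - ((N - 1) / 2) * log(Rg)
  lgamma((N - 1) / 2) - ((N - 1) / 2) * log(pi) - 0.5 * log(N) +
    logsumexp(logw + logf)
}

#' Bayes-factor repeated-measures ANOVA for the 2x2 within-subject design
#'
#' Mixed-model Bayes factors with standardized-effect g-priors: subject as
#' an additive random effect (prior scale 1), the two main effects and the
#' interaction with prior scale 0.5. Each reported BF compares the full
#' model against the matched model with the effect of interest removed
#' (top-down construction); \code{method = "inclusion"} instead averages
#' marginal likelihoods over the standard model space (null, I, E, I+E,
#' I+E+IxE, each with the subject effect) and reports the inclusion ratio.
#' Marginal likelihoods are computed by Gauss-Legendre quadrature over the
#' transformed g parameters (see \code{gprior_logml}). BFs are invariant to rescaling of the data.
#'
#' @param cells subjects x 4 matrix (columns liLE, liHE, hiLE, hiHE), or a
#'   long data frame accepted by \code{\link{cell_matrix}}.
#' @param value value column name when \code{cells} is a data frame.
#' @param rscale_fixed,rscale_random prior scales for fixed (and
#'   interaction) and subject effects.
#' @param method "topdown" (default) or "inclusion".
#' @param nodes quadrature nodes per g dimension (default adapts to model
#'   size; accuracy is tested against brute-force integration).
#' @return Object of class \code{bf_anova}: list with \code{bf} (named
#'   vector: intensity, expectation, interaction) and the model log
#'   marginal likelihoods.
#' @export
bf_rmanova_2x2 <- function(cells, value = "rating", rscale_fixed = 0.5,
                           rscale_random = 1,
                           method = c("topdown", "inclusion"), nodes = NULL) {
  method <- match.arg(method)
  if (is.data.frame(cells)) cells <- cell_matrix(cells, value)
  stopifnot(is.matrix(cells), ncol(cells) == 4, nrow(cells) >= 2)
  if (!is.null(colnames(cells))) cells <- cells[, condition_cells()]
  if (stats::sd(as.vector(cells)) == 0) stop("zero-variance data")
  n <- nrow(cells)
  y <- as.vector(t(cells))                       # subject-major
  cons <- design_contrasts()
  Xs <- kronecker(subject_contrasts(n), rep(1, 4))
  Xc <- lapply(cons, function(ck) kronecker(rep(1, n), matrix(ck, 4)))
  ml <- function(effects) {
    gprior_logml(y, c(list(Xs), Xc[effects]),
                 c(rscale_random, rep(rscale_fixed, length(effects))),
                 nodes = nodes)
  }
  eff <- c("intensity", "expectation", "interaction")
  if (method == "topdown") {
    full <- ml(eff)
    bf <- vapply(eff, function(e) exp(full - ml(setdiff(eff, e))), 0)
    lmls <- c(full = full)
  } else {
    models <- list(null = character(0), I = "intensity", E = "expectation",
                   IE = c("intensity", "expectation"),
                   IExIE = eff)
    lmls <- vapply(models, ml, 0)
    has <- sapply(eff, function(e) vapply(models, function(m) e %in% m, TRUE))
    bf <- vapply(eff, function(e) {
      exp(logmeanexp(lmls[has[, e]]) - logmeanexp(lmls[!has[, e]]))
    }, 0)
  }
  structure(list(bf = bf, logml = lmls, method = method, n = n),
            class = "bf_anova")
}

#' @export
print.bf_anova <- function(x, ...) {
  cat(sprintf("<bf_anova> n = %d subjects (%s)\n", x$n, x$method))
  cat(sprintf("  BF intensity:   %.4g\n", x$bf["intensity"]))
  cat(sprintf("  BF expectation: %.4g\n", x$bf["expectation"]))
  cat(sprintf("  BF interaction: %.4g\n", x$bf["interaction"]))
  invisible(x)
}

#' Classify a feature's response pattern from its three Bayes factors
#'
#' Main effects with BF > 3 signal intensity or expectation coding; an
#' interaction with BF > 3 signals prediction-error coding; more than one
#' BF > 3 is "multiple"; all three BFs < 1/3 is "evidence_against";
#' anything else is "none".
#'
#' @param bfs a \code{\link{bf_rmanova_2x2}} result or a numeric vector
#'   (intensity, expectation, interaction) of positive BFs.
#' @return One of "intensity", "expectation", "PE", "multiple", "none",
#'   "evidence_against".
#' @export
classify_pattern <- function(bfs) {
  if (inherits(bfs, "bf_anova")) bfs <- bfs$bf
  stopifnot(length(bfs) == 3, all(bfs > 0))
  over <- bfs > 3
  if (sum(over) > 1) return("multiple")
  if (over[1]) return("intensity")
  if (over[2]) return("expectation")
  if (over[3]) return("PE")
  if (all(bfs < 1 / 3)) return("evidence_against")
  "none"
}

#' One-sample Bayes factor for asymmetry scores
#'
#' Tests per-subject scores against zero. The default rank-based test
#' replaces the data by a latent-normal representation of the signed
#' ranks: latent values with unit variance and mean delta are Gibbs-sampled
#' under the ordering and sign constraints implied by the observed signed
#' ranks, delta carries a Cauchy(0, rscale) prior (via normal/inverse-gamma
#' augmentation), and BF10 is the Savage-Dickey density ratio at delta = 0
#' with a Rao-Blackwellized posterior density estimate. The parametric
#' method is the standard JZS one-sample t test. The data's overall sign is
#' canonicalized before sampling, making the BF exactly invariant to a
#' global sign flip (the test is two-sided).
#'
#' @param scores numeric vector, n >= 5 (zeros are dropped by the rank
#'   method).
#' @param method "rank" (default) or "parametric".
#' @param rscale Cauchy prior scale on the standardized effect (default
#'   1/sqrt(2)).
#' @param nsamp,burn Gibbs draws and burn-in for the rank method.
#' @param seed internal sampler seed (fixed for reproducibility).
#' @return List (class \code{bf_onesample}) with \code{bf}, \code{mcse}
#'   (Monte-Carlo SE of log BF; 0 for the parametric method) and
#'   \code{posterior_delta} draws for the rank method.
#' @export
bf_onesample <- function(scores, method = c("rank", "parametric"),
                         rscale = 1 / sqrt(2), nsamp = 8000, burn = 1000,
                         seed = 42) {
  method <- match.arg(method)
  x <- scores[is.finite(scores)]
  if (method == "rank") x <- x[x != 0]
  if (length(x) < 5) stop("need at least 5 nonzero scores")
  if (all(scores == 0)) stop("all scores are zero")
  flip <- sum(x) < 0
  if (flip) x <- -x
  if (method == "parametric") {
    n <- length(x); nu <- n - 1
    t <- mean(x) / (stats::sd(x) / sqrt(n))
    lik1 <- function(g)
      (1 + n * g)^(-1 / 2) * (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2)
    # g = rscale^2 / z^2, z ~ N(0,1)
    num <- 2 * stats::integrate(function(z) lik1(rscale^2 / z^2) * stats::dnorm(z),
                                0, Inf, rel.tol = 1e-9)$value
    den <- (1 + t^2 / nu)^(-(nu + 1) / 2)
    return(structure(list(bf = num / den, mcse = 0, method = method),
                     class = "bf_onesample"))
  }
  n <- length(x)
  rk <- rank(abs(x), ties.method = "first")
  sgn <- sign(x)
  ord <- order(rk)                 # subject index at each rank position
  with_seed(seed, {
    z <- sgn * stats::qnorm(0.5 + rk / (2 * (n + 1)))
    delta <- mean(z); g <- rscale^2
    keep_d <- numeric(nsamp)
    keep_dens <- numeric(nsamp)
    rtrunc <- function(m, a, b) {
      pa <- stats::pnorm(a, m, 1); pb <- stats::pnorm(b, m, 1)
      u <- stats::runif(1, pa, pb)
      v <- stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12), m, 1)
      min(max(v, a + 1e-10), b - 1e-10)
    }
    for (it in seq_len(nsamp + burn)) {
      absz <- abs(z)
      for (pos in seq_len(n)) {
        i <- ord[pos]
        lo <- if (pos == 1) 0 else absz[ord[pos - 1]]
        hi <- if (pos == n) Inf else absz[ord[pos + 1]]
        z[i] <- if (sgn[i] > 0) rtrunc(delta, lo, hi)
                else rtrunc(delta, -hi, -lo)
        absz[i] <- abs(z[i])
      }
      v <- 1 / (n + 1 / g)
      delta <- stats::rnorm(1, v * sum(z), sqrt(v))
      g <- 1 / stats::rgamma(1, 1, rate = (rscale^2 + delta^2) / 2)
      if (it > burn) {
        keep_d[it - burn] <- delta
        keep_dens[it - burn] <- stats::dnorm(0, v * sum(z), sqrt(v))
      }
    }
    post0 <- mean(keep_dens)
    prior0 <- 1 / (pi * rscale)
    # batch-means MCSE on the posterior density estimate
    nb <- 40
    bm <- tapply(keep_dens, rep(seq_len(nb), length.out = nsamp), mean)
    mcse_dens <- stats::sd(bm) / sqrt(nb)
    structure(list(bf = prior0 / post0, mcse = mcse_dens / post0,
                   posterior_delta = if (flip) -keep_d else keep_d,
                   method = method),
              class = "bf_onesample")
  })
}

#' @export
print.bf_onesample <- function(x, ...) {
  cat(sprintf("<bf_onesample> BF10 = %.4g (%s%s)\n", x$bf, x$method,
              if (x$mcse > 0) sprintf(", MC SE of log BF ~ %.3g", x$mcse) else ""))
  invisible(x)
}

#' Required sample size for a within-factor repeated-measures ANOVA
#'
#' Smallest N reaching the target power for the within-subject factor of a
#' one-group, m-measurement repeated-measures ANOVA, under the noncentral-F
#' convention of the standard power tools: noncentrality
#' \eqn{\lambda = N f^2 m \epsilon / (1 - \rho)}, numerator df
#' \eqn{(m-1)\epsilon}, denominator df \eqn{(N-1)(m-1)\epsilon}.
#'
#' @param power target power (0, 1).
#' @param alpha significance level (0, 1).
#' @param f Cohen's effect size f (> 0).
#' @param m number of repeated measurements (>= 2).
#' @param rho assumed correlation among repeated measures (default 0.5).
#' @param eps nonsphericity correction (default 1).
#' @return Smallest integer N attaining the target power.
#' @export
#' @examples
#' required_sample_size_rmanova(0.95, 0.05, 0.25, 4)  # 36
required_sample_size_rmanova <- function(power, alpha, f, m, rho = 0.5, eps = 1) {
  stopifnot(power > 0, power < 1, alpha > 0, alpha < 1, f > 0, m >= 2,
            rho >= 0, rho < 1, eps > 0, eps <= 1)
  pw <- function(N) {
    lam <- N * f^2 * m * eps / (1 - rho)
    df1 <- (m - 1) * eps
    df2 <- (N - 1) * (m - 1) * eps
    stats::pf(stats::qf(1 - alpha, df1, df2), df1, df2, ncp = lam,
              lower.tail = FALSE)
  }
  for (N in 2:1e6) if (pw(N) >= power) return(N)
  stop("target power unreachable within N <= 1e6")
}
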