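#' Condition design of the 2x2 cued-pain experiment
#'
#' Two stimulus intensities (li/hi) crossed with two probabilistic
#' expectation cues (LE/HE). The HE cue is followed by a hi stimulus with
#' probability 0.75 and the LE cue with probability 0.25, which yields the
#' unbalanced default cell counts 60/20/20/60 (liLE/liHE/hiLE/hiHE) out of
#' 160 trials.
#'
#' @param cue_contingency P(hi | HE); P(hi | LE) is its complement.
#' @param trials_per_condition named integer vector over the four cells.
#' @return An object of class \code{condition_design}.
#' @export
condition_design <- function(cue_contingency = 0.75,
                             trials_per_condition = c(liLE = 60, liHE = 20,
                                                      hiLE = 20, hiHE = 60)) {
  if (!(cue_contingency > 0 && cue_contingency < 1))
    stop("cue_contingency must lie in (0, 1)")
  if (!setequal(names(trials_per_condition), condition_cells()))
    stop("trials_per_condition must name all four cells")
  trials_per_condition <- trials_per_condition[condition_cells()]
  if (any(trials_per_condition < 1)) stop("all cell trial counts must be >= 1")
  structure(
    list(intensity_levels = c("li", "hi"), expectation_levels = c("LE", "HE"),
         cue_contingency = cue_contingency,
         trials_per_condition = trials_per_condition),
    class = "condition_design"
  )
}

default_rois <- function() c("S1", "cPO", "iPO", "ACC", "cPFC", "iPFC")

#' Effect specifications for the synthetic generator
#'
#' \code{power_effect} describes a multiplicative amplitude change of one
#' ROI's band-limited component under one experimental factor (applied in
#' the trials where the factor's "high" level is active: hi trials for
#' intensity, HE trials for expectation, cue/stimulus-mismatch trials for
#' interaction). \code{coupling_effect} describes an additive change of the
#' lagged shared-component coefficient of an ROI pair; factor "all" sets a
#' condition-independent baseline coupling. \code{directed_edge} adds a
#' bivariate MVAR component in which the source ROI drives the target at a
#' fixed sample lag.
#'
#' @param roi,from,to ROI labels.
#' @param pair length-2 character vector of ROI labels.
#' @param band band name.
#' @param factor one of "intensity", "expectation", "interaction", and for
#'   coupling also "all".
#' @param value amplitude multiplier (power) or coupling coefficient delta.
#' @param lag lag in samples (>= 1).
#' @param coef MVAR cross-coefficient of the source's lagged signal in the
#'   target's dynamics.
#' @return A one-row data frame.
#' @export
power_effect <- function(roi, band, factor, value) {
  data.frame(roi = roi, band = band, factor = factor, value = value,
             stringsAsFactors = FALSE)
}

#' @rdname power_effect
#' @export
coupling_effect <- function(pair, band, factor, value) {
  stopifnot(length(pair) == 2)
  data.frame(roi_a = pair[1], roi_b = pair[2], band = band, factor = factor,
             value = value, stringsAsFactors = FALSE)
}

#' @rdname power_effect
#' @export
directed_edge <- function(from, to, band, lag, coef) {
  data.frame(from = from, to = to, band = band, lag = as.integer(lag),
             coef = coef, stringsAsFactors = FALSE)
}

#' Configuration of the synthetic multi-subject EEG generator
#'
#' Each ROI signal is a sum of unit-variance narrowband Gaussian components
#' (one per band; amplitudes carry condition effects and log-normal
#' between-subject variation), optional lagged shared components carrying
#' phase coupling, optional bivariate MVAR components carrying directed
#' coupling, and white observation noise. A 1-s burn-in per trial is
#' simulated and discarded.
#'
#' @param n_subjects number of simulated participants (default 40).
#' @param rate sampling rate, Hz (default 500).
#' @param epoch_window peri-stimulus window in seconds (default c(-1, 1)).
#' @param rois ROI labels (default the six-region pain network).
#' @param bands list of \code{\link{band_spec}} (default
#'   \code{\link{make_bands}()}).
#' @param power_effects data frame of \code{\link{power_effect}} rows.
#' @param coupling_effects data frame of \code{\link{coupling_effect}} rows.
#' @param directed_edges data frame of \code{\link{directed_edge}} rows.
#' @param subject_sd SD of per-(subject, ROI, band) log-amplitude offsets.
#' @param noise_sd SD of broadband observation noise.
#' @param rating_params list: intercept, intensity, expectation (rating
#'   points), noise_sd, subject_sd.
#' @param trial_loss_prob probability of dropping each trial (emulates
#'   artifact rejection; default 0 = off).
#' @param edge_amp amplitude of MVAR edge components.
#' @param seed master seed; all generator randomness derives from it.
#' @return Object of class \code{simulation_config}.
#' @export
simulation_config <- function(n_subjects = 40, rate = 500,
                              epoch_window = c(-1, 1),
                              rois = default_rois(), bands = make_bands(),
                              power_effects = NULL, coupling_effects = NULL,
                              directed_edges = NULL,
                              subject_sd = 0.2, noise_sd = 1,
                              rating_params = list(intercept = 40, intensity = 20,
                                                   expectation = 5, noise_sd = 8,
                                                   subject_sd = 5),
                              trial_loss_prob = 0, edge_amp = 1, seed = 1) {
  stopifnot(n_subjects >= 1, rate > 0, length(epoch_window) == 2,
            epoch_window[1] < epoch_window[2])
  if (subject_sd < 0 || noise_sd < 0) stop("SDs must be >= 0")
  band_names <- vapply(bands, `[[`, "", "name")
  names(bands) <- band_names
  check_names <- function(x, col, valid, what) {
    if (!is.null(x) && nrow(x) && !all(x[[col]] %in% valid))
      stop("unknown ", what, ": ",
           paste(setdiff(x[[col]], valid), collapse = ", "))
  }
  check_names(power_effects, "roi", rois, "ROI in power_effects")
  check_names(power_effects, "band", band_names, "band in power_effects")
  check_names(coupling_effects, "roi_a", rois, "ROI in coupling_effects")
  check_names(coupling_effects, "roi_b", rois, "ROI in coupling_effects")
  check_names(coupling_effects, "band", band_names, "band in coupling_effects")
  check_names(directed_edges, "from", rois, "ROI in directed_edges")
  check_names(directed_edges, "to", rois, "ROI in directed_edges")
  check_names(directed_edges, "band", band_names, "band in directed_edges")
  if (!is.null(directed_edges) && nrow(directed_edges)) {
    if (any(directed_edges$lag < 1)) stop("directed edge lags must be >= 1 sample")
    check_mvar_stability(directed_edges, bands, rate)
  }
  cfg <- structure(
    list(n_subjects = n_subjects, rate = rate, epoch_window = epoch_window,
         rois = rois, bands = bands,
         power_effects = power_effects, coupling_effects = coupling_effects,
         directed_edges = directed_edges, subject_sd = subject_sd,
         noise_sd = noise_sd, rating_params = rating_params,
         trial_loss_prob = trial_loss_prob, edge_amp = edge_amp,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
  cfg
}

# AR(2) resonator coefficients for a band: poles at radius
# exp(-pi * halfwidth / rate) and angle 2*pi*center/rate, giving a
# narrowband process with roughly the band's half-width.
ar2_coef <- function(band, rate) {
  rho <- exp(-pi * band$smoothing / rate)
  th <- 2 * pi * band$center / rate
  c(2 * rho * cos(th), -rho^2)
}

# Companion-matrix stability of the bivariate MVAR implied by each edge
# (source AR(2); target AR(2) + cross-coefficient at the edge lag). Edges
# sharing a pair and band form one joint system.
check_mvar_stability <- function(edges, bands, rate) {
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to), edges$band)
  bad <- character(0)
  for (k in unique(key)) {
    e <- edges[key == k, , drop = FALSE]
    band <- bands[[e$band[1]]]
    a <- ar2_coef(band, rate)
    p <- max(2, e$lag)
    rois <- unique(c(e$from, e$to))
    d <- length(rois)
    A <- array(0, c(d, d, p))
    for (i in seq_len(d)) A[i, i, 1:2] <- a
    for (j in seq_len(nrow(e))) {
      ti <- match(e$to[j], rois); si <- match(e$from[j], rois)
      A[ti, si, e$lag[j]] <- A[ti, si, e$lag[j]] + e$coef[j]
    }
    comp <- companion_matrix(A)
    if (max(Mod(eigen(comp, only.values = TRUE)$values)) >= 1)
      bad <- c(bad, paste(e$from, "->", e$to, "(", e$band, ")", collapse = "; "))
  }
  if (length(bad))
    stop("unstable MVAR specification for edges: ", paste(bad, collapse = "; "))
  invisible(TRUE)
}

companion_matrix <- function(A) {
  d <- dim(A)[1]; p <- dim(A)[3]
  top <- matrix(A, d, d * p)
  rbind(top, cbind(diag(d * (p - 1)), matrix(0, d * (p - 1), d)))
}

# Unit-variance narrowband Gaussian stream: zero-phase band-passed white
# noise, globally rescaled.
narrowband_stream <- function(n, band, rate) {
  bf <- signal::butter(4, c(band$f_lo, band$f_hi) / (rate / 2), type = "pass")
  pad <- min(2000, n)
  x <- signal::filtfilt(bf, rnorm(n + 2 * pad))
  x <- x[(pad + 1):(pad + n)]
  x / sd(x)
}

# Per-trial amplitude multipliers from effect rows active in each label.
effect_multiplier <- function(rows, labels) {
  mult <- rep(1, length(labels))
  for (j in seq_len(nrow(rows)))
    mult[factor_indicator(rows$factor[j], labels)] <-
      mult[factor_indicator(rows$factor[j], labels)] * rows$value[j]
  mult
}

effect_additive <- function(rows, labels) {
  add <- rep(0, length(labels))
  for (j in seq_len(nrow(rows)))
    add[factor_indicator(rows$factor[j], labels)] <-
      add[factor_indicator(rows$factor[j], labels)] + rows$value[j]
  add
}

#' Simulate multi-subject ROI epochs with known ground truth
#'
#' @param config a \code{\link{simulation_config}}.
#' @param design a \code{\link{condition_design}}.
#' @return A list with \code{epochs} (per-subject \code{\link{epoch_array}}
#'   in ROI space) and \code{truth} (a \code{sim_truth} record of every
#'   applied modulation).
#' @export
simulate_epochs <- function(config, design = condition_design()) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(design, "condition_design"))
  rate <- config$rate
  n_samp <- round(diff(config$epoch_window) * rate)
  burn_n <- round(1 * rate)
  n_tot <- burn_n + n_samp
  rois <- config$rois
  nroi <- length(rois)
  time <- config$epoch_window[1] + (seq_len(n_samp) - 1) / rate

  epochs <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    epochs[[s]] <- with_seed(derive_seed(config$seed, paste0("subject", s)), {
      labels <- rep(condition_cells(), times = design$trials_per_condition)
      labels <- sample(labels)
      if (config$trial_loss_prob > 0) {
        keep <- runif(length(labels)) > config$trial_loss_prob
        # never empty a cell entirely
        for (cc in condition_cells())
          if (!any(keep & labels == cc)) keep[which(labels == cc)[1]] <- TRUE
        labels <- labels[keep]
      }
      nt <- length(labels)
      L <- nt * n_tot
      dat <- array(0, c(nt, nroi, n_tot))

      # per-(subject, roi, band) log-normal amplitude offsets
      subj_amp <- matrix(exp(config$subject_sd * rnorm(nroi * length(config$bands))),
                         nroi, length(config$bands),
                         dimnames = list(rois, names(config$bands)))

      for (b in names(config$bands)) {
        band <- config$bands[[b]]
        for (r in seq_len(nroi)) {
          x <- matrix(narrowband_stream(L, band, rate), nt, n_tot, byrow = TRUE)
          amp <- rep(subj_amp[r, b], nt)
          pe <- config$power_effects
          if (!is.null(pe)) {
            rows <- pe[pe$roi == rois[r] & pe$band == b, , drop = FALSE]
            if (nrow(rows)) amp <- amp * effect_multiplier(rows, labels)
          }
          dat[, r, ] <- dat[, r, ] + x * amp
        }
      }

      # lagged shared components -> nonzero-lag phase coupling
      ce <- config$coupling_effects
      if (!is.null(ce) && nrow(ce)) {
        key <- paste(ce$roi_a, ce$roi_b, ce$band)
        for (k in unique(key)) {
          rows <- ce[key == k, , drop = FALSE]
          band <- config$bands[[rows$band[1]]]
          lag <- max(1L, round(rate / (4 * band$center)))
          c0 <- narrowband_stream(L + lag, band, rate)
          kap <- effect_additive(rows, labels)
          ia <- match(rows$roi_a[1], rois); ib <- match(rows$roi_b[1], rois)
          xa <- matrix(c0[(lag + 1):(lag + L)], nt, n_tot, byrow = TRUE)
          xb <- matrix(c0[1:L], nt, n_tot, byrow = TRUE)
          dat[, ia, ] <- dat[, ia, ] + xa * kap
          dat[, ib, ] <- dat[, ib, ] + xb * kap
        }
      }

      # directed MVAR components (source AR(2) resonator drives target)
      de <- config$directed_edges
      if (!is.null(de) && nrow(de)) {
        for (j in seq_len(nrow(de))) {
          band <- config$bands[[de$band[j]]]
          a <- ar2_coef(band, rate)
          lag <- de$lag[j]
          xs <- stats::filter(rnorm(L + lag), a, method = "recursive")
          drive <- de$coef[j] * xs[1:L]
          xs <- as.numeric(xs[(lag + 1):(lag + L)])
          xt <- as.numeric(stats::filter(rnorm(L) + drive, a, method = "recursive"))
          xs <- xs / sd(xs); xt <- xt / sd(xt)
          isrc <- match(de$from[j], rois); itgt <- match(de$to[j], rois)
          dat[, isrc, ] <- dat[, isrc, ] +
            config$edge_amp * matrix(xs, nt, n_tot, byrow = TRUE)
          dat[, itgt, ] <- dat[, itgt, ] +
            config$edge_amp * matrix(xt, nt, n_tot, byrow = TRUE)
        }
      }

      dat <- dat + array(config$noise_sd * rnorm(length(dat)), dim(dat))
      epoch_array(dat[, , (burn_n + 1):n_tot, drop = FALSE], rate = rate,
                  time = time, labels = labels, space = "roi", channels = rois)
    })
  }

  truth <- structure(
    list(
      modulated_power_features =
        if (is.null(config$power_effects)) data.frame()
        else unique(config$power_effects[config$power_effects$factor != "all",
                                         c("roi", "band", "factor")]),
      modulated_coupling_features =
        if (is.null(config$coupling_effects)) data.frame()
        else unique(config$coupling_effects[config$coupling_effects$factor != "all",
                                            c("roi_a", "roi_b", "band", "factor")]),
      true_directions =
        if (is.null(config$directed_edges)) data.frame()
        else unique(config$directed_edges[, c("from", "to", "band")]),
      rating_effects = config$rating_params
    ),
    class = "sim_truth"
  )
  list(epochs = epochs, truth = truth)
}

#' Simulate per-subject pain ratings for the 2x2 design
#'
#' Cell mean = intercept + intensity effect (hi cells) + expectation effect
#' (HE cells) + subject offset + noise; no interaction term is generated.
#' Ratings are clipped to the 0-100 scale, with a warning when the
#' generating means fall outside it by more than 3 noise SDs.
#'
#' @inheritParams simulate_epochs
#' @return Data frame (class \code{rating_table}) with columns subject,
#'   cell, rating.
#' @export
simulate_ratings <- function(config, design = condition_design()) {
  p <- config$rating_params
  stopifnot(!is.null(p$intercept))
  cells <- condition_cells()
  mu <- p$intercept + p$intensity * cell_is_hi(cells) +
    p$expectation * cell_is_he(cells)
  if (any(mu < -3 * p$noise_sd | mu > 100 + 3 * p$noise_sd))
    warning("rating parameters place cell means outside [0, 100] by > 3 noise SDs; ",
            "clipping will distort the ANOVA")
  with_seed(derive_seed(config$seed, "ratings"), {
    out <- expand.grid(subject = seq_len(config$n_subjects), cell = cells,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    offs <- rnorm(config$n_subjects, 0, p$subject_sd)
    out$rating <- mu[match(out$cell, cells)] + offs[out$subject] +
      rnorm(nrow(out), 0, p$noise_sd)
    out$rating <- pmin(100, pmax(0, out$rating))
    class(out) <- c("rating_table", "data.frame")
    out
  })
}

#' Project ROI epochs to sensor space through a leadfield
#'
#' Instantaneous (zero-lag) linear mixing plus independent white sensor
#' noise — the forward model against which beamforming and the phase-lag
#' index's volume-conduction insensitivity are tested.
#'
#' @param epochs ROI-space \code{\link{epoch_array}}.
#' @param leadfield a \code{\link{leadfield}} whose source count matches the
#'   ROI count.
#' @param sensor_noise_sd SD of additive sensor noise (default 0).
#' @param seed seed for the sensor noise.
#' @return Sensor-space \code{epoch_array}.
#' @export
project_to_sensors <- function(epochs, leadfield, sensor_noise_sd = 0, seed = 1) {
  stopifnot(inherits(epochs, "epoch_array"), epochs$space == "roi")
  G <- leadfield$gain
  if (ncol(G) != dim(epochs$data)[2])
    stop("leadfield source count (", ncol(G), ") does not match ROI count (",
         dim(epochs$data)[2], ")")
  n <- dim(epochs$data)
  out <- array(0, c(n[1], nrow(G), n[3]))
  for (i in seq_len(n[1]))
    out[i, , ] <- G %*% epochs$data[i, , ]
  if (sensor_noise_sd > 0)
    out <- out + with_seed(seed, array(rnorm(length(out), 0, sensor_noise_sd), dim(out)))
  epoch_array(out, rate = epochs$rate, time = epochs$time,
              labels = epochs$labels, space = "sensor",
              channels = paste0("sens", seq_len(nrow(G))))
}
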