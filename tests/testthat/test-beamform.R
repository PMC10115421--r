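test_that("LCMV weights pass their own leadfield column with unit gain", {
  set.seed(21)
  for (k in 1:3) {
    lf <- random_leadfield(24, default_rois(), seed = 100 + k)
    C <- crossprod(matrix(rnorm(200 * 24), 200)) / 200
    flt <- lcmv_filter(lf, C, reg = 0.05)
    gains <- diag(flt$weights %*% lf$gain)
    expect_equal(gains, rep(1, 6), tolerance = 1e-6)
  }
})

test_that("the beamformer suppresses interfering sources", {
  set.seed(22)
  b <- make_bands()$alpha
  lf <- random_leadfield(32, c("S1", "ACC"), seed = 7)
  # two independent alpha sources, source 1 much stronger
  x1 <- 5 * nb_trials(20, 500, b)
  x2 <- nb_trials(20, 500, b)
  src <- two_channel_epochs(x1, x2)
  src$channels <- c("S1", "ACC")
  sens <- project_to_sensors(src, lf, sensor_noise_sd = 0.05, seed = 23)
  C <- band_covariance(sens, b)
  flt <- lcmv_filter(lf, C, reg = 0.05, band = b)
  rec <- apply_filter(sens, flt)
  # compare against the identically band-passed sources, so per-trial
  # filter edge transients affect both sides equally
  ref <- painconn:::bandpass_epochs(src, b)
  # reconstructed ACC should correlate with true source 2, not source 1
  r_own <- cor(as.vector(rec$data[, 2, ]), as.vector(ref$data[, 2, ]))
  r_leak <- cor(as.vector(rec$data[, 2, ]), as.vector(ref$data[, 1, ]))
  expect_gt(abs(r_own), 0.9)
  expect_lt(abs(r_leak), 0.2)
})

test_that("source to sensor to source round trip preserves band power ordering", {
  set.seed(24)
  b <- make_bands()$gamma
  lf <- random_leadfield(32, c("S1", "ACC"), seed = 9)
  amps <- c(3, 1)
  x1 <- amps[1] * nb_trials(16, 500, b)
  x2 <- amps[2] * nb_trials(16, 500, b)
  src <- two_channel_epochs(x1, x2)
  src$channels <- c("S1", "ACC")
  sens <- project_to_sensors(src, lf, sensor_noise_sd = 0, seed = 25)
  flt <- lcmv_filter(lf, band_covariance(sens, b), reg = 0.05, band = b)
  rec <- apply_filter(sens, flt)
  ref <- painconn:::bandpass_epochs(src, b)
  p_true <- attr(band_power(ref, b), "per_trial")
  p_rec <- attr(band_power(rec, b), "per_trial")
  expect_gt(cor(as.vector(p_true), as.vector(p_rec)), 0.95)
})

test_that("free-orientation sources are reconstructed via the optimal orientation", {
  set.seed(26)
  b <- make_bands()$alpha
  ns <- 32
  # two free-orientation sources with hidden true orientations u1, u2
  with_seed(27, {
    L1 <- matrix(rnorm(ns * 3), ns)
    L2 <- matrix(rnorm(ns * 3), ns)
  })
  u1 <- c(0.6, -0.64, 0.48)
  u2 <- c(0.48, 0.6, 0.64)
  g1 <- as.numeric(L1 %*% u1)
  g2 <- as.numeric(L2 %*% u2)
  x1 <- nb_trials(16, 500, b)
  x2 <- nb_trials(16, 500, b)
  src <- two_channel_epochs(x1, x2)
  src$channels <- c("S1", "ACC")
  # mix through the true effective columns
  sens0 <- project_to_sensors(src, leadfield(cbind(g1, g2), c("S1", "ACC")),
                              sensor_noise_sd = 0.02, seed = 28)
  # reconstruct knowing only the 3-column leadfields, not the orientations
  lf3 <- leadfield(cbind(g1, g2), c("S1", "ACC"), gain3 = list(L1, L2))
  flt <- lcmv_filter(lf3, band_covariance(sens0, b), reg = 0.05, band = b)
  rec <- apply_filter(sens0, flt)
  ref <- painconn:::bandpass_epochs(src, b)
  expect_gt(abs(cor(as.vector(rec$data[, 1, ]), as.vector(ref$data[, 1, ]))), 0.9)
  expect_gt(abs(cor(as.vector(rec$data[, 2, ]), as.vector(ref$data[, 2, ]))), 0.9)
})

test_that("degenerate covariances are caught or repaired by regularization", {
  lf <- random_leadfield(16, c("S1", "ACC"), seed = 2)
  Csing <- matrix(0, 16, 16)
  expect_error(lcmv_filter(lf, Csing, reg = 0), "singular|increase")
  # rank-deficient but regularized: must work and keep unit gain
  v <- rnorm(16)
  C1 <- tcrossprod(v)
  flt <- lcmv_filter(lf, C1, reg = 0.05)
  expect_equal(diag(flt$weights %*% lf$gain), rep(1, 2), tolerance = 1e-6)
  expect_error(leadfield(cbind(v, 2 * v), c("a", "b")), "full column rank")
})

test_that("filters refuse mismatched bands and sensor counts", {
  b <- make_bands()
  lf <- random_leadfield(16, c("S1", "ACC"), seed = 3)
  C <- diag(16)
  flt <- lcmv_filter(lf, C, band = b$alpha)
  d <- array(rnorm(4 * 16 * 100), c(4, 16, 100))
  ep <- epoch_array(d, rate = 500, t0 = 0, labels = condition_cells(),
                    space = "sensor")
  expect_error(apply_filter(ep, flt, band = b$gamma), "band mismatch")
  d8 <- array(rnorm(4 * 8 * 100), c(4, 8, 100))
  ep8 <- epoch_array(d8, rate = 500, t0 = 0, labels = condition_cells(),
                     space = "sensor")
  expect_error(apply_filter(ep8, flt), "sensor counts")
})

test_that("leadfields round-trip through the text reader", {
  lf <- random_leadfield(8, c("S1", "ACC", "cPFC"), seed = 4)
  path <- tempfile(fileext = ".txt")
  write.table(lf$gain, path, row.names = FALSE,
              col.names = c("S1", "ACC", "cPFC"))
  back <- read_leadfield(path)
  expect_equal(back$gain, lf$gain, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(back$roi_labels, c("S1", "ACC", "cPFC"))
  unlink(path)
})
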