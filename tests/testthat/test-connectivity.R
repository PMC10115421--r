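test_that("dwPLI is insensitive to zero-lag mixing of independent sources", {
  set.seed(41)
  b <- make_bands()$alpha
  s1 <- nb_trials(60, 500, b)
  s2 <- nb_trials(60, 500, b)
  # instantaneous mixtures of the same two independent sources
  ep <- two_channel_epochs(0.8 * s1 + 0.2 * s2, 0.3 * s1 + 0.7 * s2)
  dw <- dwpli(cross_spectra(ep, b))
  expect_lt(abs(dw$dwpli), 0.05)
})

test_that("dwPLI detects genuinely lagged coupling", {
  set.seed(42)
  b <- make_bands()$alpha
  lag <- round(500 / 10 / 4)                 # quarter period at 10 Hz
  long <- t(vapply(1:40, function(i) narrowband(500 + lag, b), numeric(500 + lag)))
  x <- long[, (lag + 1):(lag + 500)]
  y <- long[, 1:500] + 0.1 * nb_trials(40, 500, b)
  dw <- dwpli(cross_spectra(two_channel_epochs(x, y), b))
  expect_gt(dw$dwpli, 0.8)
})

test_that("the debiased estimator is centred under independence, the plain one is not", {
  set.seed(43)
  b <- make_bands()$beta
  nrep <- 50
  res <- t(replicate(nrep, {
    ep <- two_channel_epochs(nb_trials(30, 500, b), nb_trials(30, 500, b))
    cs <- cross_spectra(ep, b)
    c(d = dwpli(cs)$dwpli, p = dwpli(cs, debias = FALSE)$dwpli)
  }))
  se <- sd(res[, "d"]) / sqrt(nrep)
  expect_lt(abs(mean(res[, "d"])), 2 * se)
  expect_gt(mean(res[, "p"]), mean(res[, "d"]) + 2 * se)
})

test_that("MVAR least squares recovers known coefficients", {
  set.seed(44)
  A <- array(0, c(2, 2, 2))
  A[, , 1] <- rbind(c(0.5, 0), c(0.4, 0.5))
  A[, , 2] <- rbind(c(-0.7, 0), c(0, -0.7))
  nt <- 20; ns <- 400
  x <- array(0, c(nt, 2, ns))
  for (i in seq_len(nt)) {
    e <- matrix(rnorm(2 * (ns + 100)), 2)
    z <- matrix(0, 2, ns + 100)
    for (t in 3:(ns + 100))
      z[, t] <- A[, , 1] %*% z[, t - 1] + A[, , 2] %*% z[, t - 2] + e[, t]
    x[i, , ] <- z[, 101:(ns + 100)]
  }
  f <- fit_mvar(x, order = 2)
  expect_true(f$stable)
  expect_lt(max(abs(f$A - A)), 0.05)
  expect_lt(max(abs(f$sigma - diag(2))), 0.1)
  expect_error(fit_mvar(x[, , 1:15], order = 2), "10\\*order")
  # a constant channel makes the regression ill-conditioned
  xc <- x; xc[, 2, ] <- 1e-14 * xc[, 2, ]
  xc[, 2, ] <- 0
  expect_error(fit_mvar(xc + 0, order = 2), "ill-conditioned")
})

test_that("BIC order selection finds the generating order", {
  set.seed(45)
  A <- array(0, c(2, 2, 3))
  A[, , 1] <- diag(c(0.4, 0.3)); A[, , 2] <- diag(c(-0.3, -0.2))
  A[, , 3] <- rbind(c(0.3, 0.2), c(0, 0.3))
  x <- array(0, c(10, 2, 500))
  for (i in 1:10) {
    z <- matrix(rnorm(2 * 600), 2)
    for (t in 4:600)
      z[, t] <- A[, , 1] %*% z[, t - 1] + A[, , 2] %*% z[, t - 2] +
        A[, , 3] %*% z[, t - 3] + z[, t]
    x[i, , ] <- z[, 101:600]
  }
  expect_equal(select_mvar_order(x, max_order = 8), 3)
})

test_that("PDC columns are unit-normalized and detect direction on a known system", {
  set.seed(46)
  # unidirectional 1 -> 2 alpha-resonant system
  rho <- 0.95; f0 <- 10; rate <- 500
  a1 <- 2 * rho * cos(2 * pi * f0 / rate); a2 <- -rho^2
  nt <- 30; ns <- 500
  x <- array(0, c(nt, 2, ns))
  for (i in seq_len(nt)) {
    z <- matrix(rnorm(2 * (ns + 200)), 2)
    for (t in 3:(ns + 200)) {
      z[1, t] <- a1 * z[1, t - 1] + a2 * z[1, t - 2] + rnorm(1)
      z[2, t] <- a1 * z[2, t - 1] + a2 * z[2, t - 2] + 0.5 * z[1, t - 2] + rnorm(1)
    }
    x[i, , ] <- z[, 201:(ns + 200)]
  }
  f <- fit_mvar(x, order = 4)
  pv <- pdc(f, make_bands()$alpha, rate, full = TRUE)
  # column normalization identity at every frequency
  colnorm <- apply(pv$matrix, 3, function(M) colSums(M^2))
  expect_equal(as.vector(colnorm), rep(1, 2 * length(pv$freqs)),
               tolerance = 1e-12)
  expect_gt(pv$pdc_ab, pv$pdc_ba)
  expect_gt(asymmetry_score(pv$pdc_ab, pv$pdc_ba), 0.5)
})

test_that("asymmetry score has the documented range and edge behaviour", {
  expect_equal(asymmetry_score(0.4, 0.1), 0.6)
  expect_equal(asymmetry_score(0.1, 0.4), -0.6)
  expect_equal(asymmetry_score(0.3, 0), 1)
  a0 <- asymmetry_score(0, 0)
  expect_true(is.na(a0))
  expect_true(isTRUE(attr(a0, "undefined")))
  expect_error(asymmetry_score(-0.1, 0.2))
})

test_that("unstable models refuse to produce PDC", {
  f <- structure(list(A = array(1.2, c(2, 2, 1)), sigma = diag(2),
                      order = 1, stable = FALSE), class = "mvar_fit")
  expect_error(pdc(f, make_bands()$alpha, 500), "unstable")
})

test_that("connectivity_table computes dwPLI per subject, cell, pair and band", {
  set.seed(47)
  eps <- lapply(1:2, function(s) {
    d <- array(rnorm(8 * 3 * 400), c(8, 3, 400))
    epoch_array(d, rate = 500, t0 = 0, labels = rep(condition_cells(), 2),
                channels = c("S1", "ACC", "cPFC"))
  })
  ct <- connectivity_table(eps, make_bands())
  expect_equal(nrow(ct), 2 * 4 * 3 * 3)   # subjects x cells x pairs x bands
  expect_true(all(ct$dwpli <= 1 & ct$dwpli >= -1))
  ep1 <- subset_epochs(eps[[1]], trials = which(eps[[1]]$labels == "liLE"))
  manual <- dwpli(cross_spectra(ep1, make_bands()$alpha))
  got <- ct[ct$subject == 1 & ct$condition == "liLE" & ct$band == "alpha", ]
  expect_equal(got$dwpli, manual$dwpli)
})

test_that("directed_analysis restricts to mismatch trials when asked", {
  set.seed(48)
  b <- make_bands()$alpha
  eps <- lapply(1:2, function(s) {
    d <- array(rnorm(12 * 2 * 600), c(12, 2, 600))
    epoch_array(d, rate = 500, t0 = -0.2, labels = rep(condition_cells(), 3),
                channels = c("cPFC", "S1"))
  })
  da <- directed_analysis(eps, c("cPFC", "S1"), b, "mismatch_only", order = 3)
  expect_equal(nrow(da), 2)
  expect_equal(attr(da, "trial_filter"), "mismatch_only")
  ep1 <- eps[[1]]
  keep <- which(cell_is_mismatch(ep1$labels))
  expect_length(keep, 6)
  sub <- subset_epochs(ep1, trials = keep, channels = c("cPFC", "S1"))
  idx <- painconn:::window_index(sub, c(0, 1))
  f <- fit_mvar(sub$data[, , idx, drop = FALSE], 3)
  pv <- pdc(f, b, 500)
  expect_equal(da$pdc_ab[1], pv$pdc_ab)
})
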