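test_that("the generator is bit-identical under a fixed seed", {
  cfg <- simulation_config(n_subjects = 2, seed = 5)
  des <- condition_design(trials_per_condition = c(liLE = 6, liHE = 2,
                                                   hiLE = 2, hiHE = 6))
  s1 <- simulate_epochs(cfg, des)
  s2 <- simulate_epochs(cfg, des)
  expect_identical(s1$epochs[[1]]$data, s2$epochs[[1]]$data)
  expect_identical(s1$epochs[[2]]$labels, s2$epochs[[2]]$labels)
  r1 <- simulate_ratings(cfg)
  r2 <- simulate_ratings(cfg)
  expect_identical(r1, r2)
})

test_that("configured power effects raise band power in the targeted cells only", {
  cfg <- simulation_config(
    n_subjects = 8, subject_sd = 0, seed = 31,
    power_effects = power_effect("S1", "gamma", "intensity", 1.5))
  des <- condition_design(trials_per_condition = c(liLE = 20, liHE = 20,
                                                   hiLE = 20, hiHE = 20))
  sim <- simulate_epochs(cfg, des)
  bands <- make_bands()
  # oracle: direct per-trial band-power contrast, pooled across subjects
  contrast <- function(roi, band) {
    tv <- sapply(sim$epochs, function(ep) {
      sl <- band_power(ep, bands[[band]])
      sl <- sl[sl$roi == roi, ]
      hi <- sl$power[sl$condition %in% c("hiLE", "hiHE")]
      li <- sl$power[sl$condition %in% c("liLE", "liHE")]
      mean(hi) / mean(li)
    })
    mean(tv)
  }
  expect_gt(contrast("S1", "gamma"), 1.5)      # amplitude x1.5 => power x2.25
  expect_lt(abs(contrast("S1", "alpha") - 1), 0.15)
  expect_lt(abs(contrast("ACC", "gamma") - 1), 0.15)
  # ground truth records exactly the applied modulation
  expect_equal(nrow(sim$truth$modulated_power_features), 1)
  expect_equal(sim$truth$modulated_power_features$roi, "S1")
  expect_equal(sim$truth$modulated_power_features$factor, "intensity")
})

test_that("rating cell means follow the additive generating model", {
  cfg <- simulation_config(
    n_subjects = 3, seed = 2,
    rating_params = list(intercept = 40, intensity = 20, expectation = 5,
                         noise_sd = 0, subject_sd = 0))
  r <- simulate_ratings(cfg)
  M <- cell_matrix(r, "rating")
  expect_equal(unname(M[1, ]), c(40, 45, 60, 65))
  expect_equal(unname(M[3, ]), c(40, 45, 60, 65))

  expect_warning(simulate_ratings(simulation_config(
    n_subjects = 2, seed = 2,
    rating_params = list(intercept = 95, intensity = 30, expectation = 5,
                         noise_sd = 2, subject_sd = 0))), "outside")
})

test_that("rmANOVA on generated ratings is calibrated under null and sensitive to effects", {
  null_bf <- t(replicate(30, {
    cfg <- simulation_config(
      n_subjects = 12, seed = sample.int(1e6, 1),
      rating_params = list(intercept = 50, intensity = 0, expectation = 0,
                           noise_sd = 8, subject_sd = 5))
    bf_rmanova_2x2(cell_matrix(simulate_ratings(cfg), "rating"))$bf
  }))
  expect_lt(mean(null_bf[, "intensity"] > 3), 0.25)
  expect_lt(mean(null_bf[, "expectation"] > 3), 0.25)

  hit <- replicate(20, {
    cfg <- simulation_config(
      n_subjects = 40, seed = sample.int(1e6, 1),
      rating_params = list(intercept = 40, intensity = 20, expectation = 5,
                           noise_sd = 8, subject_sd = 5))
    bf_rmanova_2x2(cell_matrix(simulate_ratings(cfg), "rating"))$bf["intensity"] > 3
  })
  expect_gte(mean(hit), 0.95)
})

test_that("invalid effect specifications are rejected with explanations", {
  expect_error(simulation_config(
    power_effects = power_effect("BadROI", "gamma", "intensity", 2)),
    "unknown ROI")
  expect_error(simulation_config(
    coupling_effects = coupling_effect(c("S1", "ACC"), "delta", "all", 0.5)),
    "unknown band")
  expect_error(simulation_config(
    directed_edges = directed_edge("cPFC", "S1", "alpha", lag = 0, coef = 0.5)),
    "lags must be >= 1")
  # destabilizing cross-coefficient names the offending edge
  expect_error(simulation_config(
    directed_edges = rbind(directed_edge("cPFC", "S1", "alpha", 1, 2.5),
                           directed_edge("S1", "cPFC", "alpha", 1, 2.5))),
    "unstable MVAR.*cPFC")
})

test_that("sensor projection is instantaneous linear mixing plus noise", {
  d <- array(rnorm(3 * 2 * 100), c(3, 2, 100))
  ep <- epoch_array(d, rate = 500, t0 = 0,
                    labels = c("liLE", "hiHE", "hiLE"))
  # identity-like leadfield: one sensor per source
  lf <- leadfield(diag(2), c("a", "b")[1:2])
  sens <- project_to_sensors(ep, lf, sensor_noise_sd = 0)
  expect_equal(sens$data, ep$data)
  expect_equal(sens$space, "sensor")

  # 2 sources -> 32 sensors, no noise: rank of sensor covariance is 2
  lf32 <- random_leadfield(32, c("a", "b")[1:2], seed = 3)
  s32 <- project_to_sensors(ep, lf32, sensor_noise_sd = 0)
  X <- matrix(aperm(s32$data, c(3, 1, 2)), ncol = 32)
  expect_equal(qr(cov(X))$rank, 2)

  # with noise: sensor covariance = mixed source covariance + sigma^2 I
  set.seed(4)
  nlong <- 4000
  dl <- array(rnorm(1 * 2 * nlong), c(1, 2, nlong))
  epl <- epoch_array(dl, rate = 500, t0 = 0, labels = "liLE")
  sl <- project_to_sensors(epl, lf32, sensor_noise_sd = 0.5, seed = 8)
  Cemp <- cov(t(sl$data[1, , ]))
  Cth <- lf32$gain %*% t(lf32$gain) + 0.25 * diag(32)
  expect_lt(max(abs(Cemp - Cth)), 0.1)

  expect_error(project_to_sensors(ep, random_leadfield(16, letters[1:5]), 0),
               "does not match")
})
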