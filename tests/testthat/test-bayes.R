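test_that("the g-prior marginal likelihood matches a dense brute-force oracle", {
  set.seed(51)
  n <- 5
  Y <- make_cells(n, intensity = 1.2, subject_sd = 0.5)
  y <- as.vector(t(Y))
  for (eff in list(character(0), "intensity",
                   c("intensity", "expectation"),
                   c("intensity", "expectation", "interaction"))) {
    blocks <- anova_blocks(n, eff)
    rs <- c(1, rep(0.5, length(eff)))
    fast <- painconn:::gprior_logml(y, blocks, rs)
    slow <- mc_dense_logml(y, blocks, rs, nmc = 40000)
    # 5% relative error on the BF scale (i.e. in the exponent difference)
    expect_lt(abs(fast - slow), 0.05, label = paste(
      "logml mismatch for effects:", paste(eff, collapse = "+")))
  }
})

test_that("rmANOVA Bayes factors are scale invariant and label-correct", {
  set.seed(52)
  Y <- make_cells(8, intensity = 2, subject_sd = 1)
  b1 <- bf_rmanova_2x2(Y)
  b2 <- bf_rmanova_2x2(Y * 37.2)
  expect_equal(b1$bf, b2$bf, tolerance = 1e-8)
  expect_gt(b1$bf["intensity"], 3)
  expect_lt(b1$bf["expectation"], 3)
  # an interaction-only pattern loads on the interaction BF
  set.seed(53)
  Yi <- make_cells(30, interaction = 1.5, subject_sd = 1)
  bi <- bf_rmanova_2x2(Yi)
  expect_gt(bi$bf["interaction"], bi$bf["intensity"])
  expect_gt(bi$bf["interaction"], 3)
})

test_that("rmANOVA accepts long data frames and rejects degenerate input", {
  set.seed(54)
  df <- expand.grid(subject = 1:6, condition = condition_cells(),
                    stringsAsFactors = FALSE)
  df$rating <- rnorm(nrow(df)) + 2 * (df$condition %in% c("hiLE", "hiHE"))
  b <- bf_rmanova_2x2(df)
  M <- cell_matrix(df, "rating")
  expect_equal(b$bf, bf_rmanova_2x2(M)$bf)
  expect_error(bf_rmanova_2x2(matrix(1, 6, 4)), "zero-variance")
  expect_error(bf_rmanova_2x2(M[1, , drop = FALSE]))
})

test_that("topdown and inclusion Bayes factors agree in direction", {
  set.seed(55)
  Y <- make_cells(12, intensity = 1.5, subject_sd = 1)
  bt <- bf_rmanova_2x2(Y, method = "topdown")
  bi <- bf_rmanova_2x2(Y, method = "inclusion")
  expect_gt(bt$bf["intensity"], 3)
  expect_gt(bi$bf["intensity"], 3)
  expect_lt(bt$bf["expectation"], 3)
  expect_lt(bi$bf["expectation"], 3)
})

test_that("pattern classification implements the documented rules", {
  expect_equal(classify_pattern(c(5, 1, 1)), "intensity")
  expect_equal(classify_pattern(c(1, 4, 1)), "expectation")
  expect_equal(classify_pattern(c(1, 1, 8)), "PE")
  expect_equal(classify_pattern(c(5, 5, 1)), "multiple")
  expect_equal(classify_pattern(c(0.2, 0.3, 0.1)), "evidence_against")
  expect_equal(classify_pattern(c(1, 1, 1)), "none")
  expect_error(classify_pattern(c(-1, 1, 1)))
})

test_that("the rank-based one-sample BF detects shifts and is sign-flip invariant", {
  set.seed(56)
  x <- rnorm(25, mean = 0.8)
  b_pos <- bf_onesample(x)
  expect_gt(b_pos$bf, 10)
  b_neg <- bf_onesample(-x)
  expect_identical(b_pos$bf, b_neg$bf)
  # null scores: BF should not be large, and MCSE should be reported
  x0 <- rnorm(25, mean = 0)
  b0 <- bf_onesample(x0)
  expect_lt(b0$bf, 3)
  expect_gt(b0$mcse, 0)
  expect_error(bf_onesample(c(0.1, -0.2, 0.3)), "at least 5")
})

test_that("the rank BF is invariant to monotone transformations of the scores", {
  set.seed(57)
  x <- rnorm(20, mean = 0.6)
  b1 <- bf_onesample(x)
  b2 <- bf_onesample(sign(x) * abs(x)^3)   # monotone, sign-preserving
  expect_identical(b1$bf, b2$bf)
})

test_that("the parametric one-sample BF matches the standard JZS t-test formula", {
  set.seed(58)
  x <- rnorm(30, 0.5)
  b <- bf_onesample(x, method = "parametric")
  # independent oracle: one-dimensional integral over the Cauchy prior
  n <- length(x); tv <- mean(x) / (sd(x) / sqrt(n)); nu <- n - 1
  f <- function(d) suppressWarnings(dt(tv, nu, ncp = d * sqrt(n))) *
    dcauchy(d, 0, 1 / sqrt(2))
  m1 <- integrate(f, -Inf, Inf)$value
  m0 <- dt(tv, nu)
  expect_equal(b$bf, m1 / m0, tolerance = 1e-4)
  expect_equal(b$mcse, 0)
})

test_that("repeated-measures power computation reproduces the cited convention", {
  expect_equal(required_sample_size_rmanova(0.95, 0.05, 0.25, 4), 36)
  expect_error(required_sample_size_rmanova(1.2, 0.05, 0.25, 4))
  # monotone: stricter power needs more subjects
  n99 <- required_sample_size_rmanova(0.99, 0.05, 0.25, 4)
  expect_gt(n99, 36)
  # larger effect needs fewer
  expect_lt(required_sample_size_rmanova(0.95, 0.05, 0.4, 4), 36)
})
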