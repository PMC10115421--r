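# Shared fixtures: all synthetic, generated at test time.

RATE <- 500

# unit-variance narrowband noise vector
narrowband <- function(n, band, rate = RATE) {
  bf <- signal::butter(4, c(band$f_lo, band$f_hi) / (rate / 2), type = "pass")
  x <- signal::filtfilt(bf, rnorm(n + 2000))[1001:(1000 + n)]
  x / sd(x)
}

# epoch array from two trials x samples matrices
two_channel_epochs <- function(x1, x2, rate = RATE, t0 = 0) {
  nt <- nrow(x1)
  d <- array(0, c(nt, 2, ncol(x1)))
  d[, 1, ] <- x1
  d[, 2, ] <- x2
  epoch_array(d, rate = rate, t0 = t0,
              labels = rep(condition_cells(), length.out = nt))
}

# trials of narrowband noise as a trials x samples matrix
nb_trials <- function(nt, ns, band, rate = RATE) {
  t(vapply(seq_len(nt), function(i) narrowband(ns, band, rate), numeric(ns)))
}

# brute-force log evidence of the logistic model by 2-D grid quadrature
quad_logistic_evidence <- function(x, y, prior_sd = 1, lim = 8, ngrid = 201) {
  xz <- (x - mean(x)) / sd(x)
  X <- cbind(1, xz)
  b0 <- seq(-lim, lim, length.out = ngrid)
  ll <- outer(b0, b0, Vectorize(function(a, b) {
    eta <- X %*% c(a, b)
    sum(y * eta - log1p(exp(eta))) + sum(dnorm(c(a, b), 0, prior_sd, log = TRUE))
  }))
  m <- max(ll)
  m + log(sum(exp(ll - m))) + 2 * log(b0[2] - b0[1])
}

# brute-force marginal likelihood of the g-prior mixed model: dense
# N x N covariance per draw, Monte Carlo over exact prior draws of g
# (g = r^2 / chisq_1). Independent of the package's Woodbury + quadrature
# route.
mc_dense_logml <- function(y, blocks, rscales, nmc = 40000, seed = 99) {
  set.seed(seed)
  N <- length(y)
  X <- do.call(cbind, blocks)
  blk <- rep(seq_along(blocks), vapply(blocks, ncol, 1L))
  const <- lgamma((N - 1) / 2) - ((N - 1) / 2) * log(pi)
  vals <- numeric(nmc)
  for (i in seq_len(nmc)) {
    g <- rscales^2 / rchisq(length(blocks), 1)
    S <- diag(N) + X %*% (g[blk] * t(X))
    Si <- solve(S)
    Q <- drop(t(y) %*% Si %*% y - (sum(Si %*% y))^2 / sum(Si))
    vals[i] <- const - 0.5 * determinant(S)$modulus[1] -
      0.5 * log(sum(Si)) - ((N - 1) / 2) * log(Q)
  }
  m <- max(vals)
  m + log(mean(exp(vals - m)))
}

# design blocks of the 2x2 within-subject model, as the package builds them
anova_blocks <- function(n, effects = c("intensity", "expectation", "interaction")) {
  cons <- painconn:::design_contrasts()
  Xs <- kronecker(painconn:::subject_contrasts(n), rep(1, 4))
  c(list(Xs), lapply(cons[effects], function(ck)
    kronecker(rep(1, n), matrix(ck, 4))))
}

# cell matrix with given additive effects and noise
make_cells <- function(n, intensity = 0, expectation = 0, interaction = 0,
                       subject_sd = 1, noise_sd = 1) {
  cells <- condition_cells()
  mu <- intensity * (cells %in% c("hiLE", "hiHE")) +
    expectation * (cells %in% c("liHE", "hiHE")) +
    interaction * (cells %in% c("hiLE", "liHE"))
  Y <- matrix(rnorm(n * 4, 0, noise_sd), n, 4, dimnames = list(NULL, cells))
  sweep(Y, 2, mu, "+") + rnorm(n, 0, subject_sd)
}
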