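# Shared fixtures and independent brute-force oracles for the test suite.

# Random symmetric correlation-like matrix (true Pearson of random data).
rand_fc <- function(n, t = 4 * n, seed = 1) {
  set.seed(seed)
  cor(matrix(rnorm(t * n), t, n))
}

# Small ground truth + cohort, built once per test session.
.fixture_env <- new.env()

tiny_gt <- function() {
  if (is.null(.fixture_env$tiny_gt))
    .fixture_env$tiny_gt <- toy_ground_truth(seed = 7L, n_regions = 6L,
                                             k_networks = 2L,
                                             n_subjects = 6L,
                                             n_samples = 120L)
  .fixture_env$tiny_gt
}

tiny_cohort <- function() {
  if (is.null(.fixture_env$tiny_cohort))
    .fixture_env$tiny_cohort <- make_multistate_cohort(tiny_gt())
  .fixture_env$tiny_cohort
}

# Brute-force elementwise Pearson correlation.
pearson_oracle <- function(m) {
  n <- ncol(m)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    xi <- m[, i] - mean(m[, i])
    xj <- m[, j] - mean(m[, j])
    out[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  out
}

# Scalar-loop Fisher-z group average.
group_fc_oracle <- function(fcs) {
  n <- nrow(fcs[[1]])
  out <- matrix(0, n, n)
  clip <- 1 - 1e-6
  for (i in seq_len(n)) for (j in seq_len(n)) {
    zs <- vapply(fcs, function(fc)
      atanh(min(max(fc[i, j], -clip), clip)), numeric(1))
    out[i, j] <- tanh(mean(zs))
  }
  diag(out) <- 1
  out
}

# Independent windowed-SSIM implementation: explicit loop over valid window
# positions with Gaussian weights.
ssim_oracle <- function(X, Y, win = 11L, sigma = 1.5, K1 = 0.01, K2 = 0.03,
                        L = 2) {
  h <- (win - 1) / 2
  g1 <- exp(-((-h):h)^2 / (2 * sigma^2))
  W <- outer(g1, g1)
  W <- W / sum(W)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  nr <- nrow(X) - win + 1L; nc <- ncol(X) - win + 1L
  vals <- numeric(0)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    xw <- X[r:(r + win - 1), c:(c + win - 1)]
    yw <- Y[r:(r + win - 1), c:(c + win - 1)]
    mx <- sum(W * xw); my <- sum(W * yw)
    vx <- sum(W * xw^2) - mx^2
    vy <- sum(W * yw^2) - my^2
    cxy <- sum(W * xw * yw) - mx * my
    vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  mean(vals)
}

runif_seeded <- function(n, lo, hi, seed) {
  set.seed(seed)
  runif(n, lo, hi)
}

# Spectral peak frequency via plain periodogram.
fft_peak_hz <- function(x, tr) {
  T <- length(x)
  p <- Mod(fft(x - mean(x)))^2
  f <- (seq_len(T) - 1) / (T * tr)
  half <- seq_len(floor(T / 2))
  f[half][which.max(p[half])]
}
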