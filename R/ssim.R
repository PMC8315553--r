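#' Goodness of fit between two FC matrices (SSIM)
#'
#' The structural similarity index (SSIM) between two matrices treated as
#' images, used here as the goodness of fit (GoF) between simulated and
#' empirical FC. A Gaussian-weighted sliding window (11 x 11, sigma = 1.5)
#' computes local means, variances and covariance; the SSIM map uses the
#' standard stabilizing constants C1 = (K1 L)^2, C2 = (K2 L)^2 with
#' K1 = 0.01, K2 = 0.03 and data range L = 2 (correlations span [-1, 1]).
#' The returned value is the mean of the SSIM map over all fully supported
#' ("valid") window positions. Windows larger than the matrix are shrunk to
#' the largest odd size that fits.
#'
#' @param fc_a,fc_b square matrices of equal size (at least 3 x 3).
#' @param win window side length (odd).
#' @param sigma Gaussian window standard deviation, in pixels.
#' @param K1,K2 stabilizing constants.
#' @param data_range dynamic range of the inputs.
#' @return scalar in `[-1, 1]`; 1 iff the inputs are identical.
#' @export
gof <- function(fc_a, fc_b, win = 11L, sigma = 1.5, K1 = 0.01, K2 = 0.03,
                data_range = 2) {
  X <- unclass(as.matrix(fc_a))
  Y <- unclass(as.matrix(fc_b))
  if (!all(dim(X) == dim(Y)))
    stop("FC matrices must have the same shape (",
         paste(dim(X), collapse = "x"), " vs ",
         paste(dim(Y), collapse = "x"), ")")
  d <- min(dim(X))
  if (d < 3) stop("matrices must be at least 3 x 3 for SSIM")
  win <- min(win, if (d %% 2 == 1) d else d - 1L)
  if (win %% 2 == 0) win <- win - 1L

  k <- gauss_kernel_1d(win, sigma)
  Br <- band_filter_matrix(nrow(X), k)   # (rows - win + 1) x rows
  Bc <- band_filter_matrix(ncol(X), k)
  filt <- function(M) Br %*% M %*% t(Bc)

  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  mu_x <- filt(X); mu_y <- filt(Y)
  sxx <- filt(X * X) - mu_x^2
  syy <- filt(Y * Y) - mu_y^2
  sxy <- filt(X * Y) - mu_x * mu_y
  ssim_map <- ((2 * mu_x * mu_y + C1) * (2 * sxy + C2)) /
    ((mu_x^2 + mu_y^2 + C1) * (sxx + syy + C2))
  mean(ssim_map)
}

gauss_kernel_1d <- function(win, sigma) {
  h <- (win - 1) / 2
  g <- exp(-((-h):h)^2 / (2 * sigma^2))
  g / sum(g)
}

# Banded matrix implementing 1-D "valid" convolution with kernel k.
band_filter_matrix <- function(n, k) {
  w <- length(k)
  m <- n - w + 1L
  B <- matrix(0, m, n)
  for (i in seq_len(m)) B[i, i:(i + w - 1L)] <- k
  B
}
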