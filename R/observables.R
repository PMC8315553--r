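#' Analysis frequency band
#'
#' @param f_low,f_high band edges in Hz. The default 0.04-0.07 Hz band is the
#'   slow-oscillation range commonly used for resting-state FC because it
#'   carries the most reliable functional information and is least affected
#'   by physiological noise.
#' @return object of class `"band_spec"`.
#' @export
band_spec <- function(f_low = 0.04, f_high = 0.07) {
  if (!(f_low > 0 && f_high > f_low))
    stop("need 0 < f_low < f_high")
  structure(list(f_low = f_low, f_high = f_high), class = "band_spec")
}

# Butterworth band-pass design plus the steady-state initial-condition
# vector of the standard filtfilt scheme (solves the step-response fixed
# point of the direct form II transposed state).
butter_bandpass <- function(band, tr) {
  nyq <- 1 / (2 * tr)
  if (band$f_high >= nyq)
    stop("band upper edge ", band$f_high, " Hz violates the Nyquist ",
         "frequency ", nyq, " Hz at TR = ", tr, " s")
  bf <- signal::butter(2, c(band$f_low, band$f_high) / nyq, type = "pass")
  n <- max(length(bf$b), length(bf$a))
  b <- c(bf$b, numeric(n - length(bf$b)))
  a <- c(bf$a, numeric(n - length(bf$a)))
  companion <- rbind(-a[-1] / a[1], cbind(diag(1, n - 2), 0))
  zi <- solve(diag(1, n - 1) - t(companion), b[-1] - a[-1] * b[1])
  list(b = b, a = a, zi = zi)
}

#' Band-pass filter a BOLD series
#'
#' Zero-phase (forward-backward) 2nd-order Butterworth band-pass applied
#' column-wise, with odd end-extension and matched initial conditions so
#' that edge transients are suppressed. Zero phase avoids distorting
#' correlations by phase lag.
#'
#' @param x a [bold_series()].
#' @param band a [band_spec()].
#' @return filtered [bold_series()] of the same shape.
#' @export
bandpass <- function(x, band = band_spec()) {
  tr <- tr_of(x)
  bf <- butter_bandpass(band, tr)
  y <- filtfilt_cpp(bf$b, bf$a, bf$zi, unclass(x))
  bold_series(y, tr)
}

#' Column-wise z-scoring
#'
#' @param x a [bold_series()] (or plain T x N matrix with a `tr` attribute).
#' @return z-scored [bold_series()]; each column has mean 0 and sd 1.
#' @export
zscore <- function(x) {
  tr <- tr_of(x)
  m <- unclass(x)
  sds <- apply(m, 2, sd)
  if (any(sds == 0))
    stop("zero-variance region at column ", which(sds == 0)[1])
  bold_series(scale(m), tr)
}

#' Functional connectivity of one recording
#'
#' Matrix of Pearson correlation coefficients between the regional signals.
#'
#' @param x a [bold_series()].
#' @return N x N correlation matrix with attribute `kind = "pearson"`.
#' @export
compute_fc <- function(x) {
  m <- unclass(x)
  if (nrow(m) < 3) stop("need at least 3 samples to compute FC")
  sds <- apply(m, 2, sd)
  if (any(sds == 0))
    stop("zero-variance region at column ", which(sds == 0)[1])
  fc <- cor(m)
  attr(fc, "kind") <- "pearson"
  fc
}

#' Group-average FC by Fisher's R-to-z transform
#'
#' Off-diagonal correlations are transformed with atanh, averaged across
#' subjects, and transformed back with tanh (fixed-effect analysis). The
#' diagonal is reset to 1. Correlations are clipped to +/-(1 - 1e-6) before
#' atanh to avoid divergence.
#'
#' @param fcs non-empty list of same-sized FC matrices.
#' @return group FC matrix with attribute `kind = "fisher_avg"`.
#' @export
group_fc <- function(fcs) {
  if (length(fcs) == 0) stop("group_fc needs at least one FC matrix")
  n <- nrow(fcs[[1]])
  for (fc in fcs)
    if (!all(dim(fc) == c(n, n))) stop("FC matrices differ in size")
  clip <- 1 - 1e-6
  zs <- lapply(fcs, function(fc) atanh(pmin(pmax(unclass(fc), -clip), clip)))
  avg <- tanh(Reduce(`+`, zs) / length(zs))
  diag(avg) <- 1
  attr(avg, "kind") <- "fisher_avg"
  avg
}

# Welch power spectral density of a single series: Hann-windowed,
# mean-detrended segments of length min(T, nseg) with 50% overlap.
welch_psd <- function(x, fs, nseg = 128L) {
  T <- length(x)
  L <- min(T, nseg)
  step <- max(1L, floor(L / 2))
  starts <- seq(1L, T - L + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / (L - 1)))
  nf <- floor(L / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(fft(seg))^2
    acc <- acc + p[seq_len(nf)]
  }
  list(freq = (0:(nf - 1L)) * fs / L, power = acc / length(starts))
}

#' Regional natural frequencies of a cohort
#'
#' For each region, the peak frequency of the Welch periodogram of the
#' band-pass-filtered signal, averaged across subjects, returned as angular
#' frequency omega = 2*pi*f. The peak search is restricted to the analysis
#' band, so estimates always lie in `[f_low, f_high]`.
#'
#' @param cohort a [state_dataset()] holding raw BOLD series.
#' @param band a [band_spec()].
#' @param nseg Welch segment length (default `min(T, 128)`).
#' @return list with `omega` (rad/s) and `freq_hz` per region.
#' @export
natural_frequencies <- function(cohort, band = band_spec(), nseg = 128L) {
  if (!all(vapply(cohort$subjects, inherits, logical(1), "bold_series")))
    stop("natural_frequencies needs raw BOLD series, not FC matrices")
  n <- ncol(cohort$subjects[[1]])
  peaks <- matrix(NA_real_, length(cohort$subjects), n)
  for (s in seq_along(cohort$subjects)) {
    xb <- bandpass(cohort$subjects[[s]], band)
    fs <- 1 / tr_of(xb)
    for (j in seq_len(n)) {
      psd <- welch_psd(unclass(xb)[, j], fs, nseg)
      in_band <- psd$freq >= band$f_low & psd$freq <= band$f_high
      if (!any(in_band))
        stop("no spectral bins inside the band; series too short")
      fi <- psd$freq[in_band]
      peaks[s, j] <- fi[which.max(psd$power[in_band])]
    }
  }
  f <- colMeans(peaks)
  list(omega = 2 * pi * f, freq_hz = f)
}
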