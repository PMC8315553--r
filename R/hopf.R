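#' Specify a whole-brain Hopf model
#'
#' Bundles the parameters of the coupled Stuart-Landau network: per-region
#' bifurcation parameters `a` (a < 0: stable fixed point, noise-driven;
#' a > 0: limit cycle of radius sqrt(a); a ~ 0: noise-induced switching),
#' intrinsic angular frequencies `omega` (rad/s), global coupling `G`, noise
#' amplitude `beta`, integration step `dt` and the structural connectome.
#'
#' @param a numeric vector of bifurcation parameters (length N).
#' @param omega numeric vector of angular frequencies, rad/s (length N).
#' @param connectome N x N non-negative coupling matrix (see
#'   [scale_connectome()]).
#' @param G global coupling factor (default 0.5).
#' @param beta additive Gaussian noise amplitude (default 0.04).
#' @param dt Euler-Maruyama step in seconds (default 0.1).
#' @return object of class `"hopf_model_spec"`.
#' @export
hopf_model_spec <- function(a, omega, connectome, G = 0.5, beta = 0.04,
                            dt = 0.1) {
  connectome <- as.matrix(connectome)
  n <- nrow(connectome)
  validate_connectome(connectome)
  if (length(a) != n || length(omega) != n)
    stop("a and omega must have one entry per region (", n, ")")
  if (dt <= 0) stop("dt must be > 0")
  if (beta < 0) stop("beta must be >= 0")
  structure(list(a = as.numeric(a), omega = as.numeric(omega),
                 connectome = connectome, G = G, beta = beta, dt = dt),
            class = "hopf_model_spec")
}

#' @export
print.hopf_model_spec <- function(x, ...) {
  cat("Hopf model:", length(x$a), "regions, G =", x$G, ", beta =", x$beta,
      ", dt =", x$dt, "s; a in [", round(min(x$a), 3), ",",
      round(max(x$a), 3), "]\n")
  invisible(x)
}

#' Specify a periodic perturbation of one homotopic pair
#'
#' The perturbation is an additive periodic forcing F0 * cos(omega_j t)
#' applied to both nodes of a homotopic pair, each at its own intrinsic
#' frequency, modeling bilateral periodic stimulation such as tACS. By
#' default the forcing enters the real-part equation only.
#'
#' @param pair length-2 integer vector of region indices (a homotopic pair).
#' @param amplitude forcing amplitude F0 (>= 0).
#' @param force_both also add the forcing to the imaginary-part equation.
#' @return object of class `"forcing_spec"`.
#' @export
forcing_spec <- function(pair, amplitude, force_both = FALSE) {
  pair <- as.integer(pair)
  if (length(pair) != 2 || pair[1] == pair[2])
    stop("pair must be two distinct region indices")
  if (amplitude < 0) stop("amplitude must be >= 0")
  structure(list(pair = pair, amplitude = amplitude, force_both = force_both),
            class = "forcing_spec")
}

#' Simulate BOLD-like signals from the Hopf network model
#'
#' Integrates the coupled stochastic equations by the Euler-Maruyama scheme
#' at step `dt`, from a small random initial state, discards a transient and
#' records the real part x_j every `tr / dt` steps. Reproducible for a fixed
#' seed.
#'
#' @param spec a [hopf_model_spec()].
#' @param n_samples number of recorded samples.
#' @param tr sampling interval in seconds; must be an integer multiple of
#'   `spec$dt`.
#' @param seed RNG seed.
#' @param forcing optional [forcing_spec()].
#' @param transient_seconds initial integration time discarded before
#'   recording (default 100 s).
#' @return a [bold_series()] (n_samples x N).
#' @export
simulate_hopf <- function(spec, n_samples, tr = 2, seed = 1L, forcing = NULL,
                          transient_seconds = 100) {
  x <- sim_matrix(spec, n_samples, tr, seed, forcing, transient_seconds)
  bold_series(x, tr)
}

# Integration core shared by simulate_hopf and simulated_group_fc: validates
# the sampling scheme and forcing, returns the raw n_samples x N matrix.
sim_matrix <- function(spec, n_samples, tr, seed, forcing,
                       transient_seconds) {
  stopifnot(inherits(spec, "hopf_model_spec"))
  if (n_samples < 2) stop("n_samples must be >= 2")
  ratio <- tr / spec$dt
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("tr (", tr, " s) must be an integer multiple of dt (", spec$dt, " s)")
  n <- length(spec$a)
  famp <- numeric(n)
  force_both <- FALSE
  if (!is.null(forcing)) {
    stopifnot(inherits(forcing, "forcing_spec"))
    if (any(forcing$pair < 1 | forcing$pair > n))
      stop("forcing pair indices out of range")
    famp[forcing$pair] <- forcing$amplitude
    force_both <- forcing$force_both
  }
  hopf_integrate_cpp(spec$a, spec$omega, spec$connectome, spec$G, spec$beta,
                     spec$dt, as.integer(round(ratio)),
                     as.integer(n_samples),
                     as.integer(round(transient_seconds / spec$dt)),
                     as.numeric(seed), famp, force_both)
}

#' Simulated group-level FC
#'
#' Runs `n_subjects` independent simulations (subject seeds derived from the
#' master seed) and applies to each the empirical observation pipeline —
#' band-pass filter, z-score, Pearson FC — then Fisher-z averages across the
#' simulated subjects. (The z-scoring step is skipped internally: Pearson
#' correlation is invariant to affine per-column rescaling, so the result is
#' identical to the explicit pipeline.)
#'
#' @inheritParams simulate_hopf
#' @param n_subjects number of independent simulated subjects.
#' @param band a [band_spec()].
#' @return group FC matrix (see [group_fc()]).
#' @export
simulated_group_fc <- function(spec, n_subjects, n_samples, tr = 2, seed = 1L,
                               forcing = NULL, band = band_spec(),
                               transient_seconds = 100) {
  seeds <- derive_seeds(seed, n_subjects)
  bf <- butter_bandpass(band, tr)
  fcs <- lapply(seeds, function(s) {
    x <- sim_matrix(spec, n_samples, tr, s, forcing, transient_seconds)
    xf <- filtfilt_cpp(bf$b, bf$a, bf$zi, x)
    v <- colMeans(xf^2) - colMeans(xf)^2
    if (any(v <= 0))
      stop("zero-variance region at column ", which(v <= 0)[1])
    cor(xf)
  })
  group_fc(fcs)
}
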