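#' Generate a synthetic homotopically mirrored modular connectome
#'
#' Builds a weighted undirected modular graph on `n_regions / 2` homotopic
#' pairs and mirrors it across hemispheres with AAL-style interleaved
#' left/right region ordering: intra-hemispheric weights are identical in
#' both hemispheres, cross-hemispheric weights are attenuated copies, and
#' each homotopic pair is strongly connected. The result is symmetric,
#' invariant under the hemisphere-swap permutation, connected, and scaled to
#' a maximum weight of 0.2.
#'
#' @param n_regions even number of regions.
#' @param n_modules number of modules (on the pair graph).
#' @param density within-module edge probability in (0, 1]; between-module
#'   edges appear at a quarter of this probability with weaker weights.
#' @param seed RNG seed.
#' @param max_attempts redraws allowed before giving up on connectivity.
#' @return list: `connectome` (scaled matrix), `parcellation` (with
#'   interleaved homotopic pairing), `modules` (module id per region).
#' @export
make_connectome <- function(n_regions, n_modules = 2, density = 0.5,
                            seed = 1L, max_attempts = 100L) {
  if (n_regions %% 2 != 0) stop("n_regions must be even")
  if (!(density > 0 && density <= 1)) stop("density must be in (0, 1]")
  npair <- n_regions / 2
  if (n_modules > npair) stop("more modules than homotopic pairs")
  module <- rep(seq_len(n_modules), length.out = npair)
  module <- sort(module)
  attempt <- function() {
    W <- matrix(0, npair, npair)
    for (i in seq_len(npair - 1)) for (j in seq(i + 1, npair)) {
      same <- module[i] == module[j]
      p_edge <- if (same) density else density / 4
      if (runif(1) < p_edge)
        W[i, j] <- W[j, i] <- if (same) runif(1, 0.5, 1) else runif(1, 0.05, 0.3)
    }
    W
  }
  preserve_rng({
    set.seed(as.integer(seed))
    W <- NULL
    for (k in seq_len(max_attempts)) {
      cand <- attempt()
      # connectivity on the pair graph (homotopic edges connect hemispheres)
      if (is_connected_graph(cand > 0)) { W <- cand; break }
    }
    if (is.null(W))
      stop("could not draw a connected connectome at density ", density,
           " after ", max_attempts, " attempts")
    C <- matrix(0, n_regions, n_regions)
    L <- 2 * seq_len(npair) - 1
    R <- 2 * seq_len(npair)
    C[L, L] <- W
    C[R, R] <- W
    C[L, R] <- 0.3 * W
    C[R, L] <- 0.3 * W
    for (k in seq_len(npair)) C[L[k], R[k]] <- C[R[k], L[k]] <- 1
    labels <- as.vector(rbind(sprintf("R%02dL", seq_len(npair)),
                              sprintf("R%02dR", seq_len(npair))))
    parc <- parcellation(labels, rep(c("L", "R"), npair))
    list(connectome = scale_connectome(C),
         parcellation = parc,
         modules = rep(module, each = 2))
  })
}

is_connected_graph <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  frontier <- 1L
  seen[1] <- TRUE
  while (length(frontier) > 0) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Generate a hemisphere-symmetric RSN membership matrix
#'
#' Assigns each homotopic pair to one of `k_networks` networks (balanced
#' random assignment), with homotopic partners always sharing identical
#' membership rows. A fraction of regions may additionally belong to a
#' second network, emulating overlapping anatomical priors.
#'
#' @param n_regions even number of regions.
#' @param k_networks number of networks.
#' @param seed RNG seed.
#' @param overlap_fraction fraction of regions assigned to two networks.
#' @return N x K binary membership matrix.
#' @export
make_rsn_partition <- function(n_regions, k_networks, seed = 1L,
                               overlap_fraction = 0) {
  if (n_regions %% 2 != 0) stop("n_regions must be even")
  npair <- n_regions / 2
  if (k_networks > npair) stop("more networks than homotopic pairs")
  preserve_rng({
    set.seed(as.integer(seed))
    assign1 <- sample(rep_len(seq_len(k_networks), npair))
    Mp <- matrix(0, npair, k_networks)
    Mp[cbind(seq_len(npair), assign1)] <- 1
    n_overlap_pairs <- round(overlap_fraction * n_regions / 2)
    if (n_overlap_pairs > 0) {
      extra <- sample(npair, n_overlap_pairs)
      for (p in extra) {
        second <- sample(setdiff(seq_len(k_networks), assign1[p]), 1)
        Mp[p, second] <- 1
      }
    }
    Mp[rep(seq_len(npair), each = 2), ]
  })
}

#' Bundle the ground truth of a synthetic multi-state study
#'
#' @param connectome scaled coupling matrix.
#' @param parc a [parcellation()] (pairing used for forcing-derived states).
#' @param membership N x K binary RSN matrix.
#' @param omega per-region angular frequencies (rad/s).
#' @param states named list; each element a list with `g` (K-vector),
#'   optional `forcing` ([forcing_spec()] applied on top of `g`), optional
#'   `wake` (name of the state's wakefulness baseline), `route`, `depth`.
#' @param cohort_config list with `n_subjects`, `n_samples`, `tr`, `seed`.
#' @param model_config list with `G`, `beta`, `dt`.
#' @return object of class `"ground_truth"`.
#' @export
ground_truth <- function(connectome, parc, membership, omega, states,
                         cohort_config = list(n_subjects = 20L,
                                              n_samples = 200L,
                                              tr = 2, seed = 1L),
                         model_config = list(G = 0.5, beta = 0.04,
                                             dt = 0.1)) {
  for (nm in names(states)) {
    st <- states[[nm]]
    if (length(st$g) != ncol(as.matrix(membership)))
      stop("state '", nm, "' g-vector length does not match membership")
    wb <- st$wake
    if (!is.null(wb) && is.null(states[[wb]]))
      stop("wake baseline '", wb, "' of state '", nm, "' is not a state")
  }
  structure(list(connectome = connectome, parcellation = parc,
                 membership = as.matrix(membership), omega = omega,
                 states = states, cohort_config = cohort_config,
                 model_config = model_config),
            class = "ground_truth")
}

#' True regional bifurcation parameters of a ground-truth state
#' @param gt a [ground_truth()].
#' @param state state name.
#' @return N-vector `a`.
#' @export
true_a <- function(gt, state) {
  suppressWarnings(expand_parameters(gt$membership, gt$states[[state]]$g))
}

#' Default desk-scale synthetic study
#'
#' A 20-region, 3-network, 5-state fixture: a wakefulness baseline plus four
#' graded states whose network contributions move from the oscillatory side
#' of the bifurcation (wake) toward increasingly negative, noise-dominated
#' values — mirroring the ordinal structure of states of reduced
#' consciousness. Intrinsic frequencies are drawn uniformly in the
#' 0.04-0.07 Hz band, identical within each homotopic pair. Cohorts default
#' to 20 subjects per state and 200 samples at TR = 2 s, sized so the full
#' pipeline (including a scaled-down genetic algorithm) runs in minutes.
#'
#' @param seed RNG seed.
#' @param n_regions,k_networks,n_subjects,n_samples,tr scale overrides.
#' @return a [ground_truth()].
#' @export
toy_ground_truth <- function(seed = 42L, n_regions = 20L, k_networks = 3L,
                             n_subjects = 20L, n_samples = 200L, tr = 2) {
  seeds <- derive_seeds(seed, 3L)
  con <- make_connectome(n_regions, n_modules = 2, density = 0.5,
                         seed = seeds[1])
  M <- make_rsn_partition(n_regions, k_networks, seed = seeds[2])
  npair <- n_regions / 2
  f_pair <- preserve_rng({
    set.seed(seeds[3])
    runif(npair, 0.04, 0.07)
  })
  omega <- 2 * pi * rep(f_pair, each = 2)
  gs <- list(wake = c(0.08, 0.05, 0.06),
             light = c(0.02, 0.00, 0.01),
             mid = c(-0.03, -0.06, -0.04),
             deep = c(-0.09, -0.12, -0.10),
             deepest = c(-0.16, -0.18, -0.15))
  states <- list()
  for (i in seq_along(gs)) {
    nm <- names(gs)[i]
    states[[nm]] <- list(g = gs[[i]][seq_len(k_networks)],
                         wake = if (nm == "wake") NULL else "wake",
                         route = "toy", depth = i - 1)
  }
  ground_truth(con$connectome, con$parcellation, M, omega, states,
               cohort_config = list(n_subjects = n_subjects,
                                    n_samples = n_samples, tr = tr,
                                    seed = seed))
}

#' Simulate the multi-subject cohorts of a ground truth
#'
#' For every state, simulates `n_subjects` independent BOLD series from the
#' Hopf model with that state's expanded bifurcation parameters (and its
#' forcing, for forcing-derived states), then links wakefulness baselines.
#' Fully reproducible from the stored seeds.
#'
#' @param gt a [ground_truth()].
#' @return named list of [state_dataset()] objects.
#' @export
make_multistate_cohort <- function(gt) {
  cc <- gt$cohort_config
  mc <- gt$model_config
  state_seeds <- derive_seeds(cc$seed, length(gt$states))
  cohorts <- list()
  for (i in seq_along(gt$states)) {
    nm <- names(gt$states)[i]
    st <- gt$states[[i]]
    a <- suppressWarnings(expand_parameters(gt$membership, st$g))
    spec <- hopf_model_spec(a, gt$omega, gt$connectome, G = mc$G,
                            beta = mc$beta, dt = mc$dt)
    subj_seeds <- derive_seeds(state_seeds[i], cc$n_subjects)
    subjects <- lapply(subj_seeds, function(s)
      tryCatch(simulate_hopf(spec, cc$n_samples, cc$tr, s,
                             forcing = st$forcing),
               error = function(e)
                 stop("simulation failed for state '", nm, "': ",
                      conditionMessage(e))))
    cohorts[[nm]] <- state_dataset(nm, subjects, route = st$route,
                                   depth = st$depth %||% NA_real_)
  }
  for (nm in names(gt$states)) {
    wb <- gt$states[[nm]]$wake
    if (!is.null(wb)) cohorts[[nm]]$wake_baseline <- cohorts[[wb]]
  }
  cohorts
}
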