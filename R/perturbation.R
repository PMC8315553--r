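#' Normalized perturbational score
#'
#' Given the goodness of fit of (i) the target state's own best fit, (ii)
#' the unperturbed initial-state simulation and (iii) the perturbed
#' initial-state simulation — all against the target state's empirical FC —
#' returns
#' `(gof_target_fit - gof_perturbed) / (gof_target_fit - gof_initial)`.
#' 0 means the perturbed model fits the target as well as the target's own
#' best fit (a transition is likely inducible); 1 means the perturbation did
#' not move the model away from its initial state. Values below 0 (perturbed
#' fit better than the target's own) are allowed and reported.
#'
#' @param gof_target_fit GoF of the target state's fitted model vs its
#'   empirical FC.
#' @param gof_initial GoF of the unperturbed initial-state model vs the
#'   target's empirical FC.
#' @param gof_perturbed GoF of the perturbed initial-state model vs the
#'   target's empirical FC.
#' @param tol degeneracy tolerance on the denominator.
#' @return scalar score.
#' @export
delta_gof <- function(gof_target_fit, gof_initial, gof_perturbed,
                      tol = 1e-9) {
  den <- gof_target_fit - gof_initial
  if (abs(den) <= tol)
    stop("degenerate state pair: initial-state fit quality equals the ",
         "target's own fit (denominator ~ 0); exclude this pair")
  (gof_target_fit - gof_perturbed) / den
}

resolve_sweep_config <- function(sweep_config) {
  defaults <- list(amplitudes = seq(0, 2, by = 0.1), n_reps = 100L,
                   n_samples = 200L, tr = 2, G = 0.5, beta = 0.04, dt = 0.1,
                   band = band_spec(), transient_seconds = 100,
                   force_both = FALSE)
  cfg <- utils::modifyList(defaults, as.list(sweep_config))
  amps <- cfg$amplitudes
  if (is.unsorted(amps, strictly = TRUE) || amps[1] != 0)
    stop("amplitudes must be strictly increasing and start at 0")
  cfg
}

#' Amplitude sweep of homotopic periodic perturbations
#'
#' Simulates the fitted initial-state model under additive periodic forcing
#' of every homotopic pair, for each amplitude of the grid (default 0 to 2
#' in steps of 0.1), averaging `n_reps` independent simulated-FC
#' realizations per grid cell (Fisher-z averaging, as for the empirical
#' group FC), and scores each cell with [delta_gof()] against the target
#' state's empirical FC.
#'
#' The unforced baseline FC is computed once with the same realization seeds
#' and reused for every pair, so the amplitude-0 column is exactly 1 and
#' Monte-Carlo asymmetry in the score is avoided (common random numbers
#' across grid cells).
#'
#' @param fit_initial,fit_target [fit_state()] results for the initial and
#'   target states.
#' @param emp_fc_target empirical group FC of the target state.
#' @param parc a [parcellation()] (supplies the homotopic pairs).
#' @param connectome N x N scaled coupling matrix.
#' @param omega per-region angular frequencies (rad/s).
#' @param sweep_config named list overriding sweep defaults (`amplitudes`,
#'   `n_reps`, `n_samples`, `tr`, `G`, `beta`, `dt`, `band`,
#'   `transient_seconds`, `force_both`).
#' @param master_seed RNG seed for the realization family.
#' @param initial_state,target_state optional state names stored in the
#'   result.
#' @return object of class `"sweep_result"`: `pairs`, `amplitudes`,
#'   `delta_gof` (pairs x amplitudes grid), `best_per_pair`, `global_best`,
#'   `gof_target_fit`, `gof_initial`.
#' @export
amplitude_sweep <- function(fit_initial, fit_target, emp_fc_target, parc,
                            connectome, omega, sweep_config = list(),
                            master_seed = 1L,
                            initial_state = "initial",
                            target_state = "target") {
  cfg <- resolve_sweep_config(sweep_config)
  pairs <- enumerate_homotopic_pairs(parc)
  spec <- hopf_model_spec(fit_initial$a_best, omega, connectome,
                          G = cfg$G, beta = cfg$beta, dt = cfg$dt)
  gof_target_fit <- fit_target$gof_best

  baseline_fc <- simulated_group_fc(spec, cfg$n_reps, cfg$n_samples, cfg$tr,
                                    master_seed, band = cfg$band,
                                    transient_seconds = cfg$transient_seconds)
  gof_initial <- gof(baseline_fc, emp_fc_target)
  den <- gof_target_fit - gof_initial
  if (abs(den) <= 1e-9)
    stop("degenerate state pair ", initial_state, " -> ", target_state,
         ": unperturbed initial model already fits the target as well as ",
         "the target's own fit; exclude this pair")

  P <- nrow(pairs); A <- length(cfg$amplitudes)
  grid <- matrix(NA_real_, P, A)
  grid[, 1] <- 1  # F0 = 0 reuses the cached baseline: score exactly 1
  for (p in seq_len(P)) {
    for (ai in seq(2, A)) {
      frc <- forcing_spec(pairs[p, ], cfg$amplitudes[ai],
                          force_both = cfg$force_both)
      fc_pert <- simulated_group_fc(spec, cfg$n_reps, cfg$n_samples, cfg$tr,
                                    master_seed, forcing = frc,
                                    band = cfg$band,
                                    transient_seconds = cfg$transient_seconds)
      grid[p, ai] <- (gof_target_fit - gof(fc_pert, emp_fc_target)) / den
    }
  }
  best_idx <- apply(grid, 1, which.min)
  best_per_pair <- data.frame(
    pair_index = seq_len(P), i = pairs[, 1], j = pairs[, 2],
    delta_gof = grid[cbind(seq_len(P), best_idx)],
    amplitude = cfg$amplitudes[best_idx])
  gb <- which(grid == min(grid), arr.ind = TRUE)[1, ]
  structure(list(
    initial_state = initial_state, target_state = target_state,
    pairs = pairs, amplitudes = cfg$amplitudes, delta_gof = grid,
    best_per_pair = best_per_pair,
    global_best = list(value = min(grid), pair_index = unname(gb[1]),
                       amplitude = cfg$amplitudes[unname(gb[2])]),
    gof_target_fit = gof_target_fit, gof_initial = gof_initial,
    config = cfg, master_seed = master_seed),
    class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Perturbation sweep ", x$initial_state, " -> ", x$target_state, ": ",
      nrow(x$pairs), " pairs x ", length(x$amplitudes),
      " amplitudes; best score ", round(x$global_best$value, 3),
      " at pair ", x$global_best$pair_index, " (F0 = ",
      x$global_best$amplitude, ")\n", sep = "")
  invisible(x)
}

#' Perturbational distance of a sweep
#'
#' The minimum perturbational score over all homotopic pairs and forcing
#' amplitudes — the best achievable approach to the target state's fit.
#'
#' @param sweep a [amplitude_sweep()] result.
#' @return scalar minimum of the score grid.
#' @export
perturbational_distance <- function(sweep) {
  if (length(sweep$delta_gof) == 0) stop("empty sweep grid")
  min(sweep$delta_gof)
}

#' Threshold a distance matrix into a transition graph
#'
#' Directed edge i -> j present iff `distances[i, j] <= threshold`
#' (inclusive), i != j. Rows index the initial state.
#'
#' @param distances square states x states matrix (rows = initial states);
#'   dimnames supply state names.
#' @param threshold score cutoff (default 0.3).
#' @return object of class `"transition_graph"`: `nodes`, `edges`
#'   (data.frame from/to/weight), `threshold`.
#' @export
build_transition_graph <- function(distances, threshold = 0.3) {
  distances <- as.matrix(distances)
  if (nrow(distances) != ncol(distances))
    stop("distance matrix must be square")
  nodes <- rownames(distances) %||% paste0("S", seq_len(nrow(distances)))
  idx <- which(distances <= threshold & !diag(TRUE, nrow(distances)),
               arr.ind = TRUE)
  edges <- data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                      weight = distances[idx], stringsAsFactors = FALSE)
  edges <- edges[order(match(edges$from, nodes), match(edges$to, nodes)), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
            class = "transition_graph")
}

#' @export
print.transition_graph <- function(x, ...) {
  cat("Transition graph:", length(x$nodes), "states,", nrow(x$edges),
      "edges (score <=", x$threshold, ")\n")
  invisible(x)
}

#' Instability index of each state
#'
#' A state's instability is its out-degree in the thresholded transition
#' graph: the number of other states it can be pushed into by the simulated
#' perturbations.
#'
#' @param graph a [build_transition_graph()] result.
#' @return named integer vector (one entry per state).
#' @export
instability_index <- function(graph) {
  stopifnot(inherits(graph, "transition_graph"))
  out <- setNames(integer(length(graph$nodes)), graph$nodes)
  if (nrow(graph$edges) > 0) {
    tab <- table(factor(graph$edges$from, levels = graph$nodes))
    out[names(tab)] <- as.integer(tab)
  }
  out
}

#' Rank homotopic pairs by their transition-facilitating effect
#'
#' Within each sweep, pairs are ranked by their best (minimum) score
#' (rank 1 = most effective, ties get average ranks); ranks are then
#' averaged across all transitions of each group (e.g. transitions that
#' increase vs decrease the level of consciousness), and the top fraction
#' (default 50%) of pairs per group is selected.
#'
#' @param sweeps list of [amplitude_sweep()] results sharing one pair list.
#' @param grouping data.frame with columns `initial`, `target`, `group`
#'   covering every sweep (see [grouping_from_levels()]).
#' @param top_fraction fraction of best-ranked pairs to select.
#' @return named list per group: `ranks` (data.frame pair_index, i, j,
#'   avg_rank) sorted by average rank, and `top` (selected pair indices).
#' @export
rank_perturbation_targets <- function(sweeps, grouping, top_fraction = 0.5) {
  stopifnot(length(sweeps) >= 1)
  pairs <- sweeps[[1]]$pairs
  for (sw in sweeps)
    if (!identical(unname(sw$pairs), unname(pairs)))
      stop("sweeps do not share the same homotopic pair list")
  key <- function(a, b) paste(a, b, sep = " -> ")
  gmap <- setNames(grouping$group, key(grouping$initial, grouping$target))
  groups <- unique(grouping$group)
  res <- list()
  for (grp in groups) {
    rank_rows <- list()
    for (sw in sweeps) {
      g <- gmap[key(sw$initial_state, sw$target_state)]
      if (is.na(g)) stop("sweep ", key(sw$initial_state, sw$target_state),
                         " is not covered by the grouping")
      if (g != grp) next
      rank_rows[[length(rank_rows) + 1]] <-
        rank(sw$best_per_pair$delta_gof, ties.method = "average")
    }
    if (length(rank_rows) == 0) next
    avg <- Reduce(`+`, rank_rows) / length(rank_rows)
    tab <- data.frame(pair_index = seq_len(nrow(pairs)),
                      i = pairs[, 1], j = pairs[, 2], avg_rank = avg)
    tab <- tab[order(tab$avg_rank, tab$pair_index), ]
    rownames(tab) <- NULL
    n_top <- max(1L, floor(top_fraction * nrow(pairs) + 1e-9))
    res[[grp]] <- list(ranks = tab, top = tab$pair_index[seq_len(n_top)])
  }
  res
}

#' Level/stability coordinates of each state
#'
#' Places every state in a two-dimensional diagram: `level` is the Euclidean
#' distance between the state's fitted regional bifurcation parameters and
#' those of its wakefulness baseline (a model-based proxy for the level of
#' consciousness), and `instability` is the state's out-degree in the
#' transition graph.
#'
#' @param fits named list of [fit_state()] results (one per state).
#' @param graph a [build_transition_graph()] over the same states.
#' @param wake_map named character vector mapping each state to its
#'   wakefulness baseline state (also present in `fits`).
#' @return data.frame with columns `state`, `level`, `instability`.
#' @export
state_diagram <- function(fits, graph, wake_map) {
  inst <- instability_index(graph)
  states <- graph$nodes
  level <- vapply(states, function(s) {
    wb <- wake_map[[s]]
    if (is.null(wb) || is.na(wb)) stop("no wake baseline mapped for state ", s)
    if (is.null(fits[[s]]) || is.null(fits[[wb]]))
      stop("missing fit for state ", s, " or its baseline ", wb)
    model_parameter_distance(fits[[s]]$a_best, fits[[wb]]$a_best)
  }, numeric(1))
  data.frame(state = states, level = unname(level),
             instability = unname(inst[states]))
}
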