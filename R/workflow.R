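#' Group FC of a cohort via the standard observation pipeline
#'
#' Band-pass filters, z-scores and correlates every subject's recording,
#' then Fisher-z averages across subjects. Subjects already stored as FC
#' matrices are averaged directly.
#'
#' @param cohort a [state_dataset()].
#' @param band a [band_spec()].
#' @param filter apply the band-pass/z-score pipeline (default TRUE).
#' @return group FC matrix.
#' @export
cohort_group_fc <- function(cohort, band = band_spec(), filter = TRUE) {
  fcs <- lapply(cohort$subjects, function(s) {
    if (inherits(s, "bold_series")) {
      x <- if (filter) zscore(bandpass(s, band)) else s
      compute_fc(x)
    } else as.matrix(s)
  })
  group_fc(fcs)
}

#' Label transitions as increasing or decreasing the level of consciousness
#'
#' A transition initial -> target increases the level when the target is a
#' wakefulness state (depth 0) or is shallower on the same route (dataset);
#' it decreases the level when the target is deeper on the same route.
#' Cross-route transitions to non-wake states are excluded.
#'
#' @param states data.frame with columns `state`, `route`, `depth`
#'   (0 = wakefulness).
#' @return data.frame `initial`, `target`, `group` ("increase"/"decrease");
#'   excluded transitions are omitted.
#' @export
grouping_from_levels <- function(states) {
  need <- c("state", "route", "depth")
  if (!all(need %in% names(states)))
    stop("states must have columns: ", paste(need, collapse = ", "))
  if (any(is.na(states$depth)))
    stop("unranked state: ", states$state[which(is.na(states$depth))[1]])
  out <- list()
  for (i in seq_len(nrow(states))) for (j in seq_len(nrow(states))) {
    if (i == j) next
    si <- states[i, ]; sj <- states[j, ]
    grp <- if (sj$depth == 0) "increase"
    else if (si$route == sj$route) {
      if (sj$depth < si$depth) "increase"
      else if (sj$depth > si$depth) "decrease"
      else NA_character_
    } else NA_character_
    if (!is.na(grp))
      out[[length(out) + 1]] <- data.frame(initial = si$state,
                                           target = sj$state, group = grp,
                                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

fit_to_json <- function(fit, path) {
  obj <- fit
  obj$config$sim$band <- unclass(obj$config$sim$band)
  class(obj) <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

fit_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$config$sim$band <- band_spec(obj$config$sim$band$f_low,
                                   obj$config$sim$band$f_high)
  obj$run_history <- as.list(as.data.frame(obj$run_history))
  class(obj) <- "hopf_fit"
  obj
}

sweep_to_files <- function(sweep, csv_path, json_path) {
  long <- expand.grid(pair_index = seq_len(nrow(sweep$pairs)),
                      amp_index = seq_along(sweep$amplitudes))
  df <- data.frame(pair_index = long$pair_index,
                   i = sweep$pairs[long$pair_index, 1],
                   j = sweep$pairs[long$pair_index, 2],
                   amplitude = sweep$amplitudes[long$amp_index],
                   delta_gof = sweep$delta_gof[as.matrix(long)])
  write.table(df, csv_path, sep = ",", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(initial_state = sweep$initial_state,
                            target_state = sweep$target_state,
                            global_best = sweep$global_best,
                            gof_target_fit = sweep$gof_target_fit,
                            gof_initial = sweep$gof_initial),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' Run the full whole-brain modeling study on a cohort collection
#'
#' End-to-end orchestration: per-state group FC and natural frequencies,
#' per-state model fits, amplitude sweeps for every ordered state pair, the
#' four distance matrices (connectivity-correlation, classification,
#' model-parameter, perturbational) with z-scored versions, the thresholded
#' transition graph with instability indices, the level/stability state
#' diagram, regional perturbation-target rankings per transition group, and
#' a cross-metric Spearman rank-correlation table. Deterministic for a
#' fixed `master_seed`. When `out_dir` is given, each stage writes its
#' outputs there and completed stages (existing files) are skipped on rerun.
#'
#' @param cohorts named list of [state_dataset()] (e.g. from
#'   [make_multistate_cohort()]), baselines linked.
#' @param connectome scaled coupling matrix.
#' @param parc a [parcellation()].
#' @param membership N x K binary RSN matrix.
#' @param config named list overriding defaults: `band`, `ga`, `sim`,
#'   `sweep` (see the respective functions), `thresholds` (`delta_gof`,
#'   `top_fraction`, `extreme_fraction`, `r_threshold`, `alpha`,
#'   `rank_top_fraction`), `classifier` (`rf_config`, `n_permutations`).
#' @param master_seed master RNG seed.
#' @param out_dir optional output directory (created if missing).
#' @return list: `group_fcs`, `omega`, `fits`, `sweeps`, `distance_matrices`
#'   (raw and z-scored), `transition_graph`, `instability`, `state_diagram`,
#'   `grouping`, `rankings`, `metric_correlations`, `config`.
#' @export
run_full_study <- function(cohorts, connectome, parc, membership,
                           config = list(), master_seed = 1L,
                           out_dir = NULL) {
  cfg <- utils::modifyList(list(
    band = band_spec(),
    ga = list(), sim = list(), sweep = list(),
    thresholds = list(delta_gof = 0.3, top_fraction = 0.25,
                      extreme_fraction = 0.05, r_threshold = 0.5,
                      alpha = 0.05, rank_top_fraction = 0.5),
    classifier = list(rf_config = list(), n_permutations = 0L)),
    as.list(config))
  states <- names(cohorts)
  nonwake <- states[vapply(cohorts, function(cc)
    !is.null(cc$wake_baseline), logical(1))]
  wake_map <- vapply(states, function(s) {
    wb <- cohorts[[s]]$wake_baseline
    if (is.null(wb)) s else wb$state_name
  }, character(1))
  use_files <- !is.null(out_dir)
  if (use_files) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "fits"), showWarnings = FALSE)
    dir.create(file.path(out_dir, "sweeps"), showWarnings = FALSE)
    dir.create(file.path(out_dir, "distances"), showWarnings = FALSE)
  }
  seeds <- derive_seeds(master_seed, 2L + length(states) +
                          length(states)^2)
  fit_seeds <- setNames(seeds[2 + seq_along(states)], states)

  # Stage 1: empirical observables
  group_fcs <- lapply(cohorts, cohort_group_fc, band = cfg$band)
  omega <- lapply(cohorts, function(cc)
    natural_frequencies(cc, cfg$band)$omega)

  # Stage 2: per-state model fits
  fits <- list()
  for (s in states) {
    fp <- if (use_files) file.path(out_dir, "fits", paste0(s, ".json"))
    fits[[s]] <- if (use_files && file.exists(fp)) fit_from_json(fp)
    else {
      ft <- fit_state(group_fcs[[s]], connectome, membership, omega[[s]],
                      ga_config = cfg$ga, sim_config = cfg$sim,
                      master_seed = fit_seeds[[s]])
      if (use_files) fit_to_json(ft, fp)
      ft
    }
  }

  # Stage 3: amplitude sweeps for every ordered state pair
  sweep_seeds <- matrix(seeds[2 + length(states) +
                                seq_len(length(states)^2)],
                        length(states), dimnames = list(states, states))
  sweeps <- list()
  pert <- matrix(NA_real_, length(states), length(states),
                 dimnames = list(states, states))
  for (si in states) for (st in states) {
    if (si == st) next
    key <- paste0(si, "__", st)
    sw <- amplitude_sweep(fits[[si]], fits[[st]], group_fcs[[st]], parc,
                          connectome, omega[[si]], sweep_config = cfg$sweep,
                          master_seed = sweep_seeds[si, st],
                          initial_state = si, target_state = st)
    if (use_files)
      sweep_to_files(sw, file.path(out_dir, "sweeps", paste0(key, ".csv")),
                     file.path(out_dir, "sweeps", paste0(key, ".json")))
    sweeps[[key]] <- sw
    pert[si, st] <- perturbational_distance(sw)
  }
  diag(pert) <- 0
  dm_pert <- distance_matrix(pert, "perturbational")

  # Stage 4: descriptive distance matrices
  S <- length(nonwake)
  corr_m <- matrix(0, S, S, dimnames = list(nonwake, nonwake))
  for (i in seq_len(S)) for (j in seq_len(S)) {
    if (i >= j) next
    a <- nonwake[i]; b <- nonwake[j]
    d <- connectivity_correlation_distance(
      group_fcs[[a]], group_fcs[[wake_map[[a]]]],
      group_fcs[[b]], group_fcs[[wake_map[[b]]]],
      r_threshold = cfg$thresholds$r_threshold,
      alpha = cfg$thresholds$alpha)$distance
    corr_m[i, j] <- corr_m[j, i] <- d
  }
  dm_corr <- distance_matrix(corr_m, "correlation")

  class_m <- matrix(NA_real_, S, S, dimnames = list(nonwake, nonwake))
  class_seed <- seeds[1]
  for (i in seq_len(S)) for (j in seq_len(S)) {
    ce <- if (i == j) NULL else cohorts[[nonwake[j]]]
    rep_ <- classification_distance(
      cohorts[[nonwake[i]]], ce, rf_config = cfg$classifier$rf_config,
      n_permutations = cfg$classifier$n_permutations,
      seed = (class_seed + i * 131 + j) %% .Machine$integer.max)
    class_m[i, j] <- rep_$distance
  }
  dm_class <- distance_matrix(class_m, "classification")

  mp <- outer(states, states, Vectorize(function(a, b)
    model_parameter_distance(fits[[a]]$a_best, fits[[b]]$a_best)))
  dimnames(mp) <- list(states, states)
  dm_mp <- distance_matrix(mp, "model_parameter")

  dms <- list(correlation = dm_corr, classification = dm_class,
              model_parameter = dm_mp, perturbational = dm_pert)
  dms_z <- lapply(names(dms), function(nm)
    tryCatch(zscore_distance_matrix(dms[[nm]]), error = function(e) {
      warning("z-scoring skipped for the ", nm, " metric: ",
              conditionMessage(e))
      out <- unclass(dms[[nm]])
      out[] <- NA_real_
      out
    }))
  names(dms_z) <- names(dms)

  # Stage 5: transition graph, state diagram, regional rankings
  graph <- build_transition_graph(pert, cfg$thresholds$delta_gof)
  diagram <- state_diagram(fits, graph, as.list(wake_map))
  states_df <- data.frame(
    state = states,
    route = vapply(cohorts, function(cc) cc$route %||% "default",
                   character(1)),
    depth = vapply(cohorts, function(cc)
      if (is.null(cc$wake_baseline)) 0 else cc$depth, numeric(1)))
  grouping <- grouping_from_levels(states_df)
  rankings <- rank_perturbation_targets(
    sweeps, grouping, top_fraction = cfg$thresholds$rank_top_fraction)

  # Cross-metric rank correlations over unique non-wake state pairs
  pair_vec <- function(dm) {
    m <- unclass(dm)[nonwake, nonwake]
    m <- (m + t(m)) / 2  # symmetrize directed metrics
    m[upper.tri(m)]
  }
  metric_correlations <- outer(names(dms), names(dms),
    Vectorize(function(a, b)
      suppressWarnings(cor(pair_vec(dms[[a]]), pair_vec(dms[[b]]),
                           method = "spearman"))))
  dimnames(metric_correlations) <- list(names(dms), names(dms))
  diag(metric_correlations) <- 1  # degenerate metrics: self-agreement is 1

  if (use_files) {
    for (nm in names(dms)) {
      write_matrix(unclass(dms[[nm]]),
                   file.path(out_dir, "distances", paste0(nm, ".tsv")),
                   header = colnames(dms[[nm]]))
      write_matrix(unclass(dms_z[[nm]]),
                   file.path(out_dir, "distances", paste0(nm, "_z.tsv")),
                   header = colnames(dms_z[[nm]]))
    }
    write.table(graph$edges, file.path(out_dir, "transition_edges.csv"),
                sep = ",", quote = FALSE, row.names = FALSE)
    write.table(diagram, file.path(out_dir, "state_diagram.csv"),
                sep = ",", quote = FALSE, row.names = FALSE)
    for (grp in names(rankings))
      write.table(rankings[[grp]]$ranks,
                  file.path(out_dir, paste0("ranking_", grp, ".csv")),
                  sep = ",", quote = FALSE, row.names = FALSE)
    write_matrix(metric_correlations,
                 file.path(out_dir, "metric_spearman.tsv"),
                 header = colnames(metric_correlations))
    jsonlite::write_json(
      list(thresholds = cfg$thresholds, master_seed = master_seed,
           band = unclass(cfg$band), states = states),
      file.path(out_dir, "resolved_config.json"),
      auto_unbox = TRUE, digits = NA)
  }
  list(group_fcs = group_fcs, omega = omega, fits = fits, sweeps = sweeps,
       distance_matrices = dms, distance_matrices_z = dms_z,
       transition_graph = graph,
       instability = instability_index(graph),
       state_diagram = diagram, grouping = grouping, rankings = rankings,
       metric_correlations = metric_correlations, config = cfg)
}
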