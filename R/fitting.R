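#' Expand RSN contributions into regional bifurcation parameters
#'
#' Each regional bifurcation parameter is the linear combination of the
#' contributions of the resting-state networks spanning that region:
#' `a_j = sum_k M[j, k] * g[k]`. With the usual six-network prior this
#' embeds the N regional parameters into a six-dimensional search space.
#'
#' @param membership N x K binary membership matrix.
#' @param g K-vector of per-network contributions.
#' @return N-vector of regional bifurcation parameters. Regions belonging to
#'   no network receive a = 0 (with a warning).
#' @export
expand_parameters <- function(membership, g) {
  membership <- as.matrix(membership)
  if (ncol(membership) != length(g))
    stop("membership has ", ncol(membership), " networks but g has length ",
         length(g))
  zero_rows <- which(rowSums(membership) == 0)
  if (length(zero_rows) > 0)
    warning("region(s) ", paste(zero_rows, collapse = ", "),
            " belong to no network; a = 0 assigned")
  as.numeric(membership %*% g)
}

#' Model-fitting objective: 1 - GoF
#'
#' Expands `g` into regional bifurcation parameters, simulates a group FC
#' with the same cohort size and observation pipeline as the empirical data,
#' and returns `1 - gof(simulated, target)`. Deterministic for a fixed seed,
#' so a fixed per-run seed gives the optimizer a deterministic surface
#' (common random numbers). A diverging simulation returns a large penalty
#' value with a warning so population-based optimization can continue.
#'
#' @param g K-vector of RSN contributions.
#' @param target_fc empirical group FC to fit.
#' @param membership N x K binary RSN matrix.
#' @param connectome N x N scaled coupling matrix.
#' @param omega per-region angular frequencies (rad/s).
#' @param sim_config list with `n_subjects`, `n_samples`, and optionally
#'   `tr`, `band`, `G`, `beta`, `dt`, `transient_seconds`.
#' @param seed simulation seed.
#' @param penalty objective value returned on integration blow-up.
#' @return scalar objective in `[0, 2]` (or `penalty`).
#' @export
objective <- function(g, target_fc, membership, connectome, omega,
                      sim_config, seed, penalty = 10) {
  n <- nrow(as.matrix(connectome))
  if (!all(dim(target_fc) == c(n, n)))
    stop("target FC shape does not match the connectome (", n, " regions)")
  a <- suppressWarnings(expand_parameters(membership, g))
  sc <- resolve_sim_config(sim_config)
  spec <- hopf_model_spec(a, omega, connectome, G = sc$G, beta = sc$beta,
                          dt = sc$dt)
  fc_sim <- tryCatch(
    simulated_group_fc(spec, sc$n_subjects, sc$n_samples, sc$tr, seed,
                       band = sc$band,
                       transient_seconds = sc$transient_seconds),
    error = function(e) {
      warning("simulation failed (", conditionMessage(e),
              "); penalty objective returned")
      NULL
    })
  if (is.null(fc_sim)) return(penalty)
  1 - gof(fc_sim, target_fc)
}

resolve_sim_config <- function(sim_config) {
  defaults <- list(n_subjects = 10L, n_samples = 200L, tr = 2, G = 0.5,
                   beta = 0.04, dt = 0.1, band = band_spec(),
                   transient_seconds = 100)
  utils::modifyList(defaults, as.list(sim_config))
}

resolve_ga_config <- function(ga_config) {
  defaults <- list(population = 10L, generations = 200L, n_runs = 100L,
                   bounds = c(-0.3, 0.3), tournament_size = 2L,
                   crossover_rate = 0.5, mutation_rate = 0.2,
                   mutation_sd = 0.02, elitism = 1L, penalty = 10)
  cfg <- utils::modifyList(defaults, as.list(ga_config))
  if (cfg$bounds[1] >= cfg$bounds[2])
    stop("infeasible gene bounds: lower >= upper")
  cfg
}

#' Fit regional bifurcation parameters to an empirical FC
#'
#' Real-coded genetic algorithm over the K RSN contributions, minimizing
#' `1 - GoF` (SSIM) between simulated and empirical group FC. Runs
#' `n_runs` independent optimizations (defaults mirror population 10,
#' 200 generations, 100 runs, all scalable down) and keeps the solution with
#' the lowest objective, i.e. the highest SSIM, across runs. Within each run
#' every candidate is evaluated with that run's fixed simulation seed, so
#' the optimized surface is deterministic. Fully reproducible for a fixed
#' `master_seed`.
#'
#' GA operators: tournament selection (size 2), uniform crossover (per-gene
#' rate 0.5), Gaussian mutation (sd 0.02, per-gene rate 0.2), elitism of 1,
#' genes clamped to `bounds` (default `[-0.3, 0.3]`, bracketing the
#' near-bifurcation regime).
#'
#' @param target_fc empirical group FC matrix (N x N).
#' @param connectome N x N scaled coupling matrix.
#' @param membership N x K binary RSN membership matrix.
#' @param omega per-region angular frequencies (rad/s).
#' @param ga_config named list overriding GA defaults (`population`,
#'   `generations`, `n_runs`, `bounds`, `tournament_size`, `crossover_rate`,
#'   `mutation_rate`, `mutation_sd`, `elitism`, `penalty`).
#' @param sim_config named list overriding simulation defaults (see
#'   [objective()]).
#' @param master_seed master RNG seed.
#' @return object of class `"hopf_fit"`: `g_best`, `a_best`, `gof_best`,
#'   `best_run`, `run_history` (per-run best-objective traces), `config`
#'   (resolved GA/simulation settings and per-run seeds).
#' @export
fit_state <- function(target_fc, connectome, membership, omega,
                      ga_config = list(), sim_config = list(),
                      master_seed = 1L) {
  ga <- resolve_ga_config(ga_config)
  sc <- resolve_sim_config(sim_config)
  n <- nrow(as.matrix(connectome))
  if (!all(dim(target_fc) == c(n, n)))
    stop("target FC shape does not match the connectome (", n, " regions)")
  K <- ncol(as.matrix(membership))
  seeds <- derive_seeds(master_seed, 2L * ga$n_runs)
  run_seeds <- seeds[seq_len(ga$n_runs)]
  sim_seeds <- seeds[ga$n_runs + seq_len(ga$n_runs)]

  eval_g <- function(g, sim_seed) preserve_rng(
    objective(g, target_fc, membership, connectome, omega, sc, sim_seed,
              penalty = ga$penalty))

  best <- list(obj = Inf)
  run_history <- vector("list", ga$n_runs)
  for (r in seq_len(ga$n_runs)) {
    res <- ga_run(eval_g, K, ga, run_seeds[r], sim_seeds[r])
    run_history[[r]] <- res$trace
    if (res$obj < best$obj)
      best <- list(obj = res$obj, g = res$g, run = r)
  }
  structure(list(
    g_best = best$g,
    a_best = suppressWarnings(expand_parameters(membership, best$g)),
    gof_best = 1 - best$obj,
    best_run = best$run,
    run_history = run_history,
    config = list(ga = ga, sim = sc, master_seed = master_seed,
                  run_seeds = run_seeds, sim_seeds = sim_seeds)),
    class = "hopf_fit")
}

#' @export
print.hopf_fit <- function(x, ...) {
  cat("Hopf model fit: GoF =", round(x$gof_best, 4), "(best of",
      length(x$run_history), "runs)\n  g =",
      paste(round(x$g_best, 4), collapse = ", "), "\n")
  invisible(x)
}

# One GA run on a deterministic objective surface (fixed sim_seed).
ga_run <- function(eval_g, K, ga, run_seed, sim_seed) {
  set.seed(as.integer(run_seed))
  lo <- ga$bounds[1]; hi <- ga$bounds[2]
  pop <- matrix(runif(ga$population * K, lo, hi), ga$population, K)
  fit <- apply(pop, 1, eval_g, sim_seed = sim_seed)
  trace <- numeric(ga$generations)
  for (gen in seq_len(ga$generations)) {
    ord <- order(fit)
    newpop <- matrix(NA_real_, ga$population, K)
    newfit <- rep(NA_real_, ga$population)
    n_elite <- min(ga$elitism, ga$population)
    if (n_elite > 0) {
      newpop[seq_len(n_elite), ] <- pop[ord[seq_len(n_elite)], , drop = FALSE]
      newfit[seq_len(n_elite)] <- fit[ord[seq_len(n_elite)]]
    }
    for (i in seq(n_elite + 1, ga$population)) {
      p1 <- tournament_pick(fit, ga$tournament_size)
      p2 <- tournament_pick(fit, ga$tournament_size)
      child <- ifelse(runif(K) < ga$crossover_rate, pop[p1, ], pop[p2, ])
      mut <- runif(K) < ga$mutation_rate
      if (any(mut))
        child[mut] <- child[mut] + rnorm(sum(mut), 0, ga$mutation_sd)
      newpop[i, ] <- pmin(pmax(child, lo), hi)
    }
    pop <- newpop
    todo <- which(is.na(newfit))
    fit <- newfit
    fit[todo] <- apply(pop[todo, , drop = FALSE], 1, eval_g,
                       sim_seed = sim_seed)
    trace[gen] <- min(fit)
  }
  b <- which.min(fit)
  list(g = pop[b, ], obj = fit[b], trace = trace)
}

tournament_pick <- function(fit, size) {
  cand <- sample.int(length(fit), size, replace = FALSE)
  cand[which.min(fit[cand])]
}
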