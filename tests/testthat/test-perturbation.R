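test_that("the normalized perturbational score has the stated boundaries", {
  expect_equal(delta_gof(0.9, 0.5, 0.5), 1)  # no movement from initial
  expect_equal(delta_gof(0.9, 0.5, 0.9), 0)  # reaches the target's own fit
  expect_equal(delta_gof(0.9, 0.5, 0.7), 0.5)
  # overshoot beyond the target's own fit is reported, not clipped
  expect_lt(delta_gof(0.9, 0.5, 0.95), 0)
  expect_error(delta_gof(0.7, 0.7, 0.5), "degenerate")
})

make_sweep <- function(grid, amplitudes = NULL, pairs = NULL) {
  P <- nrow(grid)
  if (is.null(pairs)) pairs <- cbind(i = 2 * seq_len(P) - 1, j = 2 * seq_len(P))
  if (is.null(amplitudes)) amplitudes <- seq(0, by = 0.1, length.out = ncol(grid))
  best_idx <- apply(grid, 1, which.min)
  structure(list(initial_state = "A", target_state = "B", pairs = pairs,
                 amplitudes = amplitudes, delta_gof = grid,
                 best_per_pair = data.frame(
                   pair_index = seq_len(P), i = pairs[, 1], j = pairs[, 2],
                   delta_gof = grid[cbind(seq_len(P), best_idx)],
                   amplitude = amplitudes[best_idx])),
            class = "sweep_result")
}

test_that("perturbational distance is the exhaustive grid minimum", {
  g <- matrix(0.8, 4, 5)
  g[3, 2] <- 0.2
  expect_equal(perturbational_distance(make_sweep(g)), 0.2)
  expect_equal(perturbational_distance(make_sweep(matrix(1, 3, 3))), 1)
  set.seed(21)
  for (k in 1:20) {
    r <- matrix(runif(12, -0.2, 1.2), 3, 4)
    mn <- Inf
    for (i in 1:3) for (j in 1:4) mn <- min(mn, r[i, j])  # brute force
    expect_equal(perturbational_distance(make_sweep(r)), mn)
  }
  # enlarging the grid can only decrease the minimum
  set.seed(22)
  big <- matrix(runif(40), 5, 8)
  small <- big[1:3, 1:4]
  expect_lte(perturbational_distance(make_sweep(big)),
             perturbational_distance(make_sweep(small)))
})

test_that("transition graphs use an inclusive threshold", {
  d <- matrix(0.5, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(nrow(build_transition_graph(d, 0.3)$edges), 0)
  d["A", "B"] <- 0.3
  g <- build_transition_graph(d, 0.3)
  expect_equal(g$edges$from, "A")
  expect_equal(g$edges$to, "B")
  d["C", "C"] <- 0.1  # self-transitions never count
  expect_equal(nrow(build_transition_graph(d, 0.3)$edges), 1)
  expect_error(build_transition_graph(matrix(1, 2, 3)), "square")
})

test_that("instability is the out-degree of the transition graph", {
  d <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", c("B", "C", "D")] <- 0.1  # star out of A
  inst <- instability_index(build_transition_graph(d, 0.3))
  expect_equal(inst, c(A = 3L, B = 0L, C = 0L, D = 0L))
  empty <- instability_index(build_transition_graph(matrix(1, 3, 3), 0.3))
  expect_equal(unname(empty), c(0L, 0L, 0L))
})

test_that("graph and out-degree agree with brute-force scans", {
  set.seed(31)
  for (k in 1:25) {
    S <- sample(3:6, 1)
    d <- matrix(runif(S * S), S, S,
                dimnames = list(paste0("s", 1:S), paste0("s", 1:S)))
    thr <- runif(1, 0.2, 0.8)
    g <- build_transition_graph(d, thr)
    expected <- 0L
    outdeg <- setNames(integer(S), rownames(d))
    for (i in 1:S) for (j in 1:S)
      if (i != j && d[i, j] <= thr) {
        expected <- expected + 1L
        outdeg[i] <- outdeg[i] + 1L
      }
    expect_equal(nrow(g$edges), expected)
    expect_equal(instability_index(g), outdeg)
  }
})

test_that("pair rankings average across transitions with tie handling", {
  grouping <- data.frame(initial = c("A", "A"), target = c("B", "C"),
                         group = c("up", "up"))
  s1 <- make_sweep(matrix(c(0.1, 0.2, 0.3, 0.4), 4, 1,
                          dimnames = NULL))
  s1$target_state <- "B"
  # reversed ranking in the second transition
  s2 <- make_sweep(matrix(c(0.4, 0.3, 0.2, 0.1), 4, 1))
  s2$target_state <- "C"
  res <- rank_perturbation_targets(list(s1, s2), grouping)
  expect_equal(res$up$ranks$avg_rank, rep(2.5, 4))
  # single transition: ranks are that sweep's ranks
  res1 <- rank_perturbation_targets(list(s1), grouping[1, ])
  expect_equal(res1$up$ranks$pair_index, 1:4)
  expect_equal(res1$up$ranks$avg_rank, 1:4)
  expect_equal(res1$up$top, 1:2)  # top 50% of 4 pairs
})

test_that("pair rankings match a brute-force rank-then-mean oracle", {
  set.seed(41)
  for (k in 1:20) {
    P <- 6
    vals <- lapply(1:3, function(i) round(runif(P), 1))  # ties likely
    sweeps <- lapply(seq_along(vals), function(i) {
      sw <- make_sweep(matrix(vals[[i]], P, 1))
      sw$target_state <- paste0("T", i)
      sw
    })
    grouping <- data.frame(initial = "A", target = paste0("T", 1:3),
                           group = "g")
    got <- rank_perturbation_targets(sweeps, grouping)$g$ranks
    oracle <- rowMeans(sapply(vals, rank))  # average ties by default
    expect_equal(got$avg_rank[order(got$pair_index)], oracle)
  }
  # mismatched pair lists are rejected
  s_bad <- make_sweep(matrix(1:3 / 10, 3, 1))
  s_bad$target_state <- "T1"
  sweeps <- list(make_sweep(matrix(1:4 / 10, 4, 1)), s_bad)
  sweeps[[1]]$target_state <- "T2"
  expect_error(rank_perturbation_targets(
    sweeps, data.frame(initial = "A", target = c("T2", "T1"), group = "g")),
    "same homotopic pair list")
})

test_that("state diagram couples model distance to wake with out-degree", {
  fits <- list(
    W = list(a_best = c(0.1, 0.1)),
    S1 = list(a_best = c(0.1, 0.1)),   # identical to wake
    S2 = list(a_best = c(0.1, -0.2)))
  d <- matrix(1, 3, 3, dimnames = list(c("W", "S1", "S2"),
                                       c("W", "S1", "S2")))
  d["S2", "W"] <- 0.1
  graph <- build_transition_graph(d, 0.3)
  wake_map <- list(W = "W", S1 = "W", S2 = "W")
  sd_ <- state_diagram(fits, graph, wake_map)
  expect_equal(sd_$level[sd_$state == "W"], 0)
  expect_equal(sd_$level[sd_$state == "S1"], 0)
  expect_equal(sd_$level[sd_$state == "S2"], 0.3)
  expect_equal(sd_$instability[sd_$state == "S2"], 1)
  expect_error(state_diagram(fits, graph, list(W = "W", S1 = "W")),
               "no wake baseline")
})

test_that("amplitude sweeps cache the baseline and fill the grid", {
  gt <- tiny_gt()
  coh <- tiny_cohort()
  fc_wake <- cohort_group_fc(coh$wake)
  fc_deep <- cohort_group_fc(coh$deepest)
  # stand-in fits built from the ground truth (no GA needed here)
  fit_of <- function(state, emp_fc) {
    spec <- hopf_model_spec(true_a(gt, state), gt$omega, gt$connectome)
    sim <- simulated_group_fc(spec, 4, 100, 2, seed = 55)
    list(g_best = gt$states[[state]]$g, a_best = true_a(gt, state),
         gof_best = gof(sim, emp_fc))
  }
  sw <- amplitude_sweep(fit_of("wake", fc_wake), fit_of("deepest", fc_deep),
                        fc_deep, gt$parcellation, gt$connectome, gt$omega,
                        sweep_config = list(amplitudes = c(0, 0.5, 1),
                                            n_reps = 3, n_samples = 100),
                        master_seed = 77,
                        initial_state = "wake", target_state = "deepest")
  expect_equal(dim(sw$delta_gof), c(3, 3))  # 3 homotopic pairs x 3 amplitudes
  expect_identical(sw$delta_gof[, 1], rep(1, 3))  # exact F0 = 0 boundary
  expect_true(all(is.finite(sw$delta_gof)))
  expect_equal(sw$global_best$value, min(sw$delta_gof))
  expect_equal(perturbational_distance(sw), min(sw$delta_gof))
  # degenerate pair rejected before sweeping
  bad_target <- fit_of("wake", fc_wake)
  bad_target$gof_best <- gof(simulated_group_fc(
    hopf_model_spec(true_a(gt, "wake"), gt$omega, gt$connectome),
    3, 100, 2, seed = 77), fc_wake)
  expect_error(
    amplitude_sweep(fit_of("wake", fc_wake), bad_target, fc_wake,
                    gt$parcellation, gt$connectome, gt$omega,
                    sweep_config = list(amplitudes = c(0, 0.5), n_reps = 3,
                                        n_samples = 100),
                    master_seed = 77),
    "degenerate")
  # amplitude grids must start at zero and increase
  expect_error(
    amplitude_sweep(fit_of("wake", fc_wake), fit_of("deepest", fc_deep),
                    fc_deep, gt$parcellation, gt$connectome, gt$omega,
                    sweep_config = list(amplitudes = c(0.5, 1))),
    "start at 0")
})
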