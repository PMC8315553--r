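test_that("FC differences surface the most changed connections", {
  A <- rand_fc(10, seed = 1)
  same <- fc_difference(A, A)
  expect_true(all(same$diff == 0))
  # deterministic tie-break by index on an all-tied matrix
  expect_equal(same$top$i[1], 1)
  expect_equal(same$top$j[1], 2)
  B <- A
  B[2, 5] <- B[5, 2] <- B[2, 5] + 0.5
  d <- fc_difference(B, A, extreme_fraction = 0.1)
  expect_equal(d$top$i[1], 2)
  expect_equal(d$top$j[1], 5)
  expect_equal(d$top$value[1], 0.5)
})

test_that("extreme-edge lists match a brute-force sort on 90 regions", {
  A <- rand_fc(90, seed = 2)
  W <- rand_fc(90, seed = 3)
  res <- fc_difference(A, W, extreme_fraction = 0.05)
  expect_equal(nrow(res$top), 200)     # floor(0.05 * 4005)
  expect_equal(nrow(res$bottom), 200)
  D <- A - W
  v <- D[upper.tri(D)]
  expect_equal(sort(res$top$value, decreasing = TRUE),
               sort(v, decreasing = TRUE)[1:200])
  expect_equal(sort(res$bottom$value), sort(v)[1:200])
})

test_that("difference correlation is the upper-triangle Pearson", {
  D <- rand_fc(8, seed = 4) - rand_fc(8, seed = 5)
  expect_equal(difference_correlation(D, D), 1)
  expect_equal(difference_correlation(D, -D), -1)
  E <- rand_fc(8, seed = 6) - rand_fc(8, seed = 7)
  expect_equal(difference_correlation(D, E),
               cor(D[upper.tri(D)], E[upper.tri(E)]), tolerance = 1e-10)
  expect_error(difference_correlation(D, matrix(0, 8, 8)), "zero-variance")
})

test_that("connectivity-correlation distance detects shared change profiles", {
  W1 <- rand_fc(12, seed = 8); S1 <- rand_fc(12, seed = 9)
  # identical difference profiles: every region matches, distance 0
  r <- connectivity_correlation_distance(S1, W1, S1, W1)
  expect_equal(r$distance, 0)
  expect_true(all(r$indicator == 1))
  # negated differences: |R| = 1 everywhere, still distance 0
  W2 <- rand_fc(12, seed = 10)
  S2 <- W2 - (S1 - W1)  # so S2 - W2 = -(S1 - W1)
  rn <- connectivity_correlation_distance(S1, W1, S2, W2)
  expect_equal(rn$distance, 0)
  expect_true(all(rn$r < -0.99))
})

test_that("independent random difference profiles are maximally distant", {
  # null behavior at AAL scale: length-89 independent profiles essentially
  # never exceed |R| > 0.5 with Bonferroni-corrected significance
  set.seed(11)
  d <- replicate(3, {
    fcs <- lapply(1:4, function(i) rand_fc(90, seed = sample.int(1e6, 1)))
    connectivity_correlation_distance(fcs[[1]], fcs[[2]],
                                      fcs[[3]], fcs[[4]])$distance
  })
  expect_true(all(d >= 0.9))
})

test_that("model-parameter distance is a metric", {
  expect_equal(model_parameter_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(model_parameter_distance(1:5, 1:5), 0)
  set.seed(12)
  for (k in 1:20) {
    a <- rnorm(6); b <- rnorm(6); c <- rnorm(6)
    expect_equal(model_parameter_distance(a, b),
                 model_parameter_distance(b, a))
    expect_lte(model_parameter_distance(a, c),
               model_parameter_distance(a, b) +
                 model_parameter_distance(b, c) + 1e-12)
  }
  expect_error(model_parameter_distance(1:3, 1:4), "length")
})

test_that("distance-matrix z-scoring uses population statistics", {
  m <- matrix(0, 3, 3)
  m[upper.tri(m)] <- c(1, 2, 3)
  m <- m + t(m)
  dm <- distance_matrix(m, "model_parameter")
  z <- zscore_distance_matrix(dm)
  expect_equal(sort(z[upper.tri(z)]),
               c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(diag(z), diag(m))  # diagonal untouched
  # location invariance
  dm2 <- distance_matrix(m + 5 - diag(5, 3), "model_parameter")
  z2 <- zscore_distance_matrix(dm2)
  expect_equal(z2[upper.tri(z2)], z[upper.tri(z)], tolerance = 1e-12)
  expect_error(zscore_distance_matrix(
    distance_matrix(matrix(1, 3, 3) - diag(1, 3), "model_parameter")),
    "zero variance")
})

test_that("z-scored matrices match a mean/sd oracle and normalize exactly", {
  set.seed(13)
  for (k in 1:10) {
    S <- sample(4:7, 1)
    m <- matrix(runif(S * S), S, S)  # asymmetric: all off-diagonals count
    diag(m) <- 0
    dm <- distance_matrix(m, "perturbational")
    z <- zscore_distance_matrix(dm)
    off <- !diag(TRUE, S)
    v <- m[off]
    expect_equal(z[off], (v - mean(v)) / sqrt(mean((v - mean(v))^2)),
                 tolerance = 1e-12)
    expect_equal(mean(z[off]), 0, tolerance = 1e-12)
    expect_equal(sqrt(mean(z[off]^2)), 1, tolerance = 1e-12)
  }
})

test_that("top-fraction similarity graphs keep the closest state pairs", {
  set.seed(14)
  m <- matrix(runif(16), 4, 4)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  rownames(m) <- colnames(m) <- paste0("s", 1:4)
  dm <- distance_matrix(m, "model_parameter")
  # 6 unique pairs: fraction 0.25 keeps floor(1.5) = 1 edge, 1.0 keeps all
  expect_equal(nrow(top_fraction_graph(dm, 0.25)), 1)
  expect_equal(nrow(top_fraction_graph(dm, 1.0)), 6)
  g <- top_fraction_graph(dm, 0.5)
  v <- sort(m[upper.tri(m)])
  expect_equal(sort(g$distance), v[1:3])
  # oracle on random asymmetric matrices
  for (k in 1:20) {
    S <- sample(4:6, 1)
    a <- matrix(runif(S * S), S, S); diag(a) <- 0
    dma <- distance_matrix(a, "classification")
    frac <- runif(1, 0.2, 1)
    got <- top_fraction_graph(dma, frac)
    off <- a[!diag(TRUE, S)]
    expect_equal(nrow(got), floor(frac * length(off) + 1e-9))
    expect_equal(got$distance, sort(off)[seq_len(nrow(got))])
  }
  # an 8-unique-pair example: 0.25 keeps exactly 2
  m8 <- matrix(runif(64), 8, 8); m8 <- (m8 + t(m8)) / 2; diag(m8) <- 0
  # symmetric 8x8 has 28 pairs; build a 4-state asymmetric one instead
  m4 <- matrix(runif(16), 4, 4); diag(m4) <- 0  # 12 informative entries
  expect_equal(nrow(top_fraction_graph(distance_matrix(m4, "perturbational"),
                                       2 / 12)), 2)
})

test_that("distance_matrix validates symmetry per metric", {
  m <- matrix(runif(9), 3, 3)
  expect_error(distance_matrix(m, "correlation"), "symmetric")
  expect_s3_class(distance_matrix(m, "classification"), "distance_matrix")
})

test_that("internal AUC agrees with pROC on random scores", {
  skip_if_not_installed("pROC")
  set.seed(15)
  for (k in 1:10) {
    y <- sample(c(TRUE, FALSE), 30, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(y)) < 2) next
    s <- rnorm(30)
    ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                          quiet = TRUE, direction = "<")))
    expect_equal(hopfbrain:::auc_score(y, s), ref, tolerance = 1e-12)
  }
})

separable_cohorts <- function(n_regions = 12, n_subj = 8, shift = 0.8,
                              seed = 1) {
  set.seed(seed)
  base <- rand_fc(n_regions, seed = seed + 500)
  edges <- which(upper.tri(base), arr.ind = TRUE)
  hot <- edges[sample(nrow(edges), ceiling(0.1 * nrow(edges))), , drop = FALSE]
  mk <- function(shifted) {
    lapply(seq_len(n_subj), function(i) {
      fc <- base + matrix(rnorm(n_regions^2, 0, 0.05), n_regions)
      fc <- (fc + t(fc)) / 2
      diag(fc) <- 1
      if (shifted) for (r in seq_len(nrow(hot)))
        fc[hot[r, 1], hot[r, 2]] <- fc[hot[r, 2], hot[r, 1]] <-
          fc[hot[r, 1], hot[r, 2]] + shift
      pmin(pmax(fc, -1), 1)
    })
  }
  wake <- state_dataset("wake", mk(FALSE))
  state_dataset("deep", mk(TRUE), wake_baseline = wake)
}

test_that("classifiers separate shifted-FC cohorts and transfer", {
  coh <- separable_cohorts(seed = 2)
  rep_ <- classification_distance(coh, rf_config = list(ntree = 200),
                                  n_permutations = 0, seed = 3)
  expect_gte(rep_$auc_mean, 0.95)
  expect_lte(rep_$distance, 0.05)
  # transfer to an independently generated cohort with the same pattern
  coh2 <- separable_cohorts(seed = 2)  # same hot edges (same seed), new noise?
  coh2b <- separable_cohorts(seed = 7)
  tr <- classification_distance(coh, coh2b,
                                rf_config = list(ntree = 200, n_repeats = 3),
                                n_permutations = 0, seed = 4)
  expect_s3_class(tr, "classifier_report")
  expect_true(tr$auc_mean >= 0 && tr$auc_mean <= 1)
  # determinism
  rep2 <- classification_distance(coh, rf_config = list(ntree = 200),
                                  n_permutations = 0, seed = 3)
  expect_identical(rep_$auc_values, rep2$auc_values)
})

test_that("classification preconditions are enforced", {
  small_wake <- state_dataset("wake", lapply(1:3, function(i)
    rand_fc(6, seed = i)))
  small <- state_dataset("deep", lapply(4:6, function(i)
    rand_fc(6, seed = i)), wake_baseline = small_wake)
  expect_error(classification_distance(small), "at least 5")
  nobase <- state_dataset("deep", lapply(1:6, function(i) rand_fc(6, seed = i)))
  expect_error(classification_distance(nobase), "baseline")
})
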