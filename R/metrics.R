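#' FC difference between a state and its wakefulness baseline
#'
#' Computes the elementwise difference of two group FC matrices and lists
#' the upper-triangle connections in the top and bottom `extreme_fraction`
#' by signed difference (the connections most increased and most decreased
#' relative to wakefulness). Ties are broken deterministically by region
#' index.
#'
#' @param state_group_fc,wake_group_fc group FC matrices of equal size.
#' @param extreme_fraction fraction of edges per list (default 0.05).
#' @return list: `diff` (difference matrix, attribute `kind =
#'   "difference"`), `top`, `bottom` (data.frames i, j, value).
#' @export
fc_difference <- function(state_group_fc, wake_group_fc,
                          extreme_fraction = 0.05) {
  A <- unclass(as.matrix(state_group_fc))
  B <- unclass(as.matrix(wake_group_fc))
  if (!all(dim(A) == dim(B))) stop("FC matrices must have the same shape")
  D <- A - B
  attr(D, "kind") <- "difference"
  ut <- which(upper.tri(D), arr.ind = TRUE)
  edges <- data.frame(i = ut[, 1], j = ut[, 2], value = D[ut])
  m <- max(1L, floor(extreme_fraction * nrow(edges) + 1e-9))
  ord_desc <- order(-edges$value, edges$i, edges$j)
  ord_asc <- order(edges$value, edges$i, edges$j)
  list(diff = D,
       top = edges[head(ord_desc, m), , drop = FALSE],
       bottom = edges[head(ord_asc, m), , drop = FALSE])
}

#' Correlation between two FC difference matrices
#'
#' Pearson correlation of the upper-triangle vectors of two state-minus-wake
#' difference matrices.
#'
#' @param diff_a,diff_b difference matrices of equal size.
#' @return scalar correlation.
#' @export
difference_correlation <- function(diff_a, diff_b) {
  A <- unclass(as.matrix(diff_a)); B <- unclass(as.matrix(diff_b))
  if (!all(dim(A) == dim(B))) stop("difference matrices must match in shape")
  va <- A[upper.tri(A)]; vb <- B[upper.tri(B)]
  if (sd(va) == 0 || sd(vb) == 0)
    stop("zero-variance difference matrix; correlation undefined")
  cor(va, vb)
}

#' Connectivity-correlation distance between two states
#'
#' For each region j, the regional profile of FC changes (row j of the
#' state-minus-wake difference matrix, excluding the diagonal entry) of the
#' two states is correlated. The indicator I(j) is 1 when |R| exceeds
#' `r_threshold` and the correlation is significant at `alpha` after
#' Bonferroni correction over the N regions. The distance is
#' `1 - mean(I)`: 0 when every regional change profile is shared, 1 when
#' none is.
#'
#' @param fc_1,wake_1 group FC of state 1 and its wakefulness baseline.
#' @param fc_2,wake_2 group FC of state 2 and its wakefulness baseline.
#' @param r_threshold absolute-correlation threshold (default 0.5).
#' @param alpha significance level before Bonferroni correction
#'   (default 0.05).
#' @return list: `distance`, `indicator` (0/1 per region), `r` (signed
#'   per-region correlations, so either sign convention can be audited),
#'   `p_bonferroni`.
#' @export
connectivity_correlation_distance <- function(fc_1, wake_1, fc_2, wake_2,
                                              r_threshold = 0.5,
                                              alpha = 0.05) {
  D1 <- unclass(as.matrix(fc_1)) - unclass(as.matrix(wake_1))
  D2 <- unclass(as.matrix(fc_2)) - unclass(as.matrix(wake_2))
  if (!all(dim(D1) == dim(D2))) stop("difference matrices must match in shape")
  n <- nrow(D1)
  if (n < 3) stop("need at least 3 regions")
  r <- numeric(n); p <- rep(NA_real_, n); ind <- integer(n)
  for (j in seq_len(n)) {
    prof1 <- D1[j, -j]; prof2 <- D2[j, -j]
    if (sd(prof1) == 0 || sd(prof2) == 0) {
      warning("zero-variance regional profile at region ", j,
              "; indicator set to 0")
      r[j] <- NA_real_
      next
    }
    ct <- cor.test(prof1, prof2)
    r[j] <- unname(ct$estimate)
    p[j] <- min(1, ct$p.value * n)  # Bonferroni over regions
    ind[j] <- as.integer(abs(r[j]) > r_threshold && p[j] < alpha)
  }
  list(distance = 1 - mean(ind), indicator = ind, r = r, p_bonferroni = p)
}

#' Model-parameter distance between two fitted states
#'
#' Euclidean distance between two regional bifurcation-parameter vectors
#' (one local parameter per region of the parcellation).
#'
#' @param a_1,a_2 numeric vectors of equal length.
#' @return scalar distance.
#' @export
model_parameter_distance <- function(a_1, a_2) {
  if (length(a_1) != length(a_2))
    stop("parameter vectors differ in length")
  sqrt(sum((a_1 - a_2)^2))
}

# Upper-triangle feature vectors of a cohort's individual FC matrices.
cohort_features <- function(cohort, band = band_spec(), filter = TRUE) {
  lapply(cohort$subjects, function(s) {
    fc <- if (inherits(s, "bold_series")) {
      x <- if (filter) zscore(bandpass(s, band)) else s
      compute_fc(x)
    } else as.matrix(s)
    fc[upper.tri(fc)]
  })
}

# Rank-based (Mann-Whitney) AUC of scores for a logical positive label.
auc_score <- function(positive, score) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes present")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

rf_score <- function(X_train, y_train, X_eval, rf_config, seed) {
  mtry <- rf_config$mtry %||% max(1L, round(sqrt(ncol(X_train))))
  ntree <- rf_config$ntree %||% 1000L
  preserve_rng({
    set.seed(as.integer(seed))
    fit <- randomForest::randomForest(x = X_train, y = y_train,
                                      ntree = ntree, mtry = mtry)
    predict(fit, X_eval, type = "prob")[, 2]
  })
}

stratified_folds <- function(y, k, seed) {
  preserve_rng({
    set.seed(as.integer(seed))
    fold <- integer(length(y))
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

cv_auc <- function(X, y, k, rf_config, seed) {
  fold <- stratified_folds(y, k, seed)
  fold_seeds <- derive_seeds(seed, k)
  vapply(seq_len(k), function(f) {
    tr <- fold != f
    sc <- rf_score(X[tr, , drop = FALSE], y[tr],
                   X[!tr, , drop = FALSE], rf_config, fold_seeds[f])
    auc_score(y[!tr] == levels(y)[2], sc)
  }, numeric(1))
}

#' Classification distance between brain states
#'
#' Random-forest classifiers (1000 trees, `round(sqrt(p))` features per
#' split, Gini impurity, fully grown trees) are trained to separate a state
#' from its matched wakefulness baseline using the vectorized upper triangle
#' of each subject's FC matrix as features. Self-classification accuracy is
#' the mean AUC of a stratified 5-fold cross-validation; transfer accuracy
#' trains on the full training cohort and evaluates the AUC on another
#' state-vs-wake cohort (mean and sd over `n_repeats` forest seeds). The
#' classification distance is `1 - <AUC>`. Significance is assessed by
#' retraining on label-shuffled data (`n_permutations` times); the p-value
#' counts permuted AUCs at or above the observed mean.
#'
#' @param cohort_train [state_dataset()] with a linked wakefulness baseline;
#'   subjects may be BOLD series (FC computed via the standard pipeline) or
#'   individual FC matrices.
#' @param cohort_eval optional evaluation cohort (with baseline) for
#'   transfer; `NULL` for self-classification.
#' @param rf_config list overriding `ntree`, `mtry`, `n_folds`, `n_repeats`,
#'   `filter` (band-pass before FC), `band`.
#' @param n_permutations label shuffles for the empirical p-value (0 skips).
#' @param seed RNG seed.
#' @return list of class `"classifier_report"`: `train_state`, `eval_state`,
#'   `auc_mean`, `auc_sd`, `auc_values`, `p_value`, `n_permutations`,
#'   `distance`.
#' @export
classification_distance <- function(cohort_train, cohort_eval = NULL,
                                    rf_config = list(),
                                    n_permutations = 1000L, seed = 1L) {
  cfg <- utils::modifyList(list(ntree = 1000L, mtry = NULL, n_folds = 5L,
                                n_repeats = 10L, filter = TRUE,
                                band = band_spec()),
                           as.list(rf_config))
  build_xy <- function(cohort) {
    if (is.null(cohort$wake_baseline))
      stop("cohort '", cohort$state_name, "' has no wakefulness baseline")
    fs <- cohort_features(cohort, cfg$band, cfg$filter)
    fw <- cohort_features(cohort$wake_baseline, cfg$band, cfg$filter)
    list(X = do.call(rbind, c(fw, fs)),
         y = factor(rep(c("wake", "state"), c(length(fw), length(fs))),
                    levels = c("wake", "state")))
  }
  tr <- build_xy(cohort_train)
  if (min(table(tr$y)) < 5)
    stop("need at least 5 subjects per class for cross-validation")
  seeds <- derive_seeds(seed, 3L)

  if (is.null(cohort_eval)) {
    observed <- function(y) cv_auc(tr$X, y, cfg$n_folds, cfg, seeds[1])
    aucs <- observed(tr$y)
    eval_state <- cohort_train$state_name
  } else {
    ev <- build_xy(cohort_eval)
    if (ncol(ev$X) != ncol(tr$X))
      stop("train and eval cohorts have different region counts")
    rep_seeds <- derive_seeds(seeds[1], cfg$n_repeats)
    observed <- function(y) vapply(rep_seeds, function(s)
      auc_score(ev$y == "state",
                rf_score(tr$X, y, ev$X, cfg, s)), numeric(1))
    aucs <- observed(tr$y)
    eval_state <- cohort_eval$state_name
  }
  auc_mean <- mean(aucs)

  p_value <- NA_real_
  null_aucs <- NULL
  if (n_permutations > 0) {
    perm_seeds <- derive_seeds(seeds[2], n_permutations)
    null_aucs <- vapply(perm_seeds, function(s) {
      y_perm <- preserve_rng({ set.seed(s); sample(tr$y) })
      mean(observed(y_perm))
    }, numeric(1))
    p_value <- (1 + sum(null_aucs >= auc_mean)) / (1 + n_permutations)
  }
  structure(list(train_state = cohort_train$state_name,
                 eval_state = eval_state,
                 auc_mean = auc_mean, auc_sd = sd(aucs), auc_values = aucs,
                 null_aucs = null_aucs, p_value = p_value,
                 n_permutations = n_permutations,
                 distance = 1 - auc_mean),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("Classifier ", x$train_state, " vs wake -> ", x$eval_state,
      " vs wake: <AUC> = ", round(x$auc_mean, 3), " +/- ",
      round(x$auc_sd, 3), ", distance = ", round(x$distance, 3), sep = "")
  if (!is.na(x$p_value)) cat(", p =", signif(x$p_value, 3))
  cat("\n")
  invisible(x)
}

#' Assemble a states-by-states distance matrix
#'
#' @param values S x S numeric matrix with state dimnames.
#' @param metric one of `"correlation"`, `"classification"`,
#'   `"model_parameter"`, `"perturbational"`.
#' @return matrix of class `"distance_matrix"` with attribute `metric`;
#'   correlation and model-parameter metrics are marked symmetric.
#' @export
distance_matrix <- function(values, metric = c("correlation",
                                               "classification",
                                               "model_parameter",
                                               "perturbational")) {
  metric <- match.arg(metric)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("distance matrix must be square")
  symmetric <- metric %in% c("correlation", "model_parameter")
  if (symmetric && any(abs(values - t(values)) > 1e-8, na.rm = TRUE))
    stop(metric, " distance matrix must be symmetric")
  structure(values, metric = metric, symmetric = symmetric,
            class = c("distance_matrix", "matrix"))
}

informative_entries <- function(dm) {
  sym <- isTRUE(attr(dm, "symmetric"))
  if (sym) which(upper.tri(dm)) else which(!diag(TRUE, nrow(dm)))
}

#' Z-score a distance matrix over its informative entries
#'
#' Distances of different metrics live on different scales; z-scoring over
#' the informative entries (unique off-diagonal pairs for symmetric metrics,
#' all off-diagonal entries otherwise, using the population standard
#' deviation) makes them comparable. The diagonal is left untouched.
#'
#' @param dm a [distance_matrix()].
#' @return z-scored `distance_matrix`.
#' @export
zscore_distance_matrix <- function(dm) {
  idx <- informative_entries(dm)
  if (length(idx) < 3) stop("need at least 3 informative entries")
  v <- dm[idx]
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))  # population sd
  if (sigma == 0) stop("zero variance among informative entries")
  out <- unclass(dm)
  if (isTRUE(attr(dm, "symmetric"))) {
    z <- (out - mu) / sigma
    diag(z) <- diag(out)
    out <- z
  } else {
    off <- !diag(TRUE, nrow(out))
    out[off] <- (out[off] - mu) / sigma
  }
  structure(out, metric = attr(dm, "metric"),
            symmetric = attr(dm, "symmetric"),
            class = c("distance_matrix", "matrix"))
}

#' Closest state pairs of a distance matrix
#'
#' Returns the `fraction` of state pairs with the smallest distance
#' (strongest similarity), ties broken by index order — the edge list behind
#' "top 25%" similarity graphs.
#'
#' @param dm a [distance_matrix()].
#' @param fraction fraction of pairs to keep, in (0, 1].
#' @return data.frame `from`, `to`, `distance` sorted by distance.
#' @export
top_fraction_graph <- function(dm, fraction = 0.25) {
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  states <- rownames(dm) %||% paste0("S", seq_len(nrow(dm)))
  idx <- informative_entries(dm)
  ai <- arrayInd(idx, dim(dm))
  edges <- data.frame(from = states[ai[, 1]], to = states[ai[, 2]],
                      distance = dm[idx], stringsAsFactors = FALSE)
  ord <- order(edges$distance, ai[, 1], ai[, 2])
  m <- floor(fraction * nrow(edges) + 1e-9)
  out <- edges[head(ord, m), , drop = FALSE]
  rownames(out) <- NULL
  out
}
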