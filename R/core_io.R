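#' Construct a parcellation
#'
#' A parcellation holds the ordered region labels of an atlas, the hemisphere
#' of each region (`"L"`, `"R"` or `"M"` for midline), the index of each
#' region's homotopic (mirror-symmetric contralateral) partner, and an
#' optional binary resting-state-network (RSN) membership matrix used as an
#' anatomical prior when fitting regional model parameters.
#'
#' @param labels character vector of region names (ordered as in the data).
#' @param hemisphere character vector, one of `"L"`, `"R"`, `"M"` per region.
#' @param partner integer vector of 1-based homotopic partner indices;
#'   `NA` for unpaired (midline) regions. Defaults to AAL-style interleaved
#'   left/right ordering, pairing regions (1,2), (3,4), ...
#' @param rsn optional N x K binary membership matrix (region in network).
#'
#' @return An object of class `"parcellation"`.
#' @export
parcellation <- function(labels, hemisphere, partner = NULL, rsn = NULL) {
  n <- length(labels)
  stopifnot(length(hemisphere) == n)
  if (!all(hemisphere %in% c("L", "R", "M")))
    stop("hemisphere tags must be 'L', 'R' or 'M'")
  if (is.null(partner)) {
    if (n %% 2 != 0)
      stop("default interleaved pairing needs an even number of regions")
    partner <- as.integer(ifelse(seq_len(n) %% 2 == 1,
                                 seq_len(n) + 1L, seq_len(n) - 1L))
    partner[hemisphere == "M"] <- NA_integer_
  }
  partner <- as.integer(partner)
  stopifnot(length(partner) == n)
  for (j in seq_len(n)) {
    p <- partner[j]
    if (is.na(p)) {
      if (hemisphere[j] != "M")
        stop("lateral region '", labels[j], "' has no homotopic partner")
      next
    }
    if (p < 1 || p > n || p == j)
      stop("invalid partner index for region '", labels[j], "'")
    if (partner[p] != j)
      stop("homotopic pairing is not an involution at region '", labels[j], "'")
    if (hemisphere[p] == hemisphere[j])
      stop("homotopic partners '", labels[j], "' and '", labels[p],
           "' share hemisphere '", hemisphere[j], "'")
  }
  if (!is.null(rsn)) {
    rsn <- as.matrix(rsn)
    if (nrow(rsn) != n) stop("rsn membership must have one row per region")
    if (!all(rsn %in% c(0, 1))) stop("rsn membership entries must be 0 or 1")
  }
  structure(list(labels = labels, hemisphere = hemisphere,
                 partner = partner, rsn = rsn),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat("Parcellation:", length(x$labels), "regions,",
      sum(!is.na(x$partner)) / 2, "homotopic pairs")
  if (!is.null(x$rsn)) cat(",", ncol(x$rsn), "RSNs")
  cat("\n")
  invisible(x)
}

#' Number of regions in a parcellation
#' @param parc a [parcellation()].
#' @return integer region count.
#' @export
n_regions <- function(parc) length(parc$labels)

#' Enumerate homotopic region pairs
#'
#' Lists every homotopic (left/right mirror) pair of the parcellation once,
#' lower index first, in increasing order of the lower index. On a fully
#' paired N-region atlas this yields N/2 pairs (45 for the 90-region AAL).
#'
#' @param parc a [parcellation()].
#' @return integer matrix with columns `i`, `j` (1-based region indices).
#' @export
enumerate_homotopic_pairs <- function(parc) {
  n <- n_regions(parc)
  unpaired <- which(is.na(parc$partner) & parc$hemisphere != "M")
  if (length(unpaired) > 0)
    stop("unpaired lateral region: ", parc$labels[unpaired[1]])
  keep <- which(!is.na(parc$partner) & seq_len(n) < parc$partner)
  cbind(i = keep, j = parc$partner[keep])
}

#' Scale a structural connectome to a maximum coupling weight
#'
#' Structural connectivity matrices are rescaled so their largest entry
#' equals `ceiling` (default 0.2, the weak-coupling condition that keeps the
#' coupled oscillators in their oscillatory regime). Entry ratios are
#' preserved.
#'
#' @param C square non-negative weight matrix with zero diagonal.
#' @param ceiling target maximum weight.
#' @return the rescaled matrix, with attribute `scaled = TRUE`.
#' @export
scale_connectome <- function(C, ceiling = 0.2) {
  C <- as.matrix(C)
  validate_connectome(C)
  m <- max(C)
  if (m <= 0) stop("cannot scale an all-zero connectome")
  out <- C * (ceiling / m)
  attr(out, "scaled") <- TRUE
  out
}

validate_connectome <- function(C) {
  if (nrow(C) != ncol(C)) stop("connectome must be square")
  if (any(C < 0)) stop("connectome weights must be non-negative")
  if (any(diag(C) != 0)) stop("connectome diagonal must be zero")
  invisible(C)
}

#' Read a numeric matrix from delimited text
#'
#' Reads a whitespace- or comma-delimited numeric matrix, with an optional
#' single header line (detected when the first line contains non-numeric
#' tokens). Malformed input (ragged rows, non-numeric tokens) raises an error
#' naming the offending line.
#'
#' @param path file path.
#' @param expected_n optional expected number of columns (and, for square
#'   matrices, rows); a mismatch is an error.
#' @param square require a square matrix (default FALSE).
#' @return numeric matrix.
#' @export
read_matrix <- function(path, expected_n = NULL, square = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty matrix file: ", path)
  tokenize <- function(l) strsplit(trimws(l), "[,[:space:]]+")[[1]]
  first <- tokenize(lines[1])
  start <- 1L
  if (any(is.na(suppressWarnings(as.numeric(first))))) start <- 2L
  if (start > length(lines)) stop("no data rows in ", path)
  ncol0 <- length(tokenize(lines[start]))
  rows <- vector("list", length(lines) - start + 1L)
  for (k in seq_along(rows)) {
    ln <- start + k - 1L
    tok <- tokenize(lines[ln])
    if (length(tok) != ncol0)
      stop("parse error in ", path, " at line ", ln, ": expected ",
           ncol0, " values, found ", length(tok))
    v <- suppressWarnings(as.numeric(tok))
    if (any(is.na(v)))
      stop("parse error in ", path, " at line ", ln, ": non-numeric token '",
           tok[which(is.na(v))[1]], "'")
    rows[[k]] <- v
  }
  m <- do.call(rbind, rows)
  if (square && nrow(m) != ncol(m))
    stop("expected a square matrix in ", path, ", got ",
         nrow(m), "x", ncol(m))
  if (!is.null(expected_n) && ncol(m) != expected_n)
    stop("shape mismatch in ", path, ": expected ", expected_n,
         " columns, found ", ncol(m))
  m
}

#' Write a numeric matrix as TSV
#'
#' Full double precision is kept so that a write/read round trip reproduces
#' values to within 1e-12 relative error.
#'
#' @param m numeric matrix.
#' @param path output file path.
#' @param header optional character vector of column names.
#' @export
write_matrix <- function(m, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste(header, collapse = "\t"), con)
  writeLines(apply(m, 1, function(r)
    paste(sprintf("%.17g", r), collapse = "\t")), con)
  invisible(path)
}

#' Construct a regional BOLD time-series object
#'
#' @param samples T x N numeric matrix, one column per region.
#' @param tr_seconds sampling interval (repetition time) in seconds.
#' @return matrix of class `"bold_series"` with attribute `tr`.
#' @export
bold_series <- function(samples, tr_seconds) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 2) stop("a BOLD series needs at least 2 samples")
  if (any(!is.finite(samples))) stop("BOLD series contains missing values")
  if (!is.numeric(tr_seconds) || tr_seconds <= 0) stop("tr_seconds must be > 0")
  structure(samples, tr = tr_seconds, class = c("bold_series", "matrix"))
}

#' @export
print.bold_series <- function(x, ...) {
  cat("BOLD series:", nrow(x), "samples x", ncol(x), "regions, TR =",
      attr(x, "tr"), "s\n")
  invisible(x)
}

tr_of <- function(x) {
  tr <- attr(x, "tr")
  if (is.null(tr)) stop("missing TR attribute on BOLD series")
  tr
}

#' Group recordings of one brain state into a dataset
#'
#' A state dataset holds the per-subject recordings (BOLD series or
#' individual FC matrices) of one named brain state (e.g. N3 sleep, propofol
#' anesthesia, UWS) and, for every non-wake state, a reference to the
#' wakefulness dataset acquired at the same site.
#'
#' @param state_name state label.
#' @param subjects list of [bold_series()] objects or square FC matrices.
#' @param wake_baseline optional matched wakefulness `state_dataset`.
#' @param route optional acquisition route / dataset tag (e.g. "sleep",
#'   "propofol", "doc") used when grouping transitions.
#' @param depth optional nominal depth rank within the route (0 = wake).
#' @return object of class `"state_dataset"`.
#' @export
state_dataset <- function(state_name, subjects, wake_baseline = NULL,
                          route = NULL, depth = NA_real_) {
  stopifnot(is.character(state_name), length(subjects) >= 1)
  ns <- vapply(subjects, ncol, integer(1))
  if (length(unique(ns)) != 1)
    stop("all subjects must share the same number of regions")
  if (!is.null(wake_baseline)) {
    stopifnot(inherits(wake_baseline, "state_dataset"))
    if (ncol(wake_baseline$subjects[[1]]) != ns[1])
      stop("wake baseline has a different number of regions")
  }
  structure(list(state_name = state_name, subjects = subjects,
                 wake_baseline = wake_baseline, route = route, depth = depth),
            class = "state_dataset")
}

#' @export
print.state_dataset <- function(x, ...) {
  cat("State '", x$state_name, "': ", length(x$subjects), " subjects, ",
      ncol(x$subjects[[1]]), " regions",
      if (!is.null(x$wake_baseline))
        paste0(" (wake baseline: ", x$wake_baseline$state_name, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Read a parcellation from TSV files
#'
#' The parcellation file has columns `label`, `hemisphere`, `partner_index`
#' (0-based, -1 or empty for none) and the optional RSN file is an N x K
#' binary matrix.
#'
#' @param path parcellation TSV.
#' @param rsn_path optional RSN membership TSV.
#' @return a [parcellation()].
#' @export
read_parcellation <- function(path, rsn_path = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("label", "hemisphere", "partner_index")
  if (!all(need %in% names(df)))
    stop("parcellation file must have columns: ", paste(need, collapse = ", "))
  partner <- ifelse(df$partner_index < 0, NA_integer_,
                    as.integer(df$partner_index) + 1L)
  rsn <- if (!is.null(rsn_path)) read_matrix(rsn_path) else NULL
  parcellation(df$label, df$hemisphere, partner, rsn)
}

#' Write a parcellation to TSV files
#' @param parc a [parcellation()].
#' @param path output parcellation TSV (0-based `partner_index`, -1 = none).
#' @param rsn_path optional output path for the RSN membership matrix.
#' @export
write_parcellation <- function(parc, path, rsn_path = NULL) {
  df <- data.frame(label = parc$labels, hemisphere = parc$hemisphere,
                   partner_index = ifelse(is.na(parc$partner), -1L,
                                          parc$partner - 1L))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(rsn_path) && !is.null(parc$rsn))
    write_matrix(parc$rsn, rsn_path)
  invisible(path)
}

#' Read a structural connectome from TSV
#'
#' Probabilistic-tractography connectomes can be asymmetric (seed-dependent
#' probabilities); the loader symmetrizes by averaging the matrix with its
#' transpose before scaling, since the model uses a single coupling weight
#' per edge. No streamline-count threshold is applied.
#'
#' @param path TSV file with an N x N non-negative matrix.
#' @param ceiling maximum coupling after scaling (default 0.2).
#' @param expected_n optional expected region count.
#' @return scaled symmetric connectome matrix.
#' @export
read_connectome <- function(path, ceiling = 0.2, expected_n = NULL) {
  C <- read_matrix(path, expected_n = expected_n, square = TRUE)
  C <- (C + t(C)) / 2
  diag(C) <- 0
  scale_connectome(C, ceiling)
}

#' Read a cohort manifest
#'
#' The manifest is a JSON file listing states; each state entry has `name`,
#' `tr`, a list of subject BOLD TSV paths (`subjects`), and optionally
#' `wake_baseline` (name of its matched wakefulness state), `route` and
#' `depth`. Paths are resolved relative to the manifest directory.
#'
#' @param path manifest JSON path.
#' @return named list of [state_dataset()] objects with baselines linked.
#' @export
read_cohort_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = FALSE)
  base <- dirname(path)
  states <- list()
  for (st in man$states) {
    subs <- lapply(st$subjects, function(p) {
      fp <- if (startsWith(p, "/")) p else file.path(base, p)
      bold_series(read_matrix(fp), st$tr)
    })
    states[[st$name]] <- state_dataset(
      st$name, subs,
      route = st$route %||% NULL,
      depth = if (is.null(st$depth)) NA_real_ else st$depth)
  }
  for (st in man$states) {
    wb <- st$wake_baseline
    if (is.null(wb) || length(wb) == 0) next
    wb <- as.character(wb)
    if (is.null(states[[wb]]))
      stop("wake baseline '", wb, "' of state '", st$name, "' not in manifest")
    states[[st$name]]$wake_baseline <- states[[wb]]
  }
  states
}

`%||%` <- function(a, b) if (is.null(a)) b else a
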