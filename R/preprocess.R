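# Preprocessing: longitudinal volume tables -> per-subject correlation and
# adjacency matrices, plus the CDR-derived two-group disease labels.

#' Construct a volumetric cohort from a filled volume list
#'
#' Low-level constructor; most users should call [forward_fill_volumes()] on a
#' long-format table instead. Volumes are stored per subject as an n x t
#' matrix (structures x visits, in mm^3) together with visit times in months.
#'
#' @param subject_ids Character vector of subject identifiers.
#' @param structures Ordered character vector of n structure names, shared by
#'   all subjects.
#' @param volumes List (one per subject) of n x t numeric matrices, t >= 3.
#' @param visit_months List (one per subject) of increasing visit times.
#' @param covariates Optional data frame with columns `subject_id`,
#'   `age_years`, `icv_mm3`, `apoe_copies`, `cdr`, one row per subject.
#' @param group Optional integer vector of 0/1 disease labels; derived from
#'   CDR via [assign_groups()] when covariates are supplied and `group` is
#'   `NULL`.
#' @return An object of class `volumetric_cohort`.
#' @export
volumetric_cohort <- function(subject_ids, structures, volumes, visit_months,
                              covariates = NULL, group = NULL) {
  m <- length(subject_ids)
  if (length(volumes) != m || length(visit_months) != m)
    stopf("volumes and visit_months must have one element per subject")
  n <- length(structures)
  for (s in seq_len(m)) {
    v <- volumes[[s]]
    if (!is.matrix(v) || nrow(v) != n)
      stopf("subject %s: volume matrix must have %d rows", subject_ids[s], n)
    if (ncol(v) < 3L)
      stopf("subject %s: fewer than 3 visits", subject_ids[s])
    if (anyNA(v))
      stopf("subject %s: missing volumes remain after fill", subject_ids[s])
    if (length(visit_months[[s]]) != ncol(v))
      stopf("subject %s: visit times do not match visit count", subject_ids[s])
  }
  if (!is.null(covariates)) {
    need <- c("subject_id", "age_years", "icv_mm3", "apoe_copies", "cdr")
    miss <- setdiff(need, names(covariates))
    if (length(miss))
      stopf("covariate table lacks column(s): %s", paste(miss, collapse = ", "))
    idx <- match(subject_ids, covariates$subject_id)
    if (anyNA(idx))
      stopf("covariates missing for subject(s): %s",
            paste(subject_ids[is.na(idx)], collapse = ", "))
    covariates <- covariates[idx, need, drop = FALSE]
    rownames(covariates) <- NULL
    if (is.null(group)) {
      cdr <- covariates$cdr
      names(cdr) <- subject_ids
      group <- assign_groups(cdr)
    }
  }
  structure(list(subject_ids = subject_ids, structures = structures,
                 volumes = volumes, visit_months = visit_months,
                 covariates = covariates, group = unname(group)),
            class = "volumetric_cohort")
}

#' @export
print.volumetric_cohort <- function(x, ...) {
  cat(sprintf("Volumetric cohort: %d subjects, %d structures\n",
              length(x$subject_ids), length(x$structures)))
  visits <- vapply(x$volumes, ncol, integer(1))
  cat(sprintf("  visits per subject: %d-%d\n", min(visits), max(visits)))
  if (!is.null(x$group))
    cat(sprintf("  groups: %d none/mild, %d severe\n",
                sum(x$group == 0), sum(x$group == 1)))
  invisible(x)
}

#' Forward fill a longitudinal volume table and build a cohort
#'
#' Converts a long-format table of per-visit structure volumes into a
#' [volumetric_cohort()]. A volume missing at a later visit is replaced by the
#' most recent earlier visit's value for that subject and structure (forward
#' fill in time). Subjects are excluded, with a logged count, when they have
#' fewer than `min_visits` visits; a subject whose first visit is incomplete
#' is rejected with a diagnostic, since the fill rule has no earlier value to
#' carry forward.
#'
#' @param raw_table Data frame with columns `subject_id`, `visit_month`,
#'   `structure`, `volume_mm3`. Missing volumes may be `NA` rows or simply
#'   absent rows.
#' @param covariates Optional covariate data frame (see
#'   [volumetric_cohort()]); when provided, CDR-derived group labels are
#'   attached.
#' @param min_visits Minimum number of visits required to retain a subject
#'   (default 3; two time points do not give a meaningful correlation).
#' @return A `volumetric_cohort` containing the retained subjects with no
#'   missing values.
#' @examples
#' tab <- data.frame(subject_id = "s1",
#'                   visit_month = rep(c(0, 6, 12), each = 2),
#'                   structure = rep(c("a", "b"), 3),
#'                   volume_mm3 = c(100, 50, NA, 51, 103, 52))
#' cohort <- forward_fill_volumes(tab)
#' cohort$volumes[[1]]["a", ]  # 100 100 103
#' @export
forward_fill_volumes <- function(raw_table, covariates = NULL, min_visits = 3L) {
  need <- c("subject_id", "visit_month", "structure", "volume_mm3")
  miss <- setdiff(need, names(raw_table))
  if (length(miss))
    stopf("volume table lacks column(s): %s", paste(miss, collapse = ", "))

  structures <- unique(as.character(raw_table$structure))
  subjects <- unique(as.character(raw_table$subject_id))
  n <- length(structures)

  keep_ids <- character(0)
  volumes <- list()
  months <- list()
  n_few <- 0L
  rejected_first <- character(0)

  for (id in subjects) {
    rows <- raw_table[raw_table$subject_id == id, , drop = FALSE]
    vm <- sort(unique(rows$visit_month))
    t <- length(vm)
    if (t < min_visits) {
      n_few <- n_few + 1L
      next
    }
    v <- matrix(NA_real_, n, t, dimnames = list(structures, vm))
    v[cbind(match(as.character(rows$structure), structures),
            match(rows$visit_month, vm))] <- rows$volume_mm3
    if (anyNA(v[, 1L])) {
      rejected_first <- c(rejected_first, id)
      next
    }
    for (j in seq_len(t)[-1L]) {
      na <- is.na(v[, j])
      if (any(na)) v[na, j] <- v[na, j - 1L]
    }
    keep_ids <- c(keep_ids, id)
    volumes[[id]] <- v
    months[[id]] <- vm
  }

  if (length(rejected_first))
    warnf("rejected %d subject(s) with missing volumes at the first visit: %s",
          length(rejected_first), paste(rejected_first, collapse = ", "))
  msgf("retained %d of %d subjects (%d dropped for < %d visits, %d rejected for incomplete first visit)",
       length(keep_ids), length(subjects), n_few, min_visits,
       length(rejected_first))
  if (!length(keep_ids)) stopf("no subjects retained")

  volumetric_cohort(keep_ids, structures, volumes[keep_ids], months[keep_ids],
                    covariates = covariates)
}

#' Two-group disease labels from the Clinical Dementia Rating
#'
#' CDR has five levels: 0 (none), 0.5 (questionable), 1 (mild), 2 (moderate)
#' and 3 (severe). Subjects with CDR <= 1 form the none/mild group (label 0),
#' subjects with CDR > 1 the severe group (label 1).
#'
#' @param cdr Numeric vector of CDR values; names, when present, are used in
#'   error messages.
#' @return Integer vector of 0/1 labels, same length and names as `cdr`.
#' @export
assign_groups <- function(cdr) {
  ok <- cdr %in% c(0, 0.5, 1, 2, 3)
  if (!all(ok)) {
    who <- if (!is.null(names(cdr))) names(cdr)[!ok] else which(!ok)
    stopf("CDR value outside {0, 0.5, 1, 2, 3} for subject(s): %s",
          paste(who, collapse = ", "))
  }
  out <- as.integer(cdr > 1)
  names(out) <- names(cdr)
  out
}

#' Pearson correlation matrix of structure volume trajectories
#'
#' Correlates each pair of structures' volume trajectories across visits. A
#' structure with zero variance across visits has an undefined correlation;
#' its off-diagonal entries are set to 0 (no co-atrophy signal) with a
#' warning. The diagonal is always 1.
#'
#' @param volumes n x t numeric matrix (structures x visits), t >= 3.
#' @return Symmetric n x n correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(volumes) {
  if (!is.matrix(volumes)) volumes <- as.matrix(volumes)
  if (ncol(volumes) < 3L)
    stopf("at least 3 visits are required for a meaningful correlation")
  sds <- apply(volumes, 1L, stats::sd)
  flat <- sds == 0 | !is.finite(sds)
  r <- suppressWarnings(stats::cor(t(volumes)))
  if (any(flat)) {
    warnf("%d structure(s) with zero variance across visits; correlations set to 0",
          sum(flat))
    r[flat, ] <- 0
    r[, flat] <- 0
  }
  r[!is.finite(r)] <- 0
  r <- pmin(pmax(r, -1), 1)
  diag(r) <- 1
  dimnames(r) <- list(rownames(volumes), rownames(volumes))
  r
}

#' Threshold a correlation matrix into a binary adjacency matrix
#'
#' An edge is present between two distinct structures when the absolute
#' correlation is at least `threshold` (inclusive); the diagonal is forced to
#' 1. Absolute-value thresholding makes the output invariant to a global sign
#' flip of the correlations.
#'
#' @param corr Symmetric correlation matrix with unit diagonal.
#' @param threshold Scalar in (0, 1); default 0.8.
#' @return Symmetric binary matrix with unit diagonal.
#' @export
binarize <- function(corr, threshold = 0.8) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stopf("threshold must be a scalar in (0, 1)")
  if (!is_symmetric(corr, tol = 1e-6))
    stopf("correlation matrix must be symmetric")
  adj <- (abs(corr) >= threshold) * 1
  diag(adj) <- 1
  adj
}

#' Bundle per-subject adjacency matrices
#'
#' Validates and wraps m symmetric binary matrices with unit diagonal, the
#' observed graphs the embedding is fitted to.
#'
#' @param matrices n x n x m numeric array of 0/1 matrices.
#' @param structures Ordered structure names (length n); defaults to the
#'   array's dimnames or generated names.
#' @param subject_ids Optional subject identifiers (length m).
#' @return An object of class `adjacency_set`.
#' @export
adjacency_set <- function(matrices, structures = NULL, subject_ids = NULL) {
  if (!is.array(matrices) || length(dim(matrices)) != 3L)
    stopf("matrices must be an n x n x m array")
  d <- dim(matrices)
  if (d[1L] != d[2L]) stopf("matrices must be square")
  if (!all(matrices %in% c(0, 1)))
    stopf("adjacency entries must be 0 or 1")
  for (s in seq_len(d[3L])) {
    a <- matrices[, , s]
    if (max(abs(a - t(a))) > 0) stopf("matrix %d is not symmetric", s)
    if (any(diag(a) != 1)) stopf("matrix %d does not have a unit diagonal", s)
  }
  if (is.null(structures))
    structures <- dimnames(matrices)[[1L]] %||% default_structures(d[1L])
  structure(list(matrices = matrices, structures = structures,
                 subject_ids = subject_ids), class = "adjacency_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.adjacency_set <- function(x, ...) {
  d <- dim(x$matrices)
  dens <- mean(apply(x$matrices, 3L, function(a) {
    mean(a[upper.tri(a)])
  }))
  cat(sprintf("Adjacency set: %d graphs on %d structures (mean edge density %.3f)\n",
              d[3L], d[1L], dens))
  invisible(x)
}

#' Correlation and adjacency matrices for every subject in a cohort
#'
#' Runs [correlation_matrix()] then [binarize()] on each subject's volume
#' trajectories.
#'
#' @param cohort A `volumetric_cohort`.
#' @param threshold Absolute-correlation edge threshold (default 0.8).
#' @param return_correlations Also return the per-subject correlation
#'   matrices (needed by [select_dimension()] and the pairwise baseline).
#' @return An `adjacency_set`; when `return_correlations` is `TRUE`, a list
#'   with elements `adjacency` and `correlations` (n x n x m array).
#' @export
cohort_adjacency <- function(cohort, threshold = 0.8,
                             return_correlations = FALSE) {
  stopifnot(inherits(cohort, "volumetric_cohort"))
  n <- length(cohort$structures)
  m <- length(cohort$subject_ids)
  corr <- array(NA_real_, c(n, n, m),
                dimnames = list(cohort$structures, cohort$structures,
                                cohort$subject_ids))
  adj <- corr
  for (s in seq_len(m)) {
    r <- correlation_matrix(cohort$volumes[[s]])
    corr[, , s] <- r
    adj[, , s] <- binarize(r, threshold)
  }
  A <- adjacency_set(adj, cohort$structures, cohort$subject_ids)
  if (return_correlations) list(adjacency = A, correlations = corr) else A
}
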