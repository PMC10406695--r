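# Reference methods for comparison: mass-univariate atrophy-rate testing,
# pairwise correlation group testing, and a loadings-based logistic
# classifier demonstration.

#' Per-subject per-structure atrophy rates
#'
#' The least-squares slope of volume against visit time in years, divided by
#' the first-visit volume: the fraction of baseline volume lost (negative
#' rate) or gained per year. Robust to uneven visit spacing.
#'
#' @param cohort A `volumetric_cohort`.
#' @return m x n matrix of rates (subjects x structures).
#' @export
atrophy_rates <- function(cohort) {
  stopifnot(inherits(cohort, "volumetric_cohort"))
  m <- length(cohort$subject_ids)
  n <- length(cohort$structures)
  rates <- matrix(NA_real_, m, n,
                  dimnames = list(cohort$subject_ids, cohort$structures))
  for (s in seq_len(m)) {
    ty <- cohort$visit_months[[s]] / 12
    tc <- ty - mean(ty)
    v <- cohort$volumes[[s]]
    slope <- as.vector(v %*% tc) / sum(tc^2)
    rates[s, ] <- slope / v[, 1L]
  }
  if (!all(is.finite(rates)))
    stopf("non-finite atrophy rates (zero baseline volume?)")
  rates
}

# Combined-vs-two-groups SSE difference per response column:
# SSE about the overall mean minus the sum of within-group SSEs. Nonnegative
# by the usual between/within decomposition.
group_mean_sse <- function(Y, groups) {
  ssc <- colSums(sweep(Y, 2L, colMeans(Y))^2)
  ssw <- 0
  for (g in c(0, 1)) {
    Yg <- Y[groups == g, , drop = FALSE]
    ssw <- ssw + colSums(sweep(Yg, 2L, colMeans(Yg))^2)
  }
  pmax(ssc - ssw, 0)
}

# Shared max-statistic permutation engine over the columns of Y.
column_perm_test <- function(Y, groups, n_perm, alpha, seed, level, labels) {
  if (min(table(factor(groups, levels = c(0, 1)))) < 2L)
    stopf("each group needs at least 2 subjects")
  observed <- group_mean_sse(Y, groups)
  if (!is.null(seed)) set.seed(seed)
  perm_max <- vapply(seq_len(n_perm),
                     function(p) max(group_mean_sse(Y, sample(groups))),
                     numeric(1))
  threshold <- sort(perm_max)[ceiling((1 - alpha) * n_perm)]
  p_fwer <- vapply(observed,
                   function(x) (1 + sum(perm_max >= x)) / (1 + n_perm),
                   numeric(1))
  tab <- cbind(labels,
               data.frame(statistic = observed, p_fwer = p_fwer,
                          rejected = observed > threshold))
  tab <- tab[order(tab$p_fwer, -tab$statistic), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(level = level, observed = observed, perm_max = perm_max,
                 threshold = threshold, alpha = alpha, n_perm = n_perm,
                 p_fwer = p_fwer, table = tab,
                 rejections = tab[tab$rejected, , drop = FALSE]),
            class = "mreg_test")
}

#' Mass-univariate structure test on atrophy rates
#'
#' The traditional single-structure comparison: for each structure the
#' statistic is the SSE of atrophy rates about the combined mean minus the
#' sum of within-group SSEs (`SSE_combined - (SSE_severe + SSE_none)`), with
#' a max-statistic permutation threshold at the 95th percentile controlling
#' the FWER across structures.
#'
#' @param cohort A `volumetric_cohort` with group labels, or an m x n rate
#'   matrix (then `groups` is required).
#' @param groups Binary labels; taken from the cohort when omitted.
#' @param n_perm,alpha,seed Permutation settings (defaults 1000, 0.05).
#' @return An `mreg_test` at level `"structures"`.
#' @export
mass_univariate_test <- function(cohort, groups = NULL, n_perm = 1000L,
                                 alpha = 0.05, seed = NULL) {
  if (inherits(cohort, "volumetric_cohort")) {
    Y <- atrophy_rates(cohort)
    groups <- groups %||% cohort$group
  } else {
    Y <- as.matrix(cohort)
  }
  if (is.null(groups)) stopf("group labels are required")
  labels <- data.frame(structure = colnames(Y) %||%
                         default_structures(ncol(Y)))
  column_perm_test(Y, groups, n_perm, alpha, seed, "structures", labels)
}

#' Pairwise correlation group test
#'
#' For each unordered structure pair the response is the per-subject
#' correlation value; the statistic is the SSE under the combined-mean model
#' minus the SSE under the group-mean model, with a max-statistic permutation
#' threshold over all pairs. Optionally applies the Fisher z-transform to the
#' correlations first (`atanh`, with values clamped away from +/-1).
#'
#' @param correlations n x n x m array of per-subject correlation matrices.
#' @param groups Binary 0/1 labels.
#' @param n_perm,alpha,seed Permutation settings (defaults 1000, 0.05).
#' @param fisher_z Transform correlations with `atanh` first (default
#'   `FALSE`, matching the plain-correlation comparison).
#' @return An `mreg_test` at level `"structure_pairs"`.
#' @export
pairwise_correlation_test <- function(correlations, groups, n_perm = 1000L,
                                      alpha = 0.05, seed = NULL,
                                      fisher_z = FALSE) {
  stopifnot(is.array(correlations), length(dim(correlations)) == 3L)
  n <- dim(correlations)[1L]
  m <- dim(correlations)[3L]
  st <- dimnames(correlations)[[1L]] %||% default_structures(n)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  Y <- t(vapply(seq_len(m), function(s) correlations[, , s][ij],
                numeric(nrow(ij))))
  if (fisher_z) Y <- atanh(pmin(pmax(Y, -1 + 1e-7), 1 - 1e-7))
  labels <- data.frame(structure_i = st[ij[, 1L]], structure_j = st[ij[, 2L]])
  column_perm_test(Y, groups, n_perm, alpha, seed, "structure_pairs", labels)
}

#' Overlap between two rejection sets of structure pairs
#'
#' Compares the unordered structure pairs rejected by two tests: typically
#' the pairwise correlation baseline against the structure-structure
#' marginals of the triples test (the unique pairs appearing in any rejected
#' network-structure-structure triple).
#'
#' @param result_a,result_b `mreg_test` objects whose rejection tables carry
#'   `structure_i`/`structure_j` columns (`structure_pairs` or `triples`
#'   level).
#' @return List with the two pair counts, the shared count, and
#'   `percent_of_a`, the percentage of `result_a`'s pairs also found by
#'   `result_b`.
#' @export
pair_overlap <- function(result_a, result_b) {
  key <- function(res) {
    tab <- res$rejections
    if (!all(c("structure_i", "structure_j") %in% names(tab)))
      stopf("rejection tables must carry structure_i/structure_j columns")
    unique(paste(pmin(tab$structure_i, tab$structure_j),
                 pmax(tab$structure_i, tab$structure_j), sep = "|"))
  }
  a <- key(result_a)
  b <- key(result_b)
  shared <- length(intersect(a, b))
  list(n_a = length(a), n_b = length(b), shared = shared,
       percent_of_a = if (length(a)) 100 * shared / length(a) else NA_real_)
}

#' Cross-validated disease classification from subject loadings
#'
#' Demonstration endpoint: two logistic regressions predicting disease
#' status, one from confounders only (age, ICV, APOE indicators) and one
#' additionally using the subject-specific network loadings, compared by
#' ROC-AUC on pooled out-of-fold predictions from identical stratified fold
#' splits.
#'
#' @param lam m x d matrix of subject loadings.
#' @param covariates Confounder data frame (see [build_design()]).
#' @param groups Binary 0/1 labels.
#' @param folds Number of cross-validation folds (default 10).
#' @param seed Optional seed for the fold assignment.
#' @return List with `auc_covariates`, `auc_with_loadings`,
#'   `auc_difference`, and the pooled out-of-fold `predictions` data frame.
#' @export
disease_classifier <- function(lam, covariates, groups, folds = 10L,
                               seed = NULL) {
  lam <- as.matrix(lam)
  m <- nrow(lam)
  if (length(groups) != m) stopf("groups must have length m = %d", m)
  if (m < folds) stopf("need at least as many subjects as folds")
  if (min(table(factor(groups, levels = c(0, 1)))) < folds)
    stopf("each class needs at least one subject per fold; reduce folds")
  D <- build_design(covariates)[, -1L, drop = FALSE]  # glm adds the intercept
  X0 <- as.data.frame(D)
  X1 <- cbind(X0, as.data.frame(lam))
  colnames(X1) <- c(colnames(X0), sprintf("loading_%d", seq_len(ncol(lam))))

  if (!is.null(seed)) set.seed(seed)
  fold <- integer(m)
  for (g in c(0, 1)) {                     # stratified assignment
    idx <- which(groups == g)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }

  oof <- function(X) {
    pred <- numeric(m)
    for (f in seq_len(folds)) {
      test <- fold == f
      fit <- suppressWarnings(
        stats::glm(y ~ ., family = stats::binomial(),
                   data = cbind(y = groups, X)[!test, , drop = FALSE]))
      pred[test] <- suppressWarnings(
        stats::predict(fit, newdata = X[test, , drop = FALSE],
                       type = "response"))
    }
    pred
  }
  p0 <- oof(X0)
  p1 <- oof(X1)
  auc <- function(p) as.numeric(pROC::auc(pROC::roc(
    response = groups, predictor = p, levels = c(0, 1),
    direction = "<", quiet = TRUE)))
  a0 <- auc(p0)
  a1 <- auc(p1)
  list(auc_covariates = a0, auc_with_loadings = a1,
       auc_difference = a1 - a0,
       predictions = data.frame(group = groups, fold = fold,
                                p_covariates = p0, p_with_loadings = p1))
}
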