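# Confounder-adjusted F-type statistics on the score tensor with
# max-statistic permutation testing controlling the familywise error rate,
# at three levels: networks, network-structure pairs, and
# network-structure-structure triples.

#' Build the confounder design matrix
#'
#' The design contains an intercept, age, intracranial volume, and APOE gene
#' status coded as a categorical variable (indicator columns for 1 and 2
#' copies, 0 copies as reference). With `include_group = TRUE` a binary
#' disease-status column is appended (the "two groups" design). Constant
#' APOE indicators (e.g., no subject with 2 copies) are dropped with a
#' warning; any remaining rank deficiency is an error naming the columns.
#'
#' @param covariates Data frame with columns `age_years`, `icv_mm3`,
#'   `apoe_copies` (values 0/1/2), one row per subject.
#' @param groups Binary 0/1 disease labels, required when
#'   `include_group = TRUE`.
#' @param include_group Append the disease-status column (default `FALSE`).
#' @return Numeric m x p matrix of full column rank, first column all ones.
#' @export
build_design <- function(covariates, groups = NULL, include_group = FALSE) {
  need <- c("age_years", "icv_mm3", "apoe_copies")
  miss <- setdiff(need, names(covariates))
  if (length(miss))
    stopf("covariates lack column(s): %s", paste(miss, collapse = ", "))
  if (!all(covariates$apoe_copies %in% 0:2))
    stopf("apoe_copies must be 0, 1 or 2")
  D <- cbind(intercept = 1,
             age = as.numeric(covariates$age_years),
             icv = as.numeric(covariates$icv_mm3),
             apoe1 = as.numeric(covariates$apoe_copies == 1),
             apoe2 = as.numeric(covariates$apoe_copies == 2))
  const <- apply(D[, c("apoe1", "apoe2"), drop = FALSE], 2L,
                 function(x) length(unique(x)) == 1L)
  if (any(const)) {
    warnf("dropping constant APOE indicator column(s): %s",
          paste(names(const)[const], collapse = ", "))
    D <- D[, !(colnames(D) %in% names(const)[const]), drop = FALSE]
  }
  if (include_group) {
    if (is.null(groups)) stopf("groups required when include_group = TRUE")
    if (!all(groups %in% c(0, 1))) stopf("groups must be binary 0/1")
    D <- cbind(D, group = as.numeric(groups))
  }
  check_full_rank(D)
  D
}

# Rank check on unit-scaled columns, so the very different magnitudes of the
# design columns (intercept ~1, ICV ~1e6) cannot trigger spurious
# deficiency through qr()'s relative tolerance.
check_full_rank <- function(D) {
  Ds <- sweep(D, 2L, sqrt(colSums(D^2)), "/")
  qd <- qr(Ds)
  if (qd$rank < ncol(D)) {
    dep <- colnames(D)[qd$pivot[seq.int(qd$rank + 1L, ncol(D))]]
    stopf("design matrix is rank deficient; offending column(s): %s",
          paste(dep, collapse = ", "))
  }
  invisible(D)
}

# Intercept-only design for the unadjusted analysis variant.
intercept_design <- function(m) matrix(1, m, 1L, dimnames = list(NULL, "intercept"))

# Reshape the score tensor (m x d x n x n) to its m x q matrix layout,
# subject-major rows; column index runs over k fastest, then i, then j.
tensor_matrix <- function(T) {
  dm <- dim(T)
  matrix(T, dm[1L], prod(dm[-1L]))
}

#' Least-squares regression of the score tensor on a design matrix
#'
#' Solves `C = (D'D)^{-1} D' T` with the tensor reshaped to an m x q matrix
#' (q = d n n; columns ordered network fastest, then both structure indices)
#' and every tensor entry treated as a response. With an intercept-only
#' design the fitted value of each entry is simply its mean over subjects —
#' the unadjusted special case.
#'
#' @param T A `score_tensor` (m x d x n x n array).
#' @param D Design matrix from [build_design()] (or intercept-only).
#' @return List of class `tensor_regression`: `C_hat` (p x q), `T_hat`
#'   (fitted values in tensor layout), `residuals` (m x q matrix).
#' @export
regress_tensor <- function(T, D) {
  dm <- dim(T)
  if (nrow(D) != dm[1L])
    stopf("design matrix rows (%d) do not match subjects (%d)", nrow(D), dm[1L])
  check_full_rank(D)
  qd <- qr(D, tol = 1e-12)
  Tm <- tensor_matrix(T)
  C <- qr.coef(qd, Tm)
  fitted <- D %*% C
  T_hat <- array(fitted, dm)
  structure(list(C_hat = C, T_hat = T_hat, residuals = Tm - fitted,
                 design = D), class = "tensor_regression")
}

# Zero the diagonal (i == j) cells of a d x n x n statistic array.
zero_diag_dnn <- function(arr) {
  d <- dim(arr)[1L]
  n <- dim(arr)[2L]
  idx <- cbind(rep(seq_len(d), n), rep(seq_len(n), each = d),
               rep(seq_len(n), each = d))
  arr[idx] <- 0
  arr
}

# Aggregate per-entry SSE differences (length d*n*n, k fastest) to the
# requested level; diagonal entries are excluded from all sums.
aggregate_level <- function(x_entry, d, n, level, structures = NULL) {
  tiny <- -1e-8 * max(abs(x_entry), 1)
  if (min(x_entry) < tiny)
    stopf("internal error: nested-model SSE difference is negative")
  x_entry <- pmax(x_entry, 0)
  arr <- zero_diag_dnn(array(x_entry, c(d, n, n)))
  structures <- structures %||% default_structures(n)
  nets <- sprintf("network_%d", seq_len(d))
  out <- switch(level,
    networks = {
      v <- apply(arr, 1L, sum)
      names(v) <- nets
      v
    },
    pairs = {
      mtx <- apply(arr, c(1L, 2L), sum)
      dimnames(mtx) <- list(nets, structures)
      mtx
    },
    triples = {
      for (i in seq_len(n)) arr[, i, i] <- NA_real_
      dimnames(arr) <- list(nets, structures, structures)
      arr
    })
  out
}

#' F-type SSE-difference statistics from two nested tensor regressions
#'
#' For each tensor entry the squared residual under the combined (confounders
#' only) model minus that under the two-groups model (confounders plus
#' disease status) is summed over subjects, then over the remaining indices
#' down to the requested level: over both structure indices for networks
#' (X_k), over the second structure index for network-structure pairs
#' (X_{k,i}), and not at all for triples (X_{k,i,j}). Nesting guarantees
#' every statistic is nonnegative; diagonal (i = j) entries are excluded
#' from all sums, and triples are reported on the full off-diagonal grid
#' (values symmetric in i, j).
#'
#' @param T The `score_tensor` both fits were computed from.
#' @param fit_combined,fit_twogroups `tensor_regression` fits under the
#'   confounder-only and confounder-plus-group designs.
#' @param level `"networks"`, `"pairs"`, or `"triples"`.
#' @return Named vector (networks), matrix (pairs: networks x structures), or
#'   array (triples: networks x structures x structures with `NA` diagonal).
#' @export
sse_statistic <- function(T, fit_combined, fit_twogroups,
                          level = c("networks", "pairs", "triples")) {
  level <- match.arg(level)
  dm <- dim(T)
  x_entry <- colSums(fit_combined$residuals^2) -
    colSums(fit_twogroups$residuals^2)
  aggregate_level(x_entry, dm[2L], dm[3L], level, attr(T, "structures"))
}

# Fast per-permutation statistic: for OLS, adding one column z to design D
# reduces each response's SSE by (u'r)^2 / (u'u), where u is z residualized
# on D and r the response residualized on D. Exactly equals re-running both
# regressions (asserted in the test suite).
entry_stat_factory <- function(Tm, qd) {
  R <- qr.resid(qd, Tm)
  function(groups) {
    u <- qr.resid(qd, as.numeric(groups))
    uu <- sum(u^2)
    if (uu < 1e-10) return(numeric(ncol(Tm)))
    as.vector(crossprod(R, u))^2 / uu
  }
}

#' Max-statistic permutation test on the score tensor
#'
#' Computes the observed SSE-difference statistics at the requested level,
#' then builds the null distribution of the maximum statistic over the
#' level's whole hypothesis family by repeatedly permuting the disease
#' labels while keeping confounder columns attached to their subjects. The
#' rejection threshold is the empirical 95th percentile (more generally the
#' `1 - alpha` quantile) of the permutation maxima, which controls the
#' familywise error rate at `alpha`. FWER-corrected p-values use the add-one
#' convention `(1 + #{perm max >= observed}) / (1 + n_perm)` (ties count
#' against rejection), so the smallest reportable p-value with 10000
#' permutations is just below 1e-4 and never exactly 0.
#'
#' @param T A `score_tensor`.
#' @param covariates Confounder data frame (see [build_design()]); ignored
#'   when `confounders = FALSE`.
#' @param groups Binary 0/1 disease labels.
#' @param level `"networks"`, `"pairs"`, or `"triples"`.
#' @param n_perm Number of label permutations (default 10000).
#' @param alpha Target familywise error rate (default 0.05).
#' @param seed Optional RNG seed for the permutations.
#' @param confounders Adjust for confounders (default `TRUE`); when `FALSE`
#'   the design is intercept-only and fitted values are plain group means.
#' @return Object of class `mreg_test` with fields `level`, `observed`,
#'   `perm_max`, `threshold`, `alpha`, `n_perm`, `p_fwer`, `rejections`
#'   (data frame sorted by p-value then statistic), and `table` (all
#'   hypotheses).
#' @export
permutation_test <- function(T, covariates = NULL, groups,
                             level = c("networks", "pairs", "triples"),
                             n_perm = 10000L, alpha = 0.05, seed = NULL,
                             confounders = TRUE) {
  level <- match.arg(level)
  dm <- dim(T)
  m <- dm[1L]
  if (length(groups) != m) stopf("groups must have length m = %d", m)
  if (!all(groups %in% c(0, 1))) stopf("groups must be binary 0/1")
  if (n_perm < 1L) stopf("n_perm must be >= 1")
  if ((1 + n_perm) * alpha < 1)
    warnf("n_perm = %d is too small to resolve alpha = %g; smallest p-value is %.3g",
          n_perm, alpha, 1 / (1 + n_perm))

  D <- if (confounders) build_design(covariates) else intercept_design(m)
  qd <- qr(D, tol = 1e-12)
  Tm <- tensor_matrix(T)
  entry_stat <- entry_stat_factory(Tm, qd)
  structures <- attr(T, "structures")

  observed <- aggregate_level(entry_stat(groups), dm[2L], dm[3L], level,
                              structures)
  if (!is.null(seed)) set.seed(seed)
  perm_max <- vapply(seq_len(n_perm), function(p) {
    x <- aggregate_level(entry_stat(sample(groups)), dm[2L], dm[3L], level,
                         structures)
    max(x, na.rm = TRUE)
  }, numeric(1))

  threshold <- sort(perm_max)[ceiling((1 - alpha) * n_perm)]
  obs_vec <- as.vector(observed)
  p_vec <- rep(NA_real_, length(obs_vec))
  ok <- !is.na(obs_vec)
  p_vec[ok] <- vapply(obs_vec[ok],
                      function(x) (1 + sum(perm_max >= x)) / (1 + n_perm),
                      numeric(1))
  p_fwer <- observed
  p_fwer[] <- p_vec

  tab <- hypothesis_table(observed, p_fwer, threshold, level)
  structure(list(level = level, observed = observed, perm_max = perm_max,
                 threshold = threshold, alpha = alpha, n_perm = n_perm,
                 p_fwer = p_fwer, table = tab,
                 rejections = tab[tab$rejected, , drop = FALSE]),
            class = "mreg_test")
}

# Long-format hypothesis table sorted by p then decreasing statistic.
hypothesis_table <- function(observed, p_fwer, threshold, level) {
  if (level == "networks") {
    tab <- data.frame(network = seq_along(observed),
                      statistic = as.vector(observed),
                      p_fwer = as.vector(p_fwer))
  } else if (level == "pairs") {
    d <- nrow(observed)
    n <- ncol(observed)
    tab <- data.frame(network = rep(seq_len(d), n),
                      structure = rep(colnames(observed), each = d),
                      statistic = as.vector(observed),
                      p_fwer = as.vector(p_fwer))
  } else {
    d <- dim(observed)[1L]
    n <- dim(observed)[2L]
    st <- dimnames(observed)[[2L]]
    ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    tab <- do.call(rbind, lapply(seq_len(d), function(k) {
      data.frame(network = k, structure_i = st[ij[, 1L]],
                 structure_j = st[ij[, 2L]],
                 statistic = observed[cbind(k, ij[, 1L], ij[, 2L])],
                 p_fwer = p_fwer[cbind(k, ij[, 1L], ij[, 2L])])
    }))
  }
  tab$rejected <- tab$statistic > threshold
  tab <- tab[order(tab$p_fwer, -tab$statistic), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' @export
print.mreg_test <- function(x, n = 5L, ...) {
  cat(sprintf("Max-statistic permutation test (%s level)\n", x$level))
  cat(sprintf("  %d hypotheses, %d permutations, FWER alpha = %g\n",
              nrow(x$table), x$n_perm, x$alpha))
  cat(sprintf("  threshold (1 - alpha quantile of permutation maxima): %.4g\n",
              x$threshold))
  cat(sprintf("  rejections: %d\n", nrow(x$rejections)))
  if (nrow(x$rejections)) {
    cat("  top rejections:\n")
    print(utils::head(x$rejections, n))
  }
  invisible(x)
}
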