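# Modified MREG generative model: sigmoid-linked Bernoulli edge probabilities
# built from shared basis vectors (networks) and subject-specific loadings.

#' Construct a joint graph embedding
#'
#' An embedding consists of a shared basis `h` (n x d, one unit-norm column
#' per network) and per-subject loadings `lam` (m x d). Subject s's edge score
#' between structures i and j is `sum_k lam[s,k] * h[i,k] * h[j,k]`; the
#' sigmoid of the score is the Bernoulli edge probability.
#'
#' @param h n x d numeric matrix of basis vectors. Columns must have unit
#'   Euclidean norm unless `normalize = TRUE`, in which case each column is
#'   rescaled to unit norm and the scale is absorbed into the loadings
#'   (`lam[,k] * ||h_k||^2`), which leaves all edge scores unchanged.
#' @param lam m x d numeric matrix of subject loadings.
#' @param structures Optional ordered structure names (length n).
#' @param normalize Rescale columns of `h` to unit norm (default `FALSE`).
#' @return An object of class `mreg_embedding` with fields `h`, `lam`,
#'   `structures`, `d`.
#' @export
mreg_embedding <- function(h, lam, structures = NULL, normalize = FALSE) {
  h <- as.matrix(h)
  lam <- as.matrix(lam)
  if (ncol(h) != ncol(lam))
    stopf("h and lam must have the same number of columns (networks)")
  d <- ncol(h)
  if (d > 0) {
    nrm <- sqrt(colSums(h^2))
    if (normalize) {
      if (any(nrm == 0)) stopf("cannot normalize a zero basis column")
      h <- sweep(h, 2L, nrm, "/")
      lam <- sweep(lam, 2L, nrm^2, "*")
    } else if (any(abs(nrm - 1) > 1e-6)) {
      stopf("columns of h must have unit norm (use normalize = TRUE)")
    }
  }
  if (is.null(structures))
    structures <- rownames(h) %||% default_structures(nrow(h))
  rownames(h) <- structures
  structure(list(h = h, lam = lam, structures = structures, d = d),
            class = "mreg_embedding")
}

#' @export
print.mreg_embedding <- function(x, ...) {
  cat(sprintf("MREG embedding: %d structures, %d subjects, %d network(s)\n",
              nrow(x$h), nrow(x$lam), x$d))
  if (x$d > 0) {
    lm <- colMeans(x$lam)
    cat("  mean loading per network:", paste(sprintf("%.3g", lm), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Edge probability matrix for one subject
#'
#' Off-diagonal entry (i, j) is `sigmoid(sum_k lam[s,k] h[i,k] h[j,k])`; the
#' diagonal is forced to 1 (a structure's relation with itself carries no
#' information here). The sigmoid guarantees every entry lies in \[0, 1\] for
#' arbitrary finite parameters.
#'
#' @param emb An `mreg_embedding`.
#' @param s Subject index (row of `lam`), or a loadings d-vector directly.
#' @return Symmetric n x n matrix of probabilities with unit diagonal, class
#'   `edge_probability_matrix`.
#' @export
edge_probabilities <- function(emb, s) {
  stopifnot(inherits(emb, "mreg_embedding"))
  lam_s <- if (length(s) == 1L && s == round(s) && s >= 1 &&
               s <= nrow(emb$lam)) emb$lam[s, ] else as.numeric(s)
  if (length(lam_s) != emb$d)
    stopf("loadings must have length d = %d", emb$d)
  n <- nrow(emb$h)
  S <- if (emb$d > 0) emb$h %*% (lam_s * t(emb$h)) else matrix(0, n, n)
  S <- (S + t(S)) / 2  # remove floating-point asymmetry
  E <- sigmoid(S)
  diag(E) <- 1
  dimnames(E) <- list(emb$structures, emb$structures)
  class(E) <- c("edge_probability_matrix", class(E))
  E
}

#' Sample a graph from an edge probability matrix
#'
#' Draws one adjacency matrix: each upper-triangle edge is an independent
#' Bernoulli draw with its entry of `E`, the lower triangle is mirrored
#' (graphs are undirected, not sampled independently on both sides), and the
#' diagonal is 1. The upper triangle is traversed in row-major order
#' ((1,2), (1,3), ..., (2,3), ...) so a given seed yields bit-identical
#' samples across runs.
#'
#' @param E Symmetric n x n probability matrix with unit diagonal.
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used (and advanced).
#' @return Symmetric binary n x n matrix with unit diagonal.
#' @export
sample_graph <- function(E, seed = NULL) {
  E <- unclass(E)
  if (!is_symmetric(E, tol = 1e-8)) stopf("E must be symmetric")
  if (any(E < 0 | E > 1)) stopf("E entries must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(E)
  ut <- which(upper.tri(E), arr.ind = TRUE)
  ut <- ut[order(ut[, 1L], ut[, 2L]), , drop = FALSE]
  u <- stats::runif(nrow(ut))
  A <- matrix(0, n, n)
  A[ut] <- as.numeric(u < E[ut])
  A <- A + t(A)
  diag(A) <- 1
  dimnames(A) <- dimnames(E)
  A
}

#' Score tensor of an embedding
#'
#' Forms the m x d x n x n array `T[s,k,i,j] = lam[s,k] * h[i,k] * h[j,k]`,
#' the pre-sigmoid contribution of network k to subject s's (i, j) edge. All
#' group tests operate on this tensor; summing over k and applying the
#' sigmoid off the diagonal reproduces the edge probabilities.
#'
#' @param emb An `mreg_embedding`.
#' @return Numeric array with class `score_tensor` and a `structures`
#'   attribute.
#' @export
score_tensor <- function(emb) {
  stopifnot(inherits(emb, "mreg_embedding"))
  n <- nrow(emb$h)
  m <- nrow(emb$lam)
  d <- emb$d
  T <- array(0, c(m, d, n, n))
  for (k in seq_len(d)) {
    T[, k, , ] <- outer(emb$lam[, k], tcrossprod(emb$h[, k]))
  }
  attr(T, "structures") <- emb$structures
  class(T) <- "score_tensor"
  T
}

#' Interpolate (or extrapolate) between group mean loadings
#'
#' Returns `p * lam_control + (1 - p) * lam_ad`. Values of `p` outside
#' \[0, 1\] extrapolate beyond the two group means; this is well defined
#' because the sigmoid link keeps edge probabilities in \[0, 1\] for any
#' finite loadings.
#'
#' @param lam_control_mean,lam_ad_mean d-vectors of group mean loadings.
#' @param p Scalar or vector of interpolation weights (1 = control mean,
#'   0 = AD mean).
#' @return A d-vector, or a length(p) x d matrix when `p` has length > 1.
#' @export
interpolate_loadings <- function(lam_control_mean, lam_ad_mean, p) {
  if (length(lam_control_mean) != length(lam_ad_mean))
    stopf("group mean loadings must have equal length")
  out <- outer(p, lam_control_mean) + outer(1 - p, lam_ad_mean)
  if (length(p) == 1L) drop(out) else out
}

#' Fix the reporting sign of each basis vector
#'
#' Flips any basis column whose largest-magnitude entry is negative. Edge
#' scores are invariant (each h appears twice in the product), so this is a
#' pure display convention that stabilizes loading rankings.
#'
#' @param emb An `mreg_embedding`.
#' @return The embedding with aligned signs.
#' @export
align_embedding <- function(emb) {
  stopifnot(inherits(emb, "mreg_embedding"))
  for (k in seq_len(emb$d)) {
    i <- which.max(abs(emb$h[, k]))
    if (emb$h[i, k] < 0) emb$h[, k] <- -emb$h[, k]
  }
  emb
}

#' Top structures per network by absolute basis loading
#'
#' Ranks structures within each network by `|h[i,k]|` after sign alignment,
#' the per-network listing used to interpret fitted networks.
#'
#' @param emb An `mreg_embedding`.
#' @param k Number of structures to report per network (default 10).
#' @return Data frame with columns `network`, `rank`, `structure`, `loading`.
#' @export
top_loadings <- function(emb, k = 10L) {
  emb <- align_embedding(emb)
  out <- do.call(rbind, lapply(seq_len(emb$d), function(net) {
    o <- order(abs(emb$h[, net]), decreasing = TRUE)[seq_len(min(k, nrow(emb$h)))]
    data.frame(network = net, rank = seq_along(o),
               structure = emb$structures[o], loading = emb$h[o, net])
  }))
  rownames(out) <- NULL
  out
}
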