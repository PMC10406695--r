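# Internal numerical helpers shared across modules.

#' Logistic (sigmoid) link
#'
#' Maps a real-valued edge score to a Bernoulli probability in \[0, 1\].
#' Applied elementwise; the link is what guarantees valid edge probabilities
#' for arbitrary finite basis vectors and loadings.
#'
#' @param x Numeric vector, matrix or array of scores.
#' @return Object of the same shape with values `1 / (1 + exp(-x))`.
#' @export
sigmoid <- function(x) {
  1 / (1 + exp(-x))
}

# Numerically stable log(1 + exp(x)); avoids overflow for large positive x.
softplus <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

# Symmetry check with tolerance.
is_symmetric <- function(x, tol = 1e-8) {
  is.matrix(x) && nrow(x) == ncol(x) && max(abs(x - t(x))) <= tol
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
msgf <- function(fmt, ...) message(sprintf(fmt, ...))

# Coerce an adjacency_set or plain n x n x m array to an array, with checks.
as_adjacency_array <- function(A) {
  if (inherits(A, "adjacency_set")) return(A$matrices)
  if (is.array(A) && length(dim(A)) == 3L) return(A)
  stopf("expected an 'adjacency_set' or an n x n x m array")
}

# Default structure names used by simulators when none are given.
default_structures <- function(n) sprintf("structure_%03d", seq_len(n))
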