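# Maximum-likelihood joint graph embedding: minimize the binary cross-entropy
# loss over (h, lam) by gradient descent, greedily one dimension at a time
# (or jointly over all dimensions), plus a scree-based dimension selector.

# Internal flattened views: each adjacency matrix as a length-n^2 column,
# with index sets for the strict upper triangle and the diagonal.
flatten_adjacency <- function(A) {
  A <- as_adjacency_array(A)
  n <- dim(A)[1L]
  m <- dim(A)[3L]
  list(Av = matrix(A, n * n, m), n = n, m = m,
       ut = which(upper.tri(matrix(0, n, n))),
       dg = which(as.vector(diag(n) == 1)))
}

# Loss from a flattened score matrix S (n^2 x m), upper triangle only.
# Stable form: -[a log(sig(s)) + (1-a) log(1-sig(s))] = softplus(-s) + (1-a) s.
bce_from_scores <- function(S, Av, ut, m) {
  s <- S[ut, , drop = FALSE]
  a <- Av[ut, , drop = FALSE]
  sum(softplus(-s) + (1 - a) * s) / m
}

#' Binary cross-entropy loss of an embedding
#'
#' The negative log-likelihood of the observed adjacency matrices under the
#' model, averaged over subjects and summed over unordered structure pairs
#' i < j (the forced-to-1 diagonal carries no information and is excluded):
#' `-(1/m) sum_s sum_{i<j} A log E + (1 - A) log(1 - E)`, with E the
#' sigmoid-linked edge probabilities. With no networks at all (d = 0) every
#' off-diagonal probability is 0.5 and the loss is `n (n - 1) / 2 * log 2`.
#'
#' @param A An `adjacency_set` or n x n x m array.
#' @param emb An `mreg_embedding` (d may be 0).
#' @return Scalar loss (finite for finite parameters).
#' @export
bce_loss <- function(A, emb) {
  fa <- flatten_adjacency(A)
  if (nrow(emb$h) != fa$n || nrow(emb$lam) != fa$m)
    stopf("embedding dimensions do not match the adjacency set")
  S <- score_matrix(emb$h, emb$lam, fa$n)
  bce_from_scores(S, fa$Av, fa$ut, fa$m)
}

# Flattened n^2 x m score matrix sum_k lam[,k] vec(h_k h_k').
score_matrix <- function(h, lam, n) {
  m <- nrow(lam)
  S <- matrix(0, n * n, m)
  for (k in seq_len(ncol(h)))
    S <- S + as.vector(tcrossprod(h[, k])) %o% lam[, k]
  S
}

# Analytic gradient of bce_loss with respect to h (n x d) and lam (m x d).
# W_s = (E_s - A_s)/m with zero diagonal; grad_h_k = sum_s lam[s,k] W_s h_k,
# grad_lam[s,k] = 0.5 h_k' W_s h_k (each unordered pair counted once).
bce_gradient <- function(A, h, lam) {
  fa <- flatten_adjacency(A)
  n <- fa$n
  S <- score_matrix(h, lam, n)
  W <- (sigmoid(S) - fa$Av) / fa$m
  W[fa$dg, ] <- 0
  d <- ncol(h)
  gh <- matrix(0, n, d)
  gl <- matrix(0, fa$m, d)
  for (k in seq_len(d)) {
    gh[, k] <- matrix(W %*% lam[, k], n, n) %*% h[, k]
    gl[, k] <- 0.5 * as.vector(crossprod(W, as.vector(tcrossprod(h[, k]))))
  }
  list(h = gh, lam = gl)
}

#' Fit a joint graph embedding by gradient descent on the BCE loss
#'
#' Greedy mode adds networks one at a time: for k = 1..d the pair
#' (h_k, lam_k) is optimized for `iters_per_dim` gradient-descent iterations
#' with all earlier networks frozen, after which h_k is rescaled to unit norm
#' with the scale absorbed into lam_k (the loss is invariant to this gauge).
#' Greedy ordering makes networks come out ranked by explained variability,
#' analogous to principal components. Joint mode optimizes all d networks
#' simultaneously for `d * iters_per_dim` iterations.
#'
#' Plain gradient descent is used with separate fixed step sizes for the two
#' parameter blocks; the gradient of the loss with respect to the loadings
#' scales like 1/m, which is why the loading step is orders of magnitude
#' larger than the basis step. Steps are data-scale sensitive: the defaults
#' suit cohorts of several hundred 108-structure graphs, and a divergence
#' guard aborts with advice when the loss grows instead of shrinking.
#'
#' @param A An `adjacency_set` or n x n x m array.
#' @param d Number of networks to fit (default 4). `d = 0` returns the empty
#'   embedding and the constant baseline loss.
#' @param mode `"greedy"` (default) or `"joint"`.
#' @param step_h Gradient step size for the basis vectors (default 2).
#' @param step_lam Gradient step size for the loadings (default 20000).
#' @param iters_per_dim Iterations per added network (default 10000).
#' @param seed Initialization seed. Each h_k starts at the leading
#'   eigenvector (by absolute eigenvalue) of the mean residual matrix
#'   `mean_s(A_s - E_s)`, the direction along which a rank-one update
#'   reduces the residual fastest, with the matching loading sign; a
#'   normalized random draw is the fallback when the spectrum is degenerate.
#'   Loadings start at `sign * init_lam` (exactly zero is a stationary point
#'   of the product parameterization).
#' @param init_lam Initial loading value (default 1e-2).
#' @param divergence_factor Abort when the loss exceeds this multiple of the
#'   best loss seen so far (default 10).
#' @return List with `embedding` (an `mreg_embedding`) and `trace` (class
#'   `fit_trace`: `loss_history`, `dim_boundaries`, `final_loss`).
#' @export
fit_embedding <- function(A, d = 4L, mode = c("greedy", "joint"),
                          step_h = 2, step_lam = 20000,
                          iters_per_dim = 10000L, seed = 1L,
                          init_lam = 1e-2, divergence_factor = 10) {
  mode <- match.arg(mode)
  if (step_h <= 0 || step_lam <= 0) stopf("step sizes must be positive")
  if (d < 0) stopf("d must be >= 0")
  if (d > 0 && iters_per_dim < 1L) stopf("iters_per_dim must be >= 1")
  fa <- flatten_adjacency(A)
  n <- fa$n
  m <- fa$m
  structures <- if (inherits(A, "adjacency_set")) A$structures else
    dimnames(as_adjacency_array(A))[[1L]] %||% default_structures(n)

  if (d == 0L) {
    emb <- mreg_embedding(matrix(0, n, 0L), matrix(0, m, 0L), structures)
    trace <- structure(list(loss_history = numeric(0),
                            dim_boundaries = integer(0),
                            final_loss = n * (n - 1) / 2 * log(2)),
                       class = "fit_trace")
    return(list(embedding = emb, trace = trace))
  }

  set.seed(seed)
  loss_history <- numeric(0)
  dim_boundaries <- integer(0)
  best <- Inf
  guard <- function(loss) {
    if (!is.finite(loss) || loss > divergence_factor * best + 1e-8)
      stopf(paste("optimization diverged (loss %.4g vs best %.4g);",
                  "reduce step_h/step_lam for this data scale"), loss, best)
    best <<- min(best, loss)
  }

  descend <- function(S0, hmat, lmat, iters) {
    # optimize the active columns in hmat/lmat with frozen scores S0
    da <- ncol(hmat)
    for (it in seq_len(iters)) {
      V <- vapply(seq_len(da),
                  function(k) as.vector(tcrossprod(hmat[, k])), numeric(n * n))
      S <- S0 + V %*% t(lmat)
      loss <- bce_from_scores(S, fa$Av, fa$ut, m)
      guard(loss)
      loss_history[length(loss_history) + 1L] <<- loss
      W <- (sigmoid(S) - fa$Av) / m
      W[fa$dg, ] <- 0
      WL <- W %*% lmat                       # n^2 x da
      gl <- 0.5 * crossprod(W, V)            # m x da
      for (k in seq_len(da))
        hmat[, k] <- hmat[, k] - step_h * (matrix(WL[, k], n, n) %*% hmat[, k])
      lmat <- lmat - step_lam * gl
    }
    list(h = hmat, lam = lmat)
  }

  # Spectral initialization: the leading eigenvector (largest |eigenvalue|)
  # of the mean residual mean_s(A_s - E_s), diagonal excluded, points along
  # the rank-one direction that reduces the residual fastest; the loading
  # starts small with the eigenvalue's sign. Random fallback if degenerate.
  init_hl <- function(S0) {
    R <- matrix(rowMeans(fa$Av - sigmoid(S0)), n, n)
    diag(R) <- 0
    e <- eigen((R + t(R)) / 2, symmetric = TRUE)
    i <- which.max(abs(e$values))
    if (abs(e$values[i]) < 1e-10) {
      v <- stats::rnorm(n)
      list(h = v / sqrt(sum(v^2)), sign = 1)
    } else {
      list(h = e$vectors[, i], sign = sign(e$values[i]))
    }
  }

  if (mode == "greedy") {
    h <- matrix(0, n, 0L)
    lam <- matrix(0, m, 0L)
    S0 <- matrix(0, n * n, m)
    for (k in seq_len(d)) {
      dim_boundaries <- c(dim_boundaries, length(loss_history) + 1L)
      ini <- init_hl(S0)
      res <- descend(S0, matrix(ini$h, n, 1L),
                     matrix(ini$sign * init_lam, m, 1L), iters_per_dim)
      hk <- res$h[, 1L]
      lk <- res$lam[, 1L]
      nrm <- sqrt(sum(hk^2))
      hk <- hk / nrm
      lk <- lk * nrm^2
      S0 <- S0 + as.vector(tcrossprod(hk)) %o% lk
      h <- cbind(h, hk)
      lam <- cbind(lam, lk)
      loss_history[length(loss_history) + 1L] <-
        bce_from_scores(S0, fa$Av, fa$ut, m)
    }
  } else {
    # joint: initialize every dimension from the top-|eigenvalue| spectrum
    # of the mean centered adjacency
    S0 <- matrix(0, n * n, m)
    R <- matrix(rowMeans(fa$Av - sigmoid(S0)), n, n)
    diag(R) <- 0
    e <- eigen((R + t(R)) / 2, symmetric = TRUE)
    ord <- order(abs(e$values), decreasing = TRUE)[seq_len(d)]
    h0 <- e$vectors[, ord, drop = FALSE]
    l0 <- matrix(rep(sign(e$values[ord]) * init_lam, each = m), m, d)
    res <- descend(S0, h0, l0, d * iters_per_dim)
    nrm <- sqrt(colSums(res$h^2))
    h <- sweep(res$h, 2L, nrm, "/")
    lam <- sweep(res$lam, 2L, nrm^2, "*")
    dim_boundaries <- 1L
    loss_history[length(loss_history) + 1L] <-
      bce_from_scores(score_matrix(h, lam, n), fa$Av, fa$ut, m)
  }

  emb <- mreg_embedding(h, lam, structures)
  trace <- structure(list(loss_history = loss_history,
                          dim_boundaries = dim_boundaries,
                          final_loss = loss_history[length(loss_history)]),
                     class = "fit_trace")
  list(embedding = emb, trace = trace)
}

#' @export
print.fit_trace <- function(x, ...) {
  cat(sprintf("Fit trace: %d iterations over %d dimension segment(s), final BCE %.4f\n",
              length(x$loss_history), length(x$dim_boundaries), x$final_loss))
  invisible(x)
}

#' Suggest an embedding dimension from correlation spectra
#'
#' Computes the eigendecomposition of each subject's correlation matrix and
#' suggests the smallest number of leading components whose eigenvalue mass
#' exceeds `fraction` of the total, taken for the median subject. Also
#' returns the data for a scree plot.
#'
#' @param correlations n x n x m array or list of symmetric matrices.
#' @param fraction Target cumulative eigenvalue fraction (default 0.8).
#' @return List with `spectra` (n x m, descending eigenvalues per subject),
#'   `per_subject_d`, `suggested_d`, and `scree` (data frame of the median
#'   spectrum by component).
#' @export
select_dimension <- function(correlations, fraction = 0.8) {
  if (is.array(correlations) && length(dim(correlations)) == 3L) {
    m <- dim(correlations)[3L]
    mats <- lapply(seq_len(m), function(s) correlations[, , s])
  } else if (is.list(correlations)) {
    mats <- correlations
  } else {
    stopf("correlations must be an n x n x m array or a list of matrices")
  }
  spectra <- vapply(mats, function(r) {
    if (!is_symmetric(r, tol = 1e-6)) stopf("correlation matrices must be symmetric")
    sort(pmax(eigen(r, symmetric = TRUE, only.values = TRUE)$values, 0),
         decreasing = TRUE)
  }, numeric(nrow(mats[[1L]])))
  spectra <- as.matrix(spectra)
  per_subject <- apply(spectra, 2L, function(v) {
    cf <- cumsum(v) / sum(v)
    which(cf >= fraction)[1L]
  })
  suggested <- as.integer(ceiling(stats::median(per_subject)))
  med_spec <- apply(spectra, 1L, stats::median)
  list(spectra = spectra, per_subject_d = per_subject,
       suggested_d = suggested,
       scree = data.frame(component = seq_along(med_spec),
                          eigenvalue = med_spec,
                          cumulative_fraction = cumsum(med_spec) / sum(med_spec)))
}
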