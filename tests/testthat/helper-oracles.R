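# Independent brute-force oracles and small fixture builders, kept free of
# the package's own vectorized code paths.

# Two-pass Pearson correlation, written out by hand.
pearson_brute <- function(x, y) {
  mx <- mean(x)
  my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Triple-nested-loop BCE loss over unordered pairs i < j.
bce_brute <- function(A, h, lam) {
  A <- if (inherits(A, "adjacency_set")) A$matrices else A
  m <- dim(A)[3]
  n <- dim(A)[1]
  total <- 0
  for (s in 1:m) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        sc <- 0
        for (k in seq_len(ncol(h))) sc <- sc + lam[s, k] * h[i, k] * h[j, k]
        E <- 1 / (1 + exp(-sc))
        a <- A[i, j, s]
        total <- total - (a * log(E) + (1 - a) * log(1 - E))
      }
    }
  }
  total / m
}

# Entry-by-entry nested-model SSE differences via explicit normal equations,
# aggregated with plain loops.
sse_brute <- function(T, D, Dp, level) {
  dm <- dim(T)
  resid_of <- function(y, X) y - X %*% solve(crossprod(X), crossprod(X, y))
  X <- array(0, c(dm[2], dm[3], dm[4]))
  for (k in 1:dm[2]) {
    for (i in 1:dm[3]) {
      for (j in 1:dm[4]) {
        if (i == j) next
        y <- T[, k, i, j]
        X[k, i, j] <- sum(resid_of(y, D)^2) - sum(resid_of(y, Dp)^2)
      }
    }
  }
  switch(level,
         networks = apply(X, 1, sum),
         pairs = apply(X, c(1, 2), sum),
         triples = X)
}

# Mean absolute error of fitted edge probabilities against the generating
# truth, off-diagonal entries only.
edge_prob_mae <- function(emb, E_true) {
  m <- nrow(emb$lam)
  tot <- 0
  for (s in 1:m) {
    E <- edge_probabilities(emb, s)
    tot <- tot + mean(abs(E - E_true[, , s])[upper.tri(E)])
  }
  tot / m
}

# Minimal long-format volume table for preprocessing tests.
toy_volume_table <- function(values, months = c(0, 6, 12), id = "s1",
                             structure = "a") {
  data.frame(subject_id = id, visit_month = months, structure = structure,
             volume_mm3 = values)
}

# Small covariate table with valid CDR values; age and ICV follow different
# deterministic irregular patterns so the design never degenerates.
toy_covariates <- function(ids, cdr = 0) {
  i <- seq_along(ids)
  data.frame(subject_id = ids,
             age_years = 60 + rep_len(c(7, 2, 19, 11, 5, 16, 3, 14, 9, 21,
                                        1, 12, 18, 4, 22, 8, 15, 6, 20, 10), length(i)),
             icv_mm3 = 1.3e6 + rep_len(c(5, 12, 3, 16, 8, 1, 14, 6, 11, 2,
                                         9, 15, 4, 13, 7, 10, 16, 0, 12, 6), length(i)) * 2e4,
             apoe_copies = rep_len(c(0, 1, 2), length(ids)),
             cdr = rep_len(cdr, length(ids)))
}

# Step sizes and iteration budget used for desk-scale fits in the suite
# (largest stable steps for m ~ 50-200, n ~ 20-30 cohorts).
desk_fit <- function(A, d, iters = 1500L, seed = 7L, mode = "greedy") {
  fit_embedding(A, d = d, mode = mode, step_h = 0.005, step_lam = 200,
                iters_per_dim = iters, seed = seed)
}
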