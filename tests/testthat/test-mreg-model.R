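# Generative model: edge probabilities, graph sampling, score tensor,
# loading interpolation.

test_that("edge probabilities follow the sigmoid of the loading-weighted scores", {
  # all-zero loadings: every off-diagonal probability is 0.5
  h <- cbind(rep(1 / sqrt(4), 4))
  emb <- mreg_embedding(h, cbind(c(0, 2)))
  E0 <- edge_probabilities(emb, 1)
  expect_equal(unname(E0[upper.tri(E0)]), rep(0.5, 6))
  expect_equal(unname(diag(E0)), rep(1, 4))

  # d = 1, n = 2, h = (1/sqrt(2), 1/sqrt(2)), lambda = 2: score 1
  emb2 <- mreg_embedding(cbind(rep(1 / sqrt(2), 2)), cbind(2))
  E <- edge_probabilities(emb2, 1)
  expect_equal(E[1, 2], 1 / (1 + exp(-1)))

  # probabilities approach 1 monotonically along a positive-score direction
  # (non-integer loadings, so they cannot be read as subject indices)
  probs <- vapply(c(0.5, 1.5, 2.5, 100.5),
                  function(l) edge_probabilities(emb2, l)[1, 2], numeric(1))
  expect_true(all(diff(probs) > 0))
  expect_true(probs[4] > 1 - 1e-10)
})

test_that("edge probabilities stay in [0,1] with unit diagonal for adversarial parameters", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    d <- sample(1:3, 1)
    h <- matrix(rnorm(n * d), n, d)
    lam <- matrix(rnorm(2 * d, sd = 10^sample(0:8, 1)), 2, d)
    emb <- mreg_embedding(h, lam, normalize = TRUE)
    E <- edge_probabilities(emb, 1)
    expect_true(all(E >= 0 & E <= 1))
    expect_equal(unname(diag(E)), rep(1, n))
    expect_identical(unclass(E), t(unclass(E)))
  }
})

test_that("edge probabilities are invariant to basis sign flips and joint permutations", {
  set.seed(32)
  h <- matrix(rnorm(12), 6, 2)
  lam <- matrix(rnorm(6), 3, 2)
  emb <- mreg_embedding(h, lam, normalize = TRUE)
  E <- edge_probabilities(emb, 2)

  flipped <- mreg_embedding(emb$h %*% diag(c(-1, 1)), emb$lam)
  expect_equal(edge_probabilities(flipped, 2), E)

  permuted <- mreg_embedding(emb$h[, 2:1], emb$lam[, 2:1])
  expect_equal(edge_probabilities(permuted, 2), E)
})

test_that("graph sampling is deterministic at the extremes and seed-reproducible", {
  n <- 5
  E0 <- diag(n)  # off-diagonal probabilities all 0
  expect_equal(sample_graph(E0, seed = 1), diag(n))
  E1 <- matrix(1, n, n)
  expect_equal(sample_graph(E1, seed = 1), matrix(1, n, n))

  emb <- mreg_embedding(matrix(rnorm(10), 5, 2), matrix(c(3, -2), 1, 2),
                        normalize = TRUE)
  E <- edge_probabilities(emb, 1)
  expect_identical(sample_graph(E, seed = 99), sample_graph(E, seed = 99))
})

test_that("sampled edge frequencies match probabilities within 4 binomial SEs", {
  set.seed(33)
  emb <- mreg_embedding(matrix(rnorm(12), 6, 2), matrix(c(2, -1), 1, 2),
                        normalize = TRUE)
  E <- unclass(edge_probabilities(emb, 1))
  n_draw <- 10000
  freq <- matrix(0, 6, 6)
  for (i in seq_len(n_draw)) freq <- freq + sample_graph(E)
  freq <- freq / n_draw
  se <- sqrt(E * (1 - E) / n_draw)
  off <- upper.tri(E)
  expect_true(all(abs(freq - E)[off] <= 4 * se[off] + 1e-12))
})

test_that("score tensor matches a nested-loop reference and is symmetric in (i,j)", {
  set.seed(34)
  m <- 4; n <- 5; d <- 2
  h <- matrix(rnorm(n * d), n, d)
  h <- sweep(h, 2, sqrt(colSums(h^2)), "/")
  lam <- matrix(rnorm(m * d), m, d)
  emb <- mreg_embedding(h, lam)
  T <- score_tensor(emb)
  ref <- array(0, c(m, d, n, n))
  for (s in 1:m) for (k in 1:d) for (i in 1:n) for (j in 1:n) {
    ref[s, k, i, j] <- lam[s, k] * h[i, k] * h[j, k]
  }
  expect_equal(unclass(T), ref, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(aperm(unclass(T), c(1, 2, 4, 3)), unclass(T),
               ignore_attr = TRUE)

  # d = 1, unit loading: slice is the outer product of h with itself
  emb1 <- mreg_embedding(h[, 1, drop = FALSE], cbind(1))
  T1 <- score_tensor(emb1)
  expect_equal(T1[1, 1, , ], tcrossprod(h[, 1]))

  # negating a basis vector leaves the tensor unchanged
  embf <- mreg_embedding(-h, lam)
  expect_equal(unclass(score_tensor(embf)), unclass(T))
})

test_that("loading interpolation recovers the endpoints and the extrapolation grid", {
  ctrl <- c(1, 2)
  ad <- c(-3, 5)
  expect_equal(interpolate_loadings(ctrl, ad, 1), ctrl)
  expect_equal(interpolate_loadings(ctrl, ad, 0), ad)
  grid <- interpolate_loadings(ctrl, ad, c(1.5, 1, 0.5, 0, -0.5))
  expect_equal(dim(grid), c(5L, 2L))
  expect_equal(grid[2, ], ctrl)
  expect_equal(grid[4, ], ad)
  expect_equal(grid[3, ], (ctrl + ad) / 2)
  # extrapolated loadings still give valid probabilities through the sigmoid
  h <- cbind(rep(1 / sqrt(3), 3), c(1, -1, 1) / sqrt(3))
  for (r in 1:5) {
    E <- edge_probabilities(mreg_embedding(h, matrix(0, 1, 2)), grid[r, ])
    expect_true(all(E >= 0 & E <= 1))
  }
})

test_that("top loadings are ranked by absolute value with positive-majority signs", {
  set.seed(35)
  h <- matrix(rnorm(16), 8, 2)
  emb <- align_embedding(mreg_embedding(h, matrix(rnorm(4), 2, 2),
                                        normalize = TRUE))
  tab <- top_loadings(emb, k = 3)
  expect_equal(nrow(tab), 6L)
  for (k in 1:2) {
    v <- abs(tab$loading[tab$network == k])
    expect_true(all(diff(v) <= 0))
    expect_true(emb$h[which.max(abs(emb$h[, k])), k] > 0)
  }
})
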