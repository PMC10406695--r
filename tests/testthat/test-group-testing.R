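# Design matrices, tensor regression, SSE statistics, permutation testing.

test_that("design matrix has dummy-coded APOE and optional group column", {
  cov <- data.frame(age_years = c(70, 77, 81, 66, 74, 85),
                    icv_mm3 = c(1.41, 1.55, 1.62, 1.38, 1.58, 1.47) * 1e6,
                    apoe_copies = c(0, 1, 2, 0, 1, 2))
  D <- build_design(cov)
  expect_equal(unname(D[, "intercept"]), rep(1, 6))
  expect_equal(unname(D[1:3, c("apoe1", "apoe2")]),
               rbind(c(0, 0), c(1, 0), c(0, 1)))

  Dg <- build_design(cov, groups = c(0, 1, 1, 0, 0, 1), include_group = TRUE)
  expect_equal(unname(Dg[, "group"]), c(0, 1, 1, 0, 0, 1))

  # m = 5 toy table against a hand-built matrix, column by column
  cov5 <- data.frame(age_years = c(61, 72, 83, 66, 79),
                     icv_mm3 = c(1.2, 1.3, 1.4, 1.5, 1.6) * 1e6,
                     apoe_copies = c(0, 0, 1, 2, 1))
  hand <- cbind(intercept = rep(1, 5), age = c(61, 72, 83, 66, 79),
                icv = c(1.2, 1.3, 1.4, 1.5, 1.6) * 1e6,
                apoe1 = c(0, 0, 1, 0, 1), apoe2 = c(0, 0, 0, 1, 0))
  expect_equal(build_design(cov5), hand)

  # constant APOE indicator dropped with a warning
  cov_const <- data.frame(age_years = c(70, 75, 80, 68, 82),
                          icv_mm3 = c(1.4, 1.5, 1.6, 1.35, 1.52) * 1e6,
                          apoe_copies = c(0, 1, 0, 1, 0))
  expect_warning(Dc <- build_design(cov_const), "apoe2")
  expect_false("apoe2" %in% colnames(Dc))
})

test_that("tensor regression reduces to means for an intercept-only design and fits exactly when linear", {
  set.seed(61)
  m <- 8; d <- 2; n <- 4
  T <- array(rnorm(m * d * n * n), c(m, d, n, n))
  fit <- regress_tensor(T, mregnet:::intercept_design(m))
  expect_equal(fit$T_hat[3, , , ], apply(T, c(2, 3, 4), mean))
  expect_equal(dim(fit$C_hat), c(1L, d * n * n))

  # response exactly linear in the design: zero residuals
  D <- cbind(1, rnorm(m), rnorm(m))
  C <- matrix(rnorm(3 * d * n * n), 3)
  T_lin <- array(D %*% C, c(m, d, n, n))
  fit_lin <- regress_tensor(T_lin, D)
  expect_lt(max(abs(fit_lin$residuals)), 1e-10)

  # per-entry ordinary-least-squares oracle
  cov <- toy_covariates(sprintf("s%d", 1:m))
  D2 <- build_design(cov)
  fit2 <- regress_tensor(T, D2)
  for (idx in list(c(1, 1, 2), c(2, 3, 4), c(1, 4, 1))) {
    y <- T[, idx[1], idx[2], idx[3]]
    beta <- solve(crossprod(D2), crossprod(D2, y))
    expect_equal(fit2$T_hat[, idx[1], idx[2], idx[3]],
                 as.vector(D2 %*% beta), tolerance = 1e-8)
  }
  # normal equations: residuals orthogonal to the design columns
  expect_lt(max(abs(crossprod(D2, fit2$residuals))) /
              max(abs(crossprod(D2, mregnet:::tensor_matrix(T)))), 1e-10)
})

test_that("SSE statistics match the brute-force nested-loop computation", {
  set.seed(62)
  m <- 20; n <- 6; d <- 2
  sim <- simulate_graph_cohort(m = m, n = n, d = d, seed = 63,
                               group_shift = c(3, 0))
  T <- score_tensor(sim$truth$embedding)
  D <- build_design(sim$covariates)
  Dp <- build_design(sim$covariates, groups = sim$groups, include_group = TRUE)
  fc <- regress_tensor(T, D)
  ft <- regress_tensor(T, Dp)
  for (level in c("networks", "pairs", "triples")) {
    ours <- sse_statistic(T, fc, ft, level)
    ref <- sse_brute(unclass(T), D, Dp, level)
    if (level == "triples") {
      off <- !is.na(ours)
      expect_equal(unname(ours[off]) / ref[off], rep(1, sum(off)),
                   tolerance = 1e-10)
    } else {
      expect_equal(unname(as.vector(ours)) / as.vector(ref),
                   rep(1, length(ref)), tolerance = 1e-10)
    }
    expect_true(all(ours >= 0, na.rm = TRUE))
  }

  # network-level statistic is the sum over structures of pair-level values
  Xk <- sse_statistic(T, fc, ft, "networks")
  Xki <- sse_statistic(T, fc, ft, "pairs")
  expect_equal(unname(Xk), unname(rowSums(Xki)), tolerance = 1e-10)
})

test_that("statistics vanish when the groups have identical per-entry structure", {
  set.seed(64)
  m <- 12; d <- 2; n <- 4
  half <- array(rnorm(m / 2 * d * n * n), c(m / 2, d, n, n))
  T <- array(0, c(m, d, n, n))
  T[seq_len(m / 2), , , ] <- half
  T[m / 2 + seq_len(m / 2), , , ] <- half   # mirrored across groups
  groups <- rep(c(0, 1), each = m / 2)
  D <- mregnet:::intercept_design(m)
  Dp <- cbind(D, group = groups)
  X <- sse_statistic(T, regress_tensor(T, D), regress_tensor(T, Dp), "networks")
  expect_lt(max(X), 1e-10)
})

test_that("the fast added-variable path equals rerunning both regressions", {
  set.seed(65)
  sim <- simulate_graph_cohort(m = 25, n = 8, d = 2, seed = 66,
                               group_shift = c(2, -1))
  T <- score_tensor(sim$truth$embedding)
  D <- build_design(sim$covariates)
  Dp <- build_design(sim$covariates, groups = sim$groups, include_group = TRUE)
  x_fast <- mregnet:::entry_stat_factory(mregnet:::tensor_matrix(T), qr(D))(sim$groups)
  x_slow <- colSums(regress_tensor(T, D)$residuals^2) -
    colSums(regress_tensor(T, Dp)$residuals^2)
  expect_equal(x_fast, x_slow, tolerance = 1e-10)
})

test_that("permutation p-values are 1 for permutation-invariant tensors and never 0", {
  m <- 16; d <- 2; n <- 4
  T <- array(rep(rnorm(d * n * n), each = m), c(m, d, n, n))  # identical subjects
  groups <- rep(c(0, 1), m / 2)
  res <- permutation_test(T, groups = groups, level = "networks",
                          n_perm = 99, seed = 1, confounders = FALSE)
  expect_equal(unname(res$p_fwer), rep(1, d))
  expect_equal(nrow(res$rejections), 0L)

  # smallest reportable p-value is 1/(1 + n_perm), never 0
  sim <- simulate_graph_cohort(m = 40, n = 10, d = 2, seed = 67,
                               group_shift = c(-20, 0))
  T2 <- score_tensor(sim$truth$embedding)
  res2 <- permutation_test(T2, sim$covariates, sim$groups, "networks",
                           n_perm = 199, seed = 2)
  expect_true(all(res2$p_fwer >= 1 / 200))
  expect_equal(min(res2$p_fwer), 1 / 200)  # strong planted effect
})

test_that("pair and triple results carry structure names sorted by significance", {
  sim <- simulate_graph_cohort(m = 40, n = 8, d = 2, seed = 68,
                               group_shift = c(-15, 0))
  T <- score_tensor(sim$truth$embedding)
  res <- permutation_test(T, sim$covariates, sim$groups, "pairs",
                          n_perm = 99, seed = 3)
  expect_true(all(c("network", "structure", "p_fwer") %in% names(res$table)))
  expect_true(!is.unsorted(res$table$p_fwer))
  expect_equal(nrow(res$table), 2 * 8)

  rest <- permutation_test(T, sim$covariates, sim$groups, "triples",
                           n_perm = 99, seed = 4)
  expect_equal(nrow(rest$table), 2 * choose(8, 2))
  expect_true(all(is.na(diag(rest$observed[1, , ]))))
})

test_that("a too-coarse permutation resolution warns", {
  T <- array(rnorm(8 * 1 * 3 * 3), c(8, 1, 3, 3))
  expect_warning(permutation_test(T, groups = rep(c(0, 1), 4), level = "networks",
                                  n_perm = 10, seed = 1, confounders = FALSE),
                 "too small")
})
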