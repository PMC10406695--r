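# Seeded synthetic cohort generators with the statistical structure the
# model assumes: graph-level cohorts sampled directly from the generative
# model (with configurable group and confounder effects on the loadings),
# and volume-level cohorts whose trajectory correlations induce block
# adjacency, for exercising the preprocessing pipeline.

# Standardization constants for the simulated covariate distributions; used
# so confounder effect sizes are per standard deviation of the covariate.
SIM_AGE_MEAN <- 75
SIM_AGE_SD <- 30 / sqrt(12)       # sd of uniform(60, 90)
SIM_ICV_MEAN <- 1.5e6
SIM_ICV_SD <- 1.5e5
SIM_APOE_PROBS <- c(0.6, 0.3, 0.1)  # copies 0, 1, 2
SIM_APOE_MEAN <- sum(0:2 * SIM_APOE_PROBS)

# Block-structured basis: each network loads mainly on one contiguous block
# of structures, with small background weight elsewhere; columns unit norm.
block_basis <- function(n, d) {
  cuts <- floor(seq(0, n, length.out = d + 1L))
  h <- matrix(stats::rnorm(n * d, sd = 0.05), n, d)
  for (k in seq_len(d)) {
    idx <- seq.int(cuts[k] + 1L, cuts[k + 1L])
    h[idx, k] <- abs(stats::rnorm(length(idx), mean = 1, sd = 0.2))
  }
  sweep(h, 2L, sqrt(colSums(h^2)), "/")
}

sim_covariates <- function(m, severe_fraction) {
  n_severe <- round(m * severe_fraction)
  if (n_severe < 1L || n_severe > m - 1L)
    stopf("severe_fraction must leave at least one subject in each group")
  group <- integer(m)
  group[sample.int(m, n_severe)] <- 1L
  cdr <- ifelse(group == 1L, sample(c(2, 3), m, replace = TRUE),
                sample(c(0, 0.5, 1), m, replace = TRUE))
  data.frame(subject_id = sprintf("sim_%04d", seq_len(m)),
             age_years = stats::runif(m, 60, 90),
             icv_mm3 = stats::rnorm(m, SIM_ICV_MEAN, SIM_ICV_SD),
             apoe_copies = sample(0:2, m, replace = TRUE,
                                  prob = SIM_APOE_PROBS),
             cdr = cdr, group = group)
}

#' Simulate a cohort of graphs from the generative model
#'
#' Draws per-subject loadings around a population mean, optionally shifted
#' for the severe group and linearly perturbed by confounders, then samples
#' each subject's adjacency matrix from the sigmoid-linked Bernoulli model.
#' Confounder effects act on standardized covariates (age and ICV z-scored
#' against their generating distributions, APOE copies centered), mirroring
#' the linear adjustment the testing module assumes. The full generating
#' truth (basis, loadings, edge probabilities) is returned for parameter
#' recovery and calibration studies.
#'
#' @param m,n,d Cohort size, structure count, network count (defaults 100,
#'   30, 2 — the desk-scale fixture size).
#' @param lam_base Population mean loading, d-vector (default 25 per
#'   network, giving within-block edge probabilities around 0.85).
#' @param group_shift Loading shift added for severe subjects, scalar or
#'   d-vector (default 0: the null construction used for FWER calibration).
#' @param confounder_effects Optional list with d-vectors `age`, `icv`,
#'   `apoe` of per-standard-deviation loading effects (default all zero).
#' @param noise_sd Loading noise standard deviation (default 3).
#' @param severe_fraction Proportion of severe subjects (default 0.35).
#' @param h_true Optional n x d basis with unit-norm columns; defaults to a
#'   random block-structured basis.
#' @param seed Optional seed; a given seed reproduces the cohort exactly.
#' @return List with `adjacency` (an `adjacency_set`), `covariates` (data
#'   frame incl. CDR), `groups`, and `truth` (list: `h`, `lam`,
#'   `E` n x n x m, `embedding` as `mreg_embedding`).
#' @export
simulate_graph_cohort <- function(m = 100L, n = 30L, d = 2L,
                                  lam_base = rep(25, d), group_shift = 0,
                                  confounder_effects = NULL, noise_sd = 3,
                                  severe_fraction = 0.35, h_true = NULL,
                                  seed = NULL) {
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  lam_base <- rep_len(lam_base, d)
  group_shift <- rep_len(group_shift, d)
  eff <- lapply(c(age = "age", icv = "icv", apoe = "apoe"), function(nm) {
    v <- confounder_effects[[nm]]
    if (is.null(v)) rep(0, d) else rep_len(v, d)
  })

  cov <- sim_covariates(m, severe_fraction)
  groups <- cov$group
  h <- h_true %||% block_basis(n, d)
  if (!all(abs(sqrt(colSums(h^2)) - 1) < 1e-6))
    stopf("h_true columns must have unit norm")

  age_z <- (cov$age_years - SIM_AGE_MEAN) / SIM_AGE_SD
  icv_z <- (cov$icv_mm3 - SIM_ICV_MEAN) / SIM_ICV_SD
  apoe_c <- cov$apoe_copies - SIM_APOE_MEAN
  lam <- matrix(lam_base, m, d, byrow = TRUE) +
    outer(groups, group_shift) +
    outer(age_z, eff$age) + outer(icv_z, eff$icv) + outer(apoe_c, eff$apoe) +
    matrix(stats::rnorm(m * d, sd = noise_sd), m, d)

  structures <- default_structures(n)
  emb <- mreg_embedding(h, lam, structures)
  E <- array(NA_real_, c(n, n, m),
             dimnames = list(structures, structures, cov$subject_id))
  A <- E
  for (s in seq_len(m)) {
    Es <- edge_probabilities(emb, s)
    E[, , s] <- Es
    A[, , s] <- sample_graph(Es)
  }
  list(adjacency = adjacency_set(A, structures, cov$subject_id),
       covariates = cov[, setdiff(names(cov), "group")],
       groups = groups,
       truth = list(h = h, lam = lam, E = E, embedding = emb))
}

#' Simulate a longitudinal volume cohort with block co-atrophy
#'
#' Generates per-visit structure volumes in which designated blocks of
#' structures share one latent trajectory (a random walk over visits) plus
#' small independent noise, so their pairwise trajectory correlations are
#' high (in expectation above 0.9 at the default noise ratio) while other
#' structures follow independent trajectories. Missing volumes are injected
#' after the first visit at a configurable rate; the first visit is always
#' complete, matching the preprocessing contract.
#'
#' @param m Number of subjects (default 60).
#' @param n Number of structures (default 30).
#' @param visits Visits per subject (default 6, >= 3), spaced 6 months apart.
#' @param n_blocks Number of correlated structure blocks (default 3); the
#'   blocks tile the first 60 percent of the structures.
#' @param latent_sd Standard deviation of each latent-walk step as a
#'   fraction of baseline volume (default 0.05).
#' @param noise_sd Independent per-visit noise, same units (default 0.005).
#' @param missing_rate Probability each post-baseline volume is missing
#'   (default 0.05).
#' @param severe_fraction Proportion of severe subjects (default 0.35).
#' @param seed Optional seed.
#' @return List with `raw_table` (long format with `NA` for missing),
#'   `covariates`, `cohort` (the forward-filled `volumetric_cohort`) and
#'   `truth` (block membership).
#' @export
simulate_volume_cohort <- function(m = 60L, n = 30L, visits = 6L,
                                   n_blocks = 3L, latent_sd = 0.05,
                                   noise_sd = 0.005, missing_rate = 0.05,
                                   severe_fraction = 0.35, seed = NULL) {
  if (visits < 3L) stopf("at least 3 visits are required")
  if (missing_rate < 0 || missing_rate >= 1)
    stopf("missing_rate must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)

  structures <- default_structures(n)
  block_span <- floor(0.6 * n)
  block_of <- rep(NA_integer_, n)
  block_of[seq_len(block_span)] <-
    rep(seq_len(n_blocks), length.out = block_span)
  months <- seq(0, by = 6, length.out = visits)
  cov <- sim_covariates(m, severe_fraction)

  base <- exp(stats::runif(n, log(500), log(20000)))
  rows <- vector("list", m)
  for (s in seq_len(m)) {
    z_block <- vapply(seq_len(n_blocks),
                      function(b) cumsum(stats::rnorm(visits, sd = latent_sd)),
                      numeric(visits))          # visits x n_blocks
    v <- matrix(NA_real_, n, visits)
    for (i in seq_len(n)) {
      z <- if (is.na(block_of[i]))
        cumsum(stats::rnorm(visits, sd = latent_sd))
      else z_block[, block_of[i]]
      v[i, ] <- base[i] * (1 + z + stats::rnorm(visits, sd = noise_sd))
    }
    if (missing_rate > 0) {
      miss <- matrix(stats::runif(n * visits) < missing_rate, n, visits)
      miss[, 1L] <- FALSE
      v[miss] <- NA_real_
    }
    rows[[s]] <- data.frame(subject_id = cov$subject_id[s],
                            visit_month = rep(months, each = n),
                            structure = rep(structures, visits),
                            volume_mm3 = as.vector(v))
  }
  raw <- do.call(rbind, rows)
  covariates <- cov[, setdiff(names(cov), "group")]
  cohort <- suppressMessages(forward_fill_volumes(raw, covariates))
  list(raw_table = raw, covariates = covariates, cohort = cohort,
       truth = list(blocks = block_of, baseline = base))
}
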