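# Synthetic-data generator: genotypes, effect sizes, random effects,
# liability thresholding, sampling, misclassification injection, variance
# bookkeeping.

test_that("genotypes follow HWE at the drawn frequency", {
  set.seed(1)
  g <- simulate_genotypes(20000, 1, maf_model = "uniform",
                          maf_range = c(0.5, 0.5))
  tab <- tabulate(g$values[, 1] + 1L, 3) / 20000
  expect_equal(tab, c(0.25, 0.5, 0.25), tolerance = 0.02)
  set.seed(2)
  gd <- simulate_genotypes(50, 500, maf_model = "discrete")
  expect_true(all(attr(gd, "maf_drawn") %in% c(0.1, 0.2, 0.4)))
  # sample MAF concentrates on the drawn frequency as n grows
  set.seed(3)
  gl <- simulate_genotypes(5000, 200, maf_model = "uniform",
                           maf_range = c(0.05, 0.5))
  err <- abs(gl$maf - pmin(attr(gl, "maf_drawn"), 1 - attr(gl, "maf_drawn")))
  expect_lt(mean(err), 0.01)
})

test_that("effect sizes follow the MAF-dependent variance model", {
  cfg2 <- simulation_config(strategy = 2)
  # sd at f = 0.25: sqrt(0.1 * 0.375^-0.38)
  expect_equal(sqrt(0.1 * (2 * 0.25 * 0.75)^-0.38), 0.3810080,
               tolerance = 1e-6)
  set.seed(4)
  draws <- draw_effect_sizes(cfg2, rep(0.25, 20000))
  expect_equal(sd(draws), sqrt(0.1 * 0.375^-0.38), tolerance = 0.01)
  expect_equal(mean(draws), 0, tolerance = 0.01)
  # negative exponent: rarer alleles get larger effect variance
  v_rare <- 0.1 * (2 * 0.01 * 0.99)^-0.38
  v_common <- 0.1 * (2 * 0.5 * 0.5)^-0.38
  expect_gt(v_rare, v_common)
  cfg1 <- simulation_config(strategy = 1)
  set.seed(5)
  d1 <- draw_effect_sizes(cfg1)
  expect_equal(length(d1), 30)
  set.seed(6)
  d1b <- replicate(300, mean(draw_effect_sizes(cfg1)))
  expect_equal(mean(d1b), 2, tolerance = 3 * sqrt(0.3 / (30 * 300)))
})

test_that("random effects have the kinship covariance structure", {
  set.seed(7)
  u <- replicate(3000, simulate_random_effects(kinship_matrix(diag(4)), 2))
  expect_equal(mean(apply(u, 1, var)), 2, tolerance = 0.1)
  # duplicated individuals share their random effect
  A <- matrix(0.999, 2, 2); diag(A) <- 1
  set.seed(8)
  ud <- replicate(2000, simulate_random_effects(kinship_matrix(A), 2))
  expect_gt(cor(ud[1, ], ud[2, ]), 0.99)
  set.seed(9); u1 <- simulate_random_effects(kinship_matrix(diag(5)), 2)
  set.seed(9); u2 <- simulate_random_effects(kinship_matrix(diag(5)), 2)
  expect_identical(u1, u2)
})

test_that("liability thresholding realizes the target prevalence exactly", {
  set.seed(10)
  X <- matrix(rbinom(10000, 2, 0.3), ncol = 1)
  pop <- simulate_population_phenotype(X, 0.5, rep(0, 10000), 0.3)
  expect_equal(mean(pop$y_true), 0.3, tolerance = 1e-3)
  # null model: phenotype independent of genotype
  set.seed(11)
  pop0 <- simulate_population_phenotype(X, 0, rep(0, 10000), 0.5)
  expect_lt(abs(cor(pop0$y_true, X[, 1])), 0.05)
  expect_error(
    simulate_population_phenotype(matrix(0, 5, 1), 0, rep(0, 5) * NA, 0.5))
})

test_that("balanced structure-free replicates give 1000 cases and 1000 controls", {
  cfg <- simulation_config(strategy = 1, n_population = 2000, m_snps = 300,
                           n_causal = 10, n_cases = 1000, n_controls = 1000,
                           misclassification_fraction = 0.05)
  set.seed(12)
  ds <- simulate_study(cfg)
  expect_equal(sum(ds$y_true$values), 1000)
  expect_equal(sum(1 - ds$y_true$values), 1000)
  expect_equal(sum(ds$misclassified_mask), round(0.05 * 1000))
})

test_that("case/control sampling preserves labels and errors when short", {
  y <- c(rep(1L, 5), rep(0L, 20))
  set.seed(13)
  idx <- sample_case_control(y, 5, 10)
  expect_equal(sum(y[idx]), 5)
  expect_equal(length(idx), 15)
  expect_error(sample_case_control(y, 6, 10), "prevalence")
  set.seed(14); i1 <- sample_case_control(y, 3, 10)
  set.seed(14); i2 <- sample_case_control(y, 3, 10)
  expect_identical(i1, i2)
})

test_that("misclassification injection flips exactly the stated control fraction", {
  y <- c(rep(1L, 1000), rep(0L, 3000))
  set.seed(15)
  mis <- inject_misclassification(y, 0.01)
  expect_equal(sum(mis$mask), 30)
  expect_equal(sum(mis$y_observed), 1030)
  expect_true(all(y[mis$mask] == 0L))
  expect_identical(xor(mis$y_observed == 1L, y == 1L), mis$mask)
  mis0 <- inject_misclassification(y, 0)
  expect_identical(mis0$y_observed, y)
  expect_false(any(mis0$mask))
  for (f in c(0.05, 0.10, 0.20, 0.30, 0.40)) {
    m <- inject_misclassification(y, f)
    expect_equal(sum(m$mask), round(f * 3000))
  }
  expect_error(inject_misclassification(y, 1), "below 1")
})

test_that("variance bookkeeping matches direct ratios and sums to at most one", {
  set.seed(16)
  n <- 50000
  X <- matrix(rbinom(n, 2, 0.5), ncol = 1)  # Var = 2*0.5*0.5 = 0.5
  eps <- rnorm(n)
  v <- variance_explained(X, 1, rep(0, n), eps)
  expect_equal(v$per_snp[1], 0.5 / 1.5, tolerance = 0.02)
  expect_equal(v$h2_snp, v$h2_snp_plus_u, tolerance = 1e-12)
  # independent SNPs: fractions sum to about h2, never much above 1
  set.seed(17)
  Xm <- sapply(runif(20, 0.1, 0.5), function(f) rbinom(2000, 2, f))
  betas <- rnorm(20, 0, 0.3)
  vm <- variance_explained(Xm, betas, rep(0, 2000), rnorm(2000))
  expect_lt(sum(vm$per_snp), 1.05)
  expect_equal(sum(vm$per_snp), vm$h2_snp, tolerance = 0.05)
  null_snp <- variance_explained(cbind(Xm, Xm[, 1]), c(betas, 0),
                                 rep(0, 2000), rnorm(2000))
  expect_equal(null_snp$per_snp[21], 0)
})

test_that("population/replicate split shares genotypes and random effects", {
  cfg <- simulation_config(strategy = 2, n_population = 300, m_snps = 400,
                           n_causal = 10, n_cases = 40, n_controls = 120,
                           misclassification_fraction = 0.1)
  set.seed(18)
  pop <- simulate_population(cfg)
  r1 <- simulate_replicate(pop)
  r2 <- simulate_replicate(pop)
  expect_identical(pop$causal_indices, r1$causal_indices)
  expect_identical(r1$causal_indices, r2$causal_indices)
  expect_false(identical(r1$beta_true, r2$beta_true))
  # ground-truth bookkeeping invariant
  expect_identical(xor(r1$y_observed$values == 1L, r1$y_true$values == 1L),
                   r1$misclassified_mask)
  expect_true(all(r1$y_true$values[r1$misclassified_mask] == 0L))
  expect_gte(r1$realized_prevalence, 0.1 - 1e-9)
  expect_lte(r1$realized_prevalence, 0.5 + 1e-9)
})

test_that("structured-design variance fractions land in the expected span", {
  cfg <- simulation_config(strategy = 2, n_population = 500, m_snps = 600,
                           n_causal = 30, n_cases = 50, n_controls = 150)
  set.seed(19)
  pop <- simulate_population(cfg)
  ds <- simulate_replicate(pop)
  expect_true(all(ds$variance$per_snp >= 0))
  expect_lt(max(ds$variance$per_snp), 0.25)
  expect_gt(ds$variance$h2_snp_plus_u, ds$variance$h2_snp)
})
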