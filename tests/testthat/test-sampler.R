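# Sampler components: initialization, MH block, indicators, liability
# augmentation, Gibbs updates, adaptation, switch filtering, Geweke, and the
# assembled chain.

test_that("initialization draws from the priors with fixed u and variance", {
  priors <- prior_spec()
  set.seed(11)
  s1 <- initialize_state(priors, n = 7, k = 3)
  set.seed(11)
  s2 <- initialize_state(priors, n = 7, k = 3)
  expect_identical(s1, s2)
  expect_identical(s1$u, rep(0, 7))
  expect_identical(s1$sigma_u2, 0.1)
  set.seed(12)
  draws <- replicate(10000, initialize_state(priors, 2, 1)$alpha)
  se <- sqrt(10 / (11^2 * 12) / 10000)  # Beta(10,1) sd / sqrt(n)
  expect_lt(abs(mean(draws) - 10 / 11), 3 * se)
})

test_that("MH block accepts identical-posterior proposals and rejects invalid ones", {
  dat <- make_model_data(30, c(1, -1), 0.9, 0.1, seed = 21)
  priors <- prior_spec()
  state <- model_params(0.8, 0.2, c(0.5, -0.5), rep(0, 30), 0.1)
  # vanishing proposal scales: ratio -> 1, so acceptance is (near) certain
  set.seed(22)
  scales <- list(alpha = 1e-12, lambda = 1e-12, beta = 1e-12)
  acc <- replicate(50, mh_update_params(state, dat$y_obs, dat$X, priors,
                                        scales)$accepted)
  expect_true(all(acc))
  # non-finite proposed posterior auto-rejects rather than crashing
  bad_state <- state; bad_state$sigma_u2 <- 200  # outside support: -Inf
  set.seed(23)
  step <- mh_update_params(bad_state, dat$y_obs, dat$X, priors,
                           list(alpha = 0.1, lambda = 0.1, beta = 0.1))
  expect_false(step$accepted)
})

test_that("truncated proposals stay inside the unit interval", {
  set.seed(24)
  draws <- phenofix:::rtruncnorm(5000, mean = 0.01, sd = 0.5, 0, 1)
  expect_true(all(draws > 0 & draws < 1))
  draws_hi <- phenofix:::rtruncnorm(5000, mean = 0.99, sd = 0.5, 0, 1)
  expect_true(all(draws_hi > 0 & draws_hi < 1))
})

test_that("misclassification indicators follow the posterior Bernoulli rates", {
  state <- model_params(0.9, 0.1, 0, 0, 1)
  y <- c(1, 0)
  # lambda at machine epsilon: cases never marked
  st_eps <- state; st_eps$lambda <- 1e-300
  set.seed(31)
  marks <- replicate(2000, sample_misclassification_indicators(
    st_eps, y, c(0.5, 0.5))$marked[1])
  expect_false(any(marks))
  # alpha near 1: controls never marked
  st_a <- state; st_a$alpha <- 1 - 1e-15
  set.seed(32)
  marks <- replicate(2000, sample_misclassification_indicators(
    st_a, y, c(0.5, 0.5))$marked[2])
  expect_false(any(marks))
  # empirical mark rate matches the posterior probability
  p_expect <- case_misclassification_probability(0.9, 0.1, 0.5)
  set.seed(33)
  marks <- replicate(20000, sample_misclassification_indicators(
    state, y, c(0.5, 0.5))$marked[1])
  se <- sqrt(p_expect * (1 - p_expect) / 20000)
  expect_lt(abs(mean(marks) - p_expect), 3 * se)
  # marked samples flip y_latent relative to the observation
  set.seed(34)
  ind <- sample_misclassification_indicators(state, rep(c(1, 0), 50),
                                             rep(0.5, 100))
  y100 <- rep(c(1L, 0L), 50)
  expect_identical(ind$y_latent[ind$marked], 1L - y100[ind$marked])
  expect_identical(ind$y_latent[!ind$marked], y100[!ind$marked])
})

test_that("liability draws respect the sign constraint and half-normal moments", {
  set.seed(41)
  l_pos <- sample_latent_liability(rep(1L, 20000), rep(0, 20000))
  expect_true(all(l_pos > 0))
  expect_equal(mean(l_pos), sqrt(2 / pi), tolerance = 0.02)
  l_neg <- sample_latent_liability(rep(0L, 5000), rep(0, 5000))
  expect_true(all(l_neg <= 0))
  # far from the boundary the truncation is inactive
  l_far <- sample_latent_liability(rep(1L, 5000), rep(10, 5000))
  expect_equal(mean(l_far), 10, tolerance = 0.05)
  expect_equal(sd(l_far), 1, tolerance = 0.05)
  # extreme truncation: inverse CDF keeps drawing finite values
  l_ext <- sample_latent_liability(rep(1L, 100), rep(-15, 100))
  expect_true(all(is.finite(l_ext) & l_ext > 0))
})

test_that("random-effect sweep matches the conjugate conditional at A = I", {
  n <- 4
  l <- c(2, -1, 0.5, 3)
  eta <- rep(0, n)
  set.seed(51)
  draws <- t(replicate(20000, gibbs_update_u(l, eta, rep(0, n), diag(n), 1)))
  # with A = I, gamma = 1: u_i ~ N(l_i / 2, 1/2), independent of u_{-i}
  expect_equal(colMeans(draws), l / 2, tolerance = 0.02)
  expect_equal(apply(draws, 2, var), rep(0.5, n), tolerance = 0.03)
})

test_that("random-effect sweep targets the exact conditional MVN on a 3-sample toy", {
  A <- matrix(c(1, 0.5, 0.2,
                0.5, 1, 0.3,
                0.2, 0.3, 1), 3, 3)
  K <- kinship_matrix(A)
  l <- c(1, -0.5, 2)
  gamma <- 1 / 0.8
  # closed-form conditional: precision I + gamma * A^-1
  P <- diag(3) + gamma * K$inverse
  Sigma_exact <- solve(P)
  mu_exact <- drop(Sigma_exact %*% l)
  set.seed(52)
  u <- rep(0, 3)
  keep <- matrix(NA_real_, 20000, 3)
  for (i in seq_len(25000)) {
    u <- gibbs_update_u(l, rep(0, 3), u, K$inverse, 0.8)
    if (i > 5000) keep[i - 5000, ] <- u
  }
  expect_equal(colMeans(keep), mu_exact, tolerance = 0.03)
  expect_equal(cov(keep), Sigma_exact, tolerance = 0.05)
})

test_that("variance update matches the truncated density", {
  # mode of x^(-q/2) exp(-S/(2x)) is S/q
  q <- 4; S <- 8
  dens <- function(x) -(q / 2) * log(x) - S / (2 * x)
  xs <- c(S / q - 1e-4, S / q, S / q + 1e-4)
  expect_true(which.max(dens(xs)) == 2)
  # draws never exceed the truncation bound
  set.seed(61)
  u10 <- rnorm(10)
  draws <- replicate(2000, gibbs_update_sigma_u2(u10, diag(10)))
  expect_true(all(draws <= 100 & draws > 0))
  # KS test against the numeric CDF at q = 10, S = 20
  uS <- sqrt(rep(2, 10))  # u'u = 20 with A = I
  set.seed(62)
  draws <- replicate(20000, gibbs_update_sigma_u2(uS, diag(10)))
  ks <- suppressWarnings(
    ks.test(draws, function(x) oracle_sigma_u2_cdf(x, q = 10, S = 20)))
  expect_gt(ks$p.value, 0.01)
  # S = 0 returns the current value
  expect_equal(gibbs_update_sigma_u2(rep(0, 5), diag(5), current = 0.37),
               0.37)
})

test_that("proposal adaptation moves scales toward the target acceptance", {
  sc <- list(alpha = 0.1, lambda = 0.1, beta = 0.1)
  expect_equal(adapt_proposal_scales(sc, 0.2, 0.2, 1), sc)
  grown <- adapt_proposal_scales(sc, 1.0, 0.2, 1)
  expect_true(all(unlist(grown) > unlist(sc)))
  shrunk <- adapt_proposal_scales(sc, 0.0, 0.2, 1)
  expect_true(all(unlist(shrunk) < unlist(sc)))
  # adapted random-walk on a standard normal target settles near 0.2:
  # simple MH with the package's adaptation rule
  set.seed(71)
  x <- 0; scale <- 10; acc_hist <- logical(0); batch <- 0
  acc_window <- 0
  for (it in 1:20000) {
    prop <- rnorm(1, x, scale)
    if (log(runif(1)) < dnorm(prop, log = TRUE) - dnorm(x, log = TRUE)) {
      x <- prop; acc <- TRUE
    } else acc <- FALSE
    acc_window <- acc_window + acc
    if (it > 10000) acc_hist <- c(acc_hist, acc)
    if (it <= 10000 && it %% 50 == 0) {
      batch <- batch + 1
      scale <- adapt_proposal_scales(list(s = scale), acc_window / 50,
                                     0.2, batch)$s
      acc_window <- 0
    }
  }
  expect_gt(mean(acc_hist), 0.12)
  expect_lt(mean(acc_hist), 0.30)
})

test_that("label-switch filtering discards exactly the alpha < lambda iterations", {
  alpha <- c(rep(0.2, 10), rep(0.9, 90))
  lambda <- c(rep(0.8, 10), rep(0.1, 90))
  f <- detect_and_filter_label_switch(alpha, lambda)
  expect_equal(f$discarded, 10)
  expect_true(f$usable)
  expect_identical(which(!f$keep), 1:10)
  all_ok <- detect_and_filter_label_switch(rep(0.9, 50), rep(0.1, 50))
  expect_equal(all_ok$discarded, 0)
  mostly_switched <- detect_and_filter_label_switch(rep(0.1, 50), rep(0.9, 50))
  expect_false(mostly_switched$usable)
})

test_that("Geweke z-score flags drift and is calibrated on stationary series", {
  expect_error(geweke_z(rnorm(50)), "too short")
  drift <- c(rep(0, 500), rep(10, 500)) + rnorm(1000, sd = 0.01)
  expect_gt(abs(geweke_z(drift)), 10)
  sym <- rep(c(rnorm(200)), 5)
  expect_true(is.na(geweke_z(rep(1, 200))))
  set.seed(81)
  zs <- replicate(200, geweke_z(rnorm(5000)))
  expect_gte(mean(abs(zs) < 1.96), 0.90)
})

test_that("a chain with a single retained iteration averages to 0/1 marks", {
  dat <- make_model_data(20, c(1.5), 0.95, 0.05, seed = 91)
  cfg <- mcmc_config(n_iter = 201, burn_in = 200, seed = 5,
                     disable_mixed_model = TRUE, adapt_interval = 50)
  tr <- run_chain(dat$y_obs, matrix(dat$X, ncol = 1), NULL,
                  prior_spec(), cfg)
  expect_lte(tr$denominator, 1)
  if (tr$denominator == 1) {
    expect_true(all(tr$avg_prob %in% c(0, 1)))
  }
})

test_that("chains are bit-reproducible under a fixed seed", {
  dat <- make_model_data(40, c(1, -1), 0.9, 0.1, seed = 92)
  A <- compute_grm(make_genotypes(40, 60, seed = 93))
  cfg <- mcmc_config(n_iter = 800, burn_in = 200, seed = 99)
  t1 <- run_chain(dat$y_obs, dat$X, A, prior_spec(), cfg)
  t2 <- run_chain(dat$y_obs, dat$X, A, prior_spec(), cfg)
  expect_identical(t1$avg_prob, t2$avg_prob)
  expect_identical(t1$alpha, t2$alpha)
})

test_that("mixed-model ablation matches the full model on structure-free data", {
  dat <- make_model_data(150, c(1.2, -1.2, 0.8), 0.95, 0.08, seed = 94)
  cfg_full <- mcmc_config(n_iter = 4000, burn_in = 1000, seed = 7)
  cfg_ablat <- mcmc_config(n_iter = 4000, burn_in = 1000, seed = 7,
                           disable_mixed_model = TRUE)
  A <- kinship_matrix(diag(150))
  tr_full <- run_chain(dat$y_obs, dat$X, A, prior_spec(), cfg_full)
  tr_ablat <- run_chain(dat$y_obs, dat$X, NULL, prior_spec(), cfg_ablat)
  is_case <- dat$y_obs == 1
  rc <- cor(tr_full$avg_prob[is_case], tr_ablat$avg_prob[is_case],
            method = "spearman")
  expect_gt(rc, 0.9)
})

test_that("aggregation thresholds at the case percentile with strict inequality", {
  probs <- seq(0.01, 1, length.out = 100)
  y <- rep(1L, 100); y[1] <- 0L  # 99 cases with distinct probabilities
  res <- aggregate_and_flag(list(probs), y, t_percentile = 99)
  expect_equal(sum(res$flagged), 1)
  expect_true(res$flagged[100])
  # ties: all equal probabilities flag nothing
  res_tie <- aggregate_and_flag(list(rep(0.4, 100)), y, t_percentile = 99)
  expect_equal(sum(res_tie$flagged), 0)
  # multi-run averaging equals flags from the mean vector
  r1 <- runif(100); r2 <- runif(100)
  res_multi <- aggregate_and_flag(list(r1, r2), y, t_percentile = 95)
  res_mean <- aggregate_and_flag(list((r1 + r2) / 2), y, t_percentile = 95)
  expect_identical(res_multi$flagged, res_mean$flagged)
  # zero usable chains is a hard error
  expect_error(aggregate_and_flag(list(), y), "usable")
})

test_that("phenotype correction conserves case counts and rejects control flags", {
  y <- c(1L, 1L, 0L)
  expect_identical(correct_phenotype(y, c(TRUE, FALSE, FALSE)), c(0L, 1L, 0L))
  expect_identical(correct_phenotype(y, rep(FALSE, 3)), y)
  expect_error(correct_phenotype(y, c(FALSE, FALSE, TRUE)), "controls")
  set.seed(101)
  for (i in 1:20) {
    n <- 50
    yy <- rbinom(n, 1, 0.5); yy[1] <- 1; yy[2] <- 0
    fl <- yy == 1 & runif(n) < 0.3
    corrected <- correct_phenotype(yy, fl)
    expect_equal(sum(corrected) + sum(fl), sum(yy))
  }
})
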