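# Independent oracles and small fixture builders used across the suite.
# Every oracle here is a deliberately naive implementation (enumeration,
# closed form, or brute-force integration) kept separate from the package's
# own code paths.

# Brute-force Bayes posterior over the four-cell joint of (Y', Y):
# P(Y' = 1) = sigma, P(Y = 1 | Y' = 1) = alpha, P(Y = 1 | Y' = 0) = lambda.
oracle_joint_posterior <- function(alpha, lambda, sigma) {
  p11 <- sigma * alpha        # Y' = 1, Y = 1
  p01 <- (1 - sigma) * lambda # Y' = 0, Y = 1
  p10 <- sigma * (1 - alpha)  # Y' = 1, Y = 0
  p00 <- (1 - sigma) * (1 - lambda)
  list(case_mis = p01 / (p01 + p11),   # P(Y' = 0 | Y = 1)
       ctrl_mis = p10 / (p10 + p00))   # P(Y' = 1 | Y = 0)
}

# Hand-computed Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

# Rank-based AUC (Mann-Whitney U normalization) with tie correction.
oracle_auc_rank <- function(scores, truth) {
  truth <- as.logical(truth)
  r <- rank(scores)
  n1 <- sum(truth); n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Brute-force grid integration of the (alpha, lambda) marginal posterior for
# a tiny no-mixed-model problem: likelihood over samples x mixture, priors
# Beta(10,1) x Beta(1,1) x N(0,1) per effect, effects integrated on a grid.
oracle_grid_marginal <- function(y, x, alpha_grid, lambda_grid,
                                 beta_grid = seq(-5, 5, length.out = 201)) {
  post <- matrix(0, length(alpha_grid), length(lambda_grid))
  wb <- stats::dnorm(beta_grid)
  for (ia in seq_along(alpha_grid)) {
    a <- alpha_grid[ia]
    for (il in seq_along(lambda_grid)) {
      l <- lambda_grid[il]
      lik_b <- vapply(beta_grid, function(b) {
        s <- stats::pnorm(x * b)
        prod(ifelse(y == 1, l * (1 - s) + a * s,
                    (1 - l) * (1 - s) + (1 - a) * s))
      }, numeric(1))
      post[ia, il] <- sum(lik_b * wb) *
        stats::dbeta(a, 10, 1) * stats::dbeta(l, 1, 1)
    }
  }
  post / sum(post)
}

# CDF of the truncated conditional density of sigma_u2:
# proportional to x^(-q/2) exp(-S/(2x)) on (0, smax].
oracle_sigma_u2_cdf <- function(x, q, S, smax = 100) {
  a <- q / 2 - 1
  b <- S / 2
  num <- stats::pgamma(1 / x, a, rate = b, lower.tail = FALSE)
  den <- stats::pgamma(1 / smax, a, rate = b, lower.tail = FALSE)
  ifelse(x >= smax, 1, num / den)
}

# Small reproducible structure-free dataset drawn from the generative model
# itself: latent probit phenotype plus recording-error channel.
make_model_data <- function(n, betas, alpha, lambda, seed = 1,
                            maf = 0.3) {
  set.seed(seed)
  k <- length(betas)
  X <- matrix(stats::rbinom(n * k, 2L, maf), n, k)
  sigma <- stats::pnorm(drop(X %*% betas))
  y_true <- stats::rbinom(n, 1L, sigma)
  y_obs <- ifelse(y_true == 1L, stats::rbinom(n, 1L, alpha),
                  stats::rbinom(n, 1L, lambda))
  list(X = X, y_true = y_true, y_obs = as.integer(y_obs), sigma = sigma)
}

# Tiny genotype matrix with guaranteed polymorphic columns.
make_genotypes <- function(n, m, seed = 1, maf = NULL) {
  set.seed(seed)
  if (is.null(maf)) maf <- stats::runif(m, 0.1, 0.5)
  repeat {
    vals <- vapply(maf, function(f) stats::rbinom(n, 2L, f), integer(n))
    if (!any(apply(vals, 2, function(x) all(x == x[1])))) break
  }
  genotype_matrix(vals)
}
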