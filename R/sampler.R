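# Adaptive Metropolis-Hastings within Gibbs for the misclassification model:
# an MH block over (alpha, lambda, beta), Bernoulli misclassification
# indicators, Albert-Chib truncated-normal liability augmentation, single-site
# Gibbs updates of the random effects, and a truncated draw of their variance.

#' MCMC configuration
#'
#' @param n_iter Total iterations (default 100000).
#' @param burn_in Discarded iterations (default 20000).
#' @param target_acceptance Adaptation target for the MH block (default 0.2).
#' @param adapt_interval Iterations between proposal-scale updates during
#'   burn-in (default 50).
#' @param initial_scales Starting proposal standard deviations, named list
#'   with \code{alpha}, \code{lambda}, \code{beta} (a scalar recycled over
#'   effect components).
#' @param n_chains Number of chains (default 1; 10 is the usual choice on
#'   real data).
#' @param t_percentile Percentile (0-100) of case misclassification
#'   probabilities used as the flagging threshold t (default 99).
#' @param intercept Prepend an all-ones column to the training matrix, its
#'   coefficient carrying the same N(0,1) prior as SNP effects. Default TRUE;
#'   disabled by \code{strict_paper_mode}.
#' @param center_genotypes Center training-SNP columns (default FALSE; raw
#'   0/1/2 counts).
#' @param strict_paper_mode Disables the intercept (default FALSE).
#' @param disable_mixed_model Ablation: fix u = 0 and skip the variance
#'   update (no kinship needed).
#' @param disable_adaptation Ablation: keep proposal scales fixed.
#' @param thin Thinning interval for the stored effect trace (default keeps
#'   about 2000 draws).
#' @param seed Optional RNG seed applied at chain start.
#' @return Object of class \code{mcmc_config}.
#' @export
mcmc_config <- function(n_iter = 100000, burn_in = 20000,
                        target_acceptance = 0.2, adapt_interval = 50,
                        initial_scales = list(alpha = 0.1, lambda = 0.1,
                                              beta = 0.1),
                        n_chains = 1, t_percentile = 99,
                        intercept = TRUE, center_genotypes = FALSE,
                        strict_paper_mode = FALSE,
                        disable_mixed_model = FALSE,
                        disable_adaptation = FALSE,
                        thin = NULL, seed = NULL) {
  stopifnot(burn_in > 0, burn_in < n_iter,
            target_acceptance > 0, target_acceptance < 1,
            t_percentile > 0, t_percentile < 100, adapt_interval >= 1)
  if (strict_paper_mode) intercept <- FALSE
  if (is.null(thin)) thin <- max(1L, floor(n_iter / 2000))
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 target_acceptance = target_acceptance,
                 adapt_interval = as.integer(adapt_interval),
                 initial_scales = initial_scales,
                 n_chains = as.integer(n_chains),
                 t_percentile = t_percentile, intercept = intercept,
                 center_genotypes = center_genotypes,
                 strict_paper_mode = strict_paper_mode,
                 disable_mixed_model = disable_mixed_model,
                 disable_adaptation = disable_adaptation,
                 thin = as.integer(thin), seed = seed),
            class = "mcmc_config")
}

#' Draw a random starting state
#'
#' alpha from its Beta prior, lambda from its Beta prior, effects from their
#' Normal prior; u starts at the zero vector and sigma_u2 at 0.1.
#'
#' @param priors A \code{prior_spec}.
#' @param n Sample count.
#' @param k Number of effect components (training SNPs plus intercept if
#'   used).
#' @return A \code{model_params} state.
#' @export
initialize_state <- function(priors, n, k) {
  stopifnot(n >= 1, k >= 1)
  model_params(
    alpha = stats::rbeta(1, priors$alpha_shape[1], priors$alpha_shape[2]),
    lambda = stats::rbeta(1, priors$lambda_shape[1], priors$lambda_shape[2]),
    beta = stats::rnorm(k, priors$beta_mean, priors$beta_sd),
    u = rep(0, n),
    sigma_u2 = 0.1
  )
}

# Inverse-CDF draw from N(mean, sd) truncated to (lower, upper).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- plo + stats::runif(n) * (phi - plo)
  stats::qnorm(pmin(pmax(u, 1e-300), 1 - 1e-16), mean, sd)
}

# Log normalizing constant of a normal proposal truncated to (0, 1),
# centred at x with sd s; needed for the Hastings correction.
log_trunc_const01 <- function(x, s) {
  log(stats::pnorm((1 - x) / s) - stats::pnorm(-x / s))
}

#' Metropolis-Hastings update of (alpha, lambda, beta)
#'
#' Proposes alpha and lambda from normals truncated to (0, 1) and the effect
#' vector from independent normals, all centred at the current state, and
#' accepts or rejects the triple jointly using the observed-data likelihood
#' times the alpha/lambda/beta priors. The asymmetry of the truncated
#' proposals is corrected in the acceptance ratio.
#'
#' @param current A \code{model_params} state.
#' @param y Observed 0/1 phenotype.
#' @param X Training design matrix (intercept column included if used).
#' @param priors A \code{prior_spec}.
#' @param scales Proposal sds: list with \code{alpha}, \code{lambda},
#'   \code{beta} (scalar or length-k vector).
#' @param log_post_current Cached log-posterior of \code{current} (optional).
#' @return List with \code{params}, \code{accepted} (logical) and
#'   \code{log_post} of the returned state.
#' @export
mh_update_params <- function(current, y, X, priors, scales,
                             log_post_current = NULL) {
  if (is.null(log_post_current)) {
    log_post_current <- log_posterior(current, y, X, priors)
  }
  a_new <- rtruncnorm(1, current$alpha, scales$alpha, 0, 1)
  l_new <- rtruncnorm(1, current$lambda, scales$lambda, 0, 1)
  b_new <- stats::rnorm(length(current$beta), current$beta, scales$beta)
  prop <- current
  prop$alpha <- a_new; prop$lambda <- l_new; prop$beta <- b_new
  log_post_prop <- log_posterior(prop, y, X, priors)
  # Hastings correction: q(cur | prop) / q(prop | cur) for the two truncated
  # components (the normal beta proposal is symmetric).
  log_hastings <-
    (log_trunc_const01(current$alpha, scales$alpha) -
       log_trunc_const01(a_new, scales$alpha)) +
    (log_trunc_const01(current$lambda, scales$lambda) -
       log_trunc_const01(l_new, scales$lambda))
  log_ratio <- log_post_prop - log_post_current + log_hastings
  accept <- is.finite(log_ratio) && log(stats::runif(1)) < log_ratio
  if (accept) {
    list(params = prop, accepted = TRUE, log_post = log_post_prop)
  } else {
    list(params = current, accepted = FALSE, log_post = log_post_current)
  }
}

#' Draw per-iteration misclassification indicators
#'
#' Each observed case is marked misclassified with its case posterior
#' probability and each observed control with its control posterior
#' probability (Bernoulli draws); marked samples have their latent phenotype
#' flipped relative to the observation for this iteration.
#'
#' @param params Current \code{model_params}.
#' @param y Observed 0/1 phenotype.
#' @param sigma Genetic case probabilities at the current state.
#' @return List with \code{marked} (logical vector) and \code{y_latent}
#'   (integer vector).
#' @export
sample_misclassification_indicators <- function(params, y, sigma) {
  if (inherits(y, "phenotype_vector")) y <- y$values
  n <- length(y)
  p <- numeric(n)
  is_case <- y == 1L
  p[is_case] <- case_misclassification_probability(
    params$alpha, params$lambda, sigma[is_case])
  p[!is_case] <- control_misclassification_probability(
    params$alpha, params$lambda, sigma[!is_case])
  marked <- stats::runif(n) < p
  y_latent <- ifelse(marked, 1L - y, y)
  list(marked = marked, y_latent = as.integer(y_latent))
}

#' Sample latent liabilities given the current latent phenotype
#'
#' Albert-Chib augmentation: \eqn{l_i \sim N(X_i\beta + u_i, 1)} truncated to
#' the positive half-line when the latent phenotype is 1 and to the
#' non-positive half-line otherwise, drawn by inverse CDF so that extreme
#' truncation never loops.
#'
#' @param y_latent Current 0/1 latent phenotype.
#' @param eta Linear predictor \eqn{X\beta + u} per sample.
#' @return Liability vector.
#' @export
sample_latent_liability <- function(y_latent, eta) {
  n <- length(y_latent)
  stopifnot(length(eta) == n)
  u <- stats::runif(n)
  l <- numeric(n)
  pos <- y_latent == 1L
  # upper-tail coordinates keep precision when the mean is far from 0
  if (any(pos)) {
    v <- pmax(u[pos] * stats::pnorm(eta[pos]), 1e-300)
    l[pos] <- eta[pos] + stats::qnorm(v, lower.tail = FALSE)
  }
  if (any(!pos)) {
    v <- pmax(u[!pos] * stats::pnorm(-eta[!pos]), 1e-300)
    l[!pos] <- eta[!pos] - stats::qnorm(v, lower.tail = FALSE)
  }
  l
}

#' Gibbs update of the random effects
#'
#' Sequential single-site conditional-normal updates
#' \eqn{u_i \sim N(\hat u_i, (1 + c_{ii}\gamma)^{-1})} with
#' \eqn{\hat u_i = (1 + c_{ii}\gamma)^{-1}((l_i - X_i\beta) -
#' \gamma\, c_{i,-i} u_{-i})}, where \eqn{c} indexes the kinship inverse and
#' \eqn{\gamma = 1/\sigma_u^2}.
#'
#' @param l Liability vector.
#' @param eta_fixed Fixed-effect part \eqn{X\beta} per sample.
#' @param u Current random effects.
#' @param A_inv Kinship inverse matrix.
#' @param sigma_u2 Current random-effect variance.
#' @return Updated random-effect vector.
#' @export
gibbs_update_u <- function(l, eta_fixed, u, A_inv, sigma_u2) {
  gibbs_u_sweep(l - eta_fixed, A_inv, u, 1 / sigma_u2)
}

#' Gibbs update of the random-effect variance
#'
#' Draws from the conditional density proportional to
#' \eqn{(\sigma_u^2)^{-q/2} \exp(-S / (2\sigma_u^2))} truncated to
#' \code{(0, sigma_u2_max]}, with \eqn{S = u^\top A^{-1} u} and q the length
#' of u (flat prior on the variance). Inverse-CDF sampling through the
#' equivalent truncated gamma on the precision scale; a numeric-grid inverse
#' is used in the boundary case \eqn{q \le 2} where the gamma shape is not
#' positive.
#'
#' @param u Random-effect vector.
#' @param A_inv Kinship inverse.
#' @param sigma_u2_max Upper truncation (default 100).
#' @param current Returned unchanged when S = 0 (degenerate density).
#' @param q Exponent parameter, defaults to \code{length(u)}.
#' @return Updated variance draw in \code{(0, sigma_u2_max]}.
#' @export
gibbs_update_sigma_u2 <- function(u, A_inv, sigma_u2_max = 100,
                                  current = NULL, q = length(u)) {
  S <- drop(crossprod(u, A_inv %*% u))
  if (S <= 0) {
    if (is.null(current)) stop("S = 0 with no current value to keep")
    return(current)
  }
  shape <- q / 2 - 1
  if (shape > 0) {
    # sigma_u2 ~ inverse-gamma(shape, S/2); on the precision scale
    # v = 1/sigma_u2 ~ gamma(shape, rate = S/2) truncated to v >= 1/max
    ptail <- stats::pgamma(1 / sigma_u2_max, shape, rate = S / 2,
                           lower.tail = FALSE)
    if (ptail < 1e-300) return(sigma_u2_max)
    v <- stats::qgamma(stats::runif(1) * ptail, shape, rate = S / 2,
                       lower.tail = FALSE)
    return(min(1 / v, sigma_u2_max))
  }
  # q <= 2: integrable only because of the truncation; numeric inverse CDF
  grid <- exp(seq(log(1e-8), log(sigma_u2_max), length.out = 4096))
  logd <- -(q / 2) * log(grid) - S / (2 * grid)
  d <- exp(logd - max(logd))
  cdf <- c(0, cumsum((d[-1] + d[-length(d)]) / 2 * diff(grid)))
  cdf <- cdf / cdf[length(cdf)]
  u01 <- stats::runif(1)
  stats::approx(cdf, grid, xout = u01, ties = "ordered")$y
}

#' Multiplicative adaptation of proposal scales
#'
#' Robbins-Monro style update on the log scale:
#' \code{scale * exp(kappa * (acc_rate - target))} with gain
#' \code{kappa = 1/ceiling(batch)}, so adaptation diminishes over batches;
#' callers freeze adaptation after burn-in.
#'
#' @param scales List of proposal sds (\code{alpha}, \code{lambda},
#'   \code{beta}).
#' @param acc_rate Acceptance rate observed over the last batch.
#' @param target Target acceptance rate (default 0.2).
#' @param batch 1-based batch counter.
#' @return Updated scales list.
#' @export
adapt_proposal_scales <- function(scales, acc_rate, target = 0.2, batch = 1) {
  kappa <- 1 / ceiling(batch)
  fac <- exp(kappa * (acc_rate - target))
  lapply(scales, function(s) s * fac)
}

#' Identify and drop label-switched iterations from a trace
#'
#' The posterior has a mirror ("switch") mode in which the case/control roles
#' of the latent classes flip; it violates the identifiability constraint
#' alpha > lambda. Iterations with alpha < lambda are excluded from
#' misclassification-probability averaging.
#'
#' @param alpha,lambda Per-iteration parameter vectors (post burn-in).
#' @return List with \code{keep} (logical), \code{discarded} (count) and
#'   \code{usable} (FALSE when more than half the iterations are discarded).
#' @export
detect_and_filter_label_switch <- function(alpha, lambda) {
  stopifnot(length(alpha) == length(lambda))
  keep <- alpha >= lambda
  discarded <- sum(!keep)
  list(keep = keep, discarded = discarded,
       usable = discarded <= length(alpha) / 2)
}

#' Geweke convergence z-score
#'
#' Compares the means of the first and last fractions of a chain, with
#' standard errors from the spectral density at frequency zero (estimated by
#' an autoregressive fit). |z| < 1.96 indicates convergence.
#'
#' @param series Numeric chain segment (post burn-in), length >= 100.
#' @param first_frac Fraction forming the early window (default 0.1).
#' @param last_frac Fraction forming the late window (default 0.5).
#' @return z-score (NA for zero-variance series).
#' @export
geweke_z <- function(series, first_frac = 0.1, last_frac = 0.5) {
  n <- length(series)
  if (n < 100) stop("series too short for the Geweke diagnostic")
  s1 <- series[seq_len(floor(first_frac * n))]
  s2 <- series[(n - floor(last_frac * n) + 1L):n]
  if (stats::var(series) == 0) return(NA_real_)
  v1 <- spectrum0_ar(s1) / length(s1)
  v2 <- spectrum0_ar(s2) / length(s2)
  (mean(s1) - mean(s2)) / sqrt(v1 + v2)
}

# Spectral density at frequency zero via an AIC-selected AR fit.
spectrum0_ar <- function(x) {
  v <- stats::var(x)
  if (!is.finite(v) || v == 0) return(0)
  fit <- tryCatch(
    stats::ar(x, aic = TRUE, order.max = min(30L, floor(length(x) / 4))),
    error = function(e) NULL)
  if (is.null(fit) || length(fit$ar) == 0) return(v)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Run one MCMC chain of the misclassification model
#'
#' Per iteration: Metropolis update of (alpha, lambda, beta), Bernoulli
#' misclassification indicators, truncated-normal liability draws, the Gibbs
#' sweep over random effects, and the variance update. Post-burn-in
#' iterations satisfying the identifiability constraint alpha >= lambda
#' accumulate per-sample mark counts; the average misclassification
#' probability is marks divided by retained iterations.
#'
#' @param y Observed phenotype (0/1 vector or \code{phenotype_vector}).
#' @param X_train Training-SNP allele-count matrix (n x k_snp) or a
#'   \code{genotype_matrix} restricted to training SNPs.
#' @param A Optional \code{kinship_matrix} (required unless the mixed model
#'   is disabled).
#' @param priors A \code{prior_spec}.
#' @param config An \code{mcmc_config}.
#' @return Object of class \code{chain_trace}: per-iteration \code{alpha},
#'   \code{lambda}, \code{sigma_u2}, \code{log_post}, \code{accepted};
#'   thinned \code{beta} draws; \code{avg_prob} per sample;
#'   \code{mark_counts}; \code{denominator}; \code{discarded_switch};
#'   \code{acceptance_rate}; \code{geweke} per-parameter z-scores;
#'   \code{converged}; \code{usable}; final \code{scales}.
#' @export
run_chain <- function(y, X_train, A = NULL, priors = prior_spec(),
                      config = mcmc_config()) {
  if (inherits(y, "phenotype_vector")) y <- y$values
  if (inherits(X_train, "genotype_matrix")) X_train <- X_train$values
  X_train <- as.matrix(X_train)
  n <- length(y)
  stopifnot(nrow(X_train) == n)
  if (!is.null(config$seed)) set.seed(config$seed)
  if (config$center_genotypes) X_train <- scale(X_train, scale = FALSE)
  X <- if (config$intercept) add_intercept(X_train) else X_train
  k <- ncol(X)
  mixed <- !config$disable_mixed_model
  if (mixed) {
    if (is.null(A)) stop("kinship matrix required unless disable_mixed_model")
    if (!inherits(A, "kinship_matrix")) A <- kinship_matrix(A)
    A_inv <- A$inverse
  }

  state <- initialize_state(priors, n, k)
  if (!mixed) state$u <- rep(0, n)
  scales <- config$initial_scales
  log_post <- log_posterior(state, y, X, priors)

  n_iter <- config$n_iter; burn_in <- config$burn_in
  tr_alpha <- numeric(n_iter); tr_lambda <- numeric(n_iter)
  tr_sigma <- numeric(n_iter); tr_lp <- numeric(n_iter)
  tr_acc <- logical(n_iter)
  keep_idx <- seq(1L, n_iter, by = config$thin)
  tr_beta <- matrix(NA_real_, length(keep_idx), k)
  beta_row <- 0L
  mark_counts <- integer(n)
  denominator <- 0L
  discarded_switch <- 0L
  batch_acc <- 0L; batch <- 0L

  for (it in seq_len(n_iter)) {
    step <- mh_update_params(state, y, X, priors, scales, log_post)
    state <- step$params; log_post <- step$log_post
    tr_acc[it] <- step$accepted

    sigma <- probit_case_probability(X, state$beta, state$u)
    ind <- sample_misclassification_indicators(state, y, sigma)

    eta_fixed <- drop(X %*% state$beta)
    l <- sample_latent_liability(ind$y_latent, eta_fixed + state$u)
    if (mixed) {
      state$u <- gibbs_update_u(l, eta_fixed, state$u, A_inv, state$sigma_u2)
      state$sigma_u2 <- gibbs_update_sigma_u2(
        state$u, A_inv, priors$sigma_u2_max, current = state$sigma_u2)
      log_post <- log_posterior(state, y, X, priors)
    }
    if (!all(is.finite(state$u)) || !is.finite(state$sigma_u2)) {
      stop(sprintf("non-finite sampler state at iteration %d", it))
    }

    tr_alpha[it] <- state$alpha; tr_lambda[it] <- state$lambda
    tr_sigma[it] <- state$sigma_u2; tr_lp[it] <- log_post
    if ((it - 1L) %% config$thin == 0L) {
      beta_row <- beta_row + 1L
      tr_beta[beta_row, ] <- state$beta
    }

    if (it > burn_in) {
      if (state$alpha >= state$lambda) {
        mark_counts <- mark_counts + ind$marked
        denominator <- denominator + 1L
      } else {
        discarded_switch <- discarded_switch + 1L
      }
    } else {
      batch_acc <- batch_acc + step$accepted
      if (!config$disable_adaptation && it %% config$adapt_interval == 0L) {
        batch <- batch + 1L
        scales <- adapt_proposal_scales(
          scales, batch_acc / config$adapt_interval,
          config$target_acceptance, batch)
        batch_acc <- 0L
      }
    }
  }

  post <- (burn_in + 1L):n_iter
  gz <- function(x) if (length(x) >= 100) geweke_z(x) else NA_real_
  beta_post <- tr_beta[seq_len(beta_row), , drop = FALSE]
  beta_post <- beta_post[(seq_len(beta_row) - 1L) * config$thin + 1L > burn_in,
                         , drop = FALSE]
  geweke <- c(
    alpha = gz(tr_alpha[post]),
    lambda = gz(tr_lambda[post]),
    sigma_u2 = if (mixed) gz(tr_sigma[post]) else NA_real_,
    stats::setNames(apply(beta_post, 2, gz),
                    paste0("beta", seq_len(k)))
  )
  # convergence judged on the median |z| across parameter estimates; a
  # single slow-mixing variance component does not veto an otherwise
  # stationary chain
  converged <- is.finite(stats::median(abs(geweke), na.rm = TRUE)) &&
    stats::median(abs(geweke), na.rm = TRUE) < 1.96
  avg_prob <- if (denominator > 0) mark_counts / denominator else rep(NA_real_, n)

  structure(list(
    alpha = tr_alpha, lambda = tr_lambda, sigma_u2 = tr_sigma,
    log_post = tr_lp, accepted = tr_acc,
    beta = tr_beta[seq_len(beta_row), , drop = FALSE], beta_thin = config$thin,
    avg_prob = avg_prob, mark_counts = mark_counts, denominator = denominator,
    discarded_switch = discarded_switch,
    acceptance_rate = mean(tr_acc[post]),
    geweke = geweke, converged = converged,
    usable = denominator >= length(post) / 2,
    scales = scales, n_iter = n_iter, burn_in = burn_in
  ), class = "chain_trace")
}

#' @export
print.chain_trace <- function(x, ...) {
  cat(sprintf(
    "chain_trace: %d iterations (%d burn-in), acceptance %.2f, %d switch-mode iterations discarded\n",
    x$n_iter, x$burn_in, x$acceptance_rate, x$discarded_switch))
  cat(sprintf("  posterior means: alpha %.3f, lambda %.3f; converged: %s\n",
              mean(x$alpha[(x$burn_in + 1):x$n_iter]),
              mean(x$lambda[(x$burn_in + 1):x$n_iter]),
              x$converged))
  invisible(x)
}

#' Aggregate chains/runs and flag misclassified cases
#'
#' Averages per-sample misclassification probabilities across usable runs,
#' takes the configured percentile of the case probabilities as the
#' threshold t, and flags cases strictly above it.
#'
#' @param runs A single \code{chain_trace}, a list of them, or a list of
#'   numeric probability vectors.
#' @param y Observed phenotype (0/1 vector or \code{phenotype_vector}).
#' @param t_percentile Percentile level in (0, 100) (default 99).
#' @param pooled When TRUE the threshold is the percentile of the pooled
#'   per-run case probabilities rather than of the per-sample means.
#' @return Object of class \code{misclassification_result} with
#'   \code{avg_prob}, \code{flagged}, \code{threshold_value},
#'   \code{chains_used}.
#' @export
aggregate_and_flag <- function(runs, y, t_percentile = 99, pooled = FALSE) {
  if (inherits(y, "phenotype_vector")) y <- y$values
  if (inherits(runs, "chain_trace")) runs <- list(runs)
  probs <- lapply(runs, function(r) {
    if (inherits(r, "chain_trace")) {
      if (!isTRUE(r$usable) || !isTRUE(r$converged)) return(NULL)
      r$avg_prob
    } else {
      as.numeric(r)
    }
  })
  probs <- Filter(function(p) !is.null(p) && !anyNA(p), probs)
  if (length(probs) == 0) {
    stop("no usable converged chains; run more chains and keep those that converge")
  }
  pm <- do.call(rbind, probs)
  stopifnot(ncol(pm) == length(y))
  avg_prob <- colMeans(pm)
  is_case <- y == 1L
  threshold <- if (pooled) {
    stats::quantile(as.vector(pm[, is_case, drop = FALSE]),
                    t_percentile / 100, names = FALSE)
  } else {
    stats::quantile(avg_prob[is_case], t_percentile / 100, names = FALSE)
  }
  flagged <- is_case & avg_prob > threshold
  structure(list(avg_prob = avg_prob, flagged = flagged,
                 threshold_value = threshold, chains_used = length(probs),
                 t_percentile = t_percentile),
            class = "misclassification_result")
}

#' @export
print.misclassification_result <- function(x, ...) {
  cat(sprintf(
    "misclassification_result: %d samples, %d flagged (t = %gth percentile -> %.4f, %d run(s))\n",
    length(x$avg_prob), sum(x$flagged), x$t_percentile, x$threshold_value,
    x$chains_used))
  invisible(x)
}

#' Switch flagged cases to controls
#'
#' @param y Observed phenotype (0/1 vector or \code{phenotype_vector}).
#' @param flags Logical vector; TRUE entries must be cases.
#' @return Corrected phenotype of the same type as the input.
#' @export
correct_phenotype <- function(y, flags) {
  pv <- inherits(y, "phenotype_vector")
  vals <- if (pv) y$values else as.integer(y)
  stopifnot(length(flags) == length(vals))
  if (any(flags & vals == 0L)) {
    stop("flags on controls: only cases may be switched in this pipeline")
  }
  corrected <- vals
  corrected[flags] <- 0L
  if (pv) phenotype_vector(corrected, y$sample_ids) else corrected
}

#' Run several chains and aggregate
#'
#' @inheritParams run_chain
#' @param n_runs Number of chains; defaults to \code{config$n_chains}.
#' @param seeds Optional per-chain seeds (derived from \code{config$seed}
#'   when absent).
#' @return List with \code{chains} and the aggregated
#'   \code{misclassification_result}.
#' @export
run_misclassification_model <- function(y, X_train, A = NULL,
                                        priors = prior_spec(),
                                        config = mcmc_config(),
                                        n_runs = config$n_chains,
                                        seeds = NULL) {
  if (is.null(seeds)) {
    base <- if (is.null(config$seed)) {
      sample.int(.Machine$integer.max, 1)
    } else {
      config$seed
    }
    seeds <- (base + seq_len(n_runs) * 10007L) %% .Machine$integer.max
  }
  chains <- lapply(seq_len(n_runs), function(i) {
    cfg <- config; cfg$seed <- seeds[i]
    run_chain(y, X_train, A, priors, cfg)
  })
  result <- aggregate_and_flag(chains, y, config$t_percentile)
  list(chains = chains, result = result)
}

#' Export a thinned parameter trace as a data frame
#' @param trace A \code{chain_trace}.
#' @param thin Thinning interval (default the trace's stored interval).
#' @return data.frame with iteration, alpha, lambda, sigma_u2, log_post,
#'   accepted.
#' @export
trace_as_data_frame <- function(trace, thin = trace$beta_thin) {
  idx <- seq(1L, trace$n_iter, by = thin)
  data.frame(iteration = idx, alpha = trace$alpha[idx],
             lambda = trace$lambda[idx], sigma_u2 = trace$sigma_u2[idx],
             log_post = trace$log_post[idx], accepted = trace$accepted[idx])
}
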