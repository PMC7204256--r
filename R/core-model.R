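# Probability kernel of the misclassification model: probit mixed-model case
# probabilities, the observed-data mixture likelihood, and the per-sample
# misclassification posteriors used to mark samples at each MCMC iteration.

SIGMA_CLIP <- 1e-10

clip_prob <- function(p) pmin(pmax(p, SIGMA_CLIP), 1 - SIGMA_CLIP)

#' Probit case probabilities under the mixed model
#'
#' Computes \eqn{\sigma_i = \Phi(X_i \beta + u_i)} for each sample, the
#' probability of being a true case given SNP effects and random effects. The
#' unit-variance liability noise is absorbed by the standard normal CDF.
#'
#' @param X Numeric matrix of training-SNP allele counts (n x k), already
#'   including an intercept column if the model uses one.
#' @param beta Effect vector of length k.
#' @param u Random-effect vector of length n.
#' @return Vector of n probabilities, clipped to the open unit interval.
#' @export
probit_case_probability <- function(X, beta, u) {
  X <- as.matrix(X)
  if (ncol(X) != length(beta)) {
    stop(sprintf("dimension mismatch: %d SNP columns vs %d effects",
                 ncol(X), length(beta)))
  }
  if (nrow(X) != length(u)) {
    stop(sprintf("dimension mismatch: %d samples vs %d random effects",
                 nrow(X), length(u)))
  }
  if (!all(is.finite(X)) || !all(is.finite(beta)) || !all(is.finite(u))) {
    stop("non-finite inputs to probit_case_probability")
  }
  clip_prob(stats::pnorm(drop(X %*% beta) + u))
}

#' Posterior probability that an observed case is truly a control
#'
#' Bayes posterior \eqn{P(Y' = 0 \mid Y = 1)} given the recording rates and
#' the genetic case probability:
#' \deqn{\frac{\lambda (1-\sigma)}{\lambda (1-\sigma) + \alpha \sigma}
#'   = \frac{1}{1 + \alpha\sigma / (\lambda (1-\sigma))}.}
#'
#' @param alpha True-positive recording rate.
#' @param lambda False-positive recording rate.
#' @param sigma Genetic case probability (vectorized).
#' @return Misclassification probability for an observed case.
#' @export
case_misclassification_probability <- function(alpha, lambda, sigma) {
  if (lambda <= 0) return(rep(0, length(sigma)))
  if (alpha <= 0) return(rep(1, length(sigma)))
  sigma <- clip_prob(sigma)
  1 / (1 + (alpha * sigma) / (lambda * (1 - sigma)))
}

#' Posterior probability that an observed control is truly a case
#'
#' Bayes posterior \eqn{P(Y' = 1 \mid Y = 0)}:
#' \deqn{\frac{1}{1 + (1-\lambda)(1-\sigma) / ((1-\alpha)\sigma)}.}
#'
#' @inheritParams case_misclassification_probability
#' @return Misclassification probability for an observed control.
#' @export
control_misclassification_probability <- function(alpha, lambda, sigma) {
  if (alpha >= 1) return(rep(0, length(sigma)))
  if (lambda >= 1) return(rep(1, length(sigma)))
  sigma <- clip_prob(sigma)
  1 / (1 + ((1 - lambda) * (1 - sigma)) / ((1 - alpha) * sigma))
}

#' Observed-data log-likelihood of the misclassification mixture
#'
#' Sums, over samples, the log of the case mixture
#' \eqn{\lambda(1-\sigma_i) + \alpha\sigma_i} for observed cases and of the
#' control mixture \eqn{(1-\lambda)(1-\sigma_i) + (1-\alpha)\sigma_i} for
#' observed controls.
#'
#' @param y 0/1 observed phenotype vector (or a \code{phenotype_vector}).
#' @param sigma Genetic case probabilities per sample.
#' @param alpha,lambda Recording rates.
#' @return Log-likelihood scalar.
#' @export
log_likelihood_observed <- function(y, sigma, alpha, lambda) {
  if (inherits(y, "phenotype_vector")) y <- y$values
  stopifnot(length(y) == length(sigma))
  sigma <- clip_prob(sigma)
  p_case <- lambda * (1 - sigma) + alpha * sigma
  p_ctrl <- (1 - lambda) * (1 - sigma) + (1 - alpha) * sigma
  if (any(p_case <= 0) || any(p_ctrl <= 0)) {
    stop("non-positive mixture probability in observed-data likelihood")
  }
  sum(y * log(p_case) + (1 - y) * log(p_ctrl))
}

#' Unnormalized log-posterior of the misclassification model
#'
#' Observed-data log-likelihood plus log Beta prior densities for the
#' recording rates, log Normal densities for the effects, and the flat
#' truncated prior on the random-effect variance (0 inside its support,
#' \code{-Inf} outside). The random-effect prior term
#' \eqn{\log P(u \mid \sigma_u^2)} can be included via \code{include_u_prior};
#' the Metropolis block for (alpha, lambda, beta) omits it because it is
#' constant in those parameters.
#'
#' @param params A \code{model_params} state.
#' @param y Observed 0/1 phenotype.
#' @param X Training design matrix (n x k, intercept included if used).
#' @param priors A \code{prior_spec}.
#' @param A_inv Kinship inverse (needed only when \code{include_u_prior}).
#' @param include_u_prior Add the MVN log-density of u given sigma_u2.
#' @return Unnormalized log-posterior; \code{-Inf} for states outside the
#'   parameter support.
#' @export
log_posterior <- function(params, y, X, priors, A_inv = NULL,
                          include_u_prior = FALSE) {
  if (inherits(y, "phenotype_vector")) y <- y$values
  a <- params$alpha; l <- params$lambda
  if (a <= 0 || a >= 1 || l <= 0 || l >= 1) return(-Inf)
  if (params$sigma_u2 <= 0 || params$sigma_u2 > priors$sigma_u2_max) {
    return(-Inf)
  }
  sigma <- probit_case_probability(X, params$beta, params$u)
  lp <- log_likelihood_observed(y, sigma, a, l) +
    stats::dbeta(a, priors$alpha_shape[1], priors$alpha_shape[2], log = TRUE) +
    stats::dbeta(l, priors$lambda_shape[1], priors$lambda_shape[2], log = TRUE) +
    sum(stats::dnorm(params$beta, priors$beta_mean, priors$beta_sd, log = TRUE))
  if (include_u_prior) {
    if (is.null(A_inv)) stop("A_inv required when include_u_prior = TRUE")
    n <- length(params$u)
    quad <- drop(crossprod(params$u, A_inv %*% params$u))
    lp <- lp - n / 2 * log(params$sigma_u2) - quad / (2 * params$sigma_u2)
  }
  lp
}

#' Prepend an intercept column to a training design matrix
#' @param X Numeric matrix of training-SNP counts.
#' @return Matrix with a leading column of ones.
#' @keywords internal
add_intercept <- function(X) {
  cbind(intercept = 1, as.matrix(X))
}
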