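# Liability-threshold case/control simulator with kinship-structured random
# effects and differential misclassification injection. Two designs are
# supported: a structure-free design (balanced cases/controls, large fixed
# effects) and a structured design (kinship random effects, MAF-dependent
# effect sizes, case/control sampling from a larger population).

#' Simulation configuration
#'
#' Defaults reproduce the structured design: a 10,000-sample population of
#' 100,000 independent HWE SNPs with MAF ~ U(0, 0.5), 300 causal SNPs with
#' effects \eqn{\beta_j \sim N(0, \sigma_g^2 [2f_j(1-f_j)]^a)}
#' (\eqn{\sigma_g^2 = 0.1}, \eqn{a = -0.38}), random effects
#' \eqn{u \sim MVN(0, \sigma_u^2 A)} with \eqn{\sigma_u^2 = 2}, disease
#' prevalence drawn from (0.1, 0.5), and a 1000-case / 3000-control study
#' sample. The structure-free design (\code{strategy = 1}) uses 2000 samples,
#' 10,000 SNPs with MAF from \{0.1, 0.2, 0.4\}, 30 causal SNPs with
#' \eqn{\beta \sim N(2, 0.3)}, no random effects, and a balanced
#' 1000/1000 split at the liability median.
#'
#' @param strategy 1 (structure-free) or 2 (kinship-structured).
#' @param n_population Population size before case/control sampling.
#' @param m_snps Number of independent SNPs.
#' @param n_causal Number of causal SNPs.
#' @param sigma_u2_true Random-effect variance (strategy 2 only).
#' @param sigma_g2,maf_exponent Effect-size model parameters (strategy 2).
#' @param effect_mean,effect_var Effect-size model (strategy 1).
#' @param prevalence_range Uniform range the per-replicate prevalence is
#'   drawn from (strategy 2).
#' @param n_cases,n_controls Study-sample class sizes.
#' @param misclassification_fraction Fraction of controls switched to cases.
#' @param maf_set Discrete MAF support for strategy 1.
#' @param maf_range Continuous MAF range for strategy 2.
#' @return Object of class \code{simulation_config}.
#' @export
simulation_config <- function(strategy = 2,
                              n_population = if (strategy == 1) 2000 else 10000,
                              m_snps = if (strategy == 1) 10000 else 100000,
                              n_causal = if (strategy == 1) 30 else 300,
                              sigma_u2_true = 2, sigma_g2 = 0.1,
                              maf_exponent = -0.38,
                              effect_mean = 2, effect_var = 0.3,
                              prevalence_range = c(0.1, 0.5),
                              n_cases = 1000,
                              n_controls = if (strategy == 1) 1000 else 3000,
                              misclassification_fraction = 0.1,
                              maf_set = c(0.1, 0.2, 0.4),
                              maf_range = c(0, 0.5)) {
  stopifnot(strategy %in% c(1, 2), n_causal <= m_snps,
            misclassification_fraction >= 0, misclassification_fraction < 1,
            all(prevalence_range > 0), all(prevalence_range < 1))
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate independent HWE genotypes
#'
#' Each SNP draws an allele frequency from the configured model, then n
#' genotypes i.i.d. Binomial(2, f): Hardy-Weinberg proportions, no LD.
#' Monomorphic columns are redrawn so every SNP is polymorphic.
#'
#' @param n Samples.
#' @param m SNPs.
#' @param maf_model \code{"discrete"} (uniform over \code{maf_set}) or
#'   \code{"uniform"} (over \code{maf_range}).
#' @param maf_set,maf_range Frequency models (see
#'   \code{\link{simulation_config}}).
#' @return A \code{genotype_matrix} (its \code{maf} slot holds realized
#'   sample frequencies; drawn frequencies are in \code{attr(,"maf_drawn")}).
#' @export
simulate_genotypes <- function(n, m, maf_model = c("uniform", "discrete"),
                               maf_set = c(0.1, 0.2, 0.4),
                               maf_range = c(0, 0.5)) {
  maf_model <- match.arg(maf_model)
  f <- if (maf_model == "discrete") {
    sample(maf_set, m, replace = TRUE)
  } else {
    stats::runif(m, maf_range[1], maf_range[2])
  }
  draw <- function(fj) stats::rbinom(n, 2L, fj)
  vals <- vapply(f, draw, integer(n))
  mono <- which(apply(vals, 2, function(x) all(x == x[1])))
  while (length(mono) > 0) {
    for (j in mono) {
      if (maf_model == "uniform") f[j] <- stats::runif(1, 0.05, maf_range[2])
      vals[, j] <- draw(f[j])
    }
    mono <- mono[apply(vals[, mono, drop = FALSE], 2,
                       function(x) all(x == x[1]))]
  }
  g <- genotype_matrix(vals)
  attr(g, "maf_drawn") <- f
  g
}

#' Draw causal-SNP effect sizes
#'
#' Strategy 1: i.i.d. \eqn{N(\mu, \sigma^2)} with mean 2 and variance 0.3.
#' Strategy 2: \eqn{\beta_j \sim N(0, \sigma_g^2 [2 f_j (1-f_j)]^{a})} with
#' a negative exponent, so rarer alleles receive larger effects.
#'
#' @param config A \code{simulation_config}.
#' @param maf_causal Allele frequencies of the causal SNPs (strategy 2).
#' @return Numeric effect vector.
#' @export
draw_effect_sizes <- function(config, maf_causal = NULL) {
  if (config$strategy == 1) {
    stats::rnorm(config$n_causal, config$effect_mean,
                 sqrt(config$effect_var))
  } else {
    stopifnot(!is.null(maf_causal), all(maf_causal > 0))
    sd_j <- sqrt(config$sigma_g2 *
                   (2 * maf_causal * (1 - maf_causal))^config$maf_exponent)
    stats::rnorm(length(maf_causal), 0, sd_j)
  }
}

#' Simulate kinship-structured random effects
#'
#' \eqn{u \sim MVN(0, \sigma_u^2 A)} drawn through the Cholesky factor of
#' the (jittered) relatedness matrix.
#'
#' @param A A \code{kinship_matrix}.
#' @param sigma_u2 Random-effect variance (default 2).
#' @return Random-effect vector.
#' @export
simulate_random_effects <- function(A, sigma_u2 = 2) {
  stopifnot(inherits(A, "kinship_matrix"))
  n <- nrow(A$values)
  L <- t(chol(A$values))
  sqrt(sigma_u2) * drop(L %*% stats::rnorm(n))
}

#' Threshold liabilities into a binary population phenotype
#'
#' Liability \eqn{L_i = X_i\beta + u_i + \epsilon_i} with unit-normal noise;
#' cases are samples whose liability exceeds the empirical
#' \eqn{(1 - prevalence)} quantile, so the realized prevalence matches the
#' target exactly up to rounding. \code{prevalence = 0.5} reproduces the
#' balanced median split of the structure-free design.
#'
#' @param X_causal Causal-SNP allele-count matrix (n x n_causal).
#' @param beta_true Causal effects.
#' @param u_true Random effects (zeros for the structure-free design).
#' @param prevalence Target case fraction.
#' @return List with \code{y_true} (0/1), \code{liability}, \code{epsilon},
#'   \code{threshold}.
#' @export
simulate_population_phenotype <- function(X_causal, beta_true, u_true,
                                          prevalence) {
  X_causal <- as.matrix(X_causal)
  n <- nrow(X_causal)
  stopifnot(length(u_true) == n, prevalence > 0, prevalence < 1)
  eps <- stats::rnorm(n)
  liab <- drop(X_causal %*% beta_true) + u_true + eps
  if (stats::sd(liab) == 0) stop("degenerate liabilities: all equal")
  thr <- stats::quantile(liab, 1 - prevalence, names = FALSE)
  list(y_true = as.integer(liab > thr), liability = liab, epsilon = eps,
       threshold = thr)
}

#' Sample a case/control study from the population
#'
#' Uniform sampling without replacement within each class; returns row
#' indices into the population so genotypes, random effects and liabilities
#' subset consistently.
#'
#' @param y_true Population 0/1 phenotype.
#' @param n_cases,n_controls Study class sizes.
#' @return Integer index vector (cases first, then controls).
#' @export
sample_case_control <- function(y_true, n_cases, n_controls) {
  cases <- which(y_true == 1L)
  controls <- which(y_true == 0L)
  if (length(cases) < n_cases || length(controls) < n_controls) {
    stop(sprintf(
      "population has %d cases / %d controls (prevalence %.3f); need %d / %d",
      length(cases), length(controls), mean(y_true), n_cases, n_controls))
  }
  c(sample(cases, n_cases), sample(controls, n_controls))
}

#' Inject differential misclassification
#'
#' Switches exactly \code{round(fraction * #controls)} randomly selected
#' controls to cases; cases are never flipped (false-positive-only design).
#'
#' @param y_true Study 0/1 phenotype.
#' @param fraction Fraction of controls to switch.
#' @return List with \code{y_observed} and logical \code{mask} of switched
#'   samples.
#' @export
inject_misclassification <- function(y_true, fraction) {
  if (fraction >= 1) stop("misclassification fraction must be below 1")
  controls <- which(y_true == 0L)
  n_flip <- round(fraction * length(controls))
  if (fraction > 0 && n_flip < 1) {
    stop("fraction too small: no control would be switched")
  }
  mask <- rep(FALSE, length(y_true))
  if (n_flip > 0) mask[sample(controls, n_flip)] <- TRUE
  y_obs <- y_true
  y_obs[mask] <- 1L
  list(y_observed = y_obs, mask = mask)
}

#' Per-SNP variance explained and realized heritability
#'
#' Per causal SNP l: \eqn{Var(X_l \beta_l) / Var(\sum_j X_j \beta_j + u +
#' \epsilon)} using empirical variances. Heritability is reported under two
#' numerators — genetic fixed effects only, and fixed plus random effects —
#' since either convention appears in the field.
#'
#' @param X_causal Causal-SNP allele counts.
#' @param beta_true Causal effects.
#' @param u_true Random effects.
#' @param eps Realized liability noise.
#' @return List with \code{per_snp} fractions, \code{h2_snp} and
#'   \code{h2_snp_plus_u}.
#' @export
variance_explained <- function(X_causal, beta_true, u_true, eps) {
  X_causal <- as.matrix(X_causal)
  genetic <- drop(X_causal %*% beta_true)
  total <- genetic + u_true + eps
  vt <- stats::var(total)
  if (vt == 0) stop("zero total liability variance")
  per_snp <- vapply(seq_along(beta_true), function(l) {
    stats::var(X_causal[, l] * beta_true[l]) / vt
  }, numeric(1))
  list(per_snp = per_snp,
       h2_snp = stats::var(genetic) / vt,
       h2_snp_plus_u = stats::var(genetic + u_true) / vt)
}

#' Simulate the shared population layer of a study
#'
#' Draws the population genotypes, the causal-SNP set and — for the
#' structured design — the GRM and one random-effect vector. These are held
#' fixed across phenotype replicates: each replicate redraws effect sizes,
#' liability noise, prevalence, case/control sampling and misclassification,
#' while the genotypes, causal set and random effects are shared.
#'
#' @param config A \code{simulation_config}.
#' @return Object of class \code{simulated_population}: \code{X_pop},
#'   \code{causal_indices}, \code{u_population}, \code{A} (structured design
#'   only), \code{config}.
#' @export
simulate_population <- function(config) {
  X_pop <- simulate_genotypes(
    config$n_population, config$m_snps,
    maf_model = if (config$strategy == 1) "discrete" else "uniform",
    maf_set = config$maf_set, maf_range = config$maf_range)
  causal <- sort(sample(config$m_snps, config$n_causal))
  A <- NULL
  if (config$strategy == 2) {
    A <- compute_grm(X_pop, maf_min = 0.05)
    u_population <- simulate_random_effects(A, config$sigma_u2_true)
  } else {
    u_population <- rep(0, config$n_population)
  }
  structure(list(X_pop = X_pop, causal_indices = causal,
                 u_population = u_population, A = A, config = config),
            class = "simulated_population")
}

#' Simulate one phenotype replicate from a population
#'
#' Draws fresh effect sizes, liabilities and prevalence, thresholds into a
#' population phenotype, samples the case/control study and injects
#' differential misclassification.
#'
#' @param population A \code{simulated_population}.
#' @param misclassification_fraction Overrides the configured fraction when
#'   given.
#' @return Object of class \code{simulated_dataset}: \code{X}
#'   (\code{genotype_matrix} of the study sample), \code{y_true},
#'   \code{y_observed} (\code{phenotype_vector}s), \code{causal_indices},
#'   \code{beta_true}, \code{u_true}, \code{misclassified_mask},
#'   \code{realized_prevalence}, \code{variance} (per-SNP fractions and two
#'   heritability summaries), \code{prevalence_target}.
#' @export
simulate_replicate <- function(population,
                               misclassification_fraction = NULL) {
  stopifnot(inherits(population, "simulated_population"))
  config <- population$config
  if (is.null(misclassification_fraction)) {
    misclassification_fraction <- config$misclassification_fraction
  }
  X_pop <- population$X_pop
  causal <- population$causal_indices
  u_population <- population$u_population
  beta_true <- draw_effect_sizes(config, X_pop$maf[causal])
  prevalence <- if (config$strategy == 2) {
    stats::runif(1, config$prevalence_range[1], config$prevalence_range[2])
  } else {
    0.5  # balanced design: median split
  }

  X_causal <- X_pop$values[, causal, drop = FALSE]
  pop <- simulate_population_phenotype(X_causal, beta_true, u_population,
                                       prevalence)
  idx <- sample_case_control(pop$y_true, config$n_cases, config$n_controls)

  X <- subset_genotypes(X_pop, samples = idx)
  y_true <- pop$y_true[idx]
  mis <- inject_misclassification(y_true, misclassification_fraction)
  vexp <- variance_explained(X_causal, beta_true, u_population, pop$epsilon)

  structure(list(
    X = X,
    y_true = phenotype_vector(y_true),
    y_observed = phenotype_vector(mis$y_observed),
    causal_indices = causal,
    beta_true = beta_true,
    u_true = u_population[idx],
    misclassified_mask = mis$mask,
    realized_prevalence = mean(pop$y_true),
    prevalence_target = prevalence,
    variance = vexp,
    config = config
  ), class = "simulated_dataset")
}

#' Simulate one complete study (population plus one replicate)
#'
#' Convenience wrapper: \code{\link{simulate_population}} followed by one
#' \code{\link{simulate_replicate}}.
#'
#' @param config A \code{simulation_config}.
#' @return A \code{simulated_dataset}.
#' @export
simulate_study <- function(config) {
  simulate_replicate(simulate_population(config))
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(
    "simulated_dataset: %d samples x %d SNPs, %d causal, %d misclassified (h2 %.2f / %.2f)\n",
    nrow(x$X$values), ncol(x$X$values), length(x$causal_indices),
    sum(x$misclassified_mask), x$variance$h2_snp, x$variance$h2_snp_plus_u))
  invisible(x)
}
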