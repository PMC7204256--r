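#' Construct a genotype matrix object
#'
#' Wraps an n x m allele-count matrix (0/1/2 coding, no missing values) with
#' per-SNP metadata: identifier, chromosome, 1-based base-pair position and
#' minor-allele frequency.
#'
#' @param values Integer-valued n x m matrix with entries in \{0, 1, 2\};
#'   rows are samples, columns are SNPs.
#' @param snp_ids Character vector of m SNP identifiers. Defaults to
#'   \code{"snp1"..."snpm"}.
#' @param chrom Chromosome label per SNP (default all \code{"1"}).
#' @param pos 1-based base-pair position per SNP (default \code{1:m}).
#' @param maf Minor-allele frequencies; computed from \code{values} when
#'   omitted and cross-checked against it when supplied.
#' @return An object of class \code{genotype_matrix}: a list with elements
#'   \code{values}, \code{snp_ids}, \code{chrom}, \code{pos}, \code{maf}.
#' @export
genotype_matrix <- function(values, snp_ids = NULL, chrom = NULL, pos = NULL,
                            maf = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 2L || ncol(values) < 1L) {
    stop("genotype matrix needs n >= 2 samples and m >= 1 SNPs")
  }
  if (anyNA(values) || !all(values %in% c(0, 1, 2))) {
    stop("genotype values must be in {0, 1, 2} with no missing entries")
  }
  m <- ncol(values)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(m))
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m)
  computed_maf <- allele_frequency(values)
  if (is.null(maf)) {
    maf <- computed_maf
  } else if (max(abs(maf - computed_maf)) > 1e-12) {
    stop("stored maf disagrees with maf computed from genotype values")
  }
  stopifnot(length(snp_ids) == m, length(chrom) == m, length(pos) == m,
            length(maf) == m)
  structure(
    list(values = values, snp_ids = as.character(snp_ids),
         chrom = as.character(chrom), pos = as.integer(pos), maf = maf),
    class = "genotype_matrix"
  )
}

#' Minor-allele frequency of each column of an allele-count matrix
#' @param values n x m matrix of 0/1/2 allele counts.
#' @return Numeric vector of m frequencies between 0 and 0.5.
#' @export
allele_frequency <- function(values) {
  f <- colMeans(values) / 2
  pmin(f, 1 - f)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (MAF %.3f-%.3f)\n",
              nrow(x$values), ncol(x$values), min(x$maf), max(x$maf)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Subset a genotype matrix by sample rows and/or SNP columns
#' @param x A \code{genotype_matrix}.
#' @param samples Row index vector (optional).
#' @param snps Column index vector (optional).
#' @return A \code{genotype_matrix} over the selected rows/columns.
#' @export
subset_genotypes <- function(x, samples = NULL, snps = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.null(samples)) samples <- seq_len(nrow(x$values))
  if (is.null(snps)) snps <- seq_len(ncol(x$values))
  genotype_matrix(x$values[samples, snps, drop = FALSE],
                  snp_ids = x$snp_ids[snps], chrom = x$chrom[snps],
                  pos = x$pos[snps])
}

#' Construct a binary phenotype vector
#'
#' @param values 0/1 vector (1 = case, 0 = control).
#' @param sample_ids Sample identifiers (default \code{"s1"..."sn"}).
#' @return An object of class \code{phenotype_vector}.
#' @export
phenotype_vector <- function(values, sample_ids = NULL) {
  values <- as.integer(values)
  if (anyNA(values) || !all(values %in% c(0L, 1L))) {
    stop("phenotype values must be binary 0/1")
  }
  if (sum(values) == 0L || sum(values) == length(values)) {
    stop("phenotype must contain at least one case and one control")
  }
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_along(values))
  stopifnot(length(sample_ids) == length(values))
  structure(list(values = values, sample_ids = as.character(sample_ids)),
            class = "phenotype_vector")
}

#' @export
print.phenotype_vector <- function(x, ...) {
  cat(sprintf("phenotype_vector: %d samples (%d cases / %d controls)\n",
              length(x$values), sum(x$values), sum(1 - x$values)))
  invisible(x)
}

#' Construct a kinship (genetic relatedness) matrix object
#'
#' Validates symmetry, applies a small diagonal jitter so the matrix is
#' safely invertible, and caches its inverse for the Gibbs updates of the
#' random effects.
#'
#' @param values n x n symmetric relatedness matrix A.
#' @param jitter Diagonal augmentation relative to \code{mean(diag(A))}
#'   (default \code{1e-6}).
#' @return Object of class \code{kinship_matrix} with elements \code{values}
#'   (jittered A), \code{inverse} (its inverse), \code{jitter}.
#' @export
kinship_matrix <- function(values, jitter = 1e-6) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop("kinship matrix must be square")
  if (max(abs(values - t(values))) > 1e-8) {
    stop("kinship matrix must be symmetric (tolerance 1e-8)")
  }
  values <- (values + t(values)) / 2
  values <- values + diag(jitter * mean(diag(values)), n)
  if (any(diag(values) <= 0)) stop("kinship diagonal entries must be positive")
  ch <- tryCatch(chol(values), error = function(e) {
    stop("kinship matrix is not positive definite after jitter")
  })
  inv <- chol2inv(ch)
  structure(list(values = values, inverse = inv, jitter = jitter),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("kinship_matrix: %d x %d, mean diagonal %.3f\n",
              nrow(x$values), ncol(x$values), mean(diag(x$values))))
  invisible(x)
}

#' Prior specification for the misclassification model
#'
#' Defaults follow the informed-prior identifiability scheme: a Beta(10, 1)
#' prior on the true-positive recording rate alpha (strong prior belief that
#' true cases are recorded as cases), a flat Beta(1, 1) prior on the
#' false-positive rate lambda, independent N(0, 1) priors on SNP effects, and
#' a flat prior on the random-effect variance truncated at
#' \code{sigma_u2_max}.
#'
#' @param alpha_shape Beta shape pair for alpha (default \code{c(10, 1)}).
#' @param lambda_shape Beta shape pair for lambda (default \code{c(1, 1)}).
#' @param beta_mean,beta_sd Normal prior on each effect (default 0, 1).
#' @param sigma_u2_max Upper truncation of the flat variance prior
#'   (default 100).
#' @return Object of class \code{prior_spec}.
#' @export
prior_spec <- function(alpha_shape = c(10, 1), lambda_shape = c(1, 1),
                       beta_mean = 0, beta_sd = 1, sigma_u2_max = 100) {
  stopifnot(all(alpha_shape > 0), all(lambda_shape > 0), beta_sd > 0,
            sigma_u2_max > 0)
  structure(list(alpha_shape = alpha_shape, lambda_shape = lambda_shape,
                 beta_mean = beta_mean, beta_sd = beta_sd,
                 sigma_u2_max = sigma_u2_max),
            class = "prior_spec")
}

#' One MCMC parameter state of the misclassification model
#'
#' @param alpha True-positive recording rate P(Y = 1 | Y' = 1), in (0, 1).
#' @param lambda False-positive recording rate P(Y = 1 | Y' = 0), in (0, 1).
#' @param beta Effect vector over training SNPs (leading intercept optional).
#' @param u Random-effect vector (one entry per sample).
#' @param sigma_u2 Random-effect variance, in (0, sigma_u2_max].
#' @return Object of class \code{model_params}.
#' @export
model_params <- function(alpha, lambda, beta, u, sigma_u2) {
  stopifnot(alpha > 0, alpha < 1, lambda > 0, lambda < 1, sigma_u2 > 0)
  structure(list(alpha = alpha, lambda = lambda, beta = as.numeric(beta),
                 u = as.numeric(u), sigma_u2 = sigma_u2),
            class = "model_params")
}
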