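# GWAS-side utilities: genomic relatedness matrix, EMMAX-style linear
# mixed-model association scan, multiple-testing helpers, training-SNP
# selection, LD r^2 / pruning, and post-correction discovery identification.

#' Genomic relatedness matrix from standardized genotypes
#'
#' \eqn{A = Z Z^\top / m^*} over SNPs with MAF above the cutoff, where Z has
#' columns \eqn{(x - 2f)/\sqrt{2f(1-f)}}. The mean diagonal is approximately
#' 1.
#'
#' @param X A \code{genotype_matrix} or plain allele-count matrix.
#' @param maf_min Minimum minor-allele frequency (default 0.05).
#' @return A \code{kinship_matrix}.
#' @export
compute_grm <- function(X, maf_min = 0.05) {
  vals <- if (inherits(X, "genotype_matrix")) X$values else as.matrix(X)
  f <- colMeans(vals) / 2
  maf <- pmin(f, 1 - f)
  keep <- maf > maf_min
  if (sum(keep) < 2) {
    stop("fewer than 2 SNPs pass the MAF filter; cannot form a GRM")
  }
  vals <- vals[, keep, drop = FALSE]
  f <- f[keep]
  Z <- sweep(vals, 2, 2 * f, "-")
  Z <- sweep(Z, 2, sqrt(2 * f * (1 - f)), "/")
  kinship_matrix(tcrossprod(Z) / ncol(Z))
}

#' Linear mixed-model association scan (EMMAX-style)
#'
#' Fits variance components once on the null model by REML using the
#' eigendecomposition of the relatedness matrix, then tests each SNP by a
#' Wald test in the rotated (whitened) coordinates with the components held
#' fixed. The binary phenotype is analyzed on the quantitative scale.
#'
#' @param y Phenotype (0/1 vector or \code{phenotype_vector}); analyzed as
#'   quantitative.
#' @param X A \code{genotype_matrix} (or plain matrix) of SNPs to test.
#' @param A Optional \code{kinship_matrix}; identity (ordinary regression)
#'   when NULL.
#' @param covariates Optional numeric matrix of fixed covariates.
#' @return data.frame with snp_id, chrom, pos, maf, beta, se, p.
#' @export
lmm_association <- function(y, X, A = NULL, covariates = NULL) {
  if (inherits(y, "phenotype_vector")) y <- y$values
  gm <- inherits(X, "genotype_matrix")
  vals <- if (gm) X$values else as.matrix(X)
  n <- length(y)
  stopifnot(nrow(vals) == n)
  C <- cbind(intercept = rep(1, n), covariates)
  if (qr(C)$rank < ncol(C)) {
    bad <- colnames(C)[qr(C)$pivot[-seq_len(qr(C)$rank)]]
    stop(sprintf("singular covariate design (collinear: %s)",
                 paste(bad, collapse = ", ")))
  }

  if (is.null(A)) {
    d <- rep(1, n)
    yt <- y; Ct <- C; Gt <- vals
    w <- rep(1, n)
  } else {
    if (!inherits(A, "kinship_matrix")) A <- kinship_matrix(A)
    eig <- eigen(A$values, symmetric = TRUE)
    U <- eig$vectors; d <- pmax(eig$values, 1e-10)
    yt <- drop(crossprod(U, y))
    Ct <- crossprod(U, C)
    Gt <- crossprod(U, vals)
    delta <- reml_delta(yt, Ct, d)
    w <- 1 / (d + delta)
  }

  # weighted regression of each SNP with the null covariates; the SNP column
  # is residualized against the covariates in the whitened metric
  sw <- sqrt(w)
  yw <- yt * sw
  Cw <- Ct * sw
  Gw <- Gt * sw
  qrC <- qr(Cw)
  y_res <- qr.resid(qrC, yw)
  G_res <- qr.resid(qrC, Gw)
  gss <- colSums(G_res^2)
  gss[gss < 1e-12] <- NA_real_  # monomorphic after projection
  beta <- colSums(G_res * y_res) / gss
  df <- n - ncol(Cw) - 1L
  rss <- sum(y_res^2) - beta^2 * gss
  sigma2 <- rss / df
  se <- sqrt(sigma2 / gss)
  p <- 2 * stats::pnorm(-abs(beta / se))
  p[is.na(p)] <- 1
  data.frame(
    snp_id = if (gm) X$snp_ids else paste0("snp", seq_len(ncol(vals))),
    chrom = if (gm) X$chrom else rep("1", ncol(vals)),
    pos = if (gm) X$pos else seq_len(ncol(vals)),
    maf = if (gm) X$maf else allele_frequency(vals),
    beta = beta, se = se, p = p,
    stringsAsFactors = FALSE
  )
}

# REML profile over delta = sigma_e^2 / sigma_g^2 in the eigenbasis of A.
reml_delta <- function(yt, Ct, d, lower = 1e-5, upper = 1e5) {
  n <- length(yt); pC <- ncol(Ct)
  negloglik <- function(log_delta) {
    delta <- exp(log_delta)
    w <- 1 / (d + delta)
    sw <- sqrt(w)
    Cw <- Ct * sw; yw <- yt * sw
    qrC <- qr(Cw)
    res <- qr.resid(qrC, yw)
    rss <- sum(res^2)
    ldV <- sum(log(d + delta))
    ldC <- 2 * sum(log(abs(diag(qr.R(qrC)))))
    # standard REML profile (variance scale profiled out)
    ((n - pC) * log(rss) + ldV + ldC) / 2
  }
  opt <- stats::optimize(negloglik, c(log(lower), log(upper)))
  exp(opt$minimum)
}

#' Bonferroni family-wise threshold
#' @param m Number of tests.
#' @param family_alpha Family-wise error rate (default 0.05).
#' @return Per-test threshold \code{family_alpha / m}.
#' @export
bonferroni_threshold <- function(m, family_alpha = 0.05) {
  stopifnot(m >= 1)
  family_alpha / m
}

#' Benjamini-Hochberg step-up adjustment
#' @param p Vector of p-values in (0, 1].
#' @return Adjusted p-values.
#' @export
benjamini_hochberg <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Select training SNPs by association p-value
#'
#' @param results Association data.frame (needs columns \code{snp_id},
#'   \code{p}).
#' @param p_filter Inclusion threshold on the unadjusted p-value.
#' @return Object of class \code{training_set}: \code{indices},
#'   \code{snp_ids}, \code{p_filter}. Warns when empty (the
#'   misclassification model cannot run without informative training SNPs).
#' @export
select_training_snps <- function(results, p_filter) {
  stopifnot(nrow(results) > 0)
  idx <- which(results$p < p_filter)
  if (length(idx) == 0) {
    warning("no SNPs pass the training filter; ",
            "the misclassification model cannot run without training SNPs")
  }
  structure(list(indices = idx, snp_ids = results$snp_id[idx],
                 p_filter = p_filter),
            class = "training_set")
}

#' Squared-correlation LD between two dosage vectors
#' @param x_i,x_j Genotype dosage vectors of equal length.
#' @return r^2 between 0 and 1, or NA when either vector is constant.
#' @export
ld_r2 <- function(x_i, x_j) {
  stopifnot(length(x_i) == length(x_j))
  if (stats::sd(x_i) == 0 || stats::sd(x_j) == 0) return(NA_real_)
  stats::cor(x_i, x_j)^2
}

#' Greedy sliding-window LD pruning
#'
#' Within each window (SNPs whose positions fall in
#' \code{[pos_start, pos_start + window_kb * 1000)} on one chromosome), any
#' pair with r^2 above the threshold loses its lower-MAF member (position
#' tie-break); the window start then advances by \code{step} SNPs.
#'
#' @param X A \code{genotype_matrix} with positions sorted within chromosome.
#' @param window_kb Window size in kilobases (default 50).
#' @param step SNPs to advance between windows (default 5).
#' @param r2_threshold Pruning threshold (default 0.20).
#' @return Integer vector of retained SNP column indices.
#' @export
ld_prune <- function(X, window_kb = 50, step = 5, r2_threshold = 0.20) {
  stopifnot(inherits(X, "genotype_matrix"))
  keep <- rep(TRUE, ncol(X$values))
  for (ch in unique(X$chrom)) {
    snps <- which(X$chrom == ch)
    if (is.unsorted(X$pos[snps])) {
      stop(sprintf("positions not sorted on chromosome %s", ch))
    }
    start <- 1L
    while (start <= length(snps)) {
      pos0 <- X$pos[snps[start]]
      in_win <- snps[X$pos[snps] >= pos0 &
                       X$pos[snps] < pos0 + window_kb * 1000]
      active <- in_win[keep[in_win]]
      if (length(active) > 1) {
        repeat {
          r2 <- stats::cor(X$values[, active, drop = FALSE])^2
          diag(r2) <- 0
          r2[is.na(r2)] <- 0
          if (max(r2) <= r2_threshold) break
          worst <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
          pair <- active[worst]
          drop_snp <- if (X$maf[pair[1]] < X$maf[pair[2]]) {
            pair[1]
          } else if (X$maf[pair[2]] < X$maf[pair[1]]) {
            pair[2]
          } else {
            max(pair)  # MAF tie: drop the later position
          }
          keep[drop_snp] <- FALSE
          active <- setdiff(active, drop_snp)
          if (length(active) < 2) break
        }
      }
      start <- start + step
    }
  }
  which(keep)
}

#' Identify discoveries after phenotype correction
#'
#' A discovery is a SNP that (i) is not a training SNP, (ii) has r^2 below
#' \code{k} with every training SNP, (iii) is BH-significant (adjusted
#' p < \code{bh_alpha}) in the corrected-phenotype scan and (iv) is not
#' BH-significant in the original-phenotype scan.
#'
#' @param original_results,corrected_results Association data.frames over
#'   the identical SNP universe.
#' @param training A \code{training_set}.
#' @param X The \code{genotype_matrix} (for LD with training SNPs).
#' @param k Discovery LD cutoff on r^2 (default 1e-2).
#' @param bh_alpha Adjusted-p significance level (default 0.1).
#' @return data.frame of annotated results with columns \code{p_bh_original},
#'   \code{p_bh_corrected}, \code{is_training}, \code{max_r2_training},
#'   \code{is_discovery}, sorted as the input.
#' @export
identify_discoveries <- function(original_results, corrected_results,
                                 training, X, k = 1e-2, bh_alpha = 0.1) {
  if (!identical(original_results$snp_id, corrected_results$snp_id)) {
    stop("original and corrected result sets cover different SNP universes")
  }
  m <- nrow(original_results)
  is_training <- seq_len(m) %in% training$indices
  max_r2 <- rep(0, m)
  if (length(training$indices) > 0) {
    vals <- X$values
    tr <- vals[, training$indices, drop = FALSE]
    cc <- suppressWarnings(stats::cor(vals, tr))^2
    cc[is.na(cc)] <- 0
    max_r2 <- apply(cc, 1, max)
  }
  p_bh_orig <- benjamini_hochberg(original_results$p)
  p_bh_corr <- benjamini_hochberg(corrected_results$p)
  out <- corrected_results
  out$p_bh_original <- p_bh_orig
  out$p_bh_corrected <- p_bh_corr
  out$is_training <- is_training
  out$max_r2_training <- max_r2
  out$is_discovery <- !is_training & max_r2 < k &
    p_bh_corr < bh_alpha & p_bh_orig >= bh_alpha
  out
}
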