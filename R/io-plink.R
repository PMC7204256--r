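# PLINK binary trio (.bed/.bim/.fam) and TSV table I/O. The .bed reader and
# writer handle the SNP-major layout (magic bytes 0x6c 0x1b 0x01, two bits
# per genotype, samples packed four per byte, low bits first); genotype
# values are counts of the A1 allele.

BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

#' Write a genotype matrix as a PLINK binary trio
#'
#' @param X A \code{genotype_matrix}.
#' @param prefix Path prefix; writes \code{prefix.bed}, \code{prefix.bim},
#'   \code{prefix.fam}.
#' @param sample_ids Sample identifiers for the .fam file (default
#'   \code{"s1"..."sn"}).
#' @param phenotype Optional 0/1 phenotype stored in the .fam (written as
#'   PLINK 1/2 codes; -9 when absent).
#' @return The prefix, invisibly.
#' @export
write_plink <- function(X, prefix, sample_ids = NULL, phenotype = NULL) {
  stopifnot(inherits(X, "genotype_matrix"))
  vals <- X$values
  n <- nrow(vals); m <- ncol(vals)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  pheno <- if (is.null(phenotype)) rep(-9L, n) else as.integer(phenotype) + 1L

  # .bed: genotype -> 2-bit code (A1 count 2 -> 00, 1 -> 10, 0 -> 11)
  code <- matrix(3L, n, m)
  code[vals == 2] <- 0L
  code[vals == 1] <- 2L
  bytes_per_snp <- ceiling(n / 4)
  pad <- bytes_per_snp * 4 - n
  if (pad > 0) code <- rbind(code, matrix(0L, pad, m))
  shifts <- rep(c(0L, 2L, 4L, 6L), bytes_per_snp)
  packed <- vapply(seq_len(m), function(j) {
    v <- bitwShiftL(code[, j], shifts)
    as.raw(colSums(matrix(v, nrow = 4)))
  }, raw(bytes_per_snp))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(BED_MAGIC, con)
  writeBin(as.raw(packed), con)

  utils::write.table(
    data.frame(chrom = X$chrom, snp_id = X$snp_ids, cm = 0, pos = X$pos,
               a1 = "A", a2 = "B"),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(fid = sample_ids, iid = sample_ids, pat = 0, mat = 0,
               sex = 0, pheno = pheno),
    paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a PLINK binary trio
#'
#' @param prefix Path prefix of \code{.bed}/\code{.bim}/\code{.fam} files.
#' @return List with \code{genotypes} (a \code{genotype_matrix}),
#'   \code{sample_ids}, and \code{phenotype} (0/1 integer vector or NULL
#'   when the .fam carries no phenotype). Missing genotype codes are an
#'   error: the pipeline requires complete data.
#' @export
read_plink <- function(prefix) {
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           stringsAsFactors = FALSE)
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  bed_path <- paste0(prefix, ".bed")
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || !identical(raw[1:3], BED_MAGIC)) {
    stop(sprintf("%s is not a SNP-major PLINK .bed file (bad magic bytes)",
                 bed_path))
  }
  body <- raw[-(1:3)]
  bytes_per_snp <- ceiling(n / 4)
  if (length(body) != bytes_per_snp * m) {
    stop(sprintf("%s: expected %d genotype bytes, found %d",
                 bed_path, bytes_per_snp * m, length(body)))
  }
  ints <- as.integer(body)
  # unpack 4 two-bit codes per byte, low bits first
  codes <- rbind(bitwAnd(ints, 3L),
                 bitwAnd(bitwShiftR(ints, 2L), 3L),
                 bitwAnd(bitwShiftR(ints, 4L), 3L),
                 bitwAnd(bitwShiftR(ints, 6L), 3L))
  codes <- matrix(codes, nrow = bytes_per_snp * 4)[seq_len(n), , drop = FALSE]
  if (any(codes == 1L)) {
    stop(sprintf("%s contains missing genotypes; complete data required",
                 bed_path))
  }
  vals <- matrix(0L, n, m)
  vals[codes == 0L] <- 2L
  vals[codes == 2L] <- 1L
  genotypes <- genotype_matrix(vals, snp_ids = bim$V2, chrom = bim$V1,
                               pos = bim$V4)
  pheno <- fam$V6
  phenotype <- if (all(pheno %in% c(1L, 2L))) as.integer(pheno - 1L) else NULL
  list(genotypes = genotypes, sample_ids = as.character(fam$V2),
       phenotype = phenotype)
}

#' Read a phenotype TSV aligned to a sample-id vector
#'
#' The file needs columns \code{sample_id} and \code{phenotype} (0/1); rows
#' are joined by id, so file order is irrelevant.
#'
#' @param path TSV path.
#' @param sample_ids Ids defining the output order.
#' @return A \code{phenotype_vector} in \code{sample_ids} order.
#' @export
read_phenotype_tsv <- function(path, sample_ids) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "phenotype") %in% names(tab)))
  idx <- match(sample_ids, tab$sample_id)
  if (anyNA(idx)) {
    stop(sprintf("phenotype file lacks sample ids: %s",
                 paste(utils::head(sample_ids[is.na(idx)], 5),
                       collapse = ", ")))
  }
  phenotype_vector(tab$phenotype[idx], sample_ids)
}

#' Write per-sample misclassification probabilities as TSV
#' @param result A \code{misclassification_result}.
#' @param y A \code{phenotype_vector} (supplies ids and observed status).
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_probabilities_tsv <- function(result, y, path) {
  utils::write.table(
    data.frame(sample_id = y$sample_ids, phenotype = y$values,
               avg_misclassification_prob = result$avg_prob,
               flagged = result$flagged),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a thinned MCMC trace as TSV
#' @param trace A \code{chain_trace}.
#' @param path Output TSV path.
#' @param thin Thinning interval (default the trace's stored interval).
#' @return The path, invisibly.
#' @export
write_trace_tsv <- function(trace, path, thin = trace$beta_thin) {
  utils::write.table(trace_as_data_frame(trace, thin), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an annotated association table as TSV
#' @param results Association data.frame (as from
#'   \code{\link{identify_discoveries}} or \code{\link{lmm_association}}).
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_association_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
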