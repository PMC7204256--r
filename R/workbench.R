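# End-to-end orchestration: the phenotype-correction pipeline
# (GWAS -> training filter -> misclassification model -> correction ->
# re-GWAS -> discoveries) and the replicated simulation study with ROC/PR
# summaries.

#' Configuration of the correction pipeline
#'
#' Defaults follow the real-data operating point: training filter
#' p < 1e-5, ten sampler runs, flagging threshold t at the 95th percentile.
#' The simulation-study operating point (Bonferroni filter, one run, 99th
#' percentile) is selected by \code{\link{study_config}}.
#'
#' @param p_filter Training-SNP inclusion threshold on unadjusted p;
#'   \code{"bonferroni"} uses 0.05 / m.
#' @param t_percentile Flagging percentile over case probabilities.
#' @param n_runs Independent sampler runs to average.
#' @param k Discovery LD cutoff on r^2 (default 1e-2).
#' @param bh_alpha BH significance level for discoveries (default 0.1).
#' @param ld_prune_first Run LD pruning before the scan (default FALSE;
#'   simulated SNPs are independent by construction).
#' @param mcmc An \code{mcmc_config}.
#' @param pooled_threshold Percentile over pooled per-run probabilities
#'   instead of per-sample means (default FALSE).
#' @param seed Seed for the sampler runs.
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(p_filter = 1e-5, t_percentile = 95, n_runs = 10,
                            k = 1e-2, bh_alpha = 0.1, ld_prune_first = FALSE,
                            mcmc = mcmc_config(), pooled_threshold = FALSE,
                            seed = NULL) {
  structure(list(p_filter = p_filter, t_percentile = t_percentile,
                 n_runs = n_runs, k = k, bh_alpha = bh_alpha,
                 ld_prune_first = ld_prune_first, mcmc = mcmc,
                 pooled_threshold = pooled_threshold, seed = seed),
            class = "pipeline_config")
}

#' Run the full phenotype-correction pipeline
#'
#' Optional LD pruning, LMM association scan, training-SNP selection,
#' repeated misclassification-model runs, case flagging and switching,
#' re-scan with the corrected phenotype, and discovery identification.
#'
#' @param X A \code{genotype_matrix}.
#' @param y Observed phenotype (\code{phenotype_vector} or 0/1 vector).
#' @param covariates Optional fixed-covariate matrix for the scans.
#' @param A Optional \code{kinship_matrix}; computed from X (MAF > 5%) when
#'   NULL.
#' @param config A \code{pipeline_config}.
#' @return Object of class \code{pipeline_report}: \code{scan_original},
#'   \code{scan_corrected}, \code{training}, \code{misclassification}
#'   (\code{misclassification_result}), \code{chains}, \code{y_corrected},
#'   \code{discoveries} (annotated association table), \code{counts}
#'   (case/control accounting), \code{timings} (seconds per stage),
#'   \code{retained_snps} (after pruning).
#' @export
run_correction_pipeline <- function(X, y, covariates = NULL, A = NULL,
                                    config = pipeline_config()) {
  stopifnot(inherits(X, "genotype_matrix"))
  if (!inherits(y, "phenotype_vector")) y <- phenotype_vector(y)
  stopifnot(length(y$values) == nrow(X$values))
  timings <- c()
  tick <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    list(val = val, sec = proc.time()[["elapsed"]] - t0)
  }

  retained <- seq_len(ncol(X$values))
  if (config$ld_prune_first) {
    st <- tick(ld_prune(X))
    retained <- st$val; timings["ld_prune"] <- st$sec
    X <- subset_genotypes(X, snps = retained)
  }
  if (is.null(A)) {
    st <- tick(compute_grm(X))
    A <- st$val; timings["grm"] <- st$sec
  }

  st <- tick(lmm_association(y, X, A, covariates))
  scan_original <- st$val; timings["scan_original"] <- st$sec

  p_filter <- if (identical(config$p_filter, "bonferroni")) {
    bonferroni_threshold(nrow(scan_original))
  } else {
    config$p_filter
  }
  training <- select_training_snps(scan_original, p_filter)
  if (length(training$indices) == 0) {
    stop("no training SNPs pass the filter: the misclassification model ",
         "assumes informative strongly associated SNPs and cannot run")
  }

  mcmc <- config$mcmc
  mcmc$t_percentile <- config$t_percentile
  mcmc$seed <- config$seed
  st <- tick(run_misclassification_model(
    y, X$values[, training$indices, drop = FALSE], A,
    config = mcmc, n_runs = config$n_runs))
  timings["sampler"] <- st$sec
  chains <- st$val$chains
  mis <- aggregate_and_flag(chains, y, config$t_percentile,
                            pooled = config$pooled_threshold)

  y_corrected <- correct_phenotype(y, mis$flagged)
  st <- tick(lmm_association(y_corrected, X, A, covariates))
  scan_corrected <- st$val; timings["scan_corrected"] <- st$sec

  discoveries <- identify_discoveries(scan_original, scan_corrected,
                                      training, X, k = config$k,
                                      bh_alpha = config$bh_alpha)

  counts <- c(original_cases = sum(y$values),
              flagged = sum(mis$flagged),
              corrected_cases = sum(y_corrected$values),
              corrected_controls = sum(1 - y_corrected$values))
  stopifnot(counts["corrected_cases"] + counts["flagged"] ==
              counts["original_cases"])

  structure(list(
    scan_original = scan_original, scan_corrected = scan_corrected,
    training = training, misclassification = mis, chains = chains,
    y_corrected = y_corrected, discoveries = discoveries, counts = counts,
    timings = timings, retained_snps = retained,
    converged = vapply(chains, function(ch) isTRUE(ch$converged), logical(1)),
    config = config
  ), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("phenotype-correction pipeline report\n")
  cat(sprintf("  training SNPs: %d (p < %.3g)\n",
              length(x$training$indices), x$training$p_filter))
  cat(sprintf("  flagged cases: %d of %d (t = %gth percentile)\n",
              x$counts[["flagged"]], x$counts[["original_cases"]],
              x$misclassification$t_percentile))
  cat(sprintf("  corrected phenotype: %d cases / %d controls\n",
              x$counts[["corrected_cases"]],
              x$counts[["corrected_controls"]]))
  cat(sprintf("  discoveries: %d; converged chains: %d/%d\n",
              sum(x$discoveries$is_discovery), sum(x$converged),
              length(x$converged)))
  invisible(x)
}

#' Configuration for the replicated simulation study
#'
#' @param simulation A \code{simulation_config}.
#' @param rates Misclassification fractions to sweep.
#' @param replicates Phenotype replicates per rate.
#' @param p_filter Training filter (\code{"bonferroni"} or a number).
#' @param t_percentile Flagging percentile (default 99, the simulation-mode
#'   operating point).
#' @param mcmc An \code{mcmc_config} (one run per replicate by default).
#' @param evaluate_snp_detection Also scan true/corrected phenotypes and
#'   compute SNP-detection ROC/PR (default TRUE).
#' @param seed Master seed; replicate sub-seeds are derived from it.
#' @return Object of class \code{study_config}.
#' @export
study_config <- function(simulation = simulation_config(),
                         rates = c(0.01, 0.03, 0.05, 0.08, 0.10),
                         replicates = 100,
                         p_filter = "bonferroni", t_percentile = 99,
                         mcmc = mcmc_config(), evaluate_snp_detection = TRUE,
                         seed = 1L) {
  stopifnot(replicates >= 1, !is.unsorted(rates))
  structure(list(simulation = simulation, rates = rates,
                 replicates = replicates, p_filter = p_filter,
                 t_percentile = t_percentile, mcmc = mcmc,
                 evaluate_snp_detection = evaluate_snp_detection,
                 seed = seed),
            class = "study_config")
}

#' Desk-scale study preset
#'
#' A reduced configuration of the structured design sized for interactive
#' runs: 5 replicates, a 2000-sample population with 10,000 SNPs and 30
#' causal SNPs, a 200-case/600-control study sample, 10,000 MCMC iterations
#' with 2,000 burn-in, rates 3/5/10%, and a training filter of p < 1e-4 (at
#' this sample size the full-scale Bonferroni cut would rarely admit any
#' training SNP).
#'
#' @param seed Master seed.
#' @param replicates Phenotype replicates (default 5).
#' @param ... Overrides passed to \code{\link{study_config}}.
#' @return A \code{study_config}.
#' @export
desk_study_config <- function(seed = 1L, replicates = 5, ...) {
  study_config(
    simulation = simulation_config(strategy = 2, n_population = 2000,
                                   m_snps = 10000, n_causal = 30,
                                   n_cases = 200, n_controls = 600),
    rates = c(0.03, 0.05, 0.10),
    replicates = replicates,
    p_filter = 1e-4,
    t_percentile = 99,
    mcmc = mcmc_config(n_iter = 10000, burn_in = 2000),
    seed = seed,
    ...
  )
}

#' Run the replicated simulation study
#'
#' Per replicate: simulate a phenotype from the shared population, scan the
#' true phenotype; per misclassification rate: inject misclassification,
#' scan the observed phenotype, select training SNPs, run the
#' misclassification model, evaluate detection of the switched controls,
#' correct the phenotype, optionally re-scan and evaluate SNP detection and
#' significant-SNP counts.
#'
#' @param config A \code{study_config}.
#' @param progress Print per-replicate progress lines (default FALSE).
#' @return Object of class \code{study_result}: \code{per_replicate}
#'   (data.frame, one row per replicate x rate) and \code{summary}
#'   (medians per rate).
#' @export
run_simulation_study <- function(config = desk_study_config(),
                                 progress = FALSE) {
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, config$replicates)
  population <- simulate_population(config$simulation)
  rows <- list()

  for (r in seq_len(config$replicates)) {
    set.seed(rep_seeds[r])
    ds <- simulate_replicate(population, misclassification_fraction = 0)
    A <- compute_grm(ds$X)
    scan_true <- lmm_association(ds$y_true, ds$X, A)
    m <- ncol(ds$X$values)
    p_filter <- if (identical(config$p_filter, "bonferroni")) {
      bonferroni_threshold(m)
    } else {
      config$p_filter
    }
    auc_true <- if (config$evaluate_snp_detection) {
      snp_detection_metrics(scan_true$p, ds$causal_indices)
    }

    for (rate in config$rates) {
      mis <- inject_misclassification(ds$y_true$values, rate)
      y_obs <- phenotype_vector(mis$y_observed, ds$y_true$sample_ids)
      scan_obs <- lmm_association(y_obs, ds$X, A)
      training <- suppressWarnings(select_training_snps(scan_obs, p_filter))
      row <- data.frame(replicate = r, rate = rate,
                        n_training = length(training$indices),
                        realized_prevalence = ds$realized_prevalence,
                        h2_snp = ds$variance$h2_snp,
                        h2_snp_plus_u = ds$variance$h2_snp_plus_u,
                        skipped = FALSE, auc_roc_detect = NA_real_,
                        auc_pr_detect = NA_real_, flagged = NA_integer_,
                        true_flagged = NA_integer_,
                        converged = NA, discarded_switch = NA_integer_,
                        auc_roc_snp_true = NA_real_,
                        auc_roc_snp_obs = NA_real_,
                        auc_roc_snp_corr = NA_real_,
                        auc_pr_snp_true = NA_real_,
                        auc_pr_snp_obs = NA_real_,
                        auc_pr_snp_corr = NA_real_,
                        tp_snps = NA_integer_, novel_tp_snps = NA_integer_,
                        fp_snps = NA_integer_)
      if (length(training$indices) == 0) {
        row$skipped <- TRUE
        rows[[length(rows) + 1L]] <- row
        next
      }
      # the joint (alpha, lambda) posterior has a mirror "switch" mode; a
      # chain that spends most of its post-burn-in there is unusable, so
      # retry with a fresh seed (multi-chain policy) up to three times
      mcmc <- config$mcmc
      mcmc$t_percentile <- config$t_percentile
      chain <- NULL
      for (attempt in 0:2) {
        mcmc$seed <- (rep_seeds[r] + round(rate * 1000) +
                        attempt * 1000003) %% (.Machine$integer.max - 1L)
        cand <- run_chain(y_obs, ds$X$values[, training$indices, drop = FALSE],
                          A, prior_spec(), mcmc)
        if (isTRUE(cand$usable)) { chain <- cand; break }
      }
      if (is.null(chain)) {
        row$skipped <- TRUE
        rows[[length(rows) + 1L]] <- row
        next
      }
      res <- aggregate_and_flag(list(chain$avg_prob), y_obs,
                                config$t_percentile)
      is_case <- y_obs$values == 1L
      det <- detection_metrics(res$avg_prob[is_case], mis$mask[is_case])
      row$auc_roc_detect <- det$auc_roc
      row$auc_pr_detect <- det$auc_pr
      row$flagged <- sum(res$flagged)
      row$true_flagged <- sum(res$flagged & mis$mask)
      row$converged <- chain$converged
      row$discarded_switch <- chain$discarded_switch

      if (config$evaluate_snp_detection) {
        y_corr <- correct_phenotype(y_obs, res$flagged)
        scan_corr <- lmm_association(y_corr, ds$X, A)
        auc_obs <- snp_detection_metrics(scan_obs$p, ds$causal_indices)
        auc_corr <- snp_detection_metrics(scan_corr$p, ds$causal_indices)
        counts <- count_significant_snps(
          scan_corr$p, ds$causal_indices, "bonferroni",
          p_true = scan_true$p, p_misclassified = scan_obs$p)
        row$auc_roc_snp_true <- auc_true$auc_roc
        row$auc_roc_snp_obs <- auc_obs$auc_roc
        row$auc_roc_snp_corr <- auc_corr$auc_roc
        row$auc_pr_snp_true <- auc_true$auc_pr
        row$auc_pr_snp_obs <- auc_obs$auc_pr
        row$auc_pr_snp_corr <- auc_corr$auc_pr
        row$tp_snps <- counts$true_positive
        row$novel_tp_snps <- counts$novel_true_positive
        row$fp_snps <- counts$false_positive
      }
      rows[[length(rows) + 1L]] <- row
      if (progress) {
        message(sprintf(
          "replicate %d rate %.2f: %d training SNPs, detect AUC %.3f",
          r, rate, row$n_training, row$auc_roc_detect))
      }
    }
  }

  per_replicate <- do.call(rbind, rows)
  summary <- stats::aggregate(
    per_replicate[, c("auc_roc_detect", "auc_pr_detect", "auc_roc_snp_obs",
                      "auc_roc_snp_corr", "auc_pr_snp_obs",
                      "auc_pr_snp_corr", "n_training")],
    by = list(rate = per_replicate$rate),
    FUN = function(v) stats::median(v, na.rm = TRUE))
  structure(list(per_replicate = per_replicate, summary = summary,
                 config = config),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("study_result: %d replicates x %d rates\n",
              x$config$replicates, length(x$config$rates)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
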