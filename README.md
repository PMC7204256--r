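# phenofix

Detection and correction of misclassified case/control phenotypes in
genome-wide association studies.

Case/control labels in GWAS cohorts are noisy: diagnosis codes and
self-report misrecord some true controls as cases. `phenofix` treats the
recorded phenotype $Y$ as a noisy read-out of a latent true phenotype $Y'$
driven by a probit mixed model over strongly associated *training SNPs*,

$$\Pr(Y'_i = 1 \mid \beta, u) = \Phi(X_i\beta + u_i), \qquad
  u \sim \mathrm{MVN}(0, \sigma_u^2 A),$$

with recording rates $\alpha = P(Y{=}1 \mid Y'{=}1)$ (true-positive) and
$\lambda = P(Y{=}1 \mid Y'{=}0)$ (false-positive) and priors
$\alpha \sim \mathrm{Beta}(10,1)$, $\lambda \sim \mathrm{Beta}(1,1)$,
$\beta_j \sim N(0,1)$. Adaptive Metropolis–Hastings within Gibbs sampling
yields, for every observed case, the posterior probability of being a true
control,

$$P(Y'_i{=}0 \mid Y_i{=}1) =
  \frac{\lambda(1-\sigma_i)}{\lambda(1-\sigma_i) + \alpha\sigma_i},$$

averaged over iterations. Cases above the $t$-th percentile are switched to
controls and the association scan is re-run; non-training SNPs that become
BH-significant (adjusted $p<0.1$) only with the corrected phenotype, and are
in linkage equilibrium with the training set ($r^2 < 10^{-2}$), are reported
as supplemental discoveries.

The package is aimed at statistical geneticists who suspect label noise in
a binary GWAS phenotype, and ships the full workbench: a
liability-threshold case/control simulator with kinship-structured random
effects, an EMMAX-style linear mixed-model scan, LD utilities, ROC/PR
benchmarking of both misclassified-sample detection and SNP detection, and
PLINK `.bed/.bim/.fam` I/O.

## Worked example

Simulate a structured study, inject 10% misclassification among controls,
and run the correction pipeline:

```r
library(phenofix)

set.seed(7)
cfg <- simulation_config(strategy = 2, n_population = 2000, m_snps = 4000,
                         n_causal = 30, n_cases = 200, n_controls = 600,
                         misclassification_fraction = 0.10)
ds <- simulate_study(cfg)
ds
#> simulated_dataset: 800 samples x 4000 SNPs, 30 causal, 60 misclassified (h2 0.31 / 0.77)

report <- run_correction_pipeline(
  ds$X, ds$y_observed,
  config = pipeline_config(p_filter = 1e-4, t_percentile = 95, n_runs = 3,
                           mcmc = mcmc_config(n_iter = 10000, burn_in = 2000),
                           seed = 7))
report
#> phenotype-correction pipeline report
#>   training SNPs: 2 (p < 0.0001)
#>   flagged cases: 13 of 260 (t = 95th percentile)
#>   corrected phenotype: 247 cases / 553 controls
#>   discoveries: 0; converged chains: 2/3
```

The training filter admitted 2 SNPs; three sampler chains produced
per-sample misclassification probabilities; 13 of the 260 observed cases
(the 60 switched controls plus 200 true cases) exceeded the 95th-percentile
threshold and were returned to control status; the
re-scan surfaced no supplemental locus on this draw (discoveries require a
newly BH-significant SNP outside the training set). How well the flags
align with the truth is measured by
`detection_metrics()`:

```r
is_case <- ds$y_observed$values == 1
detection_metrics(report$misclassification$avg_prob[is_case],
                  ds$misclassified_mask[is_case])
#> detection_curves: AUC ROC 0.674, AUC PR 0.337 (60 pos / 200 neg)
```

An AUC ROC of 0.67 means a randomly chosen switched control outranks a
randomly chosen true case 67% of the time; the PR AUC of 0.34 sits well
above the 0.23 chance baseline (the fraction of cases that are switched
controls). The replicated benchmark behind these numbers is
`run_simulation_study(desk_study_config())`.

## Command line

A thin CLI over the same functions lives at `inst/cli/phenofix`
(subcommands `simulate`, `gwas`, `extract`, `correct`, `discover`,
`study`), reading PLINK trios and writing TSV tables.
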