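---
title: "Detecting and correcting misclassified case/control phenotypes in GWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and correcting misclassified case/control phenotypes in GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Case/control labels in GWAS are imperfect: diagnosis codes, self-report and
registry linkage all misrecord some true controls as cases (and, less often,
true cases as controls). Even a few percent of label noise dilutes
association signal and can hide loci that would otherwise reach
significance. `phenofix` models the recording process explicitly, estimates
a per-sample posterior probability of being mislabeled, switches
high-probability cases back to controls, and re-runs the association scan to
surface supplemental candidate loci.

## The model

Let $Y$ be the observed 0/1 phenotype of $n$ samples and $Y'$ the latent
true phenotype. Genotypes $X$ at a small set of strongly associated
*training SNPs* drive the latent phenotype through a probit mixed model:

$$\Pr(Y'_i = 1 \mid \beta, u) = \sigma_i = \Phi(X_i \beta + u_i), \qquad
  u \sim \mathrm{MVN}(0, \sigma_u^2 A),$$

where $A$ is the genetic relatedness matrix and the unit-variance liability
noise is absorbed by the standard normal CDF $\Phi$. Recording is a noisy
channel with two rates: the true-positive rate
$\alpha = P(Y = 1 \mid Y' = 1)$ and the false-positive rate
$\lambda = P(Y = 1 \mid Y' = 0)$. Marginalizing $Y'$ gives the
observed-data likelihood

$$\Pr(Y \mid \alpha, \lambda, \beta, u) =
  \prod_i \left[\lambda(1 - \sigma_i) + \alpha\sigma_i\right]^{Y_i}
  \left[(1-\lambda)(1-\sigma_i) + (1-\alpha)\sigma_i\right]^{1 - Y_i}.$$

Priors: $\alpha \sim \mathrm{Beta}(10, 1)$ (strong prior belief that true
cases are recorded as cases — in most GWAS a case must satisfy explicit
diagnostic criteria), $\lambda \sim \mathrm{Beta}(1, 1)$ (uninformative),
$\beta_j \sim N(0, 1)$, and a flat prior on $\sigma_u^2$ truncated at 100.
The quantity of interest is the per-sample misclassification posterior; for
an observed case,

$$P(Y'_i = 0 \mid Y_i = 1) =
  \frac{\lambda (1 - \sigma_i)}{\lambda (1 - \sigma_i) + \alpha \sigma_i},$$

and symmetrically for controls.

## Inference

`run_chain()` implements adaptive Metropolis–Hastings within Gibbs:

1. $(\alpha, \lambda, \beta)$ are proposed jointly — $\alpha, \lambda$ from
   normals truncated to $(0,1)$, $\beta$ from symmetric normals — and
   accepted together using the observed-data likelihood times their priors.
   The truncated proposals receive a Hastings correction.
2. Each sample draws a Bernoulli misclassification indicator with its
   posterior probability; marked samples have their latent phenotype
   flipped for this iteration.
3. Latent liabilities are drawn by truncated-normal (Albert–Chib)
   augmentation conditioned on the current latent phenotype, via inverse
   CDF so extreme truncation never loops.
4. Random effects are updated by sequential single-site conjugate normals
   using the precomputed kinship inverse (the only $O(n^2)$ step; it is
   implemented in C++), and $\sigma_u^2$ by an inverse-CDF draw from its
   truncated conditional.

Proposal scales adapt every 50 burn-in iterations toward an acceptance rate
of 0.2, with gain decaying as $1/\text{batch}$ and adaptation frozen after
burn-in so the chain's stationary distribution is preserved. Averaging the
per-iteration marks over retained post-burn-in iterations yields the
per-sample misclassification probability; cases above the $t$-th percentile
of case probabilities are flagged and switched to controls by
`correct_phenotype()`.

### Label switching

With a flat prior on $\lambda$ the joint posterior of $(\alpha, \lambda)$
is bimodal: a mirror mode swaps the roles of the latent classes. We follow
the identifiability constraint $\alpha > \lambda$ and drop iterations that
violate it from the averaging (`detect_and_filter_label_switch()`). A chain
that spends most of its post-burn-in in the mirror mode is marked unusable;
the orchestration retries such chains with a fresh seed — the practical
multi-chain policy for this posterior — and `aggregate_and_flag()` refuses
to aggregate when no usable converged chain exists. Convergence is judged
by the Geweke diagnostic ($|z| < 1.96$ comparing the first 10% and last 50%
of each parameter trace, with AR-estimated spectral standard errors).

### Numerical choices

* $\sigma_i$ is clipped to $[10^{-10}, 1 - 10^{-10}]$ before logs and
  ratios; a non-finite proposed posterior auto-rejects.
* The kinship matrix receives diagonal jitter $10^{-6}\,
  \overline{\mathrm{diag}(A)}$ before inversion; empirical GRMs can be
  singular.
* The variance conditional $\propto (\sigma_u^2)^{-n/2}
  e^{-S/(2\sigma_u^2)}$ is sampled through the equivalent truncated gamma
  on the precision scale; for $n \le 2$ (where the gamma shape is not
  positive and only the truncation makes the density proper) a numeric
  grid inverse is used. $S = 0$ keeps the current value.
* An intercept column is prepended to the training matrix by default, its
  coefficient sharing the $N(0,1)$ effect prior: a 1:3 case:control ratio
  is incompatible with a zero-intercept probit. `strict_paper_mode`
  disables it. Training genotypes enter as raw 0/1/2 counts (a centering
  option exists).
* We read $\sigma(\beta X + u + \epsilon)$ as $\Phi$ already marginalizing
  the unit liability noise $\epsilon$ rather than carrying an explicit
  noise parameter; this is the standard liability-threshold reading and
  matches the simulator's generative link.

## The association stage

`lmm_association()` is an EMMAX-style scan: variance components are
estimated once on the null model by REML in the eigenbasis of the GRM, and
each SNP then gets a Wald test with the components held fixed; binary
phenotypes are analyzed on the quantitative scale, as is common practice
for this design. With $A = I$ the scan reduces exactly to ordinary
regression, which doubles as the test oracle. The GRM uses
column-standardized genotypes over SNPs with MAF > 5%. Training SNPs are
selected by unadjusted $p$ below a filter (Bonferroni $0.05/m$ for
simulation studies; the $10^{-5}$ heuristic for real data, where genome-wide
significant SNPs may not exist). Discoveries after correction are
non-training SNPs, in linkage equilibrium with all training SNPs
($r^2 < 10^{-2}$), BH-significant (adjusted $p < 0.1$) with the corrected
phenotype and not with the original one.

## The simulator

`simulate_population()` / `simulate_replicate()` implement a
liability-threshold case/control generator in two designs:

* **Structure-free** (`strategy = 1`): MAF drawn uniformly from
  $\{0.1, 0.2, 0.4\}$, 30 causal SNPs with $\beta \sim N(2, 0.3)$, no
  random effects, balanced 1000/1000 median split. We read "multinomial
  distribution with means 0.1, 0.2, 0.4" as a uniform draw over that
  frequency set — the only self-consistent interpretation of the
  referenced simulator's default frequency vector.
* **Structured** (`strategy = 2`, default): 10,000 samples × 100,000
  independent HWE SNPs with MAF $\sim U(0, 0.5)$; 300 causal SNPs with
  MAF-dependent effects $\beta_j \sim N(0, 0.1\,[2f_j(1-f_j)]^{-0.38})$
  (rarer alleles get larger effects); random effects
  $u \sim \mathrm{MVN}(0, 2A)$ with $A$ the GRM of the simulated
  genotypes; prevalence drawn per replicate from $(0.1, 0.5)$ and imposed
  by thresholding the liability at its empirical quantile (this guarantees
  the target prevalence exactly; an intercept could only approximate it);
  1000 cases and 3000 controls sampled into the study.

Genotypes, the causal set and the random-effect vector are drawn once per
population and shared across phenotype replicates; effects, liabilities,
prevalence, sampling and misclassification are redrawn per replicate.
Differential misclassification switches exactly
$\mathrm{round}(f \cdot \#\mathrm{controls})$ random controls to cases;
cases are never flipped. Per-SNP variance explained is
$\mathrm{Var}(X_l\beta_l)/\mathrm{Var}(\sum_j X_j\beta_j + u + \epsilon)$
with empirical variances; because conventions differ on whether random
effects count as "genetic", realized heritability is reported under both
numerators (`h2_snp`, `h2_snp_plus_u`) and neither is privileged.

What the simulator deliberately omits: LD structure (SNPs are independent
by construction, which makes LD pruning a no-op and the training set
unambiguous), genotyping error and missingness, covariate effects, and
non-random (genetically correlated) misclassification — the model's own
third assumption. Passing tests on these data therefore demonstrate
correctness of the machinery and the qualitative behavior of the method,
not robustness to the full messiness of real cohorts.

## Study presets and problem sizes

`desk_study_config()` is the package's interactive-scale rendition of the
structured design: 5 replicates, a 2,000-sample population with 10,000 SNPs
and 30 causal SNPs, a 200-case/600-control study (the same 1:3 ratio),
10,000 MCMC iterations with 2,000 burn-in, and misclassification rates
3/5/10%. Its training filter is $p < 10^{-4}$ — one of the filter-sweep
values — because at $n = 800$ with per-SNP variance explained around 1%,
the full-scale Bonferroni cut would rarely admit any training SNP and the
preset would exercise only plumbing. The full-scale configuration
(`study_config()` defaults) matches the structured design's published
dimensions and is intended for cluster runs.

At desk scale the detection AUCs sit below the full-scale values — the
training set carries a handful of SNPs instead of dozens and chains run
10,000 rather than 100,000 iterations — but the qualitative signatures
remain: detection of switched controls is clearly better than chance, and
detection precision rises with the misclassification rate (the model
assumes misclassification is present, so a higher true rate matches its
expectation better).

## Known limitations

* Only case-to-control correction is wired into the pipeline (the
  simulated error process is false-positive-only); the control posterior
  is computed and exported but not acted on.
* The Rekaya-style baselines exist as ablation flags
  (`disable_mixed_model`, `disable_adaptation`) approximating the published
  full Gibbs sampler, whose exact conditionals are not public.
* Chains can be trapped by the mirror mode on weakly informative training
  sets; the retry policy makes this visible (`skipped` rows, `converged`
  flags) rather than silent.
* The LMM stage estimates variance components once on the null model
  (EMMAX approximation); exact per-SNP REML is not implemented.
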