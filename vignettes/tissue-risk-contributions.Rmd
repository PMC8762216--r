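---
title: "Ranking tissue-specific eQTL contributions to polygenic risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking tissue-specific eQTL contributions to polygenic risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqtlrisk)
```

## The model

`eqtlrisk` asks a mediation-flavoured question with purely predictive
machinery: if disease-associated SNPs act on disease risk through
tissue-specific gene regulation, then weighting each genotype by its
normalized eQTL effect size (NES) in each tissue, fitting one regularized
logistic predictor over all such features jointly, and summing absolute
fitted weights per tissue should concentrate coefficient mass on the
tissues that carry signal.

Concretely, for individual $i$ with effect-allele dosage $d_{is} \in
\{0,1,2\}$ at SNP $s$:

* one feature per eQTL association $(s, g, t)$ (SNP, eGene, tissue) with
  value $d_{is} \cdot \mathrm{NES}_{sgt}$, and
* one feature per study SNP without eQTL annotation, with value $d_{is}$.

The predictor is logistic regression with an elastic-net penalty,
$\Pr(y_i = 1) = \sigma(\beta_0 + x_i^\top \beta)$, and a tissue's
contribution is $W_t = \sum_{f \in t} |\beta_f|$, reported as the fraction
$W_t / \sum_u W_u$. No-eQTL SNP features form their own group
(`no_eqtl_snps`). This is attribution of *predictive* weight, not causal
mediation: a tissue can rank highly because its eQTL structure tags the
risk signal well, even if the biology acts elsewhere. The ensemble
stability analysis (below) addresses sampling noise in the ranking, not
this identifiability limit.

### Assumptions

* Biallelic SNPs with dosages harmonized to the eQTL effect allele, so the
  sign of $d \cdot \mathrm{NES}$ is interpretable.
* Independent individuals; no covariate adjustment (age, sex, ancestry
  principal components are out of scope).
* The eQTL reference table is treated as fixed, external knowledge; its
  association FDR is only used as a row filter (default: keep FDR < 0.05).

## Pipeline stages and the parameters that matter

### Feature filtering

Each feature column is tested with a two-sided Mann-Whitney $U$ test (case
vs control values); p-values are adjusted with the Benjamini-Yekutieli
(BY) step-up procedure,
$q_{(i)} = \min\bigl(1, \min_{j \ge i} \tfrac{m\,c(m)}{j} p_{(j)}\bigr)$
with $c(m) = \sum_{k=1}^m 1/k$, and features with $q < \alpha$ (default
$\alpha = 0.05$) are kept. BY rather than Benjamini-Hochberg because the
columns are strongly dependent by construction — features sharing a SNP
are collinear up to their NES scaling — and BY controls FDR under
arbitrary dependence. The test is two-sided since effect direction is not
known a priori, and rank-based, so it is indifferent to whether the matrix
was standardized first.

The $U$ statistic counts case-beats-control pairs with ties at one half.
The p-value is exact — full enumeration of the permutation null — when the
smaller group has at most 8 observations and there are no ties; otherwise
a normal approximation with tie-corrected variance and continuity
correction is used. The crossover at 8 keeps enumeration cheap
($\binom{16}{8} = 12{,}870$ labelings); the suite verifies the
approximation stays within 0.02 of the exact value for group sizes 8-12.

The filter runs once on the full training cohort before cross-validation.
That is the intended order of operations for this design, but it lets the
filter see data that CV later treats as held out, so out-of-fold AUCs are
mildly optimistic when few samples or many features are involved. Callers
wanting leakage-free estimates can filter inside each training fold
themselves (`filter_features()` composes with any subsetting); the default
reproduces the reference procedure.

### Standardization

Features are standardized to zero mean and unit variance before fitting
(`standardize_features()`), using the population (divide-by-$n$) standard
deviation so that replays are bit-stable. This matters because the
contribution statistic compares absolute coefficients across features on
very different natural scales (dosage × NES vs raw dosage); on
unstandardized features, coefficient magnitude conflates effect strength
with feature variance. Passing `standardize = FALSE` to `run_config()`
reproduces the literal unscaled reading. The per-column statistics are
stored in the fitted model (`replay_stats`) and are *always* replayed on
validation cohorts — a new cohort is never standardized by its own
moments, which would silently shift scores.

Constant columns (possible in small subsets) standardize to all-zero and
are flagged `degenerate`.

### Regularized fit and tuning

Fits use glmnet with `standardize = FALSE` (we standardized already),
solver tolerance $10^{-10}$, and a short warm-start path ending at the
target penalty. The user-facing `strength` is the inverse-regularization
constant $C$, mapped as $\lambda = 1/(nC)$, so the fully shrunk limit
gives an intercept-only model at the class log-odds. The hyperparameter
grid (`hyper_grid()`) crosses l1_ratio $\in \{0.25, 0.5, 0.75, 1\}$ with
13 log-spaced strengths over $10^{-4}..10^2$: the intended use case
selects a sparse subset of thousands of features, which requires an
$\ell_1$ component, while the $\ell_2$ component stabilizes selection
among the collinear per-SNP feature blocks. Tuning maximizes mean
out-of-fold AUC over 5 repeats × 10 stratified folds (one fold assignment
shared by all grid points, drawn from the user's seed); ties break toward
stronger regularization (smaller strength, then larger l1_ratio). The
returned ensemble refits the winning point on exactly the tuning folds,
so its 50 models are the models the tuning estimate describes.

Two numerical edge cases are handled explicitly: designs with fewer than
two columns are padded with all-zero columns (glmnet requires two), and a
design with no informative column at all collapses to the closed-form
intercept-only fit. Both arise naturally when the filter removes
everything under a null.

Duplicated columns under pure ridge converge to the exchange-symmetric
solution only as fast as coordinate descent converges; at tolerance
$10^{-10}$ the two coefficients agree to about $10^{-3}$, which is the
bound the test suite asserts.

### Contributions and stability

Fractions are taken over the $\ell_1$ norm of the nonzero coefficients,
excluding the intercept (an intercept is not attributable to any tissue).
Each $(s, g, t)$ coefficient counts only toward its own tissue — a SNP
driving five tissues contributes to five groups, which is the point of
the feature definition, not double counting. Rank ties break
alphabetically by group label so reports are deterministic.
`contribution_stability()` recomputes fractions in each of the 50
ensemble models (a group with all-zero coefficients in a model
contributes fraction 0) and reports per-group mean, sd, rank histogram,
and the consensus ranking by mean fraction.

### Validation and PRS comparison

`subsample_validation()` draws stratified subsets (without replacement
within a subset, independent across subsets) from a validation cohort,
scores them with the frozen model, and compares the mean subset AUC with
the training ensemble's 2.5-97.5 fold-AUC percentile range — a structural
"does the model transfer" check. `compute_prs()` provides the
conventional baseline: $\mathrm{score}_i = \sum_s \beta_s d_{is}$ with
GWAS log-odds, no shrinkage, no thresholding, after the same
effect-allele harmonization as the main pipeline.

AUC confidence intervals use a 2000-replicate stratified bootstrap rather
than the DeLong variance: the bootstrap is trivially deterministic under
a seed, at the cost of a small divergence from analytic intervals.

## The synthetic cohort generator

The generator produces data with the statistical structure the pipeline
assumes, with known ground truth:

* **Reference table**: a fraction `frac_eqtl_snps` (default 0.8) of SNPs
  receive $1 + \mathrm{Poisson}(\texttt{triples\_per\_snp} - 1)$
  (gene, tissue) records; tissues uniform over `n_tissues` labels
  (default 49, the GTEx tissue count); NES sign-symmetric with scale 0.5
  and magnitude floored at 0.05 (eQTL effect sizes are bounded away from
  zero by discovery significance). Remaining SNPs form the no-eQTL set.
* **Genotypes**: independent SNPs, dosage $\sim \mathrm{Binomial}(2,
  \mathrm{MAF})$, $\mathrm{MAF} \sim U(0.05, 0.5)$ — Hardy-Weinberg, no
  linkage disequilibrium by default.
* **Labels**: a liability $\eta_i = \beta_0 + \sum_f \gamma_f z_{if}$ over
  `n_causal_features` eQTL features planted in one tissue (one per SNP, so
  causal features are independent), with $z$ the standardized feature
  value and $\gamma_f = \pm e$ with random sign. Individuals are sampled
  retrospectively — batches drawn and labelled
  $\mathrm{Bernoulli}(\sigma(\eta))$ until the case and control quotas
  fill — matching a case-enriched cohort design. $\beta_0 = -1$ keeps the
  acceptance rate practical.
* **Calibration**: by default the per-feature effect $e$ is solved
  numerically so the *population* AUC of the generative score hits
  `target_auc` (default 0.70): with $S \sim N(0, k e^2)$, class moments
  come from reweighting by the logistic link, and the binormal identity
  $\mathrm{AUC} = \Phi(\Delta\mu / \sqrt{v_1 + v_0})$ closes the
  equation. The realized cohort's class moments are recorded in the truth
  object alongside the implied AUC.
* **Seeds**: population-level structure (MAFs, causal features, effect
  signs) is keyed to the *reference table's* seed; individual sampling is
  keyed to the cohort config's seed. Two cohorts simulated from the same
  table under different seeds therefore share one disease architecture —
  exactly what "an independent validation cohort" means.
* **Negative control**: `make_negative_control()` appends a disjoint
  control-trait SNP panel (default slightly larger than the study panel,
  ratio 313:290) with its own eQTL records and label-independent
  dosages, for filter-depletion checks.

What the generator deliberately omits — and what passing tests therefore
do not establish about real data — includes linkage disequilibrium (an
optional block-LD mode is not implemented; real SNP panels contain
correlated pairs, which mainly widens the stability distributions),
population stratification, genotyping/imputation error, covariates, and
any realistic relationship between MAF, NES and effect size. Recovery
results here are best-case: they validate the machinery, not the
difficulty of any particular disease.

## Reference problem sizes

The package validates itself at these scales, chosen to be comfortably
estimable while preserving the qualitative regime (features ≫ causal
features, filter operating near its FDR level):

* **Recovery**: 2000 cases / 2000 controls, 200 SNPs, 10 tissues, 12
  causal features in one tissue, population AUC 0.70 (`recovery_config()`).
  Expectation: the causal tissue is consensus rank 1 in ≥ 90% of seeds,
  and fitted nonzero coefficients agree in sign with the planted effects.
* **Global null**: 1000/1000, 750 SNPs, ~2100 features, no causal
  features. Expectation: kept-feature fraction ≤ α, CV AUC ≈ 0.5.
* **Ensemble checks** use a fixed mid-grid point (l1_ratio 0.5, strength
  0.1) rather than re-tuning per seed, mirroring the tune-once/reuse
  design of the main workflow.

## Known limitations

* Contribution fractions inherit the penalty's behaviour: under strong
  $\ell_1$, one feature per correlated block gets the mass; its tissue
  absorbs the block's credit.
* The pre-CV filter is mildly anti-conservative for out-of-fold AUC (see
  above).
* `strength` tuning reuses one fold assignment for all grid points; this
  is deliberate (paired comparisons across the grid) but means the
  tuning variance is not itself estimated.
* VCF input assumes biallelic-normalized records; multi-allelic sites are
  skipped, not decomposed.
* Strand-ambiguous (A/T, C/G) SNPs cannot be harmonized from allele
  labels alone; the default keeps them unflipped and flags them in the
  harmonization report, and `ambiguous = "drop"` removes them. Flagging
  preserves an audit trail where frequency-based resolution is not
  possible.
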