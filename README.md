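# eqtlrisk

Which tissues carry the regulatory signal behind a polygenic disease?
Disease-associated SNPs frequently act as expression quantitative trait loci
(eQTLs), shifting the expression of target genes (eGenes) in specific
tissues. `eqtlrisk` turns that observation into a ranking procedure: it
combines case/control genotypes with a tissue-specific eQTL reference table
into a weighted feature matrix, fits a regularized logistic risk predictor,
and decomposes the fitted model into per-tissue contributions to predicted
risk — with an ensemble-based stability analysis, a conventional polygenic
risk score (PRS) for comparison, and a calibrated cohort simulator that
makes every stage testable against known ground truth.

It is aimed at statistical geneticists who have (a) a panel of
disease-associated SNPs annotated with eQTL effects (SNP, eGene, tissue,
signed normalized effect size NES, association FDR), and (b) genotypes with
case/control labels.

## The method

For individual *i*, the feature matrix **X** has one column per
(SNP *s*, eGene *g*, tissue *t*) eQTL association,

> x_i,(s,g,t) = d_is × NES_(s,g,t)

where d_is ∈ {0,1,2} counts copies of the eQTL effect allele (dosages are
harmonized to effect alleles first), plus one raw-dosage column per study
SNP that has no eQTL annotation. The pipeline then:

1. **Filters** uninformative columns with two-sided Mann-Whitney *U* tests
   (case vs control values) under Benjamini-Yekutieli FDR control
   (q < 0.05), the step-up procedure valid under arbitrary dependence.
2. **Fits** an elastic-net-penalized logistic regression on the
   standardized surviving features, tuning hyperparameters by 5-repeat
   10-fold stratified cross-validation with out-of-fold AUC as the
   objective; the 5 × 10 fold models form a 50-model ensemble.
3. **Decomposes** the final full-cohort model into tissue contributions:
   each tissue's weight is Σ |β| over its features (no-eQTL SNPs form
   their own group), reported as a fraction of the model's total
   coefficient mass and ranked; ranking stability is assessed across the
   50 ensemble models.
4. **Validates** by scoring held-out cohorts (stratified subsampling) and
   comparing against a conventional PRS (Σ β_GWAS × dosage).

AUCs use the rank identity AUC = U/(n₁n₀); confidence intervals use a
stratified bootstrap.

## Worked example

Simulate a cohort with a known architecture — 2000 cases / 2000 controls,
200 SNPs, 10 tissues, 12 causal eQTL features planted in `tissue_01` with
effect sizes calibrated to a population AUC of 0.70 — then run the full
pipeline:

```r
library(eqtlrisk)

cfg <- recovery_config(seed = 1)
tbl <- simulate_reference(cfg)
sim <- simulate_cohort(cfg, tbl)

fm <- build_feature_matrix(sim$genotypes, tbl)
#> <feature_matrix> 4000 samples x 538 features (raw)
#>   498 eQTL features, 40 SNP-only features

filt <- filter_features(fm, alpha = 0.05)
fms  <- standardize_features(filt$matrix)

ens <- cv_ensemble(fms, l1_ratio = 0.5, strength = 0.1,
                   repeats = 5, folds = 10, seed = 1)
#> <model_ensemble> 50 models (elastic_net, C = 0.1, l1_ratio = 0.5)
#>   out-of-fold AUC 0.707 +/- 0.024 (range 0.644-0.751)

model <- fit_risk_model(fms, l1_ratio = 0.5, strength = 0.1)
contrib <- tissue_contributions(model, fms$descriptors)
head(tibble::as_tibble(contrib), 5)
#> # A tibble: 5 x 5
#>   group     weight_sum fraction  rank n_features
#> 1 tissue_01      1.06    0.386      1         13
#> 2 tissue_09      0.423   0.154      2          7
#> 3 tissue_08      0.307   0.112      3          6
#> 4 tissue_03      0.234   0.0850     4          2
#> 5 tissue_06      0.223   0.0811     5          3
```

The out-of-fold AUC (0.707 ± 0.024) matches the generative population AUC
(0.706 for this seed), and the planted causal tissue `tissue_01` is ranked
first, carrying 39% of the model's coefficient mass.
`contribution_stability(ens, fms$descriptors)` repeats the decomposition
over all 50 ensemble models; `autoplot()` methods draw the contribution
bar chart, the stability box plots, and the ensemble AUC histogram. For
real data, start from `read_eqtl_table()`, `read_genotypes()` and
`harmonize_alleles()`, or drive everything from one `run_config()` via
`run_pipeline()`.

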