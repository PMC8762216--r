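small_cfg <- function(...) {
  args <- list(n_cases = 150, n_controls = 150, n_snps = 40,
               frac_eqtl_snps = 0.8, n_tissues = 5, triples_per_snp = 2,
               n_causal_features = 4)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

test_that("simulated reference tables respect the configuration", {
  cfg <- small_cfg(seed = 11)
  tbl <- simulate_reference(cfg)
  expect_s3_class(tbl, "eqtl_table")
  expect_equal(length(unique(tbl$snp)) + length(no_eqtl_snps(tbl)), 40)
  expect_true(all(abs(tbl$nes) >= 0.05))
  expect_true(all(tbl$fdr < 0.05))
  expect_true(all(tbl$tissue %in% sprintf("tissue_%02d", 1:5)))

  # all SNPs annotated -> empty no-eQTL set
  tbl_full <- simulate_reference(small_cfg(frac_eqtl_snps = 1, seed = 2))
  expect_length(no_eqtl_snps(tbl_full), 0)

  # degenerate count distribution -> exactly one record per eQTL SNP
  tbl_one <- simulate_reference(small_cfg(triples_per_snp = 1, seed = 3))
  expect_equal(nrow(tbl_one), length(unique(tbl_one$snp)))

  expect_identical(tibble::as_tibble(simulate_reference(cfg)),
                   tibble::as_tibble(tbl))
})

test_that("simulated cohorts honor quotas, determinism and missingness settings", {
  cfg <- small_cfg(seed = 21)
  tbl <- simulate_reference(cfg)
  sim <- simulate_cohort(cfg, tbl)
  gm <- sim$genotypes
  expect_equal(sum(gm$labels == 1L), 150)
  expect_equal(sum(gm$labels == 0L), 150)
  expect_false(anyNA(gm$dosages))
  expect_length(sim$truth$causal_feature_ids, 4)
  expect_length(sim$truth$generative_coefficients, 4)
  expect_true(all(abs(sim$truth$generative_coefficients) ==
                    sim$truth$effect_size))

  sim2 <- simulate_cohort(cfg, tbl)
  expect_identical(sim2$genotypes$dosages, gm$dosages)
  expect_identical(sim2$truth$population_auc, sim$truth$population_auc)

  cfg_miss <- small_cfg(seed = 21, missing_rate = 0.05)
  sim_miss <- simulate_cohort(cfg_miss, simulate_reference(cfg_miss))
  rate <- mean(is.na(sim_miss$genotypes$dosages))
  expect_gt(rate, 0.03); expect_lt(rate, 0.07)
})

test_that("sample allele frequencies converge to the drawn MAFs", {
  cfg <- sim_config(n_cases = 400, n_controls = 400, n_snps = 30,
                    n_causal_features = 0, n_tissues = 4, seed = 5)
  tbl <- simulate_reference(cfg)
  sim <- simulate_cohort(cfg, tbl)
  n <- nrow(sim$genotypes$dosages)
  af <- colMeans(sim$genotypes$dosages) / 2
  maf <- sim$truth$mafs[colnames(sim$genotypes$dosages)]
  binom_sd <- sqrt(maf * (1 - maf) / (2 * n))
  expect_true(all(abs(af - maf) <= 3.5 * binom_sd))
})

test_that("a null configuration yields labels independent of genotypes", {
  cfg <- small_cfg(n_causal_features = 0, seed = 31)
  tbl <- simulate_reference(cfg)
  sim <- simulate_cohort(cfg, tbl)
  expect_equal(sim$truth$population_auc, 0.5)
  expect_length(sim$truth$causal_feature_ids, 0)
})

test_that("effect-size calibration hits the target population AUC", {
  # analytic calibration vs the generator's realized score separation
  aucs <- vapply(1:10, function(s) {
    cfg <- sim_config(n_cases = 2000, n_controls = 2000, n_snps = 60,
                      n_tissues = 5, triples_per_snp = 2,
                      n_causal_features = 12, target_auc = 0.70, seed = s)
    tbl <- simulate_reference(cfg)
    simulate_cohort(cfg, tbl)$truth$population_auc
  }, numeric(1))
  expect_true(all(aucs >= 0.66 & aucs <= 0.74))
  expect_equal(mean(aucs), 0.70, tolerance = 0.02)
})

test_that("requesting more causal features than available errors", {
  cfg <- small_cfg(n_causal_features = 500, seed = 41)
  tbl <- simulate_reference(cfg)
  expect_error(simulate_cohort(cfg, tbl), class = "eqtlrisk_validation_error")
})

test_that("negative-control augmentation is append-only and label-independent", {
  cfg <- small_cfg(seed = 51)
  tbl <- simulate_reference(cfg)
  sim <- simulate_cohort(cfg, tbl)
  nc <- make_negative_control(cfg, tbl, sim$genotypes)
  expect_true(all(startsWith(nc$control_snp_ids, "ctrl_rs")))
  expect_length(intersect(nc$control_snp_ids, sim$genotypes$snp_ids), 0)
  # original dosages and records unchanged
  expect_identical(nc$genotypes$dosages[, sim$genotypes$snp_ids],
                   sim$genotypes$dosages)
  expect_identical(nc$genotypes$labels, sim$genotypes$labels)
  orig <- tibble::as_tibble(tbl)
  aug <- tibble::as_tibble(nc$table)
  expect_equal(aug[!startsWith(aug$snp, "ctrl_"), ], orig, ignore_attr = TRUE)
  # deterministic under the config seed
  nc2 <- make_negative_control(cfg, tbl, sim$genotypes)
  expect_identical(nc2$genotypes$dosages, nc$genotypes$dosages)
})

test_that("simulator output flows through data_io unchanged", {
  cfg <- small_cfg(seed = 61)
  tbl <- simulate_reference(cfg)
  sim <- simulate_cohort(cfg, tbl)
  gpath <- withr::local_tempfile(fileext = ".tsv")
  ppath <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(sim$genotypes, gpath, ppath)
  back <- read_genotypes(gpath, ppath, format = "tsv")
  expect_equal(back$dosages, sim$genotypes$dosages)
  # already harmonized: every action is "kept"
  h <- harmonize_alleles(back, tbl)
  expect_true(all(harmonization_report(h)$action == "kept"))
})
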