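test_that("eQTL table loading retains sub-threshold records and tracks no-eQTL SNPs", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(toy_eqtl_df(), path)
  tbl <- read_eqtl_table(path)
  expect_s3_class(tbl, "eqtl_table")
  expect_equal(nrow(tbl), 3)
  expect_length(no_eqtl_snps(tbl), 0)

  tbl2 <- read_eqtl_table(path, study_snps = c("rsA", "rsB", "rsX"))
  expect_equal(no_eqtl_snps(tbl2), "rsX")

  # rows at or above the FDR threshold are dropped; count checked by scan
  df <- toy_eqtl_df()
  df$fdr <- c(0.01, 0.2, 0.049)
  expected_kept <- sum(df$fdr < 0.05)
  tbl3 <- eqtl_table(df)
  expect_equal(nrow(tbl3), expected_kept)
  expect_false(any(tbl3$fdr >= 0.05))
})

test_that("eQTL table validation rejects malformed input", {
  df <- toy_eqtl_df()
  expect_error(eqtl_table(df[, -2]), class = "eqtlrisk_format_error")
  bad <- df; bad$nes <- as.character(bad$nes); bad$nes[2] <- "x"
  expect_error(eqtl_table(bad), class = "eqtlrisk_parse_error")
  expect_error(eqtl_table(rbind(df, df[1, ])), class = "eqtlrisk_validation_error")
  zero_nes <- df; zero_nes$nes[1] <- 0
  expect_error(eqtl_table(zero_nes), class = "eqtlrisk_validation_error")
})

test_that("eQTL table write/read round trip is lossless for retained records", {
  tbl <- toy_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_eqtl_table(tbl, path)
  back <- read_eqtl_table(path, study_snps = c("rsA", "rsB", "rsX"))
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(tbl))
  expect_equal(no_eqtl_snps(back), no_eqtl_snps(tbl))
})

test_that("dosage TSV round trip preserves dosages, alleles and labels", {
  gm <- toy_gm()
  gpath <- withr::local_tempfile(fileext = ".tsv")
  ppath <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(gm, gpath, ppath)
  back <- read_genotypes(gpath, ppath, format = "tsv")
  expect_equal(back$dosages, gm$dosages)
  expect_equal(back$counted_allele, gm$counted_allele)
  expect_equal(back$labels, gm$labels)

  # all-zero column and missing entries survive the dialect
  gm$dosages[, "rsX"] <- 0L
  gm$dosages[2, "rsA"] <- NA_integer_
  write_genotypes(gm, gpath, ppath)
  back <- read_genotypes(gpath, ppath, format = "tsv")
  expect_true(all(back$dosages[, "rsX"] == 0L))
  expect_true(is.na(back$dosages["s2", "rsA"]))
})

test_that("samples without phenotypes are dropped; disjoint cohorts are fatal", {
  gm <- toy_gm()
  gpath <- withr::local_tempfile(fileext = ".tsv")
  ppath <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(gm, gpath)
  readr::write_tsv(tibble::tibble(sample_id = c("s1", "s3"),
                                  status = c("case", "control")), ppath)
  expect_message(back <- read_genotypes(gpath, ppath, format = "tsv"),
                 "2 genotyped sample")
  expect_equal(back$sample_ids, c("s1", "s3"))

  readr::write_tsv(tibble::tibble(sample_id = "zz", status = "case"), ppath)
  expect_error(read_genotypes(gpath, ppath, format = "tsv"),
               class = "eqtlrisk_fatal_error")
  readr::write_tsv(tibble::tibble(sample_id = "s1", status = "affected"), ppath)
  expect_error(read_genotypes(gpath, ppath, format = "tsv"),
               class = "eqtlrisk_validation_error")
})

test_that("VCF loading counts ALT alleles and skips multi-allelic sites", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "1\t100\trsA\tG\tA\t.\tPASS\t.\tGT\t0/1\t1/1\t0/0",
    "1\t200\trsM\tG\tA,T\t.\tPASS\t.\tGT\t0/1\t0/2\t0/0",
    "1\t300\trsB\tC\tT\t.\tPASS\t.\tGT\t0|1\t./.\t1|1"
  ), vcf)
  ppath <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(sample_id = c("s1", "s2", "s3"),
                                  status = c("case", "case", "control")), ppath)
  expect_warning(gm <- read_genotypes(vcf, ppath, format = "vcf"),
                 "multi-allelic")
  expect_equal(sort(gm$snp_ids), c("rsA", "rsB"))
  expect_equal(unname(gm$dosages[, "rsA"]), c(1L, 2L, 0L))
  expect_equal(unname(gm$dosages[, "rsB"]), c(1L, NA, 2L))
  expect_equal(unname(gm$counted_allele["rsA"]), "A")
  expect_equal(unname(gm$other_allele["rsA"]), "G")
})

test_that("allele harmonization keeps, flips and drops correctly", {
  tbl <- toy_table()
  dos <- matrix(c(2L, 0L, 1L, 1L), nrow = 2,
                dimnames = list(c("s1", "s2"), c("rsA", "rsB")))
  gm <- genotype_matrix(dos,
                        counted_allele = c(rsA = "A", rsB = "G"),
                        other_allele = c(rsA = "G", rsB = "T"),
                        labels = c(s1 = 1L, s2 = 0L))
  out <- harmonize_alleles(gm, tbl)
  rep <- harmonization_report(out)
  # rsA counted allele already matches the effect allele
  expect_equal(rep$action[rep$snp == "rsA"], "kept")
  expect_equal(out$dosages[, "rsA"], gm$dosages[, "rsA"])
  # rsB counted G, effect T = other declared allele -> flip 2 - d
  expect_equal(rep$action[rep$snp == "rsB"], "flipped")
  expect_equal(unname(out$dosages[, "rsB"]), c(1L, 1L))
  expect_equal(unname(out$counted_allele["rsB"]), "T")

  # effect allele matching neither declared allele drops the SNP
  gm2 <- genotype_matrix(dos,
                         counted_allele = c(rsA = "C", rsB = "G"),
                         other_allele = c(rsA = "G", rsB = "T"),
                         labels = c(s1 = 1L, s2 = 0L))
  out2 <- harmonize_alleles(gm2, tbl)
  expect_false("rsA" %in% out2$snp_ids)
  expect_equal(harmonization_report(out2)$action[1], "dropped_unmatched")
})

test_that("flipping is an involution and strand-ambiguous SNPs are flagged", {
  # table whose effect allele is the cohort's other allele -> flip;
  # harmonizing the flipped matrix against a counted-allele table flips back
  df <- toy_eqtl_df()[3, ]
  df$snp <- "rsQ"; df$effect_allele <- "T"
  tbl_flip <- eqtl_table(df)
  df$effect_allele <- "G"
  tbl_back <- eqtl_table(df)
  dos <- matrix(c(2L, 1L, 0L, NA), ncol = 1,
                dimnames = list(paste0("s", 1:4), "rsQ"))
  gm <- genotype_matrix(dos, counted_allele = c(rsQ = "G"),
                        other_allele = c(rsQ = "T"))
  once <- harmonize_alleles(gm, tbl_flip)
  expect_equal(unname(once$dosages[, 1]), c(0L, 1L, 2L, NA))
  twice <- harmonize_alleles(once, tbl_back)
  expect_equal(twice$dosages, gm$dosages)
  expect_equal(twice$counted_allele, gm$counted_allele)

  # A/T pair: ambiguous, kept unflipped by default, dropped in strict mode
  df$effect_allele <- "T"
  tbl_at <- eqtl_table(df)
  gm_at <- genotype_matrix(dos, counted_allele = c(rsQ = "A"),
                           other_allele = c(rsQ = "T"))
  flagged <- harmonize_alleles(gm_at, tbl_at)
  expect_equal(harmonization_report(flagged)$action, "flagged_ambiguous")
  expect_equal(flagged$dosages, gm_at$dosages)
  dropped <- harmonize_alleles(gm_at, tbl_at, ambiguous = "drop")
  expect_length(dropped$snp_ids, 0)
})
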