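#' Construct an eQTL reference table
#'
#' An eQTL reference table maps SNPs to the (eGene, tissue) pairs whose
#' expression they modulate, with a signed normalized effect size (NES) per
#' association. Rows failing the association FDR threshold are dropped. SNPs
#' from `study_snps` without any retained association are tracked as
#' "no-eQTL" SNPs: downstream they contribute raw allele-count features
#' rather than NES-weighted features.
#'
#' @param data A data frame with columns `snp`, `effect_allele`, `gene`,
#'   `tissue`, `nes`, `fdr`.
#' @param study_snps Optional character vector of all SNPs in the study;
#'   those with no retained eQTL record become the no-eQTL set.
#' @param fdr_threshold Associations with `fdr >=` this value are dropped
#'   (default 0.05).
#'
#' @return A tibble of retained records with class `eqtl_table` and
#'   attribute `no_eqtl_snps` (character vector).
#' @export
eqtl_table <- function(data, study_snps = NULL, fdr_threshold = 0.05) {
  required <- c("snp", "effect_allele", "gene", "tissue", "nes", "fdr")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("eQTL table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "eqtlrisk_format_error")
  }
  tbl <- tibble::as_tibble(data)[required]
  for (col in c("nes", "fdr")) {
    parsed <- suppressWarnings(as.numeric(tbl[[col]]))
    bad <- which(is.na(parsed) & !is.na(tbl[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric %s value in eQTL table row %d: '%s'",
                    col, bad[1], as.character(tbl[[col]][bad[1]])),
            class = "eqtlrisk_parse_error")
    }
    tbl[[col]] <- parsed
  }
  if (any(!tbl$effect_allele %in% DNA_BASES)) {
    bad <- which(!tbl$effect_allele %in% DNA_BASES)[1]
    abort(sprintf("invalid effect allele '%s' in row %d (must be A/C/G/T)",
                  tbl$effect_allele[bad], bad),
          class = "eqtlrisk_validation_error")
  }
  if (any(!is.finite(tbl$nes)) || any(tbl$nes == 0)) {
    abort("NES values must be finite and non-zero",
          class = "eqtlrisk_validation_error")
  }
  if (any(tbl$fdr < 0 | tbl$fdr > 1)) {
    abort("FDR values must lie in [0, 1]", class = "eqtlrisk_validation_error")
  }
  key <- paste(tbl$snp, tbl$gene, tbl$tissue, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    abort(sprintf("duplicate (snp, gene, tissue) record: %s",
                  gsub("\r", " / ", dup, fixed = TRUE)),
          class = "eqtlrisk_validation_error")
  }
  kept <- tbl[tbl$fdr < fdr_threshold, ]
  no_eqtl <- character(0)
  if (!is.null(study_snps)) {
    no_eqtl <- sort(setdiff(unique(study_snps), unique(kept$snp)))
  }
  structure(kept,
            no_eqtl_snps = no_eqtl,
            fdr_threshold = fdr_threshold,
            class = c("eqtl_table", class(tibble::tibble())))
}

#' Read an eQTL reference table from TSV
#'
#' Expects a tab-separated file with header columns `snp`, `effect_allele`,
#' `gene`, `tissue`, `nes`, `fdr`.
#'
#' @inheritParams eqtl_table
#' @param path Path to the TSV file.
#' @return An [eqtl_table].
#' @export
read_eqtl_table <- function(path, study_snps = NULL, fdr_threshold = 0.05) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  eqtl_table(raw, study_snps = study_snps, fdr_threshold = fdr_threshold)
}

#' Write an eQTL reference table to TSV
#'
#' @param table An [eqtl_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eqtl_table <- function(table, path) {
  readr::write_tsv(tibble::as_tibble(table), path, progress = FALSE)
  invisible(path)
}

#' SNPs in an eQTL table without any retained association
#' @param table An [eqtl_table].
#' @return Character vector of no-eQTL SNP identifiers.
#' @export
no_eqtl_snps <- function(table) {
  attr(table, "no_eqtl_snps") %||% character(0)
}

#' Construct a genotype matrix object
#'
#' Holds per-individual allele-count dosages (0/1/2, `NA` for missing) for a
#' set of biallelic SNPs, together with binary case/control labels and the
#' identity of the counted allele at each SNP.
#'
#' @param dosages Integer matrix, samples x SNPs, entries in {0,1,2,NA};
#'   rownames are sample ids, colnames SNP ids.
#' @param counted_allele Named character vector (per SNP): the allele whose
#'   copies `dosages` counts.
#' @param other_allele Named character vector (per SNP): the second declared
#'   allele; `NA` when unknown.
#' @param labels Named integer vector (per sample): 1 = case, 0 = control.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, counted_allele, other_allele = NULL,
                            labels = NULL) {
  stopifnot(is.matrix(dosages))
  snp_ids <- colnames(dosages) %||% character(0)
  sample_ids <- rownames(dosages)
  if ((ncol(dosages) > 0 && length(snp_ids) == 0) || is.null(sample_ids)) {
    abort("dosage matrix must have sample rownames and SNP colnames")
  }
  ok <- dosages %in% c(0L, 1L, 2L) | is.na(dosages)
  if (!all(ok)) {
    abort("dosages must be 0, 1, 2 or NA", class = "eqtlrisk_validation_error")
  }
  if (is.null(other_allele)) {
    other_allele <- setNames(rep(NA_character_, length(snp_ids)), snp_ids)
  }
  counted_allele <- counted_allele[snp_ids]
  other_allele <- other_allele[snp_ids]
  if (!is.null(labels)) {
    labels <- labels[sample_ids]
    if (anyNA(labels)) abort("every sample needs a phenotype label")
    if (!all(labels %in% c(0L, 1L))) {
      abort("labels must be 0 (control) or 1 (case)",
            class = "eqtlrisk_validation_error")
    }
  }
  structure(list(dosages = dosages,
                 counted_allele = counted_allele,
                 other_allele = other_allele,
                 labels = labels,
                 sample_ids = sample_ids,
                 snp_ids = snp_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  n_case <- if (is.null(x$labels)) NA_integer_ else sum(x$labels == 1L)
  n_ctrl <- if (is.null(x$labels)) NA_integer_ else sum(x$labels == 0L)
  cat(sprintf("<genotype_matrix> %d samples (%s cases / %s controls) x %d SNPs\n",
              length(x$sample_ids), n_case, n_ctrl, length(x$snp_ids)))
  n_miss <- sum(is.na(x$dosages))
  if (n_miss > 0) cat(sprintf("  %d missing dosage entries\n", n_miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

read_phenotypes <- function(path) {
  ph <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (!all(c("sample_id", "status") %in% names(ph))) {
    abort("phenotype table needs columns sample_id, status",
          class = "eqtlrisk_format_error")
  }
  bad <- setdiff(unique(ph$status), c("case", "control"))
  if (length(bad) > 0) {
    abort(sprintf("phenotype status must be 'case' or 'control'; found '%s'", bad[1]),
          class = "eqtlrisk_validation_error")
  }
  setNames(as.integer(ph$status == "case"), ph$sample_id)
}

#' Read case/control genotypes
#'
#' Loads dosages either from a dosage TSV or a VCF, attaching phenotypes from
#' a two-column TSV (`sample_id`, `status` in \{case, control\}). Samples
#' without a phenotype are dropped with a message; multi-allelic VCF records
#' are skipped with a warning.
#'
#' The dosage TSV dialect: tab-separated with a header row (`sample_id`
#' followed by one column per SNP), `NA` for missing entries, and two
#' metadata rows whose `sample_id` fields are `#counted_allele` and
#' `#other_allele` declaring the alleles at each SNP (`other_allele` entries
#' may be `NA`). VCF dosages count copies of the ALT allele.
#'
#' @param path Genotype file path (TSV or VCF; VCF may be gzipped).
#' @param phenotype_path Path to the phenotype TSV.
#' @param format `"tsv"` or `"vcf"`.
#' @return A [genotype_matrix] with labels attached.
#' @export
read_genotypes <- function(path, phenotype_path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  labels <- read_phenotypes(phenotype_path)
  gm <- if (format == "tsv") read_genotypes_tsv(path) else read_genotypes_vcf(path)
  shared <- intersect(gm$sample_ids, names(labels))
  if (length(shared) == 0) {
    abort("no overlapping samples between genotypes and phenotypes",
          class = "eqtlrisk_fatal_error")
  }
  n_dropped <- length(gm$sample_ids) - length(shared)
  if (n_dropped > 0) {
    inform(sprintf("dropping %d genotyped sample(s) without a phenotype", n_dropped))
  }
  genotype_matrix(gm$dosages[shared, , drop = FALSE],
                  gm$counted_allele, gm$other_allele,
                  labels = labels[shared])
}

read_genotypes_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = "NA")
  if (names(raw)[1] != "sample_id") {
    abort("dosage TSV must start with a sample_id column",
          class = "eqtlrisk_format_error")
  }
  snp_ids <- names(raw)[-1]
  meta <- raw[startsWith(raw$sample_id, "#"), ]
  body <- raw[!startsWith(raw$sample_id, "#"), ]
  pick_meta <- function(tag) {
    row <- meta[meta$sample_id == tag, ]
    if (nrow(row) == 0) return(setNames(rep(NA_character_, length(snp_ids)), snp_ids))
    setNames(as.character(row[1, -1]), snp_ids)
  }
  counted <- pick_meta("#counted_allele")
  if (anyNA(counted)) {
    abort("dosage TSV must declare a #counted_allele row",
          class = "eqtlrisk_format_error")
  }
  dos <- as.matrix(body[, -1, drop = FALSE])
  storage.mode(dos) <- "integer"
  rownames(dos) <- body$sample_id
  colnames(dos) <- snp_ids
  genotype_matrix(dos, counted, pick_meta("#other_allele"))
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warn(sprintf("skipping %d multi-allelic VCF site(s)", sum(multi)))
  }
  keep <- !multi
  gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  snp_ids <- fix[, "ID"]
  snp_ids[is.na(snp_ids) | snp_ids == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(snp_ids) | snp_ids == "."]
  # count ALT alleles in the GT string; NA for missing calls
  count_alt <- function(g) {
    out <- rep(NA_integer_, length(g))
    known <- !is.na(g) & !grepl("\\.", g)
    alleles <- strsplit(gsub("\\|", "/", g[known]), "/", fixed = FALSE)
    out[known] <- vapply(alleles, function(a) sum(a == "1"), integer(1))
    out
  }
  dos <- t(matrix(count_alt(as.vector(gt)), nrow = nrow(gt)))  # samples x SNPs
  rownames(dos) <- colnames(gt)
  colnames(dos) <- snp_ids
  genotype_matrix(dos,
                  counted_allele = setNames(fix[, "ALT"], snp_ids),
                  other_allele = setNames(fix[, "REF"], snp_ids))
}

#' Write genotypes (and phenotypes) in the dosage TSV dialect
#'
#' @param gm A [genotype_matrix].
#' @param path Output dosage TSV path.
#' @param phenotype_path Optional path for a phenotype TSV.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, phenotype_path = NULL) {
  meta <- tibble::tibble(sample_id = c("#counted_allele", "#other_allele"))
  body <- tibble::tibble(sample_id = gm$sample_ids)
  for (s in gm$snp_ids) {
    meta[[s]] <- c(gm$counted_allele[[s]], gm$other_allele[[s]])
    body[[s]] <- gm$dosages[, s]
  }
  readr::write_tsv(rbind(meta, body), path, na = "NA", progress = FALSE)
  if (!is.null(phenotype_path) && !is.null(gm$labels)) {
    readr::write_tsv(tibble::tibble(
      sample_id = gm$sample_ids,
      status = ifelse(gm$labels == 1L, "case", "control")
    ), phenotype_path, progress = FALSE)
  }
  invisible(path)
}

#' Harmonize genotype dosages to eQTL effect alleles
#'
#' NES values are signed relative to a designated effect allele, so dosages
#' must count copies of that same allele. For each SNP shared with the
#' reference table: if the counted allele already is the effect allele the
#' SNP is kept; if the effect allele is the *other* declared allele the
#' dosage is flipped (`d -> 2 - d`) unless the SNP is strand-ambiguous
#' (A/T or C/G pair); if the effect allele matches neither declared allele
#' the SNP is dropped. Strand-ambiguous SNPs are by default kept unflipped
#' and flagged; `ambiguous = "drop"` removes them instead.
#'
#' @param gm A [genotype_matrix].
#' @param table An [eqtl_table].
#' @param ambiguous `"flag"` (default) or `"drop"`.
#' @return The harmonized [genotype_matrix]; attribute
#'   `harmonization_report` holds a tibble (`snp`, `action`) with actions in
#'   \{kept, flipped, dropped_unmatched, flagged_ambiguous\}.
#' @export
harmonize_alleles <- function(gm, table, ambiguous = c("flag", "drop")) {
  ambiguous <- match.arg(ambiguous)
  effect <- tapply(table$effect_allele, table$snp, function(a) a[1])
  actions <- setNames(rep("kept", length(gm$snp_ids)), gm$snp_ids)
  dos <- gm$dosages
  counted <- gm$counted_allele
  other <- gm$other_allele
  for (s in intersect(gm$snp_ids, names(effect))) {
    ea <- effect[[s]]
    if (identical(counted[[s]], ea)) next
    if (identical(other[[s]], ea)) {
      if (is_strand_ambiguous(counted[[s]], other[[s]])) {
        if (ambiguous == "drop") actions[s] <- "dropped_unmatched"
        else actions[s] <- "flagged_ambiguous"
        next
      }
      miss <- is.na(dos[, s])
      dos[, s] <- 2L - dos[, s]
      dos[miss, s] <- NA_integer_
      tmp <- counted[[s]]
      counted[[s]] <- other[[s]]
      other[[s]] <- tmp
      actions[s] <- "flipped"
    } else {
      actions[s] <- "dropped_unmatched"
    }
  }
  keep <- names(actions)[actions != "dropped_unmatched"]
  out <- genotype_matrix(dos[, keep, drop = FALSE],
                         counted[keep], other[keep], gm$labels)
  attr(out, "harmonization_report") <-
    tibble::tibble(snp = names(actions), action = unname(actions))
  out
}

#' Harmonization audit trail
#' @param gm A harmonized [genotype_matrix].
#' @return Tibble with columns `snp`, `action`, or `NULL` if never harmonized.
#' @export
harmonization_report <- function(gm) attr(gm, "harmonization_report")
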