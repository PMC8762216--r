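#' Build the weighted genotype-eQTL effect matrix
#'
#' One column per (SNP, eGene, tissue) eQTL association, valued
#' `dosage x NES`, plus one raw-dosage column per genotyped no-eQTL SNP.
#' Missing dosages are filled with the per-SNP mean over non-missing samples
#' before weighting, so downstream filtering and model fitting see complete
#' data. eQTL feature ids are `"<snp>|<gene>|<tissue>"`; no-eQTL SNP
#' feature ids are `"<snp>_<allele>"`.
#'
#' Column order: eQTL features sorted by (snp, gene, tissue), then no-eQTL
#' SNP features sorted by snp. SNPs referenced by the table but absent from
#' the genotypes are skipped and counted in the build report; samples with
#' every dosage missing are dropped with a warning.
#'
#' @param gm A [genotype_matrix] already harmonized to effect alleles.
#' @param table An [eqtl_table].
#' @return A `feature_matrix` object: list with `values` (samples x
#'   features), `descriptors` (tibble: feature_id, kind, snp, gene, tissue,
#'   nes, allele), `labels`, `sample_ids`, `column_stats` (NULL until
#'   [standardize_features()]). Attribute `build_report` lists feature and
#'   skip counts.
#' @export
build_feature_matrix <- function(gm, table) {
  rec <- tibble::as_tibble(table)
  rec <- rec[order(rec$snp, rec$gene, rec$tissue), ]
  genotyped <- rec$snp %in% gm$snp_ids
  skipped_eqtl_snps <- setdiff(unique(rec$snp[!genotyped]), character(0))
  rec <- rec[genotyped, ]
  ne <- no_eqtl_snps(table)
  ne_genotyped <- sort(intersect(ne, gm$snp_ids))
  skipped_ne <- setdiff(ne, ne_genotyped)

  dos <- gm$dosages
  all_missing <- rowSums(!is.na(dos)) == 0
  if (any(all_missing)) {
    warn(sprintf("dropping %d sample(s) with all dosages missing", sum(all_missing)))
    dos <- dos[!all_missing, , drop = FALSE]
  }
  # per-SNP mean-dosage fill (training-cohort means)
  dosf <- apply(dos, 2, function(col) {
    if (anyNA(col)) col[is.na(col)] <- mean(col, na.rm = TRUE)
    as.numeric(col)
  })
  dosf <- matrix(dosf, nrow = nrow(dos),
                 dimnames = list(rownames(dos), colnames(dos)))

  n_feat <- nrow(rec) + length(ne_genotyped)
  if (n_feat == 0) {
    abort("no features could be created from this genotype/table pair",
          class = "eqtlrisk_fatal_error")
  }
  values <- matrix(0, nrow = nrow(dosf), ncol = n_feat)
  rownames(values) <- rownames(dosf)
  if (nrow(rec) > 0) {
    values[, seq_len(nrow(rec))] <-
      dosf[, rec$snp, drop = FALSE] * rep(rec$nes, each = nrow(dosf))
  }
  if (length(ne_genotyped) > 0) {
    values[, nrow(rec) + seq_along(ne_genotyped)] <-
      dosf[, ne_genotyped, drop = FALSE]
  }
  descriptors <- rbind(
    tibble::tibble(
      feature_id = paste(rec$snp, rec$gene, rec$tissue, sep = "|"),
      kind = rep("eqtl", nrow(rec)),
      snp = rec$snp, gene = rec$gene, tissue = rec$tissue,
      nes = rec$nes, allele = rec$effect_allele),
    tibble::tibble(
      feature_id = paste0(ne_genotyped, "_", gm$counted_allele[ne_genotyped]),
      kind = rep("snp_only", length(ne_genotyped)),
      snp = ne_genotyped,
      gene = NA_character_, tissue = NA_character_, nes = NA_real_,
      allele = unname(gm$counted_allele[ne_genotyped]))
  )
  if (anyDuplicated(descriptors$feature_id)) {
    abort("duplicate feature ids generated; check the reference table")
  }
  colnames(values) <- descriptors$feature_id
  labels <- if (is.null(gm$labels)) NULL else gm$labels[rownames(values)]
  out <- structure(list(values = values,
                        descriptors = descriptors,
                        labels = labels,
                        sample_ids = rownames(values),
                        column_stats = NULL),
                   class = "feature_matrix")
  attr(out, "build_report") <- list(
    n_eqtl_features = nrow(rec),
    n_snp_only_features = length(ne_genotyped),
    skipped_snps = sort(unique(c(skipped_eqtl_snps, skipped_ne))))
  out
}

#' @export
print.feature_matrix <- function(x, ...) {
  std <- if (is.null(x$column_stats)) "raw" else "standardized"
  cat(sprintf("<feature_matrix> %d samples x %d features (%s)\n",
              nrow(x$values), ncol(x$values), std))
  cat(sprintf("  %d eQTL features, %d SNP-only features\n",
              sum(x$descriptors$kind == "eqtl"),
              sum(x$descriptors$kind == "snp_only")))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Feature matrix as a tibble
#'
#' @param x A `feature_matrix`.
#' @param ... Unused.
#' @return A tibble with `sample_id`, `label`, and one column per feature.
#' @export
as_tibble.feature_matrix <- function(x, ...) {
  out <- tibble::as_tibble(x$values)
  tibble::add_column(out,
                     sample_id = x$sample_ids,
                     label = if (is.null(x$labels)) NA_integer_ else unname(x$labels),
                     .before = 1)
}

#' Standardize feature columns
#'
#' Transforms each column to zero mean and unit variance using that
#' matrix's own per-column statistics, recording them so the identical
#' transform can be replayed on a validation cohort (see [predict_risk()]).
#' The population (divide-by-n) standard deviation convention is used so
#' replays are bit-stable. Constant columns are set to all-zero and flagged
#' as degenerate. Standardizing an already-standardized matrix is an error.
#'
#' @param fm A `feature_matrix` with empty `column_stats`.
#' @return The standardized `feature_matrix`; `column_stats` is a tibble
#'   with `feature_id`, `mean`, `sd`, `degenerate`.
#' @export
standardize_features <- function(fm) {
  if (!is.null(fm$column_stats)) {
    abort("feature matrix is already standardized",
          class = "eqtlrisk_validation_error")
  }
  n <- nrow(fm$values)
  mu <- colMeans(fm$values)
  sdev <- sqrt(colMeans(fm$values^2) - mu^2)
  sdev[sdev < 0] <- 0  # guard tiny negative rounding
  degen <- sdev == 0
  fm$values <- sweep(fm$values, 2, mu, "-")
  scale_by <- ifelse(degen, 1, sdev)
  fm$values <- sweep(fm$values, 2, scale_by, "/")
  fm$values[, degen] <- 0
  fm$column_stats <- tibble::tibble(
    feature_id = fm$descriptors$feature_id,
    mean = unname(mu), sd = unname(sdev), degenerate = unname(degen))
  fm
}

apply_column_stats <- function(values, stats) {
  stats <- stats[match(colnames(values), stats$feature_id), ]
  values <- sweep(values, 2, stats$mean, "-")
  values <- sweep(values, 2, ifelse(stats$degenerate, 1, stats$sd), "/")
  values[, stats$degenerate] <- 0
  values
}

#' Write / read a feature matrix
#'
#' Two-file store: `<prefix>.tsv` holds the value matrix (first column
#' `sample_id`, then one column per feature), `<prefix>.json` holds
#' descriptors, labels, column statistics and an md5 checksum of the TSV.
#' The round trip is lossless (values serialized at full precision).
#'
#' @param fm A `feature_matrix`.
#' @param prefix Path prefix (without extension).
#' @return `write_feature_matrix`: `prefix`, invisibly.
#'   `read_feature_matrix`: the restored `feature_matrix`.
#' @export
write_feature_matrix <- function(fm, prefix) {
  tsv <- paste0(prefix, ".tsv")
  json <- paste0(prefix, ".json")
  df <- tibble::as_tibble(fm$values)
  df <- tibble::add_column(df, sample_id = fm$sample_ids, .before = 1)
  # full-precision serialization so the round trip is exact
  for (j in seq(2, ncol(df))) df[[j]] <- sprintf("%.17g", df[[j]])
  readr::write_tsv(df, tsv, progress = FALSE)
  meta <- list(
    descriptors = fm$descriptors,
    labels = if (is.null(fm$labels)) NULL else
      list(sample_id = fm$sample_ids, label = unname(fm$labels)),
    column_stats = fm$column_stats,
    n_samples = nrow(fm$values),
    n_features = ncol(fm$values),
    checksum = unname(tools::md5sum(tsv)))
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(prefix) {
  tsv <- paste0(prefix, ".tsv")
  json <- paste0(prefix, ".json")
  if (!file.exists(tsv) || !file.exists(json)) {
    abort("feature matrix store is incomplete", class = "eqtlrisk_corrupt_error")
  }
  meta <- jsonlite::read_json(json, simplifyVector = TRUE)
  if (!identical(unname(tools::md5sum(tsv)), meta$checksum)) {
    abort("feature matrix TSV does not match its recorded checksum",
          class = "eqtlrisk_corrupt_error")
  }
  df <- readr::read_tsv(tsv, col_types = readr::cols(
    sample_id = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$sample_id
  if (nrow(values) != meta$n_samples || ncol(values) != meta$n_features) {
    abort("feature matrix shape does not match its sidecar",
          class = "eqtlrisk_corrupt_error")
  }
  labels <- NULL
  if (!is.null(meta$labels)) {
    labels <- setNames(as.integer(meta$labels$label), meta$labels$sample_id)
  }
  cs <- NULL
  if (!is.null(meta$column_stats)) cs <- tibble::as_tibble(meta$column_stats)
  structure(list(values = values,
                 descriptors = tibble::as_tibble(meta$descriptors),
                 labels = labels,
                 sample_ids = df$sample_id,
                 column_stats = cs),
            class = "feature_matrix")
}

# Restrict a feature matrix to a subset of features and/or samples.
subset_features <- function(fm, feature_ids = NULL, sample_idx = NULL) {
  if (!is.null(feature_ids)) {
    keep <- fm$descriptors$feature_id %in% feature_ids
    fm$values <- fm$values[, keep, drop = FALSE]
    fm$descriptors <- fm$descriptors[keep, ]
    if (!is.null(fm$column_stats)) fm$column_stats <- fm$column_stats[keep, ]
  }
  if (!is.null(sample_idx)) {
    fm$values <- fm$values[sample_idx, , drop = FALSE]
    fm$sample_ids <- fm$sample_ids[sample_idx]
    if (!is.null(fm$labels)) fm$labels <- fm$labels[sample_idx]
  }
  fm
}
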