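#' End-to-end run configuration
#'
#' Exactly one input mode must be given: a [sim_config()] (synthetic
#' cohort) or a `paths` list naming real input files
#' (`eqtl`, `genotypes`, `phenotypes`, optional `format`).
#'
#' @param sim Optional [sim_config()].
#' @param paths Optional list of input paths.
#' @param alpha Mann-Whitney/BY FDR threshold.
#' @param grid Hyperparameter grid (see [hyper_grid()]); a one-row grid
#'   skips tuning and fits directly at that point.
#' @param repeats,folds Cross-validation design.
#' @param seed Seed for folds and validation subsampling.
#' @param standardize Standardize features before fitting (default TRUE).
#' @param validation Optional list: `n_subsets`, `n_cases`, `n_controls`
#'   (subsampled-validation scheme; synthetic mode simulates a matched
#'   validation cohort).
#' @return A validated `run_config`.
#' @export
run_config <- function(sim = NULL, paths = NULL, alpha = 0.05,
                       grid = hyper_grid(), repeats = 5, folds = 10,
                       seed = 1, standardize = TRUE, validation = NULL) {
  if (is.null(sim) == is.null(paths)) {
    abort("exactly one of `sim` or `paths` must be given",
          class = "eqtlrisk_validation_error")
  }
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  if (!is.null(paths)) {
    stopifnot(all(c("eqtl", "genotypes", "phenotypes") %in% names(paths)))
  }
  if (!is.null(validation)) {
    stopifnot(all(c("n_subsets", "n_cases", "n_controls") %in% names(validation)))
  }
  structure(list(sim = sim, paths = paths, alpha = alpha, grid = grid,
                 repeats = repeats, folds = folds, seed = as.integer(seed),
                 standardize = standardize, validation = validation),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> harmonize -> build feature matrix ->
#' Mann-Whitney/BY filter -> tune/fit the cross-validation ensemble ->
#' final full-cohort fit -> tissue contributions (+ ensemble stability) ->
#' optional subsampled validation, writing every artifact and a manifest
#' (stage file checksums, seeds, package version) to `out_dir`. Re-running
#' with the same config and seed reproduces byte-identical artifacts.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with all in-memory results (`table`, `gm`,
#'   `fm`, `filter`, `tuned`, `model`, `contributions`, `stability`,
#'   `validation`, `manifest`).
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  art <- function(...) file.path(out_dir, ...)
  stage <- "inputs"
  res <- tryCatch({
    if (!is.null(cfg$sim)) {
      table <- simulate_reference(cfg$sim)
      sim <- simulate_cohort(cfg$sim, table)
      gm <- sim$genotypes
      truth <- sim$truth
    } else {
      table <- read_eqtl_table(cfg$paths$eqtl)
      gm <- read_genotypes(cfg$paths$genotypes, cfg$paths$phenotypes,
                           format = cfg$paths$format %||% "tsv")
      gm <- harmonize_alleles(gm, table)
      truth <- NULL
    }
    write_eqtl_table(table, art("eqtl_table.tsv"))
    write_genotypes(gm, art("genotypes.tsv"), art("phenotypes.tsv"))

    stage <- "feature_matrix"
    fm <- build_feature_matrix(gm, table)
    if (cfg$standardize) fm_std <- standardize_features(fm) else fm_std <- fm
    write_feature_matrix(fm_std, art("feature_matrix"))

    stage <- "filter"
    filt <- filter_features(fm_std, alpha = cfg$alpha)
    write_filter_report(filt$results, art("filter_report.tsv"))

    stage <- "tune"
    if (nrow(cfg$grid) > 1) {
      tuned <- tune_risk_model(filt$matrix, grid = cfg$grid,
                               repeats = cfg$repeats, folds = cfg$folds,
                               seed = cfg$seed)
    } else {
      ens <- cv_ensemble(filt$matrix, l1_ratio = cfg$grid$l1_ratio,
                         strength = cfg$grid$strength,
                         repeats = cfg$repeats, folds = cfg$folds,
                         seed = cfg$seed)
      tuned <- list(best = dplyr::mutate(cfg$grid, mean_auc = ens$mean_auc),
                    ensemble = ens, grid_results = NULL)
    }
    readr::write_tsv(tuned$ensemble$fold_info, art("ensemble_aucs.tsv"),
                     progress = FALSE)

    stage <- "fit"
    model <- fit_risk_model(filt$matrix, l1_ratio = tuned$best$l1_ratio,
                            strength = tuned$best$strength)
    write_risk_model(model, art("model.json"))

    stage <- "contributions"
    contrib <- tissue_contributions(model, filt$matrix$descriptors)
    stability <- contribution_stability(tuned$ensemble, filt$matrix$descriptors)
    write_contribution_report(contrib, art("contributions.tsv"),
                              art("contribution_members.tsv"))
    readr::write_tsv(tibble::as_tibble(stability), art("contribution_stability.tsv"),
                     progress = FALSE)

    stage <- "validation"
    validation <- NULL
    if (!is.null(cfg$validation)) {
      if (!is.null(cfg$sim)) {
        vcfg <- cfg$sim
        vcfg$seed <- derive_seed(cfg$sim$seed, 7L)
        vsim <- simulate_cohort(vcfg, table)
        vgm <- vsim$genotypes
      } else {
        vgm <- gm
      }
      validation <- subsample_validation(
        model, vgm, table,
        n_subsets = cfg$validation$n_subsets,
        n_cases = cfg$validation$n_cases,
        n_controls = cfg$validation$n_controls,
        seed = derive_seed(cfg$seed, 8L),
        ensemble = tuned$ensemble)
      readr::write_tsv(validation$aucs, art("validation_aucs.tsv"),
                       progress = FALSE)
    }

    stage <- "manifest"
    files <- c("eqtl_table.tsv", "genotypes.tsv", "phenotypes.tsv",
               "feature_matrix.tsv", "feature_matrix.json",
               "filter_report.tsv", "ensemble_aucs.tsv", "model.json",
               "contributions.tsv", "contribution_members.tsv",
               "contribution_stability.tsv",
               if (!is.null(validation)) "validation_aucs.tsv")
    manifest <- list(
      seed = cfg$seed,
      alpha = cfg$alpha,
      standardize = cfg$standardize,
      package_version = as.character(utils::packageVersion("eqtlrisk")),
      artifacts = lapply(setNames(nm = files), function(f) {
        list(md5 = unname(tools::md5sum(art(f))))
      }))
    jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                         digits = NA)
    list(table = table, gm = gm, truth = truth, fm = fm_std, filter = filt,
         tuned = tuned, model = model, contributions = contrib,
         stability = stability, validation = validation, manifest = manifest)
  }, error = function(e) {
    if (inherits(e, "eqtlrisk_stage_error")) stop(e)
    abort(sprintf("pipeline failed at stage '%s' (partial outputs in %s): %s",
                  stage, out_dir, conditionMessage(e)),
          class = "eqtlrisk_stage_error", parent = e)
  })
  invisible(res)
}

#' Subsampled validation of a fitted model
#'
#' Draws `n_subsets` stratified random subsets (without replacement within
#' a subset, independently across subsets) from a validation cohort, scores
#' each with [predict_risk()], and reports per-subset AUCs and their mean.
#' When the training ensemble is supplied, the summary compares the mean
#' subset AUC against the ensemble's fold-AUC 2.5-97.5 percentile range.
#'
#' @param model A `risk_model`.
#' @param gm Validation cohort [genotype_matrix] (harmonized).
#' @param table The [eqtl_table] used in training.
#' @param n_subsets Number of subsets.
#' @param n_cases,n_controls Per-subset class sizes.
#' @param seed RNG seed for subset draws.
#' @param ensemble Optional training `model_ensemble` for the range
#'   comparison.
#' @return List: `aucs` (tibble `subset`, `auc`), `summary` (one-row
#'   tibble: `mean_auc`, `sd_auc`, and — given an ensemble —
#'   `ensemble_lo`, `ensemble_hi`, `within_ensemble_range`).
#' @export
subsample_validation <- function(model, gm, table, n_subsets, n_cases,
                                 n_controls, seed = 1, ensemble = NULL) {
  fm <- build_feature_matrix(gm, table)
  scores <- predict_risk(model, fm)$risk_score
  labels <- unname(fm$labels)
  case_i <- which(labels == 1L); ctrl_i <- which(labels == 0L)
  if (n_cases > length(case_i) || n_controls > length(ctrl_i)) {
    abort("subset sizes exceed validation cohort class counts",
          class = "eqtlrisk_validation_error")
  }
  aucs <- withr::with_seed(seed, {
    vapply(seq_len(n_subsets), function(b) {
      idx <- c(sample(case_i, n_cases), sample(ctrl_i, n_controls))
      rank_auc(scores[idx], labels[idx])
    }, numeric(1))
  })
  out <- tibble::tibble(subset = seq_len(n_subsets), auc = aucs)
  summary <- tibble::tibble(mean_auc = mean(aucs),
                            sd_auc = if (n_subsets > 1) sd(aucs) else NA_real_)
  if (!is.null(ensemble)) {
    rng <- unname(quantile(ensemble$fold_aucs, c(0.025, 0.975), type = 7))
    summary$ensemble_lo <- rng[1]
    summary$ensemble_hi <- rng[2]
    summary$within_ensemble_range <-
      summary$mean_auc >= rng[1] & summary$mean_auc <= rng[2]
  }
  list(aucs = out, summary = summary)
}
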