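#' Per-tissue risk contributions of a fitted model
#'
#' Decomposes a fitted risk model into grouped contributions: every eQTL
#' feature with a nonzero coefficient counts toward its tissue, and
#' SNP-only features form the `"no_eqtl_snps"` group. A group's weight is
#' the sum of the absolute values of its members' coefficients; fractions
#' are relative to the total coefficient mass (the intercept is excluded —
#' it is not attributable to any tissue). Ranks run 1..K by descending
#' weight, ties broken alphabetically by group label. A feature's SNP may
#' drive several tissues; each (SNP, gene, tissue) coefficient counts only
#' toward its own tissue.
#'
#' @param model A `risk_model`.
#' @param descriptors The `descriptors` tibble of the feature matrix the
#'   model was fitted on (must cover every nonzero-coefficient feature).
#' @return A `contribution_report` tibble: `group`, `weight_sum`,
#'   `fraction`, `rank`, `n_features`; attributes `members` (tibble
#'   `group`, `feature_id`, `coefficient`) and `total_weight`. An all-zero
#'   model yields an explicit empty report (zero rows, `total_weight` NA).
#' @export
tissue_contributions <- function(model, descriptors) {
  nz <- model$coefficients[model$coefficients != 0]
  if (length(nz) == 0) {
    out <- tibble::tibble(group = character(0), weight_sum = numeric(0),
                          fraction = numeric(0), rank = integer(0),
                          n_features = integer(0))
    attr(out, "members") <- tibble::tibble(group = character(0),
                                           feature_id = character(0),
                                           coefficient = numeric(0))
    attr(out, "total_weight") <- NA_real_
    class(out) <- c("contribution_report", class(tibble::tibble()))
    return(out)
  }
  d <- descriptors[match(names(nz), descriptors$feature_id), ]
  if (anyNA(d$feature_id)) {
    abort("descriptors do not cover every nonzero-coefficient feature",
          class = "eqtlrisk_validation_error")
  }
  members <- tibble::tibble(
    group = ifelse(d$kind == "eqtl", d$tissue, "no_eqtl_snps"),
    feature_id = names(nz),
    coefficient = unname(nz))
  total <- sum(abs(members$coefficient))
  report <- members |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(weight_sum = sum(abs(.data$coefficient)),
                     n_features = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(fraction = .data$weight_sum / total) |>
    dplyr::arrange(dplyr::desc(.data$weight_sum), .data$group) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("group", "weight_sum", "fraction", "rank", "n_features")
  attr(report, "members") <- members
  attr(report, "total_weight") <- total
  class(report) <- c("contribution_report", class(tibble::tibble()))
  report
}

#' Members of a contribution report
#' @param report A `contribution_report`.
#' @return Tibble `group`, `feature_id`, `coefficient`.
#' @export
contribution_members <- function(report) attr(report, "members")

#' Contribution-ranking stability across a cross-validation ensemble
#'
#' Recomputes the per-group contribution fractions for every model of the
#' ensemble (a group absent from a model — all coefficients zero —
#' contributes fraction 0), and summarizes each group's 50 fractions as
#' mean and sd together with a rank histogram. The consensus ranking orders
#' groups by mean fraction (ties alphabetical).
#'
#' @param ensemble A `model_ensemble`.
#' @param descriptors Feature descriptors (as for [tissue_contributions()]).
#' @return A `contribution_stability` tibble: `group`, `mean_fraction`,
#'   `sd_fraction`, `consensus_rank`; attributes `per_model` (long tibble
#'   of model x group fractions) and `rank_counts` (tibble `group`,
#'   `rank`, `n`).
#' @export
contribution_stability <- function(ensemble, descriptors) {
  if (length(ensemble$models) == 0) {
    abort("empty ensemble", class = "eqtlrisk_validation_error")
  }
  per_model <- purrr::imap(ensemble$models, function(m, i) {
    rep_i <- tissue_contributions(m, descriptors)
    if (nrow(rep_i) == 0) return(NULL)
    tibble::tibble(model = i, group = rep_i$group, fraction = rep_i$fraction,
                   rank = rep_i$rank)
  }) |> dplyr::bind_rows()
  if (nrow(per_model) == 0) {
    # every model is intercept-only: no attributable weight anywhere
    out <- tibble::tibble(group = character(0), mean_fraction = numeric(0),
                          sd_fraction = numeric(0), consensus_rank = integer(0))
    attr(out, "per_model") <- tibble::tibble(model = integer(0),
                                             group = character(0),
                                             fraction = numeric(0))
    attr(out, "rank_counts") <- tibble::tibble(group = character(0),
                                               rank = integer(0), n = integer(0))
    class(out) <- c("contribution_stability", class(tibble::tibble()))
    return(out)
  }
  groups <- sort(unique(per_model$group))
  full <- tidyr::expand_grid(model = seq_along(ensemble$models), group = groups) |>
    dplyr::left_join(per_model, by = c("model", "group")) |>
    dplyr::mutate(fraction = tidyr::replace_na(.data$fraction, 0))
  summary <- full |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean_fraction = mean(.data$fraction),
                     sd_fraction = sd(.data$fraction), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_fraction), .data$group) |>
    dplyr::mutate(consensus_rank = dplyr::row_number())
  rank_counts <- per_model |>
    dplyr::count(.data$group, .data$rank, name = "n")
  attr(summary, "per_model") <- full
  attr(summary, "rank_counts") <- rank_counts
  class(summary) <- c("contribution_stability", class(tibble::tibble()))
  summary
}

#' Write contribution report TSVs
#'
#' Writes the group-level table and, optionally, the member-level table
#' (group, feature_id, coefficient).
#'
#' @param report A `contribution_report`.
#' @param path Group table path.
#' @param members_path Optional member table path.
#' @return `path`, invisibly.
#' @export
write_contribution_report <- function(report, path, members_path = NULL) {
  readr::write_tsv(tibble::as_tibble(report), path, progress = FALSE)
  if (!is.null(members_path)) {
    readr::write_tsv(contribution_members(report), members_path, progress = FALSE)
  }
  invisible(path)
}
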