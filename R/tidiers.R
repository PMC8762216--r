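#' Tidy a fitted risk model
#'
#' @param x A `risk_model`.
#' @param ... Unused.
#' @return Tibble with one row per model term (`term`, `estimate`,
#'   `selected`), the intercept first.
#' @export
tidy.risk_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", x$feature_order),
    estimate = c(x$intercept, unname(x$coefficients[x$feature_order])),
    selected = c(TRUE, unname(x$coefficients[x$feature_order]) != 0))
}

#' @rdname tidy.risk_model
#' @export
glance.risk_model <- function(x, ...) {
  tibble::tibble(
    penalty = x$hyperparams$penalty,
    strength = x$hyperparams$strength,
    l1_ratio = x$hyperparams$l1_ratio,
    n_features = length(x$coefficients),
    n_selected = sum(x$coefficients != 0),
    train_auc = x$train_auc,
    n_case = x$n_case,
    n_control = x$n_control)
}

#' Tidy a cross-validation ensemble
#'
#' @param x A `model_ensemble`.
#' @param ... Unused.
#' @return `tidy`: one row per fold model (`repeat_id`, `fold`, `auc`,
#'   `n_selected`); `glance`: one-row summary.
#' @export
tidy.model_ensemble <- function(x, ...) {
  dplyr::mutate(x$fold_info,
                n_selected = vapply(x$models, function(m) {
                  sum(m$coefficients != 0)
                }, integer(1)))
}

#' @rdname tidy.model_ensemble
#' @export
glance.model_ensemble <- function(x, ...) {
  tibble::tibble(
    n_models = length(x$models),
    mean_auc = x$mean_auc,
    sd_auc = x$sd_auc,
    min_auc = min(x$fold_aucs),
    max_auc = max(x$fold_aucs),
    penalty = x$hyperparams$penalty,
    strength = x$hyperparams$strength,
    l1_ratio = x$hyperparams$l1_ratio)
}

#' Plot per-tissue risk contributions
#'
#' Horizontal bar chart of contribution fractions, ranked.
#'
#' @param object A `contribution_report`.
#' @param top_n Show at most this many groups (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.contribution_report <- function(object, top_n = 20, ...) {
  df <- utils::head(tibble::as_tibble(object), top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$fraction,
    y = stats::reorder(.data$group, .data$fraction))) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::scale_x_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = "fraction of total model weight", y = NULL,
                  title = "Per-tissue contributions to predicted risk") +
    ggplot2::theme_minimal()
}

#' Plot contribution stability across the ensemble
#'
#' Box plots of each group's per-model contribution fractions, ordered by
#' consensus rank.
#'
#' @param object A `contribution_stability`.
#' @param top_n Show at most this many groups (default 15).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.contribution_stability <- function(object, top_n = 15, ...) {
  keep <- utils::head(tibble::as_tibble(object), top_n)
  per_model <- attr(object, "per_model") |>
    dplyr::filter(.data$group %in% keep$group) |>
    dplyr::mutate(group = factor(.data$group, levels = rev(keep$group)))
  ggplot2::ggplot(per_model, ggplot2::aes(x = .data$fraction, y = .data$group)) +
    ggplot2::geom_boxplot(fill = "#a6bddb", outlier.size = 0.6) +
    ggplot2::scale_x_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = "fraction of model weight (per ensemble model)", y = NULL,
                  title = "Contribution-ranking stability across the CV ensemble") +
    ggplot2::theme_minimal()
}

#' Plot the ensemble's out-of-fold AUC distribution
#'
#' @param object A `model_ensemble`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.model_ensemble <- function(object, ...) {
  df <- object$fold_info
  ggplot2::ggplot(df, ggplot2::aes(x = .data$auc)) +
    ggplot2::geom_histogram(bins = 15, fill = "#2c7fb8", color = "white") +
    ggplot2::geom_vline(xintercept = object$mean_auc, linetype = 2) +
    ggplot2::labs(x = "out-of-fold AUC", y = "models",
                  title = sprintf("Ensemble AUC: %.3f +/- %.3f",
                                  object$mean_auc, object$sd_auc)) +
    ggplot2::theme_minimal()
}
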