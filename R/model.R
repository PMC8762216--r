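#' Rank-based AUC
#'
#' Area under the ROC curve computed through the Mann-Whitney identity
#' `AUC = U / (n_case * n_control)` with mid-ranks, so tied scores
#' contribute one half per pair. All-tied scores give 0.5.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary labels (1 = case, 0 = control).
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(scores, labels) {
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) {
    abort("AUC needs both cases and controls", class = "eqtlrisk_validation_error")
  }
  r <- rank(scores)
  u <- sum(r[labels == 1L]) - n1 * (n1 + 1) / 2
  u / (n1 * n0)
}

#' AUC with stratified-bootstrap confidence interval
#'
#' @inheritParams rank_auc
#' @param n_boot Number of bootstrap replicates (default 2000).
#' @param conf Confidence level (default 0.95).
#' @param seed RNG seed for the bootstrap resampling.
#' @return One-row tibble: `auc`, `ci_low`, `ci_high`, `n_case`, `n_control`.
#' @export
evaluate_auc <- function(scores, labels, n_boot = 2000, conf = 0.95, seed = 1) {
  auc <- rank_auc(scores, labels)
  case_i <- which(labels == 1L); ctrl_i <- which(labels == 0L)
  boot <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(case_i, replace = TRUE), sample(ctrl_i, replace = TRUE))
      rank_auc(scores[idx], labels[idx])
    }, numeric(1))
  })
  a <- (1 - conf) / 2
  ci <- unname(quantile(boot, c(a, 1 - a), type = 7))
  tibble::tibble(auc = auc, ci_low = ci[1], ci_high = ci[2],
                 n_case = length(case_i), n_control = length(ctrl_i))
}

# Stratified fold assignment: one integer vector per repeat, values 1..folds,
# each class split as evenly as possible.
make_cv_folds <- function(labels, folds, repeats, seed) {
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (min(n1, n0) < folds) {
    abort(sprintf("cannot build %d stratified folds with class counts %d/%d",
                  folds, n1, n0), class = "eqtlrisk_fatal_error")
  }
  withr::with_seed(seed, {
    lapply(seq_len(repeats), function(r) {
      assign <- integer(length(labels))
      for (cls in c(1L, 0L)) {
        idx <- which(labels == cls)
        assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
      assign
    })
  })
}

glmnet_lambda <- function(strength, n) 1 / (n * strength)

col_pop_var <- function(x) {
  colMeans(x^2) - colMeans(x)^2
}

penalty_name <- function(l1_ratio) {
  if (l1_ratio == 1) "l1" else if (l1_ratio == 0) "l2" else "elastic_net"
}

# glmnet needs >= 2 columns; pad with all-zero (hence coefficient-zero)
# columns so degenerate post-filter matrices still fit cleanly.
pad_design <- function(x) {
  if (ncol(x) >= 2) return(x)
  cbind(x, matrix(0, nrow(x), 2 - ncol(x)))
}

# Single deterministic glmnet fit at one (l1_ratio, strength) point.
# A design with no informative columns (possible after aggressive
# filtering) collapses to the closed-form intercept-only fit.
fit_glmnet_point <- function(x, y, l1_ratio, strength) {
  p <- ncol(x)
  if (p == 0 || all(col_pop_var(x) == 0)) {
    return(list(intercept = qlogis(mean(y)), beta = rep(0, p)))
  }
  lam <- glmnet_lambda(strength, nrow(x))
  # short warm-start path ending at the target lambda for solver stability
  path <- lam * c(64, 16, 4, 1)
  fit <- glmnet::glmnet(pad_design(x), y, family = "binomial",
                        alpha = l1_ratio, lambda = path, standardize = FALSE,
                        thresh = 1e-10, maxit = 1e6)
  beta <- as.numeric(fit$beta[, ncol(fit$beta)])[seq_len(p)]
  list(intercept = fit$a0[[length(fit$a0)]], beta = beta)
}

#' Fit a regularized logistic risk model
#'
#' Elastic-net-penalized logistic regression fitted with glmnet on a
#' filtered, standardized feature matrix. `strength` is the inverse
#' regularization constant C; it maps to the glmnet penalty as
#' `lambda = 1 / (n * strength)`, so smaller `strength` means stronger
#' shrinkage (at the fully-shrunk limit all coefficients are zero and the
#' intercept equals the log case/control odds). The fit is deterministic:
#' fixed solver tolerance 1e-10, no internal randomness.
#'
#' @param fm A standardized `feature_matrix` (see [standardize_features()]).
#' @param l1_ratio Elastic-net mixing in \[0, 1\]: 1 = lasso, 0 = ridge.
#' @param strength Inverse regularization constant C (> 0).
#' @return A `risk_model`: intercept, named coefficient vector,
#'   hyperparameters, in-sample `train_auc`, `feature_order` and
#'   `replay_stats` (the standardization statistics to replay on new
#'   cohorts).
#' @export
fit_risk_model <- function(fm, l1_ratio = 0.5, strength = 1) {
  stopifnot(strength > 0, l1_ratio >= 0, l1_ratio <= 1)
  if (is.null(fm$labels) || length(unique(fm$labels)) < 2) {
    abort("model fitting needs both cases and controls",
          class = "eqtlrisk_fatal_error")
  }
  y <- unname(fm$labels)
  pt <- fit_glmnet_point(fm$values, y, l1_ratio, strength)
  coefs <- setNames(pt$beta, fm$descriptors$feature_id)
  eta <- pt$intercept + drop(fm$values %*% pt$beta)
  model <- structure(list(
    intercept = unname(pt$intercept),
    coefficients = coefs,
    hyperparams = list(penalty = penalty_name(l1_ratio),
                       strength = strength, l1_ratio = l1_ratio),
    train_auc = rank_auc(eta, y),
    feature_order = fm$descriptors$feature_id,
    replay_stats = fm$column_stats,
    n_case = sum(y == 1L), n_control = sum(y == 0L)),
    class = "risk_model")
  model
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> %s (C = %g, l1_ratio = %g)\n",
              x$hyperparams$penalty, x$hyperparams$strength,
              x$hyperparams$l1_ratio))
  cat(sprintf("  %d features, %d selected (nonzero); train AUC %.3f\n",
              length(x$coefficients), sum(x$coefficients != 0), x$train_auc))
  invisible(x)
}

#' Repeated-CV model ensemble at fixed hyperparameters
#'
#' Builds the out-of-fold ensemble: for each repeat and fold, a model is
#' fitted on the in-fold samples and scored on the held-out fold; the
#' default 5 repeats x 10 folds yields 50 models and 50 out-of-fold AUCs.
#'
#' @inheritParams fit_risk_model
#' @param repeats,folds Cross-validation design (default 5 x 10).
#' @param seed Seed controlling stratified fold assignment.
#' @param fold_assignments Optional precomputed output of the internal fold
#'   builder (used by [tune_risk_model()] to reuse the tuning folds).
#' @return A `model_ensemble`: `models` (list of `risk_model`),
#'   `fold_info` (tibble: repeat, fold, auc), `fold_aucs`, `mean_auc`,
#'   `sd_auc`, `oof_scores` (per-model held-out linear scores).
#' @export
cv_ensemble <- function(fm, l1_ratio = 0.5, strength = 1,
                        repeats = 5, folds = 10, seed = 1,
                        fold_assignments = NULL) {
  y <- unname(fm$labels)
  if (is.null(fold_assignments)) {
    fold_assignments <- make_cv_folds(y, folds, repeats, seed)
  }
  models <- list(); info <- list(); oof <- list()
  k <- 0L
  for (r in seq_along(fold_assignments)) {
    assign <- fold_assignments[[r]]
    for (f in sort(unique(assign))) {
      k <- k + 1L
      test_idx <- which(assign == f)
      train <- subset_features(fm, sample_idx = setdiff(seq_along(y), test_idx))
      m <- fit_risk_model(train, l1_ratio = l1_ratio, strength = strength)
      eta <- m$intercept +
        drop(fm$values[test_idx, , drop = FALSE] %*%
               m$coefficients[colnames(fm$values)])
      models[[k]] <- m
      oof[[k]] <- setNames(eta, fm$sample_ids[test_idx])
      info[[k]] <- tibble::tibble(repeat_id = r, fold = f,
                                  auc = rank_auc(eta, y[test_idx]))
    }
  }
  fold_info <- dplyr::bind_rows(info)
  structure(list(models = models,
                 fold_info = fold_info,
                 fold_aucs = fold_info$auc,
                 mean_auc = mean(fold_info$auc),
                 sd_auc = sd(fold_info$auc),
                 oof_scores = oof,
                 fold_assignments = fold_assignments,
                 hyperparams = models[[1]]$hyperparams,
                 seed = seed),
            class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat(sprintf("<model_ensemble> %d models (%s, C = %g, l1_ratio = %g)\n",
              length(x$models), x$hyperparams$penalty,
              x$hyperparams$strength, x$hyperparams$l1_ratio))
  cat(sprintf("  out-of-fold AUC %.3f +/- %.3f (range %.3f-%.3f)\n",
              x$mean_auc, x$sd_auc, min(x$fold_aucs), max(x$fold_aucs)))
  invisible(x)
}

#' Default elastic-net hyperparameter grid
#'
#' l1_ratio over \{0.25, 0.5, 0.75, 1\} crossed with 13 log-spaced inverse
#' regularization strengths over 10^-4..10^2.
#'
#' @param l1_ratio,strength Vectors to cross.
#' @return Tibble with columns `l1_ratio`, `strength`.
#' @export
hyper_grid <- function(l1_ratio = c(0.25, 0.5, 0.75, 1),
                       strength = 10^seq(-4, 2, length.out = 13)) {
  tidyr::expand_grid(l1_ratio = l1_ratio, strength = strength)
}

#' Tune hyperparameters by repeated stratified cross-validation
#'
#' For every grid point the mean out-of-fold AUC over `repeats x folds`
#' stratified folds (a single fold assignment shared by all grid points) is
#' computed; the winning point maximizes mean AUC, with ties broken toward
#' stronger regularization (smaller `strength`, then larger `l1_ratio`).
#' The returned ensemble refits the winner on exactly the tuning folds, so
#' its 50 models are the ones the tuning estimate describes.
#'
#' @inheritParams cv_ensemble
#' @param grid Tibble with columns `l1_ratio`, `strength` (see
#'   [hyper_grid()]).
#' @return List: `best` (one-row tibble `l1_ratio`, `strength`,
#'   `mean_auc`), `ensemble` (the winner's `model_ensemble`),
#'   `grid_results` (per-point tibble of mean/sd out-of-fold AUC).
#' @export
tune_risk_model <- function(fm, grid = hyper_grid(), repeats = 5, folds = 10,
                            seed = 1) {
  if (nrow(grid) == 0) abort("empty hyperparameter grid")
  y <- unname(fm$labels)
  fold_assignments <- make_cv_folds(y, folds, repeats, seed)
  if (ncol(fm$values) == 0 || all(col_pop_var(fm$values) == 0)) {
    # nothing to tune: every grid point is the intercept-only model
    grid_results <- dplyr::mutate(grid, mean_auc = 0.5, sd_auc = 0)
    best <- dplyr::slice(dplyr::arrange(grid_results, .data$strength,
                                        dplyr::desc(.data$l1_ratio)), 1)
    ensemble <- cv_ensemble(fm, l1_ratio = best$l1_ratio,
                            strength = best$strength, repeats = repeats,
                            folds = folds, seed = seed,
                            fold_assignments = fold_assignments)
    return(list(best = best, ensemble = ensemble, grid_results = grid_results))
  }
  # one glmnet path per (fold, l1_ratio) covers every strength on the grid
  cells <- list()
  for (l1 in unique(grid$l1_ratio)) {
    strengths <- sort(grid$strength[grid$l1_ratio == l1], decreasing = FALSE)
    aucs <- matrix(NA_real_, nrow = 0, ncol = length(strengths))
    for (r in seq_along(fold_assignments)) {
      assign <- fold_assignments[[r]]
      for (f in sort(unique(assign))) {
        test_idx <- which(assign == f)
        xtr <- fm$values[-test_idx, , drop = FALSE]
        lam <- glmnet_lambda(strengths, nrow(xtr))  # decreasing in strength order
        path <- sort(unique(c(max(lam) * c(64, 16, 4), lam)), decreasing = TRUE)
        fit <- glmnet::glmnet(pad_design(xtr), y[-test_idx], family = "binomial",
                              alpha = l1, lambda = path, standardize = FALSE,
                              thresh = 1e-10, maxit = 1e6)
        eta <- predict(fit, pad_design(fm$values[test_idx, , drop = FALSE]),
                       s = lam)
        aucs <- rbind(aucs, vapply(seq_along(lam), function(j) {
          rank_auc(eta[, j], y[test_idx])
        }, numeric(1)))
      }
    }
    cells[[length(cells) + 1]] <- tibble::tibble(
      l1_ratio = l1, strength = strengths,
      mean_auc = colMeans(aucs), sd_auc = apply(aucs, 2, sd))
  }
  grid_results <- dplyr::bind_rows(cells)
  best <- grid_results |>
    dplyr::filter(.data$mean_auc == max(.data$mean_auc)) |>
    dplyr::arrange(.data$strength, dplyr::desc(.data$l1_ratio)) |>
    dplyr::slice(1)
  ensemble <- cv_ensemble(fm, l1_ratio = best$l1_ratio,
                          strength = best$strength,
                          repeats = repeats, folds = folds, seed = seed,
                          fold_assignments = fold_assignments)
  list(best = best, ensemble = ensemble, grid_results = grid_results)
}

#' Score a cohort with a fitted risk model
#'
#' Aligns the cohort's features to the model by feature id (column order is
#' irrelevant), replays the model's stored standardization statistics —
#' never the new cohort's own — and returns the logistic risk score
#' `sigmoid(intercept + sum coef * value)`. Model features absent from the
#' cohort are zero-filled (their standardized value is taken as 0) with a
#' message; more than 20% absent raises a warning, escalated to an error
#' in strict mode.
#'
#' @param model A `risk_model`.
#' @param fm_new A `feature_matrix` for the cohort to score. If it is
#'   unstandardized the model's replay statistics are applied; if it is
#'   already standardized its statistics must equal the model's.
#' @param strict Escalate the high-missingness warning to an error.
#' @return Tibble: `sample_id`, `risk_score` in (0, 1).
#' @export
predict_risk <- function(model, fm_new, strict = FALSE) {
  ids <- model$feature_order
  present <- intersect(ids, fm_new$descriptors$feature_id)
  n_absent <- length(ids) - length(present)
  if (n_absent > 0) {
    inform(sprintf("%d model feature(s) absent from cohort; zero-filled", n_absent))
    if (n_absent / length(ids) > 0.2) {
      msg <- sprintf("%.0f%% of model features absent from the cohort",
                     100 * n_absent / length(ids))
      if (strict) abort(msg, class = "eqtlrisk_fatal_error") else warn(msg)
    }
  }
  vals <- fm_new$values[, present, drop = FALSE]
  if (is.null(fm_new$column_stats)) {
    stats <- model$replay_stats[match(present, model$replay_stats$feature_id), ]
    vals <- sweep(vals, 2, stats$mean, "-")
    vals <- sweep(vals, 2, ifelse(stats$degenerate, 1, stats$sd), "/")
    vals[, stats$degenerate] <- 0
  } else {
    new_stats <- fm_new$column_stats[match(present, fm_new$column_stats$feature_id), ]
    old_stats <- model$replay_stats[match(present, model$replay_stats$feature_id), ]
    if (!isTRUE(all.equal(new_stats$mean, old_stats$mean)) ||
        !isTRUE(all.equal(new_stats$sd, old_stats$sd))) {
      abort(paste0("cohort was standardized with different statistics than ",
                   "the model; pass the unstandardized matrix"),
            class = "eqtlrisk_validation_error")
    }
  }
  eta <- model$intercept + drop(vals %*% model$coefficients[present])
  tibble::tibble(sample_id = fm_new$sample_ids,
                 risk_score = sigmoid(unname(eta)))
}

#' Conventional polygenic risk score
#'
#' `score_i = sum_s beta_s * dosage_{i,s}` over the SNPs shared between the
#' cohort and the GWAS effect-size table, after harmonizing dosages to each
#' beta's effect allele (flipping `d -> 2 - d` where the effect allele is
#' the other declared allele; unmatched SNPs are dropped with a message).
#' No shrinkage and no p-value thresholding. Missing dosages are mean-filled
#' per SNP.
#'
#' @param gm A [genotype_matrix].
#' @param betas Tibble with columns `snp`, `effect_allele`, `beta`
#'   (per-allele GWAS log-odds).
#' @return Tibble: `sample_id`, `prs`.
#' @export
compute_prs <- function(gm, betas) {
  shared <- intersect(gm$snp_ids, betas$snp)
  if (length(shared) == 0) {
    abort("no overlap between cohort SNPs and GWAS betas",
          class = "eqtlrisk_fatal_error")
  }
  b <- betas[match(shared, betas$snp), ]
  dos <- gm$dosages[, shared, drop = FALSE]
  dos <- apply(dos, 2, function(col) {
    if (anyNA(col)) col[is.na(col)] <- mean(col, na.rm = TRUE)
    as.numeric(col)
  })
  dos <- matrix(dos, nrow = length(gm$sample_ids),
                dimnames = list(gm$sample_ids, shared))
  use <- rep(TRUE, length(shared))
  for (j in seq_along(shared)) {
    s <- shared[j]
    if (identical(unname(gm$counted_allele[[s]]), b$effect_allele[j])) next
    if (identical(unname(gm$other_allele[[s]]), b$effect_allele[j])) {
      dos[, j] <- 2 - dos[, j]
    } else {
      use[j] <- FALSE
    }
  }
  if (any(!use)) {
    inform(sprintf("dropping %d PRS SNP(s) whose effect allele matches neither declared allele",
                   sum(!use)))
  }
  score <- drop(dos[, use, drop = FALSE] %*% b$beta[use])
  tibble::tibble(sample_id = gm$sample_ids, prs = unname(score))
}

#' Save / load a fitted risk model as JSON
#'
#' @param model A `risk_model`.
#' @param path JSON path.
#' @return `path` invisibly; `read_risk_model` returns the restored model.
#' @export
write_risk_model <- function(model, path) {
  payload <- list(
    intercept = model$intercept,
    hyperparams = model$hyperparams,
    feature_order = model$feature_order,
    coefficients = as.list(model$coefficients),
    replay_stats = model$replay_stats,
    train_auc = model$train_auc,
    n_case = model$n_case, n_control = model$n_control,
    package_version = as.character(utils::packageVersion("eqtlrisk")))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    intercept = p$intercept,
    coefficients = setNames(unlist(p$coefficients)[p$feature_order],
                            p$feature_order),
    hyperparams = p$hyperparams,
    train_auc = p$train_auc,
    feature_order = p$feature_order,
    replay_stats = tibble::as_tibble(p$replay_stats),
    n_case = p$n_case, n_control = p$n_control),
    class = "risk_model")
}
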