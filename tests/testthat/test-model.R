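std_fm <- function(n = 200, p = 10, seed = 1, signal = 0.8) {
  withr::with_seed(seed, {
    vals <- matrix(rnorm(n * p), nrow = n)
    eta <- -0.2 + signal * vals[, 1] - signal * vals[, 2]
    labels <- rbinom(n, 1L, plogis(eta))
    if (length(unique(labels)) < 2) labels[1:2] <- c(0L, 1L)
    ids <- sprintf("f%02d", seq_len(p))
    colnames(vals) <- ids
    rownames(vals) <- sprintf("s%03d", seq_len(n))
    fm <- structure(list(
      values = vals,
      descriptors = tibble::tibble(feature_id = ids, kind = "eqtl", snp = ids,
                                   gene = "G", tissue = rep(c("T1", "T2"),
                                                            length.out = p),
                                   nes = 1, allele = "A"),
      labels = setNames(labels, rownames(vals)),
      sample_ids = rownames(vals),
      column_stats = NULL), class = "feature_matrix")
    standardize_features(fm)
  })
}

test_that("rank AUC matches direct pair counting and its symmetries", {
  scores <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  labels <- c(1, 1, 1, 0, 0, 0)
  expect_equal(rank_auc(scores, labels), 1)
  withr::with_seed(13, {
    for (i in 1:10) {
      s <- sample(1:10, 30, replace = TRUE)  # ties included
      l <- rep(c(1L, 0L), 15)
      expect_equal(rank_auc(s, l),
                   oracle_u(s[l == 1], s[l == 0]) / (15 * 15))
      expect_equal(rank_auc(s, l) + rank_auc(-s, l), 1)
    }
  })
  expect_error(rank_auc(1:3, c(1, 1, 1)), class = "eqtlrisk_validation_error")
})

test_that("rank AUC agrees with pROC on continuous scores", {
  skip_if_not_installed("pROC")
  withr::with_seed(8, {
    s <- rnorm(100)
    l <- rbinom(100, 1, plogis(s))
    if (length(unique(l)) < 2) l[1:2] <- c(0L, 1L)
    ref <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                          direction = "<", levels = c(0, 1))))
    expect_equal(rank_auc(s, l), ref, tolerance = 1e-12)
  })
})

test_that("evaluate_auc is deterministic under a seed and brackets the point estimate", {
  withr::with_seed(4, {
    s <- rnorm(200); l <- rep(c(1L, 0L), 100)
  })
  a1 <- evaluate_auc(s, l, n_boot = 200, seed = 5)
  a2 <- evaluate_auc(s, l, n_boot = 200, seed = 5)
  expect_equal(a1, a2)
  expect_lte(a1$ci_low, a1$auc)
  expect_gte(a1$ci_high, a1$auc)
})

test_that("the fully shrunk model is intercept-only at the class log-odds", {
  fm <- std_fm(n = 300, p = 5, seed = 2)
  m <- fit_risk_model(fm, l1_ratio = 0.5, strength = 1e-8)
  expect_true(all(m$coefficients == 0))
  n1 <- sum(fm$labels == 1L); n0 <- sum(fm$labels == 0L)
  expect_equal(m$intercept, log(n1 / n0), tolerance = 1e-6)
})

test_that("ridge treats duplicated columns symmetrically", {
  fm <- std_fm(n = 300, p = 6, seed = 3)
  fm$values[, 6] <- fm$values[, 1]
  fm$column_stats[6, -1] <- fm$column_stats[1, -1]
  m <- fit_risk_model(fm, l1_ratio = 0, strength = 1)
  # coordinate descent approaches the exchange-symmetric ridge solution;
  # agreement is bounded by the solver tolerance, not exact
  expect_lt(abs(m$coefficients[1] - m$coefficients[6]), 1e-3)
})

test_that("refitting with the same configuration is bit-reproducible", {
  fm <- std_fm(seed = 9)
  m1 <- fit_risk_model(fm, 0.5, 0.2)
  m2 <- fit_risk_model(fm, 0.5, 0.2)
  expect_identical(m1$coefficients, m2$coefficients)
  expect_identical(m1$intercept, m2$intercept)
})

test_that("stronger l1 penalties do not inflate the selected-feature count", {
  fm <- std_fm(n = 400, p = 20, seed = 12)
  strengths <- 10^seq(-3, 1, length.out = 9)
  nz <- vapply(strengths, function(s) {
    sum(fit_risk_model(fm, l1_ratio = 1, strength = s)$coefficients != 0)
  }, numeric(1))
  # weaker regularization (larger strength) keeps at least as many features
  expect_true(all(diff(nz) >= -1))  # allow one-feature solver jitter
})

test_that("the repeated-CV ensemble has the right size and self-consistent AUCs", {
  fm <- std_fm(n = 250, p = 8, seed = 6)
  ens <- cv_ensemble(fm, l1_ratio = 0.5, strength = 0.1,
                     repeats = 5, folds = 10, seed = 3)
  expect_length(ens$models, 50)
  expect_length(ens$fold_aucs, 50)
  expect_equal(ens$mean_auc, mean(ens$fold_info$auc))
  expect_equal(ens$sd_auc, sd(ens$fold_info$auc))
  # fold AUCs recompute exactly from the stored held-out scores
  y <- unname(fm$labels)
  recomputed <- vapply(seq_along(ens$oof_scores), function(k) {
    idx <- match(names(ens$oof_scores[[k]]), fm$sample_ids)
    rank_auc(unname(ens$oof_scores[[k]]), y[idx])
  }, numeric(1))
  expect_equal(recomputed, ens$fold_aucs)
  # every sample is held out exactly once per repeat
  held <- unlist(lapply(ens$oof_scores[1:10], names))
  expect_setequal(held, fm$sample_ids)
})

test_that("tuning picks the best grid point and refits it on the tuning folds", {
  fm <- std_fm(n = 250, p = 8, seed = 16)
  grid <- hyper_grid(l1_ratio = c(0.5, 1), strength = c(0.01, 0.1, 1))
  tuned <- tune_risk_model(fm, grid = grid, repeats = 2, folds = 5, seed = 2)
  expect_equal(nrow(tuned$grid_results), nrow(grid))
  expect_equal(max(tuned$grid_results$mean_auc), tuned$best$mean_auc)
  expect_length(tuned$ensemble$models, 10)
  expect_equal(tuned$ensemble$hyperparams$strength, tuned$best$strength)
  # the ensemble's fold AUC mean matches the tuning estimate for the winner
  win <- tuned$grid_results[
    tuned$grid_results$l1_ratio == tuned$best$l1_ratio &
      tuned$grid_results$strength == tuned$best$strength, ]
  expect_equal(tuned$ensemble$mean_auc, win$mean_auc, tolerance = 1e-10)
  expect_error(tune_risk_model(fm, grid = grid[0, ]), "empty")
})

test_that("prediction aligns by feature id and replays training statistics", {
  fm <- std_fm(n = 200, p = 6, seed = 21)
  m <- fit_risk_model(fm, 0.5, 0.5)
  base <- predict_risk(m, fm)
  # column permutation leaves scores unchanged
  perm <- sample(ncol(fm$values))
  fm_perm <- fm
  fm_perm$values <- fm$values[, perm]
  fm_perm$descriptors <- fm$descriptors[perm, ]
  fm_perm$column_stats <- fm$column_stats[perm, ]
  expect_equal(predict_risk(m, fm_perm)$risk_score, base$risk_score)
  # a missing feature scores as if present and uniformly zero
  drop_id <- fm$descriptors$feature_id[2]
  fm_drop <- fm
  keep <- fm$descriptors$feature_id != drop_id
  fm_drop$values <- fm$values[, keep]
  fm_drop$descriptors <- fm$descriptors[keep, ]
  fm_drop$column_stats <- fm$column_stats[keep, ]
  fm_zero <- fm
  fm_zero$values[, drop_id] <- 0
  expect_equal(suppressMessages(predict_risk(m, fm_drop)$risk_score),
               predict_risk(m, fm_zero)$risk_score)
  # all-zero standardized row scores sigmoid(intercept)
  fm_onerow <- fm
  fm_onerow$values <- fm$values[1, , drop = FALSE] * 0
  fm_onerow$sample_ids <- fm$sample_ids[1]
  fm_onerow$labels <- fm$labels[1]
  expect_equal(predict_risk(m, fm_onerow)$risk_score,
               plogis(m$intercept))
  # strict mode escalates heavy feature loss
  fm_few <- fm
  keep2 <- fm$descriptors$feature_id %in% fm$descriptors$feature_id[1]
  fm_few$values <- fm$values[, keep2, drop = FALSE]
  fm_few$descriptors <- fm$descriptors[keep2, ]
  fm_few$column_stats <- fm$column_stats[keep2, ]
  expect_error(suppressMessages(predict_risk(m, fm_few, strict = TRUE)),
               class = "eqtlrisk_fatal_error")
})

test_that("PRS is the beta-weighted allele count with harmonized effect alleles", {
  gm <- toy_gm()
  # single SNP, beta = 1: score equals the dosage
  betas <- tibble::tibble(snp = "rsA", effect_allele = "A", beta = 1)
  expect_equal(compute_prs(gm, betas)$prs, as.numeric(gm$dosages[, "rsA"]))
  # flipping the effect allele maps scores to 2*beta - old contribution
  betas_flip <- tibble::tibble(snp = "rsA", effect_allele = "G", beta = 1)
  expect_equal(compute_prs(gm, betas_flip)$prs,
               2 - as.numeric(gm$dosages[, "rsA"]))
  # all-zero betas: constant scores, AUC 0.5 by the tie convention
  betas0 <- tibble::tibble(snp = c("rsA", "rsB"), effect_allele = c("A", "T"),
                           beta = c(0, 0))
  prs0 <- compute_prs(gm, betas0)
  expect_true(all(prs0$prs == 0))
  expect_equal(rank_auc(prs0$prs, gm$labels), 0.5)
  expect_error(compute_prs(gm, tibble::tibble(snp = "zz", effect_allele = "A",
                                              beta = 1)),
               class = "eqtlrisk_fatal_error")
})

test_that("risk models survive a JSON round trip", {
  fm <- std_fm(n = 150, p = 5, seed = 30)
  m <- fit_risk_model(fm, 1, 0.3)
  path <- withr::local_tempfile(fileext = ".json")
  write_risk_model(m, path)
  back <- read_risk_model(path)
  expect_equal(back$coefficients, m$coefficients)
  expect_equal(back$intercept, m$intercept)
  expect_equal(predict_risk(back, fm)$risk_score,
               predict_risk(m, fm)$risk_score)
})

test_that("tidy and glance summarize fitted models and ensembles", {
  fm <- std_fm(n = 150, p = 5, seed = 31)
  m <- fit_risk_model(fm, 0.5, 0.5)
  td <- tidy(m)
  expect_equal(nrow(td), 6)
  expect_equal(td$term[1], "(Intercept)")
  gl <- glance(m)
  expect_equal(gl$n_selected, sum(m$coefficients != 0))
  ens <- cv_ensemble(fm, 0.5, 0.5, repeats = 2, folds = 5, seed = 1)
  expect_equal(nrow(tidy(ens)), 10)
  expect_equal(glance(ens)$n_models, 10)
})
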