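#' Simulation configuration for synthetic case/control cohorts
#'
#' Defines the generative conditions for a synthetic cohort with the
#' statistical structure the pipeline assumes: biallelic SNP dosages under
#' Hardy-Weinberg equilibrium at uniform-random minor-allele frequencies, a
#' many-to-many SNP-to-(eGene, tissue) map with signed normalized effect
#' sizes, a subset of SNPs with no eQTL annotations, and binary disease
#' labels drawn retrospectively from a logistic liability over a planted
#' set of causal features.
#'
#' @param n_cases,n_controls Cohort class sizes.
#' @param n_snps Number of SNPs in the study panel.
#' @param frac_eqtl_snps Fraction of SNPs given eQTL records; the rest form
#'   the no-eQTL set.
#' @param n_tissues Number of tissue labels (default 49, the GTEx tissue
#'   count).
#' @param triples_per_snp Mean association count per eQTL SNP; each eQTL
#'   SNP receives `1 + Poisson(triples_per_snp - 1)` records.
#' @param maf_range Minor-allele frequency interval, within (0, 0.5].
#' @param nes_scale Spread of the signed NES values (zero-symmetric, with
#'   magnitudes clamped at a 0.05 floor).
#' @param causal_tissue Tissue label carrying the planted eQTL signal.
#' @param n_causal_features Number of causal eQTL features (each on a
#'   distinct SNP) in `causal_tissue`.
#' @param n_causal_snp_only Number of causal no-eQTL SNP features.
#' @param effect_size Per-feature log-odds on the standardized feature
#'   scale (`NULL` = calibrate to `target_auc`).
#' @param target_auc Population AUC the calibration solves for when
#'   `effect_size` is `NULL` (default 0.70).
#' @param beta0 Liability intercept (default -1; keeps retrospective
#'   sampling efficient).
#' @param missing_rate Fraction of dosage entries masked as missing.
#' @param seed Integer seed; together with the config it fully determines
#'   all outputs.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_cases = 1000, n_controls = 1000,
                       n_snps = 200, frac_eqtl_snps = 0.8,
                       n_tissues = 49, triples_per_snp = 3,
                       maf_range = c(0.05, 0.5), nes_scale = 0.5,
                       causal_tissue = "tissue_01",
                       n_causal_features = 12, n_causal_snp_only = 0,
                       effect_size = NULL, target_auc = 0.70,
                       beta0 = -1, missing_rate = 0, seed = 1) {
  stopifnot(is_count(n_cases), is_count(n_controls), is_count(n_snps),
            is_count(n_tissues), triples_per_snp >= 1,
            frac_eqtl_snps > 0, frac_eqtl_snps <= 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            nes_scale > 0, is_count(n_causal_features, min = 0L),
            is_count(n_causal_snp_only, min = 0L),
            is.null(effect_size) || effect_size > 0,
            target_auc >= 0.5, target_auc < 1,
            missing_rate >= 0, missing_rate < 1,
            is_count(seed, min = 0L))
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_snps = as.integer(n_snps),
                 frac_eqtl_snps = frac_eqtl_snps,
                 n_tissues = as.integer(n_tissues),
                 triples_per_snp = triples_per_snp,
                 maf_range = maf_range, nes_scale = nes_scale,
                 causal_tissue = causal_tissue,
                 n_causal_features = as.integer(n_causal_features),
                 n_causal_snp_only = as.integer(n_causal_snp_only),
                 effect_size = effect_size, target_auc = target_auc,
                 beta0 = beta0, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default end-to-end recovery configuration
#'
#' The reference condition used throughout the package's own validation:
#' 2000 cases / 2000 controls, 200 SNPs (80% with eQTL records), 10
#' tissues, 12 causal features planted in one tissue, effect sizes
#' calibrated to a population AUC of 0.70.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
recovery_config <- function(seed = 1, ...) {
  args <- list(n_cases = 2000, n_controls = 2000, n_snps = 200,
               frac_eqtl_snps = 0.8, n_tissues = 10, triples_per_snp = 3,
               causal_tissue = "tissue_01", n_causal_features = 12,
               n_causal_snp_only = 0, target_auc = 0.70, seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

sim_snp_ids <- function(n, prefix = "rs") sprintf("%s%06d", prefix, seq_len(n))
sim_tissues <- function(n) sprintf("tissue_%02d", seq_len(n))

#' Simulate an eQTL reference table
#'
#' `round(frac_eqtl_snps * n_snps)` SNPs receive
#' `1 + Poisson(triples_per_snp - 1)` (gene, tissue) records each, with
#' tissues uniform over the tissue labels, genes drawn without replacement
#' per SNP from a shared gene pool, and NES drawn sign-symmetrically with
#' scale `nes_scale` and a 0.05 magnitude floor. Remaining SNPs become the
#' no-eQTL set. Deterministic under the config seed.
#'
#' @param cfg A [sim_config()].
#' @return An [eqtl_table] whose attribute `snp_alleles` records each SNP's
#'   simulated effect/other allele pair.
#' @export
simulate_reference <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(derive_seed(cfg$seed, 1L), {
    snp_ids <- sim_snp_ids(cfg$n_snps)
    tissues <- sim_tissues(cfg$n_tissues)
    gene_pool <- sprintf("gene_%05d", seq_len(max(50L, 3L * cfg$n_snps)))
    n_eqtl <- max(1L, round(cfg$frac_eqtl_snps * cfg$n_snps))
    eqtl_snps <- sort(sample(snp_ids, n_eqtl))
    # non-complementary allele pairs so harmonization is unambiguous
    effect <- sample(DNA_BASES, cfg$n_snps, replace = TRUE)
    other <- vapply(effect, function(a) {
      sample(setdiff(DNA_BASES, c(a, complement_base(a))), 1)
    }, character(1))
    alleles <- tibble::tibble(snp = snp_ids, effect_allele = effect,
                              other_allele = unname(other))
    k <- 1L + rpois(n_eqtl, cfg$triples_per_snp - 1)
    rec <- purrr::map2(eqtl_snps, k, function(s, ki) {
      tibble::tibble(
        snp = s,
        effect_allele = alleles$effect_allele[alleles$snp == s],
        gene = sample(gene_pool, ki),
        tissue = sample(tissues, ki, replace = TRUE),
        nes = sample(c(-1, 1), ki, replace = TRUE) *
          pmax(0.05, abs(rnorm(ki, 0, cfg$nes_scale))),
        fdr = runif(ki, 0, 0.049))
    }) |> dplyr::bind_rows()
    tbl <- eqtl_table(rec, study_snps = snp_ids)
    attr(tbl, "snp_alleles") <- alleles
    attr(tbl, "sim_seed") <- cfg$seed
    tbl
  })
}

# Numerically solve the per-feature effect size whose liability score
# reaches a target population AUC, under a Gaussian approximation: the
# total score S ~ N(0, k * e^2) in the source population; class-conditional
# moments are obtained by reweighting with the logistic link, and the
# binormal identity AUC = Phi(dmu / sqrt(v1 + v0)) closes the equation.

#' Calibrate the planted effect size to a target population AUC
#'
#' @param n_causal Total number of causal features.
#' @param target_auc Desired population AUC (in (0.5, 1)).
#' @param beta0 Liability intercept.
#' @return The per-feature effect size (log-odds per standardized unit).
#' @export
calibrate_effect_size <- function(n_causal, target_auc = 0.70, beta0 = -1) {
  stopifnot(n_causal >= 1, target_auc > 0.5, target_auc < 1)
  t <- seq(-8, 8, length.out = 4001)
  w <- dnorm(t)
  auc_of <- function(e) {
    s <- t * sqrt(n_causal) * e
    p <- plogis(beta0 + s)
    w1 <- p * w; w0 <- (1 - p) * w
    m1 <- sum(s * w1) / sum(w1); m0 <- sum(s * w0) / sum(w0)
    v1 <- sum(s^2 * w1) / sum(w1) - m1^2
    v0 <- sum(s^2 * w0) / sum(w0) - m0^2
    pnorm((m1 - m0) / sqrt(v1 + v0))
  }
  uniroot(function(e) auc_of(e) - target_auc,
          lower = 1e-4, upper = 10, tol = 1e-8)$root
}

#' Simulate a case/control cohort from a reference table
#'
#' Dosages are Binomial(2, MAF) per SNP (Hardy-Weinberg, no linkage
#' disequilibrium), MAF ~ Uniform over `maf_range`. A liability
#' `eta = beta0 + sum_f gamma_f z_f` is computed over the planted causal
#' features (each on a distinct SNP; `z` is the standardized feature value
#' and `gamma_f = +/- effect_size` with random sign), and individuals are
#' sampled retrospectively — batches are drawn and labelled
#' `Bernoulli(sigmoid(eta))` until the case and control quotas fill,
#' matching a case-enriched cohort design. Missing entries are masked at
#' `missing_rate` after labelling.
#'
#' @param cfg A [sim_config()].
#' @param table The [simulate_reference()] output for the same config.
#' @return List: `genotypes` (a [genotype_matrix], counted alleles already
#'   the effect alleles), `truth` (ground truth: `causal_feature_ids`,
#'   `generative_coefficients`, `effect_size`, `population_auc` — the
#'   binormal AUC `Phi(dmu / sqrt(v1 + v0))` of the generative score, with
#'   its class-moment inputs recorded in `auc_inputs`).
#' @export
simulate_cohort <- function(cfg, table) {
  stopifnot(inherits(cfg, "sim_config"), inherits(table, "eqtl_table"))
  # Population-level structure (MAFs, causal features, effect signs) is a
  # property of the simulated source population, keyed by the reference
  # table's seed: cohorts drawn under different cohort seeds from the same
  # table share one disease architecture, so a validation cohort really is
  # "the same process, new individuals".
  arch_seed <- attr(table, "sim_seed") %||% cfg$seed
  arch <- withr::with_seed(derive_seed(arch_seed, 4L), {
    snp_ids <- sort(union(unique(table$snp), no_eqtl_snps(table)))
    mafs <- setNames(runif(length(snp_ids), cfg$maf_range[1], cfg$maf_range[2]),
                     snp_ids)
    causal <- pick_causal_features(cfg, table)
    n_causal <- nrow(causal)
    effect_size <- cfg$effect_size
    if (is.null(effect_size)) {
      effect_size <- if (n_causal == 0) 0 else
        calibrate_effect_size(n_causal, cfg$target_auc, cfg$beta0)
    }
    gamma <- numeric(0)
    w_snp <- NULL
    if (n_causal > 0) {
      gamma <- setNames(sample(c(-1, 1), n_causal, replace = TRUE) * effect_size,
                        causal$feature_id)
      # coefficient on the standardized *dosage* of each causal SNP
      w_snp <- setNames(unname(gamma) * causal$nes_sign, causal$snp)
    }
    list(snp_ids = snp_ids, mafs = mafs, causal = causal,
         n_causal = n_causal, effect_size = effect_size,
         gamma = gamma, w_snp = w_snp)
  })
  withr::with_seed(derive_seed(cfg$seed, 2L), {
    snp_ids <- arch$snp_ids
    n_snps <- length(snp_ids)
    mafs <- arch$mafs
    causal <- arch$causal
    n_causal <- arch$n_causal
    effect_size <- arch$effect_size
    gamma <- arch$gamma
    w_snp <- arch$w_snp

    need_case <- cfg$n_cases; need_ctrl <- cfg$n_controls
    batch <- max(2000L, need_case + need_ctrl)
    rows <- list(); labs <- integer(0); etas <- numeric(0)
    for (iter in seq_len(200L)) {
      if (need_case <= 0 && need_ctrl <= 0) break
      D <- matrix(rbinom(batch * n_snps, 2L, rep(mafs, each = batch)),
                  nrow = batch, dimnames = list(NULL, snp_ids))
      if (n_causal > 0) {
        cs <- causal$snp
        Z <- sweep(D[, cs, drop = FALSE], 2, 2 * mafs[cs], "-")
        Z <- sweep(Z, 2, sqrt(2 * mafs[cs] * (1 - mafs[cs])), "/")
        eta <- cfg$beta0 + drop(Z %*% w_snp[cs])
      } else {
        eta <- rep(cfg$beta0, batch)
      }
      lab <- rbinom(batch, 1L, plogis(eta))
      take <- (lab == 1L & cumsum(lab == 1L) <= need_case) |
        (lab == 0L & cumsum(lab == 0L) <= need_ctrl)
      if (any(take)) {
        rows[[length(rows) + 1L]] <- D[take, , drop = FALSE]
        labs <- c(labs, lab[take])
        etas <- c(etas, eta[take])
        need_case <- need_case - sum(lab[take] == 1L)
        need_ctrl <- need_ctrl - sum(lab[take] == 0L)
      }
    }
    if (need_case > 0 || need_ctrl > 0) {
      abort("retrospective sampling did not terminate; beta0 too extreme?",
            class = "eqtlrisk_fatal_error")
    }
    D <- do.call(rbind, rows)
    sample_ids <- sprintf("S%06d", seq_len(nrow(D)))
    rownames(D) <- sample_ids
    labels <- setNames(labs, sample_ids)

    # empirical class moments of the generative score -> binormal AUC
    score <- etas - cfg$beta0
    if (n_causal > 0) {
      m1 <- mean(score[labs == 1L]); m0 <- mean(score[labs == 0L])
      s1 <- sd(score[labs == 1L]); s0 <- sd(score[labs == 0L])
      population_auc <- pnorm((m1 - m0) / sqrt(s1^2 + s0^2))
      auc_inputs <- list(mean_case = m1, mean_control = m0,
                         sd_case = s1, sd_control = s0)
    } else {
      population_auc <- 0.5
      auc_inputs <- list(mean_case = 0, mean_control = 0,
                         sd_case = 0, sd_control = 0)
    }

    if (cfg$missing_rate > 0) {
      mask <- matrix(rbinom(length(D), 1L, cfg$missing_rate) == 1L, nrow = nrow(D))
      D[mask] <- NA_integer_
    }
    alleles <- attr(table, "snp_alleles")
    if (is.null(alleles)) {
      alleles <- tibble::tibble(
        snp = snp_ids,
        effect_allele = dplyr::coalesce(
          table$effect_allele[match(snp_ids, table$snp)], "A"),
        other_allele = NA_character_)
    }
    alleles <- alleles[match(snp_ids, alleles$snp), ]
    gm <- genotype_matrix(
      D,
      counted_allele = setNames(alleles$effect_allele, snp_ids),
      other_allele = setNames(alleles$other_allele, snp_ids),
      labels = labels)
    truth <- list(causal_feature_ids = causal$feature_id,
                  generative_coefficients = gamma,
                  effect_size = effect_size,
                  population_auc = population_auc,
                  auc_inputs = auc_inputs,
                  mafs = mafs)
    list(genotypes = gm, truth = truth)
  })
}

# Choose causal features: n_causal_features eQTL features in the causal
# tissue, at most one per SNP, plus n_causal_snp_only raw-dosage features.
pick_causal_features <- function(cfg, table) {
  out <- tibble::tibble(feature_id = character(0), snp = character(0),
                        nes_sign = numeric(0))
  if (cfg$n_causal_features > 0) {
    cand <- tibble::as_tibble(table) |>
      dplyr::filter(.data$tissue == cfg$causal_tissue) |>
      dplyr::arrange(.data$snp, .data$gene, .data$tissue) |>
      dplyr::distinct(.data$snp, .keep_all = TRUE)
    if (nrow(cand) < cfg$n_causal_features) {
      abort(sprintf("causal tissue '%s' has %d distinct-SNP features; %d requested",
                    cfg$causal_tissue, nrow(cand), cfg$n_causal_features),
            class = "eqtlrisk_validation_error")
    }
    cand <- cand[sample.int(nrow(cand), cfg$n_causal_features), ]
    out <- dplyr::bind_rows(out, tibble::tibble(
      feature_id = paste(cand$snp, cand$gene, cand$tissue, sep = "|"),
      snp = cand$snp, nes_sign = sign(cand$nes)))
  }
  if (cfg$n_causal_snp_only > 0) {
    ne <- no_eqtl_snps(table)
    if (length(ne) < cfg$n_causal_snp_only) {
      abort("not enough no-eQTL SNPs for the requested causal count",
            class = "eqtlrisk_validation_error")
    }
    alleles <- attr(table, "snp_alleles")
    picked <- sort(sample(ne, cfg$n_causal_snp_only))
    al <- if (!is.null(alleles)) alleles$effect_allele[match(picked, alleles$snp)]
          else rep("A", length(picked))
    out <- dplyr::bind_rows(out, tibble::tibble(
      feature_id = paste0(picked, "_", al),
      snp = picked, nes_sign = 1))
  }
  out
}

#' Append a negative-control SNP panel
#'
#' Emulates a mixed disease + control-trait design: a disjoint panel of
#' control SNPs receives its own eQTL records and Hardy-Weinberg dosages
#' but has zero generative effect on the existing labels. By default the
#' control panel is slightly larger than the study panel (ratio 313:290,
#' typical of mixed disease/control-trait panel designs). Used to verify
#' that the Mann-Whitney/BY filter depletes features carrying no
#' phenotype information.
#'
#' @param cfg The [sim_config()] that produced the cohort.
#' @param table The disease [eqtl_table].
#' @param gm The simulated cohort's [genotype_matrix].
#' @param n_control_snps Size of the control panel.
#' @return List: `table` (augmented [eqtl_table]), `genotypes` (augmented
#'   [genotype_matrix]), `control_snp_ids`.
#' @export
make_negative_control <- function(cfg, table, gm,
                                  n_control_snps = ceiling(cfg$n_snps * 313 / 290)) {
  stopifnot(inherits(cfg, "sim_config"))
  ctrl_cfg <- cfg
  ctrl_cfg$n_snps <- as.integer(n_control_snps)
  withr::with_seed(derive_seed(cfg$seed, 3L), {
    ctrl_ids <- sim_snp_ids(n_control_snps, prefix = "ctrl_rs")
    if (length(intersect(ctrl_ids, gm$snp_ids)) > 0) {
      abort("control SNP ids collide with cohort SNP ids",
            class = "eqtlrisk_validation_error")
    }
    tissues <- sim_tissues(cfg$n_tissues)
    gene_pool <- sprintf("ctrl_gene_%05d", seq_len(max(50L, 3L * n_control_snps)))
    n_eqtl <- max(1L, round(cfg$frac_eqtl_snps * n_control_snps))
    eqtl_snps <- sort(sample(ctrl_ids, n_eqtl))
    effect <- sample(DNA_BASES, n_control_snps, replace = TRUE)
    other <- vapply(effect, function(a) {
      sample(setdiff(DNA_BASES, c(a, complement_base(a))), 1)
    }, character(1))
    k <- 1L + rpois(n_eqtl, cfg$triples_per_snp - 1)
    rec <- purrr::map2(eqtl_snps, k, function(s, ki) {
      tibble::tibble(
        snp = s,
        effect_allele = effect[match(s, ctrl_ids)],
        gene = sample(gene_pool, ki),
        tissue = sample(tissues, ki, replace = TRUE),
        nes = sample(c(-1, 1), ki, replace = TRUE) *
          pmax(0.05, abs(rnorm(ki, 0, cfg$nes_scale))),
        fdr = runif(ki, 0, 0.049))
    }) |> dplyr::bind_rows()

    mafs <- runif(n_control_snps, cfg$maf_range[1], cfg$maf_range[2])
    n <- length(gm$sample_ids)
    D <- matrix(rbinom(n * n_control_snps, 2L, rep(mafs, each = n)),
                nrow = n, dimnames = list(gm$sample_ids, ctrl_ids))

    old_study <- sort(union(unique(table$snp), no_eqtl_snps(table)))
    aug_records <- dplyr::bind_rows(tibble::as_tibble(table), rec)
    aug <- eqtl_table(aug_records, study_snps = c(old_study, ctrl_ids))
    old_alleles <- attr(table, "snp_alleles")
    ctrl_alleles <- tibble::tibble(snp = ctrl_ids, effect_allele = effect,
                                   other_allele = unname(other))
    attr(aug, "snp_alleles") <- dplyr::bind_rows(old_alleles, ctrl_alleles)

    aug_gm <- genotype_matrix(
      cbind(gm$dosages, D),
      counted_allele = c(gm$counted_allele, setNames(effect, ctrl_ids)),
      other_allele = c(gm$other_allele, setNames(unname(other), ctrl_ids)),
      labels = gm$labels)
    list(table = aug, genotypes = aug_gm, control_snp_ids = ctrl_ids)
  })
}
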