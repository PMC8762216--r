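# Small in-code fixtures shared across test files.

# A three-association reference table on two SNPs plus one annotation-free SNP.
toy_eqtl_df <- function() {
  tibble::tibble(
    snp = c("rsA", "rsA", "rsB"),
    effect_allele = c("A", "A", "T"),
    gene = c("G1", "G2", "G1"),
    tissue = c("Heart_Atrial_Appendage", "Brain_Cerebellum", "Heart_Atrial_Appendage"),
    nes = c(-0.5, 0.3, 0.8),
    fdr = c(0.01, 0.01, 0.01))
}

toy_table <- function(study_snps = c("rsA", "rsB", "rsX")) {
  eqtl_table(toy_eqtl_df(), study_snps = study_snps)
}

# 4-sample genotype matrix on rsA/rsB/rsX, already harmonized to the toy
# table's effect alleles.
toy_gm <- function(labels = c(s1 = 1L, s2 = 1L, s3 = 0L, s4 = 0L)) {
  dos <- matrix(c(2L, 1L, 0L, 1L,
                  0L, 2L, 1L, 0L,
                  1L, 0L, 2L, 1L),
                nrow = 4,
                dimnames = list(c("s1", "s2", "s3", "s4"),
                                c("rsA", "rsB", "rsX")))
  genotype_matrix(dos,
                  counted_allele = c(rsA = "A", rsB = "T", rsX = "G"),
                  other_allele = c(rsA = "G", rsB = "C", rsX = "C"),
                  labels = labels)
}

# Random genotype matrix with both classes, for property-style tests.
random_gm <- function(n = 30, n_snps = 5, seed = 1, missing_rate = 0) {
  withr::with_seed(seed, {
    ids <- sprintf("rs%03d", seq_len(n_snps))
    dos <- matrix(rbinom(n * n_snps, 2L, 0.3), nrow = n,
                  dimnames = list(sprintf("s%03d", seq_len(n)), ids))
    if (missing_rate > 0) {
      dos[matrix(rbinom(length(dos), 1, missing_rate) == 1, nrow = n)] <- NA_integer_
    }
    labels <- setNames(rep(c(1L, 0L), length.out = n), rownames(dos))
    genotype_matrix(dos,
                    counted_allele = setNames(rep("A", n_snps), ids),
                    other_allele = setNames(rep("G", n_snps), ids),
                    labels = labels)
  })
}

# Independent double-loop oracle for the one-sided U statistic (case group),
# ties counted one half.
oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

# Exact two-sided permutation p-value by explicit enumeration of all
# C(n1+n2, n1) case-labelings (tie-free inputs).
oracle_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  combos <- combn(length(pooled), n1)
  u_obs <- oracle_u(x, y)
  null_u <- apply(combos, 2, function(idx) {
    oracle_u(pooled[idx], pooled[-idx])
  })
  mid <- n1 * length(y) / 2
  mean(abs(null_u - mid) >= abs(u_obs - mid) - 1e-9)
}

# Brute-force BY step-up with an explicit double loop over order statistics.
oracle_by <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  ord <- order(p)
  ps <- p[ord]
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) {
      best <- min(best, m * cm / j * ps[j])
    }
    q_sorted[i] <- min(1, best)
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Fixed hyperparameters used for ensemble-based checks: the package's
# documented mid-grid default for the synthetic study conditions.
default_hp <- list(l1_ratio = 0.5, strength = 0.1)
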