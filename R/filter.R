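#' Mann-Whitney U test for a case/control split
#'
#' Computes the one-sided U statistic for the case group — the number of
#' (case, control) pairs with case > control, counting ties as one half —
#' and a two-sided p-value. The p-value is exact, by enumeration of the
#' permutation null distribution, when the smaller group has at most
#' `exact_max` observations and the pooled values contain no ties;
#' otherwise a normal approximation with tie-corrected variance and
#' continuity correction is used. A pooled-constant input gives p = 1.
#'
#' @param x Numeric case values (non-empty).
#' @param y Numeric control values (non-empty).
#' @param exact_max Largest min-group size for which the exact permutation
#'   p-value is computed (default 8).
#' @return Named list with `u` and `p`.
#' @export
mannwhitney_u <- function(x, y, exact_max = 8) {
  if (length(x) == 0 || length(y) == 0) {
    abort("both groups must be non-empty", class = "eqtlrisk_validation_error")
  }
  n1 <- length(x); n0 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (!has_ties && min(n1, n0) <= exact_max) {
    p <- mw_exact_p(u, n1, n0)
  } else {
    p <- mw_normal_p(u, n1, n0, c(x, y))
  }
  list(u = u, p = p)
}

# Exact two-sided p by enumeration of all C(n1+n0, n1) labelings (tie-free):
# P(|U - n1*n0/2| >= |u - n1*n0/2|) under the permutation null.
mw_exact_p <- function(u, n1, n0) {
  null_u <- mw_null_distribution(n1, n0)
  mid <- n1 * n0 / 2
  mean(abs(null_u - mid) >= abs(u - mid) - 1e-9)
}

# cache exact null distributions per (n1, n0)
mw_null_cache <- new.env(parent = emptyenv())

mw_null_distribution <- function(n1, n0) {
  key <- paste(n1, n0)
  if (!is.null(mw_null_cache[[key]])) return(mw_null_cache[[key]])
  N <- n1 + n0
  idx <- combn(N, n1)
  null_u <- colSums(matrix(idx, nrow = n1)) - n1 * (n1 + 1) / 2
  mw_null_cache[[key]] <- null_u
  null_u
}

# Normal approximation with tie-corrected variance and continuity correction.
mw_normal_p <- function(u, n1, n0, pooled) {
  N <- n1 + n0
  tie_counts <- table(pooled)
  tie_term <- sum(tie_counts^3 - tie_counts) / (N * (N - 1))
  sigma2 <- n1 * n0 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  mu <- n1 * n0 / 2
  z <- max(0, abs(u - mu) - 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-z))
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' Step-up adjustment valid under arbitrary dependence: with order
#' statistics `p_(1) <= ... <= p_(m)` and harmonic factor
#' `c(m) = sum_{k=1..m} 1/k`, the adjusted value is
#' `q_(i) = min(1, min_{j >= i} m * c(m) / j * p_(j))`, returned in the
#' input order. Always at least as conservative as Benjamini-Hochberg.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, same length and order as `p`.
#' @export
by_adjust <- function(p) {
  if (length(p) == 0) abort("need at least one p-value")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1]", class = "eqtlrisk_validation_error")
  }
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  ord <- order(p)
  scaled <- m * cm / seq_len(m) * p[ord]
  q_sorted <- pmin(1, rev(cummin(rev(scaled))))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Vectorized per-column Mann-Whitney over a feature matrix.
mw_test_columns <- function(values, labels, exact_max = 8) {
  case_idx <- which(labels == 1L)
  n1 <- length(case_idx); n0 <- nrow(values) - n1
  exact_ok <- min(n1, n0) <= exact_max
  t(apply(values, 2, function(col) {
    r <- rank(col)
    u <- sum(r[case_idx]) - n1 * (n1 + 1) / 2
    if (exact_ok && anyDuplicated(col) == 0) {
      c(u, mw_exact_p(u, n1, n0))
    } else {
      c(u, mw_normal_p(u, n1, n0, col))
    }
  }))
}

#' Filter features by Mann-Whitney U with BY FDR control
#'
#' Runs a two-sided Mann-Whitney U test (case vs control values) on every
#' feature column, adjusts the p-values with the Benjamini-Yekutieli
#' procedure, and keeps features with `q < alpha`. The test is rank-based,
#' so raw and standardized matrices give identical results.
#'
#' @param fm A `feature_matrix` with both phenotype classes present.
#' @param alpha FDR threshold (default 0.05).
#' @return List with `matrix` (the `feature_matrix` restricted to kept
#'   columns; zero kept features gives an empty matrix with a warning) and
#'   `results` (tibble: `feature_id`, `u_statistic`, `p_value`, `q_value`,
#'   `kept`).
#' @export
filter_features <- function(fm, alpha = 0.05) {
  if (is.null(fm$labels) || length(unique(fm$labels)) < 2) {
    abort("feature filtering needs both cases and controls",
          class = "eqtlrisk_fatal_error")
  }
  up <- mw_test_columns(fm$values, fm$labels)
  q <- by_adjust(up[, 2])
  kept <- q < alpha
  results <- tibble::tibble(
    feature_id = fm$descriptors$feature_id,
    u_statistic = up[, 1],
    p_value = up[, 2],
    q_value = q,
    kept = kept)
  if (!any(kept)) {
    warn("no features survive the Mann-Whitney/BY filter")
  }
  list(matrix = subset_features(fm, feature_ids = results$feature_id[kept]),
       results = results)
}

#' Write a filter report TSV
#' @param results The `results` tibble from [filter_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(results, path) {
  readr::write_tsv(results, path, progress = FALSE)
  invisible(path)
}
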