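#' IHC membrane-staining extension score
#'
#' Converts the percentage of neoplastic cells with membrane staining into
#' the 0-3 ordinal extension score: 0 for 0-10%, 1 for >10-25%, 2 for
#' >25-50%, 3 for >50-100%. Band edges at exactly 10/25/50% take the lower
#' score.
#'
#' @param extension_percent numeric vector of staining extension
#'   percentages in `[0, 100]`.
#' @return Integer scores 0-3.
#' @examples
#' score_ihc_extension(c(5, 30, 100))  # 0 2 3
#' @export
score_ihc_extension <- function(extension_percent) {
  if (any(!is.finite(extension_percent)) ||
      any(extension_percent < 0 | extension_percent > 100)) {
    abort("`extension_percent` must lie in [0, 100].")
  }
  as.integer(cut(extension_percent, breaks = c(-Inf, 10, 25, 50, Inf),
                 labels = FALSE)) - 1L
}

#' IHC positivity from extension score
#'
#' Marker-specific positivity cut-offs: E-cadherin and total SRC require a
#' score of at least 2 (more than 25% of cells stained); P-cadherin and
#' pSRC(Tyr416) are positive from score 1 (staining in at least 10% of the
#' neoplastic cells).
#'
#' @param score integer score(s) 0-3.
#' @param marker one of `"E-cadherin"`, `"total-Src"`, `"P-cadherin"`,
#'   `"pSRC"` (recycled against `score`).
#' @return Logical vector: `TRUE` for positive.
#' @export
classify_positivity <- function(score, marker) {
  if (any(!score %in% 0:3)) abort("`score` must be integers 0-3.")
  cutoff <- c("E-cadherin" = 2L, "total-Src" = 2L,
              "P-cadherin" = 1L, "pSRC" = 1L)
  unknown <- setdiff(unique(marker), names(cutoff))
  if (length(unknown) > 0) {
    abort(sprintf("unknown marker(s): %s (expected %s).",
                  paste(unknown, collapse = ", "),
                  paste(names(cutoff), collapse = ", ")))
  }
  unname(score >= cutoff[marker])
}

#' Percentage of a total, rounded half-up
#'
#' Cohort tables report `100 * count / total` rounded half-up to a fixed
#' number of decimals (so 18 of 41 prints as 44%, not 43.9%).
#'
#' @param count,total non-negative integers with `count <= total`,
#'   `total > 0`.
#' @param decimals decimal places to keep.
#' @return The rounded percentage.
#' @examples
#' percent_of_total(18, 41)        # 44
#' percent_of_total(84, 416, 1)    # 20.2
#' @export
percent_of_total <- function(count, total, decimals = 0) {
  if (any(total <= 0)) abort("`total` must be positive.")
  if (any(count < 0 | count > total)) abort("`count` must lie in [0, total].")
  p <- 100 * count / total
  scale <- 10^decimals
  floor(p * scale + 0.5) / scale
}

#' Pearson chi-square test of association
#'
#' Pearson's chi-square on an r x c contingency table, without continuity
#' correction, two-sided, with `df = (r - 1)(c - 1)`. All expected counts
#' must be positive (no zero marginals).
#'
#' @param table numeric matrix (or data.frame) of non-negative integer
#'   counts, at least 2 x 2.
#' @return A one-row tibble: `chi2`, `df`, `p`.
#' @export
chi_square_test <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) < 2 || ncol(m) < 2) abort("contingency table must be at least 2 x 2.")
  if (any(m < 0) || any(!is.finite(m))) abort("counts must be non-negative and finite.")
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0)) {
    abort("a row or column marginal is zero: expected counts of 0, test undefined.")
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble(chi2 = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test. In `"exact"` mode the
#' p-value is computed from the exact null distribution of U (ties are not
#' supported exactly and fall back to the approximation with a warning); in
#' `"normal_approx"` mode a tie-corrected normal approximation without
#' continuity correction is used. `"auto"` picks the exact branch when
#' `n * m <= 400` and there are no ties.
#'
#' @param group_a,group_b non-empty numeric samples.
#' @param mode `"auto"`, `"exact"`, or `"normal_approx"`.
#' @return A one-row tibble: `U` (for `group_a`), `p`, `method`.
#' @export
mann_whitney_test <- function(group_a, group_b,
                              mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort("both groups must be non-empty.")
  }
  has_ties <- anyDuplicated(c(group_a, group_b)) > 0
  n <- length(group_a); m <- length(group_b)
  use_exact <- switch(mode,
    exact = TRUE,
    normal_approx = FALSE,
    auto = (n * m <= 400) && !has_ties
  )
  if (use_exact && has_ties) {
    warn("ties present: exact Mann-Whitney p is unavailable, using the normal approximation.")
    use_exact <- FALSE
  }
  ht <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = use_exact, correct = FALSE)
  )
  tibble(
    U = unname(ht$statistic),
    p = ht$p.value,
    method = if (use_exact) "exact" else "normal_approx"
  )
}

#' Bonferroni adjustment
#'
#' Multiplies each p-value by the number of comparisons `m` and caps at 1.
#'
#' @param p_values numeric p-values in `[0, 1]`.
#' @param m number of comparisons; defaults to `length(p_values)`.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, m = NULL) {
  if (any(p_values < 0 | p_values > 1)) abort("p-values must lie in [0, 1].")
  if (is.null(m)) m <- length(p_values)
  if (m < 1) abort("`m` must be >= 1.")
  pmin(1, p_values * m)
}

#' Xenograft tumor volume from caliper measurements
#'
#' `V = 0.5 * a * b^2` with `a` the major and `b` the minor axis in mm.
#'
#' @param a major axis, mm.
#' @param b minor axis, mm; must satisfy `a >= b > 0`.
#' @return Volume in mm^3.
#' @examples
#' tumor_volume(10, 10)  # 500
#' @export
tumor_volume <- function(a, b) {
  if (any(b <= 0)) abort("`b` must be positive.")
  if (any(a < b)) abort("`a` must be >= `b` (axes swapped?).")
  0.5 * a * b^2
}
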