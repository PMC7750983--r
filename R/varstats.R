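#' Coefficient of variation (percent)
#'
#' `100 * sd / mean` with the sample (n - 1) standard deviation.
#' Scale-invariant: multiplying all values by a positive constant leaves
#' the CV unchanged.
#'
#' @param values Numeric vector, length >= 2, with positive mean. Zeros
#'   are permitted (e.g. absent third molars give ratio 0) and inflate
#'   the CV; see [pooling_decision()] for the exclusion variant.
#' @return CV in percent.
#' @export
#' @examples
#' cv_percent(c(1, 2, 3)) # 50
cv_percent <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) {
    abort_icm("CV needs at least 2 values.", "icmolar_validation_error")
  }
  m <- mean(values)
  if (m <= 0) {
    abort_icm("CV is undefined for a non-positive mean.",
              "icmolar_validation_error")
  }
  100 * stats::sd(values) / m
}

#' Sign test: are subsample CVs below the pooled CV?
#'
#' One-sided exact binomial sign test of whether the CV of each locality
#' or sex subsample is less than the pooled, species-level CV. Ties
#' (subsample CV exactly equal to the pooled CV) are dropped.
#'
#' @param subsample_cvs Numeric vector of per-subsample CVs.
#' @param pooled_cv CV of the pooled sample.
#' @return A tibble: `k_below, n, p_value` where `p_value` is
#'   P(X >= k_below) under Binomial(n, 1/2).
#' @export
#' @examples
#' sign_test_pooled_cv(c(4, 5, 6, 7), 8) # 4 of 4 below, p = 0.0625
sign_test_pooled_cv <- function(subsample_cvs, pooled_cv) {
  informative <- subsample_cvs != pooled_cv
  if (!any(informative)) {
    abort_icm("All subsample CVs tie with the pooled CV: no informative comparisons.",
              "icmolar_validation_error")
  }
  x <- subsample_cvs[informative]
  k <- sum(x < pooled_cv)
  n <- length(x)
  p <- stats::binom.test(k, n, p = 0.5, alternative = "greater")$p.value
  tibble::tibble(k_below = k, n = n, p_value = p)
}

#' Pairwise Mann-Whitney U tests between groups
#'
#' For every pair of groups, the Mann-Whitney U statistic of the first
#' (row) group under the rank-sum convention and the Bonferroni-corrected
#' two-sided p-value (raw p multiplied by the number of pairs, capped at
#' 1; the correction is applied within the chosen ratio only). Exact
#' enumeration is used when both groups have n <= 20 and there are no
#' ties; otherwise the normal approximation with tie correction.
#'
#' @param ratios A ratio tibble from [compute_ratios()].
#' @param ratio Which ratio to compare: `"r21"` or `"r31"`.
#' @param group Name of the grouping column (default `"locality"`).
#' @return A tibble with one row per unordered pair:
#'   `group1, group2, n1, n2, statistic (U of group1), p_value,
#'   p_bonferroni`.
#' @export
pairwise_mann_whitney <- function(ratios, ratio = c("r21", "r31"),
                                  group = "locality") {
  ratio <- match.arg(ratio)
  vals <- ratios[[ratio]]
  grp <- as.character(ratios[[group]])
  keep <- !is.na(grp) & is.finite(vals)
  vals <- vals[keep]; grp <- grp[keep]
  sizes <- table(grp)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warning(sprintf("Excluding group(s) with n < 2: %s.",
                    paste(small, collapse = ", ")), call. = FALSE)
    keep <- !(grp %in% small)
    vals <- vals[keep]; grp <- grp[keep]
  }
  labels <- sort(unique(grp))
  if (length(labels) < 2) {
    abort_icm("Pairwise comparison needs at least 2 groups with n >= 2.",
              "icmolar_validation_error")
  }
  pairs <- utils::combn(labels, 2, simplify = FALSE)
  n_pairs <- length(pairs)
  out <- purrr::map_dfr(pairs, function(pr) {
    x <- vals[grp == pr[1]]
    y <- vals[grp == pr[2]]
    has_ties <- anyDuplicated(c(x, y)) > 0
    use_exact <- length(x) <= 20 && length(y) <= 20 && !has_ties
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = use_exact, correct = !use_exact)
    )
    tibble::tibble(group1 = pr[1], group2 = pr[2],
                   n1 = length(x), n2 = length(y),
                   statistic = unname(wt$statistic),
                   p_value = wt$p.value)
  })
  out$p_bonferroni <- pmin(out$p_value * n_pairs, 1)
  out
}

#' Pool-or-split decision for grouped ratio samples
#'
#' Runs pairwise Mann-Whitney comparisons (with Bonferroni correction
#' applied within each ratio) for both M2/M1 and M3/M1 and pools the
#' groups when no corrected p-value falls below `alpha`. The report also
#' carries per-group and pooled CVs and raises an over-averaging flag
#' when a pooled ratio CV exceeds 15% — a sign the sample may be pooling
#' across too much time, space or sex structure.
#'
#' @inheritParams pairwise_mann_whitney
#' @param alpha Significance level for the split decision (default 0.05).
#' @param exclude_zero Drop zero ratios (absent third molars) from CV
#'   computations instead of retaining and flagging them.
#' @return A list of class `pooling_report`: `decision` ("pool" or
#'   "split"), `alpha`, `tests` (combined pairwise table), `cv` (per-group
#'   and pooled CVs per ratio), `over_averaging` flag, and
#'   `n_zero_ratios`.
#' @export
pooling_decision <- function(ratios, group = "locality", alpha = 0.05,
                             exclude_zero = FALSE) {
  tests <- dplyr::bind_rows(
    dplyr::mutate(pairwise_mann_whitney(ratios, "r21", group), ratio = "r21"),
    dplyr::mutate(pairwise_mann_whitney(ratios, "r31", group), ratio = "r31")
  )
  decision <- if (any(tests$p_bonferroni < alpha)) "split" else "pool"

  cv_of <- function(v) {
    n_zero <- sum(v == 0, na.rm = TRUE)
    if (exclude_zero) v <- v[v != 0]
    list(cv = cv_percent(v), n_zero = n_zero)
  }
  grp <- as.character(ratios[[group]])
  cv_tab <- purrr::map_dfr(c("r21", "r31"), function(rt) {
    v <- ratios[[rt]]
    pooled <- cv_of(v)
    per_group <- purrr::map_dfr(
      split(v, grp),
      function(vg) tibble::tibble(n = length(vg), cv = cv_of(vg)$cv),
      .id = "group"
    )
    dplyr::bind_rows(
      tibble::tibble(group = "(pooled)", n = sum(is.finite(v)),
                     cv = pooled$cv),
      per_group
    ) |> dplyr::mutate(ratio = rt)
  })
  pooled_cvs <- cv_tab$cv[cv_tab$group == "(pooled)"]
  structure(
    list(decision = decision, alpha = alpha, tests = tests, cv = cv_tab,
         over_averaging = any(pooled_cvs > 15),
         n_zero_ratios = sum(ratios$r31 == 0, na.rm = TRUE)),
    class = "pooling_report"
  )
}

#' @export
print.pooling_report <- function(x, ...) {
  cat("Pooling decision:", x$decision,
      sprintf("(alpha = %g, min corrected p = %.4g)\n",
              x$alpha, min(x$tests$p_bonferroni)))
  if (x$over_averaging) {
    cat("Warning: a pooled ratio CV exceeds 15% - the sample may be over-averaging.\n")
  }
  if (x$n_zero_ratios > 0) {
    cat("Note:", x$n_zero_ratios, "specimen(s) have ratio 0 (absent M3).\n")
  }
  invisible(x)
}
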