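#' Reference intervals for ratio mean and SD
#'
#' Seeded bootstrap percentile 95% intervals for the mean and the sample
#' SD of each molar ratio (M2/M1 and M3/M1), computed from the complete
#' full sample. These intervals are the yardstick the resampling
#' simulations compare their pseudoreplicate estimates against. A
#' normal-theory interval for the mean is available as an alternative.
#'
#' @param ratios A ratio tibble from [compute_ratios()], n >= 10.
#' @param n_boot Bootstrap resamples (default 10000).
#' @param method Interval type for the mean statistic: `"bootstrap"`
#'   (default; percentile interval of the resampled mean), `"normal"`
#'   (normal-theory interval for the mean), or `"quantile"` (the inner
#'   95% quantile interval of the per-specimen ratio distribution
#'   itself — far wider than a mean CI, and the scale on which
#'   single-specimen or composite point estimates are judged). The SD
#'   interval is always the bootstrap percentile interval.
#' @param seed Integer seed; `NULL` uses the ambient RNG stream.
#' @return A tibble of class `reference_intervals`: one row per
#'   ratio x statistic with `ratio, statistic, point, lower, upper,
#'   method, n_boot`.
#' @export
reference_intervals <- function(ratios, n_boot = 10000,
                                method = c("bootstrap", "normal", "quantile"),
                                seed = NULL) {
  method <- match.arg(method)
  n <- nrow(ratios)
  if (n < 10) {
    abort_icm("Reference intervals need a full sample of n >= 10.",
              "icmolar_validation_error")
  }
  with_seed_or_not(seed, {
    out <- purrr::map_dfr(c("r21", "r31"), function(rt) {
      v <- ratios[[rt]]
      idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
      vm <- matrix(v[idx], nrow = n)
      boot_means <- colMeans(vm)
      boot_sds <- sqrt((colSums(vm^2) - n * boot_means^2) / (n - 1))
      mean_ci <- switch(
        method,
        normal = mean(v) + c(-1, 1) * stats::qnorm(0.975) * stats::sd(v) / sqrt(n),
        quantile = stats::quantile(v, c(0.025, 0.975), names = FALSE),
        stats::quantile(boot_means, c(0.025, 0.975), names = FALSE)
      )
      sd_ci <- stats::quantile(boot_sds, c(0.025, 0.975), names = FALSE)
      tibble::tibble(
        ratio = rt, statistic = c("mean", "sd"),
        point = c(mean(v), stats::sd(v)),
        lower = c(mean_ci[1], sd_ci[1]),
        upper = c(mean_ci[2], sd_ci[2])
      )
    })
    out$method <- method
    out$n_boot <- n_boot
    class(out) <- c("reference_intervals", class(out))
    out
  })
}

ref_bounds <- function(reference, rt, stat) {
  row <- reference[reference$ratio == rt & reference$statistic == stat, ]
  c(row$lower, row$upper)
}

#' Sample-size adequacy simulation for ratio mean and SD
#'
#' Resamples the full sample without replacement at each sub-sample size
#' N and records the proportion of pseudoreplicate means and SDs that
#' fall outside the full-sample reference intervals. A sample size is
#' deemed adequate once at least 95% of pseudoreplicates fall inside
#' (see [adequacy_threshold()]).
#'
#' @param ratios A ratio tibble from [compute_ratios()].
#' @param reference A `reference_intervals` for the same ratios.
#' @param n_grid Integer vector of sub-sample sizes, each in
#'   `[2, nrow(ratios)]` (default `2:(n - 1)`).
#' @param reps Pseudoreplicates per N (default 10000).
#' @param seed Integer seed; `NULL` uses the ambient RNG stream.
#' @return A tibble of class `sample_size_sim`: one row per N x ratio
#'   with `n, ratio, prop_mean_outside, prop_sd_outside, mean_sd
#'   (average pseudoreplicate SD), reps`.
#' @export
sample_size_simulation <- function(ratios, reference,
                                   n_grid = 2:(nrow(ratios) - 1),
                                   reps = 10000, seed = NULL) {
  n <- nrow(ratios)
  if (any(n_grid < 2) || any(n_grid > n)) {
    abort_icm("Every grid N must satisfy 2 <= N <= n.",
              "icmolar_validation_error")
  }
  vals <- list(r21 = ratios$r21, r31 = ratios$r31)
  with_seed_or_not(seed, {
    out <- purrr::map_dfr(n_grid, function(N) {
      idx <- vapply(seq_len(reps), function(i) sample.int(n, N),
                    integer(N))
      idx <- matrix(idx, nrow = N)
      purrr::map_dfr(names(vals), function(rt) {
        vm <- matrix(vals[[rt]][idx], nrow = N)
        means <- colMeans(vm)
        sds <- sqrt(pmax(colSums(vm^2) - N * means^2, 0) / (N - 1))
        bm <- ref_bounds(reference, rt, "mean")
        bs <- ref_bounds(reference, rt, "sd")
        tibble::tibble(
          n = N, ratio = rt,
          prop_mean_outside = mean(means < bm[1] | means > bm[2]),
          prop_sd_outside = mean(sds < bs[1] | sds > bs[2]),
          mean_sd = mean(sds), reps = reps
        )
      })
    })
    class(out) <- c("sample_size_sim", class(out))
    out
  })
}

#' Composite molar-row simulation
#'
#' Emulates estimating ratio statistics from collections of isolated
#' teeth. For each N on the grid, each outer replicate draws N teeth per
#' tooth position independently with replacement (a composite cannot
#' know specimen identity), forms a composite point estimate as the
#' ratio of per-position means, and estimates spread by an inner loop
#' that resamples one tooth per position `inner_reps` times and takes
#' the SD of those pseudosample ratios. Proportions of outer estimates
#' whose mean (and pseudosample SD) fall outside the reference intervals
#' are recorded.
#'
#' A `paired` mode draws whole specimens instead (retaining between-
#' position covariance) and exists for validation only.
#'
#' @param rows A tibble of complete molar rows (`m1, m2, m3`).
#' @param reference A `reference_intervals` computed from the complete
#'   rows' ratios.
#' @param n_grid Teeth per position (default `1:50`).
#' @param outer_reps Composite datasets per N (default 1000).
#' @param inner_reps Inner pseudosample resamples (default 1000).
#' @param paired Draw whole specimens rather than independent teeth
#'   (default `FALSE`).
#' @param seed Integer seed; `NULL` uses the ambient RNG stream.
#' @return A tibble of class `composite_sim`: one row per N x ratio with
#'   `n, ratio, prop_mean_outside, prop_sd_outside, mean_estimate,
#'   sd_of_estimates, outer_reps, inner_reps`.
#' @export
composite_simulation <- function(rows, reference, n_grid = 1:50,
                                 outer_reps = 1000, inner_reps = 1000,
                                 paired = FALSE, seed = NULL) {
  n <- nrow(rows)
  if (n == 0) {
    abort_icm("No molar rows supplied.", "icmolar_validation_error")
  }
  m1 <- rows$m1; m2 <- rows$m2; m3 <- rows$m3
  with_seed_or_not(seed, {
    out <- purrr::map_dfr(n_grid, function(N) {
      est <- matrix(NA_real_, outer_reps, 2)   # composite r21, r31
      psd <- matrix(NA_real_, outer_reps, 2)   # pseudosample SDs
      for (b in seq_len(outer_reps)) {
        if (paired) {
          i1 <- i2 <- i3 <- sample.int(n, N, replace = TRUE)
        } else {
          i1 <- sample.int(n, N, replace = TRUE)
          i2 <- sample.int(n, N, replace = TRUE)
          i3 <- sample.int(n, N, replace = TRUE)
        }
        est[b, ] <- c(mean(m2[i2]) / mean(m1[i1]),
                      mean(m3[i3]) / mean(m1[i1]))
        if (paired) {
          jj <- sample.int(N, inner_reps, replace = TRUE)
          j1 <- i1[jj]; j2 <- i2[jj]; j3 <- i3[jj]
        } else {
          j1 <- i1[sample.int(N, inner_reps, replace = TRUE)]
          j2 <- i2[sample.int(N, inner_reps, replace = TRUE)]
          j3 <- i3[sample.int(N, inner_reps, replace = TRUE)]
        }
        psd[b, ] <- c(stats::sd(m2[j2] / m1[j1]),
                      stats::sd(m3[j3] / m1[j1]))
      }
      purrr::map_dfr(1:2, function(k) {
        rt <- c("r21", "r31")[k]
        bm <- ref_bounds(reference, rt, "mean")
        bs <- ref_bounds(reference, rt, "sd")
        tibble::tibble(
          n = N, ratio = rt,
          prop_mean_outside = mean(est[, k] < bm[1] | est[, k] > bm[2]),
          prop_sd_outside = mean(psd[, k] < bs[1] | psd[, k] > bs[2]),
          mean_estimate = mean(est[, k]),
          sd_of_estimates = stats::sd(est[, k]),
          outer_reps = outer_reps, inner_reps = inner_reps
        )
      })
    })
    class(out) <- c("composite_sim", class(out))
    out
  })
}

#' Smallest adequate sample size
#'
#' Scans a [sample_size_simulation()] (or [composite_simulation()])
#' result in grid order and returns, per ratio, the smallest N whose
#' proportion of pseudoreplicates outside the reference interval is at
#' most 0.05. Non-monotone proportion sequences are reported with a
#' message, but the rule stays "first N meeting the bound".
#'
#' @param result A `sample_size_sim` or `composite_sim` tibble.
#' @param statistic `"mean"` or `"sd"`.
#' @param threshold Maximum tolerated proportion outside (default 0.05).
#' @return A tibble with one row per ratio: `ratio, statistic,
#'   n_adequate` (`NA` when no grid N qualifies).
#' @export
adequacy_threshold <- function(result, statistic = c("mean", "sd"),
                               threshold = 0.05) {
  statistic <- match.arg(statistic)
  col <- paste0("prop_", statistic, "_outside")
  purrr::map_dfr(split(result, result$ratio), function(d) {
    d <- d[order(d$n), ]
    p <- d[[col]]
    ok <- which(p <= threshold)
    if (length(ok) > 0 && any(diff(p) > 0)) {
      message(sprintf("Proportions for %s/%s are non-monotone in N; returning the first adequate N.",
                      d$ratio[1], statistic))
    }
    tibble::tibble(ratio = d$ratio[1], statistic = statistic,
                   n_adequate = if (length(ok) == 0) NA_integer_ else
                     as.integer(d$n[ok[1]]))
  })
}

#' Plot a resampling simulation result
#'
#' Proportion of pseudoreplicates outside the full-sample reference
#' interval against sub-sample size, per ratio and statistic; the dashed
#' line at 0.05 marks the adequacy rule.
#'
#' @param object A `sample_size_sim` or `composite_sim` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sample_size_sim
#' @export
autoplot.sample_size_sim <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    dplyr::all_of(c("prop_mean_outside", "prop_sd_outside")),
    names_to = "statistic", values_to = "prop_outside"
  )
  df$statistic <- sub("^prop_(.*)_outside$", "\\1", df$statistic)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$prop_outside,
                                   colour = .data$ratio)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.05, linetype = "dashed") +
    ggplot2::facet_wrap(~statistic) +
    ggplot2::labs(x = "sub-sample size N", y = "proportion outside 95% CI") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.sample_size_sim
#' @method autoplot composite_sim
#' @export
autoplot.composite_sim <- function(object, ...) {
  autoplot.sample_size_sim(object, ...)
}
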