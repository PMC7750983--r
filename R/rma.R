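#' Reduced major axis (model II) regression
#'
#' Fits the standardised (reduced) major axis: slope = SD(y)/SD(x) with
#' the sign of the correlation, intercept = mean(y) - slope * mean(x).
#' 95% confidence intervals for slope and intercept come from a seeded
#' bootstrap over observations (percentile method), and the p-value for
#' association from a one-tailed permutation test of |r|.
#'
#' In cascade terms, regressing M3/M1 on M2/M1 tests whether the fitted
#' line is compatible with the prediction M3 = 2 M2 - M1, i.e. slope 2
#' and intercept -1 in ratio space (one-third of total row length for the
#' molar module component when lengths are used).
#'
#' @param x,y Paired numeric vectors (e.g. `r21` and `r31` from
#'   [compute_ratios()]); length >= 3, each with nonzero variance.
#' @param n_resamples Bootstrap resamples for the CIs (default 9999).
#' @param n_permutations Permutations for the association p-value
#'   (default 999).
#' @param seed Integer seed; `NULL` uses the ambient RNG stream.
#' @return An object of class `rma_fit`: a list with `slope`, `intercept`,
#'   `r_squared`, `slope_ci`, `intercept_ci`, `p_value`, `n`,
#'   `n_resamples`, `n_permutations`.
#' @export
#' @examples
#' fit <- rma_regression(c(0.7, 0.8, 0.9), c(0.4, 0.6, 0.8),
#'                       n_resamples = 199, seed = 1)
#' fit$slope # 2 (points lie on the cascade line)
rma_regression <- function(x, y, n_resamples = 9999, n_permutations = 999,
                           seed = NULL) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) {
    abort_icm("RMA regression needs at least 3 paired observations.",
              "icmolar_validation_error")
  }
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) {
    abort_icm("RMA regression is undefined when either variable has zero variance.",
              "icmolar_validation_error")
  }
  r <- stats::cor(x, y)
  if (r == 0) {
    abort_icm("Correlation is exactly zero: the RMA slope sign is ambiguous.",
              "icmolar_validation_error")
  }
  slope <- sign(r) * sy / sx
  intercept <- mean(y) - slope * mean(x)

  res <- with_seed_or_not(seed, {
    boot <- vapply(seq_len(n_resamples), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      xb <- x[idx]; yb <- y[idx]
      sxb <- stats::sd(xb); syb <- stats::sd(yb)
      if (sxb == 0 || syb == 0) return(c(NA_real_, NA_real_))
      rb <- stats::cor(xb, yb)
      sb <- if (rb < 0) -syb / sxb else syb / sxb
      c(sb, mean(yb) - sb * mean(xb))
    }, numeric(2))
    perm <- vapply(seq_len(n_permutations), function(i) {
      abs(stats::cor(x, sample(y)))
    }, numeric(1))
    list(boot = boot, perm = perm)
  })
  if (n_resamples > 0) {
    slope_ci <- stats::quantile(res$boot[1, ], c(0.025, 0.975), na.rm = TRUE,
                                names = FALSE)
    intercept_ci <- stats::quantile(res$boot[2, ], c(0.025, 0.975),
                                    na.rm = TRUE, names = FALSE)
  } else {
    slope_ci <- intercept_ci <- c(NA_real_, NA_real_)
  }
  p_value <- (1 + sum(res$perm >= abs(r))) / (n_permutations + 1)

  structure(
    list(slope = slope, intercept = intercept, r_squared = r^2,
         slope_ci = slope_ci, intercept_ci = intercept_ci,
         p_value = p_value, n = n, n_resamples = n_resamples,
         n_permutations = n_permutations),
    class = "rma_fit"
  )
}

#' Association strength and permutation p-value in ratio space
#'
#' The first cascade prediction is that the regression of M3/M1 on M2/M1
#' explains a significant amount of variation. This helper reports the
#' squared correlation and a one-tailed permutation p-value.
#'
#' @inheritParams rma_regression
#' @return A tibble with columns `r_squared` and `p_value`.
#' @export
prediction_one_fit <- function(x, y, n_permutations = 999, seed = NULL) {
  fit <- rma_regression(x, y, n_resamples = 0, n_permutations = n_permutations,
                        seed = seed)
  tibble::tibble(r_squared = fit$r_squared, p_value = fit$p_value)
}

#' @export
print.rma_fit <- function(x, ...) {
  cat("Reduced major axis regression (n =", x$n, ")\n")
  cat(sprintf("  slope     %8.4f  [%.4f, %.4f]\n",
              x$slope, x$slope_ci[1], x$slope_ci[2]))
  cat(sprintf("  intercept %8.4f  [%.4f, %.4f]\n",
              x$intercept, x$intercept_ci[1], x$intercept_ci[2]))
  cat(sprintf("  r^2 = %.4f, permutation p = %.4g\n", x$r_squared, x$p_value))
  invisible(x)
}

#' Tidy an RMA fit
#'
#' @param x An `rma_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per coefficient:
#'   `term, estimate, conf.low, conf.high`.
#' @method tidy rma_fit
#' @export
tidy.rma_fit <- function(x, ...) {
  tibble::tibble(
    term = c("slope", "intercept"),
    estimate = c(x$slope, x$intercept),
    conf.low = c(x$slope_ci[1], x$intercept_ci[1]),
    conf.high = c(x$slope_ci[2], x$intercept_ci[2])
  )
}

#' Glance at an RMA fit
#'
#' @param x An `rma_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `r.squared, p.value, nobs`.
#' @method glance rma_fit
#' @export
glance.rma_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, p.value = x$p_value, nobs = x$n)
}

#' Plot molar ratios with fitted and predicted cascade lines
#'
#' Scatter of (M2/M1, M3/M1) with the fitted RMA line (red) and the
#' cascade-model line M3/M1 = 2 M2/M1 - 1 (black, dashed).
#'
#' @param object An `rma_fit`.
#' @param ratios The ratio tibble the fit was computed from (needs columns
#'   `r21`, `r31`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rma_fit
#' @export
autoplot.rma_fit <- function(object, ratios, ...) {
  ggplot2::ggplot(ratios, ggplot2::aes(x = .data$r21, y = .data$r31)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "red") +
    ggplot2::geom_abline(slope = 2, intercept = -1, linetype = "dashed") +
    ggplot2::labs(x = "M2 / M1", y = "M3 / M1",
                  title = "Molar size ratios vs. inhibitory-cascade line") +
    ggplot2::theme_minimal()
}
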