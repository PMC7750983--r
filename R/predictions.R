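#' Predicted M3/M1 ratio under the inhibitory cascade
#'
#' The cascade's linear rule implies that the mean M3/M1 ratio is
#' determined by the mean M2/M1 ratio: `mu_31 = 2 * mu_21 - 1`.
#'
#' @param mu_r21 Mean M2/M1 ratio, positive.
#' @return Predicted mean M3/M1 ratio. May be negative (for
#'   `mu_r21 < 0.5`), which is biologically impossible and is flagged
#'   downstream rather than rejected here.
#' @export
#' @examples
#' theoretical_m3_ratio(0.8) # 0.6
theoretical_m3_ratio <- function(mu_r21) {
  check_scalar_number(mu_r21, "mu_r21", lower = 0, closed_lower = FALSE)
  2 * mu_r21 - 1
}

#' Predicted M3 variance and covariances under the cascade
#'
#' If M3 = 2 M2 - M1 then variance algebra fixes the third molar's second
#' moments from the (M1, M2) block:
#' var(M3) = 4 var(M2) + var(M1) - 4 cov(M1, M2),
#' cov(M1, M3) = 2 cov(M1, M2) - var(M1),
#' cov(M2, M3) = 2 var(M2) - cov(M1, M2).
#'
#' @param var1,var2 Variances of M1 and M2 sizes (non-negative).
#' @param cov12 Covariance of M1 and M2; must satisfy
#'   `cov12^2 <= var1 * var2`.
#' @return Named numeric vector `c(var3 = , cov13 = , cov23 = )`.
#' @export
#' @examples
#' theoretical_covariances(1, 1, 0.5) # c(var3 = 3, cov13 = 0, cov23 = 1.5)
theoretical_covariances <- function(var1, var2, cov12) {
  check_scalar_number(var1, "var1", lower = 0)
  check_scalar_number(var2, "var2", lower = 0)
  check_scalar_number(cov12, "cov12")
  if (cov12^2 > var1 * var2 * (1 + 1e-12)) {
    abort_icm("Invalid covariance block: cov12^2 exceeds var1 * var2.",
              "icmolar_validation_error")
  }
  c(var3 = 4 * var2 + var1 - 4 * cov12,
    cov13 = 2 * cov12 - var1,
    cov23 = 2 * var2 - cov12)
}

# Delta-method variance of tooth_i / (m1 + m2 + m3) at (mu, Sigma),
# vectorised over draws. mu: D x 3, sigs: list of element vectors.
rel_size_var <- function(i, mu, s) {
  tot <- mu[, 1] + mu[, 2] + mu[, 3]
  # gradient g_j = (delta_ij * tot - mu_i) / tot^2
  g <- -mu[, i] / tot^2
  g_mat <- cbind(g, g, g)
  g_mat[, i] <- g_mat[, i] + 1 / tot
  g1 <- g_mat[, 1]; g2 <- g_mat[, 2]; g3 <- g_mat[, 3]
  g1^2 * s$s11 + g2^2 * s$s22 + g3^2 * s$s33 +
    2 * (g1 * g2 * s$s12 + g1 * g3 * s$s13 + g2 * g3 * s$s23)
}

#' Evaluate the six inhibitory-cascade predictions
#'
#' For every posterior draw (mu, Sigma), computes six observed quantities
#' and their cascade-theoretical counterparts, forms the
#' observed/theoretical ratio, and summarises each ratio's posterior by
#' its kernel-density mode and 95% highest-posterior-density interval.
#' A prediction is flagged `consistent` when its HPD contains 1.
#'
#' The six parameters:
#' \describe{
#'   \item{m3_mean}{observed mu3 vs. theoretical 2 mu2 - mu1 (linear
#'     cascade predictor).}
#'   \item{rel_m2_mean}{observed mu2 / (mu1 + mu2 + mu3) vs. the
#'     one-third rule.}
#'   \item{rel_m3_var}{delta-method variance of relative M3 vs. that of
#'     relative M1 (equal under the cascade).}
#'   \item{m3_var}{observed var(M3) vs. 4 var(M2) + var(M1) -
#'     4 cov(M1, M2).}
#'   \item{cov_m1_m3}{observed cov(M1, M3) vs. 2 cov(M1, M2) - var(M1).}
#'   \item{cov_m2_m3}{observed cov(M2, M3) vs. 2 var(M2) - cov(M1, M2).}
#' }
#'
#' Relative-size variances are obtained per draw by the delta method on
#' tooth / (row total) at that draw's (mu, Sigma). When a parameter's
#' theoretical value is non-positive in more than `unstable_prop` of
#' draws the ratio is unstable: the report trims those draws, marks the
#' parameter `unstable`, and sets its `consistent` flag to `NA`.
#'
#' @param draws A `molar_posterior`, normally after
#'   [adjust_measurement_error()].
#' @param prob HPD coverage (default 0.95).
#' @param unstable_prop Tolerated proportion of non-positive theoretical
#'   draws (default 0.05).
#' @return A tibble of class `icm_prediction_report`: one row per
#'   parameter with `parameter, mode, hpd_lower, hpd_upper, consistent,
#'   unstable, prop_theoretical_nonpositive`.
#' @export
evaluate_icm_predictions <- function(draws, prob = 0.95,
                                     unstable_prop = 0.05) {
  stopifnot(inherits(draws, "molar_posterior"))
  mu <- draws$mu
  s <- list(s11 = draws$Sigma[1, 1, ], s22 = draws$Sigma[2, 2, ],
            s33 = draws$Sigma[3, 3, ], s12 = draws$Sigma[1, 2, ],
            s13 = draws$Sigma[1, 3, ], s23 = draws$Sigma[2, 3, ])
  tot <- mu[, 1] + mu[, 2] + mu[, 3]
  observed <- list(
    m3_mean = mu[, 3],
    rel_m2_mean = mu[, 2] / tot,
    rel_m3_var = rel_size_var(3, mu, s),
    m3_var = s$s33,
    cov_m1_m3 = s$s13,
    cov_m2_m3 = s$s23
  )
  theoretical <- list(
    m3_mean = 2 * mu[, 2] - mu[, 1],
    rel_m2_mean = rep(1 / 3, nrow(mu)),
    rel_m3_var = rel_size_var(1, mu, s),
    m3_var = 4 * s$s22 + s$s11 - 4 * s$s12,
    cov_m1_m3 = 2 * s$s12 - s$s11,
    cov_m2_m3 = 2 * s$s22 - s$s12
  )
  out <- purrr::map_dfr(names(observed), function(p) {
    theo <- theoretical[[p]]
    obs <- observed[[p]]
    nonpos <- theo <= 0
    prop_bad <- mean(nonpos)
    unstable <- prop_bad > unstable_prop
    ratio <- (obs / theo)[!nonpos]
    hpd <- hpd_interval(ratio, prob = prob)
    tibble::tibble(
      parameter = p,
      mode = density_mode(ratio),
      hpd_lower = hpd[["lower"]],
      hpd_upper = hpd[["upper"]],
      consistent = if (unstable) NA else
        hpd[["lower"]] <= 1 && hpd[["upper"]] >= 1,
      unstable = unstable,
      prop_theoretical_nonpositive = prop_bad
    )
  })
  class(out) <- c("icm_prediction_report", class(out))
  attr(out, "metric") <- draws$metric
  attr(out, "repeatability") <- draws$repeatability
  out
}

#' Plot an ICM prediction report
#'
#' Posterior modes with 95% HPD bars of the observed/theoretical ratio
#' for the six cascade parameters; the horizontal line at 1 marks exact
#' agreement with the model.
#'
#' @param object An `icm_prediction_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot icm_prediction_report
#' @export
autoplot.icm_prediction_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$parameter <- factor(df$parameter, levels = df$parameter)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$parameter, y = .data$mode)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$hpd_lower,
                                          ymax = .data$hpd_upper)) +
    ggplot2::labs(x = NULL, y = "observed / theoretical",
                  title = "Inhibitory-cascade predictions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
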