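#' Bayesian posterior for molar-size means and covariances
#'
#' Fits a multivariate Gaussian to the per-specimen (M1, M2, M3) sizes
#' with a flat prior on the mean vector and a weakly informative
#' inverse-Wishart prior on the covariance matrix (scale `iw_scale * I3`,
#' `iw_df` degrees of freedom; covariances centred on zero). Sampling is
#' by a two-block conjugate Gibbs sampler:
#' mu | Sigma ~ N(ybar, Sigma/n) and
#' Sigma | mu ~ IW(iw_df + n, iw_scale * I + sum (y - mu)(y - mu)').
#'
#' Defaults mirror a long thinned chain (burn-in 5e5, every 1000th of a
#' further 1e6 iterations kept, 1000 draws). Because both full
#' conditionals are exact conjugate draws the chain mixes essentially
#' immediately, so far shorter settings (e.g. `burn_in = 1000`,
#' `thin = 10`) give equivalent posteriors; the long defaults are kept
#' for comparability with common practice for non-conjugate samplers.
#'
#' @param rows A tibble of complete molar rows with columns `m1, m2, m3`
#'   (>= 4 rows).
#' @param n_draws Number of posterior draws to keep (default 1000).
#' @param burn_in Iterations discarded before sampling (default 500000).
#' @param thin Keep every `thin`-th iteration after burn-in
#'   (default 1000).
#' @param iw_scale Scalar multiplying the identity in the inverse-Wishart
#'   prior scale matrix (default 1e-3).
#' @param iw_df Prior degrees of freedom (default 3.002, just above the
#'   dimension, i.e. close to non-informative).
#' @param seed Integer seed; `NULL` uses the ambient RNG stream.
#' @return An object of class `molar_posterior`: list with `mu`
#'   (n_draws x 3 matrix), `Sigma` (3 x 3 x n_draws array), `metric`,
#'   `repeatability` (1 until adjusted), `n_obs`, and the sampler
#'   settings.
#' @export
fit_size_posterior <- function(rows, n_draws = 1000, burn_in = 500000,
                               thin = 1000, iw_scale = 1e-3, iw_df = 3.002,
                               seed = NULL) {
  y <- as.matrix(rows[, c("m1", "m2", "m3")])
  storage.mode(y) <- "double"
  n <- nrow(y)
  if (n < 4) {
    abort_icm("The posterior needs at least 4 complete molar rows.",
              "icmolar_validation_error")
  }
  ybar <- colMeans(y)
  s_centered <- crossprod(sweep(y, 2, ybar))  # sum (y - ybar)(y - ybar)'
  v0 <- diag(iw_scale, 3)
  nu_n <- iw_df + n

  with_seed_or_not(seed, {
    mu_draws <- matrix(NA_real_, n_draws, 3,
                       dimnames = list(NULL, c("m1", "m2", "m3")))
    sig_draws <- array(NA_real_, c(3, 3, n_draws))
    sigma <- stats::cov(y) + v0
    total <- burn_in + n_draws * thin
    kept <- 0L
    for (it in seq_len(total)) {
      # mu | Sigma, y
      ch <- chol(sigma)
      mu <- ybar + drop(crossprod(ch, stats::rnorm(3))) / sqrt(n)
      # Sigma | mu, y : scale = V0 + S + n (ybar - mu)(ybar - mu)'
      d <- ybar - mu
      scale_m <- v0 + s_centered + n * tcrossprod(d)
      ch_s <- tryCatch(chol(scale_m), error = function(e) NULL)
      if (is.null(ch_s)) {
        abort_icm("Posterior scale matrix is not positive-definite; the sample covariance is singular. Add jitter or more data.",
                  "icmolar_singular_error")
      }
      w <- stats::rWishart(1, df = nu_n, Sigma = chol2inv(ch_s))[, , 1]
      sigma <- chol2inv(chol(w))
      if (it > burn_in && (it - burn_in) %% thin == 0) {
        kept <- kept + 1L
        mu_draws[kept, ] <- mu
        sig_draws[, , kept] <- sigma
      }
    }
    structure(
      list(mu = mu_draws, Sigma = sig_draws,
           metric = if ("metric" %in% names(rows)) rows$metric[1] else NA_character_,
           repeatability = 1, n_obs = n,
           settings = list(n_draws = n_draws, burn_in = burn_in, thin = thin,
                           iw_scale = iw_scale, iw_df = iw_df)),
      class = "molar_posterior"
    )
  })
}

#' Deflate posterior variances for measurement error
#'
#' Multiplies every variance (diagonal) draw of the posterior covariance
#' by the measurement repeatability, leaving covariances and mean draws
#' unchanged, so downstream prediction tests compare biological rather
#' than biological-plus-measurement variance. Applying repeatability r
#' and then r' is identical to applying r * r'.
#'
#' @param draws A `molar_posterior`.
#' @param repeatability Repeatability fraction in (0, 1], e.g. from
#'   [molar_repeatability()].
#' @return The adjusted `molar_posterior`; its `repeatability` field
#'   accumulates the applied factors.
#' @export
adjust_measurement_error <- function(draws, repeatability) {
  stopifnot(inherits(draws, "molar_posterior"))
  check_scalar_number(repeatability, "repeatability", lower = 0, upper = 1,
                      closed_lower = FALSE)
  for (j in 1:3) draws$Sigma[j, j, ] <- draws$Sigma[j, j, ] * repeatability
  draws$repeatability <- draws$repeatability * repeatability
  draws
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval containing `ceiling(prob * n)` of the
#' sorted sample values.
#'
#' @param samples Numeric vector of >= 10 posterior samples.
#' @param prob Coverage probability in (0, 1), default 0.95.
#' @return Named numeric vector `c(lower = , upper = )`.
#' @export
#' @examples
#' hpd_interval(rnorm(1000))
hpd_interval <- function(samples, prob = 0.95) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 10) {
    abort_icm("HPD intervals need at least 10 samples.",
              "icmolar_validation_error")
  }
  check_scalar_number(prob, "prob", lower = 0, upper = 1,
                      closed_lower = FALSE, closed_upper = FALSE)
  x <- sort(samples)
  m <- ceiling(prob * n)
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  starts <- seq_len(n - m)
  widths <- x[starts + m] - x[starts]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m])
}

# Posterior mode via Gaussian kernel density (Silverman bandwidth,
# argmax over a 512-point grid).
density_mode <- function(samples) {
  d <- stats::density(samples, bw = "nrd0", n = 512)
  d$x[which.max(d$y)]
}

#' @export
print.molar_posterior <- function(x, ...) {
  cat("Posterior for molar sizes (", nrow(x$mu), " draws, n = ", x$n_obs,
      ", metric = ", x$metric, ")\n", sep = "")
  cat("  posterior mean of mu:   ", paste(sprintf("%.4f", colMeans(x$mu)),
                                          collapse = "  "), "\n")
  cat("  repeatability applied:  ", format(x$repeatability), "\n")
  invisible(x)
}

#' Tidy posterior draws
#'
#' @param x A `molar_posterior`.
#' @param ... Unused.
#' @return A tibble with one row per draw: mean draws `mu1..mu3` and the
#'   six distinct covariance elements `s11, s22, s33, s12, s13, s23`.
#' @method tidy molar_posterior
#' @export
tidy.molar_posterior <- function(x, ...) {
  tibble::tibble(
    draw = seq_len(nrow(x$mu)),
    mu1 = x$mu[, 1], mu2 = x$mu[, 2], mu3 = x$mu[, 3],
    s11 = x$Sigma[1, 1, ], s22 = x$Sigma[2, 2, ], s33 = x$Sigma[3, 3, ],
    s12 = x$Sigma[1, 2, ], s13 = x$Sigma[1, 3, ], s23 = x$Sigma[2, 3, ]
  )
}

#' Glance at a posterior fit
#'
#' @param x A `molar_posterior`.
#' @param ... Unused.
#' @return One-row tibble with draw count, data size, metric and the
#'   repeatability factor applied.
#' @method glance molar_posterior
#' @export
glance.molar_posterior <- function(x, ...) {
  tibble::tibble(n_draws = nrow(x$mu), nobs = x$n_obs, metric = x$metric,
                 repeatability = x$repeatability)
}
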