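#' Configuration for the synthetic molar-row generator
#'
#' Bundles and validates all parameters of [simulate_molar_rows()].
#' Defaults emulate an intraspecific sample of a small myomorph rodent:
#' 70 specimens over four localities, mean M1 mesiodistal length 1.55 mm
#' with SD 0.07 mm, activator/inhibitor ratio 0.8 (so M2/M1 = 0.8), and a
#' within-row M1-M2 correlation of 0.9. The high default correlation
#' reflects strong within-row integration and keeps the cascade-implied
#' cov(M1, M3) = 2 cov(M1, M2) - var(M1) bounded away from zero (it
#' requires cor12 > sd1 / (2 sd2)), so that ICM-exact data satisfy all
#' six cascade predictions instead of leaving the covariance ratio
#' indeterminate.
#'
#' Modes:
#' * `icm_exact` draws (M1, M2) from a bivariate Gaussian and sets
#'   M3 = 2 M2 - M1 + e, e ~ N(0, `residual_sd_m3`^2); with
#'   `residual_sd_m3 = 0` every row sits exactly on the inhibitory-cascade
#'   plane.
#' * `activator_inhibitor` draws a per-specimen a/i ratio and M1 size and
#'   applies the linear cascade profile [icm_profile()].
#' * `mvn` draws (M1, M2, M3) jointly Gaussian from `mean_vector` and
#'   `covariance_matrix`.
#'
#' @param n_specimens Number of molar rows to generate.
#' @param mode One of `"icm_exact"`, `"activator_inhibitor"`, `"mvn"`.
#' @param a_over_i Mean activator/inhibitor ratio (M2/M1); must exceed 0.5
#'   for a positive M3 under the linear rule.
#' @param a_over_i_sd Between-specimen SD of a/i (`activator_inhibitor`
#'   mode).
#' @param m1_mean,m1_sd Mean and SD of M1 size, mm.
#' @param cor12 Correlation between M1 and M2 (`icm_exact` mode).
#' @param residual_sd_m3 SD of Gaussian noise off the cascade plane
#'   (`icm_exact` mode), mm. The cascade model itself says nothing about
#'   intraspecific deviations from the plane; this Gaussian residual is
#'   this package's construction.
#' @param mean_vector,covariance_matrix Mean (length 3) and 3x3 symmetric
#'   positive-definite covariance of (M1, M2, M3) for `mvn` mode. Default
#'   to the profile implied by `a_over_i` with SDs proportional to size
#'   and pairwise correlation `cor12`.
#' @param groups Optional data frame with columns `label` and `offset`
#'   (a single number added to all three tooth means) defining localities;
#'   specimens are split as evenly as possible across groups.
#' @param width_ratio Buccolingual width as a proportion of mesiodistal
#'   length, used to derive widths (hence areas) from simulated lengths.
#' @param width_cv Relative SD of the width/length proportion.
#' @param metric `"length"` or `"area"`: which size metric the returned
#'   rows carry.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_specimens = 70,
                             mode = c("icm_exact", "activator_inhibitor", "mvn"),
                             a_over_i = 0.8,
                             a_over_i_sd = 0.03,
                             m1_mean = 1.55,
                             m1_sd = 0.07,
                             cor12 = 0.9,
                             residual_sd_m3 = 0,
                             mean_vector = NULL,
                             covariance_matrix = NULL,
                             groups = NULL,
                             width_ratio = 0.65,
                             width_cv = 0.03,
                             metric = c("length", "area")) {
  mode <- match.arg(mode)
  metric <- match.arg(metric)
  check_scalar_number(n_specimens, "n_specimens", lower = 1)
  check_scalar_number(a_over_i, "a_over_i", lower = 0, closed_lower = FALSE)
  check_scalar_number(m1_mean, "m1_mean", lower = 0, closed_lower = FALSE)
  check_scalar_number(m1_sd, "m1_sd", lower = 0, closed_lower = FALSE)
  check_scalar_number(residual_sd_m3, "residual_sd_m3", lower = 0)
  check_scalar_number(cor12, "cor12", lower = -1, upper = 1)
  if (a_over_i <= 0.5) {
    warning("a_over_i <= 0.5 implies a non-positive M3 (third-molar loss) under the linear cascade rule.",
            call. = FALSE)
  }
  if (mode == "mvn") {
    if (is.null(mean_vector)) {
      mean_vector <- m1_mean * icm_profile(a_over_i)
    }
    if (is.null(covariance_matrix)) {
      sds <- m1_sd * icm_profile(a_over_i)
      cors <- matrix(cor12, 3, 3)
      diag(cors) <- 1
      covariance_matrix <- cors * tcrossprod(sds)
    }
    if (length(mean_vector) != 3) {
      abort_icm("`mean_vector` must have length 3.", "icmolar_validation_error")
    }
    if (!is_spd(covariance_matrix)) {
      abort_icm("`covariance_matrix` must be 3x3 symmetric positive-definite.",
                "icmolar_validation_error")
    }
  }
  if (!is.null(groups)) {
    groups <- tibble::as_tibble(groups)
    stopifnot(all(c("label", "offset") %in% names(groups)))
  }
  structure(
    list(n_specimens = as.integer(n_specimens), mode = mode,
         a_over_i = a_over_i, a_over_i_sd = a_over_i_sd,
         m1_mean = m1_mean, m1_sd = m1_sd, cor12 = cor12,
         residual_sd_m3 = residual_sd_m3, mean_vector = mean_vector,
         covariance_matrix = covariance_matrix, groups = groups,
         width_ratio = width_ratio, width_cv = width_cv, metric = metric),
    class = "generator_config"
  )
}

#' Expected relative-size profile under the linear inhibitory cascade
#'
#' The cascade rule predicts relative molar sizes
#' `s_x = 1 + (a/i - 1) (x - 1)` along tooth positions x = 1, 2, 3, so
#' s1 = 1, s2 = a/i and s3 = 2 a/i - 1.
#'
#' @param a_over_i Activator/inhibitor ratio, positive.
#' @return Numeric vector `c(s1, s2, s3)` with `s1 = 1`.
#' @export
#' @examples
#' icm_profile(0.8) # c(1, 0.8, 0.6)
icm_profile <- function(a_over_i) {
  check_scalar_number(a_over_i, "a_over_i", lower = 0, closed_lower = FALSE)
  if (a_over_i <= 0.5) {
    warning("a_over_i <= 0.5: the third molar's predicted size is <= 0 (biologically, M3 loss).",
            call. = FALSE)
  }
  1 + (a_over_i - 1) * (0:2)
}

#' Simulate molar rows with known statistical structure
#'
#' Generates per-specimen (M1, M2, M3) crown sizes according to a
#' [generator_config()]. Negative draws are rejected and resampled (a
#' warning is raised if more than 10% of draws are rejected). Group
#' offsets are added to the means before drawing. Output is byte-identical
#' for identical config and seed.
#'
#' @param config A `generator_config`, or arguments passed on to
#'   [generator_config()] via `...` when `config` is `NULL`.
#' @param seed Integer seed; `NULL` uses the ambient RNG stream.
#' @param ... Passed to [generator_config()] when `config` is `NULL`.
#' @return A tibble of molar rows (`specimen_id, locality, sex, metric,
#'   m1, m2, m3`) with the generated mesiodistal lengths kept in
#'   attribute `"lengths"` so replicated length/width measurements can be
#'   derived from the same rows (see [add_replicate_noise()]).
#' @export
#' @examples
#' rows <- simulate_molar_rows(generator_config(n_specimens = 5), seed = 1)
#' with(rows, all.equal(m3, 2 * m2 - m1))
simulate_molar_rows <- function(config = NULL, seed = NULL, ...) {
  if (is.null(config)) config <- generator_config(...)
  stopifnot(inherits(config, "generator_config"))
  with_seed_or_not(seed, simulate_molar_rows_impl(config))
}

simulate_molar_rows_impl <- function(config) {
  n <- config$n_specimens
  if (is.null(config$groups)) {
    group_of <- rep(NA_character_, n)
    offset_of <- rep(0, n)
  } else {
    g <- config$groups
    idx <- rep(seq_len(nrow(g)), length.out = n)
    idx <- sort(idx)
    group_of <- g$label[idx]
    offset_of <- g$offset[idx]
  }

  n_rejected <- 0L
  draw_lengths <- function(offsets) {
    m <- length(offsets)
    if (config$mode == "icm_exact") {
      mu2 <- config$a_over_i * config$m1_mean
      sd2 <- config$a_over_i * config$m1_sd
      cov12 <- config$cor12 * config$m1_sd * sd2
      sig <- matrix(c(config$m1_sd^2, cov12, cov12, sd2^2), 2, 2)
      xy <- MASS::mvrnorm(m, mu = c(config$m1_mean, mu2), Sigma = sig)
      xy <- matrix(xy, ncol = 2)
      xy[, 1] <- xy[, 1] + offsets
      xy[, 2] <- xy[, 2] + offsets
      m3 <- 2 * xy[, 2] - xy[, 1] +
        if (config$residual_sd_m3 > 0) stats::rnorm(m, 0, config$residual_sd_m3) else 0
      cbind(xy, m3)
    } else if (config$mode == "activator_inhibitor") {
      ai <- stats::rnorm(m, config$a_over_i, config$a_over_i_sd)
      m1 <- stats::rnorm(m, config$m1_mean, config$m1_sd) + offsets
      cbind(m1, ai * m1, (2 * ai - 1) * m1)
    } else {
      x <- MASS::mvrnorm(m, mu = config$mean_vector,
                         Sigma = config$covariance_matrix)
      matrix(x, ncol = 3) + offsets
    }
  }

  sizes <- draw_lengths(offset_of)
  bad <- rowSums(sizes <= 0) > 0
  guard <- 0L
  while (any(bad)) {
    n_rejected <- n_rejected + sum(bad)
    sizes[bad, ] <- draw_lengths(offset_of[bad])
    bad <- rowSums(sizes <= 0) > 0
    guard <- guard + 1L
    if (guard > 1000L) {
      abort_icm("Rejection sampling failed to produce positive sizes; means are too close to zero.",
                "icmolar_validation_error")
    }
  }
  if (n_rejected > 0.1 * n) {
    warning(sprintf("Rejected %d negative draw(s) (> 10%% of sample); means may be too close to zero.",
                    n_rejected), call. = FALSE)
  }

  widths <- sizes * config$width_ratio *
    (1 + stats::rnorm(3L * n, 0, config$width_cv))
  widths <- matrix(widths, ncol = 3)
  out_sizes <- if (config$metric == "area") sizes * widths else sizes

  rows <- tibble::tibble(
    specimen_id = sprintf("sim%04d", seq_len(n)),
    locality = group_of,
    sex = NA_character_,
    metric = config$metric,
    m1 = out_sizes[, 1], m2 = out_sizes[, 2], m3 = out_sizes[, 3]
  )
  attr(rows, "lengths") <- sizes
  attr(rows, "widths") <- widths
  attr(rows, "n_rejected") <- n_rejected
  rows
}

#' Add replicated measurement noise to simulated rows
#'
#' Turns simulated molar rows into a long measurement table with
#' replicated length and width measurements whose within-specimen noise
#' variance is calibrated so that the expected ANOVA repeatability equals
#' `target_repeatability`: for each tooth x dimension variable,
#' `sigma2_within = sigma2_among * (1 - R) / R` with `sigma2_among`
#' estimated from the rows. This inverts the repeatability estimator, so
#' [molar_repeatability()] recovers the target in expectation.
#'
#' @param rows Simulated rows from [simulate_molar_rows()] (the stored
#'   length/width attributes are used; for `metric = "length"` rows
#'   without attributes, widths default to 0.65 x length).
#' @param target_repeatability Target repeatability in (0, 1].
#' @param replicates_per_measurement Replicates per observer (>= 1).
#' @param n_observers Number of observers.
#' @param seed Integer seed; `NULL` uses the ambient RNG stream.
#' @return A `molar_measurements` tibble (see
#'   [read_molar_measurements()]).
#' @export
add_replicate_noise <- function(rows, target_repeatability = 0.93,
                                replicates_per_measurement = 3,
                                n_observers = 2, seed = NULL) {
  check_scalar_number(target_repeatability, "target_repeatability",
                      lower = 0, upper = 1, closed_lower = FALSE)
  check_scalar_number(replicates_per_measurement,
                      "replicates_per_measurement", lower = 1)
  lengths <- attr(rows, "lengths")
  widths <- attr(rows, "widths")
  if (is.null(lengths)) {
    if (!all(rows$metric == "length")) {
      abort_icm("Rows without stored length/width attributes must carry the length metric.",
                "icmolar_validation_error")
    }
    lengths <- as.matrix(rows[, c("m1", "m2", "m3")])
    widths <- lengths * 0.65
  }
  with_seed_or_not(seed, {
    n <- nrow(rows)
    n_rep <- as.integer(replicates_per_measurement) * as.integer(n_observers)
    emit <- function(base, dim_label) {
      # base: n x 3 matrix of true values for one dimension
      purrr::map_dfr(1:3, function(tooth) {
        v <- base[, tooth]
        s2_among <- stats::var(v)
        s_within <- sqrt(s2_among * (1 - target_repeatability) /
                           target_repeatability)
        reps <- rep(v, each = n_rep) +
          stats::rnorm(n * n_rep, 0, s_within)
        tibble::tibble(
          specimen_id = rep(rows$specimen_id, each = n_rep),
          locality = rep(rows$locality, each = n_rep),
          sex = rep(rows$sex, each = n_rep),
          tooth = paste0("M", tooth),
          dimension = dim_label,
          replicate = rep(rep(seq_len(replicates_per_measurement),
                              times = n_observers), times = n),
          observer = rep(rep(sprintf("obs%d", seq_len(n_observers)),
                             each = replicates_per_measurement), times = n),
          value_mm = reps
        )
      })
    }
    out <- dplyr::bind_rows(emit(lengths, "length"), emit(widths, "width"))
    out$value_mm <- pmax(out$value_mm, .Machine$double.eps)
    validate_molar_measurements(out)
  })
}
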