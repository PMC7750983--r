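ratios_fixture <- function(n = 70, seed = 601, residual_sd_m3 = 0.02) {
  compute_ratios(make_icm_rows(n = n, seed = seed,
                               residual_sd_m3 = residual_sd_m3))
}

test_that("reference intervals degenerate for constant ratios and match normal theory", {
  rat <- ratios_fixture(30)
  rat$r21 <- 0.8
  rat$r31 <- 0.6
  ref <- reference_intervals(rat, n_boot = 500, seed = 1)
  expect_true(all(ref$lower == ref$point & ref$upper == ref$point))

  set.seed(2)
  rat2 <- ratios_fixture(70)
  ref2 <- reference_intervals(rat2, n_boot = 4000, seed = 3)
  for (rt in c("r21", "r31")) {
    v <- rat2[[rt]]
    normal <- mean(v) + c(-1, 1) * qnorm(0.975) * sd(v) / sqrt(70)
    got <- ref_mean <- ref2[ref2$ratio == rt & ref2$statistic == "mean", ]
    expect_equal(got$upper - got$lower, normal[2] - normal[1],
                 tolerance = 0.1)
  }
  expect_error(reference_intervals(ratios_fixture(5)),
               class = "icmolar_validation_error")
})

test_that("bootstrap reference intervals are stable in n_boot", {
  rat <- ratios_fixture(70)
  a <- reference_intervals(rat, n_boot = 4000, seed = 5)
  b <- reference_intervals(rat, n_boot = 8000, seed = 6)
  expect_equal(a$lower, b$lower, tolerance = 0.01)
  expect_equal(a$upper, b$upper, tolerance = 0.01)
})

test_that("subsampling at N = n reproduces the full sample exactly", {
  rat <- ratios_fixture(30)
  ref <- reference_intervals(rat, n_boot = 1000, seed = 7)
  res <- sample_size_simulation(rat, ref, n_grid = 30, reps = 50, seed = 8)
  expect_true(all(res$prop_mean_outside == 0))
  expect_true(all(res$prop_sd_outside == 0))
})

test_that("subsampling near the full size leaves SDs inside the interval", {
  rat <- ratios_fixture(70)
  ref <- reference_intervals(rat, n_boot = 2000, seed = 9)
  res <- sample_size_simulation(rat, ref, n_grid = 69, reps = 400, seed = 10)
  expect_true(all(res$prop_sd_outside < 0.05))
  expect_error(sample_size_simulation(rat, ref, n_grid = 71, reps = 5),
               class = "icmolar_validation_error")
})

test_that("outside-proportions decrease with N for the mean statistic", {
  rat <- ratios_fixture(70)
  ref <- reference_intervals(rat, n_boot = 2000, seed = 11)
  res <- sample_size_simulation(rat, ref, n_grid = c(2, 5, 10, 20, 40, 60),
                                reps = 800, seed = 12)
  for (rt in c("r21", "r31")) {
    p <- res$prop_mean_outside[res$ratio == rt]
    expect_lt(cor(seq_along(p), p, method = "spearman"), 0)
    expect_lt(p[length(p)], p[1])
  }
})

test_that("identical seeds give identical simulation tables", {
  rat <- ratios_fixture(40)
  ref <- reference_intervals(rat, n_boot = 500, seed = 13)
  a <- sample_size_simulation(rat, ref, n_grid = c(5, 10), reps = 200,
                              seed = 14)
  b <- sample_size_simulation(rat, ref, n_grid = c(5, 10), reps = 200,
                              seed = 14)
  expect_identical(a, b)
  rows <- make_icm_rows(n = 40, seed = 601, residual_sd_m3 = 0.02)
  ca <- composite_simulation(rows, ref, n_grid = c(1, 3), outer_reps = 100,
                             inner_reps = 100, seed = 15)
  cb <- composite_simulation(rows, ref, n_grid = c(1, 3), outer_reps = 100,
                             inner_reps = 100, seed = 15)
  expect_identical(ca, cb)
})

test_that("composite means are unbiased for the ratio of population means", {
  rows <- make_icm_rows(n = 70, seed = 621, residual_sd_m3 = 0.02)
  rat <- compute_ratios(rows)
  ref <- reference_intervals(rat, n_boot = 1000, seed = 16)
  res <- composite_simulation(rows, ref, n_grid = 5, outer_reps = 500,
                              inner_reps = 50, seed = 17)
  target <- mean(rows$m2) / mean(rows$m1)
  got <- res[res$ratio == "r21", ]
  se <- got$sd_of_estimates / sqrt(got$outer_reps)
  expect_lt(abs(got$mean_estimate - target), 3 * se)
})

test_that("composite estimate spread shrinks with N while SD stays unrecoverable", {
  rows <- make_icm_rows(n = 70, seed = 631, residual_sd_m3 = 0.02)
  rat <- compute_ratios(rows)
  ref <- reference_intervals(rat, n_boot = 1000, seed = 18)
  res <- composite_simulation(rows, ref, n_grid = c(1, 2, 4, 8, 16),
                              outer_reps = 300, inner_reps = 150, seed = 19)
  for (rt in c("r21", "r31")) {
    d <- res[res$ratio == rt, ]
    expect_lt(cor(d$n, d$sd_of_estimates, method = "spearman"), -0.9)
    # at N = 1 the inner pseudosample is a single row: SD = 0, always outside
    expect_equal(d$prop_sd_outside[d$n == 1], 1)
  }
})

test_that("paired composites recover the variance structure that independent ones miss", {
  rows <- make_icm_rows(n = 70, seed = 641, residual_sd_m3 = 0.02)
  rat <- compute_ratios(rows)
  ref <- reference_intervals(rat, n_boot = 1000, seed = 20)
  indep <- composite_simulation(rows, ref, n_grid = 40, outer_reps = 200,
                                inner_reps = 200, seed = 21)
  paired <- composite_simulation(rows, ref, n_grid = 40, outer_reps = 200,
                                 inner_reps = 200, paired = TRUE, seed = 21)
  for (rt in c("r21", "r31")) {
    expect_gt(indep$prop_sd_outside[indep$ratio == rt], 0.5)
    expect_lt(paired$prop_sd_outside[paired$ratio == rt],
              indep$prop_sd_outside[indep$ratio == rt])
  }
})

test_that("adequacy thresholds implement the first-crossing rule", {
  fake <- tibble::tibble(
    n = rep(c(2, 10, 20, 30), 2),
    ratio = rep(c("r21", "r31"), each = 4),
    prop_mean_outside = c(0.4, 0.06, 0.04, 0.01, 0.2, 0.2, 0.2, 0.2),
    prop_sd_outside = c(0.04, 0.07, 0.03, 0.01, 0.5, 0.4, 0.3, 0.2)
  )
  mean_ad <- adequacy_threshold(fake, "mean")
  expect_equal(mean_ad$n_adequate[mean_ad$ratio == "r21"], 20L)
  expect_true(is.na(mean_ad$n_adequate[mean_ad$ratio == "r31"]))
  expect_message(sd_ad <- adequacy_threshold(fake, "sd"), "non-monotone")
  expect_equal(sd_ad$n_adequate[sd_ad$ratio == "r21"], 2L)
})
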