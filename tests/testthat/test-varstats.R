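test_that("CV values and invariances", {
  expect_equal(cv_percent(rep(2.5, 4)), 0)
  expect_equal(cv_percent(c(1, 2, 3)), 50)
  v <- rgamma(20, 5)
  expect_equal(cv_percent(v * 7.3), cv_percent(v), tolerance = 1e-12)
  expect_error(cv_percent(c(1)), class = "icmolar_validation_error")
  expect_error(cv_percent(c(-3, 1)), class = "icmolar_validation_error")
})

test_that("the sign test matches binomial tail enumeration", {
  r1 <- sign_test_pooled_cv(c(4, 5, 6, 7), 8)
  expect_equal(r1$k_below, 4)
  expect_equal(r1$p_value, 0.5^4)

  # 2 of 4 below: P(X >= 2 | Bin(4, 1/2)) = 11/16
  r2 <- sign_test_pooled_cv(c(4, 5, 9, 10), 8)
  expect_equal(r2$p_value, 11 / 16)

  # ties are dropped
  r3 <- sign_test_pooled_cv(c(8, 4, 9), 8)
  expect_equal(r3$n, 2)
  expect_error(sign_test_pooled_cv(c(8, 8), 8),
               class = "icmolar_validation_error")
})

make_grouped_ratios <- function(values, groups) {
  tibble::tibble(
    specimen_id = as.character(seq_along(values)),
    locality = groups, sex = NA_character_, metric = "length",
    m1 = 1, m2 = values, m3 = values,
    r21 = values, r31 = values,
    rel1 = 1 / 3, rel2 = 1 / 3, rel3 = 1 / 3
  )
}

test_that("pairwise Mann-Whitney matches the enumeration oracle", {
  rat <- make_grouped_ratios(c(1, 2, 3, 4, 5, 6),
                             rep(c("A", "B"), each = 3))
  res <- pairwise_mann_whitney(rat, "r21")
  oracle <- brute_force_mw(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, oracle$u) # U = 0
  expect_equal(res$p_value, oracle$p)   # exact p from 20 arrangements

  set.seed(3)
  x <- rnorm(8); y <- rnorm(7, 0.5)
  rat2 <- make_grouped_ratios(c(x, y) + 3, rep(c("A", "B"), c(8, 7)))
  res2 <- pairwise_mann_whitney(rat2, "r21")
  oracle2 <- brute_force_mw(x + 3, y + 3)
  expect_equal(res2$statistic, oracle2$u)
  expect_equal(res2$p_value, oracle2$p, tolerance = 1e-10)
})

test_that("U statistics of the two orientations sum to n1 * n2", {
  set.seed(13)
  x <- rnorm(12); y <- rnorm(9)
  rat <- make_grouped_ratios(c(x, y) + 5, rep(c("A", "B"), c(12, 9)))
  rat_swapped <- make_grouped_ratios(c(y, x) + 5, rep(c("A", "B"), c(9, 12)))
  u_ab <- pairwise_mann_whitney(rat, "r21")$statistic
  u_ba <- pairwise_mann_whitney(rat_swapped, "r21")$statistic
  expect_equal(u_ab + u_ba, 12 * 9)
})

test_that("Bonferroni correction is a capped multiplication over pairs", {
  set.seed(23)
  rat <- make_grouped_ratios(rnorm(40, 10),
                             rep(c("A", "B", "C", "D"), each = 10))
  res <- pairwise_mann_whitney(rat, "r31")
  expect_equal(nrow(res), 6)
  expect_equal(res$p_bonferroni, pmin(res$p_value * 6, 1))
  expect_true(all(res$p_bonferroni >= res$p_value))
  expect_true(all(res$p_bonferroni <= 1))
})

test_that("identical groups give corrected p = 1 and groups of n < 2 are dropped", {
  rat <- make_grouped_ratios(rep(c(1, 2, 3, 4), 2),
                             rep(c("A", "B"), each = 4))
  res <- pairwise_mann_whitney(rat, "r21")
  expect_equal(res$p_bonferroni, 1)

  rat2 <- make_grouped_ratios(c(1, 2, 3, 4, 9), c("A", "A", "B", "B", "C"))
  expect_warning(res2 <- pairwise_mann_whitney(rat2, "r21"), "n < 2")
  expect_equal(nrow(res2), 1)
})

test_that("pooling decisions follow the corrected p-values and flag over-averaging", {
  rat_same <- make_grouped_ratios(rep(c(0.95, 1, 1.05, 1.1), 2) +
                                    seq(0, 0.007, length.out = 8),
                                  rep(c("A", "B"), each = 4))
  dec <- pooling_decision(rat_same)
  expect_equal(dec$decision, "pool")

  rat_diff <- make_grouped_ratios(c(rnorm(15, 1, 0.01), rnorm(15, 2, 0.01)),
                                  rep(c("A", "B"), each = 15))
  dec2 <- pooling_decision(rat_diff)
  expect_equal(dec2$decision, "split")

  # CV > 15% raises the over-averaging flag regardless of the decision
  set.seed(31)
  v <- exp(rnorm(30, 0, 0.25)) # CV ~ 25%
  rat3 <- make_grouped_ratios(v, rep(c("A", "B"), each = 15))
  dec3 <- pooling_decision(rat3)
  expect_true(dec3$over_averaging)
})

test_that("null grouped simulations split at most rarely", {
  splits <- vapply(1:100, function(s) {
    rows <- simulate_molar_rows(
      generator_config(n_specimens = 40, residual_sd_m3 = 0.02,
                       groups = tibble::tibble(label = c("A", "B"),
                                               offset = c(0, 0))),
      seed = 5000 + s
    )
    pooling_decision(compute_ratios(rows))$decision == "split"
  }, logical(1))
  expect_lte(mean(splits), 0.10)
})

test_that("zero ratios (absent M3) are retained and counted", {
  rat <- make_grouped_ratios(c(1, 1.1, 0.9, 1, 1.2, 0.95),
                             rep(c("A", "B"), each = 3))
  rat$r31[2] <- 0
  dec <- pooling_decision(rat)
  expect_equal(dec$n_zero_ratios, 1)
  cv_with <- cv_percent(rat$r31)
  cv_without <- cv_percent(rat$r31[rat$r31 > 0])
  expect_gt(cv_with, cv_without)
})
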