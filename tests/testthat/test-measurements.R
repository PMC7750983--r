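test_that("reading a well-formed CSV preserves records and types", {
  tf <- write_measurement_csv()
  tab <- read_molar_measurements(tf)
  expect_s3_class(tab, "molar_measurements")
  expect_equal(nrow(tab), 3)
  expect_type(tab$value_mm, "double")
  expect_type(tab$replicate, "integer")
})

test_that("validation rejects bad values and missing columns", {
  tf <- write_measurement_csv("a,LA,F,M2,length,1,obs1,-1")
  expect_error(read_molar_measurements(tf), class = "icmolar_validation_error")

  tf2 <- tempfile(fileext = ".csv")
  writeLines(c("specimen_id,tooth,value_mm", "a,M1,1.2"), tf2)
  expect_error(read_molar_measurements(tf2), class = "icmolar_format_error")
})

test_that("unknown labels abort in strict mode and are dropped otherwise", {
  tf <- write_measurement_csv("a,LA,F,P4,length,1,obs1,1.2")
  expect_error(read_molar_measurements(tf, strict = TRUE),
               class = "icmolar_validation_error")
  expect_warning(tab <- read_molar_measurements(tf, strict = FALSE),
                 "Dropping 1 record")
  expect_equal(nrow(tab), 3) # the P4 record is gone
})

test_that("replicate averaging pools observers and replicates", {
  tab <- make_measurements(function(g) {
    ifelse(g$observer == "obs1", 1.0, 2.0)
  }, n = 2, reps = 3, observers = 2)
  collapsed <- average_replicates(tab)
  # one record per specimen x tooth x dimension, pooled mean 1.5
  expect_equal(nrow(collapsed), 2 * 3 * 2)
  expect_true(all(collapsed$value_mm == 1.5))
  expect_true(all(collapsed$n_measurements == 6))

  tab2 <- make_measurements(function(g) g$replicate / 5, n = 1, reps = 3)
  expect_equal(unique(average_replicates(tab2)$value_mm), mean(1:3) / 5)
})

test_that("averaging then building rows is invariant to replicate order", {
  tab <- make_measurements(function(g) {
    1 + as.integer(factor(g$tooth)) / 2 + g$replicate / 10
  }, n = 3, reps = 3)
  shuffled <- tab[sample.int(nrow(tab)), ]
  r1 <- build_row_sizes(average_replicates(tab), "area")
  r2 <- build_row_sizes(average_replicates(shuffled), "area")
  expect_equal(r1, r2)
})

test_that("row building computes areas and excludes incomplete rows", {
  tab <- make_measurements(function(g) {
    ifelse(g$dimension == "length", 1.42, 0.95)
  }, n = 2, reps = 1)
  collapsed <- average_replicates(tab)
  rows <- build_row_sizes(collapsed, "area")
  expect_equal(rows$m1, rep(1.42 * 0.95, 2), tolerance = 1e-12)

  # drop specimen s02's M3 -> excluded from rows, with a message
  collapsed2 <- collapsed[!(collapsed$specimen_id == "s02" &
                              collapsed$tooth == "M3"), ]
  expect_message(rows2 <- build_row_sizes(collapsed2, "area"),
                 "Excluded 1 specimen")
  expect_equal(rows2$specimen_id, "s01")

  # a missing width only matters for the area metric
  collapsed3 <- collapsed[!(collapsed$specimen_id == "s02" &
                              collapsed$tooth == "M3" &
                              collapsed$dimension == "width"), ]
  expect_message(build_row_sizes(collapsed3, "area"), "Excluded 1")
  expect_silent(rows_len <- build_row_sizes(collapsed3, "length"))
  expect_equal(nrow(rows_len), 2)

  expect_error(build_row_sizes(collapsed[0, ], "length"),
               class = "icmolar_validation_error")
})

test_that("ratio phenotypes are correct, sum to one, and are scale-invariant", {
  rows <- tibble::tibble(
    specimen_id = c("a", "b"), locality = NA_character_,
    sex = NA_character_, metric = "length",
    m1 = c(1, 2.0), m2 = c(1, 1.6), m3 = c(1, 1.2)
  )
  rat <- compute_ratios(rows)
  expect_equal(rat$r21, c(1, 0.8))
  expect_equal(rat$r31, c(1, 0.6))
  expect_equal(rat$rel1[2], 2 / 4.8)
  expect_equal(rat$rel1 + rat$rel2 + rat$rel3, c(1, 1), tolerance = 1e-12)

  scaled <- dplyr::mutate(rows, dplyr::across(c(m1, m2, m3), ~ .x * 3.7))
  expect_equal(compute_ratios(scaled)[, c("r21", "r31", "rel1", "rel2", "rel3")],
               rat[, c("r21", "r31", "rel1", "rel2", "rel3")],
               tolerance = 1e-12)

  expect_error(compute_ratios(dplyr::mutate(rows, m1 = c(0, 2))),
               class = "icmolar_validation_error")
})

test_that("repeatability matches the brute-force variance-components oracle", {
  set.seed(11)
  for (k in 1:5) {
    n_spec <- sample(3:5, 1)
    truth <- rnorm(n_spec, 10, 1)
    tab <- make_measurements(function(g) {
      truth[as.integer(factor(g$specimen_id))] + rnorm(nrow(g), 0, 0.3)
    }, n = n_spec, reps = 3)
    vals <- tab[tab$dimension == "length" & tab$tooth == "M1", ]
    oracle <- brute_force_repeatability(vals$value_mm, vals$specimen_id)
    est <- attr(molar_repeatability(tab, "length"), "by_tooth")[["M1"]]
    expect_equal(est, oracle, tolerance = 1e-10)
  }
})

test_that("repeatability is 1 for perfect replicates and recovers simulated variance fractions", {
  tab <- make_measurements(function(g) {
    as.integer(factor(g$specimen_id)) + as.integer(factor(g$tooth)) / 2
  }, n = 3, reps = 3)
  expect_equal(molar_repeatability(tab, "length"), 1, ignore_attr = TRUE)

  # among-specimen SD 1, within SD 0.5 -> R = 1 / (1 + 0.25) = 0.8
  set.seed(21)
  n <- 200
  truth <- rnorm(n, 10, 1)
  tab2 <- make_measurements(function(g) {
    truth[as.integer(factor(g$specimen_id))] + rnorm(nrow(g), 0, 0.5)
  }, n = n, reps = 3)
  expect_equal(molar_repeatability(tab2, "length"), 0.8,
               tolerance = 0.05, ignore_attr = TRUE)
})

test_that("single-measurement specimens are excluded or fatal as appropriate", {
  tab <- make_measurements(function(g) rnorm(nrow(g), 5), n = 3, reps = 2)
  solo <- tab[!(tab$specimen_id == "s03" & tab$replicate == 2), ]
  expect_warning(molar_repeatability(solo, "length"),
                 "single measurement")
  single_all <- tab[tab$replicate == 1, ]
  expect_error(suppressWarnings(molar_repeatability(single_all, "length")),
               class = "icmolar_validation_error")
})
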