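# Fixture builders and independent oracles shared across the suite.

# A tiny well-formed measurement CSV written to a temp file.
write_measurement_csv <- function(lines_extra = character(),
                                  header = TRUE) {
  tf <- tempfile(fileext = ".csv")
  base <- c(
    "a,LA,F,M1,length,1,obs1,1.50",
    "a,LA,F,M1,length,2,obs1,1.54",
    "a,LA,F,M1,width,1,obs1,0.98"
  )
  lines <- c(
    if (header) "specimen_id,locality,sex,tooth,dimension,replicate,observer,value_mm",
    base, lines_extra
  )
  writeLines(lines, tf)
  tf
}

# Measurement table built in memory: n specimens x 3 teeth x 2 dims,
# reps replicates per observer.
make_measurements <- function(values_fn, n = 3, reps = 2, observers = 1) {
  grid <- expand.grid(
    specimen_id = sprintf("s%02d", seq_len(n)),
    tooth = c("M1", "M2", "M3"),
    dimension = c("length", "width"),
    replicate = seq_len(reps),
    observer = sprintf("obs%d", seq_len(observers)),
    stringsAsFactors = FALSE
  )
  grid$locality <- "X"
  grid$sex <- "unknown"
  grid$value_mm <- values_fn(grid)
  validate_molar_measurements(grid)
}

# Rows exactly on the cascade plane M3 = 2 M2 - M1.
make_icm_rows <- function(n = 50, seed = 1, residual_sd_m3 = 0, ...) {
  simulate_molar_rows(
    generator_config(n_specimens = n, mode = "icm_exact",
                     residual_sd_m3 = residual_sd_m3, ...),
    seed = seed
  )
}

# Brute-force one-way variance components from the ANOVA sums-of-squares
# definitions (independent of aov()).
brute_force_repeatability <- function(values, groups) {
  groups <- as.character(groups)
  gm <- tapply(values, groups, mean)
  n_i <- tapply(values, groups, length)
  grand <- mean(values)
  ss_among <- sum(n_i * (gm[names(n_i)] - grand)^2)
  ss_within <- sum((values - gm[groups])^2)
  a <- length(n_i)
  n_tot <- length(values)
  ms_among <- ss_among / (a - 1)
  ms_within <- ss_within / (n_tot - a)
  n0 <- (n_tot - sum(n_i^2) / n_tot) / (a - 1)
  s2a <- (ms_among - ms_within) / n0
  s2a / (s2a + ms_within)
}

# Exact Mann-Whitney U null distribution by full enumeration of group
# assignments (small n only).
brute_force_mw <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(n1 + n2, n1, simplify = FALSE)
  u_all <- vapply(combos, u_of, numeric(1))
  # two-sided exact p: double the smaller tail, capped at 1
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  list(u = u_obs, p = min(p, 1))
}
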