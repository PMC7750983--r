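#' Read a molar measurement table
#'
#' Reads a long-format CSV of replicated lower-molar crown measurements and
#' validates it. One row is one measurement: a specimen, a tooth position
#' (M1, M2 or M3), a dimension (mesiodistal `length` or buccolingual
#' `width`, in mm), a replicate index and an observer label.
#'
#' The header must be exactly
#' `specimen_id,locality,sex,tooth,dimension,replicate,observer,value_mm`.
#' Unknown tooth or dimension labels are an error in strict mode and are
#' dropped with a warning otherwise. Values must be strictly positive.
#'
#' @param path Path to a UTF-8 CSV file.
#' @param strict If `TRUE` (default), unknown tooth/dimension labels abort;
#'   otherwise the offending records are dropped with a warning.
#' @return A tibble of class `molar_measurements` with the columns above
#'   (`replicate` integer, `value_mm` double, others character).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "specimen_id,locality,sex,tooth,dimension,replicate,observer,value_mm",
#'   "a,LA,F,M1,length,1,obs1,1.55",
#'   "a,LA,F,M1,length,2,obs1,1.57"
#' ), tf)
#' read_molar_measurements(tf)
read_molar_measurements <- function(path, strict = TRUE) {
  required <- c("specimen_id", "locality", "sex", "tooth", "dimension",
                "replicate", "observer", "value_mm")
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    abort_icm(
      sprintf("Measurement CSV is missing required column(s): %s.",
              paste(missing, collapse = ", ")),
      "icmolar_format_error"
    )
  }
  tab <- dplyr::select(tab, dplyr::all_of(required))
  tab <- dplyr::mutate(
    tab,
    dplyr::across(c("specimen_id", "locality", "sex", "tooth",
                    "dimension", "observer"), as.character),
    replicate = as.integer(.data$replicate),
    value_mm = as.numeric(.data$value_mm)
  )
  validate_molar_measurements(tab, strict = strict)
}

#' Validate a measurement table built in memory
#'
#' Applies the same checks as [read_molar_measurements()] to an existing
#' data frame: known tooth and dimension labels, strictly positive finite
#' values, and unique replicate indices within each
#' specimen x tooth x dimension x observer group.
#'
#' @param table A data frame with the measurement-table columns.
#' @inheritParams read_molar_measurements
#' @return A validated `molar_measurements` tibble.
#' @export
validate_molar_measurements <- function(table, strict = TRUE) {
  tab <- tibble::as_tibble(table)
  known_tooth <- c("M1", "M2", "M3")
  known_dim <- c("length", "width")
  bad <- !(tab$tooth %in% known_tooth) | !(tab$dimension %in% known_dim)
  if (any(bad)) {
    labels <- unique(c(setdiff(tab$tooth, known_tooth),
                       setdiff(tab$dimension, known_dim)))
    msg <- sprintf("Unknown tooth/dimension label(s): %s.",
                   paste(labels, collapse = ", "))
    if (strict) {
      abort_icm(msg, "icmolar_validation_error")
    }
    warning(sprintf("%s Dropping %d record(s).", msg, sum(bad)),
            call. = FALSE)
    tab <- tab[!bad, , drop = FALSE]
  }
  bad_value <- !is.finite(tab$value_mm) | tab$value_mm <= 0
  if (any(bad_value)) {
    i <- which(bad_value)[1]
    abort_icm(
      sprintf(paste0("All values must be positive and finite; offending ",
                     "record: specimen '%s', tooth %s, %s, replicate %s ",
                     "(value %s)."),
              tab$specimen_id[i], tab$tooth[i], tab$dimension[i],
              tab$replicate[i], format(tab$value_mm[i])),
      "icmolar_validation_error"
    )
  }
  dup <- dplyr::count(tab, .data$specimen_id, .data$tooth, .data$dimension,
                      .data$observer, .data$replicate)
  if (any(dup$n > 1)) {
    abort_icm("Replicate indices must be unique within specimen x tooth x dimension x observer.",
              "icmolar_validation_error")
  }
  class(tab) <- c("molar_measurements", class(tab))
  tab
}

# Per-replicate values of one measure, wide over dimension when needed.
# Returns tibble: specimen_id, value (one row per replicate x observer).
replicate_values <- function(table, measure) {
  if (measure %in% c("length", "width")) {
    out <- dplyr::filter(table, .data$dimension == measure)
    dplyr::select(out, "specimen_id", "tooth", "replicate", "observer",
                  value = "value_mm")
  } else { # area: pair length and width by replicate x observer
    wide <- tidyr::pivot_wider(
      dplyr::select(table, "specimen_id", "tooth", "replicate", "observer",
                    "dimension", "value_mm"),
      names_from = "dimension", values_from = "value_mm"
    )
    wide <- dplyr::filter(wide, !is.na(.data$length) & !is.na(.data$width))
    dplyr::transmute(wide, .data$specimen_id, .data$tooth, .data$replicate,
                     .data$observer, value = .data$length * .data$width)
  }
}

#' ANOVA repeatability of replicated measurements
#'
#' Estimates percent repeatability as the among-specimen variance fraction
#' from a one-way ANOVA with specimen as the grouping factor, computed
#' separately for each tooth position and averaged. Replicates from all
#' observers are pooled into within-group (measurement) error by default,
#' so repeatability reflects total measurement error within and between
#' observers. The variance components use the unbalanced-design estimator
#' `s2_among = (MS_among - MS_within) / n0` with
#' `n0 = (N - sum(n_i^2)/N) / (a - 1)`, and
#' `R = s2_among / (s2_among + MS_within)`, clipped to (0, 1].
#'
#' @param table A `molar_measurements` table (see
#'   [read_molar_measurements()]).
#' @param measure One of `"length"`, `"width"`, `"area"`. Area replicates
#'   pair length and width within replicate x observer before the ANOVA.
#' @param method `"pooled"` (default) treats observer as part of
#'   measurement error; `"two_way"` removes the observer main effect from
#'   the error term via a two-way ANOVA (specimen + observer).
#' @return A single repeatability fraction in (0, 1], with a `"by_tooth"`
#'   attribute giving the per-tooth estimates.
#' @export
molar_repeatability <- function(table, measure = c("length", "width", "area"),
                                method = c("pooled", "two_way")) {
  measure <- match.arg(measure)
  method <- match.arg(method)
  vals <- replicate_values(table, measure)
  per_tooth <- vapply(
    split(vals, vals$tooth),
    function(d) repeatability_one(d, method),
    numeric(1)
  )
  per_tooth <- per_tooth[!is.na(per_tooth)]
  if (length(per_tooth) == 0) {
    abort_icm("No tooth position has >= 2 specimens with >= 2 measurements each.",
              "icmolar_validation_error")
  }
  out <- mean(per_tooth)
  attr(out, "by_tooth") <- per_tooth
  out
}

repeatability_one <- function(d, method) {
  counts <- table(d$specimen_id)
  single <- names(counts)[counts < 2]
  if (length(single) > 0) {
    if (length(single) == length(counts)) {
      abort_icm("Every specimen has a single measurement; repeatability is undefined.",
                "icmolar_validation_error")
    }
    warning(sprintf("Excluding %d specimen(s) with a single measurement from repeatability.",
                    length(single)), call. = FALSE)
    d <- d[!(d$specimen_id %in% single), , drop = FALSE]
  }
  if (length(unique(d$specimen_id)) < 2) return(NA_real_)
  d$specimen_id <- factor(d$specimen_id)
  if (method == "two_way" && length(unique(d$observer)) > 1) {
    fit <- stats::aov(value ~ specimen_id + factor(observer), data = d)
  } else {
    fit <- stats::aov(value ~ specimen_id, data = d)
  }
  an <- stats::anova(fit)
  ms_among <- an["specimen_id", "Mean Sq"]
  ms_within <- an["Residuals", "Mean Sq"]
  n_i <- as.numeric(table(d$specimen_id))
  n_tot <- sum(n_i)
  a <- length(n_i)
  n0 <- (n_tot - sum(n_i^2) / n_tot) / (a - 1)
  s2_among <- (ms_among - ms_within) / n0
  r <- s2_among / (s2_among + ms_within)
  min(max(r, .Machine$double.eps), 1)
}

#' Average measurement replicates
#'
#' Collapses all replicates and observers into a single arithmetic mean
#' per specimen x tooth x dimension.
#'
#' @inheritParams molar_repeatability
#' @return A tibble with one row per specimen x tooth x dimension:
#'   `specimen_id, locality, sex, tooth, dimension, value_mm, n_measurements`.
#' @export
average_replicates <- function(table) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(table), .data$specimen_id,
                    .data$locality, .data$sex, .data$tooth, .data$dimension),
    value_mm = mean(.data$value_mm),
    n_measurements = dplyr::n(),
    .groups = "drop"
  )
}

#' Build per-specimen molar row sizes
#'
#' Derives one size per tooth per specimen for a chosen metric:
#' `"length"` is the mesiodistal crown length (the MMC phenotype);
#' `"area"` is the rectangular crown-area estimate, mesiodistal length x
#' buccolingual width (the classic ICM phenotype). Specimens lacking any
#' of the three teeth for the metric (or a width, for area) are excluded
#' and counted in a message.
#'
#' @param collapsed A collapsed table from [average_replicates()].
#' @param metric `"length"` (mm) or `"area"` (mm^2).
#' @return A tibble of complete molar rows:
#'   `specimen_id, locality, sex, metric, m1, m2, m3`.
#' @export
build_row_sizes <- function(collapsed, metric = c("length", "area")) {
  metric <- match.arg(metric)
  wide <- tidyr::pivot_wider(
    dplyr::select(collapsed, "specimen_id", "locality", "sex", "tooth",
                  "dimension", "value_mm"),
    names_from = c("tooth", "dimension"), values_from = "value_mm"
  )
  size_of <- function(tooth) {
    len <- wide[[paste0(tooth, "_length")]]
    if (is.null(len)) len <- rep(NA_real_, nrow(wide))
    if (metric == "length") return(len)
    wid <- wide[[paste0(tooth, "_width")]]
    if (is.null(wid)) wid <- rep(NA_real_, nrow(wide))
    len * wid
  }
  rows <- tibble::tibble(
    specimen_id = wide$specimen_id,
    locality = wide$locality,
    sex = wide$sex,
    metric = metric,
    m1 = size_of("M1"), m2 = size_of("M2"), m3 = size_of("M3")
  )
  complete <- stats::complete.cases(rows[, c("m1", "m2", "m3")])
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    message(sprintf("Excluded %d specimen(s) with incomplete molar rows for metric '%s'.",
                    n_dropped, metric))
  }
  rows <- rows[complete, , drop = FALSE]
  if (nrow(rows) == 0) {
    abort_icm("No complete molar rows.", "icmolar_validation_error")
  }
  rows
}

#' Molar size-ratio phenotypes
#'
#' Computes, per specimen, the ratios M2/M1 (`r21`) and M3/M1 (`r31`) and
#' each tooth's size relative to the whole molar row
#' (`rel1`, `rel2`, `rel3`, which sum to 1).
#'
#' @param rows A tibble of complete molar rows from [build_row_sizes()] or
#'   [simulate_molar_rows()].
#' @return The input tibble with columns `r21, r31, rel1, rel2, rel3`
#'   appended.
#' @export
#' @examples
#' rows <- tibble::tibble(specimen_id = "a", locality = NA, sex = NA,
#'                        metric = "length", m1 = 2, m2 = 1.6, m3 = 1.2)
#' compute_ratios(rows)
compute_ratios <- function(rows) {
  if (any(rows$m1 <= 0)) {
    abort_icm("M1 sizes must be positive to form ratios.",
              "icmolar_validation_error")
  }
  total <- rows$m1 + rows$m2 + rows$m3
  dplyr::mutate(
    tibble::as_tibble(rows),
    r21 = .data$m2 / .data$m1,
    r31 = .data$m3 / .data$m1,
    rel1 = .data$m1 / total,
    rel2 = .data$m2 / total,
    rel3 = .data$m3 / total
  )
}
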