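# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state; with seed = NULL the expression runs on the ambient stream.
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

abort_icm <- function(msg, class) {
  rlang::abort(msg, class = c(class, "icmolar_error"))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                closed_lower = TRUE, closed_upper = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (closed_lower) x >= lower else x > lower) &&
    (if (closed_upper) x <= upper else x < upper)
  if (!ok) {
    abort_icm(
      sprintf("`%s` must be a single finite number in %s%s, %s%s.",
              name,
              if (closed_lower) "[" else "(", format(lower),
              format(upper), if (closed_upper) "]" else ")"),
      "icmolar_validation_error"
    )
  }
  invisible(x)
}

# Sample standard deviation of each column, via moments (avoids apply()).
col_sds <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  sqrt((colSums(m^2) - n * mu^2) / (n - 1))
}

is_spd <- function(m, tol = 1e-10) {
  if (!isSymmetric(m, tol = 1e-8)) return(FALSE)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  all(ev > tol * max(abs(ev), 1))
}
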