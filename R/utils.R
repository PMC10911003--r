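# Internal argument checks. All error with a condition class so callers and
# tests can distinguish domain errors (bad input) from inconsistency errors
# (input incompatible with the claimed misclassification parameters).

stop_domain <- function(msg, ...) {
  abort(msg, class = "fpclaims_domain_error", ...)
}

stop_inconsistency <- function(msg, ...) {
  abort(msg, class = "fpclaims_inconsistency_error", ...)
}

check_numeric <- function(x, name) {
  if (!is.numeric(x) || anyNA(x)) {
    stop_domain(sprintf("`%s` must be numeric and non-missing.", name))
  }
  invisible(x)
}

check_proportion <- function(x, name, lo = 0, hi = 1, open_lo = FALSE) {
  check_numeric(x, name)
  bad <- if (open_lo) x <= lo | x > hi else x < lo | x > hi
  if (any(bad)) {
    stop_domain(sprintf(
      "`%s` must lie in %s%s, %s]; offending value: %s",
      name, if (open_lo) "(" else "[", format(lo), format(hi),
      format(x[bad][1], digits = 15)
    ))
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  check_numeric(x, name)
  if (any(x < 0)) {
    stop_domain(sprintf("`%s` must be >= 0; offending value: %s",
                        name, format(x[x < 0][1], digits = 15)))
  }
  invisible(x)
}

check_positive <- function(x, name) {
  check_numeric(x, name)
  if (any(x <= 0)) {
    stop_domain(sprintf("`%s` must be > 0; offending value: %s",
                        name, format(x[x <= 0][1], digits = 15)))
  }
  invisible(x)
}

# Sensitivity/specificity pair: 0 < se <= 1, 0 < sp <= 1, se + sp > 1
# (the last is the identifiability condition of the correction).
check_misclass <- function(se, sp) {
  check_proportion(se, "se", open_lo = TRUE)
  check_proportion(sp, "sp", open_lo = TRUE)
  if (any(se + sp <= 1)) {
    stop_domain("`se + sp` must exceed 1 for the misclassification correction to be identifiable.")
  }
  invisible(NULL)
}

# Tolerance for treating a corrected proportion a hair outside [0, 1] as a
# rounding artefact rather than a genuine inconsistency.
BOUND_TOL <- 1e-9
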