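#' Stratified rate tables
#'
#' The package's tabular exchange format: one row per (sex, period, age
#' group) with the value of a single epidemiologic quantity.  Required
#' columns:
#' \describe{
#'   \item{sex}{`"male"` or `"female"`.}
#'   \item{year}{Calendar year of the stratum (for pooled periods, the
#'     period midpoint).}
#'   \item{age_lo}{Lower bound of the age group, years.}
#'   \item{age_hi}{Upper bound (exclusive); `NA` marks an open-ended top
#'     group such as 90+.}
#'   \item{value}{The quantity: a proportion for prevalence, a per
#'     person-year rate for incidence/mortality, a ratio for the mortality
#'     rate ratio.}
#'   \item{population}{Optional stratum population count.}
#' }
#'
#' @param x A data frame with the columns above.
#' @param quantity One of `"prevalence"`, `"incidence"`, `"mortality"`,
#'   `"rate_ratio"`.
#' @return A validated tibble with attribute `quantity`.
#' @export
rate_table <- function(x, quantity = c("prevalence", "incidence",
                                       "mortality", "rate_ratio")) {
  quantity <- match.arg(quantity)
  x <- tibble::as_tibble(x)
  required <- c("sex", "year", "age_lo", "age_hi", "value")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop_domain(sprintf("Rate table is missing column(s): %s.",
                        paste(missing_cols, collapse = ", ")))
  }
  if (!"population" %in% names(x)) x$population <- NA_real_
  if (nrow(x) == 0) stop_domain("Rate table has no rows.")
  if (!all(x$sex %in% c("male", "female"))) {
    stop_domain("`sex` must be \"male\" or \"female\".")
  }
  check_numeric(x$year, "year")
  check_numeric(x$age_lo, "age_lo")
  closed <- !is.na(x$age_hi)
  if (any(closed & x$age_hi <= x$age_lo)) {
    stop_domain("`age_hi` must exceed `age_lo` for closed age groups.")
  }
  check_numeric(x$value, "value")
  switch(quantity,
    prevalence = check_proportion(x$value, "value"),
    incidence = check_nonnegative(x$value, "value"),
    mortality = check_nonnegative(x$value, "value"),
    rate_ratio = check_positive(x$value, "value")
  )
  key <- paste(x$sex, x$year, x$age_lo, sep = "|")
  if (anyDuplicated(key)) {
    stop_domain(sprintf("Duplicate (sex, year, age group) key: %s.",
                        key[duplicated(key)][1]))
  }
  attr(x, "quantity") <- quantity
  x
}

table_quantity <- function(x, expected, arg = "table") {
  q <- attr(x, "quantity")
  if (is.null(q)) {
    # untagged data frame: validate on the fly
    x <- rate_table(x, expected)
    q <- expected
  }
  if (!identical(q, expected)) {
    stop_domain(sprintf("`%s` holds %s, expected %s.", arg, q, expected))
  }
  x
}

#' Annotate age groups with a representative (midpoint) age
#'
#' Closed groups get their arithmetic midpoint; an open-ended top group
#' (`age_hi = NA`) gets `age_lo + open_group_offset`.  A bottom group coded
#' as `[0, 15)` naturally gets midpoint 7.5.
#'
#' @param table A rate table (see [rate_table()]).
#' @param open_group_offset Years added to `age_lo` of an open-ended group
#'   (default 2.5).
#' @return The table with an added `age_mid` column.
#' @export
midpoint_ages <- function(table, open_group_offset = 2.5) {
  q <- attr(table, "quantity")
  out <- dplyr::mutate(
    tibble::as_tibble(table),
    age_mid = ifelse(is.na(.data$age_hi),
                     .data$age_lo + open_group_offset,
                     (.data$age_lo + .data$age_hi) / 2)
  )
  attr(out, "quantity") <- q
  out
}

# Valid age span of a fitted surface: each age group speaks for its whole
# interval, so the span runs from the lowest group bound to the highest
# (open-ended groups extend symmetrically around their representative age).
table_age_span <- function(table, open_group_offset = 2.5) {
  hi <- ifelse(is.na(table$age_hi), table$age_lo + 2 * open_group_offset,
               table$age_hi)
  c(min(table$age_lo), max(hi))
}

new_idm_surface <- function(fit, quantity, transform, basis, age_range,
                            uses_time, t_ref, excluded = 0L) {
  structure(
    list(fit = fit, quantity = quantity, transform = transform,
         basis = basis, age_range = age_range, uses_time = uses_time,
         t_ref = t_ref, excluded = excluded),
    class = "idm_surface"
  )
}

check_full_rank <- function(fit) {
  cf <- coef(fit)
  if (anyNA(cf)) {
    stop_domain(sprintf("Rank-deficient design; collinear term(s): %s.",
                        paste(names(cf)[is.na(cf)], collapse = ", ")))
  }
  invisible(fit)
}

surface_model_data <- function(table, open_group_offset, t_ref) {
  d <- midpoint_ages(table, open_group_offset)
  tibble::tibble(
    age = d$age_mid,
    time = d$year - t_ref,
    sex = factor(d$sex, levels = c("male", "female")),
    value = d$value,
    population = d$population
  )
}

# Design formulas degrade gracefully when only one sex is present.
surface_formula <- function(age_term, d, with_time = FALSE) {
  rhs <- age_term
  if (with_time) rhs <- paste0(rhs, " * time")
  if (length(unique(d$sex)) > 1) rhs <- paste0(rhs, " * sex")
  stats::as.formula(paste("y ~", rhs), env = baseenv())
}

fit_weights <- function(d, weighted) {
  if (!weighted) return(NULL)
  if (anyNA(d$population)) {
    stop_domain("Population-weighted fitting requires a `population` column without missing values.")
  }
  d$population
}

# lm with the weights vector already evaluated (the formula environment is
# baseenv(), so a bare symbol would not resolve).
fit_lm <- function(formula, d, w) {
  if (is.null(w)) {
    lm(formula, data = d)
  } else {
    do.call(stats::lm, list(formula, data = d, weights = w))
  }
}

#' Fit a smooth prevalence surface
#'
#' Least-squares fit of `logit(value)` on the full factorial design of a
#' natural-spline basis in age, linear calendar time, and sex:
#' `logit(p_obs) ~ ns(age, df) * time * sex` with all lower-order terms.
#' Spline knots sit at quantiles of the observed midpoint ages, boundary
#' knots at the extremes; beyond the boundary knots the surface is linear in
#' age on the logit scale (the defining natural-spline property).
#'
#' Rows with prevalence exactly 0 or 1 have no logit and are dropped with a
#' warning; the number of dropped rows is recorded on the returned surface.
#'
#' @param table A prevalence rate table with at least two distinct years.
#' @param spline_df Degrees of freedom of the natural-spline age basis.
#' @param open_group_offset Passed to [midpoint_ages()].
#' @param weighted Use population counts as least-squares weights.
#' @return An object of class `idm_surface`; evaluate it with
#'   [predict.idm_surface()] or [evaluate_surface()].
#' @export
fit_prevalence <- function(table, spline_df = 4, open_group_offset = 2.5,
                           weighted = FALSE) {
  table <- table_quantity(table, "prevalence")
  if (length(unique(table$year)) < 2) {
    stop_domain("Prevalence fitting needs at least two survey years.")
  }
  t_ref <- mean(range(table$year))
  d <- surface_model_data(table, open_group_offset, t_ref)
  degenerate <- d$value <= 0 | d$value >= 1
  n_excl <- sum(degenerate)
  if (n_excl > 0) {
    warn(sprintf("Dropping %d prevalence row(s) with value 0 or 1 (logit undefined).",
                 n_excl), class = "fpclaims_excluded_rows")
    d <- d[!degenerate, , drop = FALSE]
  }
  d$y <- qlogis(d$value)
  w <- fit_weights(d, weighted)
  fit <- fit_lm(surface_formula(sprintf("splines::ns(age, df = %d)",
                                        spline_df),
                                d, with_time = TRUE), d, w)
  check_full_rank(fit)
  new_idm_surface(fit, "prevalence", "logit",
                  sprintf("ns(age, df = %d) * time * sex", spline_df),
                  table_age_span(table, open_group_offset),
                  uses_time = TRUE, t_ref = t_ref, excluded = n_excl)
}

#' Fit a smooth incidence surface
#'
#' Least-squares fit of `log(value)` on a natural-spline age basis crossed
#' with sex: `log(i_obs) ~ ns(age, df) * sex`.  Incidence tables are pooled
#' over a short calendar window, so no time term enters the design.
#'
#' @inheritParams fit_prevalence
#' @param table An incidence rate table with strictly positive values.
#' @return An `idm_surface`.
#' @export
fit_incidence <- function(table, spline_df = 3, open_group_offset = 2.5,
                          weighted = FALSE) {
  table <- table_quantity(table, "incidence")
  check_positive(table$value, "value")
  t_ref <- mean(range(table$year))
  d <- surface_model_data(table, open_group_offset, t_ref)
  d$y <- log(d$value)
  w <- fit_weights(d, weighted)
  age_term <- if (spline_df >= 1) {
    sprintf("splines::ns(age, df = %d)", spline_df)
  } else {
    "1"
  }
  fit <- fit_lm(surface_formula(age_term, d), d, w)
  check_full_rank(fit)
  new_idm_surface(fit, "incidence", "log",
                  sprintf("ns(age, df = %d) * sex", spline_df),
                  table_age_span(table, open_group_offset),
                  uses_time = FALSE, t_ref = t_ref)
}

#' Fit a smooth general-mortality surface
#'
#' Least-squares fit of `log(m)` on a quadratic age polynomial crossed with
#' sex: `log(m) ~ (age + age^2) * sex`, restricted to ages 15-95 before
#' fitting (rates outside that range are dropped).
#'
#' @inheritParams fit_prevalence
#' @param table A mortality rate table with strictly positive values.
#' @param age_limits Ages retained for fitting (and the surface's valid
#'   range), default `c(15, 95)`.
#' @return An `idm_surface` with `age_range = age_limits`.
#' @export
fit_mortality <- function(table, age_limits = c(15, 95),
                          open_group_offset = 2.5, weighted = FALSE) {
  table <- table_quantity(table, "mortality")
  check_positive(table$value, "value")
  t_ref <- mean(range(table$year))
  d <- surface_model_data(table, open_group_offset, t_ref)
  d <- d[d$age >= age_limits[1] & d$age <= age_limits[2], , drop = FALSE]
  for (s in unique(as.character(d$sex))) {
    if (length(unique(d$age[d$sex == s])) < 3) {
      stop_domain(sprintf(
        "Mortality fit needs >= 3 distinct ages per sex in [%g, %g]; %s has fewer.",
        age_limits[1], age_limits[2], s))
    }
  }
  d$y <- log(d$value)
  w <- fit_weights(d, weighted)
  fit <- fit_lm(surface_formula("(age + I(age^2))", d), d, w)
  check_full_rank(fit)
  new_idm_surface(fit, "mortality", "log", "(age + age^2) * sex",
                  age_limits, uses_time = FALSE, t_ref = t_ref)
}

#' Fit a smooth mortality-rate-ratio surface
#'
#' Least-squares fit of `log(R)` on a natural-spline age basis crossed with
#' sex: `log(R) ~ ns(age, df) * sex`.
#'
#' @inheritParams fit_incidence
#' @param table A rate-ratio table with strictly positive values.
#' @return An `idm_surface`.
#' @export
fit_rate_ratio <- function(table, spline_df = 3, open_group_offset = 2.5,
                           weighted = FALSE) {
  table <- table_quantity(table, "rate_ratio")
  t_ref <- mean(range(table$year))
  d <- surface_model_data(table, open_group_offset, t_ref)
  d$y <- log(d$value)
  w <- fit_weights(d, weighted)
  age_term <- if (spline_df >= 1) {
    sprintf("splines::ns(age, df = %d)", spline_df)
  } else {
    "1"
  }
  fit <- fit_lm(surface_formula(age_term, d), d, w)
  check_full_rank(fit)
  new_idm_surface(fit, "rate_ratio", "log",
                  sprintf("ns(age, df = %d) * sex", spline_df),
                  table_age_span(table, open_group_offset),
                  uses_time = FALSE, t_ref = t_ref)
}

#' Evaluate a fitted surface on the natural scale
#'
#' Back-transforms the linear predictor: `plogis` for logit-fitted
#' prevalence (so values lie in (0, 1)), `exp` for log-fitted rates and
#' ratios (so values are positive).
#'
#' @param object An `idm_surface`.
#' @param age Ages (years) at which to evaluate.
#' @param sex `"male"` or `"female"` (recycled).
#' @param year Calendar year; required for surfaces with a time term,
#'   ignored otherwise.
#' @param allow_extrapolation If `FALSE`, evaluation outside the surface's
#'   valid age range is an error; if `TRUE` (default) it is permitted (the
#'   natural-spline basis continues linearly) and flagged by
#'   [evaluate_surface()].
#' @param ... Unused.
#' @return Numeric vector of values on the quantity's natural scale.
#' @export
predict.idm_surface <- function(object, age, sex, year = NULL,
                                allow_extrapolation = TRUE, ...) {
  check_numeric(age, "age")
  outside <- age < object$age_range[1] | age > object$age_range[2]
  if (any(outside) && !allow_extrapolation) {
    stop_domain(sprintf(
      "Evaluation at age %.3g is outside the surface's valid range [%g, %g].",
      age[outside][1], object$age_range[1], object$age_range[2]))
  }
  n <- max(length(age), length(sex), length(year %||% 0))
  newdata <- data.frame(
    age = rep_len(age, n),
    sex = factor(rep_len(sex, n), levels = c("male", "female")),
    time = if (object$uses_time) {
      if (is.null(year)) {
        stop_domain(sprintf("A `year` is required to evaluate the %s surface.",
                            object$quantity))
      }
      rep_len(year, n) - object$t_ref
    } else {
      0
    }
  )
  eta <- unname(predict(object$fit, newdata = newdata))
  if (object$transform == "logit") plogis(eta) else exp(eta)
}

#' Evaluate a fitted surface, returning a tibble with extrapolation flags
#'
#' @inheritParams predict.idm_surface
#' @param surface An `idm_surface`.
#' @return A tibble with columns `age`, `sex`, `year` (if applicable),
#'   `value`, and `extrapolated` (logical: outside the valid age range).
#' @export
evaluate_surface <- function(surface, age, sex, year = NULL) {
  value <- predict(surface, age = age, sex = sex, year = year)
  n <- length(value)
  out <- tibble::tibble(
    age = rep_len(age, n),
    sex = rep_len(sex, n),
    value = value,
    extrapolated = rep_len(age, n) < surface$age_range[1] |
      rep_len(age, n) > surface$age_range[2]
  )
  if (surface$uses_time) out$year <- rep_len(year, n)
  out
}

#' @export
print.idm_surface <- function(x, ...) {
  cat(sprintf("<idm_surface> %s\n", x$quantity))
  cat(sprintf("  model: %s(value) ~ %s\n", x$transform, x$basis))
  cat(sprintf("  valid ages: [%g, %g]\n", x$age_range[1], x$age_range[2]))
  cat(sprintf("  n = %d, excluded rows = %d\n",
              length(x$fit$residuals), x$excluded))
  invisible(x)
}

#' Tidy the coefficients of a fitted surface
#'
#' @param x An `idm_surface`.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate` (coefficients on the
#'   transformed scale).
#' @method tidy idm_surface
#' @export
tidy.idm_surface <- function(x, ...) {
  cf <- coef(x$fit)
  tibble::tibble(term = names(cf), estimate = unname(cf))
}

#' One-row model summary of a fitted surface
#'
#' @param x An `idm_surface`.
#' @param ... Unused.
#' @return A tibble with `quantity`, `transform`, `nobs`, `df`, `r.squared`,
#'   `sigma`, `rss`, `excluded`.
#' @method glance idm_surface
#' @export
glance.idm_surface <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    quantity = x$quantity,
    transform = x$transform,
    nobs = length(x$fit$residuals),
    df = x$fit$rank,
    r.squared = s$r.squared,
    sigma = s$sigma,
    rss = sum(x$fit$residuals^2),
    excluded = x$excluded
  )
}

#' Plot a fitted surface against its input table
#'
#' @param object An `idm_surface`.
#' @param table Optionally, the rate table it was fitted to (points).
#' @param year Year(s) at which to draw a time-dependent surface.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot idm_surface
#' @export
autoplot.idm_surface <- function(object, table = NULL, year = NULL, ...) {
  ages <- seq(object$age_range[1], object$age_range[2], length.out = 121)
  years <- if (object$uses_time) (year %||% object$t_ref) else NA_real_
  grid <- tidyr::expand_grid(age = ages, sex = c("male", "female"),
                             year = years)
  grid$value <- predict(object, age = grid$age, sex = grid$sex,
                        year = if (object$uses_time) grid$year else NULL)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$age, y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(
      linetype = if (object$uses_time) factor(.data$year) else NULL
    )) +
    ggplot2::facet_wrap(~sex) +
    ggplot2::labs(x = "age (years)", y = object$quantity,
                  linetype = "year")
  if (!is.null(table)) {
    pts <- midpoint_ages(table)
    p <- p + ggplot2::geom_point(
      data = pts, ggplot2::aes(x = .data$age_mid, y = .data$value))
  }
  p
}
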