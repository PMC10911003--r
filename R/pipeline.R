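#' Evaluation grid for specificity inversion
#'
#' The ages at which specificity is estimated, together with the
#' characteristic length `delta = t2 - t1` joining the two prevalence
#' surveys.  Each evaluation age `a` uses observed prevalence at
#' `(t1, a - delta/2)` and `(t2, a + delta/2)` and midpoint rates at
#' `(a, (t1 + t2)/2)`.  The method needs the age resolution to be coarser
#' than the temporal distance between the surveys; a grid spacing at or
#' below `delta` triggers a warning.
#'
#' @param ages Ordered evaluation ages (default 25 to 85 in steps of 7.5).
#' @param t1,t2 The two prevalence survey years.
#' @return An object of class `evaluation_grid`.
#' @export
evaluation_grid <- function(ages = seq(25, 85, by = 7.5), t1 = 2009,
                            t2 = 2015) {
  check_numeric(ages, "ages")
  if (is.unsorted(ages, strictly = TRUE)) {
    stop_domain("`ages` must be strictly increasing.")
  }
  delta <- t2 - t1
  check_positive(delta, "t2 - t1")
  if (length(ages) > 1 && min(diff(ages)) <= delta) {
    warn(paste0("Grid spacing is not coarser than the temporal distance ",
                "between the prevalence surveys; estimates at neighbouring ",
                "ages share data."),
         class = "fpclaims_grid_resolution")
  }
  structure(list(ages = ages, delta = delta, t1 = t1, t2 = t2),
            class = "evaluation_grid")
}

#' Sample sensitivity scenarios
#'
#' Draws sensitivities uniformly from `[lo, hi]`.  With `mode = "shared"`
#' one draw per scenario applies to every evaluation age; with
#' `mode = "per_age"` each (scenario, age) cell gets an independent draw,
#' i.e. the assumed sensitivity may vary over age within a scenario.
#'
#' @param n Number of scenarios.
#' @param lo,hi Range of epidemiologically plausible sensitivities
#'   (defaults 0.5 and 0.999).
#' @param mode `"per_age"` or `"shared"`.
#' @param n_ages Number of evaluation ages (columns of the returned
#'   matrix).
#' @param seed Optional seed; when given, draws are reproducible and the
#'   caller's RNG state is untouched.
#' @return An `n` by `n_ages` matrix of sensitivities with attributes
#'   `mode`, `lo`, `hi`, `seed`.
#' @export
sample_sensitivities <- function(n, lo = 0.5, hi = 0.999,
                                 mode = c("per_age", "shared"),
                                 n_ages = 1, seed = NULL) {
  mode <- match.arg(mode)
  if (n < 1) stop_domain("`n` must be >= 1.")
  if (!(lo > 0 && lo < hi && hi <= 1)) {
    stop_domain("Sensitivity range must satisfy 0 < lo < hi <= 1.")
  }
  draw <- function() {
    if (mode == "shared") {
      matrix(runif(n, lo, hi), nrow = n, ncol = n_ages)
    } else {
      matrix(runif(n * n_ages, lo, hi), nrow = n, ncol = n_ages)
    }
  }
  m <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(m, mode = mode, lo = lo, hi = hi, seed = seed)
}

# Vectorised bisection for the specificity root over a vector of assumed
# sensitivities (one characteristic segment, many Monte-Carlo scenarios).
# Matches estimate_specificity() to within the tolerance; clipped cells are
# returned at the bracket endpoint with the smaller |residual|.
solve_sp_vectorised <- function(p1, p2, i_obs, m, R, se, delta,
                                eps = 1e-9, tol = 1e-10,
                                prevalence_rhs = "midpoint_mean",
                                p_obs_mid = NULL) {
  f <- function(sp) {
    pde_residual_unchecked(sp, p1, p2, i_obs, m, R, se, delta,
                           prevalence_rhs, p_obs_mid)
  }
  lo <- sp_bracket_lo(p1, p2, i_obs, se, eps)
  hi <- rep(1, length(se))
  f_lo <- f(lo)
  f_hi <- f(hi)
  interior <- is.finite(f_lo) & is.finite(f_hi) & (f_lo * f_hi <= 0)
  a <- lo
  b <- hi
  fa <- f_lo
  iter <- 0L
  while (max(b - a) > tol && iter < 200L) {
    mid <- (a + b) / 2
    fm <- f(mid)
    move_lo <- interior & (fa * fm > 0)
    move_hi <- interior & !move_lo
    a[move_lo] <- mid[move_lo]
    fa[move_lo] <- fm[move_lo]
    b[move_hi] <- mid[move_hi]
    iter <- iter + 1L
  }
  sp <- (a + b) / 2
  sp[!interior] <- ifelse(abs(f_lo[!interior]) < abs(f_hi[!interior]),
                          lo[!interior], hi[!interior])
  list(sp = sp, clipped = !interior)
}

# Fails loudly when a surface cannot cover the ages the grid needs.
check_surface_coverage <- function(surfaces, grid) {
  need <- list(
    prevalence = range(grid$ages) + c(-1, 1) * grid$delta / 2,
    incidence = range(grid$ages),
    mortality = range(grid$ages),
    rate_ratio = range(grid$ages)
  )
  for (nm in names(need)) {
    rng <- surfaces[[nm]]$age_range
    bad <- need[[nm]] < rng[1] | need[[nm]] > rng[2]
    if (any(bad)) {
      stop_domain(sprintf(
        "The %s surface (valid ages [%g, %g]) does not cover the grid's required ages [%g, %g].",
        nm, rng[1], rng[2], need[[nm]][1], need[[nm]][2]))
    }
  }
  invisible(NULL)
}

#' Monte-Carlo matrix of false-positive ratios
#'
#' For every sex, evaluation age and sensitivity scenario, builds the
#' characteristic segment from the fitted surfaces, inverts the prevalence
#' equation for the specificity ([estimate_specificity()]'s root, computed
#' by a vectorised bracketing bisection across scenarios), and stores
#' `fpr = 1 - sp`.  Scenarios whose residual does not change sign on the
#' admissible bracket are boundary-clipped and flagged.
#'
#' @param grid An [evaluation_grid()].
#' @param surfaces Named list with `idm_surface` elements `prevalence`,
#'   `incidence`, `mortality`, `rate_ratio`.
#' @param se_draws Sensitivity matrix from [sample_sensitivities()]
#'   (scenarios in rows, grid ages in columns; a single column is recycled
#'   across ages).
#' @param prevalence_rhs Prevalence entering the model right-hand side:
#'   the mean of the corrected endpoint prevalences (`"midpoint_mean"`,
#'   default) or the corrected fitted prevalence at the segment midpoint
#'   (`"midpoint_obs"`).
#' @param tol,eps Root-finder tolerance and bracket interior offset.
#' @return A long tibble with columns `sex`, `age`, `scenario`, `se`, `sp`,
#'   `fpr`, `clipped`.
#' @export
estimate_fpr_matrix <- function(grid, surfaces, se_draws,
                                prevalence_rhs = c("midpoint_mean",
                                                   "midpoint_obs"),
                                tol = 1e-10, eps = 1e-9) {
  prevalence_rhs <- match.arg(prevalence_rhs)
  if (!inherits(grid, "evaluation_grid")) {
    stop_domain("`grid` must be an evaluation_grid.")
  }
  check_surface_coverage(surfaces, grid)
  se_draws <- as.matrix(se_draws)
  n_ages <- length(grid$ages)
  if (ncol(se_draws) == 1 && n_ages > 1) {
    se_draws <- se_draws[, rep(1, n_ages), drop = FALSE]
  }
  if (ncol(se_draws) != n_ages) {
    stop_domain("`se_draws` must have one column per grid age (or a single column).")
  }
  t_mid <- (grid$t1 + grid$t2) / 2
  half <- grid$delta / 2
  purrr::map_dfr(c("male", "female"), function(s) {
    purrr::map_dfr(seq_along(grid$ages), function(j) {
      a <- grid$ages[j]
      p1 <- predict(surfaces$prevalence, age = a - half, sex = s,
                    year = grid$t1)
      p2 <- predict(surfaces$prevalence, age = a + half, sex = s,
                    year = grid$t2)
      i_obs <- predict(surfaces$incidence, age = a, sex = s)
      m <- predict(surfaces$mortality, age = a, sex = s)
      R <- predict(surfaces$rate_ratio, age = a, sex = s)
      p_mid <- if (prevalence_rhs == "midpoint_obs") {
        predict(surfaces$prevalence, age = a, sex = s, year = t_mid)
      } else {
        NULL
      }
      se <- se_draws[, j]
      sol <- solve_sp_vectorised(p1, p2, i_obs, m, R, se, grid$delta,
                                 eps = eps, tol = tol,
                                 prevalence_rhs = prevalence_rhs,
                                 p_obs_mid = p_mid)
      tibble::tibble(sex = s, age = a, scenario = seq_along(se), se = se,
                     sp = sol$sp, fpr = 1 - sol$sp, clipped = sol$clipped)
    })
  })
}

#' Linearly interpolate grid values to integer ages
#'
#' Linear interpolation between grid ages; constant continuation of the
#' nearest grid value outside the grid range (linear extrapolation of a
#' small ratio could go negative).
#'
#' @param grid_ages Ages at which `values` are known (>= 2).
#' @param values Values at `grid_ages`.
#' @param ages Target ages (default the integers 20 to 100).
#' @return A tibble with columns `age` and `value`.
#' @export
interpolate_to_integer_ages <- function(grid_ages, values, ages = 20:100) {
  if (length(grid_ages) < 2) {
    stop_domain("Interpolation needs at least two grid ages.")
  }
  check_numeric(values, "values")
  out <- approx(grid_ages, values, xout = ages, rule = 2)
  tibble::tibble(age = ages, value = out$y)
}

# Interpolation weights as a matrix (targets x grid ages) so that many
# Monte-Carlo columns can be interpolated with one matrix product.
interp_weight_matrix <- function(grid_ages, ages) {
  W <- matrix(0, nrow = length(ages), ncol = length(grid_ages))
  for (j in seq_along(grid_ages)) {
    unit <- rep(0, length(grid_ages))
    unit[j] <- 1
    W[, j] <- approx(grid_ages, unit, xout = ages, rule = 2)$y
  }
  W
}

#' Spread grouped population counts to integer ages
#'
#' Accepts per-sex population counts at integer ages (`age` column) or in
#' age groups (`age_lo`/`age_hi` columns; group counts are spread uniformly
#' across member integer ages, an open-ended group extending to `max_age`).
#'
#' @param population A data frame with `sex`, `count`, and either `age` or
#'   `age_lo`/`age_hi`.
#' @param ages Integer ages to return (default 20 to 100).
#' @param max_age Top age an open-ended group extends to.
#' @return A tibble with columns `sex`, `age`, `count`.
#' @export
population_by_age <- function(population, ages = 20:100, max_age = 100) {
  population <- tibble::as_tibble(population)
  if ("age" %in% names(population)) {
    out <- population[c("sex", "age", "count")]
  } else if (all(c("age_lo", "age_hi") %in% names(population))) {
    out <- purrr::pmap_dfr(population, function(sex, age_lo, age_hi, count,
                                                ...) {
      members <- seq(age_lo,
                     if (is.na(age_hi)) max_age else age_hi - 1)
      tibble::tibble(sex = sex, age = members,
                     count = count / length(members))
    })
  } else {
    stop_domain("`population` needs an `age` column or `age_lo`/`age_hi` columns.")
  }
  out <- out[out$age %in% ages, ]
  check_nonnegative(out$count, "count")
  dplyr::arrange(out, .data$sex, .data$age)
}

#' Absolute number of falsely diagnosed people
#'
#' Sums, over integer ages, the product of the number of people without the
#' condition, `S(a) = (1 - p(a)) N(a)`, and the false-positive ratio
#' `FPR(a)`:
#' \deqn{N^{fp} = \sum_a S(a) \, FPR(a).}
#'
#' @param count_table A data frame with one row per (sex, integer age) and
#'   columns `sex`, `age`, `n` (insured people), `p_corrected` (true,
#'   corrected prevalence) and `fpr`.
#' @return A tibble with one row per sex plus a `"total"` row, columns
#'   `group` and `n_fp`.
#' @examples
#' ct <- data.frame(sex = "male", age = 20:100, n = 1000,
#'                  p_corrected = 0, fpr = 0.005)
#' count_false_positives(ct) # 81 * 1000 * 0.005 = 405
#' @export
count_false_positives <- function(count_table) {
  count_table <- tibble::as_tibble(count_table)
  required <- c("sex", "age", "n", "p_corrected", "fpr")
  missing_cols <- setdiff(required, names(count_table))
  if (length(missing_cols) > 0) {
    stop_domain(sprintf("Count table is missing column(s): %s.",
                        paste(missing_cols, collapse = ", ")))
  }
  check_nonnegative(count_table$n, "n")
  check_proportion(count_table$p_corrected, "p_corrected")
  check_proportion(count_table$fpr, "fpr")
  per_sex <- count_table |>
    dplyr::mutate(s = (1 - .data$p_corrected) * .data$n) |>
    dplyr::group_by(group = .data$sex) |>
    dplyr::summarise(n_fp = sum(.data$s * .data$fpr), .groups = "drop")
  dplyr::bind_rows(per_sex,
                   tibble::tibble(group = "total",
                                  n_fp = sum(per_sex$n_fp)))
}

#' Empirical quantile summary of false-positive counts
#'
#' Per group, the empirical 2.5%, 50% and 97.5% quantiles of the
#' per-scenario counts, using linear interpolation between order statistics
#' (quantile type 7, the default definition in R).
#'
#' @param totals A data frame with columns `group`, `scenario`, `n_fp`.
#' @param unit `"persons"` or `"thousands"` (values divided by 1,000).
#' @return A tibble with columns `group`, `median`, `ci_low`, `ci_high`,
#'   `unit`.
#' @export
summarize_false_positives <- function(totals, unit = c("persons",
                                                       "thousands")) {
  unit <- match.arg(unit)
  totals <- tibble::as_tibble(totals)
  if (nrow(totals) == 0) stop_domain("`totals` has no rows.")
  scale <- if (unit == "thousands") 1000 else 1
  totals |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      median = quantile(.data$n_fp, 0.5, type = 7, names = FALSE) / scale,
      ci_low = quantile(.data$n_fp, 0.025, type = 7, names = FALSE) / scale,
      ci_high = quantile(.data$n_fp, 0.975, type = 7, names = FALSE) / scale,
      .groups = "drop"
    ) |>
    dplyr::mutate(unit = unit)
}

#' Configuration of a full analysis run
#'
#' Collects the inputs and tuning parameters of [run_full_analysis()].
#' Tables may be passed as data frames or as paths to delimited files (read
#' with [read_rate_table()]).
#'
#' @param prevalence,incidence,mortality,rate_ratio Rate tables or paths.
#' @param population Population table (or path): `sex`, `count`, and `age`
#'   or `age_lo`/`age_hi`.
#' @param t1,t2 Prevalence survey years.
#' @param grid_ages Evaluation ages.
#' @param prevalence_df,incidence_df,rate_ratio_df Natural-spline degrees
#'   of freedom of the respective fits.
#' @param se_range Sensitivity sampling range `c(lo, hi)`.
#' @param se_mode `"per_age"` or `"shared"` (see
#'   [sample_sensitivities()]).
#' @param n_scenarios Number of Monte-Carlo sensitivity scenarios.
#' @param seed Seed for all randomness of the run.
#' @param prevalence_rhs Passed to [estimate_fpr_matrix()].
#' @param weighted Population-weighted least squares in the surface fits.
#' @param open_group_offset Representative-age offset for open age groups.
#' @param count_ages Integer ages the counts are aggregated over.
#' @param count_year Calendar year at which the prevalence surface is read
#'   for the count step (default `t2`, the later survey).
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(prevalence, incidence, mortality, rate_ratio,
                            population, t1 = 2009, t2 = 2015,
                            grid_ages = seq(25, 85, by = 7.5),
                            prevalence_df = 4, incidence_df = 3,
                            rate_ratio_df = 3, se_range = c(0.5, 0.999),
                            se_mode = c("per_age", "shared"),
                            n_scenarios = 1000, seed = 42L,
                            prevalence_rhs = c("midpoint_mean",
                                               "midpoint_obs"),
                            weighted = FALSE, open_group_offset = 2.5,
                            count_ages = 20:100, count_year = t2) {
  se_mode <- match.arg(se_mode)
  prevalence_rhs <- match.arg(prevalence_rhs)
  if (n_scenarios < 1) stop_domain("`n_scenarios` must be >= 1.")
  if (!(se_range[1] > 0 && se_range[1] < se_range[2] && se_range[2] <= 1)) {
    stop_domain("`se_range` must satisfy 0 < lo < hi <= 1.")
  }
  load_tbl <- function(x, quantity) {
    if (is.character(x)) read_rate_table(x, quantity) else rate_table(x, quantity)
  }
  structure(
    list(
      prevalence = load_tbl(prevalence, "prevalence"),
      incidence = load_tbl(incidence, "incidence"),
      mortality = load_tbl(mortality, "mortality"),
      rate_ratio = load_tbl(rate_ratio, "rate_ratio"),
      population = if (is.character(population)) {
        readr::read_csv(population, show_col_types = FALSE)
      } else {
        tibble::as_tibble(population)
      },
      t1 = t1, t2 = t2, grid_ages = grid_ages,
      prevalence_df = prevalence_df, incidence_df = incidence_df,
      rate_ratio_df = rate_ratio_df, se_range = se_range,
      se_mode = se_mode, n_scenarios = as.integer(n_scenarios),
      seed = as.integer(seed), prevalence_rhs = prevalence_rhs,
      weighted = weighted, open_group_offset = open_group_offset,
      count_ages = count_ages, count_year = count_year
    ),
    class = "analysis_config"
  )
}

#' Run the complete false-positive-ratio analysis
#'
#' Orchestrates the whole method: fits the four rate surfaces, samples
#' sensitivity scenarios, inverts the prevalence equation for specificity
#' at every (sex, age, scenario), converts specificities to false-positive
#' ratios, interpolates to integer ages, aggregates to absolute counts of
#' falsely diagnosed people per scenario, and summarises the resulting
#' distributions by empirical quantiles.  Deterministic given the
#' configuration seed.
#'
#' Boundary-clipped specificity estimates enter the count step as
#' `fpr = 0` and are tallied in the audit record; a run with more than 1%
#' clipped cells emits a warning.
#'
#' @param config An [analysis_config()].
#' @return An object of class `fpr_analysis`: a list with elements
#'   `config`, `surfaces`, `grid`, `fpr` (long Monte-Carlo tibble),
#'   `totals` (per-scenario counts by group), `summary` (quantiles in
#'   thousands), `audit`, and `manifest`.
#' @export
run_full_analysis <- function(config) {
  if (!inherits(config, "analysis_config")) {
    stop_domain("`config` must be an analysis_config.")
  }
  warnings_log <- character()
  result <- withCallingHandlers(
    run_full_analysis_impl(config),
    warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  for (msg in warnings_log) warn(msg)
  result$audit$warnings <- warnings_log
  result$manifest$warnings <- warnings_log
  result
}

run_full_analysis_impl <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[stage %s] %s", name, conditionMessage(e)),
            class = "fpclaims_stage_error", parent = e)
    })
  }

  surfaces <- stage("fit", list(
    prevalence = fit_prevalence(config$prevalence, config$prevalence_df,
                                config$open_group_offset, config$weighted),
    incidence = fit_incidence(config$incidence, config$incidence_df,
                              config$open_group_offset, config$weighted),
    mortality = fit_mortality(config$mortality,
                              open_group_offset = config$open_group_offset,
                              weighted = config$weighted),
    rate_ratio = fit_rate_ratio(config$rate_ratio, config$rate_ratio_df,
                                config$open_group_offset, config$weighted)
  ))

  grid <- stage("grid", evaluation_grid(config$grid_ages, config$t1,
                                        config$t2))

  se_draws <- stage("sample", sample_sensitivities(
    config$n_scenarios, config$se_range[1], config$se_range[2],
    mode = config$se_mode, n_ages = length(grid$ages), seed = config$seed))

  fpr <- stage("invert", estimate_fpr_matrix(
    grid, surfaces, se_draws, prevalence_rhs = config$prevalence_rhs))

  pop <- stage("population", population_by_age(config$population,
                                               ages = config$count_ages))

  counts <- stage("count", scenario_counts(fpr, surfaces, grid, pop, config))

  summary <- stage("summarize",
                   summarize_false_positives(counts, unit = "thousands"))

  n_clipped <- sum(fpr$clipped)
  clip_frac <- n_clipped / nrow(fpr)
  if (clip_frac > 0.01) {
    warn(sprintf("%.1f%% of specificity estimates are boundary-clipped.",
                 100 * clip_frac),
         class = "fpclaims_clipping")
  }

  audit <- list(
    n_cells = nrow(fpr),
    n_clipped = n_clipped,
    clipped_fraction = clip_frac,
    excluded_prevalence_rows = surfaces$prevalence$excluded,
    warnings = character()
  )
  manifest <- list(
    package = "fpclaims",
    version = as.character(packageVersion("fpclaims")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = config$seed,
    config_hash = rlang::hash(config),
    n_scenarios = config$n_scenarios,
    se_mode = config$se_mode,
    records = list(
      prevalence_rows = nrow(config$prevalence),
      incidence_rows = nrow(config$incidence),
      mortality_rows = nrow(config$mortality),
      rate_ratio_rows = nrow(config$rate_ratio),
      fpr_cells = nrow(fpr),
      clipped_cells = n_clipped,
      excluded_prevalence_rows = surfaces$prevalence$excluded
    ),
    warnings = character()
  )

  structure(
    list(config = config, surfaces = surfaces, grid = grid, fpr = fpr,
         totals = counts, summary = summary, audit = audit,
         manifest = manifest),
    class = "fpr_analysis"
  )
}

# Per-scenario count aggregation, vectorised across scenarios: interpolate
# the per-age FPR and corrected prevalence of every scenario to integer
# ages with one weight-matrix product, then sum S(a) * FPR(a).
scenario_counts <- function(fpr, surfaces, grid, pop, config) {
  W <- interp_weight_matrix(grid$ages, config$count_ages)
  n_scn <- max(fpr$scenario)
  per_sex <- purrr::map_dfr(c("male", "female"), function(s) {
    d <- fpr[fpr$sex == s, ]
    ord <- order(d$scenario, d$age)
    d <- d[ord, ]
    n_ages <- length(grid$ages)
    F <- matrix(d$fpr, nrow = n_ages)       # ages x scenarios
    SP <- matrix(d$sp, nrow = n_ages)
    SE <- matrix(d$se, nrow = n_ages)
    CL <- matrix(d$clipped, nrow = n_ages)
    F[CL] <- 0                              # clipped cells count as FPR = 0
    p_obs <- predict(surfaces$prevalence, age = grid$ages, sex = s,
                     year = config$count_year)
    p_corr <- (p_obs - 1 + SP) / (SE + SP - 1)
    p_corr <- pmin(pmax(p_corr, 0), 1)
    F_int <- W %*% F                        # integer ages x scenarios
    P_int <- pmin(pmax(W %*% p_corr, 0), 1)
    n_a <- pop$count[pop$sex == s]
    if (length(n_a) != length(config$count_ages)) {
      stop_domain(sprintf("Population table does not cover all count ages for %s.", s))
    }
    S <- (1 - P_int) * n_a
    tibble::tibble(group = s, scenario = seq_len(n_scn),
                   n_fp = colSums(S * F_int))
  })
  totals <- per_sex |>
    dplyr::group_by(.data$scenario) |>
    dplyr::summarise(n_fp = sum(.data$n_fp), .groups = "drop") |>
    dplyr::mutate(group = "total")
  dplyr::bind_rows(per_sex, totals[c("group", "scenario", "n_fp")])
}

#' @export
print.fpr_analysis <- function(x, ...) {
  cat("<fpr_analysis>\n")
  cat(sprintf("  %d scenarios x %d ages x 2 sexes (%.2f%% clipped)\n",
              x$config$n_scenarios, length(x$grid$ages),
              100 * x$audit$clipped_fraction))
  cat("  falsely diagnosed people (thousands):\n")
  s <- x$summary
  for (k in seq_len(nrow(s))) {
    cat(sprintf("    %-7s median %8.1f  (95%% CI %.1f to %.1f)\n",
                s$group[k], s$median[k], s$ci_low[k], s$ci_high[k]))
  }
  invisible(x)
}

#' Tidy the summary of a full analysis
#'
#' @param x An `fpr_analysis`.
#' @param ... Unused.
#' @return The quantile summary tibble (`group`, `median`, `ci_low`,
#'   `ci_high`, `unit`).
#' @method tidy fpr_analysis
#' @export
tidy.fpr_analysis <- function(x, ...) x$summary

#' One-row overview of a full analysis
#'
#' @param x An `fpr_analysis`.
#' @param ... Unused.
#' @return A tibble with `n_scenarios`, `n_ages`, `se_mode`,
#'   `clipped_fraction`, `seed`.
#' @method glance fpr_analysis
#' @export
glance.fpr_analysis <- function(x, ...) {
  tibble::tibble(
    n_scenarios = x$config$n_scenarios,
    n_ages = length(x$grid$ages),
    se_mode = x$config$se_mode,
    clipped_fraction = x$audit$clipped_fraction,
    seed = x$config$seed
  )
}

#' Fan chart of the Monte-Carlo false-positive ratios
#'
#' Median and 95% band of the age-specific FPR per sex, per 1,000 people.
#'
#' @param object An `fpr_analysis`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fpr_analysis
#' @export
autoplot.fpr_analysis <- function(object, ...) {
  q <- object$fpr |>
    dplyr::group_by(.data$sex, .data$age) |>
    dplyr::summarise(
      med = quantile(.data$fpr, 0.5, names = FALSE),
      lo = quantile(.data$fpr, 0.025, names = FALSE),
      hi = quantile(.data$fpr, 0.975, names = FALSE),
      .groups = "drop"
    )
  ggplot2::ggplot(q, ggplot2::aes(x = .data$age)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = 1000 * .data$lo,
                                      ymax = 1000 * .data$hi),
                         alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = 1000 * .data$med)) +
    ggplot2::facet_wrap(~sex) +
    ggplot2::labs(x = "age (years)", y = "false-positive ratio per 1,000")
}

#' Histogram of the per-scenario false-positive counts
#'
#' @param x An `fpr_analysis`.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_fp_distribution <- function(x, bins = 40) {
  ggplot2::ggplot(x$totals,
                  ggplot2::aes(x = .data$n_fp / 1000)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::facet_wrap(~group, scales = "free_x") +
    ggplot2::labs(x = "falsely diagnosed people (thousands)", y = "scenarios")
}

#' Share of false-positive diagnoses among all diagnoses
#'
#' @param n_false Number of falsely diagnosed people.
#' @param n_diagnosed Number of diagnosed people.
#' @return Percentage, `100 * n_false / n_diagnosed`.
#' @examples
#' false_positive_share(217000, 5800000) # 3.7%
#' @export
false_positive_share <- function(n_false, n_diagnosed) {
  check_nonnegative(n_false, "n_false")
  check_positive(n_diagnosed, "n_diagnosed")
  100 * n_false / n_diagnosed
}

#' Rough count of undiagnosed cases in an insured population
#'
#' Applies survey-based proportions of diagnosed and undiagnosed disease to
#' an insured population: `n * (1 - p_diagnosed) * p_undiagnosed`.
#'
#' @param n Number of insured people.
#' @param p_diagnosed Proportion with a diagnosis (on `[0, 1]`).
#' @param p_undiagnosed Proportion with undetected disease (on `[0, 1]`).
#' @return Estimated number of undiagnosed cases.
#' @examples
#' undiagnosed_estimate(70e6, 0.072, 0.020) # about 1.3 million
#' @export
undiagnosed_estimate <- function(n, p_diagnosed, p_undiagnosed) {
  check_positive(n, "n")
  check_proportion(p_diagnosed, "p_diagnosed")
  check_proportion(p_undiagnosed, "p_undiagnosed")
  n * (1 - p_diagnosed) * p_undiagnosed
}
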