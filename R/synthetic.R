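#' Define a synthetic illness-death ground truth
#'
#' A scenario fully specifies a time-homogeneous illness-death process with
#' known diagnostic misclassification, from which claims-style aggregated
#' tables can be generated by [simulate_claims()].  Rates are parametric in
#' age, per sex:
#' \describe{
#'   \item{incidence}{`i(a) = exp(b0 + b1 a + b2 a^2)` (set `b2 < 0` for a
#'     rate that peaks in old age).}
#'   \item{mortality}{Gompertz, `m(a) = exp(mu0 + mu1 a)`.}
#'   \item{rate_ratio}{`R(a) = max(1, exp(g0 + g1 a))`, floored at 1.}
#'   \item{specificity}{A piecewise-linear false-positive-ratio profile
#'     `fpr(a)`, so `sp(a) = 1 - fpr(a)`; constant beyond its knots.}
#' }
#'
#' @param incidence,mortality,rate_ratio Named lists with `male`/`female`
#'   numeric parameter vectors (`c(b0, b1[, b2])`, `c(mu0, mu1)`,
#'   `c(g0, g1)`).
#' @param fpr_profile Named list with `male`/`female` data frames holding
#'   columns `age` and `fpr` (knots of the piecewise-linear profile).
#' @param se True sensitivity of the coded diagnoses (shared by prevalence
#'   and incidence observation).
#' @param t1,t2 The two prevalence survey years.
#' @param incidence_years Calendar window the incidence table is pooled
#'   over.
#' @param mortality_year,rate_ratio_year Reference years of the mortality
#'   and rate-ratio tables.
#' @param age_range Ages covered by the process; prevalence starts at 0 at
#'   the lower end.
#' @param prevalence_breaks,incidence_breaks Lower bounds of the age groups
#'   of the observed prevalence/incidence tables; the top group is
#'   open-ended.
#' @param population_fn Function of integer age returning the per-sex
#'   population count at that age.
#' @param incidence_drift Multiplicative trend of incidence on the log
#'   scale, per calendar year relative to `(t1 + t2) / 2` (0 = time
#'   homogeneous).
#' @param noise `"none"` for exact stratum values, `"binomial"` for
#'   binomial sampling of observed prevalence with the stratum population
#'   size.
#' @param seed Integer seed governing all randomness in the scenario.
#' @return An object of class `idm_scenario`.
#' @export
idm_scenario <- function(incidence, mortality, rate_ratio, fpr_profile,
                         se = 0.97, t1 = 2009, t2 = 2015,
                         incidence_years = c(2012, 2014),
                         mortality_year = 2012, rate_ratio_year = 2014,
                         age_range = c(0, 100),
                         prevalence_breaks = c(0, seq(15, 90, by = 5)),
                         incidence_breaks = c(0, 20, 40, 60, 80),
                         population_fn = default_population_fn,
                         incidence_drift = 0,
                         noise = c("none", "binomial"), seed = 1L) {
  noise <- match.arg(noise)
  check_proportion(se, "se", open_lo = TRUE)
  for (s in c("male", "female")) {
    prof <- fpr_profile[[s]]
    if (is.null(prof) || !all(c("age", "fpr") %in% names(prof))) {
      stop_domain(sprintf("`fpr_profile$%s` needs columns `age` and `fpr`.", s))
    }
    check_proportion(prof$fpr, "fpr")
    if (any(se + (1 - prof$fpr) <= 1)) {
      stop_domain("Scenario violates se + sp > 1.")
    }
  }
  if (t2 <= t1) stop_domain("`t2` must exceed `t1`.")
  structure(
    list(incidence = incidence, mortality = mortality,
         rate_ratio = rate_ratio, fpr_profile = fpr_profile, se = se,
         t1 = t1, t2 = t2, incidence_years = incidence_years,
         mortality_year = mortality_year, rate_ratio_year = rate_ratio_year,
         age_range = age_range, prevalence_breaks = prevalence_breaks,
         incidence_breaks = incidence_breaks, population_fn = population_fn,
         incidence_drift = incidence_drift, noise = noise,
         seed = as.integer(seed)),
    class = "idm_scenario"
  )
}

# Roughly pyramid-shaped population: flat through midlife, thinning in old
# age; two sexes together total ~70 million over ages 0-100.
default_population_fn <- function(age) {
  450000 * ifelse(age <= 60, 1, exp(-0.045 * (age - 60)))
}

# Parametric rate functions of a scenario for one sex.
scenario_rate_fns <- function(scn, sex) {
  b <- scn$incidence[[sex]]
  if (length(b) == 2) b <- c(b, 0)
  mu <- scn$mortality[[sex]]
  g <- scn$rate_ratio[[sex]]
  prof <- scn$fpr_profile[[sex]]
  list(
    i = function(a) exp(b[1] + b[2] * a + b[3] * a^2),
    m = function(a) exp(mu[1] + mu[2] * a),
    R = function(a) pmax(1, exp(g[1] + g[2] * a)),
    sp = function(a) 1 - approx(prof$age, prof$fpr, xout = a, rule = 2)$y
  )
}

# Incidence at calendar time t (only differs from the base rate when the
# scenario carries a drift).
scenario_incidence_at <- function(scn, sex, t) {
  fns <- scenario_rate_fns(scn, sex)
  t_mid <- (scn$t1 + scn$t2) / 2
  drift <- scn$incidence_drift
  function(a) fns$i(a) * exp(drift * (t - t_mid))
}

#' Ground-truth prevalence of a scenario
#'
#' Integrates the illness-death prevalence equation along characteristics
#' (ageing cohorts) with the scenario's rate functions, starting from zero
#' prevalence at the lower end of the age range.  For a time-homogeneous
#' scenario the result is a single prevalence-by-age curve per sex, valid at
#' every calendar time; with incidence drift the curve is computed for the
#' cohort observed at `year`.
#'
#' @param scn An [idm_scenario()].
#' @param year Calendar year of observation (only relevant under drift).
#' @param step Integration step in years.
#' @return A tibble with columns `sex`, `age`, `p`.
#' @export
true_prevalence <- function(scn, year = scn$t2, step = 0.1) {
  purrr::map_dfr(c("male", "female"), function(s) {
    fns <- scenario_rate_fns(scn, s)
    if (scn$incidence_drift == 0) {
      sol <- solve_prevalence(fns$i, fns$m, fns$R,
                              scn$age_range[1], scn$age_range[2],
                              p_start = 0, step = step)
    } else {
      # cohort aged a at `year` experienced incidence i(t - (a - x), x);
      # solve each target age separately along its own characteristic
      ages <- seq(scn$age_range[1], scn$age_range[2], by = 2.5)
      p <- vapply(ages, function(a) {
        if (a <= scn$age_range[1]) return(0)
        t_mid <- (scn$t1 + scn$t2) / 2
        i_coh <- function(x) fns$i(x) *
          exp(scn$incidence_drift * ((year - (a - x)) - t_mid))
        sol <- solve_prevalence(i_coh, fns$m, fns$R, scn$age_range[1], a,
                                p_start = 0, step = step)
        sol$p[nrow(sol)]
      }, numeric(1))
      sol <- tibble::tibble(age = ages, p = p)
    }
    tibble::tibble(sex = s, age = sol$age, p = sol$p)
  })
}

# Fast interpolators of the truth per sex, cached per (scenario, year).
true_prevalence_fun <- function(scn, year = scn$t2, step = 0.1) {
  tp <- true_prevalence(scn, year = year, step = step)
  lapply(stats::setNames(nm = c("male", "female")), function(s) {
    d <- tp[tp$sex == s, ]
    stats::approxfun(d$age, d$p, rule = 2)
  })
}

group_bounds <- function(breaks, top_open = TRUE, top_close = NULL) {
  tibble::tibble(
    age_lo = breaks,
    age_hi = c(breaks[-1], if (top_open) NA_real_ else top_close)
  )
}

group_population <- function(population_fn, age_lo, age_hi, max_age = 100) {
  vapply(seq_along(age_lo), function(k) {
    hi <- if (is.na(age_hi[k])) max_age else age_hi[k] - 1
    sum(population_fn(seq(age_lo[k], hi)))
  }, numeric(1))
}

#' Generate claims-style observed tables from a scenario
#'
#' Evaluates the ground truth at stratum midpoint ages, pushes prevalence
#' and incidence through the misclassification map with the scenario's true
#' `(se, sp(a))`, optionally adds binomial sampling noise to the observed
#' prevalence, and emits the four rate tables plus a population table.  The
#' answer key (true rates, prevalence, and misclassification parameters)
#' travels with the dataset; no synthetic dataset exists without it.
#'
#' @param scn An [idm_scenario()].
#' @param open_group_offset Representative-age offset of open-ended groups,
#'   matching the fitting side.
#' @return An object of class `synthetic_claims`: a list with tibbles
#'   `prevalence`, `incidence`, `mortality`, `rate_ratio`, `population` and
#'   a `truth` list (`se`, per-sex `sp`, `i`, `m`, `R`, `p` functions, and
#'   the scenario).
#' @export
simulate_claims <- function(scn, open_group_offset = 2.5) {
  if (!inherits(scn, "idm_scenario")) stop_domain("`scn` must be an idm_scenario.")
  withr::with_seed(scn$seed, {
    sexes <- c("male", "female")
    fns <- lapply(stats::setNames(nm = sexes), scenario_rate_fns, scn = scn)
    p_fun <- lapply(stats::setNames(nm = sexes), function(s) {
      lapply(stats::setNames(nm = c(scn$t1, scn$t2)), function(yr) {
        true_prevalence_fun(scn, year = as.numeric(yr))[[s]]
      })
    })

    prev_groups <- group_bounds(scn$prevalence_breaks)
    prev_mid <- ifelse(is.na(prev_groups$age_hi),
                       prev_groups$age_lo + open_group_offset,
                       (prev_groups$age_lo + prev_groups$age_hi) / 2)
    prev_pop <- group_population(scn$population_fn, prev_groups$age_lo,
                                 prev_groups$age_hi, scn$age_range[2])

    prevalence <- purrr::map_dfr(sexes, function(s) {
      purrr::map_dfr(c(scn$t1, scn$t2), function(yr) {
        p_true <- p_fun[[s]][[as.character(yr)]](prev_mid)
        sp <- fns[[s]]$sp(prev_mid)
        p_obs <- apply_misclassification(p_true, scn$se, sp)
        if (scn$noise == "binomial") {
          p_obs <- stats::rbinom(length(p_obs), size = round(prev_pop),
                                 prob = p_obs) / round(prev_pop)
        }
        tibble::tibble(sex = s, year = yr,
                       age_lo = prev_groups$age_lo,
                       age_hi = prev_groups$age_hi,
                       value = p_obs, population = prev_pop)
      })
    })

    inc_groups <- group_bounds(scn$incidence_breaks)
    inc_mid <- ifelse(is.na(inc_groups$age_hi),
                      inc_groups$age_lo + open_group_offset,
                      (inc_groups$age_lo + inc_groups$age_hi) / 2)
    inc_pop <- group_population(scn$population_fn, inc_groups$age_lo,
                                inc_groups$age_hi, scn$age_range[2])
    inc_year <- mean(scn$incidence_years)
    incidence <- purrr::map_dfr(sexes, function(s) {
      i_true <- scenario_incidence_at(scn, s, inc_year)(inc_mid)
      sp <- fns[[s]]$sp(inc_mid)
      i_obs <- apply_misclassification(i_true, scn$se, sp)
      tibble::tibble(sex = s, year = inc_year,
                     age_lo = inc_groups$age_lo, age_hi = inc_groups$age_hi,
                     value = i_obs, population = inc_pop)
    })

    mort_groups <- group_bounds(seq(15, 90, by = 5), top_open = FALSE,
                                top_close = 95)
    mort_mid <- (mort_groups$age_lo + mort_groups$age_hi) / 2
    mortality <- purrr::map_dfr(sexes, function(s) {
      tibble::tibble(sex = s, year = scn$mortality_year,
                     age_lo = mort_groups$age_lo,
                     age_hi = mort_groups$age_hi,
                     value = fns[[s]]$m(mort_mid),
                     population = group_population(
                       scn$population_fn, mort_groups$age_lo,
                       mort_groups$age_hi, scn$age_range[2]))
    })

    rr_groups <- group_bounds(seq(20, 90, by = 5), top_open = FALSE,
                              top_close = 95)
    rr_mid <- (rr_groups$age_lo + rr_groups$age_hi) / 2
    rate_ratio <- purrr::map_dfr(sexes, function(s) {
      tibble::tibble(sex = s, year = scn$rate_ratio_year,
                     age_lo = rr_groups$age_lo, age_hi = rr_groups$age_hi,
                     value = fns[[s]]$R(rr_mid), population = NA_real_)
    })

    pop_groups <- group_bounds(seq(0, 95, by = 5), top_open = FALSE,
                               top_close = 101)
    population <- purrr::map_dfr(sexes, function(s) {
      tibble::tibble(sex = s, age_lo = pop_groups$age_lo,
                     age_hi = pop_groups$age_hi,
                     count = group_population(scn$population_fn,
                                              pop_groups$age_lo,
                                              pop_groups$age_hi,
                                              scn$age_range[2]))
    })

    structure(
      list(
        prevalence = rate_table(prevalence, "prevalence"),
        incidence = rate_table(incidence, "incidence"),
        mortality = rate_table(mortality, "mortality"),
        rate_ratio = rate_table(rate_ratio, "rate_ratio"),
        population = population,
        truth = list(se = scn$se,
                     sp = lapply(fns, `[[`, "sp"),
                     i = lapply(fns, `[[`, "i"),
                     m = lapply(fns, `[[`, "m"),
                     R = lapply(fns, `[[`, "R"),
                     p = p_fun,
                     scenario = scn)
      ),
      class = "synthetic_claims"
    )
  })
}

#' A canned synthetic scenario with claims-like magnitudes
#'
#' A deterministic scenario whose rates are shaped like the epidemiology of
#' a common chronic condition in an ageing population: prevalence rising to
#' tens of percent in old age, incidence peaking at 1-2 per 100 person-years
#' around age 70, mortality rate ratio falling from about 4 in midlife to
#' about 1.5 in old age, Gompertz general mortality, and a sex-specific
#' false-positive profile (low and slowly rising in men; in women rising
#' steeply to about 12 per 1,000 near age 60 and falling thereafter).  Used
#' throughout the package's tests and documentation.
#'
#' @param seed Scenario seed.
#' @param noise `"none"` (default) or `"binomial"`.
#' @return An [idm_scenario()].
#' @export
default_scenario <- function(seed = 1L, noise = "none") {
  idm_scenario(
    incidence = list(male = c(-9.4, 0.144, -0.001),
                     female = c(-9.7, 0.144, -0.001)),
    mortality = list(male = c(-9.8, 0.090),
                     female = c(-10.3, 0.094)),
    rate_ratio = list(male = c(1.92, -0.0178),
                      female = c(2.10, -0.0190)),
    fpr_profile = list(
      male = data.frame(age = c(0, 30, 50, 80, 100),
                        fpr = c(0.0005, 0.001, 0.003, 0.004, 0.005)),
      female = data.frame(age = c(0, 30, 60, 70, 85, 100),
                          fpr = c(0.0005, 0.002, 0.012, 0.010, 0.004, 0.003))
    ),
    se = 0.97,
    noise = noise,
    seed = seed
  )
}

#' @export
print.idm_scenario <- function(x, ...) {
  cat("<idm_scenario>\n")
  cat(sprintf("  surveys: %d and %d; incidence pooled %d-%d\n",
              x$t1, x$t2, x$incidence_years[1], x$incidence_years[2]))
  cat(sprintf("  true se = %.3f; noise = %s; seed = %d\n",
              x$se, x$noise, x$seed))
  invisible(x)
}

#' @export
print.synthetic_claims <- function(x, ...) {
  cat("<synthetic_claims>\n")
  for (nm in c("prevalence", "incidence", "mortality", "rate_ratio")) {
    cat(sprintf("  %-11s %3d rows\n", nm, nrow(x[[nm]])))
  }
  cat(sprintf("  population  %3d rows (total %.1f million)\n",
              nrow(x$population), sum(x$population$count) / 1e6))
  cat("  truth: attached\n")
  invisible(x)
}
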