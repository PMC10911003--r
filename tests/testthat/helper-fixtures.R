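# Shared fixtures, built in code.

# A characteristic segment from a constant-rate illness-death process whose
# prevalence reaches `p_target` at the segment centre, observed under known
# (se, sp).  Serves as the parameter-recovery oracle for the specificity
# inversion: the generating sp is the answer key.
segment_fixture <- function(p_target, sp_true, se_true, m = 0.02, R = 2,
                            a0 = 60, a_start = 20, delta = 6) {
  i_const <- uniroot(function(i) {
    sol <- solve_prevalence(function(a) i, function(a) m, function(a) R,
                            a_start, a0, step = 0.25)
    sol$p[nrow(sol)] - p_target
  }, c(1e-6, 0.5), tol = 1e-12)$root
  sol <- solve_prevalence(function(a) i_const, function(a) m,
                          function(a) R, a_start, a0 + delta / 2,
                          step = 0.05)
  pfun <- stats::approxfun(sol$age, sol$p)
  list(
    p_obs_1 = apply_misclassification(pfun(a0 - delta / 2), se_true, sp_true),
    p_obs_2 = apply_misclassification(pfun(a0 + delta / 2), se_true, sp_true),
    i_obs = apply_misclassification(i_const, se_true, sp_true),
    m = m, R = R, delta = delta,
    i_true = i_const, p_mid = pfun(a0), sp_true = sp_true, se_true = se_true
  )
}

# The canned claims-like dataset, cached across tests within a run.
fixture_env <- new.env(parent = emptyenv())
fixture_dataset <- function() {
  if (is.null(fixture_env$ds)) {
    fixture_env$ds <- simulate_claims(default_scenario(seed = 1))
  }
  fixture_env$ds
}

fixture_config <- function(ds = fixture_dataset(), ...) {
  analysis_config(ds$prevalence, ds$incidence, ds$mortality, ds$rate_ratio,
                  ds$population, ...)
}

# A scenario with a flat false-positive profile, for recovery oracles.
flat_fpr_scenario <- function(fpr = 0.005, se = 0.97, seed = 1) {
  idm_scenario(
    incidence = list(male = c(-9.4, 0.144, -0.001),
                     female = c(-9.7, 0.144, -0.001)),
    mortality = list(male = c(-9.8, 0.090), female = c(-10.3, 0.094)),
    rate_ratio = list(male = c(1.92, -0.0178), female = c(2.10, -0.0190)),
    fpr_profile = list(male = data.frame(age = c(0, 100), fpr = fpr),
                       female = data.frame(age = c(0, 100), fpr = fpr)),
    se = se, seed = seed
  )
}

fit_all_surfaces <- function(ds, prevalence_df = 4, incidence_df = 3,
                             rate_ratio_df = 3) {
  list(
    prevalence = suppressWarnings(fit_prevalence(ds$prevalence, prevalence_df)),
    incidence = fit_incidence(ds$incidence, incidence_df),
    mortality = fit_mortality(ds$mortality),
    rate_ratio = fit_rate_ratio(ds$rate_ratio, rate_ratio_df)
  )
}

# Small synthetic prevalence table that is exactly logit-linear in age,
# with optional sex/time shifts, for fit self-consistency oracles.
logit_linear_prevalence <- function(b0 = -4, b_age = 0.05, b_time = 0.1,
                                    b_sex = 0.3, years = c(2009, 2015)) {
  grid <- expand.grid(sex = c("male", "female"), year = years,
                      age_lo = seq(20, 80, by = 5), stringsAsFactors = FALSE)
  grid$age_hi <- grid$age_lo + 5
  mid <- grid$age_lo + 2.5
  t_c <- grid$year - mean(range(years))
  eta <- b0 + b_age * mid + b_time * t_c + b_sex * (grid$sex == "female")
  grid$value <- plogis(eta)
  grid$population <- 1000
  rate_table(grid, "prevalence")
}

# Fine age strata and generous spline df: surface-level recovery oracles
# where the fitted surfaces are nearly exact representations of the truth.
fine_strata_dataset <- function(fpr, se = 0.97) {
  scn <- flat_fpr_scenario(fpr = fpr, se = se)
  scn$prevalence_breaks <- seq(16, 92, by = 2)
  scn$incidence_breaks <- seq(16, 88, by = 4)
  simulate_claims(scn)
}

fine_strata_surfaces <- function(ds) {
  list(
    prevalence = suppressWarnings(fit_prevalence(ds$prevalence, 8)),
    incidence = fit_incidence(ds$incidence, 6),
    mortality = fit_mortality(ds$mortality),
    rate_ratio = fit_rate_ratio(ds$rate_ratio, 4)
  )
}
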