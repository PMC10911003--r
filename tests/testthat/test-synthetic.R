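test_that("true prevalence obeys closed forms and monotone inflow", {
  # no incidence, no prevalence
  scn0 <- flat_fpr_scenario()
  scn0$incidence <- list(male = c(-60, 0), female = c(-60, 0))
  tp <- true_prevalence(scn0)
  expect_lt(max(tp$p), 1e-15)

  # R = 1, constant incidence: 1 - exp(-i (a - a0))
  scn1 <- flat_fpr_scenario()
  scn1$incidence <- list(male = c(log(0.01), 0), female = c(log(0.01), 0))
  scn1$rate_ratio <- list(male = c(0, 0), female = c(0, 0))
  scn1$age_range <- c(20, 80)
  tp1 <- true_prevalence(scn1)
  p70 <- tp1$p[tp1$sex == "male" & tp1$age == 70]
  expect_equal(p70, 1 - exp(-0.5), tolerance = 1e-8)
})

test_that("stronger excess mortality depletes prevalence pointwise", {
  lo <- flat_fpr_scenario()
  hi <- flat_fpr_scenario()
  lo$rate_ratio <- list(male = c(log(1.5), 0), female = c(log(1.5), 0))
  hi$rate_ratio <- list(male = c(log(4), 0), female = c(log(4), 0))
  p_lo <- true_prevalence(lo)
  p_hi <- true_prevalence(hi)
  keep <- p_lo$age > 30
  expect_true(all(p_hi$p[keep] < p_lo$p[keep]))
})

test_that("a perfect test observes the truth exactly at midpoints", {
  scn <- flat_fpr_scenario()
  scn$se <- 1
  scn$fpr_profile <- list(male = data.frame(age = c(0, 100), fpr = 0),
                          female = data.frame(age = c(0, 100), fpr = 0))
  ds <- simulate_claims(scn)
  m <- midpoint_ages(ds$prevalence)
  truth <- mapply(function(s, yr, a) ds$truth$p[[s]][[as.character(yr)]](a),
                  m$sex, m$year, m$age_mid)
  expect_equal(m$value, unname(truth), tolerance = 1e-12)
  mi <- midpoint_ages(ds$incidence)
  truth_i <- mapply(function(s, a) ds$truth$i[[s]](a), mi$sex, mi$age_mid)
  expect_equal(mi$value, unname(truth_i), tolerance = 1e-12)
})

test_that("observed prevalence floors at the false-positive ratio", {
  scn <- flat_fpr_scenario(fpr = 0.01)
  # essentially no true disease at any age
  scn$incidence <- list(male = c(-60, 0), female = c(-60, 0))
  ds <- simulate_claims(scn)
  expect_equal(ds$prevalence$value, rep(0.01, nrow(ds$prevalence)),
               tolerance = 1e-10)
})

test_that("the time-homogeneous truth is identical at both survey years", {
  ds <- fixture_dataset()
  a <- seq(10, 90, by = 5)
  expect_equal(ds$truth$p$male[["2009"]](a), ds$truth$p$male[["2015"]](a))
  p1 <- ds$prevalence$value[ds$prevalence$year == 2009]
  p2 <- ds$prevalence$value[ds$prevalence$year == 2015]
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("incidence drift moves the surveys apart", {
  scn <- flat_fpr_scenario()
  scn$incidence_drift <- 0.02
  ds <- simulate_claims(scn)
  p1 <- ds$prevalence$value[ds$prevalence$year == 2009 &
                              ds$prevalence$age_lo >= 40]
  p2 <- ds$prevalence$value[ds$prevalence$year == 2015 &
                              ds$prevalence$age_lo >= 40]
  expect_true(all(p2 > p1))
})

test_that("binomial noise stays within sampling bounds of the exact values", {
  scn_exact <- default_scenario(seed = 3)
  scn_noisy <- default_scenario(seed = 3, noise = "binomial")
  exact <- simulate_claims(scn_exact)$prevalence
  noisy <- simulate_claims(scn_noisy)$prevalence
  se_bin <- sqrt(exact$value * (1 - exact$value) / exact$population)
  z <- abs(noisy$value - exact$value) / pmax(se_bin, 1e-12)
  # 4-standard-error bound holds for the vast majority of strata
  expect_gte(mean(z <= 4), 0.98)
})

test_that("identical seeds reproduce identical datasets", {
  d1 <- simulate_claims(default_scenario(seed = 9, noise = "binomial"))
  d2 <- simulate_claims(default_scenario(seed = 9, noise = "binomial"))
  expect_identical(d1$prevalence, d2$prevalence)
  expect_identical(d1$incidence, d2$incidence)
})

test_that("the canned fixture has claims-like magnitudes and valid tables", {
  ds <- fixture_dataset()
  old <- midpoint_ages(ds$prevalence)
  old <- old[old$age_mid >= 70 & old$year == 2015, ]
  expect_true(all(old$value > 0.1 & old$value < 0.4))
  # tables re-validate cleanly
  for (nm in c("prevalence", "incidence", "mortality", "rate_ratio")) {
    expect_silent(rate_table(as.data.frame(ds[[nm]]),
                             attr(ds[[nm]], "quantity")))
  }
  # ground truth always travels with the data
  expect_true(all(c("se", "sp", "p", "i", "m", "R") %in% names(ds$truth)))
})

test_that("scenario validation rejects inconsistent misclassification", {
  expect_error(
    idm_scenario(
      incidence = list(male = c(-9, 0.1), female = c(-9, 0.1)),
      mortality = list(male = c(-10, 0.09), female = c(-10, 0.09)),
      rate_ratio = list(male = c(1, -0.01), female = c(1, -0.01)),
      fpr_profile = list(male = data.frame(age = c(0, 100), fpr = 0.8),
                         female = data.frame(age = c(0, 100), fpr = 0.8)),
      se = 0.1
    ),
    class = "fpclaims_domain_error"
  )
})
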