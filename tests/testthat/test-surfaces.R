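test_that("midpoint ages follow the group rules", {
  tbl <- rate_table(data.frame(
    sex = "male", year = 2009,
    age_lo = c(0, 80, 90), age_hi = c(15, 85, NA),
    value = c(0.01, 0.2, 0.25)
  ), "prevalence")
  m <- midpoint_ages(tbl)
  expect_equal(m$age_mid, c(7.5, 82.5, 92.5))
})

test_that("rate tables are validated", {
  base <- data.frame(sex = "male", year = 2009, age_lo = 40, age_hi = 45,
                     value = 0.1)
  expect_s3_class(rate_table(base, "prevalence"), "tbl_df")
  expect_error(rate_table(base[-5], "prevalence"), "value",
               class = "fpclaims_domain_error")
  expect_error(rate_table(rbind(base, base), "prevalence"), "Duplicate",
               class = "fpclaims_domain_error")
  bad <- base; bad$value <- 1.5
  expect_error(rate_table(bad, "prevalence"),
               class = "fpclaims_domain_error")
  bad <- base; bad$value <- -0.1
  expect_error(rate_table(bad, "incidence"),
               class = "fpclaims_domain_error")
})

test_that("prevalence fit reproduces an exactly representable surface", {
  tbl <- logit_linear_prevalence()
  surf <- fit_prevalence(tbl, spline_df = 3)
  m <- midpoint_ages(tbl)
  fitted <- predict(surf, age = m$age_mid, sex = m$sex, year = m$year)
  expect_equal(fitted, m$value, tolerance = 1e-8)
  # idempotence: refitting data sampled from the fitted surface changes
  # nothing at the sample points
  tbl2 <- tbl
  tbl2$value <- fitted
  surf2 <- fit_prevalence(rate_table(tbl2, "prevalence"), spline_df = 3)
  expect_equal(predict(surf2, age = m$age_mid, sex = m$sex, year = m$year),
               fitted, tolerance = 1e-8)
})

test_that("symmetric input data yield zero sex and time effects", {
  tbl <- logit_linear_prevalence(b_time = 0, b_sex = 0)
  surf <- fit_prevalence(tbl, spline_df = 3)
  cf <- tidy(surf)
  null_terms <- grepl("time|sex", cf$term)
  expect_true(any(null_terms))
  expect_lt(max(abs(cf$estimate[null_terms])), 1e-10)
})

test_that("fitting is invariant to row order", {
  tbl <- logit_linear_prevalence()
  surf1 <- fit_prevalence(tbl, spline_df = 3)
  shuffled <- rate_table(tbl[withr::with_seed(5, sample(nrow(tbl))), ],
                         "prevalence")
  surf2 <- fit_prevalence(shuffled, spline_df = 3)
  a <- seq(25, 80, by = 5)
  expect_equal(predict(surf1, a, "female", 2015),
               predict(surf2, a, "female", 2015), tolerance = 1e-10)
})

test_that("degenerate proportions are excluded with a warning and counted", {
  tbl <- logit_linear_prevalence()
  tbl$value[1] <- 0
  expect_warning(
    surf <- fit_prevalence(rate_table(tbl, "prevalence"), spline_df = 3),
    class = "fpclaims_excluded_rows"
  )
  expect_equal(surf$excluded, 1L)
})

test_that("incidence fit recovers a log-linear truth and flags extrapolation", {
  grid <- expand.grid(sex = c("male", "female"), year = 2013,
                      age_lo = seq(20, 70, by = 10),
                      stringsAsFactors = FALSE)
  grid$age_hi <- grid$age_lo + 10
  mid <- grid$age_lo + 5
  grid$value <- exp(-9 + 0.06 * mid + 0.2 * (grid$sex == "female"))
  tbl <- rate_table(grid, "incidence")
  surf <- fit_incidence(tbl, spline_df = 2)
  expect_equal(predict(surf, mid, grid$sex), grid$value, tolerance = 1e-8)
  ev <- evaluate_surface(surf, age = c(50, 95), sex = "male")
  expect_equal(ev$extrapolated, c(FALSE, TRUE))
  expect_error(predict(surf, 95, "male", allow_extrapolation = FALSE),
               class = "fpclaims_domain_error")
})

test_that("intercept-only incidence fit returns the geometric mean", {
  tbl <- rate_table(data.frame(
    sex = rep("male", 3), year = c(2012, 2013, 2014),
    age_lo = 40, age_hi = 60, value = c(0.01, 0.02, 0.04)
  ), "incidence")
  surf <- fit_incidence(tbl, spline_df = 0)
  expect_equal(predict(surf, 50, "male"), exp(mean(log(c(0.01, 0.02, 0.04)))),
               tolerance = 1e-10)
})

test_that("mortality fit is exact for quadratic log-rates and nests Gompertz", {
  grid <- expand.grid(sex = c("male", "female"), year = 2012,
                      age_lo = seq(15, 90, by = 5), stringsAsFactors = FALSE)
  grid$age_hi <- grid$age_lo + 5
  mid <- grid$age_lo + 2.5
  # pure Gompertz: log m linear in age
  grid$value <- exp(-10 + 0.09 * mid + 0.3 * (grid$sex == "female"))
  surf <- fit_mortality(rate_table(grid, "mortality"))
  cf <- tidy(surf)
  expect_lt(max(abs(cf$estimate[grepl("age\\^2", cf$term)])), 1e-12)
  expect_equal(predict(surf, mid, grid$sex), grid$value, tolerance = 1e-8)
  # exact quadratic: zero residual sum of squares
  grid$value <- exp(-11 + 0.12 * mid - 3e-4 * mid^2)
  surf2 <- fit_mortality(rate_table(grid, "mortality"))
  expect_lt(suppressWarnings(glance(surf2))$rss, 1e-16)
  # identical sexes: interaction terms vanish
  inter <- grepl("sex", tidy(surf2)$term)
  expect_lt(max(abs(tidy(surf2)$estimate[inter])), 1e-10)
})

test_that("mortality fit requires enough distinct ages per sex", {
  tbl <- rate_table(data.frame(
    sex = rep(c("male", "female"), each = 2), year = 2012,
    age_lo = c(40, 50, 40, 50), age_hi = c(45, 55, 45, 55),
    value = 0.01
  ), "mortality")
  expect_error(fit_mortality(tbl), class = "fpclaims_domain_error")
})

test_that("rate-ratio fit recovers log-linear truth and the null ratio", {
  grid <- expand.grid(sex = c("male", "female"), year = 2014,
                      age_lo = seq(20, 80, by = 10),
                      stringsAsFactors = FALSE)
  grid$age_hi <- grid$age_lo + 10
  mid <- grid$age_lo + 5
  grid$value <- exp(1.6 - 0.015 * mid - 0.1 * (grid$sex == "female"))
  surf <- fit_rate_ratio(rate_table(grid, "rate_ratio"), spline_df = 2)
  expect_equal(predict(surf, mid, grid$sex), grid$value, tolerance = 1e-8)
  grid$value <- 1
  surf1 <- fit_rate_ratio(rate_table(grid, "rate_ratio"), spline_df = 2)
  expect_lt(max(abs(tidy(surf1)$estimate)), 1e-12)
  expect_equal(predict(surf1, c(33, 57, 71), "female"), rep(1, 3),
               tolerance = 1e-10)
})

test_that("back-transformed evaluations respect the natural domain", {
  ds <- fixture_dataset()
  surfaces <- fit_all_surfaces(ds)
  a <- seq(20, 95, by = 1.5)
  for (s in c("male", "female")) {
    p <- predict(surfaces$prevalence, a, s, year = 2015)
    expect_true(all(p > 0 & p < 1))
    expect_true(all(predict(surfaces$incidence, a, s) > 0))
    expect_true(all(predict(surfaces$mortality, pmin(a, 95), s) > 0))
    expect_true(all(predict(surfaces$rate_ratio, a, s) > 0))
  }
})

test_that("the spline surface continues linearly beyond the boundary knots", {
  ds <- fixture_dataset()
  surf <- fit_incidence(ds$incidence, spline_df = 3)
  # log-scale second differences vanish outside the data's age span
  a <- seq(86, 98, by = 1)
  eta <- log(predict(surf, a, "male"))
  second_diff <- diff(diff(eta))
  expect_lt(max(abs(second_diff)), 1e-10)
})

test_that("increasing spline df never increases the residual sum of squares", {
  ds <- fixture_dataset()
  rss <- vapply(2:6, function(df) {
    glance(fit_prevalence(ds$prevalence, spline_df = df))$rss
  }, numeric(1))
  expect_true(all(diff(rss) <= 1e-10))
})

test_that("an over-parameterised design fails loudly", {
  ds <- fixture_dataset()
  suppressWarnings(
    expect_error(fit_incidence(ds$incidence, spline_df = 10),
                 class = "fpclaims_domain_error")
  )
})

test_that("surface accessors summarise the fit", {
  ds <- fixture_dataset()
  surf <- fit_mortality(ds$mortality)
  g <- suppressWarnings(glance(surf))
  expect_equal(g$quantity, "mortality")
  expect_equal(g$nobs, nrow(ds$mortality))
  expect_true(all(c("term", "estimate") %in% names(tidy(surf))))
  expect_s3_class(autoplot(surf, ds$mortality), "ggplot")
})
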