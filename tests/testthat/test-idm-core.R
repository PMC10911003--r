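test_that("pde_rhs matches direct arithmetic and limiting cases", {
  # R = 1 removes the excess-mortality term
  expect_equal(pde_rhs(p = 0.10, i = 0.01, m = 0.02, R = 1), 0.009)
  # p = 0 leaves only the incidence inflow
  expect_equal(pde_rhs(p = 0, i = 0.01, m = 0.5, R = 3), 0.01)
  # general case: 0.009 - 0.02 * 0.1 * 1 / 1.1
  expect_equal(pde_rhs(p = 0.10, i = 0.01, m = 0.02, R = 2),
               0.009 - 0.02 * 0.1 * 1 / 1.1, tolerance = 1e-12)
})

test_that("pde_rhs rejects out-of-domain states naming the field", {
  expect_error(pde_rhs(p = 1.2, i = 0.01, m = 0.02, R = 1), "`p`",
               class = "fpclaims_domain_error")
  expect_error(pde_rhs(p = 0.1, i = 0.01, m = 0.02, R = -1), "`R`",
               class = "fpclaims_domain_error")
  expect_error(pde_rhs(p = 0.1, i = -0.01, m = 0.02, R = 1), "`i`",
               class = "fpclaims_domain_error")
})

test_that("pde_rhs is increasing in i and decreasing in R", {
  p <- c(0.05, 0.3, 0.8)
  expect_true(all(pde_rhs(p, 0.02, 0.05, 2) > pde_rhs(p, 0.01, 0.05, 2)))
  expect_true(all(pde_rhs(p, 0.01, 0.05, 3) < pde_rhs(p, 0.01, 0.05, 2)))
})

test_that("misclassification forward map matches arithmetic and limits", {
  expect_equal(apply_misclassification(0.2, se = 0.9, sp = 0.95), 0.22)
  # truth absent: observed value is the false-positive ratio
  expect_equal(apply_misclassification(0, se = 0.8, sp = 0.99), 0.01)
  # truth universal: observed value is the sensitivity
  expect_equal(apply_misclassification(1, se = 0.8, sp = 0.99), 0.8)
})

test_that("prevalence correction inverts the forward map", {
  expect_equal(correct_prevalence(0.1, se = 1, sp = 1), 0.1)
  expect_equal(correct_prevalence(0.22, se = 0.9, sp = 0.95), 0.2)
  err <- expect_error(correct_prevalence(0.01, se = 0.9, sp = 0.95),
                      class = "fpclaims_inconsistency_error")
  expect_lt(err$raw, 0)
})

test_that("incidence correction follows the printed proportion-style formula", {
  expect_equal(correct_incidence(0.005, se = 1, sp = 1), 0.005)
  expect_equal(correct_incidence(0.014, se = 1, sp = 0.99),
               (0.014 - 0.01) / 0.99, tolerance = 1e-12)
  expect_error(correct_incidence(0.001, se = 0.9, sp = 0.99),
               class = "fpclaims_inconsistency_error")
})

test_that("correction round trip is the identity across randomized inputs", {
  withr::with_seed(11, {
    for (k in 1:200) {
      x <- runif(1)
      se <- runif(1, 0.55, 1)
      sp <- runif(1, 1 - (se - 0.5), 1)
      x_back <- correct_prevalence(apply_misclassification(x, se, sp), se, sp)
      expect_equal(x_back, x, tolerance = 1e-12)
    }
  })
})

test_that("misclassification parameters must be identifiable", {
  expect_error(apply_misclassification(0.2, se = 0.4, sp = 0.5),
               class = "fpclaims_domain_error")
  expect_error(correct_prevalence(0.2, se = 0, sp = 1),
               class = "fpclaims_domain_error")
})

test_that("residual is zero at the generating specificity and changes sign", {
  sg <- segment_fixture(0.1, sp_true = 0.99, se_true = 0.9)
  r_at <- function(sp) {
    pde_residual(sp, sg$p_obs_1, sg$p_obs_2, sg$i_obs, sg$m, sg$R,
                 se = sg$se_true, delta = sg$delta)
  }
  # near-zero at the truth (residual scale is ~i, per year)
  expect_lt(abs(r_at(0.99)), 1e-5)
  # consistent signs either side of the root, on the admissible sp range
  sp_lo <- max(1 - min(sg$p_obs_1, sg$p_obs_2), 1 - sg$se_true,
               1 - sg$i_obs) + 1e-6
  above <- seq(0.9905, 0.9995, by = 5e-4)
  below <- seq(sp_lo, 0.9895, by = 5e-4)
  r_above <- r_at(above)
  r_below <- r_at(below)
  expect_true(all(sign(r_above) == sign(r_above[1])))
  expect_true(all(sign(r_below) == sign(r_below[1])))
  expect_true(sign(r_above[1]) != sign(r_below[1]))
})

test_that("a perfectly observed stationary segment leaves minus the rhs", {
  # constant observed prevalence, se = sp = 1: directional derivative 0
  r <- pde_residual(1, p_obs_1 = 0.2, p_obs_2 = 0.2, i_obs_mid = 0.01,
                    m_mid = 0.03, R_mid = 2, se = 1, delta = 6)
  expect_equal(r, -pde_rhs(0.2, 0.01, 0.03, 2), tolerance = 1e-12)
})

test_that("specificity inversion recovers the generating value", {
  sg <- segment_fixture(0.1, sp_true = 0.99, se_true = 0.9)
  est <- estimate_specificity(sg$p_obs_1, sg$p_obs_2, sg$i_obs, sg$m, sg$R,
                              se = 0.9, delta = 6)
  expect_false(est$clipped)
  expect_equal(est$sp, 0.99, tolerance = 1e-4)
  expect_equal(est$fpr, 1 - est$sp)
})

test_that("the root agrees with a dense-grid scan of the residual", {
  sg <- segment_fixture(0.15, sp_true = 0.985, se_true = 0.85)
  est <- estimate_specificity(sg$p_obs_1, sg$p_obs_2, sg$i_obs, sg$m, sg$R,
                              se = 0.85, delta = 6)
  sp_lo <- max(1 - min(sg$p_obs_1, sg$p_obs_2), 0.15, 1 - sg$i_obs) + 1e-6
  grid <- seq(max(sp_lo, 0.97), 0.9999, by = 1e-5)
  r <- abs(pde_residual(grid, sg$p_obs_1, sg$p_obs_2, sg$i_obs, sg$m, sg$R,
                        se = 0.85, delta = 6))
  expect_lt(abs(est$sp - grid[which.min(r)]), 2e-5)
})

test_that("perfect specificity is recovered at or clipped to the boundary", {
  sg <- segment_fixture(0.1, sp_true = 1, se_true = 0.95)
  est <- estimate_specificity(sg$p_obs_1, sg$p_obs_2, sg$i_obs, sg$m, sg$R,
                              se = 0.95, delta = 6)
  expect_true(est$sp >= 0.9999 || (est$clipped && est$sp == 1))
})

test_that("a degenerate bracket raises a domain error", {
  expect_error(
    estimate_specificity(1, 0.5, 0.01, 0.02, 2, se = 0.9, delta = 6),
    class = "fpclaims_domain_error"
  )
})

test_that("mis-specified sensitivity barely moves the estimate at moderate prevalence", {
  sg <- segment_fixture(0.1, sp_true = 0.99, se_true = 0.98)
  sps <- vapply(seq(0.5, 0.999, length.out = 40), function(se) {
    estimate_specificity(sg$p_obs_1, sg$p_obs_2, sg$i_obs, sg$m, sg$R,
                         se = se, delta = 6)$sp
  }, numeric(1))
  expect_lt(max(abs(sps - 0.99)), 1e-3)
})

test_that("forward solver reproduces the exponential closed form when R = 1", {
  sol <- solve_prevalence(function(a) 0.01, function(a) 0.05,
                          function(a) 1, 20, 70, p_start = 0, step = 0.1)
  expect_lt(max(abs(sol$p - (1 - exp(-0.01 * (sol$age - 20))))), 1e-8)
})

test_that("forward solver returns zero prevalence without inflow", {
  sol <- solve_prevalence(function(a) 0, function(a) 0.1,
                          function(a) 3, 0, 90, p_start = 0)
  expect_true(all(sol$p == 0))
})

test_that("forward solver converges at fourth order under step halving", {
  i_fn <- function(a) 0.001 * exp(0.04 * a)
  m_fn <- function(a) exp(-10 + 0.09 * a)
  R_fn <- function(a) 1.5 + 1 / (1 + exp((a - 60) / 10))
  p_at <- function(h) {
    sol <- solve_prevalence(i_fn, m_fn, R_fn, 20, 80, step = h)
    sol$p[nrow(sol)]
  }
  e1 <- abs(p_at(0.4) - p_at(0.05))
  e2 <- abs(p_at(0.2) - p_at(0.05))
  # halving the step should shrink the error by about 2^4
  expect_lt(e2, e1 / 8)
  expect_lt(abs(p_at(0.1) - p_at(0.05)), 1e-9)
})

test_that("forward solver rejects negative rates", {
  expect_error(
    solve_prevalence(function(a) -0.01, function(a) 0.05, function(a) 1,
                     20, 30),
    class = "fpclaims_domain_error"
  )
})
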