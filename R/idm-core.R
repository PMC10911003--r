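#' Temporal change of prevalence in the illness-death model
#'
#' Right-hand side of the prevalence equation of the illness-death model for
#' an irreversible chronic condition.  Along a characteristic line (one birth
#' cohort ageing through calendar time) the age-specific prevalence `p`
#' changes at rate
#' \deqn{(1 - p)\,i - m \, \frac{p (R - 1)}{1 + p (R - 1)},}
#' where `i` is the incidence rate among the non-diseased, `m` the all-cause
#' (general) mortality of the whole population and `R` the mortality rate
#' ratio of diseased versus non-diseased people.  The second term is the
#' depletion of prevalent cases through excess mortality; it vanishes when
#' `R = 1`.
#'
#' All arguments are vectorised and recycled to a common length.
#'
#' @param p True prevalence, a proportion in `[0, 1]`.
#' @param i Incidence rate (per person-year), `>= 0`.
#' @param m General (all-cause) mortality rate (per person-year), `>= 0`.
#' @param R Mortality rate ratio diseased/non-diseased, `> 0`.
#'
#' @return Temporal change of prevalence (per year), same length as the
#'   recycled inputs.
#'
#' @examples
#' pde_rhs(p = 0.10, i = 0.01, m = 0.02, R = 2)
#' @export
pde_rhs <- function(p, i, m, R) {
  check_proportion(p, "p")
  check_nonnegative(i, "i")
  check_nonnegative(m, "m")
  check_positive(R, "R")
  pde_rhs_unchecked(p, i, m, R)
}

# Hot path used inside root finding; callers guarantee the domain.
pde_rhs_unchecked <- function(p, i, m, R) {
  (1 - p) * i - m * p * (R - 1) / (1 + p * (R - 1))
}

#' Misclassify a true proportion or rate
#'
#' Forward map from a true proportion (or rate treated like one) to the value
#' observed under imperfect sensitivity and specificity:
#' `x_obs = se * x + (1 - sp) * (1 - x)`.  This is the algebraic inverse of
#' [correct_prevalence()]; composing the two is the identity.  The
#' synthetic-data generator uses it to produce claims-style observed tables.
#'
#' @param x True value, in `[0, 1]`.
#' @param se Sensitivity, in `(0, 1]`.
#' @param sp Specificity, in `(0, 1]`; `se + sp > 1` is required.
#'
#' @return Observed value.
#' @examples
#' apply_misclassification(0.2, se = 0.9, sp = 0.95) # 0.22
#' @export
apply_misclassification <- function(x, se, sp) {
  check_misclass(se, sp)
  check_proportion(x, "x")
  se * x + (1 - sp) * (1 - x)
}

#' Correct an observed prevalence for misclassification
#'
#' Adjusts an observed (coded) prevalence for imperfect sensitivity and
#' specificity, the classical correction for a misclassified proportion:
#' `p = (p_obs - 1 + sp) / (se + sp - 1)`.
#'
#' An observed prevalence below the false-positive floor `1 - sp` (or above
#' `se`) is arithmetically incompatible with the claimed test accuracy; the
#' function then raises an inconsistency error carrying the raw corrected
#' value in its condition data (field `raw`).
#'
#' @inheritParams apply_misclassification
#' @param p_obs Observed prevalence, in `[0, 1]`.
#' @return Corrected (true) prevalence in `[0, 1]`.
#' @examples
#' correct_prevalence(0.22, se = 0.9, sp = 0.95) # 0.2
#' @export
correct_prevalence <- function(p_obs, se, sp) {
  check_misclass(se, sp)
  check_proportion(p_obs, "p_obs")
  raw <- (p_obs - 1 + sp) / (se + sp - 1)
  if (any(raw < -BOUND_TOL | raw > 1 + BOUND_TOL)) {
    bad <- raw[raw < -BOUND_TOL | raw > 1 + BOUND_TOL][1]
    stop_inconsistency(
      sprintf(paste0(
        "Observed prevalence is incompatible with se/sp: corrected value ",
        "%.6g lies outside [0, 1]."), bad),
      raw = bad
    )
  }
  pmin(pmax(raw, 0), 1)
}

#' Correct an observed incidence rate for misclassification
#'
#' Applies the proportion-style misclassification correction to an observed
#' incidence rate: `i = (i_obs - 1 + sp) / (se + sp - 1)`.  A negative
#' corrected rate raises an inconsistency error (condition field `raw`).
#'
#' @inheritParams apply_misclassification
#' @param i_obs Observed incidence rate (per person-year), `>= 0`.
#' @return Corrected incidence rate, `>= 0`.
#' @examples
#' correct_incidence(0.014, se = 1, sp = 0.99)
#' @export
correct_incidence <- function(i_obs, se, sp) {
  check_misclass(se, sp)
  check_nonnegative(i_obs, "i_obs")
  raw <- (i_obs - 1 + sp) / (se + sp - 1)
  if (any(raw < -BOUND_TOL)) {
    bad <- raw[raw < -BOUND_TOL][1]
    stop_inconsistency(
      sprintf(paste0(
        "Observed incidence is incompatible with se/sp: corrected rate ",
        "%.6g is negative."), bad),
      raw = bad
    )
  }
  pmax(raw, 0)
}

#' Discretised prevalence-equation residual as a function of specificity
#'
#' The inversion workhorse.  A characteristic segment connects the two
#' prevalence surveys: observed prevalence `p_obs_1` at `(t1, a - delta/2)`
#' and `p_obs_2` at `(t2, a + delta/2)` with `delta = t2 - t1`.  For a
#' candidate specificity `sp` (and assumed sensitivity `se`) both endpoint
#' prevalences and the midpoint incidence are corrected for
#' misclassification, and the residual is the mismatch between the discrete
#' directional derivative and the model right-hand side evaluated at the
#' segment midpoint:
#' \deqn{\frac{p_2^{c} - p_1^{c}}{\delta} -
#'   \mathrm{rhs}(\bar p, i^{c}, m, R).}
#' The prevalence entering the right-hand side is, by default, the mean of
#' the two corrected endpoint prevalences (`prevalence_rhs =
#' "midpoint_mean"`); alternatively a separately observed midpoint prevalence
#' can be corrected and used (`"midpoint_obs"`, requires `p_obs_mid`).
#'
#' The true specificity of the coded diagnoses is the root of this residual;
#' see [estimate_specificity()].
#'
#' Vectorised over `sp` (and `se`).
#'
#' @param sp Candidate specificity (or vector of candidates).
#' @param p_obs_1,p_obs_2 Observed prevalences at the segment endpoints.
#' @param i_obs_mid Observed incidence rate at the segment midpoint.
#' @param m_mid General mortality at the segment midpoint.
#' @param R_mid Mortality rate ratio at the segment midpoint.
#' @param se Assumed sensitivity.
#' @param delta Segment length in years (`t2 - t1`).
#' @param prevalence_rhs Which prevalence to use in the right-hand side.
#' @param p_obs_mid Observed midpoint prevalence, only for
#'   `prevalence_rhs = "midpoint_obs"`.
#'
#' @return Residual (per year), same length as `sp`.
#' @export
pde_residual <- function(sp, p_obs_1, p_obs_2, i_obs_mid, m_mid, R_mid, se,
                         delta,
                         prevalence_rhs = c("midpoint_mean", "midpoint_obs"),
                         p_obs_mid = NULL) {
  prevalence_rhs <- match.arg(prevalence_rhs)
  check_misclass(se, sp)
  check_proportion(p_obs_1, "p_obs_1")
  check_proportion(p_obs_2, "p_obs_2")
  check_nonnegative(i_obs_mid, "i_obs_mid")
  check_nonnegative(m_mid, "m_mid")
  check_positive(R_mid, "R_mid")
  check_positive(delta, "delta")

  p1c <- correct_prevalence(p_obs_1, se, sp)
  p2c <- correct_prevalence(p_obs_2, se, sp)
  ic <- correct_incidence(i_obs_mid, se, sp)
  p_rhs <- if (prevalence_rhs == "midpoint_mean") {
    (p1c + p2c) / 2
  } else {
    if (is.null(p_obs_mid)) {
      stop_domain("`p_obs_mid` is required when prevalence_rhs = \"midpoint_obs\".")
    }
    correct_prevalence(p_obs_mid, se, sp)
  }
  (p2c - p1c) / delta - pde_rhs_unchecked(p_rhs, ic, m_mid, R_mid)
}

# Residual without domain checks or clamping, for vectorised bisection where
# the bracket construction already guarantees validity.
pde_residual_unchecked <- function(sp, p_obs_1, p_obs_2, i_obs_mid, m_mid,
                                   R_mid, se, delta,
                                   prevalence_rhs = "midpoint_mean",
                                   p_obs_mid = NULL) {
  den <- se + sp - 1
  p1c <- (p_obs_1 - 1 + sp) / den
  p2c <- (p_obs_2 - 1 + sp) / den
  ic <- (i_obs_mid - 1 + sp) / den
  p_rhs <- if (prevalence_rhs == "midpoint_mean") {
    (p1c + p2c) / 2
  } else {
    (p_obs_mid - 1 + sp) / den
  }
  (p2c - p1c) / delta - pde_rhs_unchecked(p_rhs, ic, m_mid, R_mid)
}

# Admissible lower bracket endpoint for the specificity root: corrected
# prevalences and corrected incidence must be non-negative and se + sp > 1.
sp_bracket_lo <- function(p_obs_1, p_obs_2, i_obs_mid, se, eps = 1e-9) {
  pmax(1 - pmin(p_obs_1, p_obs_2), 1 - se, 1 - i_obs_mid) + eps
}

#' Estimate specificity by inverting the prevalence equation
#'
#' Solves for the specificity `sp` that makes the observed prevalence change
#' along a characteristic segment consistent with the illness-death model,
#' given an assumed sensitivity — the functional relation
#' `sp = Phi(se, p_obs, i_obs, m, R)`.  The root of [pde_residual()] is
#' located by a bracketing root finder on the admissible interval
#' `[max(1 - min(p_obs), 1 - se, 1 - i_obs) + eps, 1]` (all corrected
#' quantities stay in their domains there).
#'
#' If the residual does not change sign on the bracket the bracket endpoint
#' with the smaller absolute residual is returned and the estimate is
#' flagged as boundary-clipped rather than silently passed on.
#'
#' @inheritParams pde_residual
#' @param tol Convergence tolerance on `sp` for the root finder.
#' @param eps Interior offset of the bracket's lower endpoint.
#'
#' @return A one-row tibble with columns `sp`, `fpr` (`= 1 - sp`),
#'   `clipped` (logical), and `residual` (residual at the returned `sp`).
#'
#' @examples
#' # A time-homogeneous truth observed with se = 0.95, sp = 0.99:
#' sol <- solve_prevalence(function(a) 0.01, function(a) 0.02,
#'                         function(a) 2, 20, 80, step = 0.1)
#' p <- function(a) approx(sol$age, sol$p, a)$y
#' est <- estimate_specificity(
#'   p_obs_1 = apply_misclassification(p(57), 0.95, 0.99),
#'   p_obs_2 = apply_misclassification(p(63), 0.95, 0.99),
#'   i_obs_mid = apply_misclassification(0.01, 0.95, 0.99),
#'   m_mid = 0.02, R_mid = 2, se = 0.95, delta = 6
#' )
#' est$sp
#' @export
estimate_specificity <- function(p_obs_1, p_obs_2, i_obs_mid, m_mid, R_mid,
                                 se, delta, tol = 1e-10, eps = 1e-9,
                                 prevalence_rhs = c("midpoint_mean",
                                                    "midpoint_obs"),
                                 p_obs_mid = NULL) {
  prevalence_rhs <- match.arg(prevalence_rhs)
  check_proportion(p_obs_1, "p_obs_1")
  check_proportion(p_obs_2, "p_obs_2")
  if (p_obs_1 >= 1 || p_obs_2 >= 1) {
    stop_domain("Observed prevalence at 1 leaves no admissible specificity bracket.")
  }
  lo <- sp_bracket_lo(p_obs_1, p_obs_2, i_obs_mid, se, eps)
  if (lo >= 1) {
    stop_domain(sprintf(
      "Empty specificity bracket: lower admissible endpoint %.6g >= 1.", lo))
  }
  f <- function(sp) {
    pde_residual_unchecked(sp, p_obs_1, p_obs_2, i_obs_mid, m_mid, R_mid,
                           se, delta, prevalence_rhs, p_obs_mid)
  }
  f_lo <- f(lo)
  f_hi <- f(1)
  if (is.finite(f_lo) && is.finite(f_hi) && sign(f_lo) * sign(f_hi) <= 0) {
    root <- uniroot(f, lower = lo, upper = 1, f.lower = f_lo, f.upper = f_hi,
                    tol = tol)
    sp_hat <- root$root
    clipped <- FALSE
  } else {
    sp_hat <- if (abs(f_lo) < abs(f_hi)) lo else 1
    clipped <- TRUE
  }
  tibble::tibble(sp = sp_hat, fpr = 1 - sp_hat, clipped = clipped,
                 residual = f(sp_hat))
}

#' Integrate prevalence along a characteristic line
#'
#' Solves `dp/da = pde_rhs(p, i(a), m(a), R(a))` with a classical fixed-step
#' fourth-order Runge-Kutta scheme, for time-homogeneous rate functions.
#' Used by the synthetic-data generator to build ground-truth prevalence and
#' as a numerical oracle for the inversion routines.
#'
#' @param i_fn,m_fn,R_fn Vectorised functions of age returning incidence,
#'   general mortality and mortality rate ratio; rates must be non-negative
#'   (`R_fn > 0`).
#' @param a_start,a_end Age interval (`a_end > a_start`), years.
#' @param p_start Initial prevalence at `a_start`.
#' @param step Step size in years (default 0.1).
#'
#' @return A tibble with columns `age` and `p` on the grid
#'   `seq(a_start, a_end, by = step)` (final point included exactly).
#'
#' @examples
#' # With R = 1 the closed form is p(a) = 1 - exp(-c (a - a0)):
#' sol <- solve_prevalence(function(a) 0.01, function(a) 0.05,
#'                         function(a) 1, 20, 70)
#' max(abs(sol$p - (1 - exp(-0.01 * (sol$age - 20)))))
#' @export
solve_prevalence <- function(i_fn, m_fn, R_fn, a_start, a_end, p_start = 0,
                             step = 0.1) {
  check_positive(step, "step")
  check_proportion(p_start, "p_start")
  if (a_end <= a_start) stop_domain("`a_end` must exceed `a_start`.")

  n <- ceiling((a_end - a_start) / step - 1e-12)
  ages <- a_start + (0:n) * step
  ages[n + 1] <- a_end
  rate_at <- function(fn, a, name) {
    v <- fn(a)
    if (any(!is.finite(v)) || any(v < 0)) {
      stop_domain(sprintf("`%s` returned a negative or non-finite rate at age %.3f.",
                          name, a[which(!is.finite(v) | v < 0)[1]]))
    }
    v
  }
  deriv <- function(a, p) {
    i <- rate_at(i_fn, a, "i_fn")
    m <- rate_at(m_fn, a, "m_fn")
    R <- R_fn(a)
    if (any(!is.finite(R)) || any(R <= 0)) {
      stop_domain(sprintf("`R_fn` must return positive finite values (age %.3f).", a[1]))
    }
    pde_rhs_unchecked(p, i, m, R)
  }
  p <- numeric(n + 1)
  p[1] <- p_start
  for (k in seq_len(n)) {
    h <- ages[k + 1] - ages[k]
    a <- ages[k]
    y <- p[k]
    k1 <- deriv(a, y)
    k2 <- deriv(a + h / 2, y + h / 2 * k1)
    k3 <- deriv(a + h / 2, y + h / 2 * k2)
    k4 <- deriv(a + h, y + h * k3)
    p[k + 1] <- min(max(y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0), 1)
  }
  tibble::tibble(age = ages, p = p)
}
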