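# shared fixtures and independent oracles, built in code

# simple parameter set with a constant norm trajectory
make_flat_params <- function(f0 = 25, a_Y = -0.05, b_Y = 0, sigma1 = 0.5,
                             sigma0 = 2, a_Q = 1e-4, b_Q = 0, a_mu0 = 1e-5,
                             b_mu0 = 0.08, a_f0d = 0, b_f0d = 0) {
  spm_parameters(a_Y = a_Y, b_Y = b_Y, sigma1 = sigma1, sigma0 = sigma0,
                 a_Q = a_Q, b_Q = b_Q, a_mu0 = a_mu0, b_mu0 = b_mu0,
                 a_f0d = a_f0d, b_f0d = b_f0d,
                 f0_coeffs = c(f0, 0, 0, 0))
}

# quadrature oracle for the one-year survival factor and the selection
# update of the belief: moments of exp(-mu(t, y)) under N(m, gamma)
quad_survival_oracle <- function(m, gamma, Q, f0, mu0) {
  f <- function(y) exp(-mu0 - Q * (y - f0)^2) * dnorm(y, m, sqrt(gamma))
  # finite limits: infinite-range quadrature can miss a narrow Gaussian
  lo <- m - 13 * sqrt(gamma); hi <- m + 13 * sqrt(gamma)
  z <- integrate(f, lo, hi, rel.tol = 1e-12)$value
  m1 <- integrate(function(y) y * f(y), lo, hi, rel.tol = 1e-12)$value / z
  m2 <- integrate(function(y) y^2 * f(y), lo, hi, rel.tol = 1e-12)$value / z
  list(prob = z, m = m1, gamma = m2 - m1^2)
}

# well-identified parameter set for the estimation studies: every free
# parameter sits in the interior of its constraint region and the
# quadratic term carries an appreciable share of mortality, so maximum
# likelihood is regular (the chi-square reference for the LRT applies)
make_calibration_params <- function() {
  spm_parameters(a_Y = -0.09, b_Y = 2e-4, sigma1 = 0.6, sigma0 = 3,
                 a_Q = 4e-3, b_Q = 2e-5, a_mu0 = 2e-5, b_mu0 = 0.097,
                 a_f0d = 0.5, b_f0d = 0,
                 f0_coeffs = spm_default_parameters("high")$f0_coeffs)
}

# Brute-force likelihood of a toy subject by direct integration of the
# trajectory law: exams at t0 and t0 + 2 (values y1, y2), death during
# the year starting at t0 + 3. Hidden values are integrated numerically;
# never touches the package's filter.
toy_chain_loglik_oracle <- function(p, t0, y1, y2, rel.tol = 1e-10) {
  f0 <- function(t) eval_norm(t, p)
  f1 <- function(t) eval_setpoint(t, p)
  a <- function(t) eval_adaptive_capacity(t, p)
  mu <- function(t, y) eval_baseline_hazard(t, p) +
    eval_quadratic_term(t, p) * (y - f0(t))^2
  step_mean <- function(t, y) y + a(t) * (y - f1(t))
  # entry density and survival of year t0 given the exact observation y1
  l <- dnorm(y1, f1(t0), p$sigma0) * exp(-mu(t0, y1))
  # integrate the hidden value z at t0 + 1: transition, survival,
  # transition to the observed y2 (finite limits: infinite-range
  # quadrature can miss the narrow Gaussian peak entirely)
  c1 <- step_mean(t0, y1)
  lim <- range(c1, y2) + c(-12, 12) * p$sigma1
  mid <- integrate(function(z)
    dnorm(z, c1, p$sigma1) * exp(-mu(t0 + 1, z)) *
      dnorm(y2, step_mean(t0 + 1, z), p$sigma1),
    lim[1], lim[2], rel.tol = rel.tol)$value
  l <- l * mid * exp(-mu(t0 + 2, y2))
  # death during the year starting at t0 + 3
  c3 <- step_mean(t0 + 2, y2)
  pdeath <- 1 - integrate(function(y3)
    dnorm(y3, c3, p$sigma1) * exp(-mu(t0 + 3, y3)),
    c3 - 12 * p$sigma1, c3 + 12 * p$sigma1, rel.tol = rel.tol)$value
  log(l * pdeath)
}

# Independent linear-Gaussian recursion for the no-mortality case
# (Q = 0, mu0 = 0, no deaths): closed-form predictive density of each
# exam given the previous one, propagated year by year
kalman_chain_loglik_oracle <- function(exam_age, value, p) {
  ll <- dnorm(value[1], eval_setpoint(exam_age[1], p), p$sigma0, log = TRUE)
  for (i in seq_along(exam_age)[-1]) {
    m <- value[i - 1]; v <- 0
    for (t in exam_age[i - 1]:(exam_age[i] - 1)) {
      ak <- eval_adaptive_capacity(t, p)
      m <- m + ak * (m - eval_setpoint(t, p))
      v <- (1 + ak)^2 * v + p$sigma1^2
    }
    ll <- ll + dnorm(value[i], m, sqrt(v), log = TRUE)
  }
  ll
}

# minimal single-index cohort from per-subject lists
make_mini_cohort <- function(subjects) {
  subj <- do.call(rbind, lapply(subjects, function(s)
    data.frame(id = s$id, sex = "F", birth_decade = 1900, smoking = "never",
               entry_age = s$exam_age[1], event_age = s$event_age,
               death = s$death, cause = if (s$death == 1) "other" else "none")))
  exams <- do.call(rbind, lapply(subjects, function(s)
    data.frame(id = s$id, exam_age = s$exam_age, index = "BMI",
               value = s$value)))
  as_spm_cohort(subj, exams)
}

# single-process synthetic cohort (both dose groups share `p`)
make_spm_cohort <- function(n, seed, p, ...) {
  simulate_cohort(simulation_config(n_subjects = n, seed = seed,
                                    params = list("<14" = p, ">=14" = p),
                                    disease_onset = NULL, ...))
}
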