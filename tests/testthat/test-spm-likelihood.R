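test_that("survival factor: no-selection and degenerate-belief limits", {
  p <- make_flat_params(f0 = 25, a_Q = 0, a_mu0 = 1e-4, b_mu0 = 0.07)
  b <- gaussian_belief(28, 3, 60)
  s <- survival_factor(b, p)
  expect_equal(s$prob, exp(-eval_baseline_hazard(60, p)))
  expect_equal(s$updated$m, 28)
  expect_equal(s$updated$gamma, 3)
  # a point belief sees the raw hazard at its location
  p2 <- make_flat_params(f0 = 25, a_Q = 3e-4, a_mu0 = 1e-4, b_mu0 = 0.07)
  b0 <- gaussian_belief(29, 0, 70)
  s0 <- survival_factor(b0, p2)
  expect_equal(s0$prob, exp(-eval_hazard(70, 29, p2)))
  expect_equal(s0$updated$m, 29)
})

test_that("survival factor matches the worked conjugate-update example", {
  # m = 25, gamma = 4, Q = 0.01, f0 = 20, mu0 = 0 -> k = 1.08
  p <- spm_parameters(a_Y = -0.05, sigma1 = 0.5, sigma0 = 2, a_Q = 0.01,
                      a_mu0 = 0, b_mu0 = 0, f0_coeffs = c(20, 0, 0, 0))
  s <- survival_factor(gaussian_belief(25, 4, 50), p)
  expect_equal(s$prob, 1.08^(-0.5) * exp(-0.25 / 1.08), tolerance = 1e-12)
  expect_equal(s$prob, 0.7634, tolerance = 1e-4)
  expect_equal(s$updated$m, 20 + 5 / 1.08, tolerance = 1e-12)
  expect_equal(s$updated$m, 24.6296, tolerance = 1e-4)
  expect_equal(s$updated$gamma, 4 / 1.08, tolerance = 1e-12)
  expect_equal(s$updated$gamma, 3.7037, tolerance = 1e-4)
})

test_that("survival factor agrees with quadrature and shrinks the belief", {
  set.seed(41)
  for (i in 1:12) {
    m <- runif(1, 18, 32); g <- runif(1, 0.1, 9)
    Q <- runif(1, 0, 5e-3); f0 <- runif(1, 20, 28); mu0 <- runif(1, 0, 0.3)
    p <- make_flat_params(f0 = f0, a_Q = Q, a_mu0 = mu0, b_mu0 = 0)
    s <- survival_factor(gaussian_belief(m, g, 50), p)
    o <- quad_survival_oracle(m, g, Q, f0, mu0)
    expect_equal(s$prob, o$prob, tolerance = 1e-9)
    expect_equal(s$updated$m, o$m, tolerance = 1e-8)
    expect_equal(s$updated$gamma, o$gamma, tolerance = 1e-7)
    expect_true(s$prob > 0 && s$prob <= 1)
    expect_lte(s$updated$gamma, g)
    # the updated mean lies between the prior mean and the norm
    expect_lte(abs(s$updated$m - f0), abs(m - f0) + 1e-12)
  }
})

test_that("dynamics step propagates mean and variance over one year", {
  p <- make_flat_params(f0 = 24, a_Y = -0.05, sigma1 = 0.5)
  b2 <- dynamics_step(gaussian_belief(25, 1, 60), p)
  expect_equal(b2$m, 24.95)
  expect_equal(b2$gamma, 0.95^2 * 1 + 0.25)
  expect_equal(b2$t, 61)
  # the set point is a fixed point of the drift
  for (aY in c(-0.02, -0.1, -0.9)) {
    pa <- make_flat_params(f0 = 24, a_Y = aY, sigma1 = 0.5)
    expect_equal(dynamics_step(gaussian_belief(24, 2, 50), pa)$m, 24)
  }
  # noiseless propagation keeps a point belief a point
  p0 <- make_flat_params(sigma1 = 0)
  expect_equal(dynamics_step(gaussian_belief(27, 0, 50), p0)$gamma, 0)
})

test_that("observation update returns the predictive Gaussian density", {
  p <- make_flat_params(f0 = 24, sigma0 = 2)
  o <- observation_update(gaussian_belief(25, 4, 60), 27, p)
  expect_equal(o$logdensity, dnorm(27, 25, 2, log = TRUE))
  expect_equal(exp(o$logdensity), 0.1210, tolerance = 1e-3)
  expect_equal(o$logdensity, -2.1121, tolerance = 1e-4)
  expect_equal(o$updated$m, 27)
  expect_equal(o$updated$gamma, 0)
  # density is maximal at the predictive mean
  omax <- observation_update(gaussian_belief(25, 4, 60), 25, p)
  expect_equal(exp(omax$logdensity), 1 / sqrt(2 * pi * 4))
  # first observations use the entry law N(f1(t0), sigma0^2)
  of <- observation_update(gaussian_belief(0, 0, 50), 24, p, first = TRUE)
  expect_equal(exp(of$logdensity), 1 / (2 * sqrt(2 * pi)), tolerance = 1e-12)
  expect_equal(exp(of$logdensity), 0.19947, tolerance = 1e-4)
  # repeated exam in the same filter year is a data-alignment error
  expect_error(observation_update(gaussian_belief(24, 0, 50), 25, p),
               "data-alignment")
})

test_that("a single exam with same-year censoring contributes only the entry density", {
  p <- make_flat_params(f0 = 24, sigma0 = 2)
  s <- list(exam_age = 50, value = 26, event_age = 50.3, death = 0)
  expect_equal(subject_loglik(s, p), dnorm(26, 24, 2, log = TRUE))
})

test_that("subject likelihood matches brute-force integration of the trajectory law", {
  p <- spm_parameters(a_Y = -0.12, b_Y = 5e-4, sigma1 = 0.7, sigma0 = 2.5,
                      a_Q = 1e-4, b_Q = 3e-6, a_mu0 = 2e-5, b_mu0 = 0.09,
                      a_f0d = 1, b_f0d = -0.008,
                      f0_coeffs = c(12, 0.42, -0.003, 0))
  for (case in list(c(50, 26, 27.5), c(62, 22, 24), c(71, 30, 28))) {
    t0 <- case[1]; y1 <- case[2]; y2 <- case[3]
    s <- list(exam_age = c(t0, t0 + 2), value = c(y1, y2),
              event_age = t0 + 3, death = 1)
    ours <- subject_loglik(s, p)
    oracle <- toy_chain_loglik_oracle(p, t0, y1, y2)
    expect_equal(ours, oracle, tolerance = 1e-6)
  }
})

test_that("without mortality the filter is an exact linear-Gaussian recursion", {
  p <- spm_parameters(a_Y = -0.07, b_Y = 2e-4, sigma1 = 0.55, sigma0 = 2.2,
                      a_Q = 0, b_Q = 0, a_mu0 = 0, b_mu0 = 0,
                      a_f0d = 0.8, b_f0d = -0.005,
                      f0_coeffs = c(18, 0.25, -0.002, 0))
  set.seed(7)
  for (i in 1:5) {
    ages <- sort(sample(42:80, sample(3:7, 1)))
    vals <- rnorm(length(ages), 25, 3)
    s <- list(exam_age = ages, value = vals,
              event_age = max(ages), death = 0)
    expect_equal(subject_loglik(s, p),
                 kalman_chain_loglik_oracle(ages, vals, p),
                 tolerance = 1e-10)
  }
})

test_that("raising the baseline hazard lowers survival factors and censored likelihoods", {
  p1 <- make_flat_params(a_mu0 = 1e-5)
  p2 <- make_flat_params(a_mu0 = 5e-5)
  b <- gaussian_belief(27, 2, 65)
  expect_lt(survival_factor(b, p2)$prob, survival_factor(b, p1)$prob)
  s <- list(exam_age = c(50, 52, 54), value = c(26, 25, 27),
            event_age = 70, death = 0)
  expect_lt(subject_loglik(s, p2), subject_loglik(s, p1))
})

test_that("death-year contribution is a proper probability", {
  p <- make_flat_params(a_Q = 2e-4, a_mu0 = 3e-5, b_mu0 = 0.09)
  s_dead <- list(exam_age = c(50, 52), value = c(26, 29),
                 event_age = 60, death = 1)
  s_cens <- list(exam_age = c(50, 52), value = c(26, 29),
                 event_age = 60, death = 0)
  ll_d <- subject_loglik(s_dead, p)
  ll_c <- subject_loglik(s_cens, p)
  expect_true(is.finite(ll_d) && is.finite(ll_c))
  # P(die in year 60) = 1 - prob < 1, and the two variants differ only in
  # the final-year term
  expect_lt(ll_d, ll_c)
})

test_that("cohort likelihood is additive, order-invariant, and engine-consistent", {
  p <- spm_default_parameters("high")
  co <- make_spm_cohort(120, seed = 314, p)
  r_cpp <- cohort_loglik(co, p, engine = "cpp")
  r_r <- cohort_loglik(co, p, engine = "r")
  expect_equal(r_cpp$loglik, r_r$loglik, tolerance = 1e-10)
  expect_equal(r_cpp$n_observation_terms, r_r$n_observation_terms)
  expect_equal(r_cpp$n_death_terms, r_r$n_death_terms)
  # equals the sum of per-subject values
  fd <- spmaging:::prepare_cohort_filter(co, "BMI", 40)
  by_subj <- vapply(seq_len(fd$n_subjects), function(j) {
    idx <- (fd$exam_ptr[j] + 1L):fd$exam_ptr[j + 1L]
    subject_loglik(list(exam_age = fd$exam_age[idx], value = fd$exam_val[idx],
                        event_age = fd$tend[j], death = fd$death[j]),
                   p, min_age = 0)
  }, numeric(1))
  expect_equal(r_cpp$loglik, sum(by_subj), tolerance = 1e-8)
  # permuting subject order changes nothing
  perm <- sample(nrow(co$subjects))
  co2 <- as_spm_cohort(co$subjects[perm, ], co$exams, co$genotypes)
  expect_equal(cohort_loglik(co2, p)$loglik, r_cpp$loglik, tolerance = 1e-9)
  # duplicating every subject doubles the log-likelihood exactly
  s2 <- co$subjects; s2$id <- paste0(s2$id, "_b")
  e2 <- co$exams; e2$id <- paste0(e2$id, "_b")
  co_dup <- as_spm_cohort(rbind(co$subjects, s2), rbind(co$exams, e2))
  expect_equal(cohort_loglik(co_dup, p)$loglik, 2 * r_cpp$loglik,
               tolerance = 1e-8)
})

test_that("exams before the age window and missing values are handled", {
  p <- make_flat_params()
  # exams before 40 are ignored; first usable exam defines entry
  s <- list(exam_age = c(34, 36, 50, 52), value = c(20, 21, 26, 25),
            event_age = 55, death = 0)
  s_ref <- list(exam_age = c(50, 52), value = c(26, 25),
                event_age = 55, death = 0)
  expect_equal(subject_loglik(s, p), subject_loglik(s_ref, p))
  # a missing value drops the observation term but keeps survival terms
  s_na <- list(exam_age = c(50, 52, 54), value = c(26, NA, 25),
               event_age = 55, death = 0)
  s_no <- list(exam_age = c(50, 54), value = c(26, 25),
               event_age = 55, death = 0)
  expect_equal(subject_loglik(s_na, p), subject_loglik(s_no, p))
  # no usable exam: excluded with a warning, NA result
  expect_warning(r <- subject_loglik(list(exam_age = 36, value = 22,
                                          event_age = 70, death = 1), p),
                 "excluded")
  expect_true(is.na(r))
  expect_error(subject_loglik(list(exam_age = c(52, 50), value = c(1, 2),
                                   event_age = 60, death = 0), p),
               "non-monotone")
})
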