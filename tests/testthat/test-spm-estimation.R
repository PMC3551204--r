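# small cohorts keep the optimiser runs in these tests to a few seconds
fast_cfg <- function(...) spm_fit_config(n_starts = 1, ...)

test_that("norm cubic is recovered exactly from noiseless binned means", {
  cf <- c(-10, 1.2, -0.012, 2e-5)
  mids <- spmaging:::age_bin_midpoints()
  mids <- mids[mids >= 40]
  # 12 long-lived subjects, each measured at every bin midpoint
  subj <- do.call(rbind, lapply(1:12, function(k)
    data.frame(id = sprintf("L%02d", k), sex = "F", birth_decade = 1900,
               smoking = "never", entry_age = 40, event_age = 99,
               death = 1, cause = "other")))
  exams <- do.call(rbind, lapply(1:12, function(k)
    data.frame(id = sprintf("L%02d", k), exam_age = mids, index = "BMI",
               value = cf[1] + cf[2] * mids + cf[3] * mids^2 + cf[4] * mids^3)))
  co <- as_spm_cohort(subj, exams)
  # suppressed: lm warns about the (deliberately) perfect fit
  fit <- suppressWarnings(fit_norm_polynomial(co, "BMI"))
  expect_equal(fit$coeffs, cf, tolerance = 1e-8)
  # a constant trajectory has vanishing higher-degree coefficients
  exams$value <- 26
  fit2 <- suppressWarnings(fit_norm_polynomial(as_spm_cohort(subj, exams), "BMI"))
  expect_equal(fit2$coeffs, c(26, 0, 0, 0), tolerance = 1e-8)
})

test_that("norm fit recovers a noisy cubic within its own standard errors", {
  cf <- c(-10, 1.2, -0.012, 2e-5)
  mids <- spmaging:::age_bin_midpoints()
  mids <- mids[mids >= 40]
  set.seed(99)
  miss <- 0
  for (rep in 1:10) {
    subj <- do.call(rbind, lapply(1:12, function(k)
      data.frame(id = sprintf("L%02d", k), sex = "F", birth_decade = 1900,
                 smoking = "never", entry_age = 40, event_age = 99,
                 death = 1, cause = "other")))
    exams <- do.call(rbind, lapply(1:12, function(k)
      data.frame(id = sprintf("L%02d", k), exam_age = mids, index = "BMI",
                 value = cf[1] + cf[2] * mids + cf[3] * mids^2 +
                   cf[4] * mids^3 + rnorm(length(mids), 0, 0.1))))
    fit <- fit_norm_polynomial(as_spm_cohort(subj, exams), "BMI")
    miss <- miss + sum(abs(fit$coeffs - cf) > 3 * fit$se)
  }
  # 40 coefficient checks at a 3-SE bound: the occasional miss is expected
  expect_lte(miss, 3)
})

test_that("norm fit refuses cohorts with too few populated bins", {
  subj <- data.frame(id = "L01", sex = "F", birth_decade = 1900,
                     smoking = "never", entry_age = 40, event_age = 99,
                     death = 1, cause = "other")
  exams <- data.frame(id = "L01", exam_age = rep(c(42, 47, 52), each = 10),
                      index = "BMI", value = 26)
  expect_error(fit_norm_polynomial(as_spm_cohort(subj, exams), "BMI"),
               "populated age bins")
})

test_that("likelihood-ratio test has the chi-square(2) closed form", {
  mk <- function(ll, restriction)
    structure(list(loglik = ll, restriction = restriction, df = 2L),
              class = "spm_two_group_fit")
  lrt <- likelihood_ratio_test(mk(-100, "none"), mk(-103, "baseline_hazard"))
  expect_equal(lrt$statistic, 6)
  expect_equal(lrt$p, exp(-3), tolerance = 1e-12)
  expect_equal(lrt$p, 0.0498, tolerance = 1e-3)
  lrt0 <- likelihood_ratio_test(mk(-100, "none"), mk(-100, "adaptive_capacity"))
  expect_equal(lrt0$statistic, 0)
  expect_equal(lrt0$p, 1)
  expect_error(likelihood_ratio_test(mk(-100, "none"), mk(-100, "none")),
               "named restriction")
  expect_warning(likelihood_ratio_test(mk(-101, "none"), mk(-100, "quadratic_term")),
                 "may have failed")
})

test_that("fitting from the truth never decreases the likelihood", {
  truth <- spm_default_parameters("high")
  co <- make_spm_cohort(250, seed = 21, truth)
  ll_truth <- cohort_loglik(co, truth)$loglik
  fit <- fit_group(co, "BMI", init = truth, config = fast_cfg())
  expect_gte(fit$loglik, ll_truth - 1e-8)
  expect_true(fit$converged)
  # re-evaluating the returned parameters reproduces the reported loglik
  expect_equal(cohort_loglik(co, fit$params)$loglik, fit$loglik,
               tolerance = 1e-9)
  # refitting from the returned optimum barely moves
  fit2 <- fit_group(co, "BMI", init = fit$params, config = fast_cfg())
  expect_lt(abs(fit2$loglik - fit$loglik), 1e-4)
  # every constraint holds on a dense half-year grid
  expect_length(check_spm_parameters(fit$params, default_f1_bounds()$BMI), 0)
})

test_that("seeded fits are exactly reproducible", {
  truth <- spm_default_parameters("low")
  co <- make_spm_cohort(150, seed = 5, truth)
  f1 <- fit_group(co, "BMI", f0_coeffs = truth$f0_coeffs,
                  config = spm_fit_config(n_starts = 2, seed = 42))
  f2 <- fit_group(co, "BMI", f0_coeffs = truth$f0_coeffs,
                  config = spm_fit_config(n_starts = 2, seed = 42))
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(spmaging:::spm_par_vector(f1$params),
                   spmaging:::spm_par_vector(f2$params))
})

test_that("a death-free cohort drives the quadratic term to its zero boundary", {
  gen <- spm_parameters(a_Y = -0.08, b_Y = 0, sigma1 = 0.6, sigma0 = 3,
                        a_Q = 0, b_Q = 0, a_mu0 = 1e-12, b_mu0 = 0,
                        f0_coeffs = spm_default_parameters("high")$f0_coeffs)
  co <- make_spm_cohort(200, seed = 8, gen)
  expect_equal(sum(co$subjects$death), 0)
  fit <- fit_group(co, "BMI", f0_coeffs = gen$f0_coeffs, config = fast_cfg())
  expect_true(any(c("Q_lo", "Q_hi") %in% fit$bounds_active))
  expect_lte(eval_quadratic_term(75, fit$params), 1e-6)
})

test_that("restricted fits are nested and vanish for identical groups", {
  p <- spm_default_parameters("high")
  coA <- make_spm_cohort(250, seed = 31, p)
  unres <- fit_two_groups(coA, coA, "BMI", restriction = "none",
                          f0_coeffsA = p$f0_coeffs, f0_coeffsB = p$f0_coeffs,
                          config = fast_cfg())
  for (h in c("baseline_hazard", "adaptive_capacity")) {
    res <- fit_two_groups(coA, coA, "BMI", restriction = h,
                          config = fast_cfg(), init_from = unres)
    expect_lte(res$loglik, unres$loglik + 1e-6)
    lrt <- likelihood_ratio_test(unres, res)
    expect_equal(lrt$df, 2)
    # identical groups: equating parameters costs (almost) nothing
    expect_lt(lrt$statistic, 0.05)
    expect_gt(lrt$p, 0.9)
  }
})

test_that("moment-based starts land in the feasible region", {
  p <- spm_default_parameters("low")
  co <- make_spm_cohort(200, seed = 77, p)
  fd <- spmaging:::prepare_cohort_filter(co, "BMI", 40)
  init <- spmaging:::init_from_moments(fd, p$f0_coeffs, c(40, 110))
  expect_length(check_spm_parameters(init), 0)
  expect_true(is.finite(cohort_loglik(co, init)$loglik))
})
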