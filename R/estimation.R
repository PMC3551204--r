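# -- endpoint reparameterisation -------------------------------------------
#
# The free parameters are optimised as the *endpoint values* of the linear
# model functions on the age window: a(t) and Q(t) and Delta f0(t) are linear
# in age, so constraining them at the two window endpoints constrains them
# everywhere on the window, and every shape constraint becomes a box
# constraint for nlminb. Layout of the box vector v:
#   v1 = a(w1), v2 = a(w2), v3 = sigma1, v4 = sigma0,
#   v5 = Q(w1), v6 = Q(w2), v7 = a_mu0, v8 = b_mu0,
#   v9 = Df0(w1), v10 = Df0(w2)
spm_box_names <- function() {
  c("a_lo", "a_hi", "sigma1", "sigma0", "Q_lo", "Q_hi",
    "a_mu0", "b_mu0", "df0_lo", "df0_hi")
}

line_from_endpoints <- function(vlo, vhi, w) {
  slope <- (vhi - vlo) / (w[2] - w[1])
  c(intercept = vlo - slope * w[1], slope = slope)
}

line_to_endpoints <- function(intercept, slope, w) {
  c(intercept + slope * w[1], intercept + slope * w[2])
}

theta_to_box <- function(theta, w) {
  c(line_to_endpoints(theta[1], theta[2], w), theta[3], theta[4],
    line_to_endpoints(theta[5], theta[6], w), theta[7], theta[8],
    line_to_endpoints(theta[9], theta[10], w))
}

box_to_theta <- function(v, w) {
  a <- line_from_endpoints(v[1], v[2], w)
  q <- line_from_endpoints(v[5], v[6], w)
  d <- line_from_endpoints(v[9], v[10], w)
  unname(c(a[1], a[2], v[3], v[4], q[1], q[2], v[7], v[8], d[1], d[2]))
}

# box bounds; the f1 plausibility bound enters through the Delta f0
# endpoints (conservative: both endpoints inside [lo - min f0, hi - max f0],
# which guarantees f1 in [lo, hi] on the whole window since Delta f0(t) is a
# convex combination of its endpoint values there)
spm_box_bounds <- function(p, f1_bounds = NULL) {
  lower <- c(-5, -5, 1e-6, 1e-6, 0, 0, 1e-12, -0.5, -1e3, -1e3)
  upper <- c(-1e-6, -1e-6, 1e3, 1e3, 1, 1, 1, 0.5, 1e3, 1e3)
  if (!is.null(f1_bounds)) {
    tt <- seq(p$age_window[1], p$age_window[2], by = 0.5)
    f0 <- eval_norm(tt, p)
    dlo <- f1_bounds[1] - min(f0)
    dhi <- f1_bounds[2] - max(f0)
    if (dlo >= dhi)
      stop("f1 plausibility bounds leave no feasible allostatic offset; ",
           "widen the bounds for this index")
    lower[9:10] <- dlo
    upper[9:10] <- dhi
  }
  list(lower = lower, upper = upper)
}

#' Fitting configuration for the constrained likelihood maximisation
#'
#' @param n_starts number of optimisation starts (1 = the supplied or
#'   moment-based start only; further starts are seeded perturbations).
#' @param seed seed of the perturbation scheme (fits are bit-reproducible
#'   given identical config).
#' @param perturb_sd relative scale of the start perturbations.
#' @param maxit iteration cap per start.
#' @param f1_bounds length-2 plausibility bounds for f1(t), or `NULL`
#'   to look them up by index role via [default_f1_bounds()] (indices
#'   with no registered role get no bound).
#' @param min_age minimum exam age used by the likelihood.
#' @param se compute standard errors from the numerical Hessian at the
#'   optimum (adds a few hundred likelihood evaluations).
#' @return A list of class `spm_fit_config`.
#' @export
spm_fit_config <- function(n_starts = 5, seed = 1, perturb_sd = 0.3,
                           maxit = 500, f1_bounds = NULL, min_age = 40,
                           se = FALSE) {
  structure(list(n_starts = n_starts, seed = seed, perturb_sd = perturb_sd,
                 maxit = maxit, f1_bounds = f1_bounds, min_age = min_age,
                 se = se),
            class = "spm_fit_config")
}

resolve_f1_bounds <- function(config, index) {
  if (!is.null(config$f1_bounds)) return(config$f1_bounds)
  default_f1_bounds()[[index]]   # NULL when the index role is unknown
}

#' Fit the norm trajectory f0(t) from long-lived subjects
#'
#' The physiological norm is estimated empirically: the age-binned mean
#' trajectory of subjects whose lifespan exceeds 90 years (deaths after
#' 90, or censoring beyond 90) is fitted by a least-squares cubic in
#' age. The fitted coefficients are then held fixed during likelihood
#' maximisation.
#'
#' @param cohort an `spm_cohort`.
#' @param index physiological index name.
#' @param min_age minimum exam age used (years).
#' @param min_bins minimum number of populated age bins required.
#' @return A list of class `f0_fit` with `coeffs` (length 4, lowest
#'   degree first), `se` (coefficient standard errors from the
#'   least-squares fit) and `bins` (the binned summary used).
#' @export
fit_norm_polynomial <- function(cohort, index = spm_indices(cohort)[1],
                                min_age = 40, min_bins = 5) {
  s <- cohort$subjects
  ll_ids <- s$id[s$event_age > 90]
  e <- cohort$exams[cohort$exams$index == index & cohort$exams$id %in% ll_ids &
                      cohort$exams$exam_age >= min_age, , drop = FALSE]
  tr <- average_trajectory(e$exam_age, e$value, index = index,
                           group = "lifespan>90")
  mid <- age_bin_midpoints()
  ok <- !is.na(tr$mean)
  if (sum(ok) < min_bins)
    stop("cannot fit the norm trajectory: only ", sum(ok),
         " populated age bins (need at least ", min_bins,
         "); too few long-lived subjects with exams at ages >= ", min_age)
  t <- mid[ok]; y <- tr$mean[ok]
  fit <- lm(y ~ t + I(t^2) + I(t^3))
  structure(list(coeffs = unname(coef(fit)),
                 se = unname(sqrt(diag(vcov(fit)))),
                 bins = tr),
            class = "f0_fit")
}

#' @export
print.f0_fit <- function(x, ...) {
  cat("Norm trajectory f0(t): cubic fitted to long-lived binned means\n")
  cat("  coefficients (low->high degree):",
      paste(signif(x$coeffs, 6), collapse = ", "), "\n")
  cat("  populated bins:", sum(!is.na(x$bins$mean)), "\n")
  invisible(x)
}

# Moment-based starting values: lag regression of exam-to-exam changes for
# the feedback and diffusion, crude Gompertz fit of yearly death rates for
# the baseline hazard, small positive Q.
init_from_moments <- function(fd, f0_coeffs, age_window) {
  p0 <- spm_parameters(a_Y = -0.05, b_Y = 0, sigma1 = 1, sigma0 = 1,
                       a_Q = 1e-5, b_Q = 0, a_mu0 = 1e-5, b_mu0 = 0.09,
                       f0_coeffs = f0_coeffs, age_window = age_window)
  f0v <- function(t) eval_norm(t, p0)
  d1 <- c(); dev <- c(); gap <- c(); first_dev <- c()
  for (j in seq_len(fd$n_subjects)) {
    idx <- (fd$exam_ptr[j] + 1L):fd$exam_ptr[j + 1L]
    aa <- fd$exam_age[idx]; yy <- fd$exam_val[idx]
    first_dev <- c(first_dev, yy[1] - f0v(aa[1]))
    if (length(idx) >= 2) {
      g <- diff(aa)
      d1 <- c(d1, diff(yy) / g)
      dev <- c(dev, (yy - f0v(aa))[-length(yy)])
      gap <- c(gap, g)
    }
  }
  a_init <- -0.05; s1_init <- 1
  if (length(d1) > 20) {
    r <- lm(d1 ~ dev)
    a_init <- min(unname(coef(r)[2]), -0.01)
    # residual of the per-year change over a gap g has sd ~ sigma1 / sqrt(g)
    s1_init <- max(sd(r$residuals) * sqrt(mean(gap)), 0.05)
  }
  s0_init <- max(sd(first_dev), 0.1)
  # crude Gompertz from person-year death rates in 10-year bands
  mids <- c(); rates <- c()
  for (lo in seq(40, 90, by = 10)) {
    exposure <- sum(pmax(pmin(fd$tend, lo + 10) - pmax(fd$entry, lo), 0))
    deaths <- sum(fd$death == 1 & fd$tend >= lo & fd$tend < lo + 10)
    if (exposure > 0 && deaths > 0) {
      mids <- c(mids, lo + 5)
      rates <- c(rates, deaths / exposure)
    }
  }
  mu_a <- 1e-5; mu_b <- 0.09
  if (length(mids) >= 3) {
    r <- lm(log(rates) ~ mids)
    mu_b <- min(max(unname(coef(r)[2]), 0.01), 0.2)
    mu_a <- min(max(exp(unname(coef(r)[1])), 1e-10), 0.5)
  }
  spm_parameters(a_Y = a_init, b_Y = 0, sigma1 = s1_init, sigma0 = s0_init,
                 a_Q = 1e-5, b_Q = 1e-8, a_mu0 = mu_a, b_mu0 = mu_b,
                 a_f0d = mean(first_dev), b_f0d = 0,
                 f0_coeffs = f0_coeffs, age_window = age_window)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# crude moment scale for the quadratic hazard term: attribute half of the
# person-year death rate to the quadratic component evaluated at the mean
# squared deviation of the observed values from the norm
q_moment_scale <- function(fd, p) {
  exposure <- sum(pmax(fd$tend - fd$entry, 1))
  rate <- sum(fd$death) / exposure
  dev2 <- mean((fd$exam_val - eval_norm(fd$exam_age, p))^2)
  if (!is.finite(dev2) || dev2 <= 0) dev2 <- 1
  max(0.5 * rate / dev2, 1e-8)
}

# typical magnitudes of the box components, used to scale the optimiser
# (the components span ~5 orders of magnitude)
spm_box_typical <- function(v0 = NULL) {
  typ <- c(0.05, 0.05, 0.5, 2, 1e-4, 1e-4, 1e-5, 0.05, 1, 1)
  if (!is.null(v0)) typ <- pmax(abs(v0), typ)
  typ
}

# seeded perturbation of a box vector for multi-start
perturb_start <- function(v, lower, upper, sd_rel) {
  scale <- pmax(abs(v), 0.01)
  clamp(v + rnorm(length(v), 0, sd_rel) * scale,
        lower + 1e-9 + 0.0 * v, upper - 1e-9)
}

spm_negloglik_factory <- function(fd, proto, w) {
  function(v) {
    p <- spm_par_update(proto, box_to_theta(v, w))
    r <- tryCatch(cohort_loglik_filter(fd, p), error = function(e) NULL)
    if (is.null(r) || !is.finite(r$loglik)) return(1e10)
    -r$loglik
  }
}

# objective + exact analytic gradient (forward sensitivities in the C++
# kernel, chained through the linear box -> natural reparameterisation);
# one kernel call serves both nlminb callbacks via a cache
spm_obj_factory <- function(fd, proto, w) {
  A <- vapply(1:10, function(i) {
    e <- numeric(10); e[i] <- 1
    box_to_theta(e, w)
  }, numeric(10))            # column i = d theta / d v_i (map is linear)
  cache <- new.env(parent = emptyenv())
  compute <- function(v) {
    if (!is.null(cache$v) && identical(cache$v, v)) return(invisible())
    theta <- box_to_theta(v, w)
    r <- tryCatch(
      spm_cohort_loglik_cpp(fd$entry, fd$tend, fd$death, fd$exam_ptr,
                            fd$exam_age, fd$exam_val, theta,
                            proto$f0_coeffs, grad = TRUE),
      error = function(e) NULL)
    cache$v <- v
    if (is.null(r) || !is.finite(r$loglik)) {
      cache$val <- 1e10
      cache$grad <- numeric(10)
    } else {
      cache$val <- -r$loglik
      cache$grad <- as.numeric(-crossprod(A, r$gradient))
    }
    invisible()
  }
  list(fn = function(v) { compute(v); cache$val },
       gr = function(v) { compute(v); cache$grad })
}

#' Constrained maximum-likelihood fit of one group
#'
#' Maximises the cohort log-likelihood over the ten free parameters
#' subject to the shape constraints (negative adaptive capacity,
#' non-negative quadratic term and baseline hazard, non-negative
#' sigmas, set point within plausibility bounds), holding the norm
#' cubic f0(t) fixed. The linear model functions are optimised through
#' their endpoint values on the age window, which turns every
#' constraint into a box constraint; multi-start from seeded
#' perturbations guards against local optima.
#'
#' @param cohort an `spm_cohort`.
#' @param index physiological index name.
#' @param init an [spm_parameters()] object holding the fixed
#'   `f0_coeffs` and the starting values; `NULL` builds a moment-based
#'   start (then `f0_coeffs` must be given).
#' @param f0_coeffs fixed norm coefficients when `init` is `NULL`
#'   (e.g. from [fit_norm_polynomial()]).
#' @param config an [spm_fit_config()].
#' @return A list of class `spm_fit`: `params`, `loglik`, `converged`,
#'   `n_evaluations`, `seed`, `bounds_active`, `se` (named vector or
#'   `NULL`), `n_subjects`, `n_excluded`, `index`.
#' @export
fit_group <- function(cohort, index = spm_indices(cohort)[1], init = NULL,
                      f0_coeffs = NULL, config = spm_fit_config()) {
  fd <- prepare_cohort_filter(cohort, index, config$min_age)
  if (fd$n_subjects == 0) stop("no subject has a usable exam; cannot fit")
  fit_group_filter(fd, index, init, f0_coeffs, config)
}

fit_group_filter <- function(fd, index, init = NULL, f0_coeffs = NULL,
                             config = spm_fit_config()) {
  if (is.null(init)) {
    if (is.null(f0_coeffs))
      stop("either 'init' or 'f0_coeffs' must be supplied")
    init <- init_from_moments(fd, f0_coeffs, c(40, 110))
  }
  w <- init$age_window
  f1b <- resolve_f1_bounds(config, index)
  bb <- spm_box_bounds(init, f1b)
  obj <- spm_obj_factory(fd, init, w)
  v0 <- clamp(theta_to_box(spm_par_vector(init), w),
              bb$lower + 1e-9, bb$upper - 1e-9)
  if (obj$fn(v0) >= 1e10) stop("non-finite likelihood at the starting values")
  set.seed(config$seed)
  starts <- list(v0)
  if (config$n_starts > 1) {
    # deterministic second start: the likelihood can have one mode where
    # the Gompertz baseline absorbs all mortality and another where the
    # quadratic term carries its share; start the quadratic term at the
    # moment scale (half the crude death rate over the mean squared
    # deviation from the norm) to cover the second basin
    qmom <- q_moment_scale(fd, init)
    v_alt <- v0
    v_alt[5:6] <- clamp(qmom, bb$lower[5:6] + 1e-9, bb$upper[5:6] - 1e-9)
    starts[[2]] <- v_alt
    if (config$n_starts > 2)
      for (k in 3:config$n_starts)
        starts[[k]] <- perturb_start(v0, bb$lower, bb$upper, config$perturb_sd)
  }
  best <- NULL; nev <- 0L
  scale <- 1 / spm_box_typical(v0)
  for (v in starts) {
    r <- nlminb(v, obj$fn, gradient = obj$gr,
                lower = bb$lower, upper = bb$upper, scale = scale,
                control = list(iter.max = config$maxit,
                               eval.max = config$maxit * 15))
    nev <- nev + sum(r$evaluations)
    if (is.null(best) || r$objective < best$objective) best <- r
  }
  # polish: the PORT routine can stop prematurely on ridges; restart from
  # the incumbent until the objective no longer improves
  for (round in 1:5) {
    r <- nlminb(best$par, obj$fn, gradient = obj$gr,
                lower = bb$lower, upper = bb$upper, scale = scale,
                control = list(iter.max = config$maxit,
                               eval.max = config$maxit * 15))
    nev <- nev + sum(r$evaluations)
    if (r$objective < best$objective - 1e-6) best <- r else {
      if (r$objective < best$objective) best <- r
      break
    }
  }
  vhat <- best$par
  phat <- spm_par_update(init, box_to_theta(vhat, w))
  tol <- 1e-6
  active <- spm_box_names()[vhat <= bb$lower + tol * pmax(abs(bb$lower), 1) |
                              vhat >= bb$upper - tol * pmax(abs(bb$upper), 1)]
  se <- NULL
  if (config$se) {
    th_hat <- spm_par_vector(phat)
    # numerical Hessian in a scaled space: the natural parameters span
    # several orders of magnitude
    s <- pmax(abs(th_hat),
              c(0.01, 1e-4, 0.05, 0.05, 1e-5, 1e-7, 1e-6, 0.01, 0.1, 0.01))
    nll_scaled <- function(z) {
      p <- spm_par_update(init, th_hat + z * s)
      r <- tryCatch(cohort_loglik_filter(fd, p), error = function(e) NULL)
      if (is.null(r) || !is.finite(r$loglik)) return(1e10)
      -r$loglik
    }
    H <- tryCatch(pracma::hessian(nll_scaled, rep(0, 10)),
                  error = function(e) NULL)
    se <- rep(NA_real_, 10)
    if (!is.null(H)) {
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V)) {
        d <- diag(V)
        se[d > 0] <- s[d > 0] * sqrt(d[d > 0])
      }
    }
    names(se) <- spm_par_names()
  }
  structure(list(params = phat, loglik = -best$objective,
                 converged = best$convergence == 0,
                 n_evaluations = nev, seed = config$seed,
                 bounds_active = active, se = se,
                 n_subjects = fd$n_subjects,
                 n_excluded = length(fd$excluded), index = index),
            class = "spm_fit")
}

#' @export
print.spm_fit <- function(x, ...) {
  cat(sprintf("SPM fit (%s): loglik = %.4f over %d subjects%s\n",
              x$index, x$loglik, x$n_subjects,
              if (x$converged) "" else "  [did not converge]"))
  if (length(x$bounds_active))
    cat("  at boundary:", paste(x$bounds_active, collapse = ", "), "\n")
  th <- spm_par_vector(x$params)
  for (i in seq_along(th))
    cat(sprintf("  %-7s %12.6g%s\n", spm_par_names()[i], th[i],
                if (!is.null(x$se)) sprintf("  (SE %.3g)", x$se[i]) else ""))
  invisible(x)
}

spm_hypotheses <- function() {
  list(baseline_hazard = c("a_mu0", "b_mu0"),
       quadratic_term = c("a_Q", "b_Q"),
       adaptive_capacity = c("a_Y", "b_Y"),
       allostatic_trajectory = c("a_f0d", "b_f0d"))
}

# box-vector indices shared under each restriction (endpoint pairs map
# one-to-one onto the natural pairs)
spm_hypothesis_box_idx <- function(name) {
  switch(name,
         baseline_hazard = c(7L, 8L),
         quadratic_term = c(5L, 6L),
         adaptive_capacity = c(1L, 2L),
         allostatic_trajectory = c(9L, 10L),
         stop("unknown hypothesis '", name, "'"))
}

#' Joint fit of two groups, unrestricted or with one parameter pair equated
#'
#' The unrestricted model gives each group its own ten parameters (two
#' independent fits; their log-likelihoods add). A restricted model
#' equates one named parameter pair across the groups — `
#' baseline_hazard` (a_mu0, b_mu0), `quadratic_term` (a_Q, b_Q),
#' `adaptive_capacity` (a_Y, b_Y) or `allostatic_trajectory`
#' (a_f0d, b_f0d) — and maximises the joint 18-parameter likelihood.
#' Each group keeps its own fixed norm cubic f0(t).
#'
#' @param cohortA,cohortB the two groups (`spm_cohort`s).
#' @param index physiological index name.
#' @param restriction `"none"` or one of the four hypothesis names.
#' @param initA,initB per-group [spm_parameters()] starts (also carry
#'   `f0_coeffs`); `NULL` builds moment-based starts from `f0_coeffsA`
#'   / `f0_coeffsB`.
#' @param f0_coeffsA,f0_coeffsB fixed norm coefficients used when the
#'   corresponding init is `NULL`.
#' @param config an [spm_fit_config()].
#' @param init_from optional unrestricted `spm_two_group_fit` whose
#'   optimum seeds a restricted fit (the equated pair is averaged).
#' @return A list of class `spm_two_group_fit`: `restriction`, `loglik`,
#'   `df` (2 for restricted models), `fitA`, `fitB`, `converged`.
#' @export
fit_two_groups <- function(cohortA, cohortB, index = spm_indices(cohortA)[1],
                           restriction = "none",
                           initA = NULL, initB = NULL,
                           f0_coeffsA = NULL, f0_coeffsB = NULL,
                           config = spm_fit_config(), init_from = NULL) {
  fdA <- prepare_cohort_filter(cohortA, index, config$min_age)
  fdB <- prepare_cohort_filter(cohortB, index, config$min_age)
  fit_two_groups_filter(fdA, fdB, index, restriction, initA, initB,
                        f0_coeffsA, f0_coeffsB, config, init_from)
}

fit_two_groups_filter <- function(fdA, fdB, index, restriction = "none",
                                  initA = NULL, initB = NULL,
                                  f0_coeffsA = NULL, f0_coeffsB = NULL,
                                  config = spm_fit_config(),
                                  init_from = NULL) {
  if (restriction == "none") {
    fitA <- fit_group_filter(fdA, index, initA, f0_coeffsA, config)
    fitB <- fit_group_filter(fdB, index, initB, f0_coeffsB, config)
    return(structure(list(restriction = "none",
                          loglik = fitA$loglik + fitB$loglik, df = 0L,
                          fitA = fitA, fitB = fitB,
                          converged = fitA$converged && fitB$converged),
                     class = "spm_two_group_fit"))
  }
  shared <- spm_hypothesis_box_idx(restriction)
  if (!is.null(init_from)) {
    initA <- init_from$fitA$params
    initB <- init_from$fitB$params
  }
  if (is.null(initA)) initA <- init_from_moments(fdA, f0_coeffsA, c(40, 110))
  if (is.null(initB)) initB <- init_from_moments(fdB, f0_coeffsB, c(40, 110))
  w <- initA$age_window
  f1b <- resolve_f1_bounds(config, index)
  bbA <- spm_box_bounds(initA, f1b)
  bbB <- spm_box_bounds(initB, f1b)
  free <- setdiff(1:10, shared)
  vA0 <- theta_to_box(spm_par_vector(initA), w)
  vB0 <- theta_to_box(spm_par_vector(initB), w)
  vA0[shared] <- vB0[shared] <- (vA0[shared] + vB0[shared]) / 2
  # joint vector: group A's 10 box values (shared pair lives here),
  # then group B's 8 free values
  lower <- c(pmax(bbA$lower, replace(rep(-Inf, 10), shared, bbB$lower[shared])),
             bbB$lower[free])
  upper <- c(pmin(bbA$upper, replace(rep(Inf, 10), shared, bbB$upper[shared])),
             bbB$upper[free])
  u0 <- clamp(c(vA0, vB0[free]), lower + 1e-9, upper - 1e-9)
  objA <- spm_obj_factory(fdA, initA, w)
  objB <- spm_obj_factory(fdB, initB, w)
  unpackB <- function(u) {
    vB <- numeric(10)
    vB[shared] <- u[shared]
    vB[free] <- u[11:18]
    vB
  }
  obj <- function(u) objA$fn(u[1:10]) + objB$fn(unpackB(u))
  grad <- function(u) {
    gA <- objA$gr(u[1:10])
    gB <- objB$gr(unpackB(u))
    g <- c(gA, gB[free])
    g[shared] <- g[shared] + gB[shared]
    g
  }
  set.seed(config$seed)
  starts <- list(u0)
  if (config$n_starts > 1)
    for (k in 2:config$n_starts)
      starts[[k]] <- perturb_start(u0, lower, upper, config$perturb_sd)
  best <- NULL; nev <- 0L
  scale <- 1 / c(spm_box_typical(u0[1:10]),
                 spm_box_typical(unpackB(u0))[free])
  for (u in starts) {
    r <- nlminb(u, obj, gradient = grad, lower = lower, upper = upper,
                scale = scale,
                control = list(iter.max = config$maxit,
                               eval.max = config$maxit * 15))
    nev <- nev + sum(r$evaluations)
    if (is.null(best) || r$objective < best$objective) best <- r
  }
  for (round in 1:5) {   # restart polish, as in the one-group fitter
    r <- nlminb(best$par, obj, gradient = grad, lower = lower, upper = upper,
                scale = scale,
                control = list(iter.max = config$maxit,
                               eval.max = config$maxit * 15))
    nev <- nev + sum(r$evaluations)
    if (r$objective < best$objective - 1e-6) best <- r else {
      if (r$objective < best$objective) best <- r
      break
    }
  }
  pA <- spm_par_update(initA, box_to_theta(best$par[1:10], w))
  pB <- spm_par_update(initB, box_to_theta(unpackB(best$par), w))
  llA <- cohort_loglik_filter(fdA, pA)$loglik
  llB <- cohort_loglik_filter(fdB, pB)$loglik
  mk <- function(p, ll, fd) structure(
    list(params = p, loglik = ll, converged = best$convergence == 0,
         n_evaluations = nev, seed = config$seed,
         bounds_active = character(0), se = NULL,
         n_subjects = fd$n_subjects, n_excluded = length(fd$excluded),
         index = index),
    class = "spm_fit")
  structure(list(restriction = restriction, loglik = llA + llB, df = 2L,
                 fitA = mk(pA, llA, fdA), fitB = mk(pB, llB, fdB),
                 converged = best$convergence == 0),
            class = "spm_two_group_fit")
}

#' @export
print.spm_two_group_fit <- function(x, ...) {
  cat(sprintf("Two-group SPM fit (restriction: %s): joint loglik = %.4f\n",
              x$restriction, x$loglik))
  invisible(x)
}

#' Likelihood-ratio test between nested two-group fits
#'
#' The statistic is twice the log-likelihood gain of the unrestricted
#' model; under the null of an equated parameter pair it is chi-square
#' with 2 degrees of freedom.
#'
#' @param unrestricted,restricted `spm_two_group_fit` objects sharing
#'   the same data (restricted must carry a named restriction).
#' @return A list of class `spm_lrt`: `name`, `loglik_unrestricted`,
#'   `loglik_restricted`, `df`, `statistic`, `p`.
#' @export
likelihood_ratio_test <- function(unrestricted, restricted) {
  if (restricted$restriction == "none")
    stop("'restricted' must carry one of the four named restrictions")
  stat <- 2 * (unrestricted$loglik - restricted$loglik)
  if (stat < -1e-3)
    warning("restricted log-likelihood exceeds the unrestricted one by ",
            sprintf("%.4g", -stat / 2), "; optimisation may have failed")
  stat <- max(stat, 0)
  df <- restricted$df
  structure(list(name = restricted$restriction,
                 loglik_unrestricted = unrestricted$loglik,
                 loglik_restricted = restricted$loglik,
                 df = df, statistic = stat,
                 p = pchisq(stat, df, lower.tail = FALSE)),
            class = "spm_lrt")
}

#' @export
print.spm_lrt <- function(x, ...) {
  cat(sprintf("LRT %s: chi2(%d) = %.4f, p = %.4g\n",
              x$name, x$df, x$statistic, x$p))
  invisible(x)
}

#' The four group-comparison hypothesis tests
#'
#' Fits the unrestricted two-group model once, then each restricted
#' model (equal baseline hazards, equal quadratic terms, equal adaptive
#' capacities, equal allostatic trajectories), and reports the four
#' likelihood-ratio tests.
#'
#' @inheritParams fit_two_groups
#' @param hypotheses which of the four tests to run.
#' @return A list with `unrestricted`, `restricted` (named list of
#'   fits) and `table`, a data frame with one row per test: the two
#'   log-likelihoods, df, statistic, p-value and its band symbol.
#' @export
spm_hypothesis_tests <- function(cohortA, cohortB,
                                 index = spm_indices(cohortA)[1],
                                 hypotheses = names(spm_hypotheses()),
                                 initA = NULL, initB = NULL,
                                 f0_coeffsA = NULL, f0_coeffsB = NULL,
                                 config = spm_fit_config()) {
  fdA <- prepare_cohort_filter(cohortA, index, config$min_age)
  fdB <- prepare_cohort_filter(cohortB, index, config$min_age)
  unres <- fit_two_groups_filter(fdA, fdB, index, "none", initA, initB,
                                 f0_coeffsA, f0_coeffsB, config)
  # restricted fits start from the unrestricted optimum (with the equated
  # pair averaged): a single start suffices there
  config_res <- config
  config_res$n_starts <- 1
  res <- list(); rows <- list()
  for (h in hypotheses) {
    res[[h]] <- fit_two_groups_filter(fdA, fdB, index, h, config = config_res,
                                      init_from = unres)
    lrt <- likelihood_ratio_test(unres, res[[h]])
    rows[[h]] <- data.frame(hypothesis = h,
                            loglik_unrestricted = lrt$loglik_unrestricted,
                            loglik_restricted = lrt$loglik_restricted,
                            df = lrt$df, statistic = lrt$statistic,
                            p = lrt$p, band = significance_band(lrt$p))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(unrestricted = unres, restricted = res, table = tab)
}
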