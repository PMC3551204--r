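#' One-year survival factor under a Gaussian belief
#'
#' Probability of surviving one year when the index is distributed
#' N(m, gamma) among current survivors and the hazard is the quadratic
#' form mu0(t) + Q(t)(y - f0(t))^2, together with the conditional
#' (selection-updated) belief among those who survive. With
#' k = 1 + 2 Q(t) gamma the closed form is
#' \deqn{p = e^{-\mu_0(t)} k^{-1/2} \exp(-Q(t)(m - f_0(t))^2 / k),}
#' \deqn{m^* = f_0(t) + (m - f_0(t)) / k, \qquad \gamma^* = \gamma / k.}
#'
#' @param b a [gaussian_belief()].
#' @param p an [spm_parameters()] object.
#' @return List with elements `prob` (in (0, 1]) and `updated`
#'   (a [gaussian_belief()] at the same age).
#' @export
survival_factor <- function(b, p) {
  Q <- eval_quadratic_term(b$t, p)
  mu0 <- eval_baseline_hazard(b$t, p)
  if (Q < 0) stop("Q(t) < 0 at age ", b$t)
  if (mu0 < 0) stop("mu0(t) < 0 at age ", b$t)
  if (b$gamma < 0) stop("belief variance < 0")
  f0 <- eval_norm(b$t, p)
  k <- 1 + 2 * Q * b$gamma
  if (k <= 0) stop("constraint violation: 1 + 2*Q*gamma <= 0 at age ", b$t)
  dev <- b$m - f0
  prob <- exp(-mu0) / sqrt(k) * exp(-Q * dev^2 / k)
  list(prob = prob,
       updated = gaussian_belief(f0 + dev / k, b$gamma / k, b$t))
}

#' One-year dynamics step of the Gaussian belief
#'
#' Discrete-time propagation of the index over one year:
#' `m' = m + a(t)(m - f1(t))`, `gamma' = (1 + a(t))^2 gamma + sigma1^2`.
#'
#' @inheritParams survival_factor
#' @return The propagated [gaussian_belief()] at age `t + 1`.
#' @export
dynamics_step <- function(b, p) {
  a <- eval_adaptive_capacity(b$t, p)
  f1 <- eval_setpoint(b$t, p)
  gaussian_belief(b$m + a * (b$m - f1),
                  (1 + a)^2 * b$gamma + p$sigma1^2,
                  b$t + 1)
}

#' Observation update of the Gaussian belief
#'
#' Returns the Gaussian log-density of the observed index value under
#' the predictive law and resets the belief to the observation
#' (observations are treated as exact). First observations use the
#' entry law N(f1(t), sigma0^2); later observations use the propagated
#' belief (m, gamma).
#'
#' @inheritParams survival_factor
#' @param y observed index value.
#' @param first logical; is this the subject's first usable observation?
#' @return List with `logdensity` and `updated` (belief (y, 0) at the
#'   same age).
#' @export
observation_update <- function(b, y, p, first = FALSE) {
  if (first) {
    mu <- eval_setpoint(b$t, p)
    v <- p$sigma0^2
  } else {
    mu <- b$m
    v <- b$gamma
    if (v <= 0)
      stop("data-alignment error: repeated observation at age ", b$t,
           " with zero predictive variance")
  }
  list(logdensity = dnorm(y, mu, sqrt(v), log = TRUE),
       updated = gaussian_belief(y, 0, b$t))
}

# Prepare one subject's data for the integer-year filter grid.
# Returns NULL if the subject has no usable exam (reported by the caller).
prepare_subject_filter <- function(exam_age, value, event_age, death,
                                   min_age = 40) {
  if (any(diff(exam_age) <= 0)) stop("non-monotone exam ages")
  keep <- !is.na(value) & exam_age >= min_age
  if (!any(keep)) return(NULL)
  age <- round(exam_age[keep])
  val <- value[keep]
  dup <- duplicated(age)          # two exams rounding to the same year:
  age <- age[!dup]; val <- val[!dup]  # keep the first
  tend <- max(round(event_age), age[length(age)])
  list(exam_age = as.integer(age), value = val,
       entry = as.integer(age[1]), tend = as.integer(tend),
       death = as.integer(death != 0))
}

#' Log-likelihood of one subject under the stochastic process model
#'
#' Assembles the conditional-Gaussian filtering likelihood on the
#' integer-year age grid: the first usable exam contributes the entry
#' density N(f1(t0), sigma0^2) (conditioning on survival to entry is
#' implicit, so no survival factors accrue before it); each later exam
#' contributes the predictive Gaussian density and resets the belief to
#' the observed value; each whole year lived contributes the log
#' one-year survival factor followed by the dynamics step; a death in
#' year T contributes log(1 - prob) from the belief at T instead.
#'
#' @param subject a list or one-row data frame with elements/columns
#'   `exam_age` (numeric vector), `value` (numeric vector), `event_age`,
#'   `death` (0/1).
#' @param p an [spm_parameters()] object.
#' @param min_age minimum exam age used (years); earlier exams are
#'   ignored.
#' @return The subject log-likelihood, or `NA` (with a warning) if the
#'   subject has no usable exam.
#' @export
subject_loglik <- function(subject, p, min_age = 40) {
  d <- prepare_subject_filter(subject$exam_age, subject$value,
                              subject$event_age, subject$death, min_age)
  if (is.null(d)) {
    warning("subject has no usable exam at ages >= ", min_age, "; excluded")
    return(NA_real_)
  }
  ll <- 0
  b <- gaussian_belief(0, 0, d$entry)
  first <- TRUE
  for (t in d$entry:d$tend) {
    i <- match(t, d$exam_age)
    if (!is.na(i)) {
      o <- observation_update(b, d$value[i], p, first = first)
      ll <- ll + o$logdensity
      b <- o$updated
      first <- FALSE
    }
    if (t == d$tend) {
      if (d$death == 1L) {
        s <- survival_factor(b, p)
        ll <- ll + log1p(-s$prob)
      }
      break
    }
    s <- survival_factor(b, p)
    ll <- ll + log(s$prob)
    b <- dynamics_step(s$updated, p)
  }
  ll
}

# Flatten a cohort's exams into the CSR-style arrays consumed by the
# C++ kernel. Subjects with no usable exam are dropped and counted.
prepare_cohort_filter <- function(cohort, index, min_age = 40) {
  subjects <- cohort$subjects
  exams <- cohort$exams[cohort$exams$index == index, , drop = FALSE]
  n <- nrow(subjects)
  ex_split <- split(exams[c("exam_age", "value")],
                    factor(exams$id, levels = subjects$id))
  per <- vector("list", n)
  keep <- logical(n)
  for (j in seq_len(n)) {
    e <- ex_split[[j]]
    if (is.null(e) || nrow(e) == 0) next
    o <- order(e$exam_age)
    d <- prepare_subject_filter(e$exam_age[o], e$value[o],
                                subjects$event_age[j], subjects$death[j],
                                min_age)
    if (is.null(d)) next
    per[[j]] <- d
    keep[j] <- TRUE
  }
  per <- per[keep]
  nlen <- vapply(per, function(d) length(d$exam_age), integer(1))
  list(entry = vapply(per, `[[`, integer(1), "entry"),
       tend = vapply(per, `[[`, integer(1), "tend"),
       death = vapply(per, `[[`, integer(1), "death"),
       exam_ptr = c(0L, cumsum(nlen)),
       exam_age = unlist(lapply(per, `[[`, "exam_age")),
       exam_val = unlist(lapply(per, `[[`, "value")),
       n_subjects = length(per), excluded = subjects$id[!keep])
}

#' Cohort log-likelihood under the stochastic process model
#'
#' Sum of [subject_loglik()] over all included subjects for one
#' physiological index. The default engine is a compiled kernel; the
#' pure-R engine exists for cross-checking and always agrees with it.
#'
#' @param cohort an `spm_cohort` (see [as_spm_cohort()]).
#' @param p an [spm_parameters()] object.
#' @param index name of the physiological index to use (matches the
#'   `index` column of the exams table).
#' @param min_age minimum exam age used (years).
#' @param engine `"cpp"` (default) or `"r"`.
#' @return A list of class `spm_loglik` with `loglik`, `n_subjects`,
#'   `n_death_terms`, `n_observation_terms`, `n_excluded`.
#' @export
cohort_loglik <- function(cohort, p, index = spm_indices(cohort)[1],
                          min_age = 40, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  fd <- prepare_cohort_filter(cohort, index, min_age)
  if (fd$n_subjects == 0) stop("empty cohort: no subject has a usable exam")
  res <- cohort_loglik_filter(fd, p, engine)
  structure(c(res, list(n_subjects = fd$n_subjects,
                        n_excluded = length(fd$excluded))),
            class = "spm_loglik")
}

# likelihood on pre-flattened filter data (used in fitting loops to avoid
# re-preparing the cohort at every objective evaluation)
cohort_loglik_filter <- function(fd, p, engine = "cpp") {
  if (engine == "cpp") {
    spm_cohort_loglik_cpp(fd$entry, fd$tend, fd$death, fd$exam_ptr,
                          fd$exam_age, fd$exam_val,
                          spm_par_vector(p), p$f0_coeffs)
  } else {
    ll <- 0; nobs <- 0L; ndeath <- 0L
    for (j in seq_len(fd$n_subjects)) {
      idx <- (fd$exam_ptr[j] + 1L):fd$exam_ptr[j + 1L]
      s <- list(exam_age = fd$exam_age[idx], value = fd$exam_val[idx],
                event_age = fd$tend[j], death = fd$death[j])
      ll <- ll + subject_loglik(s, p, min_age = 0)  # already filtered
      nobs <- nobs + length(idx)
      ndeath <- ndeath + fd$death[j]
    }
    list(loglik = ll, n_death_terms = ndeath, n_observation_terms = nobs)
  }
}

#' @export
print.spm_loglik <- function(x, ...) {
  cat(sprintf("SPM cohort log-likelihood: %.4f\n", x$loglik))
  cat(sprintf("  %d subjects (%d excluded), %d observation terms, %d death terms\n",
              x$n_subjects, x$n_excluded, x$n_observation_terms, x$n_death_terms))
  invisible(x)
}
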