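# cubic through four (age, value) points; coefficients lowest degree first
cubic_through_points <- function(t, y) {
  stopifnot(length(t) == 4, length(y) == 4)
  as.numeric(solve(outer(t, 0:3, `^`), y))
}

#' Illustrative default parameter sets for a BMI-like index
#'
#' Two parameter sets for the carrier-dose groups of a synthetic cohort.
#' They are illustrative defaults, not estimates from any real cohort:
#' the low-dose (<14) group has a norm trajectory peaking near age 55,
#' weaker adaptive capacity, an age-increasing quadratic hazard term and
#' a higher baseline hazard; the high-dose (>=14) group has a norm
#' peaking near age 75, stronger adaptive capacity, an age-decreasing
#' quadratic term and a lower baseline hazard.
#'
#' @param group `"low"` (<14 alleles) or `"high"` (>=14 alleles).
#' @return An [spm_parameters()] object.
#' @export
spm_default_parameters <- function(group = c("low", "high")) {
  group <- match.arg(group)
  if (group == "low") {
    f0 <- cubic_through_points(c(40, 55, 75, 95), c(26.3, 27.3, 26.6, 24.8))
    spm_parameters(a_Y = -0.06, b_Y = 2e-4, sigma1 = 0.6, sigma0 = 3,
                   a_Q = 5e-5, b_Q = 2e-6, a_mu0 = 3e-5, b_mu0 = 0.095,
                   a_f0d = 1.5, b_f0d = -0.01, f0_coeffs = f0)
  } else {
    f0 <- cubic_through_points(c(40, 60, 75, 95), c(24.5, 26.0, 26.5, 25.5))
    spm_parameters(a_Y = -0.09, b_Y = 2e-4, sigma1 = 0.6, sigma0 = 3,
                   a_Q = 2.2e-4, b_Q = -1.8e-6, a_mu0 = 2e-5, b_mu0 = 0.097,
                   a_f0d = 0.5, b_f0d = 0, f0_coeffs = f0)
  }
}

#' Recipe for generating a synthetic longitudinal cohort
#'
#' Collects every knob of the generator: per-dose-group model
#' parameters, the exam schedule (biennial by default, emulating
#' biennial cohort examinations), entry-age and censoring assumptions,
#' the SNP panel with its minor-allele frequencies, optional
#' proportional-hazards mortality (for Cox-model harnesses), disease
#' onset rates, and the master seed from which all randomness flows.
#'
#' @param n_subjects number of subjects.
#' @param seed master seed (mandatory; every random draw derives from it).
#' @param index name of the physiological index generated.
#' @param params named list of [spm_parameters()] for the `"<14"` and
#'   `">=14"` dose groups.
#' @param dose_threshold carrier-count split between the groups.
#' @param entry_age_range ages (years) of the uniform entry-age law.
#' @param exam_interval years between scheduled exams (2 = biennial).
#' @param exam_missingness probability that an attended exam has a
#'   missing index value.
#' @param censor_age administrative censoring age (years).
#' @param panel SNP panel data frame (`rsid`, `maf` in percent).
#' @param mode `"spm"` (deaths from the quadratic hazard on the yearly
#'   grid) or `"ph"` (deaths from a Gompertz proportional-hazards model
#'   with per-allele dose effects, drawn in continuous time so the data
#'   satisfy the Cox model assumptions exactly).
#' @param ph list for `mode = "ph"`: `gompertz_level`, `gompertz_slope`,
#'   and `causes`, a data frame with columns `cause`, `weight`
#'   (cause-specific share of the baseline hazard) and `beta_dose`
#'   (per-allele log hazard ratio).
#' @param covariate_effects named log-hazard-ratio vector applied in
#'   `"ph"` mode: `sex_female`, `smoking`, `birth_decade` (per decade
#'   from 1900).
#' @param cause_weights death-cause assignment probabilities in `"spm"`
#'   mode.
#' @param disease_onset named list (`cancer`, `cvd`, `diabetes`) of
#'   Gompertz onset-rate parameters `c(level, slope)`, or `NULL` for no
#'   onsets.
#' @param onset_coupling log-rate shift of the onset hazards per unit
#'   deviation of the index from the norm (0 = onsets independent of the
#'   trajectory, the default).
#' @param female_frac,smoking_frac,apoe_freq marginal frequencies of
#'   female sex, ever-smoking and APOE-e4 carriage.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 1500, seed,
                              index = "BMI",
                              params = list("<14" = spm_default_parameters("low"),
                                            ">=14" = spm_default_parameters("high")),
                              dose_threshold = 14,
                              entry_age_range = c(40, 60),
                              exam_interval = 2,
                              exam_missingness = 0.1,
                              censor_age = 100,
                              panel = snp_panel(),
                              mode = c("spm", "ph"),
                              ph = list(gompertz_level = 8.5e-5,
                                        gompertz_slope = 0.085,
                                        causes = data.frame(
                                          cause = c("CVD", "cancer", "other"),
                                          weight = c(0.29, 0.19, 0.52),
                                          beta_dose = c(-0.047, -0.030, -0.071))),
                              covariate_effects = c(sex_female = -0.25,
                                                    smoking = 0.35,
                                                    birth_decade = 0.0),
                              cause_weights = c(CVD = 0.29, cancer = 0.19,
                                                other = 0.52),
                              disease_onset = list(cancer = c(1.5e-5, 0.085),
                                                   cvd = c(2.0e-5, 0.090),
                                                   diabetes = c(8.0e-6, 0.080)),
                              onset_coupling = 0,
                              female_frac = 0.55, smoking_frac = 0.45,
                              apoe_freq = 0.22) {
  if (missing(seed)) stop("a master seed is mandatory")
  mode <- match.arg(mode)
  stopifnot(exam_missingness >= 0, exam_missingness <= 1,
            entry_age_range[1] < entry_age_range[2],
            censor_age > entry_age_range[2])
  cfg <- as.list(environment())
  structure(cfg, class = "simulation_config")
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Per SNP, minor-allele counts are Binomial(2, MAF), independent across
#' loci (no linkage disequilibrium).
#'
#' @param n number of subjects.
#' @param panel data frame with columns `rsid` and `maf` (percent).
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return Data frame: `id` plus one allele-count column per SNP.
#' @export
simulate_genotypes <- function(n, panel = snp_panel(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- vapply(panel$maf / 100, function(q) rbinom(n, 2L, q), integer(n))
  g <- as.data.frame(g)
  names(g) <- panel$rsid
  cbind(data.frame(id = sprintf("S%05d", seq_len(n))), g)
}

# Gompertz yearly hazard grid from age `from` to `to` (level*exp(slope*t))
gompertz_grid <- function(level, slope, from, to) {
  t <- from:to
  list(t = t, rate = level * exp(slope * t))
}

# first-passage year of a discrete yearly hazard; NA if never
sample_onset_years <- function(n, level, slope, from = 30, to = 110) {
  gg <- gompertz_grid(level, slope, from, to)
  cum <- cumsum(gg$rate)
  e <- rexp(n)
  idx <- findInterval(e, cum) + 1L   # first year where cumulative hazard >= e
  out <- rep(NA_real_, n)
  hit <- idx <= length(gg$t)
  out[hit] <- gg$t[idx[hit]]
  out
}

# Vectorised yearly simulation of SPM trajectories, exams and (optionally)
# quadratic-hazard deaths for one parameter group. Returns per-subject
# event data and the long exam table. `ph_death` = TRUE suppresses the
# SPM death draw (mortality handled elsewhere).
simulate_spm_group <- function(p, entry, censor_age, exam_interval,
                               exam_missingness, ids, ph_death = FALSE,
                               onset_coupling = 0, disease_onset = NULL) {
  n <- length(entry)
  alive <- rep(TRUE, n)
  started <- rep(FALSE, n)
  y <- rep(NA_real_, n)
  event_age <- rep(NA_real_, n)
  death <- rep(0L, n)
  exam_id <- character(0); exam_age <- numeric(0); exam_val <- numeric(0)
  onset <- if (!is.null(disease_onset))
    matrix(NA_real_, n, length(disease_onset),
           dimnames = list(NULL, names(disease_onset))) else NULL
  onset_from <- 30L
  for (t in onset_from:(censor_age - 1L)) {
    enter <- alive & !started & entry == t
    if (any(enter)) {
      y[enter] <- rnorm(sum(enter), eval_setpoint(t, p), p$sigma0)
      started[enter] <- TRUE
    }
    act <- alive & started
    # disease onsets (coupled to the trajectory once it exists)
    if (!is.null(onset)) {
      for (d in seq_along(disease_onset)) {
        par <- disease_onset[[d]]
        cand <- alive & is.na(onset[, d]) & t >= onset_from
        if (!any(cand)) next
        dev <- ifelse(started[cand], y[cand] - eval_norm(t, p), 0)
        rate <- par[1] * exp(par[2] * t + onset_coupling * dev)
        hit <- runif(sum(cand)) < -expm1(-rate)
        onset[cand, d][hit] <- t
      }
    }
    if (any(act)) {
      scheduled <- act & (t - entry) %% exam_interval == 0
      if (any(scheduled)) {
        k <- sum(scheduled)
        val <- y[scheduled]
        val[runif(k) < exam_missingness] <- NA_real_
        exam_id <- c(exam_id, ids[scheduled])
        exam_age <- c(exam_age, rep(t, k))
        exam_val <- c(exam_val, val)
      }
      if (!ph_death) {
        mu <- eval_hazard(t, y[act], p)
        dies <- runif(sum(act)) < -expm1(-mu)
        if (any(dies)) {
          who <- which(act)[dies]
          alive[who] <- FALSE
          death[who] <- 1L
          # death occurred during year [t, t+1); the recorded age stays in
          # the first half-year so the rounded filter year equals the year
          # the death was drawn in, while survival-time follow-up stays
          # strictly positive
          event_age[who] <- t + runif(length(who), 0, 0.5)
        }
      }
      act <- alive & started
      if (any(act)) {
        a <- eval_adaptive_capacity(t, p)
        y[act] <- y[act] + a * (y[act] - eval_setpoint(t, p)) +
          p$sigma1 * rnorm(sum(act))
      }
    }
  }
  event_age[alive] <- censor_age
  list(event_age = event_age, death = death,
       exams = data.frame(id = exam_id, exam_age = exam_age, value = exam_val,
                          stringsAsFactors = FALSE),
       onset = onset)
}

#' Simulate a single subject's trajectory and survival
#'
#' One-subject convenience wrapper around the vectorised group
#' simulator: yearly Euler dynamics for the index from a
#' N(f1(entry), sigma0^2) start, biennial exams while alive, and death
#' drawn each year with probability 1 - exp(-mu(t, Y)).
#'
#' @param p an [spm_parameters()] object (refused if infeasible).
#' @param entry_age integer entry age (years).
#' @param censor_age administrative censoring age.
#' @param exam_interval years between exams.
#' @param exam_missingness per-exam missing-value probability.
#' @param seed optional seed.
#' @return List with `entry_age`, `event_age`, `death` and an `exams`
#'   data frame (`exam_age`, `value`).
#' @export
simulate_subject <- function(p, entry_age, censor_age = 100,
                             exam_interval = 2, exam_missingness = 0,
                             seed = NULL) {
  bad <- check_spm_parameters(p)
  if (length(bad)) stop("infeasible parameters: ", bad[1])
  if (!is.null(seed)) set.seed(seed)
  g <- simulate_spm_group(p, as.integer(round(entry_age)), censor_age,
                          exam_interval, exam_missingness, ids = "S00001")
  list(entry_age = as.integer(round(entry_age)), event_age = g$event_age,
       death = g$death,
       exams = g$exams[c("exam_age", "value")])
}

#' Simulate a full synthetic cohort
#'
#' Generates genotypes under Hardy-Weinberg equilibrium at the panel
#' minor-allele frequencies, the polygenic carrier-count dose and its
#' group split, demographic covariates, index trajectories with
#' biennial exams, mortality (quadratic-hazard on the yearly grid in
#' `"spm"` mode; continuous-time Gompertz proportional hazards with
#' per-allele dose effects in `"ph"` mode), cause-of-death assignment
#' and disease onsets. All randomness flows from `config$seed`; a rerun
#' with the same config is identical.
#'
#' @param config a [simulation_config()].
#' @return An `spm_cohort` with a `manifest` attribute recording the
#'   seed and config.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  for (g in names(config$params)) {
    bad <- check_spm_parameters(config$params[[g]])
    if (length(bad))
      stop("infeasible parameters for group '", g, "': ", bad[1])
  }
  set.seed(config$seed)
  n <- config$n_subjects
  geno <- simulate_genotypes(n, config$panel)
  dose <- polygenic_score(geno)
  grp <- ifelse(dose < config$dose_threshold, "<14", ">=14")
  ids <- geno$id
  sex <- ifelse(runif(n) < config$female_frac, "F", "M")
  smoking <- ifelse(runif(n) < config$smoking_frac, "ever", "never")
  birth_decade <- sample(seq(1880, 1920, by = 10), n, replace = TRUE)
  apoe_e4 <- as.integer(runif(n) < config$apoe_freq)

  if (config$mode == "spm") {
    entry <- sample(seq(config$entry_age_range[1], config$entry_age_range[2]),
                    n, replace = TRUE)
    event_age <- numeric(n); death <- integer(n)
    exams <- list()
    onset <- matrix(NA_real_, n, 3,
                    dimnames = list(NULL, c("cancer", "cvd", "diabetes")))
    for (g in names(config$params)) {
      sel <- grp == g
      if (!any(sel)) next
      r <- simulate_spm_group(config$params[[g]], entry[sel],
                              config$censor_age, config$exam_interval,
                              config$exam_missingness, ids[sel],
                              onset_coupling = config$onset_coupling,
                              disease_onset = config$disease_onset)
      event_age[sel] <- r$event_age
      death[sel] <- r$death
      exams[[g]] <- r$exams
      if (!is.null(r$onset)) onset[sel, ] <- r$onset
    }
    exams <- do.call(rbind, exams)
    cause <- rep("none", n)
    d <- death == 1L
    cause[d] <- sample(names(config$cause_weights), sum(d), replace = TRUE,
                       prob = config$cause_weights)
  } else {
    entry <- runif(n, config$entry_age_range[1], config$entry_age_range[2])
    cz <- config$ph$causes
    b <- config$ph$gompertz_slope
    ce <- config$covariate_effects
    covlp <- ce[["sex_female"]] * (sex == "F") +
      ce[["smoking"]] * (smoking == "ever") +
      ce[["birth_decade"]] * (birth_decade - 1900) / 10
    # per-subject cause-specific hazard levels; shared Gompertz slope makes
    # the all-cause cumulative hazard analytically invertible
    lev <- sapply(seq_len(nrow(cz)), function(i)
      config$ph$gompertz_level * cz$weight[i] *
        exp(cz$beta_dose[i] * dose + covlp))
    tot <- rowSums(lev)
    e <- rexp(n)
    # survival to entry is conditioned on by construction (delayed entry)
    death_time <- log(exp(b * entry) + e * b / tot) / b
    death <- as.integer(death_time < config$censor_age)
    event_age <- pmin(death_time, config$censor_age)
    cause <- rep("none", n)
    d <- death == 1L
    if (any(d))
      cause[d] <- vapply(which(d), function(i)
        sample(cz$cause, 1, prob = lev[i, ]), character(1))
    # trajectories: same SPM dynamics, mortality handled above
    exams <- list()
    ientry <- as.integer(ceiling(entry))
    for (g in names(config$params)) {
      sel <- grp == g
      if (!any(sel)) next
      r <- simulate_spm_group(config$params[[g]], ientry[sel],
                              config$censor_age, config$exam_interval,
                              config$exam_missingness, ids[sel],
                              ph_death = TRUE)
      exams[[g]] <- r$exams
    }
    exams <- do.call(rbind, exams)
    # drop exams recorded after the (independent) death time
    keep <- exams$exam_age <= event_age[match(exams$id, ids)]
    exams <- exams[keep, , drop = FALSE]
    onset <- matrix(NA_real_, n, 3,
                    dimnames = list(NULL, c("cancer", "cvd", "diabetes")))
    if (!is.null(config$disease_onset)) {
      for (d2 in seq_along(config$disease_onset)) {
        par <- config$disease_onset[[d2]]
        onset[, d2] <- sample_onset_years(n, par[1], par[2])
      }
    }
  }
  onset[!is.na(onset) & onset > event_age] <- NA_real_
  subjects <- data.frame(
    id = ids, sex = sex, birth_decade = birth_decade, smoking = smoking,
    entry_age = entry, event_age = event_age, death = death, cause = cause,
    onset_cancer = onset[, "cancer"], onset_cvd = onset[, "cvd"],
    onset_diabetes = onset[, "diabetes"], apoe_e4 = apoe_e4, dose = dose,
    dose_group = grp, stringsAsFactors = FALSE)
  exams <- data.frame(id = exams$id, exam_age = exams$exam_age,
                      index = config$index, value = exams$value,
                      stringsAsFactors = FALSE)
  exams <- exams[order(match(exams$id, ids), exams$exam_age), , drop = FALSE]
  rownames(exams) <- NULL
  cohort <- as_spm_cohort(subjects, exams, geno)
  attr(cohort, "manifest") <- list(seed = config$seed, mode = config$mode,
                                   n_subjects = n, index = config$index)
  cohort
}

#' Survivor-ensemble Monte-Carlo oracle for the mean dynamics
#'
#' Simulates `n` index trajectories with a fine-step Euler scheme,
#' killing each trajectory in every step with probability
#' `1 - exp(-mu(t, Y) dt)`, and records the mean and variance of the
#' survivors at every integer age. This is the independent simulation
#' oracle against which [integrate_mean_trajectory()] (the mean/variance
#' ODE system) is validated.
#'
#' @param p an [spm_parameters()] object.
#' @param n number of simulated trajectories.
#' @param t0,t1 start and end ages.
#' @param m0,gamma0 initial mean and variance of the index
#'   (defaults: f1(t0) and sigma0^2).
#' @param step Euler step in years (well below 1 year, so the discrete
#'   scheme approximates the continuous dynamics the ODE describes).
#' @param seed optional seed.
#' @return Data frame with columns `t` (integer ages), `n_alive`,
#'   `mean`, `var`, `se_mean`, `se_var`.
#' @export
simulate_ensemble <- function(p, n, t0, t1, m0 = NULL, gamma0 = NULL,
                              step = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(m0)) m0 <- eval_setpoint(t0, p)
  if (is.null(gamma0)) gamma0 <- p$sigma0^2
  nsteps <- round((t1 - t0) / step)
  stopifnot(abs(nsteps * step - (t1 - t0)) < 1e-9)
  y <- rnorm(n, m0, sqrt(gamma0))
  alive <- rep(TRUE, n)
  rec <- list()
  record <- function(t) {
    ys <- y[alive]
    v <- stats::var(ys)
    data.frame(t = t, n_alive = length(ys), mean = mean(ys), var = v,
               se_mean = sqrt(v / length(ys)),
               se_var = v * sqrt(2 / (length(ys) - 1)))
  }
  rec[[1]] <- record(t0)
  sqdt <- sqrt(step)
  for (i in seq_len(nsteps)) {
    t <- t0 + (i - 1) * step
    mu <- eval_hazard(t, y[alive], p)
    dies <- runif(sum(alive)) < -expm1(-mu * step)
    alive[which(alive)[dies]] <- FALSE
    a <- eval_adaptive_capacity(t, p)
    f1 <- eval_setpoint(t, p)
    y[alive] <- y[alive] + a * (y[alive] - f1) * step +
      p$sigma1 * sqdt * rnorm(sum(alive))
    tnext <- t0 + i * step
    if (abs(tnext - round(tnext)) < 1e-9) rec[[length(rec) + 1]] <- record(round(tnext))
  }
  out <- do.call(rbind, rec)
  rownames(out) <- NULL
  out
}
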