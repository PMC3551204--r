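#' Reference panel of 27 pro-survival SNPs
#'
#' The 27 loci whose minor alleles were individually associated with
#' longer lifespan, with their minor-allele frequencies (percent) and
#' chromosomes. Used as the default panel of the genotype simulator and
#' of the polygenic carrier-count score.
#'
#' @return Data frame with columns `rsid`, `maf` (percent) and `chr`,
#'   27 rows.
#' @export
snp_panel <- function() {
  p <- data.frame(
    rsid = c("rs4648884", "rs3120819", "rs1974676", "rs432203",
             "rs12623542", "rs13008689", "rs1834497", "rs9876781",
             "rs10937739", "rs1205035", "rs3800358", "rs10256972",
             "rs1327533", "rs2590504", "rs10819510", "rs739401",
             "rs2370413", "rs9517320", "rs4148544", "rs41383",
             "rs16975963", "rs2024714", "rs2826891", "rs139170",
             "rs5771675", "rs9616906", "rs13053175"),
    maf = c(27.7, 42.1, 35.4, 38.0, 36.7, 23.2, 44.7, 34.9, 41.9, 36.2,
            25.9, 36.5, 25.3, 37.3, 26.5, 32.4, 35.2, 30.8, 24.6, 25.0,
            46.7, 26.8, 36.5, 34.7, 30.9, 22.7, 28.0),
    chr = c(1, 1, 2, 2, 2, 2, 3, 3, 4, 6, 6, 7, 9, 9, 9, 11, 12, 13,
            13, 16, 19, 20, 21, 22, 22, 22, 22))
  stopifnot(nrow(p) == 27, all(p$maf > 0 & p$maf <= 50))
  p
}

#' Carrier indicator at one SNP
#'
#' Dichotomises a genotype: 1 if the individual carries at least one
#' minor allele (heterozygote or minor-allele homozygote), 0 for a
#' major-allele homozygote.
#'
#' @param genotype numeric vector of minor-allele counts (0, 1, 2) or
#'   already-dichotomised 0/1 values.
#' @param missing_as_zero if `TRUE` (default) a missing genotype counts
#'   as non-carrier; if `FALSE` it propagates NA.
#' @return Integer vector of 0/1 indicators.
#' @export
carrier_indicator <- function(genotype, missing_as_zero = TRUE) {
  out <- as.integer(genotype > 0)
  if (missing_as_zero) out[is.na(out)] <- 0L
  out
}

#' Polygenic carrier-count score ("genetic dose")
#'
#' Counts, across the SNP panel, how many SNPs carry at least one minor
#' allele: an integer from 0 to the panel size. The count is invariant
#' to SNP ordering.
#'
#' @param genotypes data frame or matrix of minor-allele counts,
#'   subjects in rows, SNPs in columns (an `id` column, if present, is
#'   ignored).
#' @param require_complete if `TRUE`, subjects with any missing genotype
#'   get an NA score; otherwise missing genotypes count 0 (conservative
#'   default).
#' @return Integer vector of scores, one per subject.
#' @export
polygenic_score <- function(genotypes, require_complete = FALSE) {
  g <- as.data.frame(genotypes)
  g$id <- NULL
  gm <- as.matrix(g)
  ind <- matrix(carrier_indicator(gm, missing_as_zero = !require_complete),
                nrow = nrow(gm))
  score <- as.integer(rowSums(ind))
  if (require_complete) score[apply(is.na(gm), 1, any)] <- NA_integer_
  score
}

#' Cox regression of cause-specific mortality on the polygenic dose
#'
#' Left-truncated (delayed-entry) proportional-hazards fit on the age
#' scale: subjects enter the risk set at `entry_age` (biospecimen
#' collection) and exit at `event_age`. The event is death from the
#' named cause; deaths from competing causes are censored at the death
#' age; cause `"total"` counts any death. Adjusted for sex, birth
#' cohort (decade of birth, categorical) and smoking (ever/never);
#' Efron tie handling.
#'
#' @param cohort an `spm_cohort` whose subjects carry `dose`, `sex`,
#'   `birth_decade`, `smoking`, `entry_age`, `event_age`, `death`,
#'   `cause`.
#' @param cause one of `"total"`, `"CVD"`, `"cancer"`, `"other"`.
#' @return A list of class `cox_dose` with `cause`, `n_events`,
#'   `n_censored`, `beta`, `se`, `p`, `hr`, `ci_lower`, `ci_upper` (95%
#'   Wald interval) and the underlying `survival::coxph` fit.
#' @export
fit_cox_dose <- function(cohort, cause = c("total", "CVD", "cancer", "other")) {
  cause <- match.arg(cause)
  s <- cohort$subjects
  need <- c("dose", "sex", "birth_decade", "smoking", "entry_age",
            "event_age", "death", "cause")
  miss <- setdiff(need, names(s))
  if (length(miss))
    stop("Cox dose model requires subject column(s): ",
         paste(miss, collapse = ", "))
  s <- s[!is.na(s$dose), , drop = FALSE]
  if (any(s$event_age <= s$entry_age))
    stop("non-positive follow-up time for subject(s) ",
         paste(head(s$id[s$event_age <= s$entry_age], 5), collapse = ", "))
  status <- if (cause == "total") as.integer(s$death == 1)
            else as.integer(s$death == 1 & s$cause == cause)
  if (sum(status) < 2)
    stop("fewer than 2 events for cause '", cause, "'")
  dat <- data.frame(entry = s$entry_age, exit = s$event_age, status = status,
                    dose = s$dose, sex = factor(s$sex),
                    birth_decade = factor(s$birth_decade),
                    smoking = factor(s$smoking))
  fit <- survival::coxph(
    survival::Surv(entry, exit, status) ~ dose + sex + birth_decade + smoking,
    data = dat, ties = "efron")
  beta <- unname(coef(fit)["dose"])
  se <- sqrt(vcov(fit)["dose", "dose"])
  z <- beta / se
  structure(list(cause = cause,
                 n_events = sum(status),
                 n_censored = nrow(dat) - sum(status),
                 beta = beta, se = se,
                 p = 2 * pnorm(-abs(z)),
                 hr = exp(beta),
                 ci_lower = exp(beta - 1.96 * se),
                 ci_upper = exp(beta + 1.96 * se),
                 fit = fit),
            class = "cox_dose")
}

#' @export
print.cox_dose <- function(x, ...) {
  cat(sprintf("Cox dose model, cause = %s: %d events, %d censored\n",
              x$cause, x$n_events, x$n_censored))
  cat(sprintf("  beta = %.4f (SE %.4f), p = %.3g, HR = %.3f (95%% CI %.3f-%.3f)\n",
              x$beta, x$se, x$p, x$hr, x$ci_lower, x$ci_upper))
  invisible(x)
}

#' Cause-specific Cox dose fits for all causes
#'
#' @param cohort an `spm_cohort` (see [fit_cox_dose()]).
#' @param causes character vector of causes to fit.
#' @return Data frame with one row per cause: events, censored, beta,
#'   SE, p, HR and its 95% CI.
#' @export
cox_dose_table <- function(cohort, causes = c("total", "CVD", "cancer", "other")) {
  rows <- lapply(causes, function(cz) {
    f <- fit_cox_dose(cohort, cz)
    data.frame(cause = cz, n_events = f$n_events, n_censored = f$n_censored,
               beta = f$beta, se = f$se, p = f$p, hr = f$hr,
               ci_lower = f$ci_lower, ci_upper = f$ci_upper)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
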