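#' Fixed age-bin scheme for trajectory summaries
#'
#' Pooled exam measurements are summarised in the bins `<35`, `35-39`,
#' five-year bins up to `85-89`, and `90+`.
#'
#' @return Character vector of ordered bin labels.
#' @export
age_bin_levels <- function() {
  lo <- seq(35, 85, by = 5)
  c("<35", paste0(lo, "-", lo + 4), "90+")
}

#' Assign ages to the fixed bin scheme
#'
#' @param age numeric vector of ages in years.
#' @return Factor with levels [age_bin_levels()].
#' @export
assign_age_bin <- function(age) {
  lev <- age_bin_levels()
  idx <- findInterval(age, c(-Inf, seq(35, 90, by = 5), Inf))
  factor(lev[idx], levels = lev)
}

# midpoints used when fitting smooth curves to binned means
age_bin_midpoints <- function() c(32.5, seq(37, 87, by = 5), 92.5)

#' Age-binned average trajectory of pooled measurements
#'
#' Per bin: number of measurements, mean, standard deviation and
#' standard error (sample SD / sqrt(n)). Bins with fewer than `min_n`
#' measurements are suppressed (mean/SD/SE reported as NA), matching the
#' convention of not showing averages based on fewer than 10
#' observations.
#'
#' @param age,value numeric vectors of equal length: measurement ages
#'   and index values pooled over all exams. NA values are dropped.
#' @param min_n minimum number of observations for a bin to be shown.
#' @param index,group optional labels carried into the output.
#' @return A data frame of class `trajectory_summary` with columns
#'   `index`, `group`, `bin`, `n`, `mean`, `sd`, `se`.
#' @export
average_trajectory <- function(age, value, min_n = 10,
                               index = NA_character_, group = NA_character_) {
  keep <- !is.na(age) & !is.na(value)
  age <- age[keep]; value <- value[keep]
  bins <- assign_age_bin(age)
  n <- as.integer(table(bins))
  mean_ <- tapply(value, bins, mean)
  sd_ <- tapply(value, bins, sd)
  out <- data.frame(index = index, group = group, bin = age_bin_levels(),
                    n = n,
                    mean = as.numeric(mean_),
                    sd = as.numeric(sd_),
                    se = as.numeric(sd_) / sqrt(n))
  sup <- out$n < min_n
  out$mean[sup] <- NA_real_
  out$sd[sup] <- NA_real_
  out$se[sup] <- NA_real_
  structure(out, min_n = min_n, class = c("trajectory_summary", "data.frame"))
}

#' Significance-band symbol for a p-value
#'
#' The fixed figure-annotation scheme: no symbol for p >= 0.05, `*` for
#' 0.01 <= p < 0.05, `#` for 0.001 <= p < 0.01, `!` for
#' 0.0001 <= p < 0.001 and `!!` for p < 0.0001.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Character vector of symbols.
#' @export
significance_band <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  out <- rep(NA_character_, length(p))
  out[!is.na(p)] <- ""
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "#"
  out[!is.na(p) & p < 0.001] <- "!"
  out[!is.na(p) & p < 0.0001] <- "!!"
  out
}

#' Per-bin comparison of two average trajectories
#'
#' Welch's unequal-variance test of equal means in every bin populated
#' (not suppressed) in both summaries, with the corresponding
#' significance-band symbol. Bins suppressed in either group yield no
#' comparison (NA p, NA band).
#'
#' @param a,b [average_trajectory()] summaries on the same bin scheme.
#' @return Data frame with columns `bin`, `p`, `band`.
#' @export
compare_groups <- function(a, b) {
  stopifnot(identical(a$bin, b$bin))
  p <- rep(NA_real_, nrow(a))
  ok <- !is.na(a$mean) & !is.na(b$mean)
  v1 <- a$se[ok]^2; v2 <- b$se[ok]^2
  tstat <- (a$mean[ok] - b$mean[ok]) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (a$n[ok] - 1) + v2^2 / (b$n[ok] - 1))
  p[ok] <- 2 * pt(-abs(tstat), df)
  data.frame(bin = a$bin, p = p, band = significance_band(p))
}

#' Stratify a cohort for the empirical trajectory analyses
#'
#' Returns labelled measurement sets (data frames with `id`, `age`,
#' `value`) for one physiological index under one of the fixed schemes:
#' \describe{
#'   \item{`short_vs_long`}{`SL` = subjects dying at ages 75 or earlier
#'     (censored subjects excluded); `LL` = subjects whose lifespan
#'     exceeds 97.44 years (deaths after, or censoring beyond, that
#'     age).}
#'   \item{`health`}{measurement-level split at the onset of unhealthy
#'     life (the minimum of the ages at first cancer, first CVD and
#'     first diabetes): measurements strictly before the onset, and all
#'     measurements of disease-free subjects, contribute to `healthy`;
#'     measurements at or after the onset to `unhealthy`.}
#'   \item{`dose`}{`<14` vs `>=14` pro-survival alleles (subject-level,
#'     requires a `dose` column).}
#'   \item{`apoe`}{`e4` carriers vs `not e4` (an `apoe` genotype string
#'     containing allele "4", or a logical/0-1 `apoe_e4` column).}
#'   \item{`compound`}{health split crossed with the dose split, four
#'     labels such as `unhealthy,<14`.}
#' }
#'
#' @param cohort an `spm_cohort`.
#' @param scheme one of `"short_vs_long"`, `"health"`, `"dose"`,
#'   `"apoe"`, `"compound"`.
#' @param index physiological index name.
#' @return Named list of data frames (`id`, `age`, `value`).
#' @export
stratify <- function(cohort, scheme = c("short_vs_long", "health", "dose",
                                        "apoe", "compound"),
                     index = spm_indices(cohort)[1]) {
  scheme <- match.arg(scheme)
  s <- cohort$subjects
  e <- cohort$exams[cohort$exams$index == index, c("id", "exam_age", "value")]
  names(e) <- c("id", "age", "value")
  measurements_of <- function(ids) e[e$id %in% ids, , drop = FALSE]

  need <- function(cols) {
    miss <- setdiff(cols, names(s))
    if (length(miss))
      stop("scheme '", scheme, "' requires subject column(s): ",
           paste(miss, collapse = ", "))
  }

  health_split <- function(tab) {
    need(c("onset_cancer", "onset_cvd", "onset_diabetes"))
    onset <- suppressWarnings(
      pmin(s$onset_cancer, s$onset_cvd, s$onset_diabetes, na.rm = TRUE))
    onset[!is.finite(onset)] <- Inf
    on <- onset[match(tab$id, s$id)]
    list(healthy = tab[tab$age < on, , drop = FALSE],
         unhealthy = tab[tab$age >= on, , drop = FALSE])
  }

  dose_ids <- function() {
    need("dose")
    list("<14" = s$id[!is.na(s$dose) & s$dose < 14],
         ">=14" = s$id[!is.na(s$dose) & s$dose >= 14])
  }

  switch(scheme,
    short_vs_long = {
      sl <- s$id[s$death == 1 & s$event_age <= 75]
      ll <- s$id[s$event_age > 97.44]
      list(SL = measurements_of(sl), LL = measurements_of(ll))
    },
    health = health_split(e),
    dose = {
      ids <- dose_ids()
      list("<14" = measurements_of(ids[["<14"]]),
           ">=14" = measurements_of(ids[[">=14"]]))
    },
    apoe = {
      carrier <- if ("apoe" %in% names(s)) grepl("4", s$apoe)
                 else if ("apoe_e4" %in% names(s)) s$apoe_e4 %in% c(TRUE, 1)
                 else stop("scheme 'apoe' requires subject column(s): apoe or apoe_e4")
      list(e4 = measurements_of(s$id[carrier]),
           "not e4" = measurements_of(s$id[!carrier]))
    },
    compound = {
      ids <- dose_ids()
      out <- list()
      for (g in names(ids)) {
        h <- health_split(measurements_of(ids[[g]]))
        out[[paste0("healthy,", g)]] <- h$healthy
        out[[paste0("unhealthy,", g)]] <- h$unhealthy
      }
      out
    })
}

#' Trajectory summaries with group comparisons for a stratification
#'
#' Convenience wrapper: stratifies, summarises every stratum with
#' [average_trajectory()], and (for two-group schemes) appends the
#' per-bin Welch p-values and band symbols of the group contrast.
#'
#' @inheritParams stratify
#' @param min_n minimum observations per shown bin.
#' @return A data frame with columns `index`, `group`, `bin`, `n`,
#'   `mean`, `se`, `p`, `band` (p/band repeated within bin, NA for
#'   schemes with more than two groups).
#' @export
trajectory_table <- function(cohort, scheme = "dose",
                             index = spm_indices(cohort)[1], min_n = 10) {
  strata <- stratify(cohort, scheme, index)
  summ <- lapply(names(strata), function(g)
    average_trajectory(strata[[g]]$age, strata[[g]]$value, min_n = min_n,
                       index = index, group = g))
  names(summ) <- names(strata)
  out <- do.call(rbind, lapply(summ, function(x) x[c("index", "group", "bin",
                                                     "n", "mean", "se")]))
  rownames(out) <- NULL
  if (length(summ) == 2) {
    cmp <- compare_groups(summ[[1]], summ[[2]])
    out$p <- cmp$p[match(out$bin, cmp$bin)]
    out$band <- cmp$band[match(out$bin, cmp$bin)]
  } else {
    out$p <- NA_real_
    out$band <- NA_character_
  }
  out
}
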