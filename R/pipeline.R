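pipeline_log <- function(stage, ..., t0 = NULL) {
  msg <- sprintf(...)
  elapsed <- if (!is.null(t0))
    sprintf(" [%.1fs]", as.numeric(proc.time()["elapsed"]) - t0) else ""
  message(sprintf("[%s] %s%s", stage, msg, elapsed))
}

#' Run the full analysis pipeline on a (synthetic or supplied) cohort
#'
#' End-to-end driver: simulate (or take) a cohort, write it out,
#' summarise age-binned trajectories under the requested stratification
#' schemes, estimate the norm trajectory from long-lived subjects, fit
#' the two dose groups and run the four likelihood-ratio tests
#' (skippable), fit the cause-specific Cox dose models, and write a
#' consolidated report. All outputs are plain CSV/JSON under `out_dir`;
#' rerunning with the same config and seed reproduces them.
#'
#' @param config a [simulation_config()]; ignored when `cohort` is
#'   supplied.
#' @param out_dir output directory.
#' @param cohort optionally, an existing `spm_cohort` to analyse.
#' @param schemes stratification schemes for the trajectory stage.
#' @param skip_spm if `TRUE`, skip the stochastic-process-model fits
#'   and likelihood-ratio tests (empirical outputs only).
#' @param skip_cox if `TRUE`, skip the Cox dose models.
#' @param fit_config an [spm_fit_config()] for the model fits.
#' @return Invisibly, a list with the cohort, the trajectory tables,
#'   the norm fit, the hypothesis-test results and the Cox table.
#' @export
run_pipeline <- function(config, out_dir, cohort = NULL,
                         schemes = c("short_vs_long", "health", "dose"),
                         skip_spm = FALSE, skip_cox = FALSE,
                         fit_config = spm_fit_config(n_starts = 1)) {
  t0 <- as.numeric(proc.time()["elapsed"])
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cohort)) {
    cohort <- simulate_cohort(config)
    pipeline_log("simulate", "%d subjects, %d exam records",
                 nrow(cohort$subjects), nrow(cohort$exams), t0 = t0)
  }
  write_cohort(cohort, file.path(out_dir, "cohort"))
  index <- spm_indices(cohort)[1]
  report <- list(index = index, n_subjects = nrow(cohort$subjects))
  if (!is.null(attr(cohort, "manifest")))
    report$manifest <- attr(cohort, "manifest")

  viol <- validate_cohort(cohort)
  write.csv(viol, file.path(out_dir, "validation.csv"), row.names = FALSE)
  pipeline_log("validate", "%d violation(s)", nrow(viol), t0 = t0)

  traj <- list()
  for (sc in schemes) {
    tab <- tryCatch(trajectory_table(cohort, sc, index),
                    error = function(e) {
                      pipeline_log("trajectories", "scheme %s skipped: %s",
                                   sc, conditionMessage(e))
                      NULL
                    })
    if (is.null(tab)) next
    traj[[sc]] <- tab
    write.csv(tab, file.path(out_dir, paste0("trajectories_", sc, ".csv")),
              row.names = FALSE)
  }
  pipeline_log("trajectories", "%d scheme(s) summarised", length(traj), t0 = t0)

  norm_fit <- NULL; tests <- NULL
  if (!skip_spm) {
    norm_fit <- tryCatch(fit_norm_polynomial(cohort, index),
                         error = function(e) {
                           pipeline_log("norm", "skipped: %s", conditionMessage(e))
                           NULL
                         })
    if (!is.null(norm_fit)) {
      jsonlite::write_json(list(coeffs = norm_fit$coeffs, se = norm_fit$se),
                           file.path(out_dir, "f0_fit.json"), digits = NA)
      pipeline_log("norm", "f0 cubic fitted on %d bins",
                   sum(!is.na(norm_fit$bins$mean)), t0 = t0)
      strata <- stratify(cohort, "dose", index)
      ids_low <- unique(strata[["<14"]]$id)
      ids_high <- unique(strata[[">=14"]]$id)
      sub <- function(ids) as_spm_cohort(
        cohort$subjects[cohort$subjects$id %in% ids, , drop = FALSE],
        cohort$exams[cohort$exams$id %in% ids, , drop = FALSE])
      tests <- spm_hypothesis_tests(sub(ids_low), sub(ids_high), index,
                                    f0_coeffsA = norm_fit$coeffs,
                                    f0_coeffsB = norm_fit$coeffs,
                                    config = fit_config)
      write.csv(tests$table, file.path(out_dir, "lrt_tests.csv"),
                row.names = FALSE)
      jsonlite::write_json(
        list(low = as.list(spm_par_vector(tests$unrestricted$fitA$params)),
             high = as.list(spm_par_vector(tests$unrestricted$fitB$params)),
             loglik = tests$unrestricted$loglik),
        file.path(out_dir, "spm_fits.json"), auto_unbox = TRUE, digits = NA)
      pipeline_log("spm", "two-group fits + %d LRT(s)", nrow(tests$table),
                   t0 = t0)
    }
  }

  cox <- NULL
  if (!skip_cox && "dose" %in% names(cohort$subjects)) {
    cox <- tryCatch(cox_dose_table(cohort),
                    error = function(e) {
                      pipeline_log("cox", "skipped: %s", conditionMessage(e))
                      NULL
                    })
    if (!is.null(cox)) {
      write.csv(cox, file.path(out_dir, "cox_dose.csv"), row.names = FALSE)
      pipeline_log("cox", "%d cause-specific fit(s)", nrow(cox), t0 = t0)
    }
  }

  report$outputs <- list.files(out_dir, recursive = TRUE)
  jsonlite::write_json(report, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  pipeline_log("done", "outputs in %s", out_dir, t0 = t0)
  invisible(list(cohort = cohort, trajectories = traj, norm_fit = norm_fit,
                 tests = tests, cox = cox))
}
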