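#!/usr/bin/env Rscript
# Stage 1: generate the two synthetic study cohorts.
#
# Cohort A ("spm"): trajectories + mortality driven by the two-group
#   stochastic process model (dose groups differ in norm trajectory,
#   adaptive capacity, quadratic term and baseline hazard). Used by the
#   trajectory and model-fitting stages.
# Cohort B ("ph"): continuous-time Gompertz proportional-hazards
#   mortality with per-allele cause-specific effects. Used by the Cox
#   dose-mortality stage.

library(spmaging)

seed <- 20260928L %% 99999L
out <- "results"
dir.create(out, showWarnings = FALSE)

cfg_spm <- simulation_config(n_subjects = 1500, seed = seed)
cohort_spm <- simulate_cohort(cfg_spm)
write_cohort(cohort_spm, file.path(out, "cohort_spm"))

cfg_ph <- simulation_config(n_subjects = 1500, seed = seed + 1L, mode = "ph")
cohort_ph <- simulate_cohort(cfg_ph)
write_cohort(cohort_ph, file.path(out, "cohort_ph"))

for (nm in c("cohort_spm", "cohort_ph")) {
  co <- if (nm == "cohort_spm") cohort_spm else cohort_ph
  s <- co$subjects
  cat(sprintf(
    "%s: %d subjects, %d exams, %.0f%% deaths (CVD %d / cancer %d / other %d), dose %d-%d (median %d), groups <14: %d, >=14: %d\n",
    nm, nrow(s), nrow(co$exams), 100 * mean(s$death),
    sum(s$cause == "CVD"), sum(s$cause == "cancer"), sum(s$cause == "other"),
    min(s$dose), max(s$dose), median(s$dose),
    sum(s$dose < 14), sum(s$dose >= 14)))
}
viol <- rbind(validate_cohort(cohort_spm), validate_cohort(cohort_ph))
cat("validation violations:", nrow(viol), "\n")
stopifnot(nrow(viol) == 0)
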