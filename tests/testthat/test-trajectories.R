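test_that("ages fall into the fixed bin scheme", {
  expect_equal(as.character(assign_age_bin(34.9)), "<35")
  expect_equal(as.character(assign_age_bin(37)), "35-39")
  expect_equal(as.character(assign_age_bin(92)), "90+")
  expect_equal(as.character(assign_age_bin(c(35, 39.99, 40, 89.9, 90))),
               c("35-39", "35-39", "40-44", "85-89", "90+"))
  # every age lands in exactly one bin
  ages <- seq(20, 105, by = 0.1)
  b <- assign_age_bin(ages)
  expect_false(any(is.na(b)))
  expect_equal(levels(b), age_bin_levels())
})

test_that("binned averages carry n, mean and SE, and suppress small bins", {
  tr <- average_trajectory(c(42, 43, 44), c(20, 22, 24), min_n = 2)
  row <- tr[tr$bin == "40-44", ]
  expect_equal(row$n, 3L)
  expect_equal(row$mean, 22)
  expect_equal(row$se, 2 / sqrt(3))
  expect_equal(row$se, 1.1547, tolerance = 1e-4)
  # nine observations in a bin are below the default threshold of ten
  tr9 <- average_trajectory(rep(51, 9), rnorm(9, 25))
  expect_equal(tr9$n[tr9$bin == "50-54"], 9L)
  expect_true(is.na(tr9$mean[tr9$bin == "50-54"]))
  tr10 <- average_trajectory(rep(51, 10), rnorm(10, 25))
  expect_false(is.na(tr10$mean[tr10$bin == "50-54"]))
  # empty input: all bins suppressed, no error
  tr0 <- average_trajectory(numeric(0), numeric(0))
  expect_true(all(tr0$n == 0L))
  expect_true(all(is.na(tr0$mean)))
})

test_that("significance bands follow the fixed p-value thresholds", {
  expect_equal(significance_band(0.2), "")
  expect_equal(significance_band(0.05), "")
  expect_equal(significance_band(0.049), "*")
  expect_equal(significance_band(0.01), "*")
  expect_equal(significance_band(0.004), "#")
  expect_equal(significance_band(0.001), "#")
  expect_equal(significance_band(0.0005), "!")
  expect_equal(significance_band(0.0001), "!")
  expect_equal(significance_band(5e-6), "!!")
  expect_equal(significance_band(c(1, 0.03, NA)), c("", "*", NA))
  expect_error(significance_band(1.2))
})

test_that("group comparison: identical groups blank, separated groups flagged", {
  set.seed(12)
  age <- rep(seq(42, 88, by = 5), each = 200)
  v1 <- rnorm(length(age), 25, 2)
  a <- average_trajectory(age, v1)
  cmp_same <- compare_groups(a, a)
  ok <- !is.na(cmp_same$p)
  expect_true(all(cmp_same$p[ok] > 0.99))
  expect_true(all(cmp_same$band[ok] == ""))
  # one-SD mean shift at n = 200 per bin is overwhelming evidence
  b <- average_trajectory(age, rnorm(length(age), 27, 2))
  cmp <- compare_groups(a, b)
  expect_true(mean(cmp$band[!is.na(cmp$p)] == "!!") > 0.9)
  # a bin suppressed in either group yields no comparison
  small_vs <- compare_groups(average_trajectory(rep(62, 50), rnorm(50, 25)),
                             average_trajectory(rep(62, 50), rnorm(50, 25)))
  expect_true(all(is.na(small_vs$p[small_vs$bin != "60-64"])))
})

make_strat_cohort <- function() {
  subj <- data.frame(
    id = c("A", "B", "C", "D", "E", "F"),
    sex = "F", birth_decade = 1900, smoking = "never",
    entry_age = 40,
    event_age = c(74, 74, 98.1, 90, 70, 99),
    death = c(1, 0, 1, 0, 1, 0),
    cause = c("CVD", "none", "other", "none", "cancer", "none"),
    onset_cancer = c(NA, NA, NA, NA, 60, NA),
    onset_cvd = c(65, NA, NA, NA, NA, NA),
    onset_diabetes = c(NA, NA, NA, NA, 62, NA),
    apoe = c("e3/e4", "e3/e3", "e2/e4", "e3/e3", "e4/e4", "e2/e3"),
    dose = c(10, 13, 20, 14, 9, 16))
  exams <- data.frame(
    id = rep(c("A", "B", "C", "D", "E", "F"), each = 3),
    exam_age = c(50, 64, 66, 50, 60, 70, 50, 70, 90, 45, 55, 65,
                 58, 61, 63, 50, 70, 95),
    index = "BMI", value = 25)
  as_spm_cohort(subj, exams)
}

test_that("short- vs long-lived stratification follows the lifespan rules", {
  co <- make_strat_cohort()
  st <- stratify(co, "short_vs_long")
  # deaths at 75 or earlier are short-lived; censored at 74 is excluded
  expect_setequal(unique(st$SL$id), c("A", "E"))
  # lifespan beyond 97.44 years is long-lived
  expect_setequal(unique(st$LL$id), c("C", "F"))
})

test_that("health stratification splits measurements at unhealthy-life onset", {
  co <- make_strat_cohort()
  st <- stratify(co, "health")
  # E's onset of unhealthy life is min(60, 62) = 60: the exam at 58 is
  # healthy, those at 61 and 63 unhealthy
  expect_true(all(st$healthy$age[st$healthy$id == "E"] == 58))
  expect_setequal(st$unhealthy$age[st$unhealthy$id == "E"], c(61, 63))
  # A's onset (CVD) is 65: exams at 50, 64 healthy, 66 unhealthy
  expect_setequal(st$healthy$age[st$healthy$id == "A"], c(50, 64))
  expect_setequal(st$unhealthy$age[st$unhealthy$id == "A"], 66)
  # disease-free subjects contribute everything to the healthy series
  expect_equal(sum(st$unhealthy$id == "B"), 0)
  expect_equal(sum(st$healthy$id == "B"), 3)
  # the split partitions each subject's measurements
  n_all <- nrow(co$exams)
  expect_equal(nrow(st$healthy) + nrow(st$unhealthy), n_all)
})

test_that("dose and APOE stratifications split subjects as labelled", {
  co <- make_strat_cohort()
  st <- stratify(co, "dose")
  expect_setequal(unique(st[["<14"]]$id), c("A", "B", "E"))
  expect_setequal(unique(st[[">=14"]]$id), c("C", "D", "F"))
  ap <- stratify(co, "apoe")
  expect_setequal(unique(ap$e4$id), c("A", "C", "E"))
  expect_setequal(unique(ap[["not e4"]]$id), c("B", "D", "F"))
  cp <- stratify(co, "compound")
  expect_named(cp, c("healthy,<14", "unhealthy,<14",
                     "healthy,>=14", "unhealthy,>=14"))
  expect_setequal(cp[["unhealthy,<14"]]$age[cp[["unhealthy,<14"]]$id == "E"],
                  c(61, 63))
  # a scheme whose columns are absent names the missing column
  co2 <- make_strat_cohort()
  co2$subjects$dose <- NULL
  expect_error(stratify(co2, "dose"), "dose")
})

test_that("trajectory tables are invariant to subject order", {
  p <- spm_default_parameters("high")
  co <- make_spm_cohort(150, seed = 63, p)
  t1 <- trajectory_table(co, "dose", "BMI")
  perm <- sample(nrow(co$subjects))
  co2 <- as_spm_cohort(co$subjects[perm, ], co$exams, co$genotypes)
  t2 <- trajectory_table(co2, "dose", "BMI")
  expect_equal(t1[order(t1$group, t1$bin), c("n", "mean", "se")],
               t2[order(t2$group, t2$bin), c("n", "mean", "se")],
               ignore_attr = TRUE)
})
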