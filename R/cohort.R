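#' Longitudinal cohort container
#'
#' A cohort is three aligned tables: `subjects` (one row per person:
#' demographics, entry/event ages, vital status, cause of death, disease
#' onset ages, polygenic dose), `exams` (long format, one row per exam
#' per index: id, exam_age, index, value; `value` may be NA for an
#' attended exam with a missing measurement), and optionally `genotypes`
#' (subjects x SNP allele counts, first column `id`).
#'
#' @param subjects data frame with at least columns `id`, `sex`,
#'   `birth_decade`, `smoking`, `entry_age`, `event_age`, `death`,
#'   `cause`.
#' @param exams data frame with columns `id`, `exam_age`, `index`,
#'   `value`.
#' @param genotypes optional data frame with column `id` plus one column
#'   per SNP (allele counts 0/1/2 or carrier 0/1).
#' @return An object of class `spm_cohort`.
#' @export
as_spm_cohort <- function(subjects, exams, genotypes = NULL) {
  req_s <- c("id", "sex", "birth_decade", "smoking", "entry_age",
             "event_age", "death", "cause")
  miss <- setdiff(req_s, names(subjects))
  if (length(miss))
    stop("subjects table is missing required column(s): ",
         paste(miss, collapse = ", "))
  req_e <- c("id", "exam_age", "index", "value")
  miss <- setdiff(req_e, names(exams))
  if (length(miss))
    stop("exams table is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(subjects$id))
    stop("duplicated subject id(s) in subjects table")
  unknown <- setdiff(unique(exams$id), subjects$id)
  if (length(unknown))
    stop("referential error: exam rows for unknown subject id(s): ",
         paste(head(unknown, 5), collapse = ", "))
  if (!is.null(genotypes)) {
    if (!"id" %in% names(genotypes)) stop("genotypes table needs an 'id' column")
    unknown <- setdiff(genotypes$id, subjects$id)
    if (length(unknown))
      stop("referential error: genotype rows for unknown subject id(s): ",
           paste(head(unknown, 5), collapse = ", "))
  }
  structure(list(subjects = subjects, exams = exams, genotypes = genotypes),
            class = "spm_cohort")
}

#' @export
print.spm_cohort <- function(x, ...) {
  cat(sprintf("spm_cohort: %d subjects, %d exam records (%s)%s\n",
              nrow(x$subjects), nrow(x$exams),
              paste(spm_indices(x), collapse = ", "),
              if (is.null(x$genotypes)) ""
              else sprintf(", genotypes for %d subjects at %d SNPs",
                           nrow(x$genotypes), ncol(x$genotypes) - 1L)))
  invisible(x)
}

#' Physiological indices present in a cohort
#' @param cohort an `spm_cohort`.
#' @return Character vector of index names.
#' @export
spm_indices <- function(cohort) sort(unique(cohort$exams$index))

#' Write a cohort to CSV files
#'
#' Writes `subjects.csv`, `exams.csv` and (if present) `genotypes.csv`
#' under `dir` (UTF-8, comma-separated, header row; ages in decimal
#' years; index values in natural units).
#'
#' @param cohort an `spm_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
  write.csv(cohort$exams, file.path(dir, "exams.csv"), row.names = FALSE)
  if (!is.null(cohort$genotypes))
    write.csv(cohort$genotypes, file.path(dir, "genotypes.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort from CSV files
#'
#' Strict reader for the layout written by [write_cohort()]: missing
#' required columns, non-numeric ages and unknown subject ids are
#' reported as errors naming the offending column or id.
#'
#' @param dir directory containing `subjects.csv`, `exams.csv` and
#'   optionally `genotypes.csv`.
#' @return An `spm_cohort`.
#' @export
read_cohort <- function(dir) {
  spath <- file.path(dir, "subjects.csv")
  epath <- file.path(dir, "exams.csv")
  gpath <- file.path(dir, "genotypes.csv")
  if (!file.exists(spath)) stop("missing file: ", spath)
  if (!file.exists(epath)) stop("missing file: ", epath)
  subjects <- read.csv(spath, stringsAsFactors = FALSE)
  exams <- read.csv(epath, stringsAsFactors = FALSE)
  genotypes <- if (file.exists(gpath)) read.csv(gpath, check.names = FALSE,
                                                stringsAsFactors = FALSE) else NULL
  for (col in c("entry_age", "event_age"))
    if (!is.numeric(subjects[[col]]))
      stop("subjects column '", col, "' must be numeric")
  if (!is.numeric(exams$exam_age)) stop("exams column 'exam_age' must be numeric")
  if (!is.numeric(exams$value)) exams$value <- as.numeric(exams$value)
  as_spm_cohort(subjects, exams, genotypes)
}

#' Validate cohort invariants
#'
#' Checks every subject-level invariant (non-negative ordered ages,
#' allowed causes of death, exam ages strictly increasing, no exam after
#' the event age, dose consistent with genotypes when both are present)
#' and returns one row per violation.
#'
#' @param cohort an `spm_cohort`.
#' @return Data frame with columns `id`, `field`, `message`; zero rows
#'   when the cohort is clean.
#' @export
validate_cohort <- function(cohort) {
  s <- cohort$subjects
  v <- list()
  add <- function(id, field, message)
    v[[length(v) + 1L]] <<- data.frame(id = id, field = field,
                                       message = message)
  bad <- which(s$entry_age < 0 | s$event_age < 0)
  for (i in bad) add(s$id[i], "age", "negative age")
  bad <- which(s$event_age < s$entry_age)
  for (i in bad) add(s$id[i], "event_age", "event age before entry age")
  allowed <- c("CVD", "cancer", "other", "none")
  bad <- which(!s$cause %in% allowed)
  for (i in bad) add(s$id[i], "cause",
                     paste0("cause '", s$cause[i], "' not in allowed set"))
  bad <- which(s$death == 0 & s$cause != "none")
  for (i in bad) add(s$id[i], "cause", "censored subject with a death cause")
  ev <- setNames(s$event_age, s$id)
  for (id in unique(cohort$exams$id)) {
    e <- cohort$exams[cohort$exams$id == id, , drop = FALSE]
    for (ix in unique(e$index)) {
      ages <- e$exam_age[e$index == ix]
      if (any(diff(sort(ages)) == 0) || anyDuplicated(ages))
        add(id, "exam_age", paste0("duplicated exam age for index ", ix))
    }
    if (any(e$exam_age > ev[[as.character(id)]] + 1e-9))
      add(id, "exam_age", "exam recorded after event age")
    if (any(e$exam_age < 0)) add(id, "exam_age", "negative exam age")
  }
  if (!is.null(cohort$genotypes) && "dose" %in% names(s)) {
    g <- cohort$genotypes
    sc <- polygenic_score(g[setdiff(names(g), "id")])
    m <- match(g$id, s$id)
    bad <- which(!is.na(s$dose[m]) & s$dose[m] != sc)
    for (i in bad) add(g$id[i], "dose",
                       "dose does not equal the carrier count of the genotypes")
  }
  if (length(v)) do.call(rbind, v)
  else data.frame(id = character(0), field = character(0),
                  message = character(0))
}
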