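#' @keywords internal
"_PACKAGE"

# Covariate schema shared by the whole package: three age classes, binary
# peritumoural vascular involvement, binary tumour size > 20 mm, binary nodal
# involvement, three histological grades.
AGE_LEVELS   <- c("le40", "40to55", "gt55")
GRADE_LEVELS <- c("I", "II", "III")
COVARIATE_COLUMNS <- c("age_group", "pvi", "size_gt20", "nodal", "grade")
SUBJECT_COLUMNS   <- c("id", COVARIATE_COLUMNS, "followup_time", "death")
RECURRENCE_COLUMNS <- c("id", "rec_time")

# Names of the design-matrix columns, in the order used by every coefficient
# vector in the package (reference levels: age > 55, grade I).
DESIGN_COLUMNS <- c("age_le40", "age_40to55", "pvi", "size_gt20", "nodal",
                    "grade_II", "grade_III")

#' Construct a cohort of subjects with recurrent events and terminal follow-up
#'
#' A cohort bundles one row per subject (baseline covariates, last follow-up
#' time in years from the study origin, death indicator) with a long table of
#' relapse calendar times. All times are continuous years from the origin
#' (typically diagnosis); relapse times must be strictly increasing within a
#' subject, positive, and no larger than the subject's follow-up time.
#'
#' @param subjects data.frame with columns `id`, `age_group` (one of
#'   `"le40"`, `"40to55"`, `"gt55"`), `pvi`, `size_gt20`, `nodal` (0/1),
#'   `grade` (`"I"`, `"II"`, `"III"`), `followup_time` (> 0, years),
#'   `death` (0/1).
#' @param recurrences data.frame with columns `id`, `rec_time`; zero rows for
#'   subjects without relapse. May be `NULL` for a relapse-free cohort.
#' @param origin free-text description of the time origin.
#' @return An object of class `"cohort"`.
#' @export
cohort <- function(subjects, recurrences = NULL, origin = "diagnosis") {
  if (is.null(recurrences)) {
    recurrences <- data.frame(id = character(0), rec_time = numeric(0))
  }
  subjects <- as.data.frame(subjects)
  recurrences <- as.data.frame(recurrences)
  miss <- setdiff(SUBJECT_COLUMNS, names(subjects))
  if (length(miss))
    stop("subject table is missing column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(RECURRENCE_COLUMNS, names(recurrences))
  if (length(miss))
    stop("recurrence table is missing column(s): ", paste(miss, collapse = ", "))
  subjects$id <- as.character(subjects$id)
  recurrences$id <- as.character(recurrences$id)
  # sort relapse times within subject, keep subject order as given
  if (nrow(recurrences)) {
    recurrences <- recurrences[order(match(recurrences$id, subjects$id),
                                     recurrences$rec_time), , drop = FALSE]
    rownames(recurrences) <- NULL
  }
  obj <- structure(list(subjects = subjects,
                        recurrences = recurrences[, RECURRENCE_COLUMNS, drop = FALSE],
                        origin = origin),
                   class = "cohort")
  validate_cohort(obj)
  obj
}

#' Validate a cohort object
#'
#' Checks the invariants of the data model: unique subject ids, covariate
#' values drawn from their stated levels, positive follow-up, binary death
#' indicator, and per-subject relapse times that are positive, strictly
#' increasing and bounded by the follow-up time. Missing covariate values are
#' rejected (complete-case policy; no imputation).
#'
#' @param x a `"cohort"` object.
#' @return `x`, invisibly; stops with an informative error otherwise.
#' @export
validate_cohort <- function(x) {
  s <- x$subjects
  r <- x$recurrences
  if (anyDuplicated(s$id))
    stop("duplicate subject id(s): ",
         paste(unique(s$id[duplicated(s$id)]), collapse = ", "))
  for (col in SUBJECT_COLUMNS)
    if (anyNA(s[[col]]))
      stop("missing values in subject column '", col,
           "' (complete cases required)")
  if (!all(s$age_group %in% AGE_LEVELS))
    stop("age_group must be one of: ", paste(AGE_LEVELS, collapse = ", "))
  if (!all(s$grade %in% GRADE_LEVELS))
    stop("grade must be one of: ", paste(GRADE_LEVELS, collapse = ", "))
  for (col in c("pvi", "size_gt20", "nodal", "death"))
    if (!all(s[[col]] %in% c(0, 1)))
      stop("column '", col, "' must be 0/1")
  if (!all(s$followup_time > 0))
    stop("followup_time must be > 0 for all subjects")
  if (nrow(r)) {
    unknown <- setdiff(r$id, s$id)
    if (length(unknown))
      stop("recurrence rows reference unknown subject id(s): ",
           paste(unknown, collapse = ", "))
    if (anyNA(r$rec_time)) stop("missing relapse times")
    fup <- s$followup_time[match(r$id, s$id)]
    bad <- r$id[r$rec_time > fup]
    if (length(bad))
      stop("relapse time exceeds follow-up time for subject(s): ",
           paste(unique(bad), collapse = ", "))
    if (any(r$rec_time <= 0)) stop("relapse times must be > 0")
    by_id <- split(r$rec_time, r$id)
    nondec <- vapply(by_id, function(t) any(diff(t) <= 0), logical(1))
    if (any(nondec))
      stop("relapse times must be strictly increasing for subject(s): ",
           paste(names(by_id)[nondec], collapse = ", "))
  }
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  s <- x$subjects
  cat("A cohort of", nrow(s), "subjects (origin:", x$origin, ")\n")
  cat("  deaths:", sum(s$death), " relapses:", nrow(x$recurrences),
      " max follow-up:", format(max(s$followup_time), digits = 4), "years\n")
  nrel <- n_relapses(x)
  tab <- table(factor(pmin(nrel, 4), levels = 0:4,
                      labels = c("0", "1", "2", "3", "4+")))
  cat("  relapse count:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Number of relapses per subject
#'
#' @param x a cohort.
#' @param before count only relapses at or before this time (default all).
#' @return integer vector aligned with `x$subjects`.
#' @export
n_relapses <- function(x, before = Inf) {
  r <- x$recurrences
  r <- r[r$rec_time <= before, , drop = FALSE]
  cnt <- table(factor(r$id, levels = x$subjects$id))
  as.integer(cnt)
}

#' Relapse times of one subject
#' @param x a cohort.
#' @param id subject id.
#' @return sorted numeric vector (possibly empty).
#' @export
relapse_times <- function(x, id) {
  x$recurrences$rec_time[x$recurrences$id == id]
}

#' Read a cohort from subject and recurrence CSV files
#'
#' `subjects.csv` must carry the columns
#' `id,age_group,pvi,size_gt20,nodal,grade,followup_time,death`;
#' `recurrences.csv` the columns `id,rec_time`, one row per relapse.
#' Both are comma-separated UTF-8 with `.` decimal. All invariants of
#' [cohort()] are enforced on read.
#'
#' @param subjects_path,recurrences_path file paths.
#' @param origin passed to [cohort()].
#' @return a `"cohort"`.
#' @export
read_cohort <- function(subjects_path, recurrences_path, origin = "diagnosis") {
  for (p in c(subjects_path, recurrences_path))
    if (!file.exists(p)) stop("file not found: ", p)
  subj <- utils::read.csv(subjects_path, colClasses = c(id = "character"))
  rec  <- utils::read.csv(recurrences_path, colClasses = c(id = "character"))
  cohort(subj, rec, origin = origin)
}

#' Write a cohort to subject and recurrence CSV files
#'
#' Times are formatted with 15 significant digits so that
#' `read_cohort(write_cohort(x))` round-trips exactly.
#'
#' @param x a cohort.
#' @param subjects_path,recurrences_path output file paths.
#' @export
write_cohort <- function(x, subjects_path, recurrences_path) {
  fmt <- function(d) {
    for (col in names(d))
      if (is.double(d[[col]])) d[[col]] <- formatC(d[[col]], digits = 15,
                                                   format = "g")
    d
  }
  utils::write.csv(fmt(x$subjects), subjects_path, row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(fmt(x$recurrences), recurrences_path, row.names = FALSE,
                   quote = FALSE)
  invisible(x)
}

#' Expand a cohort to counting-process (start, stop] rows
#'
#' One row per at-risk interval on the calendar timescale: a subject is at
#' risk for the j-th relapse only after the (j-1)-th, so the rows partition
#' (0, T_i] at the relapse times. `rec_event` is 1 exactly on rows ending at
#' a relapse; `death_event` is 1 only on the subject's final row and equals
#' the death indicator. A relapse occurring exactly at the last follow-up
#' time keeps its relapse row and the degenerate terminal row is collapsed
#' onto it (the censoring time can coincide with a recurrence time).
#'
#' @param x a cohort.
#' @return data.frame `id,t_start,t_stop,rec_event,death_event` plus the
#'   covariate columns.
#' @export
to_counting_process <- function(x) {
  s <- x$subjects
  out <- vector("list", nrow(s))
  for (i in seq_len(nrow(s))) {
    rt <- relapse_times(x, s$id[i])
    td <- s$followup_time[i]
    last_is_relapse <- length(rt) && rt[length(rt)] == td
    stops <- if (last_is_relapse) rt else c(rt, td)
    starts <- c(0, stops[-length(stops)])
    k <- length(stops)
    rec <- as.integer(seq_len(k) <= length(rt))
    death <- integer(k)
    death[k] <- s$death[i]
    out[[i]] <- data.frame(id = s$id[i], t_start = starts, t_stop = stops,
                           rec_event = rec, death_event = death,
                           s[i, COVARIATE_COLUMNS, drop = FALSE],
                           row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Baseline design matrix for a subject table
#'
#' Dummy coding with reference levels age > 55 and grade I, column order
#' `age_le40, age_40to55, pvi, size_gt20, nodal, grade_II, grade_III` — the
#' order used by all coefficient vectors in the package.
#'
#' @param subjects a subject data.frame (or a cohort).
#' @return numeric matrix with `length(DESIGN_COLUMNS)` columns.
#' @export
covariate_matrix <- function(subjects) {
  if (inherits(subjects, "cohort")) subjects <- subjects$subjects
  cbind(age_le40   = as.numeric(subjects$age_group == "le40"),
        age_40to55 = as.numeric(subjects$age_group == "40to55"),
        pvi        = as.numeric(subjects$pvi),
        size_gt20  = as.numeric(subjects$size_gt20),
        nodal      = as.numeric(subjects$nodal),
        grade_II   = as.numeric(subjects$grade == "II"),
        grade_III  = as.numeric(subjects$grade == "III"))
}
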