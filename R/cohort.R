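# Cohort table schema, CSV readers/writers, and record validation.
#
# One wide row per patient. Follow-up visits occupy up to three column
# blocks (fu1_/fu2_/fu3_, the 3/6/12-month schedule); unused blocks are
# left empty. Missing optional cells are empty in CSV and NA in R --
# never silently coerced to zero.

cohort_schema <- function() {
  panels <- c(
    paste0(rep(TRAD_PARAMS, 2), rep(c("_pre", "_post"), each = 4)),
    paste0(rep(COG_TESTS, 2), rep(c("_pre", "_post"), each = 5)),
    paste0(rep(GAIT_PARAMS, 2), rep(c("_pre", "_post"), each = 5)))
  fu <- as.vector(outer(c("days", "mrs", "inphgs_cognitive", "inphgs_gait",
                          "inphgs_urinary", "subjective"),
                        paste0("fu", 1:3), function(f, b) paste0(b, "_", f)))
  c("id", "age", "sex", "education",
    "hyperlipidemia", "hypertension", "diabetes",
    "evans_index", "desh_score",
    "sym_cognitive", "sym_gait", "sym_urinary",
    "mrs_baseline", "inphgs_cognitive", "inphgs_gait", "inphgs_urinary",
    panels, "shunted", fu)
}

#' Read and validate a cohort CSV and its normative table
#'
#' The cohort CSV is comma-separated UTF-8 with a header of snake_case
#' column names (see `eldshunt:::cohort_schema()` and the README); missing
#' optional cells are empty and become `NA`. Every record is validated
#' against the domain invariants; violations abort with a message naming
#' the row, column and violated rule.
#'
#' @param path cohort CSV path.
#' @param norm_path normative-table CSV path (columns `test`, `mean`, `sd`,
#'   `direction`); if `NULL`, norms are not read and only the cohort is
#'   returned.
#' @return list with `cohort` (data frame) and `norms` (data frame or
#'   `NULL`).
#' @export
read_cohort <- function(path, norm_path = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE,
                            na.strings = "", fileEncoding = "UTF-8")
  missing_cols <- setdiff(cohort_schema(), names(cohort))
  if (length(missing_cols))
    stop("cohort header is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  validate_cohort(cohort)
  norms <- if (!is.null(norm_path)) read_norms(norm_path) else NULL
  list(cohort = cohort, norms = norms)
}

#' @rdname read_cohort
#' @param cohort validated cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' Read a normative table
#'
#' @param path CSV with columns `test`, `mean`, `sd`, `direction`
#'   (`higher_better`/`lower_better`), one row per cognitive test in scope.
#' @export
read_norms <- function(path) {
  if (!file.exists(path)) stop("norms file not found: ", path)
  norms <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_norms(norms)
  norms
}

#' @rdname read_norms
#' @param norms norms data frame.
#' @export
write_norms <- function(norms, path) {
  utils::write.csv(norms, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Placeholder normative table (synthetic)
#'
#' The computerized battery is standardized against population norms that
#' are supplied by the user in practice. For testing and simulation this
#' synthetic placeholder set is provided; its means/SDs are chosen so that
#' a typical impaired iNPH baseline panel standardizes to a composite z
#' around -2.3. It is not a published norm set.
#'
#' @return data frame with columns `test`, `mean`, `sd`, `direction`.
#' @export
default_norms <- function() {
  data.frame(
    test = COG_TESTS,
    mean = c(9, 14, 70, 52, 85),
    sd = c(4, 5, 25, 8, 28),
    direction = c("higher_better", "higher_better", "lower_better",
                  "higher_better", "lower_better"),
    stringsAsFactors = FALSE
  )
}

validate_norms <- function(norms) {
  need <- c("test", "mean", "sd", "direction")
  if (!all(need %in% names(norms)))
    stop("norms table must have columns ", paste(need, collapse = ", "))
  missing_tests <- setdiff(COG_TESTS, norms$test)
  if (length(missing_tests))
    stop("norms table is missing test(s): ",
         paste(missing_tests, collapse = ", "))
  if (anyDuplicated(norms$test))
    stop("norms table has duplicated test entries")
  if (any(!is.finite(norms$sd) | norms$sd <= 0))
    stop("norms: sd must be > 0 for every test")
  if (!all(norms$direction %in% c("higher_better", "lower_better")))
    stop("norms: direction must be higher_better or lower_better")
  invisible(norms)
}

fail_row <- function(i, field, rule) {
  stop(sprintf("cohort row %d, column '%s': violated invariant: %s",
               i, field, rule), call. = FALSE)
}

check_range <- function(x, i, field, lo, hi, integer = FALSE,
                        allow_na = TRUE) {
  v <- x[[field]][i]
  if (is.na(v)) {
    if (allow_na) return(invisible())
    fail_row(i, field, "value required")
  }
  if (!is.numeric(v)) fail_row(i, field, "must be numeric")
  if (integer && v != round(v)) fail_row(i, field, "must be an integer")
  rule <- sprintf("%s in [%s,%s]", field, format(lo), format(hi))
  if (v < lo || v > hi) fail_row(i, field, rule)
  invisible()
}

#' Validate a cohort data frame against the domain invariants
#'
#' Checks, per record: Evans index in (0,1); DESH score an integer in
#' [0, `desh_max`]; mRS in [0,5]; each iNPHGS domain in [0,4]; MMSE in
#' [0,30]; all timed measures and gait parameters positive; step counts
#' >= 1; post panels present only where the pre panel is present;
#' follow-up intervals strictly increasing. Aborts with the row, column
#' and rule of the first violation.
#'
#' @param cohort cohort data frame.
#' @param desh_max upper bound of the DESH score scale (default 10).
#' @return the cohort, invisibly, if valid.
#' @export
validate_cohort <- function(cohort, desh_max = 10) {
  for (i in seq_len(nrow(cohort))) {
    check_range(cohort, i, "age", 0, 120)
    if (!is.na(cohort$sex[i]) && !cohort$sex[i] %in% c("male", "female"))
      fail_row(i, "sex", "sex in {male, female}")
    check_range(cohort, i, "education", 0, 30)
    v <- cohort$evans_index[i]
    if (!is.na(v) && (v <= 0 || v >= 1))
      fail_row(i, "evans_index", "evans_index in (0,1)")
    check_range(cohort, i, "desh_score", 0, desh_max, integer = TRUE)
    check_range(cohort, i, "mrs_baseline", 0, 5, integer = TRUE)
    for (dom in c("inphgs_cognitive", "inphgs_gait", "inphgs_urinary"))
      check_range(cohort, i, dom, 0, 4, integer = TRUE)
    for (ph in c("_pre", "_post")) {
      check_range(cohort, i, paste0("mmse", ph), 0, 30, integer = TRUE)
      for (f in c("tug_time", "tmwt_time", "tmt_time", "stroop_rt",
                  GAIT_PARAMS)) {
        v <- cohort[[paste0(f, ph)]][i]
        if (!is.na(v) && v <= 0)
          fail_row(i, paste0(f, ph), paste0(f, " > 0"))
      }
      v <- cohort[[paste0("tmwt_steps", ph)]][i]
      if (!is.na(v) && v < 1)
        fail_row(i, paste0("tmwt_steps", ph), "tmwt_steps >= 1")
      v <- cohort[[paste0("stroop_correct", ph)]][i]
      if (!is.na(v) && v < 0)
        fail_row(i, paste0("stroop_correct", ph), "stroop_correct >= 0")
    }
    # post panels require the matching pre panel
    for (f in c(TRAD_PARAMS, COG_TESTS, GAIT_PARAMS)) {
      if (!is.na(cohort[[paste0(f, "_post")]][i]) &&
          is.na(cohort[[paste0(f, "_pre")]][i]))
        fail_row(i, paste0(f, "_post"),
                 "post value present without pre value")
    }
    # follow-up blocks: intervals strictly increasing, scores in range
    prev_days <- -Inf
    for (b in paste0("fu", 1:3)) {
      d <- cohort[[paste0(b, "_days")]][i]
      if (is.na(d)) next
      if (d <= 0) fail_row(i, paste0(b, "_days"), "interval_days > 0")
      if (d <= prev_days)
        fail_row(i, paste0(b, "_days"),
                 "interval_days strictly increasing")
      prev_days <- d
      check_range(cohort, i, paste0(b, "_mrs"), 0, 5, integer = TRUE)
      for (dom in c("inphgs_cognitive", "inphgs_gait", "inphgs_urinary"))
        check_range(cohort, i, paste0(b, "_", dom), 0, 4, integer = TRUE)
    }
  }
  invisible(cohort)
}
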