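# Rule-based outcome classification: positive response to the drainage test
# (traditional criteria) and shunt response at the last follow-up.

#' Classify response to the drainage test by the traditional criteria
#'
#' A positive response requires (all thresholds inclusive): improvement of
#' >= 20% in either 10-m walk time or step count, or >= 10% in both; or
#' >= 10% improvement in TUG time; or an MMSE gain of >= 3 points. Walk and
#' TUG improvements are oriented percent rates (lower is better); the MMSE
#' criterion is a raw point difference.
#'
#' @param pre,post named lists or one-row data frames with `mmse`,
#'   `tug_time`, `tmwt_time`, `tmwt_steps`.
#' @return list with `positive` (logical) and `reasons` (character subset of
#'   `tmwt_20`, `tmwt_10_both`, `tug_10`, `mmse_3`). Criteria whose inputs
#'   are missing are skipped (recorded in `skipped`); if no criterion is
#'   evaluable an error is raised.
#' @export
classify_eld_response <- function(pre, post) {
  rate <- function(field) as.numeric(
    improvement_rate(pre[[field]], post[[field]], "lower_better"))
  tmwt_t <- rate("tmwt_time")
  tmwt_s <- rate("tmwt_steps")
  tug <- rate("tug_time")
  mmse_gain <- if (is_absent(pre$mmse) || is_absent(post$mmse)) NA_real_
               else post$mmse - pre$mmse

  reasons <- character(0)
  skipped <- character(0)
  if (is.na(tmwt_t) && is.na(tmwt_s)) {
    skipped <- c(skipped, "tmwt")
  } else {
    if ((!is.na(tmwt_t) && tmwt_t >= 20) || (!is.na(tmwt_s) && tmwt_s >= 20))
      reasons <- c(reasons, "tmwt_20")
    if (!is.na(tmwt_t) && !is.na(tmwt_s) && tmwt_t >= 10 && tmwt_s >= 10)
      reasons <- c(reasons, "tmwt_10_both")
  }
  if (is.na(tug)) skipped <- c(skipped, "tug")
  else if (tug >= 10) reasons <- c(reasons, "tug_10")
  if (is.na(mmse_gain)) skipped <- c(skipped, "mmse")
  else if (mmse_gain >= 3) reasons <- c(reasons, "mmse_3")

  if (length(skipped) == 3 && is.na(tmwt_t) && is.na(tmwt_s))
    stop("no traditional criterion evaluable: all inputs missing")
  list(positive = length(reasons) > 0, reasons = reasons, skipped = skipped)
}

is_absent <- function(x) is.null(x) || length(x) == 0 || is.na(x)

#' Classify shunt response at the last follow-up
#'
#' A shunted patient is a responder if, at the last follow-up (the visit
#' with the largest interval), the mRS decreased by >= 1 point versus
#' baseline or any single iNPHGS domain decreased by >= 1 point.
#' Subjective improvement alone does not qualify. With
#' `any_visit = TRUE`, improvement at any recorded visit qualifies.
#'
#' @param record one-row cohort data frame (wide follow-up blocks
#'   `fu1_`/`fu2_`/`fu3_`).
#' @param any_visit qualify on any visit rather than the last only.
#' @return list with `status` (`"responder"`, `"nonresponder"`, or
#'   `"not_shunted"`) and `basis` (character subset of `mrs`,
#'   `inphgs_cognitive`, `inphgs_gait`, `inphgs_urinary`).
#' @export
classify_shunt_response <- function(record, any_visit = FALSE) {
  if (is_absent(record$shunted) || !as.logical(record$shunted))
    return(list(status = "not_shunted", basis = character(0)))
  blocks <- paste0("fu", 1:3)
  have <- blocks[!vapply(blocks, function(b)
    is_absent(record[[paste0(b, "_days")]]), logical(1))]
  if (length(have) == 0)
    stop("shunted record has no follow-up visits")
  visits <- if (any_visit) have else {
    days <- vapply(have, function(b) record[[paste0(b, "_days")]], numeric(1))
    have[which.max(days)]
  }
  basis <- character(0)
  for (b in visits) {
    if (!is_absent(record[[paste0(b, "_mrs")]]) &&
        record$mrs_baseline - record[[paste0(b, "_mrs")]] >= 1)
      basis <- c(basis, "mrs")
    for (dom in c("inphgs_cognitive", "inphgs_gait", "inphgs_urinary")) {
      v <- record[[paste0(b, "_", dom)]]
      if (!is_absent(v) && record[[dom]] - v >= 1)
        basis <- c(basis, dom)
    }
  }
  basis <- unique(basis)
  list(status = if (length(basis)) "responder" else "nonresponder",
       basis = basis)
}

#' Label a whole cohort and summarize prevalences
#'
#' Applies [classify_eld_response()] and [classify_shunt_response()] to each
#' record.
#'
#' @param cohort validated cohort data frame.
#' @param any_visit see [classify_shunt_response()].
#' @return list with `labels` (data frame: `id`, `eld_positive`,
#'   `eld_reasons`, `shunt_status`, `shunt_basis`) and `counts` (named
#'   vector: `n`, `shunted`, `responders`, `nonresponders`).
#' @export
cohort_labels <- function(cohort, any_visit = FALSE) {
  n <- nrow(cohort)
  labels <- data.frame(id = character(n), eld_positive = logical(n),
                       eld_reasons = character(n),
                       shunt_status = character(n),
                       shunt_basis = character(n),
                       stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    row <- cohort[i, ]
    eld <- classify_eld_response(panel_of(row, TRAD_PARAMS, "_pre"),
                                 panel_of(row, TRAD_PARAMS, "_post"))
    sh <- classify_shunt_response(row)
    labels$id[i] <- as.character(row$id)
    labels$eld_positive[i] <- eld$positive
    labels$eld_reasons[i] <- paste(eld$reasons, collapse = ";")
    labels$shunt_status[i] <- sh$status
    labels$shunt_basis[i] <- paste(sh$basis, collapse = ";")
  }
  counts <- c(n = n,
              shunted = sum(labels$shunt_status != "not_shunted"),
              responders = sum(labels$shunt_status == "responder"),
              nonresponders = sum(labels$shunt_status == "nonresponder"))
  list(labels = labels, counts = counts)
}
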