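# Direction-aware standardization and composite improvement rates.
#
# Every cognitive test and gait parameter has a clinical orientation:
# higher_better (counts, velocity, stride/step length/height) or
# lower_better (times, step width). All z-scores and improvement rates are
# signed so that larger always means better performance / more improvement.

GAIT_PARAMS <- c("gait_velocity", "stride_length", "step_height",
                 "step_width", "turning_time")
GAIT_ORIENT <- c(gait_velocity = "higher_better",
                 stride_length = "higher_better",
                 step_height = "higher_better",
                 step_width = "lower_better",
                 turning_time = "lower_better")
COG_TESTS <- c("grammatical_reasoning", "one_back", "tmt_time",
               "stroop_correct", "stroop_rt")
TRAD_PARAMS <- c("mmse", "tug_time", "tmwt_time", "tmwt_steps")
TRAD_ORIENT <- c(mmse = "higher_better", tug_time = "lower_better",
                 tmwt_time = "lower_better", tmwt_steps = "lower_better")

#' Direction-aware z-score
#'
#' Standardizes a raw test score against a normative mean and SD, oriented
#' so that a larger z always means better performance: for `higher_better`
#' tests z = (raw - mean)/sd, for `lower_better` tests (timed tests)
#' z = (mean - raw)/sd.
#'
#' @param raw raw score (vectorized).
#' @param mean,sd normative mean and SD in raw-score units; `sd` must be > 0.
#' @param direction `"higher_better"` or `"lower_better"`.
#' @return z-score(s), dimensionless.
#' @examples
#' standardize(14, 10, 2, "higher_better")  # +2
#' standardize(140, 100, 20, "lower_better")  # -2: slower than norm
#' @export
standardize <- function(raw, mean, sd,
                        direction = c("higher_better", "lower_better")) {
  direction <- match.arg(direction)
  if (!is.finite(sd) || sd <= 0) stop("normative sd must be > 0")
  if (direction == "higher_better") (raw - mean) / sd else (mean - raw) / sd
}

#' Composite cognitive z-score
#'
#' Arithmetic mean of the five oriented z-scores of the computerized battery
#' (grammatical reasoning, one-back, trail-making time, Stroop correct
#' count, Stroop reaction time).
#'
#' @param panel named list or one-row data frame with elements
#'   `grammatical_reasoning`, `one_back`, `tmt_time`, `stroop_correct`,
#'   `stroop_rt` (raw scores).
#' @param norms normative table as returned by [read_norms()] or
#'   [default_norms()].
#' @param partial if `TRUE`, missing components are dropped and the mean
#'   taken over the rest; if `FALSE` (default) any missing component makes
#'   the result `NA` with attribute `flag = "missing_component"`.
#' @return composite z (scalar), possibly flagged.
#' @export
composite_cognitive_z <- function(panel, norms, partial = FALSE) {
  zs <- vapply(COG_TESTS, function(test) {
    raw <- panel[[test]]
    if (is.null(raw) || length(raw) == 0 || is.na(raw)) return(NA_real_)
    nr <- norms[norms$test == test, , drop = FALSE]
    if (nrow(nr) != 1) stop("norms table must have exactly one row for ", test)
    standardize(raw, nr$mean, nr$sd, nr$direction)
  }, numeric(1))
  if (anyNA(zs) && !partial) {
    return(structure(NA_real_, flag = "missing_component",
                     missing = COG_TESTS[is.na(zs)]))
  }
  mean(zs, na.rm = TRUE)
}

#' Oriented percent improvement rate
#'
#' Percent change between a pre- and post-drainage measurement, signed so a
#' positive rate always means clinical improvement: for `higher_better`
#' parameters (post - pre)/denom(pre) x 100, for `lower_better` parameters
#' (pre - post)/denom(pre) x 100. The denominator is `pre` itself
#' (`denom = "raw"`) or `|pre|` (`denom = "absolute"`), the latter needed
#' when `pre` can be negative (z-scores) so that improvement keeps a
#' positive sign.
#'
#' @param pre,post measurements in the same units.
#' @param orientation `"higher_better"` or `"lower_better"`.
#' @param denom denominator policy, `"raw"` or `"absolute"`.
#' @param eps near-zero guard: if `|pre| <= eps` the rate is undefined and
#'   `NA` is returned with attribute `flag = "zero_denominator"`.
#' @return signed percent (scalar).
#' @examples
#' improvement_rate(4, 2, "lower_better")     # turning time halved: +50
#' improvement_rate(0.60, 0.69, "higher_better")  # velocity up 15%: +15
#' @export
improvement_rate <- function(pre, post,
                             orientation = c("higher_better", "lower_better"),
                             denom = c("raw", "absolute"), eps = 1e-9) {
  orientation <- match.arg(orientation)
  denom <- match.arg(denom)
  if (is.na(pre) || is.na(post))
    return(structure(NA_real_, flag = "missing_component"))
  if (abs(pre) <= eps)
    return(structure(NA_real_, flag = "zero_denominator"))
  num <- if (orientation == "higher_better") post - pre else pre - post
  den <- if (denom == "absolute") abs(pre) else pre
  num / den * 100
}

#' Composite gait improvement rate
#'
#' Mean of the five oriented per-parameter improvement rates of the
#' quantitative gait analysis: gait velocity, stride length and step height
#' (higher is better), step width and turning time (lower is better).
#'
#' @param pre,post named lists or one-row data frames with the five gait
#'   parameters.
#' @param eps near-zero denominator guard passed to [improvement_rate()].
#' @return list with `rates` (named per-parameter percents) and `rate`
#'   (their mean, `NA` with `flags` if any component is undefined).
#' @export
gait_improvement <- function(pre, post, eps = 1e-9) {
  rates <- vapply(GAIT_PARAMS, function(pp)
    as.numeric(improvement_rate(pre[[pp]], post[[pp]],
                                GAIT_ORIENT[[pp]], "raw", eps)),
    numeric(1))
  flags <- if (anyNA(rates)) "missing_component" else character(0)
  list(rates = rates,
       rate = if (anyNA(rates)) NA_real_ else mean(rates),
       flags = flags)
}

#' Cognitive improvement rate from composite z-scores
#'
#' Percent change of the composite cognitive z-score after drainage.
#' Because the baseline composite z is negative for nearly all impaired
#' patients, the default denominator is `|z_pre|`, which keeps the sign of
#' the rate aligned with the direction of change (improvement > 0); the
#' signed-denominator variant is available via `denom = "raw"`.
#'
#' @param z_pre,z_post composite cognitive z-scores.
#' @param denom `"absolute"` (default) or `"raw"`.
#' @param eps near-zero guard on `|z_pre|`.
#' @return signed percent.
#' @examples
#' cognitive_improvement(-2, -1.5)  # +25: impairment reduced
#' cognitive_improvement(-2, -2.5)  # -25: worsened
#' @export
cognitive_improvement <- function(z_pre, z_post,
                                  denom = c("absolute", "raw"), eps = 1e-9) {
  denom <- match.arg(denom)
  improvement_rate(z_pre, z_post, orientation = "higher_better",
                   denom = denom, eps = eps)
}

#' Combined improvement rate
#'
#' Weighted mean of the cognitive and gait improvement rates; equal weights
#' by default, reflecting that cognition and gait are regarded as equally
#' important core domains.
#'
#' @param cognitive_rate,gait_rate signed percents.
#' @param weights length-2 nonnegative weights (cognitive, gait); rescaled
#'   to sum to 1.
#' @return signed percent, `NA` (flagged) if either input is undefined.
#' @export
combined_improvement <- function(cognitive_rate, gait_rate,
                                 weights = c(0.5, 0.5)) {
  if (length(weights) != 2 || any(weights < 0) || sum(weights) <= 0)
    stop("weights must be two nonnegative numbers with positive sum")
  if (is.na(cognitive_rate) || is.na(gait_rate))
    return(structure(NA_real_, flag = "missing_component"))
  w <- weights / sum(weights)
  w[1] * cognitive_rate + w[2] * gait_rate
}

#' Continuous traditional-test composite improvement rate
#'
#' Mean of the four oriented percent improvement rates of the traditional
#' battery: MMSE (higher is better; percent change, commensurate with the
#' other components), TUG time, 10-m walk time and 10-m walk steps (lower
#' is better). This is the continuous analogue of the binary traditional
#' response criteria, used as the traditional predictor score.
#'
#' @param pre,post named lists or one-row data frames with `mmse`,
#'   `tug_time`, `tmwt_time`, `tmwt_steps`.
#' @param eps near-zero denominator guard.
#' @return list with `rates` (named percents) and `rate` (mean, or `NA`
#'   flagged).
#' @export
traditional_composite <- function(pre, post, eps = 1e-9) {
  rates <- vapply(TRAD_PARAMS, function(pp)
    as.numeric(improvement_rate(pre[[pp]], post[[pp]],
                                TRAD_ORIENT[[pp]], "raw", eps)),
    numeric(1))
  flags <- if (anyNA(rates)) "missing_component" else character(0)
  list(rates = rates,
       rate = if (anyNA(rates)) NA_real_ else mean(rates),
       flags = flags)
}

#' Score a cohort: composite z-scores and all improvement rates
#'
#' Adds to the cohort table the pre/post composite cognitive z-scores, the
#' five per-parameter gait rates, and the cognitive, gait, combined and
#' traditional composite improvement rates.
#'
#' @param cohort validated cohort data frame (see [read_cohort()]).
#' @param norms normative table.
#' @param cog_denom denominator policy for the cognitive rate.
#' @param weights combined-rate weights (cognitive, gait).
#' @param partial allow partial composite means over missing components.
#' @return the cohort with columns `cognitive_z_pre`, `cognitive_z_post`,
#'   `rate_<gait parameter>` (5), `cognitive_rate`, `gait_rate`,
#'   `combined_rate`, `traditional_rate` appended.
#' @export
score_cohort <- function(cohort, norms = default_norms(),
                         cog_denom = c("absolute", "raw"),
                         weights = c(0.5, 0.5), partial = FALSE) {
  cog_denom <- match.arg(cog_denom)
  n <- nrow(cohort)
  zs_pre <- zs_post <- cog <- gait <- comb <- trad <- rep(NA_real_, n)
  grates <- matrix(NA_real_, n, length(GAIT_PARAMS),
                   dimnames = list(NULL, paste0("rate_", GAIT_PARAMS)))
  for (i in seq_len(n)) {
    row <- cohort[i, ]
    zs_pre[i] <- composite_cognitive_z(panel_of(row, COG_TESTS, "_pre"),
                                       norms, partial)
    zs_post[i] <- composite_cognitive_z(panel_of(row, COG_TESTS, "_post"),
                                        norms, partial)
    cog[i] <- cognitive_improvement(zs_pre[i], zs_post[i], cog_denom)
    g <- gait_improvement(panel_of(row, GAIT_PARAMS, "_pre"),
                          panel_of(row, GAIT_PARAMS, "_post"))
    grates[i, ] <- g$rates
    gait[i] <- g$rate
    comb[i] <- combined_improvement(cog[i], gait[i], weights)
    trad[i] <- traditional_composite(panel_of(row, TRAD_PARAMS, "_pre"),
                                     panel_of(row, TRAD_PARAMS, "_post"))$rate
  }
  cohort$cognitive_z_pre <- zs_pre
  cohort$cognitive_z_post <- zs_post
  cohort <- cbind(cohort, as.data.frame(grates))
  cohort$cognitive_rate <- cog
  cohort$gait_rate <- gait
  cohort$combined_rate <- comb
  cohort$traditional_rate <- trad
  cohort
}

panel_of <- function(row, params, suffix) {
  out <- lapply(params, function(pp) row[[paste0(pp, suffix)]])
  names(out) <- params
  out
}
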