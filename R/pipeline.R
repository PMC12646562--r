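# End-to-end orchestration: score -> label -> fit -> diagnose -> resample ->
# calibrate -> report.

SCORE_NAMES <- c("traditional", "gait", "cognitive", "combined")

#' Run the full drainage-test shunt-outcome analysis
#'
#' Scores the cohort (composite z-scores and improvement rates), classifies
#' drainage-test and shunt response, then — on the shunted subset with the
#' nonresponder as the positive class — fits unadjusted and adjusted
#' (sex + Evans index) Firth models for the traditional, gait, cognitive
#' and combined improvement rates, builds ROC summaries with Youden cutoffs
#' and stratified bootstrap CIs, compares each digital score against the
#' traditional score with the DeLong test, runs permutation tests on each
#' Firth model, and assesses calibration of the adjusted combined model.
#' Identical inputs and seed give an identical report. If the shunted
#' subset has a single outcome class, the modelling stages are skipped with
#' an explicit notice while scoring and labelling are still reported.
#'
#' @param cohort validated cohort data frame (from [read_cohort()] or
#'   [generate_cohort()]).
#' @param norms normative table.
#' @param boot_B bootstrap resamples for the diagnostic-metric CIs.
#' @param perm_B permutation iterations for the Firth models.
#' @param seed master seed; each resampling stage derives its own
#'   sub-seed from it.
#' @param score_scale ROC score scale: `"probability"` (Firth predicted
#'   probability of nonresponse, the default) or `"rate"` (sign-flipped
#'   improvement rate).
#' @param cog_denom,weights scoring options, see [score_cohort()].
#' @param level confidence level for all intervals.
#' @param calib_bins bins for the mean calibration error.
#' @param any_visit follow-up reading, see [classify_shunt_response()].
#' @return an `eld_report` object (nested list, JSON-serializable via
#'   [write_report()]).
#' @export
run_eld_analysis <- function(cohort, norms = default_norms(),
                             boot_B = 2000, perm_B = 5000, seed = 1,
                             score_scale = c("probability", "rate"),
                             cog_denom = c("absolute", "raw"),
                             weights = c(0.5, 0.5), level = 0.95,
                             calib_bins = 5, any_visit = FALSE) {
  score_scale <- match.arg(score_scale)
  cog_denom <- match.arg(cog_denom)
  validate_cohort(cohort)
  scored <- score_cohort(cohort, norms, cog_denom = cog_denom,
                         weights = weights)
  labs <- cohort_labels(scored, any_visit = any_visit)

  report <- list(
    software = list(package = "eldshunt",
                    version = as.character(utils::packageVersion("eldshunt"))),
    seed = seed,
    config = list(boot_B = boot_B, perm_B = perm_B,
                  score_scale = score_scale, cog_denom = cog_denom,
                  weights = weights, level = level,
                  calib_bins = calib_bins, any_visit = any_visit),
    counts = as.list(labs$counts),
    cohort_summary = cohort_summary(scored, labs),
    pre_post = pre_post_table(scored),
    notices = character(0)
  )

  sh_idx <- labs$labels$shunt_status != "not_shunted"
  sh <- scored[sh_idx, , drop = FALSE]
  y <- as.integer(labs$labels$shunt_status[sh_idx] == "nonresponder")
  if (length(unique(y)) < 2 || nrow(sh) < 4) {
    report$notices <- c(report$notices,
      "single-class outcome among shunted patients: model, ROC, calibration stages skipped")
    report$models <- NULL
    class(report) <- "eld_report"
    return(report)
  }

  rate_col <- paste0(SCORE_NAMES, "_rate")
  names(rate_col) <- SCORE_NAMES
  sexm <- as.integer(sh$sex == "male")
  evans <- sh$evans_index

  models <- list()
  diag_list <- list()
  scores_mat <- list()
  for (k in seq_along(SCORE_NAMES)) {
    nm <- SCORE_NAMES[k]
    rate <- sh[[rate_col[nm]]]
    ok <- !is.na(rate)
    X1 <- cbind(`(Intercept)` = 1, rate = rate[ok])
    X2 <- cbind(X1, sex_male = sexm[ok], evans_index = evans[ok])
    fit1 <- firth_fit(X1, y[ok])
    fit2 <- firth_fit(X2, y[ok])
    perm1 <- permutation_pvalue(X1, y[ok], "rate", B = perm_B,
                                seed = seed + 100 + k)
    perm2 <- permutation_pvalue(X2, y[ok], "rate", B = perm_B,
                                seed = seed + 200 + k)
    models[[nm]] <- list(
      unadjusted = model_block(fit1, level, perm1),
      adjusted = model_block(fit2, level, perm2))

    score <- if (score_scale == "probability") predict_prob(fit1, X1)
             else -rate[ok]
    scores_mat[[nm]] <- list(score = score, y = y[ok])
    diag_list[[nm]] <- diagnostic_block(score, y[ok], boot_B, level,
                                        seed = seed + 300 + k)
  }
  report$models <- models
  report$diagnostics <- diag_list

  report$delong <- lapply(setdiff(SCORE_NAMES, "traditional"), function(nm) {
    a <- scores_mat[[nm]]
    b <- scores_mat[["traditional"]]
    if (length(a$score) != length(b$score) || any(a$y != b$y))
      return(list(comparison = paste0(nm, " vs traditional"),
                  note = "unequal case sets (missing rates); skipped"))
    dl <- delong_test(a$score, b$score, a$y)
    list(comparison = paste0(nm, " vs traditional"),
         auc_digital = dl$auc_a, auc_traditional = dl$auc_b,
         Z = dl$Z, p = dl$p)
  })

  # calibration of the adjusted combined model
  rate <- sh$combined_rate
  ok <- !is.na(rate)
  Xc <- cbind(`(Intercept)` = 1, rate = rate[ok], sex_male = sexm[ok],
              evans_index = evans[ok])
  fitc <- firth_fit(Xc, y[ok])
  probs <- predict_prob(fitc, Xc)
  sp <- spiegelhalter_test(probs, y[ok])
  cs <- tryCatch(calibration_slope(probs, y[ok]), error = function(e)
    list(slope = NA_real_, intercept = NA_real_, method = "failed"))
  mce <- mean_calibration_error(probs, y[ok], bins = calib_bins)
  report$calibration <- list(
    model = "combined (adjusted)",
    spiegelhalter_z = sp$z, spiegelhalter_p = sp$p,
    slope = cs$slope, intercept = cs$intercept,
    recalibration_method = cs$method,
    mean_calibration_error = mce$error,
    bin_table = mce$bin_table)

  class(report) <- "eld_report"
  report
}

model_block <- function(fit, level, perm) {
  ci <- confint(fit, level = level, method = "wald")
  list(coefficients = as.list(fit$coefficients),
       se = as.list(fit$se),
       or = as.list(exp(fit$coefficients)),
       or_lower = as.list(exp(ci[, 1])),
       or_upper = as.list(exp(ci[, 2])),
       wald_p = as.list(2 * stats::pnorm(-abs(fit$coefficients / fit$se))),
       penalized_loglik = fit$loglik,
       converged = fit$converged,
       iterations = fit$iterations,
       permutation_p = perm$p,
       permutation_stat = perm$observed,
       permutation_nonconverged = perm$n_nonconverged)
}

diagnostic_block <- function(score, y, boot_B, level, seed) {
  yj <- youden_cutoff(score, y)
  cm <- confusion_metrics(score, y, yj$cutoff)
  d <- data.frame(score = score, y = y)
  boot_stat <- function(metric) {
    function(dd) {
      yc <- youden_cutoff(dd$score, dd$y)
      mm <- confusion_metrics(dd$score, dd$y, yc$cutoff)
      switch(metric,
             auc = auc(dd$score, dd$y), cutoff = yc$cutoff,
             sens = mm$sens, spec = mm$spec, ppv = mm$ppv, npv = mm$npv)
    }
  }
  metrics <- c("auc", "cutoff", "sens", "spec", "ppv", "npv")
  cis <- lapply(seq_along(metrics), function(j)
    bootstrap_ci(d, boot_stat(metrics[j]), B = boot_B, level = level,
                 strata = d$y, seed = seed + j))
  names(cis) <- metrics
  point <- list(auc = auc(score, y), cutoff = yj$cutoff, sens = cm$sens,
                spec = cm$spec, ppv = cm$ppv, npv = cm$npv)
  out <- lapply(metrics, function(m)
    list(estimate = point[[m]], lower = cis[[m]]$lower,
         upper = cis[[m]]$upper))
  names(out) <- metrics
  out$confusion <- list(tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn)
  out$youden_J <- yj$J
  out$boot_failures <- sum(vapply(cis, function(x) x$failures, numeric(1)))
  out
}

cohort_summary <- function(scored, labs) {
  grp <- ifelse(scored$shunted == 1, "shunted", "no_shunt")
  med_iqr <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    list(median = q[2], q1 = q[1], q3 = q[3])
  }
  by_group <- function(f) {
    out <- lapply(split(seq_len(nrow(scored)), grp), function(idx)
      f(scored[idx, , drop = FALSE]))
    out$all <- f(scored)
    out
  }
  list(
    n = as.list(c(table(grp), all = nrow(scored))),
    age = by_group(function(d) med_iqr(d$age)),
    sex_male_prop = by_group(function(d) mean(d$sex == "male")),
    evans_index = by_group(function(d) med_iqr(d$evans_index)),
    desh_score = by_group(function(d) med_iqr(d$desh_score)),
    cognitive_z_pre = by_group(function(d)
      list(mean = mean(d$cognitive_z_pre, na.rm = TRUE),
           sd = stats::sd(d$cognitive_z_pre, na.rm = TRUE))),
    cognitive_rate = by_group(function(d) med_iqr(d$cognitive_rate)),
    gait_rate = by_group(function(d) med_iqr(d$gait_rate)),
    combined_rate = by_group(function(d) med_iqr(d$combined_rate)),
    eld_positive_prop = mean(labs$labels$eld_positive)
  )
}

pre_post_table <- function(scored) {
  params <- c(TRAD_PARAMS, COG_TESTS, GAIT_PARAMS)
  rows <- lapply(params, function(pp) {
    pre <- scored[[paste0(pp, "_pre")]]
    post <- scored[[paste0(pp, "_post")]]
    res <- tryCatch(pre_post_comparison(pre, post, "wilcoxon_signed_rank"),
                    error = function(e) list(statistic = NA_real_,
                                             p = NA_real_))
    list(parameter = pp, median_pre = stats::median(pre, na.rm = TRUE),
         median_post = stats::median(post, na.rm = TRUE),
         wilcoxon_p = res$p)
  })
  rows
}

#' @export
print.eld_report <- function(x, ...) {
  cat("Drainage-test shunt-outcome analysis report\n")
  cat(sprintf("  cohort: n=%d, shunted=%d, responders=%d, nonresponders=%d\n",
              x$counts$n, x$counts$shunted, x$counts$responders,
              x$counts$nonresponders))
  if (length(x$notices)) cat("  notice:", paste(x$notices, collapse = "; "),
                             "\n")
  if (!is.null(x$diagnostics)) {
    cat("  diagnostics (positive class = nonresponder):\n")
    for (nm in names(x$diagnostics)) {
      d <- x$diagnostics[[nm]]
      cat(sprintf(
        "    %-12s AUC %.3f (%.3f-%.3f)  cutoff %.3f  sens %.3f  spec %.3f\n",
        nm, d$auc$estimate, d$auc$lower, d$auc$upper,
        d$cutoff$estimate, d$sens$estimate, d$spec$estimate))
    }
  }
  if (!is.null(x$delong)) {
    for (dl in x$delong) {
      if (!is.null(dl$note)) next
      cat(sprintf("  DeLong %s: Z=%.2f, p=%.4f\n", dl$comparison, dl$Z,
                  dl$p))
    }
  }
  if (!is.null(x$calibration)) {
    cat(sprintf(
      "  calibration (%s): Spiegelhalter p=%.2f, slope=%.3f, mean error=%.1f%%\n",
      x$calibration$model, x$calibration$spiegelhalter_p,
      x$calibration$slope, x$calibration$mean_calibration_error))
  }
  invisible(x)
}

strip_nan <- function(x) {
  if (is.list(x)) return(lapply(x, strip_nan))
  if (is.numeric(x)) x[is.nan(x)] <- NA_real_
  x
}

#' Write / read an analysis report as JSON
#'
#' All fitted quantities, seeds and configuration are serialized; undefined
#' metrics (`NaN`) are written as `null`, never as `NaN`.
#'
#' @param report an `eld_report`.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  x <- strip_nan(unclass(report))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
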