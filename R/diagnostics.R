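# ROC analysis, DeLong comparison, resampling inference and calibration.
#
# Orientation convention: labels mark the POSITIVE class as 1 and a higher
# score means "more positive". In the shunt-outcome pipeline the positive
# class is the nonresponder and scores are predicted probabilities of
# nonresponse (or sign-flipped improvement rates in raw-rate mode).

#' Empirical ROC curve
#'
#' Operating points over thresholds `c(-Inf, sorted unique scores, +Inf)`
#' with a positive call iff `score >= threshold`, so the curve runs from
#' (sens, spec) = (1, 0) to (0, 1).
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels binary labels (1 = positive class).
#' @return object of class `roc_curve`: list with `thresholds`, `sens`,
#'   `spec`, and the input `scores`/`labels`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- coerce_binary(labels)
  stopifnot(length(scores) == length(labels))
  if (sum(labels) == 0 || sum(labels) == length(labels))
    stop("both classes must be present to build a ROC curve")
  thr <- c(-Inf, sort(unique(scores)), Inf)
  sens <- vapply(thr, function(t) mean(scores[labels == 1] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[labels == 0] < t), numeric(1))
  structure(list(thresholds = thr, sens = sens, spec = spec,
                 scores = scores, labels = labels),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d positives / %d negatives, AUC = %.4f\n",
              sum(x$labels), sum(1 - x$labels), auc(x$scores, x$labels)))
  invisible(x)
}

#' Area under the ROC curve (Mann-Whitney form with tie credit)
#'
#' AUC = mean over all positive-negative pairs of
#' \eqn{1[s^+ > s^-] + \frac{1}{2} 1[s^+ = s^-]}, computed via midranks.
#'
#' @inheritParams roc_curve
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- coerce_binary(labels)
  m <- sum(labels)
  n <- sum(1 - labels)
  if (m == 0 || n == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels == 1]) - m * (m + 1) / 2) / (m * n)
}

#' Youden-index optimal cutoff
#'
#' Scans all candidate thresholds (midpoints between adjacent observed
#' scores, plus below-minimum and above-maximum sentinels) and returns the
#' one maximizing J = sensitivity + specificity - 1. Ties are broken toward
#' the smallest qualifying threshold. If all scores are equal, J = 0 is
#' returned with a warning.
#'
#' @param scores numeric scores (or a [roc_curve()] object).
#' @param labels binary labels (ignored when `scores` is a `roc_curve`).
#' @return list with `cutoff`, `J`, `sens`, `spec` at the cutoff.
#' @export
youden_cutoff <- function(scores, labels = NULL) {
  if (inherits(scores, "roc_curve")) {
    labels <- scores$labels
    scores <- scores$scores
  }
  labels <- coerce_binary(labels)
  u <- sort(unique(scores))
  if (length(u) == 1) {
    warning("degenerate ROC: all scores equal; J = 0")
    return(list(cutoff = u, J = 0, sens = 1, spec = 0))
  }
  cand <- c(u[1] - 1, (u[-length(u)] + u[-1]) / 2, u[length(u)] + 1)
  best <- list(cutoff = NA_real_, J = -Inf, sens = NA_real_, spec = NA_real_)
  for (t in cand) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    J <- sens + spec - 1
    if (J > best$J + 1e-12) best <- list(cutoff = t, J = J, sens = sens,
                                         spec = spec)
  }
  best
}

#' Confusion-matrix metrics at a cutoff
#'
#' Positive call iff `score >= cutoff`.
#'
#' @inheritParams roc_curve
#' @param cutoff finite decision threshold.
#' @return list with counts `tp`, `fp`, `tn`, `fn` and rates `sens`,
#'   `spec`, `ppv`, `npv` (`NaN` with a flag when a denominator is empty).
#' @export
confusion_metrics <- function(scores, labels, cutoff) {
  labels <- coerce_binary(labels)
  stopifnot(is.finite(cutoff))
  call_pos <- scores >= cutoff
  tp <- sum(call_pos & labels == 1)
  fp <- sum(call_pos & labels == 0)
  fn <- sum(!call_pos & labels == 1)
  tn <- sum(!call_pos & labels == 0)
  flags <- character(0)
  if (tp + fp == 0) flags <- c(flags, "undefined_ppv")
  if (tn + fn == 0) flags <- c(flags, "undefined_npv")
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sens = tp / (tp + fn), spec = tn / (tn + fp),
       ppv = tp / (tp + fp), npv = tn / (tn + fn), flags = flags)
}

#' Reconstruct the integer confusion matrix from rounded rates
#'
#' Given sensitivity and specificity rounded to a printed precision and the
#' class sizes, finds the unique integer matrix `(tp, fn, tn, fp)` whose
#' exact rates round to the inputs, and derives PPV/NPV from it. Errors,
#' listing the nearest candidates, if no or multiple consistent matrices
#' exist.
#'
#' @param sens,spec rounded rates in \[0, 1\].
#' @param n_pos,n_neg class sizes (positives, negatives).
#' @param digits precision at which `sens`/`spec` were rounded.
#' @return list with `tp`, `fn`, `tn`, `fp`, exact `sens`, `spec`, `ppv`,
#'   `npv`.
#' @examples
#' metrics_from_rates(0.400, 0.706, 5, 34)  # tp=2 fn=3 tn=24 fp=10
#' @export
metrics_from_rates <- function(sens, spec, n_pos, n_neg, digits = 3) {
  match_count <- function(rate, n, what) {
    k <- 0:n
    hit <- k[round(k / n, digits) == round(rate, digits)]
    if (length(hit) == 1) return(hit)
    if (length(hit) > 1)
      stop("ambiguous ", what, ": counts ", paste(hit, collapse = ", "),
           " all round to ", round(rate, digits))
    near <- k[order(abs(k / n - rate))][1:2]
    stop("no integer count of ", n, " yields ", what, " = ",
         format(rate), "; nearest candidates: ",
         paste(sprintf("%d (%.4f)", near, near / n), collapse = ", "))
  }
  tp <- match_count(sens, n_pos, "sensitivity")
  tn <- match_count(spec, n_neg, "specificity")
  fn <- n_pos - tp
  fp <- n_neg - tn
  list(tp = tp, fn = fn, tn = tn, fp = fp,
       sens = tp / n_pos, spec = tn / n_neg,
       ppv = tp / (tp + fp), npv = tn / (tn + fn))
}

# per-observation structural (placement) components of the AUC
delong_components <- function(scores, labels) {
  labels <- coerce_binary(labels)
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos)
  n <- length(neg)
  if (m == 0 || n == 0) stop("both classes must be present")
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi),
       m = m, n = n)
}

#' DeLong variance of a single AUC
#'
#' Variance estimate from the per-observation placement values:
#' `var(V10)/m + var(V01)/n`.
#'
#' @inheritParams roc_curve
#' @export
delong_auc_var <- function(scores, labels) {
  cc <- delong_components(scores, labels)
  v10 <- if (cc$m > 1) stats::var(cc$v10) else 0
  v01 <- if (cc$n > 1) stats::var(cc$v01) else 0
  v10 / cc$m + v01 / cc$n
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two scores measured on the same subjects:
#' \eqn{Z = (AUC_a - AUC_b)/\sqrt{v_a + v_b - 2c}} with variances and
#' covariance from the placement-value components; two-sided normal p.
#'
#' @param scores_a,scores_b two score vectors on the same subjects.
#' @param labels shared binary labels.
#' @return list with `auc_a`, `auc_b`, `Z`, `p`, `var_diff`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  m <- ca$m
  n <- ca$n
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- ca$auc - cb$auc
  if (var_diff <= 1e-15) {
    Z <- if (abs(diff) <= 1e-15) 0 else sign(diff) * Inf
  } else {
    Z <- diff / sqrt(var_diff)
  }
  list(auc_a = ca$auc, auc_b = cb$auc, Z = Z,
       p = 2 * stats::pnorm(-abs(Z)), var_diff = var_diff)
}

#' Stratified percentile bootstrap confidence interval
#'
#' Resamples rows with replacement, within strata when `strata` is given
#' (stratification by outcome class keeps rare classes represented in every
#' resample), and returns the percentile interval of the statistic.
#' Resample indices are pre-generated from `seed` so results do not depend
#' on evaluation order. Resamples on which the statistic errors or returns
#' `NA` are logged and dropped.
#'
#' @param data data frame (or vector) to resample.
#' @param statistic function of the resampled data returning a scalar.
#' @param B number of resamples (>= 1).
#' @param level confidence level.
#' @param strata optional stratification vector, `length(strata) == nrow`.
#' @param seed optional integer seed.
#' @return list with `estimate` (statistic on the full data), `lower`,
#'   `upper`, `B`, `failures`, `stats` (the resample values).
#' @export
bootstrap_ci <- function(data, statistic, B = 2000, level = 0.95,
                         strata = NULL, seed = NULL) {
  if (B < 1) stop("B must be >= 1")
  take <- function(d, idx) if (is.data.frame(d)) d[idx, , drop = FALSE]
                           else d[idx]
  nr <- if (is.data.frame(data)) nrow(data) else length(data)
  if (!is.null(seed)) set.seed(seed)
  idx_mat <- if (is.null(strata)) {
    matrix(sample.int(nr, nr * B, replace = TRUE), nrow = B)
  } else {
    stopifnot(length(strata) == nr)
    groups <- split(seq_len(nr), strata)
    t(replicate(B, unlist(lapply(groups, function(g)
      g[sample.int(length(g), length(g), replace = TRUE)]),
      use.names = FALSE)))
  }
  est <- statistic(data)
  stats_ <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    stats_[b] <- tryCatch(as.numeric(statistic(take(data, idx_mat[b, ]))),
                          error = function(e) NA_real_)
  }
  ok <- stats_[!is.na(stats_)]
  a <- (1 - level) / 2
  qs <- if (length(ok)) stats::quantile(ok, c(a, 1 - a), names = FALSE)
        else c(NA_real_, NA_real_)
  list(estimate = est, lower = qs[1], upper = qs[2], B = B,
       failures = sum(is.na(stats_)), stats = stats_)
}

#' Permutation test for a covariate block in a Firth model
#'
#' Permutes the outcome labels `B` times, refits the full and null Firth
#' models, and compares the penalized likelihood-ratio statistic of the
#' block of interest against its observed value:
#' p = (1 + #\{perm >= observed\}) / (B + 1). Non-converged permutation
#' refits are counted toward the numerator (conservative) and logged. When
#' the null model is intercept-only its penalized log-likelihood is
#' permutation-invariant and computed once.
#'
#' @param design full design matrix (with intercept).
#' @param outcome binary outcome.
#' @param block columns of `design` under test (names or indices); the null
#'   design drops them.
#' @param B number of permutations.
#' @param seed optional integer seed.
#' @return list with `p`, `observed` (LR statistic), `B`,
#'   `n_nonconverged`.
#' @export
permutation_pvalue <- function(design, outcome, block, B = 5000,
                               seed = NULL) {
  if (B < 1) stop("B must be >= 1")
  design <- as.matrix(design)
  y <- coerce_binary(outcome)
  if (is.character(block)) block <- match(block, colnames(design))
  if (anyNA(block) || length(block) == 0) stop("invalid covariate block")
  null_cols <- setdiff(seq_len(ncol(design)), block)
  if (length(null_cols) == 0) stop("null design would be empty")
  X_null <- design[, null_cols, drop = FALSE]
  intercept_only <- ncol(X_null) == 1 &&
    all(X_null[, 1] == X_null[1, 1]) && X_null[1, 1] != 0

  fit_full <- firth_fit(design, y)
  fit_null <- firth_fit(X_null, y)
  observed <- penalized_lr_stat(fit_full, fit_null)
  null_ll_fixed <- if (intercept_only) fit_null$loglik else NULL

  if (!is.null(seed)) set.seed(seed)
  perms <- replicate(B, sample(y), simplify = FALSE)
  n_exceed <- 0L
  n_noncvg <- 0L
  for (b in seq_len(B)) {
    yp <- perms[[b]]
    stat <- tryCatch({
      ff <- firth_fit(design, yp)
      ll0 <- if (!is.null(null_ll_fixed)) null_ll_fixed
             else firth_fit(X_null, yp)$loglik
      if (!ff$converged) stop("non-converged")
      max(0, 2 * (ff$loglik - ll0))
    }, error = function(e) NA_real_)
    if (is.na(stat)) {
      n_noncvg <- n_noncvg + 1L
      n_exceed <- n_exceed + 1L  # conservative
    } else if (stat >= observed - 1e-12) {
      n_exceed <- n_exceed + 1L
    }
  }
  list(p = (1 + n_exceed) / (B + 1), observed = observed, B = B,
       n_nonconverged = n_noncvg)
}

#' Spiegelhalter test of overall calibration
#'
#' \eqn{z = \sum_i (y_i - p_i)(1 - 2p_i) \big/
#' \sqrt{\sum_i (1 - 2p_i)^2 p_i (1 - p_i)}}, referred to the standard
#' normal. When every probability equals 1/2 both numerator and denominator
#' vanish and z is defined as 0.
#'
#' @param probs predicted probabilities strictly in (0, 1).
#' @param outcomes binary outcomes.
#' @return list with `z` and two-sided `p`.
#' @export
spiegelhalter_test <- function(probs, outcomes) {
  y <- coerce_binary(outcomes)
  stopifnot(all(probs > 0 & probs < 1))
  num <- sum((y - probs) * (1 - 2 * probs))
  den <- sqrt(sum((1 - 2 * probs)^2 * probs * (1 - probs)))
  z <- if (den == 0) 0 else num / den
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Logistic recalibration slope and intercept
#'
#' Regresses the outcomes on the logit of the predicted probabilities;
#' slope 1 and intercept 0 indicate perfect calibration, slope < 1
#' overconfidence. If the recalibration model separates, a Firth fit is
#' used instead and flagged.
#'
#' @inheritParams spiegelhalter_test
#' @return list with `slope`, `intercept`, `method`
#'   (`"ml"` or `"firth"`).
#' @export
calibration_slope <- function(probs, outcomes) {
  y <- coerce_binary(outcomes)
  stopifnot(all(probs > 0 & probs < 1))
  if (sum(y) == 0 || sum(1 - y) == 0)
    stop("both outcome classes must be present to recalibrate")
  lp <- stats::qlogis(probs)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ lp, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separated || any(abs(stats::coef(fit)) > 15)) {
    ff <- firth_fit(cbind(`(Intercept)` = 1, lp = lp), y)
    return(list(slope = unname(ff$coefficients[2]),
                intercept = unname(ff$coefficients[1]), method = "firth"))
  }
  cf <- stats::coef(fit)
  list(slope = unname(cf[2]), intercept = unname(cf[1]), method = "ml")
}

#' Mean absolute calibration error over equal-count bins
#'
#' Splits predictions into `bins` equal-count bins (empty/duplicate bins
#' merged) and averages `|mean predicted - observed event rate|`, in
#' percent.
#'
#' @inheritParams spiegelhalter_test
#' @param bins number of bins (>= 2).
#' @return list with `error` (percent) and `bin_table` (data frame:
#'   `n`, `mean_prob`, `event_rate` per bin).
#' @export
mean_calibration_error <- function(probs, outcomes, bins = 10) {
  y <- coerce_binary(outcomes)
  if (bins < 2) stop("bins must be >= 2")
  breaks <- unique(stats::quantile(probs, probs = seq(0, 1, length.out = bins + 1)))
  if (length(breaks) < 3) breaks <- c(min(probs) - 1e-9, stats::median(probs),
                                      max(probs) + 1e-9)
  grp <- cut(probs, breaks = breaks, include.lowest = TRUE)
  tab <- do.call(rbind, lapply(split(seq_along(probs), grp), function(idx) {
    if (length(idx) == 0) return(NULL)
    data.frame(n = length(idx), mean_prob = mean(probs[idx]),
               event_rate = mean(y[idx]))
  }))
  rownames(tab) <- NULL
  list(error = 100 * mean(abs(tab$mean_prob - tab$event_rate)),
       bin_table = tab)
}

#' Paired pre/post comparison
#'
#' Two-sided paired tests of a parameter before and after drainage,
#' delegating to [stats::t.test()] or [stats::wilcox.test()].
#'
#' @param pre,post equal-length paired measurement vectors.
#' @param kind `"paired_t"` or `"wilcoxon_signed_rank"`.
#' @return list with `statistic`, `p`, `kind`, and `flags` (contains
#'   `"zero_variance"` when all paired differences are 0, in which case
#'   `statistic`/`p` are `NA`).
#' @export
pre_post_comparison <- function(pre, post,
                                kind = c("paired_t",
                                         "wilcoxon_signed_rank")) {
  kind <- match.arg(kind)
  stopifnot(length(pre) == length(post))
  keep <- !(is.na(pre) | is.na(post))
  pre <- pre[keep]
  post <- post[keep]
  d <- post - pre
  if (sum(d != 0) < 1 || length(d) < 2) {
    if (length(d) >= 2 && all(d == 0))
      return(list(statistic = NA_real_, p = NA_real_, kind = kind,
                  flags = "zero_variance"))
    stop("need at least 2 pairs with a non-tied pair")
  }
  res <- if (kind == "paired_t") {
    stats::t.test(post, pre, paired = TRUE)
  } else {
    suppressWarnings(stats::wilcox.test(post, pre, paired = TRUE,
                                        exact = FALSE))
  }
  list(statistic = unname(res$statistic), p = res$p.value, kind = kind,
       flags = character(0))
}
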