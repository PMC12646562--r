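rand_instance <- function(n = NULL) {
  n <- if (is.null(n)) sample(4:30, 1) else n
  labels <- c(0, 1, rbinom(n - 2, 1, 0.4))  # both classes guaranteed
  scores <- sample(seq(0, 5, by = 0.5), n, replace = TRUE)  # many ties
  list(scores = scores, labels = labels)
}

test_that("rank-based AUC equals the brute-force pairwise definition", {
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auc(c(1, 1, 2, 2), c(0, 1, 0, 1)), 0.5)
  set.seed(31)
  for (k in 1:60) {
    inst <- rand_instance()
    a <- auc(inst$scores, inst$labels)
    expect_identical(a, auc_brute(inst$scores, inst$labels))
    # label-flip symmetry
    expect_equal(auc(inst$scores, 1 - inst$labels), 1 - a)
  }
  expect_error(auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  inst <- rand_instance(25)
  expect_equal(auc(inst$scores, inst$labels),
               as.numeric(pROC::auc(pROC::roc(inst$labels, inst$scores,
                                              direction = "<",
                                              quiet = TRUE))))
})

test_that("ROC curves are monotone with the required endpoints", {
  set.seed(13)
  inst <- rand_instance(20)
  rc <- roc_curve(inst$scores, inst$labels)
  expect_true(all(diff(rc$sens) <= 1e-12))
  expect_true(all(diff(rc$spec) >= -1e-12))
  expect_equal(c(rc$sens[1], rc$spec[1]), c(1, 0))
  expect_equal(c(rc$sens[length(rc$sens)], rc$spec[length(rc$spec)]),
               c(0, 1))
})

test_that("Youden scan equals exhaustive midpoint search", {
  # perfect separation: J = 1, cutoff strictly between the classes
  res <- youden_cutoff(c(1, 2, 8, 9), c(0, 0, 1, 1))
  expect_equal(res$J, 1)
  expect_gt(res$cutoff, 2)
  expect_lt(res$cutoff, 8)
  set.seed(17)
  for (k in 1:60) {
    inst <- rand_instance()
    fast <- youden_cutoff(inst$scores, inst$labels)
    brute <- youden_brute(inst$scores, inst$labels)
    expect_equal(fast$J, brute$J)
    expect_equal(fast$cutoff, brute$cutoff)
    # translation invariance
    shifted <- youden_cutoff(inst$scores + 10, inst$labels)
    expect_equal(shifted$J, fast$J)
    expect_equal(shifted$cutoff, fast$cutoff + 10)
  }
  expect_warning(res <- youden_cutoff(rep(2, 6), c(0, 1, 0, 1, 0, 1)),
                 "degenerate")
  expect_equal(res$J, 0)
})

test_that("confusion metrics satisfy their identities", {
  cm <- confusion_metrics(c(1, 2, 8, 9), c(0, 0, 1, 1), 5)
  expect_equal(unlist(cm[c("sens", "spec", "ppv", "npv")]),
               c(sens = 1, spec = 1, ppv = 1, npv = 1))
  set.seed(23)
  for (k in 1:40) {
    inst <- rand_instance()
    cutoff <- runif(1, -1, 6)
    cm <- confusion_metrics(inst$scores, inst$labels, cutoff)
    # naive four-counter loop
    tp <- fp <- tn <- fn <- 0
    for (i in seq_along(inst$scores)) {
      pos <- inst$scores[i] >= cutoff
      if (pos && inst$labels[i] == 1) tp <- tp + 1
      if (pos && inst$labels[i] == 0) fp <- fp + 1
      if (!pos && inst$labels[i] == 0) tn <- tn + 1
      if (!pos && inst$labels[i] == 1) fn <- fn + 1
    }
    expect_equal(unlist(cm[c("tp", "fp", "tn", "fn")]),
                 c(tp = tp, fp = fp, tn = tn, fn = fn))
    expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, length(inst$scores))
    if (fn == 0 && tn + fn > 0) expect_equal(cm$npv, 1)
  }
})

test_that("confusion matrices are reconstructed uniquely from rounded rates", {
  m <- metrics_from_rates(0.400, 0.706, 5, 34)
  expect_equal(unlist(m[c("tp", "fn", "tn", "fp")]),
               c(tp = 2, fn = 3, tn = 24, fp = 10))
  expect_equal(m$ppv, 2 / 12)
  expect_equal(m$npv, 24 / 27)
  m2 <- metrics_from_rates(1.000, 0.794, 5, 34)
  expect_equal(unlist(m2[c("tp", "fn", "tn", "fp")]),
               c(tp = 5, fn = 0, tn = 27, fp = 7))
  expect_equal(m2$ppv, 5 / 12)
  expect_equal(m2$npv, 1)
  m3 <- metrics_from_rates(1, 1, 7, 11)
  expect_equal(c(m3$ppv, m3$npv), c(1, 1))
  # inconsistent rate -> error naming nearest candidates
  expect_error(metrics_from_rates(0.333, 0.706, 5, 34), "nearest candidates")
})

test_that("DeLong variance matches brute-force structural components", {
  set.seed(41)
  for (k in 1:40) {
    inst <- rand_instance(sample(8:20, 1))
    expect_equal(delong_auc_var(inst$scores, inst$labels),
                 delong_var_brute(inst$scores, inst$labels),
                 tolerance = 1e-12)
  }
})

test_that("DeLong test is antisymmetric, null on identical scores, and matches pROC", {
  set.seed(43)
  labels <- c(rep(1, 8), rep(0, 12))
  a <- rnorm(20) + labels
  b <- rnorm(20)
  res <- delong_test(a, a, labels)
  expect_equal(res$Z, 0)
  expect_equal(res$p, 1)
  ab <- delong_test(a, b, labels)
  ba <- delong_test(b, a, labels)
  expect_equal(ab$Z, -ba$Z)
  expect_equal(ab$p, ba$p)
  skip_if_not_installed("pROC")
  pr <- pROC::roc.test(pROC::roc(labels, a, direction = "<", quiet = TRUE),
                       pROC::roc(labels, b, direction = "<", quiet = TRUE),
                       method = "delong", paired = TRUE)
  expect_equal(abs(ab$Z), abs(as.numeric(pr$statistic)), tolerance = 1e-8)
  expect_equal(ab$p, pr$p.value, tolerance = 1e-8)
})

test_that("stratified bootstrap produces sane percentile intervals", {
  x <- c(10, 10, 10, 10)
  ci <- bootstrap_ci(x, mean, B = 50, seed = 1)
  expect_equal(ci$lower, 10)
  expect_equal(ci$upper, 10)
  set.seed(2)
  x <- rnorm(40, mean = 3)
  ci <- bootstrap_ci(x, mean, B = 2000, seed = 3)
  expect_true(ci$lower <= ci$estimate && ci$estimate <= ci$upper)
  # stratification keeps the rare class in every resample
  d <- data.frame(score = rnorm(39), y = c(rep(1, 5), rep(0, 34)))
  ci <- bootstrap_ci(d, function(dd) auc(dd$score, dd$y), B = 200,
                     strata = d$y, seed = 4)
  expect_equal(ci$failures, 0)
  # determinism under the seed
  ci2 <- bootstrap_ci(d, function(dd) auc(dd$score, dd$y), B = 200,
                      strata = d$y, seed = 4)
  expect_identical(ci$stats, ci2$stats)
  expect_error(bootstrap_ci(x, mean, B = 0), "B must be")
})

test_that("permutation p-values respect their bounds and detect signal", {
  # n = 2: the statistic is invariant under label permutation -> p = 1
  X <- cbind(1, x = c(1, 2))
  res <- permutation_pvalue(X, c(0, 1), "x", B = 20, seed = 5)
  expect_equal(res$p, 1)
  # add-one bound and strong-signal significance
  set.seed(6)
  x <- rnorm(60)
  y <- rbinom(60, 1, plogis(2 * x))
  res <- permutation_pvalue(cbind(1, x = x), y, "x", B = 99, seed = 7)
  expect_gte(res$p, 1 / 100)
  expect_lte(res$p, 0.05)
  expect_error(permutation_pvalue(cbind(1, x = x), y, "nope", B = 10),
               "invalid covariate block")
})

test_that("Spiegelhalter statistic follows its closed form", {
  expect_equal(spiegelhalter_test(rep(0.5, 10), rep(c(0, 1), 5))$z, 0)
  set.seed(9)
  p <- runif(50, 0.05, 0.95)
  y <- rbinom(50, 1, p)
  res <- spiegelhalter_test(p, y)
  num <- sum((y - p) * (1 - 2 * p))
  den <- sqrt(sum((1 - 2 * p)^2 * p * (1 - p)))
  expect_equal(res$z, num / den)
  expect_equal(res$p, 2 * pnorm(-abs(res$z)))
  expect_error(spiegelhalter_test(c(0, 0.5), c(0, 1)), "probs")
})

test_that("recalibration recovers slope 1 for calibrated and 0.5 for doubled logits", {
  set.seed(10)
  n <- 4000
  q <- plogis(rnorm(n, 0, 1.2))
  y <- rbinom(n, 1, q)
  cal <- calibration_slope(q, y)
  expect_equal(cal$slope, 1, tolerance = 0.1)
  expect_equal(cal$intercept, 0, tolerance = 0.15)
  # overconfident probabilities: logits doubled -> slope 0.5
  over <- plogis(2 * qlogis(q))
  cal2 <- calibration_slope(over, y)
  expect_equal(cal2$slope, 0.5, tolerance = 0.07)
  expect_error(calibration_slope(rep(0.4, 10), rep(1, 10)), "both outcome")
})

test_that("mean calibration error matches a hand-computed binned example", {
  # two clean bins: |0.2 - 0.25| and |0.8 - 0.5| -> mean 0.175 -> 17.5%
  probs <- c(rep(0.2, 4), rep(0.8, 4))
  y <- c(1, 0, 0, 0, 1, 1, 0, 0)
  res <- mean_calibration_error(probs, y, bins = 2)
  expect_equal(res$error, 17.5)
  expect_equal(nrow(res$bin_table), 2)
  # perfectly calibrated bins -> 0
  probs3 <- c(rep(0.25, 4), rep(0.75, 4))
  y3 <- c(1, 0, 0, 0, 1, 1, 1, 0)
  expect_equal(mean_calibration_error(probs3, y3, bins = 2)$error, 0)
  # bounds
  set.seed(12)
  p <- runif(100, 0.01, 0.99)
  e <- mean_calibration_error(p, rbinom(100, 1, p), bins = 10)$error
  expect_true(e >= 0 && e <= 100)
  expect_error(mean_calibration_error(p, rbinom(100, 1, p), bins = 1),
               "bins")
})

test_that("paired pre/post comparisons delegate to the standard tests", {
  set.seed(14)
  pre <- rnorm(30, 10)
  post <- pre + 1 + rnorm(30, sd = 0.5)
  res <- pre_post_comparison(pre, post, "paired_t")
  oracle <- t.test(post, pre, paired = TRUE)
  expect_equal(res$statistic, unname(oracle$statistic))
  expect_equal(res$p, oracle$p.value)
  expect_lt(res$p, 0.01)
  # sign-flip antisymmetry of the t statistic
  flip <- pre_post_comparison(post, pre, "paired_t")
  expect_equal(flip$statistic, -res$statistic)
  # zero-variance differences are flagged, not mis-reported
  same <- pre_post_comparison(pre, pre)
  expect_true(is.na(same$p))
  expect_equal(same$flags, "zero_variance")
  w <- pre_post_comparison(pre, post, "wilcoxon_signed_rank")
  expect_lt(w$p, 0.01)
  expect_error(pre_post_comparison(1, 2), "at least 2 pairs")
})
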