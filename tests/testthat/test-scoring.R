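test_that("standardize is direction-aware and affine with slope 1/sd", {
  expect_equal(standardize(10, 10, 2, "higher_better"), 0)
  expect_equal(standardize(100, 100, 20, "lower_better"), 0)
  expect_equal(standardize(14, 10, 2, "higher_better"), 2)
  expect_equal(standardize(140, 100, 20, "lower_better"), -2)
  expect_error(standardize(1, 0, 0, "higher_better"), "sd must be > 0")
  # affine in raw with slope +-1/sd
  raws <- seq(-5, 25, by = 3)
  z_hi <- standardize(raws, 10, 4, "higher_better")
  z_lo <- standardize(raws, 10, 4, "lower_better")
  expect_equal(diff(z_hi) / diff(raws), rep(1 / 4, length(raws) - 1))
  expect_equal(diff(z_lo) / diff(raws), rep(-1 / 4, length(raws) - 1))
})

test_that("composite cognitive z is the mean of five oriented z-scores", {
  norms <- default_norms()
  # raw scores exactly at the norm means -> composite 0
  panel0 <- list(grammatical_reasoning = 9, one_back = 14, tmt_time = 70,
                 stroop_correct = 52, stroop_rt = 85)
  expect_equal(composite_cognitive_z(panel0, norms), 0)
  # components (1, 1, 1, -1, -1) -> 0.2
  panel <- list(grammatical_reasoning = 9 + 4, one_back = 14 + 5,
                tmt_time = 70 - 25, stroop_correct = 52 - 8,
                stroop_rt = 85 + 28)
  expect_equal(composite_cognitive_z(panel, norms), 0.2)
  # permuting the component order (via permuted norms) leaves it unchanged
  expect_equal(composite_cognitive_z(panel, norms[5:1, ]), 0.2)
  # missing component flags and yields NA unless partial
  panel$one_back <- NA
  res <- composite_cognitive_z(panel, norms)
  expect_true(is.na(res))
  expect_equal(attr(res, "flag"), "missing_component")
  expect_equal(composite_cognitive_z(panel, norms, partial = TRUE),
               mean(c(1, 1, -1, -1)))
})

test_that("improvement_rate is oriented so positive always means better", {
  expect_equal(improvement_rate(7, 7, "higher_better"), 0)
  expect_equal(improvement_rate(7, 7, "lower_better"), 0)
  expect_equal(improvement_rate(4, 2, "lower_better"), 50)
  expect_equal(improvement_rate(0.60, 0.69, "higher_better"), 15)
  # sign iff improvement, over random cases and both orientations
  set.seed(5)
  for (k in 1:50) {
    pre <- runif(1, 0.5, 10)
    post <- runif(1, 0.5, 10)
    hb <- improvement_rate(pre, post, "higher_better")
    lb <- improvement_rate(pre, post, "lower_better")
    expect_equal(hb > 0, post > pre)
    expect_equal(lb > 0, post < pre)
    expect_equal(hb, -lb)
  }
  # near-zero denominator flagged, not infinite
  r <- improvement_rate(1e-12, 1, "higher_better")
  expect_true(is.na(r))
  expect_equal(attr(r, "flag"), "zero_denominator")
})

test_that("gait improvement is the mean of the five oriented rates", {
  pre <- list(gait_velocity = 0.5, stride_length = 1.0, step_height = 0.08,
              step_width = 0.16, turning_time = 4)
  expect_equal(gait_improvement(pre, pre)$rate, 0)
  # construct rates (10, 10, 10, -5, 0) in the canonical parameter order
  post <- list(gait_velocity = 0.55, stride_length = 1.10,
               step_height = 0.088, step_width = 0.168, turning_time = 4)
  g <- gait_improvement(pre, post)
  expect_equal(unname(g$rates), c(10, 10, 10, -5, 0))
  expect_equal(g$rate, 5)
  # rate bounded by component min/max
  expect_true(g$rate >= min(g$rates) && g$rate <= max(g$rates))
  # missing component flags the composite
  post$step_width <- NA
  g2 <- gait_improvement(pre, post)
  expect_true(is.na(g2$rate))
  expect_equal(g2$flags, "missing_component")
})

test_that("cognitive improvement uses an absolute-value denominator", {
  expect_equal(cognitive_improvement(-2, -2), 0)
  # impaired baseline improving toward 0 must read positive
  expect_equal(cognitive_improvement(-2, -1.5), 25)
  expect_equal(cognitive_improvement(-2, -2.5), -25)
  # raw (signed) denominator flips the sign for negative baselines
  expect_equal(cognitive_improvement(-2, -1.5, denom = "raw"), -25)
  expect_equal(cognitive_improvement(2, 2.5), 25)
})

test_that("combined improvement is a weighted mean with equal default", {
  expect_equal(combined_improvement(20, 10), 15)
  for (x in c(-12.3, 0, 7)) expect_equal(combined_improvement(x, x), x)
  expect_equal(combined_improvement(20, 10, weights = c(1, 0)), 20)
  expect_error(combined_improvement(1, 1, weights = c(-1, 2)), "weights")
  r <- combined_improvement(NA, 10)
  expect_true(is.na(r))
  expect_equal(attr(r, "flag"), "missing_component")
})

test_that("traditional composite averages four oriented rates", {
  pre <- list(mmse = 25, tug_time = 10, tmwt_time = 10, tmwt_steps = 20)
  expect_equal(traditional_composite(pre, pre)$rate, 0)
  # rates (8, 12, 20, 0)
  post <- list(mmse = 27, tug_time = 8.8, tmwt_time = 8, tmwt_steps = 20)
  tr <- traditional_composite(pre, post)
  expect_equal(unname(tr$rates), c(8, 12, 20, 0))
  expect_equal(tr$rate, 10)
  # worsening only TUG time strictly decreases the composite
  worse <- post
  worse$tug_time <- 9.6
  expect_lt(traditional_composite(pre, worse)$rate, tr$rate)
})

test_that("score_cohort appends consistent composite columns", {
  gen <- generate_cohort(default_cohort_config(n_total = 20, n_shunted = 10,
                                               n_nonresponders = 3),
                         seed = 3)
  sc <- score_cohort(gen$cohort)
  expect_true(all(c("cognitive_rate", "gait_rate", "combined_rate",
                    "traditional_rate", "cognitive_z_pre") %in% names(sc)))
  # combined = mean(cognitive, gait) wherever both are defined
  ok <- !is.na(sc$cognitive_rate) & !is.na(sc$gait_rate)
  expect_equal(sc$combined_rate[ok],
               (sc$cognitive_rate[ok] + sc$gait_rate[ok]) / 2)
  # gait composite = mean of exactly the five per-parameter rates
  rate_cols <- paste0("rate_", c("gait_velocity", "stride_length",
                                 "step_height", "step_width",
                                 "turning_time"))
  expect_equal(sc$gait_rate, rowMeans(sc[, rate_cols]))
})
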