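test_that("Firth fit matches the half-cell-correction closed form on 2x2 tables", {
  # worked example: cells a=2, b=1, c=1, d=2 -> OR = 25/9
  d <- expand_2x2(2, 1, 1, 2)
  fit <- firth_fit(d$X, d$y)
  expect_true(fit$converged)
  expect_equal(exp(fit$coefficients[["x"]]), 25 / 9, tolerance = 1e-8)
  # predicted probabilities reproduce the half-corrected cell proportions
  expect_equal(sort(unique(round(fit$fitted, 8))), c(1.5 / 4, 2.5 / 4))
  # hat values sum to the number of design columns
  expect_equal(sum(fit$hat), 2, tolerance = 1e-8)

  # independent oracle: grid/optim maximization of an independently coded
  # penalized likelihood agrees with the closed form
  opt <- optim(c(0, 0), function(b) -pll_indep(d$X, d$y, b),
               method = "BFGS")
  expect_equal(exp(opt$par[2]), 25 / 9, tolerance = 1e-5)

  # property over random small tables (including zero cells)
  set.seed(42)
  for (k in 1:40) {
    cells <- rpois(4, 3)
    if (sum(cells[c(1, 3)]) == 0 || sum(cells[c(2, 4)]) == 0) next
    if (sum(cells[1:2]) == 0 || sum(cells[3:4]) == 0) next
    dd <- expand_2x2(cells[1], cells[2], cells[3], cells[4])
    ff <- firth_fit(dd$X, dd$y)
    expect_equal(exp(ff$coefficients[["x"]]),
                 firth_or_2x2(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-6)
  }
})

test_that("coefficients stay finite and converged under complete separation", {
  d <- data.frame(x = c(-4, -3, -2, -1, 1, 2, 3, 4),
                  y = c(0, 0, 0, 0, 1, 1, 1, 1))
  fit <- firth_glm(y ~ x, d)
  expect_true(fit$converged)
  expect_true(all(is.finite(coef(fit))))
  expect_true(all(is.finite(fit$se)))
  # plain ML diverges on the same data
  ml <- suppressWarnings(glm(y ~ x, binomial, d))
  expect_gt(abs(coef(ml)[2]), 5 * abs(coef(fit)[2]))
  # penalized likelihood improved over the null start
  expect_gte(fit$loglik, firth_pll(fit$X, fit$y, c(0, 0)))
})

test_that("Firth bias correction vanishes as n grows (ML oracle)", {
  gap <- vapply(c(50, 5000), function(n) {
    set.seed(99)
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.3 + 0.8 * x))
    fit <- firth_fit(cbind(1, x = x), y)
    ml <- glm(y ~ x, binomial)
    abs(fit$coefficients[["x"]] - coef(ml)[["x"]])
  }, numeric(1))
  expect_lt(gap[2], gap[1] / 5)
  expect_lt(gap[2], 0.01)
})

test_that("design validation and response coercion behave", {
  X <- cbind(1, a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
  expect_error(firth_fit(X, c(0, 1, 0, 1)), "collinear column\\(s\\): b")
  expect_error(firth_fit(cbind(1, 1:4), c(0, 0, 0, 0)),
               "at least one event")
  expect_error(firth_fit(cbind(1, 1:4), c(0, 1, 2, 1)), "binary")
  # factor response: second level is the event, as in glm
  d <- data.frame(x = c(-2, -1, 1, 2, -1.5, 1.5),
                  y = factor(c("resp", "resp", "nonresp", "nonresp",
                               "resp", "nonresp"),
                             levels = c("resp", "nonresp")))
  fit <- firth_glm(y ~ x, d)
  expect_gt(coef(fit)[["x"]], 0)
})

test_that("Wald intervals are level-monotone and bracket the estimate", {
  d <- expand_2x2(4, 2, 1, 5)
  fit <- firth_fit(d$X, d$y)
  ci95 <- confint(fit, level = 0.95)
  ci99 <- confint(fit, level = 0.99)
  or <- exp(fit$coefficients[["x"]])
  expect_equal(or, firth_or_2x2(4, 2, 1, 5), tolerance = 1e-6)
  expect_true(exp(ci95["x", "lower"]) < or && or < exp(ci95["x", "upper"]))
  expect_lt(ci99["x", "lower"], ci95["x", "lower"])
  expect_gt(ci99["x", "upper"], ci95["x", "upper"])
  nc <- fit
  nc$converged <- FALSE
  expect_error(confint(nc), "non-converged")
})

test_that("profile intervals agree with Wald at large n and stay finite under separation", {
  set.seed(7)
  n <- 600
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.2 + 0.5 * x))
  fit <- firth_fit(cbind(`(Intercept)` = 1, x = x), y)
  w <- confint(fit, parm = "x", method = "wald")
  p <- confint(fit, parm = "x", method = "profile")
  expect_equal(p[1, "lower"], w[1, "lower"], tolerance = 0.05)
  expect_equal(p[1, "upper"], w[1, "upper"], tolerance = 0.05)

  d <- data.frame(x = c(-3, -2, -1, 1, 2, 3), y = c(0, 0, 0, 1, 1, 1))
  sep <- firth_glm(y ~ x, d)
  ps <- confint(sep, parm = "x", method = "profile")
  expect_true(all(is.finite(ps)))
  expect_true(ps[1, "lower"] < coef(sep)[["x"]],
              ps[1, "upper"] > coef(sep)[["x"]])
})

test_that("prediction validates the design and is monotone in covariates", {
  d <- expand_2x2(3, 2, 1, 4)
  fit <- firth_fit(d$X, d$y)
  expect_error(predict_prob(fit, cbind(1, 1, 1)), "columns")
  probs <- predict_prob(fit, cbind(1, c(0, 1)))
  expect_true(all(probs > 0 & probs < 1))
  expect_equal(probs[1], plogis(fit$coefficients[[1]]))
  # positive coefficient -> monotone increasing in that covariate
  b <- fit$coefficients[["x"]]
  expect_equal(probs[2] > probs[1], b > 0)
})

test_that("penalized LR statistic is zero for identical models and positive for signal", {
  set.seed(21)
  n <- 200
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + log(5) * x))  # strong effect
  X1 <- cbind(`(Intercept)` = 1, x = x)
  X0 <- X1[, 1, drop = FALSE]
  full <- firth_fit(X1, y)
  null <- firth_fit(X0, y)
  expect_equal(penalized_lr_stat(full, full), 0)
  expect_gt(penalized_lr_stat(full, null), qchisq(0.95, 1))
  expect_error(penalized_lr_stat(null, full), "not nested")
  # pure-noise covariate: small but nonnegative statistic
  z <- rnorm(n)
  noise_full <- firth_fit(cbind(X1, z = z), y)
  expect_gte(penalized_lr_stat(noise_full, full), 0)
})

test_that("model methods round out the S3 interface", {
  d <- data.frame(x = c(-2, -1, -0.5, 0.5, 1, 2, -1.2, 0.8),
                  y = c(0, 0, 1, 0, 1, 1, 0, 1))
  fit <- firth_glm(y ~ x, d)
  expect_s3_class(fit, "firth_glm")
  expect_equal(unname(predict(fit, data.frame(x = 0))),
               unname(plogis(coef(fit)[1])))
  expect_equal(length(residuals(fit)), 8)
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  expect_output(print(fit), "Firth penalized")
  expect_output(print(summary(fit)), "Odds ratios")
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(8, 3))
  expect_true(all(unlist(sims) %in% 0:1))
})
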