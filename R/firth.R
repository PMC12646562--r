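# Firth penalized logistic regression: Jeffreys-prior bias reduction for
# binary logistic models, the estimator of choice when events are few or the
# data are (quasi-)separated. Implemented from scratch: modified-score Newton
# iteration with step-halving on the penalized log-likelihood.

log1pexp <- function(x) {
  out <- x
  lo <- x <= 33
  out[lo] <- log1p(exp(x[lo]))
  out
}

#' Penalized log-likelihood of a logistic model with Jeffreys penalty
#'
#' Computes \eqn{\ell(\beta) + \frac{1}{2}\log\det I(\beta)} where
#' \eqn{I(\beta) = X^T W X} is the Fisher information of the logistic model
#' and \eqn{W = \mathrm{diag}\{\pi_i(1-\pi_i)\}}.
#'
#' @param X design matrix (including intercept column).
#' @param y binary 0/1 response vector.
#' @param beta coefficient vector.
#' @return scalar penalized log-likelihood.
#' @keywords internal
firth_pll <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  pi <- stats::plogis(eta)
  w <- pi * (1 - pi)
  XtWX <- crossprod(X, X * w)
  ld <- as.numeric(determinant(XtWX, logarithm = TRUE)$modulus)
  sum(y * eta - log1pexp(eta)) + 0.5 * ld
}

#' Fit a Firth penalized logistic regression (matrix interface)
#'
#' Maximizes the Jeffreys-penalized log-likelihood
#' \eqn{\ell^*(\beta) = \ell(\beta) + \frac{1}{2}\log\det I(\beta)} by Newton
#' iteration on the modified score
#' \eqn{U^*_j = \sum_i (y_i - \pi_i + h_i(1/2 - \pi_i)) x_{ij}}, where
#' \eqn{h_i} are the leverages of the weighted design. Step-halving keeps the
#' penalized log-likelihood non-decreasing across accepted steps, so the fit
#' returns finite coefficients even under complete separation.
#'
#' @param X numeric design matrix with intercept column; must be full column
#'   rank.
#' @param y binary response: 0/1 numeric, logical, or two-level factor
#'   (second level is the event).
#' @param max_iter maximum Newton iterations.
#' @param tol convergence tolerance: iteration stops when both the
#'   infinity-norm of the modified score and of the step fall below `tol`.
#' @param max_halving maximum step-halvings per iteration.
#' @return an object of class `firth_fit`: list with `coefficients`, `se`,
#'   `vcov` (inverse penalized information), `loglik` (penalized),
#'   `iterations`, `converged`, `hat` (leverages, summing to `ncol(X)`),
#'   `fitted` (probabilities), `X`, `y`, `n`.
#' @examples
#' X <- cbind(1, c(1, 1, 1, 0, 0, 0))
#' y <- c(1, 1, 0, 1, 0, 0)
#' f <- firth_fit(X, y)
#' exp(f$coefficients[2])  # odds ratio, (2.5 * 2.5) / (1.5 * 1.5)
#' @export
firth_fit <- function(X, y, max_iter = 100L, tol = 1e-8, max_halving = 20L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- coerce_binary(y)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (sum(y) < 1 || sum(1 - y) < 1)
    stop("need at least one event and one non-event")
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }

  beta <- numeric(p)
  ll <- firth_pll(X, y, beta)
  converged <- FALSE
  iter <- 0L
  U <- numeric(p)
  Iinv <- NULL
  h <- numeric(nrow(X))

  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    pi <- stats::plogis(eta)
    w <- pmax(pi * (1 - pi), .Machine$double.xmin)
    XW <- X * w
    Info <- crossprod(X, XW)
    Iinv <- tryCatch(chol2inv(chol(Info)), error = function(e) solve(Info))
    h <- rowSums((X %*% Iinv) * XW)
    U <- drop(crossprod(X, y - pi + h * (0.5 - pi)))
    delta <- drop(Iinv %*% U)

    # step-halving: accept only steps that do not decrease the penalized ll
    ll_new <- firth_pll(X, y, beta + delta)
    halvings <- 0L
    while (!is.finite(ll_new) || ll_new < ll - 1e-12) {
      if (halvings >= max_halving) break
      delta <- delta / 2
      ll_new <- firth_pll(X, y, beta + delta)
      halvings <- halvings + 1L
    }
    if (is.finite(ll_new) && ll_new >= ll - 1e-12) {
      beta <- beta + delta
      ll <- ll_new
    }
    if (max(abs(U)) <= tol && max(abs(delta)) <= tol) {
      converged <- TRUE
      break
    }
  }

  # refresh quantities at the optimum
  eta <- drop(X %*% beta)
  pi <- stats::plogis(eta)
  w <- pmax(pi * (1 - pi), .Machine$double.xmin)
  XW <- X * w
  Info <- crossprod(X, XW)
  Iinv <- tryCatch(chol2inv(chol(Info)), error = function(e) solve(Info))
  h <- rowSums((X %*% Iinv) * XW)
  names(beta) <- colnames(X)
  dimnames(Iinv) <- list(colnames(X), colnames(X))

  structure(list(
    coefficients = beta,
    se = sqrt(diag(Iinv)),
    vcov = Iinv,
    loglik = ll,
    iterations = iter,
    converged = converged,
    hat = h,
    fitted = pi,
    X = X,
    y = y,
    n = length(y)
  ), class = "firth_fit")
}

coerce_binary <- function(y) {
  if (is.factor(y)) {
    if (nlevels(y) != 2) stop("factor response must have exactly 2 levels")
    y <- as.integer(y) - 1L
  }
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("response must be binary (0/1)")
  y
}

#' Fit a Firth penalized logistic regression (formula interface)
#'
#' Formula front end to [firth_fit()], following the conventions of
#' [stats::glm()] with `family = binomial`: for a factor response the second
#' level is the modelled event.
#'
#' @param formula model formula.
#' @param data data frame.
#' @param ... passed to [firth_fit()] (`max_iter`, `tol`, `max_halving`).
#' @return object of class `c("firth_glm", "firth_fit")` with `terms` and
#'   `call` in addition to the [firth_fit()] components.
#' @seealso [confint.firth_fit()], [predict.firth_glm()],
#'   [penalized_lr_stat()]
#' @examples
#' d <- data.frame(x = c(-2, -1, -0.5, 0.5, 1, 2),
#'                 y = c(0, 0, 0, 1, 1, 1))  # completely separated
#' f <- firth_glm(y ~ x, d)
#' coef(f)  # finite despite separation
#' @export
firth_glm <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data, drop.unused.levels = TRUE)
  mt <- attr(mf, "terms")
  y <- stats::model.response(mf)
  X <- stats::model.matrix(mt, mf)
  fit <- firth_fit(X, y, ...)
  fit$terms <- mt
  fit$xlevels <- stats::.getXlevels(mt, mf)
  fit$call <- match.call()
  class(fit) <- c("firth_glm", "firth_fit")
  fit
}

#' @export
coef.firth_fit <- function(object, ...) object$coefficients

#' @export
vcov.firth_fit <- function(object, ...) object$vcov

#' @export
logLik.firth_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            class = "logLik")
}

#' @export
fitted.firth_fit <- function(object, ...) object$fitted

#' @export
residuals.firth_fit <- function(object,
                                type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  r <- object$y - object$fitted
  if (type == "pearson")
    r <- r / sqrt(object$fitted * (1 - object$fitted))
  r
}

#' @export
print.firth_fit <- function(x, digits = 4, ...) {
  cat("Firth penalized logistic regression\n")
  if (!is.null(x$call)) {
    cat("Call: ")
    print(x$call)
  }
  cat("\nCoefficients:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("\nPenalized log-likelihood: %.4f (%d iterations%s)\n",
              x$loglik, x$iterations,
              if (x$converged) ", converged" else ", NOT converged"))
  invisible(x)
}

#' @export
summary.firth_fit <- function(object, level = 0.95, ...) {
  z <- object$coefficients / object$se
  p <- 2 * stats::pnorm(-abs(z))
  ci <- confint(object, level = level, method = "wald")
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = object$se,
               z = z, `Pr(>|z|)` = p,
               OR = exp(object$coefficients),
               `OR lo` = exp(ci[, 1]), `OR hi` = exp(ci[, 2]))
  structure(list(coefficients = tab, loglik = object$loglik,
                 iterations = object$iterations,
                 converged = object$converged, level = level,
                 call = object$call),
            class = "summary.firth_fit")
}

#' @export
print.summary.firth_fit <- function(x, ...) {
  cat("Firth penalized logistic regression\n\n")
  stats::printCoefmat(x$coefficients[, 1:4, drop = FALSE], P.values = TRUE,
                      has.Pvalue = TRUE)
  cat(sprintf("\nOdds ratios (Wald %g%% CI):\n", 100 * x$level))
  print(round(x$coefficients[, 5:7, drop = FALSE], 4))
  cat(sprintf("\nPenalized log-likelihood: %.4f (%d iterations%s)\n",
              x$loglik, x$iterations,
              if (x$converged) ", converged" else ", NOT converged"))
  invisible(x)
}

#' Confidence intervals for Firth model coefficients
#'
#' Wald intervals use the inverse penalized information at the optimum:
#' \eqn{\beta_j \pm z_{(1+level)/2}\,SE_j}. Profile intervals are penalized
#' likelihood-ratio bounds: the values of \eqn{\beta_j} at which the profile
#' penalized log-likelihood drops \eqn{\chi^2_1(level)/2} below its maximum,
#' located by root finding with an automatically widened bracket. Both are on
#' the log-odds scale; exponentiate for odds ratios.
#'
#' @param object a converged `firth_fit`.
#' @param parm coefficients to profile (names or indices); default all.
#' @param level confidence level.
#' @param method `"wald"` or `"profile"`.
#' @param ... unused.
#' @return matrix with columns `lower`, `upper`, one row per coefficient.
#' @export
confint.firth_fit <- function(object, parm, level = 0.95,
                              method = c("wald", "profile"), ...) {
  method <- match.arg(method)
  if (!object$converged)
    stop("refusing to compute intervals from a non-converged fit")
  cf <- object$coefficients
  if (missing(parm)) parm <- seq_along(cf)
  if (is.character(parm)) parm <- match(parm, names(cf))
  if (method == "wald") {
    zq <- stats::qnorm((1 + level) / 2)
    out <- cbind(lower = cf[parm] - zq * object$se[parm],
                 upper = cf[parm] + zq * object$se[parm])
  } else {
    out <- t(vapply(parm, function(j) profile_bounds(object, j, level),
                    numeric(2)))
    colnames(out) <- c("lower", "upper")
  }
  rownames(out) <- names(cf)[parm]
  out
}

# profile penalized log-likelihood at beta_j fixed = b: maximize over the
# remaining coefficients (full-model Jeffreys penalty throughout)
profile_pll <- function(object, j, b) {
  X <- object$X
  y <- object$y
  p <- ncol(X)
  free <- setdiff(seq_len(p), j)
  if (length(free) == 0L) return(firth_pll(X, y, b))
  start <- object$coefficients[free]
  obj <- function(bf) {
    beta <- numeric(p)
    beta[j] <- b
    beta[free] <- bf
    -firth_pll(X, y, beta)
  }
  opt <- stats::optim(start, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  -opt$value
}

profile_bounds <- function(object, j, level) {
  drop_ <- stats::qchisq(level, df = 1) / 2
  target <- object$loglik - drop_
  bhat <- object$coefficients[j]
  se <- max(object$se[j], 1e-6)
  g <- function(b) profile_pll(object, j, b) - target

  find <- function(direction) {
    width <- 1.5 * stats::qnorm((1 + level) / 2) * se
    for (k in 1:8) {
      b <- bhat + direction * width
      if (g(b) < 0)
        return(stats::uniroot(g, sort(c(bhat, b)), tol = 1e-6)$root)
      width <- width * 2
    }
    stop("profile bound not bracketed after widening; coefficient ",
         names(object$coefficients)[j])
  }
  c(find(-1), find(1))
}

#' Predicted event probabilities from a Firth fit
#'
#' @param object fitted `firth_glm`.
#' @param newdata data frame of covariates; omit for in-sample predictions.
#' @param type `"response"` (probability, clamped strictly inside (0,1)) or
#'   `"link"` (linear predictor).
#' @param ... unused.
#' @export
predict.firth_glm <- function(object, newdata = NULL,
                              type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- drop(object$X %*% object$coefficients)
  } else {
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
    X <- stats::model.matrix(tt, mf)
    if (!identical(colnames(X), colnames(object$X)))
      stop("newdata columns do not match the fitted design")
    eta <- drop(X %*% object$coefficients)
  }
  if (type == "link") return(eta)
  pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
}

#' @rdname predict.firth_glm
#' @param design design matrix matching the fit (matrix interface).
#' @param fit a `firth_fit`.
#' @export
predict_prob <- function(fit, design) {
  design <- as.matrix(design)
  if (ncol(design) != ncol(fit$X))
    stop("design has ", ncol(design), " columns; fit expects ", ncol(fit$X))
  eta <- drop(design %*% fit$coefficients)
  pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
}

#' @export
simulate.firth_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$fitted
  out <- as.data.frame(
    matrix(stats::rbinom(length(p) * nsim, 1, rep(p, nsim)),
           ncol = nsim, dimnames = list(NULL, paste0("sim_", seq_len(nsim)))))
  out
}

#' Penalized likelihood-ratio statistic between nested Firth fits
#'
#' \eqn{2(\ell^*_{full} - \ell^*_{null})}, floored at zero. Used as the test
#' statistic in permutation tests of a covariate block.
#'
#' @param fit_full fit of the full model.
#' @param fit_null fit of the nested null model (its design columns must be a
#'   subset of the full design's).
#' @return nonnegative scalar.
#' @export
penalized_lr_stat <- function(fit_full, fit_null) {
  if (!all(colnames(fit_null$X) %in% colnames(fit_full$X)))
    stop("null design is not nested in the full design")
  max(0, 2 * (fit_full$loglik - fit_null$loglik))
}
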