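# Four-parameter log-normal peak regression of cardiomyocyte organization
# against actin fraction:
#
#   y = y0 + a * x * exp(-0.5 * (ln(x / x0) / b)^2),   x > 0
#
# For a < 0 the curve has a unique interior minimum at x = x0 * exp(b^2).

#' Evaluate the 4-parameter log-normal curve
#'
#' @param a,b,x0,y0 coefficients (`x0 > 0`, `b != 0`).
#' @param x evaluation points, all `> 0`.
#' @return `y0 + a*x*exp(-0.5*(log(x/x0)/b)^2)`.
#' @export
lognormal_eval <- function(a, b, x0, y0, x) {
  if (any(x <= 0)) stop("x must be positive")
  if (x0 <= 0) stop("x0 must be positive")
  if (b == 0) stop("b must be nonzero")
  y0 + a * x * exp(-0.5 * (log(x / x0) / b)^2)
}

#' Location of the curve's interior extremum
#'
#' For `a < 0` this is the unique minimum of the fitted organization curve.
#'
#' @param fit a `lognormal_fit` object, or a named coefficient vector with
#'   `b` and `x0`.
#' @return `x0 * exp(b^2)`.
#' @export
lognormal_extremum <- function(fit) {
  cf <- if (inherits(fit, "lognormal_fit")) coef(fit) else fit
  unname(cf[["x0"]] * exp(cf[["b"]]^2))
}

default_lognormal_init <- function(x, y) {
  y0 <- max(y)
  sm <- stats::lowess(x, y, f = 2 / 3)
  x0 <- sm$x[which.min(sm$y)]
  if (x0 <= 0) x0 <- min(x[x > 0])
  a <- (min(y) - max(y)) / x0
  if (a == 0) a <- -1e-3
  list(a = a, b = 0.35, x0 = x0, y0 = y0)
}

#' Fit the 4-parameter log-normal regression
#'
#' Unconstrained nonlinear least squares (nl2sol trust region through
#' `stats::nls(algorithm = "port")`).  Points with `x == 0` (pure-fibroblast
#' wells, where the model is undefined) are excluded with a message;
#' negative `x` is an error.  R-squared is `1 - SS_res/SS_tot` and
#' per-coefficient standard errors and p-values come from asymptotic normal
#' theory.
#'
#' @param x,y data vectors (at least 5 usable points).
#' @param init optional named list/vector of starting values `a`, `b`, `x0`,
#'   `y0`; the default places the dip at the minimum of a lowess smooth.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the relative offset.
#' @return Object of class `lognormal_fit` with coefficients, standard
#'   errors, p-values, `r_squared`, `converged`, `n_iterations`, residuals
#'   and the retained data.
#' @export
fit_lognormal <- function(x, y, init = NULL, max_iter = 200, tol = 1e-8) {
  stopifnot(length(x) == length(y))
  if (any(x < 0)) stop("x must be nonnegative")
  drop0 <- x == 0
  n_excluded <- sum(drop0)
  if (n_excluded > 0) {
    message("excluding ", n_excluded, " point(s) with x = 0")
    x <- x[!drop0]; y <- y[!drop0]
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 5) stop("need at least 5 points with x > 0")

  if (sd(y) == 0) {
    # degenerate flat response: a ~ 0 fits exactly, R^2 undefined
    cf <- c(a = 0, b = 0.35, x0 = median(x), y0 = y[1])
    return(structure(list(coefficients = cf,
                          se = setNames(rep(NA_real_, 4), names(cf)),
                          p_values = setNames(rep(NA_real_, 4), names(cf)),
                          r_squared = NA_real_, converged = TRUE,
                          n_iterations = 0L, residuals = y - y[1],
                          fitted = rep(y[1], length(y)),
                          data = data.frame(x = x, y = y),
                          n_excluded = n_excluded),
                     class = "lognormal_fit"))
  }
  if (is.null(init)) init <- default_lognormal_init(x, y)
  dat <- data.frame(x = x, y = y)
  fit <- nls(y ~ y0 + a * x * exp(-0.5 * (log(x / x0) / b)^2),
             data = dat, start = init, algorithm = "port",
             control = stats::nls.control(maxiter = max_iter, tol = tol,
                                          warnOnly = TRUE))
  cf <- coef(fit)
  res <- resid(fit)
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
    setNames(rep(NA_real_, 4), names(cf)))
  tval <- cf / se
  pval <- 2 * pt(-abs(tval), df = length(x) - length(cf))
  conv <- fit$convInfo$isConv
  structure(list(coefficients = cf[c("a", "b", "x0", "y0")],
                 se = se[c("a", "b", "x0", "y0")],
                 p_values = pval[c("a", "b", "x0", "y0")],
                 r_squared = r2, converged = isTRUE(conv),
                 n_iterations = fit$convInfo$finIter,
                 residuals = res, fitted = stats::fitted(fit),
                 data = dat, n_excluded = n_excluded, nls = fit),
            class = "lognormal_fit")
}

#' @export
coef.lognormal_fit <- function(object, ...) object$coefficients

#' @export
residuals.lognormal_fit <- function(object, ...) object$residuals

#' @export
predict.lognormal_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x
       else if (is.data.frame(newdata)) newdata$x else newdata
  cf <- coef(object)
  lognormal_eval(cf[["a"]], cf[["b"]], cf[["x0"]], cf[["y0"]], x)
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cf <- coef(x)
  cat("Four-parameter log-normal fit: y = y0 + a*x*exp(-0.5*(ln(x/x0)/b)^2)\n")
  cat(sprintf("  a = %.4f, b = %.4f, x0 = %.4f, y0 = %.4f\n",
              cf[["a"]], cf[["b"]], cf[["x0"]], cf[["y0"]]))
  cat(sprintf("  R-squared: %s, converged: %s (%d iterations), n = %d\n",
              ifelse(is.na(x$r_squared), "undefined",
                     sprintf("%.4f", x$r_squared)),
              x$converged, x$n_iterations, nrow(x$data)))
  if (!is.na(cf[["a"]]) && cf[["a"]] < 0)
    cat(sprintf("  minimum of the curve at x = %.4f\n", lognormal_extremum(x)))
  invisible(x)
}

#' @export
summary.lognormal_fit <- function(object, ...) {
  tab <- data.frame(estimate = coef(object), std_error = object$se,
                    p_value = object$p_values)
  structure(list(coefficients = tab, r_squared = object$r_squared,
                 converged = object$converged,
                 n_iterations = object$n_iterations,
                 n = nrow(object$data), n_excluded = object$n_excluded),
            class = "summary.lognormal_fit")
}

#' @export
print.summary.lognormal_fit <- function(x, ...) {
  print(x$coefficients, digits = 4)
  cat(sprintf("R-squared %s on %d points (%d excluded at x = 0)\n",
              ifelse(is.na(x$r_squared), "undefined",
                     sprintf("%.4f", x$r_squared)), x$n, x$n_excluded))
  invisible(x)
}

#' @export
plot.lognormal_fit <- function(x, ...) {
  ord <- order(x$data$x)
  graphics::plot(x$data$x, x$data$y, xlab = "actin fraction", ylab = "OOP",
                 ...)
  xs <- seq(max(min(x$data$x), 1e-3), max(x$data$x), length.out = 200)
  graphics::lines(xs, predict(x, xs), col = "red")
  invisible(x)
}
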