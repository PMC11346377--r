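# S3 methods for fitted ssn_lm objects.

#' @export
print.ssn_lm <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  cat("\nCall:\n", paste(deparse(x$call), collapse = "\n"), "\n\n", sep = "")
  cat("Coefficients:\n")
  print.default(format(stats::coef(x), digits = digits), print.gap = 2L,
                quote = FALSE)
  cat("\nCovariance (", toupper(x$estmethod), "):\n", sep = "")
  print(x$params)
  invisible(x)
}

#' @export
coef.ssn_lm <- function(object, ...) object$coefficients

#' @export
vcov.ssn_lm <- function(object, ...) object$vcov_beta

#' @export
fitted.ssn_lm <- function(object, ...) object$fitted.values

#' Residuals of a fitted stream-network model
#'
#' @param object A fitted `ssn_lm`.
#' @param type `"response"` (marginal residuals `y - X beta`, the default) or
#'   `"standardized"` (Cholesky-whitened residuals, iid N(0, 1) under the
#'   fitted model).
#' @param ... Unused.
#' @export
residuals.ssn_lm <- function(object, type = c("response", "standardized"), ...) {
  type <- match.arg(type)
  r <- object$residuals
  if (type == "standardized") {
    r <- drop(backsolve(object$sigma_chol, r, transpose = TRUE))
  }
  r
}

#' @export
logLik.ssn_lm <- function(object, ...) {
  structure(object$loglik,
            df = object$q + if (object$estmethod == "ml") object$p else 0,
            nobs = object$n, class = "logLik")
}

#' @export
AIC.ssn_lm <- function(object, ..., k = 2) {
  -2 * object$loglik +
    k * (object$q + if (object$estmethod == "ml") object$p else 0)
}

#' @export
deviance.ssn_lm <- function(object, ...) -2 * object$loglik

#' @export
nobs.ssn_lm <- function(object, ...) object$n

#' @export
formula.ssn_lm <- function(x, ...) x$formula

#' @export
confint.ssn_lm <- function(object, parm, level = 0.95, ...) {
  est <- stats::coef(object)
  se <- sqrt(diag(object$vcov_beta))
  if (missing(parm)) parm <- names(est)
  z <- stats::qnorm((1 + level) / 2)
  out <- cbind(est[parm] - z * se[parm], est[parm] + z * se[parm])
  colnames(out) <- paste(format(100 * c((1 - level) / 2, (1 + level) / 2),
                                trim = TRUE), "%")
  out
}

#' Summarize a fitted stream-network model
#'
#' @param object A fitted `ssn_lm`.
#' @param ... Unused.
#' @return A `summary.ssn_lm` with a Wald coefficient table (z statistics,
#'   two-sided normal p-values), the covariance-parameter estimates, and fit
#'   statistics.
#' @export
summary.ssn_lm <- function(object, ...) {
  est <- stats::coef(object)
  se <- sqrt(diag(object$vcov_beta))
  zval <- est / se
  pval <- 2 * stats::pnorm(-abs(zval))
  ctab <- cbind(Estimate = est, `Std. Error` = se, `z value` = zval,
                `Pr(>|z|)` = pval)
  structure(
    list(call = object$call, coefficients = ctab, params = object$params,
         estmethod = object$estmethod, loglik = object$loglik,
         AIC = object$AIC, n = object$n, p = object$p, q = object$q,
         pseudo_r2 = pseudo_r2(object),
         residual_summary = summary(object$residuals)),
    class = "summary.ssn_lm"
  )
}

#' @export
print.summary.ssn_lm <- function(x, digits = max(3L, getOption("digits") - 3L),
                                 ...) {
  cat("\nCall:\n", paste(deparse(x$call), collapse = "\n"), "\n", sep = "")
  cat("\nResiduals:\n")
  print(x$residual_summary, digits = digits)
  cat("\nCoefficients (fixed effects):\n")
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat("\nCovariance parameters (", toupper(x$estmethod), "):\n", sep = "")
  print(x$params)
  cat("\nLog-likelihood:", format(x$loglik, digits = digits),
      "  AIC:", format(x$AIC, digits = digits), "\n")
  cat("Pseudo R-squared:", format(x$pseudo_r2, digits = digits), "\n")
  invisible(x)
}

pseudo_r2 <- function(object) {
  f <- object$fitted.values
  if (stats::sd(f) == 0) return(0)
  stats::cor(object$y, f)^2
}

#' Diagnostic plots for a fitted stream-network model
#'
#' Residuals-versus-fitted and a normal Q-Q plot of the standardized
#' (Cholesky-whitened) residuals, which are iid standard normal under a
#' correctly specified model.
#'
#' @param x A fitted `ssn_lm`.
#' @param which Subset of `1:2` selecting the plots.
#' @param ... Passed to the underlying plot calls.
#' @export
plot.ssn_lm <- function(x, which = 1:2, ...) {
  if (1 %in% which) {
    graphics::plot(fitted(x), residuals(x), xlab = "Fitted values",
                   ylab = "Residuals", main = "Residuals vs fitted", ...)
    graphics::abline(h = 0, lty = 2)
  }
  if (2 %in% which) {
    r <- residuals(x, type = "standardized")
    stats::qqnorm(r, main = "Normal Q-Q (standardized residuals)", ...)
    stats::qqline(r, lty = 2)
  }
  invisible(x)
}
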