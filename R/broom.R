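# tidy / glance / augment in the broom idiom, defined as local generics so the
# package has no tidyverse dependency.

#' Turn a fitted model into a tidy coefficient table
#' @param x A model object.
#' @param ... Method-specific arguments.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model-fit summary
#' @param x A model object.
#' @param ... Method-specific arguments.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Augment data with model quantities
#' @param x A model object.
#' @param ... Method-specific arguments.
#' @export
augment <- function(x, ...) UseMethod("augment")

#' @describeIn tidy Coefficient table of a stream-network model: one row per
#'   fixed effect with `estimate`, `std.error`, Wald `statistic`
#'   (estimate/std.error) and two-sided normal `p.value`.
#' @export
tidy.ssn_lm <- function(x, ...) {
  est <- stats::coef(x)
  se <- sqrt(diag(x$vcov_beta))
  stat <- est / se
  data.frame(term = names(est), estimate = unname(est),
             std.error = unname(se), statistic = unname(stat),
             p.value = unname(2 * stats::pnorm(-abs(stat))),
             row.names = NULL)
}

#' @describeIn glance One-row summary of a stream-network model: `n`, `p`
#'   (fixed effects), `npar` (estimated covariance parameters), `logLik`,
#'   `AIC` and `pseudo.r.squared` (squared Pearson correlation between the
#'   response and the GLS fitted means).
#' @export
glance.ssn_lm <- function(x, ...) {
  data.frame(n = x$n, p = x$p, npar = x$q, logLik = x$loglik, AIC = x$AIC,
             pseudo.r.squared = pseudo_r2(x), row.names = NULL)
}

#' @describeIn augment With `newdata = NULL` returns the observed-site table
#'   plus `.fitted` (GLS mean) and `.resid` (marginal residual
#'   `y - x' beta`; Cholesky-whitened residuals are added as `.std.resid`
#'   when `standardized = TRUE`). With `newdata` (a prediction-set name or
#'   site table) returns the prediction sites plus the kriging columns
#'   `.fitted`, `.se`, `.lower`, `.upper`, identical to [predict.ssn_lm()].
#' @param newdata Optional prediction sites (name or table).
#' @param level Prediction-interval coverage.
#' @param standardized Also return whitened residuals (observed mode)?
#' @export
augment.ssn_lm <- function(x, newdata = NULL, level = 0.95,
                           standardized = FALSE, ...) {
  if (is.null(newdata)) {
    out <- x$ssn$obs
    out$.fitted <- x$fitted.values
    out$.resid <- x$residuals
    if (standardized) out$.std.resid <- residuals(x, type = "standardized")
    return(out)
  }
  preds <- resolve_pred_sites(x, newdata)
  kr <- predict(x, newdata = preds, level = level)
  cbind(preds, kr[, c(".fitted", ".se", ".lower", ".upper"), drop = FALSE])
}

#' Write tidy/glance/augment output to CSV or JSON
#'
#' @param x A data frame as returned by [tidy()], [glance()] or [augment()].
#' @param path Output file; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, digits = NA, auto_unbox = FALSE)
  } else {
    utils::write.csv(x, path, row.names = FALSE)
  }
  invisible(path)
}
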