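#' Universal kriging prediction on a stream network
#'
#' Predicts the response at unobserved sites from a fitted [ssn_lm()] model by
#' universal kriging. The point prediction is
#' `x_p' beta + c_p' Sigma^-1 (y - X beta)` and the prediction variance is
#' `sigma2_tot - c_p' Sigma^-1 c_p + m_p' (X' Sigma^-1 X)^-1 m_p` with
#' `m_p = x_p - X' Sigma^-1 c_p` (the fixed-effect uncertainty term is
#' included) and `sigma2_tot` the sum of all partial sills and the nugget, so
#' the interval is a *prediction* interval for a new noisy observation.
#'
#' @param object A fitted `ssn_lm`.
#' @param newdata Either the name of a prediction set stored in the model's
#'   [ssn_data()], a data frame of (raw or located) sites, or `NULL` to use
#'   the first stored prediction set. Cross distances and weights are computed
#'   on the fly.
#' @param level Coverage of the prediction interval; default 0.95 with the
#'   Gaussian quantile.
#' @param ... Unused.
#' @return A data frame with one row per prediction site and columns
#'   `site_id`, `.fitted`, `.se`, `.lower`, `.upper`.
#' @export
predict.ssn_lm <- function(object, newdata = NULL, level = 0.95, ...) {
  preds <- resolve_pred_sites(object, newdata)
  if (nrow(preds) == 0L) {
    return(data.frame(site_id = preds$site_id, .fitted = numeric(0),
                      .se = numeric(0), .lower = numeric(0),
                      .upper = numeric(0)))
  }
  krige_core(object, preds, level = level)
}

resolve_pred_sites <- function(object, newdata) {
  if (is.null(newdata)) {
    if (length(object$ssn$preds) == 0L) {
      sn_error("model data contain no prediction sets; supply newdata", "value_error")
    }
    newdata <- object$ssn$preds[[1L]]
  } else if (is.character(newdata) && length(newdata) == 1L) {
    if (!newdata %in% names(object$ssn$preds)) {
      sn_error(paste0("no prediction set named '", newdata, "'; available: ",
                      paste(names(object$ssn$preds), collapse = ", ")),
               "schema_error")
    }
    newdata <- object$ssn$preds[[newdata]]
  }
  newdata <- as.data.frame(newdata)
  if (nrow(newdata) > 0L && !all(c("up_dist", "afv") %in% names(newdata))) {
    newdata <- locate_sites(newdata, object$ssn$network)
  }
  newdata
}

# shared universal-kriging engine; `preds` must be located sites
krige_core <- function(object, preds, level = 0.95) {
  obs <- object$ssn$obs
  net <- object$ssn$network
  params <- object$params
  tt <- stats::delete.response(object$terms)
  mfp <- stats::model.frame(tt, data = preds, na.action = stats::na.fail)
  Xp <- stats::model.matrix(tt, mfp)

  cd <- hydro_dist(net, obs, preds)
  Wc <- if (object$types$tailup != "none") {
    afv_col <- object$additive
    if (!afv_col %in% names(preds)) {
      sn_error(paste0("prediction sites lack additive column '", afv_col, "'"),
               "schema_error")
    }
    tailup_weights(net, obs, preds, dists = cd, afv_col = afv_col)
  }
  edc <- if (object$types$euclid != "none") euclid_dist(obs, preds)
  Cp <- make_sigma(cd, Wc, edc, params, nugget_diag = FALSE)

  R <- object$sigma_chol
  X <- object$X
  r <- object$y - drop(X %*% object$coefficients)
  Cs <- backsolve(R, Cp, transpose = TRUE)        # R'^-1 Cp
  rs <- backsolve(R, r, transpose = TRUE)
  Xs <- backsolve(R, X, transpose = TRUE)
  fitted <- drop(Xp %*% object$coefficients) + drop(crossprod(Cs, rs))
  s2tot <- total_sill(params)
  M <- Xp - crossprod(Cs, Xs)                     # m_p' rows
  se2 <- s2tot - colSums(Cs^2) + rowSums((M %*% object$vcov_beta) * M)
  neg <- se2 < 0
  if (any(neg)) {
    if (any(se2 < -1e-10 * max(s2tot, 1))) {
      sn_warn("negative kriging variance beyond numerical noise; clamped to 0",
              "numeric_warning")
    }
    se2[neg] <- 0
  }
  se <- sqrt(se2)
  z <- stats::qnorm((1 + level) / 2)
  data.frame(site_id = preds$site_id, .fitted = fitted, .se = se,
             .lower = fitted - z * se, .upper = fitted + z * se)
}

#' Leave-one-out cross-validation for a stream-network model
#'
#' Each observed site is predicted by universal kriging from the remaining
#' `n - 1` sites with the covariance parameters held at their estimates (no
#' refitting); the fixed effects are re-estimated from the reduced data inside
#' each kriging system.
#'
#' @param object A fitted `ssn_lm`.
#' @param level Interval coverage (default 0.95).
#' @return A list of class `ssn_loocv` with `table` (per-site `site_id`,
#'   `observed`, `.fitted`, `.se`, `.lower`, `.upper`) and summary statistics
#'   `bias` (mean prediction error), `RMSPE` and `coverage` (empirical
#'   interval coverage).
#' @export
loocv <- function(object, level = 0.95) {
  stopifnot(inherits(object, "ssn_lm"))
  S <- object$sigma
  X <- object$X
  y <- object$y
  n <- object$n
  s2tot <- total_sill(object$params)
  z <- stats::qnorm((1 + level) / 2)
  fitted <- se <- numeric(n)
  for (i in seq_len(n)) {
    Si <- S[-i, -i, drop = FALSE]
    ci <- S[-i, i]
    Ri <- chol_jitter(Si)
    if (is.null(Ri)) sn_error("leave-one-out covariance not positive definite",
                              "not_pd_error")
    g <- gls_estimate(X[-i, , drop = FALSE], y[-i], Ri, is_chol = TRUE)
    cs <- backsolve(Ri, ci, transpose = TRUE)
    rs <- backsolve(Ri, y[-i] - drop(X[-i, , drop = FALSE] %*% g$beta),
                    transpose = TRUE)
    Xs <- backsolve(Ri, X[-i, , drop = FALSE], transpose = TRUE)
    m <- X[i, ] - drop(crossprod(Xs, cs))
    fitted[i] <- sum(X[i, ] * g$beta) + sum(cs * rs)
    se2 <- s2tot - sum(cs^2) + drop(t(m) %*% g$vcov %*% m)
    se[i] <- sqrt(max(se2, 0))
  }
  tab <- data.frame(site_id = object$ssn$obs$site_id, observed = y,
                    .fitted = fitted, .se = se,
                    .lower = fitted - z * se, .upper = fitted + z * se)
  err <- fitted - y
  structure(
    list(table = tab, bias = mean(err), RMSPE = sqrt(mean(err^2)),
         coverage = mean(y >= tab$.lower & y <= tab$.upper), level = level),
    class = "ssn_loocv"
  )
}

#' @export
print.ssn_loocv <- function(x, digits = 4, ...) {
  cat("Leave-one-out cross-validation (", nrow(x$table), " sites)\n", sep = "")
  cat("  bias:    ", format(x$bias, digits = digits), "\n")
  cat("  RMSPE:   ", format(x$RMSPE, digits = digits), "\n")
  cat("  ", format(100 * x$level), "% interval coverage: ",
      format(x$coverage, digits = digits), "\n", sep = "")
  invisible(x)
}
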