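#' Generalized least squares given a covariance matrix
#'
#' Solves the GLS normal equations
#' `beta = (X' Sigma^-1 X)^-1 X' Sigma^-1 y` through the Cholesky factor of
#' `Sigma` (no explicit inverse is ever formed) and returns the coefficient
#' covariance `(X' Sigma^-1 X)^-1`.
#'
#' @param X Design matrix (full column rank).
#' @param y Response vector.
#' @param sigma Positive definite covariance matrix, or its upper Cholesky
#'   factor if `is_chol = TRUE`.
#' @param is_chol Is `sigma` already an upper Cholesky factor?
#' @return List with `beta`, `vcov`, the whitened residual quadratic form
#'   `quad = r' Sigma^-1 r`, and `logdet_xtsix = log|X' Sigma^-1 X|`.
#' @export
gls_estimate <- function(X, y, sigma, is_chol = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  R <- if (is_chol) sigma else chol(sigma)
  Xs <- backsolve(R, X, transpose = TRUE)
  ys <- backsolve(R, y, transpose = TRUE)
  XtSiX <- crossprod(Xs)
  cR <- tryCatch(chol(XtSiX), error = function(e) NULL)
  if (is.null(cR) || any(diag(cR) < sqrt(.Machine$double.eps) * max(diag(cR)))) {
    sn_error("X' Sigma^-1 X is (numerically) singular: rank-deficient design",
             "rank_error")
  }
  beta <- backsolve(cR, backsolve(cR, crossprod(Xs, ys), transpose = TRUE))
  beta <- drop(beta)
  names(beta) <- colnames(X)
  vcov <- chol2inv(cR)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  r <- ys - Xs %*% beta
  list(beta = beta, vcov = vcov, quad = sum(r^2),
       logdet_xtsix = 2 * sum(log(diag(cR))))
}

# Fast covariance assembly for repeated likelihood evaluations: the pair
# quantities are symmetric, so precompute the strict lower triangle as plain
# vectors once and rebuild Sigma by mirroring. Produces exactly the same
# matrix as make_sigma (the diagonal of every component is its partial sill).
make_fast_parts <- function(dists, W, ed) {
  n <- nrow(dists$h)
  lt <- which(lower.tri(dists$h))
  list(n = n, lt = lt, h = dists$h[lt], a = dists$a[lt], b = dists$b[lt],
       w = if (!is.null(W)) W[lt], ed = if (!is.null(ed)) ed[lt],
       inf = is.infinite(dists$h[lt]))
}

make_sigma_fast <- function(fp, params) {
  v <- numeric(length(fp$lt))
  tu <- params$tailup
  if (tu$type != "none") {
    cv <- fp$w * tu$de * cor_stream_fc(fp$h, tu$type, tu$range)
    cv[fp$w == 0] <- 0
    v <- v + cv
  }
  td <- params$taildown
  if (td$type != "none") {
    A <- fp$a / td$range
    B <- fp$b / td$range
    cv <- switch(td$type,
      exponential = td$de * exp(-(A + B)),
      linear_sill = td$de * pmax(1 - A, 0),
      spherical = {
        o <- td$de * (1 - A)^2 * (1 + A / 2 - 1.5 * B)
        o[A > 1] <- 0
        o
      })
    cv[fp$inf] <- 0
    v <- v + cv
  }
  eu <- params$euclid
  if (eu$type != "none") {
    t <- fp$ed / eu$range
    v <- v + switch(eu$type,
      exponential = eu$de * exp(-t),
      gaussian = eu$de * exp(-t^2),
      spherical = {
        o <- eu$de * (1 - 1.5 * t + 0.5 * t^3)
        o[t > 1] <- 0
        o
      })
  }
  S <- matrix(0, fp$n, fp$n)
  S[fp$lt] <- v
  S <- S + t(S)
  diag(S) <- total_sill(params)
  S
}

sigma_of <- function(parts, params) {
  if (!is.null(parts$fast)) {
    make_sigma_fast(parts$fast, params)
  } else {
    make_sigma(parts$dists, parts$W, parts$ed, params, nugget_diag = TRUE)
  }
}

# Map between the active-parameter log vector used by the optimizer and an
# ssn_params object. `types` is list(tailup=, taildown=, euclid=, nugget=bool).
active_par_names <- function(types) {
  nm <- character(0)
  if (types$tailup != "none") nm <- c(nm, "tailup_de", "tailup_range")
  if (types$taildown != "none") nm <- c(nm, "taildown_de", "taildown_range")
  if (types$euclid != "none") nm <- c(nm, "euclid_de", "euclid_range")
  if (types$nugget) nm <- c(nm, "nugget")
  nm
}

theta_to_params <- function(theta, types) {
  g <- function(nm, default) if (nm %in% names(theta)) exp(theta[[nm]]) else default
  ssn_params(
    tailup_type = types$tailup, tailup_de = g("tailup_de", 0),
    tailup_range = g("tailup_range", 1),
    taildown_type = types$taildown, taildown_de = g("taildown_de", 0),
    taildown_range = g("taildown_range", 1),
    euclid_type = types$euclid, euclid_de = g("euclid_de", 0),
    euclid_range = g("euclid_range", 1),
    nugget = if (types$nugget) exp(theta[["nugget"]]) else 0
  )
}

#' Minus twice the (restricted) Gaussian log-likelihood
#'
#' Evaluates the ML or REML objective of the stream-network linear model at a
#' covariance parameter vector on the log scale. Used internally by
#' [ssn_lm()] and exposed for profiling and testing.
#'
#' ML: `-2l = log|Sigma| + r' Sigma^-1 r + n log 2pi` with
#' `r = y - X beta(theta)` the GLS residual. REML adds
#' `log|X' Sigma^-1 X|` and replaces `n` by `n - p`.
#'
#' @param theta Named numeric vector of log-parameters; names are a subset of
#'   `tailup_de, tailup_range, taildown_de, taildown_range, euclid_de,
#'   euclid_range, nugget` matching the active components.
#' @param types List with elements `tailup`, `taildown`, `euclid` (type
#'   strings) and `nugget` (logical).
#' @param parts Precomputed model pieces: list with `X`, `y`, `dists`
#'   ([hydro_dist()] of the observed sites), `W` (tail-up weights or NULL) and
#'   `ed` (Euclidean distances or NULL).
#' @param reml Use the REML objective (default) rather than ML.
#' @return Scalar objective; `+Inf` if `Sigma` is not numerically positive
#'   definite after the jitter policy.
#' @export
neg2_loglik <- function(theta, types, parts, reml = TRUE) {
  params <- theta_to_params(theta, types)
  S <- sigma_of(parts, params)
  R <- chol_jitter(S)
  if (is.null(R)) return(Inf)
  n <- length(parts$y)
  p <- ncol(parts$X)
  logdet <- 2 * sum(log(diag(R)))
  g <- tryCatch(gls_estimate(parts$X, parts$y, R, is_chol = TRUE),
                error = function(e) NULL)
  if (is.null(g)) return(Inf)
  if (reml) {
    logdet + g$logdet_xtsix + g$quad + (n - p) * log(2 * pi)
  } else {
    logdet + g$quad + n * log(2 * pi)
  }
}

# Multiply every active variance component by the analytically profiled
# overall scale c = quad / (n - p) (REML) or quad / n (ML). For a common
# factor c on Sigma the objective is exactly minimized at this c, so applying
# it after a simplex run can only improve the fit; for single-variance models
# it is exact.
polish_scale <- function(theta, types, parts, reml) {
  var_names <- intersect(names(theta),
                         c("tailup_de", "taildown_de", "euclid_de", "nugget"))
  if (length(var_names) == 0L) return(theta)
  params <- theta_to_params(theta, types)
  S <- sigma_of(parts, params)
  R <- chol_jitter(S)
  if (is.null(R)) return(theta)
  g <- tryCatch(gls_estimate(parts$X, parts$y, R, is_chol = TRUE),
                error = function(e) NULL)
  if (is.null(g)) return(theta)
  n <- length(parts$y)
  p <- ncol(parts$X)
  cc <- g$quad / (if (reml) n - p else n)
  if (!is.finite(cc) || cc <= 0) return(theta)
  theta[var_names] <- theta[var_names] + log(cc)
  theta
}

default_fit_control <- function() {
  list(maxit = 2000, reltol = 1e-6, restarts = 2, restart_maxit = 300,
       polish_maxit = 300)
}

#' Fit a spatial linear model on a stream network
#'
#' The workhorse of the package: fits a Gaussian linear model whose errors are
#' the sum of up to three spatially dependent components — tail-up
#' (flow-connected only, weighted by additive function values), tail-down
#' (flow-connected and flow-unconnected) and Euclidean — plus a spatially
#' independent nugget. Covariance parameters are estimated by restricted
#' maximum likelihood (default) or maximum likelihood over log-transformed
#' partial sills, ranges and nugget, using Nelder–Mead simplex search with
#' deterministic restarts and an analytic profiling step for the overall
#' variance scale.
#'
#' @param formula Model formula for the fixed effects, evaluated in the
#'   observed-site table of `ssn` (e.g. `response ~ elev + precip`).
#' @param ssn An [ssn_data()] object (network + located observed sites +
#'   optional prediction sets).
#' @param tailup_type,taildown_type Covariance type for the stream components:
#'   `"exponential"`, `"spherical"`, `"linear_sill"` or `"none"`.
#' @param euclid_type `"exponential"`, `"gaussian"`, `"spherical"` or
#'   `"none"`.
#' @param additive Name of the observed-site column holding additive function
#'   values; required when `tailup_type != "none"`. Defaults to `"afv"`, the
#'   column filled in by [locate_sites()].
#' @param estmethod `"reml"` (default) or `"ml"`.
#' @param nugget Estimate a nugget variance? Set `FALSE` to fix it at zero
#'   (e.g. for exact-interpolation kriging).
#' @param control List overriding optimizer settings: `maxit` (2000),
#'   `reltol` (1e-8), `restarts` (2 deterministic perturbed restarts),
#'   `restart_maxit`, `polish_maxit`.
#' @return An object of class `ssn_lm` with components including
#'   `coefficients`, `vcov_beta`, `params` (an [ssn_params()] at the optimum),
#'   `loglik`, `AIC`, `n`, `p`, `q` (number of estimated covariance
#'   parameters) and `optim_info`. Methods: `print`, `summary`, `coef`,
#'   `vcov`, `logLik`, `AIC`, `fitted`, `residuals`, `predict`, `simulate`,
#'   `plot`, plus [tidy()], [glance()], [augment()] and [loocv()].
#'
#' @details AIC is `-2 loglik + 2q` under REML (covariance parameters only)
#'   and `-2 loglik + 2(q + p)` under ML. Initial values split the OLS
#'   residual variance equally across the active variance components; ranges
#'   start at half the median nonzero pairwise distance of the relevant
#'   metric. If the only free parameter is the nugget the REML/ML optimum is
#'   computed in closed form, so an iid fit reproduces OLS exactly.
#'
#' @examples
#' d <- sim_ssn_dataset(n_edges = 40, n_obs = 40, seed = 1)
#' fit <- ssn_lm(response ~ elev + precip, d,
#'               tailup_type = "exponential", taildown_type = "spherical",
#'               euclid_type = "gaussian")
#' summary(fit)
#' @export
ssn_lm <- function(formula, ssn, tailup_type = "none", taildown_type = "none",
                   euclid_type = "none", additive = "afv",
                   estmethod = c("reml", "ml"), nugget = TRUE,
                   control = list()) {
  estmethod <- match.arg(estmethod)
  reml <- estmethod == "reml"
  tailup_type <- check_cov_type(tailup_type, "tailup")
  taildown_type <- check_cov_type(taildown_type, "taildown")
  euclid_type <- check_cov_type(euclid_type, "euclid")
  if (!inherits(ssn, "ssn_data")) {
    sn_error("ssn must be an ssn_data object (see ssn_data())", "value_error")
  }
  ctrl <- utils::modifyList(default_fit_control(), control)
  types <- list(tailup = tailup_type, taildown = taildown_type,
                euclid = euclid_type, nugget = isTRUE(nugget))

  obs <- ssn$obs
  mf <- stats::model.frame(formula, data = obs, na.action = stats::na.fail)
  tt <- attr(mf, "terms")
  y <- as.numeric(stats::model.response(mf))
  X <- stats::model.matrix(tt, mf)
  n <- length(y)
  p <- ncol(X)
  if (qr(X)$rank < p) {
    sn_error("design matrix is rank-deficient", "rank_error")
  }

  if (tailup_type != "none" && !additive %in% names(obs)) {
    sn_error(paste0("additive column '", additive,
                    "' not found; it is required for a tail-up component"),
             "schema_error")
  }

  dists <- hydro_dist(ssn$network, obs)
  W <- if (tailup_type != "none") {
    tailup_weights(ssn$network, obs, dists = dists, afv_col = additive)
  }
  ed <- if (euclid_type != "none") euclid_dist(obs)
  parts <- list(X = X, y = y, dists = dists, W = W, ed = ed,
                fast = make_fast_parts(dists, W, ed))

  par_names <- active_par_names(types)
  q <- length(par_names)
  if (q == 0L) {
    sn_error("model has no variance component: set a covariance type or nugget = TRUE",
             "value_error")
  }

  # initial values: OLS residual variance split equally; ranges at half the
  # median nonzero pairwise distance of the relevant metric
  ols <- stats::lm.fit(X, y)
  s2 <- sum(ols$residuals^2) / max(n - p, 1)
  if (s2 <= 0) s2 <- stats::var(y) + 1e-8
  var_names <- intersect(par_names, c("tailup_de", "taildown_de", "euclid_de", "nugget"))
  init <- stats::setNames(numeric(q), par_names)
  init[var_names] <- log(s2 / length(var_names))
  hpos <- dists$h[is.finite(dists$h) & dists$h > 0]
  med_h <- if (length(hpos) > 0) stats::median(hpos) else 1
  if ("tailup_range" %in% par_names) init["tailup_range"] <- log(med_h / 2)
  if ("taildown_range" %in% par_names) init["taildown_range"] <- log(med_h / 2)
  if ("euclid_range" %in% par_names) {
    epos <- ed[ed > 0]
    init["euclid_range"] <- log((if (length(epos) > 0) stats::median(epos) else 1) / 2)
  }

  obj <- function(th) {
    names(th) <- par_names
    neg2_loglik(th, types, parts, reml = reml)
  }

  evals <- 0L
  conv_warn <- FALSE
  if (identical(par_names, "nugget")) {
    # closed form: Sigma = s2 * I, GLS = OLS, profiled REML/ML variance
    s2hat <- sum(ols$residuals^2) / (if (reml) n - p else n)
    best <- stats::setNames(log(s2hat), "nugget")
    best_val <- obj(best)
  } else {
    run_nm <- function(start, maxit) {
      o <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = ctrl$reltol))
      evals <<- evals + o$counts[["function"]]
      o
    }
    o0 <- run_nm(init, ctrl$maxit)
    best <- o0$par
    best_val <- o0$value
    conv_warn <- o0$convergence == 1L
    if (ctrl$restarts > 0) {
      # deterministic perturbations: alternate +/- shifts on the log scale;
      # the short restart runs are exploratory, so hitting their iteration
      # cap only matters if such a run wins
      for (k in seq_len(ctrl$restarts)) {
        delta <- 0.7 * k * rep_len(c(1, -1), q) * (-1)^k
        ok <- run_nm(init + delta, ctrl$restart_maxit)
        if (ok$value < best_val) {
          best <- ok$par
          best_val <- ok$value
          conv_warn <- ok$convergence == 1L
        }
      }
    }
    # analytic rescale of the variance components, then a short re-polish
    pol <- polish_scale(stats::setNames(best, par_names), types, parts, reml)
    pol_val <- obj(pol)
    if (pol_val < best_val - ctrl$reltol * abs(best_val)) {
      op <- run_nm(pol, ctrl$polish_maxit)
      if (op$value <= pol_val) {
        best <- op$par
        best_val <- op$value
        conv_warn <- op$convergence == 1L
      } else {
        best <- pol
        best_val <- pol_val
      }
    } else if (pol_val <= best_val) {
      best <- pol
      best_val <- pol_val
    }
    # if the accepted point came from a capped run, give it the full budget
    if (conv_warn) {
      oe <- run_nm(best, ctrl$maxit)
      if (oe$value <= best_val) {
        best <- oe$par
        best_val <- oe$value
      }
      conv_warn <- oe$convergence == 1L
    }
  }
  names(best) <- par_names
  params_hat <- theta_to_params(best, types)

  S <- make_sigma(dists, W, ed, params_hat, nugget_diag = TRUE)
  R <- chol_jitter(S)
  if (is.null(R)) {
    sn_error("estimated covariance matrix is not positive definite", "not_pd_error")
  }
  g <- gls_estimate(X, y, R, is_chol = TRUE)
  loglik <- -0.5 * best_val
  aic <- -2 * loglik + 2 * (q + if (reml) 0 else p)
  if (conv_warn) {
    sn_warn("iteration cap reached in at least one simplex run; estimates may not be fully converged",
            "convergence_warning")
  }

  fit <- structure(
    list(coefficients = g$beta, vcov_beta = g$vcov, params = params_hat,
         theta = best, loglik = loglik, AIC = aic,
         n = n, p = p, q = q, estmethod = estmethod, types = types,
         additive = if (tailup_type != "none") additive else NULL,
         formula = formula, terms = tt, call = match.call(),
         fitted.values = unname(drop(X %*% g$beta)),
         residuals = y - unname(drop(X %*% g$beta)),
         y = y, X = X, parts = parts, sigma = S, sigma_chol = R,
         ssn = ssn,
         optim_info = list(evaluations = evals, objective = best_val,
                           hit_iteration_cap = conv_warn)),
    class = "ssn_lm"
  )
  fit
}
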