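# small iid-friendly dataset for degenerate-model checks
iid_dataset <- function(n = 40, seed = 21, sigma2 = 1.5,
                        beta = c(2, 0.8)) {
  net <- sim_stream_network(30, seed = seed)
  set.seed(seed + 1)
  s <- random_sites(net, n)
  s$cov1 <- rnorm(n)
  s$response <- beta[1] + beta[2] * s$cov1 + rnorm(n, sd = sqrt(sigma2))
  ssn_data(net, s)
}

test_that("gls_estimate solves the generalized normal equations", {
  set.seed(3)
  X <- cbind(1, rnorm(10))
  y <- rnorm(10)
  # Sigma = I reduces to OLS
  g <- gls_estimate(X, y, diag(10))
  expect_equal(unname(g$beta), unname(coef(lm.fit(X, y))), tolerance = 1e-10)
  # precision-weighted mean: intercept-only, Sigma = diag(1, 4), y = (1, 5)
  g2 <- gls_estimate(matrix(1, 2, 1), c(1, 5), diag(c(1, 4)))
  expect_equal(unname(g2$beta), 1.8, tolerance = 1e-12)
  expect_equal(unname(g2$vcov[1, 1]), 1 / (1 + 1 / 4), tolerance = 1e-12)
  # duplicated covariate column
  expect_error(gls_estimate(cbind(1, X[, 2], X[, 2]), y, diag(10)),
               class = "rank_error")
})

test_that("the REML objective has its closed-form iid optimum", {
  d <- iid_dataset(n = 35, seed = 31)
  y <- d$obs$response
  X <- matrix(1, length(y), 1)
  dists <- hydro_dist(d$network, d$obs)
  parts <- list(X = X, y = y, dists = dists, W = NULL, ed = NULL)
  types <- list(tailup = "none", taildown = "none", euclid = "none",
                nugget = TRUE)
  # grid-search oracle over the nugget
  obj <- function(lv) neg2_loglik(c(nugget = lv), types, parts, reml = TRUE)
  grid <- seq(log(var(y)) - 2, log(var(y)) + 2, length.out = 4001)
  opt_grid <- grid[which.min(vapply(grid, obj, numeric(1)))]
  expect_equal(exp(opt_grid), var(y), tolerance = 1e-2)  # grid resolution
  # analytic optimum: sample variance with divisor n - 1
  expect_lte(obj(log(var(y))), min(vapply(grid, obj, numeric(1))) + 1e-10)

  # single observation, ML, at its mean: -2l = log(2 pi)
  parts1 <- list(X = matrix(1, 1, 1), y = 0,
                 dists = hydro_dist(d$network, d$obs[1, , drop = FALSE]),
                 W = NULL, ed = NULL)
  expect_equal(neg2_loglik(c(nugget = 0), types, parts1, reml = FALSE),
               log(2 * pi), tolerance = 1e-12)
})

test_that("log-determinant scales with the variance components", {
  net <- sim_stream_network(25, seed = 41)
  set.seed(42)
  s <- random_sites(net, 12)
  dists <- hydro_dist(net, s)
  W <- tailup_weights(net, s, dists = dists)
  ed <- euclid_dist(s)
  p1 <- ssn_params("exponential", 1, 5, "exponential", 0.5, 7, "gaussian", 0.3, 2,
                   nugget = 0.2)
  p2 <- ssn_params("exponential", 2, 5, "exponential", 1, 7, "gaussian", 0.6, 2,
                   nugget = 0.4)
  S1 <- make_sigma(dists, W, ed, p1)
  S2 <- make_sigma(dists, W, ed, p2)
  expect_equal(S2, 2 * S1, tolerance = 1e-12)
  expect_equal(determinant(S2)$modulus[1],
               determinant(S1)$modulus[1] + nrow(S1) * log(2), tolerance = 1e-8)
})

test_that("an all-none fit reproduces OLS and the n-p divisor variance", {
  d <- iid_dataset(n = 50, seed = 51)
  fit <- ssn_lm(response ~ cov1, d)
  ls <- lm(response ~ cov1, data = d$obs)
  expect_equal(coef(fit), coef(ls), tolerance = 1e-6)
  s2 <- sum(resid(ls)^2) / df.residual(ls)
  expect_equal(fit$params$nugget, s2, tolerance = 1e-6)
  expect_equal(unname(vcov(fit)), unname(vcov(ls) / s2 * fit$params$nugget),
               tolerance = 1e-6)
  # ML counterpart divides by n
  fit_ml <- ssn_lm(response ~ cov1, d, estmethod = "ml")
  expect_equal(fit_ml$params$nugget, sum(resid(ls)^2) / nrow(d$obs),
               tolerance = 1e-6)
})

test_that("the REML objective is invariant to mean-model translation", {
  d <- iid_dataset(n = 30, seed = 61)
  obs <- d$obs
  X <- model.matrix(~ cov1, obs)
  dists <- hydro_dist(d$network, obs)
  ed <- euclid_dist(obs)
  types <- list(tailup = "none", taildown = "none", euclid = "exponential",
                nugget = TRUE)
  theta <- c(euclid_de = log(0.7), euclid_range = log(2), nugget = log(0.5))
  p1 <- list(X = X, y = obs$response, dists = dists, W = NULL, ed = ed)
  p2 <- p1
  p2$y <- obs$response + drop(X %*% c(3, -1.7))
  expect_equal(neg2_loglik(theta, types, p1, reml = TRUE),
               neg2_loglik(theta, types, p2, reml = TRUE), tolerance = 1e-8)
})

test_that("analytic variance profiling matches numerical optimization", {
  d <- iid_dataset(n = 40, seed = 71)
  obs <- d$obs
  X <- model.matrix(~ cov1, obs)
  dists <- hydro_dist(d$network, obs)
  ed <- euclid_dist(obs)
  types <- list(tailup = "none", taildown = "none", euclid = "exponential",
                nugget = TRUE)
  parts <- list(X = X, y = obs$response, dists = dists, W = NULL, ed = ed)
  # fixed correlation structure: euclid_de : nugget = 2 : 1, range fixed;
  # one overall scale c multiplies both variances
  obj_scale <- function(logc) {
    neg2_loglik(c(euclid_de = log(2) + logc, euclid_range = log(2),
                  nugget = logc), types, parts, reml = TRUE)
  }
  num <- optimize(obj_scale, c(-10, 5), tol = 1e-10)
  # analytic profile: scale the quadratic form
  base <- c(euclid_de = log(2), euclid_range = log(2), nugget = 0)
  S <- make_sigma(dists, NULL, ed, streamnet:::theta_to_params(base, types))
  g <- gls_estimate(X, obs$response, S)
  chat <- g$quad / (length(obs$response) - ncol(X))
  expect_equal(exp(num$minimum), chat, tolerance = 1e-6)
})

test_that("rank-deficient designs are rejected", {
  d <- iid_dataset(n = 25, seed = 81)
  d$obs$cov2 <- d$obs$cov1
  expect_error(ssn_lm(response ~ cov1 + cov2, d), class = "rank_error")
})

test_that("the optimum is reproducible and never beaten by the truth", {
  truth <- ssn_params(tailup_type = "exponential", tailup_de = 2,
                      tailup_range = 8, taildown_type = "spherical",
                      taildown_de = 1, taildown_range = 12, nugget = 0.5)
  for (seed in c(101, 202)) {
    d <- sim_ssn_dataset(n_edges = 80, n_obs = 60, pred_spacing = NULL,
                         params = truth, seed = seed)
    fit <- ssn_lm(response ~ elev + precip, d, tailup_type = "exponential",
                  taildown_type = "spherical")
    fit2 <- ssn_lm(response ~ elev + precip, d, tailup_type = "exponential",
                   taildown_type = "spherical")
    # deterministic given data and initial values
    expect_identical(fit$theta, fit2$theta)
    # -2 loglik at the reported optimum matches the reported loglik exactly
    expect_equal(neg2_loglik(fit$theta, fit$types, fit$parts, reml = TRUE),
                 -2 * fit$loglik)
    # the fitted objective is at least as good as the generating parameters'
    theta_true <- log(c(tailup_de = 2, tailup_range = 8, taildown_de = 1,
                        taildown_range = 12, nugget = 0.5))
    expect_lte(-2 * fit$loglik,
               neg2_loglik(theta_true, fit$types, fit$parts, reml = TRUE) + 1e-8)
  }
})

test_that("nugget-only truth is recovered from iid simulations", {
  # moderate-size version of the parameter-recovery check: beta = 0, nugget 1
  net <- sim_stream_network(60, seed = 91)
  set.seed(92)
  s <- random_sites(net, 150)
  p0 <- ssn_params(nugget = 1)
  sims <- ssn_simulate(net, s, p0, nsim = 8, seed = 93)
  est_n <- est_b <- numeric(ncol(sims))
  for (k in seq_len(ncol(sims))) {
    s$response <- sims[, k]
    fk <- ssn_lm(response ~ 1, ssn_data(net, s))
    est_n[k] <- fk$params$nugget
    est_b[k] <- coef(fk)[[1]]
  }
  expect_lt(abs(median(est_n) - 1), 0.2)
  expect_lt(abs(median(est_b)), 0.15)
})

test_that("unknown covariance types and missing additive columns error early", {
  d <- iid_dataset(n = 20, seed = 99)
  expect_error(ssn_lm(response ~ 1, d, tailup_type = "cauchy"),
               class = "value_error")
  expect_error(ssn_lm(response ~ 1, d, euclid_type = "linear_sill"),
               class = "value_error")
  obs2 <- d$obs
  obs2$afv <- NULL
  d2 <- list(network = d$network, obs = obs2, preds = list())
  class(d2) <- "ssn_data"
  d2$obs$afv <- NULL
  expect_error(ssn_lm(response ~ 1, d2, tailup_type = "exponential",
                      additive = "missing_col"), class = "schema_error")
  expect_error(ssn_lm(response ~ 1, d, nugget = FALSE), class = "value_error")
})
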