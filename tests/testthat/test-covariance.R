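test_that("closed-form components reproduce hand-computed values", {
  # tail-up
  expect_equal(cov_tailup(0, 1, "exponential", de = 2, range = 3), 2)
  expect_equal(cov_tailup(100, 0, "exponential", de = 2, range = 3), 0)
  expect_equal(cov_tailup(5, 0.5, "exponential", de = 1, range = 10),
               0.5 * exp(-0.5))
  expect_error(cov_tailup(-1, 1, "exponential", 1, 1), class = "value_error")

  # tail-down
  expect_equal(cov_taildown(0, 0, "spherical", de = 3, range = 2), 3)
  expect_equal(cov_taildown(3, 1, "exponential", de = 1, range = 4), exp(-1))
  # kernel factorization identity for the exponential form
  expect_equal(cov_taildown(3, 1, "exponential", de = 1, range = 4),
               exp(-3 / 4) * exp(-1 / 4))
  expect_equal(cov_taildown(5, 0, "linear_sill", de = 2, range = 4), 0)
  expect_error(cov_taildown(1, 2, "exponential", de = 1, range = 1),
               class = "value_error")
  expect_error(cov_taildown(1, 1, "exponential", de = 1, range = 1,
                            flow_connected = TRUE), class = "value_error")

  # spherical flow-unconnected form reduces to flow-connected at b = 0
  tt <- seq(0, 1.2, by = 0.05)
  expect_equal(cov_taildown(tt, 0, "spherical", de = 1, range = 1),
               ifelse(tt <= 1, 1 - 1.5 * tt + 0.5 * tt^3, 0), tolerance = 1e-12)

  # Euclidean
  expect_equal(cov_euclid(0, "gaussian", de = 4, range = 1), 4)
  expect_equal(cov_euclid(2, "gaussian", de = 1, range = 2), exp(-1))
  expect_equal(cov_euclid(3, "spherical", de = 1, range = 3), 0)
  expect_equal(cov_euclid(1, "exponential", de = 1, range = 1), exp(-1))

  expect_error(cov_euclid(1, "mariah", de = 1, range = 1), class = "value_error")
})

test_that("moving-average oracle normalizes and matches analytic cases", {
  expect_equal(ma_cov_numeric("exponential", 0, 0, 2), 1, tolerance = 1e-8)
  expect_equal(ma_cov_numeric("spherical", 0, 0, 2), 1, tolerance = 1e-8)
  expect_equal(ma_cov_numeric("linear_sill", 0, 0, 2), 1, tolerance = 1e-8)
  # spherical at (a, b) = (range/2, 0): 1 - 3/4 + 1/16
  expect_equal(ma_cov_numeric("spherical", 0.5, 0, 1), 0.3125, tolerance = 1e-8)
  # exponential kernel: analytic product integral
  expect_equal(ma_cov_numeric("exponential", 1.3, 0.4, 2), exp(-(1.3 + 0.4) / 2),
               tolerance = 1e-8)
})

test_that("every closed form equals its moving-average construction", {
  for (type in c("exponential", "spherical", "linear_sill")) {
    for (alpha in c(0.7, 3)) {
      for (afrac in seq(0, 2, by = 0.25)) {
        a <- afrac * alpha
        for (b in c(0, a / 3, a)) {
          oracle <- ma_cov_numeric(type, a, b, alpha)
          expect_equal(cov_taildown(a, b, type, de = 1, range = alpha), oracle,
                       tolerance = 1e-6)
          if (b == 0) {
            # tail-up closed form uses the same correlation in h
            expect_equal(cov_tailup(a, 1, type, de = 1, range = alpha), oracle,
                         tolerance = 1e-6)
          }
        }
      }
    }
  }
})

test_that("stream correlations decay monotonically", {
  h <- seq(0, 5, by = 0.05)
  for (type in c("exponential", "spherical", "linear_sill")) {
    fc <- cov_taildown(h, 0, type, de = 1, range = 2)
    expect_true(all(diff(fc) <= 1e-12))
  }
  # flow-unconnected exponential: non-increasing in a + b at fixed a - b
  s <- seq(1, 6, by = 0.1)  # a + b, with a - b = 0.5
  fu <- cov_taildown((s + 0.5) / 2, (s - 0.5) / 2, "exponential",
                     de = 1, range = 2)
  expect_true(all(diff(fu) <= 1e-12))
})

test_that("assembled covariance sums components with nugget on the diagonal", {
  # iid model
  net <- tiny3_network()
  s <- locate_sites(data.frame(site_id = 1:3, edge_id = c(1, 2, 3),
                               ratio = c(0.5, 0.5, 0.5),
                               x = c(0, 1, 0.5), y = c(2, 2, 0)), net)
  d <- hydro_dist(net, s)
  p0 <- ssn_params(nugget = 2.5)
  expect_equal(make_sigma(d, params = p0), diag(2.5, 3))

  # exponential tail-up + spherical tail-down + gaussian Euclidean + nugget,
  # against an element-wise independent recomputation
  W <- tailup_weights(net, s, dists = d)
  ed <- euclid_dist(s)
  p <- ssn_params("exponential", 1.5, 4, "spherical", 1, 9, "gaussian", 0.5, 2,
                  nugget = 0.25)
  S <- make_sigma(d, W, ed, p)
  for (i in 1:3) {
    for (j in 1:3) {
      expected <- cov_tailup(d$h[i, j], W[i, j], "exponential", 1.5, 4) +
        cov_taildown(d$a[i, j], d$b[i, j], "spherical", 1, 9) +
        cov_euclid(ed[i, j], "gaussian", 0.5, 2) +
        (i == j) * 0.25
      expect_equal(S[i, j], expected, tolerance = 1e-14)
    }
  }
  expect_equal(S, t(S))
  # diagonal carries the full variance decomposition
  expect_equal(diag(S), rep(1.5 + 1 + 0.5 + 0.25, 3))
})

test_that("cross-network pairs keep only the Euclidean component", {
  net <- build_network(data.frame(
    edge_id = 1:2, down_edge_id = c(NA, NA), length = c(1, 1),
    additive_attr = c(1, 1), netID = c(1, 2)
  ))
  s <- locate_sites(data.frame(site_id = 1:2, edge_id = 1:2, ratio = 0.5,
                               x = c(0, 3), y = 0), net)
  d <- hydro_dist(net, s)
  W <- tailup_weights(net, s, dists = d)
  ed <- euclid_dist(s)
  p <- ssn_params("exponential", 1, 5, "spherical", 1, 5, "exponential", 2, 3,
                  nugget = 0.1)
  S <- make_sigma(d, W, ed, p)
  expect_equal(S[1, 2], 2 * exp(-1))  # Euclidean only, d = 3, range 3
})

test_that("the triangular fast assembly equals the reference assembly", {
  set.seed(99)
  net <- sim_stream_network(60, seed = 601)
  s <- random_sites(net, 30)
  d <- hydro_dist(net, s)
  W <- tailup_weights(net, s, dists = d)
  ed <- euclid_dist(s)
  fp <- streamnet:::make_fast_parts(d, W, ed)
  for (p in list(
    ssn_params("exponential", 2, 8, "spherical", 1, 12, "gaussian", 1, 3, nugget = 0.5),
    ssn_params("spherical", 1, 5, "exponential", 2, 4, "exponential", 0.3, 2, nugget = 0.1),
    ssn_params("linear_sill", 1, 10, "linear_sill", 1, 10, "spherical", 1, 6, nugget = 1),
    ssn_params(nugget = 2)
  )) {
    expect_equal(streamnet:::make_sigma_fast(fp, p),
                 make_sigma(d, W, ed, p), tolerance = 1e-15)
  }
})

test_that("assembled covariance is positive definite with a nugget", {
  set.seed(123)
  for (rep in 1:10) {
    net <- sim_stream_network(sample(20:80, 1), seed = 500 + rep)
    s <- random_sites(net, sample(10:40, 1))
    d <- hydro_dist(net, s)
    W <- tailup_weights(net, s, dists = d)
    ed <- euclid_dist(s)
    p <- ssn_params("exponential", 2, 8, "spherical", 1, 12, "gaussian", 1, 3,
                    nugget = 0)
    S <- make_sigma(d, W, ed, p)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(ev))
    Sn <- S + diag(0.5, nrow(S))
    expect_gt(min(eigen(Sn, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})
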