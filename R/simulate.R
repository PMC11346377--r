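#' Simulate Gaussian responses on a stream network
#'
#' Draws `nsim` replicates of `y = mean + L z`, where `L` is a square root of
#' the model covariance matrix assembled from `params` at the given sites and
#' `z` is iid standard normal. The Cholesky factor is used when `Sigma` is
#' numerically positive definite; a singular but positive semidefinite matrix
#' (e.g. co-located sites with no nugget) falls back to an eigendecomposition
#' square root so perfectly correlated sites receive identical values.
#'
#' @param network A `stream_network`.
#' @param sites Located site table (see [locate_sites()]).
#' @param params An [ssn_params()] describing the generating covariance.
#' @param mean Mean vector (scalar recycled; default 0).
#' @param nsim Number of replicates.
#' @param seed Optional integer seed; the global RNG state is restored
#'   afterwards and the seed is stored as an attribute of the result.
#' @return An `n x nsim` numeric matrix, one replicate per column, with
#'   attribute `"seed"`.
#' @export
ssn_simulate <- function(network, sites, params, mean = 0, nsim = 1,
                         seed = NULL) {
  stopifnot(inherits(params, "ssn_params"), is_count(nsim))
  dists <- hydro_dist(network, sites)
  W <- if (params$tailup$type != "none") tailup_weights(network, sites, dists = dists)
  ed <- if (params$euclid$type != "none") euclid_dist(sites)
  S <- make_sigma(dists, W, ed, params, nugget_diag = TRUE)
  L <- psd_sqrt(S)
  n <- nrow(S)
  mean <- rep_len(mean, n)
  out <- with_seed(seed, {
    z <- matrix(stats::rnorm(n * nsim), n, nsim)
    mean + L %*% z
  })
  dimnames(out) <- list(sites$site_id, paste0("sim_", seq_len(nsim)))
  attr(out, "seed") <- seed
  out
}

# Square root of a (numerically) positive semidefinite matrix: Cholesky when
# well conditioned, else an eigenvalue square root with small negatives
# clamped (so exactly singular matrices, e.g. co-located sites without a
# nugget, factor cleanly instead of through a spurious tiny pivot).
psd_sqrt <- function(S) {
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(R) && all(diag(R) > 1e-7 * sqrt(max(diag(S))))) return(t(R))
  e <- eigen(S, symmetric = TRUE)
  lam <- e$values
  if (min(lam) < -1e-8 * max(abs(lam), 1)) {
    sn_error("covariance matrix is not positive semidefinite", "not_pd_error")
  }
  e$vectors %*% diag(sqrt(pmax(lam, 0)), length(lam))
}

#' Simulate from a fitted stream-network model
#'
#' Draws responses at the observed sites from the fitted model: mean
#' `X beta_hat` and covariance `Sigma(theta_hat)`.
#'
#' @param object A fitted `ssn_lm`.
#' @param nsim Number of replicates.
#' @param seed Optional integer seed (stats::simulate convention).
#' @param ... Unused.
#' @return A data frame with `nsim` columns, one replicate each.
#' @export
simulate.ssn_lm <- function(object, nsim = 1, seed = NULL, ...) {
  L <- psd_sqrt(object$sigma)
  n <- object$n
  out <- with_seed(seed, {
    z <- matrix(stats::rnorm(n * nsim), n, nsim)
    object$fitted.values + L %*% z
  })
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  attr(out, "seed") <- seed
  out
}
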