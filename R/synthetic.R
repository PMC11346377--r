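# Seeded synthetic stream networks, sites and datasets. These generators make
# every analysis in the package reproducible without external data: they grow
# a random dendritic tree, embed it in the plane, place observed and
# systematically spaced prediction sites, attach covariates, and (optionally)
# simulate a response from known covariance parameters.

#' Generate a random dendritic stream network
#'
#' Grows a tree from the outlet by seeded random attachment: each new edge
#' attaches its downstream end to the upstream node of an existing edge. With
#' probability `branch_p` the parent is drawn uniformly from all edges (which
#' creates or widens a junction); otherwise from the current headwater tips
#' (which extends a path). Edge lengths are log-normal. The additive
#' attribute is the accumulated upstream edge length (own edge included), a
#' proxy for cumulative watershed area. A planar embedding draws each edge
#' away from its downstream node with a jittered heading so Euclidean
#' distances are defined everywhere; the embedding may self-intersect, which
#' is irrelevant because only network and straight-line point distances enter
#' the model.
#'
#' @param n_edges Number of edges (>= 1).
#' @param branch_p Probability a growth step attaches to an arbitrary edge
#'   rather than a tip; default 0.5.
#' @param length_meanlog,length_sdlog Log-normal edge-length parameters;
#'   defaults 0 and 0.5 (median length 1).
#' @param seed Optional integer seed.
#' @return A `stream_network` whose edge table also carries the endpoint
#'   coordinates `x_dn, y_dn, x_up, y_up`.
#' @export
sim_stream_network <- function(n_edges, branch_p = 0.5, length_meanlog = 0,
                               length_sdlog = 0.5, seed = NULL) {
  stopifnot(is_count(n_edges))
  with_seed(seed, {
    down <- rep(NA_integer_, n_edges)
    has_child <- rep(FALSE, n_edges)
    if (n_edges > 1L) {
      for (k in 2:n_edges) {
        pool <- if (stats::runif(1) < branch_p) {
          seq_len(k - 1L)
        } else {
          w <- which(!has_child[seq_len(k - 1L)])
          if (length(w) == 0L) seq_len(k - 1L) else w
        }
        parent <- if (length(pool) == 1L) pool else sample(pool, 1L)
        down[k] <- parent
        has_child[parent] <- TRUE
      }
    }
    len <- stats::rlnorm(n_edges, length_meanlog, length_sdlog)

    # accumulated upstream length as additive attribute (children before
    # parents: reverse creation order works because down[k] < k)
    addi <- len
    for (k in n_edges:2) addi[down[k]] <- addi[down[k]] + addi[k]

    # planar embedding: heading jittered around the parent's heading
    heading <- numeric(n_edges)
    heading[1L] <- pi / 2
    x_dn <- y_dn <- x_up <- y_up <- numeric(n_edges)
    x_dn[1L] <- 0
    y_dn[1L] <- 0
    for (k in seq_len(n_edges)) {
      if (k > 1L) {
        p <- down[k]
        heading[k] <- heading[p] + stats::runif(1, -0.9, 0.9)
        x_dn[k] <- x_up[p]
        y_dn[k] <- y_up[p]
      }
      x_up[k] <- x_dn[k] + len[k] * cos(heading[k])
      y_up[k] <- y_dn[k] + len[k] * sin(heading[k])
    }

    edges <- data.frame(edge_id = seq_len(n_edges), down_edge_id = down,
                        length = len, additive_attr = addi,
                        x_dn = x_dn, y_dn = y_dn, x_up = x_up, y_up = y_up)
    build_network(edges)
  })
}

site_coords <- function(network, edge_idx, ratio) {
  e <- network$edges
  if (!all(c("x_dn", "x_up") %in% names(e))) {
    sn_error("network has no planar embedding (x_dn/x_up columns)", "schema_error")
  }
  list(x = e$x_dn[edge_idx] + ratio * (e$x_up[edge_idx] - e$x_dn[edge_idx]),
       y = e$y_dn[edge_idx] + ratio * (e$y_up[edge_idx] - e$y_dn[edge_idx]))
}

site_covariates <- function(sites) {
  # elevation-like gradient increasing upstream, plus an independent Gaussian
  sites$elev <- sites$up_dist + stats::rnorm(nrow(sites))
  sites$precip <- stats::rnorm(nrow(sites))
  sites
}

#' Generate observed and prediction sites on a network
#'
#' Observed sites are placed uniformly over total network length (edges
#' sampled proportional to length, position uniform along the edge).
#' Prediction sites are systematic: on each edge of length `L`, points at
#' stream distances `s, 2s, ..., floor(L/s) * s` from the downstream node,
#' plus one site at the network outlet so the set is never empty (in
#' particular when `pred_spacing` exceeds every edge length). Both tables get
#' two covariates: `elev`, an elevation-like gradient increasing with
#' distance from the outlet, and `precip`, independent Gaussian noise.
#'
#' @param network A `stream_network` with planar embedding (see
#'   [sim_stream_network()]).
#' @param n_obs Number of observed sites.
#' @param pred_spacing Spacing of the systematic prediction set in network
#'   distance units; `NULL` for no prediction sites.
#' @param seed Optional integer seed.
#' @return List with located data frames `obs` (response set to `NA`, to be
#'   filled by simulation or data) and `pred`.
#' @export
sim_stream_sites <- function(network, n_obs = 50, pred_spacing = NULL,
                             seed = NULL) {
  stopifnot(is_count(n_obs))
  e <- network$edges
  with_seed(seed, {
    eidx <- sample(nrow(e), n_obs, replace = TRUE, prob = e$length)
    ratio <- stats::runif(n_obs)
    xy <- site_coords(network, eidx, ratio)
    obs <- data.frame(site_id = seq_len(n_obs), edge_id = e$edge_id[eidx],
                      ratio = ratio, x = xy$x, y = xy$y)
    obs <- locate_sites(obs, network)
    obs <- site_covariates(obs)
    obs$response <- NA_real_

    pred <- NULL
    if (!is.null(pred_spacing)) {
      stopifnot(pred_spacing > 0)
      pe <- integer(0)
      pr <- numeric(0)
      for (k in seq_len(nrow(e))) {
        m <- floor(e$length[k] / pred_spacing)
        if (m >= 1L) {
          pe <- c(pe, rep.int(k, m))
          pr <- c(pr, (seq_len(m) * pred_spacing) / e$length[k])
        }
      }
      # boundary rule: always one site at the network mouth
      out <- network$outlets[1L]
      pe <- c(out, pe)
      pr <- c(0, pr)
      xy <- site_coords(network, pe, pr)
      pred <- data.frame(site_id = n_obs + seq_along(pe),
                         edge_id = e$edge_id[pe], ratio = pr,
                         x = xy$x, y = xy$y)
      pred <- locate_sites(pred, network)
      pred <- site_covariates(pred)
    }
    list(obs = obs, pred = pred)
  })
}

#' Default generating parameters of the synthetic study
#'
#' The covariance truth used by [sim_ssn_dataset()] when none is supplied:
#' exponential tail-up (partial sill 2, range 8), spherical tail-down
#' (partial sill 1, range 12), gaussian Euclidean (partial sill 1, range 3)
#' and nugget 0.5 — a stream-dominated process on the scale of the default
#' 200-edge network, whose pairwise stream distances are mostly below ~25
#' units.
#'
#' @return An [ssn_params()] object.
#' @export
default_truth_params <- function() {
  ssn_params(
    tailup_type = "exponential", tailup_de = 2, tailup_range = 8,
    taildown_type = "spherical", taildown_de = 1, taildown_range = 12,
    euclid_type = "gaussian", euclid_de = 1, euclid_range = 3,
    nugget = 0.5
  )
}

#' Generate a complete synthetic stream-network dataset
#'
#' Convenience wrapper: random network, observed and prediction sites, and a
#' response simulated from known truth, `y = b0 + b1 elev + b2 precip + e`
#' with `e` Gaussian with covariance `params`. The truth is attached as
#' attribute `"truth"` so parameter-recovery studies can compare against it.
#'
#' @param n_edges,n_obs Network and sample sizes (defaults 200 edges, 100
#'   observed sites).
#' @param pred_spacing Prediction-site spacing; default 2 network units.
#' @param params Generating [ssn_params()]; default [default_truth_params()].
#' @param beta Fixed-effect truth `(intercept, elev, precip)`; default
#'   `c(10, -0.5, 0.5)`.
#' @param seed Integer seed driving network, sites and response (sub-seeds
#'   `seed`, `seed + 1`, `seed + 2`).
#' @return An [ssn_data()] object with the simulated `response` filled in and
#'   one prediction set `"pred"`.
#' @export
sim_ssn_dataset <- function(n_edges = 200, n_obs = 100, pred_spacing = 2,
                            params = default_truth_params(),
                            beta = c(10, -0.5, 0.5), seed = NULL) {
  net <- sim_stream_network(n_edges, seed = seed)
  st <- sim_stream_sites(net, n_obs = n_obs, pred_spacing = pred_spacing,
                         seed = if (is.null(seed)) NULL else seed + 1L)
  obs <- st$obs
  X <- cbind(1, obs$elev, obs$precip)
  mu <- drop(X %*% beta)
  obs$response <- as.numeric(ssn_simulate(net, obs, params, mean = mu, nsim = 1,
                                          seed = if (is.null(seed)) NULL else seed + 2L))
  d <- ssn_data(net, obs,
                preds = if (is.null(st$pred)) list() else list(pred = st$pred))
  attr(d, "truth") <- list(params = params, beta = beta)
  d
}
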