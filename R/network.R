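#' Build a validated dendritic stream network
#'
#' Constructs a `stream_network` object from an edge table. Each edge points to
#' at most one downstream neighbour (`down_edge_id`), so each connected
#' component is a tree rooted at its outlet. Upstream distances (hydrologic
#' distance from the outlet to each edge node) and additive function values
#' (AFVs) are computed during construction.
#'
#' @param edges A data frame with columns `edge_id` (unique integer ids),
#'   `down_edge_id` (id of the single downstream edge, `NA` at the outlet),
#'   `length` (positive, network distance units) and `additive_attr` (strictly
#'   positive additive attribute, e.g. cumulative watershed area, used to
#'   derive AFVs). An optional `netID` column groups edges into disconnected
#'   networks; it defaults to a single network. Extra columns (for example
#'   planar endpoint coordinates) are preserved.
#'
#' @return An object of class `stream_network`: a list with components
#'   `edges` (the validated edge table augmented with `dn_dist`, the
#'   hydrologic distance from the outlet to the downstream node of the edge,
#'   `up_dist`, the distance to the upstream node, `afv` and the per-edge
#'   segment weight `omega`), `paths` (for each edge, the index path to the
#'   outlet), `children` (immediate upstream edges) and `outlets`.
#'
#' @details AFVs satisfy `afv(outlet) = 1` and, at every junction, each
#'   upstream edge `u` of edge `d` receives
#'   `afv(u) = afv(d) * additive_attr(u) / sum(additive_attr over siblings)`.
#'   The segment weights at any junction therefore sum to one and AFVs are
#'   non-increasing moving upstream. These weights drive the tail-up
#'   covariance through [tailup_weights()].
#'
#' @examples
#' net <- build_network(data.frame(
#'   edge_id = c(1, 2, 3), down_edge_id = c(3, 3, NA),
#'   length = c(2, 4, 10), additive_attr = c(30, 10, 40)
#' ))
#' net$edges[, c("edge_id", "up_dist", "afv")]
#' @seealso [compute_afv()], [locate_sites()], [hydro_dist()]
#' @export
build_network <- function(edges) {
  edges <- as.data.frame(edges)
  req <- c("edge_id", "down_edge_id", "length", "additive_attr")
  miss <- setdiff(req, names(edges))
  if (length(miss) > 0) {
    sn_error(paste0("edge table is missing column(s): ", paste(miss, collapse = ", ")),
             "schema_error")
  }
  if (!"netID" %in% names(edges)) edges$netID <- 1L
  n <- nrow(edges)
  if (n < 1L) sn_error("edge table is empty", "schema_error")
  if (anyDuplicated(edges$edge_id) > 0L) {
    sn_error("edge_id values must be unique", "schema_error")
  }
  if (any(!is.na(edges$down_edge_id) & edges$down_edge_id == edges$edge_id)) {
    sn_error("an edge references itself as its downstream neighbour", "topology_error")
  }
  dn <- edges$down_edge_id
  bad_dn <- !is.na(dn) & !(dn %in% edges$edge_id)
  if (any(bad_dn)) {
    sn_error(paste0("down_edge_id refers to unknown edge(s): ",
                    paste(unique(dn[bad_dn]), collapse = ", ")), "schema_error")
  }
  if (any(!is.finite(edges$length) | edges$length <= 0)) {
    sn_error("edge lengths must be finite and > 0", "schema_error")
  }
  if (any(!is.finite(edges$additive_attr) | edges$additive_attr <= 0)) {
    sn_error("additive_attr must be finite and > 0 on every edge", "value_error")
  }

  idx_dn <- match(edges$down_edge_id, edges$edge_id)  # NA at outlets
  # downstream neighbour must live on the same network
  mism <- !is.na(idx_dn) & edges$netID != edges$netID[idx_dn]
  if (any(mism)) {
    sn_error("an edge and its downstream neighbour have different netID", "topology_error")
  }

  nets <- unique(edges$netID)
  outlets <- integer(0)
  for (net in nets) {
    sel <- which(edges$netID == net)
    out <- sel[is.na(idx_dn[sel])]
    if (length(out) > 1L) {
      sn_error(paste0("network ", net, " declares ", length(out),
                      " outlet edges; a dendritic network has exactly one"),
               "topology_error")
    }
    if (length(out) == 0L) {
      sn_error(paste0("network ", net,
                      " has no outlet edge: downstream pointers form a cycle"),
               "cycle_error")
    }
    outlets <- c(outlets, out)
  }

  # children lists (immediate upstream edges), then breadth-first from each
  # outlet; edges never reached sit on a cycle.
  children <- vector("list", n)
  for (i in seq_len(n)) children[[i]] <- integer(0)
  for (i in seq_len(n)) {
    if (!is.na(idx_dn[i])) children[[idx_dn[i]]] <- c(children[[idx_dn[i]]], i)
  }

  dn_dist <- rep(NA_real_, n)   # outlet -> downstream node of edge
  order_bfs <- integer(0)
  for (out in outlets) {
    dn_dist[out] <- 0
    queue <- out
    while (length(queue) > 0L) {
      e <- queue[[1L]]
      queue <- queue[-1L]
      order_bfs <- c(order_bfs, e)
      for (u in children[[e]]) {
        dn_dist[u] <- dn_dist[e] + edges$length[e]
        queue <- c(queue, u)
      }
    }
  }
  if (anyNA(dn_dist)) {
    sn_error("downstream pointers revisit an edge: cycle detected", "cycle_error")
  }

  edges$dn_dist <- dn_dist
  edges$up_dist <- dn_dist + edges$length

  # index paths to the outlet (edge itself first)
  paths <- vector("list", n)
  for (e in order_bfs) {
    paths[[e]] <- if (is.na(idx_dn[e])) e else c(e, paths[[idx_dn[e]]])
  }

  net <- structure(
    list(edges = edges, idx_dn = idx_dn, children = children,
         paths = paths, outlets = outlets, bfs_order = order_bfs),
    class = "stream_network"
  )
  compute_afv(net)
}

#' Compute additive function values on a stream network
#'
#' Populates (or recomputes) the per-edge additive function value (AFV) and
#' segment weight `omega` from the `additive_attr` column. The outlet edge of
#' every network has AFV 1; at each junction the upstream edges split the AFV
#' of the downstream edge in proportion to their additive attribute.
#'
#' @param network A `stream_network`.
#' @return The network with `edges$afv` and `edges$omega` filled; all AFVs lie
#'   in (0, 1].
#' @export
compute_afv <- function(network) {
  stopifnot(inherits(network, "stream_network"))
  edges <- network$edges
  if (any(!is.finite(edges$additive_attr) | edges$additive_attr <= 0)) {
    sn_error("additive_attr must be finite and > 0 on every edge", "value_error")
  }
  n <- nrow(edges)
  afv <- rep(NA_real_, n)
  omega <- rep(NA_real_, n)
  afv[network$outlets] <- 1
  omega[network$outlets] <- 1
  for (e in network$bfs_order) {
    kids <- network$children[[e]]
    if (length(kids) > 0L) {
      w <- edges$additive_attr[kids] / sum(edges$additive_attr[kids])
      omega[kids] <- w
      afv[kids] <- afv[e] * w
    }
  }
  network$edges$afv <- afv
  network$edges$omega <- omega
  network
}

#' Locate sites on a stream network
#'
#' Validates a raw site table against a network and computes, for each site,
#' its hydrologic distance from the outlet (`up_dist`) and the AFV of its
#' edge. A site is addressed by an edge id plus `ratio`, its fractional
#' position along that edge measured from the *downstream* node (`ratio = 0`
#' is the downstream end).
#'
#' @param sites Data frame with columns `site_id`, `edge_id`, `ratio` and
#'   planar coordinates `x`, `y`. A `response` column and any number of
#'   covariate columns are carried through unchanged.
#' @param network A `stream_network`.
#' @return The site table augmented with `up_dist`, `afv` and `netID`, ordered
#'   as supplied.
#' @export
locate_sites <- function(sites, network) {
  stopifnot(inherits(network, "stream_network"))
  sites <- as.data.frame(sites)
  req <- c("site_id", "edge_id", "ratio", "x", "y")
  miss <- setdiff(req, names(sites))
  if (length(miss) > 0) {
    sn_error(paste0("site table is missing column(s): ", paste(miss, collapse = ", ")),
             "schema_error")
  }
  idx <- match(sites$edge_id, network$edges$edge_id)
  if (anyNA(idx)) {
    sn_error(paste0("site(s) reference unknown edge_id: ",
                    paste(unique(sites$edge_id[is.na(idx)]), collapse = ", ")),
             "key_error")
  }
  if (any(!is.finite(sites$ratio) | sites$ratio < 0 | sites$ratio > 1)) {
    sn_error("site ratio must lie in [0, 1]", "value_error")
  }
  sites$up_dist <- network$edges$dn_dist[idx] +
    sites$ratio * network$edges$length[idx]
  sites$afv <- network$edges$afv[idx]
  sites$netID <- network$edges$netID[idx]
  sites
}

#' @export
print.stream_network <- function(x, ...) {
  e <- x$edges
  cat("Dendritic stream network\n")
  cat("  edges:    ", nrow(e), " on ", length(unique(e$netID)), " network(s)\n", sep = "")
  cat("  junctions:", sum(lengths(x$children) > 1L), "\n")
  cat("  total length:", format(sum(e$length), digits = 6), "\n")
  cat("  max outlet distance:", format(max(e$up_dist), digits = 6), "\n")
  invisible(x)
}
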