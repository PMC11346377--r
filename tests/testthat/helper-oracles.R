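# Shared fixtures and independent brute-force oracles. The oracles walk the
# edge graph step by step and never reuse the package's distance arithmetic,
# so they can certify the matrix implementations.

# three-edge junction: edges 1 and 2 meet above outlet edge 3
tiny3_network <- function() {
  build_network(data.frame(
    edge_id = c(1, 2, 3), down_edge_id = c(3, 3, NA),
    length = c(2, 4, 10), additive_attr = c(30, 10, 40)
  ))
}

# explicit downstream walk from a site: edge index sequence and the cumulative
# distance travelled when *entering* each subsequent edge
bf_walk <- function(network, edge_id, ratio) {
  e <- network$edges
  i <- match(edge_id, e$edge_id)
  edges_seq <- i
  enter_dist <- ratio * e$length[i]  # distance from site to downstream node
  dist_seq <- enter_dist
  while (!is.na(network$idx_dn[i])) {
    i <- network$idx_dn[i]
    edges_seq <- c(edges_seq, i)
    dist_seq <- c(dist_seq, dist_seq[length(dist_seq)] + e$length[i])
  }
  # dist_seq[k]: distance from the site to the downstream node of edges_seq[k]
  list(edges = edges_seq, dist = dist_seq)
}

# brute-force pair quantities by enumerating both downstream walks
bf_pair <- function(network, s1, s2) {
  e <- network$edges
  i1 <- match(s1$edge_id, e$edge_id)
  i2 <- match(s2$edge_id, e$edge_id)
  if (e$netID[i1] != e$netID[i2]) {
    return(list(D12 = Inf, D21 = Inf, h = Inf, a = Inf, b = Inf, fc = FALSE))
  }
  w1 <- bf_walk(network, s1$edge_id, s1$ratio)
  w2 <- bf_walk(network, s2$edge_id, s2$ratio)
  pos1 <- s1$ratio * e$length[i1]
  pos2 <- s2$ratio * e$length[i2]
  if (i1 == i2) {
    d12 <- max(pos1 - pos2, 0)
    d21 <- max(pos2 - pos1, 0)
  } else if (i2 %in% w1$edges) {
    # site 1 flows through site 2's edge: distance to 2's downstream node
    # minus 2's offset from that node
    k <- match(i2, w1$edges)
    d12 <- w1$dist[k] - pos2
    d21 <- 0
  } else if (i1 %in% w2$edges) {
    k <- match(i1, w2$edges)
    d21 <- w2$dist[k] - pos1
    d12 <- 0
  } else {
    k <- match(TRUE, w1$edges %in% w2$edges)  # first shared edge
    j <- match(w1$edges[k], w2$edges)
    # both flows enter the shared edge at its upstream node
    d12 <- w1$dist[k] - e$length[w1$edges[k]]
    d21 <- w2$dist[j] - e$length[w2$edges[j]]
  }
  a <- max(d12, d21)
  b <- min(d12, d21)
  list(D12 = d12, D21 = d21, h = d12 + d21, a = a, b = b, fc = b == 0)
}

# brute-force tail-up weight: product of segment weights omega over the edges
# of the connecting path strictly above the downstream site's edge
bf_tailup_weight <- function(network, s1, s2) {
  p <- bf_pair(network, s1, s2)
  if (!p$fc) return(0)
  up <- if (p$D12 > 0) s1 else s2
  dn <- if (p$D12 > 0) s2 else s1
  e <- network$edges
  i <- match(up$edge_id, e$edge_id)
  stop_at <- match(dn$edge_id, e$edge_id)
  prod_w <- 1
  while (i != stop_at) {
    prod_w <- prod_w * e$omega[i]
    i <- network$idx_dn[i]
    stopifnot(!is.na(i))
  }
  sqrt(prod_w)
}

# random located sites on a network
random_sites <- function(network, n) {
  e <- network$edges
  idx <- sample(nrow(e), n, replace = TRUE, prob = e$length)
  s <- data.frame(site_id = seq_len(n), edge_id = e$edge_id[idx],
                  ratio = runif(n))
  if (all(c("x_dn", "x_up") %in% names(e))) {
    s$x <- e$x_dn[idx] + s$ratio * (e$x_up[idx] - e$x_dn[idx])
    s$y <- e$y_dn[idx] + s$ratio * (e$y_up[idx] - e$y_dn[idx])
  } else {
    s$x <- rnorm(n)
    s$y <- rnorm(n)
  }
  locate_sites(s, network)
}
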