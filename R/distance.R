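#' Hydrologic distance matrices between sites
#'
#' Computes the asymmetric downstream-distance matrix among sites on a
#' dendritic network, together with the derived pair quantities used by the
#' stream covariance functions: total stream distance `h`, the decomposition
#' `h = a + b` into each site's distance to the pair's closest common
#' downstream point (`a >= b`), and the flow-connectivity flag (`b == 0`,
#' i.e. one site lies on the other's downstream path).
#'
#' @param network A `stream_network`.
#' @param sites Located site table (see [locate_sites()]); the rows of the
#'   returned matrices.
#' @param sites2 Optional second located site table for rectangular blocks
#'   (e.g. observed x prediction). Defaults to `sites`.
#' @return An object of class `hydro_dist`: a list of matrices `D` (distance
#'   from each row site downstream to the common point with each column site),
#'   `Dt` (same for the column site, so the full asymmetric matrix of a square
#'   problem is `D` with `D[j, i] = Dt[i, j]`), `h = D + Dt`, `a`, `b`, and
#'   logical `fc` (flow-connected). Pairs on different networks have infinite
#'   stream distances and `fc = FALSE`.
#'
#' @details For sites `i` and `j` on the same network the closest common
#'   downstream point is either the more downstream of the two sites (when the
#'   pair is flow-connected) or the junction where their downstream paths
#'   merge. Its distance from the outlet, `J`, gives
#'   `D[i, j] = up_dist(i) - J` and `Dt[i, j] = up_dist(j) - J`.
#' @export
hydro_dist <- function(network, sites, sites2 = NULL) {
  stopifnot(inherits(network, "stream_network"))
  square <- is.null(sites2)
  if (square) sites2 <- sites
  ei <- match(sites$edge_id, network$edges$edge_id)
  ej <- match(sites2$edge_id, network$edges$edge_id)
  if (anyNA(ei) || anyNA(ej)) {
    sn_error("sites are not located on this network (unknown edge_id)", "key_error")
  }
  ui <- sites$up_dist
  uj <- sites2$up_dist
  neti <- sites$netID
  netj <- sites2$netID
  n <- length(ui)
  m <- length(uj)

  # Edge-pair relations, computed once for the edges actually used:
  #  rel = 1 if the pair of edges lies on a common downstream path (or is the
  #  same edge), in which case the common point of two sites is simply the
  #  more downstream site; rel = 0 otherwise, with `jun` holding the outlet
  #  distance of the junction (upstream node of the first shared edge).
  used <- sort(unique(c(ei, ej)))
  k <- length(used)
  pos <- integer(nrow(network$edges))
  pos[used] <- seq_len(k)
  onpath <- matrix(FALSE, k, k)  # onpath[p,q]: edge q's path contains edge p or vice versa
  jun <- matrix(NA_real_, k, k)
  paths <- network$paths
  updist_upper <- network$edges$up_dist
  enet <- network$edges$netID
  for (p in seq_len(k)) {
    onpath[p, p] <- TRUE
    jun[p, p] <- 0  # unused for same-edge pairs
  }
  if (k > 1L) {
    for (p in 1:(k - 1L)) {
      for (q in (p + 1L):k) {
        e <- used[p]; f <- used[q]
        if (enet[e] != enet[f]) next
        pe <- paths[[e]]; pf <- paths[[f]]
        hit <- match(pe, pf)
        first <- which(!is.na(hit))[1L]
        common <- pe[first]
        if (common == e || common == f) {
          onpath[p, q] <- TRUE
          onpath[q, p] <- TRUE
        } else {
          jun[p, q] <- updist_upper[common]
          jun[q, p] <- updist_upper[common]
        }
      }
    }
  }

  D <- matrix(Inf, n, m)
  Dt <- matrix(Inf, n, m)
  pi_ <- pos[ei]
  for (j in seq_len(m)) {
    same <- neti == netj[j]
    if (!any(same)) next
    pj <- pos[ej[j]]
    onp <- onpath[pi_, pj]
    J <- ifelse(onp, pmin(ui, uj[j]), jun[pi_, pj])
    D[, j] <- ifelse(same, ui - J, Inf)
    Dt[, j] <- ifelse(same, uj[j] - J, Inf)
  }

  a <- pmax(D, Dt)
  b <- pmin(D, Dt)
  structure(
    list(D = D, Dt = Dt, h = D + Dt, a = a, b = b,
         fc = is.finite(b) & b == 0,
         square = square,
         row_ids = sites$site_id, col_ids = sites2$site_id),
    class = "hydro_dist"
  )
}

#' @export
print.hydro_dist <- function(x, ...) {
  cat("Hydrologic distances: ", nrow(x$D), " x ", ncol(x$D),
      if (x$square) " (square)" else " (rectangular)", "\n", sep = "")
  fin <- is.finite(x$h)
  cat("  flow-connected pairs:  ", sum(x$fc), "\n")
  cat("  flow-unconnected pairs:", sum(fin & !x$fc), "\n")
  if (any(fin)) cat("  stream distance range: ",
                    format(range(x$h[fin]), digits = 5), "\n")
  invisible(x)
}

#' Tail-up spatial weights
#'
#' Builds the matrix of tail-up weights between pairs of sites. For a
#' flow-connected pair the weight is `sqrt(afv_up / afv_down)`, the square
#' root of the ratio of the upstream site's additive function value to the
#' downstream site's, which equals the square root of the product of segment
#' weights at every junction passed between the two sites. Flow-unconnected
#' pairs (and pairs on different networks) get weight 0; a site paired with
#' itself gets 1.
#'
#' @param network A `stream_network` with AFVs computed.
#' @param sites,sites2 Located site tables, as in [hydro_dist()].
#' @param dists Optional precomputed [hydro_dist()] object for the same site
#'   pair; computed if missing.
#' @param afv_col Name of the site column holding additive function values
#'   (default `"afv"`, as filled in by [locate_sites()]).
#' @return A numeric matrix of weights in [0, 1].
#' @export
tailup_weights <- function(network, sites, sites2 = NULL, dists = NULL,
                           afv_col = "afv") {
  if (is.null(dists)) dists <- hydro_dist(network, sites, sites2)
  if (is.null(sites2)) sites2 <- sites
  if (!afv_col %in% names(sites) || !afv_col %in% names(sites2)) {
    sn_error(paste0("additive function value column '", afv_col, "' not found"),
             "schema_error")
  }
  ai <- sites[[afv_col]]
  aj <- sites2[[afv_col]]
  if (any(!is.finite(ai) | ai <= 0) || any(!is.finite(aj) | aj <= 0)) {
    sn_error("additive function values must be finite and > 0", "value_error")
  }
  Ai <- matrix(ai, length(ai), length(aj))
  Aj <- matrix(aj, length(ai), length(aj), byrow = TRUE)
  # the site with positive remaining distance to the common point is upstream;
  # co-located pairs (both zero) use the min/max ratio so W <= 1 regardless of
  # which sibling edge hosts the site
  W <- ifelse(dists$D > 0, sqrt(Ai / Aj),
              ifelse(dists$Dt > 0, sqrt(Aj / Ai),
                     sqrt(pmin(Ai, Aj) / pmax(Ai, Aj))))
  W[!dists$fc] <- 0
  W
}

#' Euclidean distance matrix between site coordinates
#'
#' @param sites,sites2 Site tables with planar `x`, `y` columns
#'   (`sites2` defaults to `sites`). Coordinates are assumed projected;
#'   distances are straight-line.
#' @return Matrix of Euclidean distances.
#' @export
euclid_dist <- function(sites, sites2 = NULL) {
  if (is.null(sites2)) sites2 <- sites
  dx <- outer(sites$x, sites2$x, "-")
  dy <- outer(sites$y, sites2$y, "-")
  sqrt(dx^2 + dy^2)
}

#' Persist hydrologic distance matrices to disk
#'
#' Writes the matrices of a [hydro_dist()] object as plain CSV files (one per
#' matrix, with site ids as row/column names) into a directory, mirroring the
#' conventional workflow of materialising distance matrices once before model
#' fitting.
#'
#' @param dists A `hydro_dist` object.
#' @param path Directory to create/write into.
#' @param name Label for this block, e.g. `"obs"` or a prediction-set name.
#' @param overwrite Overwrite an existing block of the same name?
#'   Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_distances <- function(dists, path, name = "obs", overwrite = FALSE) {
  stopifnot(inherits(dists, "hydro_dist"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(path, paste0(name, ".", c("D", "Dt"), ".csv"))
  if (!overwrite && any(file.exists(files))) {
    sn_error(paste0("distance block '", name, "' already exists; use overwrite = TRUE"),
             "io_error")
  }
  for (i in 1:2) {
    M <- dists[[c("D", "Dt")[i]]]
    dimnames(M) <- list(dists$row_ids, dists$col_ids)
    utils::write.csv(M, files[i])
  }
  invisible(path)
}

#' Read persisted hydrologic distance matrices
#'
#' @param path Directory written by [write_distances()].
#' @param name Block label used at write time.
#' @return A `hydro_dist` object (derived quantities recomputed).
#' @export
read_distances <- function(path, name = "obs") {
  files <- file.path(path, paste0(name, ".", c("D", "Dt"), ".csv"))
  if (!all(file.exists(files))) {
    sn_error(paste0("no persisted distance block '", name, "' under ", path),
             "io_error")
  }
  rd <- function(f) {
    df <- utils::read.csv(f, row.names = 1, check.names = FALSE)
    as.matrix(df)
  }
  D <- rd(files[1]); Dt <- rd(files[2])
  structure(
    list(D = D, Dt = Dt, h = D + Dt, a = pmax(D, Dt), b = pmin(D, Dt),
         fc = is.finite(pmin(D, Dt)) & pmin(D, Dt) == 0,
         square = identical(rownames(D), colnames(D)),
         row_ids = rownames(D), col_ids = colnames(D)),
    class = "hydro_dist"
  )
}
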