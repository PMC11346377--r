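#' Bundle a network with observed and prediction sites
#'
#' The container passed to [ssn_lm()]: a validated network, located observed
#' sites, and any number of named prediction-site sets.
#'
#' @param network A `stream_network`.
#' @param obs Observed-site table (located with [locate_sites()] if the
#'   `up_dist`/`afv` columns are missing); should contain the response and
#'   covariate columns referenced by the model formula.
#' @param preds Named list of prediction-site tables (located on demand).
#'   Prediction sites carry no usable response.
#' @return An object of class `ssn_data`.
#' @export
ssn_data <- function(network, obs, preds = list()) {
  stopifnot(inherits(network, "stream_network"))
  obs <- as.data.frame(obs)
  if (!all(c("up_dist", "afv") %in% names(obs))) obs <- locate_sites(obs, network)
  if (length(preds) > 0) {
    if (is.null(names(preds)) || anyDuplicated(names(preds)) > 0 ||
        any(names(preds) == "")) {
      sn_error("prediction sets must have unique non-empty names", "schema_error")
    }
    preds <- lapply(preds, function(p) {
      p <- as.data.frame(p)
      if (nrow(p) > 0L && !all(c("up_dist", "afv") %in% names(p))) {
        p <- locate_sites(p, network)
      }
      p
    })
  }
  structure(list(network = network, obs = obs, preds = preds),
            class = "ssn_data")
}

#' @export
print.ssn_data <- function(x, ...) {
  cat("Stream-network dataset\n")
  print(x$network)
  cat("  observed sites:", nrow(x$obs), "\n")
  if (length(x$preds) > 0) {
    for (nm in names(x$preds)) {
      cat("  prediction set '", nm, "': ", nrow(x$preds[[nm]]), " sites\n",
          sep = "")
    }
  } else {
    cat("  prediction sets: none\n")
  }
  invisible(x)
}

edge_core_cols <- c("edge_id", "down_edge_id", "length", "additive_attr", "netID")
site_core_cols <- c("site_id", "edge_id", "ratio", "x", "y")

# deterministic column ordering: core columns first, the rest sorted
ordered_cols <- function(df, core) {
  extra <- sort(setdiff(names(df), core))
  df[, c(intersect(core, names(df)), extra), drop = FALSE]
}

#' Write a stream-network dataset to a directory of CSV files
#'
#' Writes `edges.csv`, `obs.csv`, one `preds-<name>.csv` per prediction set
#' and a small `meta.json` manifest. Rows are sorted by id and columns by a
#' fixed rule, so two writes of the same dataset are byte-identical.
#'
#' @param x An [ssn_data()] object.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_ssn_data <- function(x, path) {
  stopifnot(inherits(x, "ssn_data"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, file, core, id) {
    df <- ordered_cols(df, core)
    df <- df[order(df[[id]]), , drop = FALSE]
    utils::write.csv(df, file.path(path, file), row.names = FALSE)
  }
  derived <- c("dn_dist", "up_dist", "afv", "omega")
  e <- x$network$edges
  wr(e[, setdiff(names(e), derived), drop = FALSE], "edges.csv",
     edge_core_cols, "edge_id")
  wr(x$obs[, setdiff(names(x$obs), c("up_dist", "afv")), drop = FALSE],
     "obs.csv", site_core_cols, "site_id")
  for (nm in names(x$preds)) {
    p <- x$preds[[nm]]
    wr(p[, setdiff(names(p), c("up_dist", "afv")), drop = FALSE],
       paste0("preds-", nm, ".csv"), site_core_cols, "site_id")
  }
  meta <- list(format = "streamnet-csv-v1",
               prediction_sets = as.list(names(x$preds)))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a stream-network dataset from a CSV directory
#'
#' Reads the layout written by [write_ssn_data()], rebuilds and revalidates
#' the network, relocates all sites and preserves unknown site columns as
#' covariates. Schema problems are collected and reported together.
#'
#' @param path Dataset directory.
#' @param predpts Optional character vector restricting which prediction sets
#'   to load; an unknown name is a schema error.
#' @return An [ssn_data()] object.
#' @export
read_ssn_data <- function(path, predpts = NULL) {
  problems <- character(0)
  need <- file.path(path, c("edges.csv", "obs.csv"))
  for (f in need) if (!file.exists(f)) problems <- c(problems, paste0("missing file: ", f))
  if (length(problems) > 0) {
    sn_error(paste0("invalid dataset layout:\n  ",
                    paste(problems, collapse = "\n  ")), "format_error")
  }
  edges <- utils::read.csv(file.path(path, "edges.csv"))
  obs <- utils::read.csv(file.path(path, "obs.csv"))
  for (col in setdiff(edge_core_cols, "netID")) {
    if (!col %in% names(edges)) problems <- c(problems, paste0("edges.csv lacks column ", col))
  }
  for (col in site_core_cols) {
    if (!col %in% names(obs)) problems <- c(problems, paste0("obs.csv lacks column ", col))
  }

  meta_file <- file.path(path, "meta.json")
  avail <- if (file.exists(meta_file)) {
    unlist(jsonlite::read_json(meta_file)$prediction_sets)
  } else {
    sub("^preds-(.*)\\.csv$", "\\1",
        list.files(path, pattern = "^preds-.*\\.csv$"))
  }
  avail <- as.character(avail %||% character(0))
  want <- predpts %||% avail
  for (nm in setdiff(want, avail)) {
    problems <- c(problems, paste0("prediction set '", nm, "' not present (available: ",
                                   if (length(avail)) paste(avail, collapse = ", ") else "none", ")"))
  }
  if (length(problems) > 0) {
    sn_error(paste0("schema violations:\n  ", paste(problems, collapse = "\n  ")),
             "schema_error")
  }
  network <- build_network(edges)
  preds <- list()
  for (nm in want) {
    preds[[nm]] <- utils::read.csv(file.path(path, paste0("preds-", nm, ".csv")))
  }
  ssn_data(network, obs, preds)
}

# ---- GeoJSON (point sites) ------------------------------------------------

#' Write a site table as a GeoJSON FeatureCollection of points
#'
#' Coordinates come from the `x`/`y` columns (assumed planar/projected); all
#' other columns are stored as feature properties. Rows are sorted by
#' `site_id` for deterministic output.
#'
#' @param sites Site data frame with `x` and `y`.
#' @param path Output `.geojson` file.
#' @return `path`, invisibly.
#' @export
write_geojson_sites <- function(sites, path) {
  sites <- as.data.frame(sites)
  if (!all(c("x", "y") %in% names(sites))) {
    sn_error("GeoJSON export needs x and y columns", "schema_error")
  }
  if ("site_id" %in% names(sites)) sites <- sites[order(sites$site_id), , drop = FALSE]
  propcols <- setdiff(names(sites), c("x", "y"))
  features <- lapply(seq_len(nrow(sites)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(sites$x[i], sites$y[i])),
         properties = as.list(sites[i, propcols, drop = FALSE]))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a GeoJSON FeatureCollection of point sites
#'
#' @param path A `.geojson` file of Point features.
#' @return Data frame with `x`, `y` and one column per property.
#' @export
read_geojson_sites <- function(path) {
  g <- jsonlite::read_json(path)
  if (!identical(g$type, "FeatureCollection")) {
    sn_error("not a GeoJSON FeatureCollection", "format_error")
  }
  rows <- lapply(g$features, function(f) {
    if (!identical(f$geometry$type, "Point")) {
      sn_error("only Point geometries are supported", "format_error")
    }
    props <- lapply(f$properties, function(v) if (is.null(v)) NA else v)
    c(list(x = f$geometry$coordinates[[1]], y = f$geometry$coordinates[[2]]),
      props)
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  core <- intersect(site_core_cols, names(df))
  df[, c(core, sort(setdiff(names(df), core))), drop = FALSE]
}

# ---- classic .ssn attribute-table dialect ---------------------------------

ssn_col_map <- c(
  edge_id = "rid", site_id = "pid", ratio = "ratio", x = "near_x", y = "near_y",
  length = "length", additive_attr = "afvarea", netID = "netid",
  down_edge_id = "todown"
)

match_classic_cols <- function(df, wanted, label) {
  lc <- tolower(names(df))
  out <- df
  for (std in names(wanted)) {
    hit <- which(lc == tolower(wanted[[std]]))
    if (length(hit) == 1L && !std %in% names(out)) {
      names(out)[hit] <- std
      message("read_ssn_folder: ", label, " column '", names(df)[hit],
              "' mapped to '", std, "'")
    }
  }
  out
}

#' Read a classic `.ssn`-style folder (attribute-table dialect)
#'
#' Compatibility reader for the non-proprietary `.ssn` folder layout used by
#' stream-network GIS pre-processing tools. Only the attribute tables are
#' consumed — `edges` and `sites` as `.dbf` (via the `foreign` package) or
#' `.csv` — with the classic column names matched case-insensitively
#' (`rid`, `pid`, `ratio`, `upDist`, `afvArea`, `NEAR_X`/`NEAR_Y`, `netID`)
#' and the applied mapping logged. Because the classic layout stores edge
#' topology in a binary database rather than the attribute table, this
#' dialect additionally requires a downstream-edge column (`todown`, or any
#' column already named `down_edge_id`). `ratio` is interpreted as the
#' fractional position from the downstream node, consistent with
#' `upDist(site) = upDist(downstream node) + ratio * length`.
#'
#' @param path Folder containing `edges` and `sites` tables.
#' @param predpts Character vector of prediction table names to load (without
#'   extension).
#' @return An [ssn_data()] object.
#' @export
read_ssn_folder <- function(path, predpts = character(0)) {
  read_tbl <- function(stem) {
    csv <- file.path(path, paste0(stem, ".csv"))
    dbf <- file.path(path, paste0(stem, ".dbf"))
    if (file.exists(csv)) return(utils::read.csv(csv))
    if (file.exists(dbf)) {
      if (!requireNamespace("foreign", quietly = TRUE)) {
        sn_error("reading .dbf tables requires the 'foreign' package", "format_error")
      }
      return(foreign::read.dbf(dbf, as.is = TRUE))
    }
    sn_error(paste0("no table '", stem, "' (.csv or .dbf) under ", path),
             "format_error")
  }
  edges <- match_classic_cols(read_tbl("edges"), ssn_col_map, "edges")
  if (!"down_edge_id" %in% names(edges)) {
    sn_error("edges table needs a downstream-edge column ('todown' or 'down_edge_id'); the classic binary topology database is not supported",
             "schema_error")
  }
  edges$down_edge_id[!is.na(edges$down_edge_id) & edges$down_edge_id < 0] <- NA
  sites <- match_classic_cols(read_tbl("sites"), ssn_col_map, "sites")
  if (!"site_id" %in% names(sites)) sites$site_id <- seq_len(nrow(sites))
  network <- build_network(edges)
  preds <- list()
  for (nm in predpts) {
    p <- match_classic_cols(read_tbl(nm), ssn_col_map, nm)
    if (!"site_id" %in% names(p)) p$site_id <- seq_len(nrow(p))
    preds[[nm]] <- p
  }
  ssn_data(network, sites, preds)
}
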