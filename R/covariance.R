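#' Covariance parameter set for a stream-network model
#'
#' Bundles the covariance parameters of the three spatially dependent error
#' components plus the nugget. Each spatial component has a type, a partial
#' sill (`*_de`, the variance the component contributes at distance zero) and
#' a range (`*_range`). The range is the "natural" scale of each form: the
#' e-folding distance for exponential/gaussian types and the exact support for
#' spherical/linear-with-sill types; no effective-range rescaling is applied.
#'
#' @param tailup_type,taildown_type One of `"exponential"`, `"spherical"`,
#'   `"linear_sill"`, `"none"`.
#' @param euclid_type One of `"exponential"`, `"gaussian"`, `"spherical"`,
#'   `"none"`.
#' @param tailup_de,taildown_de,euclid_de Partial sills (>= 0).
#' @param tailup_range,taildown_range,euclid_range Ranges (> 0).
#' @param nugget Spatially independent variance (>= 0).
#' @return An object of class `ssn_params`.
#' @export
ssn_params <- function(tailup_type = "none", tailup_de = 0, tailup_range = 1,
                       taildown_type = "none", taildown_de = 0, taildown_range = 1,
                       euclid_type = "none", euclid_de = 0, euclid_range = 1,
                       nugget = 0) {
  tailup_type <- check_cov_type(tailup_type, "tailup")
  taildown_type <- check_cov_type(taildown_type, "taildown")
  euclid_type <- check_cov_type(euclid_type, "euclid")
  vals <- c(tailup_de = tailup_de, tailup_range = tailup_range,
            taildown_de = taildown_de, taildown_range = taildown_range,
            euclid_de = euclid_de, euclid_range = euclid_range,
            nugget = nugget)
  if (any(!is.finite(vals))) sn_error("covariance parameters must be finite", "value_error")
  if (any(vals[c("tailup_de", "taildown_de", "euclid_de", "nugget")] < 0)) {
    sn_error("partial sills and nugget must be >= 0", "value_error")
  }
  if (any(vals[c("tailup_range", "taildown_range", "euclid_range")] <= 0)) {
    sn_error("ranges must be > 0", "value_error")
  }
  structure(
    list(tailup = list(type = tailup_type, de = tailup_de, range = tailup_range),
         taildown = list(type = taildown_type, de = taildown_de, range = taildown_range),
         euclid = list(type = euclid_type, de = euclid_de, range = euclid_range),
         nugget = nugget),
    class = "ssn_params"
  )
}

stream_types <- c("exponential", "spherical", "linear_sill", "none")
euclid_types <- c("exponential", "gaussian", "spherical", "none")

check_cov_type <- function(type, component) {
  allowed <- if (component == "euclid") euclid_types else stream_types
  if (!(is.character(type) && length(type) == 1L && type %in% allowed)) {
    sn_error(paste0("unknown ", component, " covariance type '", type,
                    "'; permitted: ", paste(allowed, collapse = ", ")),
             "value_error")
  }
  type
}

#' @export
print.ssn_params <- function(x, ...) {
  cat("Stream-network covariance parameters\n")
  comp <- rbind(
    data.frame(component = "tailup", type = x$tailup$type,
               partial_sill = x$tailup$de, range = x$tailup$range),
    data.frame(component = "taildown", type = x$taildown$type,
               partial_sill = x$taildown$de, range = x$taildown$range),
    data.frame(component = "euclid", type = x$euclid$type,
               partial_sill = x$euclid$de, range = x$euclid$range)
  )
  comp <- comp[comp$type != "none", , drop = FALSE]
  comp <- rbind(comp, data.frame(component = "nugget", type = "",
                                 partial_sill = x$nugget, range = NA))
  print(comp, row.names = FALSE, digits = 5)
  invisible(x)
}

total_sill <- function(params) {
  (if (params$tailup$type != "none") params$tailup$de else 0) +
    (if (params$taildown$type != "none") params$taildown$de else 0) +
    (if (params$euclid$type != "none") params$euclid$de else 0) +
    params$nugget
}

zeros_like <- function(x) {
  x[] <- 0
  x
}

# flow-connected stream correlation at total stream distance h
cor_stream_fc <- function(h, type, range) {
  t <- h / range
  switch(type,
    exponential = exp(-t),
    linear_sill = pmax(1 - t, 0),
    spherical = {
      out <- 1 - 1.5 * t + 0.5 * t^3
      out[t > 1] <- 0
      out
    },
    none = zeros_like(h)
  )
}

#' Tail-up covariance
#'
#' Covariance of the tail-up (strictly upstream moving-average) component for
#' a pair of sites at total stream distance `h` with tail-up weight `w`.
#' Nonzero only for flow-connected pairs (`w > 0`); returns
#' `w * de * rho(h)` where `rho` is the exponential, linear-with-sill or
#' spherical correlation in stream distance.
#'
#' @param h Total stream distance(s), >= 0 (Inf allowed for cross-network
#'   pairs).
#' @param w Tail-up weight(s) in [0, 1] (see [tailup_weights()]).
#' @param type,de,range Covariance type, partial sill and range.
#' @return Numeric covariance value(s).
#' @export
cov_tailup <- function(h, w, type, de, range) {
  type <- check_cov_type(type, "tailup")
  if (type == "none") return(zeros_like(h))
  if (any(h < 0, na.rm = TRUE)) sn_error("stream distance h must be >= 0", "value_error")
  out <- w * de * cor_stream_fc(h, type, range)
  out[w == 0] <- 0
  out
}

#' Tail-down covariance
#'
#' Covariance of the tail-down (strictly downstream moving-average) component.
#' Defined for both flow-connected and flow-unconnected pairs, without spatial
#' weights. The pair is described by `a >= b >= 0`, the two sites' stream
#' distances to their closest common downstream point (`b = 0` and total
#' distance `h = a` for flow-connected pairs).
#'
#' Closed forms (correlation scale, `A = a/range`, `B = b/range`):
#' exponential `exp(-(A + B))`; linear-with-sill `(1 - A)+`; spherical
#' `(1 - A)^2 (1 + A/2 - 3B/2)` for `a <= range`, else 0. With `b = 0` each
#' reduces to the corresponding flow-connected form in `h = a`.
#'
#' @param a,b Distances to the common downstream point, `a >= b >= 0`.
#' @param type,de,range Covariance type, partial sill and range.
#' @param flow_connected Optional logical; only used to validate that
#'   flow-connected pairs have `b = 0`.
#' @return Numeric covariance value(s).
#' @export
cov_taildown <- function(a, b, type, de, range, flow_connected = NULL) {
  type <- check_cov_type(type, "taildown")
  if (type == "none") return(zeros_like(a))
  if (any(b > a, na.rm = TRUE)) sn_error("taildown requires a >= b", "value_error")
  if (any(b < 0, na.rm = TRUE)) sn_error("taildown requires b >= 0", "value_error")
  if (!is.null(flow_connected) && any(flow_connected & b != 0)) {
    sn_error("flow-connected pairs must have b = 0", "value_error")
  }
  A <- a / range
  B <- b / range
  out <- switch(type,
    exponential = de * exp(-(A + B)),
    linear_sill = de * pmax(1 - A, 0),
    spherical = {
      o <- de * (1 - A)^2 * (1 + A / 2 - 1.5 * B)
      o[A > 1] <- 0
      o
    }
  )
  out[is.infinite(a)] <- 0
  out
}

#' Euclidean covariance
#'
#' Straight-line-distance covariance component: exponential
#' `de * exp(-d/range)`, gaussian `de * exp(-(d/range)^2)`, or the 3-D
#' spherical form with compact support `[0, range]`.
#'
#' @param d Euclidean distance(s), >= 0.
#' @param type,de,range Covariance type, partial sill and range.
#' @return Numeric covariance value(s).
#' @export
cov_euclid <- function(d, type, de, range) {
  type <- check_cov_type(type, "euclid")
  if (type == "none") return(zeros_like(d))
  t <- d / range
  switch(type,
    exponential = de * exp(-t),
    gaussian = de * exp(-t^2),
    spherical = {
      out <- de * (1 - 1.5 * t + 0.5 * t^3)
      out[t > 1] <- 0
      out
    }
  )
}

#' Assemble the full model covariance matrix
#'
#' Sums the tail-up, tail-down and Euclidean component matrices and, for
#' square observed blocks, adds the nugget on the diagonal:
#' `Sigma = Sigma_tu + Sigma_td + Sigma_e + nugget * I`.
#'
#' @param dists A [hydro_dist()] object for the site pair (square or
#'   rectangular).
#' @param W Tail-up weight matrix (required if the tail-up type is active).
#' @param ed Euclidean distance matrix (required if the Euclidean type is
#'   active); see [euclid_dist()].
#' @param params An [ssn_params()] object.
#' @param nugget_diag Add `nugget * I`? Only meaningful for square blocks;
#'   defaults to `dists$square`. Cross-covariance blocks never carry the
#'   nugget, so a prediction site co-located with an observed site is
#'   correlated with, not identical to, the observation.
#' @return Covariance matrix of the same dimension as `dists$h`.
#' @export
make_sigma <- function(dists, W = NULL, ed = NULL, params,
                       nugget_diag = dists$square) {
  stopifnot(inherits(dists, "hydro_dist"), inherits(params, "ssn_params"))
  dims <- dim(dists$h)
  S <- matrix(0, dims[1], dims[2])
  if (params$tailup$type != "none") {
    if (is.null(W)) sn_error("tail-up component requires a weight matrix W", "value_error")
    if (!identical(dim(W), dims)) sn_error("W dimensions do not match distances", "dimension_error")
    S <- S + cov_tailup(dists$h, W, params$tailup$type,
                        params$tailup$de, params$tailup$range)
  }
  if (params$taildown$type != "none") {
    S <- S + cov_taildown(dists$a, dists$b, params$taildown$type,
                          params$taildown$de, params$taildown$range)
  }
  if (params$euclid$type != "none") {
    if (is.null(ed)) sn_error("Euclidean component requires a distance matrix ed", "value_error")
    if (!identical(dim(ed), dims)) sn_error("ed dimensions do not match distances", "dimension_error")
    S <- S + cov_euclid(ed, params$euclid$type,
                        params$euclid$de, params$euclid$range)
  }
  if (nugget_diag) {
    if (dims[1] != dims[2]) sn_error("nugget diagonal requires a square block", "dimension_error")
    S <- S + diag(params$nugget, dims[1])
  }
  S
}

#' Numerical moving-average covariance oracle
#'
#' Computes the stream-network correlation directly from its moving-average
#' construction by adaptive quadrature,
#' `int_0^Inf g(x + a) g(x + b) dx / int_0^Inf g(x)^2 dx`,
#' and serves as an independent check of the closed forms in
#' [cov_tailup()] and [cov_taildown()]. The kernels are
#' `g(x) = exp(-x/range)` (exponential), the indicator of `[0, range]`
#' (linear-with-sill) and `(1 - x/range)+` (spherical); with this scaling the
#' kernel parameter coincides with the closed form's range, so no remapping is
#' needed. For a flow-connected pair call with `(h, 0)`.
#'
#' @param type `"exponential"`, `"linear_sill"` or `"spherical"`.
#' @param a,b Scalar distances to the common downstream point (order
#'   irrelevant).
#' @param range Kernel range.
#' @return Scalar correlation.
#' @export
ma_cov_numeric <- function(type, a, b, range) {
  type <- check_cov_type(type, "tailup")
  if (a < b) { tmp <- a; a <- b; b <- tmp }
  g <- switch(type,
    exponential = function(x) exp(-x / range),
    linear_sill = function(x) as.numeric(x >= 0 & x <= range),
    spherical = function(x) pmax(1 - x / range, 0),
    none = sn_error("'none' has no moving-average kernel", "value_error")
  )
  upper <- if (type == "exponential") Inf else max(range - a, 0)
  if (upper <= 0) return(0)
  num <- stats::integrate(function(x) g(x + a) * g(x + b), 0, upper,
                          rel.tol = 1e-10, abs.tol = 1e-12)$value
  den_upper <- if (type == "exponential") Inf else range
  den <- stats::integrate(function(x) g(x)^2, 0, den_upper,
                          rel.tol = 1e-10, abs.tol = 1e-12)$value
  num / den
}
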