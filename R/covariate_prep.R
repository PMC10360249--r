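# Covariate preparation: inverse-distance-weighted interpolation of the
# pollutant monitoring stations onto areas, quintile coding, and
# variance-inflation screening for multicollinearity.

#' Inverse distance weighting interpolation
#'
#' \eqn{v(x) = \sum_k z_k d_k^{-p} / \sum_k d_k^{-p}}; a query point
#' coinciding with a station returns the station value exactly, and every
#' interpolated value lies within the station value range.
#'
#' @param stations data.frame with `x`, `y` and a value column (`pm10` or
#'   `value`).
#' @param points m x 2 matrix of query points.
#' @param power IDW exponent p > 0 (default 2).
#' @return numeric vector of length m.
#' @export
idw_interpolate <- function(stations, points, power = 2) {
  if (!nrow(stations)) stop("no stations")
  if (power <= 0) stop("power must be > 0")
  vals <- if (!is.null(stations$pm10)) stations$pm10 else stations$value
  if (is.null(vals)) stop("stations need a 'pm10' or 'value' column")
  points <- matrix(points, ncol = 2L)
  out <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    d <- sqrt((stations$x - points[i, 1L])^2 + (stations$y - points[i, 2L])^2)
    hit <- which(d == 0)
    if (length(hit)) {
      out[i] <- vals[hit[1L]]
    } else {
      w <- d^(-power)
      out[i] <- sum(vals * w) / sum(w)
    }
  }
  out
}

# Deterministic interior sample points for a polygon: the centroid for
# n = 1, otherwise centroid plus points pulled from the ring vertices
# towards the centroid.
polygon_sample_points <- function(poly, n) {
  cen <- polygon_centroid(poly)
  if (n <= 1L) return(matrix(cen, 1L, 2L))
  verts <- do.call(rbind, poly)
  k <- min(n - 1L, nrow(verts))
  sel <- verts[round(seq(1L, nrow(verts), length.out = k)), , drop = FALSE]
  rbind(cen, sweep(sel, 2L, cen, function(v, c) c + 0.5 * (v - c)))
}

#' Average pollutant level per area
#'
#' IDW evaluated at deterministic sample points inside each polygon
#' (the centroid when `n_sample_points = 1`, the default) and averaged.
#'
#' @param stations station data.frame (see [idw_interpolate()]).
#' @param lattice `area_lattice`.
#' @param power IDW exponent.
#' @param n_sample_points interior points per polygon.
#' @return named numeric vector, one value per area in canonical order.
#' @export
area_pollution <- function(stations, lattice, power = 2, n_sample_points = 1L) {
  vals <- vapply(lattice$polygons, function(poly) {
    if (polygon_area(poly) <= 0) stop("polygon with zero area")
    pts <- polygon_sample_points(poly, n_sample_points)
    mean(idw_interpolate(stations, pts, power))
  }, numeric(1))
  stats::setNames(vals, lattice$area_ids)
}

#' Quintile coding
#'
#' Rank-based bins 1..5 with ties broken by position (canonical area
#' order), so bin sizes differ by at most one and binning is idempotent
#' under monotone transforms of the values.
#'
#' @param values numeric vector.
#' @return integer vector of bins in 1..5.
#' @export
quintile_bin <- function(values) {
  n <- length(values)
  r <- rank(values, ties.method = "first")
  as.integer(ceiling(r * 5 / n))
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j) from the least-squares regression of covariate j
#' on the remaining covariates plus an intercept. Exact linear dependence is
#' reported as `Inf` and flagged, not an error.
#'
#' @param covariate_matrix numeric matrix/data.frame, n rows > p + 1, no
#'   constant column.
#' @param threshold flag level (default 5).
#' @return data.frame (class `vif_report`): covariate, vif, flag.
#' @export
vif <- function(covariate_matrix, threshold = 5) {
  X <- as.matrix(covariate_matrix)
  p <- ncol(X)
  if (p < 2L) stop("need at least two covariates")
  if (nrow(X) <= p + 1L) stop("need n rows > n columns + 1")
  if (any(apply(X, 2L, stats::sd) == 0)) stop("constant column")
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("x", seq_len(p))
  out <- vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  structure(
    data.frame(covariate = nm, vif = out, flag = out >= threshold,
               stringsAsFactors = FALSE),
    class = c("vif_report", "data.frame")
  )
}
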