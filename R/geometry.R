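# Planar polygon primitives used by the lattice and synthetic-city modules.
# A "polygon" is a list of one or more rings; a ring is an n x 2 numeric
# matrix of vertices in order, NOT closed (last vertex != first). All
# coordinates are projected planar units (metres).

ring_area <- function(ring) {
  n <- nrow(ring)
  if (n < 3L) return(0)
  x <- ring[, 1L]; y <- ring[, 2L]
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Area of a polygon
#'
#' Shoelace area summed over rings (holes are not supported; every ring
#' contributes positively).
#'
#' @param poly list of rings (n x 2 matrices).
#' @return scalar area in squared map units.
#' @export
polygon_area <- function(poly) sum(vapply(poly, ring_area, numeric(1)))

#' Centroid of a polygon
#'
#' Area-weighted centroid over rings.
#'
#' @param poly list of rings.
#' @return length-2 numeric (x, y).
#' @export
polygon_centroid <- function(poly) {
  cx <- 0; cy <- 0; atot <- 0
  for (ring in poly) {
    n <- nrow(ring)
    if (n < 3L) next
    x <- ring[, 1L]; y <- ring[, 2L]
    j <- c(2:n, 1L)
    cr <- x * y[j] - x[j] * y
    a <- sum(cr) / 2
    if (abs(a) < .Machine$double.eps) next
    cx <- cx + sum((x + x[j]) * cr) / 6
    cy <- cy + sum((y + y[j]) * cr) / 6
    atot <- atot + a
  }
  if (atot == 0) stop("polygon has zero area")
  c(cx, cy) / atot
}

#' Point-in-polygon test
#'
#' Even-odd ray casting over all rings. Points exactly on the boundary are
#' implementation-defined (callers that care use a tie-break).
#'
#' @param pt length-2 numeric.
#' @param poly list of rings.
#' @return logical.
#' @export
point_in_polygon <- function(pt, poly) {
  inside <- FALSE
  for (ring in poly) {
    n <- nrow(ring)
    j <- n
    for (i in seq_len(n)) {
      yi <- ring[i, 2L]; yj <- ring[j, 2L]
      if ((yi > pt[2L]) != (yj > pt[2L])) {
        xint <- ring[j, 1L] + (pt[2L] - yj) / (yi - yj) * (ring[i, 1L] - ring[j, 1L])
        if (pt[1L] < xint) inside <- !inside
      }
      j <- i
    }
  }
  inside
}

# Sutherland-Hodgman clip of a convex/simple ring by the half-plane
# {x : a . x <= b}. Returns the clipped ring (possibly with < 3 vertices).
clip_halfplane <- function(ring, a, b) {
  n <- nrow(ring)
  if (n == 0L) return(ring)
  d <- as.numeric(ring %*% a) - b
  keep <- d <= 0
  out <- vector("list", 2L * n)
  m <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (keep[i]) {
      m <- m + 1L; out[[m]] <- ring[i, ]
      if (!keep[j]) {
        t <- d[i] / (d[i] - d[j])
        m <- m + 1L; out[[m]] <- ring[i, ] + t * (ring[j, ] - ring[i, ])
      }
    } else if (keep[j]) {
      t <- d[i] / (d[i] - d[j])
      m <- m + 1L; out[[m]] <- ring[i, ] + t * (ring[j, ] - ring[i, ])
    }
  }
  if (m == 0L) return(matrix(numeric(0), 0L, 2L))
  do.call(rbind, out[seq_len(m)])
}

#' Voronoi tessellation clipped to a rectangle
#'
#' Computes the Voronoi cell of each seed point as the intersection of
#' perpendicular-bisector half-planes, clipped to the bounding box. Cells
#' partition the box exactly (up to floating point), so polygon areas sum to
#' the box area. O(n k) half-plane clips thanks to a nearest-first pruning
#' rule: once half the distance to the next candidate exceeds the farthest
#' current cell vertex, no further point can cut the cell.
#'
#' @param pts n x 2 matrix of distinct seed points inside `bbox`.
#' @param bbox numeric c(xmin, ymin, xmax, ymax).
#' @return list of n convex rings (matrices), one per seed point, in input
#'   order.
#' @export
voronoi_cells <- function(pts, bbox) {
  stopifnot(is.matrix(pts), ncol(pts) == 2L)
  n <- nrow(pts)
  if (n < 1L) stop("need at least one seed point")
  if (!(bbox[3L] > bbox[1L] && bbox[4L] > bbox[2L])) stop("degenerate bbox")
  rect <- rbind(
    c(bbox[1L], bbox[2L]), c(bbox[3L], bbox[2L]),
    c(bbox[3L], bbox[4L]), c(bbox[1L], bbox[4L])
  )
  D <- as.matrix(stats::dist(pts))
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    ord <- order(D[i, ])
    ord <- ord[ord != i]
    ring <- rect
    for (j in ord) {
      r2 <- max((ring[, 1L] - pts[i, 1L])^2 + (ring[, 2L] - pts[i, 2L])^2)
      if ((D[i, j] / 2)^2 > r2) break
      nv <- pts[j, ] - pts[i, ]
      ring <- clip_halfplane(ring, nv, sum(nv * (pts[i, ] + pts[j, ]) / 2))
      if (nrow(ring) < 3L) break
    }
    cells[[i]] <- ring
  }
  cells
}

# All boundary segments of a polygon as an m x 4 matrix (x1, y1, x2, y2).
polygon_segments <- function(poly) {
  segs <- lapply(poly, function(ring) {
    n <- nrow(ring)
    j <- c(2:n, 1L)
    cbind(ring[, 1L], ring[, 2L], ring[j, 1L], ring[j, 2L])
  })
  do.call(rbind, segs)
}

polygon_bbox <- function(poly) {
  xs <- unlist(lapply(poly, function(r) r[, 1L]))
  ys <- unlist(lapply(poly, function(r) r[, 2L]))
  c(min(xs), min(ys), max(xs), max(ys))
}

# Squared distance from points (px, py) to segments (x1, y1)-(x2, y2),
# vectorised over rows.
pt_seg_dist2 <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  l2 <- dx * dx + dy * dy
  t <- ((px - x1) * dx + (py - y1) * dy) / ifelse(l2 == 0, 1, l2)
  t <- pmin(1, pmax(0, ifelse(l2 == 0, 0, t)))
  qx <- x1 + t * dx; qy <- y1 + t * dy
  (px - qx)^2 + (py - qy)^2
}

# Minimum distance between the boundaries of two polygons: 0 when any
# segment pair properly intersects, else the smallest endpoint-to-segment
# distance over all segment pairs.
boundary_distance <- function(poly_a, poly_b) {
  A <- polygon_segments(poly_a)
  B <- polygon_segments(poly_b)
  idx <- expand.grid(i = seq_len(nrow(A)), j = seq_len(nrow(B)))
  a <- A[idx$i, , drop = FALSE]
  b <- B[idx$j, , drop = FALSE]
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  d1 <- cross(a[, 1L], a[, 2L], a[, 3L], a[, 4L], b[, 1L], b[, 2L])
  d2 <- cross(a[, 1L], a[, 2L], a[, 3L], a[, 4L], b[, 3L], b[, 4L])
  d3 <- cross(b[, 1L], b[, 2L], b[, 3L], b[, 4L], a[, 1L], a[, 2L])
  d4 <- cross(b[, 1L], b[, 2L], b[, 3L], b[, 4L], a[, 3L], a[, 4L])
  proper <- (d1 * d2 < 0) & (d3 * d4 < 0)
  if (any(proper)) return(0)
  d2min <- pmin(
    pt_seg_dist2(a[, 1L], a[, 2L], b[, 1L], b[, 2L], b[, 3L], b[, 4L]),
    pt_seg_dist2(a[, 3L], a[, 4L], b[, 1L], b[, 2L], b[, 3L], b[, 4L]),
    pt_seg_dist2(b[, 1L], b[, 2L], a[, 1L], a[, 2L], a[, 3L], a[, 4L]),
    pt_seg_dist2(b[, 3L], b[, 4L], a[, 1L], a[, 2L], a[, 3L], a[, 4L])
  )
  sqrt(min(d2min))
}

# Length of shared (collinear, overlapping) boundary between two polygons,
# within snap tolerance `tol`. Used for rook contiguity: a positive shared
# length is required, corner contact is not enough.
shared_boundary_length <- function(poly_a, poly_b, tol) {
  A <- polygon_segments(poly_a)
  B <- polygon_segments(poly_b)
  total <- 0
  for (i in seq_len(nrow(A))) {
    ux <- A[i, 3L] - A[i, 1L]; uy <- A[i, 4L] - A[i, 2L]
    len <- sqrt(ux * ux + uy * uy)
    if (len < tol) next
    ux <- ux / len; uy <- uy / len
    # perpendicular distance of B endpoints to the line through segment i
    w1x <- B[, 1L] - A[i, 1L]; w1y <- B[, 2L] - A[i, 2L]
    w2x <- B[, 3L] - A[i, 1L]; w2y <- B[, 4L] - A[i, 2L]
    p1 <- abs(w1x * uy - w1y * ux)
    p2 <- abs(w2x * uy - w2y * ux)
    near <- p1 <= tol & p2 <= tol
    if (!any(near)) next
    t1 <- (w1x * ux + w1y * uy)[near]
    t2 <- (w2x * ux + w2y * uy)[near]
    lo <- pmax(0, pmin(t1, t2))
    hi <- pmin(len, pmax(t1, t2))
    total <- total + sum(pmax(0, hi - lo))
  }
  total
}
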