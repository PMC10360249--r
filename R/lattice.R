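# Areal lattice: polygons + identifiers + a symmetric binary neighbour
# relation. The spatial backbone of the whole pipeline. Areas are always
# stored in lexicographic area_id order; every downstream vector and matrix
# uses this canonical order.

#' Construct an areal lattice
#'
#' Bundles polygons, area identifiers and a symmetric neighbour structure.
#' Areas are reordered lexicographically by `area_id`; all per-area vectors
#' elsewhere in the package follow this order.
#'
#' @param area_ids character vector of unique identifiers.
#' @param polygons list of polygons (each a list of ring matrices), parallel
#'   to `area_ids`.
#' @param nb list of integer neighbour index vectors (indices into the
#'   reordered areas), symmetric, no self-neighbours.
#' @param scheme_label one of `"queen"`, `"rook"`, `"knn"`,
#'   `"distance_band"`, `"queen2"`.
#' @return an object of class `area_lattice` with elements `area_ids`,
#'   `polygons`, `nb`, `scheme`.
#' @export
area_lattice <- function(area_ids, polygons, nb, scheme_label = "queen") {
  area_ids <- as.character(area_ids)
  if (anyDuplicated(area_ids)) stop("duplicate area_id")
  if (length(polygons) != length(area_ids)) stop("polygon count != id count")
  ord <- order(area_ids, method = "radix")
  if (!identical(ord, seq_along(area_ids))) {
    inv <- integer(length(ord)); inv[ord] <- seq_along(ord)
    nb <- lapply(nb[ord], function(v) sort(inv[v]))
    polygons <- polygons[ord]
    area_ids <- area_ids[ord]
  }
  obj <- structure(
    list(area_ids = area_ids, polygons = polygons, nb = nb, scheme = scheme_label),
    class = "area_lattice"
  )
  validate_lattice(obj)
  obj
}

validate_lattice <- function(lattice) {
  n <- length(lattice$area_ids)
  nb <- lattice$nb
  if (length(nb) != n) stop("neighbour list length != number of areas")
  for (i in seq_len(n)) {
    v <- nb[[i]]
    if (any(v == i)) stop("self-neighbour at area ", lattice$area_ids[i])
    if (any(v < 1L | v > n)) stop("neighbour index out of range")
    for (j in v) if (!(i %in% nb[[j]])) {
      stop("asymmetric adjacency between ", lattice$area_ids[i], " and ",
           lattice$area_ids[j])
    }
  }
  invisible(lattice)
}

#' @export
print.area_lattice <- function(x, ...) {
  deg <- lengths(x$nb)
  cat("area_lattice:", length(x$area_ids), "areas,", x$scheme, "contiguity\n")
  cat("  links:", sum(deg) / 2, " islands:", sum(deg == 0L), "\n")
  invisible(x)
}

#' Number of areas in a lattice
#' @param lattice an `area_lattice`.
#' @return integer.
#' @export
n_areas <- function(lattice) length(lattice$area_ids)

#' Build an adjacency structure from polygons
#'
#' Supports the five comparison schemes used in preliminary model selection:
#' queen contiguity (boundaries share at least one point; point contact
#' suffices), rook (positive-length shared boundary), symmetrised k-nearest
#' neighbours of the centroids, a centroid distance band, and second-order
#' queen (queen neighbours plus neighbours-of-neighbours). "Touching" is
#' resolved with an explicit snap tolerance, a fraction of the map diagonal.
#'
#' @param polygons named list of polygons; names are the area ids (or pass
#'   `area_ids`).
#' @param scheme one of `"queen"`, `"rook"`, `"knn"`, `"distance_band"`,
#'   `"queen2"`.
#' @param params list: `k` (knn, default 6), `radius` (distance_band;
#'   default the smallest radius leaving no island), `snap` (relative snap
#'   tolerance, default 1e-6 of the bounding-box diagonal).
#' @param area_ids character ids; defaults to `names(polygons)`.
#' @return an [area_lattice]. Areas with no neighbours trigger a warning
#'   naming them as islands.
#' @export
build_adjacency <- function(polygons, scheme = c("queen", "rook", "knn", "distance_band", "queen2"),
                            params = list(), area_ids = names(polygons)) {
  scheme <- match.arg(scheme)
  if (is.null(area_ids)) area_ids <- sprintf("A%04d", seq_along(polygons))
  n <- length(polygons)
  if (n < 2L) stop("need at least 2 areas")
  for (i in seq_len(n)) {
    p <- polygons[[i]]
    if (!length(p) || any(!vapply(p, function(r) is.matrix(r) && nrow(r) >= 3L, logical(1))) ||
        polygon_area(p) <= 0) {
      stop("invalid or empty geometry for area ", area_ids[i])
    }
  }
  snap <- if (is.null(params$snap)) 1e-6 else params$snap
  boxes <- t(vapply(polygons, polygon_bbox, numeric(4)))
  diag_len <- sqrt((max(boxes[, 3L]) - min(boxes[, 1L]))^2 +
                   (max(boxes[, 4L]) - min(boxes[, 2L]))^2)
  tol <- snap * diag_len

  nb <- switch(scheme,
    queen = contiguity_nb(polygons, boxes, tol, rook = FALSE),
    rook = contiguity_nb(polygons, boxes, tol, rook = TRUE),
    queen2 = second_order_nb(contiguity_nb(polygons, boxes, tol, rook = FALSE)),
    knn = knn_nb(polygons, k = if (is.null(params$k)) 6L else as.integer(params$k)),
    distance_band = band_nb(polygons, radius = params$radius)
  )
  lat <- area_lattice(area_ids, polygons, nb, scheme_label = scheme)
  isl <- which(lengths(lat$nb) == 0L)
  if (length(isl)) {
    warning("island areas (no neighbours): ", paste(lat$area_ids[isl], collapse = ", "))
  }
  lat
}

# Candidate pairs by expanded bounding-box overlap, then exact geometric
# boundary tests.
contiguity_nb <- function(polygons, boxes, tol, rook) {
  n <- length(polygons)
  nb <- lapply(seq_len(n), function(i) integer(0))
  for (i in seq_len(n - 1L)) {
    bi <- boxes[i, ]
    for (j in (i + 1L):n) {
      bj <- boxes[j, ]
      if (bi[1L] > bj[3L] + tol || bj[1L] > bi[3L] + tol ||
          bi[2L] > bj[4L] + tol || bj[2L] > bi[4L] + tol) next
      touch <- if (rook) {
        shared_boundary_length(polygons[[i]], polygons[[j]], tol) > tol
      } else {
        boundary_distance(polygons[[i]], polygons[[j]]) <= tol
      }
      if (touch) {
        nb[[i]] <- c(nb[[i]], j)
        nb[[j]] <- c(nb[[j]], i)
      }
    }
  }
  lapply(nb, sort)
}

second_order_nb <- function(nb) {
  lapply(seq_along(nb), function(i) {
    v <- unique(c(nb[[i]], unlist(nb[nb[[i]]])))
    sort(v[v != i])
  })
}

knn_nb <- function(polygons, k) {
  cent <- t(vapply(polygons, polygon_centroid, numeric(2)))
  n <- nrow(cent)
  if (k >= n) stop("k must be < number of areas")
  D <- as.matrix(stats::dist(cent))
  diag(D) <- Inf
  nb <- lapply(seq_len(n), function(i) sort(order(D[i, ])[seq_len(k)]))
  # symmetrise by union
  for (i in seq_len(n)) for (j in nb[[i]]) {
    if (!(i %in% nb[[j]])) nb[[j]] <- sort(c(nb[[j]], i))
  }
  nb
}

band_nb <- function(polygons, radius = NULL) {
  cent <- t(vapply(polygons, polygon_centroid, numeric(2)))
  D <- as.matrix(stats::dist(cent))
  diag(D) <- Inf
  if (is.null(radius)) radius <- max(apply(D, 1L, min)) * (1 + 1e-9)
  lapply(seq_len(nrow(D)), function(i) sort(which(D[i, ] <= radius)))
}

#' Per-area neighbour counts
#'
#' The `#N(i)` of the conditional autoregressive structure: how many areas
#' share a boundary (under the lattice's scheme) with area i.
#'
#' @param lattice an `area_lattice`.
#' @return named integer vector in canonical area order.
#' @export
neighbor_counts <- function(lattice) {
  stats::setNames(lengths(lattice$nb), lattice$area_ids)
}

#' Sparse binary spatial weights matrix
#'
#' @param lattice an `area_lattice`.
#' @return symmetric sparse 0/1 `Matrix::sparseMatrix` with zero diagonal.
#' @export
adjacency_matrix <- function(lattice) {
  n <- n_areas(lattice)
  deg <- lengths(lattice$nb)
  ii <- rep(seq_len(n), deg)
  jj <- unlist(lattice$nb, use.names = FALSE)
  if (!length(ii)) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n),
                                dimnames = list(lattice$area_ids, lattice$area_ids)))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                       dims = c(n, n),
                       dimnames = list(lattice$area_ids, lattice$area_ids))
}

#' Unique adjacency edges
#'
#' @param lattice an `area_lattice`.
#' @return data.frame with columns `area_id_1`, `area_id_2`, one row per
#'   unordered neighbour pair (id1 < id2).
#' @export
adjacency_edges <- function(lattice) {
  n <- n_areas(lattice)
  rows <- list()
  for (i in seq_len(n)) {
    js <- lattice$nb[[i]]
    js <- js[js > i]
    if (length(js)) rows[[length(rows) + 1L]] <-
      data.frame(area_id_1 = lattice$area_ids[i], area_id_2 = lattice$area_ids[js],
                 stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(area_id_1 = character(0), area_id_2 = character(0)))
  }
  do.call(rbind, rows)
}

#' Export adjacency to disk
#'
#' Writes the unordered edge list as CSV and the full symmetric binary
#' weights matrix in MatrixMarket format.
#'
#' @param lattice an `area_lattice`.
#' @param edge_csv path for the edge-list CSV.
#' @param mm_file optional path for the MatrixMarket sparse matrix.
#' @return invisibly, the edge data.frame.
#' @export
write_adjacency <- function(lattice, edge_csv, mm_file = NULL) {
  edges <- adjacency_edges(lattice)
  utils::write.csv(edges, edge_csv, row.names = FALSE)
  if (!is.null(mm_file)) Matrix::writeMM(adjacency_matrix(lattice), mm_file)
  invisible(edges)
}

#' Moran's I with permutation inference
#'
#' Global spatial autocorrelation over binary (0/1) contiguity weights:
#' \deqn{I = (n/S_0) \sum_{ij} w_{ij}(x_i-\bar x)(x_j-\bar x) / \sum_i (x_i-\bar x)^2}
#' with \eqn{S_0 = \sum_{ij} w_{ij}}. Inference is by random permutation of
#' the values across areas; the two-sided p-value counts permuted statistics
#' at least as far from the analytical null expectation \eqn{E[I]=-1/(n-1)}
#' as the observed one, with the +1 correction
#' \eqn{p = (\#\mathrm{extreme}+1)/(B+1)}.
#'
#' @param values finite numeric vector, one per area, canonical order.
#' @param lattice an `area_lattice`.
#' @param n_permutations number of permutations (>= 99).
#' @param seed optional integer seed for the permutation draw.
#' @return object of class `moran_result`: `statistic`, `expected_value`,
#'   `p_value`, `n_permutations`.
#' @export
morans_i <- function(values, lattice, n_permutations = 999L, seed = NULL) {
  n <- n_areas(lattice)
  if (length(values) != n) stop("values length != number of areas")
  if (any(!is.finite(values))) stop("values must be finite")
  if (stats::var(values) == 0) stop("zero variance: Moran's I undefined for constant input")
  if (n_permutations < 99L) stop("n_permutations must be >= 99")
  W <- adjacency_matrix(lattice)
  s0 <- sum(W)
  if (s0 == 0) stop("lattice has no links")
  moran_stat <- function(z) {
    zc <- z - mean(z)
    (n / s0) * as.numeric(zc %*% (W %*% zc)) / sum(zc^2)
  }
  obs <- moran_stat(values)
  e_i <- -1 / (n - 1)
  if (!is.null(seed)) set.seed(seed)
  perm <- vapply(seq_len(n_permutations),
                 function(b) moran_stat(values[sample.int(n)]), numeric(1))
  extreme <- sum(abs(perm - e_i) >= abs(obs - e_i) - 1e-14)
  structure(
    list(statistic = obs, expected_value = e_i,
         p_value = (extreme + 1) / (n_permutations + 1),
         n_permutations = as.integer(n_permutations)),
    class = "moran_result"
  )
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f), permutation p = %.4f (%d perms)\n",
              x$statistic, x$expected_value, x$p_value, x$n_permutations))
  invisible(x)
}
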