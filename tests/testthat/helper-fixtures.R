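# Fixtures and independent oracles shared across test files. Oracles are
# deliberately written as direct, brute-force implementations so they stay
# independent of the package code paths they check.

# Rectangular grid of unit squares; ids row-major, zero-padded so
# lexicographic order = row-major order.
make_grid_polys <- function(nx, ny, cell = 1) {
  polys <- list()
  for (r in seq_len(ny)) for (c in seq_len(nx)) {
    x0 <- (c - 1) * cell; y0 <- (r - 1) * cell
    ring <- rbind(c(x0, y0), c(x0 + cell, y0), c(x0 + cell, y0 + cell), c(x0, y0 + cell))
    polys[[sprintf("G%02d%02d", r, c)]] <- list(ring)
  }
  polys
}

# Analytic king-move (queen) and orthogonal (rook) neighbour sets on a grid.
grid_analytic_nb <- function(nx, ny, queen = TRUE) {
  idx <- function(r, c) as.integer((r - 1) * nx + c)
  nb <- vector("list", nx * ny)
  for (r in seq_len(ny)) for (c in seq_len(nx)) {
    out <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      if (!queen && abs(dr) + abs(dc) != 1) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= ny && c2 >= 1 && c2 <= nx) out <- c(out, idx(r2, c2))
    }
    nb[[idx(r, c)]] <- sort(out)
  }
  nb
}

# Moran's I by explicit double loop over a dense binary weight matrix.
oracle_moran <- function(values, W) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# Brute-force geometric contiguity oracle for Voronoi lattices: cells of
# seeds i and j touch iff the perpendicular bisector of (p_i, p_j) has a
# nonempty closest-to-{i,j} segment, i.e. some point of the bisector inside
# the bbox is no farther from p_i than from every other seed. Evaluated by
# dense sampling along the bisector.
oracle_voronoi_nb <- function(pts, bbox, n_samp = 2000) {
  n <- nrow(pts)
  nb <- lapply(seq_len(n), function(i) integer(0))
  half_diag <- sqrt((bbox[3] - bbox[1])^2 + (bbox[4] - bbox[2])^2)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m <- (pts[i, ] + pts[j, ]) / 2
    d <- pts[j, ] - pts[i, ]
    t_dir <- c(-d[2], d[1]) / sqrt(sum(d^2))
    ts <- seq(-half_diag, half_diag, length.out = n_samp)
    touch <- FALSE
    for (t in ts) {
      q <- m + t * t_dir
      if (q[1] < bbox[1] || q[1] > bbox[3] || q[2] < bbox[2] || q[2] > bbox[4]) next
      d2 <- colSums((t(pts) - q)^2)
      if (d2[i] <= min(d2[-c(i, j)]) + 1e-9 * half_diag^2) { touch <- TRUE; break }
    }
    if (touch) {
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
  }
  lapply(nb, sort)
}

# Breadth-first search to graph distance r (independent of the package BFS).
oracle_bfs <- function(nb, start, radius) {
  dist <- rep(Inf, length(nb))
  dist[start] <- 0
  frontier <- start
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) for (w in nb[[v]]) {
      if (dist[w] > dist[v] + 1) { dist[w] <- dist[v] + 1; nxt <- c(nxt, w) }
    }
    frontier <- nxt
  }
  sort(which(dist <= radius))
}

# Minimal fit-like object for summary-level functions (draw matrices only).
fake_fit <- function(alpha = NULL, beta = NULL, u = NULL, st = NULL,
                     area_ids = NULL) {
  m <- max(length(alpha), nrow(beta), nrow(u), nrow(st), 1)
  n <- max(ncol(u), ncol(st), 1)
  if (is.null(alpha)) alpha <- numeric(m)
  if (is.null(beta)) beta <- matrix(numeric(0), m, 0)
  if (is.null(u)) u <- matrix(0, m, n)
  if (is.null(st)) st <- matrix(0, m, n)
  if (is.null(area_ids)) area_ids <- sprintf("A%03d", seq_len(ncol(u)))
  structure(list(draws = list(alpha = alpha, beta = beta, u = u, st = st),
                 area_ids = area_ids),
            class = "bym_fit")
}

# Small synthetic city + area table, fitted covariates bound; shared by
# several test files to avoid regenerating.
small_city_table <- function(n_areas = 60, seed = 7) {
  city <- synth_city(n_areas = n_areas, seed = seed)
  tab <- build_area_table(city$lattice, city$populations, city$services,
                          city$zones, covariates = city$covariates)
  list(city = city, tab = tab)
}
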