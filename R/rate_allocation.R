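# Spatial estimation of disease rates: facility-level consultation counts
# are spread over census areas through service zones weighted by population
# share, then converted to per-100 rates. Migrant-exclusive services
# contribute to the overall rate AND to a separate migrant rate with the
# total area population as denominator.

# BFS neighbourhood of graph radius r around i (including i).
graph_neighborhood <- function(nb, i, radius) {
  seen <- i
  frontier <- i
  d <- 0L
  while (d < radius && length(frontier)) {
    nxt <- setdiff(unique(unlist(nb[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
    d <- d + 1L
  }
  sort(seen)
}

# Home area of a planar point; exact-boundary ties go to the containing
# candidate with the lexicographically smallest area_id.
locate_area <- function(pt, lattice, tol = NULL) {
  hits <- which(vapply(lattice$polygons, point_in_polygon, logical(1), pt = pt))
  if (!length(hits)) {
    if (is.null(tol)) {
      box <- t(vapply(lattice$polygons, polygon_bbox, numeric(4)))
      tol <- 1e-9 * sqrt((max(box[, 3]) - min(box[, 1]))^2 +
                         (max(box[, 4]) - min(box[, 2]))^2)
    }
    seg <- c(pt, pt + c(tol / 2, 0))
    near <- which(vapply(lattice$polygons, function(p) {
      boundary_distance(list(matrix(seg, 2L, 2L, byrow = TRUE)), p) <= tol
    }, logical(1)))
    hits <- near
  }
  if (!length(hits)) return(NA_integer_)
  min(hits)  # canonical order is lexicographic, so min index = smallest id
}

#' Build service zones
#'
#' A zone is the set of areas a health service draws consultations from:
#' the service's home area plus queen neighbours up to a graph radius that
#' depends on the complexity tier (default primary = 1, intermediate = 2,
#' high = the whole lattice). Within a zone each member area gets weight
#' population_j / total zone population.
#'
#' @param services data.frame with `service_id`, `x`, `y`, `complexity`
#'   (primary/intermediate/high).
#' @param lattice `area_lattice` in canonical order.
#' @param populations per-area populations (canonical order).
#' @param config list; `radius = c(primary = 1, intermediate = 2)` is the
#'   per-tier graph radius (high-complexity always covers all areas).
#' @return list of zones: each has `service_id`, `member_idx` (integer),
#'   `member_areas` (ids), `weights` (sums to 1).
#' @export
build_service_zones <- function(services, lattice, populations, config = list()) {
  radius <- c(primary = 1L, intermediate = 2L)
  if (!is.null(config$radius)) radius[names(config$radius)] <- config$radius
  n <- n_areas(lattice)
  bad <- setdiff(unique(services$complexity), c("primary", "intermediate", "high"))
  if (length(bad)) stop("unknown complexity tier: ", paste(bad, collapse = ", "))
  lapply(seq_len(nrow(services)), function(k) {
    home <- locate_area(c(services$x[k], services$y[k]), lattice)
    if (is.na(home)) {
      stop("service outside all polygons: ", services$service_id[k])
    }
    idx <- switch(services$complexity[k],
      high = seq_len(n),
      primary = graph_neighborhood(lattice$nb, home, radius[["primary"]]),
      intermediate = graph_neighborhood(lattice$nb, home, radius[["intermediate"]])
    )
    w <- populations[idx] / sum(populations[idx])
    list(service_id = services$service_id[k], member_idx = idx,
         member_areas = lattice$area_ids[idx],
         weights = stats::setNames(w, lattice$area_ids[idx]))
  })
}

#' Allocate consultation counts to areas
#'
#' Each service's consultations are multiplied by its zone weights:
#' cases_j = sum_i consultations_i * w_ij. Totals are conserved exactly.
#'
#' @param services data.frame with `service_id` and `consultations`.
#' @param zones zones from [build_service_zones()] (matched by service_id).
#' @param populations per-area populations (defines the output length).
#' @return numeric vector of (fractional) cases per area.
#' @export
allocate_cases <- function(services, zones, populations) {
  if (any(services$consultations < 0)) stop("negative consultations")
  zid <- vapply(zones, function(z) z$service_id, character(1))
  cases <- numeric(length(populations))
  for (k in seq_len(nrow(services))) {
    z <- zones[[match(services$service_id[k], zid)]]
    if (is.null(z)) stop("no zone for service ", services$service_id[k])
    cases[z$member_idx] <- cases[z$member_idx] + services$consultations[k] * z$weights
  }
  cases
}

#' Build the per-area analysis table
#'
#' Allocates all services to cases, routes migrant-exclusive services into a
#' separate migrant allocation (they contribute to both `cases` and
#' `migrant_cases`), and computes per-100 rates.
#'
#' @param lattice `area_lattice`.
#' @param populations per-area populations.
#' @param services service data.frame (with `migrant_exclusive` logical;
#'   absent means all FALSE).
#' @param zones zones from [build_service_zones()].
#' @param covariates optional per-area covariate matrix/data.frame to bind.
#' @return data.frame (class `area_table`): area_id, population, cases,
#'   migrant_cases, rate, migrant_rate, plus covariate columns.
#' @export
build_area_table <- function(lattice, populations, services, zones, covariates = NULL) {
  migr <- if (is.null(services$migrant_exclusive)) rep(FALSE, nrow(services))
          else as.logical(services$migrant_exclusive)
  cases <- allocate_cases(services, zones, populations)
  migrant_cases <- if (any(migr)) {
    allocate_cases(services[migr, , drop = FALSE], zones, populations)
  } else numeric(length(populations))
  tab <- compute_rates(data.frame(
    area_id = lattice$area_ids,
    population = populations,
    cases = cases,
    migrant_cases = migrant_cases,
    stringsAsFactors = FALSE
  ))
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates, optional = TRUE)
    cv$area_id <- NULL
    # a measured covariate sharing a computed column's name (e.g. a
    # synthetic migrant_rate) wins; the allocation-derived column is kept
    # under an _allocated suffix
    clash <- intersect(names(cv), names(tab))
    for (nm in clash) {
      names(tab)[names(tab) == nm] <- paste0(nm, "_allocated")
    }
    tab <- cbind(tab, cv)
  }
  class(tab) <- unique(c("area_table", class(tab)))
  tab
}

#' Compute per-100 rates
#'
#' Adds/refreshes `rate = 100 * cases / population` and `migrant_rate =
#' 100 * migrant_cases / population` (total population denominator; no
#' migrant-specific population estimate exists).
#'
#' @param area_table data.frame with `population`, `cases` and optionally
#'   `migrant_cases`.
#' @return the table with `rate` and `migrant_rate` columns, class
#'   `area_table`.
#' @export
compute_rates <- function(area_table) {
  if (any(area_table$population <= 0)) stop("zero or negative population")
  if (any(area_table$cases < 0)) stop("negative cases")
  area_table$rate <- 100 * area_table$cases / area_table$population
  mc <- if (is.null(area_table$migrant_cases)) 0 else area_table$migrant_cases
  area_table$migrant_rate <- 100 * mc / area_table$population
  class(area_table) <- unique(c("area_table", class(area_table)))
  area_table
}

#' Round fractional cases for the Poisson likelihood
#'
#' Fractional allocated cases are kept throughout; only at the fitting
#' boundary are they rounded, half-to-even (banker's rounding, base
#' `round`).
#'
#' @param cases numeric vector.
#' @return integer vector.
#' @export
round_cases <- function(cases) as.integer(round(cases))
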