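# Synthetic-city generator: Voronoi lattice, populations, spatially
# structured covariates, pollutant stations, health services and
# facility-level consultation counts drawn from the same Poisson/BYM model
# the inference module fits. Ground truth is retained so downstream stages
# can be validated by parameter recovery.

# Derive a stage seed from the single global seed; stays below 2^31.
stage_seed <- function(seed, k) {
  as.integer((as.double(seed) * 31 + as.double(k) * 100003) %% 2147483629)
}

#' Generate a synthetic areal lattice
#'
#' Voronoi tessellation of uniform seed points clipped to a rectangle, with
#' queen contiguity. Polygons partition the box exactly, so areas sum to the
#' box area. Deterministic given `seed`.
#'
#' @param n_areas number of areas (>= 4).
#' @param bbox numeric c(xmin, ymin, xmax, ymax) in metres. The default is a
#'   7.2 km square, matching ~460 urban census sections of ~114,000 m2 each.
#' @param seed integer seed.
#' @return an [area_lattice] with queen adjacency; area ids are zero-padded
#'   (`"S0001"`, ...) so lexicographic and numeric order coincide.
#' @export
generate_lattice <- function(n_areas, bbox = c(0, 0, 7200, 7200), seed = 1L) {
  if (n_areas < 4L) stop("n_areas must be >= 4")
  if (!(bbox[3L] > bbox[1L] && bbox[4L] > bbox[2L])) stop("degenerate bbox")
  set.seed(stage_seed(seed, 1L))
  pts <- cbind(runif(n_areas, bbox[1L], bbox[3L]),
               runif(n_areas, bbox[2L], bbox[4L]))
  cells <- voronoi_cells(pts, bbox)
  width <- max(4L, nchar(as.character(n_areas)))
  ids <- sprintf(paste0("S%0", width, "d"), seq_len(n_areas))
  polys <- lapply(cells, function(ring) list(ring))
  names(polys) <- ids
  build_adjacency(polys, scheme = "queen")
}

# Connected components of the neighbour graph (BFS).
graph_components <- function(nb) {
  n <- length(nb)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in nb[[v]]) if (comp[w] == 0L) {
        comp[w] <- cur
        queue <- c(queue, w)
      }
    }
  }
  comp
}

# Eigendecomposition of the graph Laplacian, cached per call site.
icar_eigen <- function(lattice) {
  W <- as.matrix(adjacency_matrix(lattice))
  L <- diag(rowSums(W)) - W
  eigen(L, symmetric = TRUE)
}

#' Sample from the intrinsic CAR distribution
#'
#' Exact draw from the improper ICAR law under the sum-to-zero constraint:
#' zero mass is placed on the null eigenvector of the graph Laplacian L, and
#' the remaining spectral coordinates are independent Gaussians with
#' variance \eqn{1/(\tau \lambda_k)}. The resulting vector has density
#' proportional to \eqn{\exp(-\tau/2 \sum_{i \sim j} (st_i - st_j)^2)} on
#' the sum-to-zero subspace, which implies the conditional law
#' \eqn{st_i | st_{-i} \sim N(\mathrm{mean}(st_{N(i)}), 1/(\tau \#N(i)))}.
#'
#' @param lattice a connected `area_lattice`.
#' @param tau_st precision (> 0).
#' @param seed optional integer seed.
#' @param n_draws number of draws.
#' @param eig optional precomputed `eigen()` of the Laplacian (for repeated
#'   draws on one lattice).
#' @return numeric vector (or `n_draws` x n matrix), each draw summing to 0.
#' @export
sample_icar <- function(lattice, tau_st, seed = NULL, n_draws = 1L, eig = NULL) {
  if (tau_st <= 0) stop("tau_st must be > 0")
  comp <- graph_components(lattice$nb)
  if (max(comp) > 1L) {
    stop("lattice is disconnected (", max(comp), " components); ",
         "exact ICAR sampling needs one component - apply per-component ",
         "sum-to-zero constraints instead")
  }
  if (is.null(eig)) eig <- icar_eigen(lattice)
  n <- n_areas(lattice)
  lam <- eig$values
  pos <- lam > max(lam) * 1e-10
  if (!is.null(seed)) set.seed(seed)
  V <- eig$vectors[, pos, drop = FALSE]
  sds <- 1 / sqrt(tau_st * lam[pos])
  out <- matrix(0, n_draws, n)
  for (d in seq_len(n_draws)) {
    z <- rnorm(sum(pos)) * sds
    st <- as.numeric(V %*% z)
    out[d, ] <- st - mean(st)
  }
  if (n_draws == 1L) drop(out) else out
}

#' Default ground-truth scenario parameters
#'
#' Effect sizes mirror the published relative risks used as recovery
#' targets: exp(beta) = 1.25 per unit migrant consultation rate, 1.08 per
#' percentage point of population under 15, 1.04 per poverty-index unit;
#' the remaining covariates are null. The citywide baseline rate is 0.25
#' consultations per person-year (the published mean, 25.77 per 100).
#'
#' @return list of generator parameters (betas, target rate, precisions,
#'   covariate ranges, service counts and attraction weights).
#' @export
default_city_params <- function() {
  list(
    beta = c(migrant_rate = log(1.25), pop_under15 = log(1.08),
             imp = log(1.04), pea = 0, pop_over65 = 0),
    target_rate = 0.25,
    tau_u = 25,          # sd 0.2 on the log scale
    tau_st = 4,
    covariate_ranges = list(
      migrant_rate = c(0, 13),     # consultations per 100 persons
      pop_under15 = c(10, 30),     # %
      imp = c(0, 86),              # multidimensional poverty index
      pea = c(35, 70),             # economically-active index
      pop_over65 = c(5, 25)        # %
    ),
    covariate_smooth_tau = 1,      # ICAR precision of the covariate fields
    covariate_noise_sd = 0.4,      # white-noise sd added to the unit-sd field
    pop_meanlog = log(1500),
    pop_sdlog = 0.5,
    pop_floor = 50,
    n_stations = 3L,
    pm10_range = c(40, 50),        # ug/m3, station annual means
    n_primary = NULL,        # default: ~1 primary facility per 8 areas
    n_intermediate = NULL,   # default: ~1 per 50 areas
    n_high = 2L,
    # ARI consultations are overwhelmingly primary-care visits
    attraction = c(primary = 10, intermediate = 3, high = 1),
    null_effects = FALSE   # TRUE zeroes u and st (calibration scenario)
  )
}

#' Simulate per-area populations
#'
#' Lognormal sizes (median ~1,500 persons), rounded, floored.
#'
#' @param n number of areas.
#' @param seed integer seed.
#' @param meanlog,sdlog,floor lognormal parameters and minimum size.
#' @return integer vector of populations >= floor.
#' @export
simulate_populations <- function(n, seed, meanlog = log(1500), sdlog = 0.5, floor = 50) {
  set.seed(seed)
  pmax(as.integer(round(rlnorm(n, meanlog, sdlog))), as.integer(floor))
}

#' Simulate spatially autocorrelated covariates
#'
#' Each covariate is a unit-variance ICAR field plus white noise, affinely
#' mapped onto a stated range, giving positive Moran's I by construction.
#'
#' @param lattice connected `area_lattice`.
#' @param seed integer seed.
#' @param ranges named list of c(lo, hi) ranges per covariate.
#' @param smooth_tau ICAR precision of the smooth component.
#' @param noise_sd white-noise sd relative to the unit-sd smooth field.
#' @return numeric matrix, one named column per covariate.
#' @export
simulate_covariates <- function(lattice, seed, ranges, smooth_tau = 1, noise_sd = 0.4) {
  n <- n_areas(lattice)
  eig <- icar_eigen(lattice)
  X <- matrix(NA_real_, n, length(ranges),
              dimnames = list(lattice$area_ids, names(ranges)))
  for (k in seq_along(ranges)) {
    f <- sample_icar(lattice, smooth_tau, seed = stage_seed(seed, 10L + k), eig = eig)
    f <- f / stats::sd(f)
    set.seed(stage_seed(seed, 40L + k))
    f <- f + rnorm(n, 0, noise_sd)
    lo <- ranges[[k]][1L]; hi <- ranges[[k]][2L]
    X[, k] <- lo + (f - min(f)) / (max(f) - min(f)) * (hi - lo)
  }
  X
}

#' Simulate pollutant monitoring stations
#'
#' @param lattice `area_lattice` (stations placed uniformly in its bbox,
#'   away from the edges).
#' @param seed integer seed.
#' @param n_stations number of stations.
#' @param value_range c(lo, hi) for station annual-mean PM10.
#' @return data.frame(station_id, x, y, pm10).
#' @export
simulate_stations <- function(lattice, seed, n_stations = 3L, value_range = c(40, 50)) {
  box <- polygon_bbox(unlist(lattice$polygons, recursive = FALSE))
  set.seed(seed)
  mx <- 0.15 * (box[3L] - box[1L]); my <- 0.15 * (box[4L] - box[2L])
  data.frame(
    station_id = sprintf("ST%02d", seq_len(n_stations)),
    x = runif(n_stations, box[1L] + mx, box[3L] - mx),
    y = runif(n_stations, box[2L] + my, box[4L] - my),
    pm10 = runif(n_stations, value_range[1L], value_range[2L])
  )
}

#' Simulate per-area consultation counts
#'
#' Poisson draws under the generating model:
#' \eqn{y_i \sim Poisson(pop_i \exp(\alpha + X_i \beta + u_i + st_i))}.
#'
#' @param truth a `city_truth` list with `alpha`, `beta`, `u`, `st` (beta
#'   names must match covariate columns).
#' @param populations per-area positive populations.
#' @param covariates per-area covariate matrix.
#' @param seed integer seed.
#' @return integer vector of counts.
#' @export
simulate_counts <- function(truth, populations, covariates, seed) {
  n <- length(populations)
  beta <- truth$beta[colnames(covariates)]
  if (anyNA(beta)) stop("truth$beta missing for some covariate columns")
  eta <- truth$alpha + as.numeric(covariates %*% beta) + truth$u + truth$st
  lam <- populations * exp(eta)
  if (any(!is.finite(lam))) stop("non-finite linear predictor")
  set.seed(seed)
  rpois(n, lam)
}

#' Simulate health services
#'
#' Places primary, intermediate and high-complexity services at the
#' centroids of home areas sampled with population weight (without
#' replacement while possible). Consultation counts start at zero and are
#' filled by [scatter_cases_to_services()].
#'
#' @param lattice `area_lattice`.
#' @param populations per-area populations.
#' @param n_primary,n_intermediate,n_high service counts per tier (at least
#'   one high-complexity service is required).
#' @param seed integer seed.
#' @return data.frame(service_id, x, y, complexity, consultations,
#'   migrant_exclusive).
#' @export
simulate_services <- function(lattice, populations, n_primary = 20L,
                              n_intermediate = 6L, n_high = 2L, seed = 1L) {
  if (n_high < 1L) stop("at least one high-complexity service is required")
  n <- n_areas(lattice)
  total <- n_primary + n_intermediate + n_high
  set.seed(seed)
  homes <- sample.int(n, total, replace = total > n, prob = populations)
  cent <- t(vapply(lattice$polygons, polygon_centroid, numeric(2)))
  tiers <- c(rep("primary", n_primary), rep("intermediate", n_intermediate),
             rep("high", n_high))
  data.frame(
    service_id = sprintf("HS%03d", seq_len(total)),
    x = cent[homes, 1L], y = cent[homes, 2L],
    complexity = tiers,
    consultations = 0L,
    migrant_exclusive = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Scatter per-area cases to services
#'
#' Each area's cases are split multinomially among the services whose zone
#' covers it, with probability proportional to the service attraction
#' weight. Total consultations equal total cases exactly.
#'
#' @param counts integer per-area cases (canonical area order).
#' @param zones list of service zones from [build_service_zones()].
#' @param seed integer seed.
#' @param attraction named per-service weights (default equal).
#' @return named integer vector of consultations per service_id.
#' @export
scatter_cases_to_services <- function(counts, zones, seed, attraction = NULL) {
  n <- length(counts)
  svc_ids <- vapply(zones, function(z) z$service_id, character(1))
  if (is.null(attraction)) attraction <- stats::setNames(rep(1, length(zones)), svc_ids)
  cover <- lapply(seq_len(n), function(i) integer(0))
  for (k in seq_along(zones)) {
    for (i in zones[[k]]$member_idx) cover[[i]] <- c(cover[[i]], k)
  }
  uncovered <- which(lengths(cover) == 0L & counts > 0)
  if (length(uncovered)) {
    stop("areas covered by no service zone: index ", paste(uncovered, collapse = ", "))
  }
  out <- stats::setNames(numeric(length(zones)), svc_ids)
  set.seed(seed)
  for (i in seq_len(n)) {
    if (counts[i] == 0L) next
    ks <- cover[[i]]
    if (length(ks) == 1L) {
      out[ks] <- out[ks] + counts[i]
    } else {
      pr <- attraction[svc_ids[ks]]
      out[ks] <- out[ks] + drop(rmultinom(1L, counts[i], pr))
    }
  }
  storage.mode(out) <- "integer"
  out
}

#' Generate a full synthetic city
#'
#' Orchestrates lattice, populations, covariates, stations, BYM random
#' effects, per-area counts, services and the scattering of cases to
#' services. The intercept is calibrated so the realised citywide expected
#' rate equals `params$target_rate` exactly given the drawn effects.
#' Everything is reproducible bit-for-bit from `(params, seed)`.
#'
#' @param n_areas number of areas (default 460).
#' @param seed single global integer seed; stage seeds are derived from it.
#' @param params list as from [default_city_params()]; partial overrides are
#'   merged over the defaults.
#' @param bbox bounding box passed to [generate_lattice()].
#' @return object of class `synthetic_city`: `lattice`, `populations`,
#'   `covariates`, `stations`, `services`, `zones`, `area_counts`, `truth`
#'   (class `city_truth`: alpha, beta, tau_u, tau_st, u, st,
#'   expected_rate).
#' @export
synth_city <- function(n_areas = 460L, seed = 1L, params = list(),
                       bbox = c(0, 0, 7200, 7200)) {
  p <- utils::modifyList(default_city_params(), params)
  lattice <- generate_lattice(n_areas, bbox = bbox, seed = seed)
  n <- n_areas(lattice)
  populations <- simulate_populations(n, stage_seed(seed, 2L),
                                      p$pop_meanlog, p$pop_sdlog, p$pop_floor)
  covariates <- simulate_covariates(lattice, seed, p$covariate_ranges,
                                    p$covariate_smooth_tau, p$covariate_noise_sd)
  stations <- simulate_stations(lattice, stage_seed(seed, 3L),
                                p$n_stations, p$pm10_range)
  set.seed(stage_seed(seed, 4L))
  u <- rnorm(n, 0, 1 / sqrt(p$tau_u))
  st <- sample_icar(lattice, p$tau_st, seed = stage_seed(seed, 5L))
  if (isTRUE(p$null_effects)) {
    # null scenario: no area-level excess risk beyond the covariates
    u[] <- 0
    st[] <- 0
  }
  beta <- p$beta[colnames(covariates)]
  beta[is.na(beta)] <- 0
  names(beta) <- colnames(covariates)
  xb <- as.numeric(covariates %*% beta)
  alpha <- log(p$target_rate) - log(sum(populations * exp(xb + u + st)) / sum(populations))
  truth <- structure(
    list(alpha = alpha, beta = beta, tau_u = p$tau_u, tau_st = p$tau_st,
         u = u, st = st, expected_rate = exp(alpha + xb + u + st)),
    class = "city_truth"
  )
  area_counts <- simulate_counts(truth, populations, covariates,
                                 seed = stage_seed(seed, 6L))
  if (is.null(p$n_primary)) p$n_primary <- max(2L, as.integer(round(n / 8)))
  if (is.null(p$n_intermediate)) p$n_intermediate <- max(1L, as.integer(round(n / 50)))
  services <- simulate_services(lattice, populations, p$n_primary,
                                p$n_intermediate, p$n_high, stage_seed(seed, 7L))
  zones <- build_service_zones(services, lattice, populations)
  attraction <- stats::setNames(p$attraction[services$complexity], services$service_id)
  services$consultations <- as.integer(
    scatter_cases_to_services(area_counts, zones, stage_seed(seed, 8L), attraction)
  )
  structure(
    list(lattice = lattice, populations = populations, covariates = covariates,
         stations = stations, services = services, zones = zones,
         area_counts = area_counts, truth = truth, seed = seed),
    class = "synthetic_city"
  )
}

#' @export
print.synthetic_city <- function(x, ...) {
  cat("synthetic_city:", n_areas(x$lattice), "areas,",
      nrow(x$services), "services, total cases", sum(x$area_counts), "\n")
  invisible(x)
}

#' Write a synthetic city to disk
#'
#' Writes areas GeoJSON (with population property), covariates CSV,
#' services CSV, stations CSV, and the ground truth as JSON (for tests).
#'
#' @param city a `synthetic_city`.
#' @param dir output directory (created if needed).
#' @return invisibly, a named vector of file paths.
#' @export
write_city <- function(city, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    areas = file.path(dir, "areas.geojson"),
    covariates = file.path(dir, "covariates.csv"),
    services = file.path(dir, "services.csv"),
    stations = file.path(dir, "stations.csv"),
    truth = file.path(dir, "truth.json")
  )
  props <- data.frame(area_id = city$lattice$area_ids,
                      population = city$populations)
  write_areas_geojson(city$lattice$polygons, paths[["areas"]], properties = props)
  cov <- data.frame(area_id = city$lattice$area_ids, city$covariates,
                    check.names = FALSE)
  utils::write.csv(cov, paths[["covariates"]], row.names = FALSE)
  utils::write.csv(city$services, paths[["services"]], row.names = FALSE)
  utils::write.csv(city$stations, paths[["stations"]], row.names = FALSE)
  tr <- city$truth
  jsonlite::write_json(
    list(alpha = tr$alpha, beta = as.list(tr$beta), tau_u = tr$tau_u,
         tau_st = tr$tau_st, u = tr$u, st = tr$st,
         area_counts = city$area_counts),
    paths[["truth"]], auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
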