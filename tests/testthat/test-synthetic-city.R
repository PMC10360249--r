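# Synthetic-city generator: determinism, ICAR law, count model, services.

test_that("generate_lattice partitions the bbox and is deterministic", {
  lat <- generate_lattice(4, bbox = c(0, 0, 1, 1), seed = 1)
  expect_equal(sum(vapply(lat$polygons, polygon_area, numeric(1))), 1,
               tolerance = 1e-9)
  f1 <- tempfile(fileext = ".geojson"); f2 <- tempfile(fileext = ".geojson")
  write_areas_geojson(generate_lattice(12, seed = 5)$polygons, f1)
  write_areas_geojson(generate_lattice(12, seed = 5)$polygons, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical
  expect_error(generate_lattice(3), "n_areas")
  expect_error(generate_lattice(10, bbox = c(0, 0, 0, 1)), "degenerate")
})

test_that("generated lattices have no islands at realistic sizes", {
  lat <- generate_lattice(120, seed = 7)
  expect_true(all(neighbor_counts(lat) >= 1))
})

test_that("sample_icar satisfies the sum-to-zero constraint", {
  lat <- build_adjacency(make_grid_polys(4, 4), "queen")
  st <- sample_icar(lat, tau_st = 2, seed = 1)
  expect_lt(abs(sum(st)), 1e-10)
  # two areas: st1 = -st2
  two <- build_adjacency(make_grid_polys(2, 1), "rook")
  st2 <- sample_icar(two, tau_st = 1, seed = 3)
  expect_equal(st2[1], -st2[2], tolerance = 1e-12)
})

test_that("sample_icar obeys the conditional law E = neighbour mean, V = 1/(tau #N)", {
  lat <- build_adjacency(make_grid_polys(5, 5), "queen")
  tau <- 4
  M <- 4000
  draws <- sample_icar(lat, tau, seed = 2, n_draws = M)
  deg <- unname(neighbor_counts(lat))
  # identity for the constrained ICAR: e_i = st_i - neighbour mean has
  # mean 0 and variance exactly 1/(tau * #N(i)) (Cov(Q st) = Q)
  for (i in c(1, 7, 13, 25)) {
    e <- draws[, i] - rowMeans(draws[, lat$nb[[i]], drop = FALSE])
    v_true <- 1 / (tau * deg[i])
    expect_lt(abs(mean(e)), 4 * sqrt(v_true / M))
    expect_equal(var(e), v_true, tolerance = 0.1)
  }
})

test_that("icar marginal variance scales as 1/tau", {
  lat <- build_adjacency(make_grid_polys(5, 4), "queen")
  d1 <- sample_icar(lat, 1, seed = 4, n_draws = 1000)
  d2 <- sample_icar(lat, 2, seed = 4, n_draws = 1000)
  ratio <- mean(d1^2) / mean(d2^2)
  expect_equal(ratio, 2, tolerance = 0.1)
})

test_that("sample_icar rejects disconnected lattices", {
  polys <- make_grid_polys(2, 2)
  polys[["Z_far"]] <- list(rbind(c(9, 9), c(10, 9), c(10, 10), c(9, 10)))
  lat <- suppressWarnings(build_adjacency(polys, "queen"))
  expect_error(sample_icar(lat, 1), "disconnected")
})

test_that("simulate_counts has the right mean structure", {
  n <- 460
  lat <- generate_lattice(n, seed = 3)
  pop <- simulate_populations(n, seed = 8)
  X <- matrix(0, n, 1, dimnames = list(NULL, "x"))
  truth <- list(alpha = log(0.25), beta = c(x = 0), u = rep(0, n), st = rep(0, n))
  y <- simulate_counts(truth, pop, X, seed = 9)
  rate <- sum(y) / sum(pop)
  se <- sqrt(0.25 / sum(pop))
  expect_lt(abs(rate - 0.25), 3 * se)
  # offset linearity: doubling populations doubles expected counts
  y2 <- simulate_counts(truth, 2 * pop, X, seed = 10)
  expect_equal(sum(y2) / sum(y), 2, tolerance = 0.02)
  # error path
  truth$alpha <- Inf
  expect_error(simulate_counts(truth, pop, X, seed = 1), "non-finite")
})

test_that("counts increase with covariates at published effect sizes", {
  # one effect at a time so the binned means are not confounded by the
  # other (correlated-by-chance) covariate fields
  city <- synth_city(n_areas = 200, seed = 12)
  betas <- c(migrant_rate = log(1.25), pop_under15 = log(1.08), imp = log(1.04))
  for (v in names(betas)) {
    truth <- city$truth
    truth$beta[] <- 0
    truth$beta[v] <- betas[[v]]
    truth$u[] <- 0; truth$st[] <- 0
    y <- simulate_counts(truth, city$populations, city$covariates,
                         seed = 99 + match(v, names(betas)))
    rate <- y / city$populations
    x <- city$covariates[, v]
    bins <- cut(x, quantile(x, c(0, .25, .5, .75, 1)), include.lowest = TRUE)
    mr <- tapply(log(rate + 1e-9), bins, mean)
    expect_true(all(diff(mr) > 0))  # monotone increasing across bins
  }
})

test_that("synthetic covariates are spatially autocorrelated", {
  set.seed(0)
  med <- median(replicate(5, {
    seed <- sample.int(1000, 1)
    city <- synth_city(n_areas = 80, seed = seed)
    mean(apply(city$covariates, 2, function(x)
      morans_i(x, city$lattice, n_permutations = 99, seed = 1)$statistic))
  }))
  expect_gt(med, 0.2)
})

test_that("scatter conserves cases and splits evenly between equal services", {
  # one service covering all areas takes every case
  lat <- build_adjacency(make_grid_polys(3, 3), "queen")
  pop <- rep(100, 9)
  svc <- data.frame(service_id = "HS001",
                    x = polygon_centroid(lat$polygons[[5]])[1],
                    y = polygon_centroid(lat$polygons[[5]])[2],
                    complexity = "high", consultations = 0L,
                    migrant_exclusive = FALSE)
  zones <- build_service_zones(svc, lat, pop)
  counts <- c(3L, 0L, 5L, 2L, 8L, 1L, 0L, 4L, 6L)
  got <- scatter_cases_to_services(counts, zones, seed = 1)
  expect_equal(unname(got), sum(counts))
  # two identical services, equal attraction: ~50/50 in expectation
  svc2 <- rbind(svc, transform(svc, service_id = "HS002"))
  zones2 <- build_service_zones(svc2, lat, pop)
  tot <- replicate(200, {
    s <- scatter_cases_to_services(counts, zones2, seed = sample.int(1e6, 1))
    s[["HS001"]]
  })
  expect_equal(mean(tot) / sum(counts), 0.5, tolerance = 0.05)
})

test_that("full city generation is reproducible bit-for-bit and conserves cases", {
  c1 <- synth_city(n_areas = 50, seed = 3)
  c2 <- synth_city(n_areas = 50, seed = 3)
  expect_identical(c1, c2)
  expect_identical(sum(c1$services$consultations), sum(c1$area_counts))
  expect_lt(abs(sum(c1$truth$st)), 1e-9)
  expect_true(all(c1$populations >= 50))
  expect_true(all(apply(c1$covariates, 2, sd) > 0))
  # intercept calibration: citywide expected rate equals the target exactly
  expect_equal(sum(c1$populations * c1$truth$expected_rate) / sum(c1$populations),
               default_city_params()$target_rate, tolerance = 1e-12)
})

test_that("write_city emits readable files", {
  city <- synth_city(n_areas = 30, seed = 6)
  dir <- tempfile()
  paths <- write_city(city, dir)
  expect_true(all(file.exists(paths)))
  gj <- read_areas_geojson(paths[["areas"]])
  expect_identical(names(gj$polygons), city$lattice$area_ids)
  expect_equal(as.numeric(gj$properties$population), as.numeric(city$populations))
  cov <- read.csv(paths[["covariates"]], check.names = FALSE)
  expect_equal(as.matrix(cov[, colnames(city$covariates)]),
               unname(city$covariates), ignore_attr = TRUE)
  tr <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(tr$alpha, city$truth$alpha, tolerance = 1e-12)
})
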