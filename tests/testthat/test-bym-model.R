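# BYM model: log joint density, MCMC fit, summaries, DIC, variance fraction.

toy_data <- function(n = 9, seed = 1) {
  lat <- build_adjacency(make_grid_polys(3, 3), "queen")
  set.seed(seed)
  pop <- sample(500:2000, n)
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  y <- rpois(n, pop * 0.2)
  list(y = y, population = pop, X = X, lattice = lat)
}

test_that("log joint: Poisson term matches a scalar log-pmf oracle", {
  d <- toy_data()
  spec <- bym_model_spec(c("x1", "x2"), use_u = FALSE, use_st = FALSE)
  params <- list(alpha = log(0.2), beta = c(0, 0), u = rep(0, 9), st = rep(0, 9),
                 log_tau_u = 0, log_tau_st = 0)
  lj <- bym_log_joint(params, d, spec)
  eta <- log(0.2) + log(d$population)
  oracle <- sum(vapply(seq_len(9), function(i)
    dpois(d$y[i], exp(eta[i]), log = TRUE), numeric(1))) +
    dnorm(log(0.2), 0, sqrt(1000), log = TRUE) +
    2 * dnorm(0, 0, sqrt(1000), log = TRUE)
  expect_equal(lj, oracle, tolerance = 1e-10)
})

test_that("log joint: ICAR pairwise term is invariant to constant shifts of st", {
  d <- toy_data(seed = 2)
  spec <- bym_model_spec(c("x1", "x2"))
  set.seed(3)
  st <- rnorm(9); st <- st - mean(st)
  params <- list(alpha = -1.5, beta = c(0.1, -0.2), u = rnorm(9, 0, 0.1),
                 st = st, log_tau_u = log(4), log_tau_st = log(2))
  base <- bym_log_joint(params, d, spec)
  # shift st by c and alpha by -c: eta unchanged, ICAR pair term unchanged,
  # only the alpha prior moves
  cshift <- 0.8
  p2 <- params; p2$st <- st + cshift; p2$alpha <- params$alpha - cshift
  delta_prior <- dnorm(p2$alpha, 0, sqrt(1000), log = TRUE) -
    dnorm(params$alpha, 0, sqrt(1000), log = TRUE)
  expect_equal(bym_log_joint(p2, d, spec) - base, delta_prior, tolerance = 1e-10)
})

test_that("log joint: doubling tau_st changes the ICAR term by its closed form", {
  d <- toy_data(seed = 4)
  spec <- bym_model_spec(c("x1", "x2"))
  set.seed(5)
  st <- rnorm(9); st <- st - mean(st)
  params <- list(alpha = -1, beta = c(0, 0), u = rep(0, 9), st = st,
                 log_tau_u = log(1), log_tau_st = log(3))
  p2 <- params; p2$log_tau_st <- log(6)
  pairs <- 0
  for (i in 1:9) for (j in d$lattice$nb[[i]]) if (j > i)
    pairs <- pairs + (st[i] - st[j])^2
  a <- spec$prior_st["shape"]; b <- spec$prior_st["rate"]
  hyper_delta <- (a * log(6) - b * 6) - (a * log(3) - b * 3)
  expected <- (9 - 1) / 2 * log(2) - (6 - 3) / 2 * pairs + unname(hyper_delta)
  expect_equal(bym_log_joint(p2, d, spec) - bym_log_joint(params, d, spec),
               expected, tolerance = 1e-10)
  expect_error(
    bym_log_joint(params, list(y = d$y[1:4], population = d$population[1:4],
                               X = d$X[1:4, ], lattice = d$lattice), spec),
    "mismatch")
})

test_that("intercept-only fit matches the conjugate Poisson-Gamma oracle", {
  lat <- generate_lattice(50, seed = 8)
  set.seed(9)
  pop <- sample(800:1500, 50, replace = TRUE)
  tab <- data.frame(area_id = lat$area_ids, population = pop,
                    cases = rpois(50, pop * 0.3))
  spec <- bym_model_spec(character(0), use_u = FALSE, use_st = FALSE)
  fit <- bym_fit(tab, lat, spec, n_chains = 2, n_draws = 1000,
                 burnin = 1000, thin = 1, seed = 2)
  rate_draws <- exp(fit$draws$alpha)
  analytic <- sum(tab$cases) / sum(tab$population)
  expect_lt(abs(mean(rate_draws) - analytic), 2 * sd(rate_draws))
})

test_that("fit recovers a known coefficient and the u/st machinery converges", {
  cc <- small_city_table(n_areas = 120, seed = 13)
  tab <- cc$tab; tab$cases <- cc$city$area_counts
  spec <- bym_model_spec(c("migrant_rate", "pop_under15", "imp"))
  fit <- suppressWarnings(
    bym_fit(tab, cc$city$lattice, spec, n_chains = 2, n_draws = 800,
            burnin = 6000, thin = 6, seed = 3))
  s <- summarize_fixed_effects(fit, include_intercept = FALSE)
  expect_lt(abs(s$mean[s$parameter == "migrant_rate"] - 1.25), 0.05)
  expect_true(s$credible[s$parameter == "migrant_rate"])
  # retained draws respect the sum-to-zero constraint
  expect_lt(max(abs(rowSums(fit$draws$st))), 1e-8)
  # fixed effects converge
  expect_lt(max(fit$rhat[c("alpha", "beta_migrant_rate")]), 1.1)
  # DIC is finite and p_d positive
  expect_true(is.finite(fit$dic) && fit$p_d > 0)
})

test_that("fit is invariant to the input ordering of areas", {
  city <- synth_city(n_areas = 30, seed = 21)
  tab <- build_area_table(city$lattice, city$populations, city$services,
                          city$zones, covariates = city$covariates)
  spec <- bym_model_spec(c("migrant_rate", "imp"))
  args <- list(n_chains = 1L, n_draws = 100L, burnin = 200L, thin = 1L, seed = 5L)
  f1 <- suppressWarnings(do.call(bym_fit, c(list(tab, city$lattice, spec), args)))
  # rebuild the lattice from a shuffled polygon list; canonical ordering
  # must give the identical object, hence identical draws
  set.seed(1)
  shuffle <- sample(n_areas(city$lattice))
  lat2 <- build_adjacency(city$lattice$polygons[shuffle], "queen")
  f2 <- suppressWarnings(do.call(bym_fit, c(list(tab, lat2, spec), args)))
  expect_identical(f1$draws, f2$draws)
})

test_that("fit input validation", {
  d <- toy_data()
  tab <- data.frame(area_id = d$lattice$area_ids, population = d$population,
                    cases = d$y)
  expect_error(bym_fit(tab[1:5, ], d$lattice), "rows")
  tab2 <- tab; tab2$population[1] <- 0
  expect_error(bym_fit(tab2, d$lattice), "population")
  expect_error(bym_fit(tab, d$lattice, bym_model_spec("nope")), "absent")
})

test_that("summarize_fixed_effects: degenerate, symmetric and lognormal cases", {
  # all draws equal log 2
  f <- fake_fit(alpha = rep(0, 100),
                beta = matrix(log(2), 100, 1, dimnames = list(NULL, "b")))
  s <- summarize_fixed_effects(f, include_intercept = FALSE)
  expect_equal(s$mean, 2); expect_equal(s$q2.5, 2); expect_equal(s$q97.5, 2)
  expect_true(s$credible)
  # symmetric draws straddle 1
  set.seed(7)
  f2 <- fake_fit(beta = matrix(c(rnorm(5000)), ncol = 1,
                               dimnames = list(NULL, "b")))
  s2 <- summarize_fixed_effects(f2, include_intercept = FALSE)
  expect_false(s2$credible)
  # N(0.07, 0.01^2) draws: lognormal quantile oracle
  set.seed(8)
  f3 <- fake_fit(beta = matrix(rnorm(20000, 0.07, 0.01), ncol = 1,
                               dimnames = list(NULL, "b")))
  s3 <- summarize_fixed_effects(f3, include_intercept = FALSE)
  expect_equal(s3$mean, exp(0.07 + 0.01^2 / 2), tolerance = 1e-3)
  expect_equal(s3$q2.5, exp(qnorm(0.025, 0.07, 0.01)), tolerance = 1e-3)
  expect_equal(s3$q97.5, exp(qnorm(0.975, 0.07, 0.01)), tolerance = 1e-3)
})

test_that("dic: single draw gives p_D 0; toy deviance matches scalar oracle", {
  y <- c(3L, 0L, 7L)
  eta1 <- matrix(log(c(2.5, 1.2, 6.0)), 1)
  d1 <- dic_from_draws(y, eta1)
  dev_oracle <- -2 * sum(dpois(y, exp(eta1[1, ]), log = TRUE))
  expect_equal(unname(d1["p_d"]), 0, tolerance = 1e-10)
  expect_equal(unname(d1["dic"]), dev_oracle, tolerance = 1e-10)
  # hand-computed two-draw toy
  eta2 <- rbind(eta1[1, ], log(c(3.5, 0.8, 7.5)))
  d2 <- dic_from_draws(y, eta2)
  devs <- apply(eta2, 1, function(e) -2 * sum(dpois(y, exp(e), log = TRUE)))
  dhat <- -2 * sum(dpois(y, exp(colMeans(eta2)), log = TRUE))
  expect_equal(unname(d2["dic"]), mean(devs) + (mean(devs) - dhat),
               tolerance = 1e-10)
  expect_equal(poisson_deviance(y, eta1[1, ]), dev_oracle, tolerance = 1e-12)
})

test_that("spatial variance fraction hits its boundary cases", {
  set.seed(10)
  u <- matrix(rnorm(500), 50)
  st <- matrix(rnorm(500), 50)
  expect_equal(spatial_variance_fraction(fake_fit(u = u, st = 0 * st)), 0)
  expect_equal(spatial_variance_fraction(fake_fit(u = 0 * u, st = st)), 1)
  frac <- spatial_variance_fraction(fake_fit(u = u, st = st))
  expect_true(frac > 0 && frac < 1)
})

test_that("spec constructor validates hyperparameters", {
  expect_error(bym_model_spec(prior_u = c(0, 1)), "0")
  sp <- bym_model_spec("x", prior_u = c(shape = 1, rate = 0.1))
  expect_equal(unname(sp$prior_u), c(1, 0.1))
})
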