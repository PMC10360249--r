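# Bayesian hierarchical Poisson model with Besag-York-Mollie (convolution)
# random effects:
#   y_i ~ Poisson(lambda_i),
#   log(lambda_i) = alpha + X_i beta + log(pop_i) + u_i + st_i,
#   u_i ~ N(0, 1/tau_u) iid, st ~ ICAR(tau_st) with a sum-to-zero constraint,
#   log tau ~ logGamma (equivalently tau ~ Gamma), alpha/beta Gaussian.
# Inference is adaptive Metropolis-within-Gibbs (src/bym_mcmc.cpp): the model
# density, not the engine, is the contract.

#' Specify a BYM model
#'
#' @param covariates character vector of covariate column names in the area
#'   table (may be empty for an intercept-only model).
#' @param prior_u c(shape, rate) of the logGamma prior on the unstructured
#'   log-precision (default the winning pair of the preliminary comparison,
#'   logGamma(0.1, 0.1)).
#' @param prior_st c(shape, rate) for the structured log-precision (default
#'   logGamma(0.001, 0.001)).
#' @param prior_fixed_precision Gaussian precision of the zero-mean prior on
#'   the intercept and coefficients (default 0.001).
#' @param adjacency_scheme label recorded for bookkeeping (the lattice
#'   passed to [bym_fit()] carries the actual structure).
#' @param use_u,use_st include the unstructured / structured random effect.
#' @return list of class `bym_model_spec`.
#' @export
bym_model_spec <- function(covariates = character(0),
                           prior_u = c(shape = 0.1, rate = 0.1),
                           prior_st = c(shape = 0.001, rate = 0.001),
                           prior_fixed_precision = 0.001,
                           adjacency_scheme = "queen",
                           use_u = TRUE, use_st = TRUE) {
  stopifnot(all(prior_u > 0), all(prior_st > 0), prior_fixed_precision > 0)
  structure(
    list(covariates = as.character(covariates),
         prior_u = c(shape = unname(prior_u[1]), rate = unname(prior_u[2])),
         prior_st = c(shape = unname(prior_st[1]), rate = unname(prior_st[2])),
         prior_fixed_precision = prior_fixed_precision,
         adjacency_scheme = adjacency_scheme,
         use_u = isTRUE(use_u), use_st = isTRUE(use_st)),
    class = "bym_model_spec"
  )
}

# logGamma(a, b) density of theta = log(tau) (so tau ~ Gamma(a, b)):
# a*theta - b*exp(theta) + a*log(b) - lgamma(a).
log_gamma_logdens <- function(theta, shape, rate) {
  shape * theta - rate * exp(theta) + shape * log(rate) - lgamma(shape)
}

icar_pair_sum <- function(st, nb) {
  s <- 0
  for (i in seq_along(nb)) {
    js <- nb[[i]]
    js <- js[js > i]
    if (length(js)) s <- s + sum((st[i] - st[js])^2)
  }
  s
}

#' Log joint density of the BYM model
#'
#' Sum of the Poisson log-likelihood, the Gaussian log-density of `u`, the
#' improper ICAR log-density of `st` (rank n-1:
#' \eqn{(n-1)/2 \log\tau_{st} - \tau_{st}/2 \sum_{i\sim j}(st_i-st_j)^2},
#' constant terms dropped), the logGamma hyperpriors on the two
#' log-precisions and the Gaussian priors on the fixed effects. Adding a
#' constant to `st` leaves the ICAR pairwise term unchanged -- the intrinsic
#' invariance that makes the sum-to-zero constraint necessary.
#'
#' @param params list with `alpha`, `beta`, `u`, `st`, `log_tau_u`,
#'   `log_tau_st`.
#' @param data list with `y` (counts), `population`, `X` (matrix, may have 0
#'   columns), `lattice`.
#' @param spec a [bym_model_spec()].
#' @return finite scalar for finite inputs.
#' @export
bym_log_joint <- function(params, data, spec) {
  n <- length(data$y)
  if (length(data$lattice$nb) != n) stop("mismatched adjacency")
  X <- data$X
  xb <- if (length(spec$covariates)) as.numeric(X %*% params$beta) else 0
  eta <- params$alpha + xb + log(data$population) + params$u + params$st
  ll <- sum(stats::dpois(data$y, exp(eta), log = TRUE))
  out <- ll
  pv <- 1 / spec$prior_fixed_precision
  out <- out + stats::dnorm(params$alpha, 0, sqrt(pv), log = TRUE) +
    sum(stats::dnorm(params$beta, 0, sqrt(pv), log = TRUE))
  if (spec$use_u) {
    tau_u <- exp(params$log_tau_u)
    out <- out + sum(stats::dnorm(params$u, 0, 1 / sqrt(tau_u), log = TRUE)) +
      log_gamma_logdens(params$log_tau_u, spec$prior_u["shape"], spec$prior_u["rate"])
  }
  if (spec$use_st) {
    tau_st <- exp(params$log_tau_st)
    out <- out + (n - 1) / 2 * params$log_tau_st -
      tau_st / 2 * icar_pair_sum(params$st, data$lattice$nb) +
      log_gamma_logdens(params$log_tau_st, spec$prior_st["shape"], spec$prior_st["rate"])
  }
  unname(out)
}

# Split-R-hat (Gelman et al.): chains are split in half, between/within
# variance ratio.
split_rhat <- function(draws, chain_id) {
  halves <- list()
  for (ch in unique(chain_id)) {
    x <- draws[chain_id == ch]
    m <- length(x) %/% 2L
    halves <- c(halves, list(x[seq_len(m)], x[(m + 1L):(2L * m)]))
  }
  mns <- vapply(halves, mean, numeric(1))
  vrs <- vapply(halves, stats::var, numeric(1))
  m <- length(halves); nn <- length(halves[[1L]])
  W <- mean(vrs)
  B <- nn * stats::var(mns)
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Fit the BYM model by MCMC
#'
#' Counts are taken from `area_table$cases`, rounded half-to-even at this
#' boundary; the offset is `log(population)`. Covariates enter unscaled
#' (per-unit coefficients); internally the design is standardised for
#' sampler mixing and draws are mapped back, with the Gaussian fixed-effect
#' prior applied on the original per-unit scale. The structured effect is
#' recentred to sum to zero every sweep, its mean transferred into the
#' intercept. Split-R-hat is reported for the intercept, coefficients and
#' log-precisions, with a warning above 1.05.
#'
#' @param area_table data.frame with `cases`, `population` and the
#'   covariates named in `spec` (canonical area order).
#' @param lattice `area_lattice` aligned with the table.
#' @param spec a [bym_model_spec()].
#' @param n_chains,n_draws chains and retained draws per chain.
#' @param burnin,thin burn-in iterations and thinning interval.
#' @param seed integer seed; chain c uses a seed derived from it.
#' @return object of class `bym_fit`: `draws` (alpha, beta on the per-unit
#'   scale, u, st, tau_u, tau_st, deviance), `chain_id`, `rhat`, `dic`,
#'   `p_d`, `spatial_variance_fraction`, `y`, `population`, `X`,
#'   `area_ids`, `spec`, `eta_hat`.
#' @export
bym_fit <- function(area_table, lattice, spec = bym_model_spec(),
                    n_chains = 4L, n_draws = 1000L, burnin = 8000L,
                    thin = 8L, seed = 1L) {
  n <- n_areas(lattice)
  if (nrow(area_table) != n) stop("area_table rows != lattice areas")
  if (any(area_table$population <= 0)) stop("zero-population area")
  y <- round_cases(area_table$cases)
  if (any(y < 0)) stop("negative counts")
  miss <- setdiff(spec$covariates, names(area_table))
  if (length(miss)) stop("covariates absent from area table: ", paste(miss, collapse = ", "))
  p <- length(spec$covariates)
  X <- if (p) as.matrix(area_table[, spec$covariates, drop = FALSE]) else
    matrix(numeric(0), n, 0L)
  if (p) {
    x_mean <- colMeans(X); x_sd <- apply(X, 2L, stats::sd)
    if (any(x_sd == 0)) stop("constant covariate column")
    Xs <- sweep(sweep(X, 2L, x_mean), 2L, x_sd, "/")
  } else {
    x_mean <- numeric(0); x_sd <- numeric(0)
    Xs <- X
  }
  if (spec$use_st && max(graph_components(lattice$nb)) > 1L) {
    warning("lattice is disconnected; the sum-to-zero constraint is applied globally")
  }
  pv <- 1 / spec$prior_fixed_precision
  # prior variance on the standardised scale keeps the stated per-unit prior
  prior_var <- c(pv, pv * x_sd^2)

  res <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(stage_seed(seed, 500L + ch))
    res[[ch]] <- bym_chain_cpp(
      as.integer(y), log(area_table$population), Xs, lattice$nb,
      prior_var,
      spec$prior_u["shape"], spec$prior_u["rate"],
      spec$prior_st["shape"], spec$prior_st["rate"],
      spec$use_u, spec$use_st,
      as.integer(burnin), as.integer(n_draws), as.integer(thin)
    )
  }
  chain_id <- rep(seq_len(n_chains), each = n_draws)
  beta_s <- do.call(rbind, lapply(res, `[[`, "beta"))
  alpha_s <- unlist(lapply(res, `[[`, "alpha"))
  # back-transform to the per-unit scale
  if (p) {
    beta <- sweep(beta_s, 2L, x_sd, "/")
    alpha <- alpha_s - as.numeric(beta %*% x_mean)
    colnames(beta) <- spec$covariates
  } else {
    beta <- beta_s
    alpha <- alpha_s
  }
  draws <- list(
    alpha = alpha,
    beta = beta,
    u = do.call(rbind, lapply(res, `[[`, "u")),
    st = do.call(rbind, lapply(res, `[[`, "st")),
    tau_u = unlist(lapply(res, `[[`, "tau_u")),
    tau_st = unlist(lapply(res, `[[`, "tau_st")),
    deviance = unlist(lapply(res, `[[`, "deviance"))
  )
  colnames(draws$u) <- colnames(draws$st) <- lattice$area_ids

  rhat <- c(alpha = split_rhat(draws$alpha, chain_id))
  if (p) for (j in seq_len(p)) {
    rhat[paste0("beta_", spec$covariates[j])] <- split_rhat(draws$beta[, j], chain_id)
  }
  if (spec$use_u) rhat["log_tau_u"] <- split_rhat(log(draws$tau_u), chain_id)
  if (spec$use_st) rhat["log_tau_st"] <- split_rhat(log(draws$tau_st), chain_id)
  if (any(rhat > 1.05, na.rm = TRUE)) {
    warning("split-R-hat > 1.05 for: ",
            paste(names(rhat)[rhat > 1.05], collapse = ", "),
            " - increase burnin/draws")
  }

  eta_hat <- Reduce(`+`, lapply(res, `[[`, "eta_hat")) / n_chains
  d_bar <- mean(draws$deviance)
  d_hat <- poisson_deviance(y, eta_hat)
  p_d <- d_bar - d_hat

  fit <- structure(
    list(draws = draws, chain_id = chain_id, n_chains = n_chains,
         n_draws = n_draws, rhat = rhat,
         dic = d_bar + p_d, p_d = p_d, d_bar = d_bar,
         y = y, population = area_table$population, X = X,
         area_ids = lattice$area_ids, spec = spec, eta_hat = eta_hat,
         seed = seed),
    class = "bym_fit"
  )
  fit$spatial_variance_fraction <- spatial_variance_fraction(fit)
  fit
}

#' @export
print.bym_fit <- function(x, ...) {
  cat(sprintf("bym_fit: %d areas, %d covariates, %d chains x %d draws\n",
              length(x$y), ncol(x$X), x$n_chains, x$n_draws))
  cat(sprintf("  DIC %.2f (p_D %.1f), spatial variance fraction %.3f, max R-hat %.3f\n",
              x$dic, x$p_d, x$spatial_variance_fraction, max(x$rhat)))
  invisible(x)
}

#' Poisson deviance at a linear predictor
#'
#' \eqn{D = -2 \sum_i [y_i \eta_i - e^{\eta_i} - \log y_i!]} where eta
#' includes the offset.
#'
#' @param y counts.
#' @param eta per-area log-mean (offset included).
#' @return scalar deviance.
#' @export
poisson_deviance <- function(y, eta) {
  -2 * sum(y * eta - exp(eta) - lgamma(y + 1))
}

#' DIC from a fit
#'
#' \eqn{DIC = \bar D + p_D}, \eqn{p_D = \bar D - D(\hat\eta)} with
#' \eqn{\hat\eta} the posterior mean of the per-area linear predictor.
#' Differences below 2 between models are treated as equivalent fit.
#'
#' @param fit a `bym_fit`.
#' @return named numeric c(dic, p_d).
#' @export
dic <- function(fit) c(dic = fit$dic, p_d = fit$p_d)

#' DIC from raw draws
#'
#' Same definition as [dic()] but computed from an explicit matrix of
#' linear-predictor draws; used for toy-model verification.
#'
#' @param y counts.
#' @param eta_draws draws x areas matrix of linear predictors.
#' @return named numeric c(dic, p_d).
#' @export
dic_from_draws <- function(y, eta_draws) {
  devs <- apply(eta_draws, 1L, function(e) poisson_deviance(y, e))
  d_bar <- mean(devs)
  p_d <- d_bar - poisson_deviance(y, colMeans(eta_draws))
  c(dic = d_bar + p_d, p_d = p_d)
}

#' Exponentiated fixed-effect summaries
#'
#' Applies exp() per draw, then summarises: posterior mean, equal-tailed
#' 95% credible interval, and a credibility flag that is TRUE when the
#' interval excludes 1.
#'
#' @param fit a `bym_fit`.
#' @param include_intercept include the exp(alpha) row (default TRUE).
#' @return data.frame: parameter, mean, q2.5, q97.5, credible.
#' @export
summarize_fixed_effects <- function(fit, include_intercept = TRUE) {
  cols <- list()
  if (include_intercept) cols[["(Intercept)"]] <- fit$draws$alpha
  for (nm in colnames(fit$draws$beta)) cols[[nm]] <- fit$draws$beta[, nm]
  rows <- lapply(names(cols), function(nm) {
    e <- exp(cols[[nm]])
    q <- unname(stats::quantile(e, c(0.025, 0.975)))
    data.frame(parameter = nm, mean = mean(e), q2.5 = q[1L], q97.5 = q[2L],
               credible = q[1L] > 1 || q[2L] < 1, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Posterior summary table (natural scale)
#'
#' @param object a `bym_fit`.
#' @param ... unused.
#' @return data.frame: parameter, mean, sd, q2.5, q97.5, rhat.
#' @export
summary.bym_fit <- function(object, ...) {
  scal <- c(list(alpha = object$draws$alpha),
            if (ncol(object$draws$beta)) {
              stats::setNames(
                lapply(seq_len(ncol(object$draws$beta)),
                       function(j) object$draws$beta[, j]),
                paste0("beta_", colnames(object$draws$beta)))
            },
            if (object$spec$use_u) list(log_tau_u = log(object$draws$tau_u)),
            if (object$spec$use_st) list(log_tau_st = log(object$draws$tau_st)))
  rows <- lapply(names(scal), function(nm) {
    x <- scal[[nm]]
    q <- unname(stats::quantile(x, c(0.025, 0.975)))
    data.frame(parameter = nm, mean = mean(x), sd = stats::sd(x),
               q2.5 = q[1L], q97.5 = q[2L],
               rhat = unname(object$rhat[nm]), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fraction of between-area variance that is spatially structured
#'
#' \eqn{V_{st}/(V_{st}+V_u)} where the V's are empirical variances, across
#' areas, of the posterior-mean structured and unstructured effect vectors.
#'
#' @param fit a `bym_fit`.
#' @return scalar between 0 and 1.
#' @export
spatial_variance_fraction <- function(fit) {
  v_st <- stats::var(colMeans(fit$draws$st))
  v_u <- stats::var(colMeans(fit$draws$u))
  if (v_st + v_u == 0) return(0)
  v_st / (v_st + v_u)
}
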