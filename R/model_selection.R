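# Preliminary model selection: DIC comparison of candidate priors or
# adjacency structures, and the backward-elimination sensitivity analysis
# (drop covariates whose credible interval crosses 1, then re-add
# combinations of the dropped ones and check conclusions).

#' Default candidate hyperprior pairs
#'
#' Four non-informative logGamma (shape, rate) pairs applied symmetrically
#' to both log-precisions; the published analysis names only its winner, so
#' this menu is a configurable stand-in.
#'
#' @return named list of c(shape, rate) pairs.
#' @export
default_prior_candidates <- function() {
  list(
    "logGamma(1,0.01)"      = c(shape = 1,     rate = 0.01),
    "logGamma(0.1,0.1)"     = c(shape = 0.1,   rate = 0.1),
    "logGamma(0.001,0.001)" = c(shape = 0.001, rate = 0.001),
    "logGamma(1,0.1)"       = c(shape = 1,     rate = 0.1)
  )
}

#' Compare candidate models by DIC
#'
#' Fits every candidate on the same data with the same seed policy and
#' returns a ledger sorted by DIC. Candidates within 2 DIC units of the best
#' are flagged as equivalent fit. A candidate whose split-R-hat exceeds
#' `rhat_limit` is recorded as not converged and excluded from "chosen".
#'
#' @param area_table per-area data.
#' @param candidates named list; each element is a list with `spec` (a
#'   [bym_model_spec()]) and `lattice` (an `area_lattice`), so candidates
#'   may vary priors, covariates or adjacency.
#' @param seed integer seed shared across candidates.
#' @param n_chains,n_draws,burnin,thin MCMC settings per fit.
#' @param dic_equivalence DIC difference treated as equivalent (default 2).
#' @param rhat_limit convergence gate (default 1.1).
#' @return object of class `selection_ledger`: data.frame with candidate,
#'   dic, p_d, delta_dic, equivalent, converged, chosen; fits attached as
#'   attribute `fits`.
#' @export
compare_candidates <- function(area_table, candidates, seed = 1L,
                               n_chains = 2L, n_draws = 500L, burnin = 1000L,
                               thin = 1L, dic_equivalence = 2,
                               rhat_limit = 1.1) {
  if (length(candidates) < 2L) stop("need at least 2 candidates")
  if (is.null(names(candidates))) names(candidates) <- paste0("cand", seq_along(candidates))
  fits <- lapply(candidates, function(cand) {
    bym_fit(area_table, cand$lattice, cand$spec, n_chains = n_chains,
            n_draws = n_draws, burnin = burnin, thin = thin, seed = seed)
  })
  led <- data.frame(
    candidate = names(candidates),
    dic = vapply(fits, function(f) f$dic, numeric(1)),
    p_d = vapply(fits, function(f) f$p_d, numeric(1)),
    converged = vapply(fits, function(f) max(f$rhat, na.rm = TRUE) <= rhat_limit, logical(1)),
    stringsAsFactors = FALSE
  )
  led <- led[order(led$dic), ]
  best <- led$dic[which(led$converged)[1L]]
  if (is.na(best)) best <- led$dic[1L]
  led$delta_dic <- led$dic - best
  led$equivalent <- led$delta_dic < dic_equivalence
  led$chosen <- FALSE
  pick <- which(led$converged)[1L]
  if (!is.na(pick)) led$chosen[pick] <- TRUE
  rownames(led) <- NULL
  attr(led, "fits") <- fits
  class(led) <- c("selection_ledger", "data.frame")
  led
}

# Two-sided posterior tail probability of a coefficient crossing 0; larger
# means less credible.
beta_null_overlap <- function(b) 2 * min(mean(b > 0), mean(b < 0))

#' Backward elimination of non-credible covariates
#'
#' Starting from the full model, iteratively refits after dropping the
#' least credible covariate (the one whose 95% credible interval crosses 1
#' with the largest two-sided posterior tail probability at the null) until
#' every remaining covariate is credible. Dropped covariates are then
#' re-added in all combinations (capped at 2^5 subsets) on top of the
#' reduced model to check whether conclusions change, and the reduced model
#' is compared with the full model by DIC with the < 2 equivalence rule.
#'
#' @param area_table per-area data.
#' @param lattice `area_lattice`.
#' @param full_spec the full [bym_model_spec()].
#' @param seed integer seed (same policy for every refit).
#' @param n_chains,n_draws,burnin,thin MCMC settings per fit.
#' @param dic_equivalence DIC equivalence band (default 2).
#' @param max_readd cap on dropped covariates considered for re-addition.
#' @return list of class `elimination_ledger`: `steps` (one row per fit in
#'   the elimination path), `retained`, `dropped`, `readditions` (one row
#'   per re-added subset), `dic_full`, `dic_reduced`, `dic_difference`,
#'   `equivalent_fit` (TRUE means the reduced model "does not account for a
#'   better model fit"), and the final `fit`.
#' @export
backward_eliminate <- function(area_table, lattice, full_spec, seed = 1L,
                               n_chains = 2L, n_draws = 500L, burnin = 1000L,
                               thin = 1L, dic_equivalence = 2, max_readd = 5L) {
  fit_with <- function(covs) {
    sp <- full_spec
    sp$covariates <- covs
    bym_fit(area_table, lattice, sp, n_chains = n_chains, n_draws = n_draws,
            burnin = burnin, thin = thin, seed = seed)
  }
  covs <- full_spec$covariates
  fit <- fit_with(covs)
  dic_full <- fit$dic
  steps <- list(data.frame(step = 0L, covariates = paste(covs, collapse = "+"),
                           dropped = NA_character_, dic = fit$dic,
                           stringsAsFactors = FALSE))
  dropped <- character(0)
  step <- 0L
  while (length(covs)) {
    summ <- summarize_fixed_effects(fit, include_intercept = FALSE)
    if (all(summ$credible)) break
    overlap <- vapply(summ$parameter,
                      function(nm) beta_null_overlap(fit$draws$beta[, nm]),
                      numeric(1))
    overlap[summ$credible] <- -Inf  # never remove a credible covariate
    worst <- summ$parameter[which.max(overlap)]
    covs <- setdiff(covs, worst)
    dropped <- c(dropped, worst)
    step <- step + 1L
    if (!length(covs)) {
      warning("all covariates eliminated; returning intercept-only model")
      fit <- fit_with(character(0))
      steps[[length(steps) + 1L]] <- data.frame(
        step = step, covariates = "(intercept only)", dropped = worst,
        dic = fit$dic, stringsAsFactors = FALSE)
      break
    }
    fit <- fit_with(covs)
    steps[[length(steps) + 1L]] <- data.frame(
      step = step, covariates = paste(covs, collapse = "+"), dropped = worst,
      dic = fit$dic, stringsAsFactors = FALSE)
  }
  # re-add all combinations of the dropped covariates
  readd <- NULL
  dr <- utils::head(dropped, max_readd)
  if (length(dr)) {
    subsets <- unlist(lapply(seq_along(dr), function(k) {
      asplit(utils::combn(dr, k), 2L)
    }), recursive = FALSE)
    readd <- do.call(rbind, lapply(subsets, function(ss) {
      f2 <- fit_with(c(covs, ss))
      s2 <- summarize_fixed_effects(f2, include_intercept = FALSE)
      data.frame(
        added = paste(ss, collapse = "+"),
        dic = f2$dic,
        readded_credible = any(s2$credible[s2$parameter %in% ss]),
        retained_all_credible = all(s2$credible[s2$parameter %in% covs]),
        stringsAsFactors = FALSE
      )
    }))
  }
  diff <- fit$dic - dic_full
  structure(
    list(steps = do.call(rbind, steps), retained = covs, dropped = dropped,
         readditions = readd, dic_full = dic_full, dic_reduced = fit$dic,
         dic_difference = diff,
         equivalent_fit = abs(diff) < dic_equivalence,
         fit = fit),
    class = "elimination_ledger"
  )
}

#' @export
print.elimination_ledger <- function(x, ...) {
  cat("backward elimination:", nrow(x$steps) - 1L, "step(s); retained:",
      if (length(x$retained)) paste(x$retained, collapse = ", ") else "(none)", "\n")
  cat(sprintf("  DIC full %.2f vs reduced %.2f (diff %.2f): %s\n",
              x$dic_full, x$dic_reduced, x$dic_difference,
              if (x$equivalent_fit) "equivalent fit (reduced model does not account for a better fit)"
              else "fits differ"))
  invisible(x)
}

#' Write a selection ledger
#'
#' @param ledger a `selection_ledger` or `elimination_ledger`.
#' @param csv_path output CSV (the DIC table / elimination steps).
#' @param json_path optional JSON with the full ledger.
#' @return invisibly, `ledger`.
#' @export
write_ledger <- function(ledger, csv_path, json_path = NULL) {
  tab <- if (inherits(ledger, "selection_ledger")) as.data.frame(ledger) else ledger$steps
  utils::write.csv(tab, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    obj <- if (inherits(ledger, "selection_ledger")) as.data.frame(ledger) else
      ledger[setdiff(names(ledger), "fit")]
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(ledger)
}
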