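# Risk mapping: per-area relative risks from the marginal random effects
# (covariate contributions excluded, so the RR is relative to the citywide
# baseline after adjustment), exceedance probabilities used as a decision
# rule, and high-high / low-low cluster labels.

#' Per-area relative risk summaries
#'
#' Per draw, \eqn{RR_i = \exp(u_i + st_i)}; the summaries are the posterior
#' mean and the equal-tailed 95% interval. Because st sums to zero and u is
#' centred, the log-RRs are centred around the citywide baseline.
#'
#' @param fit a `bym_fit`.
#' @return data.frame: area_id, rr_mean, rr_q2.5, rr_q97.5.
#' @export
area_relative_risk <- function(fit) {
  rr <- exp(fit$draws$u + fit$draws$st)
  q <- apply(rr, 2L, stats::quantile, probs = c(0.025, 0.975))
  data.frame(
    area_id = fit$area_ids,
    rr_mean = colMeans(rr),
    rr_q2.5 = q[1L, ],
    rr_q97.5 = q[2L, ],
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Exceedance probabilities
#'
#' Posterior probability that the area relative risk exceeds a threshold:
#' the fraction of draws with \eqn{RR_i > t}. Monotone nonincreasing in t.
#'
#' @param fit a `bym_fit`.
#' @param threshold positive risk threshold (default 1.5, the published
#'   decision rule).
#' @return named numeric vector of probabilities between 0 and 1.
#' @export
exceedance_probability <- function(fit, threshold = 1.5) {
  if (threshold <= 0) stop("threshold must be > 0")
  rr <- exp(fit$draws$u + fit$draws$st)
  stats::setNames(colMeans(rr > threshold), fit$area_ids)
}

#' High-high / low-low cluster labels
#'
#' An area is a hotspot when its own relative risk exceeds 1 and ALL of its
#' neighbours' do too ("surrounded by" read strictly; `rule = "fraction"`
#' with `frac` relaxes this to a share of neighbours); coldspots mirror
#' this below 1. Areas above 1 that are not hotspots are labelled
#' `elevated`. Islands (no neighbours) are never hot- or coldspots.
#' Perimeter areas are judged over their existing neighbours only.
#'
#' @param rr_mean per-area posterior-mean relative risk (canonical order).
#' @param lattice `area_lattice`.
#' @param rule `"all"` (default) or `"fraction"`.
#' @param frac neighbour share required under `rule = "fraction"`.
#' @return character vector with levels hotspot/coldspot/elevated/none.
#' @export
detect_clusters <- function(rr_mean, lattice, rule = c("all", "fraction"), frac = 0.5) {
  rule <- match.arg(rule)
  n <- n_areas(lattice)
  if (length(rr_mean) != n) stop("rr_mean length != number of areas")
  labels <- rep("none", n)
  for (i in seq_len(n)) {
    js <- lattice$nb[[i]]
    hi <- rr_mean[i] > 1
    if (length(js) == 0L) {
      if (hi) labels[i] <- "elevated"
      next
    }
    share_hi <- mean(rr_mean[js] > 1)
    share_lo <- mean(rr_mean[js] < 1)
    need <- if (rule == "all") 1 else frac
    if (hi && share_hi >= need) {
      labels[i] <- "hotspot"
    } else if (hi) {
      labels[i] <- "elevated"
    } else if (rr_mean[i] < 1 && share_lo >= need) {
      labels[i] <- "coldspot"
    }
  }
  labels
}

#' Full per-area risk summary
#'
#' Combines relative risks, the exceedance probability at the decision
#' threshold, and cluster labels.
#'
#' @param fit a `bym_fit`.
#' @param lattice `area_lattice` the fit was built on.
#' @param threshold exceedance threshold (default 1.5).
#' @param rule,frac passed to [detect_clusters()].
#' @return data.frame (class `risk_summary`): area_id, rr_mean, rr_q2.5,
#'   rr_q97.5, prob_exceed, label.
#' @export
risk_summary <- function(fit, lattice, threshold = 1.5, rule = "all", frac = 0.5) {
  rr <- area_relative_risk(fit)
  rr$prob_exceed <- unname(exceedance_probability(fit, threshold))
  rr$label <- detect_clusters(rr$rr_mean, lattice, rule = rule, frac = frac)
  class(rr) <- c("risk_summary", "data.frame")
  rr
}

#' Write the risk map
#'
#' Writes the risk table as CSV and, if polygons are supplied, a GeoJSON
#' FeatureCollection with the risk fields as feature properties for
#' choropleth rendering.
#'
#' @param risk a [risk_summary()] data.frame.
#' @param csv_path output CSV path.
#' @param lattice optional `area_lattice` for the GeoJSON.
#' @param geojson_path optional output GeoJSON path.
#' @return invisibly, `risk`.
#' @export
write_risk_map <- function(risk, csv_path, lattice = NULL, geojson_path = NULL) {
  utils::write.csv(risk, csv_path, row.names = FALSE)
  if (!is.null(lattice) && !is.null(geojson_path)) {
    stopifnot(identical(risk$area_id, lattice$area_ids))
    write_areas_geojson(lattice$polygons, geojson_path, properties = risk)
  }
  invisible(risk)
}
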