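# Pipeline orchestration: a plain-text config (YAML-subset key/value file),
# seven stages (simulate, allocate, covariates, screen, fit, map, select),
# timestamped stage-tagged logging, and a manifest sufficient to re-execute
# the identical run. All geometry is assumed to share one projected planar
# CRS declared in the config; no reprojection is attempted.

#' Default pipeline configuration
#'
#' @return nested list of defaults; see the fields in the source. Thresholds
#'   follow the published decision rules: exceedance RR > 1.5 reported at
#'   probability >= 0.8, VIF >= 5 flags collinearity, DIC differences < 2
#'   are equivalent fit.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    crs = "local-metres",
    paths = list(output_dir = "bym_out", areas = NULL, services = NULL,
                 stations = NULL, covariates = NULL),
    simulate = list(enabled = TRUE, n_areas = 100L),
    adjacency = list(scheme = "queen", k = 6L, radius = NULL),
    zones = list(primary = 1L, intermediate = 2L),
    idw = list(power = 2, quintiles = FALSE, n_sample_points = 1L),
    model = list(
      covariates = c("migrant_rate", "pop_under15", "imp", "pea", "pm10"),
      chains = 4L, draws = 1000L, burnin = 8000L, thin = 8L,
      prior_u = c(0.1, 0.1), prior_st = c(0.001, 0.001),
      prior_fixed_precision = 0.001
    ),
    thresholds = list(exceedance = 1.5, probability = 0.8, vif = 5,
                      dic_equivalence = 2),
    screen = list(n_permutations = 499L),
    select = list(enabled = TRUE, chains = 2L, draws = 300L, burnin = 600L,
                  thin = 1L)
  )
}

parse_scalar <- function(s) {
  s <- trimws(s)
  if (s %in% c("true", "True", "TRUE", "yes")) return(TRUE)
  if (s %in% c("false", "False", "FALSE", "no")) return(FALSE)
  if (s %in% c("null", "~", "")) return(NULL)
  if (grepl('^".*"$', s) || grepl("^'.*'$", s)) return(substr(s, 2L, nchar(s) - 1L))
  num <- suppressWarnings(as.numeric(s))
  if (!is.na(num)) return(if (num == round(num) && abs(num) < 2^31) as.integer(num) else num)
  s
}

parse_value <- function(s) {
  s <- trimws(s)
  if (grepl("^\\[.*\\]$", s)) {
    inner <- trimws(substr(s, 2L, nchar(s) - 1L))
    if (inner == "") return(list())
    parts <- trimws(strsplit(inner, ",")[[1L]])
    vals <- lapply(parts, parse_scalar)
    return(simplify2array(vals))
  }
  parse_scalar(s)
}

#' Read a pipeline configuration file
#'
#' A small YAML-dialect reader: nested maps by 2-space indentation,
#' `key: value` scalars (numbers, true/false, quoted or bare strings) and
#' inline lists `key: [a, b, c]`. Comments (`#`) and blank lines are
#' ignored. Parsed values are merged over [default_pipeline_config()].
#'
#' @param path config file.
#' @return the merged configuration list.
#' @export
read_config <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- sub("(^|\\s)#.*$", "", raw)
  keep <- grepl("\\S", raw)
  lines <- raw[keep]
  indents <- nchar(sub("\\S.*$", "", lines)) %/% 2L
  parse_block <- function(from, to, level) {
    out <- list()
    i <- from
    while (i <= to) {
      if (indents[i] != level) stop("bad indentation at config line: ", lines[i])
      ln <- trimws(lines[i])
      m <- regmatches(ln, regexec("^([^:]+):(.*)$", ln))[[1L]]
      if (length(m) < 3L) stop("cannot parse config line: ", ln)
      key <- trimws(m[2L]); rest <- trimws(m[3L])
      j <- i + 1L
      while (j <= to && indents[j] > level) j <- j + 1L
      if (rest == "") {
        out[[key]] <- if (j > i + 1L) parse_block(i + 1L, j - 1L, level + 1L) else list()
      } else {
        v <- parse_value(rest)
        if (!is.null(v)) out[[key]] <- v
      }
      i <- j
    }
    out
  }
  cfg <- if (length(lines)) parse_block(1L, length(lines), 0L) else list()
  utils::modifyList(default_pipeline_config(), cfg)
}

pipeline_log <- function(stage, msg, seed = NA) {
  message(sprintf("[%s] [%s] %s%s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg, if (!is.na(seed)) sprintf(" (seed=%s)", seed) else ""))
}

file_md5 <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

#' Run the analysis pipeline
#'
#' Executes, in order: `simulate` (optional; writes a synthetic city),
#' `allocate` (adjacency, service zones, case allocation, rates),
#' `covariates` (IDW pollutant surface, optional quintile coding),
#' `screen` (Moran's I of the rate and covariates, VIF), `fit` (the BYM
#' model), `map` (relative risks, exceedance, clusters) and `select`
#' (DIC comparison of candidate hyperpriors). Any stage failure halts with
#' a stage-named error; outputs of completed stages are retained. A
#' manifest JSON recording the config, seed, input checksums and per-stage
#' outputs is written at the end; it contains everything needed to
#' re-execute the identical run.
#'
#' @param config a config list (see [default_pipeline_config()]) or the
#'   path of a config file for [read_config()].
#' @param output_dir overrides `config$paths$output_dir`.
#' @param stages subset of stage names to run (default: all applicable).
#' @param quiet suppress log lines.
#' @return invisibly, a list with the manifest and the in-memory artefacts
#'   (lattice, area_table, fit, risk, selection).
#' @export
run_pipeline <- function(config, output_dir = NULL, stages = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  config <- utils::modifyList(default_pipeline_config(), config)
  if (!is.null(output_dir)) config$paths$output_dir <- output_dir
  out <- config$paths$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  all_stages <- c("simulate", "allocate", "covariates", "screen", "fit", "map", "select")
  if (is.null(stages)) {
    stages <- all_stages
    if (!isTRUE(config$simulate$enabled)) stages <- setdiff(stages, "simulate")
    if (!isTRUE(config$select$enabled)) stages <- setdiff(stages, "select")
  }
  log_ <- function(stage, msg) if (!quiet) pipeline_log(stage, msg, seed)
  manifest <- list(package = "bymrisk",
                   version = as.character(utils::packageVersion("bymrisk")),
                   seed = seed, crs = config$crs, config = config,
                   inputs = list(), stages = list())
  env <- new.env(parent = emptyenv())
  run_stage <- function(name, fn) {
    if (!(name %in% stages)) return(invisible(NULL))
    log_(name, "start")
    outputs <- tryCatch(fn(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[length(manifest$stages) + 1L]] <<- list(
      name = name, status = "completed", outputs = file_md5(unlist(outputs))
    )
    log_(name, "done")
  }

  run_stage("simulate", function() {
    city <- synth_city(n_areas = as.integer(config$simulate$n_areas), seed = seed)
    paths <- write_city(city, file.path(out, "inputs"))
    config$paths$areas <<- paths[["areas"]]
    config$paths$services <<- paths[["services"]]
    config$paths$stations <<- paths[["stations"]]
    config$paths$covariates <<- paths[["covariates"]]
    paths[c("areas", "services", "stations", "covariates")]
  })

  # load inputs
  for (nm in c("areas", "services", "stations", "covariates")) {
    if (is.null(config$paths[[nm]])) stop("config$paths$", nm, " is required")
  }
  manifest$inputs <- file_md5(unlist(config$paths[c("areas", "services", "stations", "covariates")]))
  gj <- read_areas_geojson(config$paths$areas)
  env$services <- utils::read.csv(config$paths$services, stringsAsFactors = FALSE)
  env$stations <- utils::read.csv(config$paths$stations, stringsAsFactors = FALSE)
  env$covariates <- utils::read.csv(config$paths$covariates, stringsAsFactors = FALSE,
                                    check.names = FALSE)

  run_stage("allocate", function() {
    lat <- build_adjacency(gj$polygons, scheme = config$adjacency$scheme,
                           params = list(k = config$adjacency$k,
                                         radius = config$adjacency$radius))
    ordc <- match(lat$area_ids, gj$properties$area_id)
    pops <- as.numeric(gj$properties$population[ordc])
    zones <- build_service_zones(env$services, lat, pops,
                                 config = list(radius = c(
                                   primary = as.integer(config$zones$primary),
                                   intermediate = as.integer(config$zones$intermediate))))
    cvm <- env$covariates[match(lat$area_ids, env$covariates$area_id), , drop = FALSE]
    tab <- build_area_table(lat, pops, env$services, zones, covariates = cvm)
    env$lattice <- lat; env$populations <- pops; env$zones <- zones
    env$area_table <- tab
    p1 <- file.path(out, "area_table.csv")
    utils::write.csv(tab, p1, row.names = FALSE)
    p2 <- file.path(out, "adjacency_edges.csv")
    p3 <- file.path(out, "adjacency.mtx")
    write_adjacency(lat, p2, p3)
    c(p1, p2, p3)
  })

  run_stage("covariates", function() {
    pm <- area_pollution(env$stations, env$lattice, power = config$idw$power,
                         n_sample_points = config$idw$n_sample_points)
    env$area_table$pm10 <- unname(pm)
    if (isTRUE(config$idw$quintiles)) {
      env$area_table$pm10_quintile <- quintile_bin(unname(pm))
    }
    p1 <- file.path(out, "area_table.csv")
    utils::write.csv(env$area_table, p1, row.names = FALSE)
    p1
  })

  run_stage("screen", function() {
    covs <- intersect(config$model$covariates, names(env$area_table))
    vars <- c("rate", covs)
    mor <- do.call(rbind, lapply(vars, function(v) {
      m <- morans_i(env$area_table[[v]], env$lattice,
                    n_permutations = config$screen$n_permutations,
                    seed = stage_seed(seed, 100L + match(v, vars)))
      data.frame(variable = v, morans_i = m$statistic,
                 expected = m$expected_value, p_value = m$p_value)
    }))
    vf <- vif(as.matrix(env$area_table[, covs, drop = FALSE]),
              threshold = config$thresholds$vif)
    env$screen <- list(moran = mor, vif = vf)
    p1 <- file.path(out, "screen_moran.csv")
    p2 <- file.path(out, "screen_vif.csv")
    utils::write.csv(mor, p1, row.names = FALSE)
    utils::write.csv(as.data.frame(vf), p2, row.names = FALSE)
    c(p1, p2)
  })

  run_stage("fit", function() {
    covs <- intersect(config$model$covariates, names(env$area_table))
    spec <- bym_model_spec(
      covariates = covs,
      prior_u = config$model$prior_u, prior_st = config$model$prior_st,
      prior_fixed_precision = config$model$prior_fixed_precision,
      adjacency_scheme = config$adjacency$scheme
    )
    fit <- bym_fit(env$area_table, env$lattice, spec,
                   n_chains = config$model$chains, n_draws = config$model$draws,
                   burnin = config$model$burnin, thin = config$model$thin,
                   seed = seed)
    env$fit <- fit
    p1 <- file.path(out, "posterior_summary.csv")
    utils::write.csv(summary(fit), p1, row.names = FALSE)
    p2 <- file.path(out, "fixed_effects_exp.csv")
    utils::write.csv(summarize_fixed_effects(fit), p2, row.names = FALSE)
    p3 <- file.path(out, "area_effects.csv")
    utils::write.csv(data.frame(area_id = fit$area_ids,
                                u_mean = colMeans(fit$draws$u),
                                st_mean = colMeans(fit$draws$st)),
                     p3, row.names = FALSE)
    p4 <- file.path(out, "fit_meta.json")
    jsonlite::write_json(list(dic = fit$dic, p_d = fit$p_d,
                              spatial_variance_fraction = fit$spatial_variance_fraction,
                              rhat = as.list(fit$rhat)),
                         p4, auto_unbox = TRUE, digits = NA)
    c(p1, p2, p3, p4)
  })

  run_stage("map", function() {
    risk <- risk_summary(env$fit, env$lattice,
                         threshold = config$thresholds$exceedance)
    env$risk <- risk
    p1 <- file.path(out, "risk.csv")
    p2 <- file.path(out, "risk.geojson")
    write_risk_map(risk, p1, env$lattice, p2)
    c(p1, p2)
  })

  run_stage("select", function() {
    covs <- intersect(config$model$covariates, names(env$area_table))
    cands <- lapply(default_prior_candidates(), function(pr) {
      list(spec = bym_model_spec(covariates = covs, prior_u = pr, prior_st = pr,
                                 adjacency_scheme = config$adjacency$scheme),
           lattice = env$lattice)
    })
    led <- compare_candidates(env$area_table, cands, seed = seed,
                              n_chains = config$select$chains,
                              n_draws = config$select$draws,
                              burnin = config$select$burnin,
                              thin = config$select$thin,
                              dic_equivalence = config$thresholds$dic_equivalence)
    env$selection <- led
    p1 <- file.path(out, "selection_ledger.csv")
    p2 <- file.path(out, "selection_ledger.json")
    write_ledger(led, p1, p2)
    c(p1, p2)
  })

  mpath <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  log_("pipeline", paste("manifest written:", mpath))
  invisible(list(manifest = manifest, manifest_path = mpath,
                 lattice = env$lattice, area_table = env$area_table,
                 zones = env$zones, screen = env$screen, fit = env$fit,
                 risk = env$risk, selection = env$selection,
                 output_dir = out))
}
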