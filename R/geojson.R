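# Minimal GeoJSON I/O for polygon FeatureCollections. Only what the
# pipeline needs: Polygon / MultiPolygon features in a projected planar CRS,
# an "area_id" property, and arbitrary extra scalar properties.

#' Read areas from a GeoJSON FeatureCollection
#'
#' Every feature must be a Polygon or MultiPolygon carrying an `area_id`
#' property. Interior rings (holes) are not supported and are dropped with a
#' warning.
#'
#' @param path GeoJSON file.
#' @return list with `polygons` (named list of polygons, in file order) and
#'   `properties` (data.frame of feature properties, one row per feature).
#' @export
read_areas_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection")
  }
  feats <- gj$features
  if (!length(feats)) stop("empty FeatureCollection")
  polys <- vector("list", length(feats))
  props <- vector("list", length(feats))
  dropped_holes <- FALSE
  ring_from_json <- function(coords) {
    m <- do.call(rbind, lapply(coords, function(p) c(p[[1L]], p[[2L]])))
    # drop the closing vertex
    if (nrow(m) > 1L && all(m[1L, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    m
  }
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    g <- f$geometry
    rings <- switch(g$type,
      Polygon = {
        if (length(g$coordinates) > 1L) dropped_holes <- TRUE
        list(ring_from_json(g$coordinates[[1L]]))
      },
      MultiPolygon = {
        if (any(vapply(g$coordinates, length, integer(1)) > 1L)) dropped_holes <- TRUE
        lapply(g$coordinates, function(pg) ring_from_json(pg[[1L]]))
      },
      stop("unsupported geometry type: ", g$type)
    )
    polys[[k]] <- rings
    props[[k]] <- f$properties
  }
  ids <- vapply(props, function(p) {
    if (is.null(p$area_id)) stop("feature missing required property 'area_id'")
    as.character(p$area_id)
  }, character(1))
  names(polys) <- ids
  if (dropped_holes) warning("interior rings (holes) dropped")
  keys <- unique(unlist(lapply(props, names)))
  pd <- as.data.frame(
    lapply(stats::setNames(keys, keys), function(k) {
      vals <- lapply(props, function(p) if (is.null(p[[k]])) NA else p[[k]])
      unlist(vals)
    }),
    stringsAsFactors = FALSE
  )
  list(polygons = polys, properties = pd)
}

#' Write areas to GeoJSON
#'
#' @param polygons named list of polygons (names become `area_id`).
#' @param properties optional data.frame of extra per-feature properties
#'   (row order matches `polygons`; an `area_id` column, if present, must
#'   agree with the names).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_areas_geojson <- function(polygons, path, properties = NULL) {
  ids <- names(polygons)
  if (is.null(ids)) stop("polygons must be named by area_id")
  if (!is.null(properties) && "area_id" %in% names(properties) &&
      !identical(as.character(properties$area_id), ids)) {
    stop("properties$area_id does not match polygon names")
  }
  close_ring <- function(ring) {
    m <- rbind(ring, ring[1L, ])
    lapply(seq_len(nrow(m)), function(i) c(m[i, 1L], m[i, 2L]))
  }
  feats <- lapply(seq_along(polygons), function(k) {
    rings <- polygons[[k]]
    geom <- if (length(rings) == 1L) {
      list(type = "Polygon", coordinates = list(close_ring(rings[[1L]])))
    } else {
      list(type = "MultiPolygon",
           coordinates = lapply(rings, function(r) list(close_ring(r))))
    }
    pr <- list(area_id = ids[[k]])
    if (!is.null(properties)) {
      for (col in setdiff(names(properties), "area_id")) pr[[col]] <- properties[[col]][k]
    }
    list(type = "Feature", properties = pr, geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
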