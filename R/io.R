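#' GeoJSON input/output for polygon feature sets
#'
#' Polygon layers (country boundary, states, protected areas) travel as
#' GeoJSON FeatureCollections of Polygon or MultiPolygon geometries in
#' geographic coordinates. Feature `name` and `tier` properties are
#' preserved; every polygon ring becomes a ring of the corresponding
#' [poly_set()] feature (even-odd membership, so holes round-trip).
#'
#' @name treecensus-io
#' @keywords internal
NULL

#' Read a polygon feature set from GeoJSON
#'
#' @param path GeoJSON file (FeatureCollection of Polygon/MultiPolygon, or
#'   a bare geometry).
#' @return a [poly_set()].
#' @export
read_poly_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
           else list(list(type = "Feature", geometry = gj, properties = NULL))
  rings_of <- function(geom) {
    coords <- geom$coordinates
    polys <- switch(geom$type,
                    Polygon = list(coords),
                    MultiPolygon = coords,
                    stop("unsupported geometry type: ", geom$type))
    unlist(lapply(polys, function(poly) {
      lapply(poly, function(ring) {
        do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
      })
    }), recursive = FALSE)
  }
  poly_set(lapply(seq_along(feats), function(i) {
    f <- feats[[i]]
    list(name = if (!is.null(f$properties$name)) f$properties$name
                else paste0("feature_", i),
         tier = if (!is.null(f$properties$tier)) f$properties$tier
                else NA_character_,
         rings = rings_of(f$geometry))
  }))
}

close_ring <- function(r) rbind(r, r[1, , drop = FALSE])

#' Write a polygon feature set to GeoJSON
#'
#' @param ps a [poly_set()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_poly_geojson <- function(ps, path) {
  stopifnot(inherits(ps, "poly_set"))
  feats <- lapply(unclass(ps), function(f) {
    coords <- lapply(f$rings, function(r) {
      lapply(seq_len(nrow(r) + 1L), function(i) {
        p <- close_ring(r)[i, ]
        c(p[[1]], p[[2]])
      })
    })
    props <- list(name = f$name)
    if (!is.na(f$tier)) props$tier <- f$tier
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
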