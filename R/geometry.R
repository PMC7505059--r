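#' Lightweight planar geometry for occurrence mapping
#'
#' The package works in geographic coordinates (decimal degrees, WGS84
#' assumed) and projects them onto a local equidistant plane measured in
#' kilometres whenever distances or cell sizes matter. The projection is an
#' equirectangular mapping centred on a reference point, which preserves
#' distances well at country scale and keeps every spatial operation
#' (point-in-polygon, nearest-boundary distance, gridding) exactly
#' reproducible from plain arithmetic.
#'
#' @name treecensus-geometry
#' @keywords internal
NULL

EARTH_RADIUS_KM <- 6371.0088

#' Local equidistant coordinate reference system
#'
#' @param lon0,lat0 reference point in decimal degrees; the projected plane
#'   is tangent here and measured in km.
#' @return an object of class `local_crs`.
#' @export
local_crs <- function(lon0, lat0) {
  stopifnot(is.finite(lon0), is.finite(lat0), abs(lat0) < 90)
  structure(list(lon0 = lon0, lat0 = lat0, radius_km = EARTH_RADIUS_KM),
            class = "local_crs")
}

#' @export
format.local_crs <- function(x, ...) {
  sprintf("local equidistant plane centred at (%.4f, %.4f), units km",
          x$lon0, x$lat0)
}

#' @export
print.local_crs <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Project lon/lat degrees to km on a local plane (and back)
#'
#' @param lon,lat coordinates in decimal degrees.
#' @param crs a [local_crs()].
#' @return `project_xy`: list with numeric `x`, `y` in km;
#'   `unproject_xy`: list with `lon`, `lat` in degrees.
#' @export
project_xy <- function(lon, lat, crs) {
  k <- pi / 180 * crs$radius_km
  list(x = (lon - crs$lon0) * k * cos(crs$lat0 * pi / 180),
       y = (lat - crs$lat0) * k)
}

#' @rdname project_xy
#' @param x,y projected coordinates in km.
#' @export
unproject_xy <- function(x, y, crs) {
  k <- pi / 180 * crs$radius_km
  list(lon = x / (k * cos(crs$lat0 * pi / 180)) + crs$lon0,
       lat = y / k + crs$lat0)
}

#' Polygon feature sets
#'
#' A `poly_set` is the package's vector-polygon container: a list of
#' features, each with a `name`, an optional `tier` attribute (used for
#' protected areas) and one or more rings, every ring a two-column
#' (lon, lat) matrix. Ring membership is evaluated with the even-odd rule,
#' so holes are simply additional rings of the same feature.
#'
#' @param features list of features, each `list(name=, tier=, rings=)`.
#' @return an object of class `poly_set`.
#' @export
poly_set <- function(features) {
  stopifnot(is.list(features), length(features) >= 1)
  feats <- lapply(seq_along(features), function(i) {
    f <- features[[i]]
    if (is.matrix(f)) f <- list(rings = list(f))
    if (!is.list(f$rings)) stop("feature ", i, " has no rings")
    f$rings <- lapply(f$rings, function(r) {
      r <- as.matrix(r)
      if (ncol(r) != 2 || nrow(r) < 3) {
        stop("feature ", i, ": each ring needs >= 3 (lon, lat) vertices")
      }
      storage.mode(r) <- "double"
      # drop an explicitly repeated closing vertex; edges are cyclic
      if (all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
      unname(r)
    })
    if (is.null(f$name)) f$name <- paste0("feature_", i)
    if (is.null(f$tier)) f$tier <- NA_character_
    f[c("name", "tier", "rings")]
  })
  structure(feats, class = "poly_set")
}

#' @export
print.poly_set <- function(x, ...) {
  nr <- vapply(x, function(f) length(f$rings), integer(1))
  cat(sprintf("<poly_set> %d feature(s): %s\n", length(x),
              paste0(vapply(x, `[[`, "", "name"), " (", nr, " ring",
                     ifelse(nr > 1, "s", ""), ")", collapse = ", ")))
  invisible(x)
}

#' @export
names.poly_set <- function(x) vapply(unclass(x), `[[`, "", "name")

ps_bbox <- function(ps) {
  xs <- unlist(lapply(unclass(ps), function(f) lapply(f$rings, function(r) r[, 1])))
  ys <- unlist(lapply(unclass(ps), function(f) lapply(f$rings, function(r) r[, 2])))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

# Even-odd ray casting, vectorised over points. ring: n x 2 matrix.
point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  j <- c(n, seq_len(n - 1L))
  inside <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    xi <- ring[k, 1]; yi <- ring[k, 2]
    xj <- ring[j[k], 1]; yj <- ring[j[k], 2]
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- (xj - xi) * (py - yi) / (yj - yi) + xi
      hit <- crosses & (px < xint)
      inside <- xor(inside, hit)
    }
  }
  inside
}

point_in_feature <- function(px, py, feature) {
  Reduce(xor, lapply(feature$rings, function(r) point_in_ring(px, py, r)))
}

#' Point-in-polygon tests against a feature set
#'
#' @param lon,lat point coordinates in decimal degrees.
#' @param ps a [poly_set()].
#' @return `point_in_poly_set`: logical vector, `TRUE` where a point lies in
#'   any feature; `which_feature`: integer index of the first containing
#'   feature in the set's fixed order, `NA` if none (the documented
#'   tie-break for points on shared borders).
#' @export
point_in_poly_set <- function(lon, lat, ps) {
  stopifnot(inherits(ps, "poly_set"), length(lon) == length(lat))
  inside <- rep(FALSE, length(lon))
  for (f in unclass(ps)) {
    todo <- !inside
    if (!any(todo)) break
    inside[todo] <- point_in_feature(lon[todo], lat[todo], f)
  }
  inside
}

#' @rdname point_in_poly_set
#' @export
which_feature <- function(lon, lat, ps) {
  stopifnot(inherits(ps, "poly_set"), length(lon) == length(lat))
  idx <- rep(NA_integer_, length(lon))
  for (i in seq_along(ps)) {
    todo <- is.na(idx)
    if (!any(todo)) break
    hit <- point_in_feature(lon[todo], lat[todo], ps[[i]])
    idx[which(todo)[hit]] <- i
  }
  idx
}

# Nearest point on the edges of a set of rings, all in projected km.
# Returns dist (km), and the projected coordinates of the nearest point.
nearest_on_edges <- function(px, py, edges) {
  # edges: matrix with columns x1 y1 x2 y2
  n <- length(px)
  best_d2 <- rep(Inf, n)
  best_x <- rep(NA_real_, n)
  best_y <- rep(NA_real_, n)
  for (e in seq_len(nrow(edges))) {
    x1 <- edges[e, 1]; y1 <- edges[e, 2]; x2 <- edges[e, 3]; y2 <- edges[e, 4]
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    t <- if (len2 == 0) rep(0, n) else
      pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
    qx <- x1 + t * dx; qy <- y1 + t * dy
    d2 <- (px - qx)^2 + (py - qy)^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]; best_x[upd] <- qx[upd]; best_y[upd] <- qy[upd]
  }
  list(dist = sqrt(best_d2), x = best_x, y = best_y)
}

poly_set_edges_xy <- function(ps, crs) {
  rings <- unlist(lapply(unclass(ps), `[[`, "rings"), recursive = FALSE)
  do.call(rbind, lapply(rings, function(r) {
    p <- project_xy(r[, 1], r[, 2], crs)
    n <- nrow(r)
    nxt <- c(seq_len(n)[-1], 1L)
    cbind(p$x, p$y, p$x[nxt], p$y[nxt])
  }))
}

#' Distance (km) from points to the boundary of a feature set
#'
#' Distances are computed on the local equidistant plane; the sign is not
#' carried (use [point_in_poly_set()] for inside/outside).
#'
#' @inheritParams point_in_poly_set
#' @param crs a [local_crs()]; defaults to the centre of the set's extent.
#' @return list with `dist` (km), and the nearest boundary point as
#'   `lon`, `lat`.
#' @export
boundary_distance <- function(lon, lat, ps, crs = NULL) {
  if (is.null(crs)) {
    bb <- ps_bbox(ps)
    crs <- local_crs((bb["xmin"] + bb["xmax"]) / 2, (bb["ymin"] + bb["ymax"]) / 2)
  }
  edges <- poly_set_edges_xy(ps, crs)
  p <- project_xy(lon, lat, crs)
  near <- nearest_on_edges(p$x, p$y, edges)
  ll <- unproject_xy(near$x, near$y, crs)
  list(dist = near$dist, lon = ll$lon, lat = ll$lat)
}

ring_area <- function(ring) {
  n <- nrow(ring)
  nxt <- c(seq_len(n)[-1], 1L)
  abs(sum(ring[, 1] * ring[nxt, 2] - ring[nxt, 1] * ring[, 2])) / 2
}
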