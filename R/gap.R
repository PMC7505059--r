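#' Protected-area overlay and conservation-gap cells
#'
#' Protected areas come as polygon features with a `tier` attribute
#' (federal, state, municipal or private); all tiers are pooled by
#' default. The per-cell protected fraction is the share of cell area
#' covered by the union of reserves, evaluated on a deterministic midpoint
#' subgrid inside each cell: union semantics are exact under point
#' membership, overlapping reserves are never double-counted, and the
#' result is invariant to subdividing a reserve polygon. A gap cell is
#' species-rich (`richness > min_richness`) yet essentially unprotected
#' (`protected fraction <= max_protected`).
#'
#' @name treecensus-gap
#' @keywords internal
NULL

pa_tiers <- c("federal", "state", "municipal", "private")

#' Per-cell protected fraction
#'
#' @param grid a [grid_spec()].
#' @param reserves protected areas as a [poly_set()] whose features carry
#'   a `tier` in `federal`, `state`, `municipal`, `private` (or `NA`).
#' @param tiers optional subset of tiers to include (default: all).
#' @param n_sub midpoint subgrid resolution per cell side (default 24,
#'   i.e. 576 sample points per cell; geometric tolerance about
#'   `cell_km / 24`).
#' @return a `grid_layer` (kind `protected_fraction`) with values in
#'   `[0, 1]`.
#' @export
protected_fraction <- function(grid, reserves, tiers = NULL, n_sub = 24) {
  stopifnot(inherits(grid, "grid_spec"), n_sub >= 2)
  keep <- rep(TRUE, length(reserves))
  if (!is.null(reserves) && inherits(reserves, "poly_set") && !is.null(tiers)) {
    bad <- setdiff(tiers, pa_tiers)
    if (length(bad)) stop("unknown reserve tier(s): ", paste(bad, collapse = ", "))
    keep <- vapply(unclass(reserves), function(f) f$tier %in% tiers, TRUE)
  }
  vals <- matrix(0, nrow = grid$n_rows, ncol = grid$n_cols)
  sel <- if (inherits(reserves, "poly_set")) unclass(reserves)[keep] else list()
  if (length(sel)) {
    sel_ps <- poly_set(sel)
    bbs <- lapply(sel, function(f) {
      xs <- unlist(lapply(f$rings, function(r) r[, 1]))
      ys <- unlist(lapply(f$rings, function(r) r[, 2]))
      c(min(xs), min(ys), max(xs), max(ys))
    })
    f <- seq(0.5 / n_sub, 1 - 0.5 / n_sub, length.out = n_sub)
    offx <- rep(f, times = n_sub) * grid$cell_km
    offy <- rep(f, each = n_sub) * grid$cell_km
    for (row in seq_len(grid$n_rows)) {
      for (col in seq_len(grid$n_cols)) {
        x0 <- grid$x0 + (col - 1) * grid$cell_km
        y0 <- grid$y0 + (row - 1) * grid$cell_km
        cr <- unproject_xy(c(x0, x0 + grid$cell_km),
                           c(y0, y0 + grid$cell_km), grid$crs)
        touch <- vapply(bbs, function(b) {
          !(b[3] < min(cr$lon) || b[1] > max(cr$lon) ||
            b[4] < min(cr$lat) || b[2] > max(cr$lat))
        }, TRUE)
        if (!any(touch)) next
        ll <- unproject_xy(x0 + offx, y0 + offy, grid$crs)
        inside <- point_in_poly_set(ll$lon, ll$lat,
                                    poly_set(unclass(sel_ps)[touch]))
        vals[row, col] <- mean(inside)
      }
    }
  }
  new_grid_layer(grid, vals, kind = "protected_fraction")
}

#' Identify species-rich, under-protected gap cells
#'
#' @param richness a richness `grid_layer`.
#' @param prot a protected-fraction `grid_layer` on the same grid
#'   (see [protected_fraction()]).
#' @param min_richness cells must exceed this richness (strict).
#' @param max_protected cells must have protected fraction at or below
#'   this value (default 0.05 — the declared convention quantifying "few
#'   or no protected areas").
#' @param states optional state [poly_set()] for annotation.
#' @return object of class `gap_report`: a data.frame of gap cells
#'   (`cell_id`, `cell_col`, `cell_row`, `richness`, `protected_fraction`,
#'   `states`) sorted by richness descending, with the thresholds stored
#'   as attributes.
#' @export
gap_cells <- function(richness, prot, min_richness, max_protected = 0.05,
                      states = NULL) {
  stopifnot(inherits(richness, "grid_layer"), inherits(prot, "grid_layer"))
  if (!same_grid(richness$grid, prot$grid)) stop("layers are on different grids")
  peaks <- find_peaks(richness, min_richness, states)
  if (nrow(peaks)) {
    pf <- prot$values[cbind(peaks$cell_row, peaks$cell_col)]
    keep <- pf <= max_protected
    peaks <- peaks[keep, , drop = FALSE]
    peaks$protected_fraction <- pf[keep]
  } else {
    peaks$protected_fraction <- numeric(0)
  }
  names(peaks)[names(peaks) == "value"] <- "richness"
  peaks <- peaks[c("cell_id", "cell_col", "cell_row", "richness",
                   "protected_fraction", "states")]
  rownames(peaks) <- NULL
  structure(peaks, class = c("gap_report", "data.frame"),
            min_richness = min_richness, max_protected = max_protected)
}

#' @export
print.gap_report <- function(x, ...) {
  cat(sprintf("<gap_report> %d cell(s) with richness > %g and protected fraction <= %g\n",
              nrow(x), attr(x, "min_richness"), attr(x, "max_protected")))
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  invisible(x)
}

#' Export a gap report as CSV and GeoJSON cell rectangles
#'
#' @param report a [gap_cells()] result.
#' @param grid the [grid_spec()] the report was computed on.
#' @param csv_path,geojson_path output paths (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
write_gap_report <- function(report, grid, csv_path = NULL,
                             geojson_path = NULL) {
  paths <- character(0)
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(report), csv_path, row.names = FALSE)
    paths <- c(paths, csv_path)
  }
  if (!is.null(geojson_path)) {
    feats <- lapply(seq_len(nrow(report)), function(i) {
      r <- cell_rect_lonlat(grid, report$cell_col[i], report$cell_row[i])
      ll <- unproject_xy(c(r$x[1], r$x[2], r$x[2], r$x[1]),
                         c(r$y[1], r$y[1], r$y[2], r$y[2]), grid$crs)
      list(name = sprintf("gap_cell_%d", report$cell_id[i]),
           tier = NA_character_,
           rings = list(cbind(ll$lon, ll$lat)),
           properties = list(richness = report$richness[i],
                             protected_fraction = report$protected_fraction[i]))
    })
    if (length(feats)) {
      write_poly_geojson(poly_set(feats), geojson_path)
    } else {
      writeLines('{"type":"FeatureCollection","features":[]}', geojson_path)
    }
    paths <- c(paths, geojson_path)
  }
  invisible(paths)
}
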