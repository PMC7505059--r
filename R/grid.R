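#' Equal-area gridding, richness layers and peak detection
#'
#' All mapped statistics share one lattice: square cells of `cell_km` km
#' side on the local equidistant plane, anchored at the lower-left corner
#' of the boundary envelope and expanded to whole cells. Cell membership
#' uses half-open intervals `[x, x+s) x [y, y+s)`; points exactly on the
#' global upper or right envelope edge belong to the last cell. Richness
#' is the count of distinct taxa (species, genus or family) among the
#' records that pass an attribute slice; genus and family are taken from
#' the catalogue join, never from splitting the record's name string.
#'
#' @name treecensus-grid
#' @keywords internal
NULL

#' Build a grid specification over a boundary
#'
#' @param boundary country land [poly_set()].
#' @param cell_km cell side in km (default 25, giving 625 km2 cells; 10,
#'   20, 30 and 50 are the other resolutions commonly explored).
#' @param crs a [local_crs()]; defaults to the centre of the boundary
#'   envelope so that cell sizes are metrically meaningful.
#' @return object of class `grid_spec`.
#' @export
build_grid <- function(boundary, cell_km = 25, crs = NULL) {
  stopifnot(inherits(boundary, "poly_set"), cell_km > 0)
  bb <- ps_bbox(boundary)
  if (bb["xmax"] <= bb["xmin"] || bb["ymax"] <= bb["ymin"]) {
    stop("degenerate boundary: zero-area envelope")
  }
  if (is.null(crs)) {
    crs <- local_crs((bb["xmin"] + bb["xmax"]) / 2,
                     (bb["ymin"] + bb["ymax"]) / 2)
  }
  ll <- project_xy(bb["xmin"], bb["ymin"], crs)
  ur <- project_xy(bb["xmax"], bb["ymax"], crs)
  n_cols <- as.integer(ceiling((ur$x - ll$x) / cell_km - 1e-9))
  n_rows <- as.integer(ceiling((ur$y - ll$y) / cell_km - 1e-9))
  structure(list(crs = crs, x0 = unname(ll$x), y0 = unname(ll$y),
                 cell_km = cell_km, n_cols = n_cols, n_rows = n_rows),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g km (%g km2 each)\n",
              x$n_cols, x$n_rows, x$cell_km, x$cell_km^2))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a[c("x0", "y0", "cell_km", "n_cols", "n_rows")],
                   b[c("x0", "y0", "cell_km", "n_cols", "n_rows")]))
}

#' Assign records to grid cells
#'
#' @param records occurrence data.frame with `lon`, `lat`.
#' @param grid a [grid_spec()].
#' @return records with integer `cell_col`, `cell_row` (1-based) and
#'   `cell_id = (cell_row - 1) * n_cols + cell_col`. A record outside the
#'   grid extent is an error (impossible after cleaning).
#' @export
assign_cells <- function(records, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  p <- project_xy(records$lon, records$lat, grid$crs)
  s <- grid$cell_km
  # snap to a grid line when within 1e-9 km (~1 micron) so the half-open
  # convention is stable under projection round-off
  gx <- (p$x - grid$x0) / s
  gy <- (p$y - grid$y0) / s
  gx <- ifelse(abs(gx - round(gx)) < 1e-9 / s, round(gx), gx)
  gy <- ifelse(abs(gy - round(gy)) < 1e-9 / s, round(gy), gy)
  col <- floor(gx) + 1L
  row <- floor(gy) + 1L
  # points exactly on the global right/top envelope edge close into the
  # last cell; everything else is half-open
  col[gx == grid$n_cols] <- grid$n_cols
  row[gy == grid$n_rows] <- grid$n_rows
  bad <- which(col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows)
  if (length(bad)) {
    stop("record(s) outside the grid extent, e.g. id ",
         records$record_id[bad[1]])
  }
  records$cell_col <- as.integer(col)
  records$cell_row <- as.integer(row)
  records$cell_id <- as.integer((row - 1L) * grid$n_cols + col)
  records
}

new_grid_layer <- function(grid, values, kind, slice = NULL, level = NULL) {
  structure(list(grid = grid, values = values, kind = kind,
                 slice = slice, level = level),
            class = "grid_layer")
}

#' @export
print.grid_layer <- function(x, ...) {
  sl <- if (is.null(x$slice) || !length(x$slice)) "all records" else
    paste(names(x$slice), vapply(x$slice, format, ""), sep = "=", collapse = ", ")
  cat(sprintf("<grid_layer> %s%s on %d x %d cells; max %g, non-empty %d\n",
              x$kind, if (!is.null(x$level)) paste0(" (", x$level, ")") else "",
              x$grid$n_cols, x$grid$n_rows, max(x$values),
              sum(x$values > 0)))
  cat("  slice:", sl, "\n")
  invisible(x)
}

#' Per-cell record density
#'
#' @param records occurrence data.frame (kept records).
#' @param grid a [grid_spec()].
#' @return a `grid_layer` of per-cell record counts (empty cells are 0);
#'   the values sum to the number of records.
#' @export
density_layer <- function(records, grid) {
  records <- assign_cells(records, grid)
  counts <- tabulate(records$cell_id, nbins = grid$n_rows * grid$n_cols)
  new_grid_layer(grid, matrix(as.integer(counts), nrow = grid$n_rows,
                              ncol = grid$n_cols, byrow = TRUE),
                 kind = "density")
}

#' Join occurrence records to catalogue attributes
#'
#' Records whose species is absent from the catalogue are excluded and
#' reported (`attr(result, "join_miss")`: count and species names),
#' mirroring the mapped-species shortfall real inventories show.
#'
#' @param records occurrence data.frame.
#' @param cat a [catalogue()].
#' @return records with `genus`, `family`, `endemic`, `useful`,
#'   `threatened`, `banked`, `iucn`, `nom059`, `cites` columns.
#' @export
join_catalogue <- function(records, cat) {
  stopifnot(inherits(cat, "catalogue"))
  e <- cat$entries
  idx <- match(records$species, e$species)
  miss <- is.na(idx)
  join_miss <- list(n = sum(miss), species = sort(unique(records$species[miss])))
  records <- records[!miss, , drop = FALSE]
  idx <- idx[!miss]
  records$genus <- e$genus[idx]
  records$family <- e$family[idx]
  records$endemic <- e$endemic[idx]
  records$useful <- e$useful[idx]
  records$threatened <- is_threatened(e$iucn[idx])
  records$banked <- e$banked_incountry[idx] | e$banked_duplicated[idx]
  records$iucn <- e$iucn[idx]
  records$nom059 <- e$nom059[idx]
  records$cites <- e$cites[idx]
  attr(records, "join_miss") <- join_miss
  records
}

apply_slice <- function(records, slice) {
  if (is.null(slice) || !length(slice)) return(records)
  keep <- rep(TRUE, nrow(records))
  for (nm in names(slice)) {
    if (!nm %in% names(records)) stop("unknown slice attribute: ", nm)
    keep <- keep & records[[nm]] %in% slice[[nm]]
  }
  records[keep, , drop = FALSE]
}

#' Per-cell distinct-taxon richness for an attribute slice
#'
#' @param records occurrence data.frame, already joined to the catalogue
#'   (see [join_catalogue()]) or accompanied by `cat`.
#' @param grid a [grid_spec()].
#' @param cat optional [catalogue()] to join on the fly.
#' @param slice named list of attribute filters, e.g.
#'   `list(endemic = TRUE)`, `list(threatened = TRUE, useful = TRUE)`,
#'   `list(cites = c("I", "II", "II/NC", "III"))`; `NULL` means all
#'   records.
#' @param level `"species"`, `"genus"` or `"family"`.
#' @return a `grid_layer` of per-cell distinct-taxon counts; cells with no
#'   records are 0.
#' @export
richness_layer <- function(records, grid, cat = NULL, slice = NULL,
                           level = c("species", "genus", "family")) {
  level <- match.arg(level)
  if (!is.null(cat)) records <- join_catalogue(records, cat)
  if (level != "species" && is.null(records$genus)) {
    stop("genus/family richness needs catalogue-joined records")
  }
  jm <- attr(records, "join_miss")
  records <- apply_slice(records, slice)
  records <- assign_cells(records, grid)
  m <- matrix(0L, nrow = grid$n_rows, ncol = grid$n_cols)
  if (nrow(records)) {
    taxon <- records[[level]]
    u <- !duplicated(paste(records$cell_id, taxon, sep = "\r"))
    t <- tabulate(records$cell_id[u], nbins = grid$n_rows * grid$n_cols)
    m <- matrix(as.integer(t), nrow = grid$n_rows, ncol = grid$n_cols,
                byrow = TRUE)
  }
  out <- new_grid_layer(grid, m, kind = "richness", slice = slice,
                        level = level)
  attr(out, "join_miss") <- jm
  out
}

#' Distinct-taxon counts per state (choropleth table)
#'
#' States are assigned by point-in-polygon against the state polygons in
#' their fixed order (first containing polygon wins on shared borders),
#' not from the record's state column. A species spanning two states
#' counts once in each, so state counts are not additive to the national
#' total.
#'
#' @param records occurrence data.frame (joined if `level != "species"`).
#' @param states state polygons as a [poly_set()].
#' @param cat optional catalogue for the join.
#' @param level taxon level as in [richness_layer()].
#' @param slice optional attribute filter.
#' @return data.frame with `state`, `n_taxa`, `n_records`; records falling
#'   in no state polygon are tallied under `NA`.
#' @export
per_state_counts <- function(records, states, cat = NULL,
                             level = c("species", "genus", "family"),
                             slice = NULL) {
  level <- match.arg(level)
  if (!is.null(cat)) records <- join_catalogue(records, cat)
  records <- apply_slice(records, slice)
  st_names <- names(states)
  idx <- which_feature(records$lon, records$lat, states)
  taxon <- if (level == "species") records$species else records[[level]]
  out <- data.frame(state = st_names, n_taxa = 0L, n_records = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(states)) {
    sel <- !is.na(idx) & idx == i
    out$n_taxa[i] <- length(unique(taxon[sel]))
    out$n_records[i] <- sum(sel)
  }
  if (anyNA(idx)) {
    out <- rbind(out, data.frame(state = NA_character_,
                                 n_taxa = length(unique(taxon[is.na(idx)])),
                                 n_records = sum(is.na(idx))))
  }
  out
}

#' Ordinary least squares of richness on record density
#'
#' Cells with zero records are excluded by default: with them included the
#' zero-inflated empty cells dominate the fit. Both modes are exposed.
#'
#' @param d density `grid_layer`.
#' @param r richness `grid_layer` on the same grid.
#' @param include_zero_cells include cells with no records (default FALSE).
#' @return object of class `regression_result` with `slope`, `intercept`,
#'   `r_squared`, `n_cells_used`, `zero_cells_included`.
#' @export
regress_density_richness <- function(d, r, include_zero_cells = FALSE) {
  stopifnot(inherits(d, "grid_layer"), inherits(r, "grid_layer"))
  if (!same_grid(d$grid, r$grid)) stop("layers are on different grids")
  x <- as.vector(d$values); y <- as.vector(r$values)
  if (!include_zero_cells) {
    keep <- x > 0
    x <- x[keep]; y <- y[keep]
  }
  if (length(x) < 3) stop("fewer than 3 usable cells for the regression")
  fit <- stats::lm(y ~ x)
  # summary.lm warns on an exactly collinear fit; R-squared is still exact
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 n_cells_used = length(x),
                 zero_cells_included = include_zero_cells),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("richness = %.4f + %.4f * density  (R-squared %.4f, n = %d cells%s)\n",
              x$intercept, x$slope, x$r_squared, x$n_cells_used,
              if (x$zero_cells_included) ", zero cells included" else ""))
  invisible(x)
}

cell_rect_lonlat <- function(grid, col, row) {
  s <- grid$cell_km
  xs <- grid$x0 + (col - 1) * s
  ys <- grid$y0 + (row - 1) * s
  list(x = c(xs, xs + s), y = c(ys, ys + s))
}

cell_states <- function(grid, col, row, states, n_probe = 4) {
  r <- cell_rect_lonlat(grid, col, row)
  f <- seq(0.5 / n_probe, 1 - 0.5 / n_probe, length.out = n_probe)
  gx <- rep(r$x[1] + f * diff(r$x), times = n_probe)
  gy <- rep(r$y[1] + f * diff(r$y), each = n_probe)
  ll <- unproject_xy(gx, gy, grid$crs)
  idx <- which_feature(ll$lon, ll$lat, states)
  paste(names(states)[sort(unique(idx[!is.na(idx)]))], collapse = ",")
}

#' Detect richness peaks above a threshold
#'
#' A peak is any cell whose value is strictly greater than `threshold`.
#' Peaks are annotated with the state(s) intersecting the cell and sorted
#' by value descending, ties broken by cell index.
#'
#' @param layer a richness (or density) `grid_layer`.
#' @param threshold strict lower bound (`value > threshold`).
#' @param states optional state [poly_set()] for annotation.
#' @return data.frame with `cell_id`, `cell_col`, `cell_row`, `value`,
#'   `states` (comma-separated, empty when no state layer is given).
#' @export
find_peaks <- function(layer, threshold, states = NULL) {
  stopifnot(inherits(layer, "grid_layer"), threshold >= 0)
  g <- layer$grid
  hits <- which(t(layer$values) > threshold)  # t(): cell_id order
  col <- ((hits - 1L) %% g$n_cols) + 1L
  row <- ((hits - 1L) %/% g$n_cols) + 1L
  val <- layer$values[cbind(row, col)]
  ord <- order(-val, hits)
  out <- data.frame(cell_id = as.integer(hits[ord]),
                    cell_col = col[ord], cell_row = row[ord],
                    value = val[ord],
                    states = character(length(ord)),
                    stringsAsFactors = FALSE)
  if (!is.null(states) && nrow(out)) {
    out$states <- vapply(seq_len(nrow(out)), function(i) {
      cell_states(g, out$cell_col[i], out$cell_row[i], states)
    }, "")
  }
  out
}

#' Export a grid layer as gridded CSV
#'
#' One row per cell with indices, projected and geographic cell-centre
#' coordinates and the value.
#'
#' @param layer a `grid_layer`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
export_layer_csv <- function(layer, path) {
  g <- layer$grid
  grid_df <- expand.grid(cell_col = seq_len(g$n_cols),
                         cell_row = seq_len(g$n_rows))
  cx <- g$x0 + (grid_df$cell_col - 0.5) * g$cell_km
  cy <- g$y0 + (grid_df$cell_row - 0.5) * g$cell_km
  ll <- unproject_xy(cx, cy, g$crs)
  out <- data.frame(cell_id = (grid_df$cell_row - 1L) * g$n_cols + grid_df$cell_col,
                    cell_col = grid_df$cell_col, cell_row = grid_df$cell_row,
                    x_km = cx, y_km = cy, lon = ll$lon, lat = ll$lat,
                    value = layer$values[cbind(grid_df$cell_row, grid_df$cell_col)])
  out <- out[order(out$cell_id), ]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
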