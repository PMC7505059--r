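# Fixtures built in code and independent brute-force oracles.

# A square country of side `size_km`, centred on (lon0, lat0).
square_country <- function(size_km = 100, lon0 = -100, lat0 = 20) {
  crs <- local_crs(lon0, lat0)
  h <- size_km / 2
  ll <- unproject_xy(c(-h, h, h, -h), c(-h, -h, h, h), crs)
  poly_set(list(list(name = "Square", rings = list(cbind(ll$lon, ll$lat)))))
}

# Build occurrence records at explicit coordinates.
recs_at <- function(species, lon, lat, state = "Somewhere", dp = 4L) {
  occurrence_records(sprintf("r%04d", seq_along(species)), species,
                     lat, lon, state, coord_precision_dp = dp)
}

# A tiny hand-written catalogue with every vocabulary exercised.
tiny_catalogue <- function() {
  entries <- data.frame(
    family = c("Fagaceae", "Fagaceae", "Fabaceae", "Fabaceae", "Pinaceae",
               "Cactaceae"),
    genus = c("Quercus", "Quercus", "Acacia", "Inga", "Pinus",
              "Cephalocereus"),
    species = c("Quercus alba", "Quercus rubra", "Acacia cornigera",
                "Inga vera", "Pinus patula", "Cephalocereus senilis"),
    states = c("OCN", "OCN,CEN", "CES", "", "ORN", "CES"),
    endemic = c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE),
    iucn = c("EN", "LC", "NE", "VU", "LR/cd", "CR"),
    nom059 = c("P", "none", "none", "A", "Pr", "none"),
    cites = c("none", "II", "none", "none", "none", "I"),
    banked_incountry = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE),
    banked_duplicated = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
    useful = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  catalogue(entries, provenance = "test fixture")
}

# Brute-force per-cell tallies by explicit rectangle membership, written
# independently of assign_cells()/density_layer()/richness_layer().
oracle_cell_counts <- function(records, grid, species = NULL) {
  p <- project_xy(records$lon, records$lat, grid$crs)
  m <- matrix(0L, nrow = grid$n_rows, ncol = grid$n_cols)
  s <- grid$cell_km
  for (row in seq_len(grid$n_rows)) {
    for (col in seq_len(grid$n_cols)) {
      xlo <- grid$x0 + (col - 1) * s; xhi <- xlo + s
      ylo <- grid$y0 + (row - 1) * s; yhi <- ylo + s
      inx <- p$x >= xlo & (p$x < xhi | (col == grid$n_cols & p$x <= xhi))
      iny <- p$y >= ylo & (p$y < yhi | (row == grid$n_rows & p$y <= yhi))
      m[row, col] <- if (is.null(species)) sum(inx & iny)
                     else length(unique(species[inx & iny]))
    }
  }
  m
}

# Brute-force peak scan.
oracle_peaks <- function(values, threshold) {
  hits <- data.frame(row = integer(0), col = integer(0), value = integer(0))
  for (row in seq_len(nrow(values))) {
    for (col in seq_len(ncol(values))) {
      if (values[row, col] > threshold) {
        hits <- rbind(hits, data.frame(row = row, col = col,
                                       value = values[row, col]))
      }
    }
  }
  hits[order(-hits$value, (hits$row - 1) * ncol(values) + hits$col), ,
       drop = FALSE]
}

# Independent point-in-polygon via pracma, over the first containing feature.
oracle_which_feature <- function(lon, lat, ps) {
  idx <- rep(NA_integer_, length(lon))
  for (i in seq_along(ps)) {
    f <- ps[[i]]
    inside <- rep(FALSE, length(lon))
    for (r in f$rings) {
      inside <- xor(inside, pracma::inpolygon(lon, lat, r[, 1], r[, 2]))
    }
    idx[is.na(idx) & inside] <- i
  }
  idx
}

zero_rates <- function() lapply(default_error_rates(), function(z) 0)
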