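#' Synthetic study systems with ground-truth bookkeeping
#'
#' Every pipeline stage is testable without external downloads through a
#' seeded generator that emulates the inputs a national tree inventory
#' works from: an attribute-rich species catalogue, disc-shaped species
#' ranges over a synthetic country, voucher-style occurrence sampling, the
#' specific coordinate-error classes the cleaning rules target, and the
#' polygon layers (country boundary with a concave bay and two peninsulas,
#' states, protected areas). The generator records ground truth for every
#' injected error and for per-cell species composition, so pipeline
#' outputs can be compared against what was actually simulated.
#'
#' The default synthetic country spans roughly 1,100 x 800 km. Its
#' interior sentinel coordinate (lat 20 N, lon 101 W) plays the role the
#' geographic-centre placeholder plays in real voucher databases.
#'
#' @name treecensus-synthetic
#' @keywords internal
NULL

#' The synthetic country boundary
#'
#' A single landmass with a concave coastal bay on the south coast and
#' two peninsulas (south-east and west), so out-of-boundary, near-shore
#' and sentinel cleaning rules are all exercisable on one fixture.
#'
#' @return a [poly_set()] with one feature, `Mainland`.
#' @export
synthetic_country <- function() {
  ring <- matrix(c(
    -106, 17,   -103, 17,   -103, 18.8, -102, 18.8, -102, 17,
    -99,  17,   -99, 15.2,  -97.5, 15.2, -97.5, 17,  -96, 17,
    -96,  23,   -101, 23,   -106, 23,   -106, 21,   -108, 21,
    -108, 20,   -106, 20), ncol = 2, byrow = TRUE)
  poly_set(list(list(name = "Mainland", rings = list(ring))))
}

#' The synthetic state partition
#'
#' Six rectangular states covering the country (they overhang the coast;
#' on land they partition it). Point-in-state uses the fixed feature
#' order, so shared borders resolve deterministically.
#'
#' @return a [poly_set()] of six named states.
#' @export
synthetic_states <- function() {
  rect <- function(x1, y1, x2, y2) {
    matrix(c(x1, y1, x2, y1, x2, y2, x1, y2), ncol = 2, byrow = TRUE)
  }
  poly_set(list(
    list(name = "Occidente Norte", rings = list(rect(-108.5, 19.5, -103.5, 25))),
    list(name = "Occidente Sur",   rings = list(rect(-108.5, 15,   -103.5, 19.5))),
    list(name = "Centro Norte",    rings = list(rect(-103.5, 19.5, -100,   25))),
    list(name = "Centro Sur",      rings = list(rect(-103.5, 15,   -100,   19.5))),
    list(name = "Oriente Norte",   rings = list(rect(-100,   19.5, -95.5,  25))),
    list(name = "Oriente Sur",     rings = list(rect(-100,   15,   -95.5,  19.5)))))
}

synthetic_state_codes <- c("Occidente Norte" = "OCN", "Occidente Sur" = "OCS",
                           "Centro Norte" = "CEN", "Centro Sur" = "CES",
                           "Oriente Norte" = "ORN", "Oriente Sur" = "ORS")

#' Default alias table for the synthetic states
#'
#' Maps full names and official codes to the canonical codes.
#'
#' @return a [state_alias_table()].
#' @export
synthetic_state_aliases <- function() {
  state_alias_table(unname(synthetic_state_codes),
                    synthetic_state_codes)
}

#' Synthetic protected areas
#'
#' Four reserves, one per tier, placed away from the engineered gap
#' hotspot so that an unprotected richness peak exists by construction.
#'
#' @return a [poly_set()] with `tier` attributes.
#' @export
synthetic_reserves <- function() {
  rect <- function(x1, y1, x2, y2) {
    matrix(c(x1, y1, x2, y1, x2, y2, x1, y2), ncol = 2, byrow = TRUE)
  }
  poly_set(list(
    list(name = "Reserva Federal Sierra Poniente", tier = "federal",
         rings = list(rect(-105.5, 18, -103.8, 21.5))),
    list(name = "Reserva Estatal Meseta Central", tier = "state",
         rings = list(rect(-101.5, 20.5, -100, 22.5))),
    list(name = "Reserva Municipal Costa Oriente", tier = "municipal",
         rings = list(rect(-96.8, 17.5, -96.2, 18.5))),
    list(name = "Reserva Privada Bosque Norte", tier = "private",
         rings = list(rect(-102.5, 22.2, -101.8, 22.9)))))
}

#' Default per-class coordinate-error injection rates
#'
#' Rates per input record for each error class a voucher database
#' typically carries; all classes are separable by construction.
#'
#' @return named list of probabilities.
#' @export
default_error_rates <- function() {
  list(centroid = 0.005, inverted = 0.005, sign = 0.005,
       low_precision = 0.02, offshore_near = 0.005, offshore_far = 0.005,
       duplicate = 0.02, state_corrupt = 0.02)
}

zero_error_rates <- function() {
  lapply(default_error_rates(), function(x) 0)
}

default_attribute_probs <- function() {
  list(endemic = 0.44, useful = 0.23,
       banked_incountry = 0.17, banked_dup_given_incountry = 0.75,
       banked_dup_given_not = 0.01,
       iucn = c(CR = 0.004, EN = 0.039, VU = 0.043, NT = 0.009, LC = 0.223,
                DD = 0.007, `LR/cd` = 0.001, `LR/nt` = 0.0014,
                `LR/lc` = 0.006, NE = 0.6666),
       nom059 = c(P = 0.0045, A = 0.0107, Pr = 0.0101, none = 0.9747),
       cites = c(I = 0.001, II = 0.032, `II/NC` = 0.0005, III = 0.0005,
                 none = 0.966))
}

sample_point_in_poly <- function(n, ps, bb = ps_bbox(ps)) {
  lon <- numeric(n); lat <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 16L)
    cx <- stats::runif(m, bb["xmin"], bb["xmax"])
    cy <- stats::runif(m, bb["ymin"], bb["ymax"])
    # the stated (4-dp) coordinates must be on land too, so rounding can
    # never push a clean record across the coastline
    ok <- point_in_poly_set(cx, cy, ps) &
      point_in_poly_set(round(cx, 4), round(cy, 4), ps)
    take <- min(sum(ok), n - got)
    if (take > 0) {
      lon[got + seq_len(take)] <- cx[ok][seq_len(take)]
      lat[got + seq_len(take)] <- cy[ok][seq_len(take)]
      got <- got + take
    }
  }
  list(lon = lon, lat = lat)
}

#' Build a synthetic scenario
#'
#' Generates the catalogue, the disc-based species range model (each
#' species a range centre and radius; an engineered hotspot clusters a
#' configurable number of species at one point), and bundles the polygon
#' layers, sentinel coordinate and cleaning configuration. All randomness
#' is governed by `seed`; the same seed gives byte-identical scenarios.
#'
#' @param seed integer seed.
#' @param n_species,n_genera,n_families taxonomy sizes (must nest:
#'   `n_families <= n_genera <= n_species`).
#' @param mean_records expected voucher records per species (each species
#'   gets at least one).
#' @param range_radius_km two-element range from which species range radii
#'   are drawn uniformly.
#' @param hotspot `NULL` or `list(lon=, lat=, n_species=, radius_km=)`:
#'   the first `n_species` catalogue species get their range centre at the
#'   hotspot point with the given radius, engineering a known richness
#'   peak.
#' @param attribute_probs marginal probabilities for the catalogue
#'   attributes (see `default_attribute_probs`); IUCN/NOM-059/CITES
#'   vectors must sum to 1.
#' @param error_rates per-class injection rates, see
#'   [default_error_rates()].
#' @param cell_km reference grid resolution for ground-truth richness.
#' @return object of class `synthetic_scenario`.
#' @export
make_scenario <- function(seed = 1,
                          n_species = 120,
                          n_genera = max(1L, round(n_species / 3)),
                          n_families = max(1L, round(n_species / 8)),
                          mean_records = 25,
                          range_radius_km = c(30, 150),
                          hotspot = list(lon = -98.3, lat = 19.6,
                                         n_species = min(30L, ceiling(n_species / 4)),
                                         radius_km = 15),
                          attribute_probs = default_attribute_probs(),
                          error_rates = default_error_rates(),
                          cell_km = 25) {
  if (n_genera > n_species || n_families > n_genera) {
    stop("taxonomy sizes must nest: n_families <= n_genera <= n_species")
  }
  if (!is.null(hotspot) && hotspot$n_species > n_species) {
    stop("hotspot n_species exceeds n_species")
  }
  set.seed(seed)
  boundary <- synthetic_country()
  states <- synthetic_states()
  reserves <- synthetic_reserves()

  genera <- sprintf("Arbogenus%03d", seq_len(n_genera))
  families <- sprintf("Familia%02dceae", seq_len(n_families))
  genus_family <- families[c(seq_len(n_families),
                             sample.int(n_families, n_genera - n_families,
                                        replace = TRUE))]
  species_genus <- genera[c(seq_len(n_genera),
                            sample.int(n_genera, n_species - n_genera,
                                       replace = TRUE))]
  binomial <- paste(species_genus, sprintf("arborea%04d", seq_len(n_species)))

  ap <- attribute_probs
  endemic <- stats::runif(n_species) < ap$endemic
  useful <- stats::runif(n_species) < ap$useful
  b_in <- stats::runif(n_species) < ap$banked_incountry
  b_dup <- ifelse(b_in, stats::runif(n_species) < ap$banked_dup_given_incountry,
                  stats::runif(n_species) < ap$banked_dup_given_not)
  iucn <- sample(names(ap$iucn), n_species, replace = TRUE, prob = ap$iucn)
  nom <- sample(names(ap$nom059), n_species, replace = TRUE, prob = ap$nom059)
  cit <- sample(names(ap$cites), n_species, replace = TRUE, prob = ap$cites)

  ctrs <- sample_point_in_poly(n_species, boundary)
  radii <- stats::runif(n_species, range_radius_km[1], range_radius_km[2])
  hot <- logical(n_species)
  if (!is.null(hotspot) && hotspot$n_species > 0) {
    hot[seq_len(hotspot$n_species)] <- TRUE
    ctrs$lon[hot] <- hotspot$lon
    ctrs$lat[hot] <- hotspot$lat
    radii[hot] <- hotspot$radius_km
  }
  n_rec <- 1L + stats::rpois(n_species, max(mean_records - 1, 0))

  # state membership of each range centre, for the catalogue states field
  st_idx <- which_feature(ctrs$lon, ctrs$lat, states)
  st_code <- unname(synthetic_state_codes[names(states)])[st_idx]

  entries <- data.frame(
    family = genus_family[match(species_genus, genera)],
    genus = species_genus, species = binomial,
    states = ifelse(is.na(st_code), "", st_code),
    endemic = endemic, iucn = iucn, nom059 = nom, cites = cit,
    banked_incountry = b_in, banked_duplicated = b_dup, useful = useful,
    stringsAsFactors = FALSE)
  cat <- catalogue(entries,
                   provenance = sprintf("synthetic scenario seed=%d", seed))

  structure(list(
    seed = seed, boundary = boundary, states = states, reserves = reserves,
    state_aliases = synthetic_state_aliases(),
    centroid = c(lat = 20, lon = -101),
    cleaning = cleaning_config(centroid_lat = 20, centroid_lon = -101),
    catalogue = cat,
    ranges = data.frame(species = binomial, center_lon = ctrs$lon,
                        center_lat = ctrs$lat, radius_km = radii,
                        n_records = n_rec, hotspot = hot,
                        stringsAsFactors = FALSE),
    hotspot = hotspot,
    cell_km = cell_km,
    grid = build_grid(boundary, cell_km),
    error_rates = error_rates),
    class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf("<synthetic_scenario> seed %d: %d species / %d genera / %d families, ~%d records\n",
              x$seed, nrow(x$catalogue$entries),
              length(unique(x$catalogue$entries$genus)),
              length(unique(x$catalogue$entries$family)),
              sum(x$ranges$n_records)))
  if (!is.null(x$hotspot)) {
    cat(sprintf("  hotspot: %d species at (%.2f, %.2f), radius %g km\n",
                x$hotspot$n_species, x$hotspot$lat, x$hotspot$lon,
                x$hotspot$radius_km))
  }
  invisible(x)
}

#' Sample voucher-style occurrence records from a scenario
#'
#' Each species contributes its configured number of records, drawn
#' uniformly in the disc around its range centre (rejected back onto
#' land); the first record of every species sits exactly at the range
#' centre, the way a type locality anchors real collections (and so an
#' engineered hotspot cell contains every hotspot species). Coordinates
#' are stated at 4 decimal places. Ground truth (clean record count and
#' per-cell species richness on the scenario's reference grid) is
#' attached as `attr(records, "ground_truth")`.
#'
#' @param scn a [make_scenario()] result.
#' @return occurrence record data.frame in raw status.
#' @export
sample_occurrences <- function(scn) {
  stopifnot(inherits(scn, "synthetic_scenario"))
  set.seed(scn$seed + 1000003L)
  crs <- scn$grid$crs
  rows <- vector("list", nrow(scn$ranges))
  for (i in seq_len(nrow(scn$ranges))) {
    r <- scn$ranges[i, ]
    n <- r$n_records
    c_xy <- project_xy(r$center_lon, r$center_lat, crs)
    lon <- numeric(n); lat <- numeric(n)
    lon[1] <- r$center_lon; lat[1] <- r$center_lat
    for (k in seq_len(n)[-1]) {
      placed <- FALSE
      for (try in seq_len(200)) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- r$radius_km * sqrt(stats::runif(1))
        ll <- unproject_xy(c_xy$x + rad * cos(ang), c_xy$y + rad * sin(ang), crs)
        if (point_in_poly_set(round(ll$lon, 4), round(ll$lat, 4),
                              scn$boundary)) {
          lon[k] <- ll$lon; lat[k] <- ll$lat
          placed <- TRUE
          break
        }
      }
      if (!placed) { lon[k] <- r$center_lon; lat[k] <- r$center_lat }
    }
    rows[[i]] <- data.frame(species = r$species, lon = round(lon, 4),
                            lat = round(lat, 4), stringsAsFactors = FALSE)
  }
  pts <- do.call(rbind, rows)
  st_idx <- which_feature(pts$lon, pts$lat, scn$states)
  recs <- occurrence_records(
    record_id = sprintf("syn%06d", seq_len(nrow(pts))),
    species = pts$species, lat = pts$lat, lon = pts$lon,
    state_raw = ifelse(is.na(st_idx), "Mar Abierto", names(scn$states)[st_idx]),
    coord_precision_dp = 4L)
  # ground truth: per-cell species richness tallied by direct bookkeeping
  p <- project_xy(recs$lon, recs$lat, crs)
  col <- pmin(floor((p$x - scn$grid$x0) / scn$grid$cell_km) + 1L, scn$grid$n_cols)
  row <- pmin(floor((p$y - scn$grid$y0) / scn$grid$cell_km) + 1L, scn$grid$n_rows)
  cell <- (row - 1L) * scn$grid$n_cols + col
  rich <- matrix(0L, scn$grid$n_rows, scn$grid$n_cols)
  tab <- tapply(recs$species, cell, function(s) length(unique(s)))
  idx <- as.integer(names(tab))
  rich[cbind((idx - 1L) %/% scn$grid$n_cols + 1L,
             (idx - 1L) %% scn$grid$n_cols + 1L)] <- as.integer(tab)
  attr(recs, "ground_truth") <- list(
    n_clean_records = nrow(recs),
    richness_ref = rich,
    grid = scn$grid,
    injections = data.frame(record_id = character(0), class = character(0),
                            separable = logical(0)))
  recs
}

outward_point <- function(lon, lat, boundary, crs, dist_km) {
  near <- boundary_distance(lon, lat, boundary, crs)
  p <- project_xy(lon, lat, crs)
  q <- project_xy(near$lon, near$lat, crs)
  ux <- q$x - p$x; uy <- q$y - p$y
  nrm <- sqrt(ux^2 + uy^2)
  if (nrm < 1e-9) return(NULL)
  unproject_xy(q$x + ux / nrm * dist_km, q$y + uy / nrm * dist_km, crs)
}

#' Inject coordinate-error classes into sampled records
#'
#' Each selected record is perturbed by exactly one error class (classes
#' draw from disjoint record pools, so they are separable); originals and
#' class labels are recorded in the ground-truth bookkeeping
#' (`attr(records, "ground_truth")$injections`). Injected classes mirror
#' the cleaning rules: the centroid sentinel, inverted lat/lon, longitude
#' sign loss, low stated precision (only records well inland are
#' eligible, so rounding cannot push them offshore), offshore points
#' within and beyond the snap distance, exact duplicates, and state-name
#' corruption (case/spacing variants and official codes, all mappable
#' through the alias table).
#'
#' @param records output of [sample_occurrences()].
#' @param scn the scenario the records came from.
#' @return perturbed records with updated ground-truth bookkeeping.
#' @export
inject_errors <- function(records, scn) {
  stopifnot(inherits(scn, "synthetic_scenario"))
  set.seed(scn$seed + 2000003L)
  gt <- attr(records, "ground_truth")
  rates <- scn$error_rates
  n <- nrow(records)
  crs <- scn$grid$crs
  pool <- seq_len(n)
  marks <- list()
  draw <- function(k, eligible = pool) {
    k <- min(k, length(eligible))
    if (k == 0) return(integer(0))
    picked <- if (length(eligible) == 1) eligible else sample(eligible, k)
    pool <<- setdiff(pool, picked)
    picked
  }
  n_of <- function(rate) round(rate * n)

  # centroid sentinel, printed at 1 dp
  idx <- draw(n_of(rates$centroid))
  for (i in idx) {
    records$lat[i] <- scn$centroid["lat"]
    records$lon[i] <- scn$centroid["lon"]
    records$coord_precision_dp[i] <- 1L
  }
  marks$centroid <- idx

  # inverted coordinates: lat written as lon and vice versa
  idx <- draw(n_of(rates$inverted))
  amb <- logical(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    tmp <- records$lat[i]
    records$lat[i] <- records$lon[i]
    records$lon[i] <- tmp
    amb[j] <- abs(records$lat[i]) <= 90 &&
      point_in_poly_set(records$lon[i], records$lat[i], scn$boundary)
  }
  marks$inverted <- idx
  marks_inverted_ambiguous <- idx[amb]

  # longitude lacking the negative (western) sign
  idx <- draw(n_of(rates$sign))
  records$lon[idx] <- abs(records$lon[idx])
  marks$sign <- idx

  # low stated precision: only records > 12 km inland are eligible so the
  # 1-dp rounding (< ~8 km displacement) cannot interact with other rules
  inland_ok <- pool[point_in_poly_set(records$lon[pool], records$lat[pool],
                                      scn$boundary)]
  if (length(inland_ok)) {
    d <- boundary_distance(records$lon[inland_ok], records$lat[inland_ok],
                           scn$boundary, crs)$dist
    inland_ok <- inland_ok[d > 12]
    # rounding two same-species records onto the same 1-dp point would turn
    # them into duplicates; keep the class separable from deduplication
    key1 <- paste(records$species[inland_ok],
                  round(records$lat[inland_ok], 1),
                  round(records$lon[inland_ok], 1))
    inland_ok <- inland_ok[!duplicated(key1)]
  }
  idx <- draw(n_of(rates$low_precision), inland_ok)
  records$lat[idx] <- round(records$lat[idx], 1)
  records$lon[idx] <- round(records$lon[idx], 1)
  records$coord_precision_dp[idx] <- 1L
  marks$low_precision <- idx

  # offshore within the snap distance
  idx <- draw(n_of(rates$offshore_near))
  keep <- logical(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    np <- outward_point(records$lon[i], records$lat[i], scn$boundary, crs,
                        stats::runif(1, 0.2, 0.8))
    if (!is.null(np) && !point_in_poly_set(np$lon, np$lat, scn$boundary) &&
        boundary_distance(np$lon, np$lat, scn$boundary, crs)$dist <= 0.95) {
      records$lon[i] <- round(np$lon, 4)
      records$lat[i] <- round(np$lat, 4)
      keep[j] <- TRUE
    }
  }
  marks$offshore_near <- idx[keep]
  pool <- c(pool, idx[!keep])  # failed placements stay clean records

  # offshore beyond the snap distance
  idx <- draw(n_of(rates$offshore_far))
  keep <- logical(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    np <- outward_point(records$lon[i], records$lat[i], scn$boundary, crs,
                        stats::runif(1, 5, 40))
    if (!is.null(np) && !point_in_poly_set(np$lon, np$lat, scn$boundary) &&
        boundary_distance(np$lon, np$lat, scn$boundary, crs)$dist > 1.5) {
      records$lon[i] <- round(np$lon, 4)
      records$lat[i] <- round(np$lat, 4)
      keep[j] <- TRUE
    }
  }
  marks$offshore_far <- idx[keep]
  pool <- c(pool, idx[!keep])

  # state-name corruption (still resolvable through the alias table)
  idx <- draw(n_of(rates$state_corrupt))
  for (i in idx) {
    nm <- records$state_raw[i]
    records$state_raw[i] <- switch(1L + (i %% 3L),
      toupper(nm), paste0("  ", nm, "  "),
      {code <- synthetic_state_codes[nm]; if (is.na(code)) toupper(nm) else unname(code)})
  }
  marks$state_corrupt <- idx

  # exact duplicates of untouched records, appended at the end
  idx <- draw(n_of(rates$duplicate))
  if (length(idx)) {
    dup <- records[idx, , drop = FALSE]
    dup$record_id <- sprintf("dup%06d", seq_along(idx))
    records <- rbind(records, dup)
  }
  marks$duplicate <- idx

  inj <- do.call(rbind, lapply(names(marks), function(cl) {
    if (!length(marks[[cl]])) return(NULL)
    data.frame(record_id = if (cl == "duplicate")
                 sprintf("dup%06d", seq_along(marks[[cl]]))
               else records$record_id[marks[[cl]]],
               class = cl,
               separable = if (cl == "inverted")
                 !(marks[[cl]] %in% marks_inverted_ambiguous)
               else TRUE,
               stringsAsFactors = FALSE)
  }))
  gt$injections <- if (is.null(inj))
    data.frame(record_id = character(0), class = character(0),
               separable = logical(0)) else inj
  gt$n_injected <- vapply(marks, length, integer(1))
  attr(records, "ground_truth") <- gt
  rownames(records) <- NULL
  records
}

#' Write a full scenario to disk in the pipeline's input formats
#'
#' Emits the occurrence CSV (Darwin-Core-style columns, coordinates
#' printed at their stated precision), the catalogue in appendix dialect,
#' boundary/states/reserves GeoJSON, and the ground-truth bookkeeping as
#' JSON.
#'
#' @param scn a [make_scenario()] result.
#' @param records sampled (optionally error-injected) records.
#' @param dir output directory (created if needed).
#' @return invisibly, named vector of paths.
#' @export
write_scenario <- function(scn, records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(occurrences = file.path(dir, "occurrences.csv"),
             catalogue = file.path(dir, "catalogue.txt"),
             boundary = file.path(dir, "boundary.geojson"),
             states = file.path(dir, "states.geojson"),
             reserves = file.path(dir, "reserves.geojson"),
             ground_truth = file.path(dir, "ground_truth.json"))
  dp <- pmax(records$coord_precision_dp, 0L)
  fmt <- function(x) vapply(seq_along(x), function(i)
    formatC(x[i], format = "f", digits = dp[i]), "")
  utils::write.csv(data.frame(id = records$record_id,
                              scientificName = records$species,
                              decimalLatitude = fmt(records$lat),
                              decimalLongitude = fmt(records$lon),
                              stateProvince = records$state_raw,
                              stringsAsFactors = FALSE),
                   paths["occurrences"], row.names = FALSE)
  write_catalogue(scn$catalogue, paths["catalogue"])
  write_poly_geojson(scn$boundary, paths["boundary"])
  write_poly_geojson(scn$states, paths["states"])
  write_poly_geojson(scn$reserves, paths["reserves"])
  gt <- attr(records, "ground_truth")
  jsonlite::write_json(list(
    seed = scn$seed,
    n_clean_records = gt$n_clean_records,
    n_injected = as.list(gt$n_injected),
    injections = gt$injections,
    richness_ref = gt$richness_ref), paths["ground_truth"],
    auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
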