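#' Coordinate cleaning of georeferenced occurrence records
#'
#' Herbarium voucher records carry a specific, well-known set of
#' georeferencing errors. The cleaning pipeline applies four rules in a
#' fixed order, then normalises state names and removes duplicates:
#'
#' 1. records pointing at the country's geographic-centre sentinel
#'    coordinate are deleted (the sentinel is a data-entry placeholder);
#' 2. records outside the country boundary are repaired when one of the
#'    two named transcription errors explains them — inverted lat/lon, or a
#'    longitude missing its negative (western) sign — trying swap, sign
#'    negation, then both, and accepting the first candidate that falls on
#'    land; unrepairable records farther than the snap distance from land
#'    are deleted;
#' 3. records still offshore but within the snap distance (default 1 km)
#'    are moved to the nearest point inside the boundary;
#' 4. records whose stated coordinate precision is at or below the
#'    decimal-place threshold (default 1 dp, roughly 10 km) are flagged,
#'    deleted or kept according to policy (default: flagged, preserving
#'    the audit trail that a manual review would have produced).
#'
#' The centroid rule runs before the out-of-boundary rule because the
#' sentinel lies inside the country and would otherwise survive. Every
#' record ends in exactly one terminal status (kept, repaired, moved,
#' flagged, deleted) and the [cleaning_report()] partitions the input
#' exactly; the full pipeline is idempotent on its own output.
#'
#' @name treecensus-cleaning
#' @keywords internal
NULL

#' Cleaning configuration
#'
#' @param centroid_lat,centroid_lon the country-centre sentinel coordinate
#'   in decimal degrees (defaults: 23 N, 102 W).
#' @param centroid_tol match tolerance in degrees around the sentinel;
#'   the default 0.005 matches the sentinel as printed at one decimal or
#'   fewer but not nearby genuine localities.
#' @param max_snap_km offshore records within this distance of land are
#'   moved onto it; farther ones are deleted (default 1 km).
#' @param snap_epsilon_km how far inside the boundary a snapped point is
#'   nudged (default 0.01 km).
#' @param precision_dp_max stated decimal places at or below which a
#'   coordinate counts as low precision (default 1, i.e. coarser than
#'   roughly 10 km).
#' @param low_precision_policy `"flag"` (default), `"delete"` or `"keep"`.
#' @param attempt_repairs try the inverted/sign repairs before deleting
#'   out-of-boundary records (default TRUE).
#' @return an object of class `cleaning_config`.
#' @export
cleaning_config <- function(centroid_lat = 23, centroid_lon = -102,
                            centroid_tol = 0.005,
                            max_snap_km = 1, snap_epsilon_km = 0.01,
                            precision_dp_max = 1,
                            low_precision_policy = c("flag", "delete", "keep"),
                            attempt_repairs = TRUE) {
  low_precision_policy <- match.arg(low_precision_policy)
  stopifnot(centroid_tol > 0, max_snap_km > 0, snap_epsilon_km > 0,
            precision_dp_max >= 0)
  structure(list(centroid_lat = centroid_lat, centroid_lon = centroid_lon,
                 centroid_tol = centroid_tol, max_snap_km = max_snap_km,
                 snap_epsilon_km = snap_epsilon_km,
                 precision_dp_max = precision_dp_max,
                 low_precision_policy = low_precision_policy,
                 attempt_repairs = isTRUE(attempt_repairs)),
            class = "cleaning_config")
}

count_decimal_places <- function(txt) {
  txt <- trimws(txt)
  has_dot <- grepl(".", txt, fixed = TRUE)
  dp <- integer(length(txt))
  frac <- sub("^[^.]*\\.", "", txt[has_dot])
  dp[has_dot] <- nchar(sub("[^0-9].*$", "", frac))
  dp
}

#' Read occurrence records from Darwin-Core-style delimited text
#'
#' Coordinates are parsed from their text form so the stated precision
#' (number of printed decimal places) is preserved; trailing zeros count
#' only if printed. A coordinate that does not parse as a number is an
#' error naming the offending line.
#'
#' @param path delimited text file with at least the columns
#'   `scientificName`, `decimalLatitude`, `decimalLongitude`,
#'   `stateProvince`; an `id` or `recordNumber` column is used as the
#'   record id when present.
#' @param delim field delimiter (default comma).
#' @return a data.frame of occurrence records with cleaning-state columns
#'   (`status = "raw"`, empty `cleaning_note`).
#' @export
read_occurrences <- function(path, delim = ",") {
  if (!file.exists(path)) stop("occurrence file not found: ", path)
  raw <- utils::read.table(path, sep = delim, header = TRUE,
                           stringsAsFactors = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "", encoding = "UTF-8")
  need <- c("scientificName", "decimalLatitude", "decimalLongitude",
            "stateProvince")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("occurrence file lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  lat <- suppressWarnings(as.numeric(raw$decimalLatitude))
  lon <- suppressWarnings(as.numeric(raw$decimalLongitude))
  bad <- which(is.na(lat) | is.na(lon))
  if (length(bad)) {
    stop("unparseable coordinate on line ", bad[1] + 1L, ": '",
         raw$decimalLatitude[bad[1]], "', '", raw$decimalLongitude[bad[1]], "'")
  }
  id <- if (!is.null(raw$id)) raw$id
        else if (!is.null(raw$recordNumber)) raw$recordNumber
        else sprintf("rec%06d", seq_len(nrow(raw)))
  occurrence_records(id, raw$scientificName, lat, lon, raw$stateProvince,
                     coord_precision_dp = pmin(
                       count_decimal_places(raw$decimalLatitude),
                       count_decimal_places(raw$decimalLongitude)))
}

#' Assemble occurrence records from vectors
#'
#' @param record_id,species,lat,lon,state_raw record fields;
#'   `coord_precision_dp` is the stated number of decimal places.
#' @param coord_precision_dp integer vector of stated decimal places.
#' @return occurrence record data.frame in raw status.
#' @export
occurrence_records <- function(record_id, species, lat, lon, state_raw,
                               coord_precision_dp = 4L) {
  n <- length(species)
  data.frame(record_id = as.character(record_id), species = species,
             lat = as.numeric(lat), lon = as.numeric(lon),
             lat_orig = NA_real_, lon_orig = NA_real_,
             state_raw = as.character(state_raw),
             state_std = NA_character_,
             coord_precision_dp = as.integer(rep_len(coord_precision_dp, n)),
             status = "raw", cleaning_note = "",
             stringsAsFactors = FALSE)
}

#' Write occurrence records back to Darwin-Core-style CSV
#'
#' @param records occurrence data.frame.
#' @param path output file.
#' @param dp decimal places used to print coordinates (default 4); records
#'   with a coarser stated precision are printed at that precision.
#' @return invisibly, `path`.
#' @export
write_occurrences <- function(records, path, dp = 4) {
  dp_out <- pmin(dp, pmax(records$coord_precision_dp, 0L))
  fmt <- function(x, d) {
    vapply(seq_along(x), function(i) formatC(x[i], format = "f",
                                             digits = d[i]), "")
  }
  out <- data.frame(id = records$record_id,
                    scientificName = records$species,
                    decimalLatitude = fmt(records$lat, dp_out),
                    decimalLongitude = fmt(records$lon, dp_out),
                    stateProvince = records$state_raw,
                    stateCode = records$state_std,
                    status = records$status,
                    cleaningNote = records$cleaning_note,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

alive <- function(records) !(records$status %in% "deleted")

#' Rule: delete records at the country-centre sentinel
#'
#' @param records occurrence data.frame.
#' @param cfg a [cleaning_config()].
#' @return records with sentinel hits set to `deleted` (note `centroid`).
#' @export
rule_centroid <- function(records, cfg = cleaning_config()) {
  hit <- alive(records) &
    abs(records$lat - cfg$centroid_lat) <= cfg$centroid_tol &
    abs(records$lon - cfg$centroid_lon) <= cfg$centroid_tol
  records$status[hit] <- "deleted"
  records$cleaning_note[hit] <- "centroid"
  records
}

repair_candidates <- function(lat, lon) {
  list(`repair:inverted` = c(lon, lat),
       `repair:sign` = c(lat, -lon),
       `repair:inverted+sign` = c(lon, -lat))
}

#' Rule: out-of-boundary deletion with transcription repairs
#'
#' Points inside the boundary are kept. For outside points (with repairs
#' enabled) the candidates lat/lon swap, longitude sign negation, and
#' their composition are tried in that order and the first candidate on
#' land is accepted as a repair; the original coordinates are retained in
#' `lat_orig`/`lon_orig`. Unrepairable points farther than `max_snap_km`
#' from land are deleted (note `outside`); nearer ones are left for
#' [rule_coastal_snap()] (note `offshore_near`).
#'
#' @param records occurrence data.frame.
#' @param boundary country land area as a [poly_set()].
#' @param cfg a [cleaning_config()].
#' @param crs projection used for the distance-to-land test; defaults to
#'   the boundary centre.
#' @return updated records.
#' @export
rule_outside_boundary <- function(records, boundary, cfg = cleaning_config(),
                                  crs = NULL) {
  stopifnot(inherits(boundary, "poly_set"))
  act <- which(alive(records) & records$status != "moved")
  if (!length(act)) return(records)
  inside <- point_in_poly_set(records$lon[act], records$lat[act], boundary)
  records$status[act[inside & records$status[act] == "raw"]] <- "kept"
  out_idx <- act[!inside]
  for (i in out_idx) {
    lat0 <- records$lat[i]; lon0 <- records$lon[i]
    repaired <- FALSE
    if (cfg$attempt_repairs) {
      for (tag in names(repair_candidates(lat0, lon0))) {
        cand <- repair_candidates(lat0, lon0)[[tag]]
        if (abs(cand[1]) <= 90 &&
            point_in_poly_set(cand[2], cand[1], boundary)) {
          records$lat_orig[i] <- lat0; records$lon_orig[i] <- lon0
          records$lat[i] <- cand[1]; records$lon[i] <- cand[2]
          records$status[i] <- "repaired"
          records$cleaning_note[i] <- tag
          repaired <- TRUE
          break
        }
      }
    }
    if (!repaired) {
      d <- boundary_distance(lon0, lat0, boundary, crs)$dist
      if (d > cfg$max_snap_km) {
        records$status[i] <- "deleted"
        records$cleaning_note[i] <- "outside"
      } else {
        records$status[i] <- "raw"
        records$cleaning_note[i] <- "offshore_near"
      }
    }
  }
  records
}

#' Rule: snap near-shore records onto land
#'
#' Records still outside the boundary but within `max_snap_km` of it are
#' moved to the nearest boundary point, nudged inside by
#' `snap_epsilon_km`; the displacement never exceeds
#' `max_snap_km + snap_epsilon_km`.
#'
#' @inheritParams rule_outside_boundary
#' @return updated records (moved points carry note `coastal_snap`).
#' @export
rule_coastal_snap <- function(records, boundary, cfg = cleaning_config(),
                              crs = NULL) {
  if (is.null(crs)) {
    bb <- ps_bbox(boundary)
    crs <- local_crs((bb["xmin"] + bb["xmax"]) / 2,
                     (bb["ymin"] + bb["ymax"]) / 2)
  }
  act <- which(alive(records) & records$status != "moved")
  if (!length(act)) return(records)
  outside <- !point_in_poly_set(records$lon[act], records$lat[act], boundary)
  for (i in act[outside]) {
    near <- boundary_distance(records$lon[i], records$lat[i], boundary, crs)
    if (near$dist > cfg$max_snap_km) next
    p <- project_xy(records$lon[i], records$lat[i], crs)
    q <- project_xy(near$lon, near$lat, crs)
    ux <- q$x - p$x; uy <- q$y - p$y
    nrm <- sqrt(ux^2 + uy^2)
    dirs <- if (nrm < 1e-9) {
      # point effectively on the boundary: probe the compass for land
      a <- seq(0, 2 * pi, length.out = 9)[-9]
      cbind(cos(a), sin(a))
    } else {
      rbind(c(ux, uy) / nrm)
    }
    placed <- FALSE
    for (eps in c(cfg$snap_epsilon_km, cfg$snap_epsilon_km / 10)) {
      for (k in seq_len(nrow(dirs))) {
        cand <- unproject_xy(q$x + dirs[k, 1] * eps,
                             q$y + dirs[k, 2] * eps, crs)
        if (point_in_poly_set(cand$lon, cand$lat, boundary)) {
          records$lat_orig[i] <- records$lat[i]
          records$lon_orig[i] <- records$lon[i]
          records$lat[i] <- cand$lat; records$lon[i] <- cand$lon
          records$status[i] <- "moved"
          records$cleaning_note[i] <- "coastal_snap"
          placed <- TRUE
          break
        }
      }
      if (placed) break
    }
    if (!placed) {
      records$status[i] <- "deleted"
      records$cleaning_note[i] <- "outside"
    }
  }
  records
}

#' Rule: handle low-precision coordinates
#'
#' @inheritParams rule_centroid
#' @return updated records per the configured policy (`flag`, `delete`
#'   or `keep`).
#' @export
rule_low_precision <- function(records, cfg = cleaning_config()) {
  if (cfg$low_precision_policy == "keep") return(records)
  hit <- alive(records) & records$coord_precision_dp <= cfg$precision_dp_max
  if (cfg$low_precision_policy == "delete") {
    records$status[hit] <- "deleted"
    records$cleaning_note[hit] <- "low_precision"
  } else {
    records$status[hit] <- "flagged"
    records$cleaning_note[hit] <- "low_precision"
  }
  records
}

canonical_state_key <- function(x) {
  x <- tolower(trimws(gsub("[[:space:]]+", " ", x)))
  out <- suppressWarnings(iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT"))
  out[is.na(out)] <- x[is.na(out)]
  gsub("[^a-z0-9 ]", "", out)
}

#' Build a state alias table
#'
#' @param codes canonical state codes.
#' @param aliases named character vector: names are raw spellings (matched
#'   case-, whitespace- and diacritic-insensitively), values canonical
#'   codes. Codes themselves always map to themselves.
#' @return named character vector keyed by canonical form.
#' @export
state_alias_table <- function(codes, aliases = character(0)) {
  tab <- c(stats::setNames(codes, codes), aliases)
  stats::setNames(as.character(tab), canonical_state_key(names(tab)))
}

#' Standardise state names and remove duplicate records
#'
#' Raw state names are mapped to canonical codes through the alias table
#' (unmappable names become `"unknown"` with a warning, the record is
#' kept). A duplicate is a record identical on the key (species binomial,
#' latitude and longitude rounded to 4 decimals, canonical state); the
#' first occurrence in input order is kept, later ones are deleted with
#' note `duplicate`.
#'
#' @param records occurrence data.frame (individually cleaned).
#' @param aliases a [state_alias_table()].
#' @return updated records.
#' @export
normalize_and_dedup <- function(records, aliases) {
  key <- canonical_state_key(records$state_raw)
  records$state_std <- unname(aliases[key])
  un <- is.na(records$state_std)
  if (any(un & alive(records))) {
    warning("unmappable state name(s): ",
            paste(unique(records$state_raw[un & alive(records)]), collapse = ", "))
  }
  records$state_std[un] <- "unknown"
  liv <- which(alive(records))
  dkey <- paste(records$species[liv],
                sprintf("%.4f", round(records$lat[liv], 4)),
                sprintf("%.4f", round(records$lon[liv], 4)),
                records$state_std[liv], sep = "|")
  dup <- liv[duplicated(dkey)]
  records$status[dup] <- "deleted"
  records$cleaning_note[dup] <- "duplicate"
  records
}

#' Per-rule cleaning report
#'
#' Tallies every terminal status so the input is partitioned exactly:
#' `n_input = n_kept + n_deleted_centroid + n_deleted_outside +
#' n_deleted_lowprecision + n_deduplicated` (kept counts repaired, moved
#' and flagged records, which remain in the output).
#'
#' @param records cleaned occurrence data.frame.
#' @return object of class `cleaning_report`.
#' @export
cleaning_report <- function(records) {
  note <- records$cleaning_note
  del <- records$status == "deleted"
  structure(list(
    n_input = nrow(records),
    n_kept = sum(alive(records)),
    n_deleted_centroid = sum(del & note == "centroid"),
    n_deleted_outside = sum(del & note == "outside"),
    n_deleted_lowprecision = sum(del & note == "low_precision"),
    n_deduplicated = sum(del & note == "duplicate"),
    n_repaired_inverted = sum(note == "repair:inverted"),
    n_repaired_sign = sum(note == "repair:sign"),
    n_repaired_both = sum(note == "repair:inverted+sign"),
    n_moved_coastal = sum(note == "coastal_snap"),
    n_flagged_lowprecision = sum(records$status == "flagged")),
    class = "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("<cleaning_report>\n")
  cat(sprintf("  input %d -> kept %d (repaired %d inverted / %d sign / %d both; moved %d; flagged %d)\n",
              x$n_input, x$n_kept, x$n_repaired_inverted, x$n_repaired_sign,
              x$n_repaired_both, x$n_moved_coastal, x$n_flagged_lowprecision))
  cat(sprintf("  deleted: centroid %d, outside %d, low precision %d, duplicates %d\n",
              x$n_deleted_centroid, x$n_deleted_outside,
              x$n_deleted_lowprecision, x$n_deduplicated))
  invisible(x)
}

#' @export
as.list.cleaning_report <- function(x, ...) unclass(x)

#' Run the full cleaning pipeline
#'
#' Fixed rule order: centroid sentinel, out-of-boundary with repairs,
#' coastal snap, low precision, then state normalisation and
#' deduplication. Idempotent: re-running on the kept output changes no
#' coordinates and deletes nothing.
#'
#' @param records occurrence data.frame (see [read_occurrences()]).
#' @param boundary country land [poly_set()].
#' @param cfg a [cleaning_config()].
#' @param aliases a [state_alias_table()]; when `NULL`, raw state names map
#'   to themselves.
#' @return list with `records` (all records, terminal statuses), `kept`
#'   (the surviving subset) and `report` (a [cleaning_report()]).
#' @export
clean_pipeline <- function(records, boundary, cfg = cleaning_config(),
                           aliases = NULL) {
  if (is.null(aliases)) {
    aliases <- state_alias_table(sort(unique(records$state_raw)))
  }
  bb <- ps_bbox(boundary)
  crs <- local_crs((bb["xmin"] + bb["xmax"]) / 2, (bb["ymin"] + bb["ymax"]) / 2)
  # statuses are recomputed from scratch so the pipeline is idempotent:
  # a cleaned record set passes through unchanged
  records$status <- "raw"
  records$cleaning_note <- ""
  records <- rule_centroid(records, cfg)
  records <- rule_outside_boundary(records, boundary, cfg, crs)
  records <- rule_coastal_snap(records, boundary, cfg, crs)
  records <- rule_low_precision(records, cfg)
  records <- normalize_and_dedup(records, aliases)
  records$status[records$status == "raw"] <- "kept"
  list(records = records,
       kept = records[alive(records), , drop = FALSE],
       report = cleaning_report(records))
}
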