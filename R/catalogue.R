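#' Species catalogue: data model, validation and tabulation
#'
#' A catalogue holds one row per native tree species with its taxonomy and
#' all conservation and use attributes: endemism, IUCN Red List category
#' (v3.1 plus the legacy v2.3 `LR/*` codes, kept distinct), the national
#' NOM-059 protection category, CITES annex, seed-banking flags (in-country
#' collection and duplicated collection, two distinct collections whose
#' union defines "banked") and a useful-plant flag.
#'
#' @name treecensus-catalogue
#' @keywords internal
NULL

#' Controlled vocabularies for catalogue attributes
#'
#' `NE` marks species not evaluated by the IUCN; `none` marks absence of a
#' NOM-059 category or CITES annex. Legacy v2.3 Red List codes are retained
#' verbatim and are never remapped to v3.1 categories.
#'
#' @return character vector of admissible codes.
#' @export
iucn_levels <- function() {
  c("CR", "EN", "VU", "NT", "LC", "DD", "LR/cd", "LR/nt", "LR/lc", "NE")
}

#' @rdname iucn_levels
#' @export
nom059_levels <- function() c("P", "A", "Pr", "none")

#' @rdname iucn_levels
#' @export
cites_levels <- function() c("I", "II", "II/NC", "III", "none")

catalogue_columns <- c("family", "genus", "species", "states", "endemic",
                       "iucn", "nom059", "cites", "banked_incountry",
                       "banked_duplicated", "useful")

#' Construct and validate a species catalogue
#'
#' @param entries data.frame with columns `family`, `genus`, `species`
#'   (binomial), `states` (comma-separated state codes, may be empty),
#'   logical `endemic`, `iucn`, `nom059`, `cites` codes, logical
#'   `banked_incountry`, `banked_duplicated`, `useful`.
#' @param provenance free-text metadata recorded with the catalogue.
#' @return an object of class `catalogue`.
#' @export
catalogue <- function(entries, provenance = "") {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  missing_cols <- setdiff(catalogue_columns, names(entries))
  if (length(missing_cols)) {
    stop("catalogue entries lack columns: ", paste(missing_cols, collapse = ", "))
  }
  entries <- entries[catalogue_columns]
  if (nrow(entries) == 0) stop("catalogue has no entries")
  if (any(!nzchar(entries$family))) stop("empty family name in catalogue")
  first_epithet <- sub(" .*$", "", entries$species)
  bad_genus <- which(first_epithet != entries$genus)
  if (length(bad_genus)) {
    stop("genus does not match first epithet of binomial for: ",
         paste(utils::head(entries$species[bad_genus], 5), collapse = ", "))
  }
  dup <- entries$species[duplicated(entries$species)]
  if (length(dup)) {
    stop("duplicate binomials in catalogue: ",
         paste(unique(dup), collapse = ", "))
  }
  check_codes <- function(values, levels, what) {
    bad <- setdiff(unique(values), levels)
    if (length(bad)) {
      stop("unknown ", what, " code(s): ", paste(bad, collapse = ", "))
    }
  }
  check_codes(entries$iucn, iucn_levels(), "IUCN")
  check_codes(entries$nom059, nom059_levels(), "NOM-059")
  check_codes(entries$cites, cites_levels(), "CITES")
  for (col in c("endemic", "banked_incountry", "banked_duplicated", "useful")) {
    entries[[col]] <- as.logical(entries[[col]])
    if (anyNA(entries[[col]])) stop("non-logical values in column ", col)
  }
  rownames(entries) <- NULL
  structure(list(entries = entries, provenance = provenance),
            class = "catalogue")
}

#' @export
print.catalogue <- function(x, ...) {
  e <- x$entries
  cat(sprintf(paste0("<catalogue> %d species, %d genera, %d families\n",
                     "  endemic %d | useful %d | threatened %d | banked %d\n"),
              nrow(e), length(unique(e$genus)), length(unique(e$family)),
              sum(e$endemic), sum(e$useful), sum(is_threatened(x)),
              sum(is_banked(x))))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Threatened and banked status of catalogue species
#'
#' A species is *threatened* if and only if its IUCN Red List category is
#' Critically Endangered (CR), Endangered (EN) or Vulnerable (VU); the
#' legacy `LR/*` codes and NT/LC/DD/NE are not threatened. A species is
#' *banked* if it is held in the in-country seed bank, in the duplicated
#' collection abroad, or both (set union).
#'
#' @param x a `catalogue`, a data.frame of entries, or (for
#'   `is_threatened`) a character vector of IUCN codes.
#' @return logical vector, one element per species.
#' @export
is_threatened <- function(x) {
  codes <- if (inherits(x, "catalogue")) x$entries$iucn
           else if (is.data.frame(x)) x$iucn
           else as.character(x)
  codes %in% c("CR", "EN", "VU")
}

#' @rdname is_threatened
#' @export
is_banked <- function(x) {
  e <- if (inherits(x, "catalogue")) x$entries else x
  as.logical(e$banked_incountry) | as.logical(e$banked_duplicated)
}

#' Percentages with half-away-from-zero rounding
#'
#' Shared rounding policy for every printed percentage in the summary
#' tables: `100 * count / total`, rounded half away from zero to `dp`
#' decimals (so 43.81 prints as 44 at 0 dp and 66.666 as 66.67 at 2 dp).
#' Banker's rounding, R's default, is deliberately not used.
#'
#' @param count,total numeric; `total` must be positive. `count` may exceed
#'   `total` (subset denominators are legitimate).
#' @param dp decimals to keep.
#' @return numeric vector of percentages.
#' @export
percent <- function(count, total, dp = 1) {
  if (any(total == 0)) stop("percent(): total must be non-zero")
  x <- 100 * count / total
  sign(x) * floor(abs(x) * 10^dp + 0.5) / 10^dp
}

rank_table <- function(names, denominator, dp = 1) {
  tab <- table(names)
  df <- data.frame(name = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  # deterministic: count descending, then alphabetical within ties
  df <- df[order(-df$count, df$name), , drop = FALSE]
  df$percent <- percent(df$count, denominator, dp)
  df$rank <- rank(-df$count, ties.method = "min")
  rownames(df) <- NULL
  df[c("rank", "name", "count", "percent")]
}

category_table <- function(codes, levels, absent, denominator, dp = 2) {
  lv <- setdiff(levels, absent)
  counts <- vapply(lv, function(l) sum(codes == l), integer(1))
  data.frame(category = lv, count = as.integer(counts),
             percent = percent(counts, denominator, dp),
             row.names = NULL, stringsAsFactors = FALSE)
}

banked_row <- function(e, label) {
  n <- nrow(e)
  inc <- sum(e$banked_incountry)
  dup <- sum(e$banked_duplicated)
  tot <- sum(e$banked_incountry | e$banked_duplicated)
  data.frame(category = label, total = n,
             incountry = inc, incountry_pct = percent(inc, n, 1),
             duplicated = dup, duplicated_pct = percent(dup, n, 1),
             banked = tot, banked_pct = percent(tot, n, 1),
             stringsAsFactors = FALSE)
}

#' Tabulate a catalogue into inventory summary tables
#'
#' Produces the ranked family and genus tables (overall and endemic-only,
#' percentages at 1 dp against the total or endemic species count), the
#' conservation-status tables (IUCN / NOM-059 / CITES counts with
#' percentages at 2 dp against total species) and the seed-banking table
#' (per category row — overall, endemic, useful, threatened — counts and
#' percentages at 1 dp against each row's own category total). Ties in the
#' ranked tables share a rank and are listed alphabetically.
#'
#' @param cat a validated [catalogue()].
#' @param top_k how many leading families to pool for the
#'   `top_family_share_pct` headline figure (default 10).
#' @return an object of class `catalogue_summary`.
#' @export
tabulate_catalogue <- function(cat, top_k = 10) {
  stopifnot(inherits(cat, "catalogue"))
  e <- cat$entries
  n <- nrow(e)
  en <- e[e$endemic, , drop = FALSE]
  n_end <- nrow(en)
  fam <- rank_table(e$family, n)
  gen <- rank_table(e$genus, n)
  fam_end <- if (n_end) rank_table(en$family, n_end) else fam[0, ]
  gen_end <- if (n_end) rank_table(en$genus, n_end) else gen[0, ]
  thr <- e[is_threatened(e), , drop = FALSE]
  usf <- e[e$useful, , drop = FALSE]
  banked <- do.call(rbind, list(
    banked_row(e, "overall"),
    if (n_end) banked_row(en, "endemic") else NULL,
    if (nrow(usf)) banked_row(usf, "useful") else NULL,
    if (nrow(thr)) banked_row(thr, "threatened") else NULL))
  top_k_use <- min(top_k, nrow(fam))
  structure(list(
    n_species = n,
    n_genera = length(unique(e$genus)),
    n_families = length(unique(e$family)),
    n_endemic = n_end,
    n_useful = nrow(usf),
    n_threatened = nrow(thr),
    n_banked = sum(is_banked(e)),
    family_table = fam,
    genus_table = gen,
    family_table_endemic = fam_end,
    genus_table_endemic = gen_end,
    conservation = list(
      iucn = category_table(e$iucn, iucn_levels(), "NE", n),
      nom059 = category_table(e$nom059, nom059_levels(), "none", n),
      cites = category_table(e$cites, cites_levels(), "none", n)),
    banked_table = banked,
    top_family_share_pct = percent(sum(fam$count[seq_len(top_k_use)]), n, 0),
    top_family_share_endemic_pct = if (n_end)
      percent(sum(fam_end$count[seq_len(min(top_k, nrow(fam_end)))]), n_end, 0)
      else NA_real_),
    class = "catalogue_summary")
}

cell_style <- function(count, pct) sprintf("%d (%s)", count, format(pct))

#' @export
print.catalogue_summary <- function(x, ..., n_rows = 10) {
  cat(sprintf("<catalogue_summary> %d species | %d genera | %d families\n",
              x$n_species, x$n_genera, x$n_families))
  cat(sprintf("  endemic %d (%s%%)  useful %d (%s%%)  threatened %d  banked %d (%s%%)\n",
              x$n_endemic, format(percent(x$n_endemic, x$n_species, 0)),
              x$n_useful, format(percent(x$n_useful, x$n_species, 0)),
              x$n_threatened,
              x$n_banked, format(percent(x$n_banked, x$n_species, 1))))
  cat(sprintf("  top-10 family share: %s%% overall", format(x$top_family_share_pct)))
  if (!is.na(x$top_family_share_endemic_pct)) {
    cat(sprintf(", %s%% among endemics", format(x$top_family_share_endemic_pct)))
  }
  cat("\n  leading families: ",
      paste0(utils::head(x$family_table$name, 3), " ",
             mapply(cell_style, utils::head(x$family_table$count, 3),
                    utils::head(x$family_table$percent, 3)),
             collapse = "; "), "\n", sep = "")
  invisible(x)
}

#' Export the summary tables as CSV plus a printed-cell rendering
#'
#' Writes one CSV per table under `dir` and a plain-text file rendering the
#' ranked tables in the "count (percent)" cell style.
#'
#' @param summary a [tabulate_catalogue()] result.
#' @param dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_summary <- function(summary, dir) {
  stopifnot(inherits(summary, "catalogue_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(summary$family_table, "family_table")
  wr(summary$genus_table, "genus_table")
  wr(summary$family_table_endemic, "family_table_endemic")
  wr(summary$genus_table_endemic, "genus_table_endemic")
  wr(summary$conservation$iucn, "conservation_iucn")
  wr(summary$conservation$nom059, "conservation_nom059")
  wr(summary$conservation$cites, "conservation_cites")
  wr(summary$banked_table, "banked_table")
  txt <- file.path(dir, "summary.txt")
  con <- file(txt, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d species, %d genera, %d families",
                     summary$n_species, summary$n_genera, summary$n_families), con)
  writeLines("", con)
  writeLines("Most represented families (count (percent)):", con)
  ft <- summary$family_table
  writeLines(sprintf("  %2d  %-20s %s", ft$rank, ft$name,
                     cell_style(ft$count, ft$percent)), con)
  paths <- c(paths, txt)
  invisible(paths)
}
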