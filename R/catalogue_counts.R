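#' Realize a catalogue from marginal count tables
#'
#' Builds a fully populated [catalogue()] whose marginal tallies equal a
#' given set of counts: named families (with per-family endemic counts and
#' optionally named genera inside them), total species/family numbers with
#' the remainder spread evenly over autogenerated filler families, plus
#' overall conservation-listing, seed-banking and use counts assigned by
#' species index. This is how a published inventory's summary tables
#' become an executable input: [tabulate_catalogue()] on the result
#' reproduces every count and percentage from first principles.
#'
#' Filler families are sized below the smallest named family so the
#' printed ranking is preserved; filler endemics are distributed
#' round-robin so no filler family outranks a named one.
#'
#' @param family_counts data.frame with `family`, `species`,
#'   `endemic_species` for the named (ranked) families.
#' @param n_species,n_families totals; the difference with the named
#'   families is realized as filler families/species.
#' @param n_endemic total endemic species (named-family endemics plus
#'   filler endemics).
#' @param genus_counts optional data.frame `genus`, `family`, `species`,
#'   `endemic_species` for named genera; a named genus's species (and its
#'   endemics) come first within its family.
#' @param iucn_counts,nom059_counts,cites_counts named integer vectors of
#'   per-category counts (categories absent default to NE / none).
#' @param banked_incountry,banked_duplicated,banked_overlap sizes of the
#'   two seed collections and their intersection.
#' @param n_useful number of useful species.
#' @return a validated [catalogue()].
#' @export
catalogue_from_counts <- function(family_counts,
                                  n_species, n_families, n_endemic = 0,
                                  genus_counts = NULL,
                                  iucn_counts = integer(0),
                                  nom059_counts = integer(0),
                                  cites_counts = integer(0),
                                  banked_incountry = 0,
                                  banked_duplicated = 0,
                                  banked_overlap = 0,
                                  n_useful = 0) {
  stopifnot(sum(family_counts$species) <= n_species,
            nrow(family_counts) <= n_families,
            banked_overlap <= min(banked_incountry, banked_duplicated))
  n_fill_sp <- n_species - sum(family_counts$species)
  n_fill_fam <- n_families - nrow(family_counts)
  if (n_fill_fam == 0 && n_fill_sp > 0) stop("filler species need filler families")
  fill_sizes <- if (n_fill_fam > 0) {
    base <- n_fill_sp %/% n_fill_fam
    extra <- n_fill_sp %% n_fill_fam
    c(rep(base + 1L, extra), rep(base, n_fill_fam - extra))
  } else integer(0)
  if (length(fill_sizes) && max(fill_sizes) >= min(family_counts$species)) {
    stop("filler families would outrank a named family")
  }

  fam_all <- data.frame(
    family = c(family_counts$family,
               sprintf("Relictaceae%03d", seq_len(n_fill_fam))),
    species = c(family_counts$species, fill_sizes),
    endemic_species = c(family_counts$endemic_species,
                        rep(0L, n_fill_fam)),
    stringsAsFactors = FALSE)
  # spread the remaining endemics round-robin over the filler families
  fill_end <- n_endemic - sum(family_counts$endemic_species)
  if (fill_end < 0) stop("named endemic counts exceed n_endemic")
  i <- nrow(family_counts) + 1L
  while (fill_end > 0 && n_fill_fam > 0) {
    if (fam_all$endemic_species[i] < fam_all$species[i]) {
      fam_all$endemic_species[i] <- fam_all$endemic_species[i] + 1L
      fill_end <- fill_end - 1L
    }
    i <- if (i >= nrow(fam_all)) nrow(family_counts) + 1L else i + 1L
  }
  if (fill_end > 0) stop("not enough filler capacity for the endemics")

  rows <- vector("list", nrow(fam_all))
  for (k in seq_len(nrow(fam_all))) {
    fam <- fam_all$family[k]
    n_f <- fam_all$species[k]
    n_e <- fam_all$endemic_species[k]
    gen <- rep(sprintf("Genfill%03d", k), n_f)
    if (!is.null(genus_counts)) {
      gsub_df <- genus_counts[genus_counts$family == fam, , drop = FALSE]
      at <- 1L
      for (gk in seq_len(nrow(gsub_df))) {
        gen[at:(at + gsub_df$species[gk] - 1L)] <- gsub_df$genus[gk]
        at <- at + gsub_df$species[gk]
      }
    }
    rows[[k]] <- data.frame(
      family = fam, genus = gen,
      species = paste(gen, sprintf("inventa%04d", seq_len(n_f) +
                                     cumsum(c(0, fam_all$species))[k])),
      endemic = seq_len(n_f) <= n_e,
      stringsAsFactors = FALSE)
  }
  e <- do.call(rbind, rows)
  n <- nrow(e)
  assign_codes <- function(counts, default) {
    out <- rep(default, n)
    at <- 1L
    for (code in names(counts)) {
      k <- counts[[code]]
      if (k > 0) { out[at:(at + k - 1L)] <- code; at <- at + k }
    }
    out
  }
  e$states <- ""
  e$iucn <- assign_codes(iucn_counts, "NE")
  e$nom059 <- assign_codes(nom059_counts, "none")
  e$cites <- assign_codes(cites_counts, "none")
  e$banked_incountry <- seq_len(n) <= banked_incountry
  dup_from <- banked_incountry - banked_overlap + 1L
  e$banked_duplicated <- seq_len(n) >= dup_from &
    seq_len(n) < dup_from + banked_duplicated
  e$useful <- seq_len(n) <= n_useful
  catalogue(e[c("family", "genus", "species", "states", "endemic", "iucn",
                "nom059", "cites", "banked_incountry", "banked_duplicated",
                "useful")],
            provenance = "realized from marginal count tables")
}

#' Locate the bundled reference count tables
#'
#' The package ships the published national tree-inventory summary counts
#' (ranked family/genus tables, conservation listings, seed-banking table,
#' headline totals) as plain CSV under `extdata/inventory_reference`; they
#' are the inputs from which the summary machinery re-derives every
#' percentage.
#'
#' @return named list of data.frames: `family_counts`, `genus_counts`,
#'   `headline` (as a named vector), `conservation`, `banked`.
#' @export
inventory_reference_counts <- function() {
  dir <- system.file("extdata", "inventory_reference", package = "treecensus",
                     mustWork = TRUE)
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  head_df <- rd("headline_counts.csv")
  list(family_counts = rd("family_counts.csv"),
       genus_counts = rd("genus_counts.csv"),
       headline = stats::setNames(head_df$value, head_df$key),
       conservation = rd("conservation_counts.csv"),
       banked = rd("banked_counts.csv"))
}
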