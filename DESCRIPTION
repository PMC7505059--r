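Package: treecensus
Title: National Tree Inventories: Catalogue Tabulation, Occurrence Cleaning,
    Gridded Richness and Protected-Area Gap Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing national inventories of native
    tree species from attribute-rich species catalogues and herbarium voucher
    occurrence records. Provides a catalogue data model with conservation and
    use attributes (IUCN Red List, national protection listings, CITES, seed
    banking, ethnobotanical use) and the tabulations behind inventory summary
    tables; a rule-based coordinate-cleaning pipeline for georeferenced
    records (out-of-boundary repair of inverted or sign-stripped coordinates,
    country-centroid sentinels, low-precision records, near-shore snapping,
    deduplication and state-name normalisation) with an auditable per-rule
    report; equal-area gridding of record density and distinct-taxon richness
    for arbitrary attribute slices, per-state choropleth counts,
    density-richness regression and richness-peak detection; protected-area
    overlay and conservation-gap identification; and a seeded synthetic-data
    generator (clustered species ranges, voucher-style sampling, injected
    coordinate-error classes, polygon layers) with full ground-truth
    bookkeeping so every pipeline stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
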