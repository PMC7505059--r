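test_that("threatened status partitions the IUCN vocabulary exactly", {
  expected <- c(CR = TRUE, EN = TRUE, VU = TRUE, NT = FALSE, LC = FALSE,
                DD = FALSE, `LR/cd` = FALSE, `LR/nt` = FALSE,
                `LR/lc` = FALSE, NE = FALSE)
  expect_setequal(names(expected), iucn_levels())
  for (code in iucn_levels()) {
    expect_identical(is_threatened(code), unname(expected[code]),
                     label = paste("is_threatened for", code))
  }
})

test_that("banked status is the union of the two collections", {
  df <- data.frame(banked_incountry = c(TRUE, FALSE, TRUE, FALSE),
                   banked_duplicated = c(FALSE, TRUE, TRUE, FALSE))
  expect_identical(is_banked(df), c(TRUE, TRUE, TRUE, FALSE))
  # inclusion-exclusion on collection sizes: 493 in-country and 425
  # duplicated with an overlap of 358 give a banked union of 560
  n <- 600
  incountry <- seq_len(n) <= 493
  duplicated <- seq_len(n) >= 136 & seq_len(n) <= 560
  expect_equal(sum(incountry & duplicated), 358)
  expect_equal(sum(is_banked(data.frame(banked_incountry = incountry,
                                        banked_duplicated = duplicated))), 560)
})

test_that("percent applies half-away-from-zero rounding", {
  expect_equal(percent(1264, 2885, 0), 44)   # 43.81 rounds up at 0 dp
  expect_equal(percent(513, 2885, 1), 17.8)
  expect_equal(percent(0, 7, 2), 0)
  expect_equal(percent(2, 3, 2), 66.67)
  expect_equal(percent(1, 16, 1), 6.3)       # 6.25: banker's would give 6.2
  expect_equal(percent(-1, 16, 1), -6.3)
  expect_error(percent(1, 0), "total")
})

test_that("catalogue validation rejects bad structure and codes", {
  cat <- tiny_catalogue()
  expect_s3_class(cat, "catalogue")
  e <- cat$entries
  e2 <- rbind(e, e[1, ])
  expect_error(catalogue(e2), "duplicate binomial.*Quercus alba")
  e3 <- e; e3$iucn[2] <- "XX"
  expect_error(catalogue(e3), "unknown IUCN code.*XX")
  e4 <- e; e4$genus[1] <- "Fagus"
  expect_error(catalogue(e4), "first epithet")
  e5 <- e; e5$family[3] <- ""
  expect_error(catalogue(e5), "empty family")
  expect_error(catalogue(e[0, ]), "no entries")
})

test_that("tabulation matches a brute-force recomputation", {
  set.seed(42)
  n <- 180
  fams <- sprintf("Fam%02d", 1:12)
  gens <- sprintf("Gen%02d", 1:30)
  gen_fam <- fams[((seq_along(gens) - 1) %% 12) + 1]
  g <- sample(gens, n, replace = TRUE)
  entries <- data.frame(
    family = gen_fam[match(g, gens)], genus = g,
    species = paste(g, sprintf("sp%03d", 1:n)),
    states = "", endemic = runif(n) < 0.4,
    iucn = sample(iucn_levels(), n, replace = TRUE),
    nom059 = sample(nom059_levels(), n, replace = TRUE),
    cites = sample(cites_levels(), n, replace = TRUE),
    banked_incountry = runif(n) < 0.2, banked_duplicated = runif(n) < 0.15,
    useful = runif(n) < 0.25, stringsAsFactors = FALSE)
  cat <- catalogue(entries)
  s <- tabulate_catalogue(cat)

  expect_equal(sum(s$family_table$count), n)
  expect_equal(sum(s$genus_table$count), n)
  expect_equal(s$n_species, n)
  # brute-force oracle: enumerate every family by hand
  for (f in unique(entries$family)) {
    cnt <- sum(entries$family == f)
    row <- s$family_table[s$family_table$name == f, ]
    expect_equal(row$count, cnt)
    expect_equal(row$percent, percent(cnt, n, 1))
  }
  # endemic tables only use endemic entries
  expect_equal(sum(s$family_table_endemic$count), sum(entries$endemic))
  # conservation tables against direct counts (IUCN categories exclusive)
  for (code in setdiff(iucn_levels(), "NE")) {
    row <- s$conservation$iucn[s$conservation$iucn$category == code, ]
    expect_equal(row$count, sum(entries$iucn == code))
    expect_equal(row$percent, percent(sum(entries$iucn == code), n, 2))
  }
  # banked table denominators are the row category totals
  thr <- entries[is_threatened(entries$iucn), ]
  row <- s$banked_table[s$banked_table$category == "threatened", ]
  expect_equal(row$banked,
               sum(thr$banked_incountry | thr$banked_duplicated))
  expect_equal(row$banked_pct,
               percent(sum(thr$banked_incountry | thr$banked_duplicated),
                       nrow(thr), 1))
  # top-10 share equals the enumerated share
  top10 <- sum(sort(table(entries$family), decreasing = TRUE)[1:10])
  expect_equal(s$top_family_share_pct, percent(top10, n, 0))
})

test_that("ranking ties share a rank and order alphabetically", {
  entries <- data.frame(
    family = c("Bfam", "Bfam", "Afam", "Afam", "Cfam"),
    genus = c("Ga", "Gb", "Gc", "Gd", "Ge"),
    species = paste(c("Ga", "Gb", "Gc", "Gd", "Ge"), "x"),
    states = "", endemic = FALSE, iucn = "NE", nom059 = "none",
    cites = "none", banked_incountry = FALSE, banked_duplicated = FALSE,
    useful = FALSE, stringsAsFactors = FALSE)
  s <- tabulate_catalogue(catalogue(entries))
  ft <- s$family_table
  expect_equal(ft$name, c("Afam", "Bfam", "Cfam"))
  expect_equal(ft$rank, c(1L, 1L, 3L))
  # pure function: identical input gives identical summary
  expect_identical(s, tabulate_catalogue(catalogue(entries)))
})

test_that("summary export writes every table", {
  dir <- withr::local_tempdir()
  paths <- write_summary(tabulate_catalogue(tiny_catalogue()), dir)
  expect_true(all(file.exists(paths)))
  ft <- read.csv(file.path(dir, "family_table.csv"))
  expect_equal(sum(ft$count), 6)
  txt <- readLines(file.path(dir, "summary.txt"))
  expect_true(any(grepl("Fabaceae", txt)))
  expect_true(any(grepl("\\(33\\.3\\)", txt)))  # 2 of 6 in cell style
})
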