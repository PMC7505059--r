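sq100 <- square_country(100, lon0 = -100, lat0 = 20)

test_that("grid dimensions follow the envelope/cell-size ceiling", {
  expect_equal(unlist(build_grid(sq100, 25)[c("n_cols", "n_rows")]),
               c(n_cols = 4L, n_rows = 4L))
  expect_equal(build_grid(sq100, 30)$n_cols, 4L)   # ceiling(100/30)
  for (s in c(10, 20, 25, 30, 50)) {
    g <- build_grid(sq100, s)
    expect_equal(g$n_cols, as.integer(ceiling(100 / s - 1e-9)))
    expect_equal(g$n_rows, as.integer(ceiling(100 / s - 1e-9)))
  }
  country <- synthetic_country()
  g <- build_grid(country, 25)
  bb <- treecensus:::ps_bbox(country)
  ur <- project_xy(bb["xmax"], bb["ymax"], g$crs)
  ll <- project_xy(bb["xmin"], bb["ymin"], g$crs)
  expect_equal(g$n_cols, as.integer(ceiling((ur$x - ll$x) / 25 - 1e-9)))
  expect_gte(g$x0 + g$n_cols * g$cell_km, ur$x)   # whole cells cover extent
})

test_that("cell assignment uses half-open intervals with edge closure", {
  g <- build_grid(sq100, 25)
  crs <- g$crs
  pts <- unproject_xy(g$x0 + c(0, 25, 100, 99.999),
                      g$y0 + c(0, 25, 100, 0.001), crs)
  r <- assign_cells(recs_at(paste("Sp", 1:4), pts$lon, pts$lat), g)
  expect_equal(r$cell_col, c(1L, 2L, 4L, 4L))  # boundary point -> higher cell
  expect_equal(r$cell_row, c(1L, 2L, 4L, 1L))  # envelope edge -> last cell
  out <- unproject_xy(g$x0 - 5, g$y0, crs)
  expect_error(assign_cells(recs_at("Sp x", out$lon, out$lat), g),
               "outside the grid")
})

test_that("per-cell density and richness match the brute-force oracle", {
  set.seed(5)
  g <- build_grid(sq100, 25)
  n <- 1000
  pt <- unproject_xy(g$x0 + runif(n, 0, 100), g$y0 + runif(n, 0, 100), g$crs)
  sp <- sample(sprintf("Sp %02d", 1:30), n, replace = TRUE)
  r <- recs_at(sp, pt$lon, pt$lat)
  d <- density_layer(r, g)
  expect_equal(d$values, oracle_cell_counts(r, g))
  expect_equal(sum(d$values), n)
  rl <- richness_layer(r, g)
  expect_equal(rl$values, oracle_cell_counts(r, g, species = sp))
  # 5 records of 3 species in one far cell
  one <- recs_at(c("A x", "A x", "B x", "C x", "C x"),
                 rep(pt$lon[1], 5), rep(pt$lat[1], 5))
  expect_equal(max(richness_layer(one, g)$values), 3L)
  expect_equal(sum(richness_layer(one, g)$values > 0), 1L)
  # no records: all-zero layer
  expect_true(all(richness_layer(r[0, ], g)$values == 0))
})

test_that("slices are monotone and taxon levels nest through the join", {
  scn <- make_scenario(seed = 3, n_species = 60, mean_records = 10,
                       error_rates = zero_rates())
  recs <- sample_occurrences(scn)
  g <- scn$grid
  joined <- join_catalogue(recs, scn$catalogue)
  all_sp <- richness_layer(joined, g)
  endemic <- richness_layer(joined, g, slice = list(endemic = TRUE))
  expect_true(all(endemic$values <= all_sp$values))
  gen <- richness_layer(joined, g, level = "genus")
  fam <- richness_layer(joined, g, level = "family")
  expect_true(all(gen$values <= all_sp$values))
  expect_true(all(fam$values <= gen$values))
  # unknown slice attribute is an error
  expect_error(richness_layer(joined, g, slice = list(nope = 1)),
               "unknown slice attribute")
})

test_that("records missing from the catalogue are reported, not dropped silently", {
  scn <- make_scenario(seed = 3, n_species = 20, mean_records = 5,
                       error_rates = zero_rates())
  recs <- sample_occurrences(scn)
  recs$species[1:7] <- "Phantom taxon"
  joined <- join_catalogue(recs, scn$catalogue)
  jm <- attr(joined, "join_miss")
  expect_equal(jm$n, 7)
  expect_equal(jm$species, "Phantom taxon")
  expect_equal(nrow(joined), nrow(recs) - 7)
})

test_that("global distinct-species count is invariant to cell size", {
  scn <- make_scenario(seed = 13, n_species = 50, mean_records = 8,
                       error_rates = zero_rates())
  recs <- sample_occurrences(scn)
  totals <- vapply(c(10, 20, 25, 30, 50), function(s) {
    g <- build_grid(scn$boundary, s)
    r <- assign_cells(recs, g)
    length(unique(r$species))
  }, numeric(1))
  expect_true(all(totals == totals[1]))
})

test_that("per-state counts agree with an independent point-in-polygon oracle", {
  skip_if_not_installed("pracma")
  scn <- make_scenario(seed = 21, n_species = 40, mean_records = 10,
                       error_rates = zero_rates())
  recs <- sample_occurrences(scn)
  got <- per_state_counts(recs, scn$states)
  idx <- oracle_which_feature(recs$lon, recs$lat, scn$states)
  for (i in seq_along(scn$states)) {
    expect_equal(got$n_taxa[i], length(unique(recs$species[which(idx == i)])),
                 label = paste("state", names(scn$states)[i]))
    expect_equal(got$n_records[i], sum(idx == i, na.rm = TRUE))
  }
  # a species spanning two states counts once in each (set semantics)
  two <- recs_at(c("Sp z", "Sp z"), lon = c(-105, -97), lat = c(20, 20),
                 state = "X")
  g2 <- per_state_counts(two, scn$states)
  expect_equal(sum(g2$n_taxa), 2)
})

test_that("density-richness regression matches the closed form", {
  g <- build_grid(sq100, 25)
  # five occupied cells with chosen density/richness pairs
  dns <- c(3, 5, 7, 9, 11)
  rch <- c(2, 3, 5, 4, 6)
  xs <- c(12.5, 37.5, 62.5, 87.5, 12.5)
  ys <- c(12.5, 12.5, 12.5, 12.5, 37.5)
  rows <- list()
  for (i in seq_along(dns)) {
    ctr <- unproject_xy(g$x0 + xs[i], g$y0 + ys[i], g$crs)
    sp <- paste("Sp", i, c(seq_len(rch[i]), rep(1, dns[i] - rch[i])))
    rows[[i]] <- recs_at(sp, rep(ctr$lon, dns[i]), rep(ctr$lat, dns[i]))
  }
  recs <- do.call(rbind, rows)
  recs$record_id <- sprintf("r%04d", seq_len(nrow(recs)))
  fit <- regress_density_richness(density_layer(recs, g),
                                  richness_layer(recs, g))
  # closed-form OLS oracle
  bx <- sum((dns - mean(dns)) * (rch - mean(rch))) / sum((dns - mean(dns))^2)
  b0 <- mean(rch) - bx * mean(dns)
  r2 <- 1 - sum((rch - (b0 + bx * dns))^2) / sum((rch - mean(rch))^2)
  expect_equal(fit$slope, bx, tolerance = 1e-12)
  expect_equal(fit$intercept, b0, tolerance = 1e-12)
  expect_equal(fit$r_squared, r2, tolerance = 1e-12)
  expect_equal(fit$n_cells_used, 5L)
  expect_error(regress_density_richness(density_layer(recs[1:2, ], g),
                                        richness_layer(recs[1:2, ], g)),
               "fewer than 3")
})

test_that("peak detection is strict and matches a brute-force scan", {
  set.seed(8)
  scn <- make_scenario(seed = 8, n_species = 50, mean_records = 10,
                       error_rates = zero_rates())
  recs <- sample_occurrences(scn)
  rl <- richness_layer(recs, scn$grid)
  for (thr in c(0, 3, 10, max(rl$values))) {
    got <- find_peaks(rl, thr)
    want <- oracle_peaks(rl$values, thr)
    expect_equal(got$value, want$value)
    expect_equal(got$cell_row, want$row)
    expect_equal(got$cell_col, want$col)
  }
  # strictly greater: an all-zero layer has no peaks at threshold 0
  zero <- richness_layer(recs[0, ], scn$grid)
  expect_equal(nrow(find_peaks(zero, 0)), 0L)
  # one cell just over the threshold is the only peak
  g <- build_grid(sq100, 25)
  ctr <- unproject_xy(g$x0 + 12.5, g$y0 + 12.5, g$crs)
  one <- recs_at(sprintf("Sp %03d", 1:401), rep(ctr$lon, 401),
                 rep(ctr$lat, 401))
  pk <- find_peaks(richness_layer(one, g), 400)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$value, 401L)
})

test_that("layers are deterministic and export as gridded CSV", {
  scn <- make_scenario(seed = 4, n_species = 30, mean_records = 6,
                       error_rates = zero_rates())
  recs <- sample_occurrences(scn)
  a <- richness_layer(recs, scn$grid)
  b <- richness_layer(recs, scn$grid)
  expect_identical(a$values, b$values)
  path <- withr::local_tempfile(fileext = ".csv")
  export_layer_csv(a, path)
  df <- read.csv(path)
  expect_equal(nrow(df), scn$grid$n_cols * scn$grid$n_rows)
  expect_equal(sum(df$value), sum(a$values))
  expect_equal(df$value[df$cell_id == 1],
               a$values[1, 1])
})
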