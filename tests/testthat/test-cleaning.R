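# Cleaning rules are exercised on a 100 x 100 km square country centred
# at (lon -100, lat 20); its sentinel centre plays the centroid trap.

sq <- square_country(100, lon0 = -100, lat0 = 20)
sq_cfg <- cleaning_config(centroid_lat = 20, centroid_lon = -100)

test_that("centroid sentinel matching respects the tolerance", {
  cfg <- cleaning_config()  # default sentinel 23 N, 102 W, tol 0.005
  r <- recs_at(rep("Sp a", 5),
               lon = c(-102.0, -102.0, -101.996, -102.0, -102.21),
               lat = c(23.0, 22.0, 23.004, 23.006, 23.05))
  out <- rule_centroid(r, cfg)
  expect_equal(out$status, c("deleted", "raw", "deleted", "raw", "raw"))
  expect_equal(out$cleaning_note[1], "centroid")
})

test_that("out-of-boundary repairs try swap, sign, then both", {
  country <- synthetic_country()  # spans lat ~15-23, lon ~ -108..-96
  cfg <- cleaning_config()
  r <- recs_at(c("Sp a", "Sp b", "Sp c"),
               lon = c(19.4, 99.2, -99.2),
               lat = c(-99.2, 19.4, 19.4))
  out <- rule_outside_boundary(r, country, cfg)
  expect_equal(out$status, c("repaired", "repaired", "kept"))
  expect_equal(out$cleaning_note[1:2], c("repair:inverted", "repair:sign"))
  expect_equal(out$lat[1:2], c(19.4, 19.4))
  expect_equal(out$lon[1:2], c(-99.2, -99.2))
  # originals retained
  expect_equal(out$lat_orig[1], -99.2)
  expect_equal(out$lon_orig[2], 99.2)
  # repairs never produce a point outside the boundary
  expect_true(all(point_in_poly_set(out$lon, out$lat, country)))
  # with repairs off, far-out points are deleted instead
  out2 <- rule_outside_boundary(r, country,
                                cleaning_config(attempt_repairs = FALSE))
  expect_equal(out2$status, c("deleted", "deleted", "kept"))
})

test_that("coastal snap moves near-shore points inside, within the bound", {
  crs <- local_crs(-100, 20)
  # 0.5 km east of the square's east edge (x = 50), and 5 km out
  near <- unproject_xy(50.5, 0, crs)
  far <- unproject_xy(55, 0, crs)
  inside <- unproject_xy(10, 10, crs)
  r <- recs_at(c("Sp a", "Sp b", "Sp c"),
               lon = c(near$lon, far$lon, inside$lon),
               lat = c(near$lat, far$lat, inside$lat))
  out <- rule_outside_boundary(r, sq, sq_cfg, crs)
  out <- rule_coastal_snap(out, sq, sq_cfg, crs)
  expect_equal(out$status, c("moved", "deleted", "kept"))
  expect_equal(out$cleaning_note[1:2], c("coastal_snap", "outside"))
  expect_true(point_in_poly_set(out$lon[1], out$lat[1], sq))
  # displacement <= max_snap + epsilon
  p0 <- project_xy(near$lon, near$lat, crs)
  p1 <- project_xy(out$lon[1], out$lat[1], crs)
  disp <- sqrt((p1$x - p0$x)^2 + (p1$y - p0$y)^2)
  expect_lte(disp, sq_cfg$max_snap_km + sq_cfg$snap_epsilon_km + 1e-9)
  # a point already inside is never touched
  expect_equal(out$lon[3], inside$lon)
})

test_that("low-precision handling follows the configured policy", {
  r <- recs_at(c("Sp a", "Sp b"), lon = c(-99.1, -99.1234),
               lat = c(19.4, 19.4321), dp = c(1L, 4L))
  flagged <- rule_low_precision(r, cleaning_config())
  expect_equal(flagged$status, c("flagged", "raw"))
  deleted <- rule_low_precision(r,
    cleaning_config(low_precision_policy = "delete"))
  expect_equal(deleted$status, c("deleted", "raw"))
  kept <- rule_low_precision(r, cleaning_config(low_precision_policy = "keep"))
  expect_equal(kept$status, c("raw", "raw"))
})

test_that("stated precision is read from the coordinate text", {
  path <- withr::local_tempfile(lines = c(
    "id,scientificName,decimalLatitude,decimalLongitude,stateProvince",
    "a,Sp a,19.4,-99.1,Centro Sur",
    "b,Sp b,19.4321,-99.1234,Centro Sur",
    "c,Sp c,19,-99,Centro Sur",
    "d,Sp d,19.40,-99.1000,Centro Sur"))
  r <- read_occurrences(path)
  expect_equal(r$coord_precision_dp, c(1L, 4L, 0L, 2L))
  bad <- withr::local_tempfile(lines = c(
    "id,scientificName,decimalLatitude,decimalLongitude,stateProvince",
    "a,Sp a,19.4,-99.1,Centro Sur",
    "b,Sp b,not-a-number,-99.1,Centro Sur"))
  expect_error(read_occurrences(bad), "line 3.*not-a-number")
})

test_that("state normalisation is case/space/diacritic-insensitive", {
  aliases <- state_alias_table(c("VER", "OAX"),
                               c("Veracruz" = "VER", "Oaxaca" = "OAX"))
  r <- recs_at(rep("Sp a", 4), lon = c(-100, -100.1, -100.2, -100.3),
               lat = rep(20, 4),
               state = c("Veracruz", "VERACRUZ ", "  oaxaca", "Nowhere"))
  expect_warning(out <- normalize_and_dedup(r, aliases), "Nowhere")
  expect_equal(out$state_std, c("VER", "VER", "OAX", "unknown"))
  expect_false(any(out$status == "deleted"))  # unmappable records are kept
})

test_that("duplicates collapse on the 4-dp key, first occurrence kept", {
  r <- recs_at(c("Sp a", "Sp a", "Sp a", "Sp b"),
               lon = c(-99.12341, -99.12342, -99.2, -99.12341),
               lat = rep(19.5, 4), state = "X")
  out <- normalize_and_dedup(r, state_alias_table("X"))
  # first two round to the same 4-dp key; different species never collapse
  expect_equal(out$status, c("raw", "deleted", "raw", "raw"))
  expect_equal(out$cleaning_note[2], "duplicate")
  expect_equal(out$record_id[out$status != "deleted"][1], "r0001")
})

test_that("pipeline order deletes a duplicated sentinel under the centroid rule", {
  r <- recs_at(c("Sp a", "Sp a", "Sp b"),
               lon = c(-100, -100, -99.9), lat = c(20, 20, 19.9), dp = 1L)
  res <- clean_pipeline(r, sq, sq_cfg)
  expect_equal(res$report$n_deleted_centroid, 2)
  expect_equal(res$report$n_deduplicated, 0)
})

test_that("pipeline conserves records and is idempotent", {
  set.seed(99)
  scn <- make_scenario(seed = 99, n_species = 40, mean_records = 8)
  recs <- inject_errors(sample_occurrences(scn), scn)
  res <- clean_pipeline(recs, scn$boundary, scn$cleaning, scn$state_aliases)
  rep <- res$report
  expect_equal(rep$n_input,
               rep$n_kept + rep$n_deleted_centroid + rep$n_deleted_outside +
                 rep$n_deleted_lowprecision + rep$n_deduplicated)
  # every record lands in exactly one terminal class
  expect_true(all(res$records$status %in%
                    c("kept", "repaired", "moved", "flagged", "deleted")))
  # idempotence: cleaning the kept output changes nothing
  res2 <- clean_pipeline(res$kept, scn$boundary, scn$cleaning,
                         scn$state_aliases)
  expect_equal(res2$report$n_kept, res2$report$n_input)
  expect_equal(res2$kept$lon, res$kept$lon)
  expect_equal(res2$kept$lat, res$kept$lat)
  expect_equal(res2$kept$record_id, res$kept$record_id)
})

test_that("disabling repairs only shrinks the kept set", {
  scn <- make_scenario(seed = 17, n_species = 40, mean_records = 8)
  recs <- inject_errors(sample_occurrences(scn), scn)
  cfg_off <- cleaning_config(centroid_lat = 20, centroid_lon = -101,
                             attempt_repairs = FALSE)
  kept_on <- clean_pipeline(recs, scn$boundary, scn$cleaning,
                            scn$state_aliases)$kept$record_id
  kept_off <- clean_pipeline(recs, scn$boundary, cfg_off,
                             scn$state_aliases)$kept$record_id
  expect_true(all(kept_off %in% kept_on))
  expect_lt(length(kept_off), length(kept_on))
})
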