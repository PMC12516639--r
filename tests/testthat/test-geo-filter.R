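square_ring <- function() {
  cbind(lon = c(-1.6, -1.59, -1.59, -1.6, -1.6),
        lat = c(53.8, 53.8, 53.81, 53.81, 53.8))
}

test_that("coordinate imputation follows the exif/sibling/manual hierarchy", {
  im <- data.frame(
    image_id = c("I1", "I2", "I3", "I4"),
    asset_id = c("A1", "A1", "A2", "A3"),
    lon = c(-1.5, NA, NA, NA), lat = c(53.8, NA, NA, NA))
  lk <- data.frame(image_id = "I3", lon = -1.49, lat = 53.81)
  out <- impute_coordinates(im, lk)
  expect_equal(out$coord_provenance,
               c("exif", "sibling_asset", "manual", "unresolved"))
  expect_equal(out$lon[2], -1.5)   # copied from the sibling image
  expect_equal(out$lon[3], -1.49)
  expect_true(is.na(out$lon[4]))
})

test_that("buffer policy validates its buffer list", {
  expect_equal(buffer_policy()$buffers_m, c(0, 5, 10, 20))
  expect_error(buffer_policy(c(5, 10)), "buffer 0")
  expect_error(buffer_policy(c(0, 10, 5)), "ascending")
  expect_error(buffer_policy(c(-1, 0)), "non-negative")
})

# dataset with one area whose assets sit at constructed distances
boundary_dataset <- function(n_inside = 3, n_edge = 2,
                             offsets = c(7, 25)) {
  nb <- fixture_neighbourhoods(1)
  nb$geometry[[1]] <- square_ring()
  fx <- generate_boundary_fixture(square_ring(), n_inside, n_edge,
                                  offsets, seed = 42)
  assets <- data.frame(
    asset_id = fx$point_id, asset_type = "bus_shelter",
    size_class = "medium", management_company = NA_character_,
    lon = fx$lon, lat = fx$lat, area_id = nb$area_id[1])
  ds <- audit_dataset(
    nb,
    images = data.frame(image_id = paste0("I", fx$point_id),
                        capture_date = "2023-05-01",
                        area_id = nb$area_id[1], lon = fx$lon,
                        lat = fx$lat, asset_id = fx$point_id),
    assets = assets,
    adverts = data.frame(advert_id = paste0("D", fx$point_id),
                         asset_id = fx$point_id, brand = "B",
                         brand_only = FALSE, brand_food_drink = FALSE),
    products = empty_products(),
    advert_products = data.frame(advert_id = character(),
                                 product_id = character()))
  list(ds = ds, fx = fx)
}

test_that("interior points are retained at buffer zero, 7 m points at 10 m", {
  bd <- boundary_dataset()
  out <- filter_within_boundary(bd$ds)
  at <- function(b) out$asset_id[out$buffer_m == b & out$retained]
  interior <- bd$fx$point_id[bd$fx$kind == "interior"]
  seven <- bd$fx$point_id[!is.na(bd$fx$offset_m) & bd$fx$offset_m == 7]
  far <- bd$fx$point_id[!is.na(bd$fx$offset_m) & bd$fx$offset_m == 25]
  expect_true(all(interior %in% at(0)))
  expect_false(any(seven %in% at(0)))
  expect_false(any(seven %in% at(5)))
  expect_true(all(seven %in% at(10)))
  expect_true(all(seven %in% at(20)))
  expect_false(any(far %in% at(20)))
  # distance sign agrees with the buffer-0 verdict
  one <- out[out$buffer_m == 0, ]
  expect_equal(one$retained, one$distance_to_boundary_m <= 0)
  # inside_at is the smallest retaining buffer
  expect_true(all(one$inside_at[one$asset_id %in% seven] == 10))
  expect_true(all(one$inside_at[one$asset_id %in% far] == Inf))
})

test_that("retention is monotone in buffer size for every asset", {
  cfg <- generator_config(seed = 23, coordinate_jitter_m = 60)
  ds <- generate_audit(cfg)
  out <- filter_within_boundary(ds)
  wide <- tapply(out$retained,
                 list(out$asset_id,
                      factor(out$buffer_m, levels = c(0, 5, 10, 20))),
                 any)
  expect_true(all(t(apply(wide, 1, diff)) >= 0))
  expect_gt(sum(!wide[, "0"]), 0)   # jitter pushed some assets out
})

test_that("assets referencing unknown areas or missing coordinates fail", {
  bd <- boundary_dataset(2, 0, 5)
  ds <- bd$ds
  ds$assets$area_id[1] <- "ELSEWHERE"
  expect_error(filter_within_boundary(ds$assets, neighbourhoods =
                                        ds$neighbourhoods),
               "unknown area")
  ds2 <- bd$ds
  ds2$assets$lon[1] <- NA
  expect_error(filter_within_boundary(ds2), "missing coordinates")
})

test_that("retained assets export as a GeoJSON point FeatureCollection", {
  ds <- generate_audit(generator_config(seed = 14,
                                        coordinate_jitter_m = 60))
  out <- filter_within_boundary(ds)
  kept <- apply_filter(ds, out, 0)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_assets_geojson(kept$assets, path)
  gj <- jsonlite::read_json(path)
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, nrow(kept$assets))
  f1 <- gj$features[[1]]
  expect_equal(f1$geometry$type, "Point")
  expect_equal(f1$properties$asset_id, kept$assets$asset_id[1])
  expect_equal(as.numeric(unlist(f1$geometry$coordinates)),
               c(kept$assets$lon[1], kept$assets$lat[1]))
})

test_that("buffer sensitivity leaves strictly-interior audits unchanged", {
  ds <- generate_audit(generator_config(seed = 3))
  sens <- buffer_sensitivity(ds)
  expect_named(sens, c("0", "5", "10", "20"))
  for (b in c("5", "10", "20")) {
    expect_equal(sens[[b]]$n_assets, sens[["0"]]$n_assets)
    expect_equal(sens[[b]]$tables$assets_by_quintile,
                 sens[["0"]]$tables$assets_by_quintile)
    expect_equal(sens[[b]]$tables$food_drink_by_quintile,
                 sens[["0"]]$tables$food_drink_by_quintile)
  }
})

test_that("per-buffer retained counts are non-decreasing with edge assets", {
  ds <- generate_audit(generator_config(seed = 29,
                                        coordinate_jitter_m = 60))
  sens <- buffer_sensitivity(ds)
  n <- vapply(sens, function(s) s$n_assets, numeric(1))
  expect_true(all(diff(n) >= 0))
  # empty dataset: empty but well-formed summaries
  sens0 <- buffer_sensitivity(generate_audit(
    generator_config(asset_intensity = rep(0, 5))))
  expect_true(all(vapply(sens0, function(s) s$n_assets, numeric(1)) == 0))
})
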