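# Programmatic fixtures: small audit datasets built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# One square area per quintile (0.01 degree sides), ward = area.
fixture_neighbourhoods <- function(quintiles = 1:5) {
  nb <- data.frame(
    area_id = sprintf("AREA_Q%d", quintiles),
    imd_rank = seq_along(quintiles),
    imd_quintile = quintiles,
    ward_id = sprintf("WARD_Q%d", quintiles),
    area_km2 = 1, network_km = 10)
  nb$geometry <- lapply(seq_along(quintiles), function(i) {
    x0 <- -1.6 + (i - 1) * 0.02; y0 <- 53.8
    cbind(lon = c(x0, x0 + 0.01, x0 + 0.01, x0, x0),
          lat = c(y0, y0, y0 + 0.01, y0 + 0.01, y0))
  })
  nb
}

empty_products <- function() {
  data.frame(product_id = character(), product_type = character(),
             name = character(), energy_kj_per_100 = numeric(),
             satfat_g_per_100 = numeric(),
             total_sugars_g_per_100 = numeric(),
             sodium_mg_per_100 = numeric(), fibre_g_per_100 = numeric(),
             fibre_basis = character(), protein_g_per_100 = numeric(),
             fvn_percent = numeric(), portion_weight_g = numeric(),
             price = numeric())
}

# Flexible builder. `assets`: data frame with any of asset_type,
# size_class, imd_quintile (defaults bus_shelter / medium / 1); `adverts`:
# asset (row index into assets), brand_only, brand_food_drink; `products`:
# product_type plus optional nutrient columns; `links`: advert, product
# (row indices).
fixture_dataset <- function(assets = NULL, adverts = NULL, products = NULL,
                            links = NULL, validate = TRUE) {
  nb <- fixture_neighbourhoods()
  if (is.null(assets)) assets <- data.frame(asset_type = character())
  n_a <- nrow(assets)
  a <- data.frame(
    asset_id = sprintf("A%03d", seq_len(n_a)),
    asset_type = assets$asset_type %||% rep("bus_shelter", n_a),
    size_class = assets$size_class %||% rep("medium", n_a),
    management_company = rep(NA_character_, n_a),
    lon = numeric(n_a), lat = numeric(n_a),
    area_id = sprintf("AREA_Q%d", assets$imd_quintile %||% rep(1L, n_a)))
  if ("asset_type" %in% names(assets))
    a$size_class[a$asset_type %in% c("billboard", "large_hoarding")] <-
      "large"
  # centre of the asset's area square
  ctr <- t(vapply(a$area_id, function(id) {
    g <- nb$geometry[[match(id, nb$area_id)]]
    c(mean(range(g[, 1])), mean(range(g[, 2])))
  }, numeric(2)))
  if (n_a) { a$lon <- ctr[, 1]; a$lat <- ctr[, 2] }
  images <- data.frame(
    image_id = sprintf("I%03d", seq_len(n_a)),
    capture_date = rep("2023-05-15", n_a), area_id = a$area_id,
    lon = a$lon, lat = a$lat, asset_id = a$asset_id)
  if (is.null(adverts)) adverts <- data.frame(asset = integer())
  n_ad <- nrow(adverts)
  ad <- data.frame(
    advert_id = sprintf("D%03d", seq_len(n_ad)),
    asset_id = a$asset_id[adverts$asset],
    brand = rep("BrandX", n_ad),
    brand_only = adverts$brand_only %||% rep(FALSE, n_ad),
    brand_food_drink = adverts$brand_food_drink %||% rep(FALSE, n_ad))
  if (is.null(products)) {
    p <- empty_products()
  } else {
    n_p <- nrow(products)
    p <- data.frame(
      product_id = sprintf("P%03d", seq_len(n_p)),
      product_type = products$product_type,
      name = sprintf("prod %d", seq_len(n_p)))
    for (col in c("energy_kj_per_100", "satfat_g_per_100",
                  "total_sugars_g_per_100", "sodium_mg_per_100",
                  "fibre_g_per_100", "protein_g_per_100", "fvn_percent",
                  "portion_weight_g", "price"))
      p[[col]] <- products[[col]] %||% rep(NA_real_, n_p)
    p$fibre_basis <- products$fibre_basis %||% rep(NA_character_, n_p)
  }
  if (is.null(links)) {
    lk <- data.frame(advert_id = character(), product_id = character())
  } else {
    lk <- data.frame(advert_id = ad$advert_id[links$advert],
                     product_id = p$product_id[links$product])
  }
  audit_dataset(nb, images, a, ad, p, lk, validate = validate)
}

# Nutrients guaranteed HFSS (chocolate-bar-like) / passing (salad-like).
hfss_nutrients <- function() {
  list(energy_kj_per_100 = 2200, satfat_g_per_100 = 11,
       total_sugars_g_per_100 = 48, sodium_mg_per_100 = 200,
       fibre_g_per_100 = 1, fibre_basis = "AOAC",
       protein_g_per_100 = 5, fvn_percent = 0)
}
passing_nutrients <- function() {
  list(energy_kj_per_100 = 150, satfat_g_per_100 = 0.1,
       total_sugars_g_per_100 = 2, sodium_mg_per_100 = 10,
       fibre_g_per_100 = 2, fibre_basis = "AOAC",
       protein_g_per_100 = 1.5, fvn_percent = 90)
}

# Products table row-builder for the two canned nutrient sets.
fixture_products <- function(types, verdicts = NULL) {
  n <- length(types)
  out <- data.frame(product_type = types)
  if (!is.null(verdicts)) {
    for (f in names(hfss_nutrients())) {
      v <- ifelse(verdicts == "hfss", hfss_nutrients()[[f]],
                  ifelse(verdicts == "pass", passing_nutrients()[[f]], NA))
      out[[f]] <- if (f == "fibre_basis") as.character(v) else
        as.numeric(v)
    }
  }
  out
}

# A dataset realising per-quintile advert totals and food/drink counts
# (single asset per quintile hosting all its adverts; food adverts carry
# one food product each).
fixture_from_quintile_counts <- function(total_adverts, food_drink) {
  stopifnot(length(total_adverts) == 5, all(food_drink <= total_adverts))
  assets <- data.frame(asset_type = rep("totem", 5),
                       size_class = "medium", imd_quintile = 1:5)
  adverts <- data.frame(asset = rep(1:5, total_adverts))
  is_fd <- unlist(lapply(1:5, function(q)
    c(rep(TRUE, food_drink[q]),
      rep(FALSE, total_adverts[q] - food_drink[q]))))
  products <- fixture_products(ifelse(is_fd, "food", "other"),
                               ifelse(is_fd, "pass", NA))
  links <- data.frame(advert = seq_len(sum(total_adverts)),
                      product = seq_len(sum(total_adverts)))
  fixture_dataset(assets, adverts, products, links)
}
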