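#' Synthetic audit generation
#'
#' No raw audit data accompany a desk-scale methods build, so every
#' downstream stage is exercised on seeded synthetic datasets that carry
#' the statistical structure the analysis assumes: thirty neighbourhoods
#' in five deprivation quintiles, around three hundred assets of fourteen
#' types with a deprivation-dependent intensity gradient, multi-advert
#' digital assets and totems, multi-product food adverts, a realistic
#' product-category mix, nutrient vectors spanning both NPM verdicts,
#' missing-nutrition and brand-only adverts, and boundary-straddling
#' coordinates for the geographic filter.
#'
#' @name synthetic-audit
#' @keywords internal
NULL

default_asset_type_mix <- function() {
  c(bus_shelter = 0.23, non_electronic_free_standing_display = 0.13,
    totem = 0.15, billboard = 0.07, phone_box = 0.08,
    litter_recycling_bin = 0.08, other_transport_hub = 0.06,
    other = 0.10, large_hoarding = 0.02,
    electronic_free_standing_display = 0.01, banner = 0.04,
    lamp_post_banner = 0.02, poster_board = 0.01, smart_bench = 0)
}

#' Generator configuration
#'
#' Defaults mirror the desk-scale study conditions: 5 quintiles of 6 areas;
#' expected asset counts per quintile of (74, 73, 50, 72, 26) — high in the
#' three most advertising-dense quintiles and low in the least deprived —
#' summing to 295; multi-advert totems and digital displays pushing adverts
#' per asset towards ~1.5; a product-category mix of roughly 15 % food,
#' 2 % non-alcoholic beverage, 5 % alcohol, no gambling and the remainder
#' "other"; just over half of assessable food/drink products failing the
#' NPM; 17 % of food/drink adverts brand-only; and 10 % of food/drink
#' products with missing nutrition.
#'
#' @param n_quintiles Number of deprivation strata.
#' @param n_areas_per_quintile Areas per stratum.
#' @param asset_intensity Expected asset count per quintile (length
#'   `n_quintiles`); each area draws Poisson with mean
#'   `asset_intensity[q] / n_areas_per_quintile`.
#' @param asset_type_mix Named probability vector over asset types
#'   (normalised internally).
#' @param adverts_per_asset_extra Poisson mean of additional adverts on
#'   multi-advert assets (totems, electronic displays); static assets carry
#'   exactly one advert.
#' @param product_category_mix Named probability vector over the five
#'   product groups.
#' @param food_enrichment Per-quintile multiplier on the probability that
#'   an advert is a food/drink advert (length `n_quintiles`; flat by
#'   default).
#' @param extra_products_rate Poisson mean of additional products on a
#'   food/drink advert (meal combinations).
#' @param hfss_fraction Probability that an assessable food/drink product
#'   fails the NPM.
#' @param missing_nutrition_rate Probability that a food/drink product
#'   carries no usable nutrition information.
#' @param brand_only_rate Probability that a food/drink advert is
#'   brand-only.
#' @param missing_gps_rate Probability that an image lacks embedded GPS.
#' @param coordinate_jitter_m Standard deviation (metres) of Gaussian
#'   jitter applied to asset coordinates; positive values push some points
#'   across area boundaries.
#' @param seed Integer seed; a fixed seed makes generation deterministic.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_quintiles = 5, n_areas_per_quintile = 6,
                             asset_intensity = c(74, 73, 50, 72, 26),
                             asset_type_mix = default_asset_type_mix(),
                             adverts_per_asset_extra = 3,
                             product_category_mix =
                               c(food = 0.15, non_alcoholic_beverage = 0.02,
                                 alcoholic_beverage = 0.05, gambling = 0,
                                 other = 0.78),
                             food_enrichment = rep(1, n_quintiles),
                             extra_products_rate = 0.6,
                             hfss_fraction = 0.55,
                             missing_nutrition_rate = 0.10,
                             brand_only_rate = 0.17,
                             missing_gps_rate = 0.08,
                             coordinate_jitter_m = 0,
                             seed = 1) {
  cfg <- list(n_quintiles = n_quintiles,
              n_areas_per_quintile = n_areas_per_quintile,
              asset_intensity = asset_intensity,
              asset_type_mix = asset_type_mix,
              adverts_per_asset_extra = adverts_per_asset_extra,
              product_category_mix = product_category_mix,
              food_enrichment = food_enrichment,
              extra_products_rate = extra_products_rate,
              hfss_fraction = hfss_fraction,
              missing_nutrition_rate = missing_nutrition_rate,
              brand_only_rate = brand_only_rate,
              missing_gps_rate = missing_gps_rate,
              coordinate_jitter_m = coordinate_jitter_m,
              seed = seed)
  probs <- c(cfg$hfss_fraction, cfg$missing_nutrition_rate,
             cfg$brand_only_rate, cfg$missing_gps_rate)
  if (any(probs < 0 | probs > 1))
    stop("generator_config: probabilities must lie in [0, 1]",
         call. = FALSE)
  if (length(cfg$asset_intensity) != n_quintiles ||
      any(cfg$asset_intensity < 0))
    stop("generator_config: asset_intensity must be ", n_quintiles,
         " non-negative values", call. = FALSE)
  if (length(cfg$food_enrichment) != n_quintiles ||
      any(cfg$food_enrichment < 0))
    stop("generator_config: food_enrichment must be ", n_quintiles,
         " non-negative multipliers", call. = FALSE)
  for (nm in c("asset_type_mix", "product_category_mix")) {
    v <- cfg[[nm]]
    if (any(v < 0) || sum(v) <= 0)
      stop("generator_config: ", nm, " must be non-negative and not all ",
           "zero", call. = FALSE)
    cfg[[nm]] <- v / sum(v)
  }
  bad <- setdiff(names(cfg$product_category_mix), PRODUCT_TYPES)
  if (length(bad))
    stop("generator_config: unknown product group(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  # expand over all five groups, unnamed groups at probability zero
  full <- stats::setNames(numeric(length(PRODUCT_TYPES)), PRODUCT_TYPES)
  full[names(cfg$product_category_mix)] <- cfg$product_category_mix
  cfg$product_category_mix <- full
  bad <- setdiff(names(cfg$asset_type_mix), asset_type_labels())
  if (length(bad))
    stop("generator_config: unknown asset type(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(cfg, class = "generator_config")
}

# Synthetic rectangular area grid: one column of rectangles per quintile.
synthetic_area_grid <- function(n_quintiles, n_areas_per_quintile,
                                lon0 = -1.70, lat0 = 53.72,
                                w = 0.02, h = 0.012) {
  rows <- expand.grid(j = seq_len(n_areas_per_quintile),
                      q = seq_len(n_quintiles))
  nb <- data.frame(
    area_id = sprintf("LSOA_Q%d_%d", rows$q, rows$j),
    imd_rank = (rows$q - 1L) * n_areas_per_quintile + rows$j,
    imd_quintile = rows$q,
    ward_id = sprintf("WARD_Q%d_%d", rows$q, rows$j),
    area_km2 = round(w * 111.32 * cos(lat0 * pi / 180) * h * 111.32, 3),
    network_km = NA_real_)
  nb$geometry <- lapply(seq_len(nrow(nb)), function(i) {
    x0 <- lon0 + (rows$q[i] - 1) * w
    y0 <- lat0 + (rows$j[i] - 1) * h
    m <- cbind(lon = c(x0, x0 + w, x0 + w, x0, x0),
               lat = c(y0, y0, y0 + h, y0 + h, y0))
    m
  })
  nb
}

# Draw per-100 g nutrient vectors for n products from the "treat-like" or
# "staple-like" mixture component. Drinks use beverage-scaled components.
draw_nutrients <- function(n, component = c("treat", "staple"),
                           drink = FALSE) {
  component <- match.arg(component)
  pos <- function(mu, sd) pmax(stats::rnorm(n, mu, sd), 0)
  if (!drink) {
    if (component == "treat") {
      data.frame(
        energy_kj_per_100 = pos(2000, 300),
        satfat_g_per_100 = pos(9, 3),
        total_sugars_g_per_100 = pos(35, 8),
        sodium_mg_per_100 = pos(550, 150),
        fibre_g_per_100 = pos(1.2, 0.6),
        protein_g_per_100 = pos(5, 2),
        fvn_percent = ifelse(stats::runif(n) < 0.8, 0,
                             stats::runif(n, 0, 30)))
    } else {
      data.frame(
        energy_kj_per_100 = pos(330, 120),
        satfat_g_per_100 = pos(0.5, 0.3),
        total_sugars_g_per_100 = pos(3, 1.5),
        sodium_mg_per_100 = pos(60, 40),
        fibre_g_per_100 = pos(3, 1),
        protein_g_per_100 = pos(4, 2),
        fvn_percent = pmin(stats::runif(n, 40, 100), 100))
    }
  } else {
    if (component == "treat") {
      data.frame(
        energy_kj_per_100 = pos(190, 50),
        satfat_g_per_100 = pos(0.3, 0.3),
        total_sugars_g_per_100 = pos(11, 3),
        sodium_mg_per_100 = pos(25, 15),
        fibre_g_per_100 = 0,
        protein_g_per_100 = pos(0.5, 0.4),
        fvn_percent = 0)
    } else {
      data.frame(
        energy_kj_per_100 = pos(8, 6),
        satfat_g_per_100 = 0,
        total_sugars_g_per_100 = pos(0.3, 0.3),
        sodium_mg_per_100 = pos(5, 5),
        fibre_g_per_100 = 0,
        protein_g_per_100 = pos(0.1, 0.1),
        fvn_percent = 0)
    }
  }
}

# Nutrient vectors whose realised NPM verdict matches `target_hfss`,
# obtained by redrawing mismatches from the matching mixture component
# (treat-like for HFSS targets, staple-like otherwise).
draw_nutrients_for_verdict <- function(target_hfss, drink, max_rounds = 50) {
  n <- length(target_hfss)
  out <- NULL
  todo <- seq_len(n)
  for (round in seq_len(max_rounds)) {
    if (!length(todo)) break
    cand <- draw_nutrients(length(todo), "staple", drink = FALSE)
    for (grp in list(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, TRUE))) {
      sel <- which(target_hfss[todo] == grp[1] & drink[todo] == grp[2])
      if (!length(sel)) next
      cand[sel, ] <- draw_nutrients(
        length(sel), if (grp[1]) "treat" else "staple", drink = grp[2])
    }
    cand$fibre_basis <- "AOAC"
    verdict <- npm_score(cand, ifelse(drink[todo], "drink", "food"))$is_hfss
    ok <- verdict == target_hfss[todo]
    if (is.null(out)) out <- cand
    out[todo[ok], ] <- cand[ok, , drop = FALSE]
    if (round == max_rounds) out[todo[!ok], ] <- cand[!ok, , drop = FALSE]
    todo <- todo[!ok]
  }
  rownames(out) <- NULL
  out
}

#' Generate a synthetic audit dataset
#'
#' Emits a fully validated [audit_dataset()] under the configured study
#' conditions. With a fixed seed the output is deterministic. The realised
#' HFSS share among assessable food/drink products converges to
#' `hfss_fraction`: each product is assigned a target verdict and nutrient
#' vectors are rejection-sampled from a two-component mixture
#' ("treat-like" high energy/sugar/saturated-fat/sodium versus
#' "staple-like" moderate profiles) until the NPM verdict matches.
#'
#' @param config A [generator_config()].
#' @return An `audit_dataset` with a `generator_counts` attribute recording
#'   the emitted record totals.
#' @export
generate_audit <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  nq <- config$n_quintiles
  nb <- synthetic_area_grid(nq, config$n_areas_per_quintile)
  nb$network_km <- round(stats::runif(nrow(nb), 8, 45), 2)

  # ---- assets --------------------------------------------------------------
  lambda <- config$asset_intensity[nb$imd_quintile] /
    config$n_areas_per_quintile
  n_per_area <- stats::rpois(nrow(nb), lambda)
  n_assets <- sum(n_per_area)
  area_of_asset <- rep(seq_len(nrow(nb)), n_per_area)
  mix <- config$asset_type_mix
  types <- if (n_assets)
    sample(names(mix), n_assets, replace = TRUE, prob = mix)
    else character(0)
  size <- ifelse(
    types %in% LARGE_ONLY_TYPES, "large",
    sample(SIZE_CLASSES, max(n_assets, 1), replace = TRUE,
           prob = c(0.35, 0.60, 0.05))[seq_along(types)])
  # uniform placement inside the area rectangle; a 5 % edge margin keeps
  # unjittered points strictly interior, while configured jitter is meant
  # to push edge points across the boundary, so no margin is applied then
  margin <- if (config$coordinate_jitter_m > 0) 0 else 0.05
  place <- function(i) {
    g <- nb$geometry[[area_of_asset[i]]]
    rx <- range(g[, 1]); ry <- range(g[, 2])
    mx <- margin * diff(rx); my <- margin * diff(ry)
    c(stats::runif(1, rx[1] + mx, rx[2] - mx),
      stats::runif(1, ry[1] + my, ry[2] - my))
  }
  xy <- if (n_assets) t(vapply(seq_len(n_assets), place, numeric(2)))
        else matrix(numeric(0), 0, 2)
  if (config$coordinate_jitter_m > 0 && n_assets) {
    jm <- config$coordinate_jitter_m
    lat <- xy[, 2]
    xy[, 1] <- xy[, 1] + stats::rnorm(n_assets, 0, jm) /
      (111320 * cos(lat * pi / 180))
    xy[, 2] <- lat + stats::rnorm(n_assets, 0, jm) / 111320
  }
  assets <- data.frame(
    asset_id = sprintf("AST%04d", seq_len(n_assets)),
    asset_type = types, size_class = size,
    management_company = if (n_assets)
      sample(c("AdCorp", "StreetMedia", "CityAds"), n_assets,
             replace = TRUE) else character(0),
    lon = xy[, 1], lat = xy[, 2],
    area_id = nb$area_id[area_of_asset])

  # ---- images --------------------------------------------------------------
  n_img <- 1L + stats::rbinom(n_assets, 1, 0.3)
  asset_of_img <- rep(seq_len(n_assets), n_img)
  n_images <- length(asset_of_img)
  img_missing <- stats::runif(n_images) < config$missing_gps_rate
  dates <- as.character(
    as.Date("2023-05-01") +
      sample.int(35, max(n_images, 1), replace = TRUE) - 1L)
  images <- data.frame(
    image_id = sprintf("IMG%05d", seq_len(n_images)),
    capture_date = dates[seq_len(n_images)],
    area_id = assets$area_id[asset_of_img],
    lon = ifelse(img_missing, NA_real_,
                 assets$lon[asset_of_img] +
                   stats::rnorm(n_images, 0, 3) / 65000),
    lat = ifelse(img_missing, NA_real_,
                 assets$lat[asset_of_img] +
                   stats::rnorm(n_images, 0, 3) / 111320),
    asset_id = assets$asset_id[asset_of_img])

  # ---- adverts -------------------------------------------------------------
  n_adv_per_asset <- ifelse(
    types %in% MULTI_ADVERT_TYPES,
    1L + stats::rpois(max(n_assets, 1), config$adverts_per_asset_extra
                      )[seq_along(types)],
    1L)
  asset_of_adv <- rep(seq_len(n_assets), n_adv_per_asset)
  n_adverts <- length(asset_of_adv)
  q_of_adv <- nb$imd_quintile[area_of_asset[asset_of_adv]]
  base_fd <- sum(config$product_category_mix[c("food",
                                               "non_alcoholic_beverage")])
  p_fd <- pmin(base_fd * config$food_enrichment[q_of_adv], 1)
  is_fd <- stats::runif(n_adverts) < p_fd
  brand_only <- is_fd & stats::runif(n_adverts) < config$brand_only_rate
  adverts <- data.frame(
    advert_id = sprintf("ADV%04d", seq_len(n_adverts)),
    asset_id = assets$asset_id[asset_of_adv],
    brand = if (n_adverts) sprintf("Brand%03d",
                                   sample.int(200, n_adverts,
                                              replace = TRUE))
            else character(0),
    brand_only = brand_only,
    brand_food_drink = brand_only)

  # ---- products ------------------------------------------------------------
  showing <- which(!brand_only)
  mixp <- config$product_category_mix
  fd_mix <- mixp[c("food", "non_alcoholic_beverage")]
  fd_mix <- fd_mix / sum(fd_mix)
  other_mix <- mixp[c("alcoholic_beverage", "gambling", "other")]
  if (sum(other_mix) == 0) other_mix <- c(alcoholic_beverage = 0,
                                          gambling = 0, other = 1)
  other_mix <- other_mix / sum(other_mix)
  # every non-brand advert shows 1 + Poisson(extra_products_rate) products
  # (meal combos on food adverts; e.g. event line-ups on "other" adverts),
  # drawn from the advert's own class mix so food/drink status is stable
  n_prod_per_adv <- 1L + stats::rpois(length(showing),
                                      config$extra_products_rate)
  adv_ids <- rep(showing, n_prod_per_adv)
  n_products <- length(adv_ids)
  ptype <- character(n_products)
  adv_fd <- is_fd[adv_ids]
  if (any(adv_fd))
    ptype[adv_fd] <- sample(names(fd_mix), sum(adv_fd), replace = TRUE,
                            prob = fd_mix)
  if (any(!adv_fd))
    ptype[!adv_fd] <- sample(names(other_mix), sum(!adv_fd),
                             replace = TRUE, prob = other_mix)
  products <- data.frame(
    product_id = sprintf("PRD%04d", seq_len(n_products)),
    product_type = ptype,
    name = sprintf("Product %04d", seq_len(n_products)),
    energy_kj_per_100 = rep(NA_real_, n_products),
    satfat_g_per_100 = rep(NA_real_, n_products),
    total_sugars_g_per_100 = rep(NA_real_, n_products),
    sodium_mg_per_100 = rep(NA_real_, n_products),
    fibre_g_per_100 = rep(NA_real_, n_products),
    fibre_basis = rep(NA_character_, n_products),
    protein_g_per_100 = rep(NA_real_, n_products),
    fvn_percent = rep(NA_real_, n_products),
    portion_weight_g = rep(NA_real_, n_products),
    price = rep(NA_real_, n_products))
  fd_prod <- which(ptype %in% c("food", "non_alcoholic_beverage"))
  if (length(fd_prod)) {
    missing <- stats::runif(length(fd_prod)) < config$missing_nutrition_rate
    with_nut <- fd_prod[!missing]
    if (length(with_nut)) {
      target <- stats::runif(length(with_nut)) < config$hfss_fraction
      drink <- ptype[with_nut] == "non_alcoholic_beverage"
      nut <- draw_nutrients_for_verdict(target, drink)
      for (cl in names(nut)) products[[cl]][with_nut] <- nut[[cl]]
    }
  }
  links <- data.frame(advert_id = adverts$advert_id[adv_ids],
                      product_id = products$product_id)

  ds <- audit_dataset(nb, images, assets, adverts, products, links)
  attr(ds, "generator_counts") <- list(n_assets = n_assets,
                                       n_adverts = n_adverts,
                                       n_products = n_products)
  ds
}

#' Generate a dual-coded rater label table
#'
#' Rater 1's labels are the truth; rater 2's labels are drawn from a
#' row-stochastic confusion kernel (row = true label, column = coded
#' label). The expected observed agreement equals the kernel's mean
#' diagonal mass under the truth label distribution; the identity kernel
#' yields perfect agreement (kappa 1), and a uniform kernel yields
#' chance-level agreement (expected kappa 0).
#'
#' @param x An `audit_dataset` (items are its assets, truth their asset
#'   types restricted to the kernel's labels) or a character vector of
#'   truth labels.
#' @param kernel Square row-stochastic matrix with identical row/column
#'   dimnames giving the label categories.
#' @param seed Integer seed.
#' @return Data frame `item_id`, `rater1`, `rater2`.
#' @export
generate_dual_coding <- function(x, kernel, seed = 1) {
  kernel <- as.matrix(kernel)
  labels <- rownames(kernel)
  if (is.null(labels) || !identical(labels, colnames(kernel)))
    stop("generate_dual_coding: kernel needs identical row/column labels",
         call. = FALSE)
  if (any(kernel < 0) || any(abs(rowSums(kernel) - 1) > 1e-8))
    stop("generate_dual_coding: kernel rows must be non-negative and sum",
         " to 1", call. = FALSE)
  if (inherits(x, "audit_dataset")) {
    truth <- x$assets$asset_type
    ids <- x$assets$asset_id
    keep <- truth %in% labels
    truth <- truth[keep]; ids <- ids[keep]
  } else {
    truth <- as.character(x)
    ids <- sprintf("ITEM%05d", seq_along(truth))
  }
  if (any(!truth %in% labels))
    stop("generate_dual_coding: truth labels outside kernel categories",
         call. = FALSE)
  set.seed(seed)
  rater2 <- character(length(truth))
  for (lab in unique(truth)) {
    sel <- truth == lab
    rater2[sel] <- sample(labels, sum(sel), replace = TRUE,
                          prob = kernel[lab, ])
  }
  data.frame(item_id = ids, rater1 = truth, rater2 = rater2)
}

#' Construct a boundary-straddling point fixture
#'
#' Emits `n_inside` points strictly interior to the polygon plus, for each
#' offset distance, `n_edge` points placed (geodesically) that many metres
#' outside the boundary, for exercising the boundary filter's buffer
#' logic. Offset points are constructed on the outward normal of a random
#' boundary edge and re-drawn until their realised distance to the
#' boundary is within 5 % of the requested offset (guarding against
#' re-entrant geometry).
#'
#' @param polygon Two-column lon/lat ring matrix.
#' @param n_inside Number of interior points.
#' @param n_edge Number of points per offset.
#' @param offsets_m Positive offset distances in metres.
#' @param seed Integer seed.
#' @return Data frame `point_id`, `lon`, `lat`, `kind`
#'   (`"interior"`/`"edge"`), `offset_m` (`NA` for interior points).
#' @export
generate_boundary_fixture <- function(polygon, n_inside, n_edge, offsets_m,
                                      seed = 1) {
  ring <- as.matrix(polygon)
  if (nrow(ring) < 4)
    stop("generate_boundary_fixture: degenerate polygon", call. = FALSE)
  if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  # shoelace area in degree space; zero means a degenerate ring
  a2 <- sum(ring[-nrow(ring), 1] * ring[-1, 2] -
              ring[-1, 1] * ring[-nrow(ring), 2])
  if (abs(a2) < 1e-12)
    stop("generate_boundary_fixture: degenerate polygon", call. = FALSE)
  if (any(offsets_m <= 0))
    stop("generate_boundary_fixture: offsets must be positive",
         call. = FALSE)
  set.seed(seed)
  rx <- range(ring[, 1]); ry <- range(ring[, 2])
  inside <- matrix(numeric(0), 0, 2)
  while (nrow(inside) < n_inside) {
    cand <- cbind(stats::runif(n_inside * 4, rx[1], rx[2]),
                  stats::runif(n_inside * 4, ry[1], ry[2]))
    ok <- mgcv::in.out(ring, cand)
    inside <- rbind(inside, cand[ok, , drop = FALSE])
  }
  inside <- inside[seq_len(n_inside), , drop = FALSE]
  rows <- list(data.frame(lon = inside[, 1], lat = inside[, 2],
                          kind = rep("interior", n_inside),
                          offset_m = NA_real_))
  n_seg <- nrow(ring) - 1
  for (d in if (n_edge > 0) offsets_m else numeric(0)) {
    pts <- matrix(NA_real_, n_edge, 2)
    for (k in seq_len(n_edge)) {
      for (try in 1:100) {
        i <- sample.int(n_seg, 1)
        t <- stats::runif(1, 0.2, 0.8)
        p <- ring[i, ] + t * (ring[i + 1, ] - ring[i, ])
        b <- geosphere::bearing(ring[i, , drop = FALSE],
                                ring[i + 1, , drop = FALSE])
        for (side in c(90, -90)) {
          cand <- geosphere::destPoint(rbind(p), b + side, d)
          if (!mgcv::in.out(ring, cand)) {
            dd <- geosphere::dist2Line(cand, ring)[, "distance"]
            if (abs(dd - d) <= 0.05 * d) {
              pts[k, ] <- cand
              break
            }
          }
        }
        if (!is.na(pts[k, 1])) break
      }
      if (is.na(pts[k, 1]))
        stop("generate_boundary_fixture: could not place an offset point",
             call. = FALSE)
    }
    rows[[length(rows) + 1]] <- data.frame(lon = pts[, 1], lat = pts[, 2],
                                           kind = rep("edge", n_edge),
                                           offset_m = rep(d, n_edge))
  }
  out <- do.call(rbind, rows)
  out <- cbind(point_id = sprintf("PT%04d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}
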