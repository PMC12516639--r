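#' Audit data model for outdoor advertising surveys
#'
#' An audit dataset is a four-level hierarchy coded from fieldwork
#' photographs: images (one per photograph, carrying capture date and GPS),
#' assets (the physical advertising structures), adverts (one creative
#' displayed on an asset; digital assets and totems may host several) and
#' products (food or drink items shown in a creative). Neighbourhoods are
#' the areal sampling units, each with an Index of Multiple Deprivation
#' (IMD) rank and quintile (quintile 1 = most deprived) and a WGS84
#' boundary polygon.
#'
#' @name audit-model
#' @keywords internal
NULL

# The five product groups used when coding advertised products.
PRODUCT_TYPES <- c("food", "non_alcoholic_beverage", "alcoholic_beverage",
                   "gambling", "other")

SIZE_CLASSES <- c("small", "medium", "large")

# Asset types that must be coded as large structures.
LARGE_ONLY_TYPES <- c("billboard", "large_hoarding")

# Asset types that routinely display more than one advert per asset.
MULTI_ADVERT_TYPES <- c("totem", "electronic_free_standing_display")

#' Eligible advertising asset type labels
#'
#' The audit's asset-type enumeration is configuration-driven: eleven labels
#' are pre-seeded (bus shelters, billboards, totems, electronic and
#' non-electronic free-standing displays, litter/recycling bins, smart
#' benches, other transport hubs, large hoardings, phone boxes and a
#' catch-all "other"), together with three synthetic placeholder labels
#' (`banner`, added for vinyl banners encountered during piloting;
#' `lamp_post_banner`; `poster_board`) that complete the fourteen-type
#' frame. Supply `extra` to declare further labels, or `replace` to swap
#' out the placeholders for a locally agreed list.
#'
#' @param extra Character vector of additional labels to accept.
#' @param replace Optional character vector replacing the three placeholder
#'   labels.
#' @return Character vector of accepted asset-type labels.
#' @export
#' @examples
#' asset_type_labels()
asset_type_labels <- function(extra = character(), replace = NULL) {
  core <- c("bus_shelter", "billboard", "totem",
            "electronic_free_standing_display",
            "non_electronic_free_standing_display",
            "litter_recycling_bin", "smart_bench", "other_transport_hub",
            "large_hoarding", "phone_box", "other")
  placeholders <- c("banner", "lamp_post_banner", "poster_board")
  if (!is.null(replace)) {
    stopifnot(is.character(replace))
    placeholders <- replace
  }
  unique(c(core, placeholders, extra))
}

#' Construct an audit dataset
#'
#' Bundles the five entity tables (plus the advert-product link table) into
#' a validated `audit_dataset`. Each argument is a data frame in the
#' column layout produced by [generate_audit()] or read by [load_audit()].
#'
#' @param neighbourhoods Data frame: `area_id`, `imd_rank`, `imd_quintile`,
#'   `ward_id`, `area_km2`, `network_km`, and a `geometry` list-column of
#'   two-column lon/lat matrices (one outer ring per area).
#' @param images Data frame: `image_id`, `capture_date`, `area_id`, `lon`,
#'   `lat` (may be `NA` pre-imputation), `asset_id`.
#' @param assets Data frame: `asset_id`, `asset_type`, `size_class`,
#'   `management_company`, `lon`, `lat`, `area_id`.
#' @param adverts Data frame: `advert_id`, `asset_id`, `brand`,
#'   `brand_only` (logical), `brand_food_drink` (logical; whether the brand
#'   is a food/drink brand — an input flag, never inferred).
#' @param products Data frame: `product_id`, `product_type`, `name`,
#'   per-100 g nutrient columns (`energy_kj_per_100`, `satfat_g_per_100`,
#'   `total_sugars_g_per_100`, `sodium_mg_per_100`, `fibre_g_per_100`,
#'   `fibre_basis`, `protein_g_per_100`, `fvn_percent`), `portion_weight_g`,
#'   `price`. Nutrient columns may be `NA` (missing nutrition).
#' @param advert_products Link table: `advert_id`, `product_id`.
#' @param asset_types Accepted asset-type labels (see
#'   [asset_type_labels()]).
#' @param validate Run [validate_audit()] before returning?
#' @return An object of class `audit_dataset`.
#' @export
audit_dataset <- function(neighbourhoods, images, assets, adverts, products,
                          advert_products,
                          asset_types = asset_type_labels(),
                          validate = TRUE) {
  x <- structure(
    list(neighbourhoods = neighbourhoods, images = images, assets = assets,
         adverts = adverts, products = products,
         advert_products = advert_products),
    asset_types = asset_types,
    class = "audit_dataset")
  if (validate) validate_audit(x)
  x
}

#' @export
print.audit_dataset <- function(x, ...) {
  n <- count_hierarchy(x)
  cat("<audit_dataset>\n")
  cat(sprintf("  %d neighbourhoods, %d images\n",
              nrow(x$neighbourhoods), nrow(x$images)))
  cat(sprintf("  %d assets, %d adverts, %d products\n",
              n$n_assets, n$n_adverts, n$n_products))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_validation <- function(fmt, ...) {
  stop(sprintf(paste0("audit validation: ", fmt), ...), call. = FALSE)
}

check_columns <- function(df, cols, table) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    abort_validation("table '%s' lacks column(s) %s", table,
                     paste(missing, collapse = ", "))
}

check_enum <- function(values, allowed, table, column) {
  bad <- setdiff(unique(values[!is.na(values)]), allowed)
  if (length(bad))
    abort_validation("unknown %s label(s) in %s: %s", column, table,
                     paste(bad, collapse = ", "))
}

check_foreign_key <- function(child, key, parent_keys, table, parent) {
  dangling <- !(child[[key]] %in% parent_keys)
  if (any(dangling))
    abort_validation(
      "%s row(s) %s reference absent %s '%s'", table,
      paste(which(dangling), collapse = ", "), parent,
      paste(unique(child[[key]][dangling]), collapse = "', '"))
}

#' Validate an audit dataset
#'
#' Checks referential integrity (every advert's asset exists, every asset's
#' area exists, every image's asset exists, every link-table row joins two
#' existing records), enum membership (asset type, size class, product
#' type), the size rule for billboards and large hoardings, quintile range,
#' and geometry validity. Errors name the offending table and rows.
#'
#' @param x An `audit_dataset`.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_audit <- function(x) {
  stopifnot(inherits(x, "audit_dataset"))
  nb <- x$neighbourhoods
  check_columns(nb, c("area_id", "imd_rank", "imd_quintile", "ward_id",
                      "area_km2", "network_km", "geometry"),
                "neighbourhoods")
  check_columns(x$images, c("image_id", "capture_date", "area_id",
                            "lon", "lat", "asset_id"), "images")
  check_columns(x$assets, c("asset_id", "asset_type", "size_class",
                            "management_company", "lon", "lat", "area_id"),
                "assets")
  check_columns(x$adverts, c("advert_id", "asset_id", "brand", "brand_only",
                             "brand_food_drink"), "adverts")
  check_columns(x$products, c("product_id", "product_type", "name"),
                "products")
  check_columns(x$advert_products, c("advert_id", "product_id"),
                "advert_products")

  if (anyDuplicated(nb$area_id))
    abort_validation("duplicate area_id in neighbourhoods")
  if (any(!is.na(nb$imd_quintile) &
          !(nb$imd_quintile %in% 1:5)))
    abort_validation("imd_quintile outside 1..5")
  if (any(nb$area_km2 < 0, na.rm = TRUE))
    abort_validation("negative area_km2")
  for (i in seq_len(nrow(nb))) {
    g <- nb$geometry[[i]]
    if (!is.matrix(g) || ncol(g) != 2 || nrow(g) < 4)
      abort_validation("area '%s': geometry must be a closed lon/lat ring",
                       nb$area_id[i])
  }

  types <- attr(x, "asset_types") %||% asset_type_labels()
  check_enum(x$assets$asset_type, types, "assets", "asset_type")
  check_enum(x$assets$size_class, SIZE_CLASSES, "assets", "size_class")
  check_enum(x$products$product_type, PRODUCT_TYPES, "products",
             "product_type")
  big <- x$assets$asset_type %in% LARGE_ONLY_TYPES
  if (any(big & x$assets$size_class != "large"))
    abort_validation(
      "asset(s) %s: billboards and large hoardings must be size 'large'",
      paste(x$assets$asset_id[big & x$assets$size_class != "large"],
            collapse = ", "))

  if (anyDuplicated(x$assets$asset_id))
    abort_validation("duplicate asset_id")
  if (anyDuplicated(x$adverts$advert_id))
    abort_validation("duplicate advert_id")
  if (anyDuplicated(x$products$product_id))
    abort_validation("duplicate product_id")

  check_foreign_key(x$assets, "area_id", nb$area_id, "assets",
                    "area_id")
  check_foreign_key(x$images, "asset_id", x$assets$asset_id, "images",
                    "asset_id")
  check_foreign_key(x$adverts, "asset_id", x$assets$asset_id, "adverts",
                    "asset_id")
  check_foreign_key(x$advert_products, "advert_id", x$adverts$advert_id,
                    "advert_products", "advert_id")
  check_foreign_key(x$advert_products, "product_id", x$products$product_id,
                    "advert_products", "product_id")

  if (nrow(x$products)) {
    fvn <- x$products$fvn_percent
    if (!is.null(fvn) && any(fvn < 0 | fvn > 100, na.rm = TRUE))
      abort_validation("fvn_percent outside [0, 100]")
  }

  # Brand-only adverts show brand imagery with no food/drink product.
  if (nrow(x$adverts)) {
    bo <- x$adverts$advert_id[x$adverts$brand_only]
    if (length(bo)) {
      lk <- merge(x$advert_products[x$advert_products$advert_id %in% bo, ,
                                    drop = FALSE],
                  x$products[, c("product_id", "product_type")],
                  by = "product_id")
      bad <- lk$advert_id[lk$product_type %in%
                            c("food", "non_alcoholic_beverage")]
      if (length(bad))
        abort_validation("brand-only advert(s) %s carry food/drink products",
                         paste(unique(bad), collapse = ", "))
    }
  }
  invisible(x)
}

#' Count the audit hierarchy
#'
#' @param x An `audit_dataset`.
#' @return List with `n_assets`, `n_adverts`, `n_products`.
#' @export
count_hierarchy <- function(x) {
  stopifnot(inherits(x, "audit_dataset"))
  list(n_assets = nrow(x$assets), n_adverts = nrow(x$adverts),
       n_products = nrow(x$products))
}

#' Distinct product types shown on an advert
#'
#' When a single advert features more than one product type each type is
#' counted, but a type shown by several products of that advert is counted
#' once — the convention used throughout the exposure tables.
#'
#' @param x An `audit_dataset`.
#' @param advert_id A single advert identifier.
#' @return Character vector of distinct product types (possibly empty).
#' @export
product_type_set <- function(x, advert_id) {
  stopifnot(inherits(x, "audit_dataset"), length(advert_id) == 1)
  if (!advert_id %in% x$adverts$advert_id)
    abort_validation("unknown advert_id '%s'", advert_id)
  pid <- x$advert_products$product_id[
    x$advert_products$advert_id == advert_id]
  sort(unique(x$products$product_type[x$products$product_id %in% pid]))
}

# Long table of (advert_id, product_type) pairs, one row per distinct type
# per advert. Used by the exposure tables (Table-2-style counting).
advert_product_types <- function(x) {
  lk <- merge(x$advert_products,
              x$products[, c("product_id", "product_type")],
              by = "product_id")
  unique(lk[, c("advert_id", "product_type")])
}

# ---- serialisation ---------------------------------------------------------

audit_table_files <- c(images = "images.csv", assets = "assets.csv",
                       adverts = "adverts.csv", products = "products.csv",
                       advert_products = "advert_products.csv",
                       neighbourhoods = "neighbourhoods.geojson")

#' Read an audit dataset from CSV tables and a GeoJSON boundary file
#'
#' @param paths Either a directory containing the standard file names
#'   (`images.csv`, `assets.csv`, `adverts.csv`, `products.csv`,
#'   `advert_products.csv`, `neighbourhoods.geojson`) or a named list of
#'   per-table file paths with those element names.
#' @param asset_types Accepted asset-type labels.
#' @return A validated `audit_dataset`.
#' @export
load_audit <- function(paths, asset_types = asset_type_labels()) {
  if (is.character(paths) && length(paths) == 1) {
    if (!dir.exists(paths))
      stop(sprintf("load_audit: missing input file(s): '%s' is not a ",
                   paths), "directory", call. = FALSE)
    paths <- as.list(file.path(paths, audit_table_files)) |>
      stats::setNames(names(audit_table_files))
  }
  for (nm in names(audit_table_files))
    if (is.null(paths[[nm]]) || !file.exists(paths[[nm]]))
      stop(sprintf("load_audit: missing input file for '%s'", nm),
           call. = FALSE)
  rd <- function(p) utils::read.csv(p, na.strings = c("NA", ""))
  images <- rd(paths$images)
  images$capture_date <- as.character(images$capture_date)
  assets <- rd(paths$assets)
  adverts <- rd(paths$adverts)
  adverts$brand_only <- as.logical(adverts$brand_only)
  adverts$brand_food_drink <- as.logical(adverts$brand_food_drink)
  products <- rd(paths$products)
  # all-NA columns come back logical; restore the declared column types
  for (col in c("energy_kj_per_100", "satfat_g_per_100",
                "total_sugars_g_per_100", "sodium_mg_per_100",
                "fibre_g_per_100", "protein_g_per_100", "fvn_percent",
                "portion_weight_g", "price"))
    if (col %in% names(products))
      products[[col]] <- as.numeric(products[[col]])
  if ("fibre_basis" %in% names(products))
    products$fibre_basis <- as.character(products$fibre_basis)
  assets$management_company <- as.character(assets$management_company)
  for (tb in c("images", "assets"))
    for (col in c("lon", "lat")) {
      df <- get(tb); df[[col]] <- as.numeric(df[[col]]); assign(tb, df)
    }
  links <- rd(paths$advert_products)
  nb <- read_neighbourhoods(paths$neighbourhoods)
  for (col in c("image_id", "asset_id", "advert_id", "product_id",
                "area_id", "ward_id")) {
    for (tb in c("images", "assets", "adverts", "products", "links", "nb")) {
      df <- get(tb)
      if (col %in% names(df)) {
        df[[col]] <- as.character(df[[col]])
        assign(tb, df)
      }
    }
  }
  audit_dataset(nb, images, assets, adverts, products, links,
                asset_types = asset_types)
}

#' Write an audit dataset to a directory
#'
#' Emits the CSV tables and GeoJSON boundary file in the layout
#' [load_audit()] reads, so that `load_audit(write_audit(x, d))` round-trips
#' field for field.
#'
#' @param x An `audit_dataset`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_audit <- function(x, dir) {
  stopifnot(inherits(x, "audit_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f)
    utils::write.csv(df, file.path(dir, f), row.names = FALSE, na = "")
  wr(x$images, "images.csv")
  wr(x$assets, "assets.csv")
  wr(x$adverts, "adverts.csv")
  wr(x$products, "products.csv")
  wr(x$advert_products, "advert_products.csv")
  write_neighbourhoods(x$neighbourhoods,
                       file.path(dir, "neighbourhoods.geojson"))
  invisible(dir)
}

#' Read neighbourhood boundaries from GeoJSON
#'
#' Expects a FeatureCollection of Polygon features in WGS84 lon/lat with
#' properties `area_id`, `imd_rank`, `imd_quintile`, `ward_id`, `area_km2`
#' and `network_km`. Only the outer ring of each polygon is retained.
#'
#' @param path GeoJSON file path.
#' @return Neighbourhood data frame with a `geometry` list-column.
#' @export
read_neighbourhoods <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection"))
    stop("read_neighbourhoods: expected a GeoJSON FeatureCollection",
         call. = FALSE)
  feats <- gj$features
  one <- function(f) {
    p <- f$properties
    data.frame(area_id = as.character(p$area_id),
               imd_rank = as.integer(p$imd_rank),
               imd_quintile = as.integer(p$imd_quintile),
               ward_id = as.character(p$ward_id),
               area_km2 = as.numeric(p$area_km2),
               network_km = as.numeric(p$network_km))
  }
  nb <- do.call(rbind, lapply(feats, one))
  nb$geometry <- lapply(feats, function(f) {
    if (!identical(f$geometry$type, "Polygon"))
      stop("read_neighbourhoods: only Polygon geometries are supported",
           call. = FALSE)
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(xy)
      c(as.numeric(xy[[1]]), as.numeric(xy[[2]]))))
    colnames(m) <- c("lon", "lat")
    m
  })
  nb
}

#' Write neighbourhood boundaries to GeoJSON
#'
#' @param nb Neighbourhood data frame (see [read_neighbourhoods()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_neighbourhoods <- function(nb, path) {
  feats <- lapply(seq_len(nrow(nb)), function(i) {
    ring <- nb$geometry[[i]]
    list(type = "Feature",
         properties = list(area_id = nb$area_id[i],
                           imd_rank = nb$imd_rank[i],
                           imd_quintile = nb$imd_quintile[i],
                           ward_id = nb$ward_id[i],
                           area_km2 = nb$area_km2[i],
                           network_km = nb$network_km[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(j) as.numeric(ring[j, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Map advert_id -> imd_quintile through asset and neighbourhood.
advert_quintiles <- function(x) {
  a <- merge(x$adverts[, c("advert_id", "asset_id")],
             x$assets[, c("asset_id", "area_id")], by = "asset_id")
  a <- merge(a, x$neighbourhoods[, c("area_id", "imd_quintile")],
             by = "area_id")
  stats::setNames(a$imd_quintile, a$advert_id)
}

# Map asset_id -> imd_quintile.
asset_quintiles <- function(x) {
  a <- merge(x$assets[, c("asset_id", "area_id")],
             x$neighbourhoods[, c("area_id", "imd_quintile")],
             by = "area_id")
  stats::setNames(a$imd_quintile, a$asset_id)
}

# Restrict a dataset to a subset of assets (used by the boundary filter);
# adverts, products, links and images are pruned to match.
subset_assets <- function(x, asset_ids) {
  assets <- x$assets[x$assets$asset_id %in% asset_ids, , drop = FALSE]
  adverts <- x$adverts[x$adverts$asset_id %in% assets$asset_id, ,
                       drop = FALSE]
  links <- x$advert_products[
    x$advert_products$advert_id %in% adverts$advert_id, , drop = FALSE]
  products <- x$products[x$products$product_id %in% links$product_id, ,
                         drop = FALSE]
  images <- x$images[x$images$asset_id %in% assets$asset_id, , drop = FALSE]
  audit_dataset(x$neighbourhoods, images, assets, adverts, products, links,
                asset_types = attr(x, "asset_types") %||%
                  asset_type_labels(),
                validate = FALSE)
}
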