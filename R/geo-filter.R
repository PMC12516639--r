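#' Boundary filtering and buffer sensitivity
#'
#' Assets are photographed from the street, so GPS points can land just
#' outside the neighbourhood boundary (boundaries often run down the
#' middle of roads). Analysis excludes assets falling outside their area's
#' boundary, with sensitivity re-runs retaining assets within 5, 10 and
#' 20 metre buffers of the boundary edge. Point-in-polygon tests run in
#' lon/lat; metric distances to the boundary are geodesic distances on the
#' WGS84 ellipsoid, which are metre-true at this scale. Points exactly on
#' the boundary count as inside.
#'
#' @name geo-filter
#' @keywords internal
NULL

#' Buffer policy for boundary sensitivity analysis
#'
#' @param buffers_m Non-negative buffer distances in metres, ascending and
#'   including 0 (the primary analysis).
#' @return Object of class `buffer_policy`.
#' @export
buffer_policy <- function(buffers_m = c(0, 5, 10, 20)) {
  if (any(buffers_m < 0)) stop("buffers must be non-negative",
                               call. = FALSE)
  if (is.unsorted(buffers_m, strictly = TRUE))
    stop("buffers must be strictly ascending", call. = FALSE)
  if (buffers_m[1] != 0) stop("buffer 0 must be present", call. = FALSE)
  structure(list(buffers_m = buffers_m), class = "buffer_policy")
}

#' Impute missing image coordinates
#'
#' Some smartphone photographs carry no embedded GPS. Coordinates are
#' resolved, in order, from (1) the image's own EXIF coordinates, (2)
#' another image of the same asset that does have coordinates, (3) a
#' manual lookup table. Residual gaps are flagged unresolved, not fatal.
#'
#' @param images Images table (`image_id`, `asset_id`, `lon`, `lat`, ...).
#' @param manual_lookup Optional data frame `image_id`, `lon`, `lat`.
#' @return The images table with completed `lon`/`lat` where possible and
#'   a `coord_provenance` column (`exif`, `sibling_asset`, `manual`,
#'   `unresolved`).
#' @export
impute_coordinates <- function(images, manual_lookup = NULL) {
  im <- images
  has <- !is.na(im$lon) & !is.na(im$lat)
  im$coord_provenance <- ifelse(has, "exif", "unresolved")
  for (i in which(!has)) {
    sib <- which(im$asset_id == im$asset_id[i] & has)
    if (length(sib)) {
      im$lon[i] <- im$lon[sib[1]]
      im$lat[i] <- im$lat[sib[1]]
      im$coord_provenance[i] <- "sibling_asset"
    } else if (!is.null(manual_lookup)) {
      hit <- match(im$image_id[i], manual_lookup$image_id)
      if (!is.na(hit)) {
        im$lon[i] <- manual_lookup$lon[hit]
        im$lat[i] <- manual_lookup$lat[hit]
        im$coord_provenance[i] <- "manual"
      }
    }
  }
  im
}

# Signed geodesic distance (metres) from points to a polygon ring:
# negative inside (or on the boundary), positive outside.
signed_boundary_distance <- function(lon, lat, ring) {
  pts <- cbind(lon, lat)
  # close the ring for the distance computation
  if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  d <- geosphere::dist2Line(pts, ring)[, "distance"]
  inside <- as.logical(mgcv::in.out(ring, pts)) | d <= 0
  ifelse(inside, -d, d)
}

#' Filter assets against their area boundaries
#'
#' Computes, per asset, the signed geodesic distance to its own area's
#' boundary (negative = inside; points on the boundary count as inside)
#' and, per policy buffer, whether the asset is retained — i.e. whether
#' its point lies in the polygon dilated by the buffer distance. Retention
#' is monotone in buffer size by construction.
#'
#' @param x An `audit_dataset`, or an assets table (then `neighbourhoods`
#'   must be supplied).
#' @param policy A [buffer_policy()].
#' @param neighbourhoods Neighbourhood table when `x` is a plain assets
#'   table.
#' @return Data frame with one row per asset per buffer: `asset_id`,
#'   `buffer_m`, `retained`, plus per-asset `distance_to_boundary_m` and
#'   `inside_at` (smallest buffer at which retained; `Inf` if excluded at
#'   every buffer).
#' @export
filter_within_boundary <- function(x, policy = buffer_policy(),
                                   neighbourhoods = NULL) {
  if (inherits(x, "audit_dataset")) {
    assets <- x$assets
    neighbourhoods <- x$neighbourhoods
  } else assets <- x
  stopifnot(inherits(policy, "buffer_policy"))
  if (nrow(assets) == 0)
    return(data.frame(asset_id = character(), buffer_m = numeric(),
                      retained = logical(),
                      distance_to_boundary_m = numeric(),
                      inside_at = numeric()))
  unknown <- setdiff(assets$area_id, neighbourhoods$area_id)
  if (length(unknown))
    stop("filter_within_boundary: asset(s) reference unknown area(s) ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (any(is.na(assets$lon) | is.na(assets$lat)))
    stop("filter_within_boundary: assets with missing coordinates",
         call. = FALSE)
  dist <- numeric(nrow(assets))
  for (aid in unique(assets$area_id)) {
    ring <- neighbourhoods$geometry[[match(aid, neighbourhoods$area_id)]]
    sel <- assets$area_id == aid
    dist[sel] <- signed_boundary_distance(assets$lon[sel], assets$lat[sel],
                                          ring)
  }
  bufs <- policy$buffers_m
  inside_at <- vapply(dist, function(d) {
    ok <- bufs[d <= bufs]
    if (length(ok)) min(ok) else Inf
  }, numeric(1))
  out <- do.call(rbind, lapply(bufs, function(b)
    data.frame(asset_id = assets$asset_id, buffer_m = b,
               retained = dist <= b,
               distance_to_boundary_m = dist, inside_at = inside_at)))
  rownames(out) <- NULL
  out
}

#' Write assets as a GeoJSON FeatureCollection of points
#'
#' Typically used to export the assets retained by
#' [filter_within_boundary()] for mapping.
#'
#' @param assets Assets table (an `audit_dataset`'s `$assets`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_assets_geojson <- function(assets, path) {
  feats <- lapply(seq_len(nrow(assets)), function(i) {
    list(type = "Feature",
         properties = list(asset_id = assets$asset_id[i],
                           asset_type = assets$asset_type[i],
                           size_class = assets$size_class[i],
                           area_id = assets$area_id[i]),
         geometry = list(type = "Point",
                         coordinates = c(assets$lon[i], assets$lat[i])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Retained dataset at one buffer
#'
#' @param x An `audit_dataset`.
#' @param outcomes Output of [filter_within_boundary()].
#' @param buffer_m Buffer distance to apply.
#' @return The dataset restricted to assets retained at `buffer_m` (their
#'   adverts, products and images pruned accordingly).
#' @export
apply_filter <- function(x, outcomes, buffer_m = 0) {
  keep <- outcomes$asset_id[outcomes$buffer_m == buffer_m &
                              outcomes$retained]
  subset_assets(x, keep)
}

#' Exposure summaries per boundary buffer
#'
#' Re-runs the exposure tables on the dataset retained at each policy
#' buffer, for side-by-side sensitivity comparison.
#'
#' @param x An `audit_dataset`.
#' @param policy A [buffer_policy()].
#' @param scores Output of [score_products()] on the full products table
#'   (computed if `NULL`).
#' @return Named list (one element per buffer, names `"0"`, `"5"`, ...)
#'   with `n_assets`, `n_adverts` and the [exposure_tables()] list.
#' @export
buffer_sensitivity <- function(x, policy = buffer_policy(), scores = NULL) {
  stopifnot(inherits(x, "audit_dataset"))
  if (is.null(scores)) scores <- score_products(x)
  if (nrow(x$assets) == 0) {
    empty <- lapply(policy$buffers_m, function(b)
      list(n_assets = 0L, n_adverts = 0L, tables = exposure_tables(x)))
    return(stats::setNames(empty, policy$buffers_m))
  }
  outcomes <- filter_within_boundary(x, policy)
  res <- lapply(policy$buffers_m, function(b) {
    sub <- apply_filter(x, outcomes, b)
    sc <- scores[scores$product_id %in% sub$products$product_id, ,
                 drop = FALSE]
    verd <- classify_adverts(sub, sc)
    list(n_assets = nrow(sub$assets), n_adverts = nrow(sub$adverts),
         tables = exposure_tables(sub, scores = sc, verdicts = verd))
  })
  stats::setNames(res, policy$buffers_m)
}
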