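#' UK 2004/05 Nutrient Profile Model scoring
#'
#' The Food Standards Agency's 2004/05 Nutrient Profile Model (NPM) scores
#' a product per 100 g (drinks per 100 ml, treated identically here). "A"
#' points accrue from energy, saturated fat, total sugars and sodium (each
#' component 0-10); "C" points from fruit/vegetable/nut content (FVN%,
#' component 0, 1, 2 or 5), fibre and protein (each 0-5). The total score
#' is A minus the counted C components, with a protein cap: when A >= 11
#' and the FVN component is below 5, protein points are not counted. A food
#' scoring 4 or more, or a drink scoring 1 or more, fails the model and is
#' classed HFSS (high in fat, salt and sugar).
#'
#' Band thresholds are shipped as a data table
#' (`inst/extdata/npm_thresholds.csv`, checksum-pinned at load) rather than
#' code, so any divergence from the published technical guidance is
#' auditable. All band edges are strict: a nutrient value equal to a
#' threshold scores in the lower band.
#'
#' @name npm
#' @keywords internal
NULL

# md5 of the shipped threshold table; verified on first load.
NPM_TABLE_MD5 <- "f680c777fa1c7b3c8cd62d45cf67590c"

.npm_cache <- new.env(parent = emptyenv())

#' NPM band thresholds
#'
#' @return Named list of data frames (`points`, `threshold`), one per
#'   scoring component.
#' @export
npm_thresholds <- function() {
  if (is.null(.npm_cache$tab)) {
    path <- system.file("extdata", "npm_thresholds.csv", package = "adaudit",
                        mustWork = TRUE)
    sum <- unname(tools::md5sum(path))
    if (!identical(sum, NPM_TABLE_MD5))
      stop("npm_thresholds: threshold table checksum mismatch (",
           sum, ") - table has diverged from the pinned version",
           call. = FALSE)
    tab <- utils::read.csv(path)
    .npm_cache$tab <- split(tab[, c("points", "threshold")], tab$component)
  }
  .npm_cache$tab
}

# Points for nutrient values x under one component's band table.
# Strict ">": a value equal to a threshold falls in the band below.
band_points <- function(x, component) {
  tab <- npm_thresholds()[[component]]
  tab <- tab[order(tab$threshold), , drop = FALSE]
  idx <- findInterval(x, tab$threshold, left.open = TRUE)
  c(0L, tab$points)[idx + 1L]
}

check_profile <- function(profile) {
  num <- c("energy_kj_per_100", "satfat_g_per_100", "total_sugars_g_per_100",
           "sodium_mg_per_100", "fibre_g_per_100", "protein_g_per_100",
           "fvn_percent")
  for (f in num) {
    if (is.null(profile[[f]]))
      stop("nutrient profile lacks field '", f, "'", call. = FALSE)
    if (any(profile[[f]] < 0, na.rm = TRUE))
      stop("negative nutrient value in '", f, "'", call. = FALSE)
  }
  if (any(profile$fvn_percent > 100, na.rm = TRUE))
    stop("fvn_percent above 100", call. = FALSE)
  fb <- profile$fibre_basis
  if (is.null(fb) || any(!toupper(fb) %in% c("NSP", "AOAC")))
    stop("fibre_basis must be 'NSP' or 'AOAC'", call. = FALSE)
  invisible(profile)
}

#' A points (energy, saturated fat, sugars, sodium)
#'
#' @param profile Data frame (or list of equal-length vectors) of per-100 g
#'   nutrients: `energy_kj_per_100`, `satfat_g_per_100`,
#'   `total_sugars_g_per_100`, `sodium_mg_per_100`, `fibre_g_per_100`,
#'   `fibre_basis` ("NSP" or "AOAC"), `protein_g_per_100`, `fvn_percent`.
#' @return Data frame with per-component points (`energy`, `satfat`,
#'   `sugars`, `sodium`, each 0-10) and their sum `a_total` (0-40).
#' @export
#' @examples
#' a_points(data.frame(energy_kj_per_100 = 1046, satfat_g_per_100 = 2,
#'                     total_sugars_g_per_100 = 26, sodium_mg_per_100 = 100,
#'                     fibre_g_per_100 = 0, fibre_basis = "AOAC",
#'                     protein_g_per_100 = 0, fvn_percent = 0))
a_points <- function(profile) {
  check_profile(profile)
  out <- data.frame(
    energy = band_points(profile$energy_kj_per_100, "energy_kj"),
    satfat = band_points(profile$satfat_g_per_100, "satfat_g"),
    sugars = band_points(profile$total_sugars_g_per_100, "total_sugars_g"),
    sodium = band_points(profile$sodium_mg_per_100, "sodium_mg"))
  out$a_total <- out$energy + out$satfat + out$sugars + out$sodium
  out
}

#' C points (fruit/vegetable/nut content, fibre, protein)
#'
#' Fibre is banded on the declared basis: NSP (Englyst) or AOAC, per the
#' `fibre_basis` field. The FVN component takes values 0, 1, 2 or 5.
#'
#' @inheritParams a_points
#' @return Data frame with per-component points (`fvn`, `fibre`, `protein`)
#'   and their sum `c_total` (0-15).
#' @export
c_points <- function(profile) {
  check_profile(profile)
  basis <- toupper(profile$fibre_basis)
  basis <- rep_len(basis, length(profile$fibre_g_per_100))
  fibre <- integer(length(basis))
  for (b in unique(basis)) {
    comp <- if (b == "NSP") "fibre_nsp_g" else "fibre_aoac_g"
    sel <- basis == b
    fibre[sel] <- band_points(profile$fibre_g_per_100[sel], comp)
  }
  out <- data.frame(
    fvn = band_points(profile$fvn_percent, "fvn_percent"),
    fibre = fibre,
    protein = band_points(profile$protein_g_per_100, "protein_g"))
  out$c_total <- out$fvn + out$fibre + out$protein
  out
}

#' Score a product under the 2004/05 NPM
#'
#' @inheritParams a_points
#' @param product_class `"food"` or `"drink"` (recycled along rows). Foods
#'   fail (HFSS) at a total score of 4 or more, drinks at 1 or more.
#' @return Data frame with the A and C component breakdowns, the
#'   `protein_capped` flag, `total_score`, `product_class` and `is_hfss`.
#' @export
#' @examples
#' p <- data.frame(energy_kj_per_100 = 1046, satfat_g_per_100 = 2,
#'                 total_sugars_g_per_100 = 26, sodium_mg_per_100 = 100,
#'                 fibre_g_per_100 = 0.8, fibre_basis = "NSP",
#'                 protein_g_per_100 = 3, fvn_percent = 0)
#' npm_score(p, "food")
npm_score <- function(profile, product_class) {
  a <- a_points(profile)
  cc <- c_points(profile)
  if (any(!product_class %in% c("food", "drink")))
    stop("product_class must be 'food' or 'drink'", call. = FALSE)
  cls <- rep_len(product_class, nrow(a))
  capped <- a$a_total >= 11 & cc$fvn < 5
  counted_c <- ifelse(capped, cc$fvn + cc$fibre, cc$c_total)
  total <- a$a_total - counted_c
  is_hfss <- ifelse(cls == "food", total >= 4, total >= 1)
  data.frame(
    a_energy = a$energy, a_satfat = a$satfat, a_sugars = a$sugars,
    a_sodium = a$sodium, a_total = a$a_total,
    c_fvn = cc$fvn, c_fibre = cc$fibre, c_protein = cc$protein,
    c_total = cc$c_total,
    protein_capped = capped, total_score = total,
    product_class = cls, is_hfss = is_hfss)
}

#' Derive fruit/vegetable/nut percentage with provenance
#'
#' The FVN% feeding the C points is taken, in order of preference, from
#' (1) the ingredients list, by summing the declared percentages of
#' fruit/vegetable/nut entries (clamped at 100, since percentages of
#' composite ingredients can double-count); (2) a reference lookup table
#' matched on product name (case-insensitive); (3) otherwise the product is
#' assumed to contain no fruit, vegetables or nuts and scores zero for the
#' domain.
#'
#' @param ingredients `NULL`, or a data frame with columns `name`,
#'   `declared_percent` (may be `NA`) and `is_fvn` (logical), in label
#'   order.
#' @param name Product name used for reference matching (optional).
#' @param lookup `NULL`, or a reference data frame with columns `name` and
#'   `fvn_percent`.
#' @return List with `fvn_percent` and `provenance` (one of
#'   `"ingredients_sum"`, `"reference_match"`, `"assumed_zero"`).
#' @export
derive_fvn_percent <- function(ingredients = NULL, name = NULL,
                               lookup = NULL) {
  if (!is.null(ingredients) && nrow(ingredients)) {
    pc <- ingredients$declared_percent
    if (any(pc > 100, na.rm = TRUE))
      stop("derive_fvn_percent: declared percent above 100", call. = FALSE)
    declared <- !is.na(pc)
    if (any(declared & ingredients$is_fvn)) {
      tot <- sum(pc[declared & ingredients$is_fvn])
      return(list(fvn_percent = min(tot, 100),
                  provenance = "ingredients_sum"))
    }
    # an ingredients list whose FVN entries all declare percentages of zero
    # relevance still counts as evidence only when percentages are present
    if (any(declared) && !any(ingredients$is_fvn))
      return(list(fvn_percent = 0, provenance = "ingredients_sum"))
  }
  if (!is.null(lookup) && !is.null(name)) {
    hit <- match(tolower(name), tolower(lookup$name))
    if (!is.na(hit))
      return(list(fvn_percent = lookup$fvn_percent[hit],
                  provenance = "reference_match"))
  }
  list(fvn_percent = 0, provenance = "assumed_zero")
}

#' Convert per-portion nutrition to per 100 g
#'
#' Out-of-home products often declare nutrition per portion. Conversion
#' requires a product weight, sourced (in order) from manual weighing of
#' common items or a portion-size handbook; with no reasonable weight
#' source the product cannot be assessed under the NPM.
#'
#' @param nutrients_per_portion Named list/data frame of per-portion values
#'   using the per-100 field names (`energy_kj_per_100` etc., here read as
#'   per portion).
#' @param portion_weight_g Positive portion weight in grams.
#' @param weight_source One of `"measured"`, `"handbook"`, `"none"`.
#' @return List with `assessable` (logical), `profile` (one-row data frame
#'   of per-100 g values, or `NULL`) and `weight_source`.
#' @export
per_portion_to_per_100 <- function(nutrients_per_portion, portion_weight_g,
                                   weight_source = c("measured", "handbook",
                                                     "none")) {
  weight_source <- match.arg(weight_source)
  if (weight_source == "none")
    return(list(assessable = FALSE, profile = NULL, weight_source = "none"))
  if (is.na(portion_weight_g) || portion_weight_g <= 0)
    stop("per_portion_to_per_100: portion weight must be positive",
         call. = FALSE)
  scale <- 100 / portion_weight_g
  prof <- as.data.frame(nutrients_per_portion)
  num <- vapply(prof, is.numeric, logical(1))
  prof[num] <- prof[num] * scale
  list(assessable = TRUE, profile = prof, weight_source = weight_source)
}

#' Batch-score the products table of an audit dataset
#'
#' Scores every food and non-alcoholic-beverage product that carries a full
#' nutrient profile; alcoholic beverages, gambling and "other" products are
#' out of NPM scope, and products with missing nutrition are flagged not
#' assessable. Missing FVN% is scored as zero (assumed no
#' fruit/vegetable/nut content).
#'
#' @param products Products table of an `audit_dataset` (or the dataset
#'   itself).
#' @param fibre_basis Default fibre basis where the table does not declare
#'   one: `"AOAC"` (modern labels) or `"NSP"`.
#' @return The products table augmented with `in_npm_scope`, `assessable`,
#'   the A/C breakdown columns, `total_score` and `is_hfss` (`NA` where not
#'   assessable).
#' @export
score_products <- function(products, fibre_basis = c("AOAC", "NSP")) {
  fibre_basis <- match.arg(fibre_basis)
  if (inherits(products, "audit_dataset")) products <- products$products
  p <- products
  n <- nrow(p)
  scope <- p$product_type %in% c("food", "non_alcoholic_beverage")
  need <- c("energy_kj_per_100", "satfat_g_per_100", "total_sugars_g_per_100",
            "sodium_mg_per_100", "fibre_g_per_100", "protein_g_per_100")
  have <- if (n) rowSums(is.na(as.matrix(p[, need, drop = FALSE]))) == 0
          else logical(0)
  assessable <- scope & have
  cols <- c("a_energy", "a_satfat", "a_sugars", "a_sodium", "a_total",
            "c_fvn", "c_fibre", "c_protein", "c_total", "protein_capped",
            "total_score", "is_hfss")
  for (cl in cols) p[[cl]] <- rep(NA, n)
  p$product_class <- rep(NA_character_, n)
  p$in_npm_scope <- scope
  p$assessable <- assessable
  if (any(assessable)) {
    prof <- p[assessable, , drop = FALSE]
    prof$fvn_percent[is.na(prof$fvn_percent)] <- 0
    if (is.null(prof$fibre_basis)) prof$fibre_basis <- fibre_basis
    prof$fibre_basis[is.na(prof$fibre_basis) | prof$fibre_basis == ""] <-
      fibre_basis
    cls <- ifelse(prof$product_type == "food", "food", "drink")
    sc <- npm_score(prof, cls)
    for (cl in cols) p[[cl]][assessable] <- sc[[cl]]
    p$product_class[assessable] <- cls
  }
  p
}
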