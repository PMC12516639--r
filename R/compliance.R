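#' Healthier Food Advertising Policy compliance classification
#'
#' A hypothetical Healthier Food Advertising Policy (HFAP), modelled on
#' Transport for London's, restricts HFSS product adverts and food/drink
#' brand-only adverts. Classification runs at the advert level over the
#' food and non-alcoholic-beverage adverts (alcohol and gambling are
#' outside HFAP scope): a brand-only food/drink advert, or an advert
#' showing any HFSS product, "would be non-compliant"; an advert whose
#' assessable products all pass is compliant; otherwise (some product
#' could not be scored) the advert is not assessable.
#'
#' @name compliance
#' @keywords internal
NULL

#' Is an advert a food/drink advert?
#'
#' A food and drink advert is any advert displaying at least one food
#' and/or non-alcoholic beverage product, or a brand-only advert for a
#' food/drink brand. Alcoholic beverages do not count towards the
#' food/drink total.
#'
#' @param x A validated `audit_dataset`.
#' @param advert_id Optional advert identifiers to restrict to.
#' @return Logical vector along `x$adverts` rows (or along `advert_id`).
#' @export
is_food_drink_advert <- function(x, advert_id = NULL) {
  stopifnot(inherits(x, "audit_dataset"))
  apt <- advert_product_types(x)
  fd_ids <- unique(apt$advert_id[apt$product_type %in%
                                   c("food", "non_alcoholic_beverage")])
  out <- x$adverts$advert_id %in% fd_ids |
    (x$adverts$brand_only & x$adverts$brand_food_drink)
  names(out) <- x$adverts$advert_id
  if (!is.null(advert_id)) out <- out[as.character(advert_id)]
  out
}

classify_one <- function(brand_only, any_hfss, any_missing, n_assessed,
                         n_missing) {
  if (brand_only) {
    status <- "would_be_non_compliant"; reason <- "brand_only"
  } else if (any_hfss) {
    # an assessed HFSS product overrides missing data on sibling products
    status <- "would_be_non_compliant"; reason <- "hfss_product"
  } else if (any_missing) {
    status <- "not_assessable"; reason <- "missing_data"
  } else {
    status <- "compliant"; reason <- "all_assessable_pass"
  }
  data.frame(status = status, reason = reason,
             n_products_assessed = n_assessed,
             n_products_missing = n_missing)
}

#' Classify adverts against the hypothetical HFAP
#'
#' Applies the precedence rule per food/drink advert: brand-only implies
#' would-be non-compliant; else any HFSS product implies would-be
#' non-compliant; else any food/drink product without an NPM verdict
#' implies not assessable; else compliant. Only food/drink products count
#' towards the assessed/missing totals.
#'
#' @param x A validated `audit_dataset`.
#' @param scores Output of [score_products()] covering the dataset's
#'   products (computed if `NULL`). Supplying scores for product ids not in
#'   the dataset is an error.
#' @return Data frame with one row per food/drink advert: `advert_id`,
#'   `status` (`would_be_non_compliant`, `compliant`, `not_assessable`),
#'   `reason` (`brand_only`, `hfss_product`, `missing_data`,
#'   `all_assessable_pass`), `n_products_assessed`, `n_products_missing`.
#' @export
classify_adverts <- function(x, scores = NULL) {
  stopifnot(inherits(x, "audit_dataset"))
  if (is.null(scores)) scores <- score_products(x)
  extraneous <- setdiff(scores$product_id, x$products$product_id)
  if (length(extraneous))
    stop("classify_adverts: verdicts supplied for unknown product(s) ",
         paste(extraneous, collapse = ", "), call. = FALSE)
  fd <- is_food_drink_advert(x)
  ids <- x$adverts$advert_id[fd]
  if (!length(ids))
    return(data.frame(advert_id = character(), status = character(),
                      reason = character(),
                      n_products_assessed = integer(),
                      n_products_missing = integer()))
  lk <- merge(x$advert_products,
              scores[, c("product_id", "product_type", "assessable",
                         "is_hfss")], by = "product_id")
  lk <- lk[lk$product_type %in% c("food", "non_alcoholic_beverage") &
             lk$advert_id %in% ids, , drop = FALSE]
  brand_only <- stats::setNames(x$adverts$brand_only, x$adverts$advert_id)
  rows <- lapply(ids, function(id) {
    pk <- lk[lk$advert_id == id, , drop = FALSE]
    cbind(advert_id = id,
          classify_one(
            brand_only = isTRUE(brand_only[[id]]),
            any_hfss = any(pk$assessable & pk$is_hfss, na.rm = TRUE),
            any_missing = any(!pk$assessable),
            n_assessed = sum(pk$assessable),
            n_missing = sum(!pk$assessable)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-quintile compliance summary
#'
#' Counts compliant, would-be non-compliant and not-assessable food/drink
#' adverts by deprivation quintile; row sums equal the per-quintile
#' food/drink advert counts.
#'
#' @param x A validated `audit_dataset`.
#' @param verdicts Output of [classify_adverts()].
#' @return Data frame with one row per quintile and count columns
#'   `n_non_compliant`, `n_compliant`, `n_not_assessable`, `n_food_drink`.
#' @export
compliance_summary <- function(x, verdicts) {
  stopifnot(inherits(x, "audit_dataset"))
  adq <- advert_quintiles(x)
  q <- factor(adq[verdicts$advert_id], levels = 1:5)
  tab <- table(factor(verdicts$status,
                      levels = c("would_be_non_compliant", "compliant",
                                 "not_assessable")), q)
  data.frame(imd_quintile = 1:5,
             n_non_compliant = as.integer(tab["would_be_non_compliant", ]),
             n_compliant = as.integer(tab["compliant", ]),
             n_not_assessable = as.integer(tab["not_assessable", ]),
             n_food_drink = as.integer(colSums(tab)))
}
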