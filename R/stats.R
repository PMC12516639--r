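#' Reliability and exposure statistics
#'
#' Cohen's kappa for dual-coder agreement, Pearson chi-square tests with a
#' Cochran validity flag, and the per-quintile exposure summary tables.
#'
#' @name audit-stats
#' @keywords internal
NULL

#' Round half away from zero
#'
#' The uniform rounding rule used for every reported percentage: halves
#' round away from zero (so 22.5 -> 23), unlike base R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Integer percentage share under the uniform rounding rule.
pct_share <- function(n, total) {
  if (length(total) == 1 && total <= 0) return(rep(NA_real_, length(n)))
  round_half_up(100 * n / total)
}

#' Cohen's kappa from a confusion table
#'
#' Unweighted kappa for nominal categories: observed agreement `p_o` is the
#' diagonal mass, chance agreement `p_e` the sum of row-by-column margin
#' products, and kappa `(p_o - p_e) / (1 - p_e)`. When the margins make
#' chance agreement 1, kappa is undefined and returned as `NA` with
#' `undefined = TRUE` (except for the degenerate perfect-agreement case
#' `p_o = 1`, reported as kappa 1).
#'
#' @param table Square numeric matrix of counts, rater 1 in rows, rater 2
#'   in columns.
#' @return Object of class `audit_kappa`: `kappa`, `p_o`, `p_e`, `n`,
#'   `undefined`.
#' @export
#' @examples
#' cohens_kappa(matrix(c(20, 10, 5, 15), 2))
cohens_kappa <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != ncol(table))
    stop("cohens_kappa: table must be square", call. = FALSE)
  if (any(table < 0) || any(table != round(table)))
    stop("cohens_kappa: counts must be non-negative integers",
         call. = FALSE)
  n <- sum(table)
  if (n == 0) stop("cohens_kappa: all-zero table", call. = FALSE)
  p_o <- sum(diag(table)) / n
  p_e <- sum(rowSums(table) * colSums(table)) / n^2
  if (p_e >= 1) {
    kappa <- if (p_o == 1) 1 else NA_real_
    undefined <- p_o != 1
  } else {
    kappa <- (p_o - p_e) / (1 - p_e)
    undefined <- FALSE
  }
  structure(list(kappa = kappa, p_o = p_o, p_e = p_e, n = n,
                 undefined = undefined),
            class = "audit_kappa")
}

#' @export
print.audit_kappa <- function(x, ...) {
  cat(sprintf(
    "Cohen's kappa = %s (observed agreement %.2f, chance agreement %.2f, n = %d)\n",
    if (x$undefined) "undefined" else sprintf("%.2f", x$kappa),
    x$p_o, x$p_e, x$n))
  invisible(x)
}

# Cochran's validity heuristic: no expected cell below 1 and at least 80 %
# of expected cells at or above 5.
cochran_valid <- function(expected) {
  all(expected >= 1) && mean(expected >= 5) >= 0.8
}

new_chisq_result <- function(statistic, df, p_value, observed, expected,
                             kind) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), observed = observed,
                 expected = expected,
                 std_residuals = (observed - expected) / sqrt(expected),
                 valid = cochran_valid(expected), kind = kind),
            class = "audit_chisq")
}

#' @export
print.audit_chisq <- function(x, ...) {
  cat(sprintf("Pearson chi-square (%s): X2 = %.4g, df = %d\n",
              x$kind, x$statistic, x$df))
  if (x$valid) {
    cat(sprintf("  p = %.4g (valid under Cochran's rule)\n", x$p_value))
  } else {
    cat("  expected counts violate Cochran's rule;",
        "no valid test could be run\n")
  }
  invisible(x)
}

#' Pearson chi-square test of independence with validity flag
#'
#' Wraps the Pearson test (no continuity correction) on an r x c count
#' matrix, returning the statistic, degrees of freedom `(r-1)(c-1)`, the
#' upper-tail p-value, expected counts, standardised residuals
#' `(O - E)/sqrt(E)` and a validity flag under Cochran's rule (every
#' expected count at least 1, and at least 80 % at least 5). When the flag
#' is `FALSE` the p-value should not be interpreted.
#'
#' @param observed Numeric matrix of counts with at least 2 rows and 2
#'   columns and no zero margin.
#' @return Object of class `audit_chisq`.
#' @export
#' @examples
#' chisq_independence(matrix(c(10, 20, 20, 10), 2))
chisq_independence <- function(observed) {
  observed <- as.matrix(observed)
  if (nrow(observed) < 2 || ncol(observed) < 2)
    stop("chisq_independence: need at least a 2x2 table", call. = FALSE)
  if (any(observed < 0))
    stop("chisq_independence: negative counts", call. = FALSE)
  rs <- rowSums(observed); cs <- colSums(observed)
  if (any(rs == 0))
    stop("chisq_independence: zero row margin (row ",
         paste(which(rs == 0), collapse = ", "), ")", call. = FALSE)
  if (any(cs == 0))
    stop("chisq_independence: zero column margin (column ",
         paste(which(cs == 0), collapse = ", "), ")", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(observed, correct = FALSE))
  new_chisq_result(ht$statistic, ht$parameter, ht$p.value, observed,
                   ht$expected, "independence")
}

#' Chi-square goodness-of-fit with validity flag
#'
#' One-way Pearson test of observed counts against expected proportions
#' (equal by default); df is `k - 1`. Used for the total-advertising
#' exposure test, where counts across deprivation quintiles are compared
#' with a uniform expectation.
#'
#' @param observed Numeric vector of counts (length >= 2).
#' @param p Expected proportions (default equal).
#' @return Object of class `audit_chisq`.
#' @export
chisq_gof <- function(observed, p = rep(1 / length(observed),
                                        length(observed))) {
  observed <- as.numeric(observed)
  if (length(observed) < 2)
    stop("chisq_gof: need at least 2 cells", call. = FALSE)
  if (any(observed < 0)) stop("chisq_gof: negative counts", call. = FALSE)
  if (sum(observed) == 0) stop("chisq_gof: all-zero counts", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(observed, p = p))
  new_chisq_result(ht$statistic, ht$parameter, ht$p.value, observed,
                   ht$expected, "goodness-of-fit")
}

# Advert-level NPM status among food/drink adverts: "hfss" if any product
# on the advert is HFSS; "na" for brand-only adverts or adverts with an
# unassessable food/drink product (and no HFSS product); else "non_hfss".
advert_npm_status <- function(x, scores) {
  fd <- is_food_drink_advert(x)
  ids <- x$adverts$advert_id[fd]
  lk <- merge(x$advert_products,
              scores[, c("product_id", "product_type", "assessable",
                         "is_hfss")], by = "product_id")
  lk <- lk[lk$product_type %in% c("food", "non_alcoholic_beverage"), ,
           drop = FALSE]
  any_hfss <- tapply(lk$assessable & !is.na(lk$is_hfss) & lk$is_hfss,
                     lk$advert_id, any)
  any_missing <- tapply(!lk$assessable, lk$advert_id, any)
  brand_only <- stats::setNames(x$adverts$brand_only, x$adverts$advert_id)
  status <- vapply(ids, function(id) {
    if (isTRUE(any_hfss[id][[1]])) return("hfss")
    if (isTRUE(brand_only[id][[1]]) || isTRUE(any_missing[id][[1]]))
      return("na")
    "non_hfss"
  }, character(1))
  stats::setNames(status, ids)
}

count_by <- function(keys, levels) {
  tab <- table(factor(keys, levels = levels))
  as.integer(tab)
}

#' Per-quintile exposure summary tables
#'
#' Builds the descriptive exposure summary: asset, advert and size-class
#' counts by deprivation quintile; asset-type counts; product-type counts
#' by quintile (an advert showing several products of one type contributes
#' that type once; shares use the advert denominator); food/drink versus
#' other adverts; advert-level HFSS status; compliance verdicts (when
#' supplied); and the asset-type by product-type advert count matrix.
#' Percentages are rounded half away from zero.
#'
#' @param x A validated `audit_dataset`.
#' @param scores Output of [score_products()] (computed if `NULL`).
#' @param verdicts Output of [classify_adverts()] (optional).
#' @return Named list of data frames / matrices.
#' @export
exposure_tables <- function(x, scores = NULL, verdicts = NULL) {
  stopifnot(inherits(x, "audit_dataset"))
  if (is.null(scores)) scores <- score_products(x)
  q_levels <- 1:5
  aq <- asset_quintiles(x)
  adq <- advert_quintiles(x)

  n_assets <- count_by(aq[x$assets$asset_id], q_levels)
  n_adverts <- count_by(adq[x$adverts$advert_id], q_levels)
  assets_by_quintile <- data.frame(
    imd_quintile = q_levels, n_assets = n_assets,
    pct_assets = pct_share(n_assets, sum(n_assets)))
  adverts_by_quintile <- data.frame(
    imd_quintile = q_levels, n_adverts = n_adverts,
    pct_adverts = pct_share(n_adverts, sum(n_adverts)))

  size_by_quintile <- as.matrix(table(
    factor(x$assets$size_class, levels = SIZE_CLASSES),
    factor(aq[x$assets$asset_id], levels = q_levels)))
  size_overall <- data.frame(
    size_class = SIZE_CLASSES,
    n_assets = as.integer(rowSums(size_by_quintile)),
    pct_assets = pct_share(rowSums(size_by_quintile), nrow(x$assets)))

  types <- attr(x, "asset_types") %||% asset_type_labels()
  tcount <- table(factor(x$assets$asset_type, levels = types))
  asset_type_counts <- data.frame(
    asset_type = names(tcount), n_assets = as.integer(tcount),
    pct_assets = pct_share(as.integer(tcount), nrow(x$assets)))
  asset_type_by_quintile <- as.matrix(table(
    factor(x$assets$asset_type, levels = types),
    factor(aq[x$assets$asset_id], levels = q_levels)))

  # product types per advert, deduplicated within advert
  apt <- advert_product_types(x)
  product_types_by_quintile <- as.matrix(table(
    factor(apt$product_type, levels = PRODUCT_TYPES),
    factor(adq[apt$advert_id], levels = q_levels)))
  tot_pt <- rowSums(product_types_by_quintile)
  product_type_counts <- data.frame(
    product_type = PRODUCT_TYPES, n_adverts = as.integer(tot_pt),
    pct_of_adverts = pct_share(tot_pt, nrow(x$adverts)))

  fd <- is_food_drink_advert(x)
  n_fd <- count_by(adq[x$adverts$advert_id[fd]], q_levels)
  food_drink_by_quintile <- data.frame(
    imd_quintile = q_levels, n_food_drink = n_fd,
    n_other = n_adverts - n_fd,
    pct_food_drink = pct_share(n_fd, n_adverts))

  status <- advert_npm_status(x, scores)
  hfss_by_quintile <- as.matrix(table(
    factor(status, levels = c("hfss", "non_hfss", "na")),
    factor(adq[names(status)], levels = q_levels)))

  compliance_by_quintile <- NULL
  if (!is.null(verdicts))
    compliance_by_quintile <- compliance_summary(x, verdicts)

  asset_types_of_adverts <- stats::setNames(
    x$assets$asset_type[match(x$adverts$asset_id, x$assets$asset_id)],
    x$adverts$advert_id)
  asset_product_matrix <- as.matrix(table(
    factor(asset_types_of_adverts[apt$advert_id], levels = types),
    factor(apt$product_type, levels = PRODUCT_TYPES)))

  list(assets_by_quintile = assets_by_quintile,
       adverts_by_quintile = adverts_by_quintile,
       size_by_quintile = size_by_quintile,
       size_overall = size_overall,
       asset_type_counts = asset_type_counts,
       asset_type_by_quintile = asset_type_by_quintile,
       product_type_counts = product_type_counts,
       product_types_by_quintile = product_types_by_quintile,
       food_drink_by_quintile = food_drink_by_quintile,
       hfss_by_quintile = hfss_by_quintile,
       compliance_by_quintile = compliance_by_quintile,
       asset_product_matrix = asset_product_matrix)
}

#' The three planned exposure tests
#'
#' Runs the planned chi-square analyses of advertising exposure against
#' area deprivation: (1) total advertising exposure — advert counts across
#' quintiles against a uniform expectation (goodness-of-fit); (2) food and
#' non-alcoholic beverage advertising — food/drink versus other adverts by
#' quintile (independence); (3) would-be non-compliant food/drink
#' advertising — non-compliant versus compliant adverts by quintile
#' (independence; not-assessable adverts excluded). Each result carries a
#' Cochran validity flag; where the flag is `FALSE` no valid test could be
#' run and the p-value is not interpretable.
#'
#' @param x A validated `audit_dataset`.
#' @param verdicts Output of [classify_adverts()] (computed if `NULL`).
#' @param scores Output of [score_products()] (computed if `NULL`).
#' @return Named list of `audit_chisq` results (`total`, `food_drink`,
#'   `compliance`); an entry is `NULL` when its table cannot be formed
#'   (e.g. a zero margin).
#' @export
run_exposure_tests <- function(x, verdicts = NULL, scores = NULL) {
  stopifnot(inherits(x, "audit_dataset"))
  if (is.null(scores)) scores <- score_products(x)
  if (is.null(verdicts)) verdicts <- classify_adverts(x, scores)
  adq <- advert_quintiles(x)
  q_levels <- 1:5
  n_adverts <- count_by(adq[x$adverts$advert_id], q_levels)

  total <- tryCatch(chisq_gof(n_adverts), error = function(e) NULL)

  fd <- is_food_drink_advert(x)
  n_fd <- count_by(adq[x$adverts$advert_id[fd]], q_levels)
  tab_fd <- rbind(food_drink = n_fd, other = n_adverts - n_fd)
  colnames(tab_fd) <- paste0("Q", q_levels)
  food_drink <- tryCatch(chisq_independence(tab_fd),
                         error = function(e) NULL)

  v <- verdicts[verdicts$status != "not_assessable", , drop = FALSE]
  tab_c <- rbind(
    non_compliant = count_by(
      adq[v$advert_id[v$status == "would_be_non_compliant"]], q_levels),
    compliant = count_by(
      adq[v$advert_id[v$status == "compliant"]], q_levels))
  colnames(tab_c) <- paste0("Q", q_levels)
  compliance <- tryCatch(chisq_independence(tab_c),
                         error = function(e) NULL)

  list(total = total, food_drink = food_drink, compliance = compliance)
}
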