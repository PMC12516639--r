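#' End-to-end audit analysis pipeline
#'
#' Orchestrates the stages in fieldwork order: load (or generate) the
#' coded audit tables; impute missing image coordinates; exclude assets
#' outside their area boundary (with buffer sensitivity); score products
#' under the NPM; classify adverts against the hypothetical HFAP; and
#' produce the exposure tables and planned chi-square tests, together with
#' a run manifest recording seeds, a config hash and row counts at every
#' stage.
#'
#' @name pipeline
#' @keywords internal
NULL

#' Pipeline run configuration
#'
#' Exactly one of `paths` (per-table input files, see [load_audit()]) or
#' `generator` (a [generator_config()]) must be supplied.
#'
#' @param paths Input directory or named list of audit table paths.
#' @param generator A [generator_config()] for synthetic input.
#' @param manual_coords Optional manual coordinate lookup data frame
#'   (`image_id`, `lon`, `lat`).
#' @param policy A [buffer_policy()].
#' @param fibre_basis Default fibre basis for NPM scoring.
#' @param seed Integer seed recorded in the manifest and used for any
#'   pipeline-level randomness.
#' @param out_dir Optional output directory for the report bundle CSVs.
#' @return Object of class `run_config`.
#' @export
run_config <- function(paths = NULL, generator = NULL,
                       manual_coords = NULL, policy = buffer_policy(),
                       fibre_basis = c("AOAC", "NSP"), seed = 1,
                       out_dir = NULL) {
  if (is.null(paths) == is.null(generator))
    stop("run_config: supply exactly one of 'paths' or 'generator'",
         call. = FALSE)
  structure(list(paths = paths, generator = generator,
                 manual_coords = manual_coords, policy = policy,
                 fibre_basis = match.arg(fibre_basis), seed = seed,
                 out_dir = out_dir),
            class = "run_config")
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(paste(deparse(config[setdiff(names(config), "out_dir")]),
                   collapse = ""), tf)
  unname(tools::md5sum(tf))
}

#' Run the full analysis pipeline
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage logging?
#' @return A report bundle: `dataset` (as loaded/generated), `images`
#'   (with coordinate provenance), `filter_outcomes`, `analysis_dataset`
#'   (retained at buffer 0), `scored_products`, `verdicts`, `tables`,
#'   `tests`, `sensitivity` (per-buffer exposure tables) and `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  log_stage <- function(...) if (!quiet) message(sprintf(...))
  ds <- if (!is.null(config$generator)) generate_audit(config$generator)
        else load_audit(config$paths)
  n0 <- count_hierarchy(ds)
  log_stage("loaded: %d assets, %d adverts, %d products",
            n0$n_assets, n0$n_adverts, n0$n_products)

  images <- impute_coordinates(ds$images, config$manual_coords)
  n_unresolved <- sum(images$coord_provenance == "unresolved")
  if (n_unresolved)
    log_stage("coordinates: %d image(s) unresolved", n_unresolved)

  outcomes <- filter_within_boundary(ds, config$policy)
  analysis <- apply_filter(ds, outcomes, 0)
  n1 <- count_hierarchy(analysis)
  log_stage("boundary filter: %d assets retained, %d excluded",
            n1$n_assets, n0$n_assets - n1$n_assets)

  scores <- score_products(analysis$products, config$fibre_basis)
  n_na <- sum(scores$in_npm_scope & !scores$assessable)
  if (n_na)
    log_stage("NPM: %d in-scope product(s) not assessable", n_na)
  verdicts <- classify_adverts(analysis, scores)
  tables <- exposure_tables(analysis, scores = scores, verdicts = verdicts)
  tests <- run_exposure_tests(analysis, verdicts = verdicts,
                              scores = scores)
  sensitivity <- buffer_sensitivity(ds, config$policy,
                                    scores = score_products(
                                      ds$products, config$fibre_basis))

  manifest <- list(
    seed = config$seed,
    generator_seed = if (!is.null(config$generator))
      config$generator$seed,
    config_hash = config_hash(unclass(config)),
    stage_counts = list(
      input = n0,
      images_unresolved = n_unresolved,
      geo = list(records_in = n0$n_assets,
                 records_retained = n1$n_assets,
                 records_excluded = n0$n_assets - n1$n_assets),
      analysis = n1,
      products_not_assessable = n_na,
      food_drink_adverts = nrow(verdicts)))

  bundle <- list(dataset = ds, images = images,
                 filter_outcomes = outcomes, analysis_dataset = analysis,
                 scored_products = scores, verdicts = verdicts,
                 tables = tables, tests = tests,
                 sensitivity = sensitivity, manifest = manifest)
  if (!is.null(config$out_dir)) write_report_bundle(bundle, config$out_dir)
  bundle
}

write_report_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_audit(bundle$dataset, file.path(dir, "dataset"))
  wr <- function(df, f)
    utils::write.csv(df, file.path(dir, f), row.names = FALSE, na = "")
  wr(bundle$filter_outcomes, "filter_outcomes.csv")
  wr(bundle$scored_products, "scored_products.csv")
  wr(bundle$verdicts, "advert_verdicts.csv")
  tb <- bundle$tables
  for (nm in names(tb)) {
    t <- tb[[nm]]
    if (is.null(t)) next
    if (is.matrix(t)) t <- as.data.frame.matrix(t)
    utils::write.csv(t, file.path(dir, paste0("table_", nm, ".csv")))
  }
  tests <- bundle$tests
  test_rows <- do.call(rbind, lapply(names(tests), function(nm) {
    t <- tests[[nm]]
    if (is.null(t)) return(NULL)
    data.frame(test = nm, statistic = t$statistic, df = t$df,
               p_value = t$p_value, valid = t$valid)
  }))
  if (!is.null(test_rows)) wr(test_rows, "exposure_tests.csv")
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(dir)
}

#' Generate and write a synthetic audit dataset
#'
#' Convenience wrapper pairing [generate_audit()] with [write_audit()];
#' the same seed writes byte-identical files.
#'
#' @param config A [generator_config()].
#' @param dir Output directory.
#' @return The generated `audit_dataset`, invisibly.
#' @export
simulate_audit <- function(config = generator_config(), dir) {
  ds <- generate_audit(config)
  write_audit(ds, dir)
  invisible(ds)
}
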