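#' Run the full classification stage of the pipeline
#'
#' Reads an FPKM matrix, collapses it to tissue means, classifies every gene,
#' and writes the per-gene results, the category census (TSV and JSON), the
#' pairwise tissue correlation structure, and the co-enrichment network
#' (GraphML and edge list) into an output directory. Progress and the
#' thresholds in use are logged to standard error; results go only to files
#' and the returned object.
#'
#' @param config Either a YAML file path or a list with elements
#'   `matrix_path`, optional `tissue_map_path`, `out_dir`, `classification`
#'   (arguments for [spec_config()], `target_tissue` required) and optional
#'   `max_combo` (default 4).
#' @return Invisibly, a list with `results`, `census`, `correlations`,
#'   `network`, and `files` (named vector of paths written).
#' @export
run_classification <- function(config) {
  cfg <- load_pipeline_config(config)
  for (f in c("matrix_path", "out_dir", "classification")) {
    if (is.null(cfg[[f]])) abort(sprintf("Pipeline config is missing `%s`.", f))
  }
  if (!file.exists(cfg$matrix_path)) {
    abort(sprintf("Expression matrix not found: '%s'.", cfg$matrix_path))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  scfg <- do.call(spec_config, as.list(cfg$classification))
  message(sprintf(
    "classify: target=%s detection>%g high>=%gx enriched>=%gx groups %d-%d all-high>=%g",
    scfg$target_tissue, scfg$detection_limit, scfg$high_fold,
    scfg$enriched_fold, scfg$group_min, scfg$group_max, scfg$all_high_cutoff))

  x <- read_fpkm_matrix(cfg$matrix_path, tissue_map_path = cfg$tissue_map_path)
  tm <- tissue_means(x)
  res <- classify_all(tm, scfg)
  cen <- category_census(res)
  cors <- pairwise_correlations(tm)
  net <- build_network(res, max_combo = cfg$max_combo %||% 4L)

  p <- function(name) file.path(cfg$out_dir, name)
  files <- c(
    results = p("classification.tsv"),
    census = p("census.tsv"),
    census_json = p("census.json"),
    correlations = p("correlations.tsv"),
    cor_matrix = p("correlation_matrix.tsv"),
    network_graphml = p("network.graphml"),
    network_edges = p("network_edges.tsv")
  )
  write_spec_result(res, files[["results"]])
  readr::write_tsv(cen$categories, files[["census"]], progress = FALSE)
  jsonlite::write_json(
    list(categories = cen$categories, major = cen$major),
    files[["census_json"]], digits = NA, dataframe = "rows")
  write_correlations(cors, files[["correlations"]], files[["cor_matrix"]])
  write_network(net, files[["network_graphml"]], files[["network_edges"]])
  message(sprintf("classify: %d genes -> %s", nrow(res), cfg$out_dir))

  invisible(list(results = res, census = cen, correlations = cors,
                 network = net, files = files))
}

#' Run the IHC marker evaluation stage
#'
#' Reads a cohort table (TSV: `case_id`, `histology`, `compartment`,
#' `score`), evaluates each requested compartment against the
#' benign-versus-tumor split, and writes the histology breakdown, the 2x2
#' table and the statistics block per compartment. A cohort with only one
#' histology class is reported with undefined (`NA`) statistics and a
#' warning rather than an error.
#'
#' @param config YAML path or list with `cohort_path`, `out_dir`, optional
#'   `compartments` (default: every compartment present) and `collapse`
#'   (`"max"` or `"none"`).
#' @return Invisibly, a named list of `ihc_eval` objects (one per
#'   compartment) plus `files`.
#' @export
run_ihc_eval <- function(config) {
  cfg <- load_pipeline_config(config)
  for (f in c("cohort_path", "out_dir")) {
    if (is.null(cfg[[f]])) abort(sprintf("Pipeline config is missing `%s`.", f))
  }
  if (!file.exists(cfg$cohort_path)) {
    abort(sprintf("Cohort table not found: '%s'.", cfg$cohort_path))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  records <- readr::read_tsv(cfg$cohort_path, col_types = readr::cols(),
                             progress = FALSE, show_col_types = FALSE)
  bad_hist <- which(!records$histology %in% histology_levels)
  if (length(bad_hist)) {
    abort(sprintf("Unknown histology label(s) in rows: %s",
                  paste(head(bad_hist, 10L), collapse = ", ")))
  }
  if (any(!records$score %in% 0:3)) {
    abort(sprintf("Out-of-range score in rows: %s",
                  paste(head(which(!records$score %in% 0:3), 10L), collapse = ", ")))
  }
  compartments <- cfg$compartments %||% unique(records$compartment)
  collapse <- cfg$collapse %||% "max"

  evals <- list()
  files <- character()
  for (cp in compartments) {
    ev <- ihc_eval(records, compartment = cp, collapse = collapse)
    if (any(colSums(unclass(ev$table)) == 0)) {
      warn(sprintf("Compartment '%s': only one histology class present; statistics undefined.", cp))
    }
    base <- file.path(cfg$out_dir, paste0("ihc_", cp))
    readr::write_tsv(ev$breakdown, paste0(base, "_breakdown.tsv"), progress = FALSE)
    tab <- as_tibble(as.data.frame.matrix(unclass(ev$table)), rownames = "status")
    readr::write_tsv(tab, paste0(base, "_2x2.tsv"), progress = FALSE)
    readr::write_tsv(ev$stats, paste0(base, "_stats.tsv"), progress = FALSE)
    jsonlite::write_json(as.list(ev$stats), paste0(base, "_stats.json"),
                         digits = NA, auto_unbox = TRUE)
    files <- c(files, setNames(paste0(base, "_stats.tsv"), cp))
    evals[[cp]] <- ev
    message(sprintf("ihc-eval: compartment '%s', n=%d", cp, sum(ev$table)))
  }
  evals$files <- files
  invisible(evals)
}

load_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort(sprintf("Config file not found: '%s'.", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML file path.")
  config
}
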