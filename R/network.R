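#' Build the tissue co-enrichment network
#'
#' Group-enriched genes share their enrichment between the target tissue and a
#' small set of partners. The network summarises this structure: one *combo*
#' node per distinct tissue group (restricted to groups of at most `max_combo`
#' tissues), weighted by the number of genes carrying that group, linked to a
#' *tissue* node for each member. The count of highly plus moderately enriched
#' genes in the target tissue is carried alongside, mirroring how such
#' networks are usually annotated.
#'
#' @param results A `spec_result` from [classify_all()].
#' @param max_combo Largest group size displayed (default 4). Larger groups
#'   are dropped from the network but still counted by
#'   [shared_tissue_counts()].
#' @return An object of class `enrichment_network`: list with tibbles `combos`
#'   (`combo_id`, `tissues` list-column, `n_genes`), `edges` (`combo_id`,
#'   `tissue`), the `target_tissue`, and `target_enriched_count`.
#' @export
build_network <- function(results, max_combo = 4L) {
  stopifnot(inherits(results, "spec_result"))
  cfg <- attr(results, "config")
  target <- cfg$target_tissue

  res <- as_tibble(results)
  enriched_n <- sum(res$category %in% c("highly_enriched", "moderately_enriched"))

  grp <- res |>
    dplyr::filter(.data$category == "group_enriched") |>
    dplyr::mutate(combo_id = purrr::map_chr(.data$group, paste, collapse = ";"),
                  size = purrr::map_int(.data$group, length)) |>
    dplyr::filter(.data$size <= max_combo)

  combos <- grp |>
    dplyr::count(.data$combo_id, name = "n_genes") |>
    dplyr::mutate(tissues = strsplit(.data$combo_id, ";", fixed = TRUE)) |>
    dplyr::select("combo_id", "tissues", "n_genes") |>
    dplyr::arrange(.data$combo_id)

  edges <- tidyr::unnest(dplyr::select(combos, "combo_id", tissue = "tissues"),
                         "tissue")

  structure(
    list(combos = combos, edges = edges, target_tissue = target,
         target_enriched_count = enriched_n),
    class = "enrichment_network"
  )
}

#' Count group-enriched genes shared with the target per tissue
#'
#' For every non-target tissue, the number of group-enriched genes whose group
#' contains both that tissue and the target. All group sizes count here,
#' regardless of any display cutoff used for the network plot.
#'
#' @param results A `spec_result`.
#' @return Tibble `tissue`, `n_genes`, sorted by decreasing count then label;
#'   tissues sharing no gene are omitted.
#' @export
shared_tissue_counts <- function(results) {
  stopifnot(inherits(results, "spec_result"))
  target <- attr(results, "config")$target_tissue
  as_tibble(results) |>
    dplyr::filter(.data$category == "group_enriched") |>
    dplyr::select("gene_id", "group") |>
    tidyr::unnest("group") |>
    dplyr::filter(.data$group != target) |>
    dplyr::count(tissue = .data$group, name = "n_genes") |>
    dplyr::arrange(dplyr::desc(.data$n_genes), .data$tissue)
}

# enrichment_network -> igraph object with node/edge attributes
as_igraph_network <- function(net) {
  tissues <- sort(unique(c(net$target_tissue, net$edges$tissue)))
  nodes <- dplyr::bind_rows(
    tibble(name = tissues, kind = "tissue",
           weight = ifelse(tissues == net$target_tissue,
                           net$target_enriched_count, 0)),
    tibble(name = net$combos$combo_id, kind = "combo",
           weight = as.numeric(net$combos$n_genes))
  )
  igraph::graph_from_data_frame(
    d = data.frame(from = net$edges$combo_id, to = net$edges$tissue),
    directed = FALSE, vertices = as.data.frame(nodes)
  )
}

#' Export an enrichment network
#'
#' @param net An `enrichment_network`.
#' @param graphml_path Optional GraphML output (node attributes `kind`,
#'   `weight`).
#' @param edges_path Optional plain edge-list TSV (`combo_id`, `tissue`,
#'   `n_genes`).
#' @return `net`, invisibly.
#' @export
write_network <- function(net, graphml_path = NULL, edges_path = NULL) {
  stopifnot(inherits(net, "enrichment_network"))
  if (!is.null(graphml_path)) {
    igraph::write_graph(as_igraph_network(net), graphml_path, format = "graphml")
  }
  if (!is.null(edges_path)) {
    e <- dplyr::left_join(net$edges,
                          dplyr::select(net$combos, "combo_id", "n_genes"),
                          by = "combo_id")
    readr::write_tsv(e, edges_path, progress = FALSE)
  }
  invisible(net)
}

#' @describeIn build_network Combo nodes as a plain tibble (one row per
#'   tissue group with its gene count and flattened membership).
#' @param x An `enrichment_network`.
#' @param ... Unused.
#' @export
tidy.enrichment_network <- function(x, ...) {
  dplyr::mutate(dplyr::select(x$combos, "combo_id", "n_genes"),
                size = purrr::map_int(x$combos$tissues, length),
                .after = "combo_id")
}

#' @describeIn build_network One-row summary of the network.
#' @export
glance.enrichment_network <- function(x, ...) {
  tibble(
    n_combos = nrow(x$combos),
    n_tissues = length(unique(x$edges$tissue)),
    n_group_genes = sum(x$combos$n_genes),
    target_enriched_count = x$target_enriched_count
  )
}

#' @export
print.enrichment_network <- function(x, ...) {
  cat(sprintf(
    "<enrichment_network> target '%s': %d combos over %d tissues, %d group-enriched genes; %d target-enriched genes\n",
    x$target_tissue, nrow(x$combos), length(unique(x$edges$tissue)),
    sum(x$combos$n_genes), x$target_enriched_count))
  invisible(x)
}
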