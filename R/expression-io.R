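#' Build a validated FPKM expression table
#'
#' The package represents a genes-by-samples FPKM matrix as a long tibble with
#' one row per (gene, sample) measurement and the sample's tissue label carried
#' alongside. This constructor validates a wide data frame (one gene id column
#' plus one numeric column per sample) together with a sample-to-tissue map and
#' returns that long form.
#'
#' @param x A data frame: first column gene identifiers, remaining columns one
#'   numeric FPKM column per sample.
#' @param tissue_map Either `NULL` (tissue labels are derived from sample names
#'   by stripping a trailing replicate suffix such as `_1` or `.2`), or a data
#'   frame with columns `sample_id` and `tissue`.
#' @return A tibble of class `fpkm_tbl` with columns `gene_id`, `sample_id`,
#'   `tissue` and `fpkm`.
#' @details Values must be finite and non-negative; missing values are not
#'   permitted (an absent measurement must be encoded as 0 upstream). Gene and
#'   sample identifiers must be unique. Tissue labels are trimmed of
#'   surrounding whitespace and compared case-sensitively.
#' @examples
#' wide <- data.frame(gene = c("g1", "g2"),
#'                    prostate_1 = c(5, 0), prostate_2 = c(7, 0),
#'                    liver_1 = c(0.2, 3))
#' as_fpkm_tbl(wide)
#' @export
as_fpkm_tbl <- function(x, tissue_map = NULL) {
  if (!is.data.frame(x) || ncol(x) < 2L) {
    abort("`x` must be a data frame with a gene id column and >= 1 sample column.")
  }
  gene_id <- as.character(x[[1L]])
  if (anyDuplicated(gene_id)) {
    dup <- unique(gene_id[duplicated(gene_id)])
    abort(paste0("Duplicated gene ids: ", paste(head(dup, 5L), collapse = ", ")))
  }
  sample_id <- colnames(x)[-1L]
  if (anyDuplicated(sample_id)) {
    abort("Duplicated sample columns in expression input.")
  }
  vals <- as.matrix(x[, -1L, drop = FALSE])
  if (nrow(vals) > 0L && !is.numeric(vals)) {
    abort("All sample columns must be numeric FPKM values.")
  }
  storage.mode(vals) <- "double"
  bad <- which(!is.finite(vals) | vals < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(sprintf(
      "Invalid FPKM value %s at gene '%s', sample '%s' (must be finite and >= 0).",
      format(vals[bad[1L, 1L], bad[1L, 2L]]),
      gene_id[bad[1L, 1L]], sample_id[bad[1L, 2L]]
    ))
  }

  tissue <- resolve_tissues(sample_id, tissue_map)

  n_g <- length(gene_id)
  n_s <- length(sample_id)
  out <- tibble(
    gene_id = rep(gene_id, times = n_s),
    sample_id = rep(sample_id, each = n_g),
    tissue = rep(tissue, each = n_g),
    fpkm = as.vector(vals)
  )
  class(out) <- c("fpkm_tbl", class(out))
  out
}

resolve_tissues <- function(sample_id, tissue_map) {
  if (is.null(tissue_map)) {
    tissue <- sub("[._][0-9]+$", "", sample_id)
  } else {
    if (!all(c("sample_id", "tissue") %in% names(tissue_map))) {
      abort("`tissue_map` needs columns `sample_id` and `tissue`.")
    }
    idx <- match(sample_id, tissue_map$sample_id)
    if (anyNA(idx)) {
      abort(paste0("Samples missing from tissue map: ",
                   paste(sample_id[is.na(idx)], collapse = ", ")))
    }
    tissue <- as.character(tissue_map$tissue[idx])
  }
  tissue <- trimws(tissue)
  if (any(tissue == "")) abort("Empty tissue label after trimming.")
  tissue
}

#' Read an FPKM matrix from a tab-separated file
#'
#' Expects a header row, a first column of gene identifiers and one column per
#' sample. Tissue labels come from an optional two-column sidecar file
#' (`sample_id`, `tissue`, tab-separated) or are derived from the sample names
#' by stripping a trailing `_<n>`/`.<n>` replicate suffix.
#'
#' @param path Path to the expression TSV.
#' @param tissue_map_path Optional path to the sample-to-tissue sidecar TSV.
#' @return A validated `fpkm_tbl` (see [as_fpkm_tbl()]).
#' @export
read_fpkm_matrix <- function(path, tissue_map_path = NULL) {
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                       show_col_types = FALSE)
  if (ncol(x) < 2L) abort(sprintf("'%s' has no sample columns.", path))
  tm <- NULL
  if (!is.null(tissue_map_path)) {
    tm <- readr::read_tsv(tissue_map_path, col_types = readr::cols(),
                          progress = FALSE, show_col_types = FALSE)
    names(tm)[1:2] <- c("sample_id", "tissue")
  }
  as_fpkm_tbl(x, tissue_map = tm)
}

#' Write an FPKM table to a tab-separated file
#'
#' Writes the wide genes-by-samples layout with full float precision
#' (`%.6g`) so that a write/read round trip reproduces values exactly, plus an
#' optional sample-to-tissue sidecar.
#'
#' @param x An `fpkm_tbl`.
#' @param path Output TSV path.
#' @param tissue_map_path Optional path for the two-column sidecar.
#' @return `path`, invisibly.
#' @export
write_fpkm_matrix <- function(x, path, tissue_map_path = NULL) {
  stopifnot(inherits(x, "fpkm_tbl"))
  wide <- tidyr::pivot_wider(
    dplyr::select(as_tibble(x), "gene_id", "sample_id", "fpkm"),
    names_from = "sample_id", values_from = "fpkm"
  )
  fmt <- wide
  fmt[-1L] <- lapply(fmt[-1L], function(v) sprintf("%.6g", v))
  readr::write_tsv(fmt, path, progress = FALSE)
  if (!is.null(tissue_map_path)) {
    sm <- dplyr::distinct(as_tibble(x), .data$sample_id, .data$tissue)
    readr::write_tsv(sm, tissue_map_path, progress = FALSE)
  }
  invisible(path)
}

#' Collapse sample replicates to per-tissue mean FPKM
#'
#' The mean FPKM over a tissue's samples estimates that tissue's total
#' expression level and is the substrate for specificity classification.
#'
#' @param x An `fpkm_tbl` (long genes-by-samples table).
#' @return A tibble of class `tissue_means` with columns `gene_id`, `tissue`
#'   and `mean_fpkm`; tissues are ordered alphabetically within each gene.
#' @examples
#' wide <- data.frame(g = "g1", prostate_1 = 2, prostate_2 = 4, liver_1 = 1)
#' tissue_means(as_fpkm_tbl(wide))
#' @export
tissue_means <- function(x) {
  stopifnot(inherits(x, "fpkm_tbl"))
  out <- as_tibble(x) |>
    dplyr::group_by(.data$gene_id, .data$tissue) |>
    dplyr::summarise(mean_fpkm = mean(.data$fpkm), .groups = "drop") |>
    dplyr::arrange(.data$gene_id, .data$tissue)
  class(out) <- c("tissue_means", class(out))
  out
}

# tissue_means -> named genes x tissues matrix (internal workhorse)
means_matrix <- function(tm) {
  stopifnot(inherits(tm, "tissue_means"))
  wide <- tidyr::pivot_wider(as_tibble(tm), names_from = "tissue",
                             values_from = "mean_fpkm")
  m <- as.matrix(wide[-1L])
  rownames(m) <- wide$gene_id
  m[, sort(colnames(m)), drop = FALSE]
}
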