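#' Log-transform FPKM values
#'
#' Elementwise `log2(x + 1)`; the pseudo-count keeps zero FPKM at zero on the
#' log scale.
#'
#' @param x Non-negative numeric vector or matrix.
#' @return Transformed values, same shape as `x`.
#' @export
log_fpkm <- function(x) {
  if (any(!is.finite(x) | x < 0)) abort("FPKM values must be finite and >= 0.")
  log2(x + 1)
}

#' Pairwise correlation structure of samples or tissues
#'
#' Computes all pairwise Spearman and Pearson correlation coefficients on
#' `log2(FPKM + 1)` over all genes (zeros included, no detection filter).
#' Spearman uses midranks for ties. A zero-variance column yields `NA`
#' coefficients for its pairs rather than an error.
#'
#' @param x An `fpkm_tbl` (correlations between samples) or a `tissue_means`
#'   table (correlations between tissue profiles). At least 3 genes.
#' @return An object of class `cor_result`: a long tibble with one row per
#'   unordered pair (`id_a < id_b`; columns `id_a`, `id_b`, `spearman`,
#'   `pearson`, `n_genes`) carrying the full square matrices as attributes
#'   `spearman` and `pearson` (symmetric, unit diagonal).
#' @export
pairwise_correlations <- function(x) {
  if (inherits(x, "tissue_means")) {
    m <- means_matrix(x)
  } else if (inherits(x, "fpkm_tbl")) {
    wide <- tidyr::pivot_wider(
      dplyr::select(as_tibble(x), "gene_id", "sample_id", "fpkm"),
      names_from = "sample_id", values_from = "fpkm")
    m <- as.matrix(wide[-1L])
    rownames(m) <- wide$gene_id
  } else {
    abort("`x` must be an `fpkm_tbl` or a `tissue_means` table.")
  }
  if (nrow(m) < 3L) abort("Need at least 3 genes for correlations.")

  lm2 <- log_fpkm(m)
  sp <- suppressWarnings(cor(lm2, method = "spearman"))
  pe <- suppressWarnings(cor(lm2, method = "pearson"))
  diag(sp) <- 1; diag(pe) <- 1

  ids <- colnames(m)
  pairs <- which(upper.tri(sp), arr.ind = TRUE)
  out <- tibble(
    id_a = ids[pairs[, 1L]],
    id_b = ids[pairs[, 2L]],
    spearman = sp[pairs],
    pearson = pe[pairs],
    n_genes = nrow(m)
  )
  attr(out, "spearman") <- sp
  attr(out, "pearson") <- pe
  class(out) <- c("cor_result", class(out))
  out
}

#' @describeIn pairwise_correlations Long pair table as a plain tibble.
#' @param ... Unused.
#' @export
tidy.cor_result <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @describeIn pairwise_correlations One-row summary (number of pairs, mean
#'   and range of each coefficient over pairs).
#' @export
glance.cor_result <- function(x, ...) {
  tibble(
    n_pairs = nrow(x),
    n_genes = if (nrow(x)) x$n_genes[1L] else 0L,
    mean_spearman = mean(x$spearman),
    min_spearman = suppressWarnings(min(x$spearman)),
    max_spearman = suppressWarnings(max(x$spearman)),
    mean_pearson = mean(x$pearson)
  )
}

#' Write correlation results
#'
#' @param x A `cor_result`.
#' @param pairs_path Long-format TSV of pairs.
#' @param matrix_path Optional square Spearman matrix TSV.
#' @return `pairs_path`, invisibly.
#' @export
write_correlations <- function(x, pairs_path, matrix_path = NULL) {
  stopifnot(inherits(x, "cor_result"))
  readr::write_tsv(tidy(x), pairs_path, progress = FALSE)
  if (!is.null(matrix_path)) {
    sp <- attr(x, "spearman")
    readr::write_tsv(dplyr::bind_cols(tibble(id = rownames(sp)), as_tibble(sp)),
                     matrix_path, progress = FALSE)
  }
  invisible(pairs_path)
}
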