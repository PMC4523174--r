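#' Classification thresholds for tissue specificity
#'
#' Bundles the thresholds of the specificity scheme: a gene is *highly
#' enriched* in the target tissue when its mean FPKM there is at least
#' `high_fold` times the maximum in any other tissue, *moderately enriched* at
#' `enriched_fold`, *group enriched* when a group of `group_min`--`group_max`
#' tissues including the target jointly exceeds all remaining tissues
#' `enriched_fold`-fold, *expressed in all* (high/low split at
#' `all_high_cutoff` FPKM) when detected everywhere, and *enhanced* when the
#' target exceeds `enriched_fold` times the across-tissue average.
#'
#' @param target_tissue Tissue label the classification is relative to.
#' @param detection_limit FPKM above which (strictly) a gene counts as
#'   detected in a tissue. Default 1, roughly one mRNA copy per cell.
#' @param high_fold Fold cutoff for the highly-enriched tier. Default 50.
#' @param enriched_fold Fold cutoff for the moderate/group/enhanced tiers.
#'   Default 5.
#' @param group_min,group_max Allowed group sizes (target included) for the
#'   group-enrichment search. Defaults 2 and 7.
#' @param all_high_cutoff FPKM splitting expressed-in-all genes into the high
#'   and low subcategories. Default 10.
#' @return A list of class `spec_config`.
#' @export
spec_config <- function(target_tissue,
                        detection_limit = 1,
                        high_fold = 50,
                        enriched_fold = 5,
                        group_min = 2L,
                        group_max = 7L,
                        all_high_cutoff = 10) {
  stopifnot(is.character(target_tissue), length(target_tissue) == 1L)
  if (detection_limit <= 0) abort("`detection_limit` must be > 0.")
  if (!(high_fold > enriched_fold && enriched_fold > 1)) {
    abort("Need high_fold > enriched_fold > 1.")
  }
  if (group_min < 2L || group_max < group_min) {
    abort("Group sizes must satisfy 2 <= group_min <= group_max.")
  }
  structure(
    list(target_tissue = target_tissue,
         detection_limit = detection_limit,
         high_fold = high_fold,
         enriched_fold = enriched_fold,
         group_min = as.integer(group_min),
         group_max = as.integer(group_max),
         all_high_cutoff = all_high_cutoff),
    class = "spec_config"
  )
}

#' Read a classification config from YAML or key=value text
#'
#' @param path YAML file whose top-level keys are the [spec_config()]
#'   arguments.
#' @return A `spec_config`.
#' @export
read_spec_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(spec_config, vals)
}

spec_categories <- c(
  "not_detected", "highly_enriched", "moderately_enriched", "group_enriched",
  "expressed_all_high", "expressed_all_low", "enhanced", "mixed"
)

major_groups <- c(
  not_detected = "not_detected",
  mixed = "mixed",
  expressed_all_high = "expressed_in_all",
  expressed_all_low = "expressed_in_all",
  highly_enriched = "elevated",
  moderately_enriched = "elevated",
  group_enriched = "elevated",
  enhanced = "elevated"
)

#' Tissue-specific score of one gene
#'
#' The score is the mean FPKM in the target tissue divided by the maximum mean
#' FPKM among all other tissues: the fold separation between the target and
#' its closest competitor. A gene expressed only in the target scores `Inf`;
#' a gene silent everywhere scores 0.
#'
#' @param row Named non-negative numeric vector of per-tissue mean FPKM
#'   (names are tissue labels; at least two tissues).
#' @param target Target tissue label, must be one of `names(row)`.
#' @return A single number (possibly `Inf`).
#' @examples
#' tissue_specific_score(c(prostate = 4700.79, liver = 5.76), "prostate")
#' @export
tissue_specific_score <- function(row, target) {
  check_row(row)
  if (!target %in% names(row)) {
    abort(sprintf("Unknown target tissue '%s'.", target))
  }
  num <- unname(row[[target]])
  den <- max(row[names(row) != target])
  if (den == 0) {
    if (num > 0) Inf else 0
  } else {
    num / den
  }
}

check_row <- function(row) {
  if (is.null(names(row)) || anyDuplicated(names(row))) {
    abort("`row` must be a named vector with unique tissue labels.")
  }
  if (length(row) < 2L) abort("Need at least two tissues.")
  if (any(!is.finite(row) | row < 0)) abort("Tissue means must be finite and >= 0.")
  invisible(row)
}

#' Search for an enriched tissue group containing the target
#'
#' For each candidate group size k (from `group_min` to `group_max`), the
#' candidate group is the target tissue plus the k-1 highest-expressing other
#' tissues; it is accepted when the group's mean FPKM is at least
#' `enriched_fold` times the maximum FPKM among the excluded tissues and every
#' group member is detected. The smallest accepted group is returned. Top-k
#' selection is optimal for this criterion (swapping any member for a
#' higher-expressing excluded tissue can only raise the group mean and lower
#' the excluded maximum), which the test suite verifies against exhaustive
#' subset enumeration.
#'
#' @param row Named per-tissue mean FPKM vector.
#' @param cfg A [spec_config()].
#' @return Character vector of group tissue labels (sorted, containing the
#'   target), or `NULL` when no group qualifies. Ties in the top-k selection
#'   are broken by tissue label so output is deterministic.
#' @export
find_enriched_group <- function(row, cfg) {
  check_row(row)
  target <- cfg$target_tissue
  if (!target %in% names(row)) abort(sprintf("Unknown target tissue '%s'.", target))
  if (row[[target]] <= cfg$detection_limit) return(NULL)

  others <- row[names(row) != target]
  ord <- order(-others, names(others))   # expression desc, label asc on ties
  others <- others[ord]

  kmax <- min(cfg$group_max, length(row) - 1L)
  for (k in seq(cfg$group_min, kmax)) {
    members <- c(row[[target]], unname(others[seq_len(k - 1L)]))
    if (any(members <= cfg$detection_limit)) next
    excluded <- others[seq.int(k, length(others))]
    lim <- if (length(excluded)) max(excluded) else 0
    if (mean(members) >= cfg$enriched_fold * lim) {
      return(sort(c(target, names(others)[seq_len(k - 1L)])))
    }
  }
  NULL
}

#' Classify one gene's tissue profile
#'
#' Applies the category precedence chain: not detected anywhere; highly then
#' moderately enriched (fold over the maximum of the other tissues); group
#' enriched ([find_enriched_group()]); expressed in all tissues (high/low);
#' enhanced (fold over the across-tissue average, target included); otherwise
#' mixed. Categories are mutually exclusive and exhaustive.
#'
#' @inheritParams find_enriched_group
#' @return One-row tibble: `category` (factor over the eight categories),
#'   `score` (tissue-specific score; `Inf` when no other tissue is expressed),
#'   `group` (list-column, group members for group-enriched genes, else
#'   `NULL`), `n_detected_tissues`.
#' @export
classify_gene <- function(row, cfg) {
  check_row(row)
  target <- cfg$target_tissue
  if (!target %in% names(row)) abort(sprintf("Unknown target tissue '%s'.", target))

  detected <- row > cfg$detection_limit
  n_det <- sum(detected)
  score <- tissue_specific_score(row, target)
  grp <- NULL

  if (n_det == 0L) {
    cat_ <- "not_detected"
  } else if (detected[[target]] && score >= cfg$high_fold) {
    cat_ <- "highly_enriched"
  } else if (detected[[target]] && score >= cfg$enriched_fold) {
    cat_ <- "moderately_enriched"
  } else if (!is.null(grp <- find_enriched_group(row, cfg))) {
    cat_ <- "group_enriched"
  } else if (all(detected) && min(row) >= cfg$all_high_cutoff) {
    cat_ <- "expressed_all_high"
  } else if (all(detected)) {
    cat_ <- "expressed_all_low"
  } else if (detected[[target]] && row[[target]] >= cfg$enriched_fold * mean(row)) {
    cat_ <- "enhanced"
  } else {
    cat_ <- "mixed"
  }

  tibble(
    category = factor(cat_, levels = spec_categories),
    score = score,
    group = list(grp),
    n_detected_tissues = as.integer(n_det)
  )
}

#' Classify every gene of a tissue-mean matrix
#'
#' @param tm A `tissue_means` table from [tissue_means()], or an `fpkm_tbl`
#'   (collapsed internally).
#' @param cfg A [spec_config()]; its `target_tissue` must be a tissue of `tm`.
#' @return A tibble of class `spec_result` with one row per gene: `gene_id`,
#'   `category`, `score`, `group` (list-column), `n_detected_tissues`. The
#'   config is attached as attribute `config`. Summarise with
#'   [category_census()], [glance()], or plot with [autoplot()].
#' @export
classify_all <- function(tm, cfg) {
  if (inherits(tm, "fpkm_tbl")) tm <- tissue_means(tm)
  if (nrow(tm) == 0L) {
    out <- tibble(gene_id = character(),
                  category = factor(character(), levels = spec_categories),
                  score = numeric(), group = list(),
                  n_detected_tissues = integer())
    attr(out, "config") <- cfg
    class(out) <- c("spec_result", class(out))
    return(out)
  }
  m <- means_matrix(tm)
  if (!cfg$target_tissue %in% colnames(m)) {
    abort(sprintf("Target tissue '%s' absent from matrix.", cfg$target_tissue))
  }
  res <- purrr::map(seq_len(nrow(m)), function(i) classify_gene(m[i, ], cfg))
  out <- dplyr::bind_cols(
    tibble(gene_id = rownames(m)),
    dplyr::bind_rows(res)
  )
  attr(out, "config") <- cfg
  class(out) <- c("spec_result", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Census of specificity categories
#'
#' Counts genes per category and per major group (not detected / mixed /
#' expressed in all / elevated, the latter pooling the highly, moderately,
#' group-enriched and enhanced tiers).
#'
#' @param results A `spec_result` from [classify_all()].
#' @return A list with tibbles `categories` (`category`, `n`, `fraction`) and
#'   `major` (`major_group`, `n`, `fraction`); fractions sum to 1 (or are 0
#'   for an empty gene set).
#' @export
category_census <- function(results) {
  stopifnot(inherits(results, "spec_result"))
  n_genes <- nrow(results)
  cats <- tibble(category = factor(spec_categories, levels = spec_categories)) |>
    dplyr::left_join(dplyr::count(as_tibble(results), .data$category),
                     by = "category") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  fraction = if (n_genes > 0) .data$n / n_genes else 0)
  major_levels <- c("not_detected", "mixed", "expressed_in_all", "elevated")
  major <- cats |>
    dplyr::mutate(major_group = factor(major_groups[as.character(.data$category)],
                                       levels = major_levels)) |>
    dplyr::group_by(.data$major_group) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
    dplyr::mutate(fraction = if (n_genes > 0) .data$n / n_genes else 0)
  list(categories = cats, major = major)
}

#' Write per-gene classification results as TSV
#'
#' Groups are flattened to semicolon-joined tissue labels.
#'
#' @param results A `spec_result`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_spec_result <- function(results, path) {
  stopifnot(inherits(results, "spec_result"))
  flat <- as_tibble(results) |>
    dplyr::mutate(group = purrr::map_chr(.data$group,
                                         ~ paste(.x %||% character(0), collapse = ";")))
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}

#' @describeIn classify_all Per-gene results as a plain tibble with the group
#'   list-column flattened to a semicolon-joined string.
#' @param x A `spec_result`.
#' @param ... Unused.
#' @export
tidy.spec_result <- function(x, ...) {
  as_tibble(x) |>
    dplyr::mutate(group = purrr::map_chr(.data$group,
                                         ~ paste(.x %||% character(0), collapse = ";")))
}

#' @describeIn classify_all One-row summary: gene counts overall, detected in
#'   the target tissue, and per major group.
#' @export
glance.spec_result <- function(x, ...) {
  cen <- category_census(x)$major
  counts <- setNames(as.list(cen$n), paste0("n_", as.character(cen$major_group)))
  dplyr::bind_cols(tibble(n_genes = nrow(x)), as_tibble(counts))
}
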