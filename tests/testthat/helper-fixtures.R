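# Small in-code fixtures and independent brute-force oracles.

# wide genes-by-samples data frame -> fpkm_tbl
make_fpkm <- function(values, gene_ids = NULL, sample_ids = NULL, tissues = NULL) {
  values <- as.matrix(values)
  gene_ids <- gene_ids %||% sprintf("g%d", seq_len(nrow(values)))
  sample_ids <- sample_ids %||% sprintf("s%d", seq_len(ncol(values)))
  wide <- data.frame(gene_id = gene_ids, values)
  names(wide)[-1] <- sample_ids
  tm <- if (!is.null(tissues)) data.frame(sample_id = sample_ids, tissue = tissues)
  as_fpkm_tbl(wide, tissue_map = tm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a named per-tissue mean vector with given target value, one competitor, rest
make_row <- function(target = 100, competitor = 1, rest = 0.5, n = 27,
                     target_name = "prostate") {
  vals <- c(target, competitor, rep(rest, n - 2))
  setNames(vals, c(target_name, sprintf("t%02d", seq_len(n - 1))))
}

# Spearman by explicit midranks + Pearson on ranks (independent of stats::cor's
# spearman path)
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# exhaustive search over all tissue subsets containing the target: does ANY
# group of allowed size satisfy the group-enrichment criterion?
exhaustive_group <- function(row, cfg) {
  tissues <- names(row)
  others <- setdiff(tissues, cfg$target_tissue)
  best <- NULL
  for (k in seq(cfg$group_min, min(cfg$group_max, length(row) - 1))) {
    combos <- utils::combn(others, k - 1, simplify = FALSE)
    for (cmb in combos) {
      members <- c(cfg$target_tissue, cmb)
      vals <- row[members]
      excl <- row[setdiff(tissues, members)]
      lim <- if (length(excl)) max(excl) else 0
      if (all(vals > cfg$detection_limit) && mean(vals) >= cfg$enriched_fold * lim) {
        if (is.null(best)) best <- sort(members)
      }
    }
    if (!is.null(best)) return(best)
  }
  NULL
}

# AUC by enumerating all (condition, non-condition) pairs
auc_oracle <- function(score, condition) {
  pos <- score[as.logical(condition)]
  neg <- score[!as.logical(condition)]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# random 2x2 table with all margins positive
random_2x2 <- function() {
  repeat {
    t <- contingency_2x2(sample(0:50, 1), sample(0:50, 1),
                         sample(0:50, 1), sample(0:50, 1))
    m <- unclass(t)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(t)
  }
}
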