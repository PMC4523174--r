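#' Dichotomize an immunohistochemistry intensity score
#'
#' Scores follow the usual 0--3 scale (0 absent, 1 faint, 2 moderate, 3 strong
#' reactivity in >30% of epithelial cells). Scores 0--1 are *low* (marker
#' negative), 2--3 *high* (marker positive).
#'
#' @param score Integer vector with values in 0..3.
#' @return Factor with levels `low`, `high`.
#' @examples
#' dichotomize(c(0, 1, 2, 3))
#' @export
dichotomize <- function(score) {
  if (any(!score %in% 0:3)) {
    bad <- score[!score %in% 0:3]
    abort(sprintf("IHC scores must be in 0..3; got %s.",
                  paste(unique(bad), collapse = ", ")))
  }
  factor(ifelse(score >= 2, "high", "low"), levels = c("low", "high"))
}

histology_levels <- c("benign", "GG2", "GG3", "GG4", "GG5", "metastasis")

#' Construct a 2x2 marker-by-histology contingency table
#'
#' Rows are marker status (negative, positive), columns the histology split
#' (benign vs tumor, the latter pooling Gleason grades and metastases).
#'
#' @param a,b,c,d Counts: `a` negative & benign, `b` negative & tumor,
#'   `c` positive & benign, `d` positive & tumor.
#' @return An object of class `contingency_2x2` (a 2x2 integer matrix with
#'   dimnames).
#' @examples
#' contingency_2x2(29, 148, 127, 29)
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cnt <- c(a, b, c, d)
  if (any(cnt < 0) || any(cnt != round(cnt))) {
    abort("Counts must be non-negative integers.")
  }
  m <- matrix(as.integer(cnt), nrow = 2L, byrow = TRUE,
              dimnames = list(status = c("negative", "positive"),
                              histology = c("benign", "tumor")))
  class(m) <- c("contingency_2x2", class(m))
  m
}

#' Cross-tabulate marker status against histology for an IHC cohort
#'
#' Takes a per-core cohort table, optionally collapses replicate cores per
#' case, dichotomizes the staining score, and tabulates marker status against
#' the benign-versus-tumor histology split. The full breakdown over histology
#' classes (benign, Gleason grades, metastasis) is attached as attribute
#' `breakdown`.
#'
#' @param records Data frame with columns `case_id`, `histology` (one of
#'   `benign`, `GG2`..`GG5`, `metastasis`), `score` (0--3) and optionally
#'   `compartment`.
#' @param compartment If given, restrict to records of this compartment label.
#' @param collapse How to collapse replicate cores of a case: `"max"` (the
#'   usual tissue-microarray convention, default) or `"none"` to treat each
#'   core as a unit.
#' @return A `contingency_2x2` with attribute `breakdown` (tibble
#'   status x histology class counts).
#' @export
ihc_contingency <- function(records, compartment = NULL,
                            collapse = c("max", "none")) {
  collapse <- match.arg(collapse)
  records <- as_tibble(records)
  need <- c("case_id", "histology", "score")
  if (!all(need %in% names(records))) {
    abort(paste0("`records` needs columns: ", paste(need, collapse = ", ")))
  }
  if (!is.null(compartment)) {
    records <- dplyr::filter(records, .data$compartment == .env$compartment)
  }
  bad <- !records$histology %in% histology_levels
  if (any(bad)) {
    abort(sprintf("Unknown histology label(s) in rows %s: %s",
                  paste(head(which(bad), 5L), collapse = ", "),
                  paste(unique(records$histology[bad]), collapse = ", ")))
  }
  if (collapse == "max" && nrow(records) > 0L) {
    records <- records |>
      dplyr::group_by(.data$case_id, .data$histology) |>
      dplyr::summarise(score = max(.data$score), .groups = "drop")
  }

  status <- if (nrow(records)) dichotomize(records$score) else
    factor(character(), levels = c("low", "high"))
  hist_f <- factor(records$histology, levels = histology_levels)
  full <- table(status = factor(ifelse(status == "high", "positive", "negative"),
                                levels = c("negative", "positive")),
                histology = hist_f)

  breakdown <- as_tibble(as.data.frame(full)) |>
    tidyr::pivot_wider(names_from = "histology", values_from = "Freq")

  tumor_cols <- setdiff(histology_levels, "benign")
  out <- contingency_2x2(full["negative", "benign"],
                         sum(full["negative", tumor_cols]),
                         full["positive", "benign"],
                         sum(full["positive", tumor_cols]))
  attr(out, "breakdown") <- breakdown
  out
}

margins_2x2 <- function(t) {
  list(r = rowSums(unclass(t)), c = colSums(unclass(t)), n = sum(t))
}

#' Pearson chi-square for a 2x2 table
#'
#' Closed form `n (ad - bc)^2 / (r1 r2 c1 c2)`, no continuity correction,
#' df = 1; the p-value is the upper tail of chi-square(1). A zero marginal
#' makes the statistic undefined (`NA`).
#'
#' @param t A `contingency_2x2`.
#' @return Tibble with `statistic`, `df`, `p_value`.
#' @examples
#' chi_square(contingency_2x2(29, 148, 127, 29))
#' @export
chi_square <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  mg <- margins_2x2(t)
  if (any(mg$r == 0) || any(mg$c == 0)) {
    return(tibble(statistic = NA_real_, df = 1L, p_value = NA_real_))
  }
  stat <- mg$n * (t[1, 1] * t[2, 2] - t[1, 2] * t[2, 1])^2 / prod(mg$r, mg$c)
  tibble(statistic = stat, df = 1L,
         p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Likelihood-ratio G statistic for a 2x2 table
#'
#' `2 * sum(O * ln(O/E))` over non-empty cells, expectations from the margins;
#' the `0 * ln(0)` limit contributes zero. `NA` when a marginal is zero.
#'
#' @param t A `contingency_2x2`.
#' @return Tibble with `statistic`, `df`, `p_value`.
#' @export
g_test <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  mg <- margins_2x2(t)
  if (any(mg$r == 0) || any(mg$c == 0)) {
    return(tibble(statistic = NA_real_, df = 1L, p_value = NA_real_))
  }
  O <- as.vector(unclass(t))
  E <- as.vector(outer(mg$r, mg$c) / mg$n)
  stat <- 2 * sum(ifelse(O > 0, O * log(O / E), 0))
  tibble(statistic = stat, df = 1L,
         p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Phi coefficient of a 2x2 table
#'
#' `(ad - bc) / sqrt(r1 r2 c1 c2)`: the Pearson correlation of the two binary
#' variables. For binary-by-binary data the Spearman rank correlation equals
#' phi, so both are returned identically. With rows ordered negative then
#' positive and columns benign then tumor, a marker of benign tissue yields a
#' negative coefficient.
#'
#' @param t A `contingency_2x2`.
#' @return Tibble with `pearson_r`, `spearman_rho` (equal); `NA` on a zero
#'   margin.
#' @export
phi_correlation <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  mg <- margins_2x2(t)
  if (any(mg$r == 0) || any(mg$c == 0)) {
    return(tibble(pearson_r = NA_real_, spearman_rho = NA_real_))
  }
  phi <- (t[1, 1] * t[2, 2] - t[1, 2] * t[2, 1]) / sqrt(prod(mg$r, mg$c))
  tibble(pearson_r = phi, spearman_rho = phi)
}

#' Sensitivity and specificity of a marker for benign tissue
#'
#' The condition detected is *benign* tissue and a positive test is marker
#' expression: sensitivity is the positive fraction among benign cases,
#' specificity the negative fraction among tumor cases.
#'
#' @param t A `contingency_2x2`.
#' @return Tibble with `sensitivity`, `specificity` (`NA` for an empty class).
#' @export
sens_spec <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  mg <- margins_2x2(t)
  tibble(
    sensitivity = if (mg$c[["benign"]] > 0) t["positive", "benign"] / mg$c[["benign"]] else NA_real_,
    specificity = if (mg$c[["tumor"]] > 0) t["negative", "tumor"] / mg$c[["tumor"]] else NA_real_
  )
}

#' ROC AUC of a single-threshold binary test
#'
#' The ROC curve of a dichotomized marker has one interior operating point, so
#' its trapezoidal area is `(sensitivity + specificity) / 2`.
#'
#' @param t A `contingency_2x2`.
#' @return AUC as a single number (`NA` when a class is empty).
#' @export
binary_auc <- function(t) {
  ss <- sens_spec(t)
  (ss$sensitivity + ss$specificity) / 2
}

#' ROC AUC for ordinal scores (Mann-Whitney with tie correction)
#'
#' The probability that a randomly drawn positive-condition case scores above
#' a randomly drawn negative-condition one, plus half the probability of a
#' tie, computed via midranks.
#'
#' @param score Numeric (typically 0--3 IHC scores).
#' @param condition Logical or factor: `TRUE`/first level marks the condition
#'   class whose scores are expected to be higher (here, benign).
#' @return AUC in `[0, 1]`; `NA` when either class is empty.
#' @export
ordinal_auc <- function(score, condition) {
  condition <- as.logical(condition)
  stopifnot(length(score) == length(condition), !anyNA(condition))
  n1 <- sum(condition); n0 <- sum(!condition)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)                       # midranks handle ties
  (sum(r[condition]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-tabulate two marker statuses on the same cases
#'
#' Builds the 2x2 table of marker A status against marker B status (for
#' example membranous vs cytoplasmic staining of the same protein) together
#' with its association statistics.
#'
#' @param status_a,status_b Factors/characters with values `low`/`high` (or
#'   logicals, `TRUE` = positive), same length, same case order.
#' @return A list: `table` (a `contingency_2x2` whose columns are marker B
#'   negative/positive) and `stats` (chi-square and phi as one-row tibble).
#' @export
cross_tabulate <- function(status_a, status_b) {
  pos <- function(s) if (is.logical(s)) s else as.character(s) %in% c("high", "positive")
  a <- pos(status_a); b <- pos(status_b)
  stopifnot(length(a) == length(b))
  t <- contingency_2x2(sum(!a & !b), sum(!a & b), sum(a & !b), sum(a & b))
  list(table = t,
       stats = dplyr::bind_cols(
         dplyr::rename(chi_square(t), chi_square = "statistic",
                       chi_p = "p_value")[c("chi_square", "chi_p")],
         phi_correlation(t)))
}

#' All diagnostic statistics of a 2x2 marker table
#'
#' @param t A `contingency_2x2`.
#' @return One-row tibble: `n`, `chi_square`, `chi_p`, `g_statistic`, `g_p`,
#'   `pearson_r`, `spearman_rho`, `sensitivity`, `specificity`, `auc`.
#' @examples
#' diagnostic_stats(contingency_2x2(29, 148, 127, 29))
#' @export
diagnostic_stats <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  chi <- chi_square(t); g <- g_test(t)
  dplyr::bind_cols(
    tibble(n = sum(t)),
    tibble(chi_square = chi$statistic, chi_p = chi$p_value,
           g_statistic = g$statistic, g_p = g$p_value),
    phi_correlation(t),
    sens_spec(t),
    tibble(auc = binary_auc(t))
  )
}

#' Evaluate an IHC-scored marker against histology
#'
#' End-to-end evaluation: collapse replicate cores, dichotomize, tabulate
#' benign vs tumor, and compute the full statistics block.
#'
#' @inheritParams ihc_contingency
#' @return Object of class `ihc_eval`: list with `table`
#'   (`contingency_2x2`), `breakdown` (per histology class), and `stats`
#'   (one-row tibble from [diagnostic_stats()]).
#' @export
ihc_eval <- function(records, compartment = NULL, collapse = c("max", "none")) {
  t <- ihc_contingency(records, compartment = compartment, collapse = collapse)
  structure(
    list(table = t, breakdown = attr(t, "breakdown"), stats = diagnostic_stats(t)),
    class = "ihc_eval"
  )
}

#' @describeIn ihc_eval Statistics block as a tibble.
#' @param x An `ihc_eval`.
#' @param ... Unused.
#' @export
tidy.ihc_eval <- function(x, ...) x$stats

#' @describeIn ihc_eval Alias of `tidy()` (the result is already one row).
#' @export
glance.ihc_eval <- function(x, ...) x$stats

#' @export
print.ihc_eval <- function(x, ...) {
  cat("<ihc_eval>\n")
  print(unclass(x$table)[, ])
  s <- x$stats
  cat(sprintf("chi-square %.2f (p %s), phi %.2f, sens %.1f%%, spec %.1f%%, AUC %.3f\n",
              s$chi_square, format.pval(s$chi_p, digits = 3), s$pearson_r,
              100 * s$sensitivity, 100 * s$specificity, s$auc))
  invisible(x)
}
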