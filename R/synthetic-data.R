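# run code under a local, restored RNG state so generators are pure
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic multi-tissue expression matrix
#'
#' Describes a genes-by-samples FPKM matrix with planted specificity
#' structure. Defaults emulate the study conditions the package targets: 27
#' tissues with 4 samples each, a detection limit of 1 FPKM, and baseline
#' expression levels spanning roughly four orders of magnitude. Planted fold
#' margins sit strictly inside the category bands (highly enriched planted at
#' >= 75-fold, moderately at 10-fold, groups at 8-fold, enhanced well above
#' the 5-fold-over-average bound) so zero-noise classification is
#' unambiguous.
#'
#' @param n_tissues Number of tissues (default 27); the first is the target.
#' @param samples_per_tissue Replicate samples per tissue (default 4).
#' @param genes_per_category Named integer vector of planted gene counts;
#'   names from the eight category labels (see [classify_all()]).
#' @param target_tissue Label of the target tissue (default `"prostate"`).
#' @param tissue_names Optional full vector of tissue labels (length
#'   `n_tissues`, first must be `target_tissue`).
#' @param noise_sd Log2-scale standard deviation of multiplicative sample
#'   noise around each planted tissue mean (default 0.2; 0 gives exact
#'   means).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   planted target-tissue expression level (defaults `log(80)` and 1.5,
#'   clipped to 3--8000 FPKM).
#' @param group_plan Optional list of character vectors of partner tissues,
#'   one per planted group-enriched gene, fixing each gene's group exactly;
#'   default draws group sizes uniformly from 2--7 (target included) with
#'   random partners.
#' @param seed Integer seed; part of the specification so generated fixtures
#'   are reproducible bit for bit.
#' @return A list of class `matrix_spec`.
#' @export
matrix_spec <- function(n_tissues = 27L,
                        samples_per_tissue = 4L,
                        genes_per_category = c(
                          not_detected = 10L, highly_enriched = 10L,
                          moderately_enriched = 10L, group_enriched = 10L,
                          expressed_all_high = 10L, expressed_all_low = 10L,
                          enhanced = 10L, mixed = 10L),
                        target_tissue = "prostate",
                        tissue_names = NULL,
                        noise_sd = 0.2,
                        baseline_meanlog = log(80),
                        baseline_sdlog = 1.5,
                        group_plan = NULL,
                        seed = 1L) {
  if (n_tissues < 3L) abort("Need at least 3 tissues.")
  if (samples_per_tissue < 1L) abort("Need >= 1 sample per tissue.")
  bad <- setdiff(names(genes_per_category), spec_categories)
  if (length(bad)) abort(paste0("Unknown categories: ", paste(bad, collapse = ", ")))
  if (any(genes_per_category < 0)) abort("Gene counts must be >= 0.")
  if (is.null(tissue_names)) {
    tissue_names <- c(target_tissue,
                      sprintf("tissue_%02d", seq_len(n_tissues - 1L) + 1L))
  }
  if (length(tissue_names) != n_tissues || tissue_names[1L] != target_tissue) {
    abort("`tissue_names` must have length `n_tissues` and start with the target.")
  }
  gpc <- genes_per_category[genes_per_category > 0]
  if ("enhanced" %in% names(gpc) && n_tissues < 20L) {
    abort("Planting enhanced genes needs >= 20 tissues (the 5-fold-over-average pattern is too tight below that).")
  }
  if (!is.null(group_plan)) {
    n_grp <- unname(genes_per_category["group_enriched"])
    if (is.na(n_grp) || length(group_plan) != n_grp) {
      abort("`group_plan` must have one partner set per planted group-enriched gene.")
    }
  }
  structure(
    list(n_tissues = as.integer(n_tissues),
         samples_per_tissue = as.integer(samples_per_tissue),
         genes_per_category = genes_per_category,
         target_tissue = target_tissue, tissue_names = tissue_names,
         noise_sd = noise_sd, baseline_meanlog = baseline_meanlog,
         baseline_sdlog = baseline_sdlog, group_plan = group_plan,
         seed = as.integer(seed)),
    class = "matrix_spec"
  )
}

# planted per-tissue expected means for one gene of a given category;
# returns list(means, group)
plant_gene <- function(category, spec, partners = NULL) {
  tn <- spec$tissue_names
  Tn <- spec$n_tissues
  others <- tn[-1L]
  b <- min(8000, max(3, rlnorm(1, spec$baseline_meanlog, spec$baseline_sdlog)))
  mu <- setNames(numeric(Tn), tn)
  group <- NULL

  switch(category,
    not_detected = {
      mu[] <- runif(Tn, 0, 0.8)
    },
    highly_enriched = {
      mu[others] <- runif(Tn - 1L, 0, b / 75)
      mu[1L] <- b
    },
    moderately_enriched = {
      mu[others] <- runif(Tn - 1L, 0, b / 10)
      mu[sample(others, 1L)] <- b / 10     # pin the max: score exactly 10
      mu[1L] <- b
    },
    group_enriched = {
      if (is.null(partners)) {
        k <- sample(2:min(7L, Tn - 1L), 1L)
        partners <- sample(others, k - 1L)
      }
      mu[others] <- runif(Tn - 1L, 0, b / 8)
      mu[c(tn[1L], partners)] <- b
      group <- sort(c(tn[1L], partners))
    },
    expressed_all_high = {
      mu[] <- runif(Tn, 12, 40)
    },
    expressed_all_low = {
      mu[] <- runif(Tn, 2, 8)
    },
    enhanced = {
      b <- max(b, 30)
      n_und <- max(2L, round(0.2 * (Tn - 1L)))
      shuffled <- sample(others)
      mu[shuffled[1L]] <- 0.5 * b                     # competitor blocks 5-fold tiers
      mu[shuffled[2:(1 + n_und)]] <- runif(n_und, 0, 0.3)
      mid <- shuffled[-seq_len(1L + n_und)]
      mu[mid] <- 0.16 * b                             # detected mid band blocks groups
      mu[1L] <- b
    },
    mixed = {
      det <- runif(Tn - 1L) < 0.5
      if (!any(det)) det[sample(Tn - 1L, 1L)] <- TRUE
      mu[others] <- ifelse(det, runif(Tn - 1L, 2, 8), runif(Tn - 1L, 0, 0.8))
      mu[1L] <- runif(1, 0, 0.8)                      # target stays undetected
    },
    abort(sprintf("Cannot plant category '%s'.", category))
  )
  list(means = mu, group = group)
}

#' Generate an expression matrix with planted specificity structure
#'
#' Draws, for each requested gene, a per-tissue mean profile satisfying its
#' category's defining inequalities with margin, then adds multiplicative
#' log-normal sample noise (`noise_sd` on the log2 scale; exactly the planted
#' means when 0). Deterministic given the spec's seed.
#'
#' @param spec A [matrix_spec()].
#' @return A list: `matrix` (an `fpkm_tbl` of samples named
#'   `<tissue>_<replicate>`), `truth` (tibble `gene_id`, `category`, `group`
#'   list-column), and `config` (the matching [spec_config()]).
#' @export
generate_matrix <- function(spec) {
  stopifnot(inherits(spec, "matrix_spec"))
  with_local_seed(spec$seed, {
    cats <- rep(names(spec$genes_per_category), times = spec$genes_per_category)
    n_genes <- length(cats)
    gene_id <- sprintf("gene_%04d", seq_len(n_genes))

    grp_i <- 0L
    planted <- purrr::map(seq_along(cats), function(i) {
      partners <- NULL
      if (cats[i] == "group_enriched" && !is.null(spec$group_plan)) {
        grp_i <<- grp_i + 1L
        partners <- spec$group_plan[[grp_i]]
      }
      plant_gene(cats[i], spec, partners = partners)
    })

    truth <- tibble(
      gene_id = gene_id,
      category = factor(cats, levels = spec_categories),
      group = purrr::map(planted, "group")
    )

    sample_id <- as.vector(vapply(
      spec$tissue_names,
      function(t) paste0(t, "_", seq_len(spec$samples_per_tissue)),
      character(spec$samples_per_tissue)))
    sample_tissue <- rep(spec$tissue_names, each = spec$samples_per_tissue)

    vals <- matrix(0, nrow = n_genes, ncol = length(sample_id))
    for (i in seq_len(n_genes)) {
      mu <- planted[[i]]$means[sample_tissue]
      noise <- if (spec$noise_sd > 0) {
        2^rnorm(length(mu), 0, spec$noise_sd)
      } else 1
      vals[i, ] <- mu * noise
    }

    wide <- dplyr::bind_cols(tibble(gene_id = gene_id),
                             as_tibble(as.data.frame(vals) |>
                                         setNames(sample_id)))
    tm <- tibble(sample_id = sample_id, tissue = sample_tissue)
    list(matrix = as_fpkm_tbl(wide, tissue_map = tm),
         truth = truth,
         config = spec_config(spec$target_tissue))
  })
}

#' Specification of a synthetic IHC staining cohort
#'
#' Describes a tissue-microarray-style cohort: cases per histology class and,
#' per class, the probability of each staining score 0--3. Defaults mirror a
#' benign-specific membrane marker: benign cores are mostly high-scoring
#' (positivity 0.814) while tumor and metastatic cores are mostly negative
#' (positivity 0.164), at the class sizes of a ~330-case validation series.
#'
#' @param n_per_class Named integer vector of case counts over `benign`,
#'   `GG2`..`GG5`, `metastasis`.
#' @param score_probs Named list mapping each histology class to a
#'   length-4 probability vector over scores 0--3 (each summing to 1).
#' @param cores_per_case Replicate cores per case, each scored independently
#'   from the class distribution (default 1).
#' @param compartment Compartment label stamped on every record (default
#'   `"membranous"`).
#' @param seed Integer seed.
#' @return A list of class `cohort_spec` with element `positivity`, the true
#'   per-class probability of a high (2--3) score.
#' @export
cohort_spec <- function(n_per_class = c(benign = 156L, GG2 = 3L, GG3 = 76L,
                                        GG4 = 62L, GG5 = 21L, metastasis = 15L),
                        score_probs = NULL,
                        cores_per_case = 1L,
                        compartment = "membranous",
                        seed = 1L) {
  if (is.null(score_probs)) {
    benign_p <- c(0.100, 0.086, 0.400, 0.414)   # P(high) = 0.814
    tumor_p <- c(0.500, 0.336, 0.100, 0.064)    # P(high) = 0.164
    score_probs <- list(benign = benign_p, GG2 = tumor_p, GG3 = tumor_p,
                        GG4 = tumor_p, GG5 = tumor_p, metastasis = tumor_p)
  }
  bad <- setdiff(names(n_per_class), histology_levels)
  if (length(bad)) abort(paste0("Unknown histology classes: ", paste(bad, collapse = ", ")))
  if (any(n_per_class < 0)) abort("Class counts must be >= 0.")
  for (cl in names(n_per_class)[n_per_class > 0]) {
    p <- score_probs[[cl]]
    if (is.null(p) || length(p) != 4L || abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
      abort(sprintf("`score_probs$%s` must be 4 non-negative probabilities summing to 1.", cl))
    }
  }
  structure(
    list(n_per_class = n_per_class, score_probs = score_probs,
         cores_per_case = as.integer(cores_per_case),
         compartment = compartment, seed = as.integer(seed),
         positivity = vapply(score_probs, function(p) sum(p[3:4]), numeric(1))),
    class = "cohort_spec"
  )
}

#' Generate an IHC cohort with known per-class positivity
#'
#' @param spec A [cohort_spec()].
#' @return A list: `records` (tibble `case_id`, `histology`, `compartment`,
#'   `core`, `score`) and `truth` (tibble `histology`, `positivity` with the
#'   spec's true high-score probabilities).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_local_seed(spec$seed, {
    recs <- purrr::imap(spec$n_per_class[spec$n_per_class > 0], function(n, cl) {
      n <- as.integer(n)
      tibble(
        case_id = sprintf("%s_%04d", cl, rep(seq_len(n), each = spec$cores_per_case)),
        histology = cl,
        compartment = spec$compartment,
        core = rep(seq_len(spec$cores_per_case), times = n),
        score = sample(0:3, n * spec$cores_per_case, replace = TRUE,
                       prob = spec$score_probs[[cl]])
      )
    })
    list(
      records = dplyr::bind_rows(recs),
      truth = tibble(histology = names(spec$positivity),
                     positivity = unname(spec$positivity))
    )
  })
}
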