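cfg <- spec_config("prostate")

test_that("tissue-specific score is the target/max-other ratio with sentinels", {
  expect_equal(tissue_specific_score(make_row(4700.79, 5.76, 0.1), "prostate"),
               4700.79 / 5.76)
  expect_equal(tissue_specific_score(c(prostate = 5, liver = 5), "prostate"), 1)
  expect_equal(tissue_specific_score(c(prostate = 2, liver = 0), "prostate"), Inf)
  expect_equal(tissue_specific_score(c(prostate = 0, liver = 0), "prostate"), 0)
  expect_error(tissue_specific_score(c(prostate = 1, liver = 1), "spleen"),
               "Unknown target")
})

test_that("classification matches the category definitions on canonical rows", {
  cases <- list(
    list(row = make_row(4700.79, 5.76, 0.1), cat = "highly_enriched"),
    list(row = make_row(3181.86, 370.44, 1), cat = "moderately_enriched"),
    list(row = make_row(0, 0, 0), cat = "not_detected"),
    list(row = make_row(100, 100, 100), cat = "expressed_all_high"),
    list(row = make_row(8, 8, 5), cat = "expressed_all_low"),
    list(row = make_row(0.5, 50, 0.2), cat = "mixed")
  )
  for (cs in cases) {
    expect_equal(as.character(classify_gene(cs$row, cfg)$category), cs$cat)
  }
})

test_that("a gene shared by prostate, esophagus and skin is group enriched", {
  row <- setNames(c(40, 54, 65, rep(0.5, 24)),
                  c("prostate", "esophagus", "skin", sprintf("x%02d", 1:24)))
  out <- classify_gene(row, cfg)
  expect_equal(as.character(out$category), "group_enriched")
  expect_true(all(c("prostate", "esophagus", "skin") %in% out$group[[1]]))
})

test_that("score boundaries separate the enrichment tiers under defaults", {
  expect_equal(as.character(classify_gene(make_row(50, 1, 0.1), cfg)$category),
               "highly_enriched")   # exactly 50-fold counts as highly
  expect_equal(as.character(classify_gene(make_row(49, 1, 0.1), cfg)$category),
               "moderately_enriched")
  expect_equal(as.character(classify_gene(make_row(5, 1, 0.1), cfg)$category),
               "moderately_enriched")  # exactly 5-fold counts as enriched
})

test_that("enhanced needs 5-fold over the all-tissue average with target included", {
  # competitor blocks the single-tissue tiers; mid band blocks groups;
  # undetected tail keeps the gene out of expressed-in-all
  row <- setNames(c(100, 50, rep(16, 19), rep(0.2, 6)),
                  c("prostate", "comp", sprintf("m%02d", 1:19), sprintf("u%d", 1:6)))
  expect_equal(as.character(classify_gene(row, cfg)$category), "enhanced")
  expect_gte(100, 5 * mean(row))
  # same shape but target below the 5x-average bound falls through to mixed
  row2 <- row; row2["prostate"] <- 40
  expect_equal(as.character(classify_gene(row2, cfg)$category), "mixed")
})

test_that("group search returns the smallest qualifying group, target included", {
  r1 <- make_row(10, 10, 0.5, n = 27)
  g1 <- find_enriched_group(r1, cfg)
  expect_equal(length(g1), 2)
  expect_true("prostate" %in% g1)

  expect_null(find_enriched_group(make_row(10, 10, 10), cfg))  # all equal

  # 8 tissues at 10 and the next at 9: no group of <= 7 clears 5x
  r3 <- setNames(c(rep(10, 8), 9, rep(0.1, 18)),
                 c("prostate", sprintf("t%02d", 1:26)))
  expect_null(find_enriched_group(r3, cfg))
})

test_that("group search agrees with exhaustive subset enumeration", {
  small_cfg <- spec_config("prostate")
  set.seed(20)
  n_hit <- 0
  for (i in 1:300) {
    n <- sample(4:10, 1)
    row <- setNames(round(rlnorm(n, log(5), 1.5), 3),
                    c("prostate", sprintf("t%02d", seq_len(n - 1))))
    got <- find_enriched_group(row, small_cfg)
    want <- exhaustive_group(row, small_cfg)
    # same qualifying-group-size decision as brute force
    expect_equal(length(got), length(want), info = paste(row, collapse = ","))
    if (!is.null(want)) {
      n_hit <- n_hit + 1
      # the returned group must itself satisfy the criterion
      excl <- row[setdiff(names(row), got)]
      lim <- if (length(excl)) max(excl) else 0
      expect_gte(mean(row[got]), small_cfg$enriched_fold * lim)
      expect_true(all(row[got] > small_cfg$detection_limit))
    }
  }
  expect_gt(n_hit, 10)  # the case mix actually exercises hits
})

test_that("categories are exclusive, exhaustive, and scale with the census", {
  sim <- generate_matrix(matrix_spec(noise_sd = 0.3, seed = 5))
  res <- classify_all(tissue_means(sim$matrix), sim$config)
  cen <- category_census(res)
  expect_equal(sum(cen$categories$n), nrow(res))
  expect_equal(sum(cen$categories$fraction), 1)
  expect_equal(sum(cen$major$n), nrow(res))
  expect_false(anyNA(res$category))
})

test_that("uniform scaling leaves the score invariant", {
  set.seed(9)
  for (i in 1:25) {
    row <- setNames(rlnorm(10, 1, 2), c("prostate", sprintf("t%d", 1:9)))
    k <- runif(1, 0.1, 50)
    expect_equal(tissue_specific_score(row * k, "prostate"),
                 tissue_specific_score(row, "prostate"))
  }
})

test_that("enrichment tiers imply the documented score bands", {
  sim <- generate_matrix(matrix_spec(noise_sd = 0.2, seed = 13))
  res <- classify_all(tissue_means(sim$matrix), sim$config)
  hi <- res$score[res$category == "highly_enriched"]
  mod <- res$score[res$category == "moderately_enriched"]
  expect_true(all(hi >= 50))
  expect_true(all(mod >= 5 & mod < 50))
})

test_that("empty input yields empty results and an all-zero census", {
  sim <- generate_matrix(matrix_spec(
    genes_per_category = c(mixed = 0L), seed = 1))
  res <- classify_all(tissue_means(sim$matrix), spec_config("prostate"))
  expect_equal(nrow(res), 0)
  cen <- category_census(res)
  expect_true(all(cen$categories$n == 0))
  expect_true(all(cen$major$fraction == 0))
})

test_that("config validation rejects inconsistent thresholds", {
  expect_error(spec_config("p", detection_limit = 0), "detection_limit")
  expect_error(spec_config("p", high_fold = 5, enriched_fold = 5), "high_fold")
  expect_error(spec_config("p", group_min = 1), "group_min")
})
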