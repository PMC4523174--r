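# the published benign-marker tables, reconstructed from their printed counts
t_membranous <- contingency_2x2(29, 148, 127, 29)
t_cytoplasmic <- contingency_2x2(22, 129, 132, 50)

test_that("scores 0-1 are low, 2-3 high, anything else an error", {
  expect_equal(as.character(dichotomize(c(0, 1, 2, 3))),
               c("low", "low", "high", "high"))
  expect_error(dichotomize(4), "0..3")
  expect_error(dichotomize(-1), "0..3")
})

test_that("chi-square uses the uncorrected closed form", {
  expect_equal(chi_square(t_membranous)$statistic, 140.81, tolerance = 1e-4)
  expect_equal(chi_square(t_cytoplasmic)$statistic, 111.52, tolerance = 1e-4)
  expect_equal(chi_square(contingency_2x2(10, 10, 10, 10))$statistic, 0)
  expect_true(is.na(chi_square(contingency_2x2(0, 0, 5, 5))$statistic))
})

test_that("chi-square and phi agree with stats::chisq.test and cor as oracles", {
  set.seed(55)
  for (i in 1:50) {
    t <- random_2x2()
    ref <- suppressWarnings(stats::chisq.test(unclass(t), correct = FALSE))
    expect_equal(chi_square(t)$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(chi_square(t)$p_value, ref$p.value, tolerance = 1e-10)
    # phi as the Pearson correlation of the expanded binary variables
    m <- unclass(t)
    status <- rep(c(0, 0, 1, 1), times = as.vector(t(m)))
    hist <- rep(c(0, 1, 0, 1), times = as.vector(t(m)))
    if (stats::sd(status) > 0 && stats::sd(hist) > 0) {
      expect_equal(phi_correlation(t)$pearson_r, stats::cor(status, hist),
                   tolerance = 1e-10)
      expect_equal(phi_correlation(t)$spearman_rho,
                   stats::cor(status, hist, method = "spearman"),
                   tolerance = 1e-10)
    }
  }
})

test_that("chi-square equals n * phi^2 and is invariant to row swap", {
  set.seed(66)
  for (i in 1:200) {
    t <- random_2x2()
    chi <- chi_square(t)$statistic
    phi <- phi_correlation(t)$pearson_r
    expect_equal(chi, sum(t) * phi^2, tolerance = 1e-9)
    m <- unclass(t)
    t_swap <- contingency_2x2(m[2, 1], m[2, 2], m[1, 1], m[1, 2])
    expect_equal(chi_square(t_swap)$statistic, chi, tolerance = 1e-9)
    expect_equal(phi_correlation(t_swap)$pearson_r, -phi, tolerance = 1e-9)
  }
})

test_that("phi matches the published correlations with the stated orientation", {
  expect_equal(phi_correlation(t_membranous)$pearson_r, -0.65, tolerance = 0.005)
  expect_equal(phi_correlation(t_cytoplasmic)$spearman_rho, -0.58, tolerance = 0.005)
  # a perfect benign marker (positive in every benign, negative in every
  # tumor case) is maximally anti-associated with tumor histology
  expect_equal(phi_correlation(contingency_2x2(0, 5, 5, 0))$pearson_r, -1)
  expect_equal(phi_correlation(contingency_2x2(5, 0, 0, 5))$pearson_r, 1)
})

test_that("g statistic is 2*sum(O log(O/E)) with the 0 log 0 convention", {
  expect_equal(g_test(contingency_2x2(10, 10, 10, 10))$statistic, 0)
  expect_equal(g_test(t_membranous)$statistic, 152.60, tolerance = 1e-3)
  g0 <- g_test(contingency_2x2(10, 0, 5, 5))$statistic
  expect_true(is.finite(g0) && g0 > 0)
})

test_that("sensitivity/specificity/AUC read off the benign-vs-tumor table", {
  ss <- sens_spec(t_membranous)
  expect_equal(ss$sensitivity, 127 / 156)
  expect_equal(ss$specificity, 148 / 177)
  expect_equal(binary_auc(t_membranous), 0.825, tolerance = 5e-4)
  expect_equal(sens_spec(t_cytoplasmic)$sensitivity, 132 / 154)

  all_pos <- contingency_2x2(0, 0, 50, 60)
  expect_equal(sens_spec(all_pos)$sensitivity, 1)
  expect_equal(sens_spec(all_pos)$specificity, 0)
  expect_equal(binary_auc(contingency_2x2(25, 30, 25, 30)), 0.5)
  expect_equal(binary_auc(contingency_2x2(0, 60, 50, 0)), 1)
})

test_that("ordinal AUC equals brute-force pair counting and the binary AUC
           of dichotomized scores equals the table version", {
  set.seed(88)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    score <- sample(0:3, n, replace = TRUE)
    benign <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(benign) || all(benign)) next
    expect_equal(ordinal_auc(score, benign), auc_oracle(score, benign))

    status <- dichotomize(score)
    t <- contingency_2x2(sum(status == "low" & benign),
                         sum(status == "low" & !benign),
                         sum(status == "high" & benign),
                         sum(status == "high" & !benign))
    if (!anyNA(sens_spec(t))) {
      expect_equal(binary_auc(t),
                   ordinal_auc(as.integer(status == "high"), benign))
    }
  }
  expect_equal(ordinal_auc(c(2, 2, 2, 2), c(TRUE, TRUE, FALSE, FALSE)), 0.5)
  expect_equal(ordinal_auc(c(3, 3, 0, 0), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_true(is.na(ordinal_auc(c(1, 2), c(TRUE, TRUE))))
})

test_that("marker-vs-marker cross-tabulation reproduces the printed block", {
  # expand the printed membranous-vs-cytoplasmic counts into per-case calls
  counts <- c(nn = 105, np = 73, pn = 126, pp = 29)
  mem <- rep(c(FALSE, FALSE, TRUE, TRUE), times = counts)
  cyt <- rep(c(FALSE, TRUE, FALSE, TRUE), times = counts)
  ct <- cross_tabulate(mem, cyt)
  expect_equal(as.vector(unclass(ct$table)), unname(counts[c(1, 3, 2, 4)]))
  expect_equal(ct$stats$chi_square, 19.39, tolerance = 5e-3)
  expect_equal(round(ct$stats$pearson_r, 2), -0.24)
  same <- cross_tabulate(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE))
  expect_equal(same$stats$pearson_r, 1)
})

test_that("cohort records tabulate into the right 2x2 with replicate collapse", {
  records <- tibble::tibble(
    case_id = c("b1", "b1", "b2", "t1", "t2"),
    histology = c("benign", "benign", "benign", "GG3", "metastasis"),
    compartment = "membranous",
    score = c(1, 3, 0, 2, 1))
  t <- ihc_contingency(records, compartment = "membranous", collapse = "max")
  # b1 collapses to max score 3 (positive)
  expect_equal(unname(unclass(t)[, ]),
               matrix(c(1, 1, 1, 1), 2, byrow = TRUE)[, ])
  bd <- attr(t, "breakdown")
  expect_equal(sum(bd[-1]), 4)
  t2 <- ihc_contingency(records, collapse = "none")
  expect_equal(sum(t2), 5)
  expect_error(
    ihc_contingency(tibble::tibble(case_id = "x", histology = "weird",
                                   score = 1)),
    "histology")
})

test_that("empty cohorts give all-zero tables and NA statistics", {
  t <- ihc_contingency(tibble::tibble(case_id = character(),
                                      histology = character(),
                                      score = integer()))
  expect_equal(sum(t), 0)
  s <- diagnostic_stats(t)
  expect_true(is.na(s$chi_square) && is.na(s$sensitivity) && is.na(s$auc))
})
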