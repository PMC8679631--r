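test_that("percent change and the inclusive 20% response rule", {
  expect_equal(percent_change(10, 10), 0)
  expect_equal(percent_change(10, 8), -20)
  expect_equal(percent_change(10, 4.45), -55.5)
  expect_error(percent_change(0, 5), "invalid-baseline")
  expect_equal(as.character(pet_response(c(-55.5, -12.2, -20, -19.999, NA))),
               c("responder", "nonresponder", "responder", "nonresponder",
                 "not_evaluable"))
  # monotone composition: a lower post-SUV never flips responder -> non
  post <- seq(11, 1, by = -0.5)
  lab <- pet_response(percent_change(rep(10, length(post)), post))
  resp <- lab == "responder"
  expect_true(all(diff(as.integer(resp)) >= 0))
})

test_that("mRECIST categories dichotomize by CR/PR vs SD/PD", {
  expect_equal(as.character(mrecist_binary(c("CR", "PR", "SD", "PD", "NE"))),
               c("responder", "responder", "nonresponder", "nonresponder",
                 "not_evaluable"))
  expect_error(mrecist_binary("XX"), "schema-error")
})

test_that("Cohen kappa reproduces the frozen large-sample oracle", {
  # oracle values computed independently for the 2x2 table (12, 2; 2, 8)
  k <- cohen_kappa(matrix(c(12, 2, 2, 8), 2, byrow = TRUE))
  expect_equal(k$kappa, 0.657142857142857, tolerance = 1e-12)
  expect_equal(k$se, 0.15618526147401882, tolerance = 1e-9)
  expect_equal(k$conf_low, 0.35102536973780896, tolerance = 1e-8)
  expect_equal(k$conf_high, 0.9632603445479053, tolerance = 1e-8)
  expect_equal(k$p_value, 0.0012849080214106317, tolerance = 1e-9)
  expect_equal(round(k$kappa, 2), 0.66)
})

test_that("kappa limits: perfect, chance-level, symmetric", {
  a <- rep(c("responder", "nonresponder"), c(6, 4))
  expect_equal(cohen_kappa(a, a)$kappa, 1)
  # independence with matched marginals: observed = expected table
  expect_equal(cohen_kappa(matrix(c(30, 20, 30, 20), 2, byrow = TRUE))$kappa, 0)
  # symmetry in the raters and invariance to a joint label swap
  set.seed(5)
  x <- sample(c("a", "b"), 40, replace = TRUE)
  y <- sample(c("a", "b"), 40, replace = TRUE)
  expect_equal(cohen_kappa(x, y)$kappa, cohen_kappa(y, x)$kappa)
  swap <- function(v) ifelse(v == "a", "b", "a")
  expect_equal(cohen_kappa(swap(x), swap(y))$kappa, cohen_kappa(x, y)$kappa)
  expect_error(cohen_kappa(rep("a", 5), rep("a", 5)), "undefined-kappa")
  expect_true(abs(cohen_kappa(x, y)$kappa) <= 1)
})

test_that("Wilcoxon tests use exact small-sample nulls where possible", {
  g <- c(1.2, 3.4, 2.2, 5.0, 4.1)
  same <- wilcoxon_rank(g, g)
  expect_gte(same$p_value, 0.99)
  # complete separation at n = 5 per arm: exact two-sided p = 2/choose(10,5)
  lo <- 1:5; hi <- 11:15
  sep <- wilcoxon_rank(lo, hi)
  expect_equal(sep$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_error(wilcoxon_rank(c(1, 1, 1), c(1, 1, 1)), "degenerate-test")
  expect_error(wilcoxon_rank(1:2, 1:5), "n >= 3")
  paired <- wilcoxon_rank(g + 2, g, paired = TRUE)
  expect_match(paired$method, "signed rank")
})

test_that("chi-square on 2x2 tables matches the direct formula", {
  expect_equal(chi_square_2x2(matrix(5, 2, 2))$statistic, 0)
  expect_equal(chi_square_2x2(matrix(c(10, 0, 0, 10), 2))$statistic, 20)
  counts <- matrix(c(12, 2, 2, 8), 2, byrow = TRUE)
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  expect_equal(chi_square_2x2(counts)$statistic,
               sum((counts - expected)^2 / expected))
  expect_error(chi_square_2x2(matrix(c(1, 2, 0, 0), 2, byrow = TRUE)),
               "degenerate-table")
})

test_that("lesion table loads 26 typed records over 16 patients", {
  t1 <- load_table1()
  expect_equal(nrow(t1), 26L)
  expect_equal(dplyr::n_distinct(t1$patient_id), 16L)
  p10 <- t1[t1$patient_id == 10, ]
  expect_equal(p10$suv60_mean_pre, 8.1)
  expect_equal(p10$suv60_max_pre, 20.4)
  expect_equal(p10$background_suv_mean, 7.7)
  expect_equal(tumor_to_liver_ratio(p10$suv60_max_pre, p10$background_suv_mean),
               20.4 / 7.7)
  # NE propagation
  p7 <- t1[t1$patient_id == 7, ]
  expect_true(is.na(p7$pct_change_mean))
  expect_false(p7$pet_evaluable)
  expect_equal(as.character(p7$pet_label), "not_evaluable")
  expect_equal(sum(!t1$mrecist_evaluable), 2L)
  # visual categories cover the 5-level vocabulary
  expect_true(all(t1$visual_uptake %in%
                    c("hyperintense", "isotense", "hypotense", "mixed", "rim")))
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("", empty)
  expect_error(load_table1(empty), "parse-error")
})

test_that("kinetic table loads 14 records with verbatim oddities flagged", {
  t2 <- load_table2()
  expect_equal(nrow(t2), 14L)
  expect_equal(t2$k1[t2$patient_id == 3], 0.31)
  # scientific-notation vb entries survive verbatim, out-of-range is flagged
  expect_equal(t2$vb_verbatim[t2$patient_id == 1], "5.0E-0")
  expect_equal(t2$vb[t2$patient_id == 1], 5.0)
  expect_true(t2$vb_flag[t2$patient_id == 1])
  expect_equal(sum(t2$vb_flag), 1L)
  expect_equal(t2$vb[t2$patient_id == 14], 2.9e-4)
  # recomputed Ki is within one printed unit of the published column
  expect_true(all(abs(t2$ki - t2$ki_printed) <= 0.01 + 1e-12))
  expect_gte(sum(round(t2$ki, 2) == t2$ki_printed), 11L)
})

test_that("cohort summary reproduces the published aggregates", {
  t1 <- load_table1()
  s <- cohort_summary(t1)
  expect_equal(s$n_lesions, 26L)
  expect_equal(s$mean_suv60_mean_pre, 6.476923, tolerance = 1e-6)
  expect_equal(round(s$mean_suv60_mean_pre, 1), 6.5)
  expect_equal(round(s$mean_suv60_max_pre, 1), 9.7)
  expect_equal(s$n_pet_evaluable, 25L)
  expect_equal(round(s$mean_pct_change_mean, 1), -29.5)
  # the published -18.5 was computed from unrounded per-lesion changes; the
  # printed per-lesion values average to -18.584, one last-digit unit away
  expect_equal(s$mean_pct_change_max, -18.584, tolerance = 1e-6)
  expect_lte(abs(s$mean_pct_change_max - (-18.5)), 0.1)
  expect_equal(s$pet_responders, 15L)
  expect_equal(s$n_mrecist_evaluable, 24L)
  expect_equal(s$mrecist_responders, 14L)
  # adding a fully not-evaluable record changes no aggregate except counts
  ne <- t1[t1$patient_id == 7, ]
  s2 <- cohort_summary(dplyr::bind_rows(t1, ne))
  expect_equal(s2$mean_pct_change_mean, s$mean_pct_change_mean)
  expect_equal(s2$pet_responders, s$pet_responders)
  expect_equal(s2$mrecist_responders, s$mrecist_responders)
  # single-record degenerate case
  one <- cohort_summary(t1[t1$patient_id == 10, ])
  expect_equal(one$mean_suv60_mean_pre, 8.1)
  expect_error(cohort_summary(t1[0, ]), "no-data")
})

test_that("PET-mRECIST concordance reproduces the published cross-tab", {
  t1 <- load_table1()
  k <- response_concordance(t1)
  expect_equal(k$n, 24)
  expect_equal(as.vector(k$counts), c(12, 2, 2, 8))
  expect_equal(round(k$kappa, 2), 0.66)
  expect_lt(k$p_value, 0.0015)
})
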