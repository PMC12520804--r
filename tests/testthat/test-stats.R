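test_that("uncorrected Pearson chi-square reproduces frozen 2x2 results", {
  r <- pearson_chi2(carrier_counts(2, 300, 0, 589))
  expect_equal(r$statistic, 3.90943764, tolerance = 1e-8)
  expect_equal(r$p, 0.04801566, tolerance = 1e-7)
  expect_equal(r$df, 1L)

  expect_equal(pearson_chi2(carrier_counts(1, 301, 0, 589))$p,
               0.16231529, tolerance = 1e-7)

  flat <- pearson_chi2(carrier_counts(1, 99, 1, 99))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)

  expect_error(pearson_chi2(carrier_counts(0, 302, 0, 589)),
               class = "mttrna_degenerate_table")
})

test_that("chi-square agrees with stats::chisq.test without correction", {
  set.seed(11)
  for (i in 1:50) {
    a <- sample(0:30, 1); b <- sample(1:500, 1)
    c_ <- sample(0:30, 1); d <- sample(1:500, 1)
    if (a + c_ == 0) a <- 1
    m <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE)
    ours <- pearson_chi2(carrier_counts(a, b, c_, d))
    ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("chi-square is invariant to swapping the case and control columns", {
  set.seed(13)
  for (i in 1:25) {
    a <- sample(0:20, 1); b <- sample(1:200, 1)
    c_ <- sample(1:20, 1); d <- sample(1:200, 1)
    r1 <- pearson_chi2(carrier_counts(a, b, c_, d))
    r2 <- pearson_chi2(carrier_counts(c_, d, a, b))
    expect_equal(r1$statistic, r2$statistic)
    expect_equal(r1$p, r2$p)
  }
})

test_that("tabulate_carriers builds the 2x2 table from carrier rows", {
  geno <- data.frame(
    subject_id = c("case_001", "case_002"),
    group = "case", variant = "m.7544C>T", stringsAsFactors = FALSE)
  ct <- tabulate_carriers(geno, "m.7544C>T", 302, 589)
  expect_equal(unclass(ct)[c("a", "b", "c", "d")],
               list(a = 2L, b = 300L, c = 0L, d = 589L))

  empty <- tabulate_carriers(geno[0, ], "m.7544C>T", 302, 589)
  expect_equal(empty$a, 0L); expect_equal(empty$b, 302L)

  allcase <- data.frame(subject_id = sprintf("s%d", 1:302), group = "case",
                        variant = "v", stringsAsFactors = FALSE)
  expect_equal(tabulate_carriers(allcase, "v", 302, 589)$b, 0L)

  dup <- rbind(geno, geno[1, ])
  expect_error(tabulate_carriers(dup, "m.7544C>T", 302, 589),
               "duplicate", class = "mttrna_bad_input")
  both <- data.frame(subject_id = "s1", group = c("case", "control"),
                     variant = c("v1", "v2"), stringsAsFactors = FALSE)
  expect_error(tabulate_carriers(both, "v1", 302, 589),
               "both groups", class = "mttrna_bad_input")
  badgrp <- data.frame(subject_id = "s1", group = "patient", variant = "v")
  expect_error(tabulate_carriers(badgrp, "v", 302, 589),
               class = "mttrna_bad_input")
})

test_that("carrier percentages are displayed to two decimals", {
  expect_equal(carrier_percent(2, 302), 0.66)
  expect_equal(carrier_percent(4, 302), 1.32)
  expect_equal(carrier_percent(0, 589), 0)
  expect_error(carrier_percent(1, 0), class = "mttrna_bad_input")
})

test_that("pooled Student's t matches the closed form", {
  same <- students_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  r <- students_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, -3.674235, tolerance = 1e-6)
  expect_equal(r$df, 4)
  expect_equal(r$p, 0.02131164, tolerance = 1e-6)

  scaled <- students_t(c(10, 20, 30), c(40, 50, 60))
  expect_equal(scaled$statistic, r$statistic)

  expect_error(students_t(1, c(1, 2)), class = "mttrna_bad_input")
})

test_that("HOMA-IR formula and inclusive threshold", {
  r <- homa_ir(22.5, 1)
  expect_equal(r$score, 1)
  expect_false(r$ir_flag)

  r2 <- homa_ir(16.74, 5.22)  # group means; formula check only
  expect_equal(r2$score, 16.74 * 5.22 / 22.5, tolerance = 1e-12)
  expect_equal(round(r2$score, 2), 3.88)
  expect_true(r2$ir_flag)

  exactly <- homa_ir(2.69 * 22.5, 1)
  expect_equal(exactly$score, 2.69)
  expect_true(exactly$ir_flag)

  expect_error(homa_ir(-1, 5), class = "mttrna_bad_input")
})

test_that("BMI is weight over squared height", {
  expect_equal(round(bmi(60, 1.6), 2), 23.44)
  expect_equal(bmi(72, 1), 72)
  expect_equal(bmi(80, 2), bmi(80, 1) / 4)
  expect_error(bmi(0, 1.6), class = "mttrna_bad_input")
})

test_that("2^-ddCt fold change identities", {
  expect_equal(ddct_fold_change(20, 20, 20, 20), 1)
  expect_equal(ddct_fold_change(21, 20, 20, 20), 0.5)   # ddCt = 1
  expect_equal(ddct_fold_change(18, 20, 20, 20), 4)     # ddCt = -2
  expect_error(ddct_fold_change(NA, 20, 20, 20), class = "mttrna_bad_input")
})
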