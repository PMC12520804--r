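test_that("exact-count planting reproduces fixed 2x2 counts", {
  vf <- data.frame(variant = "m.7544C>T", case_freq = 2 / 302,
                   control_freq = 0)
  sim <- simulate_cohort(cohort_spec(variant_freqs = vf, seed = 99),
                         mode = "exact")
  ct <- tabulate_carriers(sim$genotypes, "m.7544C>T", 302, 589)
  expect_equal(ct$a, 2L); expect_equal(ct$b, 300L)
  expect_equal(ct$c, 0L); expect_equal(ct$d, 589L)
})

test_that("zero frequencies give an empty genotype table", {
  vf <- data.frame(variant = c("v1", "v2"), case_freq = 0, control_freq = 0)
  sim <- simulate_cohort(cohort_spec(variant_freqs = vf, seed = 1))
  expect_equal(nrow(sim$genotypes), 0)
})

test_that("bernoulli carrier counts follow the binomial law", {
  vf <- data.frame(variant = "v", case_freq = 0.5, control_freq = 0)
  for (seed in 1:5) {
    sim <- simulate_cohort(cohort_spec(variant_freqs = vf, seed = seed))
    k <- sum(sim$genotypes$group == "case")
    # within 4 sd of 302 * 0.5 (sd ~ 8.7)
    expect_gt(k, 151 - 4 * sqrt(302 * 0.25))
    expect_lt(k, 151 + 4 * sqrt(302 * 0.25))
  }
})

test_that("identical seeds give identical cohorts, different seeds differ", {
  vf <- data.frame(variant = "v", case_freq = 0.1, control_freq = 0.1)
  s1 <- simulate_cohort(cohort_spec(variant_freqs = vf, seed = 7))
  s2 <- simulate_cohort(cohort_spec(variant_freqs = vf, seed = 7))
  expect_identical(s1, s2)
  s3 <- simulate_cohort(cohort_spec(variant_freqs = vf, seed = 8))
  expect_false(identical(s1$clinical, s3$clinical))
})

test_that("clinical covariates are positive with group-faithful structure", {
  sim <- simulate_cohort(cohort_spec(seed = 5))
  cl <- sim$clinical
  expect_equal(nrow(cl), 302 + 589)
  nums <- cl[, !(names(cl) %in% c("subject_id", "group", "ir_flag"))]
  expect_true(all(nums > 0))
  # derived quantities come from the formulas, not sampling
  expect_equal(cl$homa_ir, cl$fins * cl$fpg / 22.5)
  expect_equal(cl$lh_fsh_ratio, cl$lh / cl$fsh)
  expect_equal(cl$ir_flag, cl$homa_ir >= 2.69)
  # case insulin runs far above control insulin by design
  expect_gt(mean(cl$fins[cl$group == "case"]),
            mean(cl$fins[cl$group == "control"]))
  # sample means sit near the generating means (loose, 5 SE)
  se <- 5.30 / sqrt(302)
  expect_lt(abs(mean(cl$fins[cl$group == "case"]) - 16.74), 5 * se)
})

test_that("simulated alignments hit their target conservation exactly", {
  aln <- simulate_alignment(15, match_fractions = rep(1, 10), seed = 2)
  for (j in c(1, 5, 10))
    expect_equal(conservation_index(aln, j)$ci_percent, 100)

  aln2 <- simulate_alignment(15, match_fractions = 12 / 15, length = 6,
                             seed = 3)
  for (j in 1:6)
    expect_equal(conservation_index(aln2, j)$ci_percent, 80)

  expect_identical(simulate_alignment(10, 0.5, length = 4, seed = 4),
                   simulate_alignment(10, 0.5, length = 4, seed = 4))
  expect_error(simulate_alignment(15, 0.5, length = 3, seed = 1),
               class = "mttrna_bad_input")
})

test_that("mutate_sequence validates and round-trips planted variants", {
  cat22 <- default_catalog()
  asp <- cat22$genes[cat22$genes$name == "tRNA-Asp", ]
  ref_seg <- asp$sequence   # H strand: tRNA sense equals rCRS sense
  planted <- data.frame(pos = 7544L, ref = "C", alt = "T")
  mut <- mutate_sequence(ref_seg, planted, segment_start = asp$start)
  called <- call_variants(ref_seg, mut, segment_start = asp$start)
  expect_equal(called$label, "m.7544C>T")

  expect_identical(mutate_sequence(ref_seg, planted[0, ], asp$start), ref_seg)
  expect_error(mutate_sequence(ref_seg, rbind(planted, planted), asp$start),
               class = "mttrna_bad_input")
  expect_error(mutate_sequence(ref_seg,
                               data.frame(pos = 7544L, ref = "A", alt = "G"),
                               asp$start),
               class = "mttrna_ref_mismatch")
  expect_error(mutate_sequence(ref_seg,
                               data.frame(pos = 9999L, ref = "C", alt = "T"),
                               asp$start),
               class = "mttrna_bad_input")
})

test_that("cohort_spec validates frequencies and sizes", {
  expect_error(cohort_spec(variant_freqs = data.frame(
    variant = "v", case_freq = 1.2, control_freq = 0)),
    class = "mttrna_bad_input")
  expect_error(cohort_spec(n_cases = 0), class = "mttrna_bad_input")
})
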