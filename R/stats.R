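#' Carrier counts for a 2x2 case-control table
#'
#' @param a case carriers
#' @param b case non-carriers
#' @param c control carriers
#' @param d control non-carriers
#' @return a list of class `carrier_counts`.
#' @export
carrier_counts <- function(a, b, c, d) {
  v <- c(a = a, b = b, c = c, d = d)
  if (any(v < 0) || any(v != round(v)))
    stop_mttrna("carrier counts must be non-negative integers",
                "mttrna_bad_input")
  structure(as.list(setNames(as.integer(v), names(v))),
            class = "carrier_counts")
}

#' Tabulate carriers of a variant in a case-control genotype table
#'
#' The genotype table lists carriers only: one row per (subject, variant)
#' with the subject's group.  Subjects must carry a consistent group label
#' and appear at most once per variant.
#'
#' @param genotypes data frame with columns `subject_id`, `group`
#'   (`"case"`/`"control"`) and `variant` (label).
#' @param variant_label the variant to tabulate.
#' @param n_cases,n_controls cohort sizes.
#' @return a `carrier_counts`.
#' @export
tabulate_carriers <- function(genotypes, variant_label, n_cases, n_controls) {
  if (nrow(genotypes)) {
    bad <- !genotypes$group %in% c("case", "control")
    if (any(bad))
      stop_mttrna(sprintf("unknown group label '%s' (row %d)",
                          genotypes$group[which(bad)[1]], which(bad)[1]),
                  "mttrna_bad_input")
    grp <- tapply(genotypes$group, genotypes$subject_id,
                  function(x) length(unique(x)))
    if (any(grp > 1))
      stop_mttrna(sprintf("subject '%s' appears in both groups",
                          names(grp)[grp > 1][1]), "mttrna_bad_input")
  }
  rows <- genotypes[genotypes$variant == variant_label, , drop = FALSE]
  if (anyDuplicated(rows$subject_id))
    stop_mttrna(sprintf("duplicate genotype row for subject '%s'",
                        rows$subject_id[duplicated(rows$subject_id)][1]),
                "mttrna_bad_input")
  a <- sum(rows$group == "case")
  c_ <- sum(rows$group == "control")
  if (a > n_cases || c_ > n_controls)
    stop_mttrna("more carriers than subjects in a group", "mttrna_bad_input")
  carrier_counts(a, n_cases - a, c_, n_controls - c_)
}

#' Uncorrected Pearson chi-square test on a 2x2 table
#'
#' Computes the Pearson statistic without continuity correction,
#' chi2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)), with a two-sided p-value
#' from the 1-df chi-square distribution.  No correction is applied because
#' the screen's reference results are uncorrected Pearson values; Yates or
#' Fisher would give materially different p at these counts (available via
#' [stats::chisq.test()] / [stats::fisher.test()] if a small-count
#' alternative is wanted, and flagged as a deviation in reports).
#'
#' @param counts a `carrier_counts` (or list with a, b, c, d).
#' @return list: `statistic`, `df` (= 1), `p`.
#' @export
pearson_chi2 <- function(counts) {
  a <- as.numeric(counts$a); b <- as.numeric(counts$b)
  c_ <- as.numeric(counts$c); d <- as.numeric(counts$d)
  n <- a + b + c_ + d
  if (n < 2)
    stop_mttrna("need at least two subjects", "mttrna_degenerate_table")
  if (a + c_ == 0 || b + d == 0 || a + b == 0 || c_ + d == 0)
    stop_mttrna("degenerate 2x2 table: a zero margin", "mttrna_degenerate_table")
  stat <- n * (a * d - b * c_)^2 /
    ((a + b) * (c_ + d) * (a + c_) * (b + d))
  list(statistic = stat, df = 1L, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Fisher's exact test on a 2x2 table
#'
#' Optional small-count alternative to [pearson_chi2()].  Not the screen's
#' default; reports using it are labelled accordingly.
#'
#' @param counts a `carrier_counts`.
#' @return list: `statistic` (odds ratio estimate), `df` (NA), `p`.
#' @export
fisher_exact <- function(counts) {
  m <- matrix(c(counts$a, counts$b, counts$c, counts$d), nrow = 2,
              byrow = TRUE)
  ft <- stats::fisher.test(m)
  list(statistic = unname(ft$estimate), df = NA_integer_, p = ft$p.value)
}

#' Carrier percentage for display
#'
#' @param k carriers, `n` group size.
#' @param n group size (> 0).
#' @return 100 k / n rounded to 2 decimals.
#' @export
carrier_percent <- function(k, n) {
  if (any(n <= 0)) stop_mttrna("group size must be positive", "mttrna_bad_input")
  if (any(k < 0 | k > n)) stop_mttrna("carriers outside 0..n", "mttrna_bad_input")
  round(100 * k / n, 2)
}

#' Two-sample Student's t test
#'
#' Pooled-variance two-sample t by default (df = n_a + n_b - 2); Welch's
#' unequal-variance form is available as an option.
#'
#' @param values_a,values_b numeric vectors (each of length >= 2).
#' @param var_equal pool the variances (default TRUE).
#' @return list: `statistic`, `df`, `p`.
#' @export
students_t <- function(values_a, values_b, var_equal = TRUE) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop_mttrna("each group needs at least two observations",
                "mttrna_bad_input")
  tt <- stats::t.test(values_a, values_b, var.equal = var_equal)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' HOMA-IR insulin-resistance index
#'
#' HOMA-IR = fasting insulin (mU/L) x fasting glucose (mmol/L) / 22.5.
#' Scores at or above the threshold (default 2.69) flag insulin
#' resistance; the comparison is inclusive.
#'
#' @param fins fasting insulin, mU/L (> 0).
#' @param fpg fasting plasma glucose, mmol/L (> 0).
#' @param threshold IR cut-off (default 2.69).
#' @return list: `score`, `ir_flag` (vectorised).
#' @export
homa_ir <- function(fins, fpg, threshold = 2.69) {
  if (any(fins <= 0) || any(fpg <= 0))
    stop_mttrna("insulin and glucose must be positive", "mttrna_bad_input")
  score <- fins * fpg / 22.5
  list(score = score, ir_flag = score >= threshold)
}

#' Body mass index
#'
#' @param weight_kg body weight in kg (> 0).
#' @param height_m height in metres (> 0).
#' @return weight / height^2, kg/m^2.
#' @export
bmi <- function(weight_kg, height_m) {
  if (any(weight_kg <= 0) || any(height_m <= 0))
    stop_mttrna("weight and height must be positive", "mttrna_bad_input")
  weight_kg / height_m^2
}

#' Relative expression fold change by the 2^-ddCt method
#'
#' fold = 2^-((Ct_target,test - Ct_ref,test) - (Ct_target,ctrl - Ct_ref,ctrl)).
#'
#' @param ct_target_test,ct_ref_test,ct_target_ctrl,ct_ref_ctrl finite qPCR
#'   cycle thresholds for the target/reference gene in test/control samples.
#' @return fold change (1 when all deltas cancel).
#' @export
ddct_fold_change <- function(ct_target_test, ct_ref_test,
                             ct_target_ctrl, ct_ref_ctrl) {
  cts <- c(ct_target_test, ct_ref_test, ct_target_ctrl, ct_ref_ctrl)
  if (any(!is.finite(cts)))
    stop_mttrna("Ct values must be finite", "mttrna_bad_input")
  ddct <- (ct_target_test - ct_ref_test) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
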