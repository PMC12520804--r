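#' Screen one annotated variant against the pathogenicity criteria
#'
#' The screening criteria are: (1) carried by fewer than 1 percent of
#' controls (strict), (2) conservation index at least 75 percent
#' (inclusive; a missing CI fails closed), (3) a structural alteration,
#' operationalised as a Watson-Crick pair change, and (4) impaired
#' mitochondrial function.  Criterion 4 is wet-lab evidence and is carried
#' as a tri-state input flag (`supported`/`refuted`/`untested`) that is
#' recorded but does not block candidacy, mirroring a workflow in which
#' functional assays follow the genetic screen.
#'
#' A variant is `candidate_pathogenic` when criteria 1-3 all hold (and it
#' has at least one case carrier), `benign_polymorphism` when it is absent
#' from cases but present in controls, and `uncertain` otherwise.  The two
#' named classes are mutually exclusive.
#'
#' @param annotation one-row data frame from [annotate_variant()].
#' @param counts a `carrier_counts`.
#' @param ci_percent conservation index (0..100) or NA when unknown.
#' @param previously_reported logical flag from curated lookup data.
#' @param functional_evidence `"supported"`, `"refuted"` or `"untested"`.
#' @param control_freq_threshold criterion-1 threshold as a fraction
#'   (default 0.01).
#' @param ci_threshold criterion-2 threshold in percent (default 75).
#' @param test association test: `"pearson"` (uncorrected chi-square, the
#'   screen's reference test) or `"fisher"` (exact; labelled alternative
#'   for small counts).
#' @return one-row data frame with the annotation, counts, display
#'   percentages, chi-square p (NA for tables with no carriers),
#'   criterion flags and classification.
#' @export
screen_variant <- function(annotation, counts, ci_percent = NA_real_,
                           previously_reported = NA,
                           functional_evidence = "untested",
                           control_freq_threshold = 0.01,
                           ci_threshold = 75,
                           test = c("pearson", "fisher")) {
  test <- match.arg(test)
  if (!functional_evidence %in% c("supported", "refuted", "untested"))
    stop_mttrna("functional_evidence must be supported/refuted/untested",
                "mttrna_bad_input")
  a <- counts$a; c_ <- counts$c
  n_cases <- counts$a + counts$b
  n_controls <- counts$c + counts$d
  control_freq <- c_ / n_controls
  p <- if (a + c_ == 0) NA_real_
       else if (test == "fisher") fisher_exact(counts)$p
       else pearson_chi2(counts)$p
  crit1 <- control_freq < control_freq_threshold
  crit2 <- !is.na(ci_percent) && ci_percent >= ci_threshold
  crit3 <- annotation$pair_effect != "none"
  classification <- if (a == 0 && c_ > 0) "benign_polymorphism"
    else if (a > 0 && crit1 && crit2 && crit3) "candidate_pathogenic"
    else "uncertain"
  cbind(annotation,
        data.frame(ci_percent = as.numeric(ci_percent),
                   case_carriers = a, control_carriers = c_,
                   n_cases = n_cases, n_controls = n_controls,
                   case_percent = carrier_percent(a, n_cases),
                   control_percent = carrier_percent(c_, n_controls),
                   control_freq_percent = 100 * control_freq,
                   p = p,
                   low_control_freq = crit1, conserved = crit2,
                   wc_altering = crit3,
                   functional_evidence = functional_evidence,
                   previously_reported = previously_reported,
                   classification = classification,
                   stringsAsFactors = FALSE))
}

#' Case-control association for every variant in a genotype table
#'
#' Tabulates carriers and applies the uncorrected Pearson chi-square to
#' each variant.  Variants with no carriers in either group get NA
#' statistics (the 2x2 test is degenerate there).
#'
#' @param genotypes carrier-format genotype table (see
#'   [tabulate_carriers()]).
#' @param n_cases,n_controls cohort sizes.
#' @param bonferroni also emit Bonferroni-adjusted p-values (off by
#'   default: the screen's reference analysis applies no multiplicity
#'   adjustment across its tests, so adjusted values are an explicitly
#'   labelled extra).
#' @return data frame: variant, case/control carriers, statistic, p
#'   (and p_bonferroni when requested), sorted by p.
#' @export
associate_cohort <- function(genotypes, n_cases, n_controls,
                             bonferroni = FALSE) {
  vars <- unique(genotypes$variant)
  rows <- lapply(vars, function(v) {
    ct <- tabulate_carriers(genotypes, v, n_cases, n_controls)
    if (ct$a + ct$c == 0) {
      stat <- NA_real_; p <- NA_real_
    } else {
      r <- pearson_chi2(ct)
      stat <- r$statistic; p <- r$p
    }
    data.frame(variant = v, case_carriers = ct$a, control_carriers = ct$c,
               statistic = stat, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(variant = character(0), case_carriers = integer(0),
                      control_carriers = integer(0), statistic = numeric(0),
                      p = numeric(0))
  if (bonferroni) {
    out$p_bonferroni <- stats::p.adjust(out$p, method = "bonferroni")
    warning("Bonferroni column added; the default screen is unadjusted")
  }
  out[order(out$p), , drop = FALSE]
}

#' Summarise a screen table
#'
#' @param records data frame of screen records (rows from
#'   [screen_variant()] or a loaded reference table).
#' @return list: `n_variants`, `n_genes`, `n_control_only` (absent from
#'   cases, present in controls), `n_ci_ge_75` (CI at or above 75,
#'   inclusive), `n_wc_altering`, `n_significant` (p < 0.05).
#' @export
summarize_screen <- function(records) {
  if (!nrow(records))
    return(list(n_variants = 0L, n_genes = 0L, n_control_only = 0L,
                n_ci_ge_75 = 0L, n_wc_altering = 0L, n_significant = 0L))
  list(
    n_variants = nrow(records),
    n_genes = length(unique(records$gene)),
    n_control_only = sum(records$case_carriers == 0 &
                           records$control_carriers > 0),
    n_ci_ge_75 = sum(!is.na(records$ci_percent) & records$ci_percent >= 75),
    n_wc_altering = sum(records$pair_effect != "none"),
    n_significant = sum(!is.na(records$p) & records$p < 0.05)
  )
}

#' Run the screen on a reference variant table
#'
#' Takes a loaded reference screen table (counts and CI as data, e.g. the
#' bundled 43-variant fixture), recomputes the structural annotation from
#' the catalog and the association p from the counts, and classifies every
#' variant.
#'
#' @param reference data frame from [read_table2_reference()].
#' @param catalog a `trna_catalog`.
#' @param n_cases,n_controls cohort sizes behind the reference counts.
#' @param test association test (see [screen_variant()]).
#' @return a screen table (data frame of [screen_variant()] rows) with a
#'   `provenance` attribute.
#' @export
screen_reference_table <- function(reference, catalog = default_catalog(),
                                   n_cases = 302, n_controls = 589,
                                   test = "pearson") {
  rows <- lapply(seq_len(nrow(reference)), function(i) {
    r <- reference[i, ]
    ann <- annotate_variant(parse_variant(r$mutation), catalog)
    ct <- carrier_counts(r$case_carriers, n_cases - r$case_carriers,
                         r$control_carriers, n_controls - r$control_carriers)
    screen_variant(ann, ct, ci_percent = r$ci,
                   previously_reported = identical(r$reported, "yes"),
                   test = test)
  })
  out <- do.call(rbind, rows)
  attr(out, "provenance") <- list(
    inputs = "reference screen table",
    catalog = "bundled synthetic rCRS mt-tRNA catalog",
    n_cases = n_cases, n_controls = n_controls,
    test = if (identical(test, "fisher"))
      "Fisher exact (deviation from the reference analysis)"
    else "uncorrected Pearson chi-square")
  class(out) <- c("screen_table", class(out))
  out
}

#' Compare a recomputed screen to the printed reference rows
#'
#' For each reference row, reports whether the catalog-derived gene,
#' position numbering, element, Watson-Crick effect and pair rendering,
#' and the recomputed chi-square p (rounded to the printed precision)
#' agree with the printed values.  Disagreements are reported, not
#' silently dropped: a small set of printed rows is internally
#' inconsistent (see the vignette) and downstream checks assert that the
#' mismatches are exactly the documented ones.
#'
#' @param reference reference table from [read_table2_reference()].
#' @param computed screen table from [screen_reference_table()] on the
#'   same rows.
#' @return data frame, one row per variant, with `*_match` logicals.
#' @export
compare_screen_to_reference <- function(reference,
                                        computed = screen_reference_table(reference)) {
  stopifnot(nrow(reference) == nrow(computed))
  printed_effect <- ifelse(reference$effect == "", "none", reference$effect)
  p_digits <- nchar(sub("^[^.]*\\.?", "", reference$p))
  p_rounded <- round(computed$p, p_digits)
  data.frame(
    mutation = reference$mutation,
    gene_match = computed$gene == reference$gene,
    numbering_match = computed$trna_position == reference$numbering,
    element_match = computed$element == reference$location,
    effect_match = computed$pair_effect == printed_effect,
    pair_match = computed$pair_string == reference$pair,
    p_printed = as.numeric(reference$p),
    p_recomputed = computed$p,
    p_match = !is.na(p_rounded) & p_rounded == as.numeric(reference$p),
    stringsAsFactors = FALSE
  )
}
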