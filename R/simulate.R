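# Evaluate expr with a locally-set RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Default clinical simulation parameters
#'
#' Per-covariate Gaussian parameters (mean, SD) for the case and control
#' groups of the emulated two-group cohort: age (years), BMI (kg/m2), FSH
#' and LH (IU/L), PRL (ug/L), DHEA-S (umol/L), total testosterone (ng/mL),
#' fasting insulin (mU/L), fasting glucose (mmol/L), CK (U/L) and lactate
#' (mmol/L).  The LH/FSH ratio and HOMA-IR are not sampled: they are
#' computed from the simulated hormone values so the formulas are
#' exercised.
#'
#' @return data frame: covariate, case_mean, case_sd, control_mean,
#'   control_sd.
#' @export
table1_clinical_defaults <- function() {
  read.table(text = "
covariate case_mean case_sd control_mean control_sd
age 28.54 4.79 26.14 4.27
bmi 23.89 3.21 19.12 2.34
fsh 5.27 1.38 6.79 3.11
lh 11.44 7.17 5.91 3.71
prl 20.64 7.85 13.19 11.15
dheas 9.22 3.01 6.55 2.61
tt 0.75 0.30 0.51 0.17
fins 16.74 5.30 6.21 1.55
fpg 5.22 1.51 5.19 0.49
ck 55.2 3.55 22.5 0.69
lactate 3.55 0.88 1.01 0.06
", header = TRUE, stringsAsFactors = FALSE)
}

#' Specify a synthetic case-control cohort
#'
#' @param n_cases,n_controls group sizes (defaults 302 / 589, the emulated
#'   study cohort).
#' @param variant_freqs data frame with columns `variant`, `case_freq`,
#'   `control_freq` (carrier frequencies in 0..1).
#' @param clinical_params per-covariate Gaussian parameters (default
#'   [table1_clinical_defaults()]).
#' @param seed integer RNG seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 302, n_controls = 589,
                        variant_freqs = NULL,
                        clinical_params = table1_clinical_defaults(),
                        seed = 1) {
  if (is.null(variant_freqs))
    variant_freqs <- data.frame(variant = character(0), case_freq = numeric(0),
                                control_freq = numeric(0))
  stopifnot(all(c("variant", "case_freq", "control_freq") %in%
                  names(variant_freqs)))
  freqs <- c(variant_freqs$case_freq, variant_freqs$control_freq)
  if (any(freqs < 0 | freqs > 1))
    stop_mttrna("carrier frequencies must lie in [0, 1]", "mttrna_bad_input")
  if (any(clinical_params$case_sd <= 0) || any(clinical_params$control_sd <= 0))
    stop_mttrna("clinical SDs must be positive", "mttrna_bad_input")
  if (n_cases < 1 || n_controls < 1)
    stop_mttrna("group sizes must be positive", "mttrna_bad_input")
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 variant_freqs = variant_freqs,
                 clinical_params = clinical_params,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

rnorm_pos <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  while (any(x <= 0)) {
    bad <- x <= 0
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  x
}

#' Simulate a case-control cohort
#'
#' Carrier status is drawn per subject and variant.  In `"bernoulli"` mode
#' each subject carries a variant with its group-specific frequency; in
#' `"exact"` mode exactly `round(freq * n)` carriers are planted per group,
#' which makes golden reproduction of fixed 2x2 counts deterministic.
#' Clinical covariates are independent Gaussians truncated at zero
#' (physiological values are positive); the LH/FSH ratio and HOMA-IR are
#' computed from the simulated values.  The same spec (including seed)
#' always yields identical output.
#'
#' @param spec a `cohort_spec`.
#' @param mode `"bernoulli"` or `"exact"`.
#' @return list: `genotypes` (subject_id, group, variant; carriers only)
#'   and `clinical` (one row per subject).
#' @export
simulate_cohort <- function(spec, mode = c("bernoulli", "exact")) {
  mode <- match.arg(mode)
  with_seed(spec$seed, {
    ids <- c(sprintf("case_%03d", seq_len(spec$n_cases)),
             sprintf("ctrl_%03d", seq_len(spec$n_controls)))
    grp <- rep(c("case", "control"), c(spec$n_cases, spec$n_controls))

    geno <- list()
    vf <- spec$variant_freqs
    for (i in seq_len(nrow(vf))) {
      for (g in c("case", "control")) {
        n <- if (g == "case") spec$n_cases else spec$n_controls
        f <- if (g == "case") vf$case_freq[i] else vf$control_freq[i]
        members <- ids[grp == g]
        carriers <- if (mode == "exact") {
          k <- round(f * n)
          if (k > 0) sample(members, k) else character(0)
        } else {
          members[rbinom(n, 1, f) == 1]
        }
        if (length(carriers))
          geno[[length(geno) + 1L]] <-
            data.frame(subject_id = carriers, group = g,
                       variant = vf$variant[i], stringsAsFactors = FALSE)
      }
    }
    genotypes <- if (length(geno)) do.call(rbind, geno)
      else data.frame(subject_id = character(0), group = character(0),
                      variant = character(0))

    cp <- spec$clinical_params
    clinical <- data.frame(subject_id = ids, group = grp,
                           stringsAsFactors = FALSE)
    for (i in seq_len(nrow(cp))) {
      v <- numeric(length(ids))
      v[grp == "case"] <- rnorm_pos(spec$n_cases, cp$case_mean[i],
                                    cp$case_sd[i])
      v[grp == "control"] <- rnorm_pos(spec$n_controls, cp$control_mean[i],
                                       cp$control_sd[i])
      clinical[[cp$covariate[i]]] <- v
    }
    if (all(c("lh", "fsh") %in% names(clinical)))
      clinical$lh_fsh_ratio <- clinical$lh / clinical$fsh
    if (all(c("fins", "fpg") %in% names(clinical))) {
      h <- homa_ir(clinical$fins, clinical$fpg)
      clinical$homa_ir <- h$score
      clinical$ir_flag <- h$ir_flag
    }
    list(genotypes = genotypes, clinical = clinical)
  })
}

#' Simulate a multi-species alignment with controlled conservation
#'
#' Builds a human row plus `n_species` aligned rows such that at column j
#' exactly `round(match_fractions[j] * n_species)` species carry the human
#' base; the remaining species carry a random different base.  Which
#' species match is shuffled per column under the seed.  Fractions must be
#' exactly representable as k / n_species.
#'
#' @param n_species number of non-human rows.
#' @param length number of columns (default: length of `match_fractions`).
#' @param match_fractions per-column target match fraction(s) in 0..1,
#'   recycled to `length`.
#' @param seed integer RNG seed.
#' @return a `species_alignment` with rows `Homo_sapiens`, `species_01`,
#'   ...
#' @export
simulate_alignment <- function(n_species, match_fractions,
                               length = base::length(match_fractions),
                               seed = 1) {
  f <- rep_len(match_fractions, length)
  k <- f * n_species
  if (any(abs(k - round(k)) > 1e-9))
    stop_mttrna("match fractions must be multiples of 1/n_species",
                "mttrna_bad_input")
  k <- as.integer(round(k))
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    human <- sample(bases, length, replace = TRUE)
    rows <- matrix("", nrow = n_species, ncol = length)
    for (j in seq_len(length)) {
      match_rows <- sample(n_species, k[j])
      rows[, j] <- vapply(seq_len(n_species), function(s) {
        if (s %in% match_rows) human[j]
        else sample(setdiff(bases, human[j]), 1)
      }, character(1))
    }
    seqs <- c(Homo_sapiens = paste(human, collapse = ""),
              setNames(apply(rows, 1, paste, collapse = ""),
                       sprintf("species_%02d", seq_len(n_species))))
    species_alignment(seqs, human = "Homo_sapiens")
  })
}

#' Plant substitutions into a reference segment
#'
#' Inverse of [call_variants()]: substitutes the alternate alleles into the
#' reference segment.  Every variant must lie inside the segment, match the
#' reference allele, and occupy a distinct position.
#'
#' @param ref_segment nucleotide string.
#' @param variants data frame with columns pos, ref, alt (e.g. from
#'   [call_variants()]), or a list of [variant()]s.
#' @param segment_start rCRS coordinate of the first base.
#' @return the mutated sequence.
#' @export
mutate_sequence <- function(ref_segment, variants, segment_start = 1L) {
  if (!is.data.frame(variants))
    variants <- do.call(rbind, lapply(variants, function(v)
      data.frame(pos = v$genomic_pos, ref = v$ref, alt = v$alt,
                 stringsAsFactors = FALSE)))
  s <- strsplit(ref_segment, "")[[1]]
  if (!nrow(variants)) return(ref_segment)
  if (anyDuplicated(variants$pos))
    stop_mttrna("duplicate variant positions in one segment",
                "mttrna_bad_input")
  idx <- variants$pos - segment_start + 1L
  if (any(idx < 1 | idx > length(s)))
    stop_mttrna("variant position outside the segment", "mttrna_bad_input")
  if (any(s[idx] != variants$ref))
    stop_mttrna(sprintf("reference allele mismatch at position %d",
                        variants$pos[which(s[idx] != variants$ref)[1]]),
                "mttrna_ref_mismatch")
  s[idx] <- variants$alt
  paste(s, collapse = "")
}
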