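---
title: "Screening mitochondrial tRNA variants in a case-control cohort"
author: "mttrnascreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening mitochondrial tRNA variants in a case-control cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mttrnascreen)
```

## The problem

The human mitochondrial genome encodes 22 transfer RNAs, and substitutions
in them are disproportionately represented among pathogenic mtDNA
mutations.  A standard way to triage candidate mt-tRNA variants from a
case-control sequencing study combines four kinds of evidence per
substitution:

1. **Population evidence** — the variant is rare in controls (here:
   carried by fewer than 1% of the control group) and its case/control
   carrier distribution is tested with a 2×2 chi-square;
2. **Evolutionary evidence** — the position is conserved across species,
   summarised by a *conservation index* (CI): the percentage of non-human
   species whose aligned base matches the human base. CI ≥ 75%
   (inclusive) flags functional importance;
3. **Structural evidence** — the substitution changes the tRNA cloverleaf,
   operationalised here as the creation or disruption of a Watson–Crick
   base pair in an authored secondary-structure model;
4. **Functional evidence** — wet-lab assays (e.g. in cybrid cells). This
   package records that evidence as a tri-state input flag; it never
   computes it.

A variant passing criteria 1–3 (with at least one case carrier) is
classified `candidate_pathogenic`; a variant absent from cases but present
in controls is a `benign_polymorphism`; everything else is `uncertain`.
The two named classes are mutually exclusive by construction.

The package ships the published 43-variant screen of a cohort of 302
women with insulin-resistant polycystic ovary syndrome and 589 controls
as a reference fixture, and reproduces its results end to end; the index
finding is the novel m.7544C>T substitution at position 30 of the
aspartate tRNA's anticodon stem, which disrupts the 30C–40G pair and is
the screen's only variant with p < 0.05.

## The structural model

Coordinates are 1-based inclusive rCRS (NC_012920.1) throughout.  Each of
the 22 genes carries an explicit position table — *numbering is data, not
algorithm* — because mammalian mt-tRNAs have truncated D- and T-arms and
a canonical Sprinzl-style numbering cannot be derived reliably from
sequence alone.  The bundled catalog is built from a canonical 73-position
cloverleaf template with per-gene dropped and inserted positions chosen so
that every per-variant position number printed in the reference screen is
satisfied (42 of 43 anchors; see *Known printed inconsistencies*).

Pairing in the catalog follows the conventions evident in the reference
table:

* acceptor stem (1–7 with 72–66) and anticodon stem (27–31 with 43–39)
  positions carry partners;
* D-arm and TψC-arm positions carry **no** partners: every printed
  D-arm/TψC row has an empty Watson–Crick cell, including rows at
  canonically stem positions (13, 22, 61), so the reference analysis
  clearly did not score those stems;
* the tertiary 26–44 interaction is included in the two genes where the
  printed table annotates arrows at those positions (the leucine
  tRNA-Leu(UUR) and serine tRNA-Ser(UCN)).

For the eight L-strand-encoded genes the catalog stores the tRNA-sense
sequence; rCRS-reported alleles are complemented before structural
interpretation and echoed unchanged in reports.  Wobble (G·U)
juxtapositions are *not* counted as Watson–Crick: the reference arrows
force this rule (a C-G→U·G change is marked disrupted, a U·G→C-G change
created).

**Synthetic sequences.** The true rCRS nucleotide sequence is not bundled.
The catalog's sequences are a synthetic reconstruction constrained to
carry (a) the documented reference allele at each of the 43 screened
positions, (b) the partner bases forced by the eight printed
created/disrupted arrows, and (c) Watson–Crick complements at all other
authored stem pairs; unconstrained positions are random.  Every
coordinate, numbering, element, pairing and allele the pipeline is tested
on is real, documented data; the filler bases are not.  The fixture is
named accordingly (`mt_trna_catalog_synthetic.tsv`) and applications that
need the true rCRS should load their own catalog via
`read_trna_catalog()`.

```{r annotate}
ann <- annotate_variant("m.7544C>T")
ann[, c("gene", "trna_position", "element", "partner",
        "pair_effect", "pair_string")]
```

## Conservation

`conservation_index()` computes CI at an alignment column as
100 · n_match / n_compared, where the denominator counts non-human
species with an unambiguous base at the column — gapped species drop
out, so the effective depth varies by position.  This convention was
chosen because the reference CI values (12.5, 86.6, 96.1, …) are not all
consistent with a fixed 15-species denominator.  The species set is
caller-supplied data; the package deliberately claims no default
alignment, and the reference CI values are consumed as fixture data.  The
functional-importance threshold is **inclusive** (≥ 75): the reference
count of six high-CI variants requires the 75.0 row to qualify.

## Association statistics

The 2×2 test is the **uncorrected** Pearson chi-square,
χ² = n(ad−bc)²/((a+b)(c+d)(a+c)(b+d)) with df = 1.  At the index
variant's counts — 2/302 cases vs 0/589 controls — only the uncorrected
form reproduces the reference p = 0.048 (Yates' correction gives ≈ 0.22
and Fisher's exact ≈ 0.12).  Fisher's exact remains available
(`fisher_exact()`, or `test = "fisher"` in the screen) and is labelled a
deviation in report provenance.  No multiplicity adjustment is applied by
default, matching the reference analysis across its 43 tests; a
Bonferroni column can be requested and is emitted with a warning.
Degenerate tables (no carrier in either group) raise a typed error at the
test level and propagate as missing p-values through the screen.

Clinical helpers implement the study formulas: pooled-variance Student's
t (Welch optional), BMI = weight/height², HOMA-IR = FINS × FPG / 22.5
with an inclusive flag at 2.69, and the 2^−ΔΔCt fold change.

```{r chi2}
pearson_chi2(carrier_counts(2, 300, 0, 589))
```

## The synthetic cohort generator

`simulate_cohort()` emulates the study's two-group design: 302 cases and
589 controls by default, per-variant Bernoulli carrier status at
group-specific frequencies, and independent Gaussian clinical covariates
truncated at zero using the study's published group means and SDs
(`table1_clinical_defaults()`).  Two planting modes exist because they
serve different tests: `"exact"` plants `round(freq × n)` carriers
deterministically (golden reproduction of fixed 2×2 counts), `"bernoulli"`
draws per subject (power and type-I studies).  The LH/FSH ratio and
HOMA-IR are computed from the simulated hormone values rather than
sampled, so the formulas are exercised.

What the generator does *not* emulate — and therefore what passing tests
cannot show about real data: linkage between variants, haplogroup
background, realistic mutational spectra, covariate correlation
structure, and heteroplasmy (variants are presence/absence per subject,
as in the reference analysis, which treats the index mutation as
homoplasmic).

Desk-scale study sizes used by the test suite and acceptance script: 200
replicates for the power study (planted carrier frequencies 2% in cases
vs 0.1% in controls, against nine null background variants at 0.3%, a
typical carrier frequency in the reference table) and 200 replicates for
the null calibration at 0.5% carrier frequency in both groups.  The
planted variant is recovered as the top hit by p in ≥ 90% of replicates;
the null p < 0.05 rate falls in [0.02, 0.10] — a deliberately wide band,
since the uncorrected Pearson test is mildly anticonservative at sparse
counts.

`simulate_alignment()` constructs alignments whose per-column CI is exact
by construction (`round(f × n_species)` matching rows), which is what the
conservation property tests need; fractions must be representable as
k/n_species, and an error is raised otherwise rather than silently
rounding.

## Known printed inconsistencies in the reference table

The golden comparison (`compare_screen_to_reference()`) reports per-row
agreement rather than forcing it; exactly four rows diverge, all
attributable to inconsistencies within the printed reference itself:

* **5603G>A (numbering)** — printed position 61 cannot coexist with the
  5601C>T row's printed 59: on the L-strand alanine tRNA the 5'→3'
  offsets of 5603/5601 are 53/55, and no monotone numbering maps the
  earlier offset to the later number.  The catalog satisfies the 5601
  anchor; 5603 maps to position 57 in the same element (TψC loop).
* **5603G>A, 10031T>C, 12234A>G (p-values)** — recomputing from the
  printed counts gives 0.71, 0.22 and 0.50 where the table prints 0.70,
  0.98 and 0.49.  The 10031 value appears to be a copy error (its counts
  give 0.22; the printed 0.98 matches the (1 vs 2) pattern of the 5811
  row); the other two are off by one in the final printed digit, as the
  identically-counted row 10454T>C (printed 0.71) confirms.
* **4395T>C, 5802G>A, 5821G>A (pair rendering)** — printed pair strings
  for these L-strand rows show uncomplemented rCRS alleles
  (e.g. "G-C" for a tRNA-sense C-G pair), while H-strand rows render the
  5'-side base first.  The package renders tRNA-sense pairs 5'-side
  first, uniformly.  The created/disrupted **arrows** — the substantive
  annotation — reproduce 8/8.

The test suite asserts that the divergence sets are exactly these, so any
regression that silently "fixes" or widens them fails.

## Numerical and degenerate-input choices

* Chi-square margins are computed in double precision (cohort-scale
  margin products overflow 32-bit integers).
* Ties in the power study's top-hit criterion count as recovery only if
  the planted variant's p equals the minimum; NA p-values (no carriers)
  never count.
* `call_variants()` is a positional mismatch scan over gap-free,
  equal-length segments — it is not an aligner; non-ACGT symbols are
  skipped and counted, not called.
* Overlapping gene spans (e.g. the isoleucine/glutamine overlap at
  rCRS 4329–4331) resolve to the first gene in catalog order;
  per-gene lookups via `trna_position_info()` disambiguate explicitly.
* Report rounding is fixed (CI one decimal, carrier percentages two
  decimals, p to three decimals below 0.05 and two otherwise), making
  identical tables byte-identical on disk.

## Limitations

Insertions/deletions and heteroplasmy fractions are out of the data
model; the structural criterion is the Watson–Crick pair change only (no
folding energetics); the bundled catalog's filler sequence is synthetic
as described above; and the reference CI column cannot be recomputed
without the original 15-species alignment, so CI values are consumed as
data and CI computation is verified by construction on synthetic
alignments instead.
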