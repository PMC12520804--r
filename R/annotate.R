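WC_PARTNER <- c(A = "T", T = "A", G = "C", C = "G")

complement_base <- function(x) unname(WC_PARTNER[x])

check_base <- function(x, what = "base") {
  if (!all(x %in% c("A", "C", "G", "T")))
    stop_mttrna(sprintf("invalid %s symbol '%s'", what,
                        setdiff(x, c("A", "C", "G", "T"))[1]),
                "mttrna_bad_input")
  invisible(x)
}

#' Construct a variant
#'
#' @param genomic_pos 1-based rCRS coordinate.
#' @param ref,alt reference and alternate alleles in rCRS terms (A/C/G/T).
#' @return a list with `genomic_pos`, `ref`, `alt` and the canonical label
#'   `m.<pos><ref>><alt>`.
#' @export
variant <- function(genomic_pos, ref, alt) {
  check_base(c(ref, alt), "allele")
  if (ref == alt)
    stop_mttrna("ref and alt alleles must differ", "mttrna_bad_input")
  if (genomic_pos < 1 || genomic_pos > RCRS_LENGTH)
    stop_mttrna("variant position outside the rCRS (1..16569)",
                "mttrna_bad_input")
  list(genomic_pos = as.integer(genomic_pos), ref = ref, alt = alt,
       label = sprintf("m.%d%s>%s", as.integer(genomic_pos), ref, alt))
}

#' Parse a variant label
#'
#' Accepts `"m.7544C>T"` or `"7544C>T"`.
#'
#' @param label character label.
#' @return a variant (see [variant()]).
#' @export
parse_variant <- function(label) {
  m <- regmatches(label,
                  regexec("^(?:m\\.)?([0-9]+)([ACGT])>([ACGT])$", label))[[1]]
  if (!length(m))
    stop_mttrna(sprintf("cannot parse variant label '%s'", label),
                "mttrna_parse_error")
  variant(as.integer(m[2]), m[3], m[4])
}

#' Watson-Crick effect of a substitution at a paired position
#'
#' A substitution *disrupts* a pair when the reference base forms a
#' Watson-Crick pair (A:T, T:A, G:C, C:G) with the partner and the
#' alternate base does not; it *creates* a pair in the reverse situation.
#' G:T wobble juxtapositions are not Watson-Crick under this convention.
#'
#' @param ref,alt bases at the mutated position (tRNA sense).
#' @param partner_base base at the pairing partner, or NA for unpaired
#'   positions.
#' @return `"none"`, `"created"` or `"disrupted"`.
#' @export
basepair_effect <- function(ref, alt, partner_base) {
  check_base(c(ref, alt))
  if (is.null(partner_base) || is.na(partner_base)) return("none")
  check_base(partner_base, "partner base")
  ref_wc <- WC_PARTNER[[ref]] == partner_base
  alt_wc <- WC_PARTNER[[alt]] == partner_base
  if (ref_wc && !alt_wc) "disrupted"
  else if (!ref_wc && alt_wc) "created"
  else "none"
}

#' Structurally annotate a substitution
#'
#' Finds the containing tRNA gene, the cloverleaf position number and
#' element, and the Watson-Crick consequence at paired positions.  Alleles
#' are supplied in rCRS terms; for L-strand genes they are complemented
#' before structural interpretation, and the returned record echoes the
#' original rCRS alleles.
#'
#' The rendered `pair_string` shows the intact pair (the reference pair for
#' a disruption, the mutant pair for a creation) with the 5'-side base
#' first, in tRNA sense.
#'
#' @param catalog a `trna_catalog` (default: bundled catalog).
#' @param v a variant from [variant()]/[parse_variant()], or a label.
#' @return one-row data frame: label, genomic_pos, ref, alt, gene, strand,
#'   trna_position, element, partner, pair_effect, pair_string.
#' @export
annotate_variant <- function(v, catalog = default_catalog()) {
  if (is.character(v)) v <- parse_variant(v)
  hit <- locate_gene(catalog, v$genomic_pos)
  gene <- hit$gene
  info <- trna_position_info(catalog, gene$name, v$genomic_pos)
  if (gene$strand == "H") {
    ref_t <- v$ref; alt_t <- v$alt
  } else {
    ref_t <- complement_base(v$ref); alt_t <- complement_base(v$alt)
  }
  if (info$ref_base != ref_t)
    stop_mttrna(sprintf(
      "%s: reference allele %s does not match the catalog base %s at %s position %d (wrong coordinate or strand?)",
      v$label, v$ref, info$ref_base, gene$name, info$trna_position),
      "mttrna_ref_mismatch")
  effect <- basepair_effect(ref_t, alt_t, info$partner_base)
  pair_string <- ""
  if (effect != "none") {
    here <- if (effect == "created") alt_t else ref_t
    # 5'-ness from sequence index, not label (insertions carry high labels)
    pp <- catalog$positions[catalog$positions$gene == gene$name, ]
    idx_here <- hit$offset
    idx_partner <- pp$seq_index[pp$trna_position == info$partner]
    pair_string <- if (idx_here < idx_partner)
      paste0(here, "-", info$partner_base)
    else
      paste0(info$partner_base, "-", here)
  }
  data.frame(label = v$label, genomic_pos = v$genomic_pos, ref = v$ref,
             alt = v$alt, gene = gene$name, strand = gene$strand,
             trna_position = info$trna_position, element = info$element,
             partner = ifelse(is.na(info$partner), NA_integer_, info$partner),
             pair_effect = effect, pair_string = pair_string,
             stringsAsFactors = FALSE)
}

#' Annotate a set of variants
#'
#' @param labels character vector of variant labels, or a data frame with
#'   columns pos/ref/alt.
#' @param catalog a `trna_catalog`.
#' @return data frame with one row per variant (see [annotate_variant()]).
#' @export
annotate_variants <- function(labels, catalog = default_catalog()) {
  vs <- if (is.data.frame(labels))
    apply(labels, 1, function(r) variant(as.integer(r[["pos"]]),
                                         r[["ref"]], r[["alt"]]))
  else lapply(labels, parse_variant)
  do.call(rbind, lapply(vs, annotate_variant, catalog = catalog))
}

#' Call substitutions from an aligned sample segment
#'
#' Positional mismatch scan between two equal-length, gap-free segments
#' (base calling and alignment are assumed upstream).  Positions where
#' either sequence carries a non-ACGT symbol are treated as missing and
#' skipped; the number skipped is attached as attribute `n_skipped`.
#'
#' @param ref_segment,sample_segment equal-length nucleotide strings.
#' @param segment_start rCRS coordinate of the first base.
#' @return data frame (pos, ref, alt, label) sorted by position, with
#'   attribute `n_skipped`.
#' @export
call_variants <- function(ref_segment, sample_segment, segment_start = 1L) {
  if (nchar(ref_segment) != nchar(sample_segment))
    stop_mttrna("reference and sample segments differ in length",
                "mttrna_bad_input")
  r <- strsplit(toupper(ref_segment), "")[[1]]
  s <- strsplit(toupper(sample_segment), "")[[1]]
  valid <- r %in% c("A", "C", "G", "T") & s %in% c("A", "C", "G", "T")
  n_skipped <- sum(!valid)
  idx <- which(valid & r != s)
  out <- data.frame(pos = segment_start + idx - 1L, ref = r[idx],
                    alt = s[idx], stringsAsFactors = FALSE)
  out$label <- sprintf("m.%d%s>%s", out$pos, out$ref, out$alt)
  attr(out, "n_skipped") <- n_skipped
  out
}
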