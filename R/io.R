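ARROW_UP <- "↑"
ARROW_DOWN <- "↓"

#' Read a variant table
#'
#' TSV with header columns `pos`, `ref`, `alt` and optionally `subject_id`
#' and `group`.  Malformed rows raise errors naming the offending file
#' line.
#'
#' @param path TSV file.
#' @return validated data frame with a `label` column added.
#' @export
read_variant_table <- function(path) {
  # colClasses: a lone "T" allele column must not become logical TRUE
  x <- read.delim(path, stringsAsFactors = FALSE, quote = "",
                  colClasses = "character")
  needed <- c("pos", "ref", "alt")
  if (!all(needed %in% names(x)))
    stop_mttrna(sprintf("%s: variant table needs columns %s", path,
                        paste(needed, collapse = ", ")),
                "mttrna_parse_error")
  line <- seq_len(nrow(x)) + 1L  # header is line 1
  bad <- function(cond, msg) {
    if (any(cond))
      stop_mttrna(sprintf("%s line %d: %s", path, line[which(cond)[1]], msg),
                  "mttrna_parse_error")
  }
  pos_num <- suppressWarnings(as.numeric(x$pos))
  bad(is.na(pos_num) | pos_num != round(pos_num), "non-integer position")
  x$pos <- as.integer(pos_num)
  bad(x$pos < 1 | x$pos > RCRS_LENGTH, "position outside the rCRS")
  bad(!x$ref %in% c("A", "C", "G", "T"), "malformed ref allele")
  bad(!x$alt %in% c("A", "C", "G", "T"), "malformed alt allele")
  bad(x$ref == x$alt, "ref and alt alleles are identical")
  if ("group" %in% names(x))
    bad(!x$group %in% c("case", "control"), "unknown group label")
  x$label <- sprintf("m.%d%s>%s", x$pos, x$ref, x$alt)
  x
}

#' Read a carrier-format genotype table
#'
#' TSV with columns `subject_id`, `group` (case/control) and `variant`
#' (label), one row per carried variant.
#'
#' @param path TSV file.
#' @return validated data frame.
#' @export
read_genotype_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, quote = "")
  needed <- c("subject_id", "group", "variant")
  if (!all(needed %in% names(x)))
    stop_mttrna(sprintf("%s: genotype table needs columns %s", path,
                        paste(needed, collapse = ", ")), "mttrna_parse_error")
  bad <- which(!x$group %in% c("case", "control"))
  if (length(bad))
    stop_mttrna(sprintf("%s line %d: unknown group label '%s'", path,
                        bad[1] + 1L, x$group[bad[1]]), "mttrna_parse_error")
  x
}

#' Load the bundled 43-variant reference screen table
#'
#' The reference fixture packages the published screening table: per
#' variant its gene, conservation index, structural location and
#' numbering, Watson-Crick pair annotation, case/control carrier counts
#' out of 302 / 589, printed p-value (kept as text to preserve its printed
#' precision) and previously-reported flag.
#'
#' @param path fixture path (default: bundled copy).
#' @return data frame with parsed `pos`, `ref`, `alt` columns added.
#' @export
read_table2_reference <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table2_screen.tsv",
                        package = "mttrnascreen", mustWork = TRUE)
  x <- read.delim(path, stringsAsFactors = FALSE, quote = "",
                  colClasses = c(p = "character"), encoding = "UTF-8")
  if (anyDuplicated(x$mutation))
    stop_mttrna("reference table rows must be unique by variant",
                "mttrna_parse_error")
  x$effect[is.na(x$effect)] <- ""
  x$pair[is.na(x$pair)] <- ""
  m <- regmatches(x$mutation, regexec("^([0-9]+)([ACGT])>([ACGT])$",
                                      x$mutation))
  stopifnot(all(lengths(m) == 4L))
  x$pos <- as.integer(vapply(m, `[`, "", 2))
  x$ref <- vapply(m, `[`, "", 3)
  x$alt <- vapply(m, `[`, "", 4)
  x
}

format_p <- function(p) {
  ifelse(is.na(p), "NA",
         ifelse(p < 0.05, sprintf("%.3f", p), sprintf("%.2f", p)))
}

#' Write a screen report
#'
#' Fixed column order and rounding (CI one decimal, carrier percentages
#' two decimals, p at display precision), so identical tables produce
#' byte-identical files.  The Watson-Crick column renders the intact pair
#' with a direction arrow (created \\u2191, disrupted \\u2193) or, with
#' `ascii = TRUE`, the words "created"/"disrupted".  Summary counts and
#' provenance are written as leading comment lines.
#'
#' @param records screen table ([screen_variant()] rows).
#' @param path output TSV path.
#' @param ascii use ASCII effect words instead of arrows.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(records, path, ascii = FALSE) {
  s <- summarize_screen(records)
  wc <- ifelse(records$pair_effect == "none", "",
               if (ascii)
                 paste(records$pair_string, records$pair_effect)
               else
                 paste0(records$pair_string,
                        ifelse(records$pair_effect == "created",
                               ARROW_UP, ARROW_DOWN)))
  out <- data.frame(
    gene = records$gene,
    mutation = sub("^m\\.", "", records$label),
    ci = sprintf("%.1f", records$ci_percent),
    location = records$element,
    numbering = records$trna_position,
    wc = wc,
    case_n = sprintf("%d (%.2f)", records$case_carriers,
                     records$case_percent),
    control_n = sprintf("%d (%.2f)", records$control_carriers,
                        records$control_percent),
    p = format_p(records$p),
    classification = records$classification,
    reported = ifelse(is.na(records$previously_reported), "NA",
                      ifelse(records$previously_reported, "yes", "no")),
    stringsAsFactors = FALSE)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf(
    "# mt-tRNA variant screen: %d variants, %d genes, %d control-only, %d CI>=75, %d WC-altering, %d with p<0.05",
    s$n_variants, s$n_genes, s$n_control_only, s$n_ci_ge_75,
    s$n_wc_altering, s$n_significant), con)
  prov <- attr(records, "provenance")
  if (!is.null(prov))
    writeLines(sprintf("# provenance: %s",
                       paste(names(prov), unlist(lapply(prov, paste,
                                                        collapse = " ")),
                             sep = "=", collapse = "; ")), con)
  writeLines(paste(names(out), collapse = "\t"), con)
  writeLines(do.call(paste, c(out, sep = "\t")), con)
  invisible(path)
}

#' Read back a screen report
#'
#' @param path report written by [write_screen_report()].
#' @return data frame of the report columns (display precision).
#' @export
read_screen_report <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^#", lines)]
  con <- textConnection(lines)
  on.exit(close(con))
  read.delim(con, stringsAsFactors = FALSE, quote = "",
             colClasses = "character")
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Minimal VCF import of mitochondrial SNVs
#'
#' Reads a plain-text VCF and returns the single-nucleotide substitutions
#' on the mitochondrial contig (`chrM`, `MT`, `chrMT` or `NC_012920.1`)
#' as a variant table; multi-allelic records are expanded and non-SNV
#' alleles skipped.  POS is taken as 1-based rCRS.
#'
#' @param path VCF file (uncompressed).
#' @return data frame: pos, ref, alt, label.
#' @export
read_vcf_variants <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t")[[1]]
    if (length(f) < 5) next
    if (!f[1] %in% c("chrM", "MT", "chrMT", "NC_012920.1")) next
    ref <- toupper(f[4])
    if (!ref %in% c("A", "C", "G", "T")) next
    for (alt in strsplit(toupper(f[5]), ",")[[1]]) {
      if (!alt %in% c("A", "C", "G", "T") || alt == ref) next
      out[[length(out) + 1L]] <- data.frame(
        pos = as.integer(f[2]), ref = ref, alt = alt,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out)
    else data.frame(pos = integer(0), ref = character(0),
                    alt = character(0))
  res$label <- if (nrow(res)) sprintf("m.%d%s>%s", res$pos, res$ref, res$alt)
    else character(0)
  res
}
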