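#' @importFrom utils read.delim write.table head
#' @importFrom stats setNames rnorm rbinom pchisq
NULL

pkg_env <- new.env(parent = emptyenv())

MT_TRNA_GENE_NAMES <- c(
  "tRNA-Phe", "tRNA-Val", "tRNA-Leu(UUR)", "tRNA-Ile", "tRNA-Gln",
  "tRNA-Met", "tRNA-Trp", "tRNA-Ala", "tRNA-Asn", "tRNA-Cys", "tRNA-Tyr",
  "tRNA-Ser(UCN)", "tRNA-Asp", "tRNA-Lys", "tRNA-Gly", "tRNA-Arg",
  "tRNA-His", "tRNA-Ser(AGY)", "tRNA-Leu(CUN)", "tRNA-Glu", "tRNA-Thr",
  "tRNA-Pro"
)

STRUCTURAL_ELEMENTS <- c("Acceptor arm", "D-arm", "Anticodon stem",
                         "Anticodon loop", "Variable region",
                         "TψC loop")

RCRS_LENGTH <- 16569L

stop_mttrna <- function(msg, class) {
  stop(structure(class = c(class, "mttrna_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Read an mt-tRNA cloverleaf catalog
#'
#' Parses the structured-text catalog format: a `[genes]` section (one row
#' per tRNA gene with its 1-based inclusive rCRS span, encoding strand and
#' tRNA-sense sequence) followed by a `[positions]` section mapping each
#' sequence index to its tRNA position number (mitotRNAdb-style integer
#' label), cloverleaf element and pairing partner.  For L-strand genes the
#' stored sequence is the reverse complement of the rCRS slice, i.e. the
#' sequence of the tRNA itself.
#'
#' All structural invariants are checked on load: sequence length equals
#' the genomic span, every sequence index appears exactly once, elements
#' come from the fixed cloverleaf vocabulary, and the partner relation is
#' symmetric.  Violations raise an error naming the offending gene.
#'
#' @param path path to a catalog file.
#' @param require_complete require all 22 human mt-tRNA genes (default TRUE).
#' @return an object of class `trna_catalog`: a list with data frames
#'   `genes` (name, start, end, strand, sequence) and `positions`
#'   (gene, trna_position, seq_index, element, partner).
#' @export
read_trna_catalog <- function(path, require_complete = TRUE) {
  if (!file.exists(path))
    stop_mttrna(sprintf("catalog file not found: %s", path), "mttrna_io_error")
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  gi <- which(lines == "[genes]")
  pi <- which(lines == "[positions]")
  if (length(gi) != 1L || length(pi) != 1L || pi < gi)
    stop_mttrna("catalog must contain a [genes] then a [positions] section",
                "mttrna_parse_error")
  parse_block <- function(block) {
    con <- textConnection(block)
    on.exit(close(con))
    read.delim(con, stringsAsFactors = FALSE, quote = "")
  }
  genes <- parse_block(lines[(gi + 1):(pi - 1)])
  positions <- parse_block(lines[(pi + 1):length(lines)])
  positions$partner <- suppressWarnings(as.integer(positions$partner))
  catalog <- structure(list(genes = genes, positions = positions),
                       class = "trna_catalog")
  validate_catalog(catalog, require_complete = require_complete)
  catalog
}

#' Write an mt-tRNA catalog
#'
#' Inverse of [read_trna_catalog()]; a write-then-read round trip restores
#' identical structures.
#'
#' @param catalog a `trna_catalog`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trna_catalog <- function(catalog, path) {
  g <- catalog$genes
  p <- catalog$positions
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("[genes]", con)
  writeLines(paste(c("name", "start", "end", "strand", "sequence"),
                   collapse = "\t"), con)
  writeLines(paste(g$name, g$start, g$end, g$strand, g$sequence, sep = "\t"),
             con)
  writeLines("[positions]", con)
  writeLines(paste(c("gene", "trna_position", "seq_index", "element",
                     "partner"), collapse = "\t"), con)
  writeLines(paste(p$gene, p$trna_position, p$seq_index, p$element,
                   ifelse(is.na(p$partner), "NA", p$partner), sep = "\t"),
             con)
  invisible(path)
}

#' Validate a catalog's structural invariants
#'
#' @param catalog a `trna_catalog`.
#' @param require_complete require all 22 mt-tRNA genes.
#' @return the catalog, invisibly, if valid; otherwise an error naming the
#'   first offending gene.
#' @export
validate_catalog <- function(catalog, require_complete = TRUE) {
  g <- catalog$genes
  p <- catalog$positions
  needed <- c("name", "start", "end", "strand", "sequence")
  if (!all(needed %in% names(g)))
    stop_mttrna("catalog [genes] section lacks required columns",
                "mttrna_parse_error")
  if (anyDuplicated(g$name))
    stop_mttrna(sprintf("duplicated gene '%s'", g$name[duplicated(g$name)][1]),
                "mttrna_invalid_catalog")
  if (require_complete) {
    missing <- setdiff(MT_TRNA_GENE_NAMES, g$name)
    if (length(missing))
      stop_mttrna(sprintf("catalog is missing mt-tRNA gene(s): %s",
                          paste(missing, collapse = ", ")),
                  "mttrna_invalid_catalog")
  }
  for (i in seq_len(nrow(g))) {
    nm <- g$name[i]
    if (g$start[i] > g$end[i])
      stop_mttrna(sprintf("%s: start > end", nm), "mttrna_invalid_catalog")
    if (!g$strand[i] %in% c("H", "L"))
      stop_mttrna(sprintf("%s: strand must be H or L", nm),
                  "mttrna_invalid_catalog")
    L <- g$end[i] - g$start[i] + 1L
    if (nchar(g$sequence[i]) != L)
      stop_mttrna(sprintf("%s: sequence length %d != genomic span %d",
                          nm, nchar(g$sequence[i]), L),
                  "mttrna_invalid_catalog")
    if (grepl("[^ACGT]", g$sequence[i]))
      stop_mttrna(sprintf("%s: sequence contains non-ACGT characters", nm),
                  "mttrna_invalid_catalog")
    pp <- p[p$gene == nm, ]
    if (!setequal(pp$seq_index, seq_len(L)) || anyDuplicated(pp$seq_index))
      stop_mttrna(sprintf("%s: position table does not cover each sequence index exactly once", nm),
                  "mttrna_invalid_catalog")
    if (anyDuplicated(pp$trna_position))
      stop_mttrna(sprintf("%s: duplicated tRNA position label", nm),
                  "mttrna_invalid_catalog")
    if (!all(pp$element %in% STRUCTURAL_ELEMENTS))
      stop_mttrna(sprintf("%s: unknown structural element '%s'", nm,
                          setdiff(pp$element, STRUCTURAL_ELEMENTS)[1]),
                  "mttrna_invalid_catalog")
    # partner symmetry: partner(partner(q)) == q
    paired <- pp[!is.na(pp$partner), ]
    if (nrow(paired)) {
      back <- pp$partner[match(paired$partner, pp$trna_position)]
      bad <- is.na(back) | back != paired$trna_position
      if (any(bad))
        stop_mttrna(sprintf("%s: asymmetric partner table at position %d",
                            nm, paired$trna_position[which(bad)[1]]),
                    "mttrna_invalid_catalog")
    }
  }
  orphan <- setdiff(p$gene, g$name)
  if (length(orphan))
    stop_mttrna(sprintf("positions reference unknown gene '%s'", orphan[1]),
                "mttrna_invalid_catalog")
  invisible(catalog)
}

#' The bundled mt-tRNA catalog
#'
#' Loads (and caches) the catalog shipped with the package.  Gene spans and
#' strands follow the standard rCRS (NC_012920.1) annotation of the 22
#' mitochondrial tRNA genes; cloverleaf numbering and element assignments
#' are encoded per gene as data.  The nucleotide sequences are a synthetic
#' reconstruction constrained to carry the documented reference allele at
#' every screened variant position and the documented base at every scored
#' pairing partner; they are not the true rCRS sequence (see the package
#' vignette).
#'
#' @return a `trna_catalog`.
#' @export
default_catalog <- function() {
  if (is.null(pkg_env$catalog)) {
    path <- system.file("extdata", "mt_trna_catalog_synthetic.tsv",
                        package = "mttrnascreen", mustWork = TRUE)
    pkg_env$catalog <- read_trna_catalog(path)
  }
  pkg_env$catalog
}

#' @export
print.trna_catalog <- function(x, ...) {
  cat(sprintf("mt-tRNA cloverleaf catalog: %d genes, %d mapped positions\n",
              nrow(x$genes), nrow(x$positions)))
  cat(sprintf("  rCRS span %d..%d; strands: %d H / %d L\n",
              min(x$genes$start), max(x$genes$end),
              sum(x$genes$strand == "H"), sum(x$genes$strand == "L")))
  invisible(x)
}

#' Locate the tRNA gene containing an rCRS coordinate
#'
#' @param catalog a `trna_catalog`.
#' @param genomic_pos 1-based rCRS coordinate (1..16569).
#' @return a list with `gene` (one-row data frame) and `offset`, the 1-based
#'   position within the gene's tRNA-sense sequence.  For L-strand genes the
#'   offset counts from the gene's 3'-most rCRS coordinate, i.e. from the
#'   tRNA 5' end.
#' @export
locate_gene <- function(catalog, genomic_pos) {
  if (!is.numeric(genomic_pos) || length(genomic_pos) != 1L ||
      is.na(genomic_pos) || genomic_pos < 1 || genomic_pos > RCRS_LENGTH)
    stop_mttrna("genomic_pos must be a single coordinate in 1..16569",
                "mttrna_bad_input")
  g <- catalog$genes
  hit <- which(g$start <= genomic_pos & g$end >= genomic_pos)
  if (!length(hit))
    stop_mttrna(sprintf("position %d lies outside every mt-tRNA gene",
                        genomic_pos), "mttrna_no_hit")
  gene <- g[hit[1], , drop = FALSE]
  offset <- if (gene$strand == "H") genomic_pos - gene$start + 1L
            else gene$end - genomic_pos + 1L
  list(gene = gene, offset = as.integer(offset))
}

#' Structural information for a genomic position within a tRNA gene
#'
#' @param catalog a `trna_catalog`.
#' @param gene gene name (e.g. `"tRNA-Asp"`).
#' @param genomic_pos 1-based rCRS coordinate inside the gene.
#' @return a list: `trna_position` (integer label), `element`, `partner`
#'   (integer label or NA), `ref_base` (tRNA-sense base at the position) and
#'   `partner_base` (tRNA-sense base at the partner, or NA).
#' @export
trna_position_info <- function(catalog, gene, genomic_pos) {
  g <- catalog$genes[catalog$genes$name == gene, , drop = FALSE]
  if (!nrow(g))
    stop_mttrna(sprintf("unknown gene '%s'", gene), "mttrna_bad_input")
  if (genomic_pos < g$start || genomic_pos > g$end)
    stop_mttrna(sprintf("position %d is not inside %s (%d..%d)",
                        genomic_pos, gene, g$start, g$end), "mttrna_no_hit")
  offset <- if (g$strand == "H") genomic_pos - g$start + 1L
            else g$end - genomic_pos + 1L
  pp <- catalog$positions[catalog$positions$gene == gene, ]
  row <- pp[pp$seq_index == offset, ]
  partner <- row$partner
  partner_base <- NA_character_
  if (!is.na(partner)) {
    pidx <- pp$seq_index[pp$trna_position == partner]
    partner_base <- substr(g$sequence, pidx, pidx)
  }
  list(trna_position = row$trna_position, element = row$element,
       partner = partner,
       ref_base = substr(g$sequence, offset, offset),
       partner_base = partner_base)
}
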