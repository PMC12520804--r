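GAP_CHARS <- c("-", ".", "~")

#' Construct a multi-species alignment
#'
#' @param seqs named character vector of aligned sequences (gaps allowed;
#'   all the same length).
#' @param human name of the reference (human) row.
#' @return an object of class `species_alignment`.
#' @export
species_alignment <- function(seqs, human = "Homo_sapiens") {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop_mttrna("alignment rows must carry unique species names",
                "mttrna_bad_input")
  if (length(unique(nchar(seqs))) != 1L)
    stop_mttrna("alignment rows differ in length", "mttrna_bad_input")
  if (!human %in% names(seqs))
    stop_mttrna(sprintf("human row '%s' absent from alignment", human),
                "mttrna_bad_input")
  structure(list(seqs = toupper(seqs), human = human),
            class = "species_alignment")
}

#' Read an aligned FASTA file as a species alignment
#'
#' @param path aligned FASTA file.
#' @param human name of the human row (default: first row).
#' @param species optional subset of species rows to keep (the human row is
#'   always kept), supporting caller-supplied species sets.
#' @return a `species_alignment`.
#' @export
read_species_alignment <- function(path, human = NULL, species = NULL) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- setNames(as.character(ss), names(ss))
  if (is.null(human)) human <- names(seqs)[1]
  if (!is.null(species))
    seqs <- seqs[unique(c(human, intersect(names(seqs), species)))]
  species_alignment(seqs, human = human)
}

#' @export
print.species_alignment <- function(x, ...) {
  cat(sprintf("species alignment: %d rows x %d columns (human: %s)\n",
              length(x$seqs), nchar(x$seqs[1]), x$human))
  invisible(x)
}

#' Alignment column holding a given human sequence position
#'
#' @param aln a `species_alignment`.
#' @param human_sequence_index 1-based index into the ungapped human row.
#' @return the alignment column holding that base.
#' @export
column_for_position <- function(aln, human_sequence_index) {
  h <- strsplit(aln$seqs[[aln$human]], "")[[1]]
  nongap <- which(!h %in% GAP_CHARS)
  if (human_sequence_index < 1 || human_sequence_index > length(nongap))
    stop_mttrna(sprintf("index %d outside the ungapped human row (length %d)",
                        human_sequence_index, length(nongap)),
                "mttrna_bad_input")
  nongap[human_sequence_index]
}

#' Conservation index of an alignment column
#'
#' The conservation index (CI) is the percentage of non-human species whose
#' base at the column matches the human base.  Species gapped (or carrying
#' an ambiguity symbol) at the column are excluded from the denominator, so
#' the effective depth varies by position.
#'
#' @param aln a `species_alignment`.
#' @param column alignment column index.
#' @return list: `ci_percent` (= 100 * n_match / n_compared), `n_match`,
#'   `n_compared`, `human_base`.
#' @export
conservation_index <- function(aln, column) {
  col <- toupper(substr(aln$seqs, column, column))
  if (any(col == ""))
    stop_mttrna("column index beyond alignment length", "mttrna_bad_input")
  human_base <- col[[aln$human]]
  if (!human_base %in% c("A", "C", "G", "T"))
    stop_mttrna(sprintf("human row is gap/ambiguous at column %d", column),
                "mttrna_bad_input")
  others <- col[setdiff(names(col), aln$human)]
  compared <- others[others %in% c("A", "C", "G", "T")]
  if (!length(compared))
    stop_mttrna(sprintf("conservation index undefined: no comparable species at column %d",
                        column), "mttrna_undefined_ci")
  n_match <- sum(compared == human_base)
  list(ci_percent = 100 * n_match / length(compared),
       n_match = n_match, n_compared = length(compared),
       human_base = human_base)
}

#' Conservation index at an ungapped human position
#'
#' Convenience composition of [column_for_position()] and
#' [conservation_index()].
#'
#' @inheritParams column_for_position
#' @return see [conservation_index()].
#' @export
conservation_at <- function(aln, human_sequence_index) {
  conservation_index(aln, column_for_position(aln, human_sequence_index))
}

#' Functional-importance flag for a conservation index
#'
#' Positions with CI at or above the threshold are flagged as functionally
#' important.  The comparison is inclusive: a CI of exactly 75 percent
#' qualifies.
#'
#' @param ci_percent CI value(s) in 0..100.
#' @param threshold threshold in percent (default 75).
#' @return logical vector.
#' @export
is_functionally_important <- function(ci_percent, threshold = 75) {
  if (any(ci_percent < 0 | ci_percent > 100, na.rm = TRUE))
    stop_mttrna("CI must lie in [0, 100]", "mttrna_bad_input")
  !is.na(ci_percent) & ci_percent >= threshold
}
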