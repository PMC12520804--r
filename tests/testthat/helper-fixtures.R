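# Small in-code fixtures shared across tests.

# A minimal two-gene catalog used for error-path tests.  gene A: H-strand,
# 10 nt, positions 1..10 with 1-10, 2-9 paired; gene B: L-strand, 6 nt.
tiny_catalog <- function(break_symmetry = FALSE, break_span = FALSE) {
  genes <- data.frame(
    name = c("tRNA-TestA", "tRNA-TestB"),
    start = c(101L, 201L), end = c(110L, 206L),
    strand = c("H", "L"),
    sequence = c("ACGTACGTAC", if (break_span) "ACGT" else "GATTAC"),
    stringsAsFactors = FALSE)
  pos_a <- data.frame(gene = "tRNA-TestA", trna_position = 1:10,
                      seq_index = 1:10,
                      element = c("Acceptor arm", "Acceptor arm", "D-arm",
                                  "D-arm", "Anticodon loop", "Anticodon loop",
                                  "D-arm", "D-arm", "Acceptor arm",
                                  "Acceptor arm"),
                      partner = c(10L, 9L, rep(NA, 6), 2L, 1L))
  if (break_symmetry) pos_a$partner[10] <- 3L
  pos_b <- data.frame(gene = "tRNA-TestB", trna_position = 1:6,
                      seq_index = 1:6, element = "TψC loop",
                      partner = NA_integer_)
  structure(list(genes = genes, positions = rbind(pos_a, pos_b)),
            class = "trna_catalog")
}

# the eight variants with printed Watson-Crick arrows and their directions
wc_arrow_variants <- function() {
  data.frame(
    label = c("m.3275C>T", "m.4395T>C", "m.7492C>T",
              "m.3302A>G", "m.5802G>A", "m.5821G>A", "m.7543A>G",
              "m.7544C>T"),
    effect = c(rep("created", 3), rep("disrupted", 5)),
    stringsAsFactors = FALSE)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
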