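# Builds inst/extdata/mt_trna_catalog_synthetic.tsv
#
# Gene coordinates and strands are the standard rCRS (NC_012920.1) mt-tRNA
# annotations.  Position numbering follows a canonical cloverleaf template
# (1-73) with per-gene dropped/inserted positions chosen so that every
# per-variant numbering printed in the source screening table is satisfied.
# Sequences are SYNTHETIC: random bases constrained so that (a) every
# documented variant position carries its documented reference allele in
# tRNA-sense, (b) base-pair partners implied by the documented Watson-Crick
# arrows carry the required bases, and (c) all other authored stem pairs are
# WC-complementary.  The true rCRS sequence is not reproduced.
#
# Run from the package root:  Rscript tools/make_catalog.R

set.seed(20250926)

genes <- read.table(text = "
name	start	end	strand
tRNA-Phe	577	647	H
tRNA-Val	1602	1670	H
tRNA-Leu(UUR)	3230	3304	H
tRNA-Ile	4263	4331	H
tRNA-Gln	4329	4400	L
tRNA-Met	4402	4469	H
tRNA-Trp	5512	5579	H
tRNA-Ala	5587	5655	L
tRNA-Asn	5657	5729	L
tRNA-Cys	5761	5826	L
tRNA-Tyr	5826	5891	L
tRNA-Ser(UCN)	7446	7514	L
tRNA-Asp	7518	7585	H
tRNA-Lys	8295	8364	H
tRNA-Gly	9991	10058	H
tRNA-Arg	10405	10469	H
tRNA-His	12138	12206	H
tRNA-Ser(AGY)	12207	12265	H
tRNA-Leu(CUN)	12266	12336	H
tRNA-Glu	14674	14742	L
tRNA-Thr	15888	15953	H
tRNA-Pro	15956	16023	L
", header = TRUE, sep = "\t", stringsAsFactors = FALSE)

# positions removed from / inserted into the 1-73 template, per gene
drops <- list(
  "tRNA-Phe"      = c(59, 60),
  "tRNA-Val"      = c(17, 18, 47, 48),
  "tRNA-Leu(UUR)" = integer(0),
  "tRNA-Ile"      = c(17, 18, 47, 48),
  "tRNA-Gln"      = c(59),
  "tRNA-Met"      = c(16, 17, 18, 47, 48),
  "tRNA-Trp"      = c(21, 47, 48, 59, 60),
  "tRNA-Ala"      = c(17, 18, 47, 48),
  "tRNA-Asn"      = integer(0),
  "tRNA-Cys"      = c(17, 18, 20, 21, 24, 47, 48),
  "tRNA-Tyr"      = c(17, 18, 20, 21, 47, 48, 59),
  "tRNA-Ser(UCN)" = c(18, 20, 21, 59),
  "tRNA-Asp"      = c(17, 18, 21, 47, 48),
  "tRNA-Lys"      = c(17, 18, 20, 21, 47),
  "tRNA-Gly"      = c(16, 17, 18, 47, 59),
  "tRNA-Arg"      = c(17, 18, 21, 47, 48, 57, 58, 59),
  "tRNA-His"      = c(17, 18, 47, 48),
  "tRNA-Ser(AGY)" = c(8, 9, 14:25),
  "tRNA-Leu(CUN)" = c(47, 48),
  "tRNA-Glu"      = c(8, 9, 47, 48),
  "tRNA-Thr"      = c(18, 19, 47, 56, 57, 59, 60),
  "tRNA-Pro"      = c(17, 18, 21, 47, 48)
)
# inserted positions: list of (after_template_position, integer label)
inserts <- list(
  "tRNA-Leu(UUR)" = list(c(17, 90), c(17, 91)),   # extended D-loop
  "tRNA-Lys"      = list(c(58, 95), c(58, 96))    # extended T-loop
)

element_of <- function(p) {
  if (p >= 90) stop("insert labels handled separately")
  if (p <= 7)  return("Acceptor arm")
  if (p <= 26) return("D-arm")
  if (p <= 31) return("Anticodon stem")
  if (p <= 38) return("Anticodon loop")
  if (p <= 43) return("Anticodon stem")
  if (p <= 48) return("Variable region")
  if (p <= 65) return("TψC loop")
  "Acceptor arm"
}
insert_element <- c("90" = "D-arm", "91" = "D-arm",
                    "95" = "TψC loop", "96" = "TψC loop")

# element overrides (gene, position, element) following the printed table
elem_override <- list(
  list("tRNA-Gln",       38, "Anticodon stem"),
  list("tRNA-Ser(UCN)",  26, "Anticodon stem"),
  list("tRNA-Ser(UCN)",  44, "Anticodon stem"),
  list("tRNA-Leu(UUR)",  26, "Variable region"),
  list("tRNA-Leu(UUR)",  44, "Variable region"),
  list("tRNA-Ser(AGY)",  42, "Acceptor arm")
)

# template pairs: acceptor stem 1-7 with 72-66, anticodon stem 27-31 with 43-39
template_pairs <- rbind(
  cbind(1:7, 72:66),
  cbind(27:31, 43:39)
)
pair_add    <- list("tRNA-Leu(UUR)" = c(26, 44), "tRNA-Ser(UCN)" = c(26, 44))
pair_remove <- list("tRNA-Ser(AGY)" = c(28, 42))

# tRNA-sense base constraints: documented reference alleles (complemented for
# L-strand genes) plus the partner bases forced by the documented WC arrows.
base_constraints <- list(
  "tRNA-Phe"      = c("20" = "T", "58" = "T"),
  "tRNA-Val"      = c("61" = "T"),
  "tRNA-Leu(UUR)" = c("71" = "A", "44" = "C", "59" = "T", "2" = "T", "26" = "A"),
  "tRNA-Ile"      = c("15" = "T", "54" = "C"),
  "tRNA-Gln"      = c("38" = "A", "6" = "A", "67" = "C"),
  "tRNA-Met"      = c("58" = "T"),
  "tRNA-Trp"      = c("20" = "A", "61" = "T"),
  "tRNA-Ala"      = c("59" = "G", "57" = "C"),
  "tRNA-Asn"      = c("19" = "T"),
  "tRNA-Cys"      = c("30" = "C", "16" = "A", "6" = "C", "40" = "G", "67" = "G"),
  "tRNA-Ser(UCN)" = c("26" = "G", "17" = "G", "44" = "T"),
  "tRNA-Asp"      = c("29" = "A", "30" = "C", "41" = "T", "40" = "G"),
  "tRNA-Lys"      = c("54" = "A"),
  "tRNA-Gly"      = c("20" = "T", "44" = "T", "53" = "A"),
  "tRNA-Arg"      = c("55" = "T"),
  "tRNA-His"      = c("16" = "C", "55" = "T", "56" = "T"),
  "tRNA-Ser(AGY)" = c("42" = "A", "54" = "C"),
  "tRNA-Leu(CUN)" = c("15" = "A"),
  "tRNA-Glu"      = c("54" = "T", "18" = "A"),
  "tRNA-Thr"      = c("13" = "T", "17" = "C", "22" = "A", "45" = "G", "54" = "C"),
  "tRNA-Pro"      = c("59" = "A", "7" = "T", "66" = "C")
)

comp <- c(A = "T", C = "G", G = "C", T = "A")
bases <- c("A", "C", "G", "T")

pos_rows <- list()
gene_seqs <- character(0)

for (i in seq_len(nrow(genes))) {
  g <- genes$name[i]
  L <- genes$end[i] - genes$start[i] + 1

  kept <- setdiff(1:73, drops[[g]])
  # splice inserted labels after their template anchor
  labels <- kept
  if (!is.null(inserts[[g]])) {
    for (ins in inserts[[g]]) {
      at <- which(labels == ins[1])
      labels <- append(labels, ins[2], after = at)
    }
  }
  stopifnot(length(labels) == L)

  elem <- vapply(labels, function(p) {
    if (p >= 90) return(insert_element[[as.character(p)]])
    element_of(p)
  }, character(1))
  for (ov in elem_override) {
    if (ov[[1]] == g) elem[labels == ov[[2]]] <- ov[[3]]
  }

  prs <- template_pairs
  if (!is.null(pair_add[[g]]))    prs <- rbind(prs, pair_add[[g]])
  if (!is.null(pair_remove[[g]])) {
    rm <- pair_remove[[g]]
    prs <- prs[!(prs[, 1] == rm[1] & prs[, 2] == rm[2]), , drop = FALSE]
  }
  prs <- prs[prs[, 1] %in% labels & prs[, 2] %in% labels, , drop = FALSE]
  partner <- setNames(rep(NA_integer_, L), labels)
  partner[as.character(prs[, 1])] <- prs[, 2]
  partner[as.character(prs[, 2])] <- prs[, 1]

  # sequence: constraints first, then WC-complete authored pairs, then random
  seq <- setNames(rep(NA_character_, L), labels)
  cons <- base_constraints[[g]]
  if (!is.null(cons)) seq[names(cons)] <- cons
  for (r in seq_len(nrow(prs))) {
    p <- as.character(prs[r, 1]); q <- as.character(prs[r, 2])
    if (is.na(seq[p]) && is.na(seq[q])) {
      seq[p] <- sample(bases, 1); seq[q] <- comp[[seq[p]]]
    } else if (is.na(seq[q])) {
      seq[q] <- comp[[seq[p]]]
    } else if (is.na(seq[p])) {
      seq[p] <- comp[[seq[q]]]
    } # both constrained: leave as authored (may be a deliberate mismatch)
  }
  nfill <- sum(is.na(seq))
  seq[is.na(seq)] <- sample(bases, nfill, replace = TRUE)

  gene_seqs[g] <- paste(seq, collapse = "")
  pos_rows[[g]] <- data.frame(
    gene = g, trna_position = as.integer(labels), seq_index = seq_len(L),
    element = elem, partner = as.integer(partner),
    stringsAsFactors = FALSE
  )
}

genes$sequence <- gene_seqs[genes$name]
positions <- do.call(rbind, pos_rows)
rownames(positions) <- NULL

## ---- verification against the printed anchors -----------------------------
anchors <- read.table(text = "
gene	rcrs	position	element
tRNA-Phe	596	20	D-arm
tRNA-Phe	634	58	TpsiC loop
tRNA-Val	1658	61	TpsiC loop
tRNA-Leu(UUR)	3302	71	Acceptor arm
tRNA-Leu(UUR)	3275	44	Variable region
tRNA-Leu(UUR)	3290	59	TpsiC loop
tRNA-Ile	4277	15	D-arm
tRNA-Ile	4312	54	TpsiC loop
tRNA-Gln	4363	38	Anticodon stem
tRNA-Gln	4395	6	Acceptor arm
tRNA-Met	4454	58	TpsiC loop
tRNA-Trp	5531	20	D-arm
tRNA-Trp	5567	61	TpsiC loop
tRNA-Ala	5601	59	TpsiC loop
tRNA-Asn	5711	19	D-arm
tRNA-Cys	5802	30	Anticodon stem
tRNA-Cys	5811	16	D-arm
tRNA-Cys	5821	6	Acceptor arm
tRNA-Ser(UCN)	7492	26	Anticodon stem
tRNA-Ser(UCN)	7498	17	D-arm
tRNA-Asp	7543	29	Anticodon stem
tRNA-Asp	7544	30	Anticodon stem
tRNA-Lys	8343	54	TpsiC loop
tRNA-Gly	10007	20	D-arm
tRNA-Gly	10031	44	Variable region
tRNA-Gly	10039	53	TpsiC loop
tRNA-Arg	10454	55	TpsiC loop
tRNA-His	12153	16	D-arm
tRNA-His	12188	55	TpsiC loop
tRNA-His	12189	56	TpsiC loop
tRNA-Ser(AGY)	12234	42	Acceptor arm
tRNA-Ser(AGY)	12246	54	TpsiC loop
tRNA-Leu(CUN)	12280	15	D-arm
tRNA-Glu	14693	54	TpsiC loop
tRNA-Glu	14727	18	D-arm
tRNA-Thr	15900	13	D-arm
tRNA-Thr	15904	17	D-arm
tRNA-Thr	15907	22	D-arm
tRNA-Thr	15930	45	Variable region
tRNA-Thr	15938	54	TpsiC loop
tRNA-Pro	15970	59	TpsiC loop
tRNA-Pro	16017	7	Acceptor arm
", header = TRUE, sep = "\t", stringsAsFactors = FALSE)
anchors$element <- sub("TpsiC", "TψC", anchors$element)

ok <- TRUE
for (j in seq_len(nrow(anchors))) {
  gi <- genes[genes$name == anchors$gene[j], ]
  off <- if (gi$strand == "H") anchors$rcrs[j] - gi$start + 1 else gi$end - anchors$rcrs[j] + 1
  pr <- positions[positions$gene == anchors$gene[j] & positions$seq_index == off, ]
  if (pr$trna_position != anchors$position[j] || pr$element != anchors$element[j]) {
    ok <- FALSE
    cat(sprintf("ANCHOR FAIL %s %d: got pos %d %s, want %d %s\n",
                anchors$gene[j], anchors$rcrs[j], pr$trna_position, pr$element,
                anchors$position[j], anchors$element[j]))
  }
}
stopifnot(ok)
cat("all", nrow(anchors), "numbering anchors satisfied\n")

## ---- write ----------------------------------------------------------------
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
out <- file("inst/extdata/mt_trna_catalog_synthetic.tsv", open = "w", encoding = "UTF-8")
writeLines(c(
  "# mt-tRNA cloverleaf catalog (rCRS coordinates; SYNTHETIC sequences)",
  "# generated by tools/make_catalog.R -- see that script for provenance",
  "[genes]",
  paste(c("name", "start", "end", "strand", "sequence"), collapse = "\t")), out)
for (i in seq_len(nrow(genes)))
  writeLines(paste(genes$name[i], genes$start[i], genes$end[i],
                   genes$strand[i], genes$sequence[i], sep = "\t"), out)
writeLines(c("[positions]",
             paste(c("gene", "trna_position", "seq_index", "element", "partner"),
                   collapse = "\t")), out)
for (i in seq_len(nrow(positions)))
  writeLines(paste(positions$gene[i], positions$trna_position[i],
                   positions$seq_index[i], positions$element[i],
                   ifelse(is.na(positions$partner[i]), "NA", positions$partner[i]),
                   sep = "\t"), out)
close(out)
cat("wrote inst/extdata/mt_trna_catalog_synthetic.tsv:",
    nrow(genes), "genes,", nrow(positions), "positions\n")
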