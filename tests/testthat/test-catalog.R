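test_that("bundled catalog carries all 22 mt-tRNA genes and valid maps", {
  cat22 <- default_catalog()
  expect_s3_class(cat22, "trna_catalog")
  expect_equal(nrow(cat22$genes), 22)
  expect_setequal(cat22$genes$name, mttrnascreen:::MT_TRNA_GENE_NAMES)
  # sequence length equals the genomic span for every gene
  expect_equal(nchar(cat22$genes$sequence),
               cat22$genes$end - cat22$genes$start + 1)
})

test_that("partner relation is symmetric in every one of the 22 gene maps", {
  cat22 <- default_catalog()
  for (g in cat22$genes$name) {
    pp <- cat22$positions[cat22$positions$gene == g, ]
    paired <- pp[!is.na(pp$partner), ]
    back <- pp$partner[match(paired$partner, pp$trna_position)]
    expect_equal(back, paired$trna_position,
                 label = sprintf("partner symmetry in %s", g))
  }
})

test_that("anticodon stem positions pair canonically (27-31 with 43-39)", {
  cat22 <- default_catalog()
  pp <- cat22$positions
  stem <- pp[pp$element == "Anticodon stem" & !is.na(pp$partner) &
               pp$trna_position %in% 27:31, ]
  expect_gt(nrow(stem), 0)
  expect_true(all(stem$partner == 70 - stem$trna_position))
  # partners of anticodon-stem entries are themselves stem-annotated
  for (i in seq_len(nrow(stem))) {
    mate <- pp[pp$gene == stem$gene[i] &
                 pp$trna_position == stem$partner[i], ]
    expect_equal(mate$element, "Anticodon stem")
  }
  # the aspartate tRNA pairs position 30 with 40
  asp <- pp[pp$gene == "tRNA-Asp" & pp$trna_position == 30, ]
  expect_equal(asp$partner, 40)
})

test_that("locate_gene finds the containing gene with strand-aware offsets", {
  cat22 <- default_catalog()
  expect_equal(locate_gene(cat22, 7544)$gene$name, "tRNA-Asp")
  expect_equal(locate_gene(cat22, 8343)$gene$name, "tRNA-Lys")
  # first base of an H-strand gene
  expect_equal(locate_gene(cat22, 577)$offset, 1L)
  # L-strand genes count from the 3'-most rCRS coordinate (tRNA 5' end)
  expect_equal(locate_gene(cat22, 4400)$offset, 1L)   # tRNA-Gln
  expect_equal(locate_gene(cat22, 4400)$gene$strand, "L")
  # positions outside every tRNA gene are a recoverable no-hit
  expect_error(locate_gene(cat22, 100), class = "mttrna_no_hit")
  expect_error(locate_gene(cat22, 0), class = "mttrna_bad_input")
})

test_that("trna_position_info reports numbering, element, partner and bases", {
  cat22 <- default_catalog()
  asp <- trna_position_info(cat22, "tRNA-Asp", 7544)
  expect_equal(asp$trna_position, 30)
  expect_equal(asp$element, "Anticodon stem")
  expect_equal(asp$partner, 40)
  expect_equal(asp$ref_base, "C")
  expect_equal(asp$partner_base, "G")

  leu <- trna_position_info(cat22, "tRNA-Leu(UUR)", 3302)
  expect_equal(leu$trna_position, 71)
  expect_equal(leu$element, "Acceptor arm")

  lys <- trna_position_info(cat22, "tRNA-Lys", 8343)
  expect_equal(lys$trna_position, 54)
  expect_equal(lys$element, "TψC loop")
  expect_true(is.na(lys$partner))

  expect_error(trna_position_info(cat22, "tRNA-Asp", 8343),
               class = "mttrna_no_hit")
})

test_that("catalog validation rejects broken structures, naming the gene", {
  expect_silent(validate_catalog(tiny_catalog(), require_complete = FALSE))
  expect_error(validate_catalog(tiny_catalog(break_symmetry = TRUE),
                                require_complete = FALSE),
               "tRNA-TestA.*asymmetric", class = "mttrna_invalid_catalog")
  expect_error(validate_catalog(tiny_catalog(break_span = TRUE),
                                require_complete = FALSE),
               "tRNA-TestB.*span", class = "mttrna_invalid_catalog")
  expect_error(validate_catalog(tiny_catalog(), require_complete = TRUE),
               "missing", class = "mttrna_invalid_catalog")
})

test_that("catalog write-then-read round trip restores identical structures", {
  cat22 <- default_catalog()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trna_catalog(cat22, path)
  back <- read_trna_catalog(path)
  expect_equal(back$genes, cat22$genes)
  expect_equal(back$positions, cat22$positions)
})
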