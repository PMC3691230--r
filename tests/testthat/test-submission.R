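test_that("render_fasta wraps at 70 columns with strict headers", {
  expect_identical(render_fasta(c(r1 = "ACGTA")), ">r1\nACGTA\n")

  rec71 <- c(x = strrep("A", 71L))
  lines <- strsplit(render_fasta(rec71), "\n")[[1]]
  expect_length(lines, 3L)
  expect_identical(nchar(lines), c(2L, 70L, 1L))

  expect_error(render_fasta(c(a = "AC", a = "GT")), "duplicate")
  expect_error(render_fasta(structure("AC", names = "")), "non-empty id")
})

test_that("render_fasta round-trips through an independent FASTA reader", {
  set.seed(33)
  for (i in 1:30) {
    n <- sample.int(5L, 1L)
    recs <- vapply(seq_len(n), function(j) random_dna(sample.int(400L, 1L)),
                   character(1))
    names(recs) <- sprintf("seq%02d", seq_len(n))
    f <- tempfile(fileext = ".fasta")
    writeLines(sub("\n$", "", render_fasta(recs)), f)
    back <- Biostrings::readDNAStringSet(f)
    unlink(f)
    expect_identical(as.character(back), recs)
  }
})

test_that("render_agp lays out W and N rows over the layout tiling", {
  contigs <- c(c1 = "ACGTA", c2 = "GGCC")
  asm <- assemble(scaffold(list(seq_entry("c1"), gap_entry(3L),
                                seq_entry("c2", reverse = TRUE))),
                  contigs, "scaf")
  rows <- strsplit(render_agp(asm), "\n")[[1]]
  expect_identical(rows[1L], "##agp-version 2.0")
  expect_length(rows, 4L)
  expect_identical(rows[2L], "scaf\t1\t5\t1\tW\tc1\t1\t5\t+")
  expect_identical(rows[3L], "scaf\t6\t8\t2\tN\t3\tscaffold\tyes\tunspecified")
  expect_identical(rows[4L], "scaf\t9\t12\t3\tW\tc2\t1\t4\t-")

  asm1 <- assemble(scaffold(list(seq_entry("c1"))), contigs)
  r1 <- strsplit(render_agp(asm1), "\n")[[1]][2L]
  f <- strsplit(r1, "\t")[[1]]
  expect_identical(f[5L], "W")
  expect_identical(f[7L], "1")
  expect_identical(f[9L], "+")
})

test_that("reconstruct_from_agp inverts render_agp and rejects bad tilings", {
  for (seed in 1:20) {
    fx <- generate_fixture(fixture_spec(
      n_contigs = c(2L, 4L), contig_length = c(200L, 1500L),
      gap_length = c(10L, 60L), seed = 2000L + seed))
    asm <- assemble(fx$scaffold, fx$contigs)
    expect_identical(
      reconstruct_from_agp(render_agp(asm), scaffold_components(asm)),
      asm$seq)
  }

  comp <- c(c1 = "ACGTACGT")
  whole <- "##agp-version 2.0\nobj\t1\t8\t1\tW\tc1\t1\t8\t+\n"
  expect_identical(reconstruct_from_agp(whole, comp), "ACGTACGT")

  holed <- paste0("##agp-version 2.0\n",
                  "obj\t1\t3\t1\tW\tc1\t1\t3\t+\n",
                  "obj\t5\t8\t2\tW\tc1\t5\t8\t+\n")
  expect_error(reconstruct_from_agp(holed, comp), "tiling violation")
  expect_error(
    reconstruct_from_agp("obj\t1\t9\t1\tW\tc1\t1\t9\t+\n", comp),
    "outside 'c1'")
  expect_error(
    reconstruct_from_agp("obj\t1\t4\t1\tW\tcX\t1\t4\t+\n", comp),
    "unknown component")
})

test_that("repeated placements get unique component ids in FASTA and AGP", {
  contigs <- c(dup = "ACGTACGTAC", o = "GGGG")
  asm <- assemble(scaffold(list(seq_entry("dup"), gap_entry(4L),
                                seq_entry("dup", reverse = TRUE),
                                gap_entry(4L), seq_entry("o"))),
                  contigs)
  comps <- scaffold_components(asm)
  expect_identical(names(comps), c("dup", "dup.2", "o"))
  expect_identical(reconstruct_from_agp(render_agp(asm), comps), asm$seq)
})

test_that("derive_cds emits a matching gene/CDS pair", {
  g <- make_annotations("scaf", 103L, 106L, "+",
                        attributes = list(c(ID = "g", Name = "polA",
                                            locus_tag = "X_00010",
                                            product = "DNA polymerase")))
  pair <- derive_cds(g)
  expect_length(pair, 2L)
  expect_identical(pair[[1L]]$key, "gene")
  expect_identical(pair[[2L]]$key, "CDS")
  expect_identical(c(pair[[1L]]$start, pair[[1L]]$stop), c(103L, 106L))
  expect_identical(c(pair[[2L]]$start, pair[[2L]]$stop), c(103L, 106L))
  expect_identical(pair[[2L]]$qualifiers[["product"]], "DNA polymerase")
  expect_identical(pair[[1L]]$qualifiers[["locus_tag"]], "X_00010")
  expect_identical(pair[[1L]]$qualifiers[["gene"]], "polA")

  # minus strand: start > stop in both rows
  gm <- make_annotations("scaf", 5L, 8L, "-",
                         attributes = list(c(ID = "g2",
                                             locus_tag = "X_00020")))
  pm <- derive_cds(gm)
  expect_identical(c(pm[[1L]]$start, pm[[1L]]$stop), c(8L, 5L))
  expect_identical(c(pm[[2L]]$start, pm[[2L]]$stop), c(8L, 5L))

  # product defaults to hypothetical protein
  expect_identical(pm[[2L]]$qualifiers[["product"]],
                   "hypothetical protein")

  cds <- make_annotations("scaf", 1L, 3L, "+", type = "CDS",
                          attributes = list(c(ID = "x")))
  expect_error(derive_cds(cds), "gene-type")
})

test_that("renumber_locus_tags numbers from the origin in steps of 10", {
  ann <- rbind(
    make_annotations("s", 10L, 20L, "+",
                     attributes = list(c(ID = "a", locus_tag = "OLD_1"))),
    make_annotations("s", 50L, 60L, "-",
                     attributes = list(c(ID = "b"))),
    make_annotations("s", 90L, 95L, "+",
                     attributes = list(c(ID = "c", locus_tag = "OLD_3"))))
  out <- renumber_locus_tags(ann, "PFLU")
  tags <- vapply(out$attributes, function(a) a[["locus_tag"]], character(1))
  expect_identical(tags, c("PFLU_00010", "PFLU_00020", "PFLU_00030"))

  # idempotent in assigned values
  out2 <- renumber_locus_tags(out, "PFLU")
  expect_identical(out2, out)

  one <- renumber_locus_tags(ann[3L, ], "PFLU")
  expect_identical(one$attributes[[1L]][["locus_tag"]], "PFLU_00010")

  expect_error(renumber_locus_tags(ann, ""), "non-empty")
  expect_error(renumber_locus_tags(ann[c(2L, 1L), ], "PFLU"), "sorted")
})

test_that("render_tbl produces the exact 5-column layout", {
  g <- make_annotations("scaf", 103L, 106L, "+",
                        attributes = list(c(ID = "g",
                                            locus_tag = "X_00010",
                                            product = "DNA polymerase")))
  txt <- render_tbl("scaf", derive_cds(g), 200L)
  lines <- strsplit(txt, "\n")[[1]]
  expect_identical(lines[1L], ">Feature scaf")
  # header + gene row + its locus_tag + CDS row + product + locus_tag
  expect_length(lines, 6L)
  expect_identical(lines[3L], "\t\t\tlocus_tag\tX_00010")

  expect_identical(render_tbl("scaf", list()), ">Feature scaf\n")

  gm <- make_annotations("scaf", 5L, 8L, "-",
                         attributes = list(c(ID = "m", locus_tag = "T_1")))
  lm <- strsplit(render_tbl("scaf", derive_cds(gm), 100L), "\n")[[1]]
  expect_identical(lm[2L], "8\t5\tgene")

  expect_error(render_tbl("scaf", derive_cds(g), 50L), "outside scaffold")
})

test_that("the toy project renders the hand-computed golden feature table", {
  toy <- toy_project()
  asm <- assemble(toy$scaffold, toy$contigs, "scaffold")
  rep <- lift_all(toy$annotations, asm)
  expect_identical(nrow(rep$lifted), 2L)
  expect_identical(rep$dropped$reason, "overlaps-trimmed-region")
  genes <- renumber_locus_tags(rep$lifted, "TOY")
  txt <- render_tbl("scaffold", tbl_features_from_genes(genes),
                    nchar(asm$seq))
  golden <- paste0(
    ">Feature scaffold\n",
    "11\t40\tgene\n",
    "\t\t\tgene\tdnaE\n",
    "\t\t\tlocus_tag\tTOY_00010\n",
    "11\t40\tCDS\n",
    "\t\t\tproduct\tDNA polymerase III\n",
    "\t\t\tlocus_tag\tTOY_00010\n",
    "106\t95\tgene\n",
    "\t\t\tlocus_tag\tTOY_00020\n",
    "106\t95\tCDS\n",
    "\t\t\tproduct\thypothetical protein\n",
    "\t\t\tlocus_tag\tTOY_00020\n")
  expect_identical(txt, golden)
})

test_that("emitted AGP passes the independent structural validator", {
  toy <- toy_project()
  asm <- assemble(toy$scaffold, toy$contigs, "scaffold")
  expect_identical(validate_agp_text(render_agp(asm)), character(0))
  for (seed in 1:10) {
    fx <- generate_fixture(fixture_spec(
      n_contigs = c(2L, 5L), contig_length = c(200L, 1500L),
      gap_length = c(10L, 60L), seed = 3000L + seed))
    a <- assemble(fx$scaffold, fx$contigs)
    expect_identical(validate_agp_text(render_agp(a)), character(0))
  }
})
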