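make_codon_aln <- function(ids, protein_rows, cds) {
  paln <- new_alignment(tibble::tibble(id = ids, residues = protein_rows),
                        "protein")
  cds_tbl <- tibble::tibble(id = ids, description = "", residues = cds,
                            alphabet = "dna")
  backtranslate_alignment(paln, cds_tbl)
}

test_that("backtranslation expands residues to codons and gaps to ---", {
  ca <- make_codon_aln("x", "MK", "ATGAAA")
  expect_equal(ca$residues, "ATGAAA")
  expect_equal(aln_length(ca), 6L)

  ca2 <- make_codon_aln("x", "M-K", "ATGAAA")
  expect_equal(ca2$residues, "ATG---AAA")
  expect_equal(aln_length(ca2), 9L)

  # trailing stop codon on the CDS is trimmed
  ca3 <- make_codon_aln("x", "MK", "ATGAAATAA")
  expect_equal(ca3$residues, "ATGAAA")

  expect_error(make_codon_aln("x", "MK", "ATGAA"),
               class = "setstruct_length_error")
  err <- tryCatch(make_codon_aln("x", "MW", "ATGAAA"), error = function(e) e)
  expect_s3_class(err, "setstruct_translation_error")
  expect_match(conditionMessage(err), "column 2")
})

test_that("translation fidelity holds across all rows of a backtranslation", {
  sim <- scenario_suvh(seed = 3)
  ca <- backtranslate_alignment(sim$protein_aln, sim$mrna)
  gc <- Biostrings::GENETIC_CODE
  for (k in seq_len(nrow(ca))) {
    nt <- gsub("-", "", ca$residues[k])
    codons <- substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
    aa <- gsub("-", "", sim$protein_aln$residues[
      sim$protein_aln$id == ca$id[k]])
    expect_equal(paste(unname(gc[codons]), collapse = ""), aa)
  }
})

test_that("intron projection maps CDS offsets to alignment columns", {
  genomic <- paste0("ATGGCC", "GTAAGTACAG", "GAGTAA")
  s <- infer_structure(genomic, "ATGGCCGAGTAA", gene_id = "x")
  # identity mapping: gapless row covering the full CDS
  ca <- make_codon_aln("x", "MAE", "ATGGCCGAGTAA")
  pr <- project_introns(s, ca)
  expect_equal(pr$alignment_column, 6L)
  expect_true(pr$in_region)
  expect_equal(pr$phase, 0L)

  # one leading gap codon shifts the column by 3
  ca2 <- make_codon_aln(c("x", "y"), c("-MAE", "WMAE"),
                        c("ATGGCCGAGTAA", "TGGATGGCCGAG"))
  pr2 <- project_introns(s, ca2)
  expect_equal(pr2$alignment_column, 9L)
})

test_that("a leading gap codon example projects offset 3 to column 6", {
  # row "---ATGAAA": intron after the first aligned codon
  g <- paste0("ATG", "GTAAACAG", "AAATAA")
  s <- infer_structure(g, "ATGAAATAA", gene_id = "a")
  ca <- make_codon_aln(c("a", "b"), c("-MK", "WMK"),
                       c("ATGAAATAA", "TGGATGAAA"))
  pr <- project_introns(s, ca)
  expect_equal(pr$cds_offset, 3L)
  expect_equal(pr$alignment_column, 6L)
})

test_that("introns outside the aligned sub-region are reported, not dropped", {
  # alignment covers only the second codon onward of gene a's CDS
  g <- paste0("ATG", "GTAAACAG", "AAAGAGTAA")
  s <- infer_structure(g, "ATGAAAGAGTAA", gene_id = "a")
  ca <- make_codon_aln(c("a", "b"), c("KE", "KE"), c("AAAGAG", "AAAGAA"))
  pr <- project_introns(s, ca)
  expect_equal(nrow(pr), 1L)
  expect_false(pr$in_region)
  expect_true(is.na(pr$alignment_column))

  expect_error(project_introns(s, make_codon_aln("z", "MK", "ATGAAA")),
               regexp = "absent")
})

test_that("shared positions group by exact column equality only", {
  mk <- function(gene, col) tibble::tibble(gene_id = gene, intron_index = 1L,
                                           cds_offset = col, phase = col %% 3L,
                                           in_region = TRUE,
                                           alignment_column = col)
  inc <- intron_incidence(dplyr::bind_rows(mk("A", 17L), mk("B", 17L),
                                           mk("C", 17L)))
  sh <- shared_intron_positions(inc)
  expect_equal(nrow(sh), 1L)
  expect_equal(sh$alignment_column, 17L)
  expect_equal(sh$gene_ids[[1]], c("A", "B", "C"))
  expect_true(sh$phase_agreement)

  # one base apart never merges
  inc2 <- intron_incidence(dplyr::bind_rows(mk("A", 17L), mk("B", 18L)))
  expect_equal(nrow(shared_intron_positions(inc2)), 0L)
  # but the sliding report surfaces the near-identical pair
  sl <- sliding_report(inc2, window = 6L)
  expect_equal(nrow(sl), 1L)
  expect_equal(sl$distance, 1L)

  empty <- intron_incidence(mk("A", 5L)[0, ])
  expect_equal(nrow(shared_intron_positions(empty)), 0L)
})

test_that("projection is injective per gene and gap-shift invariant", {
  g <- paste0("ATG", "GTAAACAG", "AAA", "GTCCCCAG", "GAGTGGTAA")
  s <- infer_structure(g, "ATGAAAGAGTGGTAA", gene_id = "a")
  ca <- make_codon_aln(c("a", "b"), c("MKEW", "MKEW"),
                       c("ATGAAAGAGTGGTAA", "ATGAAAGAGTGG"))
  pr <- project_introns(s, ca)
  expect_equal(anyDuplicated(pr$alignment_column), 0L)

  # insert an all-gap codon column at the front of the protein alignment:
  # every projected column shifts by exactly 3, sharing is unchanged
  ca_shift <- make_codon_aln(c("a", "b", "c"), c("-MKEW", "-MKEW", "W----"),
                             c("ATGAAAGAGTGGTAA", "ATGAAAGAGTGG", "TGG"))
  pr_shift <- project_introns(s, ca_shift)
  expect_equal(pr_shift$alignment_column, pr$alignment_column + 3L)
})

test_that("structural grouping links by shared positions, single linkage", {
  mk <- function(gene, cols) tibble::tibble(
    gene_id = gene, intron_index = seq_along(cols),
    cds_offset = cols, phase = cols %% 3L,
    in_region = TRUE, alignment_column = cols)
  proj <- dplyr::bind_rows(mk("g1", c(5L, 12L, 20L)), mk("g2", c(5L, 12L, 20L)),
                           mk("g3", c(5L, 12L, 20L)), mk("g4", c(7L, 33L)))
  inc <- intron_incidence(proj, genes = c("g1", "g2", "g3", "g4", "g5"))
  grp <- assign_structural_groups(inc, min_shared = 2L)
  expect_equal(grp$group[match(c("g1", "g2", "g3"), grp$gene_id)],
               rep("G1", 3))
  expect_equal(grp$group[grp$gene_id == "g4"], "G2")
  expect_equal(grp$group[grp$gene_id == "g5"], "intronless")

  # all genes intronless
  inc0 <- intron_incidence(proj[0, ], genes = c("a", "b"))
  grp0 <- assign_structural_groups(inc0)
  expect_equal(unique(grp0$group), "intronless")

  expect_error(assign_structural_groups(inc, min_shared = 0L),
               class = "setstruct_precondition_error")
})

test_that("incidence matrix renders phases and absences", {
  proj <- tibble::tibble(gene_id = c("a", "b"), intron_index = 1L,
                         cds_offset = c(7L, 7L), phase = c(1L, 1L),
                         in_region = TRUE, alignment_column = c(7L, 7L))
  inc <- intron_incidence(proj, genes = c("a", "b", "c"))
  m <- incidence_matrix(inc)
  expect_equal(dim(m), c(3L, 1L))
  expect_equal(unname(m[, "7"]), c("1", "1", "."))
})
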