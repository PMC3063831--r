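small_config <- function(seed = 1L, rates = list(), forced = NULL,
                         tree = "((a:0.02,b:0.02)ab:0.01,(c:0.02,d:0.02)cd:0.01,e:0.03)root;") {
  family_config(seed = seed, guide_tree = tree,
                ancestral_exon_lengths = c(60L, 45L, 48L),
                intron_length_range = c(20L, 40L),
                rates = rates, forced_events = forced)
}

test_that("config validation rejects inconsistent ancestral settings", {
  expect_error(family_config(guide_tree = "(a:1,b:1,c:1);",
                             cds_length = 90L,
                             ancestral_intron_positions = c(30L, 95L)),
               class = "setstruct_config_error")
  expect_error(family_config(guide_tree = "(a:1,b:1,c:1);",
                             ancestral_exon_lengths = c(10L, 10L)),
               class = "setstruct_config_error")  # 20 not divisible by 3
  expect_error(small_config(rates = list(intron_loss = -1)),
               class = "setstruct_config_error")
  # equivalent specification through cds_length + positions
  cfg <- family_config(guide_tree = "(a:1,b:1,c:1);", cds_length = 153L,
                       ancestral_intron_positions = c(60L, 105L),
                       intron_length_range = c(20L, 40L))
  expect_equal(cfg$ancestral_exon_lengths, c(60L, 45L, 48L))
})

test_that("the same seed reproduces the family byte for byte", {
  s1 <- simulate_family(small_config(seed = 7))
  s2 <- simulate_family(small_config(seed = 7))
  expect_identical(s1$genomic, s2$genomic)
  expect_identical(s1$mrna, s2$mrna)
  expect_identical(s1$truth$structures, s2$truth$structures)
  s3 <- simulate_family(small_config(seed = 8))
  expect_false(identical(s1$genomic$residues, s3$genomic$residues))
})

test_that("zero rates and zero-length branches reproduce the ancestor", {
  cfg <- small_config(
    tree = "((a:0,b:0)ab:0,(c:0,d:0)cd:0,e:0)root;")
  sim <- simulate_family(cfg)
  expect_equal(length(unique(sim$genomic$residues)), 1L)
  expect_equal(length(unique(sim$mrna$residues)), 1L)
  # the pipeline recovers identical structures for every gene
  structures <- infer_structures(sim$genomic, sim$mrna)
  for (s in structures) {
    tr <- sim$truth$structures[sim$truth$structures$gene_id == s$gene_id, ]
    expect_equal(s$introns$cds_offset, tr$cds_offset)
    expect_equal(s$introns$genomic_start, tr$genomic_start)
  }
})

test_that("splicing soundness: truth introns reproduce mRNA and protein", {
  sim <- simulate_family(small_config(seed = 3,
                                      rates = list(intron_gain = 0.5)))
  gc <- Biostrings::GENETIC_CODE
  for (k in seq_len(nrow(sim$genomic))) {
    gid <- sim$genomic$id[k]
    g <- sim$genomic$residues[k]
    tr <- sim$truth$structures[sim$truth$structures$gene_id == gid, ]
    tr <- tr[order(tr$genomic_start), ]
    keep <- rep(TRUE, nchar(g))
    for (r in seq_len(nrow(tr))) {
      keep[(tr$genomic_start[r] + 1L):tr$genomic_end[r]] <- FALSE
    }
    spliced <- paste(strsplit(g, "")[[1]][keep], collapse = "")
    expect_equal(spliced, sim$mrna$residues[sim$mrna$id == gid])
    # translation reproduces the emitted protein
    nt <- substr(spliced, 1, nchar(spliced) - 3L)
    codons <- substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
    expect_equal(paste(unname(gc[codons]), collapse = ""),
                 sim$protein$residues[sim$protein$id == gid])
    # every emitted intron is GT..AG
    expect_true(all(substring(g, tr$genomic_start + 1L,
                              tr$genomic_start + 2L) == "GT"))
    expect_true(all(substring(g, tr$genomic_end - 1L, tr$genomic_end) == "AG"))
  }
})

test_that("event log reconciles intron counts along each root path", {
  sim <- simulate_family(small_config(
    seed = 11, rates = list(intron_loss = 0.3, intron_gain = 0.6)))
  tree <- sim$truth$tree
  node_name <- c(tree$tip.label, tree$node.label)
  parent_of <- stats::setNames(tree$edge[, 1], node_name[tree$edge[, 2]])
  for (tip in tree$tip.label) {
    # walk from tip to root collecting branch labels
    labels <- character(); node <- match(tip, node_name)
    while (!is.null(parent_of[node_name[node]]) &&
           !is.na(parent_of[node_name[node]])) {
      labels <- c(labels, node_name[node])
      node <- unname(parent_of[node_name[node]])
    }
    ev <- sim$truth$events[sim$truth$events$branch %in% labels, ]
    n_anc <- length(sim$config$ancestral_exon_lengths) - 1L
    expected <- n_anc - sum(ev$event == "intron_loss") +
      sum(ev$event == "intron_gain")
    got <- sim$truth$counts$n_introns[sim$truth$counts$gene_id == tip]
    expect_equal(got, expected, info = tip)
  }
})

test_that("forced retroposition empties every descendant of the branch", {
  forced <- tibble::tibble(branch = "ab", event = "retroposition")
  sim <- simulate_family(small_config(seed = 2, forced = forced))
  counts <- sim$truth$counts
  expect_equal(counts$n_introns[counts$gene_id %in% c("a", "b")], c(0L, 0L))
  expect_true(all(counts$n_introns[counts$gene_id %in% c("c", "d", "e")] > 0L))
  # emitted sequences agree: genomic == mrna for retrogenes
  for (gid in c("a", "b")) {
    expect_equal(sim$genomic$residues[sim$genomic$id == gid],
                 sim$mrna$residues[sim$mrna$id == gid])
  }
})

test_that("the preset realizes conserved, remodeled and intronless clades", {
  sim <- scenario_suvh(seed = 101)
  counts <- sim$truth$counts
  v2 <- counts$n_introns[startsWith(counts$gene_id, "V2")]
  expect_true(all(v2 == 6L))
  expect_true(all(counts$n_introns[startsWith(counts$gene_id, "R")] == 0L))
  expect_true(all(counts$n_introns[startsWith(counts$gene_id, "W")] > 0L))
  # V-2-like genes share all positions (identical offsets and phases)
  v2tr <- sim$truth$structures[startsWith(sim$truth$structures$gene_id, "V2"), ]
  offs <- split(v2tr$cds_offset, v2tr$gene_id)
  expect_true(all(vapply(offs, identical, logical(1), y = offs[[1]])))

  # with retroposition disabled no intronless genes arise
  sim0 <- scenario_suvh(seed = 101, retroposition = FALSE)
  expect_true(all(sim0$truth$counts$n_introns > 0L))
})

test_that("low divergence leaves the guide-tree topology recoverable", {
  sim <- scenario_suvh(seed = 202, divergence_scale = 0.5)
  tr <- nj_tree(p_distance_matrix(sim$protein_aln))
  expect_true(same_topology(tr, sim$truth$tree))
})
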