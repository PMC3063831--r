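prot_aln <- function(...) {
  rows <- c(...)
  new_alignment(tibble::tibble(id = names(rows), residues = unname(rows)),
                "protein")
}

test_that("p-distance counts mismatches over pairwise-deleted columns", {
  a <- prot_aln(x = "ACDE", y = "ACDE")
  expect_equal(p_distance_matrix(a)$d["x", "y"], 0)

  b <- prot_aln(x = "ACDE", y = "ACDF")
  expect_equal(p_distance_matrix(b)$d["x", "y"], 0.25)

  # hand count: columns 1,2,4 comparable; one differs
  c3 <- prot_aln(x = "AC-DE", y = "AGFD-")
  pd <- p_distance_matrix(c3)
  expect_equal(pd$d["x", "y"], 1 / 3)
  expect_equal(pd$overlap["x", "y"], 3L)

  # X is deleted like a gap
  d4 <- prot_aln(x = "AXDE", y = "ACDE")
  expect_equal(p_distance_matrix(d4)$overlap["x", "y"], 3L)

  # Poisson correction
  expect_equal(p_distance_matrix(b, model = "poisson")$d["x", "y"],
               -log(1 - 0.25))

  expect_error(p_distance_matrix(prot_aln(x = "A-", y = "-A")),
               class = "setstruct_zero_overlap_error")
})

test_that("p-distance agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  set.seed(21)
  rows <- vapply(1:6, function(k) {
    paste(sample(c(strsplit("ACDEFGHIKL", "")[[1]]), 50, replace = TRUE),
          collapse = "")
  }, character(1))
  aln <- prot_aln(stats::setNames(rows, paste0("t", 1:6)))
  mine <- p_distance_matrix(aln)$d
  mat <- do.call(rbind, strsplit(rows, ""))
  rownames(mat) <- paste0("t", 1:6)
  pml <- phangorn::phyDat(mat, type = "AA")
  ref <- as.matrix(phangorn::dist.hamming(pml, exclude = "pairwise"))
  expect_equal(mine[rownames(ref), colnames(ref)], ref, tolerance = 1e-12)
})

test_that("three-taxon branch lengths follow the analytic formulas", {
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  lens <- stats::setNames(tr$edge.length,
                          tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(lens[c("a", "b", "c")]), c(2, 3, 7))
})

test_that("an additive 4-taxon matrix yields the AB|CD split exactly", {
  ids <- LETTERS[1:4]
  d <- matrix(0, 4, 4, dimnames = list(ids, ids))
  d["A", "B"] <- 3; d["A", "C"] <- 5; d["A", "D"] <- 6
  d["B", "C"] <- 6; d["B", "D"] <- 7; d["C", "D"] <- 7
  d <- d + t(d)
  tr <- nj_tree(d)
  expect_equal(split_keys(tr), "C|D")
  # path lengths reproduce the additive input exactly
  expect_equal(ape::cophenetic.phylo(tr)[ids, ids], d, tolerance = 1e-12)
})

test_that("all-equal distances resolve deterministically via the tie-break", {
  ids <- paste0("t", 1:5)
  d <- matrix(1, 5, 5, dimnames = list(ids, ids)); diag(d) <- 0
  t1 <- nj_tree(d)
  t2 <- nj_tree(d)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  # first join is the lexicographically smallest pair, so (t1, t2) is a cherry
  p1 <- t1$edge[t1$edge[, 2] == which(t1$tip.label == "t1"), 1]
  p2 <- t1$edge[t1$edge[, 2] == which(t1$tip.label == "t2"), 1]
  expect_equal(p1, p2)
  expect_error(nj_tree(d[1:2, 1:2]), class = "setstruct_precondition_error")
})

test_that("NJ recovers topology and path lengths on additive matrices", {
  set.seed(99)
  for (n in 4:8) {
    for (rep in 1:3) {
      case <- random_additive_matrix(n)
      tr <- nj_tree(case$d)
      expect_true(same_topology(tr, case$tree), info = paste("n =", n))
      ph <- ape::cophenetic.phylo(tr)
      expect_equal(ph[rownames(case$d), colnames(case$d)], case$d,
                   tolerance = 1e-9, info = paste("n =", n))
    }
  }
})

test_that("NJ topology matches exhaustive least-squares search (<= 6 taxa)", {
  skip_if_not_installed("phangorn")
  set.seed(5)
  for (n in c(5, 6)) {
    case <- random_additive_matrix(n)
    ids <- rownames(case$d)
    all_tr <- phangorn::allTrees(n, rooted = FALSE, tip.label = ids)
    fits <- vapply(all_tr, function(tp) {
      ft <- phangorn::nnls.tree(as.dist(case$d), tp)
      sum((ape::cophenetic.phylo(ft)[ids, ids] - case$d)^2)
    }, numeric(1))
    best <- all_tr[[which.min(fits)]]
    expect_lt(min(fits), 1e-12)
    expect_true(same_topology(nj_tree(case$d), best), info = paste("n =", n))
  }
})

test_that("NJ agrees with ape::nj on generic distance matrices", {
  set.seed(33)
  for (rep in 1:5) {
    rows <- vapply(1:7, function(k) {
      paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 80,
                   replace = TRUE), collapse = "")
    }, character(1))
    aln <- prot_aln(stats::setNames(rows, paste0("s", 1:7)))
    dm <- p_distance_matrix(aln)
    expect_true(same_topology(nj_tree(dm), ape::nj(as.dist(dm$d))))
  }
})

test_that("bootstrap supports are reproducible and detect clean signal", {
  set.seed(1)
  # A,B identical; C,D identical; the two blocks maximally distant
  rows <- c(A = strrep("AC", 20), B = strrep("AC", 20),
            C = strrep("KW", 20), D = strrep("KW", 20))
  aln <- prot_aln(rows)
  t1 <- bootstrap_support(aln, n_reps = 100, seed = 42)
  t2 <- bootstrap_support(aln, n_reps = 100, seed = 42)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  st <- support_table(t1)
  expect_equal(nrow(st), 1L)
  expect_equal(st$support, 100L)
  expect_equal(as.character(st$category), "strong")

  expect_error(bootstrap_support(aln, n_reps = 0),
               class = "setstruct_precondition_error")
})

test_that("duplicating signal columns never weakens the supported split", {
  set.seed(8)
  base <- c(A = "ACDEFGHIKL", B = "ACDEFGHIKV", C = "ACWWFGHIKL",
            D = "ACWWFGHIKV")
  # signal for AB|CD lives in columns 3-4; append extra copies of them
  supports <- vapply(0:3, function(extra) {
    rows <- vapply(base, function(r) {
      paste0(r, strrep(substr(r, 3, 4), extra))
    }, character(1))
    tr <- bootstrap_support(prot_aln(rows), n_reps = 200, seed = 7)
    st <- support_table(tr)
    if (nrow(st) == 0L) 0L else max(st$support)
  }, integer(1))
  expect_true(all(diff(supports) >= 0))
})

test_that("support categories implement the published ranges", {
  expect_equal(as.character(support_category(c(49, 50, 75, 76, 85, 86, 100))),
               c("unsupported", "weak", "weak", "moderate", "moderate",
                 "strong", "strong"))
  expect_equal(as.character(support_category(80)), "moderate")
  expect_error(support_category(101), class = "setstruct_precondition_error")
  expect_error(support_category(-1), class = "setstruct_precondition_error")
})

test_that("tidy() renders a pdist as a pair table", {
  aln <- prot_aln(x = "ACDE", y = "ACDF", z = "ACDE")
  td <- tidy(p_distance_matrix(aln))
  expect_equal(nrow(td), 3L)
  expect_equal(td$distance[td$id_a == "x" & td$id_b == "z"], 0)
  expect_true(all(td$overlap == 4L))
})
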