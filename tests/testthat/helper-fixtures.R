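# Fixtures and independent oracles built in code.

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

# ---- brute-force oracle for spliced decomposition ------------------------
# Enumerates every exon/intron decomposition of `g` with at most 2 introns
# (introns >= min_intron nt, flanked by >= 1 exonic base) whose exons
# concatenate to the length of `r`, scores each by
# (mismatches, non-GT-AG introns, intron count, intron coordinates left to
# right) and returns the minimal decomposition. Fully independent of the
# package's dynamic program.
oracle_decompose <- function(g, r, min_intron = 4L) {
  gc <- strsplit(g, "")[[1]]; rc <- strsplit(r, "")[[1]]
  m <- length(gc); n <- length(rc)
  total <- m - n
  canon <- function(s, e) {
    paste0(gc[s + 1L], gc[s + 2L]) == "GT" &&
      paste0(gc[e - 1L], gc[e]) == "AG"
  }
  mism <- function(spliced) {
    sc <- strsplit(spliced, "")[[1]]
    sum(sc != rc & sc != "N" & rc != "N")
  }
  best <- NULL
  consider <- function(introns) {
    segs <- character(); prev <- 0L
    for (iv in introns) {
      segs <- c(segs, substr(g, prev + 1L, iv[1]))
      prev <- iv[2]
    }
    segs <- c(segs, substr(g, prev + 1L, m))
    spliced <- paste(segs, collapse = "")
    nc <- sum(!vapply(introns, function(iv) canon(iv[1], iv[2]), logical(1)))
    key <- c(mism(spliced), nc, length(introns),
             unlist(introns, use.names = FALSE))
    if (is.null(best)) { best <<- list(key = key, introns = introns); return() }
    a <- best$key; b <- key
    len <- max(length(a), length(b))
    a <- c(a, rep(0, len - length(a))); b <- c(b, rep(0, len - length(b)))
    cmp <- b - a
    first <- which(cmp != 0)[1]
    if (!is.na(first) && cmp[first] < 0) best <<- list(key = key, introns = introns)
  }
  if (total == 0L) consider(list())
  if (total >= min_intron) {
    for (s in 1L:(m - total - 1L)) consider(list(c(s, s + total)))
  }
  if (total >= 2L * min_intron) {
    for (l1 in min_intron:(total - min_intron)) {
      l2 <- total - l1
      for (s1 in 1L:(m - total - 2L)) {
        e1 <- s1 + l1
        for (s2 in (e1 + 1L):(m - l2 - 1L)) {
          consider(list(c(s1, e1), c(s2, s2 + l2)))
        }
      }
    }
  }
  best
}

# random small spliced-gene case: returns list(genomic, mrna)
random_spliced_case <- function(n_introns, exon_core = 9L, intron_len = 6L,
                                canonical = TRUE) {
  base <- c("A", "C", "G", "T")
  mrna <- paste(sample(base, exon_core * (n_introns + 1L), replace = TRUE),
                collapse = "")
  cuts <- if (n_introns > 0L) {
    sort(sample(seq_len(nchar(mrna) - 1L), n_introns))
  } else integer()
  segs <- substring(mrna, c(0L, cuts) + 1L, c(cuts, nchar(mrna)))
  introns <- vapply(seq_len(n_introns), function(k) {
    mid <- paste(sample(base, intron_len - 4L, replace = TRUE), collapse = "")
    if (canonical) paste0("GT", mid, "AG")
    else paste0(paste(sample(base, 2L, replace = TRUE), collapse = ""), mid,
                paste(sample(base, 2L, replace = TRUE), collapse = ""))
  }, character(1))
  genomic <- segs[1]
  for (k in seq_len(n_introns)) genomic <- paste0(genomic, introns[k],
                                                  segs[k + 1L])
  list(genomic = genomic, mrna = mrna, cds_offsets = cuts)
}

# ---- additive distance matrices ------------------------------------------
# random unrooted tree with positive branch lengths; its cophenetic matrix
# is additive by construction
random_additive_matrix <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(k) stats::runif(k, 0.5, 3))
  tr$tip.label <- sort(tr$tip.label)[order(order(tr$tip.label))]  # keep labels
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# canonical bipartition keys of a phylo (non-trivial splits only)
split_keys <- function(tree) {
  pp <- ape::prop.part(tree)
  labels <- attr(pp, "labels")
  smallest <- sort(labels)[1]
  n <- length(labels)
  keys <- vapply(pp, function(part) {
    set <- labels[part]
    if (length(set) <= 1L || length(set) >= n - 1L) return(NA_character_)
    if (smallest %in% set) set <- setdiff(labels, set)
    paste(sort(set), collapse = "|")
  }, character(1))
  sort(keys[!is.na(keys)])
}

same_topology <- function(t1, t2) identical(split_keys(t1), split_keys(t2))

# expand per-group phase counts into a per-intron tibble (genes with no
# introns keep one NA-phase row so they count as genes)
phase_rows <- function(group, n_genes, n0, n1, n2) {
  ids <- sprintf("%s_g%d", group, seq_len(n_genes))
  phases <- c(rep(0L, n0), rep(1L, n1), rep(2L, n2))
  tbl <- tibble::tibble(
    gene_id = if (length(phases) > 0L) ids[1L + (seq_along(phases) %% n_genes)]
    else character(),
    phase = phases)
  empty <- setdiff(ids, tbl$gene_id)
  dplyr::bind_rows(tbl, tibble::tibble(gene_id = empty,
                                       phase = NA_integer_))
}
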