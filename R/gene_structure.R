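# Exon/intron structure inference by spliced alignment of a CDS (mRNA)
# against its genomic region.
#
# The genomic sequence is decomposed into an alternating exon/intron chain
# that starts and ends with an exon and reproduces the mRNA when introns
# are removed. Decompositions are scored lexicographically:
#   (1) fewest exonic substitutions (mismatches),
#   (2) fewest non-GT-AG introns,
#   (3) fewest introns,
#   (4) leftmost intron placement (intron start/end coordinates compared
#       left to right).
# The dynamic program below encodes (1)-(3) as a weighted sum with
# dominating weights; (4) is realized by a greedy forward walk over the
# suffix-cost tables that opens and closes introns as early as possible
# among cost-optimal continuations.

.W_MM <- 1e9   # one exonic mismatch
.W_NC <- 1e5   # one non-canonical (non-GT-AG) intron
.W_IN <- 1     # one intron
.MAX_GENOMIC <- 20000L

# backward DP tables. g, r: character vectors. Returns list(D_e, D_f)
# where D_x[i+1, j+1] is the optimal cost of finishing the alignment given
# i mRNA and j genomic characters are consumed; state "e" must consume an
# exonic base next (start of the gene, or just after an intron), state "f"
# may extend the exon or open an intron.
.spliced_dp <- function(g, r, min_intron, require_gt_ag) {
  m <- length(g); n <- length(r)
  D_e <- matrix(Inf, n + 1L, m + 1L)
  D_f <- matrix(Inf, n + 1L, m + 1L)
  D_f[n + 1L, m + 1L] <- 0

  # acceptor validity per landing index k = j' + 1 (intron ends at genomic
  # position j', 1-based bases j'-1, j' must read "AG")
  acc <- c(FALSE, FALSE, g[seq_len(m - 1L)] == "A" & g[2:m] == "G")
  # donor validity per open index k = j + 1 (intron starts at base j+1)
  don <- c(g[seq_len(m - 1L)] == "G" & g[2:m] == "T", FALSE, FALSE)[1:(m + 1L)]

  land <- seq_len(m + 1L) + min_intron   # earliest landing index per open index
  landable <- land <= m + 1L
  land_cl <- pmin(land, m + 1L)          # clamped for safe indexing

  for (i in seq(n - 1L, 0L)) {
    # D_e row i: consume exon base r[i+1] against g[j+1]
    mm <- (r[i + 1L] != g) & (r[i + 1L] != "N") & (g != "N")
    D_e[i + 1L, ] <- c(mm * .W_MM + D_f[i + 2L, 2:(m + 1L)], Inf)

    # intron open from (i, j): land on D_e[i+1, j'+1] with j' >= j+min_intron
    e_row <- D_e[i + 1L, ]
    val_any <- e_row + .W_IN
    val_ag <- ifelse(acc, val_any, Inf)
    S_any <- rev(cummin(rev(val_any)))
    S_ag <- rev(cummin(rev(val_ag)))
    if (require_gt_ag) {
      open <- ifelse(don & landable, S_ag[land_cl], Inf)
    } else {
      open <- ifelse(landable,
                     ifelse(don,
                            pmin(S_ag[land_cl], S_any[land_cl] + .W_NC),
                            S_any[land_cl] + .W_NC),
                     Inf)
    }
    D_f[i + 1L, ] <- pmin(D_e[i + 1L, ], open)
  }
  list(D_e = D_e, D_f = D_f, acc = acc)
}

# greedy forward walk: leftmost intron placement among cost-optimal paths
.spliced_trace <- function(g, r, dp, min_intron, require_gt_ag) {
  m <- length(g); n <- length(r)
  D_e <- dp$D_e; D_f <- dp$D_f; acc <- dp$acc
  i <- 0L; j <- 0L; mode <- "e"
  exon_start_g <- 0L; exon_start_c <- 0L
  exons <- list(); introns <- list()
  repeat {
    if (mode == "e") {
      i <- i + 1L; j <- j + 1L
      mode <- "f"
    } else {
      if (i == n && j == m) break
      target <- D_f[i + 1L, j + 1L]
      took_intron <- FALSE
      if (j + min_intron <= m) {
        jp <- (j + min_intron):m     # candidate intron ends
        dg <- j + 2L <= m && g[j + 1L] == "G" && g[j + 2L] == "T"
        canon <- dg & acc[jp + 1L]
        cost <- .W_IN + .W_NC * (!canon) + D_e[i + 1L, jp + 1L]
        if (require_gt_ag) cost[!canon] <- Inf
        hit <- which(cost == target)
        if (length(hit) > 0L) {
          jpr <- jp[hit[1]]
          exons[[length(exons) + 1L]] <-
            c(exon_start_g, j, exon_start_c, i)
          introns[[length(introns) + 1L]] <- c(j, jpr, i)
          j <- jpr
          exon_start_g <- jpr; exon_start_c <- i
          mode <- "e"
          took_intron <- TRUE
        }
      }
      if (!took_intron) mode <- "e"
    }
  }
  exons[[length(exons) + 1L]] <- c(exon_start_g, m, exon_start_c, n)
  list(exons = exons, introns = introns)
}

#' Infer exon/intron structure from a genomic/mRNA sequence pair
#'
#' Decomposes a genomic sequence into exons and introns such that removing
#' the introns reproduces the mRNA (the CDS including the stop codon) with
#' at most `max_mismatches` substitutions. Among valid decompositions the
#' canonical one is selected by minimizing, in order: mismatches,
#' non-GT-AG introns, intron count, and finally preferring leftmost intron
#' placement. Coordinates are 0-based half-open throughout.
#'
#' Inputs are assumed sense-strand; UTRs are not modeled. Sequences above
#' 20 kb are rejected (desk-scale tool).
#'
#' @param genomic,mrna DNA sequences: either plain strings or one-row
#'   tibbles as returned by [read_fasta()].
#' @param max_mismatches Maximum exonic substitutions tolerated (default 0).
#' @param min_intron Minimum intron length in nucleotides (default 4,
#'   must be >= 2 so donor and acceptor dinucleotides exist).
#' @param require_gt_ag If `TRUE`, only GT-AG introns are allowed; if
#'   `FALSE` (default) non-canonical introns are accepted with a warning.
#' @param gene_id Optional gene id; defaults to the mRNA record id.
#' @return A `gene_structure` object: a list with `gene_id`,
#'   `mrna_length`, `n_mismatches`, an `exons` tibble
#'   (`genomic_start`, `genomic_end`, `cds_start`, `cds_end`) and an
#'   `introns` tibble (`index`, `cds_offset`, `phase`, `genomic_start`,
#'   `genomic_end`, `donor`, `acceptor`, `canonical`), plus the input
#'   sequences.
#' @export
infer_structure <- function(genomic, mrna, max_mismatches = 0L,
                            min_intron = 4L, require_gt_ag = FALSE,
                            gene_id = NULL) {
  gs <- .as_seq(genomic, "genomic")
  rs <- .as_seq(mrna, "mrna")
  if (is.null(gene_id)) gene_id <- rs$id
  g <- .chars(gs$residues); r <- .chars(rs$residues)
  .check_residues(c(gs$id, rs$id), c(gs$residues, rs$residues), "dna")
  if (length(r) > length(g)) {
    abort(sprintf("mRNA longer than genomic sequence for '%s' (%d > %d)",
                  gene_id, length(r), length(g)),
          class = "setstruct_precondition_error")
  }
  if (length(r) == 0L) abort("empty mRNA", class = "setstruct_precondition_error")
  if (length(g) > .MAX_GENOMIC) {
    abort(sprintf("genomic sequence longer than %d nt; out of scope",
                  .MAX_GENOMIC), class = "setstruct_precondition_error")
  }
  if (min_intron < 2L) {
    abort("min_intron must be >= 2", class = "setstruct_precondition_error")
  }

  dp <- .spliced_dp(g, r, min_intron, require_gt_ag)
  best <- dp$D_e[1L, 1L]
  n_mm <- if (is.finite(best)) best %/% .W_MM else Inf
  if (!is.finite(best) || n_mm > max_mismatches) {
    abort(sprintf(
      "no exon/intron decomposition of '%s' within %d mismatch(es)%s",
      gene_id, max_mismatches,
      if (require_gt_ag) " under the GT-AG requirement" else ""),
      class = "setstruct_no_alignment_error")
  }
  tr <- .spliced_trace(g, r, dp, min_intron, require_gt_ag)

  ex <- do.call(rbind, tr$exons)
  exons <- tibble(genomic_start = as.integer(ex[, 1]),
                  genomic_end = as.integer(ex[, 2]),
                  cds_start = as.integer(ex[, 3]),
                  cds_end = as.integer(ex[, 4]))
  if (length(tr$introns) > 0L) {
    iv <- do.call(rbind, tr$introns)
    donor <- paste0(g[iv[, 1] + 1L], g[iv[, 1] + 2L])
    acceptor <- paste0(g[iv[, 2] - 1L], g[iv[, 2]])
    introns <- tibble(index = seq_len(nrow(iv)),
                      cds_offset = as.integer(iv[, 3]),
                      phase = as.integer(iv[, 3]) %% 3L,
                      genomic_start = as.integer(iv[, 1]),
                      genomic_end = as.integer(iv[, 2]),
                      donor = donor, acceptor = acceptor,
                      canonical = donor == "GT" & acceptor == "AG")
    if (!require_gt_ag && any(!introns$canonical)) {
      warn(sprintf("gene '%s': %d non-GT-AG intron(s) accepted",
                   gene_id, sum(!introns$canonical)))
    }
  } else {
    introns <- tibble(index = integer(), cds_offset = integer(),
                      phase = integer(), genomic_start = integer(),
                      genomic_end = integer(), donor = character(),
                      acceptor = character(), canonical = logical())
  }
  out <- structure(list(gene_id = gene_id,
                        mrna = rs$residues,
                        genomic = gs$residues,
                        mrna_length = length(r),
                        n_mismatches = as.integer(n_mm),
                        exons = exons, introns = introns,
                        params = list(max_mismatches = max_mismatches,
                                      min_intron = min_intron,
                                      require_gt_ag = require_gt_ag)),
                   class = "gene_structure")
  .validate_structure(out)
  out
}

.validate_structure <- function(s) {
  stopifnot(nrow(s$introns) == nrow(s$exons) - 1L,
            sum(s$exons$genomic_end - s$exons$genomic_start) == s$mrna_length,
            all(s$exons$genomic_end - s$exons$genomic_start ==
                  s$exons$cds_end - s$exons$cds_start),
            all(s$exons$genomic_end - s$exons$genomic_start > 0L),
            all(s$introns$phase == s$introns$cds_offset %% 3L))
  spliced <- spliced_sequence(s)
  n_diff <- sum(.chars(spliced) != .chars(s$mrna) &
                  .chars(spliced) != "N" & .chars(s$mrna) != "N")
  stopifnot(n_diff == s$n_mismatches)
  invisible(s)
}

#' Reconstruct the mRNA implied by a gene structure
#'
#' Concatenates the exon substrings of the genomic sequence.
#'
#' @param structure A `gene_structure`.
#' @return A single string.
#' @export
spliced_sequence <- function(structure) {
  stopifnot(inherits(structure, "gene_structure"))
  paste(substring(structure$genomic,
                  structure$exons$genomic_start + 1L,
                  structure$exons$genomic_end),
        collapse = "")
}

#' Infer structures for a set of paired sequences
#'
#' Pairs genomic and mRNA records by id and infers each gene's structure.
#'
#' @param genomic_tbl,mrna_tbl Tibbles from [read_fasta()] with matching
#'   ids.
#' @inheritParams infer_structure
#' @return A named list of `gene_structure` objects, in mRNA input order.
#' @export
infer_structures <- function(genomic_tbl, mrna_tbl, max_mismatches = 0L,
                             min_intron = 4L, require_gt_ag = FALSE) {
  missing_g <- setdiff(mrna_tbl$id, genomic_tbl$id)
  if (length(missing_g) > 0L) {
    abort(paste0("no genomic sequence for: ",
                 paste(missing_g, collapse = ", ")))
  }
  out <- lapply(mrna_tbl$id, function(id) {
    infer_structure(genomic_tbl[genomic_tbl$id == id, ],
                    mrna_tbl[mrna_tbl$id == id, ],
                    max_mismatches = max_mismatches,
                    min_intron = min_intron,
                    require_gt_ag = require_gt_ag, gene_id = id)
  })
  stats::setNames(out, mrna_tbl$id)
}

#' Intron phase from a CDS offset
#'
#' The phase of an intron is the number of coding nucleotides 5' of it,
#' modulo 3: phase 0 lies between codons, phase 1 after the first base of
#' a codon, phase 2 after the second.
#'
#' @param cds_offset Positive integer vector of coding-nucleotide offsets.
#' @return Integer vector of phases in \{0, 1, 2\}.
#' @export
compute_phase <- function(cds_offset) {
  if (length(cds_offset) == 0L) return(integer())
  if (any(is.na(cds_offset)) || any(cds_offset <= 0) ||
      any(cds_offset != as.integer(cds_offset))) {
    abort("cds_offset must be a positive integer",
          class = "setstruct_precondition_error")
  }
  as.integer(cds_offset) %% 3L
}

#' Splice-signal report for one gene
#'
#' @param structure A `gene_structure`.
#' @return A tibble with one row per intron: `intron` (index), `donor`,
#'   `acceptor`, `canonical` (`TRUE` iff GT-AG).
#' @export
splice_report <- function(structure) {
  stopifnot(inherits(structure, "gene_structure"))
  tibble(intron = structure$introns$index,
         donor = structure$introns$donor,
         acceptor = structure$introns$acceptor,
         canonical = structure$introns$canonical)
}

#' @export
print.gene_structure <- function(x, ...) {
  cat(sprintf("<gene_structure> %s: %d exon(s), %d intron(s), mRNA %d nt\n",
              x$gene_id, nrow(x$exons), nrow(x$introns), x$mrna_length))
  if (nrow(x$introns) > 0L) print(x$introns)
  invisible(x)
}

#' Tidy a gene structure into a feature table
#'
#' @param x A `gene_structure`.
#' @param display If `TRUE`, genomic coordinates are converted to 1-based
#'   inclusive for reporting; the default keeps the internal 0-based
#'   half-open convention.
#' @param ... Unused.
#' @return A tibble with one row per exon and intron: `gene_id`,
#'   `feature`, `index`, `genomic_start`, `genomic_end`, `cds_offset`,
#'   `phase`, `donor`, `acceptor`.
#' @export
tidy.gene_structure <- function(x, display = FALSE, ...) {
  ex <- tibble(gene_id = x$gene_id, feature = "exon",
               index = seq_len(nrow(x$exons)),
               genomic_start = x$exons$genomic_start,
               genomic_end = x$exons$genomic_end,
               cds_offset = NA_integer_, phase = NA_integer_,
               donor = NA_character_, acceptor = NA_character_)
  iv <- tibble(gene_id = x$gene_id, feature = "intron",
               index = x$introns$index,
               genomic_start = x$introns$genomic_start,
               genomic_end = x$introns$genomic_end,
               cds_offset = x$introns$cds_offset,
               phase = x$introns$phase,
               donor = x$introns$donor, acceptor = x$introns$acceptor)
  out <- dplyr::arrange(dplyr::bind_rows(ex, iv), .data$genomic_start,
                        .data$feature)
  if (display) {
    out$genomic_start <- out$genomic_start + 1L
  }
  out
}

#' One-row summary of a gene structure
#'
#' @param x A `gene_structure`.
#' @param ... Unused.
#' @return A tibble with `gene_id`, `n_exons`, `n_introns`,
#'   `mrna_length`, `n_canonical`, `n_mismatches`.
#' @export
glance.gene_structure <- function(x, ...) {
  tibble(gene_id = x$gene_id, n_exons = nrow(x$exons),
         n_introns = nrow(x$introns), mrna_length = x$mrna_length,
         n_canonical = sum(x$introns$canonical),
         n_mismatches = x$n_mismatches)
}

#' Feature table for a list of gene structures
#'
#' @param structures A list of `gene_structure` objects.
#' @param display Passed to [tidy.gene_structure()].
#' @return A tibble of all features across genes.
#' @export
structure_table <- function(structures, display = FALSE) {
  dplyr::bind_rows(lapply(structures, tidy, display = display))
}
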