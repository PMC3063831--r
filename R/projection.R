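# Codon-alignment construction from a protein alignment, projection of
# intron positions into alignment coordinates, and shared-position
# detection under the strict identity rule (positions differing by even
# one base pair are non-identical).

.translate_codons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"   # codons containing N/ambiguity
  aa
}

#' Back-translate a protein alignment into a codon alignment
#'
#' Each aligned residue expands to its source codon, each gap `-` to
#' `---`; a trailing stop codon on the CDS is trimmed. Every row is
#' verified: the CDS must be exactly 3x the ungapped residue count
#' (optionally plus a stop codon), and each codon must translate to the
#' aligned residue (`X` on either side matches anything).
#'
#' @param protein_aln A protein alignment (`setstruct_aln`).
#' @param cds A tibble of DNA records from [read_fasta()] covering every
#'   alignment row id.
#' @return A codon alignment: a `setstruct_aln` of DNA rows with class
#'   `codon_aln` and the protein alignment attached as attribute
#'   `protein_aln`.
#' @export
backtranslate_alignment <- function(protein_aln, cds) {
  stopifnot(inherits(protein_aln, "setstruct_aln"))
  missing_ids <- setdiff(protein_aln$id, cds$id)
  if (length(missing_ids) > 0L) {
    abort(paste0("no CDS for alignment row(s): ",
                 paste(missing_ids, collapse = ", ")))
  }
  stops <- c("TAA", "TAG", "TGA")
  rows <- vapply(seq_len(nrow(protein_aln)), function(k) {
    id <- protein_aln$id[[k]]
    row <- .chars(protein_aln$residues[[k]])
    aa <- row[row != "-"]
    nt <- cds$residues[cds$id == id][[1]]
    if (nchar(nt) == 3L * length(aa) + 3L &&
        substr(nt, nchar(nt) - 2L, nchar(nt)) %in% stops) {
      nt <- substr(nt, 1L, nchar(nt) - 3L)
    }
    if (nchar(nt) != 3L * length(aa)) {
      abort(sprintf(
        "CDS/alignment length mismatch for '%s': expected %d nt (or +stop), got %d",
        id, 3L * length(aa), nchar(cds$residues[cds$id == id][[1]])),
        class = "setstruct_length_error")
    }
    codons <- substring(nt, seq(1L, nchar(nt), 3L), seq(3L, nchar(nt), 3L))
    trans <- .translate_codons(codons)
    bad <- which(trans != aa & trans != "X" & aa != "X")
    if (length(bad) > 0L) {
      col <- which(row != "-")[bad[1]]
      abort(sprintf(
        "codon %s of '%s' translates to %s but residue %s is aligned at column %d",
        codons[bad[1]], id, trans[bad[1]], aa[bad[1]], col),
        class = "setstruct_translation_error")
    }
    out <- character(length(row))
    out[row == "-"] <- "---"
    out[row != "-"] <- codons
    paste(out, collapse = "")
  }, character(1))
  aln <- new_alignment(tibble(id = protein_aln$id, residues = rows), "dna")
  attr(aln, "protein_aln") <- protein_aln
  class(aln) <- c("codon_aln", class(aln))
  aln
}

#' Project a gene's intron positions onto a codon alignment
#'
#' The gene's row in the codon alignment may cover a sub-interval of its
#' CDS (e.g. conserved domains only); the offset of that region within the
#' CDS is located by exact substring match. Each intron whose CDS offset
#' falls inside the aligned region is assigned the 1-based nucleotide
#' alignment column of the last exonic base before the intron; introns
#' outside the region are retained with `in_region = FALSE` rather than
#' dropped.
#'
#' @param structure A `gene_structure`.
#' @param codon_alignment A `codon_aln` from [backtranslate_alignment()].
#' @return A tibble with columns `gene_id`, `intron_index`, `cds_offset`,
#'   `phase`, `in_region`, `alignment_column` (NA when out of region).
#' @export
project_introns <- function(structure, codon_alignment) {
  stopifnot(inherits(structure, "gene_structure"),
            inherits(codon_alignment, "setstruct_aln"))
  id <- structure$gene_id
  if (!id %in% codon_alignment$id) {
    abort(sprintf("gene '%s' absent from the codon alignment", id))
  }
  row <- codon_alignment$residues[codon_alignment$id == id][[1]]
  row_chars <- .chars(row)
  ungapped <- paste(row_chars[row_chars != "-"], collapse = "")
  hits <- gregexpr(ungapped, structure$mrna, fixed = TRUE)[[1]]
  if (identical(as.integer(hits), -1L)) {
    abort(sprintf(
      "aligned region of '%s' is not a substring of its mRNA", id),
      class = "setstruct_consistency_error")
  }
  if (length(hits) > 1L) {
    abort(sprintf(
      "aligned region of '%s' matches the mRNA at %d positions; ambiguous",
      id, length(hits)), class = "setstruct_consistency_error")
  }
  region_start <- as.integer(hits[1]) - 1L            # 0-based nt offset
  region_len <- nchar(ungapped)
  nongap_pos <- which(row_chars != "-")               # column of k-th exonic base

  iv <- structure$introns
  local <- iv$cds_offset - region_start
  in_region <- local >= 1L & local <= region_len
  col <- rep(NA_integer_, nrow(iv))
  col[in_region] <- nongap_pos[local[in_region]]
  out <- tibble(gene_id = id, intron_index = iv$index,
                cds_offset = iv$cds_offset, phase = iv$phase,
                in_region = in_region, alignment_column = col)
  # internal consistency: the projected column is non-gap and its non-gap
  # prefix count reproduces the local phase
  if (any(in_region)) {
    chk <- vapply(which(in_region), function(k) {
      sum(row_chars[seq_len(col[k])] != "-") %% 3L == local[k] %% 3L
    }, logical(1))
    if (!all(chk)) {
      abort(sprintf("internal consistency failure projecting '%s'", id),
            class = "setstruct_consistency_error")
    }
  }
  out
}

#' Build an intron incidence object
#'
#' Collects projected introns (in-region only) across genes into a
#' gene-by-alignment-column occupancy structure, the basis of shared-
#' position (synapomorphy) detection. Genes listed in `genes` but carrying
#' no in-region intron are retained as all-absent (intronless) rows.
#'
#' @param projected A tibble of projected introns (rows of
#'   [project_introns()] bound together).
#' @param genes Character vector of all gene ids to represent; defaults to
#'   the ids present in `projected`.
#' @return An `intron_incidence` tibble (`gene_id`, `alignment_column`,
#'   `phase`) with attribute `genes`.
#' @export
intron_incidence <- function(projected, genes = NULL) {
  if (is.null(genes)) genes <- unique(projected$gene_id)
  occ <- dplyr::filter(projected, .data$in_region)
  occ <- dplyr::select(occ, "gene_id", "alignment_column", "phase")
  occ <- dplyr::arrange(occ, .data$gene_id, .data$alignment_column)
  structure(occ, genes = genes,
            class = c("intron_incidence", class(occ)))
}

#' Gene-by-column incidence matrix
#'
#' @param incidence An `intron_incidence` object.
#' @return A character matrix (genes x sorted columns) holding the phase
#'   digit where an intron is present and `"."` where absent.
#' @export
incidence_matrix <- function(incidence) {
  stopifnot(inherits(incidence, "intron_incidence"))
  genes <- attr(incidence, "genes")
  cols <- sort(unique(incidence$alignment_column))
  m <- matrix(".", length(genes), length(cols),
              dimnames = list(genes, as.character(cols)))
  if (nrow(incidence) > 0L) {
    m[cbind(match(incidence$gene_id, genes),
            match(incidence$alignment_column, cols))] <-
      as.character(incidence$phase)
  }
  m
}

#' Shared intron positions under the strict identity rule
#'
#' Two introns share a position only when their alignment columns are
#' exactly equal; positions apart by even one base pair are non-identical.
#' Columns carried by a single gene are excluded.
#'
#' @param incidence An `intron_incidence` object.
#' @return A tibble with one row per shared column: `alignment_column`,
#'   `n_genes`, `gene_ids` (list), `phases` (list), `phase_agreement`.
#' @export
shared_intron_positions <- function(incidence) {
  stopifnot(inherits(incidence, "intron_incidence"))
  if (nrow(incidence) == 0L) {
    return(tibble(alignment_column = integer(), n_genes = integer(),
                  gene_ids = list(), phases = list(),
                  phase_agreement = logical()))
  }
  out <- dplyr::summarise(
    dplyr::group_by(as_tibble(incidence), .data$alignment_column),
    n_genes = dplyr::n_distinct(.data$gene_id),
    gene_ids = list(sort(unique(.data$gene_id))),
    phases = list(.data$phase),
    phase_agreement = dplyr::n_distinct(.data$phase) == 1L,
    .groups = "drop")
  dplyr::arrange(dplyr::filter(out, .data$n_genes >= 2L),
                 .data$alignment_column)
}

#' Report near-identical intron positions (candidate intron sliding)
#'
#' Pairs of distinct alignment columns within `window` nucleotides of each
#' other are reported for inspection but never merged.
#'
#' @param incidence An `intron_incidence` object.
#' @param window Maximum column distance to report (default 6 nt).
#' @return A tibble: `column_a`, `column_b`, `distance`, `genes_a`,
#'   `genes_b` (list columns).
#' @export
sliding_report <- function(incidence, window = 6L) {
  stopifnot(inherits(incidence, "intron_incidence"), window >= 1L)
  cols <- sort(unique(incidence$alignment_column))
  pairs <- list()
  for (a in seq_along(cols)) {
    for (b in seq_along(cols)) {
      if (b <= a) next
      d <- cols[b] - cols[a]
      if (d <= window) {
        pairs[[length(pairs) + 1L]] <- tibble(
          column_a = cols[a], column_b = cols[b], distance = d,
          genes_a = list(sort(incidence$gene_id[
            incidence$alignment_column == cols[a]])),
          genes_b = list(sort(incidence$gene_id[
            incidence$alignment_column == cols[b]])))
      }
    }
  }
  if (length(pairs) == 0L) {
    return(tibble(column_a = integer(), column_b = integer(),
                  distance = integer(), genes_a = list(), genes_b = list()))
  }
  dplyr::bind_rows(pairs)
}

#' Partition genes into structural groups by shared intron positions
#'
#' Single-linkage grouping: two genes are linked when they share at least
#' `min_shared` identical intron positions (exact alignment-column
#' equality). Genes with no in-region introns form the distinguished
#' `"intronless"` class. Groups are numbered `G1`, `G2`, ... in order of
#' their lexicographically smallest member id.
#'
#' @param incidence An `intron_incidence` object.
#' @param min_shared Minimum number of shared positions to link two genes
#'   (default 2; set to 1 for the most permissive grouping).
#' @return A tibble with columns `gene_id` and `group`.
#' @export
assign_structural_groups <- function(incidence, min_shared = 2L) {
  stopifnot(inherits(incidence, "intron_incidence"))
  if (min_shared < 1L) {
    abort("min_shared must be >= 1", class = "setstruct_precondition_error")
  }
  genes <- attr(incidence, "genes")
  with_introns <- sort(unique(incidence$gene_id))
  intronless <- setdiff(genes, with_introns)
  n <- length(with_introns)
  comp <- seq_len(n)
  if (n > 1L) {
    cols_by_gene <- lapply(with_introns, function(gid) {
      incidence$alignment_column[incidence$gene_id == gid]
    })
    find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
    for (a in seq_len(n - 1L)) {
      for (b in (a + 1L):n) {
        if (length(intersect(cols_by_gene[[a]], cols_by_gene[[b]])) >=
            min_shared) {
          ra <- find(a); rb <- find(b)
          if (ra != rb) comp[max(ra, rb)] <- min(ra, rb)
        }
      }
    }
    comp <- vapply(seq_len(n), find, integer(1))
  }
  members <- split(with_introns, comp)
  # order groups by smallest member id
  members <- members[order(vapply(members, min, character(1)))]
  rows <- list()
  for (k in seq_along(members)) {
    rows[[k]] <- tibble(gene_id = members[[k]], group = paste0("G", k))
  }
  if (length(intronless) > 0L) {
    rows[[length(rows) + 1L]] <- tibble(gene_id = sort(intronless),
                                        group = "intronless")
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) out <- tibble(gene_id = character(), group = character())
  dplyr::arrange(out, .data$group, .data$gene_id)
}
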