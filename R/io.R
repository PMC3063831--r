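#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

.DNA_CHARS <- c("A", "C", "G", "T", "N")
.PROT_CHARS <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

.alphabet_chars <- function(alphabet, gapped = FALSE) {
  chars <- switch(alphabet, dna = .DNA_CHARS, protein = .PROT_CHARS,
                  abort(paste0("unknown alphabet: ", alphabet)))
  if (gapped) chars <- c(chars, "-")
  chars
}

.check_residues <- function(ids, residues, alphabet, gapped = FALSE) {
  ok <- .alphabet_chars(alphabet, gapped)
  for (k in seq_along(residues)) {
    bad <- which(!strsplit(residues[[k]], "")[[1]] %in% ok)
    if (length(bad) > 0L) {
      abort(sprintf(
        "illegal %s residue '%s' in record '%s' at position %d",
        alphabet, substr(residues[[k]], bad[1], bad[1]), ids[[k]], bad[1]),
        class = "setstruct_format_error")
    }
  }
  invisible(TRUE)
}

.read_fasta_raw <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- as.character(ifelse(grepl("\\s", headers),
                              sub("^\\S+\\s+", "", headers), ""))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate sequence id(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "setstruct_format_error")
  }
  residues <- toupper(as.character(set))
  residues <- gsub(".", "-", residues, fixed = TRUE)
  tibble(id = unname(ids), description = unname(desc),
         residues = unname(residues))
}

#' Read unaligned sequences from a FASTA file
#'
#' Residues are uppercased on input and validated against the declared
#' alphabet (`dna` = A,C,G,T,N; `protein` = the 20 standard amino acids
#' plus X). Ids must be unique within a file.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"dna"` or `"protein"`.
#' @return A tibble with columns `id`, `description`, `residues`,
#'   `alphabet`, one row per record, input order preserved.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  tbl <- .read_fasta_raw(path)
  if (nrow(tbl) > 0L) {
    if (any(!nzchar(tbl$residues))) {
      abort(sprintf("empty sequence for record '%s'",
                    tbl$id[!nzchar(tbl$residues)][1]),
            class = "setstruct_format_error")
    }
    .check_residues(tbl$id, tbl$residues, alphabet, gapped = FALSE)
  }
  tbl$alphabet <- rep(alphabet, nrow(tbl))
  tbl
}

#' Read an aligned FASTA file
#'
#' All rows must have equal length; `.` gap characters are normalized to
#' `-`. Ungapping any row must yield a valid sequence over the declared
#' alphabet.
#'
#' @inheritParams read_fasta
#' @return An alignment object: a tibble with columns `id` and `residues`
#'   plus attributes `alphabet` and `n_sites` (class `setstruct_aln`).
#' @export
read_alignment <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  tbl <- .read_fasta_raw(path)
  new_alignment(tbl[, c("id", "residues")], alphabet)
}

#' Construct an alignment object from id/residue pairs
#'
#' @param tbl A data frame with columns `id` and `residues` (gapped rows).
#' @param alphabet `"dna"` or `"protein"`.
#' @return A `setstruct_aln` tibble.
#' @export
new_alignment <- function(tbl, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  tbl <- as_tibble(tbl)[, c("id", "residues")]
  tbl$residues <- gsub(".", "-", toupper(tbl$residues), fixed = TRUE)
  lens <- nchar(tbl$residues)
  if (nrow(tbl) > 0L && length(unique(lens)) != 1L) {
    abort(sprintf("ragged alignment: row lengths %s",
                  paste(unique(lens), collapse = ", ")),
          class = "setstruct_alignment_error")
  }
  if (anyDuplicated(tbl$id)) {
    abort("duplicate row ids in alignment", class = "setstruct_format_error")
  }
  if (nrow(tbl) > 0L) .check_residues(tbl$id, tbl$residues, alphabet, gapped = TRUE)
  structure(tbl,
            alphabet = alphabet,
            n_sites = if (nrow(tbl) > 0L) unname(lens[1]) else 0L,
            class = c("setstruct_aln", class(tbl)))
}

#' Number of columns in an alignment
#' @param aln A `setstruct_aln` object.
#' @return Integer column count.
#' @export
aln_length <- function(aln) {
  stopifnot(inherits(aln, "setstruct_aln"))
  as.integer(attr(aln, "n_sites"))
}

#' Write sequences to FASTA
#'
#' Lines are wrapped at 60 characters.
#'
#' @param seqs A tibble with columns `id`, `residues` and optionally
#'   `description` (e.g. from [read_fasta()] or an alignment).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  headers <- seqs$id
  if ("description" %in% names(seqs)) {
    headers <- ifelse(nzchar(seqs$description),
                      paste(seqs$id, seqs$description), seqs$id)
  }
  set <- Biostrings::BStringSet(stats::setNames(seqs$residues, headers))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Write a tree in Newick format
#'
#' Branch lengths are written with 6 significant digits; integer bootstrap
#' supports present as node labels are preserved.
#'
#' @param tree An `ape::phylo` tree with labeled leaves.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (any(is.na(tree$tip.label)) || any(!nzchar(tree$tip.label))) {
    abort("tree has unlabeled leaves", class = "setstruct_format_error")
  }
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}

#' Write a tabular report as TSV
#'
#' Tab-separated, header row, one record per line, columns in the order of
#' the input; list-columns are collapsed with commas.
#'
#' @param rows A data frame (possibly 0-row).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path) {
  rows <- as_tibble(rows)
  is_list <- vapply(rows, is.list, logical(1))
  for (col in names(rows)[is_list]) {
    rows[[col]] <- vapply(rows[[col]], function(x) paste(x, collapse = ","),
                          character(1))
  }
  readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}

# split a residue string into a character vector
.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# coerce a string / one-row read_fasta tibble into list(id, residues)
.as_seq <- function(x, default_id = "seq") {
  if (is.character(x) && length(x) == 1L) {
    return(list(id = default_id, residues = toupper(x)))
  }
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) abort("expected exactly one sequence record")
    return(list(id = x$id[[1]], residues = toupper(x$residues[[1]])))
  }
  abort("cannot interpret input as a sequence record")
}
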