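# Rule-based classification of ordered domain architectures of
# Su(var)3-9 class SET proteins into five types (A-E) and ten subtypes.
# Eligibility mirrors the family definition: a candidate must carry a SET
# domain plus a PreSET domain or its AWS subdomain; proteins lacking both
# are rejected. XXX tokens mark unannotated stretches and carry no
# classification signal.

#' Controlled vocabulary of domain names
#'
#' The domain names recognized by the architecture classifier; `XXX`
#' marks an unannotated stretch.
#' @format A character vector of 10 domain names.
#' @export
DOMAIN_VOCAB <- c("AT_hook", "SRA", "ZnF_C2H2", "WIYLD", "AWS", "TPR_1",
                  "PreSET", "SET", "PostSET", "XXX")

.MARKERS <- c("AT_hook", "SRA", "ZnF_C2H2", "WIYLD", "AWS", "TPR_1")

.parse_arch <- function(x) {
  if (length(x) == 1L && grepl("[,-]", x)) {
    x <- strsplit(x, "[,-]")[[1]]
  }
  trimws(x)
}

#' Classify one domain architecture
#'
#' Decision rules, applied in order on domain presence: SRA gives type A
#' (A1 with AT_hook, else A2 with PostSET, else A3); ZnF_C2H2 gives B1;
#' WIYLD gives C1 with PostSET, else C2; AWS without PreSET gives D1;
#' everything else is type E (E3 with TPR_1, E1 with PostSET, else E2).
#' Multiple copies of a domain collapse to presence; XXX is ignored.
#' A warning is issued when the decisive N-terminal marker domain occurs
#' C-terminal to SET.
#'
#' @param domains Character vector of ordered (N to C) domain names, or a
#'   single string with `,` or `-` separators.
#' @return A one-row tibble with columns `type` and `subtype`.
#' @export
classify_architecture <- function(domains) {
  domains <- .parse_arch(domains)
  unknown <- setdiff(domains, DOMAIN_VOCAB)
  if (length(unknown) > 0L) {
    abort(paste0("unknown domain name(s): ", paste(unknown, collapse = ", ")),
          class = "setstruct_format_error")
  }
  has <- function(d) d %in% domains
  if (!has("SET") || !(has("PreSET") || has("AWS"))) {
    abort(paste0("ineligible architecture [", paste(domains, collapse = "-"),
                 "]: requires SET plus PreSET or AWS"),
          class = "setstruct_rejected_architecture")
  }
  subtype <-
    if (has("SRA")) {
      if (has("AT_hook")) "A1" else if (has("PostSET")) "A2" else "A3"
    } else if (has("ZnF_C2H2")) {
      "B1"
    } else if (has("WIYLD")) {
      if (has("PostSET")) "C1" else "C2"
    } else if (has("AWS") && !has("PreSET")) {
      "D1"
    } else if (has("TPR_1")) {
      "E3"
    } else if (has("PostSET")) {
      "E1"
    } else {
      "E2"
    }
  type <- substr(subtype, 1L, 1L)
  marker <- switch(type, A = "SRA", B = "ZnF_C2H2", C = "WIYLD",
                   D = "AWS", E = if (subtype == "E3") "TPR_1" else NULL)
  if (!is.null(marker) && marker %in% domains) {
    if (match(marker, domains) > match("SET", domains)) {
      warn(sprintf("marker domain %s occurs C-terminal to SET", marker))
    }
  }
  tibble(type = type, subtype = subtype)
}

#' Classify a cohort of domain architectures
#'
#' @param arch_tbl A tibble with columns `protein_id` and `architecture`
#'   (a `,`- or `-`-separated domain string, N to C).
#' @return The input with `type` and `subtype` columns added; ineligible
#'   proteins (lacking SET, or lacking both PreSET and AWS) get `NA` in
#'   both plus `rejected = TRUE`, with a warning naming them.
#' @export
classify_architectures <- function(arch_tbl) {
  arch_tbl <- as_tibble(arch_tbl)
  stopifnot(all(c("protein_id", "architecture") %in% names(arch_tbl)))
  res <- lapply(arch_tbl$architecture, function(a) {
    tryCatch(cbind(classify_architecture(a), rejected = FALSE),
             setstruct_rejected_architecture = function(e) {
               tibble(type = NA_character_, subtype = NA_character_,
                      rejected = TRUE)
             })
  })
  out <- dplyr::bind_cols(arch_tbl, dplyr::bind_rows(res))
  if (any(out$rejected)) {
    warn(paste0("rejected ineligible architecture(s): ",
                paste(out$protein_id[out$rejected], collapse = ", ")))
  }
  out
}

.ALL_SUBTYPES <- c("A1", "A2", "A3", "B1", "C1", "C2", "D1", "E1", "E2", "E3")

#' Cross-tabulate architecture subtypes against groups
#'
#' @param classes A tibble with columns `protein_id` and `subtype` (e.g.
#'   from [classify_architectures()], rejected rows removed).
#' @param groups A tibble with columns matching ids to group labels
#'   (`gene_id` or `protein_id`, and `group`).
#' @return A tibble in long form: `subtype`, `group`, `n`, with all ten
#'   subtypes retained (zero cells included) for every observed group.
#' @export
type_by_group_table <- function(classes, groups) {
  classes <- as_tibble(classes)
  groups <- as_tibble(groups)
  id_col <- intersect(c("protein_id", "gene_id"), names(groups))[1]
  if (is.na(id_col)) abort("groups must have a protein_id or gene_id column")
  a <- sort(classes$protein_id)
  b <- sort(groups[[id_col]])
  if (!identical(a, b)) {
    abort(sprintf(
      "id mismatch: only in classes [%s]; only in groups [%s]",
      paste(setdiff(a, b), collapse = ", "),
      paste(setdiff(b, a), collapse = ", ")))
  }
  merged <- dplyr::left_join(classes,
                             stats::setNames(groups[, c(id_col, "group")],
                                             c("protein_id", "group")),
                             by = "protein_id")
  grid <- tidyr::expand_grid(subtype = .ALL_SUBTYPES,
                             group = sort(unique(groups$group)))
  counts <- dplyr::count(merged, .data$subtype, .data$group, name = "n")
  out <- dplyr::left_join(grid, counts, by = c("subtype", "group"))
  out$n[is.na(out$n)] <- 0L
  out$n <- as.integer(out$n)
  out
}
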