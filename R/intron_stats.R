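# Per-group intron phase statistics: counts by phase, totals, mean introns
# per gene, and phase percentages, with fixed rounding conventions
# (half-up to 1 decimal for means, half-up to integer for percentages).

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; published tables in this field
#' conventionally round half up (208/24 prints as 8.7).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Per-gene intron phase table from gene structures
#'
#' @param structures A list of `gene_structure` objects.
#' @return A tibble with columns `gene_id` and `phase`, one row per
#'   intron; intronless genes contribute one row with `phase = NA` so they
#'   still count as genes.
#' @export
intron_phases <- function(structures) {
  dplyr::bind_rows(lapply(structures, function(s) {
    if (nrow(s$introns) == 0L) {
      tibble(gene_id = s$gene_id, phase = NA_integer_)
    } else {
      tibble(gene_id = s$gene_id, phase = s$introns$phase)
    }
  }))
}

.as_phase_tbl <- function(structures) {
  if (is.data.frame(structures)) {
    stopifnot(all(c("gene_id", "phase") %in% names(structures)))
    as_tibble(structures)
  } else {
    intron_phases(structures)
  }
}

.as_group_map <- function(groups) {
  if (is.null(groups)) return(tibble(gene_id = character(), group = character()))
  if (is.data.frame(groups)) {
    stopifnot(all(c("gene_id", "group") %in% names(groups)))
    return(as_tibble(groups)[, c("gene_id", "group")])
  }
  tibble(gene_id = names(groups), group = unname(groups))
}

.phase_row <- function(label, n_genes, phases) {
  phases <- phases[!is.na(phases)]
  n0 <- sum(phases == 0L); n1 <- sum(phases == 1L); n2 <- sum(phases == 2L)
  tot <- n0 + n1 + n2
  tibble(group = label, n_genes = n_genes,
         phase0 = n0, phase1 = n1, phase2 = n2, total_introns = tot,
         mean_per_gene = if (n_genes > 0L)
           round_half_up(tot / n_genes, 1) else NA_real_,
         pct0 = if (tot > 0L) round_half_up(100 * n0 / tot) else NA_real_,
         pct1 = if (tot > 0L) round_half_up(100 * n1 / tot) else NA_real_,
         pct2 = if (tot > 0L) round_half_up(100 * n2 / tot) else NA_real_)
}

#' Tabulate intron counts by phase per group
#'
#' Produces one row per group (first-seen order of the group map, then of
#' the data) plus a grand-total row labelled `"Total"`. Genes without a
#' group label fall into `"Orphan"`. Counts derive solely from the intron
#' phases; means are rounded half-up to one decimal and percentages
#' half-up to integers.
#'
#' @param structures A list of `gene_structure` objects, or a tibble with
#'   columns `gene_id` and `phase` (one row per intron; `NA` phase marks
#'   an intronless gene).
#' @param groups A tibble with columns `gene_id`, `group`, or a named
#'   character vector, or `NULL` (everything becomes `"Orphan"`).
#' @return A `phase_stats` tibble with columns `group`, `n_genes`,
#'   `phase0`, `phase1`, `phase2`, `total_introns`, `mean_per_gene`,
#'   `pct0`, `pct1`, `pct2`.
#' @export
tabulate_phase_stats <- function(structures, groups = NULL) {
  tbl <- .as_phase_tbl(structures)
  gm <- .as_group_map(groups)
  gene_ids <- unique(tbl$gene_id)
  grp <- gm$group[match(gene_ids, gm$gene_id)]
  grp[is.na(grp)] <- "Orphan"
  order_levels <- unique(c(gm$group[gm$gene_id %in% gene_ids], grp))
  rows <- lapply(order_levels, function(gl) {
    ids <- gene_ids[grp == gl]
    .phase_row(gl, length(ids), tbl$phase[tbl$gene_id %in% ids])
  })
  total <- .phase_row("Total", length(gene_ids), tbl$phase)
  out <- dplyr::bind_rows(c(rows, list(total)))
  structure(out, class = c("phase_stats", class(out)))
}

#' Extreme intron counts across genes
#'
#' @param structures As in [tabulate_phase_stats()]; must be non-empty.
#' @return A tibble with rows `min` and `max`: `stat`, `count`,
#'   `gene_ids` (list of all genes attaining the extreme).
#' @export
max_min_summary <- function(structures) {
  tbl <- .as_phase_tbl(structures)
  if (nrow(tbl) == 0L) {
    abort("empty input", class = "setstruct_precondition_error")
  }
  per_gene <- dplyr::summarise(dplyr::group_by(tbl, .data$gene_id),
                               n = sum(!is.na(.data$phase)), .groups = "drop")
  tibble(stat = c("min", "max"),
         count = c(min(per_gene$n), max(per_gene$n)),
         gene_ids = list(sort(per_gene$gene_id[per_gene$n == min(per_gene$n)]),
                         sort(per_gene$gene_id[per_gene$n == max(per_gene$n)])))
}

#' Flag cells of a printed statistics table that disagree with recomputation
#'
#' Compares a computed [tabulate_phase_stats()] table against externally
#' printed values cell by cell and reports every disagreement. Useful for
#' auditing published tables whose derived cells (means, percentages) are
#' inconsistent with their own counts.
#'
#' @param computed A `phase_stats` tibble.
#' @param printed A data frame with column `group` plus any subset of the
#'   `phase_stats` numeric columns holding the printed values.
#' @return A tibble of all compared cells: `group`, `field`, `computed`,
#'   `printed`, `match`.
#' @export
flag_printed_discrepancies <- function(computed, printed) {
  printed <- as_tibble(printed)
  fields <- setdiff(intersect(names(printed), names(computed)), "group")
  rows <- list()
  for (g in printed$group) {
    crow <- computed[computed$group == g, ]
    if (nrow(crow) == 0L) next
    prow <- printed[printed$group == g, ]
    for (f in fields) {
      pv <- as.numeric(prow[[f]][[1]])
      if (is.na(pv)) next
      cv <- as.numeric(crow[[f]][[1]])
      rows[[length(rows) + 1L]] <- tibble(
        group = g, field = f, computed = cv, printed = pv,
        match = isTRUE(all.equal(cv, pv, tolerance = 1e-9)))
    }
  }
  if (length(rows) == 0L) {
    return(tibble(group = character(), field = character(),
                  computed = numeric(), printed = numeric(),
                  match = logical()))
  }
  dplyr::bind_rows(rows)
}
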