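# End-to-end orchestration: simulate (or read) inputs, infer structures,
# build the codon alignment, project introns, tabulate phase statistics,
# classify domain architectures, build the bootstrapped NJ tree, and write
# a reproducible report bundle with a run manifest.

#' Configuration for a pipeline run
#'
#' Exactly one of `simulation` (a [family_config()] or a
#' [simulate_family()] result) or `inputs` must be supplied. `inputs` is a
#' named list of file paths: `genomic`, `mrna` (paired FASTA),
#' `protein_aln` (aligned FASTA), `domains` (TSV with `protein_id`,
#' `architecture`), and optionally `groups` (TSV with `gene_id`, `group`).
#' All referenced files must exist at validation time.
#'
#' @param out_dir Output directory (created if needed).
#' @param simulation Optional simulation source.
#' @param inputs Optional named list of input paths.
#' @param params Stage parameter overrides: `max_mismatches`, `min_intron`,
#'   `require_gt_ag`, `min_shared`, `sliding_window`, `n_boot`, `model`.
#' @param seed Integer seed (bootstrap resampling; and the simulation when
#'   `simulation` is a config).
#' @return A validated `run_config` list.
#' @export
run_config <- function(out_dir, simulation = NULL, inputs = NULL,
                       params = list(), seed = 1L) {
  if (is.null(simulation) == is.null(inputs)) {
    abort("supply exactly one of `simulation` or `inputs`",
          class = "setstruct_config_error")
  }
  if (!is.null(inputs)) {
    needed <- c("genomic", "mrna", "protein_aln", "domains")
    missing_keys <- setdiff(needed, names(inputs))
    if (length(missing_keys) > 0L) {
      abort(paste0("missing input path(s): ",
                   paste(missing_keys, collapse = ", ")),
            class = "setstruct_config_error")
    }
    for (k in names(inputs)) {
      if (!file.exists(inputs[[k]])) {
        abort(sprintf("input file for '%s' not found: %s", k, inputs[[k]]),
              class = "setstruct_config_error")
      }
    }
  }
  p <- utils::modifyList(list(max_mismatches = 0L, min_intron = 4L,
                              require_gt_ag = FALSE, min_shared = 2L,
                              sliding_window = 6L, n_boot = 1000L,
                              model = "p"), as.list(params))
  structure(list(out_dir = out_dir, simulation = simulation,
                 inputs = inputs, params = p, seed = as.integer(seed)),
            class = "run_config")
}

.stage <- function(name, expr, out_dir) {
  tryCatch(expr, error = function(e) {
    writeLines(paste0("FAILED at stage: ", name, "\n", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)),
          class = "setstruct_stage_error")
  })
}

#' Run the full analysis pipeline
#'
#' Stages: obtain inputs (simulate or read), infer gene structures,
#' back-translate the protein alignment and project intron positions,
#' detect shared positions and structural groups, tabulate per-group phase
#' statistics, classify domain architectures, and build a bootstrapped NJ
#' tree. For simulated inputs a truth-vs-inferred comparison is added.
#' All outputs are written to `config$out_dir` as TSV/Newick plus a
#' `manifest.txt` recording parameters, seed and collected warnings; any
#' stage failure aborts with the stage named and leaves a `FAILED` marker.
#'
#' @param config A [run_config()].
#' @return Invisibly, a `setstruct_run` report bundle: list with
#'   `structures`, `structure_summary`, `projected`, `incidence`,
#'   `shared`, `sliding`, `groups`, `phase_stats`, `domains`, `tree`,
#'   `supports`, `truth_comparison` (or `NULL`), `paths`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  warnings_log <- character()
  note <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  sim <- NULL
  inp <- .stage("inputs", {
    if (!is.null(config$simulation)) {
      sim <- if (inherits(config$simulation, "sim_family")) {
        config$simulation
      } else {
        simulate_family(config$simulation)
      }
      list(genomic = sim$genomic, mrna = sim$mrna,
           protein_aln = sim$protein_aln, domains = sim$domains,
           groups = NULL)
    } else {
      list(genomic = read_fasta(config$inputs$genomic, "dna"),
           mrna = read_fasta(config$inputs$mrna, "dna"),
           protein_aln = read_alignment(config$inputs$protein_aln, "protein"),
           domains = readr::read_tsv(config$inputs$domains,
                                     show_col_types = FALSE),
           groups = if (!is.null(config$inputs$groups)) {
             readr::read_tsv(config$inputs$groups, show_col_types = FALSE)
           })
    }
  }, config$out_dir)

  structures <- .stage("infer_structure", withCallingHandlers(
    infer_structures(inp$genomic, inp$mrna,
                     max_mismatches = p$max_mismatches,
                     min_intron = p$min_intron,
                     require_gt_ag = p$require_gt_ag),
    warning = note), config$out_dir)

  proj <- .stage("projection", {
    codon_aln <- backtranslate_alignment(inp$protein_aln, inp$mrna)
    dplyr::bind_rows(lapply(structures, project_introns, codon_aln))
  }, config$out_dir)
  incidence <- intron_incidence(proj, genes = names(structures))
  shared <- shared_intron_positions(incidence)
  sliding <- sliding_report(incidence, window = p$sliding_window)
  groups_struct <- assign_structural_groups(incidence,
                                            min_shared = p$min_shared)

  group_map <- if (!is.null(inp$groups)) inp$groups else groups_struct
  stats_tbl <- .stage("intron_stats",
                      tabulate_phase_stats(structures, group_map),
                      config$out_dir)

  dom <- .stage("classify_domains", withCallingHandlers(
    classify_architectures(inp$domains), warning = note), config$out_dir)

  tree <- .stage("nj_tree", withCallingHandlers(
    bootstrap_support(inp$protein_aln, n_reps = p$n_boot,
                      seed = config$seed, model = p$model),
    warning = note), config$out_dir)
  supports <- support_table(tree)

  truth_cmp <- NULL
  if (!is.null(sim)) {
    truth_cmp <- .stage("truth_comparison", {
      inferred <- structure_table(structures)
      inferred <- inferred[inferred$feature == "intron", ]
      per_gene <- vapply(names(structures), function(gid) {
        tr <- sim$truth$structures[sim$truth$structures$gene_id == gid, ]
        iv <- structures[[gid]]$introns
        nrow(tr) == nrow(iv) &&
          identical(as.integer(tr$cds_offset), as.integer(iv$cds_offset)) &&
          identical(as.integer(tr$phase), as.integer(iv$phase)) &&
          identical(as.integer(tr$genomic_start), as.integer(iv$genomic_start)) &&
          identical(as.integer(tr$genomic_end), as.integer(iv$genomic_end))
      }, logical(1))
      topo_match <- tryCatch({
        setequal(stats::na.omit(.bipartition_keys(tree)),
                 stats::na.omit(.bipartition_keys(sim$truth$tree)))
      }, error = function(e) NA)
      tibble(gene_id = names(structures), structure_exact = unname(per_gene),
             topology_recovered = topo_match)
    }, config$out_dir)
  }

  paths <- list(
    structures = file.path(config$out_dir, "structures.tsv"),
    incidence = file.path(config$out_dir, "incidence_matrix.tsv"),
    shared = file.path(config$out_dir, "shared_positions.tsv"),
    sliding = file.path(config$out_dir, "sliding_candidates.tsv"),
    groups = file.path(config$out_dir, "structural_groups.tsv"),
    phase_stats = file.path(config$out_dir, "phase_stats.tsv"),
    domains = file.path(config$out_dir, "domain_classes.tsv"),
    tree = file.path(config$out_dir, "nj_tree.nwk"),
    supports = file.path(config$out_dir, "supports.tsv"),
    manifest = file.path(config$out_dir, "manifest.txt"))
  if (!is.null(truth_cmp)) {
    paths$truth <- file.path(config$out_dir, "truth_comparison.tsv")
  }

  .stage("write_outputs", {
    write_table(structure_table(structures, display = TRUE),
                paths$structures)
    im <- incidence_matrix(incidence)
    write_table(cbind(tibble(gene_id = rownames(im)), as_tibble(im)),
                paths$incidence)
    write_table(shared, paths$shared)
    write_table(sliding, paths$sliding)
    write_table(groups_struct, paths$groups)
    write_table(stats_tbl, paths$phase_stats)
    write_table(dom, paths$domains)
    write_newick(tree, paths$tree)
    write_table(supports, paths$supports)
    if (!is.null(truth_cmp)) {
      write_table(truth_cmp, paths$truth)
    }
    manifest <- c(
      paste0("setstruct version: ",
             as.character(utils::packageVersion("setstruct"))),
      paste0("seed: ", config$seed),
      paste0("params: ", paste(names(p), unlist(p), sep = "=",
                               collapse = "; ")),
      "intron position convention: 1-based nucleotide alignment column of the last exonic base before the intron",
      paste0("warnings: ", length(warnings_log)),
      warnings_log)
    writeLines(manifest, paths$manifest)
  }, config$out_dir)

  out <- structure(list(structures = structures,
                        structure_summary = dplyr::bind_rows(
                          lapply(structures, glance)),
                        projected = proj, incidence = incidence,
                        shared = shared, sliding = sliding,
                        groups = groups_struct, phase_stats = stats_tbl,
                        domains = dom, tree = tree, supports = supports,
                        truth_comparison = truth_cmp,
                        paths = paths,
                        manifest = readLines(paths$manifest)),
                   class = "setstruct_run")
  invisible(out)
}

#' One-row summary of a pipeline run
#'
#' @param x A `setstruct_run`.
#' @param ... Unused.
#' @return A tibble with `n_genes`, `n_introns`, `n_shared_positions`,
#'   `n_groups`, `n_intronless`, `pct_structures_exact` (NA for real
#'   inputs).
#' @export
glance.setstruct_run <- function(x, ...) {
  tibble(
    n_genes = length(x$structures),
    n_introns = sum(x$structure_summary$n_introns),
    n_shared_positions = nrow(x$shared),
    n_groups = length(setdiff(unique(x$groups$group), "intronless")),
    n_intronless = sum(x$groups$group == "intronless"),
    pct_structures_exact = if (is.null(x$truth_comparison)) NA_real_ else
      100 * mean(x$truth_comparison$structure_exact))
}

#' @export
print.setstruct_run <- function(x, ...) {
  cat("<setstruct_run>\n")
  print(glance(x))
  invisible(x)
}
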