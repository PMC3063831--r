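# Gene-family simulator: a single ancestral gene (exons with GT-AG
# introns) evolves along a declared guide tree under point substitution,
# intron loss, intron gain and retroposition (loss of every intron at
# once, emulating reinsertion of a reverse-transcribed mRNA). Exons are
# indel-free, so the true protein alignment is gapless and column homology
# is exact; the four splice dinucleotides are immutable so every emitted
# intron stays GT-AG. All randomness flows from one seed.

.STOP_CODONS <- c("TAA", "TAG", "TGA")
.BASES <- c("A", "C", "G", "T")

#' Configuration for a simulated gene family
#'
#' Branch lengths of the guide tree are expected substitutions per site;
#' event rates are per branch: each intron is lost independently with
#' probability `intron_loss`, the number of gains is Poisson
#' (`intron_gain`), and retroposition (all introns removed at once)
#' happens with probability `retroposition`. Deterministic scenarios use
#' `forced_events` on named branches instead of rates.
#'
#' @param seed Integer seed fixing all randomness.
#' @param guide_tree Newick string with branch lengths; internal node
#'   labels are required only for branches named in `forced_events`.
#' @param ancestral_exon_lengths Nucleotide lengths of the ancestral
#'   exons; their sum (the CDS including the stop codon) must be divisible
#'   by 3. Intron CDS offsets are the cumulative sums of all but the last
#'   exon. Alternatively supply `cds_length` + `ancestral_intron_positions`.
#' @param cds_length,ancestral_intron_positions Alternative ancestral
#'   specification: total CDS length and strictly increasing intron CDS
#'   offsets, each inside the CDS.
#' @param intron_length_range Length bounds (min, max) for ancestral and
#'   gained introns; both >= 4.
#' @param rates Named list with `intron_loss`, `intron_gain`,
#'   `retroposition`, all >= 0 (defaults 0).
#' @param forced_events `NULL` or a data frame with columns `branch` (the
#'   label of the child node of the branch) and `event` (one of
#'   `"retroposition"`, `"intron_loss"`, `"intron_gain"`).
#' @param architectures `NULL` (every gene gets `SRA,PreSET,SET,PostSET`)
#'   or a data frame with columns `protein_id`, `architecture`.
#' @return A validated `family_config` list.
#' @export
family_config <- function(seed = 1L, guide_tree,
                          ancestral_exon_lengths = NULL,
                          cds_length = NULL,
                          ancestral_intron_positions = NULL,
                          intron_length_range = c(60L, 200L),
                          rates = list(),
                          forced_events = NULL,
                          architectures = NULL) {
  if (is.null(ancestral_exon_lengths)) {
    if (is.null(cds_length) || is.null(ancestral_intron_positions)) {
      abort("supply ancestral_exon_lengths, or cds_length + ancestral_intron_positions",
            class = "setstruct_config_error")
    }
    pos <- as.integer(ancestral_intron_positions)
    if (any(diff(pos) <= 0L) || any(pos <= 0L) || any(pos >= cds_length)) {
      abort("ancestral intron positions must be strictly increasing and inside the CDS",
            class = "setstruct_config_error")
    }
    ancestral_exon_lengths <- diff(c(0L, pos, as.integer(cds_length)))
  }
  ancestral_exon_lengths <- as.integer(ancestral_exon_lengths)
  if (any(ancestral_exon_lengths <= 0L)) {
    abort("exon lengths must be positive", class = "setstruct_config_error")
  }
  cds_len <- sum(ancestral_exon_lengths)
  if (cds_len %% 3L != 0L || cds_len < 6L) {
    abort("CDS length (sum of exon lengths) must be a positive multiple of 3",
          class = "setstruct_config_error")
  }
  r <- utils::modifyList(list(intron_loss = 0, intron_gain = 0,
                              retroposition = 0), as.list(rates))
  if (any(unlist(r) < 0)) {
    abort("event rates must be >= 0", class = "setstruct_config_error")
  }
  intron_length_range <- as.integer(intron_length_range)
  if (length(intron_length_range) != 2L || intron_length_range[1] < 4L ||
      diff(intron_length_range) < 0L) {
    abort("intron_length_range must be (min, max) with min >= 4",
          class = "setstruct_config_error")
  }
  if (!is.null(forced_events)) {
    forced_events <- as_tibble(forced_events)
    stopifnot(all(c("branch", "event") %in% names(forced_events)),
              all(forced_events$event %in%
                    c("retroposition", "intron_loss", "intron_gain")))
  }
  structure(list(seed = as.integer(seed), guide_tree = guide_tree,
                 ancestral_exon_lengths = ancestral_exon_lengths,
                 cds_length = cds_len,
                 intron_length_range = intron_length_range,
                 rates = r, forced_events = forced_events,
                 architectures = architectures),
            class = "family_config")
}

.random_cds <- function(n_codons) {
  non_stop <- setdiff(apply(expand.grid(.BASES, .BASES, .BASES), 1, paste,
                            collapse = ""), .STOP_CODONS)
  body <- sample(non_stop, n_codons - 2L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), sample(.STOP_CODONS, 1L))
}

.random_intron <- function(len_range) {
  len <- sample(seq(len_range[1], len_range[2]), 1L)
  paste0("GT", paste(sample(.BASES, len - 4L, replace = TRUE), collapse = ""),
         "AG")
}

# point substitution on a CDS, never creating a stop codon and never
# touching the terminal stop codon
.mutate_cds <- function(cds, p) {
  if (p <= 0) return(cds)
  ch <- .chars(cds)
  L <- length(ch)
  sites <- which(stats::runif(L - 3L) < p)
  for (s in sites) {
    codon_start <- 3L * ((s - 1L) %/% 3L) + 1L
    alts <- sample(setdiff(.BASES, ch[s]))
    for (b in alts) {
      cand <- ch[codon_start:(codon_start + 2L)]
      cand[s - codon_start + 1L] <- b
      if (!paste(cand, collapse = "") %in% .STOP_CODONS) {
        ch[s] <- b
        break
      }
    }
  }
  paste(ch, collapse = "")
}

# point substitution inside an intron; splice dinucleotides are immutable
.mutate_intron <- function(seq, p) {
  if (p <= 0) return(seq)
  ch <- .chars(seq)
  L <- length(ch)
  if (L <= 4L) return(seq)
  sites <- 2L + which(stats::runif(L - 4L) < p)
  for (s in sites) ch[s] <- sample(setdiff(.BASES, ch[s]), 1L)
  paste(ch, collapse = "")
}

#' Simulate a gene family with known truth
#'
#' Evolves the configured ancestral gene along the guide tree and emits,
#' per extant gene: genomic DNA (exons interleaved with introns), mRNA
#' (the CDS including the stop codon), protein, the (gapless, exact)
#' protein alignment, a domain-architecture table, and a machine-readable
#' truth record (per-gene intron structures, the homologous-intron map,
#' the event log and the guide tree).
#'
#' @param config A [family_config()].
#' @return A `sim_family` list with elements `genomic`, `mrna`, `protein`
#'   (sequence tibbles), `protein_aln` (`setstruct_aln`), `domains`
#'   (tibble `protein_id`, `architecture`), `truth` (list: `structures`,
#'   `intron_map`, `events`, `tree`, `counts`), and `config`.
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "family_config"))
  set.seed(config$seed)
  tree <- ape::read.tree(text = config$guide_tree)
  if (is.null(tree$edge.length)) {
    abort("guide tree must carry branch lengths", class = "setstruct_config_error")
  }
  ntip <- length(tree$tip.label)
  if (is.null(tree$node.label) || !any(nzchar(tree$node.label))) {
    tree$node.label <- paste0("node", seq_len(tree$Nnode))
  }
  node_name <- c(tree$tip.label, tree$node.label)

  # ancestral gene
  offsets <- cumsum(utils::head(config$ancestral_exon_lengths, -1L))
  anc_introns <- if (length(offsets) > 0L) {
    tibble(id = paste0("anc", seq_along(offsets)),
           cds_offset = as.integer(offsets),
           seq = vapply(offsets, function(o)
             .random_intron(config$intron_length_range), character(1)))
  } else {
    tibble(id = character(), cds_offset = integer(), seq = character())
  }
  states <- vector("list", ntip + tree$Nnode)
  states[[ntip + 1L]] <- list(cds = .random_cds(config$cds_length %/% 3L),
                              introns = anc_introns)
  events <- list()
  gain_counter <- 0L

  forced_for <- function(label) {
    fe <- config$forced_events
    if (is.null(fe)) return(character())
    fe$event[fe$branch == label]
  }

  tree <- stats::reorder(tree, "cladewise")
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    bl <- tree$edge.length[e]
    label <- node_name[child]
    st <- states[[parent]]
    # substitution
    st$cds <- .mutate_cds(st$cds, bl)
    st$introns$seq <- vapply(st$introns$seq, .mutate_intron, character(1),
                             p = bl)
    forced <- forced_for(label)
    # intron loss
    loss_mask <- stats::runif(nrow(st$introns)) < config$rates$intron_loss
    n_forced_loss <- sum(forced == "intron_loss")
    if (n_forced_loss > 0L && any(!loss_mask)) {
      cand <- which(!loss_mask)
      extra <- cand[sample.int(length(cand),
                               min(n_forced_loss, length(cand)))]
      loss_mask[extra] <- TRUE
    }
    for (id in st$introns$id[loss_mask]) {
      events[[length(events) + 1L]] <- tibble(branch = label,
                                              event = "intron_loss",
                                              detail = id)
    }
    st$introns <- st$introns[!loss_mask, ]
    # intron gain
    n_gain <- stats::rpois(1L, config$rates$intron_gain) +
      sum(forced == "intron_gain")
    for (k in seq_len(n_gain)) {
      free <- setdiff(seq_len(config$cds_length - 1L), st$introns$cds_offset)
      if (length(free) == 0L) break
      gain_counter <- gain_counter + 1L
      off <- if (length(free) == 1L) free else sample(free, 1L)
      gid <- sprintf("gain%d_%s", gain_counter, label)
      st$introns <- dplyr::bind_rows(st$introns,
                                     tibble(id = gid, cds_offset = as.integer(off),
                                            seq = .random_intron(config$intron_length_range)))
      st$introns <- dplyr::arrange(st$introns, .data$cds_offset)
      events[[length(events) + 1L]] <- tibble(branch = label,
                                              event = "intron_gain",
                                              detail = gid)
    }
    # retroposition: the whole lineage loses every intron
    if (("retroposition" %in% forced ||
         stats::runif(1L) < config$rates$retroposition) &&
        nrow(st$introns) >= 0L) {
      events[[length(events) + 1L]] <- tibble(branch = label,
                                              event = "retroposition",
                                              detail = paste(st$introns$id,
                                                             collapse = ","))
      st$introns <- st$introns[0L, ]
    }
    states[[child]] <- st
  }

  # emit tip genes
  gene_ids <- tree$tip.label
  emit <- lapply(seq_len(ntip), function(t) {
    st <- states[[t]]
    iv <- dplyr::arrange(st$introns, .data$cds_offset)
    bounds <- c(0L, iv$cds_offset, nchar(st$cds))
    pieces <- substring(st$cds, utils::head(bounds, -1L) + 1L,
                        utils::tail(bounds, -1L))
    genomic <- pieces[1]
    ilen <- nchar(iv$seq)
    gstart <- integer(nrow(iv)); gend <- integer(nrow(iv))
    for (k in seq_len(nrow(iv))) {
      gstart[k] <- nchar(genomic)
      genomic <- paste0(genomic, iv$seq[k])
      gend[k] <- nchar(genomic)
      genomic <- paste0(genomic, pieces[k + 1L])
    }
    codons <- substring(st$cds, seq(1L, nchar(st$cds) - 3L, 3L),
                        seq(3L, nchar(st$cds) - 3L, 3L))
    list(genomic = genomic, mrna = st$cds,
         protein = paste(.translate_codons(codons), collapse = ""),
         introns = tibble(gene_id = gene_ids[t], intron_id = iv$id,
                          cds_offset = iv$cds_offset,
                          phase = iv$cds_offset %% 3L,
                          genomic_start = gstart, genomic_end = gend))
  })

  seq_tbl <- function(field, alphabet) {
    tibble(id = gene_ids, description = "",
           residues = vapply(emit, `[[`, character(1), field),
           alphabet = alphabet)
  }
  structures <- dplyr::bind_rows(lapply(emit, `[[`, "introns"))
  all_intron_ids <- unique(c(anc_introns$id,
                             structures$intron_id,
                             unlist(lapply(events, function(ev)
                               if (ev$event == "intron_gain") ev$detail else NULL))))
  intron_map <- tidyr::expand_grid(intron_id = all_intron_ids,
                                   gene_id = gene_ids)
  intron_map <- dplyr::left_join(intron_map,
                                 structures[, c("intron_id", "gene_id",
                                                "cds_offset")],
                                 by = c("intron_id", "gene_id"))
  domains <- if (is.null(config$architectures)) {
    tibble(protein_id = gene_ids,
           architecture = "SRA,PreSET,SET,PostSET")
  } else {
    as_tibble(config$architectures)
  }
  counts <- dplyr::count(structures, .data$gene_id, name = "n_introns")
  counts <- dplyr::left_join(tibble(gene_id = gene_ids), counts,
                             by = "gene_id")
  counts$n_introns[is.na(counts$n_introns)] <- 0L

  structure(list(
    genomic = seq_tbl("genomic", "dna"),
    mrna = seq_tbl("mrna", "dna"),
    protein = seq_tbl("protein", "protein"),
    protein_aln = new_alignment(
      tibble(id = gene_ids,
             residues = vapply(emit, `[[`, character(1), "protein")),
      "protein"),
    domains = domains,
    truth = list(structures = structures,
                 intron_map = intron_map,
                 events = if (length(events) > 0L) dplyr::bind_rows(events)
                 else tibble(branch = character(), event = character(),
                             detail = character()),
                 tree = tree,
                 counts = counts),
    config = config), class = "sim_family")
}

#' Preset: a SUVH/SUVR-like family with retrogenes
#'
#' Convenience scenario emulating the qualitative structure of the plant
#' Su(var)3-9 SET family: one structurally conserved intron-rich clade
#' (five genes, all introns at identical positions and phases), two
#' independently retroposed intronless clades (3 + 2 genes), and one
#' divergent intron-variable clade (four genes, WIYLD-type architecture)
#' whose stem branch remodels the ancestral structure — five intron losses
#' plus three gains — so it forms its own structural class, with further
#' gains inside the clade. Branch lengths stay at or below 0.04 expected
#' substitutions per site.
#'
#' @param seed Integer seed.
#' @param divergence_scale Multiplier applied to every branch length
#'   (default 1; use small values for a near-zero-divergence family).
#' @param retroposition If `FALSE`, the forced retroposition events are
#'   dropped and no intronless genes arise.
#' @param ... Overrides passed on to [family_config()] (e.g. `rates`).
#' @return A [simulate_family()] result.
#' @export
scenario_suvh <- function(seed = 101L, divergence_scale = 1,
                          retroposition = TRUE, ...) {
  nwk <- paste0(
    "(((V2a:0.030,V2b:0.030)i1:0.020,(V2c:0.030,(V2d:0.020,V2e:0.020)",
    "i2:0.020)i3:0.020)V2:0.030,(((R1a:0.030,R1b:0.030)i4:0.020,R1c:0.040)",
    "RETRO1:0.040,(R2a:0.030,R2b:0.030)RETRO2:0.040)SUVH:0.020,",
    "((W1:0.040,W2:0.040)i5:0.030,(W3:0.040,W4:0.040)i6:0.030)V6:0.030);")
  tips <- c("V2a", "V2b", "V2c", "V2d", "V2e", "R1a", "R1b", "R1c",
            "R2a", "R2b", "W1", "W2", "W3", "W4")
  if (divergence_scale != 1) {
    tr <- ape::read.tree(text = nwk)
    tr$edge.length <- tr$edge.length * divergence_scale
    nwk <- ape::write.tree(tr)
  }
  forced <- tibble(
    branch = c("RETRO1", "RETRO2", rep("V6", 8L), "i6", "W1"),
    event = c("retroposition", "retroposition",
              rep("intron_loss", 5L), rep("intron_gain", 3L),
              "intron_gain", "intron_gain"))
  if (!retroposition) {
    forced <- forced[!forced$event == "retroposition", ]
  }
  arch <- tibble(
    protein_id = tips,
    architecture = ifelse(startsWith(tips, "W"),
                          "WIYLD,PreSET,SET,PostSET",
                          "XXX,SRA,PreSET,SET,PostSET"))
  defaults <- list(seed = seed, guide_tree = nwk,
                   ancestral_exon_lengths = c(120L, 93L, 150L, 96L, 120L,
                                              63L, 60L),
                   intron_length_range = c(60L, 120L),
                   forced_events = forced,
                   architectures = arch)
  cfg <- do.call(family_config, utils::modifyList(defaults, list(...)))
  simulate_family(cfg)
}

#' True group labels for the [scenario_suvh()] preset
#'
#' @return A tibble with `gene_id` and `group` (`V-2like`, `retro`,
#'   `V-6like`).
#' @export
scenario_suvh_groups <- function() {
  tibble(gene_id = c(paste0("V2", letters[1:5]),
                     "R1a", "R1b", "R1c", "R2a", "R2b",
                     paste0("W", 1:4)),
         group = c(rep("V-2like", 5), rep("retro", 5), rep("V-6like", 4)))
}
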