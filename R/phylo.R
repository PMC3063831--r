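# Distance-based phylogenetics: p-distance with pairwise deletion of gaps
# and ambiguities, Saitou-Nei neighbor joining with deterministic
# tie-breaking, nonparametric column bootstrap, and bootstrap-support
# strength categories (weak 50-75, moderate 76-85, strong 86-100).

.aln_char_matrix <- function(aln) {
  mat <- do.call(rbind, strsplit(aln$residues, "", fixed = TRUE))
  rownames(mat) <- aln$id
  mat
}

.valid_mask <- function(mat, alphabet) {
  ambig <- if (alphabet == "protein") "X" else "N"
  mat != "-" & mat != ambig
}

.pdist_from_mat <- function(mat, valid, model) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  ov <- matrix(0L, n, n, dimnames = dimnames(d))
  diag(ov) <- as.integer(rowSums(valid))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- valid[i, ] & valid[j, ]
      m <- sum(both)
      if (m == 0L) {
        abort(sprintf("no comparable sites between '%s' and '%s'",
                      rownames(mat)[i], rownames(mat)[j]),
              class = "setstruct_zero_overlap_error")
      }
      p <- sum(mat[i, both] != mat[j, both]) / m
      if (model == "poisson") {
        if (p >= 1) {
          abort(sprintf(
            "Poisson correction undefined for saturated pair '%s'/'%s' (p = 1)",
            rownames(mat)[i], rownames(mat)[j]))
        }
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
      ov[i, j] <- ov[j, i] <- as.integer(m)
    }
  }
  structure(list(ids = rownames(mat), d = d, overlap = ov, model = model),
            class = "pdist")
}

#' Pairwise distance matrix with pairwise deletion
#'
#' For each pair of rows, columns holding a gap (`-`) or an ambiguity
#' character (`X` for protein, `N` for DNA) in either row are excluded;
#' the p-distance is the fraction of remaining columns that differ. The
#' Poisson-corrected distance `-ln(1 - p)` is available as an option.
#'
#' @param aln A `setstruct_aln` with at least 2 rows.
#' @param model `"p"` (default) or `"poisson"`.
#' @return A `pdist` object: list with `ids`, symmetric matrix `d`,
#'   integer matrix `overlap` of compared-site counts, and `model`.
#' @export
p_distance_matrix <- function(aln, model = c("p", "poisson")) {
  model <- match.arg(model)
  stopifnot(inherits(aln, "setstruct_aln"))
  if (nrow(aln) < 2L) {
    abort("need at least 2 sequences", class = "setstruct_precondition_error")
  }
  mat <- .aln_char_matrix(aln)
  .pdist_from_mat(mat, .valid_mask(mat, attr(aln, "alphabet")), model)
}

#' Tidy a distance matrix into a pair table
#'
#' @param x A `pdist` object.
#' @param ... Unused.
#' @return A tibble with one row per unordered pair: `id_a`, `id_b`,
#'   `distance`, `overlap`.
#' @export
tidy.pdist <- function(x, ...) {
  n <- length(x$ids)
  idx <- which(upper.tri(x$d), arr.ind = TRUE)
  tibble(id_a = x$ids[idx[, 1]], id_b = x$ids[idx[, 2]],
         distance = x$d[idx], overlap = x$overlap[idx])
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration: at each step the pair minimizing the
#' Q criterion is joined; ties are broken by the lexicographically
#' smallest pair of cluster labels (a cluster is labelled by its smallest
#' leaf id). Negative branch lengths are clamped to zero.
#'
#' @param dm A `pdist` object, or a symmetric numeric matrix with
#'   dimnames, over at least 3 taxa.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "pdist")) {
    D <- dm$d
  } else {
    D <- as.matrix(dm)
  }
  ids <- rownames(D)
  if (is.null(ids)) abort("distance matrix must have dimnames")
  n <- length(ids)
  if (n < 3L) {
    abort("neighbor joining needs at least 3 taxa",
          class = "setstruct_precondition_error")
  }
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  nwk <- ids
  lab <- ids
  while (length(lab) > 3L) {
    N <- length(lab)
    rs <- rowSums(D)
    Q <- (N - 2) * D - outer(rs, rs, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    hits <- which(Q - qmin <= abs(qmin) * 1e-12 + 1e-12, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    key <- paste(pmin(lab[hits[, 1]], lab[hits[, 2]]),
                 pmax(lab[hits[, 1]], lab[hits[, 2]]), sep = "\r")
    pick <- hits[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- D[i, j] / 2 + (rs[i] - rs[j]) / (2 * (N - 2))
    lj <- D[i, j] - li
    new_nwk <- paste0("(", nwk[i], ":", fmt(li), ",", nwk[j], ":", fmt(lj), ")")
    new_lab <- min(lab[i], lab[j])
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(N), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    D <- D2
    nwk <- c(nwk[keep], new_nwk)
    lab <- c(lab[keep], new_lab)
    dimnames(D) <- list(lab, lab)
  }
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- paste0("(", nwk[1], ":", fmt(v1), ",", nwk[2], ":", fmt(v2), ",",
                nwk[3], ":", fmt(v3), ");")
  ape::read.tree(text = txt)
}

# canonical keys of the non-trivial bipartitions of a tree, one per
# internal node (NA for trivial ones, e.g. the root's full-tip "clade")
.bipartition_keys <- function(tree) {
  pp <- ape::prop.part(tree)
  labels <- attr(pp, "labels")
  smallest <- sort(labels)[1]
  n <- length(labels)
  vapply(pp, function(part) {
    set <- labels[part]
    if (length(set) <= 1L || length(set) >= n - 1L) return(NA_character_)
    if (smallest %in% set) set <- setdiff(labels, set)
    paste(sort(set), collapse = "\r")
  }, character(1))
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Alignment columns are resampled with replacement `n_reps` times; each
#' replicate is rebuilt with [p_distance_matrix()] and [nj_tree()], and the
#' support of each internal edge of the full-data tree is the percentage
#' of retained replicates whose tree contains that bipartition.
#' Replicates in which some pair has zero comparable sites are discarded
#' and counted; a warning is raised when more than 1% are discarded.
#'
#' @param aln A `setstruct_aln`.
#' @param n_reps Number of bootstrap replicates (>= 1; the conventional
#'   choice for NJ is 1000).
#' @param seed Integer seed; fixed seed gives identical supports.
#' @param model Distance model, as in [p_distance_matrix()].
#' @return The full-data `phylo` tree with integer percent supports in
#'   `node.label` (empty for trivial edges) and attributes `n_reps`,
#'   `n_discarded`.
#' @export
bootstrap_support <- function(aln, n_reps = 1000L, seed = 1L,
                              model = c("p", "poisson")) {
  model <- match.arg(model)
  if (n_reps < 1L) {
    abort("n_reps must be >= 1", class = "setstruct_precondition_error")
  }
  set.seed(seed)
  mat <- .aln_char_matrix(aln)
  valid <- .valid_mask(mat, attr(aln, "alphabet"))
  full <- nj_tree(.pdist_from_mat(mat, valid, model))
  keys <- .bipartition_keys(full)
  counts <- stats::setNames(rep(0L, sum(!is.na(keys))), keys[!is.na(keys)])
  discarded <- 0L
  L <- ncol(mat)
  for (rep in seq_len(n_reps)) {
    idx <- sample.int(L, L, replace = TRUE)
    rep_tree <- tryCatch(
      nj_tree(.pdist_from_mat(mat[, idx, drop = FALSE],
                              valid[, idx, drop = FALSE], model)),
      setstruct_zero_overlap_error = function(e) NULL)
    if (is.null(rep_tree)) {
      discarded <- discarded + 1L
      next
    }
    rk <- .bipartition_keys(rep_tree)
    seen <- intersect(names(counts), rk)
    counts[seen] <- counts[seen] + 1L
  }
  kept <- n_reps - discarded
  if (kept == 0L) abort("all bootstrap replicates discarded")
  if (discarded > 0.01 * n_reps) {
    warn(sprintf("%d of %d bootstrap replicates discarded (zero-overlap pairs)",
                 discarded, n_reps))
  }
  support <- ifelse(is.na(keys), NA_integer_,
                    as.integer(round(100 * counts[keys] / kept)))
  full$node.label <- ifelse(is.na(support), "", as.character(support))
  attr(full, "n_reps") <- n_reps
  attr(full, "n_discarded") <- discarded
  full
}

#' Categorize bootstrap percentages
#'
#' Ranges follow the conventional strength bands: below 50 unsupported,
#' 50-75 weak, 76-85 moderate, 86-100 strong.
#'
#' @param bp Numeric vector of bootstrap percentages in \[0, 100\].
#' @return A factor with levels `unsupported`, `weak`, `moderate`,
#'   `strong`.
#' @export
support_category <- function(bp) {
  if (any(is.na(bp)) || any(bp < 0) || any(bp > 100)) {
    abort("bootstrap percentages must lie in [0, 100]",
          class = "setstruct_precondition_error")
  }
  lev <- c("unsupported", "weak", "moderate", "strong")
  factor(ifelse(bp < 50, "unsupported",
                ifelse(bp <= 75, "weak",
                       ifelse(bp <= 85, "moderate", "strong"))),
         levels = lev)
}

#' Support table for a bootstrapped tree
#'
#' @param tree A `phylo` with percent supports in `node.label`.
#' @return A tibble with `node`, `support`, `category` for every internal
#'   node carrying a support value.
#' @export
support_table <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  lab <- tree$node.label
  if (is.null(lab)) return(tibble(node = integer(), support = integer(),
                                  category = factor(character(),
                                                    levels = levels(support_category(0)))))
  nodes <- which(nzchar(lab) & !is.na(lab))
  sup <- as.integer(lab[nodes])
  tibble(node = nodes + length(tree$tip.label), support = sup,
         category = support_category(sup))
}
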