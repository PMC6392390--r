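# Tree-based assessment: neighbour-joining with bootstrap support, Fitch
# parsimony with NNI hill climbing, and rank-level monophyly scored as
# bipartition existence on the unrooted tree (no rooting scheme required).

# ambiguity-aware nucleotide bitsets for parsimony: A=1, C=2, G=4, T=8;
# gap, 'N' and '?' are fully ambiguous (never a fifth state).
FITCH_CODES <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L, M = 3L, R = 5L,
                 W = 9L, S = 6L, Y = 10L, K = 12L, V = 7L, H = 11L,
                 D = 13L, B = 14L, N = 15L, "-" = 15L, "?" = 15L)

#' Neighbour-joining tree from a divergence matrix
#'
#' Saitou-Nei neighbour joining (via [ape::nj()]); negative branch-length
#' estimates are clamped to zero with the total deficit recorded in
#' `attr(tree, "clamped_deficit")`.
#'
#' @param m a `divergence_matrix`, matrix or [stats::dist] with at least
#'   three fully defined taxa.
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(m) {
  mat <- if (inherits(m, "divergence_matrix")) m$d else as.matrix(m)
  if (nrow(mat) < 3L) stop("at least three taxa are required")
  if (anyNA(mat[upper.tri(mat)]))
    stop("distance matrix contains undefined entries; exclude the ",
         "affected specimens (or impute) before tree building")
  tr <- ape::nj(stats::as.dist(mat))
  deficit <- -sum(pmin(tr$edge.length, 0))
  tr$edge.length <- pmax(tr$edge.length, 0)
  attr(tr, "clamped_deficit") <- deficit
  tr
}

# canonical key of the bipartition {side, complement}: the side not
# containing the lexicographically smallest label, sorted and joined.
canonical_split_key <- function(side, all_labels) {
  ref <- min(all_labels)
  if (ref %in% side) side <- setdiff(all_labels, side)
  paste(sort(side), collapse = "\x1f")
}

# all non-trivial bipartitions induced by internal edges, with the internal
# node index and its support (numeric node label, NA when absent).
tree_splits <- function(tree) {
  nt <- length(tree$tip.label)
  po <- stats::reorder(tree, "postorder")
  ntot <- nt + tree$Nnode
  sets <- vector("list", ntot)
  sets[seq_len(nt)] <- as.list(tree$tip.label)
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]
    ch <- po$edge[i, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  root <- nt + 1L
  supports <- if (!is.null(tree$node.label))
    suppressWarnings(as.numeric(tree$node.label)) else
      rep(NA_real_, tree$Nnode)
  out <- list()
  for (node in setdiff(seq.int(nt + 1L, ntot), root)) {
    clade <- sets[[node]]
    if (length(clade) < 2L || length(clade) > nt - 2L) next
    out[[length(out) + 1L]] <- list(
      node = node,
      key = canonical_split_key(clade, tree$tip.label),
      support = supports[node - nt])
  }
  out
}

#' Nonparametric bootstrap support for a neighbour-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate under the same distance model, and annotates each internal
#' edge of the original tree with the percentage of replicates containing
#' its bipartition (stored as node labels). Replicates whose resampled
#' matrix contains undefined distances are skipped and excluded from the
#' denominator.
#'
#' @param aln a [locus_alignment()].
#' @param params a [distance_model_params()].
#' @param n_replicates bootstrap replicates (default 1000).
#' @param seed integer seed; the global RNG state is left untouched.
#' @return the NJ tree of the full alignment with numeric node labels in
#'   `[0, 100]` (root label `NA`).
#' @export
bootstrap_support <- function(aln, params = distance_model_params(),
                              n_replicates = 1000, seed = 1) {
  enc <- encode_alignment(aln)
  tree <- neighbor_joining(dist_from_encoded(enc, params))
  splits <- tree_splits(tree)
  keys <- vapply(splits, `[[`, "", "key")
  counts <- stats::setNames(numeric(length(keys)), keys)
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  n_ok <- 0L
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(ncol(enc), ncol(enc), replace = TRUE)
    db <- dist_from_encoded(enc, params, cols)
    if (anyNA(db$d[upper.tri(db$d)])) next
    tb <- ape::nj(stats::as.dist(db$d))
    kb <- vapply(tree_splits(tb), `[[`, "", "key")
    hit <- keys %in% kb
    counts[hit] <- counts[hit] + 1
    n_ok <- n_ok + 1L
  }
  if (n_ok == 0L) stop("all bootstrap replicates failed (undefined distances)")
  labels <- rep(NA_real_, tree$Nnode)
  nt <- length(tree$tip.label)
  for (i in seq_along(splits))
    labels[splits[[i]]$node - nt] <- 100 * counts[[i]] / n_ok
  tree$node.label <- labels
  attr(tree, "n_effective_replicates") <- n_ok
  tree
}

# tip-state matrix (tips x patterns) and per-pattern weights after
# collapsing identical alignment columns
fitch_prepare <- function(aln, tips) {
  miss <- setdiff(tips, aln$ids)
  if (length(miss))
    stop("leaf '", miss[1L], "' has no sequence in the alignment")
  m <- aln_matrix(aln)[tips, , drop = FALSE]
  codes <- FITCH_CODES[m]
  bad <- is.na(codes)
  if (any(bad))
    stop("character '", m[bad][1L], "' cannot be scored")
  st <- matrix(as.integer(codes), nrow = length(tips))
  key <- apply(st, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  list(states = st[, first, drop = FALSE],
       weights = as.vector(table(key)[key[first]]))
}

# Fitch pass over a rooted binary tree given prepared tip states
fitch_score <- function(tree, prep, tips) {
  tr <- tree
  if (!ape::is.rooted(tr))
    tr <- ape::root(tr, outgroup = tr$tip.label[1L], resolve.root = TRUE)
  po <- stats::reorder(tr, "postorder")
  nt <- length(po$tip.label)
  np <- ncol(prep$states)
  states <- matrix(0L, nrow = nt + po$Nnode, ncol = np)
  states[seq_len(nt), ] <- prep$states[match(po$tip.label, tips), ,
                                       drop = FALSE]
  seen <- logical(nt + po$Nnode)
  total <- 0
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]
    ch <- po$edge[i, 2L]
    if (!seen[p]) {
      states[p, ] <- states[ch, ]
      seen[p] <- TRUE
    } else {
      inter <- bitwAnd(states[p, ], states[ch, ])
      zero <- inter == 0L
      if (any(zero)) {
        total <- total + sum(prep$weights[zero])
        inter[zero] <- bitwOr(states[p, ], states[ch, ])[zero]
      }
      states[p, ] <- inter
    }
  }
  total
}

#' Fitch small-parsimony length of a tree on an alignment
#'
#' Minimum number of character changes required, summed over columns.
#' Gaps, `N` and `?` (and any IUPAC ambiguity code) are treated as the
#' corresponding set of nucleotides, never as an extra state; the score is
#' invariant under rerooting.
#'
#' @param tree a `phylo` whose tips all occur in the alignment.
#' @param aln a [locus_alignment()].
#' @return integer parsimony length.
#' @export
fitch_length <- function(tree, aln) {
  prep <- fitch_prepare(aln, tree$tip.label)
  fitch_score(tree, prep, tree$tip.label)
}

#' NNI parsimony search
#'
#' Hill-climbs on [fitch_length()] over nearest-neighbour-interchange
#' rearrangements (neighbour generation via [phangorn::nni()]), starting
#' from the NJ tree by default, until a local optimum or `max_rounds`.
#' With `lookahead = TRUE` (default) a strict single-move local optimum is
#' additionally probed with two-move NNI sequences (variable-depth search),
#' which reliably escapes the shallow valleys of the NNI landscape on small
#' trees at quadratic neighbourhood cost.
#'
#' @param aln a [locus_alignment()].
#' @param start starting `phylo`; default: NJ tree of the TN93 matrix.
#' @param max_rounds maximum improvement rounds (default 100).
#' @param lookahead probe depth-2 NNI moves at local optima (default
#'   TRUE).
#' @return the best tree found (unrooted), with
#'   `attr(, "parsimony_length")`; never longer than the start tree.
#' @export
parsimony_search <- function(aln, start = NULL, max_rounds = 100,
                             lookahead = TRUE) {
  if (is.null(start))
    start <- neighbor_joining(distance_matrix(aln))
  cur <- ape::unroot(start)
  tips <- cur$tip.label
  prep <- fitch_prepare(aln, tips)
  cur_len <- fitch_score(cur, prep, tips)
  for (round in seq_len(max_rounds)) {
    nbrs <- phangorn::nni(cur)
    lens <- vapply(nbrs, fitch_score, 0, prep = prep, tips = tips)
    if (min(lens) < cur_len) {
      cur <- nbrs[[which.min(lens)]]
      cur_len <- min(lens)
      next
    }
    if (!lookahead) break
    improved <- FALSE
    for (i in seq_along(nbrs)) {
      n2 <- phangorn::nni(nbrs[[i]])
      l2 <- vapply(n2, fitch_score, 0, prep = prep, tips = tips)
      if (min(l2) < cur_len) {
        cur <- n2[[which.min(l2)]]
        cur_len <- min(l2)
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  attr(cur, "parsimony_length") <- cur_len
  cur
}

# coerce a labels argument to a named leaf -> taxon vector at the rank
as_rank_labels <- function(labels, rank) {
  if (inherits(labels, "multilocus_dataset")) labels <- labels$specimens
  if (is.data.frame(labels)) {
    stopifnot(all(c("specimen_id", rank) %in% names(labels)))
    stats::setNames(norm_taxon(labels[[rank]]), labels$specimen_id)
  } else {
    stats::setNames(norm_taxon(labels), names(labels))
  }
}

#' Rank-level monophyly percentages on a support-annotated tree
#'
#' A taxon with at least two leaves is monophyletic when some edge of the
#' unrooted tree bipartitions the leaves into exactly that taxon versus the
#' rest; "supported" additionally requires that edge's support to exceed
#' `support_min` (strictly). Taxa with a single leaf are excluded from the
#' percentage, as is customary when reporting rank-level resolution.
#'
#' @param tree a `phylo`; numeric node labels are read as supports (e.g.
#'   from [bootstrap_support()] or an externally supplied newick tree).
#' @param labels leaf taxonomy: metadata data.frame (with `specimen_id` and
#'   the rank column), a [multilocus_dataset()], or a named vector.
#' @param rank `"species"`, `"genus"`, `"family"` or `"order"` (used when
#'   `labels` is tabular).
#' @param support_min support threshold in percent (default 70).
#' @param require_support when `TRUE` (default) the reported percentage
#'   counts only supported monophyletic taxa; otherwise all monophyletic
#'   taxa count.
#' @return an object of class `monophyly_report`: `per_taxon` data.frame
#'   (`taxon`, `n_leaves`, `verdict`, `support`), `percent`,
#'   `n_assessable`, `rank`.
#' @export
monophyly_percent <- function(tree, labels,
                              rank = c("species", "genus", "family",
                                       "order"),
                              support_min = 70, require_support = TRUE) {
  rank <- match.arg(rank)
  lab <- as_rank_labels(labels, rank)
  miss <- setdiff(tree$tip.label, names(lab))
  if (length(miss)) stop("leaf '", miss[1L], "' is unlabeled")
  tip_tax <- lab[tree$tip.label]
  if (any(tip_tax == ""))
    stop("leaf '", tree$tip.label[which(tip_tax == "")[1L]],
         "' has an empty ", rank, " label")
  splits <- tree_splits(tree)
  keys <- vapply(splits, `[[`, "", "key")
  sups <- vapply(splits, `[[`, 0, "support")
  # on a rooted binary tree both root children induce the same unrooted
  # split; keep the best-annotated support for it
  sup_by_key <- vapply(split(sups, keys), function(v)
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE), 0)
  nt <- length(tree$tip.label)
  taxa <- sort(unique(unname(tip_tax)))
  rows <- lapply(taxa, function(tx) {
    leaves <- tree$tip.label[tip_tax == tx]
    k <- length(leaves)
    if (k < 2L)
      return(data.frame(taxon = tx, n_leaves = k,
                        verdict = "excluded_singleton",
                        support = NA_real_, stringsAsFactors = FALSE))
    if (k >= nt - 1L) {
      # the complement is empty or a single leaf: the split exists
      # trivially (whole tree, or the pendant edge of the excluded leaf)
      # but carries no internal-edge support
      return(data.frame(taxon = tx, n_leaves = k,
                        verdict = "monophyletic_unsupported",
                        support = NA_real_, stringsAsFactors = FALSE))
    }
    key <- canonical_split_key(leaves, tree$tip.label)
    if (!key %in% names(sup_by_key))
      return(data.frame(taxon = tx, n_leaves = k,
                        verdict = "non_monophyletic", support = NA_real_,
                        stringsAsFactors = FALSE))
    sup <- sup_by_key[[key]]
    verdict <- if (!is.na(sup) && sup > support_min)
      "monophyletic_supported" else "monophyletic_unsupported"
    data.frame(taxon = tx, n_leaves = k, verdict = verdict, support = sup,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  assessable <- per$verdict != "excluded_singleton"
  n_mono_sup <- sum(per$verdict == "monophyletic_supported")
  n_mono <- n_mono_sup + sum(per$verdict == "monophyletic_unsupported")
  pct <- if (sum(assessable) == 0L) NA_real_ else
    100 * (if (require_support) n_mono_sup else n_mono) / sum(assessable)
  structure(list(per_taxon = per, percent = pct,
                 n_assessable = sum(assessable), rank = rank,
                 support_min = support_min,
                 require_support = require_support),
            class = "monophyly_report")
}

#' @export
print.monophyly_report <- function(x, ...) {
  cat(sprintf("monophyly at %s level: %.1f%% of %d assessable taxa",
              x$rank, x$percent, x$n_assessable),
      if (x$require_support)
        sprintf("(support > %g)", x$support_min) else "(any support)",
      "\n")
  invisible(x)
}

#' Congruence of a tree with reference higher-level groupings
#'
#' Checks, for each named reference group of orders (an APG-style
#' classification), whether the union of the group's leaves is monophyletic
#' by the unrooted bipartition criterion.
#'
#' @param tree a `phylo`.
#' @param order_labels leaf order labels (data.frame, dataset or named
#'   vector; see [monophyly_percent()]).
#' @param reference_groups named list of character vectors of order names.
#' @return data.frame with `group`, `status`
#'   (`recovered` / `not_recovered` / `skipped`) and `n_leaves`; groups
#'   referencing an order absent from the tree are skipped.
#' @export
reference_clade_congruence <- function(tree, order_labels,
                                       reference_groups) {
  lab <- as_rank_labels(order_labels, "order")
  tip_ord <- lab[tree$tip.label]
  if (anyNA(tip_ord) || any(tip_ord == ""))
    stop("every leaf needs an order label")
  present <- unique(unname(tip_ord))
  nt <- length(tree$tip.label)
  keys <- vapply(tree_splits(tree), `[[`, "", "key")
  rows <- lapply(names(reference_groups), function(g) {
    orders <- norm_taxon(reference_groups[[g]])
    if (!all(orders %in% present)) {
      message("reference group '", g, "' references an absent order; ",
              "skipped")
      return(data.frame(group = g, status = "skipped", n_leaves = 0L,
                        stringsAsFactors = FALSE))
    }
    leaves <- tree$tip.label[tip_ord %in% orders]
    k <- length(leaves)
    rec <- if (k <= 1L || k >= nt - 1L) TRUE else
      canonical_split_key(leaves, tree$tip.label) %in% keys
    data.frame(group = g, status = if (rec) "recovered" else
      "not_recovered", n_leaves = k, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a newick tree (supports as internal node labels)
#' @param path newick file.
#' @return a `phylo`.
#' @export
read_tree_newick <- function(path) ape::read.tree(path)

#' Write a tree to newick (supports as internal node labels)
#' @param tree a `phylo`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_tree_newick <- function(tree, path) {
  if (!is.null(tree$node.label) && is.numeric(tree$node.label))
    tree$node.label <- ifelse(is.na(tree$node.label), "",
                              format(tree$node.label, trim = TRUE))
  ape::write.tree(tree, file = path)
  invisible(path)
}
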