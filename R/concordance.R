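# Morphology-versus-molecular identification concordance: assign molecular
# labels from a local reference alignment, then score each specimen's
# agreement at species/genus/family, or flag it incorrect (both loci agree
# on a wrong family) or mislabeled (the two loci disagree at family level).

CONCORDANCE_CATEGORIES <- c("species_match", "genus_match", "family_match",
                            "incorrect", "mislabeled", "unassessed")

#' Construct a taxonomic label
#'
#' @param species,genus,family,order character scalars ("" = no label).
#'   A non-empty species requires a genus, and a non-empty genus a family.
#' @return an object of class `taxon_label`.
#' @export
taxon_label <- function(species = "", genus = "", family = "", order = "") {
  lab <- list(species = as.character(species), genus = as.character(genus),
              family = as.character(family), order = as.character(order))
  lab[vapply(lab, function(x) length(x) == 0 || is.na(x), TRUE)] <- ""
  if (norm_taxon(lab$species) != "" && norm_taxon(lab$genus) == "")
    stop("a species label requires its genus")
  if (norm_taxon(lab$genus) != "" && norm_taxon(lab$family) == "")
    stop("a genus label requires its family")
  structure(lab, class = "taxon_label")
}

# TRUE when the label carries no information at family level or deeper
label_is_empty <- function(lab) {
  is.null(lab) || norm_taxon(lab$family) == ""
}

#' Molecular identification against a local reference alignment
#'
#' Assigns the query the label of its minimum-distance reference sequence.
#' Ties at the minimum (within a 1e-9 relative tolerance) are resolved by
#' truncating the label to the deepest rank shared by all tied references:
#' species if all tied references are one species, else genus, else family,
#' else an empty label.
#'
#' @param query_seq query sequence aligned to the reference coordinates
#'   (same length as the reference alignment).
#' @param ref_aln a [locus_alignment()] of reference sequences.
#' @param ref_labels data.frame with `specimen_id`, `species`, `genus`,
#'   `family` (and optionally `order`) covering the reference members.
#' @param params a [distance_model_params()].
#' @return a [taxon_label()], or `NULL` when no reference distance is
#'   defined (unassessed).
#' @export
nearest_reference_assignment <- function(query_seq, ref_aln, ref_labels,
                                         params = distance_model_params()) {
  stopifnot(inherits(ref_aln, "locus_alignment"))
  if (nchar(query_seq) != ref_aln$length)
    stop("query is not aligned to the reference coordinates (length ",
         nchar(query_seq), " vs ", ref_aln$length, ")")
  d <- vapply(ref_aln$seqs, function(r)
    tn93_distance(pair_counts(query_seq, r), params), 0)
  if (all(is.na(d))) return(NULL)
  dmin <- min(d, na.rm = TRUE)
  hits <- ref_aln$ids[!is.na(d) & d <= dmin * (1 + 1e-9)]
  rl <- ref_labels[match(hits, ref_labels$specimen_id), , drop = FALSE]
  if (anyNA(rl$specimen_id))
    stop("reference sequence without a label: ",
         hits[is.na(rl$specimen_id)][1L])
  ord <- if ("order" %in% names(rl)) rl$order[1L] else ""
  if (length(unique(norm_taxon(rl$species))) == 1L)
    taxon_label(rl$species[1L], rl$genus[1L], rl$family[1L], ord)
  else if (length(unique(norm_taxon(rl$genus))) == 1L)
    taxon_label("", rl$genus[1L], rl$family[1L], ord)
  else if (length(unique(norm_taxon(rl$family))) == 1L)
    taxon_label("", "", rl$family[1L], ord)
  else
    taxon_label()
}

# deepest rank (3 = species, 2 = genus, 1 = family, 0 = none) at which two
# labels agree
match_depth <- function(a, b) {
  if (label_is_empty(a) || label_is_empty(b)) return(0L)
  if (norm_taxon(a$species) != "" && norm_taxon(a$species) ==
        norm_taxon(b$species)) return(3L)
  if (norm_taxon(a$genus) != "" && norm_taxon(a$genus) ==
        norm_taxon(b$genus)) return(2L)
  if (norm_taxon(a$family) == norm_taxon(b$family)) return(1L)
  0L
}

#' Classify one specimen's morphology-vs-molecular concordance
#'
#' Each locus' molecular label is compared with the morphological label;
#' the specimen's category is the deepest rank matched by any locus
#' (`species_match` / `genus_match` / `family_match`). When no locus
#' matches even at family level: `incorrect` if the molecular labels agree
#' with each other at family level (or only one locus yielded a label), and
#' `mislabeled` when two loci are present but disagree at family level
#' (suggesting mislabeling/contamination of the voucher). With no molecular
#' label at any locus the specimen is `unassessed`. Molecular labels empty
#' at family level carry no information and are treated as absent.
#'
#' @param morph morphological [taxon_label()] (family required).
#' @param mol named list of per-locus molecular labels ([taxon_label()] or
#'   `NULL`), e.g. `list(matK = ..., rbcL = ...)`.
#' @return a list (class `concordance_result`) with `category` and
#'   `evidence` (the per-locus labels).
#' @export
classify_concordance <- function(morph, mol) {
  stopifnot(inherits(morph, "taxon_label"))
  if (norm_taxon(morph$family) == "")
    stop("the morphological label must carry at least a family")
  present <- Filter(Negate(label_is_empty), mol)
  res <- list(category = "unassessed", evidence = mol)
  class(res) <- "concordance_result"
  if (length(present) == 0L) return(res)
  depth <- max(vapply(present, match_depth, 0L, b = morph))
  if (depth >= 1L) {
    res$category <- c("family_match", "genus_match",
                      "species_match")[depth]
    return(res)
  }
  if (length(present) >= 2L) {
    fams <- norm_taxon(vapply(present, `[[`, "", "family"))
    res$category <- if (length(unique(fams)) > 1L) "mislabeled"
                    else "incorrect"
  } else {
    res$category <- "incorrect"
  }
  res
}

#' Concordance for every specimen of a dataset
#'
#' Reads the morphological labels and the per-locus molecular label columns
#' (`molecular_<locus>_species` / `_genus` / `_family`) of the metadata
#' table and classifies each specimen with [classify_concordance()].
#'
#' @param ds a [multilocus_dataset()].
#' @param loci loci whose molecular labels to use (default: all loci with
#'   molecular columns present).
#' @return data.frame with `specimen_id` and `category`.
#' @export
dataset_concordance <- function(ds, loci = NULL) {
  meta <- ds$specimens
  if (is.null(loci)) {
    hits <- regmatches(names(meta),
                       regexpr("(?<=^molecular_).*(?=_species$)",
                               names(meta), perl = TRUE))
    loci <- unique(hits)
  }
  if (length(loci) == 0L)
    stop("no molecular label columns found in the metadata")
  get_label <- function(row, prefix) {
    cols <- paste0(prefix, c("species", "genus", "family"))
    vals <- lapply(cols, function(cn)
      if (cn %in% names(meta)) meta[[cn]][row] else "")
    tryCatch(taxon_label(vals[[1L]], vals[[2L]], vals[[3L]]),
             error = function(e) taxon_label())
  }
  cats <- vapply(seq_len(nrow(meta)), function(i) {
    morph <- taxon_label(meta$species[i], meta$genus[i], meta$family[i],
                         meta$order[i])
    mol <- stats::setNames(
      lapply(loci, function(l) get_label(i, paste0("molecular_", l, "_"))),
      loci)
    classify_concordance(morph, mol)$category
  }, "")
  data.frame(specimen_id = meta$specimen_id, category = cats,
             stringsAsFactors = FALSE)
}

#' Summarize concordance categories
#'
#' @param results data.frame from [dataset_concordance()] (or any frame
#'   with a `category` column).
#' @return an object of class `concordance_summary` with per-category
#'   counts and percentages over assessed specimens, plus `n_assessed` and
#'   `n_unassessed`.
#' @export
summarize_concordance <- function(results) {
  cat_col <- results$category
  assessed <- cat_col != "unassessed"
  if (!any(assessed)) stop("no assessed specimens")
  lvl <- setdiff(CONCORDANCE_CATEGORIES, "unassessed")
  counts <- vapply(lvl, function(k) sum(cat_col == k), 0L)
  structure(list(counts = counts,
                 percent = 100 * counts / sum(assessed),
                 n_assessed = sum(assessed),
                 n_unassessed = sum(!assessed)),
            class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat("morphology vs molecular concordance (n assessed =", x$n_assessed,
      ")\n")
  for (k in names(x$counts))
    cat(sprintf("  %-14s %4d (%.1f%%)\n", k, x$counts[[k]],
                x$percent[[k]]))
  invisible(x)
}
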