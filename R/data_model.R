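#' @keywords internal
"_PACKAGE"

# Characters accepted in aligned barcode sequences: IUPAC nucleotide codes,
# the gap '-' and the missing-data marker '?'.
IUPAC_CHARS <- c("A", "C", "G", "T", "U", "M", "R", "W", "S", "Y", "K",
                 "V", "H", "D", "B", "N", "-", "?")

# Missing/non-coverage characters: excluded from trimming coverage and from
# pairwise distance computation. The gap '-' and the missing codes 'N'/'?'
# are all "non-coverage" even though they are biologically distinct.
NON_COVERAGE_CHARS <- c("-", "N", "?")

#' Normalize a taxon name for comparison
#'
#' Comparisons between taxonomic labels are case-insensitive after collapsing
#' internal whitespace; empty strings and `NA` both denote "no label".
#'
#' @param x character vector of taxon names.
#' @return normalized character vector ("" for missing labels).
#' @export
norm_taxon <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Construct a locus alignment
#'
#' A `locus_alignment` holds one locus' aligned sequences: all members have
#' identical (gapped) length and unique specimen ids.
#'
#' @param locus locus name.
#' @param seqs named character vector of aligned sequences (names are
#'   specimen ids). Stored uppercase.
#' @param boundaries optional named integer vector of locus start offsets
#'   (1-based) for concatenated alignments.
#' @return an object of class `locus_alignment` with fields `locus`, `ids`,
#'   `seqs`, `length` and `boundaries`.
#' @export
locus_alignment <- function(locus, seqs, boundaries = NULL) {
  if (length(seqs) == 0L) stop("alignment '", locus, "' has no sequences")
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("all sequences must be named by specimen id")
  if (anyDuplicated(names(seqs)))
    stop("duplicate specimen id in alignment: ",
         names(seqs)[duplicated(names(seqs))][1L])
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("alignment '", locus, "' has unequal sequence lengths (",
         paste(range(lens), collapse = "-"), ")")
  if (any(lens == 0L)) stop("empty sequence in alignment '", locus, "'")
  structure(
    list(locus = locus, ids = names(seqs), seqs = seqs,
         length = unname(lens[1L]), boundaries = boundaries),
    class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("locus_alignment '", x$locus, "': ", length(x$ids),
      " sequences x ", x$length, " columns\n", sep = "")
  invisible(x)
}

# character matrix view (members x columns) of an alignment
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  rownames(m) <- aln$ids
  m
}

# restrict an alignment to a subset of specimen ids (kept in alignment order)
subset_alignment <- function(aln, ids) {
  keep <- aln$ids[aln$ids %in% ids]
  if (length(keep) == 0L)
    stop("no members of alignment '", aln$locus, "' in the requested subset")
  locus_alignment(aln$locus, aln$seqs[keep], boundaries = aln$boundaries)
}

#' Construct a multi-locus barcode dataset
#'
#' Bundles the specimen metadata table (morphological taxonomy and optional
#' per-locus molecular identifications) with one alignment per locus.
#'
#' @param specimens data.frame with columns `specimen_id`, `species`,
#'   `genus`, `family`, `order` (character; "" allowed), plus optional
#'   `molecular_<locus>_species` / `_genus` / `_family` columns.
#' @param alignments named list of [locus_alignment()] objects.
#' @return an object of class `multilocus_dataset`.
#' @export
multilocus_dataset <- function(specimens, alignments = list()) {
  required <- c("specimen_id", "species", "genus", "family", "order")
  miss <- setdiff(required, names(specimens))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  specimens <- as.data.frame(specimens, stringsAsFactors = FALSE)
  for (col in names(specimens))
    specimens[[col]] <- as.character(specimens[[col]])
  specimens[is.na(specimens)] <- ""
  dup <- specimens$specimen_id[duplicated(specimens$specimen_id)]
  if (length(dup))
    stop("duplicate specimen_id in metadata: ", dup[1L])
  # taxonomy nesting invariant: species implies genus implies family
  has_sp  <- norm_taxon(specimens$species) != ""
  has_gen <- norm_taxon(specimens$genus) != ""
  has_fam <- norm_taxon(specimens$family) != ""
  bad <- which((has_sp & !has_gen) | (has_gen & !has_fam))
  if (length(bad))
    stop("specimen '", specimens$specimen_id[bad[1L]],
         "': species/genus labels require the enclosing genus/family")
  for (aln in alignments) {
    stray <- setdiff(aln$ids, specimens$specimen_id)
    if (length(stray))
      stop("alignment '", aln$locus, "' contains id '", stray[1L],
           "' absent from the metadata")
  }
  structure(list(specimens = specimens, alignments = alignments),
            class = "multilocus_dataset")
}

#' @export
print.multilocus_dataset <- function(x, ...) {
  cat("multilocus_dataset: ", nrow(x$specimens), " specimens, ",
      length(x$alignments), " loci (",
      paste(names(x$alignments), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# validate sequence characters, reporting the first offending 1-based position
validate_sequence_chars <- function(seq, id) {
  cls <- paste0(setdiff(IUPAC_CHARS, "-"), collapse = "")
  bad <- regexpr(sprintf("[^%s-]", cls), seq)
  if (bad > 0L)
    stop("sequence '", id, "': non-IUPAC character '",
         substr(seq, bad, bad), "' at position ", bad)
  invisible(TRUE)
}

#' Read a multi-locus dataset from FASTA files and a metadata table
#'
#' @param fasta_paths named character vector mapping locus name to a FASTA
#'   file of aligned sequences; record ids must match `specimen_id` values.
#' @param metadata_path path to a UTF-8 tab-separated table with a header and
#'   columns `specimen_id`, `species`, `genus`, `family`, `order` (plus
#'   optional `molecular_<locus>_*` columns). Specimens present in the
#'   metadata but absent from every FASTA file are retained without
#'   sequences.
#' @return a [multilocus_dataset()].
#' @export
read_dataset <- function(fasta_paths, metadata_path) {
  if (is.null(names(fasta_paths)) || any(names(fasta_paths) == ""))
    stop("fasta_paths must be named by locus")
  meta <- utils::read.delim(metadata_path, sep = "\t", header = TRUE,
                            colClasses = "character",
                            fileEncoding = "UTF-8", check.names = FALSE)
  if (!"specimen_id" %in% names(meta))
    stop("metadata is missing the specimen_id column")
  dup <- meta$specimen_id[duplicated(meta$specimen_id)]
  if (length(dup)) stop("duplicate specimen_id in metadata: ", dup[1L])
  alignments <- list()
  for (locus in names(fasta_paths)) {
    recs <- seqinr::read.fasta(fasta_paths[[locus]], as.string = TRUE,
                               forceDNAtolower = FALSE, seqtype = "DNA")
    seqs <- toupper(vapply(recs, function(r) as.character(r)[1L], ""))
    names(seqs) <- vapply(recs, function(r) attr(r, "name"), "")
    if (anyDuplicated(names(seqs)))
      stop("duplicate FASTA id in locus '", locus, "': ",
           names(seqs)[duplicated(names(seqs))][1L])
    stray <- setdiff(names(seqs), meta$specimen_id)
    if (length(stray))
      stop("FASTA id '", stray[1L], "' (locus '", locus,
           "') missing from metadata")
    for (i in seq_along(seqs))
      validate_sequence_chars(seqs[[i]], names(seqs)[i])
    alignments[[locus]] <- locus_alignment(locus, seqs)
  }
  multilocus_dataset(meta, alignments)
}

#' Write a multi-locus dataset to FASTA files and a metadata table
#'
#' Inverse of [read_dataset()]: emits one FASTA per locus (input order
#' preserved) and the metadata as tab-separated UTF-8.
#'
#' @param ds a [multilocus_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (named list).
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(metadata = file.path(dir, "specimens.tsv"))
  utils::write.table(ds$specimens, paths$metadata, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  for (locus in names(ds$alignments)) {
    aln <- ds$alignments[[locus]]
    p <- file.path(dir, paste0(gsub("[^A-Za-z0-9_.+-]", "_", locus), ".fasta"))
    seqinr::write.fasta(as.list(aln$seqs), names = aln$ids, file.out = p,
                        nbchar = 70)
    paths[[locus]] <- p
  }
  invisible(paths)
}

#' Trim low-coverage alignment ends
#'
#' Removes leading and trailing columns whose fraction of non-gap,
#' non-missing characters (anything other than `-`, `N`, `?`) falls below
#' `min_coverage`. Interior columns are never removed; this reproduces the
#' usual manual practice of trimming ragged alignment ends.
#'
#' @param aln a [locus_alignment()].
#' @param min_coverage required fraction of covered characters per retained
#'   end column, in (0, 1]. Default 0.5.
#' @return a new trimmed [locus_alignment()]; the input is unmodified.
#' @export
trim_alignment_ends <- function(aln, min_coverage = 0.5) {
  stopifnot(inherits(aln, "locus_alignment"))
  if (!is.numeric(min_coverage) || min_coverage <= 0 || min_coverage > 1)
    stop("min_coverage must be in (0, 1]")
  m <- aln_matrix(aln)
  cov <- colMeans(!(matrix(m %in% NON_COVERAGE_CHARS, nrow = nrow(m))))
  ok <- cov >= min_coverage
  if (!any(ok)) stop("empty alignment after trimming")
  first <- which(ok)[1L]
  last <- which(ok)[length(which(ok))]
  seqs <- substr(aln$seqs, first, last)
  names(seqs) <- aln$ids
  locus_alignment(aln$locus, seqs)
}

#' Concatenate loci into a multi-locus barcode alignment
#'
#' Joins the requested loci column-wise, in the given order, keeping only
#' specimens that have a sequence at every requested locus (mirroring an
#' analysis restricted to samples from which all barcodes were recovered).
#'
#' @param ds a [multilocus_dataset()].
#' @param loci character vector of locus names present in `ds`.
#' @return a [locus_alignment()] named `"<locus1>+<locus2>..."` whose
#'   `boundaries` field records each locus' 1-based start offset.
#' @export
concatenate_loci <- function(ds, loci) {
  stopifnot(inherits(ds, "multilocus_dataset"))
  if (length(loci) == 0L) stop("no loci requested for concatenation")
  miss <- setdiff(loci, names(ds$alignments))
  if (length(miss))
    stop("locus '", miss[1L], "' not present in the dataset")
  alns <- ds$alignments[loci]
  shared <- Reduce(intersect, lapply(alns, `[[`, "ids"))
  shared <- ds$specimens$specimen_id[ds$specimens$specimen_id %in% shared]
  if (length(shared) == 0L)
    stop("no specimen carries all requested loci: ",
         paste(loci, collapse = ", "))
  lens <- vapply(alns, `[[`, 0L, "length")
  boundaries <- stats::setNames(cumsum(c(1L, lens[-length(lens)])), loci)
  seqs <- vapply(shared, function(id)
    paste0(vapply(alns, function(a) unname(a$seqs[id]), ""), collapse = ""),
    "")
  locus_alignment(paste(loci, collapse = "+"), seqs, boundaries = boundaries)
}

#' Keep only species with a minimum number of representatives
#'
#' Retains specimens whose morphological species has at least `k` specimens
#' in the dataset (with `k = 2` this is the usual precondition of
#' best-close-match and barcoding-gap analysis). Deterministic: no sampling.
#'
#' @param ds a [multilocus_dataset()].
#' @param k minimum number of specimens per species (positive integer).
#' @return a filtered [multilocus_dataset()] (possibly with zero specimens);
#'   with `k = 1` the dataset is returned unchanged.
#' @export
filter_min_representatives <- function(ds, k = 2) {
  stopifnot(inherits(ds, "multilocus_dataset"), k >= 1)
  if (k == 1) return(ds)
  sp <- norm_taxon(ds$specimens$species)
  counts <- table(sp[sp != ""])
  keep_sp <- names(counts)[counts >= k]
  keep <- sp %in% keep_sp
  specimens <- ds$specimens[keep, , drop = FALSE]
  rownames(specimens) <- NULL
  alignments <- list()
  for (locus in names(ds$alignments)) {
    aln <- ds$alignments[[locus]]
    ids <- aln$ids[aln$ids %in% specimens$specimen_id]
    if (length(ids))
      alignments[[locus]] <- locus_alignment(locus, aln$seqs[ids],
                                             boundaries = aln$boundaries)
  }
  out <- list(specimens = specimens, alignments = alignments)
  class(out) <- "multilocus_dataset"
  out
}

# species labels (normalized) as a named vector id -> species for a dataset
species_labels <- function(ds) {
  stats::setNames(norm_taxon(ds$specimens$species), ds$specimens$specimen_id)
}
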