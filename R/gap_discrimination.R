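# Barcoding-gap analysis (frequency distributions and the global gap test)
# and the per-species local-gap discrimination score.

#' Binned frequency distribution of intra- and interspecific divergences
#'
#' Bins both divergence classes on a shared half-open grid
#' `[k*w, (k+1)*w)` and normalizes frequencies to percent within each class
#' (the layout of the classic barcoding-gap histogram).
#'
#' @param p a `divergence_partition`.
#' @param bin_width positive bin width on the distance scale (default 0.01).
#' @return data.frame with `class` ("intraspecific"/"interspecific"),
#'   `bin_low`, `bin_high`, `count`, `percent`.
#' @export
divergence_histogram <- function(p, bin_width = 0.01) {
  stopifnot(inherits(p, "divergence_partition"))
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("bin_width must be positive")
  vals <- list(intraspecific = p$intra$distance,
               interspecific = p$inter$distance)
  if (sum(lengths(vals)) == 0L)
    stop("empty divergence partition: nothing to bin")
  kmax <- floor(max(unlist(vals)) / bin_width)
  out <- do.call(rbind, lapply(names(vals), function(cl) {
    v <- vals[[cl]]
    if (length(v) == 0L) return(NULL)
    k <- floor(v / bin_width)
    cnt <- vapply(0:kmax, function(i) sum(k == i), 0L)
    data.frame(class = cl, bin_low = (0:kmax) * bin_width,
               bin_high = (1:(kmax + 1L)) * bin_width, count = cnt,
               percent = 100 * cnt / length(v), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Global barcoding-gap test
#'
#' A barcoding gap is present when the minimum interspecific divergence
#' exceeds the maximum intraspecific divergence; otherwise the two
#' distributions overlap on `[min_inter, max_intra]`.
#'
#' @param p a `divergence_partition` with both classes non-empty.
#' @return an object of class `gap_report` with `max_intra`, `min_inter`,
#'   `gap_present`, `overlap_interval` (NULL when a gap exists), and the
#'   mean and range of each class.
#' @export
barcoding_gap_test <- function(p) {
  stopifnot(inherits(p, "divergence_partition"))
  if (nrow(p$intra) == 0L) stop("no intraspecific divergences")
  if (nrow(p$inter) == 0L) stop("no interspecific divergences")
  max_intra <- max(p$intra$distance)
  min_inter <- min(p$inter$distance)
  gap <- min_inter > max_intra
  structure(list(
    max_intra = max_intra, min_inter = min_inter, gap_present = gap,
    overlap_interval = if (gap) NULL else c(min_inter, max_intra),
    mean_intra = mean(p$intra$distance),
    mean_inter = mean(p$inter$distance),
    range_intra = range(p$intra$distance),
    range_inter = range(p$inter$distance)),
    class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat("barcoding gap:", if (x$gap_present) "PRESENT" else "absent", "\n")
  cat(sprintf("  intraspecific: mean %.4g, range [%.4g, %.4g]\n",
              x$mean_intra, x$range_intra[1L], x$range_intra[2L]))
  cat(sprintf("  interspecific: mean %.4g, range [%.4g, %.4g]\n",
              x$mean_inter, x$range_inter[1L], x$range_inter[2L]))
  if (!x$gap_present)
    cat(sprintf("  overlap: [%.4g, %.4g]\n", x$overlap_interval[1L],
                x$overlap_interval[2L]))
  invisible(x)
}

#' Per-species discrimination by the local barcoding-gap criterion
#'
#' A species is discriminated when its maximum conspecific distance is
#' strictly smaller than the minimum distance from any of its members to
#' any heterospecific member. A species sharing an identical barcode
#' (distance 0) with a heterospecific therefore necessarily fails. Species
#' with no defined heterospecific (or no defined conspecific) distance are
#' reported unassessable and excluded from the denominator.
#'
#' @param m a `divergence_matrix`.
#' @param labels species labels (see [partition_divergences()]); every
#'   species must have at least two specimens.
#' @return an object of class `discrimination_report` with `per_species`
#'   (data.frame: `species`, `max_intra`, `min_inter`, `discriminated`),
#'   `n_species` (assessable), `n_discriminated`, `percent` and
#'   `unassessable` (character vector).
#' @export
species_discrimination <- function(m, labels) {
  labels <- as_species_labels(labels)
  sp <- labels[m$ids]
  if (anyNA(sp) || any(sp == ""))
    stop("every specimen in the matrix needs a species label")
  tab <- table(sp)
  if (any(tab < 2L))
    stop("species '", names(tab)[tab < 2L][1L], "' has a single ",
         "representative; apply filter_min_representatives(k = 2) first")
  species <- sort(unique(unname(sp)))
  rows <- lapply(species, function(s) {
    mem <- sp == s
    din <- m$d[mem, mem]
    din <- din[upper.tri(din)]
    dout <- m$d[mem, !mem]
    max_in <- if (all(is.na(din))) NA_real_ else max(din, na.rm = TRUE)
    min_out <- if (all(is.na(dout))) NA_real_ else min(dout, na.rm = TRUE)
    data.frame(species = s, max_intra = max_in, min_inter = min_out,
               discriminated = if (is.na(max_in) || is.na(min_out))
                 NA else max_in < min_out,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  assessable <- !is.na(per$discriminated)
  n_disc <- sum(per$discriminated[assessable])
  structure(list(
    per_species = per, n_species = sum(assessable),
    n_discriminated = n_disc,
    percent = if (sum(assessable)) 100 * n_disc / sum(assessable)
              else NA_real_,
    unassessable = per$species[!assessable]),
    class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat(sprintf("species discrimination: %d/%d (%.1f%%)",
              x$n_discriminated, x$n_species, x$percent))
  if (length(x$unassessable))
    cat(";", length(x$unassessable), "unassessable")
  cat("\n")
  invisible(x)
}
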