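# Best-close-match identification: every barcode queries all others; only
# matches within a dataset-derived threshold T (the 95th percentile of
# intraspecific divergence) are accepted, and the species of the nearest
# match(es) decides correct / ambiguous / incorrect / unidentified.

BCM_CATEGORIES <- c("correct", "ambiguous", "incorrect", "unidentified")

#' Best-close-match configuration
#'
#' @param threshold `"auto"` (derive T from the dataset's intraspecific
#'   divergences) or an explicit non-negative distance.
#' @param percentile percentile of intraspecific distances defining the
#'   automatic threshold (default 0.95).
#' @param tie_rel_tol relative tolerance on the minimum distance when
#'   collecting tied nearest matches (default 1e-9); guards against
#'   floating-point fragility of exact-equality ties.
#' @return an object of class `bcm_config`.
#' @export
bcm_config <- function(threshold = "auto", percentile = 0.95,
                       tie_rel_tol = 1e-9) {
  if (!identical(threshold, "auto")) {
    if (!is.numeric(threshold) || threshold < 0)
      stop("threshold must be \"auto\" or a non-negative distance")
  }
  if (!is.numeric(percentile) || percentile <= 0 || percentile >= 1)
    stop("percentile must lie in (0, 1)")
  structure(list(threshold = threshold, percentile = percentile,
                 tie_rel_tol = tie_rel_tol), class = "bcm_config")
}

#' Empirical percentile threshold from intraspecific divergences
#'
#' T is the smallest intraspecific distance `x` such that at least
#' `ceiling(percentile * n)` of the `n` intraspecific distances are `<= x`
#' (the empirical quantile without interpolation, i.e. the divergence below
#' which the stated share of all intraspecific distances is found).
#'
#' @param x a `divergence_partition` or a numeric vector of intraspecific
#'   distances.
#' @param percentile fraction in (0, 1]; default 0.95.
#' @return the threshold T.
#' @export
compute_threshold <- function(x, percentile = 0.95) {
  if (inherits(x, "divergence_partition")) x <- x$intra$distance
  x <- x[!is.na(x)]
  if (length(x) == 0L)
    stop("no intraspecific distances: threshold undefined")
  if (!is.numeric(percentile) || percentile <= 0 || percentile > 1)
    stop("percentile must lie in (0, 1]")
  sort(x)[ceiling(percentile * length(x))]
}

#' Classify one query under the best-close-match rules
#'
#' The query's database is every other sequence in the matrix with a defined
#' distance to it. With `d_min` the smallest such distance: if `d_min > T`
#' (or no defined distance exists) the query is `unidentified`; otherwise
#' the match set holds every database entry within `d_min * (1 +
#' tie_rel_tol)`, and the query is `correct` when all match species equal
#' its own, `ambiguous` when they include its own plus at least one other,
#' and `incorrect` when they exclude it.
#'
#' @param query_id specimen id present in `m`.
#' @param m a `divergence_matrix`.
#' @param labels species labels (see [partition_divergences()]).
#' @param threshold the threshold T.
#' @param tie_rel_tol relative tie tolerance (default 1e-9).
#' @return a list (class `bcm_record`) with `query_id`, `category`,
#'   `min_distance`, `match_ids` and `match_species`.
#' @export
classify_query <- function(query_id, m, labels, threshold,
                           tie_rel_tol = 1e-9) {
  if (!query_id %in% m$ids)
    stop("query '", query_id, "' is not in the distance matrix")
  labels <- as_species_labels(labels)
  d <- m$d[query_id, m$ids != query_id]
  defined <- !is.na(d)
  res <- list(query_id = query_id, category = "unidentified",
              min_distance = NA_real_, match_ids = character(0),
              match_species = character(0))
  class(res) <- "bcm_record"
  if (!any(defined)) return(res)
  dmin <- min(d[defined])
  res$min_distance <- dmin
  if (dmin > threshold) return(res)
  hits <- names(d)[defined & d <= dmin * (1 + tie_rel_tol)]
  hit_sp <- unique(unname(labels[hits]))
  qsp <- unname(labels[query_id])
  res$match_ids <- hits
  res$match_species <- hit_sp
  res$category <- if (all(hit_sp == qsp)) "correct"
    else if (qsp %in% hit_sp) "ambiguous" else "incorrect"
  res
}

#' Best-close-match identification test over a whole dataset
#'
#' Every sequence serves once as query against all others. The dataset must
#' already be restricted to species with at least two representatives
#' (otherwise conspecific matches are impossible by construction); use
#' [filter_min_representatives()] first.
#'
#' @param m a `divergence_matrix` over the filtered specimens.
#' @param labels species labels (see [partition_divergences()]).
#' @param cfg a [bcm_config()]. With `threshold = "auto"`, T is the
#'   `percentile` empirical quantile of this matrix's intraspecific
#'   distances.
#' @return list with `records` (data.frame: `query_id`, `category`,
#'   `min_distance`, `match_ids`, `match_species`; match columns
#'   `;`-collapsed) and `summary` (class `bcm_summary`: per-category counts
#'   and percentages, `threshold`, `n_queries`).
#' @export
best_close_match <- function(m, labels, cfg = bcm_config()) {
  labels <- as_species_labels(labels)
  sp <- labels[m$ids]
  if (anyNA(sp) || any(sp == ""))
    stop("every specimen in the matrix needs a species label")
  tab <- table(sp)
  if (any(tab < 2L))
    stop("species '", names(tab)[tab < 2L][1L], "' has a single ",
         "representative; apply filter_min_representatives(k = 2) first")
  threshold <- cfg$threshold
  if (identical(threshold, "auto")) {
    part <- partition_divergences(m, labels)
    threshold <- compute_threshold(part, cfg$percentile)
  }
  recs <- lapply(m$ids, classify_query, m = m, labels = labels,
                 threshold = threshold, tie_rel_tol = cfg$tie_rel_tol)
  records <- data.frame(
    query_id = vapply(recs, `[[`, "", "query_id"),
    category = vapply(recs, `[[`, "", "category"),
    min_distance = vapply(recs, `[[`, 0, "min_distance"),
    match_ids = vapply(recs, function(r)
      paste(r$match_ids, collapse = ";"), ""),
    match_species = vapply(recs, function(r)
      paste(r$match_species, collapse = ";"), ""),
    stringsAsFactors = FALSE)
  counts <- vapply(BCM_CATEGORIES, function(k) sum(records$category == k), 0L)
  summary <- structure(
    list(counts = counts, percent = 100 * counts / nrow(records),
         threshold = threshold, n_queries = nrow(records)),
    class = "bcm_summary")
  list(records = records, summary = summary)
}

#' @export
print.bcm_summary <- function(x, ...) {
  cat("best-close match: n =", x$n_queries, ", T =",
      format(x$threshold, digits = 6), "\n")
  for (k in names(x$counts))
    cat(sprintf("  %-13s %4d (%.1f%%)\n", k, x$counts[[k]], x$percent[[k]]))
  invisible(x)
}
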