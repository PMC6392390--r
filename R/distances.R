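# Pairwise divergence engine: p-distance and Tamura-Nei (1993) with optional
# continuous-gamma rate correction, pairwise deletion of gap/missing sites,
# and empirical base frequencies pooled over each pair.

BASE_CODES <- c(A = 1L, C = 2L, G = 3L, T = 4L)

# encode an alignment as an integer matrix (members x columns);
# anything other than A/C/G/T (gaps, missing, ambiguity codes) becomes NA
# and is excluded by pairwise deletion.
encode_alignment <- function(aln) {
  m <- aln_matrix(aln)
  e <- matrix(BASE_CODES[m], nrow = nrow(m))
  rownames(e) <- aln$ids
  e
}

#' Distance model parameters
#'
#' @param model `"tn93"` (Tamura-Nei 1993) or `"p"` (proportion of differing
#'   sites).
#' @param gamma_shape optional positive gamma shape parameter `a` for
#'   among-site rate variation; each logarithmic term `-log(x)` of the TN93
#'   estimator is replaced by `a * (x^(-1/a) - 1)`. `NULL` (default) applies
#'   no correction. Only meaningful for `model = "tn93"`.
#' @return an object of class `distance_model_params`.
#' @export
distance_model_params <- function(model = c("tn93", "p"), gamma_shape = NULL) {
  model <- match.arg(model)
  if (!is.null(gamma_shape)) {
    if (model != "tn93")
      stop("gamma_shape is only meaningful for the tn93 model")
    if (!is.numeric(gamma_shape) || gamma_shape <= 0)
      stop("gamma_shape must be a positive real")
  }
  structure(list(model = model, gamma_shape = gamma_shape,
                 deletion = "pairwise"),
            class = "distance_model_params")
}

#' Site-pattern counts for one sequence pair
#'
#' Applies pairwise deletion: any site where either sequence carries a gap,
#' missing code or ambiguity code is excluded. The remaining sites yield the
#' fractions of purine transitions (A/G), pyrimidine transitions (C/T) and
#' transversions, plus base frequencies pooled over both sequences.
#'
#' @param seq_a,seq_b aligned sequences of equal length (character strings).
#' @return an object of class `pair_counts` with fields `n_sites`, `P1`,
#'   `P2`, `Q` and `freqs` (named A, C, G, T). With `n_sites = 0` the pair
#'   has no comparable sites and any distance computed from it is undefined.
#' @export
pair_counts <- function(seq_a, seq_b) {
  if (is.character(seq_a) && length(seq_a) == 1L) {
    if (nchar(seq_a) != nchar(seq_b))
      stop("sequences have unequal lengths (", nchar(seq_a), " vs ",
           nchar(seq_b), ")")
    a <- BASE_CODES[strsplit(toupper(seq_a), "", fixed = TRUE)[[1L]]]
    b <- BASE_CODES[strsplit(toupper(seq_b), "", fixed = TRUE)[[1L]]]
  } else {
    if (length(seq_a) != length(seq_b))
      stop("sequences have unequal lengths")
    a <- seq_a
    b <- seq_b
  }
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n == 0L)
    return(structure(list(n_sites = 0L, P1 = NA_real_, P2 = NA_real_,
                          Q = NA_real_,
                          freqs = c(A = NA_real_, C = NA_real_,
                                    G = NA_real_, T = NA_real_)),
                     class = "pair_counts"))
  a <- a[ok]
  b <- b[ok]
  ts_ag <- sum((a == 1L & b == 3L) | (a == 3L & b == 1L))
  ts_ct <- sum((a == 2L & b == 4L) | (a == 4L & b == 2L))
  ndiff <- sum(a != b)
  freqs <- (tabulate(a, 4L) + tabulate(b, 4L)) / (2 * n)
  names(freqs) <- names(BASE_CODES)
  structure(list(n_sites = n, P1 = ts_ag / n, P2 = ts_ct / n,
                 Q = (ndiff - ts_ag - ts_ct) / n, freqs = freqs),
            class = "pair_counts")
}

# vectorized TN93 closed form. P1, P2, Q and the four frequency vectors are
# equal-length numerics; returns the distance with NA where the estimator is
# out of range (a log/power argument <= 0, or observed changes of a class
# whose expected frequency is zero).
tn93_core <- function(P1, P2, Q, fA, fC, fG, fT, gamma_shape = NULL) {
  gfun <- if (is.null(gamma_shape)) {
    function(x) -log(x)
  } else {
    function(x) gamma_shape * (x^(-1 / gamma_shape) - 1)
  }
  div0 <- function(num, den) ifelse(den > 0, num / ifelse(den > 0, den, 1), 0)
  pR <- fA + fG
  pY <- fC + fT
  k1 <- div0(2 * fA * fG, pR)
  k2 <- div0(2 * fT * fC, pY)
  k3 <- 2 * (pR * pY - div0(fA * fG * pY, pR) - div0(fT * fC * pR, pY))
  w1 <- 1 - div0(P1, k1) - div0(Q, 2 * pR)
  w2 <- 1 - div0(P2, k2) - div0(Q, 2 * pY)
  w3 <- 1 - div0(Q, 2 * pR * pY)
  val <- rep(0, length(P1))
  undef <- is.na(P1)
  add_term <- function(k, P, w) {
    undef <<- undef | (!is.na(P) & ((k <= 0 & P > 0) | (k > 0 & w <= 0)))
    ok <- !is.na(P) & k > 0 & w > 0
    val[ok] <<- val[ok] + k[ok] * gfun(w[ok])
  }
  add_term(k1, P1, w1)
  add_term(k2, P2, w2)
  add_term(k3, Q, w3)
  val[undef] <- NA_real_
  val
}

#' Tamura-Nei (1993) distance from site-pattern counts
#'
#' Evaluates the TN93 closed-form distance (expected substitutions per site)
#' from the transition/transversion fractions and pooled base frequencies of
#' a sequence pair. When `params$gamma_shape = a` is set, each `-log(x)`
#' term is replaced by the standard gamma correction `a * (x^(-1/a) - 1)`.
#' Out-of-range estimator arguments (saturation) yield `NA` rather than a
#' truncated value, so undefined pairs can be excluded downstream instead of
#' silently biasing the analysis.
#'
#' @param counts a [pair_counts()] object.
#' @param params a [distance_model_params()] object.
#' @return the distance, or `NA` when undefined.
#' @export
tn93_distance <- function(counts, params = distance_model_params()) {
  stopifnot(inherits(counts, "pair_counts"),
            inherits(params, "distance_model_params"))
  if (counts$n_sites == 0L) return(NA_real_)
  if (params$model == "p") return(counts$P1 + counts$P2 + counts$Q)
  f <- counts$freqs
  tn93_core(counts$P1, counts$P2, counts$Q, f[["A"]], f[["C"]], f[["G"]],
            f[["T"]], gamma_shape = params$gamma_shape)
}

# distance matrix from an encoded alignment (optionally on resampled
# columns, used by the bootstrap). Computed with dense indicator-matrix
# products so the whole matrix is obtained in a handful of BLAS calls.
dist_from_encoded <- function(enc, params, cols = NULL) {
  if (!is.null(cols)) enc <- enc[, cols, drop = FALSE]
  ids <- rownames(enc)
  okm <- !is.na(enc)
  storage.mode(okm) <- "double"
  ind <- lapply(1:4, function(b) {
    m <- !is.na(enc) & enc == b
    storage.mode(m) <- "double"
    m
  })
  n_ab <- okm %*% t(okm)
  same <- Reduce(`+`, lapply(ind, function(m) m %*% t(m)))
  ag <- ind[[1L]] %*% t(ind[[3L]])
  ag <- ag + t(ag)
  ct <- ind[[2L]] %*% t(ind[[4L]])
  ct <- ct + t(ct)
  diffs <- n_ab - same
  safe <- ifelse(n_ab > 0, n_ab, NA_real_)
  if (params$model == "p") {
    d <- diffs / safe
  } else {
    counts2 <- lapply(ind, function(m) {
      cm <- m %*% t(okm)
      cm + t(cm)
    })
    P1 <- ag / safe
    P2 <- ct / safe
    Q <- (diffs - ag - ct) / safe
    fA <- counts2[[1L]] / (2 * safe)
    fC <- counts2[[2L]] / (2 * safe)
    fG <- counts2[[3L]] / (2 * safe)
    fT <- counts2[[4L]] / (2 * safe)
    d <- matrix(tn93_core(as.vector(P1), as.vector(P2), as.vector(Q),
                          as.vector(fA), as.vector(fC), as.vector(fG),
                          as.vector(fT), gamma_shape = params$gamma_shape),
                nrow = nrow(enc))
  }
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, d = d, params = params),
            class = "divergence_matrix")
}

#' Pairwise divergence matrix over an alignment
#'
#' Computes all unordered pairwise distances under the chosen model with
#' pairwise deletion. Undefined pairs (no comparable sites, or TN93
#' saturation) are flagged as `NA` rather than truncated.
#'
#' @param aln a [locus_alignment()] with at least two members.
#' @param params a [distance_model_params()].
#' @return an object of class `divergence_matrix` with fields `ids`, `d`
#'   (symmetric numeric matrix, zero diagonal, `NA` = undefined) and
#'   `params`.
#' @export
distance_matrix <- function(aln, params = distance_model_params()) {
  stopifnot(inherits(aln, "locus_alignment"))
  if (length(aln$ids) < 2L)
    stop("at least two sequences are required for a distance matrix")
  dist_from_encoded(encode_alignment(aln), params)
}

#' @export
print.divergence_matrix <- function(x, ...) {
  nund <- sum(is.na(x$d[upper.tri(x$d)]))
  cat("divergence_matrix: ", length(x$ids), " specimens, model ",
      x$params$model,
      if (!is.null(x$params$gamma_shape))
        paste0(" (gamma a=", x$params$gamma_shape, ")") else "",
      ", ", nund, " undefined pair(s)\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.divergence_matrix <- function(x, ...) x$d

#' @export
as.dist.divergence_matrix <- function(m, ...) stats::as.dist(m$d)

#' Write a divergence matrix to disk
#'
#' @param m a `divergence_matrix`.
#' @param path output file.
#' @param format `"tsv"` for long format (`id_a`, `id_b`, `distance`,
#'   `defined`) or `"phylip"` for lower-triangular PHYLIP-style text
#'   (undefined entries written as `NA`).
#' @return invisibly, `path`.
#' @export
write_distance_matrix <- function(m, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "phylip") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(as.character(length(m$ids)), con)
    for (i in seq_along(m$ids)) {
      vals <- if (i == 1L) character(0) else
        formatC(m$d[i, seq_len(i - 1L)], format = "g", digits = 10)
      writeLines(paste(c(m$ids[i], vals), collapse = "\t"), con)
    }
  } else {
    idx <- which(upper.tri(m$d), arr.ind = TRUE)
    df <- data.frame(id_a = m$ids[idx[, 1L]], id_b = m$ids[idx[, 2L]],
                     distance = m$d[idx], defined = !is.na(m$d[idx]))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Split pairwise divergences into intra- and interspecific sets
#'
#' @param m a `divergence_matrix`.
#' @param labels species labels: either a named character vector
#'   (specimen id -> species) or a data.frame with `specimen_id` and
#'   `species` columns (e.g. the `specimens` table of a dataset). Names are
#'   normalized with [norm_taxon()].
#' @return an object of class `divergence_partition` with data.frames
#'   `intra` (`species`, `distance`) and `inter` (`species_a`, `species_b`,
#'   `distance`). Undefined distances are excluded from both;
#'   `attr(, "n_undefined")` counts them.
#' @export
partition_divergences <- function(m, labels) {
  labels <- as_species_labels(labels)
  miss <- setdiff(m$ids, names(labels))
  if (length(miss))
    stop("specimen '", miss[1L], "' has no species label")
  sp <- labels[m$ids]
  if (any(sp == ""))
    stop("specimen '", m$ids[which(sp == "")[1L]],
         "' has an empty species label")
  idx <- which(upper.tri(m$d), arr.ind = TRUE)
  d <- m$d[idx]
  defined <- !is.na(d)
  sa <- sp[idx[, 1L]]
  sb <- sp[idx[, 2L]]
  same <- sa == sb
  intra <- data.frame(species = sa[same & defined],
                      distance = d[same & defined],
                      stringsAsFactors = FALSE)
  inter <- data.frame(species_a = pmin(sa, sb)[!same & defined],
                      species_b = pmax(sa, sb)[!same & defined],
                      distance = d[!same & defined],
                      stringsAsFactors = FALSE)
  structure(list(intra = intra, inter = inter),
            class = "divergence_partition",
            n_undefined = sum(!defined))
}

# coerce labels argument to a named, normalized species vector
as_species_labels <- function(labels) {
  if (is.data.frame(labels)) {
    stopifnot(all(c("specimen_id", "species") %in% names(labels)))
    stats::setNames(norm_taxon(labels$species), labels$specimen_id)
  } else if (inherits(labels, "multilocus_dataset")) {
    species_labels(labels)
  } else {
    stats::setNames(norm_taxon(labels), names(labels))
  }
}

#' @export
print.divergence_partition <- function(x, ...) {
  cat("divergence_partition: ", nrow(x$intra), " intraspecific, ",
      nrow(x$inter), " interspecific distances\n", sep = "")
  invisible(x)
}

#' Welch's unequal-variance two-sample t-test
#'
#' Thin wrapper around [stats::t.test()] used to compare intraspecific and
#' interspecific divergence sets.
#'
#' @param x,y numeric samples with at least two values each and nonzero
#'   variance in at least one sample.
#' @return list with `t`, `df` (Welch-Satterthwaite) and `p_value`
#'   (two-sided).
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least two values")
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("both samples are degenerate (zero variance)")
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Classical one-way analysis of variance
#'
#' @param groups list of numeric vectors (>= 2 groups, each with >= 2
#'   values; within-group variance must not be zero everywhere).
#' @return list with `F`, `df_between`, `df_within` and `p_value`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L) stop("at least two groups are required")
  if (any(lengths(groups) < 2L))
    stop("each group needs at least two values")
  if (all(vapply(groups, stats::var, 0) == 0))
    stop("all within-group variances are zero")
  v <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  a <- stats::anova(stats::lm(v ~ g))
  list(F = a[["F value"]][1L], df_between = a$Df[1L], df_within = a$Df[2L],
       p_value = a[["Pr(>F)"]][1L])
}
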