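# Independent oracles and fixture builders shared across the test files.
# Oracles are deliberately written as direct transcriptions of the
# closed-form definitions (scalar, no shared code with the package paths
# they check).

# literal TN93 closed form, scalar; a = gamma shape or NULL
tn93_reference <- function(P1, P2, Q, freqs, a = NULL) {
  pA <- freqs[1]; pC <- freqs[2]; pG <- freqs[3]; pT <- freqs[4]
  pR <- pA + pG; pY <- pC + pT
  k1 <- 2 * pA * pG / pR
  k2 <- 2 * pT * pC / pY
  k3 <- 2 * (pR * pY - pA * pG * pY / pR - pT * pC * pR / pY)
  w1 <- 1 - P1 / k1 - Q / (2 * pR)
  w2 <- 1 - P2 / k2 - Q / (2 * pY)
  w3 <- 1 - Q / (2 * pR * pY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) return(NA_real_)
  g <- if (is.null(a)) function(x) -log(x) else
    function(x) a * (x^(-1 / a) - 1)
  k1 * g(w1) + k2 * g(w2) + k3 * g(w3)
}

# pair_counts-shaped object from bare numbers (for closed-form checks)
make_counts <- function(P1, P2, Q, freqs, n_sites = 1000L) {
  structure(list(n_sites = n_sites, P1 = P1, P2 = P2, Q = Q,
                 freqs = stats::setNames(freqs, c("A", "C", "G", "T"))),
            class = "pair_counts")
}

# TN93 rate matrix (rows = from, order A,C,G,T), scaled to one expected
# substitution per unit branch length; used with Matrix::expm as the
# transition-probability oracle for the simulator
tn93_rate_matrix <- function(freqs, kappa_R, kappa_Y) {
  f <- unname(freqs[c("A", "C", "G", "T")])
  R <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    rate <- f[j]
    if ((i == 1 && j == 3) || (i == 3 && j == 1)) rate <- rate * kappa_R
    if ((i == 2 && j == 4) || (i == 4 && j == 2)) rate <- rate * kappa_Y
    R[i, j] <- rate
  }
  diag(R) <- -rowSums(R)
  mu <- -sum(f * diag(R))
  R / mu
}

# brute-force best-close-match classifier: plain loops, no shared code
brute_bcm <- function(dmat, labels, threshold, tie_rel_tol = 1e-9) {
  ids <- rownames(dmat)
  out <- character(length(ids))
  names(out) <- ids
  for (q in ids) {
    ds <- dmat[q, setdiff(ids, q)]
    ds <- ds[!is.na(ds)]
    if (length(ds) == 0 || min(ds) > threshold) {
      out[q] <- "unidentified"
      next
    }
    dmin <- min(ds)
    hits <- names(ds)[ds <= dmin * (1 + tie_rel_tol)]
    spp <- unique(labels[hits])
    qsp <- labels[[q]]
    out[q] <- if (all(spp == qsp)) "correct" else
      if (qsp %in% spp) "ambiguous" else "incorrect"
  }
  out
}

# wrap a symmetric matrix as a divergence_matrix
as_divmat <- function(dmat, params = distance_model_params()) {
  structure(list(ids = rownames(dmat), d = dmat, params = params),
            class = "divergence_matrix")
}

# random symmetric specimen distance matrix with conspecific clustering and
# optional ties (values on a coarse grid)
random_bcm_case <- function(n_species, per_species = 2, grid = NULL) {
  ids <- unlist(lapply(seq_len(n_species), function(s)
    paste0("sp", s, "_", seq_len(per_species))))
  labels <- stats::setNames(rep(paste0("sp", seq_len(n_species)),
                                each = per_species), ids)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same <- labels[i] == labels[j]
    v <- if (same) stats::runif(1, 0, 0.02) else stats::runif(1, 0, 0.3)
    if (!is.null(grid)) v <- grid * round(v / grid)
    d[i, j] <- d[j, i] <- v
  }
  list(d = d, labels = labels)
}

# divergence_partition from bare numeric vectors
make_partition <- function(intra, inter) {
  structure(list(
    intra = data.frame(species = rep("s", length(intra)),
                       distance = intra, stringsAsFactors = FALSE),
    inter = data.frame(species_a = rep("a", length(inter)),
                       species_b = rep("b", length(inter)),
                       distance = inter, stringsAsFactors = FALSE)),
    class = "divergence_partition", n_undefined = 0L)
}

# evolve an alignment down a given tree under the package's TN93 process
simulate_on_tree <- function(tree, L, config) {
  po <- ape::reorder.phylo(tree, "cladewise")
  nt <- length(tree$tip.label)
  root <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                       prob = config$base_freqs), collapse = "")
  seqs <- vector("list", nt + tree$Nnode)
  seqs[[nt + 1L]] <- root
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]
    ch <- po$edge[i, 2L]
    seqs[[ch]] <- evolve_sequence(seqs[[p]], po$edge.length[i], config)
  }
  locus_alignment("sim", stats::setNames(unlist(seqs[seq_len(nt)]),
                                         tree$tip.label))
}

# small deterministic two-locus dataset used by IO / concatenation tests
toy_dataset <- function() {
  meta <- data.frame(
    specimen_id = c("S1", "S2", "S3", "S4"),
    species = c("Ficus alba", "Ficus alba", "Litsea rubra", "Litsea rubra"),
    genus = c("Ficus", "Ficus", "Litsea", "Litsea"),
    family = c("Moraceae", "Moraceae", "Lauraceae", "Lauraceae"),
    order = c("Rosales", "Rosales", "Laurales", "Laurales"),
    stringsAsFactors = FALSE)
  a1 <- locus_alignment("matK", c(S1 = "ACGTACGTAC", S2 = "ACGTACGTAC",
                                  S3 = "ACGTTCGAAC", S4 = "ACGTTCGAAC"))
  a2 <- locus_alignment("rbcL", c(S1 = "GGGCCC", S2 = "GGGCCC",
                                  S3 = "GGTCCC", S4 = "GGTCCC"))
  multilocus_dataset(meta, list(matK = a1, rbcL = a2))
}
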