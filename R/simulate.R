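# Multi-locus barcode simulator under the TN93(+gamma) substitution process
# the distance estimator assumes. Generates a balanced
# family/genus/species/individual hierarchy with known ground truth:
# shared-barcode species (identical species-level barcodes within a genus),
# planted morphological mislabels, and per-locus sequence dropout.

#' Simulation configuration
#'
#' Defaults emulate the divergence regime of tropical plant two-locus
#' barcode surveys: two specimens per species, intraspecific divergence
#' near 0.001 and interspecific divergence of order 0.1-0.3, with a tenth
#' of the species sharing their barcode with a congener and a twentieth of
#' the specimens mislabeled.
#'
#' @param seed integer master seed; every random choice derives from it.
#' @param n_families,genera_per_family,species_per_genus balanced taxonomy
#'   sizes (defaults 5, 2, 5 = 50 species).
#' @param specimens_per_species specimens per species (default 2).
#' @param loci named integer vector of locus lengths in bp (default
#'   `c(matK = 800, rbcL = 550)`).
#' @param base_freqs equilibrium base frequencies (A, C, G, T), summing
#'   to 1.
#' @param kappa_R,kappa_Y purine (A/G) and pyrimidine (C/T)
#'   transition/transversion rate factors (default 2).
#' @param gamma_shape optional positive gamma shape for continuous
#'   among-site rate multipliers (mean 1), drawn once per locus and fixed
#'   across branches; `NULL` = equal rates.
#' @param b_family,b_genus,b_species,b_individual branch lengths in
#'   expected substitutions/site for each hierarchy level. Two conspecific
#'   specimens are `2 * b_individual` apart in expectation (default
#'   `2 * 5e-4 = 0.001`).
#' @param frac_shared_barcode fraction of species placed in within-genus
#'   barcode-sharing groups (identical species ancestors); exactly
#'   `floor(frac * n_species)` species are flagged.
#' @param frac_mislabeled fraction of specimens whose morphological label
#'   is swapped with a species from a different family; exactly
#'   `floor(frac * n_specimens)` specimens.
#' @param dropout_by_locus named fractions of specimens lacking each locus
#'   (default: none). Setting e.g. `c(matK = 0.34, rbcL = 0.05)` emulates
#'   the uneven sequence recoverability of the two standard plant loci.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1, n_families = 5,
                              genera_per_family = 2, species_per_genus = 5,
                              specimens_per_species = 2,
                              loci = c(matK = 800, rbcL = 550),
                              base_freqs = c(A = 0.31, C = 0.17, G = 0.21,
                                             T = 0.31),
                              kappa_R = 2, kappa_Y = 2, gamma_shape = NULL,
                              b_family = 0.05, b_genus = 0.05,
                              b_species = 0.05, b_individual = 5e-4,
                              frac_shared_barcode = 0.1,
                              frac_mislabeled = 0.05,
                              dropout_by_locus = numeric(0)) {
  stopifnot(n_families >= 1, genera_per_family >= 1,
            species_per_genus >= 1, specimens_per_species >= 1,
            length(loci) >= 1, !is.null(names(loci)))
  if (abs(sum(base_freqs) - 1) > 1e-9)
    stop("base_freqs must sum to 1")
  if (any(base_freqs < 0)) stop("base_freqs must be non-negative")
  for (b in c(b_family, b_genus, b_species, b_individual))
    if (b < 0) stop("branch lengths must be non-negative")
  for (f in c(frac_shared_barcode, frac_mislabeled, dropout_by_locus))
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  if (!is.null(gamma_shape) && gamma_shape <= 0)
    stop("gamma_shape must be positive")
  if (frac_shared_barcode > 0 && species_per_genus < 2)
    stop("shared-barcode species need a congener: species_per_genus >= 2")
  structure(list(seed = seed, n_families = n_families,
                 genera_per_family = genera_per_family,
                 species_per_genus = species_per_genus,
                 specimens_per_species = specimens_per_species,
                 loci = loci,
                 base_freqs = base_freqs[c("A", "C", "G", "T")],
                 kappa_R = kappa_R, kappa_Y = kappa_Y,
                 gamma_shape = gamma_shape, b_family = b_family,
                 b_genus = b_genus, b_species = b_species,
                 b_individual = b_individual,
                 frac_shared_barcode = frac_shared_barcode,
                 frac_mislabeled = frac_mislabeled,
                 dropout_by_locus = dropout_by_locus),
            class = "simulation_config")
}

# deterministic 31-bit sub-seed from the master seed and a stream tag, so
# adding a locus never perturbs the other loci's streams
derive_seed <- function(seed, tag) {
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(seed) * 48271 + h) %% 2147483647)
}

# TN93 per-site transition probabilities for branch length b (expected
# substitutions/site at the stationary distribution), optionally scaled by
# per-site rate multipliers. Returns the child codes sampled for `parent`.
evolve_codes <- function(parent, b, freqs, kappa_R, kappa_Y,
                         site_rates = NULL) {
  if (b == 0 && is.null(site_rates)) return(parent)
  L <- length(parent)
  fA <- freqs[["A"]]; fC <- freqs[["C"]]
  fG <- freqs[["G"]]; fT <- freqs[["T"]]
  pR <- fA + fG; pY <- fC + fT
  beta <- 1 / (2 * (fA * fG * kappa_R + fC * fT * kappa_Y + pR * pY))
  aR <- kappa_R * beta; aY <- kappa_Y * beta
  t <- if (is.null(site_rates)) rep(b, L) else b * site_rates
  e2 <- exp(-beta * t)
  e3 <- exp(-(pR * aR + pY * beta) * t)
  e4 <- exp(-(pY * aY + pR * beta) * t)
  prob <- matrix(0, L, 4L)
  iA <- parent == 1L; iC <- parent == 2L
  iG <- parent == 3L; iT <- parent == 4L
  # purine rows
  prob[iA, 1L] <- fA + fA * pY / pR * e2[iA] + fG / pR * e3[iA]
  prob[iA, 3L] <- fG + fG * pY / pR * e2[iA] - fG / pR * e3[iA]
  prob[iG, 3L] <- fG + fG * pY / pR * e2[iG] + fA / pR * e3[iG]
  prob[iG, 1L] <- fA + fA * pY / pR * e2[iG] - fA / pR * e3[iG]
  prob[iA | iG, 2L] <- fC * (1 - e2[iA | iG])
  prob[iA | iG, 4L] <- fT * (1 - e2[iA | iG])
  # pyrimidine rows
  prob[iC, 2L] <- fC + fC * pR / pY * e2[iC] + fT / pY * e4[iC]
  prob[iC, 4L] <- fT + fT * pR / pY * e2[iC] - fT / pY * e4[iC]
  prob[iT, 4L] <- fT + fT * pR / pY * e2[iT] + fC / pY * e4[iT]
  prob[iT, 2L] <- fC + fC * pR / pY * e2[iT] - fC / pY * e4[iT]
  prob[iC | iT, 1L] <- fA * (1 - e2[iC | iT])
  prob[iC | iT, 3L] <- fG * (1 - e2[iC | iT])
  u <- stats::runif(L)
  c1 <- prob[, 1L]
  c2 <- c1 + prob[, 2L]
  c3 <- c2 + prob[, 3L]
  1L + (u > c1) + (u > c2) + (u > c3)
}

#' Evolve a sequence along one branch under TN93(+gamma)
#'
#' Each site evolves independently under the TN93 rate matrix built from
#' the configuration's base frequencies and transition factors, scaled so
#' the expected number of substitutions per site equals `branch_length`.
#' Uses (and advances) the current RNG stream: results are deterministic
#' given the RNG state.
#'
#' @param parent nucleotide string over A/C/G/T.
#' @param branch_length expected substitutions per site (>= 0).
#' @param config a [simulation_config()].
#' @param site_rates optional per-site rate multipliers (e.g. fixed
#'   gamma(shape, mean 1) draws).
#' @return the child nucleotide string.
#' @export
evolve_sequence <- function(parent, branch_length, config,
                            site_rates = NULL) {
  stopifnot(inherits(config, "simulation_config"), branch_length >= 0)
  codes <- BASE_CODES[strsplit(toupper(parent), "", fixed = TRUE)[[1L]]]
  if (anyNA(codes)) stop("parent sequence must be over A/C/G/T")
  child <- evolve_codes(unname(codes), branch_length, config$base_freqs,
                        config$kappa_R, config$kappa_Y,
                        site_rates = site_rates)
  paste(names(BASE_CODES)[child], collapse = "")
}

# arrange k flagged species into within-genus sharing groups of size >= 2
# (one group of 3 when k is odd); genera are used at most once each
plan_shared_groups <- function(species_by_genus, k) {
  if (k == 0L) return(list())
  if (k == 1L)
    stop("frac_shared_barcode selects a single species; at least two ",
         "are needed to share a barcode")
  sizes <- if (k %% 2L == 1L) c(3L, rep(2L, (k - 3L) / 2L))
           else rep(2L, k / 2L)
  genera <- sample(names(species_by_genus))
  groups <- list()
  for (size in sizes) {
    ok <- genera[vapply(species_by_genus[genera], length, 0L) >= size]
    if (length(ok) == 0L)
      stop("cannot arrange shared-barcode groups: no remaining genus ",
           "with >= ", size, " species")
    g <- ok[1L]
    genera <- setdiff(genera, g)
    groups[[length(groups) + 1L]] <- sample(species_by_genus[[g]], size)
  }
  groups
}

#' Simulate a multi-locus barcode dataset with ground truth
#'
#' Builds a balanced taxonomy (`Fam01`, `Gen01_01`, `Sp01_01_01`, specimens
#' `Sp01_01_01_i1` ...), evolves a root sequence per locus down the
#' family/genus/species/individual branches, places the configured fraction
#' of species into within-genus barcode-sharing groups (every group
#' member's specimens carry literal copies of the group leader's
#' sequences, so all members — leader included — are flagged), then
#' applies per-locus dropout and morphological mislabels. Molecular label
#' columns carry the true taxonomy for every locus a specimen retains.
#' Fully reproducible from the master seed; the caller's RNG state is
#' preserved.
#'
#' @param config a [simulation_config()].
#' @return a list of class `simulated_barcodes` with `dataset` (a
#'   [multilocus_dataset()]) and `truth` (list: `true_labels` data.frame,
#'   `shared_barcode_species`, `shared_groups`, `mislabeled_specimens`,
#'   `dropped_by_locus`, `true_tree` (`phylo`), `config`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  nf <- config$n_families
  ng <- config$genera_per_family
  ns <- config$species_per_genus
  m <- config$specimens_per_species
  fam_of <- function(f) sprintf("Fam%02d", f)
  ord_of <- function(f) sprintf("Ord%02d", f)
  gen_of <- function(f, g) sprintf("Gen%02d_%02d", f, g)
  sp_of <- function(f, g, s) sprintf("Sp%02d_%02d_%02d", f, g, s)

  tax <- expand.grid(s = seq_len(ns), g = seq_len(ng), f = seq_len(nf))
  tax <- tax[order(tax$f, tax$g, tax$s), ]
  species_tab <- data.frame(
    species = sp_of(tax$f, tax$g, tax$s),
    genus = gen_of(tax$f, tax$g), family = fam_of(tax$f),
    order = ord_of(tax$f), stringsAsFactors = FALSE)
  specimens <- species_tab[rep(seq_len(nrow(species_tab)), each = m), ]
  specimens$specimen_id <- paste0(specimens$species, "_i",
                                  rep(seq_len(m), nrow(species_tab)))
  rownames(specimens) <- NULL
  n_spec <- nrow(specimens)

  # --- taxonomy stream: sharing groups, mislabels, dropout -------------
  set.seed(derive_seed(config$seed, "taxonomy"))
  species_by_genus <- split(species_tab$species, species_tab$genus)
  k_shared <- floor(config$frac_shared_barcode * nrow(species_tab))
  shared_groups <- plan_shared_groups(species_by_genus, k_shared)
  shared_species <- unlist(shared_groups)

  n_mis <- floor(config$frac_mislabeled * n_spec)
  mislabeled <- sort(sample(specimens$specimen_id, n_mis))
  swap_to <- character(n_mis)
  for (i in seq_along(mislabeled)) {
    fam <- specimens$family[specimens$specimen_id == mislabeled[i]]
    pool <- species_tab$species[species_tab$family != fam]
    if (length(pool) == 0L)
      stop("cannot plant mislabels: only one family simulated")
    swap_to[i] <- sample(pool, 1L)
  }

  dropped <- list()
  for (locus in names(config$loci)) {
    frac <- if (locus %in% names(config$dropout_by_locus))
      config$dropout_by_locus[[locus]] else 0
    nd <- floor(frac * n_spec)
    dropped[[locus]] <- if (nd > 0L)
      sort(sample(specimens$specimen_id, nd)) else character(0)
  }

  # --- per-locus sequence streams --------------------------------------
  fr <- config$base_freqs
  alignments <- list()
  for (locus in names(config$loci)) {
    set.seed(derive_seed(config$seed, paste0("locus:", locus)))
    L <- config$loci[[locus]]
    rates <- if (is.null(config$gamma_shape)) NULL else
      stats::rgamma(L, shape = config$gamma_shape,
                    rate = config$gamma_shape)
    ev <- function(parent, b) evolve_codes(parent, b, fr, config$kappa_R,
                                           config$kappa_Y, rates)
    root <- sample.int(4L, L, replace = TRUE, prob = fr)
    sp_anc <- list()
    for (f in seq_len(nf)) {
      fam_seq <- ev(root, config$b_family)
      for (g in seq_len(ng)) {
        gen_seq <- ev(fam_seq, config$b_genus)
        for (s in seq_len(ns))
          sp_anc[[sp_of(f, g, s)]] <- ev(gen_seq, config$b_species)
      }
    }
    seqs <- character(n_spec)
    for (i in seq_len(n_spec)) {
      child <- ev(sp_anc[[specimens$species[i]]], config$b_individual)
      seqs[i] <- paste(names(BASE_CODES)[child], collapse = "")
    }
    names(seqs) <- specimens$specimen_id
    # barcode sharing: group members carry literal copies of the leader's
    # specimen sequences (identical barcodes with a congener), so shared
    # species are undiscriminable by construction
    for (grp in shared_groups) {
      leader_ids <- specimens$specimen_id[specimens$species == grp[1L]]
      for (sp in grp[-1L]) {
        ids <- specimens$specimen_id[specimens$species == sp]
        seqs[ids] <- seqs[leader_ids]
      }
    }
    keep <- setdiff(specimens$specimen_id, dropped[[locus]])
    alignments[[locus]] <- locus_alignment(locus, seqs[keep])
  }

  # --- metadata: true molecular labels, morphological swaps ------------
  meta <- specimens[, c("specimen_id", "species", "genus", "family",
                        "order")]
  for (locus in names(config$loci)) {
    has <- !(meta$specimen_id %in% dropped[[locus]])
    for (colr in c("species", "genus", "family")) {
      cn <- paste0("molecular_", locus, "_", colr)
      meta[[cn]] <- ifelse(has, meta[[colr]], "")
    }
  }
  true_labels <- specimens[, c("specimen_id", "species", "genus",
                               "family", "order")]
  for (i in seq_along(mislabeled)) {
    row <- which(meta$specimen_id == mislabeled[i])
    tgt <- species_tab[species_tab$species == swap_to[i], ]
    meta$species[row] <- tgt$species
    meta$genus[row] <- tgt$genus
    meta$family[row] <- tgt$family
    meta$order[row] <- tgt$order
  }

  truth <- list(true_labels = true_labels,
                shared_barcode_species = sort(shared_species),
                shared_groups = shared_groups,
                mislabeled_specimens = mislabeled,
                dropped_by_locus = dropped,
                true_tree = build_true_tree(species_tab, specimens, config,
                                            shared_groups),
                config = config)
  structure(list(dataset = multilocus_dataset(meta, alignments),
                 truth = truth),
            class = "simulated_barcodes")
}

# newick tree of the generating hierarchy over specimens; shared-group
# species attach at their group node with zero-length species branches
build_true_tree <- function(species_tab, specimens, config,
                            shared_groups) {
  bi <- config$b_individual
  bs <- config$b_species
  bg <- config$b_genus
  bf <- config$b_family
  tips_of <- function(sp, stem) {
    ids <- specimens$specimen_id[specimens$species == sp]
    if (length(ids) == 1L) paste0(ids, ":", bi + stem)
    else paste0("(", paste0(ids, ":", bi, collapse = ","), "):", stem)
  }
  in_group <- unlist(shared_groups)
  units_of_genus <- function(gen) {
    sps <- species_tab$species[species_tab$genus == gen]
    own <- setdiff(sps, in_group)
    units <- vapply(own, tips_of, "", stem = bs)
    for (grp in shared_groups) {
      if (!grp[1L] %in% sps) next
      inner <- vapply(sort(grp), tips_of, "", stem = 0)
      units <- c(units, paste0("(", paste(inner, collapse = ","), "):",
                               bs))
    }
    units
  }
  fams <- unique(species_tab$family)
  fam_str <- vapply(fams, function(fam) {
    gens <- unique(species_tab$genus[species_tab$family == fam])
    gs <- vapply(gens, function(gen)
      paste0("(", paste(units_of_genus(gen), collapse = ","), "):", bg),
      "")
    paste0("(", paste(gs, collapse = ","), "):", bf)
  }, "")
  ape::read.tree(text = paste0("(", paste(fam_str, collapse = ","), ");"))
}

#' Write a simulated dataset to disk
#'
#' Emits the standard FASTA + metadata TSV pair via [write_dataset()] plus
#' a `truth.json` with the ground-truth sets and the generating tree in
#' newick.
#'
#' @param sim a `simulated_barcodes` object from [simulate_dataset()].
#' @param dir output directory.
#' @return invisibly, the named list of paths written.
#' @export
write_simulated_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "simulated_barcodes"))
  paths <- write_dataset(sim$dataset, dir)
  tj <- file.path(dir, "truth.json")
  truth <- sim$truth
  jsonlite::write_json(
    list(shared_barcode_species = truth$shared_barcode_species,
         shared_groups = truth$shared_groups,
         mislabeled_specimens = truth$mislabeled_specimens,
         dropped_by_locus = truth$dropped_by_locus,
         true_tree = ape::write.tree(truth$true_tree)),
    tj, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  paths$truth <- tj
  invisible(paths)
}
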