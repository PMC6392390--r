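small_cfg <- function(...) {
  simulation_config(n_families = 2, genera_per_family = 2,
                    species_per_genus = 2, loci = c(matK = 120, rbcL = 80),
                    frac_shared_barcode = 0, frac_mislabeled = 0, ...)
}

test_that("a balanced 2x2x2x2 simulation yields 16 specimens of 8 species", {
  sim <- simulate_dataset(small_cfg(seed = 3))
  expect_equal(nrow(sim$dataset$specimens), 16L)
  expect_equal(length(unique(sim$dataset$specimens$species)), 8L)
  expect_setequal(names(sim$dataset$alignments), c("matK", "rbcL"))
  expect_equal(length(sim$dataset$alignments$matK$ids), 16L)
  expect_equal(sim$dataset$alignments$matK$length, 120L)
  expect_equal(ape::Ntip(sim$truth$true_tree), 16L)
})

test_that("the same seed reproduces the dataset byte for byte", {
  cfg <- simulation_config(seed = 9, n_families = 2,
                           genera_per_family = 2, species_per_genus = 3,
                           loci = c(matK = 150, rbcL = 100),
                           frac_shared_barcode = 1 / 3,
                           frac_mislabeled = 0.1,
                           dropout_by_locus = c(matK = 0.2))
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$dataset$specimens, b$dataset$specimens)
  expect_identical(a$dataset$alignments$matK$seqs,
                   b$dataset$alignments$matK$seqs)
  expect_identical(a$truth$shared_barcode_species,
                   b$truth$shared_barcode_species)
  expect_identical(a$truth$mislabeled_specimens,
                   b$truth$mislabeled_specimens)
})

test_that("zero branch lengths give identical sequences everywhere", {
  sim <- simulate_dataset(small_cfg(seed = 4, b_family = 0, b_genus = 0,
                                    b_species = 0, b_individual = 0))
  expect_equal(length(unique(sim$dataset$alignments$matK$seqs)), 1L)
})

test_that("evolve_sequence honours the zero-branch and determinism contracts", {
  cfg <- small_cfg(seed = 1)
  parent <- strrep("ACGT", 25)
  expect_identical(evolve_sequence(parent, 0, cfg), parent)
  set.seed(42)
  c1 <- evolve_sequence(parent, 0.2, cfg)
  set.seed(42)
  c2 <- evolve_sequence(parent, 0.2, cfg)
  expect_identical(c1, c2)
})

test_that("substitution proportions match the matrix-exponential expectation", {
  skip_if_not_installed("Matrix")
  L <- 100000
  for (case in list(
    list(freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25), b = 0.1),
    list(freqs = c(A = 0.31, C = 0.17, G = 0.21, T = 0.31), b = 0.25))) {
    cfg <- simulation_config(loci = c(x = L), base_freqs = case$freqs,
                             kappa_R = 2, kappa_Y = 2)
    R <- tn93_rate_matrix(cfg$base_freqs, 2, 2)
    P <- as.matrix(Matrix::expm(R * case$b))
    p_expected <- 1 - sum(unname(cfg$base_freqs) * diag(P))
    set.seed(7)
    parent <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                           prob = cfg$base_freqs), collapse = "")
    child <- evolve_sequence(parent, case$b, cfg)
    p_obs <- mean(strsplit(parent, "")[[1]] != strsplit(child, "")[[1]])
    se <- sqrt(p_expected * (1 - p_expected) / L)
    expect_lt(abs(p_obs - p_expected), 3 * se)
  }
})

test_that("shared-barcode species are flagged exactly and share sequences", {
  cfg <- simulation_config(seed = 5, frac_shared_barcode = 0.2)  # 50 species
  sim <- simulate_dataset(cfg)
  truth <- sim$truth
  expect_length(truth$shared_barcode_species, 10L)
  expect_setequal(unlist(truth$shared_groups),
                  truth$shared_barcode_species)
  gen <- sim$truth$true_labels
  for (grp in truth$shared_groups) {
    expect_gte(length(grp), 2L)
    # all members congeneric
    genera <- unique(gen$genus[match(grp, gen$species)])
    expect_length(genera, 1L)
    # members carry identical sequences, specimen for specimen
    lead <- gen$specimen_id[gen$species == grp[1]]
    for (sp in grp[-1]) {
      ids <- gen$specimen_id[gen$species == sp]
      expect_identical(unname(sim$dataset$alignments$matK$seqs[ids]),
                       unname(sim$dataset$alignments$matK$seqs[lead]))
    }
  }
})

test_that("sharing demands a congener and at least a pair", {
  expect_error(simulation_config(species_per_genus = 1,
                                 frac_shared_barcode = 0.5), "congener")
  cfg <- simulation_config(n_families = 10, genera_per_family = 1,
                           species_per_genus = 2,
                           frac_shared_barcode = 0.05)  # floor(.05*20)=1
  expect_error(simulate_dataset(cfg), "at least two")
})

test_that("mislabels swap to a different family, at the configured count", {
  cfg <- simulation_config(seed = 12, frac_mislabeled = 0.1,
                           frac_shared_barcode = 0)
  sim <- simulate_dataset(cfg)
  mis <- sim$truth$mislabeled_specimens
  expect_length(mis, floor(0.1 * nrow(sim$dataset$specimens)))
  meta <- sim$dataset$specimens
  truth <- sim$truth$true_labels
  for (id in mis) {
    i <- match(id, meta$specimen_id)
    j <- match(id, truth$specimen_id)
    expect_false(meta$species[i] == truth$species[j])
    expect_false(meta$family[i] == truth$family[j])
  }
  # everyone else keeps the true label
  clean <- setdiff(meta$specimen_id, mis)
  expect_identical(meta$species[match(clean, meta$specimen_id)],
                   truth$species[match(clean, truth$specimen_id)])
})

test_that("dropout removes the configured number of sequences per locus", {
  cfg <- small_cfg(seed = 6, dropout_by_locus = c(matK = 0.25))
  sim <- simulate_dataset(cfg)
  expect_length(sim$dataset$alignments$matK$ids, 12L)  # 16 - floor(.25*16)
  expect_length(sim$dataset$alignments$rbcL$ids, 16L)
  dropped <- sim$truth$dropped_by_locus$matK
  expect_length(dropped, 4L)
  # molecular labels absent for dropped loci
  meta <- sim$dataset$specimens
  expect_true(all(meta$molecular_matK_species[
    meta$specimen_id %in% dropped] == ""))
})

test_that("intraspecific divergence sits in the low regime the defaults target", {
  cfg <- simulation_config(seed = 8, n_families = 10,
                           genera_per_family = 4, species_per_genus = 5,
                           loci = c(matK = 400, rbcL = 300),
                           frac_shared_barcode = 0, frac_mislabeled = 0)
  sim <- simulate_dataset(cfg)  # 200 species x 2 specimens
  aln <- concatenate_loci(sim$dataset, c("matK", "rbcL"))
  m <- distance_matrix(aln)
  part <- partition_divergences(m, sim$truth$true_labels)
  expect_equal(nrow(part$intra), 200L)
  mean_intra <- mean(part$intra$distance)
  expect_gt(mean_intra, 0.0005)
  expect_lt(mean_intra, 0.002)
  expect_gt(mean(part$inter$distance), 0.05)
})

test_that("raising b_species raises within-genus interspecific divergence", {
  mean_wg <- function(bs, seed) {
    cfg <- simulation_config(seed = seed, n_families = 2,
                             genera_per_family = 2, species_per_genus = 4,
                             loci = c(x = 400), b_species = bs,
                             frac_shared_barcode = 0, frac_mislabeled = 0)
    sim <- simulate_dataset(cfg)
    m <- distance_matrix(sim$dataset$alignments$x)
    lab <- sim$truth$true_labels
    gen <- stats::setNames(lab$genus, lab$specimen_id)
    sp <- stats::setNames(lab$species, lab$specimen_id)
    idx <- which(upper.tri(m$d), arr.ind = TRUE)
    a <- m$ids[idx[, 1]]; b <- m$ids[idx[, 2]]
    keep <- gen[a] == gen[b] & sp[a] != sp[b]
    mean(m$d[idx][keep], na.rm = TRUE)
  }
  lo <- mean(vapply(1:3, function(s) mean_wg(0.01, s), 0))
  hi <- mean(vapply(1:3, function(s) mean_wg(0.05, s), 0))
  expect_gt(hi, lo)
})

test_that("a simulated dataset writes and reads back through the standard pair", {
  sim <- simulate_dataset(
    simulation_config(seed = 2, n_families = 2, genera_per_family = 2,
                      species_per_genus = 2,
                      loci = c(matK = 120, rbcL = 80),
                      frac_shared_barcode = 0, frac_mislabeled = 0.2))
  dir <- withr::local_tempdir()
  paths <- write_simulated_dataset(sim, dir)
  expect_true(file.exists(paths$truth))
  back <- read_dataset(c(matK = paths$matK, rbcL = paths$rbcL),
                       paths$metadata)
  expect_identical(back$alignments$matK$seqs,
                   sim$dataset$alignments$matK$seqs)
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_identical(sort(truth$mislabeled_specimens),
                   sort(sim$truth$mislabeled_specimens))
})
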