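test_that("three-taxon NJ solves the three-point formulas", {
  # d(A,B) = a+b, d(A,C) = a+c, d(B,C) = b+c with a=2, b=3, c=4
  ids <- c("A", "B", "C")
  d <- matrix(0, 3, 3, dimnames = list(ids, ids))
  d["A", "B"] <- d["B", "A"] <- 5
  d["A", "C"] <- d["C", "A"] <- 6
  d["B", "C"] <- d["C", "B"] <- 7
  tr <- neighbor_joining(d)
  pend <- stats::setNames(tr$edge.length[tr$edge[, 2] <= 3],
                          tr$tip.label[tr$edge[tr$edge[, 2] <= 3, 2]])
  expect_equal(pend[c("A", "B", "C")], c(A = 2, B = 3, C = 4))
})

test_that("NJ exactly recovers random additive eight-taxon trees", {
  set.seed(91)
  for (rep in 1:20) {
    true <- ape::rtree(8, br = function(n) stats::runif(n, 0.05, 1))
    d <- ape::cophenetic.phylo(true)
    est <- neighbor_joining(d)
    expect_equal(ape::dist.topo(ape::unroot(true), est), 0,
                 ignore_attr = TRUE)
    d_est <- ape::cophenetic.phylo(est)[rownames(d), colnames(d)]
    expect_lt(max(abs(d_est - d)), 1e-9)
  }
})

test_that("NJ refuses undefined distances and tiny matrices", {
  d <- matrix(c(0, 1, NA, 1, 0, 1, NA, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(d), "undefined")
  expect_error(neighbor_joining(d[1:2, 1:2]), "three taxa")
})

test_that("bootstrap gives full support to an unambiguous split", {
  base <- strrep("ACGT", 30)
  alt <- paste0(strrep("GCGT", 10), substr(base, 41, 120))
  aln <- locus_alignment("x", c(a1 = base, a2 = base,
                                b1 = alt, b2 = alt))
  tr <- bootstrap_support(aln, n_replicates = 50, seed = 5)
  sup <- tr$node.label[!is.na(tr$node.label)]
  expect_true(all(sup >= 0 & sup <= 100))
  expect_true(100 %in% sup)
  tr2 <- bootstrap_support(aln, n_replicates = 50, seed = 5)
  expect_identical(tr$node.label, tr2$node.label)
  tr3 <- bootstrap_support(aln, n_replicates = 50, seed = 6)
  expect_equal(ape::dist.topo(tr, tr3), 0, ignore_attr = TRUE)
})

test_that("Fitch length scores known column patterns", {
  aln0 <- locus_alignment("x", c(t1 = "AAAA", t2 = "AAAA", t3 = "AAAA",
                                 t4 = "AAAA"))
  t12 <- ape::read.tree(text = "((t1,t2),(t3,t4));")
  t13 <- ape::read.tree(text = "((t1,t3),(t2,t4));")
  expect_equal(fitch_length(t12, aln0), 0)
  aln1 <- locus_alignment("x", c(t1 = "A", t2 = "A", t3 = "C", t4 = "C"))
  expect_equal(fitch_length(t12, aln1), 1)
  expect_equal(fitch_length(t13, aln1), 2)
  # ambiguity codes and gaps are free to match anything
  alnN <- locus_alignment("x", c(t1 = "A", t2 = "N", t3 = "-", t4 = "A"))
  expect_equal(fitch_length(t12, alnN), 0)
  expect_error(fitch_length(ape::read.tree(text = "((t1,t9),(t3,t4));"),
                            aln1), "t9")
})

test_that("Fitch length is invariant under rerooting", {
  set.seed(101)
  cfg <- simulation_config(loci = c(x = 80))
  for (rep in 1:5) {
    tr <- ape::rtree(7, br = function(n) stats::runif(n, 0.02, 0.3))
    aln <- simulate_on_tree(tr, 80, cfg)
    base <- fitch_length(ape::unroot(tr), aln)
    for (tip in sample(tr$tip.label, 3)) {
      rr <- ape::root(ape::unroot(tr), outgroup = tip,
                      resolve.root = TRUE)
      expect_equal(fitch_length(rr, aln), base)
    }
  }
})

test_that("NNI search never lengthens the tree and finds small optima", {
  set.seed(111)
  cfg <- simulation_config(loci = c(x = 60))
  for (rep in 1:5) {
    true <- ape::rtree(6, br = function(n) stats::runif(n, 0.02, 0.15))
    aln <- simulate_on_tree(true, 60, cfg)
    start <- ape::unroot(ape::rtree(6,
                                    tip.label = sample(true$tip.label)))
    start_len <- fitch_length(start, aln)
    got <- parsimony_search(aln, start = start)
    expect_lte(attr(got, "parsimony_length"), start_len)
    allt <- phangorn::allTrees(6, rooted = FALSE,
                               tip.label = true$tip.label)
    best <- min(vapply(allt, fitch_length, 0, aln = aln))
    expect_equal(attr(got, "parsimony_length"), best)
  }
})

test_that("monophyly is scored by bipartition existence with strict support", {
  tr <- ape::read.tree(text = "((A1:1,A2:1)100:1,(B1:1,B2:1)100:1);")
  lab <- stats::setNames(c("A", "A", "B", "B"), c("A1", "A2", "B1", "B2"))
  r <- monophyly_percent(tr, lab, rank = "species")
  expect_equal(r$percent, 100)
  # interleaved species are non-monophyletic
  tr2 <- ape::read.tree(text = "((A1:1,B1:1)90:1,(A2:1,B2:1)90:1);")
  r2 <- monophyly_percent(tr2, lab, rank = "species")
  expect_equal(r2$percent, 0)
  expect_true(all(r2$per_taxon$verdict == "non_monophyletic"))
  # support at or below the threshold does not count as supported
  # (unrooted fixture so the two clades carry distinct splits)
  lab3 <- c(lab, C1 = "C")
  tr3 <- ape::read.tree(text = "((A1:1,A2:1)65:1,(B1:1,B2:1)75:1,C1:1);")
  r3 <- monophyly_percent(tr3, lab3, rank = "species")
  expect_equal(sort(unique(r3$per_taxon$verdict)),
               c("excluded_singleton", "monophyletic_supported",
                 "monophyletic_unsupported"))
  expect_equal(r3$percent, 50)
  expect_equal(monophyly_percent(tr3, lab3, rank = "species",
                                 require_support = FALSE)$percent, 100)
  # strictness at exactly the threshold
  tr70 <- ape::read.tree(
    text = "((A1:1,A2:1)70:1,(B1:1,B2:1)71:1,C1:1);")
  r70 <- monophyly_percent(tr70, lab3, rank = "species")
  expect_equal(r70$percent, 50)
})

test_that("singleton taxa are excluded from the monophyly denominator", {
  tr <- ape::read.tree(
    text = "(((A1:1,A2:1)80:1,B1:1)90:1,(C1:1,C2:1)95:1);")
  lab <- stats::setNames(c("A", "A", "B", "C", "C"),
                         c("A1", "A2", "B1", "C1", "C2"))
  r <- monophyly_percent(tr, lab, rank = "species")
  expect_equal(r$n_assessable, 2L)
  expect_equal(r$per_taxon$verdict[r$per_taxon$taxon == "b"],
               "excluded_singleton")
  expect_equal(r$percent, 100)
  expect_error(monophyly_percent(tr, lab[-1], rank = "species"), "A1")
})

test_that("monophyly verdicts are independent of the rooting", {
  set.seed(121)
  cfg <- simulation_config(seed = 131, n_families = 2,
                           genera_per_family = 2, species_per_genus = 2,
                           loci = c(x = 200), frac_shared_barcode = 0,
                           frac_mislabeled = 0)
  sim <- simulate_dataset(cfg)
  tr <- neighbor_joining(distance_matrix(sim$dataset$alignments$x))
  base <- monophyly_percent(tr, sim$truth$true_labels, rank = "genus",
                            require_support = FALSE)
  for (tip in sample(tr$tip.label, 5)) {
    rr <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
    r <- monophyly_percent(rr, sim$truth$true_labels, rank = "genus",
                           require_support = FALSE)
    expect_equal(r$per_taxon$verdict, base$per_taxon$verdict)
  }
})

test_that("species with shared barcodes break monophyly; others keep it", {
  sim <- simulate_dataset(simulation_config(seed = 141,
                                            frac_mislabeled = 0))
  aln <- concatenate_loci(sim$dataset, c("matK", "rbcL"))
  tr <- neighbor_joining(distance_matrix(aln))
  lab <- sim$truth$true_labels
  shared <- norm_taxon(sim$truth$shared_barcode_species)
  keep <- lab$specimen_id[!(norm_taxon(lab$species) %in% shared)]
  r <- monophyly_percent(ape::keep.tip(tr, keep), lab, rank = "species",
                         require_support = FALSE)
  expect_equal(r$percent, 100)
})

test_that("reference groups are checked as unrooted clades", {
  tr <- ape::read.tree(
    text = "(((l1:1,l2:1):1,(m1:1,m2:1):1):1,((r1:1,r2:1):1,(s1:1,s2:1):1):1);")
  ord <- stats::setNames(c("Laurales", "Laurales", "Magnoliales",
                           "Magnoliales", "Rosales", "Rosales",
                           "Santalales", "Santalales"),
                         c("l1", "l2", "m1", "m2", "r1", "r2", "s1",
                           "s2"))
  r <- reference_clade_congruence(tr, ord, list(
    laurales = "Laurales",
    magnoliids = c("Laurales", "Magnoliales"),
    everything = c("Laurales", "Magnoliales", "Rosales", "Santalales"),
    asterids = "Ericales"))
  expect_equal(r$status[r$group == "laurales"], "recovered")
  expect_equal(r$status[r$group == "magnoliids"], "recovered")
  expect_equal(r$status[r$group == "everything"], "recovered")
  expect_equal(r$status[r$group == "asterids"], "skipped")
  # orders interdigitated with members of other groups are not recovered
  tr2 <- ape::read.tree(
    text = "(((l1:1,r1:1):1,(m1:1,s1:1):1):1,((l2:1,r2:1):1,(m2:1,s2:1):1):1);")
  r2 <- reference_clade_congruence(tr2, ord,
                                   list(magnoliids = c("Laurales",
                                                       "Magnoliales")))
  expect_equal(r2$status, "not_recovered")
})

test_that("newick round-trip preserves topology and supports", {
  tr <- ape::read.tree(text = "((A1:1,A2:1)83:1,(B1:1,B2:2)91:1);")
  path <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(tr, path)
  back <- read_tree_newick(path)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(back)), 0,
               ignore_attr = TRUE)
  expect_setequal(stats::na.omit(suppressWarnings(
    as.numeric(back$node.label))), c(83, 91))
})
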