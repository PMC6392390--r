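# barcodeval

Evaluation of multi-locus DNA barcode effectiveness for species
identification, built for plant-barcoding surveys that combine the plastid
loci *matK* and *rbcL* (singly and as a concatenated two-locus barcode).
It is aimed at researchers who have barcode sequences with morphological
determinations and want the four standard effectiveness assessments in one
tested, scriptable pipeline:

1. **Morphology vs molecular concordance** — each specimen's
   sequence-based identification is compared with its morphological one at
   species, genus and family rank; specimens whose two loci agree on a
   wrong family are flagged *incorrect*, and specimens whose loci disagree
   at family rank are flagged *mislabeled* (suspected voucher
   mislabeling/contamination).
2. **Best-close-match identification** — every barcode queries all others;
   only matches within a threshold *T* (the empirical 95th percentile of
   intraspecific divergence, no interpolation) count, and the species of
   the nearest match(es) decides *correct*, *ambiguous*, *incorrect* or
   *unidentified*.
3. **Barcoding-gap analysis** — intra- and interspecific pairwise
   divergences are separated, binned into percent frequency distributions,
   and tested for a gap (present iff min interspecific > max
   intraspecific); per-species discrimination uses the strict local-gap
   criterion (max conspecific distance < min distance to any
   heterospecific).
4. **Monophyly** — neighbour-joining trees with nonparametric bootstrap
   (and maximum-parsimony trees by Fitch scoring with NNI search) are
   scored for the percentage of species/genus/family clades recovered as
   monophyletic, counting a clade as supported only when its bipartition's
   support strictly exceeds 70%.

Divergences are Tamura–Nei (TN93) distances with pairwise deletion of
gap/missing sites and base frequencies pooled per pair:

d = −(2π_Aπ_G/π_R)·ln w₁ − (2π_Tπ_C/π_Y)·ln w₂ − 2(π_Rπ_Y − π_Aπ_Gπ_Y/π_R − π_Tπ_Cπ_R/π_Y)·ln w₃,

with w₁ = 1 − P₁/(2π_Aπ_G/π_R) − Q/(2π_R), w₂ analogous for pyrimidines,
w₃ = 1 − Q/(2π_Rπ_Y), where P₁, P₂, Q are the observed fractions of purine
transitions, pyrimidine transitions and transversions. With a gamma shape
*a* each −ln x is replaced by a(x^(−1/a) − 1). Out-of-range (saturated)
pairs are flagged undefined rather than truncated.

A sequence simulator under the same TN93(+Γ) process generates balanced
family/genus/species hierarchies with ~2 specimens per species,
intraspecific divergence near 0.001 and interspecific divergence of order
0.1–0.3, plus known "undiscriminable" species that share identical
barcodes with a congener, planted cross-family mislabels and per-locus
dropout — so every downstream statistic can be validated against ground
truth without any downloads.

## Worked example

```r
library(barcodeval)

sim <- simulate_dataset(simulation_config(seed = 2026))
ds  <- sim$dataset                 # 50 species x 2 specimens, matK + rbcL

## 1. concordance, and removal of flagged specimens
conc <- dataset_concordance(ds)
summarize_concordance(conc)
#> morphology vs molecular concordance (n assessed = 100 )
#>   species_match    95 (95.0%)
#>   genus_match       0 (0.0%)
#>   family_match      0 (0.0%)
#>   incorrect         5 (5.0%)
#>   mislabeled        0 (0.0%)
flagged <- conc$specimen_id[conc$category %in% c("incorrect", "mislabeled")]
ds <- subset_dataset(ds, setdiff(ds$specimens$specimen_id, flagged))
ds <- filter_min_representatives(ds, 2)

## 2. two-locus barcode, TN93 distances, divergence partition
two  <- concatenate_loci(ds, c("matK", "rbcL"))
m    <- distance_matrix(two, distance_model_params("tn93"))
part <- partition_divergences(m, ds$specimens)
barcoding_gap_test(part)
#> barcoding gap: absent
#>   intraspecific: mean 0.0008574, range [0, 0.003713]
#>   interspecific: mean 0.2624, range [0, 0.3378]
#>   overlap: [0, 0.003713]
welch_t_test(part$intra$distance, part$inter$distance)$p_value  # 0

## 3. best-close match and discrimination
best_close_match(m, ds$specimens)$summary
#> best-close match: n = 90 , T = 0.0029695
#>   correct         76 (84.4%)
#>   ambiguous        0 (0.0%)
#>   incorrect       10 (11.1%)
#>   unidentified     4 (4.4%)
species_discrimination(m, ds$specimens)
#> species discrimination: 40/45 (88.9%)

## 4. bootstrapped NJ tree and monophyly
tree <- bootstrap_support(two, n_replicates = 100, seed = 1)
monophyly_percent(tree, ds$specimens, rank = "species")
#> monophyly at species level: 88.9% of 45 assessable taxa (support > 70)
```

The interpretation mirrors what such surveys typically find: intraspecific
divergence is orders of magnitude below interspecific divergence (Welch
p < 0.01) yet the two distributions overlap, so there is no global
barcoding gap; identification success and discrimination sit below 100%
exactly because of the five simulated species pairs/triples that share a
barcode with a congener (here 10% of species), and those same species
break species-level monophyly.

`run_pipeline()` chains all stages for every locus and the concatenation,
writes per-query/per-species tables, newick trees, a JSON + Markdown
report and an MD5 manifest (identical input + config + seed gives an
identical manifest). A small command-line wrapper is installed at
`inst/scripts/barcode-eval.R`.

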