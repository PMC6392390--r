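---
title: "Evaluating multi-locus DNA barcodes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating multi-locus DNA barcodes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

barcodeval asks a single question of a barcode dataset: *how well do these
sequences identify the species that morphologists assigned to them?* It
answers it with four complementary assessments — identification
concordance, best-close-match success, barcoding-gap/discrimination
statistics, and monophyly on reconstructed trees — plus a simulator that
generates datasets with known answers. This vignette records the models,
the tunable parameters, and the design decisions taken where the
methodology is conventionally under-specified.

## Divergence model

All distance-based stages run on Tamura–Nei (TN93) divergences, the
standard choice when transition rates differ between purines and
pyrimidines and base composition is unequal — both typical of plastid
barcodes. For each sequence pair, sites where either sequence carries a
gap (`-`), missing data (`N`, `?`) or an ambiguity code are excluded
(*pairwise deletion*), and the estimator uses the fractions of purine
transitions $P_1$, pyrimidine transitions $P_2$ and transversions $Q$
together with base frequencies pooled over the two sequences at the
compared sites.

Decisions worth knowing:

* **Pairwise deletion, not complete deletion.** Complete deletion would
  discard most columns of a sparse multi-family alignment; pairwise
  deletion keeps every pair's own comparable sites.
* **Pairwise-pooled frequencies.** Frequencies come from the two
  sequences of the pair, not from the whole dataset. The package's test
  suite cross-checks the resulting matrices against an independent
  implementation that pools dataset-wide; agreement is within a fraction
  of a percent on homogeneous data, and the per-pair choice degrades more
  gracefully when composition drifts between families.
* **Gamma correction is opt-in.** With shape $a$, each $-\ln x$ term
  becomes $a(x^{-1/a}-1)$. Because no defensible default shape exists for
  an arbitrary dataset, `gamma_shape = NULL` (no correction) is the
  default and the correction must be requested explicitly. The corrected
  distance is never smaller than the uncorrected one and converges to it
  as $a \to \infty$ (both are tested).
* **Saturation yields `NA`, never a capped value.** When a logarithm or
  power argument is non-positive the pair is flagged undefined and
  excluded downstream. Silent truncation to a maximum distance would
  bias the gap analysis toward finding overlap at the high end.

## Threshold and best-close match

The identification test treats every sequence once as a query against all
others (the query itself is excluded from its own database — a self-match
would trivialise the test). A query with no database match within
$[0, T]$ is *unidentified*. Otherwise the match set is every database
sequence within a relative tolerance of $10^{-9}$ of the minimum distance
(exact floating-point ties are fragile); the query is *correct* if all
match species equal its own, *ambiguous* if they include its own plus
another, *incorrect* otherwise. Conspecific-first orderings get no
preference: a heterospecific tie at the minimum always demotes the query
to ambiguous.

$T$ is the empirical 95th percentile of the intraspecific distances — the
smallest observed value covering $\lceil 0.95\,n \rceil$ of the $n$
intraspecific distances, with no interpolation — computed separately for
each dataset (each locus and the concatenation get their own $T$).
Species with fewer than two representatives must be filtered out first
(`filter_min_representatives()`); with a single representative a correct
match is impossible by construction, which would deflate the statistic
rather than measure it.

## Barcoding gap and discrimination

The global gap test is the classical one: a gap is present iff the
minimum interspecific divergence exceeds the maximum intraspecific
divergence. Frequency histograms are binned on a shared half-open grid
$[kw, (k+1)w)$ with $w = 0.01$ by default (a round bin width on the
divergence scale of these barcodes) and normalised to percent within each
class.

"Able to discriminate a species" has no universally agreed definition;
barcodeval uses the **strict local-gap criterion**: a species is
discriminated iff its maximum conspecific distance is strictly smaller
than the minimum distance from any of its members to any heterospecific.
This makes the canonical failure mode — a barcode identical to a
congener's — fail automatically (both distances hit zero), and a global
gap implies 100% discrimination. The main alternative
(nearest-neighbour-is-conspecific) is recoverable from the
best-close-match records with `threshold = Inf`. Species with no defined
heterospecific distance are reported unassessable and excluded from the
denominator.

## Concordance

Molecular identifications may be supplied per locus in the metadata, or
assigned from a local reference alignment by nearest distance (ties at
the minimum truncate the label to the deepest rank shared by all tied
references). Each specimen's category is the deepest rank at which *any*
locus matches the morphological label: species, genus, or family. When no
locus matches even at family rank, two loci that agree with each other
point to a genuine misidentification (*incorrect*), while two loci that
disagree at family rank point to voucher mislabeling or contamination
(*mislabeled*). With only one locus available the two-locus disagreement
test cannot fire, and the category defaults to *incorrect*; labels empty
at family rank carry no information and are treated as absent. The
pipeline excludes flagged specimens before the distance analyses
(`exclude_flagged = TRUE`), reflecting the usual practice of removing
presumably mislabeled barcodes before measuring identification success.

## Trees and monophyly

Neighbour joining runs on the TN93 matrix (undefined entries are a hard
error — imputing them silently would fabricate topology). Negative branch
estimates are clamped to zero with the total deficit recorded. Bootstrap
support resamples alignment columns with replacement, rebuilds the NJ
tree per replicate, and scores each internal edge of the original tree by
the percentage of replicates containing its bipartition; the default is
1000 replicates, reducible for large runs.

Monophyly is assessed **unrooted**: a taxon is monophyletic iff some edge
bipartitions the leaves into exactly that taxon versus the rest. This
needs no outgroup choice and is invariant under rerooting (tested under
random rootings). "Supported" requires the edge's support to exceed 70
strictly. Taxa with one leaf are excluded from the percentage, as a
single leaf is trivially monophyletic and would inflate the statistic.
The same bipartition rule scores externally supplied newick trees (e.g.
likelihood trees) and the congruence of order-level groupings against a
reference classification.

Maximum parsimony uses Fitch scoring (gaps, `N` and `?` are fully
ambiguous states, never a fifth character) with greedy
nearest-neighbour-interchange hill climbing. A strict one-move local
optimum is additionally probed with two-move NNI sequences: on small
trees the NNI landscape has shallow valleys that single moves cannot
cross, and the two-move probe reliably reaches the exhaustive-search
optimum on six-taxon problems (verified against full enumeration of all
105 topologies). The pipeline starts the search from the NJ tree and
disables the quadratic-cost probe, since an NJ start is already near the
optimum and the probe's cost grows quadratically in the taxon count.

## The simulator: what it emulates, and what it does not

`simulate_dataset()` evolves each locus down a balanced
family/genus/species/individual hierarchy under the *same* TN93(+Γ)
process the estimator assumes, using the closed-form transition
probabilities (the test suite checks substitution proportions against a
matrix-exponential oracle). Defaults encode the regime of a tropical
two-locus plant survey, chosen once:

* 5 families × 2 genera × 5 species × 2 specimens (50 species, 100
  specimens); loci of 800 bp (*matK*) and 550 bp (*rbcL*);
* branch lengths `b_individual = 5e-4` (expected intraspecific divergence
  $2 \times 5\times10^{-4} = 0.001$, the low-intraspecific regime) and
  `b_species = b_genus = b_family = 0.05`, giving interspecific
  divergences of roughly 0.1–0.3 depending on rank;
* plastid-like base composition (0.31, 0.17, 0.21, 0.31) and
  transition/transversion factors $\kappa_R = \kappa_Y = 2$;
* 10% of species in shared-barcode groups, 5% of specimens mislabeled.

Ground-truth constructions:

* **Shared barcodes.** `floor(frac × n_species)` species are arranged
  into within-genus groups of at least two (a group of three absorbs an
  odd count); every member's specimens carry *literal copies* of the
  group leader's sequences, and every member — leader included — is
  flagged in the truth set. Copying final sequences rather than a shared
  ancestor is deliberate: with re-diverged individuals the
  non-discriminated set would match the flagged set only stochastically,
  whereas identical barcodes make "flagged = non-discriminated" an exact
  property a test can assert.
* **Mislabels.** `floor(frac × n_specimens)` specimens have their
  morphological label swapped with a species from a *different* family,
  emulating gross voucher misidentification. Within-family swaps are
  deliberately not generated: the family-level concordance rules cannot
  detect them, so planting them would only blur the ground truth the
  concordance tests recover.
* **Dropout.** Optional per-locus fractions of specimens lack that locus
  (e.g. `c(matK = 0.34, rbcL = 0.05)` emulates the uneven recoverability
  of the two standard loci); the concatenated analysis then keeps only
  specimens carrying all loci.
* **Reproducibility.** One master seed; sub-streams are derived per
  purpose (taxonomy choices, each locus) from a hash of a stream tag, so
  adding a locus never perturbs the other loci, and the caller's RNG
  state is restored.

The simulator does **not** generate indels or alignment error, rate
variation among lineages, compositional heterogeneity between clades,
unbalanced taxon sampling, or realistic taxon names. Passing tests
therefore demonstrate correctness of the *statistics* under a clean
substitution process, not robustness to alignment artefacts or model
violation — on real data those remain the user's responsibility.

## Numerical and interface choices

* Alignment columns are 0-based internally and 1-based in messages;
  sequence validation reports the 1-based position of the first
  non-IUPAC character.
* `'?'` and `'N'` are missing data, `'-'` is a gap; all three count as
  non-coverage for end trimming (`min_coverage` default 0.5 — the
  trimming rule is a parameterisation, as published workflows rarely
  state theirs) and all three are excluded sites for distances.
* Tie tolerances are relative ($10^{-9}$) everywhere distances are
  compared for equality.
* Fractional counts (shared species, mislabels, dropout) use `floor`,
  with selection by seeded shuffle — reproducible and unbiased.
* All writers emit deterministic ordering; the pipeline manifest hashes
  every artifact, and identical input + configuration + seed reproduce
  identical hashes.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` run at desk scale, chosen to
exercise every code path with comfortable margins: pairwise-estimator
consistency at $L = 2000$ with 200 replicates per divergence level;
NJ recovery on 100 random additive 8-taxon matrices; best-close-match
agreement with a brute-force classifier on 100 datasets of up to 40
specimens; parsimony optimality on 20 six-taxon alignments against full
enumeration; and the end-to-end survey emulation at the default 50
species × 2 specimens with 200 bootstrap replicates. These sizes are the
package's own validation design, small enough to re-run routinely and
large enough that the stochastic checks have negligible failure
probability under their stated tolerances.

## Known limitations

* Only the TN93 family (plus the p-distance) is implemented; no model
  selection, no likelihood distances, no composition-heterogeneity
  correction ("pattern heterogeneity between lineages" in some published
  workflows is not recoverable as a concrete estimator and is not
  attempted).
* Maximum-likelihood tree inference is out of scope; externally computed
  newick trees are accepted for monophyly scoring.
* Concordance matches normalised name strings; synonymy and fuzzy name
  resolution are out of scope.
* Multiple sequence alignment is assumed done (or simulated); the
  package only trims ragged ends.
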