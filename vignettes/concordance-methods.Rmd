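---
title: "Measuring gene tree / species tree concordance with phyloconcord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring gene tree / species tree concordance with phyloconcord}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-gene phylogenies rarely match the species phylogeny exactly. Some of
that discordance is biological (gene duplication and loss, horizontal
transfer, incomplete lineage sorting), but much of it is analytical: a short
or conserved gene simply does not carry enough phylogenetic signal to
recover any topology reliably, and its maximum-likelihood tree is noisy. If
one wants to ask whether a *particular* gene set — say, the morphological
development genes of *Streptomyces* — tracks the species phylogeny more
closely than the background of strict orthologs, the information content of
each gene has to be factored out before gene sets of very different length
and conservation can be compared fairly.

phyloconcord implements that comparison as a reusable pipeline:

1. **Topological distance.** Robinson–Foulds (RF) distances between each
   single-gene tree and a reference species tree.
2. **Exclusion rule.** Gene trees whose unresolved (multifurcating) regions
   involve at least half of the species are dropped — their RF distance
   says more about lack of resolution than about history.
3. **Information baseline.** A log-linear baseline
   `RF = a * log10(N_PIS) + b` fitted through the *best* gene trees at each
   level of parsimony-informative-site (PIS) count, and a normalized
   distance `RF' = RF / (a * log10(N_PIS) + b)`.
4. **Gene-set statistics.** Per-set means, standard deviations, and
   relative RF versus a background set, with Welch *t* tests and Pearson
   correlations for simple inference.
5. **Resampling design.** Clade-proportional random genome datasets (RGDs)
   that shrink a large genome collection to tractable replicate subsets
   while preserving its clade composition.

## Distances and the polytomy rule

All comparisons are unrooted. For trees pruned to their shared tips, the
raw RF distance is the size of the symmetric difference between the two
sets of non-trivial bipartitions, and the normalized distance divides by
`|S_gene| + |S_ref|`, the total number of non-trivial splits in the two
trees. For two binary trees on *n* tips this denominator equals the
classical maximum `2(n - 3)`, so the value lies in `[0, 1]`; unlike the
binary-only convention it also stays a proper fraction for polytomous
trees, which matters because real single-gene trees are frequently
unresolved. The convention is fixed and documented here because published
normalized RF values do not always state which denominator was used.

A gene tree is excluded when tips descending from multifurcating nodes
make up at least 50% of the species (`polytomy_threshold`, inclusive at
the boundary). Two details are worth spelling out:

* *What counts as a multifurcation.* Polytomies are judged in the
  unrooted sense: a node is multifurcating when its unrooted degree is at
  least four. A bifurcating root never counts, and neither does the basal
  trichotomy that an unrooted binary tree acquires when stored in rooted
  form — calling those polytomies would misclassify every fully resolved
  unrooted tree. This is the only reading consistent with requiring the
  fraction to be zero exactly for binary (unrooted) trees.
* *What "involving" means.* We take the union of descendant tips of the
  multifurcating nodes in the orientation the tree was supplied in.
  Because the rule has a hard threshold, records with a polytomy fraction
  within 0.05 of the threshold are flagged `near_boundary` in the output
  so borderline exclusions are visible rather than silent.

Gene trees sharing fewer than four tips with the reference have no
non-trivial splits in common; they are reported as excluded with reason
`insufficient_overlap` rather than dropped, so the per-gene table always
accounts for every manifest entry.

## The PIS baseline

Within each level of information content, the *lowest* RF values identify
genes whose trees are about as good as that much signal allows. The
baseline is estimated by:

1. sorting included records by PIS count (ties broken by gene id, so the
   procedure is reproducible),
2. cutting them into equal-sized bins of `bin_size = 1000` records — with
   fewer records than one bin, everything forms a single bin; a trailing
   remainder smaller than half a bin is merged into the last full bin
   (configurable via `remainder_policy`, since any convention here is
   arbitrary),
3. keeping the `ceiling(0.05 * n)` smallest RF values per bin (at least
   one) — the "top 5% best" gene trees; we select the value *subset*
   rather than a single percentile point per bin because it gives the
   regression many points and is configurable downstream,
4. fitting `RF = a * log10(N_PIS) + b` by unweighted ordinary least
   squares through the pooled selected points.

Each RF value is then divided by its fitted baseline. `RF' = 1` means "as
discordant as a good tree with this much signal"; the normalized scale has
no ceiling at 1, which is why comparisons after normalization are done
with *relative* RF — `(mean(set) - mean(reference)) / mean(reference)` —
the same statistic used on the raw scale. By construction the reference
set's relative RF is exactly 0.

Numerical guards: the slope is unidentifiable when all selected PIS counts
are equal (an error, not a silent constant fit), and records whose fitted
baseline is not above `epsilon = 1e-6` get `RF' = NA` with a warning
rather than a clamped value, so a pathological fit (e.g. a steeply
negative baseline extrapolated to high PIS counts) cannot quietly produce
huge or negative normalized distances.

When many replicate datasets are analysed, the baseline can be fitted
either once over the pooled records (run the pipeline on a concatenated
manifest; the default reading, which gives each bin its full 1000 records)
or per dataset (run the pipeline per manifest). Both are the same code
path applied to different manifests.

## The clade-proportional resampling design

A collection of hundreds of genomes is too large for strict-orthogroup
inference, so the design repeatedly draws replicate subsets ("random
genome datasets", RGDs) that preserve clade composition. Given a partition
of species into clades — for the *Streptomyces* reference tree, eight
clades of 1, 2, 18, 159, 36, 56, 15 and 86 species, whose two deep
branches hold 180 (C1–C4) and 193 (C5–C8) species — each replicate of 64
species is allocated across clades by **largest-remainder (Hamilton)
apportionment**: floor the proportional quotas, then give the leftover
slots to the clades with the largest fractional remainders (ties broken
by clade order). Within each clade, species are drawn uniformly without
replacement; a master seed spawns per-replicate seeds so the whole set of
100 replicates is reproducible.

Largest-remainder apportionment was chosen because it is the standard
deterministic proportional rounding and because under it the two smallest
clades (1 and 2 species) receive quota zero, which is exactly what the
published resampling mean implies: 100 × 64 / 370 ≈ 17.3 draws per
species over the 370 species that can be drawn at all. The diagnostics
report the mean both over species drawn at least once (17.3) and over the
whole partition (17.2), plus the maximum pairwise replicate overlap
(`|intersection| / 64`), which stays in the low-to-mid 30% range — the
replicates are substantially distinct. The published between-replicate
overlap bound (37.2%) sits at the upper edge of what within-clade uniform
sampling produces; under this generator the maximum over 4950 replicate
pairs occasionally reaches 24/64 = 37.5% for some seeds, which is worth
knowing when comparing against a single published realization. The
published standard deviation of resampling counts (6.2) is larger than
the ~3.8 that within-clade uniform sampling yields; whatever produced the
extra dispersion is not documented, so this package reports the sd but
makes no claim of reproducing it.

## The synthetic data generator

Real inputs (genome collections, orthology inference, alignments, ML
trees) are produced by external tools. To make every stage testable
without them, the generator emulates one RGD's analysis inputs:

* **Species tree:** a Yule (pure-birth) tree, 64 tips by default, unit
  branch lengths. The combinatorial structure is all that matters
  downstream, so no effort is spent on realistic divergence times.
* **Gene trees:** copies of the species tree perturbed by a configurable
  number of random nearest-neighbour interchanges (NNI). Each NNI changes
  at most one bipartition, so the expected RF distance grows with the
  move budget; discordance is injected topologically rather than through
  a coalescent model because every downstream statistic is topological.
  Defaults: a 10-gene low-discordance focal set ("DG", 2 moves) versus a
  500-gene background ("sOG", 8 moves), mirroring the per-dataset scale
  of roughly 10 development-gene trees versus roughly 500
  strict-orthogroup trees.
* **Alignments:** the root sequence is uniform over the 20 amino acids;
  along each branch every site substitutes with probability
  `1 - exp(-rate)` to a uniformly chosen different residue. Per gene, the
  alignment length is drawn log-uniformly from 50–2000 columns and the
  rate from 0.003–0.3, which makes realized PIS counts span roughly
  10–2000 — more than two orders of magnitude, so log10 binning is
  meaningful. There is no rate heterogeneity, no indels and no
  composition bias: the generator controls PIS count, which is the only
  alignment property the pipeline consumes.

What passing tests on this generator do **not** show: robustness to
misalignment, to model misspecification in tree inference, to paralogy
contamination, or to biological discordance processes with non-uniform
topology distributions (e.g. HGT highways). Those enter upstream of this
package's inputs.

## Problem sizes and determinism

The test suite exercises the full documented sizes where they are cheap
(200 random tree pairs against a brute-force split-enumeration oracle;
50,000-point baseline recovery, which recovers the generating slope
within ±0.02 and intercept within ±0.05; 100 replicates per NNI level on
64-tip trees; 100 seeded fixture simulations) and scaled-down replicas
elsewhere, chosen to keep a full run in a few minutes. Pipeline outputs
are written with numbers fixed to six significant digits, so re-running
the same configuration produces byte-identical tables.

## Known limitations

* RF distance is a blunt instrument: it counts splits as all-or-nothing
  and saturates quickly for poorly resolved trees. The package reports
  raw, normalized and relative values but offers no
  reconciliation-based distance; reconciled gene trees can be supplied
  as an alternative input tree set and flow through identically.
* The baseline is a single global log-linear fit. Quantile regression or
  per-set baselines are deliberately out of scope.
* The polytomy rule's "involving" is our documented reading (descendant
  tip union); trees near the 0.5 boundary are flagged rather than
  adjudicated.
* The Welch test is the default implementation of the two-sample *t*
  test (a pooled-variance mode is available); no multiple-testing
  correction is applied.
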