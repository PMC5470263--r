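---
title: "Separating duplication history from concerted evolution in multigene families"
author: "duphist package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating duplication history from concerted evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duphist)
```

## The problem

Multigene families such as the MHC class IIB genes often evolve under
*concerted evolution*: intergenic gene conversion transfers sequence
tracts between paralogous copies within a genome, homogenizing them so
that a species' copies resemble each other more than they resemble
their true orthologs in other species. When a family instead evolves by
*birth-death* dynamics, an ancient duplication leaves two divergent
gene lineages that persist across the species radiation. The footprint
of such a duplication is a set of *diagnostic sites*: alignment columns
at which the two lineages carry fixed alternative variants in (nearly)
every species. Concerted evolution erodes exactly this footprint, so
detecting an ancient duplication from present-day sequences means
separating the alignment columns that still trace the duplication from
those already homogenized.

`duphist` implements that separation as a reusable pipeline:

1. **Signature screening** (`signatureMatches()`, `callLineage()`,
   `signatureRetention()`, `interminglingReport()`): classify each
   sequence against a table of diagnostic columns with their two
   lineage variants, find each group's most lineage-A-like and most
   lineage-B-like members, and count at how many signature columns they
   still differ (*retention*: full signature length under complete
   preservation, 0 under complete homogenization). Sequences carrying
   appreciable proportions of both variants are flagged *intermingled*
   — the single-sequence footprint of short-tract conversion.
2. **Segmentation into local phylogenetic classes** (`fitPartition()`):
   partition alignment columns into "cacti", each summarized by a mean
   pairwise-difference matrix over all sequences, so that columns with
   a shared local history are pooled.
3. **Discrimination statistic** (`discriminationScores()`,
   `classifyCacti()`, `diagnosticSites()`): for each cactus take, per
   species, the distance between that species' two most distant
   sequences, average these across species, and normalize across cacti
   by the maximum. Under duplication history a species' copies sit in
   different lineages and the statistic approaches 1; under concerted
   evolution the copies cluster together and it stays low. Cacti at or
   above a threshold (default 0.5) are labeled duplication-history and
   their columns reported as candidate diagnostic sites.
4. **Verification tools** (`pDistanceMatrix()`, `neighborJoining()`,
   `isMonophyletic()`): uncorrected p-distances with pairwise deletion
   and neighbor-joining trees used to ask whether the two lineages are
   reciprocally monophyletic (duplication topology) or whether
   conspecific copies cluster (concerted topology).
5. **A forward simulator** (`simulateFamily()`) providing families with
   known ground truth, and an end-to-end experiment
   (`runRecoveryExperiment()`) quantifying how gene conversion erodes
   recovery.

## The simulator and what it emulates

`simulateFamily()` models the birth of two paralog lineages at the root
of a species radiation. A Yule species tree with `nSpecies` tips is
rescaled to depth `treeHeight`. One random ancestral sequence of
`seqLen` bases is duplicated at the root; `kDiag` columns, sampled
uniformly over the sequence (the region stands for the
signature-bearing exon stretch, across which real diagnostic sites are
scattered), receive distinct founder variants in the two copies. Both
copies then co-descend every branch:

* **Substitution**: per copy and branch, `Pois(subRate * bl * seqLen)`
  Jukes–Cantor substitutions (uniform choice among the three other
  bases). Diagnostic columns are protected from substitution (positions
  are resampled) unless `erodeBySubstitution` is set, so conversion is
  the only force eroding the footprint — this isolates the process
  under study.
* **Gene conversion**: per copy and branch, `Pois(convRate * bl)`
  events. Each copies a tract of geometric length (mean `tractMean`,
  uniform start, clipped at the sequence end) between the two
  conspecific copies in a uniformly chosen direction. Diagnostic
  columns are *not* protected from conversion.
* **Dropout**: each species loses one copy (A or B with equal odds)
  with probability `dropoutP`, emulating lineage loss.

One seeded RNG stream drives everything in a fixed order (tree,
founders, a pre-order pass over branches with substitutions before
conversions, then dropout in tip-label order), so a seed reproduces the
output byte for byte, and the full event log is returned
(`replaySimulation()` re-derives the alignment from it exactly).

Default calibration: `subRate = 0.025` at `treeHeight = 1` makes the
two lineages about 10% divergent at the tips — the 16 default
diagnostic sites in 300 columns contribute 5.3 percentage points and
neutral substitution the rest — a realistic figure for anciently
duplicated MHC exons. The defaults `convRate = 0` and `tractMean = 50`
reflect that no quantitative conversion-rate or tract-length estimates
exist for this system; experiments sweep `convRate` instead of trusting
any single value.

What the simulator does **not** model: indels and alignment error,
selection (real MHC exon 2 evolves under strong balancing selection),
rate heterogeneity among sites, more than two paralogs, and conversion
with non-conspecific copies. Tests passing on these simulations
therefore show that the statistics behave as intended under the stated
mechanism, not that real alignments are free of the confounders above.

## Segmentation: model and choices

Only variable columns are analyzed; monomorphic columns carry no signal
and inherit the state of the nearest analyzed column in the reported
per-column path. Each column is represented by its 0/1
pairwise-difference pattern over all sequence pairs (gap/`N` pairs are
missing and get zero weight). A cactus is the mean of its columns'
patterns — itself a distance matrix in [0, 1] — and the emission cost
of a column under a cactus is the mean squared deviation between the
two, over comparable pairs. The mean is kept on its natural scale:
normalizing each cactus matrix individually would erase the contrast
between strongly divergent (duplication) and homogenized (concerted)
classes that the downstream statistic measures; normalization happens
once, across cacti, at the score level.

`fitPartition()` proceeds in two stages:

* **Site classes.** Sets of at least `minSegment` columns sharing the
  *identical* difference partition are extracted first and classified
  directly. Recurrence of one exact partition is the strongest evidence
  of a shared local history — fixed inter-lineage differences repeat
  the lineage bipartition at every diagnostic column — and such sites
  are scattered by nature, so they should not pay the chain's
  contiguity cost. This stage is deterministic and independent of the
  iteration count.
* **Segmental classes.** The remaining columns are segmented by a
  Viterbi assignment with a per-switch penalty (default twice the
  median per-column cost of the initial single-cactus fit — a
  scale-free choice). Each iteration proposes a new cactus from the
  worst-fitting window along the current path, at widths `minSegment`
  and `3 * minSegment` (the wider window averages away per-column noise
  so a long block under one topology can be captured in one proposal),
  refines all assignments by coordinate descent (reassign, recompute
  matrices, repeat while the total cost drops), and keeps the proposal
  only if the total cost decreases. Rejected windows are remembered so
  later iterations explore new stretches.

Both stages are deterministic; ties in the Viterbi recursion prefer
staying in the current state and then the lowest state index, and
worst-window ties take the leftmost window. `nIterations` is the only
model-complexity knob for the segmental stage; 5 suffices for a single
extra topology class, while alignments concatenating unrelated
topologies benefit from 10–15 (the recovery numbers reported by the
tests use 15 for the two-block benchmark).

This design is a functional analog of local-phylogeny segmentation
tools that combine an HMM with a self-organising map; it is *not* a
reimplementation of any of them. The SOM half is replaced by the
two proposal mechanisms above because the scientific payload here is
the downstream discrimination statistic, validated by
boundary-recovery and site-recovery experiments rather than by
equivalence to any external tool.

## The discrimination statistic

For a cactus and a species with at least two sequences,
`withinSpeciesExtreme()` is the largest cactus distance among that
species' sequences. Using the extreme pair rather than the average of
all pairs keeps the statistic unbiased by how many sequences a species
happens to contribute. `discriminationScores()` averages the extremes
over qualifying species (species with one sequence are excluded — they
carry no within-species distance) and divides by the maximum across
cacti, so the top cactus scores exactly 1 and all scores are
comparable between runs with different iteration counts.

`classifyCacti()` labels a cactus duplication-history when its
normalized score is at or above `threshold` (default 0.5, inclusive at
the boundary); `topK` offers a rank-based alternative. The cutoff is a
package decision: diagnostic sites produce within-species divergence in
essentially *every* species (score near 1), whereas classes born from
substitutions on one deep branch affect only that clade's species, and
classes of homogenized columns score near 0. In the simulations used
by the test suite the background cactus scores well below half of the
diagnostic cactus, so the default separates cleanly; on real data with
few, column-rich cacti the threshold (or `topK`) should be read
together with the raw scores, which are always reported.

`diagnosticSites()` is then simply the sorted union of the
duplication-labeled cacti's columns, in 1-based alignment coordinates
(all file formats are 1-based; internal arithmetic converts only at the
I/O boundary).

## Distances and tree checks

`pDistance()` is the uncorrected proportion of differing sites among
columns where neither sequence has a gap or `N` (pairwise deletion —
the choice keeps sparse alignments usable and matches common practice
for uncorrected distances; complete deletion would discard most columns
in patchy families). Pairs with no comparable columns give `NA`, and
`neighborJoining()` refuses such matrices rather than guessing.
Neighbor joining itself is the standard Saitou–Nei algorithm (via ape),
with negative branch-length estimates clamped to zero.
`isMonophyletic()` asks whether an unrooted tree has an edge splitting
a leaf subset from its complement — the operational form of the
two-topology dichotomy: reciprocal monophyly of the lineages under
preserved duplication history versus species-wise clustering under
concerted evolution.

## The recovery experiment

```{r, eval = FALSE}
res <- runRecoveryExperiment(baseConfig = simConfig(),
                             convRates = c(0, 0.2, 1, 5),
                             nReps = 20, seed = 1)
res$summary
```

For every replicate and conversion rate this simulates a family, runs
the full discovery pipeline, and records: precision and recall of the
recovered sites against the true diagnostic columns, median
per-species signature retention, lineage-call accuracy of the
signature screen, reciprocal monophyly of the true lineages on the NJ
tree, and the fraction of species whose paralogs are mutual nearest
neighbors. Retention and recall fall monotonically with the conversion
rate — the quantitative form of "concerted evolution erodes the
footprints of duplication". Problem sizes used throughout the tests
(20 species, 300 columns, 16 diagnostic sites, 10–20 replicates per
condition) are the package's reference conditions; they run in seconds
and are large enough for the medians to be stable.

## Numerical and degenerate-input conventions

* Ambiguity codes other than `N` are rejected at parse time; signature
  logic relies on exact single-character comparison.
* A minority fraction exactly at `minorityThreshold` (default 0.25) is
  called intermingled; tied variant counts are always intermingled;
  sequences matching no diagnostic column are uninformative.
* `most lineage-like` ties break by fewer opposite-lineage matches,
  then lexicographically smallest id; single-sequence groups have
  retention 0 by construction.
* All-zero raw discrimination scores normalize to 0 (not NaN); a score
  exactly at the classification threshold is duplication-history.
* Alignments with no variable columns cannot be segmented and raise an
  error, as does `minSegment` exceeding the alignment length.
* FASTA output is wrapped at 70 characters so outputs are bit-stable;
  reports carry a `#` header naming the package version and seed.

## Known limitations

* The segmentation is a greedy penalized optimization; it can miss weak
  secondary classes and reports no uncertainty on boundaries.
* The discrimination statistic needs species with both copies; with
  pervasive lineage loss (`dropoutP` near 1) it is undefined.
* Under very strong conversion the within-species homogenization
  reaches a steady state set by the ratio of substitution to conversion
  coverage; species that split more recently than that equilibrium time
  cannot be distinguished from their neighbors by any distance method,
  which bounds how completely "species clustering" can be observed in
  the simulations.
* Real-data complications listed for the simulator (selection, indels,
  multiple paralogs) are out of scope.
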