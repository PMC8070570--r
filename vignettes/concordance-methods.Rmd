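---
title: "Methods: comparing OTU and ASV cluster sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing OTU and ASV cluster sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Two families of methods turn 16S rRNA amplicon reads into feature tables:
identity clustering into OTUs at a fixed cutoff (commonly 97% or 99%), and
denoising into exact amplicon sequence variants (ASVs). Studies built on one
cannot be compared with studies built on the other unless the taxonomy,
alpha- and beta-diversity profiles the two routes produce from the *same*
reads are demonstrably concordant. `ampliconcord` implements that
concordance analysis as a reusable pipeline: given two or three "cluster
sets" (feature table + centroid sequences + taxonomy + optional origin
labels and phylogeny, all derived from the same samples), it quantifies
where and how much they agree.

The package does not cluster, denoise, classify or build trees; it consumes
the standard outputs of those tools (TSV count tables, FASTA centroids,
Greengenes-style taxonomy strings, Newick trees) and analyses them.

## The filters

Two filters precede every comparison, in fixed order:

1. **Sample-singletons**: every cell equal to 1 read is zeroed, and features
   whose rows become empty are dropped. We read "sample-singleton" as a
   per-sample (per-cell) event; the whole-table reading is available behind
   `mode = "table"` for users who prefer it.
2. **Tailored abundance filter**: a feature is kept iff it reaches at least
   0.1% of the total reads of *at least one* sample. The boundary is
   inclusive and evaluated in exact integer arithmetic
   (`count * 1000 >= sample_total` for the default threshold), so no feature
   is dropped or kept by a floating-point artifact. Per-sample totals are
   those of the input table, computed once; the filter is applied exactly
   once in the pipeline, because re-application with recomputed totals is
   not guaranteed to be a no-op (removal lowers the denominators).

Low-identity-cutoff OTU pipelines shatter abundant sequences into swarms of
low-frequency "satellite" clusters; the abundance filter is what makes the
three sets comparable, and `FilterReport` objects account for every removed
read so the cost is always visible.

## Sequence-level concordance

* **Changes between centroids** are unit-cost global alignment edits
  (mismatches and indels both cost 1; matches 0), i.e. Levenshtein distance;
  identity is matching columns over alignment columns of an optimal
  transcript. No gap-open/extend parameters exist to tune. Among co-optimal
  alignments the transcript is the one `utils::adist` reports; the change
  count is invariant, the identity can in principle differ by a tie-break,
  which matters only within ~1 column of the 75% eligibility gate.
* **Exact overlap** partitions the union of centroid sequences into Venn
  compartments by exact string equality. Sequence percentages are taken
  against the union size; read percentages against the grand total over all
  sets, so compartment reads sum exactly to the sum of set totals.
  Duplicate centroid strings within a set are merged for accounting, with a
  warning.
* **Difference profiles** report, for each centroid, the distance to its
  nearest neighbour (identity ≥ 75%, a floor close to between-phyla
  identity) and the cumulative fraction of centroids with a neighbour
  within N changes. We use the per-centroid nearest-neighbour reading
  rather than a fraction-of-pairs reading; both are computable from
  `change_matrix()`, but the per-centroid curve is what "how many centroids
  differ in up to N nucleotides" asks.
* **Resilience curves** greedily re-cluster each set at a grid of identity
  thresholds: sequences in decreasing read-abundance order (ties broken
  lexicographically, so the procedure is seedless and reproducible) join
  the first existing centroid at or above the threshold or found a new one.
  Each threshold is clustered independently rather than nested, matching
  the idea of separate clustering exercises per threshold.

## Taxonomy concordance

Taxonomy strings are canonicalised to exactly 7 ranks with the rule that an
empty rank truncates everything below it (dropped labels are warned about).
A feature is *informative* at a level iff its label there is non-empty. On
that basis the package computes per-level resolution profiles (fraction of
reads with an informative label), attribution of missing species labels to
LCA truncation versus references that carry no species label (read-weighted,
two-way, unknown lineages conservatively counted as LCA), per-level taxa
Venn partitions, and cross-set Spearman correlations.

Correlations use set-wide relative abundances (taxon reads over set total
reads) rather than raw reads, because sets differ in depth; they are
restricted to informative taxa, with the union of the two sets' taxa and
zero abundance for absences, and average ranks for ties. The
differential-taxa screen splits taxa by whether their mean relative
abundance outside the reference set falls below 1/3 of the reference
abundance.

## Alpha diversity

Observed features, Shannon entropy (natural log, `0·ln 0 := 0`) and
bias-corrected Chao1 (`S_obs + F1(F1−1)/(2(F2+1))`) are computed on
independent rarefactions (multivariate hypergeometric subsampling, exact
column sums) at the depth of the smallest sample, and averaged into point
estimates; the study design uses 10,000 iterations, the default here.
Group comparisons report medians with a two-sided Wilcoxon rank-sum test
for the two-level groupings (organ, pond) and Kruskal–Wallis for the
organ-pond cross product — the standard nonparametric, median-oriented
choices; the significance level (0.05) is reported alongside, never baked
into conclusions. Groups with fewer than two samples are skipped and
flagged.

Seeding: one seed per pipeline invocation, consumed as a single sequential
RNG stream. This is simpler than deriving a stream per sample and
iteration and is fully reproducible because the package offers no parallel
execution.

## Beta diversity

Beta analyses run on *average-rarefied* tables: the element-wise mean of
`n_draws` independent rarefactions (default 100; the number behind
"average rarefied observations" is a package choice, configurable), kept
as reals so each column still sums exactly to the depth. Distances:
Bray–Curtis, binary Jaccard (presence is "> 0", including fractional
averaged counts), and UniFrac from a rooted tree pruned to the observed
features — unweighted (unique over shared branch length), weighted raw
(`Σ l_b |p_b(x) − p_b(y)|`) and weighted normalized (bounded to [0, 1];
the default weighted variant, comparable to the other metrics).

PCoA Gower-double-centers `−D²/2` and eigendecomposes; coordinates are
eigenvectors scaled by the square roots of positive eigenvalues, negative
eigenvalues are counted and reported, never corrected (no Cailliez or
Lingoes adjustment). A fully degenerate matrix (no positive eigenvalues,
e.g. an all-zero distance matrix) yields an ordination with zero axes
rather than an error.

ANOSIM uses the standard Clarke statistic
`R = (r̄_between − r̄_within) / (n(n−1)/4)` on average-tie ranks of all
off-diagonal pairs. When the label multiset admits at most 20,000 distinct
assignments the permutation distribution is enumerated exhaustively and
the p-value is exact; otherwise 999 seeded random relabelings give
`p = (1 + hits)/(1 + permutations)`. Pairwise post hoc tests run ANOSIM on
each group pair and adjust with Benjamini–Hochberg (no correction is
prescribed by convention; BH is the field default).

## The synthetic generator

`generate_truth()` + `render_cluster_sets()` build a ground-truthed
emulation of a three-set comparison so the whole pipeline can be validated
without any sequencing data:

* A community of 40 taxa (default) in 8 families, with full 7-rank
  lineages and one V3-like centroid per taxon (127–168 nt), generated by
  mutating a common ancestor so within-family identities exceed
  across-family identities while all inter-taxon identities stay below the
  97% merge cutoff.
* Lognormal base abundances (sdlog 1.5) with a detectability floor of
  0.5% — the designed community consists of taxa a 0.1% filter should
  keep, so that the *only* sub-threshold features are the designed
  satellites.
* Group structure: 2 organs × 2 ponds × 6 replicates at 20,000
  reads/sample; a 4-fold organ effect on 30% of taxa and a comparable
  3-fold pond effect on 30% of taxa (the study's marginal organ and pond
  separations are of similar magnitude, with the crossed grouping much
  stronger — the pattern the defaults reproduce); per-replicate lognormal
  overdispersion (sdlog 0.5) emulating inter-individual variability, since
  purely multinomial replicates would be unrealistically exchangeable and
  saturate ANOSIM.
* Distortions per set: the ASV-like set is the truth; the 99%-OTU-like set
  adds 5 satellites (1–2 nt off) to each of the 10 most abundant parents,
  each siphoning ~1% of the parent's reads capped strictly below the 0.1%
  per-sample threshold; the 97%-OTU-like set merges taxa at ≥ 97% identity
  (none under the default truth, by construction), swaps 20% of centroids
  for 1-nt private variants (so exactly `shared_fraction = 0.8` of true
  centroids are shared by all three sets) and truncates genus/species
  labels with probabilities 0.3/0.6, emulating the lower taxonomic
  resolution of coarse reference clusters.
* Per-set trees are rooted average-linkage (UPGMA) dendrograms on
  alignment-identity distances — adequate for exercising the UniFrac
  contracts without implementing phylogenetic inference.

What the generator does **not** emulate: sequencing error models and
chimeras (satellites are placed, not evolved), reference-database
idiosyncrasies, compositional bias, and presence/absence turnover — under
the defaults every post-filter feature occurs in every sample, so
presence-level metrics (Jaccard, unweighted UniFrac) are degenerate on the
synthetic bundle even though they are fully functional on real tables with
absences. Tests passing on this bundle therefore validate the machinery
and the designed structural signals, not distributional realism of any
particular shrimp pond.

## Problem sizes in tests

The test and validation suites scale simulation sizes to desk scale as the
package's own choice: alpha pipelines run at 100–200 rarefaction
iterations (estimator means stabilise well before 10,000 at these depths),
ANOSIM null calibrations use 500 simulated 8-sample matrices at 199
permutations, designed-effect detection uses 20 seeded replicates of the
full 24-sample bundle, and oracle-equivalence checks use ≥ 100 random
instances per estimator at ≤ 10 samples, ≤ 30 features and 6-leaf trees.

## Known limitations

* Identity from an optimal alignment transcript is tie-break dependent in
  principle (change counts are not); fixtures near the 75% gate should not
  rely on the third decimal of identity.
* `lca_attribution()` needs a caller-supplied reference map; the package
  does not ship a taxonomy database.
* Exhaustive ANOSIM enumeration is capped at 20,000 assignments; beyond
  that p-values are Monte Carlo with the stated seed.
* The run orchestrator compares sets on shared samples only in the sense
  that every table must cover samples present in the metadata; it does not
  reconcile partially overlapping sample sets.
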