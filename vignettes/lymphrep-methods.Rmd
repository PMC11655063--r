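---
title: "Methods: cross-organ antibody repertoire analysis with lymphrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-organ antibody repertoire analysis with lymphrep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lymphrep)
```

## Scope

`lymphrep` analyses IgG heavy-chain (VH) antibody repertoires sequenced
from several lymphoid organs of the same animal — typically bone marrow
(BM), spleen, and left/right axillary and inguinal lymph nodes (aLN-L,
aLN-R, iLN-L, iLN-R) — and asks three questions: how clonally expanded is
each organ repertoire, how much do organs share their clones, and do
B-cell lineages show directional migration between organs. The package
consumes AIRR-style rearrangement tables and organ-labeled lineage trees;
it does not perform read preprocessing, UMI error correction, V(D)J
alignment, or tree topology inference, all of which are expected upstream.

## Clones and clonotypes

A **clone** is the set of sequences with identical CDRH3 amino-acid
sequence and matching germline V and J genes; allele suffixes (`*01`) are
stripped before keying, because clone identity is defined at the gene
level. In paired-chain (single-cell) data the CDRL3 can be added to the
key (`mode = "paired"` in `assign_clones()`). Per organ, clone read
counts are normalized to frequencies summing to one.

A **clonotype** groups clones that plausibly descend from one
recombination event through somatic hypermutation: clones with the same
V gene, same J gene, equal CDRH3 length and CDRH3 amino-acid identity
above a threshold are linked, and connected components under
single-linkage are clonotypes. The default threshold is 90% identity,
applied **strictly** (`identity > 0.90`): a length-10 CDRH3 pair with one
mismatch (identity exactly 0.90) is *not* linked. Definitions that phrase
the same rule as "normalized Hamming distance of 0.1" include the
boundary; `inclusive = TRUE` reproduces that variant. The strict reading
is the default because the repertoire-level definition is the primary
one; the flag surfaces the discrepancy rather than hiding it.

## Clonal expansion: Hill diversity and evenness

For a clonal frequency distribution $f_1, \dots, f_n$ the Hill number of
order $\alpha \ge 0$ is

$$^{\alpha}D = \left( \sum_{i=1}^{n} f_i^{\alpha} \right)^{1/(1-\alpha)},$$

with $^{0}D = n$ (species richness, SR) and the analytic limit
$^{1}D = \exp(-\sum_i f_i \ln f_i)$ at $\alpha = 1$, where the printed
formula is undefined. **Evenness** is $^{\alpha}E = {}^{\alpha}D /
\mathrm{SR} \in (0, 1]$: 1 for a uniform repertoire, near 0 when one or
few clones dominate. The $\alpha = 1$ point (Shannon evenness) is the
conventional single-number summary of clonal expansion; the default
profile grid covers $\alpha \in [0, 10]$ in steps of 0.2.

Numerical choices: zero-frequency entries are dropped before computation
(avoiding the $0^0$ ambiguity at $\alpha = 0$); input must sum to 1
within $10^{-6}$; orders within $10^{-9}$ of 1 use the Shannon limit.
$^{\alpha}D$ is non-increasing in $\alpha$ and continuous across the
branch switch at $\alpha = 1$ — both are enforced by property tests. Note
that the derivative $\partial\,{}^{\alpha}D/\partial\alpha$ at
$\alpha = 1$ is not small for skewed repertoires, so continuity is tested
adjacent to the limit ($\alpha = 1 \pm 10^{-6}$), not at a fixed offset
like 0.999.

Expansion is also summarized non-parametrically by
`expansion_profile()`: clones are ranked by descending frequency (ties
broken lexicographically on CDRH3, for determinism) and the summed
frequency per rank bin is reported, e.g. the fraction of the repertoire
held by the top 3 clones.

## Repertoire overlap and similarity

* **Jaccard index** $J(A,B) = |A \cap B| / (|A| + |B| - |A \cap B|)$ on
  clone-key sets — presence/absence overlap.
* **Cosine similarity** over the union of clones of the two repertoires
  (absent clones contribute 0):
  $\mathrm{sim}(A,B) = \sum_i A_i B_i / (\sqrt{\sum_i A_i^2}
  \sqrt{\sum_i B_i^2})$ — frequency-weighted overlap. The square roots
  in the denominator are part of the standard definition; some printed
  renderings of this formula drop them, which would break the $[0,1]$
  range. The union-of-clones embedding is the only convention in which
  disjoint repertoires score exactly 0.
* **Organ occupancy**: each clone is annotated with the set of organs it
  occupies in its mouse; `organ_overlap_counts()` returns the degree
  histogram (clones in exactly $N$ organs) and the full Venn partition.
  The Venn partition is refused above 16 organs ($2^k$ cells), degrees
  are always computed.
* **V-gene usage**: unique-clone counts per germline V gene
  (deliberately unweighted by frequency), Pearson-correlated across
  samples over the union of V genes; samples are ordered by
  average-linkage hierarchical clustering on $1 - r$. The linkage is a
  conventional heatmap default and is not statistically load-bearing.
* **Binder matching**: clones are flagged as antigen binders by CDRH3
  string match against a binder list (screening pipelines report binder
  CDRH3s without reliable V/J context; `by_vj = TRUE` gives the strict
  variant), and binder-to-all ratios are reported per occupancy degree.

## CDRH3 similarity networks

Within a clonotype, each unique clone is a node and an edge joins clones
whose equal-length CDRH3s differ at exactly one amino-acid position
(Hamming distance 1). Node attributes record organ occupancy and
frequency; display size is $\log_{10}$ frequency rescaled into a fixed
range (default $[1, 10]$; pass `size_reference` to make sizes comparable
across the networks of one mouse). Layout is deliberately out of scope —
networks export to GraphML and any viewer can lay them out; layout is
cosmetic and nondeterministic. `select_top_diverse_clonotypes()` ranks
clonotypes per organ by unique-clone membership (ties: summed frequency,
then lexicographic id), matching the common practice of drawing the few
most diversified clonotypes.

## Migration on lineage trees: the switch-proportion test

Lineage trees (one per clonotype, rooted at the germline) carry an organ
label at every tip. Input filtering before tree analysis follows fixed
rules: sequences with fewer than 3 reads are discarded; clones are
down-sampled to at most 100 sequences; clones with fewer than 10
sequences or from a single organ are removed.

**Ancestral reconstruction.** Internal organ states are reconstructed by
maximum parsimony (Sankoff dynamic programming, unit transition costs; a
small C++ kernel). Ties among most-parsimonious labelings are resolved
deterministically: during the top-down pass the parent's state is
preferred (delaying transitions toward the tips — a conservative
counting), then lexicographic organ order. For small trees,
`strategy = "enumerate"` instead averages directional transition counts
over *all* most-parsimonious labelings; both strategies are exposed
because the resolution rule is genuinely underdetermined. The germline
tip anchors the root, takes the root's reconstructed state, and
contributes no transition.

**Polytomies.** Binary resolutions of polytomies (internal nodes
separated by zero-length branches) can inflate the inferred change
count. `reorder_polytomies()` greedily applies nearest-neighbor
interchange moves across zero-length internal edges while they strictly
reduce the parsimony score; the procedure is deterministic (fixed edge
order, first improving move) and idempotent, and never increases the
change count.

**SP statistic.** For each ordered organ pair $(x, y)$,
$\mathrm{SP}[x \to y]$ is the number of parsimony-inferred $x \to y$
changes summed over all trees, divided by the total number of changes;
entries sum to 1.

**Permutation test.** Per replicate: (i) any tree whose tip-to-change
ratio exceeds the cap (default 20) is down-sampled uniformly at random
to cap × changes tips — re-drawn each replicate, with the topology
pruned, never re-estimated; (ii) tip labels are permuted, either within
each tree (`within_tree`, the directional test) or pooled and reshuffled
across all trees of a mouse (`among_trees`, an undirected association
test in which transitions are summed over both directions); (iii)
parsimony and SP are recomputed and $\delta = \mathrm{SP}_{obs} -
\mathrm{SP}_{perm}$ recorded per pair. The p-value for directional
enrichment ($\delta > 0$) is the fraction of replicates with
$\delta \le 0$; the default is 1000 replicates. Whether a tree is
down-sampled depends only on its full-tree ratio, so the common case
(no down-sampling) evaluates all replicates of a tree in one batched
kernel call. Trees with zero changes (single-organ after filtering
should not occur, but is tolerated) contribute nothing. With a fixed
seed the entire result object is reproducible.

The `among_trees` permutation is implemented as a pooled shuffle of all
tip labels across the trees of a mouse: it preserves the per-mouse label
multiset exactly and is well defined for trees of unequal size.

## The synthetic data generator

The generator exists so every stage is testable and calibratable without
sequencing data. It emulates a two-cohort immunization study — six
organs × three mice per cohort — with:

* a few hundred founder clones per mouse, each with V/J genes drawn
  Zipf-weighted from configurable pools and a CDRH3 of realistic length
  (`CAR...W`, 10–20 aa);
* a discrete power-law (Zipf) clone-frequency distribution with
  per-organ exponent — heavy tails are the defining feature of
  immunized repertoires, where the top three clones can hold a third to
  two-thirds of an organ's reads. Exponent 0 gives a uniform repertoire
  (evenness 1), used as an analytic anchor in tests;
* organ sharing: each clone is seeded in a home organ and enters each
  other organ with probability `p_share` (scalar or per organ pair).
  Cohort defaults are 0.05 (single immunization, weak consolidation)
  vs 0.45 (boosted cohort, strong consolidation); mean pairwise Jaccard
  is monotone in `p_share`, which is the parameter-recovery test;
* SHM variants: each founder spawns a Poisson number of CDRH3 point
  mutants (≥1 substitution, uniform over the 19 alternative residues, no
  indels — the clone definition requires fixed length) that share its
  V/J and fall into its clonotype downstream;
* lineage trees: Yule topologies (`ape::rphylo`, pure birth) rooted at
  a germline node whose state is the founder organ; organ states evolve
  by a row-stochastic migration matrix applied once per branch (the SP
  test counts discrete transitions, not rates; a per-length Poisson mode
  exists as an option). Every simulated transition is recorded, giving
  ground truth for oracle comparison.

Fixed seeds give byte-identical output. What the generator does *not*
emulate — germinal-center selection, isotype switching, sequencing error,
primer bias, UMI artefacts — bounds what passing tests show: they
validate the statistical machinery, not robustness to upstream noise.

## Calibration and problem sizes

The test suite validates the SP test's error control at sizes chosen for
desk-scale runtimes: 200 null datasets of 10 trees (~12 tips, 3 organs)
with iid tip labels (a migration matrix with identical rows makes labels
exchangeable), 500 permutation replicates each. Observed type-I error at
nominal 0.05 was 10/200 = 0.050 (exact 95% CI [0.024, 0.090]) with a
Kolmogorov–Smirnov uniformity p-value of 0.47 for the null p-value
distribution. Power against the default planted migration scenario
(founder organ spleen; spleen→BM transition probability 0.15 per branch;
200 trees of ~14 tips) was 50/50 at p < 0.05. These numbers are
recomputed by `tests/testthat/test-acceptance.R` on every run.

## Known limitations

* Clone keys trust the upstream V/J calls; no realignment or allele
  genotyping is attempted.
* The parsimony model weights all organ transitions equally; unequal
  migration costs would require a cost-matrix extension of the same
  Sankoff kernel.
* `strategy = "enumerate"` is exponential in internal nodes and guarded
  at 12.
* The greedy NNI polytomy reordering finds a local optimum of the
  parsimony score; it is deterministic but not guaranteed globally
  minimal.
* Statistical comparisons *between* cohorts (t-tests, multiple-testing
  correction, rank correlations) are left to standard tools on the
  exported tables.
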