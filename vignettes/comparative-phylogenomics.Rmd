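---
title: "Comparative phylogenomics with nemacomp: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative phylogenomics with nemacomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nemacomp)
```

nemacomp packages the comparative-genomic toolkit used to study a clade of
closely related nematode genomes: which orthogroups are safe single-copy
markers, what species tree the gene trees support, how discrete
morphological characters and protein-domain counts evolved along that tree,
what genome-content features explain genome-size variation, and how gene
families duplicated and changed rate. Every stage is driven by plain
tabular or Newick inputs, and a synthetic-data module can generate all of
them with known ground truth, which is how the package tests itself. This
vignette explains the models and the judgement calls; it asserts nothing
the test suite and `scripts/acceptance.R` do not themselves compute.

## Tree handling

Trees are ape `phylo` objects with branch lengths in substitutions per
site. Internal Newick labels that parse as integers 0–100 are treated as
bootstrap supports; any other internal label is carried along but ignored.
Trees are used as rooted exactly as written — no midpoint or outgroup
re-rooting happens implicitly, because the screening and reconciliation
semantics below depend on the rooting the user chose.

`collapse_low_support(tree, threshold)` contracts every internal edge
whose child support is *strictly* below the threshold (an edge at exactly
the threshold survives). The contracted edge's length is discarded: every
consumer of a collapsed tree in this package (paralogue screening) reads
topology only, so preserving path lengths through collapsed nodes would
suggest a precision the object no longer has. Edges without a numeric
support annotation are kept — collapsing them would silently degrade trees
from tools that do not annotate every node.

## Single-copy orthogroup selection and paralogue screening

Selection takes an orthogroup table (`orthogroup_id`, `species`,
`sequence_id`, `length_aa`) and a `selection_policy()`. An orthogroup is
kept when present in at least `min_present` species and at most single
copy everywhere, except in an explicit list of species allowed up to two
copies — the escape hatch for assemblies with uncollapsed haplotypes and
for transcriptome-only proteomes, where apparent duplicates are expected
artifacts. "Up to two", not "exactly two": the allowance exists to tolerate
haplotype doubling, and absence or a clean single copy must never
disqualify an orthogroup.

Screening a gene tree for paralogy first collapses weakly supported edges
(default threshold 50), then asks, for each species with two sequences,
whether those sequences could form a clade in *some* resolution of the
collapsed tree. That is implemented as rooted-split compatibility: the
pair's leaf set must be nested-or-disjoint with every clade of the
collapsed tree. A fully collapsed star therefore blocks nothing — exactly
the behaviour wanted, since the evidence separating the two copies has
been erased. Species failing the test make the orthogroup a discard;
surviving in-paralogue pairs resolve to the longer sequence, ties broken
by lexicographically smaller id so reruns are stable. A species with three
or more copies discards the orthogroup outright: with that much
duplication the single-copy premise is gone, and guessing which copy is
orthologous would be invention. Whether in-paralogue resolution should
precede or follow the monophyly check is genuinely ambiguous in the
upstream literature; we collapse, then check, then resolve, and document
that order here.

The duplication-ratio QC statistic divides a species' total sequence count
in a selected orthogroup subset by the number of those orthogroups
containing it; it is ≥ 1 by construction and equals 1 only for a perfectly
single-copy species. `qc_screen()` selects the subset by minimum presence
and a maximum *mean* per-present-species count, defaulting to 1.5. A
strict mean of 1 would force all-single-copy orthogroups and make every
ratio exactly 1, contradicting the statistic's purpose, so "on average
single copy" is read as a rounding tolerance and left configurable.
Exclusion uses a strict `> 1.2`: a species sitting exactly at the
threshold is retained.

## Quartet supertree

The species-tree stage scores candidate topologies by their quartet
agreement with a set of gene trees: for every 4-taxon subset, a gene tree
votes for one of the three unrooted resolutions (or abstains if a polytomy
leaves the quartet unresolved, or if it lacks one of the taxa), and a
candidate's score is the number of votes for the resolutions it induces.
This is the objective that coalescent summary methods maximize; their
constrained dynamic-programming search is deliberately *not* reproduced.
At the scale this package targets, exhaustive enumeration (≤ 8 taxa,
10,395 unrooted topologies) gives certified optima, and a
nearest-neighbour-interchange hill climb from a random-addition start
covers larger taxon sets. Ties in exhaustive mode break to the
lexicographically smallest canonical Newick, so results are deterministic.
Scores are computed from restricted bipartitions, which makes them
invariant to how gene trees happen to be rooted.

## Equal-rates Mk and stochastic character mapping

Discrete characters (binary morphology; protein-domain counts treated as
unordered categories) evolve under the k-state equal-rates Markov model.
The rate convention is: total leaving rate `alpha`, split equally among
the k−1 target states, so for k = 2 the flip rate each way is `alpha`.
Fitted rates are convention-invariant given consistent use, and the test
suite checks the model depends only on `alpha × t` (rescaling the tree by
c while dividing the rate by c leaves the likelihood unchanged).

The likelihood is Felsenstein pruning with per-node rescaling (contract:
agreement with exhaustive state enumeration to 1e−9, verified on hundreds
of random trees). The root prior is uniform and exposed in `mk_model()`;
upstream tools differ between flat and stationary priors and the source
analyses do not say which was used, so the simplest choice is made
explicit. Rate fitting maximizes the likelihood on [0, 100]; because the
ER profile flattens into a plateau as `alpha` grows (tips become
independent draws), a plain golden-section search can strand on the
plateau, so the optimizer first brackets the peak on a coarse logarithmic
grid and then refines. Monomorphic characters return `alpha = 0` with a
boundary flag. On small star trees with lopsided data the MLE can sit on
that plateau; node posteriors then flatten toward the prior, which is a
property of the model, not a numerical failure.

Stochastic maps are sampled in two exact steps: joint node states by
backward filtering / forward sampling, then each branch history
conditional on its endpoints by uniformization. With the uniformization
rate set to `alpha`, the embedded jump chain is uniform over the other
k−1 states, which gives closed recursions for its n-step transition
entries; histories are exact draws, with bounded cost even at low rates on
long branches, where endpoint-conditioned rejection sampling would stall.
The mapping rate is fixed at its MLE ("empirical" mapping) rather than
sampled hierarchically, so posterior pies can differ slightly from a
fully Bayesian mapping; the summaries converge to the exact marginal
posteriors as the number of maps grows (checked at 100 vs 1000 maps), and
the default of 1000 maps matches the scale of the analyses this package
mirrors.

## PGLS under Brownian motion

Genome size is regressed on genome-content features by generalized least
squares with residual covariance proportional to shared root-to-MRCA path
length. The algebra is the textbook GLS solved via Cholesky whitening;
standard errors use the residual variance on n − p degrees of freedom and
two-sided t tests at α = 0.05, with no multiple-testing correction —
matching the per-predictor reporting convention of genome-size correlate
scans, where each predictor is fitted in its own simple regression
(a joint fit is available via `multiple = TRUE`). Species with missing
values in fitted columns are dropped with a warning rather than an error,
since trait tables routinely lack a column for a few taxa. Two exact
identities are exercised as tests rather than assumed: on a star tree with
equal depths PGLS coincides with OLS, and rescaling the tree leaves
estimates, t statistics and p-values unchanged.

## Genome and annotation metrics

Coordinates are GFF3: 1-based, inclusive. The longest isoform of each
gene (maximal summed exon length; ties to the lexicographically smaller
transcript id) is the unit of all gene-structure statistics:
`intron_count = exons − 1`, `intron_span` the summed inter-exon gaps
(`next_start − prev_end − 1`), and the conservation identity
`intron_span + exon_span = transcript extent` holds for every gene.
UTR handling is a per-dataset flag: when UTRs are annotated in only some
species, `utr = "exclude"` switches to CDS ranges so cross-species
comparisons are like-for-like; the default uses exons as annotated.
Intergenic distances sort genes by start within each scaffold, ignore
strand, exclude scaffold-terminal flanks, and floor overlapping pairs at
0 — the upstream convention is unstated, so the simplest defensible rules
are used and exposed. N50 is the largest length L such that scaffolds of
length ≥ L reach half the span. Orthologue-pair comparisons report
`log2` ratios of intron span and intron count, computed as differences of
logs so that swapping the two species negates every value exactly; pairs
with a zero on either side are dropped and tallied rather than silently
becoming infinities. Repeat content is ingested, never computed — repeat
annotation is a different tool's job.

## Gene-family analysis

Candidate family members shorter than 700 amino acids (inclusive lower
bound: exactly 700 survives) are dropped before tree-based analysis, the
standard guard against fragmented gene models. Duplication nodes are
inferred by species overlap — a node is a duplication iff at least two of
its child subtrees share a species — which is exact when no losses
occurred and degrades gracefully with loss (monitored in simulation, not
asserted as a bound). Post-duplication rate divergence compares, for the
two clades descending from a duplication node, the mean path length from
the duplication node to each tip (subtending branch included). The
alternative reading — the mean of individual edge lengths within each
clade — is available as `mode = "edges"`, because the upstream description
of "mean branch lengths" is ambiguous; the path mean is the default since
it is the only reading under which the comparison measures per-lineage
divergence since the duplication. Domain-count reconstruction maps the
distinct observed counts onto unordered Mk states and reuses the
stochastic-mapping machinery; an ordered stepwise model is out of scope.

## The synthetic-data module

Each generator emits its ground truth next to its data, and downstream
tests consume only the data. Species trees are Yule (pure birth): the
analyses need a clock-free tree with positive lengths, and pure birth is
the simplest process with a closed-form depth expectation to test against
(doubling the birth rate halves expected depth). Gene families evolve by
per-lineage duplication/loss along the species tree; a duplication whose
one daughter lineage dies out leaves no witness in the emitted tree and is
therefore not recorded as recoverable truth. Annotations lay genes
head-to-tail with configurable exon/intron/intergenic length generators,
optional second isoforms (strict exon subsets, so never the longest) and
an optional overlapping-gene fraction. Gene-tree discordance for the
supertree stage is emulated by NNI-perturbing the species topology rather
than by coalescent simulation — sufficient to exercise quartet conflict,
but not a model of incomplete lineage sorting.

What passing these tests shows — and what it does not: the synthetic data
match the *statistical assumptions* of each method (Mk characters really
are Mk, PGLS residuals really are Brownian), so the tests verify
correctness of the algorithms, calibration of the intervals and exactness
of the bookkeeping. Real genome data violate these assumptions in known
ways (rate heterogeneity, model misspecification, annotation error), and
nothing here measures robustness to that.

## Problem sizes and defaults

The shipped tests and the acceptance script use: enumeration-oracle
likelihood checks on 200 random trees of ≤ 7 leaves; 1000 stochastic maps
on a 6-leaf fixture against exact marginals; PGLS coverage and type-I
error over 200 replicates at 24 species (the scale of the genome-size
analysis the package mirrors); exhaustive-vs-NNI supertree agreement over
100 six-taxon replicates with 20 gene trees each; 200 simulated gene
families for duplication recovery; and a 500-gene synthetic annotation
for structure statistics. The demonstration pipeline (`run_demo()`) uses
16 species, 120 orthogroups and 300 maps and completes in well under a
minute on one core; all of these sizes are package choices made to keep
the checks sharp but quick, and every one is a function argument.

## Known limitations

- No missing or ambiguous tip states in the Mk machinery; no asymmetric
  or hidden-rate models.
- No Pagel's λ or OU transformations in PGLS; Brownian only.
- The supertree stage certifies optimality only at ≤ 8 taxa; NNI ascent
  can stop at local optima (empirically rare at the tested sizes).
- Species-overlap duplication inference cannot see duplications erased by
  loss, and reconciliation-based loss counting is not implemented.
- The annotation container assumes gene → transcript → exon GFF3 with
  `ID`/`Parent` attributes; pathological annotations (trans-splicing,
  shared exons across genes) are out of scope.
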