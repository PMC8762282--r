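---
title: "Methods: cross-species follicle development analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species follicle development analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(folliclemap)
```

# The scientific problem

Follicle selection — the admission of a growing follicle into the
preovulatory hierarchy — happens in every amniote ovary, but the stage
nomenclature, the compartment that synthesises sex steroids, and the
hormone trajectories differ sharply between birds and mammals. Chicken
follicles are staged by size (small yellow / pre-hierarchical at
6–8 mm, then F5 down to F1 before ovulation); mammalian follicles by
histology (primordial → primary → secondary → antral → preovulatory).
Putting granulosa (GC) and theca (TC) transcriptomes from several
species on one axis, and then asking which genes, biological processes
and core transcriptional regulators are private to one species, takes
a chain of fairly ordinary computational steps whose details are
rarely written down precisely enough to re-run. This package
implements that chain as tested, seedable components, together with
synthetic-data generators that plant a known truth for every step, so
each stage of the analysis carries a parameter-recovery test.

This vignette records the models, the tunable parameters and their
defaults, the numerical conventions, and the design decisions taken
where the methods literature leaves the choice open. All empirical
statements below are the ones the test suite and `scripts/acceptance.R`
actually compute.

# Expression integration

**Model.** Per-species FPKM matrices are joined over one-to-one
ortholog groups. A group survives only if, in *every* species, its
gene passes the expressed filter (maximum FPKM across samples ≥
`min_fpkm`, default 1). Non-1:1 groups are out of scope and dropped:
multi-mapping ortholog resolution is a research problem of its own,
and the 1:1 restriction makes `filter→map` and `map→filter` commute
(a tested invariant).

**Batch correction.** Public per-species datasets arrive one per
study, so batch and species are confounded; the default treats the
species of origin as the batch. Correction is a per-gene
location-scale adjustment on the log2(FPKM+1) working scale: within
each batch subtract the batch mean and divide by the batch SD, then
restore the gene's pooled mean and SD. Two deliberate conventions:

* *Population (1/n) SDs* for both batch and pooled moments. With
  sample SDs the restored pooled SD shrinks by √((n−B)/(n−1)) per
  application and the operation is not idempotent; with population
  SDs `remove_batch(remove_batch(x)) == remove_batch(x)` to 1e-9,
  which the tests assert.
* The corrected object carries log2-scale values (flagged `log2`),
  because a location-scale adjustment can legitimately land below
  zero on the log scale; forcing the result back to a non-negative
  FPKM scale would destroy the exact pooled-moment preservation.

No empirical-Bayes shrinkage is applied (ComBat-like but plain): with
one batch per species there is no replication across batches from
which to pool shrinkage targets, and the plain version has an exact,
testable contract. A zero-SD batch/gene receives the location step
only.

**Clustering.** Samples are clustered per compartment with average
linkage on 1 − Pearson correlation of z-scored rows (population-SD
z-scores; constant rows become zeros with a warning). Clusters are
named by the majority stage-group of the reference species' samples
they contain, ties toward the earlier developmental group, and
clusters without reference samples are "unassigned".

# Stage alignment by dynamic time warping

Per-stage profiles are replicate means on the log2 scale over the
shared ortholog index — one profile per stage, because the
cross-species comparison is of stages, not samples. The cost matrix
is 1 − Spearman correlation; undefined correlations (constant
profiles) are set to the maximum cost 2. The DTW uses the symmetric
step pattern (1,1), (1,0), (0,1) with unit weights, no window, no
slope constraint, and full boundary constraints; backtracking ties
prefer the diagonal, then the vertical step. `best_match` of a query
stage is the reference stage of minimal pair cost among optimal-path
pairs containing it, ties toward the earlier reference stage.

**A structural limitation worth knowing.** With equal-length series,
the boundary-constrained optimal path that duplicates the *final*
query stage onto an earlier reference stage strictly contains the
diagonal's cells plus one, so it can never win: a correspondence whose
last query stage repeats its predecessor's match is unrecoverable at
m = n. Stage compression earlier in the series (e.g. the map
(1, 1, 2)) is recoverable and is exactly the biological situation of
interest, where pre-hierarchical and early preovulatory stages of an
oviparous series compress onto the middle of a mammalian reference.
The synthetic fixtures plant such maps; recovery is exact at the
default noise (SD 0.2 log2 units, 3 replicates, 400 genes).

# Stage-specific and species-specific genes

**Differential expression.** The per-stage marker test is one-vs-rest:
stage S against all other stages pooled. The test is a per-gene
negative-binomial Wald test on FPKM values with method-of-moments
dispersion, `max(((v−m)/m²), 1e-8)` averaged over the two groups; the
group-mean variance is the model-based `(m + αm²)/n`, propagated to
the log2 fold change by the delta method. This self-contained test is
deliberately simple — no shrinkage across genes — so its operating
characteristics are fully captured by the null-calibration test (raw
positive rate within 3 binomial SDs of α on an effect-free fixture)
and the power test (≥ 34/40 planted 16-fold genes at padj ≤ 0.05 with
n = 3). Markers additionally require positive fold change and stage
mean FPKM ≥ 1. Multiple testing is Benjamini–Hochberg throughout.

**The funnel to a species-specific gene set.** Homology overlap of
stage sets across species is |intersection| / |union| on ortholog
groups (as a percentage). Enrichment is the exact hypergeometric
upper tail over a flat term-to-gene annotation (GO-style; a DAG-aware
propagation is a non-goal, and KEGG-style annotations run through the
same operation). Species-specific terms are those significant
(padj ≤ 0.05) in the target species and in no other. From the target
compartment's top-`top_k` terms (default 10, ordered by p), terms
also significant in the other compartment are removed; genes
annotated to the surviving terms are candidates; the final set keeps
candidates that are members of at least one target-compartment stage
set and of no other-compartment stage set. Ectopically expressed
orthologs are those whose single-compartment membership (GC-only vs
TC-only) flips between the query species and at least one other,
excluding any group observed in both compartments in any species.

# Super-enhancer calling

Peaks fully inside TSS ± 2.5 kb are removed, the rest are stitched at
a 12.5 kb gap (both ROSE conventions; all configurable), and each
stitched region's signal is the interval-length-weighted area of the
bedGraph track minus the matched control area, floored at zero.
Coordinates are 0-based half-open throughout; a TSS exactly at
region ± window is assigned, one base further is not.

**The hockey-stick cutoff.** Signals are sorted ascending and both
ranks and signals are min-max scaled to [0, 1]. The cutoff sits where
a line of slope 1 is tangent to the curve: the rank minimising
(scaled signal − scaled rank), ties to the *last* such rank, with
regions strictly above the signal at that rank flagged super. This
reproduces the textbook cases exactly — `[1,1,1,1,100]` yields one
super-enhancer, a perfectly linear ramp and all-equal signals yield
none — and is robust to noise at the bottom of the curve, where a
naive "first rank whose discrete slope exceeds 1" rule is hijacked by
a single low outlier (one large first gap) and flags essentially
everything. One honest caveat, shared with any data-driven elbow
including ROSE itself: on a continuous null (no planted
super-enhancers) the upper tail always rises faster than the
diagonal somewhere, so a handful of top regions are still flagged;
the tests assert this stays a marginal fraction rather than
pretending it is zero.

# Core regulatory circuitry

Candidate TFs are genes that have a PWM and at least one assigned
super-enhancer. Motif scanning is log-odds against background base
frequencies (default uniform), both strands, hit when the window
score reaches `threshold` × maximal attainable score (default 0.8);
reverse-strand hits are reported on forward coordinates, and windows
containing N never match. The network draws A→B when A's motif hits
any SE constituent assigned to B; self-edges are recorded but ignored
by the metrics.

Centrality is *harmonic* closeness, Σ 1/d over reachable targets,
normalised by (n−1): unlike classic closeness it is well defined on
disconnected directed graphs without reachability hacks, which these
small TF networks routinely are. Hubs are nodes with out-closeness
above mean + 1 population SD (multiplier configurable; zero variance
means no hubs). Regulatory circuits are maximal node sets of size ≥ 2
in which every ordered pair is connected — maximal cliques of the
mutual-edge graph — reported largest first.

# Clade specificity from multiple alignments

MAF blocks are parsed with minus-strand rows reverse-complemented
onto the forward frame at read time. For a reference interval, the
homologous slice takes alignment columns whose reference position
falls in the interval, concatenated across blocks in reference order;
species absent from a block contribute gaps, and reference bases
covered by no block count as gap columns for every other species —
absence of alignment is treated as the strongest deletion signal.
Gap fractions are gaps/columns per species (identically 0 for the
reference, a tested invariant, and invariant to splitting a block at
any column). The verdict at threshold `max_gap` (default 0.5; the
underlying biology offers no canonical number, so it is a parameter,
not a calibration): *clade-specific* when all clade members are at or
below the threshold and all non-members above it; *not-conserved*
when no species besides the reference is at or below it; *shared*
otherwise. Binding profiles scan each species' ungapped slice with
the candidate PWMs.

# Auxiliary statistics

The GSEA enrichment score is the classic running sum: hits add
|score|^w normalised over hits (w = 1 default, w = 0 available),
misses subtract 1/(N−Nh); the ES is the extremum of largest
magnitude, with magnitude ties resolved to the positive extremum, and
a set spanning the whole list scores +1 (the miss term is absent).
The permutation p-value reshuffles set *membership* (size preserved)
rather than phenotype labels — three replicates per group cannot
support phenotype permutation — with the add-one rule
p = (1 + #{|ES\*| ≥ |ES|})/(n_perm + 1), so p is never zero. The
egg-laying test is the exact lower-tail binomial CDF with the
baseline rate as p₀. One-way ANOVA runs through `stats::aov`;
when the omnibus test passes, pairwise LSD t-tests on the pooled MSE
are summarised as letter groups via the insert-and-absorb algorithm,
which guarantees that significantly different pairs never share a
letter and non-significant pairs share at least one (a tested
property, since letter displays are easy to get subtly wrong).

# What the synthetic data emulates — and what it does not

The generators are first-class, tested components, and their defaults
define the study conditions used by every recovery test:

* **Expression** (`generate_expression`): baseline log2-FPKM per
  ortholog drawn once from Normal(3, 2) and shared across species
  (log-normal FPKM margins, the familiar bulk RNA-seq shape);
  replicate noise SD 0.2; per-gene additive batch offsets
  Normal(0, batch_sd = 1) aligned with species; stage-marker blocks
  of 30 genes per compartment and reference stage, up-shifted by
  log2(16); 40 species-specific genes expressed (FPKM ≥ 1) only in
  their designated species/compartment/stage block, one of which is
  also planted in the TC compartment to exercise the exclusion rule.
  The off state of a specific gene is log2-FPKM −3 without batch
  response: absence is absolute, does not scale with batch, and stays
  below FPKM 1 deterministically, which is what makes the generator's
  "expressed only in the designated block" guarantee hold exactly.
* **Epigenome** (`generate_epigenome`): 1 kb constituents; typical
  per-bp amplitude LogNormal(0, 0.08); planted SE clusters of three
  constituents at 16× typical amplitude with 2 kb internal gaps
  (safely inside the stitch distance) and 80 kb spacing between
  regions so no region's TSS falls in a neighbour's assignment
  window; one gene per region, the first SEs owned by the TF genes;
  exact 12-bp consensus substrings planted so the implied regulatory
  graph (a hub with motifs in every SE constituent, a fully
  interconnected three-TF circuit, one extra edge) is recovered
  deterministically — at 12 bp the expected number of spurious exact
  matches over the whole fixture is far below one.
* **Alignments** (`generate_alignment_blocks`): 77 species (reference
  plus a 14-member bird clade plus outgroups), gap-free reference
  rows, per-column gap rates 0.05 inside conserved rows, 0.6 for
  outgroups in clade-conserved intervals and 0.8 in non-conserved
  intervals, interval length 1200 — the binomial concentration at
  that length keeps clade and outgroup fractions cleanly on either
  side of the 0.5 threshold.

Problem sizes in the tests and acceptance script (400–500 ortholog
groups, 3 species × 2 compartments × 3 stages × 3 replicates, 420
regions, 77 alignment rows, 1000 permutations) were chosen as the
smallest at which every planted structure is comfortably recoverable;
the whole suite runs in a few minutes on one core.

What passing these tests shows is that every operation implements its
contract and that the pipeline recovers clean planted structure. What
it does not show: the generators use independent log-normal noise (no
gene–gene correlation, no mean–variance trend beyond the NB moment
relation, no read-level sampling), batch effects that are purely
additive, motif plants that are exact consensus copies, and alignment
gaps that are column-independent. Real data violate all of these, so
recovery rates here are upper bounds, not forecasts, and headline
quantities from the original multi-species datasets (total homologous
gene counts, super-enhancer tallies per cell type, hub counts) depend
on those external inputs and are not asserted anywhere in the
package.

# Degenerate inputs and tie-breaks, collected

* `filter_expressed` warns (not errors) on an empty result.
* Constant rows z-score to zeros with a warning; constant profiles
  get maximum DTW cost 2.
* `hclust` merge ties resolve by smaller element index; cluster-name
  ties by earlier developmental group.
* DTW backtracking ties: diagonal, then vertical; best-match ties:
  earlier reference stage.
* All-zero genes: fold change 0, p = 1.
* Hockey-stick: all-equal signals → no super-enhancers; tangent ties
  → last rank.
* GSEA extremum magnitude ties → positive; permutation p has the
  add-one floor 1/(n_perm+1).
* LSD letters only when the omnibus ANOVA passes; zero within-group
  variance everywhere is an error, not a letter display.
* Overlapping intervals within one bedGraph track are an error;
  malformed intervals (end ≤ start) are an error.
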