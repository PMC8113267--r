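---
title: "clrseq: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{clrseq: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model behind
each stage, the parameters that matter and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and the
design decisions that were genuinely open. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The inference problem

Cluster RNA-seq sequences small clumps of physically connected cells
(partial dissociation, ~4–8 cells, a mean of 6) alongside single cells on
the same droplet platform. A clump's UMI count vector is, to a good
approximation, the sum of its member cells' counts. If the tissue is
organised into spatial domains of transcriptional states, a clump sampled
inside a domain looks like a "pure" bulk of one state, while a clump
straddling a domain boundary carries a *mixed* identity — it correlates
significantly with two state signatures at once. Mixed identities are
therefore evidence of physical adjacency between states, and the set of
observed mixed pairs constrains the spatial arrangement: for a
one-dimensional tissue (the embryonic nephric duct's rostro-caudal axis is
the motivating case), it can identify the linear order of the states.

Two caveats are built into the design. First, partial dissociation can
produce artefactual aggregates of unrelated cells ("sticky" cells), which
masquerade as mixed identities; the adjacency graph therefore requires a
minimum support of 2 mixed calls per edge, and the assignment step refuses
to interpret groups that resemble *every* state at once (Section 5).
Second, a cluster with mediocre correlation to everything is left
unassigned rather than forced into a call.

## 2. Quality control

* `min_genes = 200`, `max_mito_fraction = 0.05`: conventional per-library
  gates, computed on raw counts (mitochondrial fraction before
  normalisation, the usual QC convention).
* `cluster_umi_min = 35000`, `single_umi_max = 9500`: a library with more
  than 35,000 total UMI is a cluster, below 9,500 a single cell. The band
  in between is *ambiguous* and excluded from analysis — with a median
  single cell at ~6,000 UMI, a library at 20,000 could be one large cell
  or a small clump, and neither interpretation is safe. Note the
  consequence for the simulator's world: true clusters of 2–5 cells often
  fall below 35,000 UMI and are deliberately lost to the ambiguous band.
  The QC accuracy property ("kind recovery ≥ 99%") is therefore measured
  over the confidently classified libraries; it asserts that the two
  thresholds essentially never *cross-assign* a single as a cluster or
  vice versa, not that every library is classified.
* `est_cells = round(total_umi / median single-cell total)`, floored at 2
  for clusters: a first-order estimate that ignores per-cell depth
  variation; on the default simulation it tracks the true mean member
  count to within 1 cell.
* Gene-level tools: blacklist removal by flag (sex-linked genes by
  default), a binned-control gene-set score (25 expression bins, one
  random control gene per set gene — a deliberately simple, seed-controlled
  stand-in for published cell-cycle scorers), and covariate regression
  (per-gene OLS with intercept; covariates centred internally so the
  output retains each gene's mean level while removing the covariate
  directions). `gate_by_markers` applies strict `>` thresholds, as in
  marker-based spatial-spot gating (e.g. Pax2 > 0.5 / EGFP > 0.8 /
  Lhx1 > 0.5 on normalised expression).

## 3. Signatures

Normalisation is `ln(1 + 10^4 · c / total)`. Differential expression is a
one-vs-rest two-sided Wilcoxon rank-sum test per gene: the normal
approximation with tie correction (no continuity correction) in general,
and the exact distribution when both groups have ≤ 10 libraries and the
values are tie-free — this makes tiny examples exactly reproducible (the
fully separated 4-vs-4 case gives p = 2/70). The log fold change is
`ln((A+1)/(B+1))` with A, B the group means of `expm1(x)` — natural log and
pseudocount 1, matching the long-standing convention of the single-cell
toolkit this mirrors, so the threshold `logFC > 0.25` keeps its
conventional meaning. Benjamini–Hochberg correction is applied across
genes *within* each state (matching per-state marker tables); markers pass
`logFC > 0.25` and adjusted `p < 0.05`; the top 20 per state (ascending
adjusted p, ties by descending logFC, then gene id) form the signature
set. Signature profiles z-score each gene's state means across *all*
states; constant rows become zeros.

## 4. Correlation and the choice this package had to make

The assignment statistic is the Pearson correlation between a query
library and a state reference over the signature gene set, with calls at
`r > 0.6` and permutation `p < 0.01`. Two formulations of "correlation to
a state" coexist in the field:

1. correlate the query to **every reference cell** and average per state;
2. correlate the query to the **per-state mean profile** (centroid).

These differ by a reliability factor: formulation (1) multiplies every r
by the reference cells' own signal fraction. Under this package's stated
noise model (negative binomial with dispersion θ = 2 at ~6,000 UMI per
cell), a cluster *identical in expectation* to its state's profile reaches
a mean per-cell r of only ~0.4–0.6 depending on preprocessing — an
absolute threshold of 0.6 is then unreachable even for perfect matches,
not because the match is poor but because individual reference cells are
noisy. Formulation (2) removes the reference-side attenuation and leaves
the threshold meaningful: pure clusters reach r ≈ 0.9, cross-state
baseline sits at ≈ 0.4, and boundary clusters score ≈ 0.7 for both
constituent states.

`correlate_to_reference()` implements both (`ref_summary = "cells"` /
`"centroid"`), and both with and without prior per-gene z-scoring across
libraries (`row_standardize`). The end-to-end assignment
(`identify_queries()`, the pipeline, the acceptance checks) uses
**centroids on the raw normalised scale**, i.e. correlation coefficients
are computed on expression and any z-scoring of the *coefficient matrix*
is left to visualisation, which is also how the classical
correlation-heatmap workflow applies `cor()` and `scale()`. Per-gene
z-scoring before correlation is kept as an option; it sharpens contrasts
for display but pushes mixed profiles' correlations to both parents below
any absolute threshold, so it is not used for calling.

## 5. Grouping and the barcode-permutation test

Calls are made at the level of query *groups*, mirroring the subgroup
(Cl-a … Cl-f) granularity of the original workflow; every member library
inherits its group's call. Per-library calling is exposed
(`grouping = "per_library"`) but has an intrinsic limitation: with
singleton groups the permutation null for state *s* is the empirical
distribution of all queries' r to *s*, so a library of a state that a
quarter of the libraries share can never be in the top 1% — the group
level is where the test has meaning.

The default grouping is by **candidate identity pattern**: the set of
states whose centroid r exceeds `r_min − pattern_margin` (0.6 − 0.1 =
0.5). Boundary clusters of one state pair thus pool into a single group
of natural size, which matters because the permutation test's power grows
with group size. Hierarchical grouping on (1 − Pearson) distance between
correlation fingerprints is provided (`group_queries()`), but boundary
clusters form a *continuum* between the pure blobs (their mixture
fractions vary smoothly), which agglomerative clustering either absorbs
into the pure groups or shatters into underpowered fragments. The margin
0.1 was fixed once from the geometry of the default world: the
second-highest r of pure clusters stays below ~0.5 while boundary
clusters' minor state exceeds it in ~90% of cases, so 0.5 is where the
two densities cross.

The permutation test shuffles group labels across queries (the "barcode
shuffle", 1,000 times by default) and counts permuted statistics at least
as large: `p = (1 + #{T* ≥ T}) / (1 + n_perm)` — add-one, so p is valid
and never below `1/(n_perm+1)`; a greater-or-equal count keeps it
conservative. An exhaustive mode enumerates all distinct label
assignments for small problems. The statistic is the plain group mean r
by contract; the end-to-end wrapper uses a **studentised (Welch) variant**
— `(mean_g − mean_rest)/sqrt(s_g²/n_g + s_rest²/n_rest)`, with tiny groups
borrowing the rest's variance — because the mean's null distribution has a
heavy right tail (any random group that happens to capture several
pure-state libraries scores high), which costs exactly the power needed to
certify a mixed group's second state. Thresholding of r always happens on
the untouched group-mean correlation; only the p-value uses the
studentised null.

Two guards temper the calls. A group whose mean r exceeds 0.6 for states
*outside* its significant set is left unassigned: moderate-to-high
correlation with everything is the fingerprint of an artefactual (sticky)
aggregate, and under group-level calling all of a run's sticky clusters
can land in one coherent group — skipping the guard, they would pass the
thresholds for some non-adjacent pair and plant a false edge whose support
exceeds `min_support`. Second, `min_support = 2` in the adjacency graph
itself drops edges supported by a single mixed call.

## 6. The spatial graph and seriation

Each mixed call adds one support count to every unordered state pair in
its call set. Pairs of observed states with zero support are *forbidden* —
the computational form of "these states are never found in physical
proximity". Seriation searches all `S!/2` orders (exhaustive up to S = 9;
spectral for larger S behind an explicit flag) for minimum cost, where
cost counts supported edges whose endpoints are not adjacent in the order.
Forbidden pairs contribute no cost by default (absence of evidence is not
a constraint), though an optional penalty exists. Orders are reported
modulo reversal: a 1D axis has no intrinsic direction in the data;
orientation is user metadata.

## 7. The synthetic world

The generator emulates the stated experimental conditions: 4 states on
[0,1] with layout 1:[0,0.25), 2:[0.25,0.55), 3:[0.55,0.70), 4:[0.70,1] —
a broad second domain touching the others' neighbourhood structure as a
path 1–2–3–4; G = 2,000 genes, M = 30 markers per state at fold change
f = 4; negative-binomial counts with dispersion θ = 2; single-cell UMI
median 6,000; cluster sizes 2 + Poisson(4) (mean 6, minimum 2); member
positions within `δ = 0.03` of the cluster anchor; logistic boundary
mixing of width `w = 0.02`; sticky rate `ε = 0.02`. Choices the stated
world left open, fixed once here: baseline relative expression is
log-normal(0, 1) (two orders of magnitude of expression range); per-cell
library size is log-normal around the median with `sdlog = 0.25` (so the
mean total is `median · exp(sdlog²/2)` ≈ 6,190); "truncated normal(0, δ)"
offsets are truncated at ±δ — δ is read as the maximum positional spread —
then clipped to [0,1]; boundary softening leaks probability only across
the *nearest* boundary, `P(neighbour) = 1/(1 + exp(d/w))`, which makes a
position exactly on a boundary split 0.5/0.5 exactly. Each library draws
from its own child RNG stream of the master seed, so subsetting a run is
reproducible, and gene-level quantities are drawn once per model under
`model_seed`.

The knockout scenario removes one state: cells drawn in its domain
express the *average* of two other states' relative-expression vectors
(the "hybrid" program) and are labelled `hybrid` in the truth, never the
removed state. Scoring cells against control signatures
(`score_cells()`, mean marker z-score per state, hybrid iff the top two
scores exceed τ = 0.25) then shows a hybrid fraction strictly above the
control run's, and the removed state receives no pure cluster calls.

What the generator does **not** emulate: ambient RNA, batch effects,
doublet-specific library-size artefacts beyond additivity, UMI collisions,
2D/3D geometry, and real marker-gene expression distributions. A green
test therefore establishes that the pipeline's logic recovers a known 1D
neighbourhood structure under realistic count noise — not that any
particular biological dataset would yield the same accuracy.

## 8. Numerical and degenerate-input choices

* Wilcoxon: `σ² ≤ 0` (all values tied) gives p = 1; exact branch only
  without ties and with both groups ≤ 10.
* Correlation: constant profiles over the gene set yield r defined as 0
  with a warning; constant gene rows are left unscaled (all-zero after
  centring) rather than dividing by zero.
* Signature z-scores: constant rows become all zeros.
* Permutation: ties in the statistic count as exceedances (`≥` with a
  1e-12 slack), keeping the constant-statistic case at p = 1.
* Seriation ties: all minimum-cost orders are returned, lexicographically
  sorted, reversal duplicates removed by keeping the orientation whose
  first state precedes its last.
* Merging intersects gene axes by id (symbols are ambiguous); a
  union-with-zero-fill flag exists. Colliding barcodes get `-<source>`
  suffixes.
* est_cells requires single libraries; 0 singles is an error, fewer than
  10 a warning.
* The pipeline's signature stage reads reference state labels from the
  simulation truth; on real data the labels would come from an upstream
  clustering, which is out of scope here — the package starts from a
  labelled single-cell reference.

## 9. Known limitations

* The permutation test's power depends on group size; very small real
  groups (< ~8 queries) of genuinely mixed identity can miss `p < 0.01`
  for their minor state, which is the dominant failure mode of adjacency
  recovery at the acceptance margins.
* The ambiguity guard suppresses sticky groups at the cost of discarding
  any genuine group that correlates > 0.6 with three or more states; in a
  1D tissue with `δ` much smaller than domain widths such groups should
  not exist, but in other geometries the guard may be too strict.
* `est_cells` is biased for clusters of unusually deep or shallow member
  cells; it is a QC aid, not a deconvolution.
* Composition comparison uses a per-state Fisher exact test with BH
  correction — adequate for flagging absent/depleted states, not a
  compositional model.
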