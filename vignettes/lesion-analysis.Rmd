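---
title: "Lesion analysis of structural connectomes: models, choices, limits"
author: "coreScaffold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion analysis of structural connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The model

A subject's connectome is a symmetric, nonnegative, zero-diagonal G×G
matrix over a fixed parcellation; weights are streamline counts normalized
so each subject's unordered-pair total is 1. A cohort is N such matrices
over one parcellation, and is the unit of every statistic in this package:
all tests compare a quantity computed on each subject's *intact* network
with the same quantity after an identical in-silico lesion, pairing by
subject.

Two lesion families are simulated exhaustively. A *node* lesion deletes one
cortical parcel and its incident connections, yielding a (G−1)-node
network; under the default 165-parcel scheme the 148 cortical parcels are
lesionable while subcortex, cerebellum and brainstem remain fixed network
nodes. An *edge* lesion zeroes one unordered pair, and the sweep covers all
G(G−1)/2 pairs whether or not the edge exists in a given subject — removing
an absent edge is the identity, which downstream statistics exploit to
recognize untestable pairs. Lesioned networks are never renormalized: a
lesion removes tissue from the measured network; it does not rescale what
survives.

## Network measures

Distances use the inverse-weight rule, length = 1/weight: strong
connections are short. This is the standard convention of the
brain-connectivity toolboxes for streamline-count weights; it is exposed as
an argument (`rule`) so a binary variant is available. Integration is the
characteristic path length λ, the mean of *finite* off-diagonal distances.
The finite-pairs convention matters because lesions can disconnect a
network: an infinite λ would destroy the paired statistics, so disconnected
pairs are excluded and the value carries a `disconnected` flag; a fully
disconnected network raises an error that the sweeps convert to a counted
missing cell. Segregation is mean nodal local efficiency: for each node,
shortest-path distances are computed *within the subgraph induced by its
neighbors* and inverse distances averaged over ordered neighbor pairs
(unreachable pairs contribute 0, nodes with fewer than two neighbors score
0). The neighbor-subgraph definition is adopted because it is the only
well-formed reading of "efficiency computed on the neighborhood";
alternatives that reuse whole-network distances conflate local and global
structure.

Assortativity (Pearson correlation of endpoint degrees over the symmetrized
edge list), density, transitivity (3·triangles/triples) and per-node
clustering are computed on the binary topology (edge present iff
weight > 0) — the weighted generalizations of the clustering-type measures
are not unique, and the binary forms are the elementary ones the analysis
needs. Degenerate values (assortativity on a regular graph, transitivity
with no connected triple) surface as typed undefined values carrying a
reason, never bare NaN; sweeps count them as missing cells and the tests
drop them pairwise, reporting how many.

## Statistics

Node lesions are tested per (parcel, metric) with a two-sided paired
*t* test on healthy-minus-lesioned differences. The Bonferroni family
defaults to (number of lesioned parcels) × (number of metrics) — each
(parcel, metric) pair is one hypothesis; the family size is a named
argument for users who prefer per-metric families. All-zero differences
give t = 0, p = 1; constant nonzero differences are a degenerate flag, not
a crash.

Edge lesions are tested with the paired Hotelling T²: with differences D
(N×p, p = 4 features), T² = N·d̄ᵀS⁻¹d̄ with S the (N−1)-divisor sample
covariance, F = (N−p)T²/[p(N−1)] referred to F₍p,N−p₎, rejection when the
upper tail probability falls below α/m with m = G(G−1)/2 — *all* possible
connections, present or not, because the hypothesis family is defined by
the parcellation, not by any one cohort's topology. Two numerical rules
keep this well-posed on real sweep output:

* **Singular S.** Feature components can be constant across subjects (the
  density decrement of an always-present edge is exactly −1/m for every
  subject; in cohorts sharing one topology the same holds for
  assortativity and transitivity). S is then singular, and a naive solve
  would be wrong. The test uses the Moore–Penrose pseudoinverse with the
  effective rank of S as p in the F conversion, flagging the result. The
  practical consequence is principled: difference components with no
  across-subject variance carry no evidence about a *distribution* shift
  and are projected out.
* **Non-testable pairs.** Edges absent in every subject have all-zero
  differences (T² = 0, p = 1, never significant); edges with fewer than
  p + 2 subjects showing any nonzero difference are likewise reported
  non-testable rather than trusted to an ill-conditioned covariance.

The scaffold is the set of significant edges sorted by descending F, at a
lenient level (α = 0.05) and a stringent one (α = 0.0001); shrinking α can
only shrink the scaffold.

## Decompositions

The lesion-effect correlation matrix **R** correlates, across subjects, the
*post-lesion* metric values of one lesion with another's — post-lesion
values rather than healthy-minus-lesioned differences, because the intact
value is a shared constant within subject and the explicit definition of
the analysis is in terms of the measure "computed after the removal" of
each region. Rows follow the parcellation's ordering convention
(right hemisphere first, antero-posterior within lobe) so block structure in
**R** is anatomically interpretable. PCA is by eigendecomposition of the
column covariance; variance fractions are eigenvalue shares; each loading
column is oriented so its largest-magnitude entry is positive, making
outputs deterministic.

The edge-effect tensor has a genuine ambiguity: the raw object is 4-way
(edge i, edge j, target node, subject) and "collapse by correlation across
subjects" does not name the two series to correlate. The package's rule:
C[k,k′,k″] is the across-subject correlation between the nodal effect at
k″ of removing {k,k′} and the *global λ effect* of the same removal. This
yields exactly one coefficient per entry, reduces to a G×G×G tensor
symmetric in (k,k′), and reads as "does node k″ track the global damage
this edge causes". It is one defensible rule among several; it is isolated
in `edgeEffectTensor()` precisely so alternatives can be swapped, and no
claim is made that it reproduces any particular published map. The nodal
metric defaults to eccentricity (distance-based, hence sensitive to edge
removal); betweenness, clustering and local efficiency are available.

MPCA treats mode-3 slices (one G×G effect matrix per target region) as the
sample set, centers by the sample mean, initializes per-mode projections by
full-projection truncation (multilinear SVD) and refines them by
alternating partial-projection eigendecompositions. Each alternating step
is a coordinate ascent on captured variation, so the trace is nondecreasing
and the refinement can only improve on its initializer — both properties
are asserted in the test suite. Iteration stops when captured variation
changes by less than `tol` (default 1e-8) or at `maxIter` (default 100);
on tensors with near-tied spectra the ascent can crawl along a plateau, in
which case the result is returned with `converged = FALSE` rather than
pretending finality. Missing tensor entries (degenerate correlations) are
imputed to 0 — "no effect", the conservative value — and counted.

# The synthetic cohort generator

The generator emulates what the analysis *assumes* about real cohorts, not
any particular dataset: modular topology (planted-partition blocks), sparse
inter-module routes, positive right-skewed weights (log-normal,
`weightLogMean = 0`, `weightLogSD = 1`), per-subject multiplicative
log-normal noise (`subjectNoiseSD = 0.5`, weight CV ≈ 50%, within the range
reported for streamline counts), per-subject normalization, and optional
planted inter-module bridges boosted in weight — the recoverable ground
truth. Defaults are sized to a typical healthy-adult cohort: the 165-parcel
scheme, N = 110 subjects, six modules, within/between edge probabilities
0.6/0.05. One base topology is shared by the cohort (subjects differ in
weights), reflecting shared gross anatomy; `edgeDropout` optionally drops
non-planted edges per subject to emulate the inconsistency of weak
tractography connections and to exercise absent-edge code paths. Homotopic
left/right weight coupling (`symmetryRho`, default 0) is available when the
parcellation has mirrored labels; it is off by default because it does not
interact with any statistic computed here. Reproducibility is strict: the
base topology and weights derive from the master seed, and each subject
gets an independent substream drawn from it, so cohorts are identical
across runs and independent of iteration order.

What the generator does **not** emulate: geometric embedding and
distance-dependent wiring, hub-specific degree distributions, measurement
artifacts of tractography (length biases, false continuations), and any
quantitative match to human weight distributions. Passing tests on
synthetic cohorts therefore demonstrate the *statistical machinery* —
calibration, recovery, invariances — not anatomical fidelity.

## Design of the scaffold-recovery experiment

The recovery experiment (G = 40, N = 30, four modules of ten, ten planted
bridges) asks whether `extractScaffold()` finds exactly the planted edges.
Its cohort configuration differs deliberately from the generator defaults,
because recovery is an *identifiability* question: in a cohort whose
subjects share one topology and differ only by mild weight noise, the λ
effect of removing any present edge is near-deterministic across subjects,
so the paired test — correctly — flags dozens of genuinely load-bearing
edges, and no planted subset can be distinguished. For the planted truth to
be identifiable, planted bridges must be the only inter-module routes
(`pBetween = 0`), modules must be internally redundant
(`pWithin = 0.9`) with relatively homogeneous weights
(`weightLogSD = 0.25`) so no single within-module edge is critical, and
inter-subject variability must be realistic rather than mild
(`subjectNoiseSD = 1`, weight CV ≈ 130%, the upper range seen for weaker
connections in test–retest tractography). Bridges are boosted ×5. Under
this design the scaffold recovers 9–10 of 10 planted bridges with 0–2
false positives across master seeds 1–10; the occasional false positive is
a strong within-module edge whose alternatives happen to be weak — a
borderline case of real criticality, not a calibration failure.

# Numerical choices and degenerate inputs

* Connectome I/O writes 17 significant digits; write→read round-trips are
  bit-exact. Asymmetric, negative or NaN matrices are rejected on read,
  never repaired.
* Rank decisions (Hotelling S, PCA truncation) use an
  eigenvalue tolerance of (matrix dimension) × machine epsilon × largest
  eigenvalue.
* The empty (all-zero) connectome is a valid container; it cannot be
  normalized and its distance matrix is all-infinite off-diagonal.
* Ties in shortest paths cannot bias results: distances, λ and the tests
  depend only on path lengths, not on which optimal path is chosen.
* The pipeline (`runPipeline()`) aborts naming its failed stage; the one
  tolerated in-run degeneracy is an intact nodal metric with zero variance
  everywhere (inevitable for binary-topology metrics in shared-topology
  cohorts), which is skipped and recorded in the run summary.

# Problem sizes

The test suite and the acceptance script run at desk scale by design:
oracle comparisons on 50 random graphs of 6–12 nodes against
Floyd–Warshall / enumeration / closed-form references; Hotelling
calibration on 5,000 null replicates at N = 30, p = 4; the recovery
experiment at G = 40, N = 30 (780 pairs × 30 subjects per sweep); demo
pipelines at G = 12–20. The full 165-parcel, 110-subject configuration is
the generator default and runs through the identical code paths; only its
edge sweep (13,530 pairs × 110 subjects) is a compute job rather than a
test.

# Known limitations

* The feature vector's density component is a deterministic counter: for an
  edge present in most-but-not-all subjects it alone can drive
  significance. The rank-reduction rule neutralizes this only in the
  all-subjects-present case; interpretation of scaffolds from
  heterogeneous-topology cohorts should weigh the per-edge `pDim` and
  `nNonzero` columns.
* The edge-effect tensor collapse is one defensible convention (see above);
  conclusions drawn from MPC loadings should be checked under an
  alternative collapse before being given anatomical weight.
* MPCA convergence on near-degenerate spectra is slow; respect the
  `converged` flag.
* Synthetic cohorts validate statistics, not anatomy; no claim about any
  specific human dataset follows from the tests shipped here.
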