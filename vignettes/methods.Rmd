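---
title: "Coupling structural covariance and transcriptional brain networks: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupling structural covariance and transcriptional brain networks: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transcortex)
```

## The scientific problem

Cortical regions whose thickness co-varies across subjects tend to be
anatomically connected, and anatomically connected regions tend to share
transcriptional profiles. `transcortex` implements the full analysis chain
needed to quantify this triple coupling on a common cortical parcellation:

1. a **structural covariance network** (SCN): inter-regional Pearson
   correlation of cortical thickness across subjects, thresholded to keep a
   fixed density of the most strongly positive correlations;
2. a **transcriptional brain network** (TBN): inter-regional correlation of
   regional whole-genome expression profiles, built from scattered
   post-mortem microarray samples mapped onto the same parcellation;
3. **coupling statistics** relating the two edge sets to each other, to
   physical distance, and to the co-expression of focused gene sets — in
   particular the 19 human supragranular enriched (HSE) genes, expressed in
   cortical layers II/III where long-distance cortico-cortical projections
   originate.

Because the empirical datasets behind such analyses are large and external,
the package ships a synthetic cortex generator that reproduces the
*statistical structure* the analysis relies on, so that every stage — from
probe collapsing to permutation inference — is testable end to end.

## Expression mapping

Microarray samples arrive as donor-space coordinates with per-probe
expression. The mapping stage follows the conventions of post-mortem
transcriptome atlases:

* **Probe collapsing.** Genes measured by several probes keep the probe
  with the highest mean expression over cortical samples; exact ties go to
  the lexicographically smaller probe id (the tie rule is ours; ties are
  measure-zero in real data).
* **Hemisphere reflection.** Right-hemisphere samples are mirrored onto the
  left hemisphere (sign flip of the left-right coordinate) to increase
  sample density; the analysis is left-hemisphere only.
* **Parcel assignment with a 2 mm tolerance.** A sample belongs to the
  parcel whose surface contains it; samples up to 2 mm outside any parcel
  surface (typically mis-registered into subjacent white matter) are
  assigned to the nearest parcel, and samples further out are dropped. With
  point-cloud surfaces, containment is judged at the cloud's resolution:
  the distance to a parcel is the distance to its nearest surface point
  minus the atlas resolution, floored at zero.
* **Normalization and aggregation.** Expression is z-scored per gene
  *within donor* across that donor's assigned cortical samples, pooled over
  donors, and summarized per parcel as the median. Within-donor z-scoring
  is the minimal scheme that makes donors with different microarray scales
  commensurable and is, by construction, invariant to any per-donor affine
  rescaling — a property the test suite asserts. A parcel with no samples
  is filled with the unweighted mean of its spatially adjacent sampled
  parcels and flagged; we read "linear interpolation" of a lone empty
  parcel as this neighbour mean, since no kernel is canonical on a graph.

## Networks and topology

Both networks are thresholded by **connection density**: exactly
`floor(rho * N(N-1)/2)` of the most strongly positive correlations become
edges (negative correlations are never admitted, whatever the requested
density). Edge sets are therefore nested across densities, which the tests
verify. The topology battery — clustering coefficient, characteristic path
length over reachable pairs, local and global efficiency, small-worldness,
assortativity, rich club, participation coefficient — is normalized against
1000 degree-preserving rewired graphs (double-edge swaps). Conventions for
disconnected graphs: path length averages over reachable pairs only and
efficiency counts unreachable pairs as zero contribution, the standard
efficiency convention. Small-worldness uses the clustering/path-length
ratio form `(Cp/<Cp_rand>)/(Lp/<Lp_rand>)`.

## Community structure

Partitions come from Louvain modularity maximization at resolutions
`gamma = 1` and `gamma = 2`, using the standard `1/(2m)` Newman–Girvan
normalization with the resolution multiplying the null term
(Reichardt–Bornholdt convention). Because Louvain is stochastic, a
**consensus** partition is computed: 1000 runs are reduced to a node×node
co-assignment matrix, which is itself re-clustered (full weighted matrix,
no threshold) until every run of an iteration agrees, up to 10 iterations.
Two implementation choices matter:

* each Louvain run is followed by a deterministic single-node-move hill
  climb, which removes most run-to-run variability on small graphs and
  guarantees a node-move local optimum — on exhaustive enumerations of all
  partitions of ≤ 8-node graphs the consensus attains the global optimum;
* the reported `Q` is always re-evaluated on the *original* graph by a
  direct formula, which an independent double-loop oracle (and
  `igraph::modularity`) confirms in the tests.

## The spatially contiguous permutation null

Within-module co-expression is biased upwards by spatial autocorrelation
alone, so it is compared against pseudo-random partitions that preserve the
number of modules, the exact multiset of module sizes, *and* the spatial
contiguity of every module. Our realization grows each module (largest
first) from a random unclaimed parcel, repeatedly claiming the unclaimed
spatial neighbour closest to the module's running centroid, and rejects and
resamples any draw in which a module cannot reach its size. Label-swapping
schedules that shuffle equidistant pairs satisfy the same constraints but
are under-determined (swap order, iteration count); seeded growth provably
satisfies every stated property of the null and is easy to audit — an
independent connected-components oracle verifies all draws in the tests.
Rejection-resampling leaves the accepted ensemble unbiased; the rejection
budget defaults to 500 draws per accepted draw because fine partitions
(nine modules on 152 parcels) accept at only ~1%. Permutation p-values use
the `(1+b)/(1+n)` convention and can never be exactly zero; significance is
declared above the null's 95th percentile.

## Coupling statistics

All edge-wise statistics operate on the **edge table**: one row per
unordered region pair with structural covariance, whole-genome and per-set
co-expression, Euclidean centroid distance, and the edge flag.

* **Distance decay** is fit linearly (`y = b0 + b1 d`) and exponentially
  (`y = a exp(-d/lambda)`, `lambda` profiled over a multistart grid and
  polished by 1-D optimization), compared by the Gaussian AIC
  `n log(RSS/n) + 2k`. Only the model *ordering* is meaningful; AIC
  magnitudes depend on an arbitrary scale constant.
* **Distance-corrected coupling** residualizes both sides on log distance
  (log, because covariance declines roughly exponentially, so the log makes
  the nuisance approximately linear) and reports the partial correlation
  with a t-based p-value on `n - 3` degrees of freedom.
* **Gene-set competition** uses a nested F-test on distance-residualized
  variables: does HSE co-expression explain structural covariance beyond
  whole-genome co-expression? (`df1 = 1`, `df2 = n - 3`.)
* The **gene-set index** z-scores each set gene across regions and averages
  the z-profiles, so the whole-cortex mean is ~0 by construction; per-class
  over/under-expression is a one-sample t-test against 0 with
  Benjamini–Hochberg correction across the seven cytoarchitectonic classes.
* The **set screen** repeats the edge-wise coupling for every gene set of a
  GMT collection and ranks sets by raw `R^2`; a distance-corrected variant
  and its ranking are emitted alongside, since either can be the quantity
  of interest depending on whether shared distance constraints count as
  coupling.

## The synthetic cortex generator

The generator defines the study conditions; its defaults are fixed, not
tuning dials.

**Geometry.** The hemisphere is an idealized half-ellipsoid shell (65 × 85
× 60 mm semi-axes): the analysis consumes only centroids, Euclidean
distances, adjacency and surfaces, none of which need folding. Parcels are
a centroidal (k-means) partition of ~60 shell points each — about the area
of a 500 mm² parcel at 1.6–3 mm point spacing — with Voronoi-contact
adjacency and seven contiguous cytoarchitectonic classes grown from
well-separated seeds. The right hemisphere is an exact mirror image.

**Thickness** (`full`: 296 subjects × 152 parcels). Subject rows are
drawn from a multivariate normal whose correlation is
`0.45 exp(-d/30mm)` plus `0.5` within each of 9 planted contiguous
modules, projected to the nearest PSD correlation (eigenvalue clipping;
the projection must move the matrix by < 10% Frobenius or the
configuration is rejected). The amplitude 0.45 and decay length 30 mm give
strong short-range covariance; the within-module increment of 0.5
dominates the distance gradient, so the planted partition is recoverable
from the thresholded SCN — the recoverability invariant (adjusted Rand
index ≥ 0.9 at 300 subjects) shaped the choice of these defaults.

**Expression** (`full`: 6 donors × 250 samples, 400 genes, 1–3 probes
per gene). Each *background* gene's regional profile mixes a shared
spatially autocorrelated field (correlation `exp(-d/30mm)` plus a module
component scaled by the coupling strength) with gene-specific idiosyncratic
variation; the shared field carries 15% of the variance
(`expr_signal_frac`). This fraction is what controls how strongly
whole-genome co-expression tracks the covariance structure: with hundreds
of genes the shared field does not average out of co-expression, and a
fully shared field (fraction 1) would drive genome–SCN coupling to
`R^2 ~ 0.7`, far above anything seen in cortical data. The *planted
coupled set* (19 genes, labelled with the HSE symbols so the GMT machinery
is exercised) is different in kind: its mean profile is a noisy affine
function of the planted covariance-graph degree (per-gene loadings
`N(1, 0.3)`), and its residual gene-to-gene variation carries the full
shared field — a coherent, co-regulated set. This gives the set both the
index–degree coupling and the strongest edge-wise coupling of any same-size
set, which the recovery tests assert. Setting `coupling_strength = 0`
removes the module component *and* the degree tracking, fully decoupling
expression from the planted partition — the configuration under which the
permutation test's type-I error is calibrated.

Samples are placed at parcel surfaces and displaced into subjacent tissue:
most within the 2 mm assignment tolerance, ~4% beyond it (these must be
dropped), ~5% flagged non-cortical; two donors contribute right-hemisphere
samples; per-parcel sampling weights are gamma-distributed so parcels are
unevenly covered, and one parcel is left deliberately empty to exercise
interpolation. Donors differ by affine scale/shift; probes differ by
offsets and noise.

**What the generator does not emulate:** cortical folding and
surface-based geodesics, subject-level covariates other than an optional
linear age term, subcortical structures, probe-sequence annotation errors,
and donor-specific spatial deformations. Passing tests therefore certify
the *statistical machinery* — thresholding, nulls, consensus, coupling
inference — not anatomical realism.

## Numerical choices and degenerate inputs

* Density thresholding uses `floor`, with ties at the cut broken by larger
  weight then smaller pair order, making edge sets reproducible.
* Zero-variance regions yield `NA` correlations (never imputed) with a
  warning.
* Degenerate generator configurations (all off-diagonal covariance ~0) get
  a flat planted degree field rather than an error.
* A constant gene-set index yields `t = 0, p = 1` per class rather than a
  failed t-test.
* All random streams are split per operation from the master seed, so
  adding an operation leaves the others' draws unchanged; identical
  configurations reproduce bitwise.

## Problem sizes used in the shipped experiments

The packaged tests and the acceptance script run the `full` preset
(152 parcels, 296 subjects, 400 genes) with 200 rewired nulls, 200–500
spatial-null draws, and 100–200 consensus runs, and the `compact` preset
(60 parcels, 4 modules) for replicated experiments: 200 calibration
replicates at 200 nulls each, and 20-seed recovery sweeps. These sizes are
the package's own choice of a desk-scale experiment: large enough that the
planted effects and the 5% calibration band are resolvable, small enough
to iterate on. The gene count (400 against ~20k on a real microarray)
matters only through the `1/sqrt(n_genes)` sampling noise of co-expression
estimates; the coupling statistics themselves are scale-free in the number
of genes.

## Known limitations

* The spatial null's growth procedure, while satisfying all stated
  constraints, is one of several valid realizations; its ensemble is not
  identical to a label-swap chain's.
* `lambda` in the exponential decay is profiled, not jointly optimized with
  a nonlinear solver; for the smooth RSS profiles arising here the
  difference is below test tolerances.
* The consensus convergence criterion (all runs of an iteration identical)
  is strict; graphs with genuinely degenerate optima may return with a
  convergence warning after 10 iterations.
* Mapping operates in a single common frame; donor-native surface warping
  is out of scope, with the 2 mm tolerance standing in for volumetric
  dilation into white matter.
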