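---
title: "Validating protocol-constrained tractography and connectivity blueprints on phantom brains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating protocol-constrained tractography and connectivity blueprints on phantom brains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the package is for

Multi-template tractography pipelines chain many quantitative steps:
probabilistic streamline propagation constrained by protocol ROIs, warping of
those ROIs between template spaces, normalisation and thresholding of path
distributions, construction of connectivity blueprints (cortex-by-tract
projection matrices), and symmetric Kullback–Leibler (KL) comparison of
blueprint rows across brains for homologue identification and scalar-map
projection. On real data none of these steps has an accessible ground truth,
so pipeline defects hide easily. `tractblue` implements the whole chain at
desk scale together with a synthetic phantom generator whose every output —
fibre fields, tract masks, protocols, surfaces, parcellations, scalar maps,
cross-brain correspondences — is known exactly, so each stage can be tested
against what it should produce.

## The tracker and its parameters

`propagate_streamline()` walks a multi-fibre orientation field with the
standard constrained probabilistic semantics:

* **step size** 0.2 mm (default), **maximum** 2000 steps per direction, both
  directions tracked from the seed and concatenated;
* at each step the candidate orientations are the fibres of the *current*
  voxel (nearest-voxel lookup; no interpolation of orientations) with volume
  fraction strictly above 1%; one candidate is sampled with probability
  proportional to its fraction;
* the candidate's sign is aligned with the previous direction, and a turn
  exceeding the **curvature limit** of 80° terminates the streamline;
* propagation also ends on leaving the brain mask, entering a stop mask, or
  exhausting the step budget; a voxel without admissible fibres terminates
  with reason `no_fibre`, which is an outcome, not an error.

`run_protocol_tractography()` seeds `streamlines_per_seed_voxel` (default 50)
uniformly-jittered streamlines per active seed voxel. A streamline is *valid*
iff it intersects every waypoint mask and the target (when present) and never
touches the exclusion mask; only valid streamlines are counted, each
incrementing a voxel at most once, so counts read as "number of valid
streamlines visiting". Dividing by the number of valid streamlines
(`normalise_path_distribution()`) and thresholding at 0.1%
(`threshold_binarise()`, with a `>=` tie rule so a voxel exactly at threshold
survives) gives binary tract masks for microstructure summaries and
population percentage atlases.

`run_surface_seeded_tractography()` seeds `streamlines_per_surface_vertex`
(default 1000) streamlines per cortical vertex and counts visitations of the
brain mask down-sampled to 2 mm. Each vertex's seeds are spread over a 1.5 mm
ball: a mesh vertex stands for a cortical patch of roughly half the vertex
spacing, and seeding the patch rather than a point is what lets a vertex that
overlooks two converging bundles express a *graded* mixture over them instead
of collapsing onto whichever bundle is nearer.

## Blueprints, the product identity, and its oracle

The connectivity blueprint is the matrix product of the (vertices × coarse
voxels) visitation matrix with the (coarse voxels × tracts) matrix of
vectorised, normalised path distributions; rows are then normalised to
probability profiles. Two numerical choices are deliberate:

* the contraction is order-pinned (ascending coarse-voxel index,
  long-double accumulation per dot product) rather than delegated to BLAS, so
  that `streamline_oracle_blueprint()` — which reconstructs each vertex's
  visitation vector one streamline at a time from the raw per-streamline
  coarse-visit sets, never forming the visitation matrix — must agree
  *bit for bit*. Any discrepancy between the two routes therefore isolates to
  the visitation counting itself, which is the part worth doubting;
* rows with zero signal are excluded rather than renormalised, and
  `exclude_low_signal()` extends this to vertices whose total pre-normalised
  signal falls below 5% of the median: their few streamlines die within a
  couple of voxels, their profiles are degenerate one-hot rows carrying no
  positional information, and keeping them poisons cross-brain matching with
  spurious exact ties. This is the phantom analogue of dropping cortex that a
  tract repertoire represents poorly (in real analyses, the insula).

## Symmetric KL comparison

`symmetric_kl()` floors both profiles at `epsilon` (default `1e-8`),
renormalises, and returns the arithmetic mean of the two directed
divergences in nats. The floor keeps divergences finite in the presence of
legitimate zeros; the mean (rather than the sum) halves the scale without
reordering any comparison. `kl_matrix()` evaluates all pairs of non-excluded
rows; `min_kl_summary()` takes row-wise minima with lowest-index,
flagged tie-breaking; `find_homologue()` scores every target vertex against a
source region's average profile and masks the lowest-divergence percentile;
`project_scalar_map()` transfers a per-vertex scalar by copying the
argmin-divergence source value or by softmax weighting
`exp(-KL / temperature)` with the matrix median as the default, scale-adaptive
temperature.

## What the phantom emulates

A phantom brain is an ellipsoidal "head" (40×48×40 voxels at 1 mm by
default) with:

* **six tube-shaped tracts** following cubic Bézier curves whose control
  points sit partway from each cortical tip toward the brain centre, so tubes
  meet the cortical shell radially (like white matter entering a gyrus) and
  arc through the interior. Four are bilateral association-type **U-fibres**
  (left/right pairs of `paf` and `plf`) whose two ends both lie inside one
  surface parcel; two are **commissural** (`pac`, `pfm`), diving deeper,
  crossing the sagittal midline, and ending ~2 mm below the cortex, as
  commissures merge into deep white matter rather than reaching the surface.
  The fibre orientation along each tube is exactly the curve tangent; where
  tubes overlap, a voxel carries up to three orientations with fractions
  proportional to tube membership (fraction sum 0.85);
* **protocols** per tract: seed and target balls centred on the curve, inset
  past any corridor shared with another tract ending at the same anchor (end
  ROIs are drawn where a bundle is compact, not in interdigitation zones), a
  mid-curve waypoint ball, and a common off-tract exclusion slab;
* a **surface** (icosphere, 642 vertices) on the cortical shell with an
  8-parcel labelling (hemisphere × four angular parcels, each hosting a pair
  of tract anchors) and an areal "myelin" map — per-parcel plateaus plus a
  smooth gradient, the dominant structure of real T1w/T2w maps;
* **FA/MD maps** (0.7 / 0.2 FA inside/outside tubes; 0.7 / 1.0 ×10⁻³ mm²/s
  MD) with truncated Gaussian noise.

The attachment pattern is the load-bearing design choice. Connectivity
blueprints cannot distinguish the two ends of a single tract — both ends see
the same tube — so any end-ambiguity must be made harmless or resolvable:
U-fibres keep it *within one parcel*, and commissural attachments share their
anchor with a hemisphere-specific U-fibre so that the corridor mixture
lateralises them. Parcels whose anchors host no tract end up excluded, which
is itself realistic.

**Twin pairs** (`make_twin_pair()`) emulate two species sharing a tract
repertoire: brain B is anisotropically smaller, its tracts dive deeper
(control depth ×1.25, which makes its tube bodies graze each other's
territory and shifts every profile's minority mass), its commissures reach
closer to the cortex (tip recession 0.5 vs 2 mm), its anchors are rotated 6°
within their parcels, and its tubes are slightly thinner. Both surfaces come
from the same icosphere, so the ground-truth correspondence is index-wise and
corresponding vertices share parcel labels by construction. The myelin map on
B is the pull-back of A's map plus truncated Gaussian noise — exact at noise
zero.

## What passing tests do and do not show

The phantom exercises the *constraint logic* of tracking (curvature, masks,
validity, counting), the *algebra* of blueprints and divergences, and the
*recoverability* of known correspondences. It does not emulate diffusion
signal formation: there is no q-space, no noise floor, no orientation
posterior (orientations are fixed, as the uncertainty machinery is out of
scope), no gyrification, and the background outside tubes carries no fibres
at all, which makes phantom profiles far crisper than real ones. Passing
here means the machinery is correct, not that any particular real-data
result would replicate.

Two structural findings from the phantom are worth knowing:

* within-brain vs cross-brain divergence separation (median minimum KL across
  re-tracked same-brain blueprints vs across the twin pair) is about 13–17×
  under the default conditions — the desk-scale analogue of the two orders of
  magnitude seen between within-species and cross-species comparisons at full
  scale;
* argmin correspondence maps 87–90% of non-excluded vertices into the
  ground-truth partner parcel, and parcel-profile homologue masks reach Dice
  ≈ 0.8 when the percentile cut matches the true region's share of vertices.
  The residual errors are almost entirely commissural-committed vertices
  whose two cortical ends are exact mirror twins: a six-tract repertoire
  simply cannot lateralise them, which also caps twin myelin-map projection
  at r ≈ 0.76–0.82 overall (r ≈ 0.97 restricted to correctly-lateralised
  matches). A 42-tract repertoire does not have this degeneracy.

## Numerical conventions and degenerate inputs

* Voxel indices are 0-based; world coordinates come from the 4×4 affine; all
  geometry is in mm. Volumes are written with the sform only, since the
  quaternion form cannot represent anisotropic scalings exactly.
* Mask resampling (warps, mirroring) is trilinear with a 0.5 re-binarisation
  threshold; out-of-grid samples read 0, so ROIs near boundaries degrade
  instead of erroring. Downsampling uses integer decimation only; masks use
  the any-voxel rule by default (conservative for visitation counting).
* Path distributions with zero valid streamlines normalise to zero and are
  flagged; constant vectors make Pearson correlations `NA` with a flag;
  empty masks yield `NA` medians; vertices outside the brain are flagged
  rows, not errors.
* All generators and trackers are pure functions of their arguments and an
  integer seed; the compiled tracker uses its own 64-bit generator with a
  bit-derived uniform so runs reproduce across compilers.
* Problem sizes used by the test-suite and the acceptance script are
  desk-scale choices: 642 vertices, 400–800 streamlines per vertex,
  15–100 seeds per voxel, 6–20 twin replicates. The defaults of
  `tracking_config()` keep the field-standard values (1000 per vertex, 2000
  steps) regardless.

## Known limitations

* The tracker has no orientation uncertainty and no anatomical priors beyond
  the protocol masks; fidelity of real-brain tracking is out of scope.
* The revision operators reproduce the *kinds* of manual protocol edits
  (add/subtract masks, mirror from contralateral, erode along an interface),
  not any specific anatomical edit.
* The QC asymmetry threshold (1 − Dice > 0.5 fails) is a configurable
  convention; real protocol revision is a matter of judgement.
* Blueprint storage is dense; at 10k-vertex scale a sparse backend would be
  needed.
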