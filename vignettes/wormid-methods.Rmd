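---
title: "Methods: CRF-based neuron identification for multi-cell worm volumes"
author: "wormid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CRF-based neuron identification for multi-cell worm volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices, numerical
conventions and known limitations of `wormid`. It states no empirical
result beyond what the test suite and `scripts/acceptance.R` compute.

## The problem

A multi-cell reporter strain expresses a nuclear-localized fluorophore
in a few dozen head neurons. To interpret any per-cell measurement, each
segmented nucleus needs a neuron name. Three features of the data make
this hard: worms are imaged in arbitrary orientation (in microfluidic
devices, up to roughly 20 degrees off the imaging plane); neuron
positions vary substantially between animals; and extrachromosomal
transgenes are mosaic, so a variable subset of the candidate neurons is
visible in any one animal. `wormid` resolves identities jointly rather
than cell-by-cell: the arrangement of the whole cloud is matched to a
statistical positional atlas.

## Segmentation

Nuclei are blob-like (the fluorophore is confined to the nucleus), so
detection is seeded at strict 26-neighbourhood local maxima of the
Gaussian-smoothed red channel that exceed an intensity percentile of
the smoothed volume (default 99). Smoothing uses a separable kernel of
1 voxel sigma per axis — just enough to suppress single-voxel noise
maxima without merging adjacent nuclei (~2–3 um apart at 0.3/0.4 um
spacing). Voxel indices are converted to micrometres *before* any model
fitting, because anisotropic spacing (0.3 um z vs 0.4 um x/y) would
otherwise bias covariances and angles; voxel indexing is 0-based, so
voxel `i` sits at `i * spacing`.

Seeds initialize a 3D Gaussian mixture (one component per seed, means
at the seeds, isotropic one-voxel covariances) refined by EM on the
above-threshold voxels, each weighted by its raw intensity. The fit is
deliberately deterministic: no random restarts, an iteration cap of 100
and a relative log-likelihood tolerance of 1e-6. A small ridge (1e-6)
keeps covariances positive-definite; a component that still ends
non-positive-definite is dropped with a warning. Masks are the hard
assignment of above-threshold voxels to components, so masks of
distinct cells are disjoint and cover every seed.

Autofluorescence landmarks (gut granules, green channel) are segmented
the same way but without the mixture refinement: local maxima above the
99.85th percentile of the smoothed volume. That percentile suits
typical confocal settings and is exposed for tuning; at 100 the cloud
is empty by construction (nothing exceeds the global maximum strictly).

## Body axes

PCA on the centered cell cloud gives the initial frame: the head is
longest along AP and wider along LR than DV. Two failure modes need
correction.

*AP correction.* With spatially biased expression (e.g. mostly
anterior, ventrally clustered neurons) the first principal direction
tilts away from the body axis. Autofluorescence landmarks run the full
length of the body, so PCA on the union of cells and landmarks anchors
AP; the origin stays at the *cell* centroid so worm-frame coordinates
remain comparable across animals.

*LR correction.* Head neurons are largely bilaterally symmetric, so the
true LR axis is the normal of the cloud's best mirror plane. Candidate
normals are the initial LR rotated about the AP axis by every angle in
{-20, ..., -1, 0, 1, ..., 20} degrees — a 1-DOF family that realizes
orthogonality to AP, the 20-degree trust region and the 1-degree
resolution in one parameterization. Each candidate plane passes through
the cell centroid (kept fixed across candidates). The symmetry
deviation of a plane reflects every point and takes the distance to its
nearest original neighbour, averaging the 7 smallest distances; 7 is
the expected minimum number of bilateral pairs in a ~37-neuron strain
and is exposed for tuning. Averaging only the smallest distances keys
the score on the well-mirrored bilateral pairs and tolerates unpaired
midline cells and mosaic dropout. Ties in the score break toward the
smallest absolute rotation, then toward the negative angle, making the
search deterministic. DV is recomputed as `ap x lr`, so every returned
frame is right-handed and orthonormal to 1e-9.

A point's own pre-image is excluded from the nearest-neighbour search
only when the reflection coincides with it numerically (distance
< 1e-12) — i.e. for points lying on the candidate plane — otherwise all
original points are candidates.

Polarity (which end is anterior, which side is left) is *not* decided
by these algorithms; the frame is defined up to sign. It comes from
user flags or, in simulation, from the generator's truth. Because the
frame must stay right-handed, only even numbers of sign flips are
realizable; `flip_axes()` implements a lone DV flip by negating LR and
DV together.

## Pairwise features and their conventions

In the worm frame, every ordered cell pair (i, j) yields three binary
precedence relations — `pa[i, j]` is true iff cell i has the strictly
smaller AP coordinate ("precedes j along +AP"); likewise LR, DV — and a
unit displacement vector from i to j. One sign convention is declared
once and stored inside every atlas (`+LR` is the left side, mirrored
pairs in the generator are built accordingly); atlases and features
must share it, and `update_atlas()` refuses a mismatch. Exact
coordinate ties (< 1e-12 um) are broken by cell order and logged;
coincident cells get a flagged, undefined angular entry that inference
treats as uninformative. Features are invariant to rigid motion of the
image frame by construction (they depend only on worm-frame
coordinates); the suite verifies this property on random poses.

## Atlas model

For each ordered label pair (m, n) the atlas stores the probability
that m precedes n along each axis, the mean unit displacement
direction, and the co-observation count. Probabilities are empirical
fractions over all observations; each annotator's labelling of a worm
counts separately, so annotator disagreement widens the statistics
rather than being voted away. Angular statistics are the normalized
arithmetic mean of unit vectors plus the resultant length (a
concentration measure); the mean direction is marked absent when the
resultant is numerically zero. Ties in a coordinate contribute 0.5 to
both orders, preserving `p(m,n) + p(n,m) = 1` exactly on observed
pairs — at jitter zero, mirrored pair members share AP and DV
coordinates exactly, so those entries are genuine 0.5s rather than
noise.

Never-co-observed pairs default to p = 0.5 with no angular term, i.e.
they contribute nothing to inference. An uninformative default is the
right choice for a generic tool that cannot assume any particular
anatomical prior; a lab that has one can supply it as a base atlas,
because `update_atlas()` is exact: counts are stored, so sufficient
statistics (precede-sums, angular vector sums) are recoverable and
updating equals rebuilding on the pooled data. This also supports
layered construction — starting from an existing atlas and updating
only what the new data touches. Annotations must commit to a side for
L/R pairs; side-ambiguous labels are out of scope.

## CRF potentials and inference

The potential for hypothesizing labels (m, n) on cells (i, j) is

```
P = w_pa B_pa + w_lr B_lr + w_dv B_dv + w_ang (1 + a_mn . a_ij) / 2
```

where `B_axis` is the atlas probability of the observed precedence (its
complement if the observation is reversed; 0.5 when the atlas pair is
unobserved) and the angular term maps cosine agreement into [0, 1]
(0.5 when either direction is unavailable). All weights default to 1.
This linear-agreement form was chosen for interpretability — each term
is a probability-like agreement in [0, 1], so a pair's potential ranges
from 0 (full contradiction) to the weight sum (full agreement) — and
because the uninformative atlas then scores every assignment equally,
which the tests exploit. No unary terms are used: a multi-cell strain
provides no per-cell color or landmark identity; the slot is an
extension point.

MAP inference maximizes the sum of potentials over unordered cell pairs
subject to one-label-per-cell. When the feasible-assignment count is at
most 1e5, the optimum is found by exhaustive enumeration in
lexicographic order (cell order outer, candidate order inner), which
also fixes the tie-break. Larger problems use a greedy construction
(each step places the (cell, label) pair with the best mix of agreement
with already-placed cells and an optimistic bound on the rest) followed
by best-improvement local search over single reassignments and pairwise
swaps, with an iteration cap (1000 moves) and seeded random restarts
(default 5). The optimizer's adequacy is bounded empirically: the
acceptance suite requires agreement with exhaustive enumeration on at
least 95/100 random small problems (99/100 with noise-free atlases),
and the heuristic currently achieves 100/100 on both sweeps.

When cells outnumber candidates (over-segmentation, or a deliberately
truncated candidate list) cells may stay UNASSIGNED, contributing zero
potential; an unassigned cell counts as a mismatch in evaluation.

*Ranked predictions.* The top-k ensemble re-runs MAP inference
`n_iterations` times (default 100), each time removing `n_removed`
candidates uniformly at random (default 10% of the list, at least 1),
and reports per-cell label frequencies in descending order, ties broken
by candidate order. Randomness enters only through the removal draws —
the solver seed is held fixed — so with `n_removed = 0` the ensemble is
exactly degenerate and reproduces the best single prediction with
frequency 1.0 (computed once, not 100 times). The best single
prediction (one MAP run on the full list) is kept distinct from the
top-1 ranked label; they usually agree but need not.

## Evaluation

Accuracy is correspondence to the consensus of three annotators: a
cell's consensus is any label at least two propose; cells with
three-way disagreement are omitted from the denominator. A generalized
plurality rule for other annotator counts exists behind
`strict = FALSE`. All cohort-level numbers use leave-one-out
cross-validation — the atlas scoring worm w is built from every worm
except w. Per-neuron reporting gives, per label, the fraction of its
consensus occurrences predicted correctly and a manual-agreement score
(among cells where any annotator proposed the label, the fraction where
at least two did).

## Expression quantification

Cell intensity is the mean of the 100 brightest voxels of the mask
(masks average ~500 voxels, so this reads the nuclear core and resists
mask-boundary errors); smaller masks are averaged whole with a warning.
GFP is read through the mCherry-derived masks so both channels measure
the same region; GFP judged absent during curation is removed via an
explicit per-animal exclusion list, not an automatic threshold, because
absence calls are a curation judgement. Intensities are normalized per
animal and channel by the mean over measured neurons (exact unit mean
by construction). Because the side of the animal facing the objective
is systematically brighter (scattering), bilateral homologs are pooled
under their pair name and tagged brighter/dimmer: per animal, the side
(by LR sign) with the higher mean raw intensity across paired neurons
in the segmentation channel is "brighter"; exact ties go to the
positive-LR side (logged), and an override flag lets the user declare
the side. Midline neurons keep their own label and side tag.

## Synthetic data: what it emulates and what it does not

The generator defines the study conditions for every test:

* **Reference map** — `n_total` neurons (default 37, of which 15 exact
  bilateral pairs, the remainder on the midline) placed uniformly in an
  ellipsoidal head with semi-axes 50 x 15 x 10 um (a 10:3:2 shape,
  sized like a real adult head so micrometre-scale jitter is small
  against inter-neuron distances), minimum separation 3 um (~nuclear
  diameter). Optional sampling-range restrictions emulate spatially
  biased expression.
* **Per-worm variation** — isotropic Gaussian positional jitter
  (default sigma 1 um), mosaic dropout (default 0.2), a rigid pose with
  uniform in-plane spin and off-plane tilt uniform up to 20 degrees,
  and a random translation.
* **Landmarks** — 40 points strung along the body axis over 1.4x the
  head half-length with 2 um radial scatter, mimicking the gut's
  autofluorescent band.
* **Annotators** — three independent copies of the truth, each cell
  mislabelled with probability 0.1 (the regime suggested by ~80-90%
  inter-annotator correspondence). A replacement label is drawn from
  candidates unused in that copy so each annotator stays
  duplicate-free, as humans do; real annotator confusions are
  *structured* (neighbouring neurons), which the per-neuron tests
  emulate separately with constructed swaps.
* **Rendering** — volumes are sums of isotropic Gaussian blobs plus
  constant background and optional Poisson noise on an anisotropic
  grid; positions are interpreted relative to the volume origin.

What passing tests show, and do not show: synthetic worms have
unstructured jitter, exact pair mirroring, no body curvature, no
depth-dependent attenuation, and independent annotator errors. Results
under these conditions validate the *algorithms* (recovery when the
model holds, graceful degradation as noise grows) but do not certify
accuracy on real volumes, where positional variability is correlated
and segmentation errors are structured. Under the default conditions
the pipeline scores higher (best-single correspondence in the
mid-90s%) than the mid-80s% typical of real multi-cell data — real
anatomical variability is heavier-tailed than isotropic jitter.

## Numerical choices and degenerate inputs

* Coordinate ties: 1e-12 um tolerance; broken by cell order (features)
  or split 0.5/0.5 (atlas).
* Frames are validated to 1e-9 (unit norms, orthogonality,
  right-handedness) after every axes operation.
* Collinear clouds (2nd singular value < 1e-9 relative) are rejected;
  planar clouds are allowed since the third principal direction is
  still unique.
* TIFF volumes are written as 16-bit grayscale; integer intensities in
  [0, 65535] round-trip exactly. Spacing is a required read argument
  (acquisition metadata is unreliable). CSV coordinates use 17
  significant digits and JSON uses full precision, so all round trips
  are bit-exact.
* Atlas validation enforces `p in [0, 1]`, complement symmetry on
  observed pairs, and symmetric counts at read time.

## Problem sizes used in the checks

The test suite and acceptance script run at desk scale, chosen to
exercise every code path while keeping a full run in minutes:
100 random optimizer-vs-enumeration problems of up to 7 cells/labels;
noise-free end-to-end recovery on 5 worms of 37 labels; 50-worm axes
benchmarks; atlas-size sweeps with 20 training and 6 test worms;
ranked-prediction ensembles of 25–40 iterations. The axes *acceptance*
benchmark deliberately uses a near-circular head cross-section
(semi-axes 50 x 12 x 11) plus anterior-biased expression so that plain
PCA's LR/DV directions start up to ~15-20 degrees off — the condition
the symmetry search exists to fix; the descriptive statistics in
`scripts/acceptance.R` instead use the canonical 50 x 15 x 10 geometry.

## Known limitations

* No color/NeuroPAL unary features; identity evidence is purely
  positional and pairwise.
* Exact MAP is exponential; beyond the enumeration cap the optimizer is
  a bounded-quality heuristic, and whole-brain-scale (~200 cell)
  problems are out of scope.
* Axis polarity requires user input; there is no automatic
  anterior/left/dorsal disambiguation.
* The symmetry search cannot recover an initial LR error beyond the
  20-degree trust region (it can be widened at a cost in robustness to
  spurious symmetry planes).
* Proximity/distance-binned features and curved-worm straightening are
  not implemented.
* No compatibility with any external atlas file format is claimed;
  atlases are this package's documented JSON.
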