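---
title: "Tracking nuclei in photon-starved recordings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking nuclei in photon-starved recordings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regentrack)
```

## The problem

Long-term imaging of a regenerating epithelium is a zero-sum game with
photons. Every z slice, every time point, every lateral pixel and every
averaged replicate scan costs light, and light costs tissue health and
fluorophore lifetime. A recording budgeted for days therefore has to
choose where to be blunt: coarser z sampling, longer frame intervals,
fewer pixels or noisier frames. `regentrack` exists to make that choice
quantitatively, by scoring an automated tracking pipeline on synthetic
recordings whose ground truth is known exactly, across acquisition
variants that all correspond to *the same* total light exposure.

The package also implements the two tracking primitives such recordings
need — forward nearest-neighbour lineage linking with a motion (flow)
prior, and backward tracing of a selected cell with interpolation over
missing detections — plus the graph-edit evaluation machinery used to
compare tracking results against reference lineages.

## The lineage model

A *spot* is one nucleus at one time point: centre `(z, y, x)` in
micrometres, a radius, an intensity, and optional label. *Links* join a
parent spot to a child spot exactly one frame later. The containers
enforce at most one parent and at most two children per spot, so a
*lineage forest* decomposes into rooted trees, one per founder cell,
branching at divisions. Two consequences are used throughout:

* the number of trees equals `n_spots - n_links`, which makes the
  bookkeeping self-checking;
* a division is simply a spot of out-degree two, so division counts,
  division-link semantics for the tracking metric, and clone analyses
  all derive from the same structure.

Coordinates are physical micrometres, measured from the centre of the
first (coverslip-proximal) voxel, because every threshold that matters
(5 µm link gate, 3 µm suppression, 5 µm depth bins) is physical.
`reduce_time()` re-indexes kept frames to consecutive integers and
relinks each kept spot to its nearest kept descendants, so a division
falling on a removed frame becomes two links from the retained
ancestor; tree counts survive reduction whenever every tree touches a
kept frame.

## The synthetic recording generator

`simulate_recording()` draws a cell population and renders it into a
5D movie `(t, replicate, z, y, x)`. The default configuration
(`li_synth_config()`, seed 42) is the packaged benchmark: 60 frames at
10-minute intervals, 20 z slices of 1.24 µm, 192 × 192 pixels of
0.31 µm (a 59.5 × 59.5 × 23.6 µm field), 4 imaging replicates and about
150 founder nuclei. Its components, and what they emulate:

* **Motility** — a persistent random walk (velocity autocorrelation
  0.6, step sd 0.4 µm/frame) plus directed migration (0.15 µm/frame)
  towards the wound plane at the distal x face. Migration arrests
  within 5 µm of the wound so that arriving cells stop rather than
  compact against the boundary; nuclei are kept at least 3 µm apart by
  relaxation sweeps, emulating epithelial packing. Without the arrest
  the entire population piles into a contact-packed slab at the wall,
  which no real epithelium does.
* **Division schedule** — per-cell division probability 0 for the
  first 2.5 h (quiescence), 0.03/frame during the burst (frames
  15–35), 0.008/frame thereafter (decline). Daughters appear one
  radius to either side of the parent along a random axis and cannot
  re-divide within 6 frames (a minimum cell-cycle guard; besides being
  biologically necessary it keeps time reduction well-defined, since
  back-to-back divisions would put more than two descendants behind a
  removed frame).
* **Apoptosis** — probability 0.002/frame; the dying nucleus is
  rendered condensed (0.7 × radius) and bright (3 ×), the pyknotic
  appearance, then disappears.
* **Imaging** — nuclei are rendered as anisotropic Gaussians whose
  profile sd is `radius/2` per axis (the nominal radius sits at two
  profile sds, approximating the steep edge of a chromatin-filled
  nucleus) convolved with a Gaussian PSF (σ = 1.0, 0.35, 0.35 µm);
  depth attenuation multiplies intensity by `exp(-z/15 µm)`;
  photobleaching decays as `exp(-rate × exposures)` with rate 0.0015
  per replicate scan and a ×1.3 step recovery at frame 30 (heat-shock
  re-induction of the fluorophore); each replicate adds Poisson shot
  noise (10 intensity units per photon) and Gaussian read noise
  (sd 50) to the same noiseless scene. Peak intensity 6000 over a
  background of 100 puts the deepest slices near the detection limit,
  which is exactly the regime the depth-stratified scoring probes.

What the generator does **not** emulate: textured chromatin, cuticle
autofluorescence, scattering blur growing with depth, stage drift, or
the slow tissue pulsation seen in live recordings (an optional
sinusoidal term exists but is off by default). Tests passing on this
fixture therefore say that the pipeline's logic is correct and that its
qualitative behaviour (depth decline, z-versus-t trade-offs) follows
from the physics included; they do not certify performance numbers on
real recordings.

The generator also provides idealised detector stand-ins used to
isolate pipeline stages: `render_probability_map()` (a Gaussian bump of
each nucleus' radius, combined by maximum) and `ground_truth_flow()` /
`gt_flow_sampler()` (displacement of the nearest tracked cell between
consecutive frames).

## Equal-exposure acquisition variants

`standard_conditions()` derives five datasets from the 4-replicate
master, each at exactly ¼ of its illumination
(`z_keep × t_keep × xy_keep² × n_average / 4`): the standard setting
(half z, half t, 4 averaged), improved z (full z, half t, 2 averaged),
improved t (half z, full t, 2 averaged), and two improved z+t variants
(half xy with 4 averaged; full resolution with a single replicate).
Decimation keeps even indices — deliberately pixel *dropping*, not
binning, since binning would change the exposure accounting — and
averaging takes the arithmetic mean of the first `n_average` replicates
(sequential scans accumulate exposure in acquisition order), rounded
half-up to integers. Ground-truth annotations are physical, so only the
time axis needs reducing alongside.

## Detection

`blob_response()` computes a scale-normalised Laplacian-of-Gaussian
response over four radii geometrically spaced in [1, 5] µm (the scale
of a radius-r blob taken as r/√3), using FFT convolution with the
analytic Gaussian transfer function in physical units — anisotropic
voxels need no resampling. Each scale's response is converted to a
robust signal-to-noise ratio against the volume's median/MAD and
squashed to `p = 1 − 2^(−snr/snr_half)`; `snr_half = 8` calibrates
"half confidence" at eight noise sds. This pseudo-probability is what
the fixed threshold θ = 0.7 is applied to, mirroring how a learned
detector's probabilities are thresholded.

`extract_centers()` finds 26-neighbourhood local maxima *per scale* on
the raw responses (crowded nuclei that merge at coarse scales remain
separable at their own scale, and raw responses never plateau the way
the squashed map does), refines each peak to sub-voxel precision with a
per-axis quadratic fit, thresholds at θ, estimates radius as √3 × the
best scale clamped to [r_min, r_max], and applies greedy non-maximum
suppression: candidates in descending value order, a candidate closer
than d_sup = 3 µm (centre-to-centre) to an already-kept one is dropped,
ties broken towards smaller indices. Greedy-by-value is the standard
deterministic choice; centre-to-centre is used because annotations are
points with radii, not masks. Sub-voxel refinement matters more than it
looks: rounding to voxel centres shaves up to ~0.3 µm (xy) or 1.24 µm
(z) off pair distances, enough to mis-trigger the 3 µm suppression on
legitimately separated neighbours.

A division-candidate mode reuses the same machinery at θ = 0.8 on a
compact-scale response weighted by robustly normalised brightness,
flagging metaphase-like (bright, condensed) nuclei.

## Linking and backtracking

`link_forward()` links spots frame to frame: each spot at t+1 predicts
its origin by subtracting the flow displacement sampled at its own
position (backward warp; the sampling point is a convention, chosen
because the child position is the one actually observed), candidate
parents lie within d_max = 5 µm of that prediction, and candidates are
assigned greedily in ascending distance with each child taking at most
one parent and each parent at most two children — the cap that lets
divisions through. Greedy nearest-neighbour is O(n log n) and matches
the stated semantics; the test-suite keeps an exhaustive
minimum-total-distance assignment oracle on small instances to quantify
the (empirically zero, at fixture spacing) gap.

`backtrack()` walks a selected cell towards t = 0. Each step predicts
the previous position via the flow, looks up detections in a local
window (half-size 10 µm) around the prediction — from a supplied spot
table or by running the detector on the cropped volume — and links to
the closest detection within the vicinity radius (default d_max).
Failing that it *interpolates* a spot at the predicted position,
flagged as such, and a budget of consecutive interpolations bounds how
long the tracer may fly blind; exceeding it truncates the path (a
status, not an error). The counter resets on every real detection.
Backtracking through a division needs no special casing: the parent is
simply the nearest detection one frame earlier. One behavioural
consequence worth knowing: if the true detection is missing and a
neighbour sits inside the vicinity radius, the tracer follows the
neighbour — at clonal packing (sisters ~3 µm apart) this is the
algorithm working as specified, and it is why backtracking outputs are
proofread in practice.

`estimate_flow_block_matching()` is the classical stand-in for a
learned flow model: normalised cross-correlation of image blocks
(FFT-accelerated, zero-variance blocks giving zero displacement),
maximised over a physical search radius, written out as a
piecewise-constant voxel field.

## Evaluation

`match_spots()` matches predictions to ground truth per frame: a
prediction is a candidate for a ground-truth spot when its centre lies
inside that spot's sphere (the point-cloud counterpart of the
mask-overlap test used by the Cell Tracking Challenge), and candidates
are resolved by a maximum-cardinality, minimum-total-distance
assignment (linear sum assignment via `clue`). Matched pairs are TP; an
unmatched reference spot still covered by some matched prediction
counts as NS (that prediction would need splitting); other unmatched
references are FN and unmatched predictions FP.

`aogm()` counts the edit operations that turn the predicted graph into
the reference: the vertex operations above plus, over matched vertex
pairs, deleting redundant links (ED), adding missing links (EA) and
correcting division semantics (EC, a link being a division link iff its
source has two children). Weights default to the Cell Tracking
Challenge reference values (NS 5, FN 10, FP 1, ED 1, EA 1.5, EC 1) and
are exposed, since point annotations rather than masks are already a
departure. The normalised scores are
`TRA = 1 − min(AOGM, AOGM₀)/AOGM₀` with
`AOGM₀ = w_FN·|V| + w_EA·|E|` (building the reference from nothing),
and DET likewise with vertex-only cost. The raw, un-normalised cost is
reported as the proofreading-effort proxy: unlike DET/TRA it grows with
recording length at fixed per-frame quality, which is the practical
point — doubling temporal resolution doubles what a human must check.
Links with an unmatched endpoint are removed as part of the vertex
deletion rather than billed as ED, keeping the decomposition additive
over disjoint unions (the effort of two independent experiments is the
sum).

Detection precision/recall are `TP/(TP+FP)` and `TP/(TP+FN)` with
0/0 ≡ 1; NS is deliberately excluded from the recall denominator, as in
the DET-based definition. Linking precision/recall count predicted
links whose endpoint images form a reference link; `tra_on_gt()`
re-links the *reference spots* and scores that, isolating linker from
detector. `depth_stratified_scores()` bins by ground-truth depth in
5 µm slabs (false positives binned by their own depth for the
precision column) — the depth profile is the most decision-relevant
output, since deep layers are where acquisition settings differ most.

`run_tradeoff_experiment()` chains everything per condition —
subsample, reduce ground truth, detect, build the flow prior
(ground-truth sampler, block matching, or none), link, score — and
averages repeats. When given a `simulation_config` rather than a fixed
recording, each repeat is an independent noise realisation with a child
seed; with deterministic stages this is the only meaningful source of
repeat variation.

## Annotation transfer and clone analysis

Post-fixation stained nuclei are registered onto the last live frame by
iterative closest point: centroid + principal-axes initialisation (all
four proper sign combinations tried, best kept), alternating
nearest-neighbour correspondence with least-squares transform fits
(Kabsch for rigid; linear least squares for affine, which absorbs the
mild uniform distortion that fixation and re-mounting introduce), with
an optional trimming fraction to shed outliers. `transfer_labels()`
assigns each transformed stained nucleus to its nearest live spot
within an accept radius (default the 5 µm gate), one-to-one in
ascending distance. `progenitor_analysis()` then walks labelled
terminal cells to their roots and reports clones: progenitor position,
divisions in the clone, labelled versus unlabelled terminal
descendants.

## Numerical choices and degenerate inputs

* FFT convolution implies circular boundary conditions; nuclei are
  object-scale (≪ volume scale) so wrap-around artefacts are confined
  to within a blob radius of the faces.
* A volume with zero dynamic range, or a zero-MAD response, yields an
  all-zero probability map, not an error; flat blocks in the flow
  estimator yield zero displacement.
* Assignment ties are broken by `clue`'s deterministic solver; NMS ties
  by smaller (z, y, x) index; all stochastic stages consume a single
  seeded RNG stream, and `child_seed()` (a Lehmer-style mixing step
  modulo 2³¹ − 1) derives independent stage seeds from one user seed.
* `reduce_time()` refuses to produce more than two retained descendants
  for one spot rather than silently rewiring a biologically impossible
  history.
* Problem sizes in the shipped tests and in `scripts/acceptance.R` are
  the package's own benchmark choices: the full li-synth fixture for
  end-to-end properties; 50 seed cells for backtracking; 200 random
  ≤ 8-spot instances for the exhaustive AOGM cross-check; detection
  sweeps over every frame of the relevant conditions.

## Known limitations

* The detector is a classical blob detector: it has no texture model,
  so its absolute precision/recall are not comparable to a trained
  CNN's — the package's claims are about *relative* behaviour across
  equal-exposure conditions and depth.
* Greedy linking can in principle lose to a global assignment in
  pathological crossings; the flow prior is the intended remedy, and
  the oracle test keeps the gap measurable.
* Backtracking fidelity degrades gracefully but inevitably when
  detections are missing in densely packed clones (see above); the
  interpolation budget bounds, but cannot eliminate, neighbour capture
  within the vicinity gate.
* Proofreading effort is the raw edit cost in arbitrary units; it
  ranks conditions but does not convert to minutes of human work.
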