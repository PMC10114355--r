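---
title: "Quantifying amyloid-like aggregate morphology and kinetics with aggremorph"
author: "aggremorph authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying amyloid-like aggregate morphology and kinetics with aggremorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggremorph)
```

## The problem

Prion-like, glutamine/glycine-rich protein domains form amyloid aggregates
that are morphologically polymorphic: fluorescence microscopy of such
aggregates (for example, the N-terminal region of an insect Argonaute2 fused
to mCherry, stained with thioflavin-T) shows three recurring shapes --
**linear fractal** aggregates, in which ~0.5-µm fluorescent puncta are
connected in a chain; **branched fractal** aggregates, in which several
chains have docked onto each other; and **fibrils**, which are tens of
micrometres long and much larger than both. aggremorph implements a complete,
testable pipeline for this kind of data: channel registration and background
subtraction, aggregate detection, skeleton-based shape descriptors,
PCA + k-means classification into the three classes, sigmoid fitting of
thioflavin-T (ThT) aggregation kinetics, and fibril width profiling from
negative-stain TEM images. Because raw micrographs are large and usually
archived elsewhere, the package also ships a synthetic-scene simulator that
generates ground-truth-labelled data with the same statistical structure, so
every stage of the pipeline is validated end to end without downloads.

## The measurement pipeline

### Preprocessing

Chromatic aberration between the mCherry and ThT channels is modelled as a
pure translation, estimated from averaged calibration frames by Fourier
cross-correlation in windows around four user-chosen 3×3-px regions of
interest; the four estimates are combined by the component-wise median so a
single structureless ROI cannot corrupt the result. The estimate is refined
iteratively (estimate, correct, re-estimate), which removes the asymmetry
bias of parabolic peak interpolation; residuals on synthetic pairs are below
0.05 px, and exact integer shifts are recovered exactly. Correction resamples
the moving channel bilinearly; border pixels without source data are marked
invalid and excluded downstream.

Background is removed by the classic rolling-ball algorithm -- grayscale
opening with a ball structuring element (default radius 200 px), computed on
a presmoothed, block-minimum-downsampled grid for large radii and bilinearly
upsampled. A constant image maps to zero; features narrower than the ball
are preserved. Like all rolling-ball implementations, the estimate is
unreliable within one ball radius of the frame border.

### Detection

Aggregates are 8-connected components of pixels strictly above 60 a.u.
(out of 65 535) whose area is strictly greater than 9 px -- "more than 9
pixels" is read literally, so a 9-px component is rejected. For kinetics
imaging the threshold is 250 a.u. with the same area rule. Both constants,
the connectivity and the ball radius live in one serializable configuration
(`defaultRunConfig()`). Edge-touching regions are kept but flagged, since
their lengths are censored by the frame.

### Shape descriptors

Each detected region is thinned to a unit-width skeleton (Zhang-Suen passes
followed by sequential deletion of 8-simple points, which removes the
two-pixel diagonal staircases the parallel passes leave behind). The skeleton
is condensed to a graph with nodes at endpoints and junctions and edges as
junction-free pixel paths; path lengths count 1 px per axial and sqrt(2) px
per diagonal step. Branch points are nodes of degree ≥ 3. The longest chain
is the maximum-length simple path between endpoint nodes, found by exhaustive
search (skeleton graphs are small, so enumeration is exact); a closed
skeleton with no endpoints is flagged as a **ring** and measured by its
circumference.

Two conventions deserve mention. First, thinning erodes skeleton tips by
roughly the local half-width, which biases chain lengths low for thick or
compact objects; the chain is therefore extended at each end to the mask
boundary along the local chain direction (*tip correction*, on by default).
Second, the local width is defined as twice the Euclidean distance transform
minus one pixel, so a one-pixel line has width 1 px; width along the chain is
averaged to give the mean width. These choices are well defined at junctions
and equivalent to perpendicular profiles on straight segments.

The seven features fed to classification are: longest chain length (f1, µm),
mean width along the chain (f2, µm), their ratio (f3), total fluorescence
intensity (f4, a.u.), branch points per chain length (f5, 1/µm), intensity
peaks per chain length (f6, 1/µm), and the longest chain as a percentage of
total skeleton length (f7; computed from the uncorrected skeleton so it never
exceeds 100). Intensity peaks are counted by multi-scale Laplacian-of-Gaussian
blob detection over punctum radii 0.15-0.5 µm, keeping strict scale-space
maxima above 30 % of the region's maximum response whose local Hessian is
round (eigenvalue ratio ≥ 0.33) -- the roundness test rejects the ridge
response of a bare fibril backbone, which is not a punctum. Total skeleton
length is available as an optional eighth feature behind a flag, off by
default.

### Classification

Features are z-scored (they carry incompatible units) and decomposed by PCA;
k-means with k = 4 and 50 seeded restarts clusters the first two component
scores. Clusters are then resolved to the three named classes: any singleton
cluster that is ring-flagged or PC-outlying is folded into the fibril class
(a ring is a closed fibril); remaining clusters are sorted by median chain
length and the largest log-scale gap separates the fibril group -- fibril
lengths span a decade, so k-means regularly splits them over two clusters --
after which clusters with median branch count ≥ 1 are branched-fractal and
the rest linear-fractal. Class summaries report percentages and
median [quartile] statistics; quartiles interpolate order statistics at
plotting positions (n+1)p, so branch counts {3,4,4,5,6} give 4 [3.5-5.5].

### Kinetics

Aggregate-bound ThT intensity is summed per frame over detected aggregates
and fitted with a logistic,
`baseline + amplitude / (1 + exp(-k (t - tMid)))`, by Levenberg-Marquardt
least squares with multi-start initialization over a grid of `tMid` values.
The **lag time** is the intercept of the maximum-slope tangent with the
baseline, which for the logistic is `tMid - 2/k`; the **plateau time** is
where the fitted curve reaches 95 % of the amplitude, `tMid + log(19)/k`.
The simulator uses the same conventions, so lag recovery is a genuine
round trip. Flat traces return amplitude ≈ 0 with the lag flagged undefined
rather than erroring. Plate-reader tables are read in wide or long CSV form,
with blank-trace subtraction as a separate step; an optional exponentially
decaying component in the generator reproduces the early non-aggregate ThT
signal seen immediately after mixing dye with monomer.

### TEM widths

Negative stain accumulates at particle rims, so a fibril's perpendicular
intensity profile has two maxima exactly at its edges. A user-traced
polyline (tracing is deliberately manual, as in practice) is resampled at
1-px arc-length steps; perpendicular offsets in ±halfWindow build a
straightened band whose columns are perpendicular profiles. Per column,
local maxima with topographic prominence above 10 % of the column's dynamic
range are detected, the two most prominent are refined to sub-pixel accuracy
by parabolic interpolation, and their distance (× nm/px) is the local width;
the median and quartiles are taken over columns with at least two peaks.
Prominence is scale- and offset-free, so width estimates are invariant to
linear intensity transforms. Pixel calibration is a required user input,
since it depends on the microscope magnification.

## The synthetic-scene generator

The generator encodes a docking growth model: fluorescent puncta (diameter
0.5 µm) stick on first contact. Stage 1 docks puncta into linear chains with
bounded angular jitter. Stage 2 decorates a core chain with short
outward-pointing arms attached at interior puncta -- an arriving chain sticks
at its first contact and, screened by the cluster, points into open space, so
the arm direction maximizes clearance from the existing puncta. Free
cluster-cluster docking (stage 3, and a fallback when arm placement is
crowded) moves the incoming cluster by an off-lattice 2-D random walk until
first contact, the diffusion-limited cluster-cluster aggregation picture.
Ground truth comes from the punctum tangency graph (tolerance 1 % of the
diameter, which avoids floating-point contact ambiguity): the true longest
chain is the maximal simple path times the diameter, and true branch points
are nodes of degree ≥ 3. Fibrils are worm-like chains -- tangent-angle random
walks with variance step/persistence -- whose arc length equals the request
exactly; embedded puncta sit on the backbone.

Rendering deposits puncta as point masses and backbones as line densities by
bilinear splatting (which preserves centroids exactly), convolves with a
Gaussian PSF, adds the camera offset, and applies Poisson shot noise (scaled
by the photon gain) plus Gaussian read noise; the second channel is the first
channel's noiseless field translated by the configured chromatic shift and
then independently noised. The label mask assigns each above-threshold pixel
to the aggregate whose field dominates there. Identical parameters (including
the seed) reproduce scenes bit for bit.

### Study conditions

The generator's defaults are the conditions the pipeline is validated under,
chosen once:

* pixel size 0.1625 µm/px (a 6.5-µm camera pixel behind a 40×/0.95
  objective; 10× imaging corresponds to 0.65 µm/px), PSF sigma 0.15 µm;
* punctum integrated intensity 1300 a.u., set so that the rendered punctum's
  extent at the 60-a.u. detection threshold equals its physical 0.5-µm
  diameter -- the calibration that makes "a punctum looks 0.5 µm wide" true
  in the synthetic data, as it is in the real images;
* background 20 a.u., read noise 3 a.u., photon gain 2 a.u./photon;
* linear class: chains of 2-4 puncta (median chain ≈ 1.4 µm); branched
  class: 10-14 puncta, redrawn until the cluster has ≥ 3 true branch points
  (median measured chain ≈ 3.3-3.6 µm); fibril class: log-normal lengths,
  median 27 µm, log-sd 0.5, truncated to 12-55 µm so fibrils fit the field
  of view; classes drawn at 56 / 32 / 12 % (deterministic counts);
* kinetics: amplitude 3×10^5 a.u., baseline 1000 a.u., 10-min sampling for
  24 h, replicate noise 5 % of amplitude; unseeded lag 300 min with growth
  rate 0.01 min^-1 -- the rate is derived from the two stated anchors
  (tangent lag ≈ 300 min and 95 % plateau ≈ 800 min:
  `300 + (2 + log 19)/k ≈ 800` gives `k ≈ 0.01`); seeded lag 80 min;
* TEM ribbons at 150 nm (1 nm/px) and 1.2 µm (10 nm/px) width, edge-peak
  sharpness 4 px, optional sinusoidal twist of the width.

## What passing tests do and do not show

The simulator emulates spot statistics, optics and camera noise, not
photochemistry: there is no photobleaching, no uneven illumination, no focal
drift, no autofluorescent debris, and aggregates are placed one per field (or
on a non-overlapping grid), so touching aggregates -- which the pipeline
deliberately does not split, as no watershed step is applied -- are absent by
construction. Recovery numbers therefore bound what the algorithms can do on
data matching their assumptions; they do not certify performance on crowded
or drifting real acquisitions.

Two quantitative limitations are worth knowing. First, at 0.1625 µm/px a
0.5-µm punctum spans ~3 px, so skeleton junctions closer than the mask width
merge: measured branch-point counts under-register the true adjacency count
by roughly one branch per two to three arms (the median measured branch count
on the branched class is 2-3 against a generated median near 4, while per-
aggregate counts stay within ±1 of truth in ~95 % of cases). Second, chain
lengths of compact clusters are recovered with a median error of ~8 % (under
15 % for clusters of ≤ 10 puncta), with a residual negative bias from
skeletons cutting corners that zigzag punctum paths cannot avoid.

## Numerical choices

* Strict inequality thresholds: intensity `> 60`, area `> 9`.
* Tangency tolerance 1 % of punctum diameter; docking step d/3 with exact
  first-contact backtracking (quadratic solve along the step).
* Skeleton edge lengths: 1 px axial, sqrt(2) px diagonal; ties in the
  longest-path search broken by first-found in deterministic node order.
* k-means: k = 4 fixed, 50 restarts, `iter.max = 100`, seeded; recorded in
  the run configuration together with every threshold.
* Sigmoid fit: 8 `tMid` starts across the time span, amplitude bounded
  below by 0; traces whose fitted amplitude is below 2 % of the data range
  are declared flat.
* All randomness flows from one integer seed per object; derived seeds stay
  below 2^31.
* Validation problem sizes: 50-150 scenes per classification round trip,
  100 noisy traces for lag recovery, 20 random shifts for registration,
  10 renders per TEM width; chosen to make medians stable.

## Reproducing the validation numbers

`scripts/acceptance.R --seed <int> --out <path>` regenerates every headline
quantity from scratch -- kinetics lag and plateau, class recovery accuracy,
class proportions and medians, TEM width medians, the registration residual
and the sigmoid lag bias -- and writes them as JSON. The test suite
(`testthat::test_dir("tests/testthat")`) asserts the same properties at
fixed seeds, plus the unit-level oracles: brute-force punctum adjacency,
exhaustive pixel-graph longest paths, constructed-shift registration, and
hand-computable order statistics.
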