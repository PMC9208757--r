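---
title: "Quantifying amoeboid-like horizontal-cell migration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying amoeboid-like horizontal-cell migration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the measurement models implemented in `hcmigrate`,
the assumptions behind them, the parameters that matter, and the design
choices made where the design was genuinely open. It states no empirical
result that the package's tests and acceptance script do not themselves
compute.

## The measurement problem

Retinal horizontal cells migrate within a crowded neuroepithelium in an
amoeboid-like fashion: they deform their cell body and nucleus, extend
protrusions in many directions, round up at mitosis, and carry a
rear-enriched pool of stable cortical F-actin. The quantities that
characterize this behaviour in time-lapse light-sheet imaging are
geometric (contour shape over time), kinematic (instantaneous speed and
direction of the tracked centroid), angular (orientation of protrusion
tips relative to movement), and photometric (axial fluorescence
profiles). The package computes all of them from three kinds of input:
calibrated image stacks, point tracks, and per-frame tissue-layer
positions. Micrometres and minutes are the only internal units; pixel
size is acquisition-specific and therefore always a required argument,
never a default.

Coordinates follow the image convention: origin top-left, x rightward, y
downward, pixel (row r, col c) centred at ((c − ½), (r − ½)) px. Frames
are 0-based internally; MTrackJ-style exports with 1-based frames are
converted only under an explicit flag, because a silent off-by-one is the
classic tracking bug. The analysis is strictly 2D, matching tracking on
drift-corrected 2D projections; a thin 3-plane z mode exists solely to
exercise the max-projection contract of the polarity line scan.

## Drift correction

Long acquisitions drift laterally. Each consecutive frame pair is aligned
by the peak of its mean-subtracted circular cross-correlation, computed
by FFT after applying a Hann window — the window suppresses wrap-around
artifacts and, more importantly, the bias introduced by structures
truncated at the field border. The integer peak is refined by evaluating
the correlation on a 0.05 px grid around it via a local matrix-multiply
DFT of the cross-power spectrum, followed by a quadratic fit (ties broken
toward zero shift). Pairwise shifts are composed into a cumulative series
anchored at a reference frame.

Consecutive-pair estimation (rather than all-to-reference) is robust to
slow content change over movies lasting tens of hours; its cost is random
error accumulation, which the sub-pixel refinement keeps well below the
0.5 px contract verified in the tests. Correction resamples stacks by the
inverse translation with bilinear interpolation and zero padding;
point tracks are shifted exactly, so correcting a track with the drift
that corrupted it restores it to machine precision. Only XY translation
is modelled — no rotation or scaling.

A frame with zero intensity variance cannot be registered and inherits
the previous frame's drift with a warning.

## Segmentation

One cell per movie is segmented per frame from a seed point, in the
spirit of per-frame active-contour digitization but with a region-based
criterion: synthetic and light-sheet data have stronger region than edge
contrast. The frame is Gaussian-smoothed (`smooth_sigma`, default 1 px —
the single smoothing knob; descriptors later measure the polygon exactly
as segmented), a threshold halfway between the foreground and background
means is iterated to a fixed point, and the connected component
containing the seed is extracted. Its boundary is traced, then each
boundary point is moved along the local outward normal to the sub-pixel
position where the smoothed image crosses the threshold iso-level. The
polygon is lightly smoothed and resampled to ~1 vertex per 2 px of
perimeter, which stabilizes perimeter estimates across cell sizes. All
decisions compare relative means, making the result invariant to
intensity scaling.

Quality flags: a seed on background (or a contrast ratio below
`min_contrast`, default 0.25 relative) yields `low_contrast`; an area
jump beyond `merge_area_factor` (default 1.35) over the running reference
area yields `merged_with_neighbor`; more than `max_gap` (default 3)
consecutive failures ends the series as `lost`. Flagged frames carry no
contour. Cross-frame propagation reseeds at the previous contour centroid
rather than warping the contour, tolerating the large frame-to-frame
shape changes of amoeboid cells.

## Shape descriptors and rounding detection

For a contour polygon with area A (shoelace) and perimeter P (arc
length): sphericity is realized in 2D as circularity, `100·4πA/P²`,
because the analysis runs on 2D projections and must report 100% for a
round cell — whether the original acquisition software's "sphericity (%)"
for 2D ROIs is exactly this quantity is undocumented, so the realization
is recorded here as a design decision, not a fact about that software.
The isoperimetric inequality guarantees the value never exceeds 100. The
elongation ratio is the square root of the eigenvalue ratio of the
polygon's exact second central moment matrix (Green's-theorem integrals,
not vertex moments) — the ratio of the first to second diameters of the
equivalent ellipse, with minimum 1 attained by circles; the
moment-degenerate (circular) case returns exactly the square-rooted
eigenvalue ratio, which tends to 1.

Mitotic rounding is detected as the frame of maximal sphericity, reported
only when sphericity reaches `rounding_threshold` (default 95%) *and*
elongation is jointly minimal within a `window` (default 5 frames) around
it — during rounding the minimal perimeter, minimal elongation and
maximal sphericity coincide, and demanding the joint extremum avoids
flagging transient smooth frames of a migrating cell.

## Kinematics and speed stratification

Velocities are raw finite differences of consecutive tracked positions —
no smoothing by default, mirroring per-frame manual tracking (a centred
moving-average window is available but off). Displacements below
`min_displacement_um` (default 0.03 µm, ~0.1 px at 0.3 µm/px) are below
tracking resolution: the sample is kept but flagged invalid and its
direction is undefined. Gaps split a track; no velocity spans a gap.

Per-cell speed stratification uses the 25th and 75th percentiles of valid
speeds with linear interpolation between order statistics
(`stats::quantile` type 7). The convention is stated explicitly — and
recorded in the run manifest — because percentile conventions differ
across software and the stratification thresholds depend on it. Classes
are `low` (< p25), `high` (> p75), `mid` otherwise.

Depth relative to a tissue layer (typically the OPL) is the signed
distance, positive toward basal; layers are per-frame constant-y lines in
the primary form, with per-frame polylines accepted (point-to-polyline
distance, signed by the side of the interpolated layer). Missing layer
frames are filled from the nearest frame up to `max_gap`. The per-track
summary reports the final-frame depth and the maximal basal depth.
Centrosome offset is the Euclidean distance between centre and centrosome
at shared frames, with a front/back label from the sign of the projection
onto the instantaneous direction.

## Protrusion-angle statistics

Each (tip, frame) pair contributes one unsigned angle in [0°, 180°]
between the movement direction and the centroid-to-tip vector; angles are
unsigned because the reference definition is the angle between two unit
vectors, and rose plots mirror them for display only. Samples at frames
without a valid velocity are dropped and counted. Histograms use
half-open bins [a, b) with the last bin closed at 180°, default width 20°
(9 bins) — the reference rose plots do not state their bin width, so it
is a surfaced, manifest-recorded knob.

Two normalizations are emitted side by side: per-sample frequencies
(summing to 1) and per-frame frequencies (bin count divided by the number
of frames observed in the condition, the rose-plot convention). When
several protrusions coexist in a frame the two differ, and the source
convention is ambiguous, so both counts are reported rather than
guessing. An empty condition (e.g. no high-speed frames when all speeds
tie) produces an explicitly flagged empty histogram, never a fabricated
zero vector that sums to one.

## Front–rear polarity profiling

The cell axis is realized as the line through the contour centroid along
the instantaneous movement direction — front and back are determined by
movement, not by shape; an `axis = "shape"` alternative (equivalent-
ellipse major axis oriented by the motion sign) exists for sensitivity
analysis. The contour-clipped segment is oriented front→back, sampled at
N = 50 equally spaced positions with a 3 px-wide perpendicular average
(bilinear interpolation), and the per-frame profile is length-normalized
to s ∈ [0, 1] before averaging — cells change length frame to frame, and
an averaged profile presumes a common axis. For thin z-stacks, exactly
the three central planes are max-projected first. Frames with undefined
direction or an axis shorter than 4 px are skipped and counted.

The rear-enrichment index is the mean intensity over the back third
divided by the front third of the averaged profile; no background
subtraction is applied by default. Whether per-frame profiles should be
normalized to their own mean before averaging is not settled, so both the
raw and the mean-normalized average (and both indices) are emitted.

## The synthetic-data generator

No raw light-sheet data for this system is public, so validation rests on
a generator that emulates the statistical structure the analyses assume,
with complete ground truth. Its defaults are the study conditions:
1 min frame interval (the protrusion-imaging setting; whole-retina
stacks used 5 min), 0.3 µm/px (in the plausible 0.2–0.5 range of the
camera/objective combination — the exact value is not stated, which is
precisely why calibration is a user input), 200×200 px fields, 60 frames,
cell radius 5 µm (soma ~10 µm across, from the published scale bars), and
gamma-distributed per-frame speeds (shape 1.2) around a mean of
0.7 µm/min, which span roughly 0.06–4.4 µm/min with lower/upper quartiles
near 0.38 and 0.93 µm/min — the per-cell speed range and quartile cutoffs
reported for a tracked cell. The heading follows a wrapped-normal
correlated random walk whose turning SD is chosen so that the
direction correlation between frames equals `path_persistence` (default
0.6); paths reflect at a margin so the cell stays imageable.

Contours are star-convex: an area-preserving ellipse (axis ratio
`elongation`, default 2) aligned with the movement direction, modulated
by low-order radial Fourier wobble, and pinned so that the polygon's area
centroid sits exactly on the track position. At `rounding_frame` the
contour is an exact circle — the mitosis model is purely geometric.
Protrusion tips are drawn per frame as Poisson counts (rate 2/frame) with
angular offsets from the movement direction sampled from a von Mises
distribution whose concentration is `kappa_low` below the realized 25th
speed percentile, `kappa_high` above the 75th, linearly interpolated
between; offsets are folded to the unsigned [0°, 180°] range to match the
analysis convention, and κ = 0 degenerates to a uniform distribution. The
published work gives no quantitative protrusion rate or length, so those
defaults (rate 2/frame, length 1.2–1.8× radius) are chosen for test
power, not biological fidelity.

Rendering produces three channels — filled cell body, a 3 px cortical
band whose intensity rises linearly from front to back by
`rear_polarity_strength` (default 3; the band width deliberately exceeds
the 3 px line-scan width), and static non-overlapping neighbour nuclei
(2 per 100×100 px) that provide registration content and segmentation
context but no mechanics. Global drift accumulates per frame (frame 0
undrifted) and is applied by shifting world coordinates before
rasterization, so the recorded truth drift is exact; frames whose contour
leaves the field are flagged, never silently cropped. Each channel is
blurred by a Gaussian point-spread proxy (`psf_sigma_px`, default 0.7 px)
— real microscopy is band-limited, and crisp binary edges would be both
unrealistic and needlessly hostile to interpolation — then Gaussian noise
is added, intensities are clipped to [0, 1] and quantized to the 16-bit
grid used on disk, which makes in-memory and persisted pixels bitwise
identical and the whole dataset byte-reproducible from (config, seed).

What the generator does *not* model, and what passing tests therefore do
not demonstrate about real data: tissue mechanics (no forces, no nuclear
lamina stiffness, no basal barrier), 3D optics (no anisotropic PSF, no
attenuation), photobleaching, moving neighbours, tracking errors in the
input tracks, and protrusion lifetime structure (each simulated tip lives
one frame). Results on real light-sheet data additionally depend on
manual-tracking quality, which is outside the package's scope.

## Numerical choices and degenerate inputs

- Percentile convention: linear interpolation between order statistics
  (type 7); recorded in the manifest.
- Angle computation clamps the cosine into [−1, 1] before `acos`;
  coincident tip and centroid is an error, zero displacement frames are
  filtered before angles are computed.
- Sub-pixel drift: 0.05 px search grid plus quadratic peak fit; ties
  toward zero shift (bias-free for symmetric peaks).
- Segmentation threshold iteration stops at a fixed point of the
  component or after 8 iterations; components below 9 px are failures.
- CSV output rounds coordinates to 6 decimals (sub-nanometre at µm
  scale), making writes byte-stable; all writes are write-then-rename so
  a failure never leaves a truncated file.
- Degenerate polygons (non-positive area, < 8 vertices) and too-short
  tracks/series raise errors with diagnostics rather than producing NaN.

## Problem sizes used in validation

The package's own validation runs on deliberately small instances chosen
to keep the full suite fast while leaving each statistical check well
powered: 160–200 px fields, 16–60 frame movies for image-based checks,
300–1000-frame kinematics-only simulations (no rendering) where ≥ 1000
protrusion samples are needed, 100 random convex polygons for the shape
oracles, and 200 bootstrap resamples for the enrichment index. Where a
check compares a stochastic estimate against a tolerance (e.g. the
rear-enrichment index of an unpolarized cell), profiles from three
independent movies are pooled so the Monte Carlo error of the estimate is
small relative to the tolerance.

## Known limitations

- Segmentation assumes one bright, roughly star-convex cell near the
  seed; touching neighbours of equal intensity are flagged, not resolved.
- The boundary refinement searches ±1.5 px along the normal; extremely
  diffuse edges degrade gracefully to the pixel-level boundary.
- Depth uses per-frame layer lines/polylines; strongly curved layers are
  approximated by the polyline resolution supplied.
- The polarity index averages band and cytoplasm along the scan line, so
  it understates the raw cortical rear:front ratio (the generator's
  3:1 band contrast yields an index near 2.5); it is a monotone readout,
  not an absolute contrast estimate.
- No multi-cell tracking or association: tracks arrive identified, as in
  a manual-tracking workflow.
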