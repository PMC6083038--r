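---
title: "Methods: axon tracing, synapse-size mixtures and mEPSC analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: axon tracing, synapse-size mixtures and mEPSC analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axonmap)
```

`axonmap` quantifies descending axonal projections and the synaptic
populations they form, from three kinds of raw material: calibrated 3D
confocal stacks of fluorophore-labelled axons, distributions of synapse
sizes (fluorescent puncta surface areas, in µm²) or quantal current
amplitudes (mEPSC peaks, in pA), and voltage-clamp current recordings.
This vignette explains the models and algorithms, the parameters that
matter, and the checks behind the test suite.

## Semi-automatic axon tracing

### Image model and assumptions

The tracer assumes bright, roughly tubular axons on a darker background.
A stack is a `(z, y, x)` grid of non-negative intensities with per-axis
voxel sizes in µm; confocal stacks are anisotropic (optical sections of
0.5–0.6 µm against ~0.4 µm lateral resolution), so all µm conversions are
per-axis. Internally the algorithm works in *pixel* units on the raw grid —
smoothing scales and windows are specified in pixels — and converts to µm
only when traces are emitted. Voxel indices are 0-based and a voxel's
physical position is its centre, `(index + 0.5) * voxel_size`, which makes
analytically rendered phantoms exact.

### Stage 1: seed generation

Seeds are generated in five steps:

1. maximum-intensity projection along z;
2. band-pass binarization: a pixel is foreground iff
   `lower ≤ value ≤ upper`. Setting the two thresholds is the method's one
   interactive step. The upper cut removes saturated structures (somata,
   antibody debris) that are bright but not axonal. For a maximum
   projection of a noisy stack the lower threshold must sit above the
   *projected* noise ceiling — a maximum over `nz` planes lifts the
   background floor by roughly the upper tail of the per-voxel noise, which
   is why `benchmark_trace_params()` uses
   `background + 3.5 × noise SD`;
3. exact Euclidean distance transform of the foreground (background = 0,
   orthogonal boundary pixels = 1, medial-axis pixels locally maximal);
4. local maxima of the distance map within `N × N` windows (default
   `N = 5` px, dense enough to cover tortuous, tightly packed segments)
   give the seed `(x, y)` coordinates. Maxima are *plateau-inclusive*: the
   medial axis of a uniform-width tube is an exact plateau of the distance
   map, so demanding strict maxima would mark only the plateau's ends —
   the worst possible seeds, sitting on end-caps where the tubularity test
   fails. Tied candidates are thinned deterministically (descending
   distance score, then row/column order), never leaving two seeds within
   one window;
5. each `(x, y)` takes the z of its column's brightest voxel. Ties —
   an axon running straight down the column — resolve to the middle of the
   brightest plateau rather than its end, for the same end-cap reason.

### Stage 2: vectorial tracking

The stack is first convolved with an isotropic-in-pixels Gaussian
(`sigma`, default 5 px; the validation phantoms use 2 px because their
tubes are only 3 px wide and heavier smoothing merges nothing there) using
separable, reflective-boundary convolution. Smoothing makes the sampled
field effectively differentiable and is what places the cross-sectional
intensity maximum on the medial axis.

At each tracking node the local Hessian — the symmetric 3×3 matrix of
second partial derivatives of the smoothed field — is estimated from the
surrounding 9×9×9-pixel window with 4th-order-accurate central
finite-difference stencils (5-point pure terms, 4×4-point cross terms).
The wider stencils matter: the plain 3-point second difference carries a
truncation error of ~5% on a smoothed 2 px tube, swamping the quantity it
is supposed to measure; the 4th-order stencil brings it under 1%. Sampling
at fractional positions uses trilinear interpolation, which slightly damps
curvature between voxel centres (worst case, adds 0.25 px² of apparent
variance per lateral axis); this affects the eigenvalues' magnitude but
not their ratios, so the tubularity decision is unaffected.

For a bright tube the eigenvalues, sorted by magnitude
`|λ1| ≤ |λ2| ≤ |λ3|`, satisfy `λ2 ≈ λ3 ≪ 0`, `λ1 ≈ 0`, and the
eigenvector of `λ1` points along the axon. The approximate relations are
operationalised with two scale-free ratios (invariant under intensity
rescaling): flatness `|λ1|/|λ3| ≤ 0.25` and cross-sectional isotropy
`min(|λ2|,|λ3|)/max(|λ2|,|λ3|) ≥ 0.5`. On the analytic tube
`I = exp(−2(x²+y²)/w²)` smoothed with scale σ, the closed form is
`λ2 = λ3 = −(s₀²/s²)/s²` with `s₀² = w²/4`, `s² = s₀² + σ²` (per unit
peak), and `λ1 = 0`; the ideal pattern `(0, −1, −1)` passes the test with
margin, a blob `(−1, −1, −1)` fails it.

Marching is bidirectional — a seed sits mid-axon, not at a tip — with a
default step of 1 pixel. Each step moves along the minor eigenvector
(sign chosen to keep a positive dot product with the previous step), then
re-centres the node with a medial correction: the smoothed field is
sampled on a disc of radius `window/2` in the plane normal to the march,
at 0.5 px pitch, and the node moves to the intensity maximum, refined to
sub-pixel precision by separable parabolic interpolation around the
discrete maximum. Without the refinement the 0.25 px lateral quantisation
zig-zags the polyline and inflates arc length by several percent on
oblique tubes.

A march terminates when (a) the tubularity test fails (tube end or
branch-region geometry), (b) the smoothed intensity falls below
`min_intensity` (by default the seed stage's lower threshold; with noisy,
zero-clipped backgrounds note that clipping *raises* the effective
background mean — `E[max(b + ε, 0)]` for Gaussian ε — and the floor should
sit above that), (c) the node comes within `window/2` of a volume face,
(d) it lands on a voxel already claimed by another trace, or (e) after
`max_steps`. Claimed voxels are dilated by one voxel after each accepted
trace so adjacent seeds on an already-traced axon are suppressed; traces
shorter than `min_nodes` (default 3) are discarded as spurious. Axonal
density is the summed polyline length divided by the stack's physical
volume, in µm/µm³.

### What the phantoms show — and what they don't

`make_phantom()` renders tubes with radial profile `exp(−2d²/w²)` (`d` =
pixel-space distance to the analytic centerline, max-blended where curves
overlap), plus a uniform background, optional Gaussian read noise and
Poisson shot noise, clipped to the detector range `[0, 1]`. Because the
cross-section is the same Gaussian form used in the Hessian closed form,
tracer accuracy can be scored against exact ground truth: the validation
suite uses ten single-tube phantoms (oblique lines and two-turn helices,
tube width 3 px, peak 0.9 over 0.05 background) in 72³-voxel anisotropic
volumes, noise-free and at peak SNR 5, scoring centerline coverage within
2 voxels and mean orthogonal deviation. Density recovery runs the full
`simulate → seeds → trace → density` chain on five of them.

Real data differ in ways the phantoms deliberately do not model: branching
and crossing axons, varying calibre and brightness along an axon,
structured autofluorescence, depth-dependent attenuation, and an
anisotropic PSF beyond voxel anisotropy. Passing phantom tests therefore
demonstrates the geometry engine is correct, not that thresholds
generalise to any slide; the two user thresholds remain genuinely
interactive, per image.

Observed behaviour worth knowing: traced length is biased a few percent
*low* on straight tubes because marches stop at the end-cap (where
tubularity legitimately fails) about one smoothing scale before the true
end; coverage is unaffected.

## Sum-of-Gaussians decomposition of all-point histograms

Pooled per-event values (mEPSC peak amplitudes across cells; mGRASP puncta
surface areas) are binned by the Freedman–Diaconis rule,
`binwidth = 2·IQR/n^{1/3}`, with quartiles by the Tukey hinge
(median-of-halves) convention — the convention is isolated in one function
and documented because different quartile rules move the binwidth by a few
percent. Densities are normalised to integrate to 1.

The binned density is fitted by bounded Levenberg–Marquardt least squares
with an offset plus 1–4 area-parameterised Gaussians,

y(x) = y₀ + Σᵢ Aᵢ/(wᵢ·√(π/2)) · exp(−2(x−xcᵢ)²/wᵢ²),

in which each component integrates exactly to its area `Aᵢ` and `wᵢ` is
twice the component standard deviation. Constraints: `A > 0`, `w > 0`,
centres within the data range. Initialisation is deterministic (k
contiguous equal-mass groups of the binned data; centres and widths from
weighted group moments), so a fit is a pure function of histogram and
start. Raw `χ² = Σ residual²` drives model comparison; the reduced form
and adjusted r² are reported alongside. A fit is flagged non-converged if
the optimiser fails or any width collapses below half a bin (a spike
narrower than the binning cannot be resolved — the all-mass-in-one-bin
pathology).

Model selection probes k = 1…4 (capped so every probe keeps ≥ 3k+1 bins).
Each k > 1 starts from three deterministic inits — previous fit plus a
vanishing component (bounding the warm-started χ² trail to be
non-increasing), previous fit plus a 10%-mass component at the largest
residual, and the fresh partition — and keeps the lowest χ². A larger k is
accepted over the best accepted fit so far only if χ² improves by more
than 5% *and* the adjusted r² improves by more than 0.01 *and* no
component's area falls below 1% of the total. The χ²-only rule is not
enough: with well-separated populations the misspecified intermediate k
can be poor (its adjusted r² even drops, because of the parameter penalty
at FD bin counts), and a fourth Gaussian often buys a few percent of χ²
while "making no difference" to adjusted r² — the adjusted-r² condition is
what rejects it. Candidates are judged without stopping at the first
rejection so a poor middle rung cannot mask a clearly better higher k; the
fourth-component probe is always run and reported in the trail even when
rejected.

Component area fractions `Aᵢ/ΣA` are the population proportions of the
small/medium/large classes. Cutoffs between adjacent classes are the
crossing points of the individual offset-free component densities between
the two centres (fallback, with a warning: midpoint of centres if the
curves do not cross there); classification is `value < c₁ → small`,
`c₁ ≤ value < c₂ → medium`, `≥ c₂ → large`, computed on magnitudes for
inward (negative) currents so "large" means large quantal size, and
reported per stratum (e.g. soma/dendrite) with empty strata as `NA`, not
zero. The validation suite draws 100 seeded replicates (n = 5000) from
fractions 0.31/0.41/0.28 at centres −5/−12/−22 (widths 2, i.e. ≥ 3 widths
of separation) and requires k = 3 in ≥ 90% of replicates, median centre
error ≤ 0.5 bins and median fraction error ≤ 0.05.

## Electrophysiology features

Passive properties from a hyperpolarising step `ΔV`: `Cm = Q/ΔV` (pC/mV →
reported pF), `Gm = Iss/ΔV` (pA/mV = nS), `Rs = ΔV/Ip` (mV/pA → reported
MΩ); recordings whose `Rs` rises more than 30% over its initial value are
excluded. These are exact arithmetic, tested as such.

mEPSC detection is deliberately simple and deterministic: a running-median
baseline (50 ms default, long against the event, short against drift) is
subtracted, making detection DC-invariant; the residual is smoothed with a
0.3 ms running mean (the matched-filter scale — the events' rise time);
excursions beyond the signed threshold are found with hysteresis (an
excursion only closes at half threshold, so noise riding on a decay cannot
re-trigger); merged events are split at smoothed peaks whose connecting
valley drops below 60% of the smaller peak; a 2 ms refractory (longer than
the peak, shorter than the decay) deduplicates. Event indices are
re-centred on the raw residual's extremum.

Per event, relative to a 1 ms pre-event median baseline: signed peak
amplitude (optionally averaged over a ~0.2 ms window to suppress
single-sample noise — the single-extremum definition is the default);
10–90% rise time with linear interpolation between samples; and the
weighted decay `(A₁τ₁ + A₂τ₂)/(A₁ + A₂)` from a bounded bi-exponential
fit of the normalised decay, falling back to a single exponential when the
second component is degenerate (< 1% amplitude share or time constants
within 5%). "Weighted decay" for synaptic currents is defined here as this
amplitude-weighted time constant, the common convention. Instantaneous
frequency is the reciprocal inter-event interval assigned to the later
event.

The mEPSC generator places difference-of-exponentials events (rise
0.3 ms; decay 2 and 8 ms split equally, giving the ~5 ms weighted decay
typical of these synapses) at Poisson times, with amplitudes from a
three-component mixture (fractions 0.23/0.50/0.27 at −6/−10/−16 pA —
small/medium/large quantal classes with a ~−10 pA mean) and 0.8 pA
Gaussian noise at 20 kHz. The validation run (10 Hz, 100 s, threshold
−4 pA) requires the detected count within `3√N` of the generated count and
median amplitude error ≤ 5%. The residual count deficit (~3–5%) is
structural and worth understanding: truly overlapping events closer than
the refractory merge, and the smallest amplitude class grazes the
threshold after smoothing attenuation. The frequency-versus-stimulation-
rate analysis is ordinary least squares with slope standard error and
5%/95% confidence limits; simulated data with a true slope of 4.6 Hz/Hz
must recover it within 3 standard errors.

## Numerical and design notes

- **TIFF round trips.** 32-bit grayscale storage in the `tiff` package is
  integer-quantised; write/read reproduces intensities to better than
  1e-9, not bit-exactly. SWC round trips are exact to < 1e-6 µm.
- **SWC for traces.** Traces are serialised as standard 7-column SWC
  simple paths (root parent −1); branching files are rejected on read
  since a trace is a segment, not a tree.
- **Degenerate inputs.** Zero IQR stops FD binning with advice to supply
  explicit bins; an all-foreground mask makes the distance transform
  undefined (error); a blank stack yields an empty seed list with a
  warning, not an error; a seed failing tubularity yields an empty trace.
- **Determinism.** All generators are pure functions of spec + seed;
  fits are pure functions of data + init; seed thinning, tie-breaks and
  event merging are all deterministic.
- **Problem sizes.** The validation suite uses 72³ phantom volumes,
  100 mixture replicates of n = 5000, and one 100 s event train — sizes at
  which every statistical band in the suite is comfortably resolved while
  the whole suite runs in a few minutes.

## Known limitations

The tracer follows segments, not trees: branch points typically fail the
tubularity test and terminate a march, so a branched axon is recovered as
multiple segments. Radii are not estimated. Thresholds are interactive by
design; no automatic threshold selection is provided. Density estimates
inherit the few-percent end-cap shortfall described above. The mixture
machinery fits at most four components and performs least squares on
binned densities — it is not a maximum-likelihood EM mixture fit, by
design, and inherits binning sensitivity through the FD rule.
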