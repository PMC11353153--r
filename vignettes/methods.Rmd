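---
title: "fluopipe: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fluopipe: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluopipe)
```

This vignette is the package's own account of the science it implements:
what each stage computes, which assumptions it makes, which parameters
matter and why their defaults are what they are, and where the design was
genuinely open. No empirical claim is made here that the test suite or
`scripts/acceptance.R` does not itself compute.

## The measurement model

A session is a fluorescence movie `stack[frame, row, col, channel]` with a
fixed sampling interval. The green channel carries a calcium indicator
(OGB-1, GCaMP family) whose fluorescence follows intracellular calcium; an
optional red channel carries an astrocyte-selective marker (SR-101 class).
Two acquisition regimes are supported:

* **frame scan** — full 2-D rasters, traditionally ~1 Hz, up to ~68 Hz on
  fast hardware;
* **line scan** — a 1-D path revisited at ~125 Hz, stored as
  `[line, 1, path_position, channel]` together with the path's pixel
  coordinates in the imaged field. High line rates are what make spectral
  analysis of calcium signals meaningful at all.

Coordinates are 1-based `(row, col)` with the origin at the top-left, the R
convention used by every matrix operation downstream; frame `i` sits at
`t = (i − 1) · dt`.

Electrophysiology arrives as a plain-text recording (documented header plus
`time value` columns). The segment matching the imaging interval — located
by a tagged marker (marker time = segment **start**; markers are a natural
place for ambiguity, and start-of-segment is the convention chosen and
enforced everywhere) — is decimated by the fixed factor 10. Decimation
filters first: a zero-phase order-8 Chebyshev type-I low-pass at 0.8× the
target Nyquist (`signal::decimate`), then every 10th sample. Plain
subsampling would alias any content above the target Nyquist straight into
the bands the spectral stage analyses, so the filter is not optional in
spirit, but it is switchable in code and its description is stored with
the recording.

## ROI detection

The reference image is a pixelwise reduction (mean, max or SD) over a frame
range, or an externally supplied image of matching size. Thresholding is
Otsu (via `EBImage::otsu`), a fraction of the maximum, or absolute; the
threshold actually applied is recorded for the report. Degenerate inputs
are fail-safe rather than fatal: a flat image under Otsu or an absolute
threshold above the maximum yields an *empty* mask with a warning — a blank
frame should never crash a batch run.

Connected components are **8-connected**. Somata sampled at moderate zoom
often touch diagonally after thresholding; 4-connectivity (what
`EBImage::bwlabel` provides) would split them, so labelling is implemented
in-package. Components outside `[min_area, max_area]` are removed and the
survivors relabelled 1..K in raster order of their first pixel, which makes
labelling deterministic and re-extraction idempotent.

Eccentricity uses the ellipse-of-identical-second-moments definition,
`e = sqrt(1 − λ₂/λ₁)` on the central second moments with the standard 1/12
unit-pixel correction — the *regionprops* convention the published
threshold of 0.85 presupposes. 0 is a circle; values near 1 are line-like.

Line-scan mapping annotates each ROI with the path positions inside it and
drops ROIs with fewer than `min_line_pixels` of them. "Insufficient
representation" is not quantified anywhere authoritative, so it is an
exposed parameter; the default of 3 keeps a usable trace while rejecting
grazing intersections.

## Cell validation and classification

An ROI is validated as a cell when all three hold:

| rule | default | form |
|---|---|---|
| area | 100 px | strictly `area > 100` |
| eccentricity | 0.85 | strictly `e < 0.85` (somata are round) |
| contrast | 2.0 | `mean(inside) ≥ 2 × mean(vicinity)`, inclusive |

The strict/inclusive mix follows the rules' published wording ("higher
than", "lower than", "at least") exactly; the boundary sweeps in the
acceptance script recover all three behaviourally. The vicinity is a ring
made by dilating the ROI by `vicinity_width` (default 5 px, a disc brush)
minus the ROI *and every other ROI* — a neighbouring bright cell must not
inflate the background estimate, which would silently fail valid cells in
dense fields.

Valid cells are classified from the red/green ratio of reference-image
means over the ROI: astrocytes at or above `astro_red_green_ratio_min`
(default 1.5), neurons at or below `neuron_red_green_ratio_max` (default
0.75), and `unclassified` in between. The published rule is qualitative, so
rather than invent a single cut-off the defaults deliberately leave a gap
that forces user review; both boundaries are plain parameters. Manual and
imported labels always take precedence over re-runs of the automatic
classifier, and survive the session container round-trip. Whether
astrocytes face *extra* geometric criteria beyond validation is ambiguous
in the source material; classification here is shared validation plus the
ratio split, nothing more.

## Traces

`F[t, k, c]` is the plain pixel mean over ROI k (or over its line-path
positions). ΔF/F₀ is computed on the green channel after background
subtraction:

* `auto` — per-frame mean of all pixels outside every ROI; robust to
  global illumination drift and the default;
* `manual` / `constant` / `none` — a user series, a scalar, or nothing.

F₀ is the mean (optionally median; the choice between them is unstated in
the source material, so it is an option with mean as default) of the
corrected trace over the control range, defaulting to the first 10% of
frames — the conventional pre-stimulus baseline — and always recorded.
A non-positive F₀ marks that cell's ΔF/F₀ undefined with a warning rather
than propagating nonsense or aborting the session.

ΔG/R = (G(t) − G(1))/R(t) is the movement-robust companion: an artefact
s(t) multiplying both channels contributes ≈ (G/R)·δ(t) to ΔG/R but the
full δ(t) to ΔF/F₀, so suppression scales with the red channel's
brightness — strong for bright SR-101 labelling, and quantified (not just
asserted) in the test suite.

Smoothing is a centred moving average with odd window, edges shrunk to
fit; window 1 is the identity. Mean preservation is exact in the interior
and O(window/length) at the edges, which the tests bound explicitly.

## Spectral analysis

The continuous wavelet transform uses the analytic complex Morlet wavelet
with centre-frequency parameter ω₀ = 6 — the standard compromise between
time and frequency resolution — evaluated by FFT convolution on a
log-spaced grid, default 64 voices over 0.5–30 Hz. "Normalized
coefficients" admits several readings; the package uses **L1 per-scale
normalization** (tagged in the result object so an L2 variant can coexist):
a unit-amplitude sinusoid yields ridge magnitude ≈ 1 at every frequency,
making magnitudes directly comparable across the grid — the property the
band summaries rely on. The signal mean is removed before transforming, a
cone-of-influence mask (e-folding time √2·s per edge) is returned, and a
signal shorter than two periods of the lowest frequency triggers an
edge-domination warning.

Band powers sum magnitudes over grid frequencies in **half-open** intervals
`[f_low, f_high)`: the printed band edges 4, 8 and 13 Hz each appear in two
bands, and half-open tiling resolves the double count deterministically.
δ/θ/α/β therefore partition the grid below 30 Hz exactly, which is tested
as an identity.

`analyze_session()` runs the same transform on every cell trace (imaging
time base) and on the ephys samples (their own time base), aligned at the
shared t = 0, and drops bands that a low imaging rate pushes above the
usable grid — with a warning, not an error, so 1 Hz legacy recordings still
analyse their delta band.

## Network synchrony

Phases come from a zero-phase band-pass (Butterworth order 4, applied
forward-backward) followed by the FFT analytic signal — filter choice is
logged in the result. The alternative of reading phase off the wavelet at
band centre exists as a cross-check, but the filter route is the primary
one because its pass-band is explicit.

PLV is `|mean(exp(i·Δφ))|` over retained samples. The first and last
`edge_zero_s` seconds (default: two periods of the band's lower edge) are
**excluded from the mean rather than literally zeroed**: writing zeros into
the phase difference would pile probability at Δφ = 0 and bias PLV upward,
the opposite of the stated purpose of edge handling. For independent
phases, E[PLV] = √π/2/√N — the Rayleigh expectation — which the tests use
as a calibration oracle at N = 10², 10³, 10⁴.

Sliding-window cross-correlation computes, per window, the Pearson
correlation at every integer-sample lag in ±max_lag and reports the maximum
and its lag. Defaults derive from the sampling interval: window 256
samples, step 64, max_lag = window/4; exact values "based on the sampling
interval" are not printed anywhere authoritative, so the derivation rule is
documented and every quantity overridable in seconds. Ties in the argmax
break deterministically (smallest |lag|, then negative first). Each
unordered pair is computed once and mirrored with a negated lag, so
max-correlation symmetry and lag antisymmetry hold *exactly*, not to
tolerance. Zero-variance windows are flagged `NA` rather than fatal.
Autocorrelation is the same machinery with lag 0 excluded from the argmax.

## Reports, batch processing, events

Reports are plain HTML plus PNG panels — open, diffable and testable; a
word-processor export would be none of those. Generation embeds no
timestamps, so identical states yield bit-identical documents (tested).
"Spike detection" is deliberately minimal: an event is a contiguous run of
ΔF/F₀ above `median + k·MAD` (k = 5, MAD scaled 1.4826 for normal
consistency) — a transient flag for the report's summary table, not
deconvolution, because no deconvolution algorithm is part of this
pipeline's remit.

Batch processing loads every session container in a folder (lexicographic
order, ids from file names) and applies a catalogued operation per session
under `tryCatch`, so one corrupt session yields one error row instead of
aborting the sweep.

The session container is R-native serialization wrapped in an explicit
magic string and schema version; loading anything else, or a future schema,
raises a versioned error. The choice gives a bit-exact save/load round trip
for every field — the property the tests assert — with versioning as the
migration path.

## The synthetic generator

`make_movie()` emulates the measurement regime the pipeline targets:
disk-shaped somata (default radius 6 px ≈ 113 px area, comfortably above
the 100 px validation floor) on a jittered grid so they never touch,
green intensity `baseline · (1 + amp · env(t) · sin(2πft + φ))` per cell,
a static red channel at planted red/green ratios (defaults 3.0 for
astrocytes, 0.2 for neurons — both a factor ≥ 2 beyond the decision
boundaries, so classification should be exact and any error is a bug, not
noise), and i.i.d. Gaussian pixel noise. SNR is defined as oscillation
amplitude in intensity units over pixel noise SD; the defaults
(100 × 0.5 / 10) give SNR 5. Frame mode defaults to 68 Hz × 30 s on a
128×128 field; line mode renders a path crossing each soma twice
(horizontal and vertical chords extended past the soma edge, echoing the
double-crossing used on real scan heads to defeat inertia) at 125 Hz, and
supplies a companion reference field image for ROI detection.

Slow amplitude envelopes (low-pass-filtered standardized noise, bandwidth
`env_bw`, depth `env_depth`) can be shared among a subset of cells;
`make_ephys()` sums exactly those cells' oscillatory components over 1/f
background noise, with padding and a start-of-segment marker. Band power
then inherits the envelope, which is what makes the coupled-versus-
uncoupled correlation analysis non-degenerate: with constant amplitudes
both band-power series would be flat and their correlation meaningless.

What the generator does **not** emulate: motion artefacts, bleaching,
neuropil contamination, spike-shaped (exponential) transients beyond the
optional event-test mode, and overlapping somata. Passing tests therefore
demonstrate correctness of the computations under the stated model, not
robustness to those real-world effects; the non-goals below apply.

Calcium dynamics are sinusoidal by design: the analysis surface of this
pipeline is oscillatory/spectral, so the ground truth is expressed in the
domain being measured (frequency, phase, amplitude) rather than as spike
trains convolved with indicator kernels.

## Problem sizes and determinism

Everything is seeded and regenerated at run time; no fixture is stored.
The test and acceptance runs use: 20-seed sweeps of the default
20-cell/128×128/68 Hz/30 s movie for detection recovery; 20 seeds of a
short (2 s) variant for classification accuracy, which depends only on the
reference images; frequency localization over {0.6, 1, 2, 3, 5, 8, 10, 13,
20, 25} Hz at 68 and 125 Hz; a 1000-draw PLV null at N = 10⁴ retained
samples; and 5 seeds of a 10-cell coupled-ephys session. These sizes were
chosen as the smallest that exercise each claim at full scale.

## Known limitations

* No motion correction beyond ROI translation between sessions
  (`shift_rois()`); movies are assumed registered.
* No watershed splitting: touching cells merge into one ROI.
* No spike inference/deconvolution; event flagging is a threshold rule.
* PLV significance is calibrated against the analytic null only; surrogate
  testing, Granger causality and graph metrics are out of scope.
* Proprietary acquisition formats are not parsed; TIFF plus the documented
  text ephys format are the interchange surface.
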