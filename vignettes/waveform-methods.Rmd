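---
title: "Quantifying tardigrade sperm motility: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tardigrade sperm motility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tardicasa)
```

## The measurement problem

Tardigrade spermatozoa are unusual cells: a long head built from a coiled
nucleus and a species-specific acrosome, a mid-piece, and a flagellar tail.
The cell swims mid-piece first, with head and tail trailing. Given
high-speed video (150 frames per second) and digitised midlines of the two
filaments, the questions a motility study asks are kinematic: how fast does
the cell travel, how fast does the tail beat, how much does each part of
each filament bend, and does the bending pattern differ between swimming
straight and turning, between head and tail, or between species?

`tardicasa` implements that analysis chain for digitised midline traces:
arc-length station resampling, body-frame waveform registration, signed
curvature profiling, curvilinear velocity (VCL), beat frequency by peak
counting, straight-versus-turn classification, and per-station
variance-ratio (F) significance profiles. Because no public video or trace
data accompany the original observations, the package also ships a
synthetic flagellar-beat generator with fully known ground truth; every
estimator is validated by parameter recovery against it.

## The synthetic beat model

The generator builds each frame's shape in a body frame and then places it
rigidly on a swimming path; beating and swimming are decoupled by design.

**Shape.** Both filaments share the mid-piece base point. Along each part,
arc length $s$ runs from the base to the tip, and the signed curvature
field is a travelling wave

$$\kappa(s, t) = A(s)\,\sin\!\left(\frac{2\pi s}{\lambda} - 2\pi f t + \phi_0\right),$$

with $A(s)$ equal to the tail amplitude on the tail and that amplitude
scaled by the head factor on the head. The head factor (default 0.3, in
$[0,1]$) models the empirical observation that the stiff nucleus/acrosome
region trembles less than the tail. An optional `linear_ramp` envelope
scales $A(s)$ from zero at the base to its nominal value at the tip,
producing station-dependent beat variance for tests that need it. The
tangent angle is the running integral of $\kappa$ over $s$ and the midline
the running integral of the unit tangent, both computed by cumulative
trapezoid on an internal 0.1-µm grid — an order of magnitude finer than
the 1-µm analysis stations, so station resampling is never limited by
generator discretisation. Midlines are exported at 0.25-µm spacing.

**Swimming.** The base point advances with constant curvilinear speed
while its heading changes at a constant rate (0 °/s gives a straight
path, a nonzero rate a circular arc); body orientation follows the path
heading. Speed is imposed, not emergent — the analysis measures
kinematics, so no hydrodynamic (resistive-force or slender-body)
propulsion model is attempted, and the beat has no influence on the path.

**Sampling.** Frames sample $t = 0, 1/\mathrm{fps}, \dots$, up to and
including the requested duration, so a record of duration $T$ holds
$\mathrm{round}(T\,\mathrm{fps}) + 1$ frames and its elapsed time — the
interval count over fps, the denominator of every rate estimate — equals
$T$ exactly. This fencepost convention is what makes integer-cycle
arithmetic (say, 99 beat peaks in 2.0 s = 49.5 Hz) attainable. The
generator refuses frame rates at or below twice the beat frequency
(aliasing). Optional isotropic Gaussian noise (sd in µm) is added to every
exported coordinate; with the seed carried in the swim parameters,
identical ground truth reproduces traces bit for bit.

**Morphology presets.** Two presets carry the study species' nucleus
boundaries — 21 µm (*Paramacrobiotus* sp.) and 11 µm (*M. shonaicus*)
from the head base — and default part lengths (60.5/32.5 µm and
14.5/22.5 µm head/tail) chosen so the interior station counts at 1-µm
spacing equal the position totals over which per-station comparisons are
reported (59/31 and 13/21). The extra half-micrometre keeps the last
station robust: a curved midline's chord length is marginally shorter
than its arc length, and a part length sitting exactly on a station
multiple would let that shortening drop the final station. The recording
chamber is treated as strictly two-dimensional; the generator models
planar beating only.

## Estimators

**Stations and curvature.** Midlines are resampled at stations every
1 µm of cumulative chord length from the base (station 0, kept as a
geometric reference but excluded from statistics). Signed curvature at a
station is the turn angle between the two adjacent unit secants divided by
the spacing — the three-point discrete curvature, exact in the circle
limit, positive for counter-clockwise turning. Spline or
higher-order estimators were rejected for opacity: the turn-angle form
matches the per-micrometre station framing and has a transparent error
model (relative bias $O(\kappa^2 \Delta s^2)$, under 1 % for the
amplitudes used here). The first and last stations only admit one-sided
estimates; they are flagged `boundary` and excluded from variance
statistics, which avoids their bias at the cost of one station per end.

**Waveform registration.** "Normalized" waveforms are rigid body-frame
registrations: translate the base to the origin and rotate the base
secant onto +x. Curvature is invariant to this map, so no statistic in the
pipeline depends on it; an optional flag additionally rescales coordinates
by filament length for cross-species display. Registration is idempotent,
and reflections negate both the registered ordinate and the curvature
sign, as they must.

**VCL.** Curvilinear velocity is the summed frame-to-frame displacement of
the mid-piece divided by elapsed time, with elapsed time counted as
intervals, $(n-1)/\mathrm{fps}$. No smoothing is applied; VCL is the one
CASA speed the study uses, and the VSL/VAP/LIN battery is deliberately out
of scope.

**Beat frequency.** The beat signal is the signed curvature at the 5-µm
tail station — translation- and rotation-invariant, hence robust to the
cell's own swimming — and the estimate is peak count over elapsed time.
At 150 fps a ~50 Hz beat leaves barely three samples per cycle, and
counting strict maxima of the raw sample sequence mis-counts the cycle
straddling either end of the record for most beat phases. The count is
therefore taken on the band-limited reconstruction of the record: the
samples (excluding the last, so the retained points tile the elapsed time
exactly) are Fourier-upsampled 16-fold and peaks are counted circularly
over one period, with a topographic-prominence floor (20 % of the signal
range) and a minimum separation of 2 frames. When the beat completes a
whole number of cycles in the record the periodic reconstruction is exact
and the count is exact for every phase; otherwise the seam of the
periodic extension can displace one peak, bounding the error by half a
cycle, i.e. $0.5/T$ Hz. Peaks only are counted — not half-cycles — and no
Fourier-magnitude frequency estimate replaces counting; the spectral
machinery is used solely to interpolate the sampled waveform.

**Straight versus turning.** The study reports the two categories without
an operational rule, so the classifier here is a declared stand-in: over
non-overlapping 10-frame windows of the track, the mean absolute heading
change rate of the displacement vector is compared with a threshold
(default 90 °/s; ties fall to `straight`). Windows with mean displacement
below 0.1 µm/frame are `immotile` and excluded from pooling. Simulated
cohorts at heading rates of 0 and at least twice the threshold are
separated perfectly, and any threshold between the cohort rates yields
identical labels; conclusions that depend on the paper's per-cell labels
rather than such separable cohorts are not claimed.

## The statistical layer

Per-station amplitude comparisons use the two-sided variance-ratio F test
on signed-curvature samples pooled across the 10-frame analysis window
(one sample per frame per station): $F = s_a^2/s_b^2$,
$p = 2\min\{P(F \le f), P(F \ge f)\}$ capped at 1. Signed rather than
rectified curvature is used — the wave is mean-zero, so variance is the
natural amplitude measure — with rectification left to the caller if
wanted. Significance profiles flag stations with $p$ below the level
(default 0.01, strict), report the percentage of significant stations
rounded half-up to one decimal, and apply **no multiple-testing
correction** by default, matching the study's raw per-position reporting;
Benjamini–Hochberg adjustment is available but off. Station matching
between two series uses the intersection of arc-length positions, which
also permits head-versus-tail comparisons on their common proximal range.

Speed comparisons use the Mann–Whitney U test. For combined samples of at
most 20 without ties the two-sided p-value is exact, from a
dynamic-programming enumeration of the U null distribution (cached per
sample-size pair); larger or tied samples fall back to the mid-rank
normal approximation with tie and continuity corrections, and the result
records which path ran. The switch point keeps worst-case enumeration
desk-scale while covering the study's cohort sizes ($n = 26$ per species)
in the approximate regime only when ties occur; both paths are
cross-checked in the tests against full subset enumeration and against
`stats::wilcox.test`.

Type-I calibration is part of the test suite: over 10,000 seeded null
replicates at $n = 10$ per side, both tests reject at $\alpha = 0.01$
within [0.007, 0.013]. The exact rank test is discrete — its attainable
level just below 0.01 is 0.0089 — so its observed rate sits slightly
under the nominal level by construction, not by error.

## Numerical and design notes

* Station indexing is 1-based in micrometres from the part base; station
  $k$ sits at $k$ µm. The base is a reference point, never a statistic
  site.
* Sign convention: counter-clockwise positive in mathematical (y-up)
  coordinates; traces store mathematical y, not raster rows.
* Collinear station triples give exactly zero curvature; coincident
  points are rejected as degenerate input rather than patched.
* Trace and track files are plain CSV with header, µm and seconds, at
  least 9 significant digits; read∘write is the identity to float
  precision, and row order is immaterial. No reader for the proprietary
  tracing format used in the original study is provided (undocumented).
* All randomness flows through explicit integer seeds; reruns are
  byte-identical.

## Problem sizes

Routine tests simulate 0.03–0.4 s of beating (5–61 frames) per cell,
which the recovery properties show is already sufficient: VCL and beat
frequency are exact on noise-free records of these lengths. The
end-to-end recovery checks use 2-s records at 150 fps (301 frames), the
duration at which the reported beat-range bounds (49.5 and 52.5 Hz)
complete whole cycle counts. Cohort-level runs default to 26 cells per
species, matching the reported cohort sizes, with shorter per-cell
records to keep full experiments interactive.

## What the synthetic validation does and does not show

The generator emulates the statistical structure the analysis assumes — a
traveling curvature wave with region-dependent amplitude, stiffer head
than tail, rigid swimming, 150-fps sampling, optional coordinate noise —
so recovery tests demonstrate that the estimators are correct on data
satisfying those assumptions, at the reported magnitudes. They do not
validate the upstream tracing step (the pipeline consumes coordinates,
not video), nor physiological realism: real flagella show asymmetric and
non-sinusoidal beats, beat-path coupling, three-dimensional components,
and tracking errors that are neither isotropic nor independent. Results
on real traces inherit those caveats. Within scope, the worked-example
arithmetic (percentage summaries of significant positions) reproduces the
published fractions exactly, and the speed, beat-frequency and
head-versus-tail variance findings are reproduced on synthetic cohorts
whose ground truth is set to the published values.
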