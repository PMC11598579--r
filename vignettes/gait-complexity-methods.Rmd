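---
title: "Methods: stride-time variability and gait complexity from pocket accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stride-time variability and gait complexity from pocket accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitcx)
```

## The problem

Stride-to-stride fluctuations of walking are not noise: in healthy adults
the inter-stride-interval (ISI) series shows persistent long-range
correlation, and changes in that temporal structure -- not just in its
magnitude -- accompany ageing and fall risk. `gaitcx` estimates both the
magnitude (mean stride time, SD, coefficient of variation) and the
structure (fractal scaling, regularity, multiscale complexity, and the
decay of statistical persistence) of stride-time variability from a single
pocket-worn smartphone accelerometer recorded during ordinary,
unsupervised walking.

The pipeline has to solve three problems that laboratory gait analysis
does not have: the sampling clock is irregular, the phone's orientation is
only loosely controlled (we assume a known vertical axis and a possible
upside-down orientation, no rotation correction), and walking occurs in
bouts separated by browsing, standing and sitting.

## Preprocessing

The vertical axis is linearly interpolated onto a uniform 100 Hz grid
(duplicated timestamps are first collapsed to their mean). Linear rather
than spline interpolation is used deliberately: cubic interpolation rings
at bout edges and at the sharp heel-strike transients, and the detector
consumes local extrema, which ringing fabricates.

The gravity bias is removed as the whole-recording mean of the vertical
signal rather than a fixed 9.81 m/s^2, which absorbs any accelerometer
calibration offset. When the device is worn upside down the signal is
multiplied by -1.

Two streams are then kept:

* the **raw stream** (uniform, gravity- and orientation-corrected but
  unfiltered), consumed by the nonlinear measures, which are sensitive to
  the subtle temporal structure a filter can distort, and
* the **filtered stream**, a single-pass (causal) 4th-order Butterworth
  low-pass at 16 Hz, consumed by event detection and the linear measures.

The low-pass is causal on purpose. A causal 4th-order Butterworth at
16 Hz/100 Hz delays the passband by roughly three samples; the detection
stage exploits this by relocating each filtered-stream event in the raw
stream with a three-frame backward offset followed by a forward
local-minimum search. A zero-phase (forward-backward) filter would make
that offset meaningless.

## Heel-contact detection

Right-heel contacts are located in six steps on the filtered stream:

1. 0.1 Hz causal Butterworth high-pass, so integration drift does not
   accumulate;
2. cumulative trapezoidal integration to a vertical velocity signal;
3. convolution with a first-derivative-of-Gaussian wavelet at scale 12
   samples (at 100 Hz; the scale rescales proportionally with the rate).
   Differentiating the velocity with a Gaussian-smoothing kernel returns
   the acceleration smoothed at the wavelet scale; the sign convention is
   chosen so that trace minima align with acceleration minima near heel
   contact;
4. candidate minima: all strict local minima of the trace below a
   threshold set to 40% of the median of the 10 most-negative local
   minima, then greedy enforcement of a 0.8 s separation (the lower limit
   of a healthy adult's stride time), keeping the deeper of any
   conflicting pair. Because the threshold is relative, detection is
   invariant to positive rescaling of the signal;
5. from each candidate, search forward to the next strict local maximum of
   the trace;
6. from that maximum, search forward in the filtered acceleration to the
   first strict local minimum -- the right-heel contact.

Events are then relocated in the raw stream: start three frames before the
filtered-stream index and search forward for the first strict raw local
minimum. Throughout, a "local extremum" is a sample strictly greater/less
than both immediate neighbours, and a search that begins on an extremum
accepts it (this matters: with the three-frame filter delay, the relocated
search frequently starts exactly on the raw minimum).

Two readings of the threshold rule were possible ("10 minimum CWT values"
could mean the first ten or the ten deepest); we use the ten most-negative
local minima, which makes the threshold depend on the gait rather than on
where the recording happens to start. Separation conflicts keep the more
negative minimum because depth, not order of arrival, is what the
threshold rule already privileges.

## Bout segmentation

Gaps longer than 1.8 s between consecutive contacts split the event series
into bouts. A bout must have more than 24 strides (strides = events minus
one, so at least 26 events); its first and last two strides are then
removed so only steady-state gait remains, and at least 20 strides must
survive. The strict reading of "greater than 24" means the shortest
retained bout has 21 post-trim strides, consistent with the 20-stride
eligibility floor of the linear measures.

## Measures and eligibility

For each participant:

* **Linear** (bouts of 20+ strides, filtered stream): mean stride time
  `xISI`, sample SD (n - 1), and COV = 100 * SD / xISI, averaged across
  qualifying bouts.
* **FSI** (detrended fluctuation analysis), **ApEn**, **SaEn** (bouts of
  more than 255 strides, raw stream), averaged across qualifying bouts.
* **MSE scales 1-4, CI, SPD, EnHL**: exactly the first 800 strides of the
  longest raw-stream bout; participants whose longest bout is shorter are
  ineligible and reported as `NA` with the reason.

DFA integrates the mean-centred series, splits the profile into
non-overlapping boxes of n = 10..40 strides taken from the start (the tail
remainder is discarded; no backward pass), removes a least-squares line
per box, averages the RMS residual across boxes, and takes the slope of
log10 fluctuation against log10 box size. On exact fractional Gaussian
noise of length 1000 this estimator recovers the Hurst exponent to within
about 0.01 in the mean (20-seed means 0.512 / 0.699 / 0.891 for H = 0.5 /
0.7 / 0.9 at the package defaults), comfortably identifying white versus
persistent stride dynamics.

ApEn uses the Pincus formulation (self-matches included); SaEn excludes
self-matches and is exactly 0 for a strictly periodic series. Both use
Chebyshev distance with m = 2 and r = 0.15 times the sample SD of the
series. For multiscale entropy the radius is held fixed at 0.15 times the
scale-1 SD for all scales (the Costa convention): re-deriving r per scale
would conflate the entropy change across scales with the variance
reduction of coarse-graining. Undefined sample entropies (no template
match) are returned as `NA` with a warning, never silently as zero.

The complexity index is the trapezoidal area under the SaEn-versus-scale
curve over scales 1-4; with 800 strides the scale-4 series still has 200
points.

## Persistence decay and entropic half-life

The reshaping operator at separation `s` deals the series into `s` piles
(indices o, o+s, o+2s, ... concatenated over offsets o), validated against
the printed five-element example: separation 2 maps
`[1.13, 1.15, 1.17, 1.20, 1.22]` to `[1.13, 1.17, 1.22, 1.15, 1.20]`.
Separation 1 is the identity; so is separation n. One hundred random
permutations of the series provide the null: their DFA indices give the
critical limit `mean + 2 SD`, and their mean sample entropy anchors the
entropy normalization.

**SPD** is the smallest separation whose reshaped-series DFA index falls
strictly below the critical limit (a value exactly at the limit does not
cross); if the curve never crosses within separations 1-100 the value is
censored at 100 and flagged. The same 10-40 box range is used for
reshaped series as for the original.

**EnHL** normalizes each reshaped series' sample entropy between the
original series (0) and the random surrogates (1). This normalized curve
*rises* from 0 towards 1 as reshaping destroys short-range structure, so
a literal "first separation below 0.5" rule would fire at s = 1 for every
series. The package therefore defines the half-life as the first
separation at which the normalized entropy reaches or exceeds 0.5 -- the
point where half the series' predictability is lost, which is what a
half-life means -- and exposes the literal falling-crossing rule as
`direction = "literal"` (it censors whenever the curve is monotone). This
choice is documented rather than hidden because the published description
of the crossing direction cannot be satisfied by a curve anchored at 0.

## The synthetic-data generator

Because no participant recordings are distributed, every stage is
validated against a generator with exact ground truth.

**Stride times.** Fractional Gaussian noise is generated by circulant
embedding (Davies-Harte), whose induced covariance equals the target fGn
covariance to machine precision -- spectral approximations were rejected
because biased long-range structure would contaminate the DFA and SPD
validation. White, periodic and mixed models cover the degenerate cases.
Values are clipped below at 0.4 s (half the 0.8 s physiological floor) and
any clipping is reported; parameter choices that would clip more than 1%
of draws are rejected. Note one statistical subtlety: the sample mean of
persistent fGn deviates from the target mean with SD `sd_s * n^(H-1)`,
much wider than the i.i.d. `sd_s / sqrt(n)`; tests account for this.

**Acceleration.** Each stride contributes three smooth components: a wide
negative mid-swing trough (centred 0.55 stride-times before the contact,
width 0.10 stride-times, 3.5 m/s^2), a sharp positive impact peak (0.12 s
before contact, width 44 ms, 5 m/s^2) and a narrow negative contact
transient (at the contact, width 33 ms, 4 m/s^2) whose minimum falls
exactly at the true heel-contact time. The trough scales with stride
duration; the impact complex has fixed duration, as ground-impact
transients do not lengthen when strides slow down. A lead-in pseudo-stride
before each bout's first contact makes that contact detectable by the same
minimum-maximum-minimum chain as every other. This waveform is parametric,
not biomechanically simulated: after wavelet smoothing the trough is the
only thresholdable candidate per stride (the narrow transient survives at
under 40% of the trough's smoothed depth and is also separation-dominated),
the chain's forward maximum is the impact peak, and the first acceleration
minimum after it is the contact -- the detectability contract is exact by
construction. A pure harmonic base was tried first and rejected: harmonic
maxima are flat, and a first-local-minimum search launched from a flat
maximum is fragile under noise.

Gravity offset, orientation inversion, Gaussian timestamp jitter
(default SD 1 ms) and additive white noise complete the emulation. What
the generator does **not** emulate: turning, stairs, shuffling,
pathological gait, tri-axial orientation dynamics, or the actual spectral
content of mall walking -- no public recording was available to match it
against. Passing the package's tests therefore demonstrates that the
implementation is faithful to its stated algorithms and recovers known
structure under idealized pocket-accelerometer conditions, not that
detection performance transfers to arbitrary real-world recordings.

## Numerical choices and problem sizes

* Local extrema are strict; plateaus contain no extrema.
* The wavelet kernel is truncated at four scales on each side and edges
  are padded with the boundary value; the ramp-response error of the
  truncated kernel is below 0.1%.
* DFA requires at least two boxes at the largest box size and a
  non-constant series; surrogate DFA failures inside SPD are skipped with
  a warning rather than aborting the curve.
* All randomness (fGn, jitter, noise, surrogate permutations) flows
  through per-call integer seeds; `run_pipeline()` derives per-participant
  surrogate seeds as `config$seed + participant index`, so reports are
  bit-reproducible.
* The test-suite and validation scripts use deliberately moderate problem
  sizes -- series of 400-1608 strides, 20-seed replications, 100
  surrogates -- chosen so the full validation runs in about a minute while
  keeping every statistical check several standard errors away from its
  pass boundary.

## Known limitations

* The detector assumes one dominant wavelet minimum per stride; gait with
  severe shuffling or very asymmetric impact dynamics may violate this.
* Left-heel contacts and toe-offs are out of scope, as is any validation
  against motion capture or instrumented walkways.
* Group comparison is descriptive (means, SDs, OA-minus-YA differences);
  inferential statistics are left to the analyst.
* EnHL across coarse-grained scales is not implemented.
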