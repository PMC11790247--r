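---
title: "Models and methods behind aismorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aismorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aismorph)
```

## Scope

`aismorph` quantifies excitable axonal microdomains — the axon initial
segment (AIS) and nodes of Ranvier — from fluorescence microscopy, and the
electrophysiological signature of the neurons that carry them. Five
measurement layers are implemented: polyline-based image straightening with
normalized intensity profiles; threshold-based extent morphometry;
autocorrelation analysis of the ~190 nm spectrin/ankyrin periodicity in
STED-scale line profiles; puncta counting (synaptopodin clusters, vGAT
boutons) along the AIS; and action-potential / passive-membrane feature
extraction from current-clamp step protocols. A statistical layer implements
the outlier gate and the normality-gated comparison scheme used for such
data.

Every layer is validated against a first-class synthetic-data module that
renders images, profiles and voltage traces with known ground truth. This
vignette documents the models, the defaults and why they were chosen, the
numerical decisions, and what the synthetic validation does and does not
show about real data.

## The morphometry model

An AIS is measured by tracing a polyline from the somatic domain through the
AIS into the distal axon. The image is resampled on a moving frame along
this path ("straightening"): output column $c$ is the path point at
arclength $c$ pixels from the somatic end, rows are bilinear samples along
the local unit normal. A per-column transverse aggregate (maximum over a
band of half-width 3 px by default — robust against slight trace offsets)
gives a 1-D intensity profile, which is min–max normalized to $[0,1]$ using
the 1st percentile of column values as baseline (a robust minimum under
noise; the raw minimum would make normalization noise-dominated).

The object extent is the run from the first to the last profile position
whose normalized value exceeds 40 % (`threshold_fraction = 0.40`). With the
default pixel size of 0.21 µm/px:

* length = (last − first + 1) × 0.21 µm (inclusive pixel count, so a single
  suprathreshold pixel has length one pixel; the alternative exclusive
  convention would make it zero-length),
* distance to soma = first index × 0.21 µm (arclength from the trace start,
  which is by convention the somatic end).

If several suprathreshold runs exist, the first-above/last-above rule
bridges the gaps; `strict_contiguity = TRUE` additionally flags
fragmentation. Suprathreshold values at the profile boundary are flagged
`trace_too_short`, because the rule is only meaningful when the trace
extends beyond the object on both sides.

### Accuracy of the threshold rule

On noiseless, sharp-edged synthetic objects the measured length is within
1.2 px of truth for every object and within 1 px in the mean: 1 px is grid
quantization, and up to 0.2 px comes from bilinear resampling softening the
rendered edge combined with a threshold (40 %) below the edge midpoint
(50 %), which moves each crossing outward by up to 0.1 px.

With smooth plateau edges the bias is deterministic: for an error-function
edge of SD $s$ and threshold fraction $q$, each crossing sits at
$\Phi^{-1}(q)\,s$ outside the nominal edge, so the length bias is
$-2\Phi^{-1}(q)\,s$ (positive for $q<0.5$). The test suite verifies this
closed form; it means the 40 % rule slightly overestimates lengths on
blurred data, identically across conditions, which cancels in
between-condition differences.

## The synthetic AIS image model

Each synthetic AIS is a plateau of fluorescence along a gently meandering
path (sinusoidal transverse wiggle, amplitude 1.5 µm, period 25 µm —
curvatures typical of proximal axons) rendered at 0.21 µm/px:

* axial profile: plateau between onset and offset arclength, with
  error-function edges of 0.5 µm rise length by default (edge sharpness is
  not known for real data; 0 gives ideal sharp edges and is used for the
  exact round-trip tests);
* transverse profile: Gaussian of SD 0.3 µm (a thin axon under confocal
  blur);
* plateau 100, background 10, additive Gaussian pixel noise SD 5
  (≈ SNR 18 for the plateau — ordinary confocal quality), optional isotropic
  PSF blur;
* the ROI handed to the measurement code is the generating path itself,
  starting 3–7 µm proximal to the AIS onset and ending 8 µm distal.

Condition populations follow a hierarchical model: per-AIS true length =
condition mean + OTC offset (Normal(0, between-OTC SD), default 0 since
only per-condition dispersions are reported for such designs) + Normal(0,
between-AIS SD). Draws are floored at 1 µm; clipping affecting more than 1 %
of draws warns. The statistical unit for condition comparisons is the
per-OTC mean (6 per condition, 50 AIS each), matching the organotypic
plasticity design; per-AIS pooling is available but non-default.

What this emulates: plateau-like scaffold signal, realistic curvature,
shot-like noise, hierarchical population structure. What it does not:
uneven labeling along the AIS, neighboring structures crossing the trace,
z-attenuation, motion artifacts. Passing recovery tests therefore shows the
measurement chain is correct and unbiased under the stated model, not that
tracing errors or labeling heterogeneity are handled.

## Nanoscale periodicity

STED line profiles are modeled as an envelope (flat or Gaussian) times
$1 + m\cos(2\pi x/T)$ with period $T = 190$ nm and modulation depth $m$
(default 0.8), sampled every 10 nm. STED pixel sizes vary by setup and are
rarely reported with quantifications, so 10 nm was fixed once as a typical
value; spacing above $T/4$ is rejected as undersampled.

Autocorrelation uses the mean-removed estimator normalized at lag 0,
computed per non-overlapping 2 µm window and averaged. We use the
divide-by-$(N-k)$ (unbiased-lag) normalization rather than divide-by-$N$:
with 2 µm windows the biased estimator shrinks AC(190 nm) of a pure cosine
to ≈ 0.9, which would break the closed-form anchors AC(190) = 1 and
amplitude statistic = 2 that the analysis is calibrated against. Values are
clamped to $[-1, 1]$ so estimator noise at large lags cannot leave the
valid range. Lags at 95/190/285 nm are evaluated by linear interpolation
between sample lags.

The amplitude statistic is AC(190) − (AC(95) + AC(285))/2: positive for
190 nm-periodic signals, ≈ 0 for aperiodic ones, and exactly 0 for a 95 nm
period (all three lags then sit on maxima). Period detection takes the lag
of the first local maximum after the first local minimum, refined by
3-point parabolic interpolation; profiles without such a maximum are
reported as aperiodic rather than given a number.

## Puncta

Synthetic puncta channels place $N$ Gaussian objects (σ = 0.15 µm, ≈
0.35 µm FWHM — diffraction-limited confocal size for synaptopodin clusters
and vGAT boutons) in the straightened frame, strictly inside the AIS
extent, with transverse jitter (SD 0.25 µm) across the axon width. $N$ is
Poisson (or fixed); centers keep a hard minimum separation of 0.6 µm
because boutons and clusters are solid, non-overlapping objects of roughly
that diameter — and because below ~2σ + 1 px no intensity-based detector
can resolve a pair on a 0.21 µm grid, so the generator does not produce
configurations whose answer is undefined. Placement is by dart throwing
after the count is drawn, so the count distribution is exactly the drawn
one.

The detector smooths with a Gaussian (σ 0.15 µm), finds strict
8-neighborhood local maxima above background + 3 SD (median/MAD estimates,
making counts invariant to global intensity scaling), refines centroids by
3-point parabolic interpolation per axis, applies non-maximum suppression
at 0.4 µm (strongest first), and optionally restricts to the measured AIS
extent. All settings are config-driven; the defaults suit the punctum
scales above.

## Electrophysiology

Voltage traces come from a leaky integrator (rest −65 mV, input resistance
150 MΩ, τ 15 ms) with a template action potential inserted at each
analytically computed threshold crossing (−45 mV). Only waveform features
are analyzed downstream, so a template model is sufficient and exactly
controllable — a conductance model would add parameters without adding
testability. The template has a kink-like onset, as real cortical APs do:
an exponential upstroke over 0.35 × half-width whose onset slope
(≈ 54 mV/ms at the default 85 mV / 1 ms) exceeds any usual dV/dt criterion,
and a half-Gaussian repolarization sized so the full width at half
amplitude equals the requested half-width exactly. After each template the
membrane resets to rest, so first-spike latency shrinks and spike counts
grow with current.

Feature extraction: threshold is the voltage at the first sample of the
rising phase whose dV/dt reaches the criterion (20 mV/ms default — the
macro criterion used by acquisition software is rarely reported, so it is
config-exposed); amplitude = peak − threshold (exactly, by construction of
the measurement); half-width is measured at threshold + amplitude/2 with
linear interpolation on both flanks; max rise is the largest dV/dt between
threshold and peak. Waveform analysis uses the first AP fired at least
30 ms after step onset. Rheobase is the smallest step current eliciting at
least one AP (flagged when the lowest tested current already fires);
passive properties come from the −100 pA test sweep via Ohm's law, with the
steady state taken as the mean over the last quarter of the step. The f–I
maximum slope is the largest finite-difference slope between consecutive
steps. Note that the threshold estimator is quantization-limited: with a
54 mV/ms onset and 0.05 ms sampling, detected threshold can sit up to
~2.7 mV above nominal; the test suite checks features against an
independent enumeration oracle on the same trace.

## Statistics

The comparison layer reproduces the branching scheme standard for such
data: Shapiro–Wilk per group at α = 0.05 (the normality test itself is
rarely named in papers; Shapiro–Wilk is the default choice at these group
sizes, and groups too small to test are treated as normal), then

* 2 groups, normal → t-test (paired when pairing ids are given; zero
  variance differences are flagged as degenerate, not computed),
* 2 groups, non-normal → Mann–Whitney (paired: Wilcoxon signed-rank),
* \>2 groups, normal → one-way ANOVA + Tukey,
* \>2 groups, non-normal → Kruskal–Wallis + Dunn (hand-implemented rank-sum
  z statistics with tie correction; Bonferroni over contrasts, since no
  adjustment scheme is standard-named with Dunn).

The Grubbs outlier gate iterates the two-sided single-outlier test at
α = 0.05, with critical values computed from the t-distribution formula
rather than a lookup table. Condition summaries report mean, median and SD
(figure-legend conventions vary between mean and median; emitting both
covers either reading).

Longitudinal designs get a paired t-test on within-object differences plus
OLS of session 2 on session 1 with r². The synthetic longitudinal
generator draws a stable per-AIS component and adds within-AIS session
noise of 1.3 µm, which at a 3.9 µm population SD puts the week-to-week
r² near 0.79 — the regime of repeated in vivo length measurements of the
same AIS.

## Problem sizes and determinism

All randomness flows through one seeded helper (`with_seed()`); generators
derive per-object sub-seeds, so identical spec + seed gives byte-identical
output and manifests record every seed. Validation runs use 6 OTC × 50 AIS
per condition (the plasticity design), 30 AIS for the longitudinal design,
50 AIS for puncta recovery, 100-seed Monte-Carlo for calibration rates, and
10,000 draws for distribution-convergence checks of the fast (non-rendered)
generators; rendered convergence checks use 2,000 objects.

## Known limitations

* The extent rule measures one contiguous object per profile; genuinely
  fragmented AIS labeling is bridged (flagged in strict mode), which can
  overestimate lengths on real data with labeling gaps.
* Straightening assumes the trace stays inside the image with its
  transverse band; clipped bands produce NA samples and a warning, and the
  maximum aggregate then rests on fewer samples.
* The ephys model has no adaptation, no AP height variability and no
  channel noise; calibration statements about detector thresholds transfer
  to real recordings only qualitatively.
* The puncta detector is intensity-based; overlapping objects closer than
  ~2σ + 1 px are counted as one, which the generator's minimum-spacing
  model deliberately avoids rather than hides.
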