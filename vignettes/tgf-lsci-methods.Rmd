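---
title: "Methods: from speckle frames to TGF statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from speckle frames to TGF statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model behind
each stage, the tunable parameters and their defaults, what the synthetic
data emulate (and do not), and the numerical choices made where the design
was genuinely open.

## The physiological signal

Renal autoregulation stabilizes glomerular filtration through two
mechanisms acting on the afferent arteriole: tubuloglomerular feedback
(TGF), in which the macula densa senses distal tubular NaCl and triggers
constriction, and the faster myogenic response. TGF produces slow
oscillations of nephron blood flow, typically 0.018–0.033 Hz; the myogenic
component sits near 0.1 Hz. On the renal surface these oscillations are
visible in "star vessels" — stellate superficial microvessels downstream of
efferent arterioles — which laser speckle contrast imaging (LSCI) can
monitor across dozens of vessels simultaneously.

Two pharmacological probes frame the analysis. Furosemide blocks the
Na-K-2Cl co-transporter at the macula densa: TGF oscillations are
abolished and mean microvascular flow rises (≈ +11 %). Phlorizin inhibits
SGLT1/2 and lowers proximal Na⁺/glucose reabsorption: mean flow falls
(≈ −6 %) while TGF oscillations persist, attenuated.

## Imaging-side model

**Temporal contrast.** For each pixel, speckle contrast is
\(K = \sigma/\mu\) over consecutive non-overlapping windows of 25 frames of
the 50 Hz acquisition (sample, \(n-1\), standard deviation). The window
*stride* is an open choice — we use non-overlapping windows followed by the
per-second mean because it is the simplest scheme consistent with a
25-frame kernel and a 50 → 1 Hz output, and it is recorded in the output
metadata. Blood-flow index is \(\mathrm{BFI} = 1/K^2\), clamped at
\(K_{\min} = 10^{-3}\) so static pixels stay finite; the clamp is never
reached on realistic speckle.

A point worth stating explicitly: \(1/\hat K^2\) computed from 25-sample
windows is a *biased* estimator of \(1/K^2\). For near-Gaussian window
statistics \(E[1/S^2] = \tfrac{n-1}{n-3}\sigma^{-2}\), i.e. ≈ +9 % at
\(n = 25\), with a further kurtosis contribution at very low flow. Because
BFI is an arbitrary-units index and the bias is a fixed multiplicative
factor at a fixed kernel, it cancels from every control-versus-drug
comparison; our end-to-end calibration checks recover synthetic flow
targets within 10 %, which is exactly this bias plus sampling noise.

**Registration.** Breathing and visceral motion are in-plane and rigid to
good approximation (the fiducial is a 40 µm myograph wire on the cover
glass), so we estimate translation only; rotation is deliberately out of
scope. Each frame is reduced to a *soft fiducial map* — graded darkness
below an Otsu wire threshold after a radius-2 box blur. A hard binary mask
would quantize away subpixel information; the soft map keeps it, and
speckle fluctuation (whose per-pixel variation rivals the wire/background
contrast) is suppressed by the blur. Frames are phase-correlated against
frame 1 with quadratic interpolation of the correlation peak (adequate for
the 0.5 px accuracy target at a fraction of the cost of upsampled
correlation). Alignment resamples bilinearly; exposed borders take the
frame median so border contrast windows stay finite. Frames that lose the
fiducial are interpolated from neighbors; more than 5 % lost aborts with
the frame list.

**Segmentation.** The published workflow is "semiautomatic" with no stated
algorithm, so the package defines a reproducible stand-in: threshold the
time-averaged flow map at background *median* × (1 + 0.3) (median, not
mean, so bright vessels cannot drag the reference), radius-1 box blur
before thresholding, morphological opening of radius 1, connected
components, minimum area 20 px, and — as the manual component — optional
seed points that select components. All parameters are logged in the mask's
attributes.

## Superlet time–frequency analysis

TGF frequencies drift within a recording, so a fixed-resolution transform
must trade temporal against spectral precision. The superlet instead takes,
at each center frequency \(f\), a set of Morlet wavelets with cycle counts
\(c_1, 2c_1, \dots, oc_1\) and combines their response magnitudes
\(R_i(t,f)\) by geometric mean:
\[
P(t,f) = \Big[\prod_{i=1}^{o} R_i(t,f)\Big]^{2/o}.
\]
Short wavelets contribute temporal precision, long ones spectral precision;
the product retains both. Order 1 reduces *exactly* to base Morlet power —
a property the tests verify to 1e-9 — and the power is always bracketed by
the weakest and strongest single-wavelet powers.

Parameter conventions (all exposed in `superlet_params()`):

* Morlet envelope SD at frequency \(f\) with \(c\) cycles is
  \(b = c/(k_{sd} f)\) with \(k_{sd} = 5\); wavelets are unit-energy, so
  white noise produces a flat spectrum.
* Default grid 0.005–0.25 Hz in 0.001 Hz steps (246 bins); base cycles
  \(c_1 = 3\); order grows linearly 1 → 10 across the grid (adaptive
  superlet), rounded half-up for platform determinism.
* Cone of influence: cells within 2 envelope SDs of the longest wavelet at
  that frequency are flagged and excluded from time averages; a frequency
  with no edge-free cells is reported `NA` (this happens for short records
  at high orders) and downstream band integrals omit such bins.
* Series are demeaned before the transform; linear detrending is opt-in.
* Geometric means are accumulated in log space, so zero responses give
  zero power without underflow, and wavelet FFTs are cached per record
  geometry, which makes cohort-scale computation cheap.

For per-vessel *metric* spectra the package defaults to a 0.01–0.06 Hz
grid: it covers the TGF band (0.015–0.04 Hz) and the baseline band
(0.04–0.05 Hz) with margin, runs an order of magnitude faster than the
full grid at cohort scale, and — because the adaptive order reaches 10
already at 0.06 Hz — resolves the band more sharply. Detecting a 5 mHz
frequency drift (e.g. 0.02 → 0.025 Hz across a recording) requires
effective cycle counts above ~20, which the tests achieve with a fixed
order-5, \(c_1 = 8\) configuration.

## The three TGF metrics

* **BFI** — arithmetic mean of the 1 Hz flow series over the period.
* **Sigma** — SD of the series band-passed to 0.015–0.04 Hz. The filter is
  a 4th-order Butterworth applied forward–backward (zero phase) on an
  odd-reflection-padded, demeaned copy; the contract is gain ≥ 0.95 at
  0.0275 Hz and ≤ 0.05 at 0.1 Hz and DC (the demeaning makes DC rejection
  exact). Any filter meeting the contract is conformant. For an in-band
  sinusoid of amplitude \(A\), Sigma → \(A/\sqrt2\).
* **AUC** — trapezoidal integral of the time-averaged power spectrum over
  0.015–0.04 Hz minus a baseline area. The "median line" is interpreted as
  a *horizontal* line at the median power of the 0.04–0.05 Hz samples
  (the phrasing admits a sloped line; the choice is recorded here and in
  output metadata), so the baseline area is that median × 0.025 Hz. AUC
  may legitimately be negative when band power sits below the local noise
  floor. Spectra are power (squared-magnitude) quantities, not amplitudes;
  that convention was open and is fixed here.

The peak taxonomy (`classify_tgf_pattern()`) counts strict local maxima in
the band exceeding 3 × the baseline-band median power: 0 → no detectable
TGF, 1 → single stable frequency, ≥ 2 → drifting or multi-frequency
oscillation.

## Statistics

Metrics are compared between periods with a linear mixed-effects model
`metric ~ period + (1 | animal_id)` (REML), i.e. a random intercept per
animal and no random slope — vessels are not modeled as a nested level, an
open choice documented here. The period effect is tested with a
Satterthwaite-denominator F; p-values near a threshold can differ slightly
across denominator-df approximations, which matters only for borderline
effects. Significance uses p < 0.001. With a single animal the model is
unidentifiable and the comparison falls back to a paired t-test across
vessels with a warning. Degenerate paired tests (all differences zero)
return t = 0, p = 1 by convention. Box summaries use the
linear-interpolation percentile convention (`quantile(type = 7)`).

## The synthetic-data module

No recordings are deposited with the study this pipeline operationalizes,
so the generators *are* the study conditions.

**Flow series.** A vessel's 1 Hz record is
\(\mu + A_{tgf}\sin(2\pi\!\int f(u)du + \phi) + A_{myo}\sin(2\pi f_{myo}t)
+ \varepsilon\), with linear chirp \(f(u) = f_0 + du\) and Gaussian noise.
Defaults: 1800 s at 1 Hz (the 30-min observation period), mean BFI 60
(matching the visual scale of published example series, oscillating near
60 a.u. in control), TGF amplitude 5 a.u. before per-vessel scaling,
myogenic component 0.1 Hz at amplitude 1.5, noise SD 2. The amplitude
scale relative to mean flow is not published anywhere; these values are a
one-time choice giving band SNR in the range where all three spectral
patterns (single/none/multiple) occur, and they are not revisited.

**Cohorts.** Animals get a Gaussian random intercept (SD 5 a.u.) on mean
BFI. Vessels get a uniform TGF-amplitude multiplier in [0.2, 1] (strong
and weak oscillators coexist in one kidney), a TGF frequency uniform in
0.018–0.033 Hz, and a random phase. Drug periods regenerate each vessel
with `mean_bfi × (1 + mean_shift_frac)` and `tgf_amp × amp_scale` and
fresh noise. Presets encode the reported percent changes as generator
defaults — furosemide: +0.113 mean shift, amplitude × 0; phlorizin:
−0.0642, amplitude × 0.4 — used as inputs, not as acceptance truth.

**Speckle stacks.** Frame intensities are i.i.d. gamma draws per pixel
with coefficient of variation \(1/\sqrt{\mathrm{BFI}}\), a dark wire
fiducial stamped on every frame, whole-frame translation by the per-frame
motion (bilinear), and 8-bit quantization. Physically correlated speckle
is deliberately not modeled: the pipeline consumes only window-wise
\(\sigma/\mu\), which the gamma model reproduces. The stamped mean
intensity is 64: at the generator's minimum admissible flow (BFI = 1,
K = 1) this leaves the 8-bit clamp inactive; stamping at half-range 128
would truncate the gamma right tail at low flow and measurably bias the
window contrast (−7.5 % at BFI = 4), breaking the generator's own
calibration contract. Flow targets below 1 BFI unit are rejected because
the gamma model cannot produce contrast above 1.

**What passing tests do and do not show.** The generators emulate the
*statistical* structure the pipeline consumes: temporal contrast encoding
flow, rigid breathing motion with a trackable fiducial, stellate
high-flow regions, band-limited oscillations with drift, animal- and
vessel-level heterogeneity, and the two drug signatures. They do not
emulate speckle decorrelation physics, vascular topology,
pharmacokinetic onset, out-of-plane motion, or illumination drift —
success here shows the analysis chain is correct and well calibrated, not
that it is robust to every artifact of a live preparation.

## Problem sizes and reproducibility

The test suite and the acceptance script run cohorts of 5 animals × 60
vessels (furosemide) and 7 × 45 (phlorizin) at full 1800 s records —
matching the published group sizes and roughly their per-animal vessel
counts — plus 20 null-cohort replicates for type-I calibration, 30 s
imaging stacks for end-to-end flow calibration, and 3 s stacks for
registration accuracy. Every generator is a pure function of its
parameters and seed; `run_pipeline()` writes a manifest (package version,
config, seed, output hashes) sufficient to regenerate the metrics tables
byte for byte.

## Known limitations

* Translation-only registration; non-rigid or out-of-plane motion is not
  corrected.
* BFI is relative: no absolute perfusion calibration, and the
  \((n-1)/(n-3)\) estimator bias above applies to absolute values.
* The AUC baseline assumes the 0.04–0.05 Hz band is oscillation-free; a
  myogenic component leaking below 0.05 Hz would inflate the baseline.
* The mixed model treats vessels within an animal as exchangeable;
  spatial correlation between neighboring nephrons (a documented
  phenomenon) is ignored, which makes significance tests conservative for
  synchronized vessels.
* Cross-vessel phase/synchronization analysis is out of scope.
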