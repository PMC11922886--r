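---
title: "Models and methods behind ssmvep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ssmvep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssmvep)
```

This vignette explains the science and the numerical choices inside
**ssmvep**: how the Newton's-rings stimuli are constructed, what the
synthetic EEG generator does and does not emulate, how the spectral, SNR,
workload and classification analyses are defined, and where the design was
genuinely open and a decision had to be made.

## The paradigm

Steady-state motion visual evoked potentials (SSMVEPs) are periodic EEG
responses elicited by periodically *moving* stimuli rather than by
luminance flicker, which reduces visual fatigue relative to classical
SSVEPs. The bimodal paradigm studied here superimposes two modalities on a
concentric-rings ("Newton's rings") pattern:

* **motion** — the ring bands expand outward during the first half of each
  stimulation cycle and contract back during the second half, driving the
  magnocellular (motion-sensitive) pathway;
* **colour** — ring and background colours glide smoothly between
  black/red and white/green at the same frequency, driving the
  parvocellular (colour-sensitive) pathway, while the *perceived luminance
  of the whole field stays constant* so that no luminance flicker is
  introduced.

Single-modality controls (`single_motion`, `single_color`) disable one of
the two components. Four simultaneous targets at 3, 3.5, 4 and 4.5 Hz form
the user interface; a subject selects a command by fixating one target,
and the classifier recovers the attended frequency from six
parieto-occipital channels (Po3, Poz, Po4, O1, Oz, O2).

## Ring geometry and the area ratio C

The pattern is parameterised by the ring count $n$, a scale radius
$r_{\max}$, and the area ratio $C$ between the total band area $S_1$ and
the background area $S - S_1$ of the pattern disc:
$C = S_1 / (S - S_1)$. The outer radii form the arithmetic sequence
$r_i = (2i-1)\,r_{\max}/(2n)$, the midpoints of $n$ equal radial cells.

The per-ring band width is fixed by a per-cell rule: the disc is
partitioned into annular cells $[r_{i-1}, r_i]$ delimited by consecutive
outer radii (with $r_0 = 0$), and each band occupies the outer fraction
$C/(1+C)$ of its cell's *area*:
$$r_{i,\mathrm{inner}}^2 = r_i^2 - \frac{C}{1+C}\left(r_i^2 -
r_{i-1}^2\right).$$
Summing over cells, the bands cover exactly $C/(1+C)$ of the disc bounded
by the outermost ring radius $r_n$, so the global ratio equals $C$ by
construction. Two consequences matter for verification:

* area accounting uses the disc of radius $r_n$ (the edge of the pattern),
  not $r_{\max}$; measured against $r_{\max}$ the ratio would be biased low
  by $(r_n/r_{\max})^2$ and small ring counts could never realise large
  $C$;
* `measure_area_ratio()` verifies the realised ratio by pixel counting on
  a *binary* (non-anti-aliased) mask; at a 512-px canvas the agreement is
  within a fraction of a percent for $n \le 12$ and $C \le 1.5$.

**Motion model.** The direction of the printed recurrence for the inner
radii is degenerate if applied literally (it forces
$r_{i-1} = r_i$), and simple radial displacement of all band boundaries
changes each ring's area by roughly $2d/(r_o + r_i)$ — over 10% for inner
rings — which would make the area ratio oscillate within a cycle. The
package instead slides each band inside its cell in *squared-radius*
coordinates: the band's $r^2$-extent is constant, so its area is exactly
preserved at every frame, and the temporal profile
$s(t) = \tfrac12(1 - \cos 2\pi f t)$ moves the bands outward over phase
$0\ldots\pi$ and inward over $\pi\ldots 2\pi$. At $s = 1$ the band sits at
the outer end of its cell, which is precisely the static geometry above.
The rendered per-frame pixel-counted ratio stays within 2% of $C$; the
residual is pixelisation noise, suppressed further by the 1-px linear
edge anti-aliasing used for display frames.

## Equal-luminance colour modulation

Perceived luminance is the Rec.709 luma scaled by a device constant
$C_1$ (default 0.7, a display-dependent value):
$L = C_1(0.2126R + 0.7152G + 0.0722B)$, channels in $[0,255]$. The colour
trajectory is driven by the raised-cosine waveform
$R(t) = R_{\max}\tfrac12(1 - \cos 2\pi f t)$ — the $\tfrac12$ scaling keeps
the channel inside $[0, R_{\max}]$ (the unscaled $1-\cos$ form would peak
at $2R_{\max}$, leaving gamut).

Rings run black $\to$ red and the background white $\to$ green. A pure
green at white's luminance does not exist in gamut
($0.7152 \cdot 255 < 255$), so the background endpoint is chosen on the
white $\to$ green $\to$ dark-green path such that the *area-weighted* mean
frame luminance is invariant: if the bands cover fraction $\rho$ of the
canvas, the background endpoint's luminance is
$L_{\mathrm{white}} - \rho\, L_{\mathrm{red}}$. Because both colour
trajectories are linear in the same waveform, the mean luminance is then
constant at every instant, not just at the endpoints; the measured ripple
of rendered cycles is on the order of 0.01%, far inside the 1% target.
The brightness levels map to peak channel values
$R_{\max} \in \{85, 170, 255\}$ for low/medium/high; these are package
defaults, chosen as an even spacing of the 8-bit range, not measured
display values.

## The synthetic EEG generator

No public recordings exist for this paradigm, so all downstream analyses
are validated against a forward model whose structure mirrors the study
design: subjects $\times$ 3 brightness levels $\times$ 4 frequencies
(tasks) $\times$ trials $\times$ 6 channels $\times$ 5-s trials at
1200 Hz (6000 samples), organised in one block per paradigm with tasks run
in order 1..4. Each trial is

$$x_c(t) = g \sum_h A_h \sin(2\pi h f t + \phi_h)
  \;+\; \text{1/}f^{\gamma}\text{ noise}
  \;+\; \sum_{b \in \{\theta,\alpha,\beta\}} \text{band-limited noise}_b,$$

with $g$ the product of paradigm, brightness, channel and subject gains.
Defaults: two harmonics with $A_2 = 0.4 A_1$ (a clear second harmonic is a
known feature of these responses); $\gamma = 1$; a dedicated band
component per clinical band ($\theta$ 4–8, $\alpha$ 8–13, $\beta$
13–30 Hz) whose power changes linearly over the four tasks by a
configurable slope — this is the hook that makes workload/fatigue trends
recoverable ground truth; log-normal inter-subject amplitude factors
($\sigma = 0.3$); paradigm gains ordered bimodal $>$ single-motion $>$
single-colour (1, 0.75, 0.6). The gains are calibrated only to *preserve
this ordering*; no absolute amplitudes are published for the paradigm, so
none are claimed.

Noise components are synthesised in the frequency domain with analytically
normalised variance, which gives every test a closed-form expectation
(`analytic_band_power()`, `analytic_trial_snr()`). Determinism is strict:
one master seed, per-trial seeds derived by a stable integer hash of the
(subject, block, brightness, task, trial) coordinates, and a private RNG
stream that leaves the caller's `.Random.seed` untouched.

What the generator does **not** emulate: ocular/muscle artifacts,
non-stationarity within a trial, volume-conduction correlations between
channels, latency jitter, or realistic response amplitudes. Passing tests
therefore demonstrate that the *analysis chain* is correct and sensitive,
not that it would achieve any particular accuracy on human EEG.

## Preprocessing

The acquisition chain is an 8th-order Butterworth band-pass (2–100 Hz)
plus a 4th-order 48–52 Hz notch; analysis presets add a 1–30 Hz band-pass
before trial averaging and a 4th-order 2–40 Hz band-pass before FFT
spectra. Filters are applied zero-phase (forward–backward), a choice the
package makes so that evoked-response latencies survive averaging.

Numerically, these designs are treacherous: at 1200 Hz the 2-Hz edge sits
at 0.3% of Nyquist, and an 8th-order band-pass expressed as a single
transfer function diverges in double precision. The package therefore
designs every filter analytically — Butterworth prototype poles, prewarped
band transform, bilinear transform — and applies it as a cascade of
second-order sections with odd edge extension, which is stable at any
order. Passband gain is exact (unit at the band centre, $-3$ dB at the
printed edges) and the 50-Hz attenuation of the notch exceeds 25 dB in
practice.

Epoching cuts $[t, t+5\,\mathrm{s})$ windows at event onsets, excluding
the 1-s cue and 1-s gray intervals by construction; overlapping events are
an error, epochs past the recording end are dropped with a warning. A
minimal EDF (16-bit) writer/reader supports the disk round trip, tested
against the half-quantisation-step error bound.

## Welch PSD and the harmonic SNR

`welch_psd()` uses 2-s Hann windows with 50% overlap (0.5 Hz resolution —
enough to separate 3 from 3.5 Hz) and one-sided density normalisation, so
the integral of the PSD equals the signal variance. The SNR statistic is
the decibel ratio of the summed power at the first $n = 4$ stimulus
harmonics to the remaining power in a 1–45 Hz analysis band (below the
powerline notch).

Two numerical details make this estimator unbiased across $-10\ldots+20$
dB rather than only at high SNR:

* a harmonic *bin reading* is converted from density to sinusoid power via
  the window's equivalent noise bandwidth, so a bin-centred sinusoid of
  amplitude $A$ reads exactly $A^2/2$ regardless of the window;
* the local noise floor (flanking bins) is subtracted from each harmonic
  reading (`correct_noise_floor = TRUE`), removing the positive bias that
  noise leaking into the harmonic bins would otherwise cause at low SNR.
  The raw bin-sum variant remains available and is used where the plain
  harmonic-sum definition is wanted, e.g. for cross-paradigm comparisons.

The absolute PSD scale is pinned only up to a convention; the SNR, a
ratio, is invariant to it. With 5-s trials, FFT amplitude spectra live on
a 0.2 Hz grid: 3 and 4 Hz (and all second harmonics 6–9 Hz) localise
exactly, while 3.5 and 4.5 Hz fall between bins and may localise one bin
off — an unavoidable discretisation, not an estimator error.

## Workload and fatigue

Cognitive load is tracked by the $\theta/\alpha$ bandpower ratio, fatigue
by $(\theta+\alpha)/\beta$, with the conventional band edges above (the
study names the ratios but not the edges). Powers are Welch-integrated per
trial, channel-averaged, then averaged within each subject × paradigm ×
task cell. A least-squares line over task index 1..4 summarises the trend,
and the *variation extent* is the percent relative difference of the
fitted values, $100\,(\hat r_4 - \hat r_1)/|\hat r_1|$.

Extents are computed on raw ratios; per-subject z-scored ratios are
attached separately for cross-subject comparison, because relative
differences of z-scores are ill-defined near zero (a baseline near zero
can inflate an extent arbitrarily — a guard reports such cases as
undefined rather than as a huge number). When validating drift recovery,
the injected truth must account for the 1/f background that also falls in
each band: the recoverable extent is the component drift diluted by the
background share, which `analytic_band_power()` supplies. Stimulus
harmonics land inside the $\theta$ band (e.g. 4.5 and 9 Hz), so drift
recovery experiments use a weak evoked response to keep the bandpower
trend uncontaminated; with realistic response amplitudes the extents
acquire a task-dependent bias of several points — a caveat that applies to
the real analysis as well.

## Frequency recognition

**CCA.** Segments are correlated against sine/cosine reference sets at
harmonics 1..4 of each candidate frequency (the same harmonic count as the
SNR, for consistency). Canonical correlations are computed from the
singular values of the whitened cross-covariance
$\Sigma_{xx}^{-1/2}\Sigma_{xy}\Sigma_{yy}^{-1/2}$ with a pseudo-inverse
whitening for near-singular covariances; tests verify agreement with both
`stats::cancor` and an explicit generalized-eigendecomposition oracle to
$10^{-8}$. Ties break toward the lowest frequency, with a message.

**Compact CNN.** The convolutional classifier follows the compact
EEG-network pattern: a temporal convolution whose kernel length is half
the sampling rate (600 taps at 1200 Hz — the rule is re-applied after any
decimation), a depthwise spatial convolution spanning all six channels, a
separable (depthwise-temporal + pointwise) stage, ELU activations, average
pooling, dropout 0.25, and a dense softmax over the four classes. No deep
learning framework is a package dependency: convolutions are im2col matrix
products with analytic backpropagation and Adam, in base R. Unstated
hyperparameters follow published compact-network practice (8 temporal
filters, depth multiplier 2, 16 separable filters, cross-entropy, early
stopping on the training loss); all are exposed in
`compact_cnn_spec()`. Training is bit-reproducible given the seed: weight
initialisation, shuffling and dropout masks draw from one seeded stream.
Batch normalisation is omitted; inputs are globally scaled instead, which
suffices at these problem sizes.

Evaluation uses per-subject stratified k-fold cross-validation over
trials. Because the 600-tap kernel at 1200 Hz is costly on a CPU, the
tensor may be decimated 4× (zero-phase anti-alias low-pass at 80% of the
new Nyquist, then subsampling) before training; decimation is off by
default and enabled explicitly where used.

**Segment-length sweeps** truncate trials to the requested lengths and
report per-subject mean accuracy; on fixed-SNR synthetic data the curve is
non-decreasing in length up to sampling noise, the matched-filter
property the sweep is designed to exhibit.

## Problem sizes used in validation

The validation suite and the acceptance script run the full study
*structure* at reduced scale, a deliberate choice to keep every experiment
a closed-loop computation: geometry and luminance checks render 512-px
canvases; SNR calibration uses 200 trials at the native 1200 Hz across
constructions from $-10$ to $+20$ dB; spectral-peak checks average 10
trials per frequency at 1200 Hz; drift-recovery experiments run 50
injected and 100 control replicates of four-task sessions at 300 Hz;
classifier checks use 300 Hz sessions with 40–192 trials per paradigm,
1–2 s segments, and the architecture rule applied at the decimated rate.
Chance-level assertions use binomial confidence intervals at the stated
test-set sizes. Session generation scales linearly, so the same code runs
the full 10-subject, 1200-Hz design unchanged when more compute is
available.

## Known limitations

* The generator's amplitudes, gains and drifts are plausibility
  calibrations, not fitted to human data; only orderings and injected
  parameters are meaningful recovery targets.
* The luminance model ignores display gamma and any interaction between
  $C_1$ and the transfer function of a particular device; on real hardware
  the constant-luminance property should be verified photometrically.
* The CNN is a faithful but compact re-implementation; it is not intended
  to reproduce published accuracy figures from human recordings, and its
  runtime on full-rate data is substantial without decimation.
* EDF support covers continuous 16-bit recordings written by this package
  (no annotations, no variable record layouts).
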