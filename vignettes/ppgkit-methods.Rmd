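---
title: "ppgkit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ppgkit: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgkit)
```

ppgkit is a hardware-free toolkit for photoplethysmography (PPG) research:
it simulates PPG recordings with known ground truth, extracts windowed
heart-rate (HR) and pulse-rate-variability (PRV) metrics, assesses signal
quality both classically (pSQI) and with a dense convolutional model, and
quantifies agreement between two devices measuring the same physiology.
This vignette explains the models behind each part, the tunable parameters
and their defaults, and the places where a design had to be pinned down.

## The beat-train generator

Successive inter-beat intervals (IBIs, ms) are drawn as

$$\mathrm{IBI}_k = \frac{60000}{\mathrm{HR}} + \varepsilon_k + J_k,
\qquad \varepsilon_k \sim \mathcal N(0, \sigma_j^2),$$

where $J_k$ is 0 except on "jump" beats (probability `jump_prob` per
beat), when it takes the value $\pm$`jump_magnitude` with the sign
*alternating between successive jump events*. Alternation matters: pNN50
counts successive differences exceeding 50 ms, and with alternating signs
`jump_prob = 1` with a 60 ms magnitude drives pNN50 to exactly 100%,
whereas independent random signs would leave same-sign runs with zero
difference. The per-beat jump probability maps to expected pNN50 as
$1-(1-p)^2$, since a difference exceeds the threshold iff either adjacent
beat jumped. Intervals are clamped to the plausible range 250–2000 ms,
matching the healthy-range screen applied on the analysis side.

## Waveform rendering

Each beat is rendered as two Gaussian bumps — a systolic peak and a
smaller dicrotic wave — plus a DC offset. Bump widths scale with the
interval (they are fractions of the IBI), but the two latencies are fixed
in seconds: the systolic peak sits 0.2 s after beat onset (capped at
0.35 IBI for short beats) and the dicrotic bump at most 0.25 s later.
Two rendering choices deserve justification:

* **Fixed systolic latency.** If the peak sat at a fixed *fraction* of the
  interval, detected peak-to-peak intervals would equal
  $\mathrm{IBI}_k + c\,\Delta\mathrm{IBI}_k$ — a first-difference
  distortion that systematically corrupts pNN50 (a 60 ms excursion can
  shrink to 30 ms between peaks and fall under the 50 ms threshold).
  Physiologically the pulse-arrival latency does not scale with cycle
  length, so the fixed-latency model is both the correct one and the one
  under which peak detection can recover PRV.
* **Capped dicrotic latency.** At 45 bpm a proportional dicrotic delay
  (0.25 × 1333 ms ≈ 333 ms) lands exactly at the detector's 330 ms
  refractory boundary and gets counted as a beat. The 0.25 s cap keeps
  the dicrotic wave inside the refractory span at every supported rate.

A two-Gaussian template (rather than an ODE-based pulse model) is
deliberate: it gives full analytic control over peak positions and
spectral content, which is what the ground-truth contracts need.

## Artifacts and ground-truth quality labels

Four artifact kinds are supported: `motion_burst` (correlated broadband
noise), `baseline_wander` (a 0.15–0.4 Hz sinusoid), `clipping`
(saturation at a level) and `flatline` (the signal holds its value).
Events are placed by a Poisson process with exponential durations; the
onset rate is $-\log(1-d)/m$ for duty cycle $d$ and mean event length
$m$, so the expected covered fraction of the recording equals $d$ exactly
(the coverage of an M/G/∞ queue is $1-e^{-\lambda m}$).

Quality labels live on a 0.5 s grid. A segment is labelled bad when
artifact events overlap more than half of it, except flatline and
clipping, which mark a segment bad on *any* overlap — even brief
saturation destroys the waveform, while a short motion tap inside an
otherwise clean half-second often leaves the beat usable. This rule is a
package design decision; human annotators of real recordings may have
drawn the line differently, and nothing in the pipeline depends on the
exact rule beyond the labels themselves. A trailing partial segment is
dropped rather than padded.

## Filtering, windowing, resampling

The analysis front end is a third-order Butterworth band-pass at
0.7–4.0 Hz. The band and order are standard for pulse extraction; the
family and phase handling had to be chosen, and ppgkit applies the filter
forward–backward (zero-phase) so that peak *times* are unbiased — the
"third order" refers to the one-directional design, and the effective
magnitude response of the bidirectional pass is its square (which is also
why the 8 Hz stopband attenuation comfortably exceeds 20 dB).

Windows follow a half-open convention: window $k$ covers
$[k\,s,\ k\,s + w)$ with 0-based sample indexing, only complete windows
are emitted, and a duration $T$ yields $\lfloor (T-w)/s\rfloor + 1$
windows. HR uses $w = 30$ s, $s = 10$ s; PRV (pNN50) uses $w = 120$ s,
$s = 10$ s — so one 180 s condition yields exactly 16 HR and 7 PRV
windows. Resampling (needed to feed the quality model a fixed-rate
input) is band-limited polyphase resampling with a small-denominator
rational rate approximation.

## Beat detection and windowed metrics

Beats are local maxima exceeding an adaptive prominence threshold — a
fraction (default 0.3) of the rolling 2 s signal amplitude above the
rolling minimum — thinned by a 330 ms refractory period (a 180 bpm cap)
in which the taller peak wins and the earlier wins an exact tie. Peak
times are refined to sub-sample precision by a parabolic fit around each
maximum: at 100 Hz a half-sample error is 5 ms per peak, enough to move a
60 ms successive difference across the 50 ms pNN50 boundary, and the
refinement removes that failure mode.

Windowed HR is defined as $60000/\overline{\mathrm{IBI}}$ over the
intervals whose second beat falls in the window — robust to partial beats
at window edges, unlike beat counting. pNN50 is the percentage of
successive differences *strictly* exceeding 50 ms; differences are only
formed between intervals adjacent in the beat sequence, so intervals
discarded by the healthy-range screen (outside 250–2000 ms) break the
chain instead of creating spurious large differences. Windows with fewer
than two usable intervals (HR) or differences (pNN50) report `NA`, never
zero.

## Signal quality: pSQI and the dense model

**pSQI** is the relative power signal quality index: 100 × (periodogram
power in 0.7–4.0 Hz) / (power in 0–10 Hz), computed on the mean-removed
segment. ppgkit uses a single full-length periodogram rather than an
averaged multi-segment estimate so that the value equals a direct FFT
band-power summation exactly; with the mean removed, a constant segment
has zero power and pSQI is defined as 0% (with a warning). The band
edges are package choices: the pulse band mirrors the analysis passband,
and 10 Hz covers the harmonics that motion spreads power into.

**The dense quality model** maps an 8 s segment, z-scored and resampled
to 64 Hz (512 samples), to 16 quality scores — one per 0.5 s — through a
1-D convolutional encoder–decoder: four stride-2 encoder blocks (widths
16/32/64/64, kernel 7), one stride-2 decoder stage (width 32) and a
final 1×1 convolution with sigmoid squashing, about 61k parameters.
Per-segment z-scoring makes the model gain- and offset-invariant, which
any cross-device quality model must be. Training minimises per-0.5 s
binary cross-entropy with Adam (batch 256, learning rate 3e-3, 40
epochs) under a subject-wise train/validation split — no subject
contributes segments to both sides, which is the split that actually
tests generalisation to new wearers.

The training corpus is synthetic: 24 subjects × 5 min at 64 Hz by
default, with per-subject physiology and artifact severities drawn once
per subject. Flatline events average 12 s — sensor dropouts in practice
last tens of seconds, and the long events ensure whole 8 s segments of
dropout occur in training, so the model learns that a constant segment
is bad rather than merely that flat-to-pulsatile *transitions* are bad.

What passing the synthetic benchmarks does and does not show: the
held-out accuracy (typically 0.93–0.95 at 0.5 s resolution) demonstrates
that the architecture, loss and training loop learn dense quality
inference on signals whose corruption processes are known exactly. It
does not certify performance on real recordings, whose artifacts are
richer (pulse-amplitude drift, perfusion changes, real motion spectra)
and whose labels come from human raters. The comparison against
segment-level pSQI thresholding on flatline/clipping corpora isolates
the one structural advantage that *does* transfer: an 8 s segment
containing a 2 s dropout is invisible to a segment-level index but is
localised by dense 0.5 s inference.

## The simulated validation study

`simulate_study()` emulates a four-condition within-subject protocol:
baseline (slow breathing: low HR, high variability), easy and difficult
mental arithmetic (rising HR, falling variability), and a movement
condition, 3 min each with 1 min rests, 15 subjects by default. Each
session yields a clean "reference" record and a "device" record with the
same ground-truth beat train plus condition-specific artifacts (severity
ordered baseline < easy math < difficult math < movement) and mild
sensor noise. Everything is deterministic per (subject, condition,
seed), with subject-level HR offsets and variability multipliers.

The agreement analysis mirrors a device-validation study: band-pass,
beat detection, windowed HR and pNN50 for both records, paired pSQI
gating at 40% (windows whose *reference* pSQI falls below threshold are
discarded from both series), pooling of gated windows across subjects
within condition, and RMSE / MAE / error SD / Pearson r plus
Bland–Altman bias and 1.96-SD limits per condition and combined. Three
choices were open and are pinned as follows:

* **Pooling level.** Windows are pooled across subjects within a
  condition before computing r (one value per condition), matching the
  usual presentation of validation tables; a per-subject breakdown is
  available from the returned pairs.
* **Gate grid.** The 40% gate is applied on each metric's own window
  grid (30 s windows for HR, 120 s for pNN50), since a single gate grid
  cannot align with both.
* **Conventions.** Sample (n−1) SD and sample Pearson correlation
  throughout; these must be pinned for the statistics to be verifiable
  against independent recomputation.

No multiple-testing correction is applied to the Wilcoxon comparisons;
reports are single planned contrasts. The Wilcoxon signed-rank
implementation drops zero differences, mid-ranks ties, enumerates the
exact distribution of the observed ranks for n ≤ 15 and uses a normal
approximation with continuity and tie corrections above.

The expected qualitative outcome — which the test suite verifies over
ten study replicates with a sign test — is the pattern seen in wearable
validation generally: pooled correlation for pNN50 falls below that for
HR (beat-time errors accumulate quadratically in successive differences
but average out in window means), and mean device pSQI in the movement
condition falls below baseline.

## Numerical choices and degenerate inputs

* Tolerances: agreement statistics are checked against naive
  recomputation at 1e-9; exact Wilcoxon p-values against full sign
  enumeration at 1e-12.
* Constant or empty signals: no beats, pSQI 0% with a warning, `NA`
  metrics — never fabricated zeros.
* Ties: equal-height peaks inside one refractory span keep the earliest;
  equal-quality channels keep the first in configured order.
* Seeds: every stochastic step (interval noise, event placement, weight
  initialisation, shuffling, splits) derives a bounded child seed from
  the caller's seed; identical seeds give bit-identical output, and the
  caller's RNG state is never disturbed.
* Problem sizes: the shipped tests train the quality model on 20
  subjects × 4 min and replicate the simulated study ten times at 15
  subjects — sizes chosen so the full pipeline, including training,
  demonstrates its contracts in a few minutes on one CPU while keeping
  every sample size large enough for the statistical checks involved.

## Known limitations

* The waveform model has no respiratory modulation, no pulse-amplitude
  variability and no sensor-specific noise spectra; EDA and respiration
  channels pass through the session format untouched but are not
  synthesised or analysed.
* The quality model's reported numbers are synthetic-corpus surrogates,
  not estimates of performance on human-labelled recordings.
* The reference record in the simulated study is perfectly clean, so the
  40% pSQI gate rarely fires there; in real paired recordings the gate
  is the mechanism that removes windows where *both* devices saw motion.
* The TCP synchronization helpers are thin, blocking, single-session
  transports around the protocol state machines; the state machines are
  fully tested over an in-process loopback, the socket layer is not.
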