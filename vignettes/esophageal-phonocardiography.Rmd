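---
title: "Methods: quantifying drug-induced heart-sound changes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying drug-induced heart-sound changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esopcg)
```

## The measurement problem

An esophageal stethoscope records the heart sounds throughout surgery.
The S1 component arises at atrioventricular-valve closure and grows with
ventricular contractility; S2 arises at aortic/pulmonic-valve closure and
responds to afterload. `esopcg` quantifies how a bolus of a vasoactive
drug changes these components: each drug event yields a pair of 20-s
windows (inner edges 120 s before and after the bolus), and each window
is reduced to S1/S2 amplitudes in dB, heart rate, total spectral power,
and — from the synchronized arterial line — SBP/DBP/MAP, dP/dtmax and
SVR. Groups of episodes per drug are then compared with paired
statistics.

This vignette documents the model, the tunable parameters, the numerical
choices, and what the synthetic-data verification does and does not show.

## Signal model and processing chain

**Band-pass (25–120 Hz, zero-phase).** Cutoffs are a design choice: the
dominant S1/S2 energy sits roughly between 20 and 150 Hz, and the band
must exclude baseline drift (respiration, probe motion, < a few Hz) and
high-frequency noise. A 4th-order Butterworth run forward-backward
(`signal::filtfilt`) gives zero phase distortion so envelope peak times
are not shifted. Both edges are user arguments.

**Hilbert envelope.** The instantaneous amplitude is the magnitude of the
analytic signal, `sqrt(x² + x̂²)`, with the Hilbert transform `x̂`
computed by the FFT method (negative frequencies zeroed, positive
doubled). For a tone `A·sin(2πft)` with `f` well inside the band the
envelope equals `A` except within a few samples of the window edges; this
is tested to 1% over the central 90%.

**Peak picking.** The envelope is smoothed with a 25-ms moving average
before local-maximum detection — wide enough to merge the intra-wavelet
ripple of a 50-Hz S1, narrow enough to keep S1 and S2 (≥ 150 ms apart at
physiologic rates) separate. Peaks must exceed `threshold_frac` (default
0.25) of the window's 98th-percentile envelope value — a robust proxy for
"the S1 peak scale" that ignores the top 2% of samples — and be separated
by `min_separation_s` (default 0.1 s); within one separation window the
larger peak wins, the earlier on ties. Because smoothing attenuates a
20-ms Gaussian lobe by about 6% (−0.55 dB), amplitudes are re-read from
the *unsmoothed* envelope near each detected location; this keeps the
dB-gain recovery contract (±0.5 percentage points) attainable.

**S1/S2 labeling.** With no ECG channel, labeling uses the timing rule
that systole (S1→S2) is shorter than diastole (S2→next S1). The RR
interval is estimated as the median of adjacent inter-peak gap sums
(which equals RR for alternating peaks regardless of phase), gaps are
split at RR/2, and peaks preceded by a long gap and followed by a short
one anchor the S1 lattice. S1s missed between anchors spaced ≈ k·RR are
recovered by matching the nearest peak to the predicted lattice time
(tolerance 0.2·RR); this is what lets a spurious mid-diastolic peak —
whose two flanking gaps both look "short" — fall into `unpaired_peaks`
without stealing a true beat. If the systole and diastole medians differ
by less than 10% the rhythm is declared ambiguous and the window is
rejected rather than mislabeled.

**Metrics.** S1/S2 amplitude is `20·log10(mean per-beat envelope peak /
db_ref)`; `db_ref` defaults to 1 signal unit. Absolute dB values depend
on amplifier gain and probe depth and are not comparable across setups —
only relative (percentage) changes are contracted, and those are computed
on the dB scale, the scale on which clinical percentage changes of
phonocardiographic amplitude are internally consistent. Heart rate is
`60 / median(S1→S1 interval)`, robust to a single missed beat. Total
power is `10·log10( Σ|FFT(w·x)|² / (N·Σw²) / power_ref )` with a Hamming
window; the normalization makes the rectangular-window case equal the
time-domain mean square exactly (Parseval), which is the oracle used in
tests. `power_ref` defaults to 1e-3 squared units (a dBm-style
convention); absolute power values are again setup-dependent and only
relative changes are meaningful.

**Arterial channel.** Beats are delimited minima-to-minima with the same
peak detector (0.3-s separation); per-beat maxima, minima and time
averages give SBP, DBP and MAP. dP/dtmax is the per-beat maximum of the
first difference of the pressure after a 4-ms moving average, averaged
across beats. The 4-ms width is a deliberate choice: a boxcar of width D
attenuates the peak slope of a half-cosine upstroke of duration Tu by
`sin(πD/(2Tu))/(πD/(2Tu))`, so at 10 ms the attenuation differs enough
between, say, Tu = 0.15 s and Tu = 0.10 s to bias a pre/post dP/dt ratio
by ~0.5 percentage points; at 4 ms the bias is below 0.1. SVR uses the
standard clinical identity `80·(MAP − CVP)/CO`; CVP and CO are always
supplied (CVP has no default, to avoid a silently biased resistance), and
whether the study-style dP/dt should be a per-beat mean or a window
maximum is unspecified in clinical practice — the per-beat mean is used
here as the lower-variance choice.

## Statistics

Per variable and drug group, differences (post − pre) are tested for
normality (Shapiro–Wilk at 0.05); the paired *t* test is used when
normality is not rejected, the Wilcoxon signed-rank otherwise. With n = 2
the gate cannot run and the paired *t* is used; with zero-variance
differences the comparison is flagged degenerate with p = 1 by
convention. No multiple-testing correction is applied — each variable's
raw p value is reported, matching how such monitoring studies present
per-variable tables. Percentage changes are summarized as median (25th;
75th percentile, linear interpolation). Correlations between
percentage-change series are Pearson r² with the exact t-transform p
value. Episodes are treated as independent; repeated episodes from one
patient are not modeled hierarchically (a wash-out between boluses is
assumed, as in the clinical protocol this mirrors).

## The synthetic-data generator

The generator exists so every stage is verifiable by parameter recovery.
Its defaults are the study conditions of the clinical setting it
emulates.

* **Heart sounds**: each beat contributes an S1 wavelet
  (Gaussian-windowed cosine, 50 Hz carrier, 20 ms half-width) at cycle
  onset and an S2 wavelet (60 Hz, 15 ms) at onset + `systole_fraction`·RR
  (default 0.35). These carrier/width values are conventions from the
  known frequency content of heart sounds, not reproductions of any
  particular recording, and are configurable. Beats lie on a lattice of
  RR intervals with optional i.i.d. Gaussian jitter (CV parameter); only
  complete cycles are emitted, so the S1 count is `floor(duration/RR)` at
  zero jitter. Noise is additive white Gaussian with configurable SD.
* **Arterial pulse**: half-cosine upstroke from DBP to SBP over
  `upstroke_time_s` (so dP/dtmax = π·PP/(2·Tu) in closed form), then an
  exponential decay normalized to reach DBP exactly at cycle end
  (time constant one third of diastole) with a small Gaussian dicrotic
  bump (3% of pulse pressure, 20 ms wide, a quarter into diastole). The
  template mean is available in closed form (`arterial_template_map`).
* **Drug effects** are applied as: dB-scale percentage gains on S1/S2
  amplitudes (post dB = (1 + gain/100) × pre dB); additive HR and
  SBP/DBP shifts; an upstroke-time rescaling that embodies the target
  dP/dt change after accounting for any pulse-pressure change; and a
  cardiac-output adjustment that moves `80·(MAP − CVP)/CO` by exactly the
  target SVR percentage. Covariate (TDI S', dP/dt) post values are set so
  their percentage changes equal the ground truth; across episodes,
  `sample_covariate_pairs` draws (sound %Δ, covariate %Δ) pairs from a
  bivariate Gaussian with configurable population r² (positive root, as
  contractility covariates co-move with S1) and marginal SDs defaulting
  to 5 and 8 percentage points — the scale of between-episode spread seen
  clinically.
* **Batches** (`simulate_drug_batch`) encode four preset drug conditions
  — ephedrine (S1 +12.7%, dP/dt +45.7%, SVR +30.9%, n = 9), esmolol
  (S1 −15.3%, n = 11), phenylephrine (S2 +5.5%, SVR +13.3%, n = 7) and
  nicardipine (S2 −14.2%, SVR −43.5%, n = 2) — with mild between-episode
  baseline variation (HR SD 4 bpm, amplitude SD 1 dB, pressure level SD
  4 mmHg, upstroke SD 10 ms). The nicardipine baseline, for which no
  group statistics exist, uses its representative tracing
  (166/86 mmHg) with typical amplitudes.

**What passing recovery tests shows — and does not.** Recovery within
±0.5 percentage points on noiseless episodes shows the chain is
unbiased and internally consistent: filtering, envelope extraction,
labeling and the dB arithmetic neither attenuate nor leak effects
between S1 and S2 channels. It does not validate performance on clinical
signals, whose noise is not white or Gaussian (electrocautery, probe
motion, lung sounds), whose S1/S2 morphology varies beat to beat, and
which contain murmurs, splitting and arrhythmia that the generator
deliberately omits. Robustness is probed only lightly (labeling ≥ 95%
correct at 20 dB SNR); a clinical validation needs real recordings.

## Numerical and interface choices

* Windows are cut with inner edges 120 s from the event ("two minutes
  before and after" read as edge-anchored, configurable), half-open
  `[start, end)` in 0-based samples, so a window is always exactly
  `length_s × fs` samples with no floating-point drift.
* Records travel as WAV (IEEE float64 by default, so analysis traces
  round-trip bit-identically; float32 and PCM16 are also read) or CSV
  with a strictly increasing, uniform `time_s` column; covariates and
  event manifests are CSV tables; `run_pipeline` writes metrics and
  summary CSV/Markdown plus a JSON run log of every parameter and seed.
  The log carries no timestamps, so identical configs give byte-identical
  outputs.
* Per-event failures (too few beats, ambiguous rhythm, malformed files)
  are caught, reported per event, and do not abort the batch.
* Simulation sizes used in the package's own verification are modest by
  design — 20-s windows at 1000 Hz, group sizes 2–11 as in the clinical
  groups, 10⁵ draws for correlation convergence, 1000 replicates for the
  type-I-error property — chosen as the smallest sizes at which the
  contracted tolerances are meaningful.

## Known limitations

* No ECG-gated segmentation: at systole/diastole ratios within 10% the
  labeler refuses rather than guesses, so tachycardic rhythms with long
  systolic fractions are out of reach.
* Absolute dB amplitudes and total power depend on amplifier gain and
  probe depth; only relative changes are contracted anywhere in the
  package.
* No murmur/S3/S4/split-S2 modeling, no denoising beyond the band-pass,
  no pulse-contour cardiac output (CO is always an input), and no
  mixed-effects handling of repeated episodes per patient.
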