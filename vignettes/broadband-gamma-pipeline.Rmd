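---
title: "Broadband gamma analysis of stereo-EEG: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Broadband gamma analysis of stereo-EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seegamma)
```

## The analysis problem

Stereo-electroencephalography (sEEG) records intracranial field potentials
from depth electrodes implanted along stereotactic trajectories. The
broadband gamma amplitude (BGA) — the analytic amplitude of the 70–150 Hz
band — is the field's standard proxy for local population firing. The
scientific questions this pipeline serves are event-locked: how strongly,
and when, does each cortical site increase its gamma amplitude around a
behavioral event (a visual stimulus, the onset of audible speech), and how
do those responses aggregate across sparsely and heterogeneously sampled
patients into a population-level cortical map?

`seegamma` implements that pipeline end to end — preprocessing, envelope
extraction, epoch statistics, surface-based mixed-effects multilevel
population maps (sb-MEMA) with Monte-Carlo cluster-extent family-wise
error correction, and band-limited pair correlations — together with a
synthetic sEEG generator with known ground truth, so that every stage is
testable without patient data.

## Signal model and envelope extraction

Each channel is modeled, and synthesized, as

* a 1/f-shaped Gaussian background (power spectral density proportional to
  `f^-a`, default exponent `a = 1`),
* line noise at 60 Hz and its harmonics (harmonic k at amplitude
  `line_amp_uv / k`),
* and, in task-responsive regions, a trial-locked multiplicative increase
  of the 70–150 Hz component.

The BGA is extracted with a frequency-domain bandpass Hilbert transform:
the FFT of the signal, with negative frequencies zeroed and positive
frequencies doubled (the analytic-signal construction), is multiplied by
paired logistic ("sigmoid") flanks with half-width 1.5 Hz —
`w(f) = sigma((f - 70)/1.5) * sigma((150 - f)/1.5)` — and inverted; the
magnitude of the result is the instantaneous envelope. The FFT length is
the signal length (no padding) and the flank width is fixed in Hz, so
spectral resolution never depends on the recording duration. The envelope
is then smoothed with a third-order Savitzky-Golay FIR filter over a
151 ms frame (at 2 kHz: 302 samples, rounded down to the nearest odd
count, 301). Half a frame at each end of a smoothed trace is
edge-contaminated; `edge_samples()` reports how much, and statistics
windows should not touch it.

Line noise is removed beforehand with zero-phase (forward–backward)
second-order Butterworth band-stops, default half-width 2 Hz around each
harmonic. The 120 Hz stop band sits inside the gamma band; it removes
roughly 5% of the band's width, a bias that is identical in the baseline
and the response window and therefore cancels in percent change.
Referencing is to the common average of all retained channels (the
channel itself included; the operation is idempotent).

## The synthetic generator and what it calibrates

The generator's central design choice: instead of adding a separate gamma
"carrier" on top of the background, the 70–150 Hz component of the 1/f
background is split out exactly (an FFT soft mask whose two parts sum to
the input) and multiplied, on each trial, by `1 + A/100` with 50 ms
raised-cosine onset and offset ramps. Two properties follow *by
construction* rather than by tuning:

1. a resting channel has an exactly 1/f spectrum (the decomposition is
   lossless), and
2. the injected amplitude `A` equals the expected baseline-normalized
   percent change of the gamma envelope, because the multiplicative gain
   scales the band's envelope linearly.

Property 2 closes the calibration loop with the spectral module: an
injected 50% effect must come back as 50% ± 5% (absolute) through notch →
Hilbert envelope → Savitzky-Golay → epoching → percent change, at 200
trials. The residual deviation (~1%) comes from the smoothing of the
effect's onset ramp into the measurement window.

The carrier is broadband noise with random phase across trials, so evoked
(phase-locked) and induced (amplitude) measures dissociate: the ERP of
phase-random gamma bursts is flat. Behavioral timing uses truncated-normal
response times (floor 200 ms; reading 978 ± 221 ms, naming 1192 ± 245 ms)
with a 3000 ms inter-stimulus interval; listening tasks carry no speech
onset, and epochs must then be stimulus-aligned. Optional inter-ictal-like
spike artifacts (biphasic, derivative-of-Gaussian, ~60 ms) exercise trial
rejection.

What the generator does *not* emulate: volume conduction between channels
(other than the shared line noise), biophysical forward models, spatially
correlated background activity, non-stationary artifacts beyond spikes,
or realistic cortical folding — the "cortex" is an icosphere of ~40 mm
extent (20 mm radius) with a contiguous breadth-first parcellation.
Passing tests therefore demonstrate the *statistical machinery* under a
known, idealized data-generating process, not robustness to every
pathology of clinical recordings.

## Epoching and statistics

Windows are half-open in samples: a window of L ms at sampling rate `fs`
contains exactly `round(L * fs / 1000)` samples, and alignment is to the
nearest sample. The baseline (−500 to −100 ms) is defined relative to
*stimulus* onset even when responses are analyzed speech-aligned, so the
pipeline carries both alignments per trial; the baseline mean is pooled
across trials per channel.

Group time courses use two-stage (hierarchical) averaging — electrodes
within subject, then across subjects — so densely implanted patients do
not dominate. Per-timepoint activation is a one-tailed (above-zero)
one-sample t-test across subject means, corrected over timepoints by
Benjamini–Hochberg FDR at q = 0.05. Electrode-level window statistics use
the z-score of the window mean against the distribution of per-trial
baseline means; note that this z is an effect size in baseline-SD units,
not a calibrated test statistic — under the null its spread is
`sqrt(2 / n_trials)`, so the attached two-tailed normal p-values are
conservative. Paired condition contrasts use the Wilcoxon signed-rank
test: zeros dropped, exact distribution for up to 25 non-zero pairs, and
exact sign-flip enumeration on average ranks when magnitudes tie at
n ≤ 12 (where the stock implementation would silently fall back to the
normal approximation).

## Surface maps: sb-MEMA, smoothing, cluster correction

Electrodes are indexed to the nearest vertex of the shared mesh; a vertex
then collects, per subject, every electrode whose node lies within a
10 mm geodesic *assignment radius* (sparse sampling would otherwise leave
almost no vertex with two subjects). The subject-vertex effect is the mean
of the pooled per-trial window means and its variance the squared
standard error of that mean — electrodes within a subject are a fixed
effect, mirroring the hierarchical averaging rule.

Per vertex, the group effect is a two-level random-effects meta-analysis:
inverse-variance weights `1 / (v_i + tau^2)` with the between-subject
variance `tau^2` estimated by REML (DerSimonian–Laird on
non-convergence), `t = effect / SE` on `n - 1` degrees of freedom. Two
exact reductions anchor the implementation: with `tau^2 = 0` it is the
fixed-effect inverse-variance mean, and with all within-subject variances
zero it is the one-sample t-test on the subject estimates. The REML
estimate agrees with `metafor::rma(method = "REML")` to numerical
precision, and a 500-replicate simulation at mu = 30%, tau = 10%, n = 12
recovers the mean within ±1.5% with 95% CI coverage within 0.95 ± 0.03
(plain Wald-t intervals; the slight anticonservatism of random-effects
Wald intervals at n = 12 stays inside that band).

Geodesic distances are Dijkstra shortest paths over the mesh edge graph —
an upper bound on the exact polyhedral geodesic with error bounded by the
edge length, adequate at the mesh resolutions used here. The smoothing
kernel is `exp(-d^2 / 2 sigma^2)` with `sigma = FWHM / 2.355`, truncated
at 4 sigma and row-normalized, so constant fields are fixed points; row
normalization makes the operator slightly asymmetric, so the global mean
is preserved only approximately (tested as a bound, not an equality).
Unobserved vertices (NA) receive estimates from observed neighbors and
contribute no weight.

Cluster-extent correction follows the white-noise Monte-Carlo recipe:
simulate vertex-wise white noise, smooth it with the same kernel as the
data, standardize, threshold at the vertex alpha (two-sided), record the
largest connected supra-threshold cluster; the minimum significant extent
is one more than the `(1 - alpha_FWER)` quantile of that null maximum, so
`P(max null cluster >= threshold) <= alpha_FWER`. Static maps use
corrected p < 0.01, an absolute group-effect floor of 10%, and coverage of
at least 3 patients within a 10 mm geodesic recording zone; sliding-window
"movie" maps (150 ms width, 10 ms step) use uncorrected p < 0.01 and a 15%
floor. The effect floors apply to the (smoothed) group effect, not to any
single subject's estimate. Map recovery is scored by Dice overlap against
the ground-truth region *within the coverage mask* — cortex no patient
sampled is excluded from both sides of the comparison, exactly as
population maps black out uncovered regions.

## Pair correlations

Band-limited voltage (the zero-phase filtered signal, not its envelope)
is correlated between electrode pairs at lags up to ±100 ms in 1-sample
steps, per trial window, and averaged across trials through Fisher's z.
An instantaneously mixed (volume-conducted) pair peaks at 0 ms lag; a
genuinely lagged coupling peaks at its delay, recovered exactly at the
sample resolution. Group inference takes one summary correlation per
subject (the closest cross-region pair, Euclidean distance) and tests the
Fisher-z values against zero with the signed-rank machinery.

## Problem sizes and numerical choices

The test and acceptance runs use: an icosphere at subdivision 2
(162 vertices, ~5.5 mm edges, 4 regions); 12 patients x 4 probes x 6
contacts at 3.5 mm pitch for map recovery; 500 Hz synthesis for
multi-channel studies (the band edge at 150 Hz is comfortably below the
250 Hz Nyquist) and 2 kHz where timing precision matters; 200 trials for
envelope calibration; 500 Monte-Carlo iterations and 200 validation maps
for error-rate checks; 20 seeded two-task studies (6 subjects, 15 trials
per task) for the regional dissociation. These sizes were chosen as the
smallest at which the targeted effects are comfortably identifiable —
coverage and cluster geometry stop being degenerate, and Monte-Carlo
standard errors are small relative to the tolerances — while a full run
stays desk-scale. Recordings are padded to 5-smooth lengths so FFTs never
hit large prime sizes.

Degenerate inputs are handled explicitly rather than by crashing:
all-zero data in window z-scores (z = 0, flagged), all-tied Wilcoxon
contrasts (p = 1, warning), single-subject vertices (estimate kept, test
undefined), zero within-subject variances with unequal estimates (all
dispersion moves to `tau^2`), disconnected mesh components (smoothed
independently), and nearest-node ties (lowest vertex index).

## Known limitations

* The exact estimator of the original sb-MEMA implementation (including
  its outlier down-weighting) is not published in equation form; this
  package commits to standard REML random-effects meta-analysis and
  treats the t-test reduction and parameter-recovery simulations as the
  contract.
* Geodesic distances are graph distances; at very coarse meshes the 3 mm
  FWHM kernel degenerates toward the identity.
* The electrode-level window z is an effect size; its p-values are
  conservative by construction (see above).
* EDF I/O is 16-bit quantized by format; lossless round trips use RDS.
  Surface I/O is FreeSurfer binary + label TSV; vertex coordinates are
  stored as float32.
* Mesh vertex and face indices are 1-based throughout, as is idiomatic
  in R.
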