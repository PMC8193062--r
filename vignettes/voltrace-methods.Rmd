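---
title: "voltrace: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{voltrace: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

voltrace analyses high-speed fluorescence voltage-imaging movies of cultured
neurons labelled with a fast, brightness-increasing voltage dye, and ships a
movie generator with complete ground truth so that every stage can be
validated by parameter recovery. This vignette explains the models and the
design decisions; the README shows a worked example.

## The measurement model

A camera frame at time $t$ is modelled per pixel $p$ as

$$
C_p(t) \sim \mathrm{Poisson}\!\left(B\,\sum_n w_{pn}\,
\bigl(1 + s_n(t)/100\bigr)\, e^{-t/\tau_b} + b\right),
$$

where $B$ is the baseline brightness of a soma (counts at the footprint
peak), $w_{pn} \in [0,1]$ the spatial footprint of neuron $n$, $s_n(t)$ its
percent dF/F0 signal, $\tau_b$ an optional photobleaching constant and $b$
a uniform background. Counts are clipped to 16 bits. The dF/F0 signal is a
sum of action-potential kernels, one per spike, plus slow plateau
depolarizations:

* **AP kernel.** A two-sided Gaussian pulse: rising half-width at half
  maximum equal to 25% of the FWHM, falling 75%, so the total FWHM is exact
  by construction and the pulse is asymmetric the way real optical APs are
  (fast rise, slower decay). A symmetric Gaussian variant exists because
  its FWHM has the closed form $2\sqrt{2\ln 2}\,\sigma$, which anchors the
  analytic tests. Default amplitude is 10% dF/F0 per AP; neither the
  per-AP amplitude nor absolute camera counts are published for this dye
  and setup, so both are stated placeholders calibrated by signal-to-noise:
  with $B = 20\,000$, $b = 200$, a ~13-pixel soma mask gives per-frame
  trace noise of roughly 0.3%, i.e. a single-AP SNR around 30. These
  defaults were fixed from shot-noise arithmetic before any recovery
  testing and are not tuned per experiment.
* **Plateaus.** Flat-topped elevations (default 3% dF/F0, 1 s, 0.5/min)
  with 100-ms raised-cosine edges. An instantaneous step would carry
  broadband energy and register in a spike detector; real plateau onsets
  take tens of milliseconds.
* **Footprints.** Flat-top discs with a raised-cosine rim (soma radius 6 px
  at full scale, scaled with the field of view and floored at 2 px):
  somas are filled, softly bounded discs, and the half-maximum level set of
  such a profile tracks its support, which is what makes mask-level
  recovery comparisons meaningful.
* **Spike trains.** Homogeneous Poisson thinned by an absolute refractory
  period (5 ms); a bursting variant (Poisson burst onsets, 4–8 spikes per
  burst at 50–200 ms intervals, plus isolated spikes); and a synchronized
  variant where burst onsets are shared across the population with
  per-neuron jitter (20 ms SD) and 80% participation, emulating network
  bursts.

All randomness derives from one master seed through fixed sub-streams (one
per neuron, one for placement, one for shot noise), so a movie is
bit-reproducible and adding a neuron does not perturb the others.

### Cohort presets

Four presets parameterise the generator from published cohort statistics of
spontaneously active neuronal cultures: `WT4` (24 neurons at 1.03 Hz, AP
FWHM 14.8 ms), `WT83` (41 neurons, 0.23 Hz, 12.2 ms), `WT156` (36 neurons,
bursting, 12.3 ms) and `primary` (27 neurons, synchronized bursting,
heterogeneous per-neuron FWHM with cohort mean 10.1 ms and scale 7.14 ms).
Two choices deserve comment:

* Presets apply the cohort-mean firing rate to every neuron. The published
  cohorts scatter widely across neurons (e.g. SD 0.50 Hz around 1.03 Hz),
  but simulating that scatter would make the *cohort mean itself* fluctuate
  by several percent from seed to seed — recovery tests would then measure
  sampling noise of the generator, not fidelity of the analysis. Per-neuron
  rate distributions remain available through `sim_config()`.
* The heterogeneous FWHM preset draws from a normal truncated below at
  2 ms whose location parameter is calibrated (by root finding) so the
  *truncated* distribution's mean is exactly 10.1 ms, and it draws by
  stratified quantiles (one draw per equal-probability stratum, shuffled).
  Naive truncation at 2 ms of a normal centred at 10.1 would shift the mean
  to ~11.8 ms; i.i.d. draws of 27 values with SD ~5 ms would leave the
  realised cohort mean with an SE of ~1 ms. Both would confound a 10%
  recovery check for reasons unrelated to the pipeline.

## The analysis pipeline

`run_pipeline()` chains the stages below; each is exported on its own.

**Denoising.** `spatiotemporal_filter()` applies an isotropic spatial
Gaussian (default sigma 1 px, reflecting boundaries, constant-preserving)
and a centred temporal moving average (default 3 frames). The pipeline
exploits the linearity of both: segmentation runs on a spatially smoothed,
3-frame-binned copy of the stack; spike detection smooths the *extracted
trace* (exactly equivalent to temporal movie smoothing, since weighted
pixel sums commute with frame averages); waveform metrics use the
unsmoothed trace, because a 6-ms boxcar widens a 10-ms AP by about 7%,
which would dominate the error budget of duration estimates.

**dF/F0.** `compute_dff()` uses a sliding 20th-percentile baseline in a
10-s window (evaluated on a 1-s knot grid and interpolated; the first and
last half-window clamp to the nearest full window). A low percentile is
robust against sparse positive spikes inflating the baseline; with shot
noise it sits a fraction of a percent below the true baseline, a constant
offset that cancels in everything downstream (detection is SD-relative,
FWHM is offset-invariant). Global mean/percentile variants exist for short
synthetic segments. `detrend_bleach()` (off by default — shuttered
acquisition shows virtually no bleaching) divides out a Levenberg-Marquardt
monoexponential-plus-offset fit.

**Segmentation.** Pixelwise-centred PCA retains 3 components per expected
neuron (capped at 60, a subspace comfortably holding signal at these
densities without fitting noise); spatio-temporal ICA concatenates each
retained component's spatial eigenimage (weight $\mu = 0.5$) with its
unit-normalised temporal factor and estimates a *square* FastICA rotation
(tanh contrast, symmetric decorrelation) of the whitened component space.
The rotation is square on purpose: after per-factor normalisation the
component variances are nearly equal, so any variance-ranked truncation
inside the whitening would discard sources at random. The `n_ics` most
spatially skewed components are returned, sign-fixed so temporal skewness
is nonnegative (optical spikes are positive-going). ICs with temporal
skewness below 0.2 are discarded as noise — spiking traces are strongly
right-skewed, noise traces are not. Masks are the largest connected
component of the filter at half its maximum; traces are filter-weighted
mask means. Temporal binning (3 frames) for the segmentation copy
approximately matches the AP width and triples the per-sample spike
variance against shot noise, which is what pushes the source eigenvalues
clear of the Marchenko–Pastur noise edge at the small scaled field of view.

**Spike detection.** The nonlinear energy operator
$\psi(t) = s(t)^2 - s(t-1)\,s(t+1)$ is computed exactly on the interior
samples. Candidates are leftmost local maxima of $\psi$ at or above 3
standard deviations of the NEO signal — the SD taken about zero over the
full epoch, since $\psi$ of noise is near-zero-mean — with the spike frame
relocated to the dF/F0 maximum within ±2 frames. A hard minimum
inter-spike interval of 20 ms is enforced greedily in descending NEO
score, which resolves double-crossings of one AP deterministically in
favour of the stronger detection. Two conditioning options precede the
operator: the 3-frame smoothing above, and subtraction of an ~80-ms
running-median slow envelope. The latter matters because the NEO is not
offset-invariant: on a plateau of amplitude $b$ the operator acquires a
term $b\,(2s_t - s_{t-1} - s_{t+1})$ that amplifies noise roughly
$2b/\sigma$-fold and seeds spurious detections precisely where APs ride on
plateaus. The running median is an order of magnitude wider than an AP, so
spike amplitude and timing are untouched.

**Waveforms.** 300-ms segments centred on each spike's sample peak
(segments nearer than half a window to an edge are excluded and counted;
alignment is integer-shift only, no resampling). The local baseline is the
median of the first and last 50 ms of the segment; amplitude, 10–90% rise,
90–10% decay and FWHM use linearly interpolated level crossings, giving
sub-frame resolution. Windows overlapping a neighbouring detection are
flagged but retained — per-spike statistics are computed on all valid
segments by default, and flags allow exclusion. Truncated waveforms
(a flank that never crosses half maximum) are flagged invalid, never
extrapolated.

**Events and statistics.** A burst is any run of ≥ 4 APs whose mean
inter-spike interval is below 250 ms. The detector emits, scanning left to
right, the longest qualifying window at the earliest possible start, then
continues after it; this declarative rule (verified against exhaustive
enumeration) is preferred over prefix-greedy extension, which misses runs
whose early gap is amortised later. Remaining spikes are gap-clustered at
the same 250-ms bound into singlets/doublets/triplets — one partition rule
for the whole taxonomy. Plateau detection (procedure unspecified in the
source literature, so defined here) runs a despiking median filter, a
zero-phase 5-Hz Butterworth low-pass, and thresholds at 3 robust SDs of
the slow signal for at least 200 ms. "Instantaneous firing rate" is
operationalised as spike count over recording duration — the mean of
1/ISI diverges for Poisson-like trains and makes recovery checks
ill-posed. Bursting rate is reported per minute; inter-burst intervals are
onset-to-onset; burst duration is first-to-last spike. Group comparison is
the unpaired two-tailed pooled-variance Student's t (Welch by flag), with
conventional significance tiers and no multiple-testing correction, and
`score_detection()` gives precision/recall/F1 under greedy one-to-one
nearest-neighbour matching within ±6 ms (3 frames at 500 Hz).

## Problem sizes and what the tests show

Recovery tests run the presets at linear field-of-view scale 0.25
(50 × 38 px, soma radius 2 px) for the full 180 s at 500 Hz — 24, 41 and
27 neurons for `WT4`, `WT83` and `primary`. These sizes keep a full
pipeline run at roughly two minutes and a few gigabytes while preserving
every temporal property (rates, ISIs, durations) and the per-mask
photon budget of the full-scale configuration. On these conditions the
pipeline recovers all planted neurons, detects spikes with F1 ≈ 0.99
(≥ 0.95 required), and reproduces cohort firing rates within 2 SE and
cohort AP durations within a few percent.

The generator emulates: disjoint or controllably overlapping somas,
shot-noise-limited counts, slow plateaus, photobleaching, undersampled
(< 2-frame) APs, network bursts. It does not emulate: motion, illumination
inhomogeneity and optical sectioning, neuropil/background contamination,
dye internalisation dynamics, or correlated camera noise. Passing recovery
tests therefore demonstrate correctness of the analysis under the stated
measurement model, not robustness to those real-world artifacts; on real
recordings the segmentation and plateau stages are the ones most exposed
to them.

## Numerical details worth knowing

* Movies are integer arrays; all heavy linear algebra happens on
  chunked or binned copies so peak memory stays near the raw stack size.
* PCA forms the covariance on whichever side (pixels or frames) is
  smaller; eigenvalues are clipped at zero before variance fractions.
* FastICA starts from a seeded random orthogonal matrix; symmetric
  decorrelation uses an SVD; non-convergence returns the best iterate
  with a warning flag rather than failing a run.
* NEO thresholding handles the degenerate constant trace (SD 0) by
  returning zero candidates, not an error; detection at trace edges is
  impossible by construction (the first/last sample carry no NEO value).
* Half-max crossings and 10/90% levels are linear interpolations between
  the two bracketing samples; plateau-shaped NEO peaks take their leftmost
  sample; equal-score ISI conflicts resolve by earlier time.
* The t statistic with zero pooled variance: p = 1 for equal means, and
  the p → 0 limit is flagged `degenerate` for unequal means.

## Known limitations

* ICA assumes sources are (spatio-temporally) independent; fully
  synchronous, overlapping neurons can merge. The spatial weight
  ($\mu = 0.5$) keeps disjoint somas separable even under synchronized
  bursting, but heavily overlapping footprints degrade gracefully rather
  than perfectly.
* At 500 Hz an AP of FWHM ≤ 2 frames is undersampled; its measured
  duration is biased upward by interpolation. The generator warns when a
  configuration requests this regime.
* The sliding-percentile baseline assumes activity is sparse within any
  10-s window; pathological tonic firing (duty cycle ≫ 20%) would bias
  F0 upward.
* `read_movie()` expects grayscale multi-page TIFF with a JSON sidecar for
  metadata; other container formats are out of scope.
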