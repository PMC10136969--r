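---
title: "Error-processing EEG and post-error behavior: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Error-processing EEG and post-error behavior: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

When a person commits an error in a speeded go/no-go task, two families of
signals follow. Behaviorally, the next response tends to be slower
(post-error slowing, PES) and, under adaptive accounts, more accurate
(post-error accuracy, PEA). Neurally, the error-related negativity (ERN) — a
fronto-central, response-locked negative deflection peaking within ~100 ms of
the button press — and an induced increase in frontal midline theta power
(4–7 Hz) index the engagement of performance monitoring. `gonogoeeg`
implements the complete analysis chain that links these levels within
subjects: behavioral adjustment measures with regression-to-the-mean
controls, response-locked ERP and Hilbert-filter-bank ERSP preprocessing for
a 14-channel, 128 Hz montage, and a nonparametric inferential layer. A
fully parameterized synthetic cohort generator makes every stage testable
without any recordings.

# The task and behavioral measures

Trials are 1200 ms onset-to-onset (400 ms stimulus, 800 ms fixation cross),
90 per block, with P(go) = 0.7. Responses to go stimuli are hits; responses
to no-go stimuli are false alarms (commission errors). All RT measures use
only responded trials.

* **PES / PCS** are single-trial: next-trial RT minus current-trial RT,
  where the current trial is a false alarm (PES) or a hit (PCS). "Next"
  means the immediate successor *within the same block*; blocks are
  separated in time, so cross-block pairs are excluded. Successors of any
  stimulus class are eligible; a configuration switch
  (`successors = "hit"`) restricts the slowing averages to hit successors,
  because the measure definitions do not settle this and both readings are
  defensible.
* **Matched PCS** controls for regression toward the mean: error responses
  are fast, and fast responses are followed by slower ones for purely
  statistical reasons. In each of 20 repeats, post-correct pairs are
  RT-matched to the post-error pairs (nearest current-trial RT, without
  replacement, ties broken uniformly at random; the visiting order of the
  post-error pairs is randomized per repeat because a without-replacement
  greedy match is order-dependent and no canonical order exists). The
  control value is the mean of the 20 repeat means. If the post-correct
  pool is smaller than the post-error set the matcher falls back to
  sampling with replacement and flags the result.
* **PEA / PCA** are the percentage of *responded* successors that are hits;
  omitted successors do not enter the denominator. Matched PCA applies the
  same 20-repeat matching machinery to pair selection.
* **RSI** (response–stimulus interval) is derived from design timing:
  `soa − RT`, exactly, rather than from hardware timestamps.
* **Tertile splits** cut the rank-ordered values at ranks `⌈n/3⌉` and
  `⌈2n/3⌉`; ties keep their original order (stable sort), so sizes differ
  by at most one.
* **Inclusion**: analyses require at least 7 artifact-free error trials,
  and at least 7 per tertile (hence 21 overall) for tertile analyses. Every
  exclusion is logged; nothing is dropped silently.

# The EEG pipelines

Both pipelines start from the continuous recording and share their head:
a zero-phase windowed-sinc (Hamming) FIR bandpass at 0.5–30 Hz, then
artifact-component removal. The FIR is linear-phase with an odd tap count,
applied by FFT convolution with exact group-delay compensation; the order
follows from a 0.5 Hz transition width (about 845 taps at 128 Hz), which
keeps passband ripple well under 1 dB and pushes DC and 40 Hz leakage below
−40 dB after the single pass.

Component removal is a FastICA decomposition (eigen-whitening, symmetric
fixed-point iteration with the tanh contrast, deterministic seeded start).
Components whose time courses correlate with the blink reference trace at
|r| ≥ 0.7 are zeroed; without a reference, components are flagged
automatically when both their AF3/AF4 loading share and their kurtosis
exceed configured thresholds. With nothing flagged, reconstruction is the
identity to numerical precision.

**Amplitude (ERP) path**: response-locked epochs −450..+550 ms (the sample
holding latency *t* is `event_sample + round(t·fs/1000)`; endpoints
inclusive, 129 samples at 128 Hz), per-epoch baseline subtraction over
[−450, −50] ms, pseudo-average re-referencing to the mean of O1, O2, T7,
T8, AF3, AF4, then ±110 μV rejection, then the F3/F4 ROI average.
Rejection is applied after re-referencing for both paths: the enumerated
time-frequency pipeline places epoch rejection after referencing, and the
amplitude path mirrors it so both paths exclude identical trials (this is
an assumption where the amplitude description is silent; it is fixed in the
configuration and logged).

**Power (ERSP) path**: re-referencing on the continuous signal, then a 1 Hz
FIR filter bank over the analysis band, analytic-signal (Hilbert) envelopes
per bin, power = envelope², averaged across bins. Power is computed on
continuous data *before* segmentation so epoch edges never truncate the
envelopes. The theta band uses the bins fully inside [4, 7] Hz —
[4,5), [5,6), [6,7) — with an `edges = "inclusive"` switch that adds
[7,8) for the inclusive reading of "4 to 7 Hz". Baseline normalization is
decibel on the *trial-average* power: epochs are averaged first, then
`dB(t) = 10·log10(P̄(t)/baseline)` with baseline [−450, −350] ms, per
channel, then the ROI mean. Normalizing the trial average is deliberate and
order-sensitive: averaging per-trial dB is not the same operation on
heterogeneous trials, and the tests enforce the distinction. Re-referencing
sits between the filter bank and the envelope in the enumerated procedure;
since both are linear it commutes with the bank, and the implementation
references the continuous signal just before the bank.

# The inferential layer

The central test is a **sample-wise paired permutation t-test**: at every
time sample, a paired t statistic on within-subject condition differences;
the null distribution is built by randomly flipping the sign of entire
subject difference *series* (whole-series flips preserve the temporal
autocorrelation under the null; per-sample flips would not). Two-sided
p per sample is `(#{|t*| ≥ |t_obs|}+1)/(n_perm+1)`, or the exact proportion
over all 2^n patterns in exhaustive mode. Significance requires p < 0.01
in at least 5 consecutive samples (~40 ms at 128 Hz); maximal runs are
reported with their time extents alongside the min/max observed t. Note a
granularity constraint of the design: with n paired subjects the smallest
attainable per-sample p is 2/2^n, so p < 0.01 requires n ≥ 9 — small
simulated cohorts must respect this.

Supporting tests: Wilcoxon signed-rank with the closed-form normal
approximation (null mean n(n+1)/4, tie-corrected variance, no continuity
correction, zero differences removed), the Friedman rank test, one-way
ANOVA on waveform areas (signed trapezoidal integrals over [−50, 150] ms
for the ERP and [−350, 450] ms for the ERSP), and paired t post hocs at a
Bonferroni-adjusted level (0.05/3 = 0.0167, displayed to 4 decimals).
Effect sizes use the Rosenthal convention r = |statistic|/√n, reported to
2 decimals. The ANOVA pools the subject × tertile areas as independent
observations — with n subjects and 3 tertiles its degrees of freedom are
(2, 3n−3) — knowingly ignoring the within-subject structure; the paired
post hocs respect it.

The tertile analysis of neural activity is also exposed behind a flag as a
sample-wise contrast of tertile waveforms, without asserting which variant
is canonical; the area ANOVA is the default surface.

# The synthetic cohort generator

The generator is first-class, tested code; its defaults are the study
conditions the pipeline targets (commission rate near 36%, hit rate near
74%, correct-trial median RT near 587 ms, error-trial near 481 ms, ~150 ms
post-error slowing coupled to accuracy).

**Reaction times.** A naive model — independent lognormal draws with a
faster error distribution — cannot reproduce those conditions jointly: if
error RTs (median 481 ms) and next-trial RTs (median 587 ms) are
independent, the raw single-trial PES is ~106 ms even with *no* injected
slowing, purely by regression toward the mean. The generator instead uses
a latent *speed state*: for subject *j*, `log RT = μ_j + x_t + ν_t`, with
`x_t` a stationary AR(1) (autocorrelation 0.995, stationary SD 0.28) and
`ν_t` small motor noise. Commission errors are emitted preferentially in
fast states through a logistic tilt on the standardized state; the tilt
strength is solved numerically so the median commission RT hits its target
while the *marginal* commission probability stays exactly `p_commission`.
Because an error is a fast *state* rather than a draw from a shifted
distribution, the following trial starts from nearly the same state: raw
PES equals the injected `pes_shift_ms` (plus noise), matched PCS sits near
zero, and the difference recovers the injected shift — all three
behavioral identities hold simultaneously. The trial after a responded
false alarm receives the additive shift (SD 80 ms), and its response
probabilities are modulated by the realized slowing through a logistic
link (slope 0.6 logits per 100 ms, centered at the shift so marginal rates
stay put): more slowing makes a hit more likely and a new false alarm less
likely. This is one concrete mechanism among several the behavioral
phenomenology admits; it was chosen because it satisfies every stated
calibration condition at once.

**EEG.** Fourteen channels of 1/f background noise (slope 1, 15 μV RMS,
0.5 Hz knee) carry three event-locked components through a fixed
frontal-dominant channel-weight template (no head model; ROI-level tests
do not need one): (i) a phase-locked negativity peaking 70 ms
post-response (Gaussian, 40 ms SD — wide enough that its detectable extent
matches the ~140 ms significant windows frontal ERNs produce — with a
small positive rebound), at `ern_amp_uv` on errors and a quarter of it on
corrects; (ii) an induced theta burst (4.6–6.4 Hz carrier, 0.5 s Hanning
envelope, uniform random phase per trial, so it cancels in time-domain
averaging); (iii) blink transients on AF3/AF4 whose ground-truth time
course is stored for validating artifact removal. The burst amplitude is
calibrated per recording against the realized background theta power of
the *referenced* signal through the *actual* filter bank (a short burst is
spectrally wider than a 1 Hz bin, so naive amplitude formulas undershoot);
`theta_gain_db` therefore sets the linear trial-average power increment
the spectral pipeline observes at the ROI. The reported dB time course
averages below that nominal value because the decibel transform is concave
in power and the burst envelope is nonuniform. Error-trial gains scale
with the subsequent realized slowing (`theta_pes_coupling`, dB per 100 ms
relative to the nominal shift). Omitted responses produce no event marker,
mirroring response-locked epoching; blocks are concatenated with 2 s
noise-only padding.

**What the generator does not emulate**: realistic head volume conduction,
artifact taxonomies beyond blinks, age-specific spectral priors, or
RT sequential effects beyond the AR(1) state. Passing tests therefore
demonstrate that the pipeline recovers known injected effects under
plausible noise — not that it is robust to every pathology of real infant
EEG.

# Numerical choices and degenerate inputs

* Time-to-sample conversion is nearest-sample, endpoints inclusive; the
  −450..550 ms window is 129 samples at 128 Hz and sample times (in exact
  grid ms) are used everywhere, so analysis windows select the samples
  inside them.
* Events too close to a recording edge for a full epoch are excluded and
  logged with a reason; rejected epochs are flagged, never removed, so
  retained + rejected + edge-excluded always equals the event count.
* `x = y` inputs: the permutation test returns t = 0 everywhere and no
  significant samples; the paired t returns t = 0, p = 1; the Wilcoxon
  returns an absent result when every difference is zero; a fully tied
  Friedman table has χ² = 0 (the textbook tie correction is 0/0 there).
* Zero within-group variance with unequal means is an error (undefined F);
  zero baseline power is an error for dB normalization.
* Permutation p values are floored at 1/(n_perm+1) by construction; the
  exhaustive mode divides the tie-inclusive count by 2^n.
* All stochastic steps (generator, matching, permutations, ICA start) are
  seeded; identical seeds give bit-identical outputs, and helpers restore
  the caller's RNG state.

# Problem sizes used by the test suite

The packaged tests exercise the pipeline at sizes chosen to make every
property measurable with comfortable statistical margins while keeping a
full run in the minutes range: behavioral calibration and recovery use
60-subject × 4-block cohorts (the shift-recovery check compares the cohort
median of PES − matched PCS against each injected shift at 2 standard
errors of the median); the ERP/ERSP dissociation experiment uses twenty
replicates of 14-subject × 2-block cohorts per condition with a 10 μV
injected negativity or a 3 dB induced theta gain; null calibration runs
200 replicates of noise-only ROI series through the filtering and
epoching machinery; and the design-arithmetic check simulates over 10⁶
trials. Artifact-free replicate cohorts disable the ICA step (component
removal has its own dedicated tests against ground-truth blinks).

# Known limitations

* The ICA is a plain FastICA on the full recording; no dimensionality
  reduction or robust re-runs. Pathological recordings can fail to
  converge (reported as an error with diagnostics).
* The matched-control procedure assumes enough post-correct pairs; tiny
  pools fall back to replacement sampling and are flagged.
* The single-trial ERP denoising hook is an identity pass-through by
  design; plugging in an external denoiser is the user's responsibility.
* EDF input/output is not provided; continuous EEG travels as headered
  CSV, events as TSV, epochs as CSV plus a JSON sidecar.
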