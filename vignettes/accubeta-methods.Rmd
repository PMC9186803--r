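---
title: "Models and methods behind accubeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind accubeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accubeta)
```

# The scientific problem

In an expanded judgment task, discrete probabilistic cues (left/right, each
valid with probability 0.7) arrive every 800 ms, and the observer decides
when to stop sampling and respond. Subthalamic local field potentials
recorded during such tasks show β-band (13–30 Hz) power modulations tied to
the decision process. `accubeta` packages the computational machinery such
a study needs — behavioural models, model-derived regressors, a
baseline-free spectral pipeline, cluster permutation statistics and
cortico-subthalamic coupling measures — and, because real recordings of
this kind are scarce, pairs every stage with a synthetic-data generator
whose ground truth is known, so the pipeline's operating characteristics
(false-positive control, detection power, estimator bias) can be measured
rather than assumed.

# Evidence-accumulation models

Cues are coded $S_t \in \{-1, +1\}$ (left/right). Four nested accumulators
update a decision variable from $DV_0 = 0$:

$$DV_t = (1-\lambda)\,DV_{t-1} + (1 + \omega\,SA_t)\,S_t$$

with forgetting rate $\lambda \in [0,1]$ and repetition bonus $\omega$
($SA_t = 1$ when cue $t$ repeats cue $t-1$). M1 fixes
$\lambda = \omega = 0$; M2 frees $\lambda$; M3 frees $\omega$; M4 frees
both. The bonus is not applied at $t = 1$, where a repetition is
undefined — the only consistent reading of the recurrence.

Choices link to the DV through a logistic function,
$\ln \frac{P(R)}{P(L)} = \beta_0 + \beta_1 DV_t$, evaluated at the final
cue of each trial. We read the slope as a single coefficient rather than
one per cue position: only two link parameters are identifiable alongside
the accumulator parameters at realistic trial counts, and model complexity
stays in the 2–4 parameter range that makes BIC comparisons meaningful. A
per-stimulus likelihood (every cue contributing a no-choice-yet term) is a
possible alternative reading; we default to final choices, which is the
variant the commitment regression below complements.

Fitting is bounded L-BFGS-B from five fixed starting points
($\lambda \in [0,1]$, $\omega \in [-2,2]$, $|\beta| \le 20$; convergence
tolerance `factr = 1e4`), keeping fits deterministic for a given data set.
BIC is $k \ln n - 2 \ln \hat L$; `select_model()` ranks all four models,
breaking BIC ties toward fewer parameters. With 5,000 simulated trials the
generating model wins the BIC comparison in essentially all runs and
$\lambda, \omega$ are recovered to within a few hundredths (the acceptance
script reports these numbers on every run).

The commitment regression asks what drives the *stopping* decision: for
every cue after the first, a logistic regression predicts whether the
choice was committed after that cue from (a) evidence for the eventually
chosen option and (b) the repetition indicator. One subtlety the synthetic
agents exposed: because the choice is the sign of the final DV, the
evidence-for-chosen-option predictor is mechanically elevated at stopping
time for *any* agent whose choice follows its DV, so a pure null requires
an agent whose stop *and* choice are both cue-independent. Complete
separation (e.g. an agent that stops deterministically on a repeat) is
detected and handled by a small-ridge refit, flagged in the result.

# Bayesian normalization and surprise regressors

Two integrators $Y_L, Y_R$ start at $\ln 0.5$ and accumulate the cue
indicators, each step subtracting the previous normalization term
$STN_{t-1}$; the normalization term is
$STN_t = \ln(e^{Y_{L,t}} + e^{Y_{R,t}})$, computed with an overflow-safe
log-sum-exp. Forgetting/bonus terms are applied to the integrators exactly
as in the winning accumulator so that $Y_{R,t} - Y_{L,t} = DV_t$ holds
identically (validated to 1e-10 over thousands of random sequences).

Shannon surprise of cue $i$ is $-\ln P(cue_i \mid cue_1..cue_{i-1})$ under
the task's generative model with the *true* validity (0.7): the surprise
regressor is defined by the task model, not by a participant's fitted
parameters, so fitted values are deliberately not substituted. Both
regressors are z-scored before entering any GLM, which makes their raw
scaling immaterial.

# The synthetic-data generator

`simulate_behavior()` draws a fair-coin direction per trial and
70%-valid cues, runs a configurable agent (threshold or logistic stopping
on $|DV|$ and $SA$), and emits trial records. `simulate_recording()` lays
the trials on a continuous 300 Hz timeline (cues at the 800 ms SOA, 2 s
inter-trial silence) and builds two channels:

* **stn** — a 21.5 Hz carrier (the 13–30 Hz band centre) whose per-cue
  burst amplitude is a baseline Hann lobe over 100–450 ms plus weighted,
  z-scored regressor contributions. The cue-identity effect uses a
  two-lobed window on "different" cues: a dip lobe (50–350 ms, weight
  $-0.5$) followed by a rise lobe (550–1150 ms) that deliberately spills
  past the next cue onset, producing the dip-then-rise difference shape
  and its carry-over into the following epoch.
* **cortex** — the same carrier phase-lagged by 90° with a gain of 0.5 on
  "same" and 1.0 on "different" cues (coupling doubles under local
  conflict), inside a 100–900 ms window.

Both channels receive independent $1/f$ noise (spectrally shaped white
noise, exponent 1, SD 0.5) — real recordings supply their own background,
so the exponent is a generic brain-like default. The carrier phase is
redrawn per trial, which prevents spurious across-trial phase locking
while keeping within-trial coupling intact. Negative envelope excursions
are clipped at zero and counted in the recording's log.

What the generator does *not* emulate: sensor arrays and volume
conduction, artifacts, non-sinusoidal burst morphology, between-subject
anatomical variability, and any dependence of the behaviour on the neural
state. Passing tests therefore certify the *pipeline* — its error control
and its sensitivity to effects of the injected form — not the
neurophysiological claims themselves.

One consequence of a structured generator worth knowing: even with all
effect weights at zero, "same" cues sit at systematically later sequence
positions than "different" cues under threshold stopping (reaching a
threshold requires repeats), so condition can correlate with
position-in-trial structure. Null-calibration checks therefore randomize
labels (or use noise epochs) rather than relying on a zero-weight
generator alone.

# Baseline-free spectral pipeline

With an 800 ms SOA there is no clean pre-stimulus baseline, so power is
estimated on the *continuous* signal and slow fluctuations are removed
afterwards:

1. sliding multitaper estimate, 400 ms window, 50 ms hop;
2. natural-log transform;
3. zero-phase fifth-order Butterworth high-pass of the log-power series at
   0.5 Hz (slower than the 1.25 Hz stimulus rate);
4. epoching −500 to 800 ms around each cue onset (27 samples on the 50 ms
   grid), nearest-neighbour marker snapping (≤ 25 ms misalignment).

Band estimation defaults to a single estimate at the band centre with the
DPSS half-bandwidth spanning the band — β: 21.5 ± 8.5 Hz giving
$K = \lfloor 2TW \rfloor - 1 = 5$ tapers; θ: 5 ± 3 Hz giving 1 taper. The
"13–30 Hz average = 21.5 Hz" style of band definition supports this
centre-plus-bandwidth reading; a per-bin averaging mode
(`mode = "bins"`) is provided for the alternative, and the choice is
carried in the result object. Tapers come from the standard symmetric
tridiagonal DPSS eigenproblem.

Numerical points: power is floored at 1e-300 before the log; the log
power is demeaned before `filtfilt` (the filter removes DC anyway, and
the zero-padded filtering would otherwise leak edge transients
proportional to the offset); a pure band-centre sinusoid is flat only up
to taper sidelobe ripple (~0.2% of log power), which sets the realistic
"≈ 0 after filtering" tolerance. An SOA-rate amplitude modulation
(1.25 Hz) passes the 0.5 Hz high-pass with less than 0.1% attenuation.

Raw-signal preprocessing (`preprocess_recording()`: decimation to 300 Hz
behind an anti-alias filter, 1 Hz zero-phase high-pass) and multi-contact
handling (`bipolar_montage()` with segmented-ring averaging,
`average_channels()` per hemisphere plus an all-contacts mean) mirror the
standard LFP workflow for DBS electrodes.

# Regression and cluster statistics

`timepoint_glm()` fits OLS at each of the 27 epoch timepoints on a
z-scored design: cue identity (1 = different), Bayesian normalization,
absolute evidence, cue number; first and last cues of each trial are
excluded (no predecessor / response overlap). `cluster_permutation_test()`
forms clusters where $|t|$ exceeds the two-sided parametric critical value
at `cluster_alpha = 0.05` (the conventional default; configurable), sums
$t$ within clusters, and compares each mass to the permutation null of the
maximum |mass|, $p = (1 + \#\{null \ge obs\})/(1 + n_{perm})$ with 1000
permutations by default and the seed recorded in the output.

Exchangeability schemes: condition-label shuffles for contrasts; joint
row shuffles of the design for the GLM (preserving inter-regressor
correlation); participant-level sign flips for group-level difference
traces. The same/different contrast concatenates the cue-i and cue-i+1
segments on a 0–1600 ms timebase (carry-over epochs labelled by the
relation at cue i, collapsed across the following cue's own type) and
reports the difference trace with a 95% CI. Effect sizes: cluster-mean
difference over pooled SD for contrasts; mean/SD of subject cluster means
for sign-flip mode; a t-to-d conversion ($\bar t/\sqrt n$) for GLM
regressors, where a mean-difference d is not defined. Pooled-epoch and
group modes are both available because single-subject and cohort analyses
exchange different units; the pooled mode is the single-recording default.

Measured operating characteristics (recomputed by the acceptance script):
the family-wise false-positive rate over null simulations sits inside
[3%, 7%] at the nominal 5%, and an injected 0.5-weight dip-then-rise
conflict effect is detected with an overlapping significant cluster in
essentially every 60-trial run.

# Connectivity

`epoch_cross_spectra()` reuses the multitaper engine on a 1–30 Hz grid at
1 Hz spacing with ±2.5 Hz smoothing (fine enough to resolve low- vs
mid-β sub-bands) over −1 to 1 s epochs, accumulating taper-summed cross-
and auto-spectra per epoch. Coherence is the trial-based estimator
$|\sum_e S_{xy}| / \sqrt{\sum_e S_{xx} \sum_e S_{yy}}$; its known small-
sample bias ($E[\mathrm{coh}^2] \approx 1/n$ for independent channels
with one taper) is verified against simulation. The debiased weighted
phase-lag index is computed from the imaginary cross-spectra in its
standard debiased-square form; because that square discards the lag
direction while the package's contract requires a signed, [-1, 1]-valued
quantity, the sign of the summed imaginary part is attached. Zero-lag
mixing yields dwPLI ≈ 0 while coherence is high; a quarter-cycle lag at
the β carrier drives dwPLI to ±1 with the lag's sign.

Condition contrasts over the time-frequency plane z-score each cell
against its own permutation distribution, form 4-connected clusters above
the two-sided normal critical value, and use the max-|mass| null as in
the 1-D case. Directionality measures are intentionally out of scope.

# Pipeline orchestration

`run_pipeline()` chains simulate → fit → regressors → recording → band
power → GLM → contrast → coherence. Every stochastic stage derives its
seed deterministically from the global seed and the stage name, so a rerun
with the same configuration is bit-identical; the manifest records the
resolved configuration, per-stage seeds, package version and MD5 checksums
of every artifact. Recordings are serialized as little-endian float32
plus a JSON sidecar (sampling rate, channels, 0-based marker indices) —
a deliberately minimal, fully documented container.

# Problem sizes and defaults

The validation suites run at sizes chosen to make their statistical
assertions meaningful while staying desk-scale: behavioural rate checks at
10^5 trials (SE ≈ 0.15 pp), parameter recovery at 5,000 trials per fit,
family-wise error at 300–500 null simulations of 40 × 27 epoch matrices
with 1,000 permutations each, and end-to-end conflict recovery over dozens
of independent 60-trial recordings (~7 minutes of signal each).

# Known limitations

* The per-stimulus likelihood variant of the choice model is exposed but
  not the default; winner counts across a heterogeneous cohort depend on
  that choice.
* The generator's amplitude-to-log-power mapping is nonlinear, so
  correlated regressors can absorb small shares of each other's injected
  effects in the GLM; sign and location of injected effects are the
  validated quantities.
* Coherence saturates near 1 at high coupling SNR; condition contrasts
  are most sensitive when coupling amplitude is comparable to the noise
  floor, as in the generator defaults.
* Cluster inference is over time (or time × frequency) within a channel;
  no correction across large sensor arrays is implemented, matching the
  few-channel synthetic setting.
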