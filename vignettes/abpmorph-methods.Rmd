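---
title: "Estimating the average arterial pulse morphology from PPG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the average arterial pulse morphology from PPG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Continuous arterial blood pressure (ABP) is measured invasively; the
photoplethysmogram (PPG) is measured with a fingertip optical sensor. Both
waveforms are driven by the same cardiac cycle, so the PPG carries
information about the pressure pulse shape. `abpmorph` implements an
end-to-end method that turns a raw fingertip PPG segment, optionally with
the subject's age and gender, into the *average ABP pulse morphology*: a
per-time-step pressure value in mmHg plus a cardiac-cycle class label for
each step (onset-to-systolic-peak, peak-to-dicrotic-notch, notch-to-end,
and an "ended" padding class). From the estimated morphology the clinical
markers — diastolic and systolic pressure (DBP, SBP), the dicrotic notch
value and its time of occurrence, and the pulse duration — are read off.

Everything in the package runs on synthetic paired waveforms with exact
beat-level ground truth, so each stage is testable without access to any
clinical waveform database.

# The processing pipeline

Records at 125 Hz enter a selection protocol: records shorter than 15
minutes, lacking either channel, or without an age in [18, 89] years are
excluded (`scan_eligible()`). For each eligible record, two 15-s segments
spaced 5 minutes apart are proposed starting after a 10-minute rest
interval; each rejection moves the cursor one minute forward until the
record is exhausted (`acceptance_loop()`).

A segment pair is accepted only if every stage passes on both segments
(`check_segment()`):

* **Flat** — maximal runs where the sample-to-sample change stays within a
  tolerance (default 0, i.e. exact repetition) for at least 0.2 s, plus
  missing samples. Runs sitting at a channel's global extremes are left to
  the saturation screen, so the two screens report disjoint regions.
* **Peak** — plateaus at the global maximum or minimum (clipping), at
  least 3 samples long.
* **PPG-SQ** — the PPG is band-passed over [0.5, 8] Hz (4th-order
  Butterworth, applied forward-backward so landmark timing is preserved;
  the order and zero-phase application are package choices, the band is
  the protocol value), MinMax-normalized, and delineated into pulses.
* **ABP-SQ** — the ABP pulses must satisfy all printed rules: durations in
  [0.5, 1.5] s and counts in [10, 30] (inclusive ranges, per "limited
  to"), pulse pressure strictly above 10 mmHg and moment skewness strictly
  above 0 (strict, per "had to be higher than"). Skewness is evaluated per
  pulse; the rule's granularity is not stated, and per-pulse is the
  stricter reading.

Pulse onsets are found with a slope-sum-function detector: positive slopes
are accumulated over a 128-ms window, threshold crossings (half the 95th
percentile of the slope-sum signal) are taken with a 0.3-s refractory
period, and each onset is refined to the waveform minimum in the preceding
150 ms. The original onset marker this stands in for is a cited algorithm
whose code is not reproduced here; what downstream stages need — and what
the tests pin down — is the contract that clean-signal onsets are
recovered within ±3 samples.

Accepted ABP pulses are onset-synchronized (`align_pulses()`) and averaged
per time-step with σ-band rejection (`average_pulse()`): per column the
mean μ and standard deviation σ are computed, and the reported value is
the mean over contributors inside μ ± 1.25σ. Three choices here are the
package's own, because the protocol leaves them open:

* σ is the *population* (divide-by-n) standard deviation — stable for the
  10–30 contributors a segment yields, and with the inclusive band it
  makes σ = 0 columns well defined (all contributors kept);
* the band is applied once, not iterated to convergence;
* the average pulse is truncated at the *median* contributing pulse
  length, dropping the sparse tail where only the longest pulses
  contribute.

With ≥ 1 contributor the refined mean can never be empty (by Chebyshev's
inequality at least a 1 − 1/1.25² fraction of contributors lies inside the
band), but a fallback to the unrefined mean exists anyway.

The systolic peak is the global maximum of the averaged pulse; the
dicrotic notch is the most prominent local minimum after it, falling back
to the maximal-curvature point when the post-peak limb is monotone. The
notch location method on the *averaged* pulse is a package decision — only
the class intervals it induces are specified. Classes are then assigned by
interval: steps up to the peak, peak to notch, notch to end.

Dataset-level post-filters keep morphologies with maximum ≤ 180 mmHg,
duration ≤ 1.2 s and skewness > 0.2 (computed on the averaged values, the
stage where the filter is stated), and each subject is capped at 10
segments by seeded subsampling.

# Model inputs and targets

The raw PPG saved at acceptance is band-passed over [0.5, 45] Hz and
differentiated with a Savitzky–Golay filter (window 7, degree 3), using
the filter's analytic first-derivative coefficients rather than finite
differences of the smoothed signal. The derivative is computed after the
band-pass; the ordering is not stated in the protocol and filtering first
keeps the derivative free of wide-band noise. One second is trimmed from
each end against filter edge artifacts, leaving 13 s. Model inputs are
5-s windows (625 steps) drawn uniformly at random per epoch, each channel
MinMax-scaled over the window.

Target values are scaled to [0, 1] by a single affine map fitted on the
*training* collection's global pressure range. Because morphologies have
different lengths, each is *homogenized*: repeated cyclically to the fixed
length T = (longest pulse + 15 steps), with repeated steps labeled with
the fourth, "ended", class. The value loss is masked to the true pulse
plus 15 steps; the class loss is unmasked so the ended class is actively
forced.

Age is scaled affinely from [18, 89] to [0, 1] and gender encoded as a
binary indicator (the encoding is not specified; affine/binary is the
minimal choice and is configurable). The demographic vector is
concatenated to every decoder input step in the DI scenarios and omitted
entirely in `Mixno`.

# The seq2seq model

The encoder is a 3-layer bidirectional GRU with 4/20/100 units per layer
and direction; the decoder a 3-layer unidirectional GRU with 8/40/200
units. Both are *dense-connected*: layer l receives the module input
concatenated with all previous layer outputs. Decoder layer l starts from
the concatenated forward/backward final states of encoder layer l — the
widths (8/40/200 = 2 × 4/20/100) make this concatenation dimension-exact,
which is why it was chosen.

The GRU cell follows the gate equations with the update gate convention
h_t = (1 − z_t) ⊙ h_{t−1} + z_t ⊙ h̃_t. Learnable biases are included
(standard practice, configurable off) and initialized to zero, so a
freshly initialized cell is exactly the bias-free cell the equations
describe — the brute-force oracle tests exploit this.

Attention is Luong's *general* score: score(h_t, h̄_s) = h_tᵀ W h̄_s,
softmax-normalized over encoder steps into weights a, with context
c = Σ_s a_s h̄_s over the encoder outputs. The context is summed over the
*encoder* outputs: that is the form the architecture's data flow supports
(the encoder outputs are what is routed into the attention module), and
the only one that uses the score's second argument.

The top decoder state feeds both the attention module and the 4-unit
class head (ELU, then softmax into class probabilities); the context
vector concatenated with the top state feeds the 1-unit value head (ELU).
A softmax over a single unit is identically 1, so the softmax
normalization belongs to the class head — the only reading that yields
usable class probabilities and a regressable value. Decoding starts from
an all-ones token and runs exactly T autoregressive steps at inference,
feeding back [value ‖ class probabilities].

Training is teacher-forced: the decoder consumes ground-truth previous
outputs (the standard formulation of "trained to predict the next value of
a target sequence"); inference is always autoregressive. The loss is
masked MSE on values plus λ = 0.01 times the (conventionally negative)
categorical cross-entropy on classes. Adam starts at 10⁻³; the rate halves
after 25 epochs without strict improvement of the monitored loss and
training stops after 50 such epochs. No validation split is prescribed, so
the monitored quantity is the training loss (configurable). Batch size is
48. Head and attention weights initialize from U(−w, w) with
w = 1/√(fan-in); GRU input weights from U(−k, k) with k = 1/√units; the
recurrent transition matrices are random orthogonal.

Because the model had to be implemented from its equations (no deep
-learning framework is assumed), the full backward pass — BPTT through both
dense-connected GRU stacks, the bilinear attention and both heads — is
hand-derived in compiled code and verified against central finite
differences in the test suite.

# Scenarios and evaluation

Three scenarios: `Mixno` (subject-disjoint splits, no demographics),
`Mixno+DI` (subject-disjoint, with demographics) and `Mixyes+DI` (segments
split regardless of subject). Test sets are 20% of subjects (respectively
segments), cross-validated 5 times; the folds are disjoint (the protocol
does not say whether the five repetitions are disjoint folds or
independent resamplings; disjoint folds are the stronger guarantee).

Predictions are restored to mmHg with the training-set scaler. DBP is the
mean of the first and last in-pulse value; SBP the in-pulse maximum; the
dicrotic notch is the last step classified peak-to-notch; the pulse
duration is the time of the first ended step. The stated marker rules
contain one internal tension (the notch time attributed to a different
class than the notch value); the package uses the self-consistent reading
— notch = last peak-to-notch step, which is the step before the first
notch-to-end step. Metrics are RMSE, MAE, error SD (sample, n−1,
matching the Bland–Altman convention), R² with squared residuals, and
Pearson R with the conventional square root — the printed formulas omit
the squares and the root, and the conventional forms are the only
dimensionally consistent ones. Waveform comparisons truncate to the
shorter of the two sequences. BHS grading takes the best row of the
60/85/95, 50/75/90, 40/65/85 table whose three thresholds are all met;
Bland–Altman limits are mean ± 1.96 sd of the paired differences.

# The synthetic data generator

`make_subject()` draws ages uniformly over [18, 89], pressures around
64.5 ± 9.5 (DBP) and 131 ± 20 mmHg (SBP) — the intended cohort's
distribution — and mean heart periods well inside the 0.5–1.5 s band.
Beats are rendered as four half-cosine segments (systolic upstroke, fall
to the notch, dicrotic bump, diastolic decay), so the onset, systolic peak
and dicrotic notch sit at exactly known samples with exactly known values:
the generator's report *is* the ground truth, not an annotation. The PPG
is derived from the ABP by a fixed transform — unit scaling, 80 ms delay,
second-order 8-Hz low-pass, x^0.9 nonlinearity — plus optional Gaussian
noise; a known, nearly invertible mapping is what makes the learnability
experiments meaningful. Beat-to-beat variability is multiplicative jitter
(≤ 5% on period, ≤ 2.5% on amplitudes), enough to exercise the σ-band
averaging without destroying onset alignment. Flatline, saturation and
noise-burst artifacts can be injected at chosen positions to exercise the
Flat/Peak screens.

What the generator deliberately does *not* emulate: respiratory
modulation, arrhythmia, pathology-specific pulse shapes, sensor drift, or
any nonstationarity of the PPG-pressure coupling. Passing tests on this
data therefore demonstrate that the pipeline and model implement their
specification and that the architecture can learn a smooth, stable
PPG-to-pressure mapping — not that clinical-grade accuracy transfers to
ICU waveforms.

# Numerical choices and degenerate inputs

* Constant segments make MinMax normalization undefined and raise an
  error; the quality chain converts that into a flat rejection.
* Zero-variance vectors make skewness and correlation undefined:
  `moment_skewness()` errors, `metrics()` errors on constant truth and
  returns `NA` correlation on constant predictions.
* Class probabilities are clipped at 10⁻¹² before the log.
* The half-open 15-s window at 125 Hz is exactly 1875 samples; the
  inter-segment gap is start-to-start (the protocol does not say;
  start-to-start is adopted and flagged).
* Ties in the window-minimum onset refinement resolve to the first
  minimum; the dicrotic-notch candidate uses strict decrease on the left
  and non-strict on the right so a flat notch bottom is found at its
  first sample.

# Problem sizes used by the tests and the acceptance script

The test suite and the acceptance script train the full architecture on
200 synthetic segments for 25 epochs and check held-out waveform
correlation above 0.9 plus a strictly lower masked error than
initialized models.
These sizes are the package's desk-scale defaults for a single CPU; the
cohort-scale experiment (thousands of segments, hundreds of epochs with
the full patience schedule) uses the same code paths with larger
arguments. A small teacher-forced overfitting check (8 samples, reduced
layer widths) guards the optimizer end of the training loop.

# Known limitations

* The onset detector is contract-equivalent, not numerically identical,
  to the cited marker algorithm.
* Class-head convergence is slower than value-head convergence at the
  prescribed λ = 0.01, so marker extraction that depends on predicted
  classes (notch time, duration) needs longer training than waveform
  fidelity does.
* The container format is an R-native serialized hierarchy, not HDF5;
  the interface (`save_container()` / `load_container()`) would not
  change if an HDF5 backend were substituted.
* Headline clinical error levels require the original ICU cohort and
  multi-hour training; they are out of scope for the synthetic data this
  package ships with.
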