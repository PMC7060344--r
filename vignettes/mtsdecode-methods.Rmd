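---
title: "Time-resolved decoding of match-to-sample LFP sessions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved decoding of match-to-sample LFP sessions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mtsdecode)
```

## The problem this package addresses

In a delayed feature-match-to-sample experiment a subject sees a *sample*
stimulus (1 s) whose features — a color, a motion direction, or both — define
what to search for; after a variable memory delay (800–1600 ms) a *test*
stimulus (250 ms) appears and the subject reports, by button press within
600 ms, whether the test matches the searched-for feature(s). Three task
rules are interleaved: color matching, motion matching, and conjunction
matching (both features must match). Colors and motion directions are each
partitioned into two opposed pairs, so a non-matching test feature is always
the "opposite" member of the sample feature's pair, and the target likelihood
is exactly 1/2 in every task.

Given multichannel local field potentials (LFP) recorded during such
sessions, the scientific questions are *what* information is present in the
population signal and *when*: the identity of the test stimulus's features,
the upcoming motor response, and — most interestingly — whether the test
matches the searched-for feature, independent of the motor outcome. The
package implements the full analysis chain for those questions: LFP
preprocessing and epoching, signal-detection behavioral statistics,
covariate-balanced time-resolved decoding with linear support vector
machines, and permutation-based significance, onset-latency and
between-condition inference. Because raw recordings of this kind are rarely
public, the package also ships a synthetic-session generator with known
injected ground truth, which is what every claim about the pipeline is
validated against.

## The synthetic session generator

### Behavior

The simulated observer is an equal-variance Gaussian signal-detection model.
For each task-relevant feature it draws evidence from N(d', 1) when the test
matches the sample in that feature and N(0, 1) otherwise, and presses when
the decision variable exceeds a criterion. For conjunction trials the
decision variable is the *minimum* of the two feature evidences — both
features must look matched. This one choice reproduces the characteristic
behavioral pattern of the task: sensitivity computed against single-feature
mismatches is lower than against complete mismatches, because the matched
feature contributes false evidence for a target. Reaction times are shifted
log-normal (`rt = 250 + lognormal(log 120, 0.3)` ms by default, median
~370 ms); presses later than the 600 ms response window count as
no-response. The defaults make censoring by the response window negligible
(~2 in 10^4) so that d' recovered from outcome counts matches the generating
d'; about 0.2% of presses fall below 300 ms, exercising the downstream
exclusion rule. Wrongly answered trials re-enter the queue at a uniformly
random later position and are re-tested; all attempts are retained in the
records. Aborted (fixation-break) trials re-enter by default; a flag disables
this, since protocols differ on whether aborts are re-run.

### Signals

The continuous voltage is the sum of per-channel 1/f noise (synthesized in
the frequency domain, unit-normalized, default SD 10 uV), a shared
common-mode 1/f source, a 50 Hz line component, a stereotyped biphasic
evoked response at every sample and test onset, and the injected *effect
components* that constitute the ground truth. Each component is a windowed
sine waveform with a known latency relative to its locking event:

* `color_identity` / `motion_identity` components give each feature level its
  own random pattern of channel signs, making the four levels linearly
  separable;
* `color_match` / `motion_match` components are added on trials where the
  test matches the searched-for feature, with one common channel pattern;
* `motor_response` components are locked to the button-press event.

Two numerical choices deserve emphasis because they were forced by failures,
not taste. First, the waveform is an **integer number of sine cycles under a
Tukey window** and therefore exactly zero-mean. A unipolar bump has most of
its energy near 0 Hz; the zero-phase 1 Hz high-pass of the preprocessing
chain converts such a bump into symmetric rebounds extending close to a
second in *both* temporal directions, which makes the injected feature
decodable long before the stimulus appears. Second, the default onset/offset
ramps are 40 ms and the default packet has 3 cycles (15 Hz at the default
200 ms duration): sharper ramps put sidelobe energy into the 50 Hz notch
band, whose narrow stop band rings for hundreds of milliseconds and again
leaks the effect backward in time. With these defaults an injected effect is
confined, after the full preprocessing chain, to roughly ±15 ms around its
true support — the residual acausal smearing of the anti-alias and band-pass
filters.

The generator records a `ground_truth` object (per component: per-trial
onset samples and channel scales, plus the realized waveform) sufficient to
reconstruct the noiseless effect signal; `ground_truth_signal()` rebuilds
it, and subtracting it from the voltages provably removes all decodable
structure (tested).

### What the generator does and does not emulate

It reproduces the statistical structure the pipeline relies on: interleaved
task rules, exact 50% target probability, per-condition sensitivities,
re-entry of error trials, realistic RT distributions, event markers, 1/f
noise with common mode and line contamination, and effect components with
known latencies and selectivities. It does **not** emulate oscillatory
dynamics, cross-channel noise correlation beyond the common mode,
non-stationarity across a session, eye movements, or spiking activity.
Passing the validation suite therefore shows the *pipeline* is correct and
calibrated — not that any particular real dataset will behave this way.

## Preprocessing

The chain follows standard LFP practice, in this order: 50 Hz notch
(Butterworth band-stop, default 10 Hz stop band), 150 Hz low-pass
(4th order), resampling to 250 Hz, then a 1–80 Hz band-pass (4th order). All
IIR filters are applied forward-backward (zero phase) so that filtering
cannot bias onset latencies; the implementation uses odd signal extension
with steady-state initial conditions and matches `signal::filtfilt` to
machine precision away from the edges. Resampling at integer ratios is a
zero-phase polyphase FIR decimator (65-tap windowed sinc just below the new
Nyquist — the 150 Hz low-pass already guards it); non-integer ratios fall
back to `signal::resample`. Event indices are remapped by rounding, which
preserves relative latencies within one output sample.

The notch bandwidth trades attenuation sharpness against ringing duration
(a Q≈5 notch rings for ~300 ms). The default of 10 Hz was chosen together
with the generator's waveform smoothness so that notch ringing stays below
decodability; narrow notches remain available via `preproc_params()`.

Trials are screened for clipping on the raw signal: a trial is dropped when
any channel sits at ≥99% of the amplifier rail for ≥5 consecutive samples
(both thresholds configurable; no published convention exists for them).
Epochs are cut from the preprocessed recording on the half-open window
`[t0, t1)` at 4 ms spacing, with 0 ms at the locking-event sample; button
presses never truncate an epoch.

## Behavioral statistics

`dprime()` computes d' = qnorm(hit rate) − qnorm(false-alarm rate) with the
log-linear correction (add 0.5 to each cell, 1 to each denominator) applied
*unconditionally*, which keeps extreme rates finite and avoids a
discontinuity between corrected and uncorrected counts. Published analyses
of this task do not state their correction convention, so magnitudes can
differ slightly from printed values at extreme rates; the qualitative
orderings are unaffected.

`dprime_by_contrast()` produces, per session: conjunction targets vs each of
the three mismatch types (color-only, motion-only, complete), plus the two
single-feature tasks. Session-wise values feed paired t-tests
(`contrast_tests()`, Bonferroni-corrected alpha 0.005 by default). Reaction
times are compared on the speed scale (reciprocal latency) with two-sample
t-tests, plus raw-latency t and Wilcoxon variants as robustness checks.

## The decoding engine

For every time bin and cross-validation fold:

1. **Features**: all channels over the bins `t − 2 .. t + 2` (20 ms maximal
   width at 250 Hz, clipped at the epoch edges), concatenated.
2. **Balancing**: before any decoding, every cell of the label × covariate
   cross-tabulation is subsampled to the minimum cell count, so the label is
   exactly independent of each covariate (chi-square association of the
   retained cross-tab is identically zero) and chance is the reciprocal of
   the number of classes.
3. **Splits**: stratified 20-fold partition; each trial appears exactly once
   in a testing set, per-fold class counts balanced up to a remainder of one.
4. **Pseudo-trials**: within each training class, trials are randomly
   grouped in fives and averaged (a remainder of ≥2 is averaged; a singleton
   passes through). Averaging is training-only; test trials are scored
   singly.
5. **Standardization**: per-feature z-scoring with statistics from the
   averaged training set, applied to the test set. (Whether the original
   analyses standardized is unknowable from the text; it is the default here
   and can be disabled — this is the most likely source of numerical
   divergence from any reference implementation.)
6. **Classifier**: linear soft-margin SVM, C = 1, one-vs-one with majority
   voting for more than two classes, ties broken by summed pairwise decision
   margins. The solver is a kernel-space dual coordinate descent on the
   precomputed window Gram matrix with LIBLINEAR-style shrinking, warm
   starts across adjacent time bins, stopping tolerance 0.1 (LIBLINEAR's
   default for the dual) capped at 40 passes. The test suite cross-checks
   held-out accuracies against libSVM (`e1071`) on the same splits and
   pseudo-trials.

The choice to implement the solver in compiled code inside the package is a
throughput decision: the validation suite fits on the order of 10^6 small
SVMs (each ~30 pseudo-trials × ~80–120 features), and per-call overhead of a
general-purpose SVM interface dominates at that size. Warm starts and the
loose dual tolerance are applied identically to observed and permutation
runs, so calibration is symmetric; noise-only sessions confirm the null is
clean.

`single_channel_timecourses()` repeats the whole procedure per channel for
array-map style localization.

## Inference

The permutation null (`permutation_null()`) re-executes the *entire* run —
balancing exclusions, splits, pseudo-trial groupings — and then shuffles the
labels of the averaged training pseudo-trials once per fold (test labels
untouched), the same shuffle applied at every bin so the null traces retain
the temporal correlation of real traces. Significance per bin is a one-sided
z-test of the observed fold-mean accuracy against the null ensemble's mean
and SD, thresholded at alpha = 1e-4. The normal approximation rather than an
empirical percentile is deliberate: a 500-run (let alone 100-run) ensemble
cannot resolve p < 1e-4 empirically. For the same reason the plotted 99.9%
chance band defaults to mean ± 3.29 SD; the empirical percentile band is one
argument away, but with a few hundred runs it degenerates to the sample
min/max, whose coverage of an exchangeable trace is only (n−1)/(n+1).

The decoding onset is the center of the earliest window spanning 40 ms —
inclusive of both end bins, i.e. 11 bins on the 4 ms grid, so centers lie on
the grid — in which every bin is significant; no cluster statistic is added
on top of the fixed per-bin threshold plus run criterion. Per-fold onsets
are computed from each fold's accuracy trace against the same fold-averaged
null (a per-fold null is not constructible from fold-averaged permutation
accuracies, and fold traces are noisier, so per-fold onsets are biased late
relative to the pooled onset — they are used only *comparatively*, between
conditions). Between-condition contrasts use per-bin two-sample t-tests over
folds at a Bonferroni-corrected alpha (0.05/3 by default), reporting all
maximal significant runs of at least 40 ms; fold accuracies are treated as
independent samples, a known optimism that is inherited from the analysis
design rather than corrected here.

With a 2-sample feature radius (±8 ms) and ±20 ms window centering, a
recovered onset for an effect of true latency L is expected in
[L, L + 24 ms]; validation confirms L + 16..20 ms across L ∈ {80, 120, 200}
at 5x-noise amplitude.

## Analysis designs

`run_pipeline()` executes simulate (or ingest) → preprocess → epoch →
select/balance → decode → null → significance → onsets, with every stage's
seed derived from one master seed, and writes deterministic CSV summaries.
Three designs are configured via `analysis_config()` (or YAML):

* **feature_decoding** — labels are the test color (or motion) among correct
  trials, balanced over the other feature and the outcome;
* **outcome_decoding** — hit vs correct rejection, presses faster than
  300 ms excluded, balanced over both test features. A variant restricted to
  non-targets (false alarm vs correct rejection) balances the mismatch type
  instead, which makes it a *motor-outcome control*: any stimulus-locked
  match signal is equalized between the classes, so only genuinely
  motor-related activity can separate them;
* **match_decoding** — conjunction-task correct rejections only, half-match
  (test matches the searched-for color, or motion, but not both) vs complete
  mismatch, balanced over both test features. Because all trials share the
  no-press outcome, decodability here cannot be a motor signal.

The paired match/outcome designs reproduce the logic of dissociating a
feature-match signal from motor preparation: a stimulus-locked match
component injected by the generator is recovered by match decoding at its
true latency while the motor-outcome control stays at chance. The
literal alternative — restricting the injected component to
correct-rejection trials and demanding that hit-vs-CR decoding stay at
chance — is not achievable by construction: hits are full matches and CRs
are mismatches, so outcome and match status are confounded and any
outcome-restricted match signal partially separates hit from CR (measured
at ~0.65 accuracy). The control used here is the coherent version of the
same question.

## Validation scales and known limitations

The validation suite and `scripts/acceptance.R` run sessions of ~160–580
pool entries (~200–700 presented trials) at 500 Hz native rate, 16–24
channels, 100 time bins, with 60–100 permutation runs and up to 20 replicate
seeds per check; full-scale analyses would use the native rate of the
acquisition system and 500 permutations, which changes runtime, not code
paths. Known limitations: the generator's noise model is stationary and
spatially simple; fold accuracies are treated as independent in t-tests; the
d' correction convention is fixed rather than fitted to any reference; and
the per-fold onset distributions are meaningful only for comparisons, not as
absolute latencies.
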