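---
title: "Quantifying larval counteraction against mechanical pressure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying larval counteraction against mechanical pressure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvaforce)
```

## The measurement problem

A *Drosophila melanogaster* larva confined in a tilted cleft — a coverslip
held at a small angle above a force platform — can either crawl forward into
the narrowing wedge, pushing the cleft open and *increasing* the vertical
counteracting force it exerts, or retreat backward and let the force drop.
The raw data of the assay are (a) a uniformly sampled vertical-force trace
(mN) and (b) a table of peristaltic-wave annotations scored from video
(direction, start, end). `larvaforce` turns these into per-wave mechanical
quantities and behaviour–force coupling statistics, and simulates the
closed-loop operant training protocol in which each wave triggers an
immediate commanded force change.

The package deliberately separates the *measurement pipeline* (segmentation,
metrics, coupling — the part that would be applied to real recordings) from
the *virtual larva* (a synthetic trial generator with ground truth, used to
validate the pipeline). Every pipeline property asserted by the test suite is
a statement about recovery of known synthetic structure, not about larval
biology.

## Force-wave segmentation

`segment_waves()` implements prominence-based peak detection followed by
wave-period delimitation.

* **Candidate peaks** are local maxima collected from half-overlapping
  sliding windows of `window_s` (default 5 s) and merged by time identity.
  Plateau-topped maxima are anchored at the plateau's leftmost sample.
* **Prominence filter**: topographic prominence (peak height above the higher
  of the two key saddles, the trace boundary acting as a higher peak) must
  reach `min_prominence` (default 5 mN). This is the criterion that separates
  genuine force waves from sensor ripple.
* **Distance retention**: extrema closer than `min_distance_s` (default 3 s)
  are merged, keeping the highest (the earlier one on equal height).
  Distances are computed from index differences on the uniform grid, which
  keeps the retention decision exact at the boundary.
* **Wave period**: the start is the later of (i) the first local minimum
  after the preceding peak and (ii) the last local minimum before the current
  peak — the tightest deterministic reading of the two published candidates;
  when no minimum exists before a peak (a flat shoulder at the start of a
  recording) the base of the peak's monotone rise is used. The end is the
  earliest post-peak time at which the smoothed slope magnitude stays below
  0.5 mN s⁻¹ for at least 0.5 s. Adjacent periods are then trimmed so that
  their overlap is below 10% of the shorter period.
* **Slope estimate**: a centred finite difference of a 0.2 s moving-average
  smoothed signal, with the difference step equal to the smoothing
  half-window. Raw sample-to-sample differences at acquisition rates of
  kHz order are noise-dominated; 0.2 s is well below the 0.5 s dwell the end
  rule requires, so the smoothing cannot hide a qualifying dwell.

All window lengths are specified in seconds and converted per trace, so the
detector is sampling-rate agnostic; the same parameters apply to 5 kHz
acquisition data and to the 100 Hz synthetic traces used in the tests.

Detected waves are matched to annotated behaviour waves by maximal temporal
overlap, requiring at least 50% of the force-wave period (after widening by
the ±0.5 s synchronization tolerance); each behaviour event may claim at most
one force wave, greatest overlap first, earlier wave on ties. Matched waves
are grouped into *bouts*: maximal runs of same-direction waves whose
end-to-start gaps stay below 30 s. Unmatched waves break bouts.

## The six wave metrics

For each wave in a bout, `compute_metrics()` reports:

1. `delta_peak_prev` — peak force change from the previous wave (undefined,
   not zero, for a bout's first wave);
2. `delta_peak_bout` — peak force change from the bout's first wave;
3. `amplitude` — peak value minus end value;
4. `duration` — end minus start time;
5. `inter_wave_delay` — end of the previous wave to start of the current;
6. `work` — `(f_max² − f_min²) / 2k`, with `f_max` the wave's peak force,
   `f_min` the minimum of the trace over the wave's own period (not a global
   minimum), and `k` the elastic coefficient of the larval body in mN/mm.
   With forces in mN the work is in mN·mm = µJ. This is the energy stored
   along a linear-elastic loading path `f = kx` between the two force levels,
   and the implementation is validated against trapezoidal integration of
   that path.

Within a bout the increments telescope exactly:
`Σₙ delta_peak_prev = delta_peak_bout`, which the suite asserts as an
identity on every fixture.

To compare how a parameter evolves over consecutive waves regardless of its
scale, `rescale_series()` applies
`P_re[n] = (Para[n] − Para[1]) / |Para[1]|`, so the first wave maps to 0 and
the series is invariant under positive rescaling of the parameter. The
series is flagged undefined when the reference `Para[1]` is zero. Division
by the *absolute* first value keeps the sign of changes meaningful for
negative-valued parameters.

`delta_peak_prev` is computed within bouts only; changes across bout
boundaries (direction switches or >30 s gaps) are not differenced, since the
inter-wave structure they would measure is not a consecutive-wave effect.

## Behaviour–force coupling

`coupling_analysis()` runs: alignment → baseline subtraction → state coding →
point-biserial correlation, separately for the forward (code 1 vs 0) and
backward (−1 vs 0) states.

* **Alignment** (`align()`): the force-sensor and video clocks may disagree
  by a bounded offset (tolerance 0.5 s). The offset is estimated by lag
  search of the correlation between the per-sample activity indicator and a
  binarized force-motion indicator (smoothed |dF/dt| above the 0.5 mN s⁻¹
  flatness threshold). Because both indicators are boxcar-like, the
  correlation-versus-lag curve has an exactly flat top; the estimate is the
  midpoint of the near-maximal plateau, which is unbiased when the two
  supports are concentric. Events clipped by the trace boundaries are
  ignored during estimation. A coarse pass over a wider lag range rejects
  offsets beyond the tolerance instead of silently mis-correcting them. Both
  series are truncated at the last valid index of the common support.
* **Baseline subtraction**: the mean of the initial 5 s reference window is
  subtracted. The operation is idempotent (the first-5 s mean of a centred
  signal is zero), which the suite asserts.
* **Point-biserial statistic**: for active state *a* ∈ {forward, backward},
  samples with the *opposite* active code are excluded — the statistic's
  n₁/n₀ dichotomy presupposes two groups, and pooling the third state into
  "static" would contaminate M₀. Then
  `r_pb = ((M₁ − M₀)/S) · sqrt(n₁ n₀ / n²)` with `S` the population
  (divide-by-n) standard deviation over the included samples. With this
  normalization `r_pb` is exactly the Pearson correlation between force and
  the 0/1 activity indicator — the recognized point-biserial identity — and
  the suite asserts agreement with `stats::cor()` to 1e-12. Whole-sample
  rather than pooled-by-group normalization of `S` was chosen because it
  yields this identity; the components (M₁, M₀, S, n₁, n₀, n) are reported
  so the alternative can be reconstructed.

## The virtual larva

`simulate_trial()` emulates the structure of a measurement trial: a 5 s
linear ramp to the baseline force (25/50/75/100 mN), then policy-driven
peristaltic waves separated by inter-wave plateaus, Gaussian sensor noise,
and early termination (flagged) as soon as the force falls below 5 mN —
loss of mechanical engagement.

Choices a real dataset could not pin down, made once and documented here:

* **Wave shape**: raised-cosine rise over the first 60% of the wave to a
  transient peak, then a normalized exponential relaxation that lands
  exactly on the wave's net force offset. This reproduces the
  rise-then-partial-relaxation morphology of recorded force waves without
  claiming a measured functional form.
* **Net increments vs amplitudes**: the *net* per-wave offset defaults to
  +3 mN (forward) and −7 mN (backward), while the transient excursion above
  the plateau (~15 mN forward, ~10 mN backward) is drawn once per trial per
  direction, mimicking a per-animal push strength. Drawing the amplitude
  per trial rather than per wave makes consecutive same-direction peak
  forces exactly inherit the plateau's monotone structure, which is the
  qualitative signature of cumulative counteraction the generator must
  reproduce.
* **Force field**: linear in position, gradient `k·tan(tilt)` (zero for a
  horizontal coverslip), the simplest model consistent with the observed
  monotone force–distance relation in a small-angle cleft.
* **Sign truncation under tilt**: with a positive gradient, forward motion
  deterministically deepens confinement, so forward increments are drawn
  from a normal truncated to positive values (and backward to negative).
  Under a horizontal coverslip the increments are plain normal draws. A
  consequence worth stating plainly: tilted-cleft synthetic trials show
  ~100% direction-consistent force changes, whereas real larvae show roughly
  94%/88% — the generator does not model slipping, posture changes or
  scoring noise, so measured consistency fractions on synthetic data
  overestimate the biological ones. They validate the measurement pipeline,
  not the animal.
* **Elastic coefficient**: no measured `k` is available as a default; the
  virtual larva uses 60 mN/mm, which under a 3° cleft gives
  `k·tan(3°) ≈ 3.1 mN/mm` and hence a larva-scale ~1 mm advance per +3 mN
  forward wave. Analyses of real data must supply their own `k` (the
  pipeline configuration has no default).
* **Sampling rate**: synthetic trials default to 100 Hz, not the 5 kHz of
  the acquisition hardware. Wave dynamics are on the 1 s scale, the detector
  is rate-agnostic, and `resample()` bridges real 5 kHz recordings down to
  an analysis rate.
* **RNG discipline**: one seed per trial; draw order is fixed (per-trial
  amplitudes, then per event: delay, decision, duration, increment, then
  sensor noise), so every trial is bit-reproducible.

The locomotion policy (forward/backward/pause probabilities) and its
reward-sensitivity update are simulator stand-ins: the larva's decision rule
is not part of the measured protocol. The update is a bounded logit nudge —
a commanded-force drop after a wave makes repeating that direction more
likely, a rise less likely, with gain `reward_sensitivity` and the logit
clamped to ±4. Setting the gain to zero provably disables learning, which
the tests use as a null condition.

## Training simulation

The controller side of the training protocol is implemented exactly as
specified by the assay: 100 mN initial force; each forward wave triggers a
20 mN decrease and each backward wave a 20 mN increase under pro-forward
training (mirrored for pro-backward); the session ends when the commanded
force reaches 0 mN; two sessions per larva with the force reset between
sessions and the policy state carried across; then a single feedback-free
test session at 25 mN for 120 s in which forward and backward waves are
counted. Commanded transitions complete within the 0.2 s controller settle
time; the commanded force is clamped at zero and unbounded above (increments
during punishment are logged as given).

Exclusion rules: pro-forward larvae are excluded on ≥5 consecutive backward
waves each immediately following a commanded-force increase (the initial
application of the 100 mN force counts as an increase, so a session opening
with five backward waves is excluded), or on no peristaltic activity;
pro-backward larvae only on no activity; naive larvae never. Excluded
virtual larvae are replaced by fresh seeds so group sizes stay fixed, with a
5× attempt cap.

A session that never reaches zero is cut at a configurable safety cap
(default 1800 s) and flagged `max_time` rather than looping forever — an
event-level analogue of an experimenter ending a stalled session.

## Numerical and degenerate-input conventions

* Traces must be uniform (≤1e-6 s timestamp jitter on ingest), finite, and
  at least 2 samples; validation errors carry the offending row index.
* A trace shorter than the minimum peak distance yields an empty detection
  with a warning, not an error.
* Singleton bouts have parameters 1 and 5 reported as `NA` (flagged absent,
  never zero).
* `rescale_series` with a zero reference and `point_biserial` with an empty
  group or zero variance return flagged-undefined results instead of NaN.
* Equal-height peak ties retain the earlier peak; matching ties prefer the
  earlier wave; all tie-breaks are deterministic.
* CSV interchange uses fixed 9-decimal formatting so that write→read round
  trips reproduce force values to better than 1e-9 mN and repeated runs are
  byte-identical.

## Validation problem sizes

The shipped test suite validates: detector–oracle index equality on 100
random traces (≤2000 samples) against a brute-force prominence enumerator;
exact ground-truth recovery on 50 noiseless simulated trials (per-larva
amplitudes fixed at ≥10 mN, inter-wave delays ~8 s) plus ≥95% count recovery
under 0.5 mN noise; the work formula against 1e5-step trapezoidal
integration on 1000 random force/stiffness triples; the point-biserial ↔
Pearson identity on 1000 random series; pipeline recovery of the configured
±3/−7 mN increments from 200 detected waves per direction; the training
closed forms (5 waves to zero for an all-forward larva; the
80,60,80,60,40,20,0 trajectory); and the direction of the training effect
over 50 virtual larvae per group, with a rank-test null check at zero reward
sensitivity. These sizes were chosen to give stable statistics at desk
scale; all are regenerated programmatically at test time.

## Known limitations

* The sign of the *backward* coupling coefficient on synthetic trials
  depends on when backward bouts occur within a trial (retreat from a high
  plateau leaves force during backward states above the trial mean), so the
  generator does not constrain it; only the forward coefficient's sign is a
  construction guarantee.
* Under heavy noise the "last local minimum before the peak" start rule
  picks minima close to the peak, shortening measured durations; peak-based
  metrics (the increments) are unaffected. Pre-smoothing a noisy recording
  before segmentation is the user's decision, not something the package
  imposes silently.
* The learning rule, pause behaviour and wave-shape family are simulator
  assumptions; conclusions about real larvae should rest only on the
  measurement pipeline applied to real recordings.
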