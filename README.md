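# larvaforce

Quantification of how *Drosophila melanogaster* larvae counteract external
mechanical pressure in a tilted-cleft force assay. A larva confined between a
force platform and a slightly tilted coverslip can crawl forward into the
narrowing wedge — pushing the cleft open and *increasing* the vertical
counteracting force — or retreat backward and let the force fall. The package
turns force-sensor telemetry plus video-scored peristaltic-wave annotations
into per-wave mechanics and behaviour–force coupling statistics, and
simulates the closed-loop operant training protocol in which every wave
triggers an immediate commanded force change.

For analysts of this assay (and similar force-telemetry ethology setups) it
provides:

* **Force-wave segmentation** — prominence-based peak detection (5 s sliding
  window, 5 mN minimum prominence, 3 s minimum peak distance) with
  wave-period delimitation: start at the later of the first minimum after the
  previous peak / last minimum before the current peak; end where the
  smoothed slope magnitude stays < 0.5 mN s⁻¹ for ≥ 0.5 s; adjacent periods
  trimmed to < 10% overlap.
* **Six wave metrics** per wave within bouts of consecutive same-direction
  waves (< 30 s gaps): peak-to-peak force change, per-bout force change,
  amplitude, duration, inter-wave delay, and elastic work
  `W = (f_max² − f_min²) / 2k` (µJ, with `k` the body's elastic coefficient
  in mN/mm), plus the first-wave-relative rescaling
  `P_re[n] = (Para[n] − Para[1]) / |Para[1]|`.
* **Behaviour–force coupling** — per-sample locomotor coding (forward 1,
  static 0, backward −1), clock alignment within a 0.5 s tolerance,
  initial-5 s baseline subtraction, and the point-biserial correlation
  `r_pb = ((M₁ − M₀)/S)·sqrt(n₁n₀/n²)` per state, which equals the Pearson
  correlation with the 0/1 activity indicator.
* **Closed-loop training simulation** — 100 mN initial force, ±20 mN per-wave
  feedback, termination at 0 mN, two sessions, exclusion rules, and a 25 mN /
  120 s test session, run against a reward-sensitive virtual larva.
* **A seeded virtual-larva generator** producing trials with ground-truth
  waves (5 s ramp, rise–relax wave profiles with ~+3 mN forward / −7 mN
  backward net offsets, tilted-cleft force field, sensor noise, early
  termination below 5 mN) for validating the whole pipeline.

## Worked example

```r
library(larvaforce)

trial <- simulate_trial(larva_params(), cleft_geometry(baseline_force = 25),
                        seed = 42)
trial
#> <simulated_trial> seed 42, baseline 25 mN, 10 truth waves

waves <- group_bouts(match_to_behavior(segment_waves(trial$force_trace),
                                       trial$behavior))
head(waves[, c("wave_id", "direction", "start_s", "peak_s", "end_s",
               "peak_mN", "bout_id")], 4)
#>   wave_id direction start_s peak_s end_s  peak_mN bout_id
#> 1       1  backward   12.56  12.58 13.42 34.47834       1
#> 2       2   forward   22.16  22.17 24.07 37.58137       2
#> 3       3   forward   42.13  42.16 43.75 42.53072       2
#> 4       4   forward   52.45  52.47 53.57 46.39910       2

m <- metrics_by_bout(waves, k = 60)   # k in mN/mm
head(m[, c("bout_id", "direction", "delta_peak_prev", "amplitude",
           "inter_wave_delay", "work")], 4)
#>   bout_id direction delta_peak_prev amplitude inter_wave_delay      work
#> 1       1  backward              NA  15.69761               NA  6.997043
#> 2       2   forward              NA  13.51468               NA  7.129616
#> 3       2   forward        4.949349  15.00127            18.06  8.758260
#> 4       2   forward        3.868385  17.77039             8.70 11.277712

coupling_analysis(trial$force_trace, trial$behavior)
#> <coupling_result> r_pb forward = 0.4476 (n1 = 3054), backward = 0.1407 (n1 = 419), offset = 0.090 s
```

Reading the output: the trial ramps to a 25 mN baseline in 5 s, then the
virtual larva emits peristaltic waves. Wave 3 peaks 4.95 mN above wave 2 —
consecutive forward waves accumulate counteracting force (the per-wave net
increment is +3 mN on average, on top of which the transient push rises
~15 mN above the running plateau). `work` is the elastic energy (µJ) between
each wave's force extremes for a body stiffness of 60 mN/mm. The positive
forward `r_pb` says force runs higher during forward peristalsis than during
static phases; `NA` metrics mark quantities that are undefined for a bout's
first wave rather than zero.

Training simulation:

```r
ex <- run_experiment(c("naive", "pro_forward"), n_per_group = 10, seed = 1,
                     larva = larva_params(policy = locomotion_policy(
                       p_forward = 0.5, p_pause = 0.1,
                       reward_sensitivity = 0.5)))
ex$summary   # forward-rewarded larvae show more forward test-session waves
```

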