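test_that("force_from_position is linear, clamped and anchored at baseline", {
  p <- larva_params()
  # flat coverslip limit: baseline everywhere
  g0 <- cleft_geometry(tilt_deg = 0, baseline_force = 25, force_gradient = 0)
  expect_equal(force_from_position(g0, p, c(0, 3, 50)), rep(25, 3))

  g <- cleft_geometry(baseline_force = 25, force_gradient = 5,
                      start_distance = 10)
  expect_equal(force_from_position(g, p, 10), 25)       # starting position
  expect_equal(force_from_position(g, p, 9), 30)        # 1 mm advance
  expect_equal(force_from_position(g, p, 20), 0)        # clamped at zero
  # strictly non-increasing in distance
  xs <- seq(0, 30, by = 0.5)
  expect_true(all(diff(force_from_position(g, p, xs)) <= 0))
  expect_error(force_from_position(g, p, -1), "x must be >= 0")

  # gradient derived from k and tilt when not given
  g3 <- cleft_geometry(tilt_deg = 3, baseline_force = 25)
  f1 <- force_from_position(g3, p, 9)
  expect_equal(f1 - 25, p$elastic_coefficient_k * tanpi(3 / 180),
               tolerance = 1e-12)
})

test_that("wave profiles land exactly on the net increment", {
  dt <- 0.01
  # zero net change with default amplitude: all-zero segment
  expect_true(all(synthesize_wave_profile("forward", 0, 2, dt) == 0))

  pf <- synthesize_wave_profile("forward", 3, 4, dt, amplitude = 15)
  expect_identical(length(pf), as.integer(round(4 / dt)))
  expect_equal(pf[length(pf)], 3)
  expect_gte(max(abs(pf)), 3)
  expect_equal(max(pf), 15)

  pb <- synthesize_wave_profile("backward", -7, 2.5, dt, amplitude = 10)
  expect_equal(pb[length(pb)], -7)
  expect_gte(max(abs(pb)), 7)

  expect_error(synthesize_wave_profile("forward", 3, 0, dt), "duration")
})

test_that("behaviour sequences follow the policy and are reproducible", {
  all_f <- locomotion_policy(p_forward = 1, p_pause = 0)
  set.seed(1)
  expect_identical(sample_behavior_sequence(all_f, 5), rep("forward", 5))
  all_b <- locomotion_policy(p_forward = 0, p_pause = 0)
  set.seed(1)
  expect_identical(sample_behavior_sequence(all_b, 5), rep("backward", 5))

  pol <- locomotion_policy(p_forward = 0.6, p_pause = 0.2)
  set.seed(77); a <- sample_behavior_sequence(pol, 50)
  set.seed(77); b <- sample_behavior_sequence(pol, 50)
  expect_identical(a, b)
})

test_that("simulate_trial is bit-reproducible and structurally valid", {
  p <- larva_params()
  g <- cleft_geometry(baseline_force = 25)
  t1 <- simulate_trial(p, g, seed = 5)
  t2 <- simulate_trial(p, g, seed = 5)
  expect_identical(t1$force_trace$values, t2$force_trace$values)
  expect_identical(t1$truth, t2$truth)

  # truth intervals disjoint and inside the trace span
  tr <- t1$truth
  if (nrow(tr) > 1) expect_true(all(tr$start_s[-1] >= tr$end_s[-nrow(tr)]))
  expect_true(all(tr$end_s <= max(trace_times(t1$force_trace)) + 1e-9))

  # ramp reaches the baseline within 5 s (noiseless check)
  t0 <- simulate_trial(noiseless_params(), g, seed = 5)
  tt <- trace_times(t0$force_trace)
  expect_equal(t0$force_trace$values[which.min(abs(tt - 5))], 25,
               tolerance = 1e-9)
  expect_lt(max(t0$force_trace$values[tt < 5]), 25 + 1e-9)
})

test_that("a waveless trial stays at baseline after the ramp", {
  p <- noiseless_params(policy = locomotion_policy(p_forward = 0, p_pause = 1))
  trial <- simulate_trial(p, cleft_geometry(baseline_force = 25), seed = 2,
                          duration_s = 30)
  expect_identical(nrow(trial$truth), 0L)
  tt <- trace_times(trial$force_trace)
  expect_true(all(trial$force_trace$values[tt >= 5] == 25))
})

test_that("a single forward wave leaves a +net plateau", {
  p <- noiseless_params(policy = locomotion_policy(p_forward = 1, p_pause = 0),
                        forward_increment_sd = 0)
  trial <- simulate_trial(p, cleft_geometry(baseline_force = 25), seed = 3,
                          duration_s = 25)
  expect_gte(nrow(trial$truth), 1L)
  w1 <- trial$truth[1, ]
  tt <- trace_times(trial$force_trace)
  after <- tt > w1$end_s + 0.1 &
    tt < (if (nrow(trial$truth) > 1) trial$truth$start_s[2] else max(tt))
  expect_equal(unique(round(trial$force_trace$values[after], 9)), 25 + 3)
})

test_that("strong backward decrements terminate the trial below 5 mN", {
  p <- noiseless_params(policy = locomotion_policy(p_forward = 0, p_pause = 0),
                        backward_increment_mean = -30, backward_increment_sd = 0.5)
  trial <- simulate_trial(p, cleft_geometry(baseline_force = 25), seed = 4)
  expect_true(trial$terminated_early)
  expect_lt(max(trace_times(trial$force_trace)), 125)
})

test_that("peaks are strictly monotone within same-direction runs (tilted cleft)", {
  for (seed in 1:6) {
    trial <- simulate_trial(noiseless_params(),
                            cleft_geometry(baseline_force = 60), seed = seed)
    tr <- trial$truth
    if (nrow(tr) < 2) next
    runs <- split(seq_len(nrow(tr)), cumsum(c(1, diff(as.integer(
      factor(tr$direction, levels = c("forward", "backward")))) != 0)))
    for (ix in runs) {
      if (length(ix) < 2) next
      pk <- tr$peak_mN[ix]
      if (tr$direction[ix[1]] == "forward") expect_true(all(diff(pk) > 0))
      else expect_true(all(diff(pk) < 0))
    }
  }
})

test_that("generated per-wave increments are self-consistent with the mean", {
  p <- noiseless_params(policy = locomotion_policy(p_forward = 1, p_pause = 0))
  nets <- c()
  seed <- 100
  while (length(nets) < 200) {
    seed <- seed + 1
    trial <- simulate_trial(p, cleft_geometry(baseline_force = 25), seed = seed)
    nets <- c(nets, trial$truth$net_mN)
  }
  se <- sd(nets) / sqrt(length(nets))
  expect_lt(abs(mean(nets) - p$forward_increment_mean), 3 * se)
})

test_that("written trials round-trip through the CSV interfaces", {
  dir <- withr::local_tempdir()
  trial <- simulate_trial(larva_params(), cleft_geometry(), seed = 9)
  paths <- write_trial(trial, dir)
  tr <- read_force_csv(paths[["trace"]])
  expect_equal(tr$values, trial$force_trace$values, tolerance = 1e-9)
  bt <- read_behavior_csv(paths[["behavior"]])
  expect_identical(bt$events$direction, trial$behavior$events$direction)
  side <- jsonlite::read_json(paths[["sidecar"]])
  expect_identical(side$seed, 9L)
})

test_that("parameter invariants are enforced at construction", {
  expect_error(larva_params(elastic_coefficient_k = 0), "k must be > 0")
  expect_error(larva_params(noise_sd = -1), "noise_sd")
  expect_error(larva_params(forward_increment_mean = -1), "forward_increment_mean")
  expect_error(locomotion_policy(p_forward = 0.8, p_pause = 0.5), "<= 1")
  expect_error(cleft_geometry(tilt_deg = 0, force_gradient = 2), "implies")
  expect_error(simulate_trial(larva_params(), cleft_geometry(), duration_s = 4),
               "ramp")
})
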