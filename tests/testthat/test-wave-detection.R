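test_that("prominence matches hand-computed values on constructed traces", {
  # isolated triangular peak of height 10 on a flat baseline
  v <- c(0, 0, 2, 5, 10, 5, 2, 0, 0)
  tr <- force_trace(v, sample_interval = 1)
  expect_equal(prominence_of(tr, 5), 10)

  # twin peaks 10 and 8 with a saddle at 4: minor peak prominence = 8 - 4
  v2 <- c(0, 10, 4, 8, 0, 0)
  tr2 <- force_trace(v2, sample_interval = 1)
  expect_equal(prominence_of(tr2, 4), 4)
  expect_equal(prominence_of(tr2, 2), 10)

  # non-maximum index is an input error
  expect_error(prominence_of(tr2, 3), "not a local maximum")

  # monotone ramp: no local maxima, no peaks
  ramp <- force_trace(seq(0, 50, length.out = 200), sample_interval = 0.1)
  expect_identical(nrow(find_extrema(ramp, peak_params())), 0L)
})

test_that("find_extrema matches the brute-force prominence oracle", {
  pp <- peak_params(window_s = 1, min_prominence = 2, min_distance_s = 0.5)
  for (seed in 1:25) {
    tr <- random_trace(seed, n = 1500, dt = 0.01)
    got <- find_extrema(tr, pp, "peaks")$index
    want <- brute_force_extrema(tr$values, 0.01, 2, 0.5, "peaks")
    expect_identical(got, as.integer(want), label = paste("seed", seed))
  }
})

test_that("close peaks are merged keeping the highest; small peaks are dropped", {
  dt <- 0.1
  tt <- seq(0, 30, by = dt)
  # two 10 mN peaks 2 s apart (< 3 s min distance), differing by 1 mN
  v <- 10 * exp(-((tt - 10)^2) / 0.18) + 11 * exp(-((tt - 12)^2) / 0.18)
  tr <- force_trace(v, sample_interval = dt)
  got <- find_extrema(tr, peak_params())
  expect_identical(nrow(got), 1L)
  expect_equal(got$time, 12, tolerance = dt)

  # amplitude below the 5 mN prominence threshold: nothing reported
  v2 <- 4 * exp(-((tt - 10)^2) / 0.5) + 4 * exp(-((tt - 20)^2) / 0.5)
  expect_identical(nrow(find_extrema(force_trace(v2, dt), peak_params())), 0L)
})

test_that("injected peaks are recovered at their true times", {
  dt <- 0.01
  tt <- seq(0, 60, by = dt)
  centers <- c(10, 20, 30, 40, 50)
  v <- rowSums(sapply(centers, function(c0) 10 * exp(-((tt - c0)^2) / 0.5)))
  tr <- force_trace(v, sample_interval = dt)
  got <- find_extrema(tr, peak_params())
  expect_identical(nrow(got), 5L)
  expect_true(all(abs(got$time - centers) <= dt + 1e-9))
})

test_that("raising min_prominence never adds peaks (monotonicity)", {
  # distance retention is neutralized (one-sample minimum distance) so the
  # property isolates the prominence filter; with a wide minimum distance a
  # newly-removed high peak can release a neighbour, which is the documented
  # retention semantics rather than a filter defect
  for (seed in c(3, 8, 13)) {
    tr <- random_trace(seed, n = 1200)
    lo <- find_extrema(tr, peak_params(window_s = 1, min_prominence = 1,
                                       min_distance_s = 0.01))$index
    hi <- find_extrema(tr, peak_params(window_s = 1, min_prominence = 4,
                                       min_distance_s = 0.01))$index
    expect_true(all(hi %in% lo))
  }
})

test_that("troughs are peaks of the negated trace (duality)", {
  pp <- peak_params(window_s = 1, min_prominence = 2, min_distance_s = 0.5)
  for (seed in c(4, 9)) {
    tr <- random_trace(seed, n = 1200)
    neg <- force_trace(-tr$values, sample_interval = tr$sample_interval,
                       start_time = tr$start_time)
    troughs <- find_extrema(tr, pp, "troughs")
    peaks_of_neg <- find_extrema(neg, pp, "peaks")
    expect_identical(troughs$index, peaks_of_neg$index)
    expect_equal(troughs$value, -peaks_of_neg$value)
  }
})

test_that("short traces yield an empty result with a warning", {
  tr <- force_trace(c(0, 1, 0), sample_interval = 0.5)
  expect_warning(out <- find_extrema(tr, peak_params(min_distance_s = 3)),
                 "shorter")
  expect_identical(nrow(out), 0L)
})

test_that("wave delimitation finds the flattening point of an isolated wave", {
  # raised-cosine wave returning to baseline: analytic profile with a known
  # flattening point at its end
  dt <- 0.01
  dur <- 4
  prof <- synthesize_wave_profile("forward", peak_delta = 0, duration = dur,
                                  dt = dt, amplitude = 15)
  v <- c(rep(0, 1000), prof, rep(0, 2000))
  tr <- force_trace(v, sample_interval = dt)
  pk <- find_extrema(tr, peak_params())
  expect_identical(nrow(pk), 1L)
  lim <- delimit_wave(tr, pk$index[1])
  # start at the base of the rise
  expect_equal((lim$start_index - 1) * dt, 10, tolerance = 0.05)
  # the profile's slope falls below 0.5 mN/s while relaxing; the declared end
  # must lie within one slope window + dwell of the analytic flattening point
  rel <- prof - c(prof[-1], prof[length(prof)])
  slope_an <- -diff(prof) / dt
  flat_an <- 1000 + 0.6 * dur / dt +
    which(abs(slope_an[(0.6 * dur / dt):length(slope_an)]) < 0.5)[1]
  expect_lt(abs(lim$end_index - flat_an) * dt, 0.5 + 0.2)
})

test_that("a 0.4 s flat shelf does not end the wave (0.5 s dwell required)", {
  dt <- 0.01
  rise <- 15 * (1 - cos(pi * seq_len(200) / 200)) / 2
  shelf <- rep(15, 40)                       # 0.4 s of zero slope
  resume <- 15 + 10 * (1 - cos(pi * seq_len(150) / 150)) / 2
  fall <- seq(25, 0, length.out = 400)
  tail0 <- rep(0, 300)
  v <- c(rep(0, 200), rise, shelf, resume, fall, tail0)
  tr <- force_trace(v, sample_interval = dt)
  peak_idx <- which.max(v)[1]
  lim <- delimit_wave(tr, peak_idx)
  shelf_end_idx <- 200 + 200 + 40
  expect_gt(lim$end_index, shelf_end_idx)
})

test_that("segment_waves recovers ground-truth waves from simulated trials", {
  hits <- 0L; total <- 0L
  for (seed in 1:10) {
    trial <- simulate_trial(noiseless_params(), cleft_geometry(baseline_force = 50),
                            seed = seed)
    wv <- segment_waves(trial$force_trace)
    expect_identical(nrow(wv), nrow(trial$truth), label = paste("seed", seed))
    expect_true(all(abs(wv$peak_s - trial$truth$peak_s) <= 0.5))
    # adjacent wave periods overlap < 10% of the shorter period
    if (nrow(wv) > 1) {
      for (i in seq_len(nrow(wv) - 1)) {
        ov <- wv$end_s[i] - wv$start_s[i + 1]
        shorter <- min(wv$end_s[i] - wv$start_s[i],
                       wv$end_s[i + 1] - wv$start_s[i + 1])
        expect_lt(ov, 0.10 * shorter)
      }
    }
    hits <- hits + nrow(wv); total <- total + nrow(trial$truth)
  }
  expect_identical(hits, total)

  # constant trace: no waves
  flat <- force_trace(rep(25, 3000), sample_interval = 0.01)
  expect_identical(nrow(segment_waves(flat)), 0L)
})

test_that("segmentation is robust to 0.5 mN sensor noise", {
  ok <- 0L; total <- 0L
  for (seed in 21:30) {
    trial <- simulate_trial(larva_params(noise_sd = 0.5),
                            cleft_geometry(baseline_force = 50), seed = seed)
    wv <- segment_waves(trial$force_trace)
    total <- total + 1L
    if (nrow(wv) == nrow(trial$truth)) ok <- ok + 1L
  }
  expect_gte(ok / total, 0.9)
})

test_that("force waves are matched to behaviour events by overlap", {
  # wave exactly spanning one forward event
  waves <- data.frame(wave_id = 1L, start_s = 10, peak_s = 11, end_s = 12,
                      start_mN = 0, peak_mN = 10, end_mN = 0, f_min_mN = 0,
                      prominence_mN = 10, truncated = FALSE,
                      direction = "unmatched", matched_wave_id = NA_integer_)
  track <- behavior_track(data.frame(wave_id = 7L, direction = "forward",
                                     start_s = 10, end_s = 12))
  m <- match_to_behavior(waves, track)
  expect_identical(m$direction, "forward")
  expect_identical(m$matched_wave_id, 7L)

  # wave overlapping nothing stays unmatched
  track0 <- behavior_track(data.frame(wave_id = 1L, direction = "forward",
                                      start_s = 100, end_s = 102))
  expect_identical(match_to_behavior(waves, track0)$direction, "unmatched")

  # 60% forward overlap beats 20% backward overlap
  track2 <- behavior_track(data.frame(wave_id = c(1L, 2L),
                                      direction = c("forward", "backward"),
                                      start_s = c(9.0, 11.6), end_s = c(11.2, 13)))
  m2 <- match_to_behavior(waves, track2, tolerance_s = 0)
  expect_identical(m2$direction, "forward")

  # one behaviour event cannot claim two force waves: greatest overlap wins
  waves2 <- rbind(waves, within(waves, {
    wave_id <- 2L; start_s <- 11.5; peak_s <- 11.8; end_s <- 12.1
  }))
  m3 <- match_to_behavior(waves2, track, tolerance_s = 0)
  expect_identical(m3$direction, c("forward", "unmatched"))
})

test_that("bout grouping follows direction and the 30 s gap rule", {
  mk <- function(dirs, starts, ends) {
    data.frame(wave_id = seq_along(dirs), start_s = starts, peak_s = starts + 1,
               end_s = ends, start_mN = 0, peak_mN = 10, end_mN = 0,
               f_min_mN = 0, prominence_mN = 10, truncated = FALSE,
               direction = dirs, matched_wave_id = seq_along(dirs))
  }
  # F,F,F with gaps 5 s and 40 s -> bouts [F,F], [F]
  w <- mk(rep("forward", 3), c(0, 10, 55), c(5, 15, 60))
  b <- group_bouts(w)
  expect_identical(b$bout_id, c(1L, 1L, 2L))

  # direction change breaks bouts even with small gaps
  w2 <- mk(c("forward", "backward", "forward"), c(0, 10, 20), c(5, 15, 25))
  expect_identical(group_bouts(w2)$bout_id, 1:3)

  # unmatched waves break bouts and belong to none
  w3 <- mk(rep("forward", 3), c(0, 10, 20), c(5, 15, 25))
  w3$direction[2] <- "unmatched"
  b3 <- group_bouts(w3)
  expect_identical(b3$bout_id, c(1L, NA, 2L))

  # empty input
  expect_identical(nrow(group_bouts(w[0, ])), 0L)
})
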