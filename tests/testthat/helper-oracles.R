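# Independent oracles and fixture builders shared across tests.

# Brute-force extremum enumerator, straight from the definitions:
# every plateau-aware local maximum is checked against the topographic
# prominence definition, then min-distance retention keeps the highest
# (earlier on ties). Deliberately O(n^2)-ish and vectorized differently
# from the package implementation.
brute_force_extrema <- function(values, dt, min_prominence, min_distance_s,
                                polarity = "peaks") {
  v <- if (polarity == "troughs") -values else values
  n <- length(v)
  is_lm <- function(i) {
    if (i < 2L || v[i - 1L] >= v[i]) return(FALSE)
    k <- i + 1L
    while (k <= n && v[k] == v[i]) k <- k + 1L
    k <= n && v[k] < v[i]
  }
  locmax <- which(vapply(seq_len(n), is_lm, logical(1)))
  if (!length(locmax)) return(integer())
  prom <- vapply(locmax, function(i) {
    higher_l <- which(v[seq_len(i - 1L)] > v[i])
    lmin <- if (length(higher_l)) min(v[(max(higher_l) + 1L):(i - 1L)])
            else min(v[seq_len(i - 1L)])
    right <- v[(i + 1L):n]
    higher_r <- which(right > v[i])
    rmin <- if (length(higher_r)) min(right[seq_len(min(higher_r) - 1L)])
            else min(right)
    v[i] - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= min_prominence
  cand <- locmax[keep]
  if (!length(cand)) return(integer())
  ord <- order(-v[cand], cand)
  kept <- integer()
  for (i in ord) {
    if (!length(kept) ||
        all(abs(cand[kept] - cand[i]) * dt >= min_distance_s))
      kept <- c(kept, i)
  }
  sort(cand[kept])
}

# random rough trace for detector stress tests: a smoothed random walk with
# occasional rounding to integers to exercise plateaus and height ties
random_trace <- function(seed, n = 2000, dt = 0.01) {
  set.seed(seed)
  v <- cumsum(rnorm(n, 0, 1))
  v <- as.numeric(stats::filter(v, rep(1 / 5, 5), sides = 2))
  v[is.na(v)] <- 0
  if (seed %% 3 == 0) v <- round(v)
  force_trace(v, sample_interval = dt)
}

# symmetric triangular-bump fixture: bumps of the given height, 1 s rise and
# 1 s fall, with behaviour events spanning each bump exactly; supports of the
# force-motion and activity indicators are then concentric, which makes the
# clock-offset estimate unbiased and exactly testable
triangle_fixture <- function(bump_starts = c(10, 20, 30, 40), height = 10,
                             rate = 100, total_s = 55,
                             directions = rep("forward", length(bump_starts))) {
  dt <- 1 / rate
  tt <- seq(0, total_s, by = dt)
  v <- numeric(length(tt))
  for (s in bump_starts) {
    up <- tt >= s & tt < s + 1
    down <- tt >= s + 1 & tt <= s + 2
    v[up] <- height * (tt[up] - s)
    v[down] <- height * (2 - (tt[down] - s))
  }
  trace <- force_trace(v, sample_interval = dt)
  events <- data.frame(wave_id = seq_along(bump_starts),
                       direction = directions,
                       start_s = bump_starts, end_s = bump_starts + 2)
  list(trace = trace, track = behavior_track(events))
}

# standard quiet virtual larva for deterministic fixtures
noiseless_params <- function(...) larva_params(noise_sd = 0, ...)
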