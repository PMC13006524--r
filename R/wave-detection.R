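#' Peak-detection parameters for force-wave segmentation
#'
#' Defaults follow the standard settings for larval counteracting-force
#' telemetry: candidate extrema are searched in 5 s sliding windows, peaks with
#' topographic prominence below 5 mN are discarded as sensor ripple, and peaks
#' closer than 3 s are merged, retaining the highest.
#'
#' @param window_s Sliding-window length in seconds (> 0).
#' @param min_prominence Minimum peak prominence in mN (> 0).
#' @param min_distance_s Minimum distance between retained peaks in seconds (> 0).
#' @return An object of class `peak_params`.
#' @export
peak_params <- function(window_s = 5, min_prominence = 5, min_distance_s = 3) {
  if (window_s <= 0 || min_prominence <= 0 || min_distance_s <= 0)
    stop("peak_params: all parameters must be strictly positive")
  structure(list(window_s = window_s, min_prominence = min_prominence,
                 min_distance_s = min_distance_s),
            class = "peak_params")
}

# Plateau-aware local maxima: the leftmost index of each maximal flat run that
# is strictly higher than the samples adjoining the run on both sides.
# Trace boundaries are never maxima.
local_maxima_idx <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer())
  d <- diff(v)
  out <- integer()
  i <- 1L
  while (i <= n - 1L) {
    if (d[i] > 0) {
      j <- i + 1L             # v[j] is the candidate plateau start
      k <- j
      while (k < n && v[k + 1L] == v[j]) k <- k + 1L
      if (k < n && v[k + 1L] < v[j]) out <- c(out, j)
      i <- k
    } else {
      i <- i + 1L
    }
  }
  out
}

# Valley runs: maximal flat runs strictly lower than both adjoining samples;
# returns the left and right sample index of each run. Used for wave-period
# start candidates (a flat inter-wave plateau is one valley run).
valley_runs <- function(v) {
  n <- length(v)
  left <- integer(); right <- integer()
  if (n < 3L) return(data.frame(left = left, right = right))
  i <- 1L
  d <- diff(v)
  while (i <= n - 1L) {
    if (d[i] < 0) {
      j <- i + 1L
      k <- j
      while (k < n && v[k + 1L] == v[j]) k <- k + 1L
      if (k < n && v[k + 1L] > v[j]) { left <- c(left, j); right <- c(right, k) }
      i <- k
    } else {
      i <- i + 1L
    }
  }
  data.frame(left = left, right = right)
}

#' Topographic prominence of a peak
#'
#' Height of the peak above the higher of its two key saddles: on each side,
#' walk away from the peak until a strictly higher sample is met (the trace
#' boundary acts as a higher peak) and take the minimum over the traversed
#' stretch; the prominence is the peak value minus the larger of the two
#' side minima.
#'
#' @param trace A `force_trace` or numeric vector.
#' @param peak_index Index of a local maximum.
#' @return Prominence in the units of the trace (mN).
#' @export
prominence_of <- function(trace, peak_index) {
  v <- if (inherits(trace, "force_trace")) trace$values else as.numeric(trace)
  if (!peak_index %in% local_maxima_idx(v))
    stop("prominence_of: index ", peak_index, " is not a local maximum")
  prominence_at(v, peak_index)
}

prominence_at <- function(v, i) {
  n <- length(v)
  pv <- v[i]
  left_min <- pv
  j <- i - 1L
  while (j >= 1L) {
    if (v[j] > pv) break
    if (v[j] < left_min) left_min <- v[j]
    j <- j - 1L
  }
  right_min <- pv
  j <- i + 1L
  while (j <= n) {
    if (v[j] > pv) break
    if (v[j] < right_min) right_min <- v[j]
    j <- j + 1L
  }
  pv - max(left_min, right_min)
}

#' Find prominent extrema in a force trace
#'
#' Candidate local maxima are collected from half-overlapping sliding windows
#' of `window_s` seconds (every interior sample is interior to at least one
#' window; duplicates found in multiple windows are merged by time identity),
#' filtered by topographic prominence, and thinned so that any two retained
#' extrema are at least `min_distance_s` apart — when candidates are closer,
#' the highest is retained (the earlier one on equal height). Troughs are
#' detected as peaks of the negated trace.
#'
#' @param trace A `force_trace`.
#' @param params A `peak_params`.
#' @param polarity `"peaks"` or `"troughs"`.
#' @return A data.frame with one row per retained extremum: `index`, `time`,
#'   `value` (on the original trace), `prominence` (mN). Ordered by time.
#' @export
find_extrema <- function(trace, params = peak_params(), polarity = c("peaks", "troughs")) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(trace, "force_trace"), inherits(params, "peak_params"))
  v <- trace$values
  if (polarity == "troughs") v <- -v
  dt <- trace$sample_interval
  n <- length(v)
  empty <- data.frame(index = integer(), time = numeric(),
                      value = numeric(), prominence = numeric())
  if ((n - 1L) * dt < params$min_distance_s) {
    warning("find_extrema: trace shorter than min_distance_s; no extrema reported")
    return(empty)
  }

  win <- max(3L, round(params$window_s / dt))
  step <- max(1L, win %/% 2L)
  starts <- unique(c(seq(1L, max(1L, n - win + 1L), by = step), max(1L, n - win + 1L)))
  cand <- integer()
  for (s in starts) {
    e <- min(n, s + win - 1L)
    loc <- local_maxima_idx(v[s:e]) + s - 1L
    cand <- c(cand, loc)
  }
  cand <- sort(unique(cand))
  # canonicalize across window joins: keep only true local maxima of the
  # full trace (a plateau straddling a window edge is re-anchored)
  full <- local_maxima_idx(v)
  cand <- intersect(cand, full)
  if (!length(cand)) return(empty)

  prom <- vapply(cand, function(i) prominence_at(v, i), numeric(1))
  keep <- prom >= params$min_prominence
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(empty)

  # min-distance retention: greedily keep by height (ties: earlier index);
  # distances from index differences on the uniform grid
  ord <- order(-v[cand], cand)
  min_gap <- params$min_distance_s
  kept <- integer()
  for (i in ord) {
    if (!length(kept) || all(abs(cand[kept] - cand[i]) * dt >= min_gap))
      kept <- c(kept, i)
  }
  kept <- kept[order(cand[kept])]
  idx <- as.integer(cand[kept])
  sign <- if (polarity == "troughs") -1 else 1
  data.frame(index = idx,
             time = trace$start_time + (idx - 1L) * dt,
             value = sign * v[idx],
             prominence = prom[kept])
}

#' Delimit the wave period around a force peak
#'
#' The start of a wave period is the later of two candidates: the first local
#' minimum following the preceding peak, and the last local minimum preceding
#' the current peak (falling back to whichever exists; the trace start when
#' neither does). The end is the earliest time after the peak at which the
#' smoothed slope magnitude stays below 0.5 mN/s for at least 0.5 s; a later
#' overlap-trimming pass ([segment_waves()]) enforces that adjacent wave
#' periods overlap by less than 10% of the shorter period.
#'
#' @param trace A `force_trace`.
#' @param peak_index Index of the wave's peak.
#' @param prev_peak_index Index of the preceding retained peak, or `NA`.
#' @param next_peak_index Index of the following retained peak, or `NA`.
#' @param slope_limit Slope threshold in mN/s (default 0.5).
#' @param dwell_s Required flat dwell in seconds (default 0.5).
#' @param slope_window_s Smoothing window for the slope estimate (default 0.2 s).
#' @return A list with `start_index`, `end_index`, and `truncated` (TRUE when
#'   the wave ran into a trace boundary or the next peak before flattening).
#' @export
delimit_wave <- function(trace, peak_index, prev_peak_index = NA,
                         next_peak_index = NA, slope_limit = 0.5,
                         dwell_s = 0.5, slope_window_s = 0.2) {
  v <- trace$values
  dt <- trace$sample_interval
  n <- length(v)
  valleys <- valley_runs(v)

  # start: later of (first local min after the previous peak,
  #                  last local min before this peak)
  cand_a <- NA_integer_
  if (!is.na(prev_peak_index)) {
    vs <- valleys[valleys$left > prev_peak_index & valleys$left < peak_index, ]
    if (nrow(vs)) cand_a <- vs$left[1L]
  }
  vs <- valleys[valleys$right < peak_index, ]
  cand_b <- if (nrow(vs)) vs$right[nrow(vs)] else NA_integer_
  start_idx <- suppressWarnings(max(cand_a, cand_b, na.rm = TRUE))
  truncated <- FALSE
  if (!is.finite(start_idx)) {
    # no local minimum exists before the peak (e.g. a flat shoulder before the
    # first wave): fall back to the base of the peak's monotone rise
    j <- peak_index
    while (j > 1L && v[j - 1L] < v[j]) j <- j - 1L
    start_idx <- j
    if (j == peak_index) { start_idx <- 1L; truncated <- TRUE }
  }

  # end: earliest post-peak time where |slope| < slope_limit holds for dwell_s
  slope <- smoothed_slope(v, dt, window_s = slope_window_s)
  dwell_n <- max(1L, round(dwell_s / dt))
  flat <- abs(slope) < slope_limit
  hard_stop <- if (!is.na(next_peak_index)) next_peak_index else n
  end_idx <- NA_integer_
  i <- peak_index + 1L
  while (i + dwell_n - 1L <= n) {
    if (all(flat[i:(i + dwell_n - 1L)])) { end_idx <- i; break }
    # jump to just past the first non-flat sample in the failed window
    bad <- which(!flat[i:(i + dwell_n - 1L)])[1L]
    i <- i + bad
    if (i > hard_stop) break
  }
  if (is.na(end_idx) || end_idx > hard_stop) {
    truncated <- TRUE
    end_idx <- if (!is.na(next_peak_index)) {
      # fall back to the lowest point between the two peaks
      seg <- v[peak_index:next_peak_index]
      peak_index + which.min(seg) - 1L
    } else n
  }
  if (end_idx <= peak_index) end_idx <- min(peak_index + 1L, n)
  list(start_index = as.integer(start_idx), end_index = as.integer(end_idx),
       truncated = truncated)
}

#' Segment a force trace into force waves
#'
#' Runs prominence-based peak detection, delimits each wave's period, and trims
#' adjacent periods so that their temporal overlap is below 10% of the shorter
#' period. Each wave carries the trace minimum over its own period (`f_min`),
#' used by the elastic-work estimate.
#'
#' @param trace A `force_trace`.
#' @param params A `peak_params`.
#' @return A data.frame of class `force_waves`, one row per wave ordered by
#'   peak time: `wave_id`, `start_s`, `peak_s`, `end_s`, `start_mN`, `peak_mN`,
#'   `end_mN`, `f_min_mN`, `prominence_mN`, `truncated`, `direction`
#'   (`"unmatched"` until [match_to_behavior()]), `matched_wave_id` (`NA`).
#' @export
segment_waves <- function(trace, params = peak_params()) {
  pk <- suppressWarnings(find_extrema(trace, params, "peaks"))
  empty <- data.frame(wave_id = integer(), start_s = numeric(), peak_s = numeric(),
                      end_s = numeric(), start_mN = numeric(), peak_mN = numeric(),
                      end_mN = numeric(), f_min_mN = numeric(),
                      prominence_mN = numeric(), truncated = logical(),
                      direction = character(), matched_wave_id = integer())
  class(empty) <- c("force_waves", "data.frame")
  if (!nrow(pk)) return(empty)
  v <- trace$values
  dt <- trace$sample_interval
  m <- nrow(pk)
  se <- lapply(seq_len(m), function(i) {
    delimit_wave(trace, pk$index[i],
                 prev_peak_index = if (i > 1L) pk$index[i - 1L] else NA,
                 next_peak_index = if (i < m) pk$index[i + 1L] else NA)
  })
  start_i <- vapply(se, `[[`, integer(1), "start_index")
  end_i <- vapply(se, `[[`, integer(1), "end_index")
  trunc <- vapply(se, `[[`, logical(1), "truncated")

  # enforce <10% overlap of the shorter of adjacent periods
  for (i in seq_len(m - 1L)) {
    overlap <- (end_i[i] - start_i[i + 1L]) * dt
    if (overlap > 0) {
      shorter <- min(end_i[i] - start_i[i], end_i[i + 1L] - start_i[i + 1L]) * dt
      if (overlap >= 0.10 * shorter) {
        end_i[i] <- max(pk$index[i] + 1L, start_i[i + 1L])
      }
    }
  }

  waves <- data.frame(
    wave_id = seq_len(m),
    start_s = trace$start_time + (start_i - 1L) * dt,
    peak_s = pk$time,
    end_s = trace$start_time + (end_i - 1L) * dt,
    start_mN = v[start_i],
    peak_mN = pk$value,
    end_mN = v[end_i],
    f_min_mN = vapply(seq_len(m), function(i) min(v[start_i[i]:end_i[i]]), numeric(1)),
    prominence_mN = pk$prominence,
    truncated = trunc,
    direction = "unmatched",
    matched_wave_id = NA_integer_
  )
  class(waves) <- c("force_waves", "data.frame")
  waves
}

#' Match detected force waves to annotated behaviour waves
#'
#' Each force wave is assigned the behaviour event with the greatest temporal
#' overlap, provided the overlap (computed after widening the force-wave
#' period by the synchronization tolerance on both sides) is at least 50% of
#' the force-wave period; otherwise the wave stays `"unmatched"`. Each
#' behaviour event matches at most one force wave — the greatest overlap wins,
#' the earlier wave on ties.
#'
#' @param waves A `force_waves` data.frame from [segment_waves()].
#' @param track A `behavior_track`.
#' @param tolerance_s Synchronization tolerance in seconds (default 0.5).
#' @return The `force_waves` data.frame with `direction` and `matched_wave_id`
#'   filled in.
#' @export
match_to_behavior <- function(waves, track, tolerance_s = 0.5) {
  stopifnot(inherits(track, "behavior_track"))
  if (!nrow(waves)) return(waves)
  ev <- track$events
  waves$direction <- "unmatched"
  waves$matched_wave_id <- NA_integer_
  if (!nrow(ev)) return(waves)
  cand <- do.call(rbind, lapply(seq_len(nrow(waves)), function(i) {
    lo <- waves$start_s[i] - tolerance_s
    hi <- waves$end_s[i] + tolerance_s
    ov <- pmax(0, pmin(hi, ev$end_s) - pmax(lo, ev$start_s))
    period <- waves$end_s[i] - waves$start_s[i]
    ok <- which(ov >= 0.5 * period & ov > 0)
    if (!length(ok)) return(NULL)
    data.frame(wave = i, event = ok, overlap = ov[ok])
  }))
  if (is.null(cand) || !nrow(cand)) return(waves)
  cand <- cand[order(-cand$overlap, cand$wave), ]
  used_ev <- logical(nrow(ev))
  used_wv <- logical(nrow(waves))
  for (r in seq_len(nrow(cand))) {
    w <- cand$wave[r]; e <- cand$event[r]
    if (used_ev[e] || used_wv[w]) next
    used_ev[e] <- TRUE; used_wv[w] <- TRUE
    waves$direction[w] <- ev$direction[e]
    waves$matched_wave_id[w] <- ev$wave_id[e]
  }
  waves
}

#' Group matched force waves into consecutive-wave bouts
#'
#' Waves are consecutive only if the peristalsis direction is the same and the
#' interval between neighbouring waves (end of the previous wave to start of
#' the next) is less than `max_gap_s`. Unmatched waves break bouts and belong
#' to none.
#'
#' @param waves A matched `force_waves` data.frame (ordered by time).
#' @param max_gap_s Maximum inter-wave gap in seconds (default 30).
#' @return The input with an added integer `bout_id` column (`NA` for
#'   unmatched waves).
#' @export
group_bouts <- function(waves, max_gap_s = 30) {
  waves[["bout_id"]] <- rep(NA_integer_, nrow(waves))
  if (!nrow(waves)) return(waves)
  bout <- 0L
  prev <- NULL
  for (i in seq_len(nrow(waves))) {
    if (waves$direction[i] == "unmatched") { prev <- NULL; next }
    gap_ok <- !is.null(prev) &&
      waves$direction[i] == waves$direction[prev] &&
      (waves$start_s[i] - waves$end_s[prev]) < max_gap_s
    if (!gap_ok) bout <- bout + 1L
    waves$bout_id[i] <- bout
    prev <- i
  }
  waves
}

#' Write a wave table as CSV
#' @param waves A `force_waves` data.frame (after matching/bout grouping).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_waves_csv <- function(waves, path) {
  utils::write.csv(format(as.data.frame(waves), digits = 10, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
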