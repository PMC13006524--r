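#' Construct a force trace
#'
#' A `force_trace` is a uniformly sampled vertical-force time series, the
#' primary measured signal of the cleft assay: time in seconds (trial-relative,
#' t = 0 at ramp onset), force in millinewtons.
#'
#' @param values Numeric vector of force samples (mN), length >= 2, all finite.
#' @param sample_interval Time between samples in seconds (> 0).
#' @param start_time Time of the first sample in seconds.
#' @param meta Optional named list of metadata (source, units, baseline force).
#'
#' @return An object of class `force_trace`: a list with elements
#'   `start_time`, `sample_interval`, `values`, `meta`.
#' @export
#' @examples
#' tr <- force_trace(c(0, 1, 2, 3), sample_interval = 0.1)
#' trace_times(tr)
force_trace <- function(values, sample_interval, start_time = 0, meta = list()) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("force_trace: need at least 2 samples, got ", length(values))
  if (!all(is.finite(values)))
    stop("force_trace: non-finite force value at row ",
         which(!is.finite(values))[1L])
  if (!is.numeric(sample_interval) || length(sample_interval) != 1L ||
      !is.finite(sample_interval) || sample_interval <= 0)
    stop("force_trace: sample_interval must be a single positive number")
  structure(
    list(start_time = as.numeric(start_time),
         sample_interval = as.numeric(sample_interval),
         values = values,
         meta = meta),
    class = "force_trace"
  )
}

#' Sample times of a force trace
#' @param trace A `force_trace`.
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "force_trace"))
  trace$start_time + (seq_along(trace$values) - 1L) * trace$sample_interval
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("<force_trace> %d samples @ %.6g Hz, t = [%.3f, %.3f] s, force [%.2f, %.2f] mN\n",
              length(x$values), 1 / x$sample_interval,
              x$start_time, max(trace_times(x)),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Construct a behaviour track
#'
#' A `behavior_track` holds the per-wave behaviour annotations (from video
#' scoring): one row per peristaltic wave with direction and start/end time.
#' The derived per-sample state code is 1 inside forward events, -1 inside
#' backward events and 0 elsewhere (see [encode_states()]).
#'
#' @param events A data.frame with columns `wave_id`, `direction`
#'   (`"forward"`/`"backward"`, or `"F"`/`"B"`), `start_s`, `end_s`.
#'
#' @return An object of class `behavior_track` wrapping the validated,
#'   time-ordered event table.
#' @export
behavior_track <- function(events) {
  if (is.null(events) || nrow(events) == 0L) {
    events <- data.frame(wave_id = integer(), direction = character(),
                         start_s = numeric(), end_s = numeric())
  } else {
    req <- c("wave_id", "direction", "start_s", "end_s")
    miss <- setdiff(req, names(events))
    if (length(miss))
      stop("behavior_track: missing columns: ", paste(miss, collapse = ", "))
    events <- events[req]
    events$direction <- expand_direction(events$direction)
    bad <- which(!(events$end_s > events$start_s))
    if (length(bad))
      stop("behavior_track: end_s <= start_s at row ", bad[1L])
    events <- events[order(events$start_s), , drop = FALSE]
    if (nrow(events) > 1L) {
      ov <- which(events$start_s[-1L] < events$end_s[-nrow(events)])
      if (length(ov))
        stop("behavior_track: overlapping events at rows ", ov[1L], " and ",
             ov[1L] + 1L)
    }
    rownames(events) <- NULL
  }
  structure(list(events = events), class = "behavior_track")
}

expand_direction <- function(d) {
  d <- as.character(d)
  d[d == "F"] <- "forward"
  d[d == "B"] <- "backward"
  bad <- which(!d %in% c("forward", "backward"))
  if (length(bad))
    stop("behavior_track: unknown direction '", d[bad[1L]], "' at row ", bad[1L])
  d
}

#' @export
print.behavior_track <- function(x, ...) {
  cat(sprintf("<behavior_track> %d events (%d forward, %d backward)\n",
              nrow(x$events), sum(x$events$direction == "forward"),
              sum(x$events$direction == "backward")))
  invisible(x)
}

#' Read and write force traces as CSV
#'
#' Two-column CSV interchange format with mandatory header `time_s,force_mN`,
#' comma-separated, '.' decimal, UTF-8. Timestamps must be strictly increasing
#' and uniform to within 1e-6 s jitter.
#'
#' @param path File path.
#' @param trace A `force_trace`.
#' @return `read_force_csv` returns a `force_trace`; `write_force_csv` returns
#'   `path` invisibly. A write/read round trip reproduces force values to
#'   better than 1e-9 mN.
#' @export
read_force_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  req <- c("time_s", "force_mN")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("read_force_csv: missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df) < 2L)
    stop("read_force_csv: need at least 2 rows, got ", nrow(df))
  t <- as.numeric(df$time_s); f <- as.numeric(df$force_mN)
  bad <- which(!is.finite(t) | !is.finite(f))
  if (length(bad))
    stop("read_force_csv: non-finite value at row ", bad[1L])
  dt <- diff(t)
  nm <- which(dt <= 0)
  if (length(nm))
    stop("read_force_csv: non-monotone time at row ", nm[1L] + 1L)
  if (max(dt) - min(dt) > 1e-6)
    stop("read_force_csv: non-uniform timestamps (jitter ",
         format(max(dt) - min(dt)), " s exceeds 1e-6 s)")
  force_trace(f, sample_interval = stats::median(dt), start_time = t[1L],
              meta = list(source = path))
}

#' @rdname read_force_csv
#' @export
write_force_csv <- function(trace, path) {
  stopifnot(inherits(trace, "force_trace"))
  df <- data.frame(time_s = sprintf("%.9f", trace_times(trace)),
                   force_mN = sprintf("%.9f", trace$values))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write behaviour event tables as CSV
#'
#' Columns: `wave_id`, `direction` (`F`/`B`), `start_s`, `end_s`.
#'
#' @param path File path.
#' @param track A `behavior_track`.
#' @return `read_behavior_csv` returns a `behavior_track`.
#' @export
read_behavior_csv <- function(path) {
  # direction must stay character: a column of bare "F" would parse as logical
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(direction = "character"))
  behavior_track(df)
}

#' @rdname read_behavior_csv
#' @export
write_behavior_csv <- function(track, path) {
  stopifnot(inherits(track, "behavior_track"))
  ev <- track$events
  out <- data.frame(wave_id = ev$wave_id,
                    direction = ifelse(ev$direction == "forward", "F", "B"),
                    start_s = sprintf("%.6f", ev$start_s),
                    end_s = sprintf("%.6f", ev$end_s))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample a force trace onto a new uniform grid
#'
#' Linear interpolation onto a uniform grid at `new_rate_hz`, spanning the
#' original time support; both endpoints of the support are grid points when
#' the span is an integer multiple of the new sample interval. Bridges the
#' 5000 Hz acquisition rate to a coarser analysis rate.
#'
#' @param trace A `force_trace`.
#' @param new_rate_hz Target sampling rate (Hz, > 0).
#' @return A `force_trace` at the new rate.
#' @export
resample <- function(trace, new_rate_hz) {
  stopifnot(inherits(trace, "force_trace"))
  if (!is.numeric(new_rate_hz) || length(new_rate_hz) != 1L || new_rate_hz <= 0)
    stop("resample: new_rate_hz must be a single positive number")
  tt <- trace_times(trace)
  dt <- 1 / new_rate_hz
  n_new <- floor((tt[length(tt)] - tt[1L]) / dt + 1e-9) + 1L
  if (n_new < 2L)
    stop("resample: new rate implies fewer than 2 samples over the trace span")
  grid <- tt[1L] + (seq_len(n_new) - 1L) * dt
  vals <- stats::approx(tt, trace$values, xout = grid, rule = 2)$y
  force_trace(vals, sample_interval = dt, start_time = grid[1L],
              meta = trace$meta)
}

#' Align a force trace with a behaviour track
#'
#' Estimates a global clock offset between the force-sensor clock and the
#' video-annotation clock by lag-searching the cross-correlation between the
#' per-sample activity indicator (state != 0) and the smoothed absolute force
#' derivative, within `+/- tolerance_s`. Offsets beyond the tolerance are
#' rejected. The track is shifted by the recovered offset, the per-sample
#' state is encoded, and both series are truncated at the last valid index of
#' the common time support.
#'
#' @param trace A `force_trace`.
#' @param track A `behavior_track`.
#' @param tolerance_s Synchronization error tolerance in seconds (default 0.5).
#' @return A list of class `aligned_pair`: `time`, `force`, `state`
#'   (per-sample code in `{1, 0, -1}`), and `offset_s` (the applied shift,
#'   positive meaning the track was annotated late).
#' @export
align <- function(trace, track, tolerance_s = 0.5) {
  stopifnot(inherits(trace, "force_trace"), inherits(track, "behavior_track"))
  tt <- trace_times(trace)
  ev <- track$events
  if (nrow(ev)) {
    if (min(ev$start_s) > tt[length(tt)] || max(ev$end_s) < tt[1L])
      stop("align: no overlap between trace and track time support")
    off <- estimate_clock_offset(trace, track, tolerance_s)
    if (abs(off$coarse) > tolerance_s + trace$sample_interval / 2)
      stop(sprintf("align: detected clock offset %.3f s exceeds tolerance %.3f s",
                   off$coarse, tolerance_s))
    shift <- off$fine
    ev$start_s <- ev$start_s - shift
    ev$end_s <- ev$end_s - shift
  } else {
    shift <- 0
  }
  last_valid <- min(tt[length(tt)],
                    if (nrow(ev)) max(ev$end_s) else tt[length(tt)])
  keep <- tt <= last_valid + trace$sample_interval / 2
  tt <- tt[keep]
  force <- trace$values[keep]
  state <- encode_states(behavior_track(ev), tt)
  structure(list(time = tt, force = force, state = state, offset_s = shift),
            class = "aligned_pair")
}

# Lag search: correlation between the per-sample activity indicator and the
# binarized force-motion indicator (smoothed |dF/dt| above the 0.5 mN/s
# flatness threshold). The coarse pass searches a wide lag range and is used
# only to reject out-of-tolerance offsets; the fine estimate is the
# in-tolerance maximizer (ties broken toward the smallest |lag|).
estimate_clock_offset <- function(trace, track, tolerance_s) {
  dt <- trace$sample_interval
  tt <- trace_times(trace)
  slope <- smoothed_slope(trace$values, dt, window_s = 0.2)
  x <- as.numeric(abs(slope) > 0.5)
  n <- length(tt)
  # events clipped by the trace boundaries would bias the lag search; use
  # only events with full margin inside the support
  margin <- tolerance_s + 0.3
  ev <- track$events
  ok <- ev$start_s - margin >= tt[1L] & ev$end_s + margin <= tt[n]
  if (!any(ok)) return(list(coarse = 0, fine = 0))
  track <- behavior_track(ev[ok, , drop = FALSE])
  max_lag0 <- max(1L, ceiling(tolerance_s / dt))
  wide0 <- min(max(max_lag0 * 8L, ceiling(5 * tolerance_s / dt)), n - 2L)
  # encode once on an extended uniform grid; a lag is then an index shift
  tt_ext <- c(tt[1L] - rev(seq_len(wide0)) * dt, tt,
              tt[n] + seq_len(wide0) * dt)
  s_ext <- abs(encode_states(track, tt_ext))
  lag_corr <- function(lag_samp) {
    ind <- s_ext[(wide0 + 1L - lag_samp):(wide0 + n - lag_samp)]
    if (stats::sd(ind) == 0 || stats::sd(x) == 0) return(0)
    stats::cor(x, ind)
  }
  # the correlation-vs-lag curve has an exactly flat top when one indicator's
  # support nests inside the other's while sliding; the unbiased estimate is
  # the midpoint of the near-maximal plateau (among tied plateaus, the one
  # nearest zero lag)
  pick_lag <- function(lags, c) {
    near <- which(c >= max(c) - 1e-9)
    grp <- cumsum(c(1L, diff(near) != 1L))
    mids <- vapply(split(near, grp), function(ix)
      (lags[ix[1L]] + lags[ix[length(ix)]]) / 2, numeric(1))
    unname(round(mids[which.min(abs(mids))]))
  }
  max_lag <- max_lag0
  wide_lag <- wide0
  lags_w <- seq(-wide_lag, wide_lag)
  cw <- vapply(lags_w, lag_corr, numeric(1))
  # a maximizing lag of -lambda means the track is annotated late by +lambda
  coarse <- -pick_lag(lags_w, cw) * dt
  lags_f <- seq(-max_lag, max_lag)
  cf <- vapply(lags_f, lag_corr, numeric(1))
  fine <- -pick_lag(lags_f, cf) * dt
  list(coarse = coarse, fine = fine)
}

# Centred finite difference of a moving-average smoothed signal; the
# difference step equals the smoothing window, so the two averaged stretches
# do not overlap and the estimate is robust to sample-scale noise.
smoothed_slope <- function(values, dt, window_s = 0.2) {
  n <- length(values)
  w <- max(1L, round(window_s / dt))
  if (w %% 2L == 0L) w <- w + 1L
  sm <- stats::filter(values, rep(1 / w, w), sides = 2)
  sm <- as.numeric(sm)
  # extend the moving average to the edges with shrinking windows
  half <- (w - 1L) %/% 2L
  for (i in seq_len(min(half, n))) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    sm[i] <- mean(values[lo:hi])
    j <- n - i + 1L
    lo <- max(1L, j - half); hi <- min(n, j + half)
    sm[j] <- mean(values[lo:hi])
  }
  k <- max(1L, w)
  idx_hi <- pmin(n, seq_len(n) + k)
  idx_lo <- pmax(1L, seq_len(n) - k)
  (sm[idx_hi] - sm[idx_lo]) / ((idx_hi - idx_lo) * dt)
}

#' Read a run configuration from YAML
#'
#' @param path Path to a YAML file of pipeline parameters (seeds, elastic
#'   coefficient `k`, peak-detection parameters, baseline forces, output dir).
#' @return A named list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  cfg
}
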