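#' Encode per-sample locomotor state codes
#'
#' Classifies each sample time into one of three discrete locomotor states:
#' forward peristalsis (coded 1), static (0) and backward peristalsis (-1),
#' by membership in the track's annotated events. Event intervals are treated
#' as half-open `[start_s, end_s)`.
#'
#' @param track A `behavior_track`.
#' @param times Numeric vector of sample times (s).
#' @return Integer vector of codes in `{1, 0, -1}`, one per time.
#' @export
encode_states <- function(track, times) {
  stopifnot(inherits(track, "behavior_track"))
  ev <- track$events
  codes <- integer(length(times))
  if (!nrow(ev)) return(codes)
  for (i in seq_len(nrow(ev))) {
    inside <- times >= ev$start_s[i] & times < ev$end_s[i]
    codes[inside] <- if (ev$direction[i] == "forward") 1L else -1L
  }
  codes
}

#' Subtract the pre-compression baseline from a force trace
#'
#' Subtracts the mean of the initial 5 s of the signal (the pre-compression
#' reference phase) from every sample. Because the first-5 s mean of a
#' centred signal is zero, the operation is idempotent.
#'
#' @param trace A `force_trace` spanning at least 5 s, or a list with `time`
#'   and `force` elements (an `aligned_pair`).
#' @param baseline_s Length of the reference window in seconds (default 5).
#' @return The same type of object with the baseline-subtracted force.
#' @export
subtract_baseline <- function(trace, baseline_s = 5) {
  if (inherits(trace, "force_trace")) {
    tt <- trace_times(trace)
    span <- tt[length(tt)] - tt[1L]
    if (span < baseline_s)
      stop("subtract_baseline: trace spans ", format(span),
           " s, needs >= ", baseline_s, " s")
    ref <- mean(trace$values[tt - tt[1L] < baseline_s])
    trace$values <- trace$values - ref
    trace
  } else if (is.list(trace) && all(c("time", "force") %in% names(trace))) {
    tt <- trace$time
    if (tt[length(tt)] - tt[1L] < baseline_s)
      stop("subtract_baseline: series spans less than ", baseline_s, " s")
    ref <- mean(trace$force[tt - tt[1L] < baseline_s])
    trace$force <- trace$force - ref
    trace
  } else {
    stop("subtract_baseline: expected a force_trace or aligned pair")
  }
}

#' Point-biserial correlation between force and a locomotor state
#'
#' For the chosen active state (forward, code 1, or backward, code -1),
#' samples carrying the opposite active code are excluded and the statistic is
#' computed over active-vs-static samples:
#' `r_pb = ((M1 - M0) / S) * sqrt(n1 * n0 / n^2)`,
#' where `M1`/`M0` are the mean force during active/static samples, `S` is the
#' population (divide-by-n) standard deviation of force over the included
#' samples, `n1`/`n0` the active/static sample counts and `n = n1 + n0`. With
#' this normalization `r_pb` equals the Pearson correlation between force and
#' the 0/1 activity indicator.
#'
#' @param force Numeric vector of force samples.
#' @param codes Integer vector of state codes in `{1, 0, -1}`, same length.
#' @param active_state `"forward"` or `"backward"`.
#' @return A list: `r_pb` (`NA` when undefined), `M1`, `M0`, `S`, `n1`, `n0`,
#'   `n`, and `defined`.
#' @export
#' @examples
#' point_biserial(c(2, 2, 4, 4), c(0L, 0L, 1L, 1L), "forward")$r_pb  # 1
point_biserial <- function(force, codes, active_state = c("forward", "backward")) {
  active_state <- match.arg(active_state)
  if (length(force) != length(codes))
    stop("point_biserial: force and codes differ in length")
  active_code <- if (active_state == "forward") 1L else -1L
  keep <- codes %in% c(active_code, 0L)
  f <- force[keep]; c0 <- codes[keep]
  n1 <- sum(c0 == active_code)
  n0 <- sum(c0 == 0L)
  n <- n1 + n0
  if (n1 == 0L || n0 == 0L) {
    return(list(r_pb = NA_real_, M1 = NA_real_, M0 = NA_real_, S = NA_real_,
                n1 = n1, n0 = n0, n = n, defined = FALSE))
  }
  M1 <- mean(f[c0 == active_code])
  M0 <- mean(f[c0 == 0L])
  S <- sqrt(mean((f - mean(f))^2))
  if (S == 0) {
    return(list(r_pb = NA_real_, M1 = M1, M0 = M0, S = 0,
                n1 = n1, n0 = n0, n = n, defined = FALSE))
  }
  r <- ((M1 - M0) / S) * sqrt(n1 * n0 / n^2)
  list(r_pb = r, M1 = M1, M0 = M0, S = S, n1 = n1, n0 = n0, n = n,
       defined = TRUE)
}

#' Behaviour-force coupling analysis for one trial
#'
#' Full coupling pipeline: align the force trace with the behaviour track
#' (clock-offset correction and truncation at the last valid index), subtract
#' the initial-5 s baseline, encode per-sample locomotor states, and compute
#' the point-biserial correlation separately for the forward (1 vs 0) and
#' backward (-1 vs 0) states.
#'
#' @param trace A `force_trace`.
#' @param track A `behavior_track`.
#' @param tolerance_s Synchronization tolerance passed to [align()].
#' @param baseline_s Baseline reference window (s).
#' @return An object of class `coupling_result`: list with `forward` and
#'   `backward` point-biserial component lists (see [point_biserial()]),
#'   plus `offset_s` and `n_samples`.
#' @export
coupling_analysis <- function(trace, track, tolerance_s = 0.5, baseline_s = 5) {
  pair <- align(trace, track, tolerance_s = tolerance_s)
  pair <- subtract_baseline(pair, baseline_s = baseline_s)
  codes <- pair$state
  structure(
    list(forward = point_biserial(pair$force, codes, "forward"),
         backward = point_biserial(pair$force, codes, "backward"),
         offset_s = pair$offset_s,
         n_samples = length(pair$force)),
    class = "coupling_result"
  )
}

#' @export
print.coupling_result <- function(x, ...) {
  fr <- function(p) if (isTRUE(p$defined)) sprintf("%.4f", p$r_pb) else "undefined"
  cat(sprintf("<coupling_result> r_pb forward = %s (n1 = %d), backward = %s (n1 = %d), offset = %.3f s\n",
              fr(x$forward), x$forward$n1, fr(x$backward), x$backward$n1,
              x$offset_s))
  invisible(x)
}

#' Write a coupling result as JSON
#' @param result A `coupling_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coupling_json <- function(result, path) {
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
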