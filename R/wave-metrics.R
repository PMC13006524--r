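#' Elastic work of a force wave
#'
#' Work estimate for one force wave: `(f_max^2 - f_min^2) / (2k)`, where
#' `f_max` and `f_min` are the maximum and minimum force over the wave period
#' and `k` is the elastic coefficient of the larval body (mN/mm). This is the
#' energy stored along a linear-elastic loading path `f = k x` between the two
#' force levels; with forces in mN and `k` in mN/mm the result is in
#' mN·mm = µJ.
#'
#' @param f_max Maximum force of the wave (mN), `f_max >= f_min`.
#' @param f_min Minimum force of the wave (mN), `>= 0`.
#' @param k Elastic coefficient (mN/mm, > 0).
#' @return Work in µJ. Vectorized over its arguments.
#' @export
#' @examples
#' wave_work(5, 3, k = 2)  # (25 - 9) / 4 = 4
wave_work <- function(f_max, f_min, k) {
  if (any(k <= 0)) stop("wave_work: k must be > 0")
  if (any(f_min < 0)) stop("wave_work: f_min must be >= 0")
  if (any(f_max < f_min)) stop("wave_work: f_max must be >= f_min")
  (f_max^2 - f_min^2) / (2 * k)
}

#' Per-wave metrics within a bout of consecutive waves
#'
#' Computes the six descriptive parameters of each force wave in a bout:
#' \describe{
#'   \item{delta_peak_prev}{force change between two consecutive waves — the
#'     difference between the peak values of adjacent waves (`NA` for the
#'     bout's first wave);}
#'   \item{delta_peak_bout}{force change per bout — current peak minus the
#'     bout's first-wave peak;}
#'   \item{amplitude}{peak value minus end value of the wave;}
#'   \item{duration}{end time minus start time;}
#'   \item{inter_wave_delay}{end of the previous wave to start of the current
#'     (`NA` for the first wave);}
#'   \item{work}{elastic work `(f_max^2 - f_min^2)/2k` over the wave period.}
#' }
#'
#' @param bout A `force_waves` data.frame restricted to one bout, ordered by
#'   peak time (rows must carry `peak_mN`, `end_mN`, `start_s`, `end_s`,
#'   `f_min_mN`).
#' @param k Elastic coefficient (mN/mm, > 0).
#' @return A data.frame with one row per wave: `wave_index`, the six metric
#'   columns (times in s, forces in mN, work in µJ).
#' @export
compute_metrics <- function(bout, k) {
  if (k <= 0) stop("compute_metrics: k must be > 0")
  n <- nrow(bout)
  if (!n) {
    return(data.frame(wave_index = integer(), delta_peak_prev = numeric(),
                      delta_peak_bout = numeric(), amplitude = numeric(),
                      duration = numeric(), inter_wave_delay = numeric(),
                      work = numeric()))
  }
  if (is.unsorted(bout$peak_s)) bout <- bout[order(bout$peak_s), , drop = FALSE]
  peaks <- bout$peak_mN
  data.frame(
    wave_index = seq_len(n),
    delta_peak_prev = c(NA_real_, diff(peaks)),
    delta_peak_bout = peaks - peaks[1L],
    amplitude = peaks - bout$end_mN,
    duration = bout$end_s - bout$start_s,
    inter_wave_delay = c(NA_real_, bout$start_s[-1L] - bout$end_s[-n]),
    work = wave_work(peaks, pmin(bout$f_min_mN, peaks), k)
  )
}

#' Metrics for every bout in a wave table
#'
#' @param waves A matched, bout-grouped `force_waves` data.frame (see
#'   [group_bouts()]).
#' @param k Elastic coefficient (mN/mm).
#' @return A data.frame with one row per in-bout wave: `bout_id`, `direction`,
#'   `wave_id`, `wave_index`, and the six metric columns.
#' @export
metrics_by_bout <- function(waves, k) {
  ids <- sort(unique(waves$bout_id[!is.na(waves$bout_id)]))
  out <- lapply(ids, function(b) {
    sub <- waves[!is.na(waves$bout_id) & waves$bout_id == b, , drop = FALSE]
    m <- compute_metrics(sub, k)
    cbind(data.frame(bout_id = b, direction = sub$direction,
                     wave_id = sub$wave_id), m)
  })
  if (!length(out)) {
    return(data.frame(bout_id = integer(), direction = character(),
                      wave_id = integer(), wave_index = integer(),
                      delta_peak_prev = numeric(), delta_peak_bout = numeric(),
                      amplitude = numeric(), duration = numeric(),
                      inter_wave_delay = numeric(), work = numeric()))
  }
  do.call(rbind, out)
}

#' Rescale a per-wave parameter series within a bout
#'
#' Rescaled value of wave `n` relative to the bout's first wave:
#' `P_re[n] = (Para[n] - Para[1]) / |Para[1]|`, so `P_re[1] = 0` and the series
#' measures the change in the parameter relative to the absolute value of the
#' first wave. Undefined when `Para[1] = 0` (all `NA`, flagged).
#'
#' @param values Numeric vector, one value per wave in bout order.
#' @return An object of class `rescaled_series`: numeric vector of the same
#'   length with attributes `reference` (`Para[1]`) and `defined` (FALSE when
#'   `Para[1] = 0`).
#' @export
rescale_series <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("rescale_series: empty series")
  ref <- values[1L]
  if (is.na(ref) || ref == 0) {
    out <- rep(NA_real_, length(values))
    attr(out, "reference") <- ref
    attr(out, "defined") <- FALSE
    class(out) <- "rescaled_series"
    return(out)
  }
  out <- (values - ref) / abs(ref)
  attr(out, "reference") <- ref
  attr(out, "defined") <- TRUE
  class(out) <- "rescaled_series"
  out
}

#' Fractions of direction-consistent force changes
#'
#' Among matched waves with a defined peak-to-peak change (wave 2 onward of
#' each bout), the fraction of forward waves that increased the counteracting
#' force (`delta_peak_prev > 0`) and the fraction of backward waves that
#' decreased it (`delta_peak_prev < 0`). Ties (`delta == 0`) count against
#' consistency. Returns `NA` (flagged) for a direction with no eligible waves.
#'
#' @param wave_metrics Output of [metrics_by_bout()].
#' @return A list with `forward_increase_frac`, `backward_decrease_frac`,
#'   `n_forward`, `n_backward`.
#' @export
direction_effect_fractions <- function(wave_metrics) {
  wm <- wave_metrics[!is.na(wave_metrics$delta_peak_prev), , drop = FALSE]
  fwd <- wm$delta_peak_prev[wm$direction == "forward"]
  bwd <- wm$delta_peak_prev[wm$direction == "backward"]
  list(
    forward_increase_frac = if (length(fwd)) mean(fwd > 0) else NA_real_,
    backward_decrease_frac = if (length(bwd)) mean(bwd < 0) else NA_real_,
    n_forward = length(fwd),
    n_backward = length(bwd)
  )
}
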