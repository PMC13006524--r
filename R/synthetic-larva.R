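#' Virtual-larva parameters
#'
#' Mechanical and behavioural parameters of the synthetic larva used to
#' generate trials with ground truth. Net per-wave force increments default to
#' +3 mN per forward wave and -7 mN per backward wave (the characteristic
#' per-wave changes of the counteracting force under a 25 mN baseline), while
#' the transient wave excursion above the running plateau (the "amplitude") is
#' drawn once per trial per direction, mimicking a per-animal push strength.
#'
#' @param elastic_coefficient_k Elastic coefficient of the larval body
#'   (mN/mm, > 0). No measured default exists; 60 mN/mm gives a ~1 mm advance
#'   per +3 mN forward wave under a 3 degree cleft.
#' @param advance_per_forward_wave,retreat_per_backward_wave Distance moved per
#'   wave (mm, > 0); used only when the force gradient is zero (horizontal
#'   coverslip), otherwise displacement follows from increment / gradient.
#' @param forward_wave_duration_mean,forward_wave_duration_sd Forward wave
#'   duration (s).
#' @param backward_wave_duration_mean,backward_wave_duration_sd Backward wave
#'   duration (s).
#' @param inter_wave_delay_mean,inter_wave_delay_sd Delay between the end of a
#'   wave and the start of the next (s).
#' @param forward_increment_mean,forward_increment_sd Net force change per
#'   forward wave (mN; mean > 0).
#' @param backward_increment_mean,backward_increment_sd Net force change per
#'   backward wave (mN; mean < 0).
#' @param forward_amplitude_mean,forward_amplitude_sd Transient excursion of a
#'   forward wave above its starting plateau (mN).
#' @param backward_amplitude_mean,backward_amplitude_sd Same for backward waves.
#' @param noise_sd Gaussian sensor noise (mN, >= 0).
#' @param policy A [locomotion_policy()].
#' @return An object of class `larva_params`.
#' @export
larva_params <- function(elastic_coefficient_k = 60,
                         advance_per_forward_wave = 1,
                         retreat_per_backward_wave = 2,
                         forward_wave_duration_mean = 4,
                         forward_wave_duration_sd = 0.5,
                         backward_wave_duration_mean = 2.5,
                         backward_wave_duration_sd = 0.4,
                         inter_wave_delay_mean = 6,
                         inter_wave_delay_sd = 1,
                         forward_increment_mean = 3,
                         forward_increment_sd = 1,
                         backward_increment_mean = -7,
                         backward_increment_sd = 2,
                         forward_amplitude_mean = 15,
                         forward_amplitude_sd = 2,
                         backward_amplitude_mean = 10,
                         backward_amplitude_sd = 1.5,
                         noise_sd = 0.3,
                         policy = locomotion_policy()) {
  p <- as.list(environment())
  if (p$elastic_coefficient_k <= 0) stop("larva_params: k must be > 0")
  if (p$advance_per_forward_wave <= 0 || p$retreat_per_backward_wave <= 0)
    stop("larva_params: per-wave distances must be > 0")
  durs <- c(p$forward_wave_duration_mean, p$backward_wave_duration_mean,
            p$inter_wave_delay_mean)
  if (any(durs <= 0)) stop("larva_params: durations and delays must be > 0")
  if (p$noise_sd < 0) stop("larva_params: noise_sd must be >= 0")
  if (p$forward_increment_mean <= 0)
    stop("larva_params: forward_increment_mean must be > 0")
  if (p$backward_increment_mean >= 0)
    stop("larva_params: backward_increment_mean must be < 0")
  stopifnot(inherits(p$policy, "locomotion_policy"))
  structure(p, class = "larva_params")
}

#' Locomotion policy of the virtual larva
#'
#' Per-wave decision rule: the larva draws forward / backward / pause with the
#' given probabilities. `reward_sensitivity` is the gain of a bounded logit
#' update applied after each wave whose outcome changed the commanded force: a
#' force drop after a wave makes repeating that wave direction more likely (and
#' a force rise less likely). This decision rule is a simulator stand-in, not a
#' model of larval neurobiology.
#'
#' @param p_forward,p_pause Per-wave probabilities (`p_forward + p_pause <= 1`;
#'   backward has the remaining mass).
#' @param reward_sensitivity Dimensionless gain (>= 0); 0 disables learning.
#' @return An object of class `locomotion_policy` with the internal logit state.
#' @export
locomotion_policy <- function(p_forward = 0.7, p_pause = 0.1,
                              reward_sensitivity = 0) {
  if (p_forward < 0 || p_forward > 1 || p_pause < 0 || p_pause > 1 ||
      p_forward + p_pause > 1)
    stop("locomotion_policy: need probabilities in [0,1] with p_forward + p_pause <= 1")
  if (reward_sensitivity < 0)
    stop("locomotion_policy: reward_sensitivity must be >= 0")
  # logit of forward-vs-backward preference among non-pause moves
  p_move <- 1 - p_pause
  q <- if (p_move > 0) p_forward / p_move else 0.5
  q <- min(max(q, 1e-6), 1 - 1e-6)
  structure(list(p_forward = p_forward, p_pause = p_pause,
                 reward_sensitivity = reward_sensitivity,
                 theta = stats::qlogis(q)),
            class = "locomotion_policy")
}

policy_probs <- function(policy) {
  p_move <- 1 - policy$p_pause
  pf <- p_move * stats::plogis(policy$theta)
  c(forward = pf, backward = p_move - pf, pause = policy$p_pause)
}

# Bounded logit update after a wave: a commanded-force drop following a
# forward wave (or rise following a backward wave) nudges preference toward
# forward, and symmetrically. theta is clamped to [-4, 4].
update_policy <- function(policy, direction, delta_force) {
  g <- policy$reward_sensitivity
  if (g == 0 || delta_force == 0 || direction == "pause") return(policy)
  toward_forward <- (direction == "forward") == (delta_force < 0)
  policy$theta <- policy$theta + if (toward_forward) g else -g
  policy$theta <- min(max(policy$theta, -4), 4)
  policy
}

#' Cleft geometry
#'
#' The tilted-cleft force field: confinement force falls linearly with the
#' larva's distance from the slit. The gradient is `k * tan(tilt)` when not
#' given explicitly (force change per mm of travel for a body of elastic
#' coefficient `k` under a cleft of the given apex angle), and zero when
#' `tilt_deg = 0` (horizontal coverslip).
#'
#' @param tilt_deg Cleft apex angle (degrees, default 3).
#' @param baseline_force Initial confinement force at the starting position
#'   (mN; the assay uses 25/50/75/100).
#' @param force_gradient Force per distance (mN/mm, >= 0) or `NULL` to derive
#'   from `tilt_deg` and the larva's `k`.
#' @param slit_position Coordinate of the slit (mm).
#' @param start_distance Larva's starting distance from the slit (mm).
#' @return An object of class `cleft_geometry`.
#' @export
cleft_geometry <- function(tilt_deg = 3, baseline_force = 25,
                           force_gradient = NULL, slit_position = 0,
                           start_distance = 10) {
  if (baseline_force < 0) stop("cleft_geometry: baseline_force must be >= 0")
  if (!is.null(force_gradient)) {
    if (force_gradient < 0) stop("cleft_geometry: force_gradient must be >= 0")
    if (tilt_deg == 0 && force_gradient != 0)
      stop("cleft_geometry: tilt_deg = 0 implies force_gradient = 0")
  }
  structure(list(tilt_deg = tilt_deg, baseline_force = baseline_force,
                 force_gradient = force_gradient,
                 slit_position = slit_position,
                 start_distance = start_distance),
            class = "cleft_geometry")
}

resolve_gradient <- function(geometry, params) {
  if (!is.null(geometry$force_gradient)) return(geometry$force_gradient)
  if (geometry$tilt_deg == 0) return(0)
  params$elastic_coefficient_k * tanpi(geometry$tilt_deg / 180)
}

#' Confinement force at a position in the cleft
#'
#' Linear force field: `force(x) = baseline + gradient * (x0 - x)`, clamped at
#' zero, where `x` is the distance from the slit and `x0` the trial's starting
#' distance. Strictly non-increasing in `x` when the gradient is positive;
#' returns the baseline at the starting position.
#'
#' @param geometry A `cleft_geometry`.
#' @param params A `larva_params` (used to derive the gradient from `k` when
#'   `force_gradient` is `NULL`).
#' @param x Distance from the slit (mm, >= 0). Vectorized.
#' @return Force in mN (never negative).
#' @export
force_from_position <- function(geometry, params, x) {
  if (any(x < 0)) stop("force_from_position: x must be >= 0")
  g <- resolve_gradient(geometry, params)
  pmax(0, geometry$baseline_force + g * (geometry$start_distance - x))
}

#' Synthesize one force-wave increment profile
#'
#' Canonical wave shape: a raised-cosine rise from 0 to the transient peak over
#' the first 60% of the wave, followed by a normalized exponential relaxation
#' that lands exactly on the net offset (`peak_delta`). The profile is an
#' increment relative to the pre-wave plateau.
#'
#' @param direction `"forward"` or `"backward"` (shape is shared; the net
#'   offset's sign carries the direction).
#' @param peak_delta Net force offset after the wave (mN; e.g. +3 forward,
#'   -7 backward).
#' @param duration Wave duration (s, > dt).
#' @param dt Sample interval (s, > 0).
#' @param amplitude Transient excursion above the plateau (mN); defaults to
#'   `1.6 * |peak_delta|`.
#' @return Numeric vector of `round(duration/dt)` force increments; the last
#'   sample equals `peak_delta`, and the maximum excursion is at least
#'   `|peak_delta|`.
#' @export
synthesize_wave_profile <- function(direction = c("forward", "backward"),
                                    peak_delta, duration, dt,
                                    amplitude = 1.6 * abs(peak_delta)) {
  direction <- match.arg(direction)
  if (dt <= 0) stop("synthesize_wave_profile: dt must be > 0")
  if (duration <= dt)
    stop("synthesize_wave_profile: duration must exceed dt")
  n <- max(2L, round(duration / dt))
  top <- max(amplitude, peak_delta, 0)
  rise_n <- max(1L, round(0.6 * n))
  rise_n <- min(rise_n, n - 1L)
  rise <- top * (1 - cos(pi * seq_len(rise_n) / rise_n)) / 2
  relax_n <- n - rise_n
  j <- seq_len(relax_n)
  e <- exp(-5 * j / relax_n)
  eN <- e[relax_n]
  decay <- if (relax_n > 1L) (e - eN) / (1 - eN) else 0
  relax <- peak_delta + (top - peak_delta) * decay
  c(rise, relax)
}

#' Draw a per-wave behaviour sequence from a policy
#'
#' Draws `n_waves` decisions in `{forward, backward, pause}` from the policy's
#' current probabilities using R's global random stream (seed the stream for
#' reproducibility).
#'
#' @param policy A `locomotion_policy`.
#' @param n_waves Number of draws (>= 0).
#' @return Character vector of decisions.
#' @export
sample_behavior_sequence <- function(policy, n_waves) {
  stopifnot(inherits(policy, "locomotion_policy"), n_waves >= 0)
  if (n_waves == 0L) return(character())
  pr <- policy_probs(policy)
  sample(names(pr), n_waves, replace = TRUE, prob = pr)
}

# truncated-normal draw (rejection with analytic fallback for sd = 0)
rtnorm1 <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(min(max(mean, lower), upper))
  for (i in 1:1000) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
  min(max(mean, lower), upper)
}

#' Simulate one cleft-assay trial
#'
#' Builds a complete synthetic trial: a 5 s linear ramp to the baseline force,
#' a policy-driven sequence of peristaltic force waves (raised-cosine rise,
#' exponential partial relaxation, net offset per wave) separated by
#' inter-wave plateaus, plus Gaussian sensor noise. The trial is truncated as
#' soon as the (noiseless) force drops below 5 mN — loss of mechanical
#' engagement — and flagged. Ground-truth waves and the matching behaviour
#' annotations are returned alongside the trace.
#'
#' Per-trial draw order under `seed`: forward amplitude, backward amplitude,
#' then per event (delay, decision, duration, net increment), then sensor
#' noise.
#'
#' @param params A `larva_params`.
#' @param geometry A `cleft_geometry`.
#' @param duration_s Total trial length incl. the 5 s ramp (s, > 5;
#'   default 125 = ramp + 120 s observation window).
#' @param sample_rate_hz Sampling rate (Hz; default 100).
#' @param seed Integer seed; the trial is bit-reproducible given the seed.
#' @return An object of class `simulated_trial`: list with `force_trace`
#'   (`force_trace`), `behavior` (`behavior_track`), `truth` (data.frame:
#'   `wave_id`, `direction`, `start_s`, `end_s`, `peak_s`, `peak_mN`,
#'   `net_mN`), `terminated_early`, `seed`, `params`, `geometry`.
#' @export
simulate_trial <- function(params, geometry, duration_s = 125,
                           sample_rate_hz = 100, seed = 1) {
  stopifnot(inherits(params, "larva_params"), inherits(geometry, "cleft_geometry"))
  if (duration_s <= 5) stop("simulate_trial: duration_s must exceed the 5 s ramp")
  if (sample_rate_hz <= 0) stop("simulate_trial: sample_rate_hz must be > 0")
  set.seed(as.integer(seed))
  dt <- 1 / sample_rate_hz
  n <- floor(duration_s / dt) + 1L
  tt <- (seq_len(n) - 1L) * dt
  g <- resolve_gradient(geometry, params)
  baseline <- geometry$baseline_force

  amp_f <- rtnorm1(params$forward_amplitude_mean, params$forward_amplitude_sd,
                   lower = 0.4 * params$forward_amplitude_mean)
  amp_b <- rtnorm1(params$backward_amplitude_mean, params$backward_amplitude_sd,
                   lower = 0.4 * params$backward_amplitude_mean)

  force <- numeric(n)
  ramp_idx <- tt <= 5
  force[ramp_idx] <- baseline * tt[ramp_idx] / 5
  plateau <- baseline
  x <- geometry$start_distance
  t_cursor <- 5
  cut_index <- NA_integer_
  truth <- list()
  wave_id <- 0L
  fill_from <- function(i0, val) if (i0 <= n) force[i0:n] <<- val
  fill_from(sum(ramp_idx) + 1L, plateau)

  repeat {
    delay <- rtnorm1(params$inter_wave_delay_mean, params$inter_wave_delay_sd,
                     lower = 0.5)
    decision <- sample_behavior_sequence(params$policy, 1L)
    if (decision == "pause") {
      t_cursor <- t_cursor + delay
      if (t_cursor > duration_s) break
      next
    }
    forward <- decision == "forward"
    dur <- if (forward)
      rtnorm1(params$forward_wave_duration_mean, params$forward_wave_duration_sd,
              lower = 1)
    else
      rtnorm1(params$backward_wave_duration_mean, params$backward_wave_duration_sd,
              lower = 1)
    start_t <- t_cursor + delay
    if (start_t + dur > duration_s) break
    inc <- if (forward)
      rtnorm1(params$forward_increment_mean, params$forward_increment_sd,
              lower = if (g > 0) 1e-6 else -plateau)
    else
      rtnorm1(params$backward_increment_mean, params$backward_increment_sd,
              lower = -plateau, upper = if (g > 0) -1e-6 else Inf)
    amp <- if (forward) amp_f else amp_b
    prof <- synthesize_wave_profile(decision, inc, dur, dt, amplitude = amp)
    i0 <- round(start_t / dt) + 1L
    i1 <- min(n, i0 + length(prof) - 1L)
    force[i0:i1] <- plateau + prof[seq_len(i1 - i0 + 1L)]
    new_plateau <- plateau + inc
    fill_from(i1 + 1L, new_plateau)
    wave_id <- wave_id + 1L
    top <- max(prof)
    truth[[wave_id]] <- data.frame(
      wave_id = wave_id,
      direction = decision,
      start_s = (i0 - 1L) * dt,
      end_s = (i1 - 1L) * dt,
      peak_s = (i0 - 1L + which.max(prof) - 1L) * dt,
      peak_mN = plateau + top,
      net_mN = inc
    )
    # loss of mechanical engagement: force below 5 mN terminates the trial
    low <- which(force[i0:n] < 5)
    if (length(low)) { cut_index <- i0 + low[1L] - 1L; break }
    plateau <- new_plateau
    x <- if (g > 0) x - inc / g
         else if (forward) x - params$advance_per_forward_wave
         else x + params$retreat_per_backward_wave
    t_cursor <- start_t + dur
  }

  terminated_early <- !is.na(cut_index)
  if (terminated_early) {
    force <- force[seq_len(max(cut_index, 2L))]
    tt <- tt[seq_along(force)]
  }
  if (params$noise_sd > 0)
    force <- force + stats::rnorm(length(force), 0, params$noise_sd)

  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(wave_id = integer(), direction = character(), start_s = numeric(),
               end_s = numeric(), peak_s = numeric(), peak_mN = numeric(),
               net_mN = numeric())
  if (terminated_early && nrow(truth)) {
    truth$end_s <- pmin(truth$end_s, tt[length(tt)])
  }
  trace <- force_trace(force, sample_interval = dt, start_time = 0,
                       meta = list(source = "simulate_trial",
                                   baseline_force = baseline, seed = seed))
  track <- behavior_track(truth[c("wave_id", "direction", "start_s", "end_s")])
  structure(list(force_trace = trace, behavior = track, truth = truth,
                 terminated_early = terminated_early, seed = as.integer(seed),
                 params = params, geometry = geometry),
            class = "simulated_trial")
}

#' @export
print.simulated_trial <- function(x, ...) {
  cat(sprintf("<simulated_trial> seed %d, baseline %.0f mN, %d truth waves%s\n",
              x$seed, x$geometry$baseline_force, nrow(x$truth),
              if (x$terminated_early) " (terminated early: force < 5 mN)" else ""))
  invisible(x)
}

#' Write a simulated trial to disk
#'
#' Writes the force trace CSV (`time_s,force_mN`), behaviour events CSV
#' (`wave_id,direction,start_s,end_s`), ground-truth CSV, and a JSON sidecar
#' of parameters, geometry and seed.
#'
#' @param trial A `simulated_trial`.
#' @param dir Output directory (created if missing).
#' @param stem File-name stem (default `"trial"`).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_trial <- function(trial, dir, stem = "trial") {
  stopifnot(inherits(trial, "simulated_trial"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    trace = file.path(dir, paste0(stem, "_trace.csv")),
    behavior = file.path(dir, paste0(stem, "_behavior.csv")),
    truth = file.path(dir, paste0(stem, "_truth.csv")),
    sidecar = file.path(dir, paste0(stem, "_params.json"))
  )
  write_force_csv(trial$force_trace, paths[["trace"]])
  write_behavior_csv(trial$behavior, paths[["behavior"]])
  utils::write.csv(format(trial$truth, digits = 10, trim = TRUE),
                   paths[["truth"]], row.names = FALSE, quote = FALSE)
  side <- list(seed = trial$seed,
               terminated_early = trial$terminated_early,
               params = unclass(trial$params)[!vapply(trial$params, is.list, TRUE)],
               policy = unclass(trial$params$policy),
               geometry = unclass(trial$geometry))
  jsonlite::write_json(side, paths[["sidecar"]], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}
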