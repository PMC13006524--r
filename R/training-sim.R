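#' Closed-loop training configuration
#'
#' Protocol constants of the operant force-feedback training: a 100 mN initial
#' confinement force; each peristaltic wave triggers an immediate commanded
#' change of 20 mN (decrease for the rewarded direction, increase for the
#' other); the session ends when the commanded force reaches 0 mN; the whole
#' session is run twice; trained larvae are then tested once under a 25 mN
#' initial force for 120 s with the platform locked (no feedback).
#'
#' @param mode `"pro_forward"` (forward rewarded), `"pro_backward"` (backward
#'   rewarded), or `"naive"` (no feedback).
#' @param initial_force Session starting force (mN, >= 0; default 100).
#' @param step Per-wave commanded change (mN, > 0; default 20).
#' @param sessions Number of training sessions (default 2); the commanded
#'   force resets to `initial_force` at the start of each, policy state
#'   persists across sessions.
#' @param controller_refresh_hz Platform refresh rate (Hz; default 5).
#' @param controller_settle_s Time for a commanded change to complete (s;
#'   default 0.2). Commanded transitions are linear over this interval.
#' @param test_force Test-session initial force (mN; default 25).
#' @param test_duration_s Test-session length (s; default 120).
#' @param max_session_s Safety cap on a training session (s; default 1800);
#'   sessions cut here are flagged `max_time`.
#' @return An object of class `training_config`.
#' @export
training_config <- function(mode = c("pro_forward", "pro_backward", "naive"),
                            initial_force = 100, step = 20, sessions = 2,
                            controller_refresh_hz = 5, controller_settle_s = 0.2,
                            test_force = 25, test_duration_s = 120,
                            max_session_s = 1800) {
  mode <- match.arg(mode)
  if (step <= 0) stop("training_config: step must be > 0")
  if (initial_force < 0) stop("training_config: initial_force must be >= 0")
  if (sessions < 1) stop("training_config: sessions must be >= 1")
  structure(list(mode = mode, initial_force = initial_force, step = step,
                 sessions = sessions, controller_refresh_hz = controller_refresh_hz,
                 controller_settle_s = controller_settle_s,
                 test_force = test_force, test_duration_s = test_duration_s,
                 max_session_s = max_session_s),
            class = "training_config")
}

#' Apply per-wave force feedback
#'
#' The controller rule of the training protocol: under pro-forward training a
#' forward wave triggers a `step` decrease and a backward wave a `step`
#' increase of the commanded force; pro-backward mirrors the rule; naive
#' leaves the force unchanged. The result is clamped at 0 mN.
#'
#' @param commanded Current commanded force (mN, >= 0).
#' @param wave_direction `"forward"` or `"backward"`.
#' @param mode `"pro_forward"`, `"pro_backward"` or `"naive"`.
#' @param step Feedback step (mN; default 20).
#' @return New commanded force (mN).
#' @export
#' @examples
#' apply_feedback(100, "forward", "pro_forward")  # 80
apply_feedback <- function(commanded, wave_direction, mode, step = 20) {
  if (any(commanded < 0)) stop("apply_feedback: commanded must be >= 0")
  if (!wave_direction %in% c("forward", "backward"))
    stop("apply_feedback: unknown wave direction '", wave_direction, "'")
  delta <- switch(mode,
    pro_forward = if (wave_direction == "forward") -step else step,
    pro_backward = if (wave_direction == "backward") -step else step,
    naive = 0,
    stop("apply_feedback: unknown mode '", mode, "'")
  )
  pmax(0, commanded + delta)
}

# one policy-driven wave event at the event level: returns direction
# ("forward"/"backward"/"pause"), its duration, and the preceding delay
draw_event <- function(params) {
  delay <- rtnorm1(params$inter_wave_delay_mean, params$inter_wave_delay_sd,
                   lower = 0.5)
  decision <- sample_behavior_sequence(params$policy, 1L)
  dur <- if (decision == "forward")
    rtnorm1(params$forward_wave_duration_mean, params$forward_wave_duration_sd,
            lower = 1)
  else if (decision == "backward")
    rtnorm1(params$backward_wave_duration_mean, params$backward_wave_duration_sd,
            lower = 1)
  else 0
  list(delay = delay, direction = decision, duration = dur)
}

#' Run one closed-loop training session
#'
#' Event-level simulation of a training session: the virtual larva emits waves
#' per its (reward-updated) locomotion policy; at the end of each wave the
#' commanded force changes by the feedback rule, completing within the
#' controller's settle time; the session ends when the commanded force reaches
#' 0 mN (or at the safety cap, flagged). Policy updates persist: the returned
#' object carries the post-session larva.
#'
#' @param larva A `larva_params` (its `policy` carries learning state).
#' @param config A `training_config`.
#' @return An object of class `training_log`: list with `log` (data.frame:
#'   `time_s`, `direction`, `commanded_before`, `commanded_after`), `reason`
#'   (`"reached_zero"` or `"max_time"`), and `larva` (post-session params).
#'   Uses R's global random stream; seed it for reproducibility.
#' @export
run_training_session <- function(larva, config) {
  stopifnot(inherits(larva, "larva_params"), inherits(config, "training_config"))
  commanded <- config$initial_force
  t <- 0
  rows <- list()
  reason <- "max_time"
  i <- 0L
  while (t < config$max_session_s) {
    ev <- draw_event(larva)
    t <- t + ev$delay + ev$duration
    if (t >= config$max_session_s) break
    if (ev$direction == "pause") next
    before <- commanded
    commanded <- apply_feedback(commanded, ev$direction, config$mode, config$step)
    i <- i + 1L
    rows[[i]] <- data.frame(time_s = t, direction = ev$direction,
                            commanded_before = before,
                            commanded_after = commanded)
    # the reward signal the larva experiences is the commanded change
    larva$policy <- update_policy(larva$policy, ev$direction,
                                  commanded - before)
    if (commanded <= 0) { reason <- "reached_zero"; break }
  }
  log <- if (length(rows)) do.call(rbind, rows) else
    data.frame(time_s = numeric(), direction = character(),
               commanded_before = numeric(), commanded_after = numeric())
  structure(list(log = log, reason = reason, larva = larva, config = config),
            class = "training_log")
}

#' Exclusion decision for a training log
#'
#' Pro-forward training excludes a larva that (a) exhibited 5 or more
#' consecutive backward waves, each immediately following a commanded-force
#' increase with no intervening forward wave (the commanded state before the
#' session's first wave counts as an increase — the initial force
#' application), or (b) showed no peristaltic activity at all. Pro-backward
#' training excludes only on no activity. Naive larvae are never excluded.
#'
#' @param log A `training_log` (or a list of them, one per session).
#' @param mode Training mode; defaults to the log's own config mode.
#' @return A list: `excluded` (logical) and `rule` (`"consecutive_backward"`,
#'   `"no_activity"`, or `NA`).
#' @export
check_exclusion <- function(log, mode = NULL) {
  logs <- if (inherits(log, "training_log")) list(log) else log
  if (is.null(mode)) mode <- logs[[1L]]$config$mode
  if (mode == "naive") return(list(excluded = FALSE, rule = NA_character_))
  n_waves <- sum(vapply(logs, function(l) nrow(l$log), integer(1)))
  if (n_waves == 0L) return(list(excluded = TRUE, rule = "no_activity"))
  if (mode == "pro_forward") {
    for (l in logs) {
      df <- l$log
      run <- 0L
      last_increase <- TRUE  # initial force application counts as an increase
      for (i in seq_len(nrow(df))) {
        if (df$direction[i] == "backward" && last_increase) run <- run + 1L
        else run <- 0L
        if (run >= 5L)
          return(list(excluded = TRUE, rule = "consecutive_backward"))
        last_increase <- df$commanded_after[i] > df$commanded_before[i]
      }
    }
  }
  list(excluded = FALSE, rule = NA_character_)
}

#' Run the post-training test session
#'
#' One feedback-free measurement trial at the test force (platform locked):
#' the larva crawls for `test_duration_s` and its forward and backward
#' peristaltic waves are counted. The larva's post-training policy state is
#' used as is.
#'
#' @param larva A `larva_params` (post-training).
#' @param config A `training_config`.
#' @return A list: `n_forward`, `n_backward`. Uses R's global random stream.
#' @export
run_test_session <- function(larva, config) {
  t <- 0
  nf <- 0L; nb <- 0L
  while (TRUE) {
    ev <- draw_event(larva)
    t <- t + ev$delay + ev$duration
    if (t > config$test_duration_s) break
    if (ev$direction == "forward") nf <- nf + 1L
    else if (ev$direction == "backward") nb <- nb + 1L
  }
  list(n_forward = nf, n_backward = nb)
}

#' Simulate a full training experiment
#'
#' For each requested group (naive / pro_forward / pro_backward): simulate
#' `n_per_group` larvae, each undergoing the configured number of training
#' sessions (commanded force resets per session, policy persists) followed by
#' one test session. Larvae meeting an exclusion rule are replaced by fresh
#' seeds, up to a cap of `5 * n_per_group` attempts per group (flagged when
#' exceeded).
#'
#' @param modes Character vector of group modes.
#' @param n_per_group Larvae per group (default 10).
#' @param seed Top-level seed; per-larva seeds are derived from it.
#' @param larva Template `larva_params` for every larva (its
#'   `policy$reward_sensitivity` controls whether training can have an effect).
#' @param config_fn Function `mode -> training_config` (default:
#'   `training_config(mode)`).
#' @return A list of class `training_experiment`: `per_larva` (data.frame:
#'   `mode`, `larva`, `seed`, `n_forward`, `n_backward`, `n_excluded_before`),
#'   `summary` (per-mode mean and sd of test counts), `cap_exceeded`.
#' @export
run_experiment <- function(modes = c("naive", "pro_forward", "pro_backward"),
                           n_per_group = 10, seed = 1,
                           larva = larva_params(policy = locomotion_policy(
                             p_forward = 0.5, p_pause = 0.1,
                             reward_sensitivity = 0.5)),
                           config_fn = function(mode) training_config(mode)) {
  set.seed(as.integer(seed))
  rows <- list(); r <- 0L
  cap_exceeded <- FALSE
  if (n_per_group > 0) {
    for (mode in modes) {
      config <- config_fn(mode)
      seeds <- sample.int(2^31 - 1L, 5L * n_per_group)
      got <- 0L; tried <- 0L; skipped <- 0L
      while (got < n_per_group && tried < length(seeds)) {
        tried <- tried + 1L
        set.seed(seeds[tried])
        subj <- larva
        logs <- list()
        if (mode != "naive") {
          for (s in seq_len(config$sessions)) {
            tl <- run_training_session(subj, config)
            subj <- tl$larva
            logs[[s]] <- tl
          }
          exc <- check_exclusion(logs, mode)
          if (exc$excluded) { skipped <- skipped + 1L; next }
        }
        test <- run_test_session(subj, config)
        got <- got + 1L; r <- r + 1L
        rows[[r]] <- data.frame(mode = mode, larva = got, seed = seeds[tried],
                                n_forward = test$n_forward,
                                n_backward = test$n_backward,
                                n_excluded_before = skipped)
      }
      if (got < n_per_group) cap_exceeded <- TRUE
    }
  }
  per_larva <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mode = character(), larva = integer(), seed = integer(),
               n_forward = integer(), n_backward = integer(),
               n_excluded_before = integer())
  summary <- if (nrow(per_larva)) {
    do.call(rbind, lapply(split(per_larva, per_larva$mode), function(d)
      data.frame(mode = d$mode[1L], n = nrow(d),
                 forward_mean = mean(d$n_forward), forward_sd = stats::sd(d$n_forward),
                 backward_mean = mean(d$n_backward), backward_sd = stats::sd(d$n_backward))))
  } else {
    data.frame(mode = character(), n = integer(), forward_mean = numeric(),
               forward_sd = numeric(), backward_mean = numeric(),
               backward_sd = numeric())
  }
  rownames(summary) <- NULL
  structure(list(per_larva = per_larva, summary = summary,
                 cap_exceeded = cap_exceeded, seed = as.integer(seed)),
            class = "training_experiment")
}

#' @export
print.training_experiment <- function(x, ...) {
  cat("<training_experiment>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a training log as CSV
#' @param log A `training_log`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_training_log_csv <- function(log, path) {
  stopifnot(inherits(log, "training_log"))
  utils::write.csv(format(log$log, digits = 10, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
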