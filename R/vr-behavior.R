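# Virtual-reality task computations: tail kinematics, feedback dynamics,
# trial outcome rules, the behavioral learning criterion, halt metrics and
# the environment regressors B(t)/R(t).

#' Tail bend angle from a body centerline
#'
#' The camera views the fish along the vertical image axis; the five
#' uppermost centerline points define the (vertical) body axis and a straight
#' line is fitted through the five lowermost points. The bend is the
#' inclination of that lower segment away from the body axis (0 degrees when
#' the tail is straight), signed by the bend direction, minus a reference
#' angle that absorbs any per-fish resting bias.
#'
#' @param centerline matrix of (x, y) points ordered head to tail (y grows
#'   tailwards); at least 10 points
#' @param reference_angle rolling reference angle (degrees) to subtract,
#'   typically from [rolling_reference()]
#' @return tail bend angle in degrees
#' @export
tail_angle <- function(centerline, reference_angle = 0) {
  centerline <- as.matrix(centerline)
  if (nrow(centerline) < 10L) stop("centerline needs at least 10 points")
  lower <- centerline[(nrow(centerline) - 4L):nrow(centerline), , drop = FALSE]
  if (stats::sd(lower[, 2]) == 0) stop("degenerate lower centerline points")
  # fit x as a function of y: slope = deviation from the vertical body axis
  fit <- stats::lm.fit(cbind(1, lower[, 2]), lower[, 1])
  slope <- fit$coefficients[2]
  raw <- atan(slope) * 180 / pi
  unname(raw - reference_angle)
}

#' Rolling reference angle for tail-bend de-biasing
#'
#' Mean of the raw tail angles over a trailing time window (default 10 s),
#' used as the per-sample reference subtracted from the raw bend.
#'
#' @param angles raw tail angles, degrees
#' @param rate sampling rate, Hz
#' @param window window length, seconds
#' @return vector of reference angles, same length as `angles`
#' @export
rolling_reference <- function(angles, rate = 10, window = 10) {
  n <- length(angles)
  w <- max(1L, round(window * rate))
  cs <- cumsum(angles)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - w + 1L)
    out[i] <- (cs[i] - if (j > 1L) cs[j - 1L] else 0) / (i - j + 1L)
  }
  out
}

#' Tail-beat frequency from the last second of tail angles
#'
#' Discrete Fourier transform of the current and nine previous tail angle
#' samples (1 s at 10 Hz); the dominant non-DC bin gives the frequency.
#'
#' @param angle_history numeric vector of tail angles; the last 10 samples
#'   are used
#' @param rate sampling rate, Hz (default 10)
#' @return frequency in Hz (0 for constant input or fewer than 10 samples,
#'   with a warning in the latter case)
#' @export
tail_frequency <- function(angle_history, rate = 10) {
  n_req <- 10L
  if (length(angle_history) < n_req) {
    warning("fewer than 10 samples; returning 0 Hz")
    return(0)
  }
  a <- utils::tail(angle_history, n_req)
  sp <- Mod(stats::fft(a))
  bins <- 2:(n_req %/% 2 + 1)  # non-DC up to Nyquist
  amps <- sp[bins]
  if (max(amps) < 1e-9 * max(1, Mod(sp[1]))) return(0)
  k <- which.max(amps)
  k * rate / n_req
}

#' Advance the virtual position by one time step
#'
#' Forward speed is tail-beat frequency times the feedback gain; gain 0 is
#' the open-loop condition in which tail beats move nothing.
#'
#' @param position current position, distance units
#' @param frequency tail-beat frequency, Hz
#' @param gain feedback gain (>= 0)
#' @param dt step duration, seconds
#' @return new position
#' @export
step_environment <- function(position, frequency, gain, dt) {
  if (gain < 0) stop("gain must be >= 0")
  position + frequency * gain * dt
}

#' Classify the outcome of one trial
#'
#' GO success is a correct escape: the goal (red region at `blue_length`)
#' is reached within the trial limit. NOGO success is a correct stay: no
#' tail beats (frequency at or above the halt threshold) during the limit.
#' Failure triggers a shock at the end of the trial when shocks are enabled.
#'
#' @param trace a `behavior_trace`
#' @param trial one row of the schedule (list or one-row data frame)
#' @return a `trial_outcome` list with `trial`, `type`, `success`, `latency`
#'   (seconds, NA when the goal is not reached), `shock` and `halts`
#'   (matrix of halt-segment start/end times within the trial)
#' @export
classify_trial <- function(trace, trial) {
  config <- attr(trace, "config")
  goal <- config$blue_length
  thr <- config$halt_threshold
  idx <- which(trace$time >= trial$onset & trace$time < trial$onset + trial$limit)
  if (!length(idx)) stop("trial window outside the trace")
  freq <- trace$frequency[idx]
  pos <- trace$position[idx]
  tt <- trace$time[idx]
  if (trial$type == "GO") {
    reached <- which(pos >= goal)
    success <- length(reached) > 0L
    latency <- if (success) tt[reached[1L]] - trial$onset else NA_real_
  } else {
    success <- !any(freq >= thr)
    latency <- NA_real_
  }
  shock_on <- if (!is.null(trial$shock_on)) isTRUE(trial$shock_on) else TRUE
  runs <- true_runs(freq < thr)
  halts <- cbind(start = tt[runs[, "start"]], end = tt[runs[, "end"]])
  structure(list(trial = trial$trial, type = trial$type,
                 success = success, latency = latency,
                 shock = !success && shock_on, halts = halts),
            class = "trial_outcome")
}

#' Classify all trials of a session
#'
#' @param trace a `behavior_trace`
#' @param schedule the matching `trial_schedule`
#' @return data frame with one row per trial: `trial`, `phase`, `type`,
#'   `gain`, `success`, `latency`, `shock`
#' @export
classify_trials <- function(trace, schedule) {
  rows <- lapply(seq_len(nrow(schedule)), function(i) {
    o <- classify_trial(trace, schedule[i, ])
    data.frame(trial = o$trial, phase = schedule$phase[i], type = o$type,
               gain = schedule$gain[i], success = o$success,
               latency = o$latency, shock = o$shock,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Behavioral learning criterion
#'
#' The fish counts as a learner at the earliest trial where the success rate
#' over the past ten trials is at least 80 percent for GO and for NOGO
#' simultaneously.
#'
#' @param outcomes data frame with time-ordered `type` and `success` columns
#'   (and optionally `trial` for the returned index)
#' @param rate required trailing success rate (default 0.8)
#' @param window trailing window per trial type (default 10)
#' @return the trial index (from `outcomes$trial`, else the row number) at
#'   which the criterion is first met, or `NA` if never
#' @export
learning_criterion <- function(outcomes, rate = 0.8, window = 10L) {
  ids <- if (!is.null(outcomes$trial)) outcomes$trial else seq_len(nrow(outcomes))
  hist_go <- logical(0); hist_nogo <- logical(0)
  for (i in seq_len(nrow(outcomes))) {
    if (outcomes$type[i] == "GO") hist_go <- c(hist_go, outcomes$success[i])
    else hist_nogo <- c(hist_nogo, outcomes$success[i])
    if (length(hist_go) >= window && length(hist_nogo) >= window) {
      ok_go <- mean(utils::tail(hist_go, window)) >= rate
      ok_nogo <- mean(utils::tail(hist_nogo, window)) >= rate
      if (ok_go && ok_nogo) return(ids[i])
    }
  }
  NA_integer_
}

#' Halt metrics of a successful GO trial
#'
#' Between trial onset and goal arrival, a halt is a maximal run of frames
#' with tail frequency below the halt threshold. Returns the total halt
#' period, the number of halts, and the movement period; halt plus movement
#' equals the latency.
#'
#' @param trace a `behavior_trace`
#' @param trial one schedule row; must be a successful GO trial
#' @return list with `halt_period`, `halt_count`, `movement_period`,
#'   `latency` (all periods in seconds)
#' @export
halt_metrics <- function(trace, trial) {
  out <- classify_trial(trace, trial)
  if (trial$type != "GO" || !out$success) {
    stop("halt metrics are defined only for successful GO trials")
  }
  config <- attr(trace, "config")
  dt <- 1 / config$frame_rate
  idx <- which(trace$time >= trial$onset &
                 trace$time < trial$onset + out$latency)
  halted <- trace$frequency[idx] < config$halt_threshold
  runs <- true_runs(halted)
  halt_period <- sum(halted) * dt
  list(halt_period = halt_period,
       halt_count = nrow(runs),
       movement_period = out$latency - halt_period,
       latency = out$latency)
}

#' Environment regressors B(t) and R(t)
#'
#' Binary indicators of the fish being in the blue / red region, on the
#' trace's own time base or resampled (piecewise constant) onto `times`.
#' B and R are never both 1; during the white inter-trial interval both are 0.
#'
#' @param trace a `behavior_trace`
#' @param times optional time base to resample onto
#' @return list with `time`, `B`, `R`
#' @export
environment_regressors <- function(trace, times = NULL) {
  B <- as.numeric(trace$color == "blue")
  R <- as.numeric(trace$color == "red")
  if (is.null(times)) return(list(time = trace$time, B = B, R = R))
  f <- function(v) stats::approx(trace$time, v, xout = times,
                                 method = "constant", rule = 2)$y
  list(time = times, B = f(B), R = f(R))
}
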