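# Synthetic sessions: trial schedules and scripted fish behavior.
#
# A session follows the GO/NOGO active/passive avoidance design: in a GO
# trial the near background turns blue and the fish must swim forward to the
# red goal region within the trial limit; in a NOGO trial the near background
# is red and the fish must stay still. Failure triggers a shock at the end of
# the trial. Tail-beat frequency times the gain gives the forward speed in
# the one-dimensional virtual track (gain 0 = open loop).

#' Session configuration
#'
#' Bundle of task parameters describing one virtual-reality avoidance
#' experiment. The training session has `n_trials` trials arranged in blocks
#' of `block_size`, each block holding exactly `trials_per_type_per_block`
#' GO and NOGO trials in random order. An adaptation session (no shocks) may
#' precede training and an open-loop session (gain 0) may follow it.
#'
#' @param n_trials number of training trials (default 60)
#' @param block_size trials per randomized block (default 20)
#' @param trials_per_type_per_block GO (and NOGO) trials per block (default 10)
#' @param trial_limit trial duration in seconds (default 10)
#' @param iti inter-trial interval in seconds (default 15)
#' @param gain feedback gain: forward speed = tail frequency x gain
#'   (distance units per second per Hz); 10 closed loop, 0 open loop
#' @param frame_rate sampling rate of behavior and neural traces, Hz
#'   (about 3 for three-plane imaging)
#' @param rule `"original"` (blue dangerous) or `"reversed"`
#' @param n_adaptation adaptation trials before training (no shock; default 20)
#' @param n_openloop open-loop trials after training (gain 0; default 20)
#' @param blue_length length of the near (start-color) region in distance
#'   units; the goal region begins at this position
#' @param halt_threshold tail frequency below which the fish counts as
#'   halted, Hz
#' @param swim_freq typical tail-beat frequency of a swimming fish, Hz
#' @param seed session seed fanned out to all named substreams
#' @return an object of class `session_config`
#' @export
session_config <- function(n_trials = 60L, block_size = 20L,
                           trials_per_type_per_block = 10L,
                           trial_limit = 10, iti = 15, gain = 10,
                           frame_rate = 3, rule = c("original", "reversed"),
                           n_adaptation = 20L, n_openloop = 20L,
                           blue_length = 60, halt_threshold = 0.1,
                           swim_freq = 2.5, seed = 1L) {
  rule <- match.arg(rule)
  if (n_trials %% block_size != 0L) {
    stop("n_trials must be divisible by block_size")
  }
  if (block_size != 2L * trials_per_type_per_block) {
    stop("block_size must equal 2 * trials_per_type_per_block")
  }
  if (gain < 0) stop("gain must be >= 0")
  if (trial_limit <= 0) stop("trial_limit must be positive")
  structure(list(
    n_trials = as.integer(n_trials), block_size = as.integer(block_size),
    trials_per_type_per_block = as.integer(trials_per_type_per_block),
    trial_limit = trial_limit, iti = iti, gain = gain,
    frame_rate = frame_rate, rule = rule,
    n_adaptation = as.integer(n_adaptation),
    n_openloop = as.integer(n_openloop),
    blue_length = blue_length, halt_threshold = halt_threshold,
    swim_freq = swim_freq, seed = seed
  ), class = "session_config")
}

balanced_blocks <- function(n_trials, block_size, per_type) {
  n_blocks <- n_trials %/% block_size
  unlist(lapply(seq_len(n_blocks), function(b) {
    sample(rep(c("GO", "NOGO"), each = per_type))
  }))
}

#' Generate a balanced GO/NOGO trial schedule
#'
#' Draws the trial-type sequence block by block so that every block of
#' `block_size` trials contains exactly `trials_per_type_per_block` GO and
#' NOGO trials, and lays trials out in time separated by the trial limit
#' plus the inter-trial interval.
#'
#' @param config a [session_config()]
#' @param phase label attached to every trial: `"adaptation"`, `"training"`
#'   or `"openloop"`; adaptation trials have shocks disabled and open-loop
#'   trials have gain 0
#' @param n_trials number of trials (defaults to the phase's configured size)
#' @param t_start time of the first trial onset minus one ITI, seconds
#' @param first_trial global index of the first trial
#' @param seed seed for the block randomization (defaults to the config seed)
#' @return a `trial_schedule` data frame with columns `trial`, `phase`,
#'   `block`, `type`, `onset`, `limit`, `gain`, `rule`, `shock_on`
#' @export
generate_schedule <- function(config, phase = c("training", "adaptation", "openloop"),
                              n_trials = NULL, t_start = 0, first_trial = 1L,
                              seed = config$seed) {
  stopifnot(inherits(config, "session_config"))
  phase <- match.arg(phase)
  if (is.null(n_trials)) {
    n_trials <- switch(phase,
      training = config$n_trials,
      adaptation = config$n_adaptation,
      openloop = config$n_openloop
    )
  }
  n_trials <- as.integer(n_trials)
  if (n_trials %% config$block_size != 0L) {
    stop("n_trials must be divisible by block_size")
  }
  types <- with_substream(seed, paste0("schedule-", phase),
    balanced_blocks(n_trials, config$block_size, config$trials_per_type_per_block))
  period <- config$trial_limit + config$iti
  onsets <- t_start + config$iti + (seq_len(n_trials) - 1L) * period
  sched <- data.frame(
    trial = first_trial + seq_len(n_trials) - 1L,
    phase = phase,
    block = (seq_len(n_trials) - 1L) %/% config$block_size + 1L,
    type = types,
    onset = onsets,
    limit = config$trial_limit,
    gain = if (phase == "openloop") 0 else config$gain,
    rule = config$rule,
    shock_on = phase != "adaptation",
    stringsAsFactors = FALSE
  )
  attr(sched, "config") <- config
  class(sched) <- c("trial_schedule", "data.frame")
  sched
}

#' Generate the full experiment schedule
#'
#' Concatenates the adaptation session (no shocks), the training session and
#' the open-loop session (gain 0) on one time axis.
#'
#' @param config a [session_config()]
#' @return a `trial_schedule` covering all phases
#' @export
generate_experiment <- function(config) {
  period <- config$trial_limit + config$iti
  parts <- list()
  t0 <- 0; id0 <- 1L
  for (ph in c("adaptation", "training", "openloop")) {
    n <- switch(ph, adaptation = config$n_adaptation,
                training = config$n_trials, openloop = config$n_openloop)
    if (n == 0L) next
    parts[[ph]] <- generate_schedule(config, phase = ph, n_trials = n,
                                     t_start = t0, first_trial = id0)
    t0 <- t0 + n * period
    id0 <- id0 + n
  }
  out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  attr(out, "config") <- config
  class(out) <- c("trial_schedule", "data.frame")
  out
}

#' Simulate scripted fish behavior for a schedule
#'
#' Stand-in fish used to make every downstream stage testable. Three
#' policies are provided: `"naive"` never beats its tail; `"learner"`
#' behaves naively until `onset_trial` training trials have elapsed and then
#' swims to the goal in GO trials with probability `go_success_rate` while
#' staying still in NOGO trials; `"learner_with_halts"` additionally pauses
#' mid-swim for about `halt_duration` seconds in successful GO trials.
#' Position integrates frequency x gain over time within each trial
#' (forward only); open-loop trials have gain 0 so position never moves.
#'
#' @param schedule a `trial_schedule`
#' @param policy one of `"naive"`, `"learner"`, `"learner_with_halts"`
#' @param seed seed for behavioral randomness (defaults to the config seed)
#' @param onset_trial number of training trials after which the learner
#'   policies express the learned behavior
#' @param go_success_rate fraction of learned GO trials the fish executes;
#'   the remainder (every `round(1 / (1 - go_success_rate))`-th learned GO
#'   trial) are freezes that fail, so failed post-learning GO trials are
#'   guaranteed to occur at the configured rate
#' @param spont_bout_prob probability of a short spontaneous swim bout in an
#'   unlearned trial
#' @param halt_duration halt length inserted by `learner_with_halts`, seconds
#' @return a `behavior_trace` data frame sampled at the config frame rate
#'   with columns `frame`, `time`, `trial`, `phase`, `type`, `frequency`,
#'   `position`, `color`, `shock`
#' @export
simulate_agent_behavior <- function(schedule,
                                    policy = c("learner_with_halts", "learner", "naive"),
                                    seed = NULL, onset_trial = 10L,
                                    go_success_rate = 0.9,
                                    spont_bout_prob = 0.2,
                                    halt_duration = 2) {
  policy <- match.arg(policy)
  config <- attr(schedule, "config")
  stopifnot(inherits(config, "session_config"))
  if (is.null(seed)) seed <- config$seed
  fr <- config$frame_rate
  dt <- 1 / fr
  t_end <- max(schedule$onset + schedule$limit) + config$iti
  n_frames <- ceiling(t_end * fr)
  time <- (seq_len(n_frames) - 1L) * dt

  trace <- data.frame(
    frame = seq_len(n_frames), time = time,
    trial = NA_integer_, phase = NA_character_, type = NA_character_,
    frequency = 0, position = 0, color = "white", shock = FALSE,
    stringsAsFactors = FALSE
  )

  fail_every <- if (go_success_rate >= 1) Inf else
    max(2L, round(1 / (1 - go_success_rate)))

  with_substream(seed, paste0("behavior-", policy), {
    n_training_seen <- 0L
    n_learned_go <- 0L
    for (i in seq_len(nrow(schedule))) {
      tr <- schedule[i, ]
      idx <- which(time >= tr$onset & time < tr$onset + tr$limit)
      if (!length(idx)) next
      nf <- length(idx)
      if (tr$phase == "training") n_training_seen <- n_training_seen + 1L
      learned <- policy != "naive" &&
        ((tr$phase == "training" && n_training_seen > onset_trial) ||
           tr$phase == "openloop")

      freq <- numeric(nf)
      if (learned && tr$type == "GO") {
        n_learned_go <- n_learned_go + 1L
        if (n_learned_go %% fail_every != 0) {
          freq <- pmax(stats::rnorm(nf, config$swim_freq, 0.15), 1)
          if (policy == "learner_with_halts") {
            h0 <- min(nf, 1L + round(1 * fr))
            h1 <- min(nf, h0 + max(1L, round(halt_duration * fr)) - 1L)
            freq[h0:h1] <- 0
          }
        } # else: freeze -> failure
      } else if (policy != "naive" && !learned &&
                 stats::runif(1) < spont_bout_prob) {
        # short spontaneous bout that does not reach the goal
        b0 <- sample.int(max(nf - 2L, 1L), 1L)
        b1 <- min(nf, b0 + round(1 * fr))
        freq[b0:b1] <- pmax(stats::rnorm(b1 - b0 + 1L, 1.5, 0.2), 0.5)
      }

      # integrate forward-only motion, stop at the goal
      pos <- cumsum(freq * tr$gain * dt)
      reached <- which(pos >= config$blue_length)
      if (length(reached)) {
        k <- reached[1L]
        pos[pos > config$blue_length] <- config$blue_length
        if (k < nf) freq[(k + 1L):nf] <- 0
      }

      col <- if (tr$type == "GO") {
        ifelse(pos < config$blue_length, "blue", "red")
      } else {
        ifelse(pos < config$blue_length, "red", "blue")
      }

      trace$trial[idx] <- tr$trial
      trace$phase[idx] <- tr$phase
      trace$type[idx] <- tr$type
      trace$frequency[idx] <- freq
      trace$position[idx] <- pos
      trace$color[idx] <- col

      failed <- if (tr$type == "GO") !length(reached) else
        any(freq >= config$halt_threshold)
      if (failed && tr$shock_on) {
        shock_at <- which(time >= tr$onset + tr$limit)[1]
        if (is.na(shock_at)) shock_at <- n_frames
        trace$shock[shock_at] <- TRUE
      }
    }
  })

  attr(trace, "config") <- config
  attr(trace, "schedule") <- schedule
  class(trace) <- c("behavior_trace", "data.frame")
  trace
}
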