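# Rate-coding network model of the GO task: a blue-perceiving input drives a
# swim ensemble through a plastic synapse W; plasticity is gated by a
# reward-prediction error (RPE, evaluated at trial outcome) and optionally by
# a scenery-flow prediction error (SFPE, evaluated at every step).
#
# Per step t (logistic sigmoid `sig`, ReLU = max(x, 0)):
#   x_SF(t)   = sig(W x_BP(t - t_l) - h)          swim drive
#   Prob(swim at t) = x_SF(t - t_l)
#   x_SFP(t)  = sig(U x_BP(t) - h')               scenery-flow prediction
#   x_SFPE(t) = ReLU(x_SFP(t) - x_BF(t))          flow prediction error
#   with SFPE: W <- W + eta_SFPE x_SFPE(t)
# At trial end (punishment p = 1 on failure, 0 on success):
#   x_RP  = sig(V x_BP(t_init) - h'')             punishment prediction
#   x_RPE = ReLU(x_RP - p)
#   W <- W + eta_RPE x_RPE;  U <- U + eta' x_RPE;  V <- V - eta'' x_RPE
# x_BP = 1 while the fish sees blue (before the goal), x_BF = 1 on steps
# where a swim was executed in closed loop (backward scenery flow sensed).

#' Simulator parameters
#'
#' Defaults follow the published constants: h = 2.4, t_l = 10 steps,
#' eta_RPE = 0.2, eta_SFPE = 0.002, h' = 6, eta' = 1.6, h'' = 4,
#' eta'' = 1.6, W = U = 0 and V = 8 initially, 100 steps per trial.
#' A swim step advances the position by `step_size` distance units (default
#' 4) and the goal sits `goal_distance` units ahead (default 30), so the
#' goal takes on the order of ten swim decisions: few enough that a naive
#' agent occasionally reaches it by chance (otherwise the
#' reward-prediction-error rule, which only updates on success, could never
#' bootstrap), yet enough that halting in blue remains a meaningful
#' behavioral readout.
#'
#' @param h swim-ensemble firing threshold
#' @param t_l sensory delay in steps
#' @param eta_rpe,eta_sfpe learning rates of the two error signals
#' @param h_prime,eta_prime threshold and learning rate of the
#'   scenery-flow prediction
#' @param h_dprime,eta_dprime threshold and learning rate of the
#'   punishment prediction
#' @param W0,U0,V0 initial synaptic strengths
#' @param steps_per_trial steps per trial (must exceed `t_l`)
#' @param goal_distance distance to the red goal, units
#' @param step_size distance advanced per executed swim step
#' @param with_sfpe enable the per-step SFPE-gated update of W
#' @param closed_loop when FALSE (open loop) swims move nothing and no
#'   backward flow is sensed (x_BF = 0)
#' @return a `model_params` list
#' @export
model_params <- function(h = 2.4, t_l = 10L, eta_rpe = 0.2, eta_sfpe = 0.002,
                         h_prime = 6, eta_prime = 1.6, h_dprime = 4,
                         eta_dprime = 1.6, W0 = 0, U0 = 0, V0 = 8,
                         steps_per_trial = 100L, goal_distance = 30,
                         step_size = 4, with_sfpe = TRUE,
                         closed_loop = TRUE) {
  if (any(c(eta_rpe, eta_sfpe, eta_prime, eta_dprime) < 0)) {
    stop("learning rates must be >= 0")
  }
  if (steps_per_trial <= t_l) stop("steps_per_trial must exceed t_l")
  structure(list(h = h, t_l = as.integer(t_l), eta_rpe = eta_rpe,
                 eta_sfpe = eta_sfpe, h_prime = h_prime,
                 eta_prime = eta_prime, h_dprime = h_dprime,
                 eta_dprime = eta_dprime, W0 = W0, U0 = U0, V0 = V0,
                 steps_per_trial = as.integer(steps_per_trial),
                 goal_distance = goal_distance, step_size = step_size,
                 with_sfpe = with_sfpe, closed_loop = closed_loop),
            class = "model_params")
}

#' Initial model state
#' @param params a [model_params()]
#' @return list with synaptic strengths `W`, `U`, `V`
#' @export
init_state <- function(params) {
  list(W = params$W0, U = params$U0, V = params$V0)
}

#' End-of-trial plasticity update
#'
#' Evaluates the reward-prediction error once per trial: on success
#' (punishment p = 0) `x_RPE = x_RP = sig(V - h'') > 0`, potentiating W and U
#' and depressing V; on failure (p = 1) `x_RPE = ReLU(x_RP - 1) = 0` and
#' nothing changes. Because V decreases with every success, x_RP and hence
#' the RPE self-extinguish under repeated success.
#'
#' @param state list with `W`, `U`, `V`
#' @param params a [model_params()]
#' @param success logical trial outcome
#' @return list with the updated state and `x_rp`, `x_rpe`
#' @export
end_of_trial_update <- function(state, params, success) {
  p <- as.numeric(!success)
  x_rp <- sigmoid(state$V * 1 - params$h_dprime)  # x_BP(t_init) = 1
  x_rpe <- relu(x_rp - p)
  state$W <- state$W + params$eta_rpe * x_rpe
  state$U <- state$U + params$eta_prime * x_rpe
  state$V <- state$V - params$eta_dprime * x_rpe
  list(state = state, x_rp = x_rp, x_rpe = x_rpe)
}

#' Run one trial of the simulated GO task
#'
#' Steps the network for up to `steps_per_trial` steps or until the goal is
#' reached. The swim decision at step t is Bernoulli with probability
#' `x_SF(t - t_l)`; x_BP history before the trial is zero (white
#' inter-trial interval). Halt steps are stop decisions taken while the fish
#' is still in blue. The end-of-trial RPE update is applied before
#' returning.
#'
#' @param state list with `W`, `U`, `V`
#' @param params a [model_params()]
#' @return list with `state`, `log` (per-step data frame with `x_bp`,
#'   `x_sf`, `p_swim`, `swim`, `x_bf`, `x_sfp`, `x_sfpe`, `position`),
#'   `success`, `halt_steps`, `steps`, `mean_sfpe`, `x_rpe`
#' @export
run_trial <- function(state, params) {
  n <- params$steps_per_trial
  tl <- params$t_l
  x_bp <- numeric(n); x_sf <- numeric(n); p_swim <- numeric(n)
  swim <- logical(n); x_bf <- numeric(n); x_sfp <- numeric(n)
  x_sfpe <- numeric(n); position <- numeric(n)
  pos <- 0; halt_steps <- 0L; t_end <- n
  lag <- function(v, t, k) if (t - k >= 1L) v[t - k] else 0
  for (t in seq_len(n)) {
    x_bp[t] <- as.numeric(pos < params$goal_distance)
    x_sf[t] <- sigmoid(state$W * lag(x_bp, t, tl) - params$h)
    p_swim[t] <- if (t - tl >= 1L) x_sf[t - tl] else sigmoid(-params$h)
    swim[t] <- stats::runif(1) < p_swim[t]
    if (swim[t] && params$closed_loop && x_bp[t] == 1) {
      pos <- pos + params$step_size
    }
    x_bf[t] <- as.numeric(swim[t] && params$closed_loop)
    x_sfp[t] <- sigmoid(state$U * x_bp[t] - params$h_prime)
    x_sfpe[t] <- relu(x_sfp[t] - x_bf[t])
    if (params$with_sfpe) {
      state$W <- state$W + params$eta_sfpe * x_sfpe[t]
    }
    if (!swim[t] && x_bp[t] == 1) halt_steps <- halt_steps + 1L
    position[t] <- pos
    if (pos >= params$goal_distance) { t_end <- t; break }
  }
  keep <- seq_len(t_end)
  success <- pos >= params$goal_distance
  upd <- end_of_trial_update(state, params, success)
  list(state = upd$state,
       log = data.frame(step = keep, x_bp = x_bp[keep], x_sf = x_sf[keep],
                        p_swim = p_swim[keep], swim = swim[keep],
                        x_bf = x_bf[keep], x_sfp = x_sfp[keep],
                        x_sfpe = x_sfpe[keep], position = position[keep]),
       success = success, halt_steps = halt_steps, steps = t_end,
       mean_sfpe = mean(x_sfpe[keep]), x_rpe = upd$x_rpe)
}

#' Train an agent over many trials and seeds
#'
#' Repeats the GO task for `n_trials` trials from a fresh state per seed and
#' records per-trial halt steps, mean SFPE activity, success, and synaptic
#' strengths.
#'
#' @param params a [model_params()]
#' @param n_trials trials per run (default 100)
#' @param n_seeds independent runs (default 20)
#' @param seed base seed; run s uses substream `seed + s`
#' @return a `sim_training` list: `per_trial` (long data frame with `seed`,
#'   `trial`, `halt_steps`, `mean_sfpe`, `success`, `W`, `U`, `V`, `x_rpe`),
#'   `summary` (per-trial means over seeds), `params`
#' @export
run_training <- function(params, n_trials = 100L, n_seeds = 20L, seed = 1L) {
  rows <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    rows[[s]] <- with_substream(seed + s, "sim-training", {
      state <- init_state(params)
      out <- vector("list", n_trials)
      for (k in seq_len(n_trials)) {
        tr <- run_trial(state, params)
        state <- tr$state
        out[[k]] <- data.frame(seed = s, trial = k,
                               halt_steps = tr$halt_steps,
                               mean_sfpe = tr$mean_sfpe,
                               success = tr$success, W = state$W,
                               U = state$U, V = state$V, x_rpe = tr$x_rpe)
      }
      do.call(rbind, out)
    })
  }
  per_trial <- do.call(rbind, rows)
  summary <- stats::aggregate(
    per_trial[, c("halt_steps", "mean_sfpe", "success")],
    by = list(trial = per_trial$trial), FUN = mean)
  structure(list(per_trial = per_trial, summary = summary, params = params),
            class = "sim_training")
}
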