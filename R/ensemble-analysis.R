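# Neural-ensemble analysis: template matching, NMF with AIC order
# selection, the pairwise-swap shuffle null, candidate screening against the
# environment regressors and the flow-chart ensemble classifier.

#' @useDynLib fishvr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Build a GO or NOGO activity template
#'
#' Element-wise mean of the neurons x window activity over the initial
#' `window` seconds of every successful trial of the given type occurring
#' after the behavioral learning criterion was met (training phase only).
#'
#' @param dff matrix neurons x frames of dF/F0
#' @param times frame times, seconds
#' @param schedule `trial_schedule`
#' @param outcomes per-trial outcomes from [classify_trials()]
#' @param learn_trial trial index at which the learning criterion was met
#'   (see [learning_criterion()])
#' @param type `"GO"` or `"NOGO"`
#' @param window template length, seconds (default 2)
#' @return a `template` matrix (neurons x window frames) with attributes
#'   `type` and `n_trials`
#' @export
build_template <- function(dff, times, schedule, outcomes, learn_trial,
                           type = c("GO", "NOGO"), window = 2) {
  type <- match.arg(type)
  if (is.na(learn_trial)) stop("learning criterion never met; no template")
  dt <- stats::median(diff(times))
  wlen <- max(1L, round(window / dt))
  qual <- schedule$trial[schedule$phase == "training" &
                           schedule$type == type &
                           schedule$trial > learn_trial]
  qual <- qual[qual %in% outcomes$trial[outcomes$success]]
  if (!length(qual)) stop("no qualifying successful post-criterion trials")
  wins <- lapply(qual, function(id) {
    onset <- schedule$onset[schedule$trial == id]
    i0 <- which(times >= onset)[1]
    dff[, i0:(i0 + wlen - 1L), drop = FALSE]
  })
  tmpl <- Reduce(`+`, wins) / length(wins)
  attr(tmpl, "type") <- type
  attr(tmpl, "n_trials") <- length(qual)
  class(tmpl) <- c("activity_template", class(tmpl))
  tmpl
}

#' Similarity trace of a template over a session
#'
#' Pearson correlation between the vectorized template and the vectorized
#' sliding window of the same length at every start frame; values range from
#' -1 (anti-correlation) to +1 (perfect correlation). Zero-variance windows
#' give 0.
#'
#' @param dff matrix neurons x frames
#' @param template matrix neurons x window frames
#' @return numeric vector of length frames - window + 1
#' @export
similarity_trace <- function(dff, template) {
  if (nrow(dff) != nrow(template)) stop("neuron dimension mismatch")
  wlen <- ncol(template)
  nt <- ncol(dff)
  if (nt <= wlen) stop("dff shorter than the template window")
  tv <- as.vector(template)
  tc <- tv - mean(tv)
  tn <- sqrt(sum(tc^2))
  if (tn == 0) stop("zero-variance template")
  n_start <- nt - wlen + 1L
  out <- numeric(n_start)
  for (s in seq_len(n_start)) {
    wv <- as.vector(dff[, s:(s + wlen - 1L)])
    wc <- wv - mean(wv)
    wn <- sqrt(sum(wc^2))
    out[s] <- if (wn == 0) 0 else sum(wc * tc) / (wn * tn)
  }
  pmin(pmax(out, -1), 1)  # guard floating-point overshoot
}

#' Non-negative matrix factorization of population activity
#'
#' Factorizes the non-negative data matrix D (neurons x time) as D ~ P T by
#' minimizing the squared Frobenius error with multiplicative updates (a
#' gradient-descent family). `restarts` independent attempts start from
#' random non-negative P and T; the attempt with the smallest error wins.
#' Columns of P are neural ensembles, rows of T their activation time
#' courses.
#'
#' @param D non-negative matrix neurons x time (clip negative dF/F0 to zero
#'   beforehand, e.g. `pmax(D, 0)`)
#' @param k number of ensembles (at most `min(dim(D))`)
#' @param restarts independent random initializations (default 5)
#' @param max_iter maximum iterations per attempt (default 4000)
#' @param tol stop when the relative error change between checks falls
#'   below this value
#' @param check_every iterations between error evaluations
#' @param seed seed for the random initializations
#' @return an `nmf_result`: `P`, `T`, `error`, `k`, `restart_errors`,
#'   `error_trace` (best attempt), `iterations`
#' @export
nmf_factorize <- function(D, k, restarts = 5L, max_iter = 4000L, tol = 1e-6,
                          check_every = 10L, seed = NULL) {
  D <- as.matrix(D)
  if (any(D < 0)) stop("D must be non-negative; clip negative values first")
  if (k > min(dim(D))) stop("k exceeds min(dim(D))")
  scale0 <- sqrt(mean(D) / k + 1e-12)
  best <- NULL
  restart_errors <- numeric(restarts)
  with_substream(seed, "nmf", {
    for (r in seq_len(restarts)) {
      P0 <- matrix(stats::runif(nrow(D) * k, 0, 2 * scale0), nrow(D), k)
      T0 <- matrix(stats::runif(k * ncol(D), 0, 2 * scale0), k, ncol(D))
      fit <- .nmf_mu(D, P0, T0, as.integer(max_iter), tol,
                     as.integer(check_every))
      restart_errors[r] <- fit$error
      if (is.null(best) || fit$error < best$error) best <- fit
    }
  })
  structure(list(P = best$P, T = best$T, error = best$error, k = as.integer(k),
                 restart_errors = restart_errors,
                 error_trace = best$error_trace,
                 iterations = best$iterations),
            class = "nmf_result")
}

#' AIC over the factorization
#'
#' Gaussian-residual form: `AIC(k) = N log(Error / N) + 2 k (n + t)` with
#' `N = n t` for an n x t data matrix.
#'
#' @param error squared Frobenius reconstruction error
#' @param k model order
#' @param dims `dim(D)`
#' @return AIC value
#' @export
nmf_aic <- function(error, k, dims) {
  N <- prod(dims)
  N * log(error / N) + 2 * k * sum(dims)
}

#' Select the NMF order by AIC
#'
#' Fits every order in `k_range` and picks the AIC minimizer. The scan uses
#' lighter optimizer settings than [nmf_factorize()]'s defaults because order
#' selection needs the error magnitude, not a polished optimum; pass
#' `restarts` / `max_iter` to override.
#'
#' @param D non-negative matrix neurons x time
#' @param k_range candidate orders
#' @param seed seed
#' @param restarts,max_iter,tol optimizer settings per order
#' @return an `aic_selection`: `k` (selected order), `aic` (data frame with
#'   `k`, `error`, `aic`), `fit` (the selected `nmf_result`)
#' @export
select_order_aic <- function(D, k_range = 2:6, seed = NULL, restarts = 3L,
                             max_iter = 600L, tol = 1e-5) {
  if (!length(k_range)) stop("k_range is empty")
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    fits[[i]] <- nmf_factorize(D, k_range[i], restarts = restarts,
                               max_iter = max_iter, tol = tol,
                               seed = if (is.null(seed)) NULL
                                      else seed + 1000L * i)
  }
  tab <- data.frame(
    k = k_range,
    error = vapply(fits, `[[`, numeric(1), "error"),
    aic = vapply(seq_along(fits), function(i)
      nmf_aic(fits[[i]]$error, k_range[i], dim(D)), numeric(1))
  )
  best <- which.min(tab$aic)
  structure(list(k = k_range[best], aic = tab, fit = fits[[best]]),
            class = "aic_selection")
}

#' Pairwise-swap shuffle of neural activity
#'
#' For every neuron, two time points are chosen at random and their values
#' swapped; the process is repeated n times, where n is the timeline length.
#' The per-neuron value multiset is preserved while temporal structure is
#' destroyed.
#'
#' @param D matrix neurons x time
#' @param seed seed
#' @return shuffled matrix, same dimensions
#' @export
shuffle_activity <- function(D, seed = NULL) {
  n <- ncol(D)
  with_substream(seed, "shuffle", {
    for (r in seq_len(nrow(D))) {
      i <- sample.int(n, n, replace = TRUE)
      j <- sample.int(n, n, replace = TRUE)
      x <- D[r, ]
      for (s in seq_len(n)) {
        tmp <- x[i[s]]; x[i[s]] <- x[j[s]]; x[j[s]] <- tmp
      }
      D[r, ] <- x
    }
    D
  })
}

#' Screen NMF activations against the environment regressors
#'
#' An ensemble is a candidate when the Pearson correlation of its activation
#' time course with B(t) or R(t) is strictly greater than the threshold
#' (default 0.25). Zero-variance rows are excluded.
#'
#' @param Tmat matrix k x time of NMF activations
#' @param B,R environment regressors on the same time base
#' @param threshold selection threshold (default 0.25)
#' @return data frame with `ensemble`, `cor_b`, `cor_r`, `candidate`
#' @export
candidate_ensembles <- function(Tmat, B, R, threshold = 0.25) {
  stopifnot(ncol(Tmat) == length(B), length(B) == length(R))
  k <- nrow(Tmat)
  cb <- cr <- rep(NA_real_, k)
  for (i in seq_len(k)) {
    if (stats::sd(Tmat[i, ]) == 0) next
    cb[i] <- stats::cor(Tmat[i, ], B)
    cr[i] <- stats::cor(Tmat[i, ], R)
  }
  data.frame(ensemble = seq_len(k), cor_b = cb, cor_r = cr,
             candidate = !is.na(cb) & (cb > threshold | cr > threshold))
}

#' Per-trial peak activation
#'
#' For each selected trial, the maximum of the (self-maximum normalized)
#' activation while the fish perceives the trial's start color (blue in GO,
#' red in NOGO), or over the post-goal red window when
#' `window = "post_goal"`.
#'
#' @param activation activation time course on the behavior time base
#' @param behavior `behavior_trace`
#' @param schedule `trial_schedule`
#' @param trials trial ids to quantify
#' @param window `"start"` or `"post_goal"` (GO trials only)
#' @param normalize divide by the session maximum first (default TRUE)
#' @return named numeric vector of peaks (NA when a trial has no such window)
#' @export
trial_peaks <- function(activation, behavior, schedule, trials,
                        window = c("start", "post_goal"), normalize = TRUE) {
  window <- match.arg(window)
  if (normalize && max(activation) > 0) {
    activation <- activation / max(activation)
  }
  out <- vapply(trials, function(id) {
    row <- schedule[schedule$trial == id, ]
    start_col <- if (row$type == "GO") "blue" else "red"
    want_col <- if (window == "start") start_col else "red"
    if (window == "post_goal" && row$type != "GO") return(NA_real_)
    idx <- which(!is.na(behavior$trial) & behavior$trial == id &
                   behavior$color == want_col)
    if (!length(idx)) return(NA_real_)
    max(activation[idx])
  }, numeric(1))
  names(out) <- trials
  out
}

# Epoch-wise peak statistics backing the classifier.
ensemble_epoch_stats <- function(activation, behavior, schedule, outcomes,
                                 learn_trial) {
  st <- function(sel, window = "start") {
    ids <- schedule$trial[sel]
    if (!length(ids)) return(NA_real_)
    mean(trial_peaks(activation, behavior, schedule, ids, window),
         na.rm = TRUE)
  }
  training <- schedule$phase == "training"
  post <- training & !is.na(learn_trial) & schedule$trial > learn_trial
  succ <- schedule$trial %in% outcomes$trial[outcomes$success]
  go <- schedule$type == "GO"; nogo <- !go
  adapt <- schedule$phase == "adaptation"
  open <- schedule$phase == "openloop"
  init <- training & schedule$trial <= sort(schedule$trial[training])[
    min(10L, sum(training))]
  list(
    blue_adapt = st(adapt & go),
    blue_init = st(init & go),
    blue_post_success = st(post & go & succ),
    blue_post_fail = st(post & go & !succ),
    blue_open = st(open & go),
    red_adapt = st(adapt & nogo),
    red_nogo_post = st(post & nogo),
    red_post = mean(c(st(post & nogo),
                      st(post & go & succ, "post_goal")), na.rm = TRUE),
    n_open_go = sum(open & go)
  )
}

#' Classify a candidate ensemble
#'
#' Reconstruction of the identification flow chart from the reported
#' activation signatures, applied to one candidate activation course:
#' * active in blue already during adaptation (and still later) ->
#'   `blue_perception`;
#' * silent during adaptation, active in blue in successful post-criterion
#'   GO trials -> `blue_dangerous_rule`;
#' * silent during adaptation, active in red (NOGO start, GO goal) after
#'   training -> `red_safe_rule`;
#' * active in open-loop GO and failed closed-loop GO but not successful
#'   closed-loop GO -> `sfpe`;
#' * otherwise `unclassified`.
#'
#' "Active" means the epoch mean of per-trial normalized peaks exceeds
#' `act_threshold`; rule/SFPE ensembles must additionally exceed
#' `rule_factor` times their adaptation-epoch baseline. Ensembles without
#' color specificity are abandoned: a blue label requires the defining blue
#' epoch to exceed `spec_factor` times the activity during clean red
#' exposure (NOGO start color), and conversely for the red label. The
#' specificity contrast uses the NOGO red windows rather than the post-goal
#' window because calcium decay after a blue period bleeds into the latter.
#' When the session has no open-loop GO trials the SFPE label is unavailable
#' and flagged.
#'
#' @param activation activation time course on the behavior time base
#' @param behavior `behavior_trace`
#' @param schedule `trial_schedule`
#' @param outcomes per-trial outcomes ([classify_trials()])
#' @param learn_trial learning-criterion trial ([learning_criterion()])
#' @param cor_b,cor_r correlations with B(t)/R(t); computed from `behavior`
#'   when missing
#' @param act_threshold absolute activity threshold on normalized peaks
#' @param rule_factor required fold change over the adaptation baseline
#' @param spec_factor required fold change of the defining color's activity
#'   over the opposite color's
#' @param baseline_floor floor for baselines in the fold tests
#' @return an `ensemble_label` list: `label`, `evidence` (epoch stats),
#'   `cor_b`, `cor_r`, `sfpe_available`
#' @export
classify_ensemble <- function(activation, behavior, schedule, outcomes,
                              learn_trial, cor_b = NULL, cor_r = NULL,
                              act_threshold = 0.3, rule_factor = 3,
                              spec_factor = 2, baseline_floor = 0.05) {
  if (is.null(cor_b) || is.null(cor_r)) {
    regs <- environment_regressors(behavior)
    cor_b <- suppressWarnings(stats::cor(activation, regs$B))
    cor_r <- suppressWarnings(stats::cor(activation, regs$R))
  }
  ev <- ensemble_epoch_stats(activation, behavior, schedule, outcomes,
                             learn_trial)
  sfpe_available <- ev$n_open_go > 0L
  active <- function(x) !is.na(x) && x > act_threshold
  elevated <- function(x, base) {
    !is.na(x) && x > rule_factor * max(base, baseline_floor, na.rm = TRUE)
  }
  specific <- function(x, other) {
    !is.na(x) && x > spec_factor * max(other, baseline_floor, na.rm = TRUE)
  }

  label <- "unclassified"
  if (is.na(learn_trial)) {
    label <- "unclassified"
  } else if (!is.na(cor_r) && !is.na(cor_b) && cor_r > cor_b) {
    if (!active(ev$red_adapt) && active(ev$red_post) &&
        elevated(ev$red_post, ev$red_adapt) &&
        specific(ev$red_post, ev$blue_post_success)) {
      label <- "red_safe_rule"
    }
  } else {
    if (active(ev$blue_adapt) && active(ev$blue_post_success) &&
        specific(ev$blue_adapt, ev$red_adapt)) {
      label <- "blue_perception"
    } else if (!active(ev$blue_adapt)) {
      if (sfpe_available && active(ev$blue_open) &&
          active(ev$blue_post_fail) && !active(ev$blue_post_success) &&
          specific(ev$blue_open, ev$red_nogo_post)) {
        label <- "sfpe"
      } else if (active(ev$blue_post_success) &&
                 elevated(ev$blue_post_success, ev$blue_adapt) &&
                 specific(ev$blue_post_success, ev$red_nogo_post)) {
        label <- "blue_dangerous_rule"
      }
    }
  }
  structure(list(label = label, evidence = ev, cor_b = cor_b, cor_r = cor_r,
                 sfpe_available = sfpe_available),
            class = "ensemble_label")
}
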