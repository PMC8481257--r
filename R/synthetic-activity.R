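# Synthetic neural data with known ground truth: ensemble-structured dF/F0
# traces and raw fluorescence movies.

#' Ensemble specification for the activity generator
#'
#' Describes one embedded neural ensemble. Activation signatures:
#' * `blue_perception`: drive whenever the fish sees blue, from the very
#'   first trial (onset_trial must be 0);
#' * `blue_dangerous_rule`: drive in blue only once `onset_trial` training
#'   trials have elapsed;
#' * `red_safe_rule`: drive in red (NOGO start color and the GO goal region)
#'   only after `onset_trial`;
#' * `sfpe`: drive during the blue period of GO trials that either run in
#'   open loop (gain 0) or end in failure, after `onset_trial`; silent in
#'   successful closed-loop GO trials.
#'
#' @param label one of `"blue_perception"`, `"blue_dangerous_rule"`,
#'   `"red_safe_rule"`, `"sfpe"`
#' @param n_neurons member neurons
#' @param onset_trial training-trial index at which the signature appears
#'   (0 = from the start; required 0 for `blue_perception`, positive for the
#'   rule and SFPE ensembles)
#' @param amplitude sustained drive amplitude in dF/F0 units
#' @param spatial_center (x, y) center of the member cluster, micrometers
#' @param spatial_sd spatial spread of members, micrometers
#' @return an `ensemble_spec` list
#' @export
ensemble_spec <- function(label = c("blue_perception", "blue_dangerous_rule",
                                    "red_safe_rule", "sfpe"),
                          n_neurons = 10L, onset_trial = 0L, amplitude = 1,
                          spatial_center = c(192, 192), spatial_sd = 15) {
  label <- match.arg(label)
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (label == "blue_perception" && onset_trial != 0L) {
    stop("blue_perception must have onset_trial = 0")
  }
  if (label != "blue_perception" && onset_trial <= 0L) {
    stop("rule and sfpe ensembles must have onset_trial > 0")
  }
  structure(list(label = label, n_neurons = as.integer(n_neurons),
                 onset_trial = as.integer(onset_trial), amplitude = amplitude,
                 spatial_center = spatial_center, spatial_sd = spatial_sd),
            class = "ensemble_spec")
}

#' Default set of the four embedded ensembles
#'
#' @param n_neurons members per ensemble
#' @param amplitude drive amplitude
#' @param onset_trial onset (training trials) for the rule and SFPE ensembles
#' @param field_um imaged field width, micrometers
#' @return list of four [ensemble_spec()]s with spatially separated centers
#' @export
default_ensemble_specs <- function(n_neurons = 10L, amplitude = 1,
                                   onset_trial = 12L, field_um = 384.9) {
  q1 <- 0.25 * field_um; q3 <- 0.75 * field_um
  list(
    ensemble_spec("blue_perception", n_neurons, 0L, amplitude, c(q1, q1)),
    ensemble_spec("blue_dangerous_rule", n_neurons, onset_trial, amplitude, c(q3, q1)),
    ensemble_spec("red_safe_rule", n_neurons, onset_trial, amplitude, c(q1, q3)),
    ensemble_spec("sfpe", n_neurons, onset_trial, amplitude, c(q3, q3))
  )
}

# Per-frame drive of one ensemble spec, given behavior and trial outcomes.
ensemble_drive <- function(spec, trace, schedule, outcomes) {
  n <- nrow(trace)
  drive <- numeric(n)
  in_trial <- !is.na(trace$trial)
  # training-trial counter per trial id: adaptation = 0, openloop = Inf
  train_count <- ifelse(schedule$phase == "training",
                        cumsum(schedule$phase == "training"),
                        ifelse(schedule$phase == "openloop", Inf, 0))
  names(train_count) <- as.character(schedule$trial)
  post <- rep(FALSE, n)
  post[in_trial] <- train_count[as.character(trace$trial[in_trial])] >= spec$onset_trial
  if (spec$onset_trial == 0L) post <- in_trial

  if (spec$label == "blue_perception") {
    drive[in_trial & trace$color == "blue"] <- spec$amplitude
  } else if (spec$label == "blue_dangerous_rule") {
    drive[post & trace$color == "blue"] <- spec$amplitude
  } else if (spec$label == "red_safe_rule") {
    drive[post & trace$color == "red"] <- spec$amplitude
  } else { # sfpe
    qual <- outcomes$trial[outcomes$type == "GO" &
                             (outcomes$gain == 0 | !outcomes$success)]
    sel <- post & trace$color == "blue" & trace$type == "GO" &
      trace$trial %in% qual
    drive[which(sel)] <- spec$amplitude
  }
  drive
}

#' Generate ensemble-structured dF/F0 traces with ground truth
#'
#' Member neurons carry their ensemble's drive convolved with a
#' single-exponential calcium kernel (time constant `tau`), scaled by a
#' per-neuron weight, plus Gaussian noise; non-member neurons are pure
#' noise. Member centroids are drawn around the ensemble's spatial center so
#' that correlated neurons lie close together; the rest are uniform over the
#' imaged field.
#'
#' @param schedule a `trial_schedule`
#' @param behavior the matching `behavior_trace`
#' @param specs list of [ensemble_spec()]s (possibly empty)
#' @param n_neurons total neurons (default 300, about one imaging plane)
#' @param noise_sd Gaussian noise sd in dF/F0 units
#' @param tau calcium decay time constant, seconds
#' @param field_um imaged field width, micrometers
#' @param seed seed (defaults to the config seed)
#' @return list with `fluor` (a `fluor_matrix`: `dff` neurons x frames,
#'   `time`, `centroids` in micrometers, `plane`) and `truth` (membership
#'   weight matrix neurons x ensembles, labels, per-trial outcomes, drives)
#' @export
generate_activity <- function(schedule, behavior, specs,
                              n_neurons = 300L, noise_sd = 0.1,
                              tau = 1.5, field_um = 384.9, seed = NULL) {
  config <- attr(schedule, "config")
  if (is.null(seed)) seed <- config$seed
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  n_members <- sum(vapply(specs, function(s) s$n_neurons, integer(1)))
  if (n_members > n_neurons) stop("ensemble members exceed total neurons")

  outcomes <- classify_trials(behavior, schedule)
  n_frames <- nrow(behavior)
  dt <- 1 / config$frame_rate
  a <- exp(-dt / tau)

  drives <- vapply(specs, ensemble_drive, numeric(n_frames),
                   trace = behavior, schedule = schedule, outcomes = outcomes)
  drives <- matrix(drives, nrow = n_frames)
  # AR(1) calcium kernel, scaled so a sustained drive plateaus at `amplitude`
  signals <- apply(drives, 2, function(d) {
    as.numeric(stats::filter((1 - a) * d, a, method = "recursive"))
  })
  signals <- matrix(signals, nrow = n_frames)

  k <- length(specs)
  membership <- matrix(0, n_neurons, max(k, 1L))
  labels <- vapply(specs, `[[`, character(1), "label")
  if (k > 0) colnames(membership) <- labels

  with_substream(seed, "activity", {
    dff <- matrix(stats::rnorm(n_neurons * n_frames, 0, noise_sd),
                  n_neurons, n_frames)
    centroids <- matrix(stats::runif(n_neurons * 2, 0, field_um), n_neurons, 2)
    colnames(centroids) <- c("x_um", "y_um")
    at <- 0L
    for (j in seq_along(specs)) {
      s <- specs[[j]]
      rows <- at + seq_len(s$n_neurons)
      w <- stats::runif(s$n_neurons, 0.7, 1.3)
      membership[rows, j] <- w
      dff[rows, ] <- dff[rows, ] + outer(w, signals[, j])
      centroids[rows, 1] <- pmin(pmax(
        stats::rnorm(s$n_neurons, s$spatial_center[1], s$spatial_sd), 0), field_um)
      centroids[rows, 2] <- pmin(pmax(
        stats::rnorm(s$n_neurons, s$spatial_center[2], s$spatial_sd), 0), field_um)
      at <- at + s$n_neurons
    }
    fluor <- structure(list(dff = dff, time = behavior$time,
                            centroids = centroids,
                            plane = rep(1L, n_neurons)),
                       class = "fluor_matrix")
    list(fluor = fluor,
         truth = list(membership = membership, labels = labels,
                      outcomes = outcomes, drives = drives, specs = specs))
  })
}

#' Disk-shaped cell masks for movie synthesis
#'
#' Places `n_cells` non-overlapping disks of the given radius on the frame,
#' rejecting draws closer than `min_sep` pixels to an existing cell.
#'
#' @param n_cells number of cells
#' @param dim frame side length in pixels
#' @param radius disk radius in pixels
#' @param min_sep minimal center-to-center separation, pixels
#' @param seed seed
#' @return list with `masks` (list of two-column row/col pixel matrices) and
#'   `centroids_px` (n x 2 matrix)
#' @export
make_cell_masks <- function(n_cells, dim = 256L, radius = 3, min_sep = 12,
                            seed = 1L) {
  with_substream(seed, "masks", {
    centers <- matrix(NA_real_, n_cells, 2)
    placed <- 0L; tries <- 0L
    while (placed < n_cells && tries < 20000L) {
      tries <- tries + 1L
      p <- stats::runif(2, radius + 2, dim - radius - 1)
      if (placed == 0L ||
          min(sqrt(rowSums((centers[seq_len(placed), , drop = FALSE] -
                              matrix(p, placed, 2, byrow = TRUE))^2))) >= min_sep) {
        placed <- placed + 1L
        centers[placed, ] <- p
      }
    }
    if (placed < n_cells) stop("could not place all cells; reduce n_cells or min_sep")
    masks <- lapply(seq_len(n_cells), function(i) {
      cy <- centers[i, 1]; cx <- centers[i, 2]
      rr <- floor(cy - radius):ceiling(cy + radius)
      cc <- floor(cx - radius):ceiling(cx + radius)
      g <- expand.grid(row = rr, col = cc)
      g <- g[(g$row - cy)^2 + (g$col - cx)^2 <= radius^2, ]
      as.matrix(g)
    })
    list(masks = masks, centroids_px = centers)
  })
}

#' Render a fluorescence movie from masks and traces
#'
#' Frame t is the background plus, for every cell i, `baseline * (1 +
#' dff_i(t))` over the cell's mask, rigidly translated by the integer drift
#' of that frame, plus Gaussian noise. Pixels pushed outside the frame by
#' drift are dropped (with a warning when an entire cell leaves the frame).
#'
#' @param masks list of two-column row/col pixel matrices (see
#'   [make_cell_masks()])
#' @param traces matrix cells x frames of dF/F0 values
#' @param drift integer matrix frames x 2 of (dy, dx) shifts, or NULL
#' @param noise_sd Gaussian pixel noise sd
#' @param baseline cell baseline intensity
#' @param background background intensity
#' @param dim frame side length in pixels
#' @param seed seed
#' @return numeric array (dim x dim x frames) with attributes
#'   `pixel_size_um` (384.9 / dim) and `frame_period` (seconds)
#' @export
generate_movie <- function(masks, traces, drift = NULL, noise_sd = 2,
                           baseline = 100, background = 20, dim = 256L,
                           frame_period = 1 / 3, seed = 1L) {
  n_cells <- length(masks)
  stopifnot(nrow(traces) == n_cells)
  n_frames <- ncol(traces)
  if (is.null(drift)) drift <- matrix(0L, n_frames, 2)
  for (m in masks) {
    if (any(m < 1L) || any(m > dim)) stop("mask outside frame bounds")
  }
  movie <- array(0, c(dim, dim, n_frames))
  with_substream(seed, "movie", {
    for (t in seq_len(n_frames)) {
      fr <- matrix(background, dim, dim)
      dy <- drift[t, 1]; dx <- drift[t, 2]
      for (i in seq_len(n_cells)) {
        m <- masks[[i]]
        rr <- m[, 1] + dy; cc <- m[, 2] + dx
        keep <- rr >= 1L & rr <= dim & cc >= 1L & cc <= dim
        if (!any(keep)) {
          warning("drift pushed a cell entirely off-frame")
          next
        }
        fr[cbind(rr[keep], cc[keep])] <-
          fr[cbind(rr[keep], cc[keep])] + baseline * (1 + traces[i, t])
      }
      if (noise_sd > 0) {
        fr <- fr + matrix(stats::rnorm(dim * dim, 0, noise_sd), dim, dim)
      }
      movie[, , t] <- fr
    }
  })
  attr(movie, "pixel_size_um") <- 384.9 / dim
  attr(movie, "frame_period") <- frame_period
  movie
}

#' Transient-bearing cell traces for movie fixtures
#'
#' Poisson-timed calcium transients (exponential decay) per cell, in dF/F0
#' units; a convenience input for [generate_movie()].
#'
#' @param n_cells number of cells
#' @param n_frames frames
#' @param rate transient rate per frame
#' @param amplitude transient amplitude (dF/F0)
#' @param tau_frames decay constant in frames
#' @param seed seed
#' @return matrix cells x frames
#' @export
transient_traces <- function(n_cells, n_frames, rate = 0.03, amplitude = 1,
                             tau_frames = 5, seed = 1L) {
  a <- exp(-1 / tau_frames)
  with_substream(seed, "transients", {
    t(vapply(seq_len(n_cells), function(i) {
      ev <- stats::rbinom(n_frames, 1, rate) * amplitude
      as.numeric(stats::filter(ev, a, method = "recursive"))
    }, numeric(n_frames)))
  })
}
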