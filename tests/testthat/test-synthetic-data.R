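# Synthetic-data generator: schedules, scripted behavior, activity, movies.

test_that("schedules are balanced per block, deterministic, and validated", {
  cfg <- session_config(seed = 5)
  sched <- generate_schedule(cfg)
  expect_equal(nrow(sched), 60L)
  for (b in 1:3) {
    blk <- sched$type[sched$block == b]
    expect_equal(sum(blk == "GO"), 10L)
    expect_equal(sum(blk == "NOGO"), 10L)
  }
  # onsets separated by trial limit + ITI
  expect_true(all(abs(diff(sched$onset) - (cfg$trial_limit + cfg$iti)) < 1e-9))

  one_block <- generate_schedule(session_config(n_trials = 20L, seed = 5))
  expect_equal(nrow(one_block), 20L)
  expect_equal(sum(one_block$type == "GO"), 10L)

  again <- generate_schedule(cfg)
  expect_identical(sched$type, again$type)
  other <- generate_schedule(session_config(seed = 6))
  expect_false(identical(sched$type, other$type))

  expect_error(session_config(n_trials = 55L), "divisible")
})

test_that("experiment schedule concatenates phases with correct flags", {
  sched <- generate_experiment(small_config())
  expect_equal(unique(sched$phase), c("adaptation", "training", "openloop"))
  expect_true(all(!sched$shock_on[sched$phase == "adaptation"]))
  expect_true(all(sched$gain[sched$phase == "openloop"] == 0))
  expect_true(all(sched$gain[sched$phase == "training"] == 10))
  expect_true(all(diff(sched$onset) > 0))
})

test_that("naive policy never beats and gets shocked in GO trials", {
  cfg <- small_config()
  sched <- generate_schedule(cfg, phase = "training")
  beh <- simulate_agent_behavior(sched, policy = "naive", seed = 1)
  expect_true(all(beh$frequency == 0))
  out <- classify_trials(beh, sched)
  expect_true(all(!out$success[out$type == "GO"]))
  expect_true(all(out$shock[out$type == "GO"]))
  expect_true(all(out$success[out$type == "NOGO"]))
  # a shock lands at the end of every failed trial window
  go1 <- sched[sched$type == "GO", ][1, ]
  shock_t <- beh$time[beh$shock]
  expect_true(any(abs(shock_t - (go1$onset + go1$limit)) < 1e-9))
})

test_that("learner reaches the 80% trailing criterion after onset", {
  cfg <- session_config(seed = 3)
  sched <- generate_experiment(cfg)
  beh <- simulate_agent_behavior(sched, policy = "learner", seed = 3,
                                 onset_trial = 10L)
  out <- classify_trials(beh, sched)
  train <- out[out$phase == "training", ]
  go <- train$success[train$type == "GO"]
  # every trailing-10 window after learning holds at least 8 successes
  learned <- go[-(1:10)]
  trailing <- sapply(10:length(learned), function(i)
    mean(learned[(i - 9):i]))
  expect_true(all(trailing >= 0.8))
  expect_false(is.na(learning_criterion(train)))
})

test_that("open-loop gain keeps the position constant despite tail beats", {
  cfg <- small_config()
  sched <- generate_schedule(cfg, phase = "openloop")
  beh <- simulate_agent_behavior(sched, policy = "learner", seed = 2,
                                 onset_trial = 0L)
  go_frames <- !is.na(beh$trial) & beh$type == "GO"
  expect_true(any(beh$frequency[go_frames] > 0))   # the fish does beat
  expect_true(all(beh$position[go_frames] == 0))   # but moves nowhere
})

test_that("position is non-decreasing within every trial", {
  sched <- generate_experiment(small_config(seed = 9))
  beh <- simulate_agent_behavior(sched, policy = "learner_with_halts",
                                 seed = 9)
  for (id in unique(stats::na.omit(beh$trial))) {
    expect_true(all(diff(beh$position[!is.na(beh$trial) &
                                        beh$trial == id]) >= 0))
  }
})

test_that("ensemble drives follow their activation signatures", {
  cfg <- session_config(seed = 4)
  sched <- generate_experiment(cfg)
  beh <- simulate_agent_behavior(sched, seed = 4)
  specs <- default_ensemble_specs(onset_trial = 12L)
  act <- generate_activity(sched, beh, specs, n_neurons = 50, seed = 4)
  drives <- act$truth$drives
  colnames(drives) <- act$truth$labels
  outc <- act$truth$outcomes

  blue <- beh$color == "blue" & !is.na(beh$trial)
  # blue perception: drive in every blue period including the first trial
  expect_true(all(drives[blue, "blue_perception"] > 0))
  expect_true(all(drives[!blue, "blue_perception"] == 0))
  first_trial_frames <- which(!is.na(beh$trial) & beh$trial == 1 & blue)
  expect_true(all(drives[first_trial_frames, "blue_perception"] > 0))

  # sfpe: silent in successful closed-loop GO, active in failed GO and
  # open-loop GO after onset
  ok_go <- outc$trial[outc$type == "GO" & outc$success & outc$gain > 0]
  sel_ok <- !is.na(beh$trial) & beh$trial %in% ok_go
  expect_true(all(drives[sel_ok, "sfpe"] == 0))
  open_go <- outc$trial[outc$type == "GO" & outc$gain == 0]
  sel_open <- !is.na(beh$trial) & beh$trial %in% open_go & blue
  expect_true(all(drives[sel_open, "sfpe"] > 0))
  fail_go <- outc$trial[outc$type == "GO" & !outc$success & outc$gain > 0 &
                          outc$trial > sched$trial[sched$phase == "training"][12]]
  expect_true(length(fail_go) > 0)
  expect_true(all(drives[!is.na(beh$trial) & beh$trial %in% fail_go & blue,
                         "sfpe"] > 0))

  # rule ensembles silent before their onset trial
  adapt <- !is.na(beh$trial) & beh$phase == "adaptation"
  expect_true(all(drives[adapt, "blue_dangerous_rule"] == 0))
  expect_true(all(drives[adapt, "red_safe_rule"] == 0))
})

test_that("noise-free generation with no ensembles is all zeros", {
  cfg <- small_config()
  sched <- generate_experiment(cfg)
  beh <- simulate_agent_behavior(sched, seed = 1)
  act <- generate_activity(sched, beh, list(), n_neurons = 5, noise_sd = 0,
                           seed = 1)
  expect_true(all(act$fluor$dff == 0))
  expect_error(generate_activity(sched, beh, list(), n_neurons = 5,
                                 noise_sd = -1), "noise_sd")
})

test_that("member neurons cluster around their ensemble center", {
  cfg <- session_config(seed = 8)
  sched <- generate_experiment(cfg)
  beh <- simulate_agent_behavior(sched, seed = 8)
  spec <- ensemble_spec("blue_perception", n_neurons = 10,
                        spatial_center = c(100, 100), spatial_sd = 10)
  act <- generate_activity(sched, beh, list(spec), n_neurons = 40, seed = 8)
  members <- which(act$truth$membership[, 1] > 0)
  d <- sqrt(rowSums((act$fluor$centroids[members, ] -
                       matrix(c(100, 100), 10, 2, byrow = TRUE))^2))
  expect_true(mean(d) < 40)  # clustered, versus ~200 um for uniform
})

test_that("movie pixels follow the cell trace and drift is as applied", {
  tr <- matrix(seq(0, 1, length.out = 20), 1)
  masks <- list(cbind(row = 10:12, col = 15L))
  mov <- generate_movie(masks, tr, noise_sd = 0, baseline = 100,
                        background = 0, dim = 32L)
  px <- mov[10, 15, ]
  expect_equal(px, 100 * (1 + tr[1, ]), tolerance = 1e-12)

  drift <- matrix(0L, 20, 2); drift[5, ] <- c(3L, -2L)
  mov2 <- generate_movie(masks, tr, drift = drift, noise_sd = 0,
                         baseline = 100, background = 0, dim = 32L)
  expect_equal(mov2[13, 13, 5], mov[10, 15, 5])
  # registration recovers the applied shift
  reg <- register_frames(mov2, mov2[, , 1])
  expect_equal(unname(reg$shifts[5, ]), c(3, -2))
})

test_that("nested masks produce a resolvable overlap fixture", {
  big <- as.matrix(expand.grid(row = 10:16, col = 10:16))
  small <- as.matrix(expand.grid(row = 12:14, col = 12:14))
  rois <- list(
    structure(list(pixels = small, area = nrow(small)), class = "roi"),
    structure(list(pixels = big, area = nrow(big)), class = "roi")
  )
  kept <- fishvr:::resolve_roi_overlaps(rois, 32L * 32L, 32L)
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$area, nrow(big))
})

test_that("session IO round-trips through CSV and TIFF", {
  cfg <- small_config()
  sched <- generate_schedule(cfg, phase = "training")
  p <- withr::local_tempfile(fileext = ".csv")
  write_session_csv(sched, p)
  back <- read_session_csv(p)
  expect_equal(back$type, sched$type)
  expect_equal(back$onset, sched$onset)

  mov <- generate_movie(list(cbind(row = 5L, col = 5L)),
                        matrix(runif(10), 1), noise_sd = 1, dim = 16L,
                        seed = 2)
  tp <- withr::local_tempfile(fileext = ".tif")
  write_movie_tiff(mov, tp)
  back_mov <- read_movie_tiff(tp)
  expect_equal(dim(back_mov), dim(mov))
  expect_lt(max(abs(back_mov - mov)) / max(mov), 1e-6)
})
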