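# Ensemble analysis: templates, similarity, NMF, AIC, shuffle, candidate
# screening, classification, trial peaks.

session_fixture <- function(seed = 4L, n_neurons = 40L) {
  cfg <- session_config(seed = seed)
  sched <- generate_experiment(cfg)
  beh <- simulate_agent_behavior(sched, seed = seed)
  act <- generate_activity(sched, beh, default_ensemble_specs(),
                           n_neurons = n_neurons, seed = seed)
  out <- classify_trials(beh, sched)
  learn <- learning_criterion(out[out$phase == "training", ])
  list(cfg = cfg, sched = sched, beh = beh, act = act, out = out,
       learn = learn)
}

test_that("templates average qualifying post-criterion windows", {
  fx <- session_fixture()
  dff <- fx$act$fluor$dff
  tmpl <- build_template(dff, fx$beh$time, fx$sched, fx$out, fx$learn, "GO")
  wlen <- ncol(tmpl)
  qual <- fx$sched$trial[fx$sched$phase == "training" &
                           fx$sched$type == "GO" &
                           fx$sched$trial > fx$learn]
  qual <- qual[qual %in% fx$out$trial[fx$out$success]]
  expect_gt(length(qual), 1)
  wins <- lapply(qual, function(id) {
    onset <- fx$sched$onset[fx$sched$trial == id]
    i0 <- which(fx$beh$time >= onset)[1]
    dff[, i0:(i0 + wlen - 1)]
  })
  expect_equal(unclass(tmpl), Reduce(`+`, wins) / length(wins),
               ignore_attr = TRUE, tolerance = 1e-12)
  # a template from only the first qualifying trial equals that window
  one <- qual[1]
  sched1 <- fx$sched[fx$sched$trial <= one, ]
  tmpl1 <- build_template(dff, fx$beh$time, sched1, fx$out, fx$learn, "GO")
  expect_equal(unclass(tmpl1), wins[[1]], ignore_attr = TRUE)
  # pre-criterion trials never qualify
  expect_true(all(qual > fx$learn))
  expect_error(build_template(dff, fx$beh$time, fx$sched, fx$out,
                              NA_integer_, "GO"), "criterion")
})

test_that("similarity is +1 on the template, -1 on its reflection, bounded", {
  set.seed(9)
  dff <- matrix(rnorm(20 * 300), 20)
  tmpl <- dff[, 101:106]
  # plant the reflection about the window mean elsewhere
  dff[, 201:206] <- 2 * mean(tmpl) - tmpl
  si <- similarity_trace(dff, tmpl)
  expect_equal(si[101], 1, tolerance = 1e-12)
  expect_equal(si[201], -1, tolerance = 1e-12)
  expect_true(all(si >= -1 & si <= 1))
  # independent noise windows are rarely similar
  null_si <- si[setdiff(seq_along(si), 90:215)]
  expect_gt(mean(abs(null_si) < 0.2), 0.95)
  # zero-variance window maps to 0
  dff0 <- dff; dff0[, 1:6] <- 3
  expect_equal(similarity_trace(dff0, tmpl)[1], 0)
})

test_that("NMF recovers exact low-rank structure", {
  truth <- make_nmf_truth(n = 40, t = 400, k = 2, noise_frac = 0, seed = 2)
  fit <- nmf_factorize(truth$D, 2, restarts = 5, max_iter = 3000, seed = 2)
  expect_lt(fit$error, 1e-3 * sum(truth$D^2))
  cs <- best_cosine_match(fit$P, truth$P0)
  expect_true(all(cs > 0.99))
  expect_true(all(fit$P >= 0) && all(fit$T >= 0))
  # rank-1 constant matrix at k = 1 reconstructs almost exactly
  D1 <- matrix(3, 10, 50)
  f1 <- nmf_factorize(D1, 1, seed = 1)
  expect_lt(f1$error, 1e-6 * sum(D1^2))
})

test_that("NMF error is monotone over iterations and best-of-restarts", {
  truth <- make_nmf_truth(n = 30, t = 300, k = 3, noise_frac = 0.1, seed = 3)
  fit <- nmf_factorize(truth$D, 3, restarts = 5, max_iter = 500, seed = 3)
  expect_length(fit$restart_errors, 5L)
  expect_equal(fit$error, min(fit$restart_errors))
  expect_true(all(diff(fit$error_trace) <= 1e-8 * fit$error_trace[1]))
  expect_error(nmf_factorize(truth$D - 10, 2), "non-negative")
  expect_error(nmf_factorize(truth$D, 500), "exceeds")
})

test_that("AIC picks the embedded order and collapses on noise", {
  truth <- make_nmf_truth(n = 40, t = 600, k = 3, noise_frac = 0.05,
                          seed = 5)
  sel <- select_order_aic(truth$D, k_range = 1:5, seed = 5)
  expect_equal(sel$k, 3L)
  expect_equal(nrow(sel$aic), 5L)

  one <- make_nmf_truth(n = 40, t = 600, k = 1, noise_frac = 0.05, seed = 6)
  expect_equal(select_order_aic(one$D, k_range = 1:4, seed = 6)$k, 1L)

  set.seed(7)
  noise <- matrix(abs(rnorm(40 * 600)), 40)
  seln <- select_order_aic(noise, k_range = 1:4, seed = 7)
  expect_equal(seln$k, 1L)
})

test_that("pairwise-swap shuffle preserves multisets and kills structure", {
  set.seed(10)
  smooth <- t(sapply(1:8, function(i)
    as.numeric(stats::filter(rnorm(500), rep(1, 20),
                             method = "convolution", sides = 1))))
  smooth[is.na(smooth)] <- 0
  sh <- shuffle_activity(smooth, seed = 1)
  for (r in 1:8) expect_equal(sort(sh[r, ]), sort(smooth[r, ]))
  ac <- function(x) suppressWarnings(stats::cor(x[-1], x[-length(x)]))
  before <- mean(sapply(1:8, function(r) ac(smooth[r, ])))
  after <- mean(sapply(1:8, function(r) ac(sh[r, ])))
  expect_gt(before, 0.9)
  expect_lt(abs(after), 0.3)
  # three independent sets differ from each other
  s2 <- shuffle_activity(smooth, seed = 2)
  expect_false(identical(sh, s2))
  expect_identical(sh, shuffle_activity(smooth, seed = 1))
})

test_that("candidate screening applies the strictly-greater 0.25 rule", {
  set.seed(11)
  B <- as.numeric(rep(c(1, 0), each = 50, times = 5))
  R <- 1 - B
  Tmat <- rbind(B,                          # correlation exactly 1
                runif(length(B)),           # noise
                rep(2, length(B)))          # zero variance
  cand <- candidate_ensembles(Tmat, B, R)
  expect_true(cand$candidate[1])
  expect_equal(cand$cor_b[1], 1)
  expect_false(cand$candidate[3])           # excluded, zero variance
  # boundary: a row correlated at exactly 0.25 is not a candidate
  n <- length(B)
  x <- B - mean(B)
  y <- rnorm(n); y <- y - mean(y)
  y <- y - x * sum(x * y) / sum(x * x)      # orthogonalize
  row <- 0.25 * x / sd(x) + sqrt(1 - 0.25^2) * y / sd(y)
  expect_equal(cor(row, B), 0.25, tolerance = 1e-9)
  # a row whose correlation equals the threshold exactly is NOT a candidate
  cand2 <- candidate_ensembles(rbind(row), B, R, threshold = cor(row, B))
  expect_false(cand2$candidate[1])
  # noise rows are rarely candidates
  noise <- matrix(runif(40 * length(B)), 40)
  candn <- candidate_ensembles(noise, B, R)
  expect_gt(mean(!candn$candidate), 0.95)
})

test_that("trial peaks are self-max normalized window maxima", {
  fx <- session_fixture(seed = 6, n_neurons = 44)
  ids <- fx$sched$trial[fx$sched$phase == "adaptation"][1:5]
  zeros <- trial_peaks(rep(0, nrow(fx$beh)), fx$beh, fx$sched, ids)
  expect_true(all(zeros == 0))

  # a pulse of known height inside one trial's start-color window
  activation <- rep(0, nrow(fx$beh))
  id <- ids[1]
  w <- which(!is.na(fx$beh$trial) & fx$beh$trial == id)
  activation[w[2]] <- 4        # session max -> normalizes to 1
  other <- which(!is.na(fx$beh$trial) & fx$beh$trial == ids[2])
  activation[other[2]] <- 2    # half the session max
  pk <- trial_peaks(activation, fx$beh, fx$sched, ids[1:2])
  expect_equal(unname(pk), c(1, 0.5))
})

test_that("classifier recovers every generated ensemble signature", {
  fx <- session_fixture(seed = 12, n_neurons = 44)
  # feed the classifier the noiseless ground-truth drives
  a <- exp(-1 / (fx$cfg$frame_rate * 1.5))
  for (j in seq_along(fx$act$truth$labels)) {
    sig <- as.numeric(stats::filter((1 - a) * fx$act$truth$drives[, j], a,
                                    method = "recursive"))
    lab <- classify_ensemble(sig, fx$beh, fx$sched, fx$out, fx$learn)
    expect_equal(lab$label, fx$act$truth$labels[j])
  }
  # a blue response that fades after adaptation matches no signature
  fading <- as.numeric(fx$beh$color == "blue" &
                         !is.na(fx$beh$phase) &
                         fx$beh$phase == "adaptation")
  lab0 <- classify_ensemble(fading, fx$beh, fx$sched, fx$out, fx$learn)
  expect_equal(lab0$label, "unclassified")
})
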