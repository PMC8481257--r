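# Shared fixtures and independent oracles used across the test files.

# Small session: one training block, short adaptation/open-loop phases.
small_config <- function(seed = 1L, ...) {
  session_config(n_trials = 20L, n_adaptation = 20L, n_openloop = 20L,
                 seed = seed, ...)
}

# Intersection-over-union of two pixel sets given as row/col matrices.
mask_iou <- function(a, b) {
  ka <- paste(a[, 1], a[, 2])
  kb <- paste(b[, 1], b[, 2])
  length(intersect(ka, kb)) / length(union(ka, kb))
}

# Match detected ROIs to ground-truth masks at an IoU cutoff; returns the
# number of matched truths and the number of unmatched (spurious) ROIs.
match_rois <- function(rois, masks, cutoff = 0.3) {
  if (!length(rois)) return(list(matched = 0L, spurious = 0L))
  iou <- sapply(masks, function(tm)
    vapply(rois, function(r) mask_iou(r$pixels, tm), numeric(1)))
  iou <- matrix(iou, nrow = length(rois))
  list(matched = sum(apply(iou, 2, max) > cutoff),
       spurious = sum(apply(iou, 1, max) <= cutoff))
}

# Brute-force re-derivation of the trial outcome rules, written
# independently of classify_trial: walks the frames of the trial window and
# applies the GO/NOGO definitions literally.
oracle_trial_outcome <- function(time, freq, pos, onset, limit, type,
                                 goal, beat_threshold) {
  success <- if (type == "GO") FALSE else TRUE
  for (i in seq_along(time)) {
    if (time[i] < onset || time[i] >= onset + limit) next
    if (type == "GO" && pos[i] >= goal) success <- TRUE
    if (type == "NOGO" && freq[i] >= beat_threshold) success <- FALSE
  }
  success
}

# Exhaustive prefix scan for the learning criterion: for every prefix,
# recompute the trailing-window success rates of both types from scratch.
oracle_learning_criterion <- function(types, successes, rate = 0.8,
                                      window = 10L) {
  for (i in seq_along(types)) {
    sg <- successes[seq_len(i)][types[seq_len(i)] == "GO"]
    sn <- successes[seq_len(i)][types[seq_len(i)] == "NOGO"]
    if (length(sg) >= window && length(sn) >= window &&
        mean(tail(sg, window)) >= rate && mean(tail(sn, window)) >= rate) {
      return(i)
    }
  }
  NA_integer_
}

# Cosine similarity between the columns of two matrices after the best
# column permutation (k is small, so all permutations are scanned).
best_cosine_match <- function(A, B) {
  k <- ncol(A)
  cosm <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    cosm[i, j] <- sum(A[, i] * B[, j]) /
      (sqrt(sum(A[, i]^2)) * sqrt(sum(B[, j]^2)))
  }
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- -Inf; best_cos <- NULL
  for (p in perms(seq_len(k))) {
    cs <- cosm[cbind(seq_len(k), p)]
    if (sum(cs) > best) { best <- sum(cs); best_cos <- cs }
  }
  best_cos
}

# Ground-truth factor pair for NMF recovery tests: disjoint neuron blocks
# with random positive weights and smooth non-negative activations.
make_nmf_truth <- function(n = 100L, t = 2000L, k = 3L, noise_frac = 0.05,
                           seed = 1L) {
  set.seed(seed)
  P0 <- matrix(0, n, k)
  block <- split(seq_len(n), rep(seq_len(k), length.out = n))
  for (j in seq_len(k)) P0[block[[j]], j] <- runif(length(block[[j]]), 0.5, 1.5)
  tt <- seq_len(t)
  T0 <- t(sapply(seq_len(k), function(j) {
    (pmax(sin(2 * pi * tt / (150 + 70 * j) + j), 0))^2 +
      0.2 * (tt %% (200 + 50 * j) < 20)
  }))
  D0 <- P0 %*% T0
  D <- pmax(D0 + rnorm(n * t, 0, noise_frac * mean(D0)), 0)
  list(P0 = P0, T0 = T0, D = D)
}
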