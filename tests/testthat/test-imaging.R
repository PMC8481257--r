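# Imaging: registration, preprocessing, peaky-ness, ROI detection, traces,
# plane interpolation, dF/F0.

make_static_movie <- function(n_frames = 12L, dim = 32L, seed = 1L) {
  cells <- make_cell_masks(3, dim = dim, radius = 2, min_sep = 8, seed = seed)
  tr <- matrix(0, 3, n_frames)
  generate_movie(cells$masks, tr, noise_sd = 0, dim = dim, seed = seed)
}

test_that("reference of a static movie is the mean frame", {
  mov <- make_static_movie()
  expect_warning(ref <- build_reference(mov, n_frames = 1000L), "fewer")
  expect_equal(ref, apply(mov, c(1, 2), mean), tolerance = 1e-12)
})

test_that("shifted frames are excluded from the reference", {
  cells <- make_cell_masks(4, dim = 64L, radius = 3, seed = 2)
  tr <- matrix(0.5, 4, 30)
  drift <- matrix(0L, 30, 2)
  drift[28:30, ] <- 6L  # three badly displaced frames
  mov <- generate_movie(cells$masks, tr, drift = drift, noise_sd = 0.5,
                        dim = 64L, seed = 2)
  ref <- build_reference(mov, n_frames = 20L)
  clean_mean <- apply(mov[, , 1:27], c(1, 2), mean)
  shifted_mean <- apply(mov, c(1, 2), mean)
  expect_lt(mean(abs(ref - clean_mean)), mean(abs(ref - shifted_mean)))
})

test_that("registration recovers known integer shifts exactly", {
  cells <- make_cell_masks(5, dim = 64L, radius = 3, seed = 3)
  tr <- transient_traces(5, 40, rate = 0.1, seed = 3)
  drift <- cbind(sample(-5:5, 40, TRUE), sample(-5:5, 40, TRUE))
  drift[1, ] <- 0L
  mov <- generate_movie(cells$masks, tr, drift = drift, noise_sd = 1,
                        dim = 64L, seed = 3)
  ref <- mov[, , 1]
  reg <- register_frames(mov, ref)
  expect_equal(unname(reg$shifts), unname(drift))
  # reference against itself gives (0, 0)
  self <- register_frames(array(ref, c(64, 64, 1)), ref)
  expect_equal(unname(self$shifts[1, ]), c(0, 0))
  # residual shift after registration is zero on every frame
  reg2 <- register_frames(reg$registered, ref)
  expect_true(all(reg2$shifts == 0L))
})

test_that("all-zero frames register with a warning and zero shift", {
  mov <- array(0, c(16, 16, 2))
  mov[5, 5, 1] <- 1
  expect_warning(reg <- register_frames(mov, mov[, , 1]), "all-zero")
  expect_equal(unname(reg$shifts[2, ]), c(0, 0))
})

test_that("preprocessing median-filters and downsizes 512 to 256", {
  const <- array(7, c(32, 32, 2))
  out <- preprocess_movie(const)
  expect_equal(out, const, tolerance = 1e-4)

  imp <- array(0, c(32, 32, 1))
  imp[16, 16, 1] <- 100
  expect_lt(max(preprocess_movie(imp)[, , 1]), 1)  # impulse removed

  big <- array(runif(512 * 512 * 2), c(512, 512, 2))
  small <- preprocess_movie(big)
  expect_equal(dim(small), c(256L, 256L, 2L))
})

test_that("peaky-ness separates transient pixels from noise", {
  set.seed(11)
  n <- 200L
  mov <- array(rnorm(8 * 8 * n, 100, 2), c(8, 8, n))
  transient <- rep(0, n); transient[c(40, 110, 170)] <- 40
  mov[4, 4, ] <- 100 + as.numeric(stats::filter(transient, 0.7,
                                                method = "recursive")) +
    rnorm(n, 0, 2)
  pm <- compute_peakyness(mov)
  expect_true(all(is.finite(pm$score)))
  expect_gt(pm$score[4, 4], max(pm$score[-(8 * 3 + 4)]))
  expect_equal(pm$threshold, mean(pm$score))

  const <- array(5, c(4, 4, 120))
  pmc <- compute_peakyness(const)
  expect_true(all(pmc$score == 0))
  expect_equal(pmc$threshold, 0)
})

test_that("ROI detection recovers disjoint cells and rejects pure noise", {
  cells <- make_cell_masks(5, dim = 64L, radius = 3, min_sep = 15, seed = 4)
  tr <- transient_traces(5, 200, rate = 0.05, seed = 4)
  mov <- generate_movie(cells$masks, tr, noise_sd = 2, dim = 64L, seed = 4)
  pm <- compute_peakyness(mov)
  rois <- detect_rois(mov, pm, window = 31L)
  expect_length(rois, 5L)
  for (i in 1:5) {
    best <- which.max(vapply(rois, function(r)
      mask_iou(r$pixels, cells$masks[[i]]), numeric(1)))
    err <- sqrt(sum((rois[[best]]$centroid_px - cells$centroids_px[i, ])^2))
    expect_lt(err, 2)
  }

  set.seed(5)
  noise <- array(rnorm(64 * 64 * 150, 50, 3), c(64, 64, 150))
  pmn <- compute_peakyness(noise)
  expect_length(detect_rois(noise, pmn, window = 31L), 0L)

  expect_error(detect_rois(mov, pm, corr_threshold = 1.5), "corr_threshold")
})

test_that("overlapping cells keep only the larger ROI", {
  # two cells sharing pixels: one large, one small inside its halo
  big <- as.matrix(expand.grid(row = 20:28, col = 20:28))
  small <- as.matrix(expand.grid(row = 27:29, col = 27:29))
  colnames(big) <- colnames(small) <- c("row", "col")
  n <- 200L
  t_big <- transient_traces(1, n, rate = 0.06, seed = 6)[1, ]
  t_small <- transient_traces(1, n, rate = 0.06, seed = 7)[1, ]
  mov <- generate_movie(list(big, small), rbind(t_big, t_small),
                        noise_sd = 1, dim = 48L, seed = 6)
  pm <- compute_peakyness(mov)
  rois <- detect_rois(mov, pm, window = 31L)
  areas <- vapply(rois, `[[`, numeric(1), "area")
  # the retained ROIs are pairwise disjoint and the big cell survives
  expect_gt(max(areas), 40)
  all_pix <- do.call(rbind, lapply(rois, `[[`, "pixels"))
  expect_equal(nrow(all_pix), nrow(unique(all_pix)))
})

test_that("trace extraction averages over mask pixels", {
  mov <- array(0, c(8, 8, 5))
  a <- sin(1:5); b <- cos(1:5)
  mov[2, 2, ] <- a
  mov[2, 3, ] <- b
  roi1 <- structure(list(pixels = cbind(row = 2L, col = 2L)), class = "roi")
  roi2 <- structure(list(pixels = cbind(row = c(2L, 2L), col = c(2L, 3L))),
                    class = "roi")
  tr <- extract_traces(mov, list(roi1, roi2))
  expect_equal(tr[1, ], a)
  expect_equal(tr[2, ], (a + b) / 2)
})

test_that("plane interpolation reproduces ramps and sinusoids", {
  fp <- 0.09775
  n_planes <- 3L; n_samp <- 60L
  master_t <- (seq_len(n_planes * n_samp) - 1L) * fp
  # linear ramp: splines are exact
  ramp <- function(t) 2 + 3 * t
  planes <- lapply(seq_len(n_planes), function(p) {
    tp <- (p - 1L + n_planes * (seq_len(n_samp) - 1L)) * fp
    matrix(ramp(tp), 1)
  })
  out <- interpolate_planes(planes, frame_period = fp)
  expect_equal(out$F[1, ], ramp(master_t), tolerance = 1e-9)
  expect_equal(out$F[3, ], ramp(master_t), tolerance = 1e-9)
  expect_equal(out$plane, c(1L, 2L, 3L))

  # 0.5 Hz sinusoid sampled at ~3.4 Hz per plane: < 5% amplitude error
  # away from the extrapolated ends
  sine <- function(t) sin(2 * pi * 0.5 * t)
  planes <- lapply(seq_len(n_planes), function(p) {
    tp <- (p - 1L + n_planes * (seq_len(n_samp) - 1L)) * fp
    matrix(sine(tp), 1)
  })
  out <- interpolate_planes(planes, frame_period = fp)
  interior <- seq(4L, length(master_t) - 4L)
  expect_lt(max(abs(out$F[2, interior] - sine(master_t[interior]))), 0.05)

  # single plane: identity
  one <- interpolate_planes(list(matrix(1:10, 1)), frame_period = fp)
  expect_equal(one$F[1, ], 1:10)

  expect_error(interpolate_planes(list(matrix(1:3, 1), matrix(1:3, 1))),
               "4 samples")
})

test_that("dF/F0 has zero temporal mean and positive baselines", {
  set.seed(12)
  F <- matrix(runif(5 * 100, 50, 150), 5)
  out <- compute_dff(F)
  expect_equal(rowMeans(out$dff), rep(0, 5), tolerance = 1e-12)
  expect_true(all(out$baseline > 0))
  # constant trace maps to all zeros; doubling F0 at one frame gives 1
  Fc <- matrix(10, 1, 20)
  expect_true(all(compute_dff(Fc)$dff == 0))
  # a frame at twice the baseline maps to exactly 1
  a <- 38 / 18  # solves a = 2 * mean(c(rep(1, 19), a))
  Fd <- matrix(c(rep(1, 19), a), 1, 20)
  expect_equal(compute_dff(Fd)$dff[1, 20], 1, tolerance = 1e-12)

  Fbad <- rbind(F[1, ], -F[2, ])
  expect_warning(kept <- compute_dff(Fbad), "baseline")
  expect_equal(kept$kept, 1L)
})
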