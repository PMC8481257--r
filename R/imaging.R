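# Imaging pipeline: rigid FFT registration, median filtering and
# downsampling, peaky-ness ROI detection, trace extraction, plane
# interpolation and dF/F0 computation.
#
# Movies are numeric arrays [row, col, frame]; coordinates are 0-based pixel
# indices when converted to micrometers (um = pixel * 384.9 / width) and
# distances are Euclidean in-plane.

# Non-circular integer translation: content moves by (dy, dx); vacated
# pixels are filled with `fill`.
shift_frame <- function(m, dy, dx, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dy
  src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

# Integer displacement of `frame` relative to `ref` by the peak of the
# circular cross-correlation, computed in the frequency domain. Returns
# (dy, dx) such that frame ~ ref translated by (dy, dx).
cross_corr_shift <- function(frame, ref) {
  cc <- Re(stats::fft(stats::fft(frame) * Conj(stats::fft(ref)),
                      inverse = TRUE))
  k <- which.max(cc)
  nr <- nrow(frame)
  i <- (k - 1L) %% nr
  j <- (k - 1L) %/% nr
  if (i > nr / 2) i <- i - nr
  if (j > ncol(frame) / 2) j <- j - ncol(frame)
  c(i, j)
}

#' Build a registration reference image
#'
#' Two-pass reference: displacements of all frames are first measured
#' against the global mean image, then the `n_frames` frames with the
#' smallest displacement magnitude are aligned by their measured shifts and
#' averaged, giving a sharp reference unaffected by residual jitter.
#'
#' @param movie array row x col x frame
#' @param n_frames frames to average (default 1000); if the movie is
#'   shorter, all frames are used with a warning
#' @return reference image (matrix)
#' @export
build_reference <- function(movie, n_frames = 1000L) {
  nt <- dim(movie)[3]
  if (nt < n_frames) {
    warning("movie has fewer frames than n_frames; using all frames")
    n_frames <- nt
  }
  ref0 <- apply(movie, c(1, 2), mean)
  shifts <- t(vapply(seq_len(nt), function(t)
    cross_corr_shift(movie[, , t], ref0), numeric(2)))
  mags <- sqrt(rowSums(shifts^2))
  sel <- order(mags)[seq_len(n_frames)]
  acc <- 0
  for (t in sel) {
    fr <- movie[, , t]
    if (any(shifts[t, ] != 0)) {
      fr <- shift_frame(fr, -shifts[t, 1], -shifts[t, 2],
                        fill = stats::median(fr))
    }
    acc <- acc + fr
  }
  acc / length(sel)
}

#' Register frames to a reference by FFT cross-correlation
#'
#' Finds the integer-pixel displacement of each frame relative to the
#' reference at the peak of the frequency-domain cross-correlation, then
#' translates the frame by the negated shift. All-zero frames get shift
#' (0, 0) with a warning. No subpixel refinement is attempted.
#'
#' @param movie array row x col x frame
#' @param reference reference image of the same frame shape
#' @return list with `shifts` (frames x 2 matrix of (dy, dx)) and
#'   `registered` (array like `movie`)
#' @export
register_frames <- function(movie, reference) {
  d <- dim(movie)
  stopifnot(all(dim(reference) == d[1:2]))
  shifts <- matrix(0L, d[3], 2, dimnames = list(NULL, c("dy", "dx")))
  registered <- movie
  for (t in seq_len(d[3])) {
    fr <- movie[, , t]
    if (all(fr == 0)) {
      warning("all-zero frame; shift set to (0, 0)")
      next
    }
    s <- cross_corr_shift(fr, reference)
    shifts[t, ] <- s
    if (any(s != 0L)) {
      # fill vacated margins with the frame median so they look like
      # background rather than artificial zero-variance pixels
      registered[, , t] <- shift_frame(fr, -s[1], -s[2],
                                       fill = stats::median(fr))
    }
  }
  list(shifts = shifts, registered = registered)
}

#' Median-filter and downsample a registered movie
#'
#' Applies a radius-2 median filter to every frame and, when the frame
#' width is 512, downsizes to 256 x 256 by 2 x 2 block averaging. The median
#' filter quantizes intensities on a 2^16-level grid over the movie range
#' (relative error about 1e-5).
#'
#' @param movie array row x col x frame
#' @param radius median filter radius in pixels
#' @return preprocessed movie, same attribute layout
#' @export
preprocess_movie <- function(movie, radius = 2L) {
  d <- dim(movie)
  lo <- min(movie); hi <- max(movie)
  scale <- hi - lo
  out <- movie
  if (scale > 0) {
    for (t in seq_len(d[3])) {
      out[, , t] <- EBImage::medianFilter((movie[, , t] - lo) / scale,
                                          radius) * scale + lo
    }
  }
  if (d[1] == 512L && d[2] == 512L) {
    half <- array(0, c(256L, 256L, d[3]))
    for (t in seq_len(d[3])) {
      m <- out[, , t]
      half[, , t] <- (m[seq(1, 511, 2), seq(1, 511, 2)] +
                        m[seq(2, 512, 2), seq(1, 511, 2)] +
                        m[seq(1, 511, 2), seq(2, 512, 2)] +
                        m[seq(2, 512, 2), seq(2, 512, 2)]) / 4
    }
    attr(half, "pixel_size_um") <- 384.9 / 256
    attr(half, "frame_period") <- attr(movie, "frame_period")
    return(half)
  }
  attributes(out) <- attributes(movie)
  out
}

# Pixel-major matrix view of a movie: npix x nframes.
movie_as_matrix <- function(movie) {
  d <- dim(movie)
  matrix(movie, d[1] * d[2], d[3])
}

#' Per-pixel peaky-ness map
#'
#' Scores every pixel's transient content as (max - median) / (MAD + eps) of
#' its time course: pixels inside active cell bodies carry large brief
#' deviations and score high, noise-only pixels score low, and a constant
#' pixel scores 0. The map threshold used to stop ROI seeding is the mean
#' score over all pixels.
#'
#' @param movie array row x col x frame (at least 100 frames recommended)
#' @param eps numerical guard added to the MAD
#' @return a `peakyness_map`: list with `score` (matrix) and `threshold`
#' @export
compute_peakyness <- function(movie, eps = 1e-6) {
  mat <- movie_as_matrix(movie)
  med <- apply(mat, 1, stats::median)
  madv <- 1.4826 * apply(abs(mat - med), 1, stats::median)
  mx <- mat[, 1]
  for (t in seq_len(ncol(mat))[-1]) mx <- pmax(mx, mat[, t])
  score <- (mx - med) / (madv + eps)
  structure(list(score = matrix(score, dim(movie)[1], dim(movie)[2]),
                 threshold = mean(score)),
            class = "peakyness_map")
}

# 4-connected component of `mask` containing (sr, sc); mask is logical.
connected_component <- function(mask, sr, sc) {
  nr <- nrow(mask); nc <- ncol(mask)
  comp <- matrix(FALSE, nr, nc)
  if (!mask[sr, sc]) return(comp)
  queue <- matrix(c(sr, sc), 1)
  comp[sr, sc] <- TRUE
  while (nrow(queue)) {
    p <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      r <- p[1] + d[1]; c2 <- p[2] + d[2]
      if (r >= 1L && r <= nr && c2 >= 1L && c2 <= nc &&
          mask[r, c2] && !comp[r, c2]) {
        comp[r, c2] <- TRUE
        queue <- rbind(queue, c(r, c2))
      }
    }
  }
  comp
}

#' Detect cell-like ROIs by greedy peaky-ness descent
#'
#' Seeds are visited in decreasing peaky-ness order until the score drops
#' below the map threshold. For each unclaimed seed, the temporal
#' correlation between the seed pixel and all pixels of the surrounding
#' `window` x `window` neighborhood is computed; pixels at or above
#' `corr_threshold` that form the 4-connected region around the seed become
#' one ROI. Overlapping ROIs are resolved by keeping the larger area (ties
#' keep the earlier, higher peaky-ness seed); ROIs smaller than `min_area`
#' pixels are discarded.
#'
#' @param movie array row x col x frame
#' @param peakymap a [compute_peakyness()] result
#' @param corr_threshold temporal correlation needed to join a ROI,
#'   in (0, 1)
#' @param window neighborhood side length in pixels (odd; default 51)
#' @param min_area minimal ROI area in pixels
#' @return list of `roi` objects: `pixels` (two-column row/col matrix),
#'   `area`, `centroid_px`, `centroid_um`, `plane`, `seed_score`
#' @export
detect_rois <- function(movie, peakymap, corr_threshold = 0.5, window = 51L,
                        min_area = 4L) {
  if (corr_threshold <= 0 || corr_threshold >= 1) {
    stop("corr_threshold must be in (0, 1)")
  }
  d <- dim(movie)
  nr <- d[1]; nc <- d[2]; nt <- d[3]
  px_um <- attr(movie, "pixel_size_um")
  if (is.null(px_um)) px_um <- 384.9 / nc
  mat <- movie_as_matrix(movie)
  mu <- rowMeans(mat)
  cmat <- mat - mu
  ss <- sqrt(rowSums(cmat^2))
  z <- cmat / ifelse(ss > 0, ss, 1)   # unit-norm rows: corr = dot product
  z[ss == 0, ] <- 0

  score <- as.vector(peakymap$score)
  ord <- order(score, decreasing = TRUE)
  ord <- ord[score[ord] >= peakymap$threshold]
  claimed <- logical(nr * nc)
  half <- (window - 1L) %/% 2L
  rois <- list()

  for (s in ord) {
    if (claimed[s]) next
    sr <- (s - 1L) %% nr + 1L
    sc <- (s - 1L) %/% nr + 1L
    claimed[s] <- TRUE
    # the seed's 4-connected component is {seed} unless a direct neighbor
    # passes the correlation threshold, so check those four pixels first
    nb <- c(if (sr > 1L) s - 1L, if (sr < nr) s + 1L,
            if (sc > 1L) s - nr, if (sc < nc) s + nr)
    if (all(z[nb, , drop = FALSE] %*% z[s, ] < corr_threshold)) {
      if (min_area <= 1L) {
        cen <- c(row = as.numeric(sr), col = as.numeric(sc))
        rois[[length(rois) + 1L]] <- structure(list(
          pixels = cbind(row = sr, col = sc), area = 1L,
          centroid_px = cen,
          centroid_um = c(x = (cen[["col"]] - 1) * px_um,
                          y = (cen[["row"]] - 1) * px_um),
          plane = 1L, seed_score = score[s]
        ), class = "roi")
      }
      next
    }
    r0 <- max(1L, sr - half); r1 <- min(nr, sr + half)
    c0 <- max(1L, sc - half); c1 <- min(nc, sc + half)
    win_rows <- r0:r1; win_cols <- c0:c1
    idx <- as.vector(outer(win_rows, (win_cols - 1L) * nr, `+`))
    corr <- as.vector(z[idx, , drop = FALSE] %*% z[s, ])
    mask <- matrix(corr >= corr_threshold, length(win_rows), length(win_cols))
    comp <- connected_component(mask, sr - r0 + 1L, sc - c0 + 1L)
    sel <- which(comp, arr.ind = TRUE)
    pix <- cbind(row = win_rows[sel[, 1]], col = win_cols[sel[, 2]])
    if (nrow(pix) < min_area) next
    claimed[(pix[, "col"] - 1L) * nr + pix[, "row"]] <- TRUE
    cen <- colMeans(pix)
    rois[[length(rois) + 1L]] <- structure(list(
      pixels = pix, area = nrow(pix),
      centroid_px = c(row = cen[["row"]], col = cen[["col"]]),
      centroid_um = c(x = (cen[["col"]] - 1) * px_um,
                      y = (cen[["row"]] - 1) * px_um),
      plane = 1L, seed_score = score[s]
    ), class = "roi")
  }

  resolve_roi_overlaps(rois, nr * nc, nr)
}

# Keep the larger of every overlapping ROI pair (ties keep the earlier seed).
resolve_roi_overlaps <- function(rois, npix, nr) {
  if (length(rois) < 2L) return(rois)
  keys <- lapply(rois, function(r) (r$pixels[, "col"] - 1L) * nr + r$pixels[, "row"])
  drop <- logical(length(rois))
  for (i in seq_along(rois)[-1]) {
    for (j in seq_len(i - 1L)) {
      if (drop[j] || drop[i]) next
      if (any(keys[[i]] %in% keys[[j]])) {
        if (rois[[i]]$area > rois[[j]]$area) drop[j] <- TRUE else drop[i] <- TRUE
      }
    }
  }
  rois[!drop]
}

#' Extract per-ROI fluorescence timelines
#'
#' The fluorescence of a cell at each frame is the mean over its mask pixels.
#'
#' @param movie array row x col x frame
#' @param rois list of ROIs from [detect_rois()]
#' @return matrix ROIs x frames
#' @export
extract_traces <- function(movie, rois) {
  if (!length(rois)) return(matrix(0, 0, dim(movie)[3]))
  nr <- dim(movie)[1]
  mat <- movie_as_matrix(movie)
  t(vapply(rois, function(r) {
    if (!nrow(r$pixels)) stop("empty ROI")
    idx <- (r$pixels[, "col"] - 1L) * nr + r$pixels[, "row"]
    colMeans(mat[idx, , drop = FALSE])
  }, numeric(dim(movie)[3])))
}

#' Interpolate plane-interleaved traces onto one time base
#'
#' With an n-plane piezo cycle each cell is sampled once every n microscope
#' frames; cubic splines fill the missing frames so all neurons share one
#' uniform time base.
#'
#' @param plane_traces list (one entry per plane) of matrices
#'   neurons x samples; plane p is sampled at microscope frames
#'   p, p + n, p + 2n, ...
#' @param frame_period microscope frame period, seconds (default 0.09775)
#' @return list with `F` (matrix all-neurons x frames), `time`, `plane`
#'   (plane index per neuron)
#' @export
interpolate_planes <- function(plane_traces, frame_period = 0.09775) {
  n_planes <- length(plane_traces)
  ns <- vapply(plane_traces, ncol, integer(1))
  n_master <- n_planes * min(ns)
  master_t <- (seq_len(n_master) - 1L) * frame_period
  if (n_planes == 1L) {
    return(list(F = plane_traces[[1]], time = master_t,
                plane = rep(1L, nrow(plane_traces[[1]]))))
  }
  rows <- list(); plane_of <- integer(0)
  for (p in seq_len(n_planes)) {
    tp <- (p - 1L + n_planes * (seq_len(ns[p]) - 1L)) * frame_period
    m <- plane_traces[[p]]
    if (ncol(m) < 4L) stop("need at least 4 samples per neuron for splines")
    for (i in seq_len(nrow(m))) {
      rows[[length(rows) + 1L]] <-
        stats::spline(tp, m[i, ], xout = master_t, method = "fmm")$y
      plane_of <- c(plane_of, p)
    }
  }
  list(F = do.call(rbind, rows), time = master_t, plane = plane_of)
}

#' Compute dF/F0 with the session-mean baseline
#'
#' The baseline F0 of every neuron is its mean fluorescence over the whole
#' experiment; dF/F0 = (F - F0) / F0. Neurons with non-positive baselines
#' are dropped with a warning. By construction each neuron's dF/F0 has zero
#' temporal mean.
#'
#' @param F matrix neurons x frames of raw fluorescence
#' @return list with `dff` (matrix), `baseline` (F0 per kept neuron) and
#'   `kept` (row indices of `F` retained)
#' @export
compute_dff <- function(F) {
  f0 <- rowMeans(F)
  keep <- f0 > 0
  if (!all(keep)) warning(sum(!keep), " neuron(s) dropped: non-positive baseline")
  list(dff = (F[keep, , drop = FALSE] - f0[keep]) / f0[keep],
       baseline = f0[keep], kept = which(keep))
}
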