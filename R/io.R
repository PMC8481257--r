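# Plain-text and TIFF interchange for the pipeline's containers.

#' Write / read a behavior trace or trial schedule as CSV
#'
#' Column dictionary (behavior): `frame`, `time` (s), `trial`, `phase`,
#' `type`, `frequency` (Hz), `position` (distance units), `color`, `shock`.
#' Schedule: `trial`, `phase`, `block`, `type`, `onset` (s), `limit` (s),
#' `gain`, `rule`, `shock_on`.
#'
#' @param x data frame
#' @param path file path
#' @return `path`, invisibly (`read_session_csv` returns the data frame)
#' @export
write_session_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a movie as multi-page TIFF
#'
#' Intensities are stored as 32-bit floats scaled to [0, 1] by the recorded
#' `intensity_max`; `read_movie_tiff` restores the original scale.
#'
#' @param movie array row x col x frame
#' @param path TIFF path; a JSON sidecar `<path>.json` stores the scale and
#'   timing metadata
#' @return `path`, invisibly (`read_movie_tiff` returns the array)
#' @export
write_movie_tiff <- function(movie, path) {
  mx <- max(movie, 1e-12)
  frames <- lapply(seq_len(dim(movie)[3]), function(t) movie[, , t] / mx)
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  meta <- list(intensity_max = mx,
               frame_period = attr(movie, "frame_period"),
               pixel_size_um = attr(movie, "pixel_size_um"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  movie <- array(unlist(frames), c(dim(frames[[1]]), length(frames))) *
    meta$intensity_max
  attr(movie, "frame_period") <- meta$frame_period
  attr(movie, "pixel_size_um") <- meta$pixel_size_um
  movie
}

#' Write a fluorescence matrix as CSV with a metadata sidecar
#'
#' @param fluor a `fluor_matrix` (list with `dff`, `time`, `centroids`,
#'   `plane`)
#' @param path CSV path for the neurons x frames matrix; neuron metadata
#'   goes to `<path stem>_neurons.csv`
#' @return `path`, invisibly
#' @export
write_fluor_csv <- function(fluor, path) {
  utils::write.csv(as.data.frame(fluor$dff), path, row.names = FALSE)
  meta <- data.frame(neuron = seq_len(nrow(fluor$dff)),
                     x_um = fluor$centroids[, 1], y_um = fluor$centroids[, 2],
                     plane = fluor$plane)
  utils::write.csv(meta, sub("\\.csv$", "_neurons.csv", path),
                   row.names = FALSE)
  invisible(path)
}

#' Write ROI masks as a label image TIFF plus JSON metadata
#'
#' @param rois list of ROIs from [detect_rois()]
#' @param dim frame dimensions (rows, cols)
#' @param path TIFF path; metadata goes to `<path>.json`
#' @return `path`, invisibly
#' @export
write_roi_masks <- function(rois, dim, path) {
  lab <- matrix(0L, dim[1], dim[2])
  for (i in seq_along(rois)) lab[rois[[i]]$pixels] <- i
  tiff::writeTIFF(lab / max(1L, length(rois)), path, bits.per.sample = 16L)
  meta <- lapply(seq_along(rois), function(i) {
    r <- rois[[i]]
    list(id = i, area = r$area, centroid_px = unname(r$centroid_px),
         centroid_um = unname(r$centroid_um), plane = r$plane)
  })
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
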