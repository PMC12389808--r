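#' Extraction settings for wetting-front tracking
#'
#' Wet pixels are detected by absolute grayscale difference against the
#' pre-contact baseline frame (the first frame of the stack): a pixel is wet
#' when `|frame - baseline| > diff_threshold`. A row counts as wet when at
#' least `min_wet_pixels_per_row` of its ROI pixels are wet. The first
#' `reference_frames` frames after contact form the reference window whose
#' `reference_statistic` (mean, median, or topmost extent of the front rows)
#' defines the zero coordinate of the heights.
#'
#' @param roi integer range `c(first, last)` of frame columns covered by the
#'   strip.
#' @param diff_threshold grayscale difference (same units as the frames,
#'   `[0, 1]` for PNG input) above which a pixel counts as wet.
#' @param min_wet_pixels_per_row minimum wet pixels for a row to count.
#' @param reference_frames frames after contact used as reference (default
#'   30, i.e. 1 s at 30 fps).
#' @param reference_statistic `"mean"`, `"median"` or `"max_extent"`
#'   (topmost front row seen during the window).
#' @return An object of class `extraction_config`.
#' @export
extraction_config <- function(roi, diff_threshold = 0.2,
                              min_wet_pixels_per_row = 3L,
                              reference_frames = 30L,
                              reference_statistic = c("mean", "median",
                                                      "max_extent")) {
  reference_statistic <- match.arg(reference_statistic)
  stopifnot(length(roi) == 2L, roi[1] >= 1, roi[1] <= roi[2],
            diff_threshold > 0, min_wet_pixels_per_row >= 1,
            reference_frames >= 1)
  structure(
    list(roi = as.integer(roi), diff_threshold = diff_threshold,
         min_wet_pixels_per_row = as.integer(min_wet_pixels_per_row),
         reference_frames = as.integer(reference_frames),
         reference_statistic = reference_statistic),
    class = "extraction_config"
  )
}

# wet mask of one frame against the baseline, restricted to the ROI columns;
# returns a logical matrix [rows, roi columns]
wet_mask <- function(frame, baseline, config) {
  cols <- config$roi[1]:config$roi[2]
  abs(frame[, cols, drop = FALSE] - baseline[, cols, drop = FALSE]) >
    config$diff_threshold
}

#' Detect the contact frame
#'
#' Returns the 1-based index of the first frame whose wet-pixel count inside
#' the ROI (grayscale difference against the baseline, which is the first
#' frame) exceeds `min_wet_pixels_per_row`. With `p` dry padding frames the
#' contact frame is `p + 1`.
#'
#' @param frames array `[row, column, frame]`.
#' @param config an [extraction_config()].
#' @return Integer frame index.
#' @export
detect_contact <- function(frames, config) {
  stopifnot(length(dim(frames)) == 3L, dim(frames)[3] >= 1,
            inherits(config, "extraction_config"))
  if (config$roi[2] > dim(frames)[2]) stop("ROI exceeds frame width")
  baseline <- frames[, , 1]
  for (k in seq_len(dim(frames)[3])) {
    if (sum(wet_mask(frames[, , k], baseline, config)) >
        config$min_wet_pixels_per_row)
      return(k)
  }
  stop("no contact detected: no frame differs from the baseline by more ",
       "than the threshold")
}

#' Topmost wet row per frame
#'
#' For every frame from `contact_frame` on, finds the smallest (topmost) row
#' index inside the ROI with at least `min_wet_pixels_per_row` pixels whose
#' grayscale difference against the pre-contact baseline exceeds the
#' threshold. Frames with no wet row inherit the previous front row (the
#' bottom ROI row if it is the first), which prevents spurious zero heights
#' when the front transiently drops below the threshold.
#'
#' @inheritParams detect_contact
#' @param contact_frame 1-based index of the first wet frame, e.g. from
#'   [detect_contact()].
#' @return Integer vector of front rows, one per frame `>= contact_frame`.
#' @export
extract_front_rows <- function(frames, config, contact_frame) {
  stopifnot(length(dim(frames)) == 3L, inherits(config, "extraction_config"),
            contact_frame >= 1, contact_frame <= dim(frames)[3])
  if (config$roi[2] > dim(frames)[2]) stop("ROI exceeds frame width")
  if (config$roi[1] > config$roi[2]) stop("empty ROI")
  baseline <- frames[, , 1]
  idx <- contact_frame:dim(frames)[3]
  rows <- integer(length(idx))
  prev <- nrow(baseline)  # fall back to the bottom row before any detection
  for (j in seq_along(idx)) {
    mask <- wet_mask(frames[, , idx[j]], baseline, config)
    wet_rows <- which(rowSums(mask) >= config$min_wet_pixels_per_row)
    prev <- if (length(wet_rows)) min(wet_rows) else prev
    rows[j] <- prev
  }
  rows
}

#' Convert front rows to heights against the reference window
#'
#' The reference coordinate is the configured statistic of the first
#' `reference_frames` front rows after contact; heights are
#' `max(0, reference_row - row)` for every subsequent frame (row 0 is the top
#' of the image, so height grows upward). The retained series therefore has
#' `length(rows) - reference_frames` values.
#'
#' @param rows integer front rows from [extract_front_rows()].
#' @param config an [extraction_config()].
#' @param fps frame rate of the source video.
#' @param contact_frame optional contact index stored in the result.
#' @return A [height_series()].
#' @export
rows_to_heights <- function(rows, config, fps, contact_frame = NA_integer_) {
  stopifnot(inherits(config, "extraction_config"), fps > 0)
  R <- config$reference_frames
  if (length(rows) <= R)
    stop("need more than reference_frames (", R, ") rows, got ",
         length(rows))
  ref_window <- rows[seq_len(R)]
  reference_row <- switch(config$reference_statistic,
                          mean = mean(ref_window),
                          median = stats::median(ref_window),
                          max_extent = min(ref_window))
  heights <- pmax(0, reference_row - rows[(R + 1):length(rows)])
  height_series(heights, fps = fps, contact_frame = contact_frame,
                reference_row = reference_row)
}

#' Enforce monotone non-decreasing heights
#'
#' The wetted region cannot shrink while capillary flow advances, so a frame
#' reporting a lower front than its predecessor is a measurement error; the
#' previous value is carried forward (running maximum). Idempotent and
#' length-preserving.
#'
#' @param series a [height_series()] or bare numeric vector.
#' @return Same type as the input, with `out[i] = max(in[1..i])`.
#' @examples
#' enforce_monotone(c(0, 2, 1, 3))  # 0 2 2 3
#' @export
enforce_monotone <- function(series) {
  if (inherits(series, "height_series")) {
    series$heights <- cummax(series$heights)
    series
  } else {
    cummax(series)
  }
}

#' Extract a monotone height series from a frame stack
#'
#' Convenience chain: [detect_contact()] -> [extract_front_rows()] ->
#' [rows_to_heights()] -> [enforce_monotone()].
#'
#' @inheritParams detect_contact
#' @param fps frame rate of the stack.
#' @param monotone apply [enforce_monotone()] (default `TRUE`).
#' @return A [height_series()].
#' @export
extract_height_series <- function(frames, config, fps, monotone = TRUE) {
  contact <- detect_contact(frames, config)
  rows <- extract_front_rows(frames, config, contact)
  series <- rows_to_heights(rows, config, fps, contact_frame = contact)
  if (monotone) series <- enforce_monotone(series)
  series
}

#' Read a directory of PNG frames into an array
#'
#' Frames are read in lexicographic filename order (write zero-padded names,
#' as [write_frame_dir()] does). Color PNGs are converted to grayscale by
#' channel averaging.
#'
#' @param dir directory containing `.png` files.
#' @return Numeric array `[row, column, frame]`.
#' @export
read_frame_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop("no PNG frames found in ", dir)
  first <- png_gray(files[1])
  frames <- array(NA_real_, dim = c(nrow(first), ncol(first), length(files)))
  frames[, , 1] <- first
  for (k in seq_along(files)[-1]) frames[, , k] <- png_gray(files[k])
  frames
}

png_gray <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:3, drop = FALSE],
                                           c(1, 2), mean)
  img
}
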