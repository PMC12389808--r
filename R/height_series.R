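#' Wetting-front height series
#'
#' One value per retained frame: the fluid-front height in pixels above the
#' reference coordinate, sampled at `fps` frames per second. Time for frame
#' `i` (1-based) is `t = (i - 1) / fps` seconds, measured from the first
#' retained frame (i.e. from the end of the reference window).
#'
#' @param heights numeric vector of non-negative heights (px).
#' @param fps frame rate in frames per second.
#' @param contact_frame 1-based index of the contact frame in the source
#'   video (`NA` for directly simulated series).
#' @param reference_row pixel row used as the zero coordinate (`NA` for
#'   directly simulated series).
#' @return An object of class `height_series`.
#' @seealso [extract_height_series()], [generate_profile()]
#' @export
height_series <- function(heights, fps,
                          contact_frame = NA_integer_,
                          reference_row = NA_real_) {
  heights <- as.numeric(heights)
  stopifnot(length(heights) >= 1L, all(is.finite(heights)), fps > 0)
  if (any(heights < 0)) stop("heights must be non-negative")
  structure(
    list(heights = heights, fps = fps,
         contact_frame = as.integer(contact_frame),
         reference_row = as.numeric(reference_row)),
    class = "height_series"
  )
}

#' @export
print.height_series <- function(x, ...) {
  n <- length(x$heights)
  cat(sprintf("height_series: %d frames @ %g fps (%.2f s)\n",
              n, x$fps, n / x$fps))
  cat(sprintf("  heights [px]: %.2f .. %.2f", min(x$heights), max(x$heights)))
  if (!is.na(x$contact_frame))
    cat(sprintf("  (contact frame %d, reference row %.2f)",
                x$contact_frame, x$reference_row))
  cat("\n")
  invisible(x)
}

#' @export
length.height_series <- function(x) length(x$heights)

#' Time axis of a height series
#' @param series a [height_series()].
#' @return numeric vector of times in seconds, starting at 0.
#' @export
series_time <- function(series) {
  stopifnot(inherits(series, "height_series"))
  (seq_along(series$heights) - 1) / series$fps
}

#' Write / read a height series as CSV plus JSON metadata
#'
#' The CSV has columns `frame_index` (1-based), `t_s`, `height_px`; the
#' sidecar `<path>.json` stores fps, contact frame and reference row.
#'
#' @param series a [height_series()].
#' @param path CSV output path.
#' @return `write_height_series()` returns `path` invisibly;
#'   `read_height_series()` returns a [height_series()].
#' @export
write_height_series <- function(series, path) {
  stopifnot(inherits(series, "height_series"))
  df <- data.frame(frame_index = seq_along(series$heights),
                   t_s = series_time(series),
                   height_px = series$heights)
  write.csv(df, path, row.names = FALSE)
  meta <- list(fps = series$fps, contact_frame = series$contact_frame,
               reference_row = series$reference_row)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_height_series
#' @export
read_height_series <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  height_series(df$height_px, fps = meta$fps,
                contact_frame = if (is.null(meta$contact_frame)) NA else meta$contact_frame,
                reference_row = if (is.null(meta$reference_row)) NA else meta$reference_row)
}
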