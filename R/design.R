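#' Acquisition design of a flow-profile experiment
#'
#' Describes how a measurement campaign is laid out: how many sessions are
#' run, which tannic-acid concentration classes are measured, how many strips
#' are dipped simultaneously per class, and how the video is acquired. The
#' defaults reproduce the reference design: 14 sessions of 9 cuvettes
#' (3 concentrations x 3 replicates), 61 s of video at 30 fps and
#' 1920 x 1080 px, with the first 30 frames (1 s) after contact reserved as
#' the height reference.
#'
#' @param n_sessions number of measurement sessions.
#' @param classes ordered numeric vector of concentration labels in g/L,
#'   strictly increasing.
#' @param replicates_per_class strips measured simultaneously per class and
#'   session.
#' @param fps video frame rate (frames per second).
#' @param duration_s recording length in seconds.
#' @param reference_frames number of post-contact frames used as the height
#'   reference (discarded from the retained series).
#' @param frame_height_px,frame_width_px video resolution in pixels.
#'
#' @return An object of class `capillary_design`.
#' @examples
#' d <- experiment_design()
#' n_profiles(d)         # 126
#' n_retained_frames(d)  # 1800
#' @export
experiment_design <- function(n_sessions = 14,
                              classes = c(0.1, 0.5, 1.0),
                              replicates_per_class = 3,
                              fps = 30,
                              duration_s = 61,
                              reference_frames = 30,
                              frame_height_px = 1080,
                              frame_width_px = 1920) {
  stopifnot(
    length(n_sessions) == 1L, n_sessions >= 1, n_sessions == round(n_sessions),
    is.numeric(classes), length(classes) >= 1L, !anyDuplicated(classes),
    replicates_per_class >= 1, replicates_per_class == round(replicates_per_class),
    fps > 0, duration_s > 0, reference_frames >= 1,
    frame_height_px >= 1, frame_width_px >= 1
  )
  if (is.unsorted(classes, strictly = TRUE))
    stop("`classes` must be strictly increasing concentrations (g/L)")
  if (duration_s * fps <= reference_frames)
    stop("recording too short: duration_s * fps must exceed reference_frames")
  structure(
    list(
      n_sessions = as.integer(n_sessions),
      classes = as.numeric(classes),
      replicates_per_class = as.integer(replicates_per_class),
      fps = fps,
      duration_s = duration_s,
      reference_frames = as.integer(reference_frames),
      frame_height_px = as.integer(frame_height_px),
      frame_width_px = as.integer(frame_width_px)
    ),
    class = "capillary_design"
  )
}

#' Total number of profiles implied by a design
#' @param design a [experiment_design()] object.
#' @return integer: sessions x classes x replicates.
#' @export
n_profiles <- function(design) {
  stopifnot(inherits(design, "capillary_design"))
  design$n_sessions * length(design$classes) * design$replicates_per_class
}

#' Number of retained frames per profile
#'
#' Frames recorded after contact minus the reference window:
#' `duration_s * fps - reference_frames`.
#' @inheritParams n_profiles
#' @return integer frame count (1800 under the default design).
#' @export
n_retained_frames <- function(design) {
  stopifnot(inherits(design, "capillary_design"))
  as.integer(round(design$duration_s * design$fps) - design$reference_frames)
}

#' @export
print.capillary_design <- function(x, ...) {
  cat("Capillary flow experiment design\n")
  cat(sprintf("  sessions: %d, classes (g/L): %s, replicates/class: %d\n",
              x$n_sessions, paste(x$classes, collapse = ", "),
              x$replicates_per_class))
  cat(sprintf("  video: %g s @ %g fps, %d x %d px, %d reference frames\n",
              x$duration_s, x$fps, x$frame_width_px, x$frame_height_px,
              x$reference_frames))
  cat(sprintf("  -> %d profiles, %d retained frames each\n",
              n_profiles(x), n_retained_frames(x)))
  invisible(x)
}

#' Per-class square-root-of-time coefficient model
#'
#' Defines, for each concentration class, the distribution of the flow
#' coefficients used to simulate profiles: `a ~ N(mean_a, sd_a)` (truncated
#' positive) is the slope of `h(t) = a * sqrt(t + 1) + b` in px per sqrt(s),
#' `b ~ N(mean_b, sd_b)` the vertical offset in px, and `noise_sd_px` the
#' per-frame additive measurement noise. Higher tannic-acid concentration
#' forms more mucin aggregates at the wetting front, lowering its surface
#' tension, so `mean_a` must decrease with concentration.
#'
#' The default means (60, 45, 36 px/sqrt(s) for 0.1/0.5/1.0 g/L with
#' `sd_a = 3`) put adjacent classes 5 and 3 within-class standard deviations
#' apart and keep the front inside a 1080 px frame over 61 s.
#'
#' @param classes concentration labels (g/L), matching the design.
#' @param mean_a positive per-class means of the slope, decreasing with
#'   concentration.
#' @param sd_a non-negative per-class standard deviations of the slope.
#' @param mean_b,sd_b per-class mean and sd of the vertical offset (px).
#' @param noise_sd_px additive Gaussian measurement noise per frame (px).
#'
#' @return An object of class `class_coeff_model` (a data frame with one row
#'   per class plus a `noise_sd_px` attribute).
#' @examples
#' coefficient_model()
#' @export
coefficient_model <- function(classes = c(0.1, 0.5, 1.0),
                              mean_a = c(60, 45, 36),
                              sd_a = rep(3, length(classes)),
                              mean_b = rep(0, length(classes)),
                              sd_b = rep(2, length(classes)),
                              noise_sd_px = 2) {
  k <- length(classes)
  stopifnot(
    length(mean_a) == k, length(sd_a) == k,
    length(mean_b) == k, length(sd_b) == k,
    all(mean_a > 0), all(sd_a >= 0), all(sd_b >= 0), noise_sd_px >= 0
  )
  if (is.unsorted(classes, strictly = TRUE))
    stop("`classes` must be strictly increasing concentrations (g/L)")
  if (k > 1 && any(diff(mean_a) >= 0))
    stop("`mean_a` must strictly decrease with concentration ",
         "(more aggregate, slower flow)")
  structure(
    data.frame(class_gL = as.numeric(classes), mean_a = mean_a, sd_a = sd_a,
               mean_b = mean_b, sd_b = sd_b),
    noise_sd_px = noise_sd_px,
    class = c("class_coeff_model", "data.frame")
  )
}

# Row of the model for one class label; errors on unknown labels.
model_row <- function(model, class_label) {
  stopifnot(inherits(model, "class_coeff_model"))
  i <- match(class_label, model$class_gL)
  if (is.na(i))
    stop("unknown class label: ", class_label, " (known: ",
         paste(model$class_gL, collapse = ", "), ")")
  model[i, , drop = FALSE]
}
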