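#' Draw per-class flow coefficients
#'
#' Samples `n` pairs `(a, b)` from the class distribution in `model`:
#' `a ~ N(mean_a, sd_a)` truncated to be strictly positive (negative draws are
#' rejected and redrawn) and `b ~ N(mean_b, sd_b)`. These stand in for
#' strip-to-strip variation (paper fiber structure, cut edges, positioning)
#' within one concentration class.
#'
#' @param model a [coefficient_model()].
#' @param class_label one of `model$class_gL`.
#' @param n number of pairs to draw.
#' @param seed integer seed; the draw is reproducible and leaves the global
#'   RNG state untouched.
#' @return A data frame with `n` rows and columns `a`, `b`.
#' @export
sample_class_coefficients <- function(model, class_label, n, seed = 1L) {
  stopifnot(n >= 0, n == round(n))
  row <- model_row(model, class_label)
  if (n == 0)
    return(data.frame(a = numeric(0), b = numeric(0)))
  withr::with_seed(seed, {
    a <- rnorm(n, row$mean_a, row$sd_a)
    for (iter in seq_len(100)) {          # rejection step for the a > 0 bound
      bad <- a <= 0
      if (!any(bad)) break
      a[bad] <- rnorm(sum(bad), row$mean_a, row$sd_a)
    }
    a[a <= 0] <- row$mean_a               # pathological sd; keep positive
    b <- rnorm(n, row$mean_b, row$sd_b)
    data.frame(a = a, b = b)
  })
}

#' Simulate one noisy wetting-front profile
#'
#' The noiseless front follows the shifted square-root-of-time law
#' `h(t) = a * sqrt(t + 1) + b`, with `t` in seconds from the first retained
#' frame; the `+ 1` inside the root absorbs the 1-s reference window discarded
#' after contact. Gaussian measurement noise of sd `noise_sd_px` is added per
#' frame, heights are clipped at zero and (when `quantize`) rounded to integer
#' pixels. The noiseless series is non-decreasing; the noisy one need not be --
#' monotone enforcement is a downstream extraction step, see
#' [enforce_monotone()].
#'
#' @param a slope in px per sqrt(s); must be positive.
#' @param b vertical offset in px.
#' @param design a [experiment_design()]; determines fps and the number of
#'   retained frames.
#' @param noise_sd_px additive Gaussian noise sd (px).
#' @param seed integer seed for the noise.
#' @param quantize round heights to integer pixels. Defaults to `TRUE` only
#'   when noise is present, so that noiseless profiles follow the model to
#'   machine precision.
#' @return A [height_series()] of length [n_retained_frames()].
#' @examples
#' d <- experiment_design()
#' s <- generate_profile(2, 0, d, noise_sd_px = 0)
#' length(s)        # 1800
#' s$heights[1]     # 2 * sqrt(0 + 1) = 2
#' @export
generate_profile <- function(a, b, design, noise_sd_px = 0, seed = 1L,
                             quantize = noise_sd_px > 0) {
  stopifnot(inherits(design, "capillary_design"), noise_sd_px >= 0)
  if (a <= 0) stop("slope `a` must be positive (imbibition advances)")
  n <- n_retained_frames(design)
  t <- (seq_len(n) - 1) / design$fps
  h <- a * sqrt(t + 1) + b
  if (noise_sd_px > 0)
    h <- h + withr::with_seed(seed, rnorm(n, 0, noise_sd_px))
  h <- pmax(h, 0)
  if (quantize) h <- round(h)
  height_series(h, fps = design$fps)
}

#' Strip geometry for the synthetic renderer
#'
#' Where the paper strip sits inside the frame and how wet/dry paper looks.
#' Grayscale intensities are in `[0, 1]`; wet paper images darker than dry.
#' The default geometry is deliberately small so rendered stacks stay cheap;
#' pass the design's full resolution for production-scale frames.
#'
#' @param frame_height_px,frame_width_px frame size in pixels.
#' @param strip_cols integer range `c(first, last)` of columns covered by the
#'   strip.
#' @param baseline_row pixel row (1-based from the top) of the liquid surface
#'   where the strip enters the sample.
#' @param wet_intensity,dry_intensity grayscale levels of wet and dry paper.
#' @param texture_sd optional Gaussian texture noise added per pixel.
#' @return An object of class `strip_geometry`.
#' @export
strip_geometry <- function(frame_height_px = 200, frame_width_px = 60,
                           strip_cols = c(21, 40), baseline_row = 180,
                           wet_intensity = 0.25, dry_intensity = 0.85,
                           texture_sd = 0) {
  stopifnot(
    frame_height_px >= 2, frame_width_px >= 1,
    length(strip_cols) == 2L, strip_cols[1] >= 1,
    strip_cols[2] <= frame_width_px, strip_cols[1] <= strip_cols[2],
    baseline_row >= 1, baseline_row <= frame_height_px,
    texture_sd >= 0, wet_intensity != dry_intensity
  )
  structure(
    list(frame_height_px = as.integer(frame_height_px),
         frame_width_px = as.integer(frame_width_px),
         strip_cols = as.integer(strip_cols),
         baseline_row = as.integer(baseline_row),
         wet_intensity = wet_intensity, dry_intensity = dry_intensity,
         texture_sd = texture_sd),
    class = "strip_geometry"
  )
}

#' Render a height series as a grayscale frame stack
#'
#' Produces the video a camera would record: `pad_frames` dry frames before
#' contact, `reference_frames` frames with the front at the liquid surface
#' (the reference second), then one frame per series value with the strip wet
#' from `baseline_row - round(height)` down to `baseline_row`. Extracting the
#' stack with default settings recovers the input heights to within 1 px
#' (the rounding bound).
#'
#' @param series a [height_series()].
#' @param geometry a [strip_geometry()].
#' @param reference_frames frames rendered at the surface before the retained
#'   window (default 30, i.e. 1 s at 30 fps).
#' @param pad_frames dry pre-contact frames prepended so contact detection is
#'   exercised.
#' @param seed seed for the optional texture noise.
#' @return A numeric array `[row, column, frame]` with values in `[0, 1]`,
#'   with attributes `contact_frame` (= `pad_frames + 1`) and `geometry`.
#' @export
render_frames <- function(series, geometry, reference_frames = 30L,
                          pad_frames = 15L, seed = 1L) {
  stopifnot(inherits(series, "height_series"),
            inherits(geometry, "strip_geometry"),
            reference_frames >= 1, pad_frames >= 0)
  h <- round(series$heights)
  if (geometry$baseline_row - max(h) < 1)
    stop("front exceeds frame top: baseline_row - max(height) < 1; ",
         "enlarge the frame or lower the profile")
  n_total <- pad_frames + reference_frames + length(h)
  dims <- c(geometry$frame_height_px, geometry$frame_width_px, n_total)
  frames <- array(geometry$dry_intensity, dim = dims)
  cols <- geometry$strip_cols[1]:geometry$strip_cols[2]
  # front row per frame: dry (NA) during padding, at the surface during the
  # reference second, then baseline_row - height
  front <- c(rep(NA_integer_, pad_frames),
             rep(geometry$baseline_row, reference_frames),
             geometry$baseline_row - as.integer(h))
  for (k in seq_len(n_total)) {
    if (is.na(front[k])) next
    frames[front[k]:geometry$baseline_row, cols, k] <- geometry$wet_intensity
  }
  if (geometry$texture_sd > 0) {
    frames <- frames + withr::with_seed(
      seed, array(rnorm(prod(dims), 0, geometry$texture_sd), dim = dims))
    frames[] <- pmin(pmax(frames, 0), 1)
  }
  structure(frames, contact_frame = pad_frames + 1L, geometry = geometry)
}

#' Generate a full synthetic experiment
#'
#' Draws per-profile coefficients from the class model and simulates every
#' profile of the design: `n_sessions x length(classes) x
#' replicates_per_class` labeled height series (126 under the default
#' design). Per-profile provenance (session, class, replicate, true `a` and
#' `b`) is retained so parameter recovery can be checked downstream.
#'
#' @param design a [experiment_design()].
#' @param coeff_model a [coefficient_model()]; its classes must match the
#'   design's.
#' @param seed integer master seed; sub-seeds for coefficient draws and
#'   per-profile noise are derived from it, so identical inputs give
#'   identical experiments.
#' @param quantize round simulated heights to integer pixels (see
#'   [generate_profile()]).
#' @return An object of class `synthetic_experiment`: a list with `profiles`
#'   (matrix, one row per profile), `meta` (data frame: `session`, `class_gL`,
#'   `replicate`, `a_true`, `b_true`), `design` and `seed`.
#' @examples
#' ex <- generate_experiment(experiment_design(), coefficient_model(), seed = 1)
#' dim(ex$profiles)  # 126 x 1800
#' @export
generate_experiment <- function(design, coeff_model = coefficient_model(),
                                seed = 1L,
                                quantize = attr(coeff_model, "noise_sd_px") > 0) {
  stopifnot(inherits(design, "capillary_design"),
            inherits(coeff_model, "class_coeff_model"))
  if (!identical(as.numeric(design$classes),
                 as.numeric(coeff_model$class_gL)))
    stop("design and coefficient model disagree on the class labels")
  noise <- attr(coeff_model, "noise_sd_px")
  n_per_class <- design$n_sessions * design$replicates_per_class
  seed <- as.integer(seed) %% 199999L  # keep derived seeds well inside 2^31

  # one coefficient draw per class, in class order
  coefs <- vector("list", length(design$classes))
  for (ci in seq_along(design$classes)) {
    coefs[[ci]] <- sample_class_coefficients(
      coeff_model, design$classes[ci], n_per_class,
      seed = seed + 1000L * ci)
  }

  n_tot <- n_profiles(design)
  profiles <- matrix(NA_real_, nrow = n_tot, ncol = n_retained_frames(design))
  meta <- data.frame(session = integer(n_tot), class_gL = numeric(n_tot),
                     replicate = integer(n_tot), a_true = numeric(n_tot),
                     b_true = numeric(n_tot))
  i <- 0L
  used <- integer(length(design$classes))  # draws consumed per class
  for (s in seq_len(design$n_sessions)) {
    for (ci in seq_along(design$classes)) {
      for (r in seq_len(design$replicates_per_class)) {
        i <- i + 1L
        used[ci] <- used[ci] + 1L
        ab <- coefs[[ci]][used[ci], ]
        prof <- generate_profile(ab$a, ab$b, design, noise_sd_px = noise,
                                 seed = seed + 17L * i + 3L,
                                 quantize = quantize)
        profiles[i, ] <- prof$heights
        meta$session[i] <- s
        meta$class_gL[i] <- design$classes[ci]
        meta$replicate[i] <- r
        meta$a_true[i] <- ab$a
        meta$b_true[i] <- ab$b
      }
    }
  }
  structure(list(profiles = profiles, meta = meta, design = design,
                 seed = seed),
            class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf("synthetic_experiment: %d profiles x %d frames (%d sessions, %d classes)\n",
              nrow(x$profiles), ncol(x$profiles), x$design$n_sessions,
              length(x$design$classes)))
  invisible(x)
}

#' Write / read a synthetic experiment as CSV + JSON truth sidecar
#'
#' The CSV columns are `session`, `class_gL`, `replicate`, then `h_0` ...
#' `h_<L-1>`; the sidecar `<path>.json` stores the true coefficients, the
#' design and the master seed.
#'
#' @param experiment a [generate_experiment()] result.
#' @param path CSV output path.
#' @return `write_experiment_csv()` returns `path` invisibly;
#'   `read_experiment_csv()` returns a `synthetic_experiment` (with `a_true`,
#'   `b_true` set to `NA` if the sidecar is missing).
#' @export
write_experiment_csv <- function(experiment, path) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  m <- experiment$profiles
  colnames(m) <- paste0("h_", seq_len(ncol(m)) - 1L)
  df <- cbind(experiment$meta[, c("session", "class_gL", "replicate")], m)
  write.csv(df, path, row.names = FALSE)
  truth <- list(a_true = experiment$meta$a_true,
                b_true = experiment$meta$b_true,
                seed = experiment$seed,
                design = unclass(experiment$design))
  jsonlite::write_json(truth, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_experiment_csv
#' @export
read_experiment_csv <- function(path) {
  df <- read.csv(path)
  hc <- grep("^h_", names(df))
  profiles <- as.matrix(df[, hc])
  dimnames(profiles) <- NULL
  meta <- df[, c("session", "class_gL", "replicate")]
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    truth <- jsonlite::read_json(side, simplifyVector = TRUE)
    meta$a_true <- truth$a_true
    meta$b_true <- truth$b_true
    design <- do.call(experiment_design, truth$design)
    seed <- truth$seed
  } else {
    meta$a_true <- NA_real_
    meta$b_true <- NA_real_
    design <- NULL
    seed <- NA_integer_
  }
  structure(list(profiles = profiles, meta = meta, design = design,
                 seed = seed),
            class = "synthetic_experiment")
}

#' Write a frame stack as a directory of zero-padded PNGs
#'
#' @param frames array `[row, column, frame]` with values in `[0, 1]`
#'   (e.g. from [render_frames()]).
#' @param dir output directory, created if needed.
#' @return `write_frame_dir()` returns `dir` invisibly; [read_frame_dir()]
#'   reads such a directory back into an array.
#' @export
write_frame_dir <- function(frames, dir) {
  stopifnot(length(dim(frames)) == 3L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(frames)[3]
  width <- max(6L, nchar(n))
  for (k in seq_len(n)) {
    png::writePNG(frames[, , k],
                  file.path(dir, sprintf("frame_%0*d.png", width, k)))
  }
  invisible(dir)
}
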