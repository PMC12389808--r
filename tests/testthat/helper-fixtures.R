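# Small-scale fixtures shared across tests. Scaled-down acquisition keeps
# rendered stacks and CV loops cheap while exercising the same code paths as
# the full-resolution design.

small_design <- function(n_sessions = 2, fps = 10, duration_s = 6,
                         reference_frames = 10) {
  experiment_design(n_sessions = n_sessions, classes = c(0.1, 0.5, 1.0),
                    replicates_per_class = 3, fps = fps,
                    duration_s = duration_s,
                    reference_frames = reference_frames,
                    frame_height_px = 200, frame_width_px = 60)
}

small_geometry <- function(...) {
  strip_geometry(frame_height_px = 200, frame_width_px = 60,
                 strip_cols = c(21, 40), baseline_row = 180, ...)
}

small_extraction <- function(reference_frames = 10, ...) {
  extraction_config(roi = c(21, 40), diff_threshold = 0.2,
                    min_wet_pixels_per_row = 3,
                    reference_frames = reference_frames, ...)
}

# Deterministic one-feature dataset with perfectly separated classes; a tiny
# within-class spread keeps within-group variances nonzero (LDA/NB need it)
# without shrinking the margin.
separable_dataset <- function(per_class = 3, margin = 1) {
  jitter <- seq(-0.05, 0.05, length.out = per_class)
  a <- rep(c(1, 2, 3) * margin, each = per_class) + rep(jitter, times = 3)
  profile_dataset(matrix(a, ncol = 1), labels = rep(c(0.1, 0.5, 1.0),
                                                    each = per_class),
                  groups = rep(seq_len(per_class), times = 3),
                  feature_kind = "fit_coefficient")
}

# Brute-force two-stage grid search for the square-root-of-time model:
# exhaustive (a, b) grid, refined twice around the incumbent. Independent of
# the closed-form path used by fit_washburn().
grid_fit_oracle <- function(h, t, n_grid = 61, refinements = 2) {
  x <- sqrt(t + 1)
  rng_a <- c(0, 2 * max(1e-6, (max(h) - min(h)) / (max(x) - min(x))) + 1)
  rng_b <- range(h) + c(-1, 1) * max(1, diff(range(h)))
  best <- c(a = NA_real_, b = NA_real_)
  da <- db <- NA_real_
  for (stage in 0:refinements) {
    as <- seq(rng_a[1], rng_a[2], length.out = n_grid)
    bs <- seq(rng_b[1], rng_b[2], length.out = n_grid)
    rss <- outer(as, bs, Vectorize(function(a, b) sum((h - a * x - b)^2)))
    i <- which(rss == min(rss), arr.ind = TRUE)[1, ]
    best <- c(a = as[i[1]], b = bs[i[2]])
    da <- diff(rng_a) / (n_grid - 1)   # step of the grid just searched
    db <- diff(rng_b) / (n_grid - 1)
    rng_a <- c(max(0, best[1] - 2 * da), best[1] + 2 * da)
    rng_b <- c(best[2] - 2 * db, best[2] + 2 * db)
  }
  list(a = unname(best[1]), b = unname(best[2]), res_a = da, res_b = db)
}
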