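#' Fit the shifted square-root-of-time imbibition model
#'
#' Capillary imbibition advances with the square root of time
#' (Lucas--Washburn behavior); with the first second after contact excluded
#' as reference window, the retained profile follows
#' `h(t) = a * sqrt(t + 1) + b`, where `t` is seconds from the first retained
#' frame. The fit minimizes `sum((h_i - a * sqrt(t_i + 1) - b)^2)` over the
#' first `window_s` seconds, subject to `a >= 0`.
#'
#' The model is linear in `(a, b)`, so the unconstrained minimizer is
#' obtained in closed form by linear least squares; when its slope is
#' negative the constrained optimum lies on the boundary (`a = 0`,
#' `b = mean(h)`). The solution is therefore the exact global optimum,
#' deterministic, and always converged.
#'
#' @param series a [height_series()] or numeric vector of heights.
#' @param window_s seconds of data to use from the start (default: the full
#'   series).
#' @param fps frame rate; required when `series` is a bare vector.
#' @return An object of class `washburn_fit`: list with `a`, `b`, `window_s`,
#'   `rss`, `n_points`, `converged`.
#' @examples
#' d <- experiment_design()
#' s <- generate_profile(2, 0, d, noise_sd_px = 0)
#' fit_washburn(s)$a  # 2
#' @export
fit_washburn <- function(series, window_s = NULL, fps = NULL) {
  if (inherits(series, "height_series")) {
    fps <- fps %||% series$fps
    h <- series$heights
  } else {
    h <- as.numeric(series)
  }
  if (is.null(fps)) stop("fps unknown: pass `fps`")
  stopifnot(all(is.finite(h)))
  n <- if (is.null(window_s)) length(h)
       else min(length(h), as.integer(round(window_s * fps)))
  if (n < 3) stop("need at least 3 points in the fit window, got ", n)
  h <- h[seq_len(n)]
  t <- (seq_len(n) - 1) / fps
  x <- sqrt(t + 1)
  ls <- lm.fit(cbind(intercept = 1, sqrt_t1 = x), h)
  a <- unname(ls$coefficients["sqrt_t1"])
  b <- unname(ls$coefficients["intercept"])
  if (!is.finite(a) || a < 0) {   # boundary of the a >= 0 constraint
    a <- 0
    b <- mean(h)
  }
  rss <- sum((h - a * x - b)^2)
  structure(
    list(a = a, b = b, window_s = n / fps, rss = rss, n_points = n,
         converged = TRUE),
    class = "washburn_fit"
  )
}

#' @export
print.washburn_fit <- function(x, ...) {
  cat(sprintf(
    "washburn_fit: h(t) = %.4g * sqrt(t + 1) + %.4g  (window %.2f s, n = %d, rss = %.4g)\n",
    x$a, x$b, x$window_s, x$n_points, x$rss))
  invisible(x)
}

#' Reduce every profile to its fit coefficient
#'
#' Fits `h(t) = a * sqrt(t + 1) + b` to each row of a frame-height dataset
#' and returns a single-column dataset of the slopes `a` -- the
#' "fit coefficient dataset" (`window_s = 60`) or its 15-s variant
#' (`window_s = 15`). Labels and session groups are preserved; the full fit
#' table (`a`, `b`, `rss`, `converged` per row) is attached as attribute
#' `"fits"`.
#'
#' Fitting is best done on un-normalized (or per-profile-normalized) heights:
#' per-feature min--max scaling applies a different affine map to every
#' column and therefore does not preserve the square-root shape within a row.
#'
#' @param dataset a frame-height [profile_dataset()].
#' @param window_s seconds of data used per fit (default: full length).
#' @param fps frame rate; defaults to the dataset's.
#' @return A [profile_dataset()] with `feature_kind = "fit_coefficient"`.
#' @export
build_coefficient_dataset <- function(dataset, window_s = NULL,
                                      fps = dataset$fps) {
  stopifnot(inherits(dataset, "profile_dataset"))
  if (dataset$feature_kind != "frame_height")
    stop("coefficient extraction needs a frame-height dataset")
  if (is.null(fps)) stop("fps unknown: pass `fps` or set it on the dataset")
  fits <- lapply(seq_len(nrow(dataset$matrix)), function(i)
    fit_washburn(dataset$matrix[i, ], window_s = window_s, fps = fps))
  tab <- data.frame(session = dataset$groups, class_gL = dataset$labels,
                    a = vapply(fits, `[[`, 0, "a"),
                    b = vapply(fits, `[[`, 0, "b"),
                    rss = vapply(fits, `[[`, 0, "rss"),
                    window_s = vapply(fits, `[[`, 0, "window_s"),
                    converged = vapply(fits, `[[`, TRUE, "converged"))
  out <- profile_dataset(matrix(tab$a, ncol = 1,
                                dimnames = list(NULL, "a")),
                         labels = dataset$labels, groups = dataset$groups,
                         feature_kind = "fit_coefficient", fps = fps)
  attr(out, "fits") <- tab
  out
}

#' Write Washburn fit results as CSV
#'
#' @param coef_dataset a [build_coefficient_dataset()] result.
#' @param path CSV output path (columns: session, class_gL, a, b, rss,
#'   window_s, converged).
#' @return `path`, invisibly.
#' @export
write_fits_csv <- function(coef_dataset, path) {
  tab <- attr(coef_dataset, "fits")
  if (is.null(tab)) stop("no fit table attached to this dataset")
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
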