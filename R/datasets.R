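#' Labeled profile dataset
#'
#' A samples x features matrix with one concentration label and one session
#' id per row. `feature_kind` is `"frame_height"` (columns are frames) or
#' `"fit_coefficient"` (a single fitted-slope column). `normalization`
#' records how values were scaled (`"none"`, `"per_feature"`,
#' `"per_profile"`).
#'
#' @param matrix numeric samples x features matrix.
#' @param labels concentration class per row (numeric g/L or factor).
#' @param groups session id per row.
#' @param feature_kind `"frame_height"` or `"fit_coefficient"`.
#' @param normalization `"none"`, `"per_feature"` or `"per_profile"`.
#' @param fps frame rate behind the feature columns (frame-height datasets).
#' @param norm_params scaling parameters recorded by [minmax_normalize()].
#' @return An object of class `profile_dataset`.
#' @export
profile_dataset <- function(matrix, labels, groups,
                            feature_kind = c("frame_height",
                                             "fit_coefficient"),
                            normalization = "none", fps = NULL,
                            norm_params = NULL) {
  feature_kind <- match.arg(feature_kind)
  matrix <- as.matrix(matrix)
  stopifnot(is.numeric(matrix), nrow(matrix) >= 1,
            length(labels) == nrow(matrix), length(groups) == nrow(matrix),
            normalization %in% c("none", "per_feature", "per_profile"))
  if (feature_kind == "fit_coefficient" && ncol(matrix) != 1L)
    stop("a fit-coefficient dataset has exactly one column")
  structure(
    list(matrix = matrix, labels = labels, groups = groups,
         feature_kind = feature_kind, normalization = normalization,
         fps = fps, norm_params = norm_params),
    class = "profile_dataset"
  )
}

#' @export
print.profile_dataset <- function(x, ...) {
  cat(sprintf("profile_dataset: %d x %d (%s, normalization: %s)\n",
              nrow(x$matrix), ncol(x$matrix), x$feature_kind,
              x$normalization))
  cat("  classes:",
      paste(sprintf("%s (n=%d)", names(table(x$labels)), table(x$labels)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.profile_dataset <- function(x) dim(x$matrix)

#' Assemble the raw dataset
#'
#' Stacks profiles into a samples x frames matrix, one row per profile in
#' input order, with aligned class labels and session groups. Under the
#' reference design this is the 126 x 1800 "raw dataset".
#'
#' @param profiles a `synthetic_experiment`, a numeric matrix, or a list of
#'   [height_series()] / numeric vectors of equal length.
#' @param labels,groups per-profile class labels and session ids; taken from
#'   the experiment's metadata when `profiles` is a `synthetic_experiment`.
#' @param fps frame rate; taken from the experiment design when available.
#' @return A [profile_dataset()] with `feature_kind = "frame_height"`.
#' @export
build_raw_dataset <- function(profiles, labels = NULL, groups = NULL,
                              fps = NULL) {
  if (inherits(profiles, "synthetic_experiment")) {
    labels <- labels %||% profiles$meta$class_gL
    groups <- groups %||% profiles$meta$session
    fps <- fps %||% (if (!is.null(profiles$design)) profiles$design$fps)
    profiles <- profiles$profiles
  }
  if (is.list(profiles) && !is.matrix(profiles)) {
    vecs <- lapply(profiles, function(p)
      if (inherits(p, "height_series")) p$heights else as.numeric(p))
    lens <- lengths(vecs)
    if (length(unique(lens)) != 1L)
      stop("ragged profiles: lengths ", paste(unique(lens), collapse = ", "))
    if (is.null(fps)) {
      fpss <- unique(unlist(lapply(profiles, function(p)
        if (inherits(p, "height_series")) p$fps)))
      if (length(fpss) == 1L) fps <- fpss
    }
    profiles <- do.call(rbind, vecs)
  }
  profile_dataset(profiles, labels, groups, feature_kind = "frame_height",
                  fps = fps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Average simultaneously acquired replicates
#'
#' Collapses each (session, class) group to the elementwise arithmetic mean
#' of its rows, averaging out strip-to-strip variation from paper fiber
#' structure and positioning. Row order follows the first occurrence of each
#' group in the input. Under the reference design 126 profiles collapse to
#' the 42-row "mean dataset".
#'
#' @param dataset a [profile_dataset()].
#' @return A [profile_dataset()] with one row per (session, class).
#' @export
average_replicates <- function(dataset) {
  stopifnot(inherits(dataset, "profile_dataset"))
  key <- paste(dataset$groups, dataset$labels, sep = "\r")
  first <- !duplicated(key)
  ukey <- key[first]
  idx <- split(seq_along(key), factor(key, levels = ukey))
  m <- do.call(rbind, lapply(idx, function(i)
    colMeans(dataset$matrix[i, , drop = FALSE])))
  rownames(m) <- NULL
  profile_dataset(m, labels = dataset$labels[first],
                  groups = dataset$groups[first],
                  feature_kind = dataset$feature_kind,
                  normalization = dataset$normalization, fps = dataset$fps)
}

#' Min--max scale a dataset to the unit interval
#'
#' `per_feature` rescales each column by its own minimum and maximum across
#' samples (each frame index gets its own scale); `per_profile` rescales each
#' row by its own range. A constant column (or row) maps to all zeros. The
#' scaling parameters are recorded in `norm_params` for audit and for
#' mapping fitted coefficients back to pixel units.
#'
#' Normalizing an already-normalized dataset is a no-op (all columns/rows
#' already span `[0, 1]`), so the operation is idempotent.
#'
#' @param dataset a [profile_dataset()].
#' @param mode `"per_feature"` (default) or `"per_profile"`.
#' @return A [profile_dataset()] with values in `[0, 1]`.
#' @export
minmax_normalize <- function(dataset, mode = c("per_feature",
                                               "per_profile")) {
  stopifnot(inherits(dataset, "profile_dataset"))
  mode <- match.arg(mode)
  m <- dataset$matrix
  if (mode == "per_feature") {
    lo <- apply(m, 2, min)
    hi <- apply(m, 2, max)
    rng <- hi - lo
    out <- sweep(m, 2, lo, "-")
    out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/")
    out[, rng == 0] <- 0
  } else {
    lo <- apply(m, 1, min)
    hi <- apply(m, 1, max)
    rng <- hi - lo
    out <- sweep(m, 1, lo, "-")
    out <- sweep(out, 1, ifelse(rng > 0, rng, 1), "/")
    out[rng == 0, ] <- 0
  }
  profile_dataset(out, dataset$labels, dataset$groups,
                  feature_kind = dataset$feature_kind,
                  normalization = mode, fps = dataset$fps,
                  norm_params = list(mode = mode, min = lo, max = hi))
}

#' Keep only the first seconds of each profile
#'
#' Truncates a frame-height dataset to its first `seconds * fps` columns,
#' e.g. the first 15 s used for quick fitting.
#'
#' @param dataset a frame-height [profile_dataset()].
#' @param seconds window length in seconds.
#' @param fps frame rate; defaults to the dataset's.
#' @return A [profile_dataset()] with `round(seconds * fps)` columns.
#' @export
truncate_window <- function(dataset, seconds, fps = dataset$fps) {
  stopifnot(inherits(dataset, "profile_dataset"), seconds > 0)
  if (dataset$feature_kind != "frame_height")
    stop("truncate_window applies to frame-height datasets")
  if (is.null(fps)) stop("fps unknown: pass `fps` or set it on the dataset")
  n <- as.integer(round(seconds * fps))
  if (n > ncol(dataset$matrix))
    stop("window of ", seconds, " s (", n, " frames) exceeds the ",
         ncol(dataset$matrix), " available frames")
  profile_dataset(dataset$matrix[, seq_len(n), drop = FALSE],
                  dataset$labels, dataset$groups,
                  feature_kind = dataset$feature_kind,
                  normalization = dataset$normalization, fps = fps,
                  norm_params = dataset$norm_params)
}

#' Write / read a profile dataset as CSV plus JSON sidecar
#'
#' Columns are `session`, `class_gL`, then the feature columns; the sidecar
#' `<path>.json` stores feature kind, normalization mode and scaling
#' parameters.
#'
#' @param dataset a [profile_dataset()].
#' @param path CSV output path.
#' @return `write_dataset_csv()` returns `path` invisibly;
#'   `read_dataset_csv()` returns a [profile_dataset()].
#' @export
write_dataset_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "profile_dataset"))
  m <- dataset$matrix
  if (is.null(colnames(m)))
    colnames(m) <- if (dataset$feature_kind == "fit_coefficient") "a"
                   else paste0("h_", seq_len(ncol(m)) - 1L)
  df <- cbind(data.frame(session = dataset$groups,
                         class_gL = dataset$labels), m)
  write.csv(df, path, row.names = FALSE)
  meta <- list(feature_kind = dataset$feature_kind,
               normalization = dataset$normalization, fps = dataset$fps,
               norm_params = dataset$norm_params)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  df <- read.csv(path)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  side <- paste0(path, ".json")
  meta <- if (file.exists(side))
    jsonlite::read_json(side, simplifyVector = TRUE)
  else list(feature_kind = "frame_height", normalization = "none",
            fps = NULL, norm_params = NULL)
  profile_dataset(m, labels = df$class_gL, groups = df$session,
                  feature_kind = meta$feature_kind,
                  normalization = meta$normalization,
                  fps = meta$fps, norm_params = meta$norm_params)
}
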