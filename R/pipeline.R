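#' Pipeline run configuration
#'
#' Bundles every knob of an end-to-end run: the acquisition design, the
#' class coefficient model used for simulation, extraction settings,
#' normalization mode, fit windows, classifier selection and the master
#' seed. Fully serializable to YAML, so a stored config plus its seed
#' reproduces every artifact.
#'
#' @param design a [experiment_design()].
#' @param coeff_model a [coefficient_model()].
#' @param extraction an [extraction_config()] or `NULL` (only needed for the
#'   `extract` stage).
#' @param normalization min--max mode for the frame-height datasets
#'   (`"per_feature"` or `"per_profile"`).
#' @param fit_windows_s numeric fit windows in seconds (default `c(60, 15)`;
#'   the first is the primary window).
#' @param families classifier families to compare (default `"svm"`; set to
#'   [classifier_families()] for the full eight-way comparison).
#' @param classify_datasets which dataset variants to classify, a subset of
#'   `c("raw", "mean", "coef", "coef15")`.
#' @param frames_dir optional directory of per-profile PNG frame-stack
#'   subdirectories for the `extract` stage.
#' @param seed master integer seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(design = experiment_design(),
                       coeff_model = coefficient_model(),
                       extraction = NULL,
                       normalization = "per_feature",
                       fit_windows_s = c(60, 15),
                       families = "svm",
                       classify_datasets = c("raw", "mean", "coef",
                                             "coef15"),
                       frames_dir = NULL,
                       seed = 1L) {
  stopifnot(inherits(design, "capillary_design"),
            inherits(coeff_model, "class_coeff_model"),
            is.null(extraction) || inherits(extraction, "extraction_config"),
            normalization %in% c("per_feature", "per_profile"),
            length(fit_windows_s) >= 1, all(fit_windows_s > 0),
            all(families %in% classifier_families()),
            all(classify_datasets %in% c("raw", "mean", "coef", "coef15")))
  structure(
    list(design = design, coeff_model = coeff_model,
         extraction = extraction, normalization = normalization,
         fit_windows_s = fit_windows_s, families = families,
         classify_datasets = classify_datasets, frames_dir = frames_dir,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read / write a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns a [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- list(
    design = unclass(config$design),
    coeff_model = c(as.list(as.data.frame(config$coeff_model)),
                    list(noise_sd_px = attr(config$coeff_model,
                                            "noise_sd_px"))),
    extraction = if (!is.null(config$extraction))
      unclass(config$extraction),
    normalization = config$normalization,
    fit_windows_s = config$fit_windows_s,
    families = config$families,
    classify_datasets = config$classify_datasets,
    frames_dir = config$frames_dir,
    seed = config$seed
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  cm <- x$coeff_model
  run_config(
    design = do.call(experiment_design, x$design),
    coeff_model = coefficient_model(classes = cm$class_gL,
                                    mean_a = cm$mean_a, sd_a = cm$sd_a,
                                    mean_b = cm$mean_b, sd_b = cm$sd_b,
                                    noise_sd_px = cm$noise_sd_px),
    extraction = if (!is.null(x$extraction))
      do.call(extraction_config, x$extraction),
    normalization = x$normalization,
    fit_windows_s = as.numeric(x$fit_windows_s),
    families = x$families,
    classify_datasets = x$classify_datasets,
    frames_dir = x$frames_dir,
    seed = x$seed
  )
}

pipeline_stages <- c("simulate", "extract", "datasets", "fit", "classify",
                     "report")

artifact <- function(out_dir, name) file.path(out_dir, name)

need_artifact <- function(out_dir, name, producer) {
  p <- artifact(out_dir, name)
  if (!file.exists(p))
    stop("missing artifact `", name, "` in ", out_dir,
         ": run the `", producer, "` stage first")
  p
}

#' Run the end-to-end pipeline
#'
#' Executes the requested stages in canonical order (`simulate`, `extract`,
#' `datasets`, `fit`, `classify`, `report`), writing every intermediate as
#' CSV/JSON under `out_dir` plus a `manifest.json` with the config hash,
#' seed, package version and per-stage row counts. Later stages read their
#' inputs from `out_dir`, so stages can be re-run individually; a missing
#' upstream artifact raises an error naming the stage that produces it.
#'
#' Stage overview:
#' * `simulate` -- generate the synthetic experiment (`profiles.csv` + truth
#'   sidecar).
#' * `extract` -- read per-profile PNG frame-stack directories from
#'   `config$frames_dir` and write the extracted `profiles.csv` (alternative
#'   to `simulate` for real/rendered video input; labels are read from a
#'   `labels.csv` in that directory with columns `dir`, `session`,
#'   `class_gL`).
#' * `datasets` -- raw and replicate-averaged matrices plus their min--max
#'   normalized variants.
#' * `fit` -- Washburn coefficient datasets for every configured window
#'   (fitted on the un-normalized mean dataset).
#' * `classify` -- [compare_families()] on each configured dataset variant
#'   (normalized raw/mean; coefficient datasets as-is). Dataset-wide
#'   normalization precedes the CV split by design, mirroring the measured
#'   protocol; a note is logged.
#' * `report` -- ANOVA + Tukey letters on the primary-window coefficients
#'   and a JSON summary of the classification results.
#'
#' @param config a [run_config()].
#' @param stages subset of the stage names above (default: all but
#'   `extract`, which needs `frames_dir`).
#' @param out_dir output directory, created if needed.
#' @param quiet suppress progress messages.
#' @return The manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config,
                         stages = setdiff(pipeline_stages, "extract"),
                         out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  stages <- pipeline_stages[pipeline_stages %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[capflow] ", sprintf(...))
  manifest <- list(package_version = as.character(
    utils::packageVersion("capflow")),
    seed = config$seed, stages = stages, counts = list())
  cfg_path <- artifact(out_dir, "config.yaml")
  write_run_config(config, cfg_path)
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))

  for (stage in stages) {
    t0 <- proc.time()[["elapsed"]]
    counts <- switch(
      stage,
      simulate = {
        ex <- generate_experiment(config$design, config$coeff_model,
                                  seed = config$seed)
        write_experiment_csv(ex, artifact(out_dir, "profiles.csv"))
        list(profiles = nrow(ex$profiles), frames = ncol(ex$profiles))
      },
      extract = {
        if (is.null(config$frames_dir) || is.null(config$extraction))
          stop("`extract` needs config$frames_dir and config$extraction")
        lab <- read.csv(file.path(config$frames_dir, "labels.csv"))
        series <- lapply(lab$dir, function(d) {
          frames <- read_frame_dir(file.path(config$frames_dir, d))
          extract_height_series(frames, config$extraction,
                                fps = config$design$fps)
        })
        ds <- build_raw_dataset(series, labels = lab$class_gL,
                                groups = lab$session,
                                fps = config$design$fps)
        m <- ds$matrix
        colnames(m) <- paste0("h_", seq_len(ncol(m)) - 1L)
        write.csv(cbind(data.frame(session = lab$session,
                                   class_gL = lab$class_gL,
                                   replicate = seq_len(nrow(lab))), m),
                  artifact(out_dir, "profiles.csv"), row.names = FALSE)
        list(profiles = nrow(m), frames = ncol(m))
      },
      datasets = {
        p <- need_artifact(out_dir, "profiles.csv", "simulate (or extract)")
        ex <- read_experiment_csv(p)
        raw <- build_raw_dataset(ex$profiles, labels = ex$meta$class_gL,
                                 groups = ex$meta$session,
                                 fps = config$design$fps)
        mean_ds <- average_replicates(raw)
        write_dataset_csv(raw, artifact(out_dir, "raw_dataset.csv"))
        write_dataset_csv(mean_ds, artifact(out_dir, "mean_dataset.csv"))
        write_dataset_csv(minmax_normalize(raw, config$normalization),
                          artifact(out_dir, "raw_dataset_norm.csv"))
        write_dataset_csv(minmax_normalize(mean_ds, config$normalization),
                          artifact(out_dir, "mean_dataset_norm.csv"))
        list(raw_rows = nrow(raw$matrix), mean_rows = nrow(mean_ds$matrix))
      },
      fit = {
        p <- need_artifact(out_dir, "mean_dataset.csv", "datasets")
        mean_ds <- read_dataset_csv(p)
        n <- list()
        for (w in config$fit_windows_s) {
          cd <- build_coefficient_dataset(mean_ds, window_s = w,
                                          fps = config$design$fps)
          tag <- paste0("coef_", w, "s")
          write_dataset_csv(cd, artifact(out_dir, paste0(tag, ".csv")))
          write_fits_csv(cd, artifact(out_dir, paste0("fits_", w, "s.csv")))
          n[[tag]] <- nrow(cd$matrix)
        }
        n
      },
      classify = {
        say("note: min-max scaling uses the whole dataset before the CV split (by design)")
        sets <- list()
        if ("raw" %in% config$classify_datasets)
          sets$raw <- read_dataset_csv(
            need_artifact(out_dir, "raw_dataset_norm.csv", "datasets"))
        if ("mean" %in% config$classify_datasets)
          sets$mean <- read_dataset_csv(
            need_artifact(out_dir, "mean_dataset_norm.csv", "datasets"))
        w <- config$fit_windows_s
        if ("coef" %in% config$classify_datasets)
          sets$coef <- read_dataset_csv(need_artifact(
            out_dir, paste0("coef_", w[1], "s.csv"), "fit"))
        if ("coef15" %in% config$classify_datasets && length(w) >= 2)
          sets$coef15 <- read_dataset_csv(need_artifact(
            out_dir, paste0("coef_", w[2], "s.csv"), "fit"))
        acc <- lapply(names(sets), function(nm) {
          tab <- compare_families(sets[[nm]], families = config$families,
                                  seed = config$seed)
          tab$dataset <- nm
          attr(tab, "cv_results") <- NULL
          tab
        })
        acc <- do.call(rbind, acc)
        write.csv(acc, artifact(out_dir, "accuracy_table.csv"),
                  row.names = FALSE)
        jsonlite::write_json(acc, artifact(out_dir, "classification.json"),
                             dataframe = "rows", auto_unbox = TRUE,
                             digits = NA)
        list(models = nrow(acc))
      },
      report = {
        p <- need_artifact(out_dir,
                           paste0("fits_", config$fit_windows_s[1], "s.csv"),
                           "fit")
        fits <- read.csv(p)
        at <- anova_tukey(fits$a, fits$class_gL)
        write_letters_csv(at, artifact(out_dir, "tukey_letters.csv"))
        summary <- list(
          anova = list(F = at$F, p = at$p, alpha = at$alpha),
          letters = as.list(at$letters),
          class_means = as.list(at$means)
        )
        acc_path <- artifact(out_dir, "accuracy_table.csv")
        if (file.exists(acc_path))
          summary$accuracy_table <- read.csv(acc_path)
        jsonlite::write_json(summary, artifact(out_dir, "report.json"),
                             auto_unbox = TRUE, digits = NA,
                             dataframe = "rows")
        list(groups = length(at$letters))
      }
    )
    dt <- proc.time()[["elapsed"]] - t0
    manifest$counts[[stage]] <- counts
    manifest$timings_s[[stage]] <- round(dt, 3)
    say("stage %-9s done in %6.2f s  (%s)", stage, dt,
        paste(names(counts), unlist(counts), sep = "=", collapse = ", "))
  }
  jsonlite::write_json(manifest, artifact(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
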