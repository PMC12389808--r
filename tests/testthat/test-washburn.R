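test_that("noiseless profiles are recovered to floating-point precision", {
  d <- experiment_design()
  s <- generate_profile(2, 0, d, noise_sd_px = 0)
  s$heights <- s$heights - 1                      # shift to b = -1
  fit <- fit_washburn(s)
  expect_lt(abs(fit$a - 2) / 2, 1e-8)
  expect_lt(abs(fit$b + 1), 1e-8)
  expect_lt(fit$rss, 1e-12)
  expect_true(fit$converged)
  expect_equal(fit$n_points, 1800)
})

test_that("flat data hits the a >= 0 boundary", {
  fit <- fit_washburn(rep(7, 100), fps = 30)
  expect_equal(fit$a, 0)
  expect_equal(fit$b, 7)

  # decreasing data would want a < 0; the constrained optimum is flat
  dec <- fit_washburn(seq(10, 1, length.out = 50), fps = 10)
  expect_equal(dec$a, 0)
  expect_equal(dec$b, mean(seq(10, 1, length.out = 50)))
})

test_that("15-s and 60-s windows agree exactly on noiseless data", {
  d <- experiment_design()
  s <- generate_profile(3.5, 1.25, d, noise_sd_px = 0)
  f60 <- fit_washburn(s, window_s = 60)
  f15 <- fit_washburn(s, window_s = 15)
  expect_equal(f15$n_points, 450)
  expect_equal(f15$a, f60$a, tolerance = 1e-10)
  expect_equal(f15$b, f60$b, tolerance = 1e-10)
})

test_that("noisy fits agree with the two-stage exhaustive grid oracle", {
  d <- small_design(duration_s = 10)
  withr::with_seed(21, {
    for (rep in 1:5) {
      a <- runif(1, 5, 40)
      b <- runif(1, -5, 5)
      s <- generate_profile(a, b, d, noise_sd_px = 2, seed = rep,
                            quantize = FALSE)
      fit <- fit_washburn(s)
      oracle <- grid_fit_oracle(s$heights, series_time(s))
      expect_lt(abs(fit$a - oracle$a), 2 * oracle$res_a)
      expect_lt(abs(fit$b - oracle$b), 2 * oracle$res_b)
      # the closed form can only do better than the grid
      x <- sqrt(series_time(s) + 1)
      expect_lte(fit$rss,
                 sum((s$heights - oracle$a * x - oracle$b)^2) + 1e-9)
    }
  })
})

test_that("fits are translation- and scale-consistent", {
  d <- small_design()
  s <- generate_profile(12, 2, d, noise_sd_px = 1.5, seed = 2,
                        quantize = FALSE)
  base <- fit_washburn(s)

  shifted <- fit_washburn(s$heights + 10, fps = d$fps)
  expect_equal(shifted$a, base$a, tolerance = 1e-9)
  expect_equal(shifted$b, base$b + 10, tolerance = 1e-9)

  scaled <- fit_washburn(s$heights * 3, fps = d$fps)
  expect_equal(scaled$a, base$a * 3, tolerance = 1e-9)
  expect_equal(scaled$b, base$b * 3, tolerance = 1e-9)
})

test_that("recovery error shrinks as noise vanishes and window grows", {
  d <- experiment_design(n_sessions = 1)
  rel_err <- function(noise_sd, window_s = NULL) {
    errs <- vapply(1:15, function(i) {
      a <- 30 + 2 * i
      s <- generate_profile(a, 1, d, noise_sd_px = noise_sd, seed = 100 + i,
                            quantize = FALSE)
      abs(fit_washburn(s, window_s = window_s)$a - a) / a
    }, 0)
    median(errs)
  }
  e_hi <- rel_err(8)
  e_lo <- rel_err(0.5)
  e_0 <- rel_err(0)
  expect_gt(e_hi, e_lo)
  expect_gt(e_lo, e_0)
  expect_lt(e_0, 1e-10)
  # shorter window, same noise: worse or equal median recovery
  expect_gte(rel_err(8, window_s = 15), e_hi * 0.5)
})

test_that("an early-time disturbance biases the short-window fit only", {
  # emulates immersion-depth transients: the 15-s estimate drifts, the 60-s
  # estimate stays close to the true slope
  d <- experiment_design(n_sessions = 1)
  s <- generate_profile(40, 0, d, noise_sd_px = 0)
  t <- series_time(s)
  s$heights <- s$heights + 15 * exp(-t / 4)       # decaying disturbance
  f60 <- fit_washburn(s, window_s = 60)
  f15 <- fit_washburn(s, window_s = 15)
  expect_gt(abs(f15$a - 40), abs(f60$a - 40))
})

test_that("coefficient dataset reduces rows to their true slope", {
  d <- small_design()
  m <- coefficient_model(noise_sd_px = 0)
  ex <- generate_experiment(d, m, seed = 9, quantize = FALSE)
  raw <- build_raw_dataset(ex)
  cd <- build_coefficient_dataset(raw)
  expect_equal(ncol(cd$matrix), 1)
  expect_equal(cd$feature_kind, "fit_coefficient")
  expect_equal(cd$labels, raw$labels)
  expect_lt(max(abs(cd$matrix[, 1] - ex$meta$a_true)), 1e-6)

  # 15-s and full-window columns coincide without noise
  cd15 <- build_coefficient_dataset(raw, window_s = 1.5)
  expect_equal(cd15$matrix, cd$matrix, tolerance = 1e-8)

  fits <- attr(cd, "fits")
  expect_named(fits, c("session", "class_gL", "a", "b", "rss", "window_s",
                       "converged"))
  expect_true(all(fits$converged))
  expect_error(build_coefficient_dataset(cd), "frame-height")
})

test_that("per-profile normalization rescales the slope recoverably", {
  d <- small_design()
  ex <- generate_experiment(d, coefficient_model(noise_sd_px = 0), seed = 4,
                            quantize = FALSE)
  raw <- build_raw_dataset(ex)
  norm <- minmax_normalize(raw, "per_profile")
  cd <- build_coefficient_dataset(norm)
  scale <- norm$norm_params$max - norm$norm_params$min
  expect_lt(max(abs(cd$matrix[, 1] * scale - ex$meta$a_true)), 1e-6)
})
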