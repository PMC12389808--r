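test_that("experiment design encodes the acquisition arithmetic", {
  d <- experiment_design()
  expect_equal(n_profiles(d), 126)
  expect_equal(n_retained_frames(d), 1800)
  expect_error(experiment_design(classes = c(0.5, 0.1)), "increasing")
  expect_error(experiment_design(duration_s = 0.5, fps = 30,
                                 reference_frames = 30), "too short")
})

test_that("coefficient model enforces slowing flow with concentration", {
  m <- coefficient_model()
  expect_true(all(diff(m$mean_a) < 0))
  expect_error(coefficient_model(mean_a = c(30, 45, 36)), "decrease")
  expect_error(model_row(m, 7), "unknown class")
})

test_that("class coefficient draws respect the distribution and the bound", {
  m <- coefficient_model()
  expect_equal(nrow(sample_class_coefficients(m, 0.1, 0)), 0)

  degen <- coefficient_model(mean_a = c(4, 3, 2), sd_a = rep(0, 3),
                             mean_b = rep(0, 3), sd_b = rep(0, 3))
  expect_equal(sample_class_coefficients(degen, 0.5, 3),
               data.frame(a = c(3, 3, 3), b = c(0, 0, 0)))

  # law of large numbers: sample mean within 6 standard errors
  draws <- sample_class_coefficients(
    coefficient_model(mean_a = c(4, 3, 2), sd_a = rep(0.1, 3)),
    1.0, 10000, seed = 42)
  expect_lt(abs(mean(draws$a) - 2), 2 * (0.1 / sqrt(10000)) * 3)

  # truncation keeps a strictly positive even when the Gaussian does not
  low <- coefficient_model(mean_a = c(3, 2, 0.5), sd_a = rep(1, 3))
  expect_true(all(sample_class_coefficients(low, 1.0, 2000, seed = 3)$a > 0))

  expect_identical(sample_class_coefficients(m, 0.1, 5, seed = 9),
                   sample_class_coefficients(m, 0.1, 5, seed = 9))
})

test_that("noiseless profiles follow a*sqrt(t+1)+b exactly", {
  d <- experiment_design()
  s <- generate_profile(2, 0, d, noise_sd_px = 0)
  expect_equal(length(s), 1800)
  expect_equal(s$heights[1], 2)                   # t = 0 -> 2*sqrt(1)
  expect_equal(s$heights[3 * d$fps + 1], 4)       # t = 3 s -> 2*sqrt(4)
  t <- series_time(s)
  expect_equal(s$heights, 2 * sqrt(t + 1), tolerance = 1e-12)
  expect_false(is.unsorted(s$heights))
  expect_error(generate_profile(-1, 0, d), "positive")
})

test_that("measurement noise breaks monotonicity but not determinism", {
  d <- small_design()
  s1 <- generate_profile(10, 0, d, noise_sd_px = 3, seed = 5)
  s2 <- generate_profile(10, 0, d, noise_sd_px = 3, seed = 5)
  expect_identical(s1$heights, s2$heights)
  expect_true(is.unsorted(s1$heights))            # noise undoes monotone
  expect_true(all(s1$heights >= 0))               # clipped at zero
  expect_true(all(s1$heights == round(s1$heights)))  # pixel quantization
})

test_that("renderer places the front where the series says", {
  d <- small_design()
  g <- small_geometry()
  s <- generate_profile(10, 2, d, noise_sd_px = 0)
  fr <- render_frames(s, g, reference_frames = d$reference_frames,
                      pad_frames = 5)
  expect_equal(dim(fr)[3], 5 + d$reference_frames + length(s))

  k <- 5 + d$reference_frames + 10                # 10th retained frame
  wet <- which(fr[, 30, k] < 0.5)                 # column inside the strip
  expect_equal(min(wet), g$baseline_row - round(s$heights[10]))
  expect_equal(max(wet), g$baseline_row)

  # zero-height series: all post-contact frames identical, dry above baseline
  z <- height_series(rep(0, 10), fps = d$fps)
  fz <- render_frames(z, g, reference_frames = 3, pad_frames = 2)
  expect_true(all(fz[seq_len(g$baseline_row - 1), , 3:dim(fz)[3]] ==
                    g$dry_intensity))

  # front beyond the frame top is a geometry error
  tall <- height_series(c(10, 500), fps = d$fps)
  expect_error(render_frames(tall, g, reference_frames = 2), "frame top")
})

test_that("generated experiments have the designed shape and provenance", {
  d <- small_design()
  ex <- generate_experiment(d, coefficient_model(), seed = 11)
  expect_equal(dim(ex$profiles), c(18, 50))
  expect_equal(as.integer(table(ex$meta$class_gL)), rep(6L, 3))
  expect_named(ex$meta, c("session", "class_gL", "replicate", "a_true",
                          "b_true"))
  expect_true(all(ex$meta$a_true > 0))

  one <- generate_experiment(
    experiment_design(n_sessions = 1, classes = 0.1,
                      replicates_per_class = 1, fps = 10, duration_s = 6,
                      reference_frames = 10),
    coefficient_model(classes = 0.1, mean_a = 10, sd_a = 1, mean_b = 0,
                      sd_b = 1),
    seed = 1)
  expect_equal(nrow(one$profiles), 1)

  expect_identical(generate_experiment(d, coefficient_model(), seed = 11),
                   ex)
})

test_that("with zero spread, more concentrated classes flow strictly slower", {
  d <- small_design()
  m <- coefficient_model(sd_a = rep(0, 3), mean_b = rep(0, 3),
                         sd_b = rep(0, 3), noise_sd_px = 0)
  ex <- generate_experiment(d, m, seed = 1)
  for (ci in 1:2) {
    hi <- ex$profiles[ex$meta$class_gL == d$classes[ci], , drop = FALSE]
    lo <- ex$profiles[ex$meta$class_gL == d$classes[ci + 1], , drop = FALSE]
    expect_true(all(apply(lo, 1, function(r) all(r < t(hi)))))
  }
})

test_that("experiment CSV + truth sidecar round-trips", {
  d <- small_design()
  ex <- generate_experiment(d, coefficient_model(), seed = 2)
  path <- file.path(withr::local_tempdir(), "profiles.csv")
  write_experiment_csv(ex, path)
  back <- read_experiment_csv(path)
  expect_equal(back$profiles, ex$profiles)
  expect_equal(back$meta$a_true, ex$meta$a_true, tolerance = 1e-12)
  expect_equal(n_profiles(back$design), n_profiles(d))
})
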