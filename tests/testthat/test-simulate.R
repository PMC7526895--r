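test_that("an event-free, jitter-free rhythm is perfectly regular", {
  s <- simulate_rr(rr_model(base_period = 0.1), 20, seed = 1)
  expect_length(s$periods, 200L)
  expect_true(all(abs(s$periods - 0.1) < 1e-12))
  expect_equal(s$beat_times[1], 0)
})

test_that("simulation is deterministic under a fixed seed", {
  m <- rr_model(base_period = 0.091, jitter_sd = 0.003, skip_prob = 0.02,
                premature_prob = 0.02)
  s1 <- simulate_rr(m, 20, seed = 99)
  s2 <- simulate_rr(m, 20, seed = 99)
  expect_identical(s1$beat_times, s2$beat_times)
  s3 <- simulate_rr(m, 20, seed = 100)
  expect_false(identical(s1$beat_times, s3$beat_times))
})

test_that("skip probability reproduces as the fraction of merged periods", {
  m <- rr_model(base_period = 0.091, skip_prob = 0.05)
  s <- simulate_rr(m, 0.091 * 10500, seed = 41)   # ~10,000 beats
  frac <- mean(s$periods > 1.5 * median(s$periods))
  n <- length(s$periods)
  sd3 <- 3 * sqrt(0.05 * 0.95 / n)
  expect_gt(frac, 0.05 / (1 + 0.05) - sd3)  # merged periods shrink the count
  expect_lt(frac, 0.05 + sd3)
})

test_that("premature beats split periods without changing elapsed time", {
  m <- rr_model(base_period = 0.1, premature_prob = 0.2,
                premature_fraction = 0.6)
  s <- simulate_rr(m, 50, seed = 42)
  expect_gt(s$n_premature, 0)
  short <- sum(abs(s$periods - 0.06) < 1e-9)
  comp <- sum(abs(s$periods - 0.04) < 1e-9)
  expect_gte(short, s$n_premature - 1)   # last event may be truncated
  expect_gte(comp, s$n_premature - 1)
})

test_that("model parameter invariants are enforced", {
  expect_error(rr_model(base_period = 0), class = "ecgait_config_error")
  expect_error(rr_model(skip_prob = 0.6, premature_prob = 0.5),
               class = "ecgait_config_error")
  expect_error(rr_model(premature_fraction = 1),
               class = "ecgait_config_error")
  expect_error(simulate_rr(rr_model(), 0.1), class = "ecgait_config_error")
})

test_that("a rendered single beat puts the global negative extremum at the beat", {
  r <- suppressWarnings(render_ecg(0.5, sampling_rate = 2000, duration = 1))
  x <- r$record$samples
  t <- r$record$start_time + (seq_along(x) - 1) / 2000
  expect_lt(min(x), 0)
  expect_lt(abs(t[which.min(x)] - 0.5), 0.5 / 2000 + 1e-12)
})

test_that("a rendered 20-s recording satisfies the duration contract", {
  s <- simulate_rr(rr_model(base_period = 0.091, jitter_sd = 0.002), 20,
                   seed = 43)
  r <- render_ecg(s, seed = 44)
  expect_gte(ecg_duration(r$record), 20)
  expect_identical(r$truth, s$beat_times)
  # loader accepts it without a short-record warning after a round trip
  d <- withr_local_tempdir()
  write_ecg(r$record, file.path(d, "rec.csv"))
  expect_no_warning(read_ecg(file.path(d, "rec.csv")))
})

test_that("truth-based and pipeline metrics agree when noise is zero", {
  m <- rr_model(base_period = 0.091, jitter_sd = 0.002)
  s <- simulate_rr(m, 20, seed = 45)
  truth_hs <- heart_rate_summary(cycle_series(s$beat_times))
  r <- render_ecg(s, sampling_rate = 2000)
  pipe_hs <- heart_rate_summary(detect_rpeaks(r$record))
  expect_lt(abs(pipe_hs$hr_mean - truth_hs$hr_mean) / truth_hs$hr_mean, 0.01)
  expect_lt(abs(pipe_hs$is_mean - truth_hs$is_mean) /
              max(truth_hs$is_mean, 1), 0.01)
})

test_that("raising skip probability monotonically raises cohort irregularity", {
  lvl_means <- sapply(c(0, 0.025, 0.05), function(sp) {
    m <- rr_model(base_period = 0.091, jitter_sd = 0.002, skip_prob = sp)
    mean(sapply(1:20, function(i) {
      s <- simulate_rr(m, 20, seed = round(sp * 1e4) * 100 + i)
      heart_rate_summary(cycle_series(s$beat_times))$is_mean
    }))
  })
  expect_true(all(diff(lvl_means) > 0))
})

test_that("gait profiles span stationary to wild-type activity", {
  still <- simulate_trajectory(gait_profile(move_speed = 0), 10, seed = 46)
  expect_equal(gait_summary(still)$distance, 0)

  # constant-speed, no-turn, no-pause profile integrates exactly
  straight <- simulate_trajectory(
    gait_profile(move_speed = 10, speed_sd = 0, pause_prob = 0,
                 resume_prob = 1, turn_sd = 0), 60, seed = 47)
  gs <- gait_summary(straight, smoothing_window = 1)
  expect_equal(gs$distance, 600, tolerance = 1e-6)
  expect_equal(gs$distance_m, 6, tolerance = 1e-6)

  wt <- gait_summary(simulate_trajectory(default_gait_profile("wild_type"),
                                         60, seed = 48))
  fm <- gait_summary(simulate_trajectory(default_gait_profile("fm_model"),
                                         60, seed = 48))
  expect_gt(wt$avg_speed, fm$avg_speed)
})

test_that("cohort generation writes a loadable, deterministic cohort", {
  spec <- cohort_spec(n_per_group = 1, seed = 7, tests = "in_water_1min",
                      gait_durations = c(in_water_1min = 5),
                      ecg_duration = 10)
  d1 <- file.path(withr_local_tempdir(), "c1")
  d2 <- file.path(withr_local_tempdir(), "c2")
  m1 <- suppressWarnings(generate_cohort(spec, d1))
  m2 <- suppressWarnings(generate_cohort(spec, d2))
  expect_s3_class(m1, "cohort_manifest")
  expect_identical(nrow(m1), 2L * 2L * 2L)  # 2 subjects x 2 phases x 2 modalities
  expect_true(file.exists(file.path(d1, "truth.csv")))

  # byte-identical regeneration under the same seed
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- file.path(d2, basename(f1))
  h1 <- unname(tools::md5sum(f1))
  h2 <- unname(tools::md5sum(f2))
  expect_identical(h1, h2)

  # files load through the I/O layer
  ecg_files <- as.data.frame(m1)
  ecg_files <- ecg_files[ecg_files$modality == "ecg", "file_path"]
  rec <- suppressWarnings(read_ecg(file.path(d1, ecg_files[1])))
  expect_s3_class(rec, "ecg_record")
})
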