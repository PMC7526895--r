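clean_record <- function(rate_bpm = 660, duration = 20, fs = 2000,
                         seed = 1, jitter = 0, noise = 0) {
  sim <- simulate_rr(rr_model(base_period = 60 / rate_bpm,
                              jitter_sd = jitter), duration, seed = seed)
  ren <- render_ecg(sim, template = ecg_template(noise_sd = noise),
                    sampling_rate = fs, seed = seed + 5000)
  list(sim = sim, record = ren$record, truth = ren$truth)
}

test_that("noise-free constant-rhythm peaks are recovered to the millisecond", {
  x <- clean_record(rate_bpm = 660, duration = 20)
  cs <- detect_rpeaks(x$record)
  # 660 beats/min for 20 s forces ~220 beats
  expect_true(abs(length(cs$peak_times) - 221) <= 1)
  expect_identical(length(cs$peak_times), length(x$truth))
  expect_lt(max(abs(cs$peak_times - x$truth)), 0.001)
  expect_equal(cs$periods, diff(cs$peak_times))
})

test_that("an all-zero signal is a detection error", {
  rec <- suppressWarnings(ecg_record(rep(0, 4000), 1000))
  expect_error(detect_rpeaks(rec), class = "ecgait_detection_error")
})

test_that("auto polarity recovers identical peaks from an inverted lead", {
  x <- clean_record(seed = 3)
  up <- x$record
  down <- suppressWarnings(ecg_record(-up$samples, up$sampling_rate,
                                      start_time = up$start_time))
  cfg <- detector_config(polarity = "auto")
  expect_equal(detect_rpeaks(down, cfg)$peak_times,
               detect_rpeaks(up, cfg)$peak_times)
})

test_that("detection is invariant to positive amplitude rescaling", {
  x <- clean_record(seed = 4, jitter = 0.002, noise = 0.05)
  scaled <- suppressWarnings(ecg_record(37.5 * x$record$samples,
                                        x$record$sampling_rate,
                                        start_time = x$record$start_time))
  expect_equal(detect_rpeaks(scaled)$peak_times,
               detect_rpeaks(x$record)$peak_times)
})

test_that("shifting the trace in time shifts all peak times equally", {
  x <- clean_record(seed = 5, jitter = 0.002, noise = 0.05)
  fs <- x$record$sampling_rate
  k <- as.integer(0.5 * fs)   # half-second shift
  shifted <- suppressWarnings(
    ecg_record(c(rep(0, k), x$record$samples), fs,
               start_time = x$record$start_time))
  p0 <- detect_rpeaks(x$record)$peak_times
  p1 <- detect_rpeaks(shifted)$peak_times
  # compare interior peaks (edge filter transients aside)
  inner <- p0[p0 > 1 & p0 < 18]
  matched <- vapply(inner + k / fs,
                    function(t) min(abs(p1 - t)), numeric(1))
  expect_lt(max(matched), 1 / fs + 1e-9)
})

test_that("window selection honours strategy and boundary contracts", {
  pt <- cumsum(c(0, rep(0.1, 230)))
  s <- cycle_series(pt)
  w <- select_analysis_window(s, 50)           # default: first
  expect_identical(length(w$periods), 50L)
  expect_equal(w$peak_times, pt[1:51])
  wl <- select_analysis_window(s, 50, strategy = "last")
  expect_equal(wl$peak_times, pt[181:231])

  short <- cycle_series(cumsum(c(0, rep(0.1, 49))))
  err <- expect_error(select_analysis_window(short, 50),
                      class = "ecgait_window_error")
  expect_match(conditionMessage(err), "49")
})

test_that("min_artifact window avoids outlier periods, matching a full scan", {
  periods <- rep(0.09, 100)
  periods[10] <- 0.9                      # 10x outlier
  s <- cycle_series(cumsum(c(0, periods)))
  w <- select_analysis_window(s, 50, strategy = "min_artifact")
  expect_false(any(abs(w$periods - 0.9) < 1e-12))

  # oracle: exhaustively score every contiguous window
  med <- median(periods)
  bad <- periods < 0.25 * med | periods > 4 * med
  counts <- vapply(1:51, function(i) sum(bad[i:(i + 49)]), integer(1))
  best <- which.min(counts)
  expect_equal(w$periods, periods[best:(best + 49)])
})

test_that("detector and series constructors validate their invariants", {
  expect_error(detector_config(bandpass_low = 200, bandpass_high = 150),
               class = "ecgait_config_error")
  expect_error(detector_config(refractory = 0),
               class = "ecgait_config_error")
  expect_error(cycle_series(c(0, 0.1, 0.1)), class = "ecgait_data_error")
  expect_error(cycle_series(0.5), class = "ecgait_data_error")
})

test_that("peak CSV export writes one row per peak with a leading empty period", {
  d <- withr_local_tempdir()
  s <- cycle_series(c(0, 0.09, 0.19, 0.28))
  path <- file.path(d, "peaks.csv")
  write_peaks(s, path)
  tab <- utils::read.csv(path)
  expect_identical(names(tab), c("peak_time_s", "period_s"))
  expect_identical(nrow(tab), 4L)
  expect_true(is.na(tab$period_s[1]))
  expect_equal(tab$period_s[-1], s$periods)
})
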