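write_ecg_fixture <- function(dir, rows, fs = 1000, time_col = TRUE,
                              voltage = NULL, meta_extra = list()) {
  path <- file.path(dir, "trace.csv")
  v <- voltage %||% sin(seq_len(rows))
  if (time_col) {
    df <- data.frame(time_s = (seq_len(rows) - 1) / fs, voltage = v)
  } else {
    df <- data.frame(sample = seq_len(rows) - 1, voltage = v)
  }
  utils::write.csv(df, path, row.names = FALSE)
  meta <- c(list(sampling_rate = fs, subject_id = "m1",
                 condition_label = "pre_in_water_5min",
                 voltage_units = "au"), meta_extra)
  jsonlite::write_json(meta, file.path(dir, "trace.json"),
                       auto_unbox = TRUE, digits = NA)
  path
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("time-column ECG files load with correct duration and metadata", {
  d <- withr_local_tempdir()
  path <- write_ecg_fixture(d, rows = 2000, fs = 1000)
  expect_warning(rec <- read_ecg(path), class = "ecgait_short_record")
  expect_s3_class(rec, "ecg_record")
  expect_equal(ecg_duration(rec), 2.0)
  expect_equal(rec$subject_id, "m1")
  expect_equal(rec$sampling_rate, 1000)
})

test_that("a 20-s index-column recording meets the minimum-duration contract", {
  d <- withr_local_tempdir()
  path <- write_ecg_fixture(d, rows = 20000, fs = 1000, time_col = FALSE)
  expect_no_warning(rec <- read_ecg(path))
  expect_equal(ecg_duration(rec), 20.0)
})

test_that("non-finite voltages are rejected citing the offending row", {
  d <- withr_local_tempdir()
  v <- sin(seq_len(100)); v[37] <- NaN
  path <- write_ecg_fixture(d, rows = 100, voltage = v)
  expect_error(read_ecg(path), "row 37", class = "ecgait_data_error")
})

test_that("time spacing inconsistent with the declared rate is an error", {
  d <- withr_local_tempdir()
  path <- write_ecg_fixture(d, rows = 100, fs = 1000)
  tab <- utils::read.csv(path)
  tab$time_s[51] <- tab$time_s[51] + 0.0005   # half-sample glitch
  utils::write.csv(tab, path, row.names = FALSE)
  expect_error(read_ecg(path), "row 51", class = "ecgait_data_error")
})

test_that("a missing sidecar is a configuration error", {
  d <- withr_local_tempdir()
  path <- write_ecg_fixture(d, rows = 100)
  file.remove(file.path(d, "trace.json"))
  expect_error(read_ecg(path), class = "ecgait_config_error")
})

test_that("ECG write/read round trip is bit-exact", {
  d <- withr_local_tempdir()
  set.seed(11)
  rec <- suppressWarnings(
    ecg_record(rnorm(5000), 2000, subject_id = "m7",
               condition_label = "post_in_water_1min", start_time = -0.045))
  path <- file.path(d, "rt.csv")
  write_ecg(rec, path)
  rec2 <- suppressWarnings(read_ecg(path))
  expect_identical(rec2$samples, rec$samples)
  expect_identical(rec2$sampling_rate, rec$sampling_rate)
  expect_identical(rec2$subject_id, rec$subject_id)
  expect_identical(rec2$start_time, rec$start_time)
  # row count in = samples out
  expect_identical(length(rec2$samples), 5000L)
})

test_that("trajectories load, convert frames to seconds, and round trip", {
  d <- withr_local_tempdir()
  # 6000 frames at 100 fps is a 1-min gait test
  tr <- trajectory(0:5999, runif(6000, 0, 30), runif(6000, 0, 30),
                   frame_rate = 100, subject_id = "m2")
  expect_equal(tr$duration, 60.0)
  path <- file.path(d, "gait.csv")
  write_trajectory(tr, path)
  tr2 <- read_trajectory(path)
  expect_identical(tr2$x, tr$x)
  expect_identical(tr2$y, tr$y)
  expect_identical(tr2$frames, tr$frames)
  # frame -> time arithmetic
  tr3 <- trajectory(0:2, 1:3, 1:3, frame_rate = 100)
  expect_equal(tr3$t, c(0, 0.01, 0.02))
})

test_that("duplicate and non-monotone frames are rejected", {
  expect_error(trajectory(c(0, 1, 1, 2), 1:4, 1:4),
               "duplicate frame 1", class = "ecgait_data_error")
  expect_error(trajectory(c(0, 2, 1), 1:3, 1:3),
               class = "ecgait_data_error")
  expect_error(trajectory(0:2, c(1, NA, 3), 1:3),
               class = "ecgait_data_error")
  expect_error(trajectory(0:2, 1:3, 1:3, frame_rate = -5),
               class = "ecgait_config_error")
})

test_that("frame gaps are flagged but tolerated", {
  d <- withr_local_tempdir()
  tr <- trajectory(c(0:10, 15:20), runif(17), runif(17), frame_rate = 100)
  expect_true(tr$has_gaps)
  path <- file.path(d, "gap.csv")
  write_trajectory(tr, path)
  expect_warning(read_trajectory(path), class = "ecgait_frame_gaps")
})

test_that("manifests validate vocabulary, uniqueness, and the study design", {
  # the third-experiment design: 10 FM-model and 10 wild-type ECG, pre/post
  design <- expand.grid(subject_id = sprintf("s%02d", 1:10),
                        phase = c("pre", "post"),
                        group = c("wild_type", "fm_model"),
                        stringsAsFactors = FALSE)
  design$subject_id <- paste0(substr(design$group, 1, 2), design$subject_id)
  design$test <- "in_water_5min"
  design$modality <- "ecg"
  design$file_path <- paste0(design$subject_id, "_", design$phase, ".csv")
  m <- as_manifest(design)
  expect_s3_class(m, "cohort_manifest")
  expect_identical(nrow(m), 40L)

  bad <- design
  bad$group[1] <- "FM"
  err <- expect_error(as_manifest(bad), class = "ecgait_data_error")
  expect_match(conditionMessage(err), "wild_type, fm_model")

  dup <- rbind(design, design[1, ])
  expect_error(as_manifest(dup), "duplicate", class = "ecgait_data_error")
})

test_that("manifest write/read round trips and checks referenced files", {
  d <- withr_local_tempdir()
  tab <- data.frame(file_path = "a.csv", subject_id = "s1",
                    group = "wild_type", phase = "pre",
                    test = "in_water_1min", modality = "ecg",
                    stringsAsFactors = FALSE)
  path <- file.path(d, "manifest.csv")
  write_manifest(tab, path)
  expect_error(read_manifest(path), "missing file",
               class = "ecgait_data_error")
  file.create(file.path(d, "a.csv"))
  m <- read_manifest(path)
  expect_identical(as.data.frame(m)$file_path, "a.csv")
})
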