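# Plain-text I/O for ECG traces, gait trajectories and cohort manifests.
#
# File dialect (fixed so that round trips are bit-exact): comma-separated,
# mandatory header row, '.' decimal separator, UTF-8.  Each trace/trajectory
# CSV is paired with a JSON sidecar holding its metadata (sampling rate etc.);
# the data file itself carries only numbers.

MANIFEST_GROUPS     <- c("wild_type", "fm_model")
MANIFEST_PHASES     <- c("pre", "post")
MANIFEST_TESTS      <- c("out_of_water_5min", "in_water_1min", "in_water_5min")
MANIFEST_MODALITIES <- c("ecg", "gait")

default_meta_path <- function(path) sub("\\.[^.]+$", ".json", path)

# ---- ECGRecord -------------------------------------------------------------

#' Construct an ECG record
#'
#' A uniformly sampled single-lead voltage trace plus its acquisition
#' metadata.  Voltages are in arbitrary (amplifier) units; only relative
#' amplitude matters downstream.
#'
#' @param samples numeric vector of voltages, length >= 2, all finite.
#' @param sampling_rate samples per second, > 0.
#' @param subject_id,condition_label free-text identifiers.
#' @param start_time time of the first sample in seconds (default 0).
#' @param min_duration minimum analysable duration in seconds.  Recordings
#'   shorter than this warn by default (`strict_duration = FALSE`) or are
#'   rejected (`strict_duration = TRUE`).  The default of 20 s corresponds to
#'   roughly 200-250 cardiac cycles at mouse heart rates, comfortably more
#'   than the 50-cycle analysis window.
#' @param strict_duration logical; error instead of warning on short records.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(samples, sampling_rate, subject_id = "unknown",
                       condition_label = "unknown", start_time = 0,
                       min_duration = 20, strict_duration = FALSE) {
  if (!is_scalar_num(sampling_rate) || sampling_rate <= 0)
    config_error("sampling_rate must be a single positive number")
  if (!is.numeric(samples) || length(samples) < 2L)
    data_error("an ECG record needs at least 2 samples")
  if (!all(is.finite(samples)))
    data_error(sprintf("non-finite voltage at sample %d",
                       which(!is.finite(samples))[1L]))
  if (!is_string(subject_id) || !is_string(condition_label))
    config_error("subject_id and condition_label must be single strings")
  if (!is_scalar_num(start_time)) config_error("start_time must be a number")
  dur <- length(samples) / sampling_rate
  if (dur < min_duration) {
    msg <- sprintf("record '%s' lasts %.3f s, below the %g s minimum",
                   subject_id, dur, min_duration)
    if (strict_duration) data_error(msg) else warn_ecgait(msg, "short_record")
  }
  structure(list(subject_id = subject_id, condition_label = condition_label,
                 sampling_rate = sampling_rate, samples = as.numeric(samples),
                 start_time = start_time),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %s / %s: %d samples @ %g Hz (%.2f s)\n",
              x$subject_id, x$condition_label, length(x$samples),
              x$sampling_rate, ecg_duration(x)))
  invisible(x)
}

#' Duration of an ECG record in seconds
#' @param record an `ecg_record`.
#' @export
ecg_duration <- function(record) length(record$samples) / record$sampling_rate

#' Read an ECG trace from a CSV file and its JSON sidecar
#'
#' The CSV must have a header and two columns: either (`time_s`, `voltage`)
#' or (`sample`, `voltage`) with a 0-based sample index.  The sidecar
#' declares `sampling_rate`, `subject_id`, `condition_label` and
#' `voltage_units`.  When the first column is time, its spacing is checked
#' against the declared sampling rate to 1 part in 1e4.
#'
#' @param path CSV file path.
#' @param meta_path JSON sidecar path; defaults to `path` with a `.json`
#'   extension.
#' @param ... passed to [ecg_record()] (e.g. `min_duration`,
#'   `strict_duration`).
#' @return An [ecg_record()].
#' @export
read_ecg <- function(path, meta_path = default_meta_path(path), ...) {
  if (!file.exists(path)) data_error(sprintf("ECG file not found: %s", path))
  if (!file.exists(meta_path))
    config_error(sprintf("missing metadata sidecar: %s", meta_path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$sampling_rate))
    config_error(sprintf("sidecar %s lacks 'sampling_rate'", meta_path))
  fs <- as.numeric(meta$sampling_rate)
  tab <- read.csv(path, colClasses = "numeric")
  if (ncol(tab) != 2L)
    data_error(sprintf("%s: expected 2 columns (time/index, voltage), got %d",
                       path, ncol(tab)))
  v <- tab[[2L]]
  if (anyNA(v) || !all(is.finite(v)))
    data_error(sprintf("%s: non-finite voltage at data row %d",
                       path, which(!is.finite(v))[1L]))
  first_col <- tab[[1L]]
  is_time <- grepl("time", names(tab)[1L], ignore.case = TRUE)
  start_time <- as.numeric(meta$start_time %||% 0)
  if (is_time) {
    dt <- diff(first_col)
    rel <- abs(dt * fs - 1)
    if (any(rel > 1e-4))
      data_error(sprintf(
        "%s: sample spacing inconsistent with sampling_rate %g at data row %d",
        path, fs, which(rel > 1e-4)[1L] + 1L))
    start_time <- first_col[1L]
  } else {
    if (any(diff(first_col) != 1))
      data_error(sprintf("%s: sample index column is not consecutive", path))
  }
  ecg_record(v, fs,
             subject_id = meta$subject_id %||% "unknown",
             condition_label = meta$condition_label %||% "unknown",
             start_time = start_time, ...)
}

#' Write an ECG record as CSV plus JSON sidecar
#'
#' Voltages are written at full double precision so that
#' `read_ecg(write_ecg(x))` reproduces the samples bit-exactly.  The first
#' column is a 0-based sample index.
#'
#' @param record an `ecg_record`.
#' @param path output CSV path.
#' @param meta_path output sidecar path (default: `path` with `.json`).
#' @param voltage_units label stored in the sidecar (default "au").
#' @return `path`, invisibly.
#' @export
write_ecg <- function(record, path, meta_path = default_meta_path(path),
                      voltage_units = "au") {
  stopifnot(inherits(record, "ecg_record"))
  n <- length(record$samples)
  lines <- c("sample,voltage",
             paste0(0:(n - 1L), ",", fmt_num(record$samples)))
  writeLines(lines, path, useBytes = TRUE)
  jsonlite::write_json(
    list(sampling_rate = record$sampling_rate,
         subject_id = record$subject_id,
         condition_label = record$condition_label,
         start_time = record$start_time,
         voltage_units = voltage_units),
    meta_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- Trajectory ------------------------------------------------------------

#' Construct a gait trajectory
#'
#' Timed 2-D positions of the tracked body centroid in arena coordinates
#' (cm, origin at an arena corner; the convention is declared, not inferred).
#'
#' @param frames integer frame indices, 0-based, strictly increasing.
#' @param x,y coordinates in cm, finite.
#' @param frame_rate frames per second, > 0 (study cameras ran at 100).
#' @param subject_id,condition_label free-text identifiers.
#' @return An object of class `trajectory` with `t = frames / frame_rate`.
#'   Frame gaps are permitted but flagged in the `has_gaps` field.
#' @export
trajectory <- function(frames, x, y, frame_rate = 100,
                       subject_id = "unknown", condition_label = "unknown") {
  if (!is_scalar_num(frame_rate) || frame_rate <= 0)
    config_error("frame_rate must be a single positive number")
  n <- length(frames)
  if (length(x) != n || length(y) != n)
    data_error("frames, x and y must have equal length")
  if (n && anyDuplicated(frames))
    data_error(sprintf("duplicate frame %s",
                       frames[anyDuplicated(frames)]))
  if (n > 1L && any(diff(frames) <= 0))
    data_error("frame indices must be strictly increasing")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    data_error(sprintf("non-finite coordinate at data row %d",
                       which(!(is.finite(x) & is.finite(y)))[1L]))
  has_gaps <- n > 1L && any(diff(frames) != 1)
  structure(list(subject_id = subject_id, condition_label = condition_label,
                 frame_rate = frame_rate, frames = as.integer(frames),
                 t = frames / frame_rate, x = as.numeric(x), y = as.numeric(y),
                 has_gaps = has_gaps,
                 # frame-count convention: 6000 frames at 100 fps cover 60 s
                 duration = (frames[n] - frames[1L] + 1) / frame_rate),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s / %s: %d frames @ %g fps (%.1f s)%s\n",
              x$subject_id, x$condition_label, length(x$frames),
              x$frame_rate, diff(range(x$t)),
              if (x$has_gaps) " [gaps]" else ""))
  invisible(x)
}

#' Read a gait trajectory from CSV plus JSON sidecar
#'
#' Expects columns (`frame`, `x_cm`, `y_cm`); the sidecar declares
#' `frame_rate`, `subject_id` and `condition_label`.  Times are computed as
#' `frame / frame_rate`.  Non-monotone or duplicated frames are rejected;
#' gaps are allowed and flagged with a warning.
#'
#' @inheritParams read_ecg
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, meta_path = default_meta_path(path)) {
  if (!file.exists(path))
    data_error(sprintf("trajectory file not found: %s", path))
  if (!file.exists(meta_path))
    config_error(sprintf("missing metadata sidecar: %s", meta_path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  fr <- as.numeric(meta$frame_rate %||% -1)
  if (!is.finite(fr) || fr <= 0)
    config_error(sprintf("sidecar %s must declare a positive frame_rate",
                         meta_path))
  tab <- read.csv(path, colClasses = "numeric")
  if (ncol(tab) != 3L)
    data_error(sprintf("%s: expected 3 columns (frame, x_cm, y_cm)", path))
  traj <- trajectory(tab[[1L]], tab[[2L]], tab[[3L]], frame_rate = fr,
                     subject_id = meta$subject_id %||% "unknown",
                     condition_label = meta$condition_label %||% "unknown")
  if (traj$has_gaps)
    warn_ecgait(sprintf("%s: frame gaps present", path), "frame_gaps")
  traj
}

#' Write a trajectory as CSV plus JSON sidecar
#'
#' Coordinates are written at full double precision for bit-exact round
#' trips.
#'
#' @param traj a `trajectory`.
#' @inheritParams write_ecg
#' @export
write_trajectory <- function(traj, path, meta_path = default_meta_path(path)) {
  stopifnot(inherits(traj, "trajectory"))
  lines <- c("frame,x_cm,y_cm",
             paste0(traj$frames, ",", fmt_num(traj$x), ",", fmt_num(traj$y)))
  writeLines(lines, path, useBytes = TRUE)
  jsonlite::write_json(
    list(frame_rate = traj$frame_rate, subject_id = traj$subject_id,
         condition_label = traj$condition_label, units = "cm"),
    meta_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- CohortManifest --------------------------------------------------------

#' Read a cohort manifest
#'
#' The manifest maps recording files to subjects and study conditions.  It is
#' a CSV with columns `file_path`, `subject_id`, `group`, `phase`, `test`,
#' `modality`.  Allowed vocabularies: group in `wild_type`/`fm_model`;
#' phase in `pre`/`post` (relative to the model induction); test in
#' `out_of_water_5min`/`in_water_1min`/`in_water_5min`; modality in
#' `ecg`/`gait`.  The (subject_id, phase, test, modality) combination must be
#' unique and, when `check_files = TRUE`, every referenced file must exist
#' (paths resolved relative to the manifest's directory).
#'
#' @param path manifest CSV path.
#' @param check_files verify referenced files exist (default TRUE).
#' @return A data frame of class `cohort_manifest` with attribute `base_dir`.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path))
    data_error(sprintf("manifest not found: %s", path))
  tab <- read.csv(path, colClasses = "character")
  as_manifest(tab, base_dir = dirname(path), check_files = check_files)
}

#' Validate a manifest data frame
#'
#' @param tab data frame with the manifest columns.
#' @param base_dir directory against which relative `file_path`s resolve.
#' @param check_files verify referenced files exist.
#' @export
as_manifest <- function(tab, base_dir = ".", check_files = FALSE) {
  need <- c("file_path", "subject_id", "group", "phase", "test", "modality")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    data_error(sprintf("manifest lacks column(s): %s",
                       paste(miss, collapse = ", ")))
  check_vocab <- function(col, allowed) {
    bad <- setdiff(unique(tab[[col]]), allowed)
    if (length(bad))
      data_error(sprintf("unknown %s token(s) %s; allowed: {%s}", col,
                         paste(sQuote(bad), collapse = ", "),
                         paste(allowed, collapse = ", ")))
  }
  check_vocab("group", MANIFEST_GROUPS)
  check_vocab("phase", MANIFEST_PHASES)
  check_vocab("test", MANIFEST_TESTS)
  check_vocab("modality", MANIFEST_MODALITIES)
  key <- paste(tab$subject_id, tab$phase, tab$test, tab$modality, sep = "|")
  if (anyDuplicated(key))
    data_error(sprintf("duplicate manifest entry: %s",
                       key[anyDuplicated(key)]))
  if (check_files) {
    paths <- manifest_paths(tab, base_dir)
    missing <- !file.exists(paths)
    if (any(missing))
      data_error(sprintf("manifest references missing file(s): %s",
                         paste(paths[missing], collapse = ", ")))
  }
  structure(tab, class = c("cohort_manifest", "data.frame"),
            base_dir = base_dir)
}

manifest_paths <- function(tab, base_dir) {
  ifelse(grepl("^(/|[A-Za-z]:)", tab$file_path), tab$file_path,
         file.path(base_dir, tab$file_path))
}

#' Write a cohort manifest CSV
#' @param manifest a `cohort_manifest` (or compatible data frame).
#' @param path output CSV path.
#' @export
write_manifest <- function(manifest, path) {
  cols <- c("file_path", "subject_id", "group", "phase", "test", "modality")
  write.csv(as.data.frame(manifest)[cols], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}
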