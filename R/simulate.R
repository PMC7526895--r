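# Synthetic data: RR-interval sequences with controllable arrhythmia, ECG
# trace rendering from a beat template, correlated-random-walk gait
# trajectories, and whole-cohort generation with ground-truth tables.
#
# All randomness flows from explicit seeds; the same seed reproduces the same
# output byte for byte.

#' RR-interval model
#'
#' Generative model for mouse cycle periods.  Each nominal period is
#' `base_period + drift * t + N(0, jitter_sd)`, floored at
#' `0.2 * base_period`.  Arrhythmic events perturb the nominal rhythm:
#' a *skipped* beat (probability `skip_prob`) deletes a beat so two periods
#' merge; a *premature* beat (probability `premature_prob`) splits a period
#' into `premature_fraction * P` followed by the compensatory remainder
#' `(1 - premature_fraction) * P`, leaving mean rate unchanged.
#'
#' @param base_period mean cycle period in seconds.  Default 0.091 s
#'   (about 660 beats/min, mid-range for restrained adult mice).
#' @param jitter_sd cycle-to-cycle Gaussian SD, seconds.
#' @param skip_prob per-cycle probability of a dropped beat.
#' @param premature_prob per-cycle probability of a premature beat.
#' @param premature_fraction where the premature beat falls inside its
#'   period, in (0, 1).
#' @param drift linear change of base_period over the recording, s/s.
#' @param seed default RNG seed for [simulate_rr()]; NULL = caller's RNG.
#' @return An `rr_model` object.
#' @export
rr_model <- function(base_period = 0.091, jitter_sd = 0, skip_prob = 0,
                     premature_prob = 0, premature_fraction = 0.6,
                     drift = 0, seed = NULL) {
  if (!is_scalar_num(base_period) || base_period <= 0)
    config_error("base_period must be > 0")
  for (p in c(skip_prob, premature_prob))
    if (!is_scalar_num(p) || p < 0 || p > 1)
      config_error("event probabilities must lie in [0, 1]")
  if (skip_prob + premature_prob >= 1)
    config_error("skip_prob + premature_prob must be < 1")
  if (!is_scalar_num(premature_fraction) || premature_fraction <= 0 ||
      premature_fraction >= 1)
    config_error("premature_fraction must lie in (0, 1)")
  if (!is_scalar_num(jitter_sd) || jitter_sd < 0)
    config_error("jitter_sd must be >= 0")
  if (!is_scalar_num(drift)) config_error("drift must be a number")
  structure(list(base_period = base_period, jitter_sd = jitter_sd,
                 skip_prob = skip_prob, premature_prob = premature_prob,
                 premature_fraction = premature_fraction, drift = drift,
                 seed = seed),
            class = "rr_model")
}

#' Simulate a beat sequence
#'
#' Places beats sequentially from t = 0 until `duration` under an
#' [rr_model()].  Deterministic under a fixed seed.
#'
#' @param model an [rr_model()].
#' @param duration recording length in seconds (>= 3 base periods).
#' @param seed RNG seed; defaults to the model's.
#' @return List of class `rr_simulation`: `beat_times` (first at 0),
#'   `periods = diff(beat_times)`, `n_skipped`, `n_premature`, and the model.
#' @export
simulate_rr <- function(model, duration, seed = model$seed) {
  stopifnot(inherits(model, "rr_model"))
  if (!is_scalar_num(duration) || duration < 3 * model$base_period)
    config_error("duration must cover at least 3 base periods")
  with_seed(seed, {
    est <- as.integer(ceiling(duration / model$base_period * 1.6) + 16L)
    jit <- if (model$jitter_sd > 0) rnorm(est, 0, model$jitter_sd)
           else numeric(est)
    u <- runif(est)
    beats <- numeric(est + 1L)
    beats[1L] <- 0
    nb <- 1L
    t <- 0
    i <- 0L
    n_skip <- 0L
    n_prem <- 0L
    floor_p <- 0.2 * model$base_period
    repeat {
      i <- i + 1L
      if (i > length(jit)) {  # refill randomness in deterministic order
        jit <- c(jit, if (model$jitter_sd > 0) rnorm(est, 0, model$jitter_sd)
                      else numeric(est))
        u <- c(u, runif(est))
      }
      p <- model$base_period + model$drift * t + jit[i]
      if (p < floor_p) p <- floor_p
      if (u[i] < model$skip_prob) {
        if (t + p > duration + 1e-9) break
        t <- t + p          # beat dropped: time advances, no beat recorded
        n_skip <- n_skip + 1L
        next
      }
      if (u[i] < model$skip_prob + model$premature_prob) {
        t1 <- t + model$premature_fraction * p
        t2 <- t + p
        if (t1 > duration + 1e-9) break
        nb <- nb + 1L; beats[nb] <- t1
        n_prem <- n_prem + 1L
        if (t2 > duration + 1e-9) { t <- t1; break }
        nb <- nb + 1L; beats[nb] <- t2
        t <- t2
        next
      }
      if (t + p > duration + 1e-9) break
      t <- t + p
      nb <- nb + 1L; beats[nb] <- t
    }
    beats <- beats[seq_len(nb)]
    structure(list(beat_times = beats, periods = diff(beats),
                   n_skipped = n_skip, n_premature = n_prem,
                   duration = duration, model = model),
              class = "rr_simulation")
  })
}

#' ECG beat template
#'
#' Parametric beat shape: a dominant NEGATIVE R deflection (the study's lead
#' convention) flanked by small positive P- and T-like bumps, each a Gaussian
#' in time.  Component integrals nearly cancel so the template integrates
#' close to zero; the R deflection is required to dominate every other
#' deflection at least 3-fold.
#'
#' @param r_amplitude magnitude of the R deflection (arbitrary units).
#' @param r_width Gaussian SD of the R bump, seconds.
#' @param p_amplitude,t_amplitude amplitudes of the flanking positive bumps.
#' @param p_offset,t_offset bump centres relative to the beat time, seconds.
#' @param p_width,t_width Gaussian SDs of the flanking bumps, seconds.
#' @param noise_sd additive white Gaussian noise SD (arbitrary units).
#' @param wander_amplitude,wander_freq sinusoidal baseline wander.
#' @return An `ecg_template` object.
#' @export
ecg_template <- function(r_amplitude = 1, r_width = 0.0015,
                         p_amplitude = 0.12, p_offset = -0.025,
                         p_width = 0.006,
                         t_amplitude = 0.10, t_offset = 0.030,
                         t_width = 0.008,
                         noise_sd = 0, wander_amplitude = 0,
                         wander_freq = 0.5) {
  if (!is_scalar_num(r_amplitude) || r_amplitude <= 0)
    config_error("r_amplitude must be > 0")
  if (r_amplitude < 3 * max(p_amplitude, t_amplitude))
    config_error("R deflection must dominate other deflections >= 3-fold")
  if (noise_sd < 0 || wander_amplitude < 0)
    config_error("noise_sd and wander_amplitude must be >= 0")
  structure(list(r_amplitude = r_amplitude, r_width = r_width,
                 p_amplitude = p_amplitude, p_offset = p_offset,
                 p_width = p_width, t_amplitude = t_amplitude,
                 t_offset = t_offset, t_width = t_width,
                 noise_sd = noise_sd, wander_amplitude = wander_amplitude,
                 wander_freq = wander_freq,
                 support = 0.045),
            class = "ecg_template")
}

# template waveform at offsets tau (seconds) from the beat time
eval_template <- function(tpl, tau) {
  -tpl$r_amplitude * exp(-tau^2 / (2 * tpl$r_width^2)) +
    tpl$p_amplitude * exp(-(tau - tpl$p_offset)^2 / (2 * tpl$p_width^2)) +
    tpl$t_amplitude * exp(-(tau - tpl$t_offset)^2 / (2 * tpl$t_width^2))
}

#' Render an ECG trace from beat times
#'
#' Superposes the beat template at each beat time on a uniform sample grid,
#' then adds sinusoidal baseline wander and white noise.  Beats closer
#' together than the template half-support overlap additively (a warning
#' reports how many).
#'
#' @param beat_times beat times in seconds (an `rr_simulation` also works).
#' @param template an [ecg_template()].
#' @param sampling_rate samples per second; >= 1000 recommended so peak truth
#'   is good to about a millisecond.
#' @param duration trace length in seconds; default covers the last beat.
#' @param pad seconds of trace rendered before the first beat (the record's
#'   `start_time` becomes `-pad`), so a beat at t = 0 has its full waveform
#'   in the trace.  Defaults to the template support.
#' @param subject_id,condition_label metadata for the record.
#' @param seed RNG seed for the noise.
#' @param ... passed to [ecg_record()].
#' @return List with `record` (an [ecg_record()]) and `truth` (the beat
#'   times, i.e. true R-peak times).
#' @export
render_ecg <- function(beat_times, template = ecg_template(),
                       sampling_rate = 2000, duration = NULL,
                       pad = template$support, subject_id = "synthetic",
                       condition_label = "synthetic", seed = NULL, ...) {
  if (inherits(beat_times, "rr_simulation")) {
    if (is.null(duration)) duration <- beat_times$duration
    beat_times <- beat_times$beat_times
  }
  stopifnot(inherits(template, "ecg_template"))
  if (!is.numeric(beat_times) || length(beat_times) < 1L)
    data_error("need at least one beat time")
  if (is.null(duration)) duration <- max(beat_times) + 2 * template$support
  n <- as.integer(round((duration + pad) * sampling_rate))
  tgrid <- (0:(n - 1L)) / sampling_rate - pad
  x <- numeric(n)
  half <- template$support
  n_overlap <- sum(diff(sort(beat_times)) < half)
  if (n_overlap > 0L)
    warn_ecgait(sprintf("%d beat pair(s) closer than the template support;%s",
                        n_overlap, " rendered additively"), "beat_overlap")
  for (bt in beat_times) {
    lo <- max(1L, as.integer(floor((bt - half + pad) * sampling_rate)) + 1L)
    hi <- min(n, as.integer(ceiling((bt + half + pad) * sampling_rate)) + 1L)
    if (lo > hi) next
    idx <- lo:hi
    x[idx] <- x[idx] + eval_template(template, tgrid[idx] - bt)
  }
  with_seed(seed, {
    if (template$wander_amplitude > 0)
      x <- x + template$wander_amplitude *
        sin(2 * pi * template$wander_freq * tgrid)
    if (template$noise_sd > 0)
      x <- x + rnorm(n, 0, template$noise_sd)
    list(record = ecg_record(x, sampling_rate, subject_id = subject_id,
                             condition_label = condition_label,
                             start_time = -pad, ...),
         truth = beat_times)
  })
}

#' Gait movement profile
#'
#' Two-state (moving / paused) correlated random walk.  While moving, frame
#' speed relaxes toward `move_speed` with Gaussian fluctuation and heading
#' diffuses with SD `turn_sd` per frame; transitions to the paused state
#' occur with per-frame probability `pause_prob` and back with
#' `resume_prob`.  The walk reflects off the walls of a square arena.
#'
#' @param move_speed target speed while moving, cm/s.
#' @param speed_sd per-frame speed fluctuation SD, cm/s.
#' @param pause_prob per-frame probability of entering a pause.
#' @param resume_prob per-frame probability of leaving a pause.
#' @param turn_sd heading change SD per frame, radians.
#' @param arena_size side of the square arena, cm.
#' @return A `gait_profile` object.
#' @export
gait_profile <- function(move_speed = 10.5, speed_sd = 3, pause_prob = 0.01,
                         resume_prob = 0.05, turn_sd = 0.15,
                         arena_size = 30) {
  if (!is_scalar_num(move_speed) || move_speed < 0)
    config_error("move_speed must be >= 0")
  for (p in c(pause_prob, resume_prob))
    if (!is_scalar_num(p) || p < 0 || p > 1)
      config_error("transition probabilities must lie in [0, 1]")
  if (speed_sd < 0 || turn_sd < 0 || arena_size <= 0)
    config_error("speed_sd, turn_sd >= 0 and arena_size > 0 required")
  structure(list(move_speed = move_speed, speed_sd = speed_sd,
                 pause_prob = pause_prob, resume_prob = resume_prob,
                 turn_sd = turn_sd, arena_size = arena_size),
            class = "gait_profile")
}

#' Built-in gait profiles
#'
#' `"wild_type"` is calibrated so that average speed over a test lands near
#' 8-9 cm/s; `"fm_model"` is hypoactive (low speed, long pauses, average
#' near 1 cm/s); `"fm_model_water"` is the hypoactive animal facilitated by
#' shallow water (intermediate).
#'
#' @param name profile name.
#' @return A [gait_profile()].
#' @export
default_gait_profile <- function(name = c("wild_type", "fm_model",
                                          "fm_model_water")) {
  switch(match.arg(name),
    wild_type = gait_profile(move_speed = 10.5, speed_sd = 3,
                             pause_prob = 0.01, resume_prob = 0.05),
    fm_model = gait_profile(move_speed = 6.6, speed_sd = 1.5,
                            pause_prob = 0.05, resume_prob = 0.01),
    fm_model_water = gait_profile(move_speed = 8, speed_sd = 2,
                                  pause_prob = 0.03, resume_prob = 0.03))
}

#' Simulate a gait trajectory
#'
#' @param profile a [gait_profile()].
#' @param duration test length in seconds (study tests: 60 or 300).
#' @param frame_rate frames per second (study camera: 100).
#' @param seed RNG seed.
#' @param subject_id,condition_label metadata.
#' @return A [trajectory()].
#' @export
simulate_trajectory <- function(profile, duration, frame_rate = 100,
                                seed = NULL, subject_id = "synthetic",
                                condition_label = "synthetic") {
  stopifnot(inherits(profile, "gait_profile"))
  if (!is_scalar_num(duration) || duration <= 0)
    config_error("duration must be > 0")
  with_seed(seed, {
    n <- as.integer(round(duration * frame_rate)) + 1L
    L <- profile$arena_size
    x <- numeric(n); y <- numeric(n)
    x[1L] <- L / 2; y[1L] <- L / 2
    theta <- runif(1, 0, 2 * pi)
    v <- profile$move_speed
    moving <- TRUE
    turn <- rnorm(n, 0, profile$turn_sd)
    dv <- rnorm(n, 0, profile$speed_sd)
    u <- runif(n)
    for (i in 2:n) {
      if (moving) {
        if (u[i] < profile$pause_prob) moving <- FALSE
      } else {
        if (u[i] < profile$resume_prob) moving <- TRUE
      }
      if (moving && profile$move_speed > 0) {
        v <- max(0, 0.9 * v + 0.1 * profile$move_speed + 0.1 * dv[i])
        theta <- theta + turn[i]
        step <- v / frame_rate
        dx <- step * cos(theta); dy <- step * sin(theta)
        if (x[i - 1L] + dx < 0 || x[i - 1L] + dx > L) {
          theta <- pi - theta; dx <- -dx
        }
        if (y[i - 1L] + dy < 0 || y[i - 1L] + dy > L) {
          theta <- -theta; dy <- -dy
        }
        x[i] <- min(max(x[i - 1L] + dx, 0), L)
        y[i] <- min(max(y[i - 1L] + dy, 0), L)
      } else {
        v <- 0
        x[i] <- x[i - 1L]; y[i] <- y[i - 1L]
      }
    }
    trajectory(0:(n - 1L), x, y, frame_rate = frame_rate,
               subject_id = subject_id, condition_label = condition_label)
  })
}

#' Cohort specification
#'
#' Encodes the study's four-condition design: two groups (wild-type and
#' FM-model), recordings before and after the intervention, across three
#' gait tests.  ECG rhythm per (group, phase, test) cell comes from
#' `rr_effects`; gait comes from `gait_profiles`.  The default effects place
#' the baseline irregularity score near 2.5% everywhere, a mild rhythm
#' disturbance after the 1-min water test in FM animals (score near 5), and
#' the headline pattern after the 5-min water test in FM animals: rate
#' lowered about 10% plus skipped/premature beats driving the score near 12.
#'
#' @param n_per_group animals per group (study arms: 10).
#' @param seed master seed; every per-file seed derives from it.
#' @param ecg_duration seconds of ECG per recording (study contract: >= 20).
#' @param sampling_rate ECG sampling rate, Hz.
#' @param tests subset of the three gait tests to include.
#' @param gait_durations named seconds per test.
#' @param rr_effects named list overriding [rr_model()] arguments per
#'   condition cell, keyed `"<group>.<phase>.<test>"`; unlisted cells use
#'   `rr_baseline`.
#' @param rr_baseline [rr_model()] arguments for unlisted cells.
#' @param noise_sd,wander_amplitude rendering noise passed to
#'   [ecg_template()].
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_per_group = 10, seed = 1,
                        ecg_duration = 20, sampling_rate = 2000,
                        tests = MANIFEST_TESTS,
                        gait_durations = c(out_of_water_5min = 300,
                                           in_water_1min = 60,
                                           in_water_5min = 300),
                        rr_effects = default_rr_effects(),
                        rr_baseline = list(base_period = 0.091,
                                           jitter_sd = 0.002),
                        noise_sd = 0.05, wander_amplitude = 0.05) {
  tests <- match.arg(tests, MANIFEST_TESTS, several.ok = TRUE)
  if (!is_scalar_num(n_per_group) || n_per_group < 1)
    config_error("n_per_group must be >= 1")
  structure(list(n_per_group = as.integer(n_per_group), seed = seed,
                 ecg_duration = ecg_duration, sampling_rate = sampling_rate,
                 tests = tests, gait_durations = gait_durations,
                 rr_effects = rr_effects, rr_baseline = rr_baseline,
                 noise_sd = noise_sd, wander_amplitude = wander_amplitude),
            class = "cohort_spec")
}

#' Default per-condition rhythm effects
#'
#' @return Named list of [rr_model()] argument overrides keyed
#'   `"<group>.<phase>.<test>"`.
#' @export
default_rr_effects <- function() {
  list(
    fm_model.post.in_water_1min = list(jitter_sd = 0.0025,
                                       skip_prob = 0.008,
                                       premature_prob = 0.005),
    fm_model.post.in_water_5min = list(base_period = 0.101,
                                       jitter_sd = 0.003,
                                       skip_prob = 0.03,
                                       premature_prob = 0.02)
  )
}

rr_model_for_cell <- function(spec, group, phase, test) {
  args <- spec$rr_baseline
  key <- paste(group, phase, test, sep = ".")
  ov <- spec$rr_effects[[key]]
  if (!is.null(ov)) args[names(ov)] <- ov
  do.call(rr_model, args)
}

gait_profile_for_cell <- function(group, phase, test) {
  # pre-intervention animals in both groups behave like wild type; FM
  # animals after induction are hypoactive, partially rescued in water
  if (group == "wild_type" || phase == "pre")
    default_gait_profile("wild_type")
  else if (test == "out_of_water_5min") default_gait_profile("fm_model")
  else default_gait_profile("fm_model_water")
}

#' Generate a synthetic cohort on disk
#'
#' Writes per-animal ECG and trajectory files (CSV + JSON sidecars) for every
#' (group, phase, test) cell of the spec, a cohort manifest, and a
#' `truth.csv` table of the generating parameters (true rate, event
#' probabilities, true R-peak counts, profile speeds) for parameter-recovery
#' tests.  Deterministic: the same spec (same seed) reproduces identical
#' files.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory (created if needed).
#' @return The [read_manifest()]-validated manifest, invisibly; its
#'   `base_dir` attribute points at `out_dir`.
#' @export
generate_cohort <- function(spec, out_dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop_ecgait(sprintf("cannot create output directory %s", out_dir),
                "io_error")
  subjects <- c(sprintf("wt%02d", seq_len(spec$n_per_group)),
                sprintf("fm%02d", seq_len(spec$n_per_group)))
  groups <- rep(MANIFEST_GROUPS, each = spec$n_per_group)
  rows <- list()
  truth <- list()
  k <- 0L
  tpl <- ecg_template(noise_sd = spec$noise_sd,
                      wander_amplitude = spec$wander_amplitude)
  for (si in seq_along(subjects)) {
    for (test in spec$tests) {
      for (phase in MANIFEST_PHASES) {
        cond <- paste(phase, test, sep = "_")
        # ECG
        k <- k + 1L
        mdl <- rr_model_for_cell(spec, groups[si], phase, test)
        sim <- simulate_rr(mdl, spec$ecg_duration,
                           seed = (spec$seed * 7919 + k) %%
                             .Machine$integer.max)
        rec <- suppressWarnings(render_ecg(
          sim, template = tpl, sampling_rate = spec$sampling_rate,
          subject_id = subjects[si], condition_label = cond,
          seed = (spec$seed * 7919 + 500000L + k) %% .Machine$integer.max))
        fname <- sprintf("%s_%s_ecg.csv", subjects[si], cond)
        write_ecg(rec$record, file.path(out_dir, fname))
        writeLines(c("peak_time_s", fmt_num(rec$truth)),
                   file.path(out_dir, sprintf("%s_%s_ecg_truth.csv",
                                              subjects[si], cond)))
        rows[[length(rows) + 1L]] <- data.frame(
          file_path = fname, subject_id = subjects[si], group = groups[si],
          phase = phase, test = test, modality = "ecg",
          stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          subject_id = subjects[si], group = groups[si], phase = phase,
          test = test, modality = "ecg",
          true_rate_bpm = 60 / mdl$base_period,
          jitter_sd = mdl$jitter_sd, skip_prob = mdl$skip_prob,
          premature_prob = mdl$premature_prob,
          n_true_beats = length(rec$truth), move_speed = NA_real_,
          stringsAsFactors = FALSE)
        # gait
        k <- k + 1L
        prof <- gait_profile_for_cell(groups[si], phase, test)
        traj <- simulate_trajectory(
          prof, duration = unname(spec$gait_durations[test]),
          seed = (spec$seed * 7919 + k) %% .Machine$integer.max,
          subject_id = subjects[si], condition_label = cond)
        gname <- sprintf("%s_%s_gait.csv", subjects[si], cond)
        write_trajectory(traj, file.path(out_dir, gname))
        rows[[length(rows) + 1L]] <- data.frame(
          file_path = gname, subject_id = subjects[si], group = groups[si],
          phase = phase, test = test, modality = "gait",
          stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          subject_id = subjects[si], group = groups[si], phase = phase,
          test = test, modality = "gait", true_rate_bpm = NA_real_,
          jitter_sd = NA_real_, skip_prob = NA_real_,
          premature_prob = NA_real_, n_true_beats = NA_integer_,
          move_speed = prof$move_speed, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  write.csv(do.call(rbind, truth), file.path(out_dir, "truth.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(read_manifest(file.path(out_dir, "manifest.csv")))
}
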