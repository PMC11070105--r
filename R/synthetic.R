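#' Configuration of the synthetic overnight record generator
#'
#' The generator emulates the statistical structure the network must learn
#' from a scored polysomnography night: a two-state (wake/sleep) bout
#' alternation with a target sleep efficiency, sleep-disordered-breathing
#' (SDB) events placed as a Poisson process over sleep time, event-locked
#' cyclic variation of the RR tachogram (RR lengthening during the event,
#' abrupt shortening at its end), and a respiratory-effort quasi-sinusoid
#' whose amplitude collapses during apneas and drops partially during
#' hypopneas.
#'
#' @param tib_hours time in bed (h).
#' @param sleep_efficiency target TST/TIB in `[0, 1]`.
#' @param ahi_target event rate per hour of sleep (>= 0).
#' @param event_duration_s length-2 numeric, uniform range of event
#'   durations in seconds; minimum must be >= 10 s (the standard scoring
#'   minimum).
#' @param hypopnea_fraction fraction of events generated as hypopneas.
#' @param hr_base_bpm resting heart rate (beats/min).
#' @param hrv_sd_ms RR variability scale during sleep (ms).
#' @param wake_hrv_multiplier multiplicative HRV inflation during wake
#'   (> 1).
#' @param effort_fs_hz sampling rate of the raw effort waveform (Hz).
#' @param noise_sd additive effort noise standard deviation (effort is
#'   generated with unit breathing amplitude).
#' @param seed integer seed; identical configurations reproduce
#'   byte-identical records.
#' @param rr_event_excursion peak relative RR lengthening during an event.
#' @param rr_undershoot relative RR shortening during the ~10 s after an
#'   event ends.
#' @param apnea_floor residual effort amplitude fraction during apneas.
#' @param hypopnea_depth residual effort amplitude fraction during
#'   hypopneas.
#' @param breath_rate_hz breathing rate of the effort sinusoid.
#' @param artifact_prob per-beat probability of being marked as
#'   artifact/ectopic (masked for exclusion).
#' @param wake_effort_noise_mult extra effort noise factor during wake
#'   (body movement).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(tib_hours = 8,
                       sleep_efficiency = 0.85,
                       ahi_target = 15,
                       event_duration_s = c(10, 40),
                       hypopnea_fraction = 0.5,
                       hr_base_bpm = 60,
                       hrv_sd_ms = 50,
                       wake_hrv_multiplier = 2.5,
                       effort_fs_hz = 25,
                       noise_sd = 0.03,
                       seed = 1L,
                       rr_event_excursion = 0.15,
                       rr_undershoot = 0.10,
                       apnea_floor = 0.05,
                       hypopnea_depth = 0.4,
                       breath_rate_hz = 0.25,
                       artifact_prob = 0.02,
                       wake_effort_noise_mult = 2) {
  cfg <- list(tib_hours = tib_hours, sleep_efficiency = sleep_efficiency,
              ahi_target = ahi_target, event_duration_s = event_duration_s,
              hypopnea_fraction = hypopnea_fraction,
              hr_base_bpm = hr_base_bpm, hrv_sd_ms = hrv_sd_ms,
              wake_hrv_multiplier = wake_hrv_multiplier,
              effort_fs_hz = effort_fs_hz, noise_sd = noise_sd,
              seed = as.integer(seed),
              rr_event_excursion = rr_event_excursion,
              rr_undershoot = rr_undershoot,
              apnea_floor = apnea_floor, hypopnea_depth = hypopnea_depth,
              breath_rate_hz = breath_rate_hz,
              artifact_prob = artifact_prob,
              wake_effort_noise_mult = wake_effort_noise_mult)
  num <- unlist(cfg[vapply(cfg, is.numeric, logical(1))])
  if (any(!is.finite(num))) stop("sim_config values must all be finite")
  stopifnot(tib_hours > 0, ahi_target >= 0,
            sleep_efficiency >= 0, sleep_efficiency <= 1,
            length(event_duration_s) == 2L,
            event_duration_s[1L] >= 10,
            event_duration_s[2L] >= event_duration_s[1L],
            hypopnea_fraction >= 0, hypopnea_fraction <= 1,
            hr_base_bpm > 0, hrv_sd_ms >= 0, wake_hrv_multiplier > 1,
            effort_fs_hz >= 4, noise_sd >= 0, artifact_prob >= 0,
            artifact_prob < 1)
  structure(cfg, class = "sim_config")
}

#' Strong-signature generator configuration
#'
#' A [sim_config()] variant with pronounced, easily learnable signatures
#' (larger event-locked RR excursions, deeper effort reduction, stronger
#' wake/sleep HRV contrast, less noise and fewer artifacts), intended for
#' desk-scale recovery experiments where training budgets are small.
#'
#' @param ... overrides passed on to [sim_config()].
#' @return An object of class `sim_config`.
#' @export
sim_config_strong <- function(...) {
  defaults <- list(rr_event_excursion = 0.25, rr_undershoot = 0.10,
                   wake_hrv_multiplier = 3, hypopnea_depth = 0.3,
                   apnea_floor = 0.05, noise_sd = 0.03,
                   artifact_prob = 0.01)
  do.call(sim_config, modifyList(defaults, list(...)))
}

# Two-state semi-Markov hypnogram: per-epoch exit probabilities chosen so
# the stationary sleep fraction equals the target efficiency (mean wake
# bout fixed at 4 epochs = 2 min). Sleep epochs get a cosmetic NREM/REM
# relabel; downstream only uses the binary wake/sleep mapping.
simulate_hypnogram <- function(n_epochs, efficiency) {
  stages <- character(n_epochs)
  if (efficiency >= 1) {
    state <- rep(TRUE, n_epochs)
  } else if (efficiency <= 0) {
    state <- rep(FALSE, n_epochs)
  } else {
    exit_w <- 0.25
    exit_s <- min(1, exit_w * (1 - efficiency) / efficiency)
    state <- logical(n_epochs)
    state[1L] <- runif(1) < efficiency
    for (i in seq_len(n_epochs - 1L)) {
      flip <- runif(1) < (if (state[i]) exit_s else exit_w)
      state[i + 1L] <- if (flip) !state[i] else state[i]
    }
  }
  stages[!state] <- "W"
  n_sleep <- sum(state)
  if (n_sleep > 0)
    stages[state] <- sample(c("N1", "N2", "N3", "REM"), n_sleep,
                            replace = TRUE)
  stages
}

# Events as a renewal process on the cumulative-sleep-time axis: inter-onset
# spacing = previous duration + Exp(gap) with the gap mean chosen so the
# realized onset rate matches ahi_target per sleep hour; onsets are then
# mapped back to absolute time (so they always fall inside sleep epochs)
# and durations elapse in absolute time. Gaps >= spacing guarantee events
# never overlap.
simulate_events <- function(hypnogram, lights_off, lights_on, cfg) {
  sleep_epochs <- which(hypnogram != "W")
  tst_s <- length(sleep_epochs) * EPOCH_S
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      type = character(0), stringsAsFactors = FALSE)
  if (cfg$ahi_target <= 0 || tst_s <= 0) return(empty)
  rate <- cfg$ahi_target / 3600           # onsets per sleep second
  mean_dur <- mean(cfg$event_duration_s)
  gap_mean <- max(1 / rate - mean_dur, 5)
  epoch_abs_start <- lights_off + (sleep_epochs - 1) * EPOCH_S

  starts <- ends <- numeric(0)
  types <- character(0)
  s <- rexp(1, rate = 1 / gap_mean)
  repeat {
    if (s >= tst_s) break
    dur <- runif(1, cfg$event_duration_s[1L], cfg$event_duration_s[2L])
    idx <- floor(s / EPOCH_S) + 1
    abs_start <- epoch_abs_start[idx] + s %% EPOCH_S
    abs_end <- min(abs_start + dur, lights_on)
    if (abs_end > abs_start) {
      starts <- c(starts, abs_start)
      ends <- c(ends, abs_end)
      types <- c(types,
                 if (runif(1) < cfg$hypopnea_fraction) "hypopnea"
                 else "apnea")
    }
    s <- s + dur + rexp(1, rate = 1 / gap_mean)
  }
  data.frame(start_s = starts, end_s = ends, type = types,
             stringsAsFactors = FALSE)
}

# Event-locked RR modulation factor at times t: a raised half-sine
# lengthening during the event and a decaying undershoot for ~10 s after.
rr_modulation <- function(t, events, cfg) {
  m <- rep(1, length(t))
  if (nrow(events) == 0) return(m)
  idx <- findInterval(t, events$start_s)
  has <- idx > 0
  if (!any(has)) return(m)
  a <- events$start_s[idx[has]]
  b <- events$end_s[idx[has]]
  tt <- t[has]
  inside <- tt < b
  mm <- rep(1, length(tt))
  mm[inside] <- 1 + cfg$rr_event_excursion *
    sin(pi * (tt[inside] - a[inside]) / pmax(b[inside] - a[inside], 1e-9))
  after <- !inside & tt < b + 10
  mm[after] <- 1 - cfg$rr_undershoot * (1 - (tt[after] - b[after]) / 10)
  m[has] <- mm
  m
}

simulate_beats <- function(hypnogram, events, lights_off, lights_on, cfg) {
  base <- 60 / cfg$hr_base_bpm
  sd_s <- cfg$hrv_sd_ms / 1000
  n_guess <- ceiling((lights_on - lights_off) / base * 1.6) + 16L
  noise <- numeric(n_guess)
  noise[1L] <- rnorm(1, 0, sd_s)
  innov <- rnorm(n_guess, 0, sd_s * sqrt(1 - 0.81))
  for (k in 2:n_guess) noise[k] <- 0.9 * noise[k - 1L] + innov[k]
  art <- runif(n_guess) < cfg$artifact_prob
  art_mult <- runif(n_guess, 0.4, 1.6)

  # pre-tabulate the slowly varying event modulation on a 0.25-s grid so the
  # sequential beat loop stays cheap
  grid_fs <- 4
  grid_t <- lights_off +
    (seq_len(ceiling((lights_on - lights_off) * grid_fs) + 1L) - 1) / grid_fs
  m_grid <- rr_modulation(grid_t, events, cfg)
  wake <- hypnogram == "W"
  n_ep <- length(hypnogram)

  times <- numeric(n_guess)
  t <- lights_off
  k <- 0L
  while (t < lights_on && k < n_guess) {
    k <- k + 1L
    ep <- min(floor((t - lights_off) / EPOCH_S) + 1, n_ep)
    mult <- if (wake[ep]) cfg$wake_hrv_multiplier else 1
    m <- m_grid[floor((t - lights_off) * grid_fs) + 1L]
    rr <- base * m + noise[k] * mult
    if (art[k]) rr <- rr * art_mult[k]
    rr <- min(max(rr, 0.4), 2.0)
    t <- t + rr
    times[k] <- t
  }
  keep <- seq_len(k)
  keep <- keep[times[keep] < lights_on]
  list(times = times[keep], mask = art[keep])
}

simulate_effort <- function(hypnogram, events, lights_off, lights_on, cfg) {
  fs <- cfg$effort_fs_hz
  n <- floor((lights_on - lights_off) * fs)
  t <- lights_off + (seq_len(n) - 1) / fs
  env <- rep(1, n)
  if (nrow(events) > 0) {
    depth <- ifelse(events$type == "apnea", cfg$apnea_floor,
                    cfg$hypopnea_depth)
    for (i in seq_len(nrow(events))) {
      sel <- t >= events$start_s[i] & t < events$end_s[i]
      env[sel] <- depth[i]
    }
    # ~2 s raised-cosine smoothing of the envelope edges
    w <- max(1L, round(2 * fs))
    kern <- 0.5 - 0.5 * cos(2 * pi * seq_len(w) / (w + 1))
    kern <- kern / sum(kern)
    env <- as.numeric(stats::filter(c(rep(env[1L], w), env,
                                      rep(env[n], w)),
                                    kern, sides = 2L))[w + seq_len(n)]
  }
  phase <- 2 * pi * cfg$breath_rate_hz * (t - lights_off) +
    cumsum(rnorm(n, 0, 0.02 / sqrt(fs)))
  ep <- pmin(floor((t - lights_off) / EPOCH_S) + 1, length(hypnogram))
  noise_scale <- ifelse(hypnogram[ep] == "W",
                        cfg$noise_sd * cfg$wake_effort_noise_mult,
                        cfg$noise_sd)
  env * sin(phase) + rnorm(n, 0, 1) * noise_scale
}

#' Simulate one synthetic overnight cardiorespiratory record
#'
#' Generates a subject record with known ground truth: a hypnogram, scored
#' SDB events, heartbeat times with an artifact mask, and a raw
#' respiratory-effort waveform. All times are seconds from lights-off
#' (t = 0). The realized reference AHI is the realized event count divided
#' by the realized total sleep time.
#'
#' @param config a [sim_config()].
#' @param subject_id identifier stored in the record.
#' @return An object of class `sdb_record` with fields `subject_id`,
#'   `beat_times_s`, `beat_artifact_mask`, `effort`, `effort_fs_hz`,
#'   `hypnogram`, `events`, `lights_off_s`, `lights_on_s`, `tst_ref_h`,
#'   `ahi_ref`.
#' @export
simulate_subject <- function(config = sim_config(), subject_id = "S001") {
  stopifnot(inherits(config, "sim_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)

  lights_off <- 0
  lights_on <- config$tib_hours * 3600
  n_epochs <- floor((lights_on - lights_off) / EPOCH_S)
  hyp <- simulate_hypnogram(n_epochs, config$sleep_efficiency)
  events <- simulate_events(hyp, lights_off, lights_on, config)
  beats <- simulate_beats(hyp, events, lights_off, lights_on, config)
  effort <- simulate_effort(hyp, events, lights_off, lights_on, config)

  tst_h <- sum(hyp != "W") * EPOCH_S / 3600
  ahi_ref <- if (tst_h > 0) nrow(events) / tst_h else 0

  structure(list(subject_id = subject_id,
                 beat_times_s = beats$times,
                 beat_artifact_mask = beats$mask,
                 effort = effort,
                 effort_fs_hz = config$effort_fs_hz,
                 hypnogram = hyp,
                 events = events,
                 lights_off_s = lights_off,
                 lights_on_s = lights_on,
                 tst_ref_h = tst_h,
                 ahi_ref = ahi_ref,
                 config = config),
            class = "sdb_record")
}

#' @export
print.sdb_record <- function(x, ...) {
  cat("Synthetic overnight record", x$subject_id, "\n")
  cat(sprintf("  TIB %.2f h, TST %.2f h (efficiency %.2f)\n",
              (x$lights_on_s - x$lights_off_s) / 3600, x$tst_ref_h,
              x$tst_ref_h / ((x$lights_on_s - x$lights_off_s) / 3600)))
  cat(sprintf("  %d SDB events, reference AHI %.1f events/h\n",
              nrow(x$events), x$ahi_ref))
  cat(sprintf("  %d beats (%.1f%% masked), effort %d samples at %g Hz\n",
              length(x$beat_times_s), 100 * mean(x$beat_artifact_mask),
              length(x$effort), x$effort_fs_hz))
  invisible(x)
}

#' Simulate a cohort spanning all SDB severity strata
#'
#' Per-subject AHI targets are assigned round-robin over the four severity
#' strata (normal/mild/moderate/severe) and drawn uniformly within each
#' stratum's range, so every stratum is populated; sleep efficiency is
#' drawn uniformly from `se_range`. Every subject gets an independent
#' generator stream derived from `(seed, subject index)`.
#'
#' @param n_subjects number of subjects (>= 4, so stratified
#'   cross-validation is possible).
#' @param config base [sim_config()]; per-subject AHI target, sleep
#'   efficiency and seed are overridden.
#' @param seed cohort-level seed.
#' @param ahi_ranges named list of per-stratum target-AHI ranges.
#' @param se_range range of per-subject sleep efficiency.
#' @return A list of [simulate_subject()] records (class `sdb_cohort`).
#' @export
simulate_cohort <- function(n_subjects, config = sim_config(), seed = 1L,
                            ahi_ranges = list(normal = c(0.5, 4.5),
                                              mild = c(5.5, 14.5),
                                              moderate = c(15.5, 29.5),
                                              severe = c(30.5, 60)),
                            se_range = c(0.6, 0.95)) {
  if (n_subjects < 4)
    stop("n_subjects must be >= 4 so that all severity strata are populated")
  stopifnot(length(ahi_ranges) == 4L)
  records <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    sub_seed <- derive_seed(seed, i)
    old <- get_rng_state()
    set.seed(sub_seed)
    stratum <- ahi_ranges[[(i - 1L) %% 4L + 1L]]
    ahi <- runif(1, stratum[1L], stratum[2L])
    se <- runif(1, se_range[1L], se_range[2L])
    restore_rng_state(old)
    cfg <- config
    cfg$ahi_target <- ahi
    cfg$sleep_efficiency <- se
    cfg$seed <- derive_seed(sub_seed, 1L)
    records[[i]] <- simulate_subject(cfg, sprintf("S%03d", i))
  }
  structure(records, class = "sdb_cohort")
}

#' @export
print.sdb_cohort <- function(x, ...) {
  ahi <- vapply(x, `[[`, numeric(1), "ahi_ref")
  cat("Synthetic cohort of", length(x), "subjects\n")
  print(table(severity = severity_class(ahi)))
  invisible(x)
}
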