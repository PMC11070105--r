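#' Uniformly resampled RR-interval tachogram
#'
#' Builds the instantaneous RR series from heartbeat times: at every
#' unmasked beat the RR value is the interval to the previous unmasked
#' beat. RR values outside the physiological gate `[0.3, 3]` s (e.g. the
#' long pseudo-interval bridging a masked stretch) are discarded before
#' interpolation, so artifact periods are bridged linearly between
#' neighbouring valid RR values. The series is then linearly interpolated
#' onto a uniform 4 Hz grid over `span`, with edges extended by the nearest
#' valid value.
#'
#' @param beat_times_s strictly increasing heartbeat times (s).
#' @param artifact_mask per-beat logical, `TRUE` = artifact/ectopic beat
#'   excluded from the tachogram. `NULL` means no beat is masked.
#' @param span length-2 numeric `c(t0, t1)`: the time window to cover.
#' @param rr_gate valid RR range in seconds.
#' @return A list of class `rr_series`: `values` (length
#'   `(t1 - t0) * 4`), `t0_s`, `fs` (always 4).
#' @export
rr_tachogram <- function(beat_times_s, artifact_mask = NULL, span,
                         rr_gate = c(0.3, 3.0)) {
  n <- length(beat_times_s)
  if (is.null(artifact_mask)) artifact_mask <- rep(FALSE, n)
  stopifnot(length(artifact_mask) == n, length(span) == 2L,
            span[2L] > span[1L])
  if (n >= 2 && any(diff(beat_times_s) <= 0))
    stop("beat times must be strictly increasing")

  tv <- beat_times_s[!artifact_mask]
  if (length(tv) < 2) stop("need at least 2 unmasked beats")
  rr <- diff(tv)
  t_rr <- tv[-1L]
  ok <- rr >= rr_gate[1L] & rr <= rr_gate[2L]
  rr <- rr[ok]
  t_rr <- t_rr[ok]
  in_span <- t_rr >= span[1L] & t_rr <= span[2L]
  if (sum(in_span) < 2)
    stop("need at least 2 valid RR samples inside the requested span")

  n_out <- round((span[2L] - span[1L]) * TARGET_FS)
  grid <- span[1L] + (seq_len(n_out) - 1) / TARGET_FS
  values <- approx(t_rr, rr, xout = grid, method = "linear", rule = 2)$y
  structure(list(values = values, t0_s = span[1L], fs = TARGET_FS),
            class = "rr_series")
}

#' Condition a respiratory-effort waveform
#'
#' Removes high-frequency noise (> 2 Hz) with a zero-phase Butterworth
#' low-pass, resamples to 4 Hz, and removes baseline drift with a
#' zero-phase order-3 Butterworth high-pass at 0.05 Hz. Zero-phase
#' (forward-backward) application preserves the time alignment between the
#' waveform and the event/sleep labels.
#'
#' @param raw numeric effort waveform.
#' @param fs_in its sampling rate (Hz, >= 4).
#' @param t0_s time of the first sample (s).
#' @return A list of class `effort_series`: `values` at 4 Hz, `t0_s`, `fs`.
#' @export
condition_effort <- function(raw, fs_in, t0_s = 0) {
  stopifnot(is.numeric(raw), all(is.finite(raw)))
  if (fs_in < 4) stop("effort sampling rate must be >= 4 Hz, got ", fs_in)

  x <- raw
  if (fs_in > 4.5) {
    lp <- signal::butter(4, 2 / (fs_in / 2), type = "low")
    x <- signal::filtfilt(lp, x)
  }
  t_in <- t0_s + (seq_along(x) - 1) / fs_in
  n_out <- floor(length(x) / fs_in * TARGET_FS)
  grid <- t0_s + (seq_len(n_out) - 1) / TARGET_FS
  x4 <- approx(t_in, x, xout = grid, rule = 2)$y
  hp <- signal::butter(3, 0.05 / (TARGET_FS / 2), type = "high")
  values <- signal::filtfilt(hp, x4)
  structure(list(values = values, t0_s = t0_s, fs = TARGET_FS),
            class = "effort_series")
}

#' Fraction of masked beats inside a time window
#'
#' Used to flag segments whose span is dominated by artifact: windows with
#' more than half of their beats masked are marked unusable downstream.
#'
#' @param beat_times_s heartbeat times (s).
#' @param artifact_mask per-beat logical mask.
#' @param window length-2 `c(t0, t1)`.
#' @return Fraction in `[0, 1]` (0 when the window holds no beats).
#' @export
masked_fraction <- function(beat_times_s, artifact_mask, window) {
  sel <- beat_times_s >= window[1L] & beat_times_s < window[2L]
  if (!any(sel)) return(0)
  mean(artifact_mask[sel])
}

#' Preprocess a subject record into aligned 4 Hz channels
#'
#' Convenience wrapper producing the RR tachogram and the conditioned
#' effort series over the lights-off to lights-on window; both outputs have
#' identical length (the alignment contract for segmentation).
#'
#' @param record an `sdb_record`.
#' @return List with `rr` (`rr_series`) and `effort` (`effort_series`).
#' @export
preprocess_record <- function(record) {
  span <- c(record$lights_off_s, record$lights_on_s)
  rr <- rr_tachogram(record$beat_times_s, record$beat_artifact_mask, span)
  eff <- condition_effort(record$effort, record$effort_fs_hz,
                          t0_s = record$lights_off_s)
  n <- min(length(rr$values), length(eff$values))
  rr$values <- rr$values[seq_len(n)]
  eff$values <- eff$values[seq_len(n)]
  list(rr = rr, effort = eff)
}
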