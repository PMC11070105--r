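#' Soft min-max normalization
#'
#' Affine rescaling that maps the 5th percentile to 0 and the 95th
#' percentile to 1 (percentiles by linear interpolation); values are not
#' clipped, so output may fall outside `[0, 1]`. A degenerate spread
#' (p95 = p5) yields an all-zero output flagged via the `"degenerate"`
#' attribute.
#'
#' @param x non-empty numeric vector.
#' @return Normalized vector, with attribute `degenerate` (logical).
#' @export
soft_minmax <- function(x) {
  stopifnot(length(x) > 0)
  q <- quantile(x, c(0.05, 0.95), names = FALSE, type = 7)
  if (q[2L] <= q[1L]) {
    out <- rep(0, length(x))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (x - q[1L]) / (q[2L] - q[1L])
  attr(out, "degenerate") <- FALSE
  out
}

#' Map scored SDB events onto per-second labels of a window
#'
#' Second `j` of the window (covering `[start + j, start + j + 1)`,
#' `j = 0 ... 299`) is labelled 1 iff it intersects any event of any type;
#' events are half-open intervals `[start_s, end_s)`.
#'
#' @param events data frame with `start_s`, `end_s` columns (may be empty).
#' @param window length-2 `c(start, end)` in seconds.
#' @return Integer 0/1 vector of length `end - start`.
#' @export
map_event_labels <- function(events, window) {
  n <- round(window[2L] - window[1L])
  y <- integer(n)
  if (NROW(events) == 0) return(y)
  sec_start <- window[1L] + seq_len(n) - 1
  for (i in seq_len(nrow(events))) {
    hit <- events$start_s[i] < sec_start + 1 & events$end_s[i] > sec_start
    y[hit] <- 1L
  }
  y
}

#' Map a hypnogram onto per-epoch sleep labels of a window
#'
#' Wake epochs map to 0; any sleep stage (N1, N2, N3, REM) maps to 1. The
#' window start must be aligned to a 30-s epoch boundary (guaranteed by the
#' 180-s segmentation step anchored at lights-off).
#'
#' @param hypnogram character vector of per-30-s stages.
#' @param window length-2 `c(start, end)` in seconds.
#' @param lights_off_s time of the first epoch.
#' @return Integer 0/1 vector, one label per 30-s epoch of the window.
#' @export
map_sleep_labels <- function(hypnogram, window, lights_off_s = 0) {
  off <- window[1L] - lights_off_s
  if (abs(off %% EPOCH_S) > 1e-9)
    stop("window start is not aligned to a 30-s epoch boundary")
  e0 <- round(off / EPOCH_S)
  n_ep <- round((window[2L] - window[1L]) / EPOCH_S)
  if (e0 + n_ep > length(hypnogram))
    stop("window extends past the hypnogram (needs epochs up to ",
         e0 + n_ep, ", hypnogram has ", length(hypnogram), ")")
  as.integer(hypnogram[e0 + seq_len(n_ep)] != "W")
}

#' Cut aligned 4 Hz channels into overlapping 5-minute segments
#'
#' Windows are 300 s long with a 180-s step (2-min overlap), anchored at
#' lights-off; a trailing partial window is dropped. Each window's two
#' channels are independently soft-min-max normalized; labels are mapped at
#' 1 Hz (events) and 1/30 Hz (sleep). Windows with a degenerate channel
#' spread or more than 50% masked beats are flagged `usable = FALSE` (they
#' are still returned so whole-night stitching has no gaps).
#'
#' @param record the `sdb_record` the channels came from.
#' @param rr an `rr_series` from [rr_tachogram()].
#' @param effort an `effort_series` from [condition_effort()].
#' @return An object of class `segment_store`: list with array `X`
#'   `(n, 1200, 2)` (RR then effort), matrices `y_event` `(n, 300)` and
#'   `y_sleep` `(n, 10)`, vectors `start_s`, `usable` and `subject_id`.
#' @export
make_segments <- function(record, rr, effort) {
  stopifnot(rr$fs == TARGET_FS, effort$fs == TARGET_FS,
            length(rr$values) == length(effort$values))
  t0 <- record$lights_off_s
  t1 <- record$lights_on_s
  if (t1 - t0 < SEGMENT_S) {
    warning("record shorter than 5 minutes: no segments")
    return(empty_segment_store(record$subject_id))
  }
  starts <- seq(t0, t1 - SEGMENT_S, by = SEGMENT_STEP_S)
  n <- length(starts)
  len <- SEGMENT_S * TARGET_FS
  X <- array(NA_real_, c(n, len, 2L))
  y_event <- matrix(0L, n, SEGMENT_S)
  y_sleep <- matrix(0L, n, SEGMENT_S / EPOCH_S)
  usable <- rep(TRUE, n)
  for (i in seq_len(n)) {
    off <- round((starts[i] - rr$t0_s) * TARGET_FS)
    idx <- off + seq_len(len)
    xr <- soft_minmax(rr$values[idx])
    xe <- soft_minmax(effort$values[idx])
    if (attr(xr, "degenerate") || attr(xe, "degenerate")) usable[i] <- FALSE
    if (masked_fraction(record$beat_times_s, record$beat_artifact_mask,
                        c(starts[i], starts[i] + SEGMENT_S)) > 0.5)
      usable[i] <- FALSE
    X[i, , 1L] <- xr
    X[i, , 2L] <- xe
    win <- c(starts[i], starts[i] + SEGMENT_S)
    y_event[i, ] <- map_event_labels(record$events, win)
    y_sleep[i, ] <- map_sleep_labels(record$hypnogram, win, t0)
  }
  structure(list(X = X, y_event = y_event, y_sleep = y_sleep,
                 start_s = starts, usable = usable,
                 subject_id = rep(record$subject_id, n)),
            class = "segment_store")
}

empty_segment_store <- function(subject_id = character(0)) {
  structure(list(X = array(0, c(0L, SEGMENT_S * TARGET_FS, 2L)),
                 y_event = matrix(0L, 0L, SEGMENT_S),
                 y_sleep = matrix(0L, 0L, SEGMENT_S / EPOCH_S),
                 start_s = numeric(0), usable = logical(0),
                 subject_id = character(0)),
            class = "segment_store")
}

#' Segment a whole record (preprocess + cut) in one call
#' @param record an `sdb_record`.
#' @return A `segment_store`.
#' @export
segment_record <- function(record) {
  pre <- preprocess_record(record)
  make_segments(record, pre$rr, pre$effort)
}

#' Concatenate segment stores
#' @param ... `segment_store` objects.
#' @return A single combined `segment_store`.
#' @export
bind_segments <- function(...) {
  stores <- list(...)
  if (length(stores) == 1L && !inherits(stores[[1L]], "segment_store"))
    stores <- stores[[1L]]
  ns <- vapply(stores, function(s) dim(s$X)[1L], integer(1))
  out <- empty_segment_store()
  n <- sum(ns)
  out$X <- array(0, c(n, SEGMENT_S * TARGET_FS, 2L))
  out$y_event <- matrix(0L, n, SEGMENT_S)
  out$y_sleep <- matrix(0L, n, SEGMENT_S / EPOCH_S)
  at <- 0L
  for (s in stores) {
    k <- dim(s$X)[1L]
    if (k == 0L) next
    out$X[at + seq_len(k), , ] <- s$X
    out$y_event[at + seq_len(k), ] <- s$y_event
    out$y_sleep[at + seq_len(k), ] <- s$y_sleep
    at <- at + k
  }
  out$start_s <- unlist(lapply(stores, `[[`, "start_s"))
  out$usable <- unlist(lapply(stores, `[[`, "usable"))
  out$subject_id <- unlist(lapply(stores, `[[`, "subject_id"))
  out
}

#' Subset a segment store
#' @param store a `segment_store`.
#' @param idx integer or logical index over segments.
#' @return A `segment_store` with the selected segments.
#' @export
subset_segments <- function(store, idx) {
  structure(list(X = store$X[idx, , , drop = FALSE],
                 y_event = store$y_event[idx, , drop = FALSE],
                 y_sleep = store$y_sleep[idx, , drop = FALSE],
                 start_s = store$start_s[idx], usable = store$usable[idx],
                 subject_id = store$subject_id[idx]),
            class = "segment_store")
}

#' @export
print.segment_store <- function(x, ...) {
  cat("Segment store:", dim(x$X)[1L], "segments from",
      length(unique(x$subject_id)), "subject(s);",
      sum(!x$usable), "flagged unusable\n")
  invisible(x)
}
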