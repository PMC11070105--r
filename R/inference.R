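#' Stitch per-segment tracks into one whole-night track
#'
#' From each 5-minute segment only the central 3 minutes are kept (the
#' outer minute at each end is the half of the 2-min overlap shared with
#' the neighbouring segments); the kept windows tile the night exactly.
#' The night's first and last 60 s take their values from the first/last
#' segment's outer minutes so the whole record is covered; the returned
#' `center` mask marks samples that came from a central window (evaluation
#' uses only those).
#'
#' @param values matrix `(n_segments, L)` of per-segment values (`L = 300`
#'   for 1 Hz tracks, `10` for epoch tracks), rows ordered like `start_s`.
#' @param start_s segment start times; must lie on the 180-s grid with no
#'   gaps.
#' @param rate samples per second of the track (1 or 1/30).
#' @return List of class `night_track`: `values`, `t0_s`, `rate`, `center`
#'   (logical mask).
#' @export
stitch_predictions <- function(values, start_s, rate = 1) {
  n <- length(start_s)
  stopifnot(is.matrix(values), nrow(values) == n, n >= 1)
  o <- order(start_s)
  values <- values[o, , drop = FALSE]
  start_s <- start_s[o]
  if (n > 1) {
    gaps <- diff(start_s)
    if (any(abs(gaps - SEGMENT_STEP_S) > 1e-9))
      stop("segments are not on a contiguous 180-s grid; gap(s) after t = ",
           paste(start_s[which(abs(gaps - SEGMENT_STEP_S) > 1e-9)],
                 collapse = ", "))
  }
  edge <- round(60 * rate)           # samples per outer minute
  seg_len <- round(SEGMENT_S * rate)
  night_len <- round((start_s[n] + SEGMENT_S - start_s[1L]) * rate)
  out <- numeric(night_len)
  center <- logical(night_len)
  for (i in seq_len(n)) {
    off <- round((start_s[i] - start_s[1L]) * rate)
    keep <- (edge + 1):(seg_len - edge)
    out[off + keep] <- values[i, keep]
    center[off + keep] <- TRUE
    if (i == 1L) out[seq_len(edge)] <- values[i, seq_len(edge)]
    if (i == n) out[off + (seg_len - edge + 1):seg_len] <-
        values[i, (seg_len - edge + 1):seg_len]
  }
  structure(list(values = out, t0_s = start_s[1L], rate = rate,
                 center = center),
            class = "night_track")
}

#' Binarize stitched tracks and mask events by detected wake
#'
#' A 30-s epoch is classified sleep iff its probability reaches
#' `thresholds$sleep`; a one-second sample is an event sample iff its
#' probability reaches `thresholds$event` AND its containing epoch is
#' classified sleep (events detected during wake are reassigned to normal
#' breathing).
#'
#' @param p_sleep per-epoch sleep probabilities.
#' @param p_event per-second event probabilities (length
#'   `30 * length(p_sleep)`, trailing partial epochs tolerated).
#' @param thresholds list with `sleep` and `event` in (0, 1).
#' @return List with `sleep_binary` (per epoch) and `event_binary`
#'   (per second).
#' @export
binarize_and_mask <- function(p_sleep, p_event, thresholds) {
  sleep_bin <- as.integer(p_sleep >= thresholds$sleep)
  mask <- rep(sleep_bin, each = EPOCH_S)[seq_along(p_event)]
  event_bin <- as.integer(p_event >= thresholds$event & mask == 1L)
  list(sleep_binary = sleep_bin, event_binary = event_bin)
}

#' Merge consecutive event seconds into discrete events
#'
#' Maximal runs of 1 in a per-second binary track become half-open
#' intervals `[start_s, end_s)`.
#'
#' @param event_binary integer/logical 0-1 vector at 1 Hz.
#' @param t0_s time of the first sample.
#' @return Data frame with `start_s`, `end_s`.
#' @export
merge_events <- function(event_binary, t0_s = 0) {
  r <- rle(as.integer(event_binary))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values == 1L
  data.frame(start_s = t0_s + starts[keep], end_s = t0_s + ends[keep])
}

#' Match detected events against reference events
#'
#' Greedy one-to-one matching in time order: a detected event is a true
#' positive if it overlaps at least `min_overlap_s` seconds with a not yet
#' matched reference event; unmatched detections are false positives and
#' unmatched references false negatives.
#'
#' @param detected,reference data frames with `start_s`, `end_s`, each
#'   sorted and internally non-overlapping.
#' @param min_overlap_s minimum overlap to count a match (s).
#' @return Named list `TP`, `FP`, `FN`.
#' @export
match_events <- function(detected, reference, min_overlap_s = 1) {
  check_intervals <- function(x, what) {
    if (NROW(x) > 1) {
      if (is.unsorted(x$start_s))
        stop(what, " events must be sorted by start time")
      if (any(x$end_s[-nrow(x)] > x$start_s[-1L] + 1e-9))
        stop(what, " events overlap each other")
    }
  }
  check_intervals(detected, "detected")
  check_intervals(reference, "reference")
  n_det <- NROW(detected)
  n_ref <- NROW(reference)
  matched <- logical(n_ref)
  tp <- 0L
  for (i in seq_len(n_det)) {
    for (j in seq_len(n_ref)) {
      if (matched[j]) next
      ov <- min(detected$end_s[i], reference$end_s[j]) -
        max(detected$start_s[i], reference$start_s[j])
      if (ov >= min_overlap_s) {
        matched[j] <- TRUE
        tp <- tp + 1L
        break
      }
      if (reference$start_s[j] >= detected$end_s[i]) break
    }
  }
  list(TP = tp, FP = n_det - tp, FN = n_ref - tp)
}

#' Whole-night prediction for one subject
#'
#' Runs the model over the subject's segments, stitches the per-segment
#' outputs with the center-3-minute rule, binarizes with the given
#' thresholds, masks events by detected wake and merges event seconds into
#' discrete events. TST/AHI/REI estimates use the full stitched track;
#' agreement metrics should use the `center` masks.
#'
#' @param model a trained `sdb_net` (multi-task).
#' @param store a `segment_store` holding exactly one subject's segments.
#' @param thresholds list with `sleep`, `event`.
#' @return Object of class `night_prediction`: stitched probability and
#'   binary tracks, estimated events, reference tracks, and TST/AHI/REI
#'   estimates.
#' @export
predict_night <- function(model, store, thresholds) {
  sid <- unique(store$subject_id)
  stopifnot(length(sid) == 1L)
  pr <- predict(model, store)
  ev_track <- stitch_predictions(pr$p_event, store$start_s, rate = 1)
  ref_ev <- stitch_predictions(store$y_event, store$start_s, rate = 1)
  ref_sl <- stitch_predictions(store$y_sleep, store$start_s,
                               rate = 1 / EPOCH_S)
  if (!model$single_task) {
    sl_track <- stitch_predictions(pr$p_sleep, store$start_s,
                                   rate = 1 / EPOCH_S)
    bin <- binarize_and_mask(sl_track$values, ev_track$values, thresholds)
  } else {
    sl_track <- NULL
    bin <- list(sleep_binary = NULL,
                event_binary = as.integer(ev_track$values >=
                                            thresholds$event))
  }
  events_est <- merge_events(bin$event_binary, t0_s = ev_track$t0_s)
  tib_h <- (length(ev_track$values)) / 3600
  n_ev <- nrow(events_est)
  tst_h <- if (!model$single_task) estimate_tst(bin$sleep_binary) else NA_real_
  structure(list(subject_id = sid,
                 p_sleep = sl_track, p_event = ev_track,
                 sleep_binary = bin$sleep_binary,
                 event_binary = bin$event_binary,
                 events_est = events_est,
                 ref_sleep = ref_sl, ref_event = ref_ev,
                 tst_est_h = tst_h,
                 ahi_est = if (!model$single_task)
                   estimate_ahi(n_ev, tst_h) else NA_real_,
                 rei_est = estimate_rei(n_ev, tib_h),
                 tib_h = tib_h,
                 thresholds = thresholds),
            class = "night_prediction")
}

#' @export
print.night_prediction <- function(x, ...) {
  cat("Night prediction for", x$subject_id, "\n")
  cat(sprintf("  TST_est %.2f h, %d events, AHI_est %.1f, REI_est %.1f\n",
              x$tst_est_h, nrow(x$events_est), x$ahi_est, x$rei_est))
  invisible(x)
}

#' Export a night prediction as CSV tables
#'
#' Writes `<subject>_hypnogram.csv` (epoch index, predicted label) and
#' `<subject>_events.csv` (start_s, end_s) for a predicted night.
#'
#' @param np a `night_prediction`.
#' @param dir output directory.
#' @return The two file paths, invisibly.
#' @export
write_night_csv <- function(np, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hyp_path <- file.path(dir, paste0(np$subject_id, "_hypnogram.csv"))
  ev_path <- file.path(dir, paste0(np$subject_id, "_events.csv"))
  if (!is.null(np$sleep_binary)) {
    write.csv(data.frame(epoch = seq_along(np$sleep_binary),
                         label = np$sleep_binary),
              hyp_path, row.names = FALSE)
  }
  write.csv(np$events_est, ev_path, row.names = FALSE)
  invisible(c(hyp_path, ev_path))
}
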