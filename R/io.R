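# Annotation dialect: one JSON sidecar per record, schema_version 1.
# All times in seconds from lights-off; events half-open [start_s, end_s).
# Unknown schema versions are refused, never coerced.

RECORD_SCHEMA_VERSION <- 1L

#' Write a subject record to the JSON annotation dialect
#'
#' @param record an `sdb_record`.
#' @param path output file (`.json`).
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "sdb_record"))
  payload <- list(
    schema_version = RECORD_SCHEMA_VERSION,
    subject_id = record$subject_id,
    lights_off_s = record$lights_off_s,
    lights_on_s = record$lights_on_s,
    hypnogram = record$hypnogram,
    events = record$events[, c("start_s", "end_s", "type")],
    beat_times_s = record$beat_times_s,
    beat_artifact_mask = record$beat_artifact_mask,
    effort_fs_hz = record$effort_fs_hz,
    effort = record$effort,
    tst_ref_h = record$tst_ref_h,
    ahi_ref = record$ahi_ref)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a subject record from the JSON annotation dialect
#'
#' Validates the schema version and the record invariants (strictly
#' increasing beat times, hypnogram length matching the lights window,
#' events inside the window).
#'
#' @param path a file written by [write_record()].
#' @return An `sdb_record`.
#' @export
read_record <- function(path) {
  if (!file.exists(path)) stop("no such record file: ", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$schema_version) ||
      p$schema_version != RECORD_SCHEMA_VERSION)
    stop("unknown annotation schema version: ",
         p$schema_version %||% "<missing>", " (expected ",
         RECORD_SCHEMA_VERSION, ")")
  events <- as.data.frame(p$events)
  if (NROW(events) == 0)
    events <- data.frame(start_s = numeric(0), end_s = numeric(0),
                         type = character(0), stringsAsFactors = FALSE)
  beats <- as.numeric(p$beat_times_s)
  if (length(beats) >= 2 && any(diff(beats) <= 0))
    stop("beat times in ", path, " are not strictly increasing")
  n_ep_expect <- floor((p$lights_on_s - p$lights_off_s) / EPOCH_S)
  if (length(p$hypnogram) != n_ep_expect)
    stop("hypnogram length ", length(p$hypnogram),
         " does not match floor(TIB/30) = ", n_ep_expect)
  if (NROW(events) > 0 &&
      (any(events$start_s < p$lights_off_s) ||
         any(events$end_s > p$lights_on_s)))
    stop("events extend outside the lights window")
  structure(list(subject_id = p$subject_id,
                 beat_times_s = beats,
                 beat_artifact_mask = as.logical(p$beat_artifact_mask),
                 effort = as.numeric(p$effort),
                 effort_fs_hz = p$effort_fs_hz,
                 hypnogram = as.character(p$hypnogram),
                 events = events,
                 lights_off_s = p$lights_off_s,
                 lights_on_s = p$lights_on_s,
                 tst_ref_h = p$tst_ref_h,
                 ahi_ref = p$ahi_ref),
            class = "sdb_record")
}

#' CSV exports of events and hypnogram
#' @param record an `sdb_record`.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(record, path) {
  write.csv(record$events[, c("start_s", "end_s", "type")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
write_hypnogram_csv <- function(record, path) {
  write.csv(data.frame(epoch = seq_along(record$hypnogram),
                       stage = record$hypnogram), path, row.names = FALSE)
  invisible(path)
}

# ---- segment stores: raw little-endian doubles + JSON manifest --------

#' Write a segment store to a directory
#'
#' Numeric payloads go to raw little-endian double binaries; shapes and
#' metadata to `manifest.json`. The round trip through [read_segments()]
#' is bit-exact. Shape invariants (1200 x 2 inputs, 300 event labels, 10
#' sleep labels) are enforced on write.
#'
#' @param store a `segment_store`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_segments <- function(store, path) {
  d <- dim(store$X)
  if (length(d) != 3L || d[2L] != SEGMENT_S * TARGET_FS || d[3L] != 2L)
    stop("segment store X must be (n, 1200, 2); got (",
         paste(d, collapse = ", "), ")")
  if (!all(dim(store$y_event) == c(d[1L], SEGMENT_S)) ||
      !all(dim(store$y_sleep) == c(d[1L], SEGMENT_S %/% EPOCH_S)))
    stop("label shapes must be (n, 300) and (n, 10)")
  if (!all(store$y_event %in% 0:1) || !all(store$y_sleep %in% 0:1))
    stop("labels must be binary")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  writeBin(as.numeric(store$X), file.path(path, "X.bin"), size = 8,
           endian = "little")
  writeBin(as.integer(store$y_event), file.path(path, "y_event.bin"),
           size = 4, endian = "little")
  writeBin(as.integer(store$y_sleep), file.path(path, "y_sleep.bin"),
           size = 4, endian = "little")
  jsonlite::write_json(list(schema_version = 1L, n = d[1L],
                            subject_id = store$subject_id,
                            start_s = store$start_s,
                            usable = store$usable),
                       file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a segment store written by [write_segments()]
#' @param path the store directory.
#' @return A `segment_store`.
#' @export
read_segments <- function(path) {
  mf <- jsonlite::read_json(file.path(path, "manifest.json"),
                            simplifyVector = TRUE)
  if (mf$schema_version != 1L)
    stop("unknown segment-store schema version: ", mf$schema_version)
  n <- mf$n
  len <- SEGMENT_S * TARGET_FS
  X <- readBin(file.path(path, "X.bin"), "double", n * len * 2L, size = 8,
               endian = "little")
  structure(list(X = array(X, c(n, len, 2L)),
                 y_event = matrix(readBin(file.path(path, "y_event.bin"),
                                          "integer", n * SEGMENT_S,
                                          size = 4, endian = "little"),
                                  n, SEGMENT_S),
                 y_sleep = matrix(readBin(file.path(path, "y_sleep.bin"),
                                          "integer",
                                          n * (SEGMENT_S %/% EPOCH_S),
                                          size = 4, endian = "little"),
                                  n, SEGMENT_S %/% EPOCH_S),
                 start_s = as.numeric(mf$start_s),
                 usable = as.logical(mf$usable),
                 subject_id = as.character(mf$subject_id)),
            class = "segment_store")
}

# ---- model bundles ----------------------------------------------------

model_param_vector <- function(model) {
  out <- numeric(0)
  for (s in stack_names(model)) for (l in model[[s]]) {
    for (p in l$params) out <- c(out, as.numeric(p))
    for (b in l$buffers) out <- c(out, as.numeric(b))
  }
  out
}

model_set_param_vector <- function(model, v) {
  at <- 0L
  for (s in stack_names(model)) for (i in seq_along(model[[s]])) {
    l <- model[[s]][[i]]
    for (nm in names(l$params)) {
      k <- length(l$params[[nm]])
      l$params[[nm]][] <- v[at + seq_len(k)]
      at <- at + k
    }
    for (nm in names(l$buffers)) {
      k <- length(l$buffers[[nm]])
      l$buffers[[nm]][] <- v[at + seq_len(k)]
      at <- at + k
    }
    model[[s]][[i]] <- l
  }
  stopifnot(at == length(v))
  model
}

#' Save / load a trained model bundle
#'
#' The bundle directory holds `manifest.json` (hyperparameters,
#' single-task flag, init seed, optional decision thresholds) and
#' `weights.bin` (all parameters and batch-norm buffers as little-endian
#' doubles, bit-exact round trip).
#'
#' @param model an `sdb_net`.
#' @param path bundle directory.
#' @param thresholds optional `sdb_thresholds` stored alongside.
#' @return `path` (save) or an `sdb_net` with a `thresholds` attribute
#'   (load).
#' @export
save_model <- function(model, path, thresholds = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  h <- unclass(model$hyper)
  jsonlite::write_json(list(schema_version = 1L, hyper = h,
                            seed = model$seed,
                            single_task = model$single_task,
                            thresholds = if (!is.null(thresholds))
                              unclass(thresholds)),
                       file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeBin(model_param_vector(model), file.path(path, "weights.bin"),
           size = 8, endian = "little")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  mf <- jsonlite::read_json(file.path(path, "manifest.json"),
                            simplifyVector = TRUE)
  if (mf$schema_version != 1L)
    stop("unknown model-bundle schema version: ", mf$schema_version)
  hyper <- do.call(sdb_hyper, mf$hyper)
  model <- build_model(hyper, seed = mf$seed,
                       single_task = isTRUE(mf$single_task))
  n_expect <- length(model_param_vector(model))
  v <- readBin(file.path(path, "weights.bin"), "double", n_expect + 1L,
               size = 8, endian = "little")
  model <- model_set_param_vector(model, v)
  if (!is.null(mf$thresholds))
    attr(model, "thresholds") <- structure(as.list(mf$thresholds),
                                           class = "sdb_thresholds")
  model
}

#' Save an evaluation report as CSV + JSON + readable summary
#' @param report an `sdb_eval` object from [sdb_cv()].
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
save_report <- function(report, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$per_subject, file.path(path, "per_subject.csv"),
            row.names = FALSE)
  jsonlite::write_json(report$pooled, file.path(path, "pooled.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  con <- file(file.path(path, "summary.txt"), "w")
  sink(con)
  print(report)
  sink()
  close(con)
  invisible(path)
}
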