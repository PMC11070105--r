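# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# a short strongly-signatured overnight record plus its segments
short_record <- function() fixture("short_record", function() {
  simulate_subject(sim_config_strong(tib_hours = 1.5, ahi_target = 40,
                                     sleep_efficiency = 0.8, seed = 101),
                   "FIX01")
})

short_store <- function() fixture("short_store", function() {
  segment_record(short_record())
})

# hand-built minimal record (no simulation): constant heartbeats, pure
# sinusoid effort, alternating hypnogram
manual_record <- function(tib_s = 600, events = NULL) {
  n_ep <- tib_s %/% 30
  hyp <- rep(c("N2", "N2", "W"), length.out = n_ep)
  if (is.null(events))
    events <- data.frame(start_s = numeric(0), end_s = numeric(0),
                         type = character(0), stringsAsFactors = FALSE)
  beats <- seq(0.5, tib_s - 0.5, by = 1)
  fs <- 16
  effort <- sin(2 * pi * 0.25 * seq(0, tib_s - 1 / fs, by = 1 / fs))
  structure(list(subject_id = "MAN01",
                 beat_times_s = beats,
                 beat_artifact_mask = rep(FALSE, length(beats)),
                 effort = effort, effort_fs_hz = fs,
                 hypnogram = hyp, events = events,
                 lights_off_s = 0, lights_on_s = tib_s,
                 tst_ref_h = sum(hyp != "W") * 30 / 3600,
                 ahi_ref = 0),
            class = "sdb_record")
}

tiny_hyper <- function(dropout = 0.1) {
  sdb_hyper(gru_units = c(3L, 3L, 3L), conv_filters = c(3L, 3L, 3L),
            dense_units = 4L, dropout = dropout)
}
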