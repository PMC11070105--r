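test_that("stitching keeps the central 3 minutes and covers the edges", {
  starts <- c(0, 180, 360)
  vals <- matrix(rep(1:3, each = 300), 3, 300, byrow = TRUE)
  tr <- stitch_predictions(vals, starts, rate = 1)
  expect_length(tr$values, 660)
  # segment starting at t contributes [t+60, t+240)
  expect_true(all(tr$values[61:240] == 1))
  expect_true(all(tr$values[241:420] == 2))
  expect_true(all(tr$values[421:600] == 3))
  # night edges come from the outer minutes of the first/last segment
  expect_true(all(tr$values[1:60] == 1))
  expect_true(all(tr$values[601:660] == 3))
  # center mask excludes exactly the two edge minutes
  expect_equal(which(!tr$center), c(1:60, 601:660))
})

test_that("kept windows tile the night with no gaps or double cover", {
  starts <- seq(0, 1800 - 300, by = 180)
  n <- length(starts)
  vals <- matrix(seq_len(n), n, 300)
  tr <- stitch_predictions(vals, starts, rate = 1)
  cover <- integer(length(tr$values))
  for (i in seq_len(n)) {
    off <- (starts[i] - starts[1])
    cover[off + 61:240] <- cover[off + 61:240] + 1L
  }
  expect_true(all(cover[61:(length(cover) - 60)] == 1))
  # epoch-rate stitching aligns with the same rule
  ep <- stitch_predictions(matrix(seq_len(n), n, 10), starts, rate = 1 / 30)
  expect_length(ep$values, (starts[n] + 300 - starts[1]) / 30)
})

test_that("a single-segment night uses all ten epochs", {
  tr <- stitch_predictions(matrix(5, 1, 10), 0, rate = 1 / 30)
  expect_equal(tr$values, rep(5, 10))
})

test_that("gaps in the segment grid are reported, not silently filled", {
  expect_error(stitch_predictions(matrix(0, 2, 300), c(0, 360), rate = 1),
               "gap")
})

test_that("wake masking dominates event probabilities", {
  p_event <- rep(0.99, 300)
  p_sleep <- rep(0.1, 10)
  bin <- binarize_and_mask(p_sleep, p_event,
                           list(sleep = 0.5, event = 0.5))
  expect_true(all(bin$event_binary == 0))

  bin2 <- binarize_and_mask(rep(0.9, 10), p_event,
                            list(sleep = 0.5, event = 0.5))
  expect_true(all(bin2$event_binary == 1))

  # one wake epoch inside an event zeroes exactly its 30 seconds
  p_sleep3 <- c(0.9, 0.1, 0.9, rep(0.9, 7))
  bin3 <- binarize_and_mask(p_sleep3, p_event,
                            list(sleep = 0.5, event = 0.5))
  expect_true(all(bin3$event_binary[31:60] == 0))
  expect_true(all(bin3$event_binary[c(1:30, 61:300)] == 1))
  ev <- merge_events(bin3$event_binary)
  expect_equal(nrow(ev), 2)  # the wake epoch split the event in two
})

test_that("masking never creates event seconds", {
  set.seed(14)
  for (k in 1:20) {
    p_event <- runif(300)
    p_sleep <- runif(10)
    thr <- list(sleep = runif(1), event = runif(1))
    masked <- binarize_and_mask(p_sleep, p_event, thr)$event_binary
    unmasked <- as.integer(p_event >= thr$event)
    expect_true(all(masked <= unmasked))
  }
})

test_that("merging follows the run-length rule", {
  expect_equal(merge_events(c(0, 1, 1, 0, 1)),
               data.frame(start_s = c(1, 4), end_s = c(3, 5)))
  expect_equal(nrow(merge_events(rep(0, 300))), 0)
  expect_equal(merge_events(rep(1, 300)),
               data.frame(start_s = 0, end_s = 300))
})

test_that("merge and expand are mutually inverse", {
  set.seed(15)
  for (k in 1:25) {
    bin <- rbinom(120, 1, 0.3)
    ev <- merge_events(bin)
    back <- integer(120)
    for (i in seq_len(nrow(ev)))
      back[(ev$start_s[i] + 1):ev$end_s[i]] <- 1L
    expect_equal(back, bin)
  }
})

test_that("event matching follows the one-second-overlap greedy rule", {
  ev <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(start_s = m[, 1], end_s = m[, 2])
  }
  same <- ev(0, 10, 20, 30, 50, 70)
  expect_equal(match_events(same, same), list(TP = 3L, FP = 0L, FN = 0L))
  expect_equal(match_events(ev(0, 5), ev(100, 110, 120, 130)),
               list(TP = 0L, FP = 1L, FN = 2L))
  expect_equal(match_events(ev(0, 30), ev(10, 40, 50, 70)),
               list(TP = 1L, FP = 0L, FN = 1L))
  # sub-second overlap does not count
  expect_equal(match_events(ev(0, 10.5), ev(10, 20))$TP, 0L)
  expect_error(match_events(ev(0, 10, 5, 15), ev(0, 5)), "overlap each")
})

test_that("match counts always satisfy the bookkeeping identities", {
  set.seed(16)
  for (k in 1:30) {
    det <- random_intervals(rpois(1, 4))
    ref <- random_intervals(rpois(1, 4))
    m <- match_events(det, ref)
    expect_equal(m$TP + m$FP, nrow(det))
    expect_equal(m$TP + m$FN, nrow(ref))
    expect_equal(m, oracle_match(det, ref))
  }
})

test_that("whole-night prediction is internally consistent", {
  st <- short_store()
  m <- build_model(tiny_hyper(), seed = 9)
  np <- predict_night(m, st, list(sleep = 0.5, event = 0.5))
  # merged events reproduce the binary track exactly
  back <- integer(length(np$event_binary))
  for (i in seq_len(nrow(np$events_est)))
    back[(np$events_est$start_s[i] + 1):np$events_est$end_s[i]] <- 1L
  expect_equal(back, np$event_binary)
  # no event second inside a detected wake epoch
  wake_sec <- rep(np$sleep_binary == 0, each = 30)
  expect_true(all(np$event_binary[wake_sec] == 0))
  expect_equal(np$tst_est_h, sum(np$sleep_binary) * 30 / 3600)
})

test_that("night predictions export hypnogram and event CSV tables", {
  st <- short_store()
  m <- build_model(tiny_hyper(), seed = 9)
  np <- predict_night(m, st, list(sleep = 0.5, event = 0.5))
  dir <- tempfile()
  paths <- write_night_csv(np, dir)
  hyp <- read.csv(file.path(dir, paste0(np$subject_id, "_hypnogram.csv")))
  expect_equal(hyp$label, np$sleep_binary)
  ev <- read.csv(file.path(dir, paste0(np$subject_id, "_events.csv")))
  expect_equal(nrow(ev), nrow(np$events_est))
  unlink(dir, recursive = TRUE)
})
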