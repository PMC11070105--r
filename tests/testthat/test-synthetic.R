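test_that("zero event rate produces an event-free record", {
  rec <- simulate_subject(sim_config(tib_hours = 1, ahi_target = 0,
                                     seed = 1))
  expect_equal(nrow(rec$events), 0)
  expect_equal(rec$ahi_ref, 0)
})

test_that("perfect sleep efficiency leaves no wake after sleep onset", {
  rec <- simulate_subject(sim_config(tib_hours = 2, sleep_efficiency = 1,
                                     ahi_target = 10, seed = 2))
  expect_false(any(rec$hypnogram == "W"))
  tib_h <- (rec$lights_on_s - rec$lights_off_s) / 3600
  expect_lte(abs(rec$tst_ref_h - tib_h), 30 / 3600)
})

test_that("identical configurations reproduce byte-identical records", {
  cfg <- sim_config(tib_hours = 1, ahi_target = 20, seed = 33)
  a <- simulate_subject(cfg)
  b <- simulate_subject(cfg)
  expect_identical(a$beat_times_s, b$beat_times_s)
  expect_identical(a$effort, b$effort)
  expect_identical(a$hypnogram, b$hypnogram)
  expect_identical(a$events, b$events)
})

test_that("events never overlap and always start in sleep epochs", {
  for (seed in 1:4) {
    rec <- simulate_subject(sim_config(tib_hours = 2, ahi_target = 45,
                                       sleep_efficiency = 0.7,
                                       seed = seed))
    ev <- rec$events
    if (nrow(ev) > 1)
      expect_true(all(ev$start_s[-1] >= ev$end_s[-nrow(ev)]))
    onset_epoch <- floor((ev$start_s - rec$lights_off_s) / 30) + 1
    expect_true(all(rec$hypnogram[onset_epoch] != "W"))
    expect_true(all(ev$start_s >= rec$lights_off_s))
    expect_true(all(ev$end_s <= rec$lights_on_s))
  }
})

test_that("effort amplitude collapses inside apneas", {
  rec <- simulate_subject(sim_config(tib_hours = 2, ahi_target = 40,
                                     hypopnea_fraction = 0, seed = 5))
  t <- rec$lights_off_s +
    (seq_along(rec$effort) - 1) / rec$effort_fs_hz
  inside <- rep(FALSE, length(t))
  for (i in seq_len(nrow(rec$events))) {
    sel <- t >= rec$events$start_s[i] + 3 & t < rec$events$end_s[i] - 3
    inside <- inside | sel
  }
  expect_gt(sum(inside), 0)
  expect_lt(mean(abs(rec$effort[inside])),
            0.2 * mean(abs(rec$effort[!inside])))
})

test_that("realized event rate matches the Poisson target over replicates", {
  # Monte-Carlo oracle: count events and sleep epochs directly from the
  # returned records
  n_events <- 0
  tst_h <- 0
  for (k in 1:50) {
    rec <- simulate_subject(sim_config(tib_hours = 8, ahi_target = 30,
                                       sleep_efficiency = 0.85,
                                       seed = 1000 + k))
    n_events <- n_events + nrow(rec$events)
    tst_h <- tst_h + rec$tst_ref_h
  }
  realized <- n_events / tst_h
  expect_gt(realized, 27)
  expect_lt(realized, 33)
})

test_that("cohorts populate all severity strata", {
  co <- simulate_cohort(16, sim_config(tib_hours = 1), seed = 9)
  targets <- sapply(co, function(r) r$config$ahi_target)
  expect_equal(as.vector(table(severity_class(targets))), c(4, 4, 4, 4))

  co2 <- simulate_cohort(16, sim_config(tib_hours = 1), seed = 9)
  expect_identical(sapply(co, `[[`, "subject_id"),
                   sapply(co2, `[[`, "subject_id"))
  expect_identical(sapply(co, `[[`, "ahi_ref"),
                   sapply(co2, `[[`, "ahi_ref"))

  expect_error(simulate_cohort(3), "n_subjects")
})

test_that("a moderately large cohort realizes every severity stratum", {
  co <- simulate_cohort(100, sim_config(tib_hours = 1.5), seed = 4)
  ahi <- sapply(co, `[[`, "ahi_ref")
  expect_true(all(table(severity_class(ahi)) > 0))
})
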