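test_that("the early-stopping rule stops after 10 stalled epochs", {
  tr <- early_stop_trace(c(1.0, 0.9, rep(0.95, 10)), patience = 10)
  expect_equal(tr$stop_epoch, 12)
  expect_equal(tr$best_epoch, 2)
  tr2 <- early_stop_trace(seq(1, 0.5, by = -0.05), patience = 10)
  expect_true(is.na(tr2$stop_epoch))
  expect_equal(tr2$best_epoch, 11)
})

test_that("event samples carry weight 10 against 1 for normal breathing", {
  p <- matrix(0.5, 1, 3)
  y <- matrix(c(1, 0, 0), 1, 3)
  ls <- multitask_loss(p, y)
  manual <- mean(c(10, 1, 1) * (-log(c(0.5, 0.5, 0.5))))
  expect_equal(ls$loss_event, manual, tolerance = 1e-9)
  # gradient carries the same per-sample weights
  expect_equal(as.vector(ls$dz_event) * length(y),
               c(10, 1, 1) * (0.5 - c(1, 0, 0)))
})

test_that("a tiny network overfits a handful of segments", {
  st <- short_store()
  n <- dim(st$X)[1]
  hy <- sdb_hyper(gru_units = c(4, 4, 4), conv_filters = c(4, 4, 4),
                  dense_units = 8, dropout = 0)
  m <- build_model(hy, seed = 11)
  tr <- subset_segments(st, seq_len(min(32, n - 2)))
  va <- subset_segments(st, (min(32, n - 2) + 1):n)
  fit <- train_sdb_net(m, tr, va, epochs = 6, batch_size = 16, seed = 12,
                       check_disjoint = FALSE)
  h <- attr(fit, "history")
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
})

test_that("stratified folds partition subjects without leakage", {
  ids <- sprintf("S%02d", 1:16)
  ahi <- c(rep(2, 4), rep(8, 4), rep(20, 4), rep(40, 4))
  plan <- make_folds(ids, ahi, seed = 5)
  # 4 per stratum: each fold holds exactly one subject per stratum
  for (k in 1:4) {
    test_strata <- severity_class(ahi[match(plan[[k]]$test, ids)])
    expect_equal(as.vector(table(test_strata)), c(1, 1, 1, 1))
    roles <- c(plan[[k]]$test, plan[[k]]$train, plan[[k]]$val)
    expect_equal(sort(roles), sort(ids))     # every subject exactly once
    expect_equal(anyDuplicated(roles), 0L)   # no subject in two roles
  }
  tests <- unlist(lapply(plan, `[[`, "test"))
  expect_equal(sort(tests), sort(ids))       # test sets partition cohort

  plan2 <- make_folds(ids, ahi, seed = 5)
  expect_identical(plan, plan2)
  expect_error(make_folds(ids[1:7], ahi[1:7], seed = 1), "at least 8")
})

test_that("threshold selection matches a brute-force grid search", {
  # two validation subjects built from labels, with synthetic predictions
  st <- bind_segments(list(
    local({
      s <- subset_segments(short_store(), 1:10)
      s$subject_id <- rep("VA", 10)
      s
    }),
    local({
      s <- subset_segments(short_store(), 1:8)
      s$subject_id <- rep("VB", 8)
      s
    })))
  set.seed(21)
  noisy <- function(y) pmin(pmax(y * 0.6 + 0.2 + rnorm(length(y), 0, 0.15),
                                 1e-4), 1 - 1e-4)
  pred <- list(p_event = matrix(noisy(st$y_event), nrow(st$y_event)),
               p_sleep = matrix(noisy(st$y_sleep), nrow(st$y_sleep)))
  model <- build_model(tiny_hyper(), seed = 1)  # only single_task flag used
  thr <- select_thresholds(model, st, pred = pred)

  # brute force over the same grid, re-deriving both F1 curves
  grid <- seq(0.01, 0.99, by = 0.01)
  stitched <- function(sid, mat, rate) {
    sel <- st$subject_id == sid
    stitch_predictions(mat[sel, , drop = FALSE], st$start_s[sel], rate)
  }
  f1_sleep <- sapply(grid, function(th) {
    tp <- fp <- fn <- 0
    for (sid in c("VA", "VB")) {
      ps <- stitched(sid, pred$p_sleep, 1 / 30)
      ys <- stitched(sid, st$y_sleep, 1 / 30)
      p <- as.integer(ps$values[ps$center] >= th)
      y <- ys$values[ys$center]
      tp <- tp + sum(p & y); fp <- fp + sum(p & !y); fn <- fn + sum(!p & y)
    }
    2 * tp / (2 * tp + fp + fn)
  })
  expect_equal(thr$sleep, grid[which.max(f1_sleep)])
  expect_equal(thr$f1_sleep, max(f1_sleep))

  f1_event <- sapply(grid, function(th) {
    tp <- fp <- fn <- 0
    for (sid in c("VA", "VB")) {
      pe <- stitched(sid, pred$p_event, 1)
      ye <- stitched(sid, st$y_event, 1)
      ps <- stitched(sid, pred$p_sleep, 1 / 30)
      bin <- binarize_and_mask(ps$values, pe$values,
                               list(sleep = thr$sleep, event = th))
      m <- oracle_match(merge_events(bin$event_binary, pe$t0_s),
                        oracle_merge(ye$values, ye$t0_s))
      tp <- tp + m$TP; fp <- fp + m$FP; fn <- fn + m$FN
    }
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  })
  expect_equal(thr$event, grid[which.max(f1_event)])
})

test_that("perfect separation resolves threshold ties toward the lowest value", {
  s <- subset_segments(short_store(), 1:6)
  s$subject_id <- rep("VT", 6)
  s$y_sleep[] <- 1L    # all-sleep night so wake masking cannot interfere
  expect_gt(sum(s$y_event), 0)
  p_sleep <- matrix(0.9, nrow(s$y_sleep), ncol(s$y_sleep))
  p_event <- matrix(ifelse(s$y_event == 1, 0.95, 0.05), nrow(s$y_event))
  model <- build_model(tiny_hyper(), seed = 1)
  thr <- select_thresholds(model, s,
                           pred = list(p_event = p_event,
                                       p_sleep = p_sleep))
  # every threshold up to 0.9 classifies all epochs as sleep (F1 = 1), so
  # the tie-break returns the lowest grid value; events separate at
  # 0.05/0.95, so the first grid value above 0.05 wins
  expect_equal(thr$sleep, 0.01)
  expect_equal(thr$f1_sleep, 1)
  expect_equal(thr$event, 0.06)
  expect_equal(thr$f1_event, 1)
})

test_that("training refuses stores that share subjects", {
  st <- short_store()
  m <- build_model(tiny_hyper(), seed = 1)
  expect_error(train_sdb_net(m, st, st, epochs = 1), "share subjects")
})
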