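# Cohort-level cross-validated evaluation: the workflow of the method.
# One fold is held out per iteration; the remaining subjects are split
# 75/25 into training and validation per severity stratum; thresholds and
# early stopping see only validation subjects; test-set predictions from
# all iterations are pooled into one report.

subject_metrics_row <- function(np, record, iteration) {
  ctr <- np$ref_sleep$center
  em <- if (!is.null(np$sleep_binary))
    epoch_metrics(np$sleep_binary[ctr], np$ref_sleep$values[ctr])
  else NULL
  ref_ev <- merge_events(np$ref_event$values, np$ref_event$t0_s)
  mt <- match_events(np$events_est, ref_ev)
  se_ref <- record$tst_ref_h /
    ((record$lights_on_s - record$lights_off_s) / 3600)
  data.frame(
    subject_id = np$subject_id, iteration = iteration,
    tst_ref_h = record$tst_ref_h, tst_est_h = np$tst_est_h,
    se_ref = se_ref,
    ahi_ref = record$ahi_ref, ahi_est = as.numeric(np$ahi_est),
    rei_est = np$rei_est,
    severity_ref = as.character(severity_class(record$ahi_ref)),
    severity_est = if (is.finite(np$ahi_est))
      as.character(severity_class(as.numeric(np$ahi_est)))
    else NA_character_,
    kappa = if (!is.null(em)) as.numeric(em$kappa) else NA_real_,
    f1_sleep = if (!is.null(em)) em$sleep$f1 else NA_real_,
    f1_wake = if (!is.null(em)) em$wake$f1 else NA_real_,
    sens_sleep = if (!is.null(em)) em$sleep$sensitivity else NA_real_,
    spec_sleep = if (!is.null(em)) em$sleep$specificity else NA_real_,
    event_tp = mt$TP, event_fp = mt$FP, event_fn = mt$FN,
    stringsAsFactors = FALSE)
}

pool_report <- function(per_subject, center_pairs,
                        zones = nbl_zones_default()) {
  ps <- per_subject
  ok <- is.finite(ps$ahi_est)
  pooled <- list()
  if (length(center_pairs$pred)) {
    em <- epoch_metrics(center_pairs$pred, center_pairs$ref)
    pooled$sleep_wake <- list(kappa = as.numeric(em$kappa),
                              f1_sleep = em$sleep$f1,
                              f1_wake = em$wake$f1,
                              sens_sleep = em$sleep$sensitivity,
                              spec_sleep = em$sleep$specificity,
                              sens_wake = em$wake$sensitivity,
                              spec_wake = em$wake$specificity,
                              confusion = em$confusion)
  }
  tp <- sum(ps$event_tp); fp <- sum(ps$event_fp); fn <- sum(ps$event_fn)
  pooled$events <- list(
    TP = tp, FP = fp, FN = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn)
    else NA_real_)
  if (sum(!is.na(ps$tst_est_h)) >= 3) {
    ba <- bland_altman(ps$tst_ref_h, ps$tst_est_h)
    pooled$tst <- c(ba, list(
      spearman_r = as.numeric(spearman_r(ps$tst_ref_h, ps$tst_est_h)),
      mae = mae(ps$tst_ref_h, ps$tst_est_h)))
  }
  if (sum(ok) >= 3) {
    ba <- bland_altman(ps$ahi_ref[ok], ps$ahi_est[ok])
    pooled$ahi <- c(ba, list(
      spearman_r = as.numeric(spearman_r(ps$ahi_ref[ok], ps$ahi_est[ok])),
      mae = mae(ps$ahi_ref[ok], ps$ahi_est[ok])))
    pooled$severity <- list(
      plain = severity_confusion(ps$ahi_ref[ok], ps$ahi_est[ok],
                                 nbl = FALSE, zones = zones),
      nbl = severity_confusion(ps$ahi_ref[ok], ps$ahi_est[ok],
                               nbl = TRUE, zones = zones))
  }
  pooled
}

#' Cross-validated evaluation of the multi-task pipeline on a cohort
#'
#' Runs the full workflow on a list of subject records: preprocessing and
#' segmentation, a severity-stratified fold plan, per-iteration training
#' with early stopping, validation-based threshold selection, whole-night
#' prediction of the held-out subjects, and pooling of all test-set
#' results into one report. Optionally trains the single-task
#' (event-only) comparison model on the same fold plan; its detected
#' events over time in bed provide `rei_est`.
#'
#' @param cohort list of `sdb_record`s (e.g. [simulate_cohort()]).
#' @param hyper an [sdb_hyper()].
#' @param seed seed governing folds, initialization and shuffling.
#' @param iterations which CV iterations to run (default all 4).
#' @param epochs maximum training epochs per iteration.
#' @param compare_single_task also fit the single-task model?
#' @param stores optional precomputed list of per-subject
#'   `segment_store`s (skips preprocessing).
#' @param verbose print progress?
#' @param ... further arguments to [train_sdb_net()].
#' @return Object of class `sdb_eval`: `per_subject` data frame, `pooled`
#'   metric list, `plan`, `thresholds` and training histories.
#' @export
sdb_cv <- function(cohort, hyper = sdb_hyper(), seed = 1L,
                   iterations = NULL, epochs = 200L,
                   compare_single_task = FALSE, stores = NULL,
                   verbose = FALSE, ...) {
  ids <- vapply(cohort, `[[`, character(1), "subject_id")
  names(cohort) <- ids
  ahi_ref <- vapply(cohort, `[[`, numeric(1), "ahi_ref")
  if (is.null(stores)) {
    if (verbose) message("preprocessing and segmenting ", length(ids),
                         " records")
    stores <- lapply(cohort, segment_record)
  }
  names(stores) <- ids
  plan <- make_folds(ids, ahi_ref, seed = seed)
  if (is.null(iterations)) iterations <- seq_along(plan)

  rows <- list()
  thresholds <- list()
  histories <- list()
  center_pairs <- list(pred = integer(0), ref = integer(0))

  for (k in iterations) {
    it <- plan[[k]]
    if (verbose) message("iteration ", k, ": training on ",
                         length(it$train), " subjects")
    train_store <- bind_segments(stores[it$train])
    val_store <- bind_segments(stores[it$val])
    model <- build_model(hyper, seed = derive_seed(seed, k))
    model <- train_sdb_net(model, train_store, val_store, epochs = epochs,
                           seed = derive_seed(seed, 100L + k),
                           verbose = verbose, ...)
    thr <- select_thresholds(model, val_store)
    thresholds[[k]] <- thr
    histories[[k]] <- attr(model, "history")

    single <- NULL
    if (compare_single_task) {
      if (verbose) message("iteration ", k, ": single-task comparison")
      single <- build_single_task_model(hyper, seed = derive_seed(seed, k))
      single <- train_sdb_net(single, train_store, val_store,
                              epochs = epochs,
                              seed = derive_seed(seed, 200L + k),
                              verbose = verbose, ...)
      thr_s <- select_thresholds(single, val_store)
    }

    for (sid in it$test) {
      np <- predict_night(model, stores[[sid]],
                          list(sleep = thr$sleep, event = thr$event))
      row <- subject_metrics_row(np, cohort[[sid]], k)
      if (compare_single_task) {
        np_s <- predict_night(single, stores[[sid]],
                              list(sleep = NA_real_, event = thr_s$event))
        row$rei_est <- np_s$rei_est
      }
      rows[[sid]] <- row
      ctr <- np$ref_sleep$center
      center_pairs$pred <- c(center_pairs$pred, np$sleep_binary[ctr])
      center_pairs$ref <- c(center_pairs$ref, np$ref_sleep$values[ctr])
    }
  }
  per_subject <- do.call(rbind, rows)
  rownames(per_subject) <- NULL
  structure(list(per_subject = per_subject,
                 pooled = pool_report(per_subject, center_pairs),
                 plan = plan, thresholds = thresholds,
                 histories = histories, seed = seed),
            class = "sdb_eval")
}

#' @export
print.sdb_eval <- function(x, ...) {
  cat("Cross-validated SDB pipeline evaluation:",
      nrow(x$per_subject), "test subjects\n")
  p <- x$pooled
  if (!is.null(p$sleep_wake))
    cat(sprintf("  sleep-wake: kappa %.3f, F1(sleep) %.3f, F1(wake) %.3f\n",
                p$sleep_wake$kappa, p$sleep_wake$f1_sleep,
                p$sleep_wake$f1_wake))
  cat(sprintf("  events (pooled): sens %.3f, prec %.3f, F1 %.3f\n",
              p$events$sensitivity, p$events$precision, p$events$f1))
  if (!is.null(p$tst))
    cat(sprintf("  TST: bias %+.2f h, LoA [%.2f, %.2f], R %.3f, MAE %.3f h\n",
                p$tst$bias, p$tst$loa_low, p$tst$loa_high,
                p$tst$spearman_r, p$tst$mae))
  if (!is.null(p$ahi))
    cat(sprintf("  AHI: bias %+.2f, LoA [%.2f, %.2f], R %.3f, MAE %.2f\n",
                p$ahi$bias, p$ahi$loa_low, p$ahi$loa_high,
                p$ahi$spearman_r, p$ahi$mae))
  if (!is.null(p$severity))
    cat(sprintf("  severity: accuracy %.3f (kappa %.2f); NBL %.3f (%.2f)\n",
                p$severity$plain$accuracy, p$severity$plain$kappa,
                p$severity$nbl$accuracy, p$severity$nbl$kappa))
  invisible(x)
}

#' @export
summary.sdb_eval <- function(object, ...) {
  print(object)
  cat("\nPer-subject summary:\n")
  print(summary(object$per_subject[, c("tst_ref_h", "tst_est_h",
                                       "ahi_ref", "ahi_est", "kappa")]))
  invisible(object)
}

#' Run the full pipeline and write artifacts to disk
#'
#' Orchestrates simulate -> segment -> cross-validated train/evaluate and
#' writes records, fold plan, per-iteration thresholds, the evaluation
#' report and the resolved configuration into `out_dir`.
#'
#' @param out_dir output directory.
#' @param n_subjects cohort size.
#' @param sim base [sim_config()].
#' @param hyper an [sdb_hyper()].
#' @param seed master seed.
#' @param epochs training-epoch cap per iteration.
#' @param iterations CV iterations to run (default all).
#' @param compare_single_task also run the single-task comparison.
#' @param write_records write each simulated record as JSON?
#' @param verbose print progress?
#' @param ... passed to [train_sdb_net()].
#' @return The `sdb_eval` report, invisibly.
#' @export
run_pipeline <- function(out_dir, n_subjects = 16L, sim = sim_config(),
                         hyper = sdb_hyper(), seed = 1L, epochs = 200L,
                         iterations = NULL, compare_single_task = FALSE,
                         write_records = FALSE, verbose = TRUE, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(n_subjects, sim, seed = seed)
  if (write_records) {
    rec_dir <- file.path(out_dir, "records")
    dir.create(rec_dir, showWarnings = FALSE)
    for (r in cohort)
      write_record(r, file.path(rec_dir, paste0(r$subject_id, ".json")))
  }
  report <- sdb_cv(cohort, hyper = hyper, seed = seed, epochs = epochs,
                   iterations = iterations,
                   compare_single_task = compare_single_task,
                   verbose = verbose, ...)
  save_report(report, file.path(out_dir, "report"))
  jsonlite::write_json(
    list(n_subjects = n_subjects, seed = seed, epochs = epochs,
         sim = unclass(sim), hyper = unclass(hyper),
         compare_single_task = compare_single_task,
         package_version = as.character(utils::packageVersion("cardiosleep"))),
    file.path(out_dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' Desk-scale parameter-recovery experiment
#'
#' Simulates a 40-subject synthetic cohort with strong event signatures,
#' trains the reduced multi-task model on the first cross-validation
#' iteration and evaluates its held-out fold: the canonical end-to-end
#' check that the pipeline recovers known sleep-wake structure and AHI
#' from raw synthetic records. Problem sizes (4 h in bed, 6-unit GRUs,
#' 25-epoch cap, one iteration) are the package's desk-scale experiment
#' conditions; see the methods vignette.
#'
#' @param seed master seed for simulation, folds and training.
#' @param n_subjects cohort size.
#' @param tib_hours time in bed per subject (h).
#' @param epochs training-epoch cap per fold.
#' @param iterations CV iterations to run.
#' @param verbose print progress?
#' @return The `sdb_eval` report of the held-out subjects.
#' @export
sdb_recovery_experiment <- function(seed = 1L, n_subjects = 40L,
                                    tib_hours = 4, epochs = 25L,
                                    iterations = 1L, verbose = FALSE) {
  cohort <- simulate_cohort(n_subjects,
                            sim_config_strong(tib_hours = tib_hours),
                            seed = derive_seed(seed, 1L))
  hyper <- sdb_hyper(gru_units = c(6L, 6L, 6L),
                     conv_filters = c(6L, 6L, 6L),
                     dense_units = 16L, dropout = 0.1)
  sdb_cv(cohort, hyper = hyper, seed = derive_seed(seed, 2L),
         iterations = iterations, epochs = epochs, verbose = verbose)
}
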