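# ---- Adam optimizer over the model's parameter tree -------------------

stack_names <- function(model) {
  c("trunk", "event_head", if (!model$single_task) "sleep_head")
}

adam_init <- function(model) {
  st <- list(t = 0, m = list(), v = list())
  for (s in stack_names(model)) {
    st$m[[s]] <- lapply(model[[s]], function(l)
      lapply(l$params, function(p) array(0, dim(p) %||% length(p))))
    st$v[[s]] <- st$m[[s]]
  }
  st
}

# Weight decay is applied to every parameter; the kernel L2 penalty (the
# model's `l2` hyperparameter) additionally hits weight matrices (names
# starting with W or U), mirroring "kernel regularization" on top of the
# optimizer's weight decay.
adam_step <- function(model, grads, state, lr = 1e-3, wd = 1e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  l2 <- model$hyper$l2
  for (s in stack_names(model)) {
    for (i in seq_along(model[[s]])) {
      pn <- names(model[[s]][[i]]$params)
      for (nm in pn) {
        g <- grads[[s]][[i]][[nm]]
        if (is.null(g)) next
        p <- model[[s]][[i]]$params[[nm]]
        g <- g + wd * p
        if (l2 > 0 && substr(nm, 1, 1) %in% c("W", "U")) g <- g + l2 * p
        m <- beta1 * state$m[[s]][[i]][[nm]] + (1 - beta1) * g
        v <- beta2 * state$v[[s]][[i]][[nm]] + (1 - beta2) * g * g
        state$m[[s]][[i]][[nm]] <- m
        state$v[[s]][[i]][[nm]] <- v
        model[[s]][[i]]$params[[nm]] <- p - lr * (m / bc1) /
          (sqrt(v / bc2) + eps)
      }
    }
  }
  list(model = model, state = state)
}

# One forward + backward pass on a batch; returns loss, gradients and the
# model with refreshed batch-norm buffers.
train_batch <- function(model, X, y_event, y_sleep, event_weight = 10) {
  fw <- net_forward(model, X, train = TRUE, keep_cache = TRUE)
  b <- dim(X)[1L]
  if (model$single_task) {
    ls <- multitask_loss(fw$p_event, y_event, event_weight = event_weight)
  } else {
    ls <- multitask_loss(fw$p_event, y_event, fw$p_sleep, y_sleep,
                         event_weight = event_weight)
  }
  if (!is.finite(ls$loss))
    stop("non-finite training loss; p_event range [",
         paste(signif(range(fw$p_event), 3), collapse = ", "), "]")
  dz_e <- array(ls$dz_event, c(b, 1L, ncol(y_event)))
  bk_e <- back_stack(fw$cache$event$layers, fw$cache$event$caches, dz_e)
  d_trunk <- bk_e$dx
  grads <- list(event_head = bk_e$grads)
  if (!model$single_task) {
    dz_s <- array(ls$dz_sleep, c(b, 1L, ncol(y_sleep)))
    bk_s <- back_stack(fw$cache$sleep$layers, fw$cache$sleep$caches, dz_s)
    d_trunk <- d_trunk + bk_s$dx
    grads$sleep_head <- bk_s$grads
  }
  bk_t <- back_stack(fw$cache$trunk$layers, fw$cache$trunk$caches, d_trunk)
  grads$trunk <- bk_t$grads
  # keep refreshed BN running statistics
  model$trunk <- fw$cache$trunk$layers
  model$event_head <- fw$cache$event$layers
  if (!model$single_task) model$sleep_head <- fw$cache$sleep$layers
  list(model = model, grads = grads, loss = ls$loss)
}

# Evaluation-mode loss over a store, in batches.
eval_loss <- function(model, store, batch_size = 256L, event_weight = 10) {
  n <- dim(store$X)[1L]
  tot <- 0
  for (ix in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    fw <- net_forward(model, store$X[ix, , , drop = FALSE], train = FALSE,
                      keep_cache = FALSE)
    ls <- if (model$single_task)
      multitask_loss(fw$p_event, store$y_event[ix, , drop = FALSE],
                     event_weight = event_weight)
    else
      multitask_loss(fw$p_event, store$y_event[ix, , drop = FALSE],
                     fw$p_sleep, store$y_sleep[ix, , drop = FALSE],
                     event_weight = event_weight)
    tot <- tot + ls$loss * length(ix)
  }
  tot / n
}

#' Early-stopping bookkeeping
#'
#' Pure form of the stopping rule: training stops after the first epoch at
#' which the validation loss has not decreased for `patience` consecutive
#' epochs; the returned best epoch is the one with the lowest validation
#' loss.
#'
#' @param val_losses numeric vector of per-epoch validation losses.
#' @param patience epochs without improvement tolerated.
#' @return List: `stop_epoch` (NA if never triggered), `best_epoch`.
#' @export
early_stop_trace <- function(val_losses, patience = 10L) {
  best <- Inf
  best_epoch <- NA_integer_
  stall <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]
      best_epoch <- e
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience)
        return(list(stop_epoch = e, best_epoch = best_epoch))
    }
  }
  list(stop_epoch = NA_integer_, best_epoch = best_epoch)
}

#' Train the multi-task network
#'
#' Minibatch training with the Adam optimizer (learning rate 0.001, weight
#' decay 0.0001, batch size 128), weighted binary cross-entropy for the
#' event head (weight 10 for event seconds, 1 for normal breathing), plain
#' binary cross-entropy for the sleep head, total loss the sum of the two.
#' Training stops when the validation loss has not decreased for
#' `patience` (10) consecutive epochs, and the weights from the best
#' validation epoch are returned.
#'
#' @param model an `sdb_net` from [build_model()].
#' @param train_store,val_store `segment_store`s with disjoint subjects.
#' @param epochs maximum epoch cap.
#' @param batch_size minibatch size.
#' @param lr,weight_decay Adam settings.
#' @param patience early-stopping patience in epochs.
#' @param event_weight per-sample weight of event seconds.
#' @param seed seed for shuffling and dropout.
#' @param check_disjoint require disjoint train/validation subject sets
#'   (disable only for deliberate overfitting diagnostics).
#' @param verbose print per-epoch losses?
#' @return The trained `sdb_net` with a `history` attribute (data frame of
#'   epoch, train and validation loss) and a `best_epoch` attribute.
#' @export
train_sdb_net <- function(model, train_store, val_store,
                          epochs = 200L, batch_size = 128L,
                          lr = 1e-3, weight_decay = 1e-4,
                          patience = 10L, event_weight = 10,
                          seed = 1L, check_disjoint = TRUE,
                          verbose = FALSE) {
  stopifnot(inherits(model, "sdb_net"))
  if (check_disjoint &&
      length(intersect(unique(train_store$subject_id),
                       unique(val_store$subject_id))) > 0)
    stop("training and validation stores share subjects")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))

  n <- dim(train_store$X)[1L]
  state <- adam_init(model)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  best_val <- Inf
  best_model <- model
  best_epoch <- 0L
  stall <- 0L

  for (e in seq_len(epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (ix in split(ord, ceiling(seq_along(ord) / batch_size))) {
      step <- train_batch(model,
                          train_store$X[ix, , , drop = FALSE],
                          train_store$y_event[ix, , drop = FALSE],
                          train_store$y_sleep[ix, , drop = FALSE],
                          event_weight)
      upd <- adam_step(step$model, step$grads, state, lr = lr,
                       wd = weight_decay)
      model <- upd$model
      state <- upd$state
      tot <- tot + step$loss * length(ix)
    }
    vl <- eval_loss(model, val_store, event_weight = event_weight)
    hist <- rbind(hist, data.frame(epoch = e, train_loss = tot / n,
                                   val_loss = vl))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f", e, tot / n, vl))
    if (vl < best_val) {
      best_val <- vl
      best_model <- model
      best_epoch <- e
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  attr(best_model, "history") <- hist
  attr(best_model, "best_epoch") <- best_epoch
  best_model
}

# ---- severity-stratified fourfold cross-validation --------------------

#' Severity-stratified cross-validation fold plan
#'
#' Subjects are stratified by SDB severity class of their reference AHI
#' and each stratum is randomly split into `n_folds` quarters; one quarter
#' per stratum forms each fold. For every iteration the remaining folds
#' are re-pooled, re-stratified and split 75%/25% into training and
#' validation subjects. All assignments are subject-exclusive.
#'
#' @param subjects character vector of subject ids.
#' @param ahi_ref their reference AHI values.
#' @param seed integer seed (the plan is deterministic under it).
#' @param n_folds number of folds (default 4).
#' @param val_frac validation fraction of each non-test stratum.
#' @return Object of class `fold_plan`: a list with one element per
#'   iteration, each holding `test`, `train`, `val` subject-id vectors.
#' @export
make_folds <- function(subjects, ahi_ref, seed = 1L, n_folds = 4L,
                       val_frac = 0.25) {
  stopifnot(length(subjects) == length(ahi_ref),
            !anyDuplicated(subjects))
  if (length(subjects) < 8)
    stop("need at least 8 subjects for a stratified fold plan")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))

  strata <- severity_class(ahi_ref)
  if (any(table(strata) < n_folds))
    warning("some severity strata have fewer subjects than folds")
  fold_of <- integer(length(subjects))
  for (s in levels(strata)) {
    idx <- which(strata == s)
    if (!length(idx)) next
    idx <- idx[sample.int(length(idx))]
    fold_of[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  plan <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    test <- subjects[fold_of == k]
    pool <- which(fold_of != k)
    train <- character(0)
    val <- character(0)
    for (s in levels(strata)) {
      idx <- pool[strata[pool] == s]
      if (!length(idx)) next
      idx <- idx[sample.int(length(idx))]
      n_val <- max(1L, round(val_frac * length(idx)))
      if (n_val >= length(idx)) n_val <- length(idx) - 1L
      val <- c(val, subjects[idx[seq_len(n_val)]])
      train <- c(train, subjects[idx[-seq_len(n_val)]])
    }
    plan[[k]] <- list(test = test, train = train, val = val)
  }
  structure(plan, class = "fold_plan", seed = as.integer(seed))
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("Stratified CV plan,", length(x), "iterations\n")
  for (k in seq_along(x))
    cat(sprintf("  iter %d: %d train / %d val / %d test\n", k,
                length(x[[k]]$train), length(x[[k]]$val),
                length(x[[k]]$test)))
  invisible(x)
}

# ---- validation-based decision thresholds -----------------------------

f1_binary <- function(pred, ref) {
  tp <- sum(pred == 1L & ref == 1L)
  fp <- sum(pred == 1L & ref == 0L)
  fn <- sum(pred == 0L & ref == 1L)
  if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
}

#' Select decision thresholds on validation data
#'
#' Grid search over 0.01 ... 0.99 (step 0.01). The sleep threshold
#' maximizes epoch-level F1 with sleep as positive class over the
#' center-covered epochs of the stitched validation nights; the event
#' threshold then maximizes event-level F1 (greedy one-to-one matching of
#' merged events against reference events) after wake masking with the
#' already-chosen sleep threshold. Ties break toward the lowest threshold.
#'
#' @param model a trained `sdb_net`.
#' @param val_store `segment_store` of the validation subjects.
#' @param grid candidate thresholds.
#' @param pred optional precomputed evaluation-mode predictions (a list
#'   with `p_event` and `p_sleep` as returned by `predict`); when `NULL`
#'   they are computed from `model`.
#' @return List of class `sdb_thresholds`: `sleep`, `event`, plus the
#'   achieved `f1_sleep` and `f1_event`.
#' @export
select_thresholds <- function(model, val_store,
                              grid = seq(0.01, 0.99, by = 0.01),
                              pred = NULL) {
  pr <- if (is.null(pred)) predict(model, val_store) else pred
  subjects <- unique(val_store$subject_id)
  nights <- lapply(subjects, function(sid) {
    sel <- val_store$subject_id == sid
    st <- subset_segments(val_store, sel)
    o <- order(st$start_s)
    p_sl <- NULL
    y_sl <- NULL
    if (!model$single_task) {
      p_sl <- stitch_predictions(
        pr$p_sleep[sel, , drop = FALSE][o, , drop = FALSE],
        st$start_s[o], rate = 1 / EPOCH_S)
      y_sl <- stitch_predictions(st$y_sleep[o, , drop = FALSE],
                                 st$start_s[o], rate = 1 / EPOCH_S)
    }
    p_ev <- stitch_predictions(
      pr$p_event[sel, , drop = FALSE][o, , drop = FALSE],
      st$start_s[o], rate = 1)
    y_ev <- stitch_predictions(st$y_event[o, , drop = FALSE],
                               st$start_s[o], rate = 1)
    list(p_sl = p_sl, p_ev = p_ev, y_sl = y_sl, y_ev = y_ev)
  })

  if (!model$single_task) {
    y_all <- unlist(lapply(nights, function(nn)
      nn$y_sl$values[nn$y_sl$center]))
    p_all <- unlist(lapply(nights, function(nn)
      nn$p_sl$values[nn$p_sl$center]))
    if (!any(y_all == 1L))
      stop("validation set contains no sleep epochs")
    f1s <- vapply(grid, function(th)
      f1_binary(as.integer(p_all >= th), y_all), numeric(1))
    sleep_thr <- grid[which.max(f1s)]
    f1_sleep <- max(f1s)
  } else {
    sleep_thr <- NA_real_
    f1_sleep <- NA_real_
  }

  ref_events <- lapply(nights, function(nn)
    merge_events(nn$y_ev$values, nn$y_ev$t0_s))
  f1e <- vapply(grid, function(th) {
    tp <- fp <- fn <- 0L
    for (i in seq_along(nights)) {
      nn <- nights[[i]]
      if (model$single_task) {
        ev_bin <- as.integer(nn$p_ev$values >= th)
      } else {
        ev_bin <- binarize_and_mask(nn$p_sl$values, nn$p_ev$values,
                                    list(sleep = sleep_thr,
                                         event = th))$event_binary
      }
      det <- merge_events(ev_bin, nn$p_ev$t0_s)
      m <- match_events(det, ref_events[[i]])
      tp <- tp + m$TP
      fp <- fp + m$FP
      fn <- fn + m$FN
    }
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  event_thr <- grid[which.max(f1e)]

  structure(list(sleep = sleep_thr, event = event_thr,
                 f1_sleep = f1_sleep, f1_event = max(f1e)),
            class = "sdb_thresholds")
}
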