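#' Hyperparameters of the multi-task cardiorespiratory network
#'
#' The temporal pooling structure is fixed by the label geometry: the shared
#' trunk must downsample the 4 Hz input by a factor 4 (1200 samples to the
#' 300 one-second event labels) and the sleep head by a further factor 30
#' (300 seconds to ten 30-s epochs). Widths, kernel sizes and dropout are
#' free capacity knobs.
#'
#' @param gru_units integer vector of length 3: hidden units per direction
#'   for the two shared blocks and the event-head block.
#' @param conv_filters integer vector of length 3: filters of the three
#'   sleep-head convolution subblocks.
#' @param conv_kernel odd integer, temporal kernel length of those
#'   convolutions.
#' @param dense_units width of the hidden dense layer in each
#'   classification block.
#' @param dropout dropout probability used throughout.
#' @param pool_shared,pool_sleep temporal max-pool factors; their products
#'   must equal 4 and 30 respectively.
#' @param l2 kernel (weight-matrix) L2 penalty strength.
#' @return An object of class `sdb_hyper`.
#' @export
sdb_hyper <- function(gru_units = c(64L, 64L, 64L),
                      conv_filters = c(32L, 32L, 32L),
                      conv_kernel = 5L,
                      dense_units = 64L,
                      dropout = 0.2,
                      pool_shared = c(2L, 2L),
                      pool_sleep = c(5L, 3L, 2L),
                      l2 = 1e-4) {
  stopifnot(length(gru_units) == 3L, all(gru_units >= 1),
            length(conv_filters) == 3L, all(conv_filters >= 1),
            conv_kernel %% 2 == 1, dense_units >= 1,
            dropout >= 0, dropout < 1, l2 >= 0)
  if (prod(pool_shared) != 4L)
    stop("shared pool factors must multiply to 4 (1200 -> 300), got ",
         prod(pool_shared))
  if (prod(pool_sleep) != 30L)
    stop("sleep-head pool factors must multiply to 30 (300 -> 10), got ",
         prod(pool_sleep))
  structure(list(gru_units = as.integer(gru_units),
                 conv_filters = as.integer(conv_filters),
                 conv_kernel = as.integer(conv_kernel),
                 dense_units = as.integer(dense_units),
                 dropout = dropout,
                 pool_shared = as.integer(pool_shared),
                 pool_sleep = as.integer(pool_sleep),
                 l2 = l2),
            class = "sdb_hyper")
}

shared_block <- function(n_in, units, pool, dropout) {
  list(layer_bigru(n_in, units),
       layer_bigru(2L * units, units),
       layer_bn(2L * units),
       layer_pool(pool),
       layer_relu(),
       layer_dropout(dropout))
}

#' Build the multi-task SDB / sleep-wake network
#'
#' Constructs the shared-trunk, two-head architecture: two shared blocks of
#' stacked bidirectional GRUs (each with batch normalization, temporal
#' max-pooling, ReLU and dropout), an event head (two further bidirectional
#' GRU layers plus a dense ReLU / dense sigmoid classifier emitting one
#' probability per second) and a sleep head (three temporal-convolution
#' subblocks pooling down to epoch rate, plus the same classifier shape,
#' emitting one probability per 30-s epoch). Weights are initialized with
#' the Xavier uniform scheme.
#'
#' @param hyper an [sdb_hyper()] object.
#' @param seed integer seed controlling weight initialization.
#' @param single_task if `TRUE`, build the event-detection-only comparison
#'   model (shared trunk + event head, no sleep head).
#' @return An object of class `sdb_net`.
#' @export
build_model <- function(hyper = sdb_hyper(), seed = 1L, single_task = FALSE) {
  stopifnot(inherits(hyper, "sdb_hyper"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))

  g <- hyper$gru_units
  trunk <- c(shared_block(2L, g[1L], hyper$pool_shared[1L], hyper$dropout),
             shared_block(2L * g[1L], g[2L], hyper$pool_shared[2L],
                          hyper$dropout))
  trunk_out <- 2L * g[2L]

  event_head <- list(
    layer_bigru(trunk_out, g[3L]),
    layer_bigru(2L * g[3L], g[3L]),
    layer_bn(2L * g[3L]),
    layer_relu(),
    layer_dropout(hyper$dropout),
    layer_dense(2L * g[3L], hyper$dense_units, "relu"),
    layer_dense(hyper$dense_units, 1L, "linear"))

  sleep_head <- NULL
  if (!single_task) {
    cf <- hyper$conv_filters
    n_in <- c(trunk_out, cf[1L], cf[2L])
    sleep_head <- list()
    for (i in 1:3) {
      sleep_head <- c(sleep_head, list(
        layer_conv(n_in[i], cf[i], hyper$conv_kernel, "relu"),
        layer_bn(cf[i]),
        layer_pool(hyper$pool_sleep[i]),
        layer_dropout(hyper$dropout)))
    }
    sleep_head <- c(sleep_head, list(
      layer_dense(cf[3L], hyper$dense_units, "relu"),
      layer_dense(hyper$dense_units, 1L, "linear")))
  }

  structure(list(hyper = hyper, seed = as.integer(seed),
                 single_task = single_task,
                 trunk = trunk, event_head = event_head,
                 sleep_head = sleep_head),
            class = "sdb_net")
}

#' @rdname build_model
#' @export
build_single_task_model <- function(hyper = sdb_hyper(), seed = 1L) {
  build_model(hyper, seed, single_task = TRUE)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Forward pass. X is (batch, time, 2) as stored in segment stores; it is
# transposed to the internal (batch, features, time) layout. Returns
# sigmoid probabilities; logits and caches are kept when training.
net_forward <- function(model, X, train = FALSE, keep_cache = train) {
  stopifnot(length(dim(X)) == 3L, dim(X)[3L] == 2L)
  if (dim(X)[2L] %% (4L * prod(model$hyper$pool_sleep)) != 0)
    stop("input length ", dim(X)[2L],
         " is not divisible by the pooling structure")
  x <- aperm(X, c(1L, 3L, 2L))
  tr <- run_stack(model$trunk, x, train, keep_cache)
  ev <- run_stack(model$event_head, tr$out, train, keep_cache)
  p_event <- sigmoid(ev$out[, 1L, ])
  if (is.null(dim(p_event))) p_event <- matrix(p_event, nrow = dim(X)[1L])
  out <- list(p_event = p_event)
  sl <- NULL
  if (!model$single_task) {
    sl <- run_stack(model$sleep_head, tr$out, train, keep_cache)
    p_sleep <- sigmoid(sl$out[, 1L, ])
    if (is.null(dim(p_sleep))) p_sleep <- matrix(p_sleep, nrow = dim(X)[1L])
    out$p_sleep <- p_sleep
  }
  if (keep_cache) {
    out$cache <- list(trunk = tr, event = ev, sleep = sl)
  } else {
    # refreshed batch-norm buffers still matter in training mode
    model$trunk <- tr$layers
    model$event_head <- ev$layers
    if (!model$single_task) model$sleep_head <- sl$layers
  }
  out$model <- model
  out
}

#' Predict event and sleep probability tracks for input segments
#'
#' Runs the network in evaluation mode (dropout off, batch normalization
#' using running statistics).
#'
#' @param object a fitted or freshly built [build_model()] network.
#' @param newdata either a `(n, 1200, 2)` array or a segment store created
#'   by [make_segments()].
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return A list with `p_event` (`n x 300`) and, for multi-task models,
#'   `p_sleep` (`n x 10`).
#' @export
predict.sdb_net <- function(object, newdata, batch_size = 256L, ...) {
  X <- if (is.array(newdata)) newdata else newdata$X
  n <- dim(X)[1L]
  p_event <- NULL
  p_sleep <- NULL
  for (ix in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    fw <- net_forward(object, X[ix, , , drop = FALSE], train = FALSE,
                      keep_cache = FALSE)
    p_event <- rbind(p_event, fw$p_event)
    if (!object$single_task) p_sleep <- rbind(p_sleep, fw$p_sleep)
  }
  if (object$single_task) list(p_event = p_event)
  else list(p_event = p_event, p_sleep = p_sleep)
}

#' @export
print.sdb_net <- function(x, ...) {
  g <- x$hyper$gru_units
  cat(if (x$single_task) "Single-task" else "Multi-task",
      "cardiorespiratory SDB network\n")
  cat("  shared trunk : 2 blocks of 2 x BiGRU(", g[1L], ",", g[2L],
      "), pools ", paste(x$hyper$pool_shared, collapse = "x"),
      " (1200 -> 300)\n", sep = "")
  cat("  event head   : 2 x BiGRU(", g[3L], ") + dense -> 300 x 1 Hz\n",
      sep = "")
  if (!x$single_task)
    cat("  sleep head   : 3 conv subblocks (",
        paste(x$hyper$conv_filters, collapse = ","), "), pools ",
        paste(x$hyper$pool_sleep, collapse = "x"),
        " -> 10 x 1/30 Hz\n", sep = "")
  cat("  parameters   :", format(n_params(x), big.mark = ","), "\n")
  invisible(x)
}

#' Number of trainable parameters of a network
#' @param model an `sdb_net` object.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  stacks <- c(model$trunk, model$event_head, model$sleep_head)
  sum(vapply(stacks, function(l) sum(vapply(l$params, length, numeric(1))),
             numeric(1)))
}

# Weighted binary cross-entropy of both heads plus gradient w.r.t. logits.
# Event samples carry weight `event_weight` (default 10) against 1 for
# normal breathing; the sleep term is unweighted. Total loss is the sum of
# the two task losses.
multitask_loss <- function(p_event, y_event, p_sleep = NULL, y_sleep = NULL,
                           event_weight = 10) {
  eps <- 1e-12
  w <- 1 + (event_weight - 1) * y_event
  bce_e <- -(y_event * log(p_event + eps) +
               (1 - y_event) * log(1 - p_event + eps))
  n_e <- length(y_event)
  loss_e <- sum(w * bce_e) / n_e
  dz_event <- w * (p_event - y_event) / n_e
  out <- list(loss = loss_e, loss_event = loss_e, dz_event = dz_event)
  if (!is.null(p_sleep)) {
    bce_s <- -(y_sleep * log(p_sleep + eps) +
                 (1 - y_sleep) * log(1 - p_sleep + eps))
    n_s <- length(y_sleep)
    loss_s <- sum(bce_s) / n_s
    out$loss_sleep <- loss_s
    out$loss <- loss_e + loss_s
    out$dz_sleep <- (p_sleep - y_sleep) / n_s
  }
  out
}
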