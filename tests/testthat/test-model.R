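test_that("the forward pass honors the printed label geometry", {
  m <- build_model(tiny_hyper(), seed = 1)
  X <- array(rnorm(2 * 1200 * 2), c(2, 1200, 2))
  pr <- predict(m, X)
  expect_equal(dim(pr$p_event), c(2, 300))
  expect_equal(dim(pr$p_sleep), c(2, 10))
  expect_true(all(pr$p_event > 0 & pr$p_event < 1))
  expect_true(all(pr$p_sleep > 0 & pr$p_sleep < 1))
})

test_that("initialization and evaluation are deterministic", {
  a <- build_model(tiny_hyper(), seed = 42)
  b <- build_model(tiny_hyper(), seed = 42)
  expect_identical(a$trunk[[1]]$params$Wf, b$trunk[[1]]$params$Wf)
  expect_identical(a$sleep_head[[1]]$params$W, b$sleep_head[[1]]$params$W)
  X <- array(rnorm(1 * 1200 * 2), c(1, 1200, 2))
  expect_identical(predict(a, X), predict(a, X))
})

test_that("pooling structure violations are rejected at build time", {
  expect_error(sdb_hyper(pool_sleep = c(5, 3, 3)), "30")
  expect_error(sdb_hyper(pool_shared = c(2, 3)), "4")
})

test_that("intermediate temporal lengths divide as 1200-600-300 and 300-60-20-10", {
  m <- build_model(tiny_hyper(), seed = 3)
  x <- aperm(array(rnorm(1200 * 2), c(1, 1200, 2)), c(1, 3, 2))
  lens_trunk <- integer(0)
  for (l in m$trunk) {
    x <- layer_forward(l, x)$out
    lens_trunk <- c(lens_trunk, dim(x)[3])
  }
  expect_equal(unique(lens_trunk), c(1200, 600, 300))
  lens_sleep <- integer(0)
  y <- x
  for (l in m$sleep_head) {
    y <- layer_forward(l, y)$out
    lens_sleep <- c(lens_sleep, dim(y)[3])
  }
  expect_equal(unique(lens_sleep), c(300, 60, 20, 10))
})

test_that("the single-task variant shares the trunk but drops the sleep head", {
  m <- build_single_task_model(tiny_hyper(), seed = 2)
  full <- build_model(tiny_hyper(), seed = 2)
  expect_identical(m$trunk[[1]]$params$Wf, full$trunk[[1]]$params$Wf)
  X <- array(rnorm(1200 * 2), c(1, 1200, 2))
  pr <- predict(m, X)
  expect_named(pr, "p_event")
  expect_true(all(pr$p_event > 0 & pr$p_event < 1))
  expect_lt(n_params(m), n_params(full))
})

test_that("a batch of 128 segments passes through without shape errors", {
  m <- build_model(tiny_hyper(), seed = 4)
  X <- array(rnorm(128 * 1200 * 2, sd = 0.5), c(128, 1200, 2))
  pr <- predict(m, X)
  expect_equal(nrow(pr$p_event), 128)
})

test_that("analytic gradients agree with central finite differences", {
  hy <- sdb_hyper(gru_units = c(2, 2, 2), conv_filters = c(2, 2, 2),
                  dense_units = 3, dropout = 0)
  m <- build_model(hy, seed = 5)
  set.seed(8)
  # jitter all biases so no ReLU pre-activation sits exactly on its kink
  for (s in c("trunk", "event_head", "sleep_head"))
    for (i in seq_along(m[[s]]))
      for (nm in names(m[[s]][[i]]$params))
        if (substr(nm, 1, 1) == "b")
          m[[s]][[i]]$params[[nm]] <-
            m[[s]][[i]]$params[[nm]] +
            rnorm(length(m[[s]][[i]]$params[[nm]]), 0, 0.05)

  b <- 2; tt <- 120
  X <- array(rnorm(b * tt * 2), c(b, tt, 2))
  ye <- matrix(rbinom(b * tt / 4, 1, 0.3), b, tt / 4)
  ys <- matrix(rbinom(b * tt / 120, 1, 0.7), b, tt / 120)
  loss_at <- function(model) {
    fw <- net_forward(model, X, train = TRUE, keep_cache = FALSE)
    multitask_loss(fw$p_event, ye, fw$p_sleep, ys)$loss
  }
  step <- train_batch(m, X, ye, ys)
  eps <- 1e-6
  worst <- 0
  for (s in c("trunk", "event_head", "sleep_head")) {
    for (i in seq_along(m[[s]])) {
      for (nm in names(m[[s]][[i]]$params)) {
        p <- m[[s]][[i]]$params[[nm]]
        if (!length(p)) next
        for (k in sample(length(p), min(2, length(p)))) {
          mp <- m; mp[[s]][[i]]$params[[nm]][k] <- p[k] + eps
          mm <- m; mm[[s]][[i]]$params[[nm]][k] <- p[k] - eps
          fd <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
          an <- step$grads[[s]][[i]][[nm]][k]
          worst <- max(worst, abs(fd - an) / max(1e-6, abs(fd) + abs(an)))
        }
      }
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("gradient flows to both heads from the summed loss", {
  hy <- sdb_hyper(gru_units = c(2, 2, 2), conv_filters = c(2, 2, 2),
                  dense_units = 3, dropout = 0)
  m <- build_model(hy, seed = 6)
  set.seed(9)
  X <- array(rnorm(2 * 120 * 2), c(2, 120, 2))
  ye <- matrix(rbinom(60, 1, 0.3), 2, 30)
  ys <- matrix(rbinom(2, 1, 0.5), 2, 1)
  g <- train_batch(m, X, ye, ys)$grads
  gn <- function(gr) sum(unlist(lapply(gr, function(l)
    lapply(l, function(p) sum(abs(p))))))
  expect_gt(gn(g$event_head), 0)
  expect_gt(gn(g$sleep_head), 0)
  expect_gt(gn(g$trunk), 0)
})
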