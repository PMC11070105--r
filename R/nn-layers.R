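# Layer primitives for the multi-task network. Activations flow through the
# stack as 3-d arrays laid out (batch, features, time) so that the Rcpp GRU
# kernel and the R-side layers share one memory layout. Each layer is a plain
# list: list(type, params = <named arrays>, buffers = <running stats>, ...).
# `layer_forward()` returns the output plus the cache `layer_backward()`
# needs; gradients come back named exactly like `params` so the optimizer
# can walk them generically.

cube2mat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1L, 3L, 2L)), nrow = d[1L] * d[3L], ncol = d[2L])
}

mat2cube <- function(m, b, tt) {
  aperm(array(m, c(b, tt, ncol(m))), c(1L, 3L, 2L))
}

xavier_uniform <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  runif(n, -lim, lim)
}

# GRU weights are 3H wide with gate order [r | z | n]; Xavier limits are
# computed per gate block.
init_gru_mats <- function(n_in, h) {
  W <- matrix(0, n_in, 3L * h)
  U <- matrix(0, h, 3L * h)
  for (g in 0:2) {
    W[, g * h + seq_len(h)] <- xavier_uniform(n_in, h, n_in * h)
    U[, g * h + seq_len(h)] <- xavier_uniform(h, h, h * h)
  }
  list(W = W, U = U, b_ih = numeric(3L * h), b_hh = numeric(3L * h))
}

layer_bigru <- function(n_in, units) {
  fw <- init_gru_mats(n_in, units)
  bw <- init_gru_mats(n_in, units)
  list(type = "bigru", units = units, n_in = n_in,
       params = list(Wf = fw$W, Uf = fw$U, bif = fw$b_ih, bhf = fw$b_hh,
                     Wb = bw$W, Ub = bw$U, bib = bw$b_ih, bhb = bw$b_hh))
}

layer_bn <- function(n_feat, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", momentum = momentum, eps = eps,
       params = list(gamma = rep(1, n_feat), beta = rep(0, n_feat)),
       buffers = list(rm = rep(0, n_feat), rv = rep(1, n_feat)))
}

layer_pool <- function(k) list(type = "pool", k = k, params = list())
layer_relu <- function() list(type = "relu", params = list())
layer_dropout <- function(p) list(type = "dropout", p = p, params = list())

layer_dense <- function(n_in, n_out, act = c("relu", "linear")) {
  act <- match.arg(act)
  list(type = "dense", act = act,
       params = list(W = matrix(xavier_uniform(n_in, n_out, n_in * n_out),
                                n_in, n_out),
                     b = numeric(n_out)))
}

layer_conv <- function(n_in, filters, kernel, act = "relu") {
  stopifnot(kernel %% 2 == 1)
  W <- array(xavier_uniform(kernel * n_in, kernel * filters,
                            kernel * n_in * filters),
             c(kernel, n_in, filters))
  list(type = "conv", act = act, kernel = kernel,
       params = list(W = W, b = numeric(filters)))
}

layer_forward <- function(layer, x, train = FALSE, keep_cache = train) {
  switch(layer$type,
    bigru = {
      p <- layer$params
      ff <- cs_gru_forward(x, p$Wf, p$Uf, p$bif, p$bhf, FALSE, keep_cache)
      bb <- cs_gru_forward(x, p$Wb, p$Ub, p$bib, p$bhb, TRUE, keep_cache)
      h <- layer$units
      out <- array(0, c(dim(x)[1L], 2L * h, dim(x)[3L]))
      out[, seq_len(h), ] <- ff$h
      out[, h + seq_len(h), ] <- bb$h
      list(out = out, cache = list(x = x, ff = ff, bb = bb), layer = layer)
    },
    bn = {
      # feature-wise statistics over (batch, time) without transposing the
      # cube: per-(feature, slice) column means are pooled across slices,
      # and broadcasting uses length-(b*F) vectors recycled over time
      d <- dim(x)
      b <- d[1L]; nf <- d[2L]; tt <- d[3L]
      if (train) {
        mu <- rowMeans(matrix(.colMeans(x, b, nf * tt), nf, tt))
        ex2 <- rowMeans(matrix(.colMeans(x * x, b, nf * tt), nf, tt))
        v <- ex2 - mu * mu
        mom <- layer$momentum
        layer$buffers$rm <- (1 - mom) * layer$buffers$rm + mom * mu
        layer$buffers$rv <- (1 - mom) * layer$buffers$rv + mom * v
      } else {
        mu <- layer$buffers$rm
        v <- layer$buffers$rv
      }
      inv <- 1 / sqrt(v + layer$eps)
      xhat <- x * rep(inv, each = b) - rep(mu * inv, each = b)
      y <- xhat * rep(layer$params$gamma, each = b) +
        rep(layer$params$beta, each = b)
      list(out = y,
           cache = list(xhat = xhat, inv = inv, d = d, train = train),
           layer = layer)
    },
    pool = {
      k <- layer$k
      d <- dim(x)
      stopifnot(d[3L] %% k == 0)
      idx <- seq(1L, d[3L], by = k)
      y <- x[, , idx, drop = FALSE]
      arg <- array(1L, dim(y))
      if (k > 1L) for (j in 2:k) {
        cand <- x[, , idx + (j - 1L), drop = FALSE]
        upd <- cand > y
        y[upd] <- cand[upd]
        arg[upd] <- j
      }
      list(out = y, cache = list(arg = arg, k = k, d = d), layer = layer)
    },
    relu = {
      mask <- x > 0
      x[!mask] <- 0
      list(out = x, cache = list(mask = mask), layer = layer)
    },
    dropout = {
      if (train && layer$p > 0) {
        mask <- (runif(length(x)) >= layer$p) / (1 - layer$p)
        list(out = x * mask, cache = list(mask = mask), layer = layer)
      } else {
        list(out = x, cache = list(mask = NULL), layer = layer)
      }
    },
    dense = {
      d <- dim(x)
      m <- cube2mat(x)
      y <- sweep(m %*% layer$params$W, 2L, layer$params$b, "+")
      mask <- NULL
      if (layer$act == "relu") {
        mask <- y > 0
        y[!mask] <- 0
      }
      list(out = mat2cube(y, d[1L], d[3L]),
           cache = list(m = m, mask = mask, d = d), layer = layer)
    },
    conv = {
      d <- dim(x)
      k <- layer$kernel
      ctr <- (k + 1L) %/% 2L
      nf <- dim(layer$params$W)[3L]
      y <- array(0, c(d[1L], nf, d[3L]))
      for (j in seq_len(k)) {
        s <- j - ctr
        lo <- max(1L, 1L - s)
        hi <- min(d[3L], d[3L] - s)
        if (lo > hi) next
        tt <- seq.int(lo, hi)
        Wj <- matrix(layer$params$W[j, , ], nrow = d[2L], ncol = nf)
        contrib <- cube2mat(x[, , tt + s, drop = FALSE]) %*% Wj
        y[, , tt] <- y[, , tt, drop = FALSE] +
          mat2cube(contrib, d[1L], length(tt))
      }
      y <- sweep(y, 2L, layer$params$b, "+")
      mask <- NULL
      if (layer$act == "relu") {
        mask <- y > 0
        y[!mask] <- 0
      }
      list(out = y, cache = list(x = x, mask = mask, d = d), layer = layer)
    },
    stop("unknown layer type: ", layer$type)
  )
}

layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
    bigru = {
      h <- layer$units
      p <- layer$params
      df <- dout[, seq_len(h), , drop = FALSE]
      db <- dout[, h + seq_len(h), , drop = FALSE]
      ff <- cache$ff; bb <- cache$bb
      gf <- cs_gru_backward(df, cache$x, ff$h, ff$r, ff$z, ff$n, ff$hun,
                            p$Wf, p$Uf, FALSE)
      gb <- cs_gru_backward(db, cache$x, bb$h, bb$r, bb$z, bb$n, bb$hun,
                            p$Wb, p$Ub, TRUE)
      list(dx = gf$dX + gb$dX,
           grads = list(Wf = gf$dW, Uf = gf$dU, bif = drop(gf$db_ih),
                        bhf = drop(gf$db_hh),
                        Wb = gb$dW, Ub = gb$dU, bib = drop(gb$db_ih),
                        bhb = drop(gb$db_hh)))
    },
    bn = {
      stopifnot(cache$train)
      d <- cache$d
      b <- d[1L]; nf <- d[2L]; tt <- d[3L]
      n <- b * tt
      xhat <- cache$xhat
      dgamma <- rowSums(matrix(.colSums(dout * xhat, b, nf * tt), nf, tt))
      dbeta <- rowSums(matrix(.colSums(dout, b, nf * tt), nf, tt))
      g <- layer$params$gamma
      dx <- dout * rep(cache$inv * g, each = b) -
        rep(cache$inv * g * dbeta / n, each = b) -
        xhat * rep(cache$inv * g * dgamma / n, each = b)
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    pool = {
      k <- cache$k
      d <- cache$d
      dx <- array(0, d)
      idx <- seq(1L, d[3L], by = k)
      for (j in seq_len(k)) {
        sel <- cache$arg == j
        slab <- dout
        slab[!sel] <- 0
        dx[, , idx + (j - 1L)] <- slab
      }
      list(dx = dx, grads = list())
    },
    relu = {
      dout[!cache$mask] <- 0
      list(dx = dout, grads = list())
    },
    dropout = {
      if (!is.null(cache$mask)) dout <- dout * cache$mask
      list(dx = dout, grads = list())
    },
    dense = {
      d <- cache$d
      dy <- cube2mat(dout)
      if (!is.null(cache$mask)) dy[!cache$mask] <- 0
      list(dx = mat2cube(dy %*% t(layer$params$W), d[1L], d[3L]),
           grads = list(W = crossprod(cache$m, dy), b = colSums(dy)))
    },
    conv = {
      d <- cache$d
      k <- layer$kernel
      ctr <- (k + 1L) %/% 2L
      nf <- dim(layer$params$W)[3L]
      if (!is.null(cache$mask)) dout[!cache$mask] <- 0
      dW <- array(0, dim(layer$params$W))
      dx <- array(0, d)
      db <- colSums(cube2mat(dout))
      for (j in seq_len(k)) {
        s <- j - ctr
        lo <- max(1L, 1L - s)
        hi <- min(d[3L], d[3L] - s)
        if (lo > hi) next
        tt <- seq.int(lo, hi)
        Wj <- matrix(layer$params$W[j, , ], nrow = d[2L], ncol = nf)
        dym <- cube2mat(dout[, , tt, drop = FALSE])
        xm <- cube2mat(cache$x[, , tt + s, drop = FALSE])
        dW[j, , ] <- crossprod(xm, dym)
        dx[, , tt + s] <- dx[, , tt + s, drop = FALSE] +
          mat2cube(dym %*% t(Wj), d[1L], length(tt))
      }
      list(dx = dx, grads = list(W = dW, b = db))
    },
    stop("unknown layer type: ", layer$type)
  )
}

# Run a list of layers; returns final output, per-layer caches and layers
# with refreshed buffers (batch-norm running stats).
run_stack <- function(layers, x, train = FALSE, keep_cache = train) {
  caches <- if (keep_cache) vector("list", length(layers)) else NULL
  for (i in seq_along(layers)) {
    step <- layer_forward(layers[[i]], x, train = train,
                          keep_cache = keep_cache)
    x <- step$out
    layers[[i]] <- step$layer
    if (keep_cache) caches[[i]] <- step$cache
  }
  list(out = x, caches = caches, layers = layers)
}

# Back-propagate through a stack; returns dx and a list of gradient lists
# aligned with the layers.
back_stack <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    bk <- layer_backward(layers[[i]], caches[[i]], dout)
    dout <- bk$dx
    grads[[i]] <- bk$grads
  }
  list(dx = dout, grads = grads)
}
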