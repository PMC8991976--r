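# Minimal sequential neural-network engine: dense and 1D-convolution layers,
# ReLU, inverted dropout, batch normalisation, 1D max pooling, and the Adamax
# optimiser, with mean-squared-error, sigmoid-cross-entropy and
# softmax-cross-entropy heads. Tensors are base-R arrays: 2D (batch x
# features) for dense stacks, 3D (batch x length x channels) for conv
# stacks. Written in-package so the convolutional and dense architectures
# train on CPU with no external framework; correctness is checked against
# numerical gradients in the test suite.

.he_init <- function(n_in, n_out) {
  matrix(rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out)
}

nn_dense <- function(n_in, n_out, activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  list(type = "dense", n_in = n_in, n_out = n_out, activation = activation,
       W = .he_init(n_in, n_out), b = rep(0, n_out))
}

nn_dropout <- function(rate) list(type = "dropout", rate = rate)

nn_batchnorm <- function(dim, momentum = 0.99, eps = 1e-3) {
  list(type = "batchnorm", dim = dim, momentum = momentum, eps = eps,
       gamma = rep(1, dim), beta = rep(0, dim),
       run_mean = rep(0, dim), run_var = rep(1, dim))
}

nn_conv1d <- function(kernel, in_ch, out_ch) {
  list(type = "conv1d", kernel = kernel, in_ch = in_ch, out_ch = out_ch,
       W = .he_init(kernel * in_ch, out_ch), b = rep(0, out_ch))
}

nn_maxpool1d <- function(size = 2L) list(type = "maxpool", size = as.integer(size))

nn_flatten <- function() list(type = "flatten")

# reshape (B, L, C) -> (B*L, C); rows ordered batch-fastest
.to2d <- function(x) { d <- dim(x); dim(x) <- c(d[1] * d[2], d[3]); x }

.im2col <- function(a, kernel) {
  d <- dim(a)  # B, L, Cin
  lo <- d[2] - kernel + 1L
  x2 <- matrix(0, d[1] * lo, kernel * d[3])
  for (ki in seq_len(kernel)) {
    sl <- a[, ki:(ki + lo - 1L), , drop = FALSE]
    dim(sl) <- c(d[1] * lo, d[3])
    x2[, ((ki - 1L) * d[3] + 1L):(ki * d[3])] <- sl
  }
  x2
}

.layer_forward <- function(layer, x, training) {
  cache <- NULL
  out <- switch(layer$type,
    dense = {
      z <- sweep(x %*% layer$W, 2, layer$b, "+")
      a <- if (layer$activation == "relu") pmax(z, 0) else z
      cache <- list(x = x, z = z)
      a
    },
    dropout = {
      if (training && layer$rate > 0) {
        mask <- array(rbinom(length(x), 1, 1 - layer$rate) / (1 - layer$rate), dim(x))
        cache <- list(mask = mask)
        x * mask
      } else x
    },
    batchnorm = {
      d <- dim(x)
      x2 <- if (length(d) == 3) .to2d(x) else x
      if (training) {
        mu <- colMeans(x2)
        v <- colMeans(sweep(x2, 2, mu)^2)
        layer$run_mean <- layer$momentum * layer$run_mean + (1 - layer$momentum) * mu
        layer$run_var <- layer$momentum * layer$run_var + (1 - layer$momentum) * v
      } else {
        mu <- layer$run_mean; v <- layer$run_var
      }
      xhat <- sweep(sweep(x2, 2, mu), 2, sqrt(v + layer$eps), "/")
      y2 <- sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+")
      cache <- list(xhat = xhat, v = v, shape = d)
      if (length(d) == 3) dim(y2) <- d
      y2
    },
    conv1d = {
      x2 <- .im2col(x, layer$kernel)
      z2 <- sweep(x2 %*% layer$W, 2, layer$b, "+")
      a2 <- pmax(z2, 0)
      d <- dim(x)
      lo <- d[2] - layer$kernel + 1L
      cache <- list(x2 = x2, z2 = z2, in_shape = d, lo = lo)
      dim(a2) <- c(d[1], lo, layer$out_ch)
      a2
    },
    maxpool = {
      d <- dim(x); s <- layer$size
      lo <- d[2] %/% s
      y <- array(-Inf, c(d[1], lo, d[3]))
      amax <- array(1L, c(d[1], lo, d[3]))
      for (si in seq_len(s)) {
        sl <- x[, seq(si, by = s, length.out = lo), , drop = FALSE]
        upd <- sl > y
        amax[upd] <- si
        y[upd] <- sl[upd]
      }
      cache <- list(amax = amax, in_shape = d, lo = lo)
      y
    },
    flatten = {
      d <- dim(x)
      cache <- list(in_shape = d)
      dim(x) <- c(d[1], prod(d[-1]))
      x
    },
    stop("unknown layer type ", layer$type))
  list(out = out, cache = cache, layer = layer)
}

.layer_backward <- function(layer, cache, dy) {
  grads <- NULL
  dx <- switch(layer$type,
    dense = {
      dz <- if (layer$activation == "relu") dy * (cache$z > 0) else dy
      grads <- list(W = crossprod(cache$x, dz), b = colSums(dz))
      dz %*% t(layer$W)
    },
    dropout = if (is.null(cache)) dy else dy * cache$mask,
    batchnorm = {
      d <- cache$shape
      dy2 <- if (length(d) == 3) .to2d(dy) else dy
      xhat <- cache$xhat
      grads <- list(gamma = colSums(dy2 * xhat), beta = colSums(dy2))
      nb <- nrow(dy2)
      t1 <- sweep(dy2, 2, colMeans(dy2))
      t2 <- sweep(xhat, 2, colMeans(dy2 * xhat), "*")
      dx2 <- sweep(t1 - t2, 2, layer$gamma / sqrt(cache$v + layer$eps), "*")
      if (length(d) == 3) dim(dx2) <- d
      dx2
    },
    conv1d = {
      d <- cache$in_shape
      dy2 <- dy
      dim(dy2) <- c(d[1] * cache$lo, layer$out_ch)
      dz2 <- dy2 * (cache$z2 > 0)
      grads <- list(W = crossprod(cache$x2, dz2), b = colSums(dz2))
      dx2 <- dz2 %*% t(layer$W)  # (B*Lo, kernel*Cin)
      dxa <- array(0, d)
      for (ki in seq_len(layer$kernel)) {
        sl <- dx2[, ((ki - 1L) * d[3] + 1L):(ki * d[3]), drop = FALSE]
        dim(sl) <- c(d[1], cache$lo, d[3])
        dxa[, ki:(ki + cache$lo - 1L), ] <-
          dxa[, ki:(ki + cache$lo - 1L), , drop = FALSE] + sl
      }
      dxa
    },
    maxpool = {
      d <- cache$in_shape; s <- layer$size
      dxa <- array(0, d)
      for (si in seq_len(s)) {
        sel <- cache$amax == si
        sl <- array(0, dim(sel))
        sl[sel] <- dy[sel]
        dxa[, seq(si, by = s, length.out = cache$lo), ] <- sl
      }
      dxa
    },
    flatten = { dim(dy) <- cache$in_shape; dy },
    stop("unknown layer type ", layer$type))
  list(dx = dx, grads = grads)
}

nn_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    r <- .layer_forward(net$layers[[i]], x, training)
    x <- r$out
    caches[[i]] <- r$cache
    net$layers[[i]] <- r$layer  # batchnorm running stats
  }
  list(out = x, caches = caches, net = net)
}

nn_backward <- function(net, caches, dy) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    r <- .layer_backward(net$layers[[i]], caches[[i]], dy)
    dy <- r$dx
    grads[i] <- list(r$grads)  # keep NULL slots for parameter-free layers
  }
  grads
}

# loss value and gradient w.r.t. the network's linear output
.loss_grad <- function(task, z, y) {
  n <- nrow(z)
  switch(task,
    regression = {
      r <- z - y
      list(loss = mean(r^2), dz = 2 * r / length(r))
    },
    binary = {
      p <- 1 / (1 + exp(-z))
      eps <- 1e-12
      list(loss = -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps)),
           dz = (p - y) / n)
    },
    multiclass = {
      zs <- z - apply(z, 1, max)
      e <- exp(zs)
      p <- e / rowSums(e)
      list(loss = -mean(log(p[cbind(seq_len(n), max.col(y, "first"))] + 1e-12)) ,
           dz = (p - y) / n)
    },
    stop("unknown task"))
}

.collect_params <- function(net) {
  out <- list()
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    nm <- intersect(c("W", "b", "gamma", "beta"), names(l))
    for (p in nm) out[[paste0(i, ".", p)]] <- l[[p]]
  }
  out
}

.set_params <- function(net, params) {
  for (key in names(params)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    i <- as.integer(parts[1])
    net$layers[[i]][[parts[2]]] <- params[[key]]
  }
  net
}

#' Count trainable parameters of a network
#'
#' Sums weights and biases of dense and convolution layers and the
#' scale/shift (gamma/beta) pairs of batch-normalisation layers; running
#' statistics are not trainable and are not counted.
#'
#' @param net a network built by [build_model()] with family CNN or DNN.
#' @return integer parameter count.
#' @export
nn_count_params <- function(net) {
  if (!is.null(net$net)) net <- net$net
  sum(vapply(.collect_params(net), length, numeric(1)))
}

# Adamax update (Kingma & Ba): m <- b1 m + (1-b1) g ; u <- max(b2 u, |g|)
# theta <- theta - lr/(1-b1^t) * m / (u + eps)
.adamax_step <- function(state, params, grads, lr, t,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  for (key in names(grads)) {
    g <- grads[[key]]
    if (is.null(state$m[[key]])) {
      state$m[[key]] <- g * 0
      state$u[[key]] <- g * 0
    }
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
    state$u[[key]] <- pmax(beta2 * state$u[[key]], abs(g))
    params[[key]] <- params[[key]] -
      (lr / (1 - beta1^t)) * state$m[[key]] / (state$u[[key]] + eps)
  }
  list(state = state, params = params)
}

.flatten_grads <- function(grads) {
  out <- list()
  for (i in seq_along(grads)) {
    if (is.null(grads[[i]])) next
    for (p in names(grads[[i]])) out[[paste0(i, ".", p)]] <- grads[[i]][[p]]
  }
  out
}

.prep_input <- function(net, x) {
  if (net$input_rank == 3L && length(dim(x)) == 2) dim(x) <- c(dim(x), 1L)
  x
}

.encode_target <- function(task, y, n_classes) {
  switch(task,
    regression = matrix(as.numeric(y), ncol = 1),
    binary = matrix(as.numeric(y), ncol = 1),
    multiclass = {
      yy <- matrix(0, length(y), n_classes)
      yy[cbind(seq_along(y), as.integer(y) + 1L)] <- 1
      yy
    })
}

# re-draw all trainable parameters (He init for weights, identity for
# batchnorm) so a fit is fully determined by the architecture and the seed,
# not by the RNG state at build time
.nn_reset <- function(net) {
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (l$type == "dense") {
      l$W <- .he_init(l$n_in, l$n_out); l$b <- rep(0, l$n_out)
    } else if (l$type == "conv1d") {
      l$W <- .he_init(l$kernel * l$in_ch, l$out_ch); l$b <- rep(0, l$out_ch)
    } else if (l$type == "batchnorm") {
      l$gamma <- rep(1, l$dim); l$beta <- rep(0, l$dim)
      l$run_mean <- rep(0, l$dim); l$run_var <- rep(1, l$dim)
    }
    net$layers[[i]] <- l
  }
  net
}

#' Train a network with Adamax
#'
#' Mini-batch training with the Adamax optimiser (learning rate 0.003 by
#' default), a validation slice carved from the training data for early
#' stopping (patience in epochs, best weights restored), and a batch size
#' of 1/50th of the training samples unless given explicitly.
#'
#' @param net a network from [build_model()] (family CNN or DNN).
#' @param x numeric matrix of inputs (rows = samples).
#' @param y targets: numeric (regression), 0/1 (binary) or integer class
#'   codes 0..K-1 (multiclass).
#' @param task `"regression"`, `"binary"` or `"multiclass"`.
#' @param epochs maximum epochs (default 200).
#' @param batch_size mini-batch size; default `max(1, floor(n/50))`.
#' @param lr Adamax learning rate.
#' @param validation_split fraction of training rows held for early stopping.
#' @param patience epochs without validation improvement before stopping.
#' @param seed integer seed; fixes weight initialisation, shuffling, dropout
#'   and the validation slice, so the fit is fully reproducible.
#' @return the trained network (list) with `history` (per-epoch train/val
#'   loss) attached.
#' @export
nn_fit <- function(net, x, y, task, epochs = 200L, batch_size = NULL,
                   lr = 0.003, validation_split = 0.1, patience = 20L,
                   seed = 1L) {
  set.seed(as.integer(seed))
  net <- .nn_reset(net)
  n <- nrow(x)
  if (is.null(batch_size)) batch_size <- max(1L, n %/% 50L)
  y_enc <- .encode_target(task, y, net$n_classes)
  val_n <- max(1L, floor(validation_split * n))
  val_idx <- sample.int(n, val_n)
  tr_idx <- setdiff(seq_len(n), val_idx)
  x_tr <- x[tr_idx, , drop = FALSE]; y_tr <- y_enc[tr_idx, , drop = FALSE]
  x_va <- x[val_idx, , drop = FALSE]; y_va <- y_enc[val_idx, , drop = FALSE]
  state <- list(m = list(), u = list())
  t_step <- 0L
  best_val <- Inf; best_net <- net; wait <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  for (ep in seq_len(epochs)) {
    ord <- sample(nrow(x_tr))
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, length(ord), by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, length(ord))]
      xb <- .prep_input(net, x_tr[idx, , drop = FALSE])
      fw <- nn_forward(net, xb, training = TRUE)
      net <- fw$net
      lg <- .loss_grad(task, fw$out, y_tr[idx, , drop = FALSE])
      grads <- .flatten_grads(nn_backward(net, fw$caches, lg$dz))
      t_step <- t_step + 1L
      upd <- .adamax_step(state, .collect_params(net), grads, lr, t_step)
      state <- upd$state
      net <- .set_params(net, upd$params)
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1L
    }
    va <- nn_forward(net, .prep_input(net, x_va), training = FALSE)
    val_loss <- .loss_grad(task, va$out, y_va)$loss
    history <- rbind(history, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                         val_loss = val_loss))
    if (val_loss < best_val - 1e-9) {
      best_val <- val_loss
      best_net <- net  # weights AND batchnorm running statistics
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  net <- best_net
  net$history <- history
  net$trained <- TRUE
  net
}

#' Predict from a trained network
#'
#' @param net a network trained with [nn_fit()].
#' @param x input matrix.
#' @return regression: numeric vector; binary: probability of class 1;
#'   multiclass: matrix of class probabilities.
#' @export
nn_predict <- function(net, x) {
  z <- nn_forward(net, .prep_input(net, x), training = FALSE)$out
  switch(net$task,
    regression = as.numeric(z),
    binary = as.numeric(1 / (1 + exp(-z))),
    multiclass = {
      zs <- z - apply(z, 1, max)
      e <- exp(zs)
      e / rowSums(e)
    })
}
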