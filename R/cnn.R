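#' Convolutional classifier architecture
#'
#' Describes the small binary CNN: unpadded ('valid') 3x3 convolutions with
#' ReLU, each followed by 2x2 max-pooling with floor division, then flatten,
#' a ReLU dense layer, and a single sigmoid output unit. The default --
#' 508x508x8 input and two blocks of 16 filters -- yields the layer sizes
#' 506, 253, 251, 125 and a flatten length of 250,000. A third block can be
#' added by extending `conv_blocks`.
#'
#' @param input_shape `(rows, cols, channels)` of the input stack.
#' @param conv_blocks list of `(n_filters, kernel_side, pool_side)` triples;
#'   kernel sides must be odd, pool sides >= 1.
#' @param dense_units width of the dense layer before the sigmoid output.
#' @return object of class `cnn_config`.
#' @export
cnn_config <- function(input_shape = c(508L, 508L, 8L),
                       conv_blocks = list(c(16L, 3L, 2L), c(16L, 3L, 2L)),
                       dense_units = 64L) {
  input_shape <- as.integer(input_shape)
  stopifnot(length(input_shape) == 3L, all(input_shape >= 1L))
  if (length(conv_blocks) < 1L) stop("at least one conv block is required")
  for (b in conv_blocks) {
    b <- as.integer(b)
    if (length(b) != 3L) stop("each conv block is (n_filters, kernel, pool)")
    if (b[1] < 1L) stop("n_filters must be >= 1")
    if (b[2] %% 2L == 0L) stop("kernel_side must be odd")
    if (b[3] < 1L) stop("pool_side must be >= 1")
  }
  structure(list(input_shape = input_shape,
                 conv_blocks = lapply(conv_blocks, as.integer),
                 dense_units = as.integer(dense_units)),
            class = "cnn_config")
}

#' Training configuration
#'
#' Adam with binary cross-entropy loss, L2 weight penalty, and dropout on the
#' dense layer (training only). Defaults follow the tuned recipe for the
#' full-scale detector (learning rate 1e-6, batch 8, 80 epochs, dropout 0.2,
#' L2 0.01); small synthetic experiments typically use a larger learning rate.
#'
#' @param learning_rate Adam step size (> 0).
#' @param batch_size minibatch size.
#' @param epochs number of epochs (>= 1).
#' @param dropout dropout rate on the dense activations, in `[0, 1)`.
#' @param l2 L2 penalty coefficient on the weights.
#' @param seed integer seed controlling initialization order, shuffling, and
#'   dropout masks.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-6, batch_size = 8L, epochs = 80L,
                         dropout = 0.2, l2 = 0.01, seed = 1L) {
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1,
            dropout >= 0, dropout < 1, l2 >= 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), dropout = dropout, l2 = l2,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Infer per-layer output shapes
#'
#' Valid (unpadded) convolution shrinks each side by `kernel_side - 1`;
#' max-pooling divides each side by `pool_side` with floor. Errors if any
#' layer side would drop to zero or below.
#'
#' @param config a [cnn_config()].
#' @return data.frame with columns `layer, rows, cols, channels`, plus a
#'   `flatten` attribute holding the flatten length.
#' @examples
#' s <- infer_shapes(cnn_config())
#' attr(s, "flatten")  # 250000
#' @export
infer_shapes <- function(config) {
  stopifnot(inherits(config, "cnn_config"))
  r <- config$input_shape[1]; c <- config$input_shape[2]
  ch <- config$input_shape[3]
  rows <- list(data.frame(layer = "input", rows = r, cols = c, channels = ch))
  for (i in seq_along(config$conv_blocks)) {
    b <- config$conv_blocks[[i]]
    r <- r - (b[2] - 1L); c <- c - (b[2] - 1L); ch <- b[1]
    if (r <= 0L || c <= 0L)
      stop(sprintf("architecture infeasible: conv%d output %d x %d", i, r, c))
    rows[[length(rows) + 1L]] <-
      data.frame(layer = sprintf("conv%d", i), rows = r, cols = c,
                 channels = ch)
    r <- r %/% b[3]; c <- c %/% b[3]
    if (r <= 0L || c <= 0L)
      stop(sprintf("architecture infeasible: pool%d output %d x %d", i, r, c))
    rows[[length(rows) + 1L]] <-
      data.frame(layer = sprintf("pool%d", i), rows = r, cols = c,
                 channels = ch)
  }
  out <- do.call(rbind, rows)
  attr(out, "flatten") <- r * c * ch
  out
}

# ---- array plumbing ------------------------------------------------------

# im2col: unroll k x k patches of an (h, w, ch) array into a
# (out_h*out_w) x (k*k*ch) matrix. Row index runs column-major over output
# positions; column index runs di fastest, then dj, then channel.
im2col <- function(x, k) {
  h <- dim(x)[1]; w <- dim(x)[2]; ch <- dim(x)[3]
  oh <- h - k + 1L; ow <- w - k + 1L
  P <- matrix(0, oh * ow, k * k * ch)
  col <- 0L
  for (c0 in seq_len(ch)) {
    plane <- x[, , c0]
    for (dj in seq_len(k)) {
      for (di in seq_len(k)) {
        col <- col + 1L
        P[, col] <- plane[di:(di + oh - 1L), dj:(dj + ow - 1L)]
      }
    }
  }
  P
}

# col2im accumulation: scatter-add gradient columns back onto the input array.
col2im_add <- function(dP, dims, k) {
  h <- dims[1]; w <- dims[2]; ch <- dims[3]
  oh <- h - k + 1L; ow <- w - k + 1L
  dx <- array(0, dims)
  col <- 0L
  for (c0 in seq_len(ch)) {
    plane <- matrix(0, h, w)
    for (dj in seq_len(k)) {
      for (di in seq_len(k)) {
        col <- col + 1L
        plane[di:(di + oh - 1L), dj:(dj + ow - 1L)] <-
          plane[di:(di + oh - 1L), dj:(dj + ow - 1L)] +
          matrix(dP[, col], oh, ow)
      }
    }
    dx[, , c0] <- plane
  }
  dx
}

# Max-pool an (h, w, ch) array with floor division; returns pooled array and
# the argmax linear indices (into the cropped input plane) for backward.
maxpool_fwd <- function(x, p) {
  h <- dim(x)[1]; w <- dim(x)[2]; ch <- dim(x)[3]
  oh <- h %/% p; ow <- w %/% p
  out <- array(0, c(oh, ow, ch))
  arg <- array(0L, c(oh, ow, ch))
  if (p == 1L) {
    out <- x[seq_len(oh), seq_len(ow), , drop = FALSE]
    idx <- matrix(seq_len(oh * ow), oh, ow)  # trivial argmax
    for (c0 in seq_len(ch)) arg[, , c0] <- idx
    return(list(out = out, arg = arg, crop = c(oh * p, ow * p)))
  }
  for (c0 in seq_len(ch)) {
    plane <- x[seq_len(oh * p), seq_len(ow * p), c0]
    cand <- matrix(0, oh * ow, p * p)
    lin <- matrix(0L, oh * ow, p * p)
    s <- 0L
    base_r <- (seq_len(oh) - 1L) * p
    base_c <- (seq_len(ow) - 1L) * p
    for (dj in seq_len(p)) {
      for (di in seq_len(p)) {
        s <- s + 1L
        rr <- base_r + di
        ccc <- base_c + dj
        cand[, s] <- plane[rr, ccc]
        lin[, s] <- outer(rr, (ccc - 1L) * (oh * p), "+")
      }
    }
    best <- max.col(cand, ties.method = "first")
    pick <- cbind(seq_len(oh * ow), best)
    out[, , c0] <- matrix(cand[pick], oh, ow)
    arg[, , c0] <- matrix(lin[pick], oh, ow)
  }
  list(out = out, arg = arg, crop = c(oh * p, ow * p))
}

maxpool_bwd <- function(dout, arg, crop, dims) {
  h <- dims[1]; w <- dims[2]; ch <- dims[3]
  dx <- array(0, dims)
  for (c0 in seq_len(ch)) {
    plane <- matrix(0, crop[1], crop[2])
    plane[as.vector(arg[, , c0])] <- plane[as.vector(arg[, , c0])] +
      as.vector(dout[, , c0])
    dx[seq_len(crop[1]), seq_len(crop[2]), c0] <- plane
  }
  dx
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# numerically safe binary cross-entropy
bce <- function(p, y) {
  eps <- 1e-12
  -(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
}

# ---- model ----------------------------------------------------------------

#' Build (initialize) the convolutional classifier
#'
#' Allocates seeded He-normal weights for every layer of the architecture.
#' Two builds with the same config and seed are identical.
#'
#' @param config a [cnn_config()].
#' @param seed integer seed for the initialization RNG.
#' @return an `mc_cnn` model object (weights, config, empty history).
#' @export
build_model <- function(config = cnn_config(), seed = 1L) {
  shapes <- infer_shapes(config)  # errors if infeasible
  flat <- attr(shapes, "flatten")
  with_seed(seed, {
    layers <- list()
    ch_in <- config$input_shape[3]
    for (i in seq_along(config$conv_blocks)) {
      b <- config$conv_blocks[[i]]
      fan_in <- b[2] * b[2] * ch_in
      layers[[sprintf("conv%d", i)]] <- list(
        W = matrix(rnorm(fan_in * b[1], sd = sqrt(2 / fan_in)), fan_in, b[1]),
        b = rep(0, b[1]), k = b[2], pool = b[3])
      ch_in <- b[1]
    }
    layers$dense <- list(
      W = matrix(rnorm(flat * config$dense_units, sd = sqrt(2 / flat)),
                 flat, config$dense_units),
      b = rep(0, config$dense_units))
    layers$out <- list(
      W = matrix(rnorm(config$dense_units, sd = sqrt(1 / config$dense_units)),
                 config$dense_units, 1),
      b = 0)
    structure(list(config = config, layers = layers, shapes = shapes,
                   history = NULL, trained = FALSE, seed = as.integer(seed)),
              class = "mc_cnn")
  })
}

# Forward pass on one (h, w, ch) stack. training=TRUE applies the supplied
# dropout mask to the dense activations (inverted dropout).
cnn_forward <- function(model, x, training = FALSE, drop_mask = NULL) {
  cfg <- model$config
  if (!all(dim(x) == cfg$input_shape))
    stop(sprintf("input shape (%s) does not match model input (%s)",
                 paste(dim(x), collapse = "x"),
                 paste(cfg$input_shape, collapse = "x")))
  cache <- list(x_dims = dim(x))
  a <- x
  for (i in seq_along(cfg$conv_blocks)) {
    ly <- model$layers[[sprintf("conv%d", i)]]
    P <- im2col(a, ly$k)
    Z <- sweep(P %*% ly$W, 2, ly$b, "+")
    A <- pmax(Z, 0)
    oh <- dim(a)[1] - ly$k + 1L; ow <- dim(a)[2] - ly$k + 1L
    Aarr <- array(A, c(oh, ow, ncol(ly$W)))
    pool <- maxpool_fwd(Aarr, ly$pool)
    cache[[sprintf("conv%d", i)]] <-
      list(P = P, relu = Z > 0, in_dims = dim(a),
           conv_dims = c(oh, ow, ncol(ly$W)),
           arg = pool$arg, crop = pool$crop)
    a <- pool$out
  }
  flat <- as.vector(a)
  d <- model$layers$dense
  z1 <- as.vector(flat %*% d$W) + d$b
  a1 <- pmax(z1, 0)
  if (training && !is.null(drop_mask)) a1 <- a1 * drop_mask
  o <- model$layers$out
  z2 <- sum(a1 * o$W) + o$b
  p <- sigmoid(z2)
  cache$flat <- flat
  cache$z1 <- z1; cache$a1 <- a1; cache$drop_mask <- drop_mask
  cache$pool_dims <- dim(a)
  list(p = p, cache = cache)
}

# Backward pass for one sample; returns gradients in the same layout as
# model$layers (data loss only; the L2 term is added at the update).
cnn_backward <- function(model, cache, p, y) {
  grads <- list()
  dz2 <- p - y
  o <- model$layers$out
  grads$out <- list(W = matrix(cache$a1 * dz2, ncol = 1), b = dz2)
  da1 <- as.vector(o$W) * dz2
  if (!is.null(cache$drop_mask)) da1 <- da1 * cache$drop_mask
  dz1 <- da1 * (cache$z1 > 0)
  d <- model$layers$dense
  grads$dense <- list(W = outer(cache$flat, dz1), b = dz1)
  dflat <- as.vector(d$W %*% dz1)
  da <- array(dflat, cache$pool_dims)
  for (i in rev(seq_along(model$config$conv_blocks))) {
    cc <- cache[[sprintf("conv%d", i)]]
    ly <- model$layers[[sprintf("conv%d", i)]]
    dA <- maxpool_bwd(da, cc$arg, cc$crop, cc$conv_dims)
    dZ <- matrix(as.vector(dA), prod(cc$conv_dims[1:2]), cc$conv_dims[3])
    dZ <- dZ * cc$relu
    grads[[sprintf("conv%d", i)]] <-
      list(W = crossprod(cc$P, dZ), b = colSums(dZ))
    if (i > 1L) {
      dP <- dZ %*% t(ly$W)
      da <- col2im_add(dP, cc$in_dims, ly$k)
    }
  }
  grads
}

# Sum of squared weights (biases excluded), for the L2 penalty.
weight_ssq <- function(model) {
  s <- 0
  for (nm in names(model$layers)) s <- s + sum(model$layers[[nm]]$W^2)
  s
}

#' Loss of a model on labeled stacks
#'
#' Mean binary cross-entropy over the samples plus `l2 * sum(W^2)` over the
#' weights (dropout off). Exposed so the penalty's effect can be inspected at
#' fixed weights.
#'
#' @param model an `mc_cnn`.
#' @param x list of input stacks.
#' @param y binary labels (0/1) of the same length.
#' @param l2 penalty coefficient.
#' @return list `loss`, `data_loss`, `penalty`, `accuracy`.
#' @export
cnn_loss <- function(model, x, y, l2 = 0) {
  ps <- vapply(x, function(s) cnn_forward(model, s)$p, numeric(1))
  data_loss <- mean(bce(ps, y))
  pen <- l2 * weight_ssq(model)
  list(loss = data_loss + pen, data_loss = data_loss, penalty = pen,
       accuracy = mean((ps > 0.5) == (y > 0.5)))
}

#' Train the convolutional classifier
#'
#' Minibatch Adam on binary cross-entropy with L2 weight penalty; dropout is
#' active on the dense layer during training only. Per-epoch training and
#' validation loss/accuracy are recorded, and the weights achieving the best
#' validation loss are retained in the returned model. Fully deterministic
#' given the training seed.
#'
#' @param model an `mc_cnn` from [build_model()].
#' @param x_train,y_train list of input stacks and binary labels (both classes
#'   must be present).
#' @param x_val,y_val validation stacks/labels (may be `NULL` to skip
#'   validation tracking; the final weights are then retained).
#' @param tcfg a [train_config()].
#' @return the trained `mc_cnn`, with `$history` a data.frame
#'   `epoch, train_loss, val_loss, train_acc, val_acc`.
#' @export
train_cnn <- function(model, x_train, y_train, x_val = NULL, y_val = NULL,
                      tcfg = train_config()) {
  stopifnot(inherits(model, "mc_cnn"), inherits(tcfg, "train_config"))
  if (length(x_train) == 0L) stop("empty training set")
  y_train <- as.numeric(y_train)
  if (length(unique(y_train)) < 2L)
    stop("training set contains a single class; both classes are required")
  n <- length(x_train)
  # Adam state
  adam <- list()
  for (nm in names(model$layers))
    adam[[nm]] <- list(mW = model$layers[[nm]]$W * 0, vW = model$layers[[nm]]$W * 0,
                       mb = model$layers[[nm]]$b * 0, vb = model$layers[[nm]]$b * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  du <- model$config$dense_units
  hist <- vector("list", tcfg$epochs)
  best_val <- Inf
  best_layers <- model$layers
  with_seed(tcfg$seed, {
    for (epoch in seq_len(tcfg$epochs)) {
      ord <- sample.int(n)
      batch_losses <- c()
      correct <- 0L
      for (b0 in seq(1L, n, by = tcfg$batch_size)) {
        idx <- ord[b0:min(n, b0 + tcfg$batch_size - 1L)]
        acc_grads <- NULL
        bl <- 0
        for (s in idx) {
          mask <- if (tcfg$dropout > 0)
            (runif(du) >= tcfg$dropout) / (1 - tcfg$dropout) else NULL
          fw <- cnn_forward(model, x_train[[s]], training = TRUE,
                            drop_mask = mask)
          bl <- bl + bce(fw$p, y_train[s])
          correct <- correct + ((fw$p > 0.5) == (y_train[s] > 0.5))
          g <- cnn_backward(model, fw$cache, fw$p, y_train[s])
          if (is.null(acc_grads)) acc_grads <- g
          else for (nm in names(g)) {
            acc_grads[[nm]]$W <- acc_grads[[nm]]$W + g[[nm]]$W
            acc_grads[[nm]]$b <- acc_grads[[nm]]$b + g[[nm]]$b
          }
        }
        bl <- bl / length(idx)
        if (!is.finite(bl))
          stop(sprintf("non-finite loss at epoch %d; lower the learning rate",
                       epoch))
        batch_losses <- c(batch_losses, bl)
        t_step <- t_step + 1L
        for (nm in names(acc_grads)) {
          gW <- acc_grads[[nm]]$W / length(idx) +
            2 * tcfg$l2 * model$layers[[nm]]$W
          gb <- acc_grads[[nm]]$b / length(idx)
          st <- adam[[nm]]
          st$mW <- beta1 * st$mW + (1 - beta1) * gW
          st$vW <- beta2 * st$vW + (1 - beta2) * gW^2
          st$mb <- beta1 * st$mb + (1 - beta1) * gb
          st$vb <- beta2 * st$vb + (1 - beta2) * gb^2
          mhW <- st$mW / (1 - beta1^t_step); vhW <- st$vW / (1 - beta2^t_step)
          mhb <- st$mb / (1 - beta1^t_step); vhb <- st$vb / (1 - beta2^t_step)
          model$layers[[nm]]$W <- model$layers[[nm]]$W -
            tcfg$learning_rate * mhW / (sqrt(vhW) + eps)
          model$layers[[nm]]$b <- model$layers[[nm]]$b -
            tcfg$learning_rate * mhb / (sqrt(vhb) + eps)
          adam[[nm]] <- st
        }
      }
      val_loss <- NA_real_; val_acc <- NA_real_
      if (!is.null(x_val) && length(x_val)) {
        v <- cnn_loss(model, x_val, as.numeric(y_val), l2 = 0)
        val_loss <- v$data_loss; val_acc <- v$accuracy
        if (val_loss < best_val) {
          best_val <- val_loss
          best_layers <- model$layers
        }
      } else {
        best_layers <- model$layers
      }
      hist[[epoch]] <- data.frame(epoch = epoch,
                                  train_loss = mean(batch_losses),
                                  val_loss = val_loss,
                                  train_acc = correct / n,
                                  val_acc = val_acc)
    }
  })
  model$layers <- best_layers
  model$history <- do.call(rbind, hist)
  model$trained <- TRUE
  model
}

#' Predict on feature stacks
#'
#' Deterministic forward pass (dropout off); a stack is called positive when
#' its probability strictly exceeds the threshold (a probability exactly at
#' the threshold is negative).
#'
#' @param object an `mc_cnn`.
#' @param newdata a single `feature_stack`/array or a list of them.
#' @param threshold decision threshold (default 0.5).
#' @param ... unused.
#' @return data.frame with columns `probability`, `label` (0/1), and the
#'   threshold as an attribute.
#' @export
predict.mc_cnn <- function(object, newdata, threshold = 0.5, ...) {
  xs <- if (is.list(newdata) && !is.array(newdata)) newdata else list(newdata)
  p <- vapply(xs, function(s) cnn_forward(object, s)$p, numeric(1))
  out <- data.frame(probability = p, label = as.integer(p > threshold))
  attr(out, "threshold") <- threshold
  out
}

#' @export
print.mc_cnn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<mc_cnn: input %s, %d conv block(s), dense %d, %s>\n",
              paste(cfg$input_shape, collapse = "x"),
              length(cfg$conv_blocks), cfg$dense_units,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' @export
summary.mc_cnn <- function(object, ...) {
  print(object)
  print(object$shapes)
  cat(sprintf("flatten length: %d\nparameters: %d\n",
              attr(object$shapes, "flatten"), n_parameters(object)))
  if (!is.null(object$history)) {
    last <- object$history[nrow(object$history), ]
    cat(sprintf("final epoch %d: train loss %.4f, val loss %.4f, val acc %.3f\n",
                last$epoch, last$train_loss, last$val_loss, last$val_acc))
  }
  invisible(object)
}

#' Number of trainable parameters
#' @param model an `mc_cnn`.
#' @return integer count of weights plus biases.
#' @export
n_parameters <- function(model) {
  s <- 0L
  for (nm in names(model$layers))
    s <- s + length(model$layers[[nm]]$W) + length(model$layers[[nm]]$b)
  s
}

#' Plot training history
#' @param x a trained `mc_cnn`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.mc_cnn <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("model has no training history")
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "red"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "red"), bty = "n")
  invisible(x)
}

#' Save / load a model
#'
#' Weights and configs serialized as JSON at full double precision, with the
#' training history as a plain data.frame.
#'
#' @param model an `mc_cnn`.
#' @param path file path (`.json`).
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  payload <- list(config = unclass(model$config),
                  seed = model$seed, trained = model$trained,
                  layers = lapply(model$layers, function(l) {
                    out <- list(W = l$W, b = l$b)
                    if (!is.null(l$k)) { out$k <- l$k; out$pool <- l$pool }
                    out
                  }),
                  history = model$history)
  jsonlite::write_json(payload, path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- cnn_config(input_shape = p$config$input_shape,
                    conv_blocks = if (is.matrix(p$config$conv_blocks))
                      lapply(seq_len(nrow(p$config$conv_blocks)),
                             function(i) p$config$conv_blocks[i, ])
                    else p$config$conv_blocks,
                    dense_units = p$config$dense_units)
  layers <- lapply(p$layers, function(l) {
    out <- list(W = as.matrix(l$W), b = as.numeric(l$b))
    if (!is.null(l$k)) { out$k <- as.integer(l$k); out$pool <- as.integer(l$pool) }
    out
  })
  structure(list(config = cfg, layers = layers, shapes = infer_shapes(cfg),
                 history = p$history, trained = isTRUE(p$trained),
                 seed = p$seed),
            class = "mc_cnn")
}
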