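# A small convolutional-network engine in base R.
#
# The architecture family is parametric in depth d (1..12): d repeated
# blocks of [convolution -> batch normalization -> ReLU -> (max pooling)],
# where max pooling appears only in the last min(d, 3) blocks, followed by
# an output head.  Two heads are supported:
#   * flatten head: flatten -> FC(fc_units) -> ReLU -> dropout -> FC(2) -> softmax
#   * GAP head:     global average pool -> dropout -> FC(2) -> softmax
# The GAP head is the variant used for class-activation mapping, where the
# class-unit weights act directly on pooled feature maps.
#
# Activations are stored as (H, W, C, N) arrays.  Convolutions use "same"
# zero padding, stride 1, and are computed as a sum of k^2 shifted matrix
# products, which keeps everything inside BLAS.  Training is plain SGD with
# momentum, L2 weight decay and per-epoch exponential learning-rate decay;
# early stopping monitors validation accuracy with a fixed patience.

#' Parametric CNN specification
#'
#' The 11 tunable hyperparameters of the architecture/training family.
#'
#' @param depth number of conv blocks, 1..12.
#' @param filters_base filters in the first block.
#' @param filter_growth multiplicative filter growth per block (rounded).
#' @param kernel_size odd convolution kernel size.
#' @param pool_size max-pooling size (pooling only in the last
#'   `min(depth, 3)` blocks).
#' @param fc_units units of the hidden fully connected layer (flatten head
#'   only).
#' @param dropout_rate dropout probability before the output layer.
#' @param init_learning_rate,momentum,l2_penalty,batch_size,lr_decay SGD
#'   training hyperparameters; `lr_decay` is the per-epoch multiplicative
#'   decay in `(0, 1]`.
#' @param gap_head use the global-average-pooling head (required for CAM).
#' @return a `cnn_spec` object.
#' @export
cnn_spec <- function(depth = 3L, filters_base = 8L, filter_growth = 1.5,
                     kernel_size = 3L, pool_size = 2L, fc_units = 16L,
                     dropout_rate = 0.25, init_learning_rate = 0.03,
                     momentum = 0.9, l2_penalty = 1e-4, batch_size = 16L,
                     lr_decay = 0.95, gap_head = FALSE) {
  stopifnot(depth >= 1, depth <= 12, kernel_size %% 2 == 1,
            pool_size >= 2, dropout_rate >= 0, dropout_rate < 1,
            init_learning_rate > 0, momentum >= 0, momentum < 1,
            l2_penalty >= 0, batch_size >= 1, lr_decay > 0, lr_decay <= 1)
  structure(list(depth = as.integer(depth),
                 filters_base = as.integer(filters_base),
                 filter_growth = filter_growth,
                 kernel_size = as.integer(kernel_size),
                 pool_size = as.integer(pool_size),
                 fc_units = as.integer(fc_units),
                 dropout_rate = dropout_rate,
                 init_learning_rate = init_learning_rate,
                 momentum = momentum, l2_penalty = l2_penalty,
                 batch_size = as.integer(batch_size), lr_decay = lr_decay,
                 gap_head = isTRUE(gap_head)),
            class = "cnn_spec")
}

# per-block output channels and spatial sizes; errors on spatial underflow
cnn_shapes <- function(spec, input_size = 64L) {
  d <- spec$depth
  pool_blocks <- seq.int(d - min(d, 3L) + 1L, d)
  ch <- integer(d)
  size <- integer(d)
  s <- input_size
  for (b in seq_len(d)) {
    ch[b] <- max(1L, as.integer(round(spec$filters_base *
                                        spec$filter_growth^(b - 1))))
    if (b %in% pool_blocks) {
      if (s %% spec$pool_size != 0 || s < spec$pool_size) {
        stop("spatial size underflow: size ", s, " cannot be pooled by ",
             spec$pool_size, " in block ", b)
      }
      s <- s %/% spec$pool_size
    }
    size[b] <- s
  }
  list(channels = ch, sizes = size, pool_blocks = pool_blocks)
}

#' Build (initialize) a CNN from its specification
#'
#' @param spec a [cnn_spec()].
#' @param seed seed for the weight initialization (He-scaled normal).
#' @param input_channels input channel count (3 for RGB).
#' @param input_size input spatial size (64).
#' @return a `cnn_model`; its `n_params` field is the trainable-parameter
#'   count (conv kernels + biases, batch-norm scale/shift, FC weights).
#' @export
build_cnn <- function(spec, seed = 1L, input_channels = 3L, input_size = 64L) {
  sh <- cnn_shapes(spec, input_size)
  d <- spec$depth; k <- spec$kernel_size
  with_rng(seed, {
    blocks <- vector("list", d)
    cin <- input_channels
    for (b in seq_len(d)) {
      cout <- sh$channels[b]
      w <- array(stats::rnorm(k * k * cin * cout, 0,
                              sqrt(2 / (k * k * cin))),
                 dim = c(k, k, cin, cout))
      blocks[[b]] <- list(
        w = w, b = numeric(cout),
        gamma = rep(1, cout), beta = numeric(cout),
        run_mean = numeric(cout), run_var = rep(1, cout),
        pool = b %in% sh$pool_blocks)
      cin <- cout
    }
    feat_dim <- if (spec$gap_head) cin else sh$sizes[d]^2 * cin
    head <- if (spec$gap_head) {
      list(w2 = matrix(stats::rnorm(feat_dim * 2, 0, sqrt(2 / feat_dim)),
                       feat_dim, 2), b2 = numeric(2))
    } else {
      list(w1 = matrix(stats::rnorm(feat_dim * spec$fc_units, 0,
                                    sqrt(2 / feat_dim)),
                       feat_dim, spec$fc_units),
           b1 = numeric(spec$fc_units),
           w2 = matrix(stats::rnorm(spec$fc_units * 2, 0,
                                    sqrt(2 / spec$fc_units)),
                       spec$fc_units, 2), b2 = numeric(2))
    }
    n_params <- sum(vapply(blocks, function(bl)
      length(bl$w) + length(bl$b) + length(bl$gamma) + length(bl$beta),
      numeric(1))) +
      sum(vapply(head, length, numeric(1)))
    structure(list(spec = spec, blocks = blocks, head = head,
                   shapes = sh, input_size = input_size,
                   input_channels = input_channels,
                   n_params = as.integer(n_params), init_seed = seed,
                   trained = FALSE),
              class = "cnn_model")
  })
}

# ---- layer primitives ---------------------------------------------------
#
# Internally all activations use channels-last (H, W, N, C) layout so the
# k^2 shifted-slab matrix products need no permutations; the public API
# converts from the (H, W, C, N) image layout once per forward pass.

# x: (H, W, N, Cin); w: (k, k, Cin, Cout) -> (H, W, N, Cout), same padding.
# im2col/col2im data movement is compiled (src/cnn_ops.cpp); the products
# stay in BLAS.
conv_forward <- function(x, w, bias) {
  d <- dim(x); H <- d[1]; W <- d[2]; N <- d[3]; Cin <- d[4]
  k <- dim(w)[1]; Cout <- dim(w)[4]
  cols <- im2col_nc(x, H, W, N, Cin, k)
  wm <- w
  dim(wm) <- c(k * k * Cin, Cout)
  ymat <- cols %*% wm
  ymat <- ymat + matrix(bias, nrow(ymat), Cout, byrow = TRUE)
  dim(ymat) <- c(H, W, N, Cout)
  ymat
}

conv_backward <- function(x, w, dy) {
  d <- dim(x); H <- d[1]; W <- d[2]; N <- d[3]; Cin <- d[4]
  k <- dim(w)[1]; Cout <- dim(w)[4]
  cols <- im2col_nc(x, H, W, N, Cin, k)
  dym <- dy
  dim(dym) <- c(H * W * N, Cout)
  dw <- crossprod(cols, dym)
  dim(dw) <- dim(w)
  wm <- w
  dim(wm) <- c(k * k * Cin, Cout)
  dx <- col2im_nc(tcrossprod(dym, wm), H, W, N, Cin, k)
  dim(dx) <- c(H, W, N, Cin)
  db <- colSums(dym)
  list(dx = dx, dw = dw, db = db)
}

# x: (H, W, N, C); per-channel batch normalization
bn_forward <- function(x, gamma, beta, run_mean, run_var, training,
                       momentum = 0.9, eps = 1e-5) {
  d <- dim(x); C <- d[4]
  m <- x
  dim(m) <- c(prod(d[1:3]), C)
  if (training) {
    mu <- colMeans(m)
    va <- colMeans(m^2) - mu^2
    run_mean <- momentum * run_mean + (1 - momentum) * mu
    run_var <- momentum * run_var + (1 - momentum) * va
  } else {
    mu <- run_mean; va <- run_var
  }
  inv_sd <- 1 / sqrt(va + eps)
  nr <- nrow(m)
  xhat <- (m - matrix(mu, nr, C, byrow = TRUE)) *
    matrix(inv_sd, nr, C, byrow = TRUE)
  y <- xhat * matrix(gamma, nr, C, byrow = TRUE) +
    matrix(beta, nr, C, byrow = TRUE)
  dim(y) <- d
  list(y = y, xhat = xhat, inv_sd = inv_sd,
       run_mean = run_mean, run_var = run_var)
}

bn_backward <- function(cache, gamma, dy) {
  d <- dim(dy); C <- d[4]
  dym <- dy
  dim(dym) <- c(prod(d[1:3]), C)
  xhat <- cache$xhat
  nr <- nrow(dym)
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- dym * matrix(gamma, nr, C, byrow = TRUE)
  dxm <- (dxhat - matrix(colMeans(dxhat), nr, C, byrow = TRUE) -
            xhat * matrix(colMeans(dxhat * xhat), nr, C, byrow = TRUE)) *
    matrix(cache$inv_sd, nr, C, byrow = TRUE)
  dim(dxm) <- d
  list(dx = dxm, dgamma = dgamma, dbeta = dbeta)
}

maxpool_forward <- function(x, ps) {
  d <- dim(x); H <- d[1]; W <- d[2]
  Ho <- H %/% ps; Wo <- W %/% ps
  slabs <- vector("list", ps * ps)
  idx <- 1L
  for (di in seq_len(ps)) for (dj in seq_len(ps)) {
    slabs[[idx]] <- x[seq.int(di, H, by = ps), seq.int(dj, W, by = ps), , ,
                      drop = FALSE]
    idx <- idx + 1L
  }
  y <- slabs[[1]]
  for (i in 2:(ps * ps)) y <- pmax(y, slabs[[i]])
  list(y = y, slabs = slabs)
}

maxpool_backward <- function(cache, x_dim, ps, dy) {
  H <- x_dim[1]; W <- x_dim[2]
  dx <- array(0, dim = x_dim)
  assigned <- array(FALSE, dim = dim(dy))
  y <- cache$y
  idx <- 1L
  for (di in seq_len(ps)) for (dj in seq_len(ps)) {
    is_max <- (cache$slabs[[idx]] == y) & !assigned
    assigned <- assigned | is_max
    dx[seq.int(di, H, by = ps), seq.int(dj, W, by = ps), , ] <- dy * is_max
    idx <- idx + 1L
  }
  dx
}

softmax2 <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- forward pass -------------------------------------------------------

# Full forward pass.  training=TRUE uses batch statistics and dropout (with
# `drop_seed`); keep_acts=TRUE returns intermediate stages for RSA/CAM.
# Public input layout is (H, W, C, N); internally channels-last (H, W, N, C).
cnn_forward <- function(model, x, training = FALSE, drop_seed = NULL,
                        keep_acts = FALSE, bn_momentum = 0.9) {
  spec <- model$spec
  caches <- list()
  acts <- if (keep_acts) list(input = x) else NULL
  h <- aperm(x, c(1, 2, 4, 3))
  for (b in seq_along(model$blocks)) {
    bl <- model$blocks[[b]]
    z <- conv_forward(h, bl$w, bl$b)
    bn <- bn_forward(z, bl$gamma, bl$beta, bl$run_mean, bl$run_var, training,
                     momentum = bn_momentum)
    r <- bn$y; r[r < 0] <- 0
    relu_mask <- r > 0
    pooled <- NULL
    if (bl$pool) {
      pooled <- maxpool_forward(r, spec$pool_size)
      hout <- pooled$y
    } else hout <- r
    caches[[b]] <- list(x = h, z = z, bn = bn, relu_mask = relu_mask,
                        pool = pooled, r_dim = dim(r))
    if (keep_acts) acts[[sprintf("relu%d", b)]] <- aperm(r, c(1, 2, 4, 3))
    h <- hout
  }
  d <- dim(h); N <- d[3]
  if (spec$gap_head) {
    m <- h
    dim(m) <- c(d[1] * d[2], d[3] * d[4])
    feat <- matrix(colMeans(m), N, d[4])      # N x C
  } else {
    hc <- aperm(h, c(1, 2, 4, 3))             # (H, W, C, N)
    dim(hc) <- c(d[1] * d[2] * d[4], N)
    feat <- t(hc)                             # N x (H*W*C)
  }
  drop_mask <- NULL
  feat1 <- feat
  if (!spec$gap_head) {
    z1 <- sweep(feat %*% model$head$w1, 2, model$head$b1, `+`)
    a1 <- pmax(z1, 0)
    if (keep_acts) acts$fc <- a1
    feat1 <- a1
  } else if (keep_acts) acts$fc <- feat
  if (training && spec$dropout_rate > 0) {
    drop_mask <- with_rng(drop_seed %||% 0L,
                          matrix(stats::runif(length(feat1)) >=
                                   spec$dropout_rate, nrow(feat1)))
    feat1 <- feat1 * drop_mask / (1 - spec$dropout_rate)
  }
  z2 <- sweep(feat1 %*% model$head$w2, 2, model$head$b2, `+`)
  prob <- softmax2(z2)
  if (keep_acts) acts$output <- prob[, 2]
  list(prob = prob, caches = caches, feat = feat, feat1 = feat1,
       drop_mask = drop_mask, last_conv = h, acts = acts)
}

#' Prediction scores of a CNN
#'
#' @param model a trained `cnn_model`.
#' @param x 4-D image batch `(64, 64, 3, n)` or a single image array.
#' @param batch evaluation batch size.
#' @return numeric vector: softmax probability of the mirror unit.
#' @export
predict_cnn <- function(model, x, batch = 64L) {
  if (length(dim(x)) == 3L) x <- array(x, dim = c(dim(x), 1L))
  n <- dim(x)[4]
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch - 1L, n)
    out[i:j] <- cnn_forward(model, x[, , , i:j, drop = FALSE])$prob[, 2]
    i <- j + 1L
  }
  out
}

#' Stage activations of a CNN
#'
#' Stages: `input`, `relu1..relud` (post-ReLU of each block, before
#' pooling), `fc` (hidden FC / pooled features) and `output` (mirror
#' probability).
#'
#' @param model a `cnn_model`.
#' @param x 4-D image batch.
#' @return named list of stage activations; spatial stages keep their array
#'   shape.
#' @export
cnn_activations <- function(model, x) {
  cnn_forward(model, x, keep_acts = TRUE)$acts
}

# ---- training -----------------------------------------------------------

#' Train a CNN with SGD + momentum and early stopping
#'
#' Trains with minibatch SGD (momentum, L2 weight decay on conv/FC weights,
#' per-epoch exponential learning-rate decay).  Validation accuracy is
#' evaluated once per epoch; training stops when it has not improved for
#' `patience` validations (or after `max_epochs`).  The best-validation
#' weights are retained.
#'
#' @param model a `cnn_model` from [build_cnn()].
#' @param x,y training images `(64,64,3,n)` and labels.
#' @param val_x,val_y validation split (required).
#' @param max_epochs epoch cap.
#' @param patience validations without improvement before stopping.
#' @param seed seed for shuffling and dropout.
#' @param verbose print per-epoch progress.
#' @return the trained model, with `history` (data frame epoch, train_loss,
#'   val_accuracy) and `best_val_accuracy`.
#' @export
train_cnn <- function(model, x, y, val_x, val_y, max_epochs = 12L,
                      patience = 3L, seed = 1L, verbose = FALSE) {
  spec <- model$spec
  n <- dim(x)[4]
  if (n == 0L || length(dim(val_x)) != 4L || dim(val_x)[4] == 0L) {
    stop("empty training or validation split")
  }
  y <- as_binary_label(y); val_y <- as_binary_label(val_y)
  vel <- rapply(c(model$blocks, list(model$head)), function(p) p * 0,
                how = "list")
  blocks <- model$blocks; head <- model$head
  vel_blocks <- vel[seq_along(blocks)]
  vel_head <- vel[[length(vel)]]
  best <- list(acc = -Inf, blocks = blocks, head = head, epoch = 0L)
  since_improve <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_accuracy = numeric())
  lr <- spec$init_learning_rate
  for (epoch in seq_len(max_epochs)) {
    ord <- with_rng(derive_seed(seed, 500L + epoch), sample.int(n))
    losses <- c()
    i <- 1L
    step <- 0L
    while (i <= n) {
      j <- min(i + spec$batch_size - 1L, n)
      idx <- ord[i:j]
      xb <- x[, , , idx, drop = FALSE]
      yb <- y[idx]
      step <- step + 1L
      m_tmp <- model; m_tmp$blocks <- blocks; m_tmp$head <- head
      fw <- cnn_forward(m_tmp, xb, training = TRUE,
                        drop_seed = derive_seed(seed, epoch * 1000L + step))
      nb <- length(yb)
      p <- fw$prob
      loss <- -mean(log(pmax(p[cbind(seq_len(nb), yb + 1L)], 1e-12)))
      losses <- c(losses, loss)
      # gradient of cross-entropy wrt logits
      dz2 <- p
      dz2[cbind(seq_len(nb), yb + 1L)] <-
        dz2[cbind(seq_len(nb), yb + 1L)] - 1
      dz2 <- dz2 / nb
      g_w2 <- crossprod(fw$feat1, dz2) + spec$l2_penalty * head$w2
      g_b2 <- colSums(dz2)
      dfeat1 <- dz2 %*% t(head$w2)
      if (!is.null(fw$drop_mask)) {
        dfeat1 <- dfeat1 * fw$drop_mask / (1 - spec$dropout_rate)
      }
      g_head <- list(w2 = g_w2, b2 = g_b2)
      if (!spec$gap_head) {
        a1 <- fw$feat %*% head$w1
        a1 <- sweep(a1, 2, head$b1, `+`)
        dz1 <- dfeat1 * (a1 > 0)
        g_head$w1 <- crossprod(fw$feat, dz1) + spec$l2_penalty * head$w1
        g_head$b1 <- colSums(dz1)
        dfeat <- dz1 %*% t(head$w1)
      } else {
        dfeat <- dfeat1
      }
      # back into the conv stack; internal layout is (H, W, N, C)
      hdim <- dim(fw$last_conv)
      if (spec$gap_head) {
        dh <- array(rep(as.vector(dfeat), each = hdim[1] * hdim[2]) /
                      (hdim[1] * hdim[2]), dim = hdim)
      } else {
        dh <- t(dfeat)                               # (H*W*C) x N
        dim(dh) <- c(hdim[1], hdim[2], hdim[4], hdim[3])
        dh <- aperm(dh, c(1, 2, 4, 3))
      }
      g_blocks <- vector("list", length(blocks))
      for (b in rev(seq_along(blocks))) {
        cc <- fw$caches[[b]]
        bl <- blocks[[b]]
        if (bl$pool) {
          dr <- maxpool_backward(cc$pool, cc$r_dim, spec$pool_size, dh)
        } else dr <- dh
        dr <- dr * cc$relu_mask
        bnb <- bn_backward(cc$bn, bl$gamma, dr)
        cv <- conv_backward(cc$x, bl$w, bnb$dx)
        g_blocks[[b]] <- list(w = cv$dw + spec$l2_penalty * bl$w, b = cv$db,
                              gamma = bnb$dgamma, beta = bnb$dbeta)
        dh <- cv$dx
        # commit running BN stats from the forward pass
        blocks[[b]]$run_mean <- cc$bn$run_mean
        blocks[[b]]$run_var <- cc$bn$run_var
      }
      # SGD momentum update
      for (b in seq_along(blocks)) {
        for (p in c("w", "b", "gamma", "beta")) {
          vel_blocks[[b]][[p]] <- spec$momentum * vel_blocks[[b]][[p]] -
            lr * g_blocks[[b]][[p]]
          blocks[[b]][[p]] <- blocks[[b]][[p]] + vel_blocks[[b]][[p]]
        }
      }
      for (p in names(g_head)) {
        vel_head[[p]] <- spec$momentum * vel_head[[p]] - lr * g_head[[p]]
        head[[p]] <- head[[p]] + vel_head[[p]]
      }
      i <- j + 1L
    }
    # precise-BN calibration: set the running statistics to full-batch
    # statistics over (a sample of) the training set before evaluating
    m_eval <- model; m_eval$blocks <- blocks; m_eval$head <- head
    calib_idx <- if (n > 256L)
      with_rng(derive_seed(seed, 900L + epoch), sample.int(n, 256L))
    else seq_len(n)
    calib <- cnn_forward(m_eval, x[, , , calib_idx, drop = FALSE],
                         training = TRUE, drop_seed = 0L, bn_momentum = 0)
    for (b in seq_along(blocks)) {
      blocks[[b]]$run_mean <- calib$caches[[b]]$bn$run_mean
      blocks[[b]]$run_var <- calib$caches[[b]]$bn$run_var
    }
    m_eval$blocks <- blocks
    val_acc <- accuracy(predict_cnn(m_eval, val_x), val_y)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = mean(losses),
                                   val_accuracy = val_acc))
    if (verbose) message(sprintf("epoch %d loss %.4f val %.3f",
                                 epoch, mean(losses), val_acc))
    if (val_acc > best$acc + 1e-12) {
      best <- list(acc = val_acc, blocks = blocks, head = head, epoch = epoch)
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= patience) break
    }
    lr <- lr * spec$lr_decay
  }
  model$blocks <- best$blocks
  model$head <- best$head
  model$history <- hist
  model$best_val_accuracy <- best$acc
  model$trained <- TRUE
  model
}

#' Classifier factory wrapping the CNN for [crossval_predict()]
#'
#' Splits the provided training fold 80/20 into train/validation, trains a
#' fresh CNN and returns a model exposing `predict_score()`.
#'
#' @param spec a [cnn_spec()].
#' @param max_epochs,patience training protocol.
#' @return a factory `function(x, labels, seed)`.
#' @export
cnn_factory <- function(spec, max_epochs = 10L, patience = 3L) {
  force(spec); force(max_epochs); force(patience)
  function(x, labels, seed = 1L) {
    n <- dim(x)[4]
    y <- as_binary_label(labels)
    val_idx <- with_rng(derive_seed(seed, 17L), {
      unlist(lapply(split(seq_len(n), y), function(ix)
        sample(ix, max(1, floor(length(ix) * 0.2)))))
    })
    tr_idx <- setdiff(seq_len(n), val_idx)
    model <- build_cnn(spec, seed = derive_seed(seed, 23L))
    model <- train_cnn(model, x[, , , tr_idx, drop = FALSE], y[tr_idx],
                       x[, , , val_idx, drop = FALSE], y[val_idx],
                       max_epochs = max_epochs, patience = patience,
                       seed = derive_seed(seed, 29L))
    model$predict_score <- function(newdata) predict_cnn(model, newdata)
    model
  }
}
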