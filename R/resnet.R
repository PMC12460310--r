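# A 12-layer residual convolutional network for correlation-image
# classification, implemented directly on BLAS: im2col convolutions, batch
# normalization, ReLU, additive skip connections (y = F(x, W) + x), global
# average pooling and a softmax head, trained by mini-batch SGD with L2
# weight decay. Counted weight layers: stem conv (1) + 5 residual blocks x
# 2 convs (10) + final dense (1) = 12; the two 1x1 projection shortcuts in
# the downsampling blocks are not counted (documented counting rule).
#
# Activations travel in a canonical layout: a (H*W*N) x C matrix whose rows
# run h fastest, then w, then sample n. This makes batch norm and ReLU plain
# column operations and convolution a single gather + matrix multiply.

#' Configuration of the 12-layer residual network
#'
#' @param n_classes number of output classes.
#' @param input_size `c(height, width, channels)` of the input images;
#'   height and width must be at least 16 (the network downsamples 16x).
#' @param filters 5 filter counts: stem and the five residual blocks
#'   (default `16, 16, 32, 32, 64`; blocks 2 and 4 downsample by stride 2
#'   and change width).
#' @param learning_rate SGD learning rate (study setting: 0.01).
#' @param weight_decay L2 weight-decay coefficient lambda (study setting:
#'   1e-4), applied to convolution and dense weights.
#' @param momentum SGD momentum (default 0.9, the standard residual-network
#'   training recipe alongside lr 0.01 and weight decay 1e-4; set 0 for
#'   plain SGD).
#' @param epochs maximum training epochs.
#' @param batch_size mini-batch size.
#' @param seed integer seed for initialization and batch shuffling.
#' @return A validated `resnet_config` list.
#' @export
resnet_config <- function(n_classes = 5L, input_size = c(224L, 224L, 1L),
                          filters = c(16L, 16L, 32L, 32L, 64L),
                          learning_rate = 0.01, weight_decay = 1e-4,
                          momentum = 0.9, epochs = 50L, batch_size = 8L,
                          seed = NULL) {
  if (!is_count(n_classes) || n_classes < 2) stopf("n_classes must be >= 2")
  if (length(input_size) != 3) stopf("input_size must be (H, W, channels)")
  if (min(input_size[1:2]) < 16) {
    stopf("input (%dx%d) smaller than the total downsampling factor (16)",
          input_size[1], input_size[2])
  }
  if (length(filters) != 5) stopf("filters must have length 5")
  if (learning_rate <= 0) stopf("learning rate must be positive")
  if (weight_decay < 0) stopf("weight decay must be non-negative")
  structure(list(n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size),
                 filters = as.integer(filters),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 momentum = momentum, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = seed),
            class = "resnet_config")
}

# ---- module constructors (architecture description) ------------------------

mod_conv <- function(id, k, cin, cout, stride = 1L, pad = (k - 1L) %/% 2L) {
  list(type = "conv", id = id, k = k, cin = cin, cout = cout,
       stride = stride, pad = pad)
}
mod_bn    <- function(id, c) list(type = "bn", id = id, c = c)
mod_relu  <- function() list(type = "relu")
mod_pool  <- function() list(type = "avgpool")
mod_gap   <- function() list(type = "gap")
mod_dense <- function(id, cin, cout) list(type = "dense", id = id,
                                          cin = cin, cout = cout)
mod_seq   <- function(...) list(type = "seq", mods = list(...))

# residual unit y = relu(F(x, W) + shortcut(x)); identity blocks keep shape,
# convolution (downsampling) blocks use a 1x1 stride-2 projection shortcut
mod_resblock <- function(id, cin, cout, downsample = FALSE) {
  st <- if (downsample) 2L else 1L
  body <- mod_seq(mod_conv(paste0(id, ".conv1"), 3L, cin, cout, stride = st),
                  mod_bn(paste0(id, ".bn1"), cout),
                  mod_relu(),
                  mod_conv(paste0(id, ".conv2"), 3L, cout, cout),
                  mod_bn(paste0(id, ".bn2"), cout))
  shortcut <- if (downsample || cin != cout) {
    mod_seq(mod_conv(paste0(id, ".proj"), 1L, cin, cout, stride = st,
                     pad = 0L),
            mod_bn(paste0(id, ".projbn"), cout))
  } else NULL
  list(type = "resblock", id = id, body = body, shortcut = shortcut)
}

#' Build the 12-layer residual network
#'
#' Architecture: stem 3x3 stride-2 convolution + batch norm + ReLU + 2x2
#' average pooling, then five residual units - identity(16), downsample
#' (16 to 32), identity(32), downsample(32 to 64), identity(64), i.e. three
#' identity blocks and two convolution blocks - followed by global average
#' pooling and a dense softmax classifier. Weights use He initialization
#' under the config seed.
#'
#' @param config a [resnet_config()].
#' @return A `resnet` object (architecture + parameter environments) whose
#'   `layer_audit` lists every counted weight layer.
#' @export
build_resnet12 <- function(config) {
  stopifnot(inherits(config, "resnet_config"))
  f <- config$filters
  cin <- config$input_size[3]
  arch <- mod_seq(
    mod_conv("stem.conv", 3L, cin, f[1], stride = 2L),
    mod_bn("stem.bn", f[1]),
    mod_relu(),
    mod_pool(),
    mod_resblock("block1", f[1], f[2], downsample = FALSE),
    mod_resblock("block2", f[2], f[3], downsample = TRUE),
    mod_resblock("block3", f[3], f[4], downsample = FALSE),
    mod_resblock("block4", f[4], f[5], downsample = TRUE),
    mod_resblock("block5", f[5], f[5], downsample = FALSE),
    mod_gap(),
    mod_dense("head.dense", f[5], config$n_classes))
  params <- new.env(parent = emptyenv())
  buffers <- new.env(parent = emptyenv())
  with_seed(config$seed, init_module(arch, params, buffers))
  audit <- layer_audit(arch)
  net <- structure(list(arch = arch, params = params, buffers = buffers,
                        config = config,
                        idx_cache = new.env(parent = emptyenv()),
                        layer_audit = audit,
                        levels = NULL),
                   class = "resnet")
  net
}

init_module <- function(mod, params, buffers) {
  switch(mod$type,
    conv = {
      fan_in <- mod$k * mod$k * mod$cin
      assign(mod$id, list(
        W = matrix(stats::rnorm(fan_in * mod$cout, sd = sqrt(2 / fan_in)),
                   fan_in, mod$cout),
        b = numeric(mod$cout)), envir = params)
    },
    bn = {
      assign(mod$id, list(gamma = rep(1, mod$c), beta = numeric(mod$c)),
             envir = params)
      assign(mod$id, list(mean = numeric(mod$c), var = rep(1, mod$c)),
             envir = buffers)
    },
    dense = {
      assign(mod$id, list(
        W = matrix(stats::rnorm(mod$cin * mod$cout, sd = sqrt(2 / mod$cin)),
                   mod$cin, mod$cout),
        b = numeric(mod$cout)), envir = params)
    },
    seq = for (m in mod$mods) init_module(m, params, buffers),
    resblock = {
      init_module(mod$body, params, buffers)
      if (!is.null(mod$shortcut)) init_module(mod$shortcut, params, buffers)
    })
  invisible(NULL)
}

# counted weight layers (convs in stem/bodies + dense); projection shortcuts
# listed separately
layer_audit <- function(mod, counted = TRUE) {
  out <- list()
  walk <- function(m, counted) {
    switch(m$type,
      conv = out[[length(out) + 1]] <<- data.frame(
        layer = m$id, kind = "conv",
        counted = counted && !grepl("\\.proj$", m$id),
        stringsAsFactors = FALSE),
      dense = out[[length(out) + 1]] <<- data.frame(
        layer = m$id, kind = "dense", counted = TRUE,
        stringsAsFactors = FALSE),
      seq = for (mm in m$mods) walk(mm, counted),
      resblock = {
        walk(m$body, counted)
        if (!is.null(m$shortcut)) walk(m$shortcut, FALSE)
      })
  }
  walk(mod, counted)
  df <- do.call(rbind, out)
  df
}

#' Total trainable parameter count of a network
#'
#' @param net a [build_resnet12()] network.
#' @return Integer count over convolution/dense weights and biases and batch
#'   norm scale/shift parameters.
#' @export
count_parameters <- function(net) {
  stopifnot(inherits(net, "resnet"))
  sum(vapply(ls(net$params), function(id) {
    p <- get(id, envir = net$params)
    sum(vapply(p, length, integer(1)))
  }, numeric(1)))
}

#' @export
print.resnet <- function(x, ...) {
  n_counted <- sum(x$layer_audit$counted)
  cat(sprintf("<resnet> %d counted weight layers, %d classes, input %s, %d parameters\n",
              n_counted, x$config$n_classes,
              paste(x$config$input_size, collapse = "x"),
              count_parameters(x)))
  invisible(x)
}

# ---- im2col index cache ----------------------------------------------------

# gather indices into a padded activation array stored in (Hp, Wp, N, C)
# layout, so that im2col works directly on the canonical (h, w, n) x C
# matrix without any axis permutation
conv_indices <- function(Hp, Wp, Cin, N, k, stride, cache) {
  key <- paste(Hp, Wp, Cin, N, k, stride, sep = "_")
  if (!is.null(cache[[key]])) return(cache[[key]])
  outH <- (Hp - k) %/% stride + 1L
  outW <- (Wp - k) %/% stride + 1L
  pos_r <- (seq_len(outH) - 1L) * stride + 1L
  pos_c <- (seq_len(outW) - 1L) * stride + 1L
  base <- as.vector(outer(pos_r, (pos_c - 1L) * Hp, "+"))      # (oh, ow)
  samp <- (seq_len(N) - 1L) * (Hp * Wp)
  rows <- as.vector(outer(base, samp, "+"))                    # (oh, ow, n)
  off <- rep(0:(k - 1L), times = k * Cin) +
    rep(rep((0:(k - 1L)) * Hp, each = k), times = Cin) +
    rep((0:(Cin - 1L)) * (Hp * Wp * N), each = k * k)          # (ki, kj, ci)
  idx <- outer(rows, off, "+")
  storage.mode(idx) <- "integer"
  val <- list(idx = idx, outH = outH, outW = outW)
  cache[[key]] <- val
  val
}

# column-recycled helpers on canonical matrices (rows fastest, one column
# per channel); cheaper than sweep() for the hot path
col_add <- function(A, v) A + rep(v, each = nrow(A))
col_sub <- function(A, v) A - rep(v, each = nrow(A))
col_mul <- function(A, v) A * rep(v, each = nrow(A))

# ---- forward / backward ----------------------------------------------------

act_spatial <- function(A, H, W, C, N) list(A = A, H = H, W = W, C = C,
                                            N = N, flat = FALSE)

canonical_from_array <- function(X) {
  # X: (H, W, C, N) array -> canonical (h, w, n) x C matrix
  d <- dim(X)
  A <- matrix(aperm(X, c(1, 2, 4, 3)), nrow = d[1] * d[2] * d[4], ncol = d[3])
  act_spatial(A, d[1], d[2], d[3], d[4])
}

# canonical matrix -> zero-padded (Hp, Wp, N, C) array
pad_canonical <- function(A, H, W, C, N, pd) {
  if (pd == 0) {
    arr <- A
    dim(arr) <- c(H, W, N, C)
    return(arr)
  }
  Hp <- H + 2L * pd; Wp <- W + 2L * pd
  arr <- array(0, c(Hp, Wp, N, C))
  x4 <- A
  dim(x4) <- c(H, W, N, C)
  arr[pd + seq_len(H), pd + seq_len(W), , ] <- x4
  arr
}

forward_module <- function(mod, act, net, training) {
  switch(mod$type,
    conv = {
      p <- get(mod$id, envir = net$params)
      H <- act$H; W <- act$W; Cin <- act$C; N <- act$N
      pd <- mod$pad; k <- mod$k
      Hp <- H + 2L * pd; Wp <- W + 2L * pd
      arr <- pad_canonical(act$A, H, W, Cin, N, pd)
      ci <- conv_indices(Hp, Wp, Cin, N, k, mod$stride, net$idx_cache)
      dim(arr) <- NULL  # linear gather (a matrix subscript would be
                        # misread as coordinates when ncol(idx) == 4)
      cols <- arr[ci$idx]
      dim(cols) <- dim(ci$idx)
      out <- col_add(cols %*% p$W, p$b)
      list(act = act_spatial(out, ci$outH, ci$outW, mod$cout, N),
           cache = list(cols = cols, idx = ci$idx, Hp = Hp, Wp = Wp,
                        H = H, W = W, Cin = Cin, N = N, pad = pd))
    },
    bn = {
      p <- get(mod$id, envir = net$params)
      A <- act$A
      eps <- 1e-5
      if (training) {
        mu <- colMeans(A)
        va <- colMeans(A^2) - mu^2
        buf <- get(mod$id, envir = net$buffers)
        assign(mod$id, list(mean = 0.9 * buf$mean + 0.1 * mu,
                            var = 0.9 * buf$var + 0.1 * va),
               envir = net$buffers)
      } else {
        buf <- get(mod$id, envir = net$buffers)
        mu <- buf$mean; va <- buf$var
      }
      istd <- 1 / sqrt(va + eps)
      xhat <- col_mul(col_sub(A, mu), istd)
      act$A <- col_add(col_mul(xhat, p$gamma), p$beta)
      list(act = act, cache = list(xhat = xhat, istd = istd,
                                   training = training))
    },
    relu = {
      mask <- act$A > 0
      act$A <- act$A * mask
      list(act = act, cache = list(mask = mask))
    },
    avgpool = {
      H <- act$H; W <- act$W; C <- act$C; N <- act$N
      H2 <- H %/% 2L; W2 <- W %/% 2L
      x4 <- array(act$A, c(H, W, N, C))
      io <- seq_len(H2) * 2L - 1L; jo <- seq_len(W2) * 2L - 1L
      pooled <- (x4[io, jo, , , drop = FALSE] +
                 x4[io + 1L, jo, , , drop = FALSE] +
                 x4[io, jo + 1L, , , drop = FALSE] +
                 x4[io + 1L, jo + 1L, , , drop = FALSE]) / 4
      A2 <- matrix(pooled, nrow = H2 * W2 * N, ncol = C)
      list(act = act_spatial(A2, H2, W2, C, N),
           cache = list(H = H, W = W, C = C, N = N))
    },
    gap = {
      H <- act$H; W <- act$W; C <- act$C; N <- act$N
      arr <- array(act$A, c(H * W, N, C))
      out <- colMeans(arr, dims = 1)           # N x C
      if (is.null(dim(out))) out <- matrix(out, N, C)
      list(act = list(A = out, N = N, C = C, flat = TRUE),
           cache = list(H = H, W = W, C = C, N = N))
    },
    dense = {
      p <- get(mod$id, envir = net$params)
      out <- sweep(act$A %*% p$W, 2, p$b, "+")
      list(act = list(A = out, N = act$N, C = mod$cout, flat = TRUE),
           cache = list(X = act$A))
    },
    seq = {
      caches <- vector("list", length(mod$mods))
      for (i in seq_along(mod$mods)) {
        r <- forward_module(mod$mods[[i]], act, net, training)
        act <- r$act
        caches[[i]] <- r$cache
      }
      list(act = act, cache = caches)
    },
    resblock = {
      rb <- forward_module(mod$body, act, net, training)
      if (is.null(mod$shortcut)) {
        sc_act <- act
        sc_cache <- NULL
      } else {
        rs <- forward_module(mod$shortcut, act, net, training)
        sc_act <- rs$act
        sc_cache <- rs$cache
      }
      summed <- rb$act
      summed$A <- rb$act$A + sc_act$A
      mask <- summed$A > 0
      summed$A <- summed$A * mask
      list(act = summed, cache = list(body = rb$cache, shortcut = sc_cache,
                                      mask = mask))
    })
}

backward_module <- function(mod, cache, dact, net, grads) {
  switch(mod$type,
    conv = {
      p <- get(mod$id, envir = net$params)
      dY <- dact$A
      dW <- crossprod(cache$cols, dY)
      db <- colSums(dY)
      acc_grad(grads, mod$id, list(W = dW, b = db))
      dcols <- dY %*% t(p$W)
      dXp <- numeric(cache$Hp * cache$Wp * cache$Cin * cache$N)
      idx <- cache$idx
      for (j in seq_len(ncol(idx))) {
        ii <- idx[, j]
        dXp[ii] <- dXp[ii] + dcols[, j]
      }
      dim(dXp) <- c(cache$Hp, cache$Wp, cache$N, cache$Cin)
      pd <- cache$pad
      if (pd > 0) {
        dXp <- dXp[pd + seq_len(cache$H), pd + seq_len(cache$W), , ,
                   drop = FALSE]
      }
      dim(dXp) <- c(cache$H * cache$W * cache$N, cache$Cin)
      act_spatial(dXp, cache$H, cache$W, cache$Cin, cache$N)
    },
    bn = {
      p <- get(mod$id, envir = net$params)
      dY <- dact$A
      xhat <- cache$xhat
      M <- nrow(dY)
      dgamma <- colSums(dY * xhat)
      dbeta <- colSums(dY)
      acc_grad(grads, mod$id, list(gamma = dgamma, beta = dbeta))
      if (cache$training) {
        t1 <- col_sub(M * dY, dbeta) - col_mul(xhat, dgamma)
        dX <- col_mul(t1, p$gamma * cache$istd / M)
      } else {
        dX <- col_mul(dY, p$gamma * cache$istd)
      }
      dact$A <- dX
      dact
    },
    relu = {
      dact$A <- dact$A * cache$mask
      dact
    },
    avgpool = {
      H <- cache$H; W <- cache$W; C <- cache$C; N <- cache$N
      H2 <- H %/% 2L; W2 <- W %/% 2L
      dp <- array(dact$A, c(H2, W2, N, C)) / 4
      dX4 <- array(0, c(H, W, N, C))
      io <- seq_len(H2) * 2L - 1L; jo <- seq_len(W2) * 2L - 1L
      dX4[io, jo, , ] <- dp
      dX4[io + 1L, jo, , ] <- dp
      dX4[io, jo + 1L, , ] <- dp
      dX4[io + 1L, jo + 1L, , ] <- dp
      act_spatial(matrix(dX4, nrow = H * W * N, ncol = C), H, W, C, N)
    },
    gap = {
      H <- cache$H; W <- cache$W; C <- cache$C; N <- cache$N
      dA <- dact$A[rep(seq_len(N), each = H * W), , drop = FALSE] / (H * W)
      act_spatial(dA, H, W, C, N)
    },
    dense = {
      p <- get(mod$id, envir = net$params)
      dY <- dact$A
      acc_grad(grads, mod$id, list(W = crossprod(cache$X, dY),
                                   b = colSums(dY)))
      list(A = dY %*% t(p$W), N = dact$N, C = ncol(p$W), flat = TRUE)
    },
    seq = {
      for (i in rev(seq_along(mod$mods))) {
        dact <- backward_module(mod$mods[[i]], cache[[i]], dact, net, grads)
      }
      dact
    },
    resblock = {
      dact$A <- dact$A * cache$mask
      d_body <- backward_module(mod$body, cache$body, dact, net, grads)
      d_skip <- if (is.null(mod$shortcut)) dact else
        backward_module(mod$shortcut, cache$shortcut, dact, net, grads)
      d_body$A <- d_body$A + d_skip$A
      d_body
    })
}

acc_grad <- function(grads, id, g) {
  if (is.null(grads[[id]])) {
    grads[[id]] <- g
  } else {
    grads[[id]] <- mapply(`+`, grads[[id]], g, SIMPLIFY = FALSE)
  }
  invisible(NULL)
}

softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Class probabilities for a batch of images
#'
#' @param net a [build_resnet12()] network.
#' @param images array `H x W x N` (single channel) or `H x W x C x N`.
#' @param batch_size evaluation chunk size (memory control).
#' @return `N x n_classes` matrix of softmax probabilities (rows sum to 1).
#' @export
predict_resnet <- function(net, images, batch_size = 16L) {
  stopifnot(inherits(net, "resnet"))
  X <- images_to_array(images, net$config$input_size)
  N <- dim(X)[4]
  out <- matrix(0, N, net$config$n_classes)
  for (start in seq(1, N, by = batch_size)) {
    sel <- start:min(start + batch_size - 1, N)
    act <- canonical_from_array(X[, , , sel, drop = FALSE])
    r <- forward_module(net$arch, act, net, training = FALSE)
    out[sel, ] <- softmax(r$act$A)
  }
  colnames(out) <- net$levels %||% seq_len(ncol(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

images_to_array <- function(images, input_size) {
  d <- dim(images)
  if (length(d) == 3) {
    images <- array(images, c(d[1], d[2], 1L, d[3]))
    d <- dim(images)
  }
  if (length(d) != 4) stopf("images must be HxWxN or HxWxCxN")
  if (d[1] != input_size[1] || d[2] != input_size[2] ||
      d[3] != input_size[3]) {
    stopf("image size %dx%dx%d does not match configured input %dx%dx%d",
          d[1], d[2], d[3], input_size[1], input_size[2], input_size[3])
  }
  images
}

#' Train the residual network
#'
#' Mini-batch stochastic gradient descent on softmax cross-entropy with L2
#' weight decay on convolution and dense weights. Records per-epoch training
#' loss/accuracy (running average over batches) and, when a test set is
#' given, test loss/accuracy computed with running batch-norm statistics.
#' Fixed seeds make runs reproducible on one device.
#'
#' @param net a [build_resnet12()] network (updated in place and returned).
#' @param images training images, `H x W x N` or `H x W x C x N`.
#' @param labels factor of training labels (length N).
#' @param test_images,test_labels optional held-out set evaluated each epoch.
#' @param epochs,batch_size,learning_rate,weight_decay,momentum,seed override
#'   the corresponding `resnet_config` settings when non-`NULL`.
#' @param stop_at_perfect stop early once training and test accuracy both
#'   reach 100% (the reported figure is the best test accuracy either way).
#' @param verbose print one line per epoch.
#' @return List with the trained `net`, `curves` (data frame of per-epoch
#'   loss/accuracy), `best_test_acc`, `best_epoch`, and `epochs_run`.
#' @export
train_resnet <- function(net, images, labels,
                         test_images = NULL, test_labels = NULL,
                         epochs = NULL, batch_size = NULL,
                         learning_rate = NULL, weight_decay = NULL,
                         momentum = NULL, seed = NULL,
                         stop_at_perfect = TRUE, verbose = FALSE) {
  stopifnot(inherits(net, "resnet"))
  cfg <- net$config
  epochs <- epochs %||% cfg$epochs
  batch_size <- batch_size %||% cfg$batch_size
  lr <- learning_rate %||% cfg$learning_rate
  wd <- weight_decay %||% cfg$weight_decay
  mom <- momentum %||% cfg$momentum
  seed <- seed %||% cfg$seed
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stopf("training needs >= 2 classes")
  if (nlevels(labels) != cfg$n_classes) {
    stopf("labels have %d levels but the network has %d classes",
          nlevels(labels), cfg$n_classes)
  }
  net$levels <- levels(labels)
  X <- images_to_array(images, cfg$input_size)
  N <- dim(X)[4]
  if (length(labels) != N) stopf("labels length does not match image count")
  y <- as.integer(labels)
  K <- cfg$n_classes
  velocity <- new.env(parent = emptyenv())
  curves <- data.frame(epoch = integer(), train_loss = numeric(),
                       train_acc = numeric(), test_loss = numeric(),
                       test_acc = numeric())
  best_test_acc <- NA_real_; best_epoch <- NA_integer_
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1, N, by = batch_size)) {
        sel <- ord[start:min(start + batch_size - 1, N)]
        nb <- length(sel)
        act <- canonical_from_array(X[, , , sel, drop = FALSE])
        fw <- forward_module(net$arch, act, net, training = TRUE)
        logits <- fw$act$A
        prob <- softmax(logits)
        yb <- y[sel]
        pt <- prob[cbind(seq_len(nb), yb)]
        loss <- -mean(log(pmax(pt, 1e-12)))
        if (!is.finite(loss)) {
          stopf("non-finite training loss at epoch %d (lr too high or degenerate input)", ep)
        }
        ep_loss <- ep_loss + loss * nb
        ep_correct <- ep_correct + sum(max.col(prob, "first") == yb)
        dlogits <- prob
        dlogits[cbind(seq_len(nb), yb)] <-
          dlogits[cbind(seq_len(nb), yb)] - 1
        dlogits <- dlogits / nb
        grads <- new.env(parent = emptyenv())
        backward_module(net$arch, fw$cache, list(A = dlogits, N = nb, C = K,
                                                 flat = TRUE),
                        net, grads)
        sgd_step(net, grads, velocity, lr, wd, mom)
      }
      tr_loss <- ep_loss / N
      tr_acc <- ep_correct / N
      te_loss <- NA_real_; te_acc <- NA_real_
      if (!is.null(test_images)) {
        ev <- evaluate_loss_acc(net, test_images, test_labels)
        te_loss <- ev$loss; te_acc <- ev$acc
        if (is.na(best_test_acc) || te_acc > best_test_acc) {
          best_test_acc <- te_acc; best_epoch <- ep
        }
      }
      curves <- rbind(curves, data.frame(
        epoch = ep, train_loss = tr_loss, train_acc = tr_acc,
        test_loss = te_loss, test_acc = te_acc))
      if (verbose) {
        message(sprintf("epoch %3d  train loss %.4f acc %.3f  test acc %s",
                        ep, tr_loss, tr_acc,
                        if (is.na(te_acc)) "-" else sprintf("%.3f", te_acc)))
      }
      if (isTRUE(stop_at_perfect) && tr_acc >= 1 &&
          (!is.null(test_images) && !is.na(te_acc) && te_acc >= 1)) {
        break
      }
    }
  })
  list(net = net, curves = curves, best_test_acc = best_test_acc,
       best_epoch = best_epoch, epochs_run = nrow(curves))
}

sgd_step <- function(net, grads, velocity, lr, wd, mom) {
  for (id in ls(grads)) {
    p <- get(id, envir = net$params)
    g <- grads[[id]]
    # L2 weight decay on conv/dense weight matrices only
    if (!is.null(g$W)) g$W <- g$W + wd * p$W
    if (mom > 0) {
      v <- if (is.null(velocity[[id]])) lapply(g, function(x) x * 0) else
        velocity[[id]]
      v <- mapply(function(vv, gg) mom * vv + gg, v, g, SIMPLIFY = FALSE)
      velocity[[id]] <- v
      g <- v
    }
    upd <- mapply(function(pp, gg) pp - lr * gg, p, g, SIMPLIFY = FALSE)
    assign(id, upd, envir = net$params)
  }
  invisible(NULL)
}

evaluate_loss_acc <- function(net, images, labels) {
  prob <- predict_resnet(net, images)
  labels <- factor(labels, levels = net$levels)
  y <- as.integer(labels)
  pt <- prob[cbind(seq_along(y), y)]
  list(loss = -mean(log(pmax(pt, 1e-12))),
       acc = mean(max.col(prob, "first") == y))
}

#' Tally predictions into a confusion matrix
#'
#' @param net a trained network.
#' @param images evaluation images.
#' @param labels true labels (must use the training levels).
#' @return `K x K` integer matrix, rows = true class, columns = predicted.
#' @export
evaluate_resnet <- function(net, images, labels) {
  stopifnot(inherits(net, "resnet"))
  if (is.null(net$levels)) stopf("network has not been trained")
  labels <- factor(labels, levels = net$levels)
  if (anyNA(labels)) stopf("labels outside the trained classes")
  prob <- predict_resnet(net, images)
  pred <- factor(net$levels[max.col(prob, "first")], levels = net$levels)
  conf <- table(truth = labels, predicted = pred)
  conf <- matrix(as.integer(conf), nrow(conf), ncol(conf),
                 dimnames = dimnames(conf))
  conf
}

#' Classification metrics from a confusion matrix
#'
#' One-vs-rest tallies per class `c`: `TP = conf[c, c]`, `FP = colsum - TP`,
#' `FN = rowsum - TP`, `TN = total - TP - FP - FN`; then overall accuracy
#' `sum(diag)/total`, and per-class precision `TP/(TP+FP)`, sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)` with unweighted macro averages.
#' A 0/0 ratio is reported as `NaN` and flagged in `undefined`.
#'
#' @param conf square non-negative integer matrix, rows = true class,
#'   columns = predicted class.
#' @return List with `accuracy`, `per_class` data frame (tp/fp/fn/tn,
#'   precision, sensitivity, specificity), `macro` (named numeric vector),
#'   and `undefined` (logical matrix flagging 0/0 entries).
#' @export
confusion_metrics <- function(conf) {
  conf <- as.matrix(conf)
  if (nrow(conf) != ncol(conf)) stopf("confusion matrix must be square")
  if (any(conf < 0)) stopf("confusion counts must be non-negative")
  total <- sum(conf)
  if (total == 0) stopf("empty confusion matrix")
  k <- nrow(conf)
  tp <- diag(conf)
  fp <- colSums(conf) - tp
  fn <- rowSums(conf) - tp
  tn <- total - tp - fp - fn
  ratio <- function(a, b) ifelse(a + b == 0, NaN, a / (a + b))
  pre <- ratio(tp, fp)
  sen <- ratio(tp, fn)
  spe <- ratio(tn, fp)
  classes <- rownames(conf) %||% as.character(seq_len(k))
  per_class <- data.frame(class = classes, tp = tp, fp = fp, fn = fn,
                          tn = tn, precision = pre, sensitivity = sen,
                          specificity = spe, row.names = NULL)
  undefined <- cbind(precision = is.nan(pre), sensitivity = is.nan(sen),
                     specificity = is.nan(spe))
  rownames(undefined) <- classes
  list(accuracy = sum(tp) / total,
       per_class = per_class,
       macro = c(precision = mean(pre, na.rm = TRUE),
                 sensitivity = mean(sen, na.rm = TRUE),
                 specificity = mean(spe, na.rm = TRUE)),
       undefined = undefined)
}

#' Exponential moving-average smoothing of a training curve
#'
#' `out[1] = values[1]`; `out[i] = alpha * out[i-1] + (1 - alpha) *
#' values[i]`. `alpha = 0` returns the input unchanged; the study's display
#' setting is `alpha = 0.6`. Display-only: reported accuracies are never
#' smoothed.
#'
#' @param values numeric series (e.g. per-epoch accuracy).
#' @param alpha smoothing parameter in `[0, 1)`.
#' @return Smoothed numeric series of the same length.
#' @export
smooth_curve <- function(values, alpha = 0.6) {
  if (alpha < 0 || alpha >= 1) stopf("alpha must be in [0, 1)")
  if (length(values) == 0) return(values)
  out <- values
  for (i in seq_along(values)[-1]) {
    out[i] <- alpha * out[i - 1] + (1 - alpha) * values[i]
  }
  out
}
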