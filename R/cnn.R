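# The patch classifier: a small CNN (two classes, 33x33 grayscale input)
#
#   conv 5x5x1->32  | bn | maxpool 3x3/2 | relu
#   conv 5x5x32->32 | bn | relu | avgpool 3x3/2
#   conv 5x5x32->64 | bn | relu | avgpool 3x3/2
#   fc 4*4*64->64   | bn | relu
#   fc 64->2        | softmax
#
# Convolutions are stride 1 with zero pad 2 (spatial size preserved); the
# stride-2 pools take 33->16->8->4, padding a single trailing row/column
# where needed. Class order is fixed: column 1 = "noncone", column 2 = "cone".

CNN_CLASSES <- c("noncone", "cone")

# expected activation sizes after each named stage, for a single patch
CNN_SHAPES <- list(
  input  = c(33, 33, 1),  conv1 = c(33, 33, 32), bn1  = c(33, 33, 32),
  pool1  = c(16, 16, 32), relu1 = c(16, 16, 32), conv2 = c(16, 16, 32),
  bn2    = c(16, 16, 32), relu2 = c(16, 16, 32), pool2 = c(8, 8, 32),
  conv3  = c(8, 8, 64),   bn3   = c(8, 8, 64),   relu3 = c(8, 8, 64),
  pool3  = c(4, 4, 64),   fc1   = c(1, 1, 64),   bn4   = c(1, 1, 64),
  relu4  = c(1, 1, 64),   fc2   = c(1, 1, 2),    softmax = c(1, 1, 2))

CNN_PARAM_SHAPES <- list(
  conv1_w = c(5, 5, 1, 32),  conv1_b = 32,
  bn1_g = 32, bn1_b = 32, bn1_rm = 32, bn1_rv = 32,
  conv2_w = c(5, 5, 32, 32), conv2_b = 32,
  bn2_g = 32, bn2_b = 32, bn2_rm = 32, bn2_rv = 32,
  conv3_w = c(5, 5, 32, 64), conv3_b = 64,
  bn3_g = 64, bn3_b = 64, bn3_rm = 64, bn3_rv = 64,
  fc1_w = c(64, 1024), fc1_b = 64,
  bn4_g = 64, bn4_b = 64, bn4_rm = 64, bn4_rv = 64,
  fc2_w = c(2, 64), fc2_b = 2)

#' Training configuration for the cone classifier
#'
#' Defaults follow the published schedule: plain SGD over 45 epochs with
#' mini-batches of 100 patches, weight learning rate 0.001 (0.0001 for the
#' final fully connected layer), bias learning rate 0.1 (0.01 for the final
#' fully connected layer), both dropped by a factor of 10 entering epochs 31
#' and 41, and weight decay 0.0001. Momentum 0.9 (the training toolbox
#' default of the era) can be set to 0 for textbook SGD.
#'
#' @param epochs number of passes over the training set.
#' @param minibatch_size patches per gradient step.
#' @param lr_w,lr_w_final weight learning rates (all layers / final FC).
#' @param lr_b,lr_b_final bias learning rates (all layers / final FC).
#' @param lr_drop_epochs epochs at which all rates are divided by
#'   `lr_drop_factor`; must be < `epochs`.
#' @param lr_drop_factor learning-rate drop factor.
#' @param weight_decay L2 penalty applied to convolution/FC weights.
#' @param momentum SGD momentum (0 disables).
#' @param init_sd std of the zero-mean Gaussian weight initialisation.
#' @param bn_eps,bn_momentum batch-norm epsilon and running-statistics
#'   exponential-moving-average weight.
#' @param seed RNG seed covering initialisation and batch shuffling.
#' @return A list of class `cnn_config`.
#' @export
cnn_config <- function(epochs = 45L, minibatch_size = 100L,
                       lr_w = 1e-3, lr_w_final = 1e-4,
                       lr_b = 0.1, lr_b_final = 0.01,
                       lr_drop_epochs = c(31L, 41L), lr_drop_factor = 10,
                       weight_decay = 1e-4, momentum = 0.9,
                       init_sd = 0.01, bn_eps = 1e-5, bn_momentum = 0.1,
                       seed = 0L) {
  stopifnot(epochs >= 1, minibatch_size >= 2,
            lr_w > 0, lr_w_final > 0, lr_b > 0, lr_b_final > 0,
            lr_drop_factor > 1, weight_decay >= 0,
            momentum >= 0, momentum < 1, init_sd > 0, bn_eps > 0)
  lr_drop_epochs <- as.integer(lr_drop_epochs)
  if (length(lr_drop_epochs) && any(lr_drop_epochs >= epochs))
    stop("learning-rate drop epochs must be smaller than `epochs`")
  structure(list(epochs = as.integer(epochs),
                 minibatch_size = as.integer(minibatch_size),
                 lr_w = lr_w, lr_w_final = lr_w_final,
                 lr_b = lr_b, lr_b_final = lr_b_final,
                 lr_drop_epochs = lr_drop_epochs,
                 lr_drop_factor = lr_drop_factor,
                 weight_decay = weight_decay, momentum = momentum,
                 init_sd = init_sd, bn_eps = bn_eps,
                 bn_momentum = bn_momentum, seed = as.integer(seed)),
            class = "cnn_config")
}

# fresh parameters: Gaussian weights, zero biases, unit gammas
cnn_init_params <- function(seed, init_sd) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  par <- list()
  for (nm in names(CNN_PARAM_SHAPES)) {
    sh <- CNN_PARAM_SHAPES[[nm]]
    par[[nm]] <-
      if (grepl("_w$", nm)) {
        if (length(sh) == 4L) array(rnorm(prod(sh), sd = init_sd), dim = sh)
        else matrix(rnorm(prod(sh), sd = init_sd), sh[1], sh[2])
      } else if (grepl("_g$", nm) || grepl("_rv$", nm)) rep(1.0, sh)
      else rep(0.0, sh)
  }
  par
}

#' Build an untrained cone classifier
#'
#' Constructs the network with randomly initialised weights (zero-mean
#' Gaussian), zero biases and identity batch-norm statistics. Mostly useful
#' for testing the forward pass; [cone_cnn()] fits a network from patches.
#'
#' @param seed RNG seed for the weight initialisation.
#' @param init_sd weight initialisation standard deviation.
#' @return An object of class `cone_cnn` with `trained = FALSE`.
#' @export
init_network <- function(seed = 0L, init_sd = 0.01) {
  structure(list(par = cnn_init_params(seed, init_sd),
                 config = cnn_config(seed = as.integer(seed),
                                     init_sd = init_sd),
                 classes = CNN_CLASSES, trained = FALSE,
                 history = NULL, detection_params = NULL,
                 normalization = "minmax-0-255"),
            class = "cone_cnn")
}

# forward pass; x is [33,33,1,N]; returns probs (N x 2) and, when
# keep_cache, every intermediate needed for backprop
cnn_forward <- function(par, x, training, eps, keep_cache = FALSE) {
  N <- dim(x)[4]
  a1 <- conv2d_fwd(x, par$conv1_w, par$conv1_b, 2L)
  if (training) {
    s1 <- bn_fwd(a1, par$bn1_g, par$bn1_b, eps); y1 <- s1$y
  } else y1 <- bn_infer(a1, par$bn1_g, par$bn1_b, par$bn1_rm, par$bn1_rv, eps)
  p1 <- pool3s2_fwd(y1, "max")
  r1 <- relu_fwd(p1$y)
  a2 <- conv2d_fwd(r1, par$conv2_w, par$conv2_b, 2L)
  if (training) {
    s2 <- bn_fwd(a2, par$bn2_g, par$bn2_b, eps); y2 <- s2$y
  } else y2 <- bn_infer(a2, par$bn2_g, par$bn2_b, par$bn2_rm, par$bn2_rv, eps)
  r2 <- relu_fwd(y2)
  p2 <- pool3s2_fwd(r2, "avg")
  a3 <- conv2d_fwd(p2$y, par$conv3_w, par$conv3_b, 2L)
  if (training) {
    s3 <- bn_fwd(a3, par$bn3_g, par$bn3_b, eps); y3 <- s3$y
  } else y3 <- bn_infer(a3, par$bn3_g, par$bn3_b, par$bn3_rm, par$bn3_rv, eps)
  r3 <- relu_fwd(y3)
  p3 <- pool3s2_fwd(r3, "avg")
  f <- matrix(p3$y, 1024L, N)
  z1 <- par$fc1_w %*% f + par$fc1_b
  z1a <- array(z1, c(1L, 1L, 64L, N))
  if (training) {
    s4 <- bn_fwd(z1a, par$bn4_g, par$bn4_b, eps); y4 <- s4$y
  } else y4 <- bn_infer(z1a, par$bn4_g, par$bn4_b, par$bn4_rm, par$bn4_rv, eps)
  r4 <- relu_fwd(y4)
  m4 <- matrix(r4, 64L, N)
  z2 <- par$fc2_w %*% m4 + par$fc2_b
  zs <- sweep(z2, 2L, apply(z2, 2L, max))
  ez <- exp(zs)
  probs <- t(sweep(ez, 2L, colSums(ez), "/"))
  colnames(probs) <- CNN_CLASSES
  out <- list(probs = probs)
  if (keep_cache)
    out$cache <- list(x = x, a1 = a1, s1 = s1, y1 = y1, p1 = p1, r1 = r1,
                      a2 = a2, s2 = s2, y2 = y2, r2 = r2, p2 = p2,
                      a3 = a3, s3 = s3, y3 = y3, r3 = r3, p3 = p3,
                      f = f, z1a = z1a, s4 = s4, y4 = y4, m4 = m4)
  out
}

# gradients of the mean cross-entropy w.r.t. every learnable parameter;
# y_onehot is 2 x N (rows in CNN_CLASSES order)
cnn_backward <- function(par, cache, probs, y_onehot, eps) {
  N <- ncol(y_onehot)
  g <- list()
  dz2 <- (t(probs) - y_onehot) / N
  g$fc2_w <- dz2 %*% t(cache$m4)
  g$fc2_b <- rowSums(dz2)
  dm4 <- t(par$fc2_w) %*% dz2
  dr4 <- relu_bwd(cache$y4, array(dm4, dim(cache$y4)))
  b4 <- bn_bwd(cache$z1a, par$bn4_g, cache$s4$mean, cache$s4$var, dr4, eps)
  g$bn4_g <- b4$dgamma; g$bn4_b <- b4$dbeta
  dz1 <- matrix(b4$dx, 64L, N)
  g$fc1_w <- dz1 %*% t(cache$f)
  g$fc1_b <- rowSums(dz1)
  df <- t(par$fc1_w) %*% dz1
  dp3 <- array(df, dim(cache$p3$y))
  dr3 <- pool3s2_bwd(dp3, dim(cache$r3), "avg", integer(0))
  dy3 <- relu_bwd(cache$y3, dr3)
  b3 <- bn_bwd(cache$a3, par$bn3_g, cache$s3$mean, cache$s3$var, dy3, eps)
  g$bn3_g <- b3$dgamma; g$bn3_b <- b3$dbeta
  c3 <- conv2d_bwd(cache$p2$y, par$conv3_w, b3$dx, 2L, TRUE)
  g$conv3_w <- c3$dw; g$conv3_b <- c3$db
  dr2 <- pool3s2_bwd(c3$dx, dim(cache$r2), "avg", integer(0))
  dy2 <- relu_bwd(cache$y2, dr2)
  b2 <- bn_bwd(cache$a2, par$bn2_g, cache$s2$mean, cache$s2$var, dy2, eps)
  g$bn2_g <- b2$dgamma; g$bn2_b <- b2$dbeta
  c2 <- conv2d_bwd(cache$r1, par$conv2_w, b2$dx, 2L, TRUE)
  g$conv2_w <- c2$dw; g$conv2_b <- c2$db
  dp1 <- relu_bwd(cache$p1$y, c2$dx)
  dy1 <- pool3s2_bwd(dp1, dim(cache$y1), "max", cache$p1$idx)
  b1 <- bn_bwd(cache$a1, par$bn1_g, cache$s1$mean, cache$s1$var, dy1, eps)
  g$bn1_g <- b1$dgamma; g$bn1_b <- b1$dbeta
  c1 <- conv2d_bwd(cache$x, par$conv1_w, b1$dx, 2L, FALSE)
  g$conv1_w <- c1$dw; g$conv1_b <- c1$db
  g
}

# Recompute batch-norm inference statistics as exact population moments over
# the training set with the final weights. Layer i's input depends on the
# finalized statistics of layers < i, so the set is swept once per bn layer.
# Fixed internal batch size keeps the accumulation order deterministic.
cnn_finalize_bn <- function(par, x_all, eps, batch = 500L) {
  N <- dim(x_all)[4]
  starts <- seq(1L, N, by = batch)
  for (layer in 1:4) {
    s <- 0; ss <- 0; count <- 0
    for (b in starts) {
      take <- b:min(b + batch - 1L, N)
      x <- x_all[, , , take, drop = FALSE]
      a <- conv2d_fwd(x, par$conv1_w, par$conv1_b, 2L)
      if (layer > 1) {
        y1 <- bn_infer(a, par$bn1_g, par$bn1_b, par$bn1_rm, par$bn1_rv, eps)
        r1 <- relu_fwd(pool3s2_fwd(y1, "max")$y)
        a <- conv2d_fwd(r1, par$conv2_w, par$conv2_b, 2L)
      }
      if (layer > 2) {
        y2 <- bn_infer(a, par$bn2_g, par$bn2_b, par$bn2_rm, par$bn2_rv, eps)
        p2 <- pool3s2_fwd(relu_fwd(y2), "avg")$y
        a <- conv2d_fwd(p2, par$conv3_w, par$conv3_b, 2L)
      }
      if (layer > 3) {
        y3 <- bn_infer(a, par$bn3_g, par$bn3_b, par$bn3_rm, par$bn3_rv, eps)
        p3 <- pool3s2_fwd(relu_fwd(y3), "avg")$y
        z1 <- par$fc1_w %*% matrix(p3, 1024L, length(take)) + par$fc1_b
        a <- array(z1, c(1L, 1L, 64L, length(take)))
      }
      d <- dim(a)
      m <- matrix(aperm(a, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
      s <- s + colSums(m)
      ss <- ss + colSums(m^2)
      count <- count + nrow(m)
    }
    mu <- s / count
    par[[sprintf("bn%d_rm", layer)]] <- mu
    par[[sprintf("bn%d_rv", layer)]] <- ss / count - mu^2
  }
  par
}

# per-parameter learning-rate multipliers and weight-decay flags
cnn_param_groups <- function(cfg) {
  nms <- names(CNN_PARAM_SHAPES)
  nms <- nms[!grepl("_(rm|rv)$", nms)]
  out <- lapply(nms, function(nm) {
    if (nm == "fc2_w") list(lr = cfg$lr_w_final, wd = cfg$weight_decay)
    else if (nm == "fc2_b") list(lr = cfg$lr_b_final, wd = 0)
    else if (grepl("_w$", nm)) list(lr = cfg$lr_w, wd = cfg$weight_decay)
    else if (grepl("^bn", nm)) list(lr = cfg$lr_w, wd = 0)  # bn scale/shift
    else list(lr = cfg$lr_b, wd = 0)
  })
  names(out) <- nms
  out
}

#' Fit the cone / non-cone patch classifier
#'
#' Trains the network by stochastic gradient descent with
#' back-propagation: the patch set is reshuffled every epoch, split into
#' mini-batches, and every convolution/FC/batch-norm parameter is updated
#' under the per-layer learning-rate schedule of [cnn_config()]. Batch-norm
#' running statistics are tracked as exponential moving averages during
#' training and then replaced by exact population moments over the training
#' set with the final weights, so the inference path is reliable even after
#' short training runs. Training is bit-reproducible under a fixed seed on
#' a single thread.
#'
#' @param patches a [patch_set()] containing both classes, intensities on
#'   the normalized 0--255 scale.
#' @param config a [cnn_config()].
#' @param verbose print a per-epoch log line (epoch, mean loss, accuracy).
#' @return An object of class `cone_cnn`: list with elements `par` (learned
#'   parameters), `config`, `history` (per-epoch loss/accuracy data frame),
#'   `classes` (`c("noncone", "cone")`), `trained`, `detection_params`
#'   (NULL until set by [optimize_params()]/[set_detection_params()]).
#' @seealso [predict.cone_cnn()], [detect_cones()], [save_model()]
#' @export
cone_cnn <- function(patches, config = cnn_config(), verbose = FALSE) {
  stopifnot(inherits(patches, "patch_set"), inherits(config, "cnn_config"))
  labs <- patches$labels
  if (length(unique(labs)) < 2L)
    stop("training set must contain both cone and non-cone patches")
  N <- length(labs)
  x_all <- array(patches$patches, c(PATCH_SIZE, PATCH_SIZE, 1L, N))
  y_all <- rbind(noncone = as.numeric(labs == "noncone"),
                 cone    = as.numeric(labs == "cone"))
  net <- init_network(config$seed, config$init_sd)
  net$config <- config
  par <- net$par
  groups <- cnn_param_groups(config)
  vel <- lapply(groups, function(g) 0)
  eps <- config$bn_eps
  bnm <- config$bn_momentum
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        accuracy = numeric())
  for (epoch in seq_len(config$epochs)) {
    drop_pow <- sum(config$lr_drop_epochs <= epoch)
    lr_scale <- config$lr_drop_factor^(-drop_pow)
    ord <- sample.int(N)
    starts <- seq(1L, N, by = config$minibatch_size)
    ep_loss <- 0; ep_correct <- 0
    for (s in starts) {
      take <- ord[s:min(s + config$minibatch_size - 1L, N)]
      nb <- length(take)
      xb <- x_all[, , , take, drop = FALSE]
      yb <- y_all[, take, drop = FALSE]
      fw <- cnn_forward(par, xb, training = TRUE, eps = eps,
                        keep_cache = TRUE)
      pcorr <- colSums(t(fw$probs) * yb)
      loss <- -mean(log(pmax(pcorr, 1e-12)))
      if (!is.finite(loss))
        stop(sprintf("training diverged (non-finite loss) at epoch %d, batch %d",
                     epoch, which(starts == s)))
      ep_loss <- ep_loss + loss * nb
      ep_correct <- ep_correct + sum(max.col(fw$probs) == max.col(t(yb)))
      grads <- cnn_backward(par, fw$cache, fw$probs, yb, eps)
      for (nm in names(groups)) {
        gset <- groups[[nm]]
        gr <- grads[[nm]] + gset$wd * par[[nm]]
        vel[[nm]] <- config$momentum * vel[[nm]] - gset$lr * lr_scale * gr
        par[[nm]] <- par[[nm]] + vel[[nm]]
      }
      for (i in 1:4) {
        s_i <- fw$cache[[sprintf("s%d", i)]]
        rm_nm <- sprintf("bn%d_rm", i); rv_nm <- sprintf("bn%d_rv", i)
        par[[rm_nm]] <- (1 - bnm) * par[[rm_nm]] + bnm * s_i$mean
        par[[rv_nm]] <- (1 - bnm) * par[[rv_nm]] + bnm * s_i$var
      }
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, loss = ep_loss / N,
                                accuracy = ep_correct / N))
    if (verbose)
      message(sprintf("epoch %2d  loss %.4f  accuracy %.4f",
                      epoch, ep_loss / N, ep_correct / N))
  }
  par <- cnn_finalize_bn(par, x_all, eps)
  net$par <- par
  net$history <- history
  net$trained <- TRUE
  net
}

as_patch_array <- function(newdata) {
  if (inherits(newdata, "patch_set")) newdata <- newdata$patches
  d <- dim(newdata)
  if (is.null(d) || length(d) == 2L) {
    stopifnot(identical(dim(as.matrix(newdata)), c(33L, 33L)))
    return(array(as.matrix(newdata), c(33L, 33L, 1L, 1L)))
  }
  if (length(d) == 3L) return(array(newdata, c(d[1], d[2], 1L, d[3])))
  if (length(d) == 4L) return(newdata)
  stop("cannot interpret `newdata` as 33x33 patches")
}

#' Class probabilities for patches
#'
#' @param object a fitted [cone_cnn()].
#' @param newdata a [patch_set()], a `33 x 33 x n` array, or a single 33x33
#'   matrix.
#' @param type "prob" for the n x 2 probability matrix (columns "noncone",
#'   "cone"), "class" for hard labels.
#' @param batch_size patches per forward pass; results are independent of
#'   the batching (within 1e-6).
#' @param ... unused.
#' @return Probability matrix or character vector of labels.
#' @export
predict.cone_cnn <- function(object, newdata, type = c("prob", "class"),
                             batch_size = 500L, ...) {
  type <- match.arg(type)
  x <- as_patch_array(newdata)
  if (dim(x)[1] != PATCH_SIZE || dim(x)[2] != PATCH_SIZE)
    stop("patches must be 33 x 33")
  n <- dim(x)[4]
  probs <- matrix(NA_real_, n, 2L, dimnames = list(NULL, object$classes))
  for (s in seq(1L, n, by = batch_size)) {
    take <- s:min(s + batch_size - 1L, n)
    probs[take, ] <- cnn_forward(object$par, x[, , , take, drop = FALSE],
                                 training = FALSE,
                                 eps = object$config$bn_eps)$probs
  }
  if (type == "class") object$classes[max.col(probs)] else probs
}

#' @export
print.cone_cnn <- function(x, ...) {
  cat("<cone_cnn> 33x33 patch classifier (conv-bn-pool x3, fc-bn, fc, softmax)\n")
  cat(sprintf("  trained: %s", x$trained))
  if (x$trained)
    cat(sprintf(" (%d epochs, final loss %.4f, accuracy %.4f)",
                nrow(x$history), x$history$loss[nrow(x$history)],
                x$history$accuracy[nrow(x$history)]))
  cat("\n")
  if (!is.null(x$detection_params))
    cat(sprintf("  detection params: sigma = %g, H = %g, T = %g\n",
                x$detection_params$sigma, x$detection_params$h,
                x$detection_params$t))
  invisible(x)
}

#' @export
summary.cone_cnn <- function(object, ...) {
  shp <- vapply(CNN_SHAPES, paste, character(1), collapse = "x")
  cat("Layer activations (single 33x33 patch):\n")
  for (nm in names(shp)) cat(sprintf("  %-8s %s\n", nm, shp[[nm]]))
  npar <- sum(vapply(object$par[!grepl("_(rm|rv)$", names(object$par))],
                     length, numeric(1)))
  cat(sprintf("Learnable parameters: %d\n", npar))
  print(object)
  invisible(object)
}

#' @export
coef.cone_cnn <- function(object, ...) object$par

#' @export
plot.cone_cnn <- function(x, ...) {
  if (!x$trained) stop("network is not trained")
  h <- x$history
  op <- par(mar = c(4, 4, 2, 4)); on.exit(par(op))
  plot(h$epoch, h$loss, type = "b", pch = 16, xlab = "epoch",
       ylab = "mean training loss", main = "cone_cnn training", ...)
  par(new = TRUE)
  plot(h$epoch, h$accuracy, type = "l", lty = 2, axes = FALSE,
       xlab = "", ylab = "", ylim = c(0, 1))
  graphics::axis(4)
  graphics::mtext("training accuracy", side = 4, line = 2.5)
  invisible(x)
}

#' Activation shapes of the forward pass
#'
#' Runs a single zero patch through the network and records the dimensions
#' of every intermediate activation, for checking against the architecture
#' contract.
#'
#' @param net a `cone_cnn` object (trained or not).
#' @return Named list of `c(height, width, channels)` per stage.
#' @export
network_activation_shapes <- function(net) {
  x <- array(0, c(33L, 33L, 1L, 1L))
  par <- net$par; eps <- net$config$bn_eps
  shp <- list(input = c(33L, 33L, 1L))
  a1 <- conv2d_fwd(x, par$conv1_w, par$conv1_b, 2L)
  shp$conv1 <- dim(a1)[1:3]
  y1 <- bn_infer(a1, par$bn1_g, par$bn1_b, par$bn1_rm, par$bn1_rv, eps)
  shp$bn1 <- dim(y1)[1:3]
  p1 <- pool3s2_fwd(y1, "max")$y; shp$pool1 <- dim(p1)[1:3]
  r1 <- relu_fwd(p1); shp$relu1 <- dim(r1)[1:3]
  a2 <- conv2d_fwd(r1, par$conv2_w, par$conv2_b, 2L); shp$conv2 <- dim(a2)[1:3]
  y2 <- bn_infer(a2, par$bn2_g, par$bn2_b, par$bn2_rm, par$bn2_rv, eps)
  shp$bn2 <- dim(y2)[1:3]
  r2 <- relu_fwd(y2); shp$relu2 <- dim(r2)[1:3]
  p2 <- pool3s2_fwd(r2, "avg")$y; shp$pool2 <- dim(p2)[1:3]
  a3 <- conv2d_fwd(p2, par$conv3_w, par$conv3_b, 2L); shp$conv3 <- dim(a3)[1:3]
  y3 <- bn_infer(a3, par$bn3_g, par$bn3_b, par$bn3_rm, par$bn3_rv, eps)
  shp$bn3 <- dim(y3)[1:3]
  r3 <- relu_fwd(y3); shp$relu3 <- dim(r3)[1:3]
  p3 <- pool3s2_fwd(r3, "avg")$y; shp$pool3 <- dim(p3)[1:3]
  f <- matrix(p3, 1024L, 1L)
  z1 <- par$fc1_w %*% f + par$fc1_b; shp$fc1 <- c(1L, 1L, nrow(z1))
  shp$bn4 <- shp$fc1; shp$relu4 <- shp$fc1
  z2 <- par$fc2_w %*% matrix(z1, 64L, 1L) + par$fc2_b
  shp$fc2 <- c(1L, 1L, nrow(z2)); shp$softmax <- shp$fc2
  shp
}
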