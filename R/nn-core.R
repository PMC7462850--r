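# Minimal reverse-mode automatic differentiation over the layer set needed
# by the segmentation networks and the cycle-GAN: convolution (im2col +
# BLAS matmul), max-pooling, nearest upsampling, channel concatenation,
# pointwise nonlinearities, instance normalization, spatial dropout, dense
# layers, and fused softmax/MSE/L1 losses. Tensors are numeric arrays laid
# out [h, w, channels, batch]; dense activations are [features, batch].
#
# A forward pass records nodes on a tape (creation order is a topological
# order); nn_backward walks it in reverse accumulating gradients. Gradient
# correctness is pinned down by finite-difference tests.

.conv_cache <- new.env(parent = emptyenv())

nn_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  t$training <- FALSE
  t
}

nn_node <- function(tape, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  if (!is.null(backward)) tape$nodes[[length(tape$nodes) + 1L]] <- nd
  nd
}

# Leaf wrapping an input tensor (no gradient needed beyond accumulation).
nn_input <- function(tape, value) nn_node(tape, value)

# Trainable parameter: persistent across tapes; carries its SGD velocity.
nn_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  p$vel <- array(0, dim = dim(value) %||% length(value))
  p$parents <- list()
  p$backward <- NULL
  class(p) <- "nn_param"
  p
}

acc_grad <- function(nd, g) {
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
}

nn_zero_grads <- function(params) for (p in params) p$grad <- NULL

nn_backward <- function(tape, loss_node) {
  loss_node$grad <- 1
  for (i in rev(seq_along(tape$nodes))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

# One SGD-with-momentum step over a parameter list.
nn_sgd_step <- function(params, lr, momentum = 0.9) {
  for (p in params) {
    if (is.null(p$grad)) next
    p$vel <- momentum * p$vel - lr * p$grad
    p$value <- p$value + p$vel
  }
  invisible(NULL)
}

# Adam step (beta1 = 0.5 as in adversarial-training practice); each param
# carries its own moment buffers and step counter.
nn_adam_step <- function(params, lr, beta1 = 0.5, beta2 = 0.999,
                         eps = 1e-8) {
  for (p in params) {
    if (is.null(p$grad)) next
    if (is.null(p$adam_m)) {
      p$adam_m <- 0 * p$grad; p$adam_v <- 0 * p$grad; p$adam_t <- 0L
    }
    p$adam_t <- p$adam_t + 1L
    p$adam_m <- beta1 * p$adam_m + (1 - beta1) * p$grad
    p$adam_v <- beta2 * p$adam_v + (1 - beta2) * p$grad^2
    mh <- p$adam_m / (1 - beta1^p$adam_t)
    vh <- p$adam_v / (1 - beta2^p$adam_t)
    p$value <- p$value - lr * mh / (sqrt(vh) + eps)
  }
  invisible(NULL)
}

# ---- convolution -----------------------------------------------------------

conv_plan <- function(h, w, cin, n, k, stride, pad) {
  key <- paste(h, w, cin, n, k, stride, pad, sep = "_")
  if (!is.null(.conv_cache[[key]])) return(.conv_cache[[key]])
  hp <- h + 2 * pad; wp <- w + 2 * pad
  oh <- (hp - k) %/% stride + 1L
  ow <- (wp - k) %/% stride + 1L
  npos <- oh * ow
  oi <- rep(seq_len(oh), times = ow)
  oj <- rep(seq_len(ow), each = oh)
  pos_r <- (oi - 1L) * stride + 1L
  pos_c <- (oj - 1L) * stride + 1L
  off_r <- rep(0:(k - 1), times = k * cin)
  off_c <- rep(rep(0:(k - 1), each = k), times = cin)
  off_ch <- rep(0:(cin - 1), each = k * k)
  m0 <- outer(pos_r, off_r, "+") +
    hp * outer(pos_c - 1L, off_c, "+") +
    hp * wp * matrix(off_ch, npos, k * k * cin, byrow = TRUE)
  idx <- m0[rep(seq_len(npos), n), , drop = FALSE] +
    rep((0:(n - 1)) * hp * wp * cin, each = npos)
  idx_vec <- as.integer(idx)
  # scatter-add plan for the backward pass: sort the gather indices once and
  # reduce by cumulative-sum segments (much faster than rowsum per step)
  ord <- order(idx_vec)
  sorted <- idx_vec[ord]
  ends <- c(which(diff(sorted) != 0L), length(sorted))
  plan <- list(hp = hp, wp = wp, oh = oh, ow = ow,
               idx_vec = idx_vec, ord = ord, ends = ends,
               uniq = sorted[ends])
  .conv_cache[[key]] <- plan
  plan
}

pad_tensor <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  out
}

unpad_tensor <- function(x, pad, h, w) {
  if (pad == 0) return(x)
  x[pad + seq_len(h), pad + seq_len(w), , , drop = FALSE]
}

# 2-D convolution. W: nn_param [k*k*cin, cout]; b: nn_param length cout.
nn_conv <- function(tape, x, W, b, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  d <- dim(x$value)
  h <- d[1]; w <- d[2]; cin <- d[3]; n <- d[4]
  cout <- ncol(W$value)
  plan <- conv_plan(h, w, cin, n, k, stride, pad)
  xp <- pad_tensor(x$value, pad)
  xcol <- xp[plan$idx_vec]
  dim(xcol) <- c(plan$oh * plan$ow * n, k * k * cin)
  ymat <- xcol %*% W$value
  ymat <- sweep(ymat, 2, b$value, "+")
  oh <- plan$oh; ow <- plan$ow
  yv <- aperm(array(ymat, dim = c(oh, ow, n, cout)), c(1, 2, 4, 3))
  out <- nn_node(tape, yv, parents = list(x, W, b), backward = function(gy) {
    gmat <- matrix(aperm(gy, c(1, 2, 4, 3)), nrow = oh * ow * n, ncol = cout)
    acc_grad(W, crossprod(xcol, gmat))
    acc_grad(b, colSums(gmat))
    gxcol <- tcrossprod(gmat, W$value)
    cs <- cumsum(gxcol[plan$ord])
    sums <- cs[plan$ends] - c(0, cs[plan$ends[-length(plan$ends)]])
    gxp <- numeric(length(xp))
    gxp[plan$uniq] <- sums
    dim(gxp) <- dim(xp)
    acc_grad(x, unpad_tensor(gxp, pad, h, w))
  })
  out
}

# ---- pooling / resampling --------------------------------------------------

nn_maxpool2 <- function(tape, x) {
  d <- dim(x$value)
  if (d[1] %% 2 != 0 || d[2] %% 2 != 0) stop("maxpool needs even spatial size")
  ri <- seq(1, d[1], by = 2); ci <- seq(1, d[2], by = 2)
  s00 <- x$value[ri, ci, , , drop = FALSE]
  s10 <- x$value[ri + 1, ci, , , drop = FALSE]
  s01 <- x$value[ri, ci + 1, , , drop = FALSE]
  s11 <- x$value[ri + 1, ci + 1, , , drop = FALSE]
  y <- pmax(s00, s10, s01, s11)
  nn_node(tape, y, parents = list(x), backward = function(gy) {
    gx <- array(0, dim = d)
    # route gradient to the first maximal entry (fixed tie order)
    taken <- array(FALSE, dim = dim(y))
    for (sel in list(list(s00, ri, ci), list(s10, ri + 1, ci),
                     list(s01, ri, ci + 1), list(s11, ri + 1, ci + 1))) {
      hit <- (sel[[1]] == y) & !taken
      g <- gy; g[!hit] <- 0
      gx[sel[[2]], sel[[3]], , ] <- gx[sel[[2]], sel[[3]], , ] + g
      taken <- taken | hit
    }
    acc_grad(x, gx)
  })
}

nn_upsample2 <- function(tape, x) {
  d <- dim(x$value)
  y <- x$value[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
               drop = FALSE]
  nn_node(tape, y, parents = list(x), backward = function(gy) {
    ri <- seq(1, 2 * d[1], by = 2); ci <- seq(1, 2 * d[2], by = 2)
    gx <- gy[ri, ci, , , drop = FALSE] + gy[ri + 1, ci, , , drop = FALSE] +
      gy[ri, ci + 1, , , drop = FALSE] + gy[ri + 1, ci + 1, , , drop = FALSE]
    acc_grad(x, gx)
  })
}

nn_concat <- function(tape, a, b) {
  da <- dim(a$value); db <- dim(b$value)
  y <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a$value
  y[, , da[3] + seq_len(db[3]), ] <- b$value
  nn_node(tape, y, parents = list(a, b), backward = function(gy) {
    acc_grad(a, gy[, , seq_len(da[3]), , drop = FALSE])
    acc_grad(b, gy[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

# ---- pointwise -------------------------------------------------------------

nn_relu <- function(tape, x) {
  y <- pmax(x$value, 0)
  nn_node(tape, y, parents = list(x),
          backward = function(gy) acc_grad(x, gy * (x$value > 0)))
}

nn_lrelu <- function(tape, x, alpha = 0.2) {
  pos <- x$value > 0
  y <- ifelse(pos, x$value, alpha * x$value)
  dim(y) <- dim(x$value)
  nn_node(tape, y, parents = list(x), backward = function(gy) {
    g <- ifelse(pos, gy, alpha * gy); dim(g) <- dim(gy)
    acc_grad(x, g)
  })
}

nn_tanh <- function(tape, x) {
  y <- tanh(x$value)
  nn_node(tape, y, parents = list(x),
          backward = function(gy) acc_grad(x, gy * (1 - y^2)))
}

# Spatial dropout: whole feature channels are dropped per sample (inverted
# scaling); identity when the tape is not in training mode or rate is 0.
nn_spatial_dropout <- function(tape, x, rate) {
  if (!tape$training || rate <= 0) return(x)
  d <- dim(x$value)
  keep <- array(stats::rbinom(d[3] * d[4], 1, 1 - rate), dim = c(d[3], d[4]))
  mask <- array(rep(keep, each = d[1] * d[2]), dim = d) / (1 - rate)
  y <- x$value * mask
  nn_node(tape, y, parents = list(x),
          backward = function(gy) acc_grad(x, gy * mask))
}

# Instance normalization with per-channel affine parameters g, b.
nn_instnorm <- function(tape, x, g, b, eps = 1e-5) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  xm <- matrix(x$value, nrow = hw)            # hw x (c*n)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, istd, "*")
  gg <- rep(rep(g$value, times = d[4]), each = 1)  # per (c, n) column scale
  y <- sweep(xhat, 2, gg, "*")
  y <- sweep(y, 2, rep(b$value, times = d[4]), "+")
  dim(y) <- d
  nn_node(tape, y, parents = list(x, g, b), backward = function(gy) {
    gym <- matrix(gy, nrow = hw)
    acc_grad(g, rowSums(matrix(colSums(gym * xhat), nrow = d[3])))
    acc_grad(b, rowSums(matrix(colSums(gym), nrow = d[3])))
    gxhat <- sweep(gym, 2, gg, "*")
    # d/dx of (x - mu) * istd with mu, istd functions of x
    t1 <- sweep(gxhat, 2, istd, "*")
    t2 <- sweep(xhat, 2, colMeans(gxhat * xhat) * istd, "*")
    t3 <- matrix(rep(colMeans(gxhat) * istd, each = hw), nrow = hw)
    gx <- t1 - t2 - t3
    dim(gx) <- d
    acc_grad(x, gx)
  })
}

# Global average pooling: [h, w, c, n] -> [c, n].
nn_gap <- function(tape, x) {
  d <- dim(x$value)
  y <- apply(x$value, c(3, 4), mean)
  dim(y) <- c(d[3], d[4])
  nn_node(tape, y, parents = list(x), backward = function(gy) {
    gx <- array(rep(gy, each = d[1] * d[2]), dim = d) / (d[1] * d[2])
    acc_grad(x, gx)
  })
}

# Dense layer on [features, batch].
nn_dense <- function(tape, x, W, b) {
  y <- crossprod(W$value, x$value) + b$value
  nn_node(tape, y, parents = list(x, W, b), backward = function(gy) {
    acc_grad(W, tcrossprod(x$value, gy))
    acc_grad(b, rowSums(gy))
    acc_grad(x, W$value %*% gy)
  })
}

# ---- losses (fused with their gradient) ------------------------------------

softmax_over_channels <- function(v) {
  d <- dim(v)
  m <- matrix(aperm(v, c(3, 1, 2, 4)), nrow = d[3])
  m <- exp(sweep(m, 2, apply(m, 2, max)))
  m <- sweep(m, 2, colSums(m), "/")
  aperm(array(m, dim = c(d[3], d[1], d[2], d[4])), c(2, 3, 1, 4))
}

# Mean categorical cross-entropy over pixels and samples; `target` is a
# one-hot array of the same shape as the logits.
nn_softmax_ce <- function(tape, logits, target) {
  p <- softmax_over_channels(logits$value)
  d <- dim(p)
  npix <- d[1] * d[2] * d[4]
  loss <- -sum(target * log(pmax(p, 1e-12))) / npix
  nn_node(tape, loss, parents = list(logits),
          backward = function(gy) acc_grad(logits, gy * (p - target) / npix))
}

# Dense variant: logits [K, n], target one-hot [K, n].
nn_softmax_ce_dense <- function(tape, logits, target) {
  m <- exp(sweep(logits$value, 2, apply(logits$value, 2, max)))
  p <- sweep(m, 2, colSums(m), "/")
  n <- ncol(p)
  loss <- -sum(target * log(pmax(p, 1e-12))) / n
  nn_node(tape, loss, parents = list(logits),
          backward = function(gy) acc_grad(logits, gy * (p - target) / n))
}

nn_mse <- function(tape, x, target) {
  d <- x$value - target
  loss <- mean(d^2)
  nn_node(tape, loss, parents = list(x),
          backward = function(gy) acc_grad(x, gy * 2 * d / length(d)))
}

nn_l1 <- function(tape, x, target) {
  d <- x$value - target
  loss <- mean(abs(d))
  nn_node(tape, loss, parents = list(x),
          backward = function(gy) acc_grad(x, gy * sign(d) / length(d)))
}

nn_add_scaled <- function(tape, a, b, wa = 1, wb = 1) {
  nn_node(tape, wa * a$value + wb * b$value, parents = list(a, b),
          backward = function(gy) {
            acc_grad(a, wa * gy)
            acc_grad(b, wb * gy)
          })
}

# He-initialized convolution parameter pair.
conv_params <- function(k, cin, cout, scale = 1) {
  W <- nn_param(array(stats::rnorm(k * k * cin * cout,
                                   sd = scale * sqrt(2 / (k * k * cin))),
                      dim = c(k * k * cin, cout)))
  b <- nn_param(numeric(cout))
  list(W = W, b = b)
}
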