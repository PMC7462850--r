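# The three model families: U-Net and DenseNet-FCN semantic segmentation,
# and a small patch classifier. Paper-faithful configurations are the
# defaults; every size scales down through the config objects so the same
# code trains in CPU-minutes on synthetic cohorts.

#' U-Net configuration
#'
#' Defaults follow the adapted architecture: depth 5 (two extra encoder
#' blocks of 512 and 1024 filters over the original), spatial dropout 0.25
#' after each encoder block, 5 output classes, 512 px inputs. `base_filters`
#' sets the first block; filters double per level.
#'
#' @param depth Encoder levels (>= 2).
#' @param base_filters Filters in the first block.
#' @param dropout Spatial dropout fraction in [0, 1).
#' @param n_classes Output classes.
#' @param input_size Expected square input size (must be divisible by
#'   2^(depth-1)).
#' @return Object of class `unet_config`.
#' @export
unet_config <- function(depth = 5L, base_filters = 64L, dropout = 0.25,
                        n_classes = 5L, input_size = 512L) {
  stopifnot(depth >= 2, dropout >= 0, dropout < 1, base_filters >= 1)
  structure(list(depth = as.integer(depth),
                 base_filters = as.integer(base_filters), dropout = dropout,
                 n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size)),
            class = "unet_config")
}

#' DenseNet-FCN configuration
#'
#' Defaults per the applied network: 5 dense blocks, growth 16 filters per
#' layer, 4 layers per dense block, 256 px inputs. The blocks are arranged
#' Tiramisu-style: (blocks-1)/2 down-transitions, a bottleneck block, and
#' symmetric up-transitions.
#'
#' @param dense_blocks Total dense blocks (odd, >= 3).
#' @param growth Filters added per layer within a block.
#' @param layers_per_block Convolutional layers per dense block.
#' @param n_classes Output classes.
#' @param input_size Expected square input size.
#' @param initial_filters Stem convolution filters.
#' @return Object of class `densefcn_config`.
#' @export
densefcn_config <- function(dense_blocks = 5L, growth = 16L,
                            layers_per_block = 4L, n_classes = 5L,
                            input_size = 256L, initial_filters = 32L) {
  stopifnot(dense_blocks >= 3, dense_blocks %% 2 == 1, growth > 0,
            layers_per_block > 0)
  structure(list(dense_blocks = as.integer(dense_blocks),
                 growth = as.integer(growth),
                 layers_per_block = as.integer(layers_per_block),
                 n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size),
                 initial_filters = as.integer(initial_filters)),
            class = "densefcn_config")
}

#' Patch-classifier configuration
#'
#' A small width-scalable CNN emitting one probability vector per patch
#' (convolution/pool stages followed by global average pooling and a dense
#' softmax head). Doubling `width` roughly quadruples convolutional
#' parameter counts, the usual compound-scaling behaviour.
#'
#' @param width Base channel width.
#' @param n_stages Conv/pool stages.
#' @param n_classes Output classes (>= 2).
#' @param input_size Expected square input size.
#' @return Object of class `patchcls_config`.
#' @export
patchcls_config <- function(width = 16L, n_stages = 3L, n_classes = 5L,
                            input_size = 64L) {
  stopifnot(n_classes >= 2, width >= 1, n_stages >= 1)
  structure(list(width = as.integer(width), n_stages = as.integer(n_stages),
                 n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size)),
            class = "patchcls_config")
}

#' Training configuration
#'
#' Paper-faithful defaults: plain SGD (momentum 0.9), categorical
#' cross-entropy, batch size 3, learning rate 5e-4. Validation loss governs
#' early stopping; the patch Dice coefficient (segmentation) or accuracy
#' (classifier) is logged as the monitor metric, and the weights of the best
#' epoch under `monitor` are restored at the end.
#'
#' @param batch_size Patches per SGD step.
#' @param lr Learning rate.
#' @param momentum SGD momentum.
#' @param epochs Maximum epochs.
#' @param patience Early-stopping patience in epochs (`0` stops at the first
#'   non-improving epoch).
#' @param steps_per_epoch SGD steps per epoch (default: full pass).
#' @param monitor `"val_loss"`, `"val_dice"` or `"val_accuracy"`.
#' @param seed RNG seed for shuffling, augmentation and dropout.
#' @return Object of class `train_config`.
#' @export
train_config <- function(batch_size = 3L, lr = 5e-4, momentum = 0.9,
                         epochs = 100L, patience = 10L,
                         steps_per_epoch = NULL,
                         monitor = c("val_loss", "val_dice", "val_accuracy"),
                         seed = 1L) {
  stopifnot(batch_size >= 1, lr > 0)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 momentum = momentum, epochs = as.integer(epochs),
                 patience = as.integer(patience),
                 steps_per_epoch = steps_per_epoch,
                 monitor = match.arg(monitor), seed = as.integer(seed)),
            class = "train_config")
}

new_wsi_model <- function(arch, cfg, params, forward) {
  structure(list(arch = arch, cfg = cfg, params = params, forward = forward,
                 history = NULL),
            class = "wsi_model")
}

#' @export
print.wsi_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, function(p) length(p$value), 0))
  cat(sprintf("wsi_model '%s': %d parameter tensors, %s parameters\n",
              x$arch, length(x$params), format(n_par, big.mark = ",")))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epoch(s); best %s %.4f\n",
                nrow(x$history), attr(x$history, "monitor"),
                attr(x$history, "best")))
  invisible(x)
}

#' Build the adapted U-Net
#'
#' Same-padded 3x3 convolutions, 2x2 max pooling, nearest-neighbour
#' upsampling with skip concatenation, spatial dropout after each encoder
#' block's second convolution, and a 1x1 softmax head. Output spatial shape
#' equals input shape; per-pixel class probabilities sum to 1.
#'
#' @param cfg A [unet_config()].
#' @param seed Seed for weight initialization.
#' @return A `wsi_model`.
#' @export
build_unet <- function(cfg = unet_config(), seed = 1L) {
  stopifnot(inherits(cfg, "unet_config"))
  with_seed(seed, {
    d <- cfg$depth
    nf <- cfg$base_filters * 2^(0:(d - 1))
    params <- list()
    add <- function(name, k, cin, cout) {
      pr <- conv_params(k, cin, cout)
      params[[paste0(name, "_W")]] <<- pr$W
      params[[paste0(name, "_b")]] <<- pr$b
    }
    cin <- 3L
    for (l in seq_len(d)) {       # encoder + bottleneck blocks
      add(sprintf("enc%d_c1", l), 3, cin, nf[l])
      add(sprintf("enc%d_c2", l), 3, nf[l], nf[l])
      cin <- nf[l]
    }
    for (l in seq(d - 1, 1)) {    # decoder blocks
      add(sprintf("dec%d_up", l), 3, nf[l + 1], nf[l])
      add(sprintf("dec%d_c1", l), 3, 2 * nf[l], nf[l])
      add(sprintf("dec%d_c2", l), 3, nf[l], nf[l])
    }
    add("head", 1, nf[1], cfg$n_classes)
    forward <- function(params, x, tape) {
      hin <- dim(x$value)[1]
      if (hin %% 2^(d - 1) != 0)
        stop("input size must be divisible by 2^(depth-1)")
      skips <- vector("list", d - 1)
      h <- x
      for (l in seq_len(d)) {
        h <- nn_relu(tape, nn_conv(tape, h, params[[sprintf("enc%d_c1_W", l)]],
                                   params[[sprintf("enc%d_c1_b", l)]], 3))
        h <- nn_relu(tape, nn_conv(tape, h, params[[sprintf("enc%d_c2_W", l)]],
                                   params[[sprintf("enc%d_c2_b", l)]], 3))
        h <- nn_spatial_dropout(tape, h, cfg$dropout)
        if (l < d) {
          skips[[l]] <- h
          h <- nn_maxpool2(tape, h)
        }
      }
      for (l in seq(d - 1, 1)) {
        h <- nn_relu(tape, nn_conv(tape, nn_upsample2(tape, h),
                                   params[[sprintf("dec%d_up_W", l)]],
                                   params[[sprintf("dec%d_up_b", l)]], 3))
        h <- nn_concat(tape, skips[[l]], h)
        h <- nn_relu(tape, nn_conv(tape, h, params[[sprintf("dec%d_c1_W", l)]],
                                   params[[sprintf("dec%d_c1_b", l)]], 3))
        h <- nn_relu(tape, nn_conv(tape, h, params[[sprintf("dec%d_c2_W", l)]],
                                   params[[sprintf("dec%d_c2_b", l)]], 3))
      }
      nn_conv(tape, h, params$head_W, params$head_b, 1)
    }
    new_wsi_model("unet", cfg, params, forward)
  })
}

#' Build the fully-convolutional DenseNet
#'
#' Tiramisu-style layout: a stem convolution, dense blocks in which each 3x3
#' layer adds `growth` feature maps to a running concatenation, transition-
#' down (1x1 convolution + pooling) on the contracting side, transition-up
#' (upsampling + 3x3 convolution) with skip concatenation on the expanding
#' side, and a 1x1 softmax head at full resolution.
#'
#' @param cfg A [densefcn_config()].
#' @param seed Seed for weight initialization.
#' @return A `wsi_model`.
#' @export
build_densenet_fcn <- function(cfg = densefcn_config(), seed = 1L) {
  stopifnot(inherits(cfg, "densefcn_config"))
  with_seed(seed, {
    n_down <- (cfg$dense_blocks - 1L) %/% 2L
    params <- list()
    add <- function(name, k, cin, cout) {
      pr <- conv_params(k, cin, cout)
      params[[paste0(name, "_W")]] <<- pr$W
      params[[paste0(name, "_b")]] <<- pr$b
      cout
    }
    # channel bookkeeping mirrors the forward pass exactly
    ch <- add("stem", 3, 3L, cfg$initial_filters)
    dense_block_params <- function(tag, cin) {
      c_run <- cin
      for (j in seq_len(cfg$layers_per_block)) {
        add(sprintf("%s_l%d", tag, j), 3, c_run, cfg$growth)
        c_run <- c_run + cfg$growth
      }
      c_run
    }
    skip_ch <- integer(n_down)
    for (i in seq_len(n_down)) {
      ch <- dense_block_params(sprintf("down%d", i), ch)
      skip_ch[i] <- ch
      ch <- add(sprintf("td%d", i), 1, ch, ch %/% 2L)
    }
    ch <- dense_block_params("bottleneck", ch)
    for (i in seq(n_down, 1)) {
      ch <- add(sprintf("tu%d", i), 3, ch, ch %/% 2L)
      ch <- ch + skip_ch[i]
      ch <- dense_block_params(sprintf("up%d", i), ch)
    }
    add("head", 1, ch, cfg$n_classes)
    forward <- function(params, x, tape) {
      dense_block <- function(h, tag) {
        for (j in seq_len(cfg$layers_per_block)) {
          y <- nn_relu(tape, nn_conv(tape, h,
                                     params[[sprintf("%s_l%d_W", tag, j)]],
                                     params[[sprintf("%s_l%d_b", tag, j)]], 3))
          h <- nn_concat(tape, h, y)
        }
        h
      }
      h <- nn_relu(tape, nn_conv(tape, x, params$stem_W, params$stem_b, 3))
      skips <- vector("list", n_down)
      for (i in seq_len(n_down)) {
        h <- dense_block(h, sprintf("down%d", i))
        skips[[i]] <- h
        h <- nn_relu(tape, nn_conv(tape, h, params[[sprintf("td%d_W", i)]],
                                   params[[sprintf("td%d_b", i)]], 1))
        h <- nn_maxpool2(tape, h)
      }
      h <- dense_block(h, "bottleneck")
      for (i in seq(n_down, 1)) {
        h <- nn_relu(tape, nn_conv(tape, nn_upsample2(tape, h),
                                   params[[sprintf("tu%d_W", i)]],
                                   params[[sprintf("tu%d_b", i)]], 3))
        h <- nn_concat(tape, skips[[i]], h)
        h <- dense_block(h, sprintf("up%d", i))
      }
      nn_conv(tape, h, params$head_W, params$head_b, 1)
    }
    new_wsi_model("densefcn", cfg, params, forward)
  })
}

#' Build the patch classifier
#'
#' @param cfg A [patchcls_config()].
#' @param seed Seed for weight initialization.
#' @return A `wsi_model` whose predictions are per-patch probability vectors.
#' @export
build_patch_classifier <- function(cfg = patchcls_config(), seed = 1L) {
  stopifnot(inherits(cfg, "patchcls_config"))
  with_seed(seed, {
    params <- list()
    add <- function(name, k, cin, cout) {
      pr <- conv_params(k, cin, cout)
      params[[paste0(name, "_W")]] <<- pr$W
      params[[paste0(name, "_b")]] <<- pr$b
      cout
    }
    cin <- 3L
    for (s in seq_len(cfg$n_stages))
      cin <- add(sprintf("conv%d", s), 3, cin, cfg$width * 2^(s - 1))
    params$fc_W <- nn_param(matrix(stats::rnorm(cin * cfg$n_classes,
                                                sd = sqrt(2 / cin)),
                                   cin, cfg$n_classes))
    params$fc_b <- nn_param(numeric(cfg$n_classes))
    forward <- function(params, x, tape) {
      h <- x
      for (s in seq_len(cfg$n_stages)) {
        h <- nn_relu(tape, nn_conv(tape, h, params[[sprintf("conv%d_W", s)]],
                                   params[[sprintf("conv%d_b", s)]], 3))
        h <- nn_maxpool2(tape, h)
      }
      h <- nn_gap(tape, h)
      nn_dense(tape, h, params$fc_W, params$fc_b)
    }
    new_wsi_model("patchcls", cfg, params, forward)
  })
}

is_segmentation <- function(model) model$arch %in% c("unet", "densefcn")

#' Predict class probabilities
#'
#' Softmax probabilities for a batch of patches: `[h, w, K, n]` for
#' segmentation models, `[n, K]` (one row per patch) for the patch
#' classifier. Deterministic (dropout inactive).
#'
#' @param object A `wsi_model`.
#' @param x Input batch `[h, w, 3, n]`, values in [0, 255].
#' @param ... Unused.
#' @return Probability array.
#' @export
predict.wsi_model <- function(object, x, ...) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  tape <- nn_tape()
  logits <- object$forward(object$params, nn_input(tape, x / 255 - 0.5), tape)
  if (is_segmentation(object)) softmax_over_channels(logits$value)
  else {
    m <- exp(sweep(logits$value, 2, apply(logits$value, 2, max)))
    t(sweep(m, 2, colSums(m), "/"))
  }
}

snapshot_params <- function(params) lapply(params, function(p) p$value)
restore_params <- function(params, snap)
  for (nm in names(params)) params[[nm]]$value <- snap[[nm]]

batch_loss <- function(model, x, y, tape = nn_tape()) {
  xin <- nn_input(tape, x / 255 - 0.5)
  logits <- model$forward(model$params, xin, tape)
  loss <- if (is_segmentation(model)) nn_softmax_ce(tape, logits, y)
  else nn_softmax_ce_dense(tape, logits, t(y))
  list(tape = tape, loss = loss)
}

# Evaluate mean loss and monitor metric over a dataset without training.
eval_metrics <- function(model, x, y, cancer_idx = 1L, batch = 8L) {
  n <- if (length(dim(x)) == 4) dim(x)[4] else dim(x)[1]
  losses <- numeric(0); w <- numeric(0)
  inter <- 0; pred_pos <- 0; ref_pos <- 0; correct <- 0; total <- 0
  for (start in seq(1, n, by = batch)) {
    idx <- start:min(start + batch - 1, n)
    if (is_segmentation(model)) {
      xb <- x[, , , idx, drop = FALSE]; yb <- y[, , , idx, drop = FALSE]
      p <- predict.wsi_model(model, xb)
      losses <- c(losses, -sum(yb * log(pmax(p, 1e-12))) /
                    (dim(p)[1] * dim(p)[2] * dim(p)[4]))
      pm <- apply(p, c(1, 2, 4), which.max)
      rm_ <- apply(yb, c(1, 2, 4), which.max)
      inter <- inter + sum(pm == cancer_idx & rm_ == cancer_idx)
      pred_pos <- pred_pos + sum(pm == cancer_idx)
      ref_pos <- ref_pos + sum(rm_ == cancer_idx)
      correct <- correct + sum(pm == rm_); total <- total + length(pm)
    } else {
      xb <- x[, , , idx, drop = FALSE]; yb <- y[idx, , drop = FALSE]
      p <- predict.wsi_model(model, xb)
      losses <- c(losses, -sum(yb * log(pmax(p, 1e-12))) / length(idx))
      pm <- apply(p, 1, which.max); rm_ <- apply(yb, 1, which.max)
      correct <- correct + sum(pm == rm_); total <- total + length(pm)
    }
    w <- c(w, length(idx))
  }
  denom <- pred_pos + ref_pos
  list(loss = sum(losses * w) / sum(w),
       dice = if (denom > 0) 2 * inter / denom else 1,
       accuracy = correct / total)
}

#' Train a model by SGD with early stopping
#'
#' Minimizes categorical cross-entropy with momentum SGD. Per-epoch training
#' and validation loss plus the monitor metric (patch-level cancer Dice for
#' segmentation, accuracy for the classifier) are recorded; training stops
#' when the monitored quantity has not improved for `patience` epochs, and
#' the best epoch's weights are restored. A non-finite loss aborts with a
#' diagnostic. Fully seeded and reproducible.
#'
#' @param model A `wsi_model` (modified in place and returned).
#' @param x_train,y_train Training batch arrays: inputs `[h, w, 3, n]`,
#'   targets `[h, w, K, n]` (segmentation) or `[n, K]` one-hot (classifier).
#' @param x_val,y_val Validation arrays (same layout).
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return The trained `wsi_model`; `$history` holds the epoch log.
#' @export
train_model <- function(model, x_train, y_train, x_val, y_val,
                        cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "wsi_model"), inherits(cfg, "train_config"))
  seg <- is_segmentation(model)
  n <- if (seg) dim(x_train)[4] else dim(x_train)[4]
  if (n < 1 || (if (seg) dim(x_val)[4] else dim(x_val)[4]) < 1)
    stop("empty training or validation set")
  with_seed(cfg$seed, {
    steps <- cfg$steps_per_epoch %||% max(1L, n %/% cfg$batch_size)
    monitor_sign <- if (cfg$monitor == "val_loss") -1 else 1  # maximize
    best <- -Inf; best_snap <- snapshot_params(model$params)
    since_best <- 0L
    hist <- NULL
    for (ep in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      tl <- numeric(steps)
      for (st in seq_len(steps)) {
        take <- perm[((st - 1) * cfg$batch_size) %% n +
                       seq_len(cfg$batch_size)]
        take <- take[!is.na(take) & take <= n]
        xb <- x_train[, , , take, drop = FALSE]
        yb <- if (seg) y_train[, , , take, drop = FALSE]
        else y_train[take, , drop = FALSE]
        tape <- nn_tape(); tape$training <- TRUE
        r <- batch_loss(model, xb, yb, tape)
        if (!is.finite(r$loss$value))
          stop(sprintf("non-finite loss at epoch %d step %d: %g",
                       ep, st, r$loss$value))
        nn_zero_grads(model$params)
        nn_backward(tape, r$loss)
        nn_sgd_step(model$params, cfg$lr, cfg$momentum)
        tl[st] <- r$loss$value
      }
      vm <- eval_metrics(model, x_val, y_val)
      mon <- switch(cfg$monitor, val_loss = vm$loss, val_dice = vm$dice,
                    val_accuracy = vm$accuracy)
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(tl),
                                     val_loss = vm$loss, val_dice = vm$dice,
                                     val_accuracy = vm$accuracy))
      if (verbose)
        message(sprintf("epoch %d: train %.4f val %.4f dice %.3f acc %.3f",
                        ep, mean(tl), vm$loss, vm$dice, vm$accuracy))
      if (monitor_sign * mon > best) {
        best <- monitor_sign * mon
        best_snap <- snapshot_params(model$params)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best > cfg$patience) break
      }
    }
    restore_params(model$params, best_snap)
    attr(hist, "monitor") <- cfg$monitor
    attr(hist, "best") <- monitor_sign * best
    model$history <- hist
    model
  })
}

#' Parameter count of a model
#'
#' @param model A `wsi_model`.
#' @return Total number of trainable scalars.
#' @export
n_parameters <- function(model)
  sum(vapply(model$params, function(p) length(p$value), 0))
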