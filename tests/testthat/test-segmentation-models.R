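# Autodiff correctness and the three model families.

test_that("analytic gradients match finite differences through all layers", {
  set.seed(42)
  x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  pr <- wsiscreen:::conv_params(3, 2, 3)
  pr2 <- wsiscreen:::conv_params(3, 5, 2)
  g <- wsiscreen:::nn_param(runif(3, 0.5, 1.5))
  bb <- wsiscreen:::nn_param(rnorm(3) * 0.1)
  target <- array(abs(rnorm(6 * 6 * 2 * 2)), c(6, 6, 2, 2))
  fwd <- function() {
    tp <- wsiscreen:::nn_tape()
    xin <- wsiscreen:::nn_input(tp, x)
    h1 <- wsiscreen:::nn_relu(tp, wsiscreen:::nn_conv(tp, xin, pr$W, pr$b, 3))
    h1n <- wsiscreen:::nn_instnorm(tp, h1, g, bb)
    p <- wsiscreen:::nn_maxpool2(tp, h1n)
    u <- wsiscreen:::nn_upsample2(tp, p)
    cc <- wsiscreen:::nn_concat(tp, u, xin)
    h2 <- wsiscreen:::nn_tanh(tp,
                              wsiscreen:::nn_conv(tp, cc, pr2$W, pr2$b, 3))
    list(tp = tp, loss = wsiscreen:::nn_mse(tp, h2, target), xin = xin)
  }
  r <- fwd()
  params <- list(pr$W, pr$b, pr2$W, pr2$b, g, bb)
  wsiscreen:::nn_zero_grads(params)
  wsiscreen:::nn_backward(r$tp, r$loss)
  eps <- 1e-6
  for (p in params) {
    for (i in sample(length(p$value), min(3, length(p$value)))) {
      v0 <- p$value[i]
      p$value[i] <- v0 + eps; lp <- fwd()$loss$value
      p$value[i] <- v0 - eps; lm <- fwd()$loss$value
      p$value[i] <- v0
      num <- (lp - lm) / (2 * eps)
      expect_equal(p$grad[i], num, tolerance = 1e-5)
    }
  }
  i <- 50
  v0 <- x[i]
  x[i] <- v0 + eps; lp <- fwd()$loss$value
  x[i] <- v0 - eps; lm <- fwd()$loss$value
  x[i] <- v0
  expect_equal(r$xin$grad[i], (lp - lm) / (2 * eps), tolerance = 1e-5)
})

test_that("softmax cross-entropy gradient matches finite differences", {
  set.seed(1)
  logits <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  tgt <- array(0, dim(logits))
  for (i in 1:4) for (j in 1:4) for (n in 1:2)
    tgt[i, j, sample(3, 1), n] <- 1
  tp <- wsiscreen:::nn_tape()
  lin <- wsiscreen:::nn_input(tp, logits)
  loss <- wsiscreen:::nn_softmax_ce(tp, lin, tgt)
  wsiscreen:::nn_backward(tp, loss)
  eps <- 1e-6
  for (i in sample(length(logits), 5)) {
    v0 <- logits[i]
    f <- function(v) {
      l2 <- logits; l2[i] <- v
      tp2 <- wsiscreen:::nn_tape()
      wsiscreen:::nn_softmax_ce(tp2, wsiscreen:::nn_input(tp2, l2),
                                tgt)$value
    }
    expect_equal(lin$grad[i], (f(v0 + eps) - f(v0 - eps)) / (2 * eps),
                 tolerance = 1e-5)
  }
})

test_that("U-Net obeys the softmax and geometry contracts", {
  cfg <- unet_config(depth = 3, base_filters = 4, input_size = 16)
  m <- build_unet(cfg, seed = 1)
  x <- fixture_rgb(16, 16)
  p <- predict(m, x)
  expect_equal(dim(p), c(16, 16, 5, 1))
  expect_equal(apply(p, c(1, 2, 4), sum), array(1, c(16, 16, 1)),
               tolerance = 1e-5)
  # bottleneck spatial size is input / 2^(depth-1)
  expect_equal(16 / 2^(cfg$depth - 1), 4)
  expect_error(predict(m, fixture_rgb(15, 15)), "divisible")
  # deterministic forward given fixed weights
  expect_identical(predict(m, x), predict(m, x))
})

test_that("DenseNet-FCN grows channels by `growth` per layer and normalizes", {
  cfg <- densefcn_config(dense_blocks = 3, growth = 4, layers_per_block = 2,
                         input_size = 16, initial_filters = 8)
  m <- build_densenet_fcn(cfg, seed = 1)
  # channel arithmetic: layer k of a block consumes cin + (k-1) * growth
  w1 <- m$params[["down1_l1_W"]]
  w2 <- m$params[["down1_l2_W"]]
  expect_equal(nrow(w1$value), 9 * 8)             # stem filters in
  expect_equal(nrow(w2$value), 9 * (8 + 4))       # + growth
  expect_equal(ncol(w1$value), 4)
  p <- predict(m, fixture_rgb(16, 16))
  expect_equal(dim(p), c(16, 16, 5, 1))
  expect_equal(apply(p, c(1, 2, 4), sum), array(1, c(16, 16, 1)),
               tolerance = 1e-5)
  expect_error(densefcn_config(growth = 0), "growth")
})

test_that("patch classifier emits per-patch probabilities and scales ~4x", {
  m <- build_patch_classifier(patchcls_config(width = 8, n_stages = 2,
                                              input_size = 16), seed = 1)
  p <- predict(m, fixture_rgb(16, 16)[, , , drop = FALSE])
  x4 <- array(fixture_rgb(16, 16), c(16, 16, 3, 4))
  p4 <- predict(m, x4)
  expect_equal(dim(p4), c(4, 5))
  expect_equal(rowSums(p4), rep(1, 4), tolerance = 1e-6)
  conv_count <- function(width) {
    mm <- build_patch_classifier(patchcls_config(width = width, n_stages = 2,
                                                 input_size = 16), seed = 1)
    sum(vapply(mm$params[grep("^conv", names(mm$params))],
               function(p) length(p$value), 0))
  }
  ratio <- conv_count(16) / conv_count(8)
  expect_gt(ratio, 3.4)
  expect_lt(ratio, 4.2)
  expect_error(patchcls_config(n_classes = 1), "n_classes")
})

test_that("training reduces loss, fits degenerate data, and early-stops", {
  set.seed(3)
  mk <- function(n, base) clamp(array(rnorm(16 * 16 * 3 * n, base, 20),
                                      c(16, 16, 3, n)), 0, 255)
  x <- array(0, c(16, 16, 3, 20))
  x[, , , 1:10] <- mk(10, 80); x[, , , 11:20] <- mk(10, 180)
  y <- array(0, c(16, 16, 5, 20))
  y[, , 1, 1:10] <- 1; y[, , 2, 11:20] <- 1
  m <- build_unet(unet_config(depth = 2, base_filters = 6, dropout = 0,
                              input_size = 16), seed = 2)
  m <- train_model(m, x, y, x, y,
                   train_config(batch_size = 4, lr = 0.02, epochs = 12,
                                patience = 12, seed = 9))
  h <- m$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  expect_gt(h$val_dice[nrow(h)], 0.9)
  # single-class training degenerates to predicting that class everywhere
  m1 <- build_unet(unet_config(depth = 2, base_filters = 4, dropout = 0,
                               input_size = 16), seed = 2)
  x1 <- x[, , , 1:8, drop = FALSE]
  y1 <- array(0, c(16, 16, 5, 8)); y1[, , 3, ] <- 1
  m1 <- train_model(m1, x1, y1, x1, y1,
                    train_config(batch_size = 4, lr = 0.05, epochs = 6,
                                 patience = 6, seed = 1))
  pred <- apply(predict(m1, x1), c(1, 2, 4), which.max)
  expect_true(all(pred == 3))
  # patience 0 stops right after the first non-improving epoch
  m2 <- build_unet(unet_config(depth = 2, base_filters = 4, dropout = 0,
                               input_size = 16), seed = 2)
  m2 <- train_model(m2, x, y, x, y,
                    train_config(batch_size = 4, lr = 50, epochs = 20,
                                 patience = 0, seed = 1))
  expect_lt(nrow(m2$history), 20)
})

test_that("seeded training is bit-reproducible", {
  set.seed(3)
  x <- clamp(array(rnorm(16 * 16 * 3 * 8, 120, 40), c(16, 16, 3, 8)), 0, 255)
  y <- array(0, c(16, 16, 5, 8)); y[, , 2, ] <- 1
  run <- function() {
    m <- build_unet(unet_config(depth = 2, base_filters = 4, dropout = 0.2,
                                input_size = 16), seed = 7)
    m <- train_model(m, x, y, x, y,
                     train_config(batch_size = 4, lr = 0.01, epochs = 3,
                                  patience = 3, seed = 11))
    m$params$head_W$value
  }
  expect_identical(run(), run())
})

test_that("a reduced U-Net reaches high cancer Dice on synthetic patches", {
  xs <- list(); cls <- character(0)
  for (seed in c(31, 32, 34, 35)) {
    g <- fixture_slide("cancer", seed = seed)
    recs <- extract_patches(g$annotations, 32, 5, stride = 16)
    set.seed(seed)
    recs <- recs[sample.int(nrow(recs), min(nrow(recs), 40)), ]
    for (j in seq_len(nrow(recs))) {
      xs[[length(xs) + 1]] <- read_patch(g$slide, recs[j, ])
      cls <- c(cls, recs$class_label[j])
    }
  }
  n <- length(xs)
  x <- array(0, c(32, 32, 3, n)); y <- array(0, c(32, 32, 5, n))
  for (i in seq_len(n)) {
    x[, , , i] <- xs[[i]]; y[, , , i] <- make_target(cls[i], 32)
  }
  set.seed(2)
  val <- sample(n, max(8, round(n / 5))); tr <- setdiff(seq_len(n), val)
  # class-balanced oversampling, as in training practice
  plan <- suppressWarnings(plan_balanced_sampling(
    data.frame(class_label = cls[tr])))
  reps <- plan$multiplier[match(cls[tr], plan$class_label)]
  tr <- rep(tr, reps)
  m <- build_unet(unet_config(depth = 3, base_filters = 8, dropout = 0.1,
                              input_size = 32), seed = 5)
  m <- train_model(m, x[, , , tr, drop = FALSE], y[, , , tr, drop = FALSE],
                   x[, , , val, drop = FALSE], y[, , , val, drop = FALSE],
                   train_config(batch_size = 8, lr = 0.01, epochs = 8,
                                patience = 8, steps_per_epoch = 30,
                                seed = 5))
  metrics <- wsiscreen:::eval_metrics(m, x[, , , val, drop = FALSE],
                                      y[, , , val, drop = FALSE])
  expect_gte(metrics$dice, 0.8)
})
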