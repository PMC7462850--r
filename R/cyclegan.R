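# Cycle-consistent adversarial style normalization between two scanner
# domains: U-Net generators with instance normalization, patch-based
# discriminators, least-squares adversarial loss, and cycle-consistency L1.

#' Cycle-GAN configuration
#'
#' Defaults follow the training recipe: cycle-consistency weight 10.0,
#' discriminator (adversarial) weight 1.0, 256 px patches at 10x, 150 epochs
#' of 50 iterations with batch size 4, learning rate 5e-4 halved every 20
#' epochs, 5 slides sampled per domain. Desk-scale runs shrink `patch_size`,
#' `epochs`, `iterations_per_epoch` and the network widths.
#'
#' @param lambda_cycle Cycle-consistency loss weight.
#' @param lambda_disc Adversarial loss weight.
#' @param patch_size Training patch size (px).
#' @param magnification Sampling magnification.
#' @param epochs,iterations_per_epoch,batch_size Training schedule.
#' @param lr,lr_decay_factor,lr_decay_every Learning-rate schedule.
#' @param n_slides_per_domain Slides sampled per domain.
#' @param gen_filters,disc_filters Base channel widths.
#' @param gen_depth U-Net generator depth.
#' @param gen_instnorm Use instance normalization inside the generator.
#'   Off by default: normalizing activations erases the absolute color of a
#'   patch, which is precisely the signal a style translator must read.
#' @param gen_kind `"unet"` (default, the reference generator architecture)
#'   or `"color"`: a pointwise (1x1-convolution) color remapper with one 3x3
#'   stage for local deblurring — a stronger inductive bias when scanner
#'   styles are predominantly colorimetric, and the variant the desk-scale
#'   study uses.
#' @param seed RNG seed.
#' @return Object of class `cyclegan_config`.
#' @export
cyclegan_config <- function(lambda_cycle = 10, lambda_disc = 1,
                            patch_size = 256L, magnification = 10,
                            epochs = 150L, iterations_per_epoch = 50L,
                            batch_size = 4L, lr = 5e-4,
                            lr_decay_factor = 0.5, lr_decay_every = 20L,
                            n_slides_per_domain = 5L, gen_filters = 16L,
                            disc_filters = 16L, gen_depth = 2L,
                            gen_instnorm = FALSE,
                            gen_kind = c("unet", "color"), seed = 1L) {
  stopifnot(lambda_cycle > 0, lambda_disc > 0, patch_size > 0, epochs >= 1,
            iterations_per_epoch >= 1, batch_size >= 1, lr > 0,
            lr_decay_factor > 0, lr_decay_factor < 1, lr_decay_every >= 1)
  structure(list(lambda_cycle = lambda_cycle, lambda_disc = lambda_disc,
                 patch_size = as.integer(patch_size),
                 magnification = magnification, epochs = as.integer(epochs),
                 iterations_per_epoch = as.integer(iterations_per_epoch),
                 batch_size = as.integer(batch_size), lr = lr,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_every = as.integer(lr_decay_every),
                 n_slides_per_domain = as.integer(n_slides_per_domain),
                 gen_filters = as.integer(gen_filters),
                 disc_filters = as.integer(disc_filters),
                 gen_depth = as.integer(gen_depth),
                 gen_instnorm = isTRUE(gen_instnorm),
                 gen_kind = match.arg(gen_kind),
                 seed = as.integer(seed)),
            class = "cyclegan_config")
}

#' Learning rate after a number of epochs
#'
#' Step decay: `lr * factor^floor(epoch / every)`.
#'
#' @param cfg A [cyclegan_config()].
#' @param epoch Completed epochs.
#' @return Learning rate in effect.
#' @export
cyclegan_lr <- function(cfg, epoch)
  cfg$lr * cfg$lr_decay_factor^(epoch %/% cfg$lr_decay_every)

# U-Net generator: image in [-1, 1] -> image in [-1, 1]. The network
# predicts a residual added to its input (near-identity at initialization),
# which stabilizes adversarial training and suits style transforms that are
# mostly smooth color remappings.
build_generator <- function(cfg) {
  if (identical(cfg$gen_kind, "color")) return(build_color_generator(cfg))
  d <- cfg$gen_depth
  nf <- cfg$gen_filters * 2^(0:(d - 1))
  params <- list()
  add <- function(name, k, cin, cout) {
    pr <- conv_params(k, cin, cout)
    params[[paste0(name, "_W")]] <<- pr$W
    params[[paste0(name, "_b")]] <<- pr$b
  }
  addn <- function(name, c) {
    params[[paste0(name, "_g")]] <<- nn_param(rep(1, c))
    params[[paste0(name, "_nb")]] <<- nn_param(numeric(c))
  }
  cin <- 3L
  for (l in seq_len(d)) {
    add(sprintf("enc%d", l), 3, cin, nf[l]); addn(sprintf("enc%d", l), nf[l])
    cin <- nf[l]
  }
  add("mid", 3, nf[d], nf[d]); addn("mid", nf[d])
  for (l in seq(d - 1, 1)) {
    add(sprintf("dec%d", l), 3, nf[l + 1] + nf[l], nf[l])
    addn(sprintf("dec%d", l), nf[l])
  }
  pr_out <- conv_params(3, nf[1], 3L, scale = 0.2)
  params$out_W <- pr_out$W; params$out_b <- pr_out$b
  use_in <- isTRUE(cfg$gen_instnorm)
  forward <- function(params, x, tape) {
    norm <- function(h, tag) {
      if (!use_in) return(h)
      nn_instnorm(tape, h, params[[paste0(tag, "_g")]],
                  params[[paste0(tag, "_nb")]])
    }
    skips <- vector("list", d - 1)
    h <- x
    for (l in seq_len(d)) {
      h <- nn_conv(tape, h, params[[sprintf("enc%d_W", l)]],
                   params[[sprintf("enc%d_b", l)]], 3)
      h <- nn_relu(tape, norm(h, sprintf("enc%d", l)))
      if (l < d) { skips[[l]] <- h; h <- nn_maxpool2(tape, h) }
    }
    h <- nn_relu(tape, norm(nn_conv(tape, h, params$mid_W, params$mid_b, 3),
                            "mid"))
    for (l in seq(d - 1, 1)) {
      h <- nn_concat(tape, skips[[l]], nn_upsample2(tape, h))
      h <- nn_conv(tape, h, params[[sprintf("dec%d_W", l)]],
                   params[[sprintf("dec%d_b", l)]], 3)
      h <- nn_relu(tape, norm(h, sprintf("dec%d", l)))
    }
    delta <- nn_conv(tape, h, params$out_W, params$out_b, 3)
    nn_add_scaled(tape, x, delta, 1, 1)
  }
  list(params = params, forward = forward)
}

# Pointwise color-remapping generator: 1x1 convolutions learn the global
# color transform, one 3x3 stage provides local context for mild deblurring;
# residual output, near-identity at initialization.
build_color_generator <- function(cfg) {
  nf <- cfg$gen_filters
  p1 <- conv_params(1, 3L, nf)
  p2 <- conv_params(1, nf, nf)
  p3 <- conv_params(3, nf, nf)
  p4 <- conv_params(3, nf, 3L, scale = 0.2)
  params <- list(c1_W = p1$W, c1_b = p1$b, c2_W = p2$W, c2_b = p2$b,
                 c3_W = p3$W, c3_b = p3$b, out_W = p4$W, out_b = p4$b)
  forward <- function(params, x, tape) {
    h <- nn_relu(tape, nn_conv(tape, x, params$c1_W, params$c1_b, 1))
    h <- nn_relu(tape, nn_conv(tape, h, params$c2_W, params$c2_b, 1))
    h <- nn_relu(tape, nn_conv(tape, h, params$c3_W, params$c3_b, 3))
    delta <- nn_conv(tape, h, params$out_W, params$out_b, 3)
    nn_add_scaled(tape, x, delta, 1, 1)
  }
  list(params = params, forward = forward)
}

# Patch discriminator: stride-2 4x4 convolutions, linear 1-channel head;
# least-squares targets 1 (real) / 0 (fake).
build_discriminator <- function(cfg, n_layers = 2L) {
  params <- list()
  add <- function(name, k, cin, cout) {
    pr <- conv_params(k, cin, cout)
    params[[paste0(name, "_W")]] <<- pr$W
    params[[paste0(name, "_b")]] <<- pr$b
  }
  cin <- 3L
  for (l in seq_len(n_layers)) {
    add(sprintf("d%d", l), 4, cin, cfg$disc_filters * 2^(l - 1))
    cin <- cfg$disc_filters * 2^(l - 1)
  }
  add("head", 3, cin, 1L)
  forward <- function(params, x, tape) {
    h <- x
    for (l in seq_len(n_layers))
      h <- nn_lrelu(tape, nn_conv(tape, h, params[[sprintf("d%d_W", l)]],
                                  params[[sprintf("d%d_b", l)]], 4,
                                  stride = 2L, pad = 1L))
    nn_conv(tape, h, params$head_W, params$head_b, 3)
  }
  list(params = params, forward = forward)
}

#' Sample tissue-constrained training patches
#'
#' Draws patch centres uniformly from the tissue mask of randomly chosen
#' slides, at the configured magnification, with rotation/mirror (and mild
#' scaling) augmentation. Returns a sampler closure so training can stream
#' patches without materializing a dataset.
#'
#' @param slides List of `slide_pyramid`s (one domain).
#' @param tissue_masks Matching list of `tissue_mask`s (NULL computes them).
#' @param cfg A [cyclegan_config()].
#' @param augment Apply rotation/mirror augmentation.
#' @return Function `(n)` returning `[p, p, 3, n]` patches in [0, 255].
#' @export
sample_training_patches <- function(slides, tissue_masks = NULL, cfg,
                                    augment = TRUE) {
  stopifnot(length(slides) >= 1)
  if (is.null(tissue_masks))
    tissue_masks <- lapply(slides, compute_tissue_mask)
  rendered <- lapply(slides, read_at_magnification,
                     magnification = cfg$magnification)
  p <- cfg$patch_size
  # per-slide lists of admissible centres (tissue pixels at analysis scale
  # far enough from the border)
  centres <- lapply(seq_along(slides), function(i) {
    img <- rendered[[i]]$image
    h <- dim(img)[1]; w <- dim(img)[2]
    tm <- resize_matrix(tissue_masks[[i]]$mask * 1, h, w, nearest = TRUE) > 0.5
    ok <- which(tm, arr.ind = TRUE)
    ok <- ok[ok[, 1] > p / 2 & ok[, 1] <= h - p / 2 &
               ok[, 2] > p / 2 & ok[, 2] <= w - p / 2, , drop = FALSE]
    ok
  })
  if (all(vapply(centres, nrow, 0L) == 0))
    stop("no tissue available to sample from in this domain")
  usable <- which(vapply(centres, nrow, 0L) > 0)
  function(n) {
    out <- array(0, dim = c(p, p, 3, n))
    for (j in seq_len(n)) {
      si <- usable[sample.int(length(usable), 1)]
      cc <- centres[[si]][sample.int(nrow(centres[[si]]), 1), ]
      y0 <- cc[1] - p %/% 2; x0 <- cc[2] - p %/% 2
      patch <- rendered[[si]]$image[y0 + seq_len(p), x0 + seq_len(p), ,
                                    drop = FALSE]
      if (augment) {
        patch <- rotate90(patch, sample(0:3, 1))
        if (stats::runif(1) < 0.5) patch <- patch[, p:1, , drop = FALSE]
      }
      out[, , , j] <- patch
    }
    out
  }
}

disc_mse_value <- function(disc, x, target_val) {
  tape <- nn_tape()
  o <- disc$forward(disc$params, nn_input(tape, x), tape)
  mean((o$value - target_val)^2)
}

#' Train a cycle-GAN between two scanner domains
#'
#' Alternating least-squares GAN updates with Adam (beta1 = 0.5), the
#' optimizer of the original cycle-consistent translation recipe: the
#' generators minimize
#' `lambda_disc` x adversarial loss + `lambda_cycle` x cycle-consistency L1;
#' each discriminator minimizes the least-squares real/fake objective on
#' genuine patches versus the current fakes. The learning rate follows the
#' configured step decay. Per-epoch loss components are recorded; a
#' non-finite loss aborts with a diagnostic.
#'
#' @param sample_a,sample_b Patch samplers (functions of `n`, as returned by
#'   [sample_training_patches()]) or fixed arrays `[p, p, 3, n]`.
#' @param cfg A [cyclegan_config()].
#' @param verbose Print per-epoch losses.
#' @return Object of class `cyclegan_pair`: generators `g_ab`, `g_ba`,
#'   discriminators `d_a`, `d_b`, the `history` data frame and `cfg`.
#' @export
train_cyclegan <- function(sample_a, sample_b, cfg = cyclegan_config(),
                           verbose = FALSE) {
  stopifnot(inherits(cfg, "cyclegan_config"))
  as_sampler <- function(s) {
    if (is.function(s)) return(s)
    stopifnot(length(dim(s)) == 4)
    function(n) s[, , , sample.int(dim(s)[4], n, replace = TRUE),
                  drop = FALSE]
  }
  sa <- as_sampler(sample_a); sb <- as_sampler(sample_b)
  with_seed(cfg$seed, {
    g_ab <- build_generator(cfg); g_ba <- build_generator(cfg)
    d_a <- build_discriminator(cfg); d_b <- build_discriminator(cfg)
    g_params <- c(g_ab$params, g_ba$params)
    hist <- NULL
    for (ep in seq_len(cfg$epochs)) {
      lr <- cyclegan_lr(cfg, ep - 1)
      comp <- c(adv = 0, cycle = 0, total = 0, d_a = 0, d_b = 0)
      for (it in seq_len(cfg$iterations_per_epoch)) {
        xa <- sa(cfg$batch_size) / 127.5 - 1
        xb <- sb(cfg$batch_size) / 127.5 - 1
        # generator update
        tape <- nn_tape(); tape$training <- TRUE
        a_in <- nn_input(tape, xa); b_in <- nn_input(tape, xb)
        fb <- g_ab$forward(g_ab$params, a_in, tape)   # a -> b
        fa <- g_ba$forward(g_ba$params, b_in, tape)   # b -> a
        ra <- g_ba$forward(g_ba$params, fb, tape)     # a -> b -> a
        rb <- g_ab$forward(g_ab$params, fa, tape)     # b -> a -> b
        db_fake <- d_b$forward(d_b$params, fb, tape)
        da_fake <- d_a$forward(d_a$params, fa, tape)
        adv <- nn_add_scaled(tape, nn_mse(tape, db_fake, 1),
                             nn_mse(tape, da_fake, 1))
        cyc <- nn_add_scaled(tape, nn_l1(tape, ra, xa),
                             nn_l1(tape, rb, xb))
        loss_g <- nn_add_scaled(tape, adv, cyc, cfg$lambda_disc,
                                cfg$lambda_cycle)
        if (!is.finite(loss_g$value))
          stop(sprintf("non-finite generator loss at epoch %d", ep))
        nn_zero_grads(c(g_params, d_a$params, d_b$params))
        nn_backward(tape, loss_g)
        nn_adam_step(g_params, lr)
        # discriminator updates on detached fakes
        upd_disc <- function(disc, real, fake) {
          tape <- nn_tape(); tape$training <- TRUE
          o_r <- disc$forward(disc$params, nn_input(tape, real), tape)
          o_f <- disc$forward(disc$params, nn_input(tape, fake), tape)
          loss <- nn_add_scaled(tape, nn_mse(tape, o_r, 1),
                                nn_mse(tape, o_f, 0), 0.5, 0.5)
          if (!is.finite(loss$value))
            stop(sprintf("non-finite discriminator loss at epoch %d", ep))
          nn_zero_grads(disc$params)
          nn_backward(tape, loss)
          nn_adam_step(disc$params, lr)
          loss$value
        }
        la <- upd_disc(d_a, xa, fa$value)
        lb <- upd_disc(d_b, xb, fb$value)
        comp <- comp + c(adv$value, cyc$value, loss_g$value, la, lb)
      }
      comp <- comp / cfg$iterations_per_epoch
      hist <- rbind(hist, data.frame(epoch = ep, lr = lr,
                                     g_adv = comp[1], g_cycle = comp[2],
                                     g_total = comp[3], d_a = comp[4],
                                     d_b = comp[5], row.names = NULL))
      if (verbose)
        message(sprintf("epoch %d (lr %.2e): adv %.4f cycle %.4f d %.4f/%.4f",
                        ep, lr, comp[1], comp[2], comp[4], comp[5]))
    }
    structure(list(g_ab = g_ab, g_ba = g_ba, d_a = d_a, d_b = d_b,
                   history = hist, cfg = cfg),
              class = "cyclegan_pair")
  })
}

#' @export
print.cyclegan_pair <- function(x, ...) {
  cat(sprintf("cyclegan_pair: %d epochs x %d iterations, lambda_cycle %.1f\n",
              nrow(x$history), x$cfg$iterations_per_epoch,
              x$cfg$lambda_cycle))
  tail_h <- x$history[nrow(x$history), ]
  cat(sprintf("  final losses: adv %.4f  cycle %.4f  d %.4f/%.4f\n",
              tail_h$g_adv, tail_h$g_cycle, tail_h$d_a, tail_h$d_b))
  invisible(x)
}

# Apply a generator to an image in [0, 255] (any spatial size compatible
# with the generator's pooling depth).
apply_generator <- function(gen, img) {
  x <- img / 127.5 - 1
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  tape <- nn_tape()
  y <- gen$forward(gen$params, nn_input(tape, x), tape)$value
  clamp((y[, , , 1] + 1) * 127.5, 0, 255)
}

#' Normalize a slide with a trained generator
#'
#' Slides the generator over the rendered slide in overlapping tiles (linear
#' ramp blending across the overlap suppresses seams); tiles without tissue
#' pass through unchanged. The result is rebuilt into a pyramid of the same
#' depth.
#'
#' @param slide A `slide_pyramid`.
#' @param generator One generator from a `cyclegan_pair` (e.g. `$g_ba` to map
#'   a test domain into the development domain).
#' @param tissue_mask A `tissue_mask`, or NULL to compute one.
#' @param tile_size Sliding-window tile size.
#' @param overlap Overlap between adjacent tiles (px).
#' @param magnification Working magnification (the normalized raster is
#'   produced at this scale).
#' @return A `slide_pyramid` of the normalized slide at the working scale.
#' @export
normalize_slide <- function(slide, generator, tissue_mask = NULL,
                            tile_size = 64L, overlap = 16L,
                            magnification = 5) {
  stopifnot(inherits(slide, "slide_pyramid"))
  if (is.null(tissue_mask)) tissue_mask <- compute_tissue_mask(slide)
  ra <- read_at_magnification(slide, magnification)
  img <- ra$image
  h <- dim(img)[1]; w <- dim(img)[2]
  tm <- resize_matrix(tissue_mask$mask * 1, h, w, nearest = TRUE) > 0.5
  step <- tile_size - overlap
  ys <- unique(c(seq(1, max(h - tile_size + 1, 1), by = step),
                 max(h - tile_size + 1, 1)))
  xs <- unique(c(seq(1, max(w - tile_size + 1, 1), by = step),
                 max(w - tile_size + 1, 1)))
  ramp <- pmin(seq_len(tile_size), rev(seq_len(tile_size)))
  wtile <- outer(ramp, ramp, pmin)
  acc <- array(0, dim = c(h, w, 3)); wsum <- matrix(0, h, w)
  for (y0 in ys) for (x0 in xs) {
    hh <- min(y0 + tile_size - 1, h) - y0 + 1
    ww <- min(x0 + tile_size - 1, w) - x0 + 1
    if (hh < tile_size || ww < tile_size) next  # grid already touches edges
    if (!any(tm[y0:(y0 + hh - 1), x0:(x0 + ww - 1)])) next
    tile <- img[y0:(y0 + hh - 1), x0:(x0 + ww - 1), , drop = FALSE]
    out <- apply_generator(generator, tile)
    wt <- wtile[seq_len(hh), seq_len(ww)]
    for (ch in 1:3) {
      acc[y0:(y0 + hh - 1), x0:(x0 + ww - 1), ch] <-
        acc[y0:(y0 + hh - 1), x0:(x0 + ww - 1), ch] + out[, , ch] * wt
    }
    wsum[y0:(y0 + hh - 1), x0:(x0 + ww - 1)] <-
      wsum[y0:(y0 + hh - 1), x0:(x0 + ww - 1)] + wt
  }
  res <- img
  covered <- wsum > 0
  for (ch in 1:3) {
    rc <- res[, , ch]; ac <- acc[, , ch]
    rc[covered] <- ac[covered] / wsum[covered]
    res[, , ch] <- rc
  }
  slide_pyramid(clamp(res, 0, 255),
                slide_id = paste0(slide$slide_id, "_norm"),
                mpp = ra$mpp, n_levels = length(slide$levels))
}

#' Domain gap between two patch sets
#'
#' Mean over RGB channels of the Wasserstein-1 distance between the two
#' sets' per-channel intensity histograms (256 bins on [0, 255]). Symmetric;
#' zero iff the empirical per-channel distributions coincide; a uniform
#' shift of +s grey levels in one channel contributes s/3.
#'
#' @param patches_a,patches_b Arrays of RGB values in [0, 255] (any shape
#'   with channels third, e.g. `[h, w, 3]` or `[h, w, 3, n]`).
#' @return Non-negative scalar.
#' @export
domain_gap <- function(patches_a, patches_b) {
  stopifnot(length(patches_a) > 0, length(patches_b) > 0)
  chan_vals <- function(x, ch) {
    d <- dim(x)
    if (length(d) == 3) as.vector(x[, , ch])
    else as.vector(x[, , ch, ])
  }
  w1 <- vapply(1:3, function(ch) {
    a <- chan_vals(patches_a, ch); b <- chan_vals(patches_b, ch)
    ha <- tabulate(pmin(pmax(floor(a), 0), 255) + 1L, 256L) / length(a)
    hb <- tabulate(pmin(pmax(floor(b), 0), 255) + 1L, 256L) / length(b)
    sum(abs(cumsum(ha) - cumsum(hb)))
  }, 0)
  mean(w1)
}
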