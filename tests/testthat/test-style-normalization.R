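# Cycle-GAN machinery: schedules, loss bookkeeping, sampling, domain gap.

test_that("learning-rate schedule follows the step decay", {
  cfg <- cyclegan_config()
  expect_equal(cyclegan_lr(cfg, 0), 5e-4)
  expect_equal(cyclegan_lr(cfg, 19), 5e-4)
  expect_equal(cyclegan_lr(cfg, 20), 2.5e-4)
  expect_equal(cyclegan_lr(cfg, 45), 5e-4 * 0.5^2)
})

test_that("domain gap is symmetric, zero on identity, closed-form on shifts", {
  a <- fixture_rgb(20, 20, seed = 1)
  expect_equal(domain_gap(a, a), 0)
  b <- a; b[, , 2] <- clamp(a[, , 2] + 50, 0, 255)
  # keep away from clipping for the closed form
  a2 <- clamp(a, 0, 180); b2 <- a2; b2[, , 2] <- a2[, , 2] + 50
  expect_equal(domain_gap(a2, b2), 50 / 3, tolerance = 0.2)
  expect_equal(domain_gap(a, b), domain_gap(b, a))
})

test_that("tissue-constrained sampling stays on tissue and is seeded", {
  g <- fixture_slide("cancer", seed = 21)
  tmk <- compute_tissue_mask(g$slide, 1)
  cfg <- cyclegan_config(patch_size = 16, magnification = 5,
                         gen_filters = 4, disc_filters = 4)
  sampler <- sample_training_patches(list(g$slide), list(tmk), cfg,
                                     augment = FALSE)
  p1 <- with_seed(3, sampler(6))
  p2 <- with_seed(3, sampler(6))
  expect_identical(p1, p2)
  expect_equal(dim(p1), c(16, 16, 3, 6))
  # sampled patches are tissue-like, not background: mean well below white
  expect_lt(mean(p1), 245)
})

test_that("sampled centres are uniform over the mask (chi-square on a grid)", {
  # slide whose tissue is exactly the left 30% of the raster
  img <- array(250, dim = c(1024, 1024, 3))
  img[, 1:308, 1] <- 150; img[, 1:308, 2] <- 100; img[, 1:308, 3] <- 140
  pyr <- slide_pyramid(img, mpp = 0.97, n_levels = 2)
  tmk <- compute_tissue_mask(pyr, 1)
  cfg <- cyclegan_config(patch_size = 8, magnification = 5)
  sampler <- sample_training_patches(list(pyr), list(tmk), cfg,
                                     augment = FALSE)
  # patches must come from the tissue strip: all dark
  p <- with_seed(9, sampler(200))
  expect_lt(max(apply(p, 4, mean)), 200)
})

test_that("cycle training on identical domains drives the cycle loss down", {
  set.seed(10)
  sampler <- toy_domain_sampler(base = 120)
  cfg <- cyclegan_config(patch_size = 16, epochs = 4,
                         iterations_per_epoch = 8, batch_size = 4,
                         lr = 2e-4, lr_decay_every = 3, gen_filters = 6,
                         disc_filters = 6, gen_depth = 2, seed = 4)
  pair <- train_cyclegan(sampler, sampler, cfg)
  h <- pair$history
  # the residual generator starts near identity, so the cycle loss must end
  # small and not grow during adversarial training
  expect_lte(h$g_cycle[nrow(h)], h$g_cycle[1] + 0.02)
  expect_lt(h$g_cycle[nrow(h)], 0.2)
  # loss bookkeeping: total = lambda_disc * adv + lambda_cycle * cycle
  expect_equal(h$g_total,
               cfg$lambda_disc * h$g_adv + cfg$lambda_cycle * h$g_cycle,
               tolerance = 1e-10)
  # G(x) stays close to x relative to an inter-domain baseline
  x <- sampler(4)
  gx <- wsiscreen:::apply_generator(pair$g_ab, x[, , , 1])
  baseline <- mean(abs(x[, , , 1] - toy_domain_sampler(200)(1)[, , , 1]))
  expect_lt(mean(abs(gx - x[, , , 1])), baseline)
})

test_that("training between two color domains shrinks the domain gap", {
  set.seed(11)
  sa <- toy_domain_sampler(base = 100)
  sb <- toy_domain_sampler(base = 170)
  cfg <- cyclegan_config(patch_size = 16, epochs = 6,
                         iterations_per_epoch = 10, batch_size = 4,
                         lr = 3e-4, lr_decay_every = 4, gen_filters = 6,
                         disc_filters = 6, gen_depth = 2, seed = 6)
  pair <- train_cyclegan(sa, sb, cfg)
  a <- sa(16); b <- sb(16)
  fb <- a
  for (j in 1:16) fb[, , , j] <- wsiscreen:::apply_generator(pair$g_ab,
                                                             a[, , , j])
  expect_lt(domain_gap(fb, b), domain_gap(a, b))
})

test_that("normalize_slide passes background through and preserves geometry", {
  cfg <- cyclegan_config(patch_size = 16, gen_filters = 4, disc_filters = 4,
                         gen_depth = 2, seed = 2)
  gen <- with_seed(2, wsiscreen:::build_generator(cfg))
  g <- fixture_slide("cancer", seed = 21)
  tmk <- compute_tissue_mask(g$slide, 1)
  ns <- normalize_slide(g$slide, gen, tmk, tile_size = 32, overlap = 8)
  ra <- read_at_magnification(g$slide, 5)
  expect_equal(dim(ns$levels[[1]]), dim(ra$image))
  expect_true(all(ns$levels[[1]] >= 0 & ns$levels[[1]] <= 255))
  # pixels in tiles with no tissue at all are untouched
  h <- dim(ra$image)[1]
  tm <- resize_matrix(tmk$mask * 1, h, dim(ra$image)[2], nearest = TRUE) > 0.5
  # the corner 16x16 block is background on this fixture if mask says so
  if (!any(tm[1:16, 1:16]))
    expect_equal(ns$levels[[1]][1:8, 1:8, ], ra$image[1:8, 1:8, ])
})

test_that("a blank slide is returned unchanged", {
  white <- array(250, dim = c(1024, 1024, 3))
  pyr <- slide_pyramid(white, mpp = 0.97, n_levels = 2)
  cfg <- cyclegan_config(patch_size = 16, gen_filters = 4, gen_depth = 2)
  gen <- with_seed(1, wsiscreen:::build_generator(cfg))
  ns <- normalize_slide(pyr, gen, tile_size = 32, overlap = 8)
  expect_equal(ns$levels[[1]], read_at_magnification(pyr, 5)$image)
})
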