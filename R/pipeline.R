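# End-to-end desk-scale experiments on synthetic cohorts: development-style
# training and evaluation, and the cross-scanner style-normalization study.
# These drivers are the package's worked experiments; every stage is the
# exported module function, just wired together.

#' Desk-scale screening study on a synthetic cohort
#'
#' Generates a synthetic cohort (default 60 slides at 25% cancer prevalence,
#' development scanner style), trains a reduced U-Net on patches extracted
#' from the sparse annotations of the training slides, runs tiled inference
#' on the held-out slides, scores each with T07 and evaluates slide-level
#' ROC/AUC with a bootstrap confidence interval. The held-out manifest rows
#' are kept so the cross-scanner study can re-render and rescore the same
#' tissue in another style.
#'
#' @param seed Master seed for the whole study.
#' @param n_slides Cohort size; the last `n_test` slides are held out.
#' @param n_test Held-out slide count.
#' @param prevalence Cancer prevalence.
#' @param dev_style The development-scanner [center_style()].
#' @param slide_px Slide raster size (level 0).
#' @param patch_size Patch/tile size at the analysis magnification.
#' @param magnification Analysis magnification.
#' @param max_patches_per_slide Cap on extracted patches per slide.
#' @param unet Reduced U-Net configuration for desk-scale training.
#' @param train_cfg Training configuration.
#' @param n_boot Bootstrap resamples for the AUC interval.
#' @param verbose Progress messages.
#' @return Object of class `screening_study`: the trained model, manifest,
#'   held-out evaluation (`roc`, `points`, `scores`, `labels`), patch-level
#'   validation Dice, and cached held-out slide data.
#' @export
run_screening_study <- function(seed = 1L, n_slides = 60L, n_test = 20L,
                                prevalence = 0.25,
                                dev_style = builtin_styles()$scanner_a,
                                slide_px = 1024L, patch_size = 32L,
                                magnification = 5,
                                max_patches_per_slide = 40L,
                                unet = unet_config(depth = 3L,
                                                   base_filters = 12L,
                                                   dropout = 0.1,
                                                   input_size = patch_size),
                                train_cfg = train_config(batch_size = 8L,
                                                         lr = 0.01,
                                                         epochs = 10L,
                                                         patience = 3L,
                                                         steps_per_epoch = 40L,
                                                         seed = seed),
                                n_boot = 2000L, verbose = FALSE) {
  styles <- list(dev_style); names(styles) <- dev_style$style_id
  manifest <- plan_cohort(n_slides, prevalence, styles, seed = seed,
                          width = slide_px, height = slide_px)
  idx_test <- seq(n_slides - n_test + 1L, n_slides)
  # a degenerate single-class held-out set cannot be ROC-evaluated: swap in
  # the nearest training slide of the missing class (deterministic rule)
  if (length(unique(manifest$label[idx_test])) < 2) {
    missing_lab <- setdiff(c("cancer", "normal"), manifest$label[idx_test])
    don <- max(which(manifest$label[-idx_test] == missing_lab))
    swap <- manifest[don, ]; manifest[don, ] <- manifest[idx_test[1], ]
    manifest[idx_test[1], ] <- swap
  }
  train_rows <- manifest[-idx_test, ]
  test_rows <- manifest[idx_test, ]

  collect <- with_seed(derive_seed(seed, 101L), {
    xs <- list(); cls <- character(0)
    for (i in seq_len(nrow(train_rows))) {
      g <- generate_slide_from_row(train_rows[i, ], styles)
      recs <- extract_patches(g$annotations, patch_size = patch_size,
                             magnification = magnification,
                             stride = patch_size %/% 2L,
                             slide_id = train_rows$slide_id[i])
      if (nrow(recs) == 0) next
      if (nrow(recs) > max_patches_per_slide)
        recs <- recs[sample.int(nrow(recs), max_patches_per_slide), ]
      for (j in seq_len(nrow(recs))) {
        xs[[length(xs) + 1]] <- read_patch(g$slide, recs[j, ])
        cls <- c(cls, recs$class_label[j])
      }
      if (verbose && i %% 10 == 0)
        message(sprintf("  training slides processed: %d", i))
    }
    list(xs = xs, cls = cls)
  })
  n_pat <- length(collect$xs)
  if (n_pat < 10) stop("too few training patches extracted")
  x_all <- array(0, dim = c(patch_size, patch_size, 3, n_pat))
  y_all <- array(0, dim = c(patch_size, patch_size, 5, n_pat))
  for (i in seq_len(n_pat)) {
    x_all[, , , i] <- collect$xs[[i]]
    y_all[, , , i] <- make_target(collect$cls[i], patch_size)
  }
  # class-balanced oversampling of the training split per the sampling plan;
  # the oversampled copies are augmented (the heavier-augmentation-for-rarer-
  # classes strategy), and every training patch receives one augmentation
  # draw so the model tolerates benign color/contrast variation
  aug_cfg <- augmentation_config()
  split <- with_seed(derive_seed(seed, 102L), {
    val_idx <- sample.int(n_pat, max(4L, round(0.15 * n_pat)))
    tr_idx <- setdiff(seq_len(n_pat), val_idx)
    plan <- suppressWarnings(plan_balanced_sampling(
      data.frame(class_label = collect$cls[tr_idx])))
    reps <- plan$multiplier[match(collect$cls[tr_idx], plan$class_label)]
    list(tr = rep(tr_idx, reps), val = val_idx)
  })
  n_tr <- length(split$tr)
  x_tr <- array(0, dim = c(patch_size, patch_size, 3, n_tr))
  y_tr <- y_all[, , , split$tr, drop = FALSE]
  with_seed(derive_seed(seed, 105L), {
    for (i in seq_len(n_tr))
      x_tr[, , , i] <- augment_patch(x_all[, , , split$tr[i]], aug_cfg)
  })
  model <- build_unet(unet, seed = derive_seed(seed, 103L))
  model <- train_model(model, x_tr, y_tr,
                       x_all[, , , split$val, drop = FALSE],
                       y_all[, , , split$val, drop = FALSE],
                       train_cfg, verbose = verbose)
  val_metrics <- eval_metrics(model, x_all[, , , split$val, drop = FALSE],
                              y_all[, , , split$val, drop = FALSE])

  scores <- numeric(nrow(test_rows))
  for (i in seq_len(nrow(test_rows))) {
    g <- generate_slide_from_row(test_rows[i, ], styles)
    tmk <- compute_tissue_mask(g$slide, level = 1)
    lm <- predict_slide(model, g$slide, tmk, patch_size = patch_size,
                        magnification = magnification)
    scores[i] <- t07(derive_tumor_map(lm))
    if (verbose) message(sprintf("  held-out %s: T07 %.3f (%s)",
                                 test_rows$slide_id[i], scores[i],
                                 test_rows$label[i]))
  }
  roc <- roc_with_ci(scores, test_rows$label, n_boot = n_boot,
                     seed = derive_seed(seed, 104L))
  structure(list(model = model, manifest = manifest,
                 train_rows = train_rows, test_rows = test_rows,
                 styles = styles, scores = scores,
                 labels = test_rows$label, roc = roc,
                 points = operating_points(roc),
                 val_dice = val_metrics$dice,
                 patch_size = patch_size, magnification = magnification,
                 slide_px = slide_px, seed = seed),
            class = "screening_study")
}

#' @export
print.screening_study <- function(x, ...) {
  cat(sprintf("screening_study: %d train / %d held-out slides\n",
              nrow(x$train_rows), nrow(x$test_rows)))
  cat(sprintf("  patch-level validation cancer Dice: %.3f\n", x$val_dice))
  print(x$roc)
  print(x$points)
  invisible(x)
}

#' Cross-scanner style-normalization study
#'
#' Re-renders the held-out slides of a [run_screening_study()] in a second
#' scanner style (the "re-scanning the same tissue elsewhere" situation),
#' scores them with the unchanged model (the cross-scanner performance
#' drop), then trains a small cycle-GAN between the two styles on a handful
#' of slides per domain, normalizes the foreign-style slides into the
#' development style, and rescores. Also reports the domain gap between the
#' foreign-style and development-style renderings before and after
#' normalization.
#'
#' @param study A `screening_study`.
#' @param alt_style The foreign scanner [center_style()].
#' @param gan_cfg Desk-scale [cyclegan_config()].
#' @param n_gan_slides Slides per domain for cycle-GAN training.
#' @param verbose Progress messages.
#' @return Object of class `normalization_study`: AUCs for the development
#'   style (`auc_dev`), the foreign style before (`auc_alt`) and after
#'   (`auc_norm`) normalization, domain gaps before/after, scores, and the
#'   trained `cyclegan_pair`.
#' @export
run_normalization_study <- function(study,
                                    alt_style = builtin_styles()$scanner_b,
                                    gan_cfg = cyclegan_config(
                                      patch_size = 16L,
                                      magnification = study$magnification,
                                      epochs = 50L,
                                      iterations_per_epoch = 50L,
                                      batch_size = 4L, lr = 4e-4,
                                      lr_decay_every = 18L,
                                      gen_filters = 16L, disc_filters = 16L,
                                      gen_depth = 2L, gen_kind = "color",
                                      seed = study$seed),
                                    n_gan_slides = 5L, verbose = FALSE) {
  stopifnot(inherits(study, "screening_study"))
  model <- study$model
  alt_styles <- list(alt_style); names(alt_styles) <- alt_style$style_id
  # foreign-style renderings of the held-out slides (same tissue, same seed)
  alt_rows <- study$test_rows
  alt_rows$center_style_id <- alt_style$style_id
  alt_slides <- vector("list", nrow(alt_rows))
  alt_masks <- vector("list", nrow(alt_rows))
  scores_alt <- numeric(nrow(alt_rows))
  for (i in seq_len(nrow(alt_rows))) {
    g <- generate_slide_from_row(alt_rows[i, ], alt_styles)
    alt_slides[[i]] <- g$slide
    alt_masks[[i]] <- compute_tissue_mask(g$slide, level = 1)
    lm <- predict_slide(model, g$slide, alt_masks[[i]],
                        patch_size = study$patch_size,
                        magnification = study$magnification)
    scores_alt[i] <- t07(derive_tumor_map(lm))
  }
  roc_alt <- roc_auc(scores_alt, study$labels)
  if (verbose) message(sprintf("foreign-style AUC: %.3f (dev %.3f)",
                               roc_alt$auc, study$roc$auc))

  # cycle-GAN training material: a few development-set slides vs the first
  # foreign-style slides
  dev_slides <- lapply(seq_len(n_gan_slides), function(i)
    generate_slide_from_row(study$train_rows[i, ], study$styles)$slide)
  sa <- with_seed(derive_seed(study$seed, 201L),
                  sample_training_patches(dev_slides, NULL, gan_cfg))
  sb <- with_seed(derive_seed(study$seed, 202L),
                  sample_training_patches(alt_slides[seq_len(n_gan_slides)],
                                          alt_masks[seq_len(n_gan_slides)],
                                          gan_cfg))
  pair <- train_cyclegan(sa, sb, gan_cfg, verbose = verbose)

  # domain gap before/after, measured as a paired re-scan comparison: the
  # same held-out slides rendered in both styles, patches cut at identical
  # tissue coordinates, so only the style difference is scored
  gp <- 32L; k_per_slide <- 120L
  gap_a <- list(); gap_b <- list()
  with_seed(derive_seed(study$seed, 203L), {
    for (i in seq_len(min(2L, length(alt_slides)))) {
      ga <- generate_slide_from_row(study$test_rows[i, ], study$styles)
      ra <- read_at_magnification(ga$slide, study$magnification)$image
      rb <- read_at_magnification(alt_slides[[i]],
                                  study$magnification)$image
      tm <- resize_matrix(compute_tissue_mask(ga$slide, 1)$mask * 1,
                          dim(ra)[1], dim(ra)[2], nearest = TRUE) > 0.5
      ok <- which(tm, arr.ind = TRUE)
      ok <- ok[ok[, 1] > gp / 2 & ok[, 1] <= dim(ra)[1] - gp / 2 &
                 ok[, 2] > gp / 2 & ok[, 2] <= dim(ra)[2] - gp / 2, ,
               drop = FALSE]
      sel <- ok[sample.int(nrow(ok), min(k_per_slide, nrow(ok))), ,
                drop = FALSE]
      for (k in seq_len(nrow(sel))) {
        y0 <- sel[k, 1] - gp / 2; x0 <- sel[k, 2] - gp / 2
        gap_a[[length(gap_a) + 1]] <- ra[y0 + seq_len(gp),
                                         x0 + seq_len(gp), , drop = FALSE]
        gap_b[[length(gap_b) + 1]] <- rb[y0 + seq_len(gp),
                                         x0 + seq_len(gp), , drop = FALSE]
      }
    }
  })
  to_arr <- function(l) {
    a <- array(0, c(gp, gp, 3, length(l)))
    for (j in seq_along(l)) a[, , , j] <- l[[j]]
    a
  }
  gap_patches_a <- to_arr(gap_a)
  gap_patches_b <- to_arr(gap_b)
  gap_before <- domain_gap(gap_patches_b, gap_patches_a)
  norm_b <- gap_patches_b
  for (j in seq_len(dim(norm_b)[4]))
    norm_b[, , , j] <- apply_generator(pair$g_ba, norm_b[, , , j])
  gap_after <- domain_gap(norm_b, gap_patches_a)

  scores_norm <- numeric(length(alt_slides))
  for (i in seq_along(alt_slides)) {
    ns <- normalize_slide(alt_slides[[i]], pair$g_ba, alt_masks[[i]],
                          tile_size = 2L * study$patch_size,
                          overlap = study$patch_size %/% 2L,
                          magnification = study$magnification)
    lm <- predict_slide(model, ns, alt_masks[[i]],
                        patch_size = study$patch_size,
                        magnification = study$magnification)
    scores_norm[i] <- t07(derive_tumor_map(lm))
  }
  roc_norm <- roc_auc(scores_norm, study$labels)
  if (verbose) message(sprintf("normalized AUC: %.3f", roc_norm$auc))
  structure(list(auc_dev = study$roc$auc, auc_alt = roc_alt$auc,
                 auc_norm = roc_norm$auc, gap_before = gap_before,
                 gap_after = gap_after, scores_alt = scores_alt,
                 scores_norm = scores_norm, labels = study$labels,
                 pair = pair),
            class = "normalization_study")
}

#' @export
print.normalization_study <- function(x, ...) {
  cat(sprintf(
    "normalization_study:\n  AUC dev-style %.3f | foreign %.3f | normalized %.3f\n",
    x$auc_dev, x$auc_alt, x$auc_norm))
  cat(sprintf("  domain gap %.1f -> %.1f (ratio %.2f)\n", x$gap_before,
              x$gap_after, x$gap_after / x$gap_before))
  invisible(x)
}
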