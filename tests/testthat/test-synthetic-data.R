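# Synthetic cohort generator: determinism, label consistency, styles.

test_that("slide generation is deterministic and label-consistent", {
  g1 <- fixture_slide("cancer", seed = 21)
  spec <- slide_spec("fix_21", width = 1024L, height = 1024L,
                     label = "cancer", seed = 21L)
  g2 <- generate_slide(spec, center_style())
  expect_identical(g1$slide$levels[[1]], g2$slide$levels[[1]])
  expect_identical(g1$annotations$regions, g2$annotations$regions)
  cls <- vapply(g1$truth$regions, `[[`, "", "class_label")
  expect_gte(sum(cls == "cancer"), 1)
  gn <- fixture_slide("normal", seed = 22)
  cls_n <- vapply(gn$truth$regions, `[[`, "", "class_label")
  expect_equal(sum(cls_n == "cancer"), 0)
  ann_n <- vapply(gn$annotations$regions, `[[`, "", "class_label")
  expect_equal(sum(ann_n == "cancer"), 0)
})

test_that("slides have near-white background and sparse annotations", {
  g <- fixture_slide("cancer", seed = 21)
  img <- g$slide$levels[[1]]
  bg <- !g$truth$tissue
  expect_gt(mean(img[, , 1][bg]), 235)       # background near white
  # annotations are a subset of the placed regions
  expect_lte(length(g$annotations$regions), length(g$truth$regions))
  ann_area <- sum(vapply(g$annotations$regions,
                         function(r) polygon_area(r$polygon), 0))
  truth_area <- sum(vapply(g$truth$regions,
                           function(r) polygon_area(r$polygon), 0))
  expect_lte(ann_area, truth_area + 1e-9)
})

test_that("undersized slides are rejected", {
  expect_error(slide_spec("s", width = 512L, height = 512L), "1024")
})

test_that("cohort labels replay the seeded Bernoulli draws", {
  m <- plan_cohort(100, prevalence = 0.25, styles = builtin_styles()[1],
                   seed = 7)
  replay <- with_seed(7, stats::rbinom(100, 1, 0.25))
  expect_equal(as.integer(m$label == "cancer"), replay)
  # prevalence within binomial sampling error (3 sd)
  m2 <- plan_cohort(200, prevalence = 0.25, styles = builtin_styles()[1:2],
                    seed = 11)
  n_cancer <- sum(m2$label == "cancer")
  expect_lt(abs(n_cancer - 50), 3 * sqrt(200 * 0.25 * 0.75))
  # exact count reproducible
  m3 <- plan_cohort(200, prevalence = 0.25, styles = builtin_styles()[1:2],
                    seed = 11)
  expect_identical(m2$label, m3$label)
})

test_that("cohort planning validates inputs and assigns styles", {
  expect_equal(sum(plan_cohort(4, 1, builtin_styles()[1],
                               seed = 1)$label == "cancer"), 4)
  expect_error(plan_cohort(0, 0.5, builtin_styles()[1]), "n must be")
  expect_error(plan_cohort(4, 0.5, list()), "empty style list")
  m <- plan_cohort(6, 0.5, builtin_styles()[1:2], seed = 1)
  expect_equal(m$center_style_id,
               rep(c("scanner_a", "scanner_b"), 3))
  mb <- plan_cohort(6, 0.5, builtin_styles()[1:2], seed = 1,
                    style_assignment = "blocks")
  expect_equal(mb$center_style_id,
               rep(c("scanner_a", "scanner_b"), each = 3))
})

test_that("identity style is bit-identical and color ops are linear", {
  img <- fixture_rgb()
  expect_identical(apply_center_style(img, center_style()), img)
  grey <- array(200, dim = c(4, 4, 3))
  out <- apply_center_style(grey, center_style("b", brightness_scale = 0.5))
  expect_equal(out, array(100, dim = c(4, 4, 3)))
  expect_error(apply_center_style(matrix(1, 3, 3), center_style()), "RGB")
})

test_that("three 120-degree hue rotations return to the identity", {
  img <- fixture_rgb(seed = 5)
  s <- center_style("h", hue_shift = 120)
  x <- img
  for (i in 1:3) x <- apply_center_style(x, s)
  expect_equal(x, img, tolerance = 1e-9)
})

test_that("styles separate domains more than seeds separate slides", {
  sa <- builtin_styles()$scanner_a
  sb <- builtin_styles()$scanner_b
  g_a1 <- fixture_slide("cancer", seed = 31, style = sa)
  g_a2 <- fixture_slide("cancer", seed = 32, style = sa)
  g_b1 <- fixture_slide("cancer", seed = 31, style = sb)
  lvl <- function(g) g$slide$levels[[2]]
  gap_styles <- domain_gap(lvl(g_a1), lvl(g_b1))
  gap_seeds <- domain_gap(lvl(g_a1), lvl(g_a2))
  expect_gt(gap_styles, gap_seeds)
})

test_that("per-class textures are separable by a trivial color classifier", {
  # nearest-class-mean on mean patch color, trained on one seed and applied
  # to a fresh seed, must exceed 0.9 accuracy: the cohort is learnable
  collect <- function(seeds) {
    feats <- NULL; y <- character(0)
    for (seed in seeds) {
      g <- fixture_slide("cancer", seed = seed)
      recs <- extract_patches(g$annotations, patch_size = 16,
                              magnification = 5, stride = 16)
      # stratify: up to 12 patches per class per slide
      keep <- unlist(lapply(split(seq_len(nrow(recs)), recs$class_label),
                            utils::head, 12))
      recs <- recs[keep, ]
      feats <- rbind(feats, t(vapply(seq_len(nrow(recs)), function(j)
        apply(read_patch(g$slide, recs[j, ]), 3, mean), numeric(3))))
      y <- c(y, recs$class_label)
    }
    list(x = feats, y = y)
  }
  tr <- collect(c(31, 32, 34)); te <- collect(33)
  centroids <- do.call(rbind, lapply(split(as.data.frame(tr$x), tr$y),
                                     colMeans))
  # score only the classes the classifier has seen (sparse slides need not
  # contain every class)
  seen <- te$y %in% rownames(centroids)
  expect_gte(sum(seen), 10)
  expect_gt(length(unique(te$y[seen])), 1)
  pred <- rownames(centroids)[apply(te$x[seen, , drop = FALSE], 1,
                                    function(v)
                                      which.min(colSums((t(centroids) - v)^2)))]
  expect_gt(mean(pred == te$y[seen]), 0.9)
})

test_that("generate_cohort writes slides, annotations and manifest", {
  out <- withr::local_tempdir()
  man <- generate_cohort(2, prevalence = 1, styles = builtin_styles()[1],
                         out_dir = out, seed = 3, width = 1024L,
                         height = 1024L)
  expect_true(file.exists(file.path(out, "manifest.csv")))
  expect_true(all(file.exists(file.path(out, man$path))))
  expect_true(all(file.exists(file.path(out, man$annotation_path))))
  back <- read_slide(file.path(out, man$path[1]))
  expect_equal(length(back$levels), 2)
  ann <- read_annotations(file.path(out, man$annotation_path[1]), "asap_xml")
  expect_gt(length(ann), 0)
})
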