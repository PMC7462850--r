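# Synthetic multi-center slide cohorts. Slides emulate the statistical
# structure the pipeline assumes: near-white background, H&E-like tissue,
# five region classes with procedurally distinct textures, sparse polygon
# annotations covering only part of each class, ~25% cancer prevalence, and
# per-center scanner styles. Not photorealistic histology: the textures exist
# to be learnable by a small CNN, not to fool a pathologist.

# Per-class base colors (H&E-ish) and blob-texture parameters. Classes are
# separable mainly by color, secondarily by blob density/size.
CLASS_TEXTURES <- list(
  cancer = list(base = c(120, 60, 140), nucleus = c(60, 25, 80),
                blob_scale = 2.2, blob_frac = 0.45),
  benign = list(base = c(235, 170, 205), nucleus = c(150, 90, 140),
                blob_scale = 5.0, blob_frac = 0.20),
  other_tissue_type = list(base = c(205, 175, 120), nucleus = c(140, 110, 60),
                           blob_scale = 4.0, blob_frac = 0.30),
  hg_pin = list(base = c(175, 105, 185), nucleus = c(95, 50, 110),
                blob_scale = 3.2, blob_frac = 0.30),
  other = list(base = c(170, 185, 205), nucleus = c(110, 125, 150),
               blob_scale = 6.0, blob_frac = 0.15)
)

#' Slide generation specification
#'
#' @param slide_id Identifier.
#' @param width,height Level-0 raster size in pixels (>= 1024; smaller
#'   slides cannot be tiled meaningfully).
#' @param mpp Microns per pixel at level 0.
#' @param label `"cancer"` or `"normal"`; cancer slides receive at least one
#'   cancer region, normal slides none.
#' @param center_style_id Style identifier (bookkeeping only; the style
#'   object itself is passed to [generate_slide()]).
#' @param seed Per-slide RNG seed.
#' @return Object of class `slide_spec`.
#' @export
slide_spec <- function(slide_id, width = 4096L, height = 4096L, mpp = 0.97,
                       label = c("normal", "cancer"),
                       center_style_id = "scanner_a", seed = 1L) {
  label <- match.arg(label)
  if (width < 1024 || height < 1024)
    stop("slides below 1024 px are too small to tile")
  stopifnot(mpp > 0)
  structure(list(slide_id = slide_id, width = as.integer(width),
                 height = as.integer(height), mpp = mpp, label = label,
                 center_style_id = center_style_id, seed = as.integer(seed)),
            class = "slide_spec")
}

# Smooth blob field on an (h, w) grid: thresholded blurred white noise.
# blob_scale controls the feature size (px), blob_frac the covered fraction.
blob_field <- function(h, w, blob_scale, blob_frac) {
  coarse_h <- max(2, ceiling(h / blob_scale))
  coarse_w <- max(2, ceiling(w / blob_scale))
  z <- matrix(stats::rnorm(coarse_h * coarse_w), coarse_h, coarse_w)
  z <- resize_matrix(z, h, w)
  z <- z + matrix(stats::rnorm(h * w, sd = 0.15), h, w)
  thr <- stats::quantile(z, 1 - blob_frac, names = FALSE)
  z > thr
}

# Paint one textured region into `img` (modified in place semantics via
# return); mask_global collects the region's footprint.
paint_region <- function(img, poly, class_label) {
  tex <- CLASS_TEXTURES[[class_label]]
  x0 <- max(0, floor(min(poly[, 1]))); x1 <- min(dim(img)[2], ceiling(max(poly[, 1])))
  y0 <- max(0, floor(min(poly[, 2]))); y1 <- min(dim(img)[1], ceiling(max(poly[, 2])))
  if (x1 <= x0 || y1 <= y0) return(img)
  m <- polygon_raster_mask(poly, x0, y0, x1, y1)
  h <- nrow(m); w <- ncol(m)
  blobs <- blob_field(h, w, tex$blob_scale, tex$blob_frac)
  shade <- matrix(stats::rnorm(h * w, 0, 6), h, w)
  rows <- (y0 + 1):(y0 + h); cols <- (x0 + 1):(x0 + w)
  for (ch in 1:3) {
    base <- matrix(tex$base[ch], h, w) + shade
    base[blobs] <- tex$nucleus[ch] + shade[blobs]
    sub <- img[rows, cols, ch]
    sub[m] <- base[m]
    img[rows, cols, ch] <- sub
  }
  img
}

# Tissue backdrop: union of large soft ellipses filled with pale stroma.
tissue_backdrop <- function(h, w, n_pieces = 3L) {
  mask <- matrix(FALSE, h, w)
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), times = w), h, w)
  pieces <- vector("list", n_pieces)
  for (i in seq_len(n_pieces)) {
    cx <- stats::runif(1, 0.25 * w, 0.75 * w)
    cy <- stats::runif(1, 0.25 * h, 0.75 * h)
    rx <- stats::runif(1, 0.24, 0.34) * w
    ry <- stats::runif(1, 0.24, 0.34) * h
    th <- stats::runif(1, 0, pi)
    xr <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
    yr <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
    e <- (xr / rx)^2 + (yr / ry)^2 <= 1
    mask <- mask | e
    pieces[[i]] <- c(cx = cx, cy = cy, rx = rx, ry = ry, th = th)
  }
  list(mask = mask, pieces = pieces)
}

#' Generate one synthetic slide
#'
#' Deterministic given `spec` (including its seed) and `style`. The returned
#' annotation set is sparse: only 30-60% of each class's placed area is
#' annotated (at least one region per present class, and at least one cancer
#' region on cancer slides). The full region list and the ground-truth tissue
#' mask are attached for evaluation as `truth`.
#'
#' @param spec A [slide_spec()].
#' @param style A [center_style()] applied after rendering.
#' @return List with `slide` (a `slide_pyramid`, 2 levels), `annotations`
#'   (sparse `annotation_set`), `label`, and `truth` (list: `regions` with
#'   all placed polygons, `tissue` logical matrix at level 0).
#' @export
generate_slide <- function(spec, style = center_style()) {
  stopifnot(inherits(spec, "slide_spec"), inherits(style, "center_style"))
  with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    img <- array(stats::rnorm(h * w * 3, 245, 2), dim = c(h, w, 3))
    bd <- tissue_backdrop(h, w)
    stroma <- c(228, 205, 218)
    for (ch in 1:3) {
      layer <- img[, , ch]
      layer[bd$mask] <- stroma[ch] + stats::rnorm(sum(bd$mask), 0, 5)
      img[, , ch] <- layer
    }
    # place class regions inside tissue pieces
    n_cancer <- if (spec$label == "cancer") sample(1:3, 1) else 0L
    counts <- c(cancer = n_cancer, benign = sample(1:2, 1),
                other_tissue_type = sample(1:2, 1),
                hg_pin = sample(1:2, 1), other = sample(1:2, 1))
    r_scale <- min(h, w) / 1024
    regions <- list()
    placed <- NULL   # (cx, cy, r) of accepted regions; regions must not
                     # overlap or class labels would be corrupted by overpaint
    # interleave classes (cancer first to guarantee its slot on cancer
    # slides, the rest shuffled) so no class is starved of space
    plan <- rep(names(counts), counts)
    plan <- c(plan[plan == "cancer"], sample(plan[plan != "cancer"]))
    for (cl in plan) {
      ok <- FALSE
      for (try in 1:40) {
        piece <- bd$pieces[[sample(length(bd$pieces), 1)]]
        # keep region centres well inside the ellipse
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- sqrt(stats::runif(1)) * 0.7
        cx <- piece["cx"] + rad * piece["rx"] * cos(ang)
        cy <- piece["cy"] + rad * piece["ry"] * sin(ang)
        r <- stats::runif(1, 75, 110) * r_scale
        if (is.null(placed) ||
            all(sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2) >
                  1.2 * (placed[, 3] + r))) { ok <- TRUE; break }
      }
      if (!ok) {
        if (cl == "cancer" && spec$label == "cancer" &&
            !any(vapply(regions, `[[`, "", "class_label") == "cancer")) {
          # a cancer slide must carry >= 1 cancer region: accept crowding
        } else next
      }
      placed <- rbind(placed, c(cx, cy, r))
      poly <- random_star_polygon(cx, cy, r, n_vertices = 12,
                                  irregularity = 0.2,
                                  aspect = stats::runif(1, 0.8, 1))
      poly[, 1] <- clamp(poly[, 1], 2, w - 2)
      poly[, 2] <- clamp(poly[, 2], 2, h - 2)
      img <- paint_region(img, poly, cl)
      regions[[length(regions) + 1]] <-
        list(polygon = poly, class_label = cl,
             name = sprintf("%s_%d", cl, length(regions) + 1))
    }
    truth_tissue <- bd$mask
    img <- clamp(img, 0, 255)
    img <- apply_center_style(img, style)
    # sparse annotation: per class, annotate regions until 30-60% of the
    # class area is covered, always keeping at least one
    ann_regions <- list()
    cls <- vapply(regions, `[[`, "", "class_label")
    for (cl in unique(cls)) {
      idx <- which(cls == cl)
      areas <- vapply(idx, function(i) polygon_area(regions[[i]]$polygon), 0)
      target <- stats::runif(1, 0.3, 0.6) * sum(areas)
      ord <- sample(idx)
      cum <- 0
      for (i in ord) {
        ann_regions[[length(ann_regions) + 1]] <- regions[[i]]
        cum <- cum + polygon_area(regions[[i]]$polygon)
        if (cum >= target) break
      }
    }
    slide <- slide_pyramid(img, slide_id = spec$slide_id, mpp = spec$mpp,
                           n_levels = 2L)
    list(slide = slide,
         annotations = annotation_set(ann_regions, mpp = spec$mpp),
         label = spec$label,
         truth = list(regions = regions, tissue = truth_tissue))
  })
}

#' Plan a synthetic cohort (labels, seeds, styles)
#'
#' Draws slide labels as seeded Bernoulli trials at the given cancer
#' prevalence (default 25%, the cohort structure the pipeline assumes) and
#' assigns scanner styles either round-robin or in per-center blocks. This is
#' the pure planning step: no pixels are rendered, so a manifest can be
#' replayed slide-by-slide with [generate_slide()] via
#' [generate_slide_from_row()].
#'
#' @param n Number of slides (>= 1).
#' @param prevalence Cancer prevalence in [0, 1].
#' @param styles Named list of [center_style()] objects (non-empty).
#' @param seed Master seed; per-slide seeds are derived by splitmix-style
#'   hashing ([derive_seed()]).
#' @param style_assignment `"round_robin"` or `"blocks"`.
#' @param width,height,mpp Slide geometry passed to each [slide_spec()].
#' @return Data frame (the manifest): `slide_id`, `path`, `annotation_path`,
#'   `label`, `center_style_id`, `seed`, `width`, `height`, `mpp`.
#' @export
plan_cohort <- function(n, prevalence = 0.25, styles = builtin_styles()[1],
                        seed = 1L,
                        style_assignment = c("round_robin", "blocks"),
                        width = 4096L, height = 4096L, mpp = 0.97) {
  style_assignment <- match.arg(style_assignment)
  if (n < 1) stop("n must be >= 1")
  if (prevalence < 0 || prevalence > 1) stop("prevalence must be in [0, 1]")
  if (length(styles) == 0) stop("empty style list")
  if (is.null(names(styles)))
    names(styles) <- vapply(styles, `[[`, "", "style_id")
  labels <- with_seed(seed, stats::rbinom(n, 1, prevalence))
  style_ids <- if (style_assignment == "round_robin") {
    rep_len(names(styles), n)
  } else {
    rep(names(styles), each = ceiling(n / length(styles)))[seq_len(n)]
  }
  ids <- sprintf("slide_%03d", seq_len(n))
  data.frame(slide_id = ids,
             path = paste0(ids, ".tif"),
             annotation_path = paste0(ids, ".xml"),
             label = ifelse(labels == 1, "cancer", "normal"),
             center_style_id = style_ids,
             seed = derive_seed(seed, seq_len(n)),
             width = as.integer(width), height = as.integer(height),
             mpp = mpp, stringsAsFactors = FALSE)
}

#' Regenerate one slide from a manifest row
#'
#' @param row One row of a [plan_cohort()] manifest.
#' @param styles The style list used when planning.
#' @return As [generate_slide()].
#' @export
generate_slide_from_row <- function(row, styles = builtin_styles()) {
  spec <- slide_spec(row$slide_id, width = row$width, height = row$height,
                     mpp = row$mpp, label = row$label,
                     center_style_id = row$center_style_id, seed = row$seed)
  generate_slide(spec, styles[[row$center_style_id]])
}

#' Generate and write a synthetic cohort to disk
#'
#' Renders every slide of a [plan_cohort()] manifest, writing pyramidal TIFFs
#' (2 levels), ASAP-XML annotations, and the CSV manifest.
#'
#' @inheritParams plan_cohort
#' @param out_dir Output directory (created if missing).
#' @param annotation_dialect `"asap_xml"` or `"geojson"`.
#' @return The manifest data frame (invisibly), with paths relative to
#'   `out_dir`; also written as `manifest.csv`.
#' @export
generate_cohort <- function(n, prevalence = 0.25,
                            styles = builtin_styles()[1], out_dir,
                            seed = 1L,
                            style_assignment = c("round_robin", "blocks"),
                            width = 4096L, height = 4096L, mpp = 0.97,
                            annotation_dialect = c("asap_xml", "geojson")) {
  annotation_dialect <- match.arg(annotation_dialect)
  manifest <- plan_cohort(n, prevalence, styles, seed,
                          match.arg(style_assignment), width, height, mpp)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(names(styles)))
    names(styles) <- vapply(styles, `[[`, "", "style_id")
  ext <- if (annotation_dialect == "asap_xml") ".xml" else ".geojson"
  manifest$annotation_path <- paste0(manifest$slide_id, ext)
  for (i in seq_len(nrow(manifest))) {
    g <- generate_slide_from_row(manifest[i, ], styles)
    write_slide(g$slide, file.path(out_dir, manifest$path[i]))
    write_annotations(g$annotations,
                      file.path(out_dir, manifest$annotation_path[i]),
                      dialect = annotation_dialect)
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
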