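# Training-patch extraction from sparse annotations, single-class target
# maps, augmentation, and class-balanced sampling plans.

#' Extract patch records strictly inside annotated polygons
#'
#' Walks a regular grid (spacing `stride`, in target-magnification pixels)
#' over each polygon's bounding box and keeps every position whose square
#' patch footprint lies fully inside the polygon — patches outside
#' annotations are never emitted, because unannotated tissue has no reference
#' label. Containment is checked at the four footprint corners plus the
#' centre by the even-odd rule (boundary-inclusive); `strict = TRUE`
#' additionally requires every footprint pixel centre to be inside.
#'
#' @param annotations An `annotation_set` (empty set gives an empty record
#'   table, not an error).
#' @param patch_size Patch side length in pixels at `magnification`.
#' @param magnification Target magnification (default 5).
#' @param stride Grid spacing in target-magnification pixels; defaults to
#'   `patch_size / 2` (overlapping grid, which raises the yield from sparse
#'   annotations).
#' @param base_mpp Level-0 mpp of the annotated slide; defaults to the mpp
#'   recorded in the annotation set, else the target mpp (no rescaling).
#' @param slide_id Identifier copied into the records.
#' @param strict Use full rasterized containment instead of the corner test.
#' @return Data frame of patch records: `slide_id`, `x`, `y` (footprint
#'   centre, level-0 px), `size`, `magnification`, `class_label`.
#' @export
extract_patches <- function(annotations, patch_size = 512L, magnification = 5,
                            stride = patch_size / 2, base_mpp = NULL,
                            slide_id = "slide", strict = FALSE) {
  stopifnot(inherits(annotations, "annotation_set"))
  if (stride < 1) stop("stride must be >= 1")
  if (patch_size <= 0) stop("patch_size must be positive")
  target_mpp <- magnification_to_mpp(magnification)
  if (is.null(base_mpp)) base_mpp <- annotations$mpp
  if (is.na(base_mpp)) base_mpp <- target_mpp
  # footprint size and stride mapped to level-0 pixels
  f <- patch_size * target_mpp / base_mpp
  s <- stride * target_mpp / base_mpp
  recs <- list()
  for (r in annotations$regions) {
    poly <- r$polygon
    xmin <- min(poly[, 1]); xmax <- max(poly[, 1])
    ymin <- min(poly[, 2]); ymax <- max(poly[, 2])
    if (xmax - xmin < f - 1e-9 || ymax - ymin < f - 1e-9) next
    xs <- seq(xmin, xmax - f + 1e-9, by = s)
    ys <- seq(ymin, ymax - f + 1e-9, by = s)
    for (y0 in ys) for (x0 in xs) {
      cx <- c(x0, x0 + f, x0, x0 + f, x0 + f / 2)
      cy <- c(y0, y0, y0 + f, y0 + f, y0 + f / 2)
      if (!all(point_in_polygon(cx, cy, poly))) next
      if (strict) {
        n_sub <- min(16, max(4, ceiling(f)))
        gx <- seq(x0, x0 + f, length.out = n_sub)
        gy <- seq(y0, y0 + f, length.out = n_sub)
        gg <- expand.grid(gx, gy)
        if (!all(point_in_polygon(gg[, 1], gg[, 2], poly))) next
      }
      recs[[length(recs) + 1]] <-
        data.frame(slide_id = slide_id, x = x0 + f / 2, y = y0 + f / 2,
                   size = patch_size, magnification = magnification,
                   class_label = r$class_label, stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0)
    return(data.frame(slide_id = character(), x = numeric(), y = numeric(),
                      size = integer(), magnification = numeric(),
                      class_label = character(), stringsAsFactors = FALSE))
  do.call(rbind, recs)
}

#' Read the pixels of one patch record
#'
#' Cuts the record's level-0 footprint out of the slide and resamples it to
#' `size` x `size` at the record's magnification.
#'
#' @param slide A `slide_pyramid`.
#' @param record One row of an [extract_patches()] table.
#' @return RGB raster `size` x `size` x 3.
#' @export
read_patch <- function(slide, record) {
  target_mpp <- magnification_to_mpp(record$magnification)
  f <- record$size * target_mpp / slide$mpp_x
  x0 <- round(record$x - f / 2); y0 <- round(record$y - f / 2)
  fi <- round(f)
  x0 <- clamp(x0, 0, dim(slide$levels[[1]])[2] - fi)
  y0 <- clamp(y0, 0, dim(slide$levels[[1]])[1] - fi)
  raw <- read_region(slide, 0L, x0, y0, fi, fi)
  if (fi == record$size) raw else resize_rgb(raw, record$size, record$size)
}

#' Single-class target map for a sparse-annotation patch
#'
#' Under the sparse-annotation convention every extracted patch lies fully
#' inside one annotated polygon, so its reference is a full-patch raster of
#' that single class, one-hot along the class axis.
#'
#' @param class_label One of [wsi_classes()].
#' @param size Patch side length.
#' @param n_classes Number of classes (channel count).
#' @return `size` x `size` x `n_classes` one-hot array.
#' @export
make_target <- function(class_label, size, n_classes = 5L) {
  k <- match(class_label, WSI_CLASSES[seq_len(n_classes)])
  if (is.na(k)) stop("unknown class: ", class_label)
  out <- array(0, dim = c(size, size, n_classes))
  out[, , k] <- 1
  out
}

#' Augmentation configuration
#'
#' Ranges for the histopathology-standard augmentations: brightness, contrast
#' and saturation jitter (fractional deltas), right-angle rotations with
#' mirroring, additive Gaussian noise and Gaussian blur.
#'
#' @param brightness,contrast,saturation Two-element ranges of fractional
#'   deltas (e.g. `c(-0.2, 0.2)` for +/-20%).
#' @param rotations Set of rotation angles (degrees, multiples of 90).
#' @param mirror Allow horizontal mirroring.
#' @param noise_sigma Two-element range of noise sigmas (8-bit units).
#' @param blur_sigma Two-element range of blur sigmas (px).
#' @return Object of class `augmentation_config`.
#' @export
augmentation_config <- function(brightness = c(-0.2, 0.2),
                                contrast = c(-0.2, 0.2),
                                saturation = c(-0.2, 0.2),
                                rotations = c(0, 90, 180, 270),
                                mirror = TRUE,
                                noise_sigma = c(0, 10),
                                blur_sigma = c(0, 1.5)) {
  for (r in list(brightness, contrast, saturation, noise_sigma, blur_sigma))
    if (length(r) != 2 || r[1] > r[2]) stop("ranges must be (lo, hi)")
  structure(list(brightness = brightness, contrast = contrast,
                 saturation = saturation, rotations = rotations,
                 mirror = mirror, noise_sigma = noise_sigma,
                 blur_sigma = blur_sigma),
            class = "augmentation_config")
}

identity_augmentation <- function()
  augmentation_config(brightness = c(0, 0), contrast = c(0, 0),
                      saturation = c(0, 0), rotations = 0, mirror = FALSE,
                      noise_sigma = c(0, 0), blur_sigma = c(0, 0))

rotate90 <- function(img, k) {
  k <- (k %% 4)
  if (k == 0) return(img)
  for (i in seq_len(k)) {
    d <- dim(img)
    out <- array(0, dim = c(d[2], d[1], d[3]))
    for (ch in seq_len(d[3])) out[, , ch] <- t(img[d[1]:1, , ch])
    img <- out
  }
  img
}

#' Apply a random augmentation to a patch
#'
#' Parameters are drawn uniformly from the configured ranges using the
#' session RNG, so a fixed seed reproduces the augmentation exactly. With all
#' ranges degenerate at the identity the input is returned unchanged.
#'
#' @param patch RGB raster (values in [0, 255]).
#' @param cfg An [augmentation_config()].
#' @return Augmented raster, same shape.
#' @export
augment_patch <- function(patch, cfg = augmentation_config()) {
  stopifnot_rgb(patch)
  stopifnot(inherits(cfg, "augmentation_config"))
  br <- stats::runif(1, cfg$brightness[1], cfg$brightness[2])
  co <- stats::runif(1, cfg$contrast[1], cfg$contrast[2])
  sa <- stats::runif(1, cfg$saturation[1], cfg$saturation[2])
  rot <- cfg$rotations[sample.int(length(cfg$rotations), 1)]
  mir <- cfg$mirror && stats::runif(1) < 0.5
  ns <- stats::runif(1, cfg$noise_sigma[1], cfg$noise_sigma[2])
  bs <- stats::runif(1, cfg$blur_sigma[1], cfg$blur_sigma[2])
  out <- patch
  if (br != 0 || co != 0 || sa != 0) {
    style <- center_style("aug", saturation_scale = 1 + sa,
                          brightness_scale = 1 + br, contrast_scale = 1 + co)
    out <- apply_center_style(out, style)
  }
  out <- rotate90(out, rot / 90)
  if (mir) out <- out[, dim(out)[2]:1, , drop = FALSE]
  if (bs > 0.05) out <- gaussian_blur_rgb(out, bs)
  if (ns > 0)
    out <- out + array(stats::rnorm(length(out), 0, ns), dim = dim(out))
  clamp(out, 0, 255)
}

#' Class-balanced sampling plan
#'
#' Rarer classes are augmented more heavily: each class receives the
#' multiplier `ceiling(n_max / n_class)`, capped (default 10). Capped classes
#' keep a residual imbalance, which is flagged in the returned table. Classes
#' configured but absent from the records are warned about, not failed on —
#' sparse cohorts may genuinely miss a class.
#'
#' @param records Patch record table from [extract_patches()].
#' @param cap Maximum per-class multiplier.
#' @param classes Class vocabulary expected to be present.
#' @return Data frame: `class_label`, `n_records`, `multiplier`,
#'   `effective`, `capped`.
#' @export
plan_balanced_sampling <- function(records, cap = 10L,
                                   classes = wsi_classes()) {
  counts <- table(factor(records$class_label, levels = classes))
  missing <- names(counts)[counts == 0]
  if (length(missing))
    warning("classes absent from records: ", paste(missing, collapse = ", "))
  present <- counts[counts > 0]
  if (length(present) == 0) stop("no records at all")
  n_max <- max(present)
  mult <- pmin(cap, ceiling(n_max / as.numeric(present)))
  data.frame(class_label = names(present),
             n_records = as.integer(present),
             multiplier = as.integer(mult),
             effective = as.integer(present) * as.integer(mult),
             capped = ceiling(n_max / as.numeric(present)) > cap,
             stringsAsFactors = FALSE, row.names = NULL)
}
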