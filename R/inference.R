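# Whole-slide inference: tile the slide at the analysis magnification, run
# the model on tissue tiles only, and assemble the class-probability raster.

#' Likelihood map container
#'
#' @param probs `[h, w, K]` class-probability raster at the analysis
#'   magnification.
#' @param mpp Microns per pixel of the raster.
#' @param slide_id Source slide.
#' @param classes Class names in channel order.
#' @return Object of class `likelihood_map`.
#' @export
likelihood_map <- function(probs, mpp, slide_id = "slide",
                           classes = wsi_classes()) {
  stopifnot(length(dim(probs)) == 3, dim(probs)[3] == length(classes))
  structure(list(probs = probs, mpp = mpp, slide_id = slide_id,
                 classes = classes),
            class = "likelihood_map")
}

#' @export
print.likelihood_map <- function(x, ...) {
  d <- dim(x$probs)
  cat(sprintf("likelihood_map '%s': %d x %d x %d classes at mpp %.2f\n",
              x$slide_id, d[2], d[1], d[3], x$mpp))
  invisible(x)
}

reflect_pad_2d <- function(img, bottom, right) {
  d <- dim(img)
  if (bottom > 0) {
    take <- seq(d[1], by = -1, length.out = bottom)
    img <- array(c(aperm(img, c(2, 3, 1)),
                   aperm(img[take, , , drop = FALSE], c(2, 3, 1))),
                 dim = c(d[2], d[3], d[1] + bottom))
    img <- aperm(img, c(3, 1, 2))
    d <- dim(img)
  }
  if (right > 0) {
    take <- seq(d[2], by = -1, length.out = right)
    img <- array(c(aperm(img, c(1, 3, 2)),
                   aperm(img[, take, , drop = FALSE], c(1, 3, 2))),
                 dim = c(d[1], d[3], d[2] + right))
    img <- aperm(img, c(1, 3, 2))
  }
  img
}

#' Whole-slide likelihood map by tiled model application
#'
#' Renders the slide at the analysis magnification, tiles it on a
#' non-overlapping grid (optionally half-tile overlap with averaging for
#' seam suppression), and classifies every tile containing at least
#' `tissue_min_frac` tissue. Non-tissue tiles receive the fixed background
#' distribution: all probability mass on the "other" class. Right/bottom
#' remainder tiles are reflectively padded to the patch size and the
#' predictions cropped back, so coverage is complete.
#'
#' @param model A segmentation `wsi_model` (for a patch classifier each
#'   tile's probability vector is broadcast over its footprint).
#' @param slide A `slide_pyramid`.
#' @param tissue_mask A `tissue_mask` (any level; resampled internally), or
#'   NULL to compute one.
#' @param patch_size Tile size at the analysis magnification.
#' @param magnification Analysis magnification (defaults to 5, matching the
#'   training magnification).
#' @param tissue_min_frac Minimum tissue fraction for a tile to be
#'   classified.
#' @param overlap Use half-tile overlapping tiles with probability
#'   averaging.
#' @param batch Tiles per forward pass.
#' @return A `likelihood_map`.
#' @export
predict_slide <- function(model, slide, tissue_mask = NULL, patch_size = 32L,
                          magnification = 5, tissue_min_frac = 0.05,
                          overlap = FALSE, batch = 16L) {
  stopifnot(inherits(model, "wsi_model"), inherits(slide, "slide_pyramid"))
  n_classes <- model$cfg$n_classes
  if (n_classes != length(wsi_classes()))
    stop("model classes do not match the pipeline vocabulary")
  if (is.null(tissue_mask)) tissue_mask <- compute_tissue_mask(slide)
  ra <- read_at_magnification(slide, magnification)
  img <- ra$image
  h <- dim(img)[1]; w <- dim(img)[2]
  tm <- resize_matrix(tissue_mask$mask * 1, h, w, nearest = TRUE) > 0.5
  bg_idx <- match("other", wsi_classes())
  probs <- array(0, dim = c(h, w, n_classes))
  probs[, , bg_idx] <- 1
  wsum <- matrix(0, h, w)
  acc <- array(0, dim = c(h, w, n_classes))
  step <- if (overlap) patch_size %/% 2L else patch_size
  ys <- unique(c(seq(1, max(h - patch_size + 1, 1), by = step),
                 max(h - patch_size + 1, 1)))
  xs <- unique(c(seq(1, max(w - patch_size + 1, 1), by = step),
                 max(w - patch_size + 1, 1)))
  tiles <- expand.grid(y = ys, x = xs)
  # only tiles meeting the tissue rule are classified
  keep <- vapply(seq_len(nrow(tiles)), function(i) {
    y0 <- tiles$y[i]; x0 <- tiles$x[i]
    mean(tm[y0:min(y0 + patch_size - 1, h),
            x0:min(x0 + patch_size - 1, w)]) >= tissue_min_frac
  }, TRUE)
  tiles <- tiles[keep, , drop = FALSE]
  if (nrow(tiles) > 0) {
    for (start in seq(1, nrow(tiles), by = batch)) {
      idx <- start:min(start + batch - 1, nrow(tiles))
      xb <- array(0, dim = c(patch_size, patch_size, 3, length(idx)))
      for (j in seq_along(idx)) {
        y0 <- tiles$y[idx[j]]; x0 <- tiles$x[idx[j]]
        sub <- img[y0:min(y0 + patch_size - 1, h),
                   x0:min(x0 + patch_size - 1, w), , drop = FALSE]
        d <- dim(sub)
        if (d[1] < patch_size || d[2] < patch_size)
          sub <- reflect_pad_2d(sub, patch_size - d[1], patch_size - d[2])
        xb[, , , j] <- sub
      }
      pb <- predict.wsi_model(model, xb)
      for (j in seq_along(idx)) {
        y0 <- tiles$y[idx[j]]; x0 <- tiles$x[idx[j]]
        hh <- min(y0 + patch_size - 1, h) - y0 + 1
        ww <- min(x0 + patch_size - 1, w) - x0 + 1
        pt <- if (is_segmentation(model)) {
          pb[seq_len(hh), seq_len(ww), , j, drop = FALSE]
        } else {
          array(rep(pb[j, ], each = hh * ww), dim = c(hh, ww, n_classes, 1))
        }
        acc[y0:(y0 + hh - 1), x0:(x0 + ww - 1), ] <-
          acc[y0:(y0 + hh - 1), x0:(x0 + ww - 1), ] + pt[, , , 1]
        wsum[y0:(y0 + hh - 1), x0:(x0 + ww - 1)] <-
          wsum[y0:(y0 + hh - 1), x0:(x0 + ww - 1)] + 1
      }
    }
    covered <- wsum > 0
    for (k in seq_len(n_classes)) {
      pk <- probs[, , k]; ak <- acc[, , k]
      pk[covered] <- ak[covered] / wsum[covered]
      probs[, , k] <- pk
    }
  }
  likelihood_map(probs, mpp = ra$mpp, slide_id = slide$slide_id)
}

#' Tumor probability map and tumor area
#'
#' TPM is the cancer-class channel of the likelihood map; TA marks pixels
#' where the cancer probability strictly exceeds every other class's
#' probability (exact ties are excluded, per the strict definition).
#'
#' @param map A `likelihood_map`.
#' @return Object of class `tumor_map`: list with `tpm` (matrix in [0, 1]),
#'   `ta` (0/1 matrix), `mpp`, `slide_id`.
#' @export
derive_tumor_map <- function(map) {
  stopifnot(inherits(map, "likelihood_map"))
  k <- match("cancer", map$classes)
  tpm <- matrix(map$probs[, , k], nrow = dim(map$probs)[1])
  others <- map$probs[, , -k, drop = FALSE]
  ta <- tpm > matrix(apply(others, c(1, 2), max), nrow = nrow(tpm))
  structure(list(tpm = tpm, ta = matrix(as.integer(ta), nrow = nrow(tpm)),
                 mpp = map$mpp, slide_id = map$slide_id),
            class = "tumor_map")
}

#' Construct a tumor map directly
#'
#' Mostly useful for tests and for loading externally computed maps.
#'
#' @param tpm Tumor-probability matrix in [0, 1].
#' @param ta Binary tumor-area matrix, same shape.
#' @param mpp Raster resolution.
#' @param slide_id Identifier.
#' @return A `tumor_map`.
#' @export
tumor_map <- function(tpm, ta, mpp = 2, slide_id = "slide") {
  stopifnot(identical(dim(tpm), dim(ta)))
  structure(list(tpm = tpm, ta = matrix(as.integer(ta), nrow = nrow(tpm)),
                 mpp = mpp, slide_id = slide_id),
            class = "tumor_map")
}

#' @export
print.tumor_map <- function(x, ...) {
  cat(sprintf("tumor_map '%s': %d x %d, TA %d px, T07 %.3f\n", x$slide_id,
              ncol(x$tpm), nrow(x$tpm), sum(x$ta), t07(x)))
  invisible(x)
}

#' Write a likelihood map as multi-page TIFF (one page per class) plus a
#' JSON sidecar with mpp and class order
#'
#' @param map A `likelihood_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_likelihood_map <- function(map, path) {
  pages <- lapply(seq_along(map$classes), function(k) map$probs[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(mpp = map$mpp, slide_id = map$slide_id,
                            classes = map$classes),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_likelihood_map
#' @export
read_likelihood_map <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  probs <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) probs[, , k] <- pages[[k]]
  likelihood_map(probs, mpp = as.numeric(meta$mpp),
                 slide_id = meta$slide_id,
                 classes = unlist(meta$classes))
}
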