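# Pyramidal slide container and I/O. Conventions used everywhere:
# 0-based pixel coordinates, top-left origin, half-open regions [x, x+w);
# rasters are numeric h x w x 3 arrays with values in [0, 255].

#' Build an in-memory slide pyramid
#'
#' Wraps a level-0 RGB raster into a multi-resolution pyramid. Each further
#' level halves the previous one (bilinear), mirroring how scanners store
#' whole-slide images. Level downsamples are therefore 1, 2, 4, ...
#'
#' @param level0 RGB raster (h x w x 3, values in [0, 255]).
#' @param slide_id Identifier string.
#' @param mpp Microns per pixel at level 0 (isotropic).
#' @param n_levels Number of pyramid levels (>= 1).
#' @return Object of class `slide_pyramid`.
#' @export
slide_pyramid <- function(level0, slide_id = "slide", mpp = 0.97,
                          n_levels = 2L) {
  stopifnot_rgb(level0)
  stopifnot(mpp > 0, n_levels >= 1)
  levels <- vector("list", n_levels)
  levels[[1]] <- level0
  for (k in seq_len(n_levels - 1)) {
    prev <- levels[[k]]
    levels[[k + 1]] <- resize_rgb(prev, ceiling(dim(prev)[1] / 2),
                                  ceiling(dim(prev)[2] / 2))
  }
  structure(list(slide_id = slide_id, levels = levels,
                 downsamples = 2^(seq_len(n_levels) - 1),
                 mpp_x = mpp, mpp_y = mpp),
            class = "slide_pyramid")
}

#' @export
print.slide_pyramid <- function(x, ...) {
  cat(sprintf("slide_pyramid '%s': %d level(s), mpp %.3f\n",
              x$slide_id, length(x$levels), x$mpp_x))
  for (k in seq_along(x$levels)) {
    d <- dim(x$levels[[k]])
    cat(sprintf("  level %d: %d x %d (downsample %g, mpp %.3f)\n", k - 1,
                d[2], d[1], x$downsamples[k], x$mpp_x * x$downsamples[k]))
  }
  invisible(x)
}

#' Level geometry of a slide
#'
#' @param slide A `slide_pyramid`.
#' @return Data frame with one row per level: `level`, `width`, `height`,
#'   `downsample`, `mpp`.
#' @export
slide_levels <- function(slide) {
  stopifnot(inherits(slide, "slide_pyramid"))
  d <- t(vapply(slide$levels, dim, integer(3)))
  data.frame(level = seq_along(slide$levels) - 1L,
             width = d[, 2], height = d[, 1],
             downsample = slide$downsamples,
             mpp = slide$mpp_x * slide$downsamples)
}

# Bilinear resize of an RGB array to (h, w).
resize_rgb <- function(img, h, w) {
  eb <- EBImage::Image(aperm(img, c(2, 1, 3)) / 255, colormode = "Color")
  out <- EBImage::resize(eb, w = w, h = h)
  clamp(aperm(EBImage::imageData(out), c(2, 1, 3)) * 255, 0, 255)
}

resize_matrix <- function(m, h, w, nearest = FALSE) {
  eb <- EBImage::Image(t(m))
  out <- EBImage::resize(eb, w = w, h = h,
                         filter = if (nearest) "none" else "bilinear")
  t(EBImage::imageData(out))
}

#' Read a rectangular region from a pyramid level
#'
#' `x`/`y` address the region's top-left corner in level-0 coordinates
#' (0-based); `w`/`h` are the region size in pixels *at the requested level*.
#' The region must lie fully inside the slide.
#'
#' @param slide A `slide_pyramid`.
#' @param level Level index (0-based).
#' @param x,y Top-left corner, level-0 coordinates.
#' @param w,h Region width/height at `level`; both must be >= 1.
#' @return RGB raster (h x w x 3, values in [0, 255]).
#' @export
read_region <- function(slide, level, x, y, w, h) {
  stopifnot(inherits(slide, "slide_pyramid"))
  if (level < 0 || level >= length(slide$levels)) stop("invalid level")
  if (w < 1 || h < 1) stop("region width/height must be >= 1")
  ds <- slide$downsamples[level + 1]
  lx <- floor(x / ds); ly <- floor(y / ds)
  d <- dim(slide$levels[[level + 1]])
  if (lx < 0 || ly < 0 || lx + w > d[2] || ly + h > d[1])
    stop("region out of bounds at requested level")
  slide$levels[[level + 1]][(ly + 1):(ly + h), (lx + 1):(lx + w), , drop = FALSE]
}

#' Nominal magnification to target resolution
#'
#' Magnifications are tied to microns-per-pixel via the 40x = 0.25 um/px
#' convention, so "10x" is mpp 1.0 and "5x" is mpp 2.0.
#'
#' @param magnification Nominal magnification (e.g. 5, 10, 20, 40).
#' @return Target microns per pixel.
#' @export
magnification_to_mpp <- function(magnification) {
  stopifnot(magnification > 0)
  40 * 0.25 / magnification
}

#' Render a whole slide at a nominal magnification
#'
#' Picks the highest pyramid level whose resolution is still finer than the
#' target and bilinearly resamples it to the exact target mpp.
#'
#' @param slide A `slide_pyramid`.
#' @param magnification Nominal magnification.
#' @return List with `image` (RGB raster), `mpp` (achieved, equals target)
#'   and `scale` (target-level pixels per level-0 pixel).
#' @export
read_at_magnification <- function(slide, magnification) {
  target <- magnification_to_mpp(magnification)
  mpps <- slide$mpp_x * slide$downsamples
  k <- max(which(mpps <= target + 1e-9), 1)
  src <- slide$levels[[k]]
  factor <- mpps[k] / target
  h <- max(1, round(dim(src)[1] * factor))
  w <- max(1, round(dim(src)[2] * factor))
  img <- if (h == dim(src)[1] && w == dim(src)[2]) src else resize_rgb(src, h, w)
  list(image = img, mpp = target, scale = 1 / (target / slide$mpp_x))
}

#' Write / read a slide pyramid as a tiled multi-page TIFF
#'
#' Pages hold the pyramid levels top (level 0) first; resolution metadata
#' (mpp, level geometry, slide id) travels in a JSON sidecar `<path>.json`
#' because baseline TIFF tags cannot carry it portably. Pixel data is stored
#' 8-bit, so a write/read round trip quantizes intensities to integers.
#'
#' @param slide A `slide_pyramid`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_slide <- function(slide, path) {
  stopifnot(inherits(slide, "slide_pyramid"))
  pages <- lapply(slide$levels, function(l) clamp(l, 0, 255) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  meta <- list(slide_id = slide$slide_id, mpp_x = slide$mpp_x,
               mpp_y = slide$mpp_y, downsamples = slide$downsamples,
               levels = lapply(slide$levels,
                               function(l) c(height = dim(l)[1],
                                             width = dim(l)[2])))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_slide
#' @export
read_slide <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else
    list(slide_id = basename(path), mpp_x = 0.97)
  levels <- lapply(pages, function(p) {
    if (length(dim(p)) == 2) p <- array(rep(p, 3), dim = c(dim(p), 3))
    p[, , 1:3, drop = FALSE] * 255
  })
  structure(list(slide_id = meta$slide_id, levels = levels,
                 downsamples = 2^(seq_along(levels) - 1),
                 mpp_x = as.numeric(meta$mpp_x),
                 mpp_y = as.numeric(meta$mpp_y %||% meta$mpp_x)),
            class = "slide_pyramid")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
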