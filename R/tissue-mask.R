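# Tissue detection: separate stained tissue from the near-white slide
# background so that inference and patch sampling skip empty glass.

#' Compute a binary tissue mask for a pyramid level
#'
#' The standard recipe: work at a width of at most 1024 px (downsampling the
#' level if needed), flag pixels whose HSV saturation exceeds its Otsu
#' threshold or whose grey intensity is below 0.9 x white, then remove
#' connected components smaller than 64 px and fill holes. The mask is
#' returned at the full geometry of the requested level.
#'
#' @param slide A `slide_pyramid`.
#' @param level Level index (0-based).
#' @param max_width Working width for the threshold computation.
#' @return Object of class `tissue_mask`: list with `mask` (0/1 integer
#'   matrix at the level's geometry), `level`, `downsample` (level-0 pixels
#'   per mask pixel).
#' @export
compute_tissue_mask <- function(slide, level = length(slide$levels) - 1L,
                                max_width = 1024L) {
  stopifnot(inherits(slide, "slide_pyramid"))
  if (level < 0 || level >= length(slide$levels)) stop("invalid level")
  img <- slide$levels[[level + 1]]
  d <- dim(img)
  work <- img
  if (d[2] > max_width) {
    f <- max_width / d[2]
    work <- resize_rgb(img, max(1, round(d[1] * f)), max_width)
  }
  mx <- pmax(work[, , 1], work[, , 2], work[, , 3])
  mn <- pmin(work[, , 1], work[, , 2], work[, , 3])
  sat <- ifelse(mx > 0, (mx - mn) / mx, 0)
  grey <- (work[, , 1] + work[, , 2] + work[, , 3]) / 3
  thr <- otsu_threshold(sat)
  m <- (sat > thr & grey < 0.98 * 255) | grey < 0.9 * 255
  m <- prune_small_components(m, min_px = 64L)
  m <- EBImage::fillHull(EBImage::Image(t(m)))
  m <- t(EBImage::imageData(m)) > 0
  if (!identical(dim(m), d[1:2]))
    m <- resize_matrix(m * 1, d[1], d[2], nearest = TRUE) > 0.5
  structure(list(mask = matrix(as.integer(m), nrow = d[1]),
                 level = as.integer(level),
                 downsample = slide$downsamples[level + 1]),
            class = "tissue_mask")
}

# Otsu's threshold on values in [0, 1] (256-bin histogram).
otsu_threshold <- function(x) {
  h <- tabulate(pmin(pmax(floor(x * 255), 0), 255) + 1L, 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  (which.max(sigma_b) - 1) / 255
}

# Remove 4-connected components with fewer than min_px pixels.
prune_small_components <- function(mask, min_px = 64L) {
  lab <- EBImage::bwlabel(EBImage::Image(t(mask * 1)))
  lab <- t(EBImage::imageData(lab))
  if (max(lab) == 0) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep, nrow = nrow(mask))
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("tissue_mask at level %d: %d x %d, %.1f%% tissue\n", x$level,
              ncol(x$mask), nrow(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

#' Write a tissue mask as PNG
#'
#' @param mask A `tissue_mask`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "tissue_mask"))
  png::writePNG(mask$mask * 1, path)
  invisible(path)
}
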