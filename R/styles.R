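# Scanner "center styles": parametric color/sharpness/noise transforms that
# emulate the appearance differences between slide scanners and staining labs.

#' Construct a scanner style
#'
#' A center style bundles the appearance parameters of one scanner/lab
#' combination: a hue rotation (degrees), multiplicative saturation,
#' brightness and contrast scales, a blur sigma in pixels (negative values
#' mean unsharp masking with that absolute amount), and additive Gaussian
#' noise sigma in 8-bit intensity units. The default is the identity style,
#' which leaves images bit-identical.
#'
#' @param style_id Identifier string.
#' @param hue_shift Hue rotation in degrees.
#' @param saturation_scale,brightness_scale,contrast_scale Positive scales.
#' @param blur_sigma Gaussian blur sigma (px); negative = unsharp amount.
#' @param noise_sigma Additive Gaussian noise sigma (intensity units).
#' @return Object of class `center_style`.
#' @export
center_style <- function(style_id = "identity", hue_shift = 0,
                         saturation_scale = 1, brightness_scale = 1,
                         contrast_scale = 1, blur_sigma = 0, noise_sigma = 0) {
  stopifnot(saturation_scale > 0, brightness_scale > 0, contrast_scale > 0,
            noise_sigma >= 0)
  structure(list(style_id = style_id, hue_shift = hue_shift,
                 saturation_scale = saturation_scale,
                 brightness_scale = brightness_scale,
                 contrast_scale = contrast_scale, blur_sigma = blur_sigma,
                 noise_sigma = noise_sigma),
            class = "center_style")
}

#' @export
print.center_style <- function(x, ...) {
  cat(sprintf(
    "center_style '%s': hue %+.0f deg, sat x%.2f, bright x%.2f, contrast x%.2f, blur %.2f px, noise sd %.1f\n",
    x$style_id, x$hue_shift, x$saturation_scale, x$brightness_scale,
    x$contrast_scale, x$blur_sigma, x$noise_sigma))
  invisible(x)
}

is_identity_style <- function(s) {
  s$hue_shift == 0 && s$saturation_scale == 1 && s$brightness_scale == 1 &&
    s$contrast_scale == 1 && s$blur_sigma == 0 && s$noise_sigma == 0
}

# Vectorised HSV -> RGB (h, s, v rows in [0,1]); inverse of grDevices::rgb2hsv.
hsv_to_rgb_mat <- function(hsv) {
  h <- hsv[1, ] * 6; s <- hsv[2, ]; v <- hsv[3, ]
  i <- as.integer(floor(h) %% 6)
  f <- h - floor(h)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  out <- matrix(0, 3, length(v))
  # classic HSV hexcone table, one sector at a time (fast on megapixel input)
  pick <- list(c("v", "t", "p"), c("q", "v", "p"), c("p", "v", "t"),
               c("p", "q", "v"), c("t", "p", "v"), c("v", "p", "q"))
  comp <- list(v = v, p = p, q = q, t = t)
  for (sec in 0:5) {
    sel <- i == sec
    if (!any(sel)) next
    out[1, sel] <- comp[[pick[[sec + 1]][1]]][sel]
    out[2, sel] <- comp[[pick[[sec + 1]][2]]][sel]
    out[3, sel] <- comp[[pick[[sec + 1]][3]]][sel]
  }
  out
}

# Separable Gaussian blur on an RGB array (values on any scale).
gaussian_blur_rgb <- function(img, sigma) {
  eb <- EBImage::Image(aperm(img, c(2, 1, 3)) / 255, colormode = "Color")
  out <- EBImage::gblur(eb, sigma = sigma)
  aperm(EBImage::imageData(out), c(2, 1, 3)) * 255
}

#' Apply a scanner style to an RGB raster
#'
#' Operations are applied in a fixed order: color (hue rotation, saturation
#' and brightness scaling in HSV, then linear contrast about mid-grey), then
#' blur or unsharp sharpening, then additive Gaussian noise, then clipping to
#' [0, 255]. The identity style returns the input unchanged, bit for bit.
#' Noise is drawn from the current RNG stream, so seed the session for
#' reproducible renderings.
#'
#' @param image RGB raster: numeric h x w x 3 array with values in [0, 255].
#' @param style A [center_style()].
#' @return Styled raster, same shape, values in [0, 255].
#' @export
apply_center_style <- function(image, style) {
  stopifnot_rgb(image)
  stopifnot(inherits(style, "center_style"))
  if (is_identity_style(style)) return(image)
  d <- dim(image)
  x <- image
  if (style$hue_shift != 0 || style$saturation_scale != 1 ||
      style$brightness_scale != 1) {
    m <- x; dim(m) <- c(d[1] * d[2], 3)
    hsv <- grDevices::rgb2hsv(t(m), maxColorValue = 255)
    hsv[1, ] <- (hsv[1, ] + style$hue_shift / 360) %% 1
    hsv[2, ] <- clamp(hsv[2, ] * style$saturation_scale, 0, 1)
    hsv[3, ] <- clamp(hsv[3, ] * style$brightness_scale, 0, 1)
    x <- t(hsv_to_rgb_mat(hsv)) * 255
    dim(x) <- d
  }
  if (style$contrast_scale != 1)
    x <- (x - 127.5) * style$contrast_scale + 127.5
  if (style$blur_sigma > 0) {
    x <- gaussian_blur_rgb(x, style$blur_sigma)
  } else if (style$blur_sigma < 0) {
    x <- x + abs(style$blur_sigma) * (x - gaussian_blur_rgb(x, 1))
  }
  if (style$noise_sigma > 0)
    x <- x + array(stats::rnorm(length(x), 0, style$noise_sigma), dim = d)
  clamp(x, 0, 255)
}

#' Built-in synthetic scanner styles
#'
#' A named list of center styles emulating distinct scanners: `"scanner_a"`
#' is the development-scanner reference (identity), `"scanner_b"` is a
#' washed-out vendor look (hue-rotated, strongly desaturated, brighter and
#' lower in contrast) under which a model trained on `"scanner_a"` loses its
#' class evidence, and `"scanner_c"` is a sharper, noisier, higher-contrast
#' rendering.
#'
#' @return Named list of [center_style()] objects.
#' @export
builtin_styles <- function() {
  list(
    scanner_a = center_style("scanner_a"),
    scanner_b = center_style("scanner_b", hue_shift = 15,
                             saturation_scale = 0.45, brightness_scale = 1.4,
                             contrast_scale = 0.55, blur_sigma = 0.6,
                             noise_sigma = 1),
    scanner_c = center_style("scanner_c", hue_shift = -18,
                             saturation_scale = 1.25, brightness_scale = 0.9,
                             contrast_scale = 1.15, blur_sigma = -0.8,
                             noise_sigma = 5)
  )
}
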