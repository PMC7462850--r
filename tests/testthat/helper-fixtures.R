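# Shared fixtures, all generated in code.

# Small slide with known content, cached across test files.
fixture_slide <- local({
  cache <- new.env()
  function(label = "cancer", seed = 11L, style = center_style()) {
    key <- paste(label, seed, style$style_id)
    if (is.null(cache[[key]])) {
      spec <- slide_spec(paste0("fix_", seed), width = 1024L, height = 1024L,
                         label = label, seed = seed)
      cache[[key]] <- generate_slide(spec, style)
    }
    cache[[key]]
  }
})

# Deterministic RGB test raster.
fixture_rgb <- function(h = 24, w = 24, seed = 1) {
  set.seed(seed)
  array(runif(h * w * 3, 0, 255), dim = c(h, w, 3))
}

# Rectangle polygon helper (axis-aligned, closed implicitly).
rect_poly <- function(x0, y0, w, h)
  cbind(x = c(x0, x0 + w, x0 + w, x0), y = c(y0, y0, y0 + h, y0 + h))

# Random tumor map on an n x n grid.
random_tumor_map <- function(n = 8, seed = 1) {
  set.seed(seed)
  probs <- array(runif(n * n * 5), dim = c(n, n, 5))
  probs <- probs / array(rep(apply(probs, c(1, 2), sum), 5), dim = dim(probs))
  derive_tumor_map(likelihood_map(probs, mpp = 2))
}

# Tiny two-color patch sampler pair for GAN tests: domain A dark, domain B
# bright, each with a deterministic stream.
toy_domain_sampler <- function(base, p = 16L) {
  function(n) {
    out <- array(0, dim = c(p, p, 3, n))
    for (j in seq_len(n))
      out[, , , j] <- clamp(array(stats::rnorm(p * p * 3, base, 12),
                                  dim = c(p, p, 3)), 0, 255)
    out
  }
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Internal helpers exercised directly by some tests.
with_seed <- wsiscreen:::with_seed
resize_matrix <- wsiscreen:::resize_matrix

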