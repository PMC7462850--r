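# Internal helpers shared across modules.

# Five-class vocabulary used everywhere; "cancer" is the tumor class,
# "hg_pin" the high-grade PIN mimicker, "other" absorbs background tissue.
WSI_CLASSES <- c("cancer", "benign", "other_tissue_type", "hg_pin", "other")

#' Class vocabulary
#'
#' The fixed five-class vocabulary of the pipeline: cancer (adenocarcinoma),
#' benign glands, other tissue types, high-grade PIN (a benign mimicker of
#' cancer kept as its own class), and a catch-all other class.
#'
#' @return Character vector of the five class names, in channel order.
#' @export
wsi_classes <- function() WSI_CLASSES

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a per-item seed from a master seed
#'
#' Splitmix-style integer hashing so that per-slide generators are mutually
#' independent but fully determined by (master seed, index). All arithmetic is
#' done in double precision modulo 2^31 - 1 so results are identical across
#' platforms and always representable as R integers.
#'
#' @param master Master seed (single integer).
#' @param index Item index (vectorised).
#' @return Integer vector of derived seeds in [0, 2^31 - 2].
#' @export
derive_seed <- function(master, index) {
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  x <- (as.numeric(master) %% m + 1)
  out <- numeric(length(index))
  for (i in seq_along(index)) {
    z <- (x * 48271) %% m               # Lehmer step on the master stream
    z <- (z + as.numeric(index[i]) * 2654435761) %% m
    z <- (z * 69621) %% m
    out[i] <- z
  }
  as.integer(out)
}

# Evaluate `expr` under a local RNG state; restores the caller's state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

stopifnot_rgb <- function(img) {
  if (!(is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L))
    stop("expected an RGB raster (h x w x 3 array)", call. = FALSE)
}
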