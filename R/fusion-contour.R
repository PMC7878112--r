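#' Render a covariance map as a filled-contour RGB image
#'
#' Turns a covariance map into the fixed-size image the classifier consumes:
#' the matrix is treated as a surface over a regular grid, bilinearly
#' interpolated onto the output raster, and quantised into `levels` filled
#' isoline bands, each painted one solid colour from a dark-to-bright
#' perceptually ordered colormap (low covariance dark, high covariance
#' bright). The raster is bare — no axes, ticks, margins, text or
#' anti-aliasing — and byte-deterministic given `(C, levels, size, scaling,
#' colormap)`. Row index increases downward (image convention), so row `i`
#' of `C` maps to row `i` of the raster.
#'
#' Scaling decides the value-to-band mapping. `"per_image"` stretches
#' `[min(C), max(C)]` over the colormap, making the image invariant to a
#' global rescaling of the input signals (covariance scales with the square
#' of signal amplitude, but the band boundaries scale with it). A constant
#' map yields a single-colour image. `scaling = c(lo, hi)` fixes the range
#' for cross-window comparability; values outside are clamped.
#'
#' @param C Matrix (typically a `covariance_map`), at least 2 x 2.
#' @param levels Number of filled bands (>= 2); default 10.
#' @param size `c(height, width)` of the raster, components >= 8; default
#'   `c(300, 300)` to match the network's input.
#' @param scaling `"per_image"` or a numeric `c(lo, hi)` fixed range.
#' @param colormap Palette name understood by [grDevices::hcl.colors()];
#'   default `"viridis"` (dark violet through bright yellow).
#' @return An integer array `height x width x 3` in `[0, 255]`, class
#'   `contour_image`, with attributes `levels`, `scaling_range`, `colormap`.
#' @export
#' @examples
#' img <- render_contour(cov_signalwise(matrix(rnorm(40), 10, 4)),
#'                       levels = 10, size = c(64, 64))
#' dim(img)  # 64 64 3
render_contour <- function(C, levels = 10, size = c(300, 300),
                           scaling = "per_image", colormap = "viridis") {
  if (!is.matrix(C)) C <- as.matrix(C)
  storage.mode(C) <- "double"
  if (levels < 2) rlang::abort("levels must be >= 2")
  if (length(size) != 2 || any(size < 8)) {
    rlang::abort("size must be c(height, width) with both components >= 8")
  }
  if (!all(is.finite(C))) rlang::abort("covariance map has non-finite entries")

  M <- unclass(C)
  if (identical(scaling, "per_image")) {
    rng <- range(M)
  } else {
    stopifnot(is.numeric(scaling), length(scaling) == 2, scaling[1] < scaling[2])
    rng <- as.double(scaling)
    M <- pmin(pmax(M, rng[1]), rng[2])
  }
  if (rng[2] - rng[1] < 1e-300) {
    band <- matrix(1L, size[1], size[2])   # constant map: one solid band
  } else {
    # normalize at matrix level, then interpolate the unit field: the raster
    # is then invariant under rescaling of the input signals
    u <- bilinear_resize((M - rng[1]) / (rng[2] - rng[1]), size[1], size[2])
    band <- pmin(as.integer(floor(u * levels)) + 1L, as.integer(levels))
    band[band < 1L] <- 1L
    dim(band) <- c(size[1], size[2])
  }
  pal <- grDevices::hcl.colors(levels, palette = colormap)
  rgb <- t(grDevices::col2rgb(pal))   # levels x 3, 0..255
  px <- array(0L, dim = c(size[1], size[2], 3))
  for (k in 1:3) px[, , k] <- matrix(rgb[band, k], size[1], size[2])
  structure(px, class = "contour_image",
            levels = as.integer(levels), scaling_range = rng,
            colormap = colormap)
}

# Bilinear interpolation of a matrix onto an h x w grid spanning the same
# index range; separable (rows then columns).
bilinear_resize <- function(M, h, w) {
  src_r <- nrow(M); src_c <- ncol(M)
  ri <- if (h == 1) 1 else 1 + (seq_len(h) - 1) * (src_r - 1) / (h - 1)
  ci <- if (w == 1) 1 else 1 + (seq_len(w) - 1) * (src_c - 1) / (w - 1)
  r0 <- pmin(floor(ri), src_r - 1); wr <- ri - r0
  c0 <- pmin(floor(ci), src_c - 1); wc <- ci - c0
  if (src_r == 1) { r0 <- rep(1, h); wr <- rep(0, h) }
  if (src_c == 1) { c0 <- rep(1, w); wc <- rep(0, w) }
  top <- M[r0, , drop = FALSE] * (1 - wr) + M[pmin(r0 + 1, src_r), , drop = FALSE] * wr
  top[, c0, drop = FALSE] * rep(1 - wc, each = h) +
    top[, pmin(c0 + 1, src_c), drop = FALSE] * rep(wc, each = h)
}

#' @export
print.contour_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<contour_image> %d x %d x %d, %d bands, colormap '%s'\n",
              d[1], d[2], d[3], attr(x, "levels"), attr(x, "colormap")))
  invisible(x)
}

#' Write a contour image as PNG
#'
#' Lossless 8-bit RGB output via the png package.
#'
#' @param img A `contour_image` from [render_contour()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_contour_png <- function(img, path) {
  stopifnot(inherits(img, "contour_image"))
  png::writePNG(unclass(img) / 255, path)
  invisible(path)
}

#' Render every fused window of a window table
#'
#' Maps [render_contour()] over the `C` list-column, adding an `image`
#' list-column of `contour_image`s.
#'
#' @param windows Tibble with list-column `C` (see [fuse_windows()]).
#' @inheritParams render_contour
#' @return `windows` with an added `image` list-column.
#' @export
render_windows <- function(windows, levels = 10, size = c(300, 300),
                           scaling = "per_image", colormap = "viridis") {
  dplyr::mutate(windows, image = purrr::map(
    .data$C, render_contour,
    levels = levels, size = size, scaling = scaling, colormap = colormap
  ))
}
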