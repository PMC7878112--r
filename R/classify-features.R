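#' Extract fixed-length feature vectors from contour images
#'
#' The feature route to classification replaces end-to-end training with a
#' pluggable backbone: any callable mapping one image to a fixed-length
#' numeric vector (a pretrained deep network's layer activations in a
#' full-scale deployment, or one of the lightweight featurizers below).
#' The backbone's identity is recorded on the returned matrix.
#'
#' @param images List of `contour_image` rasters (or `HxWx3` arrays).
#' @param backbone Function `image -> numeric vector`; default
#'   [featurizer_pool()].
#' @return Numeric matrix, one row per image, with attribute `backbone`.
#' @export
extract_features <- function(images, backbone = featurizer_pool()) {
  feats <- lapply(images, function(im) as.double(backbone(im)))
  widths <- lengths(feats)
  if (length(unique(widths)) != 1) {
    rlang::abort(sprintf("backbone returned ragged feature widths: %s",
                         paste(sort(unique(widths)), collapse = ", ")))
  }
  out <- do.call(rbind, feats)
  attr(out, "backbone") <- attr(backbone, "backbone_name") %||% "custom"
  out
}

#' Lightweight image featurizers
#'
#' `featurizer_pool(cells)` average-pools each colour channel onto a
#' `cells x cells` grid, giving a `3 * cells^2` vector that preserves the
#' coarse spatial layout of the contour bands. `featurizer_hist(bins)`
#' histograms each channel's intensities into `bins` equal bins, a purely
#' distributional summary. Both are deterministic, dependency-free stand-ins
#' for a heavyweight pretrained backbone.
#'
#' @param cells Pooling grid size per side.
#' @param bins Histogram bins per channel.
#' @return A featurizer function usable as the `backbone` of
#'   [extract_features()].
#' @export
featurizer_pool <- function(cells = 8) {
  f <- function(img) {
    a <- unclass(img)
    d <- dim(a)
    rb <- ceiling(seq_len(d[1]) / (d[1] / cells))
    cb <- ceiling(seq_len(d[2]) / (d[2] / cells))
    cnt <- outer(tabulate(cb, cells), tabulate(rb, cells))
    unlist(lapply(1:3, function(k) {
      as.vector(rowsum(t(rowsum(a[, , k], rb)), cb) / cnt)
    }), use.names = FALSE) / 255
  }
  attr(f, "backbone_name") <- sprintf("pool%d", cells)
  f
}

#' @rdname featurizer_pool
#' @export
featurizer_hist <- function(bins = 16) {
  f <- function(img) {
    a <- unclass(img)
    unlist(lapply(1:3, function(k) {
      tabulate(pmin(floor(a[, , k] / 256 * bins) + 1L, bins), bins)
    }), use.names = FALSE) / (dim(a)[1] * dim(a)[2])
  }
  attr(f, "backbone_name") <- sprintf("hist%d", bins)
  f
}
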