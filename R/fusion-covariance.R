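#' Covariance map of an observation matrix
#'
#' The fusion core: a window's `m x n` observation matrix `H` (`m` time
#' samples by `n` channels) is summarised by a symmetric covariance matrix,
#' computed in one of two orientations.
#'
#' *Signal-wise* (`cov_signalwise()`): the `n x n` matrix of pairwise channel
#' covariances across the window's samples,
#' \deqn{C_{ij} = \frac{1}{m-1} \sum_{k=1}^{m} (H_{ki} - \mu_i)(H_{kj} - \mu_j),}
#' where \eqn{\mu_i} is the mean of column `i`. Suited to short windows over
#' many channels (e.g. 50-sample IMU segments).
#'
#' *Sample-wise* (`cov_samplewise()`): the same construction applied to the
#' transpose of `H`, giving the `m x m` matrix of pairwise time-sample
#' covariances across channels with normalisation `1/(n-1)`. Suited to long
#' windows (e.g. 500 samples at 64 Hz), where the map's axes index time.
#'
#' With `normalize = "correlation"` each entry is divided by
#' `sqrt(C_ii * C_jj)`; a `0/0` from a zero-variance row is defined as 0.
#' Symmetry is exact by construction (the strict lower triangle is mirrored
#' from the upper).
#'
#' @param H Numeric matrix, `m` samples x `n` channels, all entries finite
#'   (impute first; see [moving_median_impute()]).
#' @param normalize `"none"` (covariance, the default) or `"correlation"`.
#' @return A symmetric matrix of class `covariance_map` with attributes
#'   `mode` (`"signalwise"` or `"samplewise"`) and `normalize`.
#' @export
#' @examples
#' H <- cbind(a = c(1, 2, 3), b = c(2, 4, 6))
#' cov_signalwise(H)            # [[1,2],[2,4]]
#' cov_samplewise(H)            # 3 x 3, equals cov_signalwise(t(H))
cov_signalwise <- function(H, normalize = c("none", "correlation")) {
  normalize <- match.arg(normalize)
  H <- check_observation_matrix(H, min_rows = 2)
  C <- stats::cov(H)
  new_covariance_map(C, mode = "signalwise", normalize = normalize)
}

#' @rdname cov_signalwise
#' @export
cov_samplewise <- function(H, normalize = c("none", "correlation")) {
  normalize <- match.arg(normalize)
  H <- check_observation_matrix(H, min_cols = 2)
  C <- stats::cov(t(H))
  new_covariance_map(C, mode = "samplewise", normalize = normalize)
}

check_observation_matrix <- function(H, min_rows = 2, min_cols = 2) {
  if (!is.matrix(H)) H <- as.matrix(H)
  storage.mode(H) <- "double"
  if (nrow(H) < min_rows || ncol(H) < min_cols) {
    rlang::abort(sprintf("observation matrix must be at least %d x %d, got %d x %d",
                         min_rows, min_cols, nrow(H), ncol(H)))
  }
  if (!all(is.finite(H))) {
    rlang::abort(paste0(
      "observation matrix contains missing or non-finite entries; ",
      "run imputation (moving_median_impute) or fill them before fusing"
    ))
  }
  H
}

new_covariance_map <- function(C, mode, normalize) {
  # enforce exact symmetry: mirror the upper triangle
  C[lower.tri(C)] <- t(C)[lower.tri(C)]
  if (normalize == "correlation") {
    d <- sqrt(diag(C))
    denom <- outer(d, d)
    Cn <- C / denom
    Cn[denom == 0] <- 0   # zero-variance channels: define 0/0 -> 0
    diag(Cn) <- as.numeric(d > 0)
    C <- Cn
    C[lower.tri(C)] <- t(C)[lower.tri(C)]
  }
  structure(C, class = c("covariance_map", "matrix", "array"),
            mode_cov = mode, normalize = normalize)
}

#' @export
print.covariance_map <- function(x, ...) {
  cat(sprintf("<covariance_map> %s, %d x %d%s\n", attr(x, "mode_cov"),
              nrow(x), ncol(x),
              if (attr(x, "normalize") == "correlation") ", correlation-normalized" else ""))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x))), drop = FALSE])
  invisible(x)
}

#' Fuse segmented windows into covariance maps
#'
#' Applies [cov_signalwise()] or [cov_samplewise()] to the `H` list-column
#' of a window table from [segment_windows()], adding a `C` list-column.
#'
#' @param windows Tibble with list-column `H` (observation matrices).
#' @param mode `"signalwise"` or `"samplewise"`.
#' @param normalize Passed to the covariance functions.
#' @return `windows` with an added list-column `C` of `covariance_map`s.
#' @export
fuse_windows <- function(windows, mode = c("signalwise", "samplewise"),
                         normalize = c("none", "correlation")) {
  mode <- match.arg(mode)
  normalize <- match.arg(normalize)
  f <- if (mode == "signalwise") cov_signalwise else cov_samplewise
  dplyr::mutate(windows, C = purrr::map(.data$H, f, normalize = normalize))
}
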