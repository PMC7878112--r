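#' Inject missing-completely-at-random entries into an observation matrix
#'
#' Replaces exactly `round(rate * m * n)` entries of an `m x n` matrix with
#' `NA`, positions drawn uniformly without replacement. MCAR means the
#' positions are independent of both the values and the activity label; the
#' draw is fully reproducible from `seed`.
#'
#' @param H Numeric matrix with finite entries.
#' @param rate Fraction of entries to drop, in `[0, 1)`.
#' @param seed Integer seed for the position draw.
#' @return `H` with `NA` markers at the drawn positions.
#' @export
#' @examples
#' H <- matrix(rnorm(500 * 8), 500, 8)
#' sum(is.na(inject_missing(H, 0.25, seed = 1)))  # 1000
inject_missing <- function(H, rate, seed = 1L) {
  stopifnot(is.matrix(H))
  if (rate < 0 || rate >= 1) rlang::abort("missingness rate must lie in [0, 1)")
  n_miss <- round(rate * length(H))
  if (n_miss == 0) return(H)
  idx <- withr::with_seed(as.integer(seed),
                          sample.int(length(H), n_miss, replace = FALSE))
  H[idx] <- NA_real_
  H
}

#' Moving-median imputation of a univariate sequence
#'
#' Fills each missing entry with the median of the observed values inside a
#' centred window of `window` positions (for even `window` the extra
#' position falls on the right, matching the usual moving-filter
#' convention). The window shrinks at the sequence edges; if a window holds
#' no observed value it is doubled until it does, which guarantees
#' termination whenever at least one value is observed. Even-count medians
#' are the mean of the two middle values. Observed entries are never
#' modified, so the filter is idempotent, and every imputed value lies
#' within the observed min/max — medians cannot extrapolate.
#'
#' @param x Numeric vector; `NA` marks missing samples.
#' @param window Window length in samples (>= 3); default 20.
#' @return `x` with all `NA` entries replaced.
#' @export
#' @examples
#' moving_median_impute(c(1, 2, NA, 4, 10), window = 3)  # gap -> median(2,4) = 3
moving_median_impute <- function(x, window = 20) {
  if (window < 3) rlang::abort("median window must be >= 3")
  miss <- is.na(x)
  if (!any(miss)) return(x)
  if (all(miss)) rlang::abort("cannot impute an all-missing sequence")
  n <- length(x)
  half_lo <- floor((window - 1) / 2)
  half_hi <- window - 1 - half_lo
  for (i in which(miss)) {
    lo <- half_lo; hi <- half_hi
    repeat {
      w <- x[max(1, i - lo):min(n, i + hi)]
      w <- w[!is.na(w)]
      if (length(w) > 0) break
      lo <- lo * 2 + 1; hi <- hi * 2 + 1   # double the window until occupied
    }
    x[i] <- stats::median(w)
  }
  x
}

#' Impute (or zero-fill) missing entries of an observation matrix
#'
#' The moving median is a univariate filter, so imputation runs column by
#' column — each channel is repaired from its own temporal neighbourhood.
#' `method = "none"` replaces missing entries by zero instead: this is the
#' no-repair reference condition for degradation experiments, in which a
#' dropped sample simply contributes nothing to the window, corrupting the
#' covariance structure the way an unrepaired sensor dropout would.
#'
#' @param H Numeric matrix with `NA` missing markers.
#' @param method `"moving_median"` or `"none"` (zero fill).
#' @param window Median window length (samples), used by `"moving_median"`.
#' @return `H` with no remaining `NA` entries.
#' @export
impute_matrix <- function(H, method = c("moving_median", "none"), window = 20) {
  method <- match.arg(method)
  stopifnot(is.matrix(H))
  if (!anyNA(H)) return(H)
  if (method == "none") {
    H[is.na(H)] <- 0
    return(H)
  }
  apply_cols <- apply(H, 2, moving_median_impute, window = window)
  dimnames(apply_cols) <- dimnames(H)
  apply_cols
}
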