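#' Resample a signal track to a uniform rate
#'
#' Places the track on a uniform grid `t0 + k/target_rate` covering its span
#' (or an explicit `span`). Three methods are provided:
#'
#' * `"linear"` — linear interpolation between the two bracketing samples;
#'   the natural choice when upsampling regular channels.
#' * `"hold"` — zero-order hold (last observed sample persists); the
#'   conventional way to extend intermittent physiological outputs such as
#'   interbeat intervals or 10-second averaged heart rate to a dense grid.
#' * `"mean_decimate"` — block averaging into the output sampling bins;
#'   only valid when downsampling, and errors otherwise.
#'
#' Missing markers propagate and are never interpolated here: an output
#' sample whose bracketing inputs (linear), preceding input (hold), or bin
#' (mean_decimate) contain `NA` is itself `NA`. Filling gaps is the
#' imputation stage's job ([moving_median_impute()]), kept separate so that
#' missing-data experiments stay explicit.
#'
#' @param track A [signal_track()] with at least two samples.
#' @param target_rate Output rate in samples/second (> 0).
#' @param method One of `"linear"`, `"hold"`, `"mean_decimate"`.
#' @param span Optional `c(t_lo, t_hi)` limiting/anchoring the output grid;
#'   defaults to the track's own time range.
#' @return A [signal_track()] uniform at `target_rate`, same channel name.
#' @export
#' @examples
#' tr <- signal_track(c(0, 1), c(0, 8), "EDA", rate = 1)
#' resample_track(tr, 4, "linear")$value  # 0 2 4 6 8
resample_track <- function(track, target_rate,
                           method = c("linear", "hold", "mean_decimate"),
                           span = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(track, "signal_track"))
  if (target_rate <= 0) rlang::abort("target_rate must be > 0")
  if (nrow(track) < 2) {
    rlang::abort(sprintf("channel '%s': cannot resample a track with < 2 samples",
                         track_channel(track)))
  }
  span <- span %||% range(track$time)
  t_out <- seq(span[1], span[2] + 1e-12, by = 1 / target_rate)
  t_out <- t_out[t_out <= span[2] + 1e-9]
  native <- track_median_rate(track)
  if (method == "mean_decimate" && !is.na(native) && target_rate > native + 1e-9) {
    rlang::abort(sprintf(
      "channel '%s': mean_decimate needs target_rate (%g) <= native rate (%g); use linear or hold to upsample",
      track_channel(track), target_rate, native
    ))
  }
  v_out <- switch(method,
    linear = interp_linear(track$time, track$value, t_out),
    hold = interp_hold(track$time, track$value, t_out),
    mean_decimate = decimate_mean(track$time, track$value, t_out, target_rate)
  )
  signal_track(t_out, v_out, track_channel(track), rate = target_rate)
}

# Linear interpolation that keeps NA markers: an output point bracketed by an
# NA sample (or coinciding with one) stays NA.
interp_linear <- function(t, v, t_out) {
  lo <- findInterval(t_out, t)
  lo[lo < 1] <- 1
  hi <- pmin(lo + 1, length(t))
  exact <- abs(t[lo] - t_out) < 1e-9
  hi[exact] <- lo[exact]
  w <- ifelse(hi == lo, 0, (t_out - t[lo]) / (t[hi] - t[lo]))
  v[lo] * (1 - w) + v[hi] * w
}

interp_hold <- function(t, v, t_out) {
  lo <- findInterval(t_out, t)
  lo[lo < 1] <- 1
  v[lo]
}

decimate_mean <- function(t, v, t_out, rate_out) {
  bin <- findInterval(t, t_out - 1e-9)
  bin[bin < 1] <- 1
  bin[bin > length(t_out)] <- length(t_out)
  sums <- tapply(v, factor(bin, levels = seq_along(t_out)), mean)
  as.double(sums)
}

#' Resample every track of a recording onto one common grid
#'
#' Brings all channels to `rate` on a shared time axis anchored at the
#' latest track start and ending at the earliest track end, so that every
#' channel contributes one value per grid point and windows can be cut
#' directly. Regular tracks are linearly interpolated when upsampled and
#' block-averaged when downsampled; irregular tracks (rate `NA`) use
#' zero-order hold. Per-channel overrides are accepted.
#'
#' @param rec A [recording()].
#' @param rate Common rate in samples/second.
#' @param methods Optional named character vector of per-channel methods
#'   (names are channel ids, values as in [resample_track()]).
#' @return A [recording()] whose tracks share one uniform time axis.
#' @export
resample_recording <- function(rec, rate, methods = NULL) {
  stopifnot(inherits(rec, "wearable_recording"))
  t_lo <- max(vapply(rec$tracks, function(tr) tr$time[1], double(1)))
  t_hi <- min(vapply(rec$tracks, function(tr) tr$time[nrow(tr)], double(1)))
  if (t_hi <= t_lo) rlang::abort("tracks share no common time span")
  tracks <- lapply(rec$tracks, function(tr) {
    ch <- track_channel(tr)
    m <- if (!is.null(methods) && ch %in% names(methods)) {
      methods[[ch]]
    } else if (is.na(track_rate(tr))) {
      "hold"
    } else if (track_median_rate(tr) >= rate + 1e-9) {
      "mean_decimate"
    } else {
      "linear"
    }
    resample_track(tr, rate, m, span = c(t_lo, t_hi))
  })
  recording(tracks, if (nrow(rec$labels)) rec$labels else NULL)
}
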