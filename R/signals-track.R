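#' Construct a signal track
#'
#' A signal track is one channel of a wearable recording: a tibble with
#' columns `time` (seconds, 0-based within the session) and `value` (sensor
#' units, `NA` marks a missing sample), carrying the channel name and nominal
#' sampling rate as attributes. Rows are sorted by time and duplicate
#' timestamps are collapsed to the mean of their values, so the stored time
#' axis is strictly increasing.
#'
#' @param time Numeric vector of timestamps in seconds, not necessarily
#'   sorted or unique.
#' @param value Numeric vector of sensor readings, same length as `time`.
#'   `NA` entries are missing-sample markers and are preserved.
#' @param name Channel identifier, e.g. `"ACC_x"` or `"BVP"`.
#' @param rate Nominal sampling rate in samples/second, or `NA` for
#'   intermittent channels (interbeat intervals, windowed heart rate) that
#'   have no fixed rate.
#'
#' @return A tibble of class `signal_track` with columns `time` and `value`
#'   and attributes `channel` and `rate`.
#' @export
#' @examples
#' signal_track(c(0, 0.25, 0.5), c(1.2, 1.3, 1.1), "EDA", rate = 4)
signal_track <- function(time, value, name, rate = NA_real_) {
  stopifnot(is.numeric(time), is.numeric(value))
  if (length(time) != length(value)) {
    rlang::abort(sprintf(
      "channel '%s': time and value lengths differ (%d vs %d)",
      name, length(time), length(value)
    ))
  }
  ord <- order(time)
  time <- time[ord]
  value <- as.double(value)[ord]
  if (anyDuplicated(time)) {
    value <- as.double(tapply(value, time, mean))
    time <- sort(unique(time))
  }
  out <- tibble::tibble(time = as.double(time), value = value)
  attr(out, "channel") <- as.character(name)
  attr(out, "rate") <- as.double(rate)
  class(out) <- c("signal_track", class(out))
  out
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf(
    "<signal_track> channel '%s', %d samples, rate %s Hz\n",
    track_channel(x), nrow(x),
    if (is.na(track_rate(x))) "irregular" else format(track_rate(x))
  ))
  NextMethod()
}

#' Channel name and sampling rate of a track
#' @param track A [signal_track()].
#' @return The channel name (character) or nominal rate (numeric,
#'   `NA` for intermittent channels).
#' @export
track_channel <- function(track) attr(track, "channel")

#' @rdname track_channel
#' @export
track_rate <- function(track) attr(track, "rate")

# Median spacing of a track's time axis; used to sanity-check declared rates
# and to detect up- vs down-sampling.
track_median_rate <- function(track) {
  if (nrow(track) < 2) return(NA_real_)
  1 / stats::median(diff(track$time))
}

#' Assemble a multimodal recording
#'
#' Bundles one [signal_track()] per channel with a table of labeled activity
#' intervals. The channel order given here is frozen: it fixes the column
#' order of every observation matrix built from the recording, and therefore
#' the orientation of all covariance maps.
#'
#' @param tracks List of [signal_track()] objects; names are taken from the
#'   tracks' own channel attributes.
#' @param labels Data frame of activity intervals with columns `start`,
#'   `end` (seconds, half-open `[start, end)`), `activity` and `subject`.
#'   May be `NULL` for an unlabeled recording.
#'
#' @return An object of class `wearable_recording`: a list with elements
#'   `tracks` (named list) and `labels` (tibble).
#' @export
recording <- function(tracks, labels = NULL) {
  stopifnot(is.list(tracks), length(tracks) >= 1)
  ok <- vapply(tracks, inherits, logical(1), "signal_track")
  if (!all(ok)) rlang::abort("all tracks must be signal_track objects")
  names(tracks) <- vapply(tracks, track_channel, character(1))
  if (anyDuplicated(names(tracks))) {
    rlang::abort("duplicate channel names in recording")
  }
  if (is.null(labels)) {
    labels <- tibble::tibble(
      start = double(), end = double(),
      activity = character(), subject = character()
    )
  } else {
    labels <- tibble::as_tibble(labels)
    stopifnot(all(c("start", "end", "activity", "subject") %in% names(labels)))
    labels$activity <- as.character(labels$activity)
    labels$subject <- as.character(labels$subject)
    if (any(labels$end <= labels$start)) {
      rlang::abort("label intervals must satisfy start < end")
    }
    span <- range(unlist(lapply(tracks, function(tr) range(tr$time))))
    if (nrow(labels) > 0 &&
        any(labels$start < span[1] - 1e-9 | labels$end > span[2] + 1 + 1e-9)) {
      rlang::abort("label intervals fall outside the recording's time span")
    }
  }
  structure(list(tracks = tracks, labels = labels),
            class = "wearable_recording")
}

#' @export
print.wearable_recording <- function(x, ...) {
  cat(sprintf(
    "<wearable_recording> %d channels (%s), %d label interval(s)\n",
    length(x$tracks), paste(names(x$tracks), collapse = ", "),
    nrow(x$labels)
  ))
  invisible(x)
}

#' @export
as_tibble.wearable_recording <- function(x, ...) {
  purrr::map_dfr(x$tracks, function(tr) {
    tibble::tibble(channel = track_channel(tr), time = tr$time,
                   value = tr$value)
  }) |>
    dplyr::mutate(channel = factor(.data$channel, levels = names(x$tracks)))
}

#' Channel names of a recording, in frozen order
#' @param rec A [recording()].
#' @return Character vector of channel names.
#' @export
channels <- function(rec) names(rec$tracks)
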