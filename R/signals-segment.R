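#' Cut a recording into labeled fixed-length observation matrices
#'
#' Slides a window of `window_len` samples (advancing by `hop`) over a
#' recording whose tracks already share one uniform time axis (see
#' [resample_recording()]). Each surviving window yields an observation
#' matrix `H` with `window_len` rows (time samples) and one column per
#' channel, columns in the recording's frozen channel order. A window keeps
#' the label of the activity interval that fully contains its half-open time
#' span `[t, t + window_len/rate)`; windows straddling a label boundary are
#' discarded so that every segment has one unambiguous label.
#'
#' @param rec A labeled [recording()] with all tracks on one uniform grid.
#' @param window_len Window length in samples (>= 2).
#' @param hop Hop between window starts in samples (>= 1); defaults to
#'   `window_len`, i.e. non-overlapping tiling.
#' @return A tibble with one row per window: `t_start` (seconds), `label`,
#'   `subject`, and list-column `H` of `window_len x n_channels` matrices
#'   (column names are the channel ids).
#' @export
segment_windows <- function(rec, window_len, hop = window_len) {
  stopifnot(inherits(rec, "wearable_recording"))
  if (window_len < 2) rlang::abort("window_len must be >= 2")
  if (hop < 1) rlang::abort("hop must be >= 1")
  if (nrow(rec$labels) == 0) rlang::abort("recording has no labels to segment by")
  grids <- lapply(rec$tracks, function(tr) tr$time)
  n0 <- vapply(grids, length, integer(1))
  if (length(unique(n0)) != 1 ||
      max(vapply(grids, function(g) max(abs(g - grids[[1]])), double(1))) > 1e-6) {
    rlang::abort("tracks are not on a shared uniform grid; run resample_recording() first")
  }
  tgrid <- grids[[1]]
  rate <- 1 / stats::median(diff(tgrid))
  m_total <- length(tgrid)
  values <- do.call(cbind, lapply(rec$tracks, function(tr) tr$value))
  colnames(values) <- channels(rec)

  starts <- seq.int(1L, m_total - window_len + 1L, by = hop)
  rows <- purrr::map(starts, function(s) {
    t0 <- tgrid[s]
    t1 <- t0 + window_len / rate
    hit <- which(rec$labels$start <= t0 + 1e-9 & t1 <= rec$labels$end + 1e-9)
    if (length(hit) != 1) return(NULL)
    tibble::tibble(
      t_start = t0,
      label = rec$labels$activity[hit],
      subject = rec$labels$subject[hit],
      H = list(values[s:(s + window_len - 1L), , drop = FALSE])
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    rlang::warn("no window fits inside a labeled interval; zero segments returned")
    out <- tibble::tibble(t_start = double(), label = character(),
                          subject = character(), H = list())
  }
  out
}
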