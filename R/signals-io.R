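#' Read a multimodal recording from disk
#'
#' Two on-disk dialects are supported.
#'
#' `"long_csv"`: `path` is a single CSV with columns
#' `timestamp,channel,value` (seconds, channel id, reading); rows may be in
#' any order. An optional companion CSV gives labels as
#' `start,end,activity,subject`.
#'
#' `"empatica"`: `path` is a directory in the Empatica E4 export layout, one
#' CSV per channel (`ACC.csv`, `BVP.csv`, `EDA.csv`, `TEMP.csv`, `HR.csv`,
#' `IBI.csv`). For the regular channels row 1 holds the session start (epoch
#' seconds) and row 2 the sampling rate; `ACC.csv` has three value columns
#' which become tracks `ACC_x`, `ACC_y`, `ACC_z`. `IBI.csv` has the session
#' start in row 1 and `(offset s, interval s)` pairs below; it is loaded as
#' an irregular track. All times are shifted so the earliest session start
#' is 0.
#'
#' @param path File (long_csv) or directory (empatica).
#' @param dialect `"long_csv"` or `"empatica"`.
#' @param labels Optional path to a labels CSV (`start,end,activity,subject`).
#' @param channel_order Optional character vector fixing the channel order of
#'   the recording; defaults to order of first appearance (long_csv) or the
#'   canonical E4 order (empatica).
#'
#' @return A [recording()].
#' @export
read_recording <- function(path,
                           dialect = c("long_csv", "empatica"),
                           labels = NULL,
                           channel_order = NULL) {
  dialect <- match.arg(dialect)
  lab <- if (!is.null(labels)) read_labels(labels) else NULL
  switch(dialect,
    long_csv = read_long_csv(path, lab, channel_order),
    empatica = read_empatica(path, lab, channel_order)
  )
}

read_labels <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("labels file not found: %s", path))
  lab <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("start", "end", "activity", "subject")
  if (!all(need %in% names(lab))) {
    rlang::abort(sprintf("labels CSV %s must have columns %s",
                         path, paste(need, collapse = ",")))
  }
  lab
}

read_long_csv <- function(path, lab, channel_order) {
  if (!file.exists(path)) rlang::abort(sprintf("recording file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("timestamp", "channel", "value")
  if (!all(need %in% names(df))) {
    rlang::abort(sprintf(
      "long_csv file %s: expected columns %s, found %s",
      path, paste(need, collapse = ","), paste(names(df), collapse = ",")
    ))
  }
  chans <- channel_order %||% unique(df$channel)
  tracks <- lapply(chans, function(ch) {
    sub <- df[df$channel == ch, ]
    if (nrow(sub) == 0) {
      rlang::warn(sprintf("channel '%s' is empty; track dropped", ch))
      return(NULL)
    }
    tr <- signal_track(sub$timestamp, sub$value, ch)
    attr(tr, "rate") <- track_median_rate(tr)
    tr
  })
  tracks <- tracks[!vapply(tracks, is.null, logical(1))]
  recording(tracks, lab)
}

# Canonical Empatica E4 per-channel files and their layout quirks.
empatica_channels <- c("ACC", "BVP", "EDA", "TEMP", "HR", "IBI")

read_empatica <- function(path, lab, channel_order) {
  if (!dir.exists(path)) rlang::abort(sprintf("empatica directory not found: %s", path))
  chans <- channel_order %||% empatica_channels
  files <- file.path(path, paste0(chans, ".csv"))
  present <- file.exists(files)
  if (!any(present)) {
    rlang::abort(sprintf("no Empatica channel files found under %s", path))
  }
  parsed <- purrr::map2(files[present], chans[present], parse_empatica_file)
  tracks <- purrr::flatten(parsed)
  tracks <- tracks[!vapply(tracks, is.null, logical(1))]
  if (length(tracks) == 0) rlang::abort("all Empatica channels were empty")
  t0 <- min(vapply(tracks, function(tr) attr(tr, "session_start"), double(1)))
  tracks <- lapply(tracks, function(tr) {
    shift <- attr(tr, "session_start") - t0
    out <- signal_track(tr$time + shift, tr$value, track_channel(tr),
                        track_rate(tr))
    out
  })
  recording(tracks, lab)
}

# One E4 file -> list of signal_tracks (3 for ACC, 1 otherwise), each with a
# session_start attribute in epoch seconds. Header errors name the file.
parse_empatica_file <- function(file, channel) {
  raw <- tryCatch(
    utils::read.csv(file, header = FALSE, stringsAsFactors = FALSE),
    error = function(e) rlang::abort(sprintf("cannot parse %s: %s", file, conditionMessage(e)))
  )
  if (nrow(raw) < 1 || is.na(suppressWarnings(as.numeric(raw[1, 1])))) {
    rlang::abort(sprintf("%s: garbled header (row 1 must be the session start epoch)", file))
  }
  start <- as.numeric(raw[1, 1])
  if (channel == "IBI") {
    body <- raw[-1, , drop = FALSE]
    if (nrow(body) == 0) {
      rlang::warn(sprintf("%s: empty channel; track dropped", file))
      return(list(NULL))
    }
    offs <- suppressWarnings(as.numeric(body[[1]]))
    ibi <- suppressWarnings(as.numeric(body[[2]]))
    keep <- !is.na(offs) & !is.na(ibi)
    tr <- signal_track(offs[keep], ibi[keep], "IBI", rate = NA_real_)
    attr(tr, "session_start") <- start
    return(list(tr))
  }
  if (nrow(raw) < 2 || is.na(suppressWarnings(as.numeric(raw[2, 1])))) {
    rlang::abort(sprintf("%s: garbled header (row 2 must be the sampling rate)", file))
  }
  rate <- as.numeric(raw[2, 1])
  body <- raw[-(1:2), , drop = FALSE]
  if (nrow(body) == 0) {
    rlang::warn(sprintf("%s: empty channel; track dropped", file))
    return(list(NULL))
  }
  times <- (seq_len(nrow(body)) - 1) / rate
  if (channel == "ACC" && ncol(body) >= 3) {
    axes <- c("x", "y", "z")
    lapply(1:3, function(i) {
      tr <- signal_track(times, as.numeric(body[[i]]),
                         paste0("ACC_", axes[i]), rate = rate)
      attr(tr, "session_start") <- start
      tr
    })
  } else {
    tr <- signal_track(times, as.numeric(body[[1]]), channel, rate = rate)
    attr(tr, "session_start") <- start
    list(tr)
  }
}

#' Write a recording as long-format CSV
#'
#' Emits the `long_csv` dialect read back by [read_recording()]: a signals
#' CSV with columns `timestamp,channel,value` and, when the recording is
#' labeled, a labels CSV `start,end,activity,subject`.
#'
#' @param rec A [recording()].
#' @param path Output CSV path for the signals.
#' @param labels_path Output CSV path for the labels; default replaces the
#'   extension of `path` with `_labels.csv`. Ignored for unlabeled
#'   recordings.
#' @return Invisibly, the signal CSV path.
#' @export
write_recording <- function(rec, path,
                            labels_path = sub("\\.csv$", "_labels.csv", path)) {
  stopifnot(inherits(rec, "wearable_recording"))
  df <- as_tibble(rec)
  readr::write_csv(
    tibble::tibble(timestamp = df$time, channel = as.character(df$channel),
                   value = df$value),
    path
  )
  if (nrow(rec$labels) > 0) readr::write_csv(rec$labels, labels_path)
  invisible(path)
}
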