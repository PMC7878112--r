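#' Activity model for the synthetic benchmark
#'
#' The generator rests on the same premise as the fusion method itself:
#' signals captured concurrently by different sensors are statistically
#' coupled, and the coupling pattern — the cross-channel covariance — is
#' characteristic of the activity. Each activity is a linear factor model
#' with autoregressive latents: `r` independent AR(1) factors
#' `z_t = phi z_(t-1) + e_t` (`e_t ~ N(0, 1)`, `|phi| < 1`) drive the
#' channels through a mixing matrix, `x_t = A z_t + eps_t`, with
#' independent per-channel Gaussian noise. The stationary channel
#' covariance is known in closed form,
#' `Sigma = A diag(1 / (1 - phi^2)) A' + diag(sigma^2)`
#' (see [implied_covariance()]), which is what makes every downstream
#' module testable against an analytic oracle.
#'
#' @param name Activity label.
#' @param mixing `n_channels x r` mixing matrix `A`.
#' @param ar Length-`r` AR(1) coefficients, each in `(-1, 1)`.
#' @param noise_sd Per-channel noise standard deviation (scalar recycled),
#'   each > 0.
#' @return A list of class `activity_model`.
#' @export
activity_model <- function(name, mixing, ar, noise_sd = 0.3) {
  mixing <- as.matrix(mixing)
  if (any(abs(ar) >= 1)) {
    rlang::abort(sprintf("activity '%s': AR coefficients must satisfy |phi| < 1",
                         name))
  }
  if (length(ar) != ncol(mixing)) {
    rlang::abort("length(ar) must equal ncol(mixing)")
  }
  noise_sd <- rep_len(noise_sd, nrow(mixing))
  if (any(noise_sd < 0)) rlang::abort("noise_sd must be >= 0")
  structure(list(name = as.character(name), mixing = mixing,
                 ar = as.double(ar), noise_sd = noise_sd),
            class = "activity_model")
}

#' Stationary channel covariance implied by an activity model
#'
#' @param model An [activity_model()], or its mixing matrix together with
#'   `ar` and `noise_sd`.
#' @return The `n_channels x n_channels` stationary covariance
#'   `A diag(1/(1 - phi^2)) A' + diag(sigma^2)`.
#' @export
implied_covariance <- function(model) {
  stopifnot(inherits(model, "activity_model"))
  A <- model$mixing
  A %*% diag(1 / (1 - model$ar^2), length(model$ar)) %*% t(A) +
    diag(model$noise_sd^2, nrow(A))
}

#' Benchmark configuration
#'
#' Describes a full synthetic study: the activity models, the channels with
#' their native sampling rates, the common analysis rate, the windowing,
#' and how many labeled windows per class to produce across how many
#' subjects. Validity checks require at least two activities and enforce a
#' minimum relative Frobenius separation between the activities' implied
#' covariances, so a benchmark whose classes are statistically
#' indistinguishable is rejected at construction rather than discovered as
#' a mysteriously failing classifier.
#'
#' @param activities List of [activity_model()]s sharing one channel count.
#' @param channel_rates Named numeric vector of native rates
#'   (samples/second), one per channel; names become channel ids.
#' @param common_rate Rate all channels are brought to before windowing.
#' @param window_len Window length in samples at `common_rate`.
#' @param windows_per_class Total labeled windows per activity (split
#'   evenly across subjects).
#' @param n_subjects Number of synthetic subjects.
#' @param subject_sd Scale of the per-subject random rotation applied to
#'   each mixing matrix; 0 removes subject heterogeneity.
#' @param min_separation Minimum pairwise relative Frobenius distance
#'   between implied covariances.
#' @param seed Integer master seed.
#' @return A list of class `benchmark_config`.
#' @export
benchmark_config <- function(activities, channel_rates, common_rate = 32,
                             window_len = 50, windows_per_class = 40,
                             n_subjects = 5, subject_sd = 0.1,
                             min_separation = 0.1, seed = 1L) {
  if (length(activities) < 2) rlang::abort("need at least two activities")
  n_ch <- nrow(activities[[1]]$mixing)
  if (!all(vapply(activities, function(a) nrow(a$mixing), 0) == n_ch)) {
    rlang::abort("all activities must share one channel count")
  }
  if (length(channel_rates) != n_ch || is.null(names(channel_rates))) {
    rlang::abort("channel_rates must be named, one rate per channel")
  }
  if (windows_per_class %% n_subjects != 0) {
    rlang::abort("windows_per_class must be divisible by n_subjects")
  }
  covs <- lapply(activities, implied_covariance)
  scale <- mean(vapply(covs, function(S) norm(S, "F"), 0))
  for (i in seq_along(covs)) {
    for (j in seq_len(i - 1)) {
      d <- norm(covs[[i]] - covs[[j]], "F") / scale
      if (d < min_separation) {
        rlang::abort(sprintf(
          "activities '%s' and '%s' have nearly identical implied covariances (relative Frobenius distance %.3g < %.3g)",
          activities[[i]]$name, activities[[j]]$name, d, min_separation
        ))
      }
    }
  }
  structure(
    list(activities = activities, channel_rates = channel_rates,
         common_rate = common_rate, window_len = window_len,
         windows_per_class = windows_per_class, n_subjects = n_subjects,
         subject_sd = subject_sd, min_separation = min_separation,
         seed = as.integer(seed)),
    class = "benchmark_config"
  )
}

#' A ready-made three-activity benchmark
#'
#' Eight channels at heterogeneous native rates (mirroring a wristband's
#' mix of fast and slow sensors), three activities driven by three AR(1)
#' factors, 40 windows of 50 samples per class, five subjects. All
#' activities share a common base mixing structure (the wearer's physiology
#' couples the channels regardless of what they are doing) plus an
#' activity-specific deviation of comparable scale, with unit-level channel
#' noise — a regime where classes overlap enough that classification is
#' clearly above chance but well below ceiling, missing data visibly hurts,
#' and an unseen subject is genuinely harder than an unseen window. The
#' structure matrices are drawn once from `seed`.
#'
#' @param seed Master seed.
#' @param windows_per_class,n_subjects,window_len,subject_sd Overrides of
#'   the defaults above.
#' @return A [benchmark_config()].
#' @export
default_benchmark <- function(seed = 1L, windows_per_class = 40,
                              n_subjects = 5, window_len = 50,
                              subject_sd = 0.15) {
  n_ch <- 8; r <- 3
  mix <- withr::with_seed(as.integer(seed) + 1000L, {
    base <- matrix(stats::rnorm(n_ch * r), n_ch, r)
    lapply(1:3, function(k) {
      base + matrix(stats::rnorm(n_ch * r, sd = 0.9), n_ch, r)
    })
  })
  ar <- c(0.8, 0.85, 0.7)
  acts <- list(
    activity_model("eating", mix[[1]], ar = ar, noise_sd = 0.7),
    activity_model("working", mix[[2]], ar = ar, noise_sd = 0.7),
    activity_model("sleeping", mix[[3]], ar = ar, noise_sd = 0.7)
  )
  rates <- c(ch1 = 32, ch2 = 32, ch3 = 32, ch4 = 16, ch5 = 16, ch6 = 8,
             ch7 = 8, ch8 = 4)
  benchmark_config(acts, rates, common_rate = 32, window_len = window_len,
                   windows_per_class = windows_per_class,
                   n_subjects = n_subjects, subject_sd = subject_sd,
                   seed = as.integer(seed))
}

# Simulate one AR(1)-factor bout of n samples for an activity model.
simulate_bout <- function(model, n) {
  r <- length(model$ar)
  Z <- matrix(0, n, r)
  for (j in seq_len(r)) {
    phi <- model$ar[j]
    e <- stats::rnorm(n)
    z <- numeric(n)
    z[1] <- stats::rnorm(1, sd = sqrt(1 / (1 - phi^2)))
    for (t in 2:n) z[t] <- phi * z[t - 1] + e[t]
    Z[, j] <- z
  }
  X <- Z %*% t(model$mixing)
  X + matrix(stats::rnorm(length(X)), nrow(X), ncol(X)) %*%
    diag(model$noise_sd, ncol(X))
}

# Near-identity random rotation: orthogonalized perturbation of I.
random_rotation <- function(n, sd) {
  if (sd == 0) return(diag(n))
  Q <- qr.Q(qr(diag(n) + matrix(stats::rnorm(n * n, sd = sd), n, n)))
  Q %*% diag(sign(diag(Q)))
}

#' Generate one subject's labeled multimodal recording
#'
#' Concatenates one bout per activity (each sized to hold the requested
#' number of windows, plus one extra window of padding so that resampling
#' edges never eat a labeled window). Channels are generated at
#' `common_rate` from the AR factor model and then decimated to their
#' declared native rates by block averaging, so a round trip through
#' [resample_recording()] reconstructs the multi-rate ingestion path end to
#' end. Reproducible from `seed`.
#'
#' @param config A [benchmark_config()].
#' @param subject Subject id string.
#' @param windows_per_class Windows per activity for this subject; default
#'   the config total divided by `n_subjects`.
#' @param mixing_rotation Optional `n_ch x n_ch` rotation applied to every
#'   activity's mixing matrix (the subject effect); default identity.
#' @param seed Seed for this recording; default derived from the config
#'   seed.
#' @return A labeled [recording()].
#' @export
generate_recording <- function(config, subject = "S1",
                               windows_per_class = NULL,
                               mixing_rotation = NULL, seed = NULL) {
  stopifnot(inherits(config, "benchmark_config"))
  wpc <- windows_per_class %||%
    (config$windows_per_class %/% config$n_subjects)
  seed <- seed %||% config$seed
  rate <- config$common_rate
  n_ch <- length(config$channel_rates)
  R <- mixing_rotation %||% diag(n_ch)
  bout_n <- (wpc + 1L) * config$window_len
  withr::with_seed(as.integer(seed), {
    pieces <- lapply(config$activities, function(act) {
      act_rot <- act
      act_rot$mixing <- R %*% act$mixing
      simulate_bout(act_rot, bout_n)
    })
  })
  X <- do.call(rbind, pieces)
  t_all <- (seq_len(nrow(X)) - 1) / rate
  bounds <- c(0, cumsum(vapply(pieces, nrow, 0L))) / rate
  labels <- tibble::tibble(
    start = bounds[-length(bounds)],
    end = bounds[-1],
    activity = vapply(config$activities, `[[`, "", "name"),
    subject = subject
  )
  chans <- names(config$channel_rates)
  tracks <- lapply(seq_len(n_ch), function(i) {
    native <- config$channel_rates[[i]]
    tr <- signal_track(t_all, X[, i], chans[i], rate = rate)
    if (native < rate) {
      tr <- resample_track(tr, native, "mean_decimate")
    }
    tr
  })
  recording(tracks, labels)
}

#' Build the full labeled image benchmark
#'
#' Runs the whole front half of the method over generated data: per
#' subject, draw a small random rotation of the mixing matrices (the
#' subject effect that makes leave-one-subject-out genuinely harder than
#' k-fold), generate a recording, resample every channel to the common
#' rate, segment into windows, fuse each window's observation matrix into
#' a covariance map, and render the filled-contour image.
#'
#' @param config A [benchmark_config()].
#' @param mode,normalize,levels,size,colormap Fusion/rendering settings.
#' @return A tibble with one row per window: `t_start`, `label`,
#'   `subject`, and list-columns `H`, `C`, `image`. Balanced:
#'   `windows_per_class` rows per activity.
#' @export
make_benchmark <- function(config, mode = "signalwise", normalize = "none",
                           levels = 10, size = c(64, 64),
                           colormap = "viridis") {
  stopifnot(inherits(config, "benchmark_config"))
  n_ch <- length(config$channel_rates)
  wpc <- config$windows_per_class %/% config$n_subjects
  sub_seeds <- withr::with_seed(config$seed,
                                sample.int(.Machine$integer.max %/% 2,
                                           2 * config$n_subjects))
  per_subject <- lapply(seq_len(config$n_subjects), function(s) {
    Rot <- withr::with_seed(sub_seeds[s],
                            random_rotation(n_ch, config$subject_sd))
    rec <- generate_recording(
      config, subject = sprintf("S%02d", s), windows_per_class = wpc,
      mixing_rotation = Rot, seed = sub_seeds[config$n_subjects + s]
    )
    rec <- resample_recording(rec, config$common_rate)
    w <- segment_windows(rec, config$window_len)
    # balance: keep exactly wpc windows per class, earliest first
    w |>
      dplyr::group_by(.data$label) |>
      dplyr::slice_head(n = wpc) |>
      dplyr::ungroup()
  })
  windows <- dplyr::bind_rows(per_subject)
  windows |>
    fuse_windows(mode = mode, normalize = normalize) |>
    render_windows(levels = levels, size = size, colormap = colormap)
}

#' Write a benchmark recording set in the long-CSV dialect
#'
#' Materializes one generated recording per subject as
#' `subject_<id>.csv` / `subject_<id>_labels.csv` pairs consumable by
#' [read_recording()] unchanged.
#'
#' @param config A [benchmark_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written signal CSV paths.
#' @export
write_benchmark_csv <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_ch <- length(config$channel_rates)
  wpc <- config$windows_per_class %/% config$n_subjects
  sub_seeds <- withr::with_seed(config$seed,
                                sample.int(.Machine$integer.max %/% 2,
                                           2 * config$n_subjects))
  paths <- vapply(seq_len(config$n_subjects), function(s) {
    Rot <- withr::with_seed(sub_seeds[s],
                            random_rotation(n_ch, config$subject_sd))
    rec <- generate_recording(
      config, subject = sprintf("S%02d", s), windows_per_class = wpc,
      mixing_rotation = Rot, seed = sub_seeds[config$n_subjects + s]
    )
    write_recording(rec, file.path(dir, sprintf("subject_S%02d.csv", s)))
  }, character(1))
  invisible(paths)
}
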