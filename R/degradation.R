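#' Missing-data degradation experiment
#'
#' Quantifies how classifier performance decays as observation matrices
#' lose entries, and how much a moving-median repair recovers. For each
#' missingness rate the windows' observation matrices receive MCAR `NA`
#' markers ([inject_missing()]), are repaired per channel column
#' ([impute_matrix()]: `"moving_median"`, or `"none"` meaning zero fill),
#' re-fused and re-rendered with the same contour settings, and re-scored
#' under the same cross-validation folds. By default the model is *fixed*:
#' each fold trains on clean images and is scored on the degraded copies of
#' its held-out windows, isolating the effect of corruption at inference
#' time; `retrain = TRUE` instead trains each fold on equally degraded
#' images.
#'
#' @param windows Window table from [segment_windows()] (list-column `H`,
#'   columns `label` and, for LOSO, `subject`).
#' @param pipeline A `cf_pipeline` ([svm_pipeline()], [cnn_pipeline()]).
#' @param scheme A `cv_scheme`; the folds are identical across rates.
#' @param rates Fractions of entries to drop; must include 0 (the
#'   baseline).
#' @param impute `"none"` or `"moving_median"`.
#' @param median_window Moving-median window length in samples.
#' @param seed Integer seed for the MCAR draws (one derived seed per
#'   window, shared across rates).
#' @param retrain Retrain on degraded images instead of the fixed-model
#'   protocol.
#' @param mode,normalize,levels,size,colormap Fusion and rendering settings
#'   (see [fuse_windows()], [render_contour()]).
#' @return A tibble of class `degradation_table`: columns `rate`, `metric`,
#'   `value` (the full [metric_battery()] per rate, long format).
#' @export
degradation_experiment <- function(windows, pipeline, scheme, rates,
                                   impute = c("none", "moving_median"),
                                   median_window = 20, seed = 1L,
                                   retrain = FALSE,
                                   mode = "signalwise", normalize = "none",
                                   levels = 10, size = c(64, 64),
                                   colormap = "viridis") {
  impute <- match.arg(impute)
  if (!any(rates == 0)) rlang::abort("rates must include 0 as the baseline")
  n <- nrow(windows)
  win_seeds <- withr::with_seed(as.integer(seed),
                                sample.int(.Machine$integer.max %/% 2, n))
  render1 <- function(tbl) {
    render_windows(fuse_windows(tbl, mode = mode, normalize = normalize),
                   levels = levels, size = size, colormap = colormap)
  }
  clean <- render1(windows)
  out <- lapply(sort(rates), function(r) {
    if (r == 0) {
      degr <- clean
    } else {
      degr <- windows
      degr$H <- purrr::map2(windows$H, win_seeds, function(H, s) {
        impute_matrix(inject_missing(H, r, seed = s),
                      method = impute, window = median_window)
      })
      degr <- render1(degr)
    }
    cv <- if (retrain) {
      crossvalidate(degr, pipeline, scheme)
    } else {
      crossvalidate(clean, pipeline, scheme, test_data = degr)
    }
    rep <- cv_metrics(cv)
    tibble::tibble(rate = r, metric = rep$metric, value = rep$value)
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("degradation_table", class(out))
  out
}

#' Spread a degradation table into the one-column-per-rate layout
#'
#' @param x A `degradation_table`.
#' @return A tibble with one row per metric and one column per rate.
#' @export
degradation_wide <- function(x) {
  tidyr::pivot_wider(tibble::as_tibble(x), names_from = "rate",
                     values_from = "value", names_prefix = "rate_")
}
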