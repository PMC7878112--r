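# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: covariance by an explicit double loop over the
# defining sum, one-vs-rest pooling by enumerating every binarization.

cov_bruteforce <- function(H) {
  m <- nrow(H); n <- ncol(H)
  mu <- colMeans(H)
  C <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s <- 0
      for (k in seq_len(m)) s <- s + (H[k, i] - mu[i]) * (H[k, j] - mu[j])
      C[i, j] <- s / (m - 1)
    }
  }
  C
}

ovr_counts_bruteforce <- function(y_true, y_pred) {
  classes <- sort(unique(c(y_true, y_pred)))
  tot <- c(TP = 0, FP = 0, FN = 0, TN = 0)
  for (cl in classes) {
    t <- y_true == cl; p <- y_pred == cl
    tot <- tot + c(TP = sum(t & p), FP = sum(!t & p),
                   FN = sum(t & !p), TN = sum(!t & !p))
  }
  tot
}

# Tiny labeled two-channel recording on a 1 Hz grid, for windowing tests.
toy_recording <- function(n = 1000, label_change = NULL, rate = 1) {
  t <- (seq_len(n) - 1) / rate
  tr1 <- signal_track(t, sin(t / 7), "a", rate = rate)
  tr2 <- signal_track(t, cos(t / 5), "b", rate = rate)
  labs <- if (is.null(label_change)) {
    data.frame(start = 0, end = n / rate, activity = "A", subject = "S1")
  } else {
    data.frame(start = c(0, label_change / rate),
               end = c(label_change / rate, n / rate),
               activity = c("A", "B"), subject = "S1")
  }
  recording(list(tr1, tr2), labs)
}

# A deliberately easy, tiny image benchmark for classifier plumbing tests.
toy_images <- function(n_per_class = 4, size = 16, seed = 42) {
  withr::with_seed(seed, {
    imgs <- list(); labs <- character(0)
    for (cl in 1:3) {
      for (i in seq_len(n_per_class)) {
        H <- matrix(rnorm(30 * 6), 30, 6)
        H[, cl] <- H[, cl] + 3 * H[, cl %% 6 + 1]   # class-specific coupling
        imgs <- c(imgs, list(render_contour(cov_signalwise(H), 10,
                                            c(size, size))))
        labs <- c(labs, paste0("c", cl))
      }
    }
    list(images = imgs, labels = labs)
  })
}
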