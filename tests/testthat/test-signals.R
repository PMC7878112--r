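test_that("long-CSV round trip preserves tracks and labels", {
  rec <- toy_recording(50)
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- read_recording(path, "long_csv",
                         labels = sub("\\.csv$", "_labels.csv", path))
  expect_identical(channels(back), channels(rec))
  for (ch in channels(rec)) {
    expect_equal(back$tracks[[ch]]$time, rec$tracks[[ch]]$time)
    expect_equal(back$tracks[[ch]]$value, rec$tracks[[ch]]$value)
  }
  expect_equal(as.data.frame(back$labels), as.data.frame(rec$labels))
})

test_that("non-monotone and duplicate timestamps are sorted and collapsed", {
  # hand-sorted oracle: times 1,2,3,4,5 with the two t=2 rows averaged
  tr <- signal_track(c(3, 1, 2, 2, 5, 4), c(30, 10, 20, 40, 50, 41), "x")
  expect_equal(tr$time, c(1, 2, 3, 4, 5))
  expect_equal(tr$value, c(10, 30, 30, 41, 50))
})

test_that("empatica dialect splits ACC into axes and shifts sessions to 0", {
  dir <- withr::local_tempdir()
  writeLines(c("1600000000,1600000000,1600000000", "32,32,32",
               "1,4,7", "2,5,8", "3,6,9"), file.path(dir, "ACC.csv"))
  writeLines(c("1600000002", "4", "0.5", "0.6", "0.7"),
             file.path(dir, "EDA.csv"))
  writeLines(c("1600000001", "0.5,0.8", "1.4,0.9"),
             file.path(dir, "IBI.csv"))
  rec <- read_recording(dir, "empatica")
  expect_setequal(channels(rec), c("ACC_x", "ACC_y", "ACC_z", "EDA", "IBI"))
  expect_equal(rec$tracks$ACC_x$value, c(1, 2, 3))
  expect_equal(rec$tracks$ACC_y$value, c(4, 5, 6))
  expect_equal(rec$tracks$ACC_z$time, c(0, 1, 2) / 32)
  expect_true(is.na(track_rate(rec$tracks$IBI)))
  # sessions start 0, 1 and 2 s after the earliest one
  expect_equal(rec$tracks$EDA$time[1], 2)
  expect_equal(rec$tracks$IBI$time, c(0.5, 1.4) + 1)
  expect_error(read_recording(withr::local_tempdir(), "empatica"),
               "no Empatica channel files")
})

test_that("garbled empatica headers raise errors naming the file", {
  dir <- withr::local_tempdir()
  writeLines(c("not_a_number", "4", "1"), file.path(dir, "EDA.csv"))
  expect_error(read_recording(dir, "empatica"), "EDA\\.csv.*garbled")
})

test_that("linear resampling matches closed-form interpolation", {
  tr <- signal_track(c(0, 1), c(0, 8), "x", rate = 1)
  out <- resample_track(tr, 4, "linear")
  expect_equal(out$value, c(0, 2, 4, 6, 8))
  expect_equal(out$time, c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(track_rate(out), 4)
})

test_that("constants are fixed points and same-rate resampling is identity", {
  tr_const <- signal_track((0:39) / 4, rep(2.5, 40), "c", rate = 4)
  up <- resample_track(tr_const, 64, "linear")
  expect_true(all(up$value == 2.5))
  tr64 <- signal_track((0:99) / 64, rnorm(100), "b", rate = 64)
  expect_equal(resample_track(tr64, 64, "linear")$value, tr64$value)
})

test_that("linear resampling never overshoots the observed range", {
  withr::with_seed(3, {
    for (i in 1:10) {
      tr <- signal_track(sort(runif(30, 0, 10)), rnorm(30), "x")
      out <- resample_track(tr, 7, "linear")
      expect_gte(min(out$value), min(tr$value))
      expect_lte(max(out$value), max(tr$value))
    }
  })
})

test_that("hold carries the last sample and decimation refuses upsampling", {
  tr <- signal_track(c(0, 1, 2), c(1, 5, 9), "hr")
  expect_equal(resample_track(tr, 2, "hold")$value, c(1, 1, 5, 5, 9))
  expect_error(resample_track(tr, 4, "mean_decimate"), "mean_decimate")
  expect_error(resample_track(signal_track(0, 1, "x"), 4, "linear"),
               "< 2 samples")
})

test_that("missing markers propagate through resampling untouched", {
  tr <- signal_track(0:4, c(1, NA, 3, 4, 5), "x", rate = 1)
  up <- resample_track(tr, 2, "linear")
  # outputs bracketed by the NA sample are NA; others interpolate
  expect_true(is.na(up$value[2]) && is.na(up$value[3]) && is.na(up$value[4]))
  expect_equal(up$value[c(1, 5, 6, 7)], c(1, 3, 3.5, 4))
  down <- resample_track(signal_track(0:9 / 2, c(NA, 2:10), "y", rate = 2),
                         1, "mean_decimate")
  expect_true(is.na(down$value[1]))
  expect_equal(down$value[2], mean(c(3, 4)))
})

test_that("exact tiling yields floor(len/window) non-overlapping segments", {
  rec <- toy_recording(1000)
  w <- segment_windows(rec, 500, 500)
  expect_equal(nrow(w), 2)
  expect_equal(w$t_start, c(0, 500))
  expect_true(all(vapply(w$H, function(h) all(dim(h) == c(500, 2)), TRUE)))
  expect_identical(colnames(w$H[[1]]), c("a", "b"))
})

test_that("windows straddling a label boundary are discarded", {
  rec <- toy_recording(1000, label_change = 400)
  w <- segment_windows(rec, 500, hop = 100)
  # brute-force enumeration over all candidate starts
  starts <- seq(0, 500, by = 100)
  keep <- vapply(starts, function(s) {
    (s >= 0 && s + 500 <= 400) || (s >= 400 && s + 500 <= 1000)
  }, TRUE)
  expect_equal(w$t_start, starts[keep])
  expect_true(all(w$label == "B"))
  expect_warning(segment_windows(toy_recording(300, label_change = 100), 250),
                 "zero segments")
})

test_that("resample_recording aligns all channels on one grid for 8-wide H", {
  cfg <- default_benchmark(seed = 9, windows_per_class = 5, n_subjects = 1)
  rec <- generate_recording(cfg, windows_per_class = 5)
  rec64 <- resample_recording(rec, cfg$common_rate)
  w <- segment_windows(rec64, 50)
  expect_equal(dim(w$H[[1]]), c(50, 8))
})
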