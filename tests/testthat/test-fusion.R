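test_that("signal-wise covariance matches the defining sum", {
  H <- cbind(c(1, 2, 3), c(2, 4, 6))
  expect_equal(unclass(cov_signalwise(H)), matrix(c(1, 2, 2, 4), 2),
               ignore_attr = TRUE)
  # brute-force double-loop oracle on random matrices
  withr::with_seed(11, {
    for (i in 1:25) {
      m <- sample(3:20, 1); n <- sample(2:12, 1)
      H <- matrix(rnorm(m * n), m, n)
      expect_equal(unclass(cov_signalwise(H)), cov_bruteforce(H),
                   tolerance = 1e-12, ignore_attr = TRUE)
      expect_equal(unclass(cov_samplewise(H)), cov_bruteforce(t(H)),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  })
})

test_that("degenerate columns behave as zero-variance / duplicated signals", {
  H <- cbind(a = rnorm(10), b = rep(3, 10), c = rnorm(10))
  C <- cov_signalwise(H)
  expect_true(all(C[2, ] == 0) && all(C[, 2] == 0))
  H2 <- cbind(H, a2 = H[, "a"])
  C2 <- cov_signalwise(H2)
  expect_equal(C2["a", "a2"], C2["a", "a"])
})

test_that("sample-wise mode is the transpose construction", {
  withr::with_seed(2, H <- matrix(rnorm(24), 6, 4))
  expect_equal(unclass(cov_samplewise(H)), unclass(cov_signalwise(t(H))),
               ignore_attr = TRUE)
  # identical time samples produce identical rows/cols of the map
  H[3, ] <- H[5, ]
  C <- cov_samplewise(H)
  expect_equal(C[3, ], C[5, ], ignore_attr = TRUE)
  expect_equal(dim(cov_samplewise(matrix(rnorm(500 * 8), 500, 8))),
               c(500, 500))
})

test_that("covariance maps are exactly symmetric and almost PSD", {
  withr::with_seed(4, {
    for (i in 1:10) {
      H <- matrix(rnorm(15 * 6), 15, 6)
      C <- cov_signalwise(H)
      expect_identical(max(abs(C - t(C))), 0)
      ev <- eigen(unclass(C), symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(ev), -1e-8 * max(diag(C)))
    }
  })
})

test_that("correlation normalization bounds entries and zeroes 0/0", {
  withr::with_seed(5, H <- matrix(rnorm(40), 10, 4))
  H <- cbind(H, const = rep(1, 10))
  R <- cov_signalwise(H, normalize = "correlation")
  expect_true(all(abs(R) <= 1 + 1e-12))
  expect_true(all(diag(R)[1:4] == 1))
  expect_true(all(R[, 5] == 0) && all(R[5, ] == 0))
  expect_error(cov_signalwise(cbind(c(1, NA, 3), 1:3)), "imputation")
})

test_that("rendering honours size, determinism, and band counts", {
  Cg <- matrix(rep(seq(0, 1, length.out = 20), each = 20), 20, 20)
  img <- render_contour(Cg, levels = 10, size = c(300, 300))
  expect_equal(dim(img), c(300, 300, 3))
  expect_true(all(img >= 0 & img <= 255))
  # strictly monotone gradient with 10 bands -> exactly 10 distinct colors
  cols <- unique(matrix(render_contour(Cg, 10, c(64, 64)), ncol = 3))
  expect_equal(nrow(cols), 10)
  # byte-determinism across repeated calls
  expect_identical(render_contour(Cg, 10, c(64, 64)),
                   render_contour(Cg, 10, c(64, 64)))
  # constant map is a single-colour image, not an error
  const <- render_contour(matrix(5, 4, 4), 10, c(16, 16))
  expect_equal(nrow(unique(matrix(const, ncol = 3))), 1)
  expect_error(render_contour(Cg, levels = 1), "levels")
  expect_error(render_contour(Cg, size = c(4, 4)), "size")
})

test_that("low covariance is dark, high is bright", {
  Cg <- matrix(rep(seq(0, 1, length.out = 16), each = 16), 16, 16)
  img <- unclass(render_contour(Cg, 10, c(32, 32)))
  lum <- apply(img, c(1, 2), mean)
  expect_lt(mean(lum[, 1:3]), mean(lum[, 30:32]))
})

test_that("rescaling the signals leaves the per-image raster unchanged", {
  withr::with_seed(7, H <- matrix(rnorm(200), 20, 10))
  C1 <- cov_signalwise(H); C2 <- cov_signalwise(2 * H)
  expect_equal(unclass(C2), 4 * unclass(C1), ignore_attr = TRUE)
  strip <- function(x) array(unclass(x), dim = dim(x))
  expect_identical(strip(render_contour(C1, 10, c(48, 48))),
                   strip(render_contour(C2, 10, c(48, 48))))
})

test_that("PNG output round-trips the raster losslessly", {
  withr::with_seed(8, img <- render_contour(cov_signalwise(matrix(rnorm(60), 10, 6)),
                                            10, c(32, 32)))
  path <- withr::local_tempfile(fileext = ".png")
  write_contour_png(img, path)
  back <- round(png::readPNG(path) * 255)
  expect_equal(array(back, dim(img)), array(unclass(img), dim(img)))
})

test_that("fixed-range scaling clamps and differs from per-image scaling", {
  withr::with_seed(9, C <- cov_signalwise(matrix(rnorm(80), 20, 4)))
  fixed <- render_contour(C, 10, c(32, 32), scaling = c(-0.5, 0.5))
  expect_equal(attr(fixed, "scaling_range"), c(-0.5, 0.5))
  expect_equal(dim(fixed), c(32, 32, 3))
})
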