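test_that("network shape trace follows the convolution arithmetic", {
  m <- build_residual_cnn(c(64, 64, 3), n_classes = 3)
  tr <- shape_trace(m)
  expect_equal(tr$activations[tr$layer_type == "Image input"], "64 x 64 x 3")
  expect_equal(tr$activations[2], "64 x 64 x 32")
  expect_equal(tr$activations[5], "32 x 32 x 64")
  expect_equal(tr$activations[tr$layer_type == "Addition"], "32 x 32 x 128")
  expect_equal(tr$activations[tr$layer_type == "Max pooling"], "16 x 16 x 128")
  expect_equal(tr$activations[tr$layer_type == "Fully connected"],
               c("1 x 1 x 500", "1 x 1 x 10", "1 x 1 x 3"))
})

test_that("a forward pass reproduces the shape trace and normalizes softmax", {
  m <- covafuse:::init_weights(build_residual_cnn(c(32, 32, 3), 4, seed = 5))
  x <- withr::with_seed(6, array(rnorm(32 * 32 * 3 * 2), c(32, 32, 3, 2)))
  fwd <- covafuse:::cnn_forward(m, x)
  expect_equal(unname(fwd$dims$conv1), c(32, 32, 32))
  expect_equal(unname(fwd$dims$conv2), c(16, 16, 64))
  expect_equal(unname(fwd$dims$addition), c(16, 16, 128))
  expect_equal(unname(fwd$dims$pool), c(8, 8, 128))
  expect_equal(unname(fwd$dims$fc), c(500, 10, 4))
  expect_equal(rowSums(fwd$prob), c(1, 1))
  expect_true(all(fwd$prob > 0))
})

test_that("analytic gradients match central differences through every layer", {
  m <- covafuse:::init_weights(build_residual_cnn(c(8, 8, 3), 3, seed = 2))
  x <- withr::with_seed(10, array(rnorm(8 * 8 * 3 * 4), c(8, 8, 3, 4)))
  y <- diag(3)[c(1, 2, 3, 1), ]
  loss_fn <- function(mm) {
    f <- covafuse:::cnn_forward(mm, x, train = TRUE)
    -mean(log(pmax(rowSums(f$prob * y), 1e-12)))
  }
  fwd <- covafuse:::cnn_forward(m, x, train = TRUE)
  g <- covafuse:::cnn_backward(m, fwd, y)
  eps <- 1e-6
  withr::with_seed(11, {
    for (nm in c("conv1_W", "conv2_W", "conv3_W", "conv4_W", "proj_W",
                 "fc1_W", "fc3_b", "bn1_g", "bn2_b", "bn3_g", "conv2_b")) {
      p <- m$params[[nm]]
      for (i in sample(length(p), 2)) {
        m_hi <- m; m_hi$params[[nm]][i] <- p[i] + eps
        m_lo <- m; m_lo$params[[nm]][i] <- p[i] - eps
        num <- (loss_fn(m_hi) - loss_fn(m_lo)) / (2 * eps)
        # mixed tolerance: central differences carry ~1e-10 absolute noise
        expect_lt(abs(num - g[[nm]][i]), 1e-7 + 1e-5 * abs(g[[nm]][i]))
      }
    }
  })
})

test_that("piecewise schedule drops the rate by the factor every period", {
  p <- train_params()
  expect_equal(learn_rate_at(p, 1), 0.001)
  expect_equal(learn_rate_at(p, 2), 0.001)
  expect_equal(learn_rate_at(p, 3), 1e-4)
  expect_equal(learn_rate_at(p, 5), 1e-5)
  p2 <- train_params(initial_lr = 0.01, drop_factor = 0.5, drop_period = 3)
  expect_equal(learn_rate_at(p2, 7), 0.01 * 0.25)
})

test_that("training is seed-deterministic, shuffles epochs, and learns a toy set", {
  toy <- toy_images(n_per_class = 3, size = 16)
  pars <- train_params(batch_size = 3, epochs = 4, validation_split = 0,
                       seed = 3)
  fit1 <- train_cnn(build_residual_cnn(c(16, 16, 3), 3, seed = 3),
                    toy$images, toy$labels, pars)
  fit2 <- train_cnn(build_residual_cnn(c(16, 16, 3), 3, seed = 3),
                    toy$images, toy$labels, pars)
  expect_identical(fit1$history, fit2$history)
  h <- fit1$epoch_history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  expect_error(train_cnn(build_residual_cnn(c(16, 16, 3), 2),
                         toy$images[1:3], rep("a", 3)), "two classes")
  expect_error(train_cnn(build_residual_cnn(c(8, 8, 3), 3),
                         toy$images, toy$labels), "does not match")
})

test_that("feature extraction honours the backbone contract", {
  toy <- toy_images(n_per_class = 2, size = 16)
  X <- extract_features(toy$images, featurizer_pool(4))
  expect_equal(dim(X), c(6, 48))
  expect_equal(attr(X, "backbone"), "pool4")
  # identical images give identical rows
  X2 <- extract_features(list(toy$images[[1]], toy$images[[1]]))
  expect_equal(X2[1, ], X2[2, ])
  Xh <- extract_features(toy$images, featurizer_hist(8))
  expect_equal(dim(Xh), c(6, 24))
  expect_equal(unname(rowSums(Xh)), rep(3, 6))
  ragged <- function(img) rnorm(sample(3:4, 1))
  expect_error(extract_features(toy$images, ragged), "ragged")
})

test_that("same-class contour images lie closer in feature space", {
  toy <- toy_images(n_per_class = 6, size = 32)
  X <- extract_features(toy$images, featurizer_pool(8))
  D <- as.matrix(dist(X))
  same <- outer(toy$labels, toy$labels, "==") & upper.tri(D)
  diff <- outer(toy$labels, toy$labels, "!=") & upper.tri(D)
  expect_lt(mean(D[same]), mean(D[diff]))
})

test_that("k-fold partitions and LOSO folds satisfy the CV contracts", {
  folds <- covafuse:::cv_folds(cv_kfold(5, seed = 2), 100)
  expect_equal(sort(unname(unlist(folds))), 1:100)
  expect_true(all(lengths(folds) == 20))
  subj <- rep(sprintf("S%02d", 1:10), each = 6)
  lfolds <- covafuse:::cv_folds(cv_loso(), 60, subj)
  expect_equal(length(lfolds), 10)
  expect_true(all(lengths(lfolds) == 6))
  expect_error(covafuse:::cv_folds(cv_loso(), 60, NULL), "subject")
  expect_error(covafuse:::cv_folds(cv_loso(), 6, rep("a", 6)), "two subjects")
})

test_that("cross-validation predicts every sample once and pools counts", {
  toy <- toy_images(n_per_class = 5, size = 16)
  data <- tibble::tibble(image = toy$images, label = toy$labels,
                         subject = rep(sprintf("S%d", 1:5), 3))
  cv <- crossvalidate(data, svm_pipeline(featurizer_pool(4)), cv_kfold(5, 1))
  expect_equal(sort(cv$predictions$row), 1:15)
  expect_equal(unname(rowSums(cv$confusion)), as.vector(table(toy$labels)))
  expect_equal(sum(cv$confusion), 15)
  g <- glance(cv)
  expect_equal(g$n, 15)
  expect_equal(g$scheme, "kfold")
  expect_s3_class(tidy(cv), "tbl_df")
  lcv <- crossvalidate(data, svm_pipeline(featurizer_pool(4)), cv_loso())
  expect_equal(length(unique(lcv$predictions$fold)), 5)
})

test_that("single-class training folds are skipped with a warning", {
  toy <- toy_images(n_per_class = 2, size = 16)
  data <- tibble::tibble(
    image = toy$images[c(1, 2, 3, 4)],
    label = c("c1", "c1", "c2", "c2"),
    subject = c("A", "A", "B", "B")
  )
  expect_warning(cv <- crossvalidate(data, svm_pipeline(featurizer_pool(4)),
                                     cv_loso()),
                 "single-class")
  expect_lt(nrow(cv$predictions), 4)
})
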