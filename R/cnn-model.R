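#' Build the residual image classifier
#'
#' Constructs the small deep residual network used for contour-image
#' classification: four 3x3 'same'-padded convolutions (32 filters stride 1;
#' 64 filters stride 2; 128 filters stride 1; 128 filters stride 1), the
#' first three each followed by batch normalization and ReLU, a shortcut
#' that carries the first ReLU's output through a 1x1 stride-2 projection
#' convolution and is added to the fourth convolution's output, then 2x2
#' max pooling (stride 2) and fully connected layers of width 500, 10 and
#' `n_classes` feeding a softmax. With the default 300 x 300 x 3 input the
#' per-layer activation shapes are 300x300x32, 150x150x64, 150x150x128,
#' 150x150x128 (addition), 75x75x128 (pooling), then 1x1x500, 1x1x10,
#' 1x1x`n_classes`.
#'
#' Weights are materialized lazily (He-normal from `seed`) on the first
#' forward/training call, so building and shape-tracing the network is cheap
#' even for the full-size input, whose first fully connected layer alone
#' holds 360M parameters.
#'
#' @param input_shape `c(height, width, channels)`; default `c(300, 300, 3)`.
#' @param n_classes Number of output classes (>= 2).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `residual_cnn` holding the architecture, a
#'   shape trace (see [shape_trace()]), and (once materialized) the weights.
#' @export
build_residual_cnn <- function(input_shape = c(300, 300, 3), n_classes = 3,
                               seed = 1L) {
  stopifnot(length(input_shape) == 3, n_classes >= 2)
  arch <- list(
    conv1 = list(k = 3L, stride = 1L, c_out = 32L),
    conv2 = list(k = 3L, stride = 2L, c_out = 64L),
    conv3 = list(k = 3L, stride = 1L, c_out = 128L),
    conv4 = list(k = 3L, stride = 1L, c_out = 128L),
    proj = list(k = 1L, stride = 2L, c_out = 128L),
    fc = c(500L, 10L, as.integer(n_classes))
  )
  model <- structure(
    list(input_shape = as.integer(input_shape),
         n_classes = as.integer(n_classes),
         arch = arch, seed = as.integer(seed),
         params = NULL, bn = NULL),
    class = "residual_cnn"
  )
  tr <- shape_trace(model)
  add_row <- tr$activations[tr$layer_type == "Addition"]
  branch_row <- tr$activations[tr$number == 11L]
  if (!identical(add_row, branch_row)) {
    rlang::abort(sprintf(
      "residual addition shape mismatch: branch %s vs shortcut %s",
      branch_row, add_row
    ))
  }
  model$trace <- tr
  model
}

#' Per-layer activation shapes of the residual network
#'
#' Computes the activation shape after every layer from the convolution
#' arithmetic ('same' padding: output extent `ceil(len/stride)`; 2x2 pooling
#' halves both spatial extents), without materializing any weights. The
#' result is the network's shape contract; a forward pass over data
#' reproduces exactly these shapes (checked in the test suite).
#'
#' @param model A [build_residual_cnn()] model.
#' @return A tibble with columns `number`, `layer_type`, `activations`
#'   (string `"H x W x C"`).
#' @export
shape_trace <- function(model) {
  s <- model$input_shape
  a <- model$arch
  dims <- function(h, w, c) sprintf("%d x %d x %d", h, w, c)
  h <- s[1]; w <- s[2]
  rows <- list(c("Image input", dims(h, w, s[3])))
  h1 <- conv_out_len(h, 1); w1 <- conv_out_len(w, 1)
  rows <- c(rows, rep(list(NULL), 0))
  out <- list(
    c("Convolution", dims(h1, w1, a$conv1$c_out)),
    c("Batch normalization", dims(h1, w1, a$conv1$c_out)),
    c("ReLU", dims(h1, w1, a$conv1$c_out))
  )
  h2 <- conv_out_len(h1, 2); w2 <- conv_out_len(w1, 2)
  out <- c(out, list(
    c("Convolution", dims(h2, w2, a$conv2$c_out)),
    c("Batch normalization", dims(h2, w2, a$conv2$c_out)),
    c("ReLU", dims(h2, w2, a$conv2$c_out)),
    c("Convolution", dims(h2, w2, a$conv3$c_out)),
    c("Batch normalization", dims(h2, w2, a$conv3$c_out)),
    c("ReLU", dims(h2, w2, a$conv3$c_out)),
    c("Convolution", dims(h2, w2, a$conv4$c_out)),
    c("Addition", dims(h2, w2, a$conv4$c_out))
  ))
  hp <- h2 %/% 2L; wp <- w2 %/% 2L
  out <- c(out, list(c("Max pooling", dims(hp, wp, a$conv4$c_out))))
  for (width in a$fc) {
    out <- c(out, list(c("Fully connected", dims(1L, 1L, width))))
  }
  out <- c(out, list(c("Softmax", dims(1L, 1L, a$fc[3])),
                     c("Classification output", NA_character_)))
  all_rows <- c(rows, out)
  tibble::tibble(
    number = seq_along(all_rows),
    layer_type = vapply(all_rows, `[`, character(1), 1),
    activations = vapply(all_rows, `[`, character(1), 2)
  )
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

# Materialize weights and batch-norm state on first use.
init_weights <- function(model) {
  if (!is.null(model$params)) return(model)
  a <- model$arch
  c_in <- model$input_shape[3]
  tr2 <- conv_out_len(model$input_shape[1], 2) %/% 2L
  tc2 <- conv_out_len(model$input_shape[2], 2) %/% 2L
  n_flat <- tr2 * tc2 * a$conv4$c_out
  withr::with_seed(model$seed, {
    p <- list(
      conv1_W = he_init(c(3, 3, c_in, 32), 9 * c_in), conv1_b = numeric(32),
      conv2_W = he_init(c(3, 3, 32, 64), 9 * 32), conv2_b = numeric(64),
      conv3_W = he_init(c(3, 3, 64, 128), 9 * 64), conv3_b = numeric(128),
      conv4_W = he_init(c(3, 3, 128, 128), 9 * 128), conv4_b = numeric(128),
      proj_W = he_init(c(1, 1, 32, 128), 32), proj_b = numeric(128),
      fc1_W = he_init(c(n_flat, 500), n_flat), fc1_b = numeric(500),
      fc2_W = he_init(c(500, 10), 500), fc2_b = numeric(10),
      fc3_W = he_init(c(10, model$n_classes), 10),
      fc3_b = numeric(model$n_classes),
      bn1_g = rep(1, 32), bn1_b = numeric(32),
      bn2_g = rep(1, 64), bn2_b = numeric(64),
      bn3_g = rep(1, 128), bn3_b = numeric(128)
    )
  })
  model$params <- p
  model$bn <- list(
    bn1 = list(mean = numeric(32), var = rep(1, 32)),
    bn2 = list(mean = numeric(64), var = rep(1, 64)),
    bn3 = list(mean = numeric(128), var = rep(1, 128))
  )
  model
}

# Full forward pass on a (H, W, C, B) batch. Returns logits, probabilities,
# per-layer activation dims, and (in training mode) every cache needed for
# backprop plus updated batch-norm running statistics.
cnn_forward <- function(model, x, train = FALSE) {
  p <- model$params
  a <- model$arch
  cache <- list()
  dims <- list(input = dim(x)[1:3])

  c1 <- conv_forward(x, p$conv1_W, p$conv1_b, 1L)
  b1 <- bn_forward(c1$out, p$bn1_g, p$bn1_b, model$bn$bn1, train)
  r1 <- relu_forward(b1$out)
  dims$conv1 <- dim(c1$out)[1:3]

  c2 <- conv_forward(r1$out, p$conv2_W, p$conv2_b, 2L)
  b2 <- bn_forward(c2$out, p$bn2_g, p$bn2_b, model$bn$bn2, train)
  r2 <- relu_forward(b2$out)
  dims$conv2 <- dim(c2$out)[1:3]

  c3 <- conv_forward(r2$out, p$conv3_W, p$conv3_b, 1L)
  b3 <- bn_forward(c3$out, p$bn3_g, p$bn3_b, model$bn$bn3, train)
  r3 <- relu_forward(b3$out)
  dims$conv3 <- dim(c3$out)[1:3]

  c4 <- conv_forward(r3$out, p$conv4_W, p$conv4_b, 1L)
  sc <- conv_forward(r1$out, p$proj_W, p$proj_b, 2L)
  if (!identical(dim(c4$out), dim(sc$out))) {
    rlang::abort("Addition layer: branch and shortcut shapes differ")
  }
  add <- c4$out + sc$out
  dims$conv4 <- dim(c4$out)[1:3]
  dims$addition <- dim(add)[1:3]

  pl <- maxpool_forward(add)
  dims$pool <- dim(pl$out)[1:3]

  B <- dim(x)[4]
  flat <- matrix(aperm(pl$out, c(4, 1, 2, 3)), nrow = B)
  f1 <- fc_forward(flat, p$fc1_W, p$fc1_b)
  f2 <- fc_forward(f1$out, p$fc2_W, p$fc2_b)
  f3 <- fc_forward(f2$out, p$fc3_W, p$fc3_b)
  prob <- softmax_rows(f3$out)
  dims$fc <- c(ncol(f1$out), ncol(f2$out), ncol(f3$out))

  bn_new <- if (train) list(bn1 = b1$running, bn2 = b2$running,
                            bn3 = b3$running) else model$bn
  list(logits = f3$out, prob = prob, dims = dims, bn = bn_new,
       cache = if (train) list(c1 = c1, b1 = b1, r1 = r1, c2 = c2, b2 = b2,
                               r2 = r2, c3 = c3, b3 = b3, r3 = r3, c4 = c4,
                               sc = sc, pl = pl, f1 = f1, f2 = f2, f3 = f3,
                               pool_dim = dim(pl$out)) else NULL)
}

cnn_backward <- function(model, fwd, y_onehot) {
  p <- model$params
  ch <- fwd$cache
  B <- nrow(y_onehot)
  g <- list()

  dlogits <- (fwd$prob - y_onehot) / B
  gf3 <- fc_backward(dlogits, ch$f3, p$fc3_W)
  g$fc3_W <- gf3$dW; g$fc3_b <- gf3$db
  gf2 <- fc_backward(gf3$dx, ch$f2, p$fc2_W)
  g$fc2_W <- gf2$dW; g$fc2_b <- gf2$db
  gf1 <- fc_backward(gf2$dx, ch$f1, p$fc1_W)
  g$fc1_W <- gf1$dW; g$fc1_b <- gf1$db

  pd <- ch$pool_dim
  dpool <- aperm(array(gf1$dx, dim = c(B, pd[1], pd[2], pd[3])),
                 c(2, 3, 4, 1))
  dadd <- maxpool_backward(dpool, ch$pl)

  gc4 <- conv_backward(dadd, ch$c4, p$conv4_W)
  g$conv4_W <- gc4$dW; g$conv4_b <- gc4$db
  gsc <- conv_backward(dadd, ch$sc, p$proj_W)
  g$proj_W <- gsc$dW; g$proj_b <- gsc$db

  dr3 <- relu_backward(gc4$dx, ch$r3)
  gb3 <- bn_backward(dr3, ch$b3, p$bn3_g)
  g$bn3_g <- gb3$dgamma; g$bn3_b <- gb3$dbeta
  gc3 <- conv_backward(gb3$dx, ch$c3, p$conv3_W)
  g$conv3_W <- gc3$dW; g$conv3_b <- gc3$db

  dr2 <- relu_backward(gc3$dx, ch$r2)
  gb2 <- bn_backward(dr2, ch$b2, p$bn2_g)
  g$bn2_g <- gb2$dgamma; g$bn2_b <- gb2$dbeta
  gc2 <- conv_backward(gb2$dx, ch$c2, p$conv2_W)
  g$conv2_W <- gc2$dW; g$conv2_b <- gc2$db

  dr1 <- relu_backward(gc2$dx + gsc$dx, ch$r1)
  gb1 <- bn_backward(dr1, ch$b1, p$bn1_g)
  g$bn1_g <- gb1$dgamma; g$bn1_b <- gb1$dbeta
  gc1 <- conv_backward(gb1$dx, ch$c1, p$conv1_W)
  g$conv1_W <- gc1$dW; g$conv1_b <- gc1$db

  g
}

#' @export
print.residual_cnn <- function(x, ...) {
  cat(sprintf(
    "<residual_cnn> input %s, %d classes, weights %s\n",
    paste(x$input_shape, collapse = " x "), x$n_classes,
    if (is.null(x$params)) "not yet materialized" else "materialized"
  ))
  print(x$trace, n = Inf)
  invisible(x)
}
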