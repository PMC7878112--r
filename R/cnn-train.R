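#' Training parameters for the residual network
#'
#' Bundles the optimization settings with their defaults: initial learning
#' rate 0.001 on a piecewise schedule that multiplies the rate by
#' `drop_factor` (0.1) every `drop_period` (2) epochs, mini-batch size 100,
#' 10 epochs, data shuffled before every epoch, and a 70/30 train/validation
#' split stratified by label. Stochastic gradient descent uses momentum 0.9
#' (the customary companion of this schedule; set `momentum = 0` for plain
#' SGD). Any override is recorded verbatim in the fitted model's metadata.
#'
#' @param initial_lr Initial learning rate.
#' @param drop_factor Multiplier applied to the rate at each drop.
#' @param drop_period Number of epochs between drops.
#' @param batch_size Mini-batch size (clamped to the training-set size).
#' @param epochs Maximum number of epochs.
#' @param momentum SGD momentum coefficient.
#' @param shuffle Reshuffle the training data before every epoch.
#' @param validation_split Fraction held out for validation, stratified by
#'   label; 0 trains on everything.
#' @param grad_clip Global L2-norm gradient clipping threshold (`Inf`
#'   disables); small mini-batches with momentum are otherwise prone to an
#'   early divergence.
#' @param seed Integer seed controlling the split, shuffling and weight
#'   initialization.
#' @return A list of class `train_params`.
#' @export
train_params <- function(initial_lr = 0.001, drop_factor = 0.1,
                         drop_period = 2, batch_size = 100, epochs = 10,
                         momentum = 0.9, shuffle = TRUE,
                         validation_split = 0.3, grad_clip = 5,
                         seed = 1L) {
  structure(
    list(initial_lr = initial_lr, drop_factor = drop_factor,
         drop_period = drop_period, batch_size = batch_size,
         epochs = epochs, momentum = momentum, shuffle = shuffle,
         validation_split = validation_split, grad_clip = grad_clip,
         seed = as.integer(seed)),
    class = "train_params"
  )
}

#' Learning rate under the piecewise schedule
#'
#' `initial_lr * drop_factor^floor((epoch - 1) / drop_period)`; with the
#' defaults, epoch 5 trains at `0.001 * 0.1^2 = 1e-5`.
#'
#' @param params A [train_params()].
#' @param epoch Epoch number (1-based).
#' @return The learning rate in effect during `epoch`.
#' @export
learn_rate_at <- function(params, epoch) {
  params$initial_lr * params$drop_factor^floor((epoch - 1) / params$drop_period)
}

# Convert contour images (integer 0..255 rasters) to a (H, W, C, B) batch
# of doubles centred on zero.
images_to_batch <- function(images) {
  d <- dim(images[[1]])
  x <- array(0, dim = c(d, length(images)))
  for (i in seq_along(images)) x[, , , i] <- unclass(images[[i]]) / 255 - 0.5
  x
}

#' Train the residual network on labeled contour images
#'
#' Stochastic gradient descent with momentum under the piecewise
#' learning-rate schedule of [train_params()]. The history records, per
#' iteration, the epoch, learning rate, mini-batch loss and accuracy, and,
#' per epoch, loss and accuracy on the training and (when a split is held
#' out) validation sets — the curves one plots to judge convergence.
#'
#' @param model A [build_residual_cnn()] whose input shape matches the
#'   images.
#' @param images List of `contour_image` rasters (or `HxWx3` arrays).
#' @param labels Factor (or coercible) of activity labels, one per image;
#'   at least two classes must be present.
#' @param params A [train_params()].
#' @return An object of class `cnn_fit`: the trained model plus `history`
#'   (per-iteration tibble), `epoch_history`, `classes`, and the resolved
#'   `params`.
#' @export
train_cnn <- function(model, images, labels, params = train_params()) {
  stopifnot(inherits(model, "residual_cnn"))
  labels <- factor(labels)
  if (nlevels(labels) < 2) {
    rlang::abort("training requires at least two classes")
  }
  if (nlevels(labels) != model$n_classes) {
    rlang::abort(sprintf("model expects %d classes but labels have %d levels",
                         model$n_classes, nlevels(labels)))
  }
  d1 <- dim(images[[1]])
  if (!identical(as.integer(d1), model$input_shape)) {
    rlang::abort(sprintf("image shape %s does not match model input %s",
                         paste(d1, collapse = "x"),
                         paste(model$input_shape, collapse = "x")))
  }
  n <- length(images)
  model <- init_weights(model)

  split <- withr::with_seed(params$seed, {
    if (params$validation_split > 0) {
      val <- unlist(lapply(split(seq_len(n), labels), function(ix) {
        sample(ix, max(1, round(length(ix) * params$validation_split)))
      }), use.names = FALSE)
      list(train = setdiff(seq_len(n), val), val = sort(val))
    } else {
      list(train = seq_len(n), val = integer())
    }
  })
  x_all <- images_to_batch(images)
  y_int <- as.integer(labels)
  onehot <- diag(model$n_classes)[y_int, , drop = FALSE]

  vel <- lapply(model$params, function(p) p * 0)
  hist_rows <- list()
  epoch_rows <- list()
  bs <- min(params$batch_size, length(split$train))
  it <- 0L

  order_seed <- withr::with_seed(params$seed,
                                 sample.int(.Machine$integer.max %/% 2,
                                            params$epochs))
  for (epoch in seq_len(params$epochs)) {
    lr <- learn_rate_at(params, epoch)
    idx <- split$train
    if (params$shuffle) {
      idx <- withr::with_seed(order_seed[epoch], sample(idx))
    }
    batches <- split(idx, ceiling(seq_along(idx) / bs))
    for (b in batches) {
      it <- it + 1L
      xb <- x_all[, , , b, drop = FALSE]
      fwd <- cnn_forward(model, xb, train = TRUE)
      model$bn <- fwd$bn
      yb <- onehot[b, , drop = FALSE]
      loss <- -mean(log(pmax(rowSums(fwd$prob * yb), 1e-12)))
      acc <- mean(max.col(fwd$prob) == y_int[b])
      grads <- cnn_backward(model, fwd, yb)
      if (is.finite(params$grad_clip)) {
        gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
        if (gn > params$grad_clip) {
          grads <- lapply(grads, `*`, params$grad_clip / gn)
        }
      }
      for (nm in names(grads)) {
        vel[[nm]] <- params$momentum * vel[[nm]] - lr * grads[[nm]]
        model$params[[nm]] <- model$params[[nm]] + vel[[nm]]
      }
      hist_rows[[it]] <- tibble::tibble(
        iteration = it, epoch = epoch, learn_rate = lr,
        batch_loss = loss, batch_accuracy = acc
      )
    }
    tr_eval <- evaluate_batch(model, x_all, y_int, split$train)
    va_eval <- evaluate_batch(model, x_all, y_int, split$val)
    epoch_rows[[epoch]] <- tibble::tibble(
      epoch = epoch, learn_rate = lr,
      train_loss = tr_eval$loss, train_accuracy = tr_eval$accuracy,
      val_loss = va_eval$loss, val_accuracy = va_eval$accuracy
    )
  }
  structure(
    list(model = model, classes = levels(labels),
         history = dplyr::bind_rows(hist_rows),
         epoch_history = dplyr::bind_rows(epoch_rows),
         split = split, params = params),
    class = "cnn_fit"
  )
}

# Inference-mode loss/accuracy over an index set, in chunks to bound memory.
evaluate_batch <- function(model, x_all, y_int, idx, chunk = 16L) {
  if (length(idx) == 0) return(list(loss = NA_real_, accuracy = NA_real_))
  losses <- numeric(0); hits <- logical(0)
  for (part in split(idx, ceiling(seq_along(idx) / chunk))) {
    fwd <- cnn_forward(model, x_all[, , , part, drop = FALSE], train = FALSE)
    p_true <- fwd$prob[cbind(seq_along(part), y_int[part])]
    losses <- c(losses, -log(pmax(p_true, 1e-12)))
    hits <- c(hits, max.col(fwd$prob) == y_int[part])
  }
  list(loss = mean(losses), accuracy = mean(hits))
}

#' Predict activity labels for contour images
#'
#' @param object A `cnn_fit` from [train_cnn()].
#' @param images List of contour images matching the model's input shape.
#' @param type `"class"` for hard labels, `"prob"` for the softmax matrix.
#' @param ... Unused.
#' @return Factor of predicted labels, or a numeric matrix of class
#'   probabilities with one row per image.
#' @export
predict.cnn_fit <- function(object, images, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- images_to_batch(images)
  n <- dim(x)[4]
  probs <- matrix(0, n, object$model$n_classes)
  for (part in split(seq_len(n), ceiling(seq_len(n) / 16))) {
    fwd <- cnn_forward(object$model, x[, , , part, drop = FALSE],
                       train = FALSE)
    probs[part, ] <- fwd$prob
  }
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  factor(object$classes[max.col(probs)], levels = object$classes)
}

#' @export
print.cnn_fit <- function(x, ...) {
  last <- x$epoch_history[nrow(x$epoch_history), ]
  cat(sprintf(
    "<cnn_fit> %d classes, %d epochs; final train acc %.3f%s\n",
    length(x$classes), nrow(x$epoch_history), last$train_accuracy,
    if (!is.na(last$val_accuracy))
      sprintf(", val acc %.3f", last$val_accuracy) else ""
  ))
  invisible(x)
}
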