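#' Classification pipelines
#'
#' A pipeline pairs a `fit(images, labels)` step with a
#' `predict(fit, images)` step behind one interface, so the network and the
#' feature+SVM routes are interchangeable in [crossvalidate()] and
#' [degradation_experiment()].
#'
#' `svm_pipeline()` extracts features with the given backbone, standardizes
#' them on the training set, and fits one linear support-vector machine per
#' class in a one-vs-rest arrangement (unit regularization cost by
#' default); prediction takes the class with the largest decision value.
#'
#' `cnn_pipeline()` trains the [build_residual_cnn()] network from scratch
#' with the given [train_params()].
#'
#' @param backbone Featurizer for [extract_features()].
#' @param cost Soft-margin cost of each binary SVM.
#' @param params [train_params()] for the network route.
#' @param input_shape,seed Network construction arguments.
#' @return An object of class `cf_pipeline`.
#' @export
svm_pipeline <- function(backbone = featurizer_pool(8), cost = 1) {
  fit <- function(images, labels) {
    labels <- factor(labels)
    X <- extract_features(images, backbone)
    mu <- colMeans(X)
    sd <- apply(X, 2, stats::sd)
    sd[sd < 1e-12] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, sd, "/")
    fits <- lapply(levels(labels), function(cl) {
      y <- factor(ifelse(labels == cl, "pos", "rest"),
                  levels = c("pos", "rest"))
      e1071::svm(Xs, y, kernel = "linear", cost = cost, scale = FALSE)
    })
    list(fits = fits, classes = levels(labels), mu = mu, sd = sd)
  }
  pred <- function(fit, images) {
    X <- extract_features(images, backbone)
    Xs <- sweep(sweep(X, 2, fit$mu), 2, fit$sd, "/")
    scores <- vapply(fit$fits, function(m) {
      dv <- attr(stats::predict(m, Xs, decision.values = TRUE),
                 "decision.values")
      # orient so larger means 'pos' regardless of e1071's internal order
      if (grepl("^pos/", colnames(dv)[1])) dv[, 1] else -dv[, 1]
    }, numeric(length(images)))
    scores <- matrix(scores, nrow = length(images))
    factor(fit$classes[max.col(scores)], levels = fit$classes)
  }
  structure(list(fit = fit, predict = pred,
                 name = sprintf("svm_linear_ovr(%s)",
                                attr(backbone, "backbone_name") %||% "custom")),
            class = "cf_pipeline")
}

#' @rdname svm_pipeline
#' @export
cnn_pipeline <- function(params = train_params(), input_shape = NULL,
                         seed = 1L) {
  fit <- function(images, labels) {
    labels <- factor(labels)
    shp <- input_shape %||% dim(images[[1]])
    model <- build_residual_cnn(shp, nlevels(labels), seed = seed)
    train_cnn(model, images, labels, params)
  }
  pred <- function(fit, images) stats::predict(fit, images)
  structure(list(fit = fit, predict = pred, name = "residual_cnn"),
            class = "cf_pipeline")
}

#' Cross-validation schemes
#'
#' `cv_kfold(k)` partitions the samples into `k` folds of near-equal size
#' drawn at random from `seed`. `cv_loso()` is leave-one-subject-out: one
#' fold per subject id, every window of the held-out subject tested on a
#' model trained on the remaining subjects — the scheme that measures
#' generalization to an unseen wearer.
#'
#' @param k Number of folds.
#' @param seed Integer seed for the random partition.
#' @return A list of class `cv_scheme`.
#' @export
cv_kfold <- function(k = 5, seed = 1L) {
  structure(list(kind = "kfold", k = as.integer(k), seed = as.integer(seed)),
            class = "cv_scheme")
}

#' @rdname cv_kfold
#' @export
cv_loso <- function() {
  structure(list(kind = "loso"), class = "cv_scheme")
}

cv_folds <- function(scheme, n, subjects = NULL) {
  if (scheme$kind == "kfold") {
    ids <- withr::with_seed(scheme$seed,
                            sample(rep_len(seq_len(scheme$k), n)))
    split(seq_len(n), ids)
  } else {
    if (is.null(subjects)) {
      rlang::abort("leave-one-subject-out needs a 'subject' column")
    }
    if (length(unique(subjects)) < 2) {
      rlang::abort("leave-one-subject-out needs at least two subjects")
    }
    split(seq_len(n), subjects)
  }
}

#' Cross-validate a pipeline over labeled contour images
#'
#' Fits the pipeline on each training fold and predicts the held-out fold,
#' so that every sample is predicted exactly once; predictions are pooled
#' into one k-class confusion matrix (rows: truth, columns: prediction) for
#' the metric battery. A fold whose training part contains a single class
#' is skipped with a warning. `test_data`, when given, supplies alternative
#' images (e.g. degraded copies of the same windows) that are used only for
#' prediction, while training stays on `data` — the fixed-model protocol of
#' missing-data experiments.
#'
#' @param data Tibble with list-column `image`, column `label`, and (for
#'   LOSO) column `subject`.
#' @param pipeline A `cf_pipeline`.
#' @param scheme A `cv_scheme`.
#' @param test_data Optional tibble, same rows as `data`, whose `image`
#'   column replaces the held-out images at prediction time.
#' @return An object of class `cv_result` with elements `predictions`
#'   (tibble: `row`, `label`, `pred`, `fold`), `confusion`, `classes`,
#'   `scheme`, `pipeline`.
#' @export
crossvalidate <- function(data, pipeline, scheme = cv_kfold(5),
                          test_data = NULL) {
  stopifnot(inherits(pipeline, "cf_pipeline"), inherits(scheme, "cv_scheme"))
  labels <- factor(data$label)
  folds <- cv_folds(scheme, nrow(data), data[["subject"]])
  test_images <- if (is.null(test_data)) data$image else test_data$image
  preds <- list()
  for (fold_name in names(folds)) {
    test_ix <- folds[[fold_name]]
    train_ix <- setdiff(seq_len(nrow(data)), test_ix)
    y_tr <- droplevels(labels[train_ix])
    if (nlevels(y_tr) < 2) {
      rlang::warn(sprintf("fold '%s': single-class training set, skipped",
                          fold_name))
      next
    }
    fit <- pipeline$fit(data$image[train_ix], y_tr)
    p <- pipeline$predict(fit, test_images[test_ix])
    preds[[fold_name]] <- tibble::tibble(
      row = test_ix, label = as.character(labels[test_ix]),
      pred = as.character(p), fold = fold_name
    )
  }
  empty <- tibble::tibble(row = integer(), label = character(),
                          pred = character(), fold = character())
  predictions <- dplyr::arrange(dplyr::bind_rows(c(list(empty), preds)),
                                .data$row)
  conf <- confusion_matrix(predictions$label, predictions$pred,
                           levels = levels(labels))
  structure(list(predictions = predictions, confusion = conf,
                 classes = levels(labels), scheme = scheme,
                 pipeline = pipeline$name),
            class = "cv_result")
}

#' Pooled confusion matrix from label vectors
#'
#' @param truth,pred Vectors of true and predicted labels.
#' @param levels Class levels fixing row/column order; default the union.
#' @return A `k x k` integer matrix, rows = truth, columns = prediction.
#' @export
confusion_matrix <- function(truth, pred, levels = NULL) {
  levels <- levels %||% sort(unique(c(as.character(truth), as.character(pred))))
  table(truth = factor(truth, levels), pred = factor(pred, levels)) |>
    unclass()
}

#' @export
print.cv_result <- function(x, ...) {
  acc <- mean(x$predictions$label == x$predictions$pred)
  cat(sprintf("<cv_result> %s, %s CV: %d predictions, accuracy %.4f\n",
              x$pipeline, x$scheme$kind, nrow(x$predictions), acc))
  print(x$confusion)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.cv_result <- function(x, ...) x$predictions

#' @importFrom generics glance
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    accuracy = mean(x$predictions$label == x$predictions$pred),
    n = nrow(x$predictions),
    n_classes = length(x$classes),
    n_folds = length(unique(x$predictions$fold)),
    scheme = x$scheme$kind,
    pipeline = x$pipeline
  )
}
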