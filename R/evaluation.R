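# Kidney-wise data splitting, leave-one-out cross-validation, per-ROI and
# per-kidney (majority-vote) metrics, and classification reliability.

#' Assemble a kidney-level dataset
#'
#' @param kidneys List of entries, each a list with `id` (unique), `label`
#'   (class 1/2/3) and `samples` (list of preprocessed ROI samples; every
#'   sample of a kidney shares its label).
#' @return Object of class `"kidney_dataset"` with a per-kidney `split` tag
#'   (`"trainval"`/`"test"`, initially all `"trainval"`).
#' @export
kidney_dataset <- function(kidneys) {
  ids <- vapply(kidneys, function(k) as.character(k$id), character(1L))
  if (anyDuplicated(ids)) stop("duplicated kidney ids", call. = FALSE)
  labels <- vapply(kidneys, function(k) as.integer(k$label), integer(1L))
  if (any(is.na(labels))) stop("every kidney needs a class label", call. = FALSE)
  for (k in kidneys) {
    for (s in k$samples) {
      if (!is.na(s$label) && s$label != k$label) {
        stop(sprintf("kidney %s carries a sample with a different label", k$id),
             call. = FALSE)
      }
    }
  }
  structure(list(kidneys = kidneys, ids = ids, labels = labels,
                 split = stats::setNames(rep("trainval", length(ids)), ids)),
            class = "kidney_dataset")
}

#' @export
print.kidney_dataset <- function(x, ...) {
  cat(sprintf("<kidney_dataset> %d kidneys (classes: %s), %d ROI samples\n",
              length(x$ids), paste(table(x$labels), collapse = "/"),
              sum(vapply(x$kidneys, function(k) length(k$samples), integer(1L)))))
  invisible(x)
}

dataset_subset <- function(dataset, ids) {
  keep <- dataset$ids %in% ids
  kidney_dataset(dataset$kidneys[keep])
}

#' Stratified kidney-level train/test split
#'
#' Splits at kidney granularity (never ROI granularity, which would leak
#' organ-specific features across the split). Per class, `round(n * fraction)`
#' kidneys — at least one — are drawn at random into the test set.
#'
#' @param dataset A [kidney_dataset()].
#' @param test_fraction Fraction of kidneys per class for the test side
#'   (default 0.25).
#' @param seed Integer seed making the draw reproducible.
#' @return The dataset with its `split` tags set.
#' @export
stratified_split <- function(dataset, test_fraction = 0.25, seed = 0L) {
  stopifnot(inherits(dataset, "kidney_dataset"))
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie strictly between 0 and 1 (an empty side is not a split)",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  split <- stats::setNames(rep("trainval", length(dataset$ids)), dataset$ids)
  for (cl in sort(unique(dataset$labels))) {
    ids_cl <- dataset$ids[dataset$labels == cl]
    n_test <- max(1L, round(length(ids_cl) * test_fraction))
    if (n_test >= length(ids_cl)) {
      stop(sprintf("class %d has too few kidneys (%d) for a %.0f%% test split",
                   cl, length(ids_cl), 100 * test_fraction), call. = FALSE)
    }
    split[sample(ids_cl, n_test)] <- "test"
  }
  dataset$split <- split
  dataset
}

#' Kidney-wise leave-one-out folds
#'
#' One fold per kidney: that kidney (all its ROIs) is the validation set, all
#' remaining kidneys form the training set.
#'
#' @param dataset A [kidney_dataset()] (already restricted to the
#'   training+validation kidneys).
#' @return List of folds, each with `train_ids` and `val_id`.
#' @export
loocv_folds <- function(dataset) {
  stopifnot(inherits(dataset, "kidney_dataset"))
  if (length(dataset$ids) < 2L) stop("need at least 2 kidneys for LOOCV", call. = FALSE)
  lapply(dataset$ids, function(id) {
    list(train_ids = setdiff(dataset$ids, id), val_id = id)
  })
}

#' Majority vote over ROI-level labels
#'
#' Returns the modal class. Ties are broken towards the lower class number
#' (the more severe functional grade), a deliberately conservative rule, and
#' reported via a warning.
#'
#' @param roi_labels Vector of predicted class labels (>= 1 entry).
#' @return Single class label.
#' @export
majority_vote <- function(roi_labels) {
  if (length(roi_labels) == 0L) stop("majority vote over an empty label set", call. = FALSE)
  tab <- table(factor(roi_labels))
  winners <- as.integer(names(tab)[tab == max(tab)])
  if (length(winners) > 1L) {
    warning(sprintf("majority-vote tie between classes %s; choosing class %d",
                    paste(winners, collapse = ", "), min(winners)), call. = FALSE)
  }
  min(winners)
}

#' Confusion matrix and derived metrics
#'
#' Confusion matrix with actual classes as rows and predicted as columns;
#' accuracy is its trace over the total. Precision and recall are computed
#' per class and macro-averaged (classes that were never predicted contribute
#' a precision of 0).
#'
#' @param actual,predicted Equal-length vectors of labels in `1..n_classes`.
#' @param n_classes Number of classes (default 3).
#' @return List with `confusion`, `accuracy`, `precision`, `recall`, and the
#'   per-class vectors `precision_by_class`, `recall_by_class`.
#' @export
compute_metrics <- function(actual, predicted, n_classes = 3L) {
  if (length(actual) != length(predicted)) {
    stop("actual and predicted must have equal length", call. = FALSE)
  }
  if (any(!actual %in% seq_len(n_classes)) || any(!predicted %in% seq_len(n_classes))) {
    stop("labels must lie in 1..n_classes", call. = FALSE)
  }
  lev <- seq_len(n_classes)
  cm <- table(factor(actual, levels = lev), factor(predicted, levels = lev))
  cm <- matrix(as.integer(cm), n_classes, n_classes,
               dimnames = list(actual = lev, predicted = lev))
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  list(confusion = cm,
       accuracy = sum(tp) / sum(cm),
       precision = mean(prec),
       recall = mean(rec),
       precision_by_class = prec,
       recall_by_class = rec)
}

#' Classification reliability per kidney
#'
#' The proportion of a kidney's ROIs assigned its true class, in percent. A
#' reliability above 50% guarantees a correct majority vote in the 3-class
#' setting.
#'
#' @param per_roi_correct Logical vector of per-ROI correctness flags for one
#'   kidney.
#' @return Percentage in `[0, 100]`.
#' @export
classification_reliability <- function(per_roi_correct) {
  if (length(per_roi_correct) == 0L) stop("kidney without ROIs", call. = FALSE)
  100 * mean(as.logical(per_roi_correct))
}

collect_samples <- function(dataset, ids) {
  do.call(c, lapply(dataset$kidneys[dataset$ids %in% ids], function(k) {
    lapply(k$samples, function(s) { s$label <- k$label; s })
  }))
}

#' Kidney-wise leave-one-out cross-validation of one configuration
#'
#' Trains one model per fold (every kidney held out once with all its ROIs)
#' and evaluates it on the held-out kidney. Per-ROI metrics are averaged over
#' folds; the pooled ROI predictions also yield one majority vote per kidney.
#'
#' @param dataset A [kidney_dataset()] of the training+validation kidneys.
#' @param cfg A [train_config()].
#' @param train_fun,predict_fun Training and prediction backends (exposed so
#'   that a perfect oracle can be substituted in pipeline tests); defaults are
#'   [train_model()] and [predict_rois()].
#' @return List with per-fold `stopping_epochs` and `fold_accuracy`,
#'   `mean_val_accuracy` (mean per-ROI accuracy over folds),
#'   `median_stopping_epoch`, per-kidney table `kidneys` (id, actual,
#'   predicted majority label, reliability %), `roi_metrics` on the pooled
#'   predictions and `kidney_metrics` on the majority votes.
#' @export
run_loocv <- function(dataset, cfg, train_fun = train_model, predict_fun = predict_rois) {
  folds <- loocv_folds(dataset)
  stopping <- integer(0)
  fold_acc <- numeric(0)
  roi_actual <- integer(0); roi_pred <- integer(0)
  ktab <- data.frame(kidney = character(0), actual = integer(0),
                     predicted = integer(0), reliability = numeric(0),
                     stringsAsFactors = FALSE)
  for (f in folds) {
    tr_samples <- collect_samples(dataset, f$train_ids)
    va_samples <- collect_samples(dataset, f$val_id)
    fit <- train_fun(tr_samples, va_samples, cfg)
    pred <- predict_fun(fit, va_samples)
    actual <- vapply(va_samples, function(s) as.integer(s$label), integer(1L))
    stopping <- c(stopping, fit$stopping_epoch)
    fold_acc <- c(fold_acc, mean(pred$labels == actual))
    roi_actual <- c(roi_actual, actual)
    roi_pred <- c(roi_pred, pred$labels)
    ktab <- rbind(ktab, data.frame(
      kidney = f$val_id, actual = actual[1L],
      predicted = majority_vote(pred$labels),
      reliability = classification_reliability(pred$labels == actual),
      stringsAsFactors = FALSE))
  }
  list(stopping_epochs = stopping,
       fold_accuracy = fold_acc,
       mean_val_accuracy = mean(fold_acc),
       median_stopping_epoch = stats::median(stopping),
       kidneys = ktab,
       roi_metrics = compute_metrics(roi_actual, roi_pred, cfg$n_classes),
       kidney_metrics = compute_metrics(ktab$actual, ktab$predicted, cfg$n_classes))
}

#' Grid search, final retrain and held-out test evaluation
#'
#' For every configuration in the grid: LOOCV over the training+validation
#' kidneys, recording per-fold early-stopping epochs and per-ROI validation
#' accuracies. The configuration with the best mean validation accuracy is
#' then retrained on all training+validation kidneys for a fixed number of
#' epochs equal to the median of its fold stopping epochs (no validation
#' split), and that final model is applied once to the held-out test kidneys.
#'
#' @param dataset A [kidney_dataset()] whose `split` tags separate trainval
#'   from test kidneys (see [stratified_split()]).
#' @param grid List of [train_config()] objects (>= 1).
#' @param train_fun,predict_fun Backends, see [run_loocv()].
#' @return Object of class `"evaluation_report"`: `grid_results` table, the
#'   index of the `best` configuration, its LOOCV details (`validation`), and
#'   the held-out `test` block (per-kidney table, per-ROI and majority-vote
#'   metrics).
#' @export
run_experiment <- function(dataset, grid, train_fun = train_model,
                           predict_fun = predict_rois) {
  stopifnot(inherits(dataset, "kidney_dataset"))
  if (length(grid) == 0L) stop("empty configuration grid", call. = FALSE)
  trainval <- dataset_subset(dataset, dataset$ids[dataset$split == "trainval"])
  test_ids <- dataset$ids[dataset$split == "test"]

  cv <- vector("list", length(grid))
  rows <- list()
  for (i in seq_along(grid)) {
    cv[[i]] <- run_loocv(trainval, grid[[i]], train_fun, predict_fun)
    g <- grid[[i]]
    rows[[i]] <- data.frame(
      config = i, data_origin = g$data_origin, dropout_rate = g$dropout_rate,
      weight_decay = g$weight_decay, lr_decay = g$lr_decay,
      augmented = augment_active(g$augment),
      median_stopping_epoch = cv[[i]]$median_stopping_epoch,
      validation_mean_accuracy = cv[[i]]$mean_val_accuracy,
      stringsAsFactors = FALSE)
  }
  grid_results <- do.call(rbind, rows)
  best <- which.max(grid_results$validation_mean_accuracy)

  test <- NULL
  final_fit <- NULL
  if (length(test_ids)) {
    cfg <- grid[[best]]
    cfg$max_epochs <- max(1L, as.integer(round(cv[[best]]$median_stopping_epoch)))
    tr_samples <- collect_samples(trainval, trainval$ids)
    final_fit <- train_fun(tr_samples, NULL, cfg)
    testset <- dataset_subset(dataset, test_ids)
    roi_actual <- integer(0); roi_pred <- integer(0)
    ktab <- data.frame(kidney = character(0), actual = integer(0),
                       predicted = integer(0), reliability = numeric(0),
                       stringsAsFactors = FALSE)
    for (j in seq_along(testset$ids)) {
      ks <- collect_samples(testset, testset$ids[j])
      pred <- predict_fun(final_fit, ks)
      actual <- vapply(ks, function(s) as.integer(s$label), integer(1L))
      roi_actual <- c(roi_actual, actual)
      roi_pred <- c(roi_pred, pred$labels)
      ktab <- rbind(ktab, data.frame(
        kidney = testset$ids[j], actual = actual[1L],
        predicted = majority_vote(pred$labels),
        reliability = classification_reliability(pred$labels == actual),
        stringsAsFactors = FALSE))
    }
    test <- list(kidneys = ktab,
                 roi_metrics = compute_metrics(roi_actual, roi_pred, grid[[best]]$n_classes),
                 kidney_metrics = compute_metrics(ktab$actual, ktab$predicted,
                                                  grid[[best]]$n_classes))
  }
  structure(list(grid_results = grid_results, best = best,
                 validation = cv[[best]], test = test, final_fit = final_fit),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  print(x$grid_results)
  cat(sprintf("best config: %d (validation mean accuracy %.3f)\n",
              x$best, x$grid_results$validation_mean_accuracy[x$best]))
  if (!is.null(x$test)) {
    cat(sprintf("held-out test: per-ROI accuracy %.3f, majority-vote accuracy %.3f\n",
                x$test$roi_metrics$accuracy, x$test$kidney_metrics$accuracy))
  }
  invisible(x)
}
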