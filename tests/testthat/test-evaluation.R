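make_fake_dataset <- function(n_per_class, rois_per_kidney = 4L) {
  idx <- 0L
  kidneys <- list()
  for (cl in 1:3) {
    for (i in seq_len(n_per_class[cl])) {
      idx <- idx + 1L
      samples <- lapply(seq_len(rois_per_kidney), function(j) {
        list(values = array(cl, c(2, 2, 2)), wavelengths = c(500, 505),
             kidney_id = sprintf("K%02d", idx), time_point = j,
             region = "middle", label = cl)
      })
      kidneys[[idx]] <- list(id = sprintf("K%02d", idx), label = cl,
                             samples = samples)
    }
  }
  kidney_dataset(kidneys)
}

test_that("the stratified split reproduces the 4/10/12 -> 1/2/3 test counts", {
  ds <- make_fake_dataset(c(4L, 10L, 12L))
  split <- stratified_split(ds, 0.25, seed = 1L)
  test_by_class <- table(split$labels[split$split == "test"])
  expect_equal(as.integer(test_by_class), c(1L, 2L, 3L))
  expect_identical(sum(split$split == "trainval"), 20L)

  split2 <- stratified_split(ds, 0.25, seed = 1L)
  expect_identical(split$split, split2$split)            # same seed, same draw
  split3 <- stratified_split(ds, 0.25, seed = 2L)
  expect_false(identical(split$split, split3$split))

  expect_error(stratified_split(ds, 0), "between 0 and 1")
  expect_error(stratified_split(make_fake_dataset(c(1L, 2L, 2L)), 0.25),
               "too few kidneys")
})

test_that("leave-one-out folds hold out each kidney exactly once", {
  ds <- make_fake_dataset(c(4L, 8L, 8L))
  folds <- loocv_folds(ds)
  expect_length(folds, 20L)
  val_ids <- vapply(folds, `[[`, character(1), "val_id")
  expect_setequal(val_ids, ds$ids)
  for (f in folds) {
    expect_length(intersect(f$train_ids, f$val_id), 0L)
    expect_length(f$train_ids, 19L)
  }
  expect_error(loocv_folds(make_fake_dataset(c(1L, 0L, 0L))), "at least 2")
})

test_that("majority vote takes the mode and breaks ties towards severity", {
  expect_identical(majority_vote(rep(3L, 168)), 3L)
  votes <- c(rep(1L, 40), rep(2L, 28), rep(3L, 100))
  expect_identical(majority_vote(votes), 3L)
  expect_identical(majority_vote(sample(votes)), 3L)      # order-invariant
  expect_warning(tie <- majority_vote(c(rep(1L, 84), rep(2L, 84))), "tie")
  expect_identical(tie, 1L)
  expect_error(majority_vote(integer(0)), "empty")
})

test_that("metrics reproduce hand-computed values", {
  perfect <- compute_metrics(c(1, 2, 3, 1), c(1, 2, 3, 1))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)

  m <- compute_metrics(c(1, 1, 2, 3), c(1, 2, 2, 3))
  expect_equal(m$accuracy, 0.75)
  expect_equal(as.integer(m$confusion),
               as.integer(matrix(c(1, 0, 0, 1, 1, 0, 0, 0, 1), 3, 3)))
  expect_equal(sum(m$confusion), 4L)
  # precision: class1 1/1, class2 1/2, class3 1/1 -> macro 5/6
  expect_equal(m$precision, 5 / 6)
  # recall: class1 1/2, class2 1/1, class3 1/1 -> macro 5/6
  expect_equal(m$recall, 5 / 6)

  one_class <- compute_metrics(c(1, 2, 3, 3), rep(2, 4))
  expect_equal(one_class$recall_by_class, c(`1` = 0, `2` = 1, `3` = 0))
  expect_equal(one_class$precision_by_class[["2"]], 0.25)

  expect_error(compute_metrics(c(1, 5), c(1, 1)), "1..n_classes")
  expect_error(compute_metrics(1:3, 1:2), "equal length")
})

test_that("classification reliability is the percent of correct ROIs", {
  expect_equal(classification_reliability(rep(TRUE, 168)), 100)
  expect_equal(classification_reliability(c(rep(TRUE, 160), rep(FALSE, 8))),
               100 * 160 / 168)
  expect_equal(round(classification_reliability(c(rep(TRUE, 160), rep(FALSE, 8))), 1),
               95.2)
  # pigeonhole: reliability > 50% forces a correct majority vote (3 classes)
  set.seed(31)
  for (i in 1:25) {
    truth <- sample(1:3, 1)
    n <- 60L
    n_correct <- sample(31:60, 1)
    wrong <- sample(setdiff(1:3, truth), n - n_correct, replace = TRUE)
    labels <- sample(c(rep(truth, n_correct), wrong))
    expect_gt(classification_reliability(labels == truth), 50)
    expect_identical(majority_vote(labels), truth)
  }
})

test_that("a perfect oracle classifier drives the whole harness to 100%", {
  ds <- make_fake_dataset(c(2L, 3L, 3L))
  ds <- stratified_split(ds, 0.25, seed = 3L)
  grid <- list(train_config(max_epochs = 7L, block_channels = c(4L, 4L, 8L, 8L)))
  report <- run_experiment(ds, grid, train_fun = oracle_train,
                           predict_fun = oracle_predict)
  expect_identical(nrow(report$grid_results), 1L)
  expect_equal(report$validation$mean_val_accuracy, 1)
  expect_equal(report$validation$kidney_metrics$accuracy, 1)
  expect_true(all(report$validation$kidneys$reliability == 100))
  expect_equal(report$test$kidney_metrics$accuracy, 1)
  expect_true(all(report$test$kidneys$reliability == 100))
  expect_identical(dim(report$test$roi_metrics$confusion), c(3L, 3L))
  expect_error(run_experiment(ds, list()), "empty")
})

test_that("the final retrain uses the median fold stopping epoch", {
  ds <- make_fake_dataset(c(2L, 2L, 2L))
  ds$split[] <- "trainval"
  ds$split[c("K01", "K03", "K05")] <- "test"   # leaves 3 trainval kidneys = 3 folds

  # stub trainer: stopping epochs 9, 11, 7, ... per fold; capture the epoch
  # count the final retrain is asked to run
  seen <- new.env()
  seen$epochs <- integer(0)
  seen$final_max <- NA_integer_
  stub_train <- function(train_samples, val_samples, cfg) {
    if (is.null(val_samples)) {
      seen$final_max <- cfg$max_epochs
    }
    e <- c(9L, 11L, 7L, 10L, 8L)[length(seen$epochs) %% 5L + 1L]
    seen$epochs <- c(seen$epochs, e)
    structure(list(stopping_epoch = e), class = "oracle_fit")
  }
  report <- run_experiment(ds, list(train_config()), train_fun = stub_train,
                           predict_fun = oracle_predict)
  expect_identical(seen$final_max, 9L)        # median of fold epochs 9, 11, 7
  expect_equal(report$validation$median_stopping_epoch, 9)
})
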