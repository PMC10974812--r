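test_that("grid enumeration reproduces every printed configuration count", {
  expected <- c(MLP = 288L, BiLSTM = 648L, MFCC_CNN = 864L,
                MFCC_ResNet = 432L, RF = 60L, CNN1D = 144L,
                BiLSTM_raw = 108L)
  for (fam in names(expected)) {
    g <- hyper_grid(fam)
    expect_equal(grid_size(g), expected[[fam]])
    specs <- enumerate_grid(g)
    expect_length(specs, expected[[fam]])
    expect_true(all(vapply(specs, inherits, logical(1), "model_spec")))
  }
})

test_that("grid enumeration is deterministic and lexicographic", {
  g <- hyper_grid("RF")
  s1 <- enumerate_grid(g)
  s2 <- enumerate_grid(g)
  expect_identical(s1, s2)
  # the first axis varies slowest
  firsts <- vapply(s1, function(s) s$n_estimators, numeric(1))
  expect_equal(firsts, rep(c(100, 200, 300, 500, 700), each = 12))
  tiny <- structure(list(family = "RF", axes = list(n_estimators = c(1, 2))),
                    class = "hyper_grid")
  expect_length(enumerate_grid(tiny), 2L)
  empty <- structure(list(family = "RF", axes = list(n_estimators = numeric(0))),
                     class = "hyper_grid")
  expect_error(enumerate_grid(empty), "empty")
})

test_that("fold rotations produce a 60/20/20 split covering everything", {
  ds <- feature_dataset(matrix(rnorm(100 * 4), 100),
                        sample(c("Fear", "Anger"), 100, TRUE),
                        c("Anger", "Fear"), "raw_1s")
  folds <- make_folds(ds, 5, grouping = "window", seed = 9)
  for (rot in folds$rotations) {
    expect_length(rot$train, 60L)
    expect_length(rot$validation, 20L)
    expect_length(rot$test, 20L)
    expect_length(intersect(rot$train, rot$test), 0L)
    expect_length(intersect(rot$train, rot$validation), 0L)
    expect_length(intersect(rot$validation, rot$test), 0L)
  }
  tests <- lapply(folds$rotations, `[[`, "test")
  expect_equal(sort(unlist(tests)), 1:100)   # disjoint union = everything
  expect_equal(sum(vapply(tests, length, integer(1))), 100L)
})

test_that("participant grouping never splits a participant across folds", {
  meta <- data.frame(participant_id = rep(sprintf("P%02d", 1:10), each = 7))
  ds <- feature_dataset(matrix(rnorm(70 * 3), 70),
                        sample(c("Fear", "Anger"), 70, TRUE),
                        c("Anger", "Fear"), "raw_1s", meta = meta)
  folds <- make_folds(ds, 5, grouping = "participant", seed = 3)
  split_tab <- table(meta$participant_id, folds$fold)
  expect_true(all(rowSums(split_tab > 0) == 1L))
  for (rot in folds$rotations) {
    pids <- function(i) unique(meta$participant_id[i])
    expect_length(intersect(pids(rot$train), pids(rot$test)), 0L)
    expect_length(intersect(pids(rot$train), pids(rot$validation)), 0L)
    expect_length(intersect(pids(rot$validation), pids(rot$test)), 0L)
  }
  ds5 <- feature_dataset(matrix(rnorm(4 * 2), 4), rep("Fear", 4),
                         c("Anger", "Fear"), "raw_1s",
                         meta = data.frame(participant_id = c("a", "a", "b", "b")))
  expect_error(make_folds(ds5, 5, grouping = "participant", seed = 1),
               "fewer participants")
})

test_that("cross-validated RF separates the constructed synthetic classes", {
  ds <- raw_cohort_strong()
  folds <- make_folds(ds, 5, grouping = "window", seed = 1)
  spec <- model_spec("RF", n_estimators = 100, max_depth = 20,
                     balancing = "none")
  res <- cv_evaluate(spec, ds, folds, train_config(seed = 1),
                     rotations = 1:2)
  expect_false(res$failed)
  expect_equal(nrow(res$metrics), 2L)
  expect_gt(res$mean_accuracy, 0.9)
  expect_gt(res$mean_recall, 0.9)
})

test_that("configuration selection takes the best score with stable ties", {
  mk <- function(acc, ntree) {
    structure(list(spec = model_spec("RF", n_estimators = ntree,
                                     balancing = "none"),
                   metrics = data.frame(rotation = 1, accuracy = acc,
                                        recall = acc, failed = FALSE),
                   mean_accuracy = acc, mean_recall = acc, failed = FALSE),
              class = "cv_result")
  }
  gr <- structure(list(results = list(mk(0.4, 100), mk(0.6, 200)),
                       table = NULL), class = "grid_result")
  ds <- raw_cohort_strong()
  folds <- make_folds(ds, 5, grouping = "window", seed = 1)
  fin <- select_and_train_final(gr, ds, folds,
                                final_config = train_config(seed = 1))
  expect_equal(fin$config_index, 2L)
  expect_equal(fin$spec$n_estimators, 200)
  # final training reuses the winning spec verbatim
  expect_identical(fin$model$spec, fin$spec)
  expect_s3_class(fin$report, "eval_report")

  tie <- structure(list(results = list(mk(0.6, 100), mk(0.6, 200)),
                        table = NULL), class = "grid_result")
  fin2 <- select_and_train_final(tie, ds, folds,
                                 final_config = train_config(seed = 1))
  expect_equal(fin2$config_index, 1L)      # earliest config wins ties
  expect_error(select_and_train_final(structure(list(results = list()),
                                                class = "grid_result"),
                                      ds, folds), "empty")
})

test_that("a neural family trains through the CV harness on a tiny grid", {
  ds <- raw_cohort_strong()
  # make the problem small: balanced classes, 40 input samples
  small <- balanced_subsample(ds, 3)
  small$x <- small$x[, seq_len(40)]
  spec <- model_spec("MLP", dense_units = 16, dense_layers = 1,
                     dropout_rate = 0, learning_rate = 1e-2,
                     balancing = "weights", window = 5, hop = 5)
  folds <- make_folds(small, 5, grouping = "window", seed = 2)
  res <- cv_evaluate(spec, small, folds,
                     train_config(max_epochs = 8, patience = 3, seed = 4),
                     rotations = 1L)
  expect_false(res$failed)
  expect_true(is.finite(res$mean_accuracy))
  expect_true(res$mean_accuracy >= 0 && res$mean_accuracy <= 1)
})
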