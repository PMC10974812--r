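test_that("model specs validate their hyperparameter domains", {
  expect_error(model_spec("MLP", lstm_units = 64), "not valid")
  expect_error(model_spec("MLP", dropout_rate = 1.5), "dropout_rate")
  expect_error(model_spec("RF", n_estimators = -3), "n_estimators")
  expect_error(model_spec("CNN1D", balancing = "oversample"), "balancing")
  sp <- model_spec("RF", n_estimators = 300, max_depth = NA,
                   balancing = "none")
  expect_s3_class(sp, "model_spec")
})

test_that("selected configurations reproduce the tuned hyperparameters", {
  mlp <- selected_spec("MLP")
  expect_equal(mlp$dense_units, 4096)
  expect_equal(mlp$dense_layers, 2)
  expect_equal(mlp$dropout_rate, 0.2)
  expect_equal(mlp$window, 20)
  expect_equal(mlp$hop, 10)
  rf <- selected_spec("RF")
  expect_equal(rf$n_estimators, 300)
  expect_equal(rf$max_depth, 20)
  resnet <- selected_spec("MFCC_ResNet")
  expect_false(resnet$pretrained)
  expect_equal(resnet$n_mfcc, 60)
})

test_that("built architectures match their specs (round-trip introspection)", {
  mlp <- build_model(model_spec("MLP", dense_units = 32, dense_layers = 2,
                                dropout_rate = 0.2, learning_rate = 1e-3,
                                balancing = "none", window = 5, hop = 5),
                     input_shape = 40, nbemotion = 7, seed = 1)
  types <- vapply(mlp$layers, `[[`, character(1), "type")
  expect_equal(types, c("dense", "dropout", "dense", "dropout", "dense"))
  expect_equal(mlp$layers[[1]]$units, 32L)
  expect_equal(mlp$layers[[5]]$units, 7L)
  expect_equal(mlp$layers[[5]]$activation, "softmax")
  expect_identical(mlp$spec$family, "MLP")

  bl <- build_model(model_spec("BiLSTM", lstm_units = 8, lstm_layers = 2,
                               dropout_rate = 0, learning_rate = 3e-4,
                               balancing = "none", window = 5, hop = 5),
                    input_shape = c(20, 1), nbemotion = 7, seed = 1)
  types <- vapply(bl$layers, `[[`, character(1), "type")
  expect_equal(types[1:2], c("bilstm", "bilstm"))
  expect_true(bl$layers[[1]]$return_sequences)
  expect_false(bl$layers[[2]]$return_sequences)
  # dense head of 1024 then 512 units
  dense_units <- vapply(bl$layers[types == "dense"], `[[`, integer(1),
                        "units")
  expect_equal(dense_units, c(1024L, 512L, 7L))

  c1 <- build_model(selected_spec("CNN1D"), c(200, 1), nbemotion = 6,
                    seed = 1)
  types <- vapply(c1$layers, `[[`, character(1), "type")
  expect_equal(sum(types == "conv1d"), 2L)
  expect_equal(c1$layers[[1]]$filters, 96L)
  expect_equal(c1$layers[[1]]$kernel_size, 7L)
  dense <- c1$layers[[which(types == "dense")[1]]]
  expect_equal(dense$units, 100L)
  expect_equal(dense$activation, "swish")

  rn <- build_model(selected_spec("MFCC_ResNet"), c(16, 16, 3), 7, seed = 1)
  types <- vapply(rn$layers, `[[`, character(1), "type")
  expect_equal(sum(types == "residual2d"), 4L)
  expect_true("gap2d" %in% types)
})

test_that("every neural family outputs simplex probability vectors", {
  shapes <- list(MLP = 30, BiLSTM = c(15, 1), MFCC_CNN = c(12, 20, 1),
                 MFCC_ResNet = c(12, 12, 3), CNN1D = c(40, 1),
                 BiLSTM_raw = c(40, 1))
  for (fam in names(shapes)) {
    sp <- selected_spec(fam)
    if (fam %in% c("BiLSTM", "BiLSTM_raw")) sp$lstm_units <- 6
    if (fam == "MLP") sp$dense_units <- 12
    md <- build_model(sp, shapes[[fam]], 7, class_set = emotion_levels(),
                      seed = 2)
    x <- array(rnorm(3 * prod(shapes[[fam]])), c(3, shapes[[fam]]))
    if (fam == "MLP") x <- matrix(x, 3)
    p <- nn_predict_proba(md, x)
    expect_equal(dim(p), c(3L, 7L))
    expect_true(all(p >= 0))
    expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  }
})

test_that("pretrained ResNet weights require a weights file", {
  sp <- selected_spec("MFCC_ResNet")
  sp$pretrained <- TRUE
  expect_error(build_model(sp, c(12, 12, 3), 7, seed = 1),
               "pretrained_weights")
})

test_that("balance resampling hits the mean per-class count", {
  x <- matrix(rnorm(100 * 3), 100)
  y <- c(rep("Fear", 10), rep("Anger", 90))
  ds <- feature_dataset(x, y, setdiff(emotion_levels(), "Neutral"), "raw_1s")
  bal <- apply_balancing(ds, "balance", seed = 4)
  expect_s3_class(bal$data, "feature_dataset")
  counts <- table(droplevels(bal$data$y))
  expect_equal(as.integer(counts[c("Fear", "Anger")]), c(50L, 50L))
  expect_equal(nrow(bal$data$x), 100L)
  expect_null(bal$class_weights)
  none <- apply_balancing(ds, "none")
  expect_identical(none$data$x, ds$x)
})

test_that("class weights follow N / (nbclass * n_c) and conserve mass", {
  x <- matrix(rnorm(100 * 2), 100)
  y <- c(rep("Fear", 10), rep("Anger", 90))
  ds <- feature_dataset(x, y, c("Anger", "Fear"), "raw_1s")
  w <- apply_balancing(ds, "weights")$class_weights
  expect_equal(unname(w["Fear"]), 5)
  expect_equal(unname(w["Anger"]), 0.5556, tolerance = 1e-4)
  counts <- table(ds$y)
  expect_equal(sum(as.numeric(counts) * w[names(counts)]), 100)
})

test_that("argmax classification breaks ties toward the lowest index", {
  cs <- c("Anger", "Disgust", "Fear")
  expect_equal(as.character(predict_emotion(c(0.1, 0.7, 0.2), cs)),
               "Disgust")
  expect_equal(as.character(predict_emotion(c(0.5, 0.5, 0), cs)), "Anger")
  expect_error(predict_emotion(c(0.9, 0.4, 0.2), cs), "simplex")
  expect_error(predict_emotion(c(0.5, 0.5), cs), "width")
})

test_that("RF vote fractions act as the probability vector", {
  ds <- raw_cohort_strong()
  folds <- make_folds(ds, 5, grouping = "window", seed = 2)
  rot <- folds$rotations[[1]]
  train <- plantsense:::subset_dataset(ds, rot$train)
  test <- plantsense:::subset_dataset(ds, rot$test[1:20])
  md <- build_model(model_spec("RF", n_estimators = 50, max_depth = 10,
                               balancing = "none"),
                    ncol(ds$x), ds$nbemotion, class_set = ds$class_set,
                    seed = 5)
  md <- train_model(md, train)
  p <- predict_proba(md, test)
  expect_equal(rowSums(p), rep(1, 20), tolerance = 1e-6)
  # argmax of vote fractions equals the majority-vote class
  pred <- predict_emotion(p, ds$class_set)
  expect_equal(as.character(pred),
               ds$class_set[apply(p, 1, which.max)])
})
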