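# Finite-difference gradient verification of the training engine, plus
# behavioural checks (learning, early stopping, determinism).

nn_gradcheck <- function(layers, input_shape, x, n_classes = 3,
                         eps = 1e-5, n_probe = 4) {
  set.seed(42)
  m <- nn_model(layers, input_shape, n_classes,
                class_set = letters[1:n_classes], seed = 99)
  n <- dim(x)[1]
  y <- sample(n_classes, n, replace = TRUE)
  Y <- matrix(0, n, n_classes)
  Y[cbind(seq_len(n), y)] <- 1
  loss_fn <- function(mm) {
    p <- plantsense:::nn_forward(mm, x, training = FALSE)$out
    -mean(rowSums(Y * log(p + 1e-12)))
  }
  fw <- plantsense:::nn_forward(m, x, training = FALSE)
  dz <- (fw$out - Y) / n
  grads <- vector("list", length(m$layers))
  dout <- dz
  for (i in rev(seq_along(m$layers))) {
    bk <- plantsense:::layer_backward(m$layers[[i]], fw$caches[[i]], dout,
                                      dout_is_dz = (i == length(m$layers)))
    grads[i] <- list(bk$grads)
    dout <- bk$dx
  }
  worst <- 0
  for (i in seq_along(m$layers)) {
    if (is.null(grads[[i]])) next
    for (nm in names(grads[[i]])) {
      P <- m$layers[[i]]$params[[nm]]
      for (j in sample(seq_along(P), min(n_probe, length(P)))) {
        m2 <- m; m2$layers[[i]]$params[[nm]][j] <- P[j] + eps
        m3 <- m; m3$layers[[i]]$params[[nm]][j] <- P[j] - eps
        num <- (loss_fn(m2) - loss_fn(m3)) / (2 * eps)
        ana <- grads[[i]][[nm]][j]
        worst <- max(worst, abs(num - ana) / max(1e-8, abs(num) + abs(ana)))
      }
    }
  }
  worst
}

test_that("backpropagation matches finite differences for every layer type", {
  set.seed(1)
  expect_lt(nn_gradcheck(list(layer_dense(8, "relu"),
                              layer_dense(3, "softmax")),
                         6, matrix(rnorm(30), 5, 6)), 1e-6)
  expect_lt(nn_gradcheck(list(layer_dense(8, "swish"),
                              layer_dense(3, "softmax")),
                         6, matrix(rnorm(30), 5, 6)), 1e-6)
  expect_lt(nn_gradcheck(list(layer_conv1d(4, 3, "swish"),
                              layer_maxpool1d(2), layer_flatten(),
                              layer_dense(3, "softmax")),
                         c(12, 2), array(rnorm(5 * 12 * 2), c(5, 12, 2))),
            1e-6)
  expect_lt(nn_gradcheck(list(layer_conv2d(3, 3, "relu", "valid"),
                              layer_maxpool2d(2), layer_flatten(),
                              layer_dense(3, "softmax")),
                         c(8, 8, 2), array(rnorm(4 * 8 * 8 * 2),
                                           c(4, 8, 8, 2))), 1e-6)
  expect_lt(nn_gradcheck(list(layer_residual2d(5),
                              layer_global_avg_pool2d(),
                              layer_dense(3, "softmax")),
                         c(6, 6, 2), array(rnorm(4 * 6 * 6 * 2),
                                           c(4, 6, 6, 2))), 1e-6)
  expect_lt(nn_gradcheck(list(layer_bilstm(4, TRUE), layer_bilstm(3, FALSE),
                              layer_dense(3, "softmax")),
                         c(7, 2), array(rnorm(5 * 7 * 2), c(5, 7, 2))),
            1e-6)
})

test_that("training reduces loss and solves a separable problem", {
  set.seed(3)
  n <- 240; d <- 10
  y <- factor(sample(c("a", "b", "c"), n, TRUE), levels = c("a", "b", "c"))
  mu <- matrix(rnorm(3 * d, sd = 2), 3, d)
  x <- mu[as.integer(y), ] + matrix(rnorm(n * d, sd = 0.5), n, d)
  m <- nn_model(list(layer_dense(16, "relu"), layer_dense(3, "softmax")),
                d, 3, class_set = c("a", "b", "c"), seed = 1)
  m <- nn_fit(m, x, y, learning_rate = 1e-2, max_epochs = 30, seed = 2)
  expect_lt(utils::tail(m$history$train_loss, 1), m$history$train_loss[1])
  acc <- mean(predict_emotion(nn_predict_proba(m, x),
                              c("a", "b", "c")) == y)
  expect_gt(acc, 0.95)
})

test_that("early stopping restores the best validation epoch", {
  set.seed(5)
  n <- 120; d <- 6
  y <- factor(sample(c("a", "b"), n, TRUE), levels = c("a", "b"))
  x <- matrix(rnorm(n * d), n, d) + 2 * (as.integer(y) - 1.5)
  val_idx <- 1:40
  m <- nn_model(list(layer_dense(32, "relu"), layer_dense(2, "softmax")),
                d, 2, class_set = c("a", "b"), seed = 1)
  m <- nn_fit(m, x[-val_idx, ], y[-val_idx],
              validation = list(x = x[val_idx, ], y = y[val_idx]),
              learning_rate = 5e-2, max_epochs = 100, patience = 5,
              seed = 3)
  h <- m$history
  expect_gt(h$best_epoch, 0)
  # restored weights reproduce the best validation loss
  p <- plantsense:::nn_forward(m, x[val_idx, ], training = FALSE)$out
  Y <- matrix(0, 40, 2); Y[cbind(1:40, as.integer(y[val_idx]))] <- 1
  restored_loss <- -mean(rowSums(Y * log(p + 1e-12)))
  expect_equal(restored_loss, min(h$val_loss), tolerance = 1e-9)
  # stopping happened within patience of the best epoch
  expect_lte(length(h$val_loss), h$best_epoch + 5)
})

test_that("fits are deterministic under fixed seeds", {
  set.seed(7)
  x <- matrix(rnorm(200), 50, 4)
  y <- factor(rep(c("a", "b"), 25), levels = c("a", "b"))
  fit_once <- function() {
    m <- nn_model(list(layer_dense(8, "relu"), layer_dropout(0.2),
                       layer_dense(2, "softmax")),
                  4, 2, class_set = c("a", "b"), seed = 11)
    m <- nn_fit(m, x, y, learning_rate = 1e-2, max_epochs = 5, seed = 12)
    nn_predict_proba(m, x)
  }
  expect_identical(fit_once(), fit_once())
})
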