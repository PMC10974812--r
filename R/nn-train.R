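#' Assemble a neural classifier from layer descriptions
#'
#' Infers every layer's shape from `input_shape`, initializes parameters
#' (Glorot uniform, seeded), and returns an untrained model. The final layer
#' must be a softmax dense layer of `n_classes` units so the output is a
#' probability vector over the active class set.
#'
#' @param layers List of layer descriptions (see [layer_dense()] and
#'   friends).
#' @param input_shape Integer vector: `d`, `c(T, C)` or `c(H, W, C)`.
#' @param n_classes Number of output classes.
#' @param class_set Ordered class labels (length `n_classes`).
#' @param seed Integer seed for parameter initialization.
#' @return An `nn_model`.
#' @export
nn_model <- function(layers, input_shape, n_classes,
                     class_set = NULL, seed = 1L) {
  last <- layers[[length(layers)]]
  if (!identical(last$type, "dense") || !identical(last$activation, "softmax") ||
      last$units != n_classes) {
    stop("the final layer must be a softmax dense layer of n_classes units")
  }
  set.seed(as.integer(seed))
  shape <- as.integer(input_shape)
  for (i in seq_along(layers)) {
    layers[[i]] <- layer_init(layers[[i]], shape)
    shape <- layers[[i]]$out_shape
  }
  structure(list(layers = layers, input_shape = as.integer(input_shape),
                 n_classes = as.integer(n_classes), class_set = class_set,
                 trained = FALSE),
            class = "nn_model")
}

nn_forward <- function(model, x, training = FALSE) {
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    fw <- layer_forward(model$layers[[i]], x, training)
    x <- fw$out
    caches[[i]] <- fw$cache
  }
  list(out = x, caches = caches)
}

#' Class-probability predictions of a neural model
#'
#' @param model A trained `nn_model`.
#' @param x Input batch in the model's input shape (batch-first).
#' @return Matrix `[n, n_classes]` of probabilities (rows on the simplex).
#' @export
nn_predict_proba <- function(model, x) {
  p <- nn_forward(model, x, training = FALSE)$out
  colnames(p) <- model$class_set
  p
}

adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (is.null(l$params)) return(NULL)
    list(m = lapply(l$params, function(p) array(0, dim(p) %||% length(p))),
         v = lapply(l$params, function(p) array(0, dim(p) %||% length(p))))
  })
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      state[[i]]$m[[nm]] <- beta1 * state[[i]]$m[[nm]] + (1 - beta1) * g[[nm]]
      state[[i]]$v[[nm]] <- beta2 * state[[i]]$v[[nm]] + (1 - beta2) * g[[nm]]^2
      mhat <- state[[i]]$m[[nm]] / (1 - beta1^t)
      vhat <- state[[i]]$v[[nm]] / (1 - beta2^t)
      upd <- lr * mhat / (sqrt(vhat) + eps)
      layers[[i]]$params[[nm]] <- layers[[i]]$params[[nm]] - array(upd, dim(layers[[i]]$params[[nm]]) %||% length(upd))
    }
  }
  list(layers = layers, state = state)
}

one_hot <- function(y, n_classes) {
  m <- matrix(0, length(y), n_classes)
  m[cbind(seq_along(y), as.integer(y))] <- 1
  m
}

slice_batch <- function(x, idx) {
  nd <- length(dim(x))
  if (nd == 2L) x[idx, , drop = FALSE]
  else if (nd == 3L) x[idx, , , drop = FALSE]
  else x[idx, , , , drop = FALSE]
}

# Weighted categorical cross-entropy and its fused softmax gradient.
ce_loss <- function(p, Y, w) {
  eps <- 1e-12
  li <- -rowSums(Y * log(p + eps))
  sum(w * li) / sum(w)
}

#' Train a neural model
#'
#' Minibatch training with the Adam optimizer under (optionally
#' class-weighted) categorical cross-entropy, with early stopping on the
#' validation loss: when the validation loss has not improved for `patience`
#' epochs, training stops and the best-epoch weights are restored.
#'
#' @param model An `nn_model`.
#' @param x,y Training inputs (batch-first) and labels (factor over the
#'   model's class set).
#' @param validation Optional `list(x = , y = )` used for early stopping.
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size (default 64).
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience in epochs.
#' @param class_weights Optional named per-class loss weights.
#' @param seed Seed for shuffling/dropout.
#' @param verbose Print per-epoch losses?
#' @return The trained `nn_model`, with a `history` element (per-epoch train
#'   and validation loss, `best_epoch`, `diverged` flag).
#' @export
nn_fit <- function(model, x, y, validation = NULL, learning_rate = 1e-3,
                   batch_size = 64, max_epochs = 50, patience = 10,
                   class_weights = NULL, seed = 1L, verbose = FALSE) {
  y <- factor(y, levels = model$class_set %||% levels(y))
  n <- dim(x)[1]
  stopifnot(length(y) == n)
  Y <- one_hot(y, model$n_classes)
  w <- if (is.null(class_weights)) {
    rep(1, n)
  } else {
    as.numeric(class_weights[as.character(y)])
  }
  has_val <- !is.null(validation)
  if (has_val) {
    yv <- factor(validation$y, levels = levels(y))
    Yv <- one_hot(yv, model$n_classes)
  }
  set.seed(as.integer(seed))
  state <- adam_init(model$layers)
  step <- 0L
  best_loss <- Inf
  best_params <- NULL
  best_epoch <- 0L
  wait <- 0L
  hist <- list(train_loss = numeric(0), val_loss = numeric(0))
  diverged <- FALSE
  for (epoch in seq_len(max_epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_wsum <- 0
    for (b0 in seq(1L, n, by = batch_size)) {
      idx <- ord[b0:min(b0 + batch_size - 1L, n)]
      xb <- slice_batch(x, idx)
      Yb <- Y[idx, , drop = FALSE]
      wb <- w[idx]
      fw <- nn_forward(model, xb, training = TRUE)
      p <- fw$out
      loss <- ce_loss(p, Yb, wb)
      if (!is.finite(loss)) { diverged <- TRUE; break }
      ep_loss <- ep_loss + loss * sum(wb)
      ep_wsum <- ep_wsum + sum(wb)
      # fused softmax + CE gradient, sample-weighted
      dz <- (p - Yb) * (wb / sum(wb))
      grads <- vector("list", length(model$layers))
      dout <- dz
      for (i in rev(seq_along(model$layers))) {
        bk <- layer_backward(model$layers[[i]], fw$caches[[i]], dout,
                             dout_is_dz = (i == length(model$layers)))
        grads[i] <- list(bk$grads)   # keep NULL slots for param-free layers
        dout <- bk$dx
      }
      step <- step + 1L
      upd <- adam_step(model$layers, grads, state, learning_rate, step)
      model$layers <- upd$layers
      state <- upd$state
    }
    if (diverged) break
    hist$train_loss <- c(hist$train_loss, ep_loss / ep_wsum)
    if (has_val) {
      pv <- nn_forward(model, validation$x, training = FALSE)$out
      vl <- ce_loss(pv, Yv, rep(1, nrow(Yv)))
      hist$val_loss <- c(hist$val_loss, vl)
      if (vl < best_loss - 1e-9) {
        best_loss <- vl
        best_params <- lapply(model$layers, function(l) l$params)
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
    if (verbose) {
      cat(sprintf("epoch %d: train %.4f%s\n", epoch,
                  utils::tail(hist$train_loss, 1),
                  if (has_val) sprintf(", val %.4f", utils::tail(hist$val_loss, 1)) else ""))
    }
  }
  if (has_val && !is.null(best_params)) {
    for (i in seq_along(model$layers)) {
      model$layers[[i]]$params <- best_params[[i]]
    }
  }
  model$trained <- TRUE
  model$history <- c(hist, list(best_epoch = best_epoch, diverged = diverged))
  model
}
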