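model_families <- function() {
  c("MLP", "BiLSTM", "MFCC_CNN", "MFCC_ResNet", "RF", "CNN1D", "BiLSTM_raw")
}

# Which hyperparameters each family understands (data-prep knobs included).
family_fields <- list(
  MLP = c("dense_units", "dense_layers", "dropout_rate", "learning_rate",
          "balancing", "window", "hop"),
  BiLSTM = c("lstm_units", "lstm_layers", "dropout_rate", "learning_rate",
             "balancing", "window", "hop"),
  MFCC_CNN = c("conv_filters", "conv_layers", "conv_kernel_size",
               "dropout_rate", "learning_rate", "balancing", "window", "hop"),
  MFCC_ResNet = c("pretrained", "n_mfcc", "dropout_rate", "learning_rate",
                  "balancing", "window", "hop"),
  RF = c("n_estimators", "max_depth", "balancing"),
  CNN1D = c("filters", "conv_layers", "kernel_size", "dropout_rate",
            "learning_rate", "balancing"),
  BiLSTM_raw = c("lstm_units", "lstm_layers", "dropout_rate",
                 "learning_rate", "balancing")
)

#' Declare one model configuration
#'
#' A `model_spec` names a classifier family and its hyperparameters
#' (architecture, learning rate, balancing policy and — for the windowed
#' families — the data-preparation `window`/`hop`). Values are validated
#' field by field; an out-of-domain value raises an error naming the field.
#'
#' @param family One of `"MLP"`, `"BiLSTM"`, `"MFCC_CNN"`, `"MFCC_ResNet"`,
#'   `"RF"`, `"CNN1D"`, `"BiLSTM_raw"`.
#' @param ... Family-specific hyperparameters, e.g. `dense_units`,
#'   `lstm_layers`, `conv_filters`, `n_mfcc`, `n_estimators`, `balancing`.
#' @return A `model_spec` list.
#' @export
model_spec <- function(family, ...) {
  family <- match.arg(family, model_families())
  hp <- list(...)
  allowed <- family_fields[[family]]
  extra <- setdiff(names(hp), allowed)
  if (length(extra) > 0L) {
    stop("hyperparameter(s) not valid for family ", family, ": ",
         paste(extra, collapse = ", "))
  }
  check <- function(field, ok) {
    if (!is.null(hp[[field]]) && !ok(hp[[field]])) {
      stop("invalid value for hyperparameter '", field, "'")
    }
  }
  pos_int <- function(v) is.numeric(v) && length(v) == 1L && v >= 1
  check("dense_units", pos_int); check("dense_layers", pos_int)
  check("lstm_units", pos_int);  check("lstm_layers", pos_int)
  check("conv_filters", pos_int); check("conv_layers", pos_int)
  check("conv_kernel_size", pos_int); check("filters", pos_int)
  check("kernel_size", pos_int); check("n_mfcc", pos_int)
  check("n_estimators", pos_int)
  check("max_depth", function(v) is.na(v) || pos_int(v))
  check("dropout_rate", function(v) is.numeric(v) && v >= 0 && v < 1)
  check("learning_rate", function(v) is.numeric(v) && v > 0)
  check("window", function(v) is.numeric(v) && v > 0)
  check("hop", function(v) is.numeric(v) && v > 0)
  check("pretrained", function(v) is.logical(v) && length(v) == 1L)
  check("balancing", function(v) v %in% c("balance", "weights", "none"))
  structure(c(list(family = family), hp), class = "model_spec")
}

#' Grid-search-selected configuration of a family
#'
#' The hyperparameters chosen by the grid search for each family: e.g. MLP
#' with 2 dense layers of 4096 units and dropout 0.2 at window 20 s / hop
#' 10 s; RF with 300 trees of depth 20 and no balancing; both CNN families
#' with 96 filters (2 layers, kernel 7).
#'
#' @param family Model family name.
#' @return A [model_spec()].
#' @export
selected_spec <- function(family) {
  family <- match.arg(family, model_families())
  switch(family,
    MLP = model_spec("MLP", dense_units = 4096, dense_layers = 2,
                     dropout_rate = 0.2, learning_rate = 1e-3,
                     balancing = "balance", window = 20, hop = 10),
    BiLSTM = model_spec("BiLSTM", lstm_units = 1024, lstm_layers = 2,
                        dropout_rate = 0, learning_rate = 3e-4,
                        balancing = "balance", window = 20, hop = 10),
    MFCC_CNN = model_spec("MFCC_CNN", conv_filters = 96, conv_layers = 2,
                          conv_kernel_size = 7, dropout_rate = 0.2,
                          learning_rate = 3e-4, balancing = "balance",
                          window = 20, hop = 10),
    MFCC_ResNet = model_spec("MFCC_ResNet", pretrained = FALSE, n_mfcc = 60,
                             dropout_rate = 0.2, learning_rate = 1e-3,
                             balancing = "balance", window = 20, hop = 10),
    RF = model_spec("RF", n_estimators = 300, max_depth = 20,
                    balancing = "none"),
    CNN1D = model_spec("CNN1D", filters = 96, conv_layers = 2,
                       kernel_size = 7, dropout_rate = 0.2,
                       learning_rate = 3e-4, balancing = "none"),
    BiLSTM_raw = model_spec("BiLSTM_raw", lstm_units = 1024, lstm_layers = 2,
                            dropout_rate = 0, learning_rate = 3e-4,
                            balancing = "none"))
}

#' Build a trainable classifier from a spec
#'
#' Constructs the family's architecture:
#' * `MLP` — alternating ReLU dense + dropout blocks, softmax head;
#' * `BiLSTM` — a stack of bidirectional LSTM layers, then ReLU dense layers
#'   of 1024 and 512 units with dropout, softmax head;
#' * `MFCC_CNN` — ReLU 2-D convolution blocks with 2x2 max pooling, a ReLU
#'   dense layer with dropout, softmax head;
#' * `MFCC_ResNet` — a compact residual 2-D CNN backbone, global average
#'   pooling, dense 1024 + dropout, softmax head (`pretrained = TRUE`
#'   requires `pretrained_weights`, a path to previously saved backbone
#'   parameters);
#' * `RF` — a random-forest ensemble (trained lazily by [train_model()]);
#' * `CNN1D` — swish 1-D convolution + max-pooling blocks, flatten, swish
#'   dense 100, softmax head;
#' * `BiLSTM_raw` — stacked bidirectional LSTMs, swish dense 100, softmax
#'   head.
#'
#' @param spec A [model_spec()].
#' @param input_shape Input shape excluding the batch axis (`d`, `c(T, C)`
#'   or `c(H, W, C)`).
#' @param nbemotion Number of output classes.
#' @param class_set Ordered class labels.
#' @param seed Seed for weight initialization.
#' @param pretrained_weights Optional RDS path of saved layer parameters for
#'   `MFCC_ResNet` with `pretrained = TRUE`.
#' @return An `nn_model` (neural families) or an `rf_model` shell (RF).
#' @export
build_model <- function(spec, input_shape, nbemotion,
                        class_set = NULL, seed = 1L,
                        pretrained_weights = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  fam <- spec$family
  head_softmax <- layer_dense(nbemotion, "softmax")
  if (fam == "RF") {
    return(structure(list(spec = spec, nbemotion = nbemotion,
                          class_set = class_set, seed = as.integer(seed),
                          fit = NULL, trained = FALSE),
                     class = "rf_model"))
  }
  layers <- switch(fam,
    MLP = {
      stopifnot(length(input_shape) == 1L)
      blocks <- list()
      for (i in seq_len(spec$dense_layers)) {
        blocks <- c(blocks, list(layer_dense(spec$dense_units, "relu"),
                                 layer_dropout(spec$dropout_rate)))
      }
      c(blocks, list(head_softmax))
    },
    BiLSTM = {
      stopifnot(length(input_shape) == 2L)
      blocks <- list()
      for (i in seq_len(spec$lstm_layers)) {
        blocks <- c(blocks, list(
          layer_bilstm(spec$lstm_units,
                       return_sequences = i < spec$lstm_layers)))
      }
      c(blocks,
        list(layer_dense(1024, "relu"), layer_dropout(spec$dropout_rate),
             layer_dense(512, "relu"), layer_dropout(spec$dropout_rate),
             head_softmax))
    },
    MFCC_CNN = {
      stopifnot(length(input_shape) == 3L)
      blocks <- list()
      for (i in seq_len(spec$conv_layers)) {
        blocks <- c(blocks, list(
          layer_conv2d(spec$conv_filters, spec$conv_kernel_size, "relu",
                       padding = "same"),
          layer_maxpool2d(2)))
      }
      c(blocks,
        list(layer_flatten(), layer_dense(256, "relu"),
             layer_dropout(spec$dropout_rate), head_softmax))
    },
    MFCC_ResNet = {
      stopifnot(length(input_shape) == 3L)
      list(layer_conv2d(16, 3, "relu", padding = "same"),
           layer_residual2d(16), layer_residual2d(16),
           layer_maxpool2d(2),
           layer_residual2d(32), layer_residual2d(32),
           layer_global_avg_pool2d(),
           layer_dense(1024, "relu"), layer_dropout(spec$dropout_rate),
           head_softmax)
    },
    CNN1D = {
      stopifnot(length(input_shape) == 2L)
      blocks <- list()
      for (i in seq_len(spec$conv_layers)) {
        blocks <- c(blocks, list(
          layer_conv1d(spec$filters, spec$kernel_size, "swish"),
          layer_maxpool1d(2)))
      }
      c(blocks,
        list(layer_flatten(), layer_dense(100, "swish"),
             layer_dropout(spec$dropout_rate), head_softmax))
    },
    BiLSTM_raw = {
      stopifnot(length(input_shape) == 2L)
      blocks <- list()
      for (i in seq_len(spec$lstm_layers)) {
        blocks <- c(blocks, list(
          layer_bilstm(spec$lstm_units,
                       return_sequences = i < spec$lstm_layers)))
      }
      c(blocks, list(layer_dense(100, "swish"), head_softmax))
    })
  model <- nn_model(layers, input_shape, nbemotion, class_set, seed)
  model$spec <- spec
  if (fam == "MFCC_ResNet" && isTRUE(spec$pretrained)) {
    if (is.null(pretrained_weights)) {
      stop("pretrained = TRUE requires 'pretrained_weights' (a path to ",
           "saved backbone parameters); none supplied")
    }
    saved <- readRDS(pretrained_weights)
    for (i in seq_along(saved)) {
      if (!is.null(saved[[i]])) model$layers[[i]]$params <- saved[[i]]
    }
  }
  model
}

#' Rebalance a training set or derive class weights
#'
#' `mode = "balance"` resamples every class to the mean per-class count:
#' rare classes are oversampled with replacement, majority classes
#' undersampled without. `mode = "weights"` leaves the data untouched and
#' returns loss weights `w_c = N / (nbclass * n_c)` (so
#' `sum_c n_c w_c = N`). `mode = "none"` is the identity. Balancing is meant
#' for training folds only.
#'
#' @param train_set A [feature_dataset()].
#' @param mode `"balance"`, `"weights"` or `"none"`.
#' @param seed Seed for resampling.
#' @param target `"mean"` (default) or `"median"` per-class target count
#'   for `mode = "balance"`.
#' @return List with `data` (a [feature_dataset()]) and `class_weights`
#'   (named numeric or `NULL`).
#' @export
apply_balancing <- function(train_set, mode = c("none", "balance", "weights"),
                            seed = 1L, target = c("mean", "median")) {
  mode <- match.arg(mode)
  target <- match.arg(target)
  if (mode == "none") {
    return(list(data = train_set, class_weights = NULL))
  }
  # classes are counted over those present in the training data: a CV
  # training fold need not contain every class of the full class set
  counts <- table(droplevels(train_set$y))
  if (length(counts) == 0L || sum(counts) == 0L) {
    stop("empty class under '", mode, "' balancing")
  }
  if (mode == "weights") {
    n <- sum(counts)
    w <- n / (length(counts) * as.numeric(counts))
    names(w) <- names(counts)
    return(list(data = train_set, class_weights = w))
  }
  tgt <- if (target == "mean") {
    as.integer(round(mean(counts)))
  } else {
    as.integer(round(stats::median(counts)))
  }
  set.seed(as.integer(seed))
  idx <- unlist(lapply(names(counts), function(cl) {
    pool <- which(as.character(train_set$y) == cl)
    if (length(pool) >= tgt) {
      sample(pool, tgt, replace = FALSE)
    } else {
      c(pool, sample(pool, tgt - length(pool), replace = TRUE))
    }
  }))
  idx <- sort(idx)
  out <- feature_dataset(slice_batch(train_set$x, idx),
                         as.character(train_set$y)[idx],
                         train_set$class_set, train_set$track,
                         if (!is.null(train_set$meta)) {
                           train_set$meta[idx, , drop = FALSE]
                         })
  list(data = out, class_weights = NULL)
}

#' Reshape a feature dataset to a family's input contract
#'
#' MLP consumes flat vectors; the sequence models consume `(time, 1)`
#' arrays; MFCC_CNN consumes `(time_steps, n_mfcc, 1)`; MFCC_ResNet consumes
#' `(h, w, 3)` images; RF consumes the flat matrix.
#'
#' @param ds A [feature_dataset()].
#' @param family Model family name.
#' @return List with `x` (reshaped array/matrix) and `input_shape`.
#' @export
model_input <- function(ds, family) {
  family <- match.arg(family, model_families())
  d <- dim(ds$x)
  if (family %in% c("MLP", "RF")) {
    x <- if (length(d) == 2L) ds$x else matrix(ds$x, d[1], prod(d[-1]))
    return(list(x = x, input_shape = ncol(x)))
  }
  if (family %in% c("BiLSTM", "CNN1D", "BiLSTM_raw")) {
    stopifnot(length(d) == 2L)
    return(list(x = array(ds$x, c(d[1], d[2], 1L)),
                input_shape = c(d[2], 1L)))
  }
  if (family == "MFCC_CNN") {
    stopifnot(length(d) == 3L)
    return(list(x = array(ds$x, c(d, 1L)), input_shape = c(d[-1], 1L)))
  }
  # MFCC_ResNet
  stopifnot(length(d) == 4L)
  list(x = ds$x, input_shape = d[-1])
}

#' Train a built model on a feature dataset
#'
#' Neural families train with [nn_fit()] (Adam, categorical cross-entropy,
#' minibatch 64, early stopping on the validation loss). The RF family fits
#' a random forest directly (no epochs or loss; the early-stopping fields
#' are ignored).
#'
#' @param model An `nn_model` or `rf_model` from [build_model()].
#' @param train A [feature_dataset()] (already balanced if desired).
#' @param validation Optional [feature_dataset()] for early stopping.
#' @param config A [train_config()].
#' @param class_weights Optional named per-class loss weights.
#' @return The trained model.
#' @export
train_model <- function(model, train, validation = NULL,
                        config = train_config(), class_weights = NULL) {
  if (inherits(model, "rf_model")) {
    inp <- model_input(train, "RF")
    colnames(inp$x) <- paste0("s", seq_len(ncol(inp$x)))
    cw <- if (!is.null(class_weights)) {
      as.numeric(class_weights[train$class_set])
    }
    md <- model$spec$max_depth
    model$fit <- ranger::ranger(
      x = inp$x, y = factor(train$y, levels = train$class_set),
      num.trees = model$spec$n_estimators,
      max.depth = if (!is.null(md) && !is.na(md)) as.integer(md) else NULL,
      class.weights = cw, probability = TRUE,
      seed = model$seed, num.threads = 1L)
    model$trained <- TRUE
    return(model)
  }
  fam <- model$spec$family
  inp <- model_input(train, fam)
  val <- if (!is.null(validation)) {
    list(x = model_input(validation, fam)$x,
         y = factor(validation$y, levels = train$class_set))
  }
  nn_fit(model, inp$x, factor(train$y, levels = train$class_set),
         validation = val,
         learning_rate = model$spec$learning_rate %||% config$learning_rate,
         batch_size = config$batch_size, max_epochs = config$max_epochs,
         patience = config$patience, class_weights = class_weights,
         seed = config$seed)
}

#' Class-probability predictions for any trained model
#'
#' RF vote fractions are treated as the probability vector, on the same
#' footing as the neural softmax outputs.
#'
#' @param model Trained model from [train_model()].
#' @param ds A [feature_dataset()].
#' @return Matrix `[n, nbemotion]` of probabilities.
#' @export
predict_proba <- function(model, ds) {
  if (inherits(model, "rf_model")) {
    stopifnot(model$trained)
    inp <- model_input(ds, "RF")
    colnames(inp$x) <- paste0("s", seq_len(ncol(inp$x)))
    p <- stats::predict(model$fit, data = inp$x,
                        num.threads = 1L)$predictions
    return(p[, model$class_set, drop = FALSE])
  }
  inp <- model_input(ds, model$spec$family)
  nn_predict_proba(model, inp$x)
}

#' Map a probability vector to an emotion
#'
#' Argmax classification: the predicted class is the one with the highest
#' probability; exact ties break toward the lowest class index
#' (deterministic).
#'
#' @param probabilities Numeric probability vector or `[n, nbemotion]`
#'   matrix (rows on the simplex).
#' @param class_set Ordered class labels.
#' @return Factor of predicted emotions.
#' @export
predict_emotion <- function(probabilities, class_set) {
  p <- if (is.matrix(probabilities)) probabilities else rbind(probabilities)
  if (ncol(p) != length(class_set)) {
    stop("probability vector width does not match the class set")
  }
  if (any(!is.finite(p)) || any(p < -1e-9) ||
      any(abs(rowSums(p) - 1) > 1e-6)) {
    stop("malformed probability vector: entries must be a simplex")
  }
  idx <- apply(p, 1L, which.max)           # first maximum = lowest index
  factor(class_set[idx], levels = class_set)
}
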