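#' The hyperparameter search grid of a model family
#'
#' The full grids searched for each family. Axis order follows the printed
#' synthesis: architecture axes first, then dropout, learning rate,
#' balancing, and (for the windowed families) window and hop. The Cartesian
#' product sizes are 288 (MLP), 648 (BiLSTM), 864 (MFCC_CNN), 432
#' (MFCC_ResNet), 60 (RF), 144 (CNN1D) and 108 (BiLSTM_raw).
#'
#' @param family Model family name.
#' @return A `hyper_grid`: list with `family` and `axes` (named list of
#'   candidate-value vectors).
#' @export
hyper_grid <- function(family) {
  family <- match.arg(family, model_families())
  lr <- c(3e-4, 1e-3)
  bal <- c("balance", "weights", "none")
  win <- c(5, 10, 20)
  hop <- c(5, 10)
  axes <- switch(family,
    MLP = list(dense_units = c(1024, 4096), dense_layers = c(2, 4),
               dropout_rate = c(0, 0.2), learning_rate = lr,
               balancing = bal, window = win, hop = hop),
    BiLSTM = list(lstm_units = c(64, 256, 1024), lstm_layers = c(1, 2, 3),
                  dropout_rate = c(0, 0.2), learning_rate = lr,
                  balancing = bal, window = win, hop = hop),
    MFCC_CNN = list(conv_filters = c(64, 128), conv_layers = c(2, 3),
                    conv_kernel_size = c(3, 5, 7), dropout_rate = c(0, 0.2),
                    learning_rate = lr, balancing = bal, window = win,
                    hop = hop),
    MFCC_ResNet = list(pretrained = c(TRUE, FALSE), n_mfcc = c(20, 40, 60),
                       dropout_rate = c(0, 0.2), learning_rate = lr,
                       balancing = bal, window = win, hop = hop),
    RF = list(n_estimators = c(100, 200, 300, 500, 700),
              max_depth = c(NA, 10, 20, 30), balancing = bal),
    CNN1D = list(filters = c(64, 128), conv_layers = c(2, 3),
                 kernel_size = c(3, 5, 7), dropout_rate = c(0, 0.2),
                 learning_rate = lr, balancing = bal),
    BiLSTM_raw = list(lstm_units = c(64, 256, 1024), lstm_layers = c(1, 2, 3),
                      dropout_rate = c(0, 0.2), learning_rate = lr,
                      balancing = bal))
  structure(list(family = family, axes = axes), class = "hyper_grid")
}

#' Enumerate every configuration of a grid
#'
#' Full Cartesian product of the grid axes in deterministic lexicographic
#' order (the first axis varies slowest). The count equals the product of
#' the axis sizes.
#'
#' @param grid A [hyper_grid()].
#' @return List of [model_spec()]s.
#' @export
enumerate_grid <- function(grid) {
  stopifnot(inherits(grid, "hyper_grid"))
  sizes <- vapply(grid$axes, length, integer(1))
  if (any(sizes == 0L)) {
    stop("empty grid axis: ", names(sizes)[sizes == 0L][1])
  }
  combos <- rev(expand.grid(rev(grid$axes), stringsAsFactors = FALSE,
                            KEEP.OUT.ATTRS = FALSE))
  lapply(seq_len(nrow(combos)), function(i) {
    do.call(model_spec, c(list(family = grid$family), as.list(combos[i, ])))
  })
}

#' Number of configurations in a grid
#' @param grid A [hyper_grid()].
#' @return Integer product of axis sizes.
#' @export
grid_size <- function(grid) {
  prod(vapply(grid$axes, length, integer(1)))
}

#' Training-loop configuration
#'
#' @param batch_size Minibatch size (64 throughout the study).
#' @param max_epochs Epoch cap (50 during the grid search, 1000 for final
#'   training).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param learning_rate Fallback Adam learning rate when the model spec does
#'   not carry one.
#' @param seed Integer seed for shuffling, dropout and initialization.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 64, max_epochs = 50, patience = 10,
                         learning_rate = 1e-3, seed = 1L) {
  stopifnot(batch_size >= 1, max_epochs >= 1, patience >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "train_config")
}
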