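#' Build a five-fold cross-validation plan with role rotation
#'
#' Items (or whole participants, under participant grouping) are shuffled
#' and split into `k` near-equal folds. Each of the `k` rotations assigns
#' one fold as the test set, the next as the validation set, and the
#' remaining `k - 2` folds as the training set — a 60/20/20 split at
#' `k = 5`. Across the rotations every fold serves exactly once as the test
#' set, so the whole dataset is tested exactly once.
#'
#' @param dataset A [feature_dataset()] (or any object with `$meta`).
#' @param k Number of folds (default 5).
#' @param grouping `"window"` (split items independently) or
#'   `"participant"` (no participant spans folds; requires
#'   `meta$participant_id`).
#' @param seed Shuffle seed.
#' @return A `fold_plan`: list with `fold` (integer per item), `k`,
#'   `grouping`, and `rotations` (list of `list(train, validation, test)`
#'   index vectors).
#' @export
make_folds <- function(dataset, k = 5, grouping = c("participant", "window"),
                       seed = 1L) {
  grouping <- match.arg(grouping)
  n <- n_examples(dataset)
  set.seed(as.integer(seed))
  if (grouping == "participant") {
    if (is.null(dataset$meta$participant_id)) {
      stop("participant grouping requires meta$participant_id")
    }
    pids <- unique(dataset$meta$participant_id)
    if (length(pids) < k) {
      stop("fewer participants (", length(pids), ") than folds (", k, ")")
    }
    pid_fold <- stats::setNames(rep(seq_len(k), length.out = length(pids)),
                                sample(pids))
    fold <- as.integer(pid_fold[dataset$meta$participant_id])
  } else {
    if (n < k) stop("fewer items (", n, ") than folds (", k, ")")
    sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
    fold <- integer(n)
    fold[sample.int(n)] <- rep(seq_len(k), times = sizes)
  }
  if (any(tabulate(fold, k) == 0L)) stop("empty fold produced")
  rotations <- lapply(seq_len(k), function(r) {
    test_f <- r
    val_f <- r %% k + 1L
    list(train = which(!fold %in% c(test_f, val_f)),
         validation = which(fold == val_f),
         test = which(fold == test_f))
  })
  structure(list(fold = fold, k = as.integer(k), grouping = grouping,
                 rotations = rotations),
            class = "fold_plan")
}

#' Undersample a dataset to equal class counts
#'
#' Draws, without replacement, `min(class counts)` items from every class.
#' Unlike the `"balance"` training policy this never duplicates rows, so it
#' is safe to apply before fold construction — used for chance-level
#' calibration runs, where the class prior must carry no information.
#'
#' @param ds A [feature_dataset()].
#' @param seed Sampling seed.
#' @return A class-balanced [feature_dataset()].
#' @export
balanced_subsample <- function(ds, seed = 1L) {
  counts <- table(ds$y)
  if (any(counts == 0)) stop("empty class in the dataset")
  m <- min(counts)
  set.seed(as.integer(seed))
  idx <- sort(unlist(lapply(names(counts), function(cl) {
    sample(which(as.character(ds$y) == cl), m)
  })))
  subset_dataset(ds, idx)
}

subset_dataset <- function(ds, idx) {
  feature_dataset(slice_batch(ds$x, idx), as.character(ds$y)[idx],
                  ds$class_set, ds$track,
                  if (!is.null(ds$meta)) ds$meta[idx, , drop = FALSE])
}
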