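#' A model-ready feature dataset
#'
#' @param x Numeric matrix `[n, d]` (flat vectors) or array
#'   `[n, ...]` (sequences/images).
#' @param y Emotion labels (one per row).
#' @param class_set Ordered active class set.
#' @param track One of `"downsampled"`, `"mfcc"`, `"raw_1s"`, `"image"`.
#' @param meta Optional per-item metadata data frame.
#' @return A `feature_dataset`.
#' @export
feature_dataset <- function(x, y, class_set, track, meta = NULL) {
  n <- dim(x)[1]
  y <- as_emotion(y, class_set)
  stopifnot(length(y) == n)
  structure(list(x = x, y = y, class_set = class_set,
                 nbemotion = length(class_set), track = track, meta = meta),
            class = "feature_dataset")
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat(sprintf("<feature_dataset '%s': n = %d, shape = [%s], %d classes>\n",
              x$track, dim(x$x)[1],
              paste(dim(x$x)[-1], collapse = " x "), x$nbemotion))
  invisible(x)
}

n_examples <- function(ds) dim(ds$x)[1]

#' Build the downsampled-window dataset
#'
#' Downsamples every labeled window to `target_rate` and flattens it into a
#' fixed-length vector of `window_seconds * target_rate` samples — the input
#' of the MLP (flat) and of the windowed biLSTM (reshaped to `(time, 1)` by
#' the model builder).
#'
#' @param labeled A [labeled_window_set()] of `signal_window`s.
#' @param target_rate Target rate in Hz (e.g. 500).
#' @param method Downsampling method, see [downsample()].
#' @return A [feature_dataset()] with `track = "downsampled"`.
#' @export
build_downsampled_dataset <- function(labeled, target_rate, method = "fir") {
  stopifnot(inherits(labeled, "labeled_window_set"))
  windows <- labeled$items
  if (length(windows) == 0L) {
    return(feature_dataset(matrix(numeric(0), 0, 0),
                           character(0), labeled$class_set, "downsampled"))
  }
  lens <- vapply(windows, function(w) length(w$samples), integer(1))
  if (length(unique(lens)) != 1L) {
    stop("heterogeneous window lengths in the labeled set")
  }
  rows <- lapply(windows, function(w) {
    downsample(w$samples, target_rate, w$sample_rate, method)
  })
  x <- do.call(rbind, rows)
  feature_dataset(x, as.character(labeled$labels), labeled$class_set,
                  "downsampled", labeled$meta)
}

#' Build the MFCC dataset
#'
#' Computes an MFCC matrix per labeled window; all windows share a length so
#' all matrices share a `[time_steps, n_mfcc]` shape, stacked into an array
#' `[n, time_steps, n_mfcc]` — the input of the MFCC-CNN and (via
#' [mfcc_to_image()]) the MFCC-ResNet.
#'
#' @param labeled A [labeled_window_set()] of `signal_window`s.
#' @param n_mfcc Number of coefficients.
#' @param ... Passed to [mfcc_features()].
#' @return A [feature_dataset()] with `track = "mfcc"`.
#' @export
build_mfcc_dataset <- function(labeled, n_mfcc = 20, ...) {
  stopifnot(inherits(labeled, "labeled_window_set"))
  mats <- lapply(labeled$items, mfcc_features, n_mfcc = n_mfcc, ...)
  ts <- unique(vapply(mats, nrow, integer(1)))
  if (length(ts) != 1L) stop("heterogeneous window lengths in the labeled set")
  x <- array(0, c(length(mats), ts, n_mfcc))
  for (i in seq_along(mats)) x[i, , ] <- mats[[i]]
  feature_dataset(x, as.character(labeled$labels), labeled$class_set,
                  "mfcc", labeled$meta)
}

#' Build the raw one-second dataset
#'
#' One fixed-length vector per labeled z-normalized 1-s segment at the
#' native rate (10,000 samples at 10 kHz). The neural raw-track models
#' consume these rows reshaped to `(samples, 1)`.
#'
#' @param labeled A [labeled_window_set()] whose items are a segment matrix
#'   (from [label_windows()] on a `segment_set`).
#' @return A [feature_dataset()] with `track = "raw_1s"`.
#' @export
build_raw_dataset <- function(labeled) {
  stopifnot(inherits(labeled, "labeled_window_set"),
            is.matrix(labeled$items))
  feature_dataset(labeled$items, as.character(labeled$labels),
                  labeled$class_set, "raw_1s", labeled$meta)
}

# Two-pass separable bilinear interpolation of a matrix to a target size.
resize_bilinear <- function(m, out_rows, out_cols) {
  r_in <- nrow(m); c_in <- ncol(m)
  interp_axis <- function(mat, n_out) {
    n_in <- nrow(mat)
    if (n_in == n_out) return(mat)
    if (n_in == 1L) return(mat[rep(1L, n_out), , drop = FALSE])
    xi <- seq(1, n_in, length.out = n_out)
    apply(mat, 2L, function(col) stats::approx(seq_len(n_in), col, xi)$y)
  }
  m <- interp_axis(m, out_rows)
  t(interp_axis(t(m), out_cols))
}

#' Adapt an MFCC matrix to a 3-channel image tensor
#'
#' Min-max scales the matrix to `[0, 1]`, resizes it bilinearly to
#' `target_shape`, and replicates it across 3 channels — the input contract
#' of the ResNet-style image backbone. A constant (degenerate) matrix maps
#' to all zeros with a warning.
#'
#' @param m An `mfcc_matrix` or plain numeric matrix.
#' @param target_shape Integer `c(height, width)`.
#' @return Array `[height, width, 3]` in `[0, 1]`.
#' @export
mfcc_to_image <- function(m, target_shape) {
  m <- unclass(m)
  rng <- range(m)
  if (diff(rng) == 0) {
    warning("constant MFCC matrix: emitting a zero image")
    scaled <- matrix(0, nrow(m), ncol(m))
  } else {
    scaled <- (m - rng[1]) / diff(rng)
  }
  resized <- resize_bilinear(scaled, target_shape[1], target_shape[2])
  array(rep(resized, 3L), c(target_shape[1], target_shape[2], 3L))
}

#' Build the MFCC-image dataset for the ResNet track
#'
#' @param mfcc_ds A [feature_dataset()] with `track = "mfcc"`.
#' @param target_shape Integer `c(height, width)` of the image input.
#' @return A [feature_dataset()] with `track = "image"`, array
#'   `[n, height, width, 3]`.
#' @export
build_image_dataset <- function(mfcc_ds, target_shape = c(32, 32)) {
  stopifnot(identical(mfcc_ds$track, "mfcc"))
  n <- n_examples(mfcc_ds)
  x <- array(0, c(n, target_shape[1], target_shape[2], 3L))
  for (i in seq_len(n)) {
    x[i, , , ] <- mfcc_to_image(mfcc_ds$x[i, , ], target_shape)
  }
  feature_dataset(x, as.character(mfcc_ds$y), mfcc_ds$class_set, "image",
                  mfcc_ds$meta)
}
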