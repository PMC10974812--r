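hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filterbank
#'
#' @param n_mels Number of triangular filters.
#' @param n_fft FFT length.
#' @param sample_rate Sampling rate in Hz.
#' @param fmin,fmax Frequency range (Hz); `fmax` defaults to Nyquist.
#' @return Matrix `[n_mels, n_fft/2 + 1]` of filter weights.
#' @export
mel_filterbank <- function(n_mels, n_fft, sample_rate, fmin = 0,
                           fmax = sample_rate / 2) {
  n_bins <- n_fft %/% 2L + 1L
  freqs <- seq(0, sample_rate / 2, length.out = n_bins)
  mel_pts <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2L)
  hz_pts <- mel_to_hz(mel_pts)
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- hz_pts[m]; mid <- hz_pts[m + 1L]; hi <- hz_pts[m + 2L]
    up <- (freqs - lo) / (mid - lo)
    down <- (hi - freqs) / (hi - mid)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# Orthonormal DCT-II matrix (n_out x n_in), applied to log-mel energies.
dct_matrix <- function(n_out, n_in) {
  k <- seq_len(n_out) - 1L
  n <- seq_len(n_in) - 1L
  m <- sqrt(2 / n_in) * cos(outer(k, n, function(k, n) {
    pi * k * (n + 0.5) / n_in
  }))
  m[1, ] <- m[1, ] / sqrt(2)
  m
}

#' Mel-frequency cepstral coefficients of a signal window
#'
#' Standard MFCC pipeline: optional pre-emphasis, framing with a Hamming
#' window, FFT power spectrum, triangular mel filterbank, log, orthonormal
#' DCT-II, keeping the first `n_mfcc` coefficients per frame. Deterministic
#' for a fixed input and configuration.
#'
#' @param window A `signal_window`, [session_recording()], or numeric
#'   vector.
#' @param n_mfcc Number of cepstral coefficients (<= `n_mels`).
#' @param frame Analysis frame length in seconds (default 0.025).
#' @param frame_hop Hop between frame starts in seconds (default 0.010).
#' @param n_mels Number of mel filters (default 64).
#' @param sample_rate Required for bare numeric input.
#' @param pre_emphasis Pre-emphasis coefficient in `[0, 1)`; 0 disables
#'   (default).
#' @return An `mfcc_matrix`: numeric matrix `[time_steps, n_mfcc]` with
#'   attributes `frame`, `frame_hop`, `n_mfcc`.
#' @export
mfcc_features <- function(window, n_mfcc = 20, frame = 0.025,
                          frame_hop = 0.010, n_mels = 64,
                          sample_rate = NULL, pre_emphasis = 0) {
  if (inherits(window, c("signal_window", "session_recording"))) {
    sample_rate <- window$sample_rate
    x <- window$samples
  } else {
    if (is.null(sample_rate)) stop("sample_rate required for bare vectors")
    x <- as.numeric(window)
  }
  if (n_mfcc > n_mels) stop("n_mfcc cannot exceed the mel filter count")
  if (pre_emphasis > 0) {
    x <- c(x[1], x[-1] - pre_emphasis * x[-length(x)])
  }
  flen <- as.integer(round(frame * sample_rate))
  fhop <- as.integer(round(frame_hop * sample_rate))
  if (length(x) < flen) stop("window shorter than one analysis frame")
  n_frames <- (length(x) - flen) %/% fhop + 1L
  starts <- (seq_len(n_frames) - 1L) * fhop
  n_fft <- 2L^ceiling(log2(flen))
  ham <- 0.54 - 0.46 * cos(2 * pi * (seq_len(flen) - 1L) / (flen - 1L))
  frames <- matrix(0, n_fft, n_frames)
  for (j in seq_len(n_frames)) {
    frames[seq_len(flen), j] <- x[(starts[j] + 1L):(starts[j] + flen)] * ham
  }
  spec <- stats::mvfft(frames)
  n_bins <- n_fft %/% 2L + 1L
  power <- Mod(spec[seq_len(n_bins), , drop = FALSE])^2 / n_fft
  fb <- mel_filterbank(n_mels, n_fft, sample_rate)
  mel_energy <- fb %*% power                 # [n_mels, n_frames]
  log_mel <- log(mel_energy + 1e-10)
  dct <- dct_matrix(n_mfcc, n_mels)
  out <- t(dct %*% log_mel)                  # [n_frames, n_mfcc]
  structure(out, frame = frame, frame_hop = frame_hop, n_mfcc = n_mfcc,
            class = c("mfcc_matrix", class(out)))
}
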