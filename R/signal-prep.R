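#' A single-channel plant voltage recording
#'
#' @param samples Numeric vector of sensor readings.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param participant_id Participant identifier.
#' @param malfunction Logical; `TRUE` marks a sensor failure (empty samples).
#' @return A `session_recording` object.
#' @export
session_recording <- function(samples, sample_rate, participant_id = "P01",
                              malfunction = FALSE) {
  stopifnot(sample_rate > 0)
  if (malfunction && length(samples) > 0L) {
    stop("a malfunction recording must have no samples")
  }
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 participant_id = as.character(participant_id),
                 malfunction = isTRUE(malfunction)),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("<session_recording %s: %d samples @ %g Hz (%.1f s)%s>\n",
              x$participant_id, length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate,
              if (x$malfunction) ", MALFUNCTION" else ""))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording A [session_recording()].
#' @return Numeric seconds.
#' @export
recording_seconds <- function(recording) {
  length(recording$samples) / recording$sample_rate
}

#' Per-file z-normalization
#'
#' Standardizes a whole recording to mean 0 and standard deviation 1
#' (population convention, 1/N), removing session-level offset and gain so
#' that recordings are comparable across sessions regardless of electrode
#' placement or amplifier settings. Applied once per file, before any
#' partitioning.
#'
#' @param recording A [session_recording()] or a bare numeric vector.
#' @return Same type as the input, z-normalized.
#' @export
znormalize <- function(recording) {
  if (inherits(recording, "session_recording")) {
    if (recording$malfunction || length(recording$samples) == 0L) {
      stop("cannot z-normalize an empty/malfunction recording")
    }
    recording$samples <- znormalize(recording$samples)
    return(recording)
  }
  x <- as.numeric(recording)
  if (length(x) == 0L) stop("cannot z-normalize an empty signal")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) stop("constant signal: z-normalization is undefined")
  (x - m) / s
}

#' Partition a recording into sliding windows
#'
#' Windows of `window` seconds start at 0, `hop`, `2*hop`, ... seconds; only
#' complete windows are kept, so the count is
#' `floor((T - window) / hop) + 1`. Overlapping windows arise when
#' `hop < window`.
#'
#' @param recording A z-normalized [session_recording()].
#' @param window Window length in seconds (> 0).
#' @param hop Seconds between successive window starts (> 0).
#' @return List of `signal_window` objects (fields `samples`, `start_time`,
#'   `end_time`, `sample_rate`); empty list with a warning if the recording
#'   is shorter than one window.
#' @export
make_windows <- function(recording, window, hop) {
  stopifnot(inherits(recording, "session_recording"), window > 0, hop > 0)
  if (recording$malfunction) stop("cannot window a malfunction recording")
  fs <- recording$sample_rate
  T_sec <- recording_seconds(recording)
  if (window > T_sec) {
    warning("window longer than recording: no windows produced")
    return(list())
  }
  starts <- seq(0, T_sec - window, by = hop)
  wlen <- as.integer(round(window * fs))
  lapply(starts, function(s0) {
    i0 <- as.integer(round(s0 * fs))
    structure(list(samples = recording$samples[(i0 + 1L):(i0 + wlen)],
                   start_time = s0, end_time = s0 + window,
                   sample_rate = fs),
              class = "signal_window")
  })
}

#' Downsample a recording or window
#'
#' Anti-aliased polyphase FIR resampling (the default) to `target_rate`,
#' preserving duration. `method = "stride"` is a naive take-every-kth
#' subsampler kept for ablation — it aliases and is not the default.
#'
#' @param x A [session_recording()], a `signal_window`, or a numeric vector.
#' @param target_rate Target rate in Hz (<= source rate).
#' @param source_rate Source rate; required only when `x` is a bare vector.
#' @param method `"fir"` (anti-aliased, default) or `"stride"`.
#' @return Same type as `x`, at `target_rate`.
#' @export
downsample <- function(x, target_rate, source_rate = NULL,
                       method = c("fir", "stride")) {
  method <- match.arg(method)
  if (inherits(x, "session_recording")) {
    x$samples <- downsample(x$samples, target_rate, x$sample_rate, method)
    x$sample_rate <- target_rate
    return(x)
  }
  if (inherits(x, "signal_window")) {
    x$samples <- downsample(x$samples, target_rate, x$sample_rate, method)
    x$sample_rate <- target_rate
    return(x)
  }
  if (is.null(source_rate)) stop("source_rate required for bare vectors")
  if (target_rate > source_rate) {
    stop("target_rate exceeds the source sampling rate")
  }
  if (target_rate == source_rate) return(as.numeric(x))
  r <- source_rate / target_rate
  if (abs(r - round(r)) > 1e-9) {
    stop("source_rate must be an integer multiple of target_rate")
  }
  r <- as.integer(round(r))
  if (method == "stride") {
    return(as.numeric(x)[seq(1L, length(x), by = r)])
  }
  as.numeric(signal::resample(as.numeric(x), p = 1, q = r))
}

#' Segment a recording into raw one-second pieces
#'
#' The no-windowing preparation track: consecutive non-overlapping 1-s
#' segments at the native sampling rate (no downsampling), each z-normalized
#' independently. A trailing partial second is discarded with a warning.
#'
#' @param recording A [session_recording()].
#' @return A `segment_set`: list with `segments` (matrix, one row per second,
#'   `sample_rate` columns), `second` (0-based index vector), `sample_rate`,
#'   `participant_id`.
#' @export
segment_one_second <- function(recording) {
  stopifnot(inherits(recording, "session_recording"))
  if (recording$malfunction || length(recording$samples) == 0L) {
    stop("cannot segment an empty/malfunction recording")
  }
  fs <- as.integer(round(recording$sample_rate))
  n_full <- length(recording$samples) %/% fs
  if (n_full * fs < length(recording$samples)) {
    warning("trailing partial second discarded")
  }
  if (n_full == 0L) stop("recording shorter than one second")
  m <- matrix(recording$samples[seq_len(n_full * fs)],
              nrow = n_full, ncol = fs, byrow = TRUE)
  m <- t(apply(m, 1L, znormalize))
  structure(list(segments = m, second = seq_len(n_full) - 1L,
                 sample_rate = fs,
                 participant_id = recording$participant_id),
            class = "segment_set")
}
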