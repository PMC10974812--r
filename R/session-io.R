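#' Write a mono PCM-16 WAV file
#'
#' Minimal RIFF/WAVE writer for single-channel 16-bit recordings. Samples are
#' expected in `[-full_scale, full_scale]`; values outside are clipped with a
#' warning (quantization overflow).
#'
#' @param samples Numeric vector.
#' @param path Output path.
#' @param sample_rate Sampling rate in Hz.
#' @param full_scale Sensor value mapped to the largest representable PCM
#'   amplitude (default 8; the quantization step is `full_scale / 32767`).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate, full_scale = 8) {
  x <- as.numeric(samples) / full_scale
  if (any(abs(x) > 1)) {
    warning("samples exceed full scale; clipping")
    x <- pmin(1, pmax(-1, x))
  }
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")      # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")       # PCM
  writeBin(1L, con, size = 2, endian = "little")       # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")       # block align
  writeBin(16L, con, size = 2, endian = "little")      # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono PCM-16 WAV file
#'
#' @param path WAV path.
#' @param full_scale Scale factor used at write time.
#' @return List with `samples` (numeric) and `sample_rate`.
#' @export
read_wav <- function(path, full_scale = 8) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  sample_rate <- NA_integer_
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) stop("no data chunk in ", path)
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) stop("only PCM mono supported")
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, raw(), n = sz - 8L))
    } else if (identical(id, "data")) {
      pcm <- readBin(con, integer(), n = sz %/% 2L, size = 2,
                     endian = "little")
      return(list(samples = pcm / 32767 * full_scale,
                  sample_rate = sample_rate))
    } else {
      invisible(readBin(con, raw(), n = sz))
    }
  }
}

#' Write a session to disk
#'
#' Emits the recording as a 16-bit mono WAV (skipped for malfunction
#' sessions), the label stream as a `second,emotion` CSV, the schedule as
#' JSON, and appends a row to `manifest.csv` (participant, file names,
#' malfunction flag, full-scale factor).
#'
#' @param session A `synthetic_session` (see [simulate_session()]), or any
#'   list with `recording`, `labels`, `schedule`.
#' @param directory Output directory (created if needed).
#' @param full_scale WAV full-scale factor (see [write_wav()]).
#' @return Invisible list of the written paths.
#' @export
write_session <- function(session, directory, full_scale = 8) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  pid <- session$recording$participant_id
  wav <- file.path(directory, paste0(pid, ".wav"))
  labels_csv <- file.path(directory, paste0(pid, "_labels.csv"))
  schedule_json <- file.path(directory, paste0(pid, "_schedule.json"))
  malfunction <- session$recording$malfunction
  if (!malfunction) {
    write_wav(session$recording$samples, wav,
              session$recording$sample_rate, full_scale)
  }
  utils::write.csv(data.frame(second = session$labels$second,
                              emotion = as.character(session$labels$emotion)),
                   labels_csv, row.names = FALSE)
  jsonlite::write_json(as.data.frame(unclass(session$schedule)),
                       schedule_json, digits = NA)
  manifest_path <- file.path(directory, "manifest.csv")
  row <- data.frame(participant_id = pid,
                    wav = if (malfunction) "" else basename(wav),
                    labels = basename(labels_csv),
                    schedule = basename(schedule_json),
                    sample_rate = session$recording$sample_rate,
                    full_scale = full_scale,
                    malfunction = malfunction)
  if (file.exists(manifest_path)) {
    manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
    manifest <- rbind(manifest[manifest$participant_id != pid, ], row)
  } else {
    manifest <- row
  }
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  invisible(list(wav = wav, labels = labels_csv, schedule = schedule_json,
                 manifest = manifest_path))
}

#' Load sessions from a directory
#'
#' Reads the session manifest and returns the usable sessions; malfunction
#' sessions (no recorded signal) are excluded unless requested.
#'
#' @param directory Directory written by [write_session()].
#' @param include_malfunction Keep malfunction sessions (as empty
#'   recordings)?
#' @return List of lists with `recording` ([session_recording()]), `labels`
#'   ([label_stream()]), `schedule` ([video_schedule()]).
#' @export
read_sessions <- function(directory, include_malfunction = FALSE) {
  manifest_path <- file.path(directory, "manifest.csv")
  if (!file.exists(manifest_path)) stop("no manifest.csv in ", directory)
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (!include_malfunction) manifest <- manifest[!manifest$malfunction, ]
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    if (row$malfunction) {
      rec <- session_recording(numeric(0), row$sample_rate,
                               row$participant_id, malfunction = TRUE)
    } else {
      wav <- read_wav(file.path(directory, row$wav), row$full_scale)
      rec <- session_recording(wav$samples, wav$sample_rate,
                               row$participant_id)
    }
    lab <- utils::read.csv(file.path(directory, row$labels),
                           stringsAsFactors = FALSE)
    sch <- jsonlite::read_json(file.path(directory, row$schedule),
                               simplifyVector = TRUE)
    schedule <- video_schedule(sch$video_id, sch$name, sch$expected_emotion,
                               sch$duration)
    schedule$gap_after <- as.integer(sch$gap_after)
    list(recording = rec,
         labels = label_stream(lab$emotion, row$participant_id),
         schedule = schedule)
  })
}
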