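#' Construct a video schedule
#'
#' A schedule is the ordered list of stimulus videos a participant watches,
#' each with a duration in seconds and the emotion it is designed to elicit
#' (`"Multiple"` is a wildcard for mixed-emotion videos). Inter-video gaps pad
#' the session to `total_seconds`; gap seconds elicit no emotion (Neutral).
#'
#' @param video_id Integer vector of video ids.
#' @param name Character vector of video names.
#' @param expected_emotion Character vector: one of the seven emotions or
#'   `"Multiple"`.
#' @param duration Positive numeric vector of durations (whole seconds).
#' @param total_seconds Total session length; the difference to
#'   `sum(duration)` is distributed as uniform inter-video gaps placed after
#'   each video (remainder seconds go to the earliest gaps). `NULL` means no
#'   gaps.
#' @return A `video_schedule`: data frame with columns `video_id`, `name`,
#'   `expected_emotion`, `duration`, `gap_after`.
#' @export
video_schedule <- function(video_id, name, expected_emotion, duration,
                           total_seconds = NULL) {
  stopifnot(length(video_id) == length(name),
            length(name) == length(expected_emotion),
            length(expected_emotion) == length(duration))
  if (any(duration <= 0)) stop("durations must be strictly positive")
  duration <- as.integer(duration)
  ok <- expected_emotion %in% c(emotion_levels(), "Multiple")
  if (!all(ok)) {
    stop("invalid expected emotion(s): ",
         paste(unique(expected_emotion[!ok]), collapse = ", "))
  }
  n <- length(video_id)
  gap_after <- integer(n)
  if (!is.null(total_seconds)) {
    pad <- as.integer(total_seconds) - sum(duration)
    if (pad < 0) stop("total_seconds is shorter than the summed durations")
    base <- pad %/% n
    extra <- pad %% n
    gap_after <- rep(base, n) + c(rep(1L, extra), rep(0L, n - extra))
  }
  out <- data.frame(video_id = as.integer(video_id), name = name,
                    expected_emotion = expected_emotion,
                    duration = duration, gap_after = gap_after,
                    stringsAsFactors = FALSE)
  class(out) <- c("video_schedule", "data.frame")
  out
}

#' The default stimulus video sequence
#'
#' The 15-video sequence used to elicit participants' emotions: three
#' happiness videos, one disgust, two anger, two surprise, three sadness, two
#' fear and two mixed-emotion ("Multiple") videos, 560 s of video in total,
#' padded with uniform inter-video gaps to a 690-s session.
#'
#' @param total_seconds Session length to pad to (default 690).
#' @return A [video_schedule()].
#' @export
default_schedule <- function(total_seconds = 690) {
  video_schedule(
    video_id = 1:15,
    name = c("Puppies", "Avocado", "Runner", "Maggot", "Raccoon", "Trump",
             "Mountain bike", "Roof run", "Abandoned", "Waste", "Dog",
             "Roof bike", "Monster", "Condom ad", "Soldier"),
    expected_emotion = c("Happiness", "Happiness", "Happiness", "Disgust",
                         "Anger", "Anger", "Surprise", "Surprise", "Sadness",
                         "Sadness", "Sadness", "Fear", "Fear", "Multiple",
                         "Multiple"),
    duration = c(13, 8, 24, 37, 16, 52, 29, 18, 64, 31, 11, 28, 156, 38, 35),
    total_seconds = total_seconds
  )
}

#' Total session length of a schedule, in seconds
#' @param schedule A [video_schedule()].
#' @return Integer seconds (videos plus gaps).
#' @export
schedule_seconds <- function(schedule) {
  sum(schedule$duration) + sum(schedule$gap_after)
}

#' Scale a schedule's video durations
#'
#' Shrinks (or stretches) every video duration by `factor`, keeping at least
#' one second per video, and re-pads the gaps proportionally. Used to run the
#' full pipeline at reduced session length.
#'
#' @param schedule A [video_schedule()].
#' @param factor Positive scaling factor applied to durations and total.
#' @return A [video_schedule()].
#' @export
scale_schedule <- function(schedule, factor) {
  stopifnot(factor > 0)
  dur <- pmax(1L, as.integer(round(schedule$duration * factor)))
  total <- sum(dur) + as.integer(round(sum(schedule$gap_after) * factor))
  video_schedule(schedule$video_id, schedule$name, schedule$expected_emotion,
                 dur, total_seconds = total)
}

#' Expand a schedule to one row per second
#'
#' Seconds are 0-based half-open intervals `[k, k+1)`. Gap seconds carry
#' `video_id = NA` and expected emotion `"Gap"`.
#'
#' @param schedule A [video_schedule()].
#' @return Data frame with columns `second`, `video_id`, `expected_emotion`.
#' @export
expand_schedule <- function(schedule) {
  vid <- rep(c(rbind(schedule$video_id, NA)),
             times = c(rbind(schedule$duration, schedule$gap_after)))
  exp_emo <- rep(c(rbind(schedule$expected_emotion, "Gap")),
                 times = c(rbind(schedule$duration, schedule$gap_after)))
  data.frame(second = seq_along(vid) - 1L, video_id = vid,
             expected_emotion = exp_emo, stringsAsFactors = FALSE)
}
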