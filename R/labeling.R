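#' A per-second emotion label stream
#'
#' Ground-truth labels at 1 Hz (from facial-emotion analysis or simulation).
#' Seconds are 0-based and contiguous.
#'
#' @param emotion Character/factor vector of per-second emotions (second `k`
#'   at position `k + 1`).
#' @param participant_id Participant identifier.
#' @return A `label_stream`: data frame with columns `second`, `emotion`.
#' @export
label_stream <- function(emotion, participant_id = "P01") {
  emotion <- as_emotion(emotion)
  out <- data.frame(second = seq_along(emotion) - 1L, emotion = emotion)
  attr(out, "participant_id") <- as.character(participant_id)
  class(out) <- c("label_stream", "data.frame")
  out
}

#' A set of labeled windows or segments
#'
#' The unit of classification: signal excerpts joined to emotion labels,
#' together with the ordered active class set (`nbemotion = length(class_set)`,
#' 7 with Neutral or 6 without).
#'
#' @param items List of `signal_window` objects, or a numeric matrix (one
#'   row per 1-s segment).
#' @param labels Emotion labels, one per item/row.
#' @param class_set Ordered active class set.
#' @param meta Optional data frame of per-item metadata (participant, start,
#'   end).
#' @return A `labeled_window_set`.
#' @export
labeled_window_set <- function(items, labels,
                               class_set = emotion_levels(), meta = NULL) {
  n <- if (is.matrix(items)) nrow(items) else length(items)
  labels <- as_emotion(labels, class_set)
  stopifnot(length(labels) == n)
  structure(list(items = items, labels = labels, class_set = class_set,
                 nbemotion = length(class_set), meta = meta),
            class = "labeled_window_set")
}

n_items <- function(set) {
  if (is.matrix(set$items)) nrow(set$items) else length(set$items)
}

subset_set <- function(set, keep) {
  items <- if (is.matrix(set$items)) {
    set$items[keep, , drop = FALSE]
  } else {
    set$items[keep]
  }
  labeled_window_set(items, as.character(set$labels)[keep], set$class_set,
                     if (!is.null(set$meta)) set$meta[keep, , drop = FALSE])
}

#' Join per-second labels to windows or segments
#'
#' A window receives the label of the last second it fully covers (the label
#' at its end time): window `[s, e)` gets the label of second `e - 1`. A 1-s
#' segment at second `k` receives the label of second `k` (a plain temporal
#' join).
#'
#' @param windows List of `signal_window`s from [make_windows()], or a
#'   `segment_set` from [segment_one_second()].
#' @param labels A [label_stream()].
#' @return A [labeled_window_set()] with metadata columns `participant_id`,
#'   `start`, `end`, `label_second`.
#' @export
label_windows <- function(windows, labels) {
  stopifnot(inherits(labels, "label_stream"))
  pid <- attr(labels, "participant_id")
  if (inherits(windows, "segment_set")) {
    sec <- windows$second
    missing <- setdiff(sec, labels$second)
    if (length(missing) > 0L) {
      stop("label stream does not cover segment second(s): ",
           paste(utils::head(missing, 5L), collapse = ", "))
    }
    lab <- labels$emotion[match(sec, labels$second)]
    meta <- data.frame(participant_id = windows$participant_id,
                       start = sec, end = sec + 1L, label_second = sec)
    return(labeled_window_set(windows$segments, lab, meta = meta))
  }
  ends <- vapply(windows, function(w) w$end_time, numeric(1))
  label_sec <- as.integer(ceiling(ends) - 1L)
  missing <- setdiff(label_sec, labels$second)
  if (length(missing) > 0L) {
    stop("label stream does not cover window end second(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  lab <- labels$emotion[match(label_sec, labels$second)]
  meta <- data.frame(
    participant_id = pid,
    start = vapply(windows, function(w) w$start_time, numeric(1)),
    end = ends, label_second = label_sec)
  labeled_window_set(windows, lab, meta = meta)
}

#' Drop items whose label contradicts the expected emotion
#'
#' An item is kept when its label matches the emotion the video active at its
#' end time was designed to elicit. Under the default policy
#' (`"retain-neutral"`), Neutral-labeled items are always retained (the
#' participant may genuinely feel nothing), mixed-emotion (`"Multiple"`)
#' videos match any label, and gap seconds match Neutral only. Under
#' `"strict"`, Neutral survives only in gaps. The filter only drops items —
#' it never relabels.
#'
#' @param labeled A [labeled_window_set()] from [label_windows()].
#' @param schedule The session's [video_schedule()].
#' @param policy `"retain-neutral"` (default) or `"strict"`.
#' @return Filtered [labeled_window_set()]; attribute `"filter_report"`
#'   holds per-video kept/dropped counts.
#' @export
filter_expected <- function(labeled, schedule,
                            policy = c("retain-neutral", "strict")) {
  policy <- match.arg(policy)
  expanded <- expand_schedule(schedule)
  sec <- labeled$meta$label_second
  out_of_range <- setdiff(sec, expanded$second)
  if (length(out_of_range) > 0L) {
    stop("item end time(s) outside the schedule: ",
         paste(utils::head(out_of_range, 5L), collapse = ", "))
  }
  expected <- expanded$expected_emotion[match(sec, expanded$second)]
  lab <- as.character(labeled$labels)
  keep <- (lab == expected) |
    (expected == "Multiple") |
    (expected == "Gap" & lab == "Neutral")
  if (policy == "retain-neutral") {
    keep <- keep | (lab == "Neutral" & expected != "Gap")
  }
  report <- stats::aggregate(
    cbind(kept = keep, dropped = !keep),
    by = list(video_id = ifelse(is.na(expanded$video_id[match(sec, expanded$second)]),
                                0L,
                                expanded$video_id[match(sec, expanded$second)]),
              emotion = lab),
    FUN = sum)
  out <- subset_set(labeled, keep)
  attr(out, "filter_report") <- report
  out
}

#' Restrict the active class set
#'
#' `include_neutral = FALSE` removes Neutral items and reduces the class set
#' to the remaining six emotions (the no-windowing track's configuration);
#' `TRUE` is the identity (the windowed track keeps all seven).
#'
#' @param labeled A [labeled_window_set()].
#' @param include_neutral Logical.
#' @return A [labeled_window_set()] with updated `class_set`/`nbemotion`.
#' @export
restrict_classes <- function(labeled, include_neutral = TRUE) {
  if (include_neutral) return(labeled)
  keep <- as.character(labeled$labels) != "Neutral"
  new_set <- setdiff(labeled$class_set, "Neutral")
  if (length(new_set) == 0L || !any(keep)) {
    stop("restricting classes would leave an empty set")
  }
  items <- if (is.matrix(labeled$items)) {
    labeled$items[keep, , drop = FALSE]
  } else {
    labeled$items[keep]
  }
  labeled_window_set(items, as.character(labeled$labels)[keep], new_set,
                     if (!is.null(labeled$meta)) {
                       labeled$meta[keep, , drop = FALSE]
                     })
}

#' Concatenate labeled sets from several sessions
#'
#' @param sets List of [labeled_window_set()]s sharing a class set.
#' @return One combined [labeled_window_set()].
#' @export
bind_labeled_sets <- function(sets) {
  stopifnot(length(sets) > 0L)
  cs <- sets[[1]]$class_set
  for (s in sets) {
    if (!identical(s$class_set, cs)) stop("class sets differ across sets")
  }
  items <- if (is.matrix(sets[[1]]$items)) {
    do.call(rbind, lapply(sets, function(s) s$items))
  } else {
    do.call(c, lapply(sets, function(s) s$items))
  }
  labels <- unlist(lapply(sets, function(s) as.character(s$labels)))
  meta <- do.call(rbind, lapply(sets, function(s) s$meta))
  labeled_window_set(items, labels, cs, meta)
}
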