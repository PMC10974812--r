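#' The seven facial-emotion classes
#'
#' Fixed, ordered set of emotion labels used throughout the pipeline. The
#' ordering is alphabetical and defines the class-index mapping everywhere
#' (confusion-matrix rows, softmax output neurons, argmax tie-breaking).
#'
#' @return Character vector of the 7 emotion names, in canonical order.
#' @export
emotion_levels <- function() {
  c("Anger", "Disgust", "Fear", "Happiness", "Neutral", "Sadness", "Surprise")
}

#' Coerce labels to the canonical emotion factor
#'
#' @param x Character or factor vector of emotion names.
#' @param class_set Ordered class set to use as factor levels; defaults to all
#'   seven emotions.
#' @return Factor with levels `class_set`.
#' @export
as_emotion <- function(x, class_set = emotion_levels()) {
  x <- as.character(x)
  bad <- setdiff(unique(x), class_set)
  if (length(bad) > 0L) {
    stop("unknown emotion label(s): ", paste(bad, collapse = ", "))
  }
  factor(x, levels = class_set)
}

#' Default arousal weights for the synthetic signal generator
#'
#' High-arousal emotions (fear, anger, surprise) carry the strongest
#' emotion-dependent signal component, medium-arousal disgust an intermediate
#' one, low/medium-arousal happiness and sadness a weak one, and neutral none.
#' This makes high-arousal emotions the easiest to detect, the behaviour
#' hypothesised for real plant recordings (arousal drives detectability).
#'
#' @return Named numeric vector over the 7 emotions.
#' @export
arousal_weights <- function() {
  c(Anger = 1, Disgust = 0.7, Fear = 1, Happiness = 0.5,
    Neutral = 0, Sadness = 0.5, Surprise = 1)
}

#' Carrier frequencies of the emotion-dependent signal component
#'
#' Each non-neutral emotion is assigned a distinct fixed carrier frequency
#' (Hz) for the synthetic generator. All carriers are integers (so the
#' waveform repeats exactly every second and a 1-s segment is a deterministic
#' template up to noise) and lie below the Nyquist frequency of the lowest
#' sampling rate the pipeline uses (500 Hz at a 1 kHz rate).
#'
#' @return Named numeric vector (Hz); Neutral is 0 (no component).
#' @export
emotion_carriers <- function() {
  c(Anger = 37, Disgust = 53, Fear = 71, Happiness = 89,
    Neutral = 0, Sadness = 103, Surprise = 127)
}

#' Default valence-arousal quadrant map
#'
#' Maps each emotion to its quadrant in the valence-arousal plane:
#' Q1 positive valence / high arousal, Q2 negative valence / high arousal,
#' Q3 negative valence / low arousal, Center neutral. Disgust is assigned to
#' Q2 (negative valence, raised arousal), so that a disgust-for-fear confusion
#' counts as an intra-quadrant error.
#'
#' @return Named character vector emotion -> quadrant.
#' @export
quadrant_map <- function() {
  c(Anger = "Q2", Disgust = "Q2", Fear = "Q2", Happiness = "Q1",
    Neutral = "Center", Sadness = "Q3", Surprise = "Q1")
}
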