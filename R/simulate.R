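#' Configuration of one synthetic recording session
#'
#' Collects every knob of the synthetic-session generator. The generator
#' emulates a single-channel plant voltage recording at audio-like rates
#' together with the per-second facial-emotion label stream that a
#' face-analysis model would produce.
#'
#' @param participant_id Participant identifier (string).
#' @param sample_rate Sampling rate in Hz (default 10000, the bioamplifier's
#'   rate).
#' @param effect_amplitude Dimensionless strength of the emotion-dependent
#'   signal component (>= 0); 0 gives a null signal with no class information.
#' @param label_noise_rate Probability in `[0, 1]` that a second's face label
#'   is corrupted to a uniformly random other emotion (0.14 emulates the
#'   ~86% face-recognition accuracy regime of the labelling model).
#' @param neutral_rate Probability in `[0, 1]` that the participant lapses
#'   into Neutral during a video second.
#' @param dropout_prob Probability that the session records no signal at all
#'   (sensor malfunction emulation).
#' @param seed Integer seed for the session's RNG.
#' @return A `session_config` list.
#' @export
session_config <- function(participant_id = "P01", sample_rate = 10000,
                           effect_amplitude = 1, label_noise_rate = 0.14,
                           neutral_rate = 0.1, dropout_prob = 0,
                           seed = 1L) {
  stopifnot(sample_rate > 0, effect_amplitude >= 0,
            label_noise_rate >= 0, label_noise_rate <= 1,
            neutral_rate >= 0, neutral_rate <= 1,
            dropout_prob >= 0, dropout_prob <= 1)
  structure(list(participant_id = as.character(participant_id),
                 sample_rate = sample_rate,
                 effect_amplitude = effect_amplitude,
                 label_noise_rate = label_noise_rate,
                 neutral_rate = neutral_rate,
                 dropout_prob = dropout_prob,
                 seed = as.integer(seed)),
            class = "session_config")
}

#' Simulate the participant's true per-second emotion sequence
#'
#' For each video second the participant feels the video's expected emotion
#' with probability `1 - neutral_rate`, otherwise Neutral. Mixed-emotion
#' ("Multiple") videos draw one uniformly random non-Neutral emotion per
#' second. Gap seconds are Neutral.
#'
#' @param schedule A [video_schedule()].
#' @param config A [session_config()]; uses `neutral_rate` and `seed`.
#' @return Factor of length `schedule_seconds(schedule)` over the 7 emotions.
#' @export
simulate_latent_emotions <- function(schedule, config) {
  expanded <- expand_schedule(schedule)
  n <- nrow(expanded)
  withr_seed(config$seed, "latent", {
    lat <- expanded$expected_emotion
    multi <- lat == "Multiple"
    if (any(multi)) {
      lat[multi] <- sample(setdiff(emotion_levels(), "Neutral"),
                           sum(multi), replace = TRUE)
    }
    lat[lat == "Gap"] <- "Neutral"
    lapse <- stats::runif(n) < config$neutral_rate
    lat[lapse & expanded$expected_emotion != "Gap"] <- "Neutral"
    as_emotion(lat)
  })
}

# Run expr under a deterministic RNG substream derived from (seed, tag),
# restoring the caller's RNG state afterwards. Keeps every generator output
# a pure function of the session seed.
withr_seed <- function(seed, tag, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  sub <- (as.integer(seed) * 97L + utf8ToInt(substr(tag, 1L, 1L))) %% 2147483647L
  set.seed(sub)
  expr
}

#' Simulate the plant's electrical response to a latent emotion sequence
#'
#' The generated signal is the sum of a pink-ish baseline noise (an AR(1)
#' process, emulating the slow correlated fluctuations of a plant voltage
#' trace), a slow sinusoidal drift (electrode/environment conditions), and an
#' emotion-dependent component: each non-Neutral emotion contributes a
#' sinusoid at its fixed carrier frequency (see [emotion_carriers()]) with
#' amplitude `effect_amplitude * arousal_weights()[emotion]` during the
#' seconds that emotion is felt. Neutral contributes nothing. Carrier phase is
#' locked to global session time, so each 1-s segment of a given emotion is a
#' deterministic template plus noise.
#'
#' With probability `dropout_prob` the whole session is dropped: an empty
#' recording flagged as a malfunction (sensor failure emulation).
#'
#' @param latent Factor/character vector of per-second emotions.
#' @param config A [session_config()].
#' @return A [session_recording()].
#' @export
simulate_plant_signal <- function(latent, config) {
  if (length(latent) == 0L) stop("latent emotion sequence is empty")
  latent <- as_emotion(latent)
  fs <- config$sample_rate
  secs <- length(latent)
  withr_seed(config$seed, "signal", {
    if (stats::runif(1) < config$dropout_prob) {
      return(session_recording(numeric(0), fs, config$participant_id,
                               malfunction = TRUE))
    }
    n <- as.integer(round(fs * secs))
    t <- seq(0, secs, length.out = n + 1L)[-(n + 1L)]
    # AR(1) baseline: long memory, unit marginal sd
    phi <- 0.999
    innov_sd <- sqrt(1 - phi^2)
    baseline <- as.numeric(stats::filter(stats::rnorm(n, sd = innov_sd),
                                         phi, method = "recursive"))
    drift <- 0.5 * sin(2 * pi * t / max(secs, 60) + stats::runif(1, 0, 2 * pi))
    carriers <- emotion_carriers()
    weights <- arousal_weights()
    amp_per_sec <- config$effect_amplitude * weights[as.character(latent)]
    freq_per_sec <- carriers[as.character(latent)]
    sec_idx <- pmin(floor(t) + 1L, secs)
    component <- amp_per_sec[sec_idx] * sin(2 * pi * freq_per_sec[sec_idx] * t)
    session_recording(baseline + drift + component, fs, config$participant_id)
  })
}

#' Simulate the face-analysis label stream
#'
#' Copies the latent emotion sequence, independently replacing each second's
#' label with a uniformly random *other* emotion with probability
#' `label_noise_rate` — the error process of an imperfect facial-emotion
#' recognizer.
#'
#' @param latent Factor/character vector of per-second true emotions.
#' @param config A [session_config()].
#' @return A [label_stream()].
#' @export
simulate_face_labels <- function(latent, config) {
  latent <- as.character(as_emotion(latent))
  withr_seed(config$seed, "faces", {
    n <- length(latent)
    flip <- stats::runif(n) < config$label_noise_rate
    if (any(flip)) {
      latent[flip] <- vapply(latent[flip], function(e) {
        sample(setdiff(emotion_levels(), e), 1L)
      }, character(1))
    }
    label_stream(latent, config$participant_id)
  })
}

#' Simulate one complete session
#'
#' Chains [simulate_latent_emotions()], [simulate_plant_signal()] and
#' [simulate_face_labels()] under the session's seed.
#'
#' @param config A [session_config()].
#' @param schedule A [video_schedule()]; default [default_schedule()].
#' @return A `synthetic_session` list with elements `recording`, `labels`,
#'   `latent`, `schedule`, `config`.
#' @export
simulate_session <- function(config, schedule = default_schedule()) {
  latent <- simulate_latent_emotions(schedule, config)
  recording <- simulate_plant_signal(latent, config)
  labels <- simulate_face_labels(latent, config)
  structure(list(recording = recording, labels = labels, latent = latent,
                 schedule = schedule, config = config),
            class = "synthetic_session")
}

#' Simulate a cohort of sessions
#'
#' @param n_participants Number of sessions.
#' @param schedule A [video_schedule()].
#' @param seed Cohort seed; session `i` uses `seed + i`.
#' @param ... Further arguments passed to [session_config()] for every
#'   session.
#' @return List of `synthetic_session` objects.
#' @export
simulate_cohort <- function(n_participants, schedule = default_schedule(),
                            seed = 1L, ...) {
  lapply(seq_len(n_participants), function(i) {
    cfg <- session_config(participant_id = sprintf("P%02d", i),
                          seed = seed + i, ...)
    simulate_session(cfg, schedule)
  })
}
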