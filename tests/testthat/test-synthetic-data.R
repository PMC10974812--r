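withr_tempdir <- function() {
  d <- tempfile("sessions_")
  dir.create(d)
  d
}

test_that("default schedule reproduces the stimulus sequence", {
  sch <- default_schedule()
  expect_equal(nrow(sch), 15L)
  expect_equal(sch$name[1], "Puppies")
  expect_equal(sch$expected_emotion[1], "Happiness")
  expect_equal(sch$duration[1], 13L)
  expect_equal(sch$name[13], "Monster")
  expect_equal(sch$expected_emotion[13], "Fear")
  expect_equal(sch$duration[13], 156L)
  # printed durations sum to 560 s; gaps pad the session to 690 s
  expect_equal(sum(sch$duration), 560L)
  expect_equal(schedule_seconds(sch), 690L)
  expanded <- expand_schedule(sch)
  expect_equal(nrow(expanded), 690L)
  expect_equal(expanded$second, 0:689)
})

test_that("schedule construction validates durations and pads exactly", {
  expect_error(video_schedule(1, "x", "Fear", 0), "positive")
  expect_error(video_schedule(1, "x", "Fear", 10, total_seconds = 5),
               "shorter")
  sch <- video_schedule(1:3, c("a", "b", "c"), rep("Fear", 3), c(5, 5, 5),
                        total_seconds = 22)
  expect_equal(schedule_seconds(sch), 22L)
  expect_equal(sum(sch$gap_after), 7L)
})

test_that("latent emotion simulation follows the schedule and neutral rate", {
  sch <- default_schedule()
  lat0 <- simulate_latent_emotions(
    sch, session_config(neutral_rate = 0, seed = 1))
  expect_equal(as.character(lat0[1:13]), rep("Happiness", 13))
  # gap seconds are Neutral even at neutral_rate = 0
  expanded <- expand_schedule(sch)
  expect_true(all(lat0[expanded$expected_emotion == "Gap"] == "Neutral"))
  expect_true(all(lat0[expanded$expected_emotion == "Multiple"] != "Neutral"))

  lat1 <- simulate_latent_emotions(
    sch, session_config(neutral_rate = 1, seed = 1))
  expect_true(all(lat1 == "Neutral"))

  # binomial check: ~30% neutral lapses over 10,000 video seconds
  long <- video_schedule(1, "long", "Happiness", 10000)
  lat <- simulate_latent_emotions(
    long, session_config(neutral_rate = 0.3, seed = 5))
  expect_lt(abs(mean(lat == "Neutral") - 0.3), 0.02)
})

test_that("plant signal has the right length and is seed-deterministic", {
  cfg <- session_config(sample_rate = 10000, seed = 3)
  lat <- simulate_latent_emotions(default_schedule(), cfg)
  rec <- simulate_plant_signal(lat, cfg)
  expect_equal(length(rec$samples), 6900000L)
  rec2 <- simulate_plant_signal(lat, cfg)
  expect_identical(rec$samples, rec2$samples)
  expect_error(simulate_plant_signal(character(0), cfg), "empty")
})

test_that("emotion component is carrier-specific and monotone in amplitude", {
  carrier_power <- function(rec, emo, latent, fs) {
    idx <- which(latent == emo)[1:30]
    segs <- matrix(rec$samples, nrow = fs)[, idx, drop = FALSE]
    f <- emotion_carriers()[emo]
    probe <- exp(-2i * pi * f * (0:(fs - 1)) / fs)
    mean(abs(colSums(segs * probe) / fs)^2)
  }
  fs <- 500
  sch <- video_schedule(1:2, c("fear", "sad"), c("Fear", "Sadness"),
                        c(60, 60))
  pw <- sapply(c(0, 1, 3), function(a) {
    cfg <- session_config(sample_rate = fs, effect_amplitude = a,
                          neutral_rate = 0, seed = 9)
    lat <- simulate_latent_emotions(sch, cfg)
    rec <- simulate_plant_signal(lat, cfg)
    carrier_power(rec, "Fear", lat, fs)
  })
  # class-conditional power at the carrier is non-decreasing in amplitude
  expect_true(all(diff(pw) > 0))
  # at amplitude 0 the fear-carrier power matches an off-class probe
  cfg0 <- session_config(sample_rate = fs, effect_amplitude = 0,
                         neutral_rate = 0, seed = 9)
  lat0 <- simulate_latent_emotions(sch, cfg0)
  rec0 <- simulate_plant_signal(lat0, cfg0)
  expect_lt(carrier_power(rec0, "Fear", lat0, fs) /
              carrier_power(rec0, "Sadness", lat0, fs), 10)
})

test_that("face labels flip at the configured noise rate", {
  lat <- rep("Happiness", 10000)
  cfg0 <- session_config(label_noise_rate = 0, seed = 2)
  expect_equal(as.character(simulate_face_labels(lat, cfg0)$emotion), lat)
  cfg5 <- session_config(label_noise_rate = 0.5, seed = 2)
  lab <- simulate_face_labels(lat, cfg5)
  expect_lt(abs(mean(lab$emotion != lat) - 0.5), 0.02)
  # flips never reproduce the original label
  expect_true(all(lab$emotion[lab$emotion != lat] != "Happiness"))
})

test_that("sessions round-trip through WAV/CSV/JSON and flag malfunctions", {
  dir <- withr_tempdir()
  sch <- video_schedule(1:2, c("a", "b"), c("Fear", "Sadness"), c(3, 3),
                        total_seconds = 8)
  cfg <- session_config("P07", sample_rate = 200, effect_amplitude = 1,
                        seed = 4)
  ses <- simulate_session(cfg, sch)
  write_session(ses, dir)
  back <- read_sessions(dir)
  expect_length(back, 1L)
  expect_equal(as.character(back[[1]]$labels$emotion),
               as.character(ses$labels$emotion))
  # signal equal within one quantization step of the 16-bit scale
  expect_lt(max(abs(back[[1]]$recording$samples - ses$recording$samples)),
            8 / 32767)
  expect_equal(recording_seconds(back[[1]]$recording), 8)
  expect_equal(schedule_seconds(back[[1]]$schedule), 8L)

  # a dropped session is present in the manifest but excluded by the loader
  cfg_drop <- session_config("P08", sample_rate = 200, dropout_prob = 1,
                             seed = 5)
  ses_drop <- simulate_session(cfg_drop, sch)
  expect_true(ses_drop$recording$malfunction)
  write_session(ses_drop, dir)
  expect_length(read_sessions(dir), 1L)
  expect_length(read_sessions(dir, include_malfunction = TRUE), 2L)
})

test_that("identical configs give bit-identical sessions", {
  sch <- small_schedule()
  cfg <- session_config("P01", sample_rate = 250, seed = 42,
                        label_noise_rate = 0.2, neutral_rate = 0.2)
  s1 <- simulate_session(cfg, sch)
  s2 <- simulate_session(cfg, sch)
  expect_identical(s1$recording$samples, s2$recording$samples)
  expect_identical(s1$labels$emotion, s2$labels$emotion)
  expect_identical(s1$latent, s2$latent)
})
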