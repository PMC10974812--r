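# Shared fixtures, built in code. Helper files are sourced once per test
# run, so the small cohorts below are generated a single time.

# A 25%-duration schedule keeps the full video structure (all 15 videos,
# gaps, Multiple entries) at ~172 s per session.
small_schedule <- function() scale_schedule(default_schedule(), 0.25)

# Raw-track six-class dataset from a small cohort.
make_raw_cohort <- function(n = 4, effect_amplitude = 3, seed = 100,
                            sample_rate = 500, label_noise_rate = 0,
                            neutral_rate = 0, schedule = small_schedule()) {
  sets <- lapply(seq_len(n), function(i) {
    cfg <- session_config(sprintf("P%02d", i), sample_rate = sample_rate,
                          effect_amplitude = effect_amplitude,
                          label_noise_rate = label_noise_rate,
                          neutral_rate = neutral_rate, seed = seed + i)
    ses <- simulate_session(cfg, schedule)
    seg <- segment_one_second(ses$recording)
    lab <- label_windows(seg, ses$labels)
    filt <- filter_expected(lab, schedule)
    restrict_classes(filt, include_neutral = FALSE)
  })
  build_raw_dataset(bind_labeled_sets(sets))
}

fixture_env <- new.env()

raw_cohort_strong <- function() {
  if (is.null(fixture_env$strong)) {
    fixture_env$strong <- make_raw_cohort()
  }
  fixture_env$strong
}

# One short, strong-signal session reused across prep/feature tests.
strong_session <- function() {
  if (is.null(fixture_env$session)) {
    cfg <- session_config("P01", sample_rate = 500, effect_amplitude = 3,
                          label_noise_rate = 0, neutral_rate = 0, seed = 11)
    fixture_env$session <- simulate_session(cfg, small_schedule())
  }
  fixture_env$session
}

# Tiny labeled window set on the downsampled track.
small_windowed_set <- function(window = 10, hop = 5) {
  ses <- strong_session()
  rec <- znormalize(ses$recording)
  w <- make_windows(rec, window, hop)
  label_windows(w, ses$labels)
}
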