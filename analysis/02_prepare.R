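#!/usr/bin/env Rscript
# Step 2 — data preparation, both tracks.
#
# Reads the simulated sessions back from disk (malfunction sessions are
# excluded by the loader) and runs the two preparation tracks:
#
#  * windowed track: per-file z-normalization, sliding windows (window 20 s,
#    hop 10 s — the grid-selected values), end-of-window labeling, the
#    expected-emotion filter, downsampling to 100 Hz (the 500 Hz of the
#    full-scale setting scaled with the 1 kHz recording rate), and MFCC
#    matrices per window; 7-class set (Neutral kept).
#  * raw track: 1-s segments at the native rate, per-segment
#    z-normalization, same labeling and filter, Neutral excluded (6-class).
#
# Writes dataset summaries and the filter report to results/.

suppressPackageStartupMessages(library(plantsense))

sessions <- read_sessions("scratch/sessions")
schedule <- scale_schedule(default_schedule(), 0.25)
cat(sprintf("loaded %d usable sessions\n", length(sessions)))

windowed_sets <- list()
raw_sets <- list()
for (s in sessions) {
  rec <- znormalize(s$recording)
  w <- make_windows(rec, window = 20, hop = 10)
  lw <- filter_expected(label_windows(w, s$labels), schedule)
  windowed_sets[[length(windowed_sets) + 1L]] <- lw

  seg <- segment_one_second(s$recording)
  ls <- filter_expected(label_windows(seg, s$labels), schedule)
  raw_sets[[length(raw_sets) + 1L]] <-
    restrict_classes(ls, include_neutral = FALSE)
}
windowed <- bind_labeled_sets(windowed_sets)
raw <- bind_labeled_sets(raw_sets)

ds_down <- build_downsampled_dataset(windowed, target_rate = 100)
ds_mfcc <- build_mfcc_dataset(windowed, n_mfcc = 20)
ds_raw <- build_raw_dataset(raw)

summary_tab <- data.frame(
  track = c("downsampled", "mfcc", "raw_1s"),
  items = c(nrow(ds_down$x), dim(ds_mfcc$x)[1], nrow(ds_raw$x)),
  shape = c(paste(dim(ds_down$x)[-1], collapse = "x"),
            paste(dim(ds_mfcc$x)[-1], collapse = "x"),
            paste(dim(ds_raw$x)[-1], collapse = "x")),
  classes = c(ds_down$nbemotion, ds_mfcc$nbemotion, ds_raw$nbemotion))
write.csv(summary_tab, "results/02_dataset_summary.csv", row.names = FALSE)

class_counts <- as.data.frame(table(raw = ds_raw$y))
write.csv(class_counts, "results/02_raw_class_counts.csv", row.names = FALSE)

print(summary_tab)
cat("raw-track class counts (Neutral excluded):\n")
print(table(ds_raw$y))

saveRDS(list(down = ds_down, mfcc = ds_mfcc, raw = ds_raw),
        "scratch/datasets.rds")
cat("datasets cached under scratch/; summaries in results/\n")
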