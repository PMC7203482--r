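#!/usr/bin/env Rscript
# Step 2 — extract features from the on-disk cohort.
#
# Reads the sessions written by 01_simulate.R, masks questionnaire-response
# windows, slices each stream into the 13 pre-sample segments (process level)
# or the masked whole session (outcome level), and writes the EEG (315
# features) and EDA (7 features) tables.

suppressMessages(library(affectlearn))

stopifnot(dir.exists("scratch/cohort"))
dirs <- list.dirs("scratch/cohort", recursive = FALSE)
sessions <- lapply(dirs, read_session)
message("read ", length(sessions), " sessions")

dir.create("scratch/features", showWarnings = FALSE)
for (sensor in c("eeg", "eda")) {
  for (level in c("process", "outcome")) {
    tab <- cohort_features(sessions, sensor, level)
    path <- sprintf("scratch/features/%s_%s.tsv", sensor, level)
    write_feature_table(tab, path)
    message(sprintf("%s %-7s: %3d rows x %3d features -> %s",
                    sensor, level, nrow(tab), ncol(tab) - 4L, path))
  }
}

eeg <- read_feature_table("scratch/features/eeg_outcome.tsv")
message("feature census: EEG ", ncol(eeg) - 4L, " (expected 315), coverage ",
        paste(round(eeg$coverage, 3), collapse = " "))
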