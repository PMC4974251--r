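#!/usr/bin/env Rscript

# Stage 1: simulate the cued go/nogo session structure and write one
# subject's recordings in the on-disk bundle (EDF + TSV events + JSON
# montage). The cohort used by the later stages is re-generated in memory by
# each stage from the same seeds, so nothing here is load-bearing; this
# script documents the data format and verifies the task structure.

library(gonogoerp)

out_dir <- "results/example_subject"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
seed <- 20

# Desk-scale session: study task structure (5 blocks, 3 directional with 30%
# nogo targets, ITI 1500-2500 ms) at 32 trials per block and 128 Hz.
task <- task_config(trials_per_block = 32)
sched <- make_schedule(task, seed = seed)
cat(sprintf("schedule: %d trials, %d nogo (%.0f%% of directional trials)\n",
            nrow(sched), sum(sched$is_nogo),
            100 * sum(sched$is_nogo) / sum(sched$block_type == "directional")))

params <- subject_params()   # young-adult condition means
montage <- standard_montage("basic")
for (session in c("active", "sham")) {
  p <- gonogoerp:::apply_stim_effect(params, session)  # null: no-op
  rec <- simulate_subject(make_schedule(task, seed = seed), p, montage,
                          fs = 128, seed = split_seed(seed, match(session,
                                                                  c("active",
                                                                    "sham"))))
  files <- file.path(out_dir, sprintf("S01_%s%s", session,
                                      c(".edf", "_events.tsv",
                                        "_montage.json")))
  write_recording(rec, files[1], files[2], files[3])
  cat(sprintf("%s session: %.1f s of %d-channel EEG -> %s\n", session,
              ncol(rec$data) / rec$fs, nrow(rec$data), files[1]))
}

# round-trip sanity: the bundle reads back losslessly (16-bit quantization)
back <- read_recording(file.path(out_dir, "S01_sham.edf"),
                       file.path(out_dir, "S01_sham_events.tsv"),
                       file.path(out_dir, "S01_sham_montage.json"))
cat(sprintf("round trip: %d events preserved, fs = %g Hz\n",
            nrow(back$events), back$fs))
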