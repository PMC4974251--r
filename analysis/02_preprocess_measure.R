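#!/usr/bin/env Rscript

# Stage 2: run the full signal chain over the young-adult (exp1) null cohort
# - 23 subjects x 2 stimulation sessions, 32 trials/block - and write the
# long-format measure table plus condition summaries and the grand-average
# waveforms. The statistics stage (03) consumes the cached measure table.

library(gonogoerp)

dir.create("results/exp1", showWarnings = FALSE, recursive = TRUE)
cfg <- run_config("exp1", trials_per_block = 32, montage = "basic",
                  seed = 42, run_bf = FALSE, cache_dir = "results/cache")
res <- run_experiment(cfg, verbose = FALSE)

write_tables(res$measures, out_dir = "results/exp1")
cat(sprintf("measures: %d rows over %d subjects, %d excluded\n",
            nrow(res$measures), length(unique(res$measures$subject)),
            nrow(res$exclusions)))

# condition means the later stages reason about
for (ms in c("rt", "cnv", "p300_amp", "tlrp")) {
  sub <- res$measures[res$measures$measure == ms, ]
  cm <- tapply(sub$value, sub$cue, mean, na.rm = TRUE)
  cat(sprintf("  %-9s directional %8.1f   non-directional %8.1f\n",
              ms, cm[["directional"]], cm[["non-directional"]]))
}

# grand-average waveforms of one representative session, as CSV
rec <- simulate_subject(make_schedule(cfg$task, seed = 1),
                        cfg$base_params, cfg$montage, cfg$fs, seed = 1)
prep <- prepare_session(rec, cfg, "sham")
waves <- do.call(rbind, lapply(names(prep$lrp_target), function(cu) {
  data.frame(cue = cu, time_ms = prep$lrp_target[[cu]]$times,
             lrp_uv = as.numeric(prep$lrp_target[[cu]]$values))
}))
utils::write.csv(waves, "results/exp1/lrp_target_waveforms.csv",
                 row.names = FALSE)
cz <- do.call(rbind, lapply(names(prep$cue_locked), function(cell) {
  data.frame(cell = cell, time_ms = prep$cue_locked[[cell]]$times,
             cz_uv = prep$cue_locked[[cell]]$values["Cz", ])
}))
utils::write.csv(cz, "results/exp1/cue_locked_cz_waveforms.csv",
                 row.names = FALSE)
cat("waveform CSVs written under results/exp1/\n")
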