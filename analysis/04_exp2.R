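#!/usr/bin/env Rscript

# Stage 4: the older-adult (exp2) design - 37 subjects with a
# between-subjects stimulated-hemisphere factor (21 dominant /
# 16 non-dominant), lengthened ITI (2500-3500 ms), P300 window 250-650 ms -
# mixed ANOVA plus simple-effects follow-ups within each hemisphere group.

library(gonogoerp)

dir.create("results/exp2", showWarnings = FALSE, recursive = TRUE)
cfg <- run_config("exp2", trials_per_block = 24, montage = "basic",
                  seed = 43, run_bf = FALSE, cache_dir = "results/cache")
res <- run_experiment(cfg)
write_tables(res$measures, res$anova, out_dir = "results/exp2")

cat("== mixed ANOVA: cue, stimulation and hemisphere rows ==\n")
for (m in c("rt", "cnv", "p300_amp")) {
  a <- res$anova[[m]]
  show <- a[a$effect %in% c("cue", "stimulation", "group"), ]
  for (i in seq_len(nrow(show))) {
    cat(sprintf("  %-9s %-12s F(%d,%d) = %7.2f (p = %.3g)\n", m,
                show$effect[i], show$df1[i], show$df2[i], show$F[i],
                show$p[i]))
  }
}

cat("== simple effects of stimulation within each hemisphere group (RT) ==\n")
rt <- res$measures[res$measures$measure == "rt", ]
se <- simple_effects(rt, "group", within = c("stimulation", "cue", "hand"))
for (g in names(se)) {
  stim <- se[[g]][se[[g]]$effect == "stimulation", ]
  cat(sprintf("  %-13s stimulation F(%d,%d) = %5.2f (p = %.2f)\n", g,
              stim$df1, stim$df2, stim$F, stim$p))
}
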