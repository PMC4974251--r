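#' Task configuration for the cued go/nogo paradigm
#'
#' Describes the timed structure of one session: a fixation cross
#' (`fixation_dur`), replaced by the cue which stays on for the whole
#' cue-target interval (`cue_dur`), replaced by the target (`target_dur`),
#' followed by a jittered inter-trial gap drawn uniformly on
#' `[iti_min, iti_max]`. Directional-cue blocks contain a fixed proportion of
#' nogo targets; non-directional blocks contain none.
#'
#' Defaults are the young-adult profile: 500 ms fixation, 1500 ms cue-target
#' interval, 1000 ms target, ITI mean 2000 ms (1500-2500 ms), five blocks of
#' 80 trials (three directional, two non-directional), 30% nogo targets in
#' directional blocks. The older-adult profile lengthens the ITI to a mean of
#' 3000 ms (2500-3500 ms); see [experiment_profile()].
#'
#' @param fixation_dur,cue_dur,target_dur durations in ms.
#' @param iti_mean,iti_min,iti_max inter-trial interval in ms (uniform jitter).
#' @param n_blocks_directional,n_blocks_nondirectional block counts.
#' @param trials_per_block trials per block (> 0).
#' @param nogo_proportion fraction of nogo targets in directional blocks.
#' @return an object of class `task_config`.
#' @export
task_config <- function(fixation_dur = 500, cue_dur = 1500, target_dur = 1000,
                        iti_mean = 2000, iti_min = 1500, iti_max = 2500,
                        n_blocks_directional = 3, n_blocks_nondirectional = 2,
                        trials_per_block = 80, nogo_proportion = 0.3) {
  if (!(iti_min <= iti_mean && iti_mean <= iti_max)) {
    stopf("invalid ITI: need iti_min <= iti_mean <= iti_max (got %g, %g, %g)",
          iti_min, iti_mean, iti_max)
  }
  if (trials_per_block <= 0) stopf("trials_per_block must be > 0")
  if (nogo_proportion < 0 || nogo_proportion > 1) {
    stopf("nogo_proportion must be in [0, 1]")
  }
  if (nogo_proportion > 0 && n_blocks_directional == 0) {
    stopf(paste("nogo targets are defined only under directional cues;",
                "nogo_proportion > 0 requires at least one directional block"))
  }
  if (min(fixation_dur, cue_dur, target_dur) <= 0) {
    stopf("fixation_dur, cue_dur and target_dur must be positive")
  }
  structure(list(
    fixation_dur = fixation_dur, cue_dur = cue_dur, target_dur = target_dur,
    iti_mean = iti_mean, iti_min = iti_min, iti_max = iti_max,
    n_blocks_directional = n_blocks_directional,
    n_blocks_nondirectional = n_blocks_nondirectional,
    trials_per_block = trials_per_block, nogo_proportion = nogo_proportion
  ), class = "task_config")
}

#' Generate the timed trial schedule of one session
#'
#' Lays out every block and trial on a common clock (ms from schedule start):
#' fixation onset, cue onset (`fixation + fixation_dur`), target onset
#' (`cue + cue_dur`, exactly), then a uniform ITI draw before the next
#' fixation. Block order is randomized. In directional blocks the cue side is
#' drawn per trial and `floor(nogo_proportion * trials_per_block)` trials,
#' at randomized positions, carry a nogo target; go targets point to the cued
#' side. Non-directional blocks have no nogo targets and a random target side.
#'
#' @param task a [task_config()].
#' @param seed integer seed; the schedule is a deterministic function of it.
#' @return a `trial_schedule`: a data.frame with one row per trial (columns
#'   `block`, `block_type`, `trial`, `t_fix`, `t_cue`, `t_target`, `cue_side`,
#'   `is_nogo`, `target_side`, `iti`) carrying the `task` as an attribute.
#' @export
make_schedule <- function(task, seed = 1) {
  stopifnot(inherits(task, "task_config"))
  with_seed(split_seed(seed, 101L), {
    types <- c(rep("directional", task$n_blocks_directional),
               rep("non-directional", task$n_blocks_nondirectional))
    types <- sample(types)
    rows <- vector("list", length(types))
    t0 <- 0
    for (b in seq_along(types)) {
      nb <- task$trials_per_block
      directional <- types[b] == "directional"
      if (directional) {
        cue_side <- sample(c("left", "right"), nb, replace = TRUE)
        # guard against binary representation of e.g. 0.3 * 80 = 23.999...
        n_nogo <- floor(task$nogo_proportion * nb + 1e-9)
        is_nogo <- rep(FALSE, nb)
        if (n_nogo > 0) is_nogo[sample.int(nb, n_nogo)] <- TRUE
        target_side <- ifelse(is_nogo, NA_character_, cue_side)
      } else {
        cue_side <- rep(NA_character_, nb)
        is_nogo <- rep(FALSE, nb)
        target_side <- sample(c("left", "right"), nb, replace = TRUE)
      }
      iti <- stats::runif(nb, task$iti_min, task$iti_max)
      t_fix <- numeric(nb)
      for (k in seq_len(nb)) {
        t_fix[k] <- t0
        t0 <- t0 + task$fixation_dur + task$cue_dur + task$target_dur + iti[k]
      }
      rows[[b]] <- data.frame(
        block = b, block_type = types[b], trial = seq_len(nb),
        t_fix = t_fix,
        t_cue = t_fix + task$fixation_dur,
        t_target = t_fix + task$fixation_dur + task$cue_dur,
        cue_side = cue_side, is_nogo = is_nogo, target_side = target_side,
        iti = iti, stringsAsFactors = FALSE
      )
    }
    sched <- do.call(rbind, rows)
    rownames(sched) <- NULL
    structure(sched, task = task, seed = seed,
              class = c("trial_schedule", "data.frame"))
  })
}

# Cue condition label for a schedule row.
cue_condition <- function(block_type) {
  ifelse(block_type == "directional", "directional", "non-directional")
}

#' @export
print.trial_schedule <- function(x, ...) {
  task <- attr(x, "task")
  cat(sprintf("trial_schedule: %d trials in %d blocks (%d directional, %d non-directional)\n",
              nrow(x), task$n_blocks_directional + task$n_blocks_nondirectional,
              task$n_blocks_directional, task$n_blocks_nondirectional))
  cat(sprintf("  nogo trials: %d; span %.1f s\n", sum(x$is_nogo),
              (max(x$t_target) + task$target_dur) / 1000))
  invisible(x)
}
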