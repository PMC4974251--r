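# Shared fixtures: everything is generated in code at test time.

# small task: same structure as the study task, fewer trials
small_task <- function(trials = 8, ...) {
  task_config(trials_per_block = trials, ...)
}

# quiet parameters: no noise, no line hum, no lapses
quiet_params <- function(...) {
  subject_params(miss_rate = 0, false_alarm_rate = 0, noise_rms = 0,
                 line_amp = 0, ...)
}

quick_recording <- function(trials = 8, seed = 1, params = quiet_params(),
                            montage = standard_montage(), fs = 128) {
  sched <- make_schedule(small_task(trials), seed = seed)
  simulate_subject(sched, params, montage, fs, seed = seed)
}

# hand-built ERP waveform for component tests
make_erp <- function(values, times, n_trials = 10, zero_event = "target") {
  structure(list(values = values, times = times, n_trials = n_trials,
                 condition = c(cue = "directional"), baseline_interval = NULL,
                 zero_event = zero_event),
            class = "erp_waveform")
}

# balanced long-format measure table for the statistics layer:
# one row per subject x 2^k cell, cell means built from named effects
sim_measure_table <- function(n_subjects, factors = c("stimulation", "cue"),
                              effects = list(), sd_noise = 1,
                              subject_sd = 2, seed = 1) {
  lev <- list(stimulation = c("active", "sham"),
              cue = c("directional", "non-directional"),
              hand = c("left", "right"),
              hemisphere = c("dominant", "non-dominant"))
  with_seed(seed, {
    grid <- expand.grid(lapply(factors, function(f) lev[[f]]),
                        stringsAsFactors = FALSE)
    names(grid) <- factors
    rows <- lapply(seq_len(n_subjects), function(s) {
      g <- grid
      g$subject <- sprintf("S%02d", s)
      mu <- stats::rnorm(1, 0, subject_sd)
      for (f in names(effects)) {
        mu <- mu + ifelse(g[[f]] == lev[[f]][1], effects[[f]] / 2,
                          -effects[[f]] / 2)
      }
      g$value <- mu + stats::rnorm(nrow(g), 0, sd_noise)
      g
    })
    do.call(rbind, rows)
  })
}

# paired t statistic on subject cell means (oracle for F equivalence)
paired_t <- function(table, factor, dv = "value") {
  lev <- sort(unique(table[[factor]]))
  m <- tapply(table[[dv]], list(table$subject, table[[factor]]), mean)
  d <- m[, lev[1]] - m[, lev[2]]
  mean(d) / (stats::sd(d) / sqrt(length(d)))
}

# Independent quadrature oracle for the JZS one-sample Bayes factor, written
# against the substitution u = 1/(1+n g) (a different parameterization from
# the package's log-g integral).
oracle_jzs_t <- function(t, n, r = 0.5) {
  nu <- n - 1
  f <- function(u) {
    g <- (1 - u) / (n * u)
    dens <- (r^2 / 2)^0.5 / gamma(0.5) * g^(-1.5) * exp(-r^2 / (2 * g))
    like <- u^0.5 * (1 + t^2 * u / nu)^(-(nu + 1) / 2)
    like * dens / (n * u^2)
  }
  num <- stats::integrate(f, 0, 1, rel.tol = 1e-10)$value
  den <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  log(num / den)
}

paired_table <- function(d, factor = "stimulation") {
  lev <- c("active", "sham")
  data.frame(subject = rep(seq_along(d), each = 2),
             stimulation = rep(lev, length(d)),
             value = as.numeric(rbind(d / sqrt(2), -d / sqrt(2))) + 10)
}

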