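test_that("motor potential appears contralateral to the responding hand", {
  # single-trial schedule, go-left forced by a directional-only task
  task <- task_config(trials_per_block = 1, n_blocks_nondirectional = 0,
                      nogo_proportion = 0)
  sched <- make_schedule(task, seed = 2)
  sched$cue_side <- "left"; sched$target_side <- "left"
  p <- quiet_params(cnv_amp = 0, p300_amp = 0)  # isolate the motor component
  rec <- simulate_subject(sched, p, standard_montage(), 128, seed = 2)
  # left-hand response: contralateral C4 carries the deflection
  expect_lt(min(rec$data["C4", ]), -2)
  expect_equal(min(rec$data["C3", ]), 0)   # no spread to ipsilateral
  expect_lt(min(rec$data["Cz", ]), 0)      # vertex spread + CNV
})

test_that("zero stimulation effect makes sessions exchangeable", {
  p <- quiet_params()
  p_active <- gonogoerp:::apply_stim_effect(p, "active")
  expect_identical(p, p_active)
  r1 <- quick_recording(seed = 9, params = p)
  r2 <- quick_recording(seed = 9, params = p_active)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$events, r2$events)
})

test_that("generated RT cell means converge to the ex-Gaussian mean", {
  task <- task_config(trials_per_block = 300, n_blocks_directional = 1,
                      n_blocks_nondirectional = 1, nogo_proportion = 0.3)
  p <- subject_params(noise_rms = 0, line_amp = 0, miss_rate = 0,
                      false_alarm_rate = 0)
  rec <- simulate_subject(make_schedule(task, seed = 4), p,
                          standard_montage("minimal"), 128, seed = 4)
  trials <- attr(rec, "trials")
  go <- trials[!trials$is_nogo, ]
  for (cu in unique(go$cue)) for (h in c("left", "right")) {
    cell <- go$rt[go$cue == cu & go$target_side == h]
    mu <- p$rt_mu[[paste(cu, h, sep = ".")]] + p$rt_tau[[paste(cu, h, sep = ".")]]
    expect_lt(abs(mean(cell) - mu), 4 * 72 / sqrt(length(cell)))
  }
})

test_that("omission and false-alarm frequencies converge to configured rates", {
  task <- task_config(trials_per_block = 400, n_blocks_directional = 1,
                      n_blocks_nondirectional = 0, nogo_proportion = 0.3)
  p <- subject_params(noise_rms = 0, line_amp = 0, miss_rate = 0.1,
                      false_alarm_rate = 0.05)
  rec <- simulate_subject(make_schedule(task, seed = 6), p,
                          standard_montage("minimal"), 128, seed = 6)
  trials <- attr(rec, "trials")
  miss_hat <- mean(is.na(trials$rt[!trials$is_nogo]))
  fa_hat <- mean(!is.na(trials$rt[trials$is_nogo]))
  expect_lt(abs(miss_hat - 0.1), 0.06)
  expect_lt(abs(fa_hat - 0.05), 0.06)
})

test_that("zero between-subject spread reproduces the base parameters", {
  sd0 <- list(amp_shared = 0, amp_cond = 0, onset_shared = 0,
              onset_cond = 0, rt_shared = 0, rt_cond = 0)
  p <- draw_subject_params(subject_params(), sd0, seed = 5)
  expect_equal(p$cnv_amp, subject_params()$cnv_amp)
  expect_equal(p$rt_mu, subject_params()$rt_mu)
  expect_equal(p$tlrp_onset, subject_params()$tlrp_onset)
})

test_that("cohort plans carry the between-subject design and counterbalance", {
  spec <- cohort_spec(37, rep(c("dominant", "non-dominant"), c(21, 16)),
                      seed = 3)
  plan <- gonogoerp:::cohort_plan(spec)
  expect_equal(nrow(plan), 74)  # 37 subjects x 2 sessions
  expect_equal(sum(tapply(plan$group, plan$subject, unique) == "dominant"), 21)
  first <- plan$stimulation[plan$session == 1]
  expect_true(all(sort(unique(first)) == c("active", "sham")))
  expect_equal(as.numeric(abs(diff(table(first)))), 1)  # alternating order, odd n
})

test_that("cohorts are bit-reproducible from the seed", {
  spec <- cohort_spec(2, seed = 21)
  task <- small_task(4)
  a <- generate_cohort(spec, task, quiet_params(), standard_montage("minimal"))
  b <- generate_cohort(spec, task, quiet_params(), standard_montage("minimal"))
  expect_identical(a[[1]]$recording$events, b[[1]]$recording$events)
  expect_identical(a[[3]]$recording$data, b[[3]]$recording$data)
  expect_equal(length(a), 4)
})

test_that("missing required channels are rejected by name", {
  m <- structure(c(Cz = "scalp", Pz = "scalp", M1 = "mastoid",
                   M2 = "mastoid"), class = "montage")
  expect_error(
    simulate_subject(make_schedule(small_task(2), 1), quiet_params(), m, 128, 1),
    "C3")
})

test_that("1/f noise has the configured RMS and spectral slope", {
  x <- noise_1f(2^14, 128, rms = 5, alpha = 1, seed = 8)
  expect_equal(stats::sd(x), 5, tolerance = 1e-6)
  expect_identical(x, noise_1f(2^14, 128, rms = 5, alpha = 1, seed = 8))
  sp <- stats::spec.pgram(stats::ts(x, frequency = 128), plot = FALSE,
                          spans = 31)
  sel <- sp$freq > 0.5 & sp$freq < 40
  slope <- stats::coef(stats::lm(log(sp$spec[sel]) ~ log(sp$freq[sel])))[2]
  expect_lt(abs(slope - (-1)), 0.3)
})
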