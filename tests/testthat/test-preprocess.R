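# hand-built recording: known sinusoids + a simple event stream
sine_recording <- function(freqs, amps, fs = 128, dur_s = 90,
                           montage = standard_montage("minimal")) {
  n <- fs * dur_s
  t <- (0:(n - 1)) / fs
  x <- rowSums(vapply(seq_along(freqs), function(i)
    amps[i] * sin(2 * pi * freqs[i] * t), numeric(n)))
  data <- matrix(rep(x, each = length(montage)), nrow = length(montage),
                 dimnames = list(names(montage), NULL))
  events <- data.frame(onset_ms = c(5000, 5500, 7000),
                       code = c("FIX", "CUE_DIR_L", "TGT_GO_L"))
  continuous_recording(data, fs, names(montage), montage, events)
}

test_that("average-mastoid re-referencing zeroes the mastoid mean and rejects reuse", {
  rec <- quick_recording(trials = 2, seed = 3,
                         params = subject_params(noise_rms = 2))
  ref <- rereference_mastoids(rec)
  expect_lt(max(abs(colSums(ref$data[c("M1", "M2"), ]))), 1e-9)
  expect_error(rereference_mastoids(ref), "already referenced")
  # common-mode rejection: adding a constant to every channel changes nothing
  rec2 <- rec
  rec2$data <- rec2$data + 42
  ref2 <- rereference_mastoids(rec2)
  expect_equal(ref$data, ref2$data, tolerance = 1e-12)
})

test_that("band-pass and notch meet their frequency-response contracts", {
  fs <- 128
  # 50 Hz line: attenuated by at least 20 dB
  rec50 <- sine_recording(50, 10, fs = fs)
  out50 <- filter_recording(rec50, c(0.02, 30), 50)
  mid <- 3000:8000
  expect_lt(stats::sd(out50$data["Cz", mid]) / stats::sd(rec50$data["Cz", mid]),
            0.1)
  # 10 Hz passband tone: amplitude within 5%, zero-phase (no sample shift)
  rec10 <- sine_recording(10, 10, fs = fs)
  out10 <- filter_recording(rec10, c(0.02, 30), 50)
  expect_equal(stats::sd(out10$data["Cz", mid]),
               stats::sd(rec10$data["Cz", mid]), tolerance = 0.05)
  cc <- stats::ccf(out10$data["Cz", mid], rec10$data["Cz", mid],
                   lag.max = 3, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # DC is removed by the high-pass limit
  recdc <- sine_recording(10, 0, fs = fs)
  recdc$data <- recdc$data + 7
  outdc <- filter_recording(recdc, c(0.02, 30), 50)
  expect_lt(max(abs(outdc$data["Cz", mid])), 0.5)
  # invalid band edges
  expect_error(filter_recording(rec10, c(0.02, 70), 50), "Nyquist")
})

test_that("epoch extraction follows the half-open ms-to-sample convention", {
  rec <- quick_recording(trials = 3, seed = 4, fs = 256)
  ep <- extract_epochs(rec, "target", -500, 1000)
  expect_equal(dim(ep$data)[3], 384)  # round(1500 * 256 / 1000)
  expect_equal(ep$times[1], round(-500 * 256 / 1000) / 256 * 1000)
})

test_that("response-locked epochs align to target onset + RT and drop nogo", {
  m <- standard_montage("minimal")
  fs <- 128
  n <- fs * 30
  data <- matrix(0, length(m), n, dimnames = list(names(m), NULL))
  # one go trial with RT 400 and a spike at the response sample,
  # one nogo trial without a response
  events <- data.frame(
    onset_ms = c(2000, 2500, 4000, 4400, 9000, 9500, 11000),
    code = c("FIX", "CUE_DIR_L", "TGT_GO_L", "RESP_L",
             "FIX", "CUE_DIR_R", "TGT_NOGO"))
  data[, gonogoerp:::ms_to_sample(4400, fs) + 1] <- 5
  rec <- continuous_recording(data, fs, names(m), m, events)
  ep <- extract_epochs(rec, "response", -800, 200)
  expect_equal(dim(ep$data)[1], 1)          # nogo trial has no zero event
  expect_equal(attr(ep, "n_no_zero_event"), 1)
  expect_equal(ep$meta$rt, 400)
  zero_idx <- which.min(abs(ep$times))
  expect_equal(as.numeric(ep$data[1, "Cz", zero_idx]), 5)
  # requesting a zero event absent from the stream fails
  rec$events <- rec$events[rec$events$code != "RESP_L", ]
  expect_error(extract_epochs(rec, "response", -800, 200), "no 'response'")
})

test_that("baselining zeroes the interval mean, is idempotent, and shifts ramps by closed form", {
  rec <- quick_recording(trials = 3, seed = 5,
                         params = subject_params(noise_rms = 3))
  ep <- extract_epochs(rec, "target", -300, 500)
  b1 <- baseline(ep, c(-200, 0))
  sel <- b1$times >= -200 & b1$times < 0
  expect_lt(max(abs(apply(b1$data[, , sel, drop = FALSE], c(1, 2), mean))),
            1e-9)
  b2 <- baseline(b1, c(-200, 0))
  expect_equal(b1$data, b2$data, tolerance = 1e-12)
  expect_error(baseline(ep, c(-900, -700)), "outside epoch")
  # linear ramp a*t + b over baseline [-200, 0) loses the ramp's mean there
  a <- 0.03
  ep2 <- ep
  ep2$data[] <- rep(a * ep$times, each = prod(dim(ep$data)[1:2]))
  b3 <- baseline(ep2, c(-200, 0))
  expected <- a * ep$times - mean(a * ep$times[sel])
  expect_equal(as.numeric(b3$data[1, 1, ]), expected, tolerance = 1e-9)
  expect_lt(abs(mean(a * ep$times[sel]) - a * (-100)), a * 1000 / 128)
})

test_that("artifact rejection masks exactly the contaminated trials", {
  p <- subject_params(noise_rms = 3)
  rec <- quick_recording(trials = 10, seed = 6, params = p)
  trials <- attr(rec, "trials")
  spike_at <- trials$t_target[c(3, 7, 11)] + 2000 + 100
  rec <- inject_artifacts(rec, spike_at, amplitude = 500, channel = "Cz")
  ep <- extract_epochs(rec, "target", -200, 800)
  ep <- reject_artifacts(ep, 100)
  expect_equal(which(ep$reject), c(3, 7, 11))
  # effectively infinite threshold: nothing rejected
  ep2 <- reject_artifacts(extract_epochs(rec, "target", -200, 800), 1e9)
  expect_false(any(ep2$reject))
  expect_error(reject_artifacts(ep, -5), "> 0")
})

test_that("condition averaging respects cells, rejections and 1/sqrt(N) noise shrinkage", {
  rec <- quick_recording(trials = 6, seed = 7)
  ep <- baseline(extract_epochs(rec, "target", -200, 800), c(-200, 0))
  ok <- !ep$meta$is_nogo & ep$meta$correct
  avg <- average_condition(ep, c("cue", "hand"), ok)
  one <- avg[["directional|left"]]
  idx <- which(ok & ep$meta$cue == "directional" & ep$meta$hand == "left")
  expect_equal(one$n_trials, length(idx))
  expect_equal(one$values,
               colMeans(ep$data[idx, , , drop = FALSE], dims = 1))
  # identical trials average to any one of them
  ep2 <- ep
  cu1 <- ep2$meta$cue[1]
  for (i in which(ep2$meta$cue == cu1)) ep2$data[i, , ] <- ep2$data[1, , ]
  a2 <- average_condition(ep2, "cue", ep2$meta$cue == cu1)
  expect_equal(a2[[cu1]]$values, ep2$data[1, , ])
  # noise-only epochs: average RMS shrinks like 1/sqrt(N)
  set.seed(1)
  nz <- ep
  nz$data[] <- stats::rnorm(length(nz$data))
  all_avg <- average_condition(nz, "is_nogo", !nz$meta$is_nogo)
  n_used <- sum(!nz$meta$is_nogo)
  expect_equal(stats::sd(all_avg[["FALSE"]]$values), 1 / sqrt(n_used),
               tolerance = 0.15)
  # an empty requested cell errors with its name
  expect_error(average_condition(ep, c("cue", "hand"),
                                 ep$meta$cue == "nothing"), "no retained")
})

test_that("behavioral measures match direct arithmetic on the trial table", {
  p <- quiet_params()
  rec <- quick_recording(trials = 10, seed = 8, params = p)
  ep <- extract_epochs(rec, "target", -200, 800, stimulation = "sham")
  bm <- behavioral_measures(ep, "S01", "all")
  meta <- ep$meta
  for (cu in unique(meta$cue[!meta$is_nogo])) {
    cell <- meta[!meta$is_nogo & meta$cue == cu & meta$target_side == "left", ]
    got <- bm$value[bm$measure == "rt" & bm$cue == cu & bm$hand == "left"]
    expect_equal(got, mean(cell$rt[cell$correct]))
  }
  expect_true(all(bm$value[bm$measure == "error_rate"] == 0))
  expect_true(all(bm$value[bm$measure == "false_alarm_rate"] == 0))
  expect_equal(unique(bm$hand[bm$measure == "false_alarm_rate"]), "collapsed")
})

test_that("filtering and epoching commute for interior epochs", {
  p <- subject_params(noise_rms = 3)
  rec <- quick_recording(trials = 4, seed = 9, params = p)
  rec <- rereference_mastoids(rec)
  filtered <- filter_recording(rec, c(0.02, 30), 50)
  ep_then <- extract_epochs(filtered, "target", -200, 600)
  # filter each epoch after extraction instead
  ep_first <- extract_epochs(rec, "target", -200, 600)
  for (i in seq_len(dim(ep_first$data)[1])) {
    for (j in seq_len(dim(ep_first$data)[2])) {
      x <- ep_first$data[i, j, ]
      x <- gonogoerp:::filtfilt_pad(gonogoerp:::notch_coef(50, 128)$b,
                                    gonogoerp:::notch_coef(50, 128)$a, x)
      bf <- signal::butter(2, 30 / 64, type = "low")
      ep_first$data[i, j, ] <- gonogoerp:::filtfilt_pad(bf$b, bf$a, x)
    }
  }
  # the continuous high-pass removes sub-0.02 Hz drift that the short
  # epoch-wise path cannot see; per-epoch baselining removes exactly that
  # offset, after which the two routes agree on interior samples
  bl <- function(ep) baseline(ep, c(-200, 0))
  interior <- 30:70
  d <- bl(ep_then)$data[, , interior] - bl(ep_first)$data[, , interior]
  expect_lt(max(abs(d)), 0.5)
})
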