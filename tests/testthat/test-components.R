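test_that("mean amplitude is the window mean of the waveform", {
  tt <- seq(0, 1000, by = 4)
  erp <- make_erp(rbind(Cz = rep(-5, length(tt))), tt)
  expect_equal(mean_amplitude(erp, "Cz", c(200, 400)), -5)
  # linear ramp 0 -> -10 across the window: midpoint -5
  ramp <- rbind(Cz = approx(c(200, 400), c(0, -10), xout = tt, rule = 2)$y)
  expect_equal(mean_amplitude(make_erp(ramp, tt), "Cz", c(200, 400)), -5,
               tolerance = 1e-9)
  expect_error(mean_amplitude(erp, "Cz", c(2000, 2400)), "outside")
  expect_error(mean_amplitude(erp, "Fz", c(200, 400)), "not present")
})

test_that("peak measures find the extremum with earliest-tie and boundary rules", {
  tt <- seq(0, 800, by = 2)
  bump <- 10 * exp(-(tt - 350)^2 / (2 * 40^2))
  pk <- peak_measure(make_erp(rbind(Pz = bump), tt), "Pz", c(200, 500),
                     "positive")
  expect_equal(pk[["amplitude"]], 10, tolerance = 1e-6)
  expect_equal(pk[["latency"]], 350)
  # monotone rising waveform: peak at the window's last sample
  mono <- peak_measure(make_erp(rbind(Pz = tt / 100), tt), "Pz", c(200, 500),
                       "positive")
  expect_equal(mono[["latency"]], 500)
  # two equal maxima: earliest wins
  twin <- numeric(length(tt))
  twin[tt == 300] <- 4; twin[tt == 400] <- 4
  expect_equal(peak_measure(make_erp(rbind(Pz = twin), tt), "Pz",
                            c(200, 500), "positive")[["latency"]], 300)
})

test_that("LRP double subtraction satisfies its algebraic identities", {
  tt <- 0:10
  erp2 <- function(c3, c4) make_erp(rbind(C3 = rep(c3, 11), C4 = rep(c4, 11)), tt)
  # direct arithmetic: (C4-C3)_LH = -3, (C3-C4)_RH = -5 -> LRP -4
  l <- derive_lrp(erp2(3, 0), erp2(-5, 0))
  expect_equal(unique(l$values), -4)
  # activity identical for both hands (non-lateralized) cancels
  sym <- derive_lrp(erp2(1, 7), erp2(1, 7))
  expect_equal(unique(sym$values), 0)
  # swapping C3/C4 labels in both hands flips the sign
  swap <- function(e) { rownames(e$values) <- c("C4", "C3"); e }
  l2 <- derive_lrp(swap(erp2(3, 0)), swap(erp2(-5, 0)))
  expect_equal(l2$values, -l$values)
  # mismatched time bases are rejected
  bad <- erp2(1, 2); bad$times <- bad$times + 1
  expect_error(derive_lrp(erp2(1, 2), bad), "time base")
})

test_that("LRP derivation commutes with trial averaging (linearity)", {
  rec <- quick_recording(trials = 6, seed = 10)
  ep <- baseline(extract_epochs(rec, "target", -200, 800), c(-200, 0))
  ok <- !ep$meta$is_nogo & ep$meta$correct
  avg <- average_condition(ep, "hand", ok)
  lrp_avg <- derive_lrp(avg[["left"]], avg[["right"]])
  # per-trial double subtraction, then average
  li <- which(ok & ep$meta$hand == "left")
  ri <- which(ok & ep$meta$hand == "right")
  per_trial <- 0.5 *
    (colMeans(ep$data[li, "C4", , drop = FALSE] -
                ep$data[li, "C3", , drop = FALSE], dims = 1) +
       colMeans(ep$data[ri, "C3", , drop = FALSE] -
                  ep$data[ri, "C4", , drop = FALSE], dims = 1))
  expect_equal(as.numeric(lrp_avg$values), as.numeric(per_trial),
               tolerance = 1e-12)
})

test_that("the LRP low-pass is zero-phase and meets its response contract", {
  fs <- 256
  tt <- seq(-200, 800, by = 1000 / fs)
  l5 <- structure(list(values = sin(2 * pi * 5 * tt / 1000), times = tt),
                  class = "lrp_waveform")
  f5 <- lowpass_lrp(l5, 30, fs)
  mid <- 60:200
  expect_equal(stats::sd(f5$values[mid]), stats::sd(l5$values[mid]),
               tolerance = 0.05)
  l60 <- structure(list(values = sin(2 * pi * 60 * tt / 1000), times = tt),
                   class = "lrp_waveform")
  f60 <- lowpass_lrp(l60, 30, fs)
  expect_lt(stats::sd(f60$values[mid]) / stats::sd(l60$values[mid]), 0.1)
  # a smooth template's peak latency does not move
  tpl <- structure(list(values = -exp(-(tt - 300)^2 / (2 * 60^2)), times = tt),
                   class = "lrp_waveform")
  ftpl <- lowpass_lrp(tpl, 30, fs)
  expect_lt(abs(tt[which.min(ftpl$values)] - tt[which.min(tpl$values)]),
            1000 / fs + 1e-9)
  expect_error(lowpass_lrp(tpl, 200, fs), "Nyquist")
})

test_that("fractional-area latency matches closed-form integration on a pulse", {
  tt <- seq(100, 600, by = 0.25)
  v <- ifelse(tt >= 200 & tt < 400, -4, 0)
  # threshold -1.6, suprathreshold deviation -2.4 over 200 ms, area 480;
  # 25% of area is reached at 250 ms
  expect_equal(fractional_area_latency(v, tt, c(100, 600), 0.25, "negative"),
               250, tolerance = 0.5)
  # limiting fractions approach the pulse edges
  expect_equal(fractional_area_latency(v, tt, c(100, 600), 0.001, "negative"),
               200, tolerance = 1.5)
  expect_equal(fractional_area_latency(v, tt, c(100, 600), 0.999, "negative"),
               400, tolerance = 1.5)
})

test_that("fractional-area latency is monotone in the fraction and scale/shift equivariant", {
  set.seed(42)
  tt <- seq(0, 600, by = 4)
  for (rep in 1:10) {
    w <- -abs(stats::filter(stats::rnorm(length(tt)), rep(1, 15),
                            circular = TRUE))
    w <- as.numeric(w)
    fr <- seq(0.1, 0.9, by = 0.1)
    lat <- vapply(fr, function(f)
      fractional_area_latency(w, tt, c(100, 500), f, "negative"), numeric(1))
    expect_true(all(diff(lat) >= -1e-9))
    # amplitude scaling leaves the latency unchanged
    expect_equal(fractional_area_latency(3.7 * w, tt, c(100, 500), 0.25,
                                         "negative"),
                 fractional_area_latency(w, tt, c(100, 500), 0.25, "negative"))
  }
  # time-shift equivariance for an interior pulse
  pulse <- function(t0) {
    v <- numeric(length(tt)); v[tt >= t0 & tt < t0 + 100] <- -2; v
  }
  l0 <- fractional_area_latency(pulse(200), tt, c(50, 550), 0.25, "negative")
  l1 <- fractional_area_latency(pulse(260), tt, c(50, 550), 0.25, "negative")
  expect_equal(l1 - l0, 60, tolerance = 1e-9)
})

test_that("zero suprathreshold area raises the dedicated error condition", {
  tt <- seq(0, 500, by = 4)
  expect_error(
    fractional_area_latency(rep(-2, length(tt)), tt, c(100, 400), 0.25,
                            "negative"),
    class = "gonogoerp_undefined_latency")
  expect_error(fractional_area_latency(rep(1, 10), 1:10, c(1, 10), 1.2),
               "fraction")
})

test_that("component specs validate their statistic/fraction pairing", {
  expect_error(component_spec("CNV", "Cz", c(1300, 1500), "mean_amplitude",
                              fraction = 0.25), "latency")
  sp <- component_spec("tLRP", NA, c(100, 600), "fractional_area_latency")
  expect_equal(sp$fraction, 0.25)
})

test_that("measure_all produces the factorial measure layout of one session", {
  rec <- quick_recording(trials = 8, seed = 12)
  cfg <- run_config("exp1")
  prep <- prepare_session(rec, cfg, "sham")
  m <- measure_all(prep, cfg$specs, "S01", "all", "sham")
  # CNV and P300 keyed cue x hand; LRP onsets keyed by cue only
  expect_equal(sum(m$measure == "cnv"), 4)
  expect_equal(sum(m$measure == "p300_amp"), 4)
  expect_equal(sum(m$measure == "tlrp"), 2)
  expect_equal(sum(m$measure == "rlrp"), 2)
  expect_true(all(m$hand[m$measure %in% c("tlrp", "rlrp")] == "collapsed"))
  expect_equal(nrow(measure_all(prep, list(), "S01")), 0)
  expect_error(measure_all(prep, list(component_spec("XYZ", "Cz", c(0, 1),
                                                     "mean_amplitude"))),
               "resolve")
})
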