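test_that("EDF + events + montage bundle round-trips a recording", {
  rec <- quick_recording(trials = 3, seed = 13,
                         params = subject_params(noise_rms = 3))
  d <- withr::local_tempdir()
  files <- file.path(d, c("rec.edf", "rec_events.tsv", "montage.json"))
  write_recording(rec, files[1], files[2], files[3])
  back <- read_recording(files[1], files[2], files[3])
  # data within the 16-bit quantization step per channel
  rng <- apply(rec$data, 1, function(x) diff(range(x)))
  qstep <- (rng * 1.1) / 65534
  err <- apply(abs(back$data - rec$data), 1, max)
  expect_true(all(err <= qstep + 1e-9))
  # events and metadata exactly
  expect_equal(back$events, rec$events)
  expect_equal(unclass(back$montage), unclass(rec$montage))
  expect_equal(back$fs, rec$fs)
  expect_equal(back$channel_names, rec$channel_names)
})

test_that("a 64-channel montage resolves all required channels and roles", {
  m <- standard_montage("full64")
  expect_equal(length(m), 66)
  expect_silent(gonogoerp:::validate_montage(m))
  expect_equal(sum(m == "mastoid"), 2)
  expect_true(all(c("Cz", "Pz", "C3", "C4") %in% names(m)))
  d <- withr::local_tempdir()
  write_montage(m, file.path(d, "m.json"))
  expect_equal(unclass(read_montage(file.path(d, "m.json"))), unclass(m))
})

test_that("events beyond the recording or with unknown codes are rejected", {
  rec <- quick_recording(trials = 2, seed = 1)
  past_end <- ncol(rec$data) / rec$fs * 1000 + 5000
  bad <- rbind(rec$events, data.frame(onset_ms = past_end, code = "FIX"))
  expect_error(
    continuous_recording(rec$data, rec$fs, rec$channel_names, rec$montage,
                         bad), "outside recording")
  expect_error(validate_events(data.frame(onset_ms = 1, code = "BANANA")),
               "valid codes")
  # a response with no target in its trial is malformed
  expect_error(validate_events(data.frame(
    onset_ms = c(0, 100), code = c("FIX", "RESP_L"))), "no target")
  # a false alarm (response after a nogo target) is well-formed
  expect_silent(validate_events(data.frame(
    onset_ms = c(0, 500, 2000, 2400),
    code = c("FIX", "CUE_DIR_L", "TGT_NOGO", "RESP_L"))))
})

test_that("measure tables round-trip and summaries conserve cell means", {
  tab <- sim_measure_table(5, c("stimulation", "cue", "hand"),
                           effects = list(cue = 30), seed = 2)
  tab$group <- "all"; tab$measure <- "rt"; tab$value <- tab$value + 400
  d <- withr::local_tempdir()
  files <- write_tables(tab, out_dir = d)
  expect_true(file.exists(file.path(d, "measures.csv")))
  back <- read_measures(file.path(d, "measures.csv"))
  expect_equal(back$value, tab$value)
  expect_equal(back$subject, tab$subject)
  # Exp-1 layout: 2 stimulation x 2 cue x 2 hand = 8 cells
  smry <- utils::read.csv(file.path(d, "summary_rt.csv"))
  expect_equal(nrow(smry), 8)
  one <- smry[1, ]
  manual <- tab$value[tab$stimulation == one$stimulation &
                        tab$cue == one$cue & tab$hand == one$hand]
  expect_equal(one$mean, mean(manual))
  expect_equal(one$sem, stats::sd(manual) / sqrt(length(manual)))
})

test_that("empty or duplicated measure tables are rejected", {
  expect_error(write_tables(data.frame(), out_dir = tempdir()), "empty")
  tab <- sim_measure_table(2, c("stimulation", "cue"))
  tab$group <- "all"; tab$measure <- "cnv"; tab$hand <- "left"
  dup <- rbind(tab, tab[1, ])
  expect_error(write_tables(dup, out_dir = tempdir()), "duplicate")
})
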