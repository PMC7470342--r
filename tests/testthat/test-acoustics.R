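test_that("band SPL matches the closed form for a pure tone", {
  cal <- identity_cal()
  fs <- 80000
  x <- 1e6 * sin(2 * pi * 10000 * seq_len(2 * fs) / fs)  # 1 Pa rms/sqrt(2)
  bands <- default_bands()
  spl_high <- band_rms_spl(x, cal, bands$high)
  expect_equal(spl_high, 20 * log10(1e6 / sqrt(2)), tolerance = 0.1)
  # out-of-band leakage with the Hann window is far below the tone
  expect_lt(band_rms_spl(x, cal, bands$low), spl_high - 40)
  # broadband power dominates every sub-band on white noise
  set.seed(1)
  wn <- rnorm(2 * fs)
  expect_gte(band_rms_spl(wn, cal, bands$broadband),
             band_rms_spl(wn, cal, bands$high))
  expect_gte(band_rms_spl(wn, cal, bands$broadband),
             band_rms_spl(wn, cal, bands$low))
})

test_that("band powers of tiling sub-bands reconstruct broadband power", {
  cal <- identity_cal()
  set.seed(2)
  x <- rnorm(160000)
  cuts <- c(50, 1200, 7000, 20000, 40000)
  parts <- vapply(seq_len(length(cuts) - 1), function(i) {
    10^(band_rms_spl(x, cal, band_def("p", cuts[i], cuts[i + 1])) / 10)
  }, numeric(1))
  whole <- 10^(band_rms_spl(x, cal, band_def("w", 50, 40000)) / 10)
  expect_lte(sum(parts), whole * 1.01)
  expect_equal(sum(parts), whole, tolerance = 0.01)
})

test_that("calibration linearity: x10 amplitude is exactly +20 dB", {
  cal <- identity_cal()
  set.seed(3)
  x <- rnorm(100000)
  for (b in default_bands()) {
    expect_equal(band_rms_spl(10 * x, cal, b) - band_rms_spl(x, cal, b),
                 20, tolerance = 1e-9)
  }
})

test_that("band SPL rejects degenerate inputs", {
  cal <- identity_cal()
  expect_error(band_rms_spl(numeric(0), cal, default_bands()$high), "empty")
  expect_error(band_rms_spl(rep(0, 1000), cal, default_bands()$high),
               "silent")
  expect_error(band_rms_spl(rnorm(1000), cal, band_def("x", 50000, 60000)),
               "Nyquist")
  expect_warning(band_rms_spl(rnorm(10000), calibration_spec(0, 0, 1, 40000),
                              band_def("h", 7000, 40000)), "truncated")
})

test_that("manifest processing round-trips synthetic clips", {
  cal <- calibration_spec()
  dir <- withr::local_tempdir()
  targets <- list(c(high = 110, low = 100), c(high = 120, low = 105),
                  c(high = 95, low = 92))
  paths <- vapply(seq_along(targets), function(i) {
    f <- file.path(dir, sprintf("clip%d.wav", i))
    write_wav(synthesize_audio_clip(1, 80000, targets[[i]], cal, seed = i), f)
    f
  }, character(1))
  manifest <- data.frame(
    station_id = "9M",
    timestamp = as.POSIXct("2017-04-01 06:00:00", tz = "UTC") +
      1200 * (seq_along(paths) - 1),
    path = paths)
  recs <- process_recordings(manifest, cal)
  expect_equal(nrow(recs), 3)
  expect_true(all(is.finite(recs$spl_high_dB)))
  for (i in seq_along(targets)) {
    expect_lt(abs(recs$spl_high_dB[i] - targets[[i]][["high"]]), 1.1)
    expect_lt(abs(recs$spl_low_dB[i] - targets[[i]][["low"]]), 1.1)
  }
  # unreadable file: logged skip, not fatal
  manifest2 <- rbind(manifest,
                     data.frame(station_id = "9M",
                                timestamp = manifest$timestamp[3] + 1200,
                                path = file.path(dir, "missing.wav")))
  expect_message(recs2 <- process_recordings(manifest2, cal), "skipped")
  expect_equal(nrow(recs2), 3)
  expect_equal(attr(recs2, "skipped"), file.path(dir, "missing.wav"))
  # sample-rate mismatch is an error
  expect_error(process_recordings(manifest, calibration_spec(0, 0, 1, 48000)),
               "sample rate")
})

test_that("on-the-hour subsampling keeps exactly one third of a 20-min cadence", {
  ts <- seq(as.POSIXct("2017-04-01 00:00", tz = "UTC"), by = 1200,
            length.out = 72 * 3)  # three days
  recs <- data.frame(station_id = "S", timestamp_start = ts,
                     spl_high_dB = 100, spl_low_dB = 90, spl_broad_dB = 101,
                     flags = "", on_hour = NA)
  sub <- subsample_on_hour(recs)
  expect_equal(nrow(sub), nrow(recs) / 3)
  expect_true(all(as.POSIXlt(sub$timestamp_start)$min == 0))
  expect_equal(nrow(subsample_on_hour(recs[0, ])), 0)
  off <- recs[as.POSIXlt(recs$timestamp_start)$min == 20, ]
  expect_equal(nrow(subsample_on_hour(off)), 0)
})

test_that("flag exclusion drops the right records and reports counts", {
  recs <- data.frame(
    station_id = "S",
    timestamp_start = as.POSIXct("2017-04-01", tz = "UTC") + 3600 * (0:99),
    spl_high_dB = 100, spl_low_dB = 90, spl_broad_dB = 101,
    flags = c(rep("vessel", 11), rep("snapping_shrimp,fish", 80),
              rep("rain,snapping_shrimp", 9)),
    on_hour = TRUE)
  ex <- exclude_nonbiological(recs)
  expect_equal(nrow(ex$retained), 80)
  expect_equal(unname(ex$excluded_counts[["vessel"]]), 11L)
  expect_equal(ex$fraction_excluded, 0.20)
  expect_equal(unname(ex$excluded_counts[["vessel"]]) / nrow(recs), 0.11)
  expect_error(exclude_nonbiological(recs, exclude = "submarine"), "unknown")
})

test_that("subsampling and exclusion commute", {
  s <- sim_season(seed = 21)
  a <- exclude_nonbiological(subsample_on_hour(s$records))$retained
  b <- subsample_on_hour(exclude_nonbiological(s$records)$retained)
  expect_identical(a, b)
})

test_that("daily means average dB arithmetically and keep gaps as NA", {
  ts <- as.POSIXct(c("2017-04-01 01:00", "2017-04-01 13:00",
                     "2017-04-03 05:00"), tz = "UTC")
  recs <- data.frame(station_id = "S", timestamp_start = ts,
                     spl_high_dB = c(100, 110, 95), spl_low_dB = 90,
                     spl_broad_dB = 101, flags = "", on_hour = TRUE)
  d <- daily_mean_spl(recs, "high")
  expect_equal(d$mean_spl, c(105, NA, 95))
  expect_equal(nrow(d), 3)  # Apr 2 present as missing, not dropped
  expect_error(daily_mean_spl(recs[0, ]), "no records")
  # a day fully excluded stays as a missing entry
  recs$flags[3] <- "vessel"
  d2 <- daily_mean_spl(recs, "high", biological_only = TRUE)
  expect_equal(nrow(d2), 1)
})

test_that("heat-map matrix uses the noon-to-noon row convention", {
  ts <- as.POSIXct(c("2017-04-01 13:00", "2017-04-02 11:00",
                     "2017-04-02 13:00"), tz = "UTC")
  recs <- data.frame(station_id = "S", timestamp_start = ts,
                     spl_high_dB = c(1, 2, 3), spl_low_dB = 0,
                     spl_broad_dB = 0, flags = "", on_hour = TRUE)
  m <- heatmap_matrix(recs, "high")
  # 13:00 Apr 1 and 11:00 Apr 2 share the acoustic day that starts Apr 1 noon
  expect_equal(unname(m["2017-04-01", "13:00"]), 1)
  expect_equal(unname(m["2017-04-01", "11:00"]), 2)
  expect_equal(unname(m["2017-04-02", "13:00"]), 3)
  expect_equal(colnames(m)[1], "13:00")  # columns start after noon
})
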