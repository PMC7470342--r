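test_that("temperature generator degenerates to its deterministic parts", {
  p0 <- soundscape_params(annual_temp_amplitude = 0, diel_temp_amplitude = 0,
                          temp_noise_sd = 0, yearly_spring_offsets = numeric(0))
  env <- generate_temperature_series("S", "2017-03-01", "2017-03-10", p0)
  expect_true(all(env$value == p0$annual_temp_mean))

  p1 <- soundscape_params(temp_phase_day = 200, diel_temp_amplitude = 0,
                          temp_noise_sd = 0, yearly_spring_offsets = numeric(0))
  env1 <- generate_temperature_series("S", "2017-01-01", "2017-12-31", p1)
  peak_day <- day_of_year(as.Date(env1$timestamp[which.max(env1$value)]))
  expect_equal(peak_day, 200, tolerance = 1e-8)

  expect_error(generate_temperature_series("S", "2017-05-01", "2017-03-01"),
               "precede")
})

test_that("spring offsets shift mean spring temperature by their difference", {
  p <- soundscape_params(temp_noise_sd = 0.1,
                         yearly_spring_offsets = c("2017" = 1.2,
                                                   "2013" = -1.3),
                         seed = 9)
  mean_spring <- function(year) {
    sw <- spring_window(year)
    env <- generate_temperature_series("S", sw$start_date, sw$end_date, p)
    mean(env$value)
  }
  # same climatological spring; difference is the offset gap up to AR noise
  expect_equal(mean_spring(2017) - mean_spring(2013), 2.5, tolerance = 0.4)
})

test_that("water level is a clean semidiurnal tide", {
  wl <- generate_waterlevel_series("S", "2017-01-01", "2017-01-04",
                                   amplitude_m = 1, period_h = 12.42)
  v <- wl$value
  maxima <- which(diff(sign(diff(v))) == -2) + 1
  gaps_h <- diff(as.numeric(wl$timestamp[maxima])) / 3600
  expect_true(all(abs(gaps_h - 12.42) <= 1 / 3))  # within one 10-min step
  # one day holds 1-2 maxima
  day1 <- as.Date(wl$timestamp[maxima]) == as.Date("2017-01-02")
  expect_true(sum(day1) %in% 1:2)
  expect_error(generate_waterlevel_series("S", "2017-01-01", "2017-01-04",
                                          period_h = 0), "positive")
})

test_that("SPL generator hits its logistic limits exactly at zero noise", {
  p <- soundscape_params(spl_noise_sd = 0, daily_noise_sd = 0,
                         temp_noise_sd = 0, diel_temp_amplitude = 0,
                         annual_temp_amplitude = 0,
                         yearly_spring_offsets = numeric(0),
                         diel_effects = c(high = 0, low = 0, broadband = 0),
                         lunar_effects = list(
                           high = c(new = 0, first_quarter = 0, full = 0,
                                    last_quarter = 0),
                           low = c(new = 0, first_quarter = 0, full = 0,
                                   last_quarter = 0),
                           broadband = c(new = 0, first_quarter = 0,
                                         full = 0, last_quarter = 0)),
                         rain_event_rate = 0, vessel_rate_summer_day = 0)
  # far below midpoint: logistic -> 0
  p$annual_temp_mean <- p$activation_midpoint_T - 10
  cold <- generate_spl_series(
    generate_temperature_series("S", "2017-03-01", "2017-03-03", p), NULL, p)
  expect_equal(cold$spl_high_dB,
               rep(p$band_base_spl[["high"]], nrow(cold)), tolerance = 1e-8)
  # far above midpoint: logistic -> 1
  p$annual_temp_mean <- p$activation_midpoint_T + 10
  warm <- generate_spl_series(
    generate_temperature_series("S", "2017-03-01", "2017-03-03", p), NULL, p)
  expect_equal(warm$spl_low_dB,
               rep(p$band_base_spl[["low"]] + p$band_activity_gain[["low"]],
                   nrow(warm)), tolerance = 1e-8)
})

test_that("noise-free SPL is an exact function of covariates (regression oracle)", {
  p <- soundscape_params(spl_noise_sd = 0, daily_noise_sd = 0,
                         temp_noise_sd = 0, diel_temp_amplitude = 0,
                         annual_temp_amplitude = 0,
                         yearly_spring_offsets = numeric(0),
                         rain_event_rate = 0, vessel_rate_summer_day = 0)
  p$annual_temp_mean <- p$activation_midpoint_T + 10   # activation pinned at 1
  env <- generate_temperature_series("S", "2017-03-01", "2017-04-15", p)
  tide <- generate_waterlevel_series("S", "2017-03-01", "2017-04-15")
  recs <- generate_spl_series(env, tide, p)
  ann <- attach_covariates(recs, env, tide)
  fit <- lm(spl_high_dB ~ day_night + tidal + lunar, data = ann)
  # day -> night drop equals the configured diel effect
  expect_equal(unname(coef(fit)[["day_nightnight"]]),
               -p$diel_effects[["high"]], tolerance = 1e-8)
  expect_equal(unname(coef(fit)[["tidallow"]]),
               p$tidal_effects$high[["low"]] - p$tidal_effects$high[["high"]],
               tolerance = 1e-8)
  expect_lt(sigma(fit), 1e-8)
})

test_that("generators are bit-identical under a fixed seed", {
  s1 <- sim_season(seed = 7)
  s2 <- sim_season(seed = 7)
  expect_identical(s1$records, s2$records)
  sc1 <- generate_seine_catches("S", as.Date("2017-06-01") + 0:3,
                                rep(25, 4), community_params(seed = 3))
  sc2 <- generate_seine_catches("S", as.Date("2017-06-01") + 0:3,
                                rep(25, 4), community_params(seed = 3))
  expect_identical(sc1, sc2)
})

test_that("seine richness responds to temperature as configured", {
  cp <- community_params(seed = 5)
  # T far below the midpoint: nearly all hauls empty
  cold <- generate_seine_catches("S", as.Date("2017-01-01") + 0:49,
                                 rep(cp$richness_midpoint_T - 15, 50), cp)
  cold_rich <- tapply(cold$count > 0, paste(cold$date), sum)
  expect_lt(mean(cold_rich), 0.5)

  # flat logistic at 0.5: mean richness about half the maximum
  cp_flat <- community_params(richness_steepness = 1e9, seed = 6)
  flat <- generate_seine_catches("S", as.Date("2017-01-01") + 0:199,
                                 rep(20, 200), cp_flat)
  flat_rich <- tapply(flat$count > 0, paste(flat$date), sum)
  expect_equal(mean(flat_rich), cp_flat$max_expected_richness / 2,
               tolerance = 0.4)

  # warm months strictly richer than cold months (n = 50 each)
  warm <- generate_seine_catches("S", as.Date("2017-07-01") + 0:49,
                                 rep(28, 50), community_params(seed = 7))
  coldish <- generate_seine_catches("S", as.Date("2017-01-01") + 0:49,
                                    rep(10, 50), community_params(seed = 8))
  warm_rich <- mean(tapply(warm$count > 0, paste(warm$date), sum))
  cold_rich2 <- mean(tapply(coldish$count > 0, paste(coldish$date), sum))
  expect_gt(warm_rich, cold_rich2)
  expect_error(generate_seine_catches("S", as.Date(character(0)), numeric(0)),
               "non-empty")
})

test_that("audio round-trip recovers requested band levels within 1 dB", {
  cal <- calibration_spec()
  bands <- default_bands()
  for (tgt in list(c(high = 85, low = 80), c(high = 120, low = 112),
                   c(high = 138, low = 130))) {
    clip <- synthesize_audio_clip(2, 80000, tgt, cal, seed = 11)
    expect_lt(abs(band_rms_spl(clip, band = bands$high) - tgt[["high"]]), 1)
    expect_lt(abs(band_rms_spl(clip, band = bands$low) - tgt[["low"]]), 1)
  }
  # fish-only clip concentrates energy in the low band
  fish <- synthesize_audio_clip(2, 80000, c(low = 110), cal, seed = 2)
  expect_gte(band_rms_spl(fish, band = bands$low) -
               band_rms_spl(fish, band = bands$high), 10)
  # silent clip
  silent <- synthesize_audio_clip(1, 80000, c(), cal, seed = 1)
  expect_true(all(silent$samples == 0))
  expect_error(band_rms_spl(silent, band = bands$high), "silent")
  # unrepresentable target
  expect_error(synthesize_audio_clip(1, 80000, c(high = 200), cal, seed = 1),
               "representable")
})
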