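# Shared fixtures: an identity calibration (waveform units are uPa) and a
# compact one-season SPL simulation used by several statistics tests.

identity_cal <- function(fs = 80000) calibration_spec(0, 0, 1, fs)

# a short spring season of SPL records for one station-year
sim_season <- function(year = 2017, seed = 42, offsets = NULL,
                       station = "9M", with_tide = FALSE, ...) {
  p <- do.call(soundscape_params, c(list(seed = seed), list(...)))
  if (!is.null(offsets)) p$yearly_spring_offsets <- offsets
  sw <- spring_window(year)
  env <- generate_temperature_series(station, sw$start_date - 30,
                                     sw$end_date + 30, p)
  tide <- if (with_tide) {
    generate_waterlevel_series(station, sw$start_date - 30, sw$end_date + 30)
  } else NULL
  list(params = p, window = sw, env = env, tide = tide,
       records = generate_spl_series(env, tide, p))
}

# true activation-crossing day: first spring day whose daily mean
# temperature reaches the activation midpoint
true_crossing_day <- function(env, window, params) {
  d <- as.Date(env$timestamp)
  dm <- tapply(env$value, d, mean)
  days <- as.Date(names(dm))
  ok <- days >= window$start_date & days <= window$end_date &
    dm >= params$activation_midpoint_T
  days[ok][1]
}
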