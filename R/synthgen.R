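# Synthetic estuarine soundscape generator. Emulates the statistical
# structure the analysis pipeline assumes: a seasonal temperature cycle with
# year-specific spring offsets, logistic temperature activation of biological
# sound (snapping shrimp in the high band, fish choruses in the low band),
# diel/tidal/lunar modulation, summer-daytime vessel contamination, rain
# events, and seasonally varying multispecies seine catches.

BAND_NAMES <- c("high", "low", "broadband")
FLAG_LEVELS <- c("snapping_shrimp", "fish", "dolphin",
                 "wave_wind", "water_flow", "rain", "vessel")

#' Soundscape generator parameters
#'
#' Bundles every tunable of the synthetic soundscape. Defaults describe a
#' South Carolina salt-marsh estuary: water temperature cycling between about
#' 11 and 29 deg C with its maximum in late July, a small afternoon diel
#' cycle, slowly varying AR(1) noise, and biological sound that switches on
#' steeply once water temperature exceeds an activation threshold. The
#' year-specific spring offsets default to the two anomalous springs the
#' six-year monitoring period contained: a warm 2017 (+1.21 deg C) and a cold
#' 2013 (-1.33 deg C).
#'
#' @param annual_temp_mean,annual_temp_amplitude annual mean and sinusoidal
#'   amplitude of water temperature (deg C).
#' @param temp_phase_day day of year of the temperature maximum.
#' @param diel_temp_amplitude afternoon-peaking diel temperature amplitude
#'   (deg C).
#' @param temp_noise_sd innovation sd of the hourly AR(1) temperature noise
#'   (deg C); `temp_noise_phi` its autocorrelation.
#' @param yearly_spring_offsets named numeric vector, year -> deg C added
#'   uniformly within that year's spring window.
#' @param activation_midpoint_T water temperature at which biological sound
#'   is half-activated (deg C).
#' @param activation_steepness logistic scale of the activation (deg C);
#'   must be > 0. Small values give the abrupt seasonal onsets seen in
#'   estuarine soundscapes.
#' @param band_base_spl named vector (high/low/broadband), baseline SPL in
#'   dB re 1 uPa when biology is silent.
#' @param band_activity_gain named vector, dB added at full activation.
#' @param diel_effects named vector, dB added during the day (negative means
#'   louder at night, as for fish choruses).
#' @param tidal_effects,lunar_effects named lists (one named vector per
#'   band) of dB offsets by tidal / lunar category.
#' @param spl_noise_sd per-record Gaussian residual on the dB scale.
#' @param daily_noise_sd sd of a per-day random effect shared by every
#'   record of a day within a band (dB); records within a day share weather
#'   and behavioural state, so daily means retain realistic day-to-day
#'   variability instead of averaging the residual away.
#' @param vessel_rate_summer_day probability that a summer daytime record is
#'   contaminated by vessel noise.
#' @param rain_event_rate probability per day of a rain event (all records
#'   that day flagged `rain`).
#' @param seed integer RNG seed.
#' @return list of class `soundscape_params`.
#' @export
soundscape_params <- function(annual_temp_mean = 20,
                              annual_temp_amplitude = 8.5,
                              temp_phase_day = 205,
                              diel_temp_amplitude = 0.5,
                              temp_noise_sd = 0.15,
                              temp_noise_phi = 0.98,
                              yearly_spring_offsets = c("2013" = -1.33,
                                                        "2017" = 1.21),
                              activation_midpoint_T = 17,
                              activation_steepness = 0.5,
                              band_base_spl = c(high = 95, low = 90,
                                                broadband = 97),
                              band_activity_gain = c(high = 15, low = 10,
                                                     broadband = 12),
                              diel_effects = c(high = 2, low = -2,
                                               broadband = 1),
                              tidal_effects = list(
                                high = c(high = -0.5, falling = 0, low = 1,
                                         rising = 0),
                                low = c(high = 0.3, falling = 0, low = -0.3,
                                        rising = 0),
                                broadband = c(high = -0.2, falling = 0,
                                              low = 0.5, rising = 0)),
                              lunar_effects = list(
                                high = c(new = 1, first_quarter = 0,
                                         full = -0.5, last_quarter = 0),
                                low = c(new = -0.3, first_quarter = 0,
                                        full = 0.8, last_quarter = 0),
                                broadband = c(new = 0.5, first_quarter = 0,
                                              full = 0, last_quarter = 0)),
                              spl_noise_sd = 1,
                              daily_noise_sd = 1,
                              vessel_rate_summer_day = 0.15,
                              rain_event_rate = 0.1,
                              seed = 1L) {
  stopifnot(activation_steepness > 0,
            vessel_rate_summer_day >= 0, vessel_rate_summer_day <= 1,
            rain_event_rate >= 0, rain_event_rate <= 1,
            all(BAND_NAMES %in% names(band_base_spl)),
            all(BAND_NAMES %in% names(band_activity_gain)))
  structure(as.list(environment()), class = "soundscape_params")
}

as_env_series <- function(station, timestamps, variable, values) {
  stopifnot(all(diff(as.numeric(timestamps)) > 0))
  data.frame(station_id = station, timestamp = timestamps,
             variable = variable, value = values)
}

#' Generate an hourly water-temperature series
#'
#' Annual sinusoid (maximum at `temp_phase_day`) + afternoon-peaking diel
#' sinusoid + the year's spring offset (applied within the astronomical
#' spring window) + AR(1) noise. Deterministic under the parameter seed.
#'
#' @param station station label.
#' @param start_date,end_date Dates; `start_date` must precede `end_date`.
#' @param params a [soundscape_params()].
#' @return EnvSeries data.frame (`station_id`, `timestamp`, `variable`,
#'   `value`), hourly step.
#' @export
generate_temperature_series <- function(station, start_date, end_date,
                                        params = soundscape_params()) {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (start_date >= end_date) stop("start_date must precede end_date")
  ts <- seq(as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC"),
            as.POSIXct(paste(end_date, "23:00:00"), tz = "UTC"),
            by = 3600)
  lt <- as.POSIXlt(ts)
  doy <- lt$yday + 1 + lt$hour / 24
  base <- params$annual_temp_mean +
    params$annual_temp_amplitude * cos(2 * pi * (doy - params$temp_phase_day) / 365.25) +
    params$diel_temp_amplitude * cos(2 * pi * (lt$hour - 15) / 24)
  # per-year spring offsets
  yrs <- lt$year + 1900L
  off <- numeric(length(ts))
  for (ynm in names(params$yearly_spring_offsets)) {
    y <- as.integer(ynm)
    sw <- spring_window(y)
    d <- as.Date(ts)
    off[yrs == y & d >= sw$start_date & d <= sw$end_date] <-
      params$yearly_spring_offsets[[ynm]]
  }
  noise <- local_seed(params$seed, {
    if (params$temp_noise_sd > 0) {
      as.numeric(stats::arima.sim(list(ar = params$temp_noise_phi),
                                  n = length(ts),
                                  sd = params$temp_noise_sd))
    } else numeric(length(ts))
  })
  as_env_series(station, ts, "temperature_C", base + off + noise)
}

#' Generate a sinusoidal semidiurnal water-level series
#'
#' A pure tide at 10-minute step: two high tides per ~24.84 h at the default
#' 12.42 h principal lunar semidiurnal period.
#'
#' @inheritParams generate_temperature_series
#' @param amplitude_m tidal amplitude (m); 0 yields a flat series that
#'   downstream tidal categorisation rejects.
#' @param period_h tidal period in hours (> 0), default 12.42.
#' @param seed unused placeholder kept for interface symmetry (the tide is
#'   deterministic).
#' @return EnvSeries data.frame at 10-min step.
#' @export
generate_waterlevel_series <- function(station, start_date, end_date,
                                       amplitude_m = 1, period_h = 12.42,
                                       seed = NULL) {
  if (period_h <= 0) stop("period_h must be positive")
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (start_date >= end_date) stop("start_date must precede end_date")
  ts <- seq(as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC"),
            as.POSIXct(paste(end_date, "23:50:00"), tz = "UTC"),
            by = 600)
  h <- as.numeric(ts) / 3600
  as_env_series(station, ts, "water_level_m",
                amplitude_m * sin(2 * pi * h / period_h))
}

logistic_activation <- function(temp, params) {
  stats::plogis((temp - params$activation_midpoint_T) /
                  params$activation_steepness)
}

#' Generate a duty-cycled SPL record table directly (no audio)
#'
#' The fast SPL-level generator used by the statistics stages. Per band,
#' SPL = base + gain x logistic((T - midpoint)/steepness) + diel + tidal +
#' lunar category effects + Gaussian residual. Vessel flags are assigned
#' with probability `vessel_rate_summer_day` on summer (Jun-Aug) daytime
#' records; rain flags cover whole randomly drawn rain days; biological
#' flags follow the activation level. Reproducible under the parameter seed.
#'
#' @param env temperature EnvSeries covering the schedule.
#' @param tide water-level EnvSeries covering the schedule (NULL drops tidal
#'   effects).
#' @param params a [soundscape_params()].
#' @param schedule POSIXct vector of record start times (one per 20 min by
#'   default, built from the env coverage when NULL).
#' @param latitude,longitude site coordinates for day/night.
#' @return SPLRecord data.frame: `station_id`, `timestamp_start`,
#'   `duration_s`, `spl_high_dB`, `spl_low_dB`, `spl_broad_dB`, `flags`
#'   (comma-separated), `on_hour`, plus the generating `temperature_C`.
#' @export
generate_spl_series <- function(env, tide = NULL,
                                params = soundscape_params(),
                                schedule = NULL,
                                latitude = 32.21, longitude = -80.86) {
  if (is.null(schedule)) {
    schedule <- seq(min(env$timestamp), max(env$timestamp), by = 1200)
  }
  if (min(schedule) < min(env$timestamp) - 3600 ||
      max(schedule) > max(env$timestamp) + 3600) {
    stop("schedule extends beyond temperature series coverage")
  }
  st <- env$station_id[1]
  # nearest temperature
  et <- as.numeric(env$timestamp)
  idx <- findInterval(as.numeric(schedule), et)
  lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, length(et))
  pick <- ifelse(abs(as.numeric(schedule) - et[lo]) <=
                   abs(as.numeric(schedule) - et[hi]), lo, hi)
  temp <- env$value[pick]
  act <- logistic_activation(temp, params)

  dn <- day_night(schedule, latitude, longitude)
  lun <- lunar_category(schedule)
  tid <- if (!is.null(tide)) tidal_category(tide, schedule) else NULL

  lt <- as.POSIXlt(schedule)
  month <- lt$mon + 1L
  is_day <- dn == "day"
  n <- length(schedule)

  day_key <- as.Date(schedule)
  days_u <- unique(day_key)
  day_idx <- match(day_key, days_u)
  out <- local_seed(params$seed, {
    spl <- matrix(NA_real_, n, 3,
                  dimnames = list(NULL, BAND_NAMES))
    for (b in BAND_NAMES) {
      v <- params$band_base_spl[[b]] + params$band_activity_gain[[b]] * act
      v <- v + ifelse(is_day, params$diel_effects[[b]], 0)
      v <- v + params$lunar_effects[[b]][as.character(lun)]
      if (!is.null(tid)) {
        te <- params$tidal_effects[[b]][as.character(tid)]
        te[is.na(te)] <- 0
        v <- v + te
      }
      day_eff <- stats::rnorm(length(days_u), 0, params$daily_noise_sd)
      spl[, b] <- v + day_eff[day_idx] + stats::rnorm(n, 0, params$spl_noise_sd)
    }
    vessel <- (month %in% 6:8) & is_day &
      stats::runif(n) < params$vessel_rate_summer_day
    days <- unique(as.Date(schedule))
    rain_days <- days[stats::runif(length(days)) < params$rain_event_rate]
    rain <- as.Date(schedule) %in% rain_days
    list(spl = spl, vessel = vessel, rain = rain)
  })

  flags <- mapply(function(a, vs, rn) {
    f <- character(0)
    if (a > 0.1) f <- c(f, "snapping_shrimp", "fish")
    if (vs) f <- c(f, "vessel")
    if (rn) f <- c(f, "rain")
    paste(f, collapse = ",")
  }, act, out$vessel, out$rain)

  data.frame(station_id = st, timestamp_start = schedule, duration_s = 120,
             spl_high_dB = unname(out$spl[, "high"]),
             spl_low_dB = unname(out$spl[, "low"]),
             spl_broad_dB = unname(out$spl[, "broadband"]),
             flags = flags, on_hour = lt$min == 0L,
             temperature_C = temp)
}

# ---- waveform-level generator -------------------------------------------

bandpass_kernel <- function(f_lo, f_hi, fs, n = 255L) {
  # windowed-sinc bandpass FIR; f_hi at Nyquist degenerates to highpass
  nyq <- fs / 2
  f_hi <- min(f_hi, nyq * 0.999)
  t <- seq(-(n - 1) / 2, (n - 1) / 2)
  sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))
  h <- 2 * f_hi / fs * sinc(2 * f_hi / fs * t) -
    2 * f_lo / fs * sinc(2 * f_lo / fs * t)
  h * (0.5 + 0.5 * cos(2 * pi * t / n))  # Hann taper
}

#' Synthesize a raw audio clip with controlled band levels
#'
#' Builds a hydrophone-like waveform from three generic components --
#' snapping-shrimp snaps (Poisson-timed broadband impulses with 2-40 kHz
#' energy), a fish chorus (100-1000 Hz band-limited pulse trains) and
#' optional vessel noise (low-frequency tonal plus broadband wash) -- and
#' iteratively scales component amplitudes so that the measured band SPL of
#' the mixture matches each requested target within +/- 1 dB.
#'
#' @param duration_s clip length in seconds (default 120, the duty-cycle
#'   clip length).
#' @param sample_rate_hz sampling rate (default 80000).
#' @param component_levels named numeric vector of target band SPLs in dB re
#'   1 uPa; recognised names: `high` (snaps), `low` (fish chorus), `vessel`
#'   (targets the low band too). Omitted components are silent.
#' @param calibration a [calibration_spec()].
#' @param seed RNG seed.
#' @return object of class `audio_clip`: list with `samples` (full-scale
#'   units in [-1, 1]), `sample_rate_hz`, `calibration`,
#'   `component_levels`.
#' @export
synthesize_audio_clip <- function(duration_s = 120, sample_rate_hz = 80000,
                                  component_levels = c(high = 110, low = 100),
                                  calibration = calibration_spec(),
                                  seed = 1L) {
  fs <- sample_rate_hz
  n <- round(duration_s * fs)
  bands <- default_bands()
  comp <- local_seed(seed, {
    out <- list()
    if ("high" %in% names(component_levels)) {
      # Poisson snaps: ~2000 snaps/s (a dense shrimp bed), impulses shaped
      # by a 2-40 kHz kernel; amplitudes capped to keep the crest factor
      # representable at high target levels
      x <- numeric(n)
      k <- stats::rpois(1, 2000 * duration_s)
      at <- sample.int(n, min(k, n), replace = FALSE)
      amp <- (1 + pmin(stats::rexp(length(at)), 3))
      x[at] <- amp * sign(stats::rnorm(length(at)))
      kern <- bandpass_kernel(2000, fs / 2, fs, 101L)
      out$high <- stats::filter(x, kern, sides = 2)
      out$high[is.na(out$high)] <- 0
    }
    if ("low" %in% names(component_levels)) {
      # fish chorus: 100-1000 Hz noise gated into ~6 pulses/s trains
      kern <- bandpass_kernel(100, 1000, fs, 511L)
      x <- stats::filter(stats::rnorm(n), kern, sides = 2)
      x[is.na(x)] <- 0
      gate <- 0.2 + 0.8 * (sin(2 * pi * 6 * seq_len(n) / fs)^2)
      out$low <- as.numeric(x) * gate
    }
    if ("vessel" %in% names(component_levels)) {
      t <- seq_len(n) / fs
      tonal <- sin(2 * pi * 110 * t) + 0.5 * sin(2 * pi * 220 * t)
      kern <- bandpass_kernel(20, 2000, fs, 511L)
      wash <- stats::filter(stats::rnorm(n), kern, sides = 2)
      wash[is.na(wash)] <- 0
      out$vessel <- tonal + 0.3 * as.numeric(wash)
    }
    out
  })
  if (length(comp) == 0) {
    return(structure(list(samples = numeric(n), sample_rate_hz = fs,
                          calibration = calibration,
                          component_levels = component_levels),
                     class = "audio_clip"))
  }
  target_band <- c(high = "high", low = "low", vessel = "low")
  # initial per-component scaling to its target measured alone
  for (nm in names(comp)) {
    b <- bands[[target_band[[nm]]]]
    cur <- band_rms_spl(as.numeric(comp[[nm]]), calibration, b)
    comp[[nm]] <- comp[[nm]] * 10^((component_levels[[nm]] - cur) / 20)
  }
  mix <- Reduce(`+`, comp)
  # refine against the mixture (cross-band leakage)
  for (iter in 1:5) {
    ok <- TRUE
    for (nm in names(comp)) {
      b <- bands[[target_band[[nm]]]]
      cur <- band_rms_spl(as.numeric(mix), calibration, b)
      err <- component_levels[[nm]] - cur
      if (abs(err) > 0.5) {
        ok <- FALSE
        comp[[nm]] <- comp[[nm]] * 10^(err / 20)
      }
    }
    mix <- Reduce(`+`, comp)
    if (ok) break
  }
  samples <- as.numeric(mix)
  if (max(abs(samples)) > 1) {
    stop("target level exceeds representable amplitude at this calibration")
  }
  structure(list(samples = samples, sample_rate_hz = fs,
                 calibration = calibration,
                 component_levels = component_levels),
            class = "audio_clip")
}

# ---- seine community generator ------------------------------------------

default_species_pool <- function() {
  data.frame(
    species = c("mummichog", "silver_perch", "spotted_seatrout", "red_drum",
                "black_drum", "oyster_toadfish", "atlantic_croaker", "spot",
                "pinfish", "striped_mullet", "bay_anchovy", "menhaden",
                "silverside", "pipefish", "blue_crab", "penaeid_shrimp",
                "grass_shrimp", "mud_crab", "killifish", "goby"),
    sound_producer = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                       FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                       TRUE, FALSE, FALSE, FALSE, FALSE)
  )
}

#' Seine-community generator parameters
#'
#' @param species_pool data.frame with `species` and `sound_producer`
#'   columns.
#' @param richness_midpoint_T,richness_steepness logistic parameters linking
#'   water temperature (deg C) to expected species richness.
#' @param max_expected_richness asymptotic expected richness (must not
#'   exceed the pool size).
#' @param abundance_lognormal_mu,abundance_lognormal_sigma log-scale
#'   parameters of per-species counts; sigma > 0.
#' @param seine_area_range numeric length-2, m^2 range of seined areas.
#' @param seed RNG seed.
#' @export
community_params <- function(species_pool = default_species_pool(),
                             richness_midpoint_T = 17,
                             richness_steepness = 3,
                             max_expected_richness = 12,
                             abundance_lognormal_mu = 2,
                             abundance_lognormal_sigma = 1,
                             seine_area_range = c(20, 120),
                             seed = 1L) {
  stopifnot(max_expected_richness <= nrow(species_pool),
            abundance_lognormal_sigma > 0)
  structure(as.list(environment()), class = "community_params")
}

#' Generate seine catches with temperature-driven richness
#'
#' Expected richness follows a logistic in water temperature; realised
#' richness is binomial with that expectation, species are drawn without
#' replacement from the pool, per-species counts are log-normal, and the
#' seined area is uniform over `seine_area_range`.
#'
#' @param station station label.
#' @param dates Date vector, one seine haul per date (non-empty).
#' @param temperature numeric, water temperature (deg C) at each date.
#' @param params a [community_params()].
#' @return long-format SeineSample data.frame: `station_id`, `date`,
#'   `site_type`, `area_m2`, `species`, `count`, `temperature_C`,
#'   `salinity`, `pH`, `dissolved_oxygen`. Empty hauls appear as a single
#'   row with species `NA` and count 0.
#' @export
generate_seine_catches <- function(station, dates, temperature,
                                   params = community_params()) {
  if (length(dates) == 0) stop("dates must be non-empty")
  if (nrow(params$species_pool) == 0) stop("empty species pool")
  stopifnot(length(dates) == length(temperature))
  site_types <- c("tidal_pool", "intertidal_creek", "river_side")
  local_seed(params$seed, {
    rows <- lapply(seq_along(dates), function(i) {
      p <- stats::plogis((temperature[i] - params$richness_midpoint_T) /
                           params$richness_steepness)
      k <- stats::rbinom(1, params$max_expected_richness, p)
      area <- stats::runif(1, params$seine_area_range[1],
                           params$seine_area_range[2])
      site <- sample(site_types, 1)
      wq <- c(salinity = stats::rnorm(1, 30, 2),
              pH = stats::rnorm(1, 7.8, 0.15),
              dissolved_oxygen = stats::rnorm(1, 7, 1))
      if (k == 0) {
        return(data.frame(station_id = station, date = dates[i],
                          site_type = site, area_m2 = area,
                          species = NA_character_, count = 0L,
                          temperature_C = temperature[i],
                          salinity = wq[["salinity"]], pH = wq[["pH"]],
                          dissolved_oxygen = wq[["dissolved_oxygen"]]))
      }
      sp <- sample(params$species_pool$species, k, replace = FALSE)
      cnt <- pmax(1L, round(stats::rlnorm(k, params$abundance_lognormal_mu,
                                          params$abundance_lognormal_sigma)))
      data.frame(station_id = station, date = dates[i], site_type = site,
                 area_m2 = area, species = sp, count = as.integer(cnt),
                 temperature_C = temperature[i],
                 salinity = wq[["salinity"]], pH = wq[["pH"]],
                 dissolved_oxygen = wq[["dissolved_oxygen"]])
    })
    do.call(rbind, rows)
  })
}
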