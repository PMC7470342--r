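# End-to-end orchestration: simulate (or accept) SPL tables, derive daily
# biological-only series, detect spring onsets per station/band/year, and
# assemble the phenology and biodiversity report tables.

#' Pipeline run configuration
#'
#' @param stations character vector of station labels.
#' @param years integer vector of calendar years to analyse.
#' @param soundscape a [soundscape_params()]; its seed anchors all SPL
#'   randomness (station s, year y uses seed + offsets, recorded in the
#'   output).
#' @param community a [community_params()] for the seine generator.
#' @param bands bands to analyse.
#' @param sampler list of change-point sampler settings (p0, w0, burnin,
#'   mcmc).
#' @param spring_overrides optional spring-window override table (see
#'   [spring_window()]).
#' @param latitude,longitude site coordinates.
#' @param window_margin_days days of context generated/kept on each side of
#'   the spring window so the change-point model sees the pre-onset
#'   baseline.
#' @return list of class `run_config`.
#' @export
run_config <- function(stations = c("9M", "14M"), years = 2013:2018,
                       soundscape = soundscape_params(),
                       community = community_params(),
                       bands = c("high", "low", "broadband"),
                       sampler = list(p0 = 0.2, w0 = 0.2, burnin = 50,
                                      mcmc = 500),
                       spring_overrides = NULL,
                       latitude = 32.21, longitude = -80.86,
                       window_margin_days = 30) {
  structure(as.list(environment()), class = "run_config")
}

station_year_seed <- function(base, station_idx, year) {
  (base + 7919L * station_idx + (year %% 100L)) %% .Machine$integer.max
}

#' Run the soundscape phenology pipeline
#'
#' For every station x band x year: simulate (or take) the SPL record
#' table, subsample on the hour, form the daily mean series (all-sound and
#' biological-only variants), fit the change-point model over the spring
#' window (plus margin), and report the first positive change with the mean
#' spring water temperature. Day anomalies are filled per station/band
#' across years. Station-years whose spring window has no data yield a row
#' with reason "missing acoustic data".
#'
#' @param config a [run_config()].
#' @param records optional precomputed SPLRecord table (must carry
#'   `station_id`); when NULL each station-year is simulated.
#' @param temperature optional EnvSeries per station (named list); when
#'   NULL it is simulated.
#' @return list of class `phenology_run`: `events` (S3/S4-style table:
#'   year, station, band, dataset, mean_spring_temp, date, day_of_year,
#'   anomaly_days, pp_value, reason), `fits` (named list of [bcp_ppm()]
#'   objects for the biological variant), `config`.
#' @export
run_phenology <- function(config = run_config(), records = NULL,
                          temperature = NULL) {
  events <- list()
  fits <- list()
  for (si in seq_along(config$stations)) {
    st <- config$stations[si]
    for (yr in config$years) {
      sw <- spring_window(yr, overrides = config$spring_overrides)
      margin <- config$window_margin_days
      span_start <- sw$start_date - margin
      span_end <- sw$end_date + margin

      if (is.null(records)) {
        p <- config$soundscape
        p$seed <- station_year_seed(p$seed, si, yr)
        env <- generate_temperature_series(st, span_start, span_end, p)
        tide <- generate_waterlevel_series(st, span_start, span_end)
        recs <- generate_spl_series(env, tide, p,
                                    latitude = config$latitude,
                                    longitude = config$longitude)
      } else {
        recs <- records[records$station_id == st &
                          as.Date(records$timestamp_start) >= span_start &
                          as.Date(records$timestamp_start) <= span_end, ,
                        drop = FALSE]
        env <- if (!is.null(temperature)) temperature[[st]] else NULL
      }
      recs <- subsample_on_hour(recs)

      spring_temp <- mean_spring_temperature(env, recs, sw)

      for (band in config$bands) {
        for (dataset in c("all_sound", "biological")) {
          key <- paste(st, yr, band, dataset, sep = "_")
          row <- data.frame(year = yr, station_id = st, band = band,
                            dataset = dataset,
                            mean_spring_temp = spring_temp,
                            date = as.Date(NA), day_of_year = NA_integer_,
                            pp_value = NA_real_, reason = "")
          daily <- tryCatch(
            daily_mean_spl(recs, band,
                           biological_only = dataset == "biological"),
            error = function(e) NULL)
          n_spring <- if (is.null(daily)) 0L else
            sum(!is.na(daily$mean_spl) & daily$date >= sw$start_date &
                  daily$date <= sw$end_date)
          if (n_spring < 5L) {
            row$reason <- "missing acoustic data"
            events[[key]] <- row
            next
          }
          fit <- bcp_ppm(daily$mean_spl, daily$date,
                         p0 = config$sampler$p0, w0 = config$sampler$w0,
                         burnin = config$sampler$burnin,
                         mcmc = config$sampler$mcmc,
                         seed = station_year_seed(config$soundscape$seed + 1L,
                                                  si, yr))
          if (dataset == "biological") fits[[key]] <- fit
          ev <- first_positive_change(fit, sw)
          if (is.null(ev)) {
            row$reason <- "no positive change at PP >= 0.5"
          } else {
            row$date <- ev$date
            row$day_of_year <- ev$day_of_year
            row$pp_value <- ev$pp_value
          }
          events[[key]] <- row
        }
      }
    }
  }
  tab <- do.call(rbind, events)
  rownames(tab) <- NULL
  # day anomalies within station x band x dataset across years
  tab$anomaly_days <- NA_real_
  for (grp in split(seq_len(nrow(tab)),
                    paste(tab$station_id, tab$band, tab$dataset))) {
    ok <- grp[!is.na(tab$day_of_year[grp])]
    if (length(ok) >= 2) {
      tab$anomaly_days[ok] <- tab$day_of_year[ok] -
        mean(tab$day_of_year[ok])
    }
  }
  structure(list(events = tab, fits = fits, config = config),
            class = "phenology_run")
}

mean_spring_temperature <- function(env, recs, sw) {
  if (!is.null(env)) {
    d <- as.Date(env$timestamp)
    mean(env$value[d >= sw$start_date & d <= sw$end_date])
  } else if (!is.null(recs$temperature_C)) {
    d <- as.Date(recs$timestamp_start)
    mean(recs$temperature_C[d >= sw$start_date & d <= sw$end_date],
         na.rm = TRUE)
  } else NA_real_
}

#' @export
print.phenology_run <- function(x, ...) {
  ev <- x$events[x$events$dataset == "biological", ]
  cat(sprintf("Phenology run: %d station(s), years %d-%d, bands %s\n",
              length(x$config$stations), min(x$config$years),
              max(x$config$years), paste(x$config$bands, collapse = "/")))
  cat(sprintf("  onsets detected (biological dataset): %d of %d rows\n",
              sum(!is.na(ev$date)), nrow(ev)))
  invisible(x)
}

#' Run the soundscape-biodiversity comparison
#'
#' Simulates (or takes) monthly seine catches coupled to the same seasonal
#' temperature cycle as the soundscape, summarizes diversity per station x
#' month, computes monthly mean SPL per band, and returns the correlation
#' and temperature-regression report.
#'
#' @param config a [run_config()].
#' @param records optional SPLRecord table; simulated per station-year when
#'   NULL.
#' @param seines optional SeineSample table; simulated when NULL (two hauls
#'   per month at each station).
#' @return list of class `biodiversity_run` with `report` (see
#'   [correlate_soundscape_biodiversity()]), `diversity_monthly`,
#'   `spl_monthly`.
#' @export
run_biodiversity <- function(config = run_config(), records = NULL,
                             seines = NULL) {
  all_recs <- list()
  all_seines <- list()
  for (si in seq_along(config$stations)) {
    st <- config$stations[si]
    for (yr in config$years) {
      p <- config$soundscape
      p$seed <- station_year_seed(p$seed, si, yr)
      start <- as.Date(sprintf("%d-01-01", yr))
      end <- as.Date(sprintf("%d-12-31", yr))
      env <- generate_temperature_series(st, start, end, p)
      if (is.null(records)) {
        recs <- generate_spl_series(env, NULL, p,
                                    latitude = config$latitude,
                                    longitude = config$longitude,
                                    schedule = seq(min(env$timestamp),
                                                   max(env$timestamp),
                                                   by = 3600))
        all_recs[[paste(st, yr)]] <- recs
      }
      if (is.null(seines)) {
        dates <- seq(start + 9, end, by = "2 weeks")
        dt <- as.Date(env$timestamp)
        temp_at <- vapply(dates, function(d) mean(env$value[dt == d]),
                          numeric(1))
        cp <- config$community
        cp$seed <- station_year_seed(cp$seed + 13L, si, yr)
        all_seines[[paste(st, yr)]] <-
          generate_seine_catches(st, dates, temp_at, cp)
      }
    }
  }
  if (is.null(records)) records <- do.call(rbind, all_recs)
  if (is.null(seines)) seines <- do.call(rbind, all_seines)

  recs <- exclude_nonbiological(records)$retained
  month <- format(as.Date(recs$timestamp_start), "%Y-%m")
  spl_monthly <- stats::aggregate(
    recs[, c("spl_high_dB", "spl_low_dB", "spl_broad_dB")],
    by = list(station_id = recs$station_id, month = month), FUN = mean)
  temp_monthly <- if (!is.null(recs$temperature_C)) {
    stats::aggregate(list(temperature_C = recs$temperature_C),
                     by = list(station_id = recs$station_id, month = month),
                     FUN = mean)
  } else NULL

  div <- monthly_summaries(seines)
  rep <- correlate_soundscape_biodiversity(div, spl_monthly, temp_monthly)
  structure(list(report = rep, diversity_monthly = div,
                 spl_monthly = spl_monthly, temp_monthly = temp_monthly,
                 config = config),
            class = "biodiversity_run")
}

#' @export
print.biodiversity_run <- function(x, ...) {
  cat("Soundscape-biodiversity report\n")
  if (nrow(x$report$correlations)) {
    print(x$report$correlations, row.names = FALSE, digits = 3)
  } else cat("  (insufficient paired months)\n")
  invisible(x)
}

#' Write the phenology event table as CSV
#'
#' @param run a `phenology_run`.
#' @param path output CSV path.
#' @export
write_phenology_csv <- function(run, path) {
  utils::write.csv(run$events, path, row.names = FALSE)
  invisible(path)
}
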