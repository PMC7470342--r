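# Astronomical and tidal covariates attached to every SPL record: lunar and
# tidal category (four categories each), day/night, day length, and the
# astronomical spring window. All astronomy is computed in UTC; pass local
# times as POSIXct with their tz set, or rely on the default UTC-5 offset
# used by the generators.

SYNODIC_DAYS <- 29.530588853
# reference new moon epoch (first new moon of 2000)
LUNAR_EPOCH <- as.POSIXct("2000-01-06 18:14:00", tz = "UTC")

LUNAR_LEVELS <- c("new", "first_quarter", "full", "last_quarter")
TIDAL_LEVELS <- c("high", "falling", "low", "rising")

#' Lunar phase category
#'
#' Classifies instants into the four principal lunar categories from the
#' synodic age (days since a reference new moon, modulo 29.530588 d). Two
#' conventions are supported: `"centered"` quarters the cycle around the four
#' principal phases (new covers ages within +/- 3.69 d of zero), while
#' `"contiguous"` splits the cycle into quarters starting at new moon.
#'
#' @param datetime POSIXct (any tz) or Date vector.
#' @param convention `"centered"` (default) or `"contiguous"`.
#' @return factor with levels new, first_quarter, full, last_quarter.
#' @examples
#' lunar_category(as.POSIXct("2000-01-06 18:14", tz = "UTC"))  # new
#' lunar_category(as.Date("2013-03-27"))                       # full
#' @export
lunar_category <- function(datetime, convention = c("centered", "contiguous")) {
  convention <- match.arg(convention)
  t <- as.POSIXct(datetime, tz = "UTC")
  age <- as.numeric(difftime(t, LUNAR_EPOCH, units = "days")) %% SYNODIC_DAYS
  q <- SYNODIC_DAYS / 4
  idx <- if (convention == "centered") {
    (floor((age + q / 2) / q) %% 4) + 1
  } else {
    floor(age / q) + 1
  }
  factor(LUNAR_LEVELS[idx], levels = LUNAR_LEVELS)
}

# local extrema (strict sign change of differences) of a regular series
find_extrema <- function(values) {
  d <- diff(values)
  s <- sign(d)
  s[s == 0] <- NA
  s <- zoo_locf(s)
  turn <- which(diff(s) != 0) + 1L
  if (length(turn) == 0) return(list(idx = integer(0), type = character(0)))
  type <- ifelse(s[turn] < 0, "max", "min")
  list(idx = turn, type = type)
}

# last-observation-carried-forward for the sign vector (no zoo dependency)
zoo_locf <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(x)
  idx <- cummax(ifelse(ok, seq_along(x), 0L))
  x[pmax(idx, 1L)]
}

#' Tidal phase category from a water-level series
#'
#' Locates the empirical high/low extrema bracketing each query time in a
#' water-level series and quarters the cycle: `high` within one-eighth cycle
#' of a maximum, `low` within one-eighth of a minimum, `falling`/`rising` in
#' between. On a pure sinusoid each category occupies 25% of time.
#'
#' @param water_level data.frame with `timestamp` (POSIXct) and `value`
#'   columns (an `EnvSeries`), covering at least one full tidal cycle.
#' @param t POSIXct vector of query times inside the series coverage.
#' @return factor with levels high, falling, low, rising (`NA` outside the
#'   bracketed range).
#' @export
tidal_category <- function(water_level, t) {
  v <- water_level$value
  ts <- as.numeric(water_level$timestamp)
  ex <- find_extrema(v)
  if (length(ex$idx) < 2L) {
    stop("water-level series has no tidal extrema (flat series?)")
  }
  ext_t <- ts[ex$idx]
  ext_type <- ex$type
  tq <- as.numeric(as.POSIXct(t))
  out <- rep(NA_character_, length(tq))
  pos <- findInterval(tq, ext_t)
  ok <- pos >= 1L & pos < length(ext_t)
  if (any(ok)) {
    p <- pos[ok]
    frac <- (tq[ok] - ext_t[p]) / (ext_t[p + 1L] - ext_t[p])  # 0 at one extreme
    from_max <- ext_type[p] == "max"
    lab <- character(sum(ok))
    # descending half-cycle: high -> falling -> low
    lab[from_max & frac < 0.25] <- "high"
    lab[from_max & frac >= 0.25 & frac < 0.75] <- "falling"
    lab[from_max & frac >= 0.75] <- "low"
    # ascending half-cycle: low -> rising -> high
    lab[!from_max & frac < 0.25] <- "low"
    lab[!from_max & frac >= 0.25 & frac < 0.75] <- "rising"
    lab[!from_max & frac >= 0.75] <- "high"
    out[ok] <- lab
  }
  factor(out, levels = TIDAL_LEVELS)
}

# ---- solar geometry (standard NOAA equations) ---------------------------

solar_position <- function(datetime, latitude, longitude) {
  t <- as.POSIXct(datetime, tz = "UTC")
  lt <- as.POSIXlt(t, tz = "UTC")
  doy <- lt$yday + 1
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  gamma <- 2 * pi / 365 * (doy - 1 + (hour - 12) / 24)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(gamma) - 0.032077 * sin(gamma) -
                        0.014615 * cos(2 * gamma) - 0.040849 * sin(2 * gamma))
  decl <- 0.006918 - 0.399912 * cos(gamma) + 0.070257 * sin(gamma) -
    0.006758 * cos(2 * gamma) + 0.000907 * sin(2 * gamma) -
    0.002697 * cos(3 * gamma) + 0.00148 * sin(3 * gamma)
  time_offset <- eqtime + 4 * longitude            # minutes; longitude east +
  tst <- hour * 60 + time_offset                   # true solar time, minutes
  ha <- (tst / 4 - 180) * pi / 180                 # hour angle, radians
  lat <- latitude * pi / 180
  elev <- asin(sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(ha))
  list(elevation_deg = elev * 180 / pi, declination = decl)
}

#' Day/night classification
#'
#' `day` iff the sun is above the horizon by the standard sunrise/sunset
#' definition (solar elevation > -0.833 deg, accounting for refraction and
#' solar radius).
#'
#' @param datetime POSIXct vector (UTC-based computation; set tz on input).
#' @param latitude,longitude decimal degrees (longitude east positive).
#' @return factor with levels day, night.
#' @export
day_night <- function(datetime, latitude, longitude) {
  if (abs(latitude) >= 66.5) stop("polar latitudes not supported")
  sp <- solar_position(datetime, latitude, longitude)
  factor(ifelse(sp$elevation_deg > -0.833, "day", "night"),
         levels = c("day", "night"))
}

#' Day length in hours
#'
#' Sunrise-equation day length using the solar declination at local solar
#' noon and the -0.833 deg horizon.
#'
#' @param date Date vector.
#' @inheritParams day_night
#' @return hours of daylight (numeric).
#' @export
day_length <- function(date, latitude, longitude) {
  if (abs(latitude) >= 66.5) stop("polar latitudes not supported")
  noon_utc <- as.POSIXct(paste(as.Date(date), "12:00:00"), tz = "UTC") -
    longitude / 15 * 3600
  decl <- solar_position(noon_utc, latitude, longitude)$declination
  lat <- latitude * pi / 180
  cosw <- (sin(-0.833 * pi / 180) - sin(lat) * sin(decl)) /
    (cos(lat) * cos(decl))
  cosw <- pmin(pmax(cosw, -1), 1)
  2 * acos(cosw) * 180 / pi / 15
}

# Meeus polynomial approximation of the March equinox / June solstice
# instants (mean values, adequate at date resolution).
jde_to_date <- function(jde) {
  as.Date(as.POSIXct((jde - 2440587.5) * 86400, origin = "1970-01-01",
                     tz = "UTC"))
}

#' Astronomical spring window
#'
#' The interval from the vernal (March) equinox to the summer (June)
#' solstice of a given year, from a built-in astronomical approximation
#' (UTC). A table of overrides may be supplied for exact agency-published
#' dates.
#'
#' @param year integer, 1900--2100.
#' @param overrides optional data.frame with columns `year`, `start_date`,
#'   `end_date`; matching rows are returned verbatim.
#' @param method `"meeus"` (astronomical approximation, default) or
#'   `"fixed"` (March 20 / June 21 every year).
#' @return list with `year`, `start_date`, `end_date` (Dates).
#' @examples
#' spring_window(2017)  # 2017-03-20 to 2017-06-21
#' @export
spring_window <- function(year, overrides = NULL,
                          method = c("meeus", "fixed")) {
  method <- match.arg(method)
  stopifnot(year >= 1900, year <= 2100)
  if (!is.null(overrides)) {
    hit <- overrides[overrides$year == year, , drop = FALSE]
    if (nrow(hit) == 1L) {
      return(list(year = year, start_date = as.Date(hit$start_date),
                  end_date = as.Date(hit$end_date)))
    }
  }
  if (method == "fixed") {
    return(list(year = year,
                start_date = as.Date(sprintf("%d-03-20", year)),
                end_date = as.Date(sprintf("%d-06-21", year))))
  }
  T <- (year - 2000) / 1000
  jde_mar <- 2451623.80984 + 365242.37404 * T + 0.05169 * T^2 -
    0.00411 * T^3 - 0.00057 * T^4
  jde_jun <- 2451716.56767 + 365241.62603 * T + 0.00325 * T^2 +
    0.00888 * T^3 - 0.00030 * T^4
  list(year = year, start_date = jde_to_date(jde_mar),
       end_date = jde_to_date(jde_jun))
}

#' Attach covariates to SPL records
#'
#' Nearest-in-time join of temperature and water level (within a maximum
#' gap), daily join of rainfall, plus derived year, lunar category, tidal
#' category, day/night and day length for each record.
#'
#' @param records SPLRecord data.frame (needs `timestamp_start`).
#' @param temperature,water_level EnvSeries data.frames (`timestamp`,
#'   `value`); either may be NULL.
#' @param rainfall optional data.frame with `date` and `value` (mm/day).
#' @param latitude,longitude site coordinates (decimal degrees).
#' @param max_gap_h maximum allowed distance to the nearest logger reading
#'   (hours, default 1); beyond it the covariate is `NA` and the record is
#'   counted in the `n_missing` attribute.
#' @return `records` with columns `year`, `temperature_C`, `water_level_m`,
#'   `rainfall_mm`, `lunar`, `tidal`, `day_night`, `day_length_h` added.
#' @export
attach_covariates <- function(records, temperature = NULL, water_level = NULL,
                              rainfall = NULL, latitude = 32.21,
                              longitude = -80.86, max_gap_h = 1) {
  t <- as.POSIXct(records$timestamp_start)
  out <- records
  out$year <- as.POSIXlt(t)$year + 1900L
  n_missing <- c(temperature = 0L, water_level = 0L)

  nearest_join <- function(series) {
    st <- as.numeric(series$timestamp)
    idx <- findInterval(as.numeric(t), st)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, length(st))
    pick <- ifelse(abs(as.numeric(t) - st[lo]) <= abs(as.numeric(t) - st[hi]),
                   lo, hi)
    gap <- abs(as.numeric(t) - st[pick]) / 3600
    val <- series$value[pick]
    val[gap > max_gap_h] <- NA_real_
    val
  }

  if (!is.null(temperature)) {
    out$temperature_C <- nearest_join(temperature)
    n_missing["temperature"] <- sum(is.na(out$temperature_C))
  }
  if (!is.null(water_level)) {
    out$water_level_m <- nearest_join(water_level)
    n_missing["water_level"] <- sum(is.na(out$water_level_m))
    out$tidal <- tidal_category(water_level, t)
    out$tidal[is.na(out$water_level_m)] <- NA
  }
  if (!is.null(rainfall)) {
    m <- match(as.Date(t), as.Date(rainfall$date))
    out$rainfall_mm <- rainfall$value[m]
  }
  out$lunar <- lunar_category(t)
  out$day_night <- day_night(t, latitude, longitude)
  out$day_length_h <- day_length(as.Date(t), latitude, longitude)
  attr(out, "n_missing") <- n_missing
  out
}
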