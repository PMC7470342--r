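# Calibrated band-limited rms SPL from duty-cycled hydrophone recordings,
# plus the bookkeeping that isolates biological sound: on-the-hour
# subsampling and flag-based exclusion of physical and anthropogenic files.

#' Recorder calibration specification
#'
#' Converts raw full-scale waveform units to absolute pressure. The default
#' sensitivity and gain are a documented placeholder (no instrument
#' calibration sheet ships with this package); all outputs should record the
#' calibration used, and absolute levels carry its uncertainty.
#'
#' @param hydrophone_sensitivity_dB_re_1V_per_uPa hydrophone sensitivity
#'   (negative, dB re 1 V/uPa).
#' @param gain_dB recorder gain (dB).
#' @param adc_fullscale_V ADC full-scale voltage.
#' @param sample_rate_hz sampling rate of the recordings.
#' @return list of class `calibration_spec`.
#' @export
calibration_spec <- function(hydrophone_sensitivity_dB_re_1V_per_uPa = -186,
                             gain_dB = 20, adc_fullscale_V = 1,
                             sample_rate_hz = 80000) {
  stopifnot(adc_fullscale_V > 0, sample_rate_hz > 0)
  structure(list(
    hydrophone_sensitivity_dB_re_1V_per_uPa = hydrophone_sensitivity_dB_re_1V_per_uPa,
    gain_dB = gain_dB,
    adc_fullscale_V = adc_fullscale_V,
    sample_rate_hz = sample_rate_hz
  ), class = "calibration_spec")
}

#' Frequency band definition
#'
#' @param name band label.
#' @param f_lo_hz,f_hi_hz band edges in Hz, 0 < f_lo < f_hi.
#' @export
band_def <- function(name, f_lo_hz, f_hi_hz) {
  stopifnot(f_lo_hz > 0, f_hi_hz > f_lo_hz)
  structure(list(name = name, f_lo_hz = f_lo_hz, f_hi_hz = f_hi_hz),
            class = "band_def")
}

#' The three analysis bands
#'
#' High 7000-40000 Hz (snapping shrimp), low 50-1200 Hz (fish calls and the
#' lower portion of shrimp snaps), broadband 1-40000 Hz (implemented as the
#' DC-removed full band: 1 Hz lies below any resolvable spectral bin at the
#' analysis segment length).
#'
#' @return named list of [band_def()]s.
#' @export
default_bands <- function() {
  list(high = band_def("high", 7000, 40000),
       low = band_def("low", 50, 1200),
       broadband = band_def("broadband", 1, 40000))
}

# Welch PSD: Hann window, 50% overlap, per-segment mean removal. One-sided
# density in input-units^2/Hz so that sum(psd) * fs/nfft ~ total power.
welch_psd <- function(x, fs, nfft = 8192L) {
  n <- length(x)
  nfft <- min(nfft, n)
  step <- max(1L, nfft %/% 2L)
  starts <- seq(1L, n - nfft + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nfft) / (nfft + 1))
  scale <- 1 / (fs * sum(w^2))
  nb <- nfft %/% 2L + 1L
  acc <- numeric(nb)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[seq_len(nb)]
    acc <- acc + (Mod(X)^2) * scale
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nfft even)
  dbl <- rep(2, nb); dbl[1] <- 1
  if (nfft %% 2L == 0L) dbl[nb] <- 1
  list(freq = (seq_len(nb) - 1L) * fs / nfft, psd = psd * dbl,
       df = fs / nfft)
}

counts_to_upa <- function(x, calibration) {
  volts <- x * calibration$adc_fullscale_V
  volts / 10^((calibration$hydrophone_sensitivity_dB_re_1V_per_uPa +
                 calibration$gain_dB) / 20)
}

#' Band-limited rms sound pressure level
#'
#' Converts the waveform to micropascals via the calibration, estimates the
#' power spectral density by Welch's method (Hann window, 50% overlap,
#' 8192-sample segments), integrates it over the band (truncated at Nyquist
#' with a warning when the band extends beyond it, Nyquist bin included),
#' and reports 10 log10 of the band power re (1 uPa)^2.
#'
#' @param waveform numeric vector in full-scale units, or an `audio_clip`.
#' @param calibration a [calibration_spec()] (taken from the clip when a
#'   clip is passed).
#' @param band a [band_def()].
#' @param nfft Welch segment length (samples).
#' @return SPL in dB re 1 uPa (rms).
#' @examples
#' cal <- calibration_spec(0, 0, 1, 80000)      # waveform directly in uPa
#' x <- 1e6 * sin(2 * pi * 10000 * (1:160000) / 80000)  # 1 Pa, 10 kHz
#' band_rms_spl(x, cal, band_def("high", 7000, 40000))  # 116.99 dB
#' @export
band_rms_spl <- function(waveform, calibration = NULL, band, nfft = 8192L) {
  if (inherits(waveform, "audio_clip")) {
    if (is.null(calibration)) calibration <- waveform$calibration
    fs <- waveform$sample_rate_hz
    x <- waveform$samples
  } else {
    if (is.null(calibration)) stop("calibration required for bare waveforms")
    fs <- calibration$sample_rate_hz
    x <- as.numeric(waveform)
  }
  if (length(x) == 0) stop("empty waveform")
  if (all(x == 0)) stop("silent input: all-zero waveform has no defined SPL")
  nyq <- fs / 2
  if (band$f_lo_hz >= nyq) stop("band lies entirely above Nyquist")
  if (band$f_hi_hz > nyq) {
    warning(sprintf("band '%s' truncated at Nyquist (%g Hz)", band$name, nyq))
  }
  p <- counts_to_upa(x, calibration)
  sp <- welch_psd(p, fs, nfft)
  lo <- band$f_lo_hz
  hi <- min(band$f_hi_hz, nyq)
  sel <- sp$freq >= lo & sp$freq <= hi & sp$freq > 0  # DC always excluded
  if (!any(sel)) stop("no spectral bins inside band")
  pow <- sum(sp$psd[sel]) * sp$df
  10 * log10(pow)
}

# ---- minimal mono 16-bit PCM WAV I/O ------------------------------------

#' Write a waveform as 16-bit PCM WAV (mono)
#'
#' @param clip an `audio_clip` or numeric vector in [-1, 1].
#' @param path output path.
#' @param sample_rate_hz required when a bare vector is given.
#' @export
write_wav <- function(clip, path, sample_rate_hz = NULL) {
  if (inherits(clip, "audio_clip")) {
    x <- clip$samples; fs <- clip$sample_rate_hz
  } else {
    x <- as.numeric(clip)
    fs <- sample_rate_hz
    if (is.null(fs)) stop("sample_rate_hz required")
  }
  pcm <- as.integer(round(pmax(pmin(x, 1), -1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path WAV file path.
#' @return list with `samples` (full-scale units in [-1, 1]) and
#'   `sample_rate_hz`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  invisible(readBin(con, integer(), 1, size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fs <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM supported")
      if (fmt[2] != 1L) stop("only mono supported")
      fs <- readBin(con, integer(), 1, size = 4, endian = "little")
      invisible(readBin(con, integer(), 1, size = 4, endian = "little"))
      invisible(readBin(con, integer(), 1, size = 2, endian = "little"))
      bits <- readBin(con, integer(), 1, size = 2, endian = "little")
      if (bits != 16L) stop("only 16-bit PCM supported")
      if (sz > 16) invisible(readBin(con, raw(), sz - 16))
    } else if (id == "data") {
      samples <- readBin(con, integer(), sz / 2, size = 2, signed = TRUE,
                         endian = "little")
      break
    } else {
      invisible(readBin(con, raw(), sz))
    }
  }
  if (is.null(samples)) stop("no data chunk found")
  list(samples = samples / 32767, sample_rate_hz = fs)
}

#' Batch-compute SPL records from a file manifest
#'
#' One SPLRecord per manifest row; unreadable files are logged and skipped,
#' a sample-rate mismatch against the calibration is an error.
#'
#' @param manifest data.frame with `station_id`, `timestamp` (POSIXct or
#'   ISO-8601 string), `path`.
#' @param calibration a [calibration_spec()].
#' @param bands list of [band_def()]s as from [default_bands()].
#' @return SPLRecord data.frame; attribute `skipped` lists failed paths.
#' @export
process_recordings <- function(manifest, calibration = calibration_spec(),
                               bands = default_bands()) {
  stopifnot(all(c("station_id", "timestamp", "path") %in% names(manifest)))
  skipped <- character(0)
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    wav <- tryCatch(suppressWarnings(read_wav(manifest$path[i])),
                    error = function(e) NULL)
    if (is.null(wav)) {
      skipped <<- c(skipped, manifest$path[i])
      return(NULL)
    }
    if (wav$sample_rate_hz != calibration$sample_rate_hz) {
      stop(sprintf("sample rate %d of '%s' does not match calibration (%d)",
                   wav$sample_rate_hz, manifest$path[i],
                   calibration$sample_rate_hz))
    }
    spl <- vapply(bands, function(b)
      band_rms_spl(wav$samples, calibration, b), numeric(1))
    ts <- as.POSIXct(manifest$timestamp[i], tz = "UTC")
    data.frame(station_id = manifest$station_id[i], timestamp_start = ts,
               duration_s = length(wav$samples) / wav$sample_rate_hz,
               spl_high_dB = spl[["high"]], spl_low_dB = spl[["low"]],
               spl_broad_dB = spl[["broadband"]], flags = "",
               on_hour = as.POSIXlt(ts)$min == 0L)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  if (length(skipped)) {
    message(sprintf("skipped %d unreadable file(s)", length(skipped)))
  }
  attr(out, "skipped") <- skipped
  out
}

#' Keep only records that start on the hour
#'
#' The duty cycle records one clip every 20 minutes; manual flagging was
#' feasible only for the on-the-hour third of them, so every flag-dependent
#' stage runs on this subsample.
#'
#' @param records SPLRecord data.frame.
#' @return the rows whose start minute is 0, in their original order.
#' @export
subsample_on_hour <- function(records) {
  if (nrow(records) == 0) return(records)
  records[as.POSIXlt(records$timestamp_start)$min == 0L, , drop = FALSE]
}

split_flags <- function(flags) {
  strsplit(ifelse(is.na(flags) | flags == "", "", flags), ",", fixed = TRUE)
}

#' Exclude records flagged with physical or anthropogenic sound
#'
#' Drops any record whose flag set intersects the exclusion set, and
#' reports per-label exclusion counts (a record flagged with several
#' excluded labels counts once per label).
#'
#' @param records SPLRecord data.frame with a comma-separated `flags`
#'   column.
#' @param exclude character vector of flag labels to exclude; must be drawn
#'   from the known vocabulary (snapping_shrimp, fish, dolphin, wave_wind,
#'   water_flow, rain, vessel).
#' @return list with `retained` (data.frame), `excluded_counts` (named
#'   integer per excluded label), `n_excluded`, and `fraction_excluded`.
#' @export
exclude_nonbiological <- function(records,
                                  exclude = c("wave_wind", "water_flow",
                                              "rain", "vessel")) {
  unknown <- setdiff(exclude, FLAG_LEVELS)
  if (length(unknown)) {
    stop("unknown flag label(s): ", paste(unknown, collapse = ", "))
  }
  fl <- split_flags(records$flags)
  bad <- vapply(fl, function(f) any(f %in% exclude), logical(1))
  counts <- vapply(exclude, function(lab)
    sum(vapply(fl, function(f) lab %in% f, logical(1))), integer(1))
  list(retained = records[!bad, , drop = FALSE],
       excluded_counts = counts,
       n_excluded = sum(bad),
       fraction_excluded = if (nrow(records)) sum(bad) / nrow(records) else NA_real_)
}

band_column <- function(band) {
  switch(band, high = "spl_high_dB", low = "spl_low_dB",
         broadband = "spl_broad_dB",
         stop("unknown band '", band, "'"))
}

#' Daily mean SPL series
#'
#' Arithmetic mean of the dB values per calendar day. Days inside the span
#' with no (retained) records are emitted as `NA`, never zero-filled, so
#' gaps survive into the change-point stage as explicit missing days.
#'
#' @param records SPLRecord data.frame.
#' @param band `"high"`, `"low"` or `"broadband"`.
#' @param biological_only if TRUE, apply [exclude_nonbiological()] (with its
#'   default exclusion set) first.
#' @return data.frame with `date` and `mean_spl` covering every day from
#'   first to last record.
#' @export
daily_mean_spl <- function(records, band = "high", biological_only = FALSE) {
  if (nrow(records) == 0) stop("no records")
  if (biological_only) records <- exclude_nonbiological(records)$retained
  if (nrow(records) == 0) stop("no records left after exclusion")
  col <- band_column(band)
  d <- as.Date(records$timestamp_start)
  agg <- tapply(records[[col]], d, mean)
  days <- seq(min(d), max(d), by = "day")
  out <- data.frame(date = days,
                    mean_spl = as.numeric(agg[as.character(days)]))
  out
}

#' Date-by-time-of-day SPL matrix for heat maps
#'
#' Rows are noon-to-noon "acoustic days" (each row is labelled by the date
#' whose noon starts it), columns are clock times; cells hold the band SPL.
#'
#' @inheritParams daily_mean_spl
#' @return numeric matrix (dates x times) with dimnames.
#' @export
heatmap_matrix <- function(records, band = "high") {
  col <- band_column(band)
  t <- as.POSIXct(records$timestamp_start)
  shifted <- t - 12 * 3600
  row_key <- format(as.Date(shifted), "%Y-%m-%d")
  lt <- as.POSIXlt(t)
  col_key <- sprintf("%02d:%02d", lt$hour, lt$min)
  # columns ordered noon -> noon
  ord <- order((lt$hour * 60 + lt$min - 720) %% 1440)
  col_levels <- unique(col_key[ord])
  rows <- sort(unique(row_key))
  m <- matrix(NA_real_, length(rows), length(col_levels),
              dimnames = list(rows, col_levels))
  m[cbind(match(row_key, rows), match(col_key, col_levels))] <- records[[col]]
  m
}
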