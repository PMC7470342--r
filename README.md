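# estuarysound

Soundscape phenology for temperate estuaries: from duty-cycled hydrophone
recordings to the date each spring when snapping shrimp and fish "switch
on".

## The problem

Passive acoustic monitoring of shallow estuaries produces years of short
duty-cycled clips (here: 2 min every 20 min at 80 kHz). Two frequency bands
carry most of the biology — a high band (7–40 kHz) dominated by snapping
shrimp snaps and a low band (50–1200 Hz) dominated by fish choruses — and
both switch on abruptly each spring as water temperature rises. The
questions this package answers for ecologists running such programs:

* what is the calibrated band-limited rms sound pressure level
  (SPL, dB re 1 µPa) of each clip, with physical sound (wind, rain, flow)
  and vessel noise excluded;
* on what date does biological acoustic activity first rise abruptly each
  spring, and how anomalous is that date against the multi-year mean;
* which covariates (temperature, day length, rainfall, lunar phase, tide,
  day/night, site, year) drive SPL variability;
* does the soundscape track the fish/invertebrate community that seine
  surveys catch?

## The methods at its core

**Band SPL.** Welch power spectral density (Hann window, 50 % overlap,
8192-sample segments), integrated over each band after converting counts →
volts → µPa via the recorder calibration:
`SPL = 10·log10( ∫ S(f) df / (1 µPa)² )`.

**Onset detection.** The Barry–Hartigan product partition change-point
model with a Gibbs sampler. For daily mean SPL `x_1..x_n`, partitions into
constant-mean blocks get marginal posterior
`m(ρ) ∝ ∫₀^{p0} p^b (1−p)^{n−1−b} dp · ∫₀^{w0} w^{b/2} (W + Bw)^{−(n−1)/2} dw`,
where `b` is the number of change points and `W`, `B` the within/between
block sums of squares. Each sweep resamples every change indicator from its
conditional odds; the posterior probability of change (PP) at a day is the
fraction of retained sweeps with a boundary there. The **onset** is the
first day inside the astronomical spring window (vernal equinox → summer
solstice) with PP ≥ 0.5 and a rising posterior mean; the **day anomaly** is
its day-of-year minus the multi-year mean.

**Drivers.** Shadow-feature all-relevant selection over a permutation-
importance random forest (mtry 2, 200 trees, node size 5): a feature is
confirmed/rejected by a two-sided binomial test (p = 0.01) on how often it
beats the maximum importance of permuted shadow copies. Collinear seasonal
covariates (temperature / day length / rainfall) are compared as separate
model variants by out-of-bag R².

**Biodiversity.** Per-seine Shannon–Wiener `H′ = −Σ pᵢ ln pᵢ`, richness and
abundance, each standardized by seined area, averaged per station-month,
and correlated (Pearson) with monthly band SPLs.

A synthetic soundscape generator (temperature cycles with year-specific
spring offsets, logistic thermal activation of biological sound,
diel/tidal/lunar modulation, vessel/rain contamination, seine communities,
and raw audio clips with controlled band levels) makes the whole pipeline
testable without field recordings.

## Worked example

```r
library(estuarysound)

# simulate one station's spring, detect the onset
p   <- soundscape_params(seed = 101)
env <- generate_temperature_series("9M", "2017-02-18", "2017-07-21", p)
rec <- generate_spl_series(env, NULL, p)
rec <- subsample_on_hour(rec)                      # the on-the-hour third
bio <- exclude_nonbiological(rec)$retained         # drop rain/vessel files
d   <- daily_mean_spl(bio, band = "high")
fit <- bcp_ppm(d$mean_spl, d$date, seed = 5)
first_positive_change(fit, spring_window(2017))
#>         date day_of_year pp_value
#> 1 2017-03-20          79    0.992

# day anomalies from six yearly onsets
ev <- data.frame(year = 2013:2018,
                 date = as.Date(c("2013-04-09", "2014-04-03", "2015-04-01",
                                  "2016-03-25", "2017-03-23", "2018-03-29")))
day_anomalies(ev)[, c("year", "day_of_year", "anomaly_label")]
#>   year day_of_year  anomaly_label
#> 1 2013          99   9 days later
#> 2 2014          93   3 days later
#> 3 2015          91    1 day later
#> 4 2016          85 5 days earlier
#> 5 2017          82 8 days earlier
#> 6 2018          88 2 days earlier
```

The detected onset (March 20, PP 0.99) is the first spring day on which the
posterior says the daily mean high-band SPL jumped upward — here within a
day of the generated activation crossing. In the anomaly table, 2017 (the
warmest spring) is 8 days earlier than the six-year average and 2013 (the
coldest) 9 days later.

`run_phenology()` / `run_biodiversity()` orchestrate the full multi-station
multi-year pipeline from a single `run_config()`.

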