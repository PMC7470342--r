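---
title: "Models and methods behind estuarysound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind estuarysound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estuarysound)
```

`estuarysound` turns duty-cycled hydrophone recordings of a temperate
estuary into three scientific products: calibrated band-limited sound
pressure levels, the date each spring when biological acoustic activity
(snapping shrimp in the high band, fish choruses in the low band) first
rises abruptly, and the statistical relations between the soundscape, its
environmental drivers, and the seined community. This vignette documents
the models, the tunable parameters, the synthetic-data generator the test
suite runs on, and the numerical choices made where the design was open.

## 1. Band-limited SPL

Each clip is converted counts → volts → micropascals through a
`calibration_spec()` (hydrophone sensitivity in dB re 1 V/µPa, gain, ADC
full scale). Band power is the integral of the Welch power spectral
density over the band, and

$$\mathrm{SPL} = 10\log_{10}\!\left(\frac{\int_{f_1}^{f_2} S(f)\,df}
{(1\,\mu\mathrm{Pa})^2}\right).$$

Numerical choices:

* **Welch settings.** Hann window, 50 % overlap, 8192-sample segments,
  per-segment mean removal. At 80 kHz this gives ~9.8 Hz resolution and
  ~58 averages over a 2-min clip; settings are arguments, not constants.
  For a pure in-band tone the estimate matches the time-domain rms within
  0.1 dB (tested), and tiling sub-bands reconstruct broadband power within
  1 %.
* **Band edges.** High 7000–40000 Hz, low 50–1200 Hz. The broadband band
  is implemented as the DC-removed full band: a 1 Hz lower edge is below
  the first resolvable bin at the chosen segment length. The 40 kHz upper
  edge equals Nyquist at 80 kHz; the Nyquist bin is included, and bands
  reaching beyond Nyquist are truncated with a warning.
* **Degenerate inputs.** An all-zero waveform raises an explicit "silent
  input" error rather than returning −∞; a band entirely above Nyquist is
  an error.
* **Calibration.** No instrument calibration sheet ships with the package;
  the default (−186 dB re 1 V/µPa, 20 dB gain) is a documented
  placeholder. Absolute levels therefore carry the calibration's
  uncertainty, and every analysis in the package rests on *differences and
  patterns* of SPL, never on absolute values.

Bookkeeping mirrors a 2-min-every-20-min duty cycle: `subsample_on_hour()`
keeps the on-the-hour third of records (the subset for which manual
flagging is feasible), and `exclude_nonbiological()` drops files flagged
with wind/wave, water flow, rain, or vessel noise, reporting per-label
counts. Flags come from an annotation table in real use and from generator
truth in tests; no automatic classifier is attempted, since flagging in
the monitoring programs this emulates is manual.

## 2. Covariates

* **Lunar category**: synodic age (days since the 2000-01-06 reference new
  moon modulo 29.530588) quartered around the four principal phases. The
  upstream category convention this follows is not fully specified in the
  literature it comes from, so both a phase-centered (default) and a
  contiguous-from-new-moon quartering are implemented; the choice is an
  argument.
* **Tidal category**: empirical extrema of the water-level logger series;
  `high`/`low` within one-eighth cycle of an extremum, `falling`/`rising`
  between. On a sinusoid each category occupies 25 % of time (tested). No
  harmonic tide prediction is attempted — only logger data are used.
* **Day/night and day length**: standard NOAA solar-position equations
  with the −0.833° horizon; polar latitudes are refused.
* **Spring window**: vernal equinox to summer solstice from the Meeus
  polynomial approximation (date-level accuracy; 2016's June 20 solstice
  is reproduced). A fixed-date fallback (Mar 20 / Jun 21) and a per-year
  override table exist for exact agency-published dates.
* **Joins**: nearest-in-time for temperature and water level with a 1 h
  default maximum gap (records beyond it get missing covariates and are
  counted); daily join for rainfall. All astronomy is computed in UTC.

## 3. Change-point model and the onset rule

Daily mean SPL (arithmetic mean of dB values — the analyses operate on the
dB scale throughout, so dB are averaged directly rather than via power) is
modelled with the Barry–Hartigan product partition model. Conditional on a
partition $\rho$ with $b$ change points, the marginal posterior is

$$m(\rho) \propto \int_0^{p_0} p^{b}(1-p)^{n-1-b}\,dp \;
\int_0^{w_0} \frac{w^{b/2}}{(W_\rho + B_\rho w)^{(n-1)/2}}\,dw,$$

with $W_\rho$, $B_\rho$ the within/between block sums of squares, a
Uniform(0, $p_0$) prior on the change probability and Uniform(0, $w_0$) on
the within/total variance ratio. The Gibbs sampler resamples each interior
change indicator from the ratio $m(\rho_1)/m(\rho_0)$; both integrals
reduce to incomplete beta functions (with a quadrature fallback where the
second shape parameter is non-positive). Defaults $p_0 = w_0 = 0.2$, 50
burn-in + 500 retained sweeps — the conventional defaults for this
sampler, since the analysis design states none. PP at a position is the
fraction of retained sweeps with a boundary there; the posterior mean is
the across-sweep average of conditional block means, which keeps it inside
the data range by construction.

Correctness is tested two independent ways: on series of length ≤ 8 the
sampler's PP matches brute-force enumeration of all $2^{n-1}$ partitions
weighted by $m(\rho)$ (within 0.03 at 10,000 sweeps), and PP is invariant
to shifting and scaling the series.

Choices worth knowing:

* **Missing days** are compacted out, never interpolated (interpolation
  would manufacture changes); results map back to true dates.
* **Onset rule**: first date inside the spring window with PP ≥ 0.5 *and*
  posterior mean higher after than before (an increase, not a decrease).
  A tie at exactly 0.5 counts as significant.
* **Anomalies** are leap-aware day-of-year minus the multi-year mean;
  negative = earlier. Reports print rounded magnitude plus
  "earlier/later". At least two years are required; duplicate years are an
  error.
* **Resolution**: the model runs on daily means of the biological-only,
  on-the-hour dataset by default; any other series can be passed directly
  to `bcp_ppm()`.

## 4. Variable importance

`shadow_feature_selection()` re-implements the shadow-feature wrapper:
each run appends a permuted copy of every feature, fits a
permutation-importance random forest (delegated to `ranger`; the analysis
contribution is the wrapper, not the tree learner), scores a hit when a
real feature beats the maximum shadow importance, and decides by a
two-sided binomial test (null 0.5) at p = 0.01. Engine defaults are
mtry 2, 200 trees, node size 5, seed 42 — the analysis configuration this
package standardizes on. max_runs defaults to 100 and undecided features
are reported tentative, never silently confirmed. Because temperature, day
length and rainfall are collinear, `compare_collinear_models()` fits one
model per covariate and compares out-of-bag R².

A caveat the test suite makes explicit: all-relevant selection is defined
*relative to the dataset*. In small designs a noise feature can carry a
real chance correlation with the response and be legitimately confirmed;
at n = 500 and 3 noise features the long-run confirmation rate sits near a
few percent. The planted-signal benchmark therefore uses a deterministic
signal (y = x₁), for which rejection of the noise features is clean across
seeds.

`dtk_pairwise()` provides pairwise mean comparisons adjusted for unequal
variances and sample sizes: half-width
$q_{k,\nu}\sqrt{s_i^2/n_i + s_j^2/n_j}/\sqrt{2}$ with the studentized-range
quantile at per-pair Welch–Satterthwaite degrees of freedom $\nu$. With
equal sample variances it agrees with the classical Tukey–Kramer interval
within 1 % (tested against `TukeyHSD`).

## 5. Biodiversity

Shannon–Wiener $H' = -\sum p_i \ln p_i$ (nats), richness and abundance are
computed per seine, standardized by that seine's area, then averaged per
station × month ("per-seine-then-average"; the alternative
pool-then-standardize convention would weight hauls by catch size).
Pearson correlations pair station-months of diversity with monthly mean
band SPL; temperature regressions are ordinary least squares. Pairs with
fewer than 3 months or zero variance are skipped with a message. $H'$ is
cross-checked against `vegan::diversity` in the tests.

## 6. The synthetic soundscape generator

The generator encodes the statistical structure the analysis assumes, so
every downstream stage is testable without any recordings.

* **Temperature**: annual sinusoid (default mean 20 °C, amplitude 8.5 °C,
  maximum at day 205 — a South Carolina salt-marsh climate), a 0.5 °C
  afternoon diel cycle, hourly AR(1) noise (φ = 0.98, innovation 0.15 °C,
  stationary sd ≈ 0.75 °C — realistic multi-day excursions), and
  year-specific spring offsets. The default offsets are the two anomalous
  springs of the emulated six-year record: +1.21 °C in 2017 and −1.33 °C
  in 2013.
* **Activation**: band SPL = base + gain · logistic((T − 17 °C)/0.5 °C).
  The 0.5 °C steepness encodes rapid behavioural activation around a
  thermal threshold — the abrupt seasonal onsets visible in estuarine
  spectrograms — and the 17 °C midpoint places onsets in late March/April.
  Gains default to 15/10/12 dB (high/low/broadband) over bases of
  95/90/97 dB.
* **Category effects**: high band louder by day, at low tide and at new
  moon; low band louder at night and around the full moon (1–2 dB each) —
  the diel/tidal/lunar patterning the drivers analysis is meant to
  recover. A regression on noise-free generator output recovers these
  effects to machine precision (tested).
* **Residuals**: Gaussian on the dB scale (SPL is already
  log-amplitude) — 1 dB per record *plus* a 1 dB per-day shared effect.
  The shared term matters: records within a day experience the same
  weather and behavioural state, so daily means must not average residual
  variability away to nothing; without it the change-point stage would
  detect the logistic ramp's foot weeks before the midpoint crossing,
  which no real daily series would support.
* **Contamination**: vessel flags on summer daytime records with
  probability 0.15 (recreational boating is concentrated there); rain
  events on 10 % of days flag the whole day.
* **Audio**: `synthesize_audio_clip()` builds waveform-level fixtures —
  Poisson-timed broadband snaps (2–40 kHz), 100–1000 Hz gated fish chorus,
  optional vessel tonal + wash — iteratively scaled so measured band SPLs
  hit their targets within ±1 dB for targets in 80–140 dB (tested by
  round-trip through the SPL extractor). Species-specific call synthesis
  is out of scope; the components are generic band-limited stand-ins, not
  calibrated to any particular river's spectra.
* **Seines**: expected richness = 12 · logistic((T − 17)/3), realized
  binomially; species drawn from a 20-species estuarine pool; log-normal
  counts; uniform 20–120 m² areas. Warm months are richer than cold ones
  by construction, which couples the community to the same thermal driver
  as the soundscape.

Every generator is bit-identical under a fixed seed.

**What passing tests do and do not show.** The generator reproduces the
*structure* of estuarine soundscape data (seasonal activation with thermal
anomalies, diel/tidal/lunar modulation, contamination, coupled
communities), not its texture: real SPL series have autocorrelated and
heteroscedastic residuals, missing deployments, slow sensitivity drift,
storms, and vessel noise that leaks into all bands. Recovery rates
measured here (e.g. onset within ±5 days in ≥ 90 % of synthetic
station-years at 1 dB daily noise) characterize the pipeline under its own
assumptions and are upper bounds on field performance, not predictions of
it. Two further honest caveats: in springs dominated by an early warm
excursion the *first* positive change can genuinely precede the sustained
midpoint crossing by more than 5 days, and absolute SPL values are only as
good as the calibration placeholder.

## 7. Problem sizes used by the test and acceptance runs

The suites run on deliberately desk-scale versions of the study design:
single stations and one to four years where the full design had three
stations and six; 10,000-sweep sampler runs only on the short enumeration
benchmarks; 20 synthetic station-years for onset recovery; n = 500 designs
and 10–50 seeds for the selection benchmarks. These sizes give each check
sharp expected behaviour while keeping a complete run in minutes on one
CPU.

## 8. Known limitations

* No acoustic propagation model: SPL at the hydrophone is treated as the
  site's soundscape; active-space and depth effects are not modelled.
* No automatic call detection or per-species counting; flags are manual
  or generator truth.
* The change-point model assumes independent Gaussian residuals within
  blocks; strong autocorrelation inflates PP. Running on daily means (not
  per-file series) mitigates but does not remove this.
* Whether reported multi-year anomalies should be computed from rounded
  or fractional day-of-year means is ambiguous at the whole-day printing
  precision; both conventions round to the same values in every case
  exercised here, and the fractional convention is used internally.
* The lunar/tidal category boundaries follow a symmetric quartering;
  other programs may center categories differently, which shifts 1–2 dB
  category effects between neighbouring labels.
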