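---
title: "Models and methods behind nirtherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nirtherm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nirtherm` quantifies the thermal consequences of near-infrared (NIR)
reflectance for small ectotherms and their physical models. This vignette
documents the models the package implements, the conventions and tunable
parameters behind them, what the synthetic-data generators emulate (and do
not), and the design decisions taken where the underlying methodology left
choices open.

## 1. Solar-weighted reflectivity

The central quantity is the reflectivity of a surface over a wavelength
band $[i, n]$,

$$R = 100\,\frac{\int_i^n S(\lambda)\, I(\lambda)\, d\lambda}
                {\int_i^n I(\lambda)\, d\lambda}\ \,[\%],$$

with $S(\lambda)$ the reflectance relative to a white standard (a fraction,
0–1, stored internally as a fraction and only converted to percent at
reporting time, to keep a factor-of-100 error from ever entering the
integral) and $I(\lambda)$ the solar spectral irradiance in
W m$^{-2}$ nm$^{-1}$. $R$ is the irradiance-weighted mean reflectance and
determines the fraction of incident solar power the surface turns away.

**Numerics.** Spectra are piecewise-linear interpolants of their measured
points. For integration both curves are resampled to a merged 1 nm working
grid spanning the band (1 nm matches the resolution scale of the
spectrometers the pipeline targets and makes band integrals exactly
additive over band partitions); the integral is the trapezoid rule with the
band endpoints interpolated into the grid. For the smooth spectra the
pipeline handles, the trapezoid value agrees with the exact integral of the
same interpolants to better than $10^{-6}$ relative (this equivalence is
asserted in the test suite against a closed-form product-integral oracle).
Band energy fractions use the same endpoint-inserted trapezoid, so
fractions over a partition of the reference band sum to one to $10^{-9}$.

One wording caveat: reflectivity is sometimes verbally described as the
ratio of *incident to reflected* light; the formula implemented here is
reflected over incident energy, which is the quantity with the stated
physical meaning (100% = perfect reflector).

## 2. Calibration, splicing, extension

**Calibration** converts raw counts to reflectance via
$0.99\,(\mathrm{raw}-\mathrm{dark})/(\mathrm{white}-\mathrm{dark})$
against a Spectralon 99% standard (the factor is configurable). Dark-noise
can push the numerator slightly negative; those values are clipped to zero
rather than rejected, since downstream integrals treat reflectance as
non-negative. A white reference at or below dark at more than 1% of
wavelengths aborts the calibration as a saturated/invalid reference.

**Splicing** joins a UV-Vis spectrometer range (to 1000 nm) and a NIR range
(from 1000 nm). The junction is handled with a ±5 nm averaging window: the
two instruments are resampled to a 1 nm grid inside the window and
averaged where both are defined; outside it each instrument's points are
used as measured. A gap above 10 nm between the ranges is an error. The
window width is this package's choice — the two ranges nominally meet at a
point, and a small averaging window damps instrument-to-instrument offset
without distorting either range.

**Spectral extension.** Reflectance measured only to 950 nm misses roughly
a quarter of solar energy, so two extension rules to 1700 nm are provided:

- *Exponential decline*: $R(\lambda) = R(950)\,e^{-k(\lambda-950)}$ with
  $k = -m / R(950)$, where $m$ is the least-squares slope over
  850–950 nm. This is the unique single-parameter exponential through
  $R(950)$ whose initial derivative matches the measured trend; a flat or
  rising trailing slope degrades gracefully to a constant continuation
  ($k = 0$), as does zero reflectance at the anchor. The precise decay-rate
  rule is this package's construction (extrapolation conventions vary
  between laboratories), and results carry an extension-method tag so
  extended and measured reflectivities are never silently mixed.
- *Linear continuation*: the least-squares slope over 850–950 nm continued
  from $R(950)$, with negative values clipped to zero (clipping can be
  disabled). Least squares over the window is preferred to a two-point
  difference for noise robustness; a two-point rule is recovered by
  narrowing the window.

Both extensions are continuous at the anchor by construction. Group
comparison tables report means and high-minus-low differences rounded
half-to-even at one decimal.

## 3. Laboratory heating traces

The chamber protocol is an ordered phase schedule — by default 5 min dark
cooling, then 30 min heating under full-spectrum (300–1700 nm), NIR-only
(700–1700 nm) and UV-Vis-only (300–700 nm) illumination, each followed by
15 min dark cooling (8400 s total). Samples are assigned to phases by
elapsed time; a sample exactly on a boundary belongs to the later phase.

- **Heating rate** is the OLS slope of temperature on time over the first
  2 min of a heating phase, in °C min$^{-1}$. The window *includes* the
  sample at phase start (at 20 s sampling: 7 samples), reading "the first
  two minutes of heating" as including onset. Actual timestamps enter the
  fit, so sampling jitter up to ±10% of the nominal interval is handled
  exactly; an affine trace returns its slope to machine precision
  regardless of window length.
- **End-of-phase temperature** is the temperature at the phase's final
  sample. Chamber curves approach saturation, so the final sample and the
  phase maximum normally coincide; where a trace dips after an early peak
  the two differ, and the summary emits both (flagged) whenever they
  disagree by more than 0.1 °C. A `mode = "max"` option returns the phase
  maximum directly.

## 4. Field statistics

Three complementary analyses of a paired field deployment are implemented.

**Surface-vs-leaf deltas.** Per thermal image, model surface minus adjacent
leaf temperature; a Gaussian LMM with coating × size fixed effects and
random intercepts for pair and site (lme4). Variances are estimated by
REML rather than full ML: Wald chi-square tests take the estimated
variance as known, and ML's downward variance bias makes them visibly
liberal in simulation (about 10% rejection at the 5% level in a
48-pair null design, against near-nominal for REML) — REML is also what
the standard lme4 + car toolchain does by default. Fixed terms are tested
with Type II Wald chi-square tests (car) — Type II respects marginality,
the standard companion to Wald chi-square reporting for factorial LMMs.
Group estimates and asymptotic 95% CIs come from estimated marginal means
(emmeans). A singular fit drops the zero-variance component, refits, and
flags the change in the result's structure descriptor.

**Daily 95th percentiles.** Each logger series-day is summarised by its
95th percentile — a maximum-like statistic insensitive to single-sample
spikes (one model of a pair catching a brief sunspot). The quantile uses
linear interpolation of order statistics at position $(n-1)p + 1$ (R's
default type 7; no convention is canonical, this is the most common in
scientific software). Days are deployment windows, not calendar days,
since the loggers only run while deployed. Series-days with fewer than 20
samples are omitted with a warning. The LMM mirrors the delta model with a
third random intercept for logger identity.

**Paired differences with AR1 residuals.** Within-pair difference series
(LNIR − HNIR for coated pairs; large − small for the uncoated pair, which
has no size contrast) are matched timestamp-by-timestamp within 150 s —
half the logging interval. The model (nlme) has air temperature and, for
coated pairs, size as predictors; random intercepts for site and pair
(pair nested within site, because joint estimation of crossed random
effects with AR1 residual correlation is not supported by the available
likelihood machinery — the descriptor records the structure actually
fitted); and AR1 correlation within each series. Consecutive deployment
days are decorrelated by an index gap so the AR1 process never bridges a
day boundary. The scientific target is the intercept's MLE and 95% Wald
CI: an interval excluding zero means one pair member runs consistently
warmer. For that reading to hold, air temperature is centred and size
coded sum-to-zero, making the intercept the mean paired difference;
uncentred, it would be the meaningless extrapolated difference at 0 °C
air, and chance air-slopes 25 °C away from the data would swing it by
whole degrees. Non-convergence of the AR1 fit falls back, loudly flagged, to a
GLS fit without random effects and finally to independent residuals.

**Sunspot detection** flags maximal intervals where temperature exceeds a
running baseline — the median of the preceding 60 min — by at least 2 °C,
reached within 20 min of onset (a slow warming trend that eventually
clears the threshold is not a spike). These thresholds are configurable
defaults chosen to capture the 1–2 °C, 15–25 min transients that canopy
sunspots produce; they are detection conventions of this package, not a
published rule. Paired detection merges overlapping events from the two
series and reports the peak within-pair excess during the event.

Significance is reported at $\alpha = 0.05$ throughout, with no
multiple-testing correction (three pre-planned analyses answering distinct
questions).

## 5. Synthetic data

The generators produce data with exactly the statistical structure the
analyses assume, which is what makes them useful for validation — and
limits what passing tests prove about real data.

- **Spectra**: baseline + Gaussian green peak (550 nm, height 0.15,
  SD 40 nm) + logistic red-edge rise (inflection 720 nm, scale 25 nm) to a
  NIR plateau of 0.55 (high-NIR preset) or 0.10 (low-NIR), plus clipped
  Gaussian noise on a 1 nm grid. These values put the presets in the
  reflectivity range of real leaf-matching and leaf-contrasting frogs.
- **Solar irradiance**: a *synthetic* AM1.5G-like spectrum — a 5772 K
  Planck envelope attenuated by Rayleigh scattering, an Angstrom aerosol
  law, the ozone UV cut-off and Chappuis band, the O$_2$ A/B lines and the
  major water/CO$_2$ bands at airmass 1.5, with standard atmospheric
  constants (rural aerosol, ~1.4 cm precipitable water). It reproduces the
  qualitative shape of the terrestrial solar spectrum (its 300–1700 nm
  share of the 300–2600 nm total comes out at ~97.5%, versus 98.9% for the
  reference standard) but is not the ASTM G-173-03 table; analyses citing
  the standard's band shares must load the real table via
  `read_astm_g173()`.
- **Chamber traces**: a lumped first-order model. Under illumination the
  temperature relaxes exponentially (τ = 450 s, the scale of a few-cm agar
  body) toward ambient plus
  $\tau\,g\,(1 - R/100)\,f_\mathrm{band}/60$, where $g = 1.6$ °C min$^{-1}$
  is the initial heating rate of a perfect absorber under the chamber's
  ~1000 W m$^{-2}$ full-band illumination and $f_\mathrm{band}$ the energy
  fraction passed by the phase's filter. Uncoated (evaporating) surfaces
  sit 2 °C below their radiative equilibrium while illuminated. Exact
  exponential stepping at the 20 s sampling interval makes the traces free
  of integration error; the absorbed fraction $(1-R/100)$ then sets initial
  heating-rate ratios exactly. Absolute chamber temperatures are *not*
  calibrated to any real apparatus — only orderings and estimator
  behaviour are meaningful.
- **Field days**: five sites per deployment day, each holding large and
  small coated pairs (LNIR with HNIR on one leaf) and an uncoated
  large/small pair, 96 samples at 5 min (a 9:00–17:00 window). Co-located
  series share a site-level diurnal course (mean 25 °C, amplitude 3 °C —
  shaded tropical understorey) and sunspot event times; each series adds
  stationary AR1(φ = 0.8) logger noise (innovation SD 0.15 °C). Sunspots
  are rare (0.15 site$^{-1}$ day$^{-1}$), last 15–25 min, and heat low-NIR
  surfaces most (half-sine pulses of 4.0 / 2.5 / 3.0 °C for LNIR / HNIR /
  uncoated); uncoated models run 2 °C cool from evaporation. Event times
  and noise come from separate named substreams of the seed, so changing
  the noise level never moves the events.

What the generators do **not** emulate: radiative microclimate gradients
within a site, logger quantisation, evaporation drying out over a day,
heteroskedastic day–night transitions, and any absolute-temperature
realism for the chamber. Passing recovery tests therefore demonstrates
estimator correctness under the assumed structure, not robustness to every
field artefact.

## 6. Validation choices and problem sizes

The test suite fixes expected values from independent oracles (closed
forms, brute-force order statistics, an exact product-integral rule) and
checks estimator calibration by simulation: 500-replicate null simulations
for the AR1 intercept's CI coverage and bias (3 sites × 2 pairs × 60
samples per replicate) and for the factorial LMM Wald tests. The Wald
chi-square is an asymptotic test, so its null simulation uses a design
with adequate pair-level replication (14 sites × 9 pairs, two models × two
days each); at smaller designs even the REML-based Wald test drifts
anticonservative — a known finite-sample property worth remembering when
reading chi-square values from modestly sized field studies.
Intercept-recovery checks use 50 series of 80 samples at effect sizes 0,
0.5 and 1 °C.

## 7. Known limitations

- The AR1 model treats pair within site as nested and decorrelates days by
  construction; true crossed random effects with AR1 residuals would need
  a different likelihood implementation.
- Wald CIs and tests are asymptotic; no Kenward–Roger or parametric
  bootstrap small-sample correction is offered.
- The spectral extension rules are conventions, not physics: beyond
  1400 nm, real frog and paint spectra are shaped by water and binder
  absorption that neither rule models.
- The bundled solar spectrum is an analytic stand-in; all quantities that
  must match the reference standard's printed values require the real
  ASTM G-173 table.
- `calibrate()` assumes the white reference was measured under the same
  geometry and integration time as the sample; it applies no stray-light
  or non-linearity correction.
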