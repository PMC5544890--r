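---
title: "From chamber logs to conclusions: methods behind macroflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From chamber logs to conclusions: methods behind macroflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macroflux)
```

## The measurement problem

Emergent aquatic macrophytes (reeds like *Phragmites australis*, sedges
like *Carex rostrata*) pipe methane from anoxic sediments straight to the
atmosphere through their aerenchyma, bypassing the oxidation zone.  The
standard way to measure this plant-mediated flux is a static (closed)
chamber: a sealed transparent headspace is floated over a stand of plants
and a greenhouse-gas analyser logs the CH~4~ and CO~2~ mixing ratios of the
recirculated headspace air — here every 20 s during a 5-min enclosure.
The rate of concentration rise, converted through the ideal-gas law,
gives the areal flux.

`macroflux` implements the full analysis chain for such campaigns:
per-enclosure flux estimation, ebullition screening, the Henry's-law
diffusive flux of the open-water pathway, diel-agreement statistics,
daily-mean regressions, and all-subsets AIC model averaging of a Gamma
generalized linear model.  A synthetic-data generator emulates a two-lake,
two-species seasonal campaign with known ground truth so that every stage
is testable without field data.

## Per-enclosure flux estimation

**Windowed slope selection.**  The first minute of each enclosure is
discarded: the tubing and the analyser cell need that long before they
reflect average chamber air.  Over the remaining 4 min, every 2-min
window offset by 20 s is fitted by ordinary least squares — seven windows
under the default protocol — and the window with the highest r² is used
for the flux.  The slope is computed with times in days,

$$\mathrm{slope} \;=\; \frac{\sum_i (t_i - \bar t)(\mathrm{ppm}_i -
\overline{\mathrm{ppm}})}{\sum_i (t_i - \bar t)^2}
\qquad [\mathrm{ppm\,d^{-1}}],$$

and converted to an areal flux with the ideal-gas law,

$$F \;=\; \frac{\mathrm{slope}}{10^6}\cdot\frac{P_{tot}\,V}{R\,T}\cdot
\frac{1000}{A} \qquad [\mathrm{mmol\,m^{-2}\,d^{-1}}],$$

with $R = 0.082056$ L atm K⁻¹ mol⁻¹, $V$ the chamber volume (L), $A$ its
base area (m²).  Numerical choices worth knowing:

* A window with zero concentration variance reports r² = 0 (not `NA`),
  so a flat window can never win selection.
* Ties in r² go to the earliest window — deterministic, and favouring
  data closest to chamber closure.
* Window membership is the closed interval `[start, start + 120 s]` on
  sample times (0-based seconds since closure).
* The default volume is the chamber's specified 197.4 L.  The chamber's
  nominal outer dimensions imply a somewhat larger volume; the specified
  headspace volume is taken as authoritative, and both volume and area
  are plain configuration fields.
* The CO~2~ (NEE) slope is fitted over the *same* window chosen for
  CH~4~, so the paired fluxes describe the same period.  Positive flux
  means emission into the chamber.

**A bias worth knowing about.**  Selecting the maximum-r² window is not
innocent: when the trend is weak relative to analyser noise, windows in
which the noise happens to stretch the slope also look more linear, so
the selected slope is biased high.  Monte-Carlo runs with the package's
own generator put this at under 1% (mean) for a 20 mmol m⁻² d⁻¹ flux at
0.02 ppm noise, but around +10% at 5 mmol m⁻² d⁻¹ — and worse if the
noise is larger.  The tests pin these magnitudes.  For strong emitters
(the regime this design targets) the effect is negligible; for weak
fluxes a fixed-window protocol would be preferable.

**Ebullition screening.**  Bubble events appear as a sudden step in
CH~4~ concentration that also degrades the linearity of the whole record.
An enclosure is flagged when (a) the largest successive concentration
difference exceeds `threshold_k` (default 10) times the median absolute
successive difference of the retained record, and (b) the least-squares
fit over the whole retained record has r² below `r2_min` (default 0.9).
Both knobs are exposed.  The r² gate is evaluated on the whole
post-discard record rather than the best window, because the best window
routinely dodges the step entirely and would mask exactly the events the
screen exists to catch.  Flagged enclosures are kept in the flux table
(no silent row loss) and excluded by every downstream statistic.

## Diffusive flux

The open-water pathway is estimated as $F = k\,(C_w - C_{eq})$, with $k$
the gas transfer velocity (an input, derived from open-water
measurements elsewhere; if anything an overestimate inside wind-sheltered
stands), $C_w$ the measured dissolved concentration, and $C_{eq}$ the
Henry's-law equilibrium with the atmosphere.  Solubility uses a van 't
Hoff parameterisation $K_H(T) = 1.4\times10^{-3}
\exp\!\big[1750\,(1/T - 1/298.15)\big]$ mol L⁻¹ atm⁻¹, injectable if a
different parameterisation is preferred, valid over 273–308 K.  Water
temperature can be approximated by air temperature when unmeasured; that
approximation should be flagged by the caller.

## Temporal statistics

**Diel agreement (ICC).**  Each daily series is binned into 10 equal
2.4-h time classes (half-open bins, 0-based indices) and averaged within
class.  Whether the daily profiles agree across days is quantified by a
two-way absolute-agreement intra-class correlation in which the *time
classes are the targets* and the *daily series are the raters*: if every
day shows the same diel profile the coefficient approaches 1; unrelated
days give values near 0.  With between-class, between-series and error
mean squares $MS_R$, $MS_C$, $MS_E$, $k$ series and $n$ classes,

$$\mathrm{ICC}(A,1) = \frac{MS_R - MS_E}
{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)},$$

with the usual average-measures variant also reported; the p-value is
the $F = MS_R/MS_E$ test.  The single-measures coefficient is the
headline number.  Orientation matters: treating the series as targets
would score "all days identical" as zero agreement, the opposite of what
the question asks.  Any time class missing in at least one series is
dropped (with a warning giving the count) so the ANOVA stays balanced.

**Daily summaries and regressions.**  Daily means carry t-based 95%
intervals ($\pm t_{0.975,\,n-1}\,SE$; with 7–24 values per day the
normal 1.96 would be too narrow).  Relationships between daily mean flux
and daily mean drivers (air temperature, wind, light, NEE) are ordinary
least-squares regressions with two-sided slope p-values and adjusted R².

## Gamma GLZ model averaging

All (ebullition-free, positive) flux measurements are modelled with a
Gamma GLM with log link — fluxes are positive and right-skewed with
variance growing with the mean, which the Gamma family matches.  The
predictor set follows the study design: lake and species as 0/1
indicators (reference levels: the second lake and the sedge, so the lake
coefficient reads "first lake compared with second"), air temperature,
light, pressure, wind, biomass and NEE standardized to mean 0, SD 0.5
(sample SD; the half-z scale makes continuous coefficients comparable
with binary ones), and day-of-study and time-of-day with
marginality-respecting quadratics built after standardization.

Every model nested in the full model is fitted: all $2^8$ subsets of the
eight free terms crossed with {absent, linear, linear + quadratic} for
each polynomial group — 2304 candidates.  Candidates are ranked by AIC,
where the likelihood is evaluated at the deviance-based dispersion and
the parameter count includes the Gamma shape (identical to `stats::AIC`
on the corresponding `glm` fit); AICc is available by flag.  Akaike
weights $w_i = e^{-\Delta_i/2}/\sum_j e^{-\Delta_j/2}$ feed the
averaging.  No ΔAIC cutoff is applied: all candidates are retained.

The default is *full* (zero-substitution) averaging: a term absent from
a candidate contributes zero, so weakly supported terms shrink toward
zero — the behaviour wanted when the averaged table is read as an
effect-size summary.  Conditional averaging (renormalising over the
containing models) is available.  Unconditional standard errors follow
the weighted-variance-plus-spread formula
$SE_j = \sum_i w_i\sqrt{se_{ij}^2 + (\hat\beta_{ij} - \bar\beta_j)^2}$,
the 95% CI is $\pm 1.96\,SE$, and a term's relative importance is the
summed weight of the candidates containing it.

Pre-checks mirror sound practice: predictors with pairwise $|r| > 0.7$
are reduced to the higher-priority member (in the pipeline, chamber
temperature and humidity predictably fall to their coupling with air
temperature), variance-inflation factors on the retained set are
reported (computed from the inverse correlation matrix; a warning above
3), and within-day autocorrelation can be checked with Yule-Walker AR
fits under AIC order selection — informational only, since thinning
hourly days to 12 measurements (keeping every second value of a
24-measurement day, and only then) already evens the sampling intensity
and removes most serial dependence.  Note that AIC order selection
overfits white noise at a known ~25% rate for day-length series; order 0
is the modal, not the guaranteed, choice on structureless days.

## What the synthetic generator emulates — and what it does not

The generator reproduces the *design* of a two-lake campaign: one reed
and one sedge site per lake; 7 occasions for the first lake and 6 for
the second (staggered by a day); hourly enclosures on the early
occasions, 2-hourly later; 5-min enclosures logged every 20 s; one
whole daily series lost at random (25 complete series by default).
Ground truth follows
$\log F = 0.55 + 0.075\,T_{air} + \log(\text{lake multiplier}) +
\text{species offset}$, with multipliers {1, 3} (the shallow,
organic-rich lake emits about three times more), a species offset of
zero (no species effect per m², matching the study finding; settable for
power studies), Gamma multiplicative noise with CV 0.4, and an optional
built-in diel modulation (off by default).  Temperatures follow each
occasion's seasonal mean (15 → 18 → … → 7 °C from June to October) plus
a ±5 °C sinusoidal diel cycle peaking at 15:00; light is zero at night;
pressure is essentially constant at 0.99 atm; analyser noise is 0.02 ppm
per sample (the instrument class is better than this at 1 Hz; the
default is deliberately conservative, and is a free parameter, not a
claim about any particular analyser).  Ambient CH~4~ defaults to
1.9 ppm.  Ebullition is a single instantaneous step (default 5 ppm,
probability 0.005 per enclosure) at a uniform random sample time after
the discard minute — a step during the discarded mixing period would
shift all retained samples equally, be absorbed by the regression
intercept, and be unobservable in principle, so injecting there would
only blur what the detector is being tested against.

Because concentration ramps are laid down by inverting the same
ideal-gas conversion the estimator applies, a zero-noise study
round-trips every injected flux exactly — the pipeline's core identity
test.  What the generator does *not* emulate: analyser drift and
autocorrelated noise, chamber leakage and warming during enclosure,
nonlinear concentration build-up near saturation, within-site spatial
heterogeneity, water-level changes, or weather fronts (wind, pressure
and cloudiness are drawn i.i.d. per slot).  Passing tests on synthetic
data therefore demonstrate the correctness of the estimators under the
stated model, not robustness to every field pathology.

## Problem sizes and determinism

Everything is deterministic given the configuration seed, and datasets
written to disk regenerate byte-identically from their manifest.  The
shipped tests run the oracle comparisons at 1000 random series, the
detector and noisy-recovery Monte-Carlos at 200 replicates, the ICC null
at 1000 replicates of a 25 × 10 design, and the end-to-end
model-averaging recovery at 50 seeded replicates of the full campaign
(~2300 Gamma fits each) — sizes chosen to keep the whole suite in the
minutes range on a single core while leaving Monte-Carlo error well
below the asserted margins.

## Known limitations

* The best-r² selection bias at low signal-to-noise, discussed above.
* The ebullition screen targets single large steps; trains of small
  bubbles that mimic a steeper linear ramp pass through (they are, by
  construction, indistinguishable from plant flux in a 5-min record).
* Binary predictors are limited to two levels; multi-lake designs would
  need indicator expansion.
* The Gamma GLZ assumes independent observations; the design relies on
  thinning rather than explicit temporal correlation structure.
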