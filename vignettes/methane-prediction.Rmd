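---
title: "Predicting enteric methane from breath CH4/CO2 ratios: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting enteric methane from breath CH4/CO2 ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snifferch4)
```

## The measurement problem

Enteric methane from dairy cows is conventionally measured in respiration
chambers or ventilated head boxes — accurate, but far too expensive for
routine use on farms. The *sniffer method* instead samples air near a cow's
muzzle while she is at the feed bin of an automatic milking system (AMS) and
uses the breath CH4/CO2 concentration ratio as the carrier of information:
CO2 acts as a tracer gas whose daily output can be predicted from animal
records, so the ratio converts into a daily CH4 volume. This package
implements that entire chain — trace processing, flux computation,
prediction equations, and the statistical adjustment for when the cow last
ate — together with a synthetic-data generator so every stage can be tested
without animal data.

## Closed-form physiology

Energy-corrected milk standardizes yield for composition
(Tyrrell–Reid):

$$\mathrm{ECM} = \mathrm{milk} \times (376\,f + 209\,p + 948)/3138$$

with fat $f$ and protein $p$ in percent. Metabolic heat production in heat
producing units (HPU, $\times 10^3$ W) follows the CIGR formula

$$\mathrm{HPU} = (5.6\,LW^{0.75} + 22\,\mathrm{ECM} +
  1.6\times10^{-3}\,\mathrm{DIP})/10^3,$$

and converts to a daily CO2 output at the fixed equivalent of 180 L/h per
HPU, so the tracer prediction is
$\mathrm{CH_4} = \mathrm{ratio} \times 180 \times \mathrm{HPU} \times 24$
L/day. Days in pregnancy (DIP) is approximated from days in milk via a
126-day open period (median calving interval 406 days minus 280 days
gestation), zero before 126 days in milk; we additionally cap DIP at the
280-day gestation length so extreme lactation lengths cannot extrapolate
beyond a biologically possible pregnancy.

The package also ships a bundle of twelve published linear prediction
equations (seven for daily CH4 in L/day, five for the methane conversion
factor MCF in J/100 J of gross energy intake) over the covariates live
weight, dry matter intake, ECM and the breath ratio, stored verbatim at
printed precision — they are treated as data, never re-derived at load
time.

Two numerical choices deserve note:

* **CH4 energy density.** MCF needs a volumetric-to-energy conversion that
  the equation tables do not state. We use 39.54 kJ/L (the Brouwer
  combustion constant); the worked example in the README (618 L/day at
  474 MJ/day giving 5.15 J/100 J) is consistent with this value, which is
  exposed as the `ch4_energy` parameter throughout.
* **Equation consistency.** Back-solving the ECM-based CH4 equations at
  their published covariate means gives values some 4–5% above the
  published mean emission, while the DMI-only equation is internally
  consistent. This is a property of the published table (its development
  panel's ECM mean cannot be recovered from the printed summary); we
  document it rather than adjust any coefficient.

## AMS trace processing

Traces are 1-Hz CH4/CO2 concentrations (ppm) during a milking visit.
Processing follows a fixed contract:

1. **Background**: the mean concentration over a 5-min ambient window
   adjacent to the visit. Where both a pre- and a post-visit window exist
   we average them; with only one, that one is used. Windows shorter than
   60 s are rejected.
2. **Head-position filter**: a second is retained only if its CO2 excess
   over background is at least 500 ppm (`co2_threshold`); below that the
   cow's muzzle is judged to be away from the sample inlet. Corrected CH4
   is clipped at zero.
3. **Visit ratio**: the ratio of the *means* of corrected CH4 and CO2 over
   retained seconds, not the mean of per-second ratios — the per-second
   quotient is unstable when the CO2 excess is near the threshold. The
   mean-of-ratios variant is available behind `ratio_method` for
   sensitivity analysis. A visit needs at least `min_retained = 60`
   retained seconds to be valid; one minute of breath stabilizes the ratio
   while discarding only drive-by visits.
4. **Eructation rate**: belches appear as sharp CH4 spikes, so the
   per-second ratio series over retained seconds (gaps bridged, not
   interpolated) is scanned for local maxima with topographic prominence of
   at least `max(0.25 × median positive ratio, 3 × robust noise SD)` and a
   minimum spacing of 10 s. The noise SD comes from the median absolute
   first difference, so a burst-rich series does not inflate its own
   threshold. Both knobs are configuration. The rate divides the peak
   count by the *retained* observation time, not the wall-clock visit
   length — otherwise head-away dropouts would deflate the rate for
   reasons unrelated to rumen physiology.
5. **Time after eating**: activity is logged in 10-min dominant-activity
   bins; the covariate is the interval from the end of the last eating bin
   at or before the visit to the visit start, in hours, flagged missing
   when no eating bin precedes the visit. Ties in dominant activity are
   resolved in favor of eating, which conservatively shortens the
   interval.

## Head-box calorimetry

The head box is vacuumed at a measured airflow (about 520 L/min at 0 °C,
1 atm). Per-second pure-gas emission is `flow/60 × (conc − bg) × 1e−6` L/s;
15-min totals extrapolate to daily emission by 1440/15 = 96. Durations more
than 60 s off the 900-s nominal are rescaled pro rata with a warning. A
CO2 recovery factor can divide the daily value, but it defaults to 1:
recovery tests near 100% are quality control, and silently rescaling data
by them is a choice the analyst should make explicitly. Flow is assumed
already normalized to 0 °C and 1 atm; no gas-law layer is implemented.
Each cow-period's four 15-min replicates are averaged, with the replicate
count recorded.

## Statistical layer

**Equation development** is ordinary least squares. We report the adjusted
$R^2$, coefficient standard errors, variance inflation factors computed
from their defining auxiliary regressions ($\mathrm{VIF}_j = 1/(1-R_j^2)$),
and RMSE as $\sqrt{SSE/(n-p-1)}$ — the regression root mean square error
convention of the major statistical packages, chosen over $\sqrt{SSE/n}$ so
that refits are comparable with the published tables. Rank-deficient
designs raise an explicit collinearity error rather than silently dropping
terms.

**The time-after-eating model** is a linear mixed model fitted by REML
(`lmerTest`): fixed effects of time after eating, diet, and their
interaction with the high-fiber diet as reference level; random intercepts
for Latin square and cow within square. Reference-level rows are kept in
the fixed-effect table as structural zeros so the table's shape is stable.
The residual covariance structure is chosen between independence and
compound symmetry within cow-period (an extra random intercept) by AIC on
ML fits, then refitted by REML — the two structures expressible without
modelling each visit sequence as a time series. Singular fits are returned
with a boundary flag, not an error: with two squares the square variance is
weakly identified and the boundary is an expected outcome. Setting
`random_effects = FALSE` fixes all variance components at zero, reducing
the model to OLS with the same term layout (used for oracle tests). With a
single diet level the model degrades to intercept + time.

**Adjustment to 0 h.** The fitted model predicts each visit's ratio at
zero hours after eating holding everything else at observed values:
`ratio − (β_time + β_time×diet) · t`. With the generating coefficients it
is the exact inverse of the synthetic decay, and the package tests verify
that.

**Evaluation** of predicted versus observed emissions uses regression
through the origin, slope $\sum xy / \sum x^2$, with the no-intercept
conventions for adjusted $R^2$ and RMSE (total sum of squares about zero,
$n-1$ degrees of freedom). A residual-versus-days-in-milk diagnostic with
a pointwise 95% prediction band flags lactation-stage bias — the HPU route
is expected to overpredict in early lactation, when body-fat mobilization
makes the fixed 180 L/h/HPU CO2 equivalent too high.

## What the generator emulates — and what it does not

`gen_cow_panel()` draws live weight, DMI, ECM and the breath ratio from a
truncated multivariate normal with the development panel's printed moments
(DMI 16.7 ± 3.68 kg/day, ECM 27.4 ± 6.78 kg/day, ratio 0.088 ± 0.0119) and
correlations (LW–DMI 0.51, LW–ECM 0.32, DMI–ECM 0.80), then simulates CH4
from a configurable true equation plus Gaussian noise. Live weight is
Normal(650, 50) truncated to [400, 900] kg — the panel's LW distribution
is not printed, and this is consistent with the feeding-trial cows
(647 ± 36.7 kg). The ratio's correlations with the other covariates are
likewise unprinted and default to zero. Days in milk is Normal(147, 69.1)
truncated at zero; gross energy intake is DMI × 18.5 MJ/kg DM, the gross
energy density of typical rations.

`gen_ams_visit()` builds a visit as background + breath plume (CO2 excess
2,500 ppm, comfortably above the 500-ppm filter) + eructation spikes +
analyzer noise, with contiguous head-away blocks (15% of an 8-min visit by
default) where CO2 sits at background. Eructations are a Poisson-like
renewal process with a hard 10-s refractory interval whose long-run rate
equals the configured 1.1/min exactly; amplitudes are lognormal. The CH4
channel is normalized so the pre-noise mean excess ratio over head-at-bin
seconds equals the cow's latent ratio — eructations redistribute CH4
within a visit rather than adding emission on top of it. The latent ratio
declines linearly with time after eating (−0.0034/h) with additive diet
offsets (LF −0.026, MF −0.016 vs HF).

The generator is deliberately simpler than reality in ways that bound what
green tests demonstrate: the true diurnal pattern of the ratio is
nonlinear (sinusoid-like over the day), whereas the generator is linear in
time after eating — matching the fitted model, so recovery tests validate
the fitting machinery, not the linearity assumption itself. Breath CO2
excess is constant rather than respiration-modulated; analyzer drift,
cross-sensitivity and visit-to-visit background shifts are absent; and
head-away blocks are independent of cow behavior. Passing tests therefore
show the pipeline recovers what this structure encodes, not that real
barn data are this clean.

`gen_headbox_measurement()` inverts the flux computation exactly: the
integrated pre-noise flux equals the injected daily emission divided
by 96, with per-second flow jitter around 520 L/min. Mass-balance tests
close to < 0.1% noise-free and within 1% under analyzer noise.

## Reproducibility and problem sizes

Every stochastic routine takes a seed (package default 20210930); reruns
under a fixed seed are bit-identical, and the pipeline log records the
seed and the config-file hash. The test suite's simulation sizes are
chosen to make Monte-Carlo error small relative to the tolerances they
check: moment checks on a 100,000-cow panel, OLS recovery on 20 panels of
10,000 cows, mixed-model recovery on the trial design scaled to 60 visits
per cow-period (1,080 visits), 100-replicate mass-balance and 40-visit
detector-recovery checks. The bundled demo pipeline (6 cows, 3 diets,
10 visits per cow-period at 1 Hz) runs end-to-end in well under a minute.

## Known limitations

* The 0-h adjustment transports the AMS ratio to "immediately after
  eating", which is when head-box measurements are made; residual
  attenuation of AMS-based predictions (diffusion around an open feed bin)
  is observable but not modelled.
* The per-second ratio used for eructation detection is computed on
  filtered seconds only; whether unfiltered seconds should contribute is
  an open measurement question, and the choice is configurable upstream of
  the detector.
* Only independent and compound-symmetric residual structures are
  offered for the mixed model; serially correlated within-visit-sequence
  structures would require per-cow time-series modelling.
* Equations are applied only within the covariate ranges the generator
  emulates; nothing guards extrapolation to, say, non-lactating animals.
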