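---
title: "Methods: probabilistic hazard assessment for mixed solvent exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic hazard assessment for mixed solvent exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solventrisk)
```

## The problem

Workers in shipyard paint shops inhale mixtures of organic solvents —
xylene, n-butanol, ethylbenzene, isobutyl alcohol, toluene and methyl
isobutyl ketone (MIBK) — at concentrations that vary enormously between
tasks, sites and days. A deterministic risk screen (one concentration, one
set of worker habits) hides that variability, so this package treats every
exposure factor as a random variable and propagates them by Monte Carlo
simulation to a *population distribution* of risk.

Risk is scored with the standard non-carcinogenic machinery:

* the **exposure concentration** for one simulated worker is
  $EC = \dfrac{C \times ET \times ED \times EF}{AT \times 24}$,
  with airborne concentration $C$ (mg/m³ after conversion from ppm), daily
  exposure time $ET$ (hours/day), exposure duration $ED$ (years), exposure
  frequency $EF$ (days/year), and a fixed averaging time $AT$ (days,
  converted to hours in the denominator so $EC$ keeps concentration units);
* the **hazard quotient** for one chemical is $HQ = EC / RfC$, where the
  reference concentration $RfC$ (mg/m³) is the inhalation toxicity
  threshold for the relevant endpoint; $HQ > 1$ flags unacceptable risk;
* the **hazard index** for a target organ is the dose-addition sum
  $HI = \sum HQ$ over the chemicals sharing that endpoint — here a
  *nervous-system* group (xylene, n-butanol, isobutyl alcohol, toluene)
  and a *developmental* group (MIBK, ethylbenzene).

Where a chemical has only an oral reference dose for an endpoint, it is
converted with the conventional adult defaults (70 kg body weight,
20 m³/day inhaled): $RfC = RfD \times 70 / 20$. A direct $RfC$ always
takes precedence over a converted $RfD$.

## Exposure-factor distributions

The default scenario encodes the 2018 Korean steel-shipbuilding
configuration:

| factor | family | parameters (arithmetic) | unit |
|---|---|---|---|
| $C$ (per chemical) | lognormal | published mean ± SD, e.g. xylene 19.66 ± 51.24 | ppm |
| $ET$ | logistic | mean 8, SD 1.11 | hours/day |
| $ED$ | exponential | mean 11 | years |
| $EF$ | lognormal | mean 268, SD 20.92 | days/year |
| $AT$ | fixed | 69,408 | days |

Two reconstruction decisions deserve emphasis.

**Units.** The source survey table labels $ET$ "hours/week" and $EF$
"days/week" while printing the values 8 and 268, which cannot both be
weekly quantities. We read $ET$ as hours/day, $EF$ as days/year and $ED$
as years, and express $AT$ in hours ($\times 24$): under this reading the
simulated median HQs land on the published ones (toluene ≈ 0.007 vs
7.36×10⁻³, MIBK ≈ 0.017 vs 1.63×10⁻²), and no other unit reading comes
close. $AT$ = 69,408 days is used verbatim as a fixed constant; it does
not correspond to a standard lifetime and we do not reinterpret it.

**Moment matching.** The raw monitoring records behind the published
concentration fits are not publicly available; only arithmetic means and
SDs are printed. `moments_to_spec()` therefore chooses parameters whose
*analytic* mean and SD equal the printed pair: for the lognormal
$\sigma^2 = \ln(1 + (s/m)^2)$, $\mu = \ln m - \sigma^2/2$; for the
logistic $\text{scale} = s\sqrt{3}/\pi$; the exponential keeps only the
mean (rate $= 1/11$, the printed SD 8.69 is retained as metadata since a
one-parameter family cannot honour both). A zero SD degenerates to a
point mass. The printed "±" values are treated as sample SDs, not native
scale parameters — an exponential with mean 11 cannot also have SD 8.69,
so the printed pairs must be sample moments.

**What moment matching cannot recover.** A lognormal moment-matched to
(mean, SD) is the *lightest-tailed* lognormal consistent with those
moments. The published upper percentiles imply effective log-scale sigmas
around 2.1 for xylene versus the 1.43 that moment matching yields, so our
reconstruction reproduces medians and the overall ranking well but sits
below the published 95th percentiles, and consequently above the
published exceedance percentile for the developmental HI (fewer extreme
MIBK/ethylbenzene draws reach 1). The acceptance suite asserts the bands
this reconstruction can honestly meet and leaves the tail-sensitive
checks failing rather than widening them; passing tests demonstrate
fidelity of the *pipeline*, not recovery of unpublished raw-data fits.

## Fitting from raw records

When raw measurements are available (real or synthetic),
`fit_mle()` estimates parameters by maximum likelihood — closed form for
normal, lognormal and exponential; numerical otherwise, started from the
moment-matched values with fixed tolerances so results are deterministic —
and `select_by_aic()` ranks candidate families by
$AIC = 2k - 2\log L$. Ties are broken by fewest parameters, then by
family name, making the selection invariant to candidate order. Families
whose support excludes the data are reported as inapplicable rather than
failing the whole selection. The default candidate set used in the
analysis scripts is {normal, lognormal, exponential, logistic}; gamma and
Weibull are available but excluded from family-recovery checks because
they nest the exponential (their extra parameter wins the likelihood-ratio
coin-flip against AIC's penalty in a nontrivial fraction of samples, which
is a property of AIC, not a defect of the fit).

## The Monte Carlo engine

`run_simulation()` (default $n$ = 10,000 iterations) draws, per
iteration, one worker's $ET$, $ED$, $EF$ *shared across chemicals* and
one concentration *per chemical, independently*. The shared-worker design
follows from the output structure being reconstructed: the hazard-index
sensitivity tables report a single exposure-duration row, which only
makes sense if all member chemicals see the same worker draws.
Within-worker correlation of concentrations across chemicals is not
modelled (each chemical's concentration distribution is specified
marginally), which will understate HI tail mass if co-exposures are
positively correlated in reality.

Numerical conventions, stated because results depend on them:

* ppm → mg/m³ conversion uses the 25 °C / 1 atm molar volume 24.45 L/mol
  (configurable); the assessment is unit-invariant once a convention is
  fixed.
* Draws are truncated to positive values by resampling (relevant only for
  the logistic $ET$, where the rejection rate at the default parameters
  is ~10⁻⁵); a spec whose truncation rejects more than half of its
  proposals is treated as a configuration error.
* Quantiles use linear interpolation between order statistics
  (`stats::quantile` type 7).
* The *exceedance percentile* is $100 \cdot P(X \le 1)$, with ties at the
  threshold counted as non-exceeding; it complements the percent of
  iterations above 1.
* Every run records its seed, iteration count and a configuration hash;
  no global RNG state leaks (the caller's RNG stream is restored).

## Sensitivity analysis

`sensitivity_report()` computes Spearman's rank correlation between each
input factor and an output, on the *same* draw matrix as the simulation
(no re-sampling). Rank correlation is used because HQ is a monotone
function of each factor but strongly non-linear in the concentration;
the coefficient is invariant under monotone transforms, so working on HQ
or log HQ gives identical values. Coefficients are banded on $|\rho|$
into negligible (< 0.20), low, moderate, high and very high (≥ 0.90)
categories; the bands are half-open on the right (the published ones,
quoted as 0–0.19 / 0.20–0.39 / …, leave the gaps between bands
undefined, so we close them consistently). For a chemical's HQ only that
chemical's concentration is reported; for an HI, every member
concentration. No p-values are attached — with $n$ = 10,000 draws,
significance is not the interesting question.

## Synthetic data generator

`generate_measurement_table()` produces a monitoring-record table with
the published per-chemical record counts (952 / 449 / 868 / 172 / 427 /
290; 3,158 rows) and lognormal concentrations from the default scenario;
`generate_worker_factors()` produces (ET, ED, EF) samples. Both are pure
functions of (configuration, seed). The generator emulates the
*marginal* statistical structure the analysis assumes — it does not
emulate twice-yearly sampling schedules, non-detects, measurement error,
within-worker correlation, or tail behaviour beyond the stated family,
so round-trip tests certify the fitting and simulation code, not the
realism of any particular workplace. Metadata fields (business ids,
process codes) are stable synthetic strings.

## Problem sizes and determinism

The packaged scenario runs 10,000 iterations (well under a second); the
test suite's property checks use 1,000–20,000 iterations per case and the
family-recovery check fits 3 × 100 samples of size 5,000. The
brute-force exceedance oracle enumerates all 81 combinations of
three-point factor distributions exactly, giving a ground truth that the
Monte Carlo engine must match within binomial error. All stochastic
tests fix their seeds; all simulation entry points take a seed argument
and never mutate the caller's RNG state.

## Known limitations

* Inhalation only — no dermal or ingestion routes, although paint work
  involves substantial skin exposure.
* Non-carcinogenic endpoints only; no cancer slope factors.
* No process stratification (spray vs brush painting are pooled, as in
  the source statistics).
* Concentration tails: see the moment-matching discussion above; upper
  percentiles of HQ/HI are lower bounds relative to heavier-tailed fits
  of the raw records.
* Reference values are taken as given; no uncertainty-factor arithmetic
  on the underlying no-observed-adverse-effect levels.
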