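# solventrisk

Probabilistic non-carcinogenic risk assessment for workers exposed to
mixtures of organic paint solvents, for occupational-hygiene and
exposure-science analysts. The package reconstructs, as a reusable and
tested pipeline, a Monte Carlo hazard assessment of six solvents used in
steel-shipbuilding paint shops (xylene, n-butanol, ethylbenzene, isobutyl
alcohol, toluene, MIBK).

Each Monte Carlo iteration simulates one worker and computes, per chemical,

```
EC = (C × ET × ED × EF) / (AT × 24)        exposure concentration, mg/m³
HQ = EC / RfC                              hazard quotient
HI = Σ HQ   over chemicals sharing a       hazard index (dose addition)
            target-organ endpoint
```

with airborne concentration `C` (lognormal, ppm, converted via molecular
weight and 24.45 L/mol), daily exposure time `ET` (logistic, h/day),
exposure duration `ED` (exponential, years), exposure frequency `EF`
(lognormal, days/year) and fixed averaging time `AT` (days). Missing
inhalation reference concentrations are filled from oral reference doses
via `RfC = RfD × 70 kg / 20 m³`. Outputs are percentile summaries, the
percentile at which HQ/HI crosses 1, and Spearman rank-correlation
sensitivity of every output to every input factor. A fitting layer
(moment matching from published summary statistics; maximum likelihood
plus minimum-AIC family selection from raw records) and a seeded
synthetic generator of monitoring records complete the pipeline — the
real monitoring data are not publicly available.

## Worked example

```r
library(solventrisk)

config <- load_scenario()          # packaged default: six chemicals, n = 10,000
sim <- run_scenario(config)
print(sim)
#> <hq_simulation> 10000 iterations, seed 1
#> Hazard quotients:
#>          chemical      toxicity      p25      p50     p75     p95 pct_gt_1
#>            xylene       nervous 0.701800 2.665000 9.38300 50.3100    68.87
#>         n-butanol       nervous 0.105400 0.372200 1.23500  5.9360    29.14
#>  isobutyl alcohol       nervous 0.020650 0.063610 0.18410  0.7123     2.71
#>           toluene       nervous 0.001957 0.006769 0.02191  0.1064     0.13
#>              mibk developmental 0.005124 0.016580 0.04719  0.2020     0.33
#>      ethylbenzene developmental 0.032730 0.117300 0.41290  2.3120    12.42
#> Hazard indices:
#>       toxicity     p25    p50     p75    p95 pct_gt_1
#>        nervous 1.27100 4.1010 11.8300 55.310    78.79
#>  developmental 0.05232 0.1589  0.4864  2.443    13.61
```

Reading the output: the median simulated worker has a xylene HQ of 2.7 —
almost three times the acceptable threshold — and 68.9% of simulated
workers exceed HQ = 1 for xylene, while toluene stays far below 1 even at
the 95th percentile. Summed over the neurotoxic solvents, 78.8% of
workers exceed HI = 1 (the HI crosses 1 already at the 21.2nd
percentile), so neurotoxic risk from the mixture is unacceptable for most
of the population; the developmental HI crosses 1 at the 86.4th
percentile.

```r
print(sensitivity_reports(sim)[["hi: nervous"]])
#> <sensitivity_report> HI nervous (n = 10000, seed 1)
#>                           factor    rho   strength
#>            concentration: xylene 0.6210   moderate
#>         concentration: n-butanol 0.1560 negligible
#>  concentration: isobutyl alcohol 0.0320 negligible
#>           concentration: toluene 0.0231 negligible
#>                exposure duration 0.6880   moderate
#>              daily exposure time 0.0882 negligible
#>               exposure frequency 0.0324 negligible
```

Nervous-system risk is driven by the xylene concentration and by how many
years a worker has painted; daily hours and working days per year barely
matter because they vary so little.

The `analysis/` directory runs the full study as four numbered scripts
(synthesize monitoring data → select distributions by AIC → simulate risk →
sensitivity), writing CSV tables under `results/`.

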