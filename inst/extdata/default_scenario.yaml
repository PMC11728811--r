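# Default scenario: six organic paint solvents in steel-shipbuilding
# painting, 2018 monitoring summary statistics.
# Concentrations: arithmetic mean/sd in ppm, moment-matched per family.
# Reference values: RfC mg/m3, RfD mg/kg/day, keyed by toxicity endpoint.
iterations: 10000
seed: 1
molar_volume: 24.45
at_days: 69408
chemicals:
  - name: xylene
    mw: 106.17
    rfc: {nervous: 0.1}
    rfd: {other: 0.2}
    count: 952
    concentration: {family: lognormal, mean: 19.66, sd: 51.24}
  - name: n-butanol
    mw: 74.12
    rfd: {nervous: 0.1}
    count: 449
    concentration: {family: lognormal, mean: 12.84, sd: 29.37}
  - name: ethylbenzene
    mw: 106.17
    rfc: {developmental: 1.0}
    rfd: {hepatic: 0.1, urinary: 0.1}
    count: 868
    concentration: {family: lognormal, mean: 9.44, sd: 25.26}
  - name: isobutyl alcohol
    mw: 74.12
    rfd: {nervous: 0.3}
    count: 172
    concentration: {family: lognormal, mean: 4.50, sd: 6.62}
  - name: toluene
    mw: 92.14
    rfc: {nervous: 5.0}
    rfd: {urinary: 0.08}
    count: 427
    concentration: {family: lognormal, mean: 2.50, sd: 5.40}
  - name: mibk
    mw: 100.16
    rfc: {developmental: 3.0}
    count: 290
    concentration: {family: lognormal, mean: 2.56, sd: 4.07}
factors:
  et: {family: logistic, mean: 8, sd: 1.11}      # hours/day
  ed: {family: exponential, mean: 11, sd: 8.69}  # years (sd kept as metadata)
  ef: {family: lognormal, mean: 268, sd: 20.92}  # days/year
groupings:
  nervous: [xylene, n-butanol, isobutyl alcohol, toluene]
  developmental: [mibk, ethylbenzene]
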