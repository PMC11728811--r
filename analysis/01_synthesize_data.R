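#!/usr/bin/env Rscript
# Step 1 — synthesize the workplace-monitoring data.
#
# The real 2018 monitoring records for the six paint solvents are not
# publicly available, so this step generates a synthetic stand-in with the
# same statistical structure: per-chemical lognormal concentrations
# moment-matched to the published means/SDs, at the published record counts
# (952 xylene, 449 n-butanol, 868 ethylbenzene, 172 isobutyl alcohol,
# 427 toluene, 290 MIBK; 3,158 rows in total), plus a worker-factor sample
# (daily hours, years of service, working days per year) from the
# survey-derived distributions.

library(solventrisk)

seed <- 20180101L
dir.create("results", showWarnings = FALSE)

records <- generate_measurement_table(seed = seed)
write.csv(records, "results/synthetic_measurements.csv", row.names = FALSE)

workers <- generate_worker_factors(n = 5000, seed = seed + 1L)
write.csv(workers, "results/synthetic_worker_factors.csv", row.names = FALSE)

cat(sprintf("wrote %d measurement records for %d chemicals\n",
            nrow(records), length(unique(records$chemical))))
print(aggregate(concentration_ppm ~ chemical, records,
                function(x) round(c(n = length(x), mean = mean(x), sd = sd(x)), 2)))
cat(sprintf("wrote %d worker-factor rows (ET mean %.2f h, ED mean %.1f y, EF mean %.0f d)\n",
            nrow(workers), mean(workers$et_hours_day), mean(workers$ed_years),
            mean(workers$ef_days_year)))
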