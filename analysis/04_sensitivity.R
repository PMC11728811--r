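#!/usr/bin/env Rscript
# Step 4 — which inputs drive the risk?
#
# Spearman rank correlations between every input factor and each output
# (per-chemical HQ, per-group HI), computed on the same draw matrix as
# step 3 (no re-sampling), with the conventional strength bands
# (negligible < 0.20 <= low < 0.40 <= moderate < 0.70 <= high < 0.90 <=
# very high).

library(solventrisk)

config <- load_scenario()
sim <- run_scenario(config)
reports <- sensitivity_reports(sim)

for (r in reports) print(r)

hi_n <- reports[["hi: nervous"]]$table
top <- hi_n[order(-abs(hi_n$rho)), ][1:2, ]
cat(sprintf("\nThe nervous-system HI is driven mainly by %s (rho = %.2f, %s) and %s (rho = %.2f, %s).\n",
            top$factor[1], top$rho[1], top$strength[1],
            top$factor[2], top$rho[2], top$strength[2]))
hi_d <- reports[["hi: developmental"]]$table
top_d <- hi_d[order(-abs(hi_d$rho)), ][1:2, ]
cat(sprintf("The developmental HI is driven mainly by %s (rho = %.2f) and %s (rho = %.2f).\n",
            top_d$factor[1], top_d$rho[1], top_d$factor[2], top_d$rho[2]))
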