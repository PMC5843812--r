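#!/usr/bin/env Rscript
# Full S-value table over the six experimental fill volumes, compared
# against the published full-physics Monte Carlo reference. Writes
# results/svalues_computed.csv and results/svalues_comparison.csv.

suppressPackageStartupMessages(library(vialdose))

cfg <- read_run_config(overrides = list(n_histories = 2e5, seed = 1L,
                                        output_dir = "results"))
out <- svalues_report(cfg, write = TRUE)

cmp <- out$comparison
alpha <- cmp[cmp$component == "alpha", ]
beta <- cmp[cmp$component == "beta", ]
cat(sprintf("Alpha S-values agree with the reference to %.1f %% at worst (e.g. Po-213 at 10 uL: %.0f vs 130 mGy/MBq.s).\n",
            100 * max(abs(alpha$rel_dev)),
            cmp$computed[cmp$nuclide == "Po-213" & cmp$component == "alpha" &
                           cmp$volume_uL == 10]))
cat(sprintf("Beta S-values carry the simplified electron transport's bias: within %.0f %% everywhere.\n",
            100 * max(abs(beta$rel_dev))))
cat("Gamma and Auger/IC rows use bundled effective lines and are indicative only\n",
    "(flagged approximate in the computed table).\n")
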