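#!/usr/bin/env Rscript
# Estimate binding parameters from the packaged synthetic series: the 4PL
# EC50 from the DARTS dose-response scenario (truth 280 uM) and the
# quadratic-isotherm Kd from the MST scenario (truth 204 uM), both with
# seeded bootstrap intervals. Writes results/binding_fits.json.

suppressPackageStartupMessages(library(dartsdeconv))
seed <- 1L

dcfg <- darts_dose_demo_config()
tgt <- target_spec("demo", c(1, 2), ec50 = dcfg$ec50, hill = dcfg$hill)
dtab <- simulate_dose_series(tgt, dcfg$doses, noise_sd = dcfg$noise_sd,
                             seed = seed)
dfit <- fit_4pl(dtab$dose, dtab$signal, n_boot = 500, boot_seed = seed)
print(dfit)

mcfg <- mst_demo_config()
mtab <- simulate_binding_trace(mcfg$kd, mcfg$protein_conc,
                               mcfg$ligand_series, mcfg$noise_sd,
                               seed = seed)
mfit <- fit_isotherm(mtab$ligand, mtab$fraction_bound,
                     protein_conc = mcfg$protein_conc, n_boot = 500,
                     boot_seed = seed)
print(mfit)

jsonlite::write_json(list(
  ec50_uM = dfit$ec50, hill = dfit$hill,
  ec50_ci = as.list(dfit$ci["ec50", ]),
  kd_uM = mfit$kd, kd_ci = as.list(mfit$ci["kd", ])
), "results/binding_fits.json", auto_unbox = TRUE, digits = NA)
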