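#!/usr/bin/env Rscript
# Deterministic MD-system bookkeeping for a membrane-embedded channel
# complex: KCl ion counts at 0.15 M with neutralization of a +4 solute in
# a ~16000-water box, DOPC:cholesterol 10:1 leaflet composition, and the
# 200-snapshot schedule over the final 10 ns of a 150 ns trajectory.

suppressPackageStartupMessages(library(dartsdeconv))

ions <- ion_counts(16000, 0.15, solute_net_charge = 4)
leaf <- leaflet_composition(110, c(10, 1))
sched <- snapshot_schedule(140, 150, 50)

cat(sprintf("Ions for 0.15 M KCl, 16000 waters, solute +4: %d K+ / %d Cl-\n",
            ions["n_cation"], ions["n_anion"]))
cat(sprintf("Leaflet at 10:1 with 110 DOPC: %d cholesterol\n",
            leaf["n_sterol"]))
cat(sprintf("Snapshots over (140, 150] ns at 50 ps: %d\n",
            sched$n_snapshots))

jsonlite::write_json(list(
  ions = as.list(ions), leaflet = as.list(leaf),
  n_snapshots = sched$n_snapshots
), "results/system_prep.json", auto_unbox = TRUE, digits = NA)
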