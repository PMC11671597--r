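# dartsdeconv

Label-free drug–target deconvolution by **DARTS** (drug affinity
responsive target stability) coupled to LC-MS/MS peptide evidence, as an
R analysis pipeline. DARTS exploits the fact that ligand binding
stabilizes a protein's fold: in a limited-proteolysis experiment the
drug-bound target resists degradation, and in the MS readout its peptide
**sequence coverage** collapses under protease alone but recovers when
the drug is present. The package is written for chemical-biology and
proteomics analysts who need the full chain from peptide evidence to a
ranked candidate list, plus the quantitative follow-up a target call
requires.

What it implements:

* **Synthetic experiment generator** — mock proteomes; three-condition
  (control / pronase / pronase+drug) peptide-evidence tables from a
  two-stage stochastic digest with a dose-dependently protected binding
  footprint on a planted target; noisy dose–response and
  binding-saturation series; toy protein–ligand snapshot ensembles.
  Everything is seed-deterministic via labelled substreams.
* **Coverage** — peptide-to-protein mapping (all occurrences, optional
  I/L equivalence) and interval-union percent coverage per protein per
  condition.
* **Candidate screen** — per-protein degradation
  (cov<sub>control</sub> − cov<sub>pronase</sub>), stabilization
  (cov<sub>drug</sub> − cov<sub>pronase</sub>) and fold change
  (cov<sub>drug</sub> / cov<sub>pronase</sub>); strict 5/5
  coverage-point filter cascade; stabilization-then-FC ranking; heatmap
  matrix export.
* **Binding fits** — four-parameter logistic
  y = bottom + (top − bottom)/(1 + (EC50/x)<sup>h</sup>) for the DARTS
  dose series, and the exact 1:1 quadratic isotherm
  f = ((P+L+K<sub>d</sub>) − √((P+L+K<sub>d</sub>)² − 4PL))/(2P) for
  saturation (MST-style) traces; Levenberg–Marquardt on log-scale
  parameters, seeded case-resampling bootstrap intervals.
* **Alanine-scanning ledger** — ensemble-averaged per-residue
  interaction energies (Coulomb with ε(r) = 4r plus 12-6
  Lennard-Jones), Cβ-truncation mutants on wild-type geometries, and
  ΔΔG = ΔG<sub>WT</sub> − ΔG<sub>Mut</sub> with hotspot tiers
  (destabilizing mutations are negative).
* **System-prep bookkeeping** — KCl ion counts with neutralization,
  leaflet lipid composition, snapshot schedules.

See `vignettes/darts-deconvolution.Rmd` for the models, parameter
defaults and their rationale.

## Worked example

The numbered scripts under `analysis/` run the workflow end to end and
write their tables under `results/`. Stage by stage:

```sh
Rscript analysis/01_simulate_darts.R
Rscript analysis/02_coverage_screen.R
Rscript analysis/03_binding_fits.R
Rscript analysis/04_alanine_scan.R
Rscript analysis/05_system_prep.R
```

`02_coverage_screen.R` prints the filter cascade and ranked candidates:

```
Cascade: 30 proteins -> 30 degraded > 5 points -> 5 stabilized > 5 points
Top candidates (rank, id, stabilization points, fold change):
 rank protein_id stabilization fold_change
    1      P0019     32.716049    3.012658
    2      P0030     10.020877    2.548387
```

The planted target (`P0019`) ranks first: its coverage dropped under
pronase and recovered by ~33 points with the drug — the DARTS
signature — while the runners-up are digestion noise near the 5-point
threshold. `03_binding_fits.R` fits the packaged synthetic series:

```
4PL dose-response fit (n = 7 points)
  bottom 0.02848  top 0.9412  EC50 290.5 uM  Hill 1.28  RSS 0.00232
  EC50 95% CI [197.4, 1043]
1:1 quadratic isotherm fit (n = 12 points)
  Kd 204.5 uM  amplitude 1.011  baseline -0.005485  RSS 0.00263
```

i.e. the fitted EC50 (290.5 µM) and Kd (204.5 µM) recover the generator
truths of 280 µM and 204 µM from noisy single series. The alanine scan
(`04_alanine_scan.R`) ranks the planted anionic contact residue as the
sole hotspot (ΔΔG ≈ −9.4 kcal/mol against a +1 ligand), and
`05_system_prep.R` prints the membrane-system arithmetic
(39 K⁺ / 43 Cl⁻ for 0.15 M KCl around a +4 solute in 16000 waters;
11 cholesterol per 110 DOPC at 10:1; 200 snapshots over the last 10 ns
at 50 ps).

The same chain runs as a single call from one config:

```r
library(dartsdeconv)
summary <- run_pipeline(default_run_config(seed = 1))
summary$cascade; summary$target_rank; summary$ec50; summary$kd
```

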