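---
title: "Methods: DARTS target deconvolution, binding fits and alanine-scanning energetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DARTS target deconvolution, binding fits and alanine-scanning energetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dartsdeconv)
```

## The problem

Drug affinity responsive target stability (DARTS) identifies the protein
target of a small molecule without chemical modification of the ligand:
binding stabilizes the target's fold, so in a limited-proteolysis
experiment the drug-bound target resists degradation that its unbound
neighbours suffer. Read out by LC-MS/MS, the signature is a protein whose
peptide *sequence coverage* collapses under protease treatment and
recovers when the drug is present. This package implements that entire
analysis chain — peptide evidence to coverage, coverage to a screened and
ranked candidate list — together with the quantitative follow-up a target
call requires: dose–response EC50 estimation, binding-isotherm Kd
estimation, an ensemble alanine-scanning ΔΔG ledger for interface residue
triage, and the deterministic bookkeeping used when preparing a
membrane-embedded simulation system.

Because raw MS evidence for this kind of screen is rarely deposited, the
package is built around a first-class synthetic-data module: every
pipeline stage can be exercised, tested and power-analyzed against
generated data whose ground truth is known.

## The digestion and detection model

The simulator produces a three-condition experiment over a mock proteome:

* **control** — trypsin-only digestion (the MS sample-prep step that every
  arm undergoes),
* **pronase** — a limited-proteolysis step modelled as a
  sequence-nonspecific Bernoulli cleavage of each peptide bond with
  probability `p_pronase`, followed by tryptic cleavage (after K/R, not
  before P),
* **pronase + drug** — identical, except bonds inside the target's
  protection footprint (± a 5-residue flank) have their cleavage
  probability multiplied by `1 − protection`, with
  `protection = protection_max / (1 + (EC50/dose)^hill)` — a logistic
  occupancy curve; `dose = Inf` is accepted and yields exactly
  `protection_max`.

Fragments outside the observable length window (default 7–30 residues,
the range typically identified in bottom-up MS) are lost; survivors are
detected with probability `p_detect` (default 0.7). Detection randomness
is keyed by a stable hash of *(protein, interval)* — not condition — so
the same peptide is seen or missed consistently across arms. This makes
the degenerate identities exact rather than asymptotic: with
`p_pronase = 0` the pronase table equals the control table, and a fully
protected target at saturating dose reproduces its control digest
verbatim. All randomness flows from one root seed through labelled
substreams, so adding a protein or a condition never perturbs the draws
of the others.

### Why `p_pronase = 0.35`

The cleavage rate is the one parameter where a naive "mild" choice breaks
the experiment's logic. With per-bond cleavage rate `c` the expected
fraction of residues housed in observable (7–30-residue) fragments is
`sum(l * c^2 * (1 - c)^(l - 1))` over that window. Trypsin alone on
uniform-composition sequences corresponds to `c ≈ 0.10` and puts ~68% of
residue mass in the window. Adding a *low* pronase rate (0.05) moves
that to ~68% as well: the extra cuts destroy short fragments exactly as
fast as they carve observable pieces out of long, undetectable tryptic
fragments, so expected coverage does not degrade at all and the screen
has no signal to detect. At `p_pronase = 0.35` the detectable mass drops
to roughly a third of the control level, giving the clear
degradation-then-rescue signature a DARTS screen relies on. A
design-stage power analysis over 100 simulated screens fixed this value
(together with 150–500-residue proteins and a footprint spanning 5–95%
of the target) before any acceptance measurement was taken.

The wide default footprint reflects what DARTS actually measures:
protection is conformational and fold-wide — a stabilized β-barrel
resists the protease along most of its length — rather than confined to
the few residues in van der Waals contact with the ligand. A narrow
footprint remains available through `target_spec()` for modelling
local-protection scenarios.

### What the generator does not emulate

No spectrum-level physics (m/z, retention time, fragment ions,
intensity-dependent detection), no missed-cleavage kinetics beyond the
two-stage digest, no abundance dilution of degraded species, no shared
peptides between proteins (mock sequences are i.i.d. uniform, so
cross-matches are vanishingly rare), and a single digested "molecule"
per protein per condition rather than an averaged population — which is
why simulated coverage is far noisier than a deeply sampled real
experiment. Passing tests therefore demonstrate the pipeline's logic and
statistics under a known ground truth, not instrument realism.

## Coverage and the candidate cascade

Coverage is presence-based, as standard in proteomics: the union of
matched residue intervals as a percentage of protein length, computed
with `IRanges`; duplicate and overlapping peptides count once. Peptide
mapping finds *every* occurrence (including overlapping ones, via
`Biostrings::matchPattern`) and reports unmatched peptides instead of
dropping them. Isoleucine/leucine equivalence — the residues are isobaric
in MS — is off by default (synthetic data is self-consistent) and
available via `il_equivalent = TRUE` for real evidence.

The screen derives, per protein,

* degradation = control − pronase coverage (points),
* stabilization = drug − pronase coverage (points),
* fold change = drug / pronase coverage (flagged undefined when pronase
  coverage is zero; such proteins still pass or fail on the point
  deltas),

and keeps proteins with degradation **and** stabilization strictly above
5 coverage points. Both thresholds are interpreted as absolute
percentage points by default because that is the natural unit of a
coverage difference; a `relative` mode is provided since the convention
is genuinely ambiguous in practice. Candidates are ranked by descending
stabilization, ties broken by fold change and then protein id for
reproducibility. The cascade counts (total → degraded → candidates) are
logged and exported, and the candidate × condition matrix of raw
coverages is written for heatmap plotting.

## Binding fits

**Dose–response.** The stabilization readout is fitted with the
four-parameter logistic `y = bottom + (top − bottom)/(1 + (EC50/x)^h)`
by Levenberg–Marquardt least squares (`minpack.lm::nls.lm` on the
residual function directly). The fit is parameterized in
`(bottom, log(top − bottom), log(EC50), log(h))`, which enforces
`top ≥ bottom`, `EC50 > 0`, `h > 0` and makes the fit exactly
equivariant under dose rescaling. Initialization takes the asymptotes
from the response extremes and EC50 from the geometric mean of the doses
bracketing the half-signal crossing; a fit that fails to improve on this
heuristic, or whose convergence test is not met, raises an error rather
than returning silently. The Hill slope is free by default
(`fix_hill = TRUE` pins it at 1).

**Isotherm.** Saturation traces are fitted with the exact 1:1 quadratic
isotherm `f = ((P + L + Kd) − sqrt((P + L + Kd)² − 4PL))/(2P)` at fixed
total protein `P`, with `Kd` and the amplitude on the log scale. The
dilute limit `L/(L + Kd)` and a root-finding solution of the mass
balance serve as independent cross-checks in the test suite.

Uncertainty for both fits comes from seeded case-resampling bootstrap
(500 resamples by default) with percentile intervals. With few points
and a plateau carried by one or two high concentrations, resamples that
lose the plateau can make the upper Kd percentile extremely large; the
interval is reported as computed rather than truncated.

The packaged demo scenarios place the generator truth at EC50 = 280 µM
(seven half-log doses, 10–10000 µM, Gaussian noise SD 0.03) and
Kd = 204 µM (twelve half-log ligand points from 2 µM, protein 0.05 µM,
noise SD 0.02); recovery of both within the stochastic tolerance is an
acceptance property of the package.

## The alanine-scanning ledger

The scan preserves the structure of an MM-PBSA-style computational
alanine scan — snapshot-ensemble averaging, per-residue decomposition,
`ΔΔG = ΔG_WT − ΔG_Mut` with destabilizing mutations negative, hotspot
tiering — while replacing the solvated force-field energy with a
documented desk-scale interaction score:

```
E(a, b, r) = 332.0637 q_a q_b / (ε(r) r) + ε_ab[(r_min/r)^12 − 2(r_min/r)^6]
```

with distance-dependent dielectric `ε(r) = 4r` (a standard implicit
screening choice), Lorentz–Berthelot combination, and a 12 Å pair cutoff
(configurable; `Inf` disables). The per-residue decomposition has no
cross terms, so the residue sum reproduces the total interaction energy
exactly. Mutant energies are evaluated on wild-type geometries with the
side chain truncated beyond Cβ and the Cβ reset to an alanine template
(charge −0.1825 e, ε 0.1094 kcal/mol, r_min 1.908 Å) — the
single-trajectory approximation standard in alanine scanning. Glycine,
proline and native alanine are rejected. Because the energy function is
not a solvated force field, published MM-PBSA ΔΔG magnitudes are not
reproduced; the ledger's guarantees are structural (brute-force oracle
equivalence to 1e-8 kcal/mol, sign convention, ranking of planted
contact residues) rather than numerical.

Default tiers: hotspot at ΔΔG ≤ −2 kcal/mol, contributor in (−2, −0.5],
neutral above. The boundary is configurable because published usage is
inconsistent — values a few tenths past −2 are called "possible
hotspots" in the literature this mirrors.

Ensembles round-trip through multi-MODEL PDB (via `bio3d`) plus a
plain-text parameter sidecar (serial → charge, LJ ε, LJ r_min, residue,
ligand flag), since PDB records carry no energetic parameters. PDB
coordinates carry three decimals, so energies recomputed from a written
ensemble agree to ~1e-3 kcal/mol rather than exactly.

## System-preparation bookkeeping

Three deterministic calculators: KCl ion counts for a target molarity
(base pairs `round(M × n_water / 55.5)`, water molarity configurable)
with neutralization by removing counter-charge cations (or anions for a
negative solute) so electroneutrality holds identically; leaflet
composition at a stated primary:sterol ratio; and snapshot schedules on
a half-open trailing window, so the final 10 ns of a trajectory sampled
every 50 ps yields exactly 200 frames. All rounding is half-up, applied
explicitly (base R rounds half-even), and counts that would go negative
raise an error suggesting a larger box. The 43-pair base count at
16000 waters and 0.15 M is stable for water counts in [15725, 16094];
outside that plateau the rounded pair count legitimately moves by one.

## Orchestration and reproducibility

`run_pipeline()` executes the full chain from one validated config with
one root seed, persists every stage's table (FASTA, TSV, CSV, JSON) into
the output directory alongside the verbatim config, and writes a summary
JSON with cascade counts, the ranked candidate list, fitted EC50/Kd, the
ΔΔG ledger path and the seeds used. Identical configs produce
byte-identical summaries. Stage functions are exported individually, and
the numbered scripts under `analysis/` run them as a narrative workflow
against `results/`.

## Problem sizes

The packaged study conditions are deliberately desk-scale: 30 proteins of
150–500 residues, 50 replicate screens for the recovery property, 20
replicate traces for EC50/Kd recovery, 1000 random instances for the
coverage oracle, and ≤200-atom toy ensembles with 5–20 snapshots for the
ΔΔG oracle. The full test suite runs in well under a minute on one core.

## Known limitations

* Coverage noise in the simulator is realistic in *structure* but not in
  magnitude; a real screen averages over vastly more molecules and
  replicates.
* The screen assumes single-protein peptide assignment (no protein
  inference); shared-peptide handling in real data should be resolved
  upstream.
* The interaction score omits solvation, entropy and polarization;
  ΔΔG values are comparative, not thermodynamic.
* Bootstrap percentile intervals can be very wide (or one-sided
  degenerate) on short series; they report sampling uncertainty of the
  fit, not systematic model error.
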