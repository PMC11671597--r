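# Simplified interaction energy and the alanine-scanning ddG ledger.

lj_off <- function(q) list(charge = q, lj_epsilon = 0, lj_rmin = 0)

test_that("pairwise energy reproduces hand-computed Coulomb arithmetic", {
  # +1/-1 at 3 A with eps(r) = 4r: 332.0637 * (-1) / (4 * 3 * 3)
  expect_equal(pairwise_energy(lj_off(1), lj_off(-1), 3),
               -332.0637 / 36)
  expect_equal(pairwise_energy(lj_off(0), lj_off(-1), 3), 0)
  expect_error(pairwise_energy(lj_off(1), lj_off(1), 0), "singularity")
})

test_that("12-6 term reaches its minimum -eps at r = rmin", {
  a <- list(charge = 0, lj_epsilon = 0.2, lj_rmin = 3.2)
  b <- list(charge = 0, lj_epsilon = 0.45, lj_rmin = 2.8)
  eps_ab <- sqrt(0.2 * 0.45)
  rmin_ab <- 3.0
  expect_equal(pairwise_energy(a, b, rmin_ab), -eps_ab)
  expect_gt(pairwise_energy(a, b, rmin_ab * 0.8), -eps_ab)
  expect_gt(0, pairwise_energy(a, b, rmin_ab * 1.2))
})

test_that("residue-ligand energy reduces to pairwise sums", {
  ens <- generate_toy_complex(2, atoms_per_residue = 6,
                              residue_charges = c(-1, 0), cb_charge = 0,
                              jitter_sd = 0, contact_distance = 3)
  fr <- ensemble_frame(ens, 1)
  # only charged atoms interact: residue 1 tip (-1) vs ligand (+1) at 3 A
  expect_equal(residue_ligand_energy(fr, 1, cutoff = Inf), -332.0637 / 36)
  # hand-built two-atom residue: sum of two pair terms
  at <- data.frame(serial = 1:3, name = c("CB", "CG", "C1"),
                   element = "C", residue_id = c(1, 1, 2),
                   residue_name = c("ASP", "ASP", "LIG"),
                   charge = c(-0.3, -0.7, 1), lj_epsilon = 0, lj_rmin = 0,
                   is_ligand = c(FALSE, FALSE, TRUE))
  xyz <- rbind(c(0, 0, 0), c(0, 0, 2), c(0, 3, 2))
  fr2 <- complex_frame(at, xyz)
  r1 <- sqrt(13)
  expect_equal(residue_ligand_energy(fr2, 1, cutoff = Inf),
               332.0637 * (-0.3) / (4 * r1^2) +
                 332.0637 * (-0.7) / (4 * 9))
  expect_error(residue_ligand_energy(fr2, 99), "unknown")
})

test_that("distance cutoff excludes remote pairs", {
  ens <- generate_toy_complex(3, residue_charges = c(-1, -1, -1),
                              cb_charge = 0, jitter_sd = 0, spacing = 40)
  fr <- ensemble_frame(ens, 1)
  expect_equal(residue_ligand_energy(fr, 3, cutoff = 12), 0)
  expect_lt(residue_ligand_energy(fr, 3, cutoff = Inf), 0)
})

test_that("alanine truncation edits only the targeted side chain", {
  ens <- generate_toy_complex(2, residue_charges = c(-1, 0),
                              jitter_sd = 0)
  fr <- ensemble_frame(ens, 1)
  mut <- mutate_to_ala(fr, 1)
  expect_equal(nrow(mut$atoms), nrow(fr$atoms) - 1) # CG dropped
  cb <- mut$atoms$name == "CB" & mut$atoms$residue_id == 1
  expect_equal(mut$atoms$charge[cb], -0.1825)
  # untouched residue and all coordinates preserved
  expect_identical(mut$atoms[mut$atoms$residue_id == 2, ],
                   fr$atoms[fr$atoms$residue_id == 2, ])
  # idempotent
  expect_identical(mutate_to_ala(mut, 1), mut)
  expect_error(mutate_to_ala(fr, 42), "unknown")
})

test_that("glycine, proline and alanine targets are rejected", {
  ens <- generate_toy_complex(1, residue_charges = 0, jitter_sd = 0)
  fr <- ensemble_frame(ens, 1)
  for (res in c("GLY", "PRO", "ALA")) {
    fr2 <- fr
    fr2$atoms$residue_name[fr2$atoms$residue_id == 1] <- res
    expect_error(mutate_to_ala(fr2, 1), "unsupported")
  }
})

test_that("anionic contact residue gives negative ddG; ensemble matches a
          single-frame hand computation", {
  ens <- generate_toy_complex(2, residue_charges = c(-1, 0), cb_charge = 0,
                              jitter_sd = 0, n_snapshots = 1,
                              contact_distance = 3)
  rec <- ensemble_ddg(ens, c(1, 2), cutoff = Inf)
  r1 <- rec[rec$residue_id == 1, ]
  # dG_WT: tip charge -1 at 3 A; dG_Mut: template CB charge at its distance
  fr <- ensemble_frame(ens, 1)
  dg_wt <- frame_interaction_energy(fr, cutoff = Inf)
  dg_mut <- frame_interaction_energy(mutate_to_ala(fr, 1), cutoff = Inf)
  expect_equal(r1$ddg, dg_wt - dg_mut)
  expect_lt(r1$ddg, 0)
  expect_gt(r1$dg_mut, r1$dg_wt)
  # destabilizing residue ranks first (records sorted ascending)
  expect_equal(rec$residue_id[1], 1)
})

test_that("ensemble ddG matches the brute-force all-pairs oracle", {
  ens <- generate_toy_complex(6, atoms_per_residue = 6, n_snapshots = 5,
                              residue_charges = c(-1, 0, 0.4, 0, -0.5, 0),
                              lj_epsilon = 0.12, lj_rmin = 1.91,
                              jitter_sd = 0.15, seed = 8)
  expect_lte(nrow(ens$atoms), 200)
  rec <- ensemble_ddg(ens, c(1, 3, 5), cutoff = 12)
  for (rid in c(1, 3, 5)) {
    expect_equal(rec$ddg[rec$residue_id == rid],
                 brute_ensemble_ddg(ens, rid, cutoff = 12),
                 tolerance = 1e-8)
  }
})

test_that("total interaction energy equals the per-residue decomposition", {
  ens <- generate_toy_complex(5, n_snapshots = 2,
                              residue_charges = c(-1, 0.3, 0, -0.2, 0.1),
                              lj_epsilon = 0.1, jitter_sd = 0.1, seed = 4)
  fr <- ensemble_frame(ens, 2)
  per_res <- vapply(1:5, residue_ligand_energy, numeric(1), frame = fr,
                    cutoff = 12)
  expect_equal(frame_interaction_energy(fr, cutoff = 12), sum(per_res))
})

test_that("a neutral ligand zeroes electrostatic ddG of charge-only residues", {
  ens <- generate_toy_complex(3, ligand_charge = 0,
                              residue_charges = c(-1, 0.5, 0),
                              cb_charge = 0, jitter_sd = 0)
  rec <- ensemble_ddg(ens, c(1, 2), cutoff = Inf)
  expect_equal(rec$ddg, c(0, 0))
})

test_that("duplicating snapshots leaves ddG unchanged", {
  ens <- generate_toy_complex(3, n_snapshots = 3,
                              residue_charges = c(-1, 0, 0.2),
                              jitter_sd = 0.2, seed = 5)
  dup <- complex_ensemble(ens$atoms, c(ens$coords, ens$coords))
  expect_equal(ensemble_ddg(ens, c(1, 3))$ddg,
               ensemble_ddg(dup, c(1, 3))$ddg)
})

test_that("hotspot tiers follow the documented ddG thresholds", {
  rec <- data.frame(residue_id = 1:5,
                    ddg = c(-20.77, -11.99, -2.14, -0.9, 0))
  tiers <- classify_hotspots(rec)$tier
  # -2.14 sits below the -2.0 default boundary, so it tiers as a hotspot
  expect_equal(as.character(tiers),
               c("hotspot", "hotspot", "hotspot", "contributor", "neutral"))
  # a stricter boundary demotes the borderline residues to contributors
  custom <- classify_hotspots(rec, hotspot_max = -10)$tier
  expect_equal(as.character(custom),
               c("hotspot", "hotspot", "contributor", "contributor",
                 "neutral"))
})

test_that("PDB ensemble plus parameter sidecar round-trips", {
  ens <- generate_toy_complex(3, n_snapshots = 4,
                              residue_charges = c(-1, 0, 0.25),
                              lj_epsilon = 0.1, jitter_sd = 0.2, seed = 6)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  par <- withr::local_tempfile(fileext = ".tsv")
  write_ensemble_pdb(ens, pdb, par)
  back <- read_ensemble_pdb(pdb, par)
  expect_equal(back$n_snapshots, 4)
  expect_equal(back$atoms$charge, ens$atoms$charge)
  expect_equal(back$atoms$is_ligand, ens$atoms$is_ligand)
  # PDB coordinates carry 3 decimals; energies agree to that precision
  expect_equal(ensemble_ddg(back, 1)$ddg, ensemble_ddg(ens, 1)$ddg,
               tolerance = 1e-3)
})
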