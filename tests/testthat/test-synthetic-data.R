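# Synthetic-data generators: determinism, degenerate digestion regimes,
# curve-series identities, toy-complex construction.

test_that("proteome generation is seed-deterministic and respects bounds", {
  one <- generate_proteome(proteome_spec(1, c(10, 10), seed = 7))
  expect_equal(nchar(one$sequence), 10)
  expect_identical(one, generate_proteome(proteome_spec(1, c(10, 10),
                                                        seed = 7)))
  many <- generate_proteome(proteome_spec(100, c(50, 500), seed = 3))
  expect_equal(nrow(many), 100)
  expect_true(all(nchar(many$sequence) >= 50 & nchar(many$sequence) <= 500))
  expect_true(all(strsplit(paste(many$sequence, collapse = ""), "")[[1]]
                  %in% c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")))
  # substreams: enlarging the proteome leaves existing proteins unchanged
  expect_identical(many$sequence[1:20],
                   generate_proteome(proteome_spec(20, c(50, 500),
                                                   seed = 3))$sequence)
  expect_error(proteome_spec(0), "n_proteins")
  expect_error(proteome_spec(5, c(5, 50)), "length_range")
})

test_that("proteome FASTA writer round-trips with the reader", {
  prot <- generate_proteome(proteome_spec(5, c(40, 60), seed = 11))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_proteome_fasta(prot, path)
  expect_identical(read_proteome_fasta(path), prot)
})

test_that("zero pronase activity reproduces the control digest", {
  sc <- demo_triplet(5, n_proteins = 5)
  params0 <- digestion_params(p_pronase = 0, seed = 5)
  ev <- simulate_darts_triplet(sc$proteome, sc$target, 100, params0)
  ctrl <- ev[ev$condition == "control", -1]
  pron <- ev[ev$condition == "pronase", -1]
  rownames(ctrl) <- rownames(pron) <- NULL
  expect_identical(pron, ctrl)
})

test_that("total degradation leaves no detectable peptide", {
  sc <- demo_triplet(6, n_proteins = 5)
  params1 <- digestion_params(p_pronase = 1, seed = 6)
  tgt <- target_spec(sc$target$protein_id, sc$target$footprint,
                     protection_max = 0, ec50 = 280, hill = 1)
  ev <- simulate_darts_triplet(sc$proteome, tgt, 100, params1)
  expect_equal(nrow(ev[ev$condition == "pronase", ]), 0)
  expect_equal(nrow(ev[ev$condition == "pronase_drug", ]), 0)
})

test_that("full protection at saturating dose restores the control digest", {
  prot <- generate_proteome(proteome_spec(4, c(100, 200), seed = 9))
  tid <- prot$id[1]
  tlen <- nchar(prot$sequence[prot$id == tid])
  tgt <- target_spec(tid, c(1, tlen), protection_max = 1, ec50 = 280,
                     hill = 1)
  ev <- simulate_darts_triplet(prot, tgt, Inf, digestion_params(seed = 9))
  ctrl <- ev[ev$condition == "control" & ev$protein_id == tid, -1]
  drug <- ev[ev$condition == "pronase_drug" & ev$protein_id == tid, -1]
  rownames(ctrl) <- rownames(drug) <- NULL
  expect_identical(drug, ctrl)
})

test_that("triplet simulation validates its inputs and is deterministic", {
  sc <- demo_triplet(2, n_proteins = 3)
  expect_error(simulate_darts_triplet(sc$proteome,
                                      target_spec("NOPE", c(1, 10)),
                                      100, sc$params), "not found")
  again <- simulate_darts_triplet(sc$proteome, sc$target, Inf, sc$params)
  expect_identical(again, sc$evidence)
})

test_that("target coverage ordering holds in expectation across replicates", {
  covs <- t(vapply(1:50, function(s) {
    sc <- demo_triplet(s, n_proteins = 4)
    cov <- coverage_table(sc$proteome, sc$evidence)
    st <- compute_screen_stats(cov)
    unlist(st[st$protein_id == sc$target$protein_id,
              c("cov_control", "cov_pronase", "cov_drug")])
  }, numeric(3)))
  m <- colMeans(covs)
  expect_gt(m["cov_control"], m["cov_drug"])
  expect_gt(m["cov_drug"], m["cov_pronase"])
})

test_that("non-target proteins show no systematic drug-arm coverage shift", {
  diffs <- unlist(lapply(1:40, function(s) {
    sc <- demo_triplet(s, n_proteins = 4)
    st <- compute_screen_stats(coverage_table(sc$proteome, sc$evidence))
    st$stabilization[st$protein_id != sc$target$protein_id]
  }))
  expect_lt(abs(mean(diffs)), 2 * stats::sd(diffs) / sqrt(length(diffs)) + 1)
})

test_that("noiseless dose series follows the 4PL formula exactly", {
  tgt <- target_spec("X", c(1, 5), protection_max = 1, ec50 = 280, hill = 1)
  d <- simulate_dose_series(tgt, doses = c(10, 280, 1e5), noise_sd = 0)
  expect_equal(d$signal[2], 0.5) # dose = ec50 gives the midpoint
  expect_equal(d$signal, fourpl(d$dose, 0, 1, 280, 1))
  expect_gt(0.005, 1 - d$signal[3]) # saturating dose approaches the top
  expect_error(simulate_dose_series(tgt, doses = c(-1, 10)), "positive")
})

test_that("noisy dose series is seed-deterministic", {
  tgt <- target_spec("X", c(1, 5), ec50 = 280, hill = 1)
  a <- simulate_dose_series(tgt, 10 * sqrt(10)^(0:6), noise_sd = 0.03,
                            seed = 4)
  b <- simulate_dose_series(tgt, 10 * sqrt(10)^(0:6), noise_sd = 0.03,
                            seed = 4)
  expect_identical(a, b)
})

test_that("binding trace obeys the dilute-limit and zero-ligand identities", {
  tr <- simulate_binding_trace(204, 204e-6, c(0, 204), noise_sd = 0)
  expect_equal(tr$fraction_bound[1], 0)
  expect_equal(tr$fraction_bound[2], 0.5, tolerance = 1e-3)
  expect_error(simulate_binding_trace(-1, 1, c(1, 2)), "kd")
  expect_error(simulate_binding_trace(1, 1, c(-5)), "ligand")
})

test_that("toy complex with zero jitter has identical snapshots", {
  ens <- generate_toy_complex(3, n_snapshots = 4, jitter_sd = 0)
  expect_identical(ens$coords[[1]], ens$coords[[4]])
  ens2 <- generate_toy_complex(3, n_snapshots = 4, jitter_sd = 0.2, seed = 2)
  expect_false(identical(ens2$coords[[1]], ens2$coords[[2]]))
  expect_identical(ens2$coords,
                   generate_toy_complex(3, n_snapshots = 4, jitter_sd = 0.2,
                                        seed = 2)$coords)
})

test_that("fully neutral toy residues give zero interaction energy", {
  ens <- generate_toy_complex(2, ligand_charge = 0, residue_charges = 0,
                              cb_charge = 0, jitter_sd = 0)
  fr <- ensemble_frame(ens, 1)
  expect_equal(frame_interaction_energy(fr, cutoff = Inf), 0)
})
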