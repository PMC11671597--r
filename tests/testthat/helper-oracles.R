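# Independent oracles used across test files.

# Brute-force residue-mask coverage: the reference implementation for the
# interval-union statistic.
mask_coverage <- function(protein_length, matches) {
  mask <- logical(protein_length)
  for (i in seq_len(nrow(matches))) {
    mask[matches$start[i]:matches$end[i]] <- TRUE
  }
  100 * sum(mask) / protein_length
}

# Brute-force receptor-ligand interaction energy of a frame: direct double
# loop over atom pairs with the Coulomb + 12-6 LJ formula written out
# independently of the package internals.
brute_frame_energy <- function(frame, cutoff = 12) {
  at <- frame$atoms
  xyz <- frame$coords
  rec <- which(!at$is_ligand)
  lig <- which(at$is_ligand)
  e <- 0
  for (i in rec) {
    for (j in lig) {
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (r > cutoff) next
      e <- e + 332.0637 * at$charge[i] * at$charge[j] / (4 * r * r)
      epsij <- sqrt(at$lj_epsilon[i] * at$lj_epsilon[j])
      if (epsij > 0) {
        rm <- (at$lj_rmin[i] + at$lj_rmin[j]) / 2
        e <- e + epsij * ((rm / r)^12 - 2 * (rm / r)^6)
      }
    }
  }
  e
}

# Brute-force ensemble ddG for one residue: all pairs, all frames, with an
# independently coded alanine truncation.
brute_ensemble_ddg <- function(ensemble, residue_id, cutoff = 12) {
  backbone <- c("N", "CA", "C", "O", "OXT", "H", "HA")
  e_wt <- e_mut <- numeric(ensemble$n_snapshots)
  for (f in seq_len(ensemble$n_snapshots)) {
    fr <- ensemble_frame(ensemble, f)
    e_wt[f] <- brute_frame_energy(fr, cutoff)
    at <- fr$atoms
    rows <- which(!at$is_ligand & at$residue_id == residue_id)
    drop <- rows[!(at$name[rows] %in% c(backbone, "CB"))]
    cb <- rows[at$name[rows] == "CB"]
    at$charge[cb] <- -0.1825
    at$lj_epsilon[cb] <- 0.1094
    at$lj_rmin[cb] <- 1.9080
    keep <- setdiff(seq_len(nrow(at)), drop)
    mfr <- complex_frame(at[keep, , drop = FALSE],
                         fr$coords[keep, , drop = FALSE])
    e_mut[f] <- brute_frame_energy(mfr, cutoff)
  }
  mean(e_wt) - mean(e_mut)
}

# Root-finding oracle for the 1:1 binding mass balance: solve
# Kd * C = (P - C)(L - C) for the complex concentration C.
rootfind_fraction_bound <- function(L, P, kd) {
  if (L == 0) return(0)
  f <- function(C) (P - C) * (L - C) - kd * C
  C <- stats::uniroot(f, lower = 0, upper = min(P, L),
                      tol = 1e-14)$root
  C / P
}

# Small deterministic triplet scenario shared by screen tests.
demo_triplet <- function(seed, n_proteins = 30, lens = c(150, 500),
                         protection_max = 0.8, dose = Inf) {
  prot <- generate_proteome(proteome_spec(n_proteins, lens, seed = seed))
  tid <- prot$id[which.max(nchar(prot$sequence))]
  tlen <- nchar(prot$sequence[prot$id == tid])
  tgt <- target_spec(tid, c(max(1, round(0.05 * tlen)), round(0.95 * tlen)),
                     protection_max = protection_max, ec50 = 280, hill = 1)
  params <- digestion_params(seed = seed)
  list(proteome = prot, target = tgt, params = params,
       evidence = simulate_darts_triplet(prot, tgt, dose, params))
}
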