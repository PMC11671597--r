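# Ensemble alanine-scanning ledger with a simplified interaction-energy
# function: Coulomb electrostatics with a distance-dependent dielectric
# eps(r) = 4r plus a 12-6 Lennard-Jones term under Lorentz-Berthelot
# combination. Mutant energies are evaluated on wild-type geometries
# (single-trajectory approximation); ddG = dG_WT - dG_Mut, so a mutation
# that destabilizes binding yields a negative ddG.

COULOMB_KCAL <- 332.0637 # kcal*A/(mol*e^2)

# Built-in alanine C-beta template (aliphatic carbon parameters typical of
# mainstream protein force fields).
ALA_CB_TEMPLATE <- list(charge = -0.1825, lj_epsilon = 0.1094,
                        lj_rmin = 1.9080)

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT", "H", "HA")

#' Pairwise atom-atom interaction energy
#'
#' `E = 332.0637 q_a q_b / (eps(r) r) + eps_ab [ (rmin_ab/r)^12 -
#' 2 (rmin_ab/r)^6 ]` with distance-dependent dielectric `eps(r) = 4r`,
#' geometric-mean well depth `eps_ab` and arithmetic-mean `rmin_ab`
#' (Lorentz-Berthelot).
#'
#' @param a,b Atom records: lists (or one-row data frames) with fields
#'   `charge` (e), `lj_epsilon` (kcal/mol), `lj_rmin` (A).
#' @param r Interatomic distance (A), > 0.
#' @return Energy in kcal/mol.
#' @export
#' @examples
#' cation <- list(charge = 1, lj_epsilon = 0, lj_rmin = 0)
#' anion <- list(charge = -1, lj_epsilon = 0, lj_rmin = 0)
#' pairwise_energy(cation, anion, 3.0) # -332.0637 / 36
pairwise_energy <- function(a, b, r) {
  if (any(r <= 0)) stop("interatomic distance must be positive (singularity)",
                        call. = FALSE)
  e_coul <- COULOMB_KCAL * a$charge * b$charge / (4 * r * r)
  eps_ab <- sqrt(a$lj_epsilon * b$lj_epsilon)
  e_lj <- if (eps_ab > 0) {
    rmin_ab <- (a$lj_rmin + b$lj_rmin) / 2
    sr6 <- (rmin_ab / r)^6
    eps_ab * (sr6^2 - 2 * sr6)
  } else 0
  e_coul + e_lj
}

# Vectorized energy between one atom-parameter set and many: used
# internally for frame sums. q, eps, rmin are vectors over atoms of one
# group; returns total energy of group A atoms against group B atoms given
# the full distance matrix.
group_energy <- function(qa, epsa, rmina, qb, epsb, rminb, dmat, cutoff) {
  if (any(dmat <= 0)) stop("zero interatomic distance (singularity)",
                           call. = FALSE)
  within <- dmat <= cutoff
  qq <- outer(qa, qb)
  e_coul <- COULOMB_KCAL * qq / (4 * dmat * dmat)
  eps_ab <- outer(sqrt(epsa), sqrt(epsb))
  rmin_ab <- outer(rmina, rminb, function(x, y) (x + y) / 2)
  sr6 <- (rmin_ab / dmat)^6
  e_lj <- eps_ab * (sr6^2 - 2 * sr6)
  e_lj[eps_ab == 0] <- 0
  sum((e_coul + e_lj)[within])
}

#' Construct a snapshot frame
#'
#' @param atoms Atom table: data frame with columns `serial`, `name`,
#'   `element`, `residue_id`, `residue_name`, `charge`, `lj_epsilon`,
#'   `lj_rmin`, `is_ligand`.
#' @param coords Numeric matrix (n_atoms x 3) of coordinates in A.
#' @return Object of class `complex_frame`.
#' @export
complex_frame <- function(atoms, coords) {
  coords <- as.matrix(coords)
  stopifnot(nrow(atoms) == nrow(coords), ncol(coords) == 3)
  need <- c("serial", "name", "residue_id", "residue_name", "charge",
            "lj_epsilon", "lj_rmin", "is_ligand")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(atoms$lj_epsilon < 0)) stop("lj_epsilon must be >= 0",
                                      call. = FALSE)
  if (any(atoms$lj_epsilon > 0 & atoms$lj_rmin <= 0)) {
    stop("lj_rmin must be positive where lj_epsilon > 0", call. = FALSE)
  }
  structure(list(atoms = atoms, coords = coords), class = "complex_frame")
}

#' Construct a snapshot ensemble over a fixed atom roster
#'
#' @param atoms Atom table (see [complex_frame()]).
#' @param coords_list List of coordinate matrices, one per snapshot, all
#'   over the same atom roster.
#' @param interval_ps Snapshot spacing metadata (ps).
#' @return Object of class `complex_ensemble`.
#' @export
complex_ensemble <- function(atoms, coords_list, interval_ps = 50) {
  if (length(coords_list) < 1) stop("ensemble needs >= 1 snapshot",
                                    call. = FALSE)
  frames <- lapply(coords_list, function(xyz) complex_frame(atoms, xyz))
  structure(list(atoms = atoms, coords = lapply(frames, `[[`, "coords"),
                 n_snapshots = length(coords_list),
                 interval_ps = interval_ps),
            class = "complex_ensemble")
}

#' Extract one frame of an ensemble
#'
#' @param ensemble A [complex_ensemble()].
#' @param i Snapshot index.
#' @return A `complex_frame`.
#' @export
ensemble_frame <- function(ensemble, i) {
  complex_frame(ensemble$atoms, ensemble$coords[[i]])
}

frame_distances <- function(frame, rows_a, rows_b) {
  xa <- frame$coords[rows_a, , drop = FALSE]
  xb <- frame$coords[rows_b, , drop = FALSE]
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)
  sqrt(pmax(d2, 0))
}

#' Residue-ligand interaction energy in one frame
#'
#' Sum of [pairwise_energy()] over all (residue atom, ligand atom) pairs
#' within `cutoff` (set `cutoff = Inf` to disable truncation).
#'
#' @param frame A [complex_frame()].
#' @param residue_id Receptor residue id.
#' @param cutoff Pair-distance cutoff (A), default 12.
#' @return Energy in kcal/mol.
#' @export
residue_ligand_energy <- function(frame, residue_id, cutoff = 12) {
  at <- frame$atoms
  rows_r <- which(!at$is_ligand & at$residue_id == residue_id)
  rows_l <- which(at$is_ligand)
  if (length(rows_r) == 0) stop("unknown receptor residue id: ", residue_id,
                                call. = FALSE)
  if (length(rows_l) == 0) stop("frame contains no ligand atoms",
                                call. = FALSE)
  dmat <- frame_distances(frame, rows_r, rows_l)
  group_energy(at$charge[rows_r], at$lj_epsilon[rows_r],
               at$lj_rmin[rows_r], at$charge[rows_l],
               at$lj_epsilon[rows_l], at$lj_rmin[rows_l], dmat, cutoff)
}

#' Total receptor-ligand interaction energy of a frame
#'
#' Exactly the sum of [residue_ligand_energy()] over all receptor
#' residues (the per-residue decomposition has no cross terms).
#'
#' @inheritParams residue_ligand_energy
#' @return Energy in kcal/mol.
#' @export
frame_interaction_energy <- function(frame, cutoff = 12) {
  res_ids <- unique(frame$atoms$residue_id[!frame$atoms$is_ligand])
  sum(vapply(res_ids, residue_ligand_energy, numeric(1), frame = frame,
             cutoff = cutoff))
}

#' Truncate a residue to alanine in a frame
#'
#' Removes side-chain atoms beyond C-beta, resets the C-beta charge and
#' Lennard-Jones parameters to the built-in alanine template, and leaves
#' backbone atoms and all coordinates untouched (single-trajectory
#' approximation). Glycine (no C-beta), proline (cyclic backbone) and
#' native alanine are rejected. Applying the mutation twice is a no-op.
#'
#' @param frame A [complex_frame()].
#' @param residue_id Receptor residue id to mutate.
#' @return The mutated `complex_frame`.
#' @export
mutate_to_ala <- function(frame, residue_id) {
  at <- frame$atoms
  rows <- which(!at$is_ligand & at$residue_id == residue_id)
  if (length(rows) == 0) stop("unknown receptor residue id: ", residue_id,
                              call. = FALSE)
  resname <- unique(at$residue_name[rows])[1]
  if (resname %in% c("GLY", "PRO", "ALA")) {
    stop("alanine truncation unsupported for ", resname, call. = FALSE)
  }
  if (!"CB" %in% at$name[rows]) {
    stop("residue ", residue_id, " has no CB atom; cannot truncate",
         call. = FALSE)
  }
  drop <- rows[!(at$name[rows] %in% c(BACKBONE_ATOMS, "CB"))]
  cb <- rows[at$name[rows] == "CB"]
  at$charge[cb] <- ALA_CB_TEMPLATE$charge
  at$lj_epsilon[cb] <- ALA_CB_TEMPLATE$lj_epsilon
  at$lj_rmin[cb] <- ALA_CB_TEMPLATE$lj_rmin
  keep <- setdiff(seq_len(nrow(at)), drop)
  complex_frame(at[keep, , drop = FALSE],
                frame$coords[keep, , drop = FALSE])
}

#' Ensemble alanine-scanning ddG ledger
#'
#' For each requested residue, computes the mean (over snapshots) total
#' receptor-ligand interaction energy of the wild-type complex (dG_WT)
#' and of the alanine-truncated complex (dG_Mut) and reports
#' `ddG = dG_WT - dG_Mut`; records are sorted ascending so the most
#' destabilizing mutation comes first.
#'
#' @param ensemble A [complex_ensemble()].
#' @param residue_ids Receptor residue ids to scan.
#' @param cutoff Pair-distance cutoff (A) for the energy sums.
#' @return Data frame `residue_id`, `residue_name`, `dg_wt`, `dg_mut`,
#'   `ddg` (kcal/mol), sorted by `ddg` ascending.
#' @export
ensemble_ddg <- function(ensemble, residue_ids, cutoff = 12) {
  stopifnot(inherits(ensemble, "complex_ensemble"))
  if (ensemble$n_snapshots < 1) stop("empty ensemble", call. = FALSE)
  frames <- lapply(seq_len(ensemble$n_snapshots), ensemble_frame,
                   ensemble = ensemble)
  dg_wt <- mean(vapply(frames, frame_interaction_energy, numeric(1),
                       cutoff = cutoff))
  recs <- lapply(residue_ids, function(rid) {
    mut_frames <- lapply(frames, mutate_to_ala, residue_id = rid)
    dg_mut <- mean(vapply(mut_frames, frame_interaction_energy, numeric(1),
                          cutoff = cutoff))
    at <- ensemble$atoms
    rname <- at$residue_name[!at$is_ligand & at$residue_id == rid][1]
    data.frame(residue_id = rid, residue_name = rname, dg_wt = dg_wt,
               dg_mut = dg_mut, ddg = dg_wt - dg_mut,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  out <- out[order(out$ddg, out$residue_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tier ddG records into hotspots, contributors and neutral residues
#'
#' Defaults: hotspot when `ddg <= -2.0` kcal/mol, contributor when
#' `-2.0 < ddg <= -0.5`, neutral otherwise.
#'
#' @param records Data frame from [ensemble_ddg()].
#' @param hotspot_max Upper ddG bound (inclusive) for the hotspot tier.
#' @param contributor_max Upper ddG bound (inclusive) for the contributor
#'   tier.
#' @return `records` with an added `tier` factor column.
#' @export
#' @examples
#' classify_hotspots(data.frame(residue_id = 1:3,
#'                              ddg = c(-20.77, -2.14, 0)))
classify_hotspots <- function(records, hotspot_max = -2.0,
                              contributor_max = -0.5) {
  stopifnot(hotspot_max <= contributor_max)
  tier <- ifelse(records$ddg <= hotspot_max, "hotspot",
                 ifelse(records$ddg <= contributor_max, "contributor",
                        "neutral"))
  records$tier <- factor(tier, levels = c("hotspot", "contributor",
                                          "neutral"))
  records
}

#' Write a ddG ledger to CSV
#'
#' @param records (Tiered) ddG data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ddg_ledger <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
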