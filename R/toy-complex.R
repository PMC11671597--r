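# Toy protein-ligand coordinate ensembles for the alanine-scanning module,
# plus multi-MODEL PDB + parameter-sidecar round-trip I/O.

TOY_ATOM_NAMES <- c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "CZ", "CH")

#' Generate a toy protein-ligand snapshot ensemble
#'
#' Receptor residues are laid out on a line with `spacing` A between
#' residue origins; each residue's atoms are stacked 1.5 A apart along z
#' and named `N, CA, C, O, CB, CG, ...`. The last (tip) atom of each
#' residue carries that residue's side-chain charge; the C-beta carries
#' the alanine-template charge by default so that alanine truncation only
#' removes the atoms beyond C-beta. A single-atom ligand is placed
#' `contact_distance` A from the tip atom of `contact_residue`. Snapshots
#' add Gaussian positional jitter to the base coordinates, each snapshot
#' from its own seeded substream.
#'
#' @param n_residues Number of receptor residues (>= 1).
#' @param atoms_per_residue Atoms per residue (>= 1; >= 5 gives a C-beta
#'   and makes residues mutable). Default 6.
#' @param ligand_charge Ligand atom charge (e). Default +1
#'   (monoprotonated cationic ligand).
#' @param n_snapshots Number of snapshots (>= 1).
#' @param seed Integer seed.
#' @param residue_charges Numeric vector (recycled to `n_residues`) of
#'   side-chain tip charges; default 0.
#' @param contact_residue Residue whose tip the ligand is placed against.
#' @param contact_distance Ligand-tip distance (A), default 3.
#' @param spacing Distance between residue origins (A), default 8.
#' @param jitter_sd Gaussian jitter SD (A) applied per coordinate per
#'   snapshot; 0 gives identical snapshots.
#' @param lj_epsilon,lj_rmin Lennard-Jones well depth (kcal/mol) and
#'   minimum-energy distance (A) applied to every receptor atom and to the
#'   ligand; `lj_epsilon = 0` switches Lennard-Jones off.
#' @param cb_charge Charge placed on each residue's C-beta; defaults to
#'   the alanine template value.
#' @param interval_ps Snapshot-spacing metadata (ps).
#' @return A [complex_ensemble()].
#' @export
#' @examples
#' ens <- generate_toy_complex(3, residue_charges = c(-1, 0, 0),
#'                             n_snapshots = 2, jitter_sd = 0)
#' ensemble_frame(ens, 1)$atoms
generate_toy_complex <- function(n_residues, atoms_per_residue = 6,
                                 ligand_charge = 1, n_snapshots = 1,
                                 seed = 1L, residue_charges = 0,
                                 contact_residue = 1, contact_distance = 3,
                                 spacing = 8, jitter_sd = 0.1,
                                 lj_epsilon = 0, lj_rmin = 1.908,
                                 cb_charge = ALA_CB_TEMPLATE$charge,
                                 interval_ps = 50) {
  if (n_residues < 1 || atoms_per_residue < 1 || n_snapshots < 1) {
    stop("`n_residues`, `atoms_per_residue` and `n_snapshots` must be >= 1",
         call. = FALSE)
  }
  if (contact_residue < 1 || contact_residue > n_residues) {
    stop("`contact_residue` out of range", call. = FALSE)
  }
  charges <- rep_len(residue_charges, n_residues)
  names_res <- ifelse(charges < 0, "ASP", ifelse(charges > 0, "LYS", "SER"))
  atom_names <- TOY_ATOM_NAMES[seq_len(min(atoms_per_residue,
                                           length(TOY_ATOM_NAMES)))]
  if (atoms_per_residue > length(TOY_ATOM_NAMES)) {
    atom_names <- c(atom_names,
                    sprintf("X%d", seq_len(atoms_per_residue -
                                             length(TOY_ATOM_NAMES))))
  }
  rows <- list()
  xyz <- list()
  for (r in seq_len(n_residues)) {
    for (j in seq_len(atoms_per_residue)) {
      q <- 0
      if (j == atoms_per_residue) q <- charges[r]
      if (atom_names[j] == "CB" && j != atoms_per_residue) q <- cb_charge
      rows[[length(rows) + 1]] <- data.frame(
        name = atom_names[j], residue_id = r, residue_name = names_res[r],
        charge = q, lj_epsilon = lj_epsilon, lj_rmin = lj_rmin,
        is_ligand = FALSE, stringsAsFactors = FALSE)
      xyz[[length(xyz) + 1]] <- c((r - 1) * spacing, 0, (j - 1) * 1.5)
    }
  }
  tip_idx <- contact_residue * atoms_per_residue
  tip <- xyz[[tip_idx]]
  rows[[length(rows) + 1]] <- data.frame(
    name = "C1", residue_id = n_residues + 1L, residue_name = "LIG",
    charge = ligand_charge, lj_epsilon = lj_epsilon, lj_rmin = lj_rmin,
    is_ligand = TRUE, stringsAsFactors = FALSE)
  xyz[[length(xyz) + 1]] <- tip + c(0, contact_distance, 0)
  atoms <- do.call(rbind, rows)
  atoms <- cbind(serial = seq_len(nrow(atoms)), atoms)
  atoms$element <- substr(atoms$name, 1, 1)
  base <- do.call(rbind, xyz)
  coords_list <- lapply(seq_len(n_snapshots), function(s) {
    if (jitter_sd > 0) {
      jit <- with_substream(substream_seed(seed, "toy_complex", s),
                            stats::rnorm(length(base), sd = jitter_sd))
      base + matrix(jit, nrow = nrow(base))
    } else {
      base
    }
  })
  complex_ensemble(atoms, coords_list, interval_ps = interval_ps)
}

#' Write an ensemble as multi-MODEL PDB plus a parameter sidecar TSV
#'
#' The PDB carries names, residue ids/names and coordinates (one MODEL
#' per snapshot); the sidecar TSV carries `serial`, `charge`,
#' `lj_epsilon`, `lj_rmin`, `residue_id`, `is_ligand`.
#'
#' @param ensemble A [complex_ensemble()].
#' @param pdb_path Output PDB path.
#' @param params_path Output TSV path.
#' @return `pdb_path`, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, pdb_path, params_path) {
  at <- ensemble$atoms
  n <- nrow(at)
  atom_df <- data.frame(
    type = "ATOM", eleno = at$serial, elety = at$name, alt = "",
    resid = at$residue_name, chain = ifelse(at$is_ligand, "L", "A"),
    resno = at$residue_id, insert = "",
    x = ensemble$coords[[1]][, 1], y = ensemble$coords[[1]][, 2],
    z = ensemble$coords[[1]][, 3], o = 1, b = 0, segid = "",
    elesy = at$element, charge = "", stringsAsFactors = FALSE)
  xyz <- do.call(rbind, lapply(ensemble$coords, function(m) as.vector(t(m))))
  pdb <- list(atom = atom_df, xyz = xyz)
  class(pdb) <- "pdb"
  bio3d::write.pdb(pdb, file = pdb_path, xyz = xyz)
  utils::write.table(
    at[, c("serial", "charge", "lj_epsilon", "lj_rmin", "residue_id",
           "is_ligand")],
    params_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(pdb_path)
}

#' Read an ensemble from multi-MODEL PDB plus parameter sidecar TSV
#'
#' @param pdb_path PDB path (possibly multi-MODEL).
#' @param params_path Sidecar TSV path written by [write_ensemble_pdb()]
#'   or hand-prepared with the same columns.
#' @param interval_ps Snapshot-spacing metadata (ps).
#' @return A [complex_ensemble()].
#' @export
read_ensemble_pdb <- function(pdb_path, params_path, interval_ps = 50) {
  pdb <- bio3d::read.pdb(pdb_path, multi = TRUE)
  par <- utils::read.table(params_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  at <- pdb$atom
  ord <- match(at$eleno, par$serial)
  if (anyNA(ord)) stop("parameter sidecar misses atom serial(s)",
                       call. = FALSE)
  atoms <- data.frame(
    serial = at$eleno, name = at$elety, element = at$elesy,
    residue_id = par$residue_id[ord], residue_name = at$resid,
    charge = par$charge[ord], lj_epsilon = par$lj_epsilon[ord],
    lj_rmin = par$lj_rmin[ord],
    is_ligand = as.logical(par$is_ligand[ord]), stringsAsFactors = FALSE)
  n_atoms <- nrow(atoms)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  coords_list <- lapply(seq_len(nrow(xyz)), function(i) {
    matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  })
  complex_ensemble(atoms, coords_list, interval_ps = interval_ps)
}
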