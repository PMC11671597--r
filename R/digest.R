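# Two-stage digestion simulator for three-condition DARTS experiments.
#
# Model: limited proteolysis by a broad-specificity protease (pronase) is a
# sequence-nonspecific Bernoulli cleavage at each peptide bond; ligand
# binding shields the bonds inside the binding footprint (plus a flank) of
# the target protein, reducing the cleavage probability by a logistic
# function of dose. All conditions then undergo deterministic tryptic
# digestion for MS sample preparation (cleave after K/R, not before P);
# the control arm sees trypsin only. Peptides outside the observable
# length window are lost, and survivors are detected with a fixed
# probability keyed to their coordinates, so conditions producing the same
# peptide agree on whether it is seen.

#' Specification of a protected (drug-bound) target protein
#'
#' Describes the one protein whose proteolysis is dose-dependently reduced
#' inside a ligand-binding footprint. Protection of the cleavage
#' probability is `protection_max / (1 + (ec50/dose)^hill)` — a
#' four-parameter-logistic occupancy curve with bottom 0.
#'
#' @param protein_id Protein identifier present in the proteome.
#' @param footprint Integer pair, 1-based inclusive residue interval.
#' @param protection_max Maximal fractional protection in `[0, 1]`.
#' @param ec50 Half-protective ligand concentration (uM), > 0.
#' @param hill Hill coefficient, > 0.
#' @return An object of class `target_spec`.
#' @export
target_spec <- function(protein_id, footprint, protection_max = 0.8,
                        ec50 = 280, hill = 1) {
  if (length(footprint) != 2 || footprint[1] < 1 ||
      footprint[2] < footprint[1]) {
    stop("`footprint` must be (start, end) with 1 <= start <= end",
         call. = FALSE)
  }
  if (protection_max < 0 || protection_max > 1) {
    stop("`protection_max` must lie in [0, 1]", call. = FALSE)
  }
  if (ec50 <= 0) stop("`ec50` must be positive", call. = FALSE)
  if (hill <= 0) stop("`hill` must be positive", call. = FALSE)
  structure(
    list(protein_id = as.character(protein_id),
         footprint = as.integer(footprint),
         protection_max = protection_max, ec50 = ec50, hill = hill),
    class = "target_spec"
  )
}

#' Digestion and detection parameters
#'
#' @param p_pronase Per-bond pronase cleavage probability in `[0, 1]`.
#' @param detect_len_range Observable peptide length window (residues).
#' @param p_detect Detection probability for an observable peptide.
#' @param flank Residues on each side of the footprint that share its
#'   protection.
#' @param seed Integer root seed for the digestion substreams.
#' @return An object of class `digestion_params`.
#' @export
digestion_params <- function(p_pronase = 0.35, detect_len_range = c(7L, 30L),
                             p_detect = 0.7, flank = 5L, seed = 1L) {
  if (p_pronase < 0 || p_pronase > 1) {
    stop("`p_pronase` must lie in [0, 1]", call. = FALSE)
  }
  if (p_detect < 0 || p_detect > 1) {
    stop("`p_detect` must lie in [0, 1]", call. = FALSE)
  }
  if (length(detect_len_range) != 2 || detect_len_range[1] < 1 ||
      detect_len_range[2] < detect_len_range[1]) {
    stop("`detect_len_range` must be (min, max) with min >= 1", call. = FALSE)
  }
  structure(
    list(p_pronase = p_pronase,
         detect_len_range = as.integer(detect_len_range),
         p_detect = p_detect, flank = as.integer(flank),
         seed = as.integer(seed)),
    class = "digestion_params"
  )
}

#' Fractional protection of the footprint at a given dose
#'
#' @param target A [target_spec()].
#' @param dose Ligand dose (uM); `Inf` gives saturating protection
#'   `protection_max` exactly.
#' @return Fraction in `[0, protection_max]`.
#' @export
protection_at_dose <- function(target, dose) {
  if (dose < 0) stop("`dose` must be nonnegative", call. = FALSE)
  if (dose == 0) return(0)
  if (is.infinite(dose)) return(target$protection_max)
  target$protection_max / (1 + (target$ec50 / dose)^target$hill)
}

# Tryptic cleavage sites: bond index i means cleavage between residues i
# and i+1; trypsin cuts after K/R unless the next residue is P.
tryptic_sites <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 2) return(integer(0))
  i <- seq_len(n - 1)
  i[(chars[i] == "K" | chars[i] == "R") & chars[i + 1] != "P"]
}

# Split a sequence at the given bond indices into (start, end) intervals.
cut_fragments <- function(n_res, cut_bonds) {
  bounds <- sort(unique(cut_bonds))
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, n_res)
  data.frame(start = starts, end = ends)
}

# Digest one protein in one condition; returns detected peptide evidence.
digest_protein <- function(id, sequence, condition, params,
                           pronase = FALSE, target = NULL, dose = 0) {
  n <- nchar(sequence)
  cuts <- tryptic_sites(sequence)
  if (pronase && params$p_pronase > 0 && n >= 2) {
    p <- rep(params$p_pronase, n - 1)
    if (!is.null(target) && id == target$protein_id) {
      prot <- protection_at_dose(target, dose)
      lo <- max(1L, target$footprint[1] - params$flank)
      hi <- min(n - 1L, target$footprint[2] + params$flank - 1L)
      if (lo <= hi) p[lo:hi] <- p[lo:hi] * (1 - prot)
    }
    u <- with_substream(substream_seed(params$seed, "cleave", condition, id),
                        stats::runif(n - 1))
    cuts <- sort(unique(c(cuts, which(u < p))))
  }
  frags <- cut_fragments(n, cuts)
  len <- frags$end - frags$start + 1L
  keep <- len >= params$detect_len_range[1] & len <= params$detect_len_range[2]
  frags <- frags[keep, , drop = FALSE]
  if (nrow(frags) == 0) {
    return(data.frame(condition = character(0), protein_id = character(0),
                      peptide = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  # Detection keyed to (protein, interval) only: the same peptide is seen
  # (or missed) consistently across conditions.
  u_det <- vapply(seq_len(nrow(frags)), function(i) {
    hash_uniform(params$seed, "detect", id, frags$start[i], frags$end[i])
  }, numeric(1))
  frags <- frags[u_det < params$p_detect, , drop = FALSE]
  if (nrow(frags) == 0) {
    return(data.frame(condition = character(0), protein_id = character(0),
                      peptide = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  data.frame(condition = condition, protein_id = id,
             peptide = substring(sequence, frags$start, frags$end),
             start = frags$start, end = frags$end,
             stringsAsFactors = FALSE)
}

#' Simulate a three-condition DARTS peptide-evidence experiment
#'
#' Produces detected-peptide tables for the control (trypsin-only),
#' pronase, and pronase+drug arms of a DARTS experiment over a mock
#' proteome with one dose-dependently protected target.
#'
#' @param proteome A `protein_set` data frame (see [generate_proteome()]).
#' @param target A [target_spec()]; its `protein_id` must be in `proteome`.
#' @param dose Ligand dose (uM) applied in the drug arm; may be `Inf` for
#'   saturating protection.
#' @param params A [digestion_params()].
#' @return A data frame of peptide evidence with columns
#'   `condition` (one of `control`, `pronase`, `pronase_drug`),
#'   `protein_id`, `peptide`, `start`, `end` (1-based inclusive).
#' @export
#' @examples
#' prot <- generate_proteome(proteome_spec(3, c(60, 80), seed = 2))
#' tgt <- target_spec(prot$id[1], c(10, 40), protection_max = 0.8)
#' ev <- simulate_darts_triplet(prot, tgt, dose = 1000, digestion_params())
#' table(ev$condition)
simulate_darts_triplet <- function(proteome, target, dose,
                                   params = digestion_params()) {
  stopifnot(inherits(target, "target_spec"),
            inherits(params, "digestion_params"))
  if (!target$protein_id %in% proteome$id) {
    stop("target protein '", target$protein_id, "' not found in proteome",
         call. = FALSE)
  }
  tlen <- nchar(proteome$sequence[proteome$id == target$protein_id])
  if (target$footprint[2] > tlen) {
    stop("target footprint exceeds protein length (", tlen, ")",
         call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(proteome)), function(i) {
    id <- proteome$id[i]
    s <- proteome$sequence[i]
    rbind(
      digest_protein(id, s, "control", params, pronase = FALSE),
      digest_protein(id, s, "pronase", params, pronase = TRUE,
                     target = target, dose = 0),
      digest_protein(id, s, "pronase_drug", params, pronase = TRUE,
                     target = target, dose = dose)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write peptide evidence to a TSV file
#'
#' @param evidence Evidence data frame from [simulate_darts_triplet()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evidence_tsv <- function(evidence, path) {
  utils::write.table(evidence, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read peptide evidence from a TSV file
#'
#' Columns `condition`, `protein_id`, `peptide` are required; `start` and
#' `end` are optional (mapping can recover them; see [map_peptides()]).
#'
#' @param path TSV path.
#' @return Evidence data frame.
#' @export
read_evidence_tsv <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("condition", "protein_id", "peptide")
  miss <- setdiff(need, names(ev))
  if (length(miss)) {
    stop("evidence file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ev
}
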