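# Peptide-to-protein mapping and percent sequence coverage.

#' Map peptides onto a protein sequence
#'
#' Finds every exact occurrence (including overlapping ones) of each
#' peptide in the protein sequence; peptides with no occurrence are
#' returned in a rejects list rather than dropped silently. With
#' `il_equivalent = TRUE`, isoleucine and leucine are treated as
#' indistinguishable (they are isobaric in MS).
#'
#' @param protein_id Protein identifier (carried into the matches).
#' @param sequence Protein amino-acid sequence.
#' @param peptides Character vector of peptide sequences.
#' @param il_equivalent Treat I and L as equivalent (default `FALSE`).
#' @return A list with elements `matches` (data frame `protein_id`,
#'   `peptide`, `start`, `end`, 1-based inclusive) and `rejects`
#'   (character vector of unmatched peptides).
#' @export
#' @examples
#' map_peptides("prot", "MKMK", "MK")$matches
map_peptides <- function(protein_id, sequence, peptides,
                         il_equivalent = FALSE) {
  if (length(peptides) == 0 || any(!nzchar(peptides))) {
    stop("`peptides` must be non-empty strings", call. = FALSE)
  }
  subj_str <- if (il_equivalent) chartr("L", "I", sequence) else sequence
  subject <- Biostrings::AAString(subj_str)
  res <- lapply(peptides, function(pep) {
    q <- if (il_equivalent) chartr("L", "I", pep) else pep
    if (nchar(q) > nchar(subj_str)) {
      return(NULL)
    }
    hits <- Biostrings::matchPattern(q, subject)
    if (length(hits) == 0) return(NULL)
    data.frame(protein_id = protein_id, peptide = pep,
               start = BiocGenerics::start(hits),
               end = BiocGenerics::end(hits),
               stringsAsFactors = FALSE)
  })
  found <- !vapply(res, is.null, logical(1))
  matches <- if (any(found)) {
    do.call(rbind, res[found])
  } else {
    data.frame(protein_id = character(0), peptide = character(0),
               start = integer(0), end = integer(0),
               stringsAsFactors = FALSE)
  }
  rownames(matches) <- NULL
  list(matches = matches, rejects = unique(peptides[!found]))
}

#' Percent sequence coverage from peptide matches
#'
#' Coverage is the size of the union of matched residue intervals as a
#' percentage of protein length; duplicated or overlapping matches count
#' once (presence-based coverage, as standard in MS proteomics).
#'
#' @param protein_length Protein length in residues, > 0.
#' @param matches Data frame with `start` and `end` columns (1-based
#'   inclusive), or an empty data frame.
#' @return Coverage percent in `[0, 100]`.
#' @export
#' @examples
#' compute_coverage(100, data.frame(start = c(1, 6), end = c(10, 20)))
compute_coverage <- function(protein_length, matches) {
  if (protein_length <= 0) stop("`protein_length` must be positive",
                                call. = FALSE)
  if (is.null(matches) || nrow(matches) == 0) return(0)
  if (any(matches$start < 1) || any(matches$end > protein_length) ||
      any(matches$start > matches$end)) {
    stop("match interval out of bounds for protein of length ",
         protein_length, call. = FALSE)
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = matches$start,
                                         end = matches$end))
  100 * sum(BiocGenerics::width(ir)) / protein_length
}

#' Per-protein, per-condition coverage table from peptide evidence
#'
#' When the evidence carries `start`/`end` columns they are used directly
#' (after bounds validation); otherwise peptides are mapped onto the
#' sequences with [map_peptides()]. Every (protein, condition) cell is
#' present, including zero-coverage cells for proteins with no detected
#' peptides in a condition.
#'
#' @param proteome `protein_set` data frame with `id`, `sequence`.
#' @param evidence Evidence data frame with `condition`, `protein_id`,
#'   `peptide` and optionally `start`, `end`.
#' @param conditions Conditions to tabulate (default the DARTS triplet).
#' @param il_equivalent Passed to [map_peptides()] when mapping is needed.
#' @return Data frame `protein_id`, `condition`, `coverage` (percent).
#' @export
coverage_table <- function(proteome, evidence,
                           conditions = c("control", "pronase",
                                          "pronase_drug"),
                           il_equivalent = FALSE) {
  unknown <- setdiff(unique(evidence$protein_id), proteome$id)
  if (length(unknown)) {
    stop("evidence references unknown protein(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  has_coords <- all(c("start", "end") %in% names(evidence)) &&
    !anyNA(evidence$start) && !anyNA(evidence$end)
  grid <- expand.grid(protein_id = proteome$id, condition = conditions,
                      stringsAsFactors = FALSE)
  grid$coverage <- mapply(function(pid, cond) {
    len <- nchar(proteome$sequence[proteome$id == pid])
    ev <- evidence[evidence$protein_id == pid & evidence$condition == cond,
                   , drop = FALSE]
    if (nrow(ev) == 0) return(0)
    m <- if (has_coords) {
      ev[, c("start", "end"), drop = FALSE]
    } else {
      seqs <- proteome$sequence[proteome$id == pid]
      map_peptides(pid, seqs, unique(ev$peptide),
                   il_equivalent = il_equivalent)$matches
    }
    compute_coverage(len, m)
  }, grid$protein_id, grid$condition)
  grid
}

#' Write a coverage table to CSV
#'
#' @param cov Coverage data frame from [coverage_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_csv <- function(cov, path) {
  utils::write.csv(cov, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
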