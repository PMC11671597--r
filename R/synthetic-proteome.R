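# Mock proteome generation for DARTS simulations.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Specification of a mock proteome
#'
#' Stands in for an experimentally isolated protein pool (e.g. a
#' mitochondrial fraction) in simulations. Sequences are i.i.d. uniform
#' over the 20 standard amino acids with lengths uniform in `length_range`.
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param length_range Integer pair `(min, max)` residues, `min >= 10`.
#' @param seed Integer root seed.
#' @return An object of class `proteome_spec`.
#' @export
proteome_spec <- function(n_proteins, length_range = c(80L, 300L), seed = 1L) {
  if (length(n_proteins) != 1 || is.na(n_proteins) || n_proteins < 1) {
    stop("`n_proteins` must be a single integer >= 1", call. = FALSE)
  }
  if (length(length_range) != 2 || length_range[1] < 10 ||
      length_range[2] < length_range[1]) {
    stop("`length_range` must be (min, max) with min >= 10 and max >= min",
         call. = FALSE)
  }
  structure(
    list(n_proteins = as.integer(n_proteins),
         length_range = as.integer(length_range),
         seed = as.integer(seed)),
    class = "proteome_spec"
  )
}

#' Generate a mock proteome
#'
#' Deterministic given the spec's seed; each protein draws its length and
#' sequence from its own substream, so enlarging `n_proteins` leaves the
#' existing proteins unchanged.
#'
#' @param spec A [proteome_spec()].
#' @return A data frame with columns `id` and `sequence` (class
#'   `protein_set`); protein ids are `P0001`, `P0002`, ...
#' @export
#' @examples
#' prot <- generate_proteome(proteome_spec(5, c(50, 120), seed = 42))
#' nchar(prot$sequence)
generate_proteome <- function(spec) {
  stopifnot(inherits(spec, "proteome_spec"))
  ids <- sprintf("P%04d", seq_len(spec$n_proteins))
  seqs <- vapply(ids, function(id) {
    with_substream(substream_seed(spec$seed, "proteome", id), {
      lens <- spec$length_range[1]:spec$length_range[2]
      len <- lens[sample.int(length(lens), 1)]
      paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
    })
  }, character(1))
  out <- data.frame(id = ids, sequence = unname(seqs),
                    stringsAsFactors = FALSE)
  class(out) <- c("protein_set", "data.frame")
  out
}

#' Write a protein set to FASTA
#'
#' @param proteins Data frame with `id` and `sequence` columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(proteins, path) {
  ss <- Biostrings::AAStringSet(proteins$sequence)
  names(ss) <- proteins$id
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

#' Read a protein set from FASTA
#'
#' @param path FASTA file path.
#' @return A `protein_set` data frame with `id` and `sequence`.
#' @export
read_proteome_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  out <- data.frame(id = sub("\\s.*$", "", names(ss)),
                    sequence = as.character(ss),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("protein_set", "data.frame")
  out
}
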