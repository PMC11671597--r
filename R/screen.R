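# DARTS candidate-selection cascade: proteolytic susceptibility filter,
# drug-stabilization filter, fold-change ranking, heatmap export.

#' Per-protein screen statistics from a coverage table
#'
#' Pivots a long (protein, condition, coverage) table to one row per
#' protein and derives the screen statistics:
#' degradation = control - pronase coverage (points),
#' stabilization = drug - pronase coverage (points),
#' fold change = drug / pronase coverage (NA, flagged, when pronase
#' coverage is zero).
#'
#' @param cov Data frame `protein_id`, `condition`, `coverage` with the
#'   three conditions `control`, `pronase`, `pronase_drug` per protein.
#' @return Data frame `protein_id`, `cov_control`, `cov_pronase`,
#'   `cov_drug`, `degradation`, `stabilization`, `fold_change`,
#'   `fc_defined`.
#' @export
#' @examples
#' cov <- data.frame(protein_id = "A",
#'                   condition = c("control", "pronase", "pronase_drug"),
#'                   coverage = c(90, 40, 60))
#' compute_screen_stats(cov)
compute_screen_stats <- function(cov) {
  need <- c("control", "pronase", "pronase_drug")
  have <- table(cov$protein_id,
                factor(cov$condition, levels = union(need,
                                                     unique(cov$condition))))
  incomplete <- rownames(have)[rowSums(have[, need, drop = FALSE] >= 1) < 3]
  if (length(incomplete)) {
    stop("missing condition value(s) for protein(s): ",
         paste(utils::head(incomplete, 5), collapse = ", "), call. = FALSE)
  }
  wide <- stats::reshape(cov[, c("protein_id", "condition", "coverage")],
                         idvar = "protein_id", timevar = "condition",
                         direction = "wide")
  names(wide) <- sub("^coverage\\.", "", names(wide))
  out <- data.frame(
    protein_id = wide$protein_id,
    cov_control = wide$control,
    cov_pronase = wide$pronase,
    cov_drug = wide$pronase_drug,
    stringsAsFactors = FALSE
  )
  out$degradation <- out$cov_control - out$cov_pronase
  out$stabilization <- out$cov_drug - out$cov_pronase
  out$fc_defined <- out$cov_pronase > 0
  out$fold_change <- ifelse(out$fc_defined, out$cov_drug / out$cov_pronase,
                            NA_real_)
  rownames(out) <- NULL
  out
}

#' Screen thresholds for the candidate cascade
#'
#' Defaults reflect the conventional DARTS screen: proteins degraded by
#' more than 5 coverage points by the protease, then stabilized by more
#' than 5 points by the drug. `mode = "relative"` interprets the
#' thresholds as percent change relative to the reference coverage
#' instead of absolute points.
#'
#' @param min_degradation,min_stabilization Thresholds (>= 0); points when
#'   `mode = "points"`, percent of the reference when `mode = "relative"`.
#' @param strict Use strict `>` comparisons (default `TRUE`).
#' @param mode `"points"` (absolute coverage points, default) or
#'   `"relative"`.
#' @return Object of class `screen_thresholds`.
#' @export
screen_thresholds <- function(min_degradation = 5, min_stabilization = 5,
                              strict = TRUE, mode = c("points", "relative")) {
  if (min_degradation < 0 || min_stabilization < 0) {
    stop("thresholds must be >= 0", call. = FALSE)
  }
  structure(list(min_degradation = min_degradation,
                 min_stabilization = min_stabilization,
                 strict = isTRUE(strict), mode = match.arg(mode)),
            class = "screen_thresholds")
}

#' Apply the degradation/stabilization cascade and rank candidates
#'
#' Keeps proteins whose coverage dropped under protease by more than
#' `min_degradation` and recovered under drug by more than
#' `min_stabilization`; candidates are ranked by descending stabilization,
#' ties broken by descending fold change then protein id.
#'
#' @param stats Data frame from [compute_screen_stats()].
#' @param thresholds A [screen_thresholds()].
#' @return A list with `candidates` (ranked data frame with a `rank`
#'   column), `degraded` (ids passing the degradation filter), and
#'   `cascade` (named counts `total`, `degraded`, `candidates`).
#' @export
screen_candidates <- function(stats, thresholds = screen_thresholds()) {
  stopifnot(inherits(thresholds, "screen_thresholds"))
  cmp <- if (thresholds$strict) `>` else `>=`
  if (thresholds$mode == "points") {
    deg_stat <- stats$degradation
    stab_stat <- stats$stabilization
  } else {
    deg_stat <- ifelse(stats$cov_control > 0,
                       100 * stats$degradation / stats$cov_control, 0)
    stab_stat <- ifelse(stats$cov_pronase > 0,
                        100 * stats$stabilization / stats$cov_pronase,
                        ifelse(stats$cov_drug > 0, Inf, 0))
  }
  degraded <- cmp(deg_stat, thresholds$min_degradation)
  passing <- degraded & cmp(stab_stat, thresholds$min_stabilization)
  cand <- stats[passing, , drop = FALSE]
  ord <- order(-cand$stabilization,
               -ifelse(is.na(cand$fold_change), -Inf, cand$fold_change),
               cand$protein_id)
  cand <- cand[ord, , drop = FALSE]
  cand$rank <- seq_len(nrow(cand))
  rownames(cand) <- NULL
  list(
    candidates = cand,
    degraded = stats$protein_id[degraded],
    cascade = c(total = nrow(stats), degraded = sum(degraded),
                candidates = nrow(cand))
  )
}

#' Export the candidate coverage heatmap matrix
#'
#' Writes (and returns) the candidates-by-conditions matrix of raw
#' coverages, row-ordered by rank, as plotted in DARTS screen heatmaps.
#'
#' @param screen Result of [screen_candidates()].
#' @param path Optional CSV path; when `NULL` nothing is written.
#' @return The matrix (candidates x 3 conditions), invisibly when `path`
#'   is given.
#' @export
export_heatmap_matrix <- function(screen, path = NULL) {
  cand <- screen$candidates
  m <- as.matrix(cand[, c("cov_control", "cov_pronase", "cov_drug"),
                      drop = FALSE])
  colnames(m) <- c("control", "pronase", "pronase_drug")
  rownames(m) <- cand$protein_id
  if (nrow(m) == 0) warning("empty candidate set; writing header-only matrix")
  if (!is.null(path)) {
    utils::write.csv(cbind(protein_id = rownames(m), as.data.frame(m)),
                     path, row.names = FALSE, quote = FALSE)
    return(invisible(m))
  }
  m
}
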