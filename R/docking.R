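#' Ligand-efficiency score normalisation
#'
#' Docking scores grow in magnitude with molecular size, biasing raw-score
#' ranking toward large molecules. Dividing the score by the heavy (non-H)
#' atom count gives a per-atom binding efficiency; the screen's cutoff is the
#' normalised score of the reference inhibitor (colchicine: -10.01 over 29
#' heavy atoms = -0.345 at report precision).
#'
#' @param raw_score engine score (lower = better binding)
#' @param n_heavy heavy-atom count, >= 1
#' @return raw_score / n_heavy at full precision
#' @export
normalize_score <- function(raw_score, n_heavy) {
  if (any(n_heavy < 1)) stopf("normalize_score: n_heavy must be >= 1")
  raw_score / n_heavy
}

#' Read a docking score table and join heavy-atom counts
#'
#' CSV with columns `compound_id`, `raw_score`. Heavy-atom counts are joined
#' from the molecule library; unknown ids are logged and excluded. Duplicate
#' ids keep the best (lowest) raw score, mirroring the convention of keeping
#' the best-scored conformation.
#'
#' @param path CSV path (or a data.frame already in memory)
#' @param library list of `cvs_molecule` used for the heavy-atom join
#' @return data.frame: compound_id, raw_score, n_heavy, normalized_score
#' @export
read_score_table <- function(path, library) {
  tab <- if (is.data.frame(path)) path else utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("compound_id", "raw_score") %in% names(tab))) {
    stopf("score table must have columns compound_id, raw_score")
  }
  # best score per compound
  tab <- tab[order(tab$compound_id, tab$raw_score), , drop = FALSE]
  dup <- duplicated(tab$compound_id)
  if (any(dup)) {
    cvs_log(sprintf("score table: %d duplicate rows dropped (kept best score)", sum(dup)))
    tab <- tab[!dup, , drop = FALSE]
  }
  counts <- vapply(library, heavy_atom_count, integer(1))
  names(counts) <- vapply(library, function(m) m$id, character(1))
  known <- tab$compound_id %in% names(counts)
  if (any(!known)) {
    cvs_log(sprintf("score table: unknown compound ids excluded: %s",
                    paste(tab$compound_id[!known], collapse = ", ")))
  }
  tab <- tab[known, , drop = FALSE]
  tab$n_heavy <- as.integer(counts[tab$compound_id])
  tab$normalized_score <- normalize_score(tab$raw_score, tab$n_heavy)
  rownames(tab) <- NULL
  tab
}

#' Docking hits: normalised score at or below the reference's
#'
#' The cutoff is inclusive ("equal to or lower than" the reference compound's
#' normalised score). Comparison is at full precision; rounding applies only
#' to reports.
#'
#' @param records data.frame from [read_score_table()]
#' @param reference a single-row record (or list) with `normalized_score`
#' @return character vector of hit compound ids
#' @export
docking_hits <- function(records, reference) {
  cutoff <- reference$normalized_score
  if (is.null(cutoff) || length(cutoff) != 1 || !is.finite(cutoff)) {
    stopf("docking_hits: reference normalized_score missing")
  }
  records$compound_id[records$normalized_score <= cutoff]
}

#' Report-precision rounding of normalised scores
#'
#' Three decimals, ties away from zero: -10.01/29 prints as -0.345.
#'
#' @param x numeric
#' @return numeric rounded to 3 decimals
#' @export
report_score <- function(x) round_half_away(x, 3)
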