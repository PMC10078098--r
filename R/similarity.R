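#' Dual-fingerprint similarity matrix
#'
#' Computes Tanimoto similarity of every library molecule against every
#' reference active, for both fingerprint kinds (structural keys and the
#' radius-2 circular fingerprint). This is criterion (1) of the consensus
#' screen.
#'
#' @param library list of `cvs_molecule`
#' @param references list of `cvs_molecule`
#' @param nbits circular fingerprint width (default 2048)
#' @return data.frame with columns `library_id`, `reference_id`, `t_skey`,
#'   `t_circ`; one row per (library, reference) pair in input order
#' @export
similarity_matrix <- function(library, references, nbits = 2048L) {
  if (length(library) == 0 || length(references) == 0) {
    stopf("similarity_matrix: both molecule lists must be nonempty")
  }
  fp_lib_s <- lapply(library, compute_fingerprint, kind = "structural_keys_166")
  fp_lib_c <- lapply(library, compute_fingerprint, kind = "circular_r2", nbits = nbits)
  fp_ref_s <- lapply(references, compute_fingerprint, kind = "structural_keys_166")
  fp_ref_c <- lapply(references, compute_fingerprint, kind = "circular_r2", nbits = nbits)
  n <- length(library) * length(references)
  out <- data.frame(library_id = character(n), reference_id = character(n),
                    t_skey = numeric(n), t_circ = numeric(n),
                    stringsAsFactors = FALSE)
  row <- 1L
  for (i in seq_along(library)) {
    for (j in seq_along(references)) {
      out$library_id[row] <- library[[i]]$id
      out$reference_id[row] <- references[[j]]$id
      out$t_skey[row] <- tanimoto(fp_lib_s[[i]], fp_ref_s[[j]])
      out$t_circ[row] <- tanimoto(fp_lib_c[[i]], fp_ref_c[[j]])
      row <- row + 1L
    }
  }
  out
}

#' Consensus similarity thresholds: median plus one standard deviation
#'
#' For each fingerprint kind the threshold is the median of all pairwise
#' similarity values plus one sample standard deviation (denominator n-1),
#' pooled over every (library, reference) pair. A compound is later a
#' similarity hit only if it exceeds both thresholds against one reference.
#'
#' @param records data.frame from [similarity_matrix()]
#' @return list with `thr_skey`, `thr_circ`, `n_pairs`
#' @export
consensus_thresholds <- function(records) {
  if (nrow(records) < 2) {
    stopf("consensus_thresholds: need at least 2 records (SD undefined)")
  }
  list(
    thr_skey = stats::median(records$t_skey) + stats::sd(records$t_skey),
    thr_circ = stats::median(records$t_circ) + stats::sd(records$t_circ),
    n_pairs = nrow(records)
  )
}

#' Similarity hits under the consensus rule
#'
#' A library compound is a hit iff, for at least one reference, its
#' similarity is strictly above the threshold for both fingerprint kinds.
#' With `consensus_mode = "any_reference"` the two conditions may be met
#' against different references.
#'
#' @param records data.frame from [similarity_matrix()]
#' @param thresholds list from [consensus_thresholds()]
#' @param consensus_mode "same_reference" (default) or "any_reference"
#' @return character vector of hit library ids (unique, in first-seen order)
#' @export
similarity_hits <- function(records, thresholds,
                            consensus_mode = c("same_reference", "any_reference")) {
  consensus_mode <- match.arg(consensus_mode)
  if (consensus_mode == "same_reference") {
    ok <- records$t_skey > thresholds$thr_skey & records$t_circ > thresholds$thr_circ
    unique(records$library_id[ok])
  } else {
    ids <- unique(records$library_id)
    ids[vapply(ids, function(id) {
      r <- records[records$library_id == id, ]
      any(r$t_skey > thresholds$thr_skey) && any(r$t_circ > thresholds$thr_circ)
    }, logical(1))]
  }
}

#' Write similarity outputs
#'
#' @param records similarity matrix data.frame
#' @param thresholds threshold list
#' @param dir output directory
#' @return invisibly, the two paths written
#' @export
write_similarity_outputs <- function(records, thresholds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "similarity.csv")
  js <- file.path(dir, "similarity_thresholds.json")
  utils::write.csv(records, csv, row.names = FALSE)
  jsonlite::write_json(thresholds, js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
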