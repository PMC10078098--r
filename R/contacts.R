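#' Key binding-site residue sets
#'
#' Reported key contacts of the two reference inhibitors at the colchicine
#' site of tubulin: colchicine itself (Ala 180, Val 181, Cys 241, Met 259,
#' Ala 316) and the destabiliser DJ-101 (Val 181, Val 236, Leu 246, Asn 247,
#' Asn 347, Lys 350).
#'
#' @param which "colchicine" or "dj101"
#' @return character vector of "ResName ResNum" identifiers
#' @export
key_residues <- function(which = c("colchicine", "dj101")) {
  which <- match.arg(which)
  if (which == "colchicine") {
    c("Ala 180", "Val 181", "Cys 241", "Met 259", "Ala 316")
  } else {
    c("Val 181", "Val 236", "Leu 246", "Asn 247", "Asn 347", "Lys 350")
  }
}

res_id <- function(res_name, res_num) {
  nm <- paste0(toupper(substr(res_name, 1, 1)), tolower(substring(res_name, 2)))
  paste(nm, res_num)
}

#' Residues in contact with the ligand
#'
#' A residue is in contact when any of its heavy atoms lies within
#' `cutoff` Angstroms (inclusive) of any ligand heavy atom. The default
#' 4.5 A mirrors the pocket-margin scale used to define the binding site.
#'
#' @param complex a `cvs_complex`
#' @param cutoff distance cutoff in Angstroms
#' @return character vector of residue identifiers ("ResName ResNum"),
#'   unique, in protein order
#' @export
detect_contacts <- function(complex, cutoff = 4.5) {
  stopifnot(inherits(complex, "cvs_complex"))
  if (nrow(complex$ligand) == 0) stopf("detect_contacts: empty ligand")
  if (nrow(complex$protein) == 0) stopf("detect_contacts: empty protein")
  pc <- as.matrix(complex$protein[, c("x", "y", "z")])
  lc <- as.matrix(complex$ligand[, c("x", "y", "z")])
  # min distance of each protein atom to any ligand atom
  d2 <- outer(rowSums(pc^2), rowSums(lc^2), "+") - 2 * pc %*% t(lc)
  mind <- sqrt(pmax(apply(d2, 1, min), 0))
  hit <- mind <= cutoff + 1e-9
  unique(res_id(complex$protein$res_name[hit], complex$protein$res_num[hit]))
}

#' Contact persistence across an ensemble of frames
#'
#' For each residue, the fraction of frames in which [detect_contacts()]
#' reports it. All frames are weighted equally; dropping equilibration
#' frames is the caller's responsibility.
#'
#' @param frames list of `cvs_complex` with consistent residue tables
#' @param cutoff contact cutoff in Angstroms
#' @param compound_id identifier recorded in the profile
#' @return a `cvs_contact_profile`: list(compound_id, contacts = named
#'   numeric fractions, n_frames)
#' @export
contact_persistence <- function(frames, cutoff = 4.5, compound_id = "ligand") {
  if (length(frames) < 1) stopf("contact_persistence: need at least one frame")
  res_tables <- lapply(frames, function(fr)
    sort(unique(res_id(fr$protein$res_name, fr$protein$res_num))))
  if (length(unique(vapply(res_tables, paste, character(1), collapse = "|"))) != 1) {
    stopf("contact_persistence: residue tables differ across frames")
  }
  all_res <- res_tables[[1]]
  counts <- stats::setNames(numeric(length(all_res)), all_res)
  for (fr in frames) {
    hits <- detect_contacts(fr, cutoff)
    counts[hits] <- counts[hits] + 1
  }
  structure(list(compound_id = compound_id,
                 contacts = counts / length(frames),
                 n_frames = length(frames)),
            class = "cvs_contact_profile")
}

#' Key-interaction check
#'
#' Counts how many of the stated key residues the profile contacts with
#' persistence strictly above `min_fraction`; passes when at least
#' `min_matches` do. The screen's rule is "at least three of the reported
#' key interactions" of either reference inhibitor.
#'
#' @param profile a `cvs_contact_profile`
#' @param key_set character vector of residue identifiers
#' @param min_matches minimum matched residues to pass (default 3)
#' @param min_fraction persistence must exceed this (default 0)
#' @return list(n_matched, pass)
#' @export
key_interaction_check <- function(profile, key_set = key_residues("colchicine"),
                                  min_matches = 3L, min_fraction = 0.0) {
  if (length(key_set) == 0) stopf("key_interaction_check: empty key set")
  fr <- profile$contacts[key_set]
  fr[is.na(fr)] <- 0
  n <- sum(fr > min_fraction)
  list(n_matched = as.integer(n), pass = n >= min_matches)
}

#' @export
print.cvs_contact_profile <- function(x, ...) {
  cat(sprintf("<contact profile %s: %d residues tracked over %d frame(s)>\n",
              x$compound_id, length(x$contacts), x$n_frames))
  invisible(x)
}

#' Long-format contact table
#'
#' @param profiles list of `cvs_contact_profile`
#' @return data.frame: compound_id, residue, fraction
#' @export
contact_table <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(compound_id = p$compound_id, residue = names(p$contacts),
               fraction = unname(p$contacts), stringsAsFactors = FALSE)
  }))
}
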