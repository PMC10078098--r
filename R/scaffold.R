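#' Bemis-Murcko scaffold of a molecule
#'
#' The framework is obtained by iteratively deleting terminal heavy atoms
#' (heavy degree 1) that are not ring members until a fixpoint: what remains
#' is the union of ring systems and the linkers connecting them. Exocyclic
#' atoms double-bonded to a ring or linker atom are conventionally retained;
#' this implementation removes them like any other terminal atom, which is a
#' stricter graph-frame definition applied uniformly to every molecule, so
#' equality classes are unaffected for comparisons within one run.
#'
#' Acyclic molecules have an empty framework. During diversity selection an
#' empty scaffold is treated as a unique class per compound so acyclic hits
#' never collapse into one class.
#'
#' @param mol a `cvs_molecule`
#' @return a `cvs_scaffold` with `canonical_form` (canonical SMILES of the
#'   framework, "" when empty) and `is_empty`
#' @export
bemis_murcko_scaffold <- function(mol) {
  stopifnot(inherits(mol, "cvs_molecule"))
  keep <- rep(TRUE, nrow(mol$atoms))
  bonds <- mol$bonds
  repeat {
    deg <- integer(nrow(mol$atoms))
    if (nrow(bonds) > 0) {
      live <- keep[bonds$a] & keep[bonds$b]
      for (k in which(live)) {
        deg[bonds$a[k]] <- deg[bonds$a[k]] + 1L
        deg[bonds$b[k]] <- deg[bonds$b[k]] + 1L
      }
    }
    drop <- keep & deg <= 1L & !mol$atoms$in_ring
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  if (!any(keep & mol$atoms$in_ring)) {
    return(structure(list(canonical_form = "", is_empty = TRUE),
                     class = "cvs_scaffold"))
  }
  idx <- which(keep)
  remap <- match(seq_len(nrow(mol$atoms)), idx)
  sub_bonds <- bonds[keep[bonds$a] & keep[bonds$b], , drop = FALSE]
  sub_bonds$a <- remap[sub_bonds$a]
  sub_bonds$b <- remap[sub_bonds$b]
  sub_atoms <- mol$atoms[idx, c("element", "charge", "aromatic"), drop = FALSE]
  # hydrogens of the framework are re-derived from framework valence
  frame <- new_molecule(paste0(mol$id, "_scaffold"), sub_atoms, sub_bonds,
                        source = "constructed")
  frame <- rehydrogenate(frame)
  structure(list(canonical_form = canonical_smiles(frame), is_empty = FALSE),
            class = "cvs_scaffold")
}

# recompute implicit H from default valences after atom deletion
rehydrogenate <- function(mol) {
  bsum <- numeric(nrow(mol$atoms))
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      bsum[mol$bonds$a[k]] <- bsum[mol$bonds$a[k]] + mol$bonds$order[k]
      bsum[mol$bonds$b[k]] <- bsum[mol$bonds$b[k]] + mol$bonds$order[k]
    }
  }
  for (i in seq_len(nrow(mol$atoms))) {
    dv <- tryCatch(default_valence(mol$atoms$element[i], mol$atoms$charge[i]),
                   error = function(e) NA_integer_)
    if (!is.na(dv)) mol$atoms$h[i] <- max(0L, as.integer(dv - ceiling(bsum[i] - 1e-9)))
  }
  finalize_molecule(mol)
}

#' @export
print.cvs_scaffold <- function(x, ...) {
  cat(if (x$is_empty) "<scaffold: empty (acyclic)>\n"
      else sprintf("<scaffold: %s>\n", x$canonical_form))
  invisible(x)
}

# scaffold -> parseable molecule (for idempotence checks); NULL when empty
scaffold_as_molecule <- function(sc) {
  if (sc$is_empty) return(NULL)
  parse_smiles(sc$canonical_form, id = "scaffold")
}
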