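#' Basic physicochemical descriptors
#'
#' Deterministic 2D descriptors feeding the drug-likeness and solubility
#' rules:
#' \itemize{
#'   \item \code{mw} molecular weight, g/mol (standard atomic masses,
#'     implicit hydrogens included)
#'   \item \code{logp} octanol/water partition estimate from a documented
#'     atom-contribution table (see Details)
#'   \item \code{hbd} H-bond donors: N or O bearing at least one hydrogen
#'   \item \code{hba} H-bond acceptors: N or O not positively charged
#'   \item \code{rotatable_bonds} non-ring single bonds between two heavy
#'     atoms of heavy degree >= 2 (amide bonds not special-cased)
#'   \item \code{tpsa} topological polar surface area, A^2, from a fragment
#'     contribution table for N/O environments
#'   \item \code{aromatic_fraction} aromatic heavy atoms / heavy atoms (the
#'     AP term of the ESOL solubility model)
#'   \item \code{heavy_atoms} non-hydrogen atom count
#' }
#'
#' @details The logP scheme is a coarse atom-contribution model: aliphatic C
#' +0.19, aromatic C +0.29, N -0.60 (-0.95 aromatic n with H), O -0.40
#' (hydroxyl -0.45), S +0.45, F +0.15, Cl +0.65, Br +0.88, I +1.10, P -0.50,
#' any formally charged atom -1.50 extra. It is monotone in added CH2 and is
#' used only for rule thresholds, never as a literature-comparable value.
#'
#' @param mol a `cvs_molecule`
#' @return a one-row data.frame of class `cvs_descriptors`
#' @export
basic_descriptors <- function(mol) {
  stopifnot(inherits(mol, "cvs_molecule"))
  a <- mol$atoms
  mw <- sum(vapply(a$element, atomic_mass, numeric(1))) + sum(a$h) * 1.008
  hbd <- sum(a$element %in% c("N", "O") & a$h >= 1)
  hba <- sum(a$element %in% c("N", "O") & a$charge <= 0)
  rot <- 0L
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      b <- mol$bonds[k, ]
      if (b$order == 1 && !b$in_ring &&
          a$degree[b$a] >= 2 && a$degree[b$b] >= 2) {
        rot <- rot + 1L
      }
    }
  }
  logp <- sum(vapply(seq_len(nrow(a)), function(i) logp_contrib(mol, i), numeric(1)))
  tpsa <- sum(vapply(seq_len(nrow(a)), function(i) tpsa_contrib(mol, i), numeric(1)))
  heavy <- heavy_atom_count(mol)
  out <- data.frame(
    id = mol$id, mw = mw, logp = logp, hbd = hbd, hba = hba,
    rotatable_bonds = rot, tpsa = tpsa,
    aromatic_fraction = sum(a$aromatic) / heavy,
    heavy_atoms = heavy, stringsAsFactors = FALSE
  )
  class(out) <- c("cvs_descriptors", class(out))
  out
}

atomic_mass <- function(el) {
  switch(el,
    H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
    F = 18.998, P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904,
    stopf("no atomic mass tabulated for element '%s'", el))
}

logp_contrib <- function(mol, i) {
  a <- mol$atoms[i, ]
  base <- switch(a$element,
    C = if (a$aromatic) 0.29 else 0.19,
    N = if (a$aromatic && a$h > 0) -0.95 else -0.60,
    O = if (a$h > 0) -0.45 else -0.40,
    S = 0.45, P = -0.50,
    F = 0.15, Cl = 0.65, Br = 0.88, I = 1.10,
    B = 0.10, 0.0)
  if (a$charge != 0) base <- base - 1.50
  base
}

# Ertl-style polar-surface contributions, restricted to the N/O environments
# the screening chemistry produces. Sulfur/phosphorus treated as apolar
# (classic TPSA convention).
tpsa_contrib <- function(mol, i) {
  a <- mol$atoms[i, ]
  if (!(a$element %in% c("N", "O"))) return(0)
  dbl <- has_double_bond(mol, i)
  if (a$element == "O") {
    if (a$aromatic) return(13.14)
    if (dbl) return(17.07)
    if (a$h >= 1) return(20.23)
    if (a$charge < 0) return(23.06)
    return(9.23)
  }
  # nitrogen
  if (a$charge > 0) {
    return(if (a$h >= 3) 27.64 else if (a$h == 2) 16.61 else if (a$h == 1) 4.44 else 0.0)
  }
  if (a$aromatic) return(if (a$h >= 1) 15.79 else 12.89)
  if (dbl) return(if (a$h >= 1) 23.85 else 12.36)
  if (a$h >= 2) return(26.02)
  if (a$h == 1) return(12.03)
  3.24
}

has_double_bond <- function(mol, i) {
  if (nrow(mol$bonds) == 0) return(FALSE)
  any((mol$bonds$a == i | mol$bonds$b == i) & mol$bonds$order >= 2)
}

#' Descriptor table for a molecule list
#'
#' @param mols list of `cvs_molecule`
#' @return data.frame, one row per molecule
#' @export
descriptor_table <- function(mols) {
  do.call(rbind, lapply(mols, function(m) as.data.frame(basic_descriptors(m))))
}
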