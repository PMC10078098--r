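#' Molecule objects
#'
#' A molecule is stored as an atom table, a bond table, and optional 3D
#' coordinates. Hydrogens are always implicit: parsing materialises them into
#' the per-atom `h` count, and every downstream operation (heavy-atom counts,
#' score normalisation, fingerprints, ECIF typing) is defined on heavy atoms
#' only.
#'
#' Atom columns: `element` (symbol), `charge` (formal), `aromatic`, `in_ring`,
#' `h` (attached hydrogens), `degree` (heavy neighbours), `valence` (explicit
#' valence including hydrogens, aromatic bonds counted as 1.5 then rounded up
#' with the hydrogens added).
#'
#' Bond columns: `a`, `b` (1-based atom indices), `order` (1, 2, 3, or 1.5 for
#' aromatic), `in_ring`.
#'
#' @param id character identifier
#' @param atoms data.frame as described above (missing derived columns are
#'   computed)
#' @param bonds data.frame with columns `a`, `b`, `order`
#' @param coords optional numeric matrix (n_atoms x 3), Angstroms
#' @param source one of "smiles", "sdf", "pdb_ligand", "constructed"
#' @return an object of class `cvs_molecule`
#' @export
new_molecule <- function(id, atoms, bonds, coords = NULL,
                         source = "constructed") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
  if (nrow(bonds) == 0) {
    bonds <- data.frame(a = integer(), b = integer(), order = numeric())
  }
  n <- nrow(atoms)
  if (n < 1) stopf("molecule '%s': at least one atom required", id)
  if (nrow(bonds) > 0) {
    if (any(bonds$a == bonds$b)) stopf("molecule '%s': self-bond", id)
    if (any(bonds$a > n | bonds$b > n | bonds$a < 1 | bonds$b < 1)) {
      stopf("molecule '%s': bond references missing atom", id)
    }
    key <- paste(pmin(bonds$a, bonds$b), pmax(bonds$a, bonds$b))
    if (anyDuplicated(key)) stopf("molecule '%s': duplicate bond", id)
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n || ncol(coords) != 3) {
      stopf("molecule '%s': coords must be %d x 3", id, n)
    }
    storage.mode(coords) <- "double"
  }
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (is.null(atoms$aromatic)) atoms$aromatic <- FALSE
  if (is.null(atoms$h)) atoms$h <- 0L
  mol <- structure(
    list(id = id, atoms = atoms, bonds = bonds, coords = coords,
         source = source),
    class = "cvs_molecule"
  )
  finalize_molecule(mol)
}

# Recompute derived atom/bond columns (ring membership, degree, valence)
# from the connection table. Idempotent.
finalize_molecule <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- adjacency_list(mol)
  mol$atoms$degree <- vapply(adj, length, integer(1))
  ring_bonds <- ring_bond_flags(mol, adj)
  mol$bonds$in_ring <- ring_bonds
  in_ring <- logical(n)
  if (nrow(mol$bonds) > 0) {
    rb <- mol$bonds[ring_bonds, , drop = FALSE]
    in_ring[unique(c(rb$a, rb$b))] <- TRUE
  }
  mol$atoms$in_ring <- in_ring
  # explicit valence: heavy bond order sum (aromatic = 1.5, rounded up) + H
  bsum <- numeric(n)
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      o <- mol$bonds$order[k]
      bsum[mol$bonds$a[k]] <- bsum[mol$bonds$a[k]] + o
      bsum[mol$bonds$b[k]] <- bsum[mol$bonds$b[k]] + o
    }
  }
  mol$atoms$valence <- as.integer(ceiling(bsum - 1e-9)) + as.integer(mol$atoms$h)
  mol
}

# list of integer neighbour vectors, one per atom
adjacency_list <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer()
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a[k]; b <- mol$bonds$b[k]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  adj
}

# A bond is a ring bond iff its endpoints stay connected when it is removed.
ring_bond_flags <- function(mol, adj = adjacency_list(mol)) {
  nb <- nrow(mol$bonds)
  if (nb == 0) return(logical(0))
  out <- logical(nb)
  for (k in seq_len(nb)) {
    a <- mol$bonds$a[k]; b <- mol$bonds$b[k]
    out[k] <- connected_excluding(adj, a, b)
  }
  out
}

# BFS from a to b that may not traverse the direct a-b edge.
connected_excluding <- function(adj, a, b) {
  seen <- logical(length(adj))
  seen[a] <- TRUE
  queue <- a
  first <- TRUE
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (v == a && w == b && first) next
      if (w == b) return(TRUE)
      if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    first <- FALSE
  }
  FALSE
}

# Smallest rings: for every ring bond, the shortest cycle through it
# (BFS from a to b avoiding the direct edge), deduplicated.
smallest_rings <- function(mol) {
  adj <- adjacency_list(mol)
  rings <- list()
  seen <- character()
  if (nrow(mol$bonds) == 0) return(rings)
  for (k in which(mol$bonds$in_ring)) {
    a <- mol$bonds$a[k]; b <- mol$bonds$b[k]
    path <- shortest_path_excluding(adj, a, b)
    if (is.null(path)) next
    ring <- path  # path from a to b, closing bond b-a
    key <- paste(sort(ring), collapse = ",")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      rings[[length(rings) + 1]] <- ring
    }
  }
  rings
}

shortest_path_excluding <- function(adj, a, b) {
  n <- length(adj)
  prev <- integer(n); prev[] <- NA_integer_
  seen <- logical(n); seen[a] <- TRUE
  queue <- a
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (v == a && w == b) next
      if (!seen[w]) {
        seen[w] <- TRUE; prev[w] <- v
        if (w == b) {
          path <- b
          while (path[1] != a) path <- c(prev[path[1]], path)
          return(path)
        }
        queue <- c(queue, w)
      }
    }
  }
  NULL
}

#' Count non-hydrogen atoms
#'
#' The denominator of ligand-efficiency score normalisation. Hydrogens are
#' implicit in this package, so this is simply the atom-table row count minus
#' any explicit H entries (which parsing never produces, but constructed
#' molecules might).
#'
#' @param mol a `cvs_molecule`
#' @return integer heavy-atom count
#' @export
heavy_atom_count <- function(mol) {
  stopifnot(inherits(mol, "cvs_molecule"))
  sum(mol$atoms$element != "H")
}

#' @export
print.cvs_molecule <- function(x, ...) {
  cat(sprintf("<molecule %s: %d heavy atoms, %d bonds%s, source=%s>\n",
              x$id, heavy_atom_count(x), nrow(x$bonds),
              if (is.null(x$coords)) "" else ", 3D", x$source))
  invisible(x)
}

# connected components of the heavy-atom graph -> list of index vectors
components_of <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- adjacency_list(mol)
  comp <- integer(n)
  cur <- 0
  for (i in seq_len(n)) {
    if (comp[i] == 0) {
      cur <- cur + 1
      queue <- i; comp[i] <- cur
      while (length(queue) > 0) {
        v <- queue[1]; queue <- queue[-1]
        for (w in adj[[v]]) if (comp[w] == 0) { comp[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  split(seq_len(n), comp)
}
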