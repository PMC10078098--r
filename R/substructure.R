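# Subgraph-isomorphism substructure matching (VF2-style backtracking).
# Query patterns are themselves molecules parsed from SMILES. Matching rules:
#   atom: same element; aromatic flag must agree; if the query atom carries a
#         formal charge it must match; a bracket-written hydrogen count in the
#         query ([OH], [NH2]) is an "at least n H" constraint on the target;
#         implicit query hydrogens impose no constraint.
#   bond: orders equal, with the relaxation that an aromatic query bond (1.5)
#         matches an aromatic target bond only, and a single query bond
#         matches single only.
# Query hydrogens therefore act as "at least n H here" constraints, which is
# what distinguishes a hydroxyl pattern from an ether oxygen.

atom_compatible <- function(q_atoms, qi, t_atoms, ti) {
  if (q_atoms$element[qi] != t_atoms$element[ti]) return(FALSE)
  if (q_atoms$aromatic[qi] != t_atoms$aromatic[ti]) return(FALSE)
  if (q_atoms$charge[qi] != 0 && q_atoms$charge[qi] != t_atoms$charge[ti]) return(FALSE)
  if (t_atoms$charge[ti] != 0 && q_atoms$charge[qi] != t_atoms$charge[ti]) return(FALSE)
  hq <- q_atoms$h_spec[qi]
  if (!is.null(hq) && !is.na(hq) && hq > 0 && t_atoms$h[ti] < hq) return(FALSE)
  TRUE
}

#' Substructure search
#'
#' Tests whether `query` occurs as a subgraph of `mol` under the matching
#' rules documented in the package's pattern-matching notes.
#'
#' @param mol target `cvs_molecule`
#' @param query query `cvs_molecule` (typically parsed from a pattern SMILES)
#' @return TRUE if at least one embedding exists
#' @export
has_substructure <- function(mol, query) {
  nq <- nrow(query$atoms); nt <- nrow(mol$atoms)
  if (nq > nt) return(FALSE)
  q_adj <- adjacency_list(query)
  t_adj <- adjacency_list(mol)
  q_bond <- function(a, b) {
    k <- which((query$bonds$a == a & query$bonds$b == b) |
               (query$bonds$a == b & query$bonds$b == a))
    if (length(k) == 0) NA_real_ else query$bonds$order[k[1]]
  }
  t_bond <- function(a, b) {
    k <- which((mol$bonds$a == a & mol$bonds$b == b) |
               (mol$bonds$a == b & mol$bonds$b == a))
    if (length(k) == 0) NA_real_ else mol$bonds$order[k[1]]
  }
  # order query atoms so each new atom (after the first) touches the mapped set
  ord <- integer(0)
  remaining <- seq_len(nq)
  while (length(remaining) > 0) {
    if (length(ord) == 0) {
      nxt <- remaining[1]
    } else {
      touching <- remaining[vapply(remaining, function(q)
        any(q_adj[[q]] %in% ord), logical(1))]
      nxt <- if (length(touching) > 0) touching[1] else remaining[1]
    }
    ord <- c(ord, nxt)
    remaining <- setdiff(remaining, nxt)
  }

  mapping <- integer(nq)  # query atom -> target atom (0 = unmapped)
  used <- logical(nt)

  try_extend <- function(pos) {
    if (pos > nq) return(TRUE)
    qi <- ord[pos]
    mapped_nb <- q_adj[[qi]][mapping[q_adj[[qi]]] != 0]
    candidates <- if (length(mapped_nb) > 0) {
      t_adj[[mapping[mapped_nb[1]]]]
    } else {
      seq_len(nt)
    }
    for (ti in candidates) {
      if (used[ti]) next
      if (!atom_compatible(query$atoms, qi, mol$atoms, ti)) next
      ok <- TRUE
      for (qn in mapped_nb) {
        qo <- q_bond(qi, qn)
        to <- t_bond(ti, mapping[qn])
        if (is.na(to) || !bond_orders_match(qo, to)) { ok <- FALSE; break }
      }
      # degree feasibility
      if (ok && length(q_adj[[qi]]) > length(t_adj[[ti]])) ok <- FALSE
      if (ok) {
        mapping[qi] <<- ti; used[ti] <<- TRUE
        if (try_extend(pos + 1)) return(TRUE)
        mapping[qi] <<- 0L; used[ti] <<- FALSE
      }
    }
    FALSE
  }
  try_extend(1)
}

bond_orders_match <- function(qo, to) {
  if (qo == 1.5 || to == 1.5) return(qo == to)
  qo == to
}

# parse a pattern library (named character vector of SMILES) once, with
# load-time validation that names the offending pattern
parse_pattern_library <- function(patterns) {
  out <- vector("list", length(patterns))
  names(out) <- names(patterns)
  for (nm in names(patterns)) {
    out[[nm]] <- tryCatch(parse_smiles(patterns[[nm]], id = nm),
      error = function(e) stopf("invalid substructure pattern '%s': %s",
                                nm, conditionMessage(e)))
  }
  out
}
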