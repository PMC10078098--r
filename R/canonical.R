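# Canonical atom ranking (Morgan-style iterative refinement) and a SMILES
# writer driven by it. Canonical forms are an *internal* equality key — two
# molecules with the same graph yield the same string regardless of input
# atom order — and are not expected to match any other toolkit's canonical
# output.

canonical_ranks <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- adjacency_list(mol)
  bond_order_of <- function(a, b) {
    k <- which((mol$bonds$a == a & mol$bonds$b == b) |
               (mol$bonds$a == b & mol$bonds$b == a))
    mol$bonds$order[k[1]]
  }
  inv <- paste(mol$atoms$element, mol$atoms$charge, mol$atoms$aromatic,
               mol$atoms$h, mol$atoms$degree, mol$atoms$in_ring, sep = "|")
  rank <- as.integer(factor(inv, levels = sort(unique(inv))))

  refine <- function(rank) {
    repeat {
      sig <- character(n)
      for (i in seq_len(n)) {
        nb <- adj[[i]]
        if (length(nb) > 0) {
          pairs <- sort(vapply(nb, function(j)
            sprintf("%04.1f:%06d", bond_order_of(i, j), rank[j]), character(1)))
          sig[i] <- paste0(rank[i], "#", paste(pairs, collapse = ","))
        } else {
          sig[i] <- paste0(rank[i], "#")
        }
      }
      new_rank <- as.integer(factor(sig, levels = sort(unique(sig))))
      # each pass subdivides classes (sig embeds the old rank); when the class
      # count stops growing the partition is stable and labels are canonical
      if (length(unique(new_rank)) == length(unique(rank))) return(new_rank)
      rank <- new_rank
    }
  }
  rank <- refine(rank)
  # tie-breaking: symmetric atoms share a class; split deterministically
  while (length(unique(rank)) < n) {
    tab <- table(rank)
    tied <- as.integer(names(tab)[tab > 1])
    cls <- min(tied)
    members <- which(rank == cls)
    rank <- rank * 2L
    rank[members[1]] <- rank[members[1]] - 1L
    rank <- as.integer(factor(rank, levels = sort(unique(rank))))
    rank <- refine(rank)
  }
  rank
}

#' Write a molecule as SMILES
#'
#' Produces the package's canonical linear notation: atoms emitted in
#' canonical-rank order, aromatic atoms lowercase, bracket atoms only where
#' charge or a non-default hydrogen count requires them.
#'
#' @param mol a `cvs_molecule`
#' @return character SMILES
#' @export
write_smiles <- function(mol) {
  n <- nrow(mol$atoms)
  rank <- canonical_ranks(mol)
  adj <- adjacency_list(mol)
  bk <- function(a, b) which((mol$bonds$a == a & mol$bonds$b == b) |
                             (mol$bonds$a == b & mol$bonds$b == a))[1]

  atom_token <- function(i) {
    el <- mol$atoms$element[i]
    arom <- mol$atoms$aromatic[i]
    sym <- if (arom) tolower(el) else el
    chg <- mol$atoms$charge[i]
    hh <- mol$atoms$h[i]
    need_bracket <- chg != 0 ||
      !(el %in% c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")) ||
      (arom && el == "N" && hh > 0) ||
      implied_h(el, chg, i) != hh
    if (!need_bracket) return(sym)
    hpart <- if (hh == 1) "H" else if (hh > 1) paste0("H", hh) else ""
    cpart <- if (chg == 1) "+" else if (chg == -1) "-"
      else if (chg > 1) paste0("+", chg) else if (chg < -1) as.character(chg) else ""
    paste0("[", sym, hpart, cpart, "]")
  }
  # hydrogens the reader would infer for an unbracketed atom i
  implied_h <- function(el, chg, i) {
    if (chg != 0) return(-1L)
    nb <- adj[[i]]
    bsum <- 0
    for (j in nb) bsum <- bsum + mol$bonds$order[bk(i, j)]
    dv <- tryCatch(default_valence(el, 0L), error = function(e) return(-1L))
    max(0L, as.integer(dv - ceiling(bsum - 1e-9)))
  }
  bond_symbol <- function(k) {
    o <- mol$bonds$order[k]
    if (o == 2) "=" else if (o == 3) "#" else ""
  }

  # Pass 1: DFS in canonical-neighbour order to classify edges. Non-tree
  # edges become ring closures; each gets a digit recorded at both endpoints
  # so pass 2 can emit the digit at the atom encountered first.
  visited <- logical(n)
  tree_edge <- logical(nrow(mol$bonds))
  seen_edge <- logical(nrow(mol$bonds))
  closure_at <- vector("list", n)   # atom -> character digit tokens
  next_digit <- 0L
  order_children <- vector("list", n)

  dfs1 <- function(i) {
    visited[i] <<- TRUE
    nb <- adj[[i]][order(rank[adj[[i]]])]
    for (j in nb) {
      k <- bk(i, j)
      if (seen_edge[k]) next
      seen_edge[k] <<- TRUE
      if (!visited[j]) {
        tree_edge[k] <<- TRUE
        order_children[[i]] <<- c(order_children[[i]], j)
        dfs1(j)
      } else {
        next_digit <<- next_digit + 1L
        d <- if (next_digit < 10) as.character(next_digit) else sprintf("%%%02d", next_digit)
        tokn <- paste0(bond_symbol(k), d)
        closure_at[[i]] <<- c(closure_at[[i]], tokn)
        closure_at[[j]] <<- c(closure_at[[j]], tokn)
      }
    }
  }

  # Pass 2: assemble the string along the tree edges.
  emit <- function(i, from_bond) {
    closures <- paste(closure_at[[i]] %||% character(), collapse = "")
    piece <- paste0(if (is.na(from_bond)) "" else bond_symbol(from_bond),
                    atom_token(i), closures)
    kids <- order_children[[i]] %||% integer()
    kid_strs <- vapply(kids, function(j) emit(j, bk(i, j)), character(1))
    if (length(kid_strs) > 1) {
      piece <- paste0(piece,
                      paste0("(", kid_strs[-length(kid_strs)], ")", collapse = ""),
                      kid_strs[length(kid_strs)])
    } else if (length(kid_strs) == 1) {
      piece <- paste0(piece, kid_strs)
    }
    piece
  }

  comps <- components_of(mol)
  starts <- vapply(comps, function(comp) comp[which.min(rank[comp])], integer(1))
  frags <- character()
  for (start in starts[order(vapply(comps, function(comp) min(rank[comp]), integer(1)))]) {
    dfs1(start)
    frags <- c(frags, emit(start, NA_integer_))
  }
  paste(frags, collapse = ".")
}

#' Canonical SMILES of a molecule
#'
#' Equality of the returned strings is the package's molecule-identity test.
#'
#' @param mol a `cvs_molecule`
#' @return character
#' @export
canonical_smiles <- function(mol) write_smiles(mol)
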