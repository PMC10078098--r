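#' Parse a SMILES string
#'
#' Supports the organic subset (B, C, N, O, P, S, F, Cl, Br, I), aromatic
#' lowercase atoms, bracket atoms with charge/explicit H/isotope, branches,
#' ring closures (including %nn), bond symbols -, =, #, :, and dot-separated
#' fragments. Stereo markers (/ \ @) are accepted and discarded; conformers
#' and stereochemistry are out of scope.
#'
#' After graph construction, implicit hydrogens are materialised
#' (default-valence rule), ring membership is perceived, and aromaticity is
#' perceived for Kekule-written rings (6-membered C/N rings with alternating
#' double bonds; 5-membered C/N/O/S rings with two double bonds and a
#' lone-pair heteroatom), so `c1ccccc1` and `C1=CC=CC=C1` yield the same
#' molecule.
#'
#' @param text SMILES string
#' @param id identifier attached to the molecule (used in error messages)
#' @return a `cvs_molecule`
#' @export
parse_smiles <- function(text, id = text) {
  if (!is.character(text) || length(text) != 1 || is.na(text) || nchar(text) == 0) {
    stopf("SMILES parse error in record '%s': empty or non-string input", id)
  }
  tokens <- tokenize_smiles(text, id)

  element <- character(); charge <- integer(); aromatic <- logical()
  h_explicit <- integer()   # NA = implicit (organic subset), >=0 from brackets
  bond_a <- integer(); bond_b <- integer(); bond_o <- numeric()

  prev <- NA_integer_
  pending_order <- NA_real_
  stack <- integer()
  ringmap <- list()  # digit -> list(atom, order)

  add_atom <- function(sym, arom, chg, hh) {
    element[length(element) + 1] <<- sym
    aromatic[length(aromatic) + 1] <<- arom
    charge[length(charge) + 1] <<- chg
    h_explicit[length(h_explicit) + 1] <<- hh
    length(element)
  }
  add_bond <- function(a, b, o) {
    bond_a[length(bond_a) + 1] <<- a
    bond_b[length(bond_b) + 1] <<- b
    bond_o[length(bond_o) + 1] <<- o
  }

  for (tok in tokens) {
    kind <- tok$kind
    if (kind == "atom") {
      idx <- add_atom(tok$element, tok$aromatic, tok$charge, tok$h)
      if (!is.na(prev)) {
        o <- pending_order
        if (is.na(o)) {
          o <- if (aromatic[prev] && tok$aromatic) 1.5 else 1
        }
        add_bond(prev, idx, o)
      }
      prev <- idx
      pending_order <- NA_real_
    } else if (kind == "bond") {
      pending_order <- tok$order
    } else if (kind == "open") {
      if (is.na(prev)) stopf("SMILES parse error in record '%s': '(' before any atom", id)
      stack <- c(stack, prev)
    } else if (kind == "close") {
      if (length(stack) == 0) stopf("SMILES parse error in record '%s': unmatched ')'", id)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (kind == "ring") {
      key <- as.character(tok$num)
      if (is.na(prev)) stopf("SMILES parse error in record '%s': ring digit before atom", id)
      if (is.null(ringmap[[key]])) {
        ringmap[[key]] <- list(atom = prev, order = pending_order)
      } else {
        open <- ringmap[[key]]
        o <- pending_order
        if (is.na(o)) o <- open$order
        if (is.na(o)) o <- if (aromatic[open$atom] && aromatic[prev]) 1.5 else 1
        add_bond(open$atom, prev, o)
        ringmap[[key]] <- NULL
      }
      pending_order <- NA_real_
    } else if (kind == "dot") {
      prev <- NA_integer_
      pending_order <- NA_real_
    }
  }
  open_rings <- names(ringmap)[!vapply(ringmap, is.null, logical(1))]
  if (length(open_rings) > 0) {
    stopf("SMILES parse error in record '%s': unclosed ring bond(s) %s",
          id, paste(open_rings, collapse = ","))
  }
  if (length(stack) > 0) stopf("SMILES parse error in record '%s': unmatched '('", id)
  if (length(element) == 0) stopf("SMILES parse error in record '%s': no atoms", id)

  atoms <- data.frame(element = element, charge = charge, aromatic = aromatic,
                      h = 0L, h_spec = h_explicit, stringsAsFactors = FALSE)
  bonds <- data.frame(a = bond_a, b = bond_b, order = bond_o)
  # implicit hydrogens
  bsum <- numeric(nrow(atoms))
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      bsum[bonds$a[k]] <- bsum[bonds$a[k]] + bonds$order[k]
      bsum[bonds$b[k]] <- bsum[bonds$b[k]] + bonds$order[k]
    }
  }
  for (i in seq_len(nrow(atoms))) {
    if (!is.na(h_explicit[i])) {
      atoms$h[i] <- h_explicit[i]
    } else {
      dv <- default_valence(atoms$element[i], atoms$charge[i])
      atoms$h[i] <- max(0L, as.integer(dv - ceiling(bsum[i] - 1e-9)))
    }
  }

  mol <- new_molecule(id = id, atoms = atoms, bonds = bonds, source = "smiles")
  mol <- perceive_aromaticity(mol)
  mol
}

# organic-subset default valences; charge shifts valence for N+/O- style atoms
default_valence <- function(el, charge = 0L) {
  base <- switch(el,
    B = 3L, C = 4L, N = 3L, O = 2L, P = 3L, S = 2L,
    F = 1L, Cl = 1L, Br = 1L, I = 1L, H = 1L,
    stopf("no default valence for element '%s'", el))
  if (el %in% c("N", "P")) base + as.integer(charge)
  else if (el %in% c("O", "S")) base + as.integer(charge)
  else base
}

AROMATIC_OK <- c("b", "c", "n", "o", "p", "s")

tokenize_smiles <- function(text, id) {
  chars <- strsplit(text, "")[[1]]
  i <- 1; n <- length(chars)
  tokens <- list()
  push <- function(t) tokens[[length(tokens) + 1]] <<- t
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1
      if (j > n) stopf("SMILES parse error in record '%s': unterminated bracket", id)
      push(parse_bracket_atom(paste(chars[(i + 1):(j - 1)], collapse = ""), id))
      i <- j + 1
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1] %in% c("l", "r") &&
               paste0(ch, chars[i + 1]) %in% c("Cl", "Br")) {
      push(list(kind = "atom", element = paste0(ch, chars[i + 1]),
                aromatic = FALSE, charge = 0L, h = NA_integer_))
      i <- i + 2
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      push(list(kind = "atom", element = ch, aromatic = FALSE,
                charge = 0L, h = NA_integer_))
      i <- i + 1
    } else if (ch %in% AROMATIC_OK) {
      push(list(kind = "atom", element = toupper(ch), aromatic = TRUE,
                charge = 0L, h = NA_integer_))
      i <- i + 1
    } else if (grepl("[0-9]", ch)) {
      push(list(kind = "ring", num = as.integer(ch)))
      i <- i + 1
    } else if (ch == "%") {
      if (i + 2 > n) stopf("SMILES parse error in record '%s': bad %% ring id", id)
      push(list(kind = "ring", num = as.integer(paste0(chars[i + 1], chars[i + 2]))))
      i <- i + 3
    } else if (ch == "-") {
      push(list(kind = "bond", order = 1)); i <- i + 1
    } else if (ch == "=") {
      push(list(kind = "bond", order = 2)); i <- i + 1
    } else if (ch == "#") {
      push(list(kind = "bond", order = 3)); i <- i + 1
    } else if (ch == ":") {
      push(list(kind = "bond", order = 1.5)); i <- i + 1
    } else if (ch == "(") {
      push(list(kind = "open")); i <- i + 1
    } else if (ch == ")") {
      push(list(kind = "close")); i <- i + 1
    } else if (ch == ".") {
      push(list(kind = "dot")); i <- i + 1
    } else if (ch %in% c("/", "\\")) {
      i <- i + 1  # stereo bond marker: ignored
    } else {
      stopf("SMILES parse error in record '%s': unexpected character '%s' at position %d",
            id, ch, i)
    }
  }
  tokens
}

parse_bracket_atom <- function(body, id) {
  # [isotope? symbol chiral? Hcount? charge? (:class)?]
  m <- regmatches(body, regexec(
    "^([0-9]*)([A-Za-z][a-z]?)(@{1,2})?(H[0-9]*)?([+-][0-9+-]*)?(:[0-9]+)?$", body))[[1]]
  if (length(m) == 0) {
    stopf("SMILES parse error in record '%s': bad bracket atom [%s]", id, body)
  }
  sym <- m[3]
  aromatic <- sym %in% AROMATIC_OK
  if (aromatic) sym <- paste0(toupper(substr(sym, 1, 1)),
                              substring(sym, 2))
  # explicit H count (default 0 inside brackets)
  hh <- 0L
  if (nzchar(m[5])) {
    hh <- if (m[5] == "H") 1L else as.integer(substring(m[5], 2))
  }
  chg <- 0L
  if (nzchar(m[6])) {
    cs <- m[6]
    if (cs %in% c("+", "-")) chg <- if (cs == "+") 1L else -1L
    else if (grepl("^[+-][0-9]+$", cs)) chg <- as.integer(cs)
    else chg <- sum(ifelse(strsplit(cs, "")[[1]] == "+", 1L, -1L))
  }
  list(kind = "atom", element = sym, aromatic = aromatic, charge = chg, h = hh)
}

# Perceive aromaticity on Kekule-written rings and normalise aromatic ring
# bond orders to 1.5. Conservative Hueckel subset:
#  - 6-ring, all atoms C or N, every atom carries exactly one double bond to a
#    ring neighbour (benzene, pyridine, pyrimidine, ...)
#  - 5-ring, atoms in {C,N,O,S}, exactly two ring double bonds, and the
#    remaining atom is a lone-pair donor (N, O, or S) (pyrrole, furan,
#    thiophene, imidazole, ...)
# Exocyclic doubles (tropone, quinone) block perception, as intended.
perceive_aromaticity <- function(mol) {
  rings <- smallest_rings(mol)
  if (length(rings) == 0) return(mol)
  bond_key <- paste(pmin(mol$bonds$a, mol$bonds$b), pmax(mol$bonds$a, mol$bonds$b))
  bond_idx <- function(a, b) match(paste(min(a, b), max(a, b)), bond_key)
  changed <- FALSE
  for (ring in rings) {
    sz <- length(ring)
    if (!(sz %in% c(5L, 6L))) next
    els <- mol$atoms$element[ring]
    if (any(mol$atoms$aromatic[ring])) {
      # written aromatic already; ensure ring bonds are 1.5
      if (all(mol$atoms$aromatic[ring])) {
        for (k in seq_len(sz)) {
          bi <- bond_idx(ring[k], ring[if (k == sz) 1 else k + 1])
          if (!is.na(bi) && mol$bonds$order[bi] != 1.5) {
            mol$bonds$order[bi] <- 1.5; changed <- TRUE
          }
        }
      }
      next
    }
    ok_el <- if (sz == 6L) all(els %in% c("C", "N")) else all(els %in% c("C", "N", "O", "S"))
    if (!ok_el) next
    ring_bond_ids <- integer(sz)
    for (k in seq_len(sz)) {
      ring_bond_ids[k] <- bond_idx(ring[k], ring[if (k == sz) 1 else k + 1])
    }
    if (any(is.na(ring_bond_ids))) next
    orders <- mol$bonds$order[ring_bond_ids]
    if (all(orders == 1.5)) {
      # aromatic bond orders without atom flags (SDF bond type 4 input)
      mol$atoms$aromatic[ring] <- TRUE
      changed <- TRUE
      next
    }
    ndouble <- sum(orders == 2)
    # double bonds incident to each ring atom, counting only ring bonds
    dcount <- vapply(ring, function(a) {
      sum(orders == 2 & (mol$bonds$a[ring_bond_ids] == a |
                         mol$bonds$b[ring_bond_ids] == a))
    }, numeric(1))
    # exocyclic double bond on a ring atom disqualifies (cross-conjugation)
    has_exo_double <- any(vapply(ring, function(a) {
      inc <- which((mol$bonds$a == a | mol$bonds$b == a) & mol$bonds$order == 2)
      any(!(inc %in% ring_bond_ids))
    }, logical(1)))
    if (has_exo_double) next
    aromatic_ok <- if (sz == 6L) {
      ndouble == 3 && all(dcount == 1)
    } else {
      lp <- which(dcount == 0)
      ndouble == 2 && length(lp) == 1 && els[lp] %in% c("N", "O", "S")
    }
    if (aromatic_ok) {
      mol$atoms$aromatic[ring] <- TRUE
      mol$bonds$order[ring_bond_ids] <- 1.5
      changed <- TRUE
    }
  }
  if (changed) mol <- finalize_molecule(mol)
  mol
}

#' Parse a SMILES library file
#'
#' One record per line: `SMILES` optionally followed by a tab or whitespace
#' separated identifier. Unparsable records are logged and skipped; the batch
#' never aborts.
#'
#' @param path file path
#' @return list of `cvs_molecule`
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (k in seq_along(lines)) {
    parts <- strsplit(trimws(lines[k]), "[ \t]+")[[1]]
    smi <- parts[1]
    id <- if (length(parts) >= 2) parts[2] else sprintf("mol_%d", k)
    mol <- tryCatch(parse_smiles(smi, id = id), error = function(e) {
      cvs_log(sprintf("skipping record %d ('%s'): %s", k, id, conditionMessage(e)))
      NULL
    })
    if (!is.null(mol)) out[[length(out) + 1]] <- mol
  }
  out
}
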