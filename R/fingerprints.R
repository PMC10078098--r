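#' Molecular fingerprints
#'
#' Two fingerprint kinds drive the dual similarity screen:
#' \describe{
#'   \item{structural_keys_166}{a 166-slot structural-key fingerprint. Each
#'     defined key encodes presence of a substructure or graph feature
#'     (element classes, ring sizes, functional groups, branching, charges);
#'     undefined slots stay zero. The key catalogue is a documented subset in
#'     the spirit of the classic 166-bit key sets, not a bit-for-bit clone of
#'     any vendor definition.}
#'   \item{circular_r2}{a circular (Morgan-style) fingerprint of radius 2
#'     (diameter-4 neighbourhoods) hashed to `nbits` positions, default 2048.
#'     Atom initial invariants: element, heavy degree, attached H, charge,
#'     aromaticity, ring membership.}
#' }
#'
#' @param mol a `cvs_molecule`
#' @param kind "structural_keys_166" or "circular_r2"
#' @param nbits width for the circular kind (default 2048; fixed 166 for keys)
#' @return a `cvs_fingerprint`: list(kind, nbits, bits = sorted integer
#'   positions, 0-based)
#' @export
compute_fingerprint <- function(mol, kind = c("structural_keys_166", "circular_r2"),
                                nbits = 2048L) {
  kind <- match.arg(kind)
  bits <- if (kind == "structural_keys_166") {
    nbits <- 166L
    structural_key_bits(mol)
  } else {
    circular_bits(mol, radius = 2L, nbits = nbits)
  }
  structure(list(kind = kind, nbits = as.integer(nbits),
                 bits = sort(unique(as.integer(bits)))),
            class = "cvs_fingerprint")
}

#' Tanimoto coefficient between two fingerprints
#'
#' |A intersect B| / |A union B| over set bit positions; defined as 0 when
#' both sets are empty.
#'
#' @param a,b `cvs_fingerprint` objects of the same kind and width
#' @return numeric in [0, 1]
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "cvs_fingerprint"), inherits(b, "cvs_fingerprint"))
  if (a$kind != b$kind || a$nbits != b$nbits) {
    stopf("tanimoto: fingerprint kind/width mismatch (%s/%d vs %s/%d)",
          a$kind, a$nbits, b$kind, b$nbits)
  }
  u <- length(union(a$bits, b$bits))
  if (u == 0) return(0)
  length(intersect(a$bits, b$bits)) / u
}

# ---- structural keys ------------------------------------------------------

# pattern-backed keys: slot -> SMILES pattern (matched with the package's
# substructure engine)
structural_key_patterns <- function() {
  c(
    `10` = "C=O",             # carbonyl
    `12` = "OC=O",            # carboxylic acid / ester oxygen
    `15` = "NC=O",            # amide
    `18` = "C#N",             # nitrile
    `21` = "OCO",             # acetal-like
    `24` = "N=O",
    `27` = "CO",              # C-O single
    `30` = "CN",
    `33` = "C=C",
    `36` = "C#C",
    `39` = "OO",
    `42` = "SC",
    `45` = "S=O",
    `48` = "OCC=O",
    `51` = "NCC=O",
    `54` = "COC",             # ether
    `57` = "CCO",             # C-C-O linkage
    `60` = "c1ccccc1",        # benzene ring
    `63` = "OCCO",
    `66` = "NCCN",
    `69` = "CC(C)C",          # isopropyl branch
    `72` = "CC(C)(C)C",       # tert-butyl branch
    `75` = "OP",              # P-O
    `78` = "NS",              # N-S
    `81` = "ClC",             # C-Cl
    `84` = "BrC",
    `87` = "IC",
    `90` = "FC",
    `93` = "CCCCCC",          # chain length >= 6
    `96` = "CCCC",            # chain length >= 4
    `99` = "NN"
  )
}

.pattern_cache <- new.env(parent = emptyenv())

structural_key_library <- function() {
  if (is.null(.pattern_cache$skeys)) {
    .pattern_cache$skeys <- parse_pattern_library(structural_key_patterns())
  }
  .pattern_cache$skeys
}

structural_key_bits <- function(mol) {
  a <- mol$atoms
  bits <- integer(0)
  set <- function(slot, cond) if (isTRUE(cond)) bits <<- c(bits, slot)

  # element / composition keys (slots 100+)
  set(100L, any(a$element == "N"))
  set(101L, sum(a$element == "N") >= 2)
  set(102L, any(a$element == "O"))
  set(103L, sum(a$element == "O") >= 2)
  set(104L, sum(a$element == "O") >= 4)
  set(105L, any(a$element == "S"))
  set(106L, any(a$element == "P"))
  set(107L, any(a$element %in% c("F", "Cl", "Br", "I")))
  set(108L, sum(a$element %in% c("F", "Cl", "Br", "I")) >= 2)
  set(109L, any(a$element == "B"))
  set(110L, any(a$charge > 0))
  set(111L, any(a$charge < 0))
  set(112L, any(a$element == "N" & a$h >= 1))
  set(113L, any(a$element == "N" & a$h >= 2))
  set(114L, any(a$element == "O" & a$h >= 1))
  set(115L, sum(a$element == "O" & a$h >= 1) >= 2)
  set(116L, any(a$element == "C" & a$h >= 3))               # methyl
  set(117L, sum(a$element == "C" & a$h >= 3) >= 2)
  set(118L, sum(a$element == "C" & a$h >= 3) >= 3)
  set(119L, any(a$degree >= 4))
  set(120L, any(a$element == "N" & a$aromatic))
  set(121L, any(a$element == "O" & a$aromatic))
  set(122L, any(a$element == "S" & a$aromatic))

  # ring keys
  rings <- smallest_rings(mol)
  sizes <- vapply(rings, length, integer(1))
  set(130L, length(rings) >= 1)
  set(131L, length(rings) >= 2)
  set(132L, length(rings) >= 3)
  set(133L, any(sizes == 3))
  set(134L, any(sizes == 4))
  set(135L, any(sizes == 5))
  set(136L, any(sizes == 6))
  set(137L, any(sizes == 7))
  set(138L, any(sizes >= 8))
  set(139L, any(a$aromatic))
  arom_rings <- sum(vapply(rings, function(r) all(a$aromatic[r]), logical(1)))
  set(140L, arom_rings >= 1)
  set(141L, arom_rings >= 2)
  set(142L, any(a$in_ring & a$element != "C"))              # heterocycle
  set(143L, any(a$in_ring & a$element == "N"))
  set(144L, any(a$in_ring & a$element == "O"))
  set(145L, any(a$in_ring & a$element == "S"))
  # fused rings: two smallest rings sharing >= 2 atoms
  fused <- FALSE
  if (length(rings) >= 2) {
    for (i in seq_len(length(rings) - 1)) {
      for (j in (i + 1):length(rings)) {
        if (length(intersect(rings[[i]], rings[[j]])) >= 2) { fused <- TRUE; break }
      }
      if (fused) break
    }
  }
  set(146L, fused)
  # ring with exocyclic carbonyl
  if (nrow(mol$bonds) > 0) {
    exo_co <- any(vapply(seq_len(nrow(mol$bonds)), function(k) {
      b <- mol$bonds[k, ]
      b$order == 2 && !b$in_ring &&
        ((a$in_ring[b$a] && a$element[b$b] == "O") ||
         (a$in_ring[b$b] && a$element[b$a] == "O"))
    }, logical(1)))
    set(147L, exo_co)
  }
  set(148L, heavy_atom_count(mol) >= 20)
  set(149L, heavy_atom_count(mol) >= 30)

  # substructure-pattern keys
  lib <- structural_key_library()
  for (nm in names(lib)) {
    if (has_substructure(mol, lib[[nm]])) bits <- c(bits, as.integer(nm))
  }
  # hydroxyl (O with H on carbon) as an H-constrained pattern
  if (any(a$element == "O" & a$h >= 1 & a$degree == 1)) bits <- c(bits, 58L)
  bits[bits < 166L]
}

# ---- circular fingerprint -------------------------------------------------

circular_bits <- function(mol, radius = 2L, nbits = 2048L) {
  n <- nrow(mol$atoms)
  adj <- adjacency_list(mol)
  bond_order_of <- function(a, b) {
    k <- which((mol$bonds$a == a & mol$bonds$b == b) |
               (mol$bonds$a == b & mol$bonds$b == a))
    mol$bonds$order[k[1]]
  }
  a <- mol$atoms
  ids <- vapply(seq_len(n), function(i) {
    fnv1a(paste(a$element[i], a$degree[i], a$h[i], a$charge[i],
                a$aromatic[i], a$in_ring[i], sep = ";"))
  }, numeric(1))
  all_ids <- ids
  cur <- ids
  for (r in seq_len(radius)) {
    nxt <- numeric(n)
    for (i in seq_len(n)) {
      nb <- adj[[i]]
      if (length(nb) > 0) {
        parts <- sort(vapply(nb, function(j)
          sprintf("%.1f:%.0f", bond_order_of(i, j), cur[j]), character(1)))
        nxt[i] <- fnv1a(paste0(r, "|", format(cur[i], digits = 15), "|",
                               paste(parts, collapse = ",")))
      } else {
        nxt[i] <- cur[i]
      }
    }
    cur <- nxt
    all_ids <- c(all_ids, cur)
  }
  unique(as.integer(all_ids %% nbits))
}

#' @export
print.cvs_fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint %s: %d/%d bits set>\n", x$kind, length(x$bits), x$nbits))
  invisible(x)
}
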