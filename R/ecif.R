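#' ECIF atom type of a heavy atom
#'
#' The extended-connectivity interaction-feature atom type is the tuple
#' (element; explicit valence; heavy degree; attached hydrogens; aromatic;
#' in ring), rendered canonically as "El;v;d;h;a;r" with a/r as 1/0 so type
#' strings are order-comparable. Hydrogens are never typed.
#'
#' @param mol a `cvs_molecule` (perception already done by the parsers)
#' @param i atom index
#' @return character type string
#' @export
ecif_atom_type <- function(mol, i) {
  a <- mol$atoms[i, ]
  if (a$element == "H") stopf("ecif_atom_type: hydrogens are not typed")
  sprintf("%s;%d;%d;%d;%d;%d", a$element, a$valence, a$degree, a$h,
          as.integer(a$aromatic), as.integer(a$in_ring))
}

# ---- protein atom typing from residue templates ---------------------------
# PDB files carry no bonds; protein heavy atoms are typed from standard
# amino-acid connectivity. Columns: valence, heavy degree (internal residue
# bonds plus backbone peptide links), attached H, aromatic, ring.
# Terminal adjustments (OXT, N-terminal NH3+) are ignored: mid-chain
# environments are assumed, and nonstandard residues are skipped with a
# warning.
protein_atom_templates <- function() {
  if (!is.null(.pattern_cache$prot_templates)) return(.pattern_cache$prot_templates)
  txt <- "
res atom el v d h ar ring
ALL N  N 3 2 1 0 0
ALL CA C 4 3 1 0 0
ALL C  C 4 3 0 0 0
ALL O  O 2 1 0 0 0
GLY CA C 4 2 2 0 0
ALA CB C 4 1 3 0 0
VAL CB C 4 3 1 0 0
VAL CG1 C 4 1 3 0 0
VAL CG2 C 4 1 3 0 0
LEU CB C 4 2 2 0 0
LEU CG C 4 3 1 0 0
LEU CD1 C 4 1 3 0 0
LEU CD2 C 4 1 3 0 0
ILE CB C 4 3 1 0 0
ILE CG1 C 4 2 2 0 0
ILE CG2 C 4 1 3 0 0
ILE CD1 C 4 1 3 0 0
MET CB C 4 2 2 0 0
MET CG C 4 2 2 0 0
MET SD S 2 2 0 0 0
MET CE C 4 1 3 0 0
CYS CB C 4 2 2 0 0
CYS SG S 2 1 1 0 0
SER CB C 4 2 2 0 0
SER OG O 2 1 1 0 0
THR CB C 4 3 1 0 0
THR OG1 O 2 1 1 0 0
THR CG2 C 4 1 3 0 0
ASN CB C 4 2 2 0 0
ASN CG C 4 3 0 0 0
ASN OD1 O 2 1 0 0 0
ASN ND2 N 3 1 2 0 0
GLN CB C 4 2 2 0 0
GLN CG C 4 2 2 0 0
GLN CD C 4 3 0 0 0
GLN OE1 O 2 1 0 0 0
GLN NE2 N 3 1 2 0 0
ASP CB C 4 2 2 0 0
ASP CG C 4 3 0 0 0
ASP OD1 O 2 1 0 0 0
ASP OD2 O 2 1 1 0 0
GLU CB C 4 2 2 0 0
GLU CG C 4 2 2 0 0
GLU CD C 4 3 0 0 0
GLU OE1 O 2 1 0 0 0
GLU OE2 O 2 1 1 0 0
LYS CB C 4 2 2 0 0
LYS CG C 4 2 2 0 0
LYS CD C 4 2 2 0 0
LYS CE C 4 2 2 0 0
LYS NZ N 4 1 3 0 0
ARG CB C 4 2 2 0 0
ARG CG C 4 2 2 0 0
ARG CD C 4 2 2 0 0
ARG NE N 3 2 1 0 0
ARG CZ C 4 3 0 0 0
ARG NH1 N 3 1 2 0 0
ARG NH2 N 4 1 2 0 0
HIS CB C 4 2 2 0 0
HIS CG C 4 2 0 1 1
HIS ND1 N 3 2 1 1 1
HIS CD2 C 4 2 1 1 1
HIS CE1 C 4 2 1 1 1
HIS NE2 N 3 2 0 1 1
PHE CB C 4 2 2 0 0
PHE CG C 4 3 0 1 1
PHE CD1 C 4 2 1 1 1
PHE CD2 C 4 2 1 1 1
PHE CE1 C 4 2 1 1 1
PHE CE2 C 4 2 1 1 1
PHE CZ C 4 2 1 1 1
TYR CB C 4 2 2 0 0
TYR CG C 4 3 0 1 1
TYR CD1 C 4 2 1 1 1
TYR CD2 C 4 2 1 1 1
TYR CE1 C 4 2 1 1 1
TYR CE2 C 4 2 1 1 1
TYR CZ C 4 3 0 1 1
TYR OH O 2 1 1 0 0
TRP CB C 4 2 2 0 0
TRP CG C 4 3 0 1 1
TRP CD1 C 4 2 1 1 1
TRP CD2 C 4 3 0 1 1
TRP NE1 N 3 2 1 1 1
TRP CE2 C 4 3 0 1 1
TRP CE3 C 4 2 1 1 1
TRP CZ2 C 4 2 1 1 1
TRP CZ3 C 4 2 1 1 1
TRP CH2 C 4 2 1 1 1
PRO CB C 4 2 2 0 1
PRO CG C 4 2 2 0 1
PRO CD C 4 2 2 0 1
"
  tab <- utils::read.table(text = txt, header = TRUE, stringsAsFactors = FALSE)
  .pattern_cache$prot_templates <- tab
  tab
}

STANDARD_RESIDUES <- c("GLY", "ALA", "VAL", "LEU", "ILE", "MET", "CYS", "SER",
                       "THR", "ASN", "GLN", "ASP", "GLU", "LYS", "ARG", "HIS",
                       "PHE", "TYR", "TRP", "PRO")

protein_atom_type <- function(res_name, atom_name) {
  tab <- protein_atom_templates()
  if (!(res_name %in% STANDARD_RESIDUES)) return(NA_character_)
  row <- tab[tab$res == res_name & tab$atom == atom_name, ]
  if (nrow(row) == 0) row <- tab[tab$res == "ALL" & tab$atom == atom_name, ]
  if (nrow(row) == 0) return(NA_character_)
  r <- row[1, ]
  sprintf("%s;%d;%d;%d;%d;%d", r$el, r$v, r$d, r$h, r$ar, r$ring)
}

#' ECIF feature vector of a protein-ligand complex
#'
#' Counts typed protein-atom/ligand-atom pairs with Euclidean distance at or
#' below the cutoff (default 6.0 A, inclusive). Ligand atoms are typed from
#' the supplied molecule (`ligand_mol`, atom order matching the complex's
#' ligand block); protein atoms from residue templates. Protein atoms in
#' nonstandard residues are skipped with a warning.
#'
#' @param complex a `cvs_complex`
#' @param ligand_mol `cvs_molecule` giving the ligand connection table; if
#'   NULL, a pre-attached `complex$ligand_types` character vector is used
#' @param cutoff distance cutoff in Angstroms
#' @return a `cvs_ecif`: list(counts = named integer vector keyed
#'   "p_type|l_type", cutoff)
#' @export
ecif_features <- function(complex, ligand_mol = NULL, cutoff = 6.0) {
  stopifnot(inherits(complex, "cvs_complex"))
  if (nrow(complex$ligand) == 0) stopf("ecif_features: empty ligand")
  if (is.null(ligand_mol)) {
    l_types <- complex$ligand_types
    if (is.null(l_types)) stopf("ecif_features: ligand typing requires ligand_mol or ligand_types")
  } else {
    if (heavy_atom_count(ligand_mol) != nrow(complex$ligand)) {
      stopf("ecif_features: ligand_mol atom count (%d) does not match complex ligand (%d)",
            heavy_atom_count(ligand_mol), nrow(complex$ligand))
    }
    l_types <- vapply(seq_len(nrow(ligand_mol$atoms)), function(i)
      ecif_atom_type(ligand_mol, i), character(1))
  }
  p_types <- vapply(seq_len(nrow(complex$protein)), function(i)
    protein_atom_type(complex$protein$res_name[i], complex$protein$atom_name[i]),
    character(1))
  bad <- is.na(p_types)
  if (any(bad)) {
    warnf("ecif_features: %d protein atom(s) in nonstandard/unknown residues skipped",
          sum(bad))
  }
  pc <- as.matrix(complex$protein[!bad, c("x", "y", "z"), drop = FALSE])
  p_types <- p_types[!bad]
  lc <- as.matrix(complex$ligand[, c("x", "y", "z"), drop = FALSE])
  counts <- new.env(parent = emptyenv())
  if (nrow(pc) > 0) {
    d2 <- outer(rowSums(pc^2), rowSums(lc^2), "+") - 2 * pc %*% t(lc)
    within <- which(d2 <= cutoff^2 + 1e-9, arr.ind = TRUE)
    if (nrow(within) > 0) {
      keys <- paste(p_types[within[, 1]], l_types[within[, 2]], sep = "|")
      tab <- table(keys)
      for (k in names(tab)) assign(k, as.integer(tab[[k]]), envir = counts)
    }
  }
  keys <- sort(ls(counts))
  structure(list(
    counts = stats::setNames(vapply(keys, function(k) get(k, envir = counts),
                                    integer(1)), keys),
    cutoff = cutoff
  ), class = "cvs_ecif")
}

#' Construct an ECIF vector from explicit counts
#'
#' Mostly useful for building synthetic training data and for tests.
#'
#' @param counts named non-negative integer vector keyed "p_type|l_type"
#' @param cutoff the distance cutoff the counts correspond to
#' @return a `cvs_ecif`
#' @export
as_ecif_vector <- function(counts, cutoff = 6.0) {
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  structure(list(counts = counts[sort(names(counts))], cutoff = cutoff),
            class = "cvs_ecif")
}

#' @export
print.cvs_ecif <- function(x, ...) {
  cat(sprintf("<ECIF vector: %d type pairs, %d total contacts, cutoff %.1f A>\n",
              length(x$counts), sum(x$counts), x$cutoff))
  invisible(x)
}

#' Fit an affinity regressor on ECIF vectors
#'
#' Maps feature vectors to binding affinity (pKi). Two deterministic model
#' kinds:
#' \describe{
#'   \item{linear_ridge}{closed-form ridge regression on the count matrix
#'     with penalty `lambda` (default 1e-8, effectively least squares); an
#'     intercept is always fitted and unpenalised.}
#'   \item{gradient_boosting}{least-squares boosting with depth-1 regression
#'     stumps (`n_rounds` x `learning_rate`), seeded for reproducibility.}
#' }
#' The feature-key order is frozen at fit time (sorted type-pair strings);
#' unseen pairs at prediction time contribute zero.
#'
#' @param vectors list of `cvs_ecif` with one common cutoff
#' @param pki numeric response vector
#' @param model_kind "linear_ridge" or "gradient_boosting"
#' @param lambda ridge penalty
#' @param n_rounds,learning_rate boosting controls
#' @param seed integer seed for the stochastic parts of boosting
#' @return a `cvs_affinity_model`
#' @export
fit_affinity_model <- function(vectors, pki,
                               model_kind = c("linear_ridge", "gradient_boosting"),
                               lambda = 1e-8, n_rounds = 200L,
                               learning_rate = 0.1, seed = 1L) {
  model_kind <- match.arg(model_kind)
  if (length(vectors) != length(pki)) stopf("fit_affinity_model: length mismatch")
  if (length(vectors) < 10) stopf("fit_affinity_model: need >= 10 training pairs")
  cutoffs <- unique(vapply(vectors, function(v) v$cutoff, numeric(1)))
  if (length(cutoffs) != 1) stopf("fit_affinity_model: inconsistent cutoffs")
  keys <- sort(unique(unlist(lapply(vectors, function(v) names(v$counts)))))
  X <- ecif_design_matrix(vectors, keys)
  y <- as.numeric(pki)
  if (model_kind == "linear_ridge") {
    Xc <- cbind(1, X)
    p <- ncol(Xc)
    pen <- diag(p) * lambda
    pen[1, 1] <- 0
    beta <- solve(crossprod(Xc) + pen, crossprod(Xc, y))
    model <- list(intercept = beta[1], weights = stats::setNames(beta[-1], keys))
  } else {
    model <- fit_stump_boost(X, y, n_rounds = n_rounds, nu = learning_rate,
                             seed = seed)
  }
  structure(list(kind = model_kind, cutoff = cutoffs, feature_keys = keys,
                 model = model, version = "1"),
            class = "cvs_affinity_model")
}

ecif_design_matrix <- function(vectors, keys) {
  X <- matrix(0, nrow = length(vectors), ncol = length(keys),
              dimnames = list(NULL, keys))
  for (i in seq_along(vectors)) {
    cts <- vectors[[i]]$counts
    common <- intersect(names(cts), keys)
    X[i, common] <- cts[common]
  }
  X
}

fit_stump_boost <- function(X, y, n_rounds, nu, seed) {
  set.seed(seed)
  f0 <- mean(y)
  resid <- y - f0
  stumps <- vector("list", n_rounds)
  for (r in seq_len(n_rounds)) {
    best <- NULL; best_sse <- Inf
    for (j in seq_len(ncol(X))) {
      xs <- unique(X[, j])
      if (length(xs) < 2) next
      cuts <- (sort(xs)[-1] + sort(xs)[-length(xs)]) / 2
      for (cpt in cuts) {
        left <- X[, j] <= cpt
        ml <- mean(resid[left]); mr <- mean(resid[!left])
        sse <- sum((resid[left] - ml)^2) + sum((resid[!left] - mr)^2)
        if (sse < best_sse - 1e-12) {
          best_sse <- sse
          best <- list(j = j, cut = cpt, left = ml, right = mr)
        }
      }
    }
    if (is.null(best)) break
    stumps[[r]] <- best
    pred <- ifelse(X[, best$j] <= best$cut, best$left, best$right)
    resid <- resid - nu * pred
  }
  list(f0 = f0, nu = nu, stumps = Filter(Negate(is.null), stumps))
}

#' Predict pKi from an ECIF vector
#'
#' @param model a `cvs_affinity_model`
#' @param vector a `cvs_ecif` with the model's cutoff
#' @return numeric predicted pKi
#' @export
predict_pki <- function(model, vector) {
  stopifnot(inherits(model, "cvs_affinity_model"))
  if (!isTRUE(all.equal(model$cutoff, vector$cutoff))) {
    stopf("predict_pki: vector cutoff %.2f does not match model cutoff %.2f",
          vector$cutoff, model$cutoff)
  }
  x <- stats::setNames(numeric(length(model$feature_keys)), model$feature_keys)
  common <- intersect(names(vector$counts), model$feature_keys)
  x[common] <- vector$counts[common]
  if (model$kind == "linear_ridge") {
    unname(model$model$intercept + sum(model$model$weights * x))
  } else {
    m <- model$model
    pred <- m$f0
    for (s in m$stumps) {
      pred <- pred + m$nu * (if (x[s$j] <= s$cut) s$left else s$right)
    }
    unname(pred)
  }
}

#' Export an ECIF vector as a sparse CSV
#'
#' @param vector a `cvs_ecif`
#' @param path CSV path
#' @return invisibly `path`
#' @export
write_ecif_csv <- function(vector, path) {
  keys <- names(vector$counts)
  parts <- strsplit(keys, "|", fixed = TRUE)
  utils::write.csv(data.frame(
    p_type = vapply(parts, `[`, character(1), 1),
    l_type = vapply(parts, `[`, character(1), 2),
    count = unname(vector$counts), stringsAsFactors = FALSE
  ), path, row.names = FALSE)
  invisible(path)
}
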