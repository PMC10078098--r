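# Shared helpers for the suite. Everything is generated in code; no binary
# fixtures.

quiet <- function(expr) {
  withr::local_options(list(consensusVS.verbose = FALSE))
  expr
}

# a small, chemically varied SMILES panel used by round-trip/property tests
smiles_panel <- function() {
  c(
    water = "O", methane = "C", ethane = "CC", ethanol = "CCO",
    benzene = "c1ccccc1", kekule_benzene = "C1=CC=CC=C1",
    toluene = "Cc1ccccc1", phenol = "Oc1ccccc1", anisole = "COc1ccccc1",
    pyridine = "c1ccncc1", pyrrole = "c1cc[nH]c1", furan = "c1ccoc1",
    thiophene = "c1ccsc1", naphthalene = "c1ccc2ccccc2c1",
    biphenyl = "c1ccc(cc1)c1ccccc1", styrene = "C=Cc1ccccc1",
    benzamide = "NC(=O)c1ccccc1", benzoic_acid = "OC(=O)c1ccccc1",
    aniline = "Nc1ccccc1", chlorobenzene = "Clc1ccccc1",
    tma = "C[N+](C)(C)C", acetate = "CC(=O)[O-]",
    isopropylbenzene = "CC(C)c1ccccc1", hexane = "CCCCCC",
    cyclohexane = "C1CCCCC1", piperidine = "C1CCNCC1",
    morpholine = "C1COCCN1", indole_like = "c1ccc2[nH]ccc2c1",
    quinone = "O=C1C=CC(=O)C=C1", catechol = "Oc1ccccc1O",
    ibuprofen = "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
    colchicine = consensusVS::colchicine_smiles()
  )
}

panel_mols <- function() {
  smis <- smiles_panel()
  lapply(names(smis), function(nm) parse_smiles(smis[[nm]], id = nm))
}

# random rigid-body transform (rotation + translation), seeded
random_rigid_transform <- function(seed) {
  set.seed(seed)
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = runif(3, -10, 10))
}

apply_rigid <- function(xyz, tr) {
  sweep(as.matrix(xyz) %*% t(tr$R), 2, tr$t, "+")
}

transform_complex <- function(cx, tr) {
  pc <- apply_rigid(cx$protein[, c("x", "y", "z")], tr)
  lc <- apply_rigid(cx$ligand[, c("x", "y", "z")], tr)
  cx$protein$x <- pc[, 1]; cx$protein$y <- pc[, 2]; cx$protein$z <- pc[, 3]
  cx$ligand$x <- lc[, 1]; cx$ligand$y <- lc[, 2]; cx$ligand$z <- lc[, 3]
  cx
}

# brute-force Tanimoto over explicit 0/1 vectors — the independent oracle
tanimoto_oracle <- function(fp_a, fp_b) {
  va <- integer(fp_a$nbits); va[fp_a$bits + 1L] <- 1L
  vb <- integer(fp_b$nbits); vb[fp_b$bits + 1L] <- 1L
  inter <- 0L; uni <- 0L
  for (i in seq_along(va)) {
    if (va[i] == 1L && vb[i] == 1L) inter <- inter + 1L
    if (va[i] == 1L || vb[i] == 1L) uni <- uni + 1L
  }
  if (uni == 0L) 0 else inter / uni
}

# brute-force contact set: all-pairs distance loop
contacts_oracle <- function(cx, cutoff) {
  out <- character(0)
  for (i in seq_len(nrow(cx$protein))) {
    for (j in seq_len(nrow(cx$ligand))) {
      d <- sqrt(sum((unlist(cx$protein[i, c("x", "y", "z")]) -
                     unlist(cx$ligand[j, c("x", "y", "z")]))^2))
      if (d <= cutoff) {
        nm <- paste(paste0(toupper(substr(cx$protein$res_name[i], 1, 1)),
                           tolower(substring(cx$protein$res_name[i], 2))),
                    cx$protein$res_num[i])
        out <- c(out, nm)
      }
    }
  }
  unique(out)
}
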