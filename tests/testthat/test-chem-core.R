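test_that("parse_smiles perceives the basics", {
  w <- parse_smiles("O", "water")
  expect_equal(heavy_atom_count(w), 1)
  expect_equal(w$atoms$h, 2L)

  b <- parse_smiles("c1ccccc1", "benzene")
  expect_equal(heavy_atom_count(b), 6)
  expect_true(all(b$atoms$aromatic))
  expect_true(all(b$atoms$in_ring))
  expect_equal(b$atoms$h, rep(1L, 6))

  # Kekule input must perceive to the same molecule
  bk <- parse_smiles("C1=CC=CC=C1", "kekule")
  expect_identical(canonical_smiles(bk), canonical_smiles(b))

  # colchicine: C22H25NO6 -> 29 heavy atoms
  col <- parse_smiles(colchicine_smiles(), "colchicine")
  expect_equal(heavy_atom_count(col), 29)
  expect_equal(sum(col$atoms$element == "C"), 22)
  expect_equal(sum(col$atoms$element == "N"), 1)
  expect_equal(sum(col$atoms$element == "O"), 6)
})

test_that("parse_smiles rejects garbage with informative errors", {
  expect_error(parse_smiles("c1ccccc", "openring"), "unclosed ring")
  expect_error(parse_smiles("C(C", "openbranch"), "unmatched")
  expect_error(parse_smiles("C$X", "badchar"), "badchar")
  expect_error(parse_smiles("", "empty"), "empty")
})

test_that("charges, bracket atoms and heteroaromatics parse correctly", {
  tma <- parse_smiles("C[N+](C)(C)C", "tma")
  expect_equal(tma$atoms$charge[tma$atoms$element == "N"], 1L)
  expect_equal(tma$atoms$h[tma$atoms$element == "N"], 0L)

  ac <- parse_smiles("CC(=O)[O-]", "acetate")
  expect_equal(sum(ac$atoms$charge), -1L)

  pyr <- parse_smiles("c1cc[nH]c1", "pyrrole")
  expect_equal(pyr$atoms$h[pyr$atoms$element == "N"], 1L)
  pyd <- parse_smiles("c1ccncc1", "pyridine")
  expect_equal(pyd$atoms$h[pyd$atoms$element == "N"], 0L)
})

test_that("SMILES round-trip preserves heavy atoms and scaffold over the panel", {
  for (mol in panel_mols()) {
    rt <- parse_smiles(write_smiles(mol), id = paste0(mol$id, "_rt"))
    expect_equal(heavy_atom_count(rt), heavy_atom_count(mol), info = mol$id)
    expect_identical(bemis_murcko_scaffold(rt)$canonical_form,
                     bemis_murcko_scaffold(mol)$canonical_form, info = mol$id)
    # canonical form is a fixpoint
    expect_identical(canonical_smiles(rt), canonical_smiles(mol), info = mol$id)
  }
})

test_that("canonical SMILES is invariant to input atom ordering", {
  pairs <- list(
    c("OCCc1ccccc1", "c1ccccc1CCO"),
    c("CC(=O)Nc1ccccc1", "c1ccccc1NC(C)=O"),
    c("COc1ccc(Cl)cc1", "Clc1ccc(OC)cc1")
  )
  for (p in pairs) {
    expect_identical(canonical_smiles(parse_smiles(p[1], "a")),
                     canonical_smiles(parse_smiles(p[2], "b")))
  }
})

test_that("bemis_murcko_scaffold follows the iterative-pruning definition", {
  # acyclic -> empty
  expect_true(bemis_murcko_scaffold(parse_smiles("CC", "ethane"))$is_empty)
  # biphenyl is its own scaffold
  bip <- parse_smiles("c1ccc(cc1)c1ccccc1", "biphenyl")
  sc_bip <- bemis_murcko_scaffold(bip)
  expect_false(sc_bip$is_empty)
  expect_identical(sc_bip$canonical_form, canonical_smiles(bip))
  # toluene prunes to benzene
  expect_identical(bemis_murcko_scaffold(parse_smiles("Cc1ccccc1", "toluene"))$canonical_form,
                   canonical_smiles(parse_smiles("c1ccccc1", "benzene")))
  # linker between rings is retained
  dpm <- parse_smiles("c1ccc(Cc2ccccc2)cc1", "diphenylmethane")
  sc <- bemis_murcko_scaffold(dpm)
  expect_equal(heavy_atom_count(parse_smiles(sc$canonical_form, "sc")), 13)
})

test_that("scaffold extraction is idempotent and substituent-invariant", {
  variants <- c("Cc1ccc(O)cc1", "CCc1ccc(N)cc1", "Clc1ccc(F)cc1")
  keys <- vapply(variants, function(s)
    bemis_murcko_scaffold(parse_smiles(s, s))$canonical_form, character(1))
  expect_length(unique(keys), 1L)
  for (mol in panel_mols()) {
    sc <- bemis_murcko_scaffold(mol)
    if (!sc$is_empty) {
      again <- bemis_murcko_scaffold(parse_smiles(sc$canonical_form, "sc"))
      expect_identical(again$canonical_form, sc$canonical_form, info = mol$id)
    }
  }
})

test_that("basic_descriptors match hand-computed values", {
  d_me <- basic_descriptors(parse_smiles("C", "methane"))
  expect_equal(d_me$hbd, 0)
  expect_equal(d_me$hba, 0)
  expect_equal(d_me$rotatable_bonds, 0)

  d_w <- basic_descriptors(parse_smiles("O", "water"))
  expect_equal(d_w$hbd, 1)
  expect_equal(d_w$hba, 1)

  # ethanol MW = 2*12.011 + 15.999 + 6*1.008
  d_et <- basic_descriptors(parse_smiles("CCO", "ethanol"))
  expect_equal(d_et$mw, 2 * 12.011 + 15.999 + 6 * 1.008, tolerance = 1e-9)

  # adding a CH2 strictly increases logP (monotonicity of the estimator)
  lp <- vapply(c("CCO", "CCCO", "CCCCO"), function(s)
    basic_descriptors(parse_smiles(s, s))$logp, numeric(1))
  expect_true(all(diff(lp) > 0))

  # butane has one rotatable bond; 1,4-positions in benzene none
  expect_equal(basic_descriptors(parse_smiles("CCCC", "butane"))$rotatable_bonds, 1)
  expect_equal(basic_descriptors(parse_smiles("Cc1ccc(C)cc1", "xylene"))$rotatable_bonds, 0)
})

test_that("heavy_atom_count counts non-hydrogens for all panel molecules", {
  # independent oracle: count element symbols that are not H in the atom table
  for (mol in panel_mols()) {
    expect_equal(heavy_atom_count(mol), sum(mol$atoms$element != "H"),
                 info = mol$id)
    expect_gte(heavy_atom_count(mol), 1)
  }
})

test_that("SDF read/write round-trips molecules and preserves record order", {
  path <- withr::local_tempfile(fileext = ".sdf")
  mols <- lapply(c(benzene = "c1ccccc1", ethanol = "CCO", pyridine = "c1ccncc1"),
                 function(s) parse_smiles(s, id = s))
  # give one molecule coordinates, z all zero (must be kept verbatim)
  mols[[2]]$coords <- cbind(seq_len(3), seq_len(3) * 2, 0)
  write_sdf(mols, path)
  back <- parse_sdf(path)
  expect_length(back, 3)
  expect_identical(vapply(back, function(m) m$id, character(1)),
                   c("c1ccccc1", "CCO", "c1ccncc1"))
  expect_equal(back[[2]]$coords[, 3], rep(0, 3))
  for (i in seq_along(mols)) {
    expect_identical(canonical_smiles(back[[i]]), canonical_smiles(mols[[i]]))
  }
})

test_that("parse_sdf skips malformed records without aborting", {
  path <- withr::local_tempfile(fileext = ".sdf")
  good <- parse_smiles("CCO", "good")
  write_sdf(list(good), path)
  txt <- readLines(path)
  bad <- c("broken", "", "", "  garbage counts line", "$$$$")
  writeLines(c(bad, txt), path)
  out <- quiet(parse_sdf(path))
  expect_length(out, 1)
  expect_identical(canonical_smiles(out[[1]]), canonical_smiles(good))
  # empty file -> empty list
  writeLines(character(0), path)
  expect_length(parse_sdf(path), 0)
})
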