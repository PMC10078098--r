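test_that("ecif_atom_type encodes the perception tuple", {
  b <- parse_smiles("c1ccccc1", "benzene")
  expect_identical(ecif_atom_type(b, 1), "C;4;2;1;1;1")
  w <- parse_smiles("O", "water")
  expect_identical(ecif_atom_type(w, 1), "O;2;0;2;0;0")
  m <- parse_smiles("C", "methane")
  expect_identical(ecif_atom_type(m, 1), "C;4;0;4;0;0")
  # carbonyl pair in acetone
  ac <- parse_smiles("CC(=O)C", "acetone")
  i_c <- which(ac$atoms$element == "C" & ac$atoms$degree == 3)
  i_o <- which(ac$atoms$element == "O")
  expect_identical(ecif_atom_type(ac, i_c), "C;4;3;0;0;0")
  expect_identical(ecif_atom_type(ac, i_o), "O;2;1;0;0;0")
})

test_that("protein atoms are typed from residue templates", {
  expect_identical(consensusVS:::protein_atom_type("ALA", "CA"), "C;4;3;1;0;0")
  expect_identical(consensusVS:::protein_atom_type("GLY", "CA"), "C;4;2;2;0;0")
  expect_identical(consensusVS:::protein_atom_type("ALA", "O"), "O;2;1;0;0;0")
  expect_identical(consensusVS:::protein_atom_type("PHE", "CZ"), "C;4;2;1;1;1")
  expect_identical(consensusVS:::protein_atom_type("LYS", "NZ"), "N;4;1;3;0;0")
  # nonstandard residues are not typed
  expect_true(is.na(consensusVS:::protein_atom_type("XYZ", "CA")))
})

test_that("ecif_features honours the inclusive distance cutoff", {
  prot <- data.frame(element = "C", x = 0, y = 0, z = 0, chain = "A",
                     res_name = "ALA", res_num = 1L, atom_name = "CA")
  lig_near <- parse_smiles("C", "lig"); lig_near$coords <- matrix(c(5.9, 0, 0), 1)
  lig_far <- parse_smiles("C", "lig"); lig_far$coords <- matrix(c(6.1, 0, 0), 1)
  mk <- function(lig) new_complex(prot, data.frame(
    element = "C", x = lig$coords[1], y = 0, z = 0, atom_name = "C1"))
  v_near <- ecif_features(mk(lig_near), lig_near)
  expect_equal(sum(v_near$counts), 1L)
  expect_identical(names(v_near$counts), "C;4;3;1;0;0|C;4;0;4;0;0")
  v_far <- ecif_features(mk(lig_far), lig_far)
  expect_equal(sum(v_far$counts), 0L)
  # exact boundary is included
  lig_at <- lig_near; lig_at$coords <- matrix(c(6.0, 0, 0), 1)
  expect_equal(sum(ecif_features(mk(lig_at), lig_at)$counts), 1L)
})

test_that("ecif_features equals a brute-force pair loop on random complexes", {
  `%||%` <- function(a, b) if (is.null(a)) b else a
  for (seed in 1:8) {
    rc <- generate_random_complex(n_residues = 5, seed = seed)
    v <- ecif_features(rc$complex, rc$ligand_mol)
    # oracle: explicit double loop with explicit typing
    pt <- vapply(seq_len(nrow(rc$complex$protein)), function(i)
      consensusVS:::protein_atom_type(rc$complex$protein$res_name[i],
                                      rc$complex$protein$atom_name[i]),
      character(1))
    lt <- vapply(seq_len(nrow(rc$ligand_mol$atoms)), function(i)
      ecif_atom_type(rc$ligand_mol, i), character(1))
    want <- list()
    for (i in seq_along(pt)) {
      if (is.na(pt[i])) next
      for (j in seq_along(lt)) {
        d <- sqrt(sum((unlist(rc$complex$protein[i, c("x", "y", "z")]) -
                       rc$ligand_mol$coords[j, ])^2))
        if (d <= 6.0) {
          k <- paste(pt[i], lt[j], sep = "|")
          want[[k]] <- (want[[k]] %||% 0L) + 1L
        }
      }
    }
    expect_equal(as.list(v$counts), want[sort(names(want))], info = seed)
  }
})

test_that("ecif_features is rigid-transform invariant and fragment-additive", {
  rc <- generate_random_complex(n_residues = 6, seed = 99)
  base <- ecif_features(rc$complex, rc$ligand_mol)
  for (seed in 1:5) {
    tr <- random_rigid_transform(seed)
    moved <- transform_complex(rc$complex, tr)
    lig_moved <- rc$ligand_mol
    lig_moved$coords <- apply_rigid(rc$ligand_mol$coords, tr)
    # the complex ligand table must move with the molecule
    moved$ligand$x <- lig_moved$coords[, 1]
    moved$ligand$y <- lig_moved$coords[, 2]
    moved$ligand$z <- lig_moved$coords[, 3]
    v <- ecif_features(moved, lig_moved)
    expect_equal(v$counts, base$counts)
  }
  # additivity over disjoint ligand fragments: split the ligand in two
  nlig <- nrow(rc$complex$ligand)
  idx1 <- seq_len(floor(nlig / 2)); idx2 <- setdiff(seq_len(nlig), idx1)
  sub_complex <- function(idx) {
    cx <- rc$complex
    cx$ligand <- cx$ligand[idx, , drop = FALSE]
    cx$ligand_types <- vapply(idx, function(i) ecif_atom_type(rc$ligand_mol, i),
                              character(1))
    cx
  }
  v1 <- ecif_features(sub_complex(idx1))
  v2 <- ecif_features(sub_complex(idx2))
  merged <- tapply(c(v1$counts, v2$counts), c(names(v1$counts), names(v2$counts)), sum)
  expect_equal(sum(merged), sum(base$counts))
  expect_setequal(names(merged), names(base$counts))
  expect_equal(unname(as.numeric(merged[names(base$counts)])),
               unname(as.numeric(base$counts)))
})

# deterministic synthetic linear world for the regressor tests
synth_ecif_data <- function(n, p = 12, sigma = 0, seed = 1) {
  set.seed(seed)
  keys <- sprintf("C;4;%d;1;0;0|O;2;1;0;0;0", seq_len(p))
  w <- runif(p, -0.5, 0.5)
  vectors <- lapply(seq_len(n), function(i) {
    counts <- stats::setNames(rpois(p, 3), keys)
    as_ecif_vector(counts[counts > 0])
  })
  X <- consensusVS:::ecif_design_matrix(vectors, keys)
  y <- drop(X %*% w) + 2.5 + rnorm(n, 0, sigma)
  list(vectors = vectors, y = y, w = stats::setNames(w, keys), keys = keys)
}

test_that("ridge regression recovers noiseless linear weights to 1e-6", {
  d <- synth_ecif_data(n = 100, sigma = 0, seed = 42)
  fit <- fit_affinity_model(d$vectors, d$y, "linear_ridge")
  expect_lt(max(abs(fit$model$weights[d$keys] - d$w)), 1e-6)
  expect_equal(fit$model$intercept, 2.5, tolerance = 1e-6)
  preds <- vapply(d$vectors, function(v) predict_pki(fit, v), numeric(1))
  expect_lt(max(abs(preds - d$y)), 1e-6)
})

test_that("regressor contracts: constant response, determinism, linearity", {
  d <- synth_ecif_data(n = 30, sigma = 0, seed = 7)
  const <- fit_affinity_model(d$vectors, rep(4.2, 30), "linear_ridge")
  expect_equal(predict_pki(const, d$vectors[[5]]), 4.2, tolerance = 1e-6)

  # permuting training order gives the identical model
  perm <- sample(30)
  f1 <- fit_affinity_model(d$vectors, d$y, "linear_ridge")
  f2 <- fit_affinity_model(d$vectors[perm], d$y[perm], "linear_ridge")
  expect_equal(f1$model$weights, f2$model$weights, tolerance = 1e-9)

  # linearity: scaling a vector x2 scales (prediction - intercept) x2
  v <- d$vectors[[1]]
  v2 <- as_ecif_vector(v$counts * 2)
  p1 <- predict_pki(f1, v) - f1$model$intercept
  p2 <- predict_pki(f1, v2) - f1$model$intercept
  expect_equal(p2, 2 * p1, tolerance = 1e-9)

  # unseen type-pairs contribute zero
  alien <- as_ecif_vector(c("N;3;2;1;0;0|S;2;2;0;0;0" = 5L))
  expect_equal(predict_pki(f1, alien), f1$model$intercept, tolerance = 1e-9)

  # cutoff mismatch is an error
  off <- as_ecif_vector(v$counts, cutoff = 8)
  expect_error(predict_pki(f1, off), "cutoff")
  expect_error(fit_affinity_model(d$vectors[1:5], d$y[1:5]), ">= 10")
})

test_that("gradient boosting fits a learnable signal deterministically", {
  d <- synth_ecif_data(n = 60, sigma = 0, seed = 12)
  f1 <- fit_affinity_model(d$vectors, d$y, "gradient_boosting",
                           n_rounds = 100, seed = 3)
  f2 <- fit_affinity_model(d$vectors, d$y, "gradient_boosting",
                           n_rounds = 100, seed = 3)
  p1 <- vapply(d$vectors, function(v) predict_pki(f1, v), numeric(1))
  p2 <- vapply(d$vectors, function(v) predict_pki(f2, v), numeric(1))
  expect_identical(p1, p2)
  # boosting must explain most of the variance in-sample
  expect_lt(mean((p1 - d$y)^2), 0.25 * stats::var(d$y))
})
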