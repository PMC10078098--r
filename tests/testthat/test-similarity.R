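test_that("fingerprints are deterministic and class-sensible", {
  b1 <- compute_fingerprint(parse_smiles("c1ccccc1", "b1"), "structural_keys_166")
  b2 <- compute_fingerprint(parse_smiles("c1ccccc1", "b2"), "structural_keys_166")
  expect_identical(b1$bits, b2$bits)
  expect_equal(b1$nbits, 166L)
  expect_gt(length(b1$bits), 0)

  me <- compute_fingerprint(parse_smiles("C", "methane"), "structural_keys_166")
  # benzene sets ring/aromatic keys methane cannot
  expect_true(length(setdiff(b1$bits, me$bits)) > 0)
  expect_lt(tanimoto(b1, me), 1)

  c1 <- compute_fingerprint(parse_smiles("c1ccccc1", "b1"), "circular_r2")
  expect_equal(c1$nbits, 2048L)
  expect_true(all(c1$bits >= 0 & c1$bits < 2048))
})

test_that("tanimoto follows the set definition and its contracts", {
  fp <- function(bits, nbits = 166L, kind = "structural_keys_166")
    structure(list(kind = kind, nbits = nbits, bits = as.integer(bits)),
              class = "cvs_fingerprint")
  expect_equal(tanimoto(fp(c(1, 2, 3)), fp(c(1, 2, 3))), 1.0)
  expect_equal(tanimoto(fp(c(1, 2, 3)), fp(c(4, 5, 6))), 0.0)
  expect_equal(tanimoto(fp(c(1, 2, 3)), fp(c(2, 3, 9))), 0.5)   # 2 / 4
  expect_equal(tanimoto(fp(integer(0)), fp(integer(0))), 0)
  expect_error(tanimoto(fp(1), fp(1, nbits = 166L, kind = "circular_r2")),
               "mismatch")
})

test_that("tanimoto properties hold across the molecule panel", {
  mols <- panel_mols()
  fps <- lapply(mols, compute_fingerprint, kind = "structural_keys_166")
  set.seed(42)
  for (k in 1:50) {
    i <- sample(length(fps), 1); j <- sample(length(fps), 1)
    tij <- tanimoto(fps[[i]], fps[[j]])
    expect_gte(tij, 0); expect_lte(tij, 1)
    expect_equal(tij, tanimoto(fps[[j]], fps[[i]]))       # symmetry
  }
  for (f in fps) if (length(f$bits) > 0) expect_equal(tanimoto(f, f), 1.0)
})

test_that("similarity_matrix has pair cardinality and self-similarity 1", {
  lib <- lapply(c("c1ccccc1", "CCO", "c1ccncc1"), function(s) parse_smiles(s, s))
  refs <- lapply(c("c1ccccc1", "CCCCO"), function(s) parse_smiles(s, paste0("r_", s)))
  m <- similarity_matrix(lib, refs)
  expect_equal(nrow(m), 6)
  self <- m[m$library_id == "c1ccccc1" & m$reference_id == "r_c1ccccc1", ]
  expect_equal(self$t_skey, 1.0)
  expect_equal(self$t_circ, 1.0)
})

test_that("consensus_thresholds equals median plus sample SD (hand values)", {
  rec <- data.frame(library_id = "x", reference_id = letters[1:4],
                    t_skey = c(0.2, 0.4, 0.6, 0.8),
                    t_circ = c(0.5, 0.5, 0.5, 0.5))
  thr <- consensus_thresholds(rec)
  expect_equal(thr$thr_skey, 0.5 + sqrt(0.2 / 3), tolerance = 1e-12)
  expect_equal(thr$thr_skey, 0.7581989, tolerance = 1e-6)
  expect_equal(thr$thr_circ, 0.5)                       # SD 0 -> threshold c
  expect_equal(thr$n_pairs, 4L)

  # {0,1}: threshold may exceed 1, leaving no possible hit
  rec2 <- data.frame(library_id = "x", reference_id = c("a", "b"),
                     t_skey = c(0, 1), t_circ = c(0, 1))
  thr2 <- consensus_thresholds(rec2)
  expect_equal(thr2$thr_skey, 0.5 + sqrt(0.5), tolerance = 1e-12)
  expect_gt(thr2$thr_skey, 1)
  expect_length(similarity_hits(rec2, thr2), 0)

  expect_error(consensus_thresholds(rec2[1, ]), "at least 2")
})

test_that("consensus_thresholds is permutation-invariant and shift-equivariant", {
  set.seed(11)
  rec <- data.frame(library_id = rep(letters[1:10], each = 3),
                    reference_id = rep(c("r1", "r2", "r3"), 10),
                    t_skey = runif(30), t_circ = runif(30))
  thr <- consensus_thresholds(rec)
  perm <- rec[sample(nrow(rec)), ]
  thr_p <- consensus_thresholds(perm)
  expect_equal(thr$thr_skey, thr_p$thr_skey)
  expect_equal(thr$thr_circ, thr_p$thr_circ)
  # adding a constant shifts the threshold by exactly that constant
  shifted <- transform(rec, t_skey = t_skey + 0.1, t_circ = t_circ + 0.1)
  thr_s <- consensus_thresholds(shifted)
  expect_equal(thr_s$thr_skey, thr$thr_skey + 0.1, tolerance = 1e-12)
  expect_equal(thr_s$thr_circ, thr$thr_circ + 0.1, tolerance = 1e-12)
})

test_that("similarity_hits applies strict > on both metrics against one reference", {
  rec <- data.frame(
    library_id = c("hit", "boundary", "split", "split"),
    reference_id = c("r1", "r1", "r1", "r2"),
    t_skey = c(0.9, 0.5, 0.9, 0.2),
    t_circ = c(0.9, 0.5, 0.2, 0.9))
  thr <- list(thr_skey = 0.5, thr_circ = 0.5)
  # boundary: exactly equal is not a hit; split: conditions met against
  # different references fails same_reference but passes any_reference
  expect_identical(similarity_hits(rec, thr), "hit")
  expect_setequal(similarity_hits(rec, thr, consensus_mode = "any_reference"),
                  c("hit", "split"))
})

test_that("similarity_hits equals a brute-force predicate re-evaluation", {
  set.seed(13)
  rec <- data.frame(library_id = rep(sprintf("L%02d", 1:20), each = 4),
                    reference_id = rep(sprintf("R%d", 1:4), 20),
                    t_skey = runif(80), t_circ = runif(80))
  thr <- consensus_thresholds(rec)
  got <- similarity_hits(rec, thr)
  want <- character(0)
  for (id in unique(rec$library_id)) {
    sub <- rec[rec$library_id == id, ]
    ok <- FALSE
    for (k in seq_len(nrow(sub))) {
      if (sub$t_skey[k] > thr$thr_skey && sub$t_circ[k] > thr$thr_circ) ok <- TRUE
    }
    if (ok) want <- c(want, id)
  }
  expect_setequal(got, want)
  # monotonicity: raising a threshold never adds hits
  thr_up <- thr; thr_up$thr_skey <- thr$thr_skey + 0.05
  expect_true(all(similarity_hits(rec, thr_up) %in% got))
})
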