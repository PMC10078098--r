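test_that("normalize_score and report rounding reproduce the reference cutoff", {
  # colchicine: raw -10.01 over 29 heavy atoms
  col <- parse_smiles(colchicine_smiles(), "colchicine")
  expect_equal(heavy_atom_count(col), 29)
  raw <- normalize_score(-10.01, 29)
  expect_equal(raw, -10.01 / 29, tolerance = 1e-15)
  expect_equal(report_score(raw), -0.345)
  expect_equal(normalize_score(0, 17), 0)
  expect_equal(normalize_score(-10, 10), -1.0)
  expect_error(normalize_score(-5, 0), "n_heavy")
})

test_that("read_score_table joins, deduplicates and excludes unknowns", {
  lib <- lapply(c(A = "c1ccccc1", B = "CCO", C = "c1ccncc1"), function(s) s)
  lib <- Map(function(s, id) parse_smiles(s, id), lib, names(lib))
  tab <- data.frame(compound_id = c("A", "B", "B", "C", "GHOST"),
                    raw_score = c(-6, -5, -7, -4, -9))
  rec <- quiet(read_score_table(tab, lib))
  expect_equal(nrow(rec), 3)
  expect_equal(rec$raw_score[rec$compound_id == "B"], -7)   # best kept
  expect_false("GHOST" %in% rec$compound_id)
  expect_equal(rec$n_heavy[rec$compound_id == "A"], 6L)
  expect_equal(rec$normalized_score, rec$raw_score / rec$n_heavy)
  expect_error(read_score_table(data.frame(x = 1), lib), "columns")
})

test_that("docking_hits uses an inclusive cutoff and matches brute force", {
  ref <- list(normalized_score = -0.345)
  rec <- data.frame(compound_id = c("at", "below", "above"),
                    normalized_score = c(-0.345, -0.40, -0.344))
  hits <- docking_hits(rec, ref)
  expect_setequal(hits, c("at", "below"))

  set.seed(3)
  rec2 <- data.frame(compound_id = sprintf("C%03d", 1:100),
                     normalized_score = runif(100, -0.6, -0.1))
  got <- docking_hits(rec2, ref)
  want <- rec2$compound_id[rec2$normalized_score <= -0.345]
  expect_identical(got, want)
  # permutation invariance of the batch
  perm <- rec2[sample(100), ]
  expect_setequal(docking_hits(perm, ref), want)
})

test_that("detect_contacts applies an inclusive heavy-atom cutoff", {
  frames <- generate_toy_complex(
    list("Ala 180" = 3.0, "Val 181" = 4.5, "Met 259" = 6.0), n_frames = 1)
  got <- detect_contacts(frames[[1]], cutoff = 4.5)
  expect_setequal(got, c("Ala 180", "Val 181"))   # 4.5 boundary inclusive
  expect_setequal(got, contacts_oracle(frames[[1]], 4.5))
  # 4.4 vs 4.6 around the default cutoff
  f2 <- generate_toy_complex(list("Cys 241" = 4.4, "Ala 316" = 4.6))[[1]]
  expect_identical(detect_contacts(f2), "Cys 241")
})

test_that("detect_contacts is invariant under joint rigid transforms", {
  frames <- generate_toy_complex(
    list("Ala 180" = 3.2, "Val 181" = 4.5, "Cys 241" = 5.1, "Met 259" = 8.0))
  base <- detect_contacts(frames[[1]])
  for (seed in 1:20) {
    tr <- random_rigid_transform(seed)
    moved <- transform_complex(frames[[1]], tr)
    expect_setequal(detect_contacts(moved), base)
  }
})

test_that("contact_persistence matches scripted per-frame patterns", {
  frames <- generate_toy_complex(
    list("Val 181" = c(TRUE, TRUE, TRUE, FALSE),
         "Ala 180" = c(TRUE, TRUE, TRUE, TRUE),
         "Met 259" = c(FALSE, FALSE, FALSE, FALSE)),
    n_frames = 4)
  prof <- contact_persistence(frames, cutoff = 4.5, compound_id = "x")
  expect_equal(unname(prof$contacts["Val 181"]), 0.75)
  expect_equal(unname(prof$contacts["Ala 180"]), 1.0)
  expect_equal(unname(prof$contacts["Met 259"]), 0.0)
  expect_equal(prof$n_frames, 4L)
  # single frame: fractions are 0/1 and equal detect_contacts
  p1 <- contact_persistence(frames[1], cutoff = 4.5)
  expect_true(all(p1$contacts %in% c(0, 1)))
  expect_setequal(names(p1$contacts)[p1$contacts == 1],
                  detect_contacts(frames[[1]], 4.5))
  # constant trajectory == one frame with fractions 1
  const <- generate_toy_complex(list("Val 181" = 3.0), n_frames = 5)
  pc <- contact_persistence(const, 4.5)
  expect_equal(unname(pc$contacts["Val 181"]), 1.0)
})

test_that("key_interaction_check counts matches against the built-in sets", {
  expect_equal(key_residues("colchicine"),
               c("Ala 180", "Val 181", "Cys 241", "Met 259", "Ala 316"))
  expect_equal(key_residues("dj101"),
               c("Val 181", "Val 236", "Leu 246", "Asn 247", "Asn 347", "Lys 350"))
  prof <- structure(list(compound_id = "x", n_frames = 1L,
                         contacts = c("Ala 180" = 1, "Val 181" = 0.5,
                                      "Cys 241" = 0.25, "Gly 10" = 1)),
                    class = "cvs_contact_profile")
  res <- key_interaction_check(prof, key_residues("colchicine"))
  expect_equal(res$n_matched, 3L)
  expect_true(res$pass)
  # only one key residue -> fail
  prof2 <- structure(list(compound_id = "x", n_frames = 1L,
                          contacts = c("Val 181" = 1)),
                     class = "cvs_contact_profile")
  res2 <- key_interaction_check(prof2, key_residues("colchicine"))
  expect_equal(res2$n_matched, 1L)
  expect_false(res2$pass)
  # empty profile -> 0, fail
  prof3 <- structure(list(compound_id = "x", n_frames = 1L,
                          contacts = stats::setNames(numeric(0), character(0))),
                     class = "cvs_contact_profile")
  expect_equal(key_interaction_check(prof3, key_residues("dj101"))$n_matched, 0L)
  # min_fraction excludes weak persistence
  res4 <- key_interaction_check(prof, key_residues("colchicine"),
                                min_fraction = 0.3)
  expect_equal(res4$n_matched, 2L)
})

test_that("PDB frames round-trip through write/read with MODEL blocks", {
  frames <- generate_toy_complex(
    list("Val 181" = c(3, 8), "Ala 316" = c(4, 4)), n_frames = 2)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_frames(frames, path)
  back <- read_pdb_frames(path)
  expect_length(back, 2)
  expect_equal(nrow(back[[1]]$protein), 2)
  expect_equal(nrow(back[[1]]$ligand), 1)
  for (f in 1:2) {
    expect_setequal(detect_contacts(back[[f]], 4.5),
                    detect_contacts(frames[[f]], 4.5))
  }
})
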