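#' Reference inhibitor structure
#'
#' Canonical SMILES of colchicine (C22H25NO6, 29 heavy atoms), the classical
#' colchicine-site destabiliser used as the docking reference.
#'
#' @return character SMILES
#' @export
colchicine_smiles <- function() {
  "CC(=O)NC1CCC2=CC(=C(C(=C2C3=CC=C(C(=O)C=C13)OC)OC)OC)OC"
}

#' Fixture specification
#'
#' The stated world of the synthetic screen: a library built from a handful
#' of ring scaffolds with varied substituents, a reference-active set made
#' of near-duplicates of designated library members plus dissimilar decoys,
#' a docking-score table calibrated to the colchicine cutoff, and planted
#' pass/fail ground truth per stage. Defaults emulate the real screen at
#' desk scale: 50 library compounds over 5 scaffold families, 8 reference
#' actives, and per-stage pass fractions of similar magnitude to the
#' published funnel (similarity ~0.1, docking ~0.3, pharmacophore ~0.6,
#' ADMET ~0.7), with 2 compounds planted to clear every stage.
#'
#' @param n_library library size
#' @param n_references reference-active count
#' @param n_scaffolds scaffold families used
#' @param fraction_pass named list: sim, dock, pharm, admet fractions in [0,1]
#' @param n_full_hits compounds planted to pass all four stages
#' @param seed integer RNG seed; fixed seed implies identical output
#' @return a `cvs_fixture_spec` list
#' @export
fixture_spec <- function(n_library = 50L, n_references = 8L, n_scaffolds = 5L,
                         fraction_pass = list(sim = 0.1, dock = 0.3,
                                              pharm = 0.6, admet = 0.7),
                         n_full_hits = 2L, seed = 7L) {
  fr <- utils::modifyList(list(sim = 0.1, dock = 0.3, pharm = 0.6, admet = 0.7),
                          fraction_pass)
  stopifnot(all(unlist(fr) >= 0), all(unlist(fr) <= 1),
            n_library >= n_full_hits, n_scaffolds >= 1)
  structure(list(n_library = as.integer(n_library),
                 n_references = as.integer(n_references),
                 n_scaffolds = as.integer(n_scaffolds),
                 fraction_pass = fr, n_full_hits = as.integer(n_full_hits),
                 seed = as.integer(seed)),
            class = "cvs_fixture_spec")
}

# scaffold templates: sprintf cores with two substitution slots; chemically
# valid, heteroatom-diverse so structural keys spread out
fixture_cores <- function() {
  c(
    "c1cc(%s)ccc1%s",          # 1,4-benzene
    "c1cc(%s)cnc1%s",          # pyridine
    "c1ccc2cc(%s)c(%s)cc2c1",  # naphthalene
    "C1CC(%s)CCC1%s",          # cyclohexane
    "c1csc(%s)c1%s",           # thiophene
    "c1cc2ccccc2n1%s",         # (unused slot variant, kept for >5 families)
    "C1CCN(%s)CC1%s"           # piperidine
  )[1:7]
}

fixture_substituents <- function() {
  c("C", "CC", "CCC", "O", "OC", "OCC", "Cl", "F", "N", "NC", "CO", "CCO")
}

# catechol arm: appending it plants a pan-assay alert (ADMET fail);
# ring-closure digit 3 avoids clashing with any core's digits
pains_arm <- function() "c3cc(O)c(O)cc3"

#' Generate the synthetic screening library
#'
#' Builds `n_library` molecules by decorating ring cores with substituent
#' pairs, assigns per-stage planted truth, and builds the reference-active
#' set: one near-duplicate (a substituent homologue) per similarity-planted
#' compound, padded with long-chain aliphatic decoys. Written files:
#' `library.smi`, `references.smi` (SMILES TAB id).
#'
#' @param spec a `cvs_fixture_spec`
#' @param dir output directory (created); NULL keeps everything in memory
#' @return list(library, references, truth) where truth is a data.frame with
#'   columns id, scaffold_class, sim_planted, dock_pass, pharm_pass,
#'   admet_pass, full_hit
#' @export
generate_library <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cvs_fixture_spec"))
  set.seed(spec$seed)
  n <- spec$n_library
  cores <- fixture_cores()[seq_len(min(spec$n_scaffolds, length(fixture_cores())))]
  subs <- fixture_substituents()

  ids <- sprintf("LIB%03d", seq_len(n))
  core_idx <- rep_len(seq_along(cores), n)
  r1 <- sample(subs, n, replace = TRUE)
  r2 <- sample(subs, n, replace = TRUE)

  # planted truth
  full <- seq_len(spec$n_full_hits)
  rest <- setdiff(seq_len(n), full)
  pick <- function(fraction) {
    k <- max(0L, round(fraction * n) - length(full))
    sort(c(full, sample(rest, min(k, length(rest)))))
  }
  sim_set <- pick(spec$fraction_pass$sim)
  dock_set <- pick(spec$fraction_pass$dock)
  pharm_set <- pick(spec$fraction_pass$pharm)
  admet_set <- pick(spec$fraction_pass$admet)

  # similarity-planted compounds carry a methyl in slot 2; their reference
  # near-duplicate is the ethyl homologue, a change that leaves the
  # structural-key bit set essentially intact (Tanimoto > 0.9 guaranteed)
  r2[sim_set] <- "C"

  smiles <- character(n)
  for (i in seq_len(n)) {
    core <- cores[core_idx[i]]
    nslot <- lengths(regmatches(core, gregexpr("%s", core, fixed = TRUE)))
    args <- list(core, r1[i], r2[i])[seq_len(1 + nslot)]
    smiles[i] <- do.call(sprintf, args)
  }
  # ADMET failures: graft the catechol alert arm onto substituent slot 1
  for (i in setdiff(seq_len(n), admet_set)) {
    core <- cores[core_idx[i]]
    nslot <- lengths(regmatches(core, gregexpr("%s", core, fixed = TRUE)))
    args <- c(list(core), as.list(c(pains_arm(), r2[i])[seq_len(nslot)]))
    smiles[i] <- do.call(sprintf, args)
  }
  library <- lapply(seq_len(n), function(i) parse_smiles(smiles[i], id = ids[i]))

  # references: near-duplicates of similarity-planted members (homologate a
  # substituent: R2 -> R2 + CH2) plus aliphatic decoys
  refs <- list()
  for (i in sim_set) {
    core <- cores[core_idx[i]]
    nslot <- lengths(regmatches(core, gregexpr("%s", core, fixed = TRUE)))
    base1 <- if (i %in% admet_set) r1[i] else pains_arm()
    r2h <- "CC"  # ethyl homologue of the planted methyl
    args <- c(list(core), as.list(c(base1, r2h)[seq_len(nslot)]))
    refs[[length(refs) + 1]] <- parse_smiles(do.call(sprintf, args),
                                             id = sprintf("REFACT%03d", i))
  }
  n_decoy <- max(0L, spec$n_references - length(refs))
  for (k in seq_len(n_decoy)) {
    chain <- paste(rep("C", 8 + k), collapse = "")
    refs[[length(refs) + 1]] <- parse_smiles(paste0(chain, "O"),
                                             id = sprintf("REFDEC%03d", k))
  }

  scaff <- vapply(library, function(m) {
    s <- bemis_murcko_scaffold(m)
    if (s$is_empty) paste0("acyclic:", m$id) else s$canonical_form
  }, character(1))

  # Similarity truth: the consensus thresholds are an empirical function of
  # the whole library x reference distribution, so the similarity hit set
  # cannot be stated constructively; it is computed here, once, with the
  # package's own similarity module and recorded as ground truth. The
  # constructive guarantee is that planted near-duplicate pairs score > 0.9
  # on structural keys (asserted by the test suite, not assumed here).
  simmat <- similarity_matrix(library, refs)
  sim_hits_ids <- similarity_hits(simmat, consensus_thresholds(simmat))

  truth <- data.frame(
    id = ids, smiles = smiles, scaffold_class = scaff,
    sim_planted = seq_len(n) %in% sim_set,
    sim_hit = ids %in% sim_hits_ids,
    dock_pass = seq_len(n) %in% dock_set,
    pharm_pass = seq_len(n) %in% pharm_set,
    admet_pass = seq_len(n) %in% admet_set,
    full_hit = seq_len(n) %in% full,
    stringsAsFactors = FALSE
  )
  truth$all_pass <- truth$sim_hit & truth$dock_pass & truth$pharm_pass &
    truth$admet_pass
  out <- list(library = library, references = refs, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(paste(smiles, ids, sep = "\t"), file.path(dir, "library.smi"))
    writeLines(vapply(refs, function(m) paste(write_smiles(m), m$id, sep = "\t"),
                      character(1)), file.path(dir, "references.smi"))
  }
  out
}

#' Generate a docking score table calibrated to the reference cutoff
#'
#' Normalised scores are drawn uniformly below the colchicine cutoff for
#' planted docking hits and above it for the rest, then multiplied back by
#' each molecule's heavy-atom count to give raw engine scores. The reference
#' row (colchicine, raw -10.01) is included.
#'
#' @param spec a `cvs_fixture_spec`
#' @param lib output of [generate_library()]
#' @param dir optional output directory for `scores.csv`
#' @param reference_id id used for the reference row
#' @return data.frame: compound_id, raw_score
#' @export
generate_score_table <- function(spec, lib, dir = NULL,
                                 reference_id = "REF_colchicine") {
  set.seed(spec$seed + 1L)
  ref_mol <- parse_smiles(colchicine_smiles(), id = reference_id)
  cutoff <- -10.01 / heavy_atom_count(ref_mol)
  n <- nrow(lib$truth)
  counts <- vapply(lib$library, heavy_atom_count, integer(1))
  normalized <- numeric(n)
  pass <- lib$truth$dock_pass
  normalized[pass] <- stats::runif(sum(pass), cutoff - 0.40, cutoff - 0.01)
  normalized[!pass] <- stats::runif(sum(!pass), cutoff + 0.01, cutoff + 0.40)
  tab <- data.frame(compound_id = lib$truth$id,
                    raw_score = normalized * counts,
                    stringsAsFactors = FALSE)
  tab <- rbind(tab, data.frame(compound_id = reference_id, raw_score = -10.01))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(dir, "scores.csv"), row.names = FALSE)
  }
  tab
}

# fragment vocabulary realising each feature type at a 3D point
feature_fragment <- function(ftype, centre, jitter = 0.0) {
  centre <- centre + stats::runif(3, -jitter, jitter)
  if (ftype == "donor") {
    # protonated amine: donor but not acceptor
    list(atoms = data.frame(element = "N", charge = 1L, aromatic = FALSE, h = 3L,
                            stringsAsFactors = FALSE),
         bonds = data.frame(a = integer(), b = integer(), order = numeric()),
         coords = matrix(centre, 1, 3, byrow = TRUE))
  } else if (ftype == "acceptor") {
    # carbonyl oxygen: acceptor but not donor
    list(atoms = data.frame(element = c("O", "C"), charge = 0L,
                            aromatic = FALSE, h = c(0L, 2L),
                            stringsAsFactors = FALSE),
         bonds = data.frame(a = 1L, b = 2L, order = 2),
         coords = rbind(centre, centre + c(1.22, 0, 0)))
  } else if (ftype == "aromatic") {
    ang <- 2 * pi * (0:5) / 6
    ring <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
    list(atoms = data.frame(element = "C", charge = 0L, aromatic = TRUE, h = 1L,
                            stringsAsFactors = FALSE)[rep(1, 6), ],
         bonds = data.frame(a = 1:6, b = c(2:6, 1), order = 1.5),
         coords = sweep(ring, 2, centre, "+"))
  } else if (ftype == "hydrophobic") {
    pts <- rbind(c(-1.5, 0, 0), c(0, 0, 0), c(1.5, 0, 0))
    list(atoms = data.frame(element = "C", charge = 0L, aromatic = FALSE,
                            h = c(3L, 2L, 3L), stringsAsFactors = FALSE),
         bonds = data.frame(a = c(1L, 2L), b = c(2L, 3L), order = 1),
         coords = sweep(pts, 2, centre, "+"))
  } else stopf("unknown feature type '%s'", ftype)
}

assemble_pose <- function(id, fragments) {
  atoms <- NULL; bonds <- NULL; coords <- NULL; offset <- 0L
  for (fr in fragments) {
    atoms <- rbind(atoms, fr$atoms)
    if (nrow(fr$bonds) > 0) {
      bonds <- rbind(bonds, data.frame(a = fr$bonds$a + offset,
                                       b = fr$bonds$b + offset,
                                       order = fr$bonds$order))
    }
    coords <- rbind(coords, fr$coords)
    offset <- offset + nrow(fr$atoms)
  }
  if (is.null(bonds)) bonds <- data.frame(a = integer(), b = integer(), order = numeric())
  new_molecule(id, atoms, bonds, coords = coords, source = "constructed")
}

#' Default planted pharmacophore layout
#'
#' Six features (one donor, two acceptors, two aromatics, one hydrophobic)
#' spaced >= 6 A apart, with prevalences all at or above the 70% consensus
#' threshold so the built model has exactly six features.
#'
#' @return data.frame: ftype, x, y, z, prevalence
#' @export
default_feature_plan <- function() {
  data.frame(
    ftype = c("donor", "acceptor", "acceptor", "aromatic", "aromatic", "hydrophobic"),
    x = c(0, 8, -8, 0, 10, -10),
    y = c(0, 0, 0, 9, 9, 9),
    z = c(0, 0, 0, 0, 6, 6),
    prevalence = c(1.0, 0.95, 0.90, 0.85, 0.80, 0.75),
    stringsAsFactors = FALSE
  )
}

#' Generate a reference pose set with planted features
#'
#' Each planted feature is perceivable in exactly `round(prevalence *
#' n_poses)` poses at the stated point (+/- 0.1 A jitter). Which poses carry
#' a feature is a seeded sample, so prevalences are exact by construction.
#'
#' @param planted data.frame: ftype, x, y, z, prevalence
#' @param n_poses number of reference poses (default 20)
#' @param seed RNG seed
#' @param dir optional directory for `poses.sdf`
#' @return list(poses = list of molecules, planted = the plan)
#' @export
generate_pose_set <- function(planted = default_feature_plan(), n_poses = 20L,
                              seed = 7L, dir = NULL) {
  set.seed(seed)
  carriers <- lapply(seq_len(nrow(planted)), function(f) {
    k <- round(planted$prevalence[f] * n_poses)
    sort(sample(seq_len(n_poses), k))
  })
  poses <- vector("list", n_poses)
  for (p in seq_len(n_poses)) {
    frs <- list()
    for (f in seq_len(nrow(planted))) {
      if (p %in% carriers[[f]]) {
        frs[[length(frs) + 1]] <- feature_fragment(
          planted$ftype[f], c(planted$x[f], planted$y[f], planted$z[f]),
          jitter = 0.1)
      }
    }
    if (length(frs) == 0) {
      frs[[1]] <- feature_fragment("hydrophobic", c(50, 50, 50), jitter = 0.1)
    }
    poses[[p]] <- assemble_pose(sprintf("POSE%03d", p), frs)
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_sdf(poses, file.path(dir, "poses.sdf"))
  }
  list(poses = poses, planted = planted)
}

#' Generate candidate poses with planted pharmacophore pass/fail
#'
#' Planted passers exhibit all six features of the plan; failers only three
#' (below the five-of-six pass rule).
#'
#' @param lib output of [generate_library()]
#' @param planted feature plan (see [default_feature_plan()])
#' @param seed RNG seed
#' @param dir optional directory for `candidate_poses.sdf`
#' @return named list of poses keyed by compound id
#' @export
generate_candidate_poses <- function(lib, planted = default_feature_plan(),
                                     seed = 7L, dir = NULL) {
  set.seed(seed + 2L)
  poses <- list()
  for (i in seq_len(nrow(lib$truth))) {
    id <- lib$truth$id[i]
    rows <- if (lib$truth$pharm_pass[i]) seq_len(nrow(planted)) else
      seq_len(min(3L, nrow(planted)))
    frs <- lapply(rows, function(f) feature_fragment(
      planted$ftype[f], c(planted$x[f], planted$y[f], planted$z[f]), jitter = 0.1))
    poses[[id]] <- assemble_pose(id, frs)
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_sdf(poses, file.path(dir, "candidate_poses.sdf"))
  }
  poses
}

#' Generate a toy protein-ligand complex (optionally multi-frame)
#'
#' Single-atom placeholder residues (CA only) are positioned so that the
#' nearest protein-ligand heavy-atom distance equals the plan exactly per
#' frame; geometrically exact, biologically abstract. The ligand is one
#' carbon at the origin.
#'
#' @param contact_plan named list: "ResName ResNum" -> scalar distance, a
#'   numeric vector of per-frame distances, or a logical per-frame contact
#'   pattern (TRUE = 3.0 A, FALSE = 8.0 A)
#' @param n_frames number of frames
#' @param dir optional directory for `complex.pdb`
#' @return list of `cvs_complex` frames
#' @export
generate_toy_complex <- function(contact_plan, n_frames = 1L, dir = NULL) {
  res_ids <- names(contact_plan)
  stopifnot(length(res_ids) > 0)
  dists <- matrix(0, length(res_ids), n_frames)
  for (r in seq_along(res_ids)) {
    v <- contact_plan[[r]]
    if (is.logical(v)) v <- ifelse(v, 3.0, 8.0)
    if (length(v) == 1) v <- rep(v, n_frames)
    if (length(v) != n_frames) stopf("contact plan for %s: wrong length", res_ids[r])
    if (any(v <= 0)) stopf("contact plan distances must be > 0")
    dists[r, ] <- v
  }
  parts <- strsplit(res_ids, " ")
  res_name <- toupper(vapply(parts, `[`, character(1), 1))
  res_num <- as.integer(vapply(parts, `[`, character(1), 2))
  angles <- 2 * pi * (seq_along(res_ids) - 1) / length(res_ids)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    prot <- data.frame(
      element = "C",
      x = dists[, f] * cos(angles), y = dists[, f] * sin(angles), z = 0,
      chain = "A", res_name = res_name, res_num = res_num,
      atom_name = "CA", stringsAsFactors = FALSE)
    lig <- data.frame(element = "C", x = 0, y = 0, z = 0, atom_name = "C1",
                      stringsAsFactors = FALSE)
    frames[[f]] <- new_complex(prot, lig, frame_index = f - 1L)
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_pdb_frames(frames, file.path(dir, "complex.pdb"))
  }
  frames
}

#' Generate a random protein-ligand complex for oracle checks
#'
#' Standard-residue atoms at uniform random coordinates in a cube, with a
#' randomly decorated small molecule as the ligand.
#'
#' @param n_residues number of (whole, random) residues to place
#' @param seed RNG seed
#' @param box half-width of the coordinate cube, Angstroms
#' @return list(complex = `cvs_complex`, ligand_mol = `cvs_molecule`)
#' @export
generate_random_complex <- function(n_residues = 8L, seed = 1L, box = 8) {
  set.seed(seed)
  tmpl <- protein_atom_templates()
  res_pool <- setdiff(STANDARD_RESIDUES, "GLY")
  prot <- NULL
  for (r in seq_len(n_residues)) {
    res <- sample(res_pool, 1)
    at <- rbind(tmpl[tmpl$res == "ALL", ], tmpl[tmpl$res == res, ])
    centre <- stats::runif(3, -box, box)
    prot <- rbind(prot, data.frame(
      element = at$el,
      x = centre[1] + stats::runif(nrow(at), -2, 2),
      y = centre[2] + stats::runif(nrow(at), -2, 2),
      z = centre[3] + stats::runif(nrow(at), -2, 2),
      chain = "A", res_name = res, res_num = 100L + r,
      atom_name = at$atom, stringsAsFactors = FALSE))
  }
  smi <- sprintf(sample(fixture_cores()[1:5], 1),
                 sample(fixture_substituents(), 1),
                 sample(fixture_substituents(), 1))
  lig_mol <- parse_smiles(smi, id = "random_ligand")
  nlig <- heavy_atom_count(lig_mol)
  lig_mol$coords <- matrix(stats::runif(3 * nlig, -box / 2, box / 2), nlig, 3)
  lig <- data.frame(element = lig_mol$atoms$element,
                    x = lig_mol$coords[, 1], y = lig_mol$coords[, 2],
                    z = lig_mol$coords[, 3],
                    atom_name = lig_mol$atoms$element, stringsAsFactors = FALSE)
  list(complex = new_complex(prot, lig), ligand_mol = lig_mol)
}

#' Generate the complete fixture set
#'
#' Orchestrates every generator and, when `dir` is given, writes
#' `library.smi`, `references.smi`, `scores.csv`, `poses.sdf`,
#' `candidate_poses.sdf`, `complex.pdb`, and `truth.json`.
#'
#' @param spec a `cvs_fixture_spec`
#' @param dir optional output directory
#' @return list(library, references, truth, scores, ref_poses, candidate
#'   poses, complex frames, feature plan)
#' @export
generate_fixture_set <- function(spec = fixture_spec(), dir = NULL) {
  lib <- generate_library(spec, dir = dir)
  scores <- generate_score_table(spec, lib, dir = dir)
  plan <- default_feature_plan()
  ref_poses <- generate_pose_set(plan, n_poses = 20L, seed = spec$seed, dir = dir)
  cand_poses <- generate_candidate_poses(lib, plan, seed = spec$seed, dir = dir)
  frames <- generate_toy_complex(
    stats::setNames(as.list(c(3.0, 3.5, 4.0, 7.0, 8.0)),
                    key_residues("colchicine")),
    n_frames = 4L, dir = dir)
  out <- list(library = lib$library, references = lib$references,
              truth = lib$truth, scores = scores, ref_poses = ref_poses,
              candidate_poses = cand_poses, complex_frames = frames,
              feature_plan = plan, spec = spec)
  if (!is.null(dir)) {
    jsonlite::write_json(lib$truth, file.path(dir, "truth.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  out
}
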