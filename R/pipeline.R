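#' Pipeline run configuration
#'
#' Assembles and validates the consensus-screen configuration. All paths are
#' optional except the library: a stage whose inputs are absent is disabled
#' and passes every compound through with a prominent log line, so partial
#' pipelines remain runnable.
#'
#' @param library path to library SMILES (or a list of molecules)
#' @param references path to reference SMILES (or a list of molecules)
#' @param scores path to docking score CSV (or data.frame)
#' @param reference_id compound id of the docking reference row
#' @param reference_smiles SMILES used for the reference's heavy-atom count
#' @param reference_poses path to reference pose SDF (or list of molecules)
#' @param candidate_poses path to candidate pose SDF (or named list)
#' @param pharmacophore_model path to a serialized model JSON (overrides
#'   `reference_poses`)
#' @param cyp_flags optional path to external cytochrome flags CSV
#' @param consensus_mode similarity consensus mode
#' @param prevalence_threshold,min_match,merge_radius pharmacophore controls
#' @param admet_policy list merged over [default_admet_policy()]
#' @param top_k diverse hits to select (default 5)
#' @param seed integer seed recorded and used for any stochastic component
#' @return a validated `cvs_run_config`
#' @export
run_config <- function(library, references = NULL, scores = NULL,
                       reference_id = "REF_colchicine",
                       reference_smiles = colchicine_smiles(),
                       reference_poses = NULL, candidate_poses = NULL,
                       pharmacophore_model = NULL, cyp_flags = NULL,
                       consensus_mode = "same_reference",
                       prevalence_threshold = 0.70, min_match = 5L,
                       merge_radius = 1.5,
                       admet_policy = list(), top_k = 5L, seed = 1L) {
  cfg <- list(library = library, references = references, scores = scores,
              reference_id = reference_id, reference_smiles = reference_smiles,
              reference_poses = reference_poses,
              candidate_poses = candidate_poses,
              pharmacophore_model = pharmacophore_model,
              cyp_flags = cyp_flags, consensus_mode = consensus_mode,
              prevalence_threshold = prevalence_threshold,
              min_match = as.integer(min_match), merge_radius = merge_radius,
              admet_policy = admet_policy, top_k = as.integer(top_k),
              seed = as.integer(seed))
  for (field in c("library", "references", "scores", "reference_poses",
                  "candidate_poses", "pharmacophore_model", "cyp_flags")) {
    v <- cfg[[field]]
    if (is.character(v) && length(v) == 1 && !file.exists(v)) {
      stopf("run_config: %s file '%s' not readable", field, v)
    }
  }
  stopifnot(cfg$consensus_mode %in% c("same_reference", "any_reference"),
            cfg$prevalence_threshold > 0, cfg$prevalence_threshold <= 1,
            cfg$top_k >= 1)
  class(cfg) <- "cvs_run_config"
  cfg
}

#' Read a pipeline configuration from JSON
#'
#' Relative paths in the file are resolved against the file's directory.
#'
#' @param path JSON config path
#' @return a `cvs_run_config`
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  for (field in c("library", "references", "scores", "reference_poses",
                  "candidate_poses", "pharmacophore_model", "cyp_flags")) {
    v <- obj[[field]]
    if (is.character(v) && length(v) == 1 && !file.exists(v)) {
      obj[[field]] <- file.path(base, v)
    }
  }
  do.call(run_config, obj[!vapply(obj, is.null, logical(1))])
}

load_molecules <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.list(x) && all(vapply(x, inherits, logical(1), "cvs_molecule"))) return(x)
  if (is.character(x) && grepl("\\.sdf$", x, ignore.case = TRUE)) return(parse_sdf(x))
  if (is.character(x)) return(read_smiles_file(x))
  stopf("cannot interpret molecule input of class %s", class(x)[1])
}

#' Run the consensus virtual screen
#'
#' Executes the four screening criteria in order — (1) dual-fingerprint
#' similarity, (2) normalised docking score, (3) pharmacophore match,
#' (4) ADMET rules — for every compound, with no short-circuiting, so
#' per-stage funnel counts are always reportable. Disabled stages (missing
#' inputs) pass all compounds and are logged.
#'
#' @param config a `cvs_run_config`
#' @param out optional output directory for CSV/JSON/report artifacts
#' @return data.frame of consensus records (one row per compound) with
#'   attributes `thresholds`, `selected`, `summary`
#' @export
run_consensus <- function(config, out = NULL) {
  stopifnot(inherits(config, "cvs_run_config"))
  set.seed(config$seed)
  library_mols <- load_molecules(config$library)
  if (length(library_mols) == 0) {
    cvs_log("run_consensus: empty library; empty result")
    rec <- empty_consensus_records()
    attr(rec, "summary") <- list(n_total = 0L)
    return(rec)
  }
  ids <- vapply(library_mols, function(m) m$id, character(1))
  n <- length(ids)

  # stage 1: similarity
  thresholds <- NULL
  refs <- load_molecules(config$references)
  if (!is.null(refs) && length(refs) > 0) {
    simmat <- similarity_matrix(library_mols, refs)
    thresholds <- consensus_thresholds(simmat)
    sim_hit_ids <- similarity_hits(simmat, thresholds, config$consensus_mode)
    sim_hit <- ids %in% sim_hit_ids
  } else {
    cvs_log("run_consensus: similarity stage DISABLED (no references); all compounds pass")
    simmat <- NULL
    sim_hit <- rep(TRUE, n)
  }

  # stage 2: docking normalisation + cutoff
  norm_score <- rep(NA_real_, n)
  if (!is.null(config$scores)) {
    ref_mol <- parse_smiles(config$reference_smiles, id = config$reference_id)
    join_set <- c(library_mols, list(ref_mol))
    records <- read_score_table(config$scores, join_set)
    ref_row <- records[records$compound_id == config$reference_id, ]
    if (nrow(ref_row) != 1) {
      stopf("run_consensus: reference id '%s' not found in score table",
            config$reference_id)
    }
    dock_hit_ids <- docking_hits(records, ref_row)
    dock_hit <- ids %in% dock_hit_ids
    norm_score <- records$normalized_score[match(ids, records$compound_id)]
  } else {
    cvs_log("run_consensus: docking stage DISABLED (no score table); all compounds pass")
    dock_hit <- rep(TRUE, n)
  }

  # stage 3: pharmacophore
  pharm_matched <- rep(NA_integer_, n)
  model <- NULL
  if (!is.null(config$pharmacophore_model)) {
    model <- if (inherits(config$pharmacophore_model, "cvs_pharmacophore")) {
      config$pharmacophore_model
    } else read_pharmacophore(config$pharmacophore_model)
  } else if (!is.null(config$reference_poses)) {
    ref_poses <- load_molecules(config$reference_poses)
    model <- build_pharmacophore(ref_poses,
                                 prevalence_threshold = config$prevalence_threshold,
                                 merge_radius = config$merge_radius,
                                 min_match = config$min_match)
  }
  if (!is.null(model) && !is.null(config$candidate_poses)) {
    cand <- config$candidate_poses
    if (!is.list(cand) || inherits(cand, "cvs_molecule")) cand <- load_molecules(cand)
    cand_ids <- vapply(cand, function(m) m$id, character(1))
    pharm_hit <- rep(FALSE, n)
    for (i in seq_len(n)) {
      j <- match(ids[i], cand_ids)
      if (is.na(j)) next
      res <- match_pharmacophore(cand[[j]], model)
      pharm_matched[i] <- res$n_matched
      pharm_hit[i] <- res$pass
    }
  } else {
    cvs_log("run_consensus: pharmacophore stage DISABLED (no model/poses); all compounds pass")
    pharm_hit <- rep(TRUE, n)
  }

  # stage 4: ADMET
  cyp <- if (!is.null(config$cyp_flags)) read_cyp_flags(config$cyp_flags) else NULL
  admet_rows <- lapply(library_mols, function(m)
    admet_profile(m, cyp_flags = cyp[[m$id]]))
  admet_hit <- vapply(admet_rows, admet_pass, logical(1),
                      policy = config$admet_policy)
  admet_tab <- do.call(rbind, admet_rows)

  scaffolds <- vapply(library_mols, function(m) {
    s <- bemis_murcko_scaffold(m)
    if (s$is_empty) paste0("acyclic:", m$id) else s$canonical_form
  }, character(1))

  rec <- data.frame(
    compound_id = ids,
    sim_hit = sim_hit, dock_hit = dock_hit,
    pharm_matched = pharm_matched, pharm_hit = pharm_hit,
    admet_hit = admet_hit,
    all_pass = sim_hit & dock_hit & pharm_hit & admet_hit,
    normalized_score = norm_score,
    scaffold = scaffolds,
    stringsAsFactors = FALSE
  )
  selected <- select_diverse_hits(rec, top_k = config$top_k)
  summary <- list(
    n_total = n,
    n_sim = sum(rec$sim_hit), pct_sim = stage_summary(n, sum(rec$sim_hit)),
    n_dock = sum(rec$dock_hit), pct_dock = stage_summary(n, sum(rec$dock_hit)),
    n_pharm = sum(rec$pharm_hit), pct_pharm = stage_summary(n, sum(rec$pharm_hit)),
    n_admet = sum(rec$admet_hit), pct_admet = stage_summary(n, sum(rec$admet_hit)),
    n_all = sum(rec$all_pass), pct_all = stage_summary(n, sum(rec$all_pass)),
    n_sim_dock_pharm = sum(rec$sim_hit & rec$dock_hit & rec$pharm_hit),
    seed = config$seed
  )
  attr(rec, "thresholds") <- thresholds
  attr(rec, "selected") <- selected
  attr(rec, "summary") <- summary
  attr(rec, "admet") <- admet_tab
  for (nm in c("n_sim", "n_dock", "n_pharm", "n_admet", "n_all")) {
    cvs_log(sprintf("stage %s: %d/%d", sub("n_", "", nm), summary[[nm]], n))
  }
  if (!is.null(out)) write_consensus_outputs(rec, config, out, simmat)
  rec
}

empty_consensus_records <- function() {
  data.frame(compound_id = character(), sim_hit = logical(),
             dock_hit = logical(), pharm_matched = integer(),
             pharm_hit = logical(), admet_hit = logical(),
             all_pass = logical(), normalized_score = numeric(),
             scaffold = character(), stringsAsFactors = FALSE)
}

#' Scaffold-diverse top-hit selection
#'
#' Among compounds passing all criteria, sorted by normalised docking score
#' ascending (more negative = better; ties broken by compound id), greedily
#' keep compounds whose Bemis-Murcko scaffold differs from every already
#' selected one, until `top_k` or exhaustion.
#'
#' @param records consensus record data.frame (needs all_pass,
#'   normalized_score, scaffold, compound_id)
#' @param top_k maximum hits to return (default 5)
#' @return character vector of selected compound ids, best first
#' @export
select_diverse_hits <- function(records, top_k = 5L) {
  pool <- records[records$all_pass, , drop = FALSE]
  if (nrow(pool) == 0) {
    cvs_log("select_diverse_hits: no compound passes all criteria")
    return(character(0))
  }
  ord <- order(pool$normalized_score, pool$compound_id)
  pool <- pool[ord, , drop = FALSE]
  chosen <- character(0); scaffs <- character(0)
  for (i in seq_len(nrow(pool))) {
    if (length(chosen) >= top_k) break
    if (!(pool$scaffold[i] %in% scaffs)) {
      chosen <- c(chosen, pool$compound_id[i])
      scaffs <- c(scaffs, pool$scaffold[i])
    }
  }
  chosen
}

#' Funnel percentage at report precision
#'
#' 100 * n_hits / n_total, one decimal, ties away from zero (28 of 429
#' prints as 6.5).
#'
#' @param n_total total screened (> 0)
#' @param n_hits hits (0..n_total)
#' @return numeric percentage with one decimal
#' @export
stage_summary <- function(n_total, n_hits) {
  if (n_total <= 0) stopf("stage_summary: n_total must be > 0")
  stopifnot(n_hits >= 0, n_hits <= n_total)
  round_half_away(100 * n_hits / n_total, 1)
}

write_consensus_outputs <- function(rec, config, out, simmat = NULL) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(
    transform(rec, normalized_score = report_score(normalized_score)),
    file.path(out, "consensus.csv"), row.names = FALSE)
  if (!is.null(simmat)) {
    write_similarity_outputs(simmat, attr(rec, "thresholds"), out)
  }
  admet_tab <- attr(rec, "admet")
  if (!is.null(admet_tab)) {
    utils::write.csv(admet_tab, file.path(out, "admet.csv"), row.names = FALSE)
  }
  s <- attr(rec, "summary")
  report <- c(
    "# Consensus screen report", "",
    sprintf("- compounds screened: %d", s$n_total),
    sprintf("- (1) similarity hits: %d (%.1f%%)", s$n_sim, s$pct_sim),
    sprintf("- (2) docking hits: %d (%.1f%%)", s$n_dock, s$pct_dock),
    sprintf("- (3) pharmacophore hits: %d (%.1f%%)", s$n_pharm, s$pct_pharm),
    sprintf("- (4) ADMET hits: %d (%.1f%%)", s$n_admet, s$pct_admet),
    sprintf("- criteria (1)+(2)+(3): %d", s$n_sim_dock_pharm),
    sprintf("- all four criteria: %d (%.1f%%)", s$n_all, s$pct_all),
    sprintf("- diverse selection: %s",
            paste(attr(rec, "selected"), collapse = ", ")),
    sprintf("- seed: %d", s$seed))
  writeLines(report, file.path(out, "report.md"))
  # provenance copy of the resolved config: scalar fields plus the merged
  # ADMET policy; in-memory molecule lists are recorded by size only
  cfg_out <- lapply(unclass(config), function(v) {
    if (is.character(v) || is.numeric(v) || is.logical(v)) v
    else if (is.list(v)) sprintf("<in-memory: %d items>", length(v))
    else NULL
  })
  cfg_out$admet_policy <- utils::modifyList(default_admet_policy(),
                                            config$admet_policy)
  jsonlite::write_json(cfg_out[!vapply(cfg_out, is.null, logical(1))],
                       file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}
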