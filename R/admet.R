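#' Lipinski rule-of-five violations
#'
#' Counts violated conditions among MW > 500, logP > 5, HBD > 5, HBA > 10
#' (strict inequalities; a value exactly at a limit is not a violation).
#'
#' @param d one-row descriptor data.frame from [basic_descriptors()]
#' @return integer in 0..4
#' @export
lipinski_violations <- function(d) {
  as.integer((d$mw > 500) + (d$logp > 5) + (d$hbd > 5) + (d$hba > 10))
}

#' ESOL aqueous solubility estimate and class
#'
#' The classic estimated-solubility regression:
#' logS = 0.16 - 0.63 logP - 0.0062 MW + 0.066 RB - 0.74 AP, with AP the
#' aromatic fraction of heavy atoms. Class bands: < -10 insoluble,
#' [-10, -6) poorly, [-6, -4) moderately, [-4, -2) soluble, [-2, 0) very,
#' >= 0 highly.
#'
#' @param d one-row descriptor data.frame
#' @return list(logs, class)
#' @export
esol_logs <- function(d) {
  logs <- 0.16 - 0.63 * d$logp - 0.0062 * d$mw + 0.066 * d$rotatable_bonds -
    0.74 * d$aromatic_fraction
  list(logs = logs, class = solubility_class(logs))
}

solubility_class <- function(logs) {
  cut_points <- c(-Inf, -10, -6, -4, -2, 0, Inf)
  labels <- c("insoluble", "poorly", "moderately", "soluble", "very", "highly")
  labels[findInterval(logs, cut_points, left.open = FALSE)]
}

# Bundled pan-assay interference (PAINS-style) alert subset. A documented,
# mechanism-covering selection of classic interference chemotypes, not a
# full published catalogue; users can supply their own pattern file.
# Patterns are SMILES matched by the package substructure engine; bracket H
# counts are minimum-H constraints (see substructure matching notes).
pains_patterns <- function() {
  c(
    quinone_para     = "O=C1C=CC(=O)C=C1",
    quinone_ortho    = "O=C1C(=O)C=CC=C1",
    catechol         = "[OH]c1ccccc1[OH]",
    hydroquinone     = "[OH]c1ccc([OH])cc1",
    rhodanine        = "O=C1CSC(=S)N1",
    ene_rhodanine    = "S=C1SC(=CC=O)C(=O)N1",
    enone_michael    = "C=CC(=O)C=C",
    alkylidene_barbiturate = "O=C1NC(=O)C(=C)C(=O)N1",
    azo              = "cN=Nc",
    nitroso          = "N=O",
    isothiocyanate   = "N=C=S",
    aldehyde_ar      = "cC=O",
    imine_conj       = "C=NC=O",
    hydrazone        = "NN=C",
    thiourea         = "NC(=S)N",
    anhydride        = "O=COC=O",
    cyclopropanone   = "O=C1CC1"
  )
}

pains_library <- function() {
  if (is.null(.pattern_cache$pains)) {
    .pattern_cache$pains <- parse_pattern_library(pains_patterns())
  }
  .pattern_cache$pains
}

#' Count pan-assay interference alerts
#'
#' Number of distinct alert patterns with at least one substructure match
#' (a pattern matching twice counts once).
#'
#' @param mol a `cvs_molecule`
#' @param alert_library named list of pattern molecules (default: the
#'   bundled subset from `pains_patterns()`)
#' @return integer alert count
#' @export
pains_alerts <- function(mol, alert_library = pains_library()) {
  sum(vapply(alert_library, function(q) has_substructure(mol, q), logical(1)))
}

#' Full ADMET profile of a molecule
#'
#' @param mol a `cvs_molecule`
#' @param cyp_flags optional named logical vector of cytochrome-isoform
#'   inhibition flags (external classifier output, e.g. a SwissADME export)
#' @return one-row data.frame of class `cvs_admet`
#' @export
admet_profile <- function(mol, cyp_flags = NULL) {
  d <- basic_descriptors(mol)
  sol <- esol_logs(d)
  out <- data.frame(
    compound_id = mol$id, mw = d$mw, logp = d$logp, hbd = d$hbd, hba = d$hba,
    rotatable_bonds = d$rotatable_bonds, tpsa = d$tpsa,
    esol_logs = sol$logs, solubility_class = sol$class,
    lipinski_violations = lipinski_violations(d),
    pains_alerts = pains_alerts(mol),
    n_cyp_inhibited = if (is.null(cyp_flags)) NA_integer_ else as.integer(sum(cyp_flags)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cvs_admet", class(out))
  out
}

#' Default ADMET policy
#'
#' @return list of policy thresholds, each overridable
#' @export
default_admet_policy <- function() {
  list(
    max_lipinski_violations = 1L,
    min_solubility_class = "moderately",   # moderately or better
    max_pains_alerts = 0L,
    max_cyp = 2L
  )
}

#' ADMET pass/fail decision
#'
#' Default policy: at most one rule-of-five violation, solubility class
#' moderately-or-better, zero interference alerts, and (only when external
#' cytochrome flags are present) at most `max_cyp` inhibited isoforms. A
#' missing cytochrome input skips that clause.
#'
#' @param profile one-row data.frame from [admet_profile()]
#' @param policy list from [default_admet_policy()], fields overridable
#' @return logical
#' @export
admet_pass <- function(profile, policy = default_admet_policy()) {
  pol <- utils::modifyList(default_admet_policy(), policy)
  class_order <- c("insoluble", "poorly", "moderately", "soluble", "very", "highly")
  ok <- profile$lipinski_violations <= pol$max_lipinski_violations &&
    match(profile$solubility_class, class_order) >=
      match(pol$min_solubility_class, class_order) &&
    profile$pains_alerts <= pol$max_pains_alerts
  if (ok && !is.na(profile$n_cyp_inhibited)) {
    ok <- profile$n_cyp_inhibited <= pol$max_cyp
  }
  isTRUE(ok)
}

#' Read external cytochrome-inhibition flags
#'
#' CSV with `compound_id` plus one 0/1 column per isoform (cyp1a2, cyp2c9,
#' cyp2c19, cyp2d6, cyp3a4).
#'
#' @param path CSV path
#' @return named list: compound_id -> logical vector
#' @export
read_cyp_flags <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"compound_id" %in% names(tab)) stopf("cyp flags: missing compound_id column")
  iso <- setdiff(names(tab), "compound_id")
  out <- lapply(seq_len(nrow(tab)), function(i) {
    stats::setNames(as.logical(unlist(tab[i, iso])), iso)
  })
  names(out) <- tab$compound_id
  out
}
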