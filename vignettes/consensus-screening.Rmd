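---
title: "Consensus virtual screening: models, rules, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus virtual screening: models, rules, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consensusVS)
```

# The screening model

Colchicine-site inhibitors of the tubulin–microtubule system destabilise
microtubules by binding a pocket at the α/β-tubulin interface; interrupting
polymerisation dynamics arrests the cell cycle. Screening a library for such
inhibitors with any single computational method inherits that method's false
positives. This package implements a *consensus* protocol: four independent
criteria, each with an explicit, auditable rule, all evaluated for every
compound (no early exit), with the final hits drawn from the intersection.

## Criterion 1 — dual-fingerprint similarity

Similarity to known actives is measured with the Tanimoto coefficient over
two fingerprints of different character: structural keys (presence of
predefined substructure/graph features in 166 slots) and a radius-2 circular
fingerprint (hashed atom-neighbourhood identifiers up to diameter 4, 2048
bits). The hit threshold is *empirical*: for each fingerprint kind, the
median of all library × reference similarity values plus one sample standard
deviation, pooled over every pair. A compound is a hit when **both** values
are strictly above their thresholds against the **same** reference.

Design choices:

* *Pooled thresholds* (one global pair, not per-reference): this mirrors a
  screen that reports a single threshold pair and keeps the statistic stable
  with few references. Configurable only through the records supplied.
* *Strict inequality* at the threshold ("above the median plus one SD");
  the boundary case is tested.
* *Same-reference consensus* by default: the two metrics qualify the same
  comparison. `consensus_mode = "any_reference"` relaxes this.
* *Sample SD* (denominator n − 1), the convention for an empirical
  screening distribution.
* The structural-key catalogue is a documented subset in the spirit of the
  classic 166-bit key sets, not a bit-level clone of any vendor definition;
  Tanimoto values are therefore internally consistent but not comparable
  with other software's absolute values. Thresholds adapt to whatever
  catalogue is used, which is the property the protocol actually relies on.

## Criterion 2 — ligand-efficiency docking filter

Docking scores scale with molecular size, so raw-score ranking favours large
molecules. The screen divides each score by the compound's non-hydrogen atom
count and filters at the reference inhibitor's value: colchicine, raw score
−10.01 with 29 heavy atoms, gives −10.01/29 = −0.3452…, printed as −0.345
(three decimals, ties away from zero). The comparison is *inclusive*
("equal to or lower") and always uses full precision internally; rounding is
cosmetic. Duplicate score rows keep the best (lowest) score, matching the
convention of retaining the best-scored conformation.

## Criterion 3 — consensus pharmacophore

The model is built from the docked binding modes of reference actives, all
in one coordinate frame. Perceived features per pose:

| feature | rule |
|---|---|
| donor | N or O bearing ≥ 1 H, at the atom position |
| acceptor | N or O not positively charged |
| aromatic | centroid of each aromatic ring |
| hydrophobic | centroid of each maximal connected group of ≥ 3 carbons that are neither aromatic nor bonded to a heteroatom |

Features of one type are clustered across poses by single linkage with a
1.5 Å merge radius; a cluster becomes a model feature iff it draws
contributions from at least `ceiling(0.70 × n_references)` distinct poses
(14 of 20 at the defaults). Candidates pass at ≥ 5 matched features of 6,
with greedy nearest-first one-to-one assignment (ties broken by model
feature order — deterministic and, at 6 features, indistinguishable in
practice from optimal matching).

The specific published 6-feature model cannot be reproduced (it derives from
proprietary software and an unpublished reference set); the package
reproduces the *construction rule* and accepts any serialized model as JSON.
The 1.5 Å merge radius is our choice — small relative to typical
pharmacophore tolerances — and is configurable; no value is stated in the
protocol literature we re-implement.

## Criterion 4 — ADMET rules

The original protocol used a web service whose pass criteria are not stated.
The package substitutes explicit local rules, each configurable:

* Lipinski violations ≤ 1, counting MW > 500, logP > 5, HBD > 5, HBA > 10
  (strict inequalities). Donors are N/O with ≥ 1 H; acceptors are N/O not
  positively charged.
* ESOL solubility `logS = 0.16 − 0.63·logP − 0.0062·MW + 0.066·RB −
  0.74·AP` (AP = aromatic fraction of heavy atoms), class
  moderately-or-better required.
* Zero pan-assay-interference alerts from a bundled, documented subset of
  classic interference chemotypes (quinones, catechols, rhodanines,
  Michael-acceptor dienones, azo/nitroso, …). Full published catalogues are
  out of scope; users can supply their own pattern set.
* Cytochrome-isoform inhibition is an ML problem out of scope here; the
  pipeline joins an optional external 0/1 export and enforces ≤ 2 inhibited
  isoforms only when that input is present (the clause is skipped, with a
  log line, otherwise).

The logP estimator is a coarse atom-contribution scheme with documented
coefficients; tests assert only determinism and CH2-monotonicity, never
literature values, and the policy thresholds are where users should encode
any calibrated reading.

## Hit selection

Compounds passing all four criteria are sorted by normalised score
(ascending; "most potent" proxied by ligand efficiency, configurable to raw
score) and selected greedily under a Bemis–Murcko scaffold-diversity
constraint until `top_k` (default 5). The scaffold is computed by
iteratively deleting terminal non-ring heavy atoms to a fixpoint and
canonicalising the remainder; this uniform graph-pruning definition also
removes exocyclic double-bonded atoms, a deliberate simplification that
cannot split or merge equality classes within one run. Acyclic molecules
have an empty framework and are treated as one diversity class *per
compound*, so acyclic hits are never collapsed together.

## Contact analysis and ECIF

A residue is "in contact" when any of its heavy atoms is within 4.5 Å
(inclusive) of any ligand heavy atom — the same length scale used to define
the binding pocket. Persistence over a multi-frame ensemble is the fraction
of frames in contact, all frames weighted equally (no burn-in is dropped;
that is the caller's responsibility). The key-interaction rule passes a
compound contacting ≥ 3 of the colchicine set {Ala 180, Val 181, Cys 241,
Met 259, Ala 316} or the DJ-101 set {Val 181, Val 236, Leu 246, Asn 247,
Asn 347, Lys 350}. Richer interaction taxonomies (H-bond geometry, water
bridges) are deliberately not modelled; equivalence with trajectory-analysis
suites is not claimed.

ECIF vectors count typed protein–ligand heavy-atom pairs within 6.0 Å
(inclusive; the cited tool's convention leaves the number open, so it is a
config default here). Atom types are (element; explicit valence; heavy
degree; attached H; aromatic; ring). Protein atoms are typed from standard
amino-acid templates because PDB files carry no bonds; nonstandard residues
are skipped with a warning. The published pre-trained affinity model is not
shipped — redistribution of weights is avoided and the mechanism, not the
weights, is the contribution. The regressor is closed-form ridge (penalty
1e-8 by default, so noiseless linear worlds are recovered to machine
precision) or deterministic least-squares stump boosting.

# The synthetic world

All tests run against a generator that emulates the screen at desk scale
with *recorded* ground truth. Its defaults are the stated world: 50 library
compounds decorated over 5 ring-scaffold families, 8 reference actives, and
per-stage pass fractions of the same order as the published funnel
(similarity ≈ 0.1, docking 0.3, pharmacophore 0.6, ADMET 0.7), with 2
compounds planted to clear every stage.

* Structures are real, chemically valid molecules (decorated benzenes,
  pyridines, naphthalenes, thiophenes, cyclohexanes), because structural-key
  fingerprints are meaningless on random graphs.
* Reference actives are substituent homologues (methyl → ethyl) of
  designated library members — guaranteed > 0.9 structural-key Tanimoto —
  plus long-chain aliphatic decoys. The similarity *hit set* is recorded by
  running the similarity module at generation time: consensus thresholds
  are an empirical functional of the entire library, so no constructive
  statement of the hit set exists; the constructive guarantees are the
  planted near-duplicate similarities and the decoys' dissimilarity.
* Docking scores are drawn in normalised space strictly below (hits) or
  above (misses) the colchicine cutoff and multiplied back by each
  molecule's heavy-atom count — hit counts are exact by construction.
* Pose sets realise planted features with fragment chemistry chosen so
  feature classes do not overlap: protonated amines are donor-only,
  carbonyl oxygens acceptor-only, benzene hexagons aromatic-only, propane
  units hydrophobic-only. Feature positions are ≥ 6 Å apart (outside the
  1.5 Å merge radius) and jittered by ± 0.1 Å.
* ADMET failures carry a grafted catechol arm (a planted interference
  alert); passers use an alert-free substituent vocabulary.
* Toy complexes use single-atom placeholder residues positioned at exact
  planned distances — geometrically exact, biologically abstract.

What a green suite therefore establishes: every rule of the protocol is
implemented as stated, agrees with brute-force oracles, and is
deterministic, permutation-stable, and rigid-transform invariant where it
should be. What it does not establish: recovery of any published screening
count (those depend on a proprietary library, an unpublished active list,
and commercial docking/MD software), nor real-data performance of the
fingerprints, the logP scheme, or the affinity regressor.

# Numerical conventions and degenerate inputs

* Report rounding is half-away-from-zero (−10.01/29 → −0.345; 28/429 →
  6.5%); all comparisons use full precision.
* Tanimoto of two empty bit sets is defined as 0; thresholds require ≥ 2
  records (sample SD undefined below that) and may exceed 1, in which case
  no hit is possible — accepted, not clamped.
* Distance boundaries (contact 4.5 Å, ECIF 6.0 Å, docking cutoff,
  pharmacophore tolerance) are all inclusive, with a 1e-9 guard against
  floating-point representation error.
* Unparsable library/SDF records are logged and skipped; a batch never
  aborts on one bad record. Unreadable configured inputs fail at startup,
  before any computation.
* Canonical SMILES is an internal equality key (refinement-based canonical
  ranking; symmetric ties split deterministically). It is stable across
  input atom orderings but intentionally not comparable with other
  toolkits' canonical forms.

# Known limitations

* Aromaticity perception covers the common cases (6-membered C/N rings with
  alternating bonds; 5-membered C/N/O/S rings with a lone-pair heteroatom);
  exotic aromatic systems (azulenes, fused charged heteroaromatics) remain
  Kekulé.
* Stereochemistry is parsed and discarded; scaffolds and fingerprints are
  constitution-only.
* The substructure engine matches patterns written as SMILES with
  bracket-H minimum constraints — expressive enough for the bundled alert
  and key catalogues, but not a full query language.
* Protein typing assumes mid-chain residue environments (terminal OXT/NH3+
  adjustments ignored).
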