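# consensusVS

Consensus virtual screening for colchicine-site inhibitors of the
tubulin–microtubule (Tub–Mts) system — and, more generally, a reusable,
fully testable implementation of a four-criterion consensus screening
protocol for small-molecule libraries.

Destabilisers that bind the colchicine site at the α/β-tubulin interface are
a proven anticancer strategy, but hit-finding from natural-product libraries
is dominated by a few over-represented scaffolds. A *consensus* screen
combines ligand-based and structure-based filters so that no single method's
false positives survive:

1. **Similarity** — Tanimoto similarity `T(A,B) = |A∩B| / |A∪B|` against a
   panel of known actives, computed for two complementary fingerprints
   (166-slot structural keys and a radius-2 circular fingerprint). A
   compound passes when, against at least one active, both values are
   strictly above the empirical threshold `median + 1·SD` of the pooled
   similarity distribution.
2. **Docking efficiency** — external docking scores are normalised by
   heavy-atom count (`score / N_heavy`, a ligand-efficiency correction for
   size bias) and filtered at the reference inhibitor's value: colchicine's
   −10.01 over 29 heavy atoms gives the cutoff −0.345 (pass = equal or
   lower).
3. **Pharmacophore** — a consensus model is built from the docked binding
   modes of reference actives: features (donor, acceptor, aromatic centre,
   hydrophobic region) are clustered across poses and kept when present in
   ≥ 70% of references (14 of 20). A candidate passes when it matches ≥ 5 of
   the 6 model features in place.
4. **ADMET rules** — deterministic medicinal-chemistry filters: ≤ 1 Lipinski
   rule-of-five violation, ESOL solubility class moderately-or-better,
   zero pan-assay-interference (PAINS-style) alerts, and optionally ≤ 2
   inhibited cytochrome isoforms from an external classifier export.

Survivors of all four criteria are ranked by normalised score and selected
greedily under a Bemis–Murcko scaffold-diversity constraint (one hit per
framework). The package also implements per-residue contact persistence over
multi-frame ensembles (key-interaction checks against the colchicine and
DJ-101 residue sets) and extended-connectivity interaction features (ECIF:
typed protein–ligand atom-pair counts within 6 Å) with a pluggable
ridge/boosting regressor for pKi prediction.

The chemistry core (SMILES/SDF/PDB parsing, aromaticity perception,
canonicalisation, fingerprints, substructure search, scaffolds, descriptors)
is implemented natively in R — no external toolkit is required.

## Worked example

Everything below is computed by the package at run time (a synthetic fixture
world with planted ground truth; seed 7):

```r
library(consensusVS)

# the reference cutoff of criterion (2)
col <- parse_smiles(colchicine_smiles(), "colchicine")
heavy_atom_count(col)                          # 29
report_score(normalize_score(-10.01, 29))      # -0.345

# the prevalence rule of criterion (3)
min_reference_count(20, 0.70)                  # 14

# full synthetic screen
fx  <- generate_fixture_set(fixture_spec(seed = 7))
cfg <- run_config(library = fx$library, references = fx$references,
                  scores = fx$scores, reference_poses = fx$ref_poses$poses,
                  candidate_poses = fx$candidate_poses, seed = 7)
rec <- run_consensus(cfg)
attr(rec, "summary")$n_all                     # 3
attr(rec, "selected")                          # "LIB002" "LIB001" "LIB045"
```

The pipeline's Markdown report for this run prints:

```
- compounds screened: 50
- (1) similarity hits: 27 (54.0%)
- (2) docking hits: 15 (30.0%)
- (3) pharmacophore hits: 30 (60.0%)
- (4) ADMET hits: 35 (70.0%)
- all four criteria: 3 (6.0%)
- diverse selection: LIB002, LIB001, LIB045
```

Three compounds clear all four filters; the diverse selection keeps them
because their Bemis–Murcko frameworks differ (with two sharing a framework,
the worse-scoring one would be skipped). Every per-stage hit set equals the
fixture generator's recorded ground truth — that equality is asserted by the
test suite on every run.

## Command line

```sh
Rscript inst/cli/consensus-vs.R fixtures   --out fx --seed 7
Rscript inst/cli/consensus-vs.R run        --config cfg.json --out runout
Rscript inst/cli/consensus-vs.R similarity --library fx/library.smi --references fx/references.smi --out simout
Rscript inst/cli/consensus-vs.R dock-post  --library fx/library.smi --scores fx/scores.csv --out dockout
Rscript inst/cli/consensus-vs.R admet      --library fx/library.smi --out admetout
```

`cfg.json` holds paths (`library`, `references`, `scores`, `reference_poses`,
`candidate_poses`, optional `pharmacophore_model`, `cyp_flags`) and the
threshold overrides documented in `?run_config`.

## Scope notes

The docking and molecular-dynamics engines themselves are out of scope:
scores, poses, and trajectory frames are consumed as inputs. Published
screening counts for the original 429-compound natural-product library are
not reproducible without its unpublished reference-active list; the package
reproduces the *rules* of the protocol and validates them on synthetic
worlds with planted truth. See `vignettes/consensus-screening.Rmd` for the
methods account.
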