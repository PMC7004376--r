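---
title: "Pocket assignment and interaction analysis of drug poses in the HLA class I groove"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pocket assignment and interaction analysis of drug poses in the HLA class I groove}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlagroove)
```

## The scientific problem

Anti-thyroid drugs (methimazole, propylthiouracil) cause agranulocytosis
— a severe loss of granulocytes — in a small fraction of patients, and
case/control studies associate this reaction with particular HLA-B
alleles in different populations. Under the altered peptide repertoire
model, the drug binds non-covalently inside the peptide-binding groove,
a cleft between the two α-helices and the β-sheet platform that contains
six subsites (pockets A–F), and thereby shifts the set of self-peptides
presented to T cells. The informatics programme this package implements
asks: do the risk alleles share groove features — specific polymorphic
residues, or a preference for drug poses in a particular pocket — that
non-associated alleles lack?

The pipeline has six analysis stages plus a synthetic-data generator.
Each stage is a pure function of its inputs, so the whole pipeline is
reproducible bit-for-bit from a configuration and a seed.

## Control-allele selection

Association studies give case and study-control allele frequencies;
population databases give healthy frequencies for many populations. An
allele can safely be treated as non-associated when it shows no
enrichment in cases. Two rules implement this:

* **Screen**: only alleles with study-control frequency strictly over
  `min_control_freq` (default 0.03, i.e. over 3%) are considered —
  rarer alleles are uninformative.
* **Selection**: an allele is a control when its study-control
  frequency *or any* healthy-population frequency is similar to or
  greater than its case frequency. "Similar to" is not quantifiable
  from first principles, so it is a tunable relative margin: the best
  control-side frequency must reach `case_freq * (1 - tolerance)`,
  default `tolerance = 0.1`. The default is deliberately conservative:
  a 10% margin only absorbs small sampling wobble, so an allele with a
  genuinely elevated case frequency (odds ratios of interest here are
  5–70) is never admitted.

`odds_ratio()` supports reporting: `OR = ad/bc` on the carrier 2x2
table, with the Haldane–Anscombe 0.5 correction when a single cell is
zero (two zero cells in one margin leave the OR undefined and raise an
error), and a 95% CI from the log-OR normal approximation.

## Risk-unique residue scan

Aligned allele sequences carry one of four status labels: `risk`,
`possible_risk`, `control`, `common`. A column is *discriminating* when
all rows in the risk group share one residue and no row in the control
group carries it. Three conventions matter:

* Positions are reported in **mature-protein numbering** (signal
  peptide removed): the ungapped index of a designated reference row
  plus a configurable offset (0 for pre-trimmed sequences). Positions
  67 and 80 refer to this numbering.
* **Gaps never match** a residue, and columns with any gap in the risk
  group are skipped.
* `possible_risk` rows are excluded from both groups by default. This
  mirrors the treatment of an allele whose association is plausible but
  unconfirmed (it differs from a confirmed risk allele by a single
  Thr80Ile substitution); including it in either group is an explicit
  caller decision.

`mutation_label()` renders residue states against a reference residue
in the `N80T` convention used in the summary tables.

Alignment construction itself is delegated to any standard aligner; the
package consumes aligned FASTA plus a status CSV.

## Pocket model and pose assignment

Docked poses of chemically different ligands are compared through a
single designated **reference atom** (default `C1`, overridable per
ligand), so a five-atom ring and a larger thiouracil cluster together.
Assignment has three steps:

1. **Pocket model.** Each pocket is a set of mature-numbering residue
   positions; its centroid is the mean of the side-chain atom positions
   present in the structure. Defaults: F pocket
   {77, 80, 81, 84, 95, 116, 123, 124, 143, 146, 147} (the residues
   observed surrounding F-pocket ligand contacts, plus canonical 146),
   B pocket {7, 9, 24, 25, 34, 45, 63, 66, 67, 70, 99} (the canonical
   literature set — no single authoritative enumeration exists). Both
   are config-overridable.
2. **k-means with k = 2** on the reference-atom coordinates. Visual
   inspection of groove docking runs shows two distinct pose groups (B
   and F), fixing k. Because k-means is usually seed- and
   order-dependent, the implementation is made fully deterministic:
   10 restarts of farthest-point seeding (restart *r* starts from the
   *r*-th most peripheral point; all ties broken on coordinates), Lloyd
   iterations with empty clusters retaining their previous centre, best
   within-cluster sum of squares wins, and final cluster ids are
   relabelled by ascending centre coordinates. The `seed` argument is
   accepted for interface stability but cannot change the result;
   permuting pose order never changes any pose's label.
3. **Labelling.** Each cluster takes the label of the nearest pocket
   centroid among {B, F} to its cluster mean. Any individual pose whose
   reference atom lies farther than `groove_radius` (default 12 Å) from
   *both* centroids is relabelled `O` — outside the binding groove.
   The threshold is a reproducible surrogate for the visual
   outside-groove calls made when a docking search box extends beyond
   the groove; 12 Å comfortably exceeds the reach of any groove subsite
   from the B/F centroids while staying well inside the distance to
   surface pockets elsewhere on the molecule.

A consequence of fixing k = 2 worth knowing: when a pose set contains a
genuine outside-groove cloud *and* both B and F poses, the two groove
clouds can merge into one cluster (the outside cloud takes the other).
Outside poses are still flagged `O` correctly by the per-pose threshold,
but B/F counts within the groove are then approximate. Under
groove-only searches — the condition under which per-pocket counts are
interpreted — recovery is exact at realistic separations.

## Interaction detection and the Thr80 taxonomy

Contacts are detected heavy-atom-only, in the LigPlot style, with
config-overridable cutoffs (published interaction diagrams rarely state
their exact cutoffs, so these are explicit here):

* hydrophobic: protein C/S atom to ligand C/S atom at 2.9–3.9 Å;
* hydrogen bond: N/O/S donor–acceptor pair at ≤ 3.35 Å, with donor and
  acceptor capability taken from small per-residue templates (backbone
  N donates, backbone O accepts; side chains per standard chemistry;
  atoms not covered by a template count as both, so simplified
  synthetic residues behave sensibly). Ligand polar atoms default to
  both roles unless the pose carries explicit `donors`/`acceptors`
  annotations. No explicit hydrogens and no angle term.

The **thiocarbonyl sulfur** — the C=S group shared by the associated
anti-thyroid drugs — is located structurally: a terminal sulfur (exactly
one heavy neighbour within 1.85 Å) bonded to a carbon that has at least
two further heavy neighbours. The terminal-sulfur condition is what
separates C=S from thioethers (C–S–C), whose sulfur has two neighbours.
Absence of such a sulfur is a valid outcome (the non-thioamide
comparator ligands have none).

Each pose is then classified at a mature position (default 80):
`Thr80_S` if any contact at that position involves the thiocarbonyl
sulfur, `OtherThr80` if contacts exist at the position but none involve
that sulfur, `NoThr80` otherwise. `tabulate_thr80()` produces the
per-drug-allele count row plus the class of the minimum-score pose
(ties broken by lowest pose index).

## Pose summaries

One row per allele x drug x search space: the pocket label of the
lowest-scoring pose, per-pocket counts and per-pocket median scores.
Conventions fixed for determinism: even-count medians are the mean of
the two central values; empty pockets have undefined medians rendered
`"N/A"`; scores render to two decimals; minimum-score ties break by
lowest pose index. Multi-run analyses (e.g. 100 docking runs per
drug-allele pair) are summarised as five-number boxplot statistics
using type-7 (linear interpolation) quantiles.

## Motif comparison

An allele's peptide-binding motif is a 9x20 position-specific score
matrix. The distance between two motifs is `(1 - r)/2` where `r` is the
Pearson correlation of the flattened matrices — 0 for identical motifs,
1 for perfectly anti-correlated ones, matching the red(0)/white(1)
similarity scale of motif heat maps. This is a self-contained stand-in
for prediction-engine-based motif distances: the package accepts any
externally produced PSSMs rather than generating predictions itself.
The correlation distance satisfies symmetry and identity but not the
triangle inequality, which hierarchical clustering does not require.
Trees are UPGMA (average linkage), with labels sorted lexicographically
before clustering so equal-distance merges resolve deterministically,
emitted as rooted ultrametric `phylo` objects / Newick text.

## Structure and pose I/O

PDB and the AutoDock PDBQT dialect are parsed as fixed-width records;
PDBQT's partial-charge and atom-type tail columns are consumed only to
recover elements. Coordinates and residue numbers are taken verbatim
(author numbering); mapping to mature numbering is always an explicit,
separate step. Docking scores come from an embedded `REMARK ... SCORE`
line or a `run_id,score` sidecar CSV; if both are present they must
agree to 1e-6 (bit-exact provenance), and a pose without a resolvable
score is an error rather than a guess.

`superpose_rmsd()` matches atoms by (chain, residue number, atom name)
and by default applies Kabsch optimal superposition (SVD with
reflection correction). Because model-comparison RMSDs are sometimes
quoted without fitting — e.g. homology models built in the template
frame — `fit = FALSE` measures coordinates as given. The two modes
differ materially: displacing one atom of a 3-atom toy by 1 Å gives
exactly `sqrt(1/3)` ≈ 0.577 unfitted but ~0.03 after optimal
superposition.

## The synthetic-data generator

`sim_config()` fixes the study conditions; every stream (groove,
poses, sequences, frequencies, PSSMs) derives an independent substream
seed from the root seed, so adding one generator call never perturbs
another stream. Defaults and what they emulate:

* **Groove**: side-chain atoms for all configured B- and F-pocket
  residues around two centres 15 Å apart; residue 80 is THR (with OG1)
  and 67 CYS (with SG); everything else is an ALA stand-in. This is a
  geometric scaffold, not a protein fold.
* **Poses**: reference atoms Gaussian around the planted pocket centre
  with σ = 1.5 Å; 10 poses per search space; scores Normal per pocket
  (B −3.4, F −4.2, σ 0.3 kcal/mol — the magnitude and F-favouring
  direction of groove docking scores). Ligands are minimal literal
  geometries: a five-membered C/N ring with an optional C=S sulfur at
  1.68 Å — chemically plausible for distance-based contact logic, not
  force-field optimised.
* **Allele panel**: 2 risk, 1 possible-risk, 5 control, 4 common
  alleles of length 120, risk alleles sharing Cys67/Thr80 against an
  Asn-80 reference; the possible-risk allele equals one risk allele
  except for a single Thr80Ile change; scattered single-row private
  variation elsewhere. Names are synthetic (R01, P01, C01, …).
* **Frequency table**: planted odds ratio (default 7) for risk alleles
  on the allele-frequency scale, case/control frequencies binomially
  sampled on chromosomes at 50 cases / 1000 controls (the magnitudes
  typical of published agranulocytosis cohorts), plus two sub-threshold
  alleles exercising the 3%
  screen. Healthy frequencies come from 6 populations of 1000
  individuals whose true frequency is the background times a
  per-population factor U(0.6, 1.9) — population frequency databases
  show spreads of this size and larger between populations for HLA-B
  alleles, and the max-over-populations branch of the selection rule is
  exactly what makes the rule robust to case-frequency sampling noise
  at realistic cohort sizes.
* **PSSMs**: two Gaussian cluster prototypes, members = prototype +
  noise at 5% of the prototype's range, and one near-duplicate pair
  (noise at 0.2% of range) inside cluster 1 standing in for the
  almost-identical allele pair.

Planted truths (pose labels, planted positions, per-allele odds ratios,
cluster membership) travel only in a JSON sidecar, never in the
analysis-facing files.

What passing tests on these data do **not** show: real docking
energetics (scores are draws, not physics), real HLA sequence diversity
(only the planted-position contract holds), linkage between loci, or
prediction-engine motif scores. They do show that every algorithmic
step — screening, scanning, clustering, labelling, contact logic,
summarisation — is correct against independent brute-force oracles and
recovers planted structure under realistic geometry and noise.

## Numerical choices and degenerate inputs

* k-means ties (equidistant points, identical coordinates) break on
  coordinate order; all poses identical yields a single occupied
  cluster without error.
* Medians: even counts average the two central values; quantiles are
  type 7. Score rendering is fixed at two decimals.
* The hydrophobic window is closed on both ends; shrinking its upper
  bound can only remove records.
* Zero-variance PSSMs make correlation undefined and raise an error
  rather than returning a conventional value.
* Frequencies outside [0, 1], ragged alignments, duplicate allele
  names, duplicate pose `run_id`s, unresolvable scores, and pockets
  with no resolvable residues are all hard errors with messages naming
  the offending entity.

## Problem sizes

The validation suite runs 100 seeded replicates for pose-label
recovery, alignment-scan recovery and motif-tree recovery, 1000 random
groups for the summary oracle, 50 random complexes for the contact
oracle, and 200 tables for control-selection safety — sizes chosen so
the full suite completes in well under a minute while keeping binomial
confidence intervals on the measured rates tight enough to be
meaningful.

## Known limitations

* No mmCIF input, no cavity detection, no docking, and no
  peptide-binding prediction: the package starts from poses, sequences
  and matrices produced elsewhere.
* The B-pocket residue definition is a literature convention, not
  derived from the source analyses, and should be overridden when a
  different convention is in use.
* O-classification by distance threshold is a surrogate for visual
  inspection; with k fixed at 2, per-pocket counts in searches that
  include outside-groove sites are approximate (see above).
* Hydrogen-bond detection is heavy-atom and distance-only; no angles,
  no explicit hydrogens, no π-stacking or halogen bonds.
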