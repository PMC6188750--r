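---
title: "Characterizing protein-peptide interfaces from docked complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing protein-peptide interfaces from docked complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepterface)
library(dplyr)
```

## The analysis this package implements

Plants translate many small open reading frames (sORFs) into short
bioactive peptides. Stress-induced peptides (SIPs) of *Arabidopsis
thaliana* are a case in point: hundreds of candidate peptides with no
functional annotation. One productive way to generate hypotheses about
their function is structural: fragment the peptide catalogue into short
k-mers, screen the fragments against solved protein structures for
candidate binding pockets, dock the promising pairs, and then
*characterize* the docked complexes — what holds the peptide in place,
which residues pay for the binding, and whether the predicted pocket
coincides with a cofactor site or a subunit interface.

`pepterface` implements the characterization pipeline around such a
study. It deliberately does **not** dock, run molecular dynamics, or
solve the generalized Born equation; those stages are performed by
dedicated engines whose outputs (PDB models, per-snapshot MM/GBSA
tables) this package consumes. What it owns is everything downstream:

1. **Fragment library** — sliding-window k-mers with Kyte–Doolittle
   hydropathy descriptors.
2. **Screening statistics** — Benjamini–Hochberg adjustment, FDR
   filtering, and pocket-consistency analysis.
3. **Structure model** — a tidy atom table parsed from PDB with
   receptor/peptide role labels.
4. **Peptide builder** — idealized backbones from canonical dihedrals.
5. **Interaction profiler** — close contacts, hydrophobic contacts,
   hydrogen bonds, salt bridges, and pi–pi stacks from explicit
   geometric criteria.
6. **Interface/site overlap** — does the predicted pocket sit on a
   dimer interface or an annotated ligand/catalytic site?
7. **Energy decomposition** — binding free energies from MM/GBSA
   snapshot tables and the prominent-residue analysis.
8. **Dataset aggregation** — the cohort-level statistics.
9. **Synthetic data** — generators with planted ground truth that make
   the whole pipeline testable offline.

Everything is tibble-in, tibble-out, so steps compose with the pipe.

## Geometric criteria and their defaults

The detectors encode the interface conventions common in docking
post-processing tools:

| Interaction | Criterion | Default |
|---|---|---|
| Close contact | receptor atom within *d* of any peptide atom | d ≤ 4.0 Å (inclusive) |
| Hydrophobic contact | carbon–carbon cross-role pair | d ≤ 4.0 Å |
| Hydrogen bond | donor–acceptor distance and D–H…A deviation from linearity | d ≤ 4.0 Å, deviation ≤ 40° |
| Salt bridge | minimal distance between oppositely charged groups | d ≤ 4.0 Å |
| Pi–pi stack | ring-centroid distance and inter-plane angle | d ≤ 5.5 Å, angle ≤ 30° |
| Interface residue | Cα–Cα distance between chains | d **<** 6.0 Å (strict) |

Three of these deserve comment.

*Boundary semantics.* Every "within X Å" rule is inclusive (a pair at
exactly 4.0 Å counts), guarded by a 10⁻⁹ tolerance so analytically
placed boundary geometries are not lost to floating point. The
interface-residue rule is the one deliberate exception: it is strictly
"less than 6.0 Å", matching the phrasing conventionally used for
Cα-based interface definitions, and the package preserves that
asymmetry on purpose.

*Hydrogen bonds without hydrogens.* Docked models are often
unprotonated. When a model carries no explicit hydrogens the D–H…A
angle cannot be evaluated, so the detector falls back to a
distance-only rule with a stricter cutoff (D–A ≤ 3.5 Å) to compensate
for the missing angle gate, marks the result `geometry_incomplete`, and
leaves the donor side undetermined. Mixed behaviour within one model is
avoided: the fallback applies only when the model has no hydrogens at
all.

*Unstated criteria.* Salt-bridge and stacking cutoffs are rarely
printed by interaction analyzers. Our defaults — 4.0 Å minimal
inter-group distance (consistent with the close-contact scale), 5.5 Å /
30° parallel-only stacking, charged groups Arg {NE, NH1, NH2}, Lys
{NZ}, His {ND1, NE2}, Asp {OD1, OD2}, Glu {OE1, OE2} plus each chain's
N-terminal amine and C-terminal carboxylate — are documented
assumptions, configurable per call. His counts as both charged and
aromatic in composition statistics, as is conventional in this
literature. T-shaped ring geometries are not classed as stacks, and
cation–pi, halogen and water-mediated bridges are out of scope.

## Hydropathy and the fragment library

`generate_fragments()` slides windows of 4–10 residues (step 1) over
each SIP; duplicates are retained because each window carries its own
provenance, with `dedup = TRUE` available where a unique-sequence
library is wanted — both conventions appear in fragment-screening
studies, so both are provided. `gravy()` uses the published 20-residue
Kyte–Doolittle table stored as a versioned constant; the mean is
bounded by the scale extrema (−4.5, +4.5) and classification is
strictly positive ⇒ hydrophobic, so a GRAVY of exactly 0 is classed
hydrophilic. Non-standard letters (B, Z, X, U) are rejected at parse
with the offending position, never silently remapped.

```{r gravy}
gravy("LAEDTFGEIS")
library_summary(generate_fragments("LAEDTFGEIS"))
```

## Screening statistics

`bh_adjust()` applies the standard step-up false-discovery-rate
correction (delegating to `stats::p.adjust`; the test suite checks it
against an explicitly coded step-up rule), and `filter_fdr()` retains
hits at an inclusive cutoff, 0.25 by default — a deliberately permissive
threshold appropriate for an exploratory screen whose hits feed manual
triage and docking rather than final claims.

Pocket consistency ("do different peptides bind the same pocket of a
structure?") requires a notion of pocket identity that screening
servers do not define. We operationalize it as residue-set Jaccard
similarity ≥ 0.5, with greedy first-seen clustering so the result is
order-stable; the threshold is a parameter, and the reported
`frac_same_pocket` is the size of the largest pocket cluster over the
number of hits.

## Idealized peptide builders

`build_peptide()` places N, CA, C, O (and CB, except glycine) with
ideal bond lengths and angles (N–CA 1.458 Å, CA–C 1.525 Å, C–N
1.329 Å, C=O 1.231 Å; N-CA-C 111.0°, CA-C-N 117.2°, C-N-CA 121.7°) and
uniform backbone dihedrals; the three canonical conformers are
α-helical (−57°, −47°), extended (−139°, −135°) and polyproline (−78°,
+149°), all trans (ω = 180°). Side chains beyond CB are not built:
docking engines rebuild them anyway, and a CB-only model keeps every
placed atom verifiable. Atom placement uses the natural-extension
reference frame, so a build→measure round trip recovers the requested
dihedrals to numerical precision; `measure_dihedrals()` flags
degenerate (collinear) geometry as `NA` rather than failing.

```{r builder}
pep <- build_peptide("AAAAAAAAAA", "alpha")
head(measure_dihedrals(pep), 3)
helix_rise(pep)
```

A note on the helical-rise estimator: fitting the helix axis by a
principal-component fit of the CA cloud is biased upward on short
helices (a 10-mer reads ~1.61 Å/residue). `helix_rise()` instead
extracts the screw transformation mapping each residue's backbone onto
the next and reports the translation along its rotation axis, which is
exact for a uniform helix at any length — 1.564 Å/residue and
99.4°/turn-step for the α-conformer above, against the textbook 1.5 Å
and 100°.

## Binding energies and prominent residues

MM/GBSA snapshot tables are aggregated by the end-point formula: each
species' Gibbs energy is the sum of bonded, electrostatic, van der
Waals, polar-solvation and nonpolar-solvation terms, minus an entropy
term that the standard workflow omits (it defaults to absent);
per-snapshot binding energy is G(complex) − G(protein) − G(peptide),
and `delta_g_bind()` reports the mean and sample SD (n − 1; a single
snapshot reports SD 0 with a warning) over snapshots.

The prominent-residue rule: within each system, find the residue with
the largest contribution *in absolute value* — stabilizing or
destabilizing — set the threshold at 40 % of it, and keep every residue
whose |contribution| meets the threshold (inclusive). The
absolute-value, inclusive reading is our documented interpretation of
the usual "40 % of the largest contribution" phrasing; it is the only
reading under which stabilizing and destabilizing residues can coexist
in one selection, the selection is scale-invariant, and a
sign-symmetric system is treated symmetrically. Peptide residues are
additionally classed N-terminal / internal / C-terminal, the split that
exposes the characteristic destabilizing effect of the peptide's
charged N-terminal amine.

## What the synthetic generators emulate — and what they do not

`make_complex()` plants each requested interaction at exactly known
geometry in an isolated region of space ("stations" 40 Å apart along
one axis, with inert cap residues isolating the chain-terminus charged
groups), then applies a seeded rigid-body rotation. Placements are
solved analytically, not by optimization, so planted distances and
angles are exact to floating point; deliberately out-of-gate plants
(e.g. a 50°-bent hydrogen bond) carry `expected = FALSE` in the ground
truth. Distance-defined classes (close and hydrophobic contacts) take
their truth from a brute-force enumeration over the final coordinates,
because for those classes the enumeration *is* the definition.

`make_screening_table()` mixes uniform null p-values with
Beta(0.1, 10) signals; `make_decomposition()` builds snapshot tables
whose per-snapshot binding energy is ΔG* + Normal(0, σ) while the
per-residue table sums to ΔG* exactly; `make_cohort()` draws per-system
statistics from the distributions that characterize a 104-system
docking study — close contacts ~ Normal(167, 49) truncated at zero,
hydrophobic contacts ~ Normal(24, 8), hydrogen bonds ~ Normal(4.5, 2),
protein-side donors centred on 51 %, the
bridge-only : stack-only : both : neither split at
52 : 7.7 : 5.8 : 34.6 (normalized), conditional bridge and stack counts
~ Normal(1.72, 1) and Normal(1.63, 0.7) with a floor of 1, and
participation fractions centred on 23.8 % (side chain) and 38.7 %
(backbone). The cohort's binding energies are drawn from
Normal(−20, 9) kcal/mol: no cohort mean is published for such studies,
so we chose a distribution under which ~99 % of systems bind favourably
(about 103 of 104) and a −48 kcal/mol binder sits in the strong tail,
then froze it.

These fixtures are geometric scaffolds with correct local chemistry,
not foldable proteins. Passing tests therefore demonstrate that the
*detectors and statistics* are correct against known truth; they do not
validate docking poses, force-field energetics, or the realism of any
particular complex. Real models add the failure modes the generators
exclude: missing atoms, alternate conformations, chain breaks, and
correlated geometry between interaction classes.

## Numerical choices and degenerate inputs

* All "within" cutoffs inclusive with a 10⁻⁹ guard; interface rule
  strict (above).
* Grid contact search uses cutoff-sized cells and 27-neighbourhood
  lookup; it is required (and tested) to equal the all-pairs scan
  exactly, not approximately.
* altLoc resolution keeps the highest-occupancy conformer, ties broken
  alphabetically; waters and monoatomic ions are always dropped, other
  HETATM groups only without `keep_het = TRUE`; model 1 only.
* Aromatic rings with fewer than five resolved atoms are skipped with a
  warning; ring normals come from a least-squares (SVD) plane fit.
* Insertion codes ride along in residue identity; residue numbers are
  taken verbatim from the file, since site annotations use author
  numbering.
* `sd` is the sample standard deviation throughout, and the "±" in
  cohort summaries denotes SD, not SE.
* All-zero decomposition tables yield an empty prominent-residue
  selection with a degenerate-system warning; out-of-range inputs
  (p-values outside (0, 1], residue indices outside the peptide) are
  errors, not silent fixes.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data at sizes chosen for tight feedback: 100-fixture oracle sweeps,
10-residue peptides, 200-replicate screening and energy-recovery
studies, and 20 replicate cohorts of 104 systems for the dataset
statistics. All are package choices, set once in code; every number
reported by `scripts/acceptance.R` is recomputed from these inputs at
run time.

## Limitations

* No mmCIF input, no assembly generation, no protonation-state
  prediction; single-model PDB only.
* Hydrogen-bond chemistry is element-level (N/O donors with attached H,
  N/O acceptors); no hybridization-aware acceptor table.
* No cation–pi, halogen-bond or water-mediated interaction classes.
* The pipeline consumes MM/GBSA tables; it cannot diagnose problems
  upstream of them.
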