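---
title: "Counting near-attack conformations and classifying C–H site selectivity"
author: "nacsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting near-attack conformations and classifying C–H site selectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nacsel)
```

## The model

Non-heme Fe(II)/α-ketoglutarate-dependent dioxygenases (αKGDs)
hydroxylate aliphatic C–H bonds via an Fe(IV)=O (ferryl) species. The
abstraction step is rate-limiting, so the probability that a given C–H
bond reacts is usefully decomposed into

* an **intrinsic term** — the activation free energy ΔG‡ of hydrogen
  abstraction at that site against a bare truncated active-site model
  (a *theozyme*: Fe(IV)=O, two imidazole N donors for the His ligands,
  two carboxylate O donors for Asp and the succinate co-product, one
  water), and
* a **conformational term** — the fraction of an equilibrium ensemble in
  which the site presents a hydrogen in abstraction-ready geometry over
  the ferryl oxygen.

nacsel computes the conformational term by direct counting, consumes the
intrinsic term as a user-supplied table (quantum-chemical barrier
computation is out of scope), and combines the two with structural
hydrogen-bond evidence into one of three mechanistic calls.

### The active-conformation (NAC) criterion

A site is *active* in a frame when **any** of its hydrogens satisfies

$$d(\mathrm{O\cdots H}) \le d_{\max}, \qquad
  \theta(\mathrm{O\text{–}H\text{–}C}) \in
  [\theta_0 - \Delta\theta,\; \min(\theta_0 + \Delta\theta, 180^\circ)]$$

with the vertex at the hydrogen. Defaults are $d_{\max} = 2.8$ Å,
$\theta_0 = 170°$, $\Delta\theta = 15°$. Three boundary conventions are
deliberate and tested:

* **all boundaries are inclusive** (the distance criterion is stated
  with ≤; we extend inclusivity to the angle window for consistency);
* the angle window is **capped at 180°**, since a three-point angle
  cannot exceed it although the nominal window reaches 185°;
* **any hydrogen qualifies the site** — a methyl reacts through
  whichever of its three hydrogens is presented, and counting is per
  conformation per site, not per hydrogen.

The operative 2.8 Å threshold is used verbatim as a parameter; we do not
re-derive it from van der Waals radii (the Bondi C+O sum would be 3.22
Å). All criterion values are config-exposed; reports record them in
their provenance headers so non-default runs are visible.

## Hydrogen placement

Crystallographic models deposit no aliphatic hydrogens, but the
criterion is evaluated at the hydrogen. `place_site_hydrogens()` builds
them deterministically at ideal sp³ geometry with C–H = 1.09 Å:

* **CH** (3 heavy neighbours): along the negated normalised sum of the
  three neighbour unit vectors;
* **CH₂**: two hydrogens in the plane through the external bisector,
  perpendicular to the heavy–C–heavy plane, H–C–H = 109.47°;
* **CH₃**: tetrahedral cone about the C–neighbour axis, torsionally
  staggered against the lowest-index heavy atom bonded to the
  neighbour; a `rotamers` option scores additional rotor orientations
  and the tally keeps the best hydrogen.

Ideal placement rather than force-field minimisation is a deliberate
choice: the criterion tolerates ~0.1 Å of hydrogen-position error,
whereas determinism (identical input ⟹ identical counts) is essential
for a reproducible statistic. Explicit hydrogens in the model, when
present (e.g. MD-derived ensembles), are used verbatim. Placement
commutes with rigid-body motion to 10⁻⁶ Å, which is what makes NAC
counts exactly invariant under global transforms of an ensemble.

Degenerate neighbour geometry (collinear within 1°) is refused rather
than silently patched.

## Site perception

`infer_bonds()` uses single-bond covalent radii (Cordero consensus
values) with a slack of 0.45 Å; hydrogen–hydrogen pairs are never
bonded, and each hydrogen keeps only its nearest heavy atom.
`classify_carbon_sites()` then admits carbons with 1–3 heavy neighbours
and excludes

* carbonyl carbons — any C–O bond shorter than 1.30 Å;
* members of planar rings whose atoms all have exactly three bonds — an
  aromaticity *proxy* (least-squares-plane deviation < 0.1 Å), not
  Hückel perception. The DKP substrates and their aliphatic arms do not
  need more; strongly puckered aromatics or exotic ring systems would.

Deposited atom names do not carry a pathway's site numbering, so site
labels come from a YAML map (`inst/extdata/site_labels.yaml` ships the
vocabulary for substrates 1–3: C-7, C-2′, C-5a, C-6, C-5, C-3′).

## Inherent reactivity and strategy classification

`load_barriers()` reads `site → ΔG‡ (kcal/mol)` tables;
`inherent_site()` returns the minimal-barrier site, with exact ties
flagged — a tied table cannot support a classification and
`classify_strategy()` refuses it explicitly rather than guessing.

`detect_directing_contact()` requires (a) a substrate hydroxyl oxygen
(single heavy neighbour, bond ≥ 1.30 Å) within **2 covalent bonds** of
the reacting carbon — the vicinal-hydroxyl relationship abstracted from
the 2′-OH → C-3′ and 7-OH → C-6 cases — and (b) a protein O/N within
**3.5 Å** of that oxygen. Detection is heavy-atom-distance only, with no
angle term: crystal models lack polar hydrogens, and 3.5 Å is the
conventional cutoff. Both parameters are config-exposed.

The classification is a total three-way partition: observed = inherent ⟹
substrate control; otherwise directing-group control if evidence is
present, steric control if not. The observed site may come from
experiment or from `predict_sites()`; the provenance is recorded in the
narrative and reports flag disagreements between the two rather than
hiding one.

`predict_sites()` orders active sites by count, breaking ties by the
mean minimal qualifying O···H distance (closer approach first), then
lexicographically — a deterministic total order.

## Pocket volume

`pocket_volume()` is a POCASA-like grid descriptor: points within
`shell_radius` of a centre count when they escape every atom's van der
Waals sphere inflated by the probe radius (1.4 Å, water) and are
*buried* — marching along at least `buriedness_k` = 16 of the 26 lattice
directions meets an atom within the shell radius. The grid (spacing
0.5 Å default) is anchored at the centre, so the estimate is exactly
translation-invariant and rotation-invariant only to within
discretisation (tested at 10%). It is an order-of-magnitude and
rank-comparison tool; agreement with any particular cavity server's
algorithm is not claimed.

## What the synthetic generator emulates — and what it does not

`build_theozyme()` places the octahedral first shell with the oxo on +z
(Fe=O 1.62 Å — a conventional ferryl length, configurable, not a
measured value). `build_dkp()` constructs idealised, internally rigid
DKP substrates whose labelled sites have the correct CH/CH₂/CH₃ classes
and hydroxyl topology (7-OH on substrate 2; 7-OH and 2′-OH on substrate
3). `sample_nac_ensemble()` rigidly re-poses the substrate per frame:
with probability `f_active` into a constructed pose whose target
hydrogen satisfies the criterion with margin (d drawn in [2.0, 2.7] Å, θ
in [160°, 180°]) while all other sites stay ≥ 3.5 Å from the oxo;
otherwise into a distant pose with every site hydrogen beyond 3.2 Å.
The pose is found by a deterministic search over discrete orientations
(15° azimuth/spin grid, all target hydrogens), so the ground truth in
the ledger is **exact by construction**, not statistical — which is what
allows the tally tests to demand exact equality.

The generator emulates only what the NAC statistic reads: O/H/C
geometry over an ensemble. It has no force field, no solvent, no
thermostat, no internal substrate flexibility, and frames are
exchangeable (no autocorrelation). Passing the planted-recovery tests
therefore demonstrates that counting, perception and hydrogen placement
are correct — it does not demonstrate that any real trajectory would
show a particular count, and the MD-derived counts quoted for the real
enzyme systems (e.g. 10/5000) are reproducible only from the original
trajectories, which this package consumes but does not produce.

## Numerical and design choices

* Models are 0-indexed internally and 1-indexed in reports, matching
  PDB MODEL numbering; coordinates are Cartesian Å throughout.
* Altlocs resolve to highest occupancy, ties to `'A'`.
* Whole-structure RMSD pairs Cα atoms by global sequence alignment with
  identity scoring, not by residue number — homologues at 35–42%
  identity do not share numbering. No outlier-rejection cycles are
  applied; fit-and-reject protocols can shift RMSD by ~0.1–0.3 Å, so a
  single-pass all-pair fit is the reproducible default.
* The Kabsch rotation is forced proper (det = +1); near-collinear
  pairings are refused.
* Errors are classed conditions (`nacsel_config_error`,
  `nacsel_parse_error`, `nacsel_compute_error`); the command-line
  driver maps them to exit codes 2/3/4. Report writers delete partial
  outputs on failure.
* Report rounding follows crystallographic convention — distances to
  0.1 Å, angles to 1° — with machine-precision values kept in the JSON
  twins.

## Problem sizes

The shipped validation uses ensembles up to 5000 frames (the scale of
the motivating snapshot analyses) for planted-count recovery, 50-frame
mini-ensembles for brute-force oracle equivalence, 400–500-atom cavity
cages for the pocket descriptor, and 120-residue Cα traces for
superposition checks. A 5000-frame tally over four sites runs in a few
seconds on one CPU.

## Known limitations

* No bond-order or protonation perception beyond the carbonyl length
  cutoff; aromaticity is a planarity proxy.
* Methyl rotor orientation is idealised; the `rotamers` option bounds
  the error but a freely rotating methyl in a real trajectory samples
  continuously.
* Hydrogen-bond evidence is distance-only and heavy-atom based.
* The pocket descriptor depends on grid alignment at the ~5% level and
  on the buriedness threshold; only ranks and magnitudes are meaningful.
* Trajectory formats (DCD/XTC) are not read; export ensembles as
  multi-MODEL PDB first.
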