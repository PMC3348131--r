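---
title: "Methods: ensemble generation, pocket detection, tracking and Provar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble generation, pocket detection, tracking and Provar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and numerical
choices: what each stage assumes, which parameters matter and why their
defaults are what they are, what the synthetic fixtures do and do not
emulate, and where the design was genuinely open.

## Scope and substrate

All geometry is defined on **heavy atoms of standard amino acids**.
Hydrogens and heteroatoms (ligands, waters, ions) are stripped on input.
This removes any dependency on protonation placement, at the cost of
slightly cruder hydrogen-bond detection (donor–acceptor N/O distance
only, no angle term). No energy minimisation is performed; cleanup is
purely record-level. Alternate locations resolve to the highest-occupancy
copy, ties to the first listed. Multi-chain files default to the first
chain with at least 50 standard residues; insertion codes stay part of
the residue key and residues are never renumbered.

## Conformational ensembles by distance constraints

The sampler emulates the classic distance-constraint approach: native-like
conformers are exactly the coordinate sets that keep every interatomic
distance close to its template value, with "close" graded by interaction
strength.

**Constraint library.** All atom pairs within the 6.0 Å contact cutoff are
constrained to their observed distance ± a category tolerance:

| category           | detection                                     | tolerance (Å) |
|--------------------|-----------------------------------------------|---------------|
| covalent           | d ≤ 1.2 × (sum of covalent radii)             | ± 0.05        |
| angle (1-3)        | two bonds sharing an atom                     | ± 0.10        |
| hydrogen bond      | N/O pair within 3.5 Å, not bonded/1-3         | ± 0.30        |
| nonbonded contact  | any other pair within 6.0 Å                   | ± 1.5         |

The hydrogen-bond tolerance of ± 0.30 Å sits between the angle and
contact categories, reflecting intermediate interaction strength; all
four values are configurable through `constraint_policy()`.

**Sampling and correction.** Each conformer starts from the template plus
an isotropic Gaussian displacement per atom (σ = 0.75 Å by default). This
is deliberately conservative — it biases sampling toward the native basin
rather than regenerating coordinates from scratch. A correction loop then
visits every constraint in a freshly randomised order per sweep and, for
each violated pair, moves both atoms half-way each along their separation
vector onto the nearest bound (classic pairwise projection). Sweeps stop
when the **total violation** (summed one-sided bound excesses) falls to a
convergence tolerance of 1e-3 Å, or after `max_iter = 1000` sweeps. A
candidate is accepted when its total violation is at most the rejection
threshold of 30 Å. Because the loop converges far below the threshold in
practice, acceptance is effectively a guard against pathological starts.
The 30 Å default is generous relative to the convergence target; we
suspect thresholds an order of magnitude smaller are equally sensible,
and the value is exposed for that reason.

**Chirality.** Distance constraints are blind to handedness: a mirrored
side chain satisfies every pair bound. After correction, each residue's
Cα improper sign (det[N−Cα, C−Cα, Cβ−Cα]) is compared with the template;
flipped residues have their Cβ reflected across their own N–Cα–C plane —
a reflection preserves Cβ's distances to those three atoms exactly — and
correction resumes for up to three rounds. A conformer is additionally
rejected if fewer than 95% of checkable residues keep their template
sign; with the restoration step this guard rarely fires.

**Determinism.** The master seed draws the per-member sub-seed stream;
each conformer's perturbation and sweep orderings run under its sub-seed
in R's RNG. `(structure, parameters, seed)` therefore fully determine the
ensemble, including its multi-model PDB serialisation. All package
functions restore the caller's RNG state.

Accepted conformers are superposed onto the template (Kabsch/SVD over Cα,
falling back to all atoms for Cα-free toys) so that downstream
geometric-centre matching operates in one common frame.

## Pocket detection

Site points are grid positions (default spacing 1.0 Å) that are
solvent-side yet buried:

1. **outside** every van der Waals sphere (C 1.70, N 1.55, O 1.52,
   S 1.80 Å), and within 8 Å of the surface;
2. **enclosed**: of 66 rays cast along a fixed Fibonacci-sphere direction
   set, truncated at 12 Å, at least a fraction 2/3 must hit protein.

Two of these constants deserve justification because they were genuinely
open design choices:

- **Ray range 12 Å.** The range must cover the diameter of the pockets of
  interest: with a shorter range, rays crossing a wide cavity report
  "open" even though the cavity is sealed, deflating enclosure for
  wall-adjacent points. 12 Å covers every chord of the default test
  cavity (radius 6 Å) and is the scale of a large drug-binding pocket.
- **Enclosure floor 2/3.** A point just above an infinite flat surface
  has at most half of all directions blocked (exactly 1/2 in the
  infinite-range limit), so any floor ≤ 1/2 would carpet flat and convex
  surfaces with site points. The floor must exceed 1/2; we use 2/3 —
  "buried in at least two thirds of directions" — which also trims the
  shallow funnel at a pocket mouth. The value was calibrated once on the
  shell-cavity fixture against its analytic volume and is exposed in
  `pocket_config()`.

Site points cluster into pockets by 26-neighbour grid connectivity;
components below 15 points are discarded, the rest are ranked by
SiteScore and at most the top 10 are reported. Volume is one grid cell
per site point (n × spacing³).

**Typing and scores.** Each site point takes its nearest atom's
chemistry: N → donor, O → acceptor; apolar side-chain C/S → hydrophobic,
but only under a restrictive rule requiring at least two apolar atoms
within 4.5 Å; everything else is philic-neutral. The hydrophobic fraction
(scaled by a unit calibration constant) gives `h`, the complementary
polar fraction gives `p`, and `balance = h/p` with the denominator
floored at 0.1 and the ratio capped at 10 so the all-hydrophobic limit is
finite. SiteScore and Dscore use the published coefficient sets
(0.0733, 0.6688, 0.20) and (0.094, 0.60, 0.324); both are replaceable in
`pocket_config()` for recalibration.

**Rigid-motion invariance.** A world-anchored grid would make pocket
properties depend on the input frame. The grid is therefore anchored in a
canonical frame: the atom centroid plus principal axes, with axis signs
fixed by the third central moment. For structures with non-degenerate
inertia this makes volume, enclosure, character and scores invariant
under rotation and translation of the input to high precision. The
canonical frame is undefined for exactly symmetric bodies (a perfect
sphere has no preferred axes) — the near-spherical shell fixture is thus
the one place the invariance guarantee does not apply, and the
invariance tests use the asymmetric fixtures.

**Tie-breaks and degenerate inputs.** Ranking ties resolve by volume,
then lexicographically lowest centre. An empty site-point set yields an
empty pocket table, not an error; a structure with no atoms is an error.

## Tracking and persistence

Pocket identity across conformers uses geometric-centre matching against
a labelled catalog built from the template's pockets. Nearest reference
centre at distance d: d ≤ 3.75 Å assigns automatically (both boundaries
are taken inclusive on the lower-status side — the sources of these
cutoffs do not state inclusivity, so this is a declared convention);
3.75 < d ≤ 10 Å is *ambiguous* and carries the nearest label only as a
suggestion — the band that a human would inspect is never silently
auto-assigned; d > 10 Å everywhere is *new*. If two or more reference
centres fall within the auto cutoff the pocket straddles them and gets a
merged label joining the letters alphabetically with underscores
(`C_E`), treated as a distinct row in all reports.

Persistence of a label is the fraction of conformers containing at least
one *assigned* pocket with that label; ambiguous assignments never count,
and a conformer with two same-label pockets counts once.

## Provar propensities

For each conformer, a residue is pocket-lining (score 1) when any of its
atoms lies within 3.75 Å — inclusive, atom-to-sphere-centre, radii not
subtracted — of any pocket sphere; the per-residue mean over the ensemble
is the propensity. Quartiles of the propensity distribution (linear
interpolation between order statistics, quantile type 7 — declared here
because several conventions exist) provide the white and red limits for
colour mapping, and the propensities are written to the B-factor column
at two decimals, which bounds the round-trip error at 0.005.

## Reporting and docking-conformer selection

Per-site property distributions collect one value per conformer (the
highest-SiteScore pocket when a conformer has duplicates of a label — the
alternative, largest pocket, is equally defensible; this choice is fixed
and documented) and summarise as five-number boxplot statistics under the
same type-7 quartile convention. The docking pick for a site takes the
conformers with the top five SiteScores — score ties at rank five admit
all tied candidates — and among them the largest pocket volume, final
ties to the lowest conformer id. Externally supplied per-structure values
(e.g. from crystal structures) can be overlaid on the ensemble summaries
and flagged as within/below/above the observed range.

## What the fixtures emulate — and what they do not

The fixtures give every stage exact ground truth: the shell cavity has an
analytic volume (sphere minus the aperture's spherical cap), the slab
provably contains no concavity, the two-cavity fixture has two known
centres, the helix bundle has ideal backbone geometry (built by
natural-extension internal coordinates at φ/ψ = −57°/−47°) so covalent,
angle and hydrogen-bond detection and the chirality guard are genuinely
exercised, and the mask ensemble places pocket spheres so that Provar
recovery is exact by construction.

They are not proteins. Passing tests demonstrate that the geometry,
bookkeeping and statistics are correct, not that the druggability
calibration transfers to real structures: fixtures have no sequence
diversity, no side-chain packing, no solvent, and pocket walls of uniform
chemistry. Test problem sizes (300-atom bundles, 100-member ensembles,
~10⁴-point grids) were chosen as the smallest sizes at which every
contract — including the 100-conformer study condition — is exercised in
full.

## Known limitations

- The sampler is a conservative native-basin explorer; it does not
  reproduce any specific external conformer generator's output, its
  constraint taxonomy, or large-scale motions (no attempt is made to
  match published maximum-RMSD figures for such tools).
- Enclosure by ray casting reproduces the qualitative meaning of
  proprietary implementations, not their numerical output; likewise the
  score coefficients are the published calibration, while the upstream
  equations themselves are not publicly printed in full.
- Hydrogen bonds are detected without angular terms (heavy atoms only).
- Pocket correspondence assumes a common superposed frame; tracking
  across non-superposable folds is out of scope.
- The grid canonical frame is undefined for exactly symmetric inputs
  (degenerate principal axes).
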