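---
title: "Sphere-neighborhood RMSD profiling of RNA 3D models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sphere-neighborhood RMSD profiling of RNA 3D models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnasphere)
```

## The problem and the model

Predicted RNA 3D structures are usually scored against an experimentally
determined reference with a single global RMSD after optimal
superposition. A single number hides *where* a model is wrong: a
prediction can reproduce every helix locally yet misplace a whole domain,
or get the global fold right while mangling a loop. `rnasphere`
implements a local-neighborhood assessment that interpolates continuously
between those two views.

For every nucleotide $i$ of the reference, a sphere of radius $r$ is
centred on a user-chosen anchor atom of that residue (one of C1′, P,
O5′, O3′). The set $S_i(r)$ of **all** reference atoms inside the closed
ball — any residue, any chain — is collected, the corresponding model
atoms are identified, and the two point sets are optimally superimposed.
The score of cell $(i, r)$ is

$$\mathrm{RMSD}_i(r) \;=\; \min_{R,\,t}\;
\sqrt{\tfrac{1}{|S_i(r)|}\sum_{a \in S_i(r)}
\big\lVert R\,x^{\mathrm{model}}_a + t - x^{\mathrm{ref}}_a \big\rVert^2},$$

with $R$ restricted to proper rotations. Sweeping a radii vector
(default 3, 8, 20, 38, 300 Å) produces a residue × radius profile
matrix per model. Two limits anchor its interpretation: at small $r$ the
score reflects the local covalent geometry around one nucleotide; once
$r$ reaches the extent of the molecule every sphere contains every atom,
so each row equals the whole-molecule global RMSD — in this
implementation exactly, bit for bit, because the atom sets and the code
path coincide.

### Superposition

The minimizing rotation is computed by the Kabsch/McLachlan procedure:
subtract centroids, form the $3\times 3$ covariance matrix, take its
SVD, and flip the sign of the smallest singular direction whenever the
naive solution would be a reflection, so the returned rotation always
has $\det R = +1$. Reflected fits are never accepted, even when they
would score lower — a mirror image of an RNA is a wrong model, not a
good one. Rank-deficient (collinear or coplanar) point sets are still
fitted — the sign correction makes the answer well defined — but the
result carries a `degenerate` flag. Bit-identical input sets
short-circuit to the identity transform so self-comparisons are exactly
zero rather than SVD noise of order $10^{-15}$.

### Atom correspondence

Reference and model atoms are paired by structural key — (chain,
residue number, insertion code, atom name) after name normalization —
never by PDB serial number, which is a file-layout artifact. Unmatched
atoms on either side are reported, not dropped silently. Atoms of the
reference sphere whose model partner is missing are excluded from the
fit, and the fraction retained is reported as the sphere's *coverage*;
a strict mode turns any coverage below 1 into a hard failure.

### Gaps

A sphere can be undefined: its residue may lack the chosen center atom
(5′-terminal phosphates are routinely absent), or fewer than 3 paired
atoms may remain, which is below the minimum for a defined rigid-body
fit. Such cells are recorded as gaps with a reason code. Gaps are
excluded from averaged curves and from cutoff denominators rather than
being scored as infinitely bad; penalizing a missing terminal phosphate
as a modeling error would distort every aggregate. They render as breaks
in line plots and as neutral grey in maps.

## Aggregates and plots

* **Averaged curve** — the unweighted arithmetic mean of defined
  per-residue RMSDs at each radius (per nucleotide, not per atom).
* **Cutoff curve** — per radius, the percentage of defined nucleotides
  with RMSD at or below a threshold. The comparison is inclusive
  (`<=`), which keeps the self-comparison at exactly 100 % for any
  positive threshold.
* Five renderers (multi-model lines at a fixed radius; averaged curves;
  a residue × radius heat map, blue = low RMSD to red = high; a 3D
  surface of the same grid; cutoff curves) all run headless, write PNG
  or SVG, and return the plotted series invisibly so tests and callers
  can assert on data rather than pixels. Color assignment per model is
  deterministic in the model list; heat maps accept a shared `zlim` so
  a batch of models is displayed on one scale. The multi-model plot is
  Y-scaled to the worst model at that radius. The radius axis is linear
  by default with an optional log scale, since a molecule-covering
  radius such as 300 Å otherwise compresses the informative range.

## Input handling

PDB files are read at the record level through `bio3d`, then normalized:

* legacy atom-name dialect `*` mapped to `'` (`C1*` → `C1'`);
* alternate locations resolved to the highest-occupancy conformer,
  ties broken by altLoc letter so output is deterministic; duplicate
  keys *without* altLoc codes are left in place so validation can
  report them as the file defect they are;
* hydrogens and HETATM records excluded by default (models often omit
  hydrogens; an asymmetric correspondence would bias every sphere) —
  both re-includable by flag;
* multi-MODEL files: one MODEL block is used, the first by default;
* residue identity is (chain, number, insertion code), kept verbatim —
  the package never renumbers.

Validation reports every finding instead of stopping at the first:
duplicate residue identities (error), residues missing a center-atom
candidate, non-nucleotide residue names, and numbering breaks within a
chain (warnings).

## Synthetic references and decoys

The package tests itself on generated structures, not downloads.
`generate_helix()` builds an idealized single-stranded pseudo-RNA helix:
residue $i$ at axial height $(i-1)\,\mathrm{rise}$ and phase
$(i-1)\,\mathrm{twist}$, 13 named atoms per residue at fixed offsets in
the rotating local frame, with C1′ exactly on the backbone cylinder so
its inter-residue distances have a closed form. Defaults (rise 2.81 Å,
twist 32.7°, C1′ radius 9.4 Å) approximate A-form dimensions, giving
C1′–C1′ steps near 6 Å and atom densities at which the default radii
(3, 8, 20, 38 Å) produce spheres spanning one residue, a few
neighbors, a turn, and a large fragment, respectively. Geometry is
deterministic; the seed only draws the base sequence.

`perturb_structure()` produces controlled decoys: whole-molecule rigid
motion (which the method must score as zero), i.i.d. Gaussian coordinate
noise, displacement of chosen residues, rigid rotation of a contiguous
segment about a hinge, and deletion of named atoms. Each call is seeded
and restores the caller's RNG state.

What the fixtures do *not* emulate: real base-pairing geometry,
chemical plausibility, multi-chain complexes, modified nucleotides, or
correlated model errors. Passing tests demonstrate the geometric
correctness of the scoring machinery; they say nothing about how
informative any particular radius is for real predictions.

## Numerical choices

* Sphere membership uses the closed ball (distance ≤ radius). This
  makes the radius-limit identity exact and the membership monotone in
  the radius.
* Minimum 3 paired atoms per fit; below that, a gap.
* Superpositions are unweighted — no mass or occupancy weighting.
* Profiles are deterministic: identical inputs give bit-identical
  matrices, and profile CSVs store values at 17 significant digits so
  write/read round-trips are lossless.
* The noise-recovery check uses the fact that i.i.d. per-coordinate
  noise of sd $\sigma$ yields an expected whole-molecule RMSD of
  $\sigma\sqrt{3}$, with a delta-method standard error of
  $\sigma/\sqrt{2n}$ and an $O(1/n)$ downward bias from the 6 fitted
  rigid-body parameters — negligible at the $n \ge 500$ atoms used.

## Design decisions that were genuinely open

* **Pairing by key, not serial.** Atom serial numbers differ across
  predictors' files; structural keys are what shared numbering actually
  means in practice.
* **Spheres may cross chains.** No atom of the reference is excluded
  from a neighborhood on chain identity.
* **Missing model atoms degrade coverage rather than abort** (strict
  mode available), since real submissions with missing atoms are still
  scored in practice.
* **Inclusive cutoff comparison** (`<=`): the boundary convention is
  not dictated by the method; inclusivity keeps the zero-RMSD self-test
  at exactly 100 %.
* **Gap cells excluded from aggregates** rather than treated as
  infinite error.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run on helices of 10–40
residues (130–520 atoms), 50 random rigid motions, 200 random point
sets of 4–8 atoms for the superposition-vs-grid-search comparison, and
noise levels σ ∈ {0.5, 1, 2} Å. These sizes were chosen so that every
statistical check has adequate power (e.g. $n \ge 500$ atoms for the
$\sigma\sqrt{3}$ recovery) while the whole suite remains quick to run.

## Known limitations

* No sequence alignment: reference and model must share numbering, or
  correspondence fails — intentionally out of scope.
* No symmetry correction for topologically equivalent atoms (e.g.
  OP1/OP2 swaps inflate RMSD slightly).
* mmCIF is not parsed; inputs are PDB-format.
* The per-cell sphere evaluation recomputes distances per radius;
  profiles over many radii on large structures trade speed for the
  guarantee that every cell follows the identical code path as the
  global RMSD.
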