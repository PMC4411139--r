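---
title: "Hybrid FD/DH electrostatics for pH-dependent conformational analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid FD/DH electrostatics for pH-dependent conformational analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fddh)
```

## The model

Ionizable groups in proteins titrate at pH values that can differ strongly
from their model-compound pKas, and in pH-gated ion channels these shifts
carry the gating signal.  `fddh` predicts them with a hybrid continuum
scheme built from three layers.

**Per-site electrostatics.**  Each titratable group (Asp, Glu, Lys, Arg,
His; optionally Tyr, Cys and the chain termini) is assigned a formal
ionization charge distributed evenly over its terminal polar atoms (for
example $-0.5\,e$ on each carboxylate oxygen).  For a *buried* site the
intrinsic pKa follows from a finite-difference solution of the linearized
Poisson–Boltzmann equation with relative dielectric 4 inside the molecular
(probe-rolled, 1.4 Å) surface and 78.4 outside, 0.15 M monovalent salt with
a 2.0 Å Stern layer, and Debye–Hückel boundary conditions with successive
grid focusing.  Two grid runs with identical charge placement — folded
structure versus the site's residue alone — difference away the grid
self-energy and yield the desolvation (Born) penalty
$\Delta G_\mathrm{desolv}$ and the background term
$\Delta G_\mathrm{back}$ from the permanent partial charges:

$$\mathrm{p}K_\mathrm{int} = \mathrm{p}K_\mathrm{model}
 - \frac{z}{\ln 10\,k_BT}\left(\Delta G_\mathrm{desolv} +
   \Delta G_\mathrm{back}\right),\qquad z = \pm 1 .$$

For a *solvent-accessible* site the protein–solvent boundary is removed
entirely: the intrinsic pKa is the model value and all of its interactions
use the uniform-solvent screened Coulomb (Debye–Hückel) form
$W = 332.06\,q_1q_2\,e^{-\kappa r}/(\varepsilon r)$ with
$\kappa \approx 0.127\,\text{Å}^{-1}$ at 0.15 M.  A pair interaction is
FD-derived only when *both* members are FD-treated; if either member is
accessible the screened closed form is used.

**The accessibility gate.**  Whether a site is "accessible" is decided by
the maximal solvent exposure it can reach by sidechain repacking on the
fixed backbone: over all rotamers whose worst hard-sphere overlap with the
surroundings is at most the clash tolerance, the maximum SASA
(Shrake–Rupley, 960 points, 1.4 Å probe) of the charge-bearing atoms is
compared with the same atoms in an isolated model compound.  Sites at or
above a relative accessibility of 0.5 are DH-treated.  The clash tolerance
absorbs the united-atom representation and residual flexibility; its
optimum is 1.2–1.4 Å (default 1.3), and deliberately perturbing it to 0.8
and 1.6 Å provides a one-structure caricature of small conformational
change around partially buried groups.

**Ionization thermodynamics.**  Microstate energies over the protonation
vector combine the intrinsic pKas with the pair matrix $W$ (stored for the
fully ionized pair, added when both sites are ionized).  Up to 20 sites the
partition function is enumerated exactly; beyond that a Metropolis Monte
Carlo sampler with single-site flips plus paired flips for strongly coupled
pairs ($|W| > 2$ kcal/mol) is used.  Titration curves give per-site
pK-half values (linear interpolation of the half-protonation crossing;
curves that never cross inside the scanned range are clamped and flagged),
and the pH-dependent ionization free energy follows from the net charge by
the Wyman linkage relation,

$$\Delta G_\mathrm{ion}(\mathrm{pH}) = \ln 10\,k_BT
  \int_{\mathrm{pH}_\mathrm{ref}}^{\mathrm{pH}}
  \left[Q_\mathrm{folded}(u) - Q_\mathrm{ref}(u)\right]\,du ,$$

where the reference state has model-compound pKas and no interactions.
The sign is anchored by the single-site limit: an acid whose pKa is raised
by burial pays its penalty at high pH, where it must ionize, so
$\Delta G_\mathrm{ion}$ rises by $\ln 10\,k_BT\,\Delta\mathrm{p}K$ across
its titration.

## Sensors, coupling and pH50

Differencing two conformers ("open" minus "closed") turns these curves into
gating predictors.  A residue whose ionization differs between the
conformers *within the physiological window* (pH 6–8 by default)
contributes to the *slope* of the difference curve — a candidate pH
sensor.  An interaction that differs between conformers while both partners
stay fully ionized through the window (a conserved salt bridge of different
strength, say) shifts the difference curve *without* changing its window
slope — pH-*coupled*: mutating it moves the crossover pH (pH50) by
offset/slope without sensing protons.  `classify_mutation()` formalizes
this with least-squares window fits (defaults: slope threshold 0.3
kcal/mol/pH, offset threshold 0.3 kcal/mol), and `find_ph50_crossover()`
locates the sign change of the difference curve.

Two scan modes produce candidate lists.  `conformer_pka_scatter()` pairs
per-site pK-halves of two structures and `flag_sensor_candidates()` keeps
points at least 0.5 pH units off the diagonal that are not entirely below
or entirely above the window.  When only one structure exists,
`repack_perturbation_scan()` rebuilds the whole pipeline at clash
tolerances 0.8 and 1.6 Å and flags sites whose ionization difference from
the isolated compound at pH 6.5 changes by at least 0.5 e — groups whose
burial is borderline and thus most responsive to small conformational
change.

### Energy anchoring

`ionization_free_energy_curve()` anchors a curve to zero at a reference pH
(default 7).  The anchor is a gauge choice for a single curve, but it is
*not* innocuous for conformer differences: anchoring both conformers at
mid-window forces their difference to zero exactly where the coupling
offset must be read.  The comparison pipelines therefore anchor at the
acidic end of the pH grid, where every group is protonated in both the
folded and reference states and the integration constant is physically
common; mutant-versus-wild-type offsets then appear at physiological pH,
as they should.  All classification results are invariant to adding a
common constant to both curves.

## Synthetic study systems

The generator (`generate_fixtures()`, `fx_*()`) builds every structure the
tests use; nothing is downloaded.  The toys emulate, in miniature, the
situations the method is meant to distinguish:

* **Model compounds** — single blocked residues; they must titrate at their
  model pKas exactly (the DH limit).
* **Cage toys** — a Gly-Lys-Gly peptide inside a shell of uncharged
  pseudo-atoms.  The *closed* variant (nested shells) never lets the amino
  group reach solvent; the *open* variant carves a porthole along the most
  extended rotamer; the *gated* variant adds a ring of gate atoms pinching
  that rotamer at ~1.2 Å overlap, so DH eligibility flips between clash
  tolerances 0.8 and 1.6 Å — the planted repacking-scan positive, with an
  exposed aspartate on a second chain as negative control.
* **Salt-bridge toy** — Asp and Lys on separate chains, bridged at 2.8 Å in
  the closed form and separated by 8 Å in the open form, both always
  exposed: deleting the acid is pH-*coupled* (offset ≈ −0.84 kcal/mol over
  the window, slope change ≈ 0).
* **Buried-acid toy** — the cage surrounds the acid only in the closed
  form, pushing its pKa far above the window while the open form leaves it
  at 4.0: deleting it changes the window slope by ≈ 1.36 kcal/mol/pH
  (= ln10·kT per unit ionization difference) — pH-*sensing*.
* **Calcium-mimic toy** — an acid pair buried in the closed form and a
  glutamate buried in the open form; the wild-type window slope is negative
  and charge-deleting the pair (approximating bound calcium) flips it
  positive.
* **Homotrimer** — three identical chains under exact C3 symmetry;
  per-monomer pK-halves must agree and monomer averaging must be
  idempotent.
* **Born sphere** — a single 2.0 Å pseudo-atom; a centred unit charge gives
  the analytic desolvation $(332.06/2)(1/4 - 1/78.4)/2.0 = 19.7$ kcal/mol.

What the toys deliberately lack: real backbone irregularity, waters and
ions, membrane, conformational ensembles, and the sheer site count of a
channel extracellular domain.  Passing tests therefore demonstrate the
correctness of the machinery and of the classification logic on planted
ground truth, not predictive accuracy on experimental pKas.

## Numerical choices

* Constants: 332.06 kcal·Å/(mol·e²); $k_BT$ = 0.5922 kcal/mol at 298.15 K
  (so ln10·kT = 1.364, the energy of one pH unit).
* LPBE: successive over-relaxation with red–black ordering, per-edge
  dielectric from a half-spacing solvent-excluded-surface mask, trilinear
  charge spreading, convergence at max update < 1e-6 kT/e.  Default
  focusing 2.4 → 1.2 → 0.6 Å with Debye–Hückel monopole boundary values on
  the coarsest grid; the finest box carries a 6 Å border around the source
  charges.  Refining 0.6 → 0.3 Å moves the fixture desolvation terms by
  under 2%, and a 90° rotation about a grid axis leaves them unchanged to
  numerical precision.
* Packing: coarse backbone-independent chi grid (staggered sp3, planar
  terminal sp2; at most 81 rotamers), harmonic overlap penalties, damped
  self-consistent mean-field iteration, lowest-index tie-break.  The
  convergence flag also fails when the selected assignment retains a hard
  overlap beyond the tolerance — a packing that "converged" onto a clash is
  not a packing.
* Accessibility: the isolated-compound denominator is the rotamer-library
  *maximum* of the charge-atom SASA, which keeps relative accessibility in
  [0, 1] up to probe-geometry noise; when no rotamer passes the tolerance
  the least-clashing rotamers are reported with a buried flag, keeping
  attainable SASA non-decreasing in the tolerance.
* Monte Carlo: flips scale with site count (10⁵ sampling flips per pH per
  100 sites, floor 5·10⁴); standard errors from ten long batches.  Checks
  against exact enumeration use three standard errors plus an absolute
  allowance of 0.005 protonation units for the estimator noise of
  correlated sampling at titration tails.
* pH grid 0–14 in 0.1 steps throughout; problem sizes in the tests (toys of
  1–6 sites, grids up to 71³) were chosen as the smallest systems that
  exercise every code path with clean margins.

## Known limitations

Linearized PB only; no membrane slab; no explicit ions or waters (hetero
records are dropped on reading); tautomer-free histidine; a coarse rotamer
library without continuous minimization; and single-conformation
electrostatics — the two-tolerance repacking scan is an empirical probe of
conformational sensitivity, not an ensemble average.  Comparative models
inherit their backbone from the template unchanged, so threading across
low-identity alignments should be interpreted cautiously.
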