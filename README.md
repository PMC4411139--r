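# fddh

Structure-based continuum electrostatics for ionizable groups in proteins,
aimed at pH-gated ion channels: which residues *sense* protons across a
conformational transition, and which are merely *coupled* to it?

`fddh` implements a hybrid FD/DH scheme.  Every titratable group (Asp, Glu,
Lys, Arg, His; optionally Tyr/Cys and termini) is assessed for the maximal
solvent accessibility it can reach by sidechain rotamer repacking on the
fixed backbone (self-consistent mean field, hard-sphere overlaps with a vdW
clash tolerance of 1.2–1.4 Å).  Groups that can reach solvent are treated
with a uniform-solvent Debye–Hückel model,

    W = 332.06 q1 q2 exp(-kappa r) / (eps r),   kappa ≈ 0.127 1/Å at 0.15 M,

so their intrinsic pKa stays at the model-compound value; buried groups are
treated with a finite-difference linearized Poisson–Boltzmann solver
(dielectric 4 inside the probe-rolled molecular surface, 78.4 outside, grid
focusing, Debye–Hückel boundaries), whose desolvation and background terms
shift the intrinsic pKa by

    pK_int = pK_model - z (dG_desolv + dG_back) / (ln10 kT),  z = ±1.

Ionization thermodynamics over the 2^N protonation microstates come from
exact enumeration (N ≤ 20) or Metropolis Monte Carlo, yielding titration
curves, pK-half values, net charge, and the pH-dependent ionization free
energy dG(pH) = ln10·kT ∫ (Q_folded − Q_ref) dpH (Wyman linkage).
Differencing two conformers then classifies residues: ionization changes
inside the physiological window (pH 6–8) give the difference curve its
*slope* (pH sensors), while interactions that change between conformers
without window titration *shift* the curve and move the pH50 crossover
(pH-coupled).  A repacking-tolerance perturbation scan (0.8 vs 1.6 Å, read
at pH 6.5) flags borderline-buried groups when only one structure exists.

## Worked example

A two-conformer toy in which an aspartate is buried (caged) in the closed
conformer and exposed in the open one:

```r
library(fddh)
res <- compare_conformers(fx_buried_acid("closed"), fx_buried_acid("open"))
as.data.frame(res$scatter)
#>   chain resno restype  value_a  value_b flag_a flag_b flagged
#> 1     A     2     ASP 13.98929  3.99598     ok     ok    TRUE
#> 2     B     2     LYS 10.40000 10.40402     ok     ok   FALSE
```

Burial raises the acid's pK-half from its model value 4.0 to ~14 (the
desolvation penalty makes ionization unreachable below the end of the
scanned range), so its ionization differs between conformers at
physiological pH and it is flagged as a candidate sensor; the exposed
lysine control sits on the diagonal.  Deleting the acid's charge in both
conformers changes the slope of the open-minus-closed energy curve over
pH 6–8 by ln10·kT per unit of ionization difference:

```r
print(classify_toy <- {
  tr <- trim_to_common_length(fx_buried_acid("closed"), fx_buried_acid("open"))
  del <- mutation_spec("A", 2, "charge_delete")
  wt  <- delta_energy_curve(ph_energy_pipeline(tr$b)$energy,
                            ph_energy_pipeline(tr$a)$energy)
  mut <- delta_energy_curve(ph_energy_pipeline(apply_mutation(tr$b, del))$energy,
                            ph_energy_pipeline(apply_mutation(tr$a, del))$energy)
  classify_mutation(wt, mut)
})
#> pH-sensor (slope diff 1.361 kcal/mol/pH, offset 4.098 kcal/mol)
```

The same machinery classifies the salt-bridge toy (bridge made in the
closed form, broken in the open form, both partners always ionized in the
window) as `pH-coupled (slope diff -0.001 kcal/mol/pH, offset -0.840
kcal/mol)`: the deletion shifts the curve, moving pH50, without sensing
protons.

A command-line wrapper is installed at `inst/scripts/fddh` with subcommands
`pka`, `titrate`, `compare-conformers`, `repack-scan`, `classify-mutation`,
`map` (OpenDX potential maps and differences) and `fixtures`.

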