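# stargmx

Convert NMR restraints from NMR-STAR depositions into GROMACS inputs, and
validate the result.

NMR structure determination and refinement rest on restrained molecular
simulations: distance bounds from NOE cross-peaks, torsion-angle windows
from J-couplings, and residual dipolar couplings (RDCs) are added to the
force field as restraint potentials.  Getting a deposited restraint file
into a simulation engine is mostly a nomenclature problem — depositions
address degenerate proton groups through pseudo-atoms (an alanine methyl is
`MB`, an aromatic proton pair `QD`) and use hydrogen names that match none
of the force-field conventions.  `stargmx` does that conversion and the
book-keeping around it, for users who run restrained GROMACS simulations or
want to check how well an ensemble or trajectory satisfies deposited
restraints.

## What it computes

**Distance restraints** become flat-bottom potentials

```
            ½ k_dr (r − r0)²                      r < r0
V_dr(r) =   0                                     r0 ≤ r < r1
            ½ k_dr (r − r1)²                      r1 ≤ r < r2
            ½ k_dr (r2 − r1)(2r − r2 − r1)        r ≥ r2
```

with lower bound `r0`, upper bound `r1` and a second upper bound
`r2 = r1 + margin` beyond which the force stops growing.  A pseudo-atom
pair such as Ala `MB` × Ile `MD` expands to 9 proton–proton distances that
are emitted under a *single* restraint label, so the engine treats them as
one restraint under r⁻⁶ distance averaging; logical-OR alternatives in the
deposition are pooled the same way.  Name translation runs in two layers —
NMR identifier → real atoms → force-field names (Amber or Charmm) — driven
by an editable rule table shipped with the package.

**Dihedral restraints** become flat-bottom wells `phi0 ± dphi`, where
`phi0` is the circular midpoint of the deposited interval (periodicity
respected: bounds 170°/−170° give `phi0 = 180°, dphi = 10°`) and the
energy outside the well is `½ k_dihr (|Δφ| − dphi)²`.

**Orientation restraints** copy the observed couplings (Hz) with the
standard dipolar settings (exponent α = 3, per-element-pair constant); the
validation side fits the 5-component symmetric traceless alignment tensor
by least squares and reports |back-calculated − observed|.

**Validation analytics**: per-restraint violations and energies against any
structure or ensemble, and the superposition-free all-pairs **distance
RMSD** — the RMS difference of all internal atom–atom distances — with the
minimum taken over the experimental models, so a frame close to *any*
deposited model scores low.

## Worked example

Everything below is generated in code — a toy Ala-Ile-Ala peptide with a
matching topology, and an NMR-STAR file whose model 1 satisfies every
restraint except one deliberately violated by 0.05 nm:

```r
library(stargmx)
pep  <- make_peptide(c("ALA", "ILE", "ALA"), n_models = 3, seed = 1)
fx   <- make_star(pep, n_distance = 6, n_violated = 1,
                  violation_magnitude = 0.05, n_dihedral = 2, n_rdc = 2,
                  seed = 2)
conv <- convert_restraints(parse_star(fx$text), read_topology(pep$topology))
conv
#> GROMACS restraints from 'nmr-star' (amber naming)
#>         distance dihedral orientation
#> parsed         6        2           2
#> emitted        6        2           2
#> skipped        0        0           0

violations(pep$ensemble$models[[1]], conv)
#> Restraint violation report
#>   distance    : n=6  mean violation 0.0083 nm
#>   dihedral    : n=2  mean violation 0.000 deg
#>   orientation : n=2  mean violation 0.0000 Hz
```

The mean distance violation is exactly the constructed 0.05 nm spread over
6 restraints (0.05/6 ≈ 0.0083); the satisfied dihedral windows and the
noiseless couplings (reproduced exactly by the fitted tensor) report zero.
The emitted include file starts:

```
; distance restraints generated from nmr-star (amber naming)
[ distance_restraints ]
;    ai     aj  type label type'     low      up1      up2      fac
     2     35     1     0     1    0.958    1.058    1.158    1.000
     2     36     1     0     1    0.958    1.058    1.158    1.000
     2     37     1     0     1    0.958    1.058    1.158    1.000
```

— one label per logical restraint, bounds already in nm.
`write_gmx_restraints(conv, "out/")` writes `disre.itp`, `dihre.itp`,
`orire.itp` and a `restraints.mdp` fragment carrying the recommended run
parameters (`disre-fc = 1000` kJ mol⁻¹ nm⁻², `disre-tau = 500` ps,
`dihre-fc = 1000` kJ mol⁻¹ rad⁻², `orire-fc = 10` kJ mol⁻¹ Hz⁻²).

A shell front end wrapping the same functions is installed at
`system.file("scripts", "stargmx", package = "stargmx")`:

```sh
stargmx convert  --star entry_mr.str --topology topol.top --out-dir out
stargmx validate --structure ensemble.pdb --star entry_mr.str --topology topol.top
stargmx rmsd     --trajectory frames.pdb --reference ensemble.pdb --subset heavy
stargmx fixtures --out-dir demo --n-distance 10 --n-violated 2
```

## Package layout

- `R/` — parsing (`parse_star`), nomenclature (`translate_atom`,
  `expand_pair`), topology indexing (`read_topology`, `resolve_atom`),
  restraint construction and writers (`convert_restraints`, `write_itp`,
  `write_mdp_fragment`), potentials and violations (`distance_energy`,
  `effective_distance`, `dihedral_energy`, `fit_alignment_tensor`,
  `violations`), analysis (`distance_rmsd`, `min_model_rmsd`), fixtures
  (`make_peptide`, `make_star`, `perturb`) and the `cmd_*` entry points.
- `inst/extdata/atom_translations.tsv` — the editable translation rule
  table.
- `vignettes/restraint-conversion.Rmd` — the methods vignette: model,
  parameters, numerical choices, limitations.
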