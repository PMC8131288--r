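---
title: "Converting and validating NMR restraints for GROMACS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Converting and validating NMR restraints for GROMACS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stargmx)
```

## The problem

An NMR deposition stores its restraints in NMR-STAR loops addressed by
*NMR* atom nomenclature: degenerate proton groups appear as pseudo-atoms
(`MB` for the three alanine methyl protons, `QD` for the two symmetric
aromatic delta protons), and individually named hydrogens follow a scheme
(`HB2`/`HB3`, `H5'`/`H5''`) that disagrees with every major force field.
A simulation engine, by contrast, wants restraints expressed as global
atom indices into a concrete topology.  `stargmx` bridges the two: it
parses the distance, torsion-angle and residual-dipolar-coupling (RDC)
constraint loops, translates names in two layers (NMR identifier → real
atoms → force-field names, Amber or Charmm), resolves atoms against the
`[ atoms ]` section of a GROMACS topology, and writes the three restraint
include dialects plus a run-parameter fragment.  A second set of functions
evaluates the restraint potentials against structures, so the emitted
restraints can be validated without running a simulation.

## Restraint models

**Distance restraints.**  Each NOE-derived bound pair becomes a
flat-bottom harmonic potential with a lower bound $r_0$, an upper bound
$r_1$, and a second upper bound $r_2$ beyond which the potential continues
*linearly*, so a badly violated restraint exerts a bounded force:

$$
V_{dr}(r)=\begin{cases}
\tfrac12 k_{dr}(r-r_0)^2 & r<r_0\\
0 & r_0\le r<r_1\\
\tfrac12 k_{dr}(r-r_1)^2 & r_1\le r<r_2\\
\tfrac12 k_{dr}(r_2-r_1)(2r-r_2-r_1) & r\ge r_2
\end{cases}
$$

The function is continuous everywhere; at $r_2$ both branches equal
$\tfrac12 k_{dr}(r_2-r_1)^2$, an identity the test suite checks
explicitly.  Deposited bounds are in ångström and converted once, at build
time, to nm.

Depositions rarely state $r_2$.  We default to $r_2 = r_1 + 0.1$ nm
(`r2_margin`), a width comparable to the bound uncertainties themselves;
it is configurable and only matters for strongly violated restraints.
A missing lower bound becomes $r_0 = 0$, since upper-bound-only NOEs are
common.

**Pseudo-atom expansion and r⁻⁶ grouping.**  A restraint between two
pseudo-atoms expands to the Cartesian product of their proton sets — Ala
`MB` × Ile `MD` gives 9 atom pairs — and *all* pairs are emitted under one
restraint label, as are logical-OR alternatives sharing one constraint ID.
The engine (and our validator) then combines the pair distances into one
effective distance

$$ r_{\mathrm{eff}} = \left(\tfrac1N\sum_i r_i^{-6}\right)^{-1/6}, $$

reflecting the $r^{-6}$ scaling of NOE intensities.  The default is the
mean form ("averaging"); the sum form
$\left(\sum r^{-6}\right)^{-1/6}$, which is never larger than the
smallest distance, is provided for the ambiguous-NOE convention
(`averaging = "sum"`).  Per-pair weights stay at 1: degeneracy is handled
by the grouping, not by weighting.

**Dihedral restraints.**  The deposited interval $[\phi_{lo},
\phi_{hi}]$ is traversed from lower to upper bound in the increasing
(mod 360°) direction; the reference angle $\phi_0$ is the circular
midpoint of that arc and $\Delta\phi$ half its width.  Bounds of
(170°, −170°) therefore give $\phi_0 = 180°$, $\Delta\phi = 10°$, not a
340°-wide well.  Arcs of 360° or more are rejected.  The energy is the
continuous symmetric flat-bottom form

$$
V_{dihr}(\phi) = \tfrac12 k_{dihr}\,\bigl(\max(0, |\Delta| -
\Delta\phi)\bigr)^2,\qquad
\Delta = \mathrm{wrap}_{(-180°,180°]}(\phi-\phi_0),
$$

with the excess converted to radians before squaring (the force constant
is per rad²).  A widely circulated piecewise statement of this potential
subtracts $\phi_0$ a second time inside the harmonic branch even though
the wrapped difference already contains it; taken literally that form is
discontinuous at the well edge, so we implement the symmetric form above,
which matches the flat-bottom description and is periodic under
$\phi \to \phi + 360°$ (property-tested).  Some depositions carry a
target-angle column in addition to bounds; we deliberately ignore it and
always use the interval midpoint, so asymmetric intervals shift
$\phi_0$ accordingly.

Degenerate-group identifiers are illegal among the four atoms of a
torsion: an identifier translating to more than one real atom is a hard
error naming the restraint, not a silent expansion.

**Orientation restraints.**  Observed couplings $\delta$ (Hz) are copied
through to the `[ orientation_restraints ]` rows with the standard
dipolar settings: distance exponent $\alpha = 3$ and a per-element-pair
dipolar constant (N–H default 6.083, the value used in the GROMACS
documentation's example; both are configurable because the constant
depends on the gyromagnetic ratios of the pair).  Experiments are
renumbered consecutively in order of appearance and labels restart at 1
within each experiment.  For validation we fit the symmetric traceless
alignment tensor $A$ (5 independent components) by least squares against
$\delta_i = c_i\,\hat v_i^{\mathsf T} A\, \hat v_i$ over the unit
internuclear vectors, and report $|\delta_{calc}-\delta_{obs}|$ per
restraint.  Fewer than five restraints, or geometrically degenerate
vectors, leave the system rank-deficient: the fit is flagged
`underdetermined` and the minimum-norm SVD solution is returned rather
than an error, since a flagged tensor is still useful diagnostically.
Whether a published "orientation violation" is the mean absolute
deviation after such a per-structure fit is rarely stated; that is the
definition used here and reported as the class mean.

## Name translation

Translation rules live in a plain-text table
(`inst/extdata/atom_translations.tsv`, columns: residues / identifier /
Amber targets / Charmm targets) so users can extend them for other force
fields or exotic residues.  Matching is case-insensitive and typographic
primes are normalized (`″` → `''`).  Three behaviours are deliberate:

* **Pass-through fallback.**  An identifier with no applicable rule is
  returned unchanged as a singleton (flagged untranslated), rather than
  raising an error — non-standard residues should degrade to warnings at
  resolution time, not kill a conversion.
* **Deduplication.**  The reference rule set repeats several shift rows
  (HG₃→HG₂, HD₃→HD₂, HE₃→HE₂) verbatim; identical rows are collapsed on
  load.
* **Only tabulated rows.**  The shift-by-one hydrogen renames (HB2/HB3 →
  HB1/HB2 and friends) apply exactly to the residues listed; no renames
  are inferred beyond the table.

The Amber and Charmm columns differ in precisely two places — the backbone
amide proton (`H` vs `HN`) and the Ser/Thr/Cys hydroxyl proton (`HG` vs
`HG1`) — and a test asserts the translations diverge exactly there and
nowhere else.

## Topology mapping

`read_topology()` indexes every `[ atoms ]` line into a global 1-based
numbering, concatenating molecule blocks (replicated per the
`[ molecules ]` section when present) into chains labeled positionally
"A", "B", ….  Neither the deposition nor the topology names the other's
chains, so the correspondence *entity assembly 1 ↔ first molecule block*
is positional by design and documented to users.  `#include` files are
resolved next to the topology; `#ifdef` blocks take the default
(undefined) path.  Resolution misses are values, not exceptions: a
restraint is emitted only if every expanded atom resolves, otherwise it
is skipped with a warning that names the first offending atom (the
typical case being a histidine proton absent in the modeled tautomer).
The invariant `parsed = emitted + skipped` per class is part of every
conversion manifest and asserted in the tests.

## Distance RMSD

Structural agreement is measured without superposition: for atom subset
$S$, all unordered pair distances are compared,

$$ \mathrm{dRMSD} = \sqrt{\frac{1}{|P|}\sum_{(i,j)\in P}
   \bigl(r_{ij}^{frame}-r_{ij}^{ref}\bigr)^2 }, $$

which is exactly invariant under rigid motions and free of the fitting
jumps a positional RMSD can show between dissimilar conformations.
Against a multi-model reference the per-frame value is the **minimum**
over models: deposited models are equally valid, so proximity to any one
suffices.  The default subset is heavy atoms — hydrogen naming differs
between deposition- and force-field-named structures, so including
hydrogens silently compares different atoms; `"all"` and `"backbone"` are
available.  The all-pairs computation is $O(N^2)$ in memory and time via
`dist()`, perfectly fine for peptides and small proteins; for very large
chains subsample the atom set.

## The fixture generator

`make_peptide()` builds an extended toy peptide from per-residue
templates (ALA, GLY, ILE, LYS, SER — enough to exercise methyl expansion,
shift renames, pass-through and the Amber/Charmm divergences), with a
40°-per-residue twist about the chain axis so bond vectors sample distinct
orientations (without it, all N–H vectors are parallel and an alignment
tensor fit would be rank-deficient by construction).  The topology is
generated from the same atom list, so coordinates and `[ atoms ]` match
one-to-one.  Additional models add a small Gaussian jitter (default RMS
0.002 nm), well inside the default bound slack.

`make_star()` measures effective distances in model 1 and writes bounds
`measured ± slack` (default 0.05 nm), so model 1 satisfies every
restraint by construction; a requested number of records instead get
their upper bound pulled `violation_magnitude` below the measured
distance, and the generator records exactly which records it violated.
That bookkeeping is the ground truth the validation pipeline must
reproduce — the set of flagged restraints must match exactly, and the
reported magnitudes must equal the constructed ones (to the 10⁻⁴ nm
rounding of the serialized bounds).  Dihedral windows bracket the
measured backbone φ angles; couplings are back-calculated noiselessly
from a seeded random tensor, so a correct tensor fit recovers them to
numerical precision.

What the fixtures deliberately do **not** emulate: spin diffusion or any
NOE intensity physics, energy-minimized geometry, solvent, chemical-shift
or relaxation loops, stereo-specific ambiguity beyond the pseudo-atom
conventions, and multi-chain depositions (the generator emits one chain;
multi-chain parsing and indexing are tested with hand-written topologies
instead).  Passing the fixture-based tests therefore demonstrates the
conversion and validation logic, not robustness to every archival
idiosyncrasy in historical depositions.

## Run parameters

The emitted `restraints.mdp` fragment carries the constants a restrained
run needs, with defaults chosen as the values recommended from systematic
parameter evaluation on short peptides:

| parameter | default | units | role |
|---|---|---|---|
| `k_dr` | 1000 | kJ mol⁻¹ nm⁻² | distance restraint force constant |
| `tau_dr` | 500 | ps | time-averaging constant for distance restraints |
| `k_dihr` | 1000 | kJ mol⁻¹ rad⁻² | dihedral restraint force constant |
| `k_or` | 10 | kJ mol⁻¹ Hz⁻² | orientation restraint force constant |
| `r2_margin` | 0.1 | nm | width of the linear-force region |

Optimal values depend on peptide length, flexibility and starting
structure; these are sensible defaults, not universal constants.  Note
that time averaging itself happens inside the MD engine — this package
only emits `tau_dr`; its violation analytics are instantaneous per
structure.

## Numerical choices and degenerate inputs

* Angles are degrees at every interface and radians only inside energy
  expressions; wrapped differences live in (−180°, 180°], with the
  boundary assigned to +180°.
* A dihedral interval with equal bounds is a legitimate zero-width well
  (`dphi = 0`), distinct from the rejected 360° arc.
* `effective_distance()` on an empty list is an error, not NaN.
* Bounds given as (target ± error) are normalized to lower/upper once, at
  parse time; all downstream code sees a single representation.
* Tensor fits use the SVD with the conventional
  `max(dim) * max(singular value) * eps` rank tolerance.
* Conversion is deterministic: identical inputs give byte-identical
  output files (tested), and all fixture randomness is seeded.

## Problem sizes

The test suite runs entirely on generated fixtures: peptides of 2–15
residues (up to ~700 atoms of coordinate data across models), tens of
restraints per class, and property checks over dozens of randomized
cases per invariant; the whole suite completes in well under a minute.
Two acceptance-level checks reach outside the package on purpose — parsing
deposited entries to their published restraint counts (network) and an
in-vacuo minimization round-trip (GROMACS engine) — and report failures
where those externals are absent.

## Known limitations

* NEF-format restraint files, chemical-shift and relaxation loops, and
  peak lists are out of scope.
* Stereo-specific assignments are not resolved; pseudo-atom expansion
  treats all group members symmetrically.
* The topology preprocessor implements the default `#ifdef` path and
  same-directory includes only — no full CPP semantics.
* Chain matching between deposition entities and topology molecules is
  positional; reorder the topology (or relabel) when that assumption is
  wrong.
* Orientation-restraint energetics use the per-structure tensor fit;
  in-engine time/ensemble averaging of the tensor is not reproduced.
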