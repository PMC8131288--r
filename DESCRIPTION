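Package: stargmx
Title: Convert NMR-STAR Restraints to GROMACS Inputs and Validate Them
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Extracts distance (NOE), dihedral and orientation (residual
    dipolar coupling) restraints from NMR-STAR v3 depositions and writes
    GROMACS restraint topology includes and run-parameter fragments.
    Pseudo-atom identifiers for degenerate proton groups are expanded to
    real force-field atom names (Amber or Charmm) through a two-layer
    nomenclature translation; ambiguous and pseudo-atom restraints are
    grouped under one restraint label for inverse-sixth-power distance
    averaging.  Companion analytics evaluate flat-bottom restraint
    potentials and per-restraint violations against structure ensembles,
    fit residual-dipolar-coupling alignment tensors by least squares, and
    compute the superposition-free all-pairs distance RMSD with the
    minimum taken over experimental models.  Fully synthetic fixture
    generators (toy peptides, matching GROMACS topologies and NMR-STAR
    restraint files with known ground truth) support download-free
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
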