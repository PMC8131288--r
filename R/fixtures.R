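#' @title Synthetic test fixtures
#'
#' @description Fully self-contained generators for toy peptides with
#' force-field-consistent atom naming, matching GROMACS topologies,
#' multi-model coordinate ensembles, and NMR-STAR restraint files whose
#' ground truth (record counts, bounds, deliberately violated restraints)
#' is known by construction.  Geometry is chemically plausible but not
#' energy-minimized: the package converts and analyzes restraints, it
#' does not simulate.  Everything is generated in code at run time; no
#' downloads, no bundled binaries.
#'
#' @name fixtures
NULL

# Residue templates: atom offsets (nm) from the residue origin (N), in
# GROMACS Amber naming.  X-H distances ~0.1 nm, C-C ~0.15 nm.
.residue_templates <- list(
  ALA = rbind(
    N = c(0.00, 0.00, 0.00), H = c(-0.05, 0.09, 0.00),
    CA = c(0.145, 0.05, 0.00), HA = c(0.17, 0.11, 0.09),
    CB = c(0.19, 0.13, -0.12), HB1 = c(0.13, 0.10, -0.21),
    HB2 = c(0.29, 0.11, -0.14), HB3 = c(0.17, 0.24, -0.11),
    C = c(0.24, -0.08, 0.02), O = c(0.21, -0.19, 0.06)),
  GLY = rbind(
    N = c(0.00, 0.00, 0.00), H = c(-0.05, 0.09, 0.00),
    CA = c(0.145, 0.05, 0.00), HA1 = c(0.17, 0.11, 0.09),
    HA2 = c(0.17, 0.10, -0.10),
    C = c(0.24, -0.08, 0.02), O = c(0.21, -0.19, 0.06)),
  ILE = rbind(
    N = c(0.00, 0.00, 0.00), H = c(-0.05, 0.09, 0.00),
    CA = c(0.145, 0.05, 0.00), HA = c(0.17, 0.11, 0.09),
    CB = c(0.19, 0.13, -0.12), HB = c(0.29, 0.16, -0.10),
    CG2 = c(0.10, 0.25, -0.15), HG21 = c(0.00, 0.23, -0.18),
    HG22 = c(0.14, 0.31, -0.23), HG23 = c(0.10, 0.31, -0.06),
    CG1 = c(0.21, 0.05, -0.26), HG11 = c(0.12, 0.00, -0.29),
    HG12 = c(0.29, -0.02, -0.25),
    CD = c(0.25, 0.14, -0.38), HD1 = c(0.17, 0.21, -0.41),
    HD2 = c(0.34, 0.19, -0.36), HD3 = c(0.27, 0.07, -0.46),
    C = c(0.24, -0.08, 0.02), O = c(0.21, -0.19, 0.06)),
  LYS = rbind(
    N = c(0.00, 0.00, 0.00), H = c(-0.05, 0.09, 0.00),
    CA = c(0.145, 0.05, 0.00), HA = c(0.17, 0.11, 0.09),
    CB = c(0.19, 0.13, -0.12), HB1 = c(0.10, 0.18, -0.14),
    HB2 = c(0.27, 0.20, -0.11),
    CG = c(0.20, 0.04, -0.25), HG1 = c(0.11, -0.02, -0.26),
    HG2 = c(0.29, -0.02, -0.24),
    CD = c(0.21, 0.13, -0.38), HD1 = c(0.12, 0.19, -0.39),
    HD2 = c(0.30, 0.19, -0.37),
    CE = c(0.22, 0.04, -0.51), HE1 = c(0.13, -0.02, -0.52),
    HE2 = c(0.31, -0.02, -0.50),
    NZ = c(0.23, 0.13, -0.63), HZ1 = c(0.15, 0.18, -0.64),
    HZ2 = c(0.31, 0.19, -0.62), HZ3 = c(0.23, 0.07, -0.72),
    C = c(0.24, -0.08, 0.02), O = c(0.21, -0.19, 0.06)),
  SER = rbind(
    N = c(0.00, 0.00, 0.00), H = c(-0.05, 0.09, 0.00),
    CA = c(0.145, 0.05, 0.00), HA = c(0.17, 0.11, 0.09),
    CB = c(0.19, 0.13, -0.12), HB1 = c(0.10, 0.18, -0.14),
    HB2 = c(0.27, 0.20, -0.11),
    OG = c(0.20, 0.04, -0.24), HG = c(0.21, 0.10, -0.32),
    C = c(0.24, -0.08, 0.02), O = c(0.21, -0.19, 0.06)))

# NMR deposition identifiers usable per residue in generated restraints.
.residue_nmr_protons <- list(
  ALA = c("H", "HA", "MB"),
  GLY = c("H", "HA2", "HA3"),
  ILE = c("H", "HA", "HB", "MG", "MD"),
  LYS = c("H", "HA", "HB2", "HB3", "QZ"),
  SER = c("H", "HA", "HB2", "HB3", "HG"))

ff_atom_name <- function(resname, atom, force_field) {
  if (force_field == "charmm") {
    if (atom == "H") return("HN")
    if (atom == "HG" && resname %in% c("SER", "THR", "CYS")) return("HG1")
  }
  atom
}

#' Generate a toy peptide with matching topology
#'
#' Builds an idealized extended peptide from residue templates (ALA, GLY,
#' ILE, LYS, SER), with side-chain hydrogens named per the chosen force
#' field so that every pseudo-atom translation target exists, and a
#' GROMACS topology whose `[ atoms ]` section matches the coordinates
#' one-to-one.  Additional models are small deterministic perturbations
#' of the first.
#'
#' @param sequence Character vector of residue codes.
#' @param n_models Number of ensemble models (>= 1).
#' @param seed Seed for the model perturbations.
#' @param force_field `"amber"` or `"charmm"` naming for the emitted
#'   atoms and topology.
#' @param model_spread RMS atomic displacement between model 1 and the
#'   others, nm.
#' @return An object of class `"toy_peptide"`: list with `ensemble` (an
#'   [ensemble()]), `topology` (text), `sequence` and `force_field`.
#' @examples
#' pep <- make_peptide(c("ALA", "ILE"), n_models = 3)
#' pep$ensemble
#' @export
make_peptide <- function(sequence = c("ALA", "ALA", "ALA"),
                         n_models = 1, seed = 1,
                         force_field = c("amber", "charmm"),
                         model_spread = 0.002) {
  force_field <- match.arg(force_field)
  sequence <- toupper(sequence)
  stopifnot(length(sequence) >= 2)
  unknown <- setdiff(sequence, names(.residue_templates))
  if (length(unknown))
    stop("unknown residue(s): ", paste(unknown, collapse = ", "))
  atoms <- NULL
  xyz <- NULL
  for (i in seq_along(sequence)) {
    tmpl <- .residue_templates[[sequence[i]]]
    origin <- c((i - 1) * 0.38, 0.03 * (-1)^i, 0)
    # helical twist about the chain axis so that bond vectors (e.g. N-H)
    # sample distinct orientations along the sequence
    th <- (i - 1) * 40 * pi / 180
    rot <- matrix(c(1, 0, 0,
                    0, cos(th), -sin(th),
                    0, sin(th), cos(th)), 3, 3, byrow = TRUE)
    nm <- vapply(rownames(tmpl), ff_atom_name, "",
                 resname = sequence[i], force_field = force_field)
    atoms <- rbind(atoms, data.frame(
      atom = unname(nm), resseq = i, resname = sequence[i], chain = "A",
      element = infer_element(nm), stringsAsFactors = FALSE))
    xyz <- rbind(xyz, sweep(unname(tmpl) %*% t(rot), 2, -origin))
  }
  rownames(xyz) <- NULL
  set.seed(seed)
  models <- c(list(xyz), lapply(seq_len(max(0, n_models - 1)), function(m)
    xyz + matrix(stats::rnorm(length(xyz), sd = model_spread / sqrt(3)),
                 nrow(xyz), 3)))
  mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999)
  top <- c("; toy peptide topology (generated fixture)",
           "[ moleculetype ]",
           "; name  nrexcl",
           "Protein     3",
           "",
           "[ atoms ]",
           ";  nr type resnr residue atom cgnr charge mass",
           sprintf("%5d %4s %5d %6s %6s %5d %8.3f %8.3f",
                   seq_len(nrow(atoms)), atoms$element, atoms$resseq,
                   atoms$resname, atoms$atom, seq_len(nrow(atoms)),
                   0, mass[atoms$element]),
           "",
           "[ system ]",
           "toy peptide",
           "",
           "[ molecules ]",
           "Protein 1")
  structure(list(ensemble = ensemble(models, atoms),
                 topology = paste(top, collapse = "\n"),
                 sequence = sequence, force_field = force_field),
            class = "toy_peptide")
}

#' @export
print.toy_peptide <- function(x, ...) {
  cat(sprintf("Toy peptide %s (%s naming): %d atoms, %d model(s)\n",
              paste(x$sequence, collapse = "-"), x$force_field,
              nrow(x$ensemble$atoms), length(x$ensemble$models)))
  invisible(x)
}

# Effective distance (nm) between two NMR identifiers in model 1,
# after translation to the peptide's force-field naming.
fixture_effective_distance <- function(pep, res1, id1, res2, id2,
                                       mode = "mean") {
  a <- pep$ensemble$atoms
  xyz <- pep$ensemble$models[[1]]
  find <- function(resseq, id) {
    nm <- translate_atom(a$resname[match(resseq, a$resseq)], id,
                         pep$force_field)
    idx <- match(paste(resseq, nm), paste(a$resseq, a$atom))
    if (anyNA(idx)) stop("fixture identifier does not resolve: ", id)
    idx
  }
  i <- find(res1, id1); j <- find(res2, id2)
  pd <- as.vector(sqrt(outer(seq_along(i), seq_along(j),
    Vectorize(function(p, q) sum((xyz[i[p], ] - xyz[j[q], ])^2)))))
  effective_distance(pd, mode)
}

#' Generate an NMR-STAR restraint file with known ground truth
#'
#' Distance restraints are generated so that model 1 of the peptide
#' satisfies them (bounds = measured effective distance +/- `slack`),
#' except for `n_violated` records whose upper bound is pulled
#' `violation_magnitude` nm below the measured distance; the generator
#' records exactly which restraints it violated.  Optional torsion-angle
#' restraints bracket the measured backbone phi angles, and optional
#' residual-dipolar-coupling rows are back-calculated without noise from
#' a seeded random alignment tensor on the N-H vectors.
#'
#' @param pep A `"toy_peptide"`.
#' @param n_distance Number of distance restraints.
#' @param n_violated How many of them to violate deliberately (the last
#'   ones in file order).
#' @param violation_magnitude Violation size, nm.
#' @param slack Half-width of satisfied bounds, nm.
#' @param n_dihedral Number of backbone phi restraints (satisfied).
#' @param dihedral_halfwidth Half-width of the dihedral windows, degrees.
#' @param n_rdc Number of N-H coupling rows (0 or one per residue > 1).
#' @param seed Random seed (pair selection, tensor).
#' @return A list of class `"star_fixture"`: `text` (NMR-STAR), `sets`
#'   (the raw records), `truth` (data frame: class, id, violated,
#'   magnitude) and `tensor` (the 5 alignment-tensor components used for
#'   the couplings, or NULL).
#' @examples
#' pep <- make_peptide(c("ALA", "ILE", "ALA"))
#' fx <- make_star(pep, n_distance = 5, n_violated = 1, seed = 7)
#' subset(fx$truth, violated)
#' @export
make_star <- function(pep, n_distance = 10, n_violated = 0,
                      violation_magnitude = 0.05, slack = 0.05,
                      n_dihedral = 0, dihedral_halfwidth = 15,
                      n_rdc = 0, seed = 1) {
  stopifnot(inherits(pep, "toy_peptide"), n_violated <= n_distance)
  set.seed(seed)
  nres <- length(pep$sequence)
  # candidate (resseq, identifier) pool
  pool <- do.call(rbind, lapply(seq_len(nres), function(i)
    data.frame(resseq = i, resname = pep$sequence[i],
               id = .residue_nmr_protons[[pep$sequence[i]]],
               stringsAsFactors = FALSE)))
  distances <- list()
  truth <- data.frame(class = character(), id = integer(),
                      violated = logical(), magnitude = numeric(),
                      stringsAsFactors = FALSE)
  for (k in seq_len(n_distance)) {
    repeat {
      pick <- pool[sample(nrow(pool), 2), ]
      if (pick$resseq[1] != pick$resseq[2]) break
    }
    d_eff <- fixture_effective_distance(pep, pick$resseq[1], pick$id[1],
                                        pick$resseq[2], pick$id[2])
    violated <- k > n_distance - n_violated
    if (violated) {
      stopifnot(violation_magnitude < d_eff)
      lower <- 0
      upper <- d_eff - violation_magnitude
    } else {
      lower <- max(0, d_eff - slack)
      upper <- d_eff + slack
    }
    member <- list(atom_spec("A", pick$resseq[1], pick$resname[1],
                             pick$id[1]),
                   atom_spec("A", pick$resseq[2], pick$resname[2],
                             pick$id[2]))
    distances[[k]] <- list(restraint_id = k, members = list(member),
                           lower_bound = round(lower * 10, 4),
                           upper_bound = round(upper * 10, 4),
                           target = NA_real_)
    truth <- rbind(truth, data.frame(
      class = "distance", id = k, violated = violated,
      magnitude = ifelse(violated, violation_magnitude, 0)))
  }
  dihedrals <- list()
  if (n_dihedral > 0) {
    stopifnot(n_dihedral <= nres - 1)
    a <- pep$ensemble$atoms
    xyz <- pep$ensemble$models[[1]]
    bb <- function(resseq, name)
      match(paste(resseq, ff_atom_name(pep$sequence[resseq], name,
                                       pep$force_field)),
            paste(a$resseq, a$atom))
    for (k in seq_len(n_dihedral)) {
      i <- k + 1                       # phi of residue i: C(i-1) N CA C
      idx <- c(bb(i - 1, "C"), bb(i, "N"), bb(i, "CA"), bb(i, "C"))
      phi <- dihedral_angle(xyz[idx, ])
      dihedrals[[k]] <- list(
        restraint_id = k,
        atoms = list(atom_spec("A", i - 1, pep$sequence[i - 1], "C"),
                     atom_spec("A", i, pep$sequence[i], "N"),
                     atom_spec("A", i, pep$sequence[i], "CA"),
                     atom_spec("A", i, pep$sequence[i], "C")),
        angle_lower = round(phi - dihedral_halfwidth, 2),
        angle_upper = round(phi + dihedral_halfwidth, 2),
        angle_name = "PHI")
      truth <- rbind(truth, data.frame(class = "dihedral", id = k,
                                       violated = FALSE, magnitude = 0))
    }
  }
  orientations <- list()
  tensor <- NULL
  if (n_rdc > 0) {
    stopifnot(n_rdc <= nres - 1)
    comp <- stats::rnorm(5, sd = 1e-3)   # alignment is a small anisotropy
    tensor <- comp
    A <- matrix(c(comp[1], comp[3], comp[4],
                  comp[3], comp[2], comp[5],
                  comp[4], comp[5], -comp[1] - comp[2]), 3, 3)
    a <- pep$ensemble$atoms
    xyz <- pep$ensemble$models[[1]]
    const <- 6.083
    for (k in seq_len(n_rdc)) {
      i <- k + 1
      ni <- match(paste(i, "N"), paste(a$resseq, a$atom))
      hi <- match(paste(i, ff_atom_name(pep$sequence[i], "H",
                                        pep$force_field)),
                  paste(a$resseq, a$atom))
      v <- xyz[hi, ] - xyz[ni, ]
      v <- v / sqrt(sum(v^2))
      obs <- const * as.numeric(t(v) %*% A %*% v)
      orientations[[k]] <- list(
        restraint_id = k,
        atoms = list(atom_spec("A", i, pep$sequence[i], "N"),
                     atom_spec("A", i, pep$sequence[i], "H")),
        observed = obs, error = NA_real_, experiment_id = 1L)
      truth <- rbind(truth, data.frame(class = "orientation", id = k,
                                       violated = FALSE, magnitude = 0))
    }
  }
  sets <- structure(list(distances = distances, dihedrals = dihedrals,
                         orientations = orientations,
                         source_label = "fixture",
                         warnings = character(),
                         n_rows = c(distance = length(distances),
                                    dihedral = length(dihedrals),
                                    orientation = length(orientations))),
                    class = "restraint_sets")
  structure(list(text = write_star(sets), sets = sets, truth = truth,
                 tensor = tensor),
            class = "star_fixture")
}

#' Perturb a structure model
#'
#' Adds a deterministic zero-mean random displacement whose per-atom RMS
#' equals `magnitude`.
#'
#' @param model N x 3 coordinate matrix (nm) or `"structure_model"`.
#' @param magnitude RMS displacement, nm (0 returns the input).
#' @param seed Random seed.
#' @return A coordinate matrix of the same shape.
#' @export
perturb <- function(model, magnitude, seed = 1) {
  stopifnot(magnitude >= 0)
  xyz <- model_coords(model)
  if (magnitude == 0) return(xyz)
  set.seed(seed)
  xyz + matrix(stats::rnorm(length(xyz), sd = magnitude / sqrt(3)),
               nrow(xyz), 3)
}
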