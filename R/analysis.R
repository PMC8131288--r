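#' @title Ensembles and superposition-free distance RMSD
#'
#' @description A structure model is an N x 3 coordinate matrix in nm,
#' with rows addressed by global atom index; an ensemble is an ordered
#' set of models sharing one atom set (the deposited MODEL/ENDMDL blocks
#' of a multi-model PDB file).  The comparison metric is the all-pairs
#' distance RMSD: the root mean square difference between the internal
#' atom-atom distances of two structures.  Because only internal
#' distances enter, no superposition is performed and the metric is
#' exactly invariant under rigid motions, avoiding the jumps a fitted
#' positional RMSD can show between dissimilar structures.  When several
#' experimental models are available, the RMSD of a simulation frame is
#' the minimum over the models: all deposited structures are equally
#' likely, so closeness to any one of them counts.
#'
#' @name distance-rmsd
NULL

# Accept a bare N x 3 matrix or a structure_model.
model_coords <- function(x) {
  if (inherits(x, "structure_model")) return(x$xyz)
  if (is.matrix(x) && ncol(x) == 3) return(x)
  stop("expected an N x 3 coordinate matrix or a structure_model")
}

#' Structure model constructor
#' @param xyz N x 3 numeric matrix of coordinates, nm.
#' @param model_id Integer id.
#' @return An object of class `"structure_model"`.
#' @export
structure_model <- function(xyz, model_id = 1L) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, all(is.finite(xyz)))
  structure(list(model_id = as.integer(model_id), xyz = xyz),
            class = "structure_model")
}

#' All-pairs distance RMSD between two structures
#'
#' @param frame,reference Coordinate matrices (N x 3, nm) or
#'   `"structure_model"` objects with identical atom sets.
#' @param atom_subset Optional integer indices of the atoms to compare
#'   (e.g. heavy atoms from [atom_subset()]); default all rows.
#' @return The RMS difference over all unordered atom pairs of the
#'   internal distances, nm.
#' @examples
#' a <- matrix(rnorm(30), ncol = 3)
#' distance_rmsd(a, a)  # 0
#' @export
distance_rmsd <- function(frame, reference, atom_subset = NULL) {
  f <- model_coords(frame)
  r <- model_coords(reference)
  if (!is.null(atom_subset)) {
    f <- f[atom_subset, , drop = FALSE]
    r <- r[atom_subset, , drop = FALSE]
  }
  if (nrow(f) != nrow(r))
    stop("frame and reference have different atom counts")
  if (nrow(f) < 2) stop("need at least 2 atoms for a distance RMSD")
  df <- stats::dist(f)
  dr <- stats::dist(r)
  sqrt(mean((df - dr)^2))
}

#' Minimum distance RMSD over an ensemble of reference models
#'
#' @param frame Coordinates of one frame.
#' @param ensemble An `"ensemble"` (see [read_ensemble()]) or a list of
#'   coordinate matrices.
#' @param atom_subset Optional atom indices.
#' @return min over the ensemble's models of [distance_rmsd()], nm.
#' @export
min_model_rmsd <- function(frame, ensemble, atom_subset = NULL) {
  models <- if (inherits(ensemble, "ensemble")) ensemble$models
            else ensemble
  if (length(models) == 0) stop("empty ensemble")
  min(vapply(models, function(m) distance_rmsd(frame, m, atom_subset),
             numeric(1)))
}

#' Distance-RMSD time series of a trajectory against an ensemble
#'
#' @param frames List of coordinate matrices (trajectory frames in
#'   order) or an `"ensemble"`.
#' @param ensemble Reference ensemble.
#' @param atom_subset Optional atom indices.
#' @param times Optional time values (default 0, 1, 2, ... frame index).
#' @return Data frame with columns `time` and `rmsd` (nm), one row per
#'   frame, in input order.
#' @export
rmsd_timeseries <- function(frames, ensemble, atom_subset = NULL,
                            times = NULL) {
  if (inherits(frames, "ensemble")) frames <- frames$models
  if (is.null(times)) times <- seq_along(frames) - 1
  rmsd <- vapply(frames, function(f)
    min_model_rmsd(f, ensemble, atom_subset), numeric(1))
  data.frame(time = times[seq_along(frames)], rmsd = rmsd)
}

# ---------------------------------------------------------------------------
# Coordinate I/O
# ---------------------------------------------------------------------------

#' Construct an ensemble object
#' @param models List of N x 3 coordinate matrices (nm).
#' @param atoms Data frame with one row per atom: `atom`, `resseq`,
#'   `resname`, `chain`, `element`.
#' @return An object of class `"ensemble"`.
#' @export
ensemble <- function(models, atoms) {
  stopifnot(length(models) >= 1)
  n <- nrow(models[[1]])
  stopifnot(all(vapply(models, nrow, 1L) == n), nrow(atoms) == n)
  structure(list(models = models, atoms = atoms), class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("Ensemble: %d model(s), %d atoms\n",
              length(x$models), nrow(x$atoms)))
  invisible(x)
}

infer_element <- function(name) {
  toupper(substr(sub("^[0-9']+", "", name), 1, 1))
}

#' Read a coordinate file into an ensemble
#'
#' Multi-model PDB files (MODEL/ENDMDL blocks, read through bio3d) and
#' single-frame GROMACS `.gro` files are supported; coordinates are
#' returned in nm.
#'
#' @param path File path; format from the extension (`.pdb` or `.gro`).
#' @return An `"ensemble"`.
#' @export
read_ensemble <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "gro") return(read_gro_ensemble(path))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  models <- lapply(seq_len(nrow(xyz)), function(m)
    matrix(xyz[m, ], ncol = 3, byrow = TRUE) / 10)   # angstrom -> nm
  elem <- pdb$atom$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- infer_element(pdb$atom$elety)
  atoms <- data.frame(atom = normalize_id(pdb$atom$elety),
                      resseq = pdb$atom$resno,
                      resname = toupper(pdb$atom$resid),
                      chain = ifelse(is.na(pdb$atom$chain), "A",
                                     pdb$atom$chain),
                      element = toupper(elem),
                      stringsAsFactors = FALSE)
  ensemble(models, atoms)
}

read_gro_ensemble <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[2]))
  rows <- lines[3:(2 + n)]
  atoms <- data.frame(
    resseq = as.integer(substr(rows, 1, 5)),
    resname = toupper(trimws(substr(rows, 6, 10))),
    atom = normalize_id(trimws(substr(rows, 11, 15))),
    chain = "A", stringsAsFactors = FALSE)
  atoms$element <- infer_element(atoms$atom)
  xyz <- cbind(as.numeric(substr(rows, 21, 28)),
               as.numeric(substr(rows, 29, 36)),
               as.numeric(substr(rows, 37, 44)))
  ensemble(list(xyz), atoms[, c("atom", "resseq", "resname", "chain",
                                "element")])
}

#' Select an atom subset of an ensemble
#'
#' Hydrogen naming differs between deposition and force-field schemes,
#' so distance-RMSD comparisons default to heavy atoms.
#'
#' @param ens An `"ensemble"`.
#' @param subset `"heavy"` (non-hydrogen), `"all"`, or `"backbone"`
#'   (N, CA, C, O).
#' @return Integer atom indices.
#' @export
atom_subset <- function(ens, subset = c("heavy", "all", "backbone")) {
  subset <- match.arg(subset)
  switch(subset,
         all = seq_len(nrow(ens$atoms)),
         heavy = which(ens$atoms$element != "H"),
         backbone = which(ens$atoms$atom %in% c("N", "CA", "C", "O")))
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param ens An `"ensemble"` (coordinates in nm; written in angstrom).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_ensemble_pdb <- function(ens, path) {
  out <- character()
  a <- ens$atoms
  name_field <- ifelse(nchar(a$atom) < 4, paste0(" ", a$atom), a$atom)
  for (m in seq_along(ens$models)) {
    xyz <- ens$models[[m]] * 10
    out <- c(out, sprintf("MODEL     %4d", m),
             sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                     seq_len(nrow(a)), name_field, a$resname, a$chain,
                     a$resseq, xyz[, 1], xyz[, 2], xyz[, 3], a$element),
             "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}
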