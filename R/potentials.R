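#' Flat-bottom distance restraint energy
#'
#' The four-piece flat-bottom harmonic potential used for NOE distance
#' restraints: harmonic below the lower bound r0, zero between r0 and the
#' first upper bound r1, harmonic between r1 and the second upper bound
#' r2, and linear (constant force) beyond r2 so that a badly violated
#' restraint cannot generate extreme forces.  The function is continuous
#' everywhere, including at r2 where the linear branch takes the value
#' k/2 (r2 - r1)^2.
#'
#' @param r Distance(s), nm.
#' @param restraint A `"distance_restraint"` or any list with elements
#'   `r0`, `r1`, `r2` (nm).
#' @param k_dr Force constant, kJ mol^-1 nm^-2.
#' @return Energy in kJ mol^-1, vectorized over `r`.
#' @examples
#' res <- list(r0 = 0.2, r1 = 0.3, r2 = 0.4)
#' distance_energy(c(0.25, 0.35, 0.5), res, k_dr = 1000)
#' @export
distance_energy <- function(r, restraint, k_dr = 1000) {
  stopifnot(all(r > 0))
  r0 <- restraint$r0; r1 <- restraint$r1; r2 <- restraint$r2
  stopifnot(r0 <= r1, r1 <= r2)
  ifelse(r < r0, 0.5 * k_dr * (r - r0)^2,
  ifelse(r < r1, 0,
  ifelse(r < r2, 0.5 * k_dr * (r - r1)^2,
                 0.5 * k_dr * (r2 - r1) * (2 * r - r2 - r1))))
}

#' Inverse-sixth-power effective distance
#'
#' Combines the atom-pair distances grouped under one restraint label
#' into a single effective distance, reflecting the r^-6 scaling of NOE
#' intensities.  `"mean"` mode computes (mean r^-6)^(-1/6) and always
#' lies between the minimum and maximum input; `"sum"` mode computes
#' (sum r^-6)^(-1/6), the ambiguous-restraint convention, and is never
#' larger than the smallest input.
#'
#' @param pair_distances Positive distances, nm.
#' @param mode `"mean"` or `"sum"`.
#' @return Effective distance, nm.
#' @examples
#' effective_distance(c(0.3, 0.6))          # mean mode
#' effective_distance(c(0.3, 0.6), "sum")
#' @export
effective_distance <- function(pair_distances, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  if (length(pair_distances) == 0)
    stop("effective_distance: empty distance list")
  stopifnot(all(pair_distances > 0))
  s <- sum(pair_distances^-6)
  if (mode == "mean") s <- s / length(pair_distances)
  s^(-1 / 6)
}

#' Flat-bottom dihedral restraint energy
#'
#' Zero inside the allowed window phi0 +/- dphi and harmonic in the
#' excess outside it, with the angular difference wrapped into
#' (-180, 180] so the potential is periodic in 360 degrees.  Angles are
#' degrees at the interface; the force constant acts on radians, so the
#' excess is converted before squaring.
#'
#' @param phi Dihedral angle(s), degrees.
#' @param restraint A `"dihedral_restraint"` or list with `phi0`, `dphi`
#'   (degrees).
#' @param k_dihr Force constant, kJ mol^-1 rad^-2.
#' @return Energy in kJ mol^-1, vectorized over `phi`.
#' @examples
#' dihedral_energy(-110, list(phi0 = -70, dphi = 30), k_dihr = 1000)
#' @export
dihedral_energy <- function(phi, restraint, k_dihr = 1000) {
  d <- abs(wrap_angle(phi - restraint$phi0))
  excess <- pmax(0, d - restraint$dphi) * pi / 180
  0.5 * k_dihr * excess^2
}

# Dihedral angle (degrees) from four points (rows of a 4x3 matrix), via
# bio3d's torsion routine.  bio3d reports the opposite sign of the
# IUPAC convention used by MD packages; negate to match.
dihedral_angle <- function(p) {
  -bio3d::torsion.xyz(as.vector(t(p)), atm.inc = 4)[1]
}

#' Fit an alignment tensor to residual dipolar couplings
#'
#' Least-squares fit of the symmetric traceless 3x3 alignment tensor A
#' minimizing the sum of squared differences between observed couplings
#' and the standard dipolar back-calculation const * v' A v over the unit
#' internuclear vectors v of the restrained atom pairs.  Five independent
#' components (Axx, Ayy, Axy, Axz, Ayz) are determined; fewer than five
#' restraints, or collinear vectors, give a rank-deficient system which
#' is flagged `underdetermined` and solved in the minimum-norm sense via
#' the singular value decomposition.
#'
#' @param structure A numeric N x 3 coordinate matrix (nm) indexed by
#'   global atom index, or a `"structure_model"`.
#' @param restraints List of `"orientation_restraint"` objects.
#' @return An object of class `"alignment_tensor"`: list with `A` (3x3
#'   symmetric traceless matrix), `components` (the 5 parameters),
#'   `fitted` (back-calculated couplings, Hz), `underdetermined` flag.
#' @export
fit_alignment_tensor <- function(structure, restraints) {
  xyz <- model_coords(structure)
  n <- length(restraints)
  if (n == 0) stop("no orientation restraints to fit")
  D <- matrix(0, n, 5)
  obs <- numeric(n)
  for (r in seq_len(n)) {
    rr <- restraints[[r]]
    v <- xyz[rr$atoms[2], ] - xyz[rr$atoms[1], ]
    v <- v / sqrt(sum(v^2))
    x <- v[1]; y <- v[2]; z <- v[3]
    D[r, ] <- rr$const * c(x^2 - z^2, y^2 - z^2, 2 * x * y,
                           2 * x * z, 2 * y * z)
    obs[r] <- rr$obs
  }
  sv <- svd(D)
  tol <- max(dim(D)) * max(sv$d) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  comp <- sv$v %*% (dinv * crossprod(sv$u, obs))
  comp <- as.vector(comp)
  A <- matrix(c(comp[1], comp[3], comp[4],
                comp[3], comp[2], comp[5],
                comp[4], comp[5], -comp[1] - comp[2]), 3, 3)
  structure(list(A = A, components = comp,
                 fitted = as.vector(D %*% comp),
                 underdetermined = rank < 5, rank = rank),
            class = "alignment_tensor")
}

#' Back-calculate residual dipolar couplings from an alignment tensor
#'
#' @param tensor An `"alignment_tensor"` (or any 3x3 matrix).
#' @param structure Coordinates as in [fit_alignment_tensor()].
#' @param restraints List of `"orientation_restraint"` objects.
#' @return Numeric vector of couplings, Hz.
#' @export
back_calculate_rdc <- function(tensor, structure, restraints) {
  A <- if (inherits(tensor, "alignment_tensor")) tensor$A else tensor
  xyz <- model_coords(structure)
  vapply(restraints, function(rr) {
    v <- xyz[rr$atoms[2], ] - xyz[rr$atoms[1], ]
    v <- v / sqrt(sum(v^2))
    rr$const * as.numeric(t(v) %*% A %*% v)
  }, numeric(1))
}

#' Evaluate restraint violations for one structure
#'
#' Per-restraint violation magnitudes and energies for a single
#' coordinate set: a distance restraint is violated by the amount its
#' effective (r^-6 averaged) distance falls outside [r0, r1]; a dihedral
#' restraint by the amount the wrapped angular difference exceeds the
#' half-width dphi; an orientation restraint by the absolute difference
#' between its observed coupling and the coupling back-calculated after
#' fitting the alignment tensor to this structure (fit per experiment).
#' Aggregate violations are arithmetic means over the restraints of each
#' class.
#'
#' @param structure Coordinates: N x 3 matrix (nm) or
#'   `"structure_model"`; rows addressed by global atom index.
#' @param restraints A `"gmx_restraints"` object from
#'   [convert_restraints()].
#' @param config A [converter_config()]; supplies force constants and the
#'   averaging mode.
#' @return An object of class `"violation_report"`: data frames
#'   `distance` (label, r_eff, violation nm, energy), `dihedral` (phi,
#'   violation degrees, energy), `orientation` (experiment, label, obs,
#'   calc, violation Hz, energy) and `means`, the per-class mean
#'   violation.
#' @examples
#' pep <- make_peptide(c("ALA", "ALA", "ILE"))
#' star <- make_star(pep, n_distance = 5, seed = 3)
#' conv <- convert_restraints(parse_star(star$text),
#'                            read_topology(pep$topology))
#' violations(pep$ensemble$models[[1]], conv)$means
#' @export
violations <- function(structure, restraints,
                       config = restraints$config) {
  if (is.null(config)) config <- converter_config()
  xyz <- model_coords(structure)
  dist_df <- data.frame(label = integer(), r_eff = numeric(),
                        violation = numeric(), energy = numeric())
  for (d in restraints$distances) {
    pr <- sqrt(rowSums((xyz[d$pairs[, 1], , drop = FALSE] -
                          xyz[d$pairs[, 2], , drop = FALSE])^2))
    r_eff <- effective_distance(pr, config$averaging)
    viol <- max(0, r_eff - d$r1, d$r0 - r_eff)
    dist_df <- rbind(dist_df, data.frame(
      label = d$label, r_eff = r_eff, violation = viol,
      energy = distance_energy(r_eff, d, config$k_dr)))
  }
  dih_df <- data.frame(phi = numeric(), violation = numeric(),
                       energy = numeric())
  for (d in restraints$dihedrals) {
    phi <- dihedral_angle(xyz[d$atoms, , drop = FALSE])
    viol <- max(0, abs(wrap_angle(phi - d$phi0)) - d$dphi)
    dih_df <- rbind(dih_df, data.frame(
      phi = phi, violation = viol,
      energy = dihedral_energy(phi, d, config$k_dihr)))
  }
  ori_df <- data.frame(experiment = integer(), label = integer(),
                       obs = numeric(), calc = numeric(),
                       violation = numeric(), energy = numeric())
  if (length(restraints$orientations) > 0) {
    exps <- vapply(restraints$orientations, function(r) r$experiment, 1L)
    for (e in sort(unique(exps))) {
      sub <- restraints$orientations[exps == e]
      fit <- fit_alignment_tensor(xyz, sub)
      for (k in seq_along(sub)) {
        rr <- sub[[k]]
        viol <- abs(fit$fitted[k] - rr$obs)
        ori_df <- rbind(ori_df, data.frame(
          experiment = e, label = rr$label, obs = rr$obs,
          calc = fit$fitted[k], violation = viol,
          energy = 0.5 * config$k_or * rr$weight * viol^2))
      }
    }
  }
  means <- c(distance = if (nrow(dist_df)) mean(dist_df$violation) else NA,
             dihedral = if (nrow(dih_df)) mean(dih_df$violation) else NA,
             orientation = if (nrow(ori_df)) mean(ori_df$violation) else NA)
  structure(list(distance = dist_df, dihedral = dih_df,
                 orientation = ori_df, means = means),
            class = "violation_report")
}

#' @export
print.violation_report <- function(x, ...) {
  cat("Restraint violation report\n")
  cat(sprintf("  distance    : n=%d  mean violation %.4f nm\n",
              nrow(x$distance), x$means["distance"]))
  cat(sprintf("  dihedral    : n=%d  mean violation %.3f deg\n",
              nrow(x$dihedral), x$means["dihedral"]))
  cat(sprintf("  orientation : n=%d  mean violation %.4f Hz\n",
              nrow(x$orientation), x$means["orientation"]))
  invisible(x)
}
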