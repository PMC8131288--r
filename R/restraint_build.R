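# A skipped restraint is a value, not an exception: carries the reason.
restraint_miss <- function(reason) {
  structure(list(reason = reason), class = "restraint_miss")
}

#' Test for a skipped (unresolvable) restraint
#' @param x Result of [build_distance()], [build_dihedral()] or
#'   [build_orientation()].
#' @return `TRUE` if the restraint could not be built; its `$reason` says
#'   why.
#' @export
is_restraint_miss <- function(x) inherits(x, "restraint_miss")

#' Build a GROMACS distance restraint from a raw record
#'
#' Applies the two-layer nomenclature translation to every logical-OR
#' member of the record, expands pseudo-atoms, resolves all real atoms
#' against the topology and collects every resulting atom pair under one
#' restraint label, so that the MD engine treats them as a single
#' restraint with inverse-sixth-power distance averaging.  Deposited
#' bounds (angstrom) are converted to nm: r0 = lower/10, r1 = upper/10,
#' and the second upper bound r2 = r1 + `config$r2_margin` caps the
#' restraint force at large violations.
#'
#' @param record A raw distance record from [parse_star()].
#' @param topology A `"topology_index"` from [read_topology()].
#' @param config A [converter_config()].
#' @param label Integer label to assign (labels are consecutive from 0 in
#'   file order).
#' @return A list of class `"distance_restraint"` with `label`, `pairs`
#'   (two-column integer matrix of global indices), `r0`, `r1`, `r2` (nm)
#'   and `fac`; or a `"restraint_miss"` carrying the reason if any atom
#'   failed to resolve (the restraint is then skipped with a warning).
#' @export
build_distance <- function(record, topology, config = converter_config(),
                           label = 0L) {
  pairs <- matrix(integer(), ncol = 2)
  for (m in record$members) {
    exp <- expand_pair(m[[1]], m[[2]], config$force_field)
    for (r in seq_len(nrow(exp))) {
      i <- resolve_atom(topology, exp$chain_1[r], exp$resseq_1[r],
                        exp$atom_1[r])
      j <- resolve_atom(topology, exp$chain_2[r], exp$resseq_2[r],
                        exp$atom_2[r])
      if (is.na(i$index) || is.na(j$index)) {
        reason <- c(i$reason, j$reason)
        return(restraint_miss(sprintf(
          "distance restraint %d: %s", record$restraint_id,
          reason[!is.na(reason)][1])))
      }
      pairs <- rbind(pairs, c(i$index, j$index))
    }
  }
  r0 <- max(0, record$lower_bound) * 0.1
  r1 <- record$upper_bound * 0.1
  structure(list(label = as.integer(label), pairs = pairs,
                 r0 = r0, r1 = r1, r2 = r1 + config$r2_margin, fac = 1.0),
            class = "distance_restraint")
}

#' Build a GROMACS dihedral restraint from a raw record
#'
#' The deposited interval is traversed from the lower to the upper bound
#' in the increasing (mod 360 degrees) direction; the reference angle
#' phi0 is the circular midpoint of that arc and the half-width dphi is
#' half its length, so periodicity is taken into account (an interval of
#' 170 to -170 degrees gives phi0 = 180, dphi = 10).
#'
#' @inheritParams build_distance
#' @return A list of class `"dihedral_restraint"` with `atoms` (four
#'   global indices), `phi0` (degrees, wrapped into (-180, 180]), `dphi`
#'   (degrees) and `kfac`; or a `"restraint_miss"` on an unresolvable
#'   atom.
#' @export
build_dihedral <- function(record, topology, config = converter_config()) {
  names4 <- translate_dihedral(record, config$force_field)
  idx <- integer(4)
  for (k in 1:4) {
    a <- record$atoms[[k]]
    hit <- resolve_atom(topology, a$chain, a$resseq, names4[k])
    if (is.na(hit$index))
      return(restraint_miss(sprintf(
        "dihedral restraint %d: %s", record$restraint_id, hit$reason)))
    idx[k] <- hit$index
  }
  lo <- record$angle_lower
  hi <- record$angle_upper
  if (hi - lo >= 360)
    stop(sprintf("dihedral restraint %d: interval spans the full circle",
                 record$restraint_id))
  width <- (hi - lo) %% 360
  structure(list(atoms = idx,
                 phi0 = wrap_angle(lo + width / 2),
                 dphi = width / 2, kfac = 1.0,
                 name = record$angle_name),
            class = "dihedral_restraint")
}

#' Build a GROMACS orientation restraint from a raw record
#'
#' The observed coupling (Hz) is copied through; the dipolar constant is
#' looked up per element pair (N-H by default) and the distance exponent
#' alpha is 3.  Experiments are numbered consecutively in order of
#' appearance and labels restart at 1 within each experiment.
#'
#' @inheritParams build_distance
#' @param experiment Renumbered experiment id.
#' @param label Label within the experiment.
#' @return A list of class `"orientation_restraint"` with `atoms` (two
#'   global indices), `experiment`, `label`, `alpha`, `const`, `obs` (Hz)
#'   and `weight` (Hz^-2); or a `"restraint_miss"`.
#' @export
build_orientation <- function(record, topology,
                              config = converter_config(),
                              experiment = 1L, label = 1L) {
  idx <- integer(2)
  elem <- character(2)
  for (k in 1:2) {
    a <- record$atoms[[k]]
    nm <- translate_atom(a$resname, a$atom, config$force_field)
    if (length(nm) != 1)
      return(restraint_miss(sprintf(
        "orientation restraint %d: identifier %s denotes %d atoms",
        record$restraint_id, a$atom, length(nm))))
    hit <- resolve_atom(topology, a$chain, a$resseq, nm)
    if (is.na(hit$index))
      return(restraint_miss(sprintf(
        "orientation restraint %d: %s", record$restraint_id, hit$reason)))
    idx[k] <- hit$index
    elem[k] <- substr(sub("^[0-9']+", "", nm), 1, 1)
  }
  tab <- config$orire_const_table
  names(tab) <- vapply(strsplit(names(tab), ".", fixed = TRUE),
                       function(p) paste(sort(p), collapse = "."), "")
  const <- unname(tab[paste(sort(elem), collapse = ".")])
  if (length(const) != 1 || is.na(const)) const <- config$orire_const
  err <- record$error
  weight <- if (!is.null(err) && !is.na(err) && err > 0) 1 / err^2 else 1.0
  structure(list(atoms = idx, experiment = as.integer(experiment),
                 label = as.integer(label), alpha = config$orire_alpha,
                 const = const, obs = record$observed, weight = weight),
            class = "orientation_restraint")
}

#' Convert parsed restraint sets to GROMACS restraints
#'
#' Runs nomenclature translation, pseudo-atom expansion and topology
#' resolution over every parsed record.  A restraint is emitted only if
#' all of its atoms resolve; otherwise it is skipped and a warning is
#' recorded, so that emitted + skipped always equals the parsed count.
#'
#' @param sets A `"restraint_sets"` from [parse_star()].
#' @param topology A `"topology_index"` from [read_topology()].
#' @param config A [converter_config()].
#' @return An object of class `"gmx_restraints"`: lists `distances`,
#'   `dihedrals`, `orientations`, plus `counts` (matrix parsed/emitted/
#'   skipped by class), `warnings`, `source_label` and the `config`.
#' @examples
#' pep <- make_peptide(c("ALA", "ILE"))
#' star <- make_star(pep, n_distance = 3, seed = 2)
#' conv <- convert_restraints(parse_star(star$text),
#'                            read_topology(pep$topology))
#' conv$counts
#' @export
convert_restraints <- function(sets, topology,
                               config = converter_config()) {
  warnings <- character()
  distances <- list()
  label <- 0L
  for (rec in sets$distances) {
    built <- build_distance(rec, topology, config, label = label)
    if (is_restraint_miss(built)) {
      warnings <- c(warnings, paste("skipped", built$reason))
    } else {
      distances[[length(distances) + 1L]] <- built
      label <- label + 1L
    }
  }
  dihedrals <- list()
  for (rec in sets$dihedrals) {
    built <- build_dihedral(rec, topology, config)
    if (is_restraint_miss(built)) {
      warnings <- c(warnings, paste("skipped", built$reason))
    } else {
      dihedrals[[length(dihedrals) + 1L]] <- built
    }
  }
  orientations <- list()
  exp_map <- integer(0)
  exp_label <- integer(0)
  for (rec in sets$orientations) {
    e_raw <- as.character(rec$experiment_id)
    if (is.na(match(e_raw, names(exp_map)))) {
      exp_map[e_raw] <- length(exp_map) + 1L
      exp_label[e_raw] <- 0L
    }
    built <- build_orientation(rec, topology, config,
                               experiment = exp_map[[e_raw]],
                               label = exp_label[[e_raw]] + 1L)
    if (is_restraint_miss(built)) {
      warnings <- c(warnings, paste("skipped", built$reason))
    } else {
      exp_label[e_raw] <- exp_label[[e_raw]] + 1L
      orientations[[length(orientations) + 1L]] <- built
    }
  }
  counts <- rbind(
    parsed = c(distance = length(sets$distances),
               dihedral = length(sets$dihedrals),
               orientation = length(sets$orientations)),
    emitted = c(length(distances), length(dihedrals), length(orientations)))
  counts <- rbind(counts, skipped = counts["parsed", ] - counts["emitted", ])
  structure(list(distances = distances, dihedrals = dihedrals,
                 orientations = orientations, counts = counts,
                 warnings = c(sets$warnings, warnings),
                 source_label = sets$source_label, config = config),
            class = "gmx_restraints")
}

#' @export
print.gmx_restraints <- function(x, ...) {
  cat(sprintf("GROMACS restraints from '%s' (%s naming)\n",
              x$source_label, x$config$force_field))
  print(x$counts)
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Writers
# ---------------------------------------------------------------------------

#' Write restraints as a GROMACS topology include
#'
#' Emits the `[ distance_restraints ]`, `[ dihedral_restraints ]` or
#' `[ orientation_restraints ]` dialect with fixed column widths.
#' Distance lines are `ai aj 1 label 1 low up1 up2 fac`; dihedral lines
#' `ai aj ak al 1 phi0 dphi kfac`; orientation lines
#' `ai aj 1 exp label alpha const obs weight`.
#'
#' @param restraints A list of restraint objects of one kind (e.g.
#'   `conv$distances`), or a `"gmx_restraints"` object from which the kind
#'   is taken.
#' @param kind `"distance"`, `"dihedral"` or `"orientation"`.
#' @param source_label,force_field Strings for the header comment.
#' @return The include text as one string.
#' @export
write_itp <- function(restraints, kind = c("distance", "dihedral",
                                           "orientation"),
                      source_label = "restraints", force_field = "amber") {
  kind <- match.arg(kind)
  if (inherits(restraints, "gmx_restraints")) {
    source_label <- restraints$source_label
    force_field <- restraints$config$force_field
    restraints <- switch(kind, distance = restraints$distances,
                         dihedral = restraints$dihedrals,
                         orientation = restraints$orientations)
  }
  header <- sprintf("; %s restraints generated from %s (%s naming)",
                    kind, source_label, force_field)
  lines <- switch(kind,
    distance = {
      body <- unlist(lapply(restraints, function(d)
        sprintf("%6d %6d %5d %5d %5d %8.3f %8.3f %8.3f %8.3f",
                d$pairs[, 1], d$pairs[, 2], 1L, d$label, 1L,
                d$r0, d$r1, d$r2, d$fac)))
      c("[ distance_restraints ]",
        ";    ai     aj  type label type'     low      up1      up2      fac",
        body)
    },
    dihedral = {
      body <- vapply(restraints, function(d)
        sprintf("%6d %6d %6d %6d %5d %8.2f %8.2f %8.3f",
                d$atoms[1], d$atoms[2], d$atoms[3], d$atoms[4], 1L,
                d$phi0, d$dphi, d$kfac), character(1))
      c("[ dihedral_restraints ]",
        ";    ai     aj     ak     al  type     phi0     dphi     kfac",
        body)
    },
    orientation = {
      body <- vapply(restraints, function(d)
        sprintf("%6d %6d %5d %5d %5d %5d %10.4f %10.4f %10.6f",
                d$atoms[1], d$atoms[2], 1L, d$experiment, d$label,
                d$alpha, d$const, d$obs, d$weight), character(1))
      c("[ orientation_restraints ]",
        ";    ai     aj  type   exp label alpha      const        obs     weight",
        body)
    })
  paste(c(header, lines, ""), collapse = "\n")
}

#' Write the restraint run-parameter fragment
#'
#' Emits the GROMACS `.mdp` keys controlling restrained runs:
#' time-averaged distance restraining with force constant `k_dr` and
#' averaging time `tau_dr` (recommended 1000 kJ mol^-1 nm^-2 and 500 ps),
#' the dihedral force constant `k_dihr` and the orientation force
#' constant `k_or`.
#'
#' @param config A [converter_config()].
#' @return The fragment text as one string.
#' @examples
#' cat(write_mdp_fragment(converter_config()))
#' @export
write_mdp_fragment <- function(config = converter_config()) {
  paste(c("; restraint parameters",
          "disre                    = simple",
          "disre-weighting          = equal",
          sprintf("disre-fc                 = %g", config$k_dr),
          sprintf("disre-tau                = %g", config$tau_dr),
          "nstdisreout              = 0",
          sprintf("dihre-fc                 = %g", config$k_dihr),
          "orire                    = yes",
          sprintf("orire-fc                 = %g", config$k_or),
          "orire-tau                = 0",
          "orire-fitgrp             = backbone",
          ""), collapse = "\n")
}

#' Write all restraint output files
#'
#' Writes `disre.itp`, `dihre.itp`, `orire.itp` and `restraints.mdp` into
#' a directory.  Conversion is deterministic: identical inputs yield
#' byte-identical files.
#'
#' @param conv A `"gmx_restraints"` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_gmx_restraints <- function(conv, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(disre = file.path(dir, "disre.itp"),
             dihre = file.path(dir, "dihre.itp"),
             orire = file.path(dir, "orire.itp"),
             mdp = file.path(dir, "restraints.mdp"))
  writeLines(write_itp(conv, "distance"), paths["disre"])
  writeLines(write_itp(conv, "dihedral"), paths["dihre"])
  writeLines(write_itp(conv, "orientation"), paths["orire"])
  writeLines(write_mdp_fragment(conv$config), paths["mdp"])
  invisible(paths)
}
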