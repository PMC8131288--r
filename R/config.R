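#' Converter configuration
#'
#' Bundles the tunable parameters of the restraint conversion pipeline:
#' the target force-field naming scheme, the restraint force constants and
#' averaging time emitted into the run-parameter fragment, the width of the
#' second (linear-regime) upper bound added to every distance restraint, and
#' the inverse-sixth-power averaging convention used when a restraint groups
#' several atom pairs.
#'
#' @param force_field Target naming scheme, `"amber"` or `"charmm"`.
#' @param k_dr Distance-restraint force constant, kJ mol^-1 nm^-2.
#'   The recommended value is 1000.
#' @param tau_dr Time constant for time-averaged distance restraining, ps.
#'   The recommended value is 500.
#' @param k_dihr Dihedral-restraint force constant, kJ mol^-1 rad^-2.
#' @param k_or Orientation-restraint force constant, kJ mol^-1 Hz^-2.
#' @param r2_margin Width added to the first upper bound r1 to obtain the
#'   second upper bound r2 beyond which the restraint force stops growing,
#'   in nm.
#' @param averaging How several atom-pair distances sharing one restraint
#'   label combine into an effective distance: `"mean"` for
#'   (mean r^-6)^(-1/6), `"sum"` for (sum r^-6)^(-1/6).
#' @param orire_const Dipolar constant written for orientation restraints
#'   whose atom pair is not in `orire_const_table`.
#' @param orire_alpha Exponent of the internuclear distance in the
#'   orientation-restraint back-calculation (3 for dipolar couplings).
#' @param orire_const_table Named numeric vector mapping element pairs
#'   (e.g. `"N.H"`) to dipolar constants.
#'
#' @return An object of class `"converter_config"` (a named list).
#' @examples
#' cfg <- converter_config(force_field = "charmm", k_dr = 500)
#' cfg$k_dr
#' @export
converter_config <- function(force_field = c("amber", "charmm"),
                             k_dr = 1000,
                             tau_dr = 500,
                             k_dihr = 1000,
                             k_or = 10,
                             r2_margin = 0.1,
                             averaging = c("mean", "sum"),
                             orire_const = 6.083,
                             orire_alpha = 3,
                             orire_const_table = c("N.H" = 6.083)) {
  force_field <- match.arg(force_field)
  averaging <- match.arg(averaging)
  stopifnot(k_dr >= 0, tau_dr >= 0, k_dihr >= 0, k_or >= 0, r2_margin >= 0)
  structure(list(force_field = force_field,
                 k_dr = k_dr, tau_dr = tau_dr,
                 k_dihr = k_dihr, k_or = k_or,
                 r2_margin = r2_margin, averaging = averaging,
                 orire_const = orire_const, orire_alpha = orire_alpha,
                 orire_const_table = orire_const_table),
            class = "converter_config")
}

#' @export
print.converter_config <- function(x, ...) {
  cat("Restraint converter configuration\n")
  cat(sprintf("  force field : %s\n", x$force_field))
  cat(sprintf("  k_dr        : %g kJ/mol/nm^2\n", x$k_dr))
  cat(sprintf("  tau_dr      : %g ps\n", x$tau_dr))
  cat(sprintf("  k_dihr      : %g kJ/mol/rad^2\n", x$k_dihr))
  cat(sprintf("  k_or        : %g kJ/mol/Hz^2\n", x$k_or))
  cat(sprintf("  r2 margin   : %g nm\n", x$r2_margin))
  cat(sprintf("  averaging   : %s\n", x$averaging))
  invisible(x)
}

# Wrap angular differences (degrees) into (-180, 180].
wrap_angle <- function(d) {
  w <- ((d + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}
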