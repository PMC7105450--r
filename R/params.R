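#' Model parameters
#'
#' Single source of truth for the physics of the cell-migration model.
#' Lengths are in mm, time in hours, forces in arbitrary units (a.u.) and
#' flow speeds in m/s (flow enters the cell model only through the ratio
#' `v / v_max` and the unit vector of the local velocity, so no conversion
#' between the two unit systems is needed). With the overdamped mobility of
#' 1 (mm/h per a.u.), the mean magnitude of the random force,
#' `sqrt(8 * c_var / pi) ~ 0.048` a.u., translates into a mean migration
#' speed of ~48 um/h, which is what makes this unit system self-consistent
#' with the calibrated average speed of ~50 um/h.
#'
#' @param r_cell cell radius (mm). Default 0.015 (15 um).
#' @param C elastic constant of the soft-core contact repulsion (a.u.).
#' @param epsilon Lennard-Jones interaction constant (a.u.).
#' @param r_cutoff maximum interaction distance (mm); default `4 * r_cell`.
#' @param v_max flow speed (m/s) at and above which the directional flow cue
#'   saturates at `w_max`.
#' @param w_min,w_max minimum / maximum weight of the flow-velocity direction
#'   in the migration direction blend (dimensionless, in `[0, 1]`).
#'   `w_min = 0.05` models ROCK inhibition (default untreated value 0.3).
#' @param c_var variance of each normal component of the random force
#'   (a.u.^2). The resulting force magnitude follows a Maxwell-Boltzmann-type
#'   distribution with mean `sqrt(8 * c_var / pi)`.
#' @param p_change rate (per hour) at which a cell's persistent random force
#'   is replaced by a fresh draw.
#' @param nu_dyn dynamic viscosity of the perfusate (Pa s), used in the
#'   first-node wall-shear-stress estimate.
#' @param delta flow lattice spacing (mm).
#' @param mobility overdamped mobility (mm/h per a.u.); velocity of a mobile
#'   cell is `mobility * F_total`.
#' @param k_wall stiffness (a.u./mm) of the frictionless side-wall restoring
#'   force.
#' @param contact_variant which contact-area approximation the soft-core
#'   branch uses: `"printed"` for `sqrt(r_cell/2 * (2*r_cell - r))` (the
#'   default), `"caption"` for `sqrt(r_cell * (2*r_cell - r))`. The two are
#'   kept side by side because the published full-overlap repulsion value
#'   (1.658e-3 a.u.) is reproduced only by the `"caption"` variant, while the
#'   printed formula gives 3.45e-4 a.u.; neither is silently "fixed".
#'
#' @return An object of class `ec_params` (a validated list; `sigma` is
#'   always `2 * r_cell`).
#' @export
model_params <- function(r_cell = 0.015, C = 0.1, epsilon = 3e-7,
                         r_cutoff = 4 * r_cell,
                         v_max = 0.036, w_min = 0.3, w_max = 0.7,
                         c_var = 9e-4, p_change = 0.075,
                         nu_dyn = 1e-3, delta = 0.015,
                         mobility = 1, k_wall = 10,
                         contact_variant = c("printed", "caption")) {
  contact_variant <- match.arg(contact_variant)
  p <- list(r_cell = r_cell, C = C, epsilon = epsilon,
            sigma = 2 * r_cell, r_cutoff = r_cutoff,
            v_max = v_max, w_min = w_min, w_max = w_max,
            c_var = c_var, p_change = p_change,
            nu_dyn = nu_dyn, delta = delta,
            mobility = mobility, k_wall = k_wall,
            contact_variant = contact_variant)
  class(p) <- "ec_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(
    "r_cell must be > 0" = p$r_cell > 0,
    "sigma must equal 2*r_cell" = isTRUE(all.equal(p$sigma, 2 * p$r_cell)),
    "r_cutoff must exceed sigma" = p$r_cutoff > p$sigma,
    "weights must satisfy 0 <= w_min <= w_max <= 1" =
      p$w_min >= 0 && p$w_min <= p$w_max && p$w_max <= 1,
    "c_var must be > 0" = p$c_var > 0,
    "p_change must be >= 0" = p$p_change >= 0,
    "v_max must be > 0" = p$v_max > 0,
    "delta must be > 0" = p$delta > 0,
    "nu_dyn must be > 0" = p$nu_dyn > 0,
    "mobility must be > 0" = p$mobility > 0
  )
  invisible(p)
}

#' @export
print.ec_params <- function(x, ...) {
  cat("EC migration model parameters\n")
  cat(sprintf("  r_cell    %g mm   (sigma = %g, r_cutoff = %g)\n",
              x$r_cell, x$sigma, x$r_cutoff))
  cat(sprintf("  C         %g a.u.   epsilon %g a.u.\n", x$C, x$epsilon))
  cat(sprintf("  flow cue  w in [%g, %g], saturating at v_max = %g m/s\n",
              x$w_min, x$w_max, x$v_max))
  cat(sprintf("  random force: component variance %g a.u.^2, refresh rate %g /h\n",
              x$c_var, x$p_change))
  cat(sprintf("  fluid: nu = %g Pa s, lattice spacing delta = %g mm\n",
              x$nu_dyn, x$delta))
  cat(sprintf("  contact-area variant: %s\n", x$contact_variant))
  invisible(x)
}

# integer code used by the C++ kernels
contact_variant_code <- function(p) if (identical(p$contact_variant, "caption")) 1L else 0L
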