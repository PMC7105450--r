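#' Contact area of two overlapping cells
#'
#' Approximate contact radius for two spheres of radius `r_cell` whose
#' centres are a distance r below `2*r_cell` apart. The default (`"printed"`)
#' form is `sqrt(r_cell/2 * (2*r_cell - r))`; the `"caption"` alternative
#' `sqrt(r_cell * (2*r_cell - r))` is selectable through
#' `model_params(contact_variant=)` or the `variant` argument (see
#' [model_params()] for why both exist).
#'
#' @param r centre-centre distance(s), mm; must lie in `[0, 2*r_cell]`.
#' @param p an `ec_params` object.
#' @param variant override of `p$contact_variant`.
#' @return contact radius (mm), vectorized over `r`.
#' @export
contact_area <- function(r, p = model_params(), variant = p$contact_variant) {
  if (any(!is.finite(r)) || any(r < 0) || any(r > 2 * p$r_cell))
    stop("contact_area: r must lie in [0, 2*r_cell]")
  if (identical(variant, "caption")) sqrt(p$r_cell * (2 * p$r_cell - r))
  else sqrt(p$r_cell / 2 * (2 * p$r_cell - r))
}

#' Signed pairwise interaction force
#'
#' Cell-cell / cell-obstacle interaction force as a function of centre
#' distance: a truncated Lennard-Jones 12/6 force for
#' `2*r_cell <= r < r_cutoff`, a soft-core neo-Hookean contact repulsion for
#' distances below `2*r_cell` (using [contact_area()]), and exactly zero at and beyond
#' `r_cutoff`.
#'
#' Sign convention: the returned value is the force component along the
#' centre line with **positive = repulsive**. The LJ branch is therefore
#' negative (attractive) for `sigma < r < r_cutoff` and both branches vanish
#' at the equilibrium distance, `sigma = 2*r_cell`.
#'
#' @param r centre distance(s), mm; must be strictly positive (coincident
#'   centres have no defined direction and are rejected).
#' @param p an `ec_params` object.
#' @return signed force (a.u.), vectorized over `r`.
#' @export
pair_force_magnitude <- function(r, p = model_params()) {
  if (any(!is.finite(r)) || any(r <= 0))
    stop("pair_force_magnitude: r must be > 0 (coincident centres are a domain error)")
  cpp_pair_force(as.numeric(r), p$r_cell, p$C, p$epsilon, p$sigma, p$r_cutoff,
                 contact_variant_code(p))
}

#' Weight of the flow-velocity direction in the migration blend
#'
#' Linear in the local flow speed from `w_min` at `v = 0` up to `w_max` at
#' `v = v_max`, constant at `w_max` above; continuous at `v = v_max`.
#'
#' @param v local flow speed(s), m/s, non-negative.
#' @param p an `ec_params` object.
#' @return dimensionless weight(s) in `[w_min, w_max]`.
#' @export
velocity_weight <- function(v, p = model_params()) {
  if (any(!is.finite(v)) || any(v < 0))
    stop("velocity_weight: v must be >= 0")
  pmin(v / p$v_max, 1) * (p$w_max - p$w_min) + p$w_min
}

#' Blended migration direction
#'
#' Weighted average of the unit vector along the persistent random force and
#' the unit vector of the local flow velocity:
#' `d = e_rand * (1 - w) + e_vel * w`. The result is **not** renormalized
#' here; its norm is at most 1 and can degenerate to 0 when the two inputs
#' are antiparallel at `w = 0.5` (the dynamics layer resamples the random
#' force in that case).
#'
#' @param e_rand,e_vel unit 3-vectors.
#' @param w weight in `[0, 1]`.
#' @return a 3-vector.
#' @export
migration_direction <- function(e_rand, e_vel, w) {
  if (length(e_rand) != 3 || length(e_vel) != 3)
    stop("migration_direction: e_rand and e_vel must be 3-vectors")
  if (sqrt(sum(e_rand^2)) < 1e-12 || sqrt(sum(e_vel^2)) < 1e-12)
    stop("migration_direction: zero-length input vector")
  if (w < 0 || w > 1) stop("migration_direction: w must be in [0, 1]")
  e_rand * (1 - w) + e_vel * w
}

#' Migration force
#'
#' Redirects the persistent random force along the blended direction while
#' preserving its magnitude exactly: `F_migr = |F_rand| * d / |d|`.
#'
#' @param F_rand random-force 3-vector (a.u.).
#' @param d blended direction 3-vector (need not be unit length).
#' @return migration force 3-vector with `|F_migr| == |F_rand|`.
#' @export
migration_force <- function(F_rand, d) {
  nd <- sqrt(sum(d^2))
  if (nd < 1e-12)
    stop("migration_force: degenerate direction (|d| < 1e-12)")
  sqrt(sum(F_rand^2)) * d / nd
}

#' Draw persistent random forces
#'
#' Each force is the sum of three independent normal components (variance
#' `c_var`, mean 0) along x, y and z, so the magnitude follows a
#' Maxwell-Boltzmann-type distribution with mean `sqrt(8 * c_var / pi)`.
#' Uses R's global RNG stream (seed via `set.seed()` for reproducibility).
#'
#' @param n number of forces to draw.
#' @param p an `ec_params` object.
#' @return an `n x 3` matrix (a.u.).
#' @export
sample_random_force <- function(n = 1, p = model_params()) {
  matrix(rnorm(3 * n, mean = 0, sd = sqrt(p$c_var)), ncol = 3)
}

#' Total force on one cell
#'
#' Migration force plus the sum of pairwise interaction forces with all
#' cells and obstacle elements within `r_cutoff` (the neighbourhood).
#' Obstacle elements are immobile sources: they exert forces on cells but
#' receive none. See [interaction_forces()] for the population-level kernel.
#'
#' @param i cell index.
#' @param population a `cell_population`.
#' @param obstacles an `obstacle_set` (or NULL for isolated cells).
#' @param F_migr `n x 3` matrix of migration forces (a.u.); defaults to the
#'   population's stored random forces (the no-flow case, where the
#'   migration force equals the random force).
#' @param p an `ec_params` object.
#' @return force 3-vector (a.u.).
#' @export
total_force <- function(i, population, obstacles = NULL,
                        F_migr = population$F_rand, p = model_params()) {
  Fint <- interaction_forces(population$positions, obstacles, p)
  if (!is.null(attr(Fint, "coincident")) && length(attr(Fint, "coincident")))
    warning("coincident cell centres skipped in interaction sum")
  Fint[i, ] + F_migr[i, ]
}

#' Pairwise interaction forces for a whole population
#'
#' Grid-accelerated neighbour search; exact within `r_cutoff` (verified
#' against an all-pairs reference in the test suite). Newton's third law
#' holds between cells; obstacle elements receive no force.
#'
#' @param positions `n x 3` matrix of cell centres (mm).
#' @param obstacles an `obstacle_set` or NULL.
#' @param p an `ec_params` object.
#' @return `n x 3` matrix of summed interaction forces (a.u.), with an
#'   attribute `coincident` listing indices of coincident cell pairs that
#'   were skipped (empty in normal operation).
#' @export
interaction_forces <- function(positions, obstacles = NULL, p = model_params()) {
  optr <- if (is.null(obstacles)) NULL else obstacle_grid(obstacles)
  res <- cpp_interaction_forces(positions, optr,
                                p$r_cell, p$C, p$epsilon, p$sigma, p$r_cutoff,
                                contact_variant_code(p))
  out <- res$F
  attr(out, "coincident") <- unique(res$coincident)
  out
}
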