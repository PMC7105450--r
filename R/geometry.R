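#' Channel geometries
#'
#' Build the simulation domain: a straight channel (x = streamwise,
#' y = wall-normal, z = spanwise, origin at the inlet's bottom-left corner),
#' optionally with ridges (stent struts) on the floor or a backward-facing
#' step. All dimensions in mm. The published chamber dimensions are not
#' stated ("not drawn to scale"), so these defaults are the package's own,
#' recorded in every output header and fully configurable.
#'
#' @param length,height,width channel dimensions (mm).
#' @param ridge_x upstream-face x positions of the ridges (mm).
#' @param ridge_width,ridge_height ridge cross-section (mm).
#' @param step_x x position of the step face (mm; the inlet is
#'   `step_x` mm upstream of the step).
#' @param step_height height of the backward-facing step (mm); upstream of
#'   `step_x` the floor is raised to `step_height`, downstream it is at 0.
#' @return an object of class `channel_geometry`.
#' @export
flat_channel <- function(length = 6, height = 0.5, width = 0.6) {
  new_geometry(kind = "flat", length = length, height = height, width = width)
}

#' @rdname flat_channel
#' @export
ridged_channel <- function(length = 10, height = 0.5, width = 0.9,
                           ridge_x = c(5, 6.5, 8),
                           ridge_width = 0.1, ridge_height = 0.1) {
  ridges <- data.frame(x = ridge_x, width = ridge_width, height = ridge_height)
  new_geometry(kind = "ridged", length = length, height = height,
               width = width, ridges = ridges)
}

#' @rdname flat_channel
#' @export
step_channel <- function(length = 12, height = 0.75, width = 0.6,
                         step_x = 2, step_height = 0.25) {
  new_geometry(kind = "backward_step", length = length, height = height,
               width = width, step = list(x = step_x, height = step_height))
}

new_geometry <- function(kind, length, height, width, ridges = NULL, step = NULL) {
  g <- list(kind = kind, length = length, height = height, width = width,
            ridges = ridges, step = step)
  class(g) <- "channel_geometry"
  validate_geometry(g)
  g
}

validate_geometry <- function(g) {
  stopifnot(g$length > 0, g$height > 0, g$width > 0)
  if (!is.null(g$ridges)) {
    if (any(g$ridges$x < 0) || any(g$ridges$x + g$ridges$width > g$length))
      stop("geometry: ridge lies outside the domain")
    if (any(g$ridges$height >= g$height))
      stop("geometry: ridge height must be below the channel height")
  }
  if (!is.null(g$step)) {
    if (g$step$x <= 0 || g$step$x >= g$length)
      stop("geometry: step face outside the domain")
    if (g$step$height >= g$height)
      stop("geometry: step height must be below the channel height")
  }
  invisible(g)
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf("channel_geometry [%s]: %g x %g x %g mm (L x H x W)\n",
              x$kind, x$length, x$height, x$width))
  if (!is.null(x$ridges))
    cat(sprintf("  %d ridge(s) at x = %s (w %g, h %g mm)\n", nrow(x$ridges),
                paste(x$ridges$x, collapse = ", "),
                x$ridges$width[1], x$ridges$height[1]))
  if (!is.null(x$step))
    cat(sprintf("  backward step at x = %g, height %g mm\n",
                x$step$x, x$step$height))
  invisible(x)
}

#' Height of the channel floor at streamwise position x
#'
#' 0 on the flat substrate, the ridge height on top of a ridge, and the step
#' height upstream of a backward-facing step.
#' @param geom a `channel_geometry`.
#' @param x streamwise position(s), mm.
#' @return floor height(s), mm.
#' @export
floor_height <- function(geom, x) {
  h <- numeric(length(x))
  if (!is.null(geom$ridges))
    for (i in seq_len(nrow(geom$ridges))) {
      r <- geom$ridges[i, ]
      h <- ifelse(x >= r$x & x <= r$x + r$width, pmax(h, r$height), h)
    }
  if (!is.null(geom$step)) h <- ifelse(x < geom$step$x, geom$step$height, h)
  h
}

# Planar hexagonal lattice: row k at b = k * s * sqrt(3)/2, points within a
# row at a = (k %% 2) * s/2 + i * s, clipped to [0, a_len] x [0, b_len].
hex_lattice <- function(a_len, b_len, s) {
  dr <- s * sqrt(3) / 2
  nrows <- floor(b_len / dr + 1e-9) + 1
  pts <- vector("list", nrows)
  for (k in seq_len(nrows) - 1) {
    off <- (k %% 2) * s / 2
    ncol <- floor((a_len - off) / s + 1e-9) + 1
    if (ncol < 1) next
    pts[[k + 1]] <- cbind(a = off + (seq_len(ncol) - 1) * s, b = k * dr)
  }
  do.call(rbind, pts)
}

# closed-form point count of hex_lattice (used by tests as the analytic oracle)
hex_lattice_count <- function(a_len, b_len, s) {
  dr <- s * sqrt(3) / 2
  nrows <- floor(b_len / dr + 1e-9) + 1
  ks <- seq_len(nrows) - 1
  offs <- (ks %% 2) * s / 2
  sum(pmax(0, floor((a_len - offs) / s + 1e-9) + 1))
}

#' Build the obstacle-element lattice for a geometry
#'
#' Covers every wetted surface a cell can reach - the floor (substrate,
#' raised step floor, ridge tops) and all vertical faces (ridge flanks, the
#' step face) - with a hexagonal lattice of fixed spherical obstacle
#' elements spaced `1 * r_cell` apart. Cells attach to these elements
#' through the same interaction force as to each other, and the dense
#' spacing leaves no straight path of clearance larger than `r_cell`.
#'
#' @param geom a `channel_geometry`.
#' @param p an `ec_params` object.
#' @return an object of class `obstacle_set`: list with `centres`
#'   (`n x 3` matrix, mm) and `element_radius` (mm).
#' @export
build_obstacles <- function(geom, p = model_params()) {
  s <- p$r_cell
  pieces <- list()
  add_floor <- function(x0, x1, y) {
    if (x1 <= x0) return()
    h <- hex_lattice(x1 - x0, geom$width, s)  # a = x, b = z
    pieces[[length(pieces) + 1]] <<- cbind(x0 + h[, 1], y, h[, 2])
  }
  add_face <- function(x, ymax) {
    h <- hex_lattice(geom$width, ymax, s)     # a = z, b = y
    pieces[[length(pieces) + 1]] <<- cbind(x, h[, 2], h[, 1])
  }
  if (is.null(geom$step)) {
    add_floor(0, geom$length, 0)
  } else {
    add_floor(0, geom$step$x, geom$step$height)
    add_face(geom$step$x, geom$step$height)
    add_floor(geom$step$x, geom$length, 0)
  }
  if (!is.null(geom$ridges)) {
    for (i in seq_len(nrow(geom$ridges))) {
      r <- geom$ridges[i, ]
      add_floor(r$x, r$x + r$width, r$height)  # ridge top
      add_face(r$x, r$height)                  # upstream flank
      add_face(r$x + r$width, r$height)        # downstream flank
    }
  }
  centres <- do.call(rbind, pieces)
  dimnames(centres) <- NULL
  obs <- list(centres = centres, element_radius = p$r_cell,
              cache = new.env(parent = emptyenv()))
  class(obs) <- "obstacle_set"
  obs
}

#' @export
print.obstacle_set <- function(x, ...) {
  cat(sprintf("obstacle_set: %d elements, radius %g mm\n",
              nrow(x$centres), x$element_radius))
  invisible(x)
}

# Lazily built, cached C++ spatial index over the obstacle centres.
obstacle_grid <- function(obstacles, binsize = 4 * obstacles$element_radius) {
  cache <- obstacles$cache
  if (is.null(cache$grid) || !cpp_ptr_valid(cache$grid))
    cache$grid <- cpp_point_grid(obstacles$centres, binsize)
  cache$grid
}

#' Seed a hexagonal cell monolayer on the substrate
#'
#' Places cell centres on a hexagonal lattice with nearest-neighbour spacing
#' `spacing` (default `4 * r_cell` = 60 um), at height `r_cell` above the
#' local floor. Rows run spanwise and advance streamwise, so "the leftmost
#' rows" are those with the lowest x; the first `immobile_rows` of them are
#' flagged immobile (they anchor the monolayer at the upstream edge).
#'
#' @param geom a `channel_geometry`.
#' @param p an `ec_params` object.
#' @param region list with `x0`, `x1`, `z0`, `z1` (mm) delimiting the seeded
#'   footprint on the substrate.
#' @param spacing centre spacing (mm).
#' @param immobile_rows number of leftmost rows flagged immobile.
#' @return an object of class `cell_population`: list with `positions`
#'   (`n x 3`), `mobile` (logical), `F_rand` (`n x 3`, zero until the
#'   dynamics draws them).
#' @export
seed_monolayer <- function(geom, p = model_params(), region,
                           spacing = 4 * p$r_cell, immobile_rows = 4) {
  stopifnot(region$x1 > region$x0, region$z1 > region$z0)
  h <- hex_lattice(region$z1 - region$z0, region$x1 - region$x0, spacing)
  if (is.null(h) || nrow(h) == 0) stop("seed_monolayer: empty region")
  x <- region$x0 + h[, 2]
  z <- region$z0 + h[, 1]
  y <- floor_height(geom, x) + p$r_cell
  dr <- spacing * sqrt(3) / 2
  row_id <- round(h[, 2] / dr)
  mobile <- row_id >= immobile_rows
  pop <- list(positions = cbind(x, y, z), mobile = mobile,
              F_rand = matrix(0, nrow = length(x), ncol = 3))
  dimnames(pop$positions) <- NULL
  class(pop) <- "cell_population"
  pop
}

#' @export
print.cell_population <- function(x, ...) {
  cat(sprintf("cell_population: %d cells (%d mobile)\n",
              nrow(x$positions), sum(x$mobile)))
  invisible(x)
}

#' Monolayer confinement check
#'
#' Cell centres must stay within `3 * r_cell` of the nearest obstacle
#' element (the model's stand-in for ECs staying in a monolayer on the
#' substrate). Returns, for each position, whether the band is violated and
#' the correction vector to the nearest admissible point (applied as a hard
#' projection after each accepted integration step).
#'
#' @param pos `n x 3` matrix (or 3-vector) of cell centres, mm.
#' @param obstacles an `obstacle_set`.
#' @param p an `ec_params` object.
#' @return list with `violated` (logical), `dist` (mm), `correction`
#'   (`n x 3`, zero rows where admissible).
#' @export
confinement_violation <- function(pos, obstacles, p = model_params()) {
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 3)
  nn <- cpp_nearest_point(pos, obstacle_grid(obstacles))
  band <- 3 * p$r_cell
  viol <- nn$dist > band
  corr <- matrix(0, nrow(pos), 3)
  if (any(viol)) {
    oc <- obstacles$centres[nn$index[viol], , drop = FALSE]
    d <- nn$dist[viol]
    corr[viol, ] <- (oc + (pos[viol, , drop = FALSE] - oc) * (band / d)) -
      pos[viol, , drop = FALSE]
  }
  list(violated = viol, dist = nn$dist, correction = corr)
}

#' Frictionless side-wall force
#'
#' Zero inside the channel; a purely spanwise (z) restoring force
#' `k_wall * penetration` when a cell centre crosses a side plane. No
#' tangential component, ever (the walls are frictionless).
#'
#' @param pos `n x 3` matrix (or 3-vector) of cell centres, mm.
#' @param geom a `channel_geometry`.
#' @param p an `ec_params` object.
#' @return `n x 3` force matrix (a.u.), nonzero only in the z column.
#' @export
side_wall_force <- function(pos, geom, p = model_params()) {
  single <- is.null(dim(pos))
  if (single) pos <- matrix(pos, ncol = 3)
  fz <- numeric(nrow(pos))
  z <- pos[, 3]
  fz[z < 0] <- p$k_wall * (0 - z[z < 0])
  fz[z > geom$width] <- p$k_wall * (geom$width - z[z > geom$width])
  F <- cbind(0, 0, fz, deparse.level = 0)
  if (single) F[1, ] else F
}

#' Keep cell centres clear of solid surfaces
#'
#' The contact force, at its published scale, is two orders of magnitude
#' weaker than the migration force, so it shapes near-surface motion but
#' cannot by itself make surfaces impenetrable at finite step sizes.
#' Surfaces are therefore also enforced geometrically: after each accepted
#' step, any cell centre closer than `r_cell` to a solid region (substrate,
#' ridge, raised step floor, step face) is pushed out through the face of
#' least penetration. The clearance equals the seeding height, and - with
#' the default parameters - is the height at which the sampled flow cue
#' reaches `v_max`.
#'
#' @param pos `n x 3` matrix of cell centres (mm).
#' @param geom a `channel_geometry`.
#' @param p an `ec_params` object.
#' @return the corrected `n x 3` matrix.
#' @export
project_out_of_solids <- function(pos, geom, p = model_params()) {
  r <- p$r_cell
  x <- pos[, 1]; y <- pos[, 2]
  if (!is.null(geom$ridges)) {
    for (i in seq_len(nrow(geom$ridges))) {
      rd <- geom$ridges[i, ]
      x0 <- rd$x - r; x1 <- rd$x + rd$width + r; ytop <- rd$height + r
      inside <- x > x0 & x < x1 & y < ytop
      if (any(inside)) {
        dl <- x[inside] - x0; drt <- x1 - x[inside]; dtp <- ytop - y[inside]
        pick <- max.col(-cbind(dl, drt, dtp)) # smallest penetration
        xi <- x[inside]; yi <- y[inside]
        xi[pick == 1] <- x0; xi[pick == 2] <- x1; yi[pick == 3] <- ytop
        x[inside] <- xi; y[inside] <- yi
      }
    }
  }
  if (!is.null(geom$step)) {
    x1 <- geom$step$x + r; ytop <- geom$step$height + r
    inside <- x < x1 & y < ytop
    if (any(inside)) {
      drt <- x1 - x[inside]; dtp <- ytop - y[inside]
      pick <- max.col(-cbind(drt, dtp))
      xi <- x[inside]; yi <- y[inside]
      xi[pick == 1] <- x1; yi[pick == 2] <- ytop
      x[inside] <- xi; y[inside] <- yi
    }
  }
  y <- pmax(y, r) # base substrate
  cbind(x, y, pos[, 3], deparse.level = 0)
}

#' Export obstacle centres as CSV
#'
#' Writes `x,y,z,radius` rows for visualization.
#' @param obstacles an `obstacle_set`.
#' @param path output file.
#' @export
write_obstacles_csv <- function(obstacles, path) {
  df <- data.frame(x = obstacles$centres[, 1], y = obstacles$centres[, 2],
                   z = obstacles$centres[, 3], radius = obstacles$element_radius)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
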