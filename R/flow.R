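#' Steady channel flow field
#'
#' Solves the steady incompressible flow in the x-y plane of a channel
#' geometry (extruded uniformly across z) and returns it as a gridded
#' `flow_field`. For `kind = "flat"` geometries the analytic Poiseuille
#' profile is returned directly (the solver can be forced with
#' `method = "lb"`); ridged and backward-step geometries use the built-in
#' D2Q9 BGK lattice-Boltzmann solver with full-way bounce-back on walls, a
#' parabolic velocity inlet and a zero-gradient outlet, iterated until the
#' maximum relative velocity change per `check_every` steps drops below
#' `tol`.
#'
#' Grid layout: nodes at integer multiples of `delta` in x and y, with
#' on-node solid walls, so the first fluid node sits a distance `delta`
#' from the wall surface (this is the convention under which the first-node
#' wall-shear-stress estimate `nu * v / delta` is applied).
#'
#' The default inflow follows the model's calibration rule: the peak inlet
#' speed is the one for which, in the unobstructed (flat) channel of the
#' same height, the parabola at the first fluid node (height `delta` above
#' the wall) equals `v_max` - placing the first-node wall-shear-stress
#' estimate at its physiological ceiling (2.4 Pa with the default
#' parameters). The same peak speed is prescribed at the inlet opening of
#' ridged and backward-step geometries.
#'
#' @param geom a `channel_geometry`.
#' @param p an `ec_params` object.
#' @param inflow peak inlet speed (m/s); `NULL` for the calibration default.
#' @param method `"auto"` (analytic for flat, LB otherwise), `"lb"`, or
#'   `"analytic"` (flat only).
#' @param delta lattice spacing (mm).
#' @param tol convergence tolerance on the relative velocity change.
#' @param max_iter iteration budget; non-convergence is an error reporting
#'   the residual.
#' @param check_every convergence-check interval (LB steps).
#' @param rho_fluid fluid density (kg/m^3), used only for unit conversion
#'   and Reynolds reporting.
#' @return an object of class `flow_field`: node coordinates `x`, `y` (mm),
#'   velocity matrices `ux`, `uy` (m/s, `nx x ny`), logical solid `mask`,
#'   `delta`, `origin`, and solver metadata in `meta`.
#' @export
solve_channel_flow <- function(geom, p = model_params(), inflow = NULL,
                               method = c("auto", "lb", "analytic"),
                               delta = p$delta, tol = 1e-7,
                               max_iter = 500000L, check_every = 100L,
                               rho_fluid = 1000) {
  method <- match.arg(method)
  if (method == "auto") method <- if (geom$kind == "flat") "analytic" else "lb"
  if (method == "analytic" && geom$kind != "flat")
    stop("analytic profile is only available for flat channels")
  if (is.null(inflow)) inflow <- default_inflow(geom, p, delta)

  nx <- round(geom$length / delta) + 1L
  ny <- round(geom$height / delta) + 1L
  x <- (seq_len(nx) - 1) * delta
  y <- (seq_len(ny) - 1) * delta
  fl <- floor_height(geom, x)
  mask <- outer(fl, y, function(f, yy) yy <= f + 1e-12) # raised floors + substrate
  mask[, ny] <- TRUE                                    # top wall

  inlet_h <- geom$height - fl[1]
  profile <- function(yy, f, h, U) {
    s <- (yy - f) / h
    ifelse(s > 0 & s < 1, 4 * U * s * (1 - s), 0)
  }

  if (method == "analytic") {
    ux <- outer(rep(1, nx), profile(y, 0, geom$height, inflow))
    ux[mask] <- 0
    uy <- matrix(0, nx, ny)
    meta <- list(method = "analytic", inflow_peak = inflow, converged = TRUE,
                 iterations = 0L, residual = 0)
  } else {
    if (inflow <= 0) stop("LB solver needs a positive inflow")
    # lattice-unit conversion: Mach cap u_lb <= 0.05, with tau kept >= 0.52
    dx_m <- delta * 1e-3
    nu_kin <- p$nu_dyn / rho_fluid
    dt <- 0.05 * dx_m / inflow
    nu_lb <- nu_kin * dt / dx_m^2
    if (0.5 + 3 * nu_lb < 0.52) {
      dt <- (0.02 / 3) * dx_m^2 / nu_kin
      nu_lb <- 0.02 / 3
    }
    tau <- 0.5 + 3 * nu_lb
    cu <- dx_m / dt # m/s per lattice unit
    inlet_lb <- profile(y, fl[1], inlet_h, inflow) / cu
    inlet_lb[mask[1, ]] <- 0
    # initial guess: per-column flux-matched parabola on the local opening
    q_in <- sum(inlet_lb) # lattice flux (per unit delta)
    init <- matrix(0, nx, ny)
    for (i in seq_len(nx)) {
      h_c <- geom$height - fl[i]
      u_c <- 1.5 * q_in * delta / h_c # peak = 1.5 * mean
      init[i, ] <- profile(y, fl[i], h_c, u_c)
    }
    init[mask] <- 0
    res <- cpp_lb_solve(mask, inlet_lb, init, tau, tol,
                        as.integer(max_iter), as.integer(check_every))
    if (!res$converged)
      stop(sprintf(
        "LB solver did not converge: residual %.3e after %d iterations (tol %.1e)",
        res$residual, res$iterations, tol))
    ux <- res$ux * cu
    uy <- res$uy * cu
    rho_lattice <- res$rho
    meta <- list(method = "lb", inflow_peak = inflow, tau = tau, dt_s = dt,
                 u_lb_max = max(abs(inlet_lb)), iterations = res$iterations,
                 residual = res$residual, converged = TRUE,
                 reynolds_inlet = rho_fluid * (2 / 3) * inflow * (inlet_h * 1e-3) / p$nu_dyn)
  }
  ff <- list(x = x, y = y, ux = ux, uy = uy, mask = mask,
             delta = delta, origin = c(0, 0),
             rho_lattice = if (exists("rho_lattice", inherits = FALSE)) rho_lattice else NULL,
             geom_kind = geom$kind, meta = meta)
  class(ff) <- "flow_field"
  ff
}

#' @rdname solve_channel_flow
#' @export
default_inflow <- function(geom, p = model_params(), delta = p$delta) {
  # calibration anchor: the inlet parabola at the first fluid node (delta
  # above the wall) equals v_max. All default geometries share a 0.5 mm
  # inlet opening, so this is one peak speed (0.309 m/s) for every scenario.
  h_in <- geom$height - floor_height(geom, 0)
  s <- delta / h_in
  p$v_max / (4 * s * (1 - s))
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("flow_field [%s/%s]: %d x %d nodes, delta %g mm, max |u| %.4g m/s\n",
              x$geom_kind, x$meta$method, length(x$x), length(x$y), x$delta,
              max(abs(x$ux))))
  invisible(x)
}

#' Sample the flow velocity at cell positions
#'
#' Bilinear interpolation in the x-y plane, constant across z. Solid nodes
#' carry zero velocity, so the interpolant tapers to zero at walls and
#' vanishes inside solids. Positions outside the grid are an error.
#'
#' @param field a `flow_field`.
#' @param pos `n x 3` matrix (or 3-vector) of positions, mm.
#' @return `n x 3` matrix of velocities (m/s); the z component is 0.
#' @export
sample_velocity <- function(field, pos) {
  single <- is.null(dim(pos))
  if (single) pos <- matrix(pos, ncol = 3)
  px <- pos[, 1]; py <- pos[, 2]
  nx <- length(field$x); ny <- length(field$y)
  eps <- 1e-9
  if (any(px < field$x[1] - eps | px > field$x[nx] + eps |
          py < field$y[1] - eps | py > field$y[ny] + eps))
    stop("sample_velocity: position outside the flow domain")
  d <- field$delta
  i <- pmin(pmax(floor((px - field$x[1]) / d) + 1, 1), nx - 1)
  j <- pmin(pmax(floor((py - field$y[1]) / d) + 1, 1), ny - 1)
  fx <- pmin(pmax((px - field$x[i]) / d, 0), 1)
  fy <- pmin(pmax((py - field$y[j]) / d, 0), 1)
  idx <- cbind(i, j)
  bil <- function(M) {
    M[idx] * (1 - fx) * (1 - fy) + M[cbind(i + 1, j)] * fx * (1 - fy) +
      M[cbind(i, j + 1)] * (1 - fx) * fy + M[cbind(i + 1, j + 1)] * fx * fy
  }
  V <- cbind(bil(field$ux), bil(field$uy), 0)
  if (single) V[1, ] else V
}

#' First-node wall shear stress
#'
#' The model's wall-shear-stress estimate: at each bottom-wall location the
#' tangential speed at the first fluid node above the local floor, times the
#' dynamic viscosity, divided by the lattice spacing
#' (`WSS = nu * |u_first| / delta`). With `nu = 1e-3` Pa s,
#' `u = 0.036` m/s and `delta = 0.015` mm this gives the 2.4 Pa ceiling.
#'
#' @param field a `flow_field`.
#' @param p an `ec_params` object (supplies `nu_dyn`).
#' @return data.frame with `x` (mm), `y_node` (mm, first fluid node) and
#'   `wss` (Pa, non-negative).
#' @export
wall_shear_stress <- function(field, p = model_params()) {
  nw <- near_wall_profile(field)
  data.frame(x = nw$x, y_node = nw$y,
             wss = p$nu_dyn * abs(nw$ux) / (field$delta * 1e-3))
}

# streamwise velocity at the first fluid node above the local floor
near_wall_profile <- function(field) {
  nx <- length(field$x)
  xo <- numeric(0); yo <- numeric(0); uo <- numeric(0)
  for (i in seq_len(nx)) {
    j <- which(!field$mask[i, ])[1]
    if (is.na(j)) next
    xo <- c(xo, field$x[i]); yo <- c(yo, field$y[j]); uo <- c(uo, field$ux[i, j])
  }
  list(x = xo, y = yo, ux = uo)
}

#' Streamwise mass-flux profile
#'
#' Mass flux through each cross-section (sum of `rho * ux` over fluid
#' nodes, times the lattice spacing); `rho` is the lattice density where
#' the LB solver supplied it, 1 otherwise. In the weakly compressible LB
#' solution this - not the bare velocity flux - is the conserved quantity.
#'
#' @param field a `flow_field`.
#' @return data.frame with `x` (mm) and `flux` (m/s * mm per unit width).
#' @export
cross_section_flux <- function(field) {
  nx <- length(field$x)
  rho <- if (is.null(field$rho_lattice)) matrix(1, nx, length(field$y)) else field$rho_lattice
  flux <- vapply(seq_len(nx), function(i) {
    open <- !field$mask[i, ]
    sum(rho[i, open] * field$ux[i, open]) * field$delta
  }, numeric(1))
  data.frame(x = field$x, flux = flux)
}

#' Recirculation zones along the bottom wall
#'
#' Maximal streamwise intervals where the near-wall streamwise velocity
#' (first fluid node above the local floor) is negative. The downstream end
#' of each interval is the reattachment point.
#'
#' @param field a `flow_field`.
#' @return data.frame with `x_start`, `x_end` (mm); zero rows when the flow
#'   is everywhere attached.
#' @export
recirculation_zones <- function(field) {
  nw <- near_wall_profile(field)
  neg <- nw$ux < 0
  out <- data.frame(x_start = numeric(0), x_end = numeric(0))
  if (!any(neg)) return(out)
  r <- rle(neg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    out <- rbind(out, data.frame(x_start = nw$x[starts[k]], x_end = nw$x[ends[k]]))
  }
  out
}

#' Write / read a gridded flow field as plain CSV
#'
#' A text header (`# key=value` lines: delta, origin, dimensions, geometry
#' kind) followed by `x_index,y_index,ux,uy,mask` rows at full precision,
#' so node values round-trip bit-exactly.
#'
#' @param field a `flow_field`.
#' @param path file path.
#' @export
write_flow_field <- function(field, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# delta=%.17g", field$delta),
    sprintf("# origin=%.17g,%.17g", field$origin[1], field$origin[2]),
    sprintf("# nx=%d", length(field$x)),
    sprintf("# ny=%d", length(field$y)),
    sprintf("# kind=%s", field$geom_kind),
    "x_index,y_index,ux,uy,mask"), con)
  nx <- length(field$x); ny <- length(field$y)
  ij <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  writeLines(sprintf("%d,%d,%.17g,%.17g,%d", ij$i, ij$j,
                     field$ux[cbind(ij$i, ij$j)], field$uy[cbind(ij$i, ij$j)],
                     as.integer(field$mask[cbind(ij$i, ij$j)])), con)
  invisible(path)
}

#' @rdname write_flow_field
#' @export
read_flow_field <- function(path) {
  lines <- readLines(path, n = 20)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) sub(sprintf("^# %s=", key), "", hdr[grepl(paste0("^# ", key, "="), hdr)])
  delta <- as.numeric(get("delta"))
  origin <- as.numeric(strsplit(get("origin"), ",")[[1]])
  nx <- as.integer(get("nx")); ny <- as.integer(get("ny"))
  kind <- get("kind")
  df <- read.csv(path, skip = length(hdr), header = TRUE)
  ux <- matrix(0, nx, ny); uy <- matrix(0, nx, ny); mask <- matrix(FALSE, nx, ny)
  idx <- cbind(df$x_index, df$y_index)
  ux[idx] <- df$ux; uy[idx] <- df$uy; mask[idx] <- df$mask == 1
  ff <- list(x = origin[1] + (seq_len(nx) - 1) * delta,
             y = origin[2] + (seq_len(ny) - 1) * delta,
             ux = ux, uy = uy, mask = mask, delta = delta, origin = origin,
             geom_kind = kind, meta = list(method = "file", converged = TRUE))
  class(ff) <- "flow_field"
  ff
}
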