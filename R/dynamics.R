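#' Create a simulation state
#'
#' Bundles the evolving quantities of a run: simulation time (hours), the
#' cell population (positions, mobility flags, per-cell persistent random
#' forces) and the current adaptive step size.
#'
#' @param population a `cell_population`.
#' @param time simulation time (h).
#' @param dt current step size (h).
#' @return an object of class `simulation_state`.
#' @export
simulation_state <- function(population, time = 0, dt = 0.01) {
  st <- list(time = time, population = population, dt = dt)
  class(st) <- "simulation_state"
  st
}

#' Refresh persistent random forces
#'
#' Each mobile cell independently replaces its random force with a fresh
#' draw with probability `1 - exp(-p_change * dt)` (the exact exponential
#' form, so results are step-size independent); otherwise it keeps the
#' current one. The mean persistence (holding) time is `1 / p_change`.
#'
#' @param state a `simulation_state`.
#' @param p an `ec_params` object.
#' @param dt elapsed time (h); must satisfy `p_change * dt < 0.1` so single
#'   refreshes per interval dominate.
#' @return the updated `simulation_state`.
#' @export
refresh_random_forces <- function(state, p, dt) {
  if (dt <= 0) stop("refresh_random_forces: dt must be > 0")
  if (p$p_change * dt >= 0.1)
    stop("refresh_random_forces: step too large (p_change * dt must be < 0.1)")
  if (p$p_change == 0) return(state)
  pop <- state$population
  prob <- 1 - exp(-p$p_change * dt)
  hit <- pop$mobile & (runif(nrow(pop$positions)) < prob)
  if (any(hit)) {
    pop$F_rand[hit, ] <- sample_random_force(sum(hit), p)
    state$population <- pop
  }
  state
}

#' Overdamped cell velocities (right-hand side of the equation of motion)
#'
#' Velocity of each mobile cell is `mobility * F_total`, with
#' `F_total = F_migr + sum of pairwise interaction forces + side-wall
#' force`; immobile cells have zero velocity. The migration force redirects
#' the persistent random force along the blend of its own direction and the
#' local flow direction (weighted by [velocity_weight()]); where the local
#' flow speed vanishes the cell performs a pure persistent random walk.
#'
#' @param positions `n x 3` matrix of cell centres (mm).
#' @param F_rand `n x 3` matrix of persistent random forces (a.u.).
#' @param mobile logical vector.
#' @param obstacles an `obstacle_set` (or NULL).
#' @param flow a `flow_field` (or NULL for no flow).
#' @param geom a `channel_geometry` (or NULL to skip side walls).
#' @param p an `ec_params` object.
#' @return list with `V` (`n x 3`, mm/h), `degenerate` (indices whose
#'   blended direction collapsed below 1e-12 and whose random force must be
#'   resampled) and `coincident` (indices involved in coincident pairs).
#' @export
cell_velocities <- function(positions, F_rand, mobile, obstacles = NULL,
                            flow = NULL, geom = NULL, p = model_params()) {
  n <- nrow(positions)
  nF <- sqrt(rowSums(F_rand^2))
  e_rand <- F_rand / pmax(nF, 1e-300)

  if (!is.null(flow)) {
    # substep positions can overshoot the grid slightly; the cue is taken
    # at the nearest in-domain point
    spos <- positions
    nxg <- length(flow$x); nyg <- length(flow$y)
    spos[, 1] <- pmin(pmax(spos[, 1], flow$x[1]), flow$x[nxg])
    spos[, 2] <- pmin(pmax(spos[, 2], flow$y[1]), flow$y[nyg])
    v <- sample_velocity(flow, spos)
    speed <- sqrt(rowSums(v^2))
    has_flow <- speed > 1e-12
    w <- velocity_weight(speed, p)
    e_vel <- v / pmax(speed, 1e-300)
    d <- e_rand * (1 - w) + e_vel * w
    d[!has_flow, ] <- e_rand[!has_flow, ]
  } else {
    d <- e_rand
  }
  nd <- sqrt(rowSums(d^2))
  degenerate <- which(mobile & nd < 1e-12)
  safe_nd <- pmax(nd, 1e-300)
  F_migr <- (nF / safe_nd) * d

  Fint <- interaction_forces(positions, obstacles, p)
  coincident <- attr(Fint, "coincident")
  Ftot <- F_migr + Fint
  if (!is.null(geom)) Ftot <- Ftot + side_wall_force(positions, geom, p)

  V <- p$mobility * Ftot
  V[!mobile, ] <- 0
  bad <- which(!is.finite(rowSums(V)))
  if (length(bad))
    stop(sprintf("cell_velocities: non-finite force for cell(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  list(V = V, degenerate = degenerate, coincident = coincident)
}

# one classical RK4 step of the position ODE dx/dt = v(x)
rk4_step <- function(pos, dt, vfun) {
  k1 <- vfun(pos)
  k2 <- vfun(pos + dt / 2 * k1)
  k3 <- vfun(pos + dt / 2 * k2)
  k4 <- vfun(pos + dt * k3)
  pos + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Advance the state by one adaptive RK4 step
#'
#' Classical Runge-Kutta 4 with step-doubling error control: one full step
#' is compared against two half steps and accepted when the largest
#' per-cell position discrepancy is below `tol_abs`; the more accurate
#' two-half-step result is kept. The step size adapts by the standard
#' 4th-order factor and stays in `[dt_min, dt_max]`. The persistent random
#' force is held fixed within the step (forces and the flow cue are
#' re-evaluated at substep positions). After acceptance, the monolayer
#' confinement projection and the side-wall containment are applied.
#'
#' Degenerate blended directions (random force exactly opposing the flow
#' cue) trigger a resample of that cell's random force; coincident cell
#' centres are perturbed by `1e-6 * r_cell` in a random direction.
#'
#' @param state a `simulation_state`.
#' @param flow a `flow_field` or NULL.
#' @param obstacles an `obstacle_set` or NULL.
#' @param geom a `channel_geometry` or NULL.
#' @param p an `ec_params` object.
#' @param dt_try step size to attempt (h); defaults to the state's.
#' @param tol_abs step-doubling position tolerance (mm).
#' @param dt_min,dt_max step-size clamps (h).
#' @return list with the advanced `state` (its `dt` is the proposed next
#'   step) and `dt_used`, the accepted step (h).
#' @export
step_rk4_adaptive <- function(state, flow = NULL, obstacles = NULL,
                              geom = NULL, p = model_params(),
                              dt_try = state$dt, tol_abs = 1e-5,
                              dt_min = 1e-5, dt_max = 0.05) {
  pop <- state$population
  dt <- min(max(dt_try, dt_min), dt_max)

  # resolve degenerate directions / coincident centres before integrating
  for (guard in 1:10) {
    probe <- cell_velocities(pop$positions, pop$F_rand, pop$mobile,
                             obstacles, flow, geom, p)
    fixed <- TRUE
    if (length(probe$degenerate)) {
      pop$F_rand[probe$degenerate, ] <- sample_random_force(length(probe$degenerate), p)
      fixed <- FALSE
    }
    if (length(probe$coincident)) {
      idx <- probe$coincident[pop$mobile[probe$coincident]]
      if (length(idx)) {
        dirs <- matrix(rnorm(3 * length(idx)), ncol = 3)
        dirs <- dirs / sqrt(rowSums(dirs^2))
        pop$positions[idx, ] <- pop$positions[idx, ] + 1e-6 * p$r_cell * dirs
        fixed <- FALSE
      }
    }
    if (fixed) break
  }

  vfun <- function(pos) cell_velocities(pos, pop$F_rand, pop$mobile,
                                        obstacles, flow, geom, p)$V
  repeat {
    full <- rk4_step(pop$positions, dt, vfun)
    h1 <- rk4_step(pop$positions, dt / 2, vfun)
    h2 <- rk4_step(h1, dt / 2, vfun)
    err <- sqrt(max(rowSums((full - h2)^2)))
    if (err < tol_abs) break
    if (dt <= dt_min)
      stop(sprintf(
        "step_rk4_adaptive: step-size underflow (err %.3e mm at dt = %g h)",
        err, dt))
    dt <- max(dt * max(0.2, 0.9 * (tol_abs / err)^0.25), dt_min)
  }
  pop$positions <- h2
  # post-step handling: impenetrable surfaces, confinement band, side walls
  if (!is.null(geom)) {
    newp <- project_out_of_solids(pop$positions[pop$mobile, , drop = FALSE], geom, p)
    pop$positions[pop$mobile, ] <- newp
  }
  if (!is.null(obstacles)) {
    cv <- confinement_violation(pop$positions, obstacles, p)
    if (any(cv$violated & pop$mobile)) {
      fix <- cv$violated & pop$mobile
      pop$positions[fix, ] <- pop$positions[fix, ] + cv$correction[fix, ]
    }
  }
  if (!is.null(geom)) {
    z <- pop$positions[, 3]
    pop$positions[, 3] <- pmin(pmax(z, 0), geom$width)
  }

  grow <- if (err > 0) min(2, 0.9 * (tol_abs / err)^0.2) else 2
  state$population <- pop
  state$time <- state$time + dt
  state$dt <- min(max(dt * grow, dt_min), dt_max)
  list(state = state, dt_used = dt)
}

#' Run a cell-migration simulation
#'
#' Seeds the RNG, draws the initial persistent random forces, and advances
#' the population with adaptive RK4 steps, refreshing random forces after
#' each accepted step and recording all positions at every output interval.
#' Fully reproducible given the same inputs and seed.
#'
#' @param geom a `channel_geometry`.
#' @param obstacles an `obstacle_set` (use [build_obstacles()]).
#' @param flow a `flow_field` or NULL (no flow).
#' @param population a `cell_population` (use [seed_monolayer()]).
#' @param p an `ec_params` object.
#' @param hours duration (h); 0 returns the seeding as a single frame.
#' @param seed RNG seed (integer).
#' @param output_interval frame spacing (h).
#' @param tol_abs,dt_min,dt_max integrator controls (see
#'   [step_rk4_adaptive()]).
#' @param resume a `simulation_state` from a previous run's `$final_state`
#'   to continue from (checkpoint/restart); `seed` is ignored and the
#'   stored RNG state is restored.
#' @return an object of class `ec_trajectory`: `times` (h), `pos`
#'   (`n x 3 x T` array, mm), `mobile`, the parameter set, geometry, seed,
#'   and `final_state` (with the terminal RNG state) for restarts.
#' @export
run_simulation <- function(geom, obstacles, flow, population,
                           p = model_params(), hours, seed = 1,
                           output_interval = 0.1, tol_abs = 1e-5,
                           dt_min = 1e-5, dt_max = 0.05,
                           resume = NULL) {
  if (!is.null(resume)) {
    st <- resume
    assign(".Random.seed", st$rng, envir = globalenv())
  } else {
    set.seed(as.integer(seed))
    pop <- population
    pop$F_rand <- sample_random_force(nrow(pop$positions), p)
    st <- simulation_state(pop, time = 0, dt = dt_max)
  }
  t0 <- st$time
  times <- t0 + seq(0, hours, by = output_interval)
  if (abs(times[length(times)] - (t0 + hours)) > 1e-9)
    times <- c(times, t0 + hours)
  n <- nrow(st$population$positions)
  posarr <- array(NA_real_, dim = c(n, 3, length(times)))
  posarr[, , 1] <- st$population$positions

  for (fi in seq_along(times)[-1]) {
    target <- times[fi]
    while (st$time < target - 1e-12) {
      dt_try <- min(st$dt, target - st$time)
      res <- step_rk4_adaptive(st, flow, obstacles, geom, p,
                               dt_try = dt_try, tol_abs = tol_abs,
                               dt_min = dt_min, dt_max = dt_max)
      st <- res$state
      st <- refresh_random_forces(st, p, res$dt_used)
    }
    posarr[, , fi] <- st$population$positions
  }
  st$rng <- get(".Random.seed", envir = globalenv())
  traj <- list(times = times, pos = posarr, mobile = st$population$mobile,
               params = p, geom = geom, seed = if (is.null(resume)) seed else NA,
               final_state = st)
  class(traj) <- "ec_trajectory"
  traj
}

#' @export
print.ec_trajectory <- function(x, ...) {
  cat(sprintf("ec_trajectory: %d cells (%d mobile), %d frames over %.2f h\n",
              dim(x$pos)[1], sum(x$mobile), length(x$times),
              x$times[length(x$times)] - x$times[1]))
  invisible(x)
}

#' Write / read a trajectory as CSV
#'
#' Header metadata lines (`# key=value`: seed, geometry kind, dimensions)
#' followed by `time_h,cell_id,x_mm,y_mm,z_mm,mobile` rows at full
#' precision.
#'
#' @param traj an `ec_trajectory`.
#' @param path file path.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  g <- traj$geom
  writeLines(c(
    sprintf("# seed=%s", traj$seed),
    sprintf("# geometry=%s,%.17g,%.17g,%.17g", g$kind, g$length, g$height, g$width),
    "time_h,cell_id,x_mm,y_mm,z_mm,mobile"), con)
  n <- dim(traj$pos)[1]
  for (fi in seq_along(traj$times)) {
    writeLines(sprintf("%.17g,%d,%.17g,%.17g,%.17g,%d",
                       traj$times[fi], seq_len(n),
                       traj$pos[, 1, fi], traj$pos[, 2, fi], traj$pos[, 3, fi],
                       as.integer(traj$mobile)), con)
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path, n = 10)
  hdr <- lines[startsWith(lines, "#")]
  df <- read.csv(path, skip = length(hdr), header = TRUE)
  times <- sort(unique(df$time_h))
  ids <- sort(unique(df$cell_id))
  n <- length(ids)
  posarr <- array(NA_real_, dim = c(n, 3, length(times)))
  mobile <- logical(n)
  for (fi in seq_along(times)) {
    sub <- df[df$time_h == times[fi], ]
    sub <- sub[order(sub$cell_id), ]
    posarr[, , fi] <- as.matrix(sub[, c("x_mm", "y_mm", "z_mm")])
    if (fi == 1) mobile <- sub$mobile == 1
  }
  seed <- sub("^# seed=", "", hdr[grepl("^# seed=", hdr)])
  traj <- list(times = times, pos = posarr, mobile = mobile,
               params = NULL, geom = NULL,
               seed = suppressWarnings(as.integer(seed)), final_state = NULL)
  class(traj) <- "ec_trajectory"
  traj
}
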