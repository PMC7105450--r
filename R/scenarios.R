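#' Scenario configuration
#'
#' Resolves one of the four built-in experiments to a complete, validated
#' configuration: `flat_calibration` (undisturbed flow, the calibration
#' setting for the migration speed), `ridged` (three stent-strut ridges),
#' `ridged_rock` (same with the flow-cue floor `w_min` lowered 0.3 -> 0.05,
#' modelling ROCK inhibition) and `backward_step` (cells seeded downstream
#' of a backward-facing step, 48 h). Every parameter can be overridden;
#' the resolved configuration is serialized alongside outputs.
#'
#' @param scenario one of `"flat_calibration"`, `"ridged"`, `"ridged_rock"`,
#'   `"backward_step"`.
#' @param hours duration; defaults: 24 h (flat, ridged, ROCK), 48 h (step).
#' @param seed RNG seed.
#' @param params named list of [model_params()] overrides.
#' @param geometry named list of geometry-constructor overrides.
#' @param region seeded-region override (list `x0`, `x1`, `z0`, `z1`, mm).
#' @param immobile_rows override of the number of anchored upstream rows.
#' @param output_interval trajectory frame spacing (h).
#' @param inflow peak inlet speed override (m/s); `NULL` = calibration rule.
#' @param out_dir output directory or NULL.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("flat_calibration", "ridged",
                                         "ridged_rock", "backward_step"),
                            hours = NULL, seed = 1, params = list(),
                            geometry = list(), region = NULL,
                            immobile_rows = NULL, output_interval = 0.1,
                            inflow = NULL, out_dir = NULL) {
  scenario <- match.arg(scenario)
  if (scenario == "ridged_rock" && is.null(params$w_min)) params$w_min <- 0.05
  p <- do.call(model_params, params)

  geom <- switch(scenario,
    flat_calibration = do.call(flat_channel, geometry),
    ridged = ,
    ridged_rock = do.call(ridged_channel, geometry),
    backward_step = do.call(step_channel, geometry))

  zin <- 2 * p$r_cell # spanwise inset keeps the seeded sheet off the side walls
  if (is.null(region)) {
    region <- switch(scenario,
      flat_calibration = list(x0 = 1.5, x1 = 3.5, z0 = zin, z1 = geom$width - zin),
      ridged = ,
      ridged_rock = list(x0 = geom$ridges$x[1] - 2, x1 = geom$ridges$x[1],
                         z0 = zin, z1 = geom$width - zin),
      backward_step = list(x0 = geom$step$x + 2 * p$r_cell, x1 = geom$step$x + 3.5,
                           z0 = zin, z1 = geom$width - zin))
  }
  if (is.null(immobile_rows))
    immobile_rows <- if (scenario == "backward_step") 0L else 4L
  if (is.null(hours)) hours <- if (scenario == "backward_step") 48 else 24

  cfg <- list(scenario = scenario, params = p, geometry = geom,
              region = region, immobile_rows = immobile_rows,
              hours = hours, seed = as.integer(seed),
              output_interval = output_interval, inflow = inflow,
              out_dir = out_dir)
  class(cfg) <- "scenario_config"
  cfg$hash <- config_hash(cfg)
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("scenario_config [%s]: %g h, seed %d, hash %s\n",
              x$scenario, x$hours, x$seed, x$hash))
  print(x$geometry)
  cat(sprintf("  seeded region x [%g, %g], z [%g, %g] mm; %d immobile rows\n",
              x$region$x0, x$region$x1, x$region$z0, x$region$z1,
              x$immobile_rows))
  invisible(x)
}

# FNV-1a (32-bit) over the canonical deparse of the configuration;
# multiplication done in 16-bit halves to stay exact in doubles.
config_hash <- function(cfg) {
  core <- cfg[c("scenario", "region", "immobile_rows", "hours",
                "output_interval", "inflow")]
  core$params <- unclass(cfg$params)
  core$geometry <- unclass(cfg$geometry)
  s <- paste(deparse(core), collapse = "")
  h <- 2166136261
  m <- 16777619
  for (b in utf8ToInt(s)) {
    h <- bitwXor_num(h %% 2^32, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- ((lo * m) %% 2^32 + ((hi * m) %% 65536) * 65536) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31)) # printable; low 31 bits
}

# numeric XOR for values up to 2^32 (bitwXor is integer-only)
bitwXor_num <- function(a, b) {
  r <- 0
  p <- 1
  for (k in 1:32) {
    r <- r + p * as.numeric(xor(a %% 2 >= 1, b %% 2 >= 1))
    a <- a %/% 2
    b <- b %/% 2
    p <- p * 2
    if (a == 0 && b == 0) break
  }
  r
}

#' Run a full scenario
#'
#' End-to-end runner: solves (or accepts) the flow field, builds the
#' obstacle lattice, seeds the monolayer, runs the dynamics, computes the
#' standard readouts (mean migration speed, angular distribution, axial
#' distribution, and - where applicable - recirculation entrapment and the
#' density-minimum location) and optionally writes all artifacts to
#' `cfg$out_dir`. Every stage error is labelled with its stage.
#'
#' @param cfg a `scenario_config`.
#' @param flow optional precomputed `flow_field` (e.g. reused across
#'   seeds); solved from the geometry when NULL.
#' @param quiet suppress progress messages.
#' @return list with `config`, `flow`, `obstacles`, `trajectory` and
#'   `stats` (named list of analysis results).
#' @export
run_scenario <- function(cfg, flow = NULL, quiet = TRUE) {
  stage <- function(name, expr) {
    if (!quiet) message(sprintf("[%s] %s ...", format(Sys.time(), "%H:%M:%S"), name))
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  }
  p <- cfg$params
  geom <- cfg$geometry

  flow <- stage("flow", {
    if (is.null(flow)) solve_channel_flow(geom, p, inflow = cfg$inflow) else flow
  })
  obstacles <- stage("obstacles", build_obstacles(geom, p))
  pop <- stage("seeding",
    seed_monolayer(geom, p, cfg$region, immobile_rows = cfg$immobile_rows))
  traj <- stage("dynamics",
    run_simulation(geom, obstacles, flow, pop, p, hours = cfg$hours,
                   seed = cfg$seed, output_interval = cfg$output_interval))

  stats <- stage("analysis", {
    s <- list()
    s$speed <- mean_migration_speed(traj)
    if (cfg$scenario %in% c("ridged", "ridged_rock")) {
      trail <- geom$ridges$x[1] + geom$ridges$width[1]
      s$angular <- angular_distribution(traj, downstream_of = trail)
      s$axial <- axial_distribution(traj, origin = trail + 0.05)
      rz <- recirculation_zones(flow)
      rz <- rz[rz$x_start >= trail - 1e-9, , drop = FALSE]
      if (nrow(rz) > 0) {
        s$recirculation <- rz
        s$entrapment <- entrapment_count(traj, c(rz$x_start[1], rz$x_end[1]))
      }
    } else if (cfg$scenario == "backward_step") {
      s$angular <- angular_distribution(traj)
      s$axial <- axial_distribution(traj, origin = geom$step$x)
      s$density_minimum_mm <- density_minimum_location(
        s$axial, interval = c(0.1, cfg$region$x1 - geom$step$x - 0.5))
      s$recirculation <- recirculation_zones(flow)
    } else {
      s$angular <- angular_distribution(traj)
      s$axial <- axial_distribution(traj)
    }
    s
  })

  if (!is.null(cfg$out_dir)) stage("outputs", {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    o <- function(f) file.path(cfg$out_dir, f)
    write_trajectory(traj, o("trajectory.csv"))
    write_flow_field(flow, o("flow_field.csv"))
    write_obstacles_csv(obstacles, o("obstacles.csv"))
    write_scenario_config(cfg, o("config.yaml"))
    ang <- stats$angular$bins
    ang$config_hash <- cfg$hash; ang$seed <- cfg$seed
    write.csv(ang, o("angular.csv"), row.names = FALSE)
    ax <- as.data.frame(stats$axial)
    ax$config_hash <- cfg$hash; ax$seed <- cfg$seed
    write.csv(ax, o("axial.csv"), row.names = FALSE)
    sp <- data.frame(mean_umh = stats$speed$mean_umh, se_umh = stats$speed$se_umh,
                     n = stats$speed$n, config_hash = cfg$hash, seed = cfg$seed)
    write.csv(sp, o("speed.csv"), row.names = FALSE)
  })

  list(config = cfg, flow = flow, obstacles = obstacles,
       trajectory = traj, stats = stats)
}

#' Calibration sweep over the random-force refresh rate
#'
#' Runs the flat-channel scenario for each refresh rate (several replicate
#' seeds each) and tabulates the calibration readouts: mean path-length
#' migration speed and the circular spread of displacement angles. No
#' automatic "best" selection is made - the table is the deliverable.
#'
#' @param rates vector of `p_change` values (per hour).
#' @param reps replicate seeds per rate.
#' @param seed base seed; replicate r of rate i uses `seed + 1000*i + r`.
#' @param hours simulated duration per run.
#' @param cfg_args extra arguments passed to [scenario_config()].
#' @return data.frame with one row per rate: `p_change`, `mean_speed_umh`,
#'   `se_speed_umh` (across replicates), `angular_spread_deg`, `n_reps`;
#'   per-replicate rows in `attr(, "replicates")`.
#' @export
calibrate_p_change <- function(rates, reps = 3, seed = 1, hours = 24,
                               cfg_args = list()) {
  if (!length(rates)) stop("calibrate_p_change: empty rate grid")
  flow <- NULL
  rows <- list()
  for (i in seq_along(rates)) {
    for (r in seq_len(reps)) {
      cfg <- do.call(scenario_config, c(list(
        scenario = "flat_calibration", hours = hours,
        seed = seed + 1000 * i + r,
        params = list(p_change = rates[i])), cfg_args))
      res <- run_scenario(cfg, flow = flow)
      flow <- res$flow # identical across runs; reuse
      ang <- res$stats$angular
      rows[[length(rows) + 1]] <- data.frame(
        p_change = rates[i], rep = r, seed = cfg$seed,
        mean_speed_umh = res$stats$speed$mean_umh,
        angular_spread_deg = circular_spread(ang))
    }
  }
  reps_df <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(reps_df, reps_df$p_change), function(d) {
    data.frame(p_change = d$p_change[1],
               mean_speed_umh = mean(d$mean_speed_umh),
               se_speed_umh = stats::sd(d$mean_speed_umh) / sqrt(nrow(d)),
               angular_spread_deg = mean(d$angular_spread_deg),
               n_reps = nrow(d))
  }))
  rownames(agg) <- NULL
  attr(agg, "replicates") <- reps_df
  agg
}

# circular standard deviation (degrees) of the binned angular distribution
circular_spread <- function(ang) {
  th <- ang$bins$mid * pi / 180
  wgt <- ang$bins$count
  if (sum(wgt) == 0) return(NA_real_)
  C <- sum(wgt * cos(th)) / sum(wgt)
  S <- sum(wgt * sin(th)) / sum(wgt)
  R <- sqrt(C^2 + S^2)
  sqrt(-2 * log(max(R, 1e-12))) * 180 / pi
}

#' Write / read a scenario configuration (YAML)
#'
#' Human-editable structured text; unknown keys are errors (no silent
#' typos). The resolved parameter set, geometry and hash are embedded on
#' write; on read, overrides are re-resolved through [scenario_config()].
#'
#' @param cfg a `scenario_config`.
#' @param path file path.
#' @export
write_scenario_config <- function(cfg, path) {
  doc <- list(scenario = cfg$scenario, hours = cfg$hours, seed = cfg$seed,
              output_interval = cfg$output_interval,
              immobile_rows = cfg$immobile_rows,
              region = cfg$region,
              inflow = cfg$inflow,
              params = unclass(cfg$params)[setdiff(names(unclass(cfg$params)), "sigma")],
              geometry = geometry_as_args(cfg$geometry),
              hash = cfg$hash)
  yaml::write_yaml(doc[!vapply(doc, is.null, logical(1))], path)
  invisible(path)
}

geometry_as_args <- function(g) {
  out <- list(kind = g$kind, length = g$length, height = g$height, width = g$width)
  if (!is.null(g$ridges)) {
    out$ridge_x <- g$ridges$x
    out$ridge_width <- g$ridges$width[1]
    out$ridge_height <- g$ridges$height[1]
  }
  if (!is.null(g$step)) {
    out$step_x <- g$step$x
    out$step_height <- g$step$height
  }
  out
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  doc <- yaml::read_yaml(path)
  allowed <- c("scenario", "hours", "seed", "output_interval", "immobile_rows",
               "region", "inflow", "params", "geometry", "out_dir", "hash")
  unknown <- setdiff(names(doc), allowed)
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s", paste(unknown, collapse = ", ")))
  pal <- setdiff(names(formals(model_params)), "r_cutoff")
  pal <- c(pal, "r_cutoff")
  if (!is.null(doc$params)) {
    bad <- setdiff(names(doc$params), pal)
    if (length(bad))
      stop(sprintf("unknown params key(s): %s", paste(bad, collapse = ", ")))
  }
  gargs <- doc$geometry
  if (!is.null(gargs)) gargs$kind <- NULL
  scenario_config(scenario = doc$scenario,
                  hours = doc$hours, seed = if (is.null(doc$seed)) 1 else doc$seed,
                  params = if (is.null(doc$params)) list() else doc$params,
                  geometry = if (is.null(gargs)) list() else gargs,
                  region = doc$region,
                  immobile_rows = doc$immobile_rows,
                  output_interval = if (is.null(doc$output_interval)) 0.1 else doc$output_interval,
                  inflow = doc$inflow,
                  out_dir = doc$out_dir)
}
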