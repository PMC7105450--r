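test_that("random-force refresh follows the exponential holding-time law", {
  p0 <- model_params(p_change = 0)
  pop <- list(positions = matrix(runif(30), 10, 3), mobile = rep(TRUE, 10),
              F_rand = matrix(1, 10, 3))
  st <- simulation_state(pop)
  set.seed(1)
  st2 <- refresh_random_forces(st, p0, 0.5)
  expect_identical(st2$population$F_rand, pop$F_rand)

  # holding times over 1000 h at dt = 0.1 h: mean ~ 1/p_change
  p <- model_params() # p_change = 0.075 per hour
  n <- 400
  pop <- list(positions = matrix(0, n, 3), mobile = rep(TRUE, n),
              F_rand = matrix(rnorm(3 * n), n, 3))
  st <- simulation_state(pop)
  set.seed(99)
  dt <- 0.1
  last <- rep(0, n)
  holds <- numeric(0)
  for (t in seq(dt, 1000, by = dt)) {
    old <- st$population$F_rand[, 1]
    st <- refresh_random_forces(st, p, dt)
    hit <- st$population$F_rand[, 1] != old
    if (any(hit)) {
      holds <- c(holds, t - last[hit])
      last[hit] <- t
    }
  }
  expect_equal(mean(holds), 1 / p$p_change, tolerance = 0.05)
  # deterministic under a fixed seed
  st1 <- simulation_state(pop); st2 <- simulation_state(pop)
  set.seed(5); a <- refresh_random_forces(st1, p, 0.5)$population$F_rand
  set.seed(5); b <- refresh_random_forces(st2, p, 0.5)$population$F_rand
  expect_identical(a, b)
  expect_error(refresh_random_forces(st, p, 2), "step too large")
})

test_that("overdamped velocities: v = mobility * F_total, immobile cells fixed", {
  p <- model_params()
  pos <- matrix(c(1, 1, 1), 1, 3)
  Fr <- matrix(c(0.05, 0, 0), 1, 3)
  v <- cell_velocities(pos, Fr, TRUE, NULL, NULL, NULL, p)
  expect_equal(v$V[1, ], c(0.05, 0, 0)) # mm/h per a.u., mobility 1
  v0 <- cell_velocities(pos, Fr, FALSE, NULL, NULL, NULL, p)
  expect_equal(v0$V[1, ], c(0, 0, 0))
  # two-cell overlapping pair: equal and opposite velocities (Newton)
  pos2 <- rbind(c(0, 0, 0), c(1.5 * p$r_cell, 0, 0))
  Fr2 <- matrix(0, 2, 3)
  v2 <- cell_velocities(pos2, Fr2, c(TRUE, TRUE), NULL, NULL, NULL, p)
  expect_equal(v2$V[1, ], -v2$V[2, ], tolerance = 1e-15)
  expect_gt(abs(v2$V[1, 1]), 0) # soft-core repulsion separates them
})

test_that("RK4 integrates linear motion exactly and a spring to high accuracy", {
  # constant velocity: one adaptive step is exact to machine precision
  p <- model_params()
  pop <- list(positions = matrix(0, 1, 3), mobile = TRUE,
              F_rand = matrix(c(0.04, 0, 0), 1, 3))
  st <- simulation_state(pop, dt = 0.05)
  res <- step_rk4_adaptive(st, NULL, NULL, NULL, p)
  expect_equal(res$state$population$positions[1, 1],
               0.04 * res$dt_used, tolerance = 1e-15)

  # overdamped quadratic well dx/dt = -k x: matches exp(-k t)
  k <- 3
  vfun <- function(pos) -k * pos
  x <- matrix(c(1, 0.5, -0.2), 1, 3)
  t <- 0; h <- 0.01
  for (i in 1:200) x <- ecmigrate:::rk4_step(x, h, vfun)
  expect_lt(max(abs(as.numeric(x) - c(1, 0.5, -0.2) * exp(-k * 2))), 1e-8)

  # classical 4th-order convergence: halving dt shrinks the error ~16x
  err_at <- function(h) {
    x <- matrix(1, 1, 1)
    for (i in seq_len(round(1 / h))) x <- ecmigrate:::rk4_step(x, h, function(p) -k * p)
    abs(x[1] - exp(-k))
  }
  r1 <- err_at(0.05) / err_at(0.025)
  r2 <- err_at(0.025) / err_at(0.0125)
  expect_gt(r1, 12); expect_lt(r1, 21)
  expect_gt(r2, 12); expect_lt(r2, 21)
})

test_that("zero-duration runs return the seeding and identical seeds match bit-exactly", {
  p <- model_params()
  g <- flat_channel(length = 1.2, height = 0.3, width = 0.3)
  obs <- build_obstacles(g, p)
  pop <- seed_monolayer(g, p, list(x0 = 0.3, x1 = 0.8, z0 = 0.03, z1 = 0.27),
                        immobile_rows = 0)
  t0 <- run_simulation(g, obs, NULL, pop, p, hours = 0, seed = 4)
  expect_equal(dim(t0$pos)[3], 1)
  expect_identical(t0$pos[, , 1], pop$positions)

  ta <- run_simulation(g, obs, NULL, pop, p, hours = 1, seed = 7)
  tb <- run_simulation(g, obs, NULL, pop, p, hours = 1, seed = 7)
  expect_identical(ta$pos, tb$pos)
  tc <- run_simulation(g, obs, NULL, pop, p, hours = 1, seed = 8)
  expect_false(identical(tc$pos, ta$pos))
})

test_that("no-flow dynamics is isotropic and flow adds a downstream bias", {
  p <- model_params()
  g <- flat_channel(length = 3, height = 0.4, width = 0.6)
  obs <- build_obstacles(g, p)
  pop <- seed_monolayer(g, p, list(x0 = 1.2, x1 = 1.9, z0 = 0.1, z1 = 0.5),
                        immobile_rows = 0)
  traj <- run_simulation(g, obs, NULL, pop, p, hours = 8, seed = 31,
                         output_interval = 0.5)
  nd <- net_displacements(traj)
  # Hotelling-type test on the mean planar displacement: with no flow the
  # mean is zero (chi-square approximation, alpha = 0.01)
  D <- nd$disp[, c(1, 3)]
  n <- nrow(D)
  m <- colMeans(D)
  T2 <- n * drop(t(m) %*% solve(cov(D)) %*% m)
  expect_lt(T2, qchisq(0.99, df = 2))

  flow <- solve_channel_flow(g, p)
  trajf <- run_simulation(g, obs, flow, pop, p, hours = 8, seed = 31,
                          output_interval = 0.5)
  ndf <- net_displacements(trajf)
  expect_gt(mean(ndf$disp[, 1]), 3 * sd(ndf$disp[, 1]) / sqrt(n))
  # sampled path speeds are positive and bounded by the mean force scale
  # (the cue redirects the force, it never rescales it; the flow-on speed
  # is the larger one because less of the walk is spent pushing against
  # the floor and band projections)
  sp0 <- mean_migration_speed(traj)$mean_umh
  spf <- mean_migration_speed(trajf)$mean_umh
  maxwell <- 1000 * sqrt(8 * p$c_var / pi)
  expect_gt(sp0, 0.6 * maxwell)
  expect_lt(sp0, 1.05 * maxwell)
  expect_gt(spf, sp0)
  expect_lt(spf, 1.05 * maxwell)
})

test_that("cells stay in the monolayer band and never collapse onto each other", {
  p <- model_params()
  g <- flat_channel(length = 2, height = 0.4, width = 0.4)
  obs <- build_obstacles(g, p)
  flow <- solve_channel_flow(g, p)
  pop <- seed_monolayer(g, p, list(x0 = 0.5, x1 = 1.2, z0 = 0.05, z1 = 0.35))
  traj <- run_simulation(g, obs, flow, pop, p, hours = 6, seed = 12,
                         output_interval = 0.5)
  for (fi in seq_along(traj$times)) {
    frame <- traj$pos[, , fi]
    cv <- confinement_violation(frame, obs, p)
    expect_lt(max(cv$dist[traj$mobile]), 3 * p$r_cell + 1e-9)
    expect_gt(ecmigrate:::cpp_min_pair_distance(frame), 0.2 * p$r_cell)
    expect_true(all(frame[, 2] >= p$r_cell - 1e-12))
    expect_true(all(frame[, 3] >= 0 & frame[, 3] <= g$width))
  }
})

test_that("runs can be checkpointed and resumed exactly", {
  p <- model_params()
  g <- flat_channel(length = 1.5, height = 0.3, width = 0.3)
  obs <- build_obstacles(g, p)
  pop <- seed_monolayer(g, p, list(x0 = 0.4, x1 = 0.9, z0 = 0.05, z1 = 0.25),
                        immobile_rows = 0)
  full <- run_simulation(g, obs, NULL, pop, p, hours = 2, seed = 3,
                         output_interval = 0.5)
  half <- run_simulation(g, obs, NULL, pop, p, hours = 1, seed = 3,
                         output_interval = 0.5)
  rest <- run_simulation(g, obs, NULL, pop, p, hours = 1, seed = 3,
                         output_interval = 0.5, resume = half$final_state)
  expect_equal(rest$pos[, , dim(rest$pos)[3]], full$pos[, , dim(full$pos)[3]],
               tolerance = 1e-12)
})

test_that("trajectories round-trip through CSV", {
  p <- model_params()
  g <- flat_channel(length = 1.2, height = 0.3, width = 0.3)
  obs <- build_obstacles(g, p)
  pop <- seed_monolayer(g, p, list(x0 = 0.3, x1 = 0.7, z0 = 0.05, z1 = 0.25))
  traj <- run_simulation(g, obs, NULL, pop, p, hours = 0.5, seed = 2,
                         output_interval = 0.25)
  path <- tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_equal(back$times, traj$times)
  expect_identical(back$pos, traj$pos)
  expect_identical(back$mobile, traj$mobile)
  unlink(path)
})
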