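test_that("substrate lattice matches the closed-form hexagonal count", {
  p <- model_params()
  g <- flat_channel(length = 1, height = 0.3, width = 0.5)
  obs <- build_obstacles(g, p)
  s <- p$r_cell
  dr <- s * sqrt(3) / 2
  nrows <- floor(0.5 / dr + 1e-9) + 1
  counted <- sum(vapply(seq_len(nrows) - 1, function(k) {
    off <- (k %% 2) * s / 2
    floor((1 - off) / s + 1e-9) + 1
  }, numeric(1)))
  expect_equal(nrow(obs$centres), counted)
  # row spacing along z is r_cell * sqrt(3)/2
  zrows <- sort(unique(round(obs$centres[, 3], 12)))
  expect_equal(diff(zrows), rep(dr, length(zrows) - 1), tolerance = 1e-9)
  expect_true(all(obs$centres[, 2] == 0))
})

test_that("ridge tops and both vertical flanks carry obstacle elements", {
  p <- model_params()
  g <- ridged_channel(length = 2, height = 0.4, width = 0.3,
                      ridge_x = 1, ridge_width = 0.1, ridge_height = 0.1)
  obs <- build_obstacles(g, p)
  on_top <- obs$centres[, 2] == 0.1 &
    obs$centres[, 1] >= 1 & obs$centres[, 1] <= 1.1
  on_up <- obs$centres[, 1] == 1 & obs$centres[, 2] > 0
  on_down <- obs$centres[, 1] == 1.1 & obs$centres[, 2] > 0
  expect_gt(sum(on_top), 50)
  expect_gt(sum(on_up), 50)
  expect_gt(sum(on_down), 50)
})

test_that("the substrate covering leaves no gap a cell could pass through", {
  # densely sample points on the substrate plane: the distance to the
  # nearest element centre never exceeds the hexagonal covering radius
  # r_cell/sqrt(3), so no straight path of clearance > r_cell exists
  p <- model_params()
  g <- flat_channel(length = 0.8, height = 0.3, width = 0.4)
  obs <- build_obstacles(g, p)
  set.seed(5)
  probe <- cbind(runif(4000, 0.05, 0.75), 0, runif(4000, 0.05, 0.35))
  nn <- confinement_violation(probe, obs, p)
  expect_lt(max(nn$dist), p$r_cell / sqrt(3) + 1e-9)
})

test_that("obstacle lattices of mirrored geometries coincide within one element", {
  p <- model_params()
  g1 <- ridged_channel(length = 3, height = 0.4, width = 0.3,
                       ridge_x = 0.8, ridge_width = 0.1, ridge_height = 0.1)
  g2 <- ridged_channel(length = 3, height = 0.4, width = 0.3,
                       ridge_x = 3 - 0.9, ridge_width = 0.1, ridge_height = 0.1)
  o1 <- build_obstacles(g1, p)
  o2 <- build_obstacles(g2, p)
  mirrored <- o2$centres
  mirrored[, 1] <- 3 - mirrored[, 1]
  # Hausdorff-style check: every mirrored element has a counterpart within
  # one lattice spacing (the lattice phase is anchored at x = 0, so exact
  # coincidence is not expected)
  nn <- confinement_violation(mirrored, o1, p)$dist
  expect_lt(max(nn), p$r_cell + 1e-9)
})

test_that("seeded monolayer has the documented spacing, count and anchor rows", {
  p <- model_params()
  g <- flat_channel(length = 3, height = 0.4, width = 0.66)
  region <- list(x0 = 0.5, x1 = 1.1, z0 = 0.02, z1 = 0.62)
  pop <- seed_monolayer(g, p, region)
  s <- 4 * p$r_cell
  dr <- s * sqrt(3) / 2
  nrows <- floor(0.6 / dr + 1e-9) + 1
  counted <- sum(vapply(seq_len(nrows) - 1, function(k) {
    off <- (k %% 2) * s / 2
    floor((0.6 - off) / s + 1e-9) + 1
  }, numeric(1)))
  expect_equal(nrow(pop$positions), counted)
  # minimum pairwise distance is exactly the seeding spacing
  dmin <- min(dist(pop$positions))
  expect_equal(dmin, s, tolerance = 1e-12)
  # four leftmost rows are immobile
  xs <- sort(unique(round(pop$positions[, 1], 9)))
  anchors <- pop$positions[, 1] <= xs[4] + 1e-9
  expect_true(all(!pop$mobile[anchors]))
  expect_true(all(pop$mobile[!anchors]))
  # cells sit at r_cell above the substrate
  expect_true(all(pop$positions[, 2] == p$r_cell))
  # reproducible bit-exactly: no hidden randomness
  pop2 <- seed_monolayer(g, p, region)
  expect_identical(pop$positions, pop2$positions)
  expect_error(seed_monolayer(g, p, list(x0 = 1, x1 = 1, z0 = 0, z1 = 1)))
})

test_that("step-scenario monolayer is seeded on the downstream floor", {
  p <- model_params()
  g <- step_channel(length = 6, height = 0.75, width = 0.3,
                    step_x = 1, step_height = 0.25)
  pop <- seed_monolayer(g, p, list(x0 = 1.05, x1 = 3, z0 = 0.03, z1 = 0.27),
                        immobile_rows = 0)
  expect_true(all(pop$mobile))
  expect_true(all(pop$positions[, 2] == p$r_cell))
  expect_true(all(pop$positions[, 1] > 1))
})

test_that("confinement band detection and correction follow nearest-point geometry", {
  p <- model_params()
  g <- flat_channel(length = 1, height = 0.3, width = 0.4)
  obs <- build_obstacles(g, p)
  # directly above an element: admissible at 2 r_cell
  el <- obs$centres[100, ]
  ok <- confinement_violation(el + c(0, 2 * p$r_cell, 0), obs, p)
  expect_false(ok$violated)
  expect_equal(max(abs(ok$correction)), 0)
  # at 4 r_cell: violated, correction magnitude r_cell back towards the band
  bad <- confinement_violation(el + c(0, 4 * p$r_cell, 0), obs, p)
  expect_true(bad$violated)
  expect_equal(sqrt(sum(bad$correction^2)), p$r_cell, tolerance = 1e-9)
  corrected <- el + c(0, 4 * p$r_cell, 0) + bad$correction[1, ]
  after <- confinement_violation(corrected, obs, p)
  expect_false(after$violated)
  # nearest-obstacle distances agree with an R brute force on random points
  set.seed(8)
  probes <- cbind(runif(50, 0, 1), runif(50, 0, 0.1), runif(50, 0, 0.4))
  got <- confinement_violation(probes, obs, p)$dist
  want <- apply(probes, 1, function(q)
    sqrt(min(colSums((t(obs$centres) - q)^2))))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("confinement band follows a ridge face normal", {
  p <- model_params()
  g <- ridged_channel(length = 2, height = 0.4, width = 0.3,
                      ridge_x = 1, ridge_width = 0.1, ridge_height = 0.1)
  obs <- build_obstacles(g, p)
  # beside the upstream flank, high enough that the face (not the floor)
  # is the nearest surface: band measured along x
  probe <- c(1 - 2 * p$r_cell, 0.08, 0.15)
  expect_false(confinement_violation(probe, obs, p)$violated)
  probe2 <- c(1 - 4 * p$r_cell, 0.08, 0.15)
  cv <- confinement_violation(probe2, obs, p)
  expect_true(cv$violated)
  # correction points towards the face (positive x), not down to the floor
  expect_gt(cv$correction[1, 1], 0)
})

test_that("side walls are frictionless: purely spanwise restoring force", {
  p <- model_params()
  g <- flat_channel(length = 2, height = 0.4, width = 0.5)
  expect_equal(side_wall_force(c(1, 0.02, 0.25), g, p), c(0, 0, 0))
  f <- side_wall_force(c(1, 0.02, -0.5 * p$r_cell), g, p)
  expect_gt(f[3], 0)
  expect_equal(f[1:2], c(0, 0))
  f2 <- side_wall_force(c(1, 0.02, 0.5 + 0.01), g, p)
  expect_lt(f2[3], 0)
  set.seed(13)
  viol <- cbind(runif(1000, 0, 2), runif(1000, 0, 0.4),
                sample(c(-1, 1), 1000, TRUE) * runif(1000, 0, 0.05) +
                  ifelse(runif(1000) < 0.5, 0, 0.5))
  F <- side_wall_force(viol, g, p)
  expect_true(all(F[, 1] == 0 & F[, 2] == 0))
})

test_that("solid projection keeps cells clear of floors, ridges and the step", {
  p <- model_params()
  g <- ridged_channel(length = 2, height = 0.4, width = 0.3,
                      ridge_x = 1, ridge_width = 0.1, ridge_height = 0.1)
  out <- project_out_of_solids(rbind(
    c(0.5, 0.001, 0.1),   # sunk into the substrate
    c(1.05, 0.05, 0.1),   # inside the ridge
    c(0.9995, 0.05, 0.1), # just inside the upstream flank clearance
    c(0.5, 0.2, 0.1)),    # free stream
    g, p)
  expect_equal(out[1, 2], p$r_cell)
  expect_true(out[2, 2] >= 0.1 + p$r_cell - 1e-12 ||
                out[2, 1] <= 1 - p$r_cell + 1e-12 ||
                out[2, 1] >= 1.1 + p$r_cell - 1e-12)
  expect_equal(out[3, 1], 1 - p$r_cell)
  expect_equal(out[4, ], c(0.5, 0.2, 0.1), ignore_attr = TRUE)
  gs <- step_channel(length = 4, height = 0.75, width = 0.3,
                     step_x = 1, step_height = 0.25)
  st <- project_out_of_solids(rbind(c(1.005, 0.1, 0.1)), gs, p)
  expect_equal(st[1, 1], 1 + p$r_cell)
})
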