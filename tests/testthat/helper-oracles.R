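# Independent oracles and shared fixtures for the test suite.
# Oracles are written from the model definitions directly (all-pairs sums,
# closed forms, direct formula transcriptions) and never call the kernels
# they check.

# --- independent pair-force transcription (positive = repulsive) -----------
oracle_pair_force <- function(r, r_cell = 0.015, C = 0.1, eps = 3e-7,
                              variant = c("printed", "caption")) {
  variant <- match.arg(variant)
  sigma <- 2 * r_cell
  rcut <- 4 * r_cell
  vapply(r, function(ri) {
    if (ri >= rcut) return(0)
    if (ri >= sigma) {
      q <- (sigma / ri)^6
      return(48 * eps * (q^2 - q))
    }
    a <- if (variant == "caption") sqrt(r_cell * (2 * r_cell - ri)) else
      sqrt(r_cell / 2 * (2 * r_cell - ri))
    (8 * a^3 * C * (16 * a^2 - 36 * pi * a * r_cell + 27 * pi^2 * r_cell^2)) /
      (3 * r_cell * (4 * a - 3 * pi * r_cell)^2)
  }, numeric(1))
}

# --- brute-force all-pairs interaction forces (O(N^2)) ---------------------
oracle_total_forces <- function(cells, obstacles_mat = NULL, p = model_params()) {
  n <- nrow(cells)
  F <- matrix(0, n, 3)
  allpts <- rbind(cells, obstacles_mat)
  for (i in seq_len(n)) {
    for (j in seq_len(nrow(allpts))) {
      if (j == i) next
      dv <- cells[i, ] - allpts[j, ]
      r <- sqrt(sum(dv^2))
      if (r >= p$r_cutoff || r < 1e-12) next
      f <- oracle_pair_force(r, p$r_cell, p$C, p$epsilon, p$contact_variant)
      F[i, ] <- F[i, ] + f * dv / r
    }
  }
  F
}

# --- constructed trajectory from a list of n x 3 position frames -----------
make_traj <- function(frames, times = seq_along(frames) - 1,
                      mobile = rep(TRUE, nrow(frames[[1]]))) {
  n <- nrow(frames[[1]])
  pos <- array(NA_real_, dim = c(n, 3, length(frames)))
  for (k in seq_along(frames)) pos[, , k] <- frames[[k]]
  structure(list(times = times, pos = pos, mobile = mobile,
                 params = model_params(), geom = NULL, seed = NA,
                 final_state = NULL),
            class = "ec_trajectory")
}

# --- cached expensive flow solves (shared across test files) ---------------
.flow_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.flow_cache[[key]])) .flow_cache[[key]] <- force(expr)
  .flow_cache[[key]]
}

small_flat_lb <- function() cached("flat_lb", {
  solve_channel_flow(flat_channel(length = 2, height = 0.24, width = 0.3),
                     model_params(), method = "lb")
})

small_ridged_flow <- function() cached("ridged_lb", {
  solve_channel_flow(
    ridged_channel(length = 4, height = 0.5, width = 0.3,
                   ridge_x = 1.5, ridge_width = 0.1, ridge_height = 0.1),
    model_params())
})

default_step_flow <- function() cached("step_lb", {
  solve_channel_flow(step_channel(), model_params())
})
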