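#' Net displacement of each cell over a time window
#'
#' @param traj an `ec_trajectory`.
#' @param window `c(t0, t1)` in hours; the nearest recorded frames are used.
#' @return list with `start` (`n x 3` positions at t0), `disp` (`n x 3` net
#'   displacement vectors) and the actual frame times used.
#' @export
net_displacements <- function(traj, window = range(traj$times)) {
  i0 <- which.min(abs(traj$times - window[1]))
  i1 <- which.min(abs(traj$times - window[2]))
  if (i1 <= i0) stop("net_displacements: empty window")
  list(start = traj$pos[, , i0], disp = traj$pos[, , i1] - traj$pos[, , i0],
       t0 = traj$times[i0], t1 = traj$times[i1])
}

#' Angular distribution of cell displacement
#'
#' Converts each mobile cell's net displacement over the window to an angle
#' in the substrate (x-z) plane, with 180 degrees pointing downstream (+x),
#' and bins the angles (default 24 bins of 15 degrees). For ridged-channel
#' analyses, pass `downstream_of =` the x coordinate of the ridge's trailing
#' face: only cells whose window-start position lies downstream of it are
#' included (the analysis origin sits `offset` mm further downstream).
#' Cells whose displacement is below 1e-9 mm are excluded and counted
#' separately.
#'
#' @param traj an `ec_trajectory`.
#' @param window `c(t0, t1)` hours.
#' @param downstream_of optional x coordinate (mm) restricting the analysis
#'   to cells starting downstream of it.
#' @param offset origin offset downstream of `downstream_of` (mm, default
#'   0.05 = 50 um); recorded for axial re-origining.
#' @param bin_width angular bin width (degrees; must divide 360).
#' @return an `angular_histogram`: data.frame `bins` with `bin_start`,
#'   `bin_end`, `mid`, `count`, `percent` (summing to 100), plus
#'   `n_included` and `n_excluded`.
#' @export
angular_distribution <- function(traj, window = range(traj$times),
                                 downstream_of = NULL, offset = 0.05,
                                 bin_width = 15) {
  stopifnot(360 %% bin_width == 0)
  nd <- net_displacements(traj, window)
  keep <- traj$mobile
  if (!is.null(downstream_of)) keep <- keep & nd$start[, 1] > downstream_of
  disp <- nd$disp[keep, , drop = FALSE]
  mag <- sqrt(disp[, 1]^2 + disp[, 3]^2)
  moved <- mag > 1e-9
  ang <- (atan2(disp[moved, 3], disp[moved, 1]) * 180 / pi + 180) %% 360
  nb <- 360 / bin_width
  idx <- pmin(floor(ang / bin_width) + 1, nb)
  count <- tabulate(idx, nbins = nb)
  bins <- data.frame(bin_start = (seq_len(nb) - 1) * bin_width,
                     bin_end = seq_len(nb) * bin_width,
                     mid = (seq_len(nb) - 0.5) * bin_width,
                     count = count,
                     percent = if (sum(count) > 0) 100 * count / sum(count) else 0 * count)
  out <- list(bins = bins, n_included = sum(moved), n_excluded = sum(!moved),
              window = c(nd$t0, nd$t1), origin_offset = offset)
  class(out) <- "angular_histogram"
  out
}

#' @export
print.angular_histogram <- function(x, ...) {
  cat(sprintf("angular_histogram: %d cells over %.1f-%.1f h (%d excluded, zero displacement)\n",
              x$n_included, x$window[1], x$window[2], x$n_excluded))
  peak <- x$bins[which.max(x$bins$count), ]
  cat(sprintf("  peak bin %g-%g deg: %.1f%% (180 deg = downstream)\n",
              peak$bin_start, peak$bin_end, peak$percent))
  invisible(x)
}

#' Mean migration speed
#'
#' Sampled path length of each mobile cell's track divided by the window
#' duration, averaged over mobile cells; reported in um/h with its standard
#' error. (Path-based, not net-displacement-based: the standard definition
#' for migration assays.)
#'
#' @param traj an `ec_trajectory`.
#' @param window `c(t0, t1)` hours; default full span.
#' @return list with `mean_umh`, `se_umh`, `n`, `per_cell` (um/h).
#' @export
mean_migration_speed <- function(traj, window = range(traj$times)) {
  sel <- which(traj$times >= window[1] - 1e-9 & traj$times <= window[2] + 1e-9)
  if (length(sel) < 2) stop("mean_migration_speed: need at least 2 frames in window")
  dur <- traj$times[sel[length(sel)]] - traj$times[sel[1]]
  pos <- traj$pos[traj$mobile, , sel, drop = FALSE]
  dif <- pos[, , -1, drop = FALSE] - pos[, , -length(sel), drop = FALSE]
  steplen <- sqrt(dif[, 1, , drop = FALSE]^2 + dif[, 2, , drop = FALSE]^2 +
                    dif[, 3, , drop = FALSE]^2)
  per_cell <- 1000 * apply(steplen, 1, sum) / dur # mm/h -> um/h
  list(mean_umh = mean(per_cell),
       se_umh = stats::sd(per_cell) / sqrt(length(per_cell)),
       n = length(per_cell), per_cell = per_cell)
}

#' Axial (streamwise) distribution of cells
#'
#' Normalized histogram of cell x positions at a given time; integrates to
#' 1 over the binned range. The origin can be shifted (e.g. 50 um
#' downstream of a ridge's trailing face, the convention used for ridged
#' channels).
#'
#' @param traj an `ec_trajectory`.
#' @param at_time time (h); nearest frame is used.
#' @param bin_width bin width (mm), default 0.06 (one seeded cell spacing).
#' @param origin x coordinate (mm) subtracted from positions.
#' @param mobile_only drop immobile (anchor-row) cells; default TRUE.
#' @return a `density_profile`: data.frame with `bin_start`, `bin_end`,
#'   `mid` (mm, origin-relative), `count`, `density` (1/mm).
#' @export
axial_distribution <- function(traj, at_time = max(traj$times),
                               bin_width = 0.06, origin = 0,
                               mobile_only = TRUE) {
  fi <- which.min(abs(traj$times - at_time))
  x <- traj$pos[, 1, fi]
  if (mobile_only) x <- x[traj$mobile]
  x <- x - origin
  lo <- floor(min(x) / bin_width) * bin_width
  hi <- ceiling(max(x) / bin_width + 1e-12) * bin_width
  edges <- seq(lo, hi, by = bin_width)
  if (length(edges) < 2) edges <- c(lo, lo + bin_width)
  idx <- pmin(pmax(floor((x - lo) / bin_width) + 1, 1), length(edges) - 1)
  count <- tabulate(idx, nbins = length(edges) - 1)
  prof <- data.frame(bin_start = edges[-length(edges)], bin_end = edges[-1],
                     mid = edges[-length(edges)] + bin_width / 2,
                     count = count,
                     density = count / (sum(count) * bin_width))
  class(prof) <- c("density_profile", "data.frame")
  prof
}

#' Location of the density minimum
#'
#' Axial coordinate of the minimum of the 3-bin moving-average-smoothed
#' density profile within a search interval; ties resolve to the smallest
#' x (documented tie rule).
#'
#' @param profile a `density_profile`.
#' @param interval `c(x0, x1)` (mm, same origin as the profile) to search.
#' @return x of the minimum (mm, bin midpoint).
#' @export
density_minimum_location <- function(profile, interval = range(profile$mid)) {
  sm <- smooth_3bin(profile$density)
  sel <- profile$mid >= interval[1] & profile$mid <= interval[2]
  if (!any(sel)) stop("density_minimum_location: empty search interval")
  if (all(profile$count[sel] == 0))
    stop("density_minimum_location: no cells in search interval")
  mids <- profile$mid[sel]
  vals <- sm[sel]
  mids[which.min(vals)] # which.min takes the first (smallest x) on ties
}

# centred 3-bin moving average; edge bins average the available neighbours
smooth_3bin <- function(v) {
  n <- length(v)
  if (n < 3) return(v)
  out <- v
  out[2:(n - 1)] <- (v[1:(n - 2)] + v[2:(n - 1)] + v[3:n]) / 3
  out[1] <- mean(v[1:2])
  out[n] <- mean(v[(n - 1):n])
  out
}

#' Count cells entrapped in a recirculation zone
#'
#' Number of cells that enter the streamwise interval `zone` during the
#' window (an outside-to-inside transition of their x coordinate) and then
#' remain inside through the window end. Cells that merely pass through, or
#' that sit inside for the whole window without entering, are not counted.
#'
#' @param traj an `ec_trajectory`.
#' @param zone `c(x_start, x_end)` (mm), e.g. a row of
#'   [recirculation_zones()].
#' @param window `c(t0, t1)` hours.
#' @return integer count.
#' @export
entrapment_count <- function(traj, zone, window = range(traj$times)) {
  sel <- which(traj$times >= window[1] - 1e-9 & traj$times <= window[2] + 1e-9)
  if (length(sel) < 2) return(0L)
  xs <- traj$pos[, 1, sel, drop = FALSE]
  n <- 0L
  for (i in which(traj$mobile)) {
    inside <- xs[i, 1, ] >= zone[1] & xs[i, 1, ] <= zone[2]
    Tn <- length(inside)
    if (!inside[Tn]) next
    entries <- which(inside[-1] & !inside[-Tn]) + 1
    if (!length(entries)) next
    last_entry <- entries[length(entries)]
    if (all(inside[last_entry:Tn])) n <- n + 1L
  }
  n
}
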