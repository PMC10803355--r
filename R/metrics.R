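# Outcome statistics from trajectories: ratio of unsafe driving (RUD),
# per-group RUD, space-mean speed and position-binned speed profiles.

#' Ratio of unsafe driving
#'
#' RUD is the share of total distance travelled at a speed strictly above the
#' threshold, in percent. Per-step distance increments are `speed * dt`, so
#' the metric is a pure function of the recorded speeds.
#'
#' @param trajectories Data frame with at least a `speed_kmh` column (one row
#'   per vehicle-timestep).
#' @param threshold Unsafe-speed threshold in km/h (default 90).
#' @param dt Record spacing in seconds (default 1).
#' @return RUD in percent, in `[0, 100]`.
#' @export
compute_rud <- function(trajectories, threshold = 90, dt = 1) {
  if (nrow(trajectories) == 0) stop("no trajectory records")
  d <- trajectories$speed_kmh / 3.6 * dt
  tot <- sum(d)
  if (tot <= 0) stop("zero total distance: degenerate scenario")
  100 * sum(d[trajectories$speed_kmh > threshold]) / tot
}

#' Per-group ratio of unsafe driving
#'
#' [compute_rud()] restricted to each behavioural group's vehicles. Groups
#' whose vehicles cover zero distance (or that have no vehicles) are absent
#' from the result rather than reported as zero.
#'
#' @param trajectories Trajectory records with `vehicle_id` and `speed_kmh`.
#' @param vehicles Vehicle-to-driver map with `vehicle_id` and `group`
#'   (as in a `sim_result`).
#' @inheritParams compute_rud
#' @return Named numeric vector of RUD percentages, one entry per group with
#'   positive distance.
#' @export
compute_group_rud <- function(trajectories, vehicles, threshold = 90, dt = 1) {
  if (nrow(trajectories) == 0) stop("no trajectory records")
  idx <- match(trajectories$vehicle_id, vehicles$vehicle_id)
  if (anyNA(idx)) stop("trajectory references unknown vehicle_id")
  grp <- vehicles$group[idx]
  out <- c()
  for (g in intersect(c("A", "B", "C"), unique(grp))) {
    sub <- trajectories[grp == g, , drop = FALSE]
    if (sum(sub$speed_kmh) <= 0) next
    out[g] <- compute_rud(sub, threshold, dt)
  }
  out
}

#' Space-mean speed
#'
#' Total distance divided by total travel time over all recorded
#' vehicle-steps: the flow-weighted (harmonic over space) mean speed that the
#' power model takes as its input.
#'
#' @inheritParams compute_rud
#' @return Speed in km/h.
#' @export
space_mean_speed <- function(trajectories, dt = 1) {
  if (nrow(trajectories) == 0) stop("no trajectory records")
  tot_t <- nrow(trajectories) * dt
  if (tot_t <= 0) stop("zero total travel time")
  tot_d <- sum(trajectories$speed_kmh / 3.6 * dt)
  tot_d / tot_t * 3.6
}

#' Position-binned mean speed profile
#'
#' Arithmetic mean of sample speeds per position bin, optionally restricted
#' to one behavioural group. Empty bins are absent from the output.
#'
#' @inheritParams compute_group_rud
#' @param bin_width Bin width in metres (default 100).
#' @param group Optional group filter (`"A"`, `"B"` or `"C"`); requires
#'   `vehicles`.
#' @return Data frame with `bin_center`, `mean_speed_kmh`, `n_samples`,
#'   ordered by position.
#' @export
speed_profile <- function(trajectories, bin_width = 100, vehicles = NULL,
                          group = NULL) {
  stopifnot(bin_width > 0)
  tr <- trajectories
  if (!is.null(group)) {
    if (is.null(vehicles)) stop("group filter requires the vehicles table")
    idx <- match(tr$vehicle_id, vehicles$vehicle_id)
    if (anyNA(idx)) stop("trajectory references unknown vehicle_id")
    tr <- tr[vehicles$group[idx] %in% group, , drop = FALSE]
  }
  if (nrow(tr) == 0)
    return(data.frame(bin_center = numeric(0), mean_speed_kmh = numeric(0),
                      n_samples = integer(0)))
  bin <- floor(tr$position_m / bin_width)
  sp <- tapply(tr$speed_kmh, bin, mean)
  ns <- tapply(tr$speed_kmh, bin, length)
  b <- as.numeric(names(sp))
  ord <- order(b)
  data.frame(bin_center = (b[ord] + 0.5) * bin_width,
             mean_speed_kmh = as.numeric(sp[ord]),
             n_samples = as.integer(ns[ord]))
}

#' Per-scenario results row
#'
#' Collapses one simulation run into the scenario-results schema used by the
#' batch runner and downstream analyses. Metrics come from the kernel's
#' accumulated per-step summary, which aggregates exactly the quantities the
#' trajectory-level functions compute.
#'
#' @param sim A `sim_result` from [run_simulation()].
#' @return One-row data frame: `scenario_id, seed, sec_type, telematics_pct,
#'   pct_B, pct_C, demand_vph, rud_pct, rud_A, rud_B, rud_C, mean_speed_kmh,
#'   total_distance_vkm, total_time_vh` (group RUD is `NA` for groups with
#'   zero distance).
#' @export
scenario_results <- function(sim) {
  s <- sim$summary
  sc <- sim$scenario
  dist <- s$dist_m; time <- s$time_s; unsafe <- s$unsafe_m
  tot_d <- sum(dist); tot_t <- sum(time)
  if (tot_d <= 0) stop("zero total distance: degenerate scenario")
  grp_rud <- ifelse(dist > 0, 100 * unsafe / dist, NA_real_)
  data.frame(
    scenario_id = scenario_id(sc), seed = sc$seed, sec_type = sc$sec_type,
    telematics_pct = sc$telematics_pct, pct_B = sc$pct_B, pct_C = sc$pct_C,
    demand_vph = sc$demand_vph,
    rud_pct = 100 * sum(unsafe) / tot_d,
    rud_A = grp_rud[["A"]], rud_B = grp_rud[["B"]], rud_C = grp_rud[["C"]],
    mean_speed_kmh = tot_d / tot_t * 3.6,
    total_distance_vkm = tot_d / 1000,
    total_time_vh = tot_t / 3600,
    stringsAsFactors = FALSE)
}
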