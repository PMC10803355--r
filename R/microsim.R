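# Highway microsimulation: road and camera geometry, Krauss-type
# car-following update, behavioural target speeds, and the full scenario run.

#' Road specification
#'
#' A single homogeneous highway segment without exits or entries other than
#' the upstream boundary.
#'
#' @param length Segment length in metres (default 6000).
#' @param lanes Number of lanes (default 3); lane 0 is the rightmost.
#' @param speed_limit Posted limit in km/h (default 90).
#' @export
road_spec <- function(length = 6000, lanes = 3, speed_limit = 90) {
  stopifnot(length > 0, lanes >= 1, speed_limit > 0)
  structure(list(length = length, lanes = as.integer(lanes),
                 speed_limit = speed_limit), class = "road_spec")
}

#' Camera layout
#'
#' Four deployments on the segment of length L: one fixed camera at L/2
#' (`FIX1`); two at L/3 and 2L/3 (`FIX2`); three at the quartiles (`FIX3`);
#' or an average (point-to-point) section between L/4 and 3L/4 (`P2P`).
#' Fixed cameras enforce over a detection zone extending `detection_range`
#' metres upstream of each camera; the point-to-point layout enforces over
#' the whole controlled section.
#'
#' @param sec_type One of `"FIX1"`, `"FIX2"`, `"FIX3"`, `"P2P"`.
#' @param road A [road_spec()].
#' @param detection_range Upstream detection range of a fixed camera in
#'   metres (default 150).
#' @return An object of class `camera_layout` with the camera positions, the
#'   point-to-point section (if any) and the enforced-zone intervals.
#' @export
camera_layout <- function(sec_type = c("FIX1", "FIX2", "FIX3", "P2P"),
                          road = road_spec(), detection_range = 150) {
  sec_type <- match.arg(sec_type)
  stopifnot(detection_range > 0)
  L <- road$length
  positions <- switch(sec_type,
    FIX1 = L / 2,
    FIX2 = c(L / 3, 2 * L / 3),
    FIX3 = c(L / 4, L / 2, 3 * L / 4),
    P2P  = c(L / 4, 3 * L / 4))
  p2p_section <- if (sec_type == "P2P") c(L / 4, 3 * L / 4) else NULL
  zones <- if (sec_type == "P2P") {
    matrix(p2p_section, nrow = 1)
  } else {
    cbind(pmax(positions - detection_range, 0), positions)
  }
  structure(list(sec_type = sec_type, camera_positions = positions,
                 detection_range = detection_range,
                 p2p_section = p2p_section, zones = zones),
            class = "camera_layout")
}

#' Simulation parameters
#'
#' Discrete-time update parameters for the Krauss-type car-following model.
#' Defaults mirror the conventional values for passenger cars in highway
#' microsimulation: 2.6 m/s^2 acceleration, 4.5 m/s^2 braking, 1 s reaction
#' time, imperfection 0.5, 5 m vehicles with 2.5 m minimum gap.
#'
#' @param dt Timestep in seconds.
#' @param max_accel Maximum acceleration, m/s^2.
#' @param max_decel Maximum (comfortable) deceleration used by the safe-speed
#'   rule, m/s^2.
#' @param reaction_time Driver reaction time tau, seconds.
#' @param driver_imperfection Krauss sigma in `[0, 1]`: each step the speed is
#'   reduced by `sigma * max_accel * dt * U`, `U ~ Uniform(0,1)`.
#' @param vehicle_length Vehicle length, metres.
#' @param min_gap Minimum standstill gap between vehicles, metres.
#' @param duration Measured simulation horizon, seconds.
#' @param warmup Warm-up period excluded from all records and metrics,
#'   seconds.
#' @export
sim_params <- function(dt = 1, max_accel = 2.6, max_decel = 4.5,
                       reaction_time = 1, driver_imperfection = 0.5,
                       vehicle_length = 5, min_gap = 2.5,
                       duration = 3600, warmup = 600) {
  stopifnot(dt > 0, max_accel > 0, max_decel > 0, reaction_time >= 0,
            driver_imperfection >= 0, driver_imperfection <= 1,
            vehicle_length > 0, min_gap >= 0, duration > 0, warmup >= 0)
  structure(list(dt = dt, max_accel = max_accel, max_decel = max_decel,
                 reaction_time = reaction_time,
                 driver_imperfection = driver_imperfection,
                 vehicle_length = vehicle_length, min_gap = min_gap,
                 duration = duration, warmup = warmup),
            class = "sim_params")
}

#' Krauss safe speed
#'
#' The safe velocity `v_safe = -b*tau + sqrt((b*tau)^2 + v_leader^2 + 2*b*gap)`
#' with `b` the maximum deceleration and `tau` the reaction time. Driving at
#' or below this speed guarantees the follower can avoid a collision even if
#' the leader brakes at `b`.
#'
#' @param leader_speed Leader speed in m/s (vectorised).
#' @param gap Net gap to the leader in metres (>= 0).
#' @param params A [sim_params()].
#' @return Safe speed in m/s.
#' @export
safe_speed <- function(leader_speed, gap, params = sim_params()) {
  if (any(gap < 0)) stop("negative gap: vehicles overlap")
  bt <- params$max_decel * params$reaction_time
  -bt + sqrt(bt^2 + leader_speed^2 + 2 * params$max_decel * gap)
}

#' Behavioural target speed
#'
#' The speed a driver aims for at a given position. Law-abiding drivers (A)
#' always target their DFFS, which is at or below the limit. Telematics-
#' equipped violators are held to the limit everywhere. Kangaroo drivers (B)
#' drop to the limit inside a fixed camera's detection zone or anywhere
#' inside a point-to-point section, and resume their DFFS outside (the
#' distance-halo pattern). Consistent speeders (C) target their DFFS
#' regardless of enforcement.
#'
#' @param driver A list or one-row data frame with `group`, `dffs_kmh`,
#'   `telematics`.
#' @param position Position(s) along the segment in metres.
#' @param layout A [camera_layout()].
#' @param limit Speed limit in km/h.
#' @return Target speed(s) in km/h, same length as `position`.
#' @export
behavioral_target_speed <- function(driver, position, layout, limit = 90) {
  group <- as.character(driver$group)
  if (!group %in% c("A", "B", "C")) stop("unknown driver group: ", group)
  dffs <- driver$dffs_kmh
  if (any(position < 0)) stop("position before segment start")
  if (group == "A") return(rep(dffs, length(position)))
  if (isTRUE(driver$telematics)) return(rep(min(dffs, limit), length(position)))
  if (group == "C") return(rep(dffs, length(position)))
  # group B, unequipped: limit inside enforced zones, DFFS elsewhere
  out <- rep(dffs, length(position))
  for (k in seq_len(nrow(layout$zones))) {
    inz <- position >= layout$zones[k, 1] & position <= layout$zones[k, 2]
    out[inz] <- limit
  }
  out
}

# Shared driver-attribute preparation for the kernel: free speed in m/s
# (already capped for telematics) and the zone-responsive flag.
kernel_driver_args <- function(population, road) {
  limit_ms <- road$speed_limit / 3.6
  v_free <- ifelse(population$telematics,
                   pmin(population$dffs_kmh, road$speed_limit),
                   population$dffs_kmh) / 3.6
  list(v_free = v_free,
       group = match(population$group, c("A", "B", "C")),
       telem = population$telematics,
       responsive = population$group == "B" & !population$telematics,
       limit_ms = limit_ms)
}

#' One simulation step on an explicit world state
#'
#' Applies (optionally) the lane-change pass and one car-following update to
#' a world of vehicles. Exposed mainly so the update rule can be exercised
#' directly; scenario runs go through [run_simulation()].
#'
#' @param world Data frame with columns `vehicle_id`, `driver_id`,
#'   `position_m`, `speed_ms`, `lane` (0-based).
#' @param population Driver attribute table (as from [sample_population()]);
#'   `driver_id` in `world` indexes into it.
#' @param layout A [camera_layout()].
#' @param road A [road_spec()].
#' @param params A [sim_params()].
#' @param lane_change Apply the overtaking rule before the update?
#' @return List with `world` (updated state, exited vehicles flagged),
#'   `records` (trajectory rows emitted this step) and `summary`.
#' @export
sim_step <- function(world, population, layout, road = road_spec(),
                     params = sim_params(), lane_change = TRUE) {
  da <- kernel_driver_args(population, road)
  out <- ms_step_kernel(world, da$v_free, da$group, da$telem, da$responsive,
                        layout$zones, da$limit_ms, road$length, road$lanes,
                        params$dt, params$max_accel, params$max_decel,
                        params$reaction_time, params$driver_imperfection,
                        params$vehicle_length, params$min_gap,
                        road$speed_limit / 3.6, lane_change, TRUE, 0)
  if (out$summary$collisions > 0)
    stop("vehicle overlap detected after step (", out$summary$collisions,
         " violations)")
  list(world = out$world, records = out$trajectories, summary = out$summary)
}

#' Run one scenario
#'
#' Builds the driver population from the scenario composition, pre-generates
#' the Poisson arrival process, and runs warm-up plus measurement horizon.
#' All randomness derives from `scenario$seed`, so a run is fully
#' reproducible. Only records with `time >= warmup` are returned and
#' summarised.
#'
#' @param scenario A [scenario_spec()] (or list with `sec_type`,
#'   `telematics_pct`, `pct_B`, `pct_C`, `demand_vph`, `seed`).
#' @param road A [road_spec()].
#' @param params A [sim_params()].
#' @param record Keep per-step trajectory records? Batch runs set this to
#'   `FALSE` and rely on the accumulated summary, which aggregates the same
#'   per-step quantities.
#' @param unsafe_threshold Speed above which driving counts as unsafe, km/h.
#' @param dffs_params Per-group DFFS distribution parameters.
#' @return Object of class `sim_result`: list with `scenario`,
#'   `trajectories`, `vehicles` (vehicle-to-driver map), `population`,
#'   `summary`, `params`, `road`, `layout`.
#' @export
run_simulation <- function(scenario, road = road_spec(), params = sim_params(),
                           record = TRUE, unsafe_threshold = 90,
                           dffs_params = default_dffs_params()) {
  layout <- camera_layout(scenario$sec_type, road)
  total_t <- params$warmup + params$duration
  n_pop <- max(200L, as.integer(ceiling(scenario$demand_vph * total_t / 3600)))
  if (is.null(scenario$seed)) stop("scenario has no seed")
  set.seed(scenario$seed)
  spec <- population_spec(scenario$pct_B, scenario$pct_C,
                          scenario$telematics_pct,
                          dffs_params = dffs_params,
                          speed_limit = road$speed_limit)
  pop <- sample_population(spec, n_pop)
  # Poisson arrival process over [0, total_t), binned to per-step counts
  nsteps <- as.integer(round(total_t / params$dt))
  rate <- scenario$demand_vph / 3600
  n_arr <- rpois(1, rate * total_t)
  arr_steps <- if (n_arr > 0) {
    t_arr <- runif(n_arr, 0, total_t)
    tabulate(pmin(floor(t_arr / params$dt) + 1L, nsteps), nbins = nsteps)
  } else integer(nsteps)
  da <- kernel_driver_args(pop, road)
  out <- ms_run_kernel(da$v_free, da$group, da$telem, da$responsive,
                       layout$zones, da$limit_ms, road$length, road$lanes,
                       params$dt, params$max_accel, params$max_decel,
                       params$reaction_time, params$driver_imperfection,
                       params$vehicle_length, params$min_gap, params$warmup,
                       as.integer(arr_steps), unsafe_threshold / 3.6, record,
                       scenario$seed)
  if (out$summary$collisions > 0)
    stop("vehicle overlap detected during simulation (",
         out$summary$collisions, " violations)")
  vehicles <- out$vehicles
  vehicles$group <- pop$group[vehicles$driver_id]
  vehicles$dffs_kmh <- pop$dffs_kmh[vehicles$driver_id]
  vehicles$telematics <- pop$telematics[vehicles$driver_id]
  structure(list(scenario = scenario, trajectories = out$trajectories,
                 vehicles = vehicles, population = pop,
                 summary = out$summary, params = params, road = road,
                 layout = layout, unsafe_threshold = unsafe_threshold),
            class = "sim_result")
}

#' Write trajectories to CSV
#'
#' Header `vehicle_id,time_s,position_m,speed_kmh,lane`, one row per vehicle
#' per timestep after warm-up.
#'
#' @param sim A `sim_result` from [run_simulation()].
#' @param path Output file path.
#' @export
write_trajectories <- function(sim, path) {
  write.csv(sim$trajectories, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
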