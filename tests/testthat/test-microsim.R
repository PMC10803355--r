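# Simulator mechanics: geometry, safe-speed rule, behavioural targets,
# the update step, insertion and full-scenario properties.

test_that("camera layouts place cameras and enforcement zones correctly", {
  road <- road_spec()
  expect_equal(camera_layout("FIX1", road)$camera_positions, 3000)
  expect_equal(camera_layout("FIX2", road)$camera_positions, c(2000, 4000))
  expect_equal(camera_layout("FIX3", road)$camera_positions,
               c(1500, 3000, 4500))
  p2p <- camera_layout("P2P", road)
  expect_equal(p2p$p2p_section, c(1500, 4500))
  expect_equal(unname(p2p$zones[1, ]), c(1500, 4500))
  fix3 <- camera_layout("FIX3", road)
  expect_equal(unname(fix3$zones[, 1]), c(1350, 2850, 4350))
  expect_error(camera_layout("FIX9"))
})

test_that("safe speed matches the closed form and rejects overlap", {
  p <- sim_params()  # decel 4.5, tau 1
  expect_identical(safe_speed(0, 0, p), 0)
  # -4.5 + sqrt(4.5^2 + 0 + 2*4.5*10) = -4.5 + sqrt(110.25) = 6
  expect_equal(safe_speed(0, 10, p), 6, tolerance = 1e-12)
  expect_error(safe_speed(0, -1, p), "negative gap")
  # monotone in gap and leader speed
  g <- seq(0, 100, by = 5)
  expect_true(all(diff(safe_speed(10, g, p)) > 0))
  expect_true(all(safe_speed(20, 10, p) > safe_speed(10, 10, p)))
})

test_that("behavioural target speed implements the three driver classes", {
  road <- road_spec()
  fix1 <- camera_layout("FIX1", road)   # camera 3000, zone [2850, 3000]
  p2p <- camera_layout("P2P", road)
  b <- list(group = "B", dffs_kmh = 105, telematics = FALSE)
  b_tel <- list(group = "B", dffs_kmh = 105, telematics = TRUE)
  c_ <- list(group = "C", dffs_kmh = 115, telematics = FALSE)
  a <- list(group = "A", dffs_kmh = 84, telematics = FALSE)

  # kangaroo: limit inside the detection zone, DFFS before and after
  expect_equal(behavioral_target_speed(b, 2900, fix1), 90)
  expect_equal(behavioral_target_speed(b, 3100, fix1), 105)
  expect_equal(behavioral_target_speed(b, 2700, fix1), 105)
  # consistent speeder ignores every layout
  expect_equal(behavioral_target_speed(c_, c(100, 2900, 5900), fix1),
               rep(115, 3))
  expect_equal(behavioral_target_speed(c_, 3000, p2p), 115)
  # telematics enforcement holds violators to the limit everywhere
  expect_equal(behavioral_target_speed(b_tel, c(0, 2900, 5000), fix1),
               rep(90, 3))
  # law-abiding drivers keep their (sub-limit) DFFS
  expect_equal(behavioral_target_speed(a, c(0, 2900), fix1), c(84, 84))
  # P2P caps kangaroo drivers across the whole section
  expect_equal(behavioral_target_speed(b, c(1400, 1500, 3000, 4500, 4600), p2p),
               c(105, 90, 90, 90, 105))
  expect_error(behavioral_target_speed(list(group = "X", dffs_kmh = 100,
                                            telematics = FALSE), 0, fix1),
               "unknown driver group")
})

test_that("the update step has the free-flow fixed point and the safe bound", {
  road <- road_spec()
  layout <- camera_layout("FIX1", road)
  p <- sim_params(driver_imperfection = 0)
  drivers <- one_driver(group = "C", dffs_kmh = 108)  # 30 m/s, no braking

  # free flow: speed stays at DFFS, position advances by v*dt
  w <- world_row(1, 1, 1000, 30)
  out <- sim_step(w, drivers, layout, road, p)
  expect_equal(out$world$speed_ms, 30)
  expect_equal(out$world$position_m, 1030)

  # follower 10 m behind a stationary leader is capped by the safe speed
  # (leader pinned by a zero target speed)
  drivers2 <- data.frame(driver_id = 1:2, group = c("A", "C"),
                         dffs_kmh = c(0, 108), telematics = FALSE)
  w2 <- rbind(world_row(1, 1, 117.5, 0),  # leader, net gap 10 m
              world_row(2, 2, 100, 30))
  out2 <- sim_step(w2, drivers2, layout, road, p, lane_change = FALSE)
  follower <- out2$world[out2$world$vehicle_id == 2, ]
  expect_lte(follower$speed_ms, 6.0 + 1e-9)
  # spacing invariant intact
  expect_gte(out2$world$position_m[1] - follower$position_m,
             p$vehicle_length + p$min_gap)

  # exit rule: position beyond the segment end removes the vehicle
  w3 <- world_row(1, 1, 5995, 30)
  out3 <- sim_step(w3, drivers, layout, road, p)
  expect_true(out3$world$exited)
  expect_gt(out3$world$position_m, road$length)
})

test_that("arrivals follow the demand rate and zero demand inserts nothing", {
  p <- quick_params(duration = 3000, warmup = 600, sigma = 0)
  sim <- run_simulation(scenario_spec("FIX1", 0, 0, 0, 3600, seed = 2),
                        params = p, record = FALSE)
  # Poisson mean 3600 over the hour, SD 60; allow 3 SD plus residual queue
  expect_lt(abs(sim$summary$inserted + sim$summary$queued - 3600), 200)

  sim0 <- run_simulation(scenario_spec("FIX1", 0, 0, 0, 0, seed = 2),
                         params = quick_params(), record = FALSE)
  expect_equal(sim0$summary$inserted, 0)
})

test_that("a jammed entry defers insertion without creating overlap", {
  road <- road_spec(length = 400)
  p <- quick_params(duration = 300, warmup = 0, sigma = 0)
  sim <- run_simulation(scenario_spec("FIX1", 0, 0, 0, 12000, seed = 4),
                        road = road, params = p)
  expect_gt(sim$summary$queued, 0)
  expect_equal(sim$summary$collisions, 0)
  expect_equal(sim$summary$inserted,
               sim$summary$exited + sim$summary$on_road)
})

test_that("a scenario run is deterministic given its seed", {
  p <- quick_params()
  sc <- scenario_spec("P2P", 5, 30, 3, 800, seed = 21)
  a <- run_simulation(sc, params = p)
  b <- run_simulation(sc, params = p)
  expect_identical(a$trajectories, b$trajectories)
  expect_identical(a$population, b$population)
  sc2 <- scenario_spec("P2P", 5, 30, 3, 800, seed = 22)
  c_ <- run_simulation(sc2, params = p)
  expect_false(identical(a$trajectories, c_$trajectories))
})

test_that("an all-law-abiding fleet never exceeds the limit", {
  sim <- run_simulation(scenario_spec("FIX1", 0, 0, 0, 1000, seed = 5),
                        params = quick_params())
  expect_lte(max(sim$trajectories$speed_kmh), 90)
  expect_equal(compute_rud(sim$trajectories), 0)
})

test_that("kangaroo drivers comply at the camera and rebound after it", {
  p <- quick_params(duration = 1200, warmup = 300, sigma = 0)
  sim <- run_simulation(scenario_spec("FIX1", 0, 100, 0, 500, seed = 9),
                        params = p)
  near <- sim$trajectories[sim$trajectories$position_m >= 2950 &
                             sim$trajectories$position_m <= 3000, ]
  expect_gt(nrow(near), 0)
  expect_lte(max(near$speed_kmh), 90 + 1e-9)
  # downstream of the camera, speeds recover above the limit
  after <- sim$trajectories[sim$trajectories$position_m > 3300 &
                              sim$trajectories$position_m < 4000, ]
  expect_gt(mean(after$speed_kmh > 90), 0.5)
})

test_that("speeds never exceed the driver's DFFS when imperfection is off", {
  p <- quick_params(sigma = 0)
  sim <- run_simulation(scenario_spec("FIX2", 0, 30, 5, 1500, seed = 13),
                        params = p)
  idx <- match(sim$trajectories$vehicle_id, sim$vehicles$vehicle_id)
  expect_true(all(sim$trajectories$speed_kmh <=
                    sim$vehicles$dffs_kmh[idx] + 1e-9))
  expect_true(all(sim$trajectories$speed_kmh >= 0))
})
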