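# arena geometry, zone assignment, occupancy, bouts, velocity, trigger mask

test_that("open-field zone assignment follows the three-zone geometry", {
  arena <- open_field_arena()
  tr <- still_traj(c(20, 20), 2)
  expect_equal(unique(assign_zones(tr, arena)$zone), "center")
  expect_equal(unique(assign_zones(still_traj(c(2, 20), 2), arena)$zone),
               "peripheral")
  expect_equal(unique(assign_zones(still_traj(c(8, 20), 2), arena)$zone),
               "middle")
  # boundaries are closed toward the extreme zones
  expect_equal(unique(assign_zones(still_traj(c(10, 20), 2), arena)$zone),
               "center")
  expect_equal(unique(assign_zones(still_traj(c(5, 20), 2), arena)$zone),
               "peripheral")
})

test_that("zone partition is exhaustive and durations conserve trial length", {
  arena <- open_field_arena()
  set.seed(101)
  n <- 500
  tr <- trajectory(seq(0, by = 0.04, length.out = n),
                   runif(n, 0, 40), runif(n, 0, 40), 25)
  z <- assign_zones(tr, arena)
  expect_false(anyNA(z$zone))
  expect_equal(sum(zone_durations(z)), n * 0.04, tolerance = 0.04 / (n * 0.04))
  # brute-force frame tally oracle
  wall <- pmin(tr$x_cm, 40 - tr$x_cm, tr$y_cm, 40 - tr$y_cm)
  in_center <- tr$x_cm >= 10 & tr$x_cm <= 30 & tr$y_cm >= 10 & tr$y_cm <= 30
  expect_equal(unname(zone_durations(z)["center"]), sum(in_center) * 0.04)
  expect_equal(unname(zone_durations(z)["peripheral"]),
               sum(!in_center & wall <= 5) * 0.04)
})

test_that("out-of-bounds samples are flagged and excluded from durations", {
  arena <- open_field_arena()
  t <- seq(0, 1, by = 0.04)
  x <- rep(20, length(t)); x[3] <- 45   # beyond the 1-cm tolerance
  tr <- trajectory(t, x, rep(20, length(t)), 25)
  expect_message(z <- assign_zones(tr, arena), "out of bounds")
  expect_identical(attr(z, "n_flagged"), 1L)
  expect_true(is.na(z$zone[3]))
  expect_equal(sum(zone_durations(z)), (length(t) - 1) * 0.04)
})

test_that("EPM zones label arms, center and respect arm precedence", {
  arena <- epm_arena()
  mid <- 32.5
  expect_equal(unique(assign_zones(still_traj(c(10, mid), 2), arena)$zone),
               "open_arm_1")
  expect_equal(unique(assign_zones(still_traj(c(55, mid), 2), arena)$zone),
               "open_arm_2")
  expect_equal(unique(assign_zones(still_traj(c(mid, 10), 2), arena)$zone),
               "closed_arm_1")
  expect_equal(unique(assign_zones(still_traj(c(mid, 55), 2), arena)$zone),
               "closed_arm_2")
  expect_equal(unique(assign_zones(still_traj(c(mid, mid), 2), arena)$zone),
               "epm_center")
  # center/arm boundary belongs to the arm
  expect_equal(unique(assign_zones(still_traj(c(30, mid), 2), arena)$zone),
               "open_arm_1")
})

test_that("occupancy summary conserves epoch durations and is additive", {
  arena <- open_field_arena()
  tr <- still_traj(c(2, 20), duration_s = 600)   # peripheral throughout
  z <- assign_zones(tr, arena)
  occ <- occupancy_summary(z, data.frame(label = "all", start_s = 0,
                                         end_s = 600))
  expect_equal(occ$duration_s[occ$zone == "peripheral"], 600,
               tolerance = 0.04 / 600)
  expect_equal(sum(occ$duration_s[occ$zone != "peripheral"]), 0)
  # two epochs splitting the session sum to the full-session durations
  occ2 <- occupancy_summary(z, data.frame(label = c("a", "b"),
                                          start_s = c(0, 300),
                                          end_s = c(300, 600)))
  tot <- tapply(occ2$duration_s, occ2$zone, sum)
  expect_equal(unname(tot["peripheral"]),
               occ$duration_s[occ$zone == "peripheral"])
  expect_warning(
    occupancy_summary(z, data.frame(label = "empty", start_s = 100.001,
                                    end_s = 100.02)),
    "no frames")
})

test_that("approach-retreat detection finds a single clean excursion", {
  arena <- open_field_arena()
  # straight in from the wall and back out: 20 -> 2 cm -> 20
  tr <- waypoint_traj(c(0, 5, 10, 14, 19), c(2, 2, 18, 2, 2),
                      c(20, 20, 20, 20, 20))
  b <- detect_approach_retreat(tr, arena)
  expect_equal(sum(b$label == "approach"), 1)
  expect_equal(sum(b$label == "retreat"), 1)
  app <- b[b$label == "approach", ]; ret <- b[b$label == "retreat", ]
  expect_equal(app$end_s, 10, tolerance = 0.1)
  expect_equal(ret$start_s, app$end_s)
  expect_lt(abs(app$start_s - 5), 0.2)
})

test_that("stationary animals yield no bouts and short traces error", {
  arena <- open_field_arena()
  expect_equal(nrow(detect_approach_retreat(still_traj(), arena)), 0)
  t <- seq(0, 0.2, by = 0.04)
  tr <- trajectory(t, rep(2, length(t)), rep(2, length(t)), 25)
  expect_error(detect_approach_retreat(tr, arena), "shorter")
})

test_that("detector recovers planted bouts with frame-level onsets", {
  # three planted excursions on a piecewise-linear track
  times <- c(0, 10, 11.2, 12.4, 25, 26.2, 27.4, 40, 41.2, 42.4, 50)
  xs <- c(2, 2, 18, 2, 2, 18, 2, 2, 18, 2, 2)
  tr <- waypoint_traj(times, xs, rep(20, length(times)))
  b <- detect_approach_retreat(tr, open_field_arena())
  app <- b[b$label == "approach", ]
  expect_equal(nrow(app), 3)
  expect_equal(sum(b$label == "retreat"), 3)
  onset_err <- abs(app$start_s - c(10, 25, 40))
  expect_true(all(onset_err <= 2 / 25 + 1e-9))
})

test_that("minimum-interval rule excludes both members of close pairs", {
  b <- bout_table(rep("approach", 2), c(0, 2.5), c(2, 4))   # gap 0.5 s
  expect_equal(nrow(enforce_min_interval(b)), 0)
  b2 <- bout_table(rep("approach", 2), c(0, 7), c(2, 9))    # gap 5 s
  expect_equal(nrow(enforce_min_interval(b2)), 2)
  # boundary: a gap of exactly 1 s is retained (strict less-than)
  b3 <- bout_table(rep("approach", 2), c(0, 3), c(2, 5))
  expect_equal(nrow(enforce_min_interval(b3, 1)), 2)
  expect_error(enforce_min_interval(b3, -1), "nonnegative")
})

test_that("minimum-interval filtering is idempotent and label-scoped", {
  set.seed(7)
  starts <- sort(runif(20, 0, 100))
  ends <- starts + 0.4
  lab <- rep(c("approach", "retreat"), 10)
  b <- bout_table(lab, starts, ends)
  f1 <- enforce_min_interval(b)
  f2 <- enforce_min_interval(f1)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
})

test_that("velocity matches closed-form and brute-force oracles", {
  # straight 60-cm path: fixed-window velocity = 60/30
  tr <- line_traj(c(2, 2), c(2, 62), duration_s = 30)
  expect_equal(compute_velocity(tr, "fixed_window"), 2)
  # moving-time mode on a walk with a long pause
  t <- seq(0, 20, by = 0.04)
  x <- c(seq(2, 27, length.out = 251), rep(27, 250))   # 10 s walk, 10 s still
  tr2 <- trajectory(t, x, rep(5, length(t)), 25)
  v <- compute_velocity(tr2, "moving_time")
  # brute-force oracle: total path / time of frames moving > 1 cm/s
  step <- sqrt(diff(x)^2)
  sp <- stats::filter(step / 0.04, rep(1 / 12, 12), sides = 2)
  mt <- sum(0.04 * (!is.na(sp) & sp > 1))
  expect_equal(v, sum(step) / mt)
  expect_warning(v0 <- compute_velocity(still_traj(), "moving_time"),
                 "zero moving time")
  expect_true(is.na(v0))
})

test_that("trigger mask equals brute-force zone membership with clean edges", {
  arena <- open_field_arena()
  # 30 s peripheral, 10 s center, 20 s peripheral
  tr <- waypoint_traj(c(0, 29, 30, 40, 41, 60),
                      c(2, 2, 20, 20, 2, 2), rep(20, 6))
  z <- assign_zones(tr, arena)
  tm <- trigger_mask(z, c("center", "middle"), c(0, 60))
  oracle <- !is.na(z$zone) & z$zone %in% c("center", "middle") &
    z$time_s >= 0 & z$time_s < 60
  expect_identical(tm$mask, oracle)
  expect_equal(nrow(tm$edges), 1)
  expect_equal(tm$edges$off_s - tm$edges$on_s, 12, tolerance = 0.2)
  # all-peripheral animal never triggers
  tm2 <- trigger_mask(assign_zones(still_traj(c(2, 20), 10), arena),
                      c("center", "middle"), c(0, 10))
  expect_false(any(tm2$mask))
  expect_error(trigger_mask(z, c("center"), c(100, 200)), "outside")
  expect_error(trigger_mask(z, c("nowhere"), c(0, 10)), "valid zone")
})

test_that("trajectory and bout constructors validate their invariants", {
  expect_error(trajectory(c(0, 0.04, 0.04), 1:3, 1:3, 25), "increasing")
  expect_error(trajectory(seq(0, 1, 0.04), 1:26, 1:26, 50), "frame_rate")
  expect_error(bout_table("approach", 2, 1), "start_s < end_s")
  expect_error(bout_table(c("approach", "approach"), c(0, 1), c(2, 3)),
               "overlap")
  expect_error(bout_table("nap", 0, 1), "unknown bout label")
  expect_error(open_field_arena(center_side_cm = 35), "zones overlap")
})
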