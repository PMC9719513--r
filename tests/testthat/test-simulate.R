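# synthetic-data generator: determinism, ground truth, planted-parameter
# behavior; heavier parameter-recovery checks live in test-acceptance.R

small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed,
             session = list(duration_s = 400, object_in_s = 200,
                            photometry_rate_hz = 100, epm_duration_s = 300),
             ...)
}

test_that("the whole bundle is deterministic given the seed", {
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  cfg <- small_cfg(seed = 5)
  m1 <- make_fixture_bundle(cfg, d1, overwrite = TRUE)
  m2 <- make_fixture_bundle(cfg, d2, overwrite = TRUE)
  files <- sort(list.files(d1))
  expect_true(length(files) >= 7)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  # manifest records row counts for every csv
  expect_true(all(vapply(m1$files, is.numeric, logical(1))))
  expect_error(make_fixture_bundle(cfg, d1), "overwrite")
})

test_that("bundles round-trip through the readers", {
  d <- file.path(tempdir(), "bundle_rt")
  on.exit(unlink(d, recursive = TRUE))
  cfg <- small_cfg(seed = 9)
  make_fixture_bundle(cfg, d, overwrite = TRUE)
  tr <- read_trajectory(file.path(d, "trajectory.csv"))
  expect_s3_class(tr, "trajectory")
  of <- simulate_open_field_session(cfg)
  expect_equal(nrow(tr), nrow(of$traj))
  expect_equal(tr$x_cm, of$traj$x_cm, tolerance = 1e-4)
  b <- read_bouts(file.path(d, "bouts.csv"))
  expect_equal(nrow(b), nrow(of$bouts))
  fl <- read_fluor(file.path(d, "fluorescence.csv"))
  expect_s3_class(fl, "fluor_trace")
  sp <- read_spikes(file.path(d, "spikes.csv"), duration_s = 700)
  expect_s3_class(sp, "spike_set")
  ct <- read_catfish(file.path(d, "catfish.csv"))
  expect_s3_class(ct, "catfish_counts")
})

test_that("planted bout schedule responds to the bout rate", {
  cfg0 <- small_cfg(seed = 2, behavior = list(bout_rate_per_min = 0))
  expect_equal(nrow(simulate_open_field_session(cfg0)$bouts), 0)
  cfg2 <- small_cfg(seed = 2)
  of <- simulate_open_field_session(cfg2)
  expect_gt(sum(of$bouts$label == "approach"), 0)
  # every planted approach ends approach_depth_cm from the object
  app <- of$bouts[of$bouts$label == "approach", ]
  i <- vapply(app$end_s, function(s) which.min(abs(of$traj$time_s - s)),
              integer(1))
  dist <- sqrt((of$traj$x_cm[i] - 20)^2 + (of$traj$y_cm[i] - 20)^2)
  expect_true(all(abs(dist - 3) < 0.5))
  # all bouts lie in the post-object epoch
  expect_true(all(app$start_s >= of$object_epoch[1]))
})

test_that("wall preference raises post-object peripheral time", {
  t_peri <- vapply(c(0.35, 0.95), function(w) {
    cfg <- small_cfg(seed = 31, behavior = list(
      wall_preference_weight = w, bout_rate_per_min = 0))
    of <- simulate_open_field_session(cfg)
    z <- assign_zones(of$traj, of$arena)
    occ <- occupancy_summary(z, data.frame(label = "post",
                                           start_s = of$object_epoch[1],
                                           end_s = of$object_epoch[2]))
    occ$duration_s[occ$zone == "peripheral"]
  }, numeric(1))
  expect_gt(t_peri[2], t_peri[1])
})

test_that("detector recovers planted bouts on the generated session", {
  cfg <- sim_config(seed = 601)
  of <- simulate_open_field_session(cfg)
  det <- detect_approach_retreat(of$traj, of$arena)
  da <- det[det$label == "approach", ]
  gt <- of$bouts[of$bouts$label == "approach", ]
  tol <- 2 / frame_rate(of$traj)
  hits <- vapply(gt$start_s, function(s)
    any(abs(da$start_s - s) <= tol + 1e-9), logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("plus-maze avoidance and progressive slope shape open-arm time", {
  cfg1 <- small_cfg(seed = 3, behavior = list(epm_open_avoidance = 1))
  epm1 <- simulate_epm_session(cfg1)
  z1 <- zone_durations(assign_zones(epm1$traj, epm1$arena))
  expect_equal(sum(z1[c("open_arm_1", "open_arm_2")]), 0)
  # durations always partition the session
  cfg2 <- small_cfg(seed = 3)
  epm2 <- simulate_epm_session(cfg2)
  z2 <- zone_durations(assign_zones(epm2$traj, epm2$arena))
  dur <- epm2$traj$time_s[nrow(epm2$traj)]
  expect_equal(sum(z2), dur, tolerance = 2 / (25 * dur))
  # declining open-arm entry probability: first-half entries >= second-half
  # in expectation (checked over seeds)
  halves <- vapply(1:40, function(s) {
    cfg <- small_cfg(seed = s, behavior = list(epm_open_avoidance = 0.5,
                                               epm_progressive_slope = 1))
    ep <- simulate_epm_session(cfg)
    h <- cfg$session$epm_duration_s / 2
    c(sum(ep$open_entry_times < h), sum(ep$open_entry_times >= h))
  }, numeric(2))
  expect_gt(mean(halves[1, ]), mean(halves[2, ]))
})

test_that("calcium generator ties transients to planted turning points", {
  cfg <- small_cfg(seed = 17)
  of <- simulate_open_field_session(cfg)
  cal <- simulate_calcium(of$traj, cfg, of$arena, of$object_epoch,
                          bouts = of$bouts)
  gt <- cal$ground_truth
  expect_equal(nrow(gt), sum(of$bouts$label == "approach"))
  # convolved-drive peak within one kernel width of each turning point
  expect_true(all(abs(gt$peak_s - gt$turn_s) <=
                  cfg$calcium$kernel_decay_s + cfg$calcium$kernel_rise_s))
  expect_true(all(gt$peak_amp > 0))
  # EYFP mode: zero drive, noise-only fluctuations around the bleach curve
  cfg0 <- small_cfg(seed = 17, calcium = list(distance_gain = 0,
                                              noise_sd = 0))
  cal0 <- simulate_calcium(of$traj, cfg0, of$arena, of$object_epoch)
  pure <- exp(-cal0$trace$time_s / cfg0$calcium$bleach_tau_s) * 100
  expect_equal(cal0$trace$F_raw, pure, tolerance = 1e-12)
  adj <- detrend_trace(cal0$trace)
  dff <- compute_dff(adj, baseline_spec("open_field_pre_object",
                                        stimulus_in_s = 200))
  expect_lt(max(abs(dff$dff)), 0.005)
})

test_that("spike generator controls tuning and ensemble construction", {
  ev <- list(object_approach = seq(50, 560, by = 30),
             open_arm_entry = seq(600, 1000, by = 25))
  # unit gain leaves no detectable tuning
  cfg1 <- sim_config(seed = 41, spikes = list(event_gain = 1, n_units = 40))
  s1 <- simulate_spikes(ev, cfg1, 1100)
  calls1 <- classify_all_units(s1$spikes, ev$object_approach,
                               "object_approach")
  expect_lt(mean(calls1$class == "excited"), 0.12)
  # rho extremes: 1 nests B in A, 0 makes the ensembles disjoint
  cfgN <- sim_config(seed = 43, spikes = list(overlap_rho = 1, n_units = 300,
                                              tuned_fraction_A = 0.4,
                                              tuned_fraction_B = 0.3))
  sN <- simulate_spikes(ev, cfgN, 1100)
  expect_true(all(sN$labels$in_A[sN$labels$in_B]))
  cfg0 <- sim_config(seed = 43, spikes = list(overlap_rho = 0, n_units = 300,
                                              tuned_fraction_A = 0.4,
                                              tuned_fraction_B = 0.3))
  s0 <- simulate_spikes(ev, cfg0, 1100)
  expect_equal(sum(s0$labels$in_A & s0$labels$in_B), 0)
  # marginal tuned fraction of A is preserved under overlap
  expect_equal(mean(sN$labels$in_A), 0.4, tolerance = 0.08)
  expect_error(
    simulate_spikes(ev, sim_config(seed = 1, spikes = list(
      overlap_rho = 1, tuned_fraction_A = 0.2, tuned_fraction_B = 0.5)),
      1100),
    "infeasible")
})

test_that("catfish generator hits its conditional overlap and feasibility", {
  cfg <- sim_config(seed = 77, catfish = list(conditional_overlap_q = 1,
                                              n_animals = 2))
  ct <- simulate_catfish(cfg)
  expect_true(all(ct$n_both == ct$n_intron))
  expect_error(simulate_catfish(sim_config(seed = 1, catfish = list(
    p_first = 0.1, conditional_overlap_q = 0.9, p_second_marginal = 0.2))),
    "infeasible")
  # groups cycle over the animals
  expect_equal(ct$group, c("O-F", "F-O"))
})
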