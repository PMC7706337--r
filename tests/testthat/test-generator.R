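test_that("latent states encode the programmed stress trajectory", {
  des <- build_design("MAIN")
  cfg <- generator_config(seed = 3)
  traj <- simulate_latent_states(cfg, des)
  d <- traj$daily
  s0 <- stress_start_day(des)
  # 15% height deficit by stress day 6
  d6 <- d[d$day == s0 + 6, ]
  ratio <- mean(d6$height[d6$group == "stressed"]) /
    mean(d6$height[d6$group == "control"])
  expect_equal(ratio, 0.85, tolerance = 0.03)
  # control hydration constant over the full run
  for (p in split(d[d$group == "control", ], d$plant_id[d$group == "control"])) {
    if (!nrow(p)) next
    expect_lt(diff(range(p$hydration)), 1e-9)
  }
  # control biomass monotone non-decreasing
  for (p in split(d[d$group == "control", ], d$plant_id[d$group == "control"])) {
    if (!nrow(p)) next
    expect_true(all(diff(p$biomass) >= -1e-9))
  }
  # stressed biomass ends below control with no crossover after rewatering
  last_days <- d[d$day >= min(rewatered_days(des)), ]
  by_day <- split(last_days, last_days$day)
  for (dd in by_day) {
    expect_lt(mean(dd$biomass[dd$group == "stressed"]),
              mean(dd$biomass[dd$group == "control"]))
  }
  # bounded fields stay in bounds
  expect_true(all(d$hydration >= 0 & d$hydration <= 1))
  expect_true(all(d$chlorosis_frac >= 0 & d$chlorosis_frac <= 1))
  expect_true(all(d$turgor >= 0 & d$turgor <= 1))
})

test_that("same seed reproduces latent states, traces and physiology exactly", {
  des <- tiny_design()
  a <- simulate_latent_states(tiny_config(seed = 9), des)
  b <- simulate_latent_states(tiny_config(seed = 9), des)
  expect_identical(a$daily, b$daily)
  expect_identical(synthesize_sensor_trace(a), synthesize_sensor_trace(b))
  expect_identical(sample_physiology(a), sample_physiology(b))
  c2 <- simulate_latent_states(tiny_config(seed = 10), des)
  expect_false(identical(a$daily, c2$daily))
})

test_that("sensor trace realizes the saturating ion response and diurnal cycle", {
  des <- tiny_design(duration_days = 6L, stress_start = 2L, rewater = 5L)
  cfg <- tiny_config(noise_sd_sensor = 0, diurnal_amplitude = 0)
  traj <- simulate_latent_states(cfg, des)
  # constant ion concentration, zero noise, zero diurnal -> R constant
  ctl <- traj$plants$plant_id[traj$plants$group == "control"][1]
  tr <- synthesize_sensor_trace(traj)
  r <- compute_response(tr)
  rc <- r$r[r$plant_id == ctl]
  expect_lt(diff(range(rc)), 1e-12)
  # doubling the concentration increases |R| everywhere (monotone g)
  cfull <- generator_config()
  conc <- c(0.01, 0.02, 0.05, 0.1, 0.2)
  g1 <- phytosense:::ion_response(conc, cfull)
  g2 <- phytosense:::ion_response(2 * conc, cfull)
  expect_true(all(abs(g2) > abs(g1)))
  # direct evaluation of the saturating log form
  expect_equal(g1, cfull$r_baseline *
                 log10(1 + conc / cfull$ion_half_sat) /
                 log10(1 + cfull$ion_baseline / cfull$ion_half_sat))
})

test_that("daytime response is below nighttime response on every cycle", {
  des <- tiny_design(duration_days = 4L, photoperiod_h = 12)
  cfg <- tiny_config(noise_sd_sensor = 0)
  traj <- simulate_latent_states(cfg, des)
  tr <- synthesize_sensor_trace(traj)
  r <- compute_response(tr)
  one <- r[r$plant_id == r$plant_id[1], ]
  hod <- (one$time_min / 60) %% 24
  for (day in 0:3) {
    sel <- floor(one$time_min / 1440) == day
    expect_lt(mean(one$r[sel & hod < 12]), mean(one$r[sel & hod >= 12]))
  }
})

test_that("incompatible sampling interval is rejected", {
  des <- tiny_design(sampling_interval_min = 7)  # does not divide 1440
  cfg <- tiny_config()
  traj <- simulate_latent_states(cfg, des)
  expect_error(synthesize_sensor_trace(traj), "divide")
})

test_that("physiology tables carry the programmed effect sizes", {
  des <- build_design("MAIN")
  cfg <- generator_config(seed = 5)
  traj <- simulate_latent_states(cfg, des)
  ph <- sample_physiology(traj)
  # replicate counts: SC 2 leaves, RWC 2 reps, SPAD 10 leaves
  cnt <- table(ph$measure[ph$plant_id == ph$plant_id[1] & ph$day == 8])
  expect_equal(as.integer(cnt[c("SC", "FW", "SPAD")]), c(2L, 2L, 10L))
  summ <- physio_summary(ph)
  # 4-5 fold SC reduction at stress day 13 (day 14 of the run)
  expect_true(summ$sc$fold[summ$sc$day == 14] >= 4 &&
                summ$sc$fold[summ$sc$day == 14] <= 5)
  # RWC restored after rewatering
  rw <- summ$rwc_group
  expect_lt(abs(rw$drop_frac[rw$day == 22]), 0.05)
  expect_gt(rw$drop_frac[rw$day == 14], 0.15)
  # SPAD raised under stress
  sp <- summ$spad[summ$spad$day == 12, ]
  expect_gt(mean(sp$relative_spad[sp$group == "stressed"]), 1)
})

test_that("null effects produce identical group distributions", {
  des <- tiny_design()
  cfg <- null_generator_config(seed = 2, noise_sd_physio = 0, rwc_noise_sd = 0,
                               spad_noise_sd = 0)
  traj <- simulate_latent_states(cfg, des)
  ph <- sample_physiology(traj)
  sc <- ph[ph$measure == "SC", ]
  scw <- reshape(aggregate(value ~ day + group, sc, mean), idvar = "day",
                 timevar = "group", direction = "wide")
  expect_equal(scw$value.stressed, scw$value.control)
})
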