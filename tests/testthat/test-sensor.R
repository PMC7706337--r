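test_that("sensor response follows (Ids - Ids0)/Ids0", {
  tr <- data.frame(plant_id = "p", time_min = c(0, 15, 30),
                   i_ds_uA = c(-5, -6, -4.5), i_ds0_uA = c(-5, -5, -5))
  r <- compute_response(tr)
  expect_equal(r$r, c(0, 0.2, -0.1))
  # scale invariance: both currents scaled by any c != 0 leave R unchanged
  for (cc in c(2, -0.3, 1e3)) {
    tr2 <- transform(tr, i_ds_uA = i_ds_uA * cc, i_ds0_uA = i_ds0_uA * cc)
    expect_equal(compute_response(tr2)$r, r$r)
  }
})

test_that("response guards: zero baseline dropped, bad traces rejected", {
  tr <- data.frame(plant_id = "p", time_min = c(0, 15, 30),
                   i_ds_uA = c(-6, -6, -6), i_ds0_uA = c(-5, 0, -5))
  r <- compute_response(tr)
  expect_equal(nrow(r), 2L)
  expect_equal(attr(r, "n_dropped"), 1L)
  expect_error(compute_response(tr[0, ]), "empty")
  expect_error(compute_response(transform(tr, i_ds0_uA = 0)), "all samples")
  expect_error(compute_response(transform(tr, time_min = c(0, 0, 30))),
               "strictly increasing")
})

test_that("daily means average 24 h windows and flag partial days", {
  des <- tiny_design(sampling_interval_min = 60)
  t_min <- seq(0, 2 * 1440 - 60, by = 60)  # two full days
  # constant series
  resp <- data.frame(plant_id = "p", time_min = t_min, r = -0.4)
  dm <- daily_mean(resp, des)
  expect_equal(dm$r_mean, c(-0.4, -0.4))
  # zero-mean sinusoid with exact-period sampling averages to ~0
  resp$r <- sin(2 * pi * t_min / 1440)
  dm <- daily_mean(resp, des)
  expect_true(all(abs(dm$r_mean) < 1e-6))
  # 6 h of a third day: flagged incomplete, excluded by default
  extra <- data.frame(plant_id = "p",
                      time_min = seq(2 * 1440, 2 * 1440 + 5 * 60, by = 60),
                      r = 1)
  dm2 <- daily_mean(rbind(resp, extra), des)
  expect_equal(dm2$day, c(0, 1))
  dm3 <- daily_mean(rbind(resp, extra), des, keep_incomplete = TRUE)
  expect_true(dm3$incomplete[dm3$day == 2])
})

test_that("NR is the ratio of group mean daily responses", {
  s <- data.frame(plant_id = rep(c("s1", "s2"), each = 2),
                  day = rep(0:1, 2), r_mean = c(-0.35, -0.25, -0.25, -0.35))
  c0 <- data.frame(plant_id = rep(c("c1", "c2"), each = 2),
                   day = rep(0:1, 2), r_mean = c(-0.2, -0.2, -0.2, -0.2))
  nr <- normalize_nr(s, c0)
  expect_equal(nr$nr, c(1.5, 1.5))  # -0.3 / -0.2
  expect_equal(nr$n_stressed, c(2, 2))
  # null normalization: same group on both sides gives exactly 1
  expect_equal(normalize_nr(c0, c0)$nr, c(1, 1))
  # control mean at zero is masked with a warning
  cz <- transform(c0, r_mean = c(0, -0.2, 0, -0.2))
  expect_warning(nrz <- normalize_nr(s, cz), "masked")
  expect_true(is.na(nrz$nr[1]))
  expect_error(normalize_nr(s, transform(c0, day = day + 10)), "no days")
})

test_that("recovery deficit compares PIII plateau to PI baseline", {
  des <- build_design("MAIN")
  # constructed series: PI at 1, decline, plateau, recovery to 0.6 x PI
  day <- 0:23
  nrv <- c(1, seq(1, 0.4, length.out = 9), rep(0.4, 7), rep(0.6, 7))
  nr <- data.frame(day = day, nr = nrv)
  seg <- segment_phases(nr, des)
  expect_equal(recovery_deficit(nr, seg), 0.6, tolerance = 1e-6)
  # exact return to baseline gives 1
  nr2 <- data.frame(day = day, nr = c(1, seq(1, 0.4, length.out = 9),
                                      rep(0.4, 7), rep(1, 7)))
  expect_equal(recovery_deficit(nr2, segment_phases(nr2, des)), 1,
               tolerance = 1e-6)
})
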