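test_that("enzyme level follows the production/degradation balance", {
  kp <- keitt()
  fs <- fruit_state(F0 = 60, eth = 1.52, ffix = 12.7, enz0 = 0.4)
  # initial condition
  expect_equal(enzyme_level(0, kp, fs, 20), 0.4)
  # no induction: zero ethylene and zero initial enzyme stays at zero
  fs0 <- fruit_state(F0 = 60, eth = 0, ffix = 12.7, enz0 = 0)
  expect_equal(enzyme_level(c(0, 3, 10, 30), kp, fs0, 20), rep(0, 4))
  # monotone rise towards the steady state kfenz*Eth/kd (enz0 = 0)
  fs1 <- fruit_state(F0 = 60, eth = 1.52, ffix = 12.7)
  tk <- 20 + 273.15
  plateau <- arrhenius_rate(kp$kfenz_ref, kp$E_fenz, tk) * 1.52 /
    arrhenius_rate(kp$kd_ref, kp$E_d, tk)
  lev <- enzyme_level(seq(0, 60, by = 2), kp, fs1, 20)
  expect_true(all(diff(lev) > 0))
  expect_equal(lev[length(lev)], plateau, tolerance = 1e-4)
  # long-time level matches the ODE steady state
  ode_lev <- firmness_ode(temp_scenario(60, 20), kp, fs1, 60)$enzyme
  expect_equal(enzyme_level(60, kp, fs1, 20), ode_lev, tolerance = 1e-6)
  expect_error(enzyme_level(-1, kp, fs, 20), ">= 0")
})

test_that("closed form equals the ODE solution at constant temperature", {
  kp <- keitt()
  # published-parameter case: Keitt kinetics at 24 degC
  fs <- fruit_state(F0 = 60, eth = 1.52, ffix = 12.7)
  cf <- firmness_closed_form(8, kp, fs, 24)
  od <- firmness_ode(temp_scenario(16, 24), kp, fs, 8)$firmness_fi
  expect_equal(cf, od, tolerance = 1e-6)
  # full analytical solution with non-zero initial enzyme level
  fs2 <- fruit_state(F0 = 60, eth = 1.52, ffix = 12.7, enz0 = 0.35)
  tt <- seq(0, 12, by = 0.5)
  cf2 <- firmness_closed_form(tt, kp, fs2, 22)
  od2 <- firmness_ode(temp_scenario(12, 22), kp, fs2, tt)$firmness_fi
  expect_equal(cf2, od2, tolerance = 1e-6)
})

test_that("closed form and ODE agree across a random parameter sweep", {
  set.seed(401)
  worst <- 0
  for (i in 1:150) {
    cfg <- random_config()
    tt <- sort(runif(5, 0, cfg$t_end))
    cf <- firmness_closed_form(tt, cfg$kp, cfg$fs, cfg$temp_c)
    od <- firmness_ode(temp_scenario(cfg$t_end + 1, cfg$temp_c),
                       cfg$kp, cfg$fs, tt)$firmness_fi
    worst <- max(worst, max(abs(cf - od)) / cfg$fs$F0)
  }
  expect_lt(worst, 1e-5)
})

test_that("trivial firmness cases hold exactly", {
  kp <- keitt()
  fs <- fruit_state(F0 = 60, eth = 1.52, ffix = 12.7)
  expect_equal(firmness_closed_form(0, kp, fs, 20), 60)
  fs0 <- fruit_state(F0 = 60, eth = 0, ffix = 12.7)
  expect_equal(firmness_closed_form(c(0, 5, 20), kp, fs0, 20), rep(60, 3))
  expect_error(firmness_closed_form(-2, kp, fs, 20), ">= 0")
})

test_that("vanishing enzyme turnover reduces to the quadratic-exponent limit", {
  # as kd -> 0 the exponent tends to -kfenz*Eth*t^2/2
  kp <- kinetic_params(0.099, 1e-9, 0, 0)
  fs <- fruit_state(F0 = 60, eth = 1.52, ffix = 12.7)
  t <- 8
  got <- log((firmness_closed_form(t, kp, fs, 22) - 12.7) / (60 - 12.7))
  expect_equal(got, -0.099 * 1.52 * t^2 / 2, tolerance = 1e-8)
  # continuity across the series/exact branch switch at kd*t = 1e-4:
  # same evaluation time, kd straddling the threshold
  t10 <- 10
  lo <- firmness_closed_form(t10, kinetic_params(0.099, 0.999e-5, 0, 0),
                             fs, 22)
  hi <- firmness_closed_form(t10, kinetic_params(0.099, 1.001e-5, 0, 0),
                             fs, 22)
  expect_equal(lo, hi, tolerance = 1e-5)
})

test_that("firmness is monotone in time, ethylene and temperature", {
  set.seed(402)
  for (i in 1:20) {
    cfg <- random_config()
    tt <- seq(0, cfg$t_end, length.out = 12)
    f <- firmness_closed_form(tt, cfg$kp, cfg$fs, cfg$temp_c)
    expect_true(all(diff(f) <= 1e-12))
    expect_true(all(f <= cfg$fs$F0 + 1e-9))
    expect_true(all(f > cfg$fs$ffix - 1e-9))
    # decreasing in Eth
    fs_hi <- fruit_state(cfg$fs$F0, cfg$fs$eth + 1, cfg$fs$ffix)
    expect_lte(firmness_closed_form(cfg$t_end, cfg$kp, fs_hi, cfg$temp_c),
               f[length(f)] + 1e-12)
  }
  # decreasing in temperature when E_fenz > E_d (softening accelerates)
  kp <- keitt()
  fs <- fruit_state(60, 1.52, 12.7)
  f_by_temp <- vapply(c(10, 17, 24, 30),
                      function(tc) firmness_closed_form(10, kp, fs, tc),
                      numeric(1))
  expect_true(all(diff(f_by_temp) < 0))
})

test_that("ODE trajectories under temperature switches are continuous and shaped correctly", {
  kp <- keitt()
  fs <- fruit_state(F0 = 60, eth = 1.52, ffix = 12.7)
  sc <- temp_scenario(c(3, 10), c(18, 22))
  tt <- seq(0, 13, by = 0.25)
  tr <- firmness_ode(sc, kp, fs, tt)
  expect_s3_class(tr, "firmness_trajectory")
  expect_true(all(diff(tr$firmness_fi) <= 1e-9))
  expect_lt(max(abs(diff(tr$firmness_fi))), 5)  # no jumps at the switch
  # matches the chained analytical solution
  an <- firmness_analytic(sc, kp, fs, tt)
  expect_equal(tr$firmness_fi, an$firmness_fi, tolerance = 1e-6)

  # cold-then-warm storage: slow decline at 8 degC, accelerating at 20 degC
  fs3 <- fruit_state(F0 = 43.8, eth = 0.83, ffix = 3.7)
  sc3 <- temp_scenario(c(21, 10), c(8, 20))
  f <- firmness_ode(sc3, kp, fs3, c(0, 21, 31))$firmness_fi
  drop_cold <- f[1] - f[2]
  drop_warm <- f[2] - f[3]
  expect_lt(drop_cold, 0.35 * f[1])
  expect_gt(drop_warm, drop_cold)

  expect_error(firmness_ode(sc, kp, fs, 14), "beyond")
})

test_that("logged temperature traces integrate and agree with segments", {
  kp <- keitt()
  fs <- fruit_state(F0 = 60, eth = 1.52, ffix = 12.7)
  # constant trace equals the constant-segment solution
  tr_const <- temp_trace(c(0, 16), c(20, 20))
  tt <- seq(0, 16, by = 2)
  expect_equal(firmness_ode(tr_const, kp, fs, tt)$firmness_fi,
               firmness_closed_form(tt, kp, fs, 20), tolerance = 1e-6)
  # a ramp softens between the solutions at its endpoint temperatures
  ramp <- temp_trace(c(0, 16), c(10, 30))
  f_ramp <- firmness_ode(ramp, kp, fs, 16)$firmness_fi
  expect_lt(f_ramp, firmness_closed_form(16, kp, fs, 10))
  expect_gt(f_ramp, firmness_closed_form(16, kp, fs, 30))
})

test_that("ethylene factor reproduces published sub-batch values", {
  keitt <- cultivar_params("Keitt")
  kent <- cultivar_params("Kent")
  expect_equal(ethylene_factor(keitt, 0, temp_scenario(16, 20)), 0)
  # untreated Keitt batch stored 16 d at 20 degC, Eth = 2.23
  expect_equal(round(ethylene_factor(keitt, 2.23, temp_scenario(16, 20)), 3),
               0.138)
  # untreated Ivory Coast Kent sub-batch at 20 degC, Eth = 0.57
  expect_equal(round(ethylene_factor(kent, 0.57, temp_scenario(15, 20)), 3),
               0.332)
  # linear in Eth
  sc <- temp_scenario(c(2.8, 3.2), c(17.8, 13.5))
  expect_equal(ethylene_factor(keitt, 2 * 0.63, sc),
               2 * ethylene_factor(keitt, 0.63, sc))
})
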