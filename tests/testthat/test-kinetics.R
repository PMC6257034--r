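test_that("Arrhenius scaling matches direct evaluation and limiting cases", {
  # at the reference temperature the rate is unchanged
  expect_equal(arrhenius_rate(0.099, 169.9, 295.15), 0.099)
  # zero activation energy gives a temperature-independent rate
  expect_equal(arrhenius_rate(0.219, 0, 283.15), 0.219)
  # frozen value from independent evaluation of k_ref*exp((E/R)(1/Tref-1/T))
  expect_equal(arrhenius_rate(0.099, 169.9, 293.15), 0.0617289, tolerance = 1e-5)
  # increasing in temperature when E > 0
  temps <- seq(275, 315, by = 5)
  expect_true(all(diff(arrhenius_rate(0.5, 100, temps)) > 0))
})

test_that("Arrhenius scaling rejects non-physical inputs", {
  expect_error(arrhenius_rate(-0.1, 100, 290), "positive")
  expect_error(arrhenius_rate(0.1, 100, -5), "positive")
  expect_error(arrhenius_rate(0.1, -1, 290), ">= 0")
})

test_that("packaged cultivar parameter sets load with published values", {
  keitt <- cultivar_params("Keitt")
  expect_equal(keitt$kfenz_ref, 0.099)
  expect_equal(keitt$kd_ref, 0.219)
  expect_equal(keitt$E_fenz, 169.9)
  expect_equal(keitt$E_d, 0.01)
  expect_equal(keitt$t_ref, 295.15)
  kent <- cultivar_params("Kent")
  expect_equal(kent$kfenz_ref, 1)
  expect_equal(kent$E_fenz, 194.5)
  expect_equal(kent$E_d, 162.2)
})

test_that("kinetic_params validates its invariants", {
  expect_error(kinetic_params(0, 0.2, 100, 10), "kfenz_ref")
  expect_error(kinetic_params(0.1, -1, 100, 10), "kd_ref")
  expect_error(kinetic_params(0.1, 0.2, -5, 10), "activation")
  expect_error(kinetic_params(0.1, 0.2, 100, 10, t_ref = 290), "295.15")
})

test_that("time-weighted mean temperature is the duration-weighted average", {
  expect_equal(mean_storage_temp(temp_scenario(16, 20)), 20)
  # two-period scenarios of the Israeli trial
  expect_equal(mean_storage_temp(temp_scenario(c(2.8, 3.2), c(17.8, 13.5))),
               93.04 / 6, tolerance = 1e-10)
  expect_equal(round(mean_storage_temp(temp_scenario(c(2.8, 3.2),
                                                     c(17.8, 13.5))), 2),
               15.51)
  expect_equal(round(mean_storage_temp(temp_scenario(c(3.2, 9.8),
                                                     c(19.8, 22.1))), 2),
               21.53)
  # trapezoidal average of a linear trace equals the midpoint value
  expect_equal(mean_storage_temp(temp_trace(c(0, 10), c(10, 20))), 15)
})

test_that("scenario constructors validate durations and temperature range", {
  expect_error(temp_scenario(numeric(0), numeric(0)), "empty")
  expect_error(temp_scenario(c(2, 0), c(10, 12)), "positive")
  expect_error(temp_scenario(3, 60), "\\[0, 45\\]")
  expect_error(temp_trace(c(0, 1, 1), c(10, 11, 12)), "increasing")
  expect_error(temperature_at(temp_scenario(5, 20), 6), "outside")
})

test_that("temperature lookup is piecewise-constant / piecewise-linear", {
  sc <- temp_scenario(c(3, 10), c(18, 22))
  expect_equal(temperature_at(sc, c(0, 2.9, 3.1, 13)), c(18, 18, 22, 22))
  tr <- temp_trace(c(0, 4, 8), c(8, 8, 20))
  expect_equal(temperature_at(tr, c(2, 6)), c(8, 14))
})

test_that("compact scenario strings parse to scenarios", {
  sc <- parse_scenario("2.8:17.8,3.2:13.5")
  expect_equal(sc$durations, c(2.8, 3.2))
  expect_equal(sc$temps_c, c(17.8, 13.5))
  expect_error(parse_scenario("16"), "dur:temp")
  expect_error(parse_scenario("a:b"), "non-numeric")
})
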