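test_that("noise-free data are recovered exactly", {
  ds <- generate_dataset(small_design(noise_sd = 0), seed = 7)
  fit <- fit_firmness(ds, param_structure(), keitt())
  expect_true(fit$convergence$converged)
  expect_lt(fit$rss, 1e-8)
  expect_equal(coef_table(fit, "eth")$estimate, 1.2, tolerance = 1e-4)
  expect_equal(coef_table(fit, "ffix")$estimate, 12, tolerance = 1e-4)
  f0 <- coef_table(fit, "f0")
  truth <- ds$truth$fruit
  expect_equal(f0$estimate[match(truth$fruit_id, f0$cell)], truth$f0,
               tolerance = 1e-4)
})

test_that("single-fruit F0 estimate matches a brute-force grid search", {
  kp <- keitt()
  sc <- temp_scenario(16, 20)
  set.seed(31)
  tt <- seq(0, 16, by = 2)
  f_true <- fruit_state(F0 = 48.3, eth = 1.2, ffix = 12)
  obs <- firmness_closed_form(tt, kp, f_true, 20) + rnorm(length(tt), 0, 1.5)
  ds <- firmness_dataset(
    data.frame(fruit_id = "f1", batch_id = "b", time_d = tt,
               firmness_fi = obs),
    list(b = sc))
  st <- param_structure(fixed = list(eth = 1.2, ffix = 12))
  fit <- fit_firmness(ds, st, kp)
  # independent oracle: exhaustive 1-D search at 1e-3 FI resolution
  grid <- seq(13, 100, by = 1e-3)
  rss <- vapply(grid, function(F0) {
    sum((obs - firmness_closed_form(tt, kp, fruit_state(F0, 1.2, 12), 20))^2)
  }, numeric(1))
  expect_equal(coef_table(fit, "f0")$estimate, grid[which.min(rss)],
               tolerance = 2e-3)
})

test_that("nested parameter structures never increase the residual sum of squares", {
  dgs <- list(small_design("bA", 10, eth = 1.0, ffix = 12, temp_c = 20,
                           noise_sd = 2),
              small_design("bB", 10, eth = 1.8, ffix = 18, temp_c = 24,
                           noise_sd = 2))
  ds <- generate_dataset(dgs, seed = 21)
  kp <- keitt()
  f_common <- fit_firmness(ds, param_structure(eth = "common",
                                               ffix = "common"), kp)
  warm_b <- list(eth = coef_table(f_common, "eth")$estimate,
                 ffix = coef_table(f_common, "ffix")$estimate)
  f_batch <- fit_firmness(ds, param_structure(eth = "batch", ffix = "batch"),
                          kp, start = warm_b)
  ffix_fix <- setNames(coef_table(f_batch, "ffix")$estimate,
                       coef_table(f_batch, "ffix")$cell)
  f_fruit <- fit_firmness(ds, param_structure(eth = "fruit", ffix = "batch",
                                              fixed = list(ffix = ffix_fix)),
                          kp)
  expect_gte(f_common$rss, f_batch$rss - 1e-6)
  expect_gte(f_batch$rss, f_fruit$rss - 1e-6)
})

test_that("confounded parameter structures are rejected with a named pair", {
  ds <- generate_dataset(small_design(), seed = 3)
  expect_error(
    fit_firmness(ds, param_structure(kinetics = "free_all"), keitt()),
    "kfenz_ref.*eth.*unidentifiable")
  # activation energies need a temperature contrast
  expect_error(
    fit_firmness(ds, param_structure(kinetics = "free"), keitt()),
    "2 distinct")
})

test_that("standard errors calibrate Wald intervals for the ethylene driver", {
  # modest replicate count; the full calibration runs in the acceptance suite
  kp <- keitt()
  hits <- 0L
  nrep <- 20L
  for (r in seq_len(nrep)) {
    ds <- generate_dataset(small_design(n_fruit = 15, noise_sd = 1,
                                        eth = 1.52, ffix = 12.7),
                           seed = 400 + r)
    fit <- fit_firmness(ds, param_structure(), kp,
                        control = fit_control(n_starts = 2))
    e <- coef_table(fit, "eth")
    expect_gt(e$se, 0)
    if (abs(e$estimate - 1.52) <= qnorm(0.975) * e$se) hits <- hits + 1L
  }
  expect_gte(hits, 15L)
})

test_that("adjusted R2 follows the percentage-variance-accounted-for definition", {
  obs <- c(50, 42, 35, 30, 26, 24)
  expect_equal(adjusted_r2(obs, obs, 3), 100)
  expect_equal(adjusted_r2(obs, rep(mean(obs), 6), 1), 0)
  expect_error(adjusted_r2(obs, obs, 6), "more observations")
})

test_that("fits at the published residual-noise regime land in the published R2 band", {
  # the study's batch fits report 86-95% variance accounted for; the
  # matching total residual scale for the four-temperature design is
  # ~6 FI (see the methods vignette)
  kp <- keitt()
  ds <- generate_dataset(design_preset("keitt_batch2", noise_sd = 6),
                         seed = 2024)
  fit <- fit_firmness(ds, param_structure(eth = "group", ffix = "group"), kp,
                      control = fit_control(n_starts = 2))
  expect_gt(fit$adj_r2, 85)
  expect_lt(fit$adj_r2, 95)
})

test_that("staged attribution fixes Enz0 at zero and splits batch variation", {
  dgs <- list(small_design("bA", 12, eth = 1.52, ffix = 12.7, temp_c = 20,
                           noise_sd = 2),
              small_design("bB", 12, eth = 0.8, ffix = 23.7, temp_c = 17,
                           noise_sd = 2))
  ds <- generate_dataset(dgs, seed = 11)
  sf <- staged_fit(ds, keitt())
  # data simulated with Enz0 = 0: the ladder must adopt the lumped model
  expect_true(sf$enz0_fixed)
  expect_false("enz0" %in% sf$estimates$parameter)
  # RSS is non-increasing along the ladder
  expect_true(all(diff(sf$stages$rss) <= 1e-6))
  # distinct residual firmness recovered and distinguishable at 95%
  ff <- coef_table(sf, "ffix")
  ff <- ff[order(ff$estimate), ]
  expect_equal(ff$estimate, c(12.7, 23.7), tolerance = 0.25)
  expect_gt(ff$estimate[2] - qnorm(0.975) * ff$se[2],
            ff$estimate[1] + qnorm(0.975) * ff$se[1])
})

test_that("per-fruit ethylene and initial firmness estimates stay uncorrelated", {
  # truth simulated with independent F0 and per-fruit Eth
  dg <- small_design("bC", 40, eth = 1.52, ffix = 12.7, temp_c = 24,
                     noise_sd = 1.5, eth_cv = 0.25)
  ds <- generate_dataset(dg, seed = 77)
  sf <- staged_fit(ds, keitt(), per_fruit_eth = TRUE)
  eth <- coef_table(sf, "eth")
  f0 <- coef_table(sf, "f0")
  stopifnot(all(eth$cell == f0$cell))
  expect_equal(nrow(eth), 40)
  rho <- cor(eth$estimate, f0$estimate)
  expect_gte(rho, -0.3)
  expect_lte(rho, 0.3)
})

test_that("EF tables from fits are linear in the driver and need scenarios", {
  ds <- generate_dataset(small_design(eth = 1.2, ffix = 12, noise_sd = 1),
                         seed = 5)
  fit <- fit_firmness(ds, param_structure(), keitt(),
                      control = fit_control(n_starts = 2))
  ef <- ef_table(fit)
  expect_equal(ef$ef,
               ethylene_factor(keitt(), ef$eth, temp_scenario(16, 20)))
  # doubling the driver doubles EF at a fixed scenario
  fit2 <- fit
  fit2$estimates$estimate[fit2$estimates$parameter == "eth"] <- 2 * ef$eth
  expect_equal(ef_table(fit2)$ef, 2 * ef$ef, tolerance = 1e-12)
  # zero driver gives zero EF
  fit3 <- fit
  fit3$estimates$estimate[fit3$estimates$parameter == "eth"] <- 0
  expect_equal(ef_table(fit3)$ef, 0)
  # missing scenario is reported by name
  expect_error(ef_table(fit, scenarios = list()), "b1")
})
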