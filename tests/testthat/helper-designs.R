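# Small synthetic designs shared across tests.

keitt <- function() cultivar_params("Keitt")

# one constant-temperature batch, defaults suited to fast exact-recovery runs
small_design <- function(batch_id = "b1", n_fruit = 8, eth = 1.2,
                         ffix = 12, temp_c = 20, noise_sd = 0,
                         f0_mean = 55, f0_sd = 8, days = 16, by = 2, ...) {
  batch_design(batch_id, n_fruit, f0_mean = f0_mean, f0_sd = f0_sd,
               eth = eth, ffix = ffix,
               scenario = temp_scenario(days, temp_c),
               times = seq(0, days, by = by), noise_sd = noise_sd, ...)
}

# random but domain-valid model configuration for property sweeps
random_config <- function() {
  ffix <- runif(1, 0, 25)
  list(kp = kinetic_params(kfenz_ref = runif(1, 0.005, 1.5),
                           kd_ref = runif(1, 1e-6, 5),
                           E_fenz = runif(1, 0, 250),
                           E_d = runif(1, 0, 200)),
       fs = fruit_state(F0 = ffix + runif(1, 5, 80),
                        eth = runif(1, 0, 10), ffix = ffix),
       temp_c = runif(1, 5, 40),
       t_end = runif(1, 1, 30))
}
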