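#' Design of one synthetic storage batch
#'
#' Describes a constant-scenario storage unit of a simulated trial:
#' number of fruit, the initial-firmness distribution, the true model
#' parameters, the storage scenario, the measurement schedule and the
#' measurement-error level.
#'
#' @param batch_id Batch identifier (unique within a design set).
#' @param n_fruit Number of fruit (>= 1).
#' @param f0_mean,f0_sd Mean and sd (FI) of the per-fruit initial
#'   firmness, drawn Normal and truncated below at `ffix + 1` FI.
#'   Designs with `f0_mean - 2 * f0_sd <= ffix` are rejected as
#'   inconsistent with the model domain.
#' @param eth True ethylene driver of the batch (arbitrary units, >= 0).
#' @param ffix True residual firmness (FI, >= 0).
#' @param scenario A [temp_scenario()].
#' @param times Measurement times (days) within the scenario duration.
#' @param noise_sd Additive measurement-error sd (FI, >= 0). Default
#'   2 FI, a plausible acoustic-measurement error for mango; tunable.
#' @param eth_cv Optional per-fruit ethylene heterogeneity: coefficient
#'   of variation of a lognormal multiplier on `eth`, drawn independently
#'   of the initial firmness. Default 0 (all fruit share the batch
#'   driver).
#' @param group_id Optional grouping label tying several batches
#'   together (defaults to `batch_id`).
#' @param ethylene_ul_l Applied-ethylene metadata label (uL/L).
#' @return An object of class `batch_design`.
#' @export
batch_design <- function(batch_id, n_fruit, f0_mean, f0_sd, eth, ffix,
                         scenario, times, noise_sd = 2, eth_cv = 0,
                         group_id = batch_id, ethylene_ul_l = NA_real_) {
  stopifnot(inherits(scenario, "temp_scenario"))
  if (n_fruit < 1L) stop("'n_fruit' must be >= 1", call. = FALSE)
  if (f0_sd < 0 || noise_sd < 0 || eth_cv < 0)
    stop("'f0_sd', 'noise_sd' and 'eth_cv' must be >= 0", call. = FALSE)
  if (eth < 0 || ffix < 0)
    stop("'eth' and 'ffix' must be >= 0", call. = FALSE)
  if (f0_mean - 2 * f0_sd <= ffix)
    stop("inconsistent design: need f0_mean - 2*f0_sd > ffix so that ",
         "initial-firmness draws respect F0 > F_fix", call. = FALSE)
  if (any(times < 0) || max(times) > scenario_duration(scenario) + 1e-9)
    stop("measurement times must lie within the scenario duration",
         call. = FALSE)
  structure(list(batch_id = as.character(batch_id),
                 group_id = as.character(group_id),
                 n_fruit = as.integer(n_fruit),
                 f0_mean = f0_mean, f0_sd = f0_sd, eth = eth, ffix = ffix,
                 scenario = scenario, times = sort(unique(times)),
                 noise_sd = noise_sd, eth_cv = eth_cv,
                 ethylene_ul_l = ethylene_ul_l),
            class = "batch_design")
}

#' Generate a synthetic firmness dataset
#'
#' Draws per-fruit initial firmness from the design's truncated Normal,
#' computes noise-free trajectories under the storage scenario, and adds
#' iid Normal measurement error. Fully deterministic under `seed` — the
#' same seed gives a bit-identical dataset.
#'
#' For each batch the shared survival factor `S(t)` is obtained from one
#' ODE solve of the unit fruit (`F0 = 1`, `F_fix = 0`), and each fruit's
#' noise-free trajectory is `ffix + (F0_i - ffix) * S(t)`, which is exact
#' because the survival factor does not depend on `F0` or `F_fix`. With
#' per-fruit ethylene heterogeneity (`eth_cv > 0`) the per-fruit
#' trajectory is evaluated by the chained analytical solution instead.
#'
#' @param designs A [batch_design()] or a list of them (e.g. from
#'   [design_preset()]).
#' @param seed Integer seed.
#' @param cultivar Kinetic parameter set used for the truth, a
#'   [kinetic_params()] object or cultivar name. Defaults to the set
#'   attached to the designs, else 'Keitt'.
#' @return A [firmness_dataset()] with a `truth` record: per-batch true
#'   `eth`, `ffix`, `noise_sd` and per-fruit true `F0` (and per-fruit
#'   `eth` when heterogeneous).
#' @export
#' @examples
#' ds <- generate_dataset(design_preset("keitt_batch2"), seed = 42)
#' ds
generate_dataset <- function(designs, seed, cultivar = NULL) {
  if (inherits(designs, "batch_design")) designs <- list(designs)
  stopifnot(all(vapply(designs, inherits, logical(1), "batch_design")))
  if (is.null(cultivar)) cultivar <- attr(designs, "cultivar") %||% "Keitt"
  kp <- if (inherits(cultivar, "kinetic_params")) cultivar
        else cultivar_params(cultivar)
  ids <- vapply(designs, `[[`, character(1), "batch_id")
  if (anyDuplicated(ids))
    stop("duplicate batch_id in designs", call. = FALSE)

  set.seed(as.integer(seed))
  rec <- list(); truth_batch <- list(); truth_fruit <- list()
  scenarios <- list(); meta <- list()

  for (dg in designs) {
    # truncated-normal initial firmness; reject draws below ffix + 1
    lo <- dg$ffix + 1
    p_keep <- 1 - pnorm(lo, dg$f0_mean, max(dg$f0_sd, 1e-12))
    if (dg$f0_sd > 0 && p_keep < 0.5)
      stop("design '", dg$batch_id, "' inconsistent: truncation at ",
           "F_fix + 1 would reject ", round(100 * (1 - p_keep)),
           "% of initial-firmness draws", call. = FALSE)
    f0 <- numeric(dg$n_fruit)
    for (i in seq_len(dg$n_fruit)) {
      repeat {
        x <- rnorm(1, dg$f0_mean, dg$f0_sd)
        if (x > lo) break
      }
      f0[i] <- x
    }
    eth_i <- rep(dg$eth, dg$n_fruit)
    if (dg$eth_cv > 0) {
      sdlog <- sqrt(log(1 + dg$eth_cv^2))
      eth_i <- dg$eth * exp(rnorm(dg$n_fruit, -sdlog^2 / 2, sdlog))
    }

    fruit_ids <- sprintf("%s_f%02d", dg$batch_id, seq_len(dg$n_fruit))
    nt <- length(dg$times)

    if (dg$eth_cv == 0) {
      unit <- fruit_state(F0 = 1, eth = dg$eth, ffix = 0)
      S <- firmness_ode(dg$scenario, kp, unit, dg$times)$firmness_fi
      clean <- outer(f0 - dg$ffix, S) + dg$ffix     # fruit x time
    } else {
      clean <- t(vapply(seq_len(dg$n_fruit), function(i) {
        pr <- soften_propagate(kp, eth_i[i], 0, seg_durations(dg$scenario),
                               seg_temps(dg$scenario), dg$times)
        dg$ffix + (f0[i] - dg$ffix) * exp(pr$logS)
      }, numeric(nt)))
    }

    noise <- matrix(rnorm(dg$n_fruit * nt, 0, dg$noise_sd), dg$n_fruit, nt)
    obs <- pmax(clean + noise, 0.1)   # firmness is physically positive

    rec[[dg$batch_id]] <- data.frame(
      fruit_id = rep(fruit_ids, each = nt),
      batch_id = dg$batch_id, group_id = dg$group_id,
      time_d = rep(dg$times, dg$n_fruit),
      firmness_fi = as.vector(t(obs)),
      stringsAsFactors = FALSE)
    scenarios[[dg$batch_id]] <- dg$scenario
    meta[[dg$batch_id]] <- data.frame(
      batch_id = dg$batch_id, group_id = dg$group_id,
      ethylene_ul_l = dg$ethylene_ul_l, n_fruit = dg$n_fruit,
      noise_sd = dg$noise_sd, stringsAsFactors = FALSE)
    truth_batch[[dg$batch_id]] <- data.frame(
      batch_id = dg$batch_id, group_id = dg$group_id, eth = dg$eth,
      ffix = dg$ffix, f0_mean = dg$f0_mean, f0_sd = dg$f0_sd,
      noise_sd = dg$noise_sd, stringsAsFactors = FALSE)
    truth_fruit[[dg$batch_id]] <- data.frame(
      fruit_id = fruit_ids, batch_id = dg$batch_id, f0 = f0, eth = eth_i,
      stringsAsFactors = FALSE)
  }

  firmness_dataset(do.call(rbind, unname(rec)), scenarios,
                   meta = do.call(rbind, unname(meta)),
                   truth = list(batch = do.call(rbind, unname(truth_batch)),
                                fruit = do.call(rbind, unname(truth_fruit)),
                                cultivar = kp$cultivar, seed = seed))
}

seg_durations <- function(sc) {
  if (scenario_type(sc) == "segments") sc$durations
  else stop("per-fruit heterogeneity needs a segment scenario", call. = FALSE)
}
seg_temps <- function(sc) sc$temps_c

#' Named design presets reproducing the study's batch geometries
#'
#' * `"keitt_batch2"`: reefer-transported Brazilian 'Keitt' geometry —
#'   four sub-batches of 30 fruit stored 16 d at 10, 17, 24 and 30 degC,
#'   F0 ~ N(61.7, 16.8) FI, true `Eth` 1.52, `F_fix` 12.7 FI,
#'   measurements every 2 d.
#' * `"kent_batch10"`: Brazilian 'Kent' geometry — same four-temperature
#'   layout with F0 ~ N(36.3, 12.5), `Eth` 0.48, `F_fix` 6.9 ('Kent'
#'   kinetics).
#' * `"israel_batch5"`: Israeli 'Keitt' ethylene trial — eight
#'   sub-batches of 25 fruit under the four two-period temperature
#'   scenarios, paired control (`Eth` 0.63) and ethylene-treated
#'   (`Eth` 5.62) arms sharing each scenario's initial-firmness
#'   distribution (means 37.4, 41.3, 44.4, 52.3; sd 6.2), `F_fix` 18.2.
#'
#' All preset numbers come from the packaged batch and storage tables.
#'
#' @param name Preset name.
#' @param noise_sd Measurement-error sd (FI), default 2.
#' @return A list of [batch_design()] objects with a `cultivar`
#'   attribute.
#' @export
design_preset <- function(name, noise_sd = 2) {
  presets <- c("keitt_batch2", "kent_batch10", "israel_batch5")
  if (!name %in% presets)
    stop("unknown preset '", name, "'; available: ",
         paste(presets, collapse = ", "), call. = FALSE)
  if (name %in% c("keitt_batch2", "kent_batch10")) {
    row <- if (name == "keitt_batch2") c(61.7, 16.8, 1.52, 12.7)
           else c(36.3, 12.5, 0.48, 6.9)
    temps <- c(10, 17, 24, 30)
    out <- lapply(temps, function(tc) {
      batch_design(batch_id = sprintf("%s_%02dC", name, tc), n_fruit = 30,
                   f0_mean = row[1], f0_sd = row[2], eth = row[3],
                   ffix = row[4], scenario = temp_scenario(16, tc),
                   times = seq(0, 16, by = 2), noise_sd = noise_sd,
                   group_id = name, ethylene_ul_l = 0)
    })
    attr(out, "cultivar") <- if (name == "keitt_batch2") "Keitt" else "Kent"
    return(out)
  }
  # israel_batch5: paired control/ethylene arms per two-period scenario
  sc <- storage_table()
  sc <- sc[sc$batch == 5, ]
  out <- lapply(seq_len(nrow(sc)), function(i) {
    r <- sc[i, ]
    scen <- temp_scenario(c(r$dur1_d, r$dur2_d), c(r$temp1_c, r$temp2_c))
    batch_design(batch_id = r$sub_batch, n_fruit = 25,
                 f0_mean = r$f0_init_fi, f0_sd = 6.2,
                 eth = if (r$ethylene_ul_l > 0) 5.62 else 0.63,
                 ffix = 18.2, scenario = scen,
                 times = seq(0, scenario_duration(scen), length.out = 9),
                 noise_sd = noise_sd,
                 group_id = if (r$ethylene_ul_l > 0) "ethylene" else "control",
                 ethylene_ul_l = r$ethylene_ul_l)
  })
  attr(out, "cultivar") <- "Keitt"
  out
}

#' Generate a paired control/ethylene experiment
#'
#' Convenience wrapper around [generate_dataset()] for presets with
#' paired treatment arms: control and ethylene-treated sub-batches share
#' each scenario's initial-firmness distribution but differ in the true
#' ethylene driver.
#'
#' @param preset Preset name (currently `"israel_batch5"`).
#' @param seed Integer seed.
#' @param noise_sd Measurement-error sd (FI).
#' @return A [firmness_dataset()] whose `group_id` distinguishes the
#'   `"control"` and `"ethylene"` arms.
#' @export
generate_ethylene_experiment <- function(preset = "israel_batch5", seed,
                                         noise_sd = 2) {
  designs <- design_preset(preset, noise_sd = noise_sd)
  generate_dataset(designs, seed)
}
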