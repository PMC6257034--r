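#' Staged attribution of variation
#'
#' Runs the model-building ladder used in the study: (1) all parameters
#' in common; (2) residual firmness, ethylene driver and initial enzyme
#' level attributed per batch unit; (3) initial firmness per individual
#' fruit; (4) optionally the ethylene driver per individual fruit. Each
#' stage is warm-started from the previous one, so the residual sum of
#' squares is non-increasing along the ladder.
#'
#' After stage 2, if every per-unit `Enz0` estimate is indistinguishable
#' from zero (estimate below twice its standard error, or its SE is not
#' available), `Enz0` is fixed to zero and the remaining stages use the
#' lumped `k_fenz` formulation. At stage 4 all higher-level parameters
#' (`F_fix`, kinetics) are held at their stage-3 values.
#'
#' @param dataset A [firmness_dataset()].
#' @param kinetics A [kinetic_params()] object (fixed cultivar kinetics;
#'   the default workflow does not re-estimate them).
#' @param unit Index level at which batch-level variation is attributed:
#'   `"group"` or `"batch"`. Defaults to `"group"` when the dataset
#'   defines more than one group, else `"batch"`.
#' @param per_fruit_eth Run stage 4 (ethylene driver per fruit)?
#' @param free_kinetics Also free `kd_ref`, `E_fenz`, `E_d` from stage 1
#'   on (requires >= 2 storage temperatures; `kfenz_ref` stays fixed as
#'   normalisation).
#' @param enz0_factor `Enz0` is fixed to zero when every unit estimate is
#'   below `enz0_factor` times its SE (default 2).
#' @param control A [fit_control()] list.
#' @return The final `firmness_fit`, with `$stages` (per-stage RSS,
#'   parameter count, adjusted R^2) and `$enz0_fixed` (logical) attached.
#' @export
staged_fit <- function(dataset, kinetics = cultivar_params("Keitt"),
                       unit = NULL, per_fruit_eth = FALSE,
                       free_kinetics = FALSE, enz0_factor = 2,
                       control = fit_control()) {
  stopifnot(inherits(dataset, "firmness_dataset"))
  d <- dataset$data
  if (is.null(unit))
    unit <- if (length(unique(d$group_id)) > 1L) "group" else "batch"
  unit <- match.arg(unit, c("group", "batch"))
  kin <- if (free_kinetics) "free" else "fixed"
  quiet <- fit_control(n_starts = control$n_starts, seed = control$seed,
                       maxiter = control$maxiter, warn_nonconv = FALSE)

  stages <- list()
  log_stage <- function(label, fit) {
    stages[[length(stages) + 1L]] <<-
      data.frame(stage = label, rss = fit$rss, npar = fit$npar,
                 adj_r2 = fit$adj_r2, stringsAsFactors = FALSE)
  }
  warm <- function(fit) {
    est <- fit$estimates
    out <- list()
    for (kind in unique(est$parameter)) {
      v <- est$estimate[est$parameter == kind]
      names(v) <- est$cell[est$parameter == kind]
      out[[kind]] <- if (length(v) == 1L && names(v)[1] == "all") unname(v)
                     else v
    }
    out
  }

  # stage 1: everything common (full model, Enz0 free)
  s1 <- fit_firmness(dataset,
                     param_structure(f0 = "common", ffix = "common",
                                     eth = "common", enz0 = "common",
                                     kinetics = kin),
                     kinetics, quiet)
  log_stage("common", s1)

  # stage 2: batch-level attribution of F_fix, Eth, Enz0
  s2 <- fit_firmness(dataset,
                     param_structure(f0 = "common", ffix = unit,
                                     eth = unit, enz0 = unit,
                                     kinetics = kin),
                     kinetics, quiet, start = warm(s1))
  log_stage(paste0("per-", unit), s2)

  e0 <- coef_table(s2, "enz0")
  enz0_fixed <- all(is.na(e0$se) | e0$estimate < enz0_factor * e0$se)
  enz0_level <- if (enz0_fixed) "zero" else unit

  # stage 3: initial firmness per fruit (lumped model if Enz0 ~ 0)
  s3 <- fit_firmness(dataset,
                     param_structure(f0 = "fruit", ffix = unit,
                                     eth = unit, enz0 = enz0_level,
                                     kinetics = kin),
                     kinetics, quiet, start = warm(s2))
  log_stage("per-fruit F0", s3)
  final <- s3

  # stage 4: ethylene driver per fruit, higher levels held fixed
  if (per_fruit_eth) {
    w3 <- warm(s3)
    fixed <- list(ffix = w3$ffix)
    if (!enz0_fixed) fixed$enz0 <- w3$enz0
    if (free_kinetics) {
      fixed$kd_ref <- w3$kd_ref
      fixed$E_fenz <- w3$E_fenz
      fixed$E_d <- w3$E_d
    }
    # expand unit-level Eth to per-fruit warm starts
    fruit_unit <- unique(d[, c("fruit_id",
                               if (unit == "group") "group_id" else "batch_id")])
    eth_start <- if (is.null(names(w3$eth)))
      setNames(rep(w3$eth, nrow(fruit_unit)), fruit_unit$fruit_id)
    else setNames(unname(w3$eth[fruit_unit[[2]]]), fruit_unit$fruit_id)
    s4 <- fit_firmness(dataset,
                       param_structure(f0 = "fruit", ffix = unit,
                                       eth = "fruit", enz0 = enz0_level,
                                       kinetics = "fixed",
                                       fixed = fixed),
                       final$kinetics, quiet,
                       start = c(list(eth = eth_start, f0 = w3$f0)))
    log_stage("per-fruit Eth", s4)
    final <- s4
  }

  if (!final$convergence$converged && control$warn_nonconv)
    warning("staged fit: final stage did not converge: ",
            final$convergence$message, call. = FALSE)
  final$stages <- do.call(rbind, stages)
  final$enz0_fixed <- enz0_fixed
  final$unit <- unit
  final
}

#' Ethylene-factor table from a fit
#'
#' Computes EF = k_fenz x Eth at the time-weighted mean storage
#' temperature for every batch-level (or group-level) ethylene-driver
#' estimate in a fit, mirroring the published per-sub-batch EF table.
#'
#' @param fit A `firmness_fit` whose `eth` estimates are indexed per
#'   batch or group.
#' @param scenarios Optional named list of [temp_scenario()] objects per
#'   index cell; defaults to the scenarios stored in the fit (batch-level
#'   indexing). Required when `eth` is indexed per group and groups span
#'   several scenarios.
#' @return Data frame with columns `cell`, `eth`, `eth_se`,
#'   `mean_temp_c`, `ef`.
#' @export
ef_table <- function(fit, scenarios = NULL) {
  stopifnot(inherits(fit, "firmness_fit"))
  eth <- coef_table(fit, "eth")
  if (nrow(eth) == 0L)
    stop("fit contains no ethylene-driver estimates", call. = FALSE)
  if (any(eth$level == "fruit"))
    stop("ef_table needs 'eth' indexed per batch or group, not per fruit",
         call. = FALSE)
  if (is.null(scenarios)) scenarios <- fit$scenarios
  out <- eth[, c("cell", "estimate", "se")]
  names(out) <- c("cell", "eth", "eth_se")
  out$mean_temp_c <- NA_real_
  out$ef <- NA_real_
  for (i in seq_len(nrow(out))) {
    sc <- scenarios[[out$cell[i]]]
    if (is.null(sc))
      stop("no storage scenario for batch/group '", out$cell[i], "'",
           call. = FALSE)
    out$mean_temp_c[i] <- mean_storage_temp(sc)
    out$ef[i] <- ethylene_factor(fit$kinetics, out$eth[i], sc)
  }
  rownames(out) <- NULL
  out
}
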