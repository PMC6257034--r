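#' Parameter structure for the indexed least-squares fit
#'
#' Declares at which index level each model parameter varies: `"common"`
#' (one value for the whole dataset), `"group"`, `"batch"` or `"fruit"`.
#' The fitting routine estimates one value per index cell.
#'
#' Identifiability rules enforced at fit time: `k_fenz` (through
#' `kfenz_ref`) and `Eth` are never simultaneously free, because only
#' their product enters the model; freeing the kinetic parameters
#' (`kinetics = "free"`) frees `kd_ref`, `E_fenz` and `E_d` while
#' `kfenz_ref` keeps its supplied value as a units normalisation (the
#' published 'Kent' set uses exactly this convention with
#' `kfenz_ref = 1`), and requires data at >= 2 distinct temperatures.
#'
#' @param f0 Index level of the initial firmness: `"fruit"` or
#'   `"common"`. Internally `F0` is reparameterised as
#'   `F_fix + exp(theta)` so that `F0 > F_fix` holds throughout.
#' @param ffix Index level of the residual firmness: `"common"`,
#'   `"group"` or `"batch"`.
#' @param eth Index level of the ethylene driver: `"common"`, `"group"`,
#'   `"batch"` or `"fruit"`.
#' @param enz0 `"zero"` (fixed at 0, the lumped final model) or an index
#'   level (`"common"`, `"group"`, `"batch"`) to estimate the initial
#'   enzyme level with the full analytical solution.
#' @param kinetics `"fixed"` (use the supplied cultivar kinetics, the
#'   default workflow) or `"free"`.
#' @param fixed Named list of parameters to hold at given values instead
#'   of estimating: entries among `eth`, `ffix`, `enz0` (scalar, or named
#'   vector by index cell) and `kfenz_ref`, `kd_ref`, `E_fenz`, `E_d`
#'   (scalars overriding the supplied kinetics).
#' @return An object of class `param_structure`.
#' @export
param_structure <- function(f0 = "fruit", ffix = "batch", eth = "batch",
                            enz0 = "zero", kinetics = "fixed",
                            fixed = list()) {
  f0 <- match.arg(f0, c("fruit", "common"))
  ffix <- match.arg(ffix, c("batch", "group", "common"))
  eth <- match.arg(eth, c("batch", "group", "common", "fruit"))
  enz0 <- match.arg(enz0, c("zero", "batch", "group", "common"))
  kinetics <- match.arg(kinetics, c("fixed", "free", "free_all"))
  stopifnot(is.list(fixed))
  bad <- setdiff(names(fixed),
                 c("eth", "ffix", "enz0", "kfenz_ref", "kd_ref",
                   "E_fenz", "E_d"))
  if (length(bad))
    stop("unknown entries in 'fixed': ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(f0 = f0, ffix = ffix, eth = eth, enz0 = enz0,
                 kinetics = kinetics, fixed = fixed),
            class = "param_structure")
}

#' Fitting control settings
#'
#' @param n_starts Number of optimisation starts (first start is the
#'   deterministic data-driven initialisation; further starts are seeded
#'   jitters of it, guarding against local minima).
#' @param seed Seed for the start jitter (the fit restores the caller's
#'   RNG state afterwards).
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @param warn_nonconv Warn (in addition to flagging) when the best start
#'   did not converge.
#' @return A list of control settings.
#' @export
fit_control <- function(n_starts = 5L, seed = 1L, maxiter = 200L,
                        warn_nonconv = TRUE) {
  list(n_starts = as.integer(n_starts), seed = as.integer(seed),
       maxiter = as.integer(maxiter), warn_nonconv = isTRUE(warn_nonconv))
}

# index cell factor for a level, as character vector per record
level_cells <- function(level, d) {
  switch(level,
         common = rep("all", nrow(d)),
         group = d$group_id,
         batch = d$batch_id,
         fruit = d$fruit_id)
}

# run code with a private RNG stream, restoring the caller's state
with_private_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Fit the softening model by indexed nonlinear least squares
#'
#' Minimises the sum of squared residuals between observed firmness and
#' the model over all records, with parameters indexed per
#' [param_structure()]. Batches with segment scenarios are evaluated by
#' the exact chained analytical solution; batches with logged temperature
#' traces by ODE integration. Standard errors come from the Gauss-Newton
#' approximation (pooled residual variance times the inverse of J'J),
#' with delta-method transforms for internally transformed parameters.
#'
#' @param dataset A [firmness_dataset()].
#' @param structure A [param_structure()].
#' @param kinetics A [kinetic_params()] object: fixed values when
#'   `structure$kinetics == "fixed"`, otherwise initial values (with
#'   `kfenz_ref` held as normalisation).
#' @param control A [fit_control()] list.
#' @param start Optional named list of warm-start values on the natural
#'   scale: `eth`, `ffix`, `enz0` (scalar or named vector by cell),
#'   `f0` (named vector by fruit), `kd_ref`, `E_fenz`, `E_d`.
#' @return An object of class `firmness_fit`: `estimates` (data frame of
#'   parameter, level, cell, estimate, se), `rss`, `sigma`, `adj_r2`,
#'   `fitted` (per-record observed/fitted/residual), `convergence`
#'   (flag, optimizer message, iterations, gradient norm), `nobs`,
#'   `npar`.
#' @export
#' @examples
#' \donttest{
#' ds <- generate_dataset(design_preset("keitt_batch2"), seed = 1)
#' fit <- fit_firmness(ds, param_structure(eth = "group", ffix = "group"),
#'                     cultivar_params("Keitt"))
#' summary(fit)
#' }
fit_firmness <- function(dataset, structure = param_structure(),
                         kinetics = cultivar_params("Keitt"),
                         control = fit_control(), start = NULL) {
  stopifnot(inherits(dataset, "firmness_dataset"),
            inherits(structure, "param_structure"),
            inherits(kinetics, "kinetic_params"))
  ctx <- build_fit_context(dataset, structure, kinetics)

  init <- initial_values(ctx, start)
  par0 <- encode_par(ctx, init)

  starts <- list(par0)
  if (control$n_starts > 1L) {
    starts <- c(starts, with_private_seed(control$seed, {
      lapply(seq_len(control$n_starts - 1L), function(i) jitter_par(ctx, par0))
    }))
  }

  best <- NULL
  for (p0 in starts) {
    res <- try(minpack.lm::nls.lm(
      par = p0, lower = ctx$lower, upper = ctx$upper,
      fn = ctx$fn, jac = ctx$jac,
      control = minpack.lm::nls.lm.control(maxiter = control$maxiter)),
      silent = TRUE)
    if (inherits(res, "try-error")) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best))
    stop("all optimisation starts failed", call. = FALSE)

  converged <- best$info %in% 1:4
  if (!converged && control$warn_nonconv)
    warning("fit did not converge: ", best$message, call. = FALSE)

  finalize_fit(ctx, best, dataset, structure, kinetics, converged)
}

# ---- fit context -----------------------------------------------------------

build_fit_context <- function(dataset, structure, kinetics) {
  d <- dataset$data
  n <- nrow(d)
  fixed <- structure$fixed

  free_kin <- structure$kinetics %in% c("free", "free_all")
  eth_free <- !("eth" %in% names(fixed))
  if (structure$kinetics == "free_all" && eth_free)
    stop("non-identifiable structure: 'kfenz_ref' and 'eth' are jointly ",
         "unidentifiable (only their product enters the model); fix one ",
         "of them", call. = FALSE)
  if (free_kin) {
    temps <- unique(unlist(lapply(dataset$scenarios, function(s) s$temps_c)))
    if (length(unique(round(temps, 6))) < 2L)
      stop("freeing the kinetic parameters requires data at >= 2 distinct ",
           "temperatures (activation energies are not identifiable ",
           "otherwise)", call. = FALSE)
  }

  # cells per record
  cells <- list(
    ffix = level_cells(structure$ffix, d),
    eth = level_cells(structure$eth, d),
    enz0 = if (structure$enz0 == "zero") NULL
           else level_cells(structure$enz0, d),
    f0 = level_cells(structure$f0, d))

  cell_names <- lapply(cells, function(x) if (is.null(x)) NULL else unique(x))
  cell_idx <- lapply(names(cells), function(k) {
    if (is.null(cells[[k]])) NULL
    else match(cells[[k]], cell_names[[k]])
  })
  names(cell_idx) <- names(cells)

  # parameter table ----------------------------------------------------------
  # kinds: kin (log/nat), ffix (nat), eth (nat), enz0 (nat), f0 (theta)
  ptab <- list()
  add_par <- function(kind, cell, scale, lower, upper) {
    ptab[[length(ptab) + 1L]] <<- data.frame(
      kind = kind, cell = cell, scale = scale, lower = lower, upper = upper,
      stringsAsFactors = FALSE)
  }
  if (free_kin) {
    if (structure$kinetics == "free_all" && !"kfenz_ref" %in% names(fixed))
      add_par("kfenz_ref", "all", "log", log(1e-6), log(100))
    if (!"kd_ref" %in% names(fixed))
      add_par("kd_ref", "all", "log", log(1e-4), log(50))
    if (!"E_fenz" %in% names(fixed)) add_par("E_fenz", "all", "nat", 0, 400)
    if (!"E_d" %in% names(fixed)) add_par("E_d", "all", "nat", 0, 400)
  }
  for (kind in c("ffix", "eth", "enz0")) {
    if (kind == "enz0" && structure$enz0 == "zero") next
    if (kind %in% names(fixed)) next
    for (cl in cell_names[[kind]]) add_par(kind, cl, "nat", 0, Inf)
  }
  for (cl in cell_names$f0) add_par("f0", cl, "theta", log(1e-3), log(1e4))
  ptab <- do.call(rbind, ptab)
  if (is.null(ptab) || nrow(ptab) == 0L)
    stop("parameter structure has no free parameters", call. = FALSE)

  # fixed-value lookup per kind/cell
  fixed_vals <- function(kind, cl) {
    v <- fixed[[kind]]
    if (is.null(v)) return(NULL)
    if (length(v) == 1L && is.null(names(v))) return(unname(v))
    if (!cl %in% names(v))
      stop("no fixed value of '", kind, "' for cell '", cl, "'",
           call. = FALSE)
    unname(v[[cl]])
  }

  # evaluation cells: records sharing (batch, eth cell, enz0 cell) share logS
  ec_key <- paste(d$batch_id, cells$eth,
                  if (is.null(cells$enz0)) "" else cells$enz0, sep = "\r")
  ec_split <- split(seq_len(n), ec_key)
  eval_cells <- lapply(ec_split, function(idx) {
    b <- d$batch_id[idx[1]]
    list(idx = idx, scenario = dataset$scenarios[[b]],
         eth_cell = cell_idx$eth[idx[1]],
         enz0_cell = if (is.null(cell_idx$enz0)) NA_integer_
                     else cell_idx$enz0[idx[1]],
         times = d$time_d[idx])
  })

  times <- d$time_d
  obs <- d$firmness_fi

  ctx <- new.env(parent = emptyenv())
  ctx$n <- n; ctx$obs <- obs; ctx$times <- times; ctx$d <- d
  ctx$ptab <- ptab
  ctx$lower <- ptab$lower; ctx$upper <- ptab$upper
  ctx$cells <- cells; ctx$cell_names <- cell_names; ctx$cell_idx <- cell_idx
  ctx$structure <- structure; ctx$kin0 <- kinetics; ctx$fixed <- fixed
  ctx$eval_cells <- eval_cells
  ctx$fixed_vals <- fixed_vals

  # decode working parameters to natural-scale components
  kin_fixed <- list(
    kfenz_ref = if (!is.null(fixed$kfenz_ref)) fixed$kfenz_ref
                else kinetics$kfenz_ref,
    kd_ref = if (!is.null(fixed$kd_ref)) fixed$kd_ref else kinetics$kd_ref,
    E_fenz = if (!is.null(fixed$E_fenz)) fixed$E_fenz else kinetics$E_fenz,
    E_d = if (!is.null(fixed$E_d)) fixed$E_d else kinetics$E_d)

  which_kind <- function(kind) which(ptab$kind == kind)
  ctx$which_kind <- which_kind

  ctx$decode <- function(par) {
    kin <- kin_fixed
    for (kn in c("kfenz_ref", "kd_ref", "E_fenz", "E_d")) {
      w <- which_kind(kn)
      if (length(w)) kin[[kn]] <- if (ptab$scale[w] == "log") exp(par[w])
                                  else par[w]
    }
    kp <- list(kfenz_ref = kin$kfenz_ref, kd_ref = kin$kd_ref,
               E_fenz = kin$E_fenz, E_d = kin$E_d, t_ref = kinetics$t_ref)
    vals <- list()
    for (kind in c("ffix", "eth", "enz0")) {
      if (kind == "enz0" && structure$enz0 == "zero") {
        vals[[kind]] <- NULL; next
      }
      nm <- cell_names[[kind]]
      if (kind %in% names(fixed)) {
        vals[[kind]] <- vapply(nm, function(cl) fixed_vals(kind, cl),
                               numeric(1))
      } else {
        w <- which_kind(kind)
        vals[[kind]] <- setNames(par[w], ptab$cell[w])[nm]
      }
    }
    wf <- which_kind("f0")
    theta <- setNames(par[wf], ptab$cell[wf])[cell_names$f0]
    list(kp = kp, ffix = vals$ffix, eth = vals$eth, enz0 = vals$enz0,
         theta = theta)
  }

  ctx$fn <- function(par) {
    dec <- ctx$decode(par)
    logS <- numeric(n)
    for (ec in eval_cells) {
      eth <- dec$eth[[ec$eth_cell]]
      e0 <- if (is.na(ec$enz0_cell)) 0 else dec$enz0[[ec$enz0_cell]]
      sc <- ec$scenario
      if (scenario_type(sc) == "segments") {
        logS[ec$idx] <- soften_propagate(dec$kp, eth, e0, sc$durations,
                                         sc$temps_c, ec$times)$logS
      } else {
        logS[ec$idx] <- trace_logS(dec$kp, eth, e0, sc, ec$times)
      }
    }
    ffix_r <- dec$ffix[cell_idx$ffix]
    amp_r <- exp(dec$theta)[cell_idx$f0]
    obs - (ffix_r + amp_r * exp(logS))
  }

  # column -> affected records, and coloring groups for finite differences
  col_rows <- vector("list", nrow(ptab))
  rec_by_cell <- lapply(names(cells), function(k) {
    if (is.null(cells[[k]])) NULL else split(seq_len(n), cells[[k]])
  })
  names(rec_by_cell) <- names(cells)
  for (j in seq_len(nrow(ptab))) {
    kind <- ptab$kind[j]
    col_rows[[j]] <-
      if (kind %in% c("kfenz_ref", "kd_ref", "E_fenz", "E_d")) seq_len(n)
      else if (ptab$cell[j] == "all" &&
               is.null(rec_by_cell[[kind]][["all"]])) seq_len(n)
      else rec_by_cell[[kind]][[ptab$cell[j]]]
  }
  fd_groups <- list()
  for (kind in unique(ptab$kind)) {
    w <- which_kind(kind)
    if (kind %in% c("kfenz_ref", "kd_ref", "E_fenz", "E_d") ||
        (length(w) == 1L && length(col_rows[[w]]) == n)) {
      fd_groups <- c(fd_groups, as.list(w))   # dense columns: singletons
    } else {
      fd_groups <- c(fd_groups, list(w))      # cells partition the records
    }
  }

  ctx$jac <- function(par, ...) {
    r0 <- ctx$fn(par)
    J <- matrix(0, n, length(par))
    for (grp in fd_groups) {
      h <- 1e-6 * (abs(par[grp]) + 1e-6)
      flip <- par[grp] + h > ctx$upper[grp]
      h[flip] <- -h[flip]
      par2 <- par
      par2[grp] <- par2[grp] + h
      dr <- ctx$fn(par2) - r0
      for (k in seq_along(grp)) {
        rows <- col_rows[[grp[k]]]
        J[rows, grp[k]] <- dr[rows] / h[k]
      }
    }
    J
  }

  ctx
}

# logS under a logged temperature trace via ODE on the unit fruit
trace_logS <- function(kp, eth, e0, scenario, times) {
  kpo <- structure(c(kp, list(cultivar = NA)), class = "kinetic_params")
  fs <- fruit_state(F0 = 1, eth = eth, ffix = 0, enz0 = e0)
  tr <- firmness_ode(scenario, kpo, fs, times)
  log(pmax(tr$firmness_fi, 1e-300))
}

# ---- initial values and encoding ------------------------------------------

initial_values <- function(ctx, start = NULL) {
  d <- ctx$d
  cn <- ctx$cell_names
  init <- list()

  # ffix: 0.9 x minimum observed firmness per cell
  if (!is.null(cn$ffix)) {
    init$ffix <- vapply(cn$ffix, function(cl) {
      0.9 * min(d$firmness_fi[ctx$cells$ffix == cl])
    }, numeric(1))
  }
  # f0 amplitude: first observation per fruit minus cell ffix
  first_obs <- vapply(cn$f0, function(cl) {
    rows <- ctx$cells$f0 == cl
    d$firmness_fi[rows][which.min(d$time_d[rows])]
  }, numeric(1))
  ffix_of_f0 <- vapply(cn$f0, function(cl) {
    rows <- which(ctx$cells$f0 == cl)[1]
    init$ffix[[ctx$cells$ffix[rows]]] %||% 0
  }, numeric(1))
  init$f0 <- pmax(first_obs - ffix_of_f0, 0.5) + ffix_of_f0
  names(init$f0) <- cn$f0

  init$enz0 <- if (!is.null(cn$enz0)) setNames(rep(0.01, length(cn$enz0)),
                                               cn$enz0)
  init$kfenz_ref <- ctx$kin0$kfenz_ref
  init$kd_ref <- ctx$kin0$kd_ref
  init$E_fenz <- ctx$kin0$E_fenz
  init$E_d <- ctx$kin0$E_d

  # eth: coarse log-grid, one pass per candidate, argmin RSS per cell
  if (!is.null(cn$eth)) {
    init$eth <- setNames(rep(0.5, length(cn$eth)), cn$eth)
    if (!"eth" %in% names(ctx$fixed)) {
      cand <- 10^seq(-2, 1.2, length.out = 18)
      rss <- matrix(NA_real_, length(cand), length(cn$eth))
      probe <- init
      for (i in seq_along(cand)) {
        probe$eth[] <- cand[i]
        r <- ctx$fn(encode_par(ctx, probe))
        rss[i, ] <- vapply(seq_along(cn$eth), function(j) {
          sum(r[ctx$cell_idx$eth == j]^2)
        }, numeric(1))
      }
      init$eth <- setNames(cand[apply(rss, 2, which.min)], cn$eth)
    }
  }

  # warm-start overrides (natural scale)
  if (!is.null(start)) {
    for (nm in intersect(names(start), c("kfenz_ref", "kd_ref", "E_fenz", "E_d")))
      init[[nm]] <- start[[nm]]
    for (nm in intersect(names(start), c("ffix", "eth", "enz0", "f0"))) {
      v <- start[[nm]]
      if (length(v) == 1L && is.null(names(v))) init[[nm]][] <- v
      else {
        hit <- intersect(names(v), names(init[[nm]]))
        init[[nm]][hit] <- v[hit]
      }
    }
  }
  init
}

`%||%` <- function(a, b) if (is.null(a)) b else a

encode_par <- function(ctx, init) {
  ptab <- ctx$ptab
  par <- numeric(nrow(ptab))
  for (j in seq_len(nrow(ptab))) {
    kind <- ptab$kind[j]; cl <- ptab$cell[j]
    par[j] <- switch(kind,
      kfenz_ref = log(init$kfenz_ref),
      kd_ref = log(init$kd_ref),
      E_fenz = init$E_fenz,
      E_d = init$E_d,
      ffix = init$ffix[[cl]],
      eth = init$eth[[cl]],
      enz0 = init$enz0[[cl]],
      f0 = {
        ffix_cl <- ctx$cells$ffix[which(ctx$cells$f0 == cl)[1]]
        ffv <- if ("ffix" %in% names(ctx$fixed))
          ctx$fixed_vals("ffix", ffix_cl) else init$ffix[[ffix_cl]]
        log(max(init$f0[[cl]] - ffv, 1e-3))
      })
  }
  pmin(pmax(par, ctx$lower), ctx$upper)
}

jitter_par <- function(ctx, par) {
  ptab <- ctx$ptab
  for (j in seq_len(nrow(ptab))) {
    par[j] <- switch(ptab$kind[j],
      kfenz_ref = par[j] + runif(1, -0.7, 0.7),
      kd_ref = par[j] + runif(1, -0.7, 0.7),
      E_fenz = par[j] * runif(1, 0.8, 1.2),
      E_d = max(par[j] * runif(1, 0.5, 1.5) + runif(1, -10, 10), 0),
      ffix = par[j] * runif(1, 0.6, 1.1),
      eth = par[j] * exp(runif(1, -1, 1)),
      enz0 = par[j] * exp(runif(1, -1, 1)),
      f0 = par[j] + runif(1, -0.15, 0.15))
  }
  pmin(pmax(par, ctx$lower), ctx$upper)
}

# ---- results ---------------------------------------------------------------

finalize_fit <- function(ctx, opt, dataset, structure, kinetics, converged) {
  par <- opt$par
  r <- ctx$fn(par)
  n <- ctx$n
  p <- length(par)
  rss <- sum(r^2)
  sigma2 <- rss / max(n - p, 1)

  J <- ctx$jac(par)
  V <- try(sigma2 * solve(crossprod(J)), silent = TRUE)
  se_work <- if (inherits(V, "try-error")) rep(NA_real_, p) else sqrt(diag(V))
  grad_norm <- max(abs(crossprod(J, r)))

  ptab <- ctx$ptab
  dec <- ctx$decode(par)

  est <- data.frame(parameter = ptab$kind, cell = ptab$cell,
                    estimate = NA_real_, se = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(p)) {
    kind <- ptab$kind[j]
    if (ptab$scale[j] == "log") {
      est$estimate[j] <- exp(par[j])
      est$se[j] <- exp(par[j]) * se_work[j]
    } else if (ptab$scale[j] == "theta") {
      cl <- ptab$cell[j]
      row1 <- which(ctx$cells$f0 == cl)[1]
      ffix_cl <- ctx$cells$ffix[row1]
      ffv <- dec$ffix[[ffix_cl]]
      est$estimate[j] <- ffv + exp(par[j])
      # delta method including covariance with the cell's ffix, if free
      jf <- which(ptab$kind == "ffix" & ptab$cell == ffix_cl)
      if (!inherits(V, "try-error")) {
        v <- exp(2 * par[j]) * V[j, j]
        if (length(jf)) v <- v + V[jf, jf] + 2 * exp(par[j]) * V[j, jf]
        est$se[j] <- sqrt(max(v, 0))
      }
    } else {
      est$estimate[j] <- par[j]
      est$se[j] <- se_work[j]
    }
  }
  level_of <- c(kfenz_ref = "common", kd_ref = "common", E_fenz = "common", E_d = "common",
                ffix = structure$ffix, eth = structure$eth,
                enz0 = if (structure$enz0 == "zero") "zero" else structure$enz0,
                f0 = structure$f0)
  est$level <- unname(level_of[est$parameter])
  est <- est[, c("parameter", "level", "cell", "estimate", "se")]

  fitted_df <- data.frame(fruit_id = ctx$d$fruit_id,
                          batch_id = ctx$d$batch_id,
                          group_id = ctx$d$group_id,
                          time_d = ctx$d$time_d,
                          observed = ctx$obs,
                          fitted = ctx$obs - r,
                          residual = r,
                          stringsAsFactors = FALSE)

  adj <- if (n > p) adjusted_r2(ctx$obs, ctx$obs - r, p) else NA_real_

  kp_used <- kinetic_params(dec$kp$kfenz_ref, dec$kp$kd_ref, dec$kp$E_fenz,
                            dec$kp$E_d, dec$kp$t_ref, kinetics$cultivar)

  structure(list(estimates = est, rss = rss, sigma = sqrt(sigma2),
                 adj_r2 = adj, fitted = fitted_df,
                 convergence = list(converged = converged, info = opt$info,
                                    message = opt$message,
                                    iterations = opt$niter,
                                    grad_norm = grad_norm),
                 nobs = n, npar = p, structure = structure,
                 kinetics = kp_used, scenarios = dataset$scenarios,
                 par = par),
            class = "firmness_fit")
}

#' @export
print.firmness_fit <- function(x, ...) {
  cat(sprintf("Softening-model fit: %d observations, %d parameters\n",
              x$nobs, x$npar))
  cat(sprintf("  RSS = %.4g, sigma = %.3f FI, adjusted R2 = %.1f%%\n",
              x$rss, x$sigma, x$adj_r2))
  cat(sprintf("  converged: %s (%d iterations, max gradient %.2g)\n",
              x$convergence$converged, x$convergence$iterations,
              x$convergence$grad_norm))
  batchy <- x$estimates[x$estimates$parameter %in%
                          c("ffix", "eth", "enz0", "kd_ref", "E_fenz", "E_d"), ]
  if (nrow(batchy)) {
    cat("  batch/common parameters:\n")
    print(batchy, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
summary.firmness_fit <- function(object, ...) {
  print(object)
  f0 <- object$estimates[object$estimates$parameter == "f0", ]
  if (nrow(f0) > 1)
    cat(sprintf("  per-fruit F0: mean %.1f, sd %.1f FI (n = %d)\n",
                mean(f0$estimate), sd(f0$estimate), nrow(f0)))
  invisible(object)
}

#' Extract estimates for one parameter
#' @param fit A `firmness_fit`.
#' @param parameter Parameter name (e.g. `"eth"`, `"ffix"`, `"f0"`).
#' @return Data frame of cells, estimates and standard errors.
#' @export
coef_table <- function(fit, parameter) {
  stopifnot(inherits(fit, "firmness_fit"))
  out <- fit$estimates[fit$estimates$parameter == parameter, ]
  rownames(out) <- NULL
  out
}

#' Adjusted R-squared (percentage variance accounted for)
#'
#' `100 * (1 - (RSS / (n - p)) / (TSS / (n - 1)))` with TSS taken about
#' the grand mean of the observations.
#'
#' @param observed Observed values.
#' @param fitted Fitted values, same length.
#' @param n_params Number of free parameters `p`; must satisfy `n > p`.
#' @return Adjusted R-squared in percent (<= 100; 100 for a perfect fit).
#' @export
adjusted_r2 <- function(observed, fitted, n_params) {
  n <- length(observed)
  stopifnot(length(fitted) == n)
  if (n <= n_params)
    stop("adjusted R2 needs more observations than parameters",
         call. = FALSE)
  rss <- sum((observed - fitted)^2)
  tss <- sum((observed - mean(observed))^2)
  100 * (1 - (rss / (n - n_params)) / (tss / (n - 1)))
}
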