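#' Acoustic firmness index
#'
#' Converts an acoustic-firmness-tester reading — resonant frequency of
#' the second spectral peak `f` (Hz) and fruit mass `m` (kg) — into the
#' firmness index `FI = f^2 * m^(2/3) / 1e4`, in units of
#' 1e-4 Hz^2 kg^(2/3).
#'
#' @param f Resonant frequency (Hz, > 0); vectorised.
#' @param m Fruit mass (kg, > 0); vectorised.
#' @return Firmness index value(s).
#' @export
#' @examples
#' firmness_index(700, 0.45)
firmness_index <- function(f, m) {
  if (any(!is.finite(f)) || any(f <= 0))
    stop("'f' must be positive (Hz)", call. = FALSE)
  if (any(!is.finite(m)) || any(m <= 0))
    stop("'m' must be positive (kg)", call. = FALSE)
  f^2 * m^(2 / 3) / 1e4
}

#' Read a firmness dataset from CSV files
#'
#' Reads long-format measurements and per-batch storage scenarios from
#' the package's CSV dialect (RFC 4180, header row mandatory).
#'
#' The measurements file needs columns `fruit_id`, `batch_id`, `time_d`
#' and either `firmness_fi` or the pair `freq_hz` + `mass_kg` (converted
#' through [firmness_index()]); `group_id` is optional. Replicate rows
#' per (fruit, time) — e.g. four measurement positions — are averaged.
#' The scenarios file needs columns `batch_id`, `segment_index`,
#' `duration_d`, `temp_c`.
#'
#' @param measurements Path to the measurements CSV.
#' @param scenarios Path to the scenarios CSV.
#' @return A [firmness_dataset()].
#' @export
read_firmness_csv <- function(measurements, scenarios) {
  md <- read_checked_csv(measurements)
  need <- c("fruit_id", "batch_id", "time_d")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stop(measurements, ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"firmness_fi" %in% names(md)) {
    if (!all(c("freq_hz", "mass_kg") %in% names(md)))
      stop(measurements, ": needs 'firmness_fi' or 'freq_hz' + 'mass_kg'",
           call. = FALSE)
    md$firmness_fi <- firmness_index(md$freq_hz, md$mass_kg)
  }
  sd_ <- read_checked_csv(scenarios)
  needs <- c("batch_id", "segment_index", "duration_d", "temp_c")
  miss <- setdiff(needs, names(sd_))
  if (length(miss))
    stop(scenarios, ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  sc <- lapply(split(sd_, sd_$batch_id), function(b) {
    b <- b[order(b$segment_index), ]
    temp_scenario(b$duration_d, b$temp_c)
  })
  extra <- setdiff(unique(md$batch_id), names(sc))
  if (length(extra))
    stop("measurements reference batch(es) absent from the scenario file: ",
         paste(extra, collapse = ", "), call. = FALSE)
  firmness_dataset(md, sc)
}

# read.csv with a line-numbered error for malformed rows
read_checked_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  n_fields <- utils::count.fields(path, sep = ",", quote = "\"")
  bad <- which(n_fields != n_fields[1])
  if (length(bad))
    stop(path, ": line ", bad[1] + 0L, " has ", n_fields[bad[1]],
         " fields, expected ", n_fields[1], call. = FALSE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a firmness dataset to CSV files
#'
#' Writes the measurements and scenarios CSVs read back by
#' [read_firmness_csv()], and a ground-truth sidecar CSV when the
#' dataset carries a synthetic truth record. Numeric columns round-trip
#' at 12 significant digits.
#'
#' @param dataset A [firmness_dataset()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix, default `"mango"`.
#' @return Invisibly, the paths written.
#' @export
write_firmness_csv <- function(dataset, dir, prefix = "mango") {
  stopifnot(inherits(dataset, "firmness_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)

  p <- file.path(dir, paste0(prefix, "_measurements.csv"))
  md <- dataset$data
  md$firmness_fi <- signif(md$firmness_fi, 12)
  write.csv(md, p, row.names = FALSE, quote = FALSE)
  paths <- c(measurements = p)

  sc <- do.call(rbind, lapply(names(dataset$scenarios), function(b) {
    s <- dataset$scenarios[[b]]
    if (scenario_type(s) != "segments")
      stop("only segment scenarios can be written to CSV", call. = FALSE)
    data.frame(batch_id = b, segment_index = seq_along(s$durations),
               duration_d = s$durations, temp_c = s$temps_c,
               stringsAsFactors = FALSE)
  }))
  p <- file.path(dir, paste0(prefix, "_scenarios.csv"))
  write.csv(sc, p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, scenarios = p)

  if (!is.null(dataset$truth)) {
    p <- file.path(dir, paste0(prefix, "_truth_batch.csv"))
    write.csv(dataset$truth$batch, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, truth_batch = p)
    p <- file.path(dir, paste0(prefix, "_truth_fruit.csv"))
    tf <- dataset$truth$fruit
    tf$f0 <- signif(tf$f0, 12)
    write.csv(tf, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, truth_fruit = p)
  }
  invisible(paths)
}

#' Write fit results as CSV tables
#'
#' Emits an estimates table (parameter, level, cell, estimate, SE), an
#' EF table per batch unit when the fit has batch-level ethylene
#' estimates, and the per-record fitted trajectories.
#'
#' @param fit A `firmness_fit`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_fit_csv <- function(fit, dir, prefix = "fit") {
  stopifnot(inherits(fit, "firmness_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, paste0(prefix, "_estimates.csv"))
  write.csv(fit$estimates, p, row.names = FALSE, quote = FALSE)
  paths <- c(estimates = p)
  eth <- coef_table(fit, "eth")
  if (nrow(eth) && !any(eth$level == "fruit") &&
      all(eth$cell %in% names(fit$scenarios))) {
    p <- file.path(dir, paste0(prefix, "_ef.csv"))
    ef <- ef_table(fit)
    ef$ef <- round(ef$ef, 3)
    write.csv(ef, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, ef = p)
  }
  p <- file.path(dir, paste0(prefix, "_trajectories.csv"))
  tr <- fit$fitted
  tr$fitted <- round(tr$fitted, 3)
  tr$residual <- round(tr$residual, 3)
  write.csv(tr, p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, trajectories = p)
  invisible(paths)
}
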