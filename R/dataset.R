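#' Long-format repeated-measures firmness dataset
#'
#' Container pairing repeated firmness measurements with the storage
#' scenario of each batch. A "batch" here is a constant-scenario storage
#' unit (a sub-batch in multi-temperature trials); an optional `group_id`
#' ties batches together that share batch-level parameters (e.g. the four
#' temperature sub-batches of one sourcing batch, or a treatment arm).
#'
#' @param data Data frame with columns `fruit_id`, `batch_id`, `time_d`,
#'   `firmness_fi` and optionally `group_id`. If several rows share a
#'   `(fruit_id, time_d)` pair (e.g. readings at four positions on the
#'   fruit) they are averaged into one record and the position-level
#'   spread is kept as a data-quality statistic.
#' @param scenarios Named list of [temp_scenario()] objects, one per
#'   `batch_id`.
#' @param meta Optional data frame of per-batch metadata (e.g. applied
#'   ethylene level in uL/L); must contain `batch_id`.
#' @param truth Optional ground-truth parameter record (synthetic data).
#' @return An object of class `firmness_dataset`.
#' @export
firmness_dataset <- function(data, scenarios, meta = NULL, truth = NULL) {
  req <- c("fruit_id", "batch_id", "time_d", "firmness_fi")
  if (!all(req %in% names(data)))
    stop("'data' needs columns ", paste(req, collapse = ", "), call. = FALSE)
  if (!"group_id" %in% names(data)) data$group_id <- data$batch_id
  data$fruit_id <- as.character(data$fruit_id)
  data$batch_id <- as.character(data$batch_id)
  data$group_id <- as.character(data$group_id)

  if (any(data$time_d < 0)) stop("times must be >= 0", call. = FALSE)
  if (any(!is.finite(data$firmness_fi)) || any(data$firmness_fi <= 0))
    stop("firmness values must be positive and finite", call. = FALSE)

  # each fruit in exactly one batch (referential integrity)
  fb <- unique(data[, c("fruit_id", "batch_id")])
  dup <- fb$fruit_id[duplicated(fb$fruit_id)]
  if (length(dup))
    stop("fruit assigned to more than one batch: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)

  # average replicate readings per (fruit, time), keep spread statistic
  key <- paste(data$fruit_id, data$time_d, sep = "\r")
  position_sd <- NA_real_
  if (anyDuplicated(key)) {
    position_sd <- mean(tapply(data$firmness_fi, key, sd), na.rm = TRUE)
    agg <- aggregate(firmness_fi ~ fruit_id + batch_id + group_id + time_d,
                     data = data, FUN = mean)
    data <- agg[order(agg$fruit_id, agg$time_d), ]
  }

  npt <- table(data$fruit_id)
  if (any(npt < 3L))
    stop("every fruit needs >= 3 time points; offending fruit: ",
         paste(utils::head(names(npt)[npt < 3L], 5), collapse = ", "),
         call. = FALSE)

  batches <- unique(data$batch_id)
  if (!all(batches %in% names(scenarios)))
    stop("missing scenario for batch(es): ",
         paste(setdiff(batches, names(scenarios)), collapse = ", "),
         call. = FALSE)
  for (b in batches) {
    if (!inherits(scenarios[[b]], "temp_scenario"))
      stop("scenario for batch ", b, " is not a temp_scenario", call. = FALSE)
    tmax <- max(data$time_d[data$batch_id == b])
    if (tmax > scenario_duration(scenarios[[b]]) + 1e-9)
      stop("measurement time ", tmax, " d beyond scenario duration of batch ",
           b, call. = FALSE)
  }

  rownames(data) <- NULL
  structure(list(data = data, scenarios = scenarios[batches], meta = meta,
                 truth = truth, position_sd = position_sd),
            class = "firmness_dataset")
}

#' @export
print.firmness_dataset <- function(x, ...) {
  d <- x$data
  cat(sprintf(paste0("Firmness dataset: %d records, %d fruit, %d batch(es),",
                     " %d group(s)\n"),
              nrow(d), length(unique(d$fruit_id)),
              length(unique(d$batch_id)), length(unique(d$group_id))))
  cat(sprintf("  time range %g-%g d, firmness range %.1f-%.1f FI\n",
              min(d$time_d), max(d$time_d),
              min(d$firmness_fi), max(d$firmness_fi)))
  if (!is.null(x$truth)) cat("  ground-truth record attached (synthetic)\n")
  invisible(x)
}
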