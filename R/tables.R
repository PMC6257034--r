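#' Packaged storage-scenario table (ethylene-treated sub-batches)
#'
#' Storage conditions of the ethylene-treated sub-batches of the study:
#' cultivar, origin, one or two constant-temperature storage periods
#' (duration in days, temperature in degC), initial firmness where
#' recorded, applied ethylene level (uL/L) and the published ethylene
#' factor for each sub-batch.
#'
#' @return A data frame, one row per sub-batch.
#' @export
storage_table <- function() {
  read.csv(system.file("extdata", "storage_scenarios.csv",
                       package = "mangofirm", mustWork = TRUE),
           stringsAsFactors = FALSE)
}

#' Packaged batch-level estimates table
#'
#' Published batch overview: initial-firmness distribution (mean, sd) per
#' batch, estimated ethylene driver `Eth` (with SE) per ethylene
#' treatment, residual firmness `F_fix` (with SE) per batch, and the
#' percentage variance accounted for (adjusted R^2) of the batch fits.
#'
#' @return A data frame, one row per batch x treatment arm.
#' @export
batch_table <- function() {
  read.csv(system.file("extdata", "batch_estimates.csv",
                       package = "mangofirm", mustWork = TRUE),
           stringsAsFactors = FALSE)
}

#' Scenario for one row of the storage table
#' @param row One-row data frame from [storage_table()].
#' @return A [temp_scenario()].
#' @noRd
row_scenario <- function(row) {
  if (is.na(row$dur2_d)) temp_scenario(row$dur1_d, row$temp1_c)
  else temp_scenario(c(row$dur1_d, row$dur2_d), c(row$temp1_c, row$temp2_c))
}

#' Recompute the ethylene factor for every packaged sub-batch
#'
#' Joins the packaged storage scenarios with the batch-level `Eth`
#' estimates and cultivar kinetics, evaluates `k_fenz` at the
#' time-weighted mean storage temperature of each sub-batch and returns
#' both the recomputed EF and the published value. Reproducing the
#' published column to its printed 3 decimals is the package's primary
#' correctness check for the forward model.
#'
#' @return A data frame with one row per sub-batch: identifiers, mean
#'   storage temperature (`mean_temp_c`), `eth` used, recomputed `ef`
#'   and published `ef_printed`.
#' @export
#' @examples
#' ef <- reference_ef_table()
#' all(abs(ef$ef - ef$ef_printed) <= 5e-4 + 1e-12)
reference_ef_table <- function() {
  sc <- storage_table()
  be <- batch_table()
  be <- be[!is.na(be$eth), c("batch", "ethylene_ul_l", "eth")]
  out <- merge(sc, be, by = c("batch", "ethylene_ul_l"), sort = FALSE)
  kps <- list(Keitt = cultivar_params("Keitt"), Kent = cultivar_params("Kent"))
  out$mean_temp_c <- NA_real_
  out$ef <- NA_real_
  for (i in seq_len(nrow(out))) {
    scen <- row_scenario(out[i, ])
    out$mean_temp_c[i] <- mean_storage_temp(scen)
    out$ef[i] <- ethylene_factor(kps[[out$cultivar[i]]], out$eth[i], scen)
  }
  out <- out[order(out$sub_batch), ]
  rownames(out) <- NULL
  out[, c("cultivar", "batch", "sub_batch", "origin", "dur1_d", "temp1_c",
          "dur2_d", "temp2_c", "ethylene_ul_l", "eth", "mean_temp_c",
          "ef", "ef_printed")]
}
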