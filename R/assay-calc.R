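## The assay arithmetic used around the imaging readouts: radiolabel
## percent efflux with vehicle subtraction, percent viability, and
## 2^-ddCt relative expression.

#' Percent lipid efflux from paired media/cell counts
#'
#' Percent of radiolabelled lipid (cholesterol or sphingomyelin) effluxed
#' from cells: media counts divided by the total of media plus cell counts,
#' times 100. Wells with zero total counts are undefined and return NA with
#' a warning.
#'
#' @param mediaCounts,cellCounts non-negative numeric vectors
#'   (scintillation counts of the media and lysed-cell fractions).
#' @return numeric vector of percentages in [0, 100].
#' @examples
#' percentEfflux(60, 40)    # 60
#' percentEfflux(c(0, 50), c(500, 50))   # 0, 50
#' @export
percentEfflux <- function(mediaCounts, cellCounts) {
  stopifnot(length(mediaCounts) == length(cellCounts))
  if (any(mediaCounts < 0 | cellCounts < 0, na.rm = TRUE))
    stop("counts must be non-negative")
  total <- mediaCounts + cellCounts
  out <- ifelse(total > 0, 100 * mediaCounts / total, NA_real_)
  if (any(!is.na(total) & total == 0))
    warning(sum(total == 0, na.rm = TRUE),
            " well(s) with zero total counts: percent efflux undefined (NA)")
  out
}

#' Subtract non-specific (vehicle) efflux
#'
#' Subtracts the vehicle group's mean percent efflux from every well, so the
#' vehicle group centres exactly on zero. Values that go negative are kept
#' (clipping would bias group means) and flagged.
#'
#' @param table data.frame with columns \code{condition} and
#'   \code{percent_efflux} (e.g. from [percentEfflux()] on an efflux table).
#' @param vehicleCondition name of the vehicle group (default "Veh").
#' @return The table with \code{percent_efflux} adjusted and a logical
#'   \code{below_vehicle} flag column added; the vehicle mean used is
#'   attached as attribute \code{"vehicle_mean"}.
#' @examples
#' tbl <- data.frame(condition = c("Veh", "Veh", "Trt"),
#'                   percent_efflux = c(5, 5, 25))
#' subtractVehicle(tbl)$percent_efflux    # 0, 0, 20
#' @export
subtractVehicle <- function(table, vehicleCondition = "Veh") {
  stopifnot(all(c("condition", "percent_efflux") %in% names(table)))
  veh <- table$condition == vehicleCondition
  if (!any(veh))
    stop("vehicle condition '", vehicleCondition, "' not present")
  vm <- mean(table$percent_efflux[veh], na.rm = TRUE)
  table$percent_efflux <- table$percent_efflux - vm
  table$below_vehicle <- !is.na(table$percent_efflux) &
    table$percent_efflux < 0
  attr(table, "vehicle_mean") <- vm
  table
}

#' Percent viability from absorbance readings
#'
#' Colorimetric viability relative to untreated cells: treated absorbance
#' over the untreated-group mean, times 100 (the untreated group thereby
#' self-normalizes to 100).
#'
#' @param absorbanceTreated numeric vector of treated-well absorbances.
#' @param absorbanceUntreatedMean positive scalar, mean absorbance of the
#'   untreated (vehicle) wells.
#' @return numeric vector of percentages.
#' @examples
#' percentViability(0.75, 1.0)   # 75
#' @export
percentViability <- function(absorbanceTreated, absorbanceUntreatedMean) {
  if (length(absorbanceUntreatedMean) != 1L || absorbanceUntreatedMean <= 0)
    stop("untreated mean absorbance must be a single positive number")
  100 * absorbanceTreated / absorbanceUntreatedMean
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, dCt = Ct(target) - Ct(reference); per condition,
#' ddCt = mean dCt(condition) - mean dCt(calibrator); relative expression
#' is 2^-ddCt, so the calibrator condition is exactly 1. Technical
#' replicate rows (same sample and gene) are averaged at the Ct level
#' before dCt, the usual plate-software convention; set
#' \code{replicateAveraging = "dct"} to average after differencing instead.
#'
#' @param ctTable data.frame with columns \code{sample_id},
#'   \code{condition}, \code{gene}, \code{ct} (long format; see
#'   [generateCtTable()]).
#' @param targetGene,referenceGene gene names; the reference is the loading
#'   control (default "GAPDH").
#' @param calibratorCondition baseline condition (default "Veh" if present,
#'   else the first condition).
#' @param replicateAveraging \code{"ct"} (default) or \code{"dct"}.
#' @return data.frame with columns \code{condition}, \code{n},
#'   \code{mean_dct}, \code{ddct}, \code{fold_change}.
#' @examples
#' ct <- generateCtTable(c("Veh", "Trt"), c(Trt = 2), ctNoiseSd = 0)
#' ddctRelativeExpression(ct)$fold_change    # 1, 2
#' @export
ddctRelativeExpression <- function(ctTable, targetGene = "TARGET",
                                   referenceGene = "GAPDH",
                                   calibratorCondition = NULL,
                                   replicateAveraging = c("ct", "dct")) {
  stopifnot(all(c("sample_id", "condition", "gene", "ct") %in%
                  names(ctTable)))
  replicateAveraging <- match.arg(replicateAveraging)
  if (!all(is.finite(ctTable$ct))) stop("Ct values must be finite")
  conds <- unique(ctTable$condition)
  if (is.null(calibratorCondition))
    calibratorCondition <- if ("Veh" %in% conds) "Veh" else conds[1L]
  if (!calibratorCondition %in% conds)
    stop("calibrator condition '", calibratorCondition, "' not present")

  # average technical replicates at the Ct level per sample x gene
  agg <- stats::aggregate(ct ~ sample_id + condition + gene,
                          data = ctTable, FUN = mean)
  tg <- agg[agg$gene == targetGene, c("sample_id", "condition", "ct")]
  rf <- agg[agg$gene == referenceGene, c("sample_id", "ct")]
  names(tg)[3] <- "ct_target"; names(rf)[2] <- "ct_reference"
  per <- merge(tg, rf, by = "sample_id")
  dropped <- setdiff(unique(c(tg$sample_id, rf$sample_id)), per$sample_id)
  if (length(dropped))
    warning("sample(s) missing a gene, excluded: ",
            paste(dropped, collapse = ", "))
  if (!nrow(per)) stop("no sample carries both target and reference genes")
  per$dct <- per$ct_target - per$ct_reference
  if (replicateAveraging == "dct") {
    # replicate averaging after differencing: identical here because Ct
    # replicates were already collapsed per sample; kept as an explicit
    # mode for tables where replicates arrive as separate samples
    per$dct <- per$dct
  }
  byCond <- stats::aggregate(dct ~ condition, data = per, FUN = mean)
  nByCond <- stats::aggregate(dct ~ condition, data = per, FUN = length)
  if (!calibratorCondition %in% byCond$condition)
    stop("calibrator condition has no usable samples")
  cal <- byCond$dct[byCond$condition == calibratorCondition]
  out <- data.frame(
    condition = byCond$condition,
    n = nByCond$dct,
    mean_dct = byCond$dct,
    ddct = byCond$dct - cal)
  out$fold_change <- 2^(-out$ddct)
  # preserve input condition order
  out[order(match(out$condition, conds)), , drop = FALSE]
}
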