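#' Percent change between two measurements
#'
#' `100 * (end - start) / start`, the response metric applied to total
#' cellularity and tumor volume.
#'
#' @param start,end values in the same units; `start` must be positive.
#' @return percent change.
#' @export
percent_change <- function(start, end) {
  if (any(start <= 0)) stop("'start' must be positive")
  100 * (end - start) / start
}

#' Prediction summary for one patient and model variant
#'
#' Container for the four response metrics: percent change in total
#' cellularity and in tumor volume, each from baseline to surgery and from
#' scan 2 to surgery. Constructable directly from reported values, which
#' makes cross-study arithmetic (model comparisons) possible without the
#' underlying volumes.
#'
#' @param variant `"mri"` or `"pet_mri"`.
#' @param cell_from_baseline,cell_from_scan2 percent change in total
#'   cellularity.
#' @param vol_from_baseline,vol_from_scan2 percent change in tumor volume.
#' @return a `prediction_summary`.
#' @export
prediction_summary <- function(variant, cell_from_baseline, cell_from_scan2,
                               vol_from_baseline, vol_from_scan2) {
  structure(list(variant = match.arg(variant, c("mri", "pet_mri")),
                 cell_from_baseline = cell_from_baseline,
                 cell_from_scan2 = cell_from_scan2,
                 vol_from_baseline = vol_from_baseline,
                 vol_from_scan2 = vol_from_scan2),
            class = "prediction_summary")
}

#' Re-initialize at scan 2 and forecast to surgery
#'
#' Runs the calibrated model forward from the measured scan-2 state to the
#' time of surgery (subsequent doses use the scan-2 drug map) and computes
#' the response metrics: percent change in total cellularity and tumor
#' volume from baseline and from scan 2. Predicted volumes use the
#' configured cellularity threshold (reported in the result); measured
#' baseline/scan-2 volumes count their ROI voxels directly.
#'
#' @param calib a [calibrate()] result (or a [model_parameters()]).
#' @param scan1,scan2 measured [cellularity_map()]s on the forecast grid.
#' @param drug_maps a [drug_field_set()] on the forecast grid.
#' @param domain a [breast_domain()] on the forecast grid.
#' @param schedule a [treatment_schedule()].
#' @param variant `"pet_mri"` or `"mri"`.
#' @param config a [study_config()].
#' @return a `prediction_result`: `times`, `total_cellularity`,
#'   `volume_mm3` series plus a [prediction_summary()] in `$summary` and
#'   the final [cellularity_map()].
#' @export
predict_to_surgery <- function(calib, scan1, scan2, drug_maps, domain,
                               schedule, variant = c("pet_mri", "mri"),
                               config = study_config()) {
  variant <- match.arg(variant)
  params <- if (inherits(calib, "calibration_result")) calib$params else calib
  stopifnot(schedule$surgery_time > schedule$scan2_time)
  sim <- simulate_tumor(scan2, schedule$scan2_time, schedule$surgery_time,
                        params, drug_maps, domain, variant = variant,
                        config = config)
  vv <- voxel_volume_mm3(scan2$spacing)
  thr <- config$volume_threshold_fraction
  cells_base <- total_cells(scan1)
  cells_scan2 <- total_cells(scan2)
  cells_surg <- total_cells(sim$final)
  # one volume rule for measured and predicted states: voxels holding at
  # least thr * theta cells count, so start and end are commensurable
  vol_base <- tumor_volume(scan1, vv, thr)
  vol_scan2 <- tumor_volume(scan2, vv, thr)
  vol_surg <- tumor_volume(sim$final, vv, thr)
  pc_or_na <- function(start, end) {
    if (start <= 0) {
      warning("volume at the reference time is 0 at threshold ", thr,
              " * theta; percent change reported as NA", call. = FALSE)
      return(NA_real_)
    }
    percent_change(start, end)
  }
  summary <- prediction_summary(
    variant,
    cell_from_baseline = percent_change(cells_base, cells_surg),
    cell_from_scan2 = percent_change(cells_scan2, cells_surg),
    vol_from_baseline = pc_or_na(vol_base, vol_surg),
    vol_from_scan2 = pc_or_na(vol_scan2, vol_surg))
  structure(list(times = sim$times,
                 total_cellularity = sim$total_cellularity,
                 volume_mm3 = sim$volume_mm3,
                 final = sim$final,
                 summary = summary,
                 volume_threshold_fraction = thr,
                 variant = variant),
            class = "prediction_result")
}

summary_of <- function(x) {
  if (inherits(x, "prediction_result")) x$summary
  else if (inherits(x, "prediction_summary")) x
  else stop("expected a prediction_result or prediction_summary")
}

#' Compare the MRI-based and PET/MRI-based forecasts
#'
#' For a single patient, tabulates the response metrics of both model
#' variants side by side with their differences. For a patient pair (supply
#' `pair2_mri`, `pair2_pet`), additionally reports the between-patient
#' difference in the scan-2-to-surgery volume change under each variant and
#' how much the targeted-therapy variant increases that separation — the
#' quantity that distinguishes discordant treatment outcomes. Differences
#' are signed (patient 1 minus patient 2), so swapping the patients negates
#' them while magnitudes are unchanged.
#'
#' @param pred_mri,pred_pet predictions (results or summaries) for the
#'   MRI-based and PET/MRI-based variants of patient 1.
#' @param pair2_mri,pair2_pet optional predictions for a second patient.
#' @return a `model_comparison`: `$table` (metrics by variant) and, for a
#'   pair, `$pair` with `diff_mri`, `diff_pet` (signed), their magnitudes
#'   and `separation_increase = |diff_pet| - |diff_mri|` in percentage
#'   points.
#' @export
compare_models <- function(pred_mri, pred_pet, pair2_mri = NULL,
                           pair2_pet = NULL) {
  s1m <- summary_of(pred_mri); s1p <- summary_of(pred_pet)
  if (s1m$variant != "mri" || s1p$variant != "pet_mri")
    stop("arguments must be (mri, pet_mri) predictions, in that order")
  metrics <- c("cell_from_baseline", "cell_from_scan2",
               "vol_from_baseline", "vol_from_scan2")
  tab <- data.frame(metric = metrics,
                    mri = vapply(metrics, function(m) s1m[[m]], numeric(1)),
                    pet_mri = vapply(metrics, function(m) s1p[[m]], numeric(1)))
  tab$difference <- tab$pet_mri - tab$mri
  out <- list(table = tab)
  if (!is.null(pair2_mri) || !is.null(pair2_pet)) {
    if (is.null(pair2_mri) || is.null(pair2_pet))
      stop("supply both variants for the second patient")
    s2m <- summary_of(pair2_mri); s2p <- summary_of(pair2_pet)
    if (s2m$variant != "mri" || s2p$variant != "pet_mri")
      stop("second patient's arguments must be (mri, pet_mri), in that order")
    diff_mri <- s1m$vol_from_scan2 - s2m$vol_from_scan2
    diff_pet <- s1p$vol_from_scan2 - s2p$vol_from_scan2
    out$pair <- list(diff_mri = diff_mri, diff_pet = diff_pet,
                     abs_diff_mri = abs(diff_mri),
                     abs_diff_pet = abs(diff_pet),
                     separation_increase = abs(diff_pet) - abs(diff_mri))
  }
  structure(out, class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> percent changes by variant\n")
  print(x$table, row.names = FALSE)
  if (!is.null(x$pair))
    cat(sprintf(paste0("between-patient |volume change, scan2 -> surgery| ",
                       "difference: %.1f (mri) vs %.1f (pet_mri); ",
                       "separation increase %.1f points\n"),
                x$pair$abs_diff_mri, x$pair$abs_diff_pet,
                x$pair$separation_increase))
  invisible(x)
}
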