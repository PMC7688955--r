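#' Derive all modeling quantities from a patient imaging dataset
#'
#' Runs the full image-analysis chain on a two-visit dataset (as produced by
#' [generate_longitudinal_study()] or assembled from NIfTI files): ADC maps
#' from the multi-b-value diffusion stacks, fuzzy-c-means tumor ROIs inside
#' the conservative ROIs, k-means tissue segmentation of the baseline
#' contrast-enhanced frame, normalized AUC chemotherapy-delivery maps,
#' the normalized PET antibody map, the packing-geometry carrying capacity,
#' and cellularity maps for both scans.
#'
#' @param dataset a `patient_dataset` (see
#'   [generate_longitudinal_study()]): elements `dw_scan1`, `dw_scan2`,
#'   `ce_scan1`, `ce_scan2`, `pet`, `conservative_roi1`,
#'   `conservative_roi2`, `domain`, `b_values`, `spacing`, `schedule`.
#' @param config a [study_config()].
#' @return a `derived_quantities` list: `adc1`, `adc2`, `roi1`, `roi2`,
#'   `domain`, `chemo_map_scan1`, `chemo_map_scan2`, `trastuzumab_map`,
#'   `cellularity1`, `cellularity2`, `theta`, `tumor_volume1_mm3`,
#'   `tumor_volume2_mm3`.
#' @export
derive_patient_quantities <- function(dataset, config = study_config()) {
  sp <- dataset$spacing
  vv <- if (!is.null(config$voxel_volume_mm3)) config$voxel_volume_mm3
        else voxel_volume_mm3(sp)
  theta <- if (!is.null(config$theta_override)) config$theta_override
           else carrying_capacity(vv, config$packing_fraction,
                                  config$cell_radius_um)
  adc1 <- fit_adc(dataset$dw_scan1, dataset$b_values, adc_w = config$adc_w)
  adc2 <- fit_adc(dataset$dw_scan2, dataset$b_values, adc_w = config$adc_w)
  roi1 <- segment_tumor_fcm(dataset$ce_scan1, dataset$conservative_roi1,
                            n_classes = config$fcm_n_classes,
                            membership_threshold = config$fcm_membership_threshold)
  roi2 <- segment_tumor_fcm(dataset$ce_scan2, dataset$conservative_roi2,
                            n_classes = config$fcm_n_classes,
                            membership_threshold = config$fcm_membership_threshold)
  mask <- dataset$domain$mask
  tissues <- segment_tissues_kmeans(dataset$ce_scan1[[1L]], mask, roi1,
                                    adipose_is_lower = config$adipose_is_lower_intensity)
  norm_roi <- mask | roi1   # normalization region: breast plus tumor
  chemo1 <- compute_auc_drug_map(dataset$ce_scan1, roi = norm_roi,
                                 frame_interval_s = config$ce_frame_interval_s)
  chemo2 <- compute_auc_drug_map(dataset$ce_scan2, roi = norm_roi,
                                 frame_interval_s = config$ce_frame_interval_s)
  trast <- normalize_pet_map(dataset$pet, roi = norm_roi, mask = mask)
  cell1 <- cellularity_from_adc(adc1, roi1, theta, adc_w = config$adc_w)
  cell2 <- cellularity_from_adc(adc2, roi2, theta, adc_w = config$adc_w)
  structure(list(adc1 = adc1, adc2 = adc2, roi1 = roi1, roi2 = roi2,
                 domain = tissues,
                 chemo_map_scan1 = chemo1, chemo_map_scan2 = chemo2,
                 trastuzumab_map = trast,
                 cellularity1 = cell1, cellularity2 = cell2,
                 theta = theta,
                 tumor_volume1_mm3 = tumor_volume(roi1, vv),
                 tumor_volume2_mm3 = tumor_volume(roi2, vv)),
            class = "derived_quantities")
}

#' Calibrate and forecast one patient, both model variants
#'
#' Convenience wrapper running the complete analysis on derived quantities:
#' assemble the down-sampled calibration problem, calibrate the MRI-based
#' and PET/MRI-based variants independently, and forecast each from scan 2
#' to surgery on the model grid.
#'
#' @param derived a [derive_patient_quantities()] result.
#' @param schedule a [treatment_schedule()].
#' @param config a [study_config()].
#' @param variants character vector of variants to run.
#' @param control calibration control list (see [calibrate()]).
#' @return list per variant: `calibration` and `prediction`.
#' @export
run_patient_analysis <- function(derived, schedule, config = study_config(),
                                 variants = c("mri", "pet_mri"),
                                 control = list()) {
  problem <- calibration_problem(derived$cellularity1, derived$cellularity2,
                                 derived$chemo_map_scan1,
                                 derived$chemo_map_scan2,
                                 derived$trastuzumab_map,
                                 derived$domain, schedule, config)
  out <- list()
  for (v in variants) {
    calib <- calibrate(problem, variant = v, control = control)
    pred <- predict_to_surgery(calib, problem$scan1, problem$scan2,
                               problem$drug_maps, problem$domain, schedule,
                               variant = v, config = config)
    out[[v]] <- list(calibration = calib, prediction = pred)
  }
  out$problem <- problem
  out
}
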