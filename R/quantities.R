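#' Carrying capacity from packing geometry
#'
#' Maximum number of tumor cells that fit in one voxel, assuming spherical
#' cells of radius `cell_radius_um` packed at `packing_fraction`:
#' `theta = packing_fraction * voxel_volume / ((4/3) * pi * r^3)`.
#' With the nominal constants (packing 0.74, radius 10 um) a 2.18 mm^3 voxel
#' gives theta ~= 3.85e5 cells. The carrying capacity is overridable via
#' `study_config(theta_override=)` for sensitivity analyses.
#'
#' @param voxel_volume_mm3 voxel volume in mm^3.
#' @param packing_fraction dimensionless sphere packing fraction.
#' @param cell_radius_um nominal tumor cell radius in micrometres.
#' @return carrying capacity in cells per voxel.
#' @export
carrying_capacity <- function(voxel_volume_mm3, packing_fraction = 0.74,
                              cell_radius_um = 10) {
  if (voxel_volume_mm3 <= 0 || packing_fraction <= 0 || cell_radius_um <= 0)
    stop("all carrying-capacity inputs must be positive")
  r_mm <- cell_radius_um * 1e-3
  packing_fraction * voxel_volume_mm3 / ((4 / 3) * pi * r_mm^3)
}

#' Voxelwise ADC from a multi-b-value diffusion stack
#'
#' Ordinary least squares of `log S(b)` against `b` per voxel; the ADC is
#' the negated slope. Voxels with any nonpositive signal cannot be
#' log-fitted and are assigned the free-water value `adc_w` (treated as
#' fluid/background); negative fitted ADCs are floored at 0.
#'
#' @param dw_stack list of grid-compatible [image_volume()] objects, one per
#'   b-value.
#' @param b_values numeric vector of b-values in s/mm^2, matching the stack.
#' @param adc_w ADC assigned to unfittable voxels (mm^2/s).
#' @return `image_volume` of ADC in mm^2/s.
#' @export
fit_adc <- function(dw_stack, b_values, adc_w = 3.0e-3) {
  b_values <- as.numeric(b_values)
  stopifnot(length(dw_stack) == length(b_values), length(b_values) >= 2L)
  if (length(unique(b_values)) < 2L)
    stop("at least two distinct b-values are required")
  template <- dw_stack[[1L]]
  sig <- vapply(dw_stack, function(v) as.vector(v$values),
                numeric(length(template$values)))
  ok <- rowSums(sig <= 0) == 0L
  bc <- b_values - mean(b_values)
  denom <- sum(bc^2)
  slope <- as.vector(log(pmax(sig, .Machine$double.xmin)) %*% bc) / denom
  adc <- pmax(-slope, 0)
  adc[!ok] <- adc_w
  volume_like(array(adc, dim(template$values)), template)
}

#' Tumor-cell count map
#'
#' Container for the model state variable: tumor cells per voxel, bounded by
#' the carrying capacity and supported on the tumor ROI.
#'
#' @param counts 3D array of cell counts (0 outside `roi`).
#' @param theta carrying capacity (cells/voxel).
#' @param roi logical 3D array, the tumor region.
#' @param spacing,origin grid geometry, as in [image_volume()].
#' @return a `cellularity_map` object.
#' @export
cellularity_map <- function(counts, theta, roi, spacing = c(1, 1, 1),
                            origin = c(0, 0, 0)) {
  stopifnot(is.array(counts), is.array(roi), identical(dim(counts), dim(roi)))
  roi <- array(as.logical(roi), dim(roi))
  if (theta <= 0) stop("'theta' must be positive")
  if (any(counts < -1e-9) || any(counts > theta * (1 + 1e-9)))
    stop("counts must lie in [0, theta]")
  counts <- pmin(pmax(counts, 0), theta)
  if (any(counts[!roi] != 0)) stop("counts must be 0 outside the ROI")
  structure(list(counts = array(as.double(counts), dim(counts)),
                 theta = as.double(theta), roi = roi,
                 spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "cellularity_map")
}

#' @export
print.cellularity_map <- function(x, ...) {
  cat(sprintf("<cellularity_map> %s voxels, %d in ROI, theta = %.4g, total = %.4g cells\n",
              paste(dim(x$counts), collapse = " x "), sum(x$roi), x$theta,
              sum(x$counts)))
  invisible(x)
}

#' Total cell count of a cellularity map
#' @param x a [cellularity_map()].
#' @return total cells.
#' @export
total_cells <- function(x) sum(x$counts)

#' Cellularity from an ADC map
#'
#' Converts the ADC inside the tumor ROI to tumor cells per voxel via the
#' linear mapping
#' `N = theta * (adc_w - ADC) / (adc_w - ADC_min)`,
#' where `ADC_min` is the minimum ADC over the ROI (the densest voxel, which
#' therefore maps to `theta`) and `adc_w` is the ADC of free water (which
#' maps to 0). Results are clipped to `[0, theta]` and zero outside the ROI.
#'
#' @param adc [image_volume()] of ADC (mm^2/s).
#' @param roi logical array, tumor region.
#' @param theta carrying capacity (cells/voxel).
#' @param adc_w free-water ADC (mm^2/s).
#' @return a [cellularity_map()].
#' @export
cellularity_from_adc <- function(adc, roi, theta, adc_w = 3.0e-3) {
  stopifnot(is_image_volume(adc))
  roi <- array(as.logical(roi), dim(adc$values))
  if (!any(roi)) stop("'roi' is empty")
  adc_min <- min(adc$values[roi])
  if (adc_min >= adc_w)
    stop("degenerate tumor ROI: minimum ADC (", signif(adc_min, 4),
         ") is not below the free-water ADC (", adc_w, ")")
  counts <- theta * (adc_w - adc$values) / (adc_w - adc_min)
  counts <- pmin(pmax(counts, 0), theta)
  counts[!roi] <- 0
  cellularity_map(counts, theta, roi, adc$spacing, adc$origin)
}

# 1D fuzzy c-means with fuzzifier m; deterministic quantile initialization.
fcm_1d <- function(x, n_classes, m = 2, tol = 1e-5, maxit = 300L) {
  if (diff(range(x)) == 0)
    stop("degenerate feature: all values identical, cannot cluster")
  centers <- stats::quantile(x, probs = (seq_len(n_classes) - 0.5) / n_classes,
                             names = FALSE, type = 7)
  u_old <- NULL
  for (it in seq_len(maxit)) {
    d2 <- outer(x, centers, function(a, b) (a - b)^2)
    d2 <- pmax(d2, 1e-300)
    inv <- d2^(-1 / (m - 1))
    u <- inv / rowSums(inv)
    um <- u^m
    centers <- colSums(um * x) / colSums(um)
    if (!is.null(u_old) && max(abs(u - u_old)) < tol) break
    u_old <- u
  }
  list(membership = u, centers = centers, iterations = it)
}

#' Fuzzy c-means tumor segmentation
#'
#' Delineates the tumor inside a manually drawn conservative ROI by fuzzy
#' c-means clustering (fuzzifier 2) of the late contrast enhancement
#' (late post-contrast frame minus baseline). The class with the highest
#' center is taken as tumor, and voxels whose tumor-class membership reaches
#' `membership_threshold` are returned. Iteration stops when memberships
#' change by less than 1e-5 or after 300 iterations.
#'
#' @param ce_stack list of [image_volume()]: baseline then post-contrast
#'   frames.
#' @param conservative_roi logical array bounding the search region.
#' @param n_classes number of fuzzy classes (>= 2).
#' @param membership_threshold tumor-class membership cut in `[0, 1]`.
#' @param baseline_index index of the baseline frame in `ce_stack`.
#' @return logical array: the segmented tumor ROI.
#' @export
segment_tumor_fcm <- function(ce_stack, conservative_roi, n_classes = 2L,
                              membership_threshold = 0.5,
                              baseline_index = 1L) {
  stopifnot(length(ce_stack) >= 2L, n_classes >= 2L)
  conservative_roi <- array(as.logical(conservative_roi),
                            dim(ce_stack[[1L]]$values))
  if (!any(conservative_roi)) stop("'conservative_roi' is empty")
  feature <- ce_stack[[length(ce_stack)]]$values -
    ce_stack[[baseline_index]]$values
  x <- feature[conservative_roi]
  fit <- fcm_1d(x, n_classes = n_classes)
  tumor_class <- which.max(fit$centers)
  keep <- fit$membership[, tumor_class] >= membership_threshold
  out <- array(FALSE, dim(feature))
  out[conservative_roi] <- keep
  out
}

#' K-means tissue segmentation
#'
#' Partitions in-mask, non-tumor breast tissue into adipose and
#' fibroglandular classes by k = 2 clustering of the baseline
#' contrast-enhanced intensity, with deterministic quantile-based
#' initialization. On fat-suppressed contrast adipose is the darker cluster
#' (`adipose_is_lower = TRUE`); the flag inverts the assignment for the
#' opposite convention. Tumor voxels keep the tumor label.
#'
#' @param ce_baseline baseline [image_volume()].
#' @param mask logical array, inside-breast.
#' @param roi logical array, tumor region (subset of `mask`).
#' @param adipose_is_lower which cluster is adipose (see Description).
#' @return a [breast_domain()].
#' @export
segment_tissues_kmeans <- function(ce_baseline, mask, roi,
                                   adipose_is_lower = TRUE) {
  stopifnot(is_image_volume(ce_baseline))
  mask <- array(as.logical(mask), dim(ce_baseline$values))
  roi <- array(as.logical(roi), dim(ce_baseline$values))
  if (!any(mask)) stop("'mask' is empty")
  sel <- mask & !roi
  x <- ce_baseline$values[sel]
  if (length(unique(x)) < 2L)
    stop("fewer than 2 distinct intensities; cannot segment tissues")
  centers <- matrix(stats::quantile(x, c(0.25, 0.75), names = FALSE), ncol = 1)
  if (centers[1] == centers[2]) centers <- matrix(range(x), ncol = 1)
  km <- stats::kmeans(matrix(x, ncol = 1), centers = centers)
  lower <- which.min(km$centers)
  adipose_cluster <- if (adipose_is_lower) lower else 3L - lower
  labels <- array(0L, dim(mask))
  labels[sel] <- ifelse(km$cluster == adipose_cluster, 1L, 2L)
  labels[roi] <- 3L
  breast_domain(mask | roi, labels)
}

#' Normalized AUC drug-distribution map
#'
#' Surrogate for the spatial delivery of systemic chemotherapy: per voxel,
#' the trapezoidal area under the enhancement curve (signal minus baseline,
#' negatives floored at 0) over the post-injection frames, divided by the
#' maximum AUC within `roi`. Enhancement is integrated from the injection
#' time (enhancement 0) through the post-contrast frames at the configured
#' frame interval. The result is clipped to `[0, 1]`.
#'
#' @param ce_stack list of [image_volume()]: baseline then post-contrast
#'   frames, in temporal order.
#' @param roi logical array over which the normalizing maximum is taken.
#' @param baseline_index index of the baseline frame; frames after it are
#'   post-injection.
#' @param frame_interval_s frame interval in seconds (scales the AUC but not
#'   the normalized map).
#' @return `image_volume`, dimensionless in `[0, 1]`.
#' @export
compute_auc_drug_map <- function(ce_stack, roi, baseline_index = 1L,
                                 frame_interval_s = 180) {
  n <- length(ce_stack)
  if (n <= baseline_index) stop("need at least one post-contrast frame")
  roi <- array(as.logical(roi), dim(ce_stack[[1L]]$values))
  base <- ce_stack[[baseline_index]]$values
  post <- lapply((baseline_index + 1L):n,
                 function(j) pmax(ce_stack[[j]]$values - base, 0))
  np <- length(post)
  # trapezoid over nodes t = 0, dt, ..., np*dt with enhancement 0 at t = 0
  auc <- array(0, dim(base))
  prev <- array(0, dim(base))
  for (j in seq_len(np)) {
    auc <- auc + (prev + post[[j]]) / 2 * frame_interval_s
    prev <- post[[j]]
  }
  mx <- max(auc[roi])
  if (mx <= 0) stop("maximum AUC within the ROI is zero; cannot normalize")
  out <- pmin(pmax(auc / mx, 0), 1)
  volume_like(out, ce_stack[[1L]])
}

#' Normalized targeted-therapy (PET uptake) map
#'
#' Radiolabeled-trastuzumab PET uptake divided by its maximum over `roi`,
#' clipped to `[0, 1]`; the normalized map serves as the spatial
#' distribution of the HER2-targeted antibodies. Zeroed outside `mask` when
#' a mask is given.
#'
#' @param pet [image_volume()] of PET uptake (arbitrary units).
#' @param roi logical array over which the normalizing maximum is taken.
#' @param mask optional logical array; values outside it are set to 0.
#' @return `image_volume`, dimensionless in `[0, 1]`.
#' @export
normalize_pet_map <- function(pet, roi, mask = NULL) {
  stopifnot(is_image_volume(pet))
  roi <- array(as.logical(roi), dim(pet$values))
  mx <- max(pet$values[roi])
  if (mx <= 0) stop("maximum uptake within the ROI is not positive")
  out <- pmin(pmax(pet$values / mx, 0), 1)
  if (!is.null(mask)) out[!array(as.logical(mask), dim(out))] <- 0
  volume_like(out, pet)
}

#' Tumor volume
#'
#' For a measured (boolean) ROI: the voxel count times the voxel volume. For
#' a predicted [cellularity_map()]: voxels whose count reaches
#' `threshold_fraction * theta` are counted — predicted cellularity has no
#' intrinsic boundary, so the threshold (a reported analysis choice)
#' converts it to an ROI.
#'
#' @param x logical array / ROI, or a `cellularity_map`.
#' @param voxel_volume_mm3 voxel volume in mm^3.
#' @param threshold_fraction fraction of carrying capacity for predicted
#'   maps.
#' @return tumor volume in mm^3.
#' @export
tumor_volume <- function(x, voxel_volume_mm3, threshold_fraction = 0.25) {
  if (voxel_volume_mm3 <= 0) stop("'voxel_volume_mm3' must be positive")
  if (inherits(x, "cellularity_map"))
    return(sum(x$counts >= threshold_fraction * x$theta) * voxel_volume_mm3)
  sum(as.logical(x)) * voxel_volume_mm3
}

#' Drug-distribution field set
#'
#' Bundles the normalized chemotherapy delivery maps from both scans, the
#' normalized targeted-therapy map, and the dose schedule. All maps are
#' dimensionless in `[0, 1]` with maximum 1 over their normalization region.
#'
#' @param chemo_map_scan1,chemo_map_scan2 normalized AUC maps
#'   ([image_volume()]); doses given before scan 2 use the scan-1 map,
#'   later doses the scan-2 map.
#' @param trastuzumab_map normalized PET uptake map.
#' @param schedule a [treatment_schedule()].
#' @return a `drug_field_set` object.
#' @export
drug_field_set <- function(chemo_map_scan1, chemo_map_scan2, trastuzumab_map,
                           schedule) {
  stopifnot(is_image_volume(chemo_map_scan1), is_image_volume(chemo_map_scan2),
            is_image_volume(trastuzumab_map),
            inherits(schedule, "treatment_schedule"))
  for (m in list(chemo_map_scan1, chemo_map_scan2, trastuzumab_map)) {
    if (min(m$values) < 0 || max(m$values) > 1 + 1e-9)
      stop("drug maps must lie in [0, 1]")
    if (max(m$values) < 1 - 1e-6)
      stop("each drug map must attain 1 at its normalization maximum")
  }
  structure(list(chemo_map_scan1 = chemo_map_scan1,
                 chemo_map_scan2 = chemo_map_scan2,
                 trastuzumab_map = trastuzumab_map,
                 schedule = schedule),
            class = "drug_field_set")
}
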