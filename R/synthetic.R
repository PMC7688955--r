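# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. All generator sub-streams derive from the
# spec seed by fixed offsets, so whole datasets are bit-reproducible.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Separable Gaussian blur with zero padding; kernel normalized to unit sum,
# so compactly supported fields conserve their integral away from edges.
gaussian_blur3 <- function(a, fwhm_mm, spacing) {
  if (fwhm_mm < 0) stop("blur FWHM must be nonnegative")
  if (fwhm_mm == 0) return(a)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  for (ax in 1:3) {
    r <- ceiling(3 * sigma / spacing[ax])
    if (r < 1) next
    kern <- stats::dnorm((-r):r * spacing[ax], sd = sigma)
    kern <- kern / sum(kern)
    out <- a * kern[r + 1]
    for (off in 1:r) {
      sh_p <- a; sh_m <- a
      for (s in seq_len(off)) { sh_p <- shift3(sh_p, ax, +1); sh_m <- shift3(sh_m, ax, -1) }
      out <- out + kern[r + 1 + off] * sh_p + kern[r + 1 - off] * sh_m
    }
    a <- out
  }
  a
}

#' Virtual patient specification
#'
#' Describes a synthetic breast-imaging study: the grid, the breast and
#' tumor geometry, the ground-truth model parameters, the imaging noise
#' level, and the treatment schedule. The defaults emulate the clinical
#' setting of the framework: a bilateral-coil-scale breast volume sampled
#' at 2 mm isotropic, a ~9 mm radius enhancing tumor, six 3-week therapy
#' cycles with a mid-therapy scan after three, and surgery 73 days after
#' scan 2. The tumor defaults to the trial's eligibility scale (>= 2 cm
#' diameter). True dynamics parameters default to rates that reproduce the
#' reported ~0.5-0.8 %/day net cell reduction during therapy:
#' proliferation ~0.04/day, stress-free diffusion 0.15 mm^2/day,
#' chemotherapy washout half-lives of ~0.8 and ~6 days, and a
#' targeted-therapy effectiveness of 0.3.
#'
#' @param shape grid shape (voxels).
#' @param spacing_mm voxel spacing (mm).
#' @param breast_semi_axes_mm ellipsoid semi-axes of the breast (mm).
#' @param fibro_frac linear scale of the fibroglandular inner ellipsoid
#'   relative to the breast (0 disables fibroglandular tissue).
#' @param fibro_offset_mm offset of the fibroglandular region center (mm).
#' @param tumor_center_mm tumor center (mm; `NULL` = breast center).
#' @param tumor_radius_mm tumor sphere radius (mm); must exceed 2 voxels on
#'   every axis.
#' @param d0,k_mean,k_sd,alpha1,alpha2,beta1,beta2,mu ground-truth model
#'   parameters (see [model_parameters()]); `k` is a smooth random field
#'   with the given mean and SD on the proliferation support.
#' @param perfusion_bg,perfusion_tumor background level and tumor amplitude
#'   of the perfusion field (both in `[0, 1]`, summing to at most 1).
#' @param perfusion_scale_mm smoothness scale of the perfusion field.
#' @param pet_ratio tumor-to-background PET uptake ratio (>= 1).
#' @param pet_fwhm_mm PET point-spread FWHM (mm).
#' @param noise_sd relative SD of the Gaussian imaging noise (0 = noiseless).
#' @param b_values diffusion b-values (s/mm^2), including 0.
#' @param n_cycles,cycles_before_scan2,surgery_delay schedule layout (see
#'   [standard_schedule()]).
#' @param model_grid_factor down-sampling factor between the imaging grid
#'   and the grid on which the ground-truth dynamics are generated (the same
#'   factor the calibration protocol uses).
#' @param seed integer seed driving every stochastic component.
#' @return a `synthetic_patient_spec` object.
#' @export
synthetic_patient_spec <- function(shape = c(32, 32, 32),
                                   spacing_mm = c(2, 2, 2),
                                   breast_semi_axes_mm = c(26, 26, 26),
                                   fibro_frac = 0.55,
                                   fibro_offset_mm = c(5, 3, 0),
                                   tumor_center_mm = NULL,
                                   tumor_radius_mm = 12,
                                   d0 = 0.15, k_mean = 0.04, k_sd = 0.015,
                                   alpha1 = 0.35, alpha2 = 0.12,
                                   beta1 = 0.9, beta2 = 0.12, mu = 0.3,
                                   perfusion_bg = 0.2, perfusion_tumor = 0.8,
                                   perfusion_scale_mm = 6,
                                   pet_ratio = 4, pet_fwhm_mm = 5.5,
                                   noise_sd = 0,
                                   b_values = c(0, 600, 800, 1000, 1500),
                                   n_cycles = 6, cycles_before_scan2 = 3,
                                   surgery_delay = 73,
                                   model_grid_factor = 4L,
                                   seed = 1L) {
  shape <- as.integer(shape)
  spacing_mm <- as.numeric(spacing_mm)
  if (any(tumor_radius_mm <= 2 * spacing_mm))
    stop("tumor radius must exceed 2 voxels along every axis")
  if (any(c(d0, alpha1, alpha2, beta1, beta2, mu, k_mean) < 0))
    stop("true rates must be nonnegative")
  center <- (shape - 1) / 2 * spacing_mm
  if (is.null(tumor_center_mm)) tumor_center_mm <- center
  structure(list(shape = shape, spacing = spacing_mm,
                 breast_center = center,
                 breast_semi_axes = as.numeric(breast_semi_axes_mm),
                 fibro_frac = fibro_frac,
                 fibro_offset = as.numeric(fibro_offset_mm),
                 tumor_center = as.numeric(tumor_center_mm),
                 tumor_radius = tumor_radius_mm,
                 d0 = d0, k_mean = k_mean, k_sd = k_sd,
                 alpha1 = alpha1, alpha2 = alpha2,
                 beta1 = beta1, beta2 = beta2, mu = mu,
                 perfusion_bg = perfusion_bg,
                 perfusion_tumor = perfusion_tumor,
                 perfusion_scale = perfusion_scale_mm,
                 pet_ratio = pet_ratio, pet_fwhm = pet_fwhm_mm,
                 noise_sd = noise_sd, b_values = as.numeric(b_values),
                 n_cycles = n_cycles,
                 cycles_before_scan2 = cycles_before_scan2,
                 surgery_delay = surgery_delay,
                 model_grid_factor = as.integer(model_grid_factor),
                 seed = as.integer(seed)),
            class = "synthetic_patient_spec")
}

# Physical coordinate arrays of every voxel center, per axis.
coord_arrays <- function(shape, spacing, origin = c(0, 0, 0)) {
  x <- origin[1] + (seq_len(shape[1]) - 1) * spacing[1]
  y <- origin[2] + (seq_len(shape[2]) - 1) * spacing[2]
  z <- origin[3] + (seq_len(shape[3]) - 1) * spacing[3]
  list(x = array(x, shape),
       y = array(rep(y, each = shape[1]), shape),
       z = array(rep(z, each = shape[1] * shape[2]), shape))
}

#' Generate the synthetic breast domain
#'
#' Ellipsoidal breast mask, a smooth inner ellipsoid of fibroglandular
#' tissue, the remainder adipose, and a spherical tumor at the specified
#' center. Errors if the tumor sphere is not entirely inside the breast.
#'
#' @param spec a [synthetic_patient_spec()].
#' @return a [breast_domain()].
#' @export
generate_breast_domain <- function(spec) {
  co <- coord_arrays(spec$shape, spec$spacing)
  ell <- function(center, axes)
    ((co$x - center[1]) / axes[1])^2 + ((co$y - center[2]) / axes[2])^2 +
      ((co$z - center[3]) / axes[3])^2 <= 1
  mask <- ell(spec$breast_center, spec$breast_semi_axes)
  r2 <- (co$x - spec$tumor_center[1])^2 + (co$y - spec$tumor_center[2])^2 +
    (co$z - spec$tumor_center[3])^2
  tumor <- r2 <= spec$tumor_radius^2
  if (any(tumor & !mask)) stop("tumor is not entirely inside the breast mask")
  labels <- array(0L, spec$shape)
  labels[mask] <- 1L
  if (spec$fibro_frac > 0) {
    fib <- ell(spec$breast_center + spec$fibro_offset,
               spec$breast_semi_axes * spec$fibro_frac) & mask
    labels[fib] <- 2L
  }
  labels[tumor] <- 3L
  breast_domain(mask, labels)
}

#' Baseline tumor cellularity
#'
#' Draws the cell count of every tumor voxel from a normal distribution
#' truncated to `[0, theta]` (mean `theta/2`, SD `theta/4` by default),
#' zero elsewhere — the stochastic high-cellularity tumor interior the
#' pipeline's downstream stages expect. Sampling is by inverse-CDF, so the
#' draw is an exact truncated normal and reproducible from the seed.
#'
#' @param spec a [synthetic_patient_spec()].
#' @param domain a [breast_domain()].
#' @param theta carrying capacity (cells/voxel).
#' @param mean,sd moments of the parent normal (defaults `theta/2`,
#'   `theta/4`).
#' @return a [cellularity_map()].
#' @export
generate_scan1_cellularity <- function(spec, domain, theta,
                                       mean = theta / 2, sd = theta / 4) {
  roi <- tumor_roi(domain)
  if (!any(roi)) stop("tumor label region is empty")
  n <- sum(roi)
  counts <- array(0, dim(roi))
  counts[roi] <- with_seed(spec$seed + 1L, {
    plo <- stats::pnorm(0, mean, sd)
    phi <- stats::pnorm(theta, mean, sd)
    stats::qnorm(stats::runif(n, plo, phi), mean, sd)
  })
  cellularity_map(counts, theta, roi, spec$spacing)
}

#' Synthesize diffusion-weighted signals
#'
#' Mono-exponential decay `S(b) = S0 exp(-b ADC)` per voxel, plus optional
#' zero-mean Gaussian noise with SD `noise_sd * S0`.
#'
#' @param adc_field [image_volume()] of ADC (mm^2/s), nonnegative.
#' @param b_values b-values (s/mm^2), nonnegative, including 0.
#' @param s0 baseline signal: [image_volume()] or scalar.
#' @param noise_sd relative noise SD (0 = noiseless).
#' @param seed RNG seed for the noise.
#' @return list of [image_volume()], one per b-value.
#' @export
synthesize_dw_signals <- function(adc_field, b_values, s0, noise_sd = 0,
                                  seed = 1L) {
  if (any(b_values < 0)) stop("b-values must be nonnegative")
  if (min(adc_field$values) < 0) stop("ADC field must be nonnegative")
  s0v <- if (is_image_volume(s0)) s0$values else array(s0, dim(adc_field$values))
  stack <- lapply(b_values, function(b)
    volume_like(s0v * exp(-b * adc_field$values), adc_field))
  if (noise_sd > 0) {
    stack <- with_seed(seed, lapply(stack, function(v) {
      noisy <- v$values + stats::rnorm(length(v$values), sd = noise_sd * s0v)
      volume_like(pmax(noisy, 1e-6), v)
    }))
  }
  stack
}

#' Synthesize contrast-enhanced dynamics
#'
#' One baseline volume plus `n_post` post-contrast volumes whose
#' enhancement above baseline is `amplitude * P * (1 - exp(-t/tau))` with
#' `t` the time since injection — a monotone saturating profile whose AUC is
#' available in closed form and proportional to the perfusion field `P`.
#'
#' @param perfusion_field [image_volume()] with values in `[0, 1]`.
#' @param n_post number of post-contrast frames (>= 1).
#' @param baseline_signal pre-contrast signal: a scalar or an
#'   [image_volume()] carrying tissue contrast.
#' @param amplitude enhancement at full saturation for `P = 1`.
#' @param frame_interval_s frame interval (s).
#' @param tau_s saturation time constant (s).
#' @param noise_sd relative noise SD (of `baseline_signal`).
#' @param seed RNG seed for the noise.
#' @return list of `n_post + 1` [image_volume()] frames, baseline first.
#' @export
synthesize_ce_dynamics <- function(perfusion_field, n_post = 3,
                                   baseline_signal = 100, amplitude = 200,
                                   frame_interval_s = 180, tau_s = 180,
                                   noise_sd = 0, seed = 1L) {
  stopifnot(n_post >= 1)
  P <- perfusion_field$values
  base <- if (is_image_volume(baseline_signal)) baseline_signal$values
          else array(baseline_signal, dim(P))
  frames <- c(list(volume_like(base, perfusion_field)),
              lapply(seq_len(n_post), function(j) {
                t <- j * frame_interval_s
                volume_like(base + amplitude * P * (1 - exp(-t / tau_s)),
                            perfusion_field)
              }))
  if (noise_sd > 0) {
    noise_ref <- mean(base)
    frames <- with_seed(seed, lapply(frames, function(v)
      volume_like(pmax(v$values +
                         stats::rnorm(length(v$values),
                                      sd = noise_sd * noise_ref), 1e-6),
                  v)))
  }
  frames
}

#' Synthesize PET antibody uptake
#'
#' Piecewise-constant uptake (tumor = ratio, breast = 1, outside = 0)
#' convolved with a Gaussian point-spread of the stated FWHM — a coarse,
#' blurred emulation of reconstructed radiolabeled-antibody PET.
#'
#' @param domain a [breast_domain()].
#' @param tumor_to_background_ratio uptake ratio (>= 1).
#' @param blur_fwhm_mm point-spread FWHM in mm (>= 0).
#' @param spacing voxel spacing (mm).
#' @param noise_sd relative noise SD.
#' @param seed RNG seed for the noise.
#' @return an [image_volume()].
#' @export
synthesize_pet_uptake <- function(domain, tumor_to_background_ratio = 4,
                                  blur_fwhm_mm = 5.5, spacing = c(1, 1, 1),
                                  noise_sd = 0, seed = 1L) {
  if (tumor_to_background_ratio < 1)
    stop("tumor-to-background ratio must be >= 1")
  if (blur_fwhm_mm < 0) stop("blur FWHM must be nonnegative")
  up <- array(0, dim(domain$mask))
  up[domain$mask] <- 1
  up[tumor_roi(domain)] <- tumor_to_background_ratio
  up <- gaussian_blur3(up, blur_fwhm_mm, spacing)
  if (noise_sd > 0)
    up <- with_seed(seed, pmax(up + stats::rnorm(length(up), sd = noise_sd), 0))
  image_volume(array(up, dim(domain$mask)), spacing)
}

# Smooth positive perfusion surrogate: background level inside the breast
# plus a blurred bump that follows the (normalized) cellularity pattern.
perfusion_field_from <- function(pattern, domain, spec) {
  bump <- gaussian_blur3(pattern, spec$perfusion_scale, spec$spacing)
  mx <- max(bump)
  if (mx > 0) bump <- bump / mx
  p <- spec$perfusion_bg * domain$mask + spec$perfusion_tumor * bump
  p[!domain$mask] <- 0
  image_volume(pmin(p, 1), spec$spacing)
}

# Distribute each coarse-block cell total over its fine voxels using the
# scan-1 within-block pattern (uniform where scan 1 is empty), so that
# sum-mode down-sampling of the refined map reproduces the coarse map
# exactly.
refine_block_counts <- function(coarse, fine_weights, factor) {
  f <- factor
  dfine <- dim(fine_weights)
  wsum <- downsample_by_factor(image_volume(fine_weights), f, "sum")$values
  out <- array(0, dfine)
  idx <- coord_arrays(dim(coarse), c(1, 1, 1))
  # expand coarse values and block sums back to the fine grid
  expand <- function(a) {
    a[cbind(as.vector(pmin((slice.index(out, 1) - 1L) %/% f + 1L, dim(a)[1])),
            as.vector(pmin((slice.index(out, 2) - 1L) %/% f + 1L, dim(a)[2])),
            as.vector(pmin((slice.index(out, 3) - 1L) %/% f + 1L, dim(a)[3])))]
  }
  tot <- array(expand(coarse), dfine)
  ws <- array(expand(wsum), dfine)
  w <- ifelse(ws > 0, fine_weights / ws, 1 / f^3)
  tot * w
}

#' Generate a longitudinal virtual-patient study
#'
#' Builds a complete two-visit dataset with known ground truth. Scan-1
#' imaging (diffusion-weighted stack, contrast-enhanced dynamics, antibody
#' PET) is synthesized on the imaging grid; the true tumor dynamics are then
#' integrated with the forward model — at the down-sampled model resolution
#' the calibration protocol itself uses — from scan 1 to scan 2 (and on to
#' surgery) under the dosing schedule; finally, scan-2 imaging consistent
#' with the evolved cellularity is synthesized (ADC inverted through the
#' cellularity mapping, enhancement following the residual tumor). All
#' fields are produced pre-aligned on one grid, so no registration stage is
#' needed by construction.
#'
#' @param spec a [synthetic_patient_spec()].
#' @param config a [study_config()].
#' @return list with elements `dataset` (imaging stacks, conservative ROIs,
#'   schedule, acquisition metadata) and `truth` (true parameters, true
#'   cellularity at the three time points on the model grid, true drug
#'   maps, and the model-grid domain).
#' @export
generate_longitudinal_study <- function(spec, config = study_config()) {
  f <- spec$model_grid_factor
  domain <- generate_breast_domain(spec)
  sp <- spec$spacing
  theta_full <- if (!is.null(config$theta_override)) config$theta_override
    else carrying_capacity(voxel_volume_mm3(sp), config$packing_fraction,
                           config$cell_radius_um)
  schedule <- standard_schedule(spec$n_cycles, spec$cycles_before_scan2,
                                spec$surgery_delay)

  n1_full <- generate_scan1_cellularity(spec, domain, theta_full)
  roi1 <- n1_full$roi

  # --- scan-1 imaging ---------------------------------------------------
  adc_min_ref <- 0.8e-3
  adc1 <- array(2.4e-3, spec$shape)
  adc1[roi1] <- config$adc_w -
    (n1_full$counts[roi1] / theta_full) * (config$adc_w - adc_min_ref)
  adc1[!domain$mask] <- config$adc_w
  adc1 <- image_volume(adc1, sp)
  dw1 <- synthesize_dw_signals(adc1, spec$b_values, 1000,
                               noise_sd = spec$noise_sd,
                               seed = spec$seed + 11L)
  perf1 <- perfusion_field_from(array(as.double(roi1), spec$shape), domain, spec)
  # fat-suppressed-like baseline: adipose dark, fibroglandular bright
  ce_base <- array(15, spec$shape)
  ce_base[domain$tissue_labels == 1L] <- 60
  ce_base[domain$tissue_labels == 2L] <- 130
  ce_base[domain$tissue_labels == 3L] <- 100
  ce_base <- image_volume(ce_base, sp)
  ce1 <- synthesize_ce_dynamics(perf1, n_post = 3, baseline_signal = ce_base,
                                frame_interval_s = config$ce_frame_interval_s,
                                noise_sd = spec$noise_sd,
                                seed = spec$seed + 12L)
  pet <- synthesize_pet_uptake(domain, spec$pet_ratio, spec$pet_fwhm,
                               spacing = sp, noise_sd = 0)

  # --- model-grid ground truth -----------------------------------------
  labels_ds <- downsample_labels(domain$tissue_labels, f)
  domain_ds <- breast_domain(labels_ds > 0L, labels_ds)
  sp_ds <- sp * f
  theta_ds <- theta_full * f^3
  n1_ds_v <- downsample_by_factor(image_volume(n1_full$counts, sp), f, "sum")
  roi1_ds <- n1_ds_v$values > 0
  n1_ds <- cellularity_map(n1_ds_v$values, theta_ds, roi1_ds, sp_ds)

  renorm <- function(v) volume_like(v$values / max(v$values), v)
  chemo1_full <- compute_auc_drug_map(
    synthesize_ce_dynamics(perf1, 3, baseline_signal = ce_base,
                           frame_interval_s = config$ce_frame_interval_s),
    roi = domain$mask, frame_interval_s = config$ce_frame_interval_s)
  trast_full <- normalize_pet_map(pet, roi = domain$mask, mask = domain$mask)
  chemo1_ds <- renorm(downsample_by_factor(chemo1_full, f, "mean"))
  trast_ds <- renorm(downsample_by_factor(trast_full, f, "mean"))

  k_support <- dilate_mask(roi1_ds, 2L) & domain_ds$mask
  k_map <- array(0, dim(labels_ds))
  k_noise <- with_seed(spec$seed + 21L, {
    raw <- array(stats::rnorm(length(k_map)), dim(k_map))
    smooth <- gaussian_blur3(raw, 2 * max(sp_ds), sp_ds)
    # center and scale over the support so the field's mean proliferation
    # is k_mean for every seed, not a draw of the smoothing's low modes
    (smooth - mean(smooth[k_support])) / stats::sd(smooth[k_support])
  })
  k_map[k_support] <- pmax(spec$k_mean + spec$k_sd * k_noise[k_support], 0)
  params_true <- model_parameters(spec$d0, k_map, theta_ds,
                                  alpha1 = spec$alpha1, alpha2 = spec$alpha2,
                                  beta1 = spec$beta1, beta2 = spec$beta2,
                                  mu = spec$mu)

  # placeholder scan-2 map for the calibration window (no dose at or after
  # scan 2 occurs before scan2_time, so it is unused there)
  maps_cal <- drug_field_set(chemo1_ds, chemo1_ds, trast_ds, schedule)
  sim12 <- simulate_tumor(n1_ds, 0, schedule$scan2_time, params_true,
                          maps_cal, domain_ds, variant = "pet_mri",
                          config = config)
  n2_ds <- sim12$final

  # --- scan-2 imaging consistent with the evolved state ----------------
  n2_full_counts <- refine_block_counts(n2_ds$counts, n1_full$counts, f)
  n2_full_counts <- pmin(n2_full_counts, theta_full)
  roi2_full <- n2_full_counts >= 0.01 * theta_full
  n2_full_counts[!roi2_full] <- 0
  n2_full <- cellularity_map(n2_full_counts, theta_full, roi2_full, sp)
  adc2 <- array(2.4e-3, spec$shape)
  adc2[roi2_full] <- config$adc_w -
    (n2_full_counts[roi2_full] / theta_full) * (config$adc_w - adc_min_ref)
  adc2[!domain$mask] <- config$adc_w
  adc2 <- image_volume(adc2, sp)
  dw2 <- synthesize_dw_signals(adc2, spec$b_values, 1000,
                               noise_sd = spec$noise_sd,
                               seed = spec$seed + 13L)
  pat2 <- n2_full_counts / max(max(n2_full_counts), 1)
  perf2 <- perfusion_field_from(pat2, domain, spec)
  ce2 <- synthesize_ce_dynamics(perf2, n_post = 3, baseline_signal = ce_base,
                                frame_interval_s = config$ce_frame_interval_s,
                                noise_sd = spec$noise_sd,
                                seed = spec$seed + 14L)
  chemo2_full <- compute_auc_drug_map(
    synthesize_ce_dynamics(perf2, 3, baseline_signal = ce_base,
                           frame_interval_s = config$ce_frame_interval_s),
    roi = domain$mask, frame_interval_s = config$ce_frame_interval_s)
  chemo2_ds <- renorm(downsample_by_factor(chemo2_full, f, "mean"))
  maps_true <- drug_field_set(chemo1_ds, chemo2_ds, trast_ds, schedule)

  # --- truth continued to surgery --------------------------------------
  sim2s <- simulate_tumor(n2_ds, schedule$scan2_time, schedule$surgery_time,
                          params_true, maps_true, domain_ds,
                          variant = "pet_mri", config = config)

  dataset <- structure(list(
    spacing = sp, shape = spec$shape, b_values = spec$b_values,
    domain = domain,
    conservative_roi1 = dilate_mask(roi1, 3L),
    conservative_roi2 = dilate_mask(roi2_full, 3L),
    dw_scan1 = dw1, ce_scan1 = ce1, dw_scan2 = dw2, ce_scan2 = ce2,
    pet = pet, schedule = schedule, noise_sd = spec$noise_sd,
    theta = theta_full), class = "patient_dataset")
  truth <- list(
    params = params_true, theta = theta_ds,
    domain_model = domain_ds, spacing_model = sp_ds,
    scan1 = n1_ds, scan2 = n2_ds, surgery = sim2s$final,
    scan1_full = n1_full, scan2_full = n2_full,
    drug_maps = maps_true,
    roi1 = roi1_ds, roi2 = n2_ds$counts > 0,
    k_support = k_support,
    model_grid_factor = f)
  list(dataset = dataset, truth = truth)
}

#' The packaged discordant-response virtual patient pair
#'
#' Two virtual patients with the same chemotherapy world but contrasting
#' HER2-targeted-therapy delivery and effectiveness, built to mirror a
#' pCR / non-pCR contrast: patient 1 ("pCR-like") has broadly distributed,
#' maximally effective antibody (mu = 1, flat high uptake) and a modestly
#' proliferative tumor, with the mid-therapy scan after four cycles and
#' surgery 73 days later; patient 2 ("non-pCR-like") has weak targeted
#' effect (mu = 0.05, modest uptake) and a more proliferative tumor, with
#' scan 2 after three cycles and surgery 92 days later. Under the full
#' model the pair's forecasts separate; with the targeted term removed
#' they do not.
#'
#' @param seed integer; patient seeds derive from it.
#' @return list of two [synthetic_patient_spec()]s, named `pcr` and
#'   `non_pcr`.
#' @export
synthetic_patient_pair <- function(seed = 1L) {
  list(
    pcr = synthetic_patient_spec(seed = seed + 100L, mu = 1.0,
                                 pet_ratio = 8, pet_fwhm_mm = 20,
                                 k_mean = 0.03, k_sd = 0.01,
                                 cycles_before_scan2 = 4,
                                 surgery_delay = 73),
    non_pcr = synthetic_patient_spec(seed = seed + 200L, mu = 0.05,
                                     pet_ratio = 2, pet_fwhm_mm = 5.5,
                                     k_mean = 0.05, k_sd = 0.015,
                                     cycles_before_scan2 = 3,
                                     surgery_delay = 92))
}
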