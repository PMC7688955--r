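#' Study configuration
#'
#' Collects every fixed constant, numerical control, and analysis choice of
#' the modeling framework in one place. The mechanical and imaging constants
#' default to their literature-assigned values: stress-diffusion coupling
#' `gamma` = 2.0e-3 1/kPa, Poisson ratio `nu` = 0.45, cell-displacement
#' coupling `lambda` = 2.5e-3, Young moduli 2 / 4 / 20 kPa for adipose /
#' fibroglandular / tumor tissue, explicit time step `dt` = 0.25 day, ADC of
#' free water 3.0e-3 mm^2/s at 37 C, spherical packing fraction 0.74, and a
#' nominal tumor cell radius of 10 um.
#'
#' @param voxel_volume_mm3 voxel volume used for the carrying capacity; an
#'   explicit input because acquisition and modeling grids can differ. When
#'   `NULL` it is derived from the data grid at hand.
#' @param theta_override carrying capacity in cells/voxel, overriding the
#'   packing-geometry formula when supplied.
#' @param volume_threshold_fraction fraction of the carrying capacity above
#'   which a voxel of a *predicted* cellularity map counts toward tumor
#'   volume (measured ROIs are counted directly). Reported alongside any
#'   volume prediction.
#' @param mech_cadence recompute the mechanical equilibrium every this many
#'   simulation steps (1 = every step; `Inf` = once at the initial state).
#' @param thalf_drug1,thalf_drug2 literature ranges (days) for the terminal
#'   elimination half-life of the two chemotherapies; these define the decay
#'   rate bounds used in calibration.
#' @param ce_frame_interval_s dynamic contrast-enhanced frame interval in
#'   seconds.
#' @param adipose_is_lower_intensity tissue k-means label assignment: on
#'   fat-suppressed contrast adipose is the darker cluster; set `FALSE` for
#'   the opposite contrast convention.
#' @param fcm_n_classes,fcm_membership_threshold fuzzy c-means class count
#'   and the tumor-class membership cut.
#' @param alpha_cap,k_cap,mu_cap calibration bound caps for chemotherapy
#'   efficacy (1/day), voxelwise proliferation (1/day), and targeted-therapy
#'   effectiveness (dimensionless).
#' @param k_lo lower bound for the voxelwise proliferation rate. The default
#'   0 encodes that `k` is a proliferation rate: cell loss is carried by the
#'   therapy terms, which is what makes those terms identifiable from two
#'   imaging visits. Set negative to allow net-decline proliferation.
#' @param seed integer RNG seed for every stochastic component.
#' @param ... additional named entries stored verbatim.
#' @return a named list with class `study_config`.
#' @export
study_config <- function(voxel_volume_mm3 = NULL,
                         theta_override = NULL,
                         volume_threshold_fraction = 0.25,
                         mech_cadence = 1,
                         thalf_drug1 = c(0.4, 2),
                         thalf_drug2 = c(2, 12),
                         ce_frame_interval_s = 180,
                         adipose_is_lower_intensity = TRUE,
                         fcm_n_classes = 2L,
                         fcm_membership_threshold = 0.5,
                         alpha_cap = 2,
                         k_cap = 0.5,
                         k_lo = 0,
                         mu_cap = 1,
                         seed = 1L,
                         ...) {
  cfg <- list(
    gamma = 2.0e-3,            # 1/kPa
    nu = 0.45,                 # dimensionless
    lambda = 2.5e-3,           # dimensionless
    E_adipose = 2,             # kPa
    E_fibroglandular = 4,      # kPa
    E_tumor = 20,              # kPa
    dt = 0.25,                 # day
    adc_w = 3.0e-3,            # mm^2/s, free water at 37 C
    packing_fraction = 0.74,
    cell_radius_um = 10,
    voxel_volume_mm3 = voxel_volume_mm3,
    theta_override = theta_override,
    volume_threshold_fraction = volume_threshold_fraction,
    mech_cadence = mech_cadence,
    thalf_drug1 = thalf_drug1,
    thalf_drug2 = thalf_drug2,
    ce_frame_interval_s = ce_frame_interval_s,
    adipose_is_lower_intensity = adipose_is_lower_intensity,
    fcm_n_classes = as.integer(fcm_n_classes),
    fcm_membership_threshold = fcm_membership_threshold,
    alpha_cap = alpha_cap,
    k_cap = k_cap,
    k_lo = k_lo,
    mu_cap = mu_cap,
    seed = as.integer(seed)
  )
  extra <- list(...)
  cfg[names(extra)] <- extra
  structure(cfg, class = "study_config")
}

#' Treatment schedule
#'
#' Times are in days with scan 1 defining day 0. All drugs (two
#' chemotherapies plus the targeted antibodies) are administered together on
#' each dose date, every three weeks in the trial regimen.
#'
#' @param dose_times numeric vector of dose days, sorted ascending.
#' @param scan2_time day of the mid-therapy scan.
#' @param surgery_time day of surgery; must exceed `scan2_time`.
#' @param scan1_time day of the baseline scan (0 by definition).
#' @param n_chemo_drugs number of chemotherapy agents (2: docetaxel and
#'   carboplatin).
#' @return a `treatment_schedule` object.
#' @export
treatment_schedule <- function(dose_times, scan2_time, surgery_time,
                               scan1_time = 0, n_chemo_drugs = 2L) {
  dose_times <- as.numeric(dose_times)
  if (is.unsorted(dose_times)) stop("'dose_times' must be sorted ascending")
  if (!(scan1_time == 0 && scan1_time <= scan2_time && scan2_time < surgery_time))
    stop("times must satisfy scan1 = 0 <= scan2 < surgery")
  structure(list(dose_times = dose_times,
                 scan1_time = scan1_time,
                 scan2_time = scan2_time,
                 surgery_time = surgery_time,
                 n_chemo_drugs = as.integer(n_chemo_drugs)),
            class = "treatment_schedule")
}

#' Every-3-week dosing schedule helper
#'
#' Builds the trial regimen: `n_cycles` doses 21 days apart starting at day
#' 0, a mid-therapy scan after `cycles_before_scan2` cycles, and surgery
#' `surgery_delay` days after scan 2.
#'
#' @param n_cycles total number of therapy cycles (6 in the trial).
#' @param cycles_before_scan2 cycles completed before the second scan.
#' @param surgery_delay days from scan 2 to surgery.
#' @return a [treatment_schedule()].
#' @export
standard_schedule <- function(n_cycles = 6, cycles_before_scan2 = 3,
                              surgery_delay = 92) {
  doses <- 21 * (seq_len(n_cycles) - 1)
  scan2 <- 21 * cycles_before_scan2
  treatment_schedule(doses, scan2_time = scan2,
                     surgery_time = scan2 + surgery_delay)
}

#' Read / write a run configuration file
#'
#' The run configuration is a single YAML (or JSON) document holding the
#' [study_config()] entries, the [treatment_schedule()], file paths, the
#' diffusion b-values (s/mm^2), and contrast-injection indexing.
#'
#' @param path file path (`.yaml`, `.yml`, or `.json`).
#' @return `read_run_config`: a list with elements `config` (a
#'   `study_config`), `schedule` (a `treatment_schedule` when present), and
#'   any further top-level entries.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  }
  cfg <- do.call(study_config, if (is.null(raw$config)) list() else raw$config)
  sched <- NULL
  if (!is.null(raw$schedule)) sched <- do.call(treatment_schedule, raw$schedule)
  out <- raw
  out$config <- cfg
  out$schedule <- sched
  out
}

#' @rdname read_run_config
#' @param run list as returned by `read_run_config`.
#' @export
write_run_config <- function(run, path) {
  run$config <- unclass(run$config)
  run$config <- run$config[!vapply(run$config, is.null, logical(1))]
  if (!is.null(run$schedule)) run$schedule <- unclass(run$schedule)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(run, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to write YAML configs")
    yaml::write_yaml(run, path)
  }
  invisible(path)
}
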