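#' Model parameter set
#'
#' Global parameters of the governing reaction-diffusion equation plus the
#' voxelwise proliferation map. `d0` is the stress-free diffusion
#' coefficient (mm^2/day); `alpha1, alpha2` (1/day) are the efficacies and
#' `beta1, beta2` (1/day) the washout decay rates of the two
#' chemotherapies; `mu` (dimensionless) is the effectiveness of the
#' HER2-targeted therapy entering the growth modulation
#' `g = 1 - 2 mu [trastuzumab]`; `k_map` (1/day) is the spatially resolved
#' proliferation rate; `theta` the carrying capacity.
#'
#' @param d0 diffusion coefficient, mm^2/day (>= 0).
#' @param k_map 3D array of proliferation rates, 1/day.
#' @param theta carrying capacity, cells/voxel.
#' @param alpha1,alpha2 chemotherapy efficacies, 1/day (>= 0).
#' @param beta1,beta2 chemotherapy decay rates, 1/day (> 0).
#' @param mu targeted-therapy effectiveness, dimensionless (>= 0).
#' @return a `model_parameters` object.
#' @export
model_parameters <- function(d0, k_map, theta, alpha1 = 0, alpha2 = 0,
                             beta1 = 0.1, beta2 = 0.1, mu = 0) {
  stopifnot(is.array(k_map), length(dim(k_map)) == 3L)
  if (d0 < 0 || alpha1 < 0 || alpha2 < 0 || mu < 0)
    stop("d0, alphas and mu must be nonnegative")
  if (beta1 <= 0 || beta2 <= 0) stop("betas must be positive")
  if (any(!is.finite(k_map))) stop("k_map must be finite")
  structure(list(d0 = d0, k_map = k_map, theta = theta,
                 alpha1 = alpha1, alpha2 = alpha2,
                 beta1 = beta1, beta2 = beta2, mu = mu),
            class = "model_parameters")
}

# Scalar therapy time factors (1/day) for the scan-1 and scan-2 drug maps:
# the sum over administered doses of alpha_i * exp(-beta_i (t - t_d)),
# additively superposed across doses, split by which map a dose uses
# (doses before scan 2 use the scan-1 map; later doses the scan-2 map).
chemo_time_factors <- function(times, schedule, params) {
  doses <- schedule$dose_times
  epoch2 <- doses >= schedule$scan2_time
  f <- function(t, td) {
    el <- t - td[td <= t + 1e-12]
    if (!length(el)) return(0)
    sum(params$alpha1 * exp(-params$beta1 * el) +
        params$alpha2 * exp(-params$beta2 * el))
  }
  c1 <- vapply(times, function(t) f(t, doses[!epoch2]), numeric(1))
  c2 <- vapply(times, function(t) f(t, doses[epoch2]), numeric(1))
  list(c1 = c1, c2 = c2)
}

#' Chemotherapy decay field at a given time
#'
#' The therapy sink `C_drug(x, t)` of the governing equation: for every dose
#' administered at `t_d <= t`, each chemotherapy contributes
#' `alpha_i * M(x) * exp(-beta_i (t - t_d))`, where `M` is the normalized
#' AUC delivery map in force at that dose (scan-1 map before scan 2, scan-2
#' map afterwards). Contributions superpose additively across doses; both
#' chemotherapies share the delivery map and differ in `alpha_i, beta_i`.
#'
#' @param t time in days (scan 1 = 0).
#' @param drug_maps a [drug_field_set()].
#' @param params a [model_parameters()].
#' @return [image_volume()] of the therapy rate, 1/day.
#' @export
chemo_field <- function(t, drug_maps, params) {
  fac <- chemo_time_factors(t, drug_maps$schedule, params)
  volume_like(drug_maps$chemo_map_scan1$values * fac$c1 +
              drug_maps$chemo_map_scan2$values * fac$c2,
              drug_maps$chemo_map_scan1)
}

#' Targeted-therapy growth modulation
#'
#' `g = 1 - 2 mu [trastuzumab]` once the targeted therapy has been
#' administered, and 1 before. The effect is constant in time thereafter
#' (no antibody clearance). `g` may go negative, representing net cell
#' decline under a strong targeted effect; `mu` is bounded in `[0, 1]`
#' during calibration so `g >= -1`.
#'
#' @param trastuzumab_map normalized antibody distribution
#'   ([image_volume()] or array) in `[0, 1]`.
#' @param mu targeted-therapy effectiveness (dimensionless).
#' @param targeted_started has the first dose been given?
#' @return array of multiplicative proliferation factors.
#' @export
growth_modulation <- function(trastuzumab_map, mu, targeted_started = TRUE) {
  u <- if (is_image_volume(trastuzumab_map)) trastuzumab_map$values
       else trastuzumab_map
  if (!targeted_started || mu == 0) return(array(1, dim(u)))
  1 - 2 * mu * u
}

#' Explicit-scheme stability check
#'
#' The forward-Euler diffusion update is stable for
#' `dt <= 1 / (2 D_max (1/dx^2 + 1/dy^2 + 1/dz^2))`. When the nominal step
#' violates the bound, the largest uniform sub-step that divides it evenly
#' is returned and the integrator sub-steps transparently.
#'
#' @param d_field diffusivity array, [image_volume()], or scalar maximum
#'   (mm^2/day).
#' @param spacing voxel spacing (mm).
#' @param dt nominal time step (day).
#' @return list with `stable` (logical), `dt_sub` (day), `n_sub` (integer
#'   sub-steps per nominal step).
#' @export
check_stability <- function(d_field, spacing, dt) {
  dmax <- if (is_image_volume(d_field)) max(d_field$values) else max(d_field)
  if (dmax <= 0) return(list(stable = TRUE, dt_sub = dt, n_sub = 1L))
  dt_max <- 1 / (2 * dmax * sum(1 / spacing^2))
  if (dt <= dt_max + 1e-15) return(list(stable = TRUE, dt_sub = dt, n_sub = 1L))
  m <- as.integer(ceiling(dt / dt_max))
  list(stable = FALSE, dt_sub = dt / m, n_sub = m)
}

#' One explicit time step (reference implementation)
#'
#' A single forward-Euler update of the governing equation in plain
#' vectorized R: 7-point flux-form diffusion with face-averaged D and zero
#' flux across the breast boundary, logistic growth with the (possibly
#' targeted-therapy-modulated) proliferation map, and the chemotherapy
#' sink, clipped to `[0, theta]`. This is the readable reference path; the
#' integrator in [simulate_tumor()] uses a compiled equivalent that is
#' cross-checked against this function in the test suite.
#'
#' @param state a [cellularity_map()].
#' @param t current time (day).
#' @param params a [model_parameters()].
#' @param drug_maps a [drug_field_set()].
#' @param domain a [breast_domain()].
#' @param mech_state optional [solve_equilibrium()] result; when supplied,
#'   its von Mises stress damps the diffusivity, otherwise `D = d0`.
#' @param dt time step (day).
#' @param variant `"pet_mri"` (targeted term active) or `"mri"`.
#' @return the updated [cellularity_map()].
#' @export
step <- function(state, t, params, drug_maps, domain, mech_state = NULL,
                 dt = 0.25, variant = c("pet_mri", "mri")) {
  variant <- match.arg(variant)
  mask <- domain$mask
  sp <- state$spacing
  N <- state$counts
  D <- array(params$d0, dim(N))
  if (!is.null(mech_state))
    D <- damp_diffusion(params$d0, mech_state$von_mises)
  started <- length(drug_maps$schedule$dose_times) > 0 &&
    t >= min(drug_maps$schedule$dose_times) - 1e-12
  g <- if (variant == "pet_mri")
    growth_modulation(drug_maps$trastuzumab_map, params$mu, started)
  else array(1, dim(N))
  kH <- params$k_map * g
  C <- chemo_field(t, drug_maps, params)$values
  lap <- array(0, dim(N))
  for (ax in 1:3) {
    for (dir in c(+1, -1)) {
      Nn <- shift3(N, ax, dir)
      Dn <- shift3(D, ax, dir)
      open <- shift3(mask, ax, dir, fill = FALSE) & mask
      flux <- 0.5 * (D + Dn) * (Nn - N) / sp[ax]^2
      lap <- lap + flux * open
    }
  }
  out <- N + dt * (lap + kH * (1 - N / params$theta) * N - C * N)
  out <- pmin(pmax(out, 0), params$theta)
  out[!mask] <- 0
  cellularity_map(out, params$theta, state$roi | (out > 0), sp, state$origin)
}

#' Integrate the tumor growth-and-therapy model
#'
#' Integrates the governing equation from `t0` to `t1` with the explicit
#' scheme (nominal step from `config$dt`, automatic CFL sub-stepping), no
#' flux across the breast boundary, and the mechanical equilibrium
#' recomputed every `config$mech_cadence` steps (its von Mises stress damps
#' the diffusivity). `variant = "mri"` forces the targeted-therapy term off;
#' with `mu = 0` the two variants coincide exactly.
#'
#' @param initial a [cellularity_map()] at `t0`.
#' @param t0,t1 start and end times in days (`t1 > t0`).
#' @param params a [model_parameters()].
#' @param drug_maps a [drug_field_set()].
#' @param domain a [breast_domain()].
#' @param variant `"pet_mri"` or `"mri"`.
#' @param config a [study_config()] (time step, mechanics cadence, volume
#'   threshold).
#' @param mech_op optional pre-built [elastic_operator()] for the domain
#'   (cached across repeated simulations, e.g. inside calibration).
#' @return a `simulation_result`: `times` (day), `total_cellularity`
#'   (cells), `volume_mm3`, `final` (a `cellularity_map`), `clipped`
#'   (voxel-updates clipped to `[0, theta]`).
#' @export
simulate_tumor <- function(initial, t0, t1, params, drug_maps, domain,
                           variant = c("pet_mri", "mri"),
                           config = study_config(), mech_op = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(initial, "cellularity_map"), t1 > t0)
  dt <- config$dt
  nsteps <- as.integer(round((t1 - t0) / dt))
  if (abs(t0 + nsteps * dt - t1) > 1e-9)
    stop("t1 - t0 must be an integer multiple of dt = ", dt)
  sp <- initial$spacing
  mask <- domain$mask
  theta <- params$theta
  dims <- dim(initial$counts)
  vol_thr <- config$volume_threshold_fraction
  vv <- voxel_volume_mm3(sp)

  use_mech <- params$d0 > 0 && config$lambda > 0 && config$gamma > 0
  cadence <- config$mech_cadence
  materials <- op <- NULL
  if (use_mech) {
    materials <- material_field(domain, config)
    op <- if (is.null(mech_op)) elastic_operator(materials, domain, sp)
          else mech_op
  }
  sub <- check_stability(params$d0, sp, dt)
  m <- sub$n_sub
  dt_sub <- sub$dt_sub

  doses <- drug_maps$schedule$dose_times
  t_start <- if (length(doses)) min(doses) else Inf
  # chunk boundaries: mechanics cadence and the targeted-therapy onset
  bounds <- nsteps
  if (is.finite(cadence) && cadence >= 1)
    bounds <- c(bounds, seq(as.integer(cadence), nsteps, by = as.integer(cadence)))
  if (t_start > t0 && t_start < t1)
    bounds <- c(bounds, as.integer(ceiling((t_start - t0) / dt - 1e-9)))
  bounds <- sort(unique(bounds))

  M1 <- drug_maps$chemo_map_scan1$values
  M2 <- drug_maps$chemo_map_scan2$values
  u_map <- drug_maps$trastuzumab_map$values

  N <- initial$counts
  D <- array(params$d0, dims)
  D[!mask] <- 0
  totals <- numeric(nsteps + 1L)
  vols <- numeric(nsteps + 1L)
  totals[1L] <- sum(N)
  vols[1L] <- sum(N >= vol_thr * theta) * vv
  clipped <- 0
  done <- 0L
  for (b in bounds) {
    nchunk <- b - done
    if (nchunk <= 0L) next
    t_chunk <- t0 + done * dt
    if (use_mech) {
      mech <- solve_equilibrium(N, materials, domain, spacing = sp, op = op)
      D <- damp_diffusion(params$d0, mech$von_mises)
      D[!mask] <- 0
    }
    started <- t_chunk >= t_start - 1e-12
    g <- if (variant == "pet_mri" && started && params$mu > 0)
      1 - 2 * params$mu * u_map else array(1, dims)
    kH <- params$k_map * g
    # therapy factor at sub-step midpoints: second-order quadrature of the
    # decaying coefficient within the explicit update
    sub_times <- t_chunk + dt_sub * (0:(nchunk * m - 1L)) + dt_sub / 2
    fac <- chemo_time_factors(sub_times, drug_maps$schedule, params)
    res <- rd_advance(N, D, kH, theta, mask, as.integer(dims), sp,
                      dt_sub, nchunk * m, M1, M2, fac$c1, fac$c2,
                      record_every = m, vol_threshold = vol_thr)
    N <- res$N
    totals[(done + 2L):(done + nchunk + 1L)] <- res$totals
    vols[(done + 2L):(done + nchunk + 1L)] <- res$counts * vv
    clipped <- clipped + res$clipped
    done <- b
  }
  final <- cellularity_map(N, theta, mask & (N > 0) | initial$roi,
                           sp, initial$origin)
  structure(list(times = t0 + dt * (0:nsteps),
                 total_cellularity = totals,
                 volume_mm3 = vols,
                 final = final,
                 clipped = clipped,
                 variant = variant),
            class = "simulation_result")
}
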