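# Shared fixture builders. Everything is generated in code at test time;
# no data files.

# A single-voxel world: the domain, a unit drug field, and a schedule with
# one dose at t = 0. Closed-form ODE oracles live on this grid.
one_voxel_world <- function(theta = 1e6, dose_times = 0,
                            scan2_time = 50, surgery_time = 60) {
  one <- image_volume(array(1, c(1, 1, 1)))
  dom <- breast_domain(array(TRUE, c(1, 1, 1)), array(3L, c(1, 1, 1)))
  sched <- treatment_schedule(dose_times, scan2_time = scan2_time,
                              surgery_time = surgery_time)
  list(domain = dom,
       maps = drug_field_set(one, one, one, sched),
       schedule = sched, theta = theta,
       state = function(n0) cellularity_map(array(n0, c(1, 1, 1)), theta,
                                            array(TRUE, c(1, 1, 1))))
}

# Uniform drug maps over an arbitrary domain (value 1 everywhere), so the
# therapy field is spatially flat.
flat_drug_maps <- function(domain, spacing, schedule) {
  one <- image_volume(array(1, dim(domain$mask)), spacing)
  drug_field_set(one, one, one, schedule)
}

# Small, fast virtual-patient spec used by non-acceptance tests.
small_spec <- function(seed = 1, ...) {
  synthetic_patient_spec(shape = c(24, 24, 24), spacing_mm = c(2, 2, 2),
                         breast_semi_axes_mm = c(20, 20, 20),
                         tumor_radius_mm = 9, model_grid_factor = 4L,
                         seed = seed, ...)
}

# Config used by simulation-heavy tests: mechanics every 4 steps keeps the
# runtime modest without changing any physics constants.
fast_config <- function(...) study_config(mech_cadence = 4, ...)

# Truncated-normal moments on [0, theta] for the scan-1 cellularity oracle.
truncnorm_moments <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  Z <- pnorm(b) - pnorm(a)
  m <- mu + sd * (dnorm(a) - dnorm(b)) / Z
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                 ((dnorm(a) - dnorm(b)) / Z)^2)
  list(mean = m, var = v)
}

# Analytic 1D two-point boundary-value oracle: solve
#   (G + kappa) u'' = lambda * N'(x)  on (a, b),  u(a) = u(b) = 0,
# for piecewise-linear N by exact piecewise integration at the node
# positions. Independent of the package's sparse solver.
oracle_1d <- function(Nv, dx, G, kappa, lambda) {
  n <- length(Nv)
  x <- (0:(n - 1)) * dx
  a <- -dx; b <- n * dx
  m <- lambda / (G + kappa)
  nodes <- c(a, x, b); vals <- c(0, Nv, 0)
  # cumulative exact integral of the piecewise-linear N at every node
  seg <- diff(nodes) * (head(vals, -1) + tail(vals, -1)) / 2
  cumI <- c(0, cumsum(seg))
  intN <- approxfun(nodes, cumI)          # exact at node positions
  C1 <- -m * cumI[length(cumI)] / (b - a)
  m * intN(x) + C1 * (x - a)
}

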