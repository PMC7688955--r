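test_that("chemotherapy field superposes dose decays", {
  w <- one_voxel_world(dose_times = c(10, 31), scan2_time = 50,
                       surgery_time = 60)
  par <- model_parameters(0, array(0, c(1, 1, 1)), w$theta,
                          alpha1 = 0.3, beta1 = 0.2,
                          alpha2 = 0.1, beta2 = 0.05)
  expect_equal(chemo_field(5, w$maps, par)$values[1], 0)  # before first dose
  t <- 25
  expect_equal(chemo_field(t, w$maps, par)$values[1],
               0.3 * exp(-0.2 * (t - 10)) + 0.1 * exp(-0.05 * (t - 10)),
               tolerance = 1e-12)
  t <- 40  # both doses active, additive superposition
  expect_equal(chemo_field(t, w$maps, par)$values[1],
               sum(0.3 * exp(-0.2 * (t - c(10, 31))) +
                     0.1 * exp(-0.05 * (t - c(10, 31)))),
               tolerance = 1e-12)
  expect_lt(chemo_field(4000, w$maps, par)$values[1], 1e-12)  # washout limit
})

test_that("growth modulation follows g = 1 - 2 mu u", {
  u <- image_volume(array(c(0, 0.5, 1, 1), c(2, 2, 1)))
  expect_true(all(growth_modulation(u, 0) == 1))
  expect_true(all(growth_modulation(u, 0.5, targeted_started = FALSE) == 1))
  g <- growth_modulation(u, 0.25)
  expect_equal(g[1, 2, 1], 0.5)
  g2 <- growth_modulation(u, 0.75)
  expect_equal(g2[1, 2, 1], -0.5)   # net decline permitted
})

test_that("stability check sub-steps evenly when the CFL bound is violated", {
  expect_true(check_stability(0, c(1, 1, 1), 0.25)$stable)
  s <- check_stability(1e4, c(2, 2, 2), 0.25)
  expect_false(s$stable)
  expect_equal(0.25 / s$dt_sub, s$n_sub)
  expect_lte(s$dt_sub, 1 / (2 * 1e4 * 3 / 4))
  # sub-stepped trajectory agrees with a natively stable one
  w <- one_voxel_world()
  par <- model_parameters(0, array(0.05, c(1, 1, 1)), w$theta)
  cfg1 <- study_config()
  cfg2 <- study_config(); cfg2$dt <- 0.05
  s1 <- simulate_tumor(w$state(w$theta / 3), 0, 10, par, w$maps, w$domain,
                       "mri", cfg1)
  s2 <- simulate_tumor(w$state(w$theta / 3), 0, 10, par, w$maps, w$domain,
                       "mri", cfg2)
  expect_lt(abs(total_cells(s1$final) - total_cells(s2$final)) /
              total_cells(s2$final), 0.005)
})

test_that("compiled stepper agrees with the R reference step", {
  set.seed(23)
  shape <- c(7, 6, 5)
  spec <- list(spacing = c(2, 1.5, 3))
  mask <- array(runif(prod(shape)) < 0.8, shape)
  labels <- array(0L, shape); labels[mask] <- 1L
  labels[3:4, 3:4, 2:3] <- ifelse(mask[3:4, 3:4, 2:3], 3L, 0L)
  dom <- breast_domain(mask, labels)
  theta <- 1e5
  counts <- array(runif(prod(shape), 0, theta), shape); counts[!mask] <- 0
  st <- cellularity_map(counts, theta, mask, spec$spacing)
  sched <- treatment_schedule(c(0, 2), scan2_time = 3, surgery_time = 10)
  m1 <- image_volume(array(runif(prod(shape)), shape), spec$spacing)
  m1$values[which.max(m1$values)] <- 1
  maps <- drug_field_set(m1, m1, m1, sched)
  par <- model_parameters(0.3, array(0.1, shape), theta,
                          alpha1 = 0.2, beta1 = 0.4, alpha2 = 0.1,
                          beta2 = 0.1, mu = 0.3)
  t <- 2.5
  ref <- step(st, t, par, maps, dom, dt = 0.25, variant = "pet_mri")
  fac <- her2forecast:::chemo_time_factors(t, sched, par)
  kH <- par$k_map * growth_modulation(maps$trastuzumab_map, par$mu, TRUE)
  res <- her2forecast:::rd_advance(
    st$counts, array(par$d0, shape) * mask, kH, theta, mask,
    as.integer(shape), spec$spacing, 0.25, 1L,
    maps$chemo_map_scan1$values, maps$chemo_map_scan2$values,
    fac$c1, fac$c2, record_every = 1L, vol_threshold = 0.25)
  expect_lt(max(abs(res$N - ref$counts)), 1e-9 * theta * 1e-3)
})

test_that("single-voxel closed forms: logistic growth and drug decay", {
  w <- one_voxel_world(theta = 1e6)
  cfg <- study_config()
  # logistic: k = 0.1/day, N0 = theta/2, 10 days
  par <- model_parameters(0, array(0.1, c(1, 1, 1)), w$theta)
  sim <- simulate_tumor(w$state(w$theta / 2), 0, 10, par, w$maps, w$domain,
                        "mri", cfg)
  exact <- w$theta / (1 + exp(-0.1 * 10))
  expect_lt(abs(total_cells(sim$final) - exact) / exact, 1e-3)
  # drug-only decay: N(t) = N0 exp(-(alpha/beta)(1 - e^(-beta t)))
  par2 <- model_parameters(0, array(0, c(1, 1, 1)), w$theta,
                           alpha1 = 0.02, beta1 = 0.05,
                           alpha2 = 0, beta2 = 0.1)
  sim2 <- simulate_tumor(w$state(w$theta / 2), 0, 10, par2, w$maps,
                         w$domain, "mri", cfg)
  exact2 <- w$theta / 2 * exp(-(0.02 / 0.05) * (1 - exp(-0.05 * 10)))
  expect_lt(abs(total_cells(sim2$final) - exact2) / exact2, 1e-3)
  # at clinical-scale rates the explicit scheme converges at first order
  err_at <- function(dt) {
    cfgd <- study_config(); cfgd$dt <- dt
    par3 <- model_parameters(0, array(0, c(1, 1, 1)), w$theta,
                             alpha1 = 0.3, beta1 = 0.2, beta2 = 0.1)
    s <- simulate_tumor(w$state(w$theta / 2), 0, 10, par3, w$maps,
                        w$domain, "mri", cfgd)
    ex <- w$theta / 2 * exp(-(0.3 / 0.2) * (1 - exp(-0.2 * 10)))
    abs(total_cells(s$final) - ex) / ex
  }
  e1 <- err_at(0.25); e2 <- err_at(0.125)
  expect_lt(e2, 0.62 * e1)
})

test_that("no-flux flux-form diffusion conserves cells (mechanics on)", {
  spec <- small_spec(seed = 8)
  dom <- generate_breast_domain(spec)
  theta <- carrying_capacity(voxel_volume_mm3(spec$spacing))
  n0 <- generate_scan1_cellularity(spec, dom, theta)
  sched <- treatment_schedule(numeric(0), scan2_time = 10, surgery_time = 50)
  maps <- flat_drug_maps(dom, spec$spacing, sched)
  par <- model_parameters(0.3, array(0, spec$shape), theta)
  sim <- simulate_tumor(n0, 0, 20, par, maps, dom, "mri",
                        fast_config())
  expect_lt(abs(total_cells(sim$final) - total_cells(n0)) / total_cells(n0),
            1e-9)
  # bounds hold throughout
  expect_true(all(sim$final$counts >= 0 & sim$final$counts <= theta))
})

test_that("MRI and PET/MRI variants coincide exactly when mu = 0", {
  spec <- small_spec(seed = 12)
  cfg <- fast_config()
  dom <- generate_breast_domain(spec)
  theta <- carrying_capacity(voxel_volume_mm3(spec$spacing))
  n0 <- generate_scan1_cellularity(spec, dom, theta)
  sched <- standard_schedule(6, 3, 73)
  maps <- flat_drug_maps(dom, spec$spacing, sched)
  par <- model_parameters(0.2, array(0.03, spec$shape), theta,
                          alpha1 = 0.2, beta1 = 0.5, alpha2 = 0.1,
                          beta2 = 0.1, mu = 0)
  s_mri <- simulate_tumor(n0, 0, 42, par, maps, dom, "mri", cfg)
  s_pet <- simulate_tumor(n0, 0, 42, par, maps, dom, "pet_mri", cfg)
  expect_identical(s_mri$final$counts, s_pet$final$counts)
  expect_identical(s_mri$total_cellularity, s_pet$total_cellularity)
})

test_that("diffusion-only spreading follows the heat-kernel variance law", {
  n <- 33; sp <- c(2, 2, 2)
  dom <- breast_domain(array(TRUE, c(n, n, n)), array(1L, c(n, n, n)))
  co <- her2forecast:::coord_arrays(c(n, n, n), sp)
  ctr <- (n - 1) / 2 * sp
  sig0 <- 4
  theta <- 1e7
  g0 <- 1e6 * exp(-((co$x - ctr[1])^2 + (co$y - ctr[2])^2 +
                      (co$z - ctr[3])^2) / (2 * sig0^2))
  st <- cellularity_map(g0, theta, array(TRUE, c(n, n, n)), sp)
  sched <- treatment_schedule(numeric(0), scan2_time = 5, surgery_time = 20)
  maps <- flat_drug_maps(dom, sp, sched)
  D <- 0.25; t_end <- 10
  cfg <- study_config(); cfg$lambda <- 0       # pure diffusion
  par <- model_parameters(D, array(0, c(n, n, n)), theta)
  sim <- simulate_tumor(st, 0, t_end, par, maps, dom, "mri", cfg)
  w <- sim$final$counts / sum(sim$final$counts)
  var_x <- sum(w * (co$x - sum(w * co$x))^2)
  expect_lt(abs(var_x - (sig0^2 + 2 * D * t_end)) / (sig0^2 + 2 * D * t_end),
            0.02)
})
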