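test_that("breast domain geometry matches its analytic volumes", {
  spec <- small_spec()
  dom <- generate_breast_domain(spec)
  expect_s3_class(dom, "breast_domain")
  expect_true(all(dom$mask[tumor_roi(dom)]))      # tumor inside the breast

  vv <- voxel_volume_mm3(spec$spacing)
  # voxelized counts within one surface shell of the analytic volumes
  count_ok <- function(count, volume, area) {
    shell <- area * max(spec$spacing) # one-voxel-thick surface shell
    abs(count * vv - volume) <= shell
  }
  a <- spec$breast_semi_axes
  expect_true(count_ok(sum(dom$mask), 4 / 3 * pi * prod(a),
                       4 * pi * mean(a)^2))
  r <- spec$tumor_radius
  expect_true(count_ok(sum(tumor_roi(dom)), 4 / 3 * pi * r^3, 4 * pi * r^2))

  # zero fibroglandular fraction: everything non-tumor is adipose
  dom0 <- generate_breast_domain(small_spec(fibro_frac = 0))
  expect_true(all(dom0$tissue_labels[dom0$mask] %in% c(1L, 3L)))

  # tumor escaping the breast is an error
  expect_error(generate_breast_domain(
    small_spec(tumor_center_mm = c(46, 23, 23))), "inside")
})

test_that("scan-1 cellularity is a seeded truncated normal", {
  spec <- synthetic_patient_spec(shape = c(48, 48, 48),
                                 spacing_mm = c(1, 1, 1),
                                 breast_semi_axes_mm = c(22, 22, 22),
                                 tumor_radius_mm = 16, seed = 9)
  dom <- generate_breast_domain(spec)
  theta <- 1e6
  m <- generate_scan1_cellularity(spec, dom, theta)
  expect_true(all(m$counts >= 0 & m$counts <= theta))
  expect_true(all(m$counts[!tumor_roi(dom)] == 0))
  expect_identical(generate_scan1_cellularity(spec, dom, theta)$counts,
                   m$counts)                      # same seed, same draw
  n <- sum(m$roi)
  expect_gte(n, 1e4)
  mom <- truncnorm_moments(theta / 2, theta / 4, 0, theta)
  se <- sqrt(mom$var / n)
  expect_lt(abs(mean(m$counts[m$roi]) - mom$mean), 3 * se)
})

test_that("diffusion-weighted synthesis inverts through the ADC fit", {
  spec <- small_spec()
  co <- her2forecast:::coord_arrays(c(8, 8, 8), c(1, 1, 1))
  adc <- image_volume(1e-3 + 5e-5 * co$x)         # positive, spatially varying
  b <- c(0, 600, 800, 1000, 1500)
  stack <- synthesize_dw_signals(adc, b, s0 = 1000)
  expect_identical(stack[[1]]$values, array(1000, c(8, 8, 8)))  # b = 0 channel
  refit <- fit_adc(stack, b)
  expect_lt(max(abs(refit$values - adc$values) / adc$values), 1e-12)
  zero <- synthesize_dw_signals(volume_like(0 * adc$values, adc), b, 500)
  for (frame in zero) expect_true(all(frame$values == 500))     # ADC = 0
  expect_error(synthesize_dw_signals(adc, c(-5, 100), 1000), "nonnegative")
})

test_that("contrast dynamics have perfusion-proportional AUC", {
  spec <- small_spec()
  dom <- generate_breast_domain(spec)
  set.seed(3)
  perf <- image_volume(array(runif(prod(spec$shape)), spec$shape),
                       spec$spacing)
  perf$values[!dom$mask] <- 0
  stack <- synthesize_ce_dynamics(perf, n_post = 3)
  expect_length(stack, 4L)
  auc <- compute_auc_drug_map(stack, roi = dom$mask)
  sel <- dom$mask & perf$values > 0
  expect_gt(cor(auc$values[sel], perf$values[sel]), 1 - 1e-12)
  flat <- synthesize_ce_dynamics(volume_like(0 * perf$values, perf), 3)
  for (j in 2:4) expect_identical(flat[[j]]$values, flat[[1]]$values)
})

test_that("PET synthesis blurs without losing tumor-interior mass", {
  spec <- small_spec()
  dom <- generate_breast_domain(spec)
  flat <- synthesize_pet_uptake(dom, 1, 0, spec$spacing)
  expect_true(all(flat$values[dom$mask] == 1))
  expect_true(all(flat$values[!dom$mask] == 0))
  pet <- synthesize_pet_uptake(dom, 4, 5.5, spec$spacing)
  expect_true(tumor_roi(dom)[arrayInd(which.max(pet$values), dim(pet$values))])
  # Gaussian blur with a unit-sum kernel conserves the integral away from
  # the grid edge
  blob <- array(0, c(21, 21, 21)); blob[11, 11, 11] <- 100
  blurred <- her2forecast:::gaussian_blur3(blob, 6, c(1, 1, 1))
  expect_lt(abs(sum(blurred) - sum(blob)) / sum(blob), 1e-6)
  expect_error(synthesize_pet_uptake(dom, 0.5, 1, spec$spacing), ">= 1")
  expect_error(synthesize_pet_uptake(dom, 2, -1, spec$spacing), "nonnegative")
})

test_that("longitudinal study is reproducible, masked, and grid-consistent", {
  cfg <- fast_config()
  spec <- small_spec(seed = 4)
  s1 <- generate_longitudinal_study(spec, cfg)
  s2 <- generate_longitudinal_study(spec, cfg)
  expect_identical(s1$truth$scan2$counts, s2$truth$scan2$counts)
  expect_identical(s1$dataset$dw_scan1[[3]]$values,
                   s2$dataset$dw_scan1[[3]]$values)
  for (v in c(s1$dataset$dw_scan1, s1$dataset$ce_scan2, list(s1$dataset$pet)))
    expect_true(all(is.finite(v$values)))
  expect_true(grid_compatible(s1$dataset$ce_scan1[[1]],
                              s1$dataset$dw_scan2[[1]]))
  tr <- s1$truth
  expect_true(all(tr$scan2$counts >= 0 & tr$scan2$counts <= tr$theta))
  expect_identical(dim(tr$scan1$counts), dim(tr$params$k_map))
})

test_that("static world and targeted-effect monotonicity", {
  cfg <- fast_config()
  # no dynamics at all: scan 2 equals scan 1
  frozen <- generate_longitudinal_study(
    small_spec(seed = 2, d0 = 0, k_mean = 0, k_sd = 0,
               alpha1 = 0, alpha2 = 0, mu = 0), cfg)
  expect_equal(frozen$truth$scan2$counts, frozen$truth$scan1$counts,
               tolerance = 1e-12)
  # a stronger targeted effect never increases scan-2 burden
  lo <- generate_longitudinal_study(small_spec(seed = 2, mu = 0.1), cfg)
  hi <- generate_longitudinal_study(small_spec(seed = 2, mu = 0.6), cfg)
  expect_lte(total_cells(hi$truth$scan2), total_cells(lo$truth$scan2))
})

test_that("derived image quantities reproduce the synthetic truth", {
  cfg <- fast_config()
  study <- generate_longitudinal_study(small_spec(seed = 6), cfg)
  der <- derive_patient_quantities(study$dataset, cfg)
  troi <- tumor_roi(study$dataset$domain)
  expect_identical(der$roi1, troi)                # FCM finds the tumor
  truth1 <- study$truth$scan1_full
  expect_gt(cor(der$cellularity1$counts[troi], truth1$counts[troi]), 0.999)
  expect_lt(abs(total_cells(der$cellularity1) - total_cells(truth1)) /
              total_cells(truth1), 0.05)
  # tissue segmentation recovers the labels away from the tumor
  lab_true <- study$dataset$domain$tissue_labels
  sel <- lab_true %in% c(1L, 2L)
  expect_gt(mean(der$domain$tissue_labels[sel] == lab_true[sel]), 0.95)
})
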