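test_that("ADC fitting solves the log-linear problem exactly", {
  b <- c(0, 600, 800, 1000, 1500)
  shape <- c(3, 3, 3)
  mono <- function(s0, adc) lapply(b, function(bb)
    image_volume(array(s0 * exp(-bb * adc), shape)))
  adc <- fit_adc(mono(1000, 1.0e-3), b)
  expect_equal(adc$values[1], 1.0e-3, tolerance = 1e-12)
  # constant signal: zero ADC (up to floating rounding of the zero slope)
  expect_lt(max(fit_adc(mono(800, 0), b)$values), 1e-15)
  # two-point slope identity
  two <- list(image_volume(array(1000, shape)), image_volume(array(400, shape)))
  expect_equal(fit_adc(two, c(0, 1000))$values[1], log(1000 / 400) / 1000,
               tolerance = 1e-12)
  # nonpositive signals are treated as fluid
  bad <- mono(1000, 1e-3)
  bad[[2]]$values[1, 1, 1] <- 0
  expect_equal(fit_adc(bad, b, adc_w = 3e-3)$values[1, 1, 1], 3e-3)
  expect_error(fit_adc(mono(1, 1e-3), rep(500, 5)), "distinct")

  # property: random positive S0 fields recover the generating ADC to 1e-10
  set.seed(31)
  for (rep in 1:5) {
    s0 <- array(runif(27, 100, 5000), shape)
    truth <- array(runif(27, 2e-4, 2.8e-3), shape)
    stack <- lapply(b, function(bb) image_volume(s0 * exp(-bb * truth)))
    got <- fit_adc(stack, b)
    expect_lt(max(abs(got$values - truth) / truth), 1e-10)
  }
})

test_that("carrying capacity follows the packing-geometry formula", {
  cell_vol_mm3 <- 4 / 3 * pi * (10 * 1e-3)^3
  expect_equal(carrying_capacity(cell_vol_mm3, 1, 10), 1, tolerance = 1e-12)
  expect_equal(carrying_capacity(4, 0.74, 10),
               2 * carrying_capacity(2, 0.74, 10))
  # the nominal-constants value (~3.851e5 cells for a 2.18 mm^3 voxel)
  expect_equal(carrying_capacity(2.18, 0.74, 10),
               0.74 * 2.18 / cell_vol_mm3, tolerance = 1e-12)
  expect_equal(carrying_capacity(2.18, 0.74, 10), 3.851e5, tolerance = 1e-3)
  expect_error(carrying_capacity(-1, 0.74, 10), "positive")
})

test_that("ADC-to-cellularity mapping hits its endpoints and bounds", {
  theta <- 3.851e5
  adc <- image_volume(array(c(0.8e-3, 3e-3, 1.9e-3, rep(1.5e-3, 5)),
                            c(2, 2, 2)))
  roi <- array(TRUE, c(2, 2, 2))
  m <- cellularity_from_adc(adc, roi, theta, adc_w = 3e-3)
  expect_equal(m$counts[1, 1, 1], theta)              # ADC_min voxel
  expect_equal(m$counts[2, 1, 1], 0)                  # free-water voxel
  expect_equal(m$counts[1, 2, 1], 0.5 * theta)        # midpoint arithmetic
  expect_true(all(m$counts >= 0 & m$counts <= theta))
  # monotone decreasing in ADC
  ord <- order(adc$values)
  expect_true(all(diff(m$counts[ord]) <= 1e-9))
  deg <- image_volume(array(3e-3, c(2, 2, 2)))
  expect_error(cellularity_from_adc(deg, roi, theta), "degenerate")
})

test_that("fuzzy c-means matches brute-force clustering on separable data", {
  shape <- c(10, 10, 1)
  set.seed(7)
  enh <- array(rnorm(100, 100, 1), shape)
  hot <- array(FALSE, shape); hot[3:6, 4:8, 1] <- TRUE
  enh[hot] <- rnorm(sum(hot), 1000, 1)
  stack <- list(image_volume(array(0, shape)), image_volume(enh))
  roi <- array(TRUE, shape)
  mask <- segment_tumor_fcm(stack, roi, n_classes = 2,
                            membership_threshold = 0.5)
  # brute force: nearest of the two true levels
  expect_identical(mask, enh > 550)
  expect_identical(mask, hot)
  # a single bright voxel lands in the tumor class
  enh2 <- array(100, shape); enh2[5, 5, 1] <- 900
  mask2 <- segment_tumor_fcm(list(image_volume(array(0, shape)),
                                  image_volume(enh2)), roi)
  expect_true(mask2[5, 5, 1])
  # threshold 0 degenerates to the whole ROI
  expect_true(all(segment_tumor_fcm(stack, roi, membership_threshold = 0)))
  flat <- list(image_volume(array(0, shape)), image_volume(array(5, shape)))
  expect_error(segment_tumor_fcm(flat, roi), "degenerate")
})

test_that("k-means tissue segmentation partitions bimodal intensity", {
  shape <- c(8, 8, 8)
  mask <- array(TRUE, shape)
  roi <- array(FALSE, shape); roi[4:5, 4:5, 4:5] <- TRUE
  set.seed(13)
  base <- array(10 + rnorm(512, 0, 0.1), shape)
  bright <- array(runif(512) < 0.4, shape) & !roi
  base[bright] <- 100 + rnorm(sum(bright), 0, 0.1)
  dom <- segment_tissues_kmeans(image_volume(base), mask, roi)
  # 1D 2-means boundary sits between the modes: labels split exactly
  expect_true(all(dom$tissue_labels[bright] == 2L))
  expect_true(all(dom$tissue_labels[!bright & !roi] == 1L))
  expect_true(all(dom$tissue_labels[roi] == 3L))      # tumor never reassigned
  # near-unimodal: one cluster keeps >= 99% of voxels
  uni <- array(10, shape); uni[1, 1, 1:3] <- 10.5
  dom2 <- segment_tissues_kmeans(image_volume(uni), mask, roi)
  tab <- table(dom2$tissue_labels[mask & !roi])
  expect_gte(max(tab) / sum(tab), 0.99)
  expect_error(segment_tissues_kmeans(image_volume(array(1, shape)), mask, roi),
               "distinct")
})

test_that("AUC drug map integrates, normalizes, and is scale invariant", {
  shape <- c(2, 2, 1)
  mk <- function(scale = 1) {
    # voxel 1 ramps at slope 1, voxel 2 at slope 2 (per frame), others flat
    frames <- lapply(0:3, function(j) {
      a <- array(0, shape)
      a[1, 1, 1] <- j; a[2, 1, 1] <- 2 * j
      image_volume(100 * scale + a * scale)
    })
    frames
  }
  roi <- array(TRUE, shape)
  auc <- compute_auc_drug_map(mk(), roi)
  expect_equal(auc$values[2, 1, 1], 1)
  expect_equal(auc$values[1, 1, 1], 0.5, tolerance = 1e-12)  # trapezoid ratio
  expect_equal(auc$values[1, 2, 1], 0)
  # positive rescaling of the stack leaves the normalized map unchanged
  expect_equal(compute_auc_drug_map(mk(13.7), roi)$values, auc$values,
               tolerance = 1e-12)
  # uniform enhancement: map = 1 in the ROI
  uni <- lapply(c(0, 5, 5, 5), function(x) image_volume(array(100 + x, shape)))
  expect_true(all(compute_auc_drug_map(uni, roi)$values == 1))
  flat <- lapply(1:4, function(j) image_volume(array(50, shape)))
  expect_error(compute_auc_drug_map(flat, roi), "zero")
})

test_that("PET normalization is a clipped max-scaling", {
  shape <- c(3, 3, 1)
  up <- array(seq_len(9), shape)
  roi <- array(TRUE, shape)
  n1 <- normalize_pet_map(image_volume(up), roi)
  expect_equal(max(n1$values), 1)
  expect_equal(which.max(n1$values), which.max(up))
  expect_equal(normalize_pet_map(image_volume(2 * up), roi)$values, n1$values)
  expect_true(all(normalize_pet_map(image_volume(array(4, shape)),
                                    roi)$values == 1))
  expect_error(normalize_pet_map(image_volume(array(0, shape)), roi),
               "positive")
})

test_that("tumor volume counts ROI voxels or thresholded cellularity", {
  roi <- array(FALSE, c(10, 10, 10)); roi[1:4, 1:5, 1:5] <- TRUE
  expect_equal(tumor_volume(roi, 2.18), 100 * 2.18)
  expect_equal(tumor_volume(array(FALSE, c(2, 2, 2)), 1), 0)
  theta <- 1000
  counts <- array(0, c(3, 3, 3)); counts[1:2, 1, 1] <- c(300, 100)
  m <- cellularity_map(counts, theta, counts > 0)
  expect_equal(tumor_volume(m, 2, threshold_fraction = 0.25), 2)
  expect_equal(tumor_volume(m, 2, threshold_fraction = 0.5), 0)
})
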