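test_that("the disc phantom has exact insert intensities and geometry", {
  ph <- make_cirs_phantom()
  vol <- ph$volume
  st <- ph$structures
  for (i in 1:6) {
    m <- st$masks[[paste0("insert_", i)]]
    expect_equal(unique(as.numeric(vol$values[m])),
                 c(300, 600, 950, 1100, 1250, 1500)[i])
  }
  # insert volume close to the analytic cylinder volume (one voxel layer)
  vox <- prod(vol$grid$spacing)
  slices <- sum(apply(st$masks$insert_1, 3, any))
  analytic <- pi * 5^2 * slices * vol$grid$spacing[3]
  counted <- sum(st$masks$insert_1) * vox
  expect_lt(abs(counted - analytic),
            2 * pi * 5 * slices * vol$grid$spacing[3] * 1)
  # deterministic construction
  ph2 <- make_cirs_phantom()
  expect_identical(ph$volume$values, ph2$volume$values)
  # uniformity ROIs sample the flat background only
  expect_equal(unique(as.numeric(vol$values[st$masks$roi_center])), 1000)
})

test_that("organ volume factors are realised by the truth field", {
  cfg <- pelvis_phantom_config(global_amplitude_mm = 0, gas_pockets = 0L)
  ph <- make_pelvis_phantom(cfg)
  bl <- sum(ph$day_structures$masks$bladder) / sum(ph$structures$masks$bladder)
  expect_lt(abs(bl - 1.30), 0.02)
  rc <- sum(ph$day_structures$masks$rectum) / sum(ph$structures$masks$rectum)
  expect_lt(abs(rc - 0.85), 0.02)
})

test_that("a zero-magnitude deformation returns the planning image unchanged", {
  cfg <- pelvis_phantom_config(bladder_factor = 1, rectum_factor = 1,
                               global_amplitude_mm = 0, gas_pockets = 0L)
  ph <- make_pelvis_phantom(cfg)
  expect_identical(ph$day_image$values, ph$pct$values)
  expect_equal(max_displacement(ph$truth_dvf), 0)
  expect_identical(ph$day_structures$masks$bladder,
                   ph$structures$masks$bladder)
})

test_that("the truth field is smooth and bounded", {
  ph <- make_pelvis_phantom(pelvis_phantom_config(seed = 17L))
  expect_lte(max_displacement(ph$truth_dvf), 15)
  # finite-difference gradient of each component stays below 1 mm/mm
  # (no folding: well under the diffeomorphic limit)
  v <- ph$truth_dvf$vectors
  sp <- ph$grid$spacing
  n <- dim(v)[1:3]
  for (c in 1:3) {
    a <- v[, , , c]
    expect_lt(max(abs(a[2:n[1], , ] - a[1:(n[1] - 1), , ])) / sp[1], 1)
    expect_lt(max(abs(a[, 2:n[2], ] - a[, 1:(n[2] - 1), ])) / sp[2], 1)
    expect_lt(max(abs(a[, , 2:n[3]] - a[, , 1:(n[3] - 1)])) / sp[3], 1)
  }
})

test_that("phantom generation is deterministic under a fixed seed", {
  a <- make_pelvis_phantom(pelvis_phantom_config(seed = 5L))
  b <- make_pelvis_phantom(pelvis_phantom_config(seed = 5L))
  expect_identical(a$pct$values, b$pct$values)
  expect_identical(a$day_image$values, b$day_image$values)
  expect_identical(a$truth_dvf$vectors, b$truth_dvf$vectors)
  c_ <- make_pelvis_phantom(pelvis_phantom_config(seed = 6L))
  expect_false(identical(a$day_image$values, c_$day_image$values))
})

test_that("gas pockets appear in the day rectum below the gas threshold", {
  ph <- make_pelvis_phantom(pelvis_phantom_config(seed = 17L))
  gas <- detect_gas_pockets(ph$day_image,
                            body = ph$day_structures$masks$body)
  expect_gt(sum(gas & ph$day_structures$masks$rectum), 0)
  none <- make_pelvis_phantom(pelvis_phantom_config(seed = 17L,
                                                    gas_pockets = 0L))
  expect_equal(sum(none$day_image$values[none$day_structures$masks$rectum] <
                     100), 0)
})

test_that("CBCT degradation adds the configured noise and lowers SNR", {
  ph <- make_cirs_phantom()
  clean <- ph$volume
  ident <- degrade_to_cbct(clean, cbct_degradation_config(
    noise_sd = 0, cupping_amplitude = 0, scatter_offset = 0))
  expect_identical(ident$values, clean$values)

  noisy <- degrade_to_cbct(clean, cbct_degradation_config(
    noise_sd = 50, cupping_amplitude = 0, scatter_offset = 0, seed = 3L))
  flat <- ph$structures$masks$roi_center
  expect_lt(abs(sd(noisy$values[flat]) - 50), 5)

  # more noise, lower SNR in a flat region
  mild <- degrade_to_cbct(clean, cbct_degradation_config(
    noise_sd = 15, cupping_amplitude = 0, scatter_offset = 0, seed = 3L))
  expect_lt(snr(noisy, flat), snr(mild, flat))

  same1 <- degrade_to_cbct(clean, cbct_degradation_config(seed = 9L))
  same2 <- degrade_to_cbct(clean, cbct_degradation_config(seed = 9L))
  expect_identical(same1$values, same2$values)
})

test_that("synthetic dose fields honour the prescription and penumbra", {
  cfg <- pelvis_phantom_config(global_amplitude_mm = 0, gas_pockets = 0L,
                               bladder_factor = 1, rectum_factor = 1)
  ph <- make_pelvis_phantom(cfg)
  dose <- make_synthetic_dose(ph$grid, ph$structures$masks$target,
                              prescription_gy = 70, penumbra_mm = 3)
  expect_true(all(dose$dose >= 0))
  # deep target voxel: prescription to within sigmoid tail accuracy
  ctr <- which(ph$structures$masks$target, arr.ind = TRUE)
  mid <- round(colMeans(ctr))
  expect_lt(abs(dose$dose[mid[1], mid[2], mid[3]] - 70), 0.1)
  expect_gte(dvh_metric(dose, ph$structures$masks$target, "D98"), 0.95 * 70)
  # deterministic
  dose2 <- make_synthetic_dose(ph$grid, ph$structures$masks$target,
                               prescription_gy = 70, penumbra_mm = 3)
  expect_identical(dose$dose, dose2$dose)
})

test_that("phantom volumes survive an I/O round trip", {
  ph <- make_pelvis_phantom(pelvis_phantom_config(
    shape = c(32, 32, 16), global_amplitude_mm = 0, gas_pockets = 0L))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(ph$pct, f)
  back <- read_volume(f)
  expect_equal(back$values, ph$pct$values, tolerance = 1e-6,
               ignore_attr = TRUE)
})
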