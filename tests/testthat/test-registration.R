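test_that("warping under a zero field is the identity on coincident grids", {
  vol <- textured_volume(c(12, 12, 8))
  out <- warp_image(vol, zero_dvf(vol$grid))
  expect_equal(out$values, vol$values, ignore_attr = TRUE)
})

test_that("a uniform displacement pulls values by whole voxels", {
  g <- grid_geometry(c(20, 6, 6))
  vals <- array(rep(seq_len(20), 36), c(20, 6, 6))
  vol <- image_volume(vals, grid = g)
  dvf <- zero_dvf(g)
  dvf$vectors[, , , 1] <- 5   # +5 mm on a 1 mm grid: voxel i reads i + 5
  out <- warp_image(vol, dvf)
  expect_equal(out$values[3, 3, 3], vals[8, 3, 3])
  expect_equal(out$values[1:15, , ], vals[6:20, , ], ignore_attr = TRUE)
})

test_that("non-finite displacement fields are rejected", {
  g <- grid_geometry(c(6, 6, 4))
  dvf <- zero_dvf(g)
  dvf$vectors[1, 1, 1, 1] <- NaN
  vol <- image_volume(array(1, g$shape), grid = g)
  expect_error(warp_image(vol, dvf), "finite")
  expect_error(displacement_field(dvf$vectors, g), "finite")
})

test_that("mask propagation is exact for zero and whole-voxel shifts", {
  g <- grid_geometry(c(16, 16, 8))
  m <- array(FALSE, g$shape)
  m[5:8, 5:8, 3:5] <- TRUE
  expect_identical(propagate_mask(m, zero_dvf(g)), m)
  dvf <- zero_dvf(g)
  dvf$vectors[, , , 1] <- 3
  shifted <- propagate_mask(m, dvf)
  expect_identical(shifted[2:5, 5:8, 3:5], m[5:8, 5:8, 3:5])
  expect_equal(sum(shifted), sum(m))
  empty <- array(FALSE, g$shape)
  expect_equal(sum(propagate_mask(empty, dvf)), 0)
})

test_that("composing a field with its negation restores smooth images", {
  vol <- textured_volume(c(24, 24, 12), sigma_vox = c(4, 4, 2))
  g <- vol$grid
  dvf <- zero_dvf(g)
  dvf$vectors[, , , 1] <- 2.5
  dvf$vectors[, , , 3] <- 1.5
  there <- warp_image(vol, dvf, background = 1000)
  back <- warp_image(there, displacement_field(-dvf$vectors, g),
                     background = 1000)
  core <- array(FALSE, g$shape)
  core[6:19, 6:19, 4:9] <- TRUE
  expect_lt(max(abs(back$values[core] - vol$values[core])), 25)
})

test_that("optical flow on identical images returns a negligible field", {
  vol <- textured_volume(c(20, 20, 10))
  dvf <- iof_register(vol, vol)
  expect_lt(max_displacement(dvf), 0.1)
})

test_that("optical flow recovers a known translation of a textured volume", {
  vol <- textured_volume(c(32, 32, 16), seed = 7)
  mov <- translated_volume(vol, c(3, 0, 0))   # truth pull field: ux = -3
  dvf <- iof_register(vol, mov, background = 1000)
  core <- array(FALSE, vol$grid$shape)
  core[6:27, 6:27, 4:13] <- TRUE
  expect_lt(abs(mean(dvf$vectors[, , , 1][core]) - (-3)), 1)
  expect_lt(abs(mean(dvf$vectors[, , , 2][core])), 0.5)
})

test_that("optical flow never worsens the SSD, stage by stage", {
  vol <- textured_volume(c(24, 24, 12), seed = 8)
  mov <- translated_volume(vol, c(2, -1, 0))
  dvf <- iof_register(vol, mov, background = 1000)
  log <- attr(dvf, "log")
  expect_true(all(diff(log$ssd) <= 1e-9))
  expect_lte(ssd_final <- log$ssd[nrow(log)], log$ssd[1])
})

test_that("constant images leave the flow at its initial field with a warning", {
  g <- grid_geometry(c(10, 10, 6))
  flat <- image_volume(array(5, g$shape), grid = g)
  expect_warning(dvf <- iof_register(flat, flat), "constant")
  expect_equal(max_displacement(dvf), 0)
})

test_that("the literal stage order can be requested", {
  vol <- textured_volume(c(16, 16, 8), seed = 9)
  mov <- translated_volume(vol, c(1, 0, 0))
  sch <- registration_schedule(stages = list(
    list(scale = 1L, iterations = 2L, passes = 2L),
    list(scale = 2L, iterations = 2L, passes = 2L)),
    multigrid_cycles = 0L, listed_order = TRUE)
  dvf <- iof_register(vol, mov, sch, background = 1000)
  log <- attr(dvf, "log")
  expect_equal(log$scale[-1], c(1L, 2L))  # listed order preserved
})

test_that("B-spline registration is stable on identical images", {
  vol <- textured_volume(c(24, 24, 12), seed = 10)
  dvf <- bspline_register(vol, vol,
                          bspline_config(spacings_mm = c(32, 16, 8)))
  expect_lt(max_displacement(dvf), 0.5)
  log <- attr(dvf, "log")
  expect_lte(log$ssd[nrow(log)], log$ssd[1])
})

test_that("B-spline registration recovers a global translation", {
  vol <- textured_volume(c(32, 32, 16), seed = 11)
  mov <- translated_volume(vol, c(-3, 0, 0))  # truth pull field: ux = +3
  dvf <- bspline_register(vol, mov,
                          bspline_config(spacings_mm = c(32, 16, 8),
                                         prealign = TRUE),
                          background = 1000)
  core <- array(FALSE, vol$grid$shape)
  core[6:27, 6:27, 4:13] <- TRUE
  expect_lt(abs(mean(dvf$vectors[, , , 1][core]) - 3), 0.5)
})

test_that("the densified FFD matches a direct tensor-spline evaluation", {
  g <- grid_geometry(c(12, 10, 8), c(2, 2, 3))
  lat <- cbctdir:::ffd_lattice(g, 12)
  set.seed(12)
  coef <- rnorm(3 * prod(lat$cdim), sd = 3)
  dvf <- cbctdir:::ffd_dense_dvf(coef, lat, g)
  pts_idx <- cbind(c(1, 4, 7, 12), c(1, 3, 6, 10), c(1, 2, 5, 8))
  pts <- sweep(sweep(pts_idx - 1, 2, g$spacing, "*"), 2, g$origin, "+")
  ref <- oracle_ffd(coef, lat$cdim, lat$cspacing, lat$corigin, pts)
  got <- t(vapply(seq_len(nrow(pts_idx)), function(r)
    dvf$vectors[pts_idx[r, 1], pts_idx[r, 2], pts_idx[r, 3], ], numeric(3)))
  expect_lt(max(abs(got - ref)), 1e-6)
})

test_that("hybrid registration refines the B-spline initialisation", {
  vol <- textured_volume(c(24, 24, 12), seed = 13)
  mov <- translated_volume(vol, c(2, 0, 0))
  h <- hybrid_register(vol, mov,
                       bspline_config(spacings_mm = c(32, 16, 8)),
                       registration_schedule(multigrid_cycles = 1L),
                       background = 1000)
  ssd_b <- cbctdir:::ssd_under(vol, mov, h$dvf_bspline, 1000)
  ssd_h <- cbctdir:::ssd_under(vol, mov, h$dvf, 1000)
  expect_lte(ssd_h, ssd_b)
  # identity case: dCT equals moving up to interpolation
  h0 <- hybrid_register(vol, vol,
                        bspline_config(spacings_mm = c(32, 16, 8)),
                        registration_schedule(multigrid_cycles = 0L))
  expect_lt(max(abs(h0$dct$values - vol$values)), 20)
})

test_that("two-step registration is the identity for identical inputs", {
  vol <- textured_volume(c(20, 20, 10), seed = 14)
  m <- array(FALSE, vol$grid$shape)
  m[6:12, 6:12, 3:7] <- TRUE
  # all four structures share one mask; the override is then well defined
  # through the target-first priority rule
  ss <- structure_set(list(bladder = m, target = m, rectum = m,
                           subcutaneous_fat = m), vol$grid)
  out <- two_step_register(vol, vol, ss, ss,
                           schedule = registration_schedule(
                             stages = list(list(scale = 1L, iterations = 2L,
                                                passes = 3L)),
                             multigrid_cycles = 0L))
  expect_lt(max_displacement(out$dvf), 0.1)
  expect_lt(max(abs(out$dct$values - vol$values)), 1e-6)
})

test_that("registrations are bit-identical across reruns", {
  vol <- textured_volume(c(16, 16, 8), seed = 15)
  mov <- translated_volume(vol, c(1.5, 0, 0))
  sch <- registration_schedule(stages = list(
    list(scale = 2L, iterations = 3L, passes = 3L),
    list(scale = 1L, iterations = 2L, passes = 2L)), multigrid_cycles = 1L)
  d1 <- iof_register(vol, mov, sch, background = 1000)
  d2 <- iof_register(vol, mov, sch, background = 1000)
  expect_identical(d1$vectors, d2$vectors)
  b1 <- bspline_register(vol, mov, bspline_config(spacings_mm = c(24, 12, 6)),
                         background = 1000)
  b2 <- bspline_register(vol, mov, bspline_config(spacings_mm = c(24, 12, 6)),
                         background = 1000)
  expect_identical(b1$vectors, b2$vectors)
})
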