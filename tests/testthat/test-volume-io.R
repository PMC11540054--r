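test_that("NIfTI round trip preserves values, spacing and origin", {
  set.seed(1)
  vol <- image_volume(array(rnorm(8 * 8 * 8), c(8, 8, 8)),
                      spacing = c(0.9, 0.9, 2), origin = c(-10, 5, 2.5),
                      modality = "pCT")
  f <- tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  back <- read_volume(f, modality = "pCT")
  expect_equal(back$values, vol$values, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_lt(max(abs(back$grid$spacing - c(0.9, 0.9, 2))), 1e-6)
  expect_lt(max(abs(back$grid$origin - vol$grid$origin)), 1e-6)
})

test_that("HU volumes can be shifted into offset units on read", {
  vol <- image_volume(array(-1000, c(4, 4, 4)), units = "hu")
  f <- tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  back <- read_volume(f, shift_to_offset = TRUE)
  expect_equal(unique(as.numeric(back$values)), 0)  # air: -1000 HU -> 0
  expect_identical(back$units, "offset")
})

test_that("masks and displacement fields survive a round trip", {
  g <- grid_geometry(c(6, 6, 4), c(1, 1, 3))
  set.seed(2)
  mask <- array(runif(prod(g$shape)) > 0.5, g$shape)
  f <- tempfile(fileext = ".nii.gz")
  write_volume(mask, f, grid = g)
  back <- read_volume(f)
  expect_true(all(back$values %in% c(0, 1)))
  expect_equal(back$values > 0.5, mask, ignore_attr = TRUE)

  dvf <- displacement_field(array(rnorm(prod(g$shape) * 3), c(g$shape, 3)), g)
  fd <- tempfile(fileext = ".nii.gz")
  write_volume(dvf, fd)
  back_dvf <- read_dvf(fd)
  expect_equal(back_dvf$vectors, dvf$vectors, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("label-map structure sets read back with disjoint masks", {
  g <- grid_geometry(c(10, 10, 4))
  lab <- array(0L, g$shape)
  lab[2:4, 2:4, 2] <- 1L
  lab[6:8, 6:8, 3] <- 2L
  dir <- tempfile()
  dir.create(dir)
  nii <- file.path(dir, "labels.nii.gz")
  write_volume(lab, nii, grid = g)
  man <- file.path(dir, "structs.json")
  jsonlite::write_json(list(labelmap = "labels.nii.gz",
                            names = list(`1` = "bladder", `2` = "rectum")),
                       man, auto_unbox = TRUE)
  ss <- read_structures(man)
  expect_setequal(names(ss$masks), c("bladder", "rectum"))
  expect_equal(sum(ss$masks$bladder), 9)
  expect_false(any(ss$masks$bladder & ss$masks$rectum))
})

test_that("structure sets round trip through write_structures", {
  g <- grid_geometry(c(8, 8, 4))
  m1 <- array(FALSE, g$shape); m1[2:3, 2:3, 2] <- TRUE
  m2 <- array(FALSE, g$shape); m2[5:6, 5:6, 3] <- TRUE
  ss <- structure_set(list(bladder = m1, target = m2), g)
  man <- file.path(tempfile(fileext = ".json"))
  write_structures(ss, man)
  back <- read_structures(man)
  expect_equal(back$masks$bladder, m1, ignore_attr = TRUE)
  expect_equal(back$masks$target, m2, ignore_attr = TRUE)
})

test_that("empty structures warn but do not error", {
  g <- grid_geometry(c(6, 6, 2))
  lab <- array(0L, g$shape)
  lab[2, 2, 1] <- 1L
  dir <- tempfile(); dir.create(dir)
  write_volume(lab, file.path(dir, "labels.nii.gz"), grid = g)
  man <- file.path(dir, "structs.json")
  jsonlite::write_json(list(labelmap = "labels.nii.gz",
                            names = list(`1` = "bladder", `2` = "rectum")),
                       man, auto_unbox = TRUE)
  expect_warning(ss <- read_structures(man), "empty")
  expect_equal(sum(ss$masks$rectum), 0)
})

test_that("polygon contours rasterize by voxel-centre inclusion", {
  # 10 x 10 mm square covering exactly the centres 0..9 on a 1 mm grid
  g <- grid_geometry(c(12, 12, 3))
  sq <- list(list(z = 1, points = rbind(c(-0.5, -0.5), c(9.5, -0.5),
                                        c(9.5, 9.5), c(-0.5, 9.5))))
  m <- rasterize_contours(sq, g)
  expect_equal(sum(m), 100)
  expect_equal(sum(m[, , 2]), 100)  # slice at z = 1
  # even-odd rule: a square with a square hole
  holey <- list(list(z = 1, points = rbind(c(-0.5, -0.5), c(9.5, -0.5),
                                           c(9.5, 9.5), c(-0.5, 9.5))),
                list(z = 1, points = rbind(c(1.5, 1.5), c(7.5, 1.5),
                                           c(7.5, 7.5), c(1.5, 7.5))))
  mh <- rasterize_contours(holey, g)
  expect_equal(sum(mh), 100 - 36)
})

test_that("read_volume rejects missing or malformed files", {
  expect_error(read_volume(tempfile()), "not found")
  bad <- tempfile(fileext = ".nii")
  writeLines("not a nifti", bad)
  expect_error(read_volume(bad))
})

test_that("resampling is exact on coincident grids and interpolates ramps", {
  set.seed(3)
  vol <- image_volume(array(rnorm(6 * 5 * 4), c(6, 5, 4)),
                      spacing = c(1, 2, 3))
  same <- resample_to_grid(vol, vol$grid)
  expect_identical(same$values, vol$values)

  const <- image_volume(array(7, c(6, 5, 4)), spacing = c(1, 2, 3))
  tg <- grid_geometry(c(3, 3, 2), c(1.7, 2.1, 3.3), c(0.2, 0.3, 0.4))
  expect_equal(as.numeric(resample_to_grid(const, tg)$values), rep(7, 18))

  ramp <- image_volume(array(c(0, 10, 20), c(3, 1, 1)))
  q <- grid_geometry(c(1, 1, 1), origin = c(0.5, 0, 0))
  expect_equal(as.numeric(resample_to_grid(ramp, q)$values), 5)
})

test_that("nearest-neighbour resampling keeps masks binary", {
  set.seed(4)
  g <- grid_geometry(c(10, 10, 6), c(1, 1, 2))
  mask <- array(runif(600) > 0.6, g$shape)
  tg <- grid_geometry(c(7, 7, 4), c(1.4, 1.4, 2.9), c(0.3, 0.3, 0.7))
  out <- resample_mask(mask, g, tg)
  expect_type(out, "logical")
})

test_that("grid geometry enforces its invariants", {
  expect_error(grid_geometry(c(4, 4, 4), c(1, 0, 1)), "positive")
  expect_error(grid_geometry(c(4, 0, 4)), ">= 1")
  expect_error(image_volume(array(c(NA, rep(1, 7)), c(2, 2, 2))), "finite")
  g <- grid_geometry(c(4, 4, 2), c(1, 1, 3), c(5, -2, 0))
  expect_equal(grid_points(g)[1, ], c(5, -2, 0))
  expect_equal(grid_points(g)[2, ], c(6, -2, 0))
})

test_that("crop_to_overlap restricts to the common extent", {
  a <- image_volume(array(1, c(10, 10, 168)), spacing = c(1, 1, 2))
  b <- image_volume(array(2, c(10, 10, 84)), spacing = c(1, 1, 2))
  out <- crop_to_overlap(a, b)
  expect_equal(out$a$grid$shape[3], 84L)
  expect_equal(out$b$grid$shape[3], 84L)

  same <- crop_to_overlap(a, a)
  expect_equal(same$a$grid$shape, a$grid$shape)

  far <- image_volume(array(0, c(4, 4, 4)), origin = c(1000, 1000, 1000))
  expect_error(crop_to_overlap(a, far), "overlap")
})
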