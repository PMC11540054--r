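test_that("remove_table zeroes everything outside a supplied body mask", {
  set.seed(10)
  img <- image_volume(array(runif(500, 900, 1100), c(10, 10, 5)))
  body <- array(FALSE, c(10, 10, 5))
  body[3:8, 3:8, 2:4] <- TRUE
  out <- remove_table(img, body = body)
  expect_true(all(out$image$values[!body] == 0))
  expect_identical(out$image$values[body], img$values[body])
})

test_that("auto body derivation keeps the largest component and drops the table", {
  vals <- array(0, c(20, 20, 4))
  vals[5:15, 5:15, ] <- 1000          # "patient" disc
  vals[1:2, 1:20, ] <- 1200           # detached table bar
  vals[9:11, 9:11, 2] <- 0            # enclosed air hole, must be filled
  img <- image_volume(vals)
  out <- remove_table(img, threshold = 500)
  expect_true(all(out$image$values[1:2, , ] == 0))
  expect_equal(sum(out$body), 11 * 11 * 4)  # hole filled, bar gone
  expect_error(remove_table(image_volume(array(0, c(4, 4, 4))),
                            threshold = 500), "empty body")
})

test_that("gas detection uses a strict threshold in offset units", {
  vals <- array(1000, c(6, 6, 3))
  vals[2, 2, 2] <- 750
  vals[3, 3, 2] <- 800
  img <- image_volume(vals)
  m <- detect_gas_pockets(img)
  expect_true(m[2, 2, 2])        # below 800: gas
  expect_false(m[3, 3, 2])       # exactly 800: not gas
  expect_equal(sum(detect_gas_pockets(image_volume(array(1000, c(4, 4, 4))))),
               0)
  body <- array(FALSE, c(6, 6, 3))
  expect_equal(sum(detect_gas_pockets(img, body = body)), 0)
})

test_that("gas detection is monotone in the threshold", {
  set.seed(11)
  img <- image_volume(array(runif(1000, 0, 1500), c(10, 10, 10)))
  thr <- sort(runif(5, 200, 1200))
  for (i in seq_len(length(thr) - 1)) {
    m1 <- detect_gas_pockets(img, thr[i])
    m2 <- detect_gas_pockets(img, thr[i + 1])
    expect_true(all(m2[m1]))  # mask(t1) subset of mask(t2)
  }
})

test_that("gas filling blends exactly and fixes deep pockets to the fill value", {
  set.seed(12)
  d <- c(48, 48, 16)
  vals <- array(rnorm(prod(d), 1000, 30), d)
  # pocket large enough that its core is beyond the truncated smoothing
  # window (3.5 sigma) of the boundary, with clean margin to the faces
  vals[17:32, 17:32, 4:13] <- 300
  img <- image_volume(vals, spacing = c(1, 1, 2))
  gas <- detect_gas_pockets(img)
  res <- fill_gas_pockets(img, gas, fill = 1060, dilation_vox = 2,
                          sigma_mm = 2)
  expect_true(all(res$m2[res$m1]))                      # M2 contains M1
  expect_true(all(res$m2_blurred >= 0 & res$m2_blurred <= 1))
  untouched <- res$m2_blurred == 0
  expect_gt(sum(untouched), 0)
  expect_identical(res$output$values[untouched], img$values[untouched])
  # deep interior: smoothing window entirely inside the painted region
  expect_equal(res$output$values[24, 24, 8], 1060)
  # convex combination bound holds voxelwise
  lo <- pmin(img$values, res$i_painted_smoothed)
  hi <- pmax(img$values, res$i_painted_smoothed)
  expect_true(all(res$output$values >= lo - 1e-9 &
                    res$output$values <= hi + 1e-9))
  # blend identity: output = w * painted_smoothed + (1 - w) * original
  recon <- res$m2_blurred * res$i_painted_smoothed +
    (1 - res$m2_blurred) * img$values
  expect_equal(res$output$values, recon, ignore_attr = TRUE)
  expect_error(fill_gas_pockets(img, gas, dilation_vox = 0), "positive")
  expect_error(fill_gas_pockets(img, gas, sigma_mm = -1), "positive")
})

test_that("intensity override applies I - I_average + C inside each mask", {
  g <- grid_geometry(c(10, 10, 4))
  vals <- array(500, c(10, 10, 4))  # I_average is exactly 500
  bl <- array(FALSE, c(10, 10, 4)); bl[2:4, 2:4, 2] <- TRUE
  vals[bl][1] <- vals[bl][1]  # keep mean tractable: set bladder voxels to 520
  vals[bl] <- 520
  n_bl <- sum(bl)
  ntot <- length(vals)
  i_avg <- (520 * n_bl + 500 * (ntot - n_bl)) / ntot
  tg <- array(FALSE, c(10, 10, 4)); tg[7:8, 7:8, 3] <- TRUE
  rc <- array(FALSE, c(10, 10, 4)); rc[2:3, 7:8, 3] <- TRUE
  sf <- array(FALSE, c(10, 10, 4)); sf[7:8, 2:3, 2] <- TRUE
  ss <- structure_set(list(bladder = bl, target = tg, rectum = rc,
                           subcutaneous_fat = sf), g)
  img <- image_volume(vals, grid = g)
  out <- override_structures(img, ss)
  expect_equal(out$i_average, i_avg)
  expect_equal(unique(out$image$values[bl]), 520 - i_avg + 800)
  outside <- !(bl | tg | rc | sf)
  expect_identical(out$image$values[outside], vals[outside])
})

test_that("override preserves within-region SD and shifts the mean exactly", {
  set.seed(13)
  g <- grid_geometry(c(12, 12, 6))
  vals <- array(rnorm(prod(g$shape), 1000, 80), g$shape)
  masks <- list(bladder = array(FALSE, g$shape), target = array(FALSE, g$shape),
                rectum = array(FALSE, g$shape),
                subcutaneous_fat = array(FALSE, g$shape))
  masks$bladder[2:6, 2:6, 2:4] <- TRUE
  masks$target[8:11, 8:11, 2:4] <- TRUE
  masks$rectum[8:11, 2:4, 4:5] <- TRUE
  masks$subcutaneous_fat[2:4, 8:11, 4:5] <- TRUE
  img <- image_volume(vals, grid = g)
  out <- override_structures(img, structure_set(masks, g))
  i_avg <- mean(vals)
  consts <- c(bladder = 800, target = 1200, rectum = 800,
              subcutaneous_fat = 1200)
  for (nm in names(masks)) {
    m <- masks[[nm]]
    expect_lt(abs(sd(out$image$values[m]) - sd(vals[m])), 1e-9)
    expect_lt(abs(mean(out$image$values[m]) -
                    (mean(vals[m]) - i_avg + consts[nm])), 1e-9)
  }
})

test_that("override with C equal to the regional mean of a constant region is identity there", {
  g <- grid_geometry(c(8, 8, 4))
  vals <- array(650, g$shape)
  m <- array(FALSE, g$shape); m[3:6, 3:6, 2:3] <- TRUE
  ss <- structure_set(list(bladder = m), g)
  out <- override_structures(image_volume(vals, grid = g), ss,
                             override_spec(c(bladder = 650)))
  expect_equal(out$image$values, vals, ignore_attr = TRUE)
})

test_that("overlapping override masks resolve with target priority", {
  g <- grid_geometry(c(8, 8, 4))
  vals <- array(500, g$shape)
  shared <- array(FALSE, g$shape); shared[3:5, 3:5, 2] <- TRUE
  ss <- structure_set(list(bladder = shared, target = shared), g)
  out <- override_structures(image_volume(vals, grid = g), ss,
                             override_spec(c(bladder = 800, target = 1200)))
  expect_equal(unique(out$image$values[shared]), 500 - 500 + 1200)
})

test_that("override errors name the missing structures", {
  g <- grid_geometry(c(6, 6, 2))
  m <- array(FALSE, g$shape); m[2:3, 2:3, 1] <- TRUE
  ss <- structure_set(list(bladder = m), g)
  img <- image_volume(array(500, g$shape), grid = g)
  expect_error(override_structures(img, ss),
               "missing structure.*target.*available.*bladder")
})
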