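# Deterministic digital phantoms: an electron-density disc phantom with
# tissue-equivalent inserts, and a deformable pelvis with ground-truth
# displacement fields. These generators supply every test input used by the
# package; all randomness is controlled by explicit seeds.

# internal: evaluate code under a temporary RNG seed, restoring state after
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# internal: world-coordinate component arrays of a grid, centred at 0
centered_coords <- function(grid) {
  s <- grid$shape
  ctr <- (s - 1) / 2 * grid$spacing
  x <- (seq_len(s[1]) - 1) * grid$spacing[1] - ctr[1]
  y <- (seq_len(s[2]) - 1) * grid$spacing[2] - ctr[2]
  z <- (seq_len(s[3]) - 1) * grid$spacing[3] - ctr[3]
  list(x = array(rep(x, times = s[2] * s[3]), s),
       y = array(rep(rep(y, each = s[1]), times = s[3]), s),
       z = array(rep(z, each = s[1] * s[2]), s))
}

# internal: ellipsoid mask |(p - center)/radii| <= 1 (mm, centred coords)
ellipsoid_mask <- function(cc, center, radii) {
  ((cc$x - center[1]) / radii[1])^2 + ((cc$y - center[2]) / radii[2])^2 +
    ((cc$z - center[3]) / radii[3])^2 <= 1
}

#' Digital electron-density disc phantom
#'
#' A water-equivalent disc with a dense outer ring and cylindrical
#' tissue-equivalent inserts arranged on a circle, emulating a CT
#' image-quality phantom. Noiseless; intensities are exact, so insert means
#' equal their configured values. Central and peripheral ROI masks for
#' uniformity analysis are included.
#'
#' @param shape,spacing grid definition.
#' @param body_radius_mm disc radius.
#' @param ring_thickness_mm dense outer ring thickness.
#' @param insert_radius_mm insert cylinder radius.
#' @param insert_circle_mm radius of the circle the inserts sit on.
#' @param insert_values offset-unit intensity per insert.
#' @param body_value,ring_value disc and ring intensities (offset units).
#' @return A list with \code{volume} (\code{image_volume}) and
#'   \code{structures} (\code{structure_set}: body, ring, insert_i, roi
#'   masks).
#' @export
make_cirs_phantom <- function(shape = c(96, 96, 24), spacing = c(1, 1, 3),
                              body_radius_mm = 40, ring_thickness_mm = 5,
                              insert_radius_mm = 5, insert_circle_mm = 26,
                              insert_values = c(300, 600, 950, 1100, 1250, 1500),
                              body_value = 1000, ring_value = 1450) {
  grid <- grid_geometry(shape, spacing)
  cc <- centered_coords(grid)
  r2 <- cc$x^2 + cc$y^2
  zext <- (shape[3] - 1) / 2 * spacing[3] * 0.8
  inz <- abs(cc$z) <= zext
  body <- r2 <= body_radius_mm^2 & inz
  ring <- r2 <= body_radius_mm^2 &
    r2 > (body_radius_mm - ring_thickness_mm)^2 & inz
  vals <- array(0, shape)
  vals[body] <- body_value
  vals[ring] <- ring_value
  masks <- list(body = body, ring = ring)
  nin <- length(insert_values)
  ang <- 2 * pi * (seq_len(nin) - 1) / nin
  for (i in seq_len(nin)) {
    cxy <- insert_circle_mm * c(cos(ang[i]), sin(ang[i]))
    m <- (cc$x - cxy[1])^2 + (cc$y - cxy[2])^2 <= insert_radius_mm^2 & inz
    vals[m] <- insert_values[i]
    masks[[paste0("insert_", i)]] <- m
  }
  masks$roi_center <- r2 <= 8^2 & inz
  for (i in 1:4) {
    a <- pi / 4 + (i - 1) * pi / 2
    cxy <- (body_radius_mm - ring_thickness_mm - 10) * c(cos(a), sin(a))
    masks[[paste0("roi_peripheral_", i)]] <-
      (cc$x - cxy[1])^2 + (cc$y - cxy[2])^2 <= 6^2 & inz
  }
  # peripheral/centre ROIs must sample the uniform background, not inserts
  bg <- body & !ring
  for (i in seq_len(nin)) bg <- bg & !masks[[paste0("insert_", i)]]
  for (nm in grep("^roi_", names(masks), value = TRUE))
    masks[[nm]] <- masks[[nm]] & bg
  list(volume = image_volume(vals, grid = grid, modality = "pCT"),
       structures = structure_set(masks, grid))
}

#' Configuration of the deformable pelvis phantom
#'
#' Geometry, tissue intensities (offset units: fat 900, muscle 1040,
#' bladder contents 1010, target 1070, rectum 980, bone 1400, gas 50) and
#' the "treatment-day" deformation: per-organ volume-change factors realised
#' as radial scalings plus a smooth random global field, all integrated to a
#' diffeomorphic DVF by scaling-and-squaring.
#'
#' @param shape,spacing grid definition (defaults 96 x 96 x 48 at
#'   (1, 1, 2) mm).
#' @param bladder_factor,rectum_factor treatment-day volume-change factors.
#' @param global_amplitude_mm peak magnitude of the smooth global field.
#' @param global_sigma_mm smoothness scale of the global field.
#' @param texture_sd,texture_sigma_mm soft-tissue texture (smoothed noise).
#' @param gas_pockets number of gas pockets inserted into the day rectum.
#' @param gas_radius_mm radius range the pocket radii are drawn from.
#' @param seed RNG seed fixing all randomness.
#' @return A list of class \code{pelvis_phantom_config}.
#' @export
pelvis_phantom_config <- function(shape = c(96, 96, 48), spacing = c(1, 1, 2),
                                  bladder_factor = 1.3, rectum_factor = 0.85,
                                  global_amplitude_mm = 3,
                                  global_sigma_mm = 15,
                                  texture_sd = 15, texture_sigma_mm = 3,
                                  gas_pockets = 2L,
                                  gas_radius_mm = c(3, 5), seed = 17L) {
  stopifnot(bladder_factor > 0, rectum_factor > 0, global_amplitude_mm >= 0)
  structure(list(shape = shape, spacing = spacing,
                 bladder_factor = bladder_factor,
                 rectum_factor = rectum_factor,
                 global_amplitude_mm = global_amplitude_mm,
                 global_sigma_mm = global_sigma_mm,
                 texture_sd = texture_sd, texture_sigma_mm = texture_sigma_mm,
                 gas_pockets = as.integer(gas_pockets),
                 gas_radius_mm = gas_radius_mm, seed = as.integer(seed),
                 organs = list(
                   bladder = list(center = c(0, -10, 8), radii = c(16, 14, 12),
                                  value = 1010),
                   target = list(center = c(0, 8, -8), radii = c(12, 10, 10),
                                 value = 1070),
                   rectum = list(center = c(0, 24, -4), radii = c(8, 8, 22),
                                 value = 980),
                   femoral_head_l = list(center = c(-33, 4, 0),
                                         radii = c(11, 11, 13), value = 1400),
                   femoral_head_r = list(center = c(33, 4, 0),
                                         radii = c(11, 11, 13), value = 1400)),
                 body_radii = c(46, 40), fat_thickness_mm = 8,
                 values = c(fat = 900, muscle = 1040, gas = 50)),
            class = "pelvis_phantom_config")
}

# internal: smooth random field (one component), peak-normalised
smooth_random_field <- function(grid, sigma_mm, amplitude) {
  raw <- array(stats::rnorm(prod(grid$shape)), grid$shape)
  sm <- cpp_gauss3(as.numeric(raw), grid$shape, sigma_mm / grid$spacing)
  sm <- sm / max(abs(sm), 1e-12) * amplitude
  array(sm, grid$shape)
}

# internal: integrate a stationary velocity field (mm) to a displacement
# field by scaling and squaring (2^n_square compositions), giving a
# diffeomorphic transform
integrate_velocity <- function(vel, grid, n_square = 4L) {
  v <- vel / 2^n_square
  dvf <- displacement_field(v, grid)
  for (i in seq_len(n_square)) dvf <- compose_dvf(dvf, dvf)
  dvf
}

#' Deformable digital pelvis phantom with ground-truth DVF
#'
#' Builds a planning-CT-like pelvis (fat shell, muscle, bladder, target,
#' rectum, femoral heads, soft texture), then a "treatment-day" image by
#' warping it under a synthetic diffeomorphic DVF combining organ-centred
#' radial volume changes (bladder fill up, rectum down by the configured
#' factors) with a smooth random global field. The day structures are
#' exactly the masks propagated through the truth field.
#'
#' @param config a \code{\link{pelvis_phantom_config}}.
#' @return A list: \code{pct}, \code{structures}, \code{day_image},
#'   \code{day_structures}, \code{truth_dvf}, \code{grid}.
#' @export
make_pelvis_phantom <- function(config = pelvis_phantom_config()) {
  grid <- grid_geometry(config$shape, config$spacing)
  cc <- centered_coords(grid)

  # analytic anatomy: masks evaluated at arbitrary (possibly warped)
  # centred coordinates, so ground-truth day masks are exact
  masks_at <- function(px, py, pz) {
    body <- (px / config$body_radii[1])^2 + (py / config$body_radii[2])^2 <= 1
    inner <- (px / (config$body_radii[1] - config$fat_thickness_mm))^2 +
      (py / (config$body_radii[2] - config$fat_thickness_mm))^2 <= 1
    m <- list(body = body, subcutaneous_fat = body & !inner)
    for (nm in names(config$organs)) {
      o <- config$organs[[nm]]
      m[[nm]] <- ((px - o$center[1]) / o$radii[1])^2 +
        ((py - o$center[2]) / o$radii[2])^2 +
        ((pz - o$center[3]) / o$radii[3])^2 <= 1
    }
    m
  }
  masks <- masks_at(cc$x, cc$y, cc$z)
  inner <- masks$body & !masks$subcutaneous_fat

  vals <- array(0, config$shape)
  vals[masks$body] <- config$values["fat"]
  vals[inner] <- config$values["muscle"]
  for (nm in names(config$organs)) vals[masks[[nm]]] <- config$organs[[nm]]$value

  pct_vals <- with_seed(config$seed, {
    if (config$texture_sd > 0) {
      tex <- smooth_random_field(grid, config$texture_sigma_mm, 1)
      tex <- tex / max(stats::sd(tex), 1e-12) * config$texture_sd
      v <- vals
      v[inner] <- v[inner] + tex[inner]
      v
    } else vals
  })
  pct <- image_volume(pct_vals, grid = grid, modality = "pCT")
  structures <- structure_set(masks, grid)

  # velocity field: organ radial scalings + smooth global component
  vel <- array(0, c(config$shape, 3))
  scale_for <- c(bladder = config$bladder_factor,
                 rectum = config$rectum_factor)
  for (nm in names(scale_for)) {
    s <- scale_for[[nm]]^(1 / 3)
    if (abs(s - 1) < 1e-9) next
    o <- config$organs[[nm]]
    rho <- sqrt(((cc$x - o$center[1]) / o$radii[1])^2 +
                  ((cc$y - o$center[2]) / o$radii[2])^2 +
                  ((cc$z - o$center[3]) / o$radii[3])^2)
    # weight 1 well past the (possibly expanded) boundary, smooth decay to 0
    r1 <- max(1.25, s * 1.1)
    r0 <- r1 + 0.8
    w <- ifelse(rho <= r1, 1,
                ifelse(rho >= r0, 0, (cos((rho - r1) / (r0 - r1) * pi) + 1) / 2))
    f <- -log(s) * w
    vel[, , , 1] <- vel[, , , 1] + f * (cc$x - o$center[1])
    vel[, , , 2] <- vel[, , , 2] + f * (cc$y - o$center[2])
    vel[, , , 3] <- vel[, , , 3] + f * (cc$z - o$center[3])
  }
  if (config$global_amplitude_mm > 0) {
    gf <- with_seed(config$seed + 1L, lapply(1:3, function(i)
      smooth_random_field(grid, config$global_sigma_mm,
                          config$global_amplitude_mm)))
    for (c in 1:3) vel[, , , c] <- vel[, , , c] + gf[[c]]
  }

  if (max(abs(vel)) == 0) {
    truth <- zero_dvf(grid)
    day_image <- pct
    day_structures <- structures
  } else {
    truth <- integrate_velocity(vel, grid)
    day_image <- warp_image(pct, truth)
    day_image$modality <- "kVCBCT"
    # exact propagation: evaluate the analytic anatomy at x + u(x)
    day_structures <- structure_set(
      masks_at(cc$x + truth$vectors[, , , 1],
               cc$y + truth$vectors[, , , 2],
               cc$z + truth$vectors[, , , 3]), grid)
  }

  # optional gas pockets in the day rectum
  if (config$gas_pockets > 0) {
    rec <- which(day_structures$masks$rectum, arr.ind = TRUE)
    if (nrow(rec)) {
      day_image$values <- with_seed(config$seed + 2L, {
        v <- day_image$values
        for (p in seq_len(config$gas_pockets)) {
          ctr_idx <- rec[sample.int(nrow(rec), 1), ]
          rad <- stats::runif(1, config$gas_radius_mm[1],
                              config$gas_radius_mm[2])
          # pocket centre in the same centred coordinates as cc
          cx <- (ctr_idx - 1) * grid$spacing - (grid$shape - 1) / 2 * grid$spacing
          pocket <- ((cc$x - cx[1])^2 + (cc$y - cx[2])^2 +
                       (cc$z - cx[3])^2) <= rad^2
          pocket <- pocket & day_structures$masks$rectum
          v[pocket] <- config$values["gas"]
        }
        v
      })
    }
  }

  list(pct = pct, structures = structures, day_image = day_image,
       day_structures = day_structures, truth_dvf = truth, grid = grid)
}

#' CBCT-style degradation configuration
#'
#' Additive Gaussian noise, a radial cupping artifact (centre depressed,
#' edge raised, zero mean at mid-radius) and a constant scatter offset,
#' emulating the quality gap between a planning CT and an on-board CBCT.
#'
#' @param noise_sd additive Gaussian noise SD (offset units).
#' @param cupping_amplitude cupping depth at the centre (offset units).
#' @param cupping_radius_mm radial scale of the cupping profile.
#' @param scatter_offset constant additive offset (offset units).
#' @param seed RNG seed for the noise.
#' @return A list of class \code{cbct_degradation_config}.
#' @export
cbct_degradation_config <- function(noise_sd = 40, cupping_amplitude = 60,
                                    cupping_radius_mm = 45,
                                    scatter_offset = 30, seed = 99L) {
  stopifnot(noise_sd >= 0)
  structure(list(noise_sd = noise_sd, cupping_amplitude = cupping_amplitude,
                 cupping_radius_mm = cupping_radius_mm,
                 scatter_offset = scatter_offset, seed = as.integer(seed)),
            class = "cbct_degradation_config")
}

#' Apply CBCT-style degradation to an image
#'
#' @param image an \code{\link{image_volume}}.
#' @param config a \code{\link{cbct_degradation_config}}.
#' @param body optional body mask restricting cupping/scatter (default: all
#'   voxels with value > 0).
#' @return The degraded \code{image_volume} (modality "kVCBCT").
#' @export
degrade_to_cbct <- function(image, config = cbct_degradation_config(),
                            body = NULL) {
  v <- image$values
  if (is.null(body)) body <- v > 0
  cc <- centered_coords(image$grid)
  if (config$cupping_amplitude != 0) {
    r2 <- (cc$x^2 + cc$y^2) / config$cupping_radius_mm^2
    cup <- config$cupping_amplitude * (r2 - 0.5)
    v[body] <- v[body] + cup[body]
  }
  if (config$scatter_offset != 0) v[body] <- v[body] + config$scatter_offset
  if (config$noise_sd > 0) {
    v <- v + with_seed(config$seed,
                       array(stats::rnorm(length(v), 0, config$noise_sd),
                             dim(v)))
  }
  image_volume(v, grid = image$grid, modality = "kVCBCT",
               units = image$units)
}

#' Synthetic dose field around a target
#'
#' Prescription dose covering the target, with the sigmoid falloff of the
#' stated penumbra placed \code{margin_mm} outside the target surface (as a
#' plan with a margin would), computed from the signed Euclidean distance
#' to the target surface. Deterministic.
#'
#' @param grid a \code{\link{grid_geometry}}.
#' @param target_mask logical target mask on the grid, non-empty.
#' @param prescription_gy prescription dose (Gy).
#' @param penumbra_mm falloff scale of the sigmoid.
#' @param margin_mm distance from the target surface to the 50% isodose
#'   (default: one penumbra, so the surface itself stays near the
#'   prescription).
#' @return A \code{\link{dose_grid}}.
#' @export
make_synthetic_dose <- function(grid, target_mask, prescription_gy = 70,
                                penumbra_mm = 5, margin_mm = penumbra_mm) {
  if (!any(target_mask)) stop("empty target mask")
  sp <- surface_points(target_mask, grid$spacing, grid$origin)
  pts <- grid_points(grid)
  # restrict the distance computation to a band around the target; the
  # sigmoid is numerically zero beyond it
  cut <- 6 * penumbra_mm + margin_mm
  lo <- apply(sp, 2, min) - cut
  hi <- apply(sp, 2, max) + cut
  inband <- pts[, 1] >= lo[1] & pts[, 1] <= hi[1] &
    pts[, 2] >= lo[2] & pts[, 2] <= hi[2] &
    pts[, 3] >= lo[3] & pts[, 3] <= hi[3]
  d <- rep(Inf, nrow(pts))
  d[inband] <- as.numeric(cpp_nn_dist(pts[inband, , drop = FALSE], sp))
  sgn <- ifelse(as.numeric(target_mask), -1, 1)
  dose <- prescription_gy / (1 + exp(4 * (sgn * d - margin_mm) / penumbra_mm))
  dose[!inband] <- 0
  dose[is.infinite(d) & sgn < 0] <- prescription_gy
  dim(dose) <- grid$shape
  dose_grid(dose, grid = grid)
}
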