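#' Multiresolution schedule for the iterative optical flow
#'
#' A stage is a list with \code{scale} (integer downsampling factor per
#' axis), \code{iterations} (inner flow-update steps per pass) and
#' \code{passes} (outer loops, each followed by Gaussian smoothing of the
#' DVF with \code{dvf_sigma_mm}). The default mirrors the two-step
#' registration's stated schedule: a full-resolution stage with 5 iterations
#' and 10 passes, a half-resolution stage with 30 iterations and 50 passes,
#' sigma = 1 mm on the DVF, plus two multigrid V-cycles. Stages are executed
#' coarse-to-fine unless \code{listed_order = TRUE}, which runs them exactly
#' in the listed order.
#'
#' @param stages list of stage lists (see above).
#' @param dvf_sigma_mm Gaussian sigma (mm) applied to the DVF after each
#'   pass.
#' @param multigrid_cycles number of V-cycles appended after the stages.
#' @param listed_order keep the listed stage order instead of sorting
#'   coarse-to-fine.
#' @return An object of class \code{registration_schedule}.
#' @export
registration_schedule <- function(stages = list(
                                    list(scale = 1L, iterations = 5L, passes = 10L),
                                    list(scale = 2L, iterations = 30L, passes = 50L)),
                                  dvf_sigma_mm = 1,
                                  multigrid_cycles = 2L,
                                  listed_order = FALSE) {
  for (s in stages) {
    if (s$scale < 1 || s$iterations < 1 || s$passes < 1)
      stop("each stage needs scale >= 1, iterations >= 1, passes >= 1")
  }
  if (dvf_sigma_mm < 0) stop("dvf_sigma_mm must be >= 0")
  structure(list(stages = stages, dvf_sigma_mm = dvf_sigma_mm,
                 multigrid_cycles = as.integer(multigrid_cycles),
                 listed_order = isTRUE(listed_order)),
            class = "registration_schedule")
}

#' Configuration for the multiresolution B-spline registration
#'
#' Three coarse-to-fine levels of a cubic free-form deformation optimized by
#' gradient descent (with backtracking line search) on the sum of squared
#' differences.
#'
#' @param spacings_mm control-point spacings per level, decreasing.
#' @param iterations gradient-descent iterations per level.
#' @param image_scales integer image downsampling factor per level.
#' @param prealign estimate a global translation from intensity centroids
#'   before the first level.
#' @return An object of class \code{bspline_config}.
#' @export
bspline_config <- function(spacings_mm = c(64, 32, 16), iterations = 20L,
                           image_scales = c(4L, 2L, 1L), prealign = FALSE) {
  if (any(diff(spacings_mm) >= 0))
    stop("spacings_mm must decrease (coarse to fine)")
  if (length(image_scales) != length(spacings_mm))
    stop("one image scale per level required")
  structure(list(spacings_mm = spacings_mm, iterations = as.integer(iterations),
                 image_scales = as.integer(image_scales),
                 prealign = isTRUE(prealign)),
            class = "bspline_config")
}

#' Iterative optical flow (demons-type) deformable registration
#'
#' Intensity-driven registration: each inner iteration warps the moving
#' image under the current DVF and adds the demons force
#' \eqn{(F - M_w)\nabla M_w / (|\nabla M_w|^2 + \alpha (F - M_w)^2 / \bar s^2)},
#' and the DVF is Gaussian-regularized after every pass. Stages run on
#' downsampled grids per the schedule, with the DVF restricted/prolonged
#' between resolutions (also used for the closing multigrid V-cycles). The
#' returned field never has a larger SSD than the initial field.
#'
#' @param fixed fixed \code{\link{image_volume}} (the CBCT in the clinical
#'   workflow); its grid carries the result.
#' @param moving moving \code{image_volume} (the planning CT).
#' @param schedule a \code{\link{registration_schedule}}.
#' @param init optional initial \code{\link{displacement_field}} on the
#'   fixed grid (used by the hybrid method).
#' @param alpha demons force normalization weight.
#' @param background intensity used outside the moving extent.
#' @param verbose print per-stage SSD.
#' @return A \code{\link{displacement_field}} with an attached per-stage SSD
#'   log (attribute \code{"log"}).
#' @export
iof_register <- function(fixed, moving, schedule = registration_schedule(),
                         init = NULL, alpha = 1, background = 0,
                         verbose = FALSE) {
  fg <- fixed$grid
  dvf <- if (is.null(init)) zero_dvf(fg) else {
    if (!grid_equal(init$grid, fg)) resample_dvf(init, fg) else init
  }
  if (stats::sd(fixed$values) == 0 || stats::sd(moving$values) == 0) {
    warning("constant image: no intensity gradient to drive the flow; ",
            "returning the initial field")
    attr(dvf, "log") <- data.frame(stage = character(), scale = integer(),
                                   ssd = numeric())
    return(dvf)
  }

  best <- dvf
  best_ssd <- ssd_under(fixed, moving, dvf, background)
  log <- data.frame(stage = "init", scale = 1L, ssd = best_ssd)

  stages <- schedule$stages
  if (!schedule$listed_order)
    stages <- stages[order(-vapply(stages, function(s) s$scale, 1L))]

  run_stage <- function(dvf, scale, iterations, passes, label) {
    sg <- downsample_grid(fg, scale)
    if (scale > 1) {
      # anti-alias pyramid: low-pass both images before working coarse
      sig_mm <- scale / 2 * fg$spacing
      fixed_s <- resample_to_grid(smooth_volume(fixed, sig_mm), sg,
                                  background = background)
      moving_s <- smooth_volume(moving, sig_mm)
      dvf_s <- resample_dvf(dvf, sg)
    } else {
      fixed_s <- fixed
      moving_s <- moving
      dvf_s <- dvf
    }
    mg <- moving_s$grid
    stage_best <- dvf_s
    stage_best_ssd <- ssd_under(fixed_s, moving_s, dvf_s, background)
    for (p in seq_len(passes)) {
      res <- cpp_demons_pass(as.numeric(fixed_s$values), sg$shape, sg$spacing,
                             sg$origin, as.numeric(moving_s$values), mg$shape,
                             mg$spacing, mg$origin, dvf_vec(dvf_s),
                             as.integer(iterations), alpha, background)
      v <- res$dvf
      dim(v) <- c(sg$shape, 3)
      dvf_s <- smooth_dvf(displacement_field(v, sg), schedule$dvf_sigma_mm)
      s <- ssd_under(fixed_s, moving_s, dvf_s, background)
      if (s < stage_best_ssd) {
        stage_best_ssd <- s
        stage_best <- dvf_s
      }
    }
    out <- if (scale > 1) resample_dvf(stage_best, fg) else stage_best
    s_full <- ssd_under(fixed, moving, out, background)
    if (s_full < best_ssd) {
      best_ssd <<- s_full
      best <<- out
    }
    log <<- rbind(log, data.frame(stage = label, scale = scale, ssd = best_ssd))
    if (verbose) message(sprintf("%s (scale %d): SSD %.4g", label, scale, best_ssd))
    best
  }

  for (i in seq_along(stages)) {
    s <- stages[[i]]
    dvf <- run_stage(dvf, s$scale, s$iterations, s$passes,
                     sprintf("stage%d", i))
  }
  # multigrid V-cycles: a short coarse correction followed by a fine sweep
  for (cyc in seq_len(schedule$multigrid_cycles)) {
    dvf <- run_stage(dvf, 2L, 2L, 3L, sprintf("vcycle%d_coarse", cyc))
    dvf <- run_stage(dvf, 1L, 2L, 3L, sprintf("vcycle%d_fine", cyc))
  }
  attr(best, "log") <- log
  best
}

# internal: control lattice covering a grid for cp spacing delta (mm)
ffd_lattice <- function(grid, delta) {
  extent <- (grid$shape - 1) * grid$spacing
  corigin <- grid$origin - delta
  cdim <- as.integer(floor(1 + extent / delta) + 3)
  list(cdim = cdim, cspacing = rep(delta, 3), corigin = corigin)
}

# internal: dense DVF on `grid` from FFD coefficients
ffd_dense_dvf <- function(coef, lat, grid) {
  v <- cpp_ffd_dense(coef, lat$cdim, lat$cspacing, lat$corigin, grid$shape,
                     grid$spacing, grid$origin)
  displacement_field(array(v, c(grid$shape, 3)), grid)
}

#' Multiresolution B-spline (free-form deformation) registration
#'
#' Optimizes cubic B-spline control-point displacements by gradient descent
#' on the SSD over three coarse-to-fine levels, then densifies the final
#' transform to a per-voxel DVF on the fixed grid. If a level cannot
#' improve the SSD the best field found so far is returned.
#'
#' @param fixed,moving \code{\link{image_volume}} objects.
#' @param config a \code{\link{bspline_config}}.
#' @param background intensity outside the moving extent.
#' @param verbose print per-level SSD.
#' @return A \code{\link{displacement_field}} with attributes \code{"log"}
#'   (per-level SSD) and \code{"ffd"} (final lattice and coefficients).
#' @export
bspline_register <- function(fixed, moving, config = bspline_config(),
                             background = 0, verbose = FALSE) {
  fg <- fixed$grid
  mg <- moving$grid
  zero <- zero_dvf(fg)
  ssd0 <- ssd_under(fixed, moving, zero, background)
  log <- data.frame(level = 0L, ssd = ssd0)

  shift <- c(0, 0, 0)
  if (config$prealign) {
    wf <- grid_points(fg)
    wm <- grid_points(mg)
    pf <- pmax(as.numeric(fixed$values), 0)
    pm <- pmax(as.numeric(moving$values), 0)
    comf <- colSums(wf * pf) / sum(pf)
    comm <- colSums(wm * pm) / sum(pm)
    shift <- comm - comf  # pull convention: sample moving at x + shift
  }

  prev_dvf <- NULL
  coef <- NULL
  lat <- NULL
  for (lev in seq_along(config$spacings_mm)) {
    delta <- config$spacings_mm[lev]
    scale <- config$image_scales[lev]
    sg <- downsample_grid(fg, scale)
    fixed_s <- if (scale > 1) resample_to_grid(fixed, sg, background = background) else fixed
    lat <- ffd_lattice(fg, delta)
    nc <- prod(lat$cdim)
    coef <- numeric(3 * nc)
    if (!is.null(prev_dvf)) {
      # seed the finer lattice with the previous level's field sampled at
      # the control points (exact for constant fields, smoothing otherwise)
      cpts <- as.matrix(expand.grid(
        lat$corigin[1] + (seq_len(lat$cdim[1]) - 1) * lat$cspacing[1],
        lat$corigin[2] + (seq_len(lat$cdim[2]) - 1) * lat$cspacing[2],
        lat$corigin[3] + (seq_len(lat$cdim[3]) - 1) * lat$cspacing[3]))
      for (c in 1:3)
        coef[(c - 1) * nc + seq_len(nc)] <-
          cpp_resample_world(as.numeric(prev_dvf$vectors[, , , c]), fg$shape,
                             fg$spacing, fg$origin, cpts, 0L, 0)
    } else if (any(shift != 0)) {
      coef <- c(rep(shift[1], nc), rep(shift[2], nc), rep(shift[3], nc))
    }

    obj <- function(cf) {
      d <- cpp_ffd_dense(cf, lat$cdim, lat$cspacing, lat$corigin, sg$shape,
                         sg$spacing, sg$origin)
      cpp_ssd_warp(as.numeric(fixed_s$values), sg$shape, sg$spacing, sg$origin,
                   as.numeric(moving$values), mg$shape, mg$spacing, mg$origin,
                   d, background)
    }
    cur <- obj(coef)
    step <- NULL
    for (it in seq_len(config$iterations)) {
      d <- cpp_ffd_dense(coef, lat$cdim, lat$cspacing, lat$corigin, sg$shape,
                         sg$spacing, sg$origin)
      w <- cpp_warp_to_grid(as.numeric(moving$values), mg$shape, mg$spacing,
                            mg$origin, sg$shape, sg$spacing, sg$origin, d, 0L,
                            background)
      resid <- w - as.numeric(fixed_s$values)
      grad <- cpp_gradient3(w, sg$shape, sg$spacing)
      n <- length(w)
      fld <- c(2 * resid * grad[seq_len(n)],
               2 * resid * grad[n + seq_len(n)],
               2 * resid * grad[2 * n + seq_len(n)])
      g <- cpp_ffd_adjoint(fld, lat$cdim, lat$cspacing, lat$corigin, sg$shape,
                           sg$spacing, sg$origin)
      gmax <- max(abs(g))
      if (gmax < 1e-12) break
      if (is.null(step)) step <- 0.4 * delta / gmax
      improved <- FALSE
      for (bt in 1:8) {
        cand <- coef - step * g
        val <- obj(cand)
        if (val < cur) {
          coef <- cand
          cur <- val
          step <- step * 1.2
          improved <- TRUE
          break
        }
        step <- step / 2
      }
      if (!improved) break
    }
    prev_dvf <- ffd_dense_dvf(coef, lat, fg)
    log <- rbind(log, data.frame(level = lev,
                                 ssd = ssd_under(fixed, moving, prev_dvf,
                                                 background)))
    if (verbose) message(sprintf("level %d (delta %g mm): SSD %.4g", lev,
                                 delta, log$ssd[nrow(log)]))
  }

  out <- prev_dvf
  final_ssd <- log$ssd[nrow(log)]
  if (final_ssd > ssd0) {
    warning("B-spline registration did not improve SSD; returning the zero field")
    out <- zero
  }
  attr(out, "log") <- log
  attr(out, "ffd") <- list(coef = coef, cdim = lat$cdim,
                           cspacing = lat$cspacing, corigin = lat$corigin)
  out
}

#' Hybrid registration: B-spline initialisation, optical-flow refinement
#'
#' The B-spline DVF is used as the initial condition for the iterative
#' optical flow; the final field warps the moving image into the deformed
#' CT (dCT_H).
#'
#' @param fixed,moving \code{\link{image_volume}} objects.
#' @param bcfg a \code{\link{bspline_config}}.
#' @param schedule a \code{\link{registration_schedule}}.
#' @param background intensity outside the moving extent.
#' @param verbose print progress.
#' @return A list: \code{dvf} (final field), \code{dct} (warped moving
#'   image), \code{dvf_bspline} (the initialisation).
#' @export
hybrid_register <- function(fixed, moving, bcfg = bspline_config(),
                            schedule = registration_schedule(),
                            background = 0, verbose = FALSE) {
  dvf_b <- bspline_register(fixed, moving, bcfg, background, verbose)
  dvf <- iof_register(fixed, moving, schedule, init = dvf_b,
                      background = background, verbose = verbose)
  list(dvf = dvf, dct = warp_image(moving, dvf, background = background),
       dvf_bspline = dvf_b)
}

#' Two-step registration with structure intensity override
#'
#' Step 1: override the named structure intensities on both images
#' (\code{I' = I - I_average + C}); step 2: run the iterative optical flow
#' on the overridden pair (overridden CBCT fixed, overridden planning CT
#' moving); step 3: apply the resulting DVF to the original, non-overridden
#' planning CT to produce the two-step deformed image (dCT_C). The override
#' never leaks into the output intensities.
#'
#' @param pct planning-CT \code{\link{image_volume}} (moving).
#' @param cbct CBCT \code{image_volume} (fixed); carries the output grid.
#' @param pct_structs,cbct_structs \code{\link{structure_set}} objects on
#'   the respective grids.
#' @param spec an \code{\link{override_spec}}.
#' @param schedule a \code{\link{registration_schedule}}.
#' @param background intensity outside the moving extent.
#' @param verbose print progress.
#' @return A list: \code{dvf}, \code{dct}, \code{i_average_pct},
#'   \code{i_average_cbct}.
#' @export
two_step_register <- function(pct, cbct, pct_structs, cbct_structs,
                              spec = override_spec(),
                              schedule = registration_schedule(),
                              background = 0, verbose = FALSE) {
  op <- override_structures(pct, pct_structs, spec)
  oc <- override_structures(cbct, cbct_structs, spec)
  dvf <- iof_register(oc$image, op$image, schedule, background = background,
                      verbose = verbose)
  list(dvf = dvf, dct = warp_image(pct, dvf, background = background),
       i_average_pct = op$i_average, i_average_cbct = oc$i_average)
}
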