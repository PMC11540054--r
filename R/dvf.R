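#' Warp an image under a displacement field
#'
#' Pull convention: the output lives on the DVF's (fixed) grid and takes, at
#' world point x, the moving image's value sampled at x + u(x).
#'
#' @param moving the \code{\link{image_volume}} to warp.
#' @param dvf a \code{\link{displacement_field}} on the output grid.
#' @param interp "linear" or "nearest".
#' @param background fill for samples outside the moving extent.
#' @return An \code{image_volume} on \code{dvf$grid}.
#' @export
warp_image <- function(moving, dvf, interp = c("linear", "nearest"),
                       background = 0) {
  interp <- match.arg(interp)
  if (any(!is.finite(dvf$vectors))) stop("displacement field contains non-finite values")
  mg <- moving$grid
  fg <- dvf$grid
  out <- cpp_warp_to_grid(as.numeric(moving$values), mg$shape, mg$spacing,
                          mg$origin, fg$shape, fg$spacing, fg$origin,
                          dvf_vec(dvf), if (interp == "nearest") 1L else 0L,
                          background)
  dim(out) <- fg$shape
  image_volume(out, grid = fg, modality = "dCT", units = moving$units)
}

#' Propagate a binary mask through a displacement field
#'
#' The mask is warped with linear interpolation and thresholded at 0.5, so
#' the result is guaranteed binary.
#'
#' @param mask logical 3-D array on the moving grid.
#' @param dvf a \code{\link{displacement_field}}.
#' @param grid the mask's own \code{grid_geometry} (defaults to
#'   \code{dvf$grid}, i.e. coincident grids).
#' @return Logical array on \code{dvf$grid}.
#' @export
propagate_mask <- function(mask, dvf, grid = dvf$grid) {
  if (!identical(as.integer(dim(mask)), grid$shape))
    stop("mask does not match its grid")
  mv <- image_volume(array(as.numeric(mask), dim(mask)), grid = grid,
                     units = "binary")
  warp_image(mv, dvf, interp = "linear", background = 0)$values >= 0.5
}

#' Resample a displacement field onto another grid
#'
#' Each vector component is linearly interpolated at the target voxel
#' centres; displacement values (mm) are unchanged in units. Used for the
#' multigrid restrict/prolong steps.
#'
#' @param dvf a \code{\link{displacement_field}}.
#' @param target target \code{grid_geometry}.
#' @return A \code{displacement_field} on \code{target}.
#' @export
resample_dvf <- function(dvf, target) {
  g <- dvf$grid
  pts <- grid_points(target)
  comps <- lapply(1:3, function(c) {
    # edge-clamped sampling: a displacement field has no meaningful
    # "background", and clamping avoids spurious kinks at the volume faces
    v <- cpp_resample_world(as.numeric(dvf$vectors[, , , c]), g$shape,
                            g$spacing, g$origin, pts, 2L, 0)
    dim(v) <- target$shape
    v
  })
  displacement_field(array(c(comps[[1]], comps[[2]], comps[[3]]),
                           c(target$shape, 3)), target)
}

#' Compose two displacement fields
#'
#' Returns the field of the composite warp "apply \code{outer}, then
#' \code{inner}": u(x) = u_outer(x) + u_inner(x + u_outer(x)). Both fields
#' must share a world frame; the result lives on \code{outer}'s grid.
#'
#' @param outer,inner \code{\link{displacement_field}} objects.
#' @return A \code{displacement_field} on \code{outer$grid}.
#' @export
compose_dvf <- function(outer, inner) {
  g <- outer$grid
  pts <- grid_points(g)
  pts_shift <- pts + cbind(as.numeric(outer$vectors[, , , 1]),
                           as.numeric(outer$vectors[, , , 2]),
                           as.numeric(outer$vectors[, , , 3]))
  ig <- inner$grid
  add <- vapply(1:3, function(c) {
    cpp_resample_world(as.numeric(inner$vectors[, , , c]), ig$shape,
                       ig$spacing, ig$origin, pts_shift, 2L, 0)
  }, numeric(nrow(pts)))
  v <- outer$vectors
  for (c in 1:3) v[, , , c] <- v[, , , c] + array(add[, c], g$shape)
  displacement_field(v, g)
}

#' Gaussian-smooth a displacement field
#'
#' @param dvf a \code{\link{displacement_field}}.
#' @param sigma_mm isotropic Gaussian sigma in mm (0 = no-op).
#' @return The smoothed \code{displacement_field}.
#' @export
smooth_dvf <- function(dvf, sigma_mm) {
  if (sigma_mm <= 0) return(dvf)
  g <- dvf$grid
  sig_vox <- sigma_mm / g$spacing
  v <- dvf$vectors
  for (c in 1:3) {
    s <- cpp_gauss3(as.numeric(v[, , , c]), g$shape, sig_vox)
    v[, , , c] <- array(s, g$shape)
  }
  displacement_field(v, g)
}

#' Maximum displacement magnitude of a field
#' @param dvf a \code{\link{displacement_field}}.
#' @return Max |u| in mm.
#' @export
max_displacement <- function(dvf) {
  sqrt(max(dvf$vectors[, , , 1]^2 + dvf$vectors[, , , 2]^2 +
             dvf$vectors[, , , 3]^2))
}

# internal: SSD between fixed image and moving warped under dvf
ssd_under <- function(fixed, moving, dvf, background = 0) {
  fg <- fixed$grid
  mg <- moving$grid
  cpp_ssd_warp(as.numeric(fixed$values), fg$shape, fg$spacing, fg$origin,
               as.numeric(moving$values), mg$shape, mg$spacing, mg$origin,
               dvf_vec(dvf), background)
}

# internal: downsample a grid by an integer factor per axis (voxel centres
# at every factor-th source centre, so grids stay aligned)
downsample_grid <- function(grid, factor) {
  if (factor <= 1) return(grid)
  shape <- pmax(1L, as.integer(ceiling(grid$shape / factor)))
  grid_geometry(shape, grid$spacing * factor, grid$origin)
}
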