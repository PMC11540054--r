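#' Resample a volume onto a target grid
#'
#' Values are interpolated at the world coordinates of the target voxel
#' centres; points outside the source extent take \code{background}
#' (default 0 = air in offset units). Exact on grid-coincident points, so
#' resampling onto the same grid is the identity.
#'
#' @param vol an \code{\link{image_volume}} (or \code{dose_grid}).
#' @param target target \code{\link{grid_geometry}}.
#' @param interp "linear" or "nearest".
#' @param background fill value outside the source extent.
#' @return An object of the same class as \code{vol} on \code{target}.
#' @export
resample_to_grid <- function(vol, target, interp = c("linear", "nearest"),
                             background = 0) {
  interp <- match.arg(interp)
  arr <- if (inherits(vol, "dose_grid")) vol$dose else vol$values
  g <- vol$grid
  pts <- grid_points(target)
  out <- cpp_resample_world(as.numeric(arr), g$shape, g$spacing, g$origin,
                            pts, if (interp == "nearest") 1L else 0L,
                            background)
  dim(out) <- target$shape
  if (inherits(vol, "dose_grid")) dose_grid(out, grid = target)
  else image_volume(out, grid = target, modality = vol$modality,
                    units = vol$units)
}

#' Resample a binary mask onto a target grid (nearest neighbour)
#' @param mask logical 3-D array.
#' @param grid the mask's \code{grid_geometry}.
#' @param target target \code{grid_geometry}.
#' @return Logical array on \code{target}.
#' @export
resample_mask <- function(mask, grid, target) {
  v <- image_volume(array(as.numeric(mask), dim(mask)), grid = grid,
                    units = "binary")
  resample_to_grid(v, target, interp = "nearest")$values > 0.5
}

#' Crop two volumes to their common world extent
#'
#' Both volumes keep their own spacing and voxel centres; each is restricted
#' to the voxels whose centres fall inside the intersection of the two world
#' bounding boxes, expanded by \code{margin_mm}.
#'
#' @param a,b \code{\link{image_volume}} objects.
#' @param margin_mm extra margin kept around the overlap box.
#' @return A list with cropped \code{a} and \code{b}.
#' @export
crop_to_overlap <- function(a, b, margin_mm = 0) {
  ea <- grid_extent(a$grid)
  eb <- grid_extent(b$grid)
  lo <- pmax(ea[1, ], eb[1, ]) - margin_mm
  hi <- pmin(ea[2, ], eb[2, ]) + margin_mm
  if (any(lo > hi + 1e-9)) stop("volumes have no overlapping world extent")
  list(a = crop_volume(a, lo, hi), b = crop_volume(b, lo, hi))
}

# internal: restrict a volume to voxels whose centres lie in [lo, hi]
crop_volume <- function(vol, lo, hi) {
  g <- vol$grid
  idx <- lapply(1:3, function(ax) {
    ctr <- g$origin[ax] + (seq_len(g$shape[ax]) - 1) * g$spacing[ax]
    which(ctr >= lo[ax] - 1e-9 & ctr <= hi[ax] + 1e-9)
  })
  if (any(vapply(idx, length, 1L) == 0))
    stop("crop leaves no voxels along an axis")
  vals <- vol$values[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  org <- g$origin + (vapply(idx, min, 1L) - 1) * g$spacing
  image_volume(vals, grid = grid_geometry(dim(vals), g$spacing, org),
               modality = vol$modality, units = vol$units)
}

#' Gaussian-smooth an image volume
#'
#' Separable Gaussian low-pass with per-axis sigma in mm (used e.g. as the
#' anti-alias filter of the registration pyramids).
#'
#' @param vol an \code{\link{image_volume}}.
#' @param sigma_mm scalar or length-3 sigma in mm.
#' @return The smoothed \code{image_volume}.
#' @export
smooth_volume <- function(vol, sigma_mm) {
  g <- vol$grid
  if (length(sigma_mm) == 1) sigma_mm <- rep(sigma_mm, 3)
  v <- cpp_gauss3(as.numeric(vol$values), g$shape, sigma_mm / g$spacing)
  image_volume(array(v, g$shape), grid = g, modality = vol$modality,
               units = vol$units)
}
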