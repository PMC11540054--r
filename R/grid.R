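#' Grid geometry of a voxel lattice
#'
#' Describes the sampling lattice shared by images, masks, displacement
#' fields and dose grids: voxel counts, spacing in mm and the world
#' coordinate (mm) of the centre of the first voxel. Axes are the NIfTI
#' sform axes in fixed (x, y, z) order; the world coordinate of voxel
#' \code{(i, j, k)} (1-based, R convention) is
#' \code{origin + (i - 1, j - 1, k - 1) * spacing}.
#'
#' @param shape integer vector of length 3, voxel counts (nx, ny, nz).
#' @param spacing numeric vector of length 3, mm per voxel; all > 0.
#' @param origin numeric vector of length 3, mm coordinates of the centre of
#'   the first voxel.
#' @return An object of class \code{grid_geometry}.
#' @export
grid_geometry <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(shape) == 3, length(spacing) == 3, length(origin) == 3)
  if (any(shape < 1L)) stop("all shape entries must be >= 1")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all spacings must be positive and finite")
  if (any(!is.finite(origin))) stop("origin must be finite")
  structure(list(shape = shape, spacing = spacing, origin = origin,
                 axes = "xyz"),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("grid_geometry: %d x %d x %d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Test two grids for (near-)equality
#'
#' @param a,b \code{grid_geometry} objects.
#' @param tol tolerance in mm on spacing and origin.
#' @return Logical scalar.
#' @export
grid_equal <- function(a, b, tol = 1e-3) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' World coordinates of all voxel centres
#'
#' @param grid a \code{grid_geometry}.
#' @return An n-by-3 matrix of mm coordinates, voxel order matching the
#'   column-major layout of the value arrays (x fastest).
#' @export
grid_points <- function(grid) {
  s <- grid$shape
  cbind(
    rep.int(grid$origin[1] + (seq_len(s[1]) - 1) * grid$spacing[1], s[2] * s[3]),
    rep.int(rep(grid$origin[2] + (seq_len(s[2]) - 1) * grid$spacing[2],
                each = s[1]), s[3]),
    rep(grid$origin[3] + (seq_len(s[3]) - 1) * grid$spacing[3],
        each = s[1] * s[2])
  )
}

#' World extent of a grid
#'
#' @param grid a \code{grid_geometry}.
#' @return 2-by-3 matrix: first row the world coordinate of the first voxel
#'   centre, second row that of the last.
#' @export
grid_extent <- function(grid) {
  rbind(grid$origin, grid$origin + (grid$shape - 1) * grid$spacing)
}

#' Scalar image volume on a voxel lattice
#'
#' Values are CT numbers in offset units (HU + 1000) unless tagged
#' otherwise: with that convention air is about 0, water about 1000, and the
#' gas/override constants used throughout the package (gas below 800, fill
#' 1060, override targets 800-1200) are directly meaningful.
#'
#' @param values numeric 3-D array.
#' @param spacing,origin grid geometry (mm), or pass \code{grid}.
#' @param grid optional \code{grid_geometry} overriding spacing/origin.
#' @param modality one of "pCT", "kVCBCT", "dCT", "other".
#' @param units "offset" (HU + 1000) or "hu".
#' @return An object of class \code{image_volume}.
#' @export
image_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         grid = NULL, modality = "other", units = "offset") {
  if (length(dim(values)) != 3)
    stop("values must be a 3-D array")
  if (is.null(grid)) grid <- grid_geometry(dim(values), spacing, origin)
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("values dimensions do not match grid shape")
  if (any(!is.finite(values)))
    stop("image values must be finite")
  structure(list(values = values, grid = grid, modality = modality,
                 units = units),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("image_volume [%s, %s units]\n", x$modality, x$units))
  print(x$grid)
  cat(sprintf("  value range [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Named binary structure masks on a shared grid
#'
#' @param masks named list of logical (or 0/1) 3-D arrays, one per structure.
#'   Canonical names: body, bladder, rectum, target, subcutaneous_fat,
#'   femoral_head_l, femoral_head_r.
#' @param grid the shared \code{grid_geometry}.
#' @return An object of class \code{structure_set}.
#' @export
structure_set <- function(masks, grid) {
  if (is.null(names(masks)) || any(names(masks) == ""))
    stop("all masks must be named")
  if (anyDuplicated(tolower(names(masks))))
    stop("structure names must be unique (case-insensitive)")
  masks <- lapply(masks, function(m) {
    if (!identical(as.integer(dim(m)), grid$shape))
      stop("mask dimensions do not match grid shape")
    storage.mode(m) <- "logical"
    m
  })
  structure(list(masks = masks, grid = grid), class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat("structure_set:\n")
  for (nm in names(x$masks))
    cat(sprintf("  %-18s %d voxels\n", nm, sum(x$masks[[nm]])))
  invisible(x)
}

#' Absorbed dose on a voxel lattice
#'
#' @param dose numeric 3-D array of dose in Gy, non-negative and finite.
#' @param spacing,origin,grid grid geometry as for \code{\link{image_volume}}.
#' @return An object of class \code{dose_grid}.
#' @export
dose_grid <- function(dose, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      grid = NULL) {
  if (length(dim(dose)) != 3) stop("dose must be a 3-D array")
  if (is.null(grid)) grid <- grid_geometry(dim(dose), spacing, origin)
  if (!identical(as.integer(dim(dose)), grid$shape))
    stop("dose dimensions do not match grid shape")
  if (any(!is.finite(dose)) || any(dose < 0))
    stop("dose must be finite and non-negative")
  structure(list(dose = dose, grid = grid), class = "dose_grid")
}

#' Per-voxel displacement field (DVF)
#'
#' Pull (backward-warp) convention on the fixed-image grid: the warped image
#' at world point x takes the moving image's value at x + u(x), with u in mm.
#'
#' @param vectors numeric 4-D array \code{c(shape, 3)}: ux, uy, uz in mm.
#' @param grid the fixed-image \code{grid_geometry}.
#' @return An object of class \code{displacement_field}.
#' @export
displacement_field <- function(vectors, grid) {
  d <- dim(vectors)
  if (length(d) != 4 || d[4] != 3)
    stop("vectors must be a 4-D array with last dimension 3")
  if (!identical(as.integer(d[1:3]), grid$shape))
    stop("vector dimensions do not match grid shape")
  if (any(!is.finite(vectors)))
    stop("displacement field must be finite")
  structure(list(vectors = vectors, grid = grid),
            class = "displacement_field")
}

#' Zero displacement field on a grid
#' @param grid a \code{grid_geometry}.
#' @return A \code{displacement_field} of all-zero vectors.
#' @export
zero_dvf <- function(grid) {
  displacement_field(array(0, c(grid$shape, 3)), grid)
}

#' @export
print.displacement_field <- function(x, ...) {
  mag <- sqrt(x$vectors[, , , 1]^2 + x$vectors[, , , 2]^2 + x$vectors[, , , 3]^2)
  cat("displacement_field (pull convention, mm)\n")
  print(x$grid)
  cat(sprintf("  |u|: mean %.3f mm, max %.3f mm\n", mean(mag), max(mag)))
  invisible(x)
}

# internal: flatten a DVF to the 3-block layout the C++ kernels use
dvf_vec <- function(dvf) as.numeric(dvf$vectors)

# internal: mask as integer vector for C++ morphology kernels
mask_int <- function(mask) {
  m <- as.integer(mask)
  dim(m) <- NULL
  m
}
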