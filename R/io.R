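#' Read a volumetric image from NIfTI
#'
#' Spacing and origin are taken from the NIfTI header (sform). Values are
#' kept as stored; if \code{shift_to_offset} is TRUE the volume is assumed to
#' hold raw HU and 1000 is added so the result uses the package's offset
#' convention (HU + 1000).
#'
#' @param path path to a .nii or .nii.gz file.
#' @param modality modality tag to attach.
#' @param units units tag of the stored values.
#' @param shift_to_offset add 1000 to convert raw HU to offset units.
#' @return An \code{\link{image_volume}}.
#' @export
read_volume <- function(path, modality = "other", units = "offset",
                        shift_to_offset = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI file ", path,
                                           ": ", conditionMessage(e)))
  vals <- as.array(img)
  if (length(dim(vals)) == 4 && dim(vals)[4] == 1) dim(vals) <- dim(vals)[1:3]
  if (length(dim(vals)) != 3) stop("expected a 3-D volume in ", path)
  geo <- nifti_geometry(img)
  if (shift_to_offset) {
    vals <- vals + 1000
    units <- "offset"
  }
  image_volume(vals, grid = grid_geometry(dim(vals), geo$spacing, geo$origin),
               modality = modality, units = units)
}

# internal: spacing/origin from a NIfti header (sform preferred)
nifti_geometry <- function(img) {
  xf <- RNifti::xform(img)
  spacing <- sqrt(colSums(xf[1:3, 1:3]^2))
  if (any(spacing <= 0)) spacing <- RNifti::pixdim(img)[1:3]
  list(spacing = as.numeric(spacing), origin = as.numeric(xf[1:3, 4]))
}

# internal: attach grid geometry to an array and write as NIfTI
write_nifti_array <- function(arr, grid, path, datatype = "auto") {
  img <- RNifti::asNifti(arr, datatype = datatype)
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- c(grid$spacing, rep(1, nd - 3))
  aff <- diag(4)
  diag(aff)[1:3] <- grid$spacing
  aff[1:3, 4] <- grid$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a volume, mask, dose grid or DVF to NIfTI
#'
#' Masks are written as integer 0/1; displacement fields as a 4-D volume with
#' three components in mm.
#'
#' @param vol an \code{image_volume}, \code{dose_grid},
#'   \code{displacement_field}, or a bare array with an accompanying
#'   \code{grid}.
#' @param path output .nii or .nii.gz path.
#' @param grid required when \code{vol} is a bare array.
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path, grid = NULL) {
  if (inherits(vol, "image_volume")) {
    write_nifti_array(vol$values, vol$grid, path)
  } else if (inherits(vol, "dose_grid")) {
    write_nifti_array(vol$dose, vol$grid, path)
  } else if (inherits(vol, "displacement_field")) {
    write_nifti_array(vol$vectors, vol$grid, path)
  } else if (is.array(vol) && !is.null(grid)) {
    if (is.logical(vol)) storage.mode(vol) <- "integer"
    write_nifti_array(vol, grid, path)
  } else stop("unsupported object for write_volume")
  invisible(path)
}

#' Read a displacement field written by \code{write_volume}
#' @param path NIfTI path holding a 4-D, 3-component field in mm.
#' @return A \code{\link{displacement_field}}.
#' @export
read_dvf <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  if (length(dim(vals)) != 4 || dim(vals)[4] != 3)
    stop("expected a 4-D, 3-component field in ", path)
  geo <- nifti_geometry(img)
  displacement_field(vals, grid_geometry(dim(vals)[1:3], geo$spacing,
                                         geo$origin))
}

#' Read a dose grid from NIfTI
#' @param path NIfTI path with dose in Gy.
#' @return A \code{\link{dose_grid}}.
#' @export
read_dose <- function(path) {
  v <- read_volume(path, modality = "other", units = "Gy")
  dose_grid(v$values, grid = v$grid)
}

#' Read a structure set
#'
#' The manifest is a JSON file with one of three layouts: a label map
#' (\code{labelmap} NIfTI path + \code{names} mapping label value to
#' structure name), one binary NIfTI per structure (\code{masks} mapping name
#' to path), or planar polygon contours (\code{contours} mapping name to a
#' list of \code{\{z, points\}} entries in world mm) rasterized onto
#' \code{grid} with even-odd fill at voxel centres. Relative paths resolve
#' against the manifest's directory.
#'
#' @param path JSON manifest path.
#' @param grid grid to align/rasterize to; defaults to the masks' own grid
#'   (required for contours).
#' @param tol_mm grid-agreement tolerance in mm.
#' @return A \code{\link{structure_set}}.
#' @export
read_structures <- function(path, grid = NULL, tol_mm = 1e-3) {
  man <- jsonlite::read_json(path, simplifyVector = FALSE)
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)

  if (!is.null(man$labelmap)) {
    lv <- read_volume(resolve(man$labelmap), units = "label")
    check_structure_grid(lv$grid, grid, tol_mm)
    nmap <- man$names
    masks <- list()
    for (lab in names(nmap)) {
      nm <- tolower(as.character(nmap[[lab]]))
      if (nm %in% names(masks)) stop("duplicate structure name: ", nm)
      m <- lv$values == as.numeric(lab)
      if (!any(m)) warning("structure '", nm, "' is empty")
      masks[[nm]] <- m
    }
    return(structure_set(masks, lv$grid))
  }
  if (!is.null(man$masks)) {
    masks <- list()
    g <- grid
    for (nm in names(man$masks)) {
      v <- read_volume(resolve(man$masks[[nm]]), units = "binary")
      if (is.null(g)) g <- v$grid else check_structure_grid(v$grid, g, tol_mm)
      nml <- tolower(nm)
      if (nml %in% names(masks)) stop("duplicate structure name: ", nml)
      m <- v$values > 0.5
      if (!any(m)) warning("structure '", nml, "' is empty")
      masks[[nml]] <- m
    }
    return(structure_set(masks, g))
  }
  if (!is.null(man$contours)) {
    if (is.null(grid)) stop("a target grid is required to rasterize contours")
    masks <- lapply(man$contours, function(cl) {
      cl <- lapply(cl, function(ct) list(
        z = as.numeric(ct$z),
        points = do.call(rbind, lapply(ct$points, unlist))))
      rasterize_contours(cl, grid)
    })
    names(masks) <- tolower(names(man$contours))
    empty <- !vapply(masks, any, logical(1))
    if (any(empty)) warning("empty structure(s): ",
                            paste(names(masks)[empty], collapse = ", "))
    return(structure_set(masks, grid))
  }
  stop("manifest must contain 'labelmap', 'masks' or 'contours'")
}

check_structure_grid <- function(g, target, tol_mm) {
  if (!is.null(target) && !grid_equal(g, target, tol_mm))
    stop("structure grid does not match the target grid within ", tol_mm,
         " mm")
  invisible(TRUE)
}

#' Rasterize planar polygon contours to a binary mask
#'
#' Even-odd (crossing-count) fill evaluated at voxel centres with the
#' half-open convention: a centre exactly on a lower edge is inside, on an
#' upper edge outside. Each contour is assigned to the nearest slice.
#'
#' @param contours list of \code{list(z = mm, points = n-by-2 matrix of (x, y)
#'   mm)} entries; the polygon is closed implicitly.
#' @param grid target \code{grid_geometry}.
#' @return A logical 3-D array on \code{grid}.
#' @export
rasterize_contours <- function(contours, grid) {
  mask <- array(FALSE, grid$shape)
  xs <- grid$origin[1] + (seq_len(grid$shape[1]) - 1) * grid$spacing[1]
  ys <- grid$origin[2] + (seq_len(grid$shape[2]) - 1) * grid$spacing[2]
  zs <- grid$origin[3] + (seq_len(grid$shape[3]) - 1) * grid$spacing[3]
  for (ct in contours) {
    k <- which.min(abs(zs - ct$z))
    if (abs(zs[k] - ct$z) > grid$spacing[3] / 2 + 1e-9) next
    p <- ct$points
    inside <- matrix(FALSE, length(xs), length(ys))
    n <- nrow(p)
    jprev <- n
    for (e in seq_len(n)) {
      x1 <- p[jprev, 1]; y1 <- p[jprev, 2]
      x2 <- p[e, 1]; y2 <- p[e, 2]
      jprev <- e
      if (y1 == y2) next
      for (jy in seq_along(ys)) {
        py <- ys[jy]
        if ((y1 > py) != (y2 > py)) {
          xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
          inside[xs < xint, jy] <- !inside[xs < xint, jy]
        }
      }
    }
    # even-odd across contours on the same slice: an inner contour carves
    # a hole out of an outer one
    mask[, , k] <- xor(mask[, , k], inside)
  }
  mask
}

#' Write a structure set as a label map plus JSON manifest
#'
#' Later structures overwrite earlier ones where masks overlap in the label
#' map; the manifest records the name table.
#'
#' @param structs a \code{\link{structure_set}}.
#' @param path JSON manifest path; the label map is written alongside it.
#' @return The manifest path, invisibly.
#' @export
write_structures <- function(structs, path) {
  lab <- array(0L, structs$grid$shape)
  nmap <- list()
  i <- 0L
  for (nm in names(structs$masks)) {
    i <- i + 1L
    lab[structs$masks[[nm]]] <- i
    nmap[[as.character(i)]] <- nm
  }
  nii <- sub("\\.json$", "_labels.nii.gz", path)
  write_nifti_array(lab, structs$grid, nii)
  jsonlite::write_json(list(labelmap = basename(nii), names = nmap), path,
                       auto_unbox = TRUE)
  invisible(path)
}
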