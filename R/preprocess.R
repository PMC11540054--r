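#' Remove the treatment table / background from an image
#'
#' Everything outside the body mask is set to the background value. When no
#' mask is supplied, the body is derived as the largest 26-connected
#' component of voxels above \code{threshold} (offset units), with enclosed
#' holes filled slice by slice.
#'
#' @param image an \code{\link{image_volume}} in offset units.
#' @param body optional logical body mask on the image grid.
#' @param threshold offset-unit threshold for auto-derivation (default 500,
#'   i.e. -500 HU, between air and soft tissue).
#' @param background value assigned outside the body.
#' @return A list with the cleaned \code{image} and the \code{body} mask.
#' @export
remove_table <- function(image, body = NULL, threshold = 500, background = 0) {
  if (is.null(body)) {
    fg <- image$values > threshold
    if (!any(fg)) stop("empty body: no voxels above threshold")
    lab <- cpp_label3d(mask_int(fg), image$grid$shape)
    tab <- tabulate(lab)
    keep <- lab == which.max(tab)
    dim(keep) <- image$grid$shape
    filled <- cpp_fill_holes_2d(mask_int(keep), image$grid$shape)
    body <- array(filled == 1L, image$grid$shape)
  } else {
    storage.mode(body) <- "logical"
    if (!any(body)) stop("empty body mask")
  }
  vals <- image$values
  vals[!body] <- background
  list(image = image_volume(vals, grid = image$grid,
                            modality = image$modality, units = image$units),
       body = body)
}

#' Detect gas pockets
#'
#' Voxels strictly below the threshold (800 offset units = -200 HU by
#' default) are classified as gas; the test is restricted to a body mask
#' when one is given.
#'
#' @param image an \code{\link{image_volume}} in offset units.
#' @param threshold offset-unit gas threshold (strict \code{<}).
#' @param body optional logical mask limiting the search.
#' @return Logical gas mask (may be empty).
#' @export
detect_gas_pockets <- function(image, threshold = 800, body = NULL) {
  m <- image$values < threshold
  if (!is.null(body)) m <- m & body
  m
}

#' Fill gas pockets by paint-and-blend
#'
#' Three steps: (1) paint the gas voxels (mask M1) to the fill value and
#' Gaussian-smooth the painted image; (2) dilate M1 by \code{dilation_vox}
#' voxels (ball) to M2 and Gaussian-smooth it into a [0,1] blend weight;
#' (3) blend: \code{output = w * painted_smoothed + (1 - w) * original}.
#' Voxels with zero blend weight are returned bit-identical; deep pocket
#' interiors become exactly the fill value.
#'
#' @param image an \code{\link{image_volume}} in offset units.
#' @param gas logical gas mask (M1) on the image grid.
#' @param fill fill value in offset units (default 1060, slightly above
#'   water, emulating bowel content).
#' @param dilation_vox dilation radius in voxels.
#' @param sigma_mm Gaussian sigma (mm) for both smoothing steps.
#' @return A list of class \code{gas_fill_result}: \code{m1},
#'   \code{i_painting}, \code{i_painted_smoothed}, \code{m2},
#'   \code{m2_blurred}, and the blended \code{output} image.
#' @export
fill_gas_pockets <- function(image, gas, fill = 1060, dilation_vox = 2,
                             sigma_mm = 2) {
  if (dilation_vox <= 0) stop("dilation_vox must be positive")
  if (sigma_mm <= 0) stop("sigma_mm must be positive")
  if (!identical(dim(gas), dim(image$values)))
    stop("gas mask does not match the image grid")
  g <- image$grid
  sig_vox <- sigma_mm / g$spacing

  i_painting <- image$values
  i_painting[gas] <- fill
  i_ps <- cpp_gauss3(as.numeric(i_painting), g$shape, sig_vox)
  dim(i_ps) <- g$shape

  m2 <- cpp_dilate_ball(mask_int(gas), g$shape, as.integer(dilation_vox))
  m2arr <- array(m2 == 1L, g$shape)
  m2b <- cpp_gauss3(as.numeric(m2), g$shape, sig_vox)
  m2b <- pmin(pmax(m2b, 0), 1)
  dim(m2b) <- g$shape
  # the truncated Gaussian kernel has finite support, so weights are exactly
  # zero away from M2 and those voxels stay bit-identical in the blend
  out <- m2b * i_ps + (1 - m2b) * image$values
  structure(list(m1 = gas, i_painting = i_painting, i_painted_smoothed = i_ps,
                 m2 = m2arr, m2_blurred = m2b,
                 output = image_volume(out, grid = g,
                                       modality = image$modality,
                                       units = image$units)),
            class = "gas_fill_result")
}

#' Structure intensity override specification
#'
#' Per-structure override constants C in offset units for the override rule
#' \code{I' = I - I_average + C} applied inside each named mask.
#'
#' @param constants named numeric vector, structure name to C.
#' @param mean_region "whole_image" or "body_mask": scope over which
#'   I_average is computed.
#' @return An object of class \code{override_spec}.
#' @export
override_spec <- function(constants = c(bladder = 800, target = 1200,
                                        rectum = 800, subcutaneous_fat = 1200),
                          mean_region = c("whole_image", "body_mask")) {
  mean_region <- match.arg(mean_region)
  if (is.null(names(constants)) || any(!is.finite(constants)))
    stop("constants must be a named, finite numeric vector")
  structure(list(constants = constants, mean_region = mean_region),
            class = "override_spec")
}

#' Override structure intensities
#'
#' Inside each structure named in the spec, values become
#' \code{I - I_average + C}; elsewhere they are unchanged. I_average is the
#' image mean over the configured scope, computed once. Overlapping masks
#' are resolved by fixed priority: target > rectum > bladder >
#' subcutaneous_fat > (others in spec order); the winner is applied last.
#'
#' @param image an \code{\link{image_volume}} in offset units.
#' @param structures a \code{\link{structure_set}} on the image grid.
#' @param spec an \code{\link{override_spec}}.
#' @param body optional body mask when \code{mean_region = "body_mask"}.
#' @return A list with the overridden \code{image} and \code{i_average}.
#' @export
override_structures <- function(image, structures, spec = override_spec(),
                                body = NULL) {
  wanted <- names(spec$constants)
  have <- names(structures$masks)
  missing <- setdiff(wanted, have)
  if (length(missing))
    stop("missing structure(s): ", paste(missing, collapse = ", "),
         "; available: ", paste(have, collapse = ", "))
  if (!grid_equal(image$grid, structures$grid))
    stop("structure set grid does not match the image grid")
  i_avg <- if (spec$mean_region == "body_mask") {
    if (is.null(body)) stop("body mask required for mean_region='body_mask'")
    mean(image$values[body])
  } else mean(image$values)

  priority <- c("subcutaneous_fat", "bladder", "rectum", "target")
  order_names <- c(setdiff(wanted, priority), intersect(priority, wanted))
  vals <- image$values
  for (nm in order_names) {
    m <- structures$masks[[nm]]
    vals[m] <- image$values[m] - i_avg + spec$constants[[nm]]
  }
  list(image = image_volume(vals, grid = image$grid,
                            modality = image$modality, units = image$units),
       i_average = i_avg)
}
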