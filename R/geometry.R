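#' Dice similarity coefficient
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}. Two empty masks are defined as perfect
#' agreement (1, with a warning).
#'
#' @param a,b logical masks on the same grid.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks are on different grids")
  na <- sum(a)
  nb <- sum(b)
  if (na + nb == 0) {
    warning("both masks empty; Dice defined as 1")
    return(1)
  }
  2 * sum(a & b) / (na + nb)
}

#' Surface voxels of a binary mask
#'
#' A surface voxel is a mask voxel with at least one face neighbour outside
#' the mask (volume faces count as outside).
#'
#' @param mask logical 3-D array.
#' @return Logical array marking surface voxels.
#' @export
surface_voxels <- function(mask) {
  d <- dim(mask)
  pad <- array(FALSE, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  core & !nb
}

# internal: world-mm coordinates of surface voxel centres
surface_points <- function(mask, spacing, origin = c(0, 0, 0)) {
  idx <- which(surface_voxels(mask), arr.ind = TRUE)
  cbind(origin[1] + (idx[, 1] - 1) * spacing[1],
        origin[2] + (idx[, 2] - 1) * spacing[2],
        origin[3] + (idx[, 3] - 1) * spacing[3])
}

#' Directed surface distances between two masks
#'
#' For each surface voxel centre of one mask, the Euclidean distance (mm)
#' to the nearest surface voxel centre of the other.
#'
#' @param a,b logical masks on the same grid, both non-empty.
#' @param spacing voxel spacing in mm.
#' @return A list with \code{a_to_b} and \code{b_to_a} distance vectors.
#' @export
surface_distances <- function(a, b, spacing = c(1, 1, 1)) {
  if (!identical(dim(a), dim(b))) stop("masks are on different grids")
  if (!any(a)) stop("mask 'a' is empty")
  if (!any(b)) stop("mask 'b' is empty")
  pa <- surface_points(a, spacing)
  pb <- surface_points(b, spacing)
  list(a_to_b = as.numeric(cpp_nn_dist(pa, pb)),
       b_to_a = as.numeric(cpp_nn_dist(pb, pa)))
}

#' 95% Hausdorff distance
#'
#' The maximum of the two directed 95th percentiles of surface distances
#' (percentile by linear interpolation on the sorted distances). With
#' \code{directed = TRUE} only the a-to-b percentile is returned.
#'
#' @param a,b logical masks on the same grid.
#' @param spacing voxel spacing in mm.
#' @param percentile percentile of the directed distances (default 95).
#' @param directed return only the a-to-b directed value.
#' @return Distance in mm.
#' @export
hd95 <- function(a, b, spacing = c(1, 1, 1), percentile = 95,
                 directed = FALSE) {
  sd_ <- surface_distances(a, b, spacing)
  qa <- stats::quantile(sd_$a_to_b, percentile / 100, names = FALSE, type = 7)
  if (directed) return(qa)
  qb <- stats::quantile(sd_$b_to_a, percentile / 100, names = FALSE, type = 7)
  max(qa, qb)
}

#' Mean surface distance
#' @inheritParams hd95
#' @return Mean of all directed surface distances, mm.
#' @export
mean_surface_distance <- function(a, b, spacing = c(1, 1, 1)) {
  sd_ <- surface_distances(a, b, spacing)
  mean(c(sd_$a_to_b, sd_$b_to_a))
}

#' Contour-agreement report for two structure sets
#'
#' TG-132-style per-structure Dice, 95% Hausdorff distance and mean surface
#' distance, with the aggregate arithmetic mean and SD over the listed
#' structures.
#'
#' @param reference,test \code{\link{structure_set}} objects on the same
#'   grid.
#' @param structures structure names to evaluate (default: common names).
#' @return A data.frame (one row per structure) with attribute
#'   \code{"aggregate"} holding means and SDs.
#' @export
geometry_report <- function(reference, test, structures = NULL) {
  if (is.null(structures))
    structures <- intersect(names(reference$masks), names(test$masks))
  if (!length(structures)) stop("no common structures to evaluate")
  sp <- reference$grid$spacing
  rows <- lapply(structures, function(nm) {
    a <- reference$masks[[nm]]
    b <- test$masks[[nm]]
    data.frame(structure = nm, dsc = dice(a, b), hd95_mm = hd95(a, b, sp),
               msd_mm = mean_surface_distance(a, b, sp))
  })
  out <- do.call(rbind, rows)
  attr(out, "aggregate") <- c(
    dsc_mean = mean(out$dsc), dsc_sd = stats::sd(out$dsc),
    hd95_mean = mean(out$hd95_mm), hd95_sd = stats::sd(out$hd95_mm))
  out
}

#' Percent reduction between two metric values
#'
#' Convenience for reporting improvements such as the HD95 reduction from
#' one registration method to another: \code{100 * (from - to) / from}.
#'
#' @param from baseline value.
#' @param to improved value.
#' @return Percent reduction (positive when \code{to < from}).
#' @export
percent_reduction <- function(from, to) 100 * (from - to) / from
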