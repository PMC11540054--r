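#' Cumulative dose-volume histogram
#'
#' Fraction of the structure volume receiving at least each bin-edge dose.
#' The curve starts at 100% at 0 Gy and is non-increasing.
#'
#' @param dose a \code{\link{dose_grid}}.
#' @param mask logical structure mask on the dose grid, non-empty.
#' @param bin_width_gy dose bin width.
#' @return An object of class \code{dvh_curve}: data.frame with
#'   \code{dose_gy} (bin edges) and \code{volume_pct}; attributes
#'   \code{structure_volume_cc} and \code{doses} (the raw voxel doses).
#' @export
compute_dvh <- function(dose, mask, bin_width_gy = 0.1) {
  if (!identical(as.integer(dim(mask)), dose$grid$shape))
    stop("mask does not match the dose grid")
  if (!any(mask)) stop("empty structure mask")
  d <- dose$dose[mask]
  edges <- seq(0, max(d) + bin_width_gy, by = bin_width_gy)
  vol <- vapply(edges, function(e) mean(d >= e) * 100, 0)
  vox_cc <- prod(dose$grid$spacing) / 1000
  structure(data.frame(dose_gy = edges, volume_pct = vol),
            structure_volume_cc = sum(mask) * vox_cc, doses = d,
            class = c("dvh_curve", "data.frame"))
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("DVH: %d bins, volume %.2f cc, max dose %.2f Gy\n",
              nrow(x), attr(x, "structure_volume_cc"), max(x$dose_gy)))
  invisible(x)
}

#' Plot a cumulative DVH
#' @param x a \code{dvh_curve}.
#' @param ... passed to \code{plot}.
#' @export
plot.dvh_curve <- function(x, ...) {
  plot(x$dose_gy, x$volume_pct, type = "l", xlab = "dose (Gy)",
       ylab = "volume (%)", ylim = c(0, 100), ...)
  invisible(x)
}

#' DVH summary metric
#'
#' Supported specs: \code{"Dmean"}, \code{"Dmax"}, \code{"Dmin"},
#' \code{"D<p>"} (e.g. \code{"D98"}: minimum dose to the hottest p% of the
#' volume, i.e. the (1 - p/100) quantile of the voxel doses with linear
#' interpolation), and \code{"V<x>"} (e.g. \code{"V75"}: percent of the
#' volume receiving at least x Gy).
#'
#' @param dose a \code{\link{dose_grid}} or \code{dvh_curve}.
#' @param mask structure mask (ignored for a \code{dvh_curve}).
#' @param spec metric specification string.
#' @return Gy for D-metrics, percent for V-metrics.
#' @export
dvh_metric <- function(dose, mask = NULL, spec = "Dmean") {
  d <- if (inherits(dose, "dvh_curve")) attr(dose, "doses") else {
    if (is.null(mask)) stop("mask required with a dose grid")
    if (!any(mask)) stop("empty structure mask")
    dose$dose[mask]
  }
  spec <- trimws(spec)
  if (spec == "Dmean") return(mean(d))
  if (spec == "Dmax") return(max(d))
  if (spec == "Dmin") return(min(d))
  if (grepl("^D[0-9.]+%?$", spec)) {
    p <- as.numeric(sub("^D([0-9.]+)%?$", "\\1", spec))
    if (p <= 0 || p > 100) stop("Dp% needs p in (0, 100]")
    return(stats::quantile(d, 1 - p / 100, names = FALSE, type = 7))
  }
  if (grepl("^V[0-9.]+$", spec)) {
    x <- as.numeric(sub("^V", "", spec))
    return(mean(d >= x) * 100)
  }
  stop("unrecognized DVH metric spec: ", spec)
}

#' Gamma-analysis parameters
#'
#' Defaults follow the common clinical criterion: 3% dose difference,
#' 3 mm distance-to-agreement, global normalization to the reference
#' maximum, 10% low-dose threshold, search radius twice the DTA, and
#' sub-voxel search step of 0.3 mm.
#'
#' @param dose_diff_pct dose-difference criterion, percent.
#' @param dta_mm distance-to-agreement, mm.
#' @param normalization "global" (reference max) or "local".
#' @param low_dose_threshold_pct skip reference voxels below this percent of
#'   the reference maximum (0 evaluates everything).
#' @param search_radius_mm candidate-displacement radius.
#' @param step_mm candidate lattice step (<= 0.3 mm recommended).
#' @return An object of class \code{gamma_params}.
#' @export
gamma_params <- function(dose_diff_pct = 3, dta_mm = 3,
                         normalization = c("global", "local"),
                         low_dose_threshold_pct = 10,
                         search_radius_mm = 2 * dta_mm, step_mm = 0.3) {
  normalization <- match.arg(normalization)
  stopifnot(dose_diff_pct > 0, dta_mm > 0, step_mm > 0,
            search_radius_mm > 0)
  structure(list(dose_diff_pct = dose_diff_pct, dta_mm = dta_mm,
                 normalization = normalization,
                 low_dose_threshold_pct = low_dose_threshold_pct,
                 search_radius_mm = search_radius_mm, step_mm = step_mm),
            class = "gamma_params")
}

# internal: candidate displacement lattice sorted by increasing norm
gamma_offsets <- function(radius, step) {
  s <- seq(-radius, radius, by = step)
  g <- as.matrix(expand.grid(x = s, y = s, z = s))
  d2 <- rowSums(g^2)
  keep <- d2 <= radius^2 + 1e-12
  g <- g[keep, , drop = FALSE]
  d2 <- d2[keep]
  o <- order(d2)
  list(offsets = g[o, , drop = FALSE], dist2 = d2[o])
}

#' Gamma-index comparison of two dose distributions
#'
#' For each reference voxel above the low-dose threshold, the gamma index is
#' the minimum over candidate displacements d (|d| up to the search radius,
#' on a lattice of the configured step) of
#' \eqn{\sqrt{(\Delta D / \delta D)^2 + (|d| / \delta r)^2}}, with the
#' evaluated dose trilinearly interpolated at the displaced position. A
#' voxel passes when gamma <= 1 (the boundary counts as a pass).
#'
#' @param reference reference \code{\link{dose_grid}}.
#' @param evaluated evaluated \code{dose_grid} (may be on another grid).
#' @param params a \code{\link{gamma_params}}.
#' @return An object of class \code{gamma_result}: list with \code{gamma}
#'   (array, NA where not evaluated), \code{pass_rate} (percent of evaluated
#'   voxels with gamma <= 1) and \code{n_evaluated}.
#' @export
gamma_map <- function(reference, evaluated, params = gamma_params()) {
  rg <- reference$grid
  eg <- evaluated$grid
  rmax <- max(reference$dose)
  thr <- params$low_dose_threshold_pct / 100 * rmax
  eval_mask <- reference$dose > thr
  if (!any(eval_mask)) stop("no reference voxels above the low-dose threshold")
  dd <- if (params$normalization == "global") {
    array(params$dose_diff_pct / 100 * rmax, rg$shape)
  } else {
    params$dose_diff_pct / 100 * reference$dose
  }
  # voxels with zero local tolerance cannot be evaluated meaningfully
  eval_mask <- eval_mask & dd > 0
  off <- gamma_offsets(params$search_radius_mm, params$step_mm)
  g <- cpp_gamma_map(as.numeric(reference$dose), rg$shape, rg$spacing,
                     rg$origin, as.numeric(evaluated$dose), eg$shape,
                     eg$spacing, eg$origin, off$offsets, off$dist2,
                     params$dta_mm, as.numeric(dd), mask_int(eval_mask))
  dim(g) <- rg$shape
  vals <- g[!is.na(g)]
  # the gamma = 1 boundary counts as a pass; the relative epsilon keeps
  # exact boundary cases from failing on floating-point rounding
  structure(list(gamma = g,
                 pass_rate = if (length(vals))
                   mean(vals <= 1 + 1e-9) * 100 else NA_real_,
                 n_evaluated = length(vals), params = params),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("gamma analysis (%g%%/%g mm, %s): pass rate %.2f%% over %d voxels\n",
              x$params$dose_diff_pct, x$params$dta_mm,
              x$params$normalization, x$pass_rate, x$n_evaluated))
  invisible(x)
}
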