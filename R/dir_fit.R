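#' Fit a deformable registration between two volumes
#'
#' Front-end over the four registration methods, returning a classed fit
#' object with the usual accessors: \code{coef} (the displacement field),
#' \code{predict} (warp a new image or propagate a mask through the fitted
#' field), \code{residuals} (fixed minus warped intensities),
#' \code{summary} and \code{plot}.
#'
#' @param fixed fixed \code{\link{image_volume}} (CBCT in the clinical
#'   workflow).
#' @param moving moving \code{image_volume} (planning CT).
#' @param method "iof", "bspline", "hybrid" or "twostep".
#' @param fixed_structures,moving_structures \code{\link{structure_set}}
#'   objects; required for \code{method = "twostep"}.
#' @param schedule a \code{\link{registration_schedule}} (flow methods).
#' @param bspline a \code{\link{bspline_config}} (bspline/hybrid).
#' @param override an \code{\link{override_spec}} (twostep).
#' @param background intensity outside the moving extent.
#' @param verbose print progress.
#' @return An object of class \code{dir_fit}.
#' @export
dir_register <- function(fixed, moving,
                         method = c("iof", "bspline", "hybrid", "twostep"),
                         fixed_structures = NULL, moving_structures = NULL,
                         schedule = registration_schedule(),
                         bspline = bspline_config(),
                         override = override_spec(),
                         background = 0, verbose = FALSE) {
  method <- match.arg(method)
  ssd0 <- ssd_under(fixed, moving, zero_dvf(fixed$grid), background)
  extras <- list()
  if (method == "iof") {
    dvf <- iof_register(fixed, moving, schedule, background = background,
                        verbose = verbose)
    warped <- warp_image(moving, dvf, background = background)
  } else if (method == "bspline") {
    dvf <- bspline_register(fixed, moving, bspline, background, verbose)
    warped <- warp_image(moving, dvf, background = background)
  } else if (method == "hybrid") {
    h <- hybrid_register(fixed, moving, bspline, schedule, background, verbose)
    dvf <- h$dvf
    warped <- h$dct
    extras$dvf_bspline <- h$dvf_bspline
  } else {
    if (is.null(fixed_structures) || is.null(moving_structures))
      stop("method='twostep' requires structure sets for both images")
    t2 <- two_step_register(moving, fixed, moving_structures,
                            fixed_structures, override, schedule,
                            background, verbose)
    dvf <- t2$dvf
    warped <- t2$dct
    extras$i_average <- c(pct = t2$i_average_pct, cbct = t2$i_average_cbct)
  }
  structure(list(method = method, dvf = dvf, warped = warped, fixed = fixed,
                 moving = moving, ssd_initial = ssd0,
                 ssd_final = ssd_under(fixed, moving, dvf, background),
                 log = attr(dvf, "log"), extras = extras,
                 background = background),
            class = "dir_fit")
}

#' @export
print.dir_fit <- function(x, ...) {
  cat(sprintf("Deformable registration fit (method: %s)\n", x$method))
  print(x$fixed$grid)
  cat(sprintf("  SSD: %.4g -> %.4g (%.1f%% reduction)\n", x$ssd_initial,
              x$ssd_final,
              100 * (1 - x$ssd_final / max(x$ssd_initial, .Machine$double.eps))))
  cat(sprintf("  max |u| = %.2f mm\n", max_displacement(x$dvf)))
  invisible(x)
}

#' @export
summary.dir_fit <- function(object, ...) {
  mag <- sqrt(object$dvf$vectors[, , , 1]^2 + object$dvf$vectors[, , , 2]^2 +
                object$dvf$vectors[, , , 3]^2)
  out <- list(method = object$method, ssd_initial = object$ssd_initial,
              ssd_final = object$ssd_final, log = object$log,
              displacement = c(mean = mean(mag), median = stats::median(mag),
                               max = max(mag)))
  class(out) <- "summary.dir_fit"
  out
}

#' @export
print.summary.dir_fit <- function(x, ...) {
  cat(sprintf("Deformable registration (method: %s)\n", x$method))
  cat(sprintf("  SSD %.6g -> %.6g\n", x$ssd_initial, x$ssd_final))
  cat(sprintf("  |u| mm: mean %.3f, median %.3f, max %.3f\n",
              x$displacement["mean"], x$displacement["median"],
              x$displacement["max"]))
  if (!is.null(x$log) && nrow(x$log)) {
    cat("  per-stage SSD:\n")
    print(x$log, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.dir_fit <- function(object, ...) object$dvf

#' Warp new data through a fitted registration
#'
#' @param object a \code{dir_fit}.
#' @param newdata an \code{\link{image_volume}}, a \code{\link{structure_set}}
#'   or a logical mask array on the moving grid; defaults to the moving
#'   image.
#' @param type "image" (interpolated warp) or "mask" (binary propagation).
#' @param ... unused.
#' @return The warped object on the fixed grid.
#' @export
predict.dir_fit <- function(object, newdata = NULL,
                            type = c("image", "mask"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) return(object$warped)
  if (inherits(newdata, "structure_set")) {
    masks <- lapply(newdata$masks, propagate_mask, dvf = object$dvf,
                    grid = newdata$grid)
    return(structure_set(masks, object$dvf$grid))
  }
  if (is.array(newdata) && type == "mask")
    return(propagate_mask(newdata, object$dvf, grid = object$moving$grid))
  if (inherits(newdata, "image_volume")) {
    if (type == "mask")
      return(propagate_mask(newdata$values > 0.5, object$dvf,
                            grid = newdata$grid))
    return(warp_image(newdata, object$dvf, background = object$background))
  }
  stop("unsupported newdata")
}

#' @export
residuals.dir_fit <- function(object, ...) {
  object$fixed$values - object$warped$values
}

#' Mid-slice comparison plot of a registration fit
#'
#' @param x a \code{dir_fit}.
#' @param slice axial slice index (default: middle).
#' @param ... passed to \code{graphics::image}.
#' @export
plot.dir_fit <- function(x, slice = NULL, ...) {
  k <- if (is.null(slice)) ceiling(x$fixed$grid$shape[3] / 2) else slice
  op <- graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  gr <- grDevices::gray.colors(128)
  graphics::image(x$fixed$values[, , k], col = gr, axes = FALSE,
                  main = "fixed", ...)
  graphics::image(x$warped$values[, , k], col = gr, axes = FALSE,
                  main = sprintf("warped (%s)", x$method), ...)
  graphics::image(x$fixed$values[, , k] - x$warped$values[, , k],
                  col = grDevices::hcl.colors(128, "Blue-Red"), axes = FALSE,
                  main = "residual", ...)
  invisible(x)
}
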