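#' Mean and SD over a region of interest
#'
#' @param image an \code{\link{image_volume}} (or bare array).
#' @param mask logical mask, non-empty.
#' @return Named vector \code{c(mean, sd)} (sample SD, n - 1).
#' @export
roi_stats <- function(image, mask) {
  vals <- if (inherits(image, "image_volume")) image$values else image
  if (!any(mask)) stop("empty ROI mask")
  v <- vals[mask]
  c(mean = mean(v), sd = stats::sd(v))
}

#' Signal-to-noise ratio of a region
#'
#' mean/SD over the ROI. A zero SD yields \code{Inf} with a warning.
#'
#' @inheritParams roi_stats
#' @return Unitless SNR.
#' @export
snr <- function(image, mask) {
  s <- roi_stats(image, mask)
  if (s["sd"] == 0) {
    warning("zero SD in ROI; SNR is infinite")
    return(Inf)
  }
  unname(s["mean"] / s["sd"])
}

#' Contrast-to-noise ratio between an insert and background
#'
#' \code{(mean_roi - mean_bg) / sd_bg}.
#'
#' @param image an \code{\link{image_volume}}.
#' @param mask insert ROI.
#' @param background_mask background ROI.
#' @return Unitless CNR.
#' @export
cnr <- function(image, mask, background_mask) {
  s <- roi_stats(image, mask)
  b <- roi_stats(image, background_mask)
  if (b["sd"] == 0) {
    warning("zero SD in background ROI; CNR is infinite")
    return(Inf)
  }
  unname((s["mean"] - b["mean"]) / b["sd"])
}

#' Uniformity index (percent)
#'
#' Largest relative deviation of the peripheral ROI means from the central
#' ROI mean: \code{max_i |mean_i - mean_c| / |mean_c| * 100}.
#'
#' @param image an \code{\link{image_volume}}.
#' @param center_mask central ROI.
#' @param peripheral_masks list of peripheral ROIs.
#' @return Percent uniformity deviation (0 for a perfectly flat image).
#' @export
uniformity <- function(image, center_mask, peripheral_masks) {
  mc <- roi_stats(image, center_mask)["mean"]
  devs <- vapply(peripheral_masks,
                 function(m) abs(roi_stats(image, m)["mean"] - mc), 0)
  unname(max(devs) / abs(mc) * 100)
}

#' Paired intensity errors between a test and a reference volume
#'
#' ME = mean(test - ref); MAE = mean |test - ref|; PSNR =
#' \code{20 log10(data_range / RMSE)} in dB, with the data range defaulting
#' to the reference max - min within the mask. Identical volumes are
#' reported with infinite PSNR.
#'
#' @param reference,test \code{\link{image_volume}} objects on one grid.
#' @param mask optional logical evaluation mask (default: whole volume).
#' @param data_range fixed data range for PSNR; NULL = reference range.
#' @return Named vector \code{c(mae, me, psnr)}.
#' @export
paired_errors <- function(reference, test, mask = NULL, data_range = NULL) {
  if (!grid_equal(reference$grid, test$grid))
    stop("volumes are on different grids")
  if (is.null(mask)) mask <- array(TRUE, reference$grid$shape)
  r <- reference$values[mask]
  t <- test$values[mask]
  d <- t - r
  rmse <- sqrt(mean(d^2))
  rng <- if (is.null(data_range)) diff(range(r)) else data_range
  psnr <- if (rmse == 0) Inf else 20 * log10(rng / rmse)
  c(mae = mean(abs(d)), me = mean(d), psnr = psnr)
}

#' Structural similarity index (3-D, Gaussian windows)
#'
#' Standard local-window SSIM with Gaussian weighting, averaged over the
#' mask; constants \code{k1 = 0.01}, \code{k2 = 0.03} applied to the data
#' range.
#'
#' @param reference,test \code{\link{image_volume}} objects on one grid.
#' @param window_sigma Gaussian window sigma in voxels.
#' @param k1,k2 stabilisation constants.
#' @param mask optional evaluation mask.
#' @param data_range dynamic range L; NULL = reference max - min.
#' @return Mean SSIM in [-1, 1].
#' @export
ssim <- function(reference, test, window_sigma = 1.5, k1 = 0.01, k2 = 0.03,
                 mask = NULL, data_range = NULL) {
  if (!grid_equal(reference$grid, test$grid))
    stop("volumes are on different grids")
  g <- reference$grid
  if (any(ceiling(3.5 * window_sigma) * 2 + 1 > 2 * g$shape))
    stop("SSIM window larger than the volume")
  L <- if (is.null(data_range)) diff(range(reference$values)) else data_range
  if (L == 0) L <- 1
  c1 <- (k1 * L)^2
  c2 <- (k2 * L)^2
  sw <- rep(window_sigma, 3)
  sm <- function(a) array(cpp_gauss3(as.numeric(a), g$shape, sw), g$shape)
  x <- reference$values
  y <- test$values
  mx <- sm(x)
  my <- sm(y)
  vx <- sm(x * x) - mx^2
  vy <- sm(y * y) - my^2
  cxy <- sm(x * y) - mx * my
  map <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  if (is.null(mask)) mean(map) else mean(map[mask])
}

#' Identity-function profile (IFP)
#'
#' Bins the reference intensities and records the mean test intensity per
#' bin; an ideal deformed image reproduces the reference CT numbers so the
#' curve follows the identity line. The deviation score is the RMS of
#' (per-bin mean test - per-bin mean reference) over occupied bins.
#'
#' @param reference,test \code{\link{image_volume}} objects on one grid.
#' @param bins number of equal-width reference-intensity bins.
#' @param mask optional evaluation mask, non-empty.
#' @return An object of class \code{ifp_curve}: data.frame of
#'   \code{bin_center}, \code{mean_reference}, \code{mean_test},
#'   \code{count}, plus a \code{score} attribute.
#' @export
ifp <- function(reference, test, bins = 64, mask = NULL) {
  if (!grid_equal(reference$grid, test$grid))
    stop("volumes are on different grids")
  if (is.null(mask)) mask <- array(TRUE, reference$grid$shape)
  if (!any(mask)) stop("empty evaluation mask")
  r <- reference$values[mask]
  t <- test$values[mask]
  edges <- seq(min(r), max(r), length.out = bins + 1)
  edges[length(edges)] <- edges[length(edges)] + 1e-9
  idx <- findInterval(r, edges, rightmost.closed = TRUE)
  idx[idx > bins] <- bins
  cnt <- tabulate(idx, bins)
  if (sum(cnt > 0) < 2) stop("fewer than 2 occupied intensity bins")
  mr <- vapply(seq_len(bins), function(b) if (cnt[b]) mean(r[idx == b]) else NA_real_, 0)
  mt <- vapply(seq_len(bins), function(b) if (cnt[b]) mean(t[idx == b]) else NA_real_, 0)
  occ <- cnt > 0
  curve <- data.frame(bin_center = (edges[-length(edges)] + edges[-1]) / 2,
                      mean_reference = mr, mean_test = mt, count = cnt)
  structure(curve, score = sqrt(mean((mt[occ] - mr[occ])^2)),
            class = c("ifp_curve", "data.frame"))
}

#' @export
print.ifp_curve <- function(x, ...) {
  cat(sprintf("identity-function profile: %d occupied bins, deviation score %.4g\n",
              sum(x$count > 0), attr(x, "score")))
  invisible(x)
}

#' Plot an identity-function profile
#' @param x an \code{ifp_curve}.
#' @param ... passed to \code{plot}.
#' @export
plot.ifp_curve <- function(x, ...) {
  occ <- x$count > 0
  plot(x$mean_reference[occ], x$mean_test[occ], xlab = "reference intensity",
       ylab = "mean deformed intensity", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Combined image-quality report
#'
#' @param reference,test \code{\link{image_volume}} objects on one grid.
#' @param mask optional evaluation mask.
#' @param bins IFP bins.
#' @return A list with \code{mae}, \code{me}, \code{psnr}, \code{ssim} and
#'   the IFP deviation \code{ifp_score}.
#' @export
quality_report <- function(reference, test, mask = NULL, bins = 64) {
  pe <- paired_errors(reference, test, mask)
  list(mae = unname(pe["mae"]), me = unname(pe["me"]),
       psnr = unname(pe["psnr"]),
       ssim = ssim(reference, test, mask = mask),
       ifp_score = attr(ifp(reference, test, bins, mask), "score"))
}
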