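# Independent brute-force oracles used to validate the fast implementations.

# exhaustive all-pairs HD95: full distance matrix + interpolated percentiles
oracle_hd95 <- function(a, b, spacing) {
  pa <- which(surface_voxels(a), arr.ind = TRUE)
  pb <- which(surface_voxels(b), arr.ind = TRUE)
  pa <- sweep(pa - 1, 2, spacing, "*")
  pb <- sweep(pb - 1, 2, spacing, "*")
  D <- sqrt(outer(rowSums(pa^2), rep(1, nrow(pb))) +
              outer(rep(1, nrow(pa)), rowSums(pb^2)) -
              2 * pa %*% t(pb))
  D[D < 0 | is.na(D)] <- 0
  d_ab <- apply(D, 1, min)
  d_ba <- apply(D, 2, min)
  max(stats::quantile(d_ab, 0.95, names = FALSE, type = 7),
      stats::quantile(d_ba, 0.95, names = FALSE, type = 7))
}

# plain-R trilinear interpolation of a volume at world points (NA outside)
oracle_trilinear <- function(arr, spacing, origin, pts) {
  d <- dim(arr)
  x <- (pts[, 1] - origin[1]) / spacing[1]
  y <- (pts[, 2] - origin[2]) / spacing[2]
  z <- (pts[, 3] - origin[3]) / spacing[3]
  ok <- x >= 0 & y >= 0 & z >= 0 & x <= d[1] - 1 & y <= d[2] - 1 &
    z <= d[3] - 1
  out <- rep(NA_real_, nrow(pts))
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  x0 <- pmin(floor(x), d[1] - 2); x0[d[1] == 1] <- 0
  y0 <- pmin(floor(y), d[2] - 2); y0[d[2] == 1] <- 0
  z0 <- pmin(floor(z), d[3] - 2); z0[d[3] == 1] <- 0
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  at <- function(i, j, k) arr[cbind(i + 1, j + 1, k + 1)]
  x1 <- pmin(x0 + 1, d[1] - 1)
  y1 <- pmin(y0 + 1, d[2] - 1)
  z1 <- pmin(z0 + 1, d[3] - 1)
  v <- (1 - fz) * ((1 - fy) * ((1 - fx) * at(x0, y0, z0) + fx * at(x1, y0, z0)) +
                     fy * ((1 - fx) * at(x0, y1, z0) + fx * at(x1, y1, z0))) +
    fz * ((1 - fy) * ((1 - fx) * at(x0, y0, z1) + fx * at(x1, y0, z1)) +
            fy * ((1 - fx) * at(x0, y1, z1) + fx * at(x1, y1, z1)))
  out[ok] <- v
  out
}

# exhaustive gamma: loop over every candidate displacement (no pruning),
# vectorised over voxels, using the plain-R interpolator
oracle_gamma <- function(reference, evaluated, params) {
  rg <- reference$grid
  eg <- evaluated$grid
  rmax <- max(reference$dose)
  dd <- if (params$normalization == "global")
    rep(params$dose_diff_pct / 100 * rmax, length(reference$dose))
  else params$dose_diff_pct / 100 * as.numeric(reference$dose)
  thr <- params$low_dose_threshold_pct / 100 * rmax
  emask <- as.numeric(reference$dose) > thr & dd > 0
  s <- seq(-params$search_radius_mm, params$search_radius_mm,
           by = params$step_mm)
  off <- as.matrix(expand.grid(s, s, s))
  keep <- rowSums(off^2) <= params$search_radius_mm^2 + 1e-12
  off <- off[keep, , drop = FALSE]
  pts <- grid_points(rg)
  best <- rep(Inf, nrow(pts))
  refv <- as.numeric(reference$dose)
  for (i in seq_len(nrow(off))) {
    de <- oracle_trilinear(evaluated$dose, eg$spacing, eg$origin,
                           sweep(pts, 2, off[i, ], "+"))
    g2 <- (de - refv)^2 / dd^2 + sum(off[i, ]^2) / params$dta_mm^2
    g2[is.na(g2)] <- Inf
    best <- pmin(best, g2)
  }
  g <- sqrt(best)
  g[!emask] <- NA
  dim(g) <- rg$shape
  g
}

# tensor-product cubic B-spline evaluated directly in R at world points
oracle_ffd <- function(coef, cdim, cspacing, corigin, pts) {
  b3 <- function(t) {
    w <- matrix(0, length(t), 4)
    w[, 1] <- (1 - t)^3 / 6
    w[, 2] <- (3 * t^3 - 6 * t^2 + 4) / 6
    w[, 3] <- (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6
    w[, 4] <- t^3 / 6
    w
  }
  nc <- prod(cdim)
  out <- matrix(0, nrow(pts), 3)
  for (r in seq_len(nrow(pts))) {
    tloc <- (pts[r, ] - corigin) / cspacing
    i0 <- pmin(pmax(floor(tloc), 1), cdim - 3)
    wx <- b3(tloc[1] - i0[1])[1, ]
    wy <- b3(tloc[2] - i0[2])[1, ]
    wz <- b3(tloc[3] - i0[3])[1, ]
    for (cmp in 1:3) {
      s <- 0
      for (c in 0:3) for (b in 0:3) for (a in 0:3) {
        l <- (i0[1] - 1 + a) + cdim[1] * (i0[2] - 1 + b) +
          cdim[1] * cdim[2] * (i0[3] - 1 + c) + 1
        s <- s + wx[a + 1] * wy[b + 1] * wz[c + 1] * coef[(cmp - 1) * nc + l]
      }
      out[r, cmp] <- s
    }
  }
  out
}
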