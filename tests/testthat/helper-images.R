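# Shared fixtures built in code. Heavy phantom computations are memoised in
# this environment so several test files can reuse one run.
.fixtures <- new.env(parent = emptyenv())

# smooth random texture volume (mean 1000) on a given grid
textured_volume <- function(shape = c(32, 32, 16), spacing = c(1, 1, 2),
                            sd_amp = 200, sigma_vox = c(3, 3, 1.5),
                            seed = 7) {
  g <- grid_geometry(shape, spacing)
  set.seed(seed)
  tex <- array(stats::rnorm(prod(shape)), shape)
  tex <- array(cbctdir:::cpp_gauss3(as.numeric(tex), shape, sigma_vox), shape)
  image_volume(1000 + tex / stats::sd(tex) * sd_amp, grid = g)
}

# uniform-translation copy of a volume (pull convention: recovering DVF
# should equal -shift_mm)
translated_volume <- function(vol, shift_mm, background = 1000) {
  d <- zero_dvf(vol$grid)
  for (c in 1:3) d$vectors[, , , c] <- shift_mm[c]
  warp_image(vol, d, background = background)
}

# the default-condition pelvis experiment: phantom + degradation + gas fill,
# registered with two-step and plain IOF; memoised
default_pelvis_run <- function() {
  if (!is.null(.fixtures$pelvis_run)) return(.fixtures$pelvis_run)
  ph <- make_pelvis_phantom(pelvis_phantom_config(seed = 17L))
  cbct <- degrade_to_cbct(ph$day_image, cbct_degradation_config(seed = 18L),
                          body = ph$day_structures$masks$body)
  gas <- detect_gas_pockets(cbct, body = ph$day_structures$masks$body)
  cbct_filled <- fill_gas_pockets(cbct, gas)$output
  ts <- two_step_register(ph$pct, cbct_filled, ph$structures,
                          ph$day_structures)
  iof <- iof_register(cbct_filled, ph$pct)
  organs <- c("bladder", "rectum", "target")
  eval_dvf <- function(dvf) {
    prop <- lapply(ph$structures$masks[organs], propagate_mask, dvf = dvf,
                   grid = ph$grid)
    sapply(organs, function(nm) c(
      dsc = dice(ph$day_structures$masks[[nm]], prop[[nm]]),
      hd95 = hd95(ph$day_structures$masks[[nm]], prop[[nm]],
                  ph$grid$spacing)))
  }
  d <- ts$dvf$vectors - ph$truth_dvf$vectors
  epe <- sqrt(d[, , , 1]^2 + d[, , , 2]^2 + d[, , , 3]^2)
  .fixtures$pelvis_run <- list(
    phantom = ph, cbct = cbct, cbct_filled = cbct_filled,
    twostep = ts, iof_dvf = iof,
    metrics_twostep = eval_dvf(ts$dvf), metrics_iof = eval_dvf(iof),
    mean_epe_body = mean(epe[ph$day_structures$masks$body]))
  .fixtures$pelvis_run
}
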