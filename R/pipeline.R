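#' Default pipeline configuration
#'
#' The run configuration drives \code{\link{run_pipeline}}: phantom
#' generation (or input paths), preprocessing constants, registration
#' method and schedule, and evaluation settings. Unknown keys are rejected
#' so typos fail loudly.
#'
#' @param method registration method for the main run.
#' @param seed master seed for phantom generation and degradation.
#' @param out_dir output directory for reports and volumes.
#' @return A list of class \code{run_config}.
#' @export
default_run_config <- function(method = "twostep", seed = 17L,
                               out_dir = tempfile("cbctdir_run_")) {
  structure(list(
    version = 1L,
    seed = as.integer(seed),
    out_dir = out_dir,
    method = method,
    inputs = list(pct = NULL, cbct = NULL, pct_structures = NULL,
                  cbct_structures = NULL),
    phantom = list(enabled = TRUE),
    degradation = list(noise_sd = 40, cupping_amplitude = 60,
                       scatter_offset = 30),
    preprocess = list(gas_threshold = 800, gas_fill = 1060,
                      gas_sigma_mm = 2, gas_dilation_vox = 2),
    override = list(bladder = 800, target = 1200, rectum = 800,
                    subcutaneous_fat = 1200),
    schedule = list(stages = list(list(scale = 1L, iterations = 5L, passes = 10L),
                                  list(scale = 2L, iterations = 30L, passes = 50L)),
                    dvf_sigma_mm = 1, multigrid_cycles = 2L,
                    listed_order = FALSE),
    evaluation = list(gamma_dd_pct = 3, gamma_dta_mm = 3,
                      prescription_gy = 70, penumbra_mm = 5,
                      dvh_metrics = c("D98", "D2", "Dmean", "Dmax", "V50",
                                      "V60", "V65", "V70", "V75"))),
    class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys overlay the defaults of
#'   \code{\link{default_run_config}}. Unknown keys are an error.
#' @return A \code{run_config} list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_run_config()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]])) {
      bad <- setdiff(names(user[[k]]), names(base[[k]]))
      if (length(bad))
        stop("unknown config key(s) under '", k, "': ",
             paste(bad, collapse = ", "))
      base[[k]][names(user[[k]])] <- user[[k]]
    } else base[[k]] <- user[[k]]
  }
  class(base) <- "run_config"
  base
}

#' Run the full registration and evaluation pipeline
#'
#' Generates (or loads) the planning CT, treatment-day CBCT and structure
#' sets, gas-fills the CBCT, runs the configured registration method,
#' propagates the planning structures, and writes geometry, image-quality
#' and dose reports plus the deformed CT and DVF to the output directory.
#' Deterministic for a fixed config and seed.
#'
#' @param config a \code{run_config} (or path to a YAML file).
#' @param write_volumes also write NIfTI volumes (deformed CT, DVF).
#' @return The report bundle, invisibly: a list with \code{geometry},
#'   \code{quality}, \code{dose}, \code{fit} and output paths.
#' @export
run_pipeline <- function(config = default_run_config(), write_volumes = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (isTRUE(config$phantom$enabled)) {
    ph <- make_pelvis_phantom(pelvis_phantom_config(seed = config$seed))
    deg <- cbct_degradation_config(
      noise_sd = config$degradation$noise_sd,
      cupping_amplitude = config$degradation$cupping_amplitude,
      scatter_offset = config$degradation$scatter_offset,
      seed = config$seed + 1L)
    cbct <- degrade_to_cbct(ph$day_image, deg,
                            body = ph$day_structures$masks$body)
    pct <- ph$pct
    pct_structs <- ph$structures
    cbct_structs <- ph$day_structures
    truth_structs <- ph$day_structures
    reference_image <- ph$day_image
  } else {
    inp <- config$inputs
    if (any(vapply(inp[c("pct", "cbct", "pct_structures",
                         "cbct_structures")], is.null, TRUE)))
      stop("config error: phantom disabled but input paths missing")
    pct <- read_volume(inp$pct, modality = "pCT")
    cbct <- read_volume(inp$cbct, modality = "kVCBCT")
    pct_structs <- read_structures(inp$pct_structures, pct$grid)
    cbct_structs <- read_structures(inp$cbct_structures, cbct$grid)
    truth_structs <- cbct_structs
    reference_image <- NULL
  }

  pp <- config$preprocess
  gas <- detect_gas_pockets(cbct, pp$gas_threshold,
                            body = cbct_structs$masks$body)
  cbct_filled <- if (any(gas)) {
    fill_gas_pockets(cbct, gas, fill = pp$gas_fill,
                     dilation_vox = pp$gas_dilation_vox,
                     sigma_mm = pp$gas_sigma_mm)$output
  } else cbct

  ov <- override_spec(unlist(config$override))
  sch <- registration_schedule(config$schedule$stages,
                               config$schedule$dvf_sigma_mm,
                               config$schedule$multigrid_cycles,
                               config$schedule$listed_order)
  fit <- dir_register(cbct_filled, pct, method = config$method,
                      fixed_structures = cbct_structs,
                      moving_structures = pct_structs,
                      schedule = sch, override = ov)
  prop <- predict(fit, pct_structs)

  geo <- geometry_report(truth_structs, prop,
                         structures = intersect(
                           c("bladder", "rectum", "target"),
                           names(truth_structs$masks)))
  qual <- if (!is.null(reference_image))
    quality_report(reference_image, fit$warped,
                   mask = truth_structs$masks$body) else NULL

  dose <- NULL
  if (!is.null(truth_structs$masks$target)) {
    ev <- config$evaluation
    ref_dose <- make_synthetic_dose(cbct$grid, truth_structs$masks$target,
                                    ev$prescription_gy, ev$penumbra_mm)
    test_dose <- make_synthetic_dose(cbct$grid, prop$masks$target,
                                     ev$prescription_gy, ev$penumbra_mm)
    gm <- gamma_map(ref_dose, test_dose,
                    gamma_params(ev$gamma_dd_pct, ev$gamma_dta_mm))
    dmet <- vapply(ev$dvh_metrics, function(s)
      dvh_metric(test_dose, prop$masks$target, s), 0)
    dref <- vapply(ev$dvh_metrics, function(s)
      dvh_metric(ref_dose, truth_structs$masks$target, s), 0)
    dose <- list(gamma_pass_rate = gm$pass_rate,
                 dvh_test = dmet, dvh_reference = dref)
  }

  paths <- list(
    geometry = file.path(config$out_dir, "geometry_report.csv"),
    report = file.path(config$out_dir, "report.json"),
    log = file.path(config$out_dir, "run_log.csv"),
    config = file.path(config$out_dir, "config.yaml"))
  utils::write.csv(geo, paths$geometry, row.names = FALSE)
  if (!is.null(fit$log)) utils::write.csv(fit$log, paths$log, row.names = FALSE)
  cfg_out <- config
  class(cfg_out) <- NULL
  yaml::write_yaml(cfg_out, paths$config)
  report <- list(method = config$method, seed = config$seed,
                 geometry = geo,
                 geometry_aggregate = as.list(attr(geo, "aggregate")),
                 quality = qual, dose = dose,
                 ssd_initial = fit$ssd_initial, ssd_final = fit$ssd_final)
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  if (write_volumes) {
    paths$dct <- file.path(config$out_dir, "dct.nii.gz")
    paths$dvf <- file.path(config$out_dir, "dvf.nii.gz")
    paths$structures <- file.path(config$out_dir, "propagated_structures.json")
    write_volume(fit$warped, paths$dct)
    write_volume(fit$dvf, paths$dvf)
    write_structures(prop, paths$structures)
  }
  invisible(c(report, list(fit = fit, paths = paths)))
}
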