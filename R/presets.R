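#' Load a shipped scan preset
#'
#' Presets encode each figure-style protocol's parameters as YAML under
#' `inst/presets` (`fig1` ... `fig6`, `s1`). Grid shorthand
#' `{from, to, by}` is expanded to a numeric sequence.
#'
#' @param name preset name (e.g. `"fig3"`) or a path to a YAML file
#' @return named list of scan parameters
#' @export
load_preset <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("presets", paste0(name, ".yaml"), package = "burstlab")
  if (!nzchar(path) || !file.exists(path)) stop("unknown preset: ", name)
  p <- yaml::read_yaml(path)
  expand <- function(x) {
    if (is.list(x) && all(c("from", "to", "by") %in% names(x)))
      seq(x$from, x$to, by = x$by)
    else x
  }
  lapply(p, expand)
}

#' Run a preset scan end to end
#'
#' Builds the calibrated model, dispatches on the preset's `experiment`
#' field, and optionally writes the result tables as CSV plus a JSON run
#' manifest (preset, seed, package version).
#'
#' @param preset preset name or path (see [load_preset()])
#' @param seed master seed
#' @param reps override the preset's repetitions per cell
#' @param out_dir optional output directory for CSV tables + manifest
#' @param model optional pre-built `neuron_model`
#' @return the scan result (invisibly when writing to `out_dir`)
#' @export
run_preset <- function(preset, seed = 1, reps = NULL, out_dir = NULL,
                       model = NULL) {
  p <- load_preset(preset)
  if (!is.null(reps)) p$reps <- reps
  model <- model %||% attach_biophysics(discretize(build_reduced_l5pc()))
  res <- switch(p$experiment,
    sigma_dt = scan_sigma_dt(model, sigmas = p$sigmas, dt_grid = p$dt_grid,
                             n_basal = p$n_basal, n_tuft = p$n_tuft,
                             reps = p$reps, seed = seed),
    synapse_grid = scan_synapse_grid(model, n_basal_grid = p$n_basal_grid,
                                     n_tuft_grid = p$n_tuft_grid,
                                     sigma = p$sigma, dt = p$dt,
                                     reps = p$reps, seed = seed),
    inhibition = {
      locs <- if (!is.null(p$strips)) p$strips else p$locations
      scan_inhibition(model, locations = locs,
                      dt_inh_grid = p$dt_inh_grid, n_basal = p$n_basal,
                      n_tuft = p$n_tuft, single_branch = p$single_branch,
                      sigma = p$sigma, reps = p$reps, n_inh = p$n_inh,
                      seed = seed)
    },
    spatial_extent = {
      list(tuft = scan_spatial_extent(model, "tuft_excitation",
                                      fractions = p$fractions,
                                      n_basal = p$n_basal, n_tuft = p$n_tuft,
                                      sigma = p$sigma, reps = p$reps,
                                      seed = seed),
           inhibition = scan_spatial_extent(model, "inhibition",
                                            fractions = p$fractions,
                                            n_basal = p$n_basal,
                                            n_tuft = p$n_tuft,
                                            sigma = p$sigma, reps = p$reps,
                                            seed = seed))
    },
    plasticity = {
      pp <- plasticity_params(theta_p = p$theta_p %||% 0.4,
                              theta_d = p$theta_d %||% 0.25,
                              repetitions = p$repetitions %||% 10)
      lapply(p$loci, function(l)
        run_plasticity_protocol(model, locus = l,
                                dt_inh_grid = p$dt_inh_grid,
                                n_basal = p$n_basal, n_tuft = p$n_tuft,
                                sigma = p$sigma, p = pp, seed = seed))
    },
    traces = {
      m <- model$cable$morphology
      lapply(p$sigmas, function(sg) {
        pat <- sample_excitatory(m, p$n_basal, p$n_tuft, sigma = sg,
                                 dt = p$dt, tuft_stretch = p$tuft_stretch,
                                 seed = seed)
        simulate(model, pat, simulation_config())
      })
    },
    stop("unknown experiment kind: ", p$experiment))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(preset = preset, seed = seed,
                     parameters = p,
                     package_version =
                       as.character(utils::packageVersion("burstlab")),
                     timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    flat <- if (is.data.frame(res)) list(result = res)
            else Filter(is.data.frame, res)
    for (nm in names(flat))
      utils::write.csv(flat[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    return(invisible(res))
  }
  res
}
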