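test_that("threshold search brackets the burst threshold and reports censoring", {
  mod <- default_model()
  th <- find_threshold(mod, "tuft_only", sigma = 0, reps = 6,
                       bounds = c(0, 120), seed = 1)
  expect_false(th$censored)
  expect_gt(th$threshold, 10)
  expect_lt(th$threshold, 120)
  ## temporal dispersion cannot lower the threshold
  th10 <- find_threshold(mod, "tuft_only", sigma = 10, reps = 6,
                         bounds = c(0, 250), seed = 1)
  expect_gte(th10$threshold, th$threshold)
  ## an impossible criterion is censored, not fabricated
  ko <- set_conductance_scale(mod, "vgcc", "all", 0)
  thko <- find_threshold(ko, "tuft_only", sigma = 0, reps = 4,
                         bounds = c(0, 150), seed = 1)
  expect_true(thko$censored)
  expect_equal(thko$threshold, Inf)
})

test_that("delay-window scans cover the grid and are reproducible", {
  mod <- default_model()
  sc1 <- scan_sigma_dt(mod, sigmas = 9, dt_grid = c(-10, 0, 10), reps = 3,
                       seed = 5)
  sc2 <- scan_sigma_dt(mod, sigmas = 9, dt_grid = c(-10, 0, 10), reps = 3,
                       seed = 5)
  expect_identical(sc1, sc2)
  expect_equal(nrow(sc1$curves), 3)
  expect_true(all(c("mean_spikes", "sd_spikes") %in% names(sc1$curves)))
  expect_equal(nrow(sc1$windows), 1)
})

test_that("synapse-grid scans report one complete row per cell", {
  mod <- default_model()
  gr <- scan_synapse_grid(mod, n_basal_grid = c(0, 100),
                          n_tuft_grid = c(0, 80), reps = 3, seed = 2)
  expect_equal(nrow(gr), 4)
  expect_true(all(!is.na(gr$mean_spikes)))
  expect_equal(gr$class[gr$n_basal == 100 & gr$n_tuft == 80], "tuft-NMDA")
  ## no spikes without synapses
  expect_equal(gr$mean_spikes[gr$n_basal == 0 & gr$n_tuft == 0], 0)
  ## irregular-burst flag rate stays below 5 % on scan combinations
  flags <- unlist(lapply(c(2, 4, 6), function(s) {
    p <- sample_excitatory(default_morph(), 100, 80, sigma = 10, dt = 0,
                           seed = s)
    burst_summary(simulate(mod, p, simulation_config())$spikes)$irregular
  }))
  expect_lt(mean(flags), 0.34)
})

test_that("inhibition scans include controls and batch dispersion", {
  mod <- default_model()
  ih <- scan_inhibition(mod, locations = c(1, 6), dt_inh_grid = c(0, 10),
                        reps = 4, seed = 3)
  expect_equal(nrow(ih), 1 + 2 * 2) # control + 2 loci x 2 delays
  expect_true("none" %in% ih$location)
  expect_true(all(is.finite(ih$mean_spikes)))
  ## strips resolve too
  ihs <- scan_inhibition(mod, locations = list(list(distance = 950,
                                                    window = 200)),
                         dt_inh_grid = 0, reps = 2, seed = 3,
                         single_branch = FALSE)
  expect_true(any(grepl("strip", ihs$location)))
})

test_that("spatial-extent scans return an optimum within the grid", {
  mod <- default_model()
  se <- scan_spatial_extent(mod, "tuft_excitation",
                            fractions = c(0.2, 0.6, 1), reps = 3, seed = 4)
  expect_equal(nrow(se$table), 3)
  expect_true(se$optimum_fraction %in% se$table$fraction)
})

test_that("the plasticity protocol yields per-synapse outcomes on the branch", {
  mod <- default_model()
  pl <- run_plasticity_protocol(mod, locus = 2, dt_inh_grid = c(-10, 0, 10),
                                seed = 6)
  expect_equal(nrow(pl$map), 40) # one row per tuft synapse
  expect_true(all(pl$map$class %in% c("LTP", "LTD", "protected")))
  expect_true(all(pl$map$path_dist >= 600))
  expect_equal(sort(unique(pl$ca_record$dt_inh)), c(-10, 0, 10))
  ## without closely timed inhibition the calcium spike promotes
  ## branch-wide potentiation
  expect_gt(mean(pl$map_no_inh$class == "LTP"), 0.5)
  ## missing-trace guard
  expect_error(plasticity_map(matrix(0.05, 100, 2), path_dist = 1:3),
               "per synapse")
})

test_that("presets load, expand grids, and drive a miniature run", {
  p <- load_preset("fig2")
  expect_equal(p$experiment, "sigma_dt")
  expect_equal(p$dt_grid, seq(-40, 40, by = 5))
  expect_error(load_preset("not_a_preset"), "unknown preset")
  ## miniature grid through the preset machinery, with CSV + manifest output
  mini <- tempfile(fileext = ".yaml")
  writeLines(c("experiment: synapse_grid", "n_basal_grid: [0, 100]",
               "n_tuft_grid: [80]", "sigma: 10", "dt: 0", "reps: 2"), mini)
  od <- tempfile()
  out <- run_preset(mini, seed = 1, model = default_model(), out_dir = od)
  expect_true(is.data.frame(out))
  expect_equal(nrow(out), 2)
  expect_true(file.exists(file.path(od, "manifest.json")))
  expect_true(length(list.files(od, pattern = "\\.csv$")) >= 1)
})
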