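test_that("gate relaxation matches the closed-form exponential", {
  vhalf <- -40; k <- 6; tau <- c(3, 5, -50, 20)
  v <- -55
  dt <- 0.025
  n <- 400
  x <- 0.1
  for (i in seq_len(n)) x <- gate_update(x, v, vhalf, k, tau, dt)
  xinf <- gate_inf(v, vhalf, k)
  closed <- xinf + (0.1 - xinf) * exp(-n * dt / gate_tau(v, tau))
  expect_lt(abs(x - closed), 1e-10)
  ## fixed point and large-step limit stay in [0, 1]
  expect_equal(gate_update(xinf, v, vhalf, k, tau, dt), xinf)
  expect_equal(gate_update(0, v, vhalf, k, tau, 1e6), xinf, tolerance = 1e-12)
})

test_that("the implicit solver reproduces passive cable attenuation", {
  ## sealed cable of one length constant: V(L)/V(0) = 1/cosh(1) = 0.6481
  g_pas <- 1e-4; ra <- 100; diam <- 2
  lambda <- sqrt((1 / g_pas) * (diam * 1e-4) / (4 * ra)) * 1e4 # um
  mod <- passive_cable_model(n_comp = 50, length_um = lambda, diam = diam,
                             g_pas = g_pas, ra = ra)
  cp <- mod$cable$comp
  on_cable <- cp$region %in% c("trunk", "hotspot")
  tip <- which(on_cable)[which.max(cp$path_dist[on_cable])]
  r <- simulate(mod, NULL,
                simulation_config(duration = 150, v_init = -70,
                                  probes = c(1L, tip)),
                iclamp = data.frame(site = 1L, start = 20, dur = 1e4,
                                    amp = 0.05))
  v0 <- unname(tail(r$v[, "soma"], 1) - r$v[1, "soma"])
  vL <- unname(tail(r$v[, 2], 1) - r$v[1, 2])
  x_tip <- cp$path_dist[tip]
  expected <- cosh((lambda - x_tip) / lambda) / cosh(1)
  expect_equal(vL / v0, expected, tolerance = 0.01)
  expect_equal(vL / v0, 0.6481, tolerance = 0.015)
})

test_that("an isopotential passive compartment charges with tau = Rm * Cm", {
  mod <- passive_cable_model(n_comp = 2, length_um = 30, diam = 2,
                             g_pas = 1e-4, cm = 1) # tau = 10 ms
  r <- simulate(mod, NULL, simulation_config(duration = 120, v_init = -70),
                iclamp = data.frame(site = 1L, start = 20, dur = 1e4,
                                    amp = 0.02))
  i <- r$time >= 20 & r$time <= 60
  v <- r$v[i, "soma"] - r$v[1, "soma"]
  vinf <- tail(r$v[, "soma"], 1) - r$v[1, "soma"]
  y <- vinf - v
  keep <- y > 0.02 * vinf
  fit <- stats::lm(log(y[keep]) ~ r$time[i][keep])
  expect_equal(-1 / coef(fit)[[2]], 10, tolerance = 0.03)
})

test_that("the calibrated model rests quietly at its equilibrium", {
  r <- simulate(default_model(), NULL, simulation_config(duration = 1500))
  late <- r$time >= 900
  expect_lt(diff(range(r$v[late, "soma"])), 0.5)
  expect_length(detect_spikes(r$v[, "soma"], r$time), 0)
  ## resting potential near the initialization value
  expect_lt(abs(tail(r$v[, "soma"], 1) - (-76)), 3)
})

test_that("simulation is deterministic and stable under dt doubling", {
  mod <- default_model()
  pat <- sample_excitatory(default_morph(), 50, 30, sigma = 0, dt = 0,
                           seed = 2)
  r1 <- simulate(mod, pat, simulation_config(duration = 400))
  r2 <- simulate(mod, pat, simulation_config(duration = 400))
  expect_identical(r1$spikes, r2$spikes)
  expect_identical(r1$v, r2$v)
  r3 <- simulate(mod, pat, simulation_config(duration = 400, dt = 0.05))
  expect_equal(length(r3$spikes), length(r1$spikes))
})

test_that("calcium relaxes to baseline with the configured time constant", {
  mod <- default_model()
  pat <- sample_excitatory(default_morph(), 50, 30, sigma = 0, dt = 0,
                           seed = 2)
  r <- simulate(mod, pat, simulation_config(duration = 600))
  i <- r$time >= 280 & r$time <= 480 # post-burst tail, VGCCs closed
  y <- r$ca[i, "nexus"] - mod$calcium$ca0
  expect_true(all(y > 0))
  fit <- stats::lm(log(y) ~ r$time[i])
  expect_equal(-1 / coef(fit)[[2]], mod$calcium$tau_ca,
               tolerance = 0.02)
  ## positivity throughout
  expect_true(all(r$ca >= 0))
})

test_that("conductance scaling is exact at factor 1 and validates inputs", {
  mod <- default_model()
  pat <- sample_excitatory(default_morph(), 30, 20, sigma = 5, dt = 0,
                           seed = 5)
  same <- set_conductance_scale(mod, "ca_hva", "hotspot", 1)
  cfg <- simulation_config(duration = 250)
  expect_identical(simulate(mod, pat, cfg)$v, simulate(same, pat, cfg)$v)
  expect_error(set_conductance_scale(mod, "not_a_channel", "soma", 0),
               "unknown channel")
  expect_error(set_conductance_scale(mod, "na_t", "nowhere", 0),
               "region")
  ## the vgcc alias reaches every calcium channel
  ko <- set_conductance_scale(mod, "vgcc", "all", 0)
  expect_true(all(ko$gbar$ca_hva == 0) && all(ko$gbar$ca_lva == 0))
})

test_that("events outside the simulated window are flagged", {
  mod <- default_model()
  pat <- sample_excitatory(default_morph(), 5, 0, sigma = 0, dt = 0,
                           t_ref = 500, seed = 1)
  expect_warning(simulate(mod, pat, simulation_config(duration = 300)),
                 "beyond the simulated duration")
  ## empty pattern: no spikes
  r <- simulate(mod, NULL, simulation_config(duration = 200))
  expect_length(r$spikes, 0)
})
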