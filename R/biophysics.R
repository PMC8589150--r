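#' Define an ion channel
#'
#' Hodgkin-Huxley-style channel with activation gate `m^p` (and optional
#' inactivation `h^q`), Boltzmann steady states
#' `x_inf(V) = 1/(1 + exp((vhalf - V)/k))` and constant-or-bell time
#' constants `tau(V) = tau_min + tau_amp * exp(-((V - v_peak)/v_sigma)^2)`.
#' Calcium-gated channels (`ca_gated = TRUE`) replace the activation steady
#' state with a Hill function of intracellular calcium. Kinetics are
#' pre-scaled to the reference temperature (34 C).
#'
#' @param name channel name
#' @param e_rev reversal potential (mV)
#' @param p,q activation / inactivation gate exponents (q = 0: no inactivation)
#' @param m_vhalf,m_k activation Boltzmann parameters (mV); `k < 0` gives a
#'   curve decreasing in V
#' @param m_tau activation tau: c(tau_min, tau_amp, v_peak, v_sigma) (ms, mV)
#' @param h_vhalf,h_k,h_tau inactivation gate parameters (when q > 0)
#' @param ca_gated gate driven by calcium instead of voltage
#' @param ca_half,ca_hill,z_tau calcium half-activation (uM), Hill
#'   coefficient and gate time constant (ms) for calcium-gated channels
#' @param is_ca channel current carries calcium (feeds the calcium pool)
#' @param density named per-region maximal conductance density (nS/um^2)
#' @param gradient optional function(path_dist, region) returning a density
#'   multiplier per compartment (e.g. a decaying sodium profile on the trunk)
#' @return a `channel_spec` list
#' @export
channel_spec <- function(name, e_rev, p = 1, q = 0,
                         m_vhalf = NA, m_k = NA, m_tau = c(1, 0, 0, 1),
                         h_vhalf = NA, h_k = NA, h_tau = c(1, 0, 0, 1),
                         ca_gated = FALSE, ca_half = 0.35, ca_hill = 4,
                         z_tau = 5, is_ca = FALSE, density = c(),
                         gradient = NULL) {
  if (!ca_gated) {
    stopifnot(is.finite(m_vhalf), m_k != 0, m_tau[1] > 0)
    if (q > 0) stopifnot(is.finite(h_vhalf), h_k != 0, h_tau[1] > 0)
  }
  if (any(density < 0)) stop("densities must be >= 0")
  structure(list(name = name, e_rev = e_rev, p = as.integer(p),
                 q = as.integer(q), m_vhalf = m_vhalf, m_k = m_k,
                 m_tau = m_tau, h_vhalf = h_vhalf, h_k = h_k, h_tau = h_tau,
                 ca_gated = ca_gated, ca_half = ca_half, ca_hill = ca_hill,
                 z_tau = z_tau, is_ca = is_ca, density = density,
                 gradient = gradient),
            class = "channel_spec")
}

#' Gate steady state, time constant, and exact exponential update
#'
#' `gate_inf` and `gate_tau` evaluate the Boltzmann steady state and the
#' constant-or-bell time constant of a gate; [gate_update()] advances a gate
#' by the exact first-order relaxation
#' `x <- x_inf + (x - x_inf) * exp(-dt / tau)`, which stays in \[0, 1\] for
#' any dt.
#'
#' @param v membrane potential (mV)
#' @param vhalf,k Boltzmann parameters
#' @param tau tau parameters c(tau_min, tau_amp, v_peak, v_sigma)
#' @return steady state / time constant (ms)
#' @export
gate_inf <- function(v, vhalf, k) 1 / (1 + exp((vhalf - v) / k))

#' @rdname gate_inf
#' @export
gate_tau <- function(v, tau) {
  if (tau[2] <= 0) return(rep_len(tau[1], length(v)))
  tau[1] + tau[2] * exp(-((v - tau[3]) / tau[4])^2)
}

#' @rdname gate_inf
#' @param x current gate value in \[0, 1\]
#' @param dt time step (ms)
#' @export
gate_update <- function(x, v, vhalf, k, tau, dt) {
  stopifnot(all(x >= 0 & x <= 1))
  xi <- gate_inf(v, vhalf, k)
  xi + (x - xi) * exp(-dt / gate_tau(v, tau))
}

#' The calibrated reduced channel set
#'
#' A minimal complement supporting every phenomenon the scan protocols test:
#' transient sodium (soma-dominant, decaying along the apical trunk) for
#' somatic spikes and the backpropagating action potential; a fast somatic
#' delayed-rectifier potassium (carrying the 1.5x after-depolarization fix);
#' a slow muscarinic-type potassium for stabilization plus a slower somatic
#' adaptation conductance that limits repetitive firing; high- and low-voltage
#' -activated calcium channels concentrated in the apical hotspot (low
#' density elsewhere in the tuft); a calcium-activated potassium (Hill n = 4)
#' terminating spikes and bursts; and an optional h-current (density 0 by
#' default). Densities are the shipped calibration result (nS/um^2).
#'
#' @return named list of [channel_spec()]s
#' @export
default_channels <- function() {
  list(
    na_t = channel_spec(
      "na_t", e_rev = 50, p = 3, q = 1,
      m_vhalf = -38, m_k = 6, m_tau = c(0.1, 0, 0, 1),
      h_vhalf = -48, h_k = -6.5, h_tau = c(0.3, 2, -75, 18),
      density = c(soma = 70, trunk = 0.2, oblique = 0.3, basal = 0.3,
                  hotspot = 1.2, tuft = 1.2),
      gradient = function(path_dist, region)
        ifelse(region == "trunk", exp(-path_dist / 350), 1)),
    na_ax = channel_spec(
      "na_ax", e_rev = 50, p = 3, q = 1,
      m_vhalf = -49, m_k = 5, m_tau = c(0.08, 0, 0, 1),
      h_vhalf = -57, h_k = -3.5, h_tau = c(0.4, 2, -70, 15),
      density = c(axon = 250)),
    k_fast = channel_spec(
      "k_fast", e_rev = -85, p = 1, q = 0,
      m_vhalf = 0, m_k = 6, m_tau = c(0.6, 0, 0, 1),
      density = c(soma = 60, axon = 40, trunk = 0.4, hotspot = 0.6,
                  tuft = 0.3)),
    k_slow = channel_spec(
      "k_slow", e_rev = -85, p = 1, q = 0,
      m_vhalf = -30, m_k = 5, m_tau = c(20, 0, 0, 1),
      density = c(soma = 0.2, trunk = 0.1, hotspot = 0.8, tuft = 0.25,
                  axon = 2)),
    k_adapt = channel_spec(
      "k_adapt", e_rev = -85, p = 1, q = 0,
      m_vhalf = -50, m_k = 4, m_tau = c(70, 0, 0, 1),
      density = c(soma = 0.92)),
    ca_hva = channel_spec(
      "ca_hva", e_rev = 120, p = 2, q = 1, is_ca = TRUE,
      m_vhalf = -22, m_k = 6, m_tau = c(2, 0, 0, 1),
      h_vhalf = -50, h_k = -8, h_tau = c(80, 0, 0, 1),
      density = c(hotspot = 2.0, tuft = 0.3, trunk = 0.01, soma = 1.2,
                  basal = 0.005)),
    ca_lva = channel_spec(
      "ca_lva", e_rev = 120, p = 2, q = 1, is_ca = TRUE,
      m_vhalf = -43, m_k = 6, m_tau = c(5, 0, 0, 1),
      h_vhalf = -72, h_k = -5, h_tau = c(60, 0, 0, 1),
      density = c(hotspot = 0.25, tuft = 0.02, trunk = 0.01)),
    k_ca = channel_spec(
      "k_ca", e_rev = -85, p = 1, ca_gated = TRUE,
      ca_half = 0.5, ca_hill = 4, z_tau = 6,
      density = c(soma = 0.2, hotspot = 1.0, tuft = 0.05)),
    ih = channel_spec(
      "ih", e_rev = -45, p = 1, q = 0,
      m_vhalf = -90, m_k = -8, m_tau = c(50, 0, 0, 1),
      density = c())
  )
}

#' Passive membrane parameters
#'
#' @param cm_soma,cm_dend specific capacitance (uF/cm^2)
#' @param g_pas leak conductance density (S/cm^2)
#' @param e_pas leak reversal (mV)
#' @param ra axial resistivity (ohm cm)
#' @return list of passive parameters
#' @export
passive_params <- function(cm_soma = 1, cm_dend = 1.0, g_pas = 2.2e-5,
                           e_pas = -75.5, ra = 100) {
  as.list(environment())
}

#' Calcium pool parameters
#'
#' Single submembrane shell: `d[Ca]/dt = -gamma * I_Ca / (2 F depth area)
#' - ([Ca] - ca0) / tau_ca`, with `gamma` the fraction of calcium current
#' reaching the pool (the rest standing for fast endogenous buffering).
#'
#' @param ca0 resting concentration (uM)
#' @param tau_ca decay time constant (ms)
#' @param depth shell depth (um)
#' @param gamma unbuffered fraction of the calcium current
#' @param gamma_region optional named per-region multipliers on `gamma`
#'   (endogenous buffering differs between the perisomatic region and the
#'   apical dendrite)
#' @return list of calcium parameters
#' @export
calcium_params <- function(ca0 = 0.05, tau_ca = 80, depth = 0.1,
                           gamma = 3e-5, gamma_region = c(soma = 12, tuft = 4)) {
  as.list(environment())
}

#' Attach biophysics to a discretized cable
#'
#' Computes per-compartment capacitance, leak and axial conductances and
#' resolves channel densities (with optional spatial gradients) into
#' per-compartment maximal conductances.
#'
#' @param cable a `cable_model` from [discretize()]
#' @param channels list of [channel_spec()]s
#' @param passive [passive_params()]
#' @param calcium [calcium_params()]
#' @return a `neuron_model`
#' @export
attach_biophysics <- function(cable, channels = default_channels(),
                              passive = passive_params(),
                              calcium = calcium_params()) {
  cp <- cable$comp
  n <- nrow(cp)
  if (any(cp$parent[-1] >= seq_len(n)[-1]))
    stop("compartments are not Hines-ordered")
  cm <- ifelse(cp$region == "soma", passive$cm_soma, passive$cm_dend)
  c_m <- cm * cp$area * 1e-5                     # nF
  g_leak <- passive$g_pas * cp$area * 0.01       # uS
  ## axial conductance to parent from the two half-segment resistances
  rh <- cp$r_half * (passive$ra / 100)           # MOhm
  g_ax <- numeric(n)
  g_ax[-1] <- 1 / (rh[-1] + rh[cp$parent[-1]])   # uS
  gbar <- lapply(channels, function(ch) {
    dens <- rep(0, n)
    for (r in names(ch$density)) dens[cp$region == r] <- ch$density[[r]]
    if (!is.null(ch$gradient))
      dens <- dens * ch$gradient(cp$path_dist, cp$region)
    dens * cp$area * 1e-3                        # uS
  })
  names(gbar) <- names(channels)
  phi <- 5.182e3 * calcium$gamma / (calcium$depth * cp$area)  # uM/ms per nA
  for (r in names(calcium$gamma_region))
    phi[cp$region == r] <- phi[cp$region == r] * calcium$gamma_region[[r]]
  structure(list(cable = cable, channels = channels, passive = passive,
                 calcium = calcium, c_m = c_m, g_leak = g_leak,
                 g_axial = g_ax, gbar = gbar, phi = phi,
                 scale_log = list()),
            class = "neuron_model")
}

#' @export
print.neuron_model <- function(x, ...) {
  cat("neuron_model:", nrow(x$cable$comp), "compartments,",
      length(x$channels), "channel types\n")
  invisible(x)
}

#' Scale a channel density in a region
#'
#' Multiplies the maximal conductance of `channel` by `factor` in `region`
#' (`"all"` for everywhere); factor 0 is a knockout. `channel = "vgcc"`
#' addresses all calcium channels at once.
#'
#' @param model a `neuron_model`
#' @param channel channel name, or `"vgcc"`
#' @param region region name (see [region_length()]) or `"all"`
#' @param factor multiplier >= 0
#' @return the modified `neuron_model`
#' @export
set_conductance_scale <- function(model, channel, region = "all", factor) {
  chs <- if (identical(channel, "vgcc")) {
    names(model$channels)[vapply(model$channels, `[[`, TRUE, "is_ca")]
  } else channel
  unknown <- setdiff(chs, names(model$gbar))
  if (length(unknown)) stop("unknown channel: ", paste(unknown, collapse = ", "))
  sel <- if (identical(region, "all")) rep(TRUE, nrow(model$cable$comp))
         else model$cable$comp$region %in% resolve_region(region)
  if (!any(sel)) stop("unknown or empty region: ", region)
  for (ch in chs) model$gbar[[ch]][sel] <- model$gbar[[ch]][sel] * factor
  model$scale_log <- c(model$scale_log,
                       list(list(channel = channel, region = region,
                                 factor = factor)))
  model
}

#' Simulation configuration
#'
#' @param dt integration step (ms)
#' @param duration simulated time (ms)
#' @param temperature reference temperature (C); kinetics are pre-scaled to
#'   34 C, the value is recorded with results
#' @param v_init initial voltage (mV)
#' @param probes voltage probe sites: compartment indices or names among
#'   `"soma"`, `"nexus"`, `"mid_tuft"`, `"distal_tuft"`
#' @param ca_probes calcium probe sites (same conventions); default = probes
#' @param record_stride record every n-th step
#' @param vgcc_off knockout flag: zero all voltage-gated calcium channels
#' @param nmda_off knockout flag: zero the NMDA conductance (AMPA-only)
#' @param fastk_scale somatic fast-potassium scale factor (default 1.5, the
#'   after-depolarization fix)
#' @param tau_nmda NMDA decay time constant (ms); 43 by default, with 70 a
#'   contemporary alternative
#' @param mg,mg_gamma,mg_scale magnesium block parameters: concentration
#'   (mM), voltage steepness (1/mV) and concentration scale (mM)
#' @return a `simulation_config`
#' @export
simulation_config <- function(dt = 0.025, duration = 600, temperature = 34,
                              v_init = -76, probes = c("soma", "nexus",
                                                       "distal_tuft"),
                              ca_probes = NULL, record_stride = 2L,
                              vgcc_off = FALSE, nmda_off = FALSE,
                              fastk_scale = 1.5, tau_nmda = 43,
                              mg = 1.0, mg_gamma = 0.062, mg_scale = 3.57) {
  stopifnot(dt > 0, duration > 0)
  structure(as.list(environment()), class = "simulation_config")
}

#' Resolve named probe sites to compartment indices
#'
#' @param model a `neuron_model`
#' @param probes character names (`"soma"`, `"nexus"`, `"mid_tuft"`,
#'   `"distal_tuft"`) or integer compartment indices
#' @return named integer vector
#' @export
probe_sites <- function(model, probes) {
  cp <- model$cable$comp
  if (is.numeric(probes)) return(setNames(as.integer(probes),
                                          paste0("comp", probes)))
  idx <- vapply(probes, function(p) switch(p,
    soma = 1L,
    nexus = {
      tr <- which(cp$region %in% c("trunk", "hotspot") & cp$path_dist <= 610)
      tr[which.max(cp$path_dist[tr])]
    },
    mid_tuft = {
      tu <- which(cp$region == "tuft")
      tu[which.min(abs(cp$path_dist[tu] - 950))]
    },
    distal_tuft = {
      tu <- which(cp$region == "tuft")
      tu[which.max(cp$path_dist[tu])]
    },
    stop("unknown probe name: ", p)), integer(1))
  setNames(idx, probes)
}

## expand pattern events into per-receptor rows for the core
.expand_events <- function(model, pattern, cfg) {
  kinds <- list(AMPA = synapse_params("AMPA"),
                NMDA = synapse_params("NMDA", tau_decay = cfg$tau_nmda),
                GABA_A = synapse_params("GABA_A"))
  norm <- vapply(kinds, function(p) {
    tp <- p$tau_rise * p$tau_decay / (p$tau_decay - p$tau_rise) *
      log(p$tau_decay / p$tau_rise)
    1 / (exp(-tp / p$tau_decay) - exp(-tp / p$tau_rise))
  }, numeric(1))
  ev <- if (is.null(pattern)) {
    data.frame(node_id = integer(0), onset = numeric(0),
               kind = character(0), weight = numeric(0))
  } else pattern$events
  comp <- compartments_of(model$cable, ev$node_id)
  rows <- list()
  exc <- ev$kind == "exc"
  if (any(exc)) {
    rows$ampa <- data.frame(comp = comp[exc] - 1L, onset = ev$onset[exc],
                            kind = 0L,
                            g_inc = norm[["AMPA"]] * kinds$AMPA$g_max *
                              ev$weight[exc] * 1e-3)
    if (!cfg$nmda_off) {
      rows$nmda <- data.frame(comp = comp[exc] - 1L, onset = ev$onset[exc],
                              kind = 1L,
                              g_inc = norm[["NMDA"]] * kinds$NMDA$g_max *
                                ev$weight[exc] * 1e-3)
    }
  }
  inh <- ev$kind == "inh"
  if (any(inh)) {
    rows$gaba <- data.frame(comp = comp[inh] - 1L, onset = ev$onset[inh],
                            kind = 2L,
                            g_inc = norm[["GABA_A"]] * kinds$GABA_A$g_max *
                              ev$weight[inh] * 1e-3)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(comp = integer(0), onset = numeric(0), kind = integer(0),
               g_inc = numeric(0))
  out <- out[out$onset >= 0, , drop = FALSE]
  out[order(out$onset), , drop = FALSE]
}

#' Simulate the model under one input pattern
#'
#' Backward-Euler integration of the full model for `cfg$duration` ms.
#' Deterministic given (model, pattern, config): no randomness enters the
#' integrator. Somatic spikes are detected from the soma probe by upward
#' 0 mV crossings.
#'
#' @param model a `neuron_model`
#' @param pattern an `input_pattern` (or NULL for no synaptic input)
#' @param cfg a [simulation_config()]
#' @param iclamp optional current injections: data.frame(site, start, dur,
#'   amp) with site a probe name or compartment index, times in ms, amp in nA
#' @return a `simulation_result`: list(time, v, ca, spikes, config, ...)
#' @export
simulate <- function(model, pattern = NULL, cfg = simulation_config(),
                     iclamp = NULL) {
  if (!is.null(pattern) && nrow(pattern$events) &&
      max(pattern$events$onset) > cfg$duration)
    warning("input events beyond the simulated duration are never delivered")
  vp <- probe_sites(model, cfg$probes)
  if (!1L %in% vp) vp <- c(soma = 1L, vp)
  names(vp)[vp == 1L][1] <- "soma"
  cp <- probe_sites(model, cfg$ca_probes %||% cfg$probes)
  gbar <- model$gbar
  soma <- model$cable$comp$region == "soma"
  gbar$k_fast[soma] <- gbar$k_fast[soma] * cfg$fastk_scale
  if (cfg$vgcc_off) {
    for (ch in names(model$channels))
      if (model$channels[[ch]]$is_ca) gbar[[ch]][] <- 0
  }
  chans <- lapply(names(model$channels), function(nm) {
    c(model$channels[[nm]][setdiff(names(model$channels[[nm]]),
                                   c("density", "gradient"))],
      list(gbar = gbar[[nm]]))
  })
  ev <- .expand_events(model, pattern, cfg)
  ic <- if (is.null(iclamp)) {
    data.frame(comp = integer(0), start = numeric(0), dur = numeric(0),
               amp = numeric(0))
  } else {
    data.frame(comp = probe_sites(model, iclamp$site) - 1L,
               start = iclamp$start, dur = iclamp$dur, amp = iclamp$amp)
  }
  syn <- list(tau_decay = c(1.7, cfg$tau_nmda, 8), tau_rise = c(0.2, 2, 0.5),
              e_rev = c(0, 0, -80), mg = cfg$mg, mg_gamma = cfg$mg_gamma,
              mg_scale = cfg$mg_scale)
  n <- nrow(model$cable$comp)
  out <- .simulate_core(as.integer(model$cable$comp$parent - 1L),
                        model$g_axial, model$c_m, model$g_leak,
                        model$passive$e_pas, chans,
                        rep(model$calcium$ca0, n), model$calcium$tau_ca,
                        model$phi, syn, ev, ic,
                        cfg$dt, cfg$duration, cfg$v_init,
                        as.integer(vp - 1L), as.integer(cp - 1L),
                        as.integer(cfg$record_stride))
  colnames(out$v) <- names(vp)
  colnames(out$ca) <- names(cp)
  spikes <- detect_spikes(out$v[, "soma"], time = out$time)
  structure(list(time = out$time, v = out$v, ca = out$ca, spikes = spikes,
                 v_final = out$v_final, ca_final = out$ca_final,
                 n_events = out$n_events_applied, config = cfg,
                 probes = vp, ca_probes = cp),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("simulation_result: %.0f ms, %d spikes", max(x$time),
              length(x$spikes)))
  if (length(x$spikes)) cat(" at", paste(sprintf("%.2f", x$spikes),
                                         collapse = ", "), "ms")
  cat("\n")
  invisible(x)
}

#' Export recorded traces as CSV
#'
#' @param result a `simulation_result`
#' @param path output file
#' @return the path, invisibly
#' @export
write_traces <- function(result, path) {
  df <- data.frame(time = result$time, result$v,
                   setNames(as.data.frame(result$ca),
                            paste0("ca_", colnames(result$ca))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
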