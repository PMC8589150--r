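#' Synapse kinetic parameters
#'
#' Dual-exponential conductance synapses. Decay time constants follow the
#' modelled receptor kinetics (AMPA 1.7 ms, NMDA 43 ms, GABA-A 8 ms); rise
#' times are standard values. Peak conductance is 0.4 nS per excitatory
#' receptor component (AMPA and NMDA have equal weight) and 1 nS per
#' inhibitory synapse. Excitatory reversal 0 mV, GABA-A reversal -80 mV.
#'
#' @param kind one of `"AMPA"`, `"NMDA"`, `"GABA_A"`
#' @param tau_rise,tau_decay rise and decay time constants (ms)
#' @param e_rev reversal potential (mV)
#' @param g_max peak conductance (nS)
#' @param weight dimensionless weight multiplier (plastic; initial 1)
#' @return a `synapse_params` list
#' @export
synapse_params <- function(kind = c("AMPA", "NMDA", "GABA_A"),
                           tau_rise = NULL, tau_decay = NULL,
                           e_rev = NULL, g_max = NULL, weight = 1) {
  kind <- match.arg(kind)
  def <- switch(kind,
    AMPA   = list(tau_rise = 0.2, tau_decay = 1.7, e_rev = 0,   g_max = 0.4),
    NMDA   = list(tau_rise = 2.0, tau_decay = 43,  e_rev = 0,   g_max = 0.4),
    GABA_A = list(tau_rise = 0.5, tau_decay = 8,   e_rev = -80, g_max = 1.0))
  p <- list(kind = kind,
            tau_rise = tau_rise %||% def$tau_rise,
            tau_decay = tau_decay %||% def$tau_decay,
            e_rev = e_rev %||% def$e_rev,
            g_max = g_max %||% def$g_max,
            weight = weight)
  if (!(p$tau_decay > p$tau_rise && p$tau_rise > 0))
    stop("must have tau_decay > tau_rise > 0")
  if (p$g_max < 0 || p$weight < 0) stop("g_max and weight must be >= 0")
  class(p) <- "synapse_params"
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synaptic conductance waveform
#'
#' Dual-exponential conductance, normalized so its peak equals
#' `weight * g_max`: zero at onset, rising with `tau_rise`, decaying with
#' `tau_decay`.
#'
#' @param p a [synapse_params()]
#' @param t time since onset (ms); vectorized, negative times give 0
#' @return conductance in nS
#' @export
conductance_waveform <- function(p, t) {
  tr <- p$tau_rise; td <- p$tau_decay
  tp <- tr * td / (td - tr) * log(td / tr)
  norm <- 1 / (exp(-tp / td) - exp(-tp / tr))
  g <- p$weight * p$g_max * norm * (exp(-t / td) - exp(-t / tr))
  g[t < 0] <- 0
  g
}

#' Magnesium block of the NMDA conductance
#'
#' Voltage-dependent relief of the magnesium block,
#' `1 / (1 + (Mg / scale) * exp(-gamma * V))`: strictly increasing in V,
#' in (0, 1], equal to 1 when Mg = 0.
#'
#' @param v membrane potential (mV); vectorized
#' @param mg extracellular magnesium concentration (mM)
#' @param gamma voltage steepness (1/mV)
#' @param scale concentration scale (mM)
#' @return unblocked fraction in (0, 1]
#' @export
mg_block <- function(v, mg = 1.0, gamma = 0.062, scale = 3.57) {
  1 / (1 + (mg / scale) * exp(-gamma * v))
}

#' Synaptic current
#'
#' `g(t) * (V - E_rev)`, with the NMDA conductance additionally multiplied by
#' the magnesium block factor. Inward current is negative.
#'
#' @param p a [synapse_params()]
#' @param t time since onset (ms)
#' @param v membrane potential (mV)
#' @param mg,gamma,scale magnesium block parameters (NMDA only)
#' @return current in nA (g in nS, V in mV: nS * mV = pA; returned in nA)
#' @export
synaptic_current <- function(p, t, v, mg = 1.0, gamma = 0.062, scale = 3.57) {
  g <- conductance_waveform(p, t)
  if (p$kind == "NMDA") g <- g * mg_block(v, mg, gamma, scale)
  g * (v - p$e_rev) * 1e-3
}
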