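#' Calcium-dependent plasticity parameters
#'
#' Thresholds split the calcium axis into a protected regime below `theta_d`,
#' long-term depression between `theta_d` and `theta_p`, and potentiation
#' above `theta_p`. The learning rate is a saturating Hill function of
#' calcium, near zero at resting concentration so baseline activity leaves
#' weights untouched.
#'
#' @param theta_p potentiation threshold (uM)
#' @param theta_d depression threshold (uM)
#' @param steepness sigmoid steepness of the weight-target function (1/uM)
#' @param eta_max maximal learning rate (1/s)
#' @param k_eta calcium half-activation of the learning rate (uM)
#' @param h_eta Hill coefficient of the learning rate
#' @param repetitions input repetitions of the plasticity protocol
#' @param epsilon classification band around weight 1 ("protected")
#' @return a `plasticity_params` list
#' @export
plasticity_params <- function(theta_p = 0.4, theta_d = 0.25, steepness = 80,
                              eta_max = 1, k_eta = 0.3, h_eta = 4,
                              repetitions = 10, epsilon = 0.02) {
  if (!(theta_p > theta_d && theta_d > 0)) stop("need theta_p > theta_d > 0")
  if (eta_max < 0) stop("eta_max must be >= 0")
  structure(as.list(environment()), class = "plasticity_params")
}

## numerically safe logistic
.sigm <- function(x) ifelse(x >= 0, 1 / (1 + exp(-x)), exp(x) / (1 + exp(x)))

#' Calcium-dependent weight target (omega)
#'
#' `omega(ca) = 0.25 + sigm(k (ca - theta_p)) - 0.25 sigm(k (ca - theta_d))`
#' with logistic `sigm` and steepness `k`: ~0.25 at low calcium (protected,
#' since the learning rate also vanishes there), a trough near zero between
#' the thresholds (LTD), and saturation at 1 above the potentiation
#' threshold (LTP).
#'
#' @param ca intracellular calcium concentration (uM); vectorized
#' @param p a [plasticity_params()]
#' @return omega values in (0, 1.25)
#' @export
omega <- function(ca, p = plasticity_params()) {
  stopifnot(all(ca >= 0))
  k <- p$steepness
  0.25 + .sigm(k * (ca - p$theta_p)) - 0.25 * .sigm(k * (ca - p$theta_d))
}

#' Calcium-dependent learning rate (eta)
#'
#' Monotone saturating Hill function of calcium,
#' `eta_max / (1 + (k_eta / ca)^h_eta)`: effectively zero at resting calcium
#' and saturating at high concentrations.
#'
#' @param ca intracellular calcium concentration (uM); vectorized
#' @param p a [plasticity_params()]
#' @return learning rate in 1/s
#' @export
eta <- function(ca, p = plasticity_params()) {
  stopifnot(all(ca >= 0))
  out <- numeric(length(ca))
  pos <- ca > 0
  out[pos] <- p$eta_max / (1 + (p$k_eta / ca[pos])^p$h_eta)
  out
}

#' Integrate the weight dynamics along a calcium trace
#'
#' Integrates `dw/dt = eta(ca) (omega(ca) - w)` along the sampled trace,
#' repeated `p$repetitions` times in succession (non-overlapping), using the
#' exact exponential update per sample (eta and omega held constant over a
#' step), which keeps w within the envelope of omega regardless of dt.
#'
#' @param ca_trace calcium trace (uM) sampled at `dt`; or a matrix with one
#'   column per synapse site
#' @param w0 initial weight(s)
#' @param p a [plasticity_params()]
#' @param dt sample interval (ms)
#' @param repetitions override `p$repetitions`
#' @return final weight(s)
#' @export
update_weight <- function(ca_trace, w0 = 1, p = plasticity_params(),
                          dt = 0.025, repetitions = NULL) {
  reps <- repetitions %||% p$repetitions
  ca <- if (is.matrix(ca_trace)) ca_trace else matrix(ca_trace, ncol = 1)
  if (anyNA(ca)) stop("NaN/NA in calcium trace")
  nsyn <- ncol(ca)
  w <- rep_len(w0, nsyn)
  dts <- dt / 1000 # eta is 1/s
  om <- omega(as.vector(ca), p)
  et <- eta(as.vector(ca), p)
  dim(om) <- dim(et) <- dim(ca)
  a <- exp(-et * dts)
  ## each sample applies the affine map w -> a w + om (1 - a); compose one
  ## repetition into (A, B) per synapse, then iterate repetitions
  A <- rep(1, nsyn); B <- rep(0, nsyn)
  for (i in seq_len(nrow(ca))) {
    ai <- a[i, ]
    A <- ai * A
    B <- ai * B + om[i, ] * (1 - ai)
  }
  for (r in seq_len(reps)) w <- A * w + B
  if (is.matrix(ca_trace)) w else w[1]
}

#' Per-synapse plasticity outcomes and distance profile
#'
#' Applies the weight dynamics to each synapse's co-located compartmental
#' calcium trace and classifies the outcome: LTP (w > 1 + eps), LTD
#' (w < 1 - eps) or protected. Also records each site's maximal calcium and
#' the time spent above the depression and potentiation thresholds.
#'
#' The absolute efficacy starts at `w_init` (default 0.5, the midpoint of
#' the omega range, so that both depression toward the omega trough and
#' potentiation toward its saturation are expressible); reported weights are
#' normalized to the initial value, so 1 means unchanged.
#'
#' @param ca_traces matrix (time x synapse) of calcium traces (uM)
#' @param path_dist per-synapse path distance (um)
#' @param p a [plasticity_params()]
#' @param dt sample interval (ms)
#' @param repetitions override `p$repetitions`
#' @param w_init absolute initial efficacy the normalized weights refer to
#' @return data frame: synapse, path_dist, weight (normalized to initial),
#'   class, max_ca, t_above_theta_d, t_above_theta_p (ms per repetition)
#' @export
plasticity_map <- function(ca_traces, path_dist, p = plasticity_params(),
                           dt = 0.025, repetitions = NULL, w_init = 0.5) {
  if (is.null(dim(ca_traces))) ca_traces <- matrix(ca_traces, ncol = 1)
  if (ncol(ca_traces) != length(path_dist))
    stop("need one calcium trace per synapse (", length(path_dist),
         " synapses, ", ncol(ca_traces), " traces)")
  w <- update_weight(ca_traces, w_init, p, dt, repetitions) / w_init
  cls <- ifelse(w > 1 + p$epsilon, "LTP",
                ifelse(w < 1 - p$epsilon, "LTD", "protected"))
  data.frame(
    synapse = seq_along(path_dist),
    path_dist = path_dist,
    weight = w,
    class = cls,
    max_ca = apply(ca_traces, 2, max),
    t_above_theta_d = colSums(ca_traces > p$theta_d) * dt,
    t_above_theta_p = colSums(ca_traces > p$theta_p) * dt)
}

#' Potentiation-threshold scan of a plasticity map
#'
#' Recomputes final weights over a grid of potentiation thresholds with the
#' depression threshold kept at a fixed ratio (default 0.6) of theta_p,
#' returning a synapse x theta_p matrix of log2 weight changes.
#'
#' @param ca_traces matrix (time x synapse) of calcium traces (uM)
#' @param theta_p_grid potentiation thresholds to scan (uM)
#' @param ratio theta_d / theta_p ratio
#' @param p base [plasticity_params()]
#' @param dt sample interval (ms)
#' @param w_init absolute initial efficacy (see [plasticity_map()])
#' @return matrix of log2(final weight, normalized to initial), synapses in
#'   rows
#' @export
theta_scan <- function(ca_traces, theta_p_grid = seq(0.2, 0.8, by = 0.1),
                       ratio = 0.6, p = plasticity_params(), dt = 0.025,
                       w_init = 0.5) {
  if (is.null(dim(ca_traces))) ca_traces <- matrix(ca_traces, ncol = 1)
  out <- sapply(theta_p_grid, function(tp) {
    pi <- plasticity_params(theta_p = tp, theta_d = ratio * tp,
                            steepness = p$steepness, eta_max = p$eta_max,
                            k_eta = p$k_eta, h_eta = p$h_eta,
                            repetitions = p$repetitions, epsilon = p$epsilon)
    log2(update_weight(ca_traces, w_init, pi, dt) / w_init)
  })
  out <- matrix(out, nrow = ncol(ca_traces),
                dimnames = list(NULL, sprintf("theta_p=%g", theta_p_grid)))
  out
}
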