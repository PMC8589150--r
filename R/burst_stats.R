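#' Detect somatic spikes by threshold crossing
#'
#' One spike per upward crossing of the detection threshold (default 0 mV).
#' The somatic action potential is narrow (< 2 ms) and the soma repolarizes
#' well below threshold between spikes, so crossings and spikes are in
#' one-to-one correspondence and the count is insensitive to moving the
#' threshold within roughly -20..+20 mV.
#'
#' @param v voltage trace (mV) on a uniform time grid
#' @param time time grid (ms), or NULL with `dt` given
#' @param dt sample interval (ms) when `time` is NULL
#' @param threshold detection threshold (mV)
#' @return numeric vector of spike times (ms), strictly increasing
#' @export
detect_spikes <- function(v, time = NULL, dt = NULL, threshold = 0) {
  if (is.null(time)) {
    if (is.null(dt)) stop("supply time or dt")
    time <- (seq_along(v) - 1L) * dt
  }
  above <- v >= threshold
  up <- which(!above[-length(above)] & above[-1]) + 1L
  time[up]
}

#' Group spikes into bursts by inter-spike interval
#'
#' Maximal runs of consecutive spikes whose inter-spike intervals are all
#' `<= max_isi` (default 20 ms). Isolated spikes form singleton groups.
#'
#' @param spikes sorted spike times (ms)
#' @param max_isi burst-grouping interval (ms)
#' @return list of numeric vectors (one per group)
#' @export
group_bursts <- function(spikes, max_isi = 20) {
  if (!length(spikes)) return(list())
  if (is.unsorted(spikes, strictly = TRUE)) stop("spike times must be strictly increasing")
  brk <- c(0L, which(diff(spikes) > max_isi), length(spikes))
  lapply(seq_len(length(brk) - 1L),
         function(i) spikes[(brk[i] + 1L):brk[i + 1L]])
}

#' Spikes per burst of a trial
#'
#' The size of the largest ISI-linked group (isolated spikes preceding or
#' following the burst are not averaged in). `method = "mean"` instead
#' averages group sizes.
#'
#' @param spikes spike times (ms)
#' @param max_isi burst-grouping interval (ms)
#' @param method `"largest"` (default) or `"mean"`
#' @return non-negative number (0 for no spikes)
#' @export
spikes_per_burst <- function(spikes, max_isi = 20, method = c("largest", "mean")) {
  method <- match.arg(method)
  g <- group_bursts(spikes, max_isi)
  if (!length(g)) return(0)
  n <- lengths(g)
  if (method == "largest") max(n) else mean(n)
}

#' Intra-burst firing rate of one group
#'
#' `(n - 1) / (t_last - t_first)` in Hz for groups of n >= 2 spikes; isolated
#' spikes count as a 0 Hz burst.
#'
#' @param group spike times of one burst group (ms)
#' @return rate in Hz
#' @export
intra_burst_rate <- function(group) {
  n <- length(group)
  if (n < 2L) return(0)
  (n - 1) / (group[n] - group[1]) * 1000
}

#' Per-trial burst summary
#'
#' @param spikes spike times (ms)
#' @param max_isi burst-grouping interval (ms)
#' @return list: groups, spikes_per_burst, rates (per group, Hz), weights
#'   (spike count per group), irregular (any group whose max/min within-burst
#'   ISI ratio is >= 1.5)
#' @export
burst_summary <- function(spikes, max_isi = 20) {
  g <- group_bursts(spikes, max_isi)
  rates <- vapply(g, intra_burst_rate, numeric(1))
  irr <- vapply(g, function(x) {
    if (length(x) < 3L) return(FALSE)
    isi <- diff(x)
    max(isi) / min(isi) >= 1.5
  }, logical(1))
  list(groups = g,
       spikes_per_burst = if (length(g)) max(lengths(g)) else 0,
       rates = rates,
       weights = if (length(g)) lengths(g) else integer(0),
       irregular = any(irr))
}

#' Aggregate intra-burst firing rate over trials
#'
#' The mean over all spikes of all bursts: the spike-count-weighted mean of
#' per-group rates across every trial of one parameter combination, with
#' isolated spikes contributing a 0 Hz burst of weight 1. The unweighted
#' per-group mean is available as an option.
#'
#' @param trials list of spike-time vectors (one per trial)
#' @param max_isi burst-grouping interval (ms)
#' @param weighted spike-count weighting (default TRUE)
#' @param bursts_only drop singleton (0 Hz) groups before averaging
#' @return rate in Hz (NA if no groups)
#' @export
aggregate_rate <- function(trials, max_isi = 20, weighted = TRUE,
                           bursts_only = FALSE) {
  rates <- numeric(0); w <- numeric(0)
  for (s in trials) {
    b <- burst_summary(s, max_isi)
    rates <- c(rates, b$rates)
    w <- c(w, if (weighted) b$weights else rep(1, length(b$rates)))
  }
  if (bursts_only) {
    keep <- rates > 0
    rates <- rates[keep]; w <- w[keep]
  }
  if (!length(rates)) return(NA_real_)
  sum(rates * w) / sum(w)
}

#' Standard deviation of batch means
#'
#' Splits trials into `n_batch` consecutive batches (default 10 x 20) and
#' returns the SD of the batch means, the dispersion measure used for scan
#' summaries.
#'
#' @param x per-trial values
#' @param n_batch number of batches
#' @return SD of batch means (NA if fewer than 2 batches can be formed)
#' @export
batch_mean_sd <- function(x, n_batch = 10) {
  n <- length(x)
  if (n < 2 * n_batch) n_batch <- max(2L, n %/% 2L)
  if (n < 2L) return(NA_real_)
  idx <- sort(rep_len(seq_len(n_batch), n))
  stats::sd(tapply(x, idx, mean))
}

#' Delay-window metrics of a tuning curve
#'
#' Given mean spikes/burst sampled on a delay grid, returns the extent of the
#' contiguous super-level set (at `level`, default 2 spikes/burst) containing
#' the curve maximum, with linear interpolation at the crossings, and the
#' midpoint of that interval. If several disjoint intervals exceed the level,
#' the one containing the global maximum is used.
#'
#' @param dt_grid delay values (ms), increasing
#' @param mean_spikes mean spikes/burst at each delay
#' @param level window level (spikes/burst)
#' @return list(width, center, lo, hi); width 0 and center NA when the curve
#'   never reaches `level`
#' @export
window_metrics <- function(dt_grid, mean_spikes, level = 2) {
  stopifnot(length(dt_grid) == length(mean_spikes), !is.unsorted(dt_grid))
  above <- mean_spikes >= level
  if (!any(above)) return(list(width = 0, center = NA_real_,
                               lo = NA_real_, hi = NA_real_))
  imax <- which.max(mean_spikes)
  if (!above[imax]) imax <- which(above)[1] # guard: max below level numerically
  ## expand around the maximum
  lo_i <- imax; while (lo_i > 1L && above[lo_i - 1L]) lo_i <- lo_i - 1L
  hi_i <- imax; while (hi_i < length(above) && above[hi_i + 1L]) hi_i <- hi_i + 1L
  interp <- function(i1, i2) {
    ## crossing between grid points i1 (below) and i2 (above) or vice versa
    x1 <- dt_grid[i1]; x2 <- dt_grid[i2]
    y1 <- mean_spikes[i1]; y2 <- mean_spikes[i2]
    x1 + (level - y1) / (y2 - y1) * (x2 - x1)
  }
  lo <- if (lo_i == 1L) dt_grid[1] else interp(lo_i - 1L, lo_i)
  hi <- if (hi_i == length(above)) dt_grid[length(above)] else interp(hi_i + 1L, hi_i)
  list(width = hi - lo, center = (lo + hi) / 2, lo = lo, hi = hi)
}

#' Burst-class rule from activated synapse counts
#'
#' `tuft-NMDA` for > 40 tuft and < 120 basal synapses; `coincidence` for
#' > 150 basal and < 100 tuft synapses; otherwise `unassigned`.
#'
#' @param n_basal,n_tuft activated excitatory synapse counts (vectorized)
#' @return character vector of class labels
#' @export
classify_regime <- function(n_basal, n_tuft) {
  stopifnot(all(n_basal >= 0), all(n_tuft >= 0))
  out <- rep("unassigned", length(n_basal))
  out[n_tuft > 40 & n_basal < 120] <- "tuft-NMDA"
  out[n_basal > 150 & n_tuft < 100] <- "coincidence"
  out
}

#' Coefficient of variation and Fano factor of inter-spike intervals
#'
#' CV = sd/mean and Fano = var/mean of the ISIs (population moments); either
#' exceeding 1 marks firing more irregular than a Poisson process (the
#' bursting criterion).
#'
#' @param isis inter-spike intervals (ms), at least 2
#' @return list(cv, fano)
#' @export
cv_fano <- function(isis) {
  if (length(isis) < 2L) stop("need at least 2 ISIs")
  m <- mean(isis)
  v <- mean((isis - m)^2)
  list(cv = sqrt(v) / m, fano = v / m)
}
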