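## Experiment drivers: each scan runs seeded stochastic input instantiations
## through the calibrated model and summarizes bursts. Every function is
## reproducible bit-for-bit from its arguments and master seed.

#' Deterministic per-repetition seed
#'
#' Combines a master seed with a grid-cell index and repetition number into
#' an integer seed below 2^31, so every scan cell is reproducible in
#' isolation.
#' @param master master seed
#' @param cell grid-cell index
#' @param rep repetition number
#' @return integer seed
#' @export
rep_seed <- function(master, cell, rep) {
  as.integer((as.numeric(master) * 7919 + cell * 104729 + rep * 1299721) %%
               2147483647)
}

.run_trial <- function(model, m, n_basal, n_tuft, sigma, dt, seed,
                       tuft_target = NULL, inh = NULL, cfg = NULL) {
  cfg <- cfg %||% simulation_config()
  pat <- sample_excitatory(m, n_basal, n_tuft, sigma = sigma, dt = dt,
                           tuft_target = tuft_target, seed = seed)
  if (!is.null(inh)) {
    ip <- sample_inhibitory(m, n_inh = inh$n %||% 20, target = inh$target,
                            dt_inh = inh$dt_inh %||% 0, sigma = sigma,
                            branch = inh$branch, seed = seed)
    pat <- combine_patterns(pat, ip)
  }
  simulate(model, pat, cfg)
}

#' Minimal synapse count eliciting a burst
#'
#' Bisects the activated synapse count until the smallest count is found for
#' which at least `criterion` of the seeded instantiations produce a burst
#' (>= 2 spikes within one ISI-linked group). Modes: basal count with a fixed
#' tuft count (`"basal_given_tuft"`), tuft only, or basal only.
#'
#' @param model a `neuron_model`
#' @param mode threshold mode
#' @param fixed fixed count of the other population (basal_given_tuft)
#' @param sigma temporal jitter SD (ms)
#' @param reps seeded instantiations per tested count
#' @param criterion burst fraction required (default 0.5)
#' @param bounds count search range
#' @param resolution stop when the bracket is this tight (synapses)
#' @param seed master seed
#' @param cfg simulation configuration
#' @return list(threshold, censored, trace); `censored = TRUE` when the
#'   criterion is never met within `bounds` (threshold = Inf)
#' @export
find_threshold <- function(model, mode = c("basal_given_tuft", "tuft_only",
                                           "basal_only"),
                           fixed = 30, sigma = 0, reps = 20, criterion = 0.5,
                           bounds = c(0, 400), resolution = 5, seed = 1,
                           cfg = simulation_config()) {
  mode <- match.arg(mode)
  m <- model$cable$morphology
  frac <- function(n) {
    hits <- vapply(seq_len(reps), function(r) {
      s <- rep_seed(seed, n, r)
      nb <- switch(mode, basal_given_tuft = n, tuft_only = 0, basal_only = n)
      nt <- switch(mode, basal_given_tuft = fixed, tuft_only = n,
                   basal_only = 0)
      res <- .run_trial(model, m, nb, nt, sigma, 0, s, cfg = cfg)
      spikes_per_burst(res$spikes) >= 2
    }, logical(1))
    mean(hits)
  }
  trace <- list()
  lo <- bounds[1]; hi <- bounds[2]
  f_hi <- frac(hi)
  trace[[length(trace) + 1L]] <- c(n = hi, frac = f_hi)
  if (f_hi < criterion) {
    return(list(threshold = Inf, censored = TRUE,
                trace = do.call(rbind, trace)))
  }
  f_lo <- frac(lo)
  trace[[length(trace) + 1L]] <- c(n = lo, frac = f_lo)
  if (f_lo >= criterion) {
    return(list(threshold = lo, censored = FALSE,
                trace = do.call(rbind, trace)))
  }
  while (hi - lo > resolution) {
    mid <- round((lo + hi) / 2)
    f <- frac(mid)
    trace[[length(trace) + 1L]] <- c(n = mid, frac = f)
    if (f >= criterion) hi <- mid else lo <- mid
  }
  list(threshold = hi, censored = FALSE, trace = do.call(rbind, trace))
}

#' Scan the basal-tuft delay window over temporal jitter values
#'
#' For each (sigma, delta-t) cell, runs seeded instantiations of the standard
#' excitation (default 50 basal + 30 tuft), computes mean spikes/burst, and
#' summarizes each sigma's curve by its width and center at the 2-spikes/burst
#' level.
#'
#' @param model a `neuron_model`
#' @param sigmas temporal jitter values (ms)
#' @param dt_grid delay grid (ms)
#' @param n_basal,n_tuft activated synapse counts
#' @param reps instantiations per grid cell
#' @param seed master seed
#' @param vgcc_off knockout companion scan flag
#' @param cfg simulation configuration
#' @return list(curves = data.frame(sigma, dt, mean_spikes, sd_spikes),
#'   windows = data.frame(sigma, width, center))
#' @export
scan_sigma_dt <- function(model, sigmas = c(3, 6, 9, 12),
                          dt_grid = seq(-40, 40, by = 5),
                          n_basal = 50, n_tuft = 30, reps = 20, seed = 1,
                          vgcc_off = FALSE, cfg = NULL) {
  m <- model$cable$morphology
  cfg <- cfg %||% simulation_config(vgcc_off = vgcc_off)
  rows <- list(); wins <- list()
  for (sg in sigmas) {
    ms <- sapply(seq_along(dt_grid), function(i) {
      spb <- vapply(seq_len(reps), function(r) {
        s <- rep_seed(seed, i + 1000 * which(sigmas == sg), r)
        res <- .run_trial(model, m, n_basal, n_tuft, sg, dt_grid[i], s,
                          cfg = cfg)
        spikes_per_burst(res$spikes)
      }, numeric(1))
      c(mean(spb), stats::sd(spb))
    })
    rows[[length(rows) + 1L]] <- data.frame(sigma = sg, dt = dt_grid,
                                            mean_spikes = ms[1, ],
                                            sd_spikes = ms[2, ])
    wm <- window_metrics(dt_grid, ms[1, ])
    wins[[length(wins) + 1L]] <- data.frame(sigma = sg, width = wm$width,
                                            center = wm$center)
  }
  list(curves = do.call(rbind, rows), windows = do.call(rbind, wins))
}

#' Scan the basal x tuft synapse-count grid
#'
#' Per grid cell: mean spikes/burst and the aggregate intra-burst rate over
#' all instantiations, plus the burst-class label from the count rule. Also
#' returns the per-cell scatter table (spikes/burst vs rate) that mirrors the
#' two-cluster summary.
#'
#' @param model a `neuron_model`
#' @param n_basal_grid,n_tuft_grid synapse-count grids
#' @param sigma,dt temporal parameters (defaults 10 ms, 0)
#' @param reps instantiations per cell
#' @param seed master seed
#' @param nmda_off AMPA-only companion flag
#' @param cfg simulation configuration
#' @return data.frame(n_basal, n_tuft, mean_spikes, rate, burst_frac, class)
#' @export
scan_synapse_grid <- function(model, n_basal_grid = seq(0, 300, by = 50),
                              n_tuft_grid = seq(0, 120, by = 20),
                              sigma = 10, dt = 0, reps = 20, seed = 1,
                              nmda_off = FALSE, cfg = NULL) {
  m <- model$cable$morphology
  cfg <- cfg %||% simulation_config(nmda_off = nmda_off)
  grid <- expand.grid(n_basal = n_basal_grid, n_tuft = n_tuft_grid)
  out <- lapply(seq_len(nrow(grid)), function(g) {
    trials <- lapply(seq_len(reps), function(r) {
      s <- rep_seed(seed, g, r)
      .run_trial(model, m, grid$n_basal[g], grid$n_tuft[g], sigma, dt, s,
                 cfg = cfg)$spikes
    })
    spb <- vapply(trials, spikes_per_burst, numeric(1))
    data.frame(n_basal = grid$n_basal[g], n_tuft = grid$n_tuft[g],
               mean_spikes = mean(spb), burst_frac = mean(spb >= 2),
               rate = aggregate_rate(trials),
               class = classify_regime(grid$n_basal[g], grid$n_tuft[g]))
  })
  do.call(rbind, out)
}

#' Scan inhibition location and timing
#'
#' Runs the standard excitation (default 70 basal + 40 tuft) with 20
#' inhibitory synapses placed at numbered loci (single-branch configuration)
#' or iso-distance strips (whole-tuft configuration), over a grid of
#' inhibition delays, plus control rows without inhibition.
#'
#' @param model a `neuron_model`
#' @param locations locus numbers (1-9) or a list of
#'   `list(distance =, window =)` strips
#' @param dt_inh_grid inhibition-minus-excitation delays (ms)
#' @param n_basal,n_tuft excitation counts
#' @param single_branch restrict tuft excitation (and tuft loci) to one
#'   600 um nexus-to-tip branch
#' @param sigma temporal jitter (ms)
#' @param reps instantiations per cell
#' @param n_inh inhibitory synapse count
#' @param seed master seed
#' @param cfg simulation configuration
#' @param record_ca also return per-trial maximal hotspot calcium
#' @return data.frame(location, dt_inh, mean_spikes, batch_sd, rate,
#'   max_ca_nexus); control rows have location = "none"
#' @export
scan_inhibition <- function(model, locations = 1:9, dt_inh_grid = 0,
                            n_basal = 70, n_tuft = 40, single_branch = TRUE,
                            sigma = 10, reps = 20, n_inh = 20, seed = 1,
                            cfg = simulation_config(), record_ca = FALSE) {
  m <- model$cable$morphology
  branch <- if (single_branch)
    select_span(m, "tuft", "named_branch", rng = derive_seed(seed, "spatial"))
  loc_list <- c(list(NULL), as.list(locations))
  rows <- list()
  for (li in seq_along(loc_list)) {
    loc <- loc_list[[li]]
    dts <- if (is.null(loc)) 0 else dt_inh_grid
    for (di in dts) {
      spb <- numeric(reps); camax <- numeric(reps)
      trials <- vector("list", reps)
      for (r in seq_len(reps)) {
        s <- rep_seed(seed, li * 1000 + round(di), r)
        inh <- if (!is.null(loc)) list(target = loc, dt_inh = di,
                                       branch = branch, n = n_inh)
        res <- .run_trial(model, m, n_basal, n_tuft, sigma, 0, s,
                          tuft_target = branch, inh = inh, cfg = cfg)
        spb[r] <- spikes_per_burst(res$spikes)
        trials[[r]] <- res$spikes
        camax[r] <- max(res$ca[, "nexus"])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        location = if (is.null(loc)) "none" else
          if (is.numeric(loc)) as.character(loc) else
            sprintf("strip%g", loc$distance),
        dt_inh = di, mean_spikes = mean(spb),
        batch_sd = batch_mean_sd(spb),
        rate = aggregate_rate(trials),
        max_ca_nexus = mean(camax))
    }
  }
  do.call(rbind, rows)
}

#' Scan the spatial extent of excitation or inhibition
#'
#' Varies the fraction of the target region over which synapses are
#' distributed and reports mean spikes/burst per extent, with the argmax
#' (excitation) or argmin (inhibition) extent.
#'
#' @param model a `neuron_model`
#' @param what `"tuft_excitation"`, `"basal_excitation"` or `"inhibition"`
#' @param fractions extents as fractions of the target region's cable
#' @param n_basal,n_tuft excitation counts
#' @param sigma temporal jitter (ms)
#' @param reps instantiations per extent
#' @param seed master seed
#' @param cfg simulation configuration
#' @return list(table = data.frame(fraction, length_um, mean_spikes),
#'   optimum_fraction)
#' @export
scan_spatial_extent <- function(model, what = c("tuft_excitation",
                                                "basal_excitation",
                                                "inhibition"),
                                fractions = c(0.05, 0.1, 0.2, 0.4, 0.7, 1),
                                n_basal = 50, n_tuft = 30, sigma = 9,
                                reps = 20, seed = 1,
                                cfg = simulation_config()) {
  what <- match.arg(what)
  m <- model$cable$morphology
  tuft_total <- region_length(m, "tuft")
  basal_total <- region_length(m, "basal")
  rows <- lapply(seq_along(fractions), function(fi) {
    f <- fractions[fi]
    spb <- vapply(seq_len(reps), function(r) {
      s <- rep_seed(seed, fi, r)
      res <- switch(what,
        tuft_excitation = {
          tgt <- select_span(m, "tuft", "fraction", f,
                             rng = derive_seed(s, "spatial"))
          .run_trial(model, m, n_basal, n_tuft, sigma, 0, s,
                     tuft_target = tgt, cfg = cfg)
        },
        basal_excitation = {
          ## spread the basal synapses over a stretch of the basal tree
          tgt <- select_span(m, "basal", "fraction", f,
                             rng = derive_seed(s, "spatial"))
          pat_b <- sample_excitatory(m, 0, n_basal, sigma = sigma, dt = 0,
                                     tuft_target = tgt, seed = s)
          pat_b$events$group <- "basal"
          tuft <- select_span(m, "tuft", "length", 750,
                              rng = derive_seed(s + 1, "spatial"))
          pat_t <- sample_excitatory(m, 0, n_tuft, sigma = sigma, dt = 0,
                                     tuft_target = tuft, seed = s + 1)
          simulate(model, combine_patterns(pat_b, pat_t), cfg)
        },
        inhibition = {
          ext <- f * tuft_total
          tgt <- select_span(m, "tuft", "length", max(ext, 40),
                             rng = derive_seed(s, "spatial"))
          inh <- list(target = tgt, dt_inh = 0)
          .run_trial(model, m, n_basal, n_tuft, sigma, 0, s, inh = inh,
                     cfg = cfg)
        })
      spikes_per_burst(res$spikes)
    }, numeric(1))
    data.frame(fraction = f,
               length_um = f * if (what == "basal_excitation") basal_total
                           else tuft_total,
               mean_spikes = mean(spb))
  })
  tab <- do.call(rbind, rows)
  opt <- if (what == "inhibition") tab$fraction[which.min(tab$mean_spikes)]
         else tab$fraction[which.max(tab$mean_spikes)]
  list(table = tab, optimum_fraction = opt)
}

#' Run the calcium-dependent plasticity protocol
#'
#' Single-branch excitation (70 basal + 40 tuft by default) with 20
#' inhibitory synapses at one of the apical loci, simulated with calcium
#' probes at every excitatory tuft synapse; the weight dynamics are then
#' integrated over the configured number of input repetitions. Returns the
#' per-synapse weight map and the maximal-calcium-versus-delay record.
#'
#' @param model a `neuron_model`
#' @param locus inhibition locus: 1 (trunk, proximal to the hotspot),
#'   2 (just distal to the hotspot) or 3 (distal tuft); NULL = no inhibition
#' @param dt_inh_grid inhibition delays for the calcium record (ms)
#' @param n_basal,n_tuft excitation counts
#' @param sigma temporal jitter (ms)
#' @param whole_tuft use whole-tuft excitation instead of one branch
#' @param p plasticity parameters
#' @param seed master seed
#' @param cfg simulation configuration (duration must cover the input)
#' @return list(map = plasticity outcome data frame for dt_inh = 0,
#'   ca_record = data.frame(dt_inh, site, max_ca), branch)
#' @export
run_plasticity_protocol <- function(model, locus = 2,
                                    dt_inh_grid = seq(-20, 20, by = 10),
                                    n_basal = 70, n_tuft = 40, sigma = 10,
                                    whole_tuft = FALSE,
                                    p = plasticity_params(), seed = 1,
                                    cfg = simulation_config()) {
  m <- model$cable$morphology
  branch <- if (whole_tuft) NULL else
    select_span(m, "tuft", "named_branch", rng = derive_seed(seed, "spatial"))
  ## plasticity loci: trunk below the hotspot, just distal to it, distal tuft
  loci_dist <- c(500, 850, 1150)
  pat <- sample_excitatory(m, n_basal, n_tuft, sigma = sigma, dt = 0,
                           tuft_target = branch, seed = seed)
  ev <- pat$events
  tuft_ev <- which(ev$group == "tuft")
  syn_comp <- compartments_of(model$cable, ev$node_id[tuft_ev])
  probes <- unique(syn_comp)
  run_one <- function(di, with_inh = TRUE) {
    pp <- pat
    if (with_inh && !is.null(locus)) {
      tgt <- iso_distance_sites(m, loci_dist[locus], 200,
                                region = if (locus == 1) "apical" else "tuft")
      if (!whole_tuft && locus > 1) {
        keep <- tgt$node_id %in% branch$node_id
        if (any(keep)) tgt <- .cset(m, tgt$node_id[keep])
      }
      ip <- sample_inhibitory(m, 20, tgt, dt_inh = di, sigma = sigma,
                              seed = seed)
      pp <- combine_patterns(pat, ip)
    }
    cfg2 <- cfg
    cfg2$ca_probes <- probes
    cfg2$probes <- "soma"
    simulate(model, pp, cfg2)
  }
  ## calcium-versus-delay record at three reference sites
  ca_rows <- list()
  for (di in dt_inh_grid) {
    res <- run_one(di)
    mx <- apply(res$ca, 2, max)
    ca_rows[[length(ca_rows) + 1L]] <- data.frame(
      dt_inh = di, site = colnames(res$ca), max_ca = unname(mx))
  }
  ## weight map at dt_inh = 0 (and a no-inhibition control)
  res0 <- run_one(0)
  idx <- match(syn_comp, probes)
  traces <- res0$ca[, idx, drop = FALSE]
  map <- plasticity_map(traces, model$cable$comp$path_dist[syn_comp], p,
                        dt = cfg$dt * cfg$record_stride)
  ctrl <- run_one(0, with_inh = FALSE)
  map_ctrl <- plasticity_map(ctrl$ca[, idx, drop = FALSE],
                             model$cable$comp$path_dist[syn_comp], p,
                             dt = cfg$dt * cfg$record_stride)
  list(map = map, map_no_inh = map_ctrl,
       ca_record = do.call(rbind, ca_rows), branch = branch,
       locus = locus, spikes = res0$spikes, spikes_no_inh = ctrl$spikes)
}
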