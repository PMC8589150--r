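## deterministic seed splitting: one master seed feeds independent spatial and
## temporal substreams, so protocols can vary activation times while keeping
## synapse locations fixed (and vice versa)
#' Derive a deterministic substream seed
#'
#' Splits one master seed into independent substreams (spatial, temporal,
#' background, inhibition, protocol) so that protocols can vary one aspect
#' of an input pattern while holding the others fixed.
#' @param seed master seed (integer)
#' @param stream one of "spatial", "temporal", "background", "inhibition", "protocol"
#' @return integer seed below 2^31
#' @export
derive_seed <- function(seed, stream) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  k <- match(stream, c("spatial", "temporal", "background", "inhibition",
                       "protocol"))
  if (is.na(k)) stop("unknown stream")
  as.integer((s * 48271 + k * 10139043) %% 2147483647)
}

.pattern <- function(events, m, seed = NULL, meta = list()) {
  ev <- events[order(events$onset), , drop = FALSE]
  rownames(ev) <- NULL
  structure(list(events = ev, seed = seed, meta = meta),
            class = "input_pattern")
}

#' @export
print.input_pattern <- function(x, ...) {
  ev <- x$events
  cat("input_pattern:", nrow(ev), "events")
  if (nrow(ev)) {
    cat(sprintf(" (%d exc, %d inh), onsets %.1f-%.1f ms",
                sum(ev$kind == "exc"), sum(ev$kind == "inh"),
                min(ev$onset), max(ev$onset)))
  }
  cat("\n")
  invisible(x)
}

#' Combine input patterns
#' @param ... `input_pattern` objects
#' @return a single `input_pattern` with all events
#' @export
combine_patterns <- function(...) {
  ps <- list(...)
  ps <- ps[!vapply(ps, is.null, logical(1))]
  ev <- do.call(rbind, lapply(ps, `[[`, "events"))
  structure(list(events = ev[order(ev$onset), , drop = FALSE],
                 seed = ps[[1]]$seed, meta = ps[[1]]$meta),
            class = "input_pattern")
}

## draw n synapse sites uniformly per unit cable length within a set
.sample_sites <- function(m, cset, n) {
  if (n == 0L) return(integer(0))
  ids <- cset$node_id
  if (!length(ids)) stop("empty target with positive synapse count")
  ids[sample.int(length(ids), n, replace = TRUE, prob = cset$edge_len)]
}

#' Sample excitatory synaptic input (basal + tuft)
#'
#' Synapse locations are uniform per unit cable length over the whole basal
#' tree and over an apical tuft target (by default a randomly drawn continuous
#' 750 um stretch). Activation times are normal with shared standard deviation
#' `sigma`; the basal and tuft means are separated by `dt`, with positive `dt`
#' meaning the tuft group fires first (mean basal onset - mean tuft onset =
#' dt). Spatial and temporal draws use independent substreams of `seed`, so
#' changing only the temporal parameters leaves synapse locations untouched.
#'
#' @param m a `morphology`
#' @param n_basal,n_tuft numbers of activated excitatory synapses
#' @param sigma temporal jitter SD (ms); a single value shared by both
#'   groups (the default assumption) or `c(basal, tuft)` for per-group SDs
#' @param dt basal-minus-tuft mean onset offset (ms); > 0 = tuft first
#' @param t_ref reference mean activation time (ms)
#' @param tuft_target a `compartment_set` for the apical synapses, or NULL to
#'   draw a continuous stretch of `tuft_stretch` um with the spatial stream
#' @param tuft_stretch stretch length (um) when `tuft_target` is NULL
#' @param seed master seed (integer) or NULL to use the current RNG
#' @return an `input_pattern`; events have node_id, onset, kind ("exc"),
#'   group ("basal"/"tuft"), weight
#' @export
sample_excitatory <- function(m, n_basal, n_tuft, sigma = 10, dt = 0,
                              t_ref = 150, tuft_target = NULL,
                              tuft_stretch = 750, seed = NULL) {
  stopifnot(n_basal >= 0, n_tuft >= 0, all(sigma >= 0),
            length(sigma) %in% 1:2)
  sigma <- rep_len(sigma, 2)
  old <- .save_rng(); on.exit(.restore_rng(old))
  ## spatial stream
  if (!is.null(seed)) set.seed(derive_seed(seed, "spatial"))
  if (is.null(tuft_target) && n_tuft > 0) {
    tuft_target <- select_span(m, "tuft", "length", tuft_stretch)
  }
  basal <- .cset(m, m$nodes$id[m$nodes$region == "basal" & m$nodes$parent != -1L])
  site_b <- .sample_sites(m, basal, n_basal)
  site_t <- if (n_tuft > 0) .sample_sites(m, tuft_target, n_tuft) else integer(0)
  ## temporal stream
  if (!is.null(seed)) set.seed(derive_seed(seed, "temporal"))
  mu_b <- t_ref + dt / 2
  mu_t <- t_ref - dt / 2
  on_b <- rnorm(n_basal, mu_b, sigma[1])
  on_t <- rnorm(n_tuft, mu_t, sigma[2])
  ev <- data.frame(
    node_id = c(site_b, site_t),
    onset = c(on_b, on_t),
    kind = rep("exc", n_basal + n_tuft),
    group = rep(c("basal", "tuft"), c(n_basal, n_tuft)),
    weight = rep(1, n_basal + n_tuft))
  .pattern(ev, m, seed,
           list(n_basal = n_basal, n_tuft = n_tuft, sigma = sigma, dt = dt,
                t_ref = t_ref, tuft_target = tuft_target))
}

## inhibition locus centres (um path distance): trunk loci 1-5, tuft 6-9;
## locus 6 sits on the hotspot, locus 7 just distal ("off-path")
INHIBITION_LOCI <- c(50, 175, 300, 450, 550, 675, 800, 950, 1150)

#' Cable sites of a numbered inhibition locus
#'
#' Loci 1-5 lie on the apical trunk, loci 6-9 on the tuft (6 on the calcium
#' hotspot, 7 immediately distal to it, 8-9 progressively distal). Sites
#' extend up to `dispersion` um from the locus centre; tuft loci can be
#' restricted to one branch (the single-branch excitation configuration).
#'
#' @param m a `morphology`
#' @param locus integer 1-9
#' @param dispersion maximal path-distance offset from the centre (um)
#' @param branch optional `compartment_set` restricting tuft loci to a branch
#' @return a `compartment_set`
#' @export
locus_sites <- function(m, locus, dispersion = 100, branch = NULL) {
  stopifnot(locus %in% seq_along(INHIBITION_LOCI))
  centre <- INHIBITION_LOCI[locus]
  region <- if (centre <= m$params$trunk_length %||% 600) "trunk" else "tuft"
  s <- iso_distance_sites(m, centre, 2 * dispersion, region)
  if (!is.null(branch) && region == "tuft") {
    keep <- s$node_id %in% branch$node_id
    if (!any(keep)) stop("locus ", locus, " has no sites on the given branch")
    s <- .cset(m, s$node_id[keep])
  }
  s
}

#' Sample inhibitory synaptic input
#'
#' Twenty GABA-A synapses (1 nS peak conductance each by default) placed
#' uniformly per unit length within a locus dispersion window or an
#' iso-distance strip, with activation times normal around the excitatory
#' mean shifted by `dt_inh` (negative = inhibition first).
#'
#' @param m a `morphology`
#' @param n_inh number of inhibitory synapses
#' @param target a `compartment_set`, a locus number 1-9, or
#'   `list(distance =, window =)` for an iso-distance strip
#' @param dt_inh inhibitory-minus-excitatory mean onset offset (ms)
#' @param sigma temporal jitter SD (ms)
#' @param t_ref excitatory reference mean time (ms)
#' @param branch optional branch restriction for numbered tuft loci
#' @param seed master seed or NULL
#' @return an `input_pattern` with kind `"inh"`
#' @export
sample_inhibitory <- function(m, n_inh = 20, target = 6, dt_inh = 0,
                              sigma = 10, t_ref = 150, branch = NULL,
                              seed = NULL) {
  stopifnot(n_inh >= 0, sigma >= 0)
  cset <- if (inherits(target, "compartment_set")) target
    else if (is.numeric(target) && length(target) == 1L)
      locus_sites(m, target, branch = branch)
    else if (is.list(target))
      iso_distance_sites(m, target$distance, target$window %||% 200)
    else stop("unresolvable inhibition target")
  old <- .save_rng(); on.exit(.restore_rng(old))
  if (!is.null(seed)) set.seed(derive_seed(seed, "inhibition"))
  sites <- .sample_sites(m, cset, n_inh)
  onsets <- rnorm(n_inh, t_ref + dt_inh, sigma)
  ev <- data.frame(node_id = sites, onset = onsets,
                   kind = rep("inh", n_inh), group = rep("inh", n_inh),
                   weight = rep(1, n_inh))
  .pattern(ev, m, seed, list(n_inh = n_inh, dt_inh = dt_inh, sigma = sigma))
}

#' Sample uniform background input
#'
#' Excitatory events uniform over the dendrites and uniform in time across a
#' window (the in-vivo-like noise condition: a 600 ms window starting 100 ms
#' before the targeted activity).
#'
#' @param m a `morphology`
#' @param n_events number of background activations
#' @param duration window length (ms)
#' @param t_start window start (ms)
#' @param seed master seed or NULL
#' @return an `input_pattern`
#' @export
sample_background <- function(m, n_events, duration = 600, t_start = 50,
                              seed = NULL) {
  stopifnot(n_events >= 0, duration > 0)
  old <- .save_rng(); on.exit(.restore_rng(old))
  if (!is.null(seed)) set.seed(derive_seed(seed, "background"))
  dend <- .cset(m, m$nodes$id[m$nodes$region != "soma" & m$nodes$parent != -1L])
  sites <- .sample_sites(m, dend, n_events)
  ev <- data.frame(node_id = sites,
                   onset = runif(n_events, t_start, t_start + duration),
                   kind = rep("exc", n_events),
                   group = rep("background", n_events),
                   weight = rep(1, n_events))
  .pattern(ev, m, seed, list(n_background = n_events))
}

#' Write / read an input pattern as JSON lines
#'
#' One event per line: `{"node_id":..,"onset":..,"kind":..,"group":..,
#' "weight":..}`.
#'
#' @param pattern an `input_pattern`
#' @param path file path
#' @return `read_pattern` returns an `input_pattern`
#' @export
write_pattern <- function(pattern, path) {
  ev <- pattern$events
  lines <- vapply(seq_len(nrow(ev)), function(i)
    as.character(jsonlite::toJSON(as.list(ev[i, ]), auto_unbox = TRUE,
                                  digits = NA)),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pattern
#' @export
read_pattern <- function(path) {
  lines <- readLines(path)
  ev <- do.call(rbind, lapply(lines, function(l)
    as.data.frame(jsonlite::fromJSON(l))))
  .pattern(ev, NULL, NULL, list())
}

#' Maximum-likelihood recovery of temporal input parameters
#'
#' Estimates the shared temporal jitter `sigma` and basal-tuft offset `dt`
#' from a collection of generated patterns (pooled within-group MLE), mainly
#' a generator self-check.
#'
#' @param patterns list of `input_pattern`s from [sample_excitatory()]
#' @return list(sigma, dt)
#' @export
recover_temporal_params <- function(patterns) {
  devs <- numeric(0); diffs <- numeric(0)
  for (p in patterns) {
    ev <- p$events
    b <- ev$onset[ev$group == "basal"]
    t <- ev$onset[ev$group == "tuft"]
    devs <- c(devs, b - mean(b), t - mean(t))
    diffs <- c(diffs, mean(b) - mean(t))
  }
  list(sigma = sqrt(mean(devs^2)), dt = mean(diffs))
}
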