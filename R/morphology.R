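#' @useDynLib burstlab, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd setNames approx optim coef lm var
#' @importFrom utils head tail read.table write.csv
NULL

REGIONS <- c("soma", "axon", "basal", "trunk", "oblique", "hotspot", "tuft")

#' Default geometry of the reduced layer-5 pyramidal cell
#'
#' The reduced cell keeps the landmark path distances of a thick-tufted L5
#' pyramidal neuron: oblique branches leaving the trunk at ~100 um, the main
#' apical bifurcation (nexus) at 600 um, a calcium hotspot spanning the nexus
#' and the proximal tuft (600-750 um), and nexus-to-tip tuft branches of
#' 600 um (tips at 1200 um).
#'
#' @param n_basal number of basal branches
#' @param basal_length basal branch length (um)
#' @param basal_diam basal branch diameter (um)
#' @param trunk_length apical trunk length (um); the nexus sits at its end
#' @param trunk_diam_base,trunk_diam_tip trunk diameter taper (um)
#' @param n_oblique number of oblique branches off the trunk
#' @param oblique_attach path distance at which obliques attach (um)
#' @param oblique_length,oblique_diam oblique branch geometry (um)
#' @param n_tuft_primary number of primary tuft branches leaving the nexus
#' @param tuft_primary_length length of each primary tuft branch (um)
#' @param tuft_primary_diam diameter of primary tuft branches (um)
#' @param tuft_terminal_length length of each terminal tuft branch (um);
#'   each primary bifurcates into two terminals
#' @param tuft_terminal_diam diameter of terminal tuft branches (um)
#' @param hotspot_span path-distance interval \[um, um\] labelled as the
#'   calcium hotspot; must contain the nexus
#' @param soma_diam equivalent somatic cylinder diameter and length (um)
#' @param axon_length,axon_diam axon-equivalent process (um): a single short
#'   cable carrying the spike-initiation sodium conductance (no further
#'   axonal detail)
#' @param node_step spacing of morphology nodes along branches (um)
#' @return a list of geometry parameters
#' @export
reduced_geometry <- function(n_basal = 8, basal_length = 200, basal_diam = 1.35,
                             trunk_length = 600, trunk_diam_base = 6.5,
                             trunk_diam_tip = 5.0,
                             n_oblique = 2, oblique_attach = 100,
                             oblique_length = 150, oblique_diam = 1.0,
                             n_tuft_primary = 4, tuft_primary_length = 150,
                             tuft_primary_diam = 1.6,
                             tuft_terminal_length = 450,
                             tuft_terminal_diam = 2.2,
                             hotspot_span = c(600, 750),
                             soma_diam = 20, axon_length = 30,
                             axon_diam = 1.5, node_step = 10) {
  p <- as.list(environment())
  lens <- c(basal_length, trunk_length, oblique_length, tuft_primary_length,
            tuft_terminal_length, soma_diam, node_step)
  if (any(lens <= 0)) stop("all geometry lengths must be > 0")
  if (length(hotspot_span) != 2 || hotspot_span[1] >= hotspot_span[2])
    stop("hotspot_span must be an increasing interval")
  apical_max <- trunk_length + tuft_primary_length + tuft_terminal_length
  if (hotspot_span[1] > trunk_length || hotspot_span[2] > apical_max)
    stop("hotspot_span must intersect the nexus and lie within the apical extent")
  p
}

## lay one straight branch of `length` um starting at `origin` in direction
## `dir`, `step` um between nodes; returns node data.frame rows
.branch_nodes <- function(origin, dir, length, diam_base, diam_tip, step,
                          region, parent_id, id0, parent_dist) {
  n <- max(1L, as.integer(ceiling(length / step)))
  s <- seq_len(n) * (length / n)
  dirn <- dir / sqrt(sum(dir^2))
  frac <- s / length
  data.frame(
    id = id0 + seq_len(n) - 1L,
    parent = c(parent_id, id0 + seq_len(n - 1L) - 1L),
    x = origin[1] + dirn[1] * s,
    y = origin[2] + dirn[2] * s,
    z = origin[3] + dirn[3] * s,
    radius = (diam_base + (diam_tip - diam_base) * frac) / 2,
    region = region,
    path_dist = parent_dist + s,
    edge_len = c(s[1], diff(s))
  )
}

#' Build the reduced layer-5 pyramidal cell morphology
#'
#' Deterministically constructs the reduced branched tree: a somatic cylinder,
#' a fan of basal branches, an apical trunk with oblique branches, and a tuft
#' of primary branches that bifurcate into terminal branches. Nodes whose path
#' distance falls inside `hotspot_span` on the apical side are labelled
#' `hotspot` (the span always contains the nexus).
#'
#' @param params geometry list from [reduced_geometry()]
#' @return an object of class `morphology`: list with a `nodes` data frame
#'   (id, parent, x, y, z, radius, region, path_dist, edge_len) and the
#'   geometry `params`. The root (soma) has parent -1 and path distance 0.
#' @export
build_reduced_l5pc <- function(params = reduced_geometry()) {
  p <- params
  soma <- data.frame(id = 1L, parent = -1L, x = 0, y = 0, z = 0,
                     radius = p$soma_diam / 2, region = "soma",
                     path_dist = 0, edge_len = 0)
  nodes <- list(soma)
  id0 <- 2L

  ## axon-equivalent: a single short process for spike initiation
  ax <- .branch_nodes(c(0, 0, 0), c(0, -1, 0), p$axon_length, p$axon_diam,
                      p$axon_diam, p$node_step, "axon", 1L, id0, 0)
  nodes[[length(nodes) + 1L]] <- ax
  id0 <- id0 + nrow(ax)

  ## basal fan, pointing downwards
  for (k in seq_len(p$n_basal)) {
    ang <- pi + (k - 0.5) / p$n_basal * pi # spread under the soma
    dir <- c(cos(ang), sin(ang) - 0.2, 0.05 * k)
    b <- .branch_nodes(c(0, 0, 0), dir, p$basal_length, p$basal_diam,
                       p$basal_diam * 0.7, p$node_step, "basal", 1L, id0, 0)
    nodes[[length(nodes) + 1L]] <- b
    id0 <- id0 + nrow(b)
  }

  ## apical trunk, straight up
  tr <- .branch_nodes(c(0, 0, 0), c(0, 1, 0), p$trunk_length,
                      p$trunk_diam_base, p$trunk_diam_tip, p$node_step,
                      "trunk", 1L, id0, 0)
  id0 <- id0 + nrow(tr)
  nexus_id <- tr$id[nrow(tr)]
  nexus_dist <- tr$path_dist[nrow(tr)]
  ## oblique attach node: nearest trunk node to the attach distance
  oi <- which.min(abs(tr$path_dist - p$oblique_attach))
  nodes[[length(nodes) + 1L]] <- tr

  for (k in seq_len(p$n_oblique)) {
    ang <- if (k %% 2 == 0) 0.25 * pi else 0.75 * pi
    dir <- c(cos(ang) * ifelse(k %% 2 == 0, 1, -1), 0.4, 0.1)
    ob <- .branch_nodes(c(tr$x[oi], tr$y[oi], tr$z[oi]), dir,
                        p$oblique_length, p$oblique_diam, p$oblique_diam * 0.8,
                        p$node_step, "oblique", tr$id[oi], id0, tr$path_dist[oi])
    nodes[[length(nodes) + 1L]] <- ob
    id0 <- id0 + nrow(ob)
  }

  ## tuft: primaries from the nexus, each bifurcating into two terminals
  nexus_xyz <- c(tr$x[nrow(tr)], tr$y[nrow(tr)], tr$z[nrow(tr)])
  for (k in seq_len(p$n_tuft_primary)) {
    ang <- (k - 0.5) / p$n_tuft_primary * pi
    dir <- c(cos(ang), 0.8, 0.1 * (k - 2))
    pr <- .branch_nodes(nexus_xyz, dir, p$tuft_primary_length,
                        p$tuft_primary_diam, p$tuft_primary_diam * 0.9,
                        p$node_step, "tuft", nexus_id, id0, nexus_dist)
    id0 <- id0 + nrow(pr)
    nodes[[length(nodes) + 1L]] <- pr
    pr_tip <- nrow(pr)
    for (j in 1:2) {
      tang <- ang + (j - 1.5) * 0.5
      tdir <- c(cos(tang), 1.0, 0.05 * j)
      te <- .branch_nodes(c(pr$x[pr_tip], pr$y[pr_tip], pr$z[pr_tip]), tdir,
                          p$tuft_terminal_length, p$tuft_terminal_diam,
                          p$tuft_terminal_diam * 0.8, p$node_step, "tuft",
                          pr$id[pr_tip], id0, pr$path_dist[pr_tip])
      id0 <- id0 + nrow(te)
      nodes[[length(nodes) + 1L]] <- te
    }
  }

  nd <- do.call(rbind, nodes)
  rownames(nd) <- NULL
  ## hotspot label: apical-side nodes within the span
  apical <- nd$region %in% c("trunk", "tuft")
  hs <- apical & nd$path_dist >= p$hotspot_span[1] - 1e-9 &
    nd$path_dist <= p$hotspot_span[2] + 1e-9
  nd$region[hs] <- "hotspot"
  m <- structure(list(nodes = nd, params = p, nexus_id = nexus_id),
                 class = "morphology")
  validate_morphology(m)
  m
}

#' Validate a morphology object
#'
#' Checks the tree invariants: a single root, acyclic parent links, strictly
#' increasing path distance away from the soma, known region labels, and a
#' contiguous hotspot containing the nexus (if any hotspot nodes exist).
#'
#' @param m a `morphology`
#' @return `m`, invisibly; errors on violation
#' @export
validate_morphology <- function(m) {
  nd <- m$nodes
  if (sum(nd$parent == -1L) != 1L) stop("morphology must have exactly one root")
  if (nd$region[nd$parent == -1L] != "soma") stop("root must be the soma")
  if (!all(nd$region %in% REGIONS)) stop("unknown region label")
  idx <- match(nd$parent, nd$id)
  bad <- which(nd$parent != -1L & is.na(idx))
  if (length(bad)) stop("node ", nd$id[bad[1]], " has unknown parent")
  ## cycle check + path distance monotonicity via one sweep
  has_par <- nd$parent != -1L
  if (any(nd$parent[has_par] == nd$id[has_par])) stop("node is its own parent")
  depth <- rep.int(NA_integer_, nrow(nd))
  depth[nd$parent == -1L] <- 0L
  remaining <- which(has_par)
  for (pass in seq_len(nrow(nd))) {
    if (!length(remaining)) break
    ready <- remaining[!is.na(depth[idx[remaining]])]
    if (!length(ready)) stop("cycle detected in parent links")
    depth[ready] <- depth[idx[ready]] + 1L
    remaining <- setdiff(remaining, ready)
  }
  pd <- nd$path_dist
  if (abs(pd[nd$parent == -1L]) > 1e-9) stop("soma path distance must be 0")
  if (any(pd[has_par] <= pd[idx[has_par]]))
    stop("path distance must strictly increase from the soma")
  err <- abs(pd[has_par] - (pd[idx[has_par]] + nd$edge_len[has_par]))
  if (any(err > 1e-6)) stop("path distance must equal parent distance + edge length")
  hs <- which(nd$region == "hotspot")
  if (length(hs)) {
    ## contiguity: every hotspot node's parent is hotspot or trunk-adjacent
    par_reg <- nd$region[idx[hs]]
    if (!all(par_reg %in% c("hotspot", "trunk")))
      stop("hotspot nodes must form a contiguous apical set")
  }
  invisible(m)
}

#' @export
print.morphology <- function(x, ...) {
  nd <- x$nodes
  cat("Reduced L5PC morphology:", nrow(nd), "nodes,",
      sprintf("%.0f um total cable\n", sum(nd$edge_len)))
  tab <- tapply(nd$edge_len, nd$region, sum)
  for (r in intersect(REGIONS, names(tab)))
    cat(sprintf("  %-8s %8.0f um\n", r, tab[[r]]))
  cat(sprintf("  nexus at %.0f um; max path distance %.0f um\n",
              nd$path_dist[nd$id == x$nexus_id], max(nd$path_dist)))
  invisible(x)
}

## region name -> vector of node labels; "tuft" means the tuft subtree,
## which includes the hotspot span
resolve_region <- function(region) {
  out <- unlist(lapply(region, function(r) switch(r,
    apical = c("trunk", "oblique", "hotspot", "tuft"),
    tuft = c("hotspot", "tuft"),
    dendrites = c("basal", "trunk", "oblique", "hotspot", "tuft"),
    all = REGIONS,
    r)))
  if (!all(out %in% REGIONS)) stop("unknown region: ",
                                   paste(setdiff(out, REGIONS), collapse = ", "))
  unique(out)
}

#' Total cable length of a region
#' @param m a `morphology`
#' @param region region name(s); `"tuft"` includes the hotspot span,
#'   `"apical"` = trunk + obliques + tuft, `"dendrites"` = everything but soma
#' @return length in um
#' @export
region_length <- function(m, region) {
  labs <- resolve_region(region)
  sum(m$nodes$edge_len[m$nodes$region %in% labs])
}

.cset <- function(m, ids) {
  nd <- m$nodes
  sel <- nd[match(ids, nd$id), , drop = FALSE]
  structure(list(node_id = sel$id, edge_len = sel$edge_len,
                 path_dist = sel$path_dist,
                 total_length = sum(sel$edge_len)),
            class = "compartment_set")
}

#' @export
print.compartment_set <- function(x, ...) {
  cat(sprintf("compartment_set: %d segments, %.1f um total, path %.0f-%.0f um\n",
              length(x$node_id), x$total_length,
              min(x$path_dist - x$edge_len), max(x$path_dist)))
  invisible(x)
}

## children list keyed by node id
.children_map <- function(nd) split(nd$id, factor(nd$parent, levels = nd$id))

#' Select a continuous cable stretch within a region
#'
#' Draws a topologically continuous stretch (a connected subtree segment) of a
#' requested total cable length inside a region, as used to place clustered
#' excitatory input on part of the apical tuft. The start segment is drawn
#' uniformly per unit length; the stretch then grows segment by segment,
#' choosing uniformly at random among adjacent in-region segments whenever the
#' growth front branches.
#'
#' @param m a `morphology`
#' @param region region name (see [region_length()])
#' @param mode `"length"` (um), `"fraction"` (of the region's cable), or
#'   `"named_branch"` (one nexus-to-tip tuft path)
#' @param value stretch length in um (`"length"`) or fraction in (0, 1\]
#' @param rng an integer seed for the draw, or NULL to use the current RNG
#' @return a `compartment_set` (segments = morphology edges, identified by
#'   their child node id)
#' @export
select_span <- function(m, region = "tuft", mode = c("length", "fraction",
                                                     "named_branch"),
                        value = NULL, rng = NULL) {
  mode <- match.arg(mode)
  if (!is.null(rng)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(rng)
  }
  nd <- m$nodes
  labs <- resolve_region(region)
  in_reg <- nd$region %in% labs & nd$parent != -1L
  ids <- nd$id[in_reg]
  if (!length(ids)) stop("empty region")
  total <- sum(nd$edge_len[in_reg])

  if (mode == "named_branch") {
    ## one nexus-to-tip path through the tuft
    kids <- .children_map(nd)
    tips <- ids[!(ids %in% nd$parent)]
    tip <- if (length(tips) > 1L) tips[sample.int(length(tips), 1L)] else tips
    path <- integer(0)
    cur <- tip
    repeat {
      path <- c(path, cur)
      par <- nd$parent[match(cur, nd$id)]
      if (par == -1L || !(par %in% ids)) break
      cur <- par
    }
    path <- setdiff(path, m$nexus_id) # the nexus edge belongs to the trunk
    return(.cset(m, rev(path)))
  }

  target <- switch(mode,
                   length = value,
                   fraction = value * total)
  if (is.null(target) || target <= 0) stop("value must be positive")
  if (target > total + 1e-6)
    stop(sprintf("requested length %.0f um exceeds region total %.0f um",
                 target, total))
  if (target >= total - 1e-6) return(.cset(m, ids)) # whole region
  ## start edge uniform per unit length; grow a connected set, preferring
  ## in-region segments and bridging silently through off-region nodes
  ## (e.g. the soma between sibling basal branches) when the front empties
  w <- nd$edge_len[in_reg]
  start <- ids[sample.int(length(ids), 1L, prob = w)]
  visited <- logical(max(nd$id) + 1L)
  in_set <- logical(max(nd$id) + 1L)
  kids <- .children_map(nd)
  neighbours <- function(id) {
    par <- nd$parent[match(id, nd$id)]
    c(if (par > 0L) par, kids[[as.character(id)]])
  }
  visited[start] <- TRUE; in_set[start] <- TRUE
  len <- nd$edge_len[match(start, nd$id)]
  frontier <- setdiff(neighbours(start), which(visited))
  while (len < target - 1e-9 && length(frontier)) {
    cand_reg <- frontier[frontier %in% ids]
    pool <- if (length(cand_reg)) cand_reg else frontier
    nxt <- if (length(pool) > 1L) pool[sample.int(length(pool), 1L)] else pool
    visited[nxt] <- TRUE
    if (nxt %in% ids) {
      in_set[nxt] <- TRUE
      len <- len + nd$edge_len[match(nxt, nd$id)]
    }
    frontier <- unique(c(setdiff(frontier, nxt), neighbours(nxt)))
    frontier <- frontier[!visited[frontier]]
  }
  .cset(m, nd$id[in_set[nd$id]])
}

#' Segments at a fixed path distance from the soma
#'
#' Returns all cable segments whose path distance falls within
#' `distance ± window/2`, across all branches: an iso-distance strip, as used
#' to distribute inhibition at a fixed distance from the soma.
#'
#' @param m a `morphology`
#' @param distance target path distance (um)
#' @param window strip width (um)
#' @param region optional region restriction (default: all dendrites)
#' @return a `compartment_set`
#' @export
iso_distance_sites <- function(m, distance, window = 200, region = "dendrites") {
  nd <- m$nodes
  if (distance <= 0 || distance >= max(nd$path_dist)) {
    stop(sprintf("distance %.0f um outside the tree (max %.0f um)",
                 distance, max(nd$path_dist)))
  }
  labs <- resolve_region(region)
  mid <- nd$path_dist - nd$edge_len / 2
  sel <- nd$parent != -1L & nd$region %in% labs &
    mid >= distance - window / 2 & mid <= distance + window / 2
  if (!any(sel)) {
    stop(sprintf(
      "no cable at %.0f +/- %.0f um; populated distances span %.0f-%.0f um",
      distance, window / 2, min(mid[nd$parent != -1L]), max(mid)))
  }
  .cset(m, nd$id[sel])
}

## ---- SWC I/O -------------------------------------------------------------

SWC_TYPE <- c(soma = 1L, axon = 2L, basal = 3L, trunk = 4L, oblique = 4L,
              hotspot = 4L, tuft = 4L)

#' Write a morphology to SWC text
#'
#' Standard 7-column SWC (id, type, x, y, z, radius, parent). Type codes:
#' 1 = soma, 3 = basal dendrite, 4 = apical dendrite. Because SWC type codes
#' cannot distinguish trunk/oblique/hotspot/tuft, the full region labels are
#' written to a JSON sidecar when `labels_path` is given (and embedded as a
#' header comment otherwise).
#'
#' @param m a `morphology`
#' @param path optional file to write; if NULL the text is only returned
#' @param labels_path optional JSON sidecar file for region labels
#' @return SWC text, invisibly when writing to a file
#' @export
write_swc <- function(m, path = NULL, labels_path = NULL) {
  nd <- m$nodes
  lines <- sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                   nd$id, SWC_TYPE[nd$region], nd$x, nd$y, nd$z, nd$radius,
                   nd$parent)
  hdr <- "# SWC reduced L5PC (burstlab); columns: id type x y z radius parent"
  if (is.null(labels_path)) {
    lab <- paste0("# regions: ",
                  jsonlite::toJSON(setNames(as.list(nd$region),
                                            as.character(nd$id)),
                                   auto_unbox = TRUE))
    txt <- paste(c(hdr, lab, lines), collapse = "\n")
  } else {
    jsonlite::write_json(setNames(as.list(nd$region), as.character(nd$id)),
                         labels_path, auto_unbox = TRUE)
    txt <- paste(c(hdr, lines), collapse = "\n")
  }
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a morphology from SWC
#'
#' Accepts a file path or SWC text. Region labels come from a JSON sidecar
#' (`labels`, a file path or named character vector), from an embedded
#' `# regions:` header comment, or failing those from the SWC type code table
#' (1 = soma, 3 = basal, 4 = apical trunk refined by the hotspot span of the
#' default geometry only when labels are absent: plain `trunk`).
#'
#' @param source file path or character SWC content
#' @param labels optional sidecar: JSON path or named character vector
#' @return a `morphology`
#' @export
read_swc <- function(source, labels = NULL) {
  txt <- if (length(source) == 1L && !grepl("\n", source) && file.exists(source))
    readLines(source) else strsplit(paste(source, collapse = "\n"), "\n")[[1]]
  lab_map <- NULL
  if (is.null(labels)) {
    lab_line <- grep("^# regions: ", txt, value = TRUE)
    if (length(lab_line)) {
      lab_map <- unlist(jsonlite::fromJSON(sub("^# regions: ", "", lab_line[1])))
    }
  } else if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
    lab_map <- unlist(jsonlite::fromJSON(labels))
  } else {
    lab_map <- labels
  }
  body <- which(!grepl("^\\s*(#|$)", txt))
  if (!length(body)) stop("no SWC records found")
  rows <- lapply(body, function(i) {
    f <- strsplit(trimws(txt[i]), "\\s+")[[1]]
    if (length(f) != 7L)
      stop("line ", i, ": expected 7 SWC columns, found ", length(f))
    v <- suppressWarnings(as.numeric(f))
    if (any(is.na(v))) stop("line ", i, ": non-numeric SWC field")
    v
  })
  sw <- do.call(rbind, rows)
  id <- as.integer(sw[, 1]); parent <- as.integer(sw[, 7])
  if (anyDuplicated(id)) stop("duplicate SWC node id")
  if (any(parent == id)) {
    bad <- body[which(parent == id)[1]]
    stop("line ", bad, ": node is its own parent")
  }
  known <- parent == -1L | parent %in% id
  if (!all(known)) stop("line ", body[which(!known)[1]], ": unknown parent id ",
                        parent[!known][1])
  region <- if (!is.null(lab_map)) {
    unname(lab_map[as.character(id)])
  } else {
    c("soma", "axon", "basal", "trunk")[match(sw[, 2], c(1, 2, 3, 4))]
  }
  if (any(is.na(region))) stop("missing region label for some nodes")
  nd <- data.frame(id = id, parent = parent, x = sw[, 3], y = sw[, 4],
                   z = sw[, 5], radius = sw[, 6], region = region)
  ## edge lengths and path distances from coordinates
  pidx <- match(nd$parent, nd$id)
  nd$edge_len <- ifelse(is.na(pidx), 0,
                        sqrt((nd$x - nd$x[pidx])^2 + (nd$y - nd$y[pidx])^2 +
                             (nd$z - nd$z[pidx])^2))
  if (any(nd$edge_len[!is.na(pidx)] <= 0))
    stop("zero-length edge (coincident parent/child nodes)")
  ## accumulate path distance root-down
  nd$path_dist <- rep(NA_real_, nrow(nd))
  root <- which(nd$parent == -1L)
  if (length(root) != 1L) stop("SWC must contain exactly one root")
  nd$path_dist[root] <- 0
  remaining <- setdiff(seq_len(nrow(nd)), root)
  while (length(remaining)) {
    ready <- remaining[!is.na(nd$path_dist[pidx[remaining]])]
    if (!length(ready)) stop("cyclic or orphaned SWC nodes")
    nd$path_dist[ready] <- nd$path_dist[pidx[ready]] + nd$edge_len[ready]
    remaining <- setdiff(remaining, ready)
  }
  nexus_id <- {
    tk <- nd$id[nd$region %in% c("trunk", "hotspot")]
    if (length(tk)) tk[which.max(nd$path_dist[match(tk, nd$id)] *
                                   (nd$region[match(tk, nd$id)] != "hotspot") +
                                   0)] else nd$id[root]
  }
  ## nexus: deepest trunk node
  tk <- which(nd$region == "trunk")
  nexus_id <- if (length(tk)) nd$id[tk[which.max(nd$path_dist[tk])]] else nd$id[root]
  m <- structure(list(nodes = nd, params = NULL, nexus_id = nexus_id),
                 class = "morphology")
  validate_morphology(m)
  m
}

## ---- discretization ------------------------------------------------------

#' Discretize a morphology into electrical compartments
#'
#' Splits every unbranched section into compartments no longer than `max_seg`
#' (equal length within a section), computing per-compartment membrane area
#' and half-segment axial resistance factors from the cylinder geometry. A
#' node-to-compartment map is retained so synapse placements expressed on
#' morphology segments resolve to compartments.
#'
#' @param m a `morphology`
#' @param max_seg maximum compartment length (um), default 20
#' @return a `cable_model`: list with `comp` data frame (parent, length, diam,
#'   area, path_dist, region), `comp_of_node` (index per morphology node id),
#'   and the morphology
#' @export
discretize <- function(m, max_seg = 20) {
  if (max_seg <= 0) stop("max_seg must be > 0")
  nd <- m$nodes
  pidx <- match(nd$parent, nd$id)
  nkids <- table(factor(nd$parent, levels = nd$id))
  is_branch <- as.integer(nkids[as.character(nd$id)]) != 1L
  is_branch[is.na(is_branch)] <- TRUE

  ## sections: maximal unbranched chains of edges (start after root/branchpoint)
  ## walk from each section head down to the next branch point
  heads <- which(nd$parent != -1L &
                   (nd$parent == nd$id[1] | is_branch[pidx] | pidx == 1L))
  ## a node starts a section if its parent is the root or a branch point
  starts <- which(nd$parent != -1L & (is.na(pidx) | is_branch[pidx]))
  sec_of <- integer(nrow(nd)); sec_of[] <- NA_integer_
  sections <- list()
  for (s in starts) {
    chain <- s
    cur <- s
    repeat {
      kid_ids <- nd$id[which(!is.na(pidx) & pidx == cur)]
      if (length(kid_ids) != 1L) break
      nxt <- match(kid_ids, nd$id)
      chain <- c(chain, nxt)
      cur <- nxt
    }
    sections[[length(sections) + 1L]] <- chain
    sec_of[chain] <- length(sections)
  }

  comp <- list()
  comp_of_node <- integer(nrow(nd))
  comp_of_node[1] <- 1L # soma node -> compartment 1
  ## soma compartment
  sd <- nd$radius[1] * 2
  comp[[1]] <- data.frame(parent = 0L, length = sd, diam = sd,
                          area = pi * sd * sd, path_dist = 0, region = "soma",
                          r_half = (sd / 2) / (pi * (sd / 2)^2))
  ncomp <- 1L
  sec_first_comp <- integer(length(sections))
  sec_last_comp <- integer(length(sections))

  for (si in seq_along(sections)) {
    chain <- sections[[si]]
    L <- sum(nd$edge_len[chain])
    nseg <- max(1L, as.integer(ceiling(L / max_seg - 1e-9)))
    seg_len <- L / nseg
    ## cumulative arc position of each node end within the section
    ends <- cumsum(nd$edge_len[chain])
    seg_idx <- pmin(nseg, pmax(1L, as.integer(ceiling(
      (ends - nd$edge_len[chain] / 2) / seg_len))))
    par_node <- pidx[chain[1]]
    base_dist <- nd$path_dist[par_node]
    for (k in seq_len(nseg)) {
      memb <- chain[seg_idx == k]
      if (!length(memb)) memb <- chain[which.min(abs(ends - (k - 0.5) * seg_len))]
      dmean <- mean(nd$radius[memb]) * 2
      parent_comp <- if (k == 1L) comp_of_node[par_node] else ncomp
      ncomp <- ncomp + 1L
      comp[[ncomp]] <- data.frame(
        parent = parent_comp, length = seg_len, diam = dmean,
        area = pi * dmean * seg_len,
        path_dist = base_dist + (k - 0.5) * seg_len,
        region = nd$region[memb[length(memb)]],
        r_half = (seg_len / 2) / (pi * (dmean / 2)^2))
      comp_of_node[memb] <- ncomp
      if (k == 1L) sec_first_comp[si] <- ncomp
    }
    sec_last_comp[si] <- ncomp
  }
  cp <- do.call(rbind, comp)
  rownames(cp) <- NULL
  structure(list(comp = cp, comp_of_node = comp_of_node, morphology = m,
                 max_seg = max_seg),
            class = "cable_model")
}

#' @export
print.cable_model <- function(x, ...) {
  cat("cable_model:", nrow(x$comp), "compartments (max_seg",
      x$max_seg, "um)\n")
  invisible(x)
}

#' Map a compartment set to cable-model compartment indices
#'
#' @param cable a `cable_model`
#' @param cset a `compartment_set` (or vector of morphology node ids)
#' @return integer compartment indices (one per segment)
#' @export
compartments_of <- function(cable, cset) {
  ids <- if (inherits(cset, "compartment_set")) cset$node_id else cset
  cable$comp_of_node[match(ids, cable$morphology$nodes$id)]
}

## RNG save/restore helpers (keep user RNG untouched when a seed is supplied)
.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
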