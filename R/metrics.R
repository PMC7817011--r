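#' Vascular-network graph over visited voxels
#'
#' Builds the graph whose nodes are the given voxels (typically every voxel
#' ever occupied by a cell up to some time) and whose edges are the
#' hexagonal-lattice adjacencies among them, each of length `h` micrometres.
#' Distances within this graph are the "network manifold" distances used by
#' the mixing measure.
#'
#' @param lattice a [hex_lattice()].
#' @param nodes voxel indices.
#' @return an `igraph` graph; vertex attribute `voxel` holds the voxel
#'   index, edge attribute `weight` the edge length in micrometres.
#' @export
network_graph <- function(lattice, nodes) {
  nodes <- sort(unique(as.integer(nodes)))
  idx <- integer(lattice$n)
  idx[nodes] <- seq_along(nodes)
  from <- integer(0); to <- integer(0)
  for (s in 1:6) {
    nb <- lattice$nbr[nodes, s]
    ok <- !is.na(nb) & idx[ifelse(is.na(nb), 1L, nb)] > 0 & nb > nodes
    from <- c(from, idx[nodes[ok]])
    to <- c(to, idx[nb[ok]])
  }
  g <- igraph::make_graph(rbind(from, to), n = length(nodes), directed = FALSE)
  igraph::V(g)$voxel <- nodes
  igraph::E(g)$weight <- rep(lattice$h, igraph::ecount(g))
  g
}

#' Network graph of a simulation
#'
#' Nodes are all voxels visited by any cell up to time `t` (from the
#' trajectory log), edges the lattice adjacencies among them.
#'
#' @param sim an `angio_sim` (or a trajectory-log data frame via `log`).
#' @param t time cutoff (default: all times).
#' @param log optionally a trajectory log data frame instead of `sim`.
#' @export
simulation_network <- function(sim = NULL, t = Inf, log = NULL) {
  if (is.null(log)) log <- trajectory_log(sim)
  lattice <- sim$setup$lattice
  network_graph(lattice, log$voxel[log$t <= t])
}

#' Network (manifold) distance between two voxels
#'
#' Shortest-path distance within the vascular network graph, in
#' micrometres; `Inf` when the voxels lie in disconnected components.
#'
#' @param network an igraph from [network_graph()].
#' @param i,j voxel indices (must be network nodes).
#' @export
network_distance <- function(network, i, j) {
  vi <- match(i, igraph::V(network)$voxel)
  vj <- match(j, igraph::V(network)$voxel)
  if (is.na(vi) || is.na(vj)) stop("voxel is not a network node")
  as.numeric(igraph::distances(network, v = vi, to = vj))
}

# all-pairs voxel distances within the network (matrix indexed by voxel id)
network_distance_matrix <- function(network) {
  d <- igraph::distances(network)
  rownames(d) <- colnames(d) <- igraph::V(network)$voxel
  d
}

#' Per-cell displacement distribution
#'
#' Euclidean displacement of every cell over disjoint windows of
#' `window_min` minutes, pooled over cells (and over realisations when logs
#' are concatenated).
#'
#' @param log a trajectory log (see [trajectory_log()]); logs of several
#'   realisations may be row-bound if their `label`s are disambiguated.
#' @param window_min window length in minutes (default 15).
#' @param minutes_per_unit time-unit conversion (default 500).
#' @return numeric vector of displacements (micrometres), one per
#'   cell-window.
#' @export
displacement_histogram <- function(log, window_min = 15,
                                   minutes_per_unit = 500) {
  w <- window_min / minutes_per_unit
  times <- sort(unique(log$t))
  if (length(times) > 1) {
    dt <- min(diff(times))
    if (w < dt - 1e-9 || abs(w / dt - round(w / dt)) > 1e-6)
      stop("window must be a multiple of the sampling interval")
  }
  out <- c()
  for (lb in unique(log$label)) {
    tr <- log[log$label == lb, ]
    tr <- tr[order(tr$t), ]
    k <- floor((tr$t - tr$t[1]) / w + 1e-9)
    first <- !duplicated(k)
    xs <- tr$x[first]; ys <- tr$y[first]
    if (length(xs) > 1)
      out <- c(out, sqrt(diff(xs)^2 + diff(ys)^2))
  }
  out
}

#' Trajectory orientation (persistence) statistic
#'
#' Per cell, the ratio of the length of a smoothed trajectory (moving
#' average of the positions) to the actual path length; straight persistent
#' paths give values near 1, tortuous paths smaller values.  Cells with
#' zero path length are excluded.
#'
#' @param log a trajectory log.
#' @param k smoothing window (odd, default 3 samples).
#' @return named numeric vector of per-cell ratios in (0, 1].
#' @export
orientation_statistic <- function(log, k = 3) {
  stopifnot(k >= 1)
  res <- c()
  for (lb in unique(log$label)) {
    tr <- log[log$label == lb, ]
    tr <- tr[order(tr$t), ]
    if (nrow(tr) < 2) next
    path <- sum(sqrt(diff(tr$x)^2 + diff(tr$y)^2))
    if (path == 0) next
    if (nrow(tr) <= k) {              # too short to smooth: net displacement
      net <- sqrt((tr$x[nrow(tr)] - tr$x[1])^2 + (tr$y[nrow(tr)] - tr$y[1])^2)
      res <- c(res, structure(min(1, net / path), names = lb))
      next
    }
    xs <- as.numeric(stats::filter(tr$x, rep(1 / k, k), sides = 2))
    ys <- as.numeric(stats::filter(tr$y, rep(1 / k, k), sides = 2))
    na <- is.na(xs)                       # partial windows at the ends
    xs[na] <- tr$x[na]; ys[na] <- tr$y[na]
    sm <- sum(sqrt(diff(xs)^2 + diff(ys)^2))
    res <- c(res, structure(min(1, sm / path), names = lb))
  }
  res
}

#' Directionality of cell movement relative to sprout elongation
#'
#' Classifies each cell-window as anterograde (moving with the local sprout
#' elongation direction), retrograde (against it) or still (net displacement
#' below `h/2`).  The elongation direction at a cell is the unit vector from
#' the sprout base to the cell's position; the base is the nearest voxel of
#' `base_voxels` (by Euclidean distance), by default the voxels occupied at
#' the first sample time.
#'
#' @param log a trajectory log.
#' @param lattice the [hex_lattice()] of the simulation.
#' @param window_min window length in minutes (default 20).
#' @param base_voxels voxel indices of the sprout base / vascular plexus.
#' @param exclude_base skip windows that start on a base voxel (cells
#'   resident in the vascular bed have no sprout-elongation direction).
#' @param minutes_per_unit time-unit conversion.
#' @return list with `proportions` (named: anterograde, retrograde, still)
#'   and `n` (number of cell-windows).
#' @export
directionality <- function(log, lattice, window_min = 20,
                           base_voxels = NULL, exclude_base = TRUE,
                           minutes_per_unit = 500) {
  w <- window_min / minutes_per_unit
  if (is.null(base_voxels)) base_voxels <- unique(log$voxel[log$t == min(log$t)])
  bx <- lattice$centers[base_voxels, 1]
  by <- lattice$centers[base_voxels, 2]
  h <- lattice$h
  counts <- c(anterograde = 0, retrograde = 0, still = 0)
  for (lb in unique(log$label)) {
    tr <- log[log$label == lb, ]
    tr <- tr[order(tr$t), ]
    k <- floor((tr$t - tr$t[1]) / w + 1e-9)
    first <- !duplicated(k)
    xs <- tr$x[first]; ys <- tr$y[first]
    if (length(xs) < 2) next
    for (q in seq_len(length(xs) - 1)) {
      dx <- xs[q + 1] - xs[q]; dy <- ys[q + 1] - ys[q]
      nb <- which.min((bx - xs[q])^2 + (by - ys[q])^2)
      ex <- xs[q] - bx[nb]; ey <- ys[q] - by[nb]
      at_base <- sqrt(ex^2 + ey^2) < h / 2
      if (exclude_base && at_base) next
      if (sqrt(dx^2 + dy^2) < h / 2) {
        counts["still"] <- counts["still"] + 1
      } else {
        if (at_base) { ex <- dx; ey <- dy }
        cls <- if (dx * ex + dy * ey >= 0) "anterograde" else "retrograde"
        counts[cls] <- counts[cls] + 1
      }
    }
  }
  n <- sum(counts)
  list(proportions = if (n > 0) counts / n else counts * NA, n = n)
}

#' Tip-cell proportion at a time point
#'
#' Fraction of cells in the tip phenotype (Delta at or above the baseline
#' expression) at the sample time nearest to `t`.
#'
#' @param log a trajectory log.
#' @param t time point.
#' @return proportion in `[0, 1]`, or `NA` when no cells are present.
#' @export
tip_proportion <- function(log, t) {
  ts <- unique(log$t)
  tt <- ts[which.min(abs(ts - t))]
  ph <- log$phenotype[log$t == tt]
  if (!length(ph)) return(NA_real_)
  mean(ph == "tip")
}

#' Mixing measure
#'
#' Quantifies cell rearrangement: for all unordered pairs of cells that
#' occupy the cluster voxels at time `t`, the change in their pairwise
#' network (manifold) distance over the lag `t_m`, summed and normalised by
#' the cluster size and by the maximum pairwise network distance among cells
#' at the final time.
#'
#' @param log a trajectory log.
#' @param network the vascular network graph (e.g. [simulation_network()]
#'   at the final time); pairwise distances are measured within it.
#' @param cluster voxel indices of the initial cluster.
#' @param t reference time.
#' @param t_m lag (time units; default 0.4, i.e. 200 minutes).
#' @param d_max optional normalising distance; by default the maximum
#'   pairwise network distance among cells at the last sample time.
#' @return the mixing measure (scalar), or `NA` when fewer than two cluster
#'   cells are present or the normalisation is degenerate.
#' @export
mixing_measure <- function(log, network, cluster, t, t_m = 0.4, d_max = NULL) {
  ts <- sort(unique(log$t))
  t0 <- ts[which.min(abs(ts - t))]
  t1 <- ts[which.min(abs(ts - (t + t_m)))]
  dm <- network_distance_matrix(network)
  vox_chr <- function(v) as.character(v)
  if (is.null(d_max)) {
    vf <- log$voxel[log$t == max(ts)]
    dd <- dm[vox_chr(vf), vox_chr(vf)]
    d_max <- max(dd[is.finite(dd)])
  }
  if (!is.finite(d_max) || d_max <= 0) return(NA_real_)
  at0 <- log[log$t == t0 & log$voxel %in% cluster, ]
  if (nrow(at0) < 2) return(NA_real_)
  at1 <- log[log$t == t1, ]
  total <- 0
  labs <- at0$label
  for (a in seq_len(length(labs) - 1)) for (b in (a + 1):length(labs)) {
    va0 <- at0$voxel[a]; vb0 <- at0$voxel[b]
    va1 <- at1$voxel[match(labs[a], at1$label)]
    vb1 <- at1$voxel[match(labs[b], at1$label)]
    if (is.na(va1) || is.na(vb1)) next
    total <- total + (dm[vox_chr(va1), vox_chr(vb1)] -
                      dm[vox_chr(va0), vox_chr(vb0)])
  }
  total / (length(cluster) * d_max)
}

#' Topological thinning of a voxel network
#'
#' Reduces a (possibly several voxels wide) set of network voxels to a
#' one-voxel-wide skeleton by iteratively deleting boundary voxels whose
#' occupied-neighbour pattern forms a single contiguous arc (deletion then
#' preserves local connectivity); endpoint voxels are never deleted, so
#' sprout tips survive.  Thin networks are returned unchanged.
#'
#' @param lattice a [hex_lattice()].
#' @param nodes voxel indices of the network.
#' @return the skeleton voxel indices (a subset of `nodes`).
#' @export
skeletonize_network <- function(lattice, nodes) {
  inset <- logical(lattice$n)
  inset[nodes] <- TRUE
  repeat {
    removed <- FALSE
    for (v in which(inset)) {
      nb <- lattice$nbr[v, ]
      pat <- ifelse(is.na(nb), FALSE, inset[ifelse(is.na(nb), 1L, nb)])
      deg <- sum(pat)
      if (deg < 2 || deg > 5) next
      trans <- sum(pat != pat[c(2:6, 1)]) / 2   # contiguous-arc condition
      if (trans == 1) {
        inset[v] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  which(inset)
}

#' Vascular-network morphometrics
#'
#' Skeleton statistics of the network graph: branching points (nodes with
#' at least three incident segments of length >= 2 voxel widths, which
#' prunes spurious junctions created by single-voxel bumps), segments
#' (maximal paths between branching points and tips), their lengths, the
#' network area (voxel count times voxel area) and branching points per
#' 100 square micrometres of network area.
#'
#' When a `lattice` is supplied the node set is first reduced to its
#' one-voxel-wide skeleton (see [skeletonize_network()]): simulated networks
#' can be several voxels wide, and branch/segment statistics are properties
#' of the centreline.  The network area always counts the full node set.
#'
#' @param network an igraph from [network_graph()].
#' @param h voxel width (micrometres).
#' @param lattice optional [hex_lattice()]; enables skeletonization.
#' @return list with `n_branch_points`, `n_segments`, `segment_lengths`
#'   (micrometres), `network_area` (square micrometres) and
#'   `branch_points_per_100um2`.
#' @export
network_morphometrics <- function(network, h = 10, lattice = NULL) {
  nv <- igraph::vcount(network)
  if (nv == 0) stop("empty network")
  area <- nv * sqrt(3) / 2 * h^2
  if (!is.null(lattice)) {
    skel <- skeletonize_network(lattice, igraph::V(network)$voxel)
    network <- network_graph(lattice, skel)
  }
  deg <- igraph::degree(network)
  junctions <- which(deg >= 3)
  # trace maximal paths whose interior nodes have degree 2
  endpoints <- which(deg != 2)
  segs <- list()
  visited_edge <- rep(FALSE, igraph::ecount(network))
  for (v in endpoints) {
    for (e in igraph::incident(network, v)) {
      if (visited_edge[e]) next
      len <- 0L
      prev <- v
      cur_e <- e
      repeat {
        visited_edge[cur_e] <- TRUE
        len <- len + 1L
        ends <- igraph::ends(network, cur_e)[1, ]
        nxt <- if (ends[1] == prev) ends[2] else ends[1]
        if (deg[nxt] != 2) break
        nes <- igraph::incident(network, nxt)
        cur_e <- nes[!visited_edge[nes]][1]
        if (is.na(cur_e)) break
        prev <- nxt
      }
      segs[[length(segs) + 1]] <- list(from = v, to = nxt, len = len)
    }
  }
  # isolated cycles (all degree 2) are not traced; count them as one segment
  if (!all(visited_edge)) {
    rem <- which(!visited_edge)
    comp <- igraph::components(
      igraph::subgraph_from_edges(network, rem, delete.vertices = FALSE))
    extra <- sum(comp$csize > 1)
    for (k in seq_len(extra))
      segs[[length(segs) + 1]] <- list(from = NA, to = NA, len = sum(!visited_edge) / max(1, extra))
  }
  seg_len <- vapply(segs, function(s) as.numeric(s$len), numeric(1)) * h
  # prune: a junction counts as a branching point only if >= 3 incident
  # segments measure at least 2 voxel widths
  bp <- 0L
  for (v in junctions) {
    inc <- vapply(segs, function(s)
      (!is.na(s$from) && (s$from == v || s$to == v)) && s$len * h >= 2 * h,
      logical(1))
    if (sum(inc) >= 3) bp <- bp + 1L
  }
  list(n_branch_points = bp,
       n_segments = length(segs),
       segment_lengths = seg_len,
       network_area = area,
       branch_points_per_100um2 = bp / (area / 100))
}
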