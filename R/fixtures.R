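#' Fully occupied monolayer for pure signalling experiments
#'
#' Every voxel of an `nx x ny` lattice holds a cell; migration, matrix
#' fields and influx are disabled so the stochastic juxtacrine circuit can
#' be studied in isolation (this is the configuration in which the
#' alternating tip/stalk pattern forms).
#'
#' @param nx,ny lattice dimensions (>= 2 each).
#' @param params an `angio_params` object.
#' @param V uniform VEGF concentration (ng/ml).
#' @param xi initial-condition fluctuation amplitude (overrides
#'   `params$xi` when given).
#' @return an `angio_setup`.
#' @export
make_monolayer <- function(nx = 10, ny = 12, params = default_params(),
                           V = 5, xi = NULL) {
  stopifnot(nx >= 2, ny >= 2)
  if (!is.null(xi)) params$xi <- xi
  lat <- hex_lattice(nx, ny, params$lattice$h)
  angio_setup(lat, occupied = seq_len(lat$n), lineage_of = "WT",
              lineages = list(WT = params), V = V,
              c0 = 0, m0 = 0,
              freeze = c("migration", "fields", "orientation", "influx"))
}

#' Linear sprout for the cell-competition (overtaking) assay
#'
#' A fully occupied strip of `width` rows and `length` columns devoid of
#' collagen; the lattice is exactly the sprout, so cells shuffle by
#' overtaking and cannot invade the surroundings.  A basement membrane
#' (`m = 1`) sheathes the sprout and the orientation landscape points
#' towards the leading edge (the rightmost column), giving the strongly
#' polarised, proteolysis-free shuffling regime of the assay.  Lineages are
#' assigned to cells independently with the given probabilities.
#'
#' @param length number of columns (>= 2).
#' @param width number of rows (default 2; the two rightmost voxels are the
#'   leading positions).
#' @param lineages named list of `angio_params`.
#' @param mix lineage probabilities (defaults to uniform).
#' @param V uniform VEGF concentration (ng/ml).
#' @param l_init initial orientation-landscape value along the sprout axis.
#' @param freeze extra dynamics groups to disable.
#' @return an `angio_setup`.
#' @export
make_linear_sprout <- function(length = 10, width = 2,
                               lineages = list(WT = default_params()),
                               mix = NULL, V = 5, l_init = 1,
                               freeze = character(0)) {
  stopifnot(length >= 2, width >= 1)
  base <- lineages[[1]]
  lat <- hex_lattice(length, width, base$lattice$h)
  n_lin <- base::length(lineages)
  if (is.null(mix)) mix <- rep(1 / n_lin, n_lin)
  lin_of <- if (n_lin == 1) names(lineages) else
    sample(names(lineages), lat$n, replace = TRUE, prob = mix)
  angio_setup(lat, occupied = seq_len(lat$n), lineage_of = lin_of,
              lineages = lineages, V = V, c0 = 0, m0 = 1,
              l0 = list(s = "r", value = l_init),
              freeze = union(freeze, c("fields", "influx")))
}

#' Leading-edge voxels of a linear sprout
#'
#' @param setup an `angio_setup` created by [make_linear_sprout()].
#' @return integer voxel indices of the rightmost column (Position 1 is the
#'   bottom row, Position 2 the row above).
#' @export
leading_positions <- function(setup) {
  lat <- setup$lattice
  vapply(seq_len(lat$ny), function(r) (r - 1L) * lat$nx + lat$nx, integer(1))
}

#' Random lattice-embedded network with synthetic random-walk trajectories
#'
#' Grows a random tree-like connected voxel set on a hexagonal lattice and
#' lets labelled walkers perform independent unbiased random walks on it;
#' used to exercise the trajectory metrics and morphometrics on known
#' ground truth without running the full model.
#'
#' @param n_nodes number of network voxels (>= 2).
#' @param branching_prob probability that growth continues from a random
#'   old node rather than the most recent one (higher values branch more).
#' @param n_walkers,n_steps walkers and samples per walker.
#' @param lattice optional [hex_lattice()]; default 30 x 30.
#' @return list with `network` (an igraph over voxel ids, see
#'   [network_graph()]), `nodes` (voxel indices), `log` (a trajectory log
#'   data frame) and the `lattice`.
#' @export
make_random_network <- function(n_nodes = 30, branching_prob = 0.3,
                                n_walkers = 5, n_steps = 20, lattice = NULL) {
  stopifnot(n_nodes >= 2)
  lat <- if (is.null(lattice)) hex_lattice(30, 30, 10) else lattice
  start <- (lat$ny %/% 2) * lat$nx + lat$nx %/% 2
  nodes <- start
  tip <- start
  while (length(nodes) < n_nodes) {
    from <- if (stats::runif(1) < branching_prob)
      nodes[sample.int(length(nodes), 1)] else tip
    nb <- lat$nbr[from, ]
    nb <- nb[!is.na(nb) & !(nb %in% nodes)]
    if (!length(nb)) { tip <- nodes[sample.int(length(nodes), 1)]; next }
    nxt <- nb[sample.int(length(nb), 1)]
    nodes <- c(nodes, nxt)
    tip <- nxt
  }
  g <- network_graph(lat, nodes)
  rows <- list()
  for (w in seq_len(n_walkers)) {
    v <- nodes[sample.int(length(nodes), 1)]
    for (k in seq_len(n_steps)) {
      rows[[length(rows) + 1]] <- data.frame(
        t = (k - 1) * 0.01, label = w, voxel = v,
        x = lat$centers[v, 1], y = lat$centers[v, 2],
        D = 0, phenotype = "stalk", lineage = "WT",
        stringsAsFactors = FALSE)
      nb <- lat$nbr[v, ]
      nb <- nb[!is.na(nb) & nb %in% nodes]
      if (length(nb)) v <- nb[sample.int(length(nb), 1)]
    }
  }
  list(network = g, nodes = nodes, log = do.call(rbind, rows), lattice = lat)
}

#' Canned experimental setups
#'
#' Builds the four simulation scenarios used throughout the package:
#' \describe{
#'   \item{setup1_plexus}{sprouting from a vascular plexus: the bottom row
#'     of the lattice is the plexus (occupied, matrix-free, refilled on
#'     vacancy), the rest of the domain carries uniform matrix at `c_max`
#'     and a uniform VEGF bath (`V` in \{0, 5, 50\} ng/ml);
#'     `T_max = 2.5` (1250 min).}
#'   \item{setup2_gradient}{an initial vessel (occupied horizontal row near
#'     the bottom) in a linear VEGF ramp increasing from 0 at `y = 0` to
#'     `V_top` at the top of the domain; no influx; `T_max = 2.5`.}
#'   \item{setup3_bead}{a central bead of cells sheathed in basement
#'     membrane, embedded in matrix of density `c_max`, under a linear VEGF
#'     ramp from 0 ng/ml at `y = 0` to 5 ng/ml at `y = 125` um;
#'     `T_max = 1.0` (500 min).}
#'   \item{setup4_sprout}{the width-2 linear-sprout competition assay (see
#'     [make_linear_sprout()]); `T_max = 50`.}
#' }
#' The returned object carries the recommended final time in
#' `attr(x, "T_max")`.
#'
#' @param name setup name (see above).
#' @param params wild-type `angio_params`.
#' @param V uniform VEGF (setup 1) or ramp top value (setup 2).
#' @param c_max matrix density (setup 3 collagen condition; also stored in
#'   the tissue parameters).
#' @param nx,ny lattice dimensions (defaults per setup).
#' @param lineages,mix competition lineages for setup 4 (passed to
#'   [make_linear_sprout()]).
#' @param sprout_length setup 4 columns.
#' @return an `angio_setup`.
#' @export
make_setup <- function(name = c("setup1_plexus", "setup2_gradient",
                                "setup3_bead", "setup4_sprout"),
                       params = default_params(), V = 5, c_max = NULL,
                       nx = NULL, ny = NULL,
                       lineages = NULL, mix = NULL, sprout_length = 14) {
  name <- match.arg(name)
  h <- params$lattice$h
  if (name == "setup1_plexus") {
    nx <- if (is.null(nx)) 24 else nx
    ny <- if (is.null(ny)) 24 else ny
    lat <- hex_lattice(nx, ny, h)
    plexus <- seq_len(nx)              # bottom row
    c0 <- rep(params$tissue$c_max, lat$n)
    c0[plexus] <- 0
    st <- angio_setup(lat, occupied = plexus, lineages = list(WT = params),
                      V = V, c0 = c0, m0 = 0,
                      l0 = list(s = "ur", value = 1), plexus = plexus)
    attr(st, "T_max") <- 2.5
    return(st)
  }
  if (name == "setup2_gradient") {
    nx <- if (is.null(nx)) 24 else nx
    ny <- if (is.null(ny)) 24 else ny
    lat <- hex_lattice(nx, ny, h)
    vessel <- (3L * nx + 1L):(4L * nx)  # horizontal vessel on the 4th row
    c0 <- rep(params$tissue$c_max, lat$n)
    c0[vessel] <- 0
    ytop <- max(lat$centers[, 2])
    Vf <- V * lat$centers[, 2] / ytop
    st <- angio_setup(lat, occupied = vessel, lineages = list(WT = params),
                      V = Vf, c0 = c0, m0 = 0, l0 = list(s = "ur", value = 1))
    attr(st, "T_max") <- 2.5
    return(st)
  }
  if (name == "setup3_bead") {
    nx <- if (is.null(nx)) 17 else nx
    ny <- if (is.null(ny)) 17 else ny
    if (!is.null(c_max)) params$tissue$c_max <- c_max
    lat <- hex_lattice(nx, ny, h)
    ctr <- lat$centers[(ny %/% 2) * nx + nx %/% 2 + 1, ]
    d <- sqrt((lat$centers[, 1] - ctr[1])^2 + (lat$centers[, 2] - ctr[2])^2)
    bead <- which(d <= 2.1 * h)
    c0 <- rep(params$tissue$c_max, lat$n)
    c0[bead] <- 0
    m0 <- rep(0, lat$n); m0[bead] <- 1   # basement-membrane sheath of the bead
    Vf <- pmin(lat$centers[, 2], 125) / 125 * 5
    st <- angio_setup(lat, occupied = bead, lineages = list(WT = params),
                      V = Vf, c0 = c0, m0 = m0)
    attr(st, "T_max") <- 1.0
    return(st)
  }
  # setup4_sprout
  if (is.null(lineages)) lineages <- list(WT = params, WT2 = params)
  st <- make_linear_sprout(length = sprout_length, width = 2,
                           lineages = lineages, mix = mix)
  attr(st, "T_max") <- 50
  st
}
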