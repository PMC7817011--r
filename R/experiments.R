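#' Linear-sprout cell-competition assay
#'
#' Reproduces the overtaking competition between two cell lineages mixed
#' 1:1 in a width-2 linear sprout: for each realisation the fraction of
#' simulated time that each lineage occupies the two leading (rightmost)
#' voxels is recorded, and summarised as mean and standard deviation over
#' realisations.
#'
#' @param lineage_a,lineage_b lineage names (`"WT"`, `"VEGFR2het"`,
#'   `"VEGFR1het"`; `lineage_b` may equal `lineage_a`, giving the control
#'   experiment with two identical lines).
#' @param dapt apply the DAPT (Notch-abolishing) override to both lineages?
#' @param n_realisations number of independent realisations.
#' @param T_max final time per realisation (time units).
#' @param length sprout length (columns).
#' @param params wild-type base parameters.
#' @param V uniform VEGF concentration of the assay (ng/ml).
#' @param seed base seed; realisation `r` uses `seed + r`.
#' @param r1_kv_factor VEGFR1 heterozygote override strength.
#' @return list with `table` (data frame: position, lineage, mean and sd of
#'   percent occupancy) and `raw` (matrix of per-realisation occupancy
#'   fractions of lineage A, columns Position 1 and 2).
#' @export
competition_experiment <- function(lineage_a = "WT", lineage_b = "WT",
                                   dapt = FALSE, n_realisations = 10,
                                   T_max = 50, length = 14,
                                   params = default_params(), V = 5,
                                   seed = 1, r1_kv_factor = 3) {
  pa <- lineage_params(params, lineage_a, dapt = dapt,
                       r1_kv_factor = r1_kv_factor)
  pb <- lineage_params(params, lineage_b, dapt = dapt,
                       r1_kv_factor = r1_kv_factor)
  nm <- make.unique(c(lineage_a, lineage_b))
  raw <- matrix(NA_real_, n_realisations, 2,
                dimnames = list(NULL, c("Position 1", "Position 2")))
  for (r in seq_len(n_realisations)) {
    set.seed(seed + r)
    st <- make_linear_sprout(length = length, width = 2,
                             lineages = stats::setNames(list(pa, pb), nm),
                             V = V)
    sim <- simulate_angio(st, T_max = T_max, dt_sample = 0)
    lead <- leading_positions(st)
    raw[r, ] <- sim$occ_time[lead, nm[1]] / sim$clock
  }
  tab <- rbind(
    data.frame(position = c("Position 1", "Position 2"), lineage = nm[1],
               mean_pct = 100 * colMeans(raw), sd_pct = 100 * apply(raw, 2, stats::sd)),
    data.frame(position = c("Position 1", "Position 2"), lineage = nm[2],
               mean_pct = 100 * (1 - colMeans(raw)),
               sd_pct = 100 * apply(raw, 2, stats::sd))
  )
  rownames(tab) <- NULL
  list(table = tab, raw = raw)
}

#' Trajectory metrics of a plexus-sprouting run
#'
#' Convenience wrapper running `setup1` realisations and pooling the
#' displacement, orientation, directionality and tip-proportion statistics.
#'
#' @param V uniform VEGF concentration (ng/ml).
#' @param n_realisations realisations to pool.
#' @param T_max final time.
#' @param params base parameters.
#' @param seed base seed.
#' @param nx,ny lattice size.
#' @return list with pooled `displacements`, `orientation`, `directionality`
#'   (pooled proportions), `tip_proportion` (at `T_max`), and the last
#'   realisation's `sim` object.
#' @export
sprouting_metrics <- function(V = 5, n_realisations = 5, T_max = 2.5,
                              params = default_params(), seed = 1,
                              nx = 24, ny = 24) {
  disp <- c(); ori <- c(); counts <- c(anterograde = 0, retrograde = 0, still = 0)
  tipp <- c(); sim <- NULL
  for (r in seq_len(n_realisations)) {
    set.seed(seed + r)
    st <- make_setup("setup1_plexus", params = params, V = V, nx = nx, ny = ny)
    sim <- simulate_angio(st, T_max = T_max, dt_sample = 0.01)
    log <- trajectory_log(sim)
    disp <- c(disp, displacement_histogram(log))
    ori <- c(ori, orientation_statistic(log))
    dd <- directionality(log, st$lattice, base_voxels = st$plexus)
    counts <- counts + dd$proportions * dd$n
    tipp <- c(tipp, tip_proportion(log, T_max))
  }
  list(displacements = disp, orientation = ori,
       directionality = counts / sum(counts),
       tip_proportion = mean(tipp), sim = sim)
}

#' One-at-a-time parameter sensitivity sweep
#'
#' Varies one cellular- or tissue-scale parameter by the given relative
#' deltas around its default, runs plexus-sprouting realisations for each
#' value, and tabulates the trajectory and network metrics (anterograde
#' proportion, orientation, displacement, branching points per 100 square
#' micrometres, segment count and mean segment length).
#'
#' @param param_name name of a `cellular` or `tissue` parameter (e.g.
#'   `"K"`, `"D_c"`, `"D_m"`).
#' @param deltas relative perturbations (e.g. `c(-0.2, 0, 0.2)`).
#' @param n_realisations realisations per value.
#' @param V VEGF concentration.
#' @param T_max final time.
#' @param params base parameters.
#' @param seed base seed.
#' @param nx,ny lattice size.
#' @return data frame, one row per (delta, realisation), with the metric
#'   columns.
#' @export
sensitivity_sweep <- function(param_name,
                              deltas = c(-0.2, -0.15, -0.1, -0.05, -0.01,
                                         -0.001, 0.001, 0.01, 0.05, 0.1,
                                         0.15, 0.2),
                              n_realisations = 10, V = 5, T_max = 2.5,
                              params = default_params(), seed = 1,
                              nx = 24, ny = 24) {
  group <- if (param_name %in% names(params$cellular)) "cellular"
           else if (param_name %in% names(params$tissue)) "tissue"
           else stop("unknown parameter: ", param_name)
  base_value <- params[[group]][[param_name]]
  rows <- list()
  for (d in deltas) {
    p <- params
    p[[group]][[param_name]] <- base_value * (1 + d)
    for (r in seq_len(n_realisations)) {
      set.seed(seed + 1000 * which(deltas == d) + r)
      st <- make_setup("setup1_plexus", params = p, V = V, nx = nx, ny = ny)
      sim <- simulate_angio(st, T_max = T_max, dt_sample = 0.01)
      log <- trajectory_log(sim)
      net <- simulation_network(sim, log = log)
      mm <- network_morphometrics(net, h = p$lattice$h, lattice = st$lattice)
      dd <- directionality(log, st$lattice, base_voxels = st$plexus)
      rows[[length(rows) + 1]] <- data.frame(
        param = param_name, delta = d, value = base_value * (1 + d),
        realisation = r,
        anterograde = unname(dd$proportions["anterograde"]),
        orientation = mean(orientation_statistic(log)),
        displacement = mean(displacement_histogram(log)),
        bp_per_100um2 = mm$branch_points_per_100um2,
        n_segments = mm$n_segments,
        mean_segment_length = mean(mm$segment_lengths),
        network_area = mm$network_area,
        n_cells = sum(sim$E))
    }
  }
  do.call(rbind, rows)
}
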