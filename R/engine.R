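#' @useDynLib angiosprout, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Assemble a simulation setup
#'
#' Low-level constructor of a simulation state ready for [simulate_angio()].
#' Most users will call [make_setup()], [make_monolayer()] or
#' [make_linear_sprout()] instead.
#'
#' @param lattice a [hex_lattice()].
#' @param occupied integer/logical vector of occupied voxels (indices).
#' @param lineage_of character vector, one lineage name per occupied voxel
#'   (recycled).
#' @param lineages named list of `angio_params`, one per lineage; the first
#'   is the reference for shared lattice/tissue/cellular constants.
#' @param V VEGF field: scalar or per-voxel vector (ng/ml).
#' @param c0,m0 initial matrix density and basement membrane (scalar or
#'   per-voxel).
#' @param l0 initial orientation landscape: an `n x 6` matrix, or `NULL` for
#'   all-zero, or a named list `list(s = "ur", value = 1)` placing `value`
#'   in direction `s` everywhere.
#' @param plexus voxel indices refilled with fresh cells whenever vacated
#'   (the vascular-plexus boundary condition); empty for closed systems.
#' @param plexus_lineage_probs influx lineage mix (defaults to uniform over
#'   `lineages`).
#' @param freeze character vector among `"migration"`, `"reactions"`,
#'   `"fields"`, `"orientation"`, `"influx"` disabling parts of the dynamics
#'   (used to unit-test each scale in isolation).
#' @param embedded logical; `TRUE` when the lattice is a sub-region (such
#'   as a sprout) embedded in a larger cell-free domain, in which case the
#'   neighbourhood-average denominators run over the full interaction disc
#'   (the empty surroundings dilute the signals) instead of the in-lattice
#'   weights.
#' @param proteins optional `n x 5` matrix of initial copy numbers
#'   (N, D, I, R2, R2s); by default drawn uniformly within a fluctuation
#'   band `xi` around the baseline expression of each cell's lineage.
#' @return an object of class `angio_setup`.
#' @export
angio_setup <- function(lattice, occupied, lineage_of = "WT",
                        lineages = list(WT = default_params()),
                        V = 5, c0 = 0, m0 = 0, l0 = NULL,
                        plexus = integer(0), plexus_lineage_probs = NULL,
                        freeze = character(0), proteins = NULL,
                        embedded = FALSE) {
  n <- lattice$n
  occupied <- sort(unique(as.integer(occupied)))
  stopifnot(all(occupied >= 1 & occupied <= n))
  if (any(duplicated(occupied))) stop("initial cells must occupy distinct voxels")
  ln_names <- names(lineages)
  if (is.null(ln_names)) stop("lineages must be a named list")
  lineage_of <- rep_len(as.character(lineage_of), length(occupied))
  stopifnot(all(lineage_of %in% ln_names))
  base <- lineages[[1]]
  V <- rep_len(V, n)
  if (any(V < 0)) stop("VEGF field must be non-negative")
  c0 <- rep_len(c0, n); m0 <- rep_len(m0, n)
  if (is.null(l0)) l0 <- matrix(0, n, 6)
  else if (is.list(l0)) {
    s <- match(l0$s, hex_directions()$label)
    tmp <- matrix(0, n, 6); tmp[, s] <- l0$value; l0 <- tmp
  }
  stopifnot(is.matrix(l0), nrow(l0) == n, ncol(l0) == 6)

  E0 <- integer(n); E0[occupied] <- 1L
  lineage0 <- rep(-1L, n)
  lineage0[occupied] <- match(lineage_of, ln_names) - 1L
  label0 <- integer(n)
  label0[occupied] <- seq_along(occupied)

  if (is.null(proteins)) {
    proteins <- matrix(0L, n, 5,
                       dimnames = list(NULL, c("N", "D", "I", "R2", "R2s")))
    for (k in seq_along(occupied)) {
      i <- occupied[k]
      p <- lineages[[lineage_of[k]]]
      proteins[i, 1:3] <- 0L
      b <- baseline_counts(p)
      proteins[i, "N"] <- draw_band(b["N"], p$xi)
      proteins[i, "D"] <- draw_band(b["D"], p$xi)
      proteins[i, "R2"] <- draw_band(b["R2"], p$xi)
    }
  }

  probs <- plexus_lineage_probs
  if (is.null(probs)) probs <- rep(1 / length(lineages), length(lineages))
  structure(list(
    lattice = lattice, base = base, lineages = lineages,
    lineage_names = ln_names,
    E0 = E0, lineage0 = lineage0, label0 = label0, prot0 = proteins,
    V = V, c0 = c0, m0 = m0, l0 = l0,
    plexus = as.integer(plexus), plexus_lineage_probs = probs,
    freeze = freeze,
    stencil_s = build_stencil(lattice, base$lattice$R_s_factor * lattice$h,
                              denominator = if (embedded) "disc" else "lattice"),
    stencil_c = build_stencil(lattice, base$cellular$R_c_factor * lattice$h,
                              denominator = if (embedded) "disc" else "lattice")
  ), class = "angio_setup")
}

# baseline expression levels (copy numbers) used for initial conditions
baseline_counts <- function(params) {
  s <- params$subcellular
  round(params$Omega * c(N = s$b_N, D = s$b_D, R2 = s$b_R2) / s$gamma)
}

draw_band <- function(base, xi) {
  lo <- floor(base * (1 - xi)); hi <- ceiling(base * (1 + xi))
  if (hi <= lo) return(as.integer(lo))
  as.integer(lo + floor(stats::runif(1) * (hi - lo + 1)))
}

lineage_par_matrix <- function(lineages) {
  keys <- c("b_N", "b_D", "b_R2", "gamma", "gamma_e", "k_t", "k_c", "k_v",
            "eta", "I0", "lambda_I_N", "n_N", "lambda_I_R2", "n_R2",
            "R2s0", "lambda_R2s_D", "n_D")
  t(vapply(lineages, function(p) unlist(p$subcellular[keys]),
           numeric(length(keys))))
}

#' Run the multiscale simulation
#'
#' Executes the Next-Subvolume event loop of the coupled
#' subcellular/cellular/tissue model until `T_max` (simulation time units;
#' one unit is 500 minutes).
#'
#' @param setup an `angio_setup`.
#' @param T_max final time (time units).
#' @param seed optional integer; if given, `set.seed(seed)` is called so
#'   the run is reproducible.
#' @param dt_sample trajectory sampling interval (time units); 0.01
#'   (5 minutes) by default, `0` disables trajectory recording.
#' @param snapshot_times times at which full field snapshots are stored.
#' @param record_events number of leading events to record (0 = none).
#' @param max_events stop after this many events (default unlimited).
#' @return an object of class `angio_sim`: the final state (occupancy,
#'   labels, lineages, copy numbers, fields, orientation landscape), the
#'   trajectory log (see [trajectory_log()]), per-voxel occupancy-time
#'   integrals by lineage, snapshots, event counters and the per-voxel
#'   propensities as maintained by the scheduler.
#' @export
simulate_angio <- function(setup, T_max, seed = NULL, dt_sample = 0.01,
                           snapshot_times = numeric(0), record_events = 0,
                           max_events = Inf) {
  stopifnot(inherits(setup, "angio_setup"), T_max >= 0)
  if (!is.null(seed)) set.seed(seed)
  base <- setup$base
  gl <- c(Omega = base$Omega, Dtil = migration_rate_scale(base),
          unlist(base$cellular[c("p_max", "s_p", "D_p", "E_F1", "E_F2",
                                 "s_F1", "s_F2", "K", "k_m", "k_D",
                                 "a_H", "n_H")]),
          unlist(base$tissue[c("eta_max", "s_c", "D_c", "gamma_max", "s_m",
                               "D_m", "Delta_l", "eta_l", "c_max")]),
          xi = base$xi)
  flags <- c(reactions = !"reactions" %in% setup$freeze,
             migration = !"migration" %in% setup$freeze,
             fields = !"fields" %in% setup$freeze,
             orientation = !"orientation" %in% setup$freeze,
             influx = !"influx" %in% setup$freeze && length(setup$plexus) > 0)
  lin_base <- t(vapply(setup$lineages, baseline_counts, numeric(3)))
  storage.mode(lin_base) <- "integer"
  cfg <- list(
    n = setup$lattice$n,
    nbr0 = {
      nb <- setup$lattice$nbr; nb[is.na(nb)] <- 0L; nb - 1L
    },
    ux = hex_directions()$ux, uy = hex_directions()$uy,
    a_ptr = setup$stencil_s$ptr, a_idx0 = setup$stencil_s$idx - 1L,
    a_w = setup$stencil_s$w, a_wsum = setup$stencil_s$wsum,
    p_ptr = setup$stencil_c$ptr, p_idx0 = setup$stencil_c$idx - 1L,
    p_w = setup$stencil_c$w, p_wsum = setup$stencil_c$wsum,
    V = setup$V, lin_par = lineage_par_matrix(setup$lineages),
    lin_base = lin_base, glob = gl, flags = flags,
    plexus0 = setup$plexus - 1L,
    plexus_lin_probs = setup$plexus_lineage_probs,
    E0 = setup$E0, lineage0 = setup$lineage0, label0 = setup$label0,
    prot0 = setup$prot0, c0 = setup$c0, m0 = setup$m0, l0 = setup$l0,
    T_max = T_max, dt_sample = dt_sample,
    snapshot_times = as.numeric(snapshot_times),
    record_events = as.integer(record_events),
    max_events = as.double(max_events),
    next_label = max(setup$label0) + 1L
  )
  res <- engine_run(cfg)
  res$setup <- setup
  res$T_max <- T_max
  colnames(res$occ_time) <- setup$lineage_names
  class(res) <- "angio_sim"
  res
}

#' @export
print.angio_sim <- function(x, ...) {
  cat(sprintf(paste0("angio_sim: %d x %d lattice, t = %g (%d cells, ",
                     "%g events, %g moves, %g swaps, %g influx)\n"),
              x$setup$lattice$nx, x$setup$lattice$ny, x$clock, sum(x$E),
              x$n_events, x$n_moves, x$n_swaps, x$influx_count))
  invisible(x)
}

#' Trajectory log of a simulation
#'
#' The time-stamped per-cell record used by all metrics: sampling time,
#' cell label, voxel, centre coordinates (micrometres), Delta level
#' (concentration scale), phenotype and lineage.
#'
#' @param sim an `angio_sim`.
#' @return a data frame sorted by time then label.
#' @export
trajectory_log <- function(sim) {
  tr <- sim$traj
  lat <- sim$setup$lattice
  b_D <- sim$setup$base$subcellular$b_D
  out <- data.frame(
    t = tr$t, label = tr$label, voxel = tr$voxel,
    x = lat$centers[tr$voxel, 1], y = lat$centers[tr$voxel, 2],
    D = tr$D, phenotype = classify_phenotype(tr$D, b_D),
    lineage = sim$setup$lineage_names[tr$lineage + 1L],
    stringsAsFactors = FALSE
  )
  out[order(out$t, out$label), , drop = FALSE]
}

# R-side mirror of the scheduler's per-voxel total propensity, recomputed
# from scratch from a simulation's final state; used to validate the
# incrementally maintained schedule.
total_propensity_R <- function(sim) {
  setup <- sim$setup
  base <- setup$base
  lat <- setup$lattice
  Om <- base$Omega
  Dc <- sim$prot[, 2] / Om
  Nc <- sim$prot[, 1] / Om
  sig <- external_signals(lat, Dc, Nc, stencil = setup$stencil_s)
  st <- setup$stencil_c
  EN <- numeric(lat$n)
  for (i in seq_len(lat$n)) {
    k <- seq_len(st$ptr[i + 1] - st$ptr[i]) + st$ptr[i]
    if (length(k)) EN[i] <- sum(st$w[k] * sim$E[st$idx[k]]) / st$wsum[i]
  }
  tot <- numeric(lat$n)
  mig_on <- !"migration" %in% setup$freeze
  rea_on <- !"reactions" %in% setup$freeze
  for (i in seq_len(lat$n)) {
    if (sim$E[i] == 0) next
    p <- setup$lineages[[sim$lineage[i] + 1L]]
    if (rea_on) {
      counts <- sim$prot[i, ]
      names(counts) <- c("N", "D", "I", "R2", "R2s")
      tot[i] <- sum(reaction_propensities(counts, sig$Dbar[i], sig$Nbar[i],
                                          setup$V[i], p))
    }
    if (mig_on) {
      tot[i] <- tot[i] + migration_rate_scale(base) *
        ecm_speed_factor(sim$c[i], base$tissue$c_max) *
        neighbourhood_function(EN[i], base)
    }
  }
  tot
}
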