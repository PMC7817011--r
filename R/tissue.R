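#' Matrix proteolysis rate
#'
#' Sigmoidal dependence of the matrix-degradation rate on the resident
#' cell's Delta level (tip cells carry most proteolytic activity), with
#' midpoint `D_c`, slope `s_c` and ceiling `eta_max`.
#'
#' @param D Delta level (concentration scale), vectorised.
#' @param params an `angio_params` object.
#' @export
proteolysis_rate <- function(D, params) {
  q <- params$tissue
  q$eta_max / (1 + exp(-q$s_c * (D - q$D_c)))
}

#' Basement-membrane deposition rate
#'
#' Sigmoidal dependence of basal-lamina deposition on the resident cell's
#' Delta level, with midpoint `D_m`, slope `s_m` and ceiling `gamma_max`.
#'
#' @param D Delta level, vectorised.
#' @param params an `angio_params` object.
#' @export
bm_deposition_rate <- function(D, params) {
  q <- params$tissue
  q$gamma_max / (1 + exp(-q$s_m * (D - q$D_m)))
}

#' Advance matrix density and basement membrane over a waiting time
#'
#' Exact piecewise-linear integration of the matrix fields between
#' stochastic events: in voxels containing a cell, matrix density decreases
#' at the cell's proteolysis rate (clamped at 0) and basement membrane
#' accumulates at the deposition rate (clamped at 1); empty voxels are
#' frozen.  The Delta level is constant over the interval, so the update is
#' exact.
#'
#' @param c,m per-voxel fields.
#' @param D per-voxel Delta level (concentration scale).
#' @param occupied per-voxel 0/1 occupancy.
#' @param tau elapsed time (>= 0).
#' @param params an `angio_params` object.
#' @return list with updated `c` and `m`.
#' @export
advance_fields <- function(c, m, D, occupied, tau, params) {
  if (tau < 0) stop("tau must be >= 0")
  occ <- occupied == 1
  c[occ] <- pmax(0, c[occ] - proteolysis_rate(D[occ], params) * tau)
  m[occ] <- pmin(1, m[occ] + bm_deposition_rate(D[occ], params) * tau)
  list(c = c, m = m)
}

#' Stretch the orientation landscape along a migration direction
#'
#' After a move from voxel `i` to voxel `j` in direction `s`, both voxels'
#' orientation-landscape components along `s` grow by `Delta_l * D_i`
#' (Delta-weighted: tip cells realign fibrils more strongly).
#'
#' @param l n x 6 orientation-landscape matrix.
#' @param i,j source and target voxel indices.
#' @param s direction label or index 1..6.
#' @param D_i mover's Delta level.
#' @param Delta_l stretch increment per unit Delta.
#' @return updated `l`.
#' @export
stretch_orientation <- function(l, i, j, s, D_i, Delta_l) {
  if (is.character(s)) s <- match(s, hex_directions()$label)
  l[i, s] <- l[i, s] + Delta_l * D_i
  l[j, s] <- l[j, s] + Delta_l * D_i
  l
}

#' Relax the orientation landscape
#'
#' Elastic exponential decay of every component at rate `eta_l` over a
#' waiting time `tau`; satisfies the semigroup property
#' `relax(t1) o relax(t2) = relax(t1 + t2)`.
#'
#' @param l n x 6 orientation-landscape matrix (or vector).
#' @param tau elapsed time (>= 0).
#' @param eta_l relaxation rate.
#' @return updated `l`.
#' @export
relax_orientation <- function(l, tau, eta_l) {
  if (tau < 0) stop("tau must be >= 0")
  l * exp(-eta_l * tau)
}
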