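#' Matrix-density speed factor
#'
#' Linear slow-down of cell motility with local matrix density: `1 - c/c_max`
#' below the maximum density and 0 at or above it (cells cannot move through
#' saturated matrix until they have degraded it).
#'
#' @param c local matrix density (>= 0), vectorised.
#' @param c_max maximum matrix density.
#' @export
ecm_speed_factor <- function(c, c_max) {
  ifelse(c < c_max, pmax(0, 1 - c / c_max), 0)
}

#' Cell-cell adhesion (neighbourhood) function
#'
#' Positive part of the sum of a rising logistic at `E_F1` and a falling
#' logistic at `E_F2`, minus one.  Cells that have lost contact with
#' neighbours (weighted neighbourhood occupancy below `E_F1`) halt, as do
#' cells in crowded regions (above `E_F2`).
#'
#' @param E_N weighted neighbourhood occupancy in `[0, 1]`, vectorised.
#' @param params an `angio_params` object (uses `$cellular`).
#' @export
neighbourhood_function <- function(E_N, params) {
  q <- params$cellular
  v <- 1 / (1 + exp(-q$s_F1 * (E_N - q$E_F1))) +
       1 / (1 + exp( q$s_F2 * (E_N - q$E_F2))) - 1
  pmax(0, v)
}

#' Overtaking (position-switch) probability
#'
#' Logistic increase of the probability that a moving cell displaces an
#' occupying neighbour, with the mover's Delta level: tip cells, with
#' stronger filopodia, overtake more readily.
#'
#' @param D mover's Delta level (concentration scale), vectorised.
#' @param params an `angio_params` object.
#' @export
switching_probability <- function(D, params) {
  q <- params$cellular
  q$p_max / (1 + exp(-q$s_p * (D - q$D_p)))
}

#' Move acceptance probability for a target voxel
#'
#' 1 when the target voxel is empty; the Delta-dependent switching
#' probability when it is occupied (in which case an accepted move exchanges
#' the two cells, the overtaken cell performing the retrograde displacement).
#'
#' @param D_mover mover's Delta level.
#' @param target_occupied logical.
#' @param params an `angio_params` object.
#' @export
overtaking_probability <- function(D_mover, target_occupied, params) {
  ifelse(target_occupied, switching_probability(D_mover, params), 1)
}

#' Cell exploratoriness
#'
#' Concentration parameter of the polarity distribution,
#' `kappa = K * exp(k_m * m - k_D * D)`: basement-membrane deposits make
#' cells more persistent (larger kappa), high Delta (tip phenotype) makes
#' them more exploratory (smaller kappa).
#'
#' @param D Delta level, `m` basement-membrane concentration; vectorised.
#' @param m basement-membrane concentration in `[0, 1]`.
#' @param params an `angio_params` object.
#' @export
exploratoriness <- function(D, m, params) {
  q <- params$cellular
  q$K * exp(q$k_m * m - q$k_D * D)
}

#' Mean polarisation direction from the orientation landscape
#'
#' Saturates each directional fibril-alignment value through a Hill function
#' `l^n / (a^n + l^n)`, sums the six direction unit vectors with those
#' weights, and returns the principal argument of the resultant.  A vanishing
#' resultant (perfectly isotropic landscape) leaves the angle undefined and
#' the caller falls back to isotropic exploration (`kappa = 0`).
#'
#' @param l numeric vector of 6 orientation-landscape values (order
#'   r, ur, ul, l, dl, dr).
#' @param params an `angio_params` object (uses `a_H`, `n_H`).
#' @return list with `mu` (angle, `NA` if undefined), `defined` (logical)
#'   and `p` (the resultant vector).
#' @export
mean_polarisation <- function(l, params) {
  stopifnot(length(l) == 6, all(l >= 0))
  q <- params$cellular
  w <- l^q$n_H / (q$a_H^q$n_H + l^q$n_H)
  d <- hex_directions()
  p <- c(sum(w * d$ux), sum(w * d$uy))
  if (sqrt(sum(p^2)) < 1e-12) list(mu = NA_real_, defined = FALSE, p = p)
  else list(mu = atan2(p[2], p[1]), defined = TRUE, p = p)
}

#' Probability mass of a migration direction under the polarity distribution
#'
#' Integral of the von Mises density with mean `mu` and concentration
#' `kappa` over the angle interval of direction `s`.  The six masses sum to
#' one for any `(mu, kappa)`; `kappa = 0` gives 1/6 each.
#'
#' @param mu mean polarisation angle (radians).
#' @param kappa concentration (>= 0).
#' @param s direction label or index 1..6.
#' @return probability in `[0, 1]`.
#' @export
direction_mass <- function(mu, kappa, s) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (is.character(s)) s <- match(s, hex_directions()$label)
  if (kappa == 0) return(1 / 6)
  iv <- c(hex_directions()$phi_min[s], hex_directions()$phi_max[s])
  # exponentially scaled integrand for numerical stability at large kappa
  f <- function(phi) exp(kappa * (cos(phi - mu) - 1))
  z <- 2 * pi * besselI(kappa, 0, expon.scaled = TRUE)
  stats::integrate(f, iv[1], iv[2], rel.tol = 1e-11,
                   abs.tol = 1e-13)$value / z
}

#' Migration transition rate between neighbouring voxels
#'
#' The composite persistent-random-walk rate
#' `omega(i -> j) = (D_omega/h^2) E_i S(c_i) F(E^N_i) rho_ij(D_i) P_s(mu_i,
#' kappa_i)`, where `P_s` is the von Mises mass of the direction from `i`
#' to `j`, `mu_i` and `kappa_i` derive from the local orientation landscape,
#' Delta level and basement membrane, and `rho_ij` is the overtaking
#' probability.  The rate is zero for empty source voxels and is expressed
#' per simulation time unit.
#'
#' @param i,j neighbouring voxel indices.
#' @param state a simulation state (list with `lattice`, `E`, `EN`, `D`
#'   concentrations, `c`, `m`, `l` matrix).
#' @param params an `angio_params` object.
#' @export
migration_rate <- function(i, j, state, params) {
  s_idx <- which(state$lattice$nbr[i, ] == j)
  if (!length(s_idx)) stop("voxels are not neighbours")
  if (state$E[i] == 0) return(0)
  pol <- mean_polarisation(state$l[i, ], params)
  kap <- if (pol$defined) exploratoriness(state$D[i], state$m[i], params) else 0
  mass <- direction_mass(if (pol$defined) pol$mu else 0, kap, s_idx)
  migration_rate_scale(params) *
    ecm_speed_factor(state$c[i], params$tissue$c_max) *
    neighbourhood_function(state$EN[i], params) *
    overtaking_probability(state$D[i], state$E[j] == 1, params) *
    mass
}
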