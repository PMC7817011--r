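#' Shifted Hill function
#'
#' `(1 + lam * (X/X0)^n) / (1 + (X/X0)^n)`: a transcriptional response factor
#' equal to 1 at `X = 0`, `(1 + lam)/2` at `X = X0`, and saturating at `lam`;
#' activation for `lam > 1`, repression for `lam < 1`.
#'
#' @param X regulator level (>= 0), vectorised.
#' @param X0 threshold (> 0).
#' @param lam fold change (> 0).
#' @param n Hill exponent (> 0).
#' @export
shifted_hill <- function(X, X0, lam, n) {
  r <- (X / X0)^n
  (1 + lam * r) / (1 + r)
}

# order of species and reaction channels used throughout the package
SPECIES <- c("N", "D", "I", "R2", "R2s")

#' Reaction propensities of the VEGF-Delta-Notch circuit in one cell
#'
#' Twelve elementary channels: Hill-modulated production of Notch, Delta and
#' VEGFR2; linear decay of Notch, Delta and VEGFR2 (rate `gamma`) and of NICD
#' and active VEGFR2 (rate `gamma_e`); trans-activation of Notch by
#' neighbouring Delta (consumes one Notch, produces one NICD);
#' trans-consumption of Delta by neighbouring Notch; cis-inhibition
#' (removes one Notch and one Delta); and VEGF binding (VEGFR2 to active
#' VEGFR2).  Copy numbers are integers; `Omega` converts the
#' concentration-scale rate constants, so production propensities scale as
#' `Omega * b` and the bimolecular cis channel as `k_c / Omega`.
#'
#' @param counts named integer vector `c(N, D, I, R2, R2s)` (copy numbers).
#' @param Dext,Next external Delta/Notch concentrations (neighbourhood
#'   weighted averages on the concentration scale).
#' @param V local VEGF concentration (ng/ml).
#' @param params an `angio_params` object (uses `$subcellular` and `$Omega`).
#' @return named numeric vector of 12 propensities (per time unit).
#' @export
reaction_propensities <- function(counts, Dext, Next, V, params) {
  if (any(counts < 0)) stop("negative copy number")
  s <- params$subcellular
  Om <- params$Omega
  Ic <- counts[["I"]] / Om
  R2sc <- counts[["R2s"]] / Om
  c(
    prod_N  = Om * s$b_N * shifted_hill(Ic, s$I0, s$lambda_I_N, s$n_N),
    prod_D  = Om * s$b_D * shifted_hill(R2sc, s$R2s0, s$lambda_R2s_D, s$n_D),
    prod_R2 = Om * s$b_R2 * shifted_hill(Ic, s$I0, s$lambda_I_R2, s$n_R2),
    dec_N   = s$gamma * counts[["N"]],
    dec_D   = s$gamma * counts[["D"]],
    dec_R2  = s$gamma * counts[["R2"]],
    dec_I   = s$gamma_e * counts[["I"]],
    dec_R2s = s$gamma_e * counts[["R2s"]],
    trans_act  = s$k_t * Dext * counts[["N"]],
    trans_cons = s$eta * s$k_t * Next * counts[["D"]],
    cis     = s$k_c / Om * counts[["N"]] * counts[["D"]],
    vegf_act = s$k_v * V * counts[["R2"]]
  )
}

# stoichiometry matrix (species x channel), concentration-scale equivalent
reaction_stoichiometry <- function() {
  ch <- c("prod_N", "prod_D", "prod_R2", "dec_N", "dec_D", "dec_R2",
          "dec_I", "dec_R2s", "trans_act", "trans_cons", "cis", "vegf_act")
  S <- matrix(0L, 5, 12, dimnames = list(SPECIES, ch))
  S["N", "prod_N"] <- 1L;  S["D", "prod_D"] <- 1L;  S["R2", "prod_R2"] <- 1L
  S["N", "dec_N"] <- -1L;  S["D", "dec_D"] <- -1L;  S["R2", "dec_R2"] <- -1L
  S["I", "dec_I"] <- -1L;  S["R2s", "dec_R2s"] <- -1L
  S["N", "trans_act"] <- -1L; S["I", "trans_act"] <- 1L
  S["D", "trans_cons"] <- -1L
  S["N", "cis"] <- -1L; S["D", "cis"] <- -1L
  S["R2", "vegf_act"] <- -1L; S["R2s", "vegf_act"] <- 1L
  S
}

#' Mean-field right-hand side of the signalling circuit
#'
#' Time derivatives of `(N, D, I, R2, R2s)` on the concentration scale for a
#' single cell exposed to constant external Delta and Notch.
#'
#' @param x numeric vector `c(N, D, I, R2, R2s)` (concentrations).
#' @param Dext,Next external Delta/Notch concentrations.
#' @param V VEGF concentration (ng/ml).
#' @param params an `angio_params` object.
#' @return numeric vector of 5 derivatives.
#' @export
mean_field_rhs <- function(x, Dext, Next, V, params) {
  s <- params$subcellular
  N <- x[1]; D <- x[2]; I <- x[3]; R2 <- x[4]; R2s <- x[5]
  c(
    s$b_N * shifted_hill(I, s$I0, s$lambda_I_N, s$n_N) -
      s$gamma * N - s$k_t * Dext * N - s$k_c * N * D,
    s$b_D * shifted_hill(R2s, s$R2s0, s$lambda_R2s_D, s$n_D) -
      s$gamma * D - s$eta * s$k_t * Next * D - s$k_c * N * D,
    s$k_t * Dext * N - s$gamma_e * I,
    s$b_R2 * shifted_hill(I, s$I0, s$lambda_I_R2, s$n_R2) -
      s$gamma * R2 - s$k_v * V * R2,
    s$k_v * V * R2 - s$gamma_e * R2s
  )
}

#' Phenotype classification from the Delta proxy
#'
#' A cell is a tip cell when its Delta level reaches the baseline Delta gene
#' expression `b_D`, and a stalk cell otherwise.
#'
#' @param D Delta level (concentration scale), vectorised.
#' @param b_D baseline Delta expression; defaults to the packaged value.
#' @return character vector `"tip"`/`"stalk"`.
#' @export
classify_phenotype <- function(D, b_D = default_params()$subcellular$b_D) {
  ifelse(D >= b_D, "tip", "stalk")
}

#' External-signal averages over the juxtacrine neighbourhood
#'
#' Weighted averages of neighbouring Delta and Notch, with weights equal to
#' the fractional overlap of each voxel with the signalling disc of radius
#' `R_s`; the weight denominator runs over the full neighbourhood, so empty
#' voxels dilute the signal and an isolated cell receives zero.
#'
#' @param lattice a [hex_lattice()].
#' @param D,N per-voxel Delta/Notch concentrations (length `lattice$n`).
#' @param stencil optional precomputed [build_stencil()] result at `R_s`.
#' @param R_s signalling radius (um), used when `stencil` is missing.
#' @return list with per-voxel vectors `Dbar` and `Nbar`.
#' @export
external_signals <- function(lattice, D, N, stencil = NULL, R_s = 1.5 * lattice$h) {
  if (is.null(stencil)) stencil <- build_stencil(lattice, R_s)
  Dbar <- Nbar <- numeric(lattice$n)
  for (i in seq_len(lattice$n)) {
    k <- (stencil$ptr[i] + 1):stencil$ptr[i + 1]
    if (stencil$ptr[i + 1] == stencil$ptr[i]) next
    j <- stencil$idx[k]; w <- stencil$w[k]
    Dbar[i] <- sum(w * D[j]) / stencil$wsum[i]
    Nbar[i] <- sum(w * N[j]) / stencil$wsum[i]
  }
  list(Dbar = Dbar, Nbar = Nbar)
}

# All fixed points of the mean-field system for constant (Dext, Next, V).
# The system reduces to one equation in N: given N, NICD, VEGFR2 and the
# active receptor follow explicitly, Delta follows from its own balance, and
# the Notch balance closes the loop.  Roots are bracketed on a fine grid.
steady_states <- function(params, V, Dext, Next = Dext, n_grid = 600) {
  s <- params$subcellular
  derived <- function(N) {
    I <- s$k_t * Dext * N / s$gamma_e
    R2 <- s$b_R2 * shifted_hill(I, s$I0, s$lambda_I_R2, s$n_R2) /
      (s$gamma + s$k_v * V)
    R2s <- s$k_v * V * R2 / s$gamma_e
    D <- s$b_D * shifted_hill(R2s, s$R2s0, s$lambda_R2s_D, s$n_D) /
      (s$gamma + s$eta * s$k_t * Next + s$k_c * N)
    list(I = I, R2 = R2, R2s = R2s, D = D)
  }
  g <- function(N) {
    d <- derived(N)
    s$b_N * shifted_hill(d$I, s$I0, s$lambda_I_N, s$n_N) -
      (s$gamma + s$k_t * Dext + s$k_c * d$D) * N
  }
  Nmax <- s$b_N * max(1, s$lambda_I_N) / s$gamma
  grid <- seq(0, Nmax * 1.05, length.out = n_grid)
  gv <- vapply(grid, g, numeric(1))
  roots <- c()
  for (k in seq_len(n_grid - 1)) {
    if (is.finite(gv[k]) && is.finite(gv[k + 1]) && gv[k] * gv[k + 1] < 0) {
      roots <- c(roots, stats::uniroot(g, c(grid[k], grid[k + 1]),
                                       tol = 1e-12)$root)
    } else if (gv[k] == 0) roots <- c(roots, grid[k])
  }
  if (!length(roots)) stop("no fixed point found")
  out <- lapply(roots, function(N) {
    d <- derived(N)
    x <- c(N = N, D = d$D, I = d$I, R2 = d$R2, R2s = d$R2s)
    J <- numeric_jacobian(function(z) mean_field_rhs(z, Dext, Next, V, params), x)
    ev <- eigen(J, only.values = TRUE)$values
    c(x, stable = as.numeric(max(Re(ev)) < 0))
  })
  as.data.frame(do.call(rbind, out))
}

numeric_jacobian <- function(f, x, eps = 1e-6) {
  n <- length(x)
  J <- matrix(0, n, n)
  f0 <- f(x)
  for (j in seq_len(n)) {
    dx <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + dx
    J[, j] <- (f(xp) - f0) / dx
  }
  J
}

#' Steady-state scan of the circuit over external Delta
#'
#' Locates all fixed points of the mean-field single-cell system on a grid
#' of external Delta values (with `Next = Dext`), classifies their stability
#' from the Jacobian eigenvalues, and reports the interval of `Dext` where
#' the tip and stalk states coexist.
#'
#' @param params an `angio_params` object.
#' @param Dext_grid external-Delta values to scan.
#' @param V VEGF concentration (ng/ml).
#' @return list with `branches` (data frame: `Dext`, the five state
#'   variables, `stable`) and `bistable_interval` (`c(lo, hi)` of `Dext`
#'   values with >= 2 stable states, or `NULL`).
#' @export
bifurcation_scan <- function(params, Dext_grid, V) {
  rows <- lapply(Dext_grid, function(De) {
    ss <- steady_states(params, V, De)
    cbind(Dext = De, ss)
  })
  branches <- do.call(rbind, rows)
  ns <- tapply(branches$stable, branches$Dext, sum)
  bi <- as.numeric(names(ns)[ns >= 2])
  list(branches = branches,
       bistable_interval = if (length(bi)) range(bi) else NULL)
}

# Direct (first-reaction) stochastic simulation of the signalling circuit on
# a frozen multicellular occupancy; reference implementation used as an
# independent oracle for the event engine.  `counts` is an n x 5 integer
# matrix; cells with occupancy 0 are skipped.  Returns the state at T and
# the time of the first event.
ssa_direct <- function(lattice, counts, occupied, V, params, T_end,
                       stencil = NULL, max_events = Inf) {
  if (is.null(stencil))
    stencil <- build_stencil(lattice, params$lattice$R_s_factor * lattice$h)
  t <- 0; first <- NA_real_; n_ev <- 0
  colnames(counts) <- SPECIES
  Om <- params$Omega
  Svec <- reaction_stoichiometry()
  repeat {
    sig <- external_signals(lattice, counts[, "D"] / Om, counts[, "N"] / Om,
                            stencil = stencil)
    props <- matrix(0, lattice$n, 12)
    for (i in which(occupied == 1L)) {
      Vi <- if (length(V) > 1) V[i] else V
      props[i, ] <- reaction_propensities(counts[i, ], sig$Dbar[i],
                                          sig$Nbar[i], Vi, params)
    }
    a0 <- sum(props)
    if (a0 <= 0 || n_ev >= max_events) break
    tau <- stats::rexp(1, a0)
    if (t + tau > T_end) { t <- T_end; break }
    t <- t + tau
    if (is.na(first)) first <- t
    pick <- sample.int(lattice$n * 12, 1, prob = as.vector(props))
    i <- (pick - 1) %% lattice$n + 1
    ch <- (pick - 1) %/% lattice$n + 1
    counts[i, ] <- counts[i, ] + Svec[, ch]
    n_ev <- n_ev + 1
  }
  list(counts = counts, t = t, first_event_time = first, n_events = n_ev)
}
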