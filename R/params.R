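#' Default model parameters
#'
#' Returns the full parameter set of the multiscale model as a nested list
#' (class `angio_params`).  One simulation time unit corresponds to 500
#' minutes; all rates are expressed per time unit and all lengths in
#' micrometres.  Protein amounts are handled on a concentration scale
#' (the scale on which the cellular-scale response functions below are
#' written); the system-size constant `Omega` converts concentrations to
#' the discrete copy numbers evolved by the stochastic engine, so that the
#' intrinsic noise amplitude scales as `1/sqrt(Omega * X)`.
#'
#' The components are:
#' \describe{
#'   \item{subcellular}{VEGF-Delta-Notch circuit: baseline production rates
#'     `b_N`, `b_D`, `b_R2`; dilution rate `gamma` and fast degradation rate
#'     `gamma_e` (NICD and active receptor); trans-binding `k_t`,
#'     cis-inhibition `k_c`, VEGF binding `k_v` (per ng/ml), trans-Delta
#'     consumption factor `eta`; shifted-Hill parameters for the three
#'     transcriptional couplings (NICD to Notch, activation; NICD to VEGFR2,
#'     repression, sharing threshold `I0`; active VEGFR2 to Delta,
#'     activation).}
#'   \item{cellular}{macroscale diffusion coefficient `D_omega` (um^2/min);
#'     overtaking sigmoid `p_max`, `s_p`, `D_p`; neighbourhood (adhesion)
#'     function `E_F1`, `E_F2`, `s_F1`, `s_F2`; exploratoriness `K`, `k_m`,
#'     `k_D`; polarity saturation Hill `a_H`, `n_H`; interaction radius
#'     factor `R_c = R_c_factor * h`.}
#'   \item{tissue}{proteolysis sigmoid `eta_max`, `s_c`, `D_c`; basement
#'     membrane deposition sigmoid `gamma_max`, `s_m`, `D_m`; orientation
#'     landscape stretch increment `Delta_l` and relaxation rate `eta_l`;
#'     maximum matrix density `c_max`.}
#'   \item{lattice}{voxel width `h` (um) and signalling radius factor
#'     `R_s = R_s_factor * h`.}
#' }
#'
#' @param ... named overrides, e.g. `default_params(cellular = list(K = 10))`
#'   replaces single entries inside a component.
#' @return an `angio_params` list.
#' @export
default_params <- function(...) {
  p <- list(
    subcellular = list(
      b_N = 2000, b_D = 1000, b_R2 = 1000,
      gamma = 1, gamma_e = 5,
      k_t = 1.8e-4, k_c = 1e-3, k_v = 0.2, eta = 1,
      I0 = 25, lambda_I_N = 3, n_N = 2,
      lambda_I_R2 = 0.1, n_R2 = 4,
      R2s0 = 25, lambda_R2s_D = 6, n_D = 8
    ),
    cellular = list(
      D_omega = 20, p_max = 0.26, s_p = 0.0015, D_p = 1500,
      E_F1 = 0.15, E_F2 = 0.6, s_F1 = 30, s_F2 = 10,
      K = 13.6, k_m = 2.2, k_D = 2e-4,
      a_H = 0.5, n_H = 2, R_c_factor = 1.5
    ),
    tissue = list(
      eta_max = 5, s_c = 0.004, D_c = 2500,
      gamma_max = 2, s_m = 0.003, D_m = 3000,
      Delta_l = 5e-4, eta_l = 1, c_max = 1
    ),
    lattice = list(h = 10, R_s_factor = 1.5),
    Omega = 0.1,
    xi = 0.1,
    minutes_per_unit = 500
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(p)) stop("unknown parameter group: ", nm)
    if (is.list(p[[nm]])) {
      bad <- setdiff(names(dots[[nm]]), names(p[[nm]]))
      if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
      p[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else p[[nm]] <- dots[[nm]]
  }
  class(p) <- "angio_params"
  p
}

#' Lineage and treatment overrides
#'
#' Produces the parameter set of a cell lineage from a base (wild-type)
#' parameter set.  Heterozygous VEGFR2 knockouts halve the baseline VEGFR2
#' production rate.  Heterozygous VEGFR1 knockouts lose half of the decoy
#' receptor that competes with VEGFR2 for ligand, which is represented as an
#' increased effective VEGF-binding rate of VEGFR2 (`k_v` multiplier,
#' default 3).  DAPT treatment (gamma-secretase inhibition) abolishes
#' Notch trans-activation, `k_t = 0`.
#'
#' @param base an `angio_params` object (wild-type values).
#' @param lineage one of `"WT"`, `"VEGFR2het"`, `"VEGFR1het"`.
#' @param dapt logical; apply the DAPT override?
#' @param r1_kv_factor effective VEGF-availability multiplier of the
#'   VEGFR1 heterozygote.
#' @return an `angio_params` object with the overrides applied.
#' @export
lineage_params <- function(base, lineage = c("WT", "VEGFR2het", "VEGFR1het"),
                           dapt = FALSE, r1_kv_factor = 3) {
  lineage <- match.arg(lineage)
  p <- base
  if (lineage == "VEGFR2het") p$subcellular$b_R2 <- p$subcellular$b_R2 / 2
  if (lineage == "VEGFR1het") p$subcellular$k_v <- p$subcellular$k_v * r1_kv_factor
  if (dapt) p$subcellular$k_t <- 0
  p
}

# migration rate scale per simulation time unit: (D_omega / h^2) * minutes
migration_rate_scale <- function(params) {
  params$cellular$D_omega / params$lattice$h^2 * params$minutes_per_unit
}
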