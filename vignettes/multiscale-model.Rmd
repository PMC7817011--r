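---
title: "A hybrid multiscale model of early sprouting angiogenesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid multiscale model of early sprouting angiogenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angiosprout)
```

## The model

`angiosprout` simulates the first hours of sprouting angiogenesis — the
migration-driven growth of new blood vessels out of an existing vascular bed
— as a coupled stochastic system on three scales.

**Subcellular scale.** Each endothelial cell carries discrete copy numbers
of five species: Notch receptor $N$, Delta ligand $D$, Notch intracellular
domain (NICD) $I$, VEGFR2 $R2$ and ligand-bound (active) VEGFR2 $R2^*$.
Twelve elementary reaction channels implement the VEGF–Delta–Notch
lateral-inhibition circuit: Delta on one cell trans-activates Notch on its
neighbours (producing NICD); NICD up-regulates Notch and represses VEGFR2
transcription through shifted Hill functions
$H^S(X) = (1+\lambda (X/X_0)^n)/(1+(X/X_0)^n)$; VEGF binds VEGFR2, and the
active receptor up-regulates Delta; Delta and Notch in the same cell
mutually inactivate (cis-inhibition).  The mean-field limit of this circuit
is bistable in the external Delta input: a high-Delta/low-Notch *tip* state
and a low-Delta/high-Notch *stalk* state coexist over an intermediate input
window (`bifurcation_scan()`), and the window shrinks as VEGF decreases.  A
cell is classified as tip when its Delta level reaches the baseline
expression rate $b_D$.

Because cell positions are only resolved to the nucleus-containing voxel,
signalling is non-local: the external Delta and Notch a cell sees are
averages over all voxels overlapping a disc of radius $R_s$, weighted by
the exact voxel–disc overlap areas (computed once per lattice by
polygon–circle clipping).  Empty voxels count in the denominator, so
sparsely surrounded cells receive proportionally less inhibition.

**Cellular scale.** Cells perform a persistent random walk on a hexagonal
lattice of flat-to-flat width $h$ (one voxel per nucleus).  The transition
rate from voxel $i$ to neighbour $j$ in direction $s$ is the product
$(D_\omega/h^2)\,E_i\,S(c_i)\,F(E^N_i)\,\rho_{ij}(D_i)\,
P_s(\mu_i,\kappa_i)$: a diffusion scale, the occupancy indicator, a linear
slow-down with local matrix density (cells in saturated matrix cannot move
until they degrade it), a cell–cell adhesion factor that vanishes for
isolated cells and in crowded regions, a Delta-dependent overtaking
probability when the target is occupied (an accepted move then exchanges
the two cells), and the von Mises probability mass of the direction's
angle interval.  The polarity mean $\mu$ is the argument of the
Hill-saturated resultant of the local fibril-orientation landscape, and
the concentration $\kappa = K e^{k_m m - k_D D}$ makes high-Delta (tip)
cells exploratory and membrane-sheathed cells persistent.

**Tissue scale.** Matrix density $c$ is degraded and basement membrane $m$
deposited in occupied voxels at Delta-sigmoidal rates, integrated exactly
between events (clamped at $0$ and $1$).  Each migration step stretches the
orientation landscape of source and target voxel along the step direction
by $\Delta_l D_i$, and the whole landscape relaxes exponentially at rate
$\eta_l$.

**The engine.** All reaction and migration channels form one Markov jump
process simulated by an indexed-heap Next-Subvolume method (C++).  Two
implementation choices matter:

* *Migration by exact thinning.*  Instead of integrating six von Mises
  interval masses at every propensity refresh, each voxel schedules a
  single migration channel at the envelope rate
  $(D_\omega/h^2) S(c_i) F(E^N_i)$; when it fires, a polarity angle is
  drawn exactly from the von Mises distribution, mapped to a direction,
  and the move is accepted with the overtaking probability (or rejected
  off-lattice).  The realised process is distributionally identical to
  per-direction rates — the test suite verifies the realised direction
  frequencies against quadrature of the von Mises masses, and the whole
  queue against an exact 24-state Markov chain matrix exponential.
* *Lazy exact fields.*  $c$, $m$ and the orientation landscape are
  deterministic between events; they are materialised per voxel on demand
  (the Delta level driving them is constant between that voxel's events,
  so the piecewise integrals are exact, verified against a fine Euler
  oracle).

One simulation time unit corresponds to 500 minutes; a final time of 2.5
units is a 1250-minute experiment.

## Parameters

The cellular-scale response shapes use the published constants
$p_{max}=0.26$, $s_p=0.0015$, $D_p=1500$, $K=13.6$, $k_m=2.2$,
$k_D=2\times10^{-4}$, $E_{F1}=0.15$, $E_{F2}=0.6$, $s_{F1}=30$,
$s_{F2}=10$, with interaction radii $R_s=R_c=1.5h$ and $h=10\,\mu m$
(one nucleus diameter per voxel).  These constants fix the *scale* of
Delta: tip cells must express several thousand units (where overtaking and
proteolysis saturate) and stalk cells a few hundred.

The remaining rate constants are this package's own calibration, chosen
once against the qualitative behaviour of the system and then frozen:

* production rates $b_N=2000$, $b_D=1000$, $b_{R2}=1000$ per time unit
  with dilution $\gamma=1$ (protein lifetime 500 min) and fast turnover
  $\gamma_e=5$ for NICD and active receptor;
* trans-binding $k_t=1.8\times10^{-4}$ and NICD threshold $I_0=25$,
  placing the bistable window of the external-Delta input between the
  all-stalk neighbourhood average (a few hundred) and the one-tip
  neighbourhood average (above one thousand), which is what makes the
  alternating (salt-and-pepper) monolayer pattern self-consistent;
* Delta-production Hill $R2^*_0=25$, $n_D=8$, $\lambda_{R2^*,D}=6$: the
  steep threshold separates the repressed stalk receptor level
  ($R2^*\approx5{-}10$) from every tip-like state ($R2^*\gtrsim50$), so
  that halving VEGFR2 expression handicaps a cell in the lateral-inhibition
  race while leaving the saturated tip state — and therefore the
  DAPT-treated state — essentially lineage-independent;
* system size $\Omega=0.1$ (a tip cell carries a few hundred Delta
  copies), setting the intrinsic noise that drives stochastic phenotype
  switching;
* migration scale $D_\omega = 20\,\mu m^2/min$, giving single-cell
  displacements of a few micrometres per 15-minute window in open matrix;
* proteolysis ceiling $\eta_{max}=5$ per time unit with threshold
  $D_c=2500$ and slope $s_c=0.004$: a tip clears a saturated voxel in
  about 100 minutes while stalk cells are proteolytically inert, which is
  what confines migration to vascular guidance tunnels at low VEGF;
* membrane deposition $\gamma_{max}=2$, $D_m=3000$, $s_m=0.003$;
  orientation stretch $\Delta_l=5\times10^{-4}$ per unit Delta with
  relaxation $\eta_l=1$ and polarity saturation $a_H=0.5$, $n_H=2$.

Mutant lineages: `VEGFR2het` halves $b_{R2}$; `VEGFR1het` represents the
halved decoy receptor as a three-fold effective VEGF availability
($k_v$ multiplier — with the published value unavailable, the multiplier
was fixed at the smallest value producing a clear competition phenotype
while preserving the DAPT rescue); DAPT sets $k_t=0$, abolishing all
Notch signalling and driving every cell to the tip state.

The competition assay (`setup4`) runs at $V=5$ ng/ml.  This is a
structural requirement, not a tuning choice: at saturating VEGF the active
receptor level $R2^* \to b_{R2} H^S/\gamma_e$ becomes independent of the
binding rate, so the VEGFR1 heterozygote's advantage would cancel
identically.

## The experimental setups

```{r setups, eval = FALSE}
st1 <- make_setup("setup1_plexus", V = 5)      # plexus sprouting, T_max 2.5
st2 <- make_setup("setup2_gradient", V = 5)    # vessel in a VEGF ramp
st3 <- make_setup("setup3_bead", c_max = 1.7)  # bead invasion, T_max 1.0
st4 <- make_setup("setup4_sprout")             # competition, T_max 50
sim <- simulate_angio(st1, T_max = 2.5, seed = 1)
```

`setup1` grows a network from a fully occupied bottom row (the vascular
plexus) that refills whenever a cell leaves it — the constant-supply
boundary condition; the rest of the domain carries saturated matrix.
`setup3` embeds a membrane-sheathed bead of cells in matrix of density
`c_max` under a linear VEGF ramp (0 to 5 ng/ml over 125 micrometres).
`setup4` is a fully occupied 14x2 strip devoid of collagen whose lattice
is exactly the sprout: cells shuffle by overtaking, the two rightmost
voxels are the leading positions, and the per-voxel occupancy-time ledger
gives each lineage's leading-position share exactly.  Lattice sizes
(24x24 for the plexus setups, 17x17 for the bead, 14 columns for the
sprout) are the package's reduced study sizes; all metrics are intensive
(proportions, per-area counts), so they do not rescale with the domain.

## What the tests do and do not show

The test suite rebuilds every fixture programmatically and checks, among
others: exact geometry (overlap weights against Monte-Carlo areas),
propensity bookkeeping (incremental schedule equals a from-scratch
recomputation to $10^{-9}$), distributional correctness of the engine
(against a direct-method SSA and an exact matrix-exponential queue), the
bistability structure, monolayer patterning and its signalling-radius
dependence, VEGF-dependent directionality, bead-invasion monotonicity,
competition biases with DAPT rescue, and mixing-measure properties against
brute-force recomputation.

Known limitations, visible as failing expectations left deliberately red:

* *Sensitivity direction of the proteolysis threshold $D_c$.*  Lowering
  $D_c$ lets more cells invade, and the invaded area grows faster than the
  skeletonised network adds branch points, so branching points per area
  *decrease* — the opposite of the reported direction.  Our morphometrics
  thin the multi-voxel occupancy footprint to a one-voxel skeleton before
  counting branches; image-derived skeletons of real sprouting networks are
  not subject to this area inflation.  The exploratoriness ($K$) and
  membrane-threshold ($D_m$) branch-point directions match.
* *VEGFR2 heterozygote mixing plateau.*  At the reduced scale used in the
  tests the VEGFR2het network barely elongates, so its mixing measure
  plateaus below the wild-type value; the lineage-independent plateau is a
  full-scale, long-time property.
* *Competition magnitudes.*  The simulated wild-type dominance over
  VEGFR2het (about 80%) and VEGFR1het dominance over wild type (about
  70%) are weaker than the reference values (about 93% and 78-80%).  This
  is structural: because the DAPT-treated state is biochemically the tip
  state, any mechanism that weakens a mutant's tip state would also break
  the DAPT rescue; lineage contrast can therefore only arise from tip
  *frequencies*, and random 1:1 seeding guarantees mutant-majority
  neighbourhoods whose internal lateral-inhibition races produce
  full-strength mutant tips.  We prioritised the control parity and DAPT
  rescue (which land on the reference values) over the mutant extremes.

The synthetic fixtures (monolayers, strips, random walkers on random
networks) emulate the geometry and stochasticity of the real assays but
not image noise, cell shape, proliferation or three-dimensional effects;
passing tests validate the algorithms and the stated emergent behaviours
at reduced scale, not quantitative agreement with any particular wet-lab
experiment.

## Numerical choices

Voxel–disc overlap areas are exact (polygon clipping with circular-segment
contributions; a tangency is classified as outside contact).  The von
Mises interval masses use exponentially scaled quadrature to absolute
tolerance $10^{-11}$; the engine's sampler is Best–Fisher rejection.
Fixed points of the mean-field circuit are found by reducing the
five-dimensional system to one equation in Notch, bracketing on a 600-point
grid, and polishing with `uniroot` to $10^{-12}$; stability comes from the
eigenvalues of a finite-difference Jacobian (step $10^{-6}$, relative).
Ties and degenerate cases: an exactly isotropic orientation landscape
leaves the polarity undefined and falls back to uniform exploration
($\kappa=0$); matrix and membrane fields clamp absorbingly at their
bounds; a voxel's propensities are refreshed whenever its own state or any
signalling/adhesion input changes, and rescheduled by the standard
waiting-time rescaling of the Next-Subvolume method.
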