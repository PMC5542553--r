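---
title: "An individual-based biofilm model with discrete-element mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An individual-based biofilm model with discrete-element mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(biofilmDEM)
```

## The model

`biofilmDEM` simulates microbial communities as collections of spherical
agents in a rectangular box with the substratum at $z=0$. Each agent carries
a position, a core biomass (in COD equivalents), an attached EPS shell (for
heterotrophs), a velocity and a functional group — active heterotrophs
(HET), ammonia oxidisers (AOB) and nitrite oxidisers (NOB), free EPS
particles and dead (inert) agents. Voxels of a uniform Cartesian grid hold
solute concentrations and the imposed fluid velocity. The coupled processes
are:

* **Growth and decay.** Each agent's mass obeys $dm/dt = r\,m$ with the net
  specific rate assembled from a configurable reaction network: products of
  a maximum rate, Monod factors $S/(K+S)$ and optional inhibition factors
  $K/(K+S)$ over named solutes, mapped onto particulate and soluble
  components by a stoichiometric matrix. The single-species preset used for
  all headline simulations has heterotrophic growth on one carbonaceous
  substrate ($\mu_m S/(K_S+S)$, yield $Y$, EPS yield $Y_{EPS}$), first-order
  decay $b$, and negligible (zero-rate) decay of EPS and inert agents. A
  three-species HET/AOB/NOB preset demonstrates the multi-species capability
  with activated-sludge-style rate forms; its constants are a plausible,
  clearly non-canonical choice.
* **Division, EPS excretion, death, removal.** Agents divide at 1.25 µm core
  diameter into daughters of $m/2 \pm 10\%\,m$ (uniformly drawn), the second
  daughter placed in a uniformly random direction; heterotroph shells are
  excreted as free EPS particles when the composite diameter reaches 1.25
  times the core diameter; active agents shrinking to 0.8 µm become inert;
  anything shrinking to 0.1 µm is removed and ledgered.
* **Quasi-steady nutrients.** Solute fields are relaxed to steady state for
  the current biomass distribution (time-scale separation: diffusion
  equilibrates in seconds, biomass grows over $10^3$ s), with a Dirichlet
  feed wall at the top (or bottom), a no-flux opposite wall and periodic
  lateral boundaries.
* **Mechanics.** Hookean (optionally Hertzian) frictionless spring contact
  between agents and with the substratum ("wall as a particle of infinite
  radius"), EPS-mediated adhesive springs of stiffness
  $k_{eps}\,m^{eps}_{ij}$ anchored at the sum of radii and breaking
  permanently at twice that rest length, and Stokes drag
  $6\pi\mu r (U - v)$ from an imposed linear shear flow $U_x=\dot\gamma z$.
  One-way coupling only: the particles do not perturb the flow.

Morphology is summarised by the mean height, RMS surface roughness, and
overall porosity $1-\sum F(i,j,k)/(N_xN_y h_{max})$ of the voxel occupancy
up to the maximum height; composition by group volume fractions; activity
by an active-layer thickness; and erosion by connected-component detachment
events and their cluster-volume statistics (including a lognormal ML fit).

Three dimensionless groups organise the behaviour:
$$\delta=\frac{S_b D_S}{Y \mu_m \rho_X L_z^2},\qquad
  \kappa=\frac{K_S}{S_b},\qquad \beta=\frac{b}{\mu_m},$$
the transport-to-consumption ratio (a non-dimensional active-layer
thickness), the non-dimensional Monod coefficient, and the relative decay
rate. The default parameter set gives $\kappa=0.35$, $\beta=1.33\times
10^{-2}$ and $\delta=1.52\times10^{-2}$ on the reference 100 µm domain.

## Parameters and units

Defaults (see `?bfParams`) are the conventional single-species biofilm
parameterisation: $\mu_m=1\,\mathrm{h^{-1}}$, $b=1.33\times10^{-2}\,
\mathrm{h^{-1}}$, $K_S=3.5\times10^{-5}\,\mathrm{kg\,m^{-3}}$, $Y=0.61$,
$Y_{EPS}=0.18$, $D_S=1.6\times10^{-9}\,\mathrm{m^2\,s^{-1}}$,
$S_b=10^{-4}\,\mathrm{kg\,m^{-3}}$, $k_n=10^{-4}\,\mathrm{N\,m^{-1}}$,
$\gamma_n=10^{-5}\,\mathrm{s^{-1}}$, $k_{eps}=5\times10^9\,\mathrm{s^{-2}}$,
water viscosity, a $100\times40\times100$ µm box on a $30\times12\times30$
grid, 1 µm inoculum cells. Internally everything is converted to
micrometres, femtograms and seconds (conveniently, 1 kg m⁻³ ≡ 1 fg µm⁻³),
which keeps all magnitudes within comfortable double range.

Two quantities are not part of the reference table and are derived:

* **Biomass density** $\rho_X$ is obtained by inverting the $\delta$
  definition so that the default set attains $\delta=1.52\times10^{-2}$ at
  $L_z=100$ µm, giving $\rho_X \approx 6.21$ kg COD m⁻³. It is logged at
  config load and freely overridable.
* **EPS density** defaults to $\rho_{EPS}=\rho_X/4$. The choice is
  constrained by the excretion rule: a shell growing at $Y_{EPS}/Y$ of the
  core reaches at most the volume ratio $(Y_{EPS}/Y)(\rho_X/\rho_{EPS})$
  relative to the core, so the 1.25× composite-diameter threshold
  ($1.25^3-1\approx0.95$) is attainable only for $\rho_{EPS}\lesssim0.31\rho_X$.
  An EPS phase four times lighter than biomass makes the excretion pathway
  operative while remaining within the conventional
  "EPS-much-lighter-than-biomass" range of the IbM literature.

Other defaults chosen where the source material is silent: tangential
contact constants $k_t = \tfrac{2}{7}k_n$ and $\gamma_t=\gamma_n/2$ (the
granular-DEM convention; see below for how tangential terms are used),
adhesive links forming within $1.1\,(r_i+r_j)$, daughters placed touching
(sum of radii; the literal sum-of-diameters placement is available via
`divSep = "diameters"`), and decay shrinking core and shell proportionally.

## Numerical choices

**Biomass update.** The explicit Euler update $m \leftarrow m(1+r\,\Delta t)$
is sub-stepped so that no sub-step changes a mass by more than 0.1%
(`growthSubstepFrac`); with rates frozen over the biological step this
tracks the exponential solution to well under 1% over ten hours even at
$\Delta t_{bio}=100$ s, and the sub-stepping cost is negligible because the
update is vectorised.

**Quasi-steady solver.** Forward-Euler flux-form central differences with
first-order upwind advection (central advection is unstable at negligible
diffusion; at these voxel Péclet numbers upwind diffusion is immaterial).
The time step obeys the explicit diffusive/CFL bound; Monod sinks are
treated semi-implicitly (production explicit, destruction divided through by
$1+\Delta t\, D$, the Patankar trick), which keeps concentrations positive
and stable even where dense biomass makes the local consumption rate orders
of magnitude stiffer than transport, while leaving the converged steady
state exact. Convergence is declared when the per-step relative change drops
below $10^{-6}$; fields are warm-started between biological steps.
Cross-solute Monod factors are refreshed every sweep (Picard). The
relative-diffusivity closure $D_e = D_S f(X)$ defaults to $f\equiv1$ and is
pluggable.

**Mechanical relaxation.** Growth and division leave the packing out of
equilibrium; relaxation seeks the force balance of the
contact/adhesion/drag network. The overdamped time constants span four
orders of magnitude (contact $\zeta/k_n \sim 10^{-4}$ s versus EPS adhesion
$\sim 1$ s), so the package uses FIRE minimisation with
stiffness-preconditioned inertia ($m_i = \sum_j k_{ij}$) and a
displacement-capped step for assemblies, and plain overdamped per-agent
descent (exact inertia-free trajectories) for small systems (≤ 64 agents,
`method = "auto"`). Convergence requires either the virial pressure
$P=|\sum F_{ij}d_{ij}|/3V$ to fall below $10^{-3}$ of its running peak — the
growth-induced pressure release criterion — or every agent to sit within
`posTol` (2×10⁻⁴ µm API default; 10⁻³ µm inside the simulation loop) of its
local force balance; the second criterion matters because jammed adhesive
assemblies retain a permanent virial at equilibrium. Tangential
spring-dashpot terms are implemented in the reference force functions
(`contactForce`) but the dynamics kernel runs frictionless normal contact:
with EPS adhesion (including substratum adhesion) providing cohesion and
anchoring, tangential contact history adds cost without changing the
studied behaviour, a simplification common to biofilm DEM codes.

**Substratum adhesion.** Nothing in the force model would otherwise anchor
a frictionless biofilm laterally (there is no gravity at this scale), so a
sheared film would translate as a rigid body. The wall-as-infinite-particle
rule is therefore extended from contact to the adhesive force: EPS-carrying
agents within reach of the substratum form a wall link with rest length
$r_i$ that breaks at $2r_i$, exactly the pairwise law. This reflects the
physical role of EPS in surface attachment and can be disabled
(`wallAdhesion = FALSE`).

**Flow phase.** Erosion of a pre-grown biofilm is integrated in real time:
$v = U + F_{adh}/\zeta$ with the stiff contacts resolved by positional
projection after each step (stiff-splitting). The observable creep,
streamer elongation and discrete link-breakage cascades then evolve on the
physical adhesion/drag time scale. Detached connected components advect
with the flow, may re-agglomerate (links can re-form between recording
steps once partners re-enter the formation distance), and leave through the
outflow boundary, where their biomass is ledgered.

**Event ordering and reproducibility.** Within a biological step: division,
then EPS excretion, then death/removal, each sweeping agents in ascending id
order with a single RNG stream, so a (configuration, seed) pair reproduces a
run bit for bit.

## What the scaled study conditions emulate

The full-scale reference scenario — a $100\times40\times100$ µm box grown to 15%
volume (order $10^4$–$10^5$ agents over 4–16 simulated days), and a 48 µm
biofilm eroded in a 200 µm box — is beyond a desk-scale test budget in this
implementation. The package's trend suite therefore runs a
$40\times10\times40$ µm box ($16\times4\times16$ grid, 8-cell inoculum,
stop at 12% box volume, five replicates), with conditions transported by
dimensionless similarity: `paramsForGroups()` solves $S_b$ and $K_S$ so
that requested $(\delta,\kappa)$ hold at the scaled $L_z$.

Two deliberate design choices follow from finite-size effects observed in
pilot runs, and are fixed once here:

* The $(\delta,\kappa)$ grid for the morphology trend uses multipliers
  (0.25, 0.5, 1) of the reference smallest condition
  ($\delta=1.52\times10^{-2}$, $\kappa=0.35$) as its increasing axis. On a
  40 µm box the active layer is thick relative to the attainable biofilm
  height, so the reference range sits mostly in the
  morphologically-insensitive regime; shifting the grid down in $\delta$
  and $\kappa$ restores the fingering-to-compact transition that the
  full-scale study exhibits across its own range. The top grid point is the
  reference condition itself.
* Growth-phase shear rates are (0, 0.002, 0.01) s⁻¹, i.e.
  $\dot\gamma/\mu_m$ = 0, 7.2 and 36, the upper point inside the reference
  non-dimensional range (up to 144). On the scaled box the smoothing
  response saturates at low rates — the film grows for a comparable number
  of generations but is much shorter, so the cumulative strain per unit
  height is larger, and beyond $\dot\gamma \gtrsim 0.04$ detached material
  wrapping around the short periodic box re-attaches and piles up, which
  raises the roughness again. The chosen rates span the responsive
  quiescent-to-shear-dominated transition. Erosion of the pre-grown film
  uses 0.1–0.4 s⁻¹ (drag-to-adhesion balance of the reference 0.04–0.24 s⁻¹
  at 48 µm transported to 13 µm), compared over a fixed total strain
  $T^{**}=\dot\gamma t = 60$.

Morphology metrics are averaged over the last five recorded frames to damp
snapshot-level noise of the $h_{max}$-normalised porosity.

What passing the scaled trends does and does not show: it demonstrates that
the implemented mechanisms reproduce the directions of the full-scale reference
responses — rougher, more porous films under stronger nutrient limitation;
smoother, more compact films under growth-phase shear; flatter films under
substratum feeding; rise-and-fall erosion event dynamics with mean cluster
size decreasing in shear — under conditions where those mechanisms are the
dominant ones. It does not reproduce full-scale magnitudes (heights,
absolute event counts), and agreement of the scaled detached-biomass
fractions with the full-scale reference percentages, while encouragingly close, should
be read as order-of-magnitude consistency only.

The synthetic environment also idealises real biofilms: mono-sized
inoculum, a single limiting substrate, no detachment by decay weakening, no
pH/temperature effects, no two-way fluid coupling (the flow field is
prescribed), and lognormal cluster statistics estimated from modest event
counts.

## Known limitations

* Quasi-static relaxation discards the transient trajectory between
  equilibria during growth; only the flow phase is time-resolved.
* The advective term is first-order upwind; at high grid Péclet numbers the
  solute front would smear (irrelevant at the shear rates studied).
* Re-agglomerated clusters merge into the attached film without memory of
  their detachment history beyond the event log.
* The three-species preset is a capability demonstration, not a calibrated
  nitrification model.

## Problem sizes used by the test suite

Unit and property tests run on toy systems (1–50 agents, ≤ 30³ voxels).
The trend suite runs five replicates per condition on the scaled box
described above (a few thousand agents per run); the erosion trend grows
one film per replicate and reuses it across three shear rates via the
`init` argument of `runSimulation()`. `scripts/acceptance.R` re-runs the
growth and erosion studies at the same sizes.
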