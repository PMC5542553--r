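#' Functional groups of particulate agents
#'
#' Active groups are heterotrophs (HET), ammonia oxidisers (AOB) and nitrite
#' oxidisers (NOB); EPS particles and dead (inert) agents are the passive
#' groups. Generic single-species simulations use HET.
#'
#' @export
agentGroups <- function() c("HET", "AOB", "NOB", "EPS", "INERT")

.ACTIVE_GROUPS <- c("HET", "AOB", "NOB")

#' Model parameters
#'
#' Kinetic, stoichiometric, mass-transfer and mechanical constants, stored in
#' the units in which they are conventionally reported (rates per hour,
#' concentrations and densities in kg m^-3, spring constants in N m^-1,
#' viscosity in Pa s, lengths in um). Conversion to the internal um/fg/s
#' system happens inside the numerical kernels.
#'
#' @slot muMax maximum specific growth rate (h^-1)
#' @slot decay first-order decay coefficient of active biomass (h^-1)
#' @slot KS substrate affinity / Monod half-saturation (kg m^-3)
#' @slot yield growth yield Y (gCOD biomass per gCOD substrate)
#' @slot yieldEPS EPS formation coefficient Y_EPS (gCOD EPS per gCOD substrate)
#' @slot epsDecay first-order decay of free EPS (h^-1, 0 = negligible)
#' @slot inertDecay first-order decay of inert agents (h^-1, 0 = negligible)
#' @slot DS substrate diffusivity (m^2 s^-1)
#' @slot Sb bulk substrate concentration (kg m^-3)
#' @slot kn normal contact spring coefficient (N m^-1)
#' @slot gammaN normal contact damping coefficient (s^-1)
#' @slot kt tangential spring coefficient (N m^-1)
#' @slot gammaT tangential damping coefficient (s^-1)
#' @slot kEps EPS adhesive stiffness per unit EPS mass (s^-2)
#' @slot muFluid dynamic viscosity of the medium (Pa s)
#' @slot rhoX biomass density in COD equivalents (kg m^-3)
#' @slot rhoEPS EPS density in COD equivalents (kg m^-3)
#' @slot dDiv division threshold diameter (um)
#' @slot dDead death threshold diameter (um)
#' @slot dRemove removal threshold diameter (um)
#' @slot epsExcreteRatio shell/core diameter ratio triggering EPS excretion
#' @slot dtBio biological time step (s)
#' @slot dtMech mechanical time step cap (s)
#' @slot dtDiff diffusion time step cap (s)
#' @slot gammaDot applied shear rate (s^-1)
#' @slot divSep daughter placement rule: "radii" (touching spheres, default)
#'   or "diameters" (literal sum of daughter diameters)
#' @slot linkFormFactor adhesive links form below linkFormFactor*(r_i+r_j)
#' @slot wallAdhesion logical; EPS-carrying agents form adhesive links to the
#'   substratum (wall treated as a particle of infinite radius)
#' @slot pressureTolRel relative virial-pressure tolerance for relaxation
#' @slot relaxMaxIter iteration cap per relaxation phase
#' @slot growthSubstepFrac per-substep growth increment cap of the explicit
#'   Euler biomass update (dimensionless)
#' @slot contactModel "hookean" or "hertzian"
#' @export
setClass("BfParams", representation(
  muMax = "numeric", decay = "numeric", KS = "numeric",
  yield = "numeric", yieldEPS = "numeric",
  epsDecay = "numeric", inertDecay = "numeric",
  DS = "numeric", Sb = "numeric",
  kn = "numeric", gammaN = "numeric", kt = "numeric", gammaT = "numeric",
  kEps = "numeric", muFluid = "numeric",
  rhoX = "numeric", rhoEPS = "numeric",
  dDiv = "numeric", dDead = "numeric", dRemove = "numeric",
  epsExcreteRatio = "numeric",
  dtBio = "numeric", dtMech = "numeric", dtDiff = "numeric",
  gammaDot = "numeric",
  divSep = "character", linkFormFactor = "numeric",
  wallAdhesion = "logical",
  pressureTolRel = "numeric", relaxMaxIter = "numeric",
  growthSubstepFrac = "numeric", contactModel = "character"
))

setValidity("BfParams", function(object) {
  msgs <- character()
  pos <- c("muMax", "KS", "yield", "DS", "Sb", "kn", "kEps", "muFluid",
           "rhoX", "rhoEPS", "dDiv", "dDead", "dRemove",
           "dtBio", "dtMech", "dtDiff", "growthSubstepFrac")
  for (s in pos) {
    v <- slot(object, s)
    if (length(v) != 1 || !is.finite(v) || v <= 0)
      msgs <- c(msgs, sprintf("'%s' must be a single positive finite number", s))
  }
  nonneg <- c("decay", "yieldEPS", "epsDecay", "inertDecay", "gammaN",
              "gammaT", "kt", "gammaDot")
  for (s in nonneg) {
    v <- slot(object, s)
    if (length(v) != 1 || !is.finite(v) || v < 0)
      msgs <- c(msgs, sprintf("'%s' must be a single non-negative finite number", s))
  }
  if (length(msgs) == 0) {
    if (!(object@dRemove < object@dDead && object@dDead < object@dDiv))
      msgs <- c(msgs, "size thresholds must satisfy dRemove < dDead < dDiv")
    if (object@epsExcreteRatio <= 1)
      msgs <- c(msgs, "'epsExcreteRatio' must be > 1")
    if (!(object@dtDiff <= object@dtMech && object@dtMech <= object@dtBio))
      msgs <- c(msgs, "time steps must satisfy dtDiff <= dtMech <= dtBio")
    if (!object@divSep %in% c("radii", "diameters"))
      msgs <- c(msgs, "'divSep' must be \"radii\" or \"diameters\"")
    if (!object@contactModel %in% c("hookean", "hertzian"))
      msgs <- c(msgs, "'contactModel' must be \"hookean\" or \"hertzian\"")
  }
  if (length(msgs)) msgs else TRUE
})

#' Computational domain
#'
#' A rectangular box \eqn{[0,L_x]\times[0,L_y]\times[0,L_z]} with the
#' substratum at z = 0, discretised into Nx x Ny x Nz voxels for the solute
#' solver. Lateral boundaries are periodic by default; the x boundary can be
#' set to "outflow" for detachment runs (agents leaving downstream are removed
#' and ledgered). Nutrient feed is a Dirichlet wall at the top (z = Lz) or at
#' the bottom substratum; the opposite wall is no-flux.
#'
#' @slot Lx,Ly,Lz box dimensions (um)
#' @slot Nx,Ny,Nz voxel counts
#' @slot bcX,bcY lateral boundary mode, "periodic" or "outflow"
#' @slot feed nutrient feed wall, "top" or "bottom"
#' @export
setClass("BfDomain", representation(
  Lx = "numeric", Ly = "numeric", Lz = "numeric",
  Nx = "integer", Ny = "integer", Nz = "integer",
  bcX = "character", bcY = "character", feed = "character"
))

setValidity("BfDomain", function(object) {
  msgs <- character()
  for (s in c("Lx", "Ly", "Lz")) {
    v <- slot(object, s)
    if (length(v) != 1 || !is.finite(v) || v <= 0)
      msgs <- c(msgs, sprintf("'%s' must be positive", s))
  }
  for (s in c("Nx", "Ny", "Nz")) {
    v <- slot(object, s)
    if (length(v) != 1 || is.na(v) || v < 1)
      msgs <- c(msgs, sprintf("'%s' must be a positive integer", s))
  }
  if (!object@bcX %in% c("periodic", "outflow"))
    msgs <- c(msgs, "'bcX' must be \"periodic\" or \"outflow\"")
  if (!object@bcY %in% c("periodic", "outflow"))
    msgs <- c(msgs, "'bcY' must be \"periodic\" or \"outflow\"")
  if (!object@feed %in% c("top", "bottom"))
    msgs <- c(msgs, "'feed' must be \"top\" or \"bottom\"")
  if (length(msgs)) msgs else TRUE
})

#' A population of spherical agents
#'
#' Column-oriented container (one row per agent) used by all kernels:
#' id, group, position (um), velocity (um s^-1), core biomass `mass` (fg COD),
#' attached EPS shell `eps` (fg COD), and the mechanical (outer) radius
#' `radius` (um), derived from core and shell volume at their respective
#' densities. EPS and INERT agents always have `eps = 0`.
#'
#' @slot agents data.frame with columns id, group, x, y, z, vx, vy, vz,
#'   mass, eps, radius
#' @slot nextId next free integer agent id
#' @export
setClass("AgentSet", representation(agents = "data.frame", nextId = "integer"))

.AGENT_COLS <- c("id", "group", "x", "y", "z", "vx", "vy", "vz",
                 "mass", "eps", "radius")

setValidity("AgentSet", function(object) {
  a <- object@agents
  msgs <- character()
  if (!all(.AGENT_COLS %in% names(a)))
    msgs <- c(msgs, paste("agent table must have columns:",
                          paste(.AGENT_COLS, collapse = ", ")))
  else if (nrow(a) > 0) {
    if (anyDuplicated(a$id)) msgs <- c(msgs, "agent ids must be unique")
    if (!all(a$group %in% agentGroups()))
      msgs <- c(msgs, "unknown agent group")
    if (any(a$mass <= 0)) msgs <- c(msgs, "agent masses must be positive")
    if (any(a$eps < 0)) msgs <- c(msgs, "EPS shell masses must be non-negative")
    if (any(a$eps[a$group %in% c("EPS", "INERT")] != 0))
      msgs <- c(msgs, "EPS and INERT agents must have zero shell mass")
  }
  if (length(msgs)) msgs else TRUE
})

#' Reaction network (rate expressions + stoichiometry)
#'
#' Each process has an acting particulate group, a maximum specific rate
#' (h^-1), and optional Monod \eqn{S/(K+S)} and inhibition \eqn{K/(K+S)}
#' factors over named solutes. The stoichiometric matrix maps each process to
#' the particulate groups (HET, AOB, NOB, EPS, INERT) and to the solutes;
#' rates are expressed per unit mass of the acting group, so the volumetric
#' rate of process p in a voxel is rate_p(S) x X_acting (kg m^-3 s^-1).
#' Consumption carries a negative stoichiometric coefficient.
#'
#' @slot processes list of process descriptors (name, group, muMax, monod,
#'   inhibition)
#' @slot stoich numeric matrix, processes x components
#' @slot solutes character vector of solute names
#' @export
setClass("ReactionNetwork", representation(
  processes = "list", stoich = "matrix", solutes = "character"
))

setValidity("ReactionNetwork", function(object) {
  msgs <- character()
  comp <- c(agentGroups(), object@solutes)
  if (nrow(object@stoich) != length(object@processes))
    msgs <- c(msgs, "stoichiometry must have one row per process")
  if (!all(colnames(object@stoich) %in% comp))
    msgs <- c(msgs, "stoichiometry columns must be groups or declared solutes")
  for (p in object@processes) {
    if (!p$group %in% agentGroups())
      msgs <- c(msgs, sprintf("process '%s': unknown acting group", p$name))
    bad <- setdiff(c(names(p$monod), names(p$inhibition)), object@solutes)
    if (length(bad))
      msgs <- c(msgs, sprintf("process '%s': undeclared solute(s) %s",
                              p$name, paste(bad, collapse = ",")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Solute concentration fields
#'
#' One 3-D array (Nx x Ny x Nz, voxel centres, kg m^-3) per solute.
#'
#' @slot fields named list of 3-D arrays
#' @slot domain the [BfDomain-class] the fields live on
#' @export
setClass("SoluteFields", representation(fields = "list", domain = "BfDomain"))

setValidity("SoluteFields", function(object) {
  d <- object@domain
  dims <- c(d@Nx, d@Ny, d@Nz)
  msgs <- character()
  for (nm in names(object@fields)) {
    f <- object@fields[[nm]]
    if (!is.array(f) || !identical(dim(f), as.integer(dims)))
      msgs <- c(msgs, sprintf("field '%s' must be a %s array",
                              nm, paste(dims, collapse = "x")))
    else if (any(f < 0))
      msgs <- c(msgs, sprintf("field '%s' has negative concentrations", nm))
  }
  if (length(msgs)) msgs else TRUE
})

#' Simulation scenario
#'
#' Bundles inoculum specification, feed wall, shear schedule and stop
#' condition for [runSimulation()].
#'
#' @slot name scenario name
#' @slot inoculum list(count, groups, diameter, placement)
#' @slot feed "top" or "bottom"
#' @slot gammaDot shear rate during growth phase (s^-1)
#' @slot shearPhase list describing an optional post-growth shear phase:
#'   gammaDot, duration (s), dtRecord (s); NULL for none
#' @slot stop list(volumeFrac, height, maxSteps); first condition reached wins
#' @slot seed RNG seed
#' @export
setClass("BfScenario", representation(
  name = "character", inoculum = "list", feed = "character",
  gammaDot = "numeric", shearPhase = "list", stop = "list", seed = "numeric"
))

#' Time series of simulation snapshots
#'
#' Frames are recorded after every biological (or shear-phase) step and carry
#' the simulation time plus its non-dimensional forms T* = t mu_m and
#' T** = t gamma_dot, the full agent table, and per-frame summary metrics.
#' Division/EPS/death/removal/detachment events and the COD ledger are global.
#'
#' @slot frames list of frames (time, Tstar, Tss, agents, metrics)
#' @slot events data.frame event log
#' @slot ledger list of cumulative COD bookkeeping totals (fg)
#' @slot params the [BfParams-class] used
#' @slot domain the [BfDomain-class] used
#' @slot scenarioName scenario name
#' @export
setClass("SnapshotSeries", representation(
  frames = "list", events = "data.frame", ledger = "list",
  params = "BfParams", domain = "BfDomain", scenarioName = "character"
))

setValidity("SnapshotSeries", function(object) {
  tt <- vapply(object@frames, function(f) f$time, numeric(1))
  if (length(tt) > 1 && any(diff(tt) <= 0))
    return("frame timestamps must be strictly increasing")
  TRUE
})
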