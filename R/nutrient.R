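## Quasi-steady solute transport on the voxel (MAC) grid: forward-Euler /
## central-difference diffusion, first-order upwind advection of the imposed
## shear flow, Monod reaction sinks, Dirichlet feed wall + no-flux opposite
## wall + periodic lateral boundaries.

#' Create solute fields initialised to the bulk concentration
#'
#' @param domain a [BfDomain-class]
#' @param solutes solute names (or a [ReactionNetwork-class])
#' @param init initial concentration(s), recycled over solutes (kg m^-3)
#' @return a [SoluteFields-class]
#' @export
soluteFields <- function(domain, solutes = "S_S", init = 1e-4) {
  if (is(solutes, "ReactionNetwork")) solutes <- solutes@solutes
  init <- rep_len(init, length(solutes))
  dims <- c(domain@Nx, domain@Ny, domain@Nz)
  f <- lapply(seq_along(solutes), function(i) array(init[i], dims))
  names(f) <- solutes
  methods::new("SoluteFields", fields = f, domain = domain)
}

#' Effective diffusion coefficient per voxel
#'
#' \eqn{D_e = D_S f(X)} with \eqn{X} the total particulate concentration in
#' the voxel. The relative-diffusivity closure `f` must satisfy f(0) = 1,
#' 0 < f <= 1, non-increasing; the default is f = 1 (no hindrance by
#' biomass), and any closure can be plugged in, e.g.
#' `function(X) 1 - 0.2 * pmin(X / Xmax, 1)`.
#'
#' @param aset an [AgentSet-class]
#' @param domain a [BfDomain-class]
#' @param params a [BfParams-class]
#' @param closure relative diffusivity as a function of biomass
#'   concentration (kg m^-3)
#' @return 3-D array of diffusivities (m^2 s^-1)
#' @export
effectiveDiffusivity <- function(aset, domain, params,
                                 closure = function(X) rep(1, length(X))) {
  dims <- c(domain@Nx, domain@Ny, domain@Nz)
  X <- array(0, dims)
  for (g in agentGroups()) X <- X + .biomassField(aset@agents, domain, g)
  f <- closure(as.vector(X))
  if (any(f <= 0 | f > 1))
    stop("relative-diffusivity closure must map into (0, 1]")
  array(params@DS * f, dims)
}

## stability bound for the explicit scheme (s)
.diffStabilityDt <- function(De, domain, gammaDot) {
  hx <- domain@Lx / domain@Nx
  hy <- domain@Ly / domain@Ny
  hz <- domain@Lz / domain@Nz
  DeI <- max(De) * .UM2_PER_M2                    # um^2/s
  diffRate <- 2 * DeI * (1 / hx^2 + 1 / hy^2 + 1 / hz^2)
  advRate <- abs(gammaDot) * domain@Lz / hx
  1 / (diffRate + advRate + 1e-300)
}

#' One explicit step of the advection-diffusion-reaction equation
#'
#' Forward-Euler update with central-difference diffusion (effective
#' diffusivity averaged at faces), first-order upwind advection of the
#' imposed shear flow, and a fixed volumetric source `R`. Boundary
#' conditions: Dirichlet S = Sb at the feed wall, no-flux at the opposite
#' wall, periodic laterally; `feed = "none"` closes both walls (no-flux),
#' which conserves total solute mass exactly in the absence of reaction.
#'
#' @param fields a [SoluteFields-class]
#' @param solute which field to advance
#' @param De 3-D diffusivity array (m^2 s^-1), from [effectiveDiffusivity()]
#' @param R volumetric source (kg m^-3 s^-1); negative = consumption
#' @param dt time step (s); must satisfy the explicit stability bound
#' @param params a [BfParams-class] (Sb, gammaDot defaults)
#' @param feed "top", "bottom" or "none" (default: the domain's feed wall)
#' @param gammaDot shear rate (s^-1)
#' @param Sb feed concentration (kg m^-3)
#' @param nsteps number of identical steps to take
#' @return the updated [SoluteFields-class]
#' @export
stepSolute <- function(fields, solute = "S_S", De, R = NULL, dt, params,
                       feed = fields@domain@feed, gammaDot = params@gammaDot,
                       Sb = params@Sb, nsteps = 1L) {
  d <- fields@domain
  dtMax <- .diffStabilityDt(De, d, gammaDot)
  if (dt > dtMax)
    stop(sprintf("explicit stability bound violated: dt = %g > %g s", dt, dtMax))
  dims <- c(d@Nx, d@Ny, d@Nz)
  if (is.null(R)) R <- array(0, dims)
  feedMode <- match(feed, c("none", "top", "bottom")) - 1L
  if (is.na(feedMode)) stop("'feed' must be \"top\", \"bottom\" or \"none\"")
  res <- cpp_diffuse(fields@fields[[solute]], as.vector(De) * .UM2_PER_M2,
                     matrix(0, 0, 0), numeric(0), as.vector(R),
                     d@Nx, d@Ny, d@Nz,
                     d@Lx / d@Nx, d@Ly / d@Ny, d@Lz / d@Nz,
                     dt, as.integer(nsteps), Sb, feedMode, gammaDot,
                     -1, max(Sb, 1e-300))
  fields@fields[[solute]] <- res$S
  fields
}

#' Solve the solute fields to quasi-steady state
#'
#' Pseudo-time iteration of the explicit scheme (with the reaction term
#' re-evaluated from the current concentrations at every step: Monod sinks
#' in the solute itself stay live, cross-solute factors are refreshed every
#' outer sweep — Picard iteration) until the maximum relative change per
#' step falls below `tol`. Concentrations are clipped at zero. Diffusion is
#' treated as quasi-steady with respect to biomass growth, so the converged
#' field is the steady solution for the current biomass distribution.
#'
#' @param aset an [AgentSet-class] (provides the biomass distribution)
#' @param fields a [SoluteFields-class]; used as the initial guess
#'   (warm start across biological steps)
#' @param net a [ReactionNetwork-class]
#' @param params a [BfParams-class]
#' @param tol relative change per pseudo-time step declaring convergence
#' @param maxIters pseudo-time step budget
#' @param feed feed wall override ("top"/"bottom"/"none")
#' @param gammaDot shear rate for the advective term
#' @param closure relative-diffusivity closure (see
#'   [effectiveDiffusivity()])
#' @return list(fields, iters, relChange, converged)
#' @export
solveQuasiSteady <- function(aset, fields, net, params, tol = 1e-6,
                             maxIters = 200000,
                             feed = fields@domain@feed,
                             gammaDot = params@gammaDot,
                             closure = function(X) rep(1, length(X))) {
  stopifnot(tol > 0)
  d <- fields@domain
  De <- effectiveDiffusivity(aset, d, params, closure)
  dt <- 0.9 * .diffStabilityDt(De, d, gammaDot)
  feedMode <- match(feed, c("none", "top", "bottom")) - 1L
  if (is.na(feedMode)) stop("'feed' must be \"top\", \"bottom\" or \"none\"")
  DeI <- as.vector(De) * .UM2_PER_M2
  chunk <- 400L
  itersTot <- 0L
  relChange <- Inf
  multi <- length(net@solutes) > 1
  cl <- .uptakeClosures(aset, fields, net, params)
  while (itersTot < maxIters) {
    worst <- 0
    stepsThis <- 0L
    for (s in net@solutes) {
      A <- cl[[s]]$A
      if (is.null(A)) A <- matrix(0, 0, 0)
      res <- cpp_diffuse(fields@fields[[s]], DeI, A, cl[[s]]$K, cl[[s]]$B,
                         d@Nx, d@Ny, d@Nz,
                         d@Lx / d@Nx, d@Ly / d@Ny, d@Lz / d@Nz,
                         dt, min(chunk, maxIters - itersTot),
                         params@Sb, feedMode, gammaDot, tol,
                         max(params@Sb, 1e-300))
      fields@fields[[s]] <- res$S
      worst <- max(worst, res$relChange)
      stepsThis <- max(stepsThis, res$steps)
    }
    itersTot <- itersTot + stepsThis
    relChange <- worst
    if (relChange < tol) break
    if (multi) cl <- .uptakeClosures(aset, fields, net, params)
  }
  converged <- relChange < tol
  if (!converged)
    warning(sprintf(
      "quasi-steady solve did not converge in %d steps (residual %.3g)",
      itersTot, relChange))
  list(fields = fields, iters = itersTot, relChange = relChange,
       converged = converged)
}

#' Sample solute concentrations at agent positions
#'
#' Concentrations of the voxel containing each agent's centre (agents sense
#' their own voxel).
#'
#' @param aset an [AgentSet-class]
#' @param fields a [SoluteFields-class]
#' @return matrix, agents x solutes (kg m^-3)
#' @export
localConcentrations <- function(aset, fields) {
  a <- aset@agents
  d <- fields@domain
  out <- matrix(0, nrow(a), length(fields@fields),
                dimnames = list(NULL, names(fields@fields)))
  if (nrow(a) == 0) return(out)
  vox <- .voxelIndex(a, d)
  lin <- (vox[, 3] - 1L) * d@Nx * d@Ny + (vox[, 2] - 1L) * d@Nx + vox[, 1]
  for (s in names(fields@fields)) out[, s] <- fields@fields[[s]][lin]
  out
}
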