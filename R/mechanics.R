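## DEM forces and mechanical relaxation.
##
## R-level force functions implement the model equations directly (and are
## what the tests exercise); the C++ kernels reimplement the same forces for
## the inner loops and are cross-checked against the R versions.

#' Spring-dashpot contact force between two agents
#'
#' Normal force \eqn{F_n = f(\delta)(k_n \delta \hat n - \gamma_n m_{eff}
#' v_n)} and tangential force \eqn{F_t = f(\delta)(-k_t \delta_t - \gamma_t
#' m_{eff} v_t)}, with \eqn{f = 1} for the Hookean model and
#' \eqn{f = \sqrt{\delta d}}, \eqn{d = d_i d_j / (2(d_i + d_j))} for the
#' Hertzian model. Overlap uses the minimum-image convention when a domain
#' is supplied. Non-overlapping pairs experience zero force; the returned
#' pair obeys Newton's third law exactly.
#'
#' @param xi,xj centre positions, length-3 (um)
#' @param ri,rj radii (um)
#' @param vi,vj velocities, length-3 (um s^-1)
#' @param mi,mj masses (fg)
#' @param params a [BfParams-class]
#' @param model "hookean" or "hertzian" (default from `params`)
#' @param deltaT accumulated tangential displacement, length-3 (um)
#' @param domain optional [BfDomain-class] for periodic minimum image
#' @return list(Fi, Fj, overlap): forces on i and j (fg um s^-2)
#' @export
contactForce <- function(xi, xj, ri, rj, vi = c(0, 0, 0), vj = c(0, 0, 0),
                         mi = 1, mj = 1, params = bfParams(),
                         model = params@contactModel,
                         deltaT = c(0, 0, 0), domain = NULL) {
  d <- xj - xi
  if (!is.null(domain)) {
    if (domain@bcX == "periodic") d[1] <- d[1] - round(d[1] / domain@Lx) * domain@Lx
    if (domain@bcY == "periodic") d[2] <- d[2] - round(d[2] / domain@Ly) * domain@Ly
  }
  dist <- sqrt(sum(d^2))
  ov <- ri + rj - dist
  if (ov <= 0) return(list(Fi = c(0, 0, 0), Fj = c(0, 0, 0), overlap = ov))
  if (dist < 1e-12) {
    warning("coincident agent centres; using +z fallback normal")
    nHat <- c(0, 0, 1)
  } else nHat <- d / dist
  f <- if (model == "hertzian") {
    di <- 2 * ri; dj <- 2 * rj
    sqrt(ov * 0.5 * di * dj / (di + dj))
  } else 1
  knI <- params@kn * .FGS2_PER_NM
  ktI <- params@kt * .FGS2_PER_NM
  meff <- mi * mj / (mi + mj)
  vRel <- vj - vi
  vN <- sum(vRel * nHat) * nHat
  vT <- vRel - vN
  ## force on j (normal points i -> j): repulsion pushes j away from i
  FnJ <- f * (knI * ov * nHat - params@gammaN * meff * vN)
  FtJ <- f * (-ktI * deltaT - params@gammaT * meff * vT)
  Fj <- FnJ + FtJ
  list(Fi = -Fj, Fj = Fj, overlap = ov)
}

#' Contact force with the substratum wall
#'
#' The wall at z = 0 acts as a particle of infinite radius: the same
#' spring-dashpot law with effective mass equal to the agent mass and the
#' wall normal +z.
#'
#' @param x position, length-3 (um)
#' @param r radius (um)
#' @param v velocity, length-3 (um s^-1)
#' @param m mass (fg)
#' @param params a [BfParams-class]
#' @param model contact model
#' @return force on the agent, length-3 (fg um s^-2)
#' @export
wallContact <- function(x, r, v = c(0, 0, 0), m = 1, params = bfParams(),
                        model = params@contactModel) {
  ov <- r - x[3]
  if (ov <= 0) return(c(0, 0, 0))
  f <- if (model == "hertzian") sqrt(ov * r) else 1
  knI <- params@kn * .FGS2_PER_NM
  vN <- c(0, 0, v[3])
  f * (knI * ov * c(0, 0, 1) - params@gammaN * m * (-vN))
}

#' EPS-mediated adhesive force of a link
#'
#' Central spring of stiffness \eqn{k_{eps} m^{eps}_{ij}} anchored at rest
#' length \eqn{d_{0ij} = r_i + r_j}: \eqn{F = k_{eps} m^{eps}_{ij} (d_{ij} -
#' d_{0ij}) \hat d}, attractive when stretched. The link breaks (zero force,
#' permanently inactive) once \eqn{d_{ij} \ge 2 d_{0ij}}.
#'
#' @param xi,xj centre positions (um)
#' @param d0 rest length r_i + r_j (um)
#' @param meps combined EPS mass of the pair (fg)
#' @param params a [BfParams-class]
#' @param active link state flag
#' @param domain optional periodic domain
#' @return list(Fi, Fj, active)
#' @export
adhesiveForce <- function(xi, xj, d0, meps, params = bfParams(),
                          active = TRUE, domain = NULL) {
  zero <- list(Fi = c(0, 0, 0), Fj = c(0, 0, 0), active = active)
  if (!active || meps <= 0) return(zero)
  d <- xj - xi
  if (!is.null(domain)) {
    if (domain@bcX == "periodic") d[1] <- d[1] - round(d[1] / domain@Lx) * domain@Lx
    if (domain@bcY == "periodic") d[2] <- d[2] - round(d[2] / domain@Ly) * domain@Ly
  }
  dist <- sqrt(sum(d^2))
  if (dist >= 2 * d0) { zero$active <- FALSE; return(zero) }
  if (dist < 1e-12) return(zero)
  fmag <- params@kEps * meps * (dist - d0)
  Fj <- -fmag * d / dist   # stretched (fmag > 0): j pulled towards i
  list(Fi = -Fj, Fj = Fj, active = TRUE)
}

#' Stokes drag force on an agent
#'
#' \eqn{F = 6 \pi \mu r (U - v)}: zero only when the agent moves with the
#' local fluid.
#'
#' @param r radius (um)
#' @param U local fluid velocity, length-3 (um s^-1)
#' @param v agent velocity, length-3 (um s^-1)
#' @param params a [BfParams-class]
#' @return force, length-3 (fg um s^-2)
#' @export
dragForce <- function(r, U, v = c(0, 0, 0), params = bfParams()) {
  stokesZeta(r, params@muFluid) * (U - v)
}

#' Fluid velocity of the imposed flow at given positions
#'
#' Quiescent (`gammaDot = 0`) or simple shear: U_x = gammaDot * z, zero at
#' the substratum, maximal at the top wall.
#'
#' @param z heights (um)
#' @param gammaDot shear rate (s^-1)
#' @return matrix with columns Ux, Uy, Uz (um s^-1)
#' @export
shearVelocity <- function(z, gammaDot) {
  cbind(Ux = gammaDot * z, Uy = rep(0, length(z)), Uz = rep(0, length(z)))
}

## Adhesive EPS mass an agent contributes to a link: its shell, plus its own
## mass if it is a free EPS particle.
.adhesiveMass <- function(a) a$eps + ifelse(a$group == "EPS", a$mass, 0)

#' Build the adhesive-link table for the current configuration
#'
#' Links form between pairs within `linkFormFactor` times the sum of radii
#' whose combined EPS mass (shells plus free-EPS particle masses) is
#' positive; the rest length is r_i + r_j. When `wallAdhesion` is enabled,
#' EPS-carrying agents within reach of the substratum are linked to it in
#' the same way (wall as particle of infinite radius, rest length r_i).
#' Links are identified by agent ids so they survive reordering.
#'
#' @param aset an [AgentSet-class]
#' @param params a [BfParams-class]
#' @param domain a [BfDomain-class]
#' @return list(pairs = data.frame(idI, idJ, d0, meps, active),
#'   wall = data.frame(id, d0, meps, active))
#' @export
buildLinks <- function(aset, params, domain) {
  a <- aset@agents
  emptyPairs <- data.frame(idI = integer(), idJ = integer(), d0 = numeric(),
                           meps = numeric(), active = logical())
  emptyWall <- data.frame(id = integer(), d0 = numeric(), meps = numeric(),
                          active = logical())
  if (nrow(a) < 1) return(list(pairs = emptyPairs, wall = emptyWall))
  am <- .adhesiveMass(a)
  pairs <- emptyPairs
  if (nrow(a) >= 2) {
    cp <- cpp_close_pairs(as.matrix(a[, c("x", "y", "z")]), a$radius,
                          params@linkFormFactor, domain@Lx, domain@Ly,
                          domain@bcX == "periodic", domain@bcY == "periodic")
    if (length(cp$i)) {
      meps <- am[cp$i] + am[cp$j]
      keep <- meps > 0
      if (any(keep)) {
        pairs <- data.frame(idI = a$id[cp$i[keep]], idJ = a$id[cp$j[keep]],
                            d0 = a$radius[cp$i[keep]] + a$radius[cp$j[keep]],
                            meps = meps[keep], active = TRUE)
      }
    }
  }
  wall <- emptyWall
  if (params@wallAdhesion) {
    nearWall <- which(am > 0 & a$z < params@linkFormFactor * a$radius)
    if (length(nearWall))
      wall <- data.frame(id = a$id[nearWall], d0 = a$radius[nearWall],
                         meps = am[nearWall], active = TRUE)
  }
  list(pairs = pairs, wall = wall)
}

## Marshal links (id-keyed) into row-indexed arrays for the kernels.
.linkArrays <- function(a, links, params) {
  rowOf <- match(links$pairs$idI, a$id)
  rowOf2 <- match(links$pairs$idJ, a$id)
  keep <- !is.na(rowOf) & !is.na(rowOf2)
  lp <- links$pairs[keep, , drop = FALSE]
  lm <- cbind(rowOf[keep], rowOf2[keep])
  if (length(lm) == 0) lm <- matrix(0L, 0, 2)
  wk <- numeric(nrow(a)); wd0 <- rep(1, nrow(a)); wact <- rep(FALSE, nrow(a))
  if (nrow(links$wall)) {
    wrow <- match(links$wall$id, a$id)
    ok <- !is.na(wrow)
    wk[wrow[ok]] <- params@kEps * links$wall$meps[ok]
    wd0[wrow[ok]] <- links$wall$d0[ok]
    wact[wrow[ok]] <- links$wall$active[ok]
  }
  list(mat = lm, k = params@kEps * lp$meps, d0 = lp$d0,
       active = lp$active, pairsKept = lp,
       wk = wk, wd0 = wd0, wact = wact)
}

#' Mechanically relax the agent assembly to force equilibrium
#'
#' Overdamped relaxation of the elastic network (contact, wall contact, EPS
#' adhesion, optional static drag loads) until the virial pressure
#' \eqn{P = |\sum_{pairs} F_{ij} d_{ij}| / (3V)} has fallen below
#' `pressureTolRel` times its running maximum. The position update is a
#' capped-displacement overdamped descent with the step bounded by the
#' stiffest engaged spring, which converges to the same equilibria as
#' time-resolved damped dynamics at these (inertia-free) scales. Adhesive
#' links that stretch beyond twice their rest length break permanently
#' within the phase.
#'
#' @param aset an [AgentSet-class]
#' @param links link tables from [buildLinks()]
#' @param params a [BfParams-class]
#' @param domain a [BfDomain-class]
#' @param dragLoad optional n x 3 matrix of static external forces (fg um
#'   s^-2), e.g. `stokesZeta(r, mu) * U` for agents loaded by the flow
#' @param maxIter iteration cap (default `params@relaxMaxIter`)
#' @param dispCap per-iteration displacement cap (um)
#' @param velTol equilibrium criterion on the overdamped velocity of
#'   spring-free agents (um s^-1)
#' @param posTol per-agent equilibrium criterion (um): converged when the
#'   displacement that would cancel each agent's net force is below this
#'   (jammed adhesive assemblies keep a permanent virial, so vanishing
#'   net force is accepted as equilibrium alongside the pressure criterion)
#' @param method "descent" integrates the overdamped dynamics directly
#'   (inertia-free trajectories, monotone approach); "fire" runs FIRE
#'   minimization with stiffness-preconditioned inertia, which reaches the
#'   same equilibria orders of magnitude faster on large jammed assemblies;
#'   "auto" (default) picks descent below 65 agents and FIRE above
#' @return list(aset, links, pressure, trace, iters)
#' @export
relaxAgents <- function(aset, links, params, domain, dragLoad = NULL,
                        maxIter = params@relaxMaxIter, dispCap = 0.05,
                        velTol = 1e-3, posTol = 2e-4,
                        method = c("auto", "fire", "descent")) {
  method <- match.arg(method)
  a <- aset@agents
  if (nrow(a) == 0)
    return(list(aset = aset, links = links, pressure = 0,
                trace = numeric(0), iters = 0L))
  la <- .linkArrays(a, links, params)
  ext <- if (is.null(dragLoad)) matrix(0, 0, 3) else dragLoad
  res <- cpp_relax(as.matrix(a[, c("x", "y", "z")]), a$radius,
                   stokesZeta(a$radius, params@muFluid),
                   la$mat, la$k, la$d0, la$active, la$wk, la$wd0, la$wact,
                   ext, params@kn * .FGS2_PER_NM,
                   params@contactModel == "hertzian",
                   domain@Lx, domain@Ly, domain@Lz,
                   domain@bcX == "periodic", domain@bcY == "periodic",
                   params@pressureTolRel, .pressAbs(params, domain),
                   as.integer(maxIter), dispCap, params@dtMech, velTol, posTol,
                   switch(method, fire = TRUE, descent = FALSE,
                          auto = nrow(a) > 64))
  a$x <- res$pos[, 1]; a$y <- res$pos[, 2]; a$z <- res$pos[, 3]
  a$vx <- res$vel[, 1]; a$vy <- res$vel[, 2]; a$vz <- res$vel[, 3]
  aset@agents <- a
  links$pairs <- la$pairsKept
  links$pairs$active <- as.logical(res$linkActive)
  if (nrow(links$wall)) {
    wrow <- match(links$wall$id, a$id)
    links$wall$active <- links$wall$active & as.logical(res$wallActive)[wrow]
  }
  list(aset = aset, links = links, pressure = res$pressure,
       trace = res$pressureTrace, iters = res$iters)
}

## absolute pressure floor: the virial of one barely-resolved contact
.pressAbs <- function(params, domain) {
  knI <- params@kn * .FGS2_PER_NM
  knI * 1e-6 * 1 / (3 * domain@Lx * domain@Ly * domain@Lz)
}

#' Advance the assembly through a shear-flow interval
#'
#' Real-time overdamped integration of \eqn{v = U + F_{adh}/\zeta} (EPS
#' adhesion plus Stokes drag under the imposed shear), with the stiff
#' contact interactions resolved by positional projection after each step.
#' Free (detached) material advects with the flow; the attached structure
#' creeps on the adhesive time scale \eqn{\zeta / (k_{eps} m_{eps})}, which
#' is where the time-dependent deformation, streamer elongation and
#' discrete link-breakage events come from.
#'
#' @param aset an [AgentSet-class]
#' @param links link tables from [buildLinks()]
#' @param params a [BfParams-class] (uses `gammaDot` unless overridden)
#' @param domain a [BfDomain-class]
#' @param duration flow time to integrate (s)
#' @param gammaDot shear rate (s^-1)
#' @param dtMax outer step cap (s)
#' @param dispCap displacement cap per step (um)
#' @return list(aset, links, pressure, trace, iters, time)
#' @export
flowPhase <- function(aset, links, params, domain, duration,
                      gammaDot = params@gammaDot, dtMax = 0.25,
                      dispCap = 0.25) {
  a <- aset@agents
  if (nrow(a) == 0)
    return(list(aset = aset, links = links, pressure = 0,
                trace = numeric(0), iters = 0L, time = duration))
  la <- .linkArrays(a, links, params)
  res <- cpp_flow_phase(as.matrix(a[, c("x", "y", "z")]), a$radius,
                        stokesZeta(a$radius, params@muFluid),
                        la$mat, la$k, la$d0, la$active,
                        la$wk, la$wd0, la$wact,
                        params@kn * .FGS2_PER_NM,
                        params@contactModel == "hertzian",
                        domain@Lx, domain@Ly, domain@Lz,
                        domain@bcX == "periodic", domain@bcY == "periodic",
                        gammaDot, duration, dtMax, dispCap,
                        12L, 0.05, as.integer(1e7))
  a$x <- res$pos[, 1]; a$y <- res$pos[, 2]; a$z <- res$pos[, 3]
  a$vx <- res$vel[, 1]; a$vy <- res$vel[, 2]; a$vz <- res$vel[, 3]
  aset@agents <- a
  links$pairs <- la$pairsKept
  links$pairs$active <- as.logical(res$linkActive)
  if (nrow(links$wall)) {
    wrow <- match(links$wall$id, a$id)
    links$wall$active <- links$wall$active & as.logical(res$wallActive)[wrow]
  }
  list(aset = aset, links = links, pressure = res$pressure,
       trace = res$pressureTrace, iters = res$iters, time = res$time)
}

#' Total elastic force on every agent (diagnostic)
#'
#' @inheritParams relaxAgents
#' @param contacts,adhesion include contact / adhesive contributions
#' @return list(F (n x 3), pressure, virial, maxOverlap, nContact)
#' @export
assemblyForces <- function(aset, links, params, domain,
                           contacts = TRUE, adhesion = TRUE) {
  a <- aset@agents
  la <- .linkArrays(a, links, params)
  cpp_forces(as.matrix(a[, c("x", "y", "z")]), a$radius,
             stokesZeta(a$radius, params@muFluid),
             la$mat, la$k, la$d0, la$active, la$wk, la$wd0, la$wact,
             params@kn * .FGS2_PER_NM, params@contactModel == "hertzian",
             domain@Lx, domain@Ly, domain@Lz,
             domain@bcX == "periodic", domain@bcY == "periodic",
             contacts, adhesion)
}
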