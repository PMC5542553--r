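## Discrete lifecycle events: division, EPS excretion, death, removal.
## All random draws are taken in ascending agent-id order so that a run is
## fully reproducible from its seed.

## one uniformly distributed direction on the sphere
.randomDirection <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

#' Divide an agent into two daughters
#'
#' The first daughter receives a mass fraction drawn uniformly from
#' [0.45, 0.55] of the mother's core mass (m/2 plus or minus 10 percent of
#' m), the second the exact remainder, so total mass is conserved to the
#' bit. The EPS shell is split in proportion to the daughter core masses.
#' Daughter 1 keeps the mother's position and id; daughter 2 is displaced
#' along a uniformly random 3-D direction at separation equal to the sum of
#' the daughter radii (touching spheres; set `divSep = "diameters"` on the
#' parameter object for the literal sum-of-diameters placement).
#'
#' @param agent one-row agent data.frame at or above the division threshold
#' @param params a [BfParams-class]
#' @param newId id to assign to the second daughter
#' @return two-row agent data.frame (daughter 1 first)
#' @export
divideAgent <- function(agent, params, newId = agent$id + 1L) {
  stopifnot(nrow(agent) == 1)
  dCore <- 2 * coreRadius(agent$mass, agent$group, params)
  if (dCore < params@dDiv)
    stop(sprintf("agent %d below division threshold (%.3g < %g um)",
                 agent$id, dCore, params@dDiv))
  frac <- stats::runif(1, 0.45, 0.55)
  m1 <- frac * agent$mass
  m2 <- agent$mass - m1
  e1 <- agent$eps * (m1 / agent$mass)
  e2 <- agent$eps - e1
  d1 <- agent; d2 <- agent
  d1$mass <- m1; d1$eps <- e1
  d2$mass <- m2; d2$eps <- e2; d2$id <- as.integer(newId)
  d1$radius <- outerRadius(m1, e1, agent$group, params)
  d2$radius <- outerRadius(m2, e2, agent$group, params)
  sep <- d1$radius + d2$radius
  if (params@divSep == "diameters") sep <- 2 * sep
  dir <- .randomDirection()
  d2$x <- d2$x + dir[1] * sep
  d2$y <- d2$y + dir[2] * sep
  d2$z <- max(d2$z + dir[3] * sep, 0.02)
  rbind(d1, d2)
}

#' Excrete a saturated EPS shell as a free EPS particle
#'
#' When the composite (core + shell) diameter of a heterotroph reaches
#' `epsExcreteRatio` (default 1.25) times its core diameter, the entire
#' shell mass becomes a free EPS agent placed adjacent to the cell in a
#' uniformly random direction, and the shell resets to zero. The shell
#' volume is computed at the EPS density.
#'
#' @param agent one-row agent data.frame (HET)
#' @param params a [BfParams-class]
#' @param newId id for the excreted EPS agent
#' @return list(agent = updated one-row data.frame, eps = one-row data.frame
#'   for the new EPS agent, or NULL when below threshold)
#' @export
secreteEps <- function(agent, params, newId) {
  stopifnot(nrow(agent) == 1)
  if (agent$group != "HET" || agent$eps <= 0)
    return(list(agent = agent, eps = NULL))
  rCore <- coreRadius(agent$mass, agent$group, params)
  rOuter <- outerRadius(agent$mass, agent$eps, agent$group, params)
  if (rOuter < params@epsExcreteRatio * rCore)
    return(list(agent = agent, eps = NULL))
  epsMass <- agent$eps
  agent$eps <- 0
  agent$radius <- outerRadius(agent$mass, 0, agent$group, params)
  rEps <- radiusFromMass(epsMass, params@rhoEPS)
  dir <- .randomDirection()
  sep <- agent$radius + rEps
  eps <- agent
  eps$id <- as.integer(newId)
  eps$group <- "EPS"
  eps$mass <- epsMass
  eps$eps <- 0
  eps$radius <- rEps
  eps$x <- agent$x + dir[1] * sep
  eps$y <- agent$y + dir[2] * sep
  eps$z <- max(agent$z + dir[3] * sep, 0.02)
  list(agent = agent, eps = eps)
}

#' Death and removal sweep
#'
#' Active agents whose core diameter has shrunk to the death threshold
#' (default 0.8 um) become inert; any remaining shell is released as a free
#' EPS particle at the agent's position so that dead agents carry no shell.
#' Agents whose outer diameter has shrunk to the removal threshold (default
#' 0.1 um) are deleted and their mass is added to the removal ledger.
#'
#' @param aset an [AgentSet-class]
#' @param params a [BfParams-class]
#' @return list(aset, removedMass (fg), events (data.frame))
#' @export
deathAndRemoval <- function(aset, params) {
  a <- aset@agents
  ev <- list()
  nextId <- aset@nextId
  if (nrow(a)) {
    dCore <- 2 * coreRadius(a$mass, a$group, params)
    dying <- which(a$group %in% .ACTIVE_GROUPS & dCore <= params@dDead)
    if (length(dying)) {
      shells <- NULL
      for (i in dying[order(a$id[dying])]) {
        if (a$eps[i] > 0) {
          sh <- a[i, ]
          sh$id <- as.integer(nextId); nextId <- nextId + 1L
          sh$group <- "EPS"; sh$mass <- a$eps[i]; sh$eps <- 0
          sh$radius <- radiusFromMass(sh$mass, params@rhoEPS)
          shells <- rbind(shells, sh)
          a$eps[i] <- 0
        }
        ev[[length(ev) + 1L]] <- data.frame(type = "death", id1 = a$id[i],
                                            id2 = NA_integer_, mass = a$mass[i])
      }
      a$group[dying] <- "INERT"
      a <- .refreshRadii(a, params)
      if (!is.null(shells)) a <- rbind(a, shells)
    }
  }
  removedMass <- 0
  if (nrow(a)) {
    dOuter <- 2 * outerRadius(a$mass, a$eps, a$group, params)
    gone <- which(dOuter <= params@dRemove)
    if (length(gone)) {
      for (i in gone)
        ev[[length(ev) + 1L]] <- data.frame(type = "removal", id1 = a$id[i],
                                            id2 = NA_integer_,
                                            mass = a$mass[i] + a$eps[i])
      removedMass <- sum(a$mass[gone] + a$eps[gone])
      a <- a[-gone, , drop = FALSE]
    }
  }
  aset@agents <- a
  aset@nextId <- as.integer(nextId)
  list(aset = aset, removedMass = removedMass,
       events = if (length(ev)) do.call(rbind, ev) else .emptyEvents())
}

.emptyEvents <- function() {
  data.frame(type = character(), id1 = integer(), id2 = integer(),
             mass = numeric())
}

#' Apply one full lifecycle sweep (division, EPS excretion, death, removal)
#'
#' Events are applied in a fixed deterministic order: all eligible divisions
#' in ascending id order, then EPS excretion checks in ascending id order,
#' then the death/removal sweep, so a given RNG seed reproduces the run
#' exactly.
#'
#' @param aset an [AgentSet-class]
#' @param params a [BfParams-class]
#' @return list(aset, removedMass, events)
#' @export
lifecycleStep <- function(aset, params) {
  a <- aset@agents
  nextId <- aset@nextId
  ev <- list()
  if (nrow(a)) {
    dCore <- 2 * coreRadius(a$mass, a$group, params)
    divIdx <- which(a$group %in% .ACTIVE_GROUPS & dCore >= params@dDiv)
    rows <- list()
    if (length(divIdx)) {
      divIdx <- divIdx[order(a$id[divIdx])]
      for (i in divIdx) {
        dd <- divideAgent(a[i, ], params, newId = nextId)
        nextId <- nextId + 1L
        a[i, ] <- dd[1, ]
        rows[[length(rows) + 1L]] <- dd[2, ]
        ev[[length(ev) + 1L]] <- data.frame(type = "division", id1 = dd$id[1],
                                            id2 = dd$id[2], mass = sum(dd$mass))
      }
      if (length(rows)) a <- rbind(a, do.call(rbind, rows))
    }
    ## EPS excretion
    hetIdx <- which(a$group == "HET" & a$eps > 0)
    if (length(hetIdx)) {
      hetIdx <- hetIdx[order(a$id[hetIdx])]
      newEps <- list()
      for (i in hetIdx) {
        res <- secreteEps(a[i, ], params, newId = nextId)
        if (!is.null(res$eps)) {
          nextId <- nextId + 1L
          a[i, ] <- res$agent
          newEps[[length(newEps) + 1L]] <- res$eps
          ev[[length(ev) + 1L]] <- data.frame(type = "eps_excrete",
                                              id1 = res$agent$id,
                                              id2 = res$eps$id,
                                              mass = res$eps$mass)
        }
      }
      if (length(newEps)) a <- rbind(a, do.call(rbind, newEps))
    }
  }
  aset@agents <- a
  aset@nextId <- as.integer(nextId)
  dr <- deathAndRemoval(aset, params)
  events <- rbind(if (length(ev)) do.call(rbind, ev) else .emptyEvents(),
                  dr$events)
  list(aset = dr$aset, removedMass = dr$removedMass, events = events)
}
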