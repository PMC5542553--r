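## Scenario presets, inoculum generation and the main simulation loop.

#' Construct a scenario
#'
#' @param name scenario label
#' @param inoculum list(count, groups, diameter, placement, xFrac):
#'   `placement` is "grid" (evenly spread on the substratum), "centre", or a
#'   matrix of xyz positions; `xFrac` restricts grid placement to the first
#'   fraction of the x extent (used by detachment runs in a doubled box)
#' @param feed nutrient feed wall, "top" or "bottom"
#' @param gammaDot shear rate during the growth phase (s^-1)
#' @param shearPhase NULL, or list(gammaDot, duration, dtRecord, biology)
#'   describing a post-growth shear/erosion phase
#' @param stop list with any of volumeFrac (stop when total agent volume
#'   reaches this fraction of the box), height (um), maxSteps
#' @param seed RNG seed
#' @return a [BfScenario-class]
#' @export
bfScenario <- function(name = "growth_grid",
                       inoculum = list(count = 40, groups = "HET",
                                       diameter = 1, placement = "grid",
                                       xFrac = 1),
                       feed = "top", gammaDot = 0, shearPhase = NULL,
                       stop = list(volumeFrac = 0.15, maxSteps = 2000),
                       seed = 1) {
  if (is.null(stop$maxSteps)) stop$maxSteps <- 2000
  methods::new("BfScenario", name = name, inoculum = inoculum, feed = feed,
               gammaDot = gammaDot,
               shearPhase = if (is.null(shearPhase)) list() else shearPhase,
               stop = stop, seed = seed)
}

#' Scenario presets
#'
#' \describe{
#'   \item{growth_grid}{40 bacteria of 1 um diameter evenly distributed on
#'     the substratum, quiescent medium, stop at 15 percent box volume.}
#'   \item{three_species_demo}{one HET, one AOB and one NOB inoculated at
#'     the centre of the substratum.}
#'   \item{shear_growth}{growth under simple shear at `gammaDot`.}
#'   \item{detachment}{a biofilm grown without flow to a target height,
#'     then eroded under shear; pair it with a domain doubled in x with an
#'     outflow boundary so detached clusters can be tracked and leave.}
#' }
#'
#' @param name preset name
#' @param gammaDot shear rate where applicable (s^-1)
#' @param seed RNG seed
#' @param ... overrides passed to [bfScenario()]
#' @return a [BfScenario-class]
#' @export
scenarioPreset <- function(name = c("growth_grid", "three_species_demo",
                                    "shear_growth", "detachment"),
                           gammaDot = 0.2, seed = 1, ...) {
  name <- match.arg(name)
  base <- switch(name,
    growth_grid = list(),
    three_species_demo = list(
      inoculum = list(count = 3, groups = c("HET", "AOB", "NOB"),
                      diameter = 1, placement = "centre", xFrac = 1),
      stop = list(volumeFrac = 0.05, maxSteps = 400)),
    shear_growth = list(gammaDot = gammaDot),
    detachment = list(
      inoculum = list(count = 4, groups = "HET", diameter = 1,
                      placement = "grid", xFrac = 0.5),
      stop = list(height = 48, maxSteps = 2000),
      shearPhase = list(gammaDot = gammaDot, duration = 600,
                        dtRecord = 5, biology = FALSE)))
  args <- utils::modifyList(c(base, list(name = name, seed = seed)), list(...))
  do.call(bfScenario, args)
}

#' Generate the initial inoculum
#'
#' Cells of the specified diameter (default 1 um) are placed resting on the
#' substratum (z = r). Grid placement spreads `count` cells evenly over the
#' substratum (over the first `xFrac` of x); "centre" clusters them around
#' the middle of the substratum, one diameter apart. Identical seeds give
#' bitwise-identical inocula.
#'
#' @param spec inoculum list (see [bfScenario()])
#' @param params a [BfParams-class]
#' @param domain a [BfDomain-class]
#' @return an [AgentSet-class]
#' @export
makeInoculum <- function(spec, params, domain) {
  count <- spec$count
  if (is.null(count) || count < 1) stop("inoculum count must be >= 1")
  diam <- spec$diameter %||% 1
  groups <- rep_len(spec$groups %||% "HET", count)
  xFrac <- spec$xFrac %||% 1
  r <- diam / 2
  if (is.matrix(spec$placement)) {
    pos <- spec$placement
    if (nrow(pos) != count) stop("placement matrix must have 'count' rows")
  } else if (identical(spec$placement, "centre")) {
    off <- (seq_len(count) - (count + 1) / 2) * diam
    pos <- cbind(domain@Lx / 2 + off, domain@Ly / 2, r)
  } else {
    Lx <- domain@Lx * xFrac
    if (count > floor(Lx / diam) * floor(domain@Ly / diam))
      stop("inoculum count exceeds substratum packing")
    nx <- max(1L, ceiling(sqrt(count * Lx / domain@Ly)))
    ny <- ceiling(count / nx)
    g <- expand.grid(i = seq_len(nx), j = seq_len(ny))[seq_len(count), ]
    pos <- cbind((g$i - 0.5) / nx * Lx, (g$j - 0.5) / ny * domain@Ly, r)
  }
  mass <- massFromRadius(r, params@rhoX)
  agentSet(data.frame(group = groups, x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      mass = mass, eps = 0), params)
}

## ---- the simulation loop ---------------------------------------------------

.emptyRunEvents <- function() {
  data.frame(time = numeric(), type = character(), id1 = integer(),
             id2 = integer(), mass = numeric(), n = integer(),
             volume = numeric(), normVolume = numeric())
}

.padEvents <- function(ev, time) {
  if (nrow(ev) == 0) return(.emptyRunEvents())
  data.frame(time = time, type = ev$type, id1 = ev$id1, id2 = ev$id2,
             mass = ev$mass, n = NA_integer_, volume = NA_real_,
             normVolume = NA_real_)
}

## detachment bookkeeping: flag clusters newly detached, count each agent at
## most once, return events + updated counted set
.detachEvents <- function(a, cc, counted, time, params) {
  ev <- .emptyRunEvents()
  if (nrow(a) == 0) return(list(events = ev, counted = counted))
  attVol <- sum(4 / 3 * pi * a$radius[cc$attached]^3)
  for (cl in unique(cc$cluster[!cc$attached])) {
    ids <- cc$id[cc$cluster == cl]
    fresh <- setdiff(ids, counted)
    if (length(fresh) == 0) next
    rows <- match(fresh, a$id)
    vol <- sum(4 / 3 * pi * a$radius[rows]^3)
    ev <- rbind(ev, data.frame(
      time = time, type = "detach", id1 = fresh[1], id2 = NA_integer_,
      mass = sum(a$mass[rows] + a$eps[rows]), n = length(fresh),
      volume = vol,
      normVolume = if (attVol > 0) vol / attVol else NA_real_))
    counted <- c(counted, fresh)
  }
  ## re-attached agents may detach again later as a new event
  counted <- setdiff(counted, cc$id[cc$attached])
  list(events = ev, counted = counted)
}

## remove agents that left through an outflow x boundary
.outflowSweep <- function(aset, domain) {
  a <- aset@agents
  if (domain@bcX != "outflow" || nrow(a) == 0)
    return(list(aset = aset, mass = 0, n = 0L))
  gone <- a$x - a$radius > domain@Lx | a$x + a$radius < 0
  m <- sum(a$mass[gone] + a$eps[gone])
  aset@agents <- a[!gone, , drop = FALSE]
  list(aset = aset, mass = m, n = sum(gone))
}

#' Run a full biofilm simulation
#'
#' Per biological step: (1) solve the solute fields to quasi-steady state
#' for the current biomass distribution; (2) grow/decay all agents at their
#' local concentrations; (3) apply division, EPS excretion, death and
#' removal; (4) rebuild adhesive links; (5) relax to mechanical force
#' equilibrium (with static drag loading of the attached structure under
#' shear, and real-time advection of detached material); then record a
#' snapshot and evaluate the stop condition. A scenario with a `shearPhase`
#' then switches to real-time erosion stepping of the grown biofilm under
#' the phase's shear rate, recording detachment events.
#'
#' @param scenario a [BfScenario-class]
#' @param params a [BfParams-class]
#' @param domain a [BfDomain-class]
#' @param net a [ReactionNetwork-class]; default [singleSpeciesNetwork()]
#' @param init optional [AgentSet-class] (e.g. a re-loaded snapshot) used as
#'   the starting population instead of generating an inoculum; with
#'   `stop = list(maxSteps = 0)` this runs only the shear phase on a
#'   pre-grown biofilm
#' @param recordSolutes keep the final solute fields on the series
#' @param quasiTol quasi-steady convergence tolerance
#' @param verbose print per-step progress
#' @return a [SnapshotSeries-class]
#' @export
runSimulation <- function(scenario, params, domain, net = NULL, init = NULL,
                          recordSolutes = FALSE, quasiTol = 1e-6,
                          verbose = FALSE) {
  stopifnot(is(scenario, "BfScenario"), is(params, "BfParams"),
            is(domain, "BfDomain"))
  if (is.null(net)) net <- singleSpeciesNetwork(params)
  set.seed(scenario@seed)
  aset <- if (is.null(init)) makeInoculum(scenario@inoculum, params, domain)
          else init
  fields <- soluteFields(domain, net, init = params@Sb)
  feed <- scenario@feed
  gD <- scenario@gammaDot
  boxVol <- domain@Lx * domain@Ly * domain@Lz
  ledger <- list(initial = sum(aset@agents$mass) + sum(aset@agents$eps),
                 grown = 0, decayed = 0, removed = 0, outflow = 0)
  events <- .emptyRunEvents()
  frames <- list()
  counted <- integer(0)
  links <- buildLinks(aset, params, domain)
  t <- 0

  recordFrame <- function(aset, fields, pressure, phase) {
    a <- aset@agents
    rownames(a) <- NULL
    rates <- if (nrow(a)) {
      .agentRates(a, localConcentrations(aset, fields), net)$growth
    } else numeric(0)
    h <- heightField(a, domain)
    F <- occupancyField(a, domain)
    mo <- morphology(h, F, domain)
    metrics <- c(mo[c("meanHeight", "maxHeight", "roughness", "porosity")],
                 as.list(volumeFractions(a, params)),
                 list(activeLayer = activeLayerThickness(a, rates, domain),
                      nAgents = nrow(a), totalMass = sum(a$mass) + sum(a$eps),
                      volumeFrac = agentVolume(a, params) / boxVol,
                      pressure = pressure, phase = phase))
    frames[[length(frames) + 1L]] <<- list(
      time = t, Tstar = t * perHourToPerSec(params@muMax),
      Tss = t * max(gD, if (length(scenario@shearPhase)) scenario@shearPhase$gammaDot else 0),
      agents = a, metrics = metrics)
  }

  stopHit <- function(a) {
    st <- scenario@stop
    if (!is.null(st$volumeFrac) &&
        agentVolume(a, params) / boxVol >= st$volumeFrac) return(TRUE)
    if (!is.null(st$height) && nrow(a) &&
        max(a$z + a$radius) >= st$height) return(TRUE)
    FALSE
  }

  ## ---- growth phase ----
  for (step in seq_len(scenario@stop$maxSteps)) {
    qs <- solveQuasiSteady(aset, fields, net, params, tol = quasiTol,
                           feed = feed, gammaDot = gD)
    fields <- qs$fields
    localS <- localConcentrations(aset, fields)
    sb <- stepBiomass(aset, localS, net, params)
    aset <- sb$aset
    ledger$grown <- ledger$grown + sb$grown
    ledger$decayed <- ledger$decayed + sb$decayed
    lc <- lifecycleStep(aset, params)
    aset <- lc$aset
    ledger$removed <- ledger$removed + lc$removedMass
    events <- rbind(events, .padEvents(lc$events, t))
    links <- buildLinks(aset, params, domain)
    dragLoad <- NULL
    if (gD > 0 && nrow(aset@agents)) {
      cc0 <- clusterComponents(aset, links, params, domain)
      U <- shearVelocity(aset@agents$z, gD)
      zeta <- stokesZeta(aset@agents$radius, params@muFluid)
      dragLoad <- U * zeta * cc0$attached
    }
    rx <- relaxAgents(aset, links, params, domain, dragLoad = dragLoad,
                      posTol = 1e-3)
    aset <- rx$aset
    links <- rx$links
    t <- t + params@dtBio
    if (gD > 0 && nrow(aset@agents)) {
      ## advect detached material through the biological step in real time
      cc <- clusterComponents(aset, links, params, domain)
      free <- !cc$attached
      if (any(free)) {
        a <- aset@agents
        dx <- gD * a$z[free] * params@dtBio
        xNew <- a$x[free] + dx
        if (domain@bcX == "periodic") xNew <- xNew %% domain@Lx
        a$x[free] <- xNew
        aset@agents <- a
        ow <- .outflowSweep(aset, domain)
        aset <- ow$aset
        ledger$outflow <- ledger$outflow + ow$mass
      }
    }
    cc <- clusterComponents(aset, links, params, domain)
    de <- .detachEvents(aset@agents, cc, counted, t, params)
    events <- rbind(events, de$events)
    counted <- de$counted
    recordFrame(aset, fields, rx$pressure, "growth")
    if (verbose)
      message(sprintf("step %d t=%.3gd n=%d h=%.3g P=%.3g", step, t / 86400,
                      nrow(aset@agents),
                      frames[[length(frames)]]$metrics$maxHeight, rx$pressure))
    if (stopHit(aset@agents)) break
    if (nrow(aset@agents) == 0) break
  }

  ## ---- shear / erosion phase ----
  sp <- scenario@shearPhase
  if (length(sp)) {
    gS <- sp$gammaDot
    dtRec <- sp$dtRecord %||% 5
    nRec <- ceiling((sp$duration %||% 600) / dtRec)
    initVol <- agentVolume(aset@agents, params)
    for (k in seq_len(nRec)) {
      if (nrow(aset@agents) == 0) break
      if (isTRUE(sp$biology)) {
        qs <- solveQuasiSteady(aset, fields, net, params, tol = quasiTol,
                               feed = feed, gammaDot = gS)
        fields <- qs$fields
        localS <- localConcentrations(aset, fields)
        sb <- stepBiomass(aset, localS, net, params, dt = dtRec)
        aset <- sb$aset
        ledger$grown <- ledger$grown + sb$grown
        ledger$decayed <- ledger$decayed + sb$decayed
        lc <- lifecycleStep(aset, params)
        aset <- lc$aset
        ledger$removed <- ledger$removed + lc$removedMass
        events <- rbind(events, .padEvents(lc$events, t))
      }
      ## new links may form between bio/record steps (re-agglomeration);
      ## broken pairs only re-form if they drift back within formation range
      links <- buildLinks(aset, params, domain)
      fp <- flowPhase(aset, links, params, domain, duration = dtRec,
                      gammaDot = gS)
      aset <- fp$aset
      links <- fp$links
      t <- t + dtRec
      ow <- .outflowSweep(aset, domain)
      aset <- ow$aset
      ledger$outflow <- ledger$outflow + ow$mass
      cc <- clusterComponents(aset, links, params, domain)
      de <- .detachEvents(aset@agents, cc, counted, t, params)
      events <- rbind(events, de$events)
      counted <- de$counted
      recordFrame(aset, fields, fp$pressure, "shear")
      if (verbose)
        message(sprintf("shear %d t=%.4gs n=%d events=%d", k, t,
                        nrow(aset@agents), sum(events$type == "detach")))
    }
  }

  out <- methods::new("SnapshotSeries", frames = frames, events = events,
                      ledger = ledger, params = params, domain = domain,
                      scenarioName = scenario@name)
  if (recordSolutes) out@frames[[length(out@frames)]]$solutes <- fields
  out
}
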