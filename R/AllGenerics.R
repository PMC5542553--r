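#' @include AllClasses.R
NULL

#' Extract the agent table
#' @param x an [AgentSet-class] or [SnapshotSeries-class]
#' @param ... further arguments (frame index `i` for a series)
#' @return data.frame, one row per agent
#' @export
setGeneric("agentTable", function(x, ...) standardGeneric("agentTable"))

#' Number of agents
#' @param x an [AgentSet-class] or [SnapshotSeries-class]
#' @export
setGeneric("nAgents", function(x) standardGeneric("nAgents"))

#' Frame times of a snapshot series (s)
#' @param x a [SnapshotSeries-class]
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' Event log of a simulation
#' @param x a [SnapshotSeries-class]
#' @export
setGeneric("eventLog", function(x) standardGeneric("eventLog"))

#' Cumulative COD ledger of a simulation
#' @param x a [SnapshotSeries-class]
#' @export
setGeneric("codLedger", function(x) standardGeneric("codLedger"))

#' @describeIn agentTable agents of an AgentSet
#' @export
setMethod("agentTable", "AgentSet", function(x, ...) x@agents)

#' @describeIn nAgents number of agents in an AgentSet
#' @export
setMethod("nAgents", "AgentSet", function(x) nrow(x@agents))

#' @describeIn agentTable agents of frame `i` (default: last frame)
#' @param i frame index
#' @export
setMethod("agentTable", "SnapshotSeries", function(x, i = length(x@frames), ...) {
  x@frames[[i]]$agents
})

#' @describeIn nAgents agents in the final frame of a series
#' @export
setMethod("nAgents", "SnapshotSeries", function(x) {
  nrow(x@frames[[length(x@frames)]]$agents)
})

#' @describeIn frameTimes frame times in seconds
#' @export
setMethod("frameTimes", "SnapshotSeries", function(x) {
  vapply(x@frames, function(f) f$time, numeric(1))
})

#' @describeIn eventLog the event data.frame (one row per discrete event)
#' @export
setMethod("eventLog", "SnapshotSeries", function(x) x@events)

#' @describeIn codLedger named list of cumulative COD totals (fg)
#' @export
setMethod("codLedger", "SnapshotSeries", function(x) x@ledger)

setMethod("show", "BfParams", function(object) {
  cat("BfParams (biofilm IbM parameters)\n")
  cat(sprintf("  kinetics: mu_m=%g/h b=%g/h K_S=%g kg/m3 Y=%g Y_EPS=%g\n",
              object@muMax, object@decay, object@KS, object@yield,
              object@yieldEPS))
  cat(sprintf("  transfer: D_S=%g m2/s S_b=%g kg/m3\n", object@DS, object@Sb))
  cat(sprintf("  mechanics: k_n=%g N/m k_eps=%g 1/s2 mu=%g Pa.s (%s contact)\n",
              object@kn, object@kEps, object@muFluid, object@contactModel))
  cat(sprintf("  densities: rho_X=%.4g rho_EPS=%.4g kg/m3 (COD)\n",
              object@rhoX, object@rhoEPS))
  cat(sprintf("  thresholds: divide %g um, die %g um, remove %g um, EPS shell x%g\n",
              object@dDiv, object@dDead, object@dRemove, object@epsExcreteRatio))
  cat(sprintf("  time steps: bio %gs mech %gs diff %gs; shear %g/s\n",
              object@dtBio, object@dtMech, object@dtDiff, object@gammaDot))
})

setMethod("show", "BfDomain", function(object) {
  cat(sprintf("BfDomain %gx%gx%g um, grid %dx%dx%d, bc x/y: %s/%s, feed: %s\n",
              object@Lx, object@Ly, object@Lz, object@Nx, object@Ny, object@Nz,
              object@bcX, object@bcY, object@feed))
})

setMethod("show", "AgentSet", function(object) {
  a <- object@agents
  cat(sprintf("AgentSet with %d agents", nrow(a)))
  if (nrow(a)) {
    tab <- table(factor(a$group, levels = agentGroups()))
    cat(": ", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), sep = "")
    cat(sprintf("\n  total biomass %.4g fg COD (+%.4g fg EPS shell), max height %.3g um\n",
                sum(a$mass), sum(a$eps), max(a$z + a$radius)))
  } else cat("\n")
})

setMethod("show", "ReactionNetwork", function(object) {
  cat(sprintf("ReactionNetwork: %d processes over solutes %s\n",
              length(object@processes), paste(object@solutes, collapse = ", ")))
  for (p in object@processes)
    cat(sprintf("  %-16s acting on %-5s muMax=%g/h monod(%s)\n",
                p$name, p$group, p$muMax,
                paste(names(p$monod), collapse = ",")))
})

setMethod("show", "SnapshotSeries", function(object) {
  nf <- length(object@frames)
  cat(sprintf("SnapshotSeries '%s': %d frames", object@scenarioName, nf))
  if (nf) {
    tf <- object@frames[[nf]]
    cat(sprintf(", t = %.3g s (%.3g d), %d agents in final frame",
                tf$time, tf$time / 86400, nrow(tf$agents)))
  }
  cat(sprintf("\n  %d logged events\n", nrow(object@events)))
})
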