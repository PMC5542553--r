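#' Monod saturation factor
#'
#' \eqn{S/(K+S)}: 0 at S = 0, one half at S = K, approaching 1 as S grows.
#'
#' @param S substrate concentration (kg m^-3), non-negative
#' @param K half-saturation constant (kg m^-3), positive
#' @return dimensionless factor in [0, 1)
#' @examples
#' monod(3.5e-5, 3.5e-5)  # 0.5
#' @export
monod <- function(S, K) {
  if (any(K <= 0)) stop("'K' must be positive")
  if (any(S < 0)) stop("negative substrate concentration")
  S / (K + S)
}

#' Inhibition factor K/(K+S)
#' @inheritParams monod
#' @return dimensionless factor in (0, 1]
#' @export
inhibition <- function(S, K) {
  if (any(K <= 0)) stop("'K' must be positive")
  if (any(S < 0)) stop("negative substrate concentration")
  K / (K + S)
}

## rate of one process (1/h per unit acting biomass) at local concentrations
.processRate <- function(p, local) {
  r <- p$muMax
  for (s in names(p$monod)) r <- r * monod(local[[s]], p$monod[[s]])
  for (s in names(p$inhibition)) r <- r * inhibition(local[[s]], p$inhibition[[s]])
  r
}

#' Specific net growth/decay rate of an agent group
#'
#' Sums stoichiometry-weighted rates of all processes acting on the group,
#' evaluated at the solute concentrations of the voxel holding the agent:
#' for a heterotroph in the single-species network this is
#' \eqn{\mu_m S/(K_S+S) - b}. The sign may be negative (net shrinkage).
#'
#' @param group agent group ("HET", "AOB", "NOB", "EPS" or "INERT")
#' @param local named list/vector of local solute concentrations (kg m^-3)
#' @param net a [ReactionNetwork-class]
#' @return net specific rate (h^-1)
#' @export
specificRate <- function(group, local, net) {
  acting <- vapply(net@processes, function(p) p$group == group, logical(1))
  if (!any(acting))
    stop(sprintf("agent group '%s' has no process in the reaction network", group))
  r <- 0
  for (i in which(acting)) {
    p <- net@processes[[i]]
    r <- r + net@stoich[i, group] * .processRate(p, local)
  }
  r
}

## Per-agent kinetic decomposition at frozen local concentrations.
## Returns per-agent growth rate, decay rate and shell-accrual rate (1/h):
##   core:  dm/dt  = (g - d) m
##   shell: de/dt  = gEps m - d e        (shell decays with the core)
.agentRates <- function(a, localS, net) {
  n <- nrow(a)
  g <- numeric(n); d <- numeric(n); gEps <- numeric(n)
  for (i in seq_along(net@processes)) {
    p <- net@processes[[i]]
    sel <- a$group == p$group
    if (!any(sel)) next
    loc <- lapply(stats::setNames(colnames(localS), colnames(localS)),
                  function(s) localS[sel, s])
    rate <- .processRate(p, loc)            # vector over selected agents
    coef <- net@stoich[i, p$group]
    if (coef >= 0) {
      g[sel] <- g[sel] + coef * rate
      gEps[sel] <- gEps[sel] + net@stoich[i, "EPS"] * rate
    } else {
      d[sel] <- d[sel] - coef * rate
    }
  }
  list(growth = g, decay = d, shellGain = gEps)
}

#' Advance agent biomass by one biological step
#'
#' Explicit Euler update \eqn{m \leftarrow m (1 + r\,\Delta t)} of core mass
#' and EPS shell at frozen (quasi-steady) local solute concentrations. To
#' bound the truncation error of the explicit scheme, the step is divided
#' into equal sub-steps such that no sub-step changes any mass by more than
#' `growthSubstepFrac` (default 1 percent); with rates frozen over the step
#' this reproduces the exponential solution to well below 1 percent over
#' typical step sizes.
#'
#' HET shells accrue EPS at \eqn{(Y_{EPS}/Y)\,\mu\,m} (the EPS
#' stoichiometry of the growth process) and decay proportionally with the
#' core. Agents whose core shrinks below the death/removal thresholds are
#' left for [deathAndRemoval()]; masses never cross zero under the sub-step
#' cap.
#'
#' @param aset an [AgentSet-class]
#' @param localS matrix of local solute concentrations (agents x solutes)
#' @param net a [ReactionNetwork-class]
#' @param params a [BfParams-class]
#' @param dt biological time step (s); defaults to `params@dtBio`
#' @return list(aset, grown, decayed): updated agents plus total COD (fg)
#'   produced by growth and lost to decay during the step
#' @export
stepBiomass <- function(aset, localS, net, params, dt = params@dtBio) {
  stopifnot(dt > 0)
  a <- aset@agents
  if (nrow(a) == 0) return(list(aset = aset, grown = 0, decayed = 0))
  rt <- .agentRates(a, localS, net)
  gS <- perHourToPerSec(rt$growth)
  dS <- perHourToPerSec(rt$decay)
  geS <- perHourToPerSec(rt$shellGain)
  maxRate <- max(abs(gS - dS), gS + geS, dS, 1e-300)
  nSub <- max(1L, ceiling(maxRate * dt / params@growthSubstepFrac))
  h <- dt / nSub
  m <- a$mass; e <- a$eps
  grown <- 0; decayed <- 0
  for (s in seq_len(nSub)) {
    dmG <- gS * m * h
    dmD <- dS * m * h
    deG <- geS * m * h
    deD <- dS * e * h
    grown <- grown + sum(dmG) + sum(deG)
    decayed <- decayed + sum(dmD) + sum(deD)
    m <- m + dmG - dmD
    e <- e + deG - deD
  }
  a$mass <- m
  a$eps <- e
  a <- .refreshRadii(a, params)
  aset@agents <- a
  list(aset = aset, grown = grown, decayed = decayed)
}

#' Volumetric nutrient uptake/production rates per voxel
#'
#' Evaluates \eqn{R(\mathrm{voxel}, s) = \sum_p \nu_{ps}\,
#' \mathrm{rate}_p(S_{\mathrm{voxel}})\, X_{\mathrm{acting}(p)}} where
#' \eqn{X} is the per-voxel biomass concentration of the acting group
#' (EPS shells count towards EPS in the host's voxel). Consumption is
#' negative.
#'
#' @param aset an [AgentSet-class]
#' @param fields a [SoluteFields-class]
#' @param net a [ReactionNetwork-class]
#' @param params a [BfParams-class]
#' @return named list of 3-D arrays (kg m^-3 s^-1), one per solute
#' @export
uptakeField <- function(aset, fields, net, params) {
  d <- fields@domain
  dims <- c(d@Nx, d@Ny, d@Nz)
  out <- lapply(net@solutes, function(s) array(0, dims))
  names(out) <- net@solutes
  a <- aset@agents
  if (nrow(a) == 0) return(out)
  Xg <- list()
  for (i in seq_along(net@processes)) {
    p <- net@processes[[i]]
    if (is.null(Xg[[p$group]])) Xg[[p$group]] <- .biomassField(a, d, p$group)
    X <- Xg[[p$group]]
    rate <- array(perHourToPerSec(p$muMax), dims)
    for (s in names(p$monod)) rate <- rate * monod(fields@fields[[s]], p$monod[[s]])
    for (s in names(p$inhibition))
      rate <- rate * inhibition(fields@fields[[s]], p$inhibition[[s]])
    for (s in net@solutes) {
      coef <- net@stoich[i, s]
      if (coef != 0) out[[s]] <- out[[s]] + coef * rate * X
    }
  }
  out
}

## Linearised reaction closures for the quasi-steady solver.
##
## For each solute s the local source is decomposed as
##   R_s(S) = sum_q A_q(vox) * S/(K_q + S) + B(vox)
## where the Monod factor in s itself stays live inside the inner solver and
## all other factors (cross-solute Monod/inhibition terms) are frozen at the
## current concentrations (Picard). Single-substrate networks are exact.
.uptakeClosures <- function(aset, fields, net, params) {
  d <- fields@domain
  dims <- c(d@Nx, d@Ny, d@Nz)
  nVox <- prod(dims)
  a <- aset@agents
  out <- list()
  Xg <- list()
  for (s in net@solutes) out[[s]] <- list(A = NULL, K = numeric(0), B = rep(0, nVox))
  if (nrow(a) == 0) return(out)
  for (i in seq_along(net@processes)) {
    p <- net@processes[[i]]
    if (is.null(Xg[[p$group]])) Xg[[p$group]] <- .biomassField(a, d, p$group)
    X <- as.vector(Xg[[p$group]])
    if (all(X == 0)) next
    for (s in net@solutes) {
      coef <- net@stoich[i, s]
      if (coef == 0) next
      amp <- coef * perHourToPerSec(p$muMax) * X
      for (ss in names(p$monod)) {
        if (ss == s) next
        amp <- amp * as.vector(monod(fields@fields[[ss]], p$monod[[ss]]))
      }
      for (ss in names(p$inhibition)) {
        if (ss == s) next
        amp <- amp * as.vector(inhibition(fields@fields[[ss]], p$inhibition[[ss]]))
      }
      if (s %in% names(p$inhibition))
        amp <- amp * as.vector(inhibition(fields@fields[[s]], p$inhibition[[s]]))
      if (s %in% names(p$monod)) {
        out[[s]]$A <- cbind(out[[s]]$A, amp)
        out[[s]]$K <- c(out[[s]]$K, p$monod[[s]])
      } else {
        out[[s]]$B <- out[[s]]$B + amp
      }
    }
  }
  out
}
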