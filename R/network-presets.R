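#' Single-species reaction network
#'
#' The network behind the headline simulations: one generic heterotrophic
#' bacterium limited by the carbonaceous substrate S_S. Processes:
#' \itemize{
#'   \item HET growth at \eqn{\mu_m S/(K_S+S)}: +1 HET, +Y_EPS/Y EPS (the
#'     shell), -1/Y S_S;
#'   \item HET decay, first order at rate b (biomass oxidised, no substrate
#'     return);
#'   \item EPS decay and inert decay to substrate, both first order with
#'     rates 0 by default (decay of dead and EPS agents treated as
#'     negligible relative to growth).
#' }
#'
#' @param params a [BfParams-class] supplying the kinetic constants
#' @return a [ReactionNetwork-class]
#' @export
singleSpeciesNetwork <- function(params = bfParams()) {
  procs <- list(
    list(name = "het_growth", group = "HET", muMax = params@muMax,
         monod = c(S_S = params@KS), inhibition = numeric(0)),
    list(name = "het_decay", group = "HET", muMax = params@decay,
         monod = numeric(0), inhibition = numeric(0)),
    list(name = "eps_decay", group = "EPS", muMax = params@epsDecay,
         monod = numeric(0), inhibition = numeric(0)),
    list(name = "inert_decay", group = "INERT", muMax = params@inertDecay,
         monod = numeric(0), inhibition = numeric(0))
  )
  comp <- c(agentGroups(), "S_S")
  st <- matrix(0, nrow = length(procs), ncol = length(comp),
               dimnames = list(vapply(procs, `[[`, "", "name"), comp))
  fEPS <- params@yieldEPS / params@yield
  st["het_growth", c("HET", "EPS", "S_S")] <- c(1, fEPS, -1 / params@yield)
  st["het_decay", "HET"] <- -1
  st["eps_decay", c("EPS", "S_S")] <- c(-1, 1)
  st["inert_decay", c("INERT", "S_S")] <- c(-1, 1)
  methods::new("ReactionNetwork", processes = procs, stoich = st,
               solutes = "S_S")
}

#' Three-species HET/AOB/NOB reaction network
#'
#' A demonstration network for carbon oxidation plus two-step nitrification,
#' with rate forms and constants in the style of the activated-sludge model
#' literature. The specific constants here are a plausible, clearly
#' non-canonical preset (exact canonical constants are not
#' reproduced); all values are overridable through the process list.
#'
#' Solutes: S_S (organic substrate), S_NH4, S_NO2, S_NO3, S_O2.
#' HET grow aerobically on S_S; AOB oxidise NH4 to NO2; NOB oxidise NO2 to
#' NO3. Oxygen is consumed by all three and fed like the substrate.
#'
#' @param params a [BfParams-class]; HET kinetics are taken from it
#' @param muAOB,muNOB maximum specific growth rates (h^-1)
#' @param KNH4,KNO2,KO2 half-saturation constants (kg m^-3)
#' @param YAOB,YNOB yields (g biomass COD per g N)
#' @return a [ReactionNetwork-class]
#' @export
threeSpeciesNetwork <- function(params = bfParams(),
                                muAOB = 0.033, muNOB = 0.045,
                                KNH4 = 1.0e-3, KNO2 = 1.3e-3, KO2 = 8.0e-4,
                                YAOB = 0.15, YNOB = 0.041) {
  sol <- c("S_S", "S_NH4", "S_NO2", "S_NO3", "S_O2")
  procs <- list(
    list(name = "het_growth", group = "HET", muMax = params@muMax,
         monod = c(S_S = params@KS, S_O2 = KO2), inhibition = numeric(0)),
    list(name = "aob_growth", group = "AOB", muMax = muAOB,
         monod = c(S_NH4 = KNH4, S_O2 = KO2), inhibition = numeric(0)),
    list(name = "nob_growth", group = "NOB", muMax = muNOB,
         monod = c(S_NO2 = KNO2, S_O2 = KO2), inhibition = numeric(0)),
    list(name = "het_decay", group = "HET", muMax = params@decay,
         monod = numeric(0), inhibition = numeric(0)),
    list(name = "aob_decay", group = "AOB", muMax = params@decay,
         monod = numeric(0), inhibition = numeric(0)),
    list(name = "nob_decay", group = "NOB", muMax = params@decay,
         monod = numeric(0), inhibition = numeric(0)),
    list(name = "eps_decay", group = "EPS", muMax = params@epsDecay,
         monod = numeric(0), inhibition = numeric(0)),
    list(name = "inert_decay", group = "INERT", muMax = params@inertDecay,
         monod = numeric(0), inhibition = numeric(0))
  )
  comp <- c(agentGroups(), sol)
  st <- matrix(0, nrow = length(procs), ncol = length(comp),
               dimnames = list(vapply(procs, `[[`, "", "name"), comp))
  fEPS <- params@yieldEPS / params@yield
  Y <- params@yield
  st["het_growth", c("HET", "EPS", "S_S", "S_O2")] <-
    c(1, fEPS, -1 / Y, -(1 - Y - params@yieldEPS) / Y)
  st["aob_growth", c("AOB", "S_NH4", "S_NO2", "S_O2")] <-
    c(1, -1 / YAOB, 1 / YAOB, -(3.43 - YAOB) / YAOB)
  st["nob_growth", c("NOB", "S_NO2", "S_NO3", "S_O2")] <-
    c(1, -1 / YNOB, 1 / YNOB, -(1.14 - YNOB) / YNOB)
  st["het_decay", "HET"] <- -1
  st["aob_decay", "AOB"] <- -1
  st["nob_decay", "NOB"] <- -1
  st["eps_decay", c("EPS", "S_S")] <- c(-1, 1)
  st["inert_decay", c("INERT", "S_S")] <- c(-1, 1)
  methods::new("ReactionNetwork", processes = procs, stoich = st,
               solutes = sol)
}

#' Serialise a reaction network to plain lists (YAML/JSON-friendly)
#' @param net a [ReactionNetwork-class]
#' @return a list with elements `processes`, `stoich`, `solutes`
#' @export
networkAsList <- function(net) {
  list(
    processes = lapply(net@processes, function(p) list(
      name = p$name, group = p$group, muMax = p$muMax,
      monod = as.list(p$monod), inhibition = as.list(p$inhibition))),
    stoich = stats::setNames(
      lapply(seq_len(nrow(net@stoich)), function(i) {
        idx <- which(net@stoich[i, ] != 0)
        stats::setNames(as.list(net@stoich[i, idx]), colnames(net@stoich)[idx])
      }),
      rownames(net@stoich)),
    solutes = as.list(net@solutes)
  )
}

#' Rebuild a reaction network from its list form
#' @param x a list as produced by [networkAsList()]
#' @return a [ReactionNetwork-class]
#' @export
networkFromList <- function(x) {
  sol <- unlist(x$solutes)
  procs <- lapply(x$processes, function(p) list(
    name = p$name, group = p$group, muMax = p$muMax,
    monod = unlist(p$monod) %||% numeric(0),
    inhibition = unlist(p$inhibition) %||% numeric(0)))
  comp <- c(agentGroups(), sol)
  st <- matrix(0, nrow = length(procs), ncol = length(comp),
               dimnames = list(vapply(procs, `[[`, "", "name"), comp))
  for (nm in names(x$stoich))
    for (cc in names(x$stoich[[nm]]))
      st[nm, cc] <- x$stoich[[nm]][[cc]]
  methods::new("ReactionNetwork", processes = procs, stoich = st, solutes = sol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
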