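#' Construct a parameter set
#'
#' Defaults reproduce the reference single-species parameterisation of the biofilm IbM literature: maximum
#' specific growth rate 1 h^-1, decay 1.33e-2 h^-1, K_S = 3.5e-5 kg m^-3,
#' Y = 0.61 and Y_EPS = 0.18 gCOD/gCOD, D_S = 1.6e-9 m^2 s^-1,
#' S_b = 1e-4 kg m^-3, k_n = 1e-4 N m^-1, gamma_n = 1e-5 s^-1,
#' k_eps = 5e9 s^-2 and water viscosity 1e-3 Pa s. Size thresholds: agents
#' divide at 1.25 um diameter, die (become inert) at 0.8 um, and are removed
#' at 0.1 um; the EPS shell is excreted when the composite diameter reaches
#' 1.25x the core diameter.
#'
#' The biomass density (COD basis) is not part of the reference table; unless
#' given, it is derived by inverting the dimensionless transport/consumption
#' ratio \eqn{\delta = S_b D_S / (Y \mu_m \rho_X L_z^2)} so that the default
#' parameter set attains `deltaTarget` (default 1.52e-2, the smallest value of
#' the reference configuration) at the reference domain height `LzRef` (default
#' 100 um). `rhoEPS` defaults to `rhoX / 4`, light enough that the EPS excretion
#' threshold is attainable at the configured yields.
#'
#' @param muMax,decay,KS,yield,yieldEPS,epsDecay,inertDecay kinetics (rates h^-1)
#' @param DS,Sb mass transfer (m^2 s^-1, kg m^-3)
#' @param kn,gammaN,kt,gammaT,kEps,muFluid mechanics; `kt`/`gammaT` default to
#'   the granular-DEM convention 2/7 kn and gammaN/2
#' @param rhoX,rhoEPS densities (kg m^-3 COD); NULL = derive (see Details)
#' @param deltaTarget,LzRef delta value and domain height used to derive rhoX
#' @param dDiv,dDead,dRemove,epsExcreteRatio lifecycle thresholds (um)
#' @param dtBio,dtMech,dtDiff time steps (s)
#' @param gammaDot applied shear rate (s^-1)
#' @param divSep daughter placement rule, "radii" or "diameters"
#' @param linkFormFactor adhesive-link formation distance factor
#' @param wallAdhesion allow EPS adhesion to the substratum
#' @param pressureTolRel,relaxMaxIter relaxation controls
#' @param growthSubstepFrac Euler sub-step growth cap
#' @param contactModel "hookean" (default) or "hertzian"
#' @return a validated [BfParams-class]
#' @examples
#' p <- bfParams()
#' dimensionlessGroups(p, bfDomain())
#' @export
bfParams <- function(muMax = 1, decay = 1.33e-2, KS = 3.5e-5,
                     yield = 0.61, yieldEPS = 0.18,
                     epsDecay = 0, inertDecay = 0,
                     DS = 1.6e-9, Sb = 1e-4,
                     kn = 1e-4, gammaN = 1e-5,
                     kt = 2 / 7 * kn, gammaT = gammaN / 2,
                     kEps = 5e9, muFluid = 1e-3,
                     rhoX = NULL, rhoEPS = NULL,
                     deltaTarget = 1.52e-2, LzRef = 100,
                     dDiv = 1.25, dDead = 0.8, dRemove = 0.1,
                     epsExcreteRatio = 1.25,
                     dtBio = 1000, dtMech = 0.01, dtDiff = 1e-3,
                     gammaDot = 0,
                     divSep = "radii", linkFormFactor = 1.1,
                     wallAdhesion = TRUE,
                     pressureTolRel = 1e-3, relaxMaxIter = 2000,
                     growthSubstepFrac = 1e-3,
                     contactModel = "hookean") {
  if (is.null(rhoX))
    rhoX <- rhoXFromDelta(deltaTarget, Sb = Sb, DS = DS, yield = yield,
                          muMax = muMax, Lz = LzRef)
  if (is.null(rhoEPS)) rhoEPS <- rhoX / 4
  methods::new("BfParams",
    muMax = muMax, decay = decay, KS = KS, yield = yield, yieldEPS = yieldEPS,
    epsDecay = epsDecay, inertDecay = inertDecay, DS = DS, Sb = Sb,
    kn = kn, gammaN = gammaN, kt = kt, gammaT = gammaT, kEps = kEps,
    muFluid = muFluid, rhoX = rhoX, rhoEPS = rhoEPS,
    dDiv = dDiv, dDead = dDead, dRemove = dRemove,
    epsExcreteRatio = epsExcreteRatio,
    dtBio = dtBio, dtMech = dtMech, dtDiff = dtDiff, gammaDot = gammaDot,
    divSep = divSep, linkFormFactor = linkFormFactor,
    wallAdhesion = wallAdhesion, pressureTolRel = pressureTolRel,
    relaxMaxIter = relaxMaxIter, growthSubstepFrac = growthSubstepFrac,
    contactModel = contactModel)
}

#' Construct a computational domain
#'
#' Defaults to the reference configuration: a 100 x 40 x 100 um box on a
#' 30 x 12 x 30 voxel grid, periodic in x and y, nutrient fed from the top.
#'
#' @param Lx,Ly,Lz box dimensions (um)
#' @param Nx,Ny,Nz voxel counts
#' @param bcX,bcY "periodic" or "outflow"
#' @param feed "top" or "bottom"
#' @return a validated [BfDomain-class]
#' @export
bfDomain <- function(Lx = 100, Ly = 40, Lz = 100,
                     Nx = 30, Ny = 12, Nz = 30,
                     bcX = "periodic", bcY = "periodic", feed = "top") {
  methods::new("BfDomain", Lx = Lx, Ly = Ly, Lz = Lz,
               Nx = as.integer(Nx), Ny = as.integer(Ny), Nz = as.integer(Nz),
               bcX = bcX, bcY = bcY, feed = feed)
}

#' Dimensionless groups governing biofilm morphology
#'
#' \deqn{\delta = \frac{S_b D_S}{Y \mu_m \rho_X L_z^2}, \qquad
#'       \kappa = \frac{K_S}{S_b}, \qquad \beta = \frac{b}{\mu_m}}
#'
#' delta is the ratio of maximal nutrient transport to maximal consumption
#' (a non-dimensional active-layer thickness), kappa the non-dimensional
#' Monod coefficient, beta the relative decay rate. All three are invariant
#' to the unit system as long as it is used consistently; the computation
#' here is done in SI.
#'
#' @param p a [BfParams-class]
#' @param d a [BfDomain-class] (only `Lz` enters)
#' @return named numeric vector c(delta, kappa, beta)
#' @examples
#' g <- dimensionlessGroups(bfParams(), bfDomain())
#' g[["kappa"]]  # 0.35 for the default parameter set
#' @export
dimensionlessGroups <- function(p, d) {
  stopifnot(is(p, "BfParams"), is(d, "BfDomain"))
  if (p@Sb <= 0) stop("'Sb' must be positive")
  LzM <- d@Lz * 1e-6
  muSI <- perHourToPerSec(p@muMax)
  den <- p@yield * muSI * p@rhoX * LzM^2
  if (den == 0) stop("zero denominator in delta (check yield, muMax, rhoX, Lz)")
  c(delta = p@Sb * p@DS / den,
    kappa = p@KS / p@Sb,
    beta = p@decay / p@muMax)
}

#' Biomass density that attains a given delta
#'
#' Algebraic inversion of the delta definition (see
#' [dimensionlessGroups()]) for \eqn{\rho_X}.
#'
#' @param delta target dimensionless transport/consumption ratio
#' @param Sb bulk substrate concentration (kg m^-3)
#' @param DS substrate diffusivity (m^2 s^-1)
#' @param yield growth yield
#' @param muMax maximum specific growth rate (h^-1)
#' @param Lz domain height (um)
#' @return biomass density (kg m^-3, COD basis)
#' @export
rhoXFromDelta <- function(delta, Sb = 1e-4, DS = 1.6e-9, yield = 0.61,
                          muMax = 1, Lz = 100) {
  stopifnot(delta > 0, Sb > 0, DS > 0, yield > 0, muMax > 0, Lz > 0)
  Sb * DS / (yield * perHourToPerSec(muMax) * delta * (Lz * 1e-6)^2)
}

#' Radius of a sphere of given mass and density
#'
#' @param mass mass (fg)
#' @param density density (kg m^-3, numerically equal to fg um^-3)
#' @return radius (um)
#' @examples
#' radiusFromMass(massFromRadius(0.5, 6.21), 6.21)  # 0.5
#' @export
radiusFromMass <- function(mass, density) {
  if (any(mass <= 0) || any(density <= 0))
    stop("'mass' and 'density' must be positive")
  (3 * mass / (4 * pi * density))^(1 / 3)
}

#' Mass of a sphere of given radius and density
#' @param radius radius (um)
#' @param density density (kg m^-3 == fg um^-3)
#' @return mass (fg)
#' @export
massFromRadius <- function(radius, density) {
  if (any(radius <= 0) || any(density <= 0))
    stop("'radius' and 'density' must be positive")
  4 / 3 * pi * radius^3 * density
}

## ---- config file I/O -------------------------------------------------------

.PARAM_KEYS <- c(
  mu_m = "muMax", b = "decay", K_S = "KS", Y = "yield", Y_EPS = "yieldEPS",
  eps_decay = "epsDecay", inert_decay = "inertDecay",
  D_S = "DS", S_b = "Sb", k_n = "kn", gamma_n = "gammaN", k_t = "kt",
  gamma_t = "gammaT", k_eps = "kEps", mu_fluid = "muFluid",
  rho_X = "rhoX", rho_EPS = "rhoEPS",
  d_div = "dDiv", d_dead = "dDead", d_remove = "dRemove",
  eps_excrete_ratio = "epsExcreteRatio",
  dt_bio = "dtBio", dt_mech = "dtMech", dt_diff = "dtDiff",
  gamma_dot = "gammaDot", div_sep = "divSep",
  link_form_factor = "linkFormFactor", wall_adhesion = "wallAdhesion",
  pressure_tol_rel = "pressureTolRel", relax_max_iter = "relaxMaxIter",
  growth_substep_frac = "growthSubstepFrac", contact_model = "contactModel")

.DOMAIN_KEYS <- c(L_x = "Lx", L_y = "Ly", L_z = "Lz",
                  N_x = "Nx", N_y = "Ny", N_z = "Nz",
                  bc_x = "bcX", bc_y = "bcY", nutrient_feed = "feed")

#' Load a run configuration from a YAML file
#'
#' Flat keys mirror the conventional symbols (`mu_m`, `K_S`, `k_n`, ...)
#' under a `parameters` block, domain keys (`L_x`, `N_x`, `bc_x`,
#' `nutrient_feed`) under `domain`, plus optional `scenario` and `seed`.
#' Missing keys take the reference defaults; `rho_X`, if omitted, is derived
#' from `delta_target` (see [bfParams()]) and reported via a message.
#'
#' @param path config file path
#' @param overrides named list applied on top of the file (CLI-style
#'   overrides, e.g. `list(gamma_dot = 0.2, seed = 7)`)
#' @return list with elements `params` ([BfParams-class]),
#'   `domain` ([BfDomain-class]), `scenario` (character name or list),
#'   and `seed`
#' @export
loadConfig <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config file is not a YAML mapping: ", path)
  cfg <- utils::modifyList(cfg, overrides)

  pc <- cfg$parameters
  if (is.null(pc)) pc <- list()
  unknown <- setdiff(names(pc), c(names(.PARAM_KEYS), "delta_target"))
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  args <- list()
  for (k in names(pc)) {
    if (k == "delta_target") args$deltaTarget <- pc[[k]]
    else args[[.PARAM_KEYS[[k]]]] <- pc[[k]]
  }
  dc <- cfg$domain
  if (is.null(dc)) dc <- list()
  unknown <- setdiff(names(dc), names(.DOMAIN_KEYS))
  if (length(unknown))
    stop("unknown domain key(s): ", paste(unknown, collapse = ", "))
  dargs <- list()
  for (k in names(dc)) dargs[[.DOMAIN_KEYS[[k]]]] <- dc[[k]]
  domain <- do.call(bfDomain, dargs)
  if (is.null(args$rhoX) && !is.null(domain@Lz)) args$LzRef <- domain@Lz
  params <- tryCatch(do.call(bfParams, args), error = function(e)
    stop("invalid parameter configuration: ", conditionMessage(e), call. = FALSE))
  if (is.null(pc$rho_X))
    message(sprintf("rho_X derived from delta=%g at L_z=%g um: %.6g kg/m3",
                    if (is.null(args$deltaTarget)) 1.52e-2 else args$deltaTarget,
                    domain@Lz, params@rhoX))
  list(params = params, domain = domain,
       scenario = if (is.null(cfg$scenario)) "growth_grid" else cfg$scenario,
       seed = if (is.null(cfg$seed)) 1L else cfg$seed)
}

#' Write a run configuration to a YAML file
#'
#' Inverse of [loadConfig()]: `writeConfig` then `loadConfig` round-trips
#' losslessly.
#'
#' @param params a [BfParams-class]
#' @param domain a [BfDomain-class]
#' @param path output file
#' @param scenario scenario name or list
#' @param seed RNG seed
#' @return `path`, invisibly
#' @export
writeConfig <- function(params, domain, path, scenario = "growth_grid",
                        seed = 1L) {
  pc <- lapply(stats::setNames(names(.PARAM_KEYS), names(.PARAM_KEYS)),
               function(k) slot(params, .PARAM_KEYS[[k]]))
  dc <- lapply(stats::setNames(names(.DOMAIN_KEYS), names(.DOMAIN_KEYS)),
               function(k) {
                 v <- slot(domain, .DOMAIN_KEYS[[k]])
                 if (is.integer(v)) as.integer(v) else v
               })
  yaml::write_yaml(list(parameters = pc, domain = dc,
                        scenario = scenario, seed = seed), path,
                   precision = 15L)
  invisible(path)
}

#' Parameter set attaining given dimensionless groups on a given domain
#'
#' Holds the biomass density and kinetics of `base` fixed and solves the
#' bulk concentration and half-saturation constant so that
#' [dimensionlessGroups()] returns the requested delta and kappa on the
#' given domain. This is how conditions are transported between domain
#' sizes: morphology is governed by (delta, kappa, beta), so a scaled-down
#' box reproduces a study condition by matching the groups rather than the
#' raw concentrations.
#'
#' @param delta,kappa target dimensionless groups
#' @param domain a [BfDomain-class] (its `Lz` enters delta)
#' @param base template [BfParams-class]
#' @return a [BfParams-class] with adjusted `Sb` and `KS`
#' @export
paramsForGroups <- function(delta, kappa, domain, base = bfParams()) {
  stopifnot(delta > 0, kappa > 0)
  muSI <- perHourToPerSec(base@muMax)
  Sb <- delta * base@yield * muSI * base@rhoX * (domain@Lz * 1e-6)^2 / base@DS
  p <- base
  p@Sb <- Sb
  p@KS <- kappa * Sb
  methods::validObject(p)
  p
}
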