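#' Create an agent set
#'
#' @param df data.frame with at least columns group, x, y, z, mass (fg COD);
#'   eps defaults to 0, velocities to 0, ids are assigned sequentially when
#'   absent; radius is (re)derived from mass, shell and densities
#' @param params a [BfParams-class] (for the densities)
#' @return an [AgentSet-class]
#' @export
agentSet <- function(df = NULL, params = bfParams()) {
  if (is.null(df) || nrow(df) == 0) {
    empty <- data.frame(id = integer(), group = character(),
                        x = numeric(), y = numeric(), z = numeric(),
                        vx = numeric(), vy = numeric(), vz = numeric(),
                        mass = numeric(), eps = numeric(), radius = numeric(),
                        stringsAsFactors = FALSE)
    return(methods::new("AgentSet", agents = empty, nextId = 1L))
  }
  n <- nrow(df)
  if (is.null(df$id)) df$id <- seq_len(n)
  if (is.null(df$eps)) df$eps <- 0
  for (v in c("vx", "vy", "vz")) if (is.null(df[[v]])) df[[v]] <- 0
  df$radius <- outerRadius(df$mass, df$eps, df$group, params)
  df <- df[, .AGENT_COLS]
  methods::new("AgentSet", agents = df, nextId = as.integer(max(df$id) + 1L))
}

#' Outer (mechanical) radius of agents
#'
#' Core biomass occupies volume mass/rho_X (rho_EPS for free EPS particles);
#' the attached shell adds eps/rho_EPS. The mechanical radius is that of the
#' composite sphere.
#'
#' @param mass core mass (fg)
#' @param eps shell mass (fg)
#' @param group agent group vector
#' @param params a [BfParams-class]
#' @return radius (um)
#' @export
outerRadius <- function(mass, eps, group, params) {
  coreDensity <- ifelse(group == "EPS", params@rhoEPS, params@rhoX)
  vol <- mass / coreDensity + eps / params@rhoEPS
  (3 * vol / (4 * pi))^(1 / 3)
}

#' Core radius of agents (biomass sphere only, shell excluded)
#' @inheritParams outerRadius
#' @return radius (um)
#' @export
coreRadius <- function(mass, group, params) {
  coreDensity <- ifelse(group == "EPS", params@rhoEPS, params@rhoX)
  radiusFromMass(mass, coreDensity)
}

## refresh the derived radius column in place
.refreshRadii <- function(a, params) {
  a$radius <- outerRadius(a$mass, a$eps, a$group, params)
  a
}

#' Total biovolume of agents (um^3)
#' @param a agent data.frame
#' @param params a [BfParams-class]
#' @export
agentVolume <- function(a, params) {
  if (nrow(a) == 0) return(0)
  sum(4 / 3 * pi * outerRadius(a$mass, a$eps, a$group, params)^3)
}

## voxel index (1-based triple) containing each agent centre
.voxelIndex <- function(a, domain) {
  hx <- domain@Lx / domain@Nx
  hy <- domain@Ly / domain@Ny
  hz <- domain@Lz / domain@Nz
  ix <- pmin(pmax(floor(a$x / hx), 0), domain@Nx - 1) + 1L
  iy <- pmin(pmax(floor(a$y / hy), 0), domain@Ny - 1) + 1L
  iz <- pmin(pmax(floor(a$z / hz), 0), domain@Nz - 1) + 1L
  cbind(ix, iy, iz)
}

## per-voxel biomass concentration (fg/um^3 == kg/m^3) for one group,
## EPS shells counted as EPS in the host's voxel
.biomassField <- function(a, domain, group) {
  dims <- c(domain@Nx, domain@Ny, domain@Nz)
  X <- array(0, dims)
  if (nrow(a) == 0) return(X)
  vox <- .voxelIndex(a, domain)
  voxVol <- (domain@Lx / domain@Nx) * (domain@Ly / domain@Ny) *
    (domain@Lz / domain@Nz)
  lin <- (vox[, 3] - 1L) * dims[1] * dims[2] + (vox[, 2] - 1L) * dims[1] + vox[, 1]
  m <- if (group == "EPS") {
    ifelse(a$group == "EPS", a$mass, 0) + a$eps
  } else ifelse(a$group == group, a$mass, 0)
  keep <- m > 0
  if (any(keep)) {
    agg <- rowsum(m[keep], lin[keep])
    X[as.integer(rownames(agg))] <- agg[, 1] / voxVol
  }
  X
}
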