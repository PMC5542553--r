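## Morphology, composition and detachment analyses.

#' Biofilm height field
#'
#' Agents are binned into (x, y) columns of the analysis grid; each column
#' reports the maximum of z + r over its agents (0 for empty columns).
#'
#' @param a agent data.frame (or [AgentSet-class])
#' @param domain a [BfDomain-class]
#' @return Nx x Ny matrix of heights (um)
#' @export
heightField <- function(a, domain) {
  if (is(a, "AgentSet")) a <- a@agents
  h <- matrix(0, domain@Nx, domain@Ny)
  if (nrow(a) == 0) return(h)
  vox <- .voxelIndex(a, domain)
  top <- a$z + a$radius
  for (r in seq_len(nrow(a))) {
    i <- vox[r, 1]; j <- vox[r, 2]
    if (top[r] > h[i, j]) h[i, j] <- top[r]
  }
  h
}

#' Voxel occupancy of the biofilm
#'
#' A voxel counts as filled when any agent sphere intersects it (default),
#' or — with `rule = "centre"` — when it contains an agent centre.
#'
#' @param a agent data.frame (or [AgentSet-class])
#' @param domain a [BfDomain-class]
#' @param rule "overlap" or "centre"
#' @return logical Nx x Ny x Nz array
#' @export
occupancyField <- function(a, domain, rule = c("overlap", "centre")) {
  rule <- match.arg(rule)
  if (is(a, "AgentSet")) a <- a@agents
  dims <- c(domain@Nx, domain@Ny, domain@Nz)
  F <- array(FALSE, dims)
  if (nrow(a) == 0) return(F)
  hx <- domain@Lx / domain@Nx
  hy <- domain@Ly / domain@Ny
  hz <- domain@Lz / domain@Nz
  if (rule == "centre") {
    vox <- .voxelIndex(a, domain)
    F[cbind(vox[, 1], vox[, 2], vox[, 3])] <- TRUE
    return(F)
  }
  for (r in seq_len(nrow(a))) {
    x <- a$x[r]; y <- a$y[r]; z <- a$z[r]; rad <- a$radius[r]
    i0 <- max(1L, floor((x - rad) / hx) + 1L); i1 <- min(dims[1], floor((x + rad) / hx) + 1L)
    j0 <- max(1L, floor((y - rad) / hy) + 1L); j1 <- min(dims[2], floor((y + rad) / hy) + 1L)
    k0 <- max(1L, floor((z - rad) / hz) + 1L); k1 <- min(dims[3], floor((z + rad) / hz) + 1L)
    if (i0 > i1 || j0 > j1 || k0 > k1) next   # sphere fully outside the grid
    for (i in i0:i1) for (j in j0:j1) for (k in k0:k1) {
      if (F[i, j, k]) next
      ## closest point of voxel box to the sphere centre
      cx <- min(max(x, (i - 1) * hx), i * hx)
      cy <- min(max(y, (j - 1) * hy), j * hy)
      cz <- min(max(z, (k - 1) * hz), k * hz)
      if ((cx - x)^2 + (cy - y)^2 + (cz - z)^2 <= rad^2) F[i, j, k] <- TRUE
    }
  }
  F
}

#' Morphology metrics: average height, RMS roughness, porosity
#'
#' \deqn{\bar h = \mathrm{mean}(h), \quad
#'  \mathrm{roughness} = \sqrt{\mathrm{mean}((h - \bar h)^2)}, \quad
#'  \mathrm{porosity} = 1 - \frac{\sum F(i,j,k)}{N_x N_y h_{max}}}
#' with \eqn{h_{max}} the maximum of the height field expressed in voxel
#' units (occupancy counted up to that height). A zero-height biofilm has
#' undefined porosity, reported as 0 with `defined = FALSE`.
#'
#' @param h height field from [heightField()]
#' @param F occupancy array from [occupancyField()]
#' @param domain a [BfDomain-class]
#' @return list(meanHeight, maxHeight, roughness, porosity, defined)
#' @export
morphology <- function(h, F, domain) {
  hbar <- mean(h)
  rough <- sqrt(mean((h - hbar)^2))
  hmaxVox <- max(h) / (domain@Lz / domain@Nz)
  if (hmaxVox <= 0)
    return(list(meanHeight = 0, maxHeight = 0, roughness = rough,
                porosity = 0, defined = FALSE))
  ## occupancy counted up to h_max, the partially covered top voxel layer
  ## entering with fractional weight so the metric is continuous in h_max
  hmaxVox <- min(hmaxVox, domain@Nz)
  kfull <- floor(hmaxVox)
  filled <- if (kfull >= 1) sum(F[, , seq_len(kfull), drop = FALSE]) else 0
  fracTop <- hmaxVox - kfull
  if (fracTop > 0 && kfull < domain@Nz)
    filled <- filled + fracTop * sum(F[, , kfull + 1])
  list(meanHeight = hbar, maxHeight = max(h), roughness = rough,
       porosity = 1 - filled / (domain@Nx * domain@Ny * hmaxVox),
       defined = TRUE)
}

#' Volume fractions by functional class
#'
#' Fractions of total agent volume held by active bacteria (HET+AOB+NOB),
#' EPS (free particles plus shells) and inert agents. Fractions sum to 1
#' when agents exist, and are all zero for an empty set.
#'
#' @param a agent data.frame (or [AgentSet-class])
#' @param params a [BfParams-class]
#' @return named numeric c(bacteria, EPS, inert)
#' @export
volumeFractions <- function(a, params) {
  if (is(a, "AgentSet")) a <- a@agents
  if (nrow(a) == 0) return(c(bacteria = 0, EPS = 0, inert = 0))
  coreVol <- a$mass / ifelse(a$group == "EPS", params@rhoEPS, params@rhoX)
  shellVol <- a$eps / params@rhoEPS
  vBact <- sum(coreVol[a$group %in% .ACTIVE_GROUPS])
  vEPS <- sum(coreVol[a$group == "EPS"]) + sum(shellVol)
  vInert <- sum(coreVol[a$group == "INERT"])
  tot <- vBact + vEPS + vInert
  c(bacteria = vBact, EPS = vEPS, inert = vInert) / tot
}

#' Active-layer thickness
#'
#' Cells are "active" when their specific growth rate is at least
#' `fracThreshold` times the population maximum. Per (x, y) column the
#' active layer extends from the local height h(x, y) down to the underside
#' (z - r) of the lowest active cell; the thickness is the mean over columns
#' containing active cells (0 when none are active).
#'
#' @param a agent data.frame (or [AgentSet-class])
#' @param rates per-agent specific growth rates (h^-1), aligned with rows
#' @param domain a [BfDomain-class]
#' @param fracThreshold activity threshold as a fraction of the maximum rate
#' @return thickness (um)
#' @export
activeLayerThickness <- function(a, rates, domain, fracThreshold = 0.5) {
  if (is(a, "AgentSet")) a <- a@agents
  if (nrow(a) == 0 || all(rates <= 0)) return(0)
  h <- heightField(a, domain)
  act <- rates >= fracThreshold * max(rates)
  if (!any(act)) return(0)
  vox <- .voxelIndex(a, domain)
  cols <- paste(vox[, 1], vox[, 2])
  zmin <- tapply(ifelse(act, a$z - a$radius, Inf), cols, min)
  zmin <- zmin[is.finite(zmin)]
  if (length(zmin) == 0) return(0)
  ij <- do.call(rbind, strsplit(names(zmin), " "))
  hcol <- h[cbind(as.integer(ij[, 1]), as.integer(ij[, 2]))]
  mean(pmax(hcol - zmin, 0))
}

#' Partition agents into mechanically connected clusters
#'
#' Adjacency is contact overlap (distance below r_i + r_j, with a small
#' tolerance) or an active adhesive link. A cluster is "attached" when any
#' member touches the substratum (directly or through an active wall link).
#' Components are computed with igraph; the partition is invariant to agent
#' ordering and to rigid periodic translations.
#'
#' @param aset an [AgentSet-class] (or agent data.frame)
#' @param links link tables from [buildLinks()] (optional)
#' @param params a [BfParams-class]
#' @param domain a [BfDomain-class]
#' @param contactTol relative slack on the contact distance
#' @return data.frame, one row per agent: id, cluster, attached
#' @export
clusterComponents <- function(aset, links = NULL, params, domain,
                              contactTol = 1e-9) {
  a <- if (is(aset, "AgentSet")) aset@agents else aset
  n <- nrow(a)
  if (n == 0)
    return(data.frame(id = integer(), cluster = integer(), attached = logical()))
  edges <- matrix(integer(0), 0, 2)
  if (n >= 2) {
    cp <- cpp_close_pairs(as.matrix(a[, c("x", "y", "z")]), a$radius,
                          1 + contactTol, domain@Lx, domain@Ly,
                          domain@bcX == "periodic", domain@bcY == "periodic")
    if (length(cp$i)) edges <- cbind(cp$i, cp$j)
    if (!is.null(links) && nrow(links$pairs)) {
      act <- links$pairs[links$pairs$active, , drop = FALSE]
      if (nrow(act)) {
        e2 <- cbind(match(act$idI, a$id), match(act$idJ, a$id))
        e2 <- e2[stats::complete.cases(e2), , drop = FALSE]
        edges <- rbind(edges, e2)
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  touching <- a$z <= a$radius * (1 + 1e-6)
  if (!is.null(links) && nrow(links$wall)) {
    wact <- links$wall[links$wall$active, , drop = FALSE]
    touching <- touching | a$id %in% wact$id
  }
  attachedComp <- unique(comp[touching])
  data.frame(id = a$id, cluster = as.integer(comp),
             attached = comp %in% attachedComp)
}

#' Summarise detachment events
#'
#' From the detachment event log: event counts per time bin, the
#' distribution of detached cluster volumes (normalised by the remaining
#' biofilm volume at the time of the event), a lognormal maximum-likelihood
#' fit of the volumes, and the mean detachment rate (total detached volume
#' over total time).
#'
#' @param events data.frame with at least columns time and volume (um^3);
#'   a normVolume column (cluster volume / remaining biofilm volume) is
#'   used for the normalised summaries when present
#' @param initialVolume biofilm volume at the start of the shear phase
#'   (um^3), used for the total detached fraction
#' @param duration observation window (s)
#' @param nBins number of time bins for the event-count trace
#' @return list(nEvents, countsPerBin (data.frame), rate (um^3 s^-1),
#'   lognormal (meanlog, sdlog, se.meanlog, se.sdlog), totalVolume,
#'   detachedFraction, maxNormVolume, meanNormVolume)
#' @export
detachmentStatistics <- function(events, initialVolume, duration,
                                 nBins = 20) {
  if (is.null(events) || nrow(events) == 0) {
    return(list(nEvents = 0L,
                countsPerBin = data.frame(tMid = numeric(), count = integer()),
                rate = 0, lognormal = NULL, totalVolume = 0,
                detachedFraction = 0, maxNormVolume = NA_real_,
                meanNormVolume = NA_real_))
  }
  breaks <- seq(0, duration, length.out = nBins + 1)
  cnt <- as.integer(table(cut(pmin(events$time, duration), breaks,
                              include.lowest = TRUE)))
  counts <- data.frame(tMid = (breaks[-1] + breaks[-length(breaks)]) / 2,
                       count = cnt)
  fit <- NULL
  v <- events$volume[events$volume > 0]
  if (length(v) >= 3) {
    f <- MASS::fitdistr(v, "lognormal")
    fit <- list(meanlog = unname(f$estimate["meanlog"]),
                sdlog = unname(f$estimate["sdlog"]),
                se.meanlog = unname(f$sd["meanlog"]),
                se.sdlog = unname(f$sd["sdlog"]))
  }
  nv <- if ("normVolume" %in% names(events) && !all(is.na(events$normVolume)))
    events$normVolume else events$volume / initialVolume
  list(nEvents = nrow(events), countsPerBin = counts,
       rate = sum(events$volume) / duration, lognormal = fit,
       totalVolume = sum(events$volume),
       detachedFraction = sum(events$volume) / initialVolume,
       maxNormVolume = max(nv, na.rm = TRUE),
       meanNormVolume = mean(nv, na.rm = TRUE),
       meanVolume = mean(events$volume))
}
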