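# Shared fixtures: small domains, agent configurations and networks built in
# code at test time.

smallDomain <- function(...) {
  bfDomain(Lx = 40, Ly = 10, Lz = 40, Nx = 16, Ny = 4, Nz = 16, ...)
}

# a single-agent set resting at a given position
oneAgent <- function(params, x = 20, y = 5, z = 10, r = 0.5, group = "HET") {
  dens <- if (group == "EPS") params@rhoEPS else params@rhoX
  agentSet(data.frame(group = group, x = x, y = y, z = z,
                      mass = massFromRadius(r, dens), eps = 0), params)
}

# n agents at uniformly random positions inside the box (seeded by caller)
randomAgents <- function(n, params, domain, rRange = c(0.3, 0.6)) {
  r <- runif(n, rRange[1], rRange[2])
  agentSet(data.frame(
    group = sample(c("HET", "EPS", "INERT"), n, replace = TRUE,
                   prob = c(0.6, 0.3, 0.1)),
    x = runif(n, 0, domain@Lx), y = runif(n, 0, domain@Ly),
    z = runif(n, 0.5, domain@Lz / 2),
    mass = massFromRadius(r, params@rhoX), eps = 0), params)
}

# brute-force union-find over the full pair matrix (independent oracle for
# the cluster partition)
bruteClusters <- function(a, domain, linkPairs = NULL) {
  n <- nrow(a)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- a$x[j] - a$x[i]; dy <- a$y[j] - a$y[i]; dz <- a$z[j] - a$z[i]
    if (domain@bcX == "periodic") dx <- dx - round(dx / domain@Lx) * domain@Lx
    if (domain@bcY == "periodic") dy <- dy - round(dy / domain@Ly) * domain@Ly
    if (sqrt(dx^2 + dy^2 + dz^2) < (a$radius[i] + a$radius[j]) * (1 + 1e-9))
      union(i, j)
  }
  if (!is.null(linkPairs) && nrow(linkPairs)) {
    for (k in seq_len(nrow(linkPairs))) {
      if (!linkPairs$active[k]) next
      union(match(linkPairs$idI[k], a$id), match(linkPairs$idJ[k], a$id))
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# canonical form of a partition for comparisons
canonPartition <- function(m) as.integer(factor(m, levels = unique(m)))
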