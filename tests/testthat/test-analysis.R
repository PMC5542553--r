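test_that("height field reports max(z + r) per column", {
  p <- bfParams()
  d <- smallDomain()
  expect_true(all(heightField(agentSet(NULL, p), d) == 0))
  ## single agent: its column reads z + r
  a <- oneAgent(p, x = 5, y = 5, z = 10, r = 0.5)
  h <- heightField(a, d)
  expect_equal(max(h), 10.5)
  expect_equal(sum(h > 0), 1)
  ## a monolayer of 1 um agents reads 1 everywhere
  g <- expand.grid(x = seq(1.25, 38.75, 2.5), y = seq(1.25, 8.75, 2.5))
  mono <- agentSet(data.frame(group = "HET", x = g$x, y = g$y, z = 0.5,
                              mass = massFromRadius(0.5, bfParams()@rhoX),
                              eps = 0), p)
  expect_true(all(abs(heightField(mono, d) - 1) < 1e-12))
})

test_that("morphology matches hand-computed values on a staircase", {
  p <- bfParams()
  d <- bfDomain(Lx = 4, Ly = 2, Lz = 10, Nx = 4, Ny = 2, Nz = 10)
  ## staircase height field 1,2,3,4 across x (both y rows)
  h <- matrix(rep(1:4, 2), 4, 2)
  ## occupancy: fill all voxels under the local height
  F <- array(FALSE, c(4, 2, 10))
  for (i in 1:4) F[i, , 1:i] <- TRUE
  mo <- morphology(h, F, d)
  expect_equal(mo$meanHeight, 2.5)
  expect_equal(mo$roughness, sqrt(mean((1:4 - 2.5)^2)))
  ## porosity: filled = 2*(1+2+3+4) = 20 of Nx*Ny*hmax = 4*2*4 = 32
  expect_equal(mo$porosity, 1 - 20 / 32)
  ## flat film: zero roughness; full slab: zero porosity
  hf <- matrix(3, 4, 2)
  Ff <- array(FALSE, c(4, 2, 10)); Ff[, , 1:3] <- TRUE
  mof <- morphology(hf, Ff, d)
  expect_equal(mof$roughness, 0)
  expect_equal(mof$porosity, 0)
  ## checkerboard occupancy at uniform height: porosity 1/2
  Fc <- array(FALSE, c(4, 2, 10))
  for (i in 1:4) for (j in 1:2) for (k in 1:4)
    Fc[i, j, k] <- (i + j + k) %% 2 == 0
  moc <- morphology(matrix(4, 4, 2), Fc, d)
  expect_equal(moc$porosity, 0.5)
  ## empty biofilm: undefined porosity flagged
  mo0 <- morphology(matrix(0, 4, 2), array(FALSE, c(4, 2, 10)), d)
  expect_false(mo0$defined)
  expect_equal(mo0$porosity, 0)
})

test_that("voxel occupancy follows the sphere-overlap rule", {
  p <- bfParams()
  d <- bfDomain(Lx = 10, Ly = 10, Lz = 10, Nx = 10, Ny = 10, Nz = 10)
  ## a sphere centred in a voxel but spilling into neighbours
  a <- oneAgent(p, x = 5.5, y = 5.5, z = 5.5, r = 0.9)
  Fo <- occupancyField(a@agents, d)
  Fc <- occupancyField(a@agents, d, rule = "centre")
  expect_equal(sum(Fc), 1)
  expect_gt(sum(Fo), 1)          # overlap rule fills neighbours
  expect_true(Fo[6, 6, 6] && Fc[6, 6, 6])
})

test_that("volume fractions sum to one and split by group", {
  p <- bfParams()
  mk <- function(group, r, n) {
    dens <- if (group == "EPS") p@rhoEPS else p@rhoX
    data.frame(group = group, x = seq_len(n), y = 1, z = 1,
               mass = massFromRadius(r, dens), eps = 0)
  }
  allHet <- agentSet(mk("HET", 0.5, 4), p)
  expect_equal(volumeFractions(allHet, p),
               c(bacteria = 1, EPS = 0, inert = 0))
  ## equal volumes of HET and EPS -> 0.5 / 0.5
  mix <- agentSet(rbind(mk("HET", 0.5, 2), mk("EPS", 0.5, 2)), p)
  expect_equal(volumeFractions(mix, p)[["bacteria"]], 0.5)
  expect_equal(volumeFractions(mix, p)[["EPS"]], 0.5)
  ## random populations always sum to 1
  set.seed(19)
  d <- smallDomain()
  for (rep in 1:5) {
    a <- randomAgents(30, p, d)
    a@agents$eps[a@agents$group == "HET"] <- runif(sum(a@agents$group == "HET"))
    expect_equal(sum(volumeFractions(a, p)), 1, tolerance = 1e-12)
  }
  expect_equal(sum(volumeFractions(agentSet(NULL, p), p)), 0)
})

test_that("active-layer thickness interpolates between all and top-only", {
  p <- bfParams()
  d <- smallDomain()
  ## two stacked layers in every column of a 2x1 patch
  a <- agentSet(data.frame(
    group = "HET", x = rep(c(5, 7.5), each = 2), y = 5,
    z = rep(c(0.5, 1.5), 2),
    mass = massFromRadius(0.5, p@rhoX), eps = 0), p)
  ## all active: thickness equals local height (2 um)
  expect_equal(activeLayerThickness(a, rates = rep(1, 4), d), 2)
  ## only the top agents active: about one diameter
  rates <- ifelse(a@agents$z > 1, 1, 0.1)
  expect_equal(activeLayerThickness(a, rates, d, fracThreshold = 0.5), 1)
  ## no active cells
  expect_equal(activeLayerThickness(a, rates = rep(0, 4), d), 0)
})

test_that("cluster partition equals the brute-force union-find oracle", {
  p <- bfParams()
  d <- smallDomain()
  set.seed(37)
  for (rep in 1:8) {
    a <- randomAgents(50, p, d)
    links <- buildLinks(a, p, d)
    cc <- clusterComponents(a, links, p, d)
    oracleLinks <- links$pairs
    oracle <- bruteClusters(a@agents, d, oracleLinks)
    expect_equal(canonPartition(cc$cluster), canonPartition(oracle))
  }
})

test_that("cluster partition is invariant to ordering and periodic shifts", {
  p <- bfParams()
  d <- smallDomain()
  set.seed(43)
  a <- randomAgents(40, p, d)
  links <- buildLinks(a, p, d)
  cc <- clusterComponents(a, links, p, d)
  ## permute agent rows
  perm <- sample(40)
  a2 <- a; a2@agents <- a@agents[perm, ]
  cc2 <- clusterComponents(a2, buildLinks(a2, p, d), p, d)
  m1 <- canonPartition(cc$cluster[order(cc$id)])
  m2 <- canonPartition(cc2$cluster[order(cc2$id)])
  expect_equal(m1, m2)
  ## rigid periodic translation
  a3 <- a
  a3@agents$x <- (a3@agents$x + 17.3) %% d@Lx
  cc3 <- clusterComponents(a3, buildLinks(a3, p, d), p, d)
  expect_equal(canonPartition(cc3$cluster[order(cc3$id)]), m1)
})

test_that("attachment requires a path to the substratum", {
  p <- bfParams()
  d <- smallDomain()
  a <- agentSet(data.frame(
    group = "HET",
    x = c(5, 5.9, 20), y = 5, z = c(0.5, 0.6, 20),
    mass = massFromRadius(0.5, p@rhoX), eps = 0), p)
  cc <- clusterComponents(a, NULL, p, d)
  expect_equal(length(unique(cc$cluster)), 2)
  expect_true(all(cc$attached[1:2]))       # touching pair on the substratum
  expect_false(cc$attached[3])             # isolated agent at height: detached
})

test_that("detachment statistics summarise events and fit the lognormal", {
  ## single event: rate = V / T
  ev <- data.frame(time = 50, volume = 12, normVolume = 0.1)
  st <- detachmentStatistics(ev, initialVolume = 120, duration = 100)
  expect_equal(st$rate, 12 / 100)
  expect_equal(st$detachedFraction, 0.1)
  expect_equal(st$nEvents, 1L)
  ## no events: empty statistics
  st0 <- detachmentStatistics(NULL, 1, 1)
  expect_equal(st0$nEvents, 0L)
  expect_equal(st0$rate, 0)
  ## lognormal ML fit recovers the generating parameters at n = 500
  set.seed(53)
  v <- rlnorm(500, meanlog = -2, sdlog = 0.7)
  evl <- data.frame(time = runif(500, 0, 100), volume = v)
  stl <- detachmentStatistics(evl, initialVolume = sum(v) * 10, duration = 100)
  expect_lt(abs(stl$lognormal$meanlog - (-2)), 3 * stl$lognormal$se.meanlog + 1e-9)
  expect_lt(abs(stl$lognormal$sdlog - 0.7), 3 * stl$lognormal$se.sdlog + 1e-9)
  ## counts per bin sum to the number of events
  expect_equal(sum(stl$countsPerBin$count), 500L)
})
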