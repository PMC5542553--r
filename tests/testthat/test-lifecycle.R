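test_that("division conserves mass exactly and splits shells proportionally", {
  p <- bfParams()
  set.seed(11)
  for (rep in 1:20) {
    m <- runif(1, 6.5, 12)
    e <- runif(1, 0, 1)
    mother <- data.frame(id = 1L, group = "HET", x = 10, y = 5, z = 3,
                         vx = 0, vy = 0, vz = 0, mass = m, eps = e,
                         radius = outerRadius(m, e, "HET", p))
    dd <- divideAgent(mother, p, newId = 2L)
    expect_identical(sum(dd$mass), m)        # exact conservation
    expect_identical(sum(dd$eps), e)
    expect_equal(dd$eps[1] / dd$mass[1], e / m, tolerance = 1e-12)
    ## daughter 1 keeps the mother's position
    expect_equal(unlist(dd[1, c("x", "y", "z")]), c(x = 10, y = 5, z = 3))
    ## separation equals the sum of the daughter radii (touching)
    sep <- sqrt(sum((dd[2, c("x", "y", "z")] - dd[1, c("x", "y", "z")])^2))
    expect_equal(sep, sum(dd$radius), tolerance = 1e-9)
  }
  expect_error(divideAgent(transform(mother, mass = 0.1,
                                     radius = outerRadius(0.1, 0, "HET", p)), p),
               "below division threshold")
})

test_that("daughter mass fractions are uniform on [0.45, 0.55] (KS test)", {
  p <- bfParams()
  mother <- data.frame(id = 1L, group = "HET", x = 10, y = 5, z = 3,
                       vx = 0, vy = 0, vz = 0, mass = 8, eps = 0,
                       radius = outerRadius(8, 0, "HET", p))
  set.seed(101)
  frac <- replicate(1e4, divideAgent(mother, p, 2L)$mass[1] / 8)
  expect_true(all(frac >= 0.45 & frac <= 0.55))
  ks <- suppressWarnings(ks.test(frac, "punif", 0.45, 0.55))
  expect_gt(ks$p.value, 0.01)
})

test_that("division directions are uniform on the sphere", {
  p <- bfParams()
  mother <- data.frame(id = 1L, group = "HET", x = 0, y = 0, z = 100,
                       vx = 0, vy = 0, vz = 0, mass = 8, eps = 0,
                       radius = outerRadius(8, 0, "HET", p))
  set.seed(202)
  dirs <- t(replicate(1e4, {
    dd <- divideAgent(mother, p, 2L)
    v <- unlist(dd[2, c("x", "y", "z")]) - unlist(dd[1, c("x", "y", "z")])
    v / sqrt(sum(v^2))
  }))
  ## mean direction vector of a uniform sphere sample is ~0 (se = 1/sqrt(3n))
  expect_true(all(abs(colMeans(dirs)) < 4 / sqrt(3 * nrow(dirs))))
  ## z component uniform on [-1, 1]
  ks <- suppressWarnings(ks.test(dirs[, 3], "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("EPS shells are excreted at the composite-diameter threshold", {
  p <- bfParams()
  m <- massFromRadius(0.5, p@rhoX)
  ## shell just below threshold: nothing happens
  rCore <- 0.5
  volNeeded <- (p@epsExcreteRatio^3 - 1) * (4 / 3) * pi * rCore^3
  eBelow <- 0.9 * volNeeded * p@rhoEPS
  ag <- data.frame(id = 1L, group = "HET", x = 5, y = 5, z = 5,
                   vx = 0, vy = 0, vz = 0, mass = m, eps = eBelow,
                   radius = outerRadius(m, eBelow, "HET", p))
  res <- secreteEps(ag, p, newId = 2L)
  expect_null(res$eps)
  expect_identical(res$agent, ag)
  ## at threshold: HET core untouched, EPS agent carries the whole shell
  eAt <- 1.001 * volNeeded * p@rhoEPS
  ag$eps <- eAt
  ag$radius <- outerRadius(m, eAt, "HET", p)
  set.seed(5)
  res <- secreteEps(ag, p, newId = 2L)
  expect_equal(res$agent$mass, m)
  expect_equal(res$agent$eps, 0)
  expect_equal(res$eps$mass, eAt)       # conservation
  expect_equal(res$eps$group, "EPS")
  ## placed adjacent: separation = r_HET + r_EPS
  sep <- sqrt(sum((unlist(res$eps[c("x", "y", "z")]) -
                   unlist(res$agent[c("x", "y", "z")]))^2))
  expect_equal(sep, res$agent$radius + res$eps$radius, tolerance = 1e-9)
  ## excreted EPS decays when EPS decay is enabled
  pDec <- bfParams(epsDecay = 0.1)
  netDec <- singleSpeciesNetwork(pDec)
  expect_lt(specificRate("EPS", list(S_S = 1e-4), netDec), 0)
})

test_that("death and removal thresholds convert and delete agents", {
  p <- bfParams()
  mk <- function(diam, group = "HET") {
    dens <- if (group == "EPS") p@rhoEPS else p@rhoX
    m <- massFromRadius(diam / 2, dens)
    data.frame(group = group, x = 5, y = 5, z = 5, mass = m, eps = 0)
  }
  a <- agentSet(rbind(mk(0.79), mk(0.09), mk(1.0)), p)
  res <- deathAndRemoval(a, p)
  out <- res$aset@agents
  expect_equal(nrow(out), 2)                       # 0.09 um agent removed
  expect_setequal(out$group, c("INERT", "HET"))    # 0.79 um agent now inert
  expect_equal(sort(2 * coreRadius(out$mass, out$group, p)),
               sort(c(0.79, 1.0)), tolerance = 1e-9)  # masses unchanged
  expect_equal(res$removedMass, massFromRadius(0.045, p@rhoX))
  expect_setequal(res$events$type, c("death", "removal"))
  ## dying agent releases its shell as a free EPS particle
  ag2 <- agentSet(mk(0.79), p)
  ag2@agents$eps <- 0.3
  res2 <- deathAndRemoval(ag2, p)
  expect_equal(sum(res2$aset@agents$eps), 0)
  expect_equal(sum(res2$aset@agents$mass[res2$aset@agents$group == "EPS"]), 0.3)
})

test_that("lifecycle sweep is deterministic given the seed", {
  p <- bfParams()
  d <- smallDomain()
  mk <- function() {
    set.seed(99)
    a <- randomAgents(40, p, d, rRange = c(0.55, 0.75))
    set.seed(1234)
    lifecycleStep(a, p)
  }
  r1 <- mk(); r2 <- mk()
  expect_identical(r1$aset@agents, r2$aset@agents)
  expect_identical(r1$events, r2$events)
})

test_that("the COD ledger balances across a full simulated step", {
  d <- smallDomain()
  p <- paramsForGroups(1.52e-2, 0.35, d)
  sc <- bfScenario(inoculum = list(count = 8, groups = "HET", diameter = 1,
                                   placement = "grid", xFrac = 1),
                   stop = list(height = 8, maxSteps = 40), seed = 3)
  ss <- runSimulation(sc, p, d)
  a <- agentTable(ss)
  total <- sum(a$mass) + sum(a$eps)
  led <- codLedger(ss)
  balance <- led$initial + led$grown - led$decayed - led$removed - led$outflow
  expect_equal(total, balance, tolerance = 1e-9)
})
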