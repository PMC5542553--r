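test_that("contact force follows the spring law and Newton's third law", {
  p <- bfParams()
  knI <- p@kn * 1e18                       # N/m -> fg/s^2
  ## static overlapping pair, Hookean: |F_n| = k_n * overlap
  cf <- contactForce(c(0, 0, 0), c(0.9, 0, 0), 0.5, 0.5, params = p)
  expect_equal(cf$overlap, 0.1)
  expect_equal(cf$Fj, c(knI * 0.1, 0, 0))
  expect_equal(cf$Fi + cf$Fj, c(0, 0, 0))
  ## non-overlapping pair: zero
  cf0 <- contactForce(c(0, 0, 0), c(1.2, 0, 0), 0.5, 0.5, params = p)
  expect_equal(cf0$Fj, c(0, 0, 0))
  ## Hertzian factor sqrt(overlap * d), d = di dj / (2 (di + dj))
  cfH <- contactForce(c(0, 0, 0), c(0.9, 0, 0), 0.5, 0.5, params = p,
                      model = "hertzian")
  dEff <- 0.5 * 1 * 1 / (1 + 1)
  expect_equal(cfH$Fj[1], sqrt(0.1 * dEff) * knI * 0.1)
  ## third law holds for random states (with damping and tangential terms)
  set.seed(31)
  for (k in 1:10) {
    xi <- runif(3); xj <- xi + runif(3, -0.5, 0.5)
    cfr <- contactForce(xi, xj, 0.5, 0.45, vi = rnorm(3), vj = rnorm(3),
                        mi = 2, mj = 3, params = p, deltaT = rnorm(3, 0, 0.01))
    expect_equal(cfr$Fi + cfr$Fj, c(0, 0, 0))
  }
  ## periodic minimum image: pair straddling the x boundary interacts
  d <- bfDomain()
  cfp <- contactForce(c(0.2, 5, 5), c(99.7, 5, 5), 0.5, 0.5, params = p,
                      domain = d)
  expect_gt(cfp$overlap, 0)
})

test_that("wall contact acts as a particle of infinite radius", {
  p <- bfParams()
  knI <- p@kn * 1e18
  ## grazing: zero force at z = r
  expect_equal(wallContact(c(5, 5, 0.5), 0.5, params = p), c(0, 0, 0))
  ## 10% penetration: repulsive +z spring force
  f <- wallContact(c(5, 5, 0.45), 0.5, params = p)
  expect_equal(f, c(0, 0, knI * 0.05))
  ## far away: zero
  expect_equal(wallContact(c(5, 5, 30), 0.5, params = p), c(0, 0, 0))
})

test_that("adhesive springs match Eq-style direct evaluation and break at 2 d0", {
  p <- bfParams()
  ## rest length: zero force
  af <- adhesiveForce(c(0, 0, 0), c(1, 0, 0), d0 = 1, meps = 2, params = p)
  expect_equal(af$Fj, c(0, 0, 0))
  expect_true(af$active)
  ## stretched: attractive with magnitude k_eps * m_eps * (d - d0)
  af2 <- adhesiveForce(c(0, 0, 0), c(1.5, 0, 0), d0 = 1, meps = 2, params = p)
  expect_equal(af2$Fj, c(-p@kEps * 2 * 0.5, 0, 0))
  expect_equal(af2$Fi, -af2$Fj)
  ## compressed: repulsive
  af3 <- adhesiveForce(c(0, 0, 0), c(0.8, 0, 0), d0 = 1, meps = 2, params = p)
  expect_gt(af3$Fj[1], 0)
  ## at twice the rest length the link breaks permanently
  af4 <- adhesiveForce(c(0, 0, 0), c(2, 0, 0), d0 = 1, meps = 2, params = p)
  expect_false(af4$active)
  expect_equal(af4$Fj, c(0, 0, 0))
  ## zero EPS mass: no force at any separation
  af5 <- adhesiveForce(c(0, 0, 0), c(1.9, 0, 0), d0 = 1, meps = 0, params = p)
  expect_equal(af5$Fj, c(0, 0, 0))
})

test_that("Stokes drag matches 6 pi mu r v_rel and is linear in radius", {
  p <- bfParams()
  ## mu = 1e-3 Pa s, r = 0.5 um, |v_rel| = 1 um/s:
  ## 6 pi * 1e-3 * 0.5e-6 * 1e-6 N = 9.42e-15 N = 9.42e9 fg um/s^2
  f <- dragForce(0.5, U = c(1, 0, 0), v = c(0, 0, 0), params = p)
  expect_equal(f[1], 6 * pi * 1e-3 * 0.5e-6 * 1e-6 * 1e24, tolerance = 1e-12)
  ## moving with the fluid: zero
  expect_equal(dragForce(0.5, c(1, 2, 3), c(1, 2, 3), p), c(0, 0, 0))
  ## doubling the radius doubles the drag
  expect_equal(dragForce(1, c(1, 0, 0), params = p),
               2 * dragForce(0.5, c(1, 0, 0), params = p))
})

test_that("kernel forces agree with the R force functions", {
  p <- bfParams()
  d <- smallDomain()
  set.seed(41)
  a <- randomAgents(40, p, d)
  links <- buildLinks(a, p, d)
  ff <- assemblyForces(a, links, p, d)
  ag <- a@agents
  n <- nrow(ag)
  FR <- matrix(0, n, 3)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cf <- contactForce(unlist(ag[i, c("x", "y", "z")]),
                       unlist(ag[j, c("x", "y", "z")]),
                       ag$radius[i], ag$radius[j], params = p, domain = d)
    FR[i, ] <- FR[i, ] + cf$Fi
    FR[j, ] <- FR[j, ] + cf$Fj
  }
  for (i in seq_len(n))
    FR[i, ] <- FR[i, ] + wallContact(unlist(ag[i, c("x", "y", "z")]),
                                     ag$radius[i], params = p)
  lp <- links$pairs
  if (nrow(lp)) for (k in seq_len(nrow(lp))) {
    i <- match(lp$idI[k], ag$id); j <- match(lp$idJ[k], ag$id)
    af <- adhesiveForce(unlist(ag[i, c("x", "y", "z")]),
                        unlist(ag[j, c("x", "y", "z")]),
                        lp$d0[k], lp$meps[k], params = p, domain = d)
    FR[i, ] <- FR[i, ] + af$Fi
    FR[j, ] <- FR[j, ] + af$Fj
  }
  lw <- links$wall
  if (nrow(lw)) for (k in seq_len(nrow(lw))) {
    i <- match(lw$id[k], ag$id)
    FR[i, 3] <- FR[i, 3] - p@kEps * lw$meps[k] * (ag$z[i] - lw$d0[k])
  }
  scale <- max(abs(FR)) + 1e-300
  expect_lt(max(abs(ff$F - FR)) / scale, 1e-10)
})

test_that("internal forces sum to zero when no walls are engaged", {
  p <- bfParams()
  d <- smallDomain()
  set.seed(13)
  for (rep in 1:5) {
    a <- randomAgents(30, p, d)
    a@agents$z <- a@agents$z + 5          # keep clear of the substratum
    links <- buildLinks(a, p, d)
    links$wall <- links$wall[0, ]
    ff <- assemblyForces(a, links, p, d)
    scale <- max(abs(ff$F), 1)
    expect_lt(max(abs(colSums(ff$F))) / scale, 1e-9)
  }
})

test_that("pair forces are invariant under rigid periodic translation", {
  p <- bfParams()
  d <- smallDomain()
  set.seed(17)
  a <- randomAgents(25, p, d)
  links <- buildLinks(a, p, d)
  f1 <- assemblyForces(a, links, p, d)
  a2 <- a
  a2@agents$x <- (a2@agents$x + d@Lx) %% d@Lx
  a2@agents$y <- (a2@agents$y + 0.5 * d@Ly) %% d@Ly
  links2 <- links
  f2 <- assemblyForces(a2, links2, p, d)
  expect_equal(f2$F[, 1], f1$F[, 1], tolerance = 1e-9)
  expect_equal(f2$F[, 3], f1$F[, 3], tolerance = 1e-9)
  expect_equal(f2$pressure, f1$pressure, tolerance = 1e-9)
})

test_that("two overlapping spheres relax to touching separation", {
  p <- bfParams()
  d <- bfDomain()
  r <- 0.5
  m <- massFromRadius(r, p@rhoX)
  a <- agentSet(data.frame(group = "HET", x = c(50, 50.9), y = 20,
                           z = c(20, 20), mass = m, eps = 0), p)
  rx <- relaxAgents(a, buildLinks(a, p, d), p, d)
  aa <- rx$aset@agents
  sep <- sqrt(sum((unlist(aa[1, c("x", "y", "z")]) -
                   unlist(aa[2, c("x", "y", "z")]))^2))
  expect_lt(abs(sep - 2 * r), 1e-3 * r)
  ## pressure trace decays towards zero after the initial state
  expect_lt(rx$trace[length(rx$trace)], 1e-2 * rx$trace[1])
})

test_that("relaxation releases the growth-induced pressure of a packed cluster", {
  p <- bfParams()
  d <- smallDomain()
  ## overlapping cluster around a point (a just-divided microcolony)
  set.seed(23)
  th <- runif(12, 0, 2 * pi); ph <- acos(runif(12, -1, 1))
  a <- agentSet(data.frame(
    group = "HET",
    x = 20 + 0.7 * sin(ph) * cos(th), y = 5 + 0.7 * sin(ph) * sin(th),
    z = 8 + 0.7 * cos(ph),
    mass = massFromRadius(0.55, p@rhoX), eps = 0), p)
  rx <- relaxAgents(a, buildLinks(a, p, d), p, d, method = "descent",
                    maxIter = 20000)
  ## final pressure a small fraction of the initial (released over time)
  expect_lt(rx$pressure, 5e-3 * max(rx$trace))
  ## no residual overlaps beyond the equilibrium tolerance
  ff <- assemblyForces(rx$aset, rx$links, p, d)
  expect_lt(ff$maxOverlap, 5e-3)
})

test_that("a lone agent in shear reaches the local fluid velocity", {
  p <- bfParams()
  d <- smallDomain()
  a <- oneAgent(p, x = 20, y = 5, z = 10, r = 0.5, group = "EPS")
  fp <- flowPhase(a, buildLinks(a, p, d), p, d, duration = 2, gammaDot = 0.1)
  ## terminal velocity = gammaDot * z, displacement = v * t
  expect_equal(fp$aset@agents$vx, 0.1 * fp$aset@agents$z, tolerance = 1e-6)
  expect_equal(fp$aset@agents$x, (20 + 0.1 * 10 * 2) %% d@Lx,
               tolerance = 0.05)
})

test_that("adhesive links break permanently under sustained shear stretch", {
  p <- bfParams()
  d <- smallDomain()
  ## a two-agent chain anchored by wall adhesion, sheared hard
  m <- massFromRadius(0.5, p@rhoX)
  a <- agentSet(data.frame(group = "HET", x = 20, y = 5, z = c(0.5, 1.5),
                           mass = m, eps = c(0.5, 0.5)), p)
  links <- buildLinks(a, p, d)
  expect_equal(nrow(links$pairs), 1)
  fp <- flowPhase(a, links, p, d, duration = 40, gammaDot = 2)
  expect_false(any(fp$links$pairs$active))
  ## the freed upper agent is advected downstream
  expect_gt(abs(fp$aset@agents$vx[2]), 0)
})
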