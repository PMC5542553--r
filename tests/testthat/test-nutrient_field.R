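test_that("uniform bulk field with no reaction is a fixed point", {
  p <- bfParams()
  d <- smallDomain()
  f <- soluteFields(d, "S_S", init = p@Sb)
  De <- effectiveDiffusivity(agentSet(NULL, p), d, p)
  f2 <- stepSolute(f, "S_S", De, R = NULL, dt = 1e-4, params = p, feed = "top")
  expect_equal(f2@fields$S_S, f@fields$S_S, tolerance = 1e-14)
  ## quasi-steady solver agrees in at most one sweep
  qs <- solveQuasiSteady(agentSet(NULL, p), f, singleSpeciesNetwork(p), p)
  expect_lte(qs$iters, 1)
  expect_true(qs$converged)
})

test_that("stability bound violations and bad closures are rejected", {
  p <- bfParams()
  d <- smallDomain()
  f <- soluteFields(d, "S_S", init = p@Sb)
  De <- effectiveDiffusivity(agentSet(NULL, p), d, p)
  expect_error(stepSolute(f, "S_S", De, dt = 10, params = p), "stability")
  expect_error(effectiveDiffusivity(agentSet(NULL, p), d, p,
                                    closure = function(X) rep(2, length(X))),
               "closure")
})

test_that("effective diffusivity follows the pluggable closure", {
  p <- bfParams()
  d <- smallDomain()
  ## empty voxels: D_e = D_S everywhere
  De <- effectiveDiffusivity(agentSet(NULL, p), d, p)
  expect_true(all(De == 1.6e-9))
  ## linear hindrance 1 - 0.2 X/Xmax evaluated directly
  a <- oneAgent(p, x = 5, y = 5, z = 5, r = 0.6)
  voxVol <- (d@Lx / d@Nx) * (d@Ly / d@Ny) * (d@Lz / d@Nz)
  X <- a@agents$mass / voxVol
  cl <- function(Xv) 1 - 0.2 * pmin(Xv / X, 1)
  De2 <- effectiveDiffusivity(a, d, p, closure = cl)
  expect_equal(min(De2), 0.8 * p@DS, tolerance = 1e-12)
  expect_equal(max(De2), p@DS)
})

test_that("closed boundaries conserve solute mass to 1e-10 per step", {
  p <- bfParams()
  d <- smallDomain()
  set.seed(8)
  f <- soluteFields(d, "S_S", init = p@Sb)
  f@fields$S_S[] <- runif(length(f@fields$S_S), 0, 2e-4)
  De <- effectiveDiffusivity(agentSet(NULL, p), d, p)
  m0 <- sum(f@fields$S_S)
  f2 <- stepSolute(f, "S_S", De, dt = 1e-4, params = p, feed = "none",
                   nsteps = 200)
  expect_equal(sum(f2@fields$S_S), m0, tolerance = 1e-10)
  ## with shear advection switched on, still conservative (periodic x)
  f3 <- stepSolute(f, "S_S", De, dt = 1e-4, params = p, feed = "none",
                   gammaDot = 0.2, nsteps = 200)
  expect_equal(sum(f3@fields$S_S), m0, tolerance = 1e-10)
})

test_that("zero-order sink reproduces the 1D parabolic profile within 2%", {
  ## steady state of D S'' = R0 with S(Lz) = Sb (top feed), S'(0) = 0:
  ## S(z) = Sb - (R0 / 2 De) (Lz^2 - z^2)
  p <- bfParams()
  d <- bfDomain(Lx = 10, Ly = 10, Lz = 100, Nx = 3, Ny = 3, Nz = 30)
  De <- effectiveDiffusivity(agentSet(NULL, p), d, p)
  DeU <- p@DS * 1e12                     # um^2/s
  R0 <- 0.5 * p@Sb * DeU / 100^2         # sink keeping S > 0 everywhere
  R <- array(-R0, c(3, 3, 30))
  f <- soluteFields(d, "S_S", init = p@Sb)
  dt <- 0.9 / (2 * DeU * (1 / (10 / 3)^2 * 2 + 1 / (100 / 30)^2))
  for (i in 1:60) f <- stepSolute(f, "S_S", De, R, dt = dt, params = p,
                                  feed = "top", nsteps = 500)
  z <- (seq_len(30) - 0.5) * (100 / 30)
  exact <- p@Sb - R0 / (2 * DeU) * (100^2 - z^2)
  num <- f@fields$S_S[2, 2, ]
  expect_lt(max(abs(num - exact) / p@Sb), 0.02)
  ## bottom feed mirrors the profile
  fb <- soluteFields(d, "S_S", init = p@Sb)
  for (i in 1:60) fb <- stepSolute(fb, "S_S", De, R, dt = dt, params = p,
                                   feed = "bottom", nsteps = 500)
  ## by symmetry: distance measured from the bottom feed wall
  zB <- 100 - z
  exactB <- p@Sb - R0 / (2 * DeU) * (100^2 - zB^2)
  expect_lt(max(abs(fb@fields$S_S[2, 2, ] - exactB) / p@Sb), 0.02)
})

test_that("quasi-steady Monod sink obeys the maximum principle and feeds correctly", {
  d <- smallDomain()
  p <- paramsForGroups(1.52e-2, 0.35, d)
  net <- singleSpeciesNetwork(p)
  set.seed(21)
  ## a dense slab of biomass near the bottom
  a <- agentSet(data.frame(
    group = "HET",
    x = runif(150, 0, d@Lx), y = runif(150, 0, d@Ly), z = runif(150, 0.5, 6),
    mass = massFromRadius(0.6, p@rhoX), eps = 0), p)
  f <- soluteFields(d, net, init = p@Sb)
  qs <- solveQuasiSteady(a, f, net, p, tol = 1e-7)
  S <- qs$fields@fields$S_S
  expect_true(all(S >= 0 & S <= p@Sb * (1 + 1e-12)))
  ## monotone towards the top feed, depleted at the base
  prof <- apply(S, 3, mean)
  expect_lt(prof[1], 0.5 * p@Sb)
  expect_true(all(diff(prof) > -1e-15))
  expect_gt(prof[d@Nz], 0.9 * p@Sb)
  ## feeding from the bottom instead inverts the gradient
  qsB <- solveQuasiSteady(a, qs$fields, net, p, tol = 1e-7, feed = "bottom")
  profB <- apply(qsB$fields@fields$S_S, 3, mean)
  expect_gt(profB[1], profB[d@Nz])
})

test_that("halving the voxel size changes the 1D profile at O(h^2)", {
  p <- bfParams()
  DeU <- p@DS * 1e12
  R0 <- 0.5 * p@Sb * DeU / 100^2
  solve1d <- function(Nz) {
    d <- bfDomain(Lx = 10, Ly = 10, Lz = 100, Nx = 2, Ny = 2, Nz = Nz)
    De <- effectiveDiffusivity(agentSet(NULL, p), d, p)
    f <- soluteFields(d, "S_S", init = p@Sb)
    dt <- 0.9 / (2 * DeU * (2 / 25 + Nz^2 / 1e4))
    for (i in 1:80) f <- stepSolute(f, "S_S", De, array(-R0, c(2, 2, Nz)),
                                    dt = dt, params = p, feed = "top",
                                    nsteps = 400)
    zc <- (seq_len(Nz) - 0.5) * (100 / Nz)
    max(abs(f@fields$S_S[1, 1, ] -
            (p@Sb - R0 / (2 * DeU) * (100^2 - zc^2)))) / p@Sb
  }
  e1 <- solve1d(10)
  e2 <- solve1d(20)
  expect_gt(e1 / e2, 3)   # second-order: error ratio ~4
})
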