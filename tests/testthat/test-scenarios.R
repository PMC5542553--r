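test_that("inoculum generation matches the preset specifications", {
  p <- bfParams()
  d <- bfDomain()
  ## 40 cells of 1 um diameter evenly spread on the substratum
  a <- makeInoculum(list(count = 40, groups = "HET", diameter = 1,
                         placement = "grid", xFrac = 1), p, d)
  expect_equal(nAgents(a), 40)
  expect_true(all(a@agents$z == 0.5))
  expect_true(all(a@agents$group == "HET"))
  expect_equal(unique(round(2 * coreRadius(a@agents$mass, "HET", p), 9)), 1)
  ## even coverage: 10 distinct x positions, 4 distinct y positions
  expect_equal(length(unique(a@agents$x)), 10)
  expect_equal(length(unique(a@agents$y)), 4)
  ## three-species demo: one of each group near the domain centre
  a3 <- makeInoculum(scenarioPreset("three_species_demo")@inoculum, p, d)
  expect_setequal(a3@agents$group, c("HET", "AOB", "NOB"))
  expect_true(all(abs(a3@agents$x - d@Lx / 2) <= 2))
  ## packing limit enforced
  expect_error(makeInoculum(list(count = 1e5, diameter = 1,
                                 placement = "grid"), p, d), "packing")
})

test_that("identical seeds give bitwise-identical runs", {
  d <- smallDomain()
  p <- paramsForGroups(1.52e-2, 0.35, d)
  sc <- bfScenario(inoculum = list(count = 6, groups = "HET", diameter = 1,
                                   placement = "grid", xFrac = 1),
                   stop = list(height = 5, maxSteps = 15), seed = 77)
  s1 <- runSimulation(sc, p, d)
  s2 <- runSimulation(sc, p, d)
  expect_identical(agentTable(s1), agentTable(s2))
  expect_identical(eventLog(s1), eventLog(s2))
  expect_identical(frameTimes(s1), frameTimes(s2))
})

test_that("zero-growth parameters give a fixed point of the loop", {
  d <- smallDomain()
  p <- bfParams(muMax = 1e-12, decay = 0, Sb = 1.6e-5, KS = 5.6e-6)
  sc <- bfScenario(inoculum = list(count = 6, groups = "HET", diameter = 1,
                                   placement = "grid", xFrac = 1),
                   stop = list(maxSteps = 4), seed = 1)
  ss <- runSimulation(sc, p, d)
  a0 <- ss@frames[[1]]$agents
  aN <- agentTable(ss)
  expect_equal(nrow(aN), 6)
  expect_equal(aN$mass, a0$mass, tolerance = 1e-9)
  expect_equal(aN$x, a0$x, tolerance = 1e-9)
  expect_equal(aN$z, a0$z, tolerance = 1e-9)
})

test_that("a lone agent grows along the exponential closed form", {
  d <- smallDomain()
  p <- paramsForGroups(1.52e-2, 0.35, d)
  p@dDiv <- 50            # keep it from dividing
  sc <- bfScenario(inoculum = list(count = 1, groups = "HET", diameter = 1,
                                   placement = "grid", xFrac = 1),
                   stop = list(maxSteps = 10), seed = 1)
  ss <- runSimulation(sc, p, d)
  m0 <- massFromRadius(0.5, p@rhoX)
  ## nutrient stays near the bulk value for a single cell
  r <- (p@muMax * monod(p@Sb, p@KS) - p@decay) / 3600
  t <- max(frameTimes(ss))
  a <- agentTable(ss)
  expect_equal(sum(a$mass[a$group == "HET"]), m0 * exp(r * t),
               tolerance = 0.02)
})

test_that("snapshot series round-trip through the directory store", {
  d <- smallDomain()
  p <- paramsForGroups(1.52e-2, 0.35, d)
  sc <- bfScenario(inoculum = list(count = 6, groups = "HET", diameter = 1,
                                   placement = "grid", xFrac = 1),
                   stop = list(height = 5, maxSteps = 12), seed = 5)
  ss <- runSimulation(sc, p, d)
  dir <- withr::local_tempdir()
  writeSnapshotSeries(ss, dir)
  ss2 <- readSnapshotSeries(dir)
  expect_equal(frameTimes(ss2), frameTimes(ss))
  expect_equal(agentTable(ss2), agentTable(ss))
  expect_equal(codLedger(ss2)$grown, codLedger(ss)$grown)
  expect_equal(nrow(eventLog(ss2)), nrow(eventLog(ss)))
  ## write -> read -> write is byte-identical
  dir2 <- withr::local_tempdir()
  writeSnapshotSeries(ss2, dir2)
  for (f in list.files(dir))
    expect_identical(readLines(file.path(dir2, f)),
                     readLines(file.path(dir, f)), info = f)
})

test_that("XYZ and VTK exports have the right shape", {
  d <- smallDomain()
  p <- paramsForGroups(1.52e-2, 0.35, d)
  sc <- bfScenario(inoculum = list(count = 6, groups = "HET", diameter = 1,
                                   placement = "grid", xFrac = 1),
                   stop = list(maxSteps = 3), seed = 5)
  ss <- runSimulation(sc, p, d, recordSolutes = TRUE)
  xyz <- withr::local_tempfile(fileext = ".xyz")
  writeXYZ(ss, xyz)
  lines <- readLines(xyz)
  n1 <- as.integer(lines[1])
  expect_equal(n1, nrow(ss@frames[[1]]$agents))   # frame row count = agents
  ## every frame contributes count + comment + rows
  total <- sum(vapply(ss@frames, function(f) nrow(f$agents) + 2L, integer(1)))
  expect_equal(length(lines), total)
  vtk <- withr::local_tempfile(fileext = ".vtk")
  writeSoluteVTK(ss@frames[[length(ss@frames)]]$solutes, d, vtk)
  vl <- readLines(vtk)
  expect_true(any(grepl("DIMENSIONS 16 4 16", vl)))
  expect_equal(sum(grepl("^[0-9.eE+-]+$", vl[-seq_len(10)])), 16 * 4 * 16)
})

test_that("three-species demo runs and HET dominates under default kinetics", {
  d <- smallDomain()
  p <- paramsForGroups(1.52e-2, 0.35, d)
  net <- threeSpeciesNetwork(p)
  sc <- scenarioPreset("three_species_demo", seed = 2)
  sc@stop <- list(maxSteps = 25, volumeFrac = 0.5)
  ss <- runSimulation(sc, p, d, net = net)
  a <- agentTable(ss)
  mHET <- sum(a$mass[a$group == "HET"])
  expect_gt(mHET, sum(a$mass[a$group == "AOB"]))
  expect_gt(mHET, sum(a$mass[a$group == "NOB"]))
  ## all three lineages still present or recorded
  expect_true(all(c("HET") %in% a$group))
})
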