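# Synthetic-data generators: determinism, construction guarantees, and
# end-to-end statistical recovery of the generating parameters.

test_that("generators are pure functions of (spec, seed)", {
  expect_identical(coords(makeToyChannel()), coords(makeToyChannel()))
  s1 <- simulateGatingTrajectory(nFrames = 30, nReplicas = 2, seed = 71)
  s2 <- simulateGatingTrajectory(nFrames = 30, nReplicas = 2, seed = 71)
  expect_identical(s1$ensembles[[2]]@coords, s2$ensembles[[2]]@coords)
  expect_identical(s1$states, s2$states)
  expect_identical(simulateDoseResponse(seed = 72),
                   simulateDoseResponse(seed = 72))
  expect_identical(simulateKinetics(seed = 73), simulateKinetics(seed = 73))
  # a different seed changes the draw
  expect_false(identical(simulateDoseResponse(seed = 72),
                         simulateDoseResponse(seed = 74)))
})

test_that("overlapping toy-channel atoms are rejected", {
  bad <- toyChannelSpec(tailXY = rbind(c(8.3, 0), c(8.3, 0),
                                       c(-8.3, 0), c(0, -8.4)))
  expect_error(makeToyChannel(bad), "overlap")
})

test_that("the toy channel encodes its gate distances exactly", {
  spec <- toyChannelSpec(tailXY = rbind(c(8.3, 0), c(0, 8.4),
                                        c(-8.3, 0), c(0, -8.4)))
  gd <- gateDistances(makeToyChannel(spec))
  expect_equal(gd@d1, 16.6, tolerance = 1e-9)
  expect_equal(gd@d2, 16.8, tolerance = 1e-9)
  expect_equal(spec$trueD1, 16.6, tolerance = 1e-12)
})

test_that("generated ensembles survive I/O round-trip and canonicalization", {
  sim <- simulateGatingTrajectory(ions = ionModelSpec(nIons = 3),
                                  nFrames = 4, nReplicas = 1, seed = 75)
  ens <- sim$ensembles[[1]]
  ft <- withr::local_tempfile(fileext = ".pdb")
  fx <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(ens@topology, ft)
  writeTrajectory(ens, fx)
  back <- readTrajectory(ft, fx)
  expect_equal(nFrames(back), 4)
  expect_lt(max(abs(coords(back) - ens@coords)), 1e-3)
  canon <- canonicalizeFrames(back, makeToyChannel(), toyCanonicalSpec())
  spec <- toyCanonicalSpec()
  for (i in seq_len(nFrames(canon))) {
    fr <- getFrame(canon, i)
    xy <- colMeans(coords(fr)[selectAtoms(fr, spec$xyCenter)@indices, ])
    zz <- colMeans(coords(fr)[selectAtoms(fr, spec$zCenter)@indices, ])
    expect_lt(max(abs(c(xy[1:2], zz[3]))), 1e-6)
  }
})

test_that("a symmetric switching chain spends half its time wetted", {
  wet <- wettingModelSpec(kWet = 0.5, kDry = 0.5)   # iid chain
  sim <- simulateGatingTrajectory(wet = wet, ions = ionModelSpec(nIons = 0),
                                  nFrames = 2000, nReplicas = 1, seed = 76)
  frac <- mean(sim$states[[1]])
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("the two-state gate water means are recovered from the frames", {
  sim <- simulateGatingTrajectory(ions = ionModelSpec(nIons = 0),
                                  nFrames = 1200, nReplicas = 4, seed = 77)
  counts <- unlist(lapply(sim$ensembles, gateWaterCount))
  states <- unlist(sim$states)
  mDry <- mean(counts[states == 0])
  mWet <- mean(counts[states == 1])
  seDry <- sd(counts[states == 0]) / sqrt(sum(states == 0))
  seWet <- sd(counts[states == 1]) / sqrt(sum(states == 1))
  expect_lt(abs(mDry - 4), 3 * seDry)
  expect_lt(abs(mWet - 12), 3 * seWet)
  # and the stationary wetted fraction matches the chain parameters
  p <- sim$trueWettedFraction
  seFrac <- markovFractionSE(p, length(states), sim$wet$kWet, sim$wet$kDry)
  expect_lt(abs(mean(states) - p), 3 * seFrac)
})

test_that("threshold classification matches its analytic two-state limit", {
  sim <- simulateGatingTrajectory(ions = ionModelSpec(nIons = 0),
                                  nFrames = 1500, nReplicas = 4, seed = 78)
  counts <- unlist(lapply(sim$ensembles, gateWaterCount))
  frac <- mean(classifyWetting(counts) == "wetted")
  p <- sim$trueWettedFraction
  limit <- p * (1 - ppois(9, 12)) + (1 - p) * (1 - ppois(9, 4))
  se <- markovFractionSE(p, length(counts), sim$wet$kWet, sim$wet$kDry)
  expect_lt(abs(frac - limit), 3 * se)
})

test_that("reflecting gates show zero permeation; scripted crossings are exact", {
  simR <- simulateGatingTrajectory(ions = ionModelSpec(nIons = 25),
                                   nFrames = 300, nReplicas = 2, seed = 79)
  for (e in simR$ensembles)
    expect_equal(nrow(detectPermeation(e, simR$ionSelection)), 0)
  simP <- simulateGatingTrajectory(
    ions = ionModelSpec(nIons = 0, permeationMode = "permeant",
                        nScripted = 3),
    nFrames = 200, nReplicas = 1, seed = 80)
  ev <- detectPermeation(simP$ensembles[[1]], simP$ionSelection)
  expect_equal(simP$nScriptedCrossings, 3)
  expect_equal(nrow(ev), 3)
  expect_true(all(ev$direction == "inward"))
})

test_that("d2 fluctuates with the configured ~4 A excursion scale", {
  sim <- simulateGatingTrajectory(ions = ionModelSpec(nIons = 0),
                                  nFrames = 1500, nReplicas = 1, seed = 81)
  gd <- gateDistances(sim$ensembles[[1]])
  expect_equal(mean(gd@d2), 16.8, tolerance = 0.15)
  dev <- max(abs(gd@d2 - 16.8))
  expect_gt(dev, 2)       # excursions well beyond thermal jitter
  expect_lt(dev, 8)       # but bounded near the configured scale
})

test_that("noiseless and clipped dose-response generation behave as specified", {
  d0 <- simulateDoseResponse(noiseSd = 0)
  mu <- 1 / (1 + 11.4 / d0$concentration)
  expect_equal(d0$response, mu, tolerance = 1e-12)
  expect_error(simulateDoseResponse(noiseSd = -0.1), "non-negative")
  dBig <- simulateDoseResponse(noiseSd = 0.5, seed = 82)
  expect_true(all(dBig$response >= 0 & dBig$response <= 1))
  k0 <- simulateKinetics(noiseSd = 0, mode = "decay", tau = 5)
  expect_equal(k0$response, exp(-k0$time / 5), tolerance = 1e-12)
})
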