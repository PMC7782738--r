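# Hydration profiles, gate water counts, wetting classification and
# permeation detection.

test_that("uniform cylinder water gives a flat normalized profile", {
  set.seed(21)
  sys <- makeWaterSystem(cylinderPoints(4000, 8.5, -20, 20))
  prof <- axialWaterProfile(asEnsemble(sys),
                            cylinderSpec(zMin = -20, zMax = 20, nSlices = 8))
  expect_equal(max(prof$probability), 1)
  expect_true(all(prof$probability > 0.85))   # flat within binomial noise
})

test_that("an isolated pore water shows as a small peak in its slice", {
  set.seed(22)
  bulk <- cylinderPoints(600, 8.5, 10, 20)     # dense solvent slab
  lone <- matrix(c(1, 1, -12.5), 1)            # single water, slice [-13,-12)
  sys <- makeWaterSystem(rbind(bulk, lone))
  prof <- axialWaterProfile(asEnsemble(sys),
                            cylinderSpec(zMin = -20, zMax = 20, nSlices = 40))
  pore <- prof$sliceCenters < 0
  hit <- which(pore & prof$probability > 0)
  expect_length(hit, 1)
  expect_equal(prof$sliceCenters[hit], -12.5)
  expect_equal(max(prof$probability), 1)
})

test_that("a waterless system has no solvent slice to normalize by", {
  dry <- makeSystem("CA", "ALA", 1L, "A", matrix(0, 1, 3))
  expect_error(axialWaterProfile(asEnsemble(dry)), "no solvent slice")
})

test_that("profile aggregation gives the across-replica mean and sample-SD SEM", {
  mk <- function(v) list(sliceCenters = c(0.5, 1.5), probability = c(1, v))
  agg <- aggregateProfiles(list(mk(0.4), mk(0.6)))
  expect_equal(agg@meanProbability, c(1, 0.5))
  expect_equal(agg@sem, c(0, 0.1))             # sd(0.4,0.6)/sqrt(2)
  # one replica and identical replicas both give zero SEM
  expect_equal(aggregateProfiles(list(mk(0.3)))@sem, c(0, 0))
  expect_equal(aggregateProfiles(list(mk(0.3), mk(0.3), mk(0.3)))@sem,
               c(0, 0))
  expect_error(aggregateProfiles(list(mk(0.3),
    list(sliceCenters = c(0, 2), probability = c(1, 0.3)))), "mismatch")
})

test_that("gate water counting matches construction and a brute-force oracle", {
  gate <- gateRegion()
  set.seed(23)
  inGate <- cylinderPoints(3, gate$radius - 0.5, gate$zMin + 1, gate$zMax - 1)
  bulk <- cylinderPoints(50, 8, 5, 30)
  expect_equal(gateWaterCount(makeWaterSystem(rbind(inGate, bulk)), gate), 3)
  expect_equal(gateWaterCount(makeWaterSystem(bulk), gate), 0)
  # random configuration against an independent per-atom membership loop
  pts <- cbind(runif(100, -12, 12), runif(100, -12, 12),
               runif(100, -35, -10))
  oracle <- 0
  for (i in 1:100) {
    r <- sqrt(pts[i, 1]^2 + pts[i, 2]^2)
    if (pts[i, 3] > gate$zMin && pts[i, 3] < gate$zMax && r <= gate$radius)
      oracle <- oracle + 1
  }
  expect_equal(gateWaterCount(makeWaterSystem(pts), gate), oracle)
})

test_that("gate count equals the integral of the unnormalized profile over gate slices", {
  gate <- gateRegion()           # z in (-28, -15)
  set.seed(24)
  nGate <- 7
  inGate <- cylinderPoints(nGate, 8.5, -27.9, -15.1)
  solvent <- cylinderPoints(100, 8.5, 5, 6)    # 100 waters in one 1-A slice
  sys <- makeWaterSystem(rbind(inGate, solvent))
  cyl <- cylinderSpec(zMin = -28, zMax = 7, nSlices = 35)  # 1-A aligned
  prof <- axialWaterProfile(asEnsemble(sys), cyl)
  g <- prof$sliceCenters > gate$zMin & prof$sliceCenters < gate$zMax
  integral <- sum(prof$probability[g]) * 100   # solvent slice holds 100
  expect_equal(integral, gateWaterCount(sys, gate))
})

test_that("gate water-count distributions normalize per replica and average across", {
  gate <- gateRegion()
  mkConst <- function(n, rep) {
    frames <- lapply(1:4, function(i) {
      pts <- cylinderPoints(n, 8, gate$zMin + 0.5, gate$zMax - 0.5)
      rbind(pts, cylinderPoints(20, 8, 5, 30))
    })
    set.seed(100 + rep)
    sys <- makeWaterSystem(frames[[1]])
    newFrameEnsemble(sys, frames, replicaId = rep)
  }
  set.seed(25)
  oneRep <- nwaterDistribution(mkConst(4, 1), gate)
  expect_equal(oneRep@meanProbability[oneRep@counts == 4], 1)
  expect_equal(oneRep@perReplicaMeanN, 4)
  expect_equal(oneRep@sem, rep(0, length(oneRep@counts)))
  two <- nwaterDistribution(list(mkConst(3, 1), mkConst(5, 2)), gate)
  expect_equal(two@meanProbability[two@counts == 3], 0.5)
  expect_equal(two@meanProbability[two@counts == 5], 0.5)
  # sample-SD convention: sd(c(1,0))/sqrt(2)
  expect_equal(two@sem[two@counts == 3], 0.5)
  expect_equal(rowSums(two@perReplica), c(1, 1), tolerance = 1e-12)
})

test_that("wetting classification uses the inclusive 10-water threshold", {
  expect_equal(as.character(classifyWetting(c(3, 9, 10, 15))),
               c("dewetted", "dewetted", "wetted", "wetted"))
  expect_error(classifyWetting(5, threshold = 0), "at least 1")
})

test_that("connected-path wetting requires a spanning water chain", {
  gate <- gateRegion()
  zs <- seq(gate$zMin - 1, gate$zMax + 1, by = 2.5)   # continuous column
  column <- cbind(0, 0, zs)
  expect_equal(as.character(classifyWettingPath(makeWaterSystem(column),
                                                gate)), "wetted")
  broken <- column[abs(column[, 3] + 21) > 3, ]       # cut the middle out
  expect_equal(as.character(classifyWettingPath(makeWaterSystem(broken),
                                                gate)), "dewetted")
})

test_that("permeation detection finds scripted crossings and nothing else", {
  gate <- gateRegion()
  ion <- data.frame(name = "NA", resname = "SOD", resid = 1L, chain = "I",
                    x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
  water <- data.frame(name = "O", resname = "HOH", resid = 2L, chain = "W",
                      x = 0, y = 0, z = 30, stringsAsFactors = FALSE)
  topo <- newMolecularSystem(rbind(ion, water))
  mkEns <- function(zPath, xPath = rep(0, length(zPath))) {
    frames <- lapply(seq_along(zPath), function(i)
      rbind(c(xPath[i], 0, zPath[i]), c(0, 0, 30)))
    newFrameEnsemble(topo, frames)
  }
  # never approaches the gate
  expect_equal(nrow(detectPermeation(mkEns(seq(5, 40, length.out = 10)),
                                     "resname SOD", gate)), 0)
  # monotone walk from -10 to -32 inside the cylinder: one inward event
  z <- seq(-10, -32, by = -1)
  ev <- detectPermeation(mkEns(z), "resname SOD", gate)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, "inward")
  expect_equal(ev$entryFrame, which(z <= gate$zMax)[1])
  expect_equal(ev$exitFrame, which(z < gate$zMin)[1])
  expect_lt(ev$entryFrame, ev$exitFrame)
  # the reverse path is an outward event
  expect_equal(detectPermeation(mkEns(rev(z)), "resname SOD",
                                gate)$direction, "outward")
  # leaving the cylinder mid-gate voids the traversal (hysteresis)
  zq <- c(-10, -16, -20, -24, -29, -32)
  xq <- c(0, 0, 12, 12, 0, 0)
  expect_equal(nrow(detectPermeation(mkEns(zq, xq), "resname SOD", gate)), 0)
  # empty ion selection is an error
  expect_error(detectPermeation(mkEns(z), "resname XXX", gate), "empty")
})

test_that("permeation count is invariant under rigid motion before canonicalization", {
  sim <- simulateGatingTrajectory(ions = ionModelSpec(nIons = 20),
                                  nFrames = 150, nReplicas = 1, seed = 31)
  ens <- sim$ensembles[[1]]
  n0 <- nrow(detectPermeation(ens, sim$ionSelection))
  R <- poregate:::.rotationAboutAxis(c(1, 2, 3), 1.1)
  moved <- applyTransform(ens, new("RigidTransform", rotation = R,
                                   translation = c(7, -3, 12)))
  canon <- canonicalizeFrames(moved, makeToyChannel(), toyCanonicalSpec())
  expect_equal(nrow(detectPermeation(canon, sim$ionSelection)), n0)
})
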