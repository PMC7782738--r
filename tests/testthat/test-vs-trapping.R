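# Static-structure comparison metrics: RMSD, displacement, ion pairs,
# helix typing, buried interface area.

test_that("RMSD of a structure against itself is zero over all residues", {
  sys <- makeSyntheticCaTrace(50, seed = 51)
  r <- rmsdOverSelection(sys, sys)
  expect_equal(r$rmsd, 0, tolerance = 1e-12)
  expect_equal(r$nResidues, 50)
  expect_equal(r$nUnpaired, 0)
})

test_that("a uniform 1 A offset gives RMSD exactly 1 without superposition", {
  xyz <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(3.8, 3.8, 0))
  a <- makeSystem(rep("CA", 3), "GLY", 1:3, "A", xyz)
  b <- makeSystem(rep("CA", 3), "GLY", 1:3, "A",
                  sweep(xyz, 2, -c(1, 0, 0)))
  expect_equal(rmsdOverSelection(a, b, superpose = FALSE)$rmsd, 1,
               tolerance = 1e-12)
})

test_that("superposed RMSD matches the quaternion oracle and is symmetric", {
  set.seed(52)
  for (i in 1:10) {
    a <- makeSyntheticCaTrace(40, seed = 520 + i)
    b <- perturbStructure(a, sd = 0.5, seed = 530 + i)
    rab <- rmsdOverSelection(a, b)$rmsd
    expect_lt(abs(rab - quaternionRmsd(coords(a), coords(b))), 1e-6)
    expect_lt(abs(rab - rmsdOverSelection(b, a)$rmsd), 1e-9)
  }
})

test_that("unpaired atoms are dropped and counted", {
  a <- makeSyntheticCaTrace(30, seed = 53)
  at <- atoms(a)
  b <- newMolecularSystem(at[at$resid <= 20, ])       # truncated copy
  r <- rmsdOverSelection(a, b)
  expect_equal(r$nResidues, 20)
  expect_equal(r$nUnpaired, 10)
  noMatch <- makeSystem("CA", "ALA", 999L, "Q", matrix(0, 1, 3))
  expect_error(rmsdOverSelection(a, noMatch), "zero atoms")
})

test_that("residue displacement isolates the moved residue", {
  a <- makeSyntheticCaTrace(30, seed = 54)
  at <- atoms(a)
  at$z[at$resid == 15] <- at$z[at$resid == 15] + 11
  b <- newMolecularSystem(at)
  d <- residueDisplacement(a, b, "resid 10-20", "resid 1-9 or resid 21-30")
  expect_equal(d$displacement[d$resid == 15], 11, tolerance = 1e-9)
  expect_lt(max(d$displacement[d$resid != 15]), 1e-9)
})

test_that("ion pairs are detected at the construction distance and cut off sharply", {
  arg <- data.frame(name = c("CZ", "NH1"), resname = "ARG", resid = 1L,
                    chain = "A", x = c(0, 1), y = 0, z = 0,
                    stringsAsFactors = FALSE)
  asp <- data.frame(name = "OD1", resname = "ASP", resid = 2L, chain = "A",
                    x = 4, y = 0, z = 0, stringsAsFactors = FALSE)
  sys <- newMolecularSystem(rbind(arg, asp))
  pairs <- ionPairCensus(sys, "resname ARG", "resname ASP")
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$minDistance, 3.0, tolerance = 1e-12)
  expect_equal(pairs$side, "other")
  expect_equal(nrow(ionPairCensus(sys, "resname ARG", "resname ASP",
                                  cutoff = 2.5)), 0)
})

test_that("the ion-pair census is monotone in the cutoff", {
  vs <- makeSyntheticVoltageSensor("intermediate")
  keyOf <- function(p) paste(p$basicResid, p$acidicResid)
  cuts <- c(2.0, 2.9, 3.5, 4.0, 6.0)
  sets <- lapply(cuts, function(ct)
    keyOf(ionPairCensus(vs$system, vs$basicSpec, vs$acidicSpec,
                        cutoff = ct)))
  for (i in seq_along(cuts)[-1])
    expect_true(all(sets[[i - 1]] %in% sets[[i]]))
})

test_that("ENC/INC sides follow the acidic residue's z against the HCS", {
  vs <- makeSyntheticVoltageSensor("intermediate")
  pairs <- ionPairCensus(vs$system, vs$basicSpec, vs$acidicSpec,
                         hcsZ = vs$hcsZ)
  expect_equal(nrow(pairs), 4)
  expect_equal(sum(pairs$side == "ENC"), 2)
  expect_equal(sum(pairs$side == "INC"), 2)
  # the two outermost gating charges pair with the extracellular cluster
  encBasic <- sort(pairs$basicResid[pairs$side == "ENC"])
  expect_equal(encBasic, vs$gatingResids[1:2])
})

test_that("ideal helices are typed correctly from internal-coordinate constructions", {
  alpha <- buildIdealHelix(12, phi = -57, psi = -47)
  h310 <- buildIdealHelix(12, phi = -49, psi = -26)
  la <- helixTypeAssignment(alpha, 2:8)
  l3 <- helixTypeAssignment(h310, 2:8)
  expect_true(all(la$label == "alpha"))
  expect_true(all(l3$label == "three_ten"))
  # a 2-residue fragment has no i+3 partner at all
  frag <- newMolecularSystem(atoms(alpha)[atoms(alpha)$resid <= 2, ])
  expect_true(all(helixTypeAssignment(frag, 1:2)$label == "other"))
})

test_that("helix typing is invariant under rigid motion", {
  h <- buildIdealHelix(12, phi = -49, psi = -26)
  R <- poregate:::.rotationAboutAxis(c(2, -1, 5), 2.2)
  moved <- applyTransform(h, new("RigidTransform", rotation = R,
                                 translation = c(10, 20, -5)))
  expect_equal(helixTypeAssignment(moved, 2:8)$label,
               helixTypeAssignment(h, 2:8)$label)
})

test_that("residues with missing backbone warn and fall back to 'other'", {
  h <- buildIdealHelix(10, phi = -57, psi = -47)
  at <- atoms(h)
  broken <- newMolecularSystem(at[!(at$resid == 4 & at$name == "O"), ])
  expect_warning(lab <- helixTypeAssignment(broken, 3:5), "missing backbone")
  expect_equal(lab$label[lab$resid == 4], "other")
})

test_that("groups far apart bury no area; overlapping groups error", {
  sys <- makeSystem(c("CA", "CA"), "GLY", 1:2, c("A", "B"),
                    rbind(c(0, 0, 0), c(100, 0, 0)))
  ia <- interfaceArea(sys, "chain A", "chain B")
  expect_equal(ia$buriedA, 0, tolerance = 1e-9)
  expect_equal(ia$buriedB, 0, tolerance = 1e-9)
  expect_error(interfaceArea(sys, "chain A", "chain A or chain B"),
               "overlap")
})

test_that("two touching spheres match the analytic spherical-cap burial within 2%", {
  rv <- 2.0; probe <- 1.4; d <- 2 * rv
  sys <- makeSystem(c("S1", "S2"), "UNK", 1:2, c("A", "B"),
                    rbind(c(0, 0, 0), c(d, 0, 0)))
  ia <- interfaceArea(sys, "chain A", "chain B", probe = probe,
                      radii = c(S = rv))
  Re <- rv + probe
  analytic <- 2 * pi * Re * (Re - d / 2)     # cap height Re - d/2
  expect_equal(ia$buriedA, analytic, tolerance = 0.02)
  expect_equal(ia$buriedB, analytic, tolerance = 0.02)
})

test_that("the synthetic docked complex buries a site-3-scale footprint on both sides", {
  cx <- makeSyntheticInterfaceComplex()
  ia <- interfaceArea(cx, "chain P", "chain T", nPoints = 480)
  expect_gt(ia$buriedA, 700)
  expect_gt(ia$buriedB, 700)
  expect_lt(abs(ia$buriedA - ia$buriedB) / ia$buriedA, 0.15)
})
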