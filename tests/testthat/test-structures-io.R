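# Structure and trajectory I/O plus the selection mini-grammar.

test_that("a single ATOM record is echoed faithfully", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "END"), f)
  sys <- readStructure(f)
  expect_equal(nAtoms(sys), 1)
  a <- atoms(sys)
  expect_equal(a$name, "CA")
  expect_equal(a$resname, "ALA")
  expect_equal(a$resid, 1L)
  expect_equal(c(a$x, a$y, a$z), c(1, 2, 3))
})

test_that("write-then-read round-trips atoms, chains, residues and coordinates", {
  sys <- makeToyChannel()
  f <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(sys, f)
  back <- readStructure(f)
  expect_equal(nAtoms(back), nAtoms(sys))
  expect_equal(atoms(back)$name, atoms(sys)$name)
  expect_equal(atoms(back)$chain, atoms(sys)$chain)
  expect_equal(atoms(back)$resid, atoms(sys)$resid)
  expect_lt(max(abs(coords(back) - coords(sys))), 1e-3)
})

test_that("a hand-written 3-chain file preserves chain ids in order", {
  f <- withr::local_tempfile(fileext = ".pdb")
  lines <- sprintf(
    "ATOM  %5d  CA  GLY %1s%4d       0.000   0.000  %6.3f  1.00  0.00           C",
    1:6, rep(c("A", "B", "C"), each = 2), rep(1:2, 3), seq(0, 5))
  writeLines(c(lines, "END"), f)
  sys <- readStructure(f)
  expect_equal(unique(atoms(sys)$chain), c("A", "B", "C"))
})

test_that("altloc conformers collapse to the highest-occupancy one", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.60  0.00           C",
    "END"), f)
  sys <- readStructure(f)
  expect_equal(nAtoms(sys), 1)
  expect_equal(atoms(sys)$x, 5)
})

test_that("unknown formats and unparsable files raise explicit errors", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines("nonsense", f)
  expect_error(readStructure(f), "cannot infer")
  g <- withr::local_tempfile(fileext = ".pdb")
  writeLines("this is not a pdb", g)
  expect_error(readStructure(g), "pdb")
})

test_that("selection grammar resolves the activation-gate residues", {
  sys <- makeToyChannel()
  sel <- selectAtoms(sys, "name CA and resid 410-413")
  expect_length(sel@indices, 4)
  expect_equal(atoms(sys)$resid[sel@indices], 410:413)
  # empty selection is legal, not an error
  expect_length(selectAtoms(sys, "resid 9999")@indices, 0)
  # malformed spec errors with a position
  expect_error(selectAtoms(sys, "name CA and"), "parse error")
  expect_error(selectAtoms(sys, "resid 41x"), "parse error")
})

test_that("water recognition covers PDB and MD residue dialects", {
  xyz <- matrix(seq(0, 26, by = 1), ncol = 3)
  sys <- makeWaterSystem(xyz[1:7, , drop = FALSE])
  tip <- data.frame(name = "O", resname = "TIP3", resid = 8:9, chain = "W",
                    x = c(30, 31), y = 0, z = 0, stringsAsFactors = FALSE)
  prot <- data.frame(name = c("CA", "O"), resname = "ALA", resid = 1:2,
                     chain = "A", x = 40:41, y = 0, z = 0,
                     stringsAsFactors = FALSE)
  all <- newMolecularSystem(rbind(atoms(sys)[, c("name", "resname", "resid",
                                                 "chain", "x", "y", "z")],
                                  tip, prot))
  expect_length(selectAtoms(all, "water and name O")@indices, 9)
  # the protein carbonyl O is not water
  expect_length(selectAtoms(all, "water")@indices, 9)
})

test_that("selections are idempotent, order-stable, and partition to the full set", {
  sys <- makeToyChannel()
  s1 <- selectAtoms(sys, "name CA")
  expect_identical(selectAtoms(sys, s1)@indices, s1@indices)
  expect_false(is.unsorted(s1@indices))
  s2 <- selectAtoms(sys, "not name CA")
  expect_identical(sort(c(s1@indices, s2@indices)), seq_len(nAtoms(sys)))
  # boolean composition
  both <- selectAtoms(sys, "name CA or not name CA")
  expect_identical(both@indices, seq_len(nAtoms(sys)))
})

test_that("multi-model PDB trajectories round-trip with frame counts intact", {
  topo <- makeSystem(c("CA", "CA"), "ALA", 1:2, "A",
                     rbind(c(0, 0, 0), c(3.8, 0, 0)))
  frames <- lapply(1:5, function(i) coords(topo) + i)
  ens <- newFrameEnsemble(topo, frames, dt = 10)
  ft <- withr::local_tempfile(fileext = ".pdb")
  fx <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(topo, ft)
  writeTrajectory(ens, fx)
  back <- readTrajectory(ft, fx, dt = 10)
  expect_equal(nFrames(back), 5)
  expect_lt(max(abs(coords(back) - ens@coords)), 1e-3)
  expect_equal(frameTimes(back), frameTimes(ens))
})

test_that("atom-count mismatch between topology and trajectory is reported", {
  topo3 <- makeSystem(rep("CA", 3), "ALA", 1:3, "A", diag(3) * 3.8)
  topo2 <- makeSystem(rep("CA", 2), "ALA", 1:2, "A",
                      rbind(c(0, 0, 0), c(3.8, 0, 0)))
  ft3 <- withr::local_tempfile(fileext = ".pdb")
  fx <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(topo3, ft3)
  writeTrajectory(asEnsemble(topo2), fx)
  expect_error(readTrajectory(ft3, fx), "3 atoms.*2")
})

test_that("out-of-order MODEL records keep file order and warn", {
  topo <- makeSystem("CA", "ALA", 1L, "A", matrix(c(0, 0, 0), 1))
  ft <- withr::local_tempfile(fileext = ".pdb")
  fx <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(topo, ft)
  writeLines(c(
    "MODEL        2",
    "ATOM      1  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       2.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL", "END"), fx)
  expect_warning(ens <- readTrajectory(ft, fx), "out of order")
  expect_equal(as.numeric(ens@coords[1, 1, ]), c(1, 2))
  expect_equal(frameTimes(ens), c(0, 1))
})

test_that("XTC input is rejected with an explicit message", {
  topo <- makeSystem("CA", "ALA", 1L, "A", matrix(0, 1, 3))
  ft <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(topo, ft)
  fx <- withr::local_tempfile(fileext = ".xtc")
  writeLines("", fx)
  expect_error(readTrajectory(ft, fx), "XTC")
})
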