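# Synthetic stand-in structures. These generators build labelled
# synthetic models whose geometry encodes the hallmark features of the
# toxin-trapped versus apo channel states (gate widths, constriction
# diameter, S4 gating-charge displacement, bridging ion pairs, 3-10
# helix, a site-3-scale binding footprint), so the static-structure
# metrics can be exercised end-to-end with known ground truth.

#' Synthetic channel gate model (toxin-bound or apo state)
#'
#' A \code{\link{makeToyChannel}} preset: the toxin-bound state has S6
#' tails at offsets giving (d1, d2) = (16.6, 16.8) Angstrom and a
#' constriction ring giving a 6.6 Angstrom van der Waals gate diameter;
#' the apo state is narrower, (16.1, 16.6) Angstrom with a 5.6 Angstrom
#' gate (about 1 Angstrom smaller).
#'
#' @param state \code{"toxin"} or \code{"apo"}.
#' @return A \code{MolecularSystem} (synthetic).
#' @export
makeSyntheticGateModel <- function(state = c("toxin", "apo")) {
  state <- match.arg(state)
  spec <- if (state == "toxin")
    toyChannelSpec(tailXY = rbind(c(8.3, 0), c(0, 8.4),
                                  c(-8.3, 0), c(0, -8.4)),
                   constrictionRadius = 5.0)
  else
    toyChannelSpec(tailXY = rbind(c(8.05, 0), c(0, 8.3),
                                  c(-8.05, 0), c(0, -8.3)),
                   constrictionRadius = 4.5)
  sys <- makeToyChannel(spec)
  sys@label <- sprintf("synthetic %s-state gate model", state)
  sys
}

#' Synthetic voltage-sensor model (intermediate-activated or activated)
#'
#' Builds an S4 helix (chain S, residues 101-120) carrying six
#' gating-charge arginines at every third position (R1-R6 at residues
#' 104, 107, ..., 119), four acidic partner residues (chain V) whose
#' carboxylate oxygens sit 2.9 Angstrom from the R1-R4 guanidinium
#' nitrogens -- two in the extracellular negative cluster above the
#' hydrophobic constriction site (z = 0) and two in the intracellular
#' cluster below -- and a rigid reference scaffold (chain F) shared by
#' both states. The \code{"intermediate"} (toxin-trapped) state is a
#' 3-10 helix; the \code{"activated"} state is the same sensor displaced
#' 11 Angstrom outward (+z) along the membrane normal, so the
#' gating-charge Calpha displacement between states is ~11 Angstrom.
#'
#' @param state \code{"intermediate"} or \code{"activated"}.
#' @param seed integer seed for the small coordinate jitter applied to
#'   the activated state.
#' @return list with \code{system} (a synthetic \code{MolecularSystem}),
#'   \code{hcsZ} (z of the hydrophobic constriction site),
#'   \code{basicSpec} and \code{acidicSpec} (selection expressions for
#'   the gating charges R1-R4 and the ENC/INC acidic residues), and
#'   \code{gatingResids} (R1-R4 residue numbers).
#' @export
makeSyntheticVoltageSensor <- function(state = c("intermediate",
                                                 "activated"),
                                       seed = 1L) {
  state <- match.arg(state)
  argResids <- seq(104L, 119L, by = 3L)     # R1..R6
  helix <- buildIdealHelix(20, phi = -49, psi = -26, chain = "S",
                           startResid = 101L)
  helix@atoms$resname[helix@atoms$resid %in% argResids] <- "ARG"
  # N-terminus (R1 end) extracellular: axis from first to last residue
  # points -z, placing R1 at the top
  helix <- orientHelix(helix, axis = c(0, 0, -1), origin = c(6, 0, 0))
  at <- helix@atoms
  rows <- list(at[, c("name", "resname", "resid", "chain",
                      "x", "y", "z")])
  addAtom <- function(name, resname, resid, chain, p) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, resname = resname, resid = resid, chain = chain,
      x = p[1], y = p[2], z = p[3], stringsAsFactors = FALSE)
  }
  # guanidinium N atoms for R1-R4, pointing radially out from the axis
  r14 <- argResids[1:4]
  nh1Pos <- list()
  for (r in r14) {
    ca <- unlist(at[at$resid == r & at$name == "CA", c("x", "y", "z")])
    u <- c(ca[1], ca[2], 0)
    u <- u / sqrt(sum(u^2))
    addAtom("NE", "ARG", r, "S", ca + 2.8 * u)
    nh1 <- ca + 4.2 * u
    addAtom("NH1", "ARG", r, "S", nh1)
    addAtom("NH2", "ARG", r, "S", nh1 + c(0, 0, 1.1))
    nh1Pos[[as.character(r)]] <- nh1
  }
  # HCS marker between R2 and R3 (z = 0 by construction of the helix
  # centroid); ENC acidic partners for R1/R2, INC for R3/R4
  caZ <- vapply(r14, function(r)
    at$z[at$resid == r & at$name == "CA"], numeric(1))
  hcsZ <- mean(caZ[2:3])
  addAtom("CZ", "PHE", 200L, "H", c(8, 0, hcsZ))
  acidResn <- c("ASP", "ASP", "GLU", "GLU")
  acidO <- list(c("OD1", "OD2"), c("OD1", "OD2"),
                c("OE1", "OE2"), c("OE1", "OE2"))
  for (i in 1:4) {
    nh1 <- nh1Pos[[as.character(r14[i])]]
    u <- c(nh1[1], nh1[2], 0)
    u <- u / sqrt(sum(u^2))
    o1 <- nh1 + 2.9 * u
    addAtom(acidO[[i]][1], acidResn[i], 10L + i, "V", o1)
    addAtom(acidO[[i]][2], acidResn[i], 10L + i, "V", o1 + c(0, 0, 1.4))
  }
  # rigid scaffold shared by both states (superposition reference)
  for (j in 1:12) {
    ang <- 2 * pi * (j - 1) / 12
    addAtom("CA", "GLY", 500L + j, "F",
            c(20 * cos(ang), 20 * sin(ang), 3 * ((j %% 3) - 1)))
  }
  atoms <- do.call(rbind, rows)
  if (state == "activated") {
    move <- atoms$chain %in% c("S", "V")
    atoms$z[move] <- atoms$z[move] + 11
    set.seed(seed)
    n <- sum(move)
    atoms$x[move] <- atoms$x[move] + stats::rnorm(n, 0, 0.1)
    atoms$y[move] <- atoms$y[move] + stats::rnorm(n, 0, 0.1)
    atoms$z[move] <- atoms$z[move] + stats::rnorm(n, 0, 0.1)
  }
  sys <- newMolecularSystem(atoms,
                            label = sprintf("synthetic %s voltage sensor",
                                            state))
  list(system = sys, hcsZ = hcsZ,
       basicSpec = sprintf("chain S and resid %s",
                           paste(r14, collapse = ",")),
       acidicSpec = "chain V", gatingResids = r14)
}

#' Synthetic toxin-channel interface complex
#'
#' A channel-surface slab (chain P) and a disk-shaped toxin footprint
#' (chain T) docked 2.0 Angstrom above it -- close enough to exclude a
#' 1.4 Angstrom solvent probe across the whole contact -- emulating a
#' receptor-site footprint of site-3 scale (default disk radius 15.5
#' Angstrom, a contact patch of roughly 800 Angstrom^2 per side).
#'
#' @param footprintRadius toxin disk radius, Angstrom.
#' @param gap vdW-surface separation across the contact, Angstrom
#'   (must be < 2 x probe radius for full burial).
#' @param spacing atom grid spacing, Angstrom.
#' @return A \code{MolecularSystem} (synthetic); group selections are
#'   \code{"chain P"} and \code{"chain T"}.
#' @export
makeSyntheticInterfaceComplex <- function(footprintRadius = 15.5,
                                          gap = 2.0, spacing = 1.8) {
  halfSlab <- ceiling((footprintRadius + 9) / spacing) * spacing
  g <- seq(-halfSlab, halfSlab, by = spacing)
  slab <- expand.grid(x = g, y = g)
  rows <- list()
  n <- 0L
  addLayer <- function(xy, z, chain, resname) {
    n <<- n + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      name = "CA", resname = resname,
      resid = seq_len(nrow(xy)) + 1000L * length(rows), chain = chain,
      x = xy[, 1], y = xy[, 2], z = z, stringsAsFactors = FALSE)
  }
  addLayer(as.matrix(slab), 0, "P", "GLY")
  addLayer(as.matrix(slab), -spacing, "P", "GLY")
  rC <- vdwRadii("C")
  zTox <- 2 * rC + gap                     # vdW surfaces gap apart
  disk <- as.matrix(slab[slab$x^2 + slab$y^2 <= footprintRadius^2, ])
  addLayer(disk, zTox, "T", "ALA")
  addLayer(disk, zTox + spacing, "T", "ALA")
  newMolecularSystem(do.call(rbind, rows),
                     label = "synthetic toxin-channel interface")
}

#' Synthetic Calpha trace
#'
#' A smooth random-walk Calpha chain (3.8 Angstrom steps with direction
#' momentum), used as a neutral protein-sized backbone for RMSD-scale
#' comparisons.
#'
#' @param n residues.
#' @param seed integer seed.
#' @param step Calpha-Calpha step, Angstrom.
#' @return A \code{MolecularSystem} (synthetic), chain A, residues 1..n.
#' @export
makeSyntheticCaTrace <- function(n, seed = 1L, step = 3.8) {
  set.seed(seed)
  dirs <- matrix(0, n, 3)
  d <- c(1, 0, 0)
  pos <- matrix(0, n, 3)
  for (i in 2:n) {
    d <- 0.8 * d + 0.4 * stats::rnorm(3)
    d <- d / sqrt(sum(d^2))
    pos[i, ] <- pos[i - 1, ] + step * d
  }
  newMolecularSystem(data.frame(name = "CA", resname = "ALA",
                                resid = seq_len(n), chain = "A",
                                x = pos[, 1], y = pos[, 2], z = pos[, 3],
                                stringsAsFactors = FALSE),
                     label = "synthetic CA trace")
}

#' Perturb a structure with Gaussian coordinate noise
#'
#' Adds independent zero-mean Gaussian noise (SD \code{sd} per
#' coordinate) to every atom, giving an expected all-atom RMSD of
#' \code{sd * sqrt(3)} to the original.
#'
#' @param system \code{MolecularSystem}.
#' @param sd per-coordinate noise SD, Angstrom.
#' @param seed integer seed.
#' @return The perturbed \code{MolecularSystem}.
#' @export
perturbStructure <- function(system, sd, seed = 1L) {
  set.seed(seed)
  cm <- .coordMatrix(system)
  .setCoords(system, cm + matrix(stats::rnorm(length(cm), 0, sd),
                                 ncol = 3))
}
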